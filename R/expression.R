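## Microarray stage: quantile normalisation, background subtraction,
## error-weighted one-way ANOVA, BH-FDR, signed linear fold changes,
## timepoint-specific set extraction and PCA.

#' Construct an ExpressionMatrix
#'
#' @param intensities numeric matrix, probes x samples, linear scale,
#'   strictly positive, with dimnames.
#' @param ses matrix of per-value standard errors, same shape.
#' @param groups character vector of group labels, one per sample.
#' @param rowTruth optional `DataFrame` of per-probe truth columns (used by
#'   the synthetic generator).
#' @return an [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(intensities, ses, groups, rowTruth = NULL) {
  stopifnot(identical(dim(intensities), dim(ses)),
            length(groups) == ncol(intensities))
  cd <- DataFrame(group = groups, row.names = colnames(intensities))
  se <- SummarizedExperiment(
    assays = list(intensity = intensities, se = ses), colData = cd)
  if (!is.null(rowTruth)) rowData(se) <- rowTruth
  new("ExpressionMatrix", se)
}

#' @rdname ExpressionMatrix-class
#' @param x an `ExpressionMatrix`
#' @export
setMethod("intensities", "ExpressionMatrix", function(x) assay(x, "intensity"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("standardErrors", "ExpressionMatrix", function(x) assay(x, "se"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("sampleGroups", "ExpressionMatrix", function(x)
  setNames(as.character(colData(x)$group), colnames(x)))

#' Quantile normalise an expression matrix
#'
#' Forces every sample to the same intensity distribution: each column's
#' sorted values are replaced by the across-column mean of sorted values
#' (ties receive the mean over their rank range). Standard errors are
#' rescaled by each value's normalisation ratio so relative errors are
#' preserved.
#'
#' @param x an [ExpressionMatrix-class] without missing values.
#' @return a normalised [ExpressionMatrix-class].
#' @export
quantileNormalize <- function(x) {
  y <- intensities(x)
  if (anyNA(y)) stop("missing values are not supported")
  if (ncol(y) == 1L) return(x)
  yn <- limma::normalizeQuantiles(y, ties = TRUE)
  dimnames(yn) <- dimnames(y)
  ratio <- yn / y
  ExpressionMatrix(pmax(yn, 1e-6), standardErrors(x) * ratio,
                   as.character(colData(x)$group),
                   rowTruth = rowData(x))
}

#' Background subtraction against negative-control probes
#'
#' Subtracts, per sample, the mean intensity of the listed negative-control
#' probes, flooring the result at a small positive constant so downstream
#' ratios stay defined.
#'
#' @param x an [ExpressionMatrix-class].
#' @param negctrlProbes character vector of control probe ids present in `x`.
#' @param floor lower bound applied after subtraction (1 by default).
#' @return a background-subtracted [ExpressionMatrix-class].
#' @export
backgroundSubtract <- function(x, negctrlProbes, floor = 1) {
  if (length(negctrlProbes) == 0) stop("empty negative-control list")
  if (!all(negctrlProbes %in% rownames(x)))
    stop("negative-control probes missing from the matrix")
  y <- intensities(x)
  bg <- colMeans(y[negctrlProbes, , drop = FALSE])
  y <- pmax(sweep(y, 2, bg), floor)
  ExpressionMatrix(y, standardErrors(x), as.character(colData(x)$group),
                   rowTruth = rowData(x))
}

#' Error-weighted one-way ANOVA
#'
#' One-way ANOVA in which each observation is weighted by the inverse
#' square of its measurement standard error. With all SEs equal this
#' reduces exactly to ordinary one-way ANOVA. The F statistic is
#' `[sum_g W_g (ybar_g - ybar)^2 / (k-1)] / [sum_i w_i (y_i - ybar_g(i))^2 / (N-k)]`
#' with `w_i = 1/se_i^2`, weighted group means `ybar_g` and weighted grand
#' mean `ybar`; p-values come from the `F(k-1, N-k)` upper tail.
#'
#' @param values numeric vector (one probe) or matrix (probes x samples).
#' @param ses standard errors, same shape, all positive.
#' @param groups group labels, one per sample; at least two groups and
#'   `N > k` observations.
#' @return data.frame with columns `statistic`, `p`, `df1`, `df2` and
#'   `degenerate` (TRUE where within-group variability was exactly zero;
#'   there `p` is reported as 0).
#' @export
errorWeightedAnova <- function(values, ses, groups) {
  if (is.vector(values)) {
    values <- matrix(values, nrow = 1)
    ses <- matrix(ses, nrow = 1)
  }
  if (any(ses <= 0)) stop("standard errors must be positive")
  f <- factor(groups)
  k <- nlevels(f)
  n <- length(groups)
  if (k < 2) stop("need at least two groups")
  if (n <= k) stop("need more observations than groups")

  ind <- stats::model.matrix(~ f - 1)           # samples x k
  w <- 1 / ses^2
  Wg <- w %*% ind                               # probes x k
  Sg <- (w * values) %*% ind
  ybarG <- Sg / Wg
  grand <- rowSums(w * values) / rowSums(w)
  ssb <- rowSums(Wg * (ybarG - grand)^2)
  fitted <- ybarG[, as.integer(f), drop = FALSE]
  ssw <- rowSums(w * (values - fitted)^2)

  degenerate <- ssw < .Machine$double.eps * rowSums(w * values^2 + 1)
  stat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(stat, k - 1, n - k, lower.tail = FALSE)
  p[degenerate & ssb > 0] <- 0
  p[degenerate & ssb == 0] <- 1
  stat[degenerate & ssb == 0] <- 0
  data.frame(statistic = stat, p = p, df1 = k - 1, df2 = n - k,
             degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone-enforced, capped at 1), returned in the
#' input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Signed linear fold change
#'
#' The display convention used for linear-scale microarray ratios: an
#' increase from `meanA` to `meanB` is `meanB / meanA`, a decrease is
#' `-(meanA / meanB)`, so the magnitude is always at least 1 and the sign
#' carries the direction.
#'
#' @param meanA,meanB positive group means (reference first).
#' @return signed ratio with `|fc| >= 1`; vectorised.
#' @export
foldChange <- function(meanA, meanB) {
  if (any(meanA <= 0) || any(meanB <= 0)) stop("group means must be positive")
  ifelse(meanB >= meanA, meanB / meanA, -(meanA / meanB))
}

#' Pairwise differential expression
#'
#' For each contrast (reference group, test group): per-probe error-weighted
#' ANOVA restricted to the two groups, BH adjustment within the contrast,
#' signed fold change of the inverse-variance weighted group means, and a
#' significance call at `q <= alpha`.
#'
#' @param x an [ExpressionMatrix-class].
#' @param contrasts list of 2-vectors `c(reference, test)`.
#' @param alpha FDR threshold (0.05).
#' @return named list (`"<test>_vs_<ref>"`) of data.frames with columns
#'   `probe_id`, `fold_change`, `statistic`, `p`, `q`, `significant`.
#' @export
pairwiseDE <- function(x, contrasts, alpha = 0.05) {
  groups <- sampleGroups(x)
  out <- lapply(contrasts, function(ct) {
    stopifnot(length(ct) == 2)
    if (!all(ct %in% groups)) stop("contrast group not found: ",
                                   paste(setdiff(ct, groups), collapse = ", "))
    sel <- groups %in% ct
    if (any(table(groups[sel]) < 2)) stop("each contrast group needs >= 2 samples")
    y <- intensities(x)[, sel, drop = FALSE]
    s <- standardErrors(x)[, sel, drop = FALSE]
    g <- groups[sel]
    aov <- errorWeightedAnova(y, s, g)
    w <- 1 / s^2
    wm <- function(grp) rowSums((w * y)[, g == grp, drop = FALSE]) /
      rowSums(w[, g == grp, drop = FALSE])
    fc <- foldChange(wm(ct[1]), wm(ct[2]))
    q <- bhAdjust(aov$p)
    data.frame(probe_id = rownames(x), fold_change = fc,
               statistic = aov$statistic, p = aov$p, q = q,
               significant = q <= alpha, row.names = NULL)
  })
  names(out) <- vapply(contrasts, function(ct) paste0(ct[2], "_vs_", ct[1]),
                       character(1))
  out
}

#' Timepoint-specific differentially expressed set
#'
#' Extracts the probes attributable to one timepoint. The default
#' (`"specific"`) rule keeps probes significant in the focal contrast and
#' in none of the others; `"intersection"` requires significance in every
#' contrast, `"union"` in any. The rule used is recorded in the result's
#' `"mode"` attribute.
#'
#' @param deList named list of [pairwiseDE] result tables.
#' @param focal name of the focal contrast (e.g. `"day2_vs_day0"`).
#' @param mode `"specific"`, `"intersection"` or `"union"`.
#' @return character vector of probe ids with attribute `mode`.
#' @export
timepointSpecificSet <- function(deList, focal = "day2_vs_day0",
                                 mode = c("specific", "intersection", "union")) {
  mode <- match.arg(mode)
  if (!focal %in% names(deList)) stop("missing focal contrast: ", focal)
  sig <- lapply(deList, function(d) d$probe_id[d$significant])
  others <- sig[setdiff(names(deList), focal)]
  ids <- switch(mode,
    specific = setdiff(sig[[focal]], unlist(others)),
    intersection = Reduce(intersect, sig),
    union = unique(unlist(sig)))
  structure(ids, mode = mode)
}

#' Principal-component sample scores
#'
#' Centred PCA of the log2 intensities (samples as observations), for
#' visualising group separation. Reporting only; nothing downstream depends
#' on it.
#'
#' @param x an [ExpressionMatrix-class].
#' @param nComponents number of components to return (<= number of samples).
#' @param scale. logical, scale probes to unit variance before rotation.
#' @param log2Transform take log2 of intensities first (TRUE).
#' @return data.frame with `sample`, `group` and `PC1..PCn` columns;
#'   attribute `"varianceExplained"` holds the per-component fractions.
#' @export
pcaScores <- function(x, nComponents = 2, scale. = FALSE,
                      log2Transform = TRUE) {
  y <- intensities(x)
  m <- t(if (log2Transform) log2(y) else y)
  if (scale.) m <- m[, apply(m, 2, stats::sd) > 0, drop = FALSE]
  pc <- prcomp(m, center = TRUE, scale. = scale.)
  if (nComponents > ncol(pc$x))
    stop("nComponents exceeds the rank of the matrix")
  scores <- pc$x[, seq_len(nComponents), drop = FALSE]
  out <- data.frame(sample = colnames(y),
                    group = as.character(colData(x)$group), scores,
                    row.names = NULL)
  attr(out, "varianceExplained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nComponents)]
  out
}
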