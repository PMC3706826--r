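## Synthetic-data generators. Every generator is deterministic for a fixed
## seed; all planted coordinates are aligned to the 200 bp window grid so
## the caller's window counts line up exactly with the truth.

.TRUTH_CLASSES <- c("bivalent", "k4_only", "k27_only", "unmarked")
.GRID <- 200L          # placement grid; matches the default caller window
.GENE_LENGTH <- 2000L  # synthetic gene body length

#' Plant two-mark ground truth on a genome layout
#'
#' Places non-overlapping gene slots along the chromosomes (filled in
#' chromosome order, so with few genes later chromosomes stay background
#' only), assigns each slot a randomly shuffled truth class, and plants
#' H3K4me3 / H3K27me3 enriched regions of `regionWidth` bp centred on the
#' gene's TSS according to that class. Slot spacing is
#' `2 * (regionWidth + 4000)` bp so that a TSS +/- 2 kb window of one gene
#' can never touch a neighbour's planted region. Region centres sit on the
#' 200 bp window grid and `regionWidth` must be a multiple of 400, which
#' makes every planted region exactly window-aligned.
#'
#' @param layout a [GenomeLayout-class].
#' @param nBivalent,nK4Only,nK27Only,nUnmarked gene counts per truth class.
#' @param regionWidth planted region width in bp (multiple of 400).
#' @param seed integer seed; identical seeds give identical truth.
#' @param enrichmentFold Poisson rate multiplier inside planted regions
#'   (>= 1; 8 by default, a strong mark).
#' @param backgroundRate background tags per 200 bp window (0.25 default).
#' @return a [PlantedTruth-class].
#' @examples
#' truth <- plantTruth(makeGenome(2, 500000), 5, 5, 5, 5, seed = 1)
#' table(truthClasses(truth))
#' @export
plantTruth <- function(layout, nBivalent, nK4Only, nK27Only, nUnmarked,
                       regionWidth = 2000, seed = 1,
                       enrichmentFold = 8, backgroundRate = 0.25) {
  if (regionWidth %% 400 != 0)
    stop("regionWidth must be a multiple of 400 so regions are window-aligned")
  counts <- c(nBivalent, nK4Only, nK27Only, nUnmarked)
  if (any(counts < 0)) stop("gene counts must be non-negative")
  n <- sum(counts)
  spacing <- 2 * (regionWidth + 4000)
  margin <- regionWidth / 2 + 4000

  ## candidate slot centres, chromosome by chromosome, snapped to the grid
  sl <- chromLengths(layout)
  centres <- list()
  for (chr in names(sl)) {
    len <- sl[[chr]]
    cand <- seq(margin, len - margin, by = spacing)
    cand <- .GRID * round(cand / .GRID)
    cand <- cand[cand - margin >= 0 & cand + margin <= len]
    centres[[chr]] <- cand
  }
  capacity <- sum(lengths(centres))
  if (n > capacity)
    stop("genome too small: ", n, " genes requested but only ",
         capacity, " slots fit")

  if (n == 0L) {
    empty <- GRanges(seqinfo = seqinfo(layout))
    return(new("PlantedTruth",
               k4Regions = empty, k27Regions = empty, genes = empty,
               enrichmentFold = enrichmentFold, backgroundRate = backgroundRate))
  }

  chrOf <- rep(names(centres), lengths(centres))[seq_len(n)]
  ctr <- unlist(centres, use.names = FALSE)[seq_len(n)]

  withr::with_seed(seed, {
    cls <- sample(rep(.TRUTH_CLASSES, counts))
    strands <- sample(c("+", "-"), n, replace = TRUE)
  })

  ## genes: TSS at the slot centre (0-based coordinate == centre)
  tss0 <- ctr
  gStart1 <- ifelse(strands == "+", tss0 + 1, tss0 + 2 - .GENE_LENGTH)
  genes <- GRanges(chrOf, IRanges(gStart1, width = .GENE_LENGTH),
                   strand = strands, seqinfo = seqinfo(layout))
  genes$gene_id <- sprintf("geneS%03d", seq_len(n))
  genes$truth_class <- cls

  half <- regionWidth / 2
  regionFor <- function(keep) {
    if (!any(keep)) return(GRanges(seqinfo = seqinfo(layout)))
    GRanges(chrOf[keep], IRanges(ctr[keep] - half + 1, ctr[keep] + half),
            seqinfo = seqinfo(layout))
  }
  k4 <- regionFor(cls %in% c("bivalent", "k4_only"))
  k27 <- regionFor(cls %in% c("bivalent", "k27_only"))

  new("PlantedTruth", k4Regions = sort(k4), k27Regions = sort(k27),
      genes = genes, enrichmentFold = enrichmentFold,
      backgroundRate = backgroundRate)
}

#' @rdname PlantedTruth-class
#' @param x a `PlantedTruth`
#' @param mark `"H3K4me3"` or `"H3K27me3"`
#' @export
setMethod("plantedGenes", "PlantedTruth", function(x) x@genes)

#' @rdname PlantedTruth-class
#' @export
setMethod("plantedRegions", "PlantedTruth", function(x, mark) {
  switch(match.arg(mark, c("H3K4me3", "H3K27me3")),
         H3K4me3 = x@k4Regions, H3K27me3 = x@k27Regions)
})

#' @rdname PlantedTruth-class
#' @export
setMethod("truthClasses", "PlantedTruth", function(x)
  setNames(x@genes$truth_class, x@genes$gene_id))

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@genes), "genes (",
      paste(names(table(object@genes$truth_class)),
            table(object@genes$truth_class), collapse = ", "), ");",
      length(object@k4Regions), "K4 /", length(object@k27Regions),
      "K27 regions; fold", object@enrichmentFold,
      "over background", object@backgroundRate, "tags/window\n")
})

#' Simulate ChIP-seq tags for one mark against planted truth
#'
#' Window-level counts are drawn from `Poisson(backgroundRate)` outside the
#' planted regions of `mark` and `Poisson(backgroundRate * enrichmentFold)`
#' in windows fully inside a region; each tag is then placed uniformly
#' within its window. No fragment-shift is modelled: the emitted position is
#' the counted position.
#'
#' @param truth a [PlantedTruth-class].
#' @param layout the generating [GenomeLayout-class].
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param window window size in bp (200 default).
#' @param seed integer seed.
#' @return a [TagCollection-class].
#' @export
simulateTags <- function(truth, layout, mark, window = 200, seed = 1) {
  mark <- match.arg(mark, c("H3K4me3", "H3K27me3"))
  if (truth@backgroundRate <= 0) stop("backgroundRate must be positive")
  regions <- plantedRegions(truth, mark)
  w <- as.integer(window)
  sl <- chromLengths(layout)

  grs <- withr::with_seed(seed, {
    lapply(names(sl), function(chr) {
      len <- sl[[chr]]
      nW <- ceiling(len / w)
      rate <- rep(truth@backgroundRate, nW)
      reg <- regions[seqnames(regions) == chr]
      for (i in seq_along(reg)) {
        s0 <- start(reg)[i] - 1L  # 0-based region bounds
        e0 <- end(reg)[i]
        inside <- which((seq_len(nW) - 1L) * w >= s0 & seq_len(nW) * w <= e0)
        rate[inside] <- truth@backgroundRate * truth@enrichmentFold
      }
      cnt <- rpois(nW, rate)
      if (sum(cnt) == 0) return(GRanges(seqinfo = seqinfo(layout)))
      winIdx <- rep(seq_len(nW) - 1L, cnt)
      winWidth <- pmin(w, len - winIdx * w)
      pos0 <- winIdx * w + floor(runif(length(winIdx)) * winWidth)
      GRanges(chr, IRanges(pos0 + 1, width = 1), seqinfo = seqinfo(layout))
    })
  })
  TagCollection(mark, sort(do.call(c, grs)))
}

#' Simulate a probe x sample expression matrix with planted effects
#'
#' Non-differential probes share a group-independent mean intensity drawn
#' from a log-normal; differential probes are shifted by `lfc` (log2, with
#' random sign) in `deGroup`. Per-value standard errors are
#' `seScale * baseline * c` with `c` drawn from a scaled chi distribution
#' (`sqrt(chisq(df)/df)`, mean ~ 1), and observed intensities are the group
#' mean plus Gaussian noise of exactly that standard error — so the
#' downstream inverse-variance weights are correctly specified.
#'
#' @param nProbes number of probes.
#' @param design character vector of group labels, one per sample (e.g.
#'   `rep(c("day0","day2","day4","day10","HSVEC"), each = 3)`).
#' @param nDe number of differential probes planted (<= nProbes).
#' @param lfc absolute planted log2 fold change.
#' @param seScale relative standard-error scale (unitless).
#' @param deGroup group receiving the planted shift.
#' @param seDf degrees of freedom of the chi noise on the SEs.
#' @param seed integer seed.
#' @return an [ExpressionMatrix-class] with truth columns `is_de` and
#'   `true_lfc` in `rowData`.
#' @export
simulateExpression <- function(nProbes, design, nDe, lfc = 1, seScale = 0.1,
                               deGroup = "day2", seDf = 4, seed = 1) {
  groups <- unique(design)
  if (length(groups) < 2) stop("degenerate design: need at least two groups")
  if (any(table(design) < 2)) stop("every group needs >= 2 samples")
  if (nDe > nProbes) stop("nDe must not exceed nProbes")
  if (nDe > 0 && !deGroup %in% groups) stop("deGroup not in design")
  nS <- length(design)

  withr::with_seed(seed, {
    base <- rlnorm(nProbes, meanlog = log(500), sdlog = 1)
    trueLfc <- numeric(nProbes)
    if (nDe > 0) {
      deIdx <- sample.int(nProbes, nDe)
      trueLfc[deIdx] <- sample(c(-1, 1), nDe, replace = TRUE) * lfc
    }
    mu <- matrix(base, nProbes, nS)
    shifted <- design == deGroup
    mu[, shifted] <- mu[, shifted] * 2^trueLfc
    se <- seScale * base * matrix(sqrt(rchisq(nProbes * nS, seDf) / seDf),
                                  nProbes, nS)
    y <- mu + matrix(rnorm(nProbes * nS), nProbes, nS) * se
    y <- pmax(y, 1e-6)
  })

  probes <- sprintf("P%05d", seq_len(nProbes))
  reps <- stats::ave(seq_len(nS), design, FUN = seq_along)
  samples <- paste0(design, "_r", reps)
  dimnames(y) <- dimnames(se) <- list(probes, samples)
  ExpressionMatrix(y, se, design,
                   rowTruth = DataFrame(is_de = trueLfc != 0, true_lfc = trueLfc))
}

#' Simulate a qPCR Ct table with known relative quantity
#'
#' Produces replicate Ct rows for a calibrator and a test sample over a
#' target and an endogenous-control assay. The test sample's target Ct is
#' `ctRef - log2(trueRq)` plus Gaussian noise; control Cts are flat, so the
#' comparative-Ct pipeline should recover `trueRq` exactly at zero noise.
#'
#' @param trueRq true relative quantity of the test sample (> 0).
#' @param ctRef calibrator target Ct (cycles).
#' @param noiseSd Gaussian Ct noise, cycles (target rows only).
#' @param nRep technical replicates per (sample, target).
#' @param ctControl flat endogenous-control Ct.
#' @param seed integer seed.
#' @return data.frame with columns sample, target, replicate, ct.
#' @export
simulateCtTable <- function(trueRq, ctRef = 25, noiseSd = 0, nRep = 3,
                            ctControl = 18, seed = 1) {
  if (trueRq <= 0) stop("trueRq must be positive")
  if (nRep < 1) stop("nRep must be >= 1")
  withr::with_seed(seed, {
    calTarget <- ctRef + rnorm(nRep, 0, noiseSd)
    testTarget <- ctRef - log2(trueRq) + rnorm(nRep, 0, noiseSd)
  })
  rbind(
    data.frame(sample = "calibrator", target = "target",
               replicate = seq_len(nRep), ct = calTarget),
    data.frame(sample = "test", target = "target",
               replicate = seq_len(nRep), ct = testTarget),
    data.frame(sample = rep(c("calibrator", "test"), each = nRep),
               target = "control", replicate = rep(seq_len(nRep), 2),
               ct = ctControl)
  )
}
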