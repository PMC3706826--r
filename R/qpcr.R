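## Comparative-Ct quantitation and ChIP-qPCR enrichment. Amplification
## efficiency is fixed at 2 per cycle (the classic comparative method);
## replicates are averaged on the Ct scale before exponentiation.

#' Relative quantity by the comparative (delta-delta-Ct) method
#'
#' Replicate Cts are averaged per (sample, target); per sample,
#' `dCt = Ct_target - Ct_control`; against the calibrator,
#' `ddCt = dCt_sample - dCt_calibrator` and `RQ = 2^-ddCt`. The calibrator's
#' RQ is 1 by construction.
#'
#' @param ct data.frame with columns `sample`, `target`, `ct` (a
#'   `replicate` column is allowed and ignored).
#' @param target name of the target assay in the `target` column.
#' @param control name of the endogenous-control assay.
#' @param calibrator name of the calibrator sample.
#' @return data.frame with `sample`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @examples
#' tab <- simulateCtTable(trueRq = 2, noiseSd = 0)
#' relativeQuantity(tab)
#' @export
relativeQuantity <- function(ct, target = "target", control = "control",
                             calibrator = "calibrator") {
  need <- c("sample", "target", "ct")
  if (!all(need %in% names(ct))) stop("ct table needs columns sample, target, ct")
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  mean_ct <- stats::aggregate(ct ~ sample + target, data = ct, FUN = mean)
  wide <- merge(mean_ct[mean_ct$target == target, c("sample", "ct")],
                mean_ct[mean_ct$target == control, c("sample", "ct")],
                by = "sample", suffixes = c("_target", "_control"),
                all.x = TRUE)
  if (anyNA(wide$ct_control))
    stop("missing endogenous control for sample(s): ",
         paste(wide$sample[is.na(wide$ct_control)], collapse = ", "))
  if (!calibrator %in% wide$sample) stop("calibrator sample not present")
  wide$delta_ct <- wide$ct_target - wide$ct_control
  dctCal <- wide$delta_ct[wide$sample == calibrator]
  wide$delta_delta_ct <- wide$delta_ct - dctCal
  wide$rq <- 2^(-wide$delta_delta_ct)
  wide[, c("sample", "delta_ct", "delta_delta_ct", "rq")]
}

#' ChIP-qPCR input container
#'
#' @param ctIp named numeric vector of immunoprecipitation Cts, one per
#'   antibody (e.g. H3K4me3, H3K27me3, H3).
#' @param ctIgg Ct of the IgG negative-control immunoprecipitation.
#' @param ctInput Ct of the non-immunoprecipitated chromatin input.
#' @param inputFraction fraction of chromatin used as input (0.02 for the
#'   conventional 2 percent input).
#' @return list of class `EnrichmentInput`.
#' @export
enrichmentInput <- function(ctIp, ctIgg, ctInput = NA_real_,
                            inputFraction = 0.02) {
  if (inputFraction <= 0 || inputFraction > 1)
    stop("inputFraction must lie in (0, 1]")
  if (is.null(names(ctIp)) || any(!nzchar(names(ctIp))))
    stop("ctIp must be a named vector (one Ct per antibody)")
  structure(list(ctIp = ctIp, ctIgg = ctIgg, ctInput = ctInput,
                 inputFraction = inputFraction),
            class = "EnrichmentInput")
}

#' Fold enrichment over the IgG negative control
#'
#' `2^(Ct_IgG - Ct_IP)`: one cycle earlier than IgG doubles the enrichment.
#'
#' @param inp an [enrichmentInput] object.
#' @param antibody name of the antibody in `ctIp`.
#' @return unitless fold enrichment.
#' @export
foldEnrichment <- function(inp, antibody) {
  if (is.na(inp$ctIgg)) stop("IgG Ct is required")
  if (!antibody %in% names(inp$ctIp)) stop("unknown antibody: ", antibody)
  2^(inp$ctIgg - inp$ctIp[[antibody]])
}

#' Percent of input recovered by an immunoprecipitation
#'
#' The input Ct is first adjusted to a 100 percent-input equivalent
#' (`ctInput - log2(1 / inputFraction)`), then
#' `%input = 100 * 2^(adjusted - Ct_IP)`.
#'
#' @inheritParams foldEnrichment
#' @return percentage of input.
#' @export
percentInput <- function(inp, antibody) {
  if (is.na(inp$ctInput)) stop("input Ct is required")
  if (!antibody %in% names(inp$ctIp)) stop("unknown antibody: ", antibody)
  adjusted <- inp$ctInput - log2(1 / inp$inputFraction)
  100 * 2^(adjusted - inp$ctIp[[antibody]])
}
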