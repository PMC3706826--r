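makeEM <- function(y, groups, se = NULL) {
  if (is.null(se)) se <- matrix(1, nrow(y), ncol(y))
  dimnames(y) <- list(paste0("p", seq_len(nrow(y))),
                      paste0("s", seq_len(ncol(y))))
  dimnames(se) <- dimnames(y)
  ExpressionMatrix(y, se, groups)
}

test_that("quantileNormalize equalises column distributions", {
  ## hand calculation: columns (1,3) and (2,8) both become (1.5, 5.5)
  em <- makeEM(matrix(c(1, 3, 2, 8), 2), c("a", "b"))
  got <- intensities(quantileNormalize(em))
  expect_equal(unname(got), matrix(c(1.5, 5.5, 1.5, 5.5), 2))

  ## a single column is left untouched
  one <- makeEM(matrix(c(4, 2, 9), 3), "a")
  expect_equal(intensities(quantileNormalize(one)), intensities(one))

  ## all columns share the same sorted vector afterwards; idempotent
  set.seed(1)
  em2 <- makeEM(matrix(rlnorm(200), 50), rep(c("a", "b"), each = 2))
  n1 <- quantileNormalize(em2)
  srt <- apply(intensities(n1), 2, sort)
  expect_true(all(abs(srt - srt[, 1]) < 1e-12))
  n2 <- quantileNormalize(n1)
  expect_equal(intensities(n2), intensities(n1), tolerance = 1e-12)
})

test_that("backgroundSubtract removes the control mean with a floor", {
  y <- matrix(c(250, 100, 100, 350, 100, 100), 3,
              dimnames = list(c("probe", "neg1", "neg2"), c("s1", "s2")))
  em <- ExpressionMatrix(y, matrix(1, 3, 2), c("a", "a"))
  out <- intensities(backgroundSubtract(em, c("neg1", "neg2")))
  expect_equal(unname(out["probe", ]), c(150, 250))

  ## all-zero controls leave the matrix unchanged (no real zeros allowed,
  ## so use a tiny positive control intensity and a generous tolerance)
  yz <- matrix(c(250, 1e-6, 350, 1e-6), 2,
               dimnames = list(c("probe", "neg"), c("s1", "s2")))
  emz <- ExpressionMatrix(yz, matrix(1, 2, 2), c("a", "a"))
  expect_equal(intensities(backgroundSubtract(emz, "neg"))["probe", ],
               yz["probe", ], tolerance = 1e-6)

  ## value below the control mean is floored
  yf <- matrix(c(50, 100, 100), 3,
               dimnames = list(c("probe", "neg1", "neg2"), "s1"))
  emf <- ExpressionMatrix(yf, matrix(1, 3, 1), "a")
  expect_equal(unname(intensities(backgroundSubtract(emf, c("neg1", "neg2")))["probe", ]), 1)

  expect_error(backgroundSubtract(em, character(0)), "empty")
})

test_that("errorWeightedAnova reduces to ordinary ANOVA with equal SEs", {
  g <- rep(c("a", "b", "c"), each = 6)
  set.seed(3)
  for (rep in 1:5) {
    y <- rnorm(18, mean = rep(c(0, 0.5, 2), each = 6))
    ewa <- errorWeightedAnova(y, rep(1.7, 18), g)
    ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
    expect_equal(ewa$statistic, unname(ow$statistic), tolerance = 1e-10)
    expect_equal(ewa$p, unname(ow$p.value), tolerance = 1e-10)
  }

  ## flat data: F = 0, p = 1
  flat <- errorWeightedAnova(rep(10, 8), rep(1, 8), rep(c("a", "b"), 4))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  ## zero within-group variability with a real effect: flagged, p = 0
  degen <- errorWeightedAnova(rep(c(1, 5), each = 4), rep(1, 8),
                              rep(c("a", "b"), each = 4))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)

  expect_error(errorWeightedAnova(1:4, rep(1, 4), rep("a", 4)), "two groups")
  expect_error(errorWeightedAnova(1:2, rep(1, 2), c("a", "b")), "observations")
})

test_that("weighted-ANOVA p-values are uniform under the heteroscedastic null", {
  design <- rep(c("day0", "day2", "day4", "day10", "HSVEC"), each = 3)
  em <- simulateExpression(2000, design, nDe = 0, seed = 11)
  p <- errorWeightedAnova(intensities(em), standardErrors(em), design)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("bhAdjust reproduces the step-up hand computation", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  ## hand computation: m=4; 0.01*4/1, 0.02*4/2, 0.04*4/3, 0.8 -> monotone
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.16 / 3, 0.8))
  ## order invariance
  p <- c(0.04, 0.8, 0.01, 0.02)
  expect_equal(bhAdjust(p)[order(p)], bhAdjust(sort(p)))
  expect_error(bhAdjust(numeric(0)), "empty")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("foldChange follows the signed-reciprocal display convention", {
  expect_equal(foldChange(10, 20), 2)
  expect_equal(foldChange(10, 5), -2)
  expect_equal(foldChange(7, 7), 1)
  ## antisymmetry away from the unit boundary
  set.seed(5)
  a <- runif(20, 1, 50); b <- runif(20, 1, 50)
  keep <- abs(a / b - 1) > 0.01
  expect_equal(foldChange(a, b)[keep], -foldChange(b, a)[keep])
  expect_true(all(abs(foldChange(a, b)) >= 1))
  expect_error(foldChange(0, 1), "positive")
})

test_that("pairwiseDE recovers planted effects with controlled error", {
  design <- rep(c("day0", "day2", "day4", "day10", "HSVEC"), each = 3)
  em <- simulateExpression(2000, design, nDe = 200, lfc = 1, seScale = 0.05,
                           seed = 12)
  de <- pairwiseDE(em, list(c("day0", "day2")))$day2_vs_day0
  truth <- rowData(em)$is_de
  called <- de$significant
  expect_gte(sum(called & truth) / sum(truth), 0.8)          # sensitivity
  expect_lte(sum(called & !truth) / max(1, sum(called)), 0.08)  # empirical FDR
  ## recovered direction always matches the planted direction
  rec <- called & truth
  expect_true(all(sign(de$fold_change[rec]) ==
                  sign(rowData(em)$true_lfc[rec])))
  expect_true(all(de$q >= de$p))

  ## identical groups: false positives bounded by expectation under the null
  em0 <- simulateExpression(1000, design, nDe = 0, seed = 13)
  de0 <- pairwiseDE(em0, list(c("day0", "day4")))$day4_vs_day0
  expect_lte(sum(de0$significant), 0.05 * 1000)
  expect_error(pairwiseDE(em, list(c("day0", "nope"))), "not found")
})

test_that("timepointSpecificSet applies the specificity rule", {
  mk <- function(ids, sig) data.frame(probe_id = ids, significant = sig)
  deList <- list(
    day2_vs_day0 = mk(c("a", "b", "c"), c(TRUE, TRUE, FALSE)),
    day4_vs_day0 = mk(c("a", "b", "c"), c(FALSE, FALSE, FALSE)),
    day10_vs_day0 = mk(c("a", "b", "c"), c(FALSE, TRUE, TRUE)))
  expect_equal(as.character(timepointSpecificSet(deList)), "a")
  expect_equal(as.character(timepointSpecificSet(deList, mode = "union")),
               c("a", "b", "c"))
  expect_length(timepointSpecificSet(deList, mode = "intersection"), 0)
  expect_error(timepointSpecificSet(deList, focal = "day7_vs_day0"), "missing")

  empty <- lapply(deList, function(d) d[0, ])
  expect_length(timepointSpecificSet(empty), 0)
})

test_that("pcaScores reports consistent, group-separating coordinates", {
  design <- rep(c("day0", "day2", "HSVEC"), each = 3)
  em <- simulateExpression(400, design, nDe = 120, lfc = 3, seScale = 0.05,
                           deGroup = "HSVEC", seed = 14)
  pc <- pcaScores(em, 2)
  ve <- attr(pc, "varianceExplained")
  expect_lte(sum(ve), 1)
  ## the mature-EC-like group separates from the rest on PC1
  hs <- pc$PC1[pc$group == "HSVEC"]
  rest <- pc$PC1[pc$group != "HSVEC"]
  expect_true(max(hs) < min(rest) || min(hs) > max(rest))

  ## a duplicated sample gets identical scores
  y <- intensities(em); s <- standardErrors(em)
  y2 <- cbind(y, dup = y[, 1]); s2 <- cbind(s, dup = s[, 1])
  em2 <- ExpressionMatrix(y2, s2, c(design, design[1]))
  pc2 <- pcaScores(em2, 2)
  expect_equal(unlist(pc2[1, c("PC1", "PC2")]),
               unlist(pc2[nrow(pc2), c("PC1", "PC2")]), tolerance = 1e-8)

  expect_error(pcaScores(em, 50), "rank|exceeds")
})
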