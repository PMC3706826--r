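test_that("poissonTail matches closed forms and direct pmf summation", {
  expect_equal(poissonTail(0, 3.7), 1)
  expect_equal(poissonTail(1, 1), 1 - exp(-1))
  ## independent oracle: sum the pmf terms directly
  directTail <- function(k, lambda)
    1 - sum(exp(-lambda) * lambda^(0:(k - 1)) / factorial(0:(k - 1)))
  expect_equal(poissonTail(3, 1), directTail(3, 1), tolerance = 1e-12)
  expect_equal(poissonTail(3, 1), 0.080301, tolerance = 1e-5)
  expect_equal(poissonTail(7, 2.5), directTail(7, 2.5), tolerance = 1e-12)
  expect_error(poissonTail(-1, 1), "non-negative")
  expect_error(poissonTail(1, 0), "positive")
})

test_that("eligibilityThreshold picks the smallest sub-p0 count and is monotone", {
  expect_equal(eligibilityThreshold(1, 0.2), 3)     # tails .264 at 2, .080 at 3
  expect_equal(eligibilityThreshold(1e-6, 0.2), 1)  # P(X>=1) ~ lambda < p0
  for (lambda in c(0.1, 0.5, 1, 3, 10)) {
    ks <- vapply(c(0.5, 0.2, 0.1, 0.01, 0.001),
                 function(p0) eligibilityThreshold(lambda, p0), integer(1))
    expect_true(all(diff(ks) >= 0))          # decreasing p0 never decreases k
    k <- eligibilityThreshold(lambda, 0.2)   # definition check
    expect_lt(poissonTail(k, lambda), 0.2)
    if (k > 1) expect_gte(poissonTail(k - 1, lambda), 0.2)
  }
})

test_that("countWindowTags assigns, shifts and conserves tags", {
  layout <- makeGenome(1, 10000)
  empty <- TagCollection("H3K4me3", GRanges(seqinfo = seqinfo(layout)))
  wc <- countWindowTags(empty, layout, 200)
  expect_true(all(wc@counts$chrS1 == 0))

  ## 0-based positions 0, 150, 250 -> windows {0,0,1}
  tc <- TagCollection("H3K4me3",
    GRanges("chrS1", IRanges(c(1, 151, 251), width = 1),
            seqinfo = seqinfo(layout)))
  cnt <- countWindowTags(tc, layout, 200)@counts$chrS1
  expect_equal(cnt[1:2], c(2, 1))
  expect_equal(sum(cnt), 3)

  ## last base lands in the last window
  last <- TagCollection("H3K4me3",
    GRanges("chrS1", IRanges(10000, width = 1), seqinfo = seqinfo(layout)))
  cntL <- countWindowTags(last, layout, 200)@counts$chrS1
  expect_equal(cntL[50], 1)

  ## strand-directed shift: + moves right, - moves left; clamped at ends
  stranded <- TagCollection("H3K4me3",
    GRanges("chrS1", IRanges(c(151, 251, 1, 10000), width = 1),
            strand = c("+", "-", "-", "+"), seqinfo = seqinfo(layout)))
  cntS <- countWindowTags(stranded, layout, 200, shift = 75)@counts$chrS1
  expect_equal(cntS[1], 2)   # clamped minus tag at base 1, and 250-75=175
  expect_equal(cntS[2], 1)   # 150+75=225
  expect_equal(cntS[50], 1)  # clamped plus tag at the end
  expect_equal(sum(cntS), 4) # conservation under shift

  ## conservation on random tags
  set.seed(1)
  pos <- sample(10000, 500, replace = TRUE)
  rnd <- TagCollection("H3K27me3",
    GRanges("chrS1", IRanges(sort(pos), width = 1), seqinfo = seqinfo(layout)))
  expect_equal(sum(countWindowTags(rnd, layout, 200)@counts$chrS1), 500)
})

test_that("linkIslands bridges short gaps and agrees with brute force", {
  ## hand traces of the [1,1,0,1] mask
  m <- c(TRUE, TRUE, FALSE, TRUE)
  one <- linkIslands(m, g = 200, w = 200)
  expect_equal(unname(one), matrix(c(1L, 4L), 1))
  two <- linkIslands(m, g = 0, w = 200)
  expect_equal(unname(two), matrix(c(1L, 4L, 2L, 4L), 2))
  expect_equal(nrow(linkIslands(rep(FALSE, 6), 200, 200)), 0)
  expect_error(linkIslands(m, g = 300, w = 200), "multiple")

  ## exhaustive random-mask comparison against the quadratic enumerator
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    mask <- runif(n) < 0.35
    gmax <- sample(0:4, 1)
    got <- linkIslands(mask, g = gmax * 200, w = 200)
    want <- bruteIslands(mask, gmax)
    expect_equal(unname(got), unname(want))
  }
})

test_that("islandScore sums -log pmf over eligible windows only", {
  expect_equal(islandScore(integer(0), logical(0), 1), 0)
  expect_equal(islandScore(c(3L), c(TRUE), 1), 1 + log(6))
  expect_equal(islandScore(c(3L, 5L), c(TRUE, FALSE), 1), 1 + log(6))
  ## additivity under concatenation
  c1 <- c(2L, 0L, 3L); m1 <- c(TRUE, FALSE, TRUE)
  c2 <- c(4L, 2L); m2 <- c(TRUE, TRUE)
  expect_equal(islandScore(c(c1, c2), c(m1, m2), 0.5),
               islandScore(c1, m1, 0.5) + islandScore(c2, m2, 0.5))
})

test_that("calibrateScoreThreshold respects the E-value semantics", {
  ## huge E: everything passes
  expect_equal(calibrateScoreThreshold(0.25, 1000, 600, eValue = 1e9,
                                       seed = 1), 0)
  ## monotone: stricter E never lowers the threshold
  s01 <- calibrateScoreThreshold(0.25, 5000, 600, eValue = 0.1, seed = 7)
  s10 <- calibrateScoreThreshold(0.25, 5000, 600, eValue = 1.0, seed = 7)
  expect_gte(s01, s10)
  ## deterministic per seed
  expect_identical(s01, calibrateScoreThreshold(0.25, 5000, 600,
                                                eValue = 0.1, seed = 7))
  ## self-consistency on fresh background
  thr <- calibrateScoreThreshold(0.3, 2000, 400, eValue = 0.5, mcReps = 200,
                                 seed = 11)
  kMin <- eligibilityThreshold(0.3, 0.2)
  set.seed(99)
  surviving <- vapply(1:200, function(r) {
    cnt <- rpois(2000, 0.3)
    msk <- cnt >= kMin
    isl <- linkIslands(msk, 400, 200)
    if (nrow(isl) == 0) return(0L)
    sc <- vapply(seq_len(nrow(isl)), function(i) {
      idx <- seq(isl[i, "start"], isl[i, "end"])
      islandScore(cnt[idx], msk[idx], 0.3)
    }, numeric(1))
    sum(sc >= thr)
  }, integer(1))
  expect_lte(mean(surviving), 3 * 0.5)
})

test_that("callDomains recovers planted truth and leaves background clean", {
  layout <- studyLayout()
  truth <- plantTruth(layout, 5, 5, 5, 5, seed = 1)
  tc <- simulateTags(truth, layout, "H3K4me3", seed = 2)
  ds <- callDomains(tc, layout, CallerParams(gapSize = 600))

  reg <- plantedRegions(truth, "H3K4me3")
  expect_equal(sum(overlapsAny(reg, domains(ds))), length(reg))
  expect_equal(sum(seqnames(domains(ds)) == "chrS2"), 0)

  ## domain structure invariants
  d <- domains(ds)
  expect_true(all(d$island_score >= scoreThreshold(ds)))
  expect_true(all((start(d) - 1) %% 200 == 0))
  kMin <- ds@kMin
  wc <- countWindowTags(tc, layout, 200)
  for (i in seq_along(d)) {
    chr <- as.character(seqnames(d))[i]
    w0 <- (start(d)[i] - 1) / 200 + 1
    w1 <- ceiling(end(d)[i] / 200)
    expect_gte(wc@counts[[chr]][w0], kMin)  # boundary windows eligible
    expect_gte(wc@counts[[chr]][w1], kMin)
  }

  expect_error(callDomains(
    TagCollection("H3K4me3", GRanges(seqinfo = seqinfo(layout))), layout),
    "empty")
})

test_that("candidate-island coverage grows with the gap size", {
  set.seed(13)
  for (rep in 1:20) {
    mask <- runif(150) < 0.25
    cover <- function(g) {
      isl <- linkIslands(mask, g, 200)
      if (nrow(isl) == 0) return(integer(0))
      unlist(lapply(seq_len(nrow(isl)),
                    function(i) seq(isl[i, "start"], isl[i, "end"])))
    }
    expect_true(all(cover(200) %in% cover(1000)))
  }
})

test_that("a genome with no eligible windows yields an empty DomainSet", {
  layout <- makeGenome(1, 10000)  # 50 windows
  ## one tag per window: lambda = 1, kMin = 3, nothing eligible
  tc <- TagCollection("H3K4me3",
    GRanges("chrS1", IRanges(seq(100, 9900, by = 200), width = 1),
            seqinfo = seqinfo(layout)))
  ds <- callDomains(tc, layout, CallerParams(gapSize = 200))
  expect_length(domains(ds), 0)
})
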