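## Independent oracles and small fixture builders shared across tests.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## Brute-force island enumerator. V[i, j] says windows i..j form a valid
## candidate (eligible endpoints, no internal ineligible run longer than
## gmax); an island is a valid pair that cannot be extended on either side.
## Quadratic and entirely independent of the package's diff/which logic.
bruteIslands <- function(mask, gmax) {
  n <- length(mask)
  V <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!mask[i]) next
    run <- 0L
    for (j in i:n) {
      if (mask[j]) {
        run <- 0L
        V[i, j] <- TRUE
      } else {
        run <- run + 1L
        if (run > gmax) break
      }
    }
  }
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!V[i, j]) next
      extendableLeft <- i > 1L && any(V[seq_len(i - 1L), j])
      extendableRight <- j < n && any(V[i, seq(j + 1L, n)])
      if (!extendableLeft && !extendableRight) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  colnames(out) <- c("start", "end")
  out
}

## Base-by-base overlap scan between one window and a set of domains.
bruteOverlapsAny <- function(win, doms) {
  doms <- doms[as.character(seqnames(doms)) == as.character(seqnames(win))]
  if (length(doms) == 0) return(FALSE)
  bases <- seq(start(win), end(win))
  for (i in seq_along(doms))
    if (any(bases >= start(doms)[i] & bases <= end(doms)[i])) return(TRUE)
  FALSE
}

## Hand-built DomainSet around explicit intervals (threshold 0 so the
## validity check passes whatever the scores).
makeDomainSet <- function(mark, gap, chrom, starts, ends, scores = NULL) {
  gr <- GRanges(chrom, IRanges(starts, ends))
  if (length(gr) > 0)
    gr$island_score <- if (is.null(scores)) rep(1, length(gr)) else scores
  new("DomainSet", mark = mark, gapSize = as.integer(gap), domains = gr,
      lambda = 1, kMin = 1L, scoreThreshold = 0,
      params = CallerParams(gapSize = gap))
}

## Study-scale synthetic genome shared by the recovery tests: 1 Mb over two
## chromosomes; planted genes fill chrS1, leaving chrS2 background-only.
studyLayout <- function() makeGenome(2, 500000)
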