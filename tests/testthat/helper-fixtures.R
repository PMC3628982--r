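# small in-code fixtures shared across test files

tiny_catalog <- function() {
  transcript_catalog(
    c("tA", "tB", "tC", "tD"),
    c(1000, 2000, 500, 1500),
    description = c("alpha", "beta", "gamma", "delta"),
    go_terms = list("GO:0007049", c("GO:0007049", "GO:0005856"),
                    character(0), "GO:0005856"))
}

tiny_libraries <- function(catalog = tiny_catalog()) {
  lapply(c("4dv", "4dd", "8dv", "8dd"), function(cond) {
    counts <- c(tA = 10, tB = 40, tC = 0, tD = 25)
    library_counts(cond, counts, 1e6)
  })
}

# brute-force two-sided Fisher p by enumeration over margin-fixed tables,
# using log-factorials only (independent of dhyper)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(m, k)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
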