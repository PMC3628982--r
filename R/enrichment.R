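# Gene Ontology enrichment of transcript groups: per-term 2x2 contingency
# tables tested with Fisher's exact test, Benjamini-Hochberg FDR across all
# tested terms.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table (the convention of [stats::fisher.test()]). Degenerate
#' tables (an empty row or column) return p = 1.
#'
#' @param a,b,c,d non-negative integer cells: `a` test-set members carrying
#'   the term, `b` test-set members without it, `c` and `d` likewise for the
#'   reference set.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  m <- a + b            # test-set size
  n <- c + d            # reference-set size
  k <- a + c            # transcripts carrying the term
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards ties against floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' One-sided (enrichment) Fisher p-value
#'
#' Upper hypergeometric tail: probability of observing `a` or more test-set
#' members carrying the term given the margins.
#'
#' @inheritParams fisher_exact_two_sided
#' @return The one-sided p-value.
#' @export
fisher_exact_enrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0) return(1)
  stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q(i) = min over j with p(j) >= p(i) of
#' p(j) * m / rank(j)`, capped at 1, returned in input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' GO term enrichment between transcript groups
#'
#' Builds one 2x2 table per GO term annotating at least one transcript of
#' the union of the two groups, tests each with Fisher's exact test, and
#' adjusts across all tested terms with Benjamini-Hochberg.
#'
#' Two comparison modes mirror the two published workflows:
#' `group_vs_group` tests a transcript group against another disjoint group
#' (dorsal-up versus ventral-up); `group_vs_rest` tests a group against all
#' remaining transcripts of the catalog.
#'
#' @param test_ids character vector of test-set transcript ids.
#' @param reference_ids character vector of reference transcript ids
#'   (ignored in `group_vs_rest` mode, where the reference is the catalog
#'   complement of the test set).
#' @param catalog a [transcript_catalog()] carrying GO annotation.
#' @param alpha FDR significance level, default 0.05.
#' @param mode `"group_vs_group"` or `"group_vs_rest"`.
#' @param sided `"two"` (default) or `"greater"` for an enrichment-only test.
#' @return Data frame with columns `go_id`, `a`, `b`, `c`, `d`, `p_value`,
#'   `fdr`, `enriched_in` (`"test"` or `"reference"`), `significant`;
#'   sorted by `fdr` then `go_id`.
#' @export
enrich <- function(test_ids, reference_ids = NULL, catalog, alpha = 0.05,
                   mode = c("group_vs_group", "group_vs_rest"),
                   sided = c("two", "greater")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  stopifnot(inherits(catalog, "transcript_catalog"), alpha > 0, alpha < 1)
  test_ids <- unique(as.character(test_ids))
  empty <- data.frame(go_id = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_value = numeric(0),
                      fdr = numeric(0), enriched_in = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(test_ids) == 0) {
    warning("empty test set; no enrichment computed")
    return(empty)
  }
  if (mode == "group_vs_rest") {
    reference_ids <- setdiff(catalog$transcript_id, test_ids)
  } else {
    reference_ids <- unique(as.character(reference_ids))
    if (length(intersect(test_ids, reference_ids)))
      stop("test and reference sets must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(c(test_ids, reference_ids), catalog$transcript_id)
  if (length(unknown))
    stop("transcripts absent from catalog: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)

  anno <- catalog$go_terms
  names(anno) <- catalog$transcript_id
  test_terms <- anno[test_ids]
  ref_terms <- anno[reference_ids]
  terms <- sort(unique(c(unlist(test_terms), unlist(ref_terms))))
  if (length(terms) == 0) return(empty)

  n_test <- length(test_ids)
  n_ref <- length(reference_ids)
  a <- tabulate(match(unlist(test_terms), terms), nbins = length(terms))
  c_ <- tabulate(match(unlist(ref_terms), terms), nbins = length(terms))
  b <- n_test - a
  d <- n_ref - c_
  pfun <- if (sided == "two") fisher_exact_two_sided else fisher_exact_enrichment
  p <- mapply(pfun, a, b, c_, d)
  fdr <- bh_fdr(p)
  enriched_in <- ifelse(a / n_test >= c_ / max(n_ref, 1), "test", "reference")
  out <- data.frame(go_id = terms, a = a, b = b, c = c_, d = d,
                    p_value = p, fdr = fdr, enriched_in = enriched_in,
                    significant = fdr < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
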