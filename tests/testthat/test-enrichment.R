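test_that("two-sided Fisher p agrees with enumeration and fisher.test", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
  # random tables against the lchoose enumeration oracle and stats
  set.seed(7)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    p <- fisher_exact_two_sided(a, b, c_, d)
    expect_equal(p, fisher_oracle(a, b, c_, d), tolerance = 1e-12)
    expect_equal(p,
                 stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("one-sided Fisher is the upper hypergeometric tail", {
  expect_equal(fisher_exact_enrichment(5, 0, 0, 5), 1 / 252)
  set.seed(8)
  for (i in 1:50) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    c_ <- sample(0:10, 1); d <- sample(0:10, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0) next
    expect_equal(fisher_exact_enrichment(a, b, c_, d),
                 stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches hand-worked step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # pointwise >= p and order invariance
  set.seed(9)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("enrichment finds a strongly planted term and respects symmetry", {
  set.seed(10)
  n <- 1000
  ids <- paste0("t", 1:n)
  go <- lapply(1:n, function(i)
    c("GO:0000001", "GO:0000002")[runif(2) < 0.1])
  test_ids <- ids[1:50]
  # plant GO:0007049 in 40/50 test transcripts, 50/950 reference
  planted <- c(sample(1:50, 40), sample(51:n, 50))
  for (i in planted) go[[i]] <- union(go[[i]], "GO:0007049")
  cat <- transcript_catalog(ids, rep(1000, n), go_terms = go)
  res <- enrich(test_ids, catalog = cat, mode = "group_vs_rest")
  row <- res[res$go_id == "GO:0007049", ]
  expect_true(row$significant)
  expect_lt(row$fdr, 1e-6)
  expect_equal(row$enriched_in, "test")
  expect_equal(row$a, 40)
  expect_equal(row$a + row$b, 50)
  # symmetry: swapping test and reference keeps p, flips direction
  ref_ids <- ids[51:150]
  r1 <- enrich(test_ids, ref_ids, cat)
  r2 <- enrich(ref_ids, test_ids, cat)
  expect_equal(r1$p_value[match(r2$go_id, r1$go_id)], r2$p_value)
  k <- r1$go_id == "GO:0007049"
  expect_equal(r1$enriched_in[k], "test")
  expect_equal(r2$enriched_in[r2$go_id == "GO:0007049"], "reference")
  expect_error(enrich(test_ids, test_ids, cat), "disjoint")
  expect_warning(res0 <- enrich(character(0), ref_ids, cat), "empty")
  expect_equal(nrow(res0), 0)
})

test_that("type-I error is controlled under a null annotation", {
  frac <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 400
    ids <- paste0("t", 1:n)
    terms <- sprintf("GO:%07d", 1:30)
    go <- lapply(1:n, function(i) terms[runif(30) < 0.08])
    cat <- transcript_catalog(ids, rep(1000, n), go_terms = go)
    res <- enrich(sample(ids, 50), catalog = cat, mode = "group_vs_rest")
    if (nrow(res) == 0) return(0)
    mean(res$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("OBO parsing and ancestor propagation are idempotent", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "",
    "[Term]", "id: GO:0000002", "name: mid", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf", "is_a: GO:0000002",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of", "name: part of"), obo)
  ont <- read_obo(obo)
  expect_equal(nrow(ont$terms), 3)  # obsolete term dropped
  expect_setequal(ont$parents[["GO:0000003"]], c("GO:0000002", "GO:0000001"))
  cat <- transcript_catalog(c("a", "b", "c"), c(100, 100, 100),
                            go_terms = list("GO:0000003", "GO:0000001",
                                            character(0)))
  prop <- propagate_annotations(cat, ont)
  expect_setequal(prop$go_terms[[1]],
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(prop$go_terms[[2]], "GO:0000001")  # root-only unchanged
  expect_equal(prop$go_terms[[3]], character(0))
  # idempotence
  expect_equal(propagate_annotations(prop, ont)$go_terms, prop$go_terms)
  # cycles are rejected
  cyc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000005", "is_a: GO:0000006", "",
               "[Term]", "id: GO:0000006", "is_a: GO:0000005"), cyc)
  expect_error(propagate_annotations(cat, read_obo(cyc)), "cycle")
})
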