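# Seeded synthetic-data generator emulating the study design: four libraries
# (dorsal/ventral iris x 4/8 days post-lentectomy) of overdispersed counts
# over a few thousand transcripts, with planted dorsal-up, ventral-up and
# side-exclusive sets carrying known GO labels, a valid-but-silent spot set
# for cutoff estimation, and qPCR dilution series plus replicate Cts.

#' Specification for the synthetic data generator
#'
#' All downstream randomness is fixed by `seed`. Counts follow a
#' gamma-multinomial (Dirichlet-multinomial) scheme whose marginals are
#' negative-binomial-like with the requested overdispersion, while library
#' totals match the requested sizes exactly.
#'
#' @param seed integer seed.
#' @param n_transcripts number of transcripts, default 5000.
#' @param library_sizes named vector of total mapped reads per condition
#'   (`4dv`, `4dd`, `8dv`, `8dd`), default 2e6 each.
#' @param dispersion negative-binomial overdispersion of counts, default 0.2.
#' @param length_meanlog,length_sdlog log-normal transcript length
#'   parameters (bp), defaults `log(1500)` and 0.5.
#' @param expr_meanlog,expr_sdlog log-normal baseline expression parameters,
#'   defaults 0 and 1.
#' @param n_dorsal_up,n_ventral_up sizes of the planted up-regulated sets,
#'   default 50 each.
#' @param planted_fold true per-day dorsal/ventral fold of planted sets
#'   (> 1), default 8.
#' @param n_dorsal_exclusive,n_ventral_exclusive planted side-exclusive
#'   transcripts (zero reads on the opposite side), default 3 each.
#' @param n_go_terms size of the GO vocabulary, default 50.
#' @param go_background_freq per-term background annotation probability,
#'   default 0.05.
#' @param planted_go_term term enriched in the dorsal-up set, default
#'   `"GO:0007049"` (cell cycle, the dominant dorsal category in the study).
#' @param planted_go_freq annotation probability of the planted term inside
#'   the dorsal-up set, default 0.8.
#' @param n_null_spots number of structurally valid, signal-free spots,
#'   default 101; they map (with duplicates, a few unmapped) onto
#'   `n_null_transcripts` low-expression transcripts, default 81.
#' @param n_null_transcripts see above.
#' @param n_bad_spots spots failing at least one quality rule, default 40.
#' @param qpcr_genes named list of true relative amounts `c(v4=, d4=, v8=,
#'   d8=)` per gene; default a TBX5-like dorsal 8:1 gene and an NTN1-like
#'   ventral 8:1 gene, both with a mild day effect.
#' @param qpcr_sigma_ct Gaussian Ct noise (cycles), default 0.15.
#' @param qpcr_slope,qpcr_intercept standard-curve parameters, defaults
#'   `-1/log10(2)` (perfect doubling) and 30.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed,
                            n_transcripts = 5000,
                            library_sizes = c(`4dv` = 2e6, `4dd` = 2e6,
                                              `8dv` = 2e6, `8dd` = 2e6),
                            dispersion = 0.2,
                            length_meanlog = log(1500), length_sdlog = 0.5,
                            expr_meanlog = 0, expr_sdlog = 1,
                            n_dorsal_up = 50, n_ventral_up = 50,
                            planted_fold = 8,
                            n_dorsal_exclusive = 3, n_ventral_exclusive = 3,
                            n_go_terms = 50, go_background_freq = 0.05,
                            planted_go_term = "GO:0007049",
                            planted_go_freq = 0.8,
                            n_null_spots = 101, n_null_transcripts = 81,
                            n_bad_spots = 40,
                            qpcr_genes = list(
                              TBX5 = c(v4 = 1, d4 = 8, v8 = 1.5, d8 = 12),
                              NTN1 = c(v4 = 8, d4 = 1, v8 = 12, d8 = 1.5)),
                            qpcr_sigma_ct = 0.15,
                            qpcr_slope = -1 / log10(2),
                            qpcr_intercept = 30) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (planted_fold <= 1) stop("planted_fold must exceed 1", call. = FALSE)
  n_planted <- n_dorsal_up + n_ventral_up + n_dorsal_exclusive +
    n_ventral_exclusive
  if (n_planted > n_transcripts)
    stop("planted sets larger than n_transcripts", call. = FALSE)
  if (!setequal(names(library_sizes), CONDITIONS))
    stop("library_sizes must name the four conditions", call. = FALSE)
  if (n_null_transcripts > n_null_spots)
    stop("n_null_transcripts cannot exceed n_null_spots", call. = FALSE)
  spec <- as.list(environment())
  class(spec) <- "simulation_spec"
  spec
}

# run expr with a private, seed-derived RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Simulate the four count libraries with planted structure
#'
#' Baseline expression is log-normal; per-library counts are drawn by gamma
#' perturbation of expected read mass (shape `1/dispersion`) followed by a
#' multinomial of the library size, giving negative-binomial-like marginals
#' with totals exactly equal to the requested library sizes. Planted
#' dorsal-up transcripts have ventral expression divided by the true fold at
#' both days (symmetrically for ventral-up); exclusive transcripts have zero
#' expression on the opposite side. Planted sets are drawn from transcripts
#' with above-median baseline so they are expressed.
#'
#' @param spec a [simulation_spec()].
#' @return List with `catalog` (GO-annotated [transcript_catalog()]),
#'   `libraries` (list of four [library_counts()]), `truth` (data frame
#'   `transcript_id`, `planted_set`, `true_fold`, `baseline_expr`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_transcripts
    ids <- sprintf("synthtx%05d", seq_len(n))
    len <- pmax(200, round(stats::rlnorm(n, spec$length_meanlog,
                                         spec$length_sdlog)))
    base <- stats::rlnorm(n, spec$expr_meanlog, spec$expr_sdlog)

    expressed_pool <- which(base > stats::median(base))
    n_pl <- c(spec$n_dorsal_up, spec$n_ventral_up,
              spec$n_dorsal_exclusive, spec$n_ventral_exclusive)
    pick <- sample(expressed_pool, sum(n_pl))
    sets <- split(pick, rep(c("dorsal_up", "ventral_up", "dorsal_exclusive",
                              "ventral_exclusive"), n_pl))

    planted_set <- rep("null", n)
    true_fold <- rep(1, n)
    for (nm in names(sets)) planted_set[sets[[nm]]] <- nm
    true_fold[planted_set %in% c("dorsal_up", "ventral_up")] <-
      spec$planted_fold

    # per-side expression, identical across days (the planted contrast is
    # dorsoventral, not temporal)
    expr_d <- base
    expr_v <- base
    expr_v[sets$dorsal_up] <- base[sets$dorsal_up] / spec$planted_fold
    expr_d[sets$ventral_up] <- base[sets$ventral_up] / spec$planted_fold
    expr_v[sets$dorsal_exclusive] <- 0
    expr_d[sets$ventral_exclusive] <- 0

    side_expr <- list(`4dv` = expr_v, `4dd` = expr_d,
                      `8dv` = expr_v, `8dd` = expr_d)
    shape <- 1 / spec$dispersion
    libraries <- lapply(CONDITIONS, function(cond) {
      mass <- side_expr[[cond]] * len
      w <- ifelse(mass > 0,
                  stats::rgamma(n, shape = shape, rate = shape) * mass, 0)
      N <- spec$library_sizes[[cond]]
      counts <- as.vector(stats::rmultinom(1, size = N, prob = w))
      names(counts) <- ids
      library_counts(cond, counts[counts > 0 | TRUE], N)
    })

    # GO annotation: background frequency per term, planted term enriched in
    # the dorsal-up set
    terms <- sprintf("GO:%07d", seq_len(spec$n_go_terms))
    if (!spec$planted_go_term %in% terms)
      terms[1] <- spec$planted_go_term
    go <- lapply(seq_len(n), function(i) {
      hit <- terms[stats::runif(spec$n_go_terms) < spec$go_background_freq]
      hit
    })
    planted_hit <- stats::runif(length(sets$dorsal_up)) < spec$planted_go_freq
    for (j in seq_along(sets$dorsal_up)) {
      i <- sets$dorsal_up[j]
      if (planted_hit[j]) go[[i]] <- union(go[[i]], spec$planted_go_term)
    }

    catalog <- transcript_catalog(ids, len, go_terms = go)
    truth <- data.frame(transcript_id = ids, planted_set = planted_set,
                        true_fold = true_fold, baseline_expr = base,
                        stringsAsFactors = FALSE)
    list(catalog = catalog, libraries = libraries, truth = truth)
  })
}

#' Simulate microarray spots for cutoff estimation
#'
#' Generates `n_null_spots` spots that pass every quality rule (valid flag,
#' circularity > 80, small intensity variation, snr < 1), mapped with
#' deliberate duplicates onto `n_null_transcripts` of the supplied
#' low-expression transcripts and with a few spots left unmapped, plus
#' `n_bad_spots` spots that each fail at least one rule.
#'
#' @param spec a [simulation_spec()].
#' @param null_pool character vector of candidate (low-expression)
#'   transcript ids to map silent spots onto.
#' @return List with `spots` (data frame), `pass_spot_ids`,
#'   `null_transcripts` (the planted transcript set).
#' @export
simulate_null_spots <- function(spec, null_pool) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$n_null_spots < 1) stop("n_null_spots must be >= 1", call. = FALSE)
  if (length(null_pool) < spec$n_null_transcripts)
    stop("null_pool smaller than n_null_transcripts", call. = FALSE)
  .with_seed(spec$seed + 1L, {
    n_pass <- spec$n_null_spots
    n_unmapped <- min(5L, max(0L, n_pass - spec$n_null_transcripts))
    n_mapped <- n_pass - n_unmapped
    tx <- sample(null_pool, spec$n_null_transcripts)
    mapping <- c(tx, sample(tx, n_mapped - length(tx), replace = TRUE))
    mapping <- sample(c(mapping, rep(NA_character_, n_unmapped)))
    pass <- data.frame(
      spot_id = sprintf("spot%04d", seq_len(n_pass)),
      circularity_pct = stats::runif(n_pass, 82, 99),
      intensity_cv = stats::runif(n_pass, 0.01, 0.15),
      valid_flag = TRUE,
      snr = stats::runif(n_pass, 0.05, 0.9),
      transcript_id = mapping,
      stringsAsFactors = FALSE)
    n_bad <- spec$n_bad_spots
    fail_mode <- sample(c("circ", "cv", "flag", "snr"), n_bad, replace = TRUE)
    bad <- data.frame(
      spot_id = sprintf("spot%04d", n_pass + seq_len(n_bad)),
      circularity_pct = ifelse(fail_mode == "circ",
                               stats::runif(n_bad, 40, 79),
                               stats::runif(n_bad, 82, 99)),
      intensity_cv = ifelse(fail_mode == "cv", stats::runif(n_bad, 0.3, 0.8),
                            stats::runif(n_bad, 0.01, 0.15)),
      valid_flag = fail_mode != "flag",
      snr = ifelse(fail_mode == "snr", stats::runif(n_bad, 3, 20),
                   stats::runif(n_bad, 0.05, 0.9)),
      transcript_id = sample(null_pool, n_bad, replace = TRUE),
      stringsAsFactors = FALSE)
    spots <- rbind(pass, bad)
    spots <- spots[sample(nrow(spots)), , drop = FALSE]
    rownames(spots) <- NULL
    list(spots = spots, pass_spot_ids = pass$spot_id, null_transcripts = tx)
  })
}

#' Simulate qPCR standards and replicate sample Cts
#'
#' Standards follow the specified line exactly (one Ct per dilution point,
#' five decades). Sample Cts are `slope * log10(true amount) + intercept`
#' plus Gaussian noise; the reference gene is constant across conditions.
#'
#' @param spec a [simulation_spec()].
#' @param n_replicates replicates per side/day cell, default 3.
#' @param reference_gene name of the constant housekeeping gene, default
#'   `"RPL27"`.
#' @return List with `standards`, `samples` (data frames as consumed by
#'   [qpcr_analyze()]) and `truth` (true relative amounts per gene/cell).
#' @export
simulate_qpcr <- function(spec, n_replicates = 3, reference_gene = "RPL27") {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$seed + 2L, {
    genes <- spec$qpcr_genes
    genes[[reference_gene]] <- c(v4 = 1, d4 = 1, v8 = 1, d8 = 1)
    scale <- 0.01  # places sample amounts inside the standard range
    dil <- -4:0
    standards <- do.call(rbind, lapply(names(genes), function(g)
      data.frame(gene = g, log10_amount = dil,
                 ct = spec$qpcr_slope * dil + spec$qpcr_intercept,
                 stringsAsFactors = FALSE)))
    grid <- expand.grid(side = c("dorsal", "ventral"), day = c(4, 8),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    samples <- do.call(rbind, lapply(names(genes), function(g) {
      lab <- paste0(ifelse(grid$side == "dorsal", "d", "v"), grid$day)
      amount <- genes[[g]][lab] * scale
      ct <- spec$qpcr_slope * log10(amount) + spec$qpcr_intercept +
        stats::rnorm(nrow(grid), 0, spec$qpcr_sigma_ct)
      data.frame(gene = g, side = grid$side, day = grid$day,
                 replicate = grid$replicate, ct = ct,
                 stringsAsFactors = FALSE)
    }))
    rownames(samples) <- NULL
    truth <- do.call(rbind, lapply(names(genes), function(g)
      data.frame(gene = g, cell = names(genes[[g]]),
                 true_amount = unname(genes[[g]]) * scale,
                 stringsAsFactors = FALSE)))
    list(standards = standards, samples = samples, truth = truth)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates [simulate_counts()], [simulate_null_spots()] (mapped onto
#' the lowest-baseline unplanted transcripts) and [simulate_qpcr()], and
#' derives the expression table and estimated cutoffs.
#'
#' @param spec a [simulation_spec()].
#' @return List with `catalog`, `libraries`, `truth`, `expression`,
#'   `spots`, `spot_truth`, `cutoffs`, `qpcr`.
#' @export
simulate_dataset <- function(spec) {
  sim <- simulate_counts(spec)
  expr <- expression_table(sim$libraries, sim$catalog)
  nulls <- sim$truth$planted_set == "null"
  pool <- sim$truth$transcript_id[nulls][
    order(sim$truth$baseline_expr[nulls])][
      seq_len(min(sum(nulls), 4 * spec$n_null_transcripts))]
  sp <- simulate_null_spots(spec, pool)
  cuts <- estimate_cutoffs(expr, sp$null_transcripts)
  qp <- simulate_qpcr(spec)
  list(catalog = sim$catalog, libraries = sim$libraries, truth = sim$truth,
       expression = expr, spots = sp$spots,
       spot_truth = sp[c("pass_spot_ids", "null_transcripts")],
       cutoffs = cuts, qpcr = qp)
}
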