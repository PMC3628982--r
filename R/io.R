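# Readers and writers for the pipeline's plain-text formats, the published
# reference tables, and the end-to-end driver.

fmt3 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 3))

#' Read the four count libraries from TSV
#'
#' @param counts_path TSV with columns `transcript_id`, `count_4dv`,
#'   `count_4dd`, `count_8dv`, `count_8dd`.
#' @param libraries_path TSV with columns `condition`,
#'   `total_mapped_reads`.
#' @return List of four [library_counts()] objects.
#' @export
read_counts_tsv <- function(counts_path, libraries_path) {
  cols <- paste0("count_", CONDITIONS)
  df <- read_table_checked(counts_path, "\t", c("transcript_id", cols))
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript_id in ", counts_path, call. = FALSE)
  libs <- read_table_checked(libraries_path, "\t",
                             c("condition", "total_mapped_reads"))
  if (!setequal(libs$condition, CONDITIONS))
    stop("library table must list the four conditions", call. = FALSE)
  lapply(CONDITIONS, function(cond) {
    N <- libs$total_mapped_reads[match(cond, libs$condition)]
    cnt <- df[[paste0("count_", cond)]]
    if (any(is.na(cnt)))
      stop("non-numeric count cells in ", counts_path, " (", cond, ")",
           call. = FALSE)
    library_counts(cond, stats::setNames(cnt, df$transcript_id), N)
  })
}

#' Write count libraries to TSV
#'
#' @param libraries list of four [library_counts()] objects.
#' @param counts_path,libraries_path output paths (see
#'   [read_counts_tsv()]).
#' @export
write_counts_tsv <- function(libraries, counts_path, libraries_path) {
  conds <- vapply(libraries, function(l) l$condition, character(1))
  libraries <- libraries[match(CONDITIONS, conds)]
  ids <- sort(unique(unlist(lapply(libraries, function(l) names(l$counts)))))
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (lib in libraries) {
    cnt <- stats::setNames(rep(0, length(ids)), ids)
    cnt[names(lib$counts)] <- lib$counts
    out[[paste0("count_", lib$condition)]] <- unname(cnt)
  }
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  libtab <- data.frame(
    condition = CONDITIONS,
    total_mapped_reads = vapply(libraries, function(l) l$total_mapped_reads,
                                numeric(1)))
  utils::write.table(libtab, libraries_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a microarray spot quality table from CSV
#'
#' @param path CSV with columns `spot_id`, `circularity_pct`,
#'   `intensity_cv`, `valid_flag` (0/1 or logical), `snr` and optional
#'   `transcript_id` (empty where unmapped).
#' @return Data frame as consumed by [select_null_spots()].
#' @export
read_spot_csv <- function(path) {
  df <- read_table_checked(path, ",",
                           c("spot_id", "circularity_pct", "intensity_cv",
                             "valid_flag", "snr"))
  df$valid_flag <- as.logical(as.numeric(df$valid_flag) != 0 |
                                df$valid_flag %in% c("TRUE", "true"))
  if ("transcript_id" %in% names(df)) {
    df$transcript_id <- as.character(df$transcript_id)
    df$transcript_id[!nzchar(df$transcript_id) |
                       is.na(df$transcript_id)] <- NA_character_
  }
  df
}

#' Write a spot table to CSV
#' @param spots spot data frame.
#' @param path output path.
#' @export
write_spot_csv <- function(spots, path) {
  spots$valid_flag <- as.integer(spots$valid_flag)
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}

#' Write estimated cutoffs to TSV
#' @param cutoffs a `cutoff_set`.
#' @param path output path.
#' @export
write_cutoffs_tsv <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  utils::write.table(
    data.frame(condition = names(cutoffs$cutoffs),
               cutoff = fmt3(unname(cutoffs$cutoffs))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read cutoffs from TSV
#' @param path TSV with columns `condition` (v4/d4/v8/d8) and `cutoff`.
#' @return A `cutoff_set`.
#' @export
read_cutoffs_tsv <- function(path) {
  df <- read_table_checked(path, "\t", c("condition", "cutoff"))
  cu <- stats::setNames(as.numeric(df$cutoff), df$condition)
  miss <- setdiff(unname(CONDITION_LABELS), names(cu))
  if (length(miss))
    stop("cutoff file missing condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cutoff_set(cu[["v4"]], cu[["d4"]], cu[["v8"]], cu[["d8"]])
}

#' Write a gradient or temporal table to TSV
#'
#' Numeric columns are printed with 3 decimals and undefined log ratios as
#' `NA`, mirroring the layout of the published tables.
#'
#' @param table output of [build_gradient_table()] or
#'   [build_temporal_table()].
#' @param path output path.
#' @export
write_result_tsv <- function(table, path) {
  out <- table
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- fmt3(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read qPCR sample and standard tables from CSV
#'
#' @param path CSV path; samples need `gene`, `side`, `day`, `replicate`,
#'   `ct`; standards need `gene`, `log10_amount`, `ct`.
#' @return Data frame.
#' @name qpcr_io
#' @export
read_qpcr_samples_csv <- function(path) {
  df <- read_table_checked(path, ",",
                           c("gene", "side", "day", "replicate", "ct"))
  if (any(is.na(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be positive and numeric in ", path, call. = FALSE)
  df
}

#' @rdname qpcr_io
#' @export
read_qpcr_standards_csv <- function(path) {
  read_table_checked(path, ",", c("gene", "log10_amount", "ct"))
}

#' Published dorsal- and ventral-enriched reference tables
#'
#' The two 50-transcript tables of top dorsal-up and ventral-up transcripts
#' shipped with the package: RPKM quadruples (`v4`, `d4`, `v8`, `d8`) and
#' the printed per-day and combined log2 fold-change columns, with
#' spreadsheet placeholders of the original tables normalized to `NA`.
#'
#' @return List with data frames `dorsal` and `ventral`.
#' @export
reference_gradient_tables <- function() {
  rd <- function(f) {
    path <- system.file("extdata", f, package = "irisgradient",
                        mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  }
  list(dorsal = rd("dorsal_up_reference.tsv"),
       ventral = rd("ventral_up_reference.tsv"))
}

#' The published per-library RPKM detection cutoffs
#'
#' The study's thresholds estimated from 81 valid-but-silent array-spot
#' transcripts: 0.64 (v4), 1.14 (d4), 1.13 (v8), 1.10 (d8). They are
#' reference values for use with the shipped tables; the estimation
#' procedure itself is [estimate_cutoffs()].
#'
#' @return A `cutoff_set`.
#' @export
reference_cutoffs <- function() cutoff_set(0.64, 1.14, 1.13, 1.1)

#' Run the full pipeline on file inputs
#'
#' Reads counts, catalog and spot tables, estimates cutoffs, builds the
#' dorsoventral and temporal tables, runs both enrichment workflows on the
#' classified groups, optionally analyzes qPCR tables, and writes every
#' result plus a run manifest to `out_dir`. Each stage failure is reported
#' with its stage name.
#'
#' @param config list with paths `counts`, `libraries`, `catalog`, `spots`
#'   (optional `qpcr_samples`, `qpcr_standards`, `obo`), parameters
#'   `fold_threshold_dv` (default 2), `fold_threshold_temporal` (2),
#'   `alpha` (0.05), `cv_max` (0.2), `circularity_min` (80), `snr_max` (1),
#'   flags `one_sided_fisher`, `propagate_go`, `require_both_sides`
#'   (all `FALSE`), and `out_dir`.
#' @return Invisibly, a list of the in-memory results.
#' @export
run_all <- function(config) {
  p <- function(name, default = NULL)
    if (!is.null(config[[name]])) config[[name]] else default
  out_dir <- p("out_dir")
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  catalog <- stage("catalog", read_catalog_tsv(p("catalog")))
  libraries <- stage("counts", read_counts_tsv(p("counts"), p("libraries")))
  if (isTRUE(p("propagate_go", FALSE))) {
    ontology <- stage("obo", read_obo(p("obo")))
    catalog <- stage("obo", propagate_annotations(catalog, ontology))
  }
  expr <- stage("quantify", expression_table(libraries, catalog))
  cutoffs <- stage("cutoff", {
    if (is.null(p("spots"))) stop("no spot table configured")
    spots <- read_spot_csv(p("spots"))
    sel <- select_null_spots(spots, p("circularity_min", 80),
                             p("snr_max", 1), p("cv_max", 0.2))
    estimate_cutoffs(expr, map_spots_to_transcripts(sel, spots))
  })
  gradient <- stage("compare", build_gradient_table(
    expr, cutoffs, p("fold_threshold_dv", 2),
    p("require_both_sides", FALSE)))
  temporal <- stage("compare", build_temporal_table(
    expr, cutoffs, p("fold_threshold_temporal", 2)))
  sided <- if (isTRUE(p("one_sided_fisher", FALSE))) "greater" else "two"
  alpha <- p("alpha", 0.05)
  enr_dv <- stage("enrich", enrich(
    gradient$transcript_id[gradient$dv_class %in%
                             c("dorsal_up", "dorsal_exclusive")],
    gradient$transcript_id[gradient$dv_class %in%
                             c("ventral_up", "ventral_exclusive")],
    catalog, alpha, "group_vs_group", sided))
  enr_day4 <- stage("enrich", enrich(
    temporal$transcript_id[temporal$day_class == "day4_up"],
    catalog = catalog, alpha = alpha, mode = "group_vs_rest", sided = sided))
  enr_day8 <- stage("enrich", enrich(
    temporal$transcript_id[temporal$day_class == "day8_up"],
    catalog = catalog, alpha = alpha, mode = "group_vs_rest", sided = sided))

  qpcr <- NULL
  if (!is.null(p("qpcr_samples")))
    qpcr <- stage("qpcr", qpcr_analyze(
      read_qpcr_samples_csv(p("qpcr_samples")),
      read_qpcr_standards_csv(p("qpcr_standards")),
      p("reference_gene", "RPL27")))

  write_cutoffs_tsv(cutoffs, file.path(out_dir, "cutoffs.tsv"))
  write_result_tsv(gradient, file.path(out_dir, "gradient_dorsoventral.tsv"))
  write_result_tsv(temporal, file.path(out_dir, "gradient_temporal.tsv"))
  write_result_tsv(enr_dv, file.path(out_dir, "enrichment_dorsoventral.tsv"))
  write_result_tsv(enr_day4, file.path(out_dir, "enrichment_day4.tsv"))
  write_result_tsv(enr_day8, file.path(out_dir, "enrichment_day8.tsv"))
  if (!is.null(qpcr)) {
    write_result_tsv(qpcr$t_tests, file.path(out_dir, "qpcr_t_tests.tsv"))
    write_result_tsv(qpcr$anova, file.path(out_dir, "qpcr_anova.tsv"))
  }
  manifest <- c(
    paste0("irisgradient version: ",
           as.character(utils::packageVersion("irisgradient"))),
    paste0("R version: ", R.version.string),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("fold_threshold_dv: ", p("fold_threshold_dv", 2)),
    paste0("fold_threshold_temporal: ", p("fold_threshold_temporal", 2)),
    paste0("alpha: ", alpha),
    paste0("cv_max: ", p("cv_max", 0.2)),
    paste0("circularity_min: ", p("circularity_min", 80)),
    paste0("snr_max: ", p("snr_max", 1)),
    paste0("one_sided_fisher: ", isTRUE(p("one_sided_fisher", FALSE))),
    paste0("propagate_go: ", isTRUE(p("propagate_go", FALSE))),
    paste0("require_both_sides: ", isTRUE(p("require_both_sides", FALSE))),
    paste0("cutoffs: ",
           paste(names(cutoffs$cutoffs), fmt3(cutoffs$cutoffs),
                 sep = "=", collapse = " ")))
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(list(cutoffs = cutoffs, gradient = gradient, temporal = temporal,
                 enrichment = list(dorsoventral = enr_dv, day4 = enr_day4,
                                   day8 = enr_day8),
                 qpcr = qpcr))
}
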