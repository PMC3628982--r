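# Dorsoventral and temporal fold-change classification.
#
# The ranking statistic of the published dorsal- and ventral-enriched tables
# is the combined two-timepoint log2 fold change
#   log2( (d4 + d8) / (v4 + v8) ),
# i.e. log2 of summed dorsal RPKM over summed ventral RPKM. The per-day
# columns are plain log2(d/v) ratios, undefined (NA) when either side is 0.

#' Per-day log2 fold change
#'
#' `log2(numerator/denominator)`, `NA` when either value is zero (the
#' published tables carry spreadsheet placeholders in those cells; this
#' package prints `NA`).
#'
#' @param numerator,denominator non-negative RPKM values (vectorised).
#' @return Numeric vector of log2 ratios with `NA` where undefined.
#' @examples
#' log2_fold_change(4.549, 0.272)  # 4.06, a strongly dorsal transcript
#' @export
log2_fold_change <- function(numerator, denominator) {
  if (any(numerator < 0, na.rm = TRUE) || any(denominator < 0, na.rm = TRUE))
    stop("RPKM values must be non-negative", call. = FALSE)
  out <- ifelse(numerator > 0 & denominator > 0,
                log2(numerator / denominator), NA_real_)
  as.numeric(out)
}

#' Combined two-timepoint dorsoventral log2 fold change
#'
#' `log2((d4 + d8) / (v4 + v8))`: the dorsal RPKM values of both days are
#' summed, likewise the ventral, and the log2 ratio of the sums is taken.
#' This remains defined when a single day is zero on one side, matching the
#' published tables where a day-4 ratio can be undefined while the combined
#' statistic is printed. `NA` when either two-day sum is zero.
#'
#' @param d4,d8,v4,v8 non-negative RPKM values (vectorised).
#' @return Numeric vector of combined log2 fold changes.
#' @examples
#' combined_log2_fold_change(4.549, 12.007, 0.272, 0.248)  # 4.99 (TBX5)
#' @export
combined_log2_fold_change <- function(d4, d8, v4, v8) {
  if (any(c(d4, d8, v4, v8) < 0, na.rm = TRUE))
    stop("RPKM values must be non-negative", call. = FALSE)
  dsum <- d4 + d8
  vsum <- v4 + v8
  out <- ifelse(dsum > 0 & vsum > 0, log2(dsum / vsum), NA_real_)
  as.numeric(out)
}

# internal: does ratio num/den pass the fold threshold? A zero denominator
# with a positive numerator is an infinite fold and always passes.
.fold_passes <- function(num, den, threshold, strict) {
  ifelse(den == 0, num > 0,
         if (strict) num / den > threshold else num / den >= threshold)
}

#' Classify a transcript along the dorsoventral axis
#'
#' Implements the dorsoventral selection rules applied at both timepoints:
#' \itemize{
#'   \item \strong{dorsal_exclusive}: zero ventral \emph{reads} at both days
#'     and dorsal RPKM above the cutoff at both days;
#'   \item \strong{dorsal_up}: dorsal RPKM above the cutoff at both days and
#'     dorsal/ventral fold at least `fold_threshold` at both days (a zero
#'     ventral RPKM with expressed dorsal passes any threshold);
#'   \item symmetric \strong{ventral_exclusive} / \strong{ventral_up};
#'   \item otherwise \strong{unclassified}.
#' }
#' Exclusivity takes precedence over the fold rule. The fold comparison is
#' inclusive (`>=`, "at least 2-fold") by default.
#'
#' @param v4,d4,v8,d8 RPKM quadruple (vectorised).
#' @param count_v4,count_v8,count_d4,count_d8 raw read counts; default
#'   derived from RPKM (zero RPKM iff zero count), override when counts are
#'   available.
#' @param cutoffs a `cutoff_set` (see [estimate_cutoffs()], [cutoff_set()]).
#' @param fold_threshold fold-change threshold (> 1), default 2.
#' @param require_both_sides if `TRUE`, additionally require the
#'   down-regulated side to be expressed above its cutoff; default `FALSE`
#'   (the published workflow gates only the up-regulated side).
#' @return Character vector with levels `dorsal_up`, `ventral_up`,
#'   `dorsal_exclusive`, `ventral_exclusive`, `unclassified`.
#' @export
classify_dorsoventral <- function(v4, d4, v8, d8, cutoffs,
                                  count_v4 = NULL, count_v8 = NULL,
                                  count_d4 = NULL, count_d8 = NULL,
                                  fold_threshold = 2,
                                  require_both_sides = FALSE) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1", call. = FALSE)
  cu <- cutoffs$cutoffs
  miss <- setdiff(c("v4", "d4", "v8", "d8"), names(cu))
  if (length(miss))
    stop("cutoff set missing condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(count_v4)) count_v4 <- v4
  if (is.null(count_v8)) count_v8 <- v8
  if (is.null(count_d4)) count_d4 <- d4
  if (is.null(count_d8)) count_d8 <- d8

  d_expr <- d4 > cu[["d4"]] & d8 > cu[["d8"]]
  v_expr <- v4 > cu[["v4"]] & v8 > cu[["v8"]]

  d_excl <- count_v4 == 0 & count_v8 == 0 & d_expr
  v_excl <- count_d4 == 0 & count_d8 == 0 & v_expr

  d_fold <- .fold_passes(d4, v4, fold_threshold, strict = FALSE) &
    .fold_passes(d8, v8, fold_threshold, strict = FALSE)
  v_fold <- .fold_passes(v4, d4, fold_threshold, strict = FALSE) &
    .fold_passes(v8, d8, fold_threshold, strict = FALSE)

  d_up <- d_expr & d_fold & if (require_both_sides) v_expr else TRUE
  v_up <- v_expr & v_fold & if (require_both_sides) d_expr else TRUE

  out <- rep("unclassified", length(v4))
  out[d_up] <- "dorsal_up"
  out[v_up] <- "ventral_up"
  out[d_excl] <- "dorsal_exclusive"
  out[v_excl] <- "ventral_exclusive"
  out
}

#' Classify a transcript between the two timepoints
#'
#' A transcript is `day4_up` when it is expressed above the cutoff in both
#' day-4 libraries and up-regulated strictly more than `fold_threshold`-fold
#' from day 8 to day 4 in \emph{both} the dorsal and the ventral iris;
#' `day8_up` symmetrically; otherwise `neither`. The comparison is strict
#' (`>`, "more than 2-fold"). A zero denominator with a positive numerator
#' passes (infinite fold).
#'
#' @inheritParams classify_dorsoventral
#' @return Character vector with levels `day4_up`, `day8_up`, `neither`.
#' @export
classify_temporal <- function(v4, d4, v8, d8, cutoffs, fold_threshold = 2) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1", call. = FALSE)
  cu <- cutoffs$cutoffs
  day4_expr <- d4 > cu[["d4"]] & v4 > cu[["v4"]]
  day8_expr <- d8 > cu[["d8"]] & v8 > cu[["v8"]]
  up4 <- day4_expr &
    .fold_passes(d4, d8, fold_threshold, strict = TRUE) &
    .fold_passes(v4, v8, fold_threshold, strict = TRUE)
  up8 <- day8_expr &
    .fold_passes(d8, d4, fold_threshold, strict = TRUE) &
    .fold_passes(v8, v4, fold_threshold, strict = TRUE)
  out <- rep("neither", length(v4))
  out[up4] <- "day4_up"
  out[up8] <- "day8_up"
  out
}

#' Build the ranked dorsoventral gradient table
#'
#' One row per transcript with the RPKM quadruple, the three log2 fold-change
#' statistics and the dorsoventral class, sorted by descending combined
#' log2 fold change. Rows whose combined statistic is undefined because the
#' ventral (resp. dorsal) two-day sum is zero sort above (resp. below) all
#' finite values — dorsal-exclusive transcripts head the table, as in the
#' published ranking; ties are broken lexicographically by `transcript_id`.
#'
#' @param expression an [expression_table()], or any data frame with columns
#'   `transcript_id`, `v4`, `d4`, `v8`, `d8` and optional count columns
#'   `count_4dv` etc.
#' @param cutoffs a `cutoff_set`.
#' @param fold_threshold fold threshold passed to [classify_dorsoventral()].
#' @param require_both_sides see [classify_dorsoventral()].
#' @return Data frame with columns `transcript_id`, `v4`, `d4`, `v8`, `d8`,
#'   `log2fc4`, `log2fc8`, `log2fc`, `dv_class`.
#' @export
build_gradient_table <- function(expression, cutoffs, fold_threshold = 2,
                                 require_both_sides = FALSE) {
  if (nrow(expression) == 0) {
    out <- data.frame(transcript_id = character(0), v4 = numeric(0),
                      d4 = numeric(0), v8 = numeric(0), d8 = numeric(0),
                      log2fc4 = numeric(0), log2fc8 = numeric(0),
                      log2fc = numeric(0), dv_class = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  cnt <- function(cond, rpkm) {
    col <- paste0("count_", cond)
    if (col %in% names(expression)) expression[[col]] else rpkm
  }
  with_counts <- list(
    count_v4 = cnt("4dv", expression$v4), count_d4 = cnt("4dd", expression$d4),
    count_v8 = cnt("8dv", expression$v8), count_d8 = cnt("8dd", expression$d8))
  out <- data.frame(
    transcript_id = expression$transcript_id,
    v4 = expression$v4, d4 = expression$d4,
    v8 = expression$v8, d8 = expression$d8,
    log2fc4 = log2_fold_change(expression$d4, expression$v4),
    log2fc8 = log2_fold_change(expression$d8, expression$v8),
    log2fc = combined_log2_fold_change(expression$d4, expression$d8,
                                       expression$v4, expression$v8),
    dv_class = classify_dorsoventral(
      expression$v4, expression$d4, expression$v8, expression$d8, cutoffs,
      count_v4 = with_counts$count_v4, count_v8 = with_counts$count_v8,
      count_d4 = with_counts$count_d4, count_d8 = with_counts$count_d8,
      fold_threshold = fold_threshold,
      require_both_sides = require_both_sides),
    stringsAsFactors = FALSE)
  dsum <- out$d4 + out$d8
  vsum <- out$v4 + out$v8
  key <- out$log2fc
  key[is.na(key) & dsum > 0 & vsum == 0] <- Inf
  key[is.na(key) & dsum == 0 & vsum > 0] <- -Inf
  ord <- order(-key, out$transcript_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the temporal comparison table
#'
#' Per-side day-4/day-8 log2 ratios and the temporal class of every
#' transcript, sorted by descending mean of the defined per-side log ratios
#' with `transcript_id` as tie-breaker.
#'
#' @inheritParams build_gradient_table
#' @return Data frame with columns `transcript_id`, the RPKM quadruple,
#'   `log2_d4_d8`, `log2_v4_v8`, `day_class`.
#' @export
build_temporal_table <- function(expression, cutoffs, fold_threshold = 2) {
  out <- data.frame(
    transcript_id = expression$transcript_id,
    v4 = expression$v4, d4 = expression$d4,
    v8 = expression$v8, d8 = expression$d8,
    log2_d4_d8 = log2_fold_change(expression$d4, expression$d8),
    log2_v4_v8 = log2_fold_change(expression$v4, expression$v8),
    day_class = classify_temporal(expression$v4, expression$d4,
                                  expression$v8, expression$d8,
                                  cutoffs, fold_threshold),
    stringsAsFactors = FALSE)
  key <- rowMeans(cbind(out$log2_d4_d8, out$log2_v4_v8), na.rm = TRUE)
  key[is.nan(key)] <- NA_real_
  ord <- order(-key, out$transcript_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
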