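#' @keywords internal
"_PACKAGE"

# the four libraries of the design: ventral/dorsal iris at 4 and 8 days
# post-lentectomy; column labels v4/d4/v8/d8 mirror the published tables
CONDITIONS <- c("4dv", "4dd", "8dv", "8dd")
CONDITION_LABELS <- c(`4dv` = "v4", `4dd` = "d4", `8dv` = "v8", `8dd` = "d8")

#' Per-library unique read counts
#'
#' @param condition one of `"4dv"`, `"4dd"`, `"8dv"`, `"8dd"` (ventral/dorsal
#'   iris at 4/8 days post-lentectomy).
#' @param counts named non-negative integer vector of uniquely mapping read
#'   counts, names are transcript identifiers.
#' @param total_mapped_reads positive scalar, the library's total mapped
#'   reads (`N` of the RPKM formula).
#' @return An object of class `library_counts`.
#' @export
library_counts <- function(condition, counts, total_mapped_reads) {
  condition <- match.arg(condition, CONDITIONS)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by transcript_id", call. = FALSE)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!is.finite(total_mapped_reads) || total_mapped_reads <= 0)
    stop("invalid library: total_mapped_reads must be > 0", call. = FALSE)
  if (sum(counts) > total_mapped_reads)
    stop("sum of counts exceeds total_mapped_reads", call. = FALSE)
  structure(list(condition = condition, counts = counts,
                 total_mapped_reads = total_mapped_reads),
            class = "library_counts")
}

#' Compute RPKM values for one library
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM(t) = 10^9 \, C(t) / (N \, L(t))}
#' where `C` is the transcript's unique read count, `N` the library's total
#' mapped reads and `L` the transcript length in bp. Transcripts of the
#' catalog absent from the count vector get RPKM 0, so the zero-read
#' exclusivity rule downstream can see them: RPKM is 0 if and only if the
#' count is 0.
#'
#' @param counts a [library_counts()] object.
#' @param catalog a [transcript_catalog()].
#' @return Named numeric vector of RPKM values over all catalog transcripts.
#' @examples
#' cat <- transcript_catalog("t1", 1000)
#' lib <- library_counts("4dd", c(t1 = 10), 1e6)
#' compute_rpkm(lib, cat)  # 10
#' @export
compute_rpkm <- function(counts, catalog) {
  stopifnot(inherits(counts, "library_counts"),
            inherits(catalog, "transcript_catalog"))
  unknown <- setdiff(names(counts$counts), catalog$transcript_id)
  if (length(unknown))
    stop("catalog mismatch: counted transcripts absent from catalog: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  C <- stats::setNames(rep(0, nrow(catalog)), catalog$transcript_id)
  C[names(counts$counts)] <- counts$counts
  1e9 * C / (counts$total_mapped_reads * catalog$length_bp)
}

#' Build the four-condition expression table
#'
#' Combines the four libraries into one table with raw counts and RPKM per
#' condition, using the published column labels v4, d4, v8, d8 for the RPKM
#' quadruple.
#'
#' @param libraries list of four [library_counts()] objects, one per
#'   condition (any order).
#' @param catalog a [transcript_catalog()].
#' @return An `expression_table`: data frame keyed by `transcript_id` with
#'   columns `v4`, `d4`, `v8`, `d8` (RPKM) and `count_4dv`, `count_4dd`,
#'   `count_8dv`, `count_8dd`.
#' @export
expression_table <- function(libraries, catalog) {
  conds <- vapply(libraries, function(l) l$condition, character(1))
  if (!setequal(conds, CONDITIONS) || length(conds) != 4)
    stop("need exactly one library per condition (",
         paste(CONDITIONS, collapse = ", "), ")", call. = FALSE)
  libraries <- libraries[match(CONDITIONS, conds)]
  out <- data.frame(transcript_id = catalog$transcript_id,
                    stringsAsFactors = FALSE)
  for (lib in libraries) {
    lab <- CONDITION_LABELS[[lib$condition]]
    out[[lab]] <- unname(compute_rpkm(lib, catalog))
    cnt <- stats::setNames(rep(0, nrow(catalog)), catalog$transcript_id)
    cnt[names(lib$counts)] <- lib$counts
    out[[paste0("count_", lib$condition)]] <- unname(cnt)
  }
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Expressed / not-expressed call
#'
#' A transcript is called expressed in a library when its RPKM is strictly
#' greater than that library's detection cutoff.
#'
#' @param rpkm non-negative numeric vector of RPKM values.
#' @param cutoff non-negative scalar detection threshold.
#' @return Logical vector, `TRUE` where `rpkm > cutoff`.
#' @examples
#' is_expressed(1.2, 1.14)   # TRUE
#' is_expressed(1.14, 1.14)  # FALSE: the inequality is strict
#' @export
is_expressed <- function(rpkm, cutoff) {
  if (any(!is.finite(rpkm)) || any(rpkm < 0))
    stop("rpkm must be finite and non-negative", call. = FALSE)
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff < 0)
    stop("cutoff must be a single finite non-negative value", call. = FALSE)
  rpkm > cutoff
}
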