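#' Build a transcript catalog
#'
#' The catalog holds, for every transcript of the de novo assembled
#' transcriptome, its identifier, length in base pairs (the `L` of the RPKM
#' formula), a free-text annotation and a set of Gene Ontology labels.
#'
#' @param transcript_id character vector of unique transcript identifiers.
#' @param length_bp integer vector of transcript lengths (>= 1 bp).
#' @param description optional character vector of annotations.
#' @param go_terms optional list of character vectors of GO identifiers
#'   (`"GO:"` followed by seven digits), one element per transcript. A
#'   semicolon-separated character vector is also accepted.
#' @return An object of class `transcript_catalog`: a data frame with columns
#'   `transcript_id`, `length_bp`, `description` and a list-column `go_terms`.
#' @examples
#' transcript_catalog(c("t1", "t2"), c(1500, 800),
#'                    go_terms = list("GO:0007049", character(0)))
#' @export
transcript_catalog <- function(transcript_id, length_bp, description = "",
                               go_terms = NULL) {
  transcript_id <- as.character(transcript_id)
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript_id in catalog: ",
         paste(unique(transcript_id[duplicated(transcript_id)])[1:3],
               collapse = ", "), call. = FALSE)
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp < 1))
    stop("transcript lengths must be finite and >= 1 bp", call. = FALSE)
  n <- length(transcript_id)
  if (length(length_bp) != n)
    stop("transcript_id and length_bp differ in length", call. = FALSE)
  description <- rep_len(as.character(description), n)
  if (is.null(go_terms)) {
    go_terms <- rep(list(character(0)), n)
  } else if (is.character(go_terms)) {
    go_terms <- strsplit(go_terms, ";", fixed = TRUE)
    go_terms <- lapply(go_terms, function(x) x[nzchar(trimws(x))])
  }
  go_terms <- lapply(go_terms, function(x) unique(trimws(as.character(x))))
  bad <- unlist(go_terms)[!grepl("^GO:[0-9]{7}$", unlist(go_terms))]
  if (length(bad))
    stop("malformed GO identifiers: ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  out <- data.frame(transcript_id = transcript_id, length_bp = length_bp,
                    description = description, stringsAsFactors = FALSE)
  out$go_terms <- go_terms
  class(out) <- c("transcript_catalog", "data.frame")
  out
}

#' Read a transcript catalog from a TSV file
#'
#' Expects columns `transcript_id`, `length_bp` and optionally `description`
#' and `go_terms` (semicolon-separated GO identifiers).
#'
#' @param path path to a tab-separated file with a header row.
#' @return A [transcript_catalog()].
#' @export
read_catalog_tsv <- function(path) {
  df <- read_table_checked(path, sep = "\t",
                           required = c("transcript_id", "length_bp"))
  transcript_catalog(
    df$transcript_id, df$length_bp,
    description = if ("description" %in% names(df)) df$description else "",
    go_terms = if ("go_terms" %in% names(df)) as.character(df$go_terms) else NULL
  )
}

#' Read a transcript catalog from a FASTA file
#'
#' Transcript lengths are taken from sequence lengths; identifiers from the
#' first whitespace-delimited token of each header.
#'
#' @param path path to an uncompressed FASTA file.
#' @return A [transcript_catalog()] with empty GO annotation.
#' @export
read_catalog_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    return(transcript_catalog(ids, Biostrings::width(seqs)))
  }
  # minimal fallback parser for plain FASTA
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  lens <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) sum(nchar(gsub("\\s", "", x))), numeric(1))
  transcript_catalog(ids, lens[as.character(seq_along(ids))])
}

# internal: read a delimited table and fail loudly on schema problems
read_table_checked <- function(path, sep, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, quote = ""),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 && ncol(df) == 0)
    stop("empty file: ", path, call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}
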