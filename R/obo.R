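# Minimal OBO 1.2 reader and annotation propagation. Only the fields the
# enrichment workflow needs are consumed: id, name, is_a and
# relationship: part_of. None of the installed ontology tooling targets the
# OBO flat-file format, so the parser is written here.

#' Read a Gene Ontology OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `is_a` and
#' `relationship: part_of` edges. Obsolete terms are dropped.
#'
#' @param path path to an uncompressed OBO file.
#' @return A `go_ontology`: list with `terms` (data frame `go_id`, `name`)
#'   and `parents` (named list mapping each term to its is_a/part_of
#'   parents).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {   # some other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln))
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^relationship:\\s*part_of", ln))
      cur$parents <- c(cur$parents,
                       trimws(sub("^relationship:\\s*part_of", "", ln)))
    else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(unique(t$parents), ids))
  names(parents) <- ids
  tf <- data.frame(go_id = ids,
                   name = vapply(terms, function(t)
                     if (is.null(t$name)) NA_character_ else t$name,
                     character(1)),
                   stringsAsFactors = FALSE)
  rownames(tf) <- NULL
  structure(list(terms = tf, parents = parents), class = "go_ontology")
}

# internal: ancestors (transitive closure over parents) of every term;
# errors on cycles
.go_ancestors <- function(ontology) {
  parents <- ontology$parents
  ids <- names(parents)
  anc <- stats::setNames(vector("list", length(ids)), ids)
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) stop("cycle detected in ontology at ", id,
                                call. = FALSE)
    state[[id]] <<- 1L
    up <- parents[[id]]
    res <- up
    for (p in up) res <- union(res, visit(p))
    anc[[id]] <<- res
    state[[id]] <<- 2L
    res
  }
  for (id in ids) visit(id)
  anc
}

#' Close transcript GO annotation under ontology ancestors
#'
#' Every transcript gains all is_a/part_of ancestors of its annotated terms.
#' Idempotent. Terms absent from the ontology are kept as-is.
#'
#' @param catalog a [transcript_catalog()].
#' @param ontology a `go_ontology` from [read_obo()].
#' @return The catalog with propagated `go_terms`.
#' @export
propagate_annotations <- function(catalog, ontology) {
  stopifnot(inherits(catalog, "transcript_catalog"),
            inherits(ontology, "go_ontology"))
  anc <- .go_ancestors(ontology)
  catalog$go_terms <- lapply(catalog$go_terms, function(terms) {
    extra <- unlist(anc[intersect(terms, names(anc))], use.names = FALSE)
    sort(union(terms, extra))
  })
  catalog
}
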