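#' @importFrom rlang .data
NULL

# Namespace used to wrap bare entity labels when serializing to N-Triples.
# In-memory graphs carry bare labels; round-tripping strips this prefix again.
bkg_ns <- "urn:bkg:"

#' Build a triple graph
#'
#' A triple graph is an ordinary tibble with character columns `subject`,
#' `predicate` and `object`, one row per RDF assertion, under set semantics:
#' exact duplicates are dropped and row order never affects any downstream
#' result. Objects may be literals (kept in their quoted `"..."` form);
#' subjects, predicates and all resources that extend chain paths are bare
#' labels or IRIs.
#'
#' @param subject,predicate,object Character vectors of equal length.
#' @return A deduplicated tibble with columns `subject`, `predicate`, `object`.
#' @examples
#' triple_graph("Herb_0", "treatment", "Disease_0")
#' @export
triple_graph <- function(subject = character(), predicate = character(),
                         object = character()) {
  as_triple_graph(tibble::tibble(subject = as.character(subject),
                                 predicate = as.character(predicate),
                                 object = as.character(object)))
}

#' Coerce a data frame to a triple graph
#'
#' Validates the three required columns, trims whitespace, rejects empty
#' components and drops exact duplicates.
#'
#' @param x A data frame with columns `subject`, `predicate`, `object`.
#' @return A deduplicated tibble of triples.
#' @export
as_triple_graph <- function(x) {
  if (!is.data.frame(x)) {
    stop("a triple graph must be a data frame with subject/predicate/object",
         call. = FALSE)
  }
  need <- c("subject", "predicate", "object")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("triple graph is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  g <- tibble::as_tibble(x)[need]
  for (col in need) g[[col]] <- trimws(as.character(g[[col]]))
  if (nrow(g) && !all(nzchar(as.matrix(g)))) {
    stop("triples may not contain empty components", call. = FALSE)
  }
  dplyr::distinct(g)
}

# Convert an N-Triples term to the in-memory label convention:
# IRIs under the package namespace become bare labels, other IRIs keep their
# full text, literals keep their quoted form (including any datatype/lang tag).
term_to_label <- function(term) {
  is_iri <- startsWith(term, "<")
  out <- term
  inner <- substr(term[is_iri], 2L, nchar(term[is_iri]) - 1L)
  strip <- startsWith(inner, bkg_ns)
  inner[strip] <- substring(inner[strip], nchar(bkg_ns) + 1L)
  out[is_iri] <- inner
  out
}

label_to_term <- function(lab) {
  is_lit <- startsWith(lab, "\"")
  has_scheme <- grepl("^[A-Za-z][A-Za-z0-9+.-]*:", lab)
  iri <- ifelse(has_scheme, lab, paste0(bkg_ns, lab))
  ifelse(is_lit, lab, paste0("<", iri, ">"))
}

ntriples_pattern <- paste0(
  "^\\s*(<[^<>\"]+>)",                                   # subject IRI
  "\\s+(<[^<>\"]+>)",                                    # predicate IRI
  "\\s+(<[^<>\"]+>|\"(?:[^\"\\\\]|\\\\.)*\"",            # object IRI or literal
  "(?:\\^\\^<[^<>\"]+>|@[A-Za-z][A-Za-z0-9-]*)?)",       # optional tag
  "\\s*\\.\\s*$"
)

#' Read an N-Triples file
#'
#' One statement per line, `.`-terminated; `#` comment lines and blank lines
#' are skipped. Line order is discarded and duplicate statements collapse.
#' IRIs under the internal `urn:bkg:` namespace are returned as bare labels.
#'
#' @param path Path to an N-Triples file.
#' @return A triple graph tibble (empty file gives an empty graph).
#' @export
read_ntriples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(triple_graph())
  m <- regmatches(lines[idx], regexec(ntriples_pattern, lines[idx]))
  bad <- which(lengths(m) == 0L)
  if (length(bad)) {
    stop(sprintf("malformed N-Triples statement at line %d: %s",
                 idx[bad[1L]], lines[idx[bad[1L]]]), call. = FALSE)
  }
  parts <- do.call(rbind, m)
  triple_graph(subject = term_to_label(parts[, 2L]),
               predicate = term_to_label(parts[, 3L]),
               object = term_to_label(parts[, 4L]))
}

#' Write a triple graph as N-Triples
#'
#' Bare labels are wrapped as IRIs under a fixed internal namespace; labels
#' that already carry a scheme are emitted verbatim, quoted objects as
#' literals. Statements are written in sorted order so serialization is
#' deterministic.
#'
#' @param graph A triple graph (any data frame accepted by
#'   [as_triple_graph()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(graph, path) {
  g <- as_triple_graph(graph)
  if (any(startsWith(g$predicate, "\""))) {
    stop("predicates must be resources, not literals", call. = FALSE)
  }
  lines <- character()
  if (nrow(g)) {
    lines <- sort(paste(label_to_term(g$subject), label_to_term(g$predicate),
                        label_to_term(g$object), "."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a three-column TSV edge list as a triple graph
#'
#' Columns are subject, predicate, object (no header); `#` lines are comments.
#'
#' @param path Path to a TSV file.
#' @return A triple graph tibble.
#' @export
read_triples_tsv <- function(path) {
  df <- readr::read_delim(path, delim = "\t", quote = "",
                          col_names = c("subject", "predicate", "object"),
                          col_types = "ccc", comment = "#", progress = FALSE)
  as_triple_graph(df)
}

#' Write a triple graph as a three-column TSV
#'
#' @inheritParams write_ntriples
#' @return `path`, invisibly.
#' @export
write_triples_tsv <- function(graph, path) {
  g <- dplyr::arrange(as_triple_graph(graph), .data$subject, .data$predicate,
                      .data$object)
  readr::write_delim(g, path, delim = "\t", quote = "none", escape = "none",
                     col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' The printed worked-example instance graph
#'
#' Eight instance triples linking two herbs through a disease, drug, target,
#' protein and Entrez identifier to one gene, plus one irrelevant
#' `geneSequence` assertion that no herb-to-gene chain uses.
#'
#' @return A triple graph tibble of 8 triples.
#' @examples
#' fixture_g0()
#' @export
fixture_g0 <- function() {
  triple_graph(
    subject = c("Herb_0", "Disease_0", "Drug_0", "Target_0", "Protein_0",
                "EntrezID_0", "Herb_1", "Target_0"),
    predicate = c("treatment", "possibleDrug", "hasTarget", "hasAccession",
                  "classifiedWith", "symbol", "treatment", "geneSequence"),
    object = c("Disease_0", "Drug_0", "Target_0", "Protein_0", "EntrezID_0",
               "Gene_0", "Disease_0", "Sequence_0")
  )
}
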