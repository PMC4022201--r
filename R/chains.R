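# Formal chain model: reasoning rule chains, OWL property chains (OPCs)
# composed with an associative concatenation operator, property chain sets
# (PCS) whose positions define PIDs, and multichain configurations.

opc_sep <- "|"

validate_properties <- function(props, what = "property") {
  props <- as.character(props)
  if (!length(props)) stop("at least one ", what, " is required", call. = FALSE)
  if (any(!nzchar(trimws(props)))) {
    stop(what, " names must be non-empty", call. = FALSE)
  }
  if (any(grepl(opc_sep, props, fixed = TRUE))) {
    stop(what, " names may not contain \"", opc_sep,
         "\" (reserved for chain composition)", call. = FALSE)
  }
  trimws(props)
}

#' Build a reasoning rule chain
#'
#' A rule chain is an ordered list of class-to-class rule triples, such as
#' (Herb, treatment, Disease) followed by (Disease, possibleDrug, Drug): the
#' target class of every rule must equal the source class of the next.
#'
#' @param source_class,property,target_class Character vectors of equal
#'   length, one element per rule.
#' @return A tibble with columns `source_class`, `property`, `target_class`.
#' @examples
#' rule_chain(c("Herb", "Disease"), c("treatment", "possibleDrug"),
#'            c("Disease", "Drug"))
#' @export
rule_chain <- function(source_class, property, target_class) {
  chain <- tibble::tibble(source_class = trimws(as.character(source_class)),
                          property = validate_properties(property),
                          target_class = trimws(as.character(target_class)))
  if (!nrow(chain)) stop("a rule chain needs at least one rule", call. = FALSE)
  if (any(!nzchar(chain$source_class)) || any(!nzchar(chain$target_class))) {
    stop("class names must be non-empty", call. = FALSE)
  }
  n <- nrow(chain)
  if (n > 1L && any(chain$target_class[-n] != chain$source_class[-1L])) {
    stop("rule chain is not sequential: each rule's target class must equal ",
         "the next rule's source class", call. = FALSE)
  }
  chain
}

#' The canonical six-rule herb-to-gene chain
#'
#' Herb -> Disease -> Drug -> Target -> Protein -> EntrezID -> Gene via the
#' properties treatment, possibleDrug, hasTarget, hasAccession,
#' classifiedWith, symbol.
#'
#' @return A six-row rule chain tibble.
#' @export
herb_gene_chain <- function() {
  cls <- c("Herb", "Disease", "Drug", "Target", "Protein", "EntrezID", "Gene")
  rule_chain(cls[-7L],
             c("treatment", "possibleDrug", "hasTarget", "hasAccession",
               "classifiedWith", "symbol"),
             cls[-1L])
}

#' Initial property chain set of a rule chain
#'
#' Every rule contributes one single-property OPC, in rule order. A PCS is
#' represented as a character vector of canonical OPC names; position `k`
#' (zero-based) is the PID of that OPC.
#'
#' @param chain A rule chain tibble or a character vector of property names.
#' @return A character vector of canonical OPC names.
#' @export
rrc_to_pcs <- function(chain) {
  as_pcs(chain)
}

# Accept a rule chain tibble or a bare property vector as a PCS.
as_pcs <- function(chain) {
  if (is.data.frame(chain)) {
    if (!"property" %in% names(chain)) {
      stop("a rule chain data frame needs a `property` column", call. = FALSE)
    }
    return(validate_properties(chain$property))
  }
  if (is.character(chain)) {
    props <- as.character(chain)
    if (!length(props)) stop("PCS must be non-empty", call. = FALSE)
    if (any(!nzchar(trimws(props)))) {
      stop("OPC names must be non-empty", call. = FALSE)
    }
    return(trimws(props))
  }
  stop("cannot interpret object of class ", paste(class(chain), collapse = "/"),
       " as a property chain set", call. = FALSE)
}

#' Compose two OWL property chains
#'
#' The composition operator concatenates component lists; the canonical name
#' of an OPC is its components joined by `"|"`, which parses back
#' unambiguously because primitive property names may not contain `"|"`.
#'
#' @param left,right Canonical OPC names (vectorized).
#' @return Canonical names of the compositions.
#' @examples
#' opc_compose("treatment", "possibleDrug")
#' @export
opc_compose <- function(left, right) {
  paste(left, right, sep = opc_sep)
}

#' Split a canonical OPC name into its primitive components
#'
#' @param opc Character vector of canonical OPC names.
#' @return A list of character vectors of primitive property names.
#' @export
opc_components <- function(opc) {
  strsplit(as.character(opc), opc_sep, fixed = TRUE)
}

#' Assign the PID(s) of a predicate against a PCS
#'
#' Returns the zero-based position(s) of the OPC whose canonical name equals
#' the predicate, or `-1` if the predicate is absent (such triples are ignored
#' by the reasoners). A predicate occurring at several positions yields one
#' PID per position, and the triple participates at each.
#'
#' @param predicate A single predicate name.
#' @param pcs A property chain set (character vector of canonical OPC names).
#' @return An integer vector: positions in `0:(length(pcs) - 1)`, or `-1`.
#' @examples
#' assign_pid("treatment", rrc_to_pcs(herb_gene_chain()))
#' assign_pid("geneSequence", rrc_to_pcs(herb_gene_chain()))
#' @export
assign_pid <- function(predicate, pcs) {
  pcs <- as_pcs(pcs)
  pos <- which(pcs == predicate)
  if (!length(pos)) return(-1L)
  as.integer(pos - 1L)
}

# Replicate graph rows once per matching PID, dropping PID -1 rows.
pid_fan_out <- function(graph, pcs) {
  pids <- lapply(graph$predicate, assign_pid, pcs = pcs)
  out <- graph[rep.int(seq_len(nrow(graph)), lengths(pids)), , drop = FALSE]
  out$pid <- as.integer(unlist(pids, use.names = FALSE))
  if (!nrow(out)) out$pid <- integer()
  out[out$pid >= 0L, , drop = FALSE]
}

#' Merge the first two OPCs of a PCS
#'
#' The update step of the naive algorithm: after an iteration the first two
#' OPCs merge, the merged OPC takes PID 0 and every later PID drops by one,
#' so the PCS shortens by exactly one.
#'
#' @param pcs A property chain set of length at least 2.
#' @return A PCS one element shorter.
#' @export
merge_first_two <- function(pcs) {
  pcs <- as_pcs(pcs)
  if (length(pcs) < 2L) {
    stop("PCS already has length 1: reasoning is complete", call. = FALSE)
  }
  c(opc_compose(pcs[[1L]], pcs[[2L]]), pcs[-(1:2)])
}

#' Halve a PCS by merging adjacent OPC pairs
#'
#' The update step of the parity-rule algorithm: positions (0,1), (2,3), ...
#' merge pairwise; an unpaired final OPC (odd length) is carried over
#' unchanged. The new length is `ceiling(old / 2)`.
#'
#' @param pcs A property chain set of length at least 2.
#' @return The halved PCS.
#' @export
halve_pcs <- function(pcs) {
  pcs <- as_pcs(pcs)
  n <- length(pcs)
  if (n < 2L) {
    stop("PCS already has length 1: reasoning is complete", call. = FALSE)
  }
  i <- seq.int(1L, n - 1L, by = 2L)
  out <- opc_compose(pcs[i], pcs[i + 1L])
  if (n %% 2L == 1L) out <- c(out, pcs[[n]])
  out
}

#' Read a chain configuration file
#'
#' The YAML file holds a top-level `chains:` list; each entry has `id`,
#' `source_class`, `sink_class` and an ordered `properties` list. Together
#' the rows form the reasoning network (the set of chains run jointly) and
#' the associated result set (the class pair each chain answers).
#'
#' @param path Path to a YAML chain configuration.
#' @return A tibble with columns `chain_id`, `source_class`, `sink_class` and
#'   list-column `properties`.
#' @export
read_chain_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chains) || !length(cfg$chains)) {
    stop("chain config needs a non-empty top-level `chains:` list",
         call. = FALSE)
  }
  rows <- purrr::map(cfg$chains, function(ch) {
    for (f in c("id", "source_class", "sink_class", "properties")) {
      if (is.null(ch[[f]])) {
        stop("chain config entry is missing field `", f, "`", call. = FALSE)
      }
    }
    tibble::tibble(chain_id = as.character(ch$id),
                   source_class = as.character(ch$source_class),
                   sink_class = as.character(ch$sink_class),
                   properties = list(validate_properties(ch$properties)))
  })
  as_chain_set(dplyr::bind_rows(rows))
}

#' Assemble a chain set from rule chains
#'
#' @param ... Named rule chains (tibbles from [rule_chain()]); names become
#'   chain ids.
#' @return A chain-set tibble as returned by [read_chain_config()].
#' @examples
#' chain_set(herb_gene = herb_gene_chain())
#' @export
chain_set <- function(...) {
  chains <- list(...)
  if (!length(chains) || is.null(names(chains)) || any(!nzchar(names(chains)))) {
    stop("chain_set() needs named rule-chain arguments", call. = FALSE)
  }
  rows <- purrr::imap(chains, function(ch, id) {
    tibble::tibble(chain_id = id,
                   source_class = ch$source_class[[1L]],
                   sink_class = ch$target_class[[nrow(ch)]],
                   properties = list(as_pcs(ch)))
  })
  as_chain_set(dplyr::bind_rows(rows))
}

as_chain_set <- function(chains) {
  need <- c("chain_id", "source_class", "sink_class", "properties")
  miss <- setdiff(need, names(chains))
  if (length(miss)) {
    stop("chain set is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(chains$chain_id)) {
    stop("chain ids must be unique", call. = FALSE)
  }
  tibble::as_tibble(chains)[need]
}

write_chain_config <- function(chains, path) {
  chains <- as_chain_set(chains)
  cfg <- list(chains = purrr::pmap(chains, function(chain_id, source_class,
                                                    sink_class, properties) {
    list(id = chain_id, source_class = source_class, sink_class = sink_class,
         properties = as.list(properties))
  }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
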