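# Brute-force reference: sequential nested joins along the primitive
# property sequence. Quadratic per hop, used as the correctness oracle for
# all three reasoners.

#' Brute-force chain associations
#'
#' Flattens the PCS into its primitive property sequence and extends a
#' frontier hop by hop: start from all triples bearing the first property,
#' then repeatedly match the frontier's end node to the subjects of the next
#' property's triples. Because the PCS is flattened, any re-bracketed
#' composition of the same primitive sequence gives the identical result.
#'
#' @param graph A triple graph.
#' @param pcs A property chain set (or rule chain) of length >= 1.
#' @return A tibble of distinct `(source, sink)` endpoint pairs.
#' @examples
#' brute_force_associations(fixture_g0(), herb_gene_chain())
#' @export
brute_force_associations <- function(graph, pcs) {
  props <- unlist(opc_components(as_pcs(pcs)), use.names = FALSE)
  g <- as_triple_graph(graph)
  first <- g[g$predicate == props[[1L]], , drop = FALSE]
  frontier <- dplyr::distinct(tibble::tibble(source = first$subject,
                                             node = first$object))
  for (p in props[-1L]) {
    hop <- g[g$predicate == p, c("subject", "object"), drop = FALSE]
    frontier <- dplyr::inner_join(frontier, hop, by = c(node = "subject"),
                                  relationship = "many-to-many")
    frontier <- dplyr::distinct(tibble::tibble(source = frontier$source,
                                               node = frontier$object))
    if (!nrow(frontier)) break
  }
  dplyr::arrange(tibble::tibble(source = frontier$source,
                                sink = frontier$node),
                 .data$source, .data$sink)
}
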