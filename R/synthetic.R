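# Seeded generator of layered knowledge graphs with known ground truth,
# shaped like the herb -> disease -> drug -> target -> protein -> EntrezID
# -> gene backbone, plus distractor assertions outside every chain.

distractor_predicates <- c("crossRef", "annotation")

#' Generate a layered synthetic knowledge graph
#'
#' Entities are named `<Class>_<i>` (zero-based) in consecutive layers;
#' forward edges from layer `i` to `i + 1` carry `properties[i]`. Distractor
#' triples attach reserved out-of-chain predicates (`crossRef`,
#' `annotation`) from random chain entities to fresh `Aux_<j>` nodes, so they
#' can never extend a chain path. Ground truth (all source-to-sink endpoint
#' pairs) is computed layer by layer during generation. Identical seeds give
#' byte-identical datasets.
#'
#' @param layer_sizes Positive integer entity counts, one per class layer.
#' @param classes Class names, one per layer.
#' @param properties Property names, one fewer than layers; may not include
#'   the reserved distractor predicates.
#' @param out_degree Forward edges per entity (capped at the next layer's
#'   size; under `injective` wiring each target is used at most once).
#' @param distractor_fraction Fraction of the final graph made of distractor
#'   triples, in `[0, 1)`.
#' @param injective Use injective wiring (requires
#'   `size_i * out_degree <= size_{i+1}`); with `out_degree = 1` and equal
#'   layer sizes this yields disjoint linear paths.
#' @param seed Integer seed; all randomness is local to this call.
#' @return A `synthetic_network` list: `graph` (triple tibble), `chain` (rule
#'   chain tibble), `ground_truth` (tibble of source/sink pairs) and
#'   `config`.
#' @examples
#' ds <- generate_network(layer_sizes = rep(4L, 7), seed = 1)
#' nrow(ds$ground_truth)
#' @export
generate_network <- function(layer_sizes = rep(20L, 7L),
                             classes = c("Herb", "Disease", "Drug", "Target",
                                         "Protein", "EntrezID", "Gene"),
                             properties = c("treatment", "possibleDrug",
                                            "hasTarget", "hasAccession",
                                            "classifiedWith", "symbol"),
                             out_degree = 2L,
                             distractor_fraction = 0.2,
                             injective = FALSE,
                             seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  n_layers <- length(layer_sizes)
  if (n_layers < 2L) stop("need at least two layers", call. = FALSE)
  if (any(layer_sizes < 1L)) stop("every layer must be non-empty",
                                  call. = FALSE)
  if (length(classes) != n_layers) {
    stop("`classes` must name one class per layer", call. = FALSE)
  }
  properties <- validate_properties(properties)
  if (length(properties) != n_layers - 1L) {
    stop("`properties` must have one entry fewer than `layer_sizes`",
         call. = FALSE)
  }
  if (any(distractor_predicates %in% properties)) {
    stop("properties may not use the reserved distractor predicates: ",
         paste(distractor_predicates, collapse = ", "), call. = FALSE)
  }
  if (out_degree < 0) stop("`out_degree` must be >= 0", call. = FALSE)
  if (distractor_fraction < 0 || distractor_fraction >= 1) {
    stop("`distractor_fraction` must be in [0, 1)", call. = FALSE)
  }
  entities <- purrr::map2(classes, layer_sizes,
                          function(cl, k) paste0(cl, "_", seq_len(k) - 1L))
  withr::with_seed(as.integer(seed), {
    edges <- vector("list", n_layers - 1L)
    for (i in seq_len(n_layers - 1L)) {
      src <- entities[[i]]
      tgt <- entities[[i + 1L]]
      deg <- min(as.integer(out_degree), length(tgt))
      if (deg == 0L) {
        edges[[i]] <- tibble::tibble(from = character(), to = character())
        next
      }
      if (injective) {
        if (length(src) * deg > length(tgt)) {
          stop("injective wiring needs size_i * out_degree <= size_{i+1} ",
               sprintf("(layer %d)", i), call. = FALSE)
        }
        pool <- sample(tgt, length(src) * deg)
        edges[[i]] <- tibble::tibble(from = rep(src, each = deg), to = pool)
      } else {
        edges[[i]] <- dplyr::bind_rows(purrr::map(src, function(s) {
          tibble::tibble(from = s, to = sample(tgt, deg))
        }))
      }
    }
    chain_triples <- dplyr::bind_rows(purrr::map2(edges, properties,
      function(e, p) tibble::tibble(subject = e$from, predicate = p,
                                    object = e$to)))
    # layer-by-layer reachability, recorded as ground truth at generation time
    reach <- edges[[1L]]
    names(reach) <- c("source", "node")
    reach <- dplyr::distinct(reach)
    if (n_layers > 2L) {
      for (i in 2:(n_layers - 1L)) {
        m <- merge(reach, edges[[i]], by.x = "node", by.y = "from")
        reach <- dplyr::distinct(tibble::tibble(source = m$source,
                                                node = m$to))
        if (!nrow(reach)) break
      }
    }
    ground_truth <- dplyr::arrange(
      tibble::tibble(source = reach$source, sink = reach$node),
      .data$source, .data$sink)
    n_edges <- nrow(chain_triples)
    f <- distractor_fraction
    n_distract <- if (f > 0 && n_edges > 0) round(f / (1 - f) * n_edges) else 0L
    distractors <- empty_derived()
    if (n_distract > 0L) {
      all_entities <- unlist(entities, use.names = FALSE)
      distractors <- tibble::tibble(
        subject = sample(all_entities, n_distract, replace = TRUE),
        predicate = rep_len(distractor_predicates, n_distract),
        object = paste0("Aux_", seq_len(n_distract) - 1L))
    }
    graph <- as_triple_graph(dplyr::bind_rows(chain_triples, distractors))
  })
  chain <- rule_chain(classes[-n_layers], properties, classes[-1L])
  structure(list(graph = graph, chain = chain, ground_truth = ground_truth,
                 config = list(layer_sizes = layer_sizes, classes = classes,
                               properties = properties,
                               out_degree = out_degree,
                               distractor_fraction = distractor_fraction,
                               injective = injective,
                               seed = as.integer(seed))),
            class = "synthetic_network")
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf("<synthetic_network: %d layers, %d triples, %d ground-truth pairs, seed %d>\n",
              length(x$config$layer_sizes), nrow(x$graph),
              nrow(x$ground_truth), x$config$seed))
  invisible(x)
}

# Split `<Prefix>_<i>` names; returns NA index for non-conforming names.
split_entity_names <- function(x) {
  has_idx <- grepl("_[0-9]+$", x)
  idx <- rep(NA_integer_, length(x))
  idx[has_idx] <- as.integer(sub("^.*_([0-9]+)$", "\\1", x[has_idx]))
  prefix <- x
  prefix[has_idx] <- sub("_[0-9]+$", "", x[has_idx])
  list(prefix = prefix, index = idx)
}

#' Scale a synthetic dataset by disjoint replication
#'
#' Produces a graph with `factor` times the entities per layer under fresh
#' disjoint names (entity indices are offset per class), with the reasoning
#' rules unchanged. Ground truth replicates accordingly: association counts
#' scale exactly with `factor` while reasoner iteration counts, which depend
#' only on chain length, do not change.
#'
#' @param dataset A `synthetic_network` from [generate_network()].
#' @param factor Positive integer replication factor.
#' @return A scaled `synthetic_network`.
#' @export
scale_dataset <- function(dataset, factor) {
  stopifnot(inherits(dataset, "synthetic_network"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  if (factor == 1L) return(dataset)
  resources <- unique(c(dataset$graph$subject, dataset$graph$object,
                        dataset$ground_truth$source,
                        dataset$ground_truth$sink))
  parts <- split_entity_names(resources)
  ok <- !is.na(parts$index)
  offsets <- tapply(parts$index[ok], parts$prefix[ok],
                    function(v) max(v) + 1L)
  rename <- function(x, copy) {
    p <- split_entity_names(x)
    out <- x
    ok <- !is.na(p$index) & p$prefix %in% names(offsets)
    out[ok] <- paste0(p$prefix[ok], "_",
                      p$index[ok] + (copy - 1L) * offsets[p$prefix[ok]])
    out
  }
  graphs <- purrr::map(seq_len(factor), function(cp) {
    tibble::tibble(subject = rename(dataset$graph$subject, cp),
                   predicate = dataset$graph$predicate,
                   object = rename(dataset$graph$object, cp))
  })
  gts <- purrr::map(seq_len(factor), function(cp) {
    tibble::tibble(source = rename(dataset$ground_truth$source, cp),
                   sink = rename(dataset$ground_truth$sink, cp))
  })
  cfg <- dataset$config
  cfg$layer_sizes <- cfg$layer_sizes * factor
  structure(list(graph = as_triple_graph(dplyr::bind_rows(graphs)),
                 chain = dataset$chain,
                 ground_truth = dplyr::arrange(
                   dplyr::distinct(dplyr::bind_rows(gts)),
                   .data$source, .data$sink),
                 config = cfg),
            class = "synthetic_network")
}

#' Write a synthetic dataset to a directory
#'
#' Emits `graph.nt` (N-Triples), `ground_truth.tsv` (source/sink pairs with a
#' header) and `chains.yaml` (a single-chain configuration matching the
#' dataset's rule chain).
#'
#' @param dataset A `synthetic_network`.
#' @param dir Output directory, created if absent.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(graph = file.path(dir, "graph.nt"),
             ground_truth = file.path(dir, "ground_truth.tsv"),
             chains = file.path(dir, "chains.yaml"))
  write_ntriples(dataset$graph, paths[["graph"]])
  readr::write_tsv(dataset$ground_truth, paths[["ground_truth"]],
                   progress = FALSE)
  ch <- dataset$chain
  chains <- tibble::tibble(chain_id = "chain_0",
                           source_class = ch$source_class[[1L]],
                           sink_class = ch$target_class[[nrow(ch)]],
                           properties = list(as_pcs(ch)))
  write_chain_config(chains, paths[["chains"]])
  invisible(paths)
}
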