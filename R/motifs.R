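triad_classes <- c("003", "012", "102", "021D", "021U", "021C",
                   "111D", "111U", "030T", "030C", "201",
                   "120D", "120U", "120C", "210", "300")

# Classes whose underlying undirected triple is connected.
connected_triads <- c("021D", "021U", "021C", "111D", "111U", "030T",
                      "030C", "201", "120D", "120U", "120C", "210", "300")

# Which triad classes contain a fan-in (some node with in-degree >= 2
# within the triad)? Determined by enumerating all 3-node digraphs once.
fanin_lookup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    arcs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
    has_fanin <- stats::setNames(logical(16), triad_classes)
    for (mask in 0:63) {
      sel <- as.logical(bitwAnd(mask, 2^(0:5)))
      g <- igraph::graph_from_edgelist(arcs[sel, , drop = FALSE][,
        , drop = FALSE], directed = TRUE)
      g <- igraph::add_vertices(g, 3 - igraph::vcount(g))
      cls <- triad_classes[which(igraph::triad_census(g) == 1)]
      if (any(igraph::degree(g, mode = "in") >= 2)) {
        has_fanin[cls] <- TRUE
      }
    }
    cache <<- has_fanin
    cache
  }
})

as_directed_graph <- function(edges) {
  if (is.data.frame(edges)) {
    el <- cbind(as.character(edges$source), as.character(edges$target))
  } else {
    el <- cbind(as.character(edges[, 1]), as.character(edges[, 2]))
  }
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) stripped before motif analysis")
    el <- el[!loops, , drop = FALSE]
  }
  igraph::simplify(igraph::graph_from_edgelist(el, directed = TRUE),
                   remove.multiple = TRUE, remove.loops = TRUE)
}

#' Count connected 3-node directed motifs
#'
#' Classifies every connected 3-node induced subgraph of a simple
#' directed network into its isomorphism class (standard triad-census
#' nomenclature) and flags the classes that contain a fan-in — two
#' directed edges converging on the same node. The pure fan-in motif
#' itself is class `021U` (exactly two edges, both pointing at one node).
#' Interaction signs are ignored: motif topology is assessed on the
#' unsigned directed graph.
#'
#' @param edges a data.frame with `source`/`target` columns, or a
#'   two-column matrix of directed edges. Self-loops are stripped with a
#'   warning.
#' @return data.frame with columns `motif_class`, `observed`,
#'   `contains_fanin`, one row per connected triad class.
#' @examples
#' count_triad_motifs(data.frame(source = c("A", "B"), target = c("C", "C")))
#' @export
count_triad_motifs <- function(edges) {
  g <- as_directed_graph(edges)
  counts <- if (igraph::vcount(g) < 3) {
    stats::setNames(rep(0, 16), triad_classes)
  } else {
    stats::setNames(igraph::triad_census(g), triad_classes)
  }
  data.frame(motif_class = connected_triads,
             observed = as.numeric(counts[connected_triads]),
             contains_fanin = unname(fanin_lookup()[connected_triads]),
             stringsAsFactors = FALSE)
}

#' Motif significance against degree-preserving null networks
#'
#' Builds a null ensemble by degree-preserving directed edge swaps
#' (every node keeps its exact in- and out-degree) and reports, per
#' connected triad class, the observed count, null mean and sd, and
#' z-score \eqn{z = (obs - mean) / sd}. When the null sd is 0 (e.g. a
#' graph with no legal swaps) the z-score is undefined and reported as
#' `NA`.
#'
#' @param edges directed edge list as in [count_triad_motifs()].
#' @param n_random number of randomized networks (>= 10).
#' @param seed optional seed.
#' @param swaps_per_edge swap attempts per edge per randomization.
#' @return data.frame: `motif_class`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `contains_fanin`.
#' @export
motif_significance <- function(edges, n_random = 1000, seed = NULL,
                               swaps_per_edge = 100) {
  if (n_random < 10) stop("`n_random` must be >= 10")
  g <- as_directed_graph(edges)
  if (igraph::ecount(g) < 2) {
    warning("graph too sparse for degree-preserving swaps; sampling a ",
            "configuration-model null instead")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- count_triad_motifs(
    igraph::as_edgelist(g, names = TRUE))
  niter <- swaps_per_edge * max(igraph::ecount(g), 1)
  null_counts <- vapply(seq_len(n_random), function(r) {
    gr <- if (igraph::ecount(g) >= 2) {
      igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                               niter = niter))
    } else {
      igraph::sample_degseq(igraph::degree(g, mode = "out"),
                            igraph::degree(g, mode = "in"))
    }
    stats::setNames(igraph::triad_census(gr),
                    triad_classes)[connected_triads]
  }, numeric(length(connected_triads)))
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1, stats::sd)
  z <- ifelse(null_sd > 0, (obs$observed - null_mean) / null_sd, NA_real_)
  data.frame(motif_class = connected_triads,
             observed = obs$observed,
             null_mean = null_mean, null_sd = null_sd, z = z,
             contains_fanin = obs$contains_fanin,
             stringsAsFactors = FALSE)
}
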