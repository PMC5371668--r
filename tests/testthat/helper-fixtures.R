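# Shared fixture builders (all generated in code; no data files).

# 10-taxon weak background with 10 planted strong pairs, the standard
# community for consensus-recovery checks.
make_planted_system <- function(seed = 7) {
  bg <- sample_interaction_matrix(
    10,
    type_mixture = c(mutual = 0.15, competitive = 0.15, commensal = 0.1,
                     amensal = 0.1, none = 0.5),
    magnitude_range = c(0.02, 0.08), diag_range = c(1.5, 2.0),
    seed = seed)
  planted <- data.frame(
    taxon_a = paste0("T", c(1, 2, 3, 4, 5, 6, 1, 3, 5, 7)),
    taxon_b = paste0("T", c(2, 3, 4, 5, 6, 7, 8, 9, 10, 8)),
    type = c("mutual", "mutual", "mutual", "competitive", "competitive",
             "competitive", "commensal", "commensal", "amensal",
             "amensal"),
    stringsAsFactors = FALSE)
  model <- plant_interactions(bg, planted, magnitude_range = c(0.5, 0.9),
                              seed = seed + 1)
  list(model = model, planted = planted,
       planted_edges = attr(model, "planted"))
}

# Pooled noisy trajectories from the planted system (24 subjects x 13
# points over 6 days).
make_planted_profiles <- function(model, n_traj = 24, t_end = 6,
                                  dt = 0.5, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_traj), function(k) {
    x0 <- stats::runif(length(model$taxa), 0.05, 0.4)
    simulate_glv(model, x0, seq(0, t_end, by = dt), noise_sd = noise_sd,
                 seed = seed * 1000 + k, renormalize = FALSE)
  })
}

# Directed graph with a dense random core plus pure fan-ins planted on
# fresh target nodes whose two source nodes are deliberately unconnected;
# degree-preserving rewiring tends to connect the rewired sources, so the
# exact-convergent class is enriched in the observed graph.
make_fanin_graph <- function(seed = 3, n_core = 20, m_core = 200,
                             n_fan = 100) {
  set.seed(seed)
  el <- unique(t(replicate(m_core * 3, sample(n_core, 2))))[
    seq_len(m_core), , drop = FALSE]
  core <- data.frame(source = paste0("N", el[, 1]),
                     target = paste0("N", el[, 2]),
                     stringsAsFactors = FALSE)
  adj <- matrix(FALSE, n_core, n_core)
  adj[el] <- TRUE
  fan <- NULL
  made <- 0
  while (made < n_fan) {
    ab <- sample(n_core, 2)
    if (!adj[ab[1], ab[2]] && !adj[ab[2], ab[1]]) {
      made <- made + 1
      fan <- rbind(fan, data.frame(source = paste0("N", ab),
                                   target = paste0("F", made),
                                   stringsAsFactors = FALSE))
    }
  }
  rbind(core, fan)
}

# Fixture IIP network realizing given per-type pair counts on disjoint
# taxon pairs (arithmetic fixture, not an inferred network).
make_count_network <- function(n_commensal, n_amensal, n_mutual,
                               n_competitive) {
  total <- n_commensal + n_amensal + n_mutual + n_competitive
  a <- sprintf("PairA_%05d", seq_len(total))
  b <- sprintf("PairB_%05d", seq_len(total))
  type <- rep(c("commensal", "amensal", "mutual", "competitive"),
              c(n_commensal, n_amensal, n_mutual, n_competitive))
  src <- character(0); tgt <- character(0); sgn <- integer(0)
  one_way <- type %in% c("commensal", "amensal")
  src <- c(a, b[!one_way])
  tgt <- c(b, a[!one_way])
  sgn <- c(ifelse(type %in% c("mutual", "commensal"), 1L, -1L),
           ifelse(type[!one_way] == "mutual", 1L, -1L))
  consensus_network(data.frame(source = src, target = tgt, sign = sgn,
                               stringsAsFactors = FALSE))
}

# Star fixture: one focal taxon with partner pairs of given type counts
# (commensal toward the partner, amensal toward the partner).
make_star_pairs <- function(focal, n_commensal, n_mutual, n_amensal,
                            n_competitive) {
  total <- n_commensal + n_mutual + n_amensal + n_competitive
  partners <- sprintf("Partner_%03d", seq_len(total))
  type <- rep(c("commensal", "mutual", "amensal", "competitive"),
              c(n_commensal, n_mutual, n_amensal, n_competitive))
  src <- focal
  edges <- do.call(rbind, lapply(seq_len(total), function(i) {
    switch(type[i],
      commensal = data.frame(source = focal, target = partners[i],
                             sign = 1L),
      amensal = data.frame(source = focal, target = partners[i],
                           sign = -1L),
      mutual = data.frame(source = c(focal, partners[i]),
                          target = c(partners[i], focal),
                          sign = c(1L, 1L)),
      competitive = data.frame(source = c(focal, partners[i]),
                               target = c(partners[i], focal),
                               sign = c(-1L, -1L)))
  }))
  classify_pairs(consensus_network(edges))
}

# Synthetic consistency scores realizing given class counts for one
# (focal, group) cell.
make_scores <- function(focal, group, n_consistent, n_conflict,
                        n_nodiff) {
  total <- n_consistent + n_conflict + n_nodiff
  if (!total) return(NULL)
  data.frame(
    focal = focal,
    partner = sprintf("%s_p%03d", focal, seq_len(total)),
    group = group,
    expected = "increase",
    observed = rep(c("increase", "decrease", "no-difference"),
                   c(n_consistent, n_conflict, n_nodiff)),
    class = rep(c("consistent", "conflict", "no-difference"),
                c(n_consistent, n_conflict, n_nodiff)),
    stringsAsFactors = FALSE)
}
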