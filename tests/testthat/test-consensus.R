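make_tally <- function(taxa, retained, pos, neg, coef_sum, R) {
  dimnames(retained) <- dimnames(pos) <- dimnames(neg) <-
    dimnames(coef_sum) <- list(taxa, taxa)
  structure(list(retained = retained, pos = pos, neg = neg,
                 coef_sum = coef_sum, R = R, taxa = taxa,
                 top_fraction = 0.25),
            class = "edge_tally")
}

test_that("replicate support behaves at the degenerate settings", {
  set.seed(21)
  m <- sample_interaction_matrix(4, seed = 21)
  prof <- simulate_glv(m, stats::runif(4, 0.1, 0.4), seq(0, 3, 0.25),
                       noise_sd = 0.05, seed = 22, renormalize = FALSE)
  one <- replicate_inference(prof, R = 1, top_fraction = 0.25, seed = 1,
                             max_gap = Inf)
  expect_true(all(one$retained %in% c(0, 1)))
  net1 <- build_consensus(one, cutoff = 0.5)
  expect_true(all(net1$edges$support == 1))

  # no bootstrap variation, full top fraction: every ordered pair kept
  # in every replicate
  all_edges <- replicate_inference(prof, R = 3, top_fraction = 1,
                                   bootstrap = FALSE, seed = 1,
                                   max_gap = Inf)
  off <- row(all_edges$retained) != col(all_edges$retained)
  expect_true(all(all_edges$retained[off] == 3))
  expect_equal(nrow(build_consensus(all_edges, 1)$edges), 4 * 3)

  expect_error(replicate_inference(prof, R = 0), ">= 1")
  expect_error(replicate_inference(prof, top_fraction = 1.5), "top_fraction")
})

test_that("a dominant planted edge attains maximal support", {
  m <- sample_interaction_matrix(
    5, type_mixture = c(none = 1), seed = 31)
  A <- m$interactions
  A["T2", "T1"] <- 0.9   # strong effect of T1 on T2
  m <- glv_model(m$growth_rates, A, m$taxa)
  set.seed(32)
  profs <- lapply(1:24, function(k) {
    simulate_glv(m, stats::runif(5, 0.05, 0.4), seq(0, 6, 0.5),
                 noise_sd = 0.05, seed = 320 + k, renormalize = FALSE)
  })
  tal <- replicate_inference(profs, R = 50, top_fraction = 0.25,
                             seed = 33, lambda = 1e-3, max_gap = Inf,
                             predictor = "midpoint")
  expect_equal(max(tal$retained), tal$retained["T2", "T1"])
})

test_that("consensus thresholding is inclusive and majority-signed", {
  taxa <- c("A", "B")
  z <- matrix(0, 2, 2)
  ret <- matrix(c(0, 49, 50, 0), 2, 2)  # [i,j] = edge j -> i
  pos <- matrix(c(0, 49, 30, 0), 2, 2)
  neg <- matrix(c(0, 0, 20, 0), 2, 2)
  cs <- matrix(c(0, 4.9, 1.0, 0), 2, 2)
  tal <- make_tally(taxa, ret, pos, neg, cs, R = 100)
  net <- build_consensus(tal, cutoff = 0.5)
  # support 50/100 retained ("at least 50 times"), 49/100 dropped
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "B")
  expect_equal(net$edges$target, "A")
  expect_equal(net$edges$support, 0.5)
  expect_equal(net$edges$sign, 1L)
  expect_equal(net$edges$mean_coeff, 1 / 50)

  # exact sign ties drop the edge
  tie <- make_tally(taxa, matrix(c(0, 0, 60, 0), 2, 2),
                    matrix(c(0, 0, 30, 0), 2, 2),
                    matrix(c(0, 0, 30, 0), 2, 2), z, R = 100)
  expect_message(tied <- build_consensus(tie, 0.5), "sign tie")
  expect_equal(nrow(tied$edges), 0)

  # empty tallies give an empty network
  empty <- build_consensus(make_tally(taxa, z, z, z, z, 10), 0.5)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(classify_pairs(empty)), 0)

  expect_error(build_consensus(tal, cutoff = 0), "cutoff")
})

test_that("raising the cutoff never adds edges", {
  set.seed(41)
  m <- sample_interaction_matrix(5, seed = 41)
  prof <- simulate_glv(m, stats::runif(5, 0.1, 0.4), seq(0, 4, 0.5),
                       noise_sd = 0.1, seed = 42, renormalize = FALSE)
  tal <- replicate_inference(prof, R = 30, seed = 43, max_gap = Inf)
  sizes <- vapply(c(0.2, 0.5, 0.8, 1), function(ct) {
    nrow(build_consensus(tal, ct)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("pair classification implements the sign conventions", {
  edges <- data.frame(
    source = c("A", "B", "C", "D", "E", "G", "I"),
    target = c("B", "A", "D", "C", "F", "H", "J"),
    sign = c(1L, 1L, -1L, -1L, 1L, -1L, 1L),
    support = c(0.9, 0.7, 0.8, 0.6, 0.55, 0.95, 0.5))
  edges <- rbind(edges,
                 data.frame(source = "J", target = "I", sign = -1L,
                            support = 0.6))
  pairs <- classify_pairs(consensus_network(edges))
  types <- stats::setNames(pairs$type,
                           paste(pairs$taxon_a, pairs$taxon_b))
  expect_equal(unname(types["A B"]), "mutual")
  expect_equal(unname(types["C D"]), "competitive")
  expect_equal(unname(types["E F"]), "commensal")
  expect_equal(unname(types["G H"]), "amensal")
  expect_equal(unname(types["I J"]), "exploitative")
  # partition: five classes cover every pair with a retained edge
  expect_equal(nrow(pairs), 5)
  expect_equal(sum(table(pairs$type)), nrow(pairs))
  # directional bookkeeping for the commensal pair
  ef <- pairs[pairs$taxon_a == "E", ]
  expect_equal(ef$sign_ab, 1L)
  expect_equal(ef$sign_ba, 0L)
})

test_that("partner subnetworks reproduce printed-count arithmetic", {
  pairs <- make_star_pairs("Lactococcus", n_commensal = 1, n_mutual = 41,
                           n_amensal = 1, n_competitive = 41)
  sub <- partner_subnetwork(pairs, "Lactococcus")
  expect_equal(nrow(sub$pairs), 84)
  bd <- stats::setNames(sub$breakdown$n, sub$breakdown$type)
  expect_equal(unname(bd[c("commensal", "mutual", "amensal",
                           "competitive")]), c(1, 41, 1, 41))

  # a known taxon with no edges yields an empty subset
  none <- partner_subnetwork(pairs, "Hermit", taxa = "Hermit")
  expect_equal(nrow(none$pairs), 0)
  expect_error(partner_subnetwork(pairs, "Unknown"), "not present")

  # union over focals equals union of individual queries
  p2 <- rbind(pairs,
              make_star_pairs("Bacillus", 1, 2, 1, 2))
  both <- partner_subnetwork(p2, c("Lactococcus", "Bacillus"))
  u <- unique(rbind(partner_subnetwork(p2, "Lactococcus")$pairs,
                    partner_subnetwork(p2, "Bacillus")$pairs))
  expect_setequal(paste(both$pairs$taxon_a, both$pairs$taxon_b),
                  paste(u$taxon_a, u$taxon_b))
})

test_that("network export round-trips through the TSV edge list", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      sign = c(1L, -1L), support = c(0.8, 0.6),
                      mean_coeff = c(0.5, -0.2))
  net <- consensus_network(edges, taxa = c("A", "B", "C"))
  path <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, path, graphml_path = gml)
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(back$source, edges$source)
  expect_equal(back$mean_coeff, edges$mean_coeff)
  expect_true(file.exists(gml))
})
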