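rel_table <- function(mat, group) {
  colnames(mat) <- paste0(group, "_a", seq_len(ncol(mat)))
  abundance_table(mat, metadata = data.frame(sample = colnames(mat),
                                             group = group),
                  integer_counts = FALSE)
}

test_that("fold-change classification uses strict relevance thresholds", {
  expect_equal(classify_fold_change(c(9.88, 1.91, 0.3, 2, 0.5, 2.0001)),
               c("increase", "no-difference", "decrease", "no-difference",
                 "no-difference", "increase"))
})

test_that("fold changes are ratios of group mean relative abundances", {
  tr <- rel_table(matrix(c(0.22, 0.78, 0.18, 0.82), 2, 2,
                         dimnames = list(c("P", "Q"), NULL)), "G1")
  ct <- rel_table(matrix(c(0.02, 0.98, 0.02, 0.98), 2, 2,
                         dimnames = list(c("P", "Q"), NULL)), "G5")
  fc <- fold_changes(tr, ct)
  expect_equal(fc$fc[fc$taxon == "P"], 0.2 / 0.02)
  expect_equal(fc$class[fc$taxon == "P"], "increase")
  expect_equal(fc$class[fc$taxon == "Q"], "no-difference")
  expect_true(all(fc$fc > 0))

  # swapping treatment and control inverts fold changes and classes
  rev <- fold_changes(ct, tr)
  expect_equal(rev$fc[rev$taxon == "P"], 1 / fc$fc[fc$taxon == "P"])
  expect_equal(rev$class[rev$taxon == "P"], "decrease")

  # zero-abundance taxa are excluded and named
  tr0 <- rel_table(matrix(c(0.2, 0.8, 0, 0.3, 0.7, 0), 3, 2,
                          dimnames = list(c("P", "Q", "Gone"), NULL)),
                   "G1")
  ct0 <- rel_table(matrix(c(0.1, 0.8, 0.1, 0.2, 0.7, 0.1), 3, 2,
                          dimnames = list(c("P", "Q", "Gone"), NULL)),
                   "G5")
  fc0 <- fold_changes(tr0, ct0)
  expect_equal(attr(fc0, "excluded"), "Gone")
  expect_false("Gone" %in% fc0$taxon)
  expect_error(fold_changes(tr0, ct0, taxa = "Gone"), "no evaluable")
})

test_that("consistency scoring applies the expected-direction rule", {
  edges <- data.frame(
    source = c("P", "M", "P", "N", "P", "P", "R"),
    target = c("M", "P", "N", "P", "C", "D", "P"),
    sign = c(1L, 1L, -1L, -1L, 1L, -1L, 1L))
  pairs <- classify_pairs(consensus_network(edges))
  fc <- data.frame(
    taxon = c("M", "N", "C", "D", "R"),
    fc = c(3.0, 3.0, 1.2, 0.2, 5),
    class = classify_fold_change(c(3.0, 3.0, 1.2, 0.2, 5)),
    stringsAsFactors = FALSE)
  sc <- score_consistency(pairs, fc, administered = "P", group = "G1")
  cls <- stats::setNames(sc$class, sc$partner)
  expect_equal(unname(cls["M"]), "consistent")     # mutual, FC 3
  expect_equal(unname(cls["N"]), "conflict")       # competitive, FC 3
  expect_equal(unname(cls["C"]), "no-difference")  # commensal, FC 1.2
  expect_equal(unname(cls["D"]), "consistent")     # amensal, FC 0.2
  # R benefits P but receives no edge: skipped, no expectation
  expect_false("R" %in% sc$partner)
  expect_true("R" %in% attr(sc, "skipped"))
  # every scored IIP gets exactly one class
  expect_equal(nrow(sc), 4)
  expect_error(score_consistency(pairs, fc, administered = "Zed"),
               "absent")
})

test_that("validation summaries reproduce count arithmetic", {
  scores <- rbind(make_scores("Lactococcus", "G1", 34, 15, 16),
                  make_scores("Corynebacterium", "G1", 27, 18, 12),
                  make_scores("Bacillus", "G1", 24, 18, 10))
  sm <- summarize_validation(scores)
  lac <- sm$by_focal[sm$by_focal$focal == "Lactococcus", ]
  expect_equal(lac$n, 65)
  expect_equal(lac$consistent_pct, 52.3)
  expect_equal(lac$conflict_pct, 23.1)
  pooled <- sm$pooled
  expect_equal(pooled$n, 174)
  expect_equal(pooled$consistent, 85)
  expect_equal(pooled$consistent_pct, 48.9)
  expect_equal(pooled$conflict_pct, 29.3)
  # classes partition the evaluable IIPs
  expect_equal(pooled$consistent + pooled$conflict +
                 pooled$no_difference, pooled$n)

  empty <- summarize_validation(
    data.frame(focal = character(0), group = character(0),
               class = character(0)))
  expect_equal(nrow(empty$pooled), 0)
})

test_that("delta-delta-Ct log2 fold changes follow the qPCR convention", {
  same <- expression_log2fc(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$log2fc, 0)

  lower <- expression_log2fc(c(3, 4, 5), c(5, 6, 7))
  expect_equal(lower$log2fc, 2)

  # constructed sets with mean paired difference -2.34
  ctrl <- c(6.1, 5.8, 6.4, 6.0)
  trt <- ctrl - 2.34 + c(0.05, -0.05, 0.1, -0.1)
  res <- expression_log2fc(trt, ctrl)
  expect_equal(res$log2fc, 2.34)
  expect_lt(res$p, 0.05)

  unpaired <- expression_log2fc(c(3, 4, 5), c(5, 6, 7, 8),
                                paired = FALSE)
  expect_equal(unpaired$log2fc, 2.5)
  expect_error(expression_log2fc(2, c(1, 2)), "n >= 2")
  expect_error(expression_log2fc(c(1, 2, 3), c(1, 2)), "equal group")
})

test_that("trial data from a known network validates end to end", {
  # rare administered probiotic P, strong positive edge P -> Q, strong
  # negative edge P -> R, bystanders S and U; feasible equilibrium
  taxa <- c("P", "Q", "R", "S", "U")
  A <- diag(-1, 5)
  A[2, 1] <- 0.8   # P benefits Q
  A[3, 1] <- -0.8  # P harms R
  b <- c(0.01, 0.3, 0.3, 0.3, 0.3)
  model <- glv_model(b, A, taxa)
  xs <- glv_equilibrium(model)
  expect_true(all(xs > 0))
  baseline <- xs / sum(xs)

  des <- trial_design(list(G1 = "P", G5 = character(0)),
                      n_per_group = 4, boost = 15)
  trial <- generate_trial(model, baseline, des, seed = 55,
                          animal_sd = 0.1, depth = NULL)
  fc <- fold_changes(trial$G1, trial$G5)
  # the administered genus ends up relevantly elevated (its nominal
  # 15x boost is diluted by the partners' compositional response)
  expect_gt(fc$fc[fc$taxon == "P"], 2)
  expect_equal(fc$class[fc$taxon == "P"], "increase")

  pairs <- classify_pairs(consensus_network(data.frame(
    source = c("P", "P"), target = c("Q", "R"), sign = c(1L, -1L))))
  sc <- score_consistency(pairs, fc, administered = "P", group = "G1")
  cls <- stats::setNames(sc$class, sc$partner)
  expect_equal(unname(cls["Q"]), "consistent")
  expect_equal(unname(cls["R"]), "consistent")
})
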