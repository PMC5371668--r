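#' Default pipeline configuration
#'
#' Defaults mirror the motivating study design: 12 sampling points over
#' 15 days, 100 inference replicates, top-25% magnitude filter, support
#' cutoff 0.5, and fold-change relevance thresholds 2 and 0.5. Simulation
#' sizes (taxa, depth, motif randomizations) are desk-scale.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_taxa = 12,
    times = default_schedule(),
    depth = 5000,
    noise_sd = 0.1,
    lambda = 0.01,
    pseudo = NULL,
    max_gap = 5,
    replicates = 100,
    top_fraction = 0.25,
    cutoff = 0.5,
    motif_randomizations = 100,
    n_per_group = 4,
    boost = 15,
    fc_upper = 2,
    fc_lower = 0.5
  )
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                           call. = FALSE)
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one number")
  check(cfg$n_taxa >= 2, "n_taxa must be >= 2")
  check(length(cfg$times) >= 3 && all(diff(cfg$times) > 0),
        "times must be >= 3 strictly increasing values")
  check(cfg$depth >= 1, "depth must be >= 1")
  check(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  check(cfg$lambda >= 0, "lambda must be >= 0")
  check(cfg$replicates >= 1, "replicates must be >= 1")
  check(cfg$top_fraction > 0 && cfg$top_fraction <= 1,
        "top_fraction must be in (0, 1]")
  check(cfg$cutoff > 0 && cfg$cutoff <= 1, "cutoff must be in (0, 1]")
  check(cfg$motif_randomizations >= 10,
        "motif_randomizations must be >= 10")
  check(cfg$n_per_group >= 2, "n_per_group must be >= 2")
  check(cfg$boost > 0, "boost must be > 0")
  check(cfg$fc_upper > cfg$fc_lower, "fc_upper must exceed fc_lower")
  cfg
}

write_tsv_stage <- function(df, path, header) {
  writeLines(paste0("# ", header), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  path
}

#' Run the full synthetic-community analysis pipeline
#'
#' Executes simulate -> normalize -> diversity -> fit -> consensus ->
#' classify -> motifs -> trial -> validate in order, writing one TSV per
#' stage plus a JSON manifest recording every parameter, seed and output
#' digest. Identical configuration and seed give byte-identical numeric
#' outputs.
#'
#' @param config named list (or path to a YAML file) overriding
#'   [default_config()]; validated before any compute.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`model`, `profile`, `counts`, `diversity`, `fit`, `network`,
#'   `pairs`, `motifs`, `trial`, `validation`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gutglv_run_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  # --- simulate ------------------------------------------------------
  model <- stage("simulate:model", {
    sample_interaction_matrix(cfg$n_taxa, seed = cfg$seed)
  })
  x0 <- stage("simulate:trajectory", {
    set.seed(cfg$seed + 1)
    x0 <- stats::runif(cfg$n_taxa, 0.02, 0.2)
    x0 / sum(x0)
  })
  profile <- stage("simulate:profile", {
    simulate_glv(model, x0, cfg$times, noise_sd = cfg$noise_sd,
                 seed = cfg$seed + 2)
  })
  counts <- stage("simulate:counts", {
    counts_from_profile(profile, depth = cfg$depth, seed = cfg$seed + 3)
  })
  truth_path <- file.path(out_dir, "ground_truth_edges.tsv")
  write_ground_truth(model, truth_path)
  counts_path <- file.path(out_dir, "counts.tsv")
  write_table(counts, counts_path)

  # --- diversity -----------------------------------------------------
  div <- stage("diversity", diversity_table(counts))
  div_path <- write_tsv_stage(div, file.path(out_dir, "diversity.tsv"),
    "per-time alpha diversity (mean and standard error across samples)")

  # --- fit -----------------------------------------------------------
  fitted <- stage("fit", {
    sys <- build_regression_system(to_profile(counts), pseudo = cfg$pseudo,
                                   max_gap = cfg$max_gap)
    fit_glv(sys, lambda = cfg$lambda)
  })
  fit_path <- file.path(out_dir, "fitted_edges.tsv")
  write_model(fitted, fit_path,
              growth_path = file.path(out_dir, "fitted_growth_rates.tsv"))

  # --- consensus + classify -----------------------------------------
  network <- stage("consensus", {
    tal <- replicate_inference(to_profile(counts), R = cfg$replicates,
                               top_fraction = cfg$top_fraction,
                               seed = cfg$seed + 4, lambda = cfg$lambda,
                               pseudo = cfg$pseudo, max_gap = cfg$max_gap)
    build_consensus(tal, cutoff = cfg$cutoff)
  })
  net_path <- file.path(out_dir, "consensus_network.tsv")
  write_network(network, net_path,
                graphml_path = file.path(out_dir, "consensus_network.graphml"))
  pairs <- stage("classify", classify_pairs(network))
  pairs_path <- write_tsv_stage(pairs, file.path(out_dir, "iips.tsv"),
    "inferred interaction pairs (IIPs); sign_ab is the effect of taxon_a on taxon_b")

  # --- motifs --------------------------------------------------------
  motifs <- stage("motifs", {
    if (nrow(network$edges) >= 2) {
      motif_significance(network$edges,
                         n_random = cfg$motif_randomizations,
                         seed = cfg$seed + 5)
    } else {
      count_triad_motifs(network$edges)
    }
  })
  motifs_path <- write_tsv_stage(motifs, file.path(out_dir, "motifs.tsv"),
    "3-node directed motif report vs degree-preserving nulls")

  # --- trial + validate ---------------------------------------------
  administered <- model$taxa[1:min(3, cfg$n_taxa)]
  groups <- c(stats::setNames(as.list(administered),
                              paste0("G", seq_along(administered))),
              list(G4 = administered, G5 = character(0)))
  design <- trial_design(groups, n_per_group = cfg$n_per_group,
                         boost = cfg$boost)
  trial <- stage("trial", {
    generate_trial(model, baseline = profile$abundances[, 1],
                   design = design, seed = cfg$seed + 6,
                   depth = cfg$depth)
  })
  validation <- stage("validate", {
    scores <- do.call(rbind, lapply(setdiff(design$groups, "G5"),
      function(g) {
        fc <- fold_changes(trial[[g]], trial$G5)
        score_consistency(pairs, fc, design$administered[[g]], group = g)
      }))
    summarize_validation(scores)
  })
  val_path <- write_tsv_stage(validation$by_focal,
    file.path(out_dir, "validation_by_focal.tsv"),
    "per-focal consistency of trial fold changes with the inferred network")
  pooled_path <- write_tsv_stage(validation$pooled,
    file.path(out_dir, "validation_pooled.tsv"),
    "pooled consistency ratios per trial group")

  # --- manifest ------------------------------------------------------
  outputs <- c(truth_path, counts_path, div_path, fit_path, net_path,
               pairs_path, motifs_path, val_path, pooled_path)
  manifest <- list(
    package = "gutglv",
    version = as.character(utils::packageVersion("gutglv")),
    config = cfg[order(names(cfg))],
    seeds = list(model = cfg$seed, x0 = cfg$seed + 1,
                 noise = cfg$seed + 2, counts = cfg$seed + 3,
                 consensus = cfg$seed + 4, motifs = cfg$seed + 5,
                 trial = cfg$seed + 6),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(model = model, profile = profile, counts = counts,
                 diversity = div, fit = fitted, network = network,
                 pairs = pairs, motifs = motifs, trial = trial,
                 validation = validation, manifest = manifest,
                 out_dir = out_dir))
}
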