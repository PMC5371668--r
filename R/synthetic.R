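#' Sample a ground-truth gLV interaction matrix
#'
#' Draws a community model whose unordered taxon pairs realize a requested
#' mixture of ecological interaction types. Pair types are assigned by
#' permutation so the realized counts match a deterministic
#' largest-remainder allocation of `type_mixture` over the
#' \eqn{\binom{n}{2}} pairs exactly, rather than by independent draws.
#' Sign conventions follow the pairwise classification used downstream:
#' mutual (+,+), competitive (-,-), commensal (+,0), amensal (-,0),
#' none (0,0); for the one-sided types the affected direction is chosen at
#' random.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param type_mixture named or positional numeric vector of proportions
#'   over `c("mutual", "competitive", "commensal", "amensal", "none")`;
#'   must be non-negative and sum to 1.
#' @param magnitude_range interval from which off-diagonal coefficient
#'   magnitudes are drawn uniformly.
#' @param diag_range interval (of magnitudes) for the strictly negative
#'   diagonal self-limitation terms.
#' @param growth_range interval for intrinsic growth rates.
#' @param seed optional integer seed; identical inputs and seed give an
#'   identical model.
#' @return A [glv_model] with attribute `pair_types`, a data.frame of the
#'   planted type per unordered pair (the ground truth for recovery
#'   tests).
#' @export
sample_interaction_matrix <- function(n_taxa,
                                      type_mixture = c(mutual = 0.2,
                                                       competitive = 0.2,
                                                       commensal = 0.15,
                                                       amensal = 0.15,
                                                       none = 0.3),
                                      magnitude_range = c(0.1, 0.5),
                                      diag_range = c(0.8, 1.2),
                                      growth_range = c(0.3, 0.8),
                                      seed = NULL) {
  if (n_taxa < 2) stop("`n_taxa` must be >= 2")
  types <- c("mutual", "competitive", "commensal", "amensal", "none")
  mix <- type_mixture
  if (!is.null(names(mix))) {
    if (!all(names(mix) %in% types)) {
      stop("unknown interaction type(s): ",
           paste(setdiff(names(mix), types), collapse = ", "))
    }
    full <- stats::setNames(numeric(5), types)
    full[names(mix)] <- mix
    mix <- full
  } else {
    if (length(mix) != 5) stop("positional `type_mixture` needs 5 entries")
    names(mix) <- types
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("`type_mixture` proportions must be non-negative and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)

  pairs <- utils::combn(n_taxa, 2)
  n_pairs <- ncol(pairs)
  counts <- largest_remainder(mix * n_pairs)
  pair_type <- sample(rep(types, counts))

  taxa <- paste0("T", seq_len(n_taxa))
  A <- matrix(0, n_taxa, n_taxa, dimnames = list(taxa, taxa))
  mag <- function(k) stats::runif(k, magnitude_range[1], magnitude_range[2])
  for (p in seq_len(n_pairs)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    switch(pair_type[p],
      mutual =      { A[i, j] <-  mag(1); A[j, i] <-  mag(1) },
      competitive = { A[i, j] <- -mag(1); A[j, i] <- -mag(1) },
      commensal =   { if (stats::runif(1) < 0.5) A[i, j] <-  mag(1)
                      else                       A[j, i] <-  mag(1) },
      amensal =     { if (stats::runif(1) < 0.5) A[i, j] <- -mag(1)
                      else                       A[j, i] <- -mag(1) },
      none = NULL)
  }
  diag(A) <- -stats::runif(n_taxa, diag_range[1], diag_range[2])
  b <- stats::runif(n_taxa, growth_range[1], growth_range[2])
  model <- glv_model(b, A, taxa)
  attr(model, "pair_types") <- data.frame(
    taxon_a = taxa[pairs[1, ]], taxon_b = taxa[pairs[2, ]],
    type = pair_type, stringsAsFactors = FALSE)
  model
}

#' Plant strong interaction pairs into a background model
#'
#' Overwrites selected unordered pairs of a (typically weak) background
#' model with strong coefficients of a requested ecological type, giving
#' a ground truth with a clear signal-to-background separation for
#' recovery experiments.
#'
#' @param model a [glv_model] (the background).
#' @param planted data.frame with columns `taxon_a`, `taxon_b` (labels or
#'   indices) and `type` in mutual/competitive/commensal/amensal. For the
#'   one-sided types, `taxon_a` acts on `taxon_b`.
#' @param magnitude_range interval for the planted coefficient
#'   magnitudes.
#' @param seed optional seed.
#' @return The modified [glv_model]; the realized planted coefficients
#'   are recorded in `attr(, "planted")` (columns source, target,
#'   coefficient).
#' @export
plant_interactions <- function(model, planted,
                               magnitude_range = c(0.5, 0.9),
                               seed = NULL) {
  stopifnot(inherits(model, "glv_model"))
  if (!is.null(seed)) set.seed(seed)
  A <- model$interactions
  taxa <- model$taxa
  as_idx <- function(x) if (is.numeric(x)) x else match(x, taxa)
  mag <- function() stats::runif(1, magnitude_range[1], magnitude_range[2])
  rec <- list()
  for (r in seq_len(nrow(planted))) {
    i <- as_idx(planted$taxon_a[r]); j <- as_idx(planted$taxon_b[r])
    if (anyNA(c(i, j))) stop("unknown taxon in planted pair ", r)
    A[i, j] <- 0; A[j, i] <- 0
    switch(planted$type[r],
      mutual =      { A[i, j] <- mag(); A[j, i] <- mag() },
      competitive = { A[i, j] <- -mag(); A[j, i] <- -mag() },
      commensal =   { A[j, i] <- mag() },
      amensal =     { A[j, i] <- -mag() },
      stop("unknown planted type: ", planted$type[r]))
    for (pr in list(c(j, i), c(i, j))) {
      if (A[pr[1], pr[2]] != 0) {
        rec[[length(rec) + 1]] <- data.frame(
          source = taxa[pr[2]], target = taxa[pr[1]],
          coefficient = A[pr[1], pr[2]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- glv_model(model$growth_rates, A, taxa)
  attr(out, "pair_types") <- attr(model, "pair_types")
  attr(out, "planted") <- do.call(rbind, rec)
  out
}

# Deterministic largest-remainder rounding of non-negative quotas to
# integers summing to round(sum(quotas)); ties go to earlier entries.
largest_remainder <- function(quotas) {
  total <- round(sum(quotas))
  base <- floor(quotas)
  rem <- quotas - base
  short <- total - sum(base)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Simulate a gLV community time series
#'
#' Integrates \eqn{dx_i/dt = x_i(b_i + \sum_j a_{ij} x_j)} with an
#' adaptive solver (`deSolve::ode`, lsoda), samples the trajectory at
#' `times`, applies multiplicative log-normal observation noise, clamps
#' abundances at an extinction floor, and (by default) renormalizes each
#' column to relative abundance.
#'
#' @param model a [glv_model].
#' @param x0 strictly positive initial abundances at `times[1]`.
#' @param times strictly increasing sampling times (days).
#' @param noise_sd standard deviation of the log-normal noise on the log
#'   scale; 0 for noise-free output.
#' @param seed optional seed (used only when `noise_sd > 0`).
#' @param extinction_floor abundances below this value are clamped up to
#'   it before renormalization, preventing log-domain failures downstream.
#' @param renormalize if `TRUE`, columns are scaled to sum to 1
#'   (compositional output); if `FALSE` the raw state is returned.
#' @param overflow_guard any state exceeding this aborts with an error
#'   naming the first divergent time.
#' @return A [ts_profile].
#' @export
simulate_glv <- function(model, x0, times, noise_sd = 0, seed = NULL,
                         extinction_floor = 1e-8, renormalize = TRUE,
                         overflow_guard = 1e8) {
  stopifnot(inherits(model, "glv_model"))
  if (length(x0) != length(model$taxa)) {
    stop("`x0` must have one entry per taxon")
  }
  if (any(x0 <= 0)) stop("`x0` must be strictly positive")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  b <- model$growth_rates
  A <- model$interactions
  deriv <- function(t, x, parms) list(x * (b + drop(A %*% x)))
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = deriv,
                      parms = NULL)
  mat <- t(unname(sol[, -1, drop = FALSE]))
  bad <- colSums(!is.finite(mat) | abs(mat) > overflow_guard) > 0
  if (any(bad)) {
    stop("trajectory diverged at time ", times[which(bad)[1]],
         " (state not finite or exceeding overflow guard)")
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mat <- mat * exp(matrix(stats::rnorm(length(mat), 0, noise_sd),
                            nrow(mat), ncol(mat)))
  }
  mat[mat < extinction_floor] <- extinction_floor
  if (renormalize) mat <- sweep(mat, 2, colSums(mat), "/")
  ts_profile(mat, times, taxa = model$taxa, normalized = renormalize)
}

#' Draw sequencing counts from a relative-abundance profile
#'
#' Emulates amplicon sequencing depth: each sample is an independent
#' multinomial draw of size `depth` from that column's proportions.
#'
#' @param profile a normalized [ts_profile] (or any taxa-by-samples
#'   proportion matrix).
#' @param depth reads per sample (>= 1).
#' @param seed optional seed.
#' @return An [abundance_table] of counts with per-sample `time` metadata
#'   when `profile` is a `ts_profile`.
#' @export
counts_from_profile <- function(profile, depth = 5000, seed = NULL) {
  if (depth < 1) stop("`depth` must be >= 1")
  if (inherits(profile, "ts_profile")) {
    prop <- profile$abundances
    meta <- data.frame(sample = paste0("S", seq_along(profile$times)),
                       time = profile$times, stringsAsFactors = FALSE)
    taxa <- profile$taxa
  } else {
    prop <- as.matrix(profile)
    meta <- NULL
    taxa <- rownames(prop)
    if (is.null(taxa)) taxa <- paste0("T", seq_len(nrow(prop)))
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- apply(prop, 2, function(p) {
    stats::rmultinom(1, size = depth, prob = p)[, 1]
  })
  colnames(counts) <- if (is.null(meta)) colnames(prop) else meta$sample
  rownames(counts) <- taxa
  abundance_table(counts, taxonomy = taxa, metadata = meta)
}

#' Describe a probiotic trial design
#'
#' Mirrors the study layout by default: four treatment groups receiving
#' single taxa or a combination, plus a control group receiving nothing.
#'
#' @param administered named list, one element per group, each a character
#'   vector of administered taxon labels (the control group has an empty
#'   vector).
#' @param n_per_group fecal samples (animals) per group (>= 2).
#' @param boost multiplicative elevation applied to each administered
#'   taxon's baseline relative abundance (the study observed ~10-26x
#'   elevations of the administered genus).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(administered, n_per_group = 4, boost = 15) {
  if (is.null(names(administered)) || any(names(administered) == "")) {
    stop("`administered` must be a fully named list (one name per group)")
  }
  if (n_per_group < 2) stop("`n_per_group` must be >= 2")
  if (!any(lengths(administered) == 0)) {
    stop("at least one group must be a control (empty administered list)")
  }
  structure(list(groups = names(administered),
                 administered = administered,
                 n_per_group = as.integer(n_per_group),
                 boost = boost),
            class = "trial_design")
}

#' Generate probiotic-trial abundance tables from a known network
#'
#' For each treatment group, the administered taxa's baseline relative
#' abundances are multiplied by the design's boost, the composition is
#' renormalized, and partner responses are propagated through one
#' discrete gLV step
#' \eqn{x \leftarrow x \exp(\Delta t (b + A x))} under `model`. Daily
#' dosing acts as a press perturbation, so the administered taxa are held
#' at their boosted level through the step rather than relaxing under
#' their own self-limitation. Per-animal variation is multiplicative
#' log-normal. Control groups are drawn from the baseline with per-animal
#' variation only.
#'
#' @param model a [glv_model] (the ground-truth network).
#' @param baseline baseline relative abundances (named by taxa or in model
#'   order); renormalized internally.
#' @param design a [trial_design].
#' @param seed optional seed.
#' @param step_days length of the emulated trial (days) over which the
#'   single propagation step integrates the partner response; defaults to
#'   the two-week trial the generator emulates.
#' @param animal_sd log-normal per-animal variation (log-scale sd).
#' @param depth reads per sample for multinomial count sampling, or `NULL`
#'   to return exact relative abundances.
#' @return Named list, one [abundance_table] per group, each carrying
#'   `group` metadata.
#' @export
generate_trial <- function(model, baseline, design, seed = NULL,
                           step_days = 14, animal_sd = 0.25, depth = 20000) {
  stopifnot(inherits(model, "glv_model"), inherits(design, "trial_design"))
  taxa <- model$taxa
  base <- as.numeric(baseline)
  if (!is.null(names(baseline))) base <- base[match(taxa, names(baseline))]
  if (length(base) != length(taxa) || any(is.na(base)) || any(base < 0)) {
    stop("`baseline` must give a non-negative abundance for every model taxon")
  }
  base <- base / sum(base)
  unknown <- setdiff(unlist(design$administered), taxa)
  if (length(unknown)) {
    stop("unknown administered taxa: ", paste(unknown, collapse = ", "),
         "; valid labels are: ", paste(taxa, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  b <- model$growth_rates
  A <- model$interactions
  out <- lapply(design$groups, function(g) {
    adm <- design$administered[[g]]
    x <- base
    if (length(adm)) {
      held <- match(adm, taxa)
      x[held] <- x[held] * design$boost
      x <- x / sum(x)
      x_b <- x
      x <- x * exp(step_days * (b + drop(A %*% x)))
      x[held] <- x_b[held]  # dosing sustains the administered taxa
      x <- pmax(x, 1e-12)
      x <- x / sum(x)
    }
    cols <- vapply(seq_len(design$n_per_group), function(k) {
      xi <- x * if (animal_sd > 0)
        exp(stats::rnorm(length(x), 0, animal_sd)) else 1
      xi / sum(xi)
    }, numeric(length(x)))
    rownames(cols) <- taxa
    colnames(cols) <- paste0(g, "_a", seq_len(design$n_per_group))
    meta <- data.frame(sample = colnames(cols), group = g,
                       stringsAsFactors = FALSE)
    if (!is.null(depth)) {
      counts <- apply(cols, 2, function(p)
        stats::rmultinom(1, size = depth, prob = p)[, 1])
      rownames(counts) <- taxa
      abundance_table(counts, taxonomy = taxa, metadata = meta)
    } else {
      abundance_table(cols, taxonomy = taxa, metadata = meta,
                      integer_counts = FALSE)
    }
  })
  names(out) <- design$groups
  out
}

#' Export a model's interactions as a ground-truth edge list
#'
#' @param model a [glv_model].
#' @param path output TSV path (columns source, target, coefficient; the
#'   edge source -> target carries coefficient `interactions[target,
#'   source]`, i.e. the effect of source on target).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(model, path) {
  A <- model$interactions
  idx <- which(row(A) != col(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(source = model$taxa[idx[, "col"]],
                   target = model$taxa[idx[, "row"]],
                   coefficient = A[idx])
  writeLines("# ground-truth gLV edges: source affects target", path)
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}
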