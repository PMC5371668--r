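#' Alpha diversity of one composition
#'
#' Computes richness (taxa with non-zero abundance), Shannon entropy in
#' nats (\eqn{H = -\sum p \ln p}, with \eqn{0 \ln 0 = 0}), the
#' Gini-Simpson index (\eqn{1 - \sum p^2}) and the inverse Simpson index
#' (\eqn{1/\sum p^2}). The two Simpson forms share \eqn{\sum p^2}, so
#' `inverse_simpson * (1 - simpson) = 1` always, and the Hill-number
#' ordering \eqn{e^H \ge 1/\sum p^2} holds for every composition.
#'
#' @param proportions non-negative vector summing to 1 (within 1e-6).
#' @return A one-row data.frame with columns `richness`, `shannon`,
#'   `simpson`, `inverse_simpson`.
#' @examples
#' alpha_diversity(rep(0.25, 4))  # shannon = log(4), simpson = 0.75
#' @export
alpha_diversity <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) {
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  }
  data.frame(
    richness = sum(p > 0),
    shannon = unname(vegan::diversity(p, index = "shannon")),
    simpson = unname(vegan::diversity(p, index = "simpson")),
    inverse_simpson = unname(vegan::diversity(p, index = "invsimpson"))
  )
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{BC = 1 - 2\sum_i \min(a_i, b_i) / (\sum a + \sum b)}; symmetric,
#' in \eqn{[0, 1]}, 0 for identical samples, 1 for disjoint supports.
#'
#' @param sample_a,sample_b non-negative abundance vectors over the same
#'   taxon set.
#' @return Scalar dissimilarity.
#' @export
bray_curtis <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) != length(b)) stop("samples must share one taxon set")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  if (sum(a) == 0 && sum(b) == 0) {
    stop("Bray-Curtis is undefined for two all-zero samples")
  }
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Two-sample comparison between time points
#'
#' Two-sided two-sample t-test; pooled-variance Student's test by default,
#' Welch selectable. When both groups have zero variance the test is
#' degenerate: equal means give `t = 0, p = 1`, different means
#' `t = +/-Inf, p = 0` (documented convention).
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @return List with `t` and `p`.
#' @export
compare_timepoints <- function(values_a, values_b,
                               test = c("student", "welch")) {
  test <- match.arg(test)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = (test == "student"))
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Monte-Carlo rarefaction curve for one sample
#'
#' Subsamples reads without replacement at each requested depth and
#' averages the number of observed taxa over `reps` draws.
#'
#' @param counts integer counts for one sample.
#' @param depths subsampling depths, each <= `sum(counts)`.
#' @param reps Monte-Carlo repetitions per depth.
#' @param seed optional seed.
#' @return data.frame with columns `depth` and `mean_taxa`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 100, seed = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be non-negative integers")
  }
  total <- sum(counts)
  if (any(depths > total)) {
    stop("depth(s) exceed the sample total of ", total)
  }
  if (!is.null(seed)) set.seed(seed)
  reads <- rep.int(seq_along(counts), counts)
  mean_taxa <- vapply(depths, function(d) {
    mean(vapply(seq_len(reps), function(r) {
      length(unique(sample(reads, d))) }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_taxa = mean_taxa)
}

#' Per-time-point diversity summary table
#'
#' Computes alpha diversity per sample and summarizes mean and standard
#' error per time point, in the shape of a time-by-index diversity table.
#'
#' @param table an [abundance_table] with `time` metadata.
#' @return data.frame with per-time mean and se of richness, Shannon,
#'   Simpson, and inverse Simpson.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$metadata) || !"time" %in% names(table$metadata)) {
    stop("`table` must carry `time` metadata")
  }
  rel <- to_relative(table)
  per_sample <- do.call(rbind, lapply(seq_len(ncol(rel$counts)),
    function(j) alpha_diversity(rel$counts[, j])))
  per_sample$time <- as.numeric(table$metadata$time)
  times <- sort(unique(per_sample$time))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  do.call(rbind, lapply(times, function(tt) {
    sub <- per_sample[per_sample$time == tt, ]
    data.frame(
      time = tt, n = nrow(sub),
      richness = mean(sub$richness), richness_se = se(sub$richness),
      shannon = mean(sub$shannon), shannon_se = se(sub$shannon),
      simpson = mean(sub$simpson), simpson_se = se(sub$simpson),
      inverse_simpson = mean(sub$inverse_simpson),
      inverse_simpson_se = se(sub$inverse_simpson))
  }))
}
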