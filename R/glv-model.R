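#' Construct a generalized Lotka-Volterra community model
#'
#' A gLV model consists of per-taxon intrinsic growth rates \eqn{b_i}
#' (1/day) and a dense interaction matrix \eqn{A = (a_{ij})}, where
#' \eqn{a_{ij}} is the per-unit-abundance effect of taxon \eqn{j} on taxon
#' \eqn{i} (1/day per relative-abundance unit). The community dynamics are
#' \deqn{dx_i/dt = x_i (b_i + \sum_j a_{ij} x_j).}
#' Diagonal entries must be strictly negative (self-limitation), which
#' keeps trajectories bounded for realistic parameterizations.
#'
#' @param growth_rates numeric vector of intrinsic growth rates, one per
#'   taxon (1/day).
#' @param interactions square numeric matrix; entry `[i, j]` is the effect
#'   of taxon `j` on taxon `i`.
#' @param taxa character vector of taxon labels; defaults to names of
#'   `growth_rates` or `T1..Tn`.
#' @param self_limiting require strictly negative diagonal entries
#'   (`TRUE` for ground-truth and simulation models). Fitted models may
#'   carry non-negative diagonals (e.g. a fit to equilibrium data is all
#'   zeros) and are built with `FALSE`.
#' @return An object of class `glv_model` with elements `taxa`,
#'   `growth_rates` (named) and `interactions` (dimnamed matrix).
#' @examples
#' m <- glv_model(c(A = 0.5), matrix(-0.5, dimnames = list("A", "A")))
#' glv_equilibrium(m)  # x* = -b/a = 1
#' @export
glv_model <- function(growth_rates, interactions, taxa = NULL,
                      self_limiting = TRUE) {
  growth_rates <- as.numeric(growth_rates)
  interactions <- as.matrix(interactions)
  n <- length(growth_rates)
  if (is.null(taxa)) {
    taxa <- names(growth_rates)
    if (is.null(taxa)) taxa <- rownames(interactions)
    if (is.null(taxa)) taxa <- paste0("T", seq_len(n))
  }
  if (nrow(interactions) != n || ncol(interactions) != n) {
    stop("`interactions` must be a ", n, " x ", n,
         " matrix (one row/column per taxon)")
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  if (!all(is.finite(growth_rates)) || !all(is.finite(interactions))) {
    stop("growth rates and interaction coefficients must be finite")
  }
  if (self_limiting && any(diag(interactions) >= 0)) {
    stop("diagonal interaction entries must be strictly negative ",
         "(self-limitation)")
  }
  names(growth_rates) <- taxa
  dimnames(interactions) <- list(taxa, taxa)
  structure(
    list(taxa = taxa, growth_rates = growth_rates,
         interactions = interactions),
    class = "glv_model"
  )
}

#' @export
print.glv_model <- function(x, ...) {
  cat("gLV model:", length(x$taxa), "taxa\n")
  cat("  growth rates in [", round(min(x$growth_rates), 3), ",",
      round(max(x$growth_rates), 3), "]\n")
  off <- x$interactions[row(x$interactions) != col(x$interactions)]
  cat("  off-diagonal interactions:", sum(off != 0), "non-zero of",
      length(off), "\n")
  invisible(x)
}

#' Interior equilibrium of a gLV model
#'
#' Solves \eqn{A x^* = -b}. The fixed point is only ecologically feasible
#' when all components are positive.
#'
#' @param model a [glv_model].
#' @return Named numeric vector \eqn{x^*}.
#' @export
glv_equilibrium <- function(model) {
  x <- solve(model$interactions, -model$growth_rates)
  names(x) <- model$taxa
  x
}

#' Construct a time-series abundance profile
#'
#' A profile holds a taxa-by-times matrix of abundances sampled at
#' strictly increasing times (days). Relative-abundance profiles
#' (`normalized = TRUE`, the usual case for compositional sequencing data)
#' must have columns summing to 1; raw gLV state trajectories can be kept
#' unnormalized, which matters for parameter-recovery work because
#' renormalization confounds the interaction coefficients with the
#' community total (see the package vignette).
#'
#' @param abundances numeric matrix, taxa x times, non-negative.
#' @param times numeric vector of sampling times (days), strictly
#'   increasing.
#' @param taxa taxon labels; defaults to rownames.
#' @param normalized logical; if `TRUE` columns must sum to 1 (within
#'   1e-9).
#' @return An object of class `ts_profile`.
#' @export
ts_profile <- function(abundances, times, taxa = rownames(abundances),
                       normalized = TRUE) {
  abundances <- as.matrix(abundances)
  if (is.null(taxa)) taxa <- paste0("T", seq_len(nrow(abundances)))
  times <- as.numeric(times)
  if (ncol(abundances) != length(times)) {
    stop("number of columns must equal number of sampling times")
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (normalized) {
    cs <- colSums(abundances)
    if (any(abs(cs - 1) > 1e-9)) {
      stop("relative-abundance columns must sum to 1 (worst deviation ",
           format(max(abs(cs - 1))), "); use normalized = FALSE for raw ",
           "trajectories")
    }
  }
  dimnames(abundances) <- list(taxa, paste0("t", times))
  structure(
    list(taxa = taxa, times = times, abundances = abundances,
         normalized = normalized),
    class = "ts_profile"
  )
}

#' @export
print.ts_profile <- function(x, ...) {
  cat("Time-series profile:", length(x$taxa), "taxa x",
      length(x$times), "time points (days ", min(x$times), "-",
      max(x$times), "), ",
      if (x$normalized) "relative" else "raw", " abundances\n", sep = "")
  invisible(x)
}

#' The study-style 12-point sampling schedule
#'
#' Twelve sampling times over 15 days with a long initial fast, a dense
#' 6-hourly phase immediately after the perturbation, and 12-hourly
#' sampling thereafter.
#'
#' @return Numeric vector of days.
#' @export
default_schedule <- function() {
  c(1, 11, 11.25, 11.5, 11.75, 12, 12.5, 13, 13.5, 14, 14.5, 15)
}
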