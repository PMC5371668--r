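#' Build the gradient-matching regression system from a profile
#'
#' Discretizing \eqn{d \ln x_i/dt = b_i + \sum_j a_{ij} x_j} between
#' consecutive samples gives, for each taxon \eqn{i} and interval
#' \eqn{[t_k, t_{k+1}]}, the response
#' \eqn{y_i(t_k) = (\ln x_i(t_{k+1}) - \ln x_i(t_k)) / (t_{k+1} - t_k)}
#' with predictor row \eqn{[1, x_1(t_k), \ldots, x_n(t_k)]} (abundances
#' taken at interval start — the explicit Euler convention; a midpoint
#' convention averaging the two interval endpoints is selectable and has
#' second- rather than first-order discretization bias, which matters for
#' parameter recovery from densely sampled noise-free data). Uneven
#' sampling is handled by dividing each response by its own
#' \eqn{\Delta t}; intervals longer than `max_gap` days (e.g. the long
#' pre-perturbation fast in the motivating design) are excluded because a
#' single long interval would otherwise dominate the fit.
#'
#' @param profile a [ts_profile] with at least 3 time points, or a list
#'   of profiles over the same taxa (e.g. replicate subjects or repeated
#'   perturbation episodes), whose intervals are pooled into one system —
#'   pooling independent trajectories is what makes the regression well
#'   conditioned, since a single trajectory relaxing to equilibrium
#'   explores only a thin slice of state space.
#' @param pseudo zero-replacement value applied before taking logs;
#'   default half the smallest non-zero abundance in the profile.
#' @param max_gap maximum interval length (days) retained; `Inf` keeps
#'   every interval.
#' @param zero_handling `"pseudo"` substitutes `pseudo` for zeros;
#'   `"drop"` instead drops (taxon, interval) rows with a zero endpoint,
#'   and taxa left with fewer than 2 usable intervals are flagged
#'   un-inferable and excluded with a warning.
#' @param predictor `"start"` (explicit Euler, default) uses abundances
#'   at interval start; `"midpoint"` uses the endpoint average.
#' @return An object of class `glv_regression` with elements `X`
#'   (intervals x (1 + n) design), `Y` (intervals x n responses),
#'   `usable` (logical mask, intervals x n), `weights` (per-interval
#'   regression weights proportional to \eqn{\Delta t^2}, the
#'   inverse-variance weighting when observation noise on log abundances
#'   is homoscedastic), `taxa`, `dt`, `times`.
#' @export
build_regression_system <- function(profile, pseudo = NULL, max_gap = 5,
                                    zero_handling = c("pseudo", "drop"),
                                    predictor = c("start", "midpoint")) {
  zero_handling <- match.arg(zero_handling)
  predictor <- match.arg(predictor)
  if (is.list(profile) && !inherits(profile, "ts_profile")) {
    systems <- lapply(profile, build_regression_system, pseudo = pseudo,
                      max_gap = max_gap, zero_handling = zero_handling,
                      predictor = predictor)
    taxa <- systems[[1]]$taxa
    if (!all(vapply(systems, function(s) identical(s$taxa, taxa),
                    logical(1)))) {
      stop("all profiles must share one taxon set (same order)")
    }
    pooled <- structure(list(
      X = do.call(rbind, lapply(systems, `[[`, "X")),
      Y = do.call(rbind, lapply(systems, `[[`, "Y")),
      usable = do.call(rbind, lapply(systems, `[[`, "usable")),
      weights = do.call(c, lapply(systems, `[[`, "weights")),
      taxa = taxa,
      dt = do.call(c, lapply(systems, `[[`, "dt")),
      times = NA_real_,
      pseudo = systems[[1]]$pseudo), class = "glv_regression")
    return(pooled)
  }
  stopifnot(inherits(profile, "ts_profile"))
  if (length(profile$times) < 3) {
    stop("at least 3 time points are required for inference")
  }
  ab <- profile$abundances
  if (is.null(pseudo)) {
    nz <- ab[ab > 0]
    if (!length(nz)) stop("profile contains no non-zero abundances")
    pseudo <- min(nz) / 2
  }
  dt_all <- diff(profile$times)
  keep <- which(dt_all <= max_gap)
  if (length(keep) < 2) {
    stop("fewer than 2 usable intervals after the max_gap filter")
  }
  dt <- dt_all[keep]
  n <- nrow(ab)
  ab_sub <- ab
  ab_sub[ab_sub == 0] <- pseudo
  heads <- keep
  tails <- keep + 1
  la <- log(ab_sub)
  Y <- t((la[, tails, drop = FALSE] - la[, heads, drop = FALSE]) /
           rep(dt, each = n))
  pred <- if (predictor == "start") ab_sub[, heads, drop = FALSE] else
    (ab_sub[, heads, drop = FALSE] + ab_sub[, tails, drop = FALSE]) / 2
  X <- cbind(1, t(pred))
  colnames(X) <- c("(intercept)", profile$taxa)
  colnames(Y) <- profile$taxa
  usable <- matrix(TRUE, length(keep), n, dimnames = list(NULL, profile$taxa))
  if (zero_handling == "drop") {
    zero_end <- t(ab[, heads, drop = FALSE] == 0 |
                    ab[, tails, drop = FALSE] == 0)
    usable <- !zero_end
    few <- colSums(usable) < 2
    if (any(few)) {
      warning("taxa un-inferable (< 2 usable intervals), excluded: ",
              paste(profile$taxa[few], collapse = ", "))
      usable[, few] <- FALSE
    }
  }
  structure(list(X = X, Y = Y, usable = usable,
                 weights = dt^2 / mean(dt^2), taxa = profile$taxa,
                 dt = dt, times = profile$times[c(keep, length(profile$times))],
                 pseudo = pseudo),
            class = "glv_regression")
}

# Weighted ridge solve for one taxon: intercept unpenalized.
ridge_solve <- function(X, y, lambda, w = NULL) {
  p <- ncol(X)
  if (!is.null(w)) {
    sw <- sqrt(w)
    X <- X * sw
    y <- y * sw
  }
  D <- diag(c(0, rep(1, p - 1)))
  M <- crossprod(X) + lambda * D
  beta <- tryCatch(solve(M, crossprod(X, y)),
                   error = function(e) {
                     stop("singular regression system at lambda = ", lambda,
                          "; use lambda > 0", call. = FALSE)
                   })
  drop(beta)
}

# Leave-one-interval-out CV error for one taxon over a lambda grid.
ridge_cv <- function(X, y, grid, w = NULL) {
  n <- nrow(X)
  err <- vapply(grid, function(l) {
    se <- vapply(seq_len(n), function(k) {
      beta <- tryCatch(
        ridge_solve(X[-k, , drop = FALSE], y[-k], l, w[-k]),
        error = function(e) NULL)
      if (is.null(beta)) return(NA_real_)
      (y[k] - sum(X[k, ] * beta))^2
    }, numeric(1))
    mean(se)
  }, numeric(1))
  grid[which.min(err)]
}

#' Fit a gLV model by ridge-regularized gradient matching
#'
#' Solves, independently per taxon, the penalized least-squares problem
#' \eqn{\min_\beta \|y - X\beta\|^2 + \lambda \|\beta_{-1}\|^2} where the
#' intercept (growth rate \eqn{b_i}) is unpenalized. With `lambda = NULL`
#' the penalty is chosen per taxon by leave-one-interval-out
#' cross-validation over a log-spaced grid.
#'
#' @param system a `glv_regression` from [build_regression_system()].
#' @param lambda ridge penalty (>= 0), or `NULL` for per-taxon CV.
#' @param lambda_grid grid searched when `lambda` is `NULL`.
#' @return A [glv_model]; taxa excluded from the system get zero rows and
#'   a weakly negative diagonal placeholder. The chosen penalties are in
#'   `attr(, "lambda")`.
#' @export
fit_glv <- function(system, lambda = NULL,
                    lambda_grid = 10^seq(-8, 1, length.out = 10)) {
  stopifnot(inherits(system, "glv_regression"))
  if (!is.null(lambda) && lambda < 0) stop("`lambda` must be >= 0")
  n <- length(system$taxa)
  B <- matrix(0, n, n + 1)
  lambdas <- numeric(n)
  for (i in seq_len(n)) {
    rows <- system$usable[, i]
    if (!any(rows)) next
    X <- system$X[rows, , drop = FALSE]
    y <- system$Y[rows, i]
    w <- system$weights[rows]
    li <- if (is.null(lambda)) ridge_cv(X, y, lambda_grid, w) else lambda
    lambdas[i] <- li
    B[i, ] <- ridge_solve(X, y, li, w)
  }
  b <- B[, 1]
  A <- B[, -1, drop = FALSE]
  model <- glv_model(b, A, system$taxa, self_limiting = FALSE)
  attr(model, "lambda") <- stats::setNames(lambdas, system$taxa)
  model
}

#' Forward-simulate a fitted model for diagnostics
#'
#' Noise-free deterministic integration of a fitted [glv_model] at the
#' requested times (thin wrapper over [simulate_glv()]).
#'
#' @param model a [glv_model].
#' @param x0 initial abundances.
#' @param times sampling times.
#' @param renormalize return relative abundances (default) or raw state.
#' @return A [ts_profile].
#' @export
predict_trajectory <- function(model, x0, times, renormalize = TRUE) {
  simulate_glv(model, x0, times, noise_sd = 0, renormalize = renormalize)
}

#' Export a fitted model as edge-list and growth-rate tables
#'
#' @param model a [glv_model].
#' @param edges_path TSV path for the interaction edge list (source,
#'   target, coefficient; source affects target).
#' @param growth_path optional TSV path for per-taxon growth rates.
#' @return `edges_path`, invisibly.
#' @export
write_model <- function(model, edges_path, growth_path = NULL) {
  write_ground_truth(model, edges_path)
  if (!is.null(growth_path)) {
    utils::write.table(
      data.frame(taxon = model$taxa, growth_rate = model$growth_rates),
      growth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edges_path)
}
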