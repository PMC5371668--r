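#' Replicate the gLV inference and tally edge support
#'
#' Runs the gradient-matching fit `R` times. Each replicate resamples the
#' regression intervals with replacement (bootstrap; optional), fits the
#' model, ranks all off-diagonal coefficients by absolute magnitude, and
#' retains only the strongest `top_fraction` of the n(n-1) possible
#' directed relationships. The tally records, per ordered pair, how many
#' replicates retained it and with which sign.
#'
#' @param profile a [ts_profile].
#' @param R number of replicates (>= 1).
#' @param top_fraction fraction of directed relationships kept per
#'   replicate (0 < f <= 1); 0.25 keeps the top quarter by |a_ij|.
#' @param seed optional seed.
#' @param lambda ridge penalty used in each replicate fit.
#' @param lambda_jitter relative jitter applied to `lambda` per replicate
#'   (e.g. 0.25 draws lambda uniformly within +/-25%); 0 disables.
#' @param bootstrap resample intervals with replacement; `FALSE` refits
#'   the full system every time (only useful with `lambda_jitter > 0` or
#'   for the degenerate R = 1 case).
#' @param ... passed to [build_regression_system()].
#' @return An object of class `edge_tally`: matrices `retained`, `pos`,
#'   `neg`, `coef_sum` (n x n, ordered-pair entry `[i, j]` is the edge
#'   j -> i, "j affects i"), plus `R`, `taxa`, `top_fraction`.
#' @export
replicate_inference <- function(profile, R = 100, top_fraction = 0.25,
                                seed = NULL, lambda = 0.01,
                                lambda_jitter = 0, bootstrap = TRUE, ...) {
  if (R < 1) stop("`R` must be >= 1")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must be in (0, 1]")
  }
  system <- build_regression_system(profile, ...)
  n <- length(system$taxa)
  n_int <- nrow(system$X)
  if (!is.null(seed)) set.seed(seed)
  off <- row(diag(n)) != col(diag(n))
  k_keep <- ceiling(top_fraction * sum(off))
  retained <- pos <- neg <- coef_sum <- matrix(
    0, n, n, dimnames = list(system$taxa, system$taxa))
  for (r in seq_len(R)) {
    rows <- if (bootstrap) sample.int(n_int, n_int, replace = TRUE)
            else seq_len(n_int)
    if (bootstrap && length(unique(rows)) == 1) {
      warning("degenerate bootstrap replicate: all resampled intervals ",
              "identical")
    }
    sub <- system
    sub$X <- system$X[rows, , drop = FALSE]
    sub$Y <- system$Y[rows, , drop = FALSE]
    sub$usable <- system$usable[rows, , drop = FALSE]
    sub$weights <- system$weights[rows]
    li <- lambda
    if (lambda_jitter > 0) {
      li <- lambda * stats::runif(1, 1 - lambda_jitter, 1 + lambda_jitter)
    }
    fit <- fit_glv(sub, lambda = li)
    A <- fit$interactions
    vals <- abs(A[off])
    ord <- order(vals, decreasing = TRUE)
    sel <- logical(length(vals))
    sel[ord[seq_len(k_keep)]] <- TRUE
    keep <- matrix(FALSE, n, n)
    keep[off] <- sel
    retained <- retained + keep
    pos <- pos + (keep & A > 0)
    neg <- neg + (keep & A < 0)
    coef_sum <- coef_sum + ifelse(keep, A, 0)
  }
  structure(list(retained = retained, pos = pos, neg = neg,
                 coef_sum = coef_sum, R = R, taxa = system$taxa,
                 top_fraction = top_fraction),
            class = "edge_tally")
}

#' Build the consensus network from replicate tallies
#'
#' A directed edge j -> i is retained when it survived the per-replicate
#' top-magnitude filter in at least `cutoff * R` replicates (inclusive:
#' support 50/100 passes at cutoff 0.5). Its sign is the majority sign
#' among the retaining replicates; exact sign ties are dropped with a
#' message, since an edge without a stable sign is not ecologically
#' interpretable. The mean coefficient is averaged over retaining
#' replicates.
#'
#' @param tallies an `edge_tally` from [replicate_inference()].
#' @param cutoff support threshold in (0, 1].
#' @return An object of class `consensus_network`: data.frame `edges`
#'   (source, target, sign, support, mean_coeff; source affects target),
#'   plus `taxa` and `R`.
#' @export
build_consensus <- function(tallies, cutoff = 0.5) {
  stopifnot(inherits(tallies, "edge_tally"))
  if (cutoff <= 0 || cutoff > 1) stop("`cutoff` must be in (0, 1]")
  n <- length(tallies$taxa)
  support <- tallies$retained / tallies$R
  idx <- which(support >= cutoff & row(support) != col(support),
               arr.ind = TRUE)
  edges <- data.frame(source = character(0), target = character(0),
                      sign = integer(0), support = numeric(0),
                      mean_coeff = numeric(0), stringsAsFactors = FALSE)
  if (nrow(idx)) {
    p <- tallies$pos[idx]; q <- tallies$neg[idx]
    tie <- p == q
    if (any(tie)) {
      message(sum(tie), " edge(s) dropped for an exact sign tie across ",
              "replicates")
    }
    idx <- idx[!tie, , drop = FALSE]
    p <- p[!tie]; q <- q[!tie]
    edges <- data.frame(
      # entry [i, j] is the effect of j on i: source = column taxon
      source = tallies$taxa[idx[, "col"]],
      target = tallies$taxa[idx[, "row"]],
      sign = ifelse(p > q, 1L, -1L),
      support = support[idx],
      mean_coeff = tallies$coef_sum[idx] / tallies$retained[idx],
      stringsAsFactors = FALSE)
    edges <- edges[order(-edges$support, edges$source, edges$target), ]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, taxa = tallies$taxa, R = tallies$R,
                 cutoff = cutoff),
            class = "consensus_network")
}

#' Assemble a consensus network directly from an edge data.frame
#'
#' Convenience constructor for fixture networks and for re-loading
#' exported edge lists.
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (+1/-1), and optionally `support` and `mean_coeff`.
#' @param taxa taxon universe; defaults to the labels present in `edges`.
#' @param R nominal replicate count.
#' @return A `consensus_network`.
#' @export
consensus_network <- function(edges, taxa = NULL, R = 1) {
  edges <- as.data.frame(edges)
  needed <- c("source", "target", "sign")
  if (!all(needed %in% names(edges))) {
    stop("`edges` needs columns: ", paste(needed, collapse = ", "))
  }
  if (!"support" %in% names(edges)) edges$support <- 1
  if (!"mean_coeff" %in% names(edges)) edges$mean_coeff <- edges$sign
  if (!all(edges$sign %in% c(-1L, 1L))) stop("`sign` entries must be +1/-1")
  if (anyDuplicated(edges[c("source", "target")])) {
    stop("at most one retained edge per ordered pair")
  }
  if (is.null(taxa)) taxa <- sort(unique(c(edges$source, edges$target)))
  structure(list(edges = edges, taxa = taxa, R = R, cutoff = NA_real_),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("Consensus network:", length(x$taxa), "taxa,", nrow(x$edges),
      "retained directed edges (R =", x$R, ")\n")
  invisible(x)
}

#' Classify unordered taxon pairs into interaction types
#'
#' Each unordered pair with at least one retained directed edge is
#' classified from the two directed-edge statuses: (+,+) mutual;
#' (-,-) competitive; (+, absent) commensal; (-, absent) amensal;
#' (+,-) exploitative. Exploitative pairs are reported as a fifth class,
#' kept outside the classical four-type tally.
#'
#' @param network a `consensus_network`.
#' @return data.frame of inferred interaction pairs (IIPs): `taxon_a`,
#'   `taxon_b` (a < b), `type`, directed signs `sign_ab` (a -> b) /
#'   `sign_ba` (0 = absent) and the corresponding supports.
#' @export
classify_pairs <- function(network) {
  stopifnot(inherits(network, "consensus_network"))
  e <- network$edges
  if (!nrow(e)) {
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      type = character(0), sign_ab = integer(0),
                      sign_ba = integer(0), support_ab = numeric(0),
                      support_ba = numeric(0), stringsAsFactors = FALSE))
  }
  a <- pmin(e$source, e$target)
  b <- pmax(e$source, e$target)
  key <- paste(a, b, sep = "\r")
  out <- lapply(split(seq_len(nrow(e)), key), function(rows) {
    ta <- min(e$source[rows[1]], e$target[rows[1]])
    tb <- max(e$source[rows[1]], e$target[rows[1]])
    sign_ab <- 0L; sign_ba <- 0L; sup_ab <- 0; sup_ba <- 0
    for (r in rows) {
      if (e$source[r] == ta) { sign_ab <- e$sign[r]; sup_ab <- e$support[r] }
      else                   { sign_ba <- e$sign[r]; sup_ba <- e$support[r] }
    }
    type <- pair_type(sign_ab, sign_ba)
    data.frame(taxon_a = ta, taxon_b = tb, type = type,
               sign_ab = sign_ab, sign_ba = sign_ba,
               support_ab = sup_ab, support_ba = sup_ba,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

pair_type <- function(s_ab, s_ba) {
  if (s_ab > 0 && s_ba > 0) return("mutual")
  if (s_ab < 0 && s_ba < 0) return("competitive")
  if (s_ab * s_ba < 0) return("exploitative")
  if (s_ab > 0 || s_ba > 0) return("commensal")
  if (s_ab < 0 || s_ba < 0) return("amensal")
  stop("pair with no retained edge")
}

#' Partner subnetwork of focal taxa
#'
#' Extracts every IIP touching any focal taxon and tabulates the
#' per-focal breakdown by interaction type.
#'
#' @param pairs IIP data.frame from [classify_pairs()].
#' @param focal character vector of focal taxa.
#' @param taxa optional taxon universe; a focal taxon must appear either
#'   here or in `pairs` (a known taxon with no edges yields an empty
#'   subset, an unknown label is an error).
#' @return List with `pairs` (the induced IIP subset) and `breakdown`
#'   (data.frame: focal, type, n).
#' @export
partner_subnetwork <- function(pairs, focal, taxa = NULL) {
  all_taxa <- unique(c(pairs$taxon_a, pairs$taxon_b, taxa))
  unknown <- setdiff(focal, all_taxa)
  if (length(unknown)) {
    stop("focal taxa not present in the network: ",
         paste(unknown, collapse = ", "))
  }
  hit <- pairs$taxon_a %in% focal | pairs$taxon_b %in% focal
  sub <- pairs[hit, , drop = FALSE]
  types <- c("commensal", "mutual", "amensal", "competitive",
             "exploitative")
  breakdown <- do.call(rbind, lapply(focal, function(f) {
    fs <- sub[sub$taxon_a == f | sub$taxon_b == f, , drop = FALSE]
    data.frame(focal = f, type = types,
               n = vapply(types, function(tt) sum(fs$type == tt),
                          numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(breakdown) <- NULL
  list(pairs = sub, breakdown = breakdown)
}

#' Export a consensus network
#'
#' Writes a TSV edge list (source, target, sign, support, mean_coeff;
#' the stored edge source -> target means "source affects target") and
#' optionally a GraphML file for network viewers.
#'
#' @param network a `consensus_network`.
#' @param path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml_path = NULL) {
  stopifnot(inherits(network, "consensus_network"))
  writeLines("# consensus gLV network: edge source -> target means 'source affects target'",
             path)
  suppressWarnings(utils::write.table(
    network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = TRUE,
      vertices = data.frame(name = network$taxa))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
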