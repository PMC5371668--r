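#' Classify a fold change by the relevance thresholds
#'
#' Strict inequalities: `increase` iff FC > 2, `decrease` iff FC < 0.5,
#' otherwise `no-difference` (a fold change of exactly 2 or exactly 0.5
#' is not relevant).
#'
#' @param fc positive fold change(s).
#' @return Character vector of classes.
#' @export
classify_fold_change <- function(fc) {
  ifelse(fc > 2, "increase", ifelse(fc < 0.5, "decrease", "no-difference"))
}

#' Fold changes of treatment vs control relative abundances
#'
#' Per taxon: ratio of the treatment group's mean relative abundance to
#' the control group's. Taxa with zero abundance across all samples of
#' either group are excluded (and listed in the `excluded` attribute),
#' mirroring the practice of dropping pairs with no abundance data. A
#' two-sided Wilcoxon rank-sum test (exact for small groups, mid-ranks
#' under ties) across the per-sample relative abundances is attached.
#'
#' @param treatment,control [abundance_table]s (>= 2 samples each).
#' @param taxa optional subset of taxa to evaluate (e.g. the partners of
#'   an administered genus); default all shared taxa.
#' @return data.frame with columns `taxon`, `fc`, `treatment_mean`,
#'   `control_mean`, `sd` (of per-sample treatment/control-mean ratios),
#'   `class`, `wilcoxon_p`; excluded taxa in `attr(, "excluded")`.
#' @export
fold_changes <- function(treatment, control, taxa = NULL) {
  stopifnot(inherits(treatment, "abundance_table"),
            inherits(control, "abundance_table"))
  if (ncol(treatment$counts) < 2 || ncol(control$counts) < 2) {
    stop("each group needs >= 2 samples")
  }
  tr <- to_relative(treatment)$counts
  ct <- to_relative(control)$counts
  shared <- intersect(rownames(tr), rownames(ct))
  if (is.null(taxa)) taxa <- shared
  missing <- setdiff(taxa, shared)
  if (length(missing)) {
    stop("taxa absent from the tables: ", paste(missing, collapse = ", "))
  }
  tm <- rowMeans(tr[taxa, , drop = FALSE])
  cm <- rowMeans(ct[taxa, , drop = FALSE])
  excluded <- taxa[tm == 0 | cm == 0]
  keep <- setdiff(taxa, excluded)
  if (!length(keep)) {
    stop("no evaluable taxa left after zero-abundance exclusions (",
         length(excluded), " excluded)")
  }
  res <- do.call(rbind, lapply(keep, function(tx) {
    a <- tr[tx, ]; b <- ct[tx, ]
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    fc <- tm[tx] / cm[tx]
    data.frame(taxon = tx, fc = fc,
               treatment_mean = tm[tx], control_mean = cm[tx],
               sd = stats::sd(a / cm[tx]),
               class = classify_fold_change(fc),
               wilcoxon_p = p, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Score trial outcomes for consistency with the inferred network
#'
#' For each administered taxon P and each network partner Q, the inferred
#' direct effect of P on Q (the sign of the retained directed edge
#' P -> Q) sets an expectation: a positive effect (mutual, or commensal
#' with Q the beneficiary) predicts an increase of Q under treatment, a
#' negative effect (competitive, or amensal with Q the harmed party)
#' predicts a decrease. The observed relevance class of Q's fold change
#' then yields: `consistent` if it matches the expectation, `conflict`
#' if it is the opposite relevant class, `no-difference` otherwise.
#' Partners with no retained edge directed at them from P (P is only a
#' receiver) carry no expectation and are skipped, as are partners
#' excluded from the fold-change table. With several administered taxa
#' (combination groups) each partner is evaluated once per focal taxon.
#'
#' @param pairs IIP data.frame from [classify_pairs()] (needs the
#'   directional `sign_ab`/`sign_ba` columns).
#' @param fold_changes data.frame from [fold_changes()] for the treatment
#'   group under evaluation.
#' @param administered character vector of administered (focal) taxa.
#' @param group optional group label copied into the output.
#' @return data.frame: `focal`, `partner`, `group`, `expected`
#'   ("increase"/"decrease"), `observed`, `class`. Skipped partners are
#'   listed in `attr(, "skipped")`.
#' @export
score_consistency <- function(pairs, fold_changes, administered,
                              group = NA_character_) {
  present <- unique(c(pairs$taxon_a, pairs$taxon_b))
  unknown <- setdiff(administered, present)
  if (length(unknown)) {
    stop("administered taxa absent from the IIP set: ",
         paste(unknown, collapse = ", "))
  }
  skipped <- character(0)
  rows <- list()
  for (p_taxon in administered) {
    sub <- pairs[pairs$taxon_a == p_taxon | pairs$taxon_b == p_taxon, ,
                 drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      partner <- if (sub$taxon_a[r] == p_taxon) sub$taxon_b[r]
                 else sub$taxon_a[r]
      if (partner %in% administered) next
      effect <- if (sub$taxon_a[r] == p_taxon) sub$sign_ab[r]
                else sub$sign_ba[r]
      if (effect == 0) {
        skipped <- c(skipped, partner)
        next
      }
      fcrow <- fold_changes[fold_changes$taxon == partner, , drop = FALSE]
      if (!nrow(fcrow)) {
        skipped <- c(skipped, partner)
        next
      }
      expected <- if (effect > 0) "increase" else "decrease"
      observed <- fcrow$class[1]
      cls <- if (observed == "no-difference") "no-difference"
             else if (observed == expected) "consistent"
             else "conflict"
      rows[[length(rows) + 1]] <- data.frame(
        focal = p_taxon, partner = partner, group = group,
        expected = expected, observed = observed, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(focal = character(0), partner = character(0),
               group = character(0), expected = character(0),
               observed = character(0), class = character(0),
               stringsAsFactors = FALSE)
  attr(res, "skipped") <- unique(skipped)
  res
}

#' Summarize consistency scores into a validation table
#'
#' Tallies consistent / conflict / no-difference counts per focal taxon
#' and group with one-decimal percentages, plus pooled ratios across
#' focal taxa per group.
#'
#' @param scores data.frame from [score_consistency()] (rows from several
#'   groups/focals can be concatenated).
#' @return List with `by_focal` (focal, group, n, counts and
#'   percentages) and `pooled` (per group, counts and percentages across
#'   all focal taxa).
#' @export
summarize_validation <- function(scores) {
  classes <- c("consistent", "conflict", "no-difference")
  empty <- data.frame(n = 0, consistent = 0, conflict = 0,
                      no_difference = 0, consistent_pct = 0,
                      conflict_pct = 0, no_difference_pct = 0)
  if (!nrow(scores)) {
    return(list(by_focal = cbind(data.frame(focal = character(0),
                                            group = character(0)),
                                 empty[0, ]),
                pooled = cbind(data.frame(group = character(0)),
                               empty[0, ])))
  }
  tally <- function(cls) {
    n <- length(cls)
    cnt <- vapply(classes, function(k) sum(cls == k), numeric(1))
    pct <- if (n > 0) round(100 * cnt / n, 1) else cnt
    data.frame(n = n, consistent = cnt[1], conflict = cnt[2],
               no_difference = cnt[3], consistent_pct = pct[1],
               conflict_pct = pct[2], no_difference_pct = pct[3])
  }
  key <- interaction(scores$focal, scores$group, drop = TRUE)
  by_focal <- do.call(rbind, lapply(split(scores, key), function(s) {
    cbind(data.frame(focal = s$focal[1], group = s$group[1],
                     stringsAsFactors = FALSE), tally(s$class))
  }))
  pooled <- do.call(rbind, lapply(split(scores, scores$group),
    function(s) {
      cbind(data.frame(group = s$group[1], stringsAsFactors = FALSE),
            tally(s$class))
    }))
  rownames(by_focal) <- rownames(pooled) <- NULL
  list(by_focal = by_focal, pooled = pooled)
}

#' qPCR expression log2 fold change from delta-Ct values
#'
#' Implements the delta-delta-Ct convention: with
#' \eqn{\Delta Ct = Ct_{target} - Ct_{housekeeping}} per animal,
#' \eqn{\log_2 FC = -(\overline{\Delta Ct}_{treat} -
#' \overline{\Delta Ct}_{ctrl})}; a treatment running uniformly 2 cycles
#' lower than control therefore reports a log2 fold change of 2 (4-fold
#' expression). A two-sided paired Student's t-test is attached when
#' `paired = TRUE` (default), a two-sample test otherwise.
#'
#' @param delta_ct_treatment,delta_ct_control numeric delta-Ct vectors
#'   (n >= 2; equal lengths when paired).
#' @return List with `log2fc`, `sd` (of per-pair log2 fold changes when
#'   paired, else pooled), and `p`.
#' @export
expression_log2fc <- function(delta_ct_treatment, delta_ct_control,
                              paired = TRUE) {
  a <- as.numeric(delta_ct_treatment)
  b <- as.numeric(delta_ct_control)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (paired && length(a) != length(b)) {
    stop("paired analysis requires equal group sizes")
  }
  if (paired) {
    per_animal <- -(a - b)
    l2 <- mean(per_animal)
    s <- stats::sd(per_animal)
    p <- if (s == 0) as.numeric(l2 == 0) else
      stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    l2 <- -(mean(a) - mean(b))
    s <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    p <- stats::t.test(a, b)$p.value
  }
  list(log2fc = l2, sd = s, p = p)
}
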