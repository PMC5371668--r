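# Independent brute-force oracles used across the suite. None of these
# share code with the package implementation.

# Fixed-step explicit Euler integration of the gLV ODE.
euler_glv <- function(b, A, x0, times, h = 1e-5) {
  out <- matrix(NA_real_, length(x0), length(times))
  x <- as.numeric(x0)
  t_now <- times[1]
  out[, 1] <- x
  for (k in 2:length(times)) {
    while (t_now < times[k] - 1e-12) {
      step <- min(h, times[k] - t_now)
      x <- x + step * x * (b + drop(A %*% x))
      t_now <- t_now + step
    }
    out[, k] <- x
  }
  out
}

# Exhaustive 3-node motif enumeration: classifies every connected node
# triple by a canonical adjacency form (minimum bit pattern over the 6
# node permutations).
brute_triads <- function(edges) {
  nodes <- sort(unique(c(as.character(edges$source),
                         as.character(edges$target))))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adj[cbind(as.character(edges$source), as.character(edges$target))] <- TRUE
  diag(adj) <- FALSE
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  canon <- function(m) {
    min(vapply(perms, function(p) {
      mm <- m[p, p]
      sum(as.integer(mm[row(mm) != col(mm)]) * 2^(0:5))
    }, numeric(1)))
  }
  counts <- integer(0)
  fanin_exact <- 0L  # induced subgraph is exactly two edges into one node
  if (n >= 3) {
    triples <- utils::combn(n, 3)
    for (tt in seq_len(ncol(triples))) {
      sub <- adj[triples[, tt], triples[, tt]]
      und <- sub | t(sub)
      # connected underlying triple?
      deg <- rowSums(und)
      if (sum(sub) == 0 || any(deg == 0) || sum(und) < 4) next
      key <- as.character(canon(sub))
      counts[key] <- (if (is.na(counts[key])) 0L else counts[key]) + 1L
      if (sum(sub) == 2 && max(colSums(sub)) == 2) {
        fanin_exact <- fanin_exact + 1L
      }
    }
  }
  list(class_counts = sort(unname(counts[counts > 0])),
       total = sum(counts), fanin = fanin_exact)
}

# Exact two-sided permutation test on the difference of group means.
perm_test <- function(a, b) {
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(pooled), length(a))
  stats <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(stats >= obs - 1e-12)
}

# Unpenalized / ridge normal-equations solve written independently
# (explicit matrix inverse, intercept unpenalized).
normal_eq_ridge <- function(X, y, lambda) {
  D <- diag(c(0, rep(1, ncol(X) - 1)))
  drop(solve(t(X) %*% X + lambda * D) %*% (t(X) %*% y))
}
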