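# Independent brute-force oracles and small fixture builders.  Everything
# here is deliberately naive (loops, enumeration, fixed-step integration)
# and shares no code path with the package implementation it checks.

# product-moment correlation written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# pair-by-pair threshold enumeration
oracle_threshold_edges <- function(corr, threshold, mode) {
  ids <- rownames(corr)
  out <- NULL
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      v <- if (mode == "absolute") abs(corr[i, j]) else corr[i, j]
      if (v >= threshold) out <- rbind(out, sort(c(ids[i], ids[j])))
    }
  }
  if (is.null(out)) matrix(character(0), 0, 2) else out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# naive UPGMA agglomeration on a distance matrix; returns the cophenetic
# matrix (merge height = size-weighted average of original dissimilarities)
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  ids <- rownames(d)
  clusters <- as.list(seq_along(ids))
  coph <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  avg_dist <- function(ci, cj) mean(d[ci, cj])
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- avg_dist(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    ci <- clusters[[best[1]]]; cj <- clusters[[best[2]]]
    coph[ids[ci], ids[cj]] <- best_h
    coph[ids[cj], ids[ci]] <- best_h
    clusters[[best[1]]] <- c(ci, cj)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# two-sided Fisher P by explicit hypergeometric table enumeration
oracle_fisher <- function(e_a, e_b, m) {
  k <- e_a + e_b
  xs <- max(0, k - m):min(k, m)
  probs <- stats::dhyper(xs, m, m, k)
  obs <- stats::dhyper(e_a, m, m, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# all acyclic directed graphs on the given nodes (feasible for n <= 3)
oracle_all_dags <- function(ids) {
  n <- length(ids)
  slots <- which(diag(n) == 0)
  out <- list()
  for (mask in 0:(2^length(slots) - 1)) {
    amat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    amat[slots[bitwAnd(bitwShiftR(mask, seq_along(slots) - 1), 1L) == 1L]] <- TRUE
    if (any(amat & t(amat))) next
    if (spongenet::is_acyclic(amat)) out[[length(out) + 1L]] <- amat
  }
  out
}

# brute-force single-edit neighbours of a DAG (add/delete/reverse), kept
# if acyclic and within the parent cap
oracle_local_moves <- function(amat, max_parents) {
  n <- nrow(amat)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (!amat[i, j] && !amat[j, i]) {
        cand <- amat; cand[i, j] <- TRUE
        if (spongenet::is_acyclic(cand) && sum(cand[, j]) <= max_parents) {
          out[[length(out) + 1L]] <- cand
        }
      } else if (amat[i, j]) {
        cand <- amat; cand[i, j] <- FALSE
        out[[length(out) + 1L]] <- cand
        cand[j, i] <- TRUE
        if (spongenet::is_acyclic(cand) && sum(cand[, i]) <= max_parents) {
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}

# exhaustive maximum clique by bitmask subset enumeration (n <= 12)
oracle_max_clique <- function(adj) {
  n <- nrow(adj)
  ids <- rownames(adj)
  best <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
    if (length(members) <= length(best)) next
    ok <- TRUE
    for (i in members) {
      for (j in members) {
        if (i < j && !adj[i, j]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) best <- members
  }
  sort(ids[best])
}

# fixed-step classical RK4 on the competition model, sampled on a uniform
# grid of n_out points
oracle_rk4 <- function(spec, dt, n_out = spec$n_out) {
  rhs <- function(s) {
    x <- s[1]; y <- s[2]; a <- s[3]; b <- s[4]; al <- spec$alpha; rho <- spec$rho
    c(rho - al[1, 1] * x * a - al[1, 2] * x * b,
      rho - al[2, 1] * y * a - al[2, 2] * y * b,
      rho - al[1, 1] * x * a - al[2, 1] * y * a,
      rho - al[1, 2] * x * b - al[2, 2] * y * b)
  }
  grid <- seq(0, spec$t_end, length.out = n_out)
  out <- matrix(NA_real_, n_out, 4)
  s <- c(spec$x0, spec$y0, spec$a0, spec$b0)
  out[1, ] <- s
  n_steps <- round(spec$t_end / dt)
  per_seg <- n_steps / (n_out - 1)
  stopifnot(per_seg == round(per_seg))
  gi <- 2L
  for (i in seq_len(n_steps)) {
    k1 <- rhs(s); k2 <- rhs(s + dt / 2 * k1); k3 <- rhs(s + dt / 2 * k2); k4 <- rhs(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% per_seg == 0) { out[gi, ] <- s; gi <- gi + 1L }
  }
  colnames(out) <- c("x", "y", "a", "b")
  out
}

# random undirected mirna_network on the given ids with edge prob p
random_network <- function(ids, p = 0.3, method = "custom") {
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  spongenet::mirna_network(ids, pairs[keep, , drop = FALSE], method = method)
}

# random DAG: random topological order, then edges forward with prob p
random_dag <- function(ids, p = 0.4, max_parents = 4) {
  n <- length(ids)
  ord <- sample(n)
  amat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (runif(1) < p && sum(amat[, ord[b]]) < max_parents) {
        amat[ord[a], ord[b]] <- TRUE
      }
    }
  }
  amat
}

# small strictly positive expression fixture
random_expression <- function(n_samples, mirnas, sd = 1) {
  x <- exp(matrix(rnorm(n_samples * length(mirnas), 0, sd), n_samples,
                  dimnames = list(sprintf("S%02d", seq_len(n_samples)), mirnas)))
  x
}
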