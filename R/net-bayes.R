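# Static Bayesian-network inference: quantile discretization, BDe scoring,
# all-local-moves proposals, simulated-annealing search.

#' Quantile-discretize an expression matrix
#'
#' Each column is split independently at its empirical quantiles into
#' `levels` bins of as-equal-as-possible counts.  A value lying exactly on
#' a cut point is assigned to the lower bin.  Constant columns collapse to
#' a single level (code 0) with a warning.
#'
#' @param data samples-by-miRNAs expression matrix.
#' @param levels number of levels per variable (default 3; must not exceed
#'   the sample count).
#' @return A `discrete_matrix`: list with `codes` (integer matrix of
#'   values in `0 .. levels-1`), `levels` (per-column level count) and
#'   `breaks` (per-column cut points).
#' @export
quantile_discretize <- function(data, levels = 3L) {
  check_expression(data)
  levels <- as.integer(levels)
  if (levels < 2L) abort("levels must be at least 2")
  if (levels > nrow(data)) {
    abort(sprintf("levels (%d) exceeds the sample count (%d)", levels, nrow(data)))
  }
  breaks <- lapply(seq_len(ncol(data)), function(j) {
    unname(stats::quantile(data[, j], probs = seq_len(levels - 1L) / levels))
  })
  names(breaks) <- colnames(data)
  codes <- vapply(seq_len(ncol(data)), function(j) {
    findInterval(data[, j], breaks[[j]], left.open = TRUE)
  }, integer(nrow(data)))
  dimnames(codes) <- dimnames(data)
  constant <- apply(data, 2L, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning("constant column(s) collapse to one level: ",
            paste(colnames(data)[constant], collapse = ", "))
  }
  structure(
    list(codes = codes, levels = rep(levels, ncol(data)), breaks = breaks),
    class = "discrete_matrix"
  )
}

# ---- DAG plumbing --------------------------------------------------------
# A DAG is a logical adjacency matrix amat[parent, child] with id dimnames.

empty_dag <- function(ids) {
  amat <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  amat
}

dag_amat <- function(dag) {
  if (inherits(dag, "dag_model")) dag$amat else dag
}

#' Test a directed adjacency matrix for acyclicity
#'
#' Topological leaf stripping: repeatedly remove nodes without children;
#' a cycle remains iff some nodes can never be removed.
#'
#' @param amat logical adjacency matrix, `amat[p, c]` meaning p -> c.
#' @export
is_acyclic <- function(amat) {
  amat <- dag_amat(amat)
  alive <- rep(TRUE, nrow(amat))
  repeat {
    leaves <- alive & rowSums(amat[, alive, drop = FALSE]) == 0
    if (!any(leaves)) break
    alive[leaves] <- FALSE
    if (!any(alive)) return(TRUE)
  }
  !any(alive)
}

# boolean reachability closure: closure[i, j] TRUE iff a directed path i ~> j
reach_closure <- function(amat) {
  r <- amat
  repeat {
    r2 <- r | (r %*% r) > 0
    if (identical(r2, r)) return(r)
    r <- r2
  }
}

# is there a directed path from i to j in amat?
has_path <- function(amat, i, j) {
  frontier <- which(amat[i, ])
  seen <- logical(nrow(amat))
  while (length(frontier)) {
    if (j %in% frontier) return(TRUE)
    seen[frontier] <- TRUE
    frontier <- which(colSums(amat[frontier, , drop = FALSE]) > 0 & !seen)
  }
  FALSE
}

# enumerate legal single-edge moves as a data frame (type, i, j)
enumerate_moves <- function(amat, max_parents) {
  n <- nrow(amat)
  indeg <- colSums(amat)
  closure <- reach_closure(amat)
  # additions i -> j: no edge either way, j under parent cap, no path j ~> i
  can_add <- !amat & !t(amat) & !t(closure) &
    matrix(indeg < max_parents, n, n, byrow = TRUE)
  diag(can_add) <- FALSE
  adds <- which(can_add, arr.ind = TRUE)
  dels <- which(amat, arr.ind = TRUE)
  revs <- if (nrow(dels)) {
    ok <- vapply(seq_len(nrow(dels)), function(k) {
      i <- dels[k, 1L]; j <- dels[k, 2L]
      if (indeg[i] + 1L > max_parents) return(FALSE)
      tmp <- amat
      tmp[i, j] <- FALSE
      !has_path(tmp, i, j)
    }, logical(1L))
    dels[ok, , drop = FALSE]
  } else {
    dels
  }
  # move matrix: columns type (1 add, 2 delete, 3 reverse), i, j
  cbind(
    type = rep(1:3, c(nrow(adds), nrow(dels), nrow(revs))),
    i = c(adds[, 1L], dels[, 1L], revs[, 1L]),
    j = c(adds[, 2L], dels[, 2L], revs[, 2L])
  )
}

apply_move <- function(amat, type, i, j) {
  if (type == 1L) {
    amat[i, j] <- TRUE
  } else if (type == 2L) {
    amat[i, j] <- FALSE
  } else {
    amat[i, j] <- FALSE
    amat[j, i] <- TRUE
  }
  amat
}

#' All single-edge neighbours of a DAG
#'
#' Every DAG reachable by one edge addition, deletion or reversal that
#' preserves acyclicity and the parent-set cap.
#'
#' @param dag logical adjacency matrix (or `dag_model`).
#' @param max_parents maximum parents per node.
#' @return List of adjacency matrices.
#' @export
local_moves <- function(dag, max_parents = 4L) {
  amat <- dag_amat(dag)
  moves <- enumerate_moves(amat, max_parents)
  lapply(seq_len(nrow(moves)), function(k) {
    apply_move(amat, moves[k, 1L], moves[k, 2L], moves[k, 3L])
  })
}

# ---- BDe score -----------------------------------------------------------

# log BDe contribution of one family (child j given its parents)
family_score <- function(codes, levels, j, parents, ess) {
  n <- nrow(codes)
  r <- levels[j]
  q <- if (length(parents)) prod(levels[parents]) else 1L
  a_ijk <- ess / (q * r)
  a_ij <- ess / q
  if (length(parents)) {
    mult <- cumprod(c(1L, levels[parents][-length(parents)]))
    cfg <- as.vector(codes[, parents, drop = FALSE] %*% mult) # 0-based
  } else {
    cfg <- integer(n)
  }
  nk <- tabulate(cfg * r + codes[, j] + 1L, nbins = q * r)
  nj <- colSums(matrix(nk, nrow = r))
  sum(lgamma(a_ij) - lgamma(a_ij + nj)) +
    sum(lgamma(a_ijk + nk) - lgamma(a_ijk))
}

#' Log BDe score of a DAG on discretized data
#'
#' Bayesian Dirichlet equivalence metric with equivalent sample size `ess`:
#' for node i with `r_i` levels and `q_i` parent configurations, the family
#' contribution is
#' `sum_j [ lgamma(a_ij) - lgamma(a_ij + N_ij) + sum_k ( lgamma(a_ijk + N_ijk) - lgamma(a_ijk) ) ]`
#' with `a_ijk = ess / (q_i r_i)`.  The score is decomposable (a sum of
#' per-family terms) and assigns equal values to Markov-equivalent DAGs.
#'
#' @param dag adjacency matrix or `dag_model`; must be acyclic.
#' @param disc a `discrete_matrix` from [quantile_discretize()].
#' @param ess equivalent sample size (> 0), default 1.
#' @return Log marginal likelihood (numeric scalar).
#' @export
bde_score <- function(dag, disc, ess = 1) {
  amat <- dag_amat(dag)
  stopifnot(inherits(disc, "discrete_matrix"))
  if (!is_acyclic(amat)) abort("bde_score() requires an acyclic graph")
  if (ess <= 0) abort("ess must be positive")
  sum(vapply(seq_len(ncol(disc$codes)), function(j) {
    family_score(disc$codes, disc$levels, j, which(amat[, j]), ess)
  }, numeric(1L)))
}

# ---- simulated annealing -------------------------------------------------

#' Learn a Bayesian network by simulated annealing
#'
#' Starts from the empty DAG, repeatedly draws a uniformly random legal
#' single-edge neighbour, accepts it when the score does not decrease and
#' otherwise with Boltzmann probability `exp(delta / T)`, under geometric
#' cooling.  The single highest-scoring DAG ever visited is tracked and
#' returned (the n-best-networks setting of 1).  Scores are updated
#' incrementally per affected family (BDe decomposability).
#'
#' @param disc a `discrete_matrix`.
#' @param ess equivalent sample size (default 1).
#' @param max_parents parent-set cap (default 4).
#' @param t0 initial temperature (default 1).
#' @param cooling geometric cooling factor in (0, 1) (default 0.999).
#' @param moves_per_temp proposals per temperature step (default 100).
#' @param max_iter total proposals (default 20000).
#' @param seed integer seed; fixed seed gives an identical output DAG.
#' @param time_budget wall-clock cap in seconds; on expiry the best DAG so
#'   far is returned with attribute `budget_hit = TRUE`.
#' @return A `dag_model`: list with `amat`, `score`, `parents` (per-node
#'   parent sets), `n_iter`, `best_iter`, `budget_hit` and the search
#'   configuration.
#' @export
anneal_search <- function(disc, ess = 1, max_parents = 4L, t0 = 1,
                          cooling = 0.999, moves_per_temp = 100L,
                          max_iter = 20000L, seed = NULL,
                          time_budget = Inf) {
  stopifnot(inherits(disc, "discrete_matrix"))
  if (cooling <= 0 || cooling >= 1) abort("cooling factor must lie in (0, 1)")
  ids <- colnames(disc$codes)
  amat <- empty_dag(ids)
  fam <- vapply(seq_along(ids), function(j) {
    family_score(disc$codes, disc$levels, j, integer(0), ess)
  }, numeric(1L))
  score <- sum(fam)
  best <- list(amat = amat, score = score, iter = 0L)
  budget_hit <- FALSE
  started <- Sys.time()

  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      if (is.finite(time_budget) && iter %% 50L == 0L &&
          as.numeric(Sys.time() - started, units = "secs") > time_budget) {
        budget_hit <- TRUE
        break
      }
      moves <- enumerate_moves(amat, max_parents)
      if (!nrow(moves)) break
      mv <- moves[sample.int(nrow(moves), 1L), ]
      cand <- apply_move(amat, mv[1L], mv[2L], mv[3L])
      affected <- if (mv[1L] == 3L) c(mv[2L], mv[3L]) else mv[3L]
      new_fam <- vapply(affected, function(j) {
        family_score(disc$codes, disc$levels, j, which(cand[, j]), ess)
      }, numeric(1L))
      delta <- sum(new_fam) - sum(fam[affected])
      temp <- t0 * cooling^((iter - 1L) %/% moves_per_temp)
      if (delta >= 0 || stats::runif(1L) < exp(delta / temp)) {
        amat <- cand
        fam[affected] <- new_fam
        score <- score + delta
        if (score > best$score) best <- list(amat = amat, score = score, iter = iter)
      }
    }
  })
  stopifnot(is_acyclic(best$amat))
  structure(
    list(
      amat = best$amat, score = best$score,
      parents = apply(best$amat, 2L, function(col) ids[col], simplify = FALSE),
      n_iter = max_iter, best_iter = best$iter, budget_hit = budget_hit,
      config = list(ess = ess, max_parents = max_parents, t0 = t0,
                    cooling = cooling, moves_per_temp = moves_per_temp,
                    max_iter = max_iter, seed = seed)
    ),
    class = "dag_model"
  )
}

#' @export
print.dag_model <- function(x, ...) {
  cat(sprintf("<dag_model: %d nodes, %d edges, log BDe score %.4f>\n",
              nrow(x$amat), sum(x$amat), x$score))
  invisible(x)
}

#' Undirected skeleton of a learned DAG
#'
#' Drops orientation for comparison with the correlation- and
#' cluster-method networks (edge counts of the three methods are compared
#' on a common undirected footing); the learned direction is retained as
#' the `direction` edge attribute.
#'
#' @param dag a `dag_model` or adjacency matrix.
#' @return A `mirna_network` (method `"bayes"`).
#' @export
dag_to_network <- function(dag) {
  amat <- dag_amat(dag)
  ids <- rownames(amat)
  idx <- which(amat, arr.ind = TRUE)
  edges <- cbind(ids[idx[, 1L]], ids[idx[, 2L]])
  attrs <- if (nrow(idx)) {
    data.frame(direction = paste(ids[idx[, 1L]], ids[idx[, 2L]], sep = "->"))
  } else {
    NULL
  }
  mirna_network(ids, edges, attrs, method = "bayes")
}

#' Build the Bayes-method network from expression data
#'
#' Quantile discretization followed by annealed structure search and
#' skeleton extraction.
#'
#' @inheritParams quantile_discretize
#' @inheritParams anneal_search
#' @return A `mirna_network` with the fitted `dag_model` attached as
#'   attribute `"dag"`.
#' @export
build_bayes_network <- function(data, levels = 3L, ess = 1, max_parents = 4L,
                                t0 = 1, cooling = 0.999, moves_per_temp = 100L,
                                max_iter = 20000L, seed = NULL,
                                time_budget = Inf) {
  disc <- quantile_discretize(data, levels = levels)
  dag <- anneal_search(disc, ess = ess, max_parents = max_parents, t0 = t0,
                       cooling = cooling, moves_per_temp = moves_per_temp,
                       max_iter = max_iter, seed = seed,
                       time_budget = time_budget)
  net <- dag_to_network(dag)
  attr(net, "dag") <- dag
  net
}
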