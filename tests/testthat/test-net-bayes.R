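# Bayesian-network module: discretization, BDe scoring, local moves,
# annealed search.

# build a discrete_matrix directly (bypasses the expression-matrix
# preconditions; bde_score only needs codes + levels)
make_disc <- function(codes, levels) {
  codes <- as.matrix(codes)
  structure(list(codes = codes, levels = rep(levels, ncol(codes)),
                 breaks = NULL),
            class = "discrete_matrix")
}

test_that("quantile discretization splits columns into equal-count bins", {
  x <- cbind(m1 = c(1, 2, 3, 4, 5, 6), m2 = c(6, 5, 4, 3, 2, 1))
  rownames(x) <- sprintf("S%d", 1:6)
  d <- quantile_discretize(x, 3)
  expect_equal(unname(d$codes[, "m1"]), c(0, 0, 1, 1, 2, 2))
  expect_equal(unname(d$codes[, "m2"]), c(2, 2, 1, 1, 0, 0))

  y <- cbind(m1 = c(1, 2, 3), m2 = c(7, 7, 7))
  rownames(y) <- sprintf("S%d", 1:3)
  expect_warning(dc <- quantile_discretize(y, 2), "m2")
  expect_equal(unname(dc$codes[, "m2"]), c(0, 0, 0))

  expect_error(quantile_discretize(y, 4), "exceeds")
})

test_that("ties at a cut value go to the lower bin (rank oracle)", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    levels <- sample(2:4, 1)
    x <- matrix(sample(exp(1:4), n * 2, replace = TRUE), n,
                dimnames = list(sprintf("S%02d", 1:n), c("a", "b")))
    d <- suppressWarnings(quantile_discretize(x, levels))
    for (j in 1:2) {
      br <- unname(stats::quantile(x[, j], seq_len(levels - 1) / levels))
      naive <- unname(vapply(x[, j], function(v) sum(br < v), 0))
      expect_equal(unname(d$codes[, j]), naive)
    }
  }
})

test_that("BDe score matches the closed-form Gamma evaluation", {
  # one binary node, data (0, 1), ess = 1:
  # lgamma(1) - lgamma(3) + 2 * (lgamma(1.5) - lgamma(0.5))
  d <- make_disc(matrix(c(0L, 1L), 2, dimnames = list(NULL, "X")), 2L)
  expect_equal(bde_score(matrix(FALSE, 1, 1, dimnames = list("X", "X")), d),
               lgamma(1) - lgamma(3) + 2 * (lgamma(1.5) - lgamma(0.5)),
               tolerance = 1e-12)
})

test_that("BDe is likelihood-equivalent on two-node graphs", {
  set.seed(62)
  for (rep in 1:10) {
    codes <- matrix(sample(0:2, 40, replace = TRUE), 20,
                    dimnames = list(NULL, c("X", "Y")))
    d <- make_disc(codes, 3L)
    xy <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2,
                 dimnames = list(c("X", "Y"), c("X", "Y")))
    yx <- t(xy)
    ess <- sample(c(0.5, 1, 4), 1)
    expect_equal(bde_score(xy, d, ess), bde_score(yx, d, ess),
                 tolerance = 1e-12)
  }
})

test_that("BDe is decomposable and rejects cyclic graphs", {
  set.seed(63)
  codes <- matrix(sample(0:1, 60, replace = TRUE), 20,
                  dimnames = list(NULL, c("X", "Y", "Z")))
  d <- make_disc(codes, 2L)
  amat <- matrix(FALSE, 3, 3, dimnames = list(colnames(codes), colnames(codes)))
  amat["X", "Y"] <- TRUE
  fam <- vapply(1:3, function(j) {
    spongenet:::family_score(d$codes, d$levels, j, which(amat[, j]), 1)
  }, 0)
  expect_equal(bde_score(amat, d), sum(fam), tolerance = 1e-12)

  # adding Z -> Y changes only Y's family term
  amat2 <- amat
  amat2["Z", "Y"] <- TRUE
  fam2 <- vapply(1:3, function(j) {
    spongenet:::family_score(d$codes, d$levels, j, which(amat2[, j]), 1)
  }, 0)
  expect_equal(fam2[c(1, 3)], fam[c(1, 3)])

  cyc <- amat
  cyc["Y", "X"] <- TRUE
  expect_error(bde_score(cyc, d), "acyclic")
})

test_that("a planted dependency beats the empty graph over all 25 DAGs", {
  set.seed(64)
  n <- 100
  x <- runif(n)
  y <- x + rnorm(n, 0, 0.05) # noisy copy
  z <- runif(n)
  dat <- exp(cbind(X = x, Y = y, Z = z))
  rownames(dat) <- sprintf("S%03d", 1:n)
  d <- quantile_discretize(dat, 3)

  dags <- oracle_all_dags(c("X", "Y", "Z"))
  expect_length(dags, 25)
  scores <- vapply(dags, bde_score, 0, disc = d)
  empty_idx <- which(vapply(dags, function(a) !any(a), TRUE))
  xy_idx <- which(vapply(dags, function(a) {
    a["X", "Y"] && sum(a) == 1
  }, TRUE))
  expect_gt(scores[xy_idx], scores[empty_idx])
  # the global optimum links X and Y
  best <- dags[[which.max(scores)]]
  expect_true(best["X", "Y"] || best["Y", "X"])
})

test_that("local_moves enumerates exactly the legal single-edge edits", {
  ids <- c("X", "Y")
  empty2 <- matrix(FALSE, 2, 2, dimnames = list(ids, ids))
  mv <- local_moves(empty2)
  expect_length(mv, 2)
  expect_true(any(vapply(mv, function(m) m["X", "Y"], TRUE)))
  expect_true(any(vapply(mv, function(m) m["Y", "X"], TRUE)))

  # chain X->Y->Z plus the shortcut X->Z: reversing the shortcut would
  # close the cycle X->Y->Z->X, so no neighbour carries Z->X; the other
  # two reversals leave alternate paths intact and are legal
  ids3 <- c("X", "Y", "Z")
  amat <- matrix(FALSE, 3, 3, dimnames = list(ids3, ids3))
  amat["X", "Y"] <- amat["Y", "Z"] <- amat["X", "Z"] <- TRUE
  mv3 <- local_moves(amat)
  expect_false(any(vapply(mv3, function(m) m["Z", "X"], TRUE)))
  expect_true(any(vapply(mv3, function(m) m["Y", "X"], TRUE)))
  expect_true(any(vapply(mv3, function(m) m["Z", "Y"], TRUE)))
  for (m in mv3) expect_true(is_acyclic(m))
})

test_that("local_moves agrees with the brute-force neighbour generator", {
  set.seed(65)
  canon <- function(lst) sort(vapply(lst, function(m) paste(m + 0, collapse = ""), ""))
  for (rep in 1:25) {
    n <- sample(3:5, 1)
    maxp <- sample(2:4, 1)
    amat <- random_dag(paste0("n", seq_len(n)), p = 0.5, max_parents = maxp)
    expect_identical(canon(local_moves(amat, maxp)),
                     canon(oracle_local_moves(amat, maxp)))
  }
})

test_that("annealing is seed-deterministic and acyclic", {
  set.seed(66)
  dat <- random_expression(60, c("X", "Y", "Z"))
  d <- quantile_discretize(dat, 3)
  a <- anneal_search(d, max_iter = 500, seed = 9)
  b <- anneal_search(d, max_iter = 500, seed = 9)
  expect_identical(a$amat, b$amat)
  expect_equal(a$score, b$score)
  expect_true(is_acyclic(a$amat))
  expect_gte(a$score, bde_score(matrix(FALSE, 3, 3,
                                       dimnames = list(c("X", "Y", "Z"),
                                                       c("X", "Y", "Z"))), d))
})

test_that("annealing keeps independent noise sparse and finds planted chains", {
  # independence: the BDe complexity penalty favours the empty skeleton
  set.seed(67)
  dat <- random_expression(500, c("X", "Y", "Z"))
  d <- quantile_discretize(dat, 3)
  empty_hits <- 0L
  for (seed in 1:20) {
    fit <- anneal_search(d, max_iter = 800, seed = 400 + seed)
    empty_hits <- empty_hits + (sum(fit$amat) == 0L)
    expect_gte(fit$score, bde_score(spongenet:::empty_dag(c("X", "Y", "Z")), d))
  }
  expect_gte(empty_hits, 18L)

  # planted chain X -> Y -> Z: search reaches the exhaustive optimum
  set.seed(68)
  x <- runif(500)
  y <- x + rnorm(500, 0, 0.1)
  z <- y + rnorm(500, 0, 0.1)
  dat2 <- exp(cbind(X = x, Y = y, Z = z))
  rownames(dat2) <- sprintf("S%03d", 1:500)
  d2 <- quantile_discretize(dat2, 3)
  opt <- max(vapply(oracle_all_dags(c("X", "Y", "Z")), bde_score, 0, disc = d2))
  opt_hits <- 0L
  for (seed in 1:20) {
    fit <- anneal_search(d2, max_iter = 1200, seed = 500 + seed)
    opt_hits <- opt_hits + (abs(fit$score - opt) < 1e-9)
  }
  expect_gte(opt_hits, 18L)
})

test_that("dag_to_network takes the undirected skeleton", {
  ids <- c("X", "Y", "Z")
  empty <- matrix(FALSE, 3, 3, dimnames = list(ids, ids))
  expect_equal(n_edges(dag_to_network(empty)), 0L)
  expect_identical(dag_to_network(empty)$nodes, ids)

  chain <- empty
  chain["X", "Y"] <- chain["Y", "Z"] <- TRUE
  net <- dag_to_network(chain)
  expect_identical(unname(net$edges), rbind(c("X", "Y"), c("Y", "Z")))
  expect_identical(net$method, "bayes")

  set.seed(69)
  for (rep in 1:10) {
    amat <- random_dag(paste0("n", 1:5), p = 0.5)
    net <- dag_to_network(amat)
    sym <- amat | t(amat)
    expect_equal(n_edges(net), sum(sym) / 2)
    for (k in seq_len(n_edges(net))) {
      expect_true(sym[net$edges[k, 1], net$edges[k, 2]])
    }
  }
})
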