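# independent closed-form LDA oracle: w = S^-1 (m2 - m1), threshold at the
# midpoint with log-prior offset
lda_oracle <- function(X, y, Xnew) {
  lev <- sort(unique(y))
  X1 <- X[y == lev[1], , drop = FALSE]
  X2 <- X[y == lev[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  S <- (crossprod(sweep(X1, 2, m1)) + crossprod(sweep(X2, 2, m2))) /
    (nrow(X) - 2)
  w <- solve(S, m2 - m1)
  s <- drop(Xnew %*% w) - sum(w * (m1 + m2)) / 2 +
    log(nrow(X2) / nrow(X1))
  ifelse(s > 0, lev[2], lev[1])
}

test_that("rLDA separates well-separated clouds and matches the closed form at gamma 0", {
  toy <- gaussian_toy(200, 5, delta = 6, seed = 1)
  m <- rlda_fit(toy$X, toy$y, gamma = 0)
  expect_equal(mean(predict(m, toy$X) == toy$y), 1)

  toy2 <- gaussian_toy(500, 8, delta = 1.2, seed = 2)
  set.seed(3)
  Xnew <- matrix(stats::rnorm(200 * 8), 200, 8)
  m2 <- rlda_fit(toy2$X, toy2$y, gamma = 0)
  expect_identical(predict(m2, Xnew), lda_oracle(toy2$X, toy2$y, Xnew))
  # decision scores, not only labels, agree with the oracle
  s_pkg <- drop(Xnew %*% m2$weights) + m2$bias
  m1 <- colMeans(toy2$X[toy2$y == "a", ]); mu2 <- colMeans(toy2$X[toy2$y == "b", ])
  S <- (crossprod(sweep(toy2$X[toy2$y == "a", ], 2, m1)) +
          crossprod(sweep(toy2$X[toy2$y == "b", ], 2, mu2))) / (nrow(toy2$X) - 2)
  w_or <- solve(S, mu2 - m1)
  s_or <- drop(Xnew %*% w_or) - sum(w_or * (m1 + mu2)) / 2
  expect_equal(s_pkg, s_or, tolerance = 1e-6)
})

test_that("gamma 1 reduces to the nearest-class-mean rule", {
  toy <- gaussian_toy(50, 4, delta = 2, seed = 4)
  m <- rlda_fit(toy$X, toy$y, gamma = 1, priors = c(0.5, 0.5))
  set.seed(5)
  Xnew <- matrix(stats::rnorm(100 * 4), 100, 4)
  d1 <- rowSums(sweep(Xnew, 2, m$class_means[1, ])^2)
  d2 <- rowSums(sweep(Xnew, 2, m$class_means[2, ])^2)
  expect_identical(predict(m, Xnew), ifelse(d2 < d1, "b", "a"))
})

test_that("rLDA prediction is deterministic with documented tie-breaks", {
  toy <- gaussian_toy(50, 3, delta = 3, seed = 6)
  m <- rlda_fit(toy$X, toy$y, gamma = 0.2, priors = c(0.5, 0.5))
  expect_equal(unname(predict(m, matrix(m$class_means[1, ], 1))), "a")
  expect_equal(unname(predict(m, matrix(m$class_means[2, ], 1))), "b")
  # a point scoring exactly zero goes to class 0 ("a")
  m_tie <- m
  m_tie$weights <- c(1, 0, 0)
  m_tie$bias <- 0
  expect_equal(unname(predict(m_tie, matrix(0, 1, 3))), "a")
  expect_equal(unname(predict(m_tie, matrix(c(1e-9, 0, 0), 1))), "b")
  expect_error(predict(m, matrix(0, 1, 5)), class = "passivebci_shape_error")
  expect_error(rlda_fit(toy$X, rep("a", nrow(toy$X))),
               class = "passivebci_fit_error")
  expect_error(rlda_fit(toy$X, toy$y, gamma = 1.5),
               class = "passivebci_parameter_error")
})

test_that("labels are invariant to feature scaling absorbed at fit time", {
  toy <- gaussian_toy(100, 6, delta = 1.5, seed = 7)
  set.seed(8)
  Xnew <- matrix(stats::rnorm(50 * 6), 50, 6)
  scale <- c(0.01, 1, 100, 5, 0.5, 10)
  m_raw <- rlda_fit(toy$X, toy$y, gamma = 0)
  m_scaled <- rlda_fit(sweep(toy$X, 2, scale, `*`), toy$y, gamma = 0)
  expect_identical(predict(m_raw, Xnew),
                   predict(m_scaled, sweep(Xnew, 2, scale, `*`)))
})

test_that("analytic shrinkage grows as samples become scarce", {
  # anisotropic covariance: the scaled-identity target is genuinely wrong,
  # so shrinkage should vanish with ample data and grow when it is scarce
  sds <- seq(1, 10, length.out = 10)
  make <- function(n, seed) {
    toy <- gaussian_toy(n, 10, seed = seed)
    toy$X <- sweep(toy$X, 2, sds, `*`)
    toy
  }
  toy_big <- make(400, 9)
  toy_small <- make(12, 9)
  g_big <- rlda_fit(toy_big$X, toy_big$y)$gamma
  g_small <- rlda_fit(toy_small$X, toy_small$y)$gamma
  expect_gt(g_small, g_big)
  expect_true(g_big >= 0 && g_small <= 1)
})

make_training_set <- function(n = 40, p = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  wl <- rep(c("easy", "difficult"), length.out = n)
  af <- rep(c("relaxed", "relaxed", "stressed", "stressed"), length.out = n)
  X[wl == "difficult", 1] <- X[wl == "difficult", 1] + 2
  X[af == "stressed", 2] <- X[af == "stressed", 2] + 2
  list(features = X, workload = wl, affect = af)
}

test_that("ensembles are stratified by the other state and vote by majority", {
  ts <- make_training_set()
  ens_w <- ensemble_fit("workload", ts)
  expect_equal(ens_w$strata, c("relaxed", "stressed", "both"))
  ens_a <- ensemble_fit("affect", ts)
  expect_equal(ens_a$strata, c("easy", "difficult", "both"))
  expect_length(ens_w$voters, 3)

  # the two single-stratum training sets partition the pooled one
  n_rel <- sum(ts$affect == "relaxed")
  n_str <- sum(ts$affect == "stressed")
  expect_equal(n_rel + n_str, length(ts$affect))

  # majority logic via a stub trainer with controlled outputs
  stub <- function(out) structure(list(out = out), class = "stub_voter")
  assign("predict.stub_voter",
         function(object, features, ...) rep(object$out, nrow(features)),
         envir = globalenv())
  on.exit(rm("predict.stub_voter", envir = globalenv()), add = TRUE)
  ens <- ens_w
  ens$voters <- list(stub("difficult"), stub("difficult"), stub("easy"))
  expect_equal(unname(predict(ens, matrix(0, 2, 6))), rep("difficult", 2))
  ens$voters <- list(stub("easy"), stub("easy"), stub("easy"))
  expect_equal(unname(predict(ens, matrix(0, 1, 6))), "easy")
})

test_that("ensemble prediction is permutation-invariant in its voters", {
  ts <- make_training_set(seed = 2)
  ens <- ensemble_fit("workload", ts)
  set.seed(3)
  Xnew <- matrix(stats::rnorm(30 * 6), 30, 6)
  base <- predict(ens, Xnew)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    ens_p <- ens
    ens_p$voters <- ens$voters[perm]
    expect_identical(predict(ens_p, Xnew), base)
  }
})

test_that("an empty or single-class stratum raises a stratification error", {
  ts <- make_training_set()
  ts$affect <- rep("relaxed", length(ts$affect))
  expect_error(ensemble_fit("workload", ts),
               class = "passivebci_stratification_error")
  ts2 <- make_training_set()
  ts2$workload[ts2$affect == "relaxed"] <- "easy"
  expect_error(ensemble_fit("workload", ts2),
               class = "passivebci_stratification_error")
})

test_that("stratified voting protects against cross-state interference", {
  # the stress effect moves the workload feature in opposite directions per
  # stratum, so a pooled classifier is corrupted but single-stratum voters
  # are not
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 120
    wl <- rep(c("easy", "difficult"), length.out = n)
    af <- rep(c("relaxed", "stressed"), each = 2, length.out = n)
    X <- matrix(stats::rnorm(n * 4, sd = 0.8), n, 4)
    eff <- ifelse(af == "relaxed", 1.4, -1.4)
    X[, 1] <- X[, 1] + ifelse(wl == "difficult", eff, 0)
    tr <- list(features = X[1:80, ], workload = wl[1:80], affect = af[1:80])
    te_idx <- 81:n
    ens <- ensemble_fit("workload", tr, gamma = 0.1)
    pooled <- rlda_fit(tr$features, tr$workload, gamma = 0.1)
    c(mean(predict(ens, X[te_idx, ]) == wl[te_idx]),
      mean(predict(pooled, X[te_idx, ]) == wl[te_idx]))
  }, c(1, 1))
  expect_gte(mean(accs[1, ]), mean(accs[2, ]))
})

test_that("the sliding vote smooths as enumerated by hand", {
  expect_equal(sliding_vote(c(0, 0, 1, 0, 1, 1)), c(0, 0, 0, 0, 1, 1))
  expect_equal(sliding_vote(rep(1, 10)), rep(1, 10))
  x <- c(rep(0, 5), 1, rep(0, 5))
  expect_equal(sliding_vote(x), rep(0, 11))
  expect_equal(sliding_vote(c("a", "b", "a")), c("a", "b", "a"))
  expect_error(sliding_vote(c(0, 1), k = 2), class = "passivebci_parameter_error")
})

test_that("the sliding vote never flips a label that agrees with both neighbours", {
  set.seed(11)
  for (rep_i in 1:20) {
    raw <- sample(c(0, 1), 50, replace = TRUE)
    sm <- sliding_vote(raw)
    agree <- which(raw[-c(1, 50)] == raw[-c(49, 50)] &
                     raw[-c(1, 50)] == raw[-c(1, 2)]) + 1
    expect_equal(sm[agree], raw[agree])
  }
})
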