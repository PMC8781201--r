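test_that("weight initialization is seeded, positive and uses the closed-form rate", {
  split <- toy_split(n_s = 100, m = 10)
  st1 <- init_weights(split, N = 20, seed = 5)
  st2 <- init_weights(split, N = 20, seed = 5)
  expect_identical(st1$weights, st2$weights)
  expect_true(all(st1$weights > 0))
  expect_length(st1$weights, 110)
  # beta = 1 / (1 + sqrt(2 ln(n_s) / N)) evaluated independently
  expect_equal(st1$beta, 1 / (1 + sqrt(2 * log(100) / 20)), tolerance = 1e-12)
  expect_equal(st1$beta, 0.595731, tolerance = 1e-5)
  expect_true(st1$beta > 0 && st1$beta < 1)
  st_u <- init_weights(split, N = 20, seed = 5, init = "uniform")
  expect_true(all(st_u$weights == 1))
})

test_that("weight normalization divides by the total and keeps raw weights", {
  split <- toy_split(n_s = 2, m = 1)
  st <- init_weights(split, N = 5, seed = 1)
  st$weights <- c(2, 2, 4)
  st <- normalize_weights(st)
  expect_equal(st$p_t, c(0.25, 0.25, 0.5))
  expect_equal(st$weights, c(2, 2, 4))
  for (s in 1:5) {
    st$weights <- stats::runif(3) + 0.1
    expect_lt(abs(sum(normalize_weights(st)$p_t) - 1), 1e-12)
  }
  st$weights <- c(1, NA, 1)
  expect_error(normalize_weights(st), class = "passivebci_numeric_error")
})

test_that("the weighted target-training error is clipped into its working range", {
  split <- toy_split(n_s = 4, m = 3)
  st <- init_weights(split, N = 5, seed = 1)
  st$weights <- c(rep(1, 4), 0.2, 0.3, 0.5)
  expect_equal(compute_error(st, c(0, 1, 0), c(0, 1, 0)), 1e-10)
  # only the third (weight 0.5) sample wrong: raw error 0.5, clipped to 0.49
  expect_equal(compute_error(st, c(0, 1, 1), c(0, 1, 0)), 0.49)
  expect_equal(compute_error(st, c(1, 0, 1), c(0, 1, 0)), 0.49)
  # an intermediate weighted error passes through unclipped
  expect_equal(compute_error(st, c(1, 1, 0), c(0, 1, 0)), 0.2)
})

test_that("weight updates shift trust in the boosting directions", {
  split <- toy_split(n_s = 4, m = 4)
  st <- init_weights(split, N = 10, seed = 2, init = "uniform")
  y <- c(0, 1, 0, 1)

  # all correct: normalized weights unchanged
  h_ok <- y
  attr(h_ok, "err_sd") <- rep(0, 4)
  st_ok <- update_weights(st, h_ok, y)
  expect_equal(st_ok$p_t, st$p_t, tolerance = 1e-12)

  # one wrong source, one wrong target sample
  h <- c(1, 1, 0, 1)                       # target sample 1 wrong
  attr(h, "err_sd") <- c(1, 0, 0, 0)       # source sample 1 wrong
  st2 <- update_weights(st, h, y)
  # misclassified source is down-weighted relative to a correct source
  expect_lt(st2$p_t[1] / st2$p_t[2], st$p_t[1] / st$p_t[2])
  # misclassified target is up-weighted relative to a correct target
  expect_gt(st2$p_t[5] / st2$p_t[6], st$p_t[5] / st$p_t[6])
  expect_true(all(st2$weights > 0))
  expect_lt(abs(sum(st2$p_t) - 1), 1e-12)
  expect_equal(st2$beta_t_history,
               compute_error(st, c(1, 1, 0, 1), y) /
                 (1 - compute_error(st, c(1, 1, 0, 1), y)))
})

test_that("the final hypothesis equals the exhaustive product form", {
  # brute-force oracle: evaluate prod(beta_t^-h) >= prod(beta_t^-1/2)
  product_oracle <- function(beta_t, H) {
    N <- length(beta_t)
    t0 <- ceiling(N / 2)
    vapply(seq_len(ncol(H)), function(j) {
      lhs <- prod(beta_t[t0:N]^(-H[t0:N, j]))
      rhs <- prod(beta_t[t0:N]^(-0.5))
      as.integer(lhs >= rhs)
    }, 1L)
  }
  set.seed(7)
  for (N in 1:4) {
    for (rep_i in 1:20) {
      beta_t <- stats::runif(N, 0.05, 0.95)
      H <- matrix(sample(0:1, N * 8, replace = TRUE), N, 8)
      st <- structure(list(N = N, t = N, beta_t_history = beta_t),
                      class = "boost_state")
      expect_identical(final_hypothesis(st, H), product_oracle(beta_t, H))
    }
  }
  # equal rates reduce to simple majority; ties go to class 1
  st3 <- structure(list(N = 3, t = 3, beta_t_history = rep(0.3, 3)),
                   class = "boost_state")
  expect_identical(final_hypothesis(st3, matrix(c(1, 1, 0), 3, 1)), 1L)
  expect_identical(final_hypothesis(st3, matrix(c(0, 0, 0), 3, 1)), 0L)
  st2 <- structure(list(N = 2, t = 2, beta_t_history = c(0.4, 0.4)),
                   class = "boost_state")
  expect_identical(final_hypothesis(st2, matrix(c(1, 0), 2, 1)), 1L)
})

test_that("EasyTL labels targets at the class centers correctly", {
  split <- toy_split(n_s = 40, m = 10, seed = 3)
  y01 <- as.integer(c(split$Tsd$labels, split$Ttd$labels) == "b")
  X <- rbind(split$Tsd$features, split$Ttd$features)
  p <- rep(1 / nrow(X), nrow(X))
  mu_a <- colMeans(X[y01 == 0, ]); mu_b <- colMeans(X[y01 == 1, ])
  targets <- rbind(mu_a, mu_b, mu_a, mu_b)
  fit <- easytl_fit_predict(X, y01, p, targets, min_class_mass = 1)
  expect_equal(fit$labels, c(0L, 1L, 0L, 1L))
  expect_true(all(rowSums(fit$model$soft_labels) - 1 < 1e-9))

  # doubling all weights changes nothing
  fit2 <- easytl_fit_predict(X, y01, 2 * p, targets, min_class_mass = 1)
  expect_identical(fit2$labels, fit$labels)
})

test_that("correlation alignment beats no alignment under a domain shift", {
  wins <- vapply(1:12, function(s) {
    set.seed(s)
    n <- 60; p <- 4
    y <- rep(0:1, each = n / 2)
    Xs <- matrix(stats::rnorm(n * p), n, p); Xs[y == 1, 1] <- Xs[y == 1, 1] + 2
    shift <- stats::rnorm(p, 0, 2)
    A <- diag(p) + matrix(stats::rnorm(p * p, 0, 0.2), p)
    Xt <- (matrix(stats::rnorm(n * p), n, p) +
             cbind(2 * y, matrix(0, n, p - 1))) %*% A
    Xt <- sweep(Xt, 2, shift, `+`)
    w <- rep(1 / n, n)
    fit <- easytl_fit_predict(Xs, y, w, Xt)
    acc_aligned <- mean(fit$labels == y)
    # nearest source-center without alignment
    ctr <- rbind(colMeans(Xs[y == 0, ]), colMeans(Xs[y == 1, ]))
    D <- cbind(sqrt(rowSums(sweep(Xt, 2, ctr[1, ])^2)),
               sqrt(rowSums(sweep(Xt, 2, ctr[2, ])^2)))
    acc_plain <- mean(as.integer(D[, 2] < D[, 1]) == y)
    acc_aligned - acc_plain
  }, 1)
  expect_gt(mean(wins), 0)
})

test_that("the intra-domain program attains the LP optimum on small instances", {
  # independent oracle: substituting a[j,2] = 1 - a[j,1] reduces the
  # program to min sum(c x) with c = D1 - D2, mass <= sum(x) <= n - mass,
  # 0 <= x <= 1, whose exact solution follows from sorting the costs
  # (fractional knapsack): activate every negative cost up to the upper
  # budget, then fill up to the lower budget with the cheapest remainder.
  knapsack_oracle <- function(D, mass) {
    n <- nrow(D)
    cc <- D[, 1] - D[, 2]
    ord <- order(cc)
    x <- numeric(n)
    x[ord[seq_len(min(sum(cc < 0), n - mass))]] <- 1  # all helpful, capped
    if (sum(x) < mass) {
      for (j in ord) {
        if (sum(x) >= mass) break
        x[j] <- 1
      }
    }
    sum(D[, 2]) + sum(cc * x)
  }
  set.seed(10)
  for (rep_i in 1:20) {
    n <- sample(3:8, 1)
    D <- matrix(stats::runif(2 * n, 0.1, 2), n, 2)
    mass <- sample(1:floor(n / 2), 1)
    mine <- passivebci:::intra_domain_program(D, mass)
    expect_true(all(mine >= -1e-12))
    expect_true(all(abs(rowSums(mine) - 1) < 1e-9))
    expect_true(all(colSums(mine) >= mass - 1e-9))
    expect_equal(sum(D * mine), knapsack_oracle(D, mass), tolerance = 1e-8)
  }
})

test_that("an infeasible program falls back to nearest centers with a warning", {
  D <- matrix(c(0.1, 0.9, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_warning(out <- passivebci:::intra_domain_program(D, mass = 2),
                 "infeasible")
  expect_equal(out, rbind(c(1, 0), c(1, 0)))
})

test_that("one boosting iteration reduces to the single EasyTL hypothesis on S", {
  split <- toy_split(n_s = 30, m = 10, n_S = 12, seed = 4)
  m1 <- instance_easytl(split, N = 1, seed = 9)
  st <- init_weights(split, N = 1, seed = 9)
  y01 <- passivebci:::split_y01(split)
  fit <- easytl_fit_predict(rbind(split$Tsd$features, split$Ttd$features),
                            y01, st$p_t,
                            rbind(split$Ttd$features, split$S))
  expect_identical(m1$labels01_S, fit$labels[-(1:10)])
})

test_that("the boosting loop preserves weight invariants and ignores S for updates", {
  split <- toy_split(n_s = 30, m = 10, n_S = 12, shift = 1, seed = 5)
  m <- instance_easytl(split, N = 6, seed = 2)
  st <- m$state
  expect_equal(st$t, 6L)
  expect_true(all(st$weights > 0))
  expect_lt(abs(sum(st$p_t) - 1), 1e-12)
  expect_true(all(st$epsilon_t >= 1e-10 & st$epsilon_t <= 0.49))
  expect_true(all(st$beta_t_history > 0 & st$beta_t_history < 1))

  # replacing S must not change the weight trajectory driven by Ttd...
  split2 <- split
  set.seed(77)
  split2$S <- split$S + matrix(stats::rnorm(length(split$S), 0, 1e-8),
                               nrow(split$S))
  m2 <- instance_easytl(split2, N = 6, seed = 2)
  expect_equal(m2$state$weights, m$state$weights, tolerance = 1e-4)
})

test_that("source order does not matter given the same per-sample weights", {
  split <- toy_split(n_s = 20, m = 8, n_S = 10, seed = 6)
  m_a <- instance_easytl(split, N = 3, seed = 1, init = "uniform")
  perm <- sample(20)
  split_p <- split
  split_p$Tsd$features <- split$Tsd$features[perm, ]
  split_p$Tsd$labels <- split$Tsd$labels[perm]
  m_b <- instance_easytl(split_p, N = 3, seed = 1, init = "uniform")
  expect_identical(m_a$labels01_S, m_b$labels01_S)
})

test_that("persistently misclassified target samples accumulate weight", {
  # fixture: one Ttd subset is mislabeled relative to its features, so the
  # base learner keeps erring on it; its normalized weight must not shrink
  split <- toy_split(n_s = 30, m = 10, n_S = 10, seed = 8)
  flip <- 1:3
  split$Ttd$labels[flip] <- ifelse(split$Ttd$labels[flip] == "a", "b", "a")
  st <- init_weights(split, N = 8, seed = 3, init = "uniform")
  y01 <- passivebci:::split_y01(split)
  y_td <- y01[31:40]
  targets <- rbind(split$Ttd$features, split$S)
  Xtrain <- rbind(split$Tsd$features, split$Ttd$features)
  mass_series <- numeric(0)
  for (t in 1:8) {
    fit <- easytl_fit_predict(Xtrain, y01, st$p_t, targets)
    h_td <- fit$labels[1:10]
    mass_series <- c(mass_series, sum(st$p_t[30 + flip]))
    attr(h_td, "err_sd") <- abs(fit$labels_train[1:30] - y01[1:30])
    st <- update_weights(st, h_td, y_td)
  }
  expect_true(all(diff(mass_series) >= -1e-9))
  expect_gt(mass_series[length(mass_series)], mass_series[1])
})
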