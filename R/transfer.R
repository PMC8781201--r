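#' Construct a cross-subject domain split
#'
#' Splits the data for one target subject the way the transfer-learning
#' paradigm requires: `Tsd` holds the labeled source epochs (all other
#' subjects), `Ttd` the target subject's labeled training epochs (their
#' chronologically first two blocks), and `S` the target subject's test
#' epochs (final two blocks).  `Ttd` is merged with `Tsd` to form the
#' enlarged source domain; `S` is only ever labeled by the final
#' hypothesis, never used for weight updates.
#'
#' @param Tsd list with `features` (matrix) and `labels` (binary vector).
#' @param Ttd list with `features` and `labels` for the target subject's
#'   training blocks.
#' @param S feature matrix of the target subject's test epochs.
#' @return A `domain_split`.
#' @export
domain_split <- function(Tsd, Ttd, S) {
  stop_if_not(nrow(Tsd$features) == length(Tsd$labels) &&
                nrow(Ttd$features) == length(Ttd$labels),
              "features and labels must align",
              class = "passivebci_domain_error")
  stop_if_not(nrow(Tsd$features) >= 2 && nrow(Ttd$features) >= 1,
              "source and target-training domains must be non-empty",
              class = "passivebci_domain_error")
  lev <- sort(unique(c(as.character(Tsd$labels), as.character(Ttd$labels))))
  stop_if_not(length(lev) == 2, "labels must be binary",
              class = "passivebci_domain_error")
  structure(list(Tsd = Tsd, Ttd = Ttd, S = as.matrix(S), levels = lev),
            class = "domain_split")
}

split_y01 <- function(split) {
  c(as.integer(as.character(split$Tsd$labels) == split$levels[2]),
    as.integer(as.character(split$Ttd$labels) == split$levels[2]))
}

#' Initialize instance weights for the boosting loop
#'
#' Per-sample weights over the joint training set `Tsd` and `Ttd` are
#' drawn uniformly from (0, 1] (`init = "uniform"` sets them all equal
#' instead).  The fixed source learning rate is computed once as
#' `beta = 1 / (1 + sqrt(2 ln(n_s) / N))`.
#'
#' @param split a [domain_split()].
#' @param N number of boosting iterations (recorded in the state; the
#'   learning rate depends on it).
#' @param seed integer seed for the random draw.
#' @param init `"random"` (default) or `"uniform"`.
#' @return A `boost_state` holding raw weights, normalized weights,
#'   `beta`, and empty iteration history.
#' @export
init_weights <- function(split, N = 20, seed = 1, init = c("random", "uniform")) {
  init <- match.arg(init)
  n_s <- nrow(split$Tsd$features)
  m <- nrow(split$Ttd$features)
  stop_if_not(n_s >= 2 && m >= 1, "need n_s >= 2 source and m >= 1 target samples",
              class = "passivebci_domain_error")
  stop_if_not(N >= 1, "N must be >= 1", class = "passivebci_parameter_error")
  set.seed(seed)
  w <- if (init == "random") 1 - stats::runif(n_s + m) else rep(1, n_s + m)
  state <- structure(list(
    weights = w, p_t = NULL, n_s = n_s, m = m, N = N, t = 0L,
    beta = 1 / (1 + sqrt(2 * log(n_s) / N)),
    beta_t_history = numeric(0), epsilon_t = numeric(0),
    hypotheses = list()), class = "boost_state")
  normalize_weights(state)
}

#' Normalize boosting weights to a distribution
#'
#' Divides every weight by the sum of all weights and stores the result as
#' `p_t`; the raw weights are left untouched.
#'
#' @param state a `boost_state`.
#' @return The state with `p_t` summing to one.
#' @export
normalize_weights <- function(state) {
  stop_if_not(all(is.finite(state$weights)), "non-finite weight",
              class = "passivebci_numeric_error")
  s <- sum(state$weights)
  stop_if_not(s > 0, "weights must have positive sum",
              class = "passivebci_numeric_error")
  state$p_t <- state$weights / s
  state
}

#' Weighted classification error on the target-training domain
#'
#' `epsilon_t = sum_{x in Ttd} w_x |h_t(x) - y(x)| / sum_{x in Ttd} w_x`,
#' i.e. the weight-normalized error over the target-training samples only,
#' clipped into \[1e-10, 0.49\] so the per-iteration learning rate
#' `beta_t = epsilon_t / (1 - epsilon_t)` stays in (0, 1) and the boosting
#' direction remains defined even for a perfect or failing base learner.
#'
#' @param state a `boost_state`.
#' @param h_t predicted 0/1 labels on `Ttd`.
#' @param y true 0/1 labels on `Ttd`.
#' @return Clipped `epsilon_t`.
#' @export
compute_error <- function(state, h_t, y) {
  stop_if_not(length(h_t) == state$m && length(y) == state$m,
              "labels must cover exactly the Ttd samples",
              class = "passivebci_shape_error")
  w <- state$weights[state$n_s + seq_len(state$m)]
  eps <- sum(w * abs(h_t - y)) / sum(w)
  min(max(eps, 1e-10), 0.49)
}

#' One boosting weight update
#'
#' Misclassified source samples are down-weighted by the fixed rate
#' (`w * beta^{|h-y|}`, beta < 1), while misclassified target-training
#' samples are up-weighted by the iteration rate
#' (`w * beta_t^{-|h-y|}`, beta_t < 1 when epsilon_t < 0.5): trust shifts
#' from source instances that mislead the learner toward target instances
#' it still gets wrong.  Weights are renormalized afterwards and the
#' iteration history (`epsilon_t`, `beta_t`) is appended.
#'
#' @param state a `boost_state`.
#' @param h_t,y predicted and true 0/1 labels on `Ttd`.
#' @param eps_t optional precomputed [compute_error()] value.
#' @return The updated, renormalized state with `t` advanced.
#' @export
update_weights <- function(state, h_t, y, eps_t = NULL) {
  if (is.null(eps_t)) eps_t <- compute_error(state, h_t, y)
  beta_t <- eps_t / (1 - eps_t)
  err_td <- abs(h_t - y)
  # the source part of |h_t - y| is supplied via attribute when available
  err_sd <- attr(h_t, "err_sd") %||% NULL
  i_td <- state$n_s + seq_len(state$m)
  if (!is.null(err_sd)) {
    state$weights[seq_len(state$n_s)] <-
      state$weights[seq_len(state$n_s)] * state$beta^err_sd
  }
  state$weights[i_td] <- state$weights[i_td] * beta_t^(-err_td)
  state$t <- state$t + 1L
  state$epsilon_t <- c(state$epsilon_t, eps_t)
  state$beta_t_history <- c(state$beta_t_history, beta_t)
  normalize_weights(state)
}

## ---- EasyTL base learner --------------------------------------------

ridge_cov <- function(X, ridge, w = NULL) {
  if (is.null(w)) {
    C <- stats::cov(X)
    mu <- colMeans(X)
  } else {
    w <- w / sum(w)
    mu <- colSums(X * w)
    Xc <- sweep(X, 2, mu) * sqrt(w)
    C <- crossprod(Xc) / max(1 - sum(w^2), 1e-12)
  }
  list(C = C + diag(ridge * max(mean(diag(C)), 1e-12), ncol(X)), mu = mu)
}

mat_power <- function(C, pow) {
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-12)
  eg$vectors %*% (vals^pow * t(eg$vectors))
}

#' EasyTL: intra-domain alignment and programming
#'
#' The non-parametric transfer-learning base learner.  Three stages:
#' (i) correlation alignment of the labeled training samples to the
#' unlabeled target batch (whiten by the instance-weighted source
#' covariance, re-color by the target covariance, translate to the target
#' mean); (ii) instance-weighted class centroids of the aligned training
#' data; (iii) intra-domain programming: soft target labels solving the
#' linear program that minimizes total centroid-sample distance, over
#' per-sample probability simplexes, subject to each class receiving a
#' minimum total mass (default: half the batch, the balanced-design
#' prior; the blocked session design presents both classes equally).
#' Distances are taken in target-batch-standardized coordinates so that
#' high-variance features cannot dominate the assignment.  Hard labels
#' are the soft-label argmax (ties to class 0).
#'
#' Singular covariances are ridge-regularized; when the program is
#' infeasible (fewer target samples than the required class mass allows)
#' nearest-centroid labels are returned with a warning.
#'
#' @param features labeled training samples (rows).
#' @param y01 training labels in 0/1.
#' @param p per-sample weights (any positive scale; only ratios matter).
#' @param targets unlabeled samples to label.
#' @param ridge relative ridge added to both covariances.
#' @param min_class_mass minimum total soft mass per class; `NULL` uses
#'   half the target batch.
#' @return List with `model` (an `easytl_model`: class centers in target
#'   space, the alignment map, distance scaling, soft labels), `labels`
#'   (hard 0/1 labels on `targets`) and `labels_train` (nearest-centroid
#'   labels of the aligned training rows, used for the boosting source
#'   update).
#' @export
easytl_fit_predict <- function(features, y01, p, targets,
                               ridge = 1e-3, min_class_mass = NULL) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  stop_if_not(length(unique(y01)) == 2 &&
                all(tapply(p, y01, sum) > 0),
              "both classes must be present with positive weight",
              class = "passivebci_fit_error")
  Cs <- ridge_cov(features, ridge, w = p)
  Ct <- ridge_cov(targets, ridge)
  A <- mat_power(Cs$C, -0.5) %*% mat_power(Ct$C, 0.5)
  aligned <- sweep(features, 2, Cs$mu) %*% A
  aligned <- sweep(aligned, 2, Ct$mu, `+`)
  centers <- rbind(
    colSums(aligned[y01 == 0, , drop = FALSE] * p[y01 == 0]) / sum(p[y01 == 0]),
    colSums(aligned[y01 == 1, , drop = FALSE] * p[y01 == 1]) / sum(p[y01 == 1]))
  feat_scale <- apply(targets, 2, stats::sd)
  feat_scale <- pmax(feat_scale, 1e-12 * max(feat_scale, 1e-300))
  if (is.null(min_class_mass)) min_class_mass <- nrow(targets) / 2
  D <- center_distances(targets, centers, feat_scale)
  soft <- intra_domain_program(D, min_class_mass)
  labels <- as.integer(soft[, 2] > soft[, 1])   # tie (0.5, 0.5) -> class 0
  Dtr <- center_distances(aligned, centers, feat_scale)
  model <- structure(list(centers = centers, alignment = A,
                          source_mean = Cs$mu, target_mean = Ct$mu,
                          feat_scale = feat_scale,
                          soft_labels = soft), class = "easytl_model")
  list(model = model, labels = labels,
       labels_train = as.integer(Dtr[, 2] < Dtr[, 1]))
}

center_distances <- function(X, centers, feat_scale = NULL) {
  if (!is.null(feat_scale)) {
    X <- sweep(X, 2, feat_scale, `/`)
    centers <- sweep(centers, 2, feat_scale, `/`)
  }
  cbind(sqrt(rowSums(sweep(X, 2, centers[1, ])^2)),
        sqrt(rowSums(sweep(X, 2, centers[2, ])^2)))
}

#' @export
predict.easytl_model <- function(object, features, ...) {
  D <- center_distances(as.matrix(features), object$centers, object$feat_scale)
  as.integer(D[, 2] < D[, 1])
}

# Exact solution of the binary intra-domain program:
# min sum_jc D[j,c] a[j,c]  s.t.  rows on the simplex, colSums(a) >= mass.
# The unconstrained optimum puts each row's mass on its nearer center; a
# deficient class then takes mass from the rows with the smallest distance
# margin, the last one fractionally.  With two classes at most one class
# can be deficient, so this greedy exchange is the LP optimum.
intra_domain_program <- function(D, mass = 1) {
  n <- nrow(D)
  if (n < 2 * mass) {
    warning("intra-domain program infeasible; falling back to nearest-center labels")
    a <- matrix(0, n, 2)
    a[cbind(seq_len(n), ifelse(D[, 2] < D[, 1], 2L, 1L))] <- 1
    return(a)
  }
  assign2 <- D[, 2] < D[, 1]
  a <- cbind(as.numeric(!assign2), as.numeric(assign2))
  for (cls in 1:2) {
    deficit <- mass - sum(a[, cls])
    if (deficit <= 0) next
    other <- 3 - cls
    donors <- which(a[, other] > 0)
    margin <- D[donors, cls] - D[donors, other]
    ord <- donors[order(margin)]
    for (j in ord) {
      if (deficit <= 0) break
      move <- min(a[j, other], deficit)
      a[j, other] <- a[j, other] - move
      a[j, cls] <- a[j, cls] + move
      deficit <- deficit - move
    }
  }
  a
}

#' Final boosted hypothesis
#'
#' Combines the stored per-iteration hypotheses over the second half of
#' the run (iterations `ceil(N/2)` to `N`): a sample is labeled 1 when the
#' `-log(beta_t)`-weighted vote for class 1 reaches half the total vote
#' weight, i.e. the log-space form of the product-threshold rule; exact
#' ties go to class 1.
#'
#' @param state a completed `boost_state` (`t == N`).
#' @param hypotheses iterations x samples 0/1 matrix; defaults to the
#'   hypotheses on `S` recorded by [instance_easytl()].
#' @return 0/1 labels.
#' @export
final_hypothesis <- function(state, hypotheses = NULL) {
  stop_if_not(state$t >= state$N, "boosting has not completed N iterations",
              class = "passivebci_state_error")
  H <- hypotheses %||% do.call(rbind, state$hypotheses)
  t0 <- as.integer(ceiling(state$N / 2))
  idx <- t0:state$N
  wts <- -log(state$beta_t_history[idx])
  votes <- drop(wts %*% H[idx, , drop = FALSE])
  as.integer(votes >= sum(wts) / 2)
}

#' InstanceEasyTL: instance-reweighted transfer learning
#'
#' The full cross-subject boosting loop.  Each iteration normalizes the
#' instance weights, runs the weighted EasyTL base learner on the merged
#' source (`Tsd` + `Ttd`) against the unlabeled target batch
#' (`Ttd` + `S`), measures the weighted error on `Ttd` only, and shifts
#' weight away from misleading source instances and toward
#' still-misclassified target instances.  `S` never influences the weight
#' updates; it is labeled once by the final hypothesis.
#'
#' @param split a [domain_split()].
#' @param N boosting iterations (default 20).
#' @param seed seed for the initial weight draw.
#' @param init,ridge,min_class_mass passed to [init_weights()] and
#'   [easytl_fit_predict()] (`min_class_mass = NULL`: half the target
#'   batch).
#' @return An `instance_easytl_model` with `labels_S` (on the original
#'   label levels), the per-iteration trace (`epsilon_t`, `beta_t`),
#'   stored base models, and a `predict` method that applies the boosted
#'   nearest-center vote to new target-domain epochs.
#' @export
instance_easytl <- function(split, N = 20, seed = 1,
                            init = "random", ridge = 1e-3,
                            min_class_mass = NULL) {
  stop_if_not(inherits(split, "domain_split"), "split must be a domain_split",
              class = "passivebci_domain_error")
  state <- init_weights(split, N = N, seed = seed, init = init)
  Xtrain <- rbind(split$Tsd$features, split$Ttd$features)
  y_all <- split_y01(split)
  y_td <- y_all[state$n_s + seq_len(state$m)]
  targets <- rbind(split$Ttd$features, split$S)
  i_td <- seq_len(state$m)
  n_S <- nrow(split$S)
  H_S <- matrix(0L, N, n_S)
  models <- vector("list", N)
  for (t in seq_len(N)) {
    fit <- easytl_fit_predict(Xtrain, y_all, state$p_t, targets,
                              ridge = ridge, min_class_mass = min_class_mass)
    h_full <- fit$labels
    h_td <- h_full[i_td]
    H_S[t, ] <- h_full[-i_td]
    models[[t]] <- fit$model
    eps <- compute_error(state, h_td, y_td)
    # source errors (on aligned source rows) for the fixed-rate down-weighting
    h_sd <- fit$labels_train[seq_len(state$n_s)]
    attr(h_td, "err_sd") <- abs(h_sd - y_all[seq_len(state$n_s)])
    state$hypotheses[[t]] <- h_full
    state <- update_weights(state, h_td, y_td, eps_t = eps)
  }
  labels01 <- final_hypothesis(state, H_S)
  structure(list(
    labels_S = split$levels[labels01 + 1L],
    labels01_S = labels01,
    state = state, models = models, levels = split$levels,
    N = N, seed = seed,
    trace = data.frame(t = seq_len(N), epsilon_t = state$epsilon_t,
                       beta_t = state$beta_t_history)),
    class = "instance_easytl_model")
}

#' Predict labels for new target-domain epochs from a boosted model
#'
#' Applies each stored iteration's aligned class centers as a
#' nearest-center rule and combines the second-half iterations with the
#' same `-log(beta_t)`-weighted vote as the final hypothesis.  This causal
#' form lets the fitted model label epochs one at a time in streaming
#' order.
#'
#' @param object an `instance_easytl_model`.
#' @param features epochs to classify (rows), in the target domain.
#' @param ... unused.
#' @return Character labels on the original levels.
#' @export
predict.instance_easytl_model <- function(object, features, ...) {
  features <- as.matrix(features)
  st <- object$state
  t0 <- as.integer(ceiling(st$N / 2))
  idx <- t0:st$N
  wts <- -log(st$beta_t_history[idx])
  H <- vapply(idx, function(t) predict(object$models[[t]], features),
              integer(nrow(features)))
  H <- matrix(H, nrow = nrow(features))
  votes <- drop(H %*% wts)
  object$levels[as.integer(votes >= sum(wts) / 2) + 1L]
}
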