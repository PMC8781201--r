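#' Fit a shrinkage-regularized linear discriminant
#'
#' Binary LDA whose pooled covariance is shrunk toward a scaled identity,
#' `(1 - gamma) * S + gamma * nu * I` with `nu = tr(S)/p`.  When `gamma`
#' is omitted it is set by Ledoit-Wolf analytic shrinkage, the standard
#' choice for high-dimensional EEG band-power features where the epoch
#' count is far below the feature count.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels binary label vector (factor, character or 0/1); the first
#'   sorted level is class 0.
#' @param gamma shrinkage intensity in \[0, 1\], or `NULL` for the
#'   analytic estimate.
#' @param priors class priors; defaults to the empirical frequencies.
#' @return An `rlda_model` with the class means, shrunk pooled
#'   covariance, discriminant weights and `gamma`.
#' @export
rlda_fit <- function(features, labels, gamma = NULL, priors = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  stop_if_not(length(lev) == 2, "rlda_fit needs exactly two classes",
              class = "passivebci_fit_error")
  if (!is.null(gamma))
    stop_if_not(gamma >= 0 && gamma <= 1, "gamma must lie in [0, 1]",
                class = "passivebci_parameter_error")
  n <- nrow(features); p <- ncol(features)
  mu0 <- colMeans(features[labels == lev[1], , drop = FALSE])
  mu1 <- colMeans(features[labels == lev[2], , drop = FALSE])
  Z <- features
  Z[labels == lev[1], ] <- sweep(features[labels == lev[1], , drop = FALSE], 2, mu0)
  Z[labels == lev[2], ] <- sweep(features[labels == lev[2], , drop = FALSE], 2, mu1)
  S <- crossprod(Z) / (n - 2)
  nu <- sum(diag(S)) / p
  if (is.null(gamma)) gamma <- lw_gamma(Z)
  Sh <- (1 - gamma) * S
  diag(Sh) <- diag(Sh) + gamma * nu
  w <- solve(Sh, mu1 - mu0)
  if (is.null(priors)) priors <- c(mean(labels == lev[1]), mean(labels == lev[2]))
  priors <- priors / sum(priors)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(priors[2] / priors[1])
  structure(list(levels = lev, class_means = rbind(mu0, mu1),
                 pooled_cov_shrunk = Sh, gamma = gamma, priors = priors,
                 weights = w, bias = b),
            class = "rlda_model")
}

# Ledoit-Wolf analytic shrinkage intensity toward nu * I, from the
# (class-)centered data rows Z.  Uses the maximum-likelihood covariance
# S_ml = Z'Z/n and the identities ||z z' - S||_F^2 summed over rows
# = sum(|z_i|^4) - n ||S||_F^2, so no p x p outer products are formed.
lw_gamma <- function(Z) {
  n <- nrow(Z); p <- ncol(Z)
  S <- crossprod(Z) / n
  nu <- sum(diag(S)) / p
  d2 <- sum(S^2) - 2 * nu * sum(diag(S)) + p * nu^2   # ||S - nu I||_F^2
  if (d2 < 1e-300) return(0)
  b2 <- (sum(rowSums(Z^2)^2) - n * sum(S^2)) / n^2
  b2 <- min(b2, d2)
  max(0, min(1, b2 / d2))
}

#' Predict class labels from a fitted discriminant
#'
#' Deterministic: a sample exactly on the decision boundary is assigned
#' class 0 (the first sorted training level).
#'
#' @param object an `rlda_model`.
#' @param features numeric matrix with the training feature dimension.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.rlda_model <- function(object, features, ...) {
  features <- as.matrix(features)
  stop_if_not(ncol(features) == length(object$weights),
              "feature dimension does not match the fitted model",
              class = "passivebci_shape_error")
  score <- drop(features %*% object$weights) + object$bias
  ifelse(score > 0, object$levels[2], object$levels[1])
}

#' Fit a condition-stratified majority-vote ensemble
#'
#' Decoding one state in the presence of the other uses three voters per
#' task: for workload (easy vs difficult) they are trained on relaxed-only
#' epochs, stressed-only epochs, and both; for affect (relaxed vs
#' stressed) on easy-only, difficult-only, and both.  The final prediction
#' is the majority among the three.
#'
#' @param task `"workload"` or `"affect"`.
#' @param training_set list with `features` (matrix), `workload` and
#'   `affect` label vectors (as from [epoch_features()]).
#' @param trainer function `(features, labels, stratum)` returning a
#'   fitted model with a `predict` method; defaults to [rlda_fit()].
#' @param ... passed to the default trainer.
#' @return A `bci_ensemble` with three voters and their strata.
#' @export
ensemble_fit <- function(task = c("workload", "affect"), training_set,
                         trainer = NULL, ...) {
  task <- match.arg(task)
  if (is.null(trainer))
    trainer <- function(features, labels, stratum) rlda_fit(features, labels, ...)
  feats <- training_set$features
  y <- if (task == "workload") training_set$workload else training_set$affect
  strat_by <- if (task == "workload") training_set$affect else training_set$workload
  strata <- if (task == "workload") c("relaxed", "stressed", "both")
            else c("easy", "difficult", "both")
  voters <- lapply(strata, function(s) {
    keep <- if (s == "both") rep(TRUE, length(y)) else strat_by == s
    stop_if_not(any(keep), sprintf("empty training stratum: %s", s),
                class = "passivebci_stratification_error")
    stop_if_not(length(unique(y[keep])) == 2,
                sprintf("stratum %s lacks both target classes", s),
                class = "passivebci_stratification_error")
    trainer(feats[keep, , drop = FALSE], y[keep], s)
  })
  structure(list(task = task, strata = strata, voters = voters,
                 levels = sort(unique(y))),
            class = "bci_ensemble")
}

#' Majority-vote prediction from a stratified ensemble
#'
#' @param object a `bci_ensemble`.
#' @param features numeric matrix of epochs to classify.
#' @param ... passed to the voters' predict methods.
#' @return Character vector: the per-sample majority among the three
#'   voters.
#' @export
predict.bci_ensemble <- function(object, features, ...) {
  votes <- vapply(object$voters, function(v) predict(v, features, ...),
                  character(nrow(as.matrix(features))))
  votes <- matrix(votes, ncol = length(object$voters))
  pos <- object$levels[2]
  ifelse(rowSums(votes == pos) * 2 > ncol(votes), pos, object$levels[1])
}

#' Temporal sliding-window majority vote
#'
#' Smooths a chronological label stream: each output is the majority over
#' the current and `k - 1` preceding raw labels.  Early steps use the
#' available prefix; a tied prefix keeps the raw label.  A label agreeing
#' with both neighbours is never changed.
#'
#' @param raw vector of per-step labels (two distinct values).
#' @param k odd window length (default 3: the sample and its two
#'   predecessors).
#' @return Smoothed label vector of the same length.
#' @export
sliding_vote <- function(raw, k = 3) {
  stop_if_not(k %% 2 == 1, "k must be odd",
              class = "passivebci_parameter_error")
  n <- length(raw)
  out <- raw
  for (i in seq_len(n)) {
    win <- raw[max(1, i - k + 1):i]
    tab <- table(as.character(win))
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) win[match(top, as.character(win))] else raw[i]
  }
  out
}
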