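#' Concatenate the arithmetic-task trials of selected blocks
#'
#' Baseline trials are omitted from analysis: the classified stream is the
#' chronological concatenation of the easy/difficult trials of the chosen
#' blocks.  Returns the concatenated recording and a trial table on the
#' concatenated clock.
#'
#' @param recording the full-session [eeg_recording()].
#' @param truth session trial table (from [simulate_session()]).
#' @param blocks block ids to keep (e.g. the chronologically first two).
#' @return List with `recording` and `truth`.
#' @export
concat_task_trials <- function(recording, truth, blocks) {
  tr <- truth[truth$block %in% blocks & truth$kind %in% c("easy", "difficult"), ,
              drop = FALSE]
  tr <- tr[order(tr$start_s), , drop = FALSE]
  stop_if_not(nrow(tr) > 0, sprintf("no task trials in blocks %s",
                                    paste(blocks, collapse = ",")),
              class = "passivebci_data_error")
  pieces <- lapply(seq_len(nrow(tr)), function(i)
    crop_recording(recording, tr$start_s[i], tr$end_s[i])$data)
  X <- do.call(cbind, pieces)
  dur <- tr$end_s - tr$start_s
  new_start <- cumsum(c(0, dur[-length(dur)]))
  tr$start_s <- new_start
  tr$end_s <- new_start + dur
  list(recording = eeg_recording(X, recording$fs_hz, recording$channel_labels),
       truth = tr)
}

#' Prepare one subject's session for classification
#'
#' Runs the full subject-level preparation: estimate the individual alpha
#' frequency from the opening eyes-closed baseline, band-pass and resample
#' the session, calibrate ASR on the training blocks' eyes-open baseline
#' trials, split the four task blocks chronologically (first R + first S
#' block for training, final two for testing), concatenate their task
#' trials, and epoch both streams into the two feature subsets.
#'
#' @param session list with `recording` and `truth` from
#'   [simulate_session()] (or equivalent real data).
#' @param cutoff_k ASR threshold multiplier; `NULL` disables ASR.
#' @param target_fs analysis sampling rate (default 256).
#' @param win_s,step_s epoching parameters (defaults 4 and 2).
#' @param log_power classify on `log10` band power (default `TRUE`; band
#'   power is approximately log-normal, and the log brings the features
#'   close to the Gaussian assumption of the discriminant).
#' @param keep_raw which concatenated raw streams to retain in the
#'   result (`"test"` is needed for online simulation; source subjects
#'   in cross-subject paradigms need none, and dropping them bounds
#'   memory on session-length data).
#' @return A `subject_features` list: `iaf`, `scheme`, `asr`, and for
#'   `train`/`test` each a list with `all63` and `workload49` feature
#'   matrices, labels, step times, plus (per `keep_raw`) the raw
#'   concatenated recording for online simulation.
#' @export
prepare_subject <- function(session, cutoff_k = 20, target_fs = 256,
                            win_s = 4, step_s = 2, log_power = TRUE,
                            keep_raw = "test") {
  rec <- session$recording
  truth <- session$truth
  closed <- truth[truth$kind == "eyes_closed_baseline", ]
  baseline <- crop_recording(rec, closed$start_s[1], closed$end_s[1])
  baseline <- resample_recording(bandpass_filter(baseline), target_fs)
  iaf <- estimate_iaf(baseline)
  scheme <- make_bands(as.numeric(iaf))

  blocks <- unique(truth$block[truth$kind %in% c("easy", "difficult")])
  train_blocks <- blocks[1:2]
  test_blocks <- blocks[3:4]

  asr <- NULL
  if (!is.null(cutoff_k)) {
    bl <- truth[truth$block %in% train_blocks & truth$kind == "eyes_open_baseline", ]
    calib <- do.call(cbind, lapply(seq_len(nrow(bl)), function(i)
      crop_recording(rec, bl$start_s[i], bl$end_s[i])$data))
    calib <- eeg_recording(calib, rec$fs_hz, rec$channel_labels)
    calib <- resample_recording(bandpass_filter(calib), target_fs)
    asr <- asr_calibrate(calib, cutoff_k = cutoff_k)
  }

  prep_stream <- function(blocks, keep) {
    ct <- concat_task_trials(rec, truth, blocks)
    proc <- resample_recording(bandpass_filter(ct$recording), target_fs)
    ep <- epoch_features(proc, ct$truth, scheme, subset = "all63",
                         win_s = win_s, step_s = step_s, asr = asr)
    motor_cols <- grepl(paste0("^(", paste(motor_channels(), collapse = "|"), ")\\."),
                        colnames(ep$features))
    if (log_power) ep$features <- log10(ep$features + 1e-12)
    list(all63 = ep$features,
         workload49 = ep$features[, !motor_cols, drop = FALSE],
         workload = ep$workload, affect = ep$affect,
         time_s = ep$time_s, n_steps = length(ep$workload),
         raw = if (keep) ct$recording else NULL, truth = ct$truth)
  }
  out <- list(iaf = as.numeric(iaf), iaf_fallback = isTRUE(attr(iaf, "fallback")),
              scheme = scheme, asr = asr,
              train = prep_stream(train_blocks, "train" %in% keep_raw),
              test = prep_stream(test_blocks, "test" %in% keep_raw),
              win_s = win_s, step_s = step_s, target_fs = target_fs,
              log_power = log_power)
  class(out) <- "subject_features"
  out
}

task_features <- function(stream, task) {
  if (task == "workload") stream$workload49 else stream$all63
}

task_positive <- function(task) {
  if (task == "workload") "difficult" else "stressed"
}

#' Run one classification paradigm for one target subject
#'
#' The three paradigms share the chronological split (the target's first
#' R and S blocks train, the final two test):
#' `subject_specific` fits the stratified shrinkage-LDA ensemble on the
#' target's training epochs only; `cross_subject` additionally pools every
#' epoch from all other subjects; `cross_subject_tl` gives each of the
#' three voters its own InstanceEasyTL run on the stratum-filtered source
#' and target-training data.  The test stream is then classified
#' chronologically, one prediction per step, raw and 3-sample smoothed.
#'
#' @param paradigm `"subject_specific"`, `"cross_subject"` or
#'   `"cross_subject_tl"`.
#' @param task `"workload"` or `"affect"`.
#' @param target a `subject_features` (the test subject).
#' @param sources list of `subject_features` for the other subjects
#'   (cross-subject paradigms; their train and test epochs are all
#'   source data).
#' @param N,seed InstanceEasyTL settings (TL paradigm only).
#' @param gamma fixed LDA shrinkage, or `NULL` for analytic.
#' @return List with `stream` (a data frame: step time, truth, raw and
#'   smoothed predictions) and `scores` (accuracy % and F1, raw and
#'   smoothed).
#' @export
run_paradigm <- function(paradigm = c("subject_specific", "cross_subject",
                                      "cross_subject_tl"),
                         task = c("workload", "affect"),
                         target, sources = list(), N = 20, seed = 1,
                         gamma = NULL) {
  paradigm <- match.arg(paradigm)
  task <- match.arg(task)
  stop_if_not(paradigm == "subject_specific" || length(sources) > 0,
              "cross-subject paradigms need source subjects",
              class = "passivebci_data_error")
  tr <- target$train
  Xtd <- task_features(tr, task)
  S <- task_features(target$test, task)

  source_pool <- function() {
    feats <- do.call(rbind, unlist(lapply(sources, function(s)
      list(task_features(s$train, task), task_features(s$test, task))),
      recursive = FALSE))
    wl <- unlist(lapply(sources, function(s) c(s$train$workload, s$test$workload)))
    af <- unlist(lapply(sources, function(s) c(s$train$affect, s$test$affect)))
    list(features = feats, workload = wl, affect = af)
  }

  training_set <- switch(paradigm,
    subject_specific = list(features = Xtd, workload = tr$workload,
                            affect = tr$affect),
    {
      sp <- source_pool()
      list(features = rbind(Xtd, sp$features),
           workload = c(tr$workload, sp$workload),
           affect = c(tr$affect, sp$affect))
    })

  if (paradigm == "cross_subject_tl") {
    sp <- source_pool()
    strat_src <- if (task == "workload") sp$affect else sp$workload
    strat_td <- if (task == "workload") tr$affect else tr$workload
    y_src <- if (task == "workload") sp$workload else sp$affect
    y_td <- if (task == "workload") tr$workload else tr$affect
    trainer <- function(features, labels, stratum) {
      keep <- if (stratum == "both") rep(TRUE, length(y_src)) else strat_src == stratum
      split <- domain_split(
        Tsd = list(features = sp$features[keep, , drop = FALSE],
                   labels = y_src[keep]),
        Ttd = list(features = features, labels = labels),
        S = S)
      instance_easytl(split, N = N, seed = seed)
    }
    ens <- ensemble_fit(task, list(features = Xtd, workload = tr$workload,
                                   affect = tr$affect), trainer = trainer)
  } else {
    ens <- ensemble_fit(task, training_set,
                        trainer = function(features, labels, stratum)
                          rlda_fit(features, labels, gamma = gamma))
  }

  raw <- if (paradigm == "cross_subject_tl") {
    # each voter's final boosted hypothesis on S (computed transductively
    # inside InstanceEasyTL); majority vote across the three voters
    votes <- vapply(ens$voters, function(v) v$labels_S, character(nrow(S)))
    pos <- ens$levels[2]
    ifelse(rowSums(matrix(votes == pos, ncol = 3)) * 2 > 3, pos, ens$levels[1])
  } else {
    predict(ens, S)
  }
  smoothed <- sliding_vote(raw, 3)
  truth_lab <- if (task == "workload") target$test$workload else target$test$affect
  stream <- data.frame(step_time_s = target$test$time_s, truth = truth_lab,
                       raw = raw, smoothed = smoothed,
                       stringsAsFactors = FALSE)
  pos <- task_positive(task)
  list(stream = stream, ensemble = ens,
       scores = data.frame(
         paradigm = paradigm, task = task,
         acc_raw = score(raw, truth_lab, pos)$accuracy,
         f1_raw = score(raw, truth_lab, pos)$f1,
         acc_smoothed = score(smoothed, truth_lab, pos)$accuracy,
         f1_smoothed = score(smoothed, truth_lab, pos)$f1,
         stringsAsFactors = FALSE))
}

#' Accuracy and F1 of a prediction stream
#'
#' @param pred,truth aligned label vectors.
#' @param positive the positive class for F1 (difficult / stressed).
#' @return List with `accuracy` (percent) and `f1`.
#' @export
score <- function(pred, truth, positive) {
  stop_if_not(length(pred) == length(truth),
              "prediction and truth streams differ in length",
              class = "passivebci_alignment_error")
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = 100 * mean(pred == truth), f1 = f1)
}

#' Exact binomial chance threshold
#'
#' Smallest accuracy that a binomial test at level `alpha` declares above
#' chance: the minimal `k` with `P(X >= k) <= alpha` for
#' `X ~ Binomial(n, p)`, reported as `100 k / n` rounded to 0.1 (the
#' exact `k` is attached as an attribute).
#'
#' @param n number of classified samples.
#' @param p chance success probability (0.5 for balanced binary).
#' @param alpha significance level.
#' @return Threshold accuracy in percent with attribute `k`.
#' @export
binomial_threshold <- function(n, p = 0.5, alpha = 0.05) {
  stop_if_not(n >= 1 && p > 0 && p < 1 && alpha > 0 && alpha <= 1,
              "invalid binomial test parameters",
              class = "passivebci_parameter_error")
  tails <- stats::pbinom(0:n - 1, n, p, lower.tail = FALSE)  # P(X >= k)
  k <- (0:n)[which(tails <= alpha)[1]]
  structure(round(100 * k / n, 1), k = k)
}

#' Simulate strictly online classification of a test stream
#'
#' Streams the raw test recording chronologically (4 s windows, one per
#' 2 s step) and, for each step, preprocesses only that window (band-pass,
#' resample, ASR), extracts both feature subsets, and predicts both states
#' with the fitted ensembles, logging per-stage wall time.  No sample
#' beyond the current window's end is ever touched, so predictions for
#' step t are unchanged by truncating the recording after t.
#'
#' @param recording raw concatenated test-stream [eeg_recording()].
#' @param models list with fitted `workload` and/or `affect` ensembles
#'   (or any object with a predict method over the matching subset).
#' @param scheme the target subject's `band_scheme`.
#' @param asr optional `asr_model` at `target_fs`.
#' @param truth trial table on the stream clock (for per-step labels).
#' @param win_s,step_s,target_fs streaming parameters.
#' @param log_power must match the transform the models were trained on
#'   (default `TRUE`, as in [prepare_subject()]).
#' @return List with `stream` (per-step times, truth and raw/smoothed
#'   predictions per task) and `latency_s` (one row per step: preprocess,
#'   features, classify).
#' @export
simulate_online <- function(recording, models, scheme, asr = NULL,
                            truth = NULL, win_s = 4, step_s = 2,
                            target_fs = 256, log_power = TRUE) {
  sw <- stream_windows(recording, win_s, step_s)
  n <- sw$n_steps
  pred <- list(workload = character(n), affect = character(n))
  lat <- matrix(0, n, 3, dimnames = list(NULL, c("preprocess", "features", "classify")))
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    w <- preprocess_window(sw$get_window(i), recording$fs_hz, asr,
                           target_fs = target_fs,
                           labels = recording$channel_labels)
    t1 <- proc.time()[["elapsed"]]
    f_all <- extract_features(w, scheme, "all63", target_fs, log_power = log_power)
    f_wl <- extract_features(w, scheme, "workload49", target_fs, log_power = log_power)
    t2 <- proc.time()[["elapsed"]]
    if (!is.null(models$workload))
      pred$workload[i] <- predict(models$workload, matrix(f_wl, 1))
    if (!is.null(models$affect))
      pred$affect[i] <- predict(models$affect, matrix(f_all, 1))
    t3 <- proc.time()[["elapsed"]]
    lat[i, ] <- c(t1 - t0, t2 - t1, t3 - t2)
  }
  stream <- data.frame(step_index = seq_len(n), step_time_s = sw$step_times_s)
  if (!is.null(truth)) {
    lab <- function(col) vapply(sw$step_times_s, function(tend) {
      tr <- truth[truth$start_s < tend & truth$end_s >= tend, , drop = FALSE]
      if (nrow(tr)) tr[[col]][1] else "none"
    }, "")
    stream$truth_workload <- lab("kind")
    stream$truth_affect <- lab("affect")
  }
  if (!is.null(models$workload)) {
    stream$workload_raw <- pred$workload
    stream$workload_smoothed <- sliding_vote(pred$workload, 3)
  }
  if (!is.null(models$affect)) {
    stream$affect_raw <- pred$affect
    stream$affect_smoothed <- sliding_vote(pred$affect, 3)
  }
  list(stream = stream, latency_s = as.data.frame(lat))
}

#' Summarize per-subject paradigm scores
#'
#' Binds per-subject score rows and appends mean and sample-sd summary
#' rows per paradigm and task (a single subject yields sd 0, flagged).
#'
#' @param rows data frames as produced in `run_paradigm()$scores`, each
#'   with a `subject` column added.
#' @return An `eval_report` data frame.
#' @export
report <- function(rows) {
  stop_if_not(length(rows) >= 1, "report needs at least one row")
  tab <- do.call(rbind, rows)
  metrics <- intersect(c("acc_raw", "f1_raw", "acc_smoothed", "f1_smoothed"),
                       names(tab))
  summaries <- lapply(split(tab, list(tab$paradigm, tab$task), drop = TRUE),
    function(g) {
      mrow <- g[1, , drop = FALSE]
      mrow$subject <- "mean"
      srow <- g[1, , drop = FALSE]
      srow$subject <- if (nrow(g) > 1) "sd" else "sd (single subject)"
      for (m in metrics) {
        mrow[[m]] <- mean(g[[m]])
        srow[[m]] <- if (nrow(g) > 1) stats::sd(g[[m]]) else 0
      }
      rbind(mrow, srow)
    })
  out <- rbind(tab, do.call(rbind, summaries))
  rownames(out) <- NULL
  class(out) <- c("eval_report", class(out))
  out
}
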