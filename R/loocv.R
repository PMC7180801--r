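# Pairing pipeline (trial -> aligned normalized waveform pair) and the
# leave-one-subject-out cross-validation harness.

#' Compute the aligned, normalized waveform pair of one trial
#'
#' Runs the full preprocessing chain on a [trial_record()]: skeleton-model and
#' marker-model angle waveforms, resampling of both onto the common 300 Hz
#' grid, cross-correlation synchronization, zero-lag low-pass filtering
#' (applied identically to both systems), and 101-point time normalization.
#'
#' @param trial a [trial_record()].
#' @param sync_channel synchronization channel (default `"EFE"`).
#' @param fc low-pass cut-off in Hz (default 6).
#' @param target_hz common grid rate (default 300).
#' @return list with normalized waveforms `input` (skeleton, model Phi) and
#'   `target` (gold standard, model Gamma), plus the synchronization `lag`.
#' @export
prepare_trial_pair <- function(trial, sync_channel = "EFE", fc = 6,
                               target_hz = 300) {
  stopifnot(inherits(trial, "trial_record"))
  kphi <- kinematics_kinect(trial$kinect_stream)
  kgam <- kinematics_uwa(trial)
  kphi <- resample_waveform(kphi, target_hz)
  kgam <- resample_waveform(kgam, target_hz)
  sync <- synchronize_waveforms(kgam, kphi, channel = sync_channel)
  kgam <- lowpass_zero_lag(sync$a, fc = fc)
  kphi <- lowpass_zero_lag(sync$b, fc = fc)
  input <- time_normalize(kphi)
  target <- time_normalize(kgam)
  for (nm in c("task", "subject_id", "trial_id")) {
    input[[nm]] <- trial[[nm]]
    target[[nm]] <- trial[[nm]]
  }
  input$source <- "kinect"; target$source <- "uwa"
  list(input = input, target = target, lag = sync$lag,
       subject_id = trial$subject_id, task = trial$task,
       trial_id = trial$trial_id)
}

#' Prepare all pairs of a corpus
#'
#' @param corpus list of [trial_record()]s.
#' @param task optional task filter.
#' @param ... passed to [prepare_trial_pair()].
#' @return list of pairs (see [prepare_trial_pair()]).
#' @export
prepare_corpus_pairs <- function(corpus, task = NULL, ...) {
  if (!is.null(task)) {
    task <- match.arg(task, TASKS)
    corpus <- Filter(function(tr) tr$task == task, corpus)
  }
  if (length(corpus) == 0) stop("no trials to prepare", call. = FALSE)
  lapply(corpus, prepare_trial_pair, ...)
}

#' Leave-one-subject-out cross-validation of the refinement network
#'
#' For each subject: fit the channel scaler and train one network on all
#' remaining subjects' trials of the task, then refine the held-out subject's
#' skeleton waveforms. Subject leakage is structurally impossible (the fold's
#' training set and scaler never see the held-out subject) and is additionally
#' asserted.
#'
#' @param corpus list of [trial_record()]s (or pre-computed pairs from
#'   [prepare_corpus_pairs()], each carrying `subject_id`).
#' @param task task to validate (required when `corpus` holds several).
#' @param seed integer; fold f trains with seed `seed + f`.
#' @param epochs,batch_size,lr training hyperparameters (paper defaults).
#' @param verbose print fold progress.
#' @return list of fold results, one per subject: held-out `subject_id`,
#'   `model`, and per-trial lists `input`, `target`, `refined` plus per-channel
#'   `rmse_before` / `rmse_after` matrices (trials x channels, degrees).
#' @export
loocv_refine <- function(corpus, task = NULL, seed = 1, epochs = 200,
                         batch_size = 20, lr = 0.006, verbose = FALSE) {
  pairs <- if (length(corpus) > 0 && inherits(corpus[[1]], "trial_record")) {
    prepare_corpus_pairs(corpus, task = task)
  } else {
    if (!is.null(task)) Filter(function(p) p$task == task, corpus) else corpus
  }
  subjects <- unique(vapply(pairs, `[[`, "", "subject_id"))
  if (length(subjects) < 3) {
    stop("leave-one-subject-out validation needs at least 3 subjects",
         call. = FALSE)
  }
  folds <- vector("list", length(subjects))
  for (f in seq_along(subjects)) {
    held <- subjects[f]
    train_pairs <- Filter(function(p) p$subject_id != held, pairs)
    test_pairs <- Filter(function(p) p$subject_id == held, pairs)
    test_pairs <- lapply(test_pairs, function(p) {
      for (nm in c("subject_id", "task", "trial_id")) {
        p$input[[nm]] <- p[[nm]]
        p$target[[nm]] <- p[[nm]]
      }
      p
    })
    if (any(vapply(train_pairs, `[[`, "", "subject_id") == held)) {
      stop("subject leakage detected in fold ", f, call. = FALSE)
    }
    model <- train_refine_model(train_pairs, epochs = epochs,
                                batch_size = batch_size, lr = lr,
                                seed = seed + f,
                                task = test_pairs[[1]]$task)
    refined <- lapply(test_pairs, function(p) refine_waveform(model, p$input))
    rmse_tab <- function(get) {
      t(vapply(seq_along(test_pairs), function(i) {
        vapply(ANGLE_CHANNELS, function(ch) {
          rmse(get(i)$values[, ch], test_pairs[[i]]$target$values[, ch])
        }, numeric(1))
      }, numeric(4)))
    }
    rmse_before <- rmse_tab(function(i) test_pairs[[i]]$input)
    rmse_after <- rmse_tab(function(i) refined[[i]])
    colnames(rmse_before) <- colnames(rmse_after) <- ANGLE_CHANNELS
    if (verbose) {
      message(sprintf("fold %d/%d (subject %s): mean RMSE %.2f -> %.2f deg",
                      f, length(subjects), held, mean(rmse_before),
                      mean(rmse_after)))
    }
    folds[[f]] <- structure(list(subject_id = held, model = model,
                                 input = lapply(test_pairs, `[[`, "input"),
                                 target = lapply(test_pairs, `[[`, "target"),
                                 refined = refined,
                                 rmse_before = rmse_before,
                                 rmse_after = rmse_after),
                            class = "loocv_fold")
  }
  folds
}

#' @export
print.loocv_fold <- function(x, ...) {
  cat(sprintf("<loocv_fold> held-out subject %s, %d trial(s)\n",
              x$subject_id, length(x$refined)))
  cat(" mean RMSE before/after (deg):",
      sprintf("%.2f/%.2f", mean(x$rmse_before), mean(x$rmse_after)), "\n")
  invisible(x)
}
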