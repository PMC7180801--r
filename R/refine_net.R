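# The refinement network N: a 3-layer LSTM (hidden size 100) mapping the
# normalized 101 x 4 skeleton waveform onto the gold-standard waveform, with
# a time-distributed linear output head. Training uses mean squared error and
# Adam; all randomness (weight init, batch shuffling) is drawn from R's RNG so
# a seed fully determines the run.

LSTM_LAYERS <- 3L
LSTM_HIDDEN <- 100L
SEQ_LEN <- 101L

# Uniform fan-in initialization, U(-1/sqrt(H), 1/sqrt(H)) for every LSTM
# parameter (the standard recurrent-network scheme); the forget-gate bias is
# raised to +1 so early gradients flow through the stacked layers.
init_lstm_weights <- function(n_in = 4L, n_out = 4L, hidden = LSTM_HIDDEN,
                              layers = LSTM_LAYERS) {
  k <- 1 / sqrt(hidden)
  rmat <- function(r, c) matrix(stats::runif(r * c, -k, k), r, c)
  lay <- vector("list", layers)
  for (l in seq_len(layers)) {
    nin <- if (l == 1) n_in else hidden
    b <- stats::runif(4 * hidden, -k, k)
    b[(hidden + 1):(2 * hidden)] <- 1  # forget gate
    lay[[l]] <- list(W = rmat(4 * hidden, nin), U = rmat(4 * hidden, hidden),
                     b = b)
  }
  list(layers = lay, V = rmat(n_out, hidden), d = rep(0, n_out))
}

# Stack a list of normalized waveforms into an (N, 4, 101 + warmup) array.
# `warmup` replicas of the first sample are prepended so the recurrent state
# can settle before the scored part of the sequence; the corresponding
# outputs are discarded at inference.
stack_waveforms <- function(wfs, warmup = 0L) {
  for (w in wfs) {
    if (!w$normalized || nrow(w$values) != SEQ_LEN) {
      stop("all waveforms must be time-normalized to 101 samples", call. = FALSE)
    }
  }
  arr <- array(NA_real_, dim = c(length(wfs), 4L, SEQ_LEN + warmup))
  for (i in seq_along(wfs)) {
    v <- wfs[[i]]$values
    if (warmup > 0) {
      v <- rbind(matrix(v[1, ], warmup, 4L, byrow = TRUE), v)
    }
    arr[i, , ] <- t(v)
  }
  arr
}

#' Train the LSTM refinement network
#'
#' Trains the 3-layer, 100-unit LSTM on paired (skeleton, gold-standard)
#' waveforms. Both sides must be time-normalized to 101 samples; the scaler is
#' fitted here on the pooled training waveforms of both systems and stored in
#' the model. Training minimizes the mean squared error on the unit-interval
#' scale with Adam (batch size 20, learning rate 0.006, 200 epochs by
#' default). Given a seed, training is deterministic.
#'
#' @param pairs list of `list(input = , target = )` pairs of normalized
#'   [angle_waveform()]s (degrees).
#' @param epochs,batch_size,lr training hyperparameters.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param scaler optionally a pre-fitted [fit_scaler()]; by default fitted on
#'   the pooled inputs and targets of `pairs`.
#' @param warmup number of replicated lead-in samples prepended to every
#'   sequence so the recurrent state settles before the movement; the
#'   corresponding outputs are discarded at inference (default 10).
#' @param task optional task tag stored in the model.
#' @param verbose print the loss every 25 epochs.
#' @return object of class `refine_model`.
#' @export
train_refine_model <- function(pairs, epochs = 200, batch_size = 20,
                               lr = 0.006, seed = 1, scaler = NULL,
                               task = NULL, warmup = 10L, verbose = FALSE) {
  if (length(pairs) < 2) stop("need at least 2 training pairs", call. = FALSE)
  inputs <- lapply(pairs, `[[`, "input")
  targets <- lapply(pairs, `[[`, "target")
  if (is.null(scaler)) scaler <- fit_scaler(c(inputs, targets))
  xs <- lapply(inputs, function(w) apply_scaler(scaler, w))
  ys <- lapply(targets, function(w) apply_scaler(scaler, w))
  warmup <- as.integer(warmup)
  X <- stack_waveforms(xs, warmup)
  Y <- stack_waveforms(ys, warmup)
  n <- length(pairs)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  weights <- init_lstm_weights()
  order <- t(vapply(seq_len(epochs), function(e) sample.int(n), integer(n)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  fit <- cpp_lstm_train(X, Y, weights, as.integer(epochs),
                        as.integer(batch_size), lr,
                        matrix(as.integer(order), nrow = epochs))
  loss <- as.numeric(fit$loss)
  # moving-average non-increase check on well-posed corpora
  if (epochs >= 20) {
    ma <- stats::filter(loss, rep(1 / 10, 10), sides = 1)
    ma <- ma[!is.na(ma)]
    if (length(ma) > 1 && ma[length(ma)] > ma[1]) {
      warning("training loss did not decrease in moving average; ",
              "the corpus may be ill-posed or the learning rate too high")
    }
  }
  if (verbose) {
    message(sprintf("final training MSE (unit scale): %.3g", loss[epochs]))
  }
  structure(list(weights = fit$weights, scaler = scaler, task = task,
                 hidden = LSTM_HIDDEN, layers = LSTM_LAYERS, warmup = warmup,
                 meta = list(epochs = epochs, batch_size = batch_size,
                             lr = lr, seed = seed,
                             final_loss = loss[epochs], n_pairs = n),
                 loss = loss),
            class = "refine_model")
}

#' @export
print.refine_model <- function(x, ...) {
  cat(sprintf(paste0("<refine_model> %d-layer LSTM, %d units%s\n",
                     "  trained %d epochs on %d pairs, final MSE %.3g\n"),
              x$layers, x$hidden,
              if (!is.null(x$task)) paste0(", task ", x$task) else "",
              x$meta$epochs, x$meta$n_pairs, x$meta$final_loss))
  invisible(x)
}

#' Refine a skeleton angle waveform
#'
#' Applies the trained network: scale to the unit interval, run the LSTM,
#' invert the scaling. Input and output are normalized 101 x 4 waveforms in
#' degrees.
#'
#' @param model a [train_refine_model()] result.
#' @param wf normalized [angle_waveform()] (degrees).
#' @return refined [angle_waveform()] (`source = "refined"`).
#' @export
refine_waveform <- function(model, wf) {
  stopifnot(inherits(model, "refine_model"))
  if (!wf$normalized || nrow(wf$values) != SEQ_LEN) {
    stop("refine_waveform needs a 101-sample normalized waveform", call. = FALSE)
  }
  if (!is.null(model$task) && !is.null(wf$task) &&
      !identical(model$task, wf$task)) {
    warning("waveform task (", wf$task, ") does not match the model's (",
            model$task, ")")
  }
  warmup <- if (is.null(model$warmup)) 0L else model$warmup
  x <- apply_scaler(model$scaler, wf)
  X <- stack_waveforms(list(x), warmup)
  Yp <- cpp_lstm_predict(X, model$weights)
  out <- wf_with_values(wf, t(Yp[1, , warmup + seq_len(SEQ_LEN)]))
  out <- invert_scaler(model$scaler, out)
  out$source <- "refined"
  validate_angle_waveform(out)
  out
}

#' Save / load a refinement model
#'
#' Serializes weights, scaler and metadata to one JSON document (text, so the
#' archive travels with plain-text repositories).
#'
#' @param model a `refine_model`; `path` file path.
#' @return `path` / the restored model.
#' @export
write_refine_model <- function(model, path) {
  doc <- list(layers = lapply(model$weights$layers, function(l) {
                list(W = l$W, U = l$U, b = l$b)
              }),
              V = model$weights$V, d = model$weights$d,
              scaler = list(min = model$scaler$min, max = model$scaler$max),
              task = model$task, warmup = model$warmup, meta = model$meta)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_refine_model
#' @export
read_refine_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  weights <- list(layers = lapply(doc$layers, function(l) {
    list(W = as.matrix(l$W), U = as.matrix(l$U), b = as.numeric(l$b))
  }), V = as.matrix(doc$V), d = as.numeric(doc$d))
  scaler <- structure(list(min = stats::setNames(as.numeric(doc$scaler$min), ANGLE_CHANNELS),
                           max = stats::setNames(as.numeric(doc$scaler$max), ANGLE_CHANNELS)),
                      class = "channel_scaler")
  structure(list(weights = weights, scaler = scaler, task = doc$task,
                 hidden = LSTM_HIDDEN, layers = LSTM_LAYERS,
                 warmup = if (is.null(doc$warmup)) 0L else as.integer(doc$warmup),
                 meta = doc$meta, loss = NULL),
            class = "refine_model")
}
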