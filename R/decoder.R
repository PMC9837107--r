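## Downsampling and the biLSTM waveform decoder.

#' Anti-aliased downsampling
#'
#' Zero-phase low-pass (96-tap FIR applied forward and backward) with
#' cutoff at 0.4 times the new sampling rate, then decimation; output
#' length is `ceiling(N / factor)`.
#'
#' @param series numeric vector
#' @param factor integer decimation factor (default 10, i.e. 1000 -> 100 Hz)
#' @return decimated numeric vector
#' @export
downsample <- function(series, factor = 10) {
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  if (factor == 1) return(series)
  if (length(series) <= 97)
    stop("series too short for the anti-aliasing filter warm-up")
  fir <- signal::fir1(96, 0.8 / factor, type = "low")
  fir <- fir / sum(fir)                    # exact unit DC gain
  y <- zp_filtfilt(fir, series, pad = 3 * 97)
  y[seq(1, length(y), by = factor)]
}

#' Decoder architecture specification
#'
#' The experiment-scale architecture is 4 stacked biLSTM layers of 250
#' hidden units per direction ([full_decoder_spec()]); the default here is
#' a desk-scale variant (1 layer, 32 units) that trains in seconds.
#'
#' @param input_dim number of feature rows
#' @param n_bilstm_layers stacked biLSTM layers (default 1)
#' @param hidden_units hidden units per direction (default 32)
#' @param epochs training epochs (default 15)
#' @param learning_rate Adam learning rate (default 1e-3)
#' @param clip global gradient-norm clip (default 1)
#' @param chunk_s training sequence chunk length in seconds (default 10)
#' @param seed seed for weight initialisation
#' @return a `decoder_spec`
#' @export
decoder_spec <- function(input_dim, n_bilstm_layers = 1, hidden_units = 32,
                         epochs = 15, learning_rate = 1e-3, clip = 1,
                         chunk_s = 10, seed = 1) {
  if (input_dim < 1) stop("input_dim must be positive")
  if (n_bilstm_layers < 1) stop("need at least one biLSTM layer")
  structure(list(input_dim = as.integer(input_dim),
                 n_bilstm_layers = as.integer(n_bilstm_layers),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, clip = clip,
                 chunk_s = chunk_s, seed = seed),
            class = "decoder_spec")
}

#' @rdname decoder_spec
#' @export
full_decoder_spec <- function(input_dim, ...) {
  decoder_spec(input_dim, n_bilstm_layers = 4, hidden_units = 250, ...)
}

## uniform initialisation, scaled by fan-in; forget-gate bias starts at 1
init_weights <- function(spec) {
  H <- spec$hidden_units
  mk <- function(r, c) matrix(stats::runif(r * c, -1, 1) / sqrt(c), r, c)
  layers <- vector("list", spec$n_bilstm_layers)
  din <- spec$input_dim
  for (l in seq_len(spec$n_bilstm_layers)) {
    b0 <- rep(0, 4 * H); b0[(H + 1):(2 * H)] <- 1
    layers[[l]] <- list(Wf = mk(4 * H, din), Uf = mk(4 * H, H), bf = b0,
                        Wb = mk(4 * H, din), Ub = mk(4 * H, H), bb = b0)
    din <- 2 * H
  }
  list(layers = layers, w_out = stats::runif(2 * H, -1, 1) / sqrt(2 * H),
       b_out = 0)
}

## split a (rows x T) sequence into chunks of chunk_len steps; short tails
## below min_len are folded into the previous chunk
chunk_sequence <- function(T_len, chunk_len, min_len = chunk_len %/% 4) {
  if (T_len <= chunk_len) return(list(seq_len(T_len)))
  starts <- seq(1L, T_len, by = chunk_len)
  idx <- lapply(starts, function(s) s:min(s + chunk_len - 1L, T_len))
  n <- length(idx)
  if (n > 1 && length(idx[[n]]) < min_len) {
    idx[[n - 1]] <- c(idx[[n - 1]], idx[[n]])
    idx[[n]] <- NULL
  }
  idx
}

#' Fit a bidirectional LSTM sequence regressor
#'
#' Trains a stacked biLSTM with a linear read-out on one or more
#' feature-sequence / target-sequence pairs by minimising the per-step mean
#' squared error (Adam, gradient clipping, chunked backpropagation through
#' time). Deterministic for a fixed spec seed.
#'
#' @param x list of feature matrices (rows x time), or a single matrix
#' @param y list of numeric target vectors matching `x` in length
#' @param spec a [decoder_spec()]
#' @return a fitted `bilstm` object with `weights`, `loss_curve`, `spec`
#' @export
bilstm <- function(x, y, spec) {
  if (is.matrix(x)) { x <- list(x); y <- list(y) }
  stopifnot(length(x) == length(y))
  for (i in seq_along(x)) {
    if (nrow(x[[i]]) != spec$input_dim)
      stop("sequence ", i, " has ", nrow(x[[i]]), " rows; spec expects ",
           spec$input_dim)
    if (ncol(x[[i]]) != length(y[[i]]))
      stop("sequence ", i, ": feature and target lengths differ")
  }
  w0 <- with_seed(spec$seed, init_weights(spec))
  fit <- cpp_bilstm_train(w0, x, y, spec$epochs, spec$learning_rate, spec$clip)
  if (isTRUE(fit$diverged))
    stop("biLSTM training diverged (non-finite loss)")
  structure(list(weights = fit$weights, loss_curve = as.numeric(fit$loss_curve),
                 spec = spec),
            class = "bilstm")
}

#' @export
print.bilstm <- function(x, ...) {
  s <- x$spec
  cat("biLSTM decoder: ", s$n_bilstm_layers, " layer(s) x ", s$hidden_units,
      " units/direction, input ", s$input_dim, " rows\n", sep = "")
  cat("  final training MSE: ",
      signif(utils::tail(x$loss_curve, 1), 4), " after ", s$epochs,
      " epochs\n", sep = "")
  invisible(x)
}

#' @export
coef.bilstm <- function(object, ...) object$weights

#' Reconstruct a waveform from features
#'
#' One scalar output per input time step; deterministic given the trained
#' weights.
#'
#' @param object a fitted `bilstm`
#' @param newdata feature matrix (rows x time) matching the model's input_dim
#' @param ... unused
#' @return numeric vector of length `ncol(newdata)`
#' @export
predict.bilstm <- function(object, newdata, ...) {
  if (nrow(newdata) != object$spec$input_dim)
    stop("newdata has ", nrow(newdata), " rows; model expects ",
         object$spec$input_dim)
  as.numeric(cpp_bilstm_forward(object$weights, newdata))
}

#' @rdname predict.bilstm
#' @param model a fitted `bilstm`
#' @param features feature matrix (rows x time)
#' @export
reconstruct <- function(model, features) predict(model, features)

#' Run-wise cross-validation fold plan
#'
#' One fold per run; each run is the test set exactly once.
#'
#' @param runs vector of run labels
#' @return a `fold_plan`: list of `(train, test)` run sets
#' @export
fold_plan <- function(runs) {
  runs <- sort(unique(runs))
  if (length(runs) < 2) stop("need at least two runs for cross-validation")
  folds <- lapply(runs, function(r) list(train = setdiff(runs, r), test = r))
  structure(list(folds = folds, scheme = paste0(length(runs), "-fold run-wise")),
            class = "fold_plan")
}

#' Train the decoder in the run-wise cross-fold scheme
#'
#' For each fold, a fresh biLSTM is trained on the concatenated music-trial
#' sequences of the training runs (targets z-scored per run) and used to
#' reconstruct every music trial of the held-out run. No test-run sample
#' ever enters training.
#'
#' @param trials list of music-trial records, each a list with `features`
#'   (rows x time), `target` (numeric), `trial_id`, `run`, `piece_id`
#' @param spec a [decoder_spec()]
#' @param plan a [fold_plan()] over the runs present in `trials`
#' @param fs feature/target sampling rate in Hz (default 100), used to turn
#'   `spec$chunk_s` into samples
#' @return a `decoder_result`: list with `models` (one `bilstm` per fold,
#'   `NULL` for aborted folds), `reconstructions` (per-trial records with
#'   `yhat`, `fold`), `plan`
#' @export
train_decoder <- function(trials, spec, plan, fs = 100) {
  runs <- vapply(trials, `[[`, 0, "run")
  recs <- list(); models <- vector("list", length(plan$folds))
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    stopifnot(length(intersect(fold$train, fold$test)) == 0)
    tr_idx <- which(runs %in% fold$train)
    te_idx <- which(runs %in% fold$test)
    if (!length(tr_idx) || !length(te_idx))
      stop("fold ", fi, ": empty train or test set")

    xs <- list(); ys <- list()
    for (r in fold$train) {
      ridx <- which(runs == r)
      tcat <- unlist(lapply(trials[ridx], `[[`, "target"))
      mu <- mean(tcat); sdv <- stats::sd(tcat)
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      for (i in ridx) {
        z <- (trials[[i]]$target - mu) / sdv
        ch <- chunk_sequence(length(z), round(spec$chunk_s * fs))
        for (cc in ch) {
          xs[[length(xs) + 1]] <- trials[[i]]$features[, cc, drop = FALSE]
          ys[[length(ys) + 1]] <- z[cc]
        }
      }
    }
    model <- tryCatch(bilstm(xs, ys, spec), error = function(e) {
      warning("fold ", fi, " aborted: ", conditionMessage(e))
      NULL
    })
    models[[fi]] <- model
    if (is.null(model)) next
    for (i in te_idx) {
      rec <- trials[[i]]
      rec$yhat <- predict(model, rec$features)
      rec$fold <- fi
      rec$features <- NULL
      recs[[length(recs) + 1]] <- rec
    }
  }
  structure(list(models = models, reconstructions = recs, plan = plan),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  ok <- sum(!vapply(x$models, is.null, TRUE))
  cat("Decoder result: ", ok, "/", length(x$models), " folds trained, ",
      length(x$reconstructions), " trials reconstructed (",
      x$plan$scheme, ")\n", sep = "")
  invisible(x)
}
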