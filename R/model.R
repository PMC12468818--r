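#' Model configuration
#'
#' Architecture of the sequence classifier: a stack of bidirectional GRU
#' layers over the Log-Mel frame sequence, temporal mean pooling of the
#' per-frame hidden states into one utterance vector, dropout, and a linear
#' classification head with softmax output.
#'
#' @param input_size Feature dimension per frame (number of Mel bands).
#' @param hidden_size Hidden units per GRU direction.
#' @param num_layers Number of stacked bidirectional GRU layers.
#' @param bidirectional Run the recurrence in both time directions and
#'   concatenate.
#' @param dropout_p Dropout probability, applied between recurrent layers and
#'   on the pooled vector before the head (training mode only).
#' @param n_classes Number of output classes (2 for the binary tasks, 3 for
#'   pain intensity).
#' @return A `model_config` list.
#' @export
model_config <- function(input_size = 64L, hidden_size = 64L, num_layers = 3L,
                         bidirectional = TRUE, dropout_p = 0.5,
                         n_classes = 2L) {
  stopifnot(input_size >= 1, hidden_size >= 1, num_layers >= 1,
            dropout_p >= 0, dropout_p < 1, n_classes >= 2)
  structure(list(
    input_size = as.integer(input_size), hidden_size = as.integer(hidden_size),
    num_layers = as.integer(num_layers), bidirectional = isTRUE(bidirectional),
    dropout_p = dropout_p, n_classes = as.integer(n_classes)
  ), class = "model_config")
}

.init_gru_cell <- function(input_size, hidden_size) {
  s <- 1 / sqrt(hidden_size)
  m <- function(r, c) matrix(stats::runif(r * c, -s, s), r, c)
  v <- function(r) stats::runif(r, -s, s)
  list(W_z = m(hidden_size, input_size), U_z = m(hidden_size, hidden_size),
       b_z = v(hidden_size),
       W_r = m(hidden_size, input_size), U_r = m(hidden_size, hidden_size),
       b_r = v(hidden_size),
       W_h = m(hidden_size, input_size), U_h = m(hidden_size, hidden_size),
       b_h = v(hidden_size))
}

#' Initialize model parameters
#'
#' All weights are drawn uniformly from `[-1/sqrt(H), 1/sqrt(H)]` with a
#' seeded generator, so identical `(config, seed)` give identical parameters.
#' Layer 1 takes `input_size` features; deeper layers take the concatenated
#' bidirectional output (`2 * hidden_size`) of the layer below.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A `model_params` list: `layers` (per layer, `fwd`/`bwd` GRU cell
#'   parameter sets), `head` (`W`, `b`), `config`, `seed`.
#' @export
model_init <- function(config = model_config(), seed = 0L) {
  dirs <- if (config$bidirectional) c("fwd", "bwd") else "fwd"
  width <- config$hidden_size * length(dirs)
  params <- with_seed(seed, {
    layers <- lapply(seq_len(config$num_layers), function(l) {
      in_size <- if (l == 1L) config$input_size else width
      stats::setNames(lapply(dirs, function(d) {
        .init_gru_cell(in_size, config$hidden_size)
      }), dirs)
    })
    s <- 1 / sqrt(config$hidden_size)
    head <- list(
      W = matrix(stats::runif(config$n_classes * width, -s, s),
                 config$n_classes, width),
      b = stats::runif(config$n_classes, -s, s)
    )
    list(layers = layers, head = head)
  })
  structure(c(params, list(config = config, seed = as.integer(seed))),
            class = "model_params")
}

#' One GRU cell update
#'
#' The gated update for a single time step and a single sequence:
#' \deqn{z = \sigma(W_z x + U_z h + b_z)}
#' \deqn{r = \sigma(W_r x + U_r h + b_r)}
#' \deqn{\tilde h = \tanh(W_h x + U_h (r \odot h) + b_h)}
#' \deqn{h' = (1 - z) \odot h + z \odot \tilde h}
#'
#' @param x_t Input vector at time t.
#' @param h_prev Previous hidden state.
#' @param p GRU cell parameter list (`W_z, U_z, b_z, W_r, U_r, b_r, W_h,
#'   U_h, b_h`).
#' @return The updated hidden state, same length as `h_prev`.
#' @export
gru_cell_step <- function(x_t, h_prev, p) {
  if (length(x_t) != ncol(p$W_z) || length(h_prev) != ncol(p$U_z)) {
    stop("gru_cell_step: input/hidden sizes do not match parameters",
         call. = FALSE)
  }
  z <- .sigmoid(drop(p$W_z %*% x_t) + drop(p$U_z %*% h_prev) + p$b_z)
  r <- .sigmoid(drop(p$W_r %*% x_t) + drop(p$U_r %*% h_prev) + p$b_r)
  h_tilde <- tanh(drop(p$W_h %*% x_t) + drop(p$U_h %*% (r * h_prev)) + p$b_h)
  (1 - z) * h_prev + z * h_tilde
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Bidirectional GRU layer over one sequence
#'
#' Runs the forward recurrence `t = 1..T` and the backward recurrence
#' `t = T..1`, both from zero initial state, and concatenates the two hidden
#' sequences per step, giving a `T x 2H` output.
#'
#' @param X `T x input` matrix (one row per time step).
#' @param fwd,bwd GRU cell parameters for the forward and backward direction.
#' @return `T x 2H` matrix; row t is `[h_fwd_t ; h_bwd_t]`.
#' @export
run_layer_bidirectional <- function(X, fwd, bwd) {
  if (!is.matrix(X) || nrow(X) < 1) {
    stop("input sequence must be a non-empty matrix", call. = FALSE)
  }
  T_len <- nrow(X)
  H <- length(fwd$b_z)
  out <- matrix(0, T_len, 2 * H)
  h <- numeric(H)
  for (t in seq_len(T_len)) {
    h <- gru_cell_step(X[t, ], h, fwd)
    out[t, seq_len(H)] <- h
  }
  h <- numeric(H)
  for (t in rev(seq_len(T_len))) {
    h <- gru_cell_step(X[t, ], h, bwd)
    out[t, H + seq_len(H)] <- h
  }
  out
}

#' Encode a frame sequence through the GRU stack
#'
#' Applies the stacked (bi)directional GRU layers in order, with inverted
#' dropout between layers when `training = TRUE`. Evaluation mode is fully
#' deterministic.
#'
#' @param X `T x input_size` feature matrix (e.g. `logmel()$values`).
#' @param params A [model_init()] parameter set.
#' @param training Apply inter-layer dropout?
#' @return `T x 2H` matrix of top-layer hidden states.
#' @export
encode <- function(X, params, training = FALSE) {
  cfg <- params$config
  if (ncol(X) != cfg$input_size) {
    stop(sprintf("input width %d does not match model input_size %d",
                 ncol(X), cfg$input_size), call. = FALSE)
  }
  out <- X
  for (l in seq_along(params$layers)) {
    layer <- params$layers[[l]]
    out <- if (cfg$bidirectional) {
      run_layer_bidirectional(out, layer$fwd, layer$bwd)
    } else {
      run_layer_bidirectional(out, layer$fwd, layer$fwd)[, seq_len(cfg$hidden_size),
                                                         drop = FALSE]
    }
    if (training && cfg$dropout_p > 0 && l < length(params$layers)) {
      mask <- matrix(stats::rbinom(length(out), 1, 1 - cfg$dropout_p),
                     nrow(out)) / (1 - cfg$dropout_p)
      out <- out * mask
    }
  }
  out
}

#' Temporal mean pooling
#'
#' Collapses the per-frame hidden sequence to a single utterance embedding by
#' averaging over time (equivalently, adaptive average pooling to output
#' size 1).
#'
#' @param H_seq `T x D` matrix of per-frame vectors.
#' @return Numeric vector of length `D`.
#' @export
temporal_mean_pool <- function(H_seq) {
  if (!is.matrix(H_seq) || nrow(H_seq) < 1) {
    stop("temporal_mean_pool needs a non-empty matrix", call. = FALSE)
  }
  colMeans(H_seq)
}

#' Linear classification head
#'
#' `o = W h + b`, with inverted dropout on `h` first when `training = TRUE`.
#'
#' @param h_bar Pooled utterance vector.
#' @param head List with `W` (`n_classes x D`) and `b`.
#' @param training Apply dropout to `h_bar`?
#' @param dropout_p Dropout probability used in training mode.
#' @return Logit vector of length `n_classes`.
#' @export
head_logits <- function(h_bar, head, training = FALSE, dropout_p = 0) {
  if (length(h_bar) != ncol(head$W)) {
    stop("pooled vector length does not match head width", call. = FALSE)
  }
  if (training && dropout_p > 0) {
    mask <- stats::rbinom(length(h_bar), 1, 1 - dropout_p) / (1 - dropout_p)
    h_bar <- h_bar * mask
  }
  drop(head$W %*% h_bar) + head$b
}

#' Softmax probabilities and predicted class
#'
#' Numerically stable softmax over the logits; the predicted label is the
#' argmax, with ties broken toward the lowest class index.
#'
#' @param o Finite logit vector.
#' @return List with `probabilities` (sums to 1) and `label` (1-based class
#'   index).
#' @export
predict_class <- function(o) {
  if (any(!is.finite(o))) stop("logits must be finite", call. = FALSE)
  p <- softmax(o)
  list(probabilities = p, label = which.max(p))
}

#' @rdname predict_class
#' @export
softmax <- function(o) {
  e <- exp(o - max(o))
  e / sum(e)
}

#' Classify one audio clip end-to-end
#'
#' Composition of the full pipeline: standardize the waveform
#' ([preprocess()]), extract Log-Mel features ([logmel()]), encode through
#' the GRU stack, mean-pool over time, apply the head, and take the softmax.
#' Runs in evaluation mode (no dropout), so the output is deterministic.
#'
#' @param clip A [waveform()] (any rate/length/channels).
#' @param params A [model_init()] parameter set (typically trained).
#' @param preproc A [preproc_config()].
#' @param spec A [spectrogram_config()].
#' @return List with `probabilities` and `label` as in [predict_class()].
#' @export
model_forward <- function(clip, params, preproc = preproc_config(),
                          spec = spectrogram_config()) {
  x <- preprocess(clip, preproc)
  feats <- logmel(x, spec)$values
  h <- encode(feats, params, training = FALSE)
  o <- head_logits(temporal_mean_pool(h), params$head)
  predict_class(o)
}

#' Evaluate a scoped expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so library calls do not perturb user randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  expr
}
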