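# Shared fixtures, all generated in code at test time.

# Small, fast synthetic corpus settings: short clips, few speakers.
small_synth_config <- function(seed = 11, ...) {
  synth_config(n_speakers = 6, clips_per_speaker = 8,
               duration_mean = 0.8, duration_sd = 0.1, seed = seed, ...)
}

# One small corpus on disk, built once per test run.
small_corpus_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "pv_small_corpus")
      if (!file.exists(file.path(dir, "metadata.csv"))) {
        synth_corpus(small_synth_config(), dir)
      }
      cache <<- dir
    }
    cache
  }
})

small_corpus <- function() {
  read_corpus(file.path(small_corpus_dir(), "metadata.csv"))
}

# A tiny model for structural tests.
tiny_model <- function(input_size = 3, hidden_size = 2, num_layers = 1,
                       n_classes = 2, dropout_p = 0, seed = 1) {
  model_init(model_config(input_size = input_size, hidden_size = hidden_size,
                          num_layers = num_layers, dropout_p = dropout_p,
                          n_classes = n_classes), seed = seed)
}

# Independent scalar-loop evaluation of the GRU cell update: explicit sums,
# no matrix algebra, used as the equation-level oracle.
gru_cell_scalar_oracle <- function(x, h, p) {
  Hn <- length(h)
  sig <- function(v) 1 / (1 + exp(-v))
  h_new <- numeric(Hn)
  r <- numeric(Hn); z <- numeric(Hn)
  for (i in seq_len(Hn)) {
    az <- p$b_z[i]; ar <- p$b_r[i]
    for (j in seq_along(x)) {
      az <- az + p$W_z[i, j] * x[j]
      ar <- ar + p$W_r[i, j] * x[j]
    }
    for (j in seq_len(Hn)) {
      az <- az + p$U_z[i, j] * h[j]
      ar <- ar + p$U_r[i, j] * h[j]
    }
    z[i] <- sig(az); r[i] <- sig(ar)
  }
  for (i in seq_len(Hn)) {
    ac <- p$b_h[i]
    for (j in seq_along(x)) ac <- ac + p$W_h[i, j] * x[j]
    for (j in seq_len(Hn)) ac <- ac + p$U_h[i, j] * (r[j] * h[j])
    h_new[i] <- (1 - z[i]) * h[i] + z[i] * tanh(ac)
  }
  h_new
}

random_cell_params <- function(input_size, hidden_size) {
  m <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.5), r, c)
  list(W_z = m(hidden_size, input_size), U_z = m(hidden_size, hidden_size),
       b_z = stats::rnorm(hidden_size, sd = 0.5),
       W_r = m(hidden_size, input_size), U_r = m(hidden_size, hidden_size),
       b_r = stats::rnorm(hidden_size, sd = 0.5),
       W_h = m(hidden_size, input_size), U_h = m(hidden_size, hidden_size),
       b_h = stats::rnorm(hidden_size, sd = 0.5))
}

# Random tiny labelled dataset of feature matrices for optimizer tests.
random_dataset <- function(n, T_len = 5, F_dim = 4, n_classes = 2,
                           seed = 123) {
  set.seed(seed)
  list(x = lapply(seq_len(n), function(i) matrix(rnorm(T_len * F_dim),
                                                 T_len, F_dim)),
       y = sample(seq_len(n_classes), n, replace = TRUE))
}
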