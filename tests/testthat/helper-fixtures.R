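# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small protocol-shaped subject with ground truth (4 trials, ~200 s)
demo_subject <- function() {
  fixture("demo_subject", function() {
    cfg <- synth_config(n_subjects = 1,
                        protocol = list(eo_s = 20, rest_s = 10, ec_s = 20,
                                        n_trials = 4),
                        seed = 42)
    generate_subject(cfg, 1)
  })
}

# the same subject preprocessed, plus its alpha power series
demo_pipeline <- function() {
  fixture("demo_pipeline", function() {
    sub <- demo_subject()
    cfg <- load_config()
    pp <- preprocess_recording(sub$recording, cfg)
    ps <- alpha_power_series(pp$recording, pp$mask, cfg)
    list(subject = sub, pp = pp, ps = ps, cfg = cfg)
  })
}

# well-separated synthetic sequence dataset: EC power ~3x the EO mean
separable_seqs <- function(n_per_class = 60, n_w = 16, seed = 7) {
  with_seed(seed, {
    mk <- function(mu) lapply(seq_len(n_per_class), function(i)
      cbind(p_o1 = stats::rlnorm(n_w, mu, 0.3),
            p_o2 = stats::rlnorm(n_w, mu, 0.3)))
    seqs <- c(mk(log(2)), mk(log(6)))
    structure(list(
      sequences = seqs,
      labels = factor(rep(c("EO", "EC"), each = n_per_class),
                      levels = c("EO", "EC")),
      provenance = data.frame(subject = "T", segment = 1,
                              end_index = seq_along(seqs),
                              end_time = seq_along(seqs)),
      n_w = n_w, window_s = n_w / 16, hop = 1L, fs_power = 16),
      class = "seq_dataset")
  })
}

# logical-state power series built directly (no signal processing)
toy_power_series <- function(p_o1, p_o2 = p_o1, labels,
                             states = labels, fs_power = 16) {
  structure(list(times = (seq_along(p_o1) - 1) / fs_power,
                 p_o1 = p_o1, p_o2 = p_o2,
                 labels = labels, states = states, fs_power = fs_power),
            class = "power_series")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# naive R recurrence oracle for the LSTM forward pass
naive_lstm_probs <- function(model, sequence) {
  x_seq <- sequence
  for (l in seq_along(model$layers)) {
    par <- model$layers[[l]]
    H <- length(par$b) / 4
    h <- rep(0, H); c <- rep(0, H)
    hs <- matrix(0, nrow(x_seq), H)
    for (t in seq_len(nrow(x_seq))) {
      st <- lstm_cell_step(x_seq[t, ], h, c, par)
      h <- st$h; c <- st$c
      hs[t, ] <- h
    }
    x_seq <- hs
  }
  a <- drop(model$dense$W %*% h) + model$dense$b
  e <- exp(a - max(a))
  e / sum(e)
}

random_lstm_model <- function(layers = 1, cells = 3, input_dim = 2) {
  lay <- vector("list", layers)
  d <- input_dim
  for (l in seq_len(layers)) {
    lay[[l]] <- list(W = matrix(stats::rnorm(4 * cells * (cells + d)),
                                4 * cells, cells + d),
                     b = stats::rnorm(4 * cells))
    d <- cells
  }
  structure(list(layers = lay,
                 dense = list(W = matrix(stats::rnorm(2 * cells), 2, cells),
                              b = stats::rnorm(2)),
                 n_layers = layers, cells = cells, n_w = NA, window_s = NA,
                 fs_power = 16, loss = NA, classes = c("EO", "EC")),
            class = "winbci_lstm")
}
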