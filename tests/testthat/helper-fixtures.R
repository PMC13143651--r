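# Fixtures built in code: small random networks and desk-scale cohorts.

# A randomly initialized survival net (no training) with the package's
# parameter layout; `scale` widens the weights so activations and
# hazards leave the near-linear regime.
random_net <- function(p, width = 6, n_blocks = 2, J = 4, seed = 1,
                       scale = 2, zero_bias = FALSE) {
  params <- survattrib:::init_params(p, width, n_blocks, J, seed)
  params$W <- lapply(params$W, function(w) scale * w)
  if (!zero_bias) {
    params$b <- survattrib:::with_seed(survattrib::child_seed(seed, 99L), {
      lapply(params$b, function(b) stats::rnorm(length(b), sd = 0.3))
    })
  }
  ids <- sprintf("g%03d", seq_len(p))
  structure(list(params = params,
                 time_grid = structure(list(bin_edges = as.numeric(0:J),
                                            n_bins = as.integer(J)),
                                       class = "time_grid"),
                 feature_names = ids,
                 training_mean = stats::setNames(rep(0, p), ids),
                 selected_checkpoint = "best_loss",
                 config = survattrib::training_config()),
            class = "survival_net")
}

# A bias-free stack of linear layers ending in a scalar output.
random_linear_stack <- function(p, widths = c(5, 3), seed = 1) {
  dims <- c(p, widths, 1)
  layers <- survattrib:::with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      list(type = "linear",
           W = matrix(stats::rnorm(dims[l] * dims[l + 1]), dims[l], dims[l + 1]),
           b = rep(0, dims[l + 1]))
    })
  })
  survattrib:::new_net_stack(layers)
}

# Small quickly-trainable configuration used across tests.
small_training_config <- function(seed = 1, max_epochs = 60, ...) {
  training_config(hidden_width = 32, n_snn_blocks = 2,
                  max_epochs = max_epochs, seed = seed, ...)
}

named_matrix <- function(data, n, p, prefix = "g") {
  matrix(data, n, p, dimnames = list(NULL, sprintf("%s%03d", prefix, seq_len(p))))
}
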