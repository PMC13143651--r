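# Survival network: variance filter, time grid, forward pass, loss,
# curves, risk, concordance, gradients, and the training protocol.

test_that("variance filter keeps the highest-variance genes in order", {
  X <- named_matrix(0, 10, 3)
  set.seed(1)
  X[, 1] <- rnorm(10, sd = 2)   # var ~ 4
  X[, 2] <- rnorm(10, sd = 1)   # var ~ 1
  X[, 3] <- rnorm(10, sd = 3)   # var ~ 9
  kept <- variance_filter(X, 2)
  expect_identical(colnames(kept), c("g001", "g003"))

  expect_identical(variance_filter(X, 3), X)
  expect_error(variance_filter(X, 4), "configuration error")

  Xc <- cbind(X[, c(1, 3)], const = rep(5, 10))
  expect_false("const" %in% colnames(variance_filter(Xc, 2)))
})

test_that("variance ties break lexicographically by gene id", {
  X <- matrix(c(1, -1, 1, -1, 1, -1, 2, -2), 2, 4,
              dimnames = list(NULL, c("d", "b", "c", "a")))
  # d, b, c share variance 2; a has variance 8
  expect_identical(colnames(variance_filter(X, 2)), c("b", "a"))
})

test_that("time grid edges sit at event-time quantiles", {
  g <- make_time_grid(1:100, rep(1, 100), n_bins = 4)
  expect_equal(g$bin_edges[2:4],
               unname(quantile(1:100, c(0.25, 0.5, 0.75))))
  expect_equal(g$bin_edges[1], 0)
  expect_equal(g$bin_edges[5], 100)

  g2 <- make_time_grid(c(1, 3), c(1, 1), n_bins = 2)
  expect_equal(g2$bin_edges, c(0, 2, 3))

  gd <- make_time_grid(rep(4, 10), rep(1, 10), n_bins = 6)
  expect_equal(gd$n_bins, 1L)
  expect_equal(gd$bin_edges, c(0, 4))

  expect_error(make_time_grid(1:5, rep(0, 5), 3), "degenerate")
})

test_that("discretization maps times into (edge_j, edge_{j+1}]", {
  g <- structure(list(bin_edges = c(0, 2, 5, 10), n_bins = 3L),
                 class = "time_grid")
  expect_identical(discretize_times(g, c(0.5, 2, 2.1, 5, 9, 10, 12)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
})

test_that("forward pass yields hazards in (0,1) and honors zero heads", {
  net <- random_net(p = 5, J = 3, seed = 2)
  X <- named_matrix(rnorm(20 * 5), 20, 5)
  h <- predict(net, X, type = "hazard")
  expect_true(all(h > 0 & h < 1))
  expect_identical(h, predict(net, X, type = "hazard"))  # eval mode deterministic

  net0 <- net
  net0$params$W[[3]] <- net0$params$W[[3]] * 0
  net0$params$b[[3]] <- net0$params$b[[3]] * 0
  expect_equal(unname(predict(net0, X, type = "hazard")),
               matrix(0.5, 20, 3))
})

test_that("discrete-hazard NLL matches hand-evaluated cases", {
  expect_equal(nll_loss(matrix(0.5, 1, 3), bin = 1L, event = 1L), log(2))
  expect_equal(nll_loss(matrix(0.5, 1, 3), bin = 2L, event = 0L), 2 * log(2))
  h_perfect <- matrix(c(1e-9, 1e-9, 1 - 1e-9), 1, 3)
  expect_lt(nll_loss(h_perfect, bin = 3L, event = 1L), 1e-5)
})

test_that("survival curve and risk follow their closed forms", {
  S <- survival_curve(matrix(c(0.5, 0.5), 1, 2))
  expect_equal(unname(S), matrix(c(0.5, 0.25), 1, 2))

  h <- matrix(runif(40, 0.05, 0.95), 8, 5)
  Sm <- survival_curve(h)
  expect_true(all(Sm[, -1] <= Sm[, -5]))
  expect_true(all(Sm > 0 & Sm < 1))
  expect_lt(max(abs(survival_curve(matrix(1e-9, 4, 6)) - 1)), 1e-6)

  expect_equal(risk_score(matrix(c(1.0, 0.8, 0.5), 1, 3)), -2.3)
  # dominance: elementwise-higher survival means strictly lower risk
  SA <- matrix(c(0.9, 0.8, 0.7), 1, 3)
  SB <- matrix(c(0.9, 0.6, 0.5), 1, 3)
  expect_lt(risk_score(SA), risk_score(SB))
  # J bins of perfect survival approach the -J lower bound
  expect_equal(risk_score(matrix(1 - 1e-12, 1, 7)), -7, tolerance = 1e-9)
})

test_that("concordance index handles the documented cases", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_equal(concordance_index(c(3, 1, 2), c(1, 2, 3), c(1, 1, 0)), 2 / 3)
  expect_error(concordance_index(c(1, 2), c(5, 5), c(1, 1)), "degenerate")
})

test_that("concordance index agrees with the brute-force enumerator", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    time <- sample(1:8, n, replace = TRUE)       # heavy ties
    event <- rbinom(n, 1, 0.7)
    risk <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # tied risks
    expected <- brute_cindex(risk, time, event)
    if (is.na(expected)) {
      expect_error(concordance_index(risk, time, event), "degenerate")
    } else {
      expect_identical(concordance_index(risk, time, event), expected)
    }
  }
})

test_that("analytic loss gradients match finite differences", {
  net <- random_net(p = 4, width = 5, n_blocks = 2, J = 3, seed = 6)
  X <- named_matrix(rnorm(6 * 4), 6, 4)
  bin <- c(1L, 2L, 3L, 1L, 2L, 3L)
  event <- c(1L, 0L, 1L, 0L, 1L, 1L)

  loss_at <- function(params) {
    survattrib:::nll_loss(
      survattrib:::snn_forward(params, X)$h, bin, event)
  }
  fw <- survattrib:::snn_forward(net$params, X)
  d_logits <- survattrib:::nll_logit_gradient(fw$h, bin, event)
  grads <- survattrib:::snn_backward(net$params, fw, d_logits)

  eps <- 1e-6
  for (l in c(1, 3)) {
    for (idx in list(c(1, 1), c(2, 3))) {
      pp <- net$params
      pp$W[[l]][idx[1], idx[2]] <- pp$W[[l]][idx[1], idx[2]] + eps
      pm <- net$params
      pm$W[[l]][idx[1], idx[2]] <- pm$W[[l]][idx[1], idx[2]] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- grads$gW[[l]][idx[1], idx[2]]
      expect_lt(abs(num - ana) / max(abs(num), 1e-8), 1e-4)
    }
  }
})

test_that("training respects min_epochs, patience and determinism", {
  cfg <- synthetic_config(n_samples = 120, n_genes = 15, n_blocks = 3,
                          n_prognostic = 2, seed = 12)
  coh <- generate_cohort(cfg)
  # patience 1 forces the earliest possible stop; warmup 2 + min 15 must
  # still be honored even when the validation loss stalls immediately
  tc <- training_config(hidden_width = 8, n_snn_blocks = 2, warmup_epochs = 2,
                        min_epochs = 15, patience = 1, max_epochs = 60,
                        seed = 4)
  net <- train_survival_net(coh$expression, coh$survival, tc)
  expect_gte(nrow(net$history), 15)

  net2 <- train_survival_net(coh$expression, coh$survival, tc)
  expect_identical(net$params, net2$params)
  expect_identical(net$selected_checkpoint, net2$selected_checkpoint)
})

test_that("the selected checkpoint is the best-C-index snapshot", {
  cfg <- synthetic_config(n_samples = 150, n_genes = 12, n_blocks = 3,
                          n_prognostic = 3, seed = 19)
  coh <- generate_cohort(cfg)
  net <- train_survival_net(coh$expression, coh$survival,
                            small_training_config(seed = 3, max_epochs = 30))
  expect_identical(net$selected_checkpoint, "best_cindex")
  expect_identical(net$params, net$checkpoint_best_cindex)
  expect_equal(net$best_val_cindex,
               max(net$history$val_cindex[-seq_len(net$config$warmup_epochs)],
                   na.rm = TRUE))
})

test_that("a strong planted gene is learned: held-out C-index above 0.6", {
  cfg <- synthetic_config(n_samples = 400, n_genes = 20, n_blocks = 4,
                          n_prognostic = 1, effect_size = 2, seed = 23)
  coh <- generate_cohort(cfg)
  train_idx <- 1:300
  test_idx <- 301:400
  net <- train_survival_net(coh$expression[train_idx, ],
                            coh$survival[train_idx, ],
                            small_training_config(seed = 7))
  ci <- concordance_index(predict(net, coh$expression[test_idx, ]),
                          coh$survival$time[test_idx],
                          coh$survival$event[test_idx])
  expect_gt(ci, 0.6)
})

test_that("activations neither explode nor vanish after training", {
  cfg <- synthetic_config(n_samples = 200, n_genes = 30, n_blocks = 6,
                          n_prognostic = 4, seed = 31)
  coh <- generate_cohort(cfg)
  net <- train_survival_net(coh$expression, coh$survival,
                            small_training_config(seed = 2))
  fw <- survattrib:::snn_forward(net$params, coh$expression)
  for (l in seq_along(fw$Z)) {
    v <- var(as.vector(fw$A[[l + 1]]))
    expect_gt(v, 0.1)
    expect_lt(v, 10)
  }
})

test_that("networks serialize to JSON and back without drift", {
  cfg <- synthetic_config(n_samples = 80, n_genes = 8, n_blocks = 2,
                          n_prognostic = 2, seed = 14)
  coh <- generate_cohort(cfg)
  net <- train_survival_net(coh$expression, coh$survival,
                            training_config(hidden_width = 6, n_snn_blocks = 2,
                                            max_epochs = 25, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_survival_net(net, path)
  back <- load_survival_net(path)
  expect_equal(back$params$W, net$params$W, ignore_attr = TRUE)
  expect_identical(back$selected_checkpoint, net$selected_checkpoint)
  expect_equal(predict(back, coh$expression[1:5, ]),
               predict(net, coh$expression[1:5, ]))
})
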