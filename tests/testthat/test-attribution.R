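# Attribution suite: references, explained output and gradient, the six
# methods with their closed-form and conservation identities,
# aggregation, and top-k selection.

test_that("reference input is the training-set column mean", {
  X <- named_matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(unname(reference_input(X)), c(1, 1))
  expect_equal(unname(reference_input(X[1, , drop = FALSE])), c(0, 2))
  Xs <- scale(named_matrix(rnorm(200), 20, 10))
  expect_lt(max(abs(reference_input(Xs))), 1e-8)
  expect_error(reference_input(X[0, , drop = FALSE]), "degenerate")
})

test_that("explained output is the composed risk and its gradient is exact", {
  net <- random_net(p = 6, J = 4, seed = 11)
  X <- named_matrix(rnorm(5 * 6), 5, 6)
  composed <- risk_score(survival_curve(predict(net, X, type = "hazard")))
  expect_equal(explained_output(net, X), composed)

  g <- explained_gradient(net, X)
  for (j in c(1, 4, 6)) {
    eps <- 1e-5
    Xp <- X; Xp[, j] <- Xp[, j] + eps
    Xm <- X; Xm[, j] <- Xm[, j] - eps
    num <- (explained_output(net, Xp) - explained_output(net, Xm)) / (2 * eps)
    expect_lt(max(abs(g[, j] - num) / pmax(abs(num), 1e-6)), 1e-3)
  }

  net0 <- random_net(p = 6, J = 4, seed = 11, scale = 0, zero_bias = TRUE)
  expect_equal(max(abs(explained_gradient(net0, X))), 0)
})

test_that("all path/propagation methods recover w (x - ref) on linear models", {
  set.seed(7)
  for (i in 1:5) {
    p <- sample(3:10, 1)
    w <- rnorm(p)
    names(w) <- sprintf("g%03d", seq_len(p))
    lin <- linear_model(w, b = rnorm(1))
    X <- named_matrix(rnorm(4 * p), 4, p)
    ref <- rnorm(p)
    expected <- sweep(X, 2, ref) * matrix(w, 4, p, byrow = TRUE)

    expect_equal(unclass(integrated_gradients(lin, X, ref, steps = 2)),
                 expected, ignore_attr = TRUE)
    expect_equal(unclass(deeplift_rescale(lin, X, ref)),
                 expected, ignore_attr = TRUE)
    bg <- matrix(ref, 1, p, dimnames = list(NULL, names(w)))
    expect_equal(unclass(deep_shap(lin, X, bg)), expected,
                 ignore_attr = TRUE)
    # epsilon-rule relevance measured against the zero reference
    lin0 <- linear_model(w, b = 0)
    expect_equal(unclass(lrp_epsilon(lin0, X, epsilon = 1e-10)),
                 X * matrix(w, 4, p, byrow = TRUE),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("integrated gradients vanish at the reference and converge to completeness", {
  net <- random_net(p = 8, J = 5, seed = 3)
  ref <- rnorm(8)
  names(ref) <- net$feature_names
  Xref <- matrix(ref, 3, 8, byrow = TRUE, dimnames = list(NULL, names(ref)))
  expect_equal(max(abs(integrated_gradients(net, Xref, ref, steps = 8))), 0)

  X <- named_matrix(rnorm(6 * 8), 6, 8)
  f <- explained_output(net, X)
  f0 <- explained_output(net, matrix(ref, 1, 8,
                                     dimnames = list(NULL, names(ref))))
  gap <- function(steps) {
    max(abs(rowSums(integrated_gradients(net, X, ref, steps = steps)) -
              (f - f0)) / abs(f - f0))
  }
  g64 <- gap(64)
  g1024 <- gap(1024)
  g8192 <- gap(8192)
  expect_lt(g1024, g64)
  expect_lt(g8192, g1024)
  expect_lt(g8192, 1e-3)
})

test_that("gradient SHAP matches the linear expectation and is seeded", {
  set.seed(5)
  p <- 6
  w <- rnorm(p)
  names(w) <- sprintf("g%03d", seq_len(p))
  lin <- linear_model(w)
  bg <- named_matrix(rnorm(50 * p), 50, p)
  X <- named_matrix(rnorm(2 * p), 2, p)

  gs <- gradient_shap(lin, X, bg, n_samples = 2000, noise_sd = 0, seed = 9)
  expected <- sweep(X, 2, colMeans(bg)) * matrix(w, 2, p, byrow = TRUE)
  # Monte-Carlo mean within 3 standard errors of the linear closed form
  draws_sd <- apply(bg, 2, sd) * abs(w) # background spread drives the MC noise
  se <- matrix(draws_sd / sqrt(2000), 2, p, byrow = TRUE)
  expect_true(all(abs(gs - expected) < 3 * se + 1e-12))

  expect_equal(max(abs(gradient_shap(lin, X, X[1, , drop = FALSE] [rep(1, 2), ],
                                     n_samples = 10, seed = 1)[1, ])), 0)
  expect_identical(gradient_shap(lin, X, bg, n_samples = 20, seed = 3),
                   gradient_shap(lin, X, bg, n_samples = 20, seed = 3))
})

test_that("DeepLIFT satisfies summation-to-delta on every random net", {
  for (seed in 1:20) {
    p <- 4 + (seed %% 4)
    net <- random_net(p = p, width = 5, n_blocks = 2, J = 3, seed = seed)
    X <- named_matrix(rnorm(4 * p), 4, p)
    ref <- rnorm(p)
    names(ref) <- net$feature_names
    a <- deeplift_rescale(net, X, ref)
    f <- explained_output(net, X)
    f0 <- explained_output(net, matrix(ref, 1, p,
                                       dimnames = list(NULL, names(ref))))
    expect_lt(max(abs(rowSums(a) - (f - f0)) / pmax(abs(f - f0), 1e-10)), 1e-5)
  }
  # x = reference gives exactly zero
  net <- random_net(p = 5, seed = 77)
  ref <- rnorm(5)
  names(ref) <- net$feature_names
  Xr <- matrix(ref, 2, 5, byrow = TRUE, dimnames = list(NULL, names(ref)))
  expect_equal(max(abs(deeplift_rescale(net, Xr, ref))), 0)
})

test_that("DeepSHAP degenerates to DeepLIFT and conserves in expectation", {
  net <- random_net(p = 7, J = 4, seed = 15)
  X <- named_matrix(rnorm(3 * 7), 3, 7)
  bg1 <- named_matrix(rnorm(7), 1, 7)
  expect_equal(unclass(deep_shap(net, X, bg1)),
               unclass(deeplift_rescale(net, X, bg1[1, ])),
               ignore_attr = TRUE)

  bg <- named_matrix(rnorm(12 * 7), 12, 7)
  ds <- deep_shap(net, X, bg)
  f <- explained_output(net, X)
  fb <- mean(explained_output(net, bg))
  expect_lt(max(abs(rowSums(ds) - (f - fb)) / pmax(abs(f - fb), 1e-10)), 1e-5)

  sub <- deep_shap(net, X, bg, background_max = 5, seed = 21)
  expect_identical(sub, deep_shap(net, X, bg, background_max = 5, seed = 21))
})

test_that("epsilon-LRP matches the hand-worked case and conserves without bias", {
  # single linear layer, x = (1, 2), w = (3, 1): z = 5, R = (3, 2)
  lin <- linear_model(c(a = 3, b = 1))
  R <- lrp_epsilon(lin, matrix(c(1, 2), 1, 2,
                               dimnames = list(NULL, c("a", "b"))))
  expect_equal(unclass(R), matrix(c(3, 2), 1, 2), tolerance = 1e-5,
               ignore_attr = TRUE)

  for (seed in 1:20) {
    stk <- random_linear_stack(p = 6, widths = c(5, 4), seed = seed)
    X <- named_matrix(rnorm(3 * 6), 3, 6)
    Rg <- survattrib:::lrp_epsilon(stk, X, epsilon = 1e-6)
    out <- survattrib:::stack_output(stk, X)
    expect_lt(max(abs(rowSums(Rg) - out) / abs(out)), 1e-4)
  }

  net <- random_net(p = 5, seed = 8)
  X0 <- named_matrix(0, 2, 5)
  expect_equal(max(abs(lrp_epsilon(net, X0))), 0)
  expect_error(lrp_epsilon(net, X0, epsilon = 0), "configuration error")
})

test_that("permutation importance finds dead and informative features", {
  # model that reads only the first gene
  cfg <- synthetic_config(n_samples = 500, n_genes = 4, n_blocks = 1,
                          n_prognostic = 1, effect_size = 1.5, seed = 41)
  X <- generate_expression(cfg)
  w <- c(2, 0, 0, 0)
  names(w) <- colnames(X)
  lin <- linear_model(w)
  truth <- make_ground_truth(cfg)
  truth$prognostic_gene_ids <- colnames(X)[1]
  truth$coefficients <- setNames(1.5, colnames(X)[1])
  surv <- generate_survival(X, truth, cfg)

  imp <- permutation_importance(lin, X, surv$time, surv$event,
                                repeats = 3, seed = 6)
  expect_equal(imp$score[imp$gene_id != colnames(X)[1]], rep(0, 3))
  base_c <- attr(imp, "baseline_cindex")
  expect_lt(abs(imp$score[imp$gene_id == colnames(X)[1]] - (base_c - 0.5)),
            0.05)
  expect_identical(imp,
                   permutation_importance(lin, X, surv$time, surv$event,
                                          repeats = 3, seed = 6))
})

test_that("duplicated collinear signals depress permutation importance", {
  # two identical copies of one signal vs an equally-coefficiented
  # unique signal: the model splits its reliance across the copies, so
  # permuting either copy alone hurts less than permuting the unique gene
  set.seed(13)
  n <- 400
  z <- rnorm(n)
  X <- cbind(dup1 = z, dup2 = z, uniq = rnorm(n), noise = rnorm(n))
  w <- c(dup1 = 0.75, dup2 = 0.75, uniq = 1.5, noise = 0)
  lin <- linear_model(w)
  eta <- as.vector(X %*% w)
  t_event <- rexp(n, rate = 0.1 * exp(eta))
  t_cens <- runif(n, 0, 32)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  imp <- permutation_importance(lin, X, time, event, repeats = 5, seed = 3)
  s <- setNames(imp$score, imp$gene_id)
  expect_lt(s[["dup1"]], s[["uniq"]])
  expect_lt(s[["dup2"]], s[["uniq"]])
})

test_that("global aggregation and top-k follow their documented rules", {
  A <- matrix(c(1, -1, 2, 2), 2, 2, dimnames = list(NULL, c("g1", "g2")))
  attr(A, "method") <- "deeplift"
  expect_equal(aggregate_global(A, "mean_abs")$score, c(1, 2))
  expect_equal(aggregate_global(A, "mean_signed")$score, c(0, 2))
  expect_equal(aggregate_global(A[2:1, ], "mean_abs")$score, c(1, 2))

  g <- data.frame(gene_id = c("a", "b", "c"), score = c(3, 1, 2))
  expect_identical(top_k(g, 2), c("a", "c"))
  expect_identical(top_k(g, 3), c("a", "c", "b"))  # all genes, by score
  expect_error(top_k(g, 4), "configuration error")
  tie <- data.frame(gene_id = c("b", "a"), score = c(1, 1))
  expect_identical(top_k(tie, 1), "a")
})

test_that("attribution methods are deterministic given net, input and seed", {
  net <- random_net(p = 6, seed = 5)
  X <- named_matrix(rnorm(4 * 6), 4, 6)
  bg <- named_matrix(rnorm(9 * 6), 9, 6)
  expect_identical(integrated_gradients(net, X, steps = 16),
                   integrated_gradients(net, X, steps = 16))
  expect_identical(lrp_epsilon(net, X), lrp_epsilon(net, X))
  expect_identical(deep_shap(net, X, bg), deep_shap(net, X, bg))
})
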