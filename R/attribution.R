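# The six post-hoc attribution algorithms, implemented against a layer
# stack abstraction: "linear" layers (weights + bias), elementwise
# "selu" nonlinearities, and a terminal "risk_head" mapping J logits
# through the logistic function to conditional hazards and on to the
# scalar risk -sum_j S_j. Dropout is identity at explanation time
# (evaluation mode). All methods attribute the risk scalar: it is the
# model's single continuous output and the quantity scored by the
# C-index.

# ---- layer stacks ----------------------------------------------------

new_net_stack <- function(layers) structure(list(layers = layers), class = "net_stack")

as_net_stack <- function(net, ...) UseMethod("as_net_stack")

#' @export
as_net_stack.net_stack <- function(net, ...) net

#' @export
as_net_stack.survival_net <- function(net, ...) {
  p <- net$params
  layers <- list()
  for (l in seq_len(p$n_blocks)) {
    layers[[length(layers) + 1]] <- list(type = "linear", W = p$W[[l]], b = p$b[[l]])
    layers[[length(layers) + 1]] <- list(type = "selu")
  }
  layers[[length(layers) + 1]] <- list(type = "linear",
                                       W = p$W[[p$n_blocks + 1]],
                                       b = p$b[[p$n_blocks + 1]])
  layers[[length(layers) + 1]] <- list(type = "risk_head")
  new_net_stack(layers)
}

#' A linear model usable with every attribution method
#'
#' `f(x) = w . x + b`, exposed through the same interface as the trained
#' survival network. The closed-form attributions of a linear model
#' (`w_g (x_g - ref_g)`) make it the canonical sanity check for the
#' gradient- and propagation-based methods.
#'
#' @param w coefficient vector (named or not).
#' @param b intercept.
#' @return an object of classes `linear_model` and `net_stack`.
#' @export
linear_model <- function(w, b = 0) {
  structure(list(layers = list(list(type = "linear",
                                    W = matrix(w, ncol = 1,
                                               dimnames = list(names(w), NULL)),
                                    b = b))),
            class = c("linear_model", "net_stack"))
}

# risk-head primitives on a hazard matrix ------------------------------

risk_from_logits <- function(z) {
  h <- stats::plogis(z)
  risk_score(survival_curve(h))
}

# reverse cumulative row sums: out[, l] = sum_{j >= l} x[, j]
rev_row_cumsum <- function(x) {
  J <- ncol(x)
  out <- x
  if (J > 1) for (j in (J - 1):1) out[, j] <- out[, j] + out[, j + 1]
  out
}

# gradient of risk w.r.t. the logits: d(-sum_j S_j)/dz_l = h_l * T_l with
# T_l = sum_{j >= l} S_j  (since dS_j/dh_l = -S_j/(1-h_l) for l <= j and
# dh/dz = h(1-h)).
risk_logit_gradient <- function(z) {
  h <- stats::plogis(z)
  S <- survival_curve(h)
  h * rev_row_cumsum(S)
}

# Full forward pass through a stack, keeping the input of every layer.
stack_forward <- function(stack, X) {
  acts <- vector("list", length(stack$layers) + 1)
  acts[[1]] <- X
  for (i in seq_along(stack$layers)) {
    ly <- stack$layers[[i]]
    acts[[i + 1]] <- switch(ly$type,
      linear = sweep(acts[[i]] %*% ly$W, 2, ly$b, "+"),
      selu = selu(acts[[i]]),
      risk_head = matrix(risk_from_logits(acts[[i]]), ncol = 1),
      stop("unsupported layer type: ", ly$type))
  }
  acts
}

stack_output <- function(stack, X) {
  out <- stack_forward(stack, X)[[length(stack$layers) + 1]]
  drop(out[, 1])
}

# Gradient of the scalar stack output w.r.t. the input matrix (n x p).
stack_input_gradient <- function(stack, X, acts = NULL) {
  if (is.null(acts)) acts <- stack_forward(stack, X)
  nl <- length(stack$layers)
  G <- matrix(1, nrow(X), 1)
  for (i in rev(seq_len(nl))) {
    ly <- stack$layers[[i]]
    G <- switch(ly$type,
      linear = G %*% t(ly$W),
      selu = G * selu_deriv(acts[[i]]),
      risk_head = as.vector(G) * risk_logit_gradient(acts[[i]]))
  }
  G
}

#' The scalar output every attribution method explains
#'
#' For a trained survival network this is
#' `risk_score(survival_curve(forward(net, x)))`; for a [linear_model()]
#' it is the linear output itself.
#'
#' @param net a `survival_net` or `linear_model`.
#' @param X one sample (vector) or a samples x genes matrix.
#' @return numeric vector of explained outputs, one per sample.
#' @export
explained_output <- function(net, X) {
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  stack_output(stack, X)
}

#' Gradient of the explained output with respect to the input
#'
#' @inheritParams explained_output
#' @return samples x genes matrix of partial derivatives.
#' @export
explained_gradient <- function(net, X) {
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  g <- stack_input_gradient(stack, X)
  dimnames(g) <- dimnames(X)
  g
}

align_stack_input <- function(net, X) {
  if (inherits(net, "survival_net")) return(align_features(net, X))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  X
}

#' Attribution reference: the training-set mean
#'
#' @param X_train non-empty training expression matrix.
#' @return column-wise mean vector.
#' @export
reference_input <- function(X_train) {
  if (is.null(dim(X_train)) || nrow(X_train) == 0) {
    stop("degenerate input: empty training matrix")
  }
  colMeans(X_train)
}

default_reference <- function(net, reference) {
  if (!is.null(reference)) return(reference)
  if (inherits(net, "survival_net") && !is.null(net$training_mean)) {
    return(net$training_mean)
  }
  stop("a reference input is required")
}

new_attribution <- function(scores, X, method) {
  dimnames(scores) <- dimnames(X)
  structure(scores, method = method, explained = "risk")
}

# ---- gradient-based methods ------------------------------------------

#' Integrated Gradients
#'
#' Path integral of the output gradient from the reference (by default
#' the training-set mean) to each explained sample:
#' `a_g = (x_g - ref_g) * mean_alpha df/dx_g(ref + alpha (x - ref))`,
#' approximated on a trapezoidal alpha grid over `[0, 1]`.
#'
#' @param net a `survival_net` or `linear_model`.
#' @param X samples x genes matrix to explain.
#' @param reference baseline vector; defaults to the training mean stored
#'   in the network.
#' @param steps number of integration steps (>= 2).
#' @return samples x genes attribution matrix (attribute `method`).
#' @export
integrated_gradients <- function(net, X, reference = NULL, steps = 50) {
  if (steps < 2) stop("configuration error: steps must be >= 2")
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  ref <- default_reference(net, reference)
  D <- sweep(X, 2, ref)
  R <- matrix(ref, nrow(X), ncol(X), byrow = TRUE)
  w <- c(0.5, rep(1, steps - 1), 0.5) / steps
  acc <- matrix(0, nrow(X), ncol(X))
  for (m in 0:steps) {
    acc <- acc + w[m + 1] * stack_input_gradient(stack, R + (m / steps) * D)
  }
  new_attribution(D * acc, X, "integrated_gradients")
}

#' GradientSHAP: expected gradients over a background distribution
#'
#' Shapley-value approximation by expected gradients: for each draw, a
#' background sample `b`, a path position `alpha ~ U(0,1)` and optional
#' gaussian smoothing noise are sampled, and
#' `(x_g - b_g) * df/dx_g(b + alpha (x - b) + noise)` is averaged over
#' draws.
#'
#' @inheritParams integrated_gradients
#' @param background matrix of background (training) samples.
#' @param n_samples Monte-Carlo draws per explained sample.
#' @param noise_sd standard deviation of the smoothing noise (0 = none).
#' @param seed integer seed for the draws.
#' @return samples x genes attribution matrix.
#' @export
gradient_shap <- function(net, X, background, n_samples = 50, noise_sd = 0,
                          seed = 1) {
  if (is.null(dim(background)) || nrow(background) == 0) {
    stop("degenerate input: empty background")
  }
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  n <- nrow(X)
  p <- ncol(X)
  acc <- matrix(0, n, p)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      B <- background[sample(nrow(background), n, replace = TRUE), , drop = FALSE]
      alpha <- stats::runif(n)
      P <- B + alpha * (X - B)
      if (noise_sd > 0) P <- P + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
      acc <- acc + (X - B) * stack_input_gradient(stack, P)
    }
  })
  new_attribution(acc / n_samples, X, "gradient_shap")
}

# ---- propagation-based methods ---------------------------------------

# Risk-head DeepLIFT multipliers by sequential substitution: hazards are
# switched from the reference value to the explained value one bin at a
# time (left to right); the multiplier of bin l is the resulting risk
# change divided by delta-h_l, falling back to the analytic partial
# derivative at the mixed point when |delta-h| < 1e-7. The telescoping
# construction makes the multipliers satisfy summation-to-delta exactly.
risk_head_multipliers <- function(z_x, z_ref) {
  J <- ncol(z_x)
  n <- nrow(z_x)
  hx <- stats::plogis(z_x)
  hr <- stats::plogis(z_ref)                     # 1 x J
  Px <- t(apply(1 - hx, 1, cumprod))
  if (J == 1) Px <- matrix(1 - hx, n, 1)
  pr <- cumprod(1 - as.vector(hr))               # length J
  qr <- rev(cumsum(rev(pr)))                     # sum_{j >= l} pr_j
  # risk_mix(l) = -( sum_{j<=l} Px_j + (Px_l / pr_l) * sum_{j>l} pr_j )
  Qx <- t(apply(Px, 1, cumsum))
  if (J == 1) Qx <- Px
  rm_prev <- rep(-qr[1], n)                      # l = 0: all-reference risk
  M <- matrix(0, n, J)
  hr_row <- as.vector(hr)
  Px_prev <- rep(1, n)
  for (l in seq_len(J)) {
    tail_l <- if (l < J) qr[l + 1] / pr[l] else 0
    rm_l <- -(Qx[, l] + Px[, l] * tail_l)
    dh <- hx[, l] - hr_row[l]
    contrib <- rm_l - rm_prev
    m <- contrib / dh
    small <- abs(dh) < 1e-7
    if (any(small)) {
      # analytic d(risk_mix)/dh_l given x-prefix and reference-suffix
      m[small] <- (Px_prev * (1 + tail_l))[small]
    }
    M[, l] <- m
    rm_prev <- rm_l
    Px_prev <- Px[, l]
  }
  M
}

# Shared DeepLIFT backward pass for a batch of samples against a single
# reference row; acts_x may be precomputed (reused across references).
deeplift_core <- function(stack, X, ref, acts_x = NULL) {
  if (is.null(acts_x)) acts_x <- stack_forward(stack, X)
  acts_r <- stack_forward(stack, matrix(ref, nrow = 1))
  nl <- length(stack$layers)
  M <- matrix(1, nrow(X), 1)
  for (i in rev(seq_len(nl))) {
    ly <- stack$layers[[i]]
    if (ly$type == "linear") {
      M <- M %*% t(ly$W)
    } else if (ly$type == "selu") {
      zx <- acts_x[[i]]
      zr <- acts_r[[i]]
      dz <- sweep(zx, 2, as.vector(zr))
      ds <- sweep(selu(zx), 2, as.vector(selu(zr)))
      mult <- ds / dz
      small <- abs(dz) < 1e-7
      if (any(small)) mult[small] <- selu_deriv(zx)[small]
      M <- M * mult
    } else if (ly$type == "risk_head") {
      zx <- acts_x[[i]]
      zr <- acts_r[[i]]
      m_h <- risk_head_multipliers(zx, zr)
      hx <- stats::plogis(zx)
      hr <- stats::plogis(zr)
      dz <- sweep(zx, 2, as.vector(zr))
      dh <- sweep(hx, 2, as.vector(hr))
      mult <- dh / dz
      small <- abs(dz) < 1e-7
      if (any(small)) mult[small] <- (hx * (1 - hx))[small]
      M <- as.vector(M) * (m_h * mult)
    }
  }
  M * sweep(X, 2, ref)
}

#' DeepLIFT with the Rescale rule
#'
#' Decomposes the difference between the explained output and the output
#' at the reference layer by layer: linear layers contribute their
#' weights, each elementwise nonlinearity contributes the ratio of its
#' output change to its input change (falling back to the pointwise
#' derivative when the input change is below 1e-7), and the nonlinear
#' risk head contributes exact sequential-substitution multipliers. The
#' chain product times `(x - ref)` gives attributions that satisfy
#' summation-to-delta: they add up to `f(x) - f(ref)`.
#'
#' @inheritParams integrated_gradients
#' @return samples x genes attribution matrix.
#' @export
deeplift_rescale <- function(net, X, reference = NULL) {
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  ref <- default_reference(net, reference)
  new_attribution(deeplift_core(stack, X, ref), X, "deeplift")
}

#' DeepSHAP: DeepLIFT averaged over a background distribution
#'
#' Runs the DeepLIFT Rescale decomposition once per background sample
#' (the entire training set, or `background_max` seeded subsamples) and
#' averages, approximating Shapley values under the background
#' distribution.
#'
#' @inheritParams gradient_shap
#' @param background_max cap on the number of background rows used
#'   (`Inf` = all of them).
#' @return samples x genes attribution matrix.
#' @export
deep_shap <- function(net, X, background, background_max = Inf, seed = 1) {
  if (is.null(dim(background)) || nrow(background) == 0) {
    stop("degenerate input: empty background")
  }
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  if (is.finite(background_max) && nrow(background) > background_max) {
    idx <- with_seed(seed, sample(nrow(background), background_max))
    background <- background[idx, , drop = FALSE]
  }
  acts_x <- stack_forward(stack, X)
  acc <- matrix(0, nrow(X), ncol(X))
  for (r in seq_len(nrow(background))) {
    acc <- acc + deeplift_core(stack, X, background[r, ], acts_x = acts_x)
  }
  new_attribution(acc / nrow(background), X, "deepshap")
}

#' Layer-wise Relevance Propagation with the epsilon rule
#'
#' Output relevance starts at the explained risk and is carried through
#' the nonlinear risk head by a first-order Taylor (gradient x
#' activation) step at the logits; from there, each linear layer
#' redistributes relevance proportional to weighted activations with an
#' epsilon stabilizer in the denominator and bias terms excluded
#' (`R_j = sum_k a_j w_jk / (z_k + sign(z_k) eps) R_k`,
#' `z_k = sum_j a_j w_jk`), while SELU and dropout layers pass relevance
#' unchanged. Note the head step is a Taylor approximation: strict
#' conservation holds only below it, on bias-free linear stacks.
#'
#' @inheritParams integrated_gradients
#' @param epsilon positive stabilizer of the epsilon rule.
#' @return samples x genes relevance matrix.
#' @export
lrp_epsilon <- function(net, X, epsilon = 1e-6) {
  if (epsilon <= 0) stop("configuration error: epsilon must be positive")
  stack <- as_net_stack(net)
  X <- align_stack_input(net, X)
  acts <- stack_forward(stack, X)
  nl <- length(stack$layers)
  i <- nl
  if (stack$layers[[nl]]$type == "risk_head") {
    z <- acts[[nl]]
    R <- z * risk_logit_gradient(z)    # Taylor: relevance at the logits
    i <- nl - 1
  } else {
    R <- acts[[nl + 1]]                # linear output is its own relevance
  }
  while (i >= 1) {
    ly <- stack$layers[[i]]
    if (ly$type == "linear") {
      A_in <- acts[[i]]
      Zno <- A_in %*% ly$W             # bias excluded
      denom <- Zno + ifelse(Zno >= 0, epsilon, -epsilon)
      R <- A_in * ((R / denom) %*% t(ly$W))
    }
    # selu (and dropout at explanation time): identity pass-through
    i <- i - 1
  }
  new_attribution(R, X, "lrp")
}

# ---- perturbation-based method ---------------------------------------

#' Permutation feature importance on the C-index
#'
#' Shuffles one gene column at a time on the held-out evaluation set and
#' measures the decline of the model's C-index; each gene is permuted
#' `repeats` times and the average decline is reported (it may be
#' negative). This is a global importance: one score per gene.
#'
#' @param net a trained `survival_net`.
#' @param X_test held-out expression matrix.
#' @param time,event held-out survival outcomes.
#' @param repeats permutations per gene.
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `gene_id`, `score` (attribute
#'   `method = "pfi"`).
#' @export
permutation_importance <- function(net, X_test, time, event, repeats = 5,
                                   seed = 1) {
  if (repeats < 1) stop("configuration error: repeats must be >= 1")
  X <- align_stack_input(net, X_test)
  stack <- as_net_stack(net)
  n <- nrow(X)
  base_c <- concordance_index(stack_output(stack, X), time, event)
  p <- ncol(X)
  scores <- numeric(p)
  time_rep <- rep(time, repeats)
  event_rep <- rep(event, repeats)
  with_seed(seed, {
    for (g in seq_len(p)) {
      Xg <- X[rep(seq_len(n), repeats), , drop = FALSE]
      col <- numeric(n * repeats)
      for (r in seq_len(repeats)) {
        col[((r - 1) * n + 1):(r * n)] <- X[sample(n), g]
      }
      Xg[, g] <- col
      risk <- stack_output(stack, Xg)
      cs <- vapply(seq_len(repeats), function(r) {
        ii <- ((r - 1) * n + 1):(r * n)
        concordance_index(risk[ii], time_rep[ii], event_rep[ii])
      }, numeric(1))
      scores[g] <- base_c - mean(cs)
    }
  })
  structure(data.frame(gene_id = colnames(X), score = scores,
                       stringsAsFactors = FALSE),
            method = "pfi", baseline_cindex = base_c)
}

# ---- aggregation -----------------------------------------------------

#' Aggregate per-sample attributions to one score per gene
#'
#' Default `mean_abs`: the mean absolute attribution over samples
#' (sign-agnostic prognostic relevance, the usual SHAP summary);
#' `mean_signed` averages signed values. A PFI result (already global)
#' passes through unchanged.
#'
#' @param attr attribution matrix (samples x genes) or a PFI data.frame.
#' @param mode `"mean_abs"` or `"mean_signed"`.
#' @return data.frame with columns `gene_id`, `score`.
#' @export
aggregate_global <- function(attr, mode = c("mean_abs", "mean_signed")) {
  mode <- match.arg(mode)
  if (is.data.frame(attr)) return(attr)
  if (length(attr) == 0) stop("degenerate input: empty attribution matrix")
  s <- switch(mode,
              mean_abs = colMeans(abs(attr)),
              mean_signed = colMeans(attr))
  ids <- colnames(attr)
  if (is.null(ids)) ids <- as.character(seq_along(s))
  structure(data.frame(gene_id = ids, score = as.numeric(s),
                       stringsAsFactors = FALSE),
            method = attr(attr, "method"))
}

#' Top-k genes by global importance
#'
#' Descending score order; ties are broken lexicographically by gene
#' identifier so the selection is reproducible.
#'
#' @param global data.frame from [aggregate_global()] or
#'   [permutation_importance()].
#' @param k number of genes to return.
#' @return character vector of k gene identifiers.
#' @export
top_k <- function(global, k) {
  if (k > nrow(global)) stop("configuration error: k exceeds the number of genes")
  ord <- order(-global$score, global$gene_id)
  global$gene_id[ord[seq_len(k)]]
}

#' Attribution method configuration
#'
#' Bundles one method name with its tunables; used by the benchmark
#' driver to dispatch [compute_attribution()].
#'
#' @param method one of `integrated_gradients`, `gradient_shap`,
#'   `deeplift`, `deepshap`, `lrp`, `pfi`.
#' @param ig_steps integration steps for IG.
#' @param gs_n_samples,gs_noise_sd GradientSHAP draws and noise sd.
#' @param lrp_epsilon epsilon-rule stabilizer.
#' @param pfi_repeats permutations per gene for PFI.
#' @param background_max cap on DeepSHAP background rows.
#' @param seed integer seed.
#' @return an object of class `attribution_config`.
#' @export
attribution_config <- function(method = c("integrated_gradients", "gradient_shap",
                                          "deeplift", "deepshap", "lrp", "pfi"),
                               ig_steps = 50, gs_n_samples = 50, gs_noise_sd = 0,
                               lrp_epsilon = 1e-6, pfi_repeats = 5,
                               background_max = Inf, seed = 1) {
  method <- match.arg(method)
  if (ig_steps < 2) stop("configuration error: ig_steps must be >= 2")
  if (pfi_repeats < 1) stop("configuration error: pfi_repeats must be >= 1")
  structure(list(method = method, ig_steps = as.integer(ig_steps),
                 gs_n_samples = as.integer(gs_n_samples),
                 gs_noise_sd = gs_noise_sd, lrp_epsilon = lrp_epsilon,
                 pfi_repeats = as.integer(pfi_repeats),
                 background_max = background_max, seed = as.integer(seed)),
            class = "attribution_config")
}

#' Run one attribution method and return global importances
#'
#' @param net a trained `survival_net`.
#' @param X_test samples to explain (the fold's held-out samples).
#' @param config an [attribution_config()].
#' @param background training-fold expression matrix (reference source).
#' @param time,event held-out outcomes; required by PFI only.
#' @return data.frame with columns `gene_id`, `score`.
#' @export
compute_attribution <- function(net, X_test, config, background,
                                time = NULL, event = NULL) {
  stopifnot(inherits(config, "attribution_config"))
  ref <- reference_input(background)
  attr <- switch(config$method,
    integrated_gradients = integrated_gradients(net, X_test, ref,
                                                steps = config$ig_steps),
    gradient_shap = gradient_shap(net, X_test, background,
                                  n_samples = config$gs_n_samples,
                                  noise_sd = config$gs_noise_sd,
                                  seed = config$seed),
    deeplift = deeplift_rescale(net, X_test, ref),
    deepshap = deep_shap(net, X_test, background,
                         background_max = config$background_max,
                         seed = config$seed),
    lrp = lrp_epsilon(net, X_test, epsilon = config$lrp_epsilon),
    pfi = {
      if (is.null(time) || is.null(event)) {
        stop("pfi requires held-out time and event")
      }
      permutation_importance(net, X_test, time, event,
                             repeats = config$pfi_repeats, seed = config$seed)
    })
  aggregate_global(attr)
}

#' Write global importances or an attribution matrix as TSV
#'
#' Genes as rows (`gene_id`, `score`, plus one column per sample for a
#' matrix), with a JSON sidecar recording the method tag.
#'
#' @param attr attribution matrix or global data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(attr, path) {
  if (is.data.frame(attr)) {
    df <- attr
  } else {
    df <- data.frame(gene_id = colnames(attr), score = colMeans(abs(attr)),
                     t(attr), check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(method = attr(attr, "method"),
                            explained = "risk"),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}
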