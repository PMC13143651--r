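# Discrete-time self-normalizing survival network, implemented directly
# on base-R matrix algebra: four fully connected SELU/Alpha-Dropout
# blocks of width 256, a J-logit head mapped through the logistic
# function to conditional hazards, discrete-hazard negative
# log-likelihood with L1/L2 penalties, Adam, warmup + early stopping,
# and dual (best-loss / best-C-index) checkpoints.

SELU_LAMBDA <- 1.0507009873554804934
SELU_ALPHA <- 1.6732632423543772848

selu <- function(x) {
  out <- SELU_LAMBDA * x
  neg <- x < 0
  out[neg] <- SELU_LAMBDA * SELU_ALPHA * (exp(x[neg]) - 1)
  out
}

selu_deriv <- function(x) {
  out <- matrix(SELU_LAMBDA, nrow(x), ncol(x))
  neg <- x < 0
  out[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(x[neg])
  out
}

# Alpha-dropout affine constants for dropout probability p: dropped units
# are set to -lambda*alpha and the layer output is rescaled so mean and
# variance are preserved (the self-normalizing property).
alpha_dropout_constants <- function(p) {
  ap <- -SELU_LAMBDA * SELU_ALPHA
  q <- 1 - p
  a <- (q + ap^2 * q * p)^(-0.5)
  list(a = a, b = -a * ap * p, ap = ap)
}

#' Training configuration for the survival network
#'
#' Defaults are the model's standard protocol: Adam with learning rate
#' 2e-4, L1 and L2 penalties of 1e-5 each, Alpha Dropout 0.25, four
#' hidden blocks of width 256, a 5-epoch warmup before early-stopping
#' evaluation begins, a minimum training cycle of 20 epochs, and
#' patience 7 on the validation loss.
#'
#' @param learning_rate Adam step size.
#' @param l1_lambda,l2_lambda coefficients of the explicit L1 / L2 weight
#'   penalties added to the loss (weights only, not biases).
#' @param dropout_rate Alpha-Dropout probability during training.
#' @param hidden_width neurons per hidden block.
#' @param n_snn_blocks number of SELU blocks.
#' @param warmup_epochs epochs before checkpointing/early stopping engage.
#' @param min_epochs training never stops before this many epochs.
#' @param patience consecutive epochs without validation-loss improvement
#'   (by more than 1e-6) after which training stops.
#' @param max_epochs hard cap on epochs.
#' @param batch_size minibatch size. The default (8) is sized for
#'   desk-scale cohorts: warmup, patience and the minimum training cycle
#'   are all counted in epochs, so an epoch must contain enough gradient
#'   updates (~32 at 250 internal-training samples) for those counters
#'   to describe meaningful amounts of optimization.
#' @param internal_val_fraction fraction of the training data held out as
#'   the internal validation split (stratified on the event indicator).
#' @param n_bins number of time-grid intervals requested from
#'   [make_time_grid()] (duplicate event-time quantiles may shrink it).
#' @param seed integer seed controlling the split, initialization,
#'   shuffling and dropout masks.
#' @return an object of class `training_config`.
#' @export
training_config <- function(learning_rate = 2e-4, l1_lambda = 1e-5,
                            l2_lambda = 1e-5, dropout_rate = 0.25,
                            hidden_width = 256, n_snn_blocks = 4,
                            warmup_epochs = 5, min_epochs = 20, patience = 7,
                            max_epochs = 200, batch_size = 8,
                            internal_val_fraction = 0.2, n_bins = 10,
                            seed = 1) {
  if (learning_rate <= 0 || dropout_rate < 0 || dropout_rate >= 1) {
    stop("configuration error: invalid learning_rate or dropout_rate")
  }
  if (internal_val_fraction <= 0 || internal_val_fraction >= 1) {
    stop("configuration error: internal_val_fraction must lie in (0,1)")
  }
  structure(list(learning_rate = learning_rate, l1_lambda = l1_lambda,
                 l2_lambda = l2_lambda, dropout_rate = dropout_rate,
                 hidden_width = as.integer(hidden_width),
                 n_snn_blocks = as.integer(n_snn_blocks),
                 warmup_epochs = as.integer(warmup_epochs),
                 min_epochs = as.integer(min_epochs),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 internal_val_fraction = internal_val_fraction,
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "training_config")
}

#' Keep the highest-variance genes
#'
#' Retains the `n_top` genes of largest per-gene (sample) variance,
#' preserving the original column order among the kept genes. Variance
#' ties are broken by gene-identifier lexicographic order so the result
#' is reproducible.
#'
#' @param expr samples x genes matrix with gene-id colnames.
#' @param n_top number of genes to keep.
#' @return the filtered expression matrix.
#' @export
variance_filter <- function(expr, n_top) {
  if (n_top > ncol(expr)) {
    stop("configuration error: n_top exceeds the number of genes")
  }
  v <- apply(expr, 2, stats::var)
  ids <- colnames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(expr)))
  ord <- order(-v, ids)
  keep <- sort(ord[seq_len(n_top)])
  expr[, keep, drop = FALSE]
}

#' Build a discrete time grid from event-time quantiles
#'
#' Interior edges sit at quantiles (type 7, linear interpolation) of the
#' event times only; duplicated quantiles are collapsed so the number of
#' intervals J may shrink below `n_bins`. The first edge is 0 and the
#' last edge is the maximum observed (event or censoring) time.
#'
#' @param times observed times (positive reals).
#' @param events 0/1 event indicators.
#' @param n_bins requested number of intervals (>= 2).
#' @return an object of class `time_grid` with fields `bin_edges`
#'   (J+1 increasing reals) and `n_bins` (J).
#' @export
make_time_grid <- function(times, events, n_bins = 10) {
  if (!any(events == 1)) stop("degenerate input: no events to place bin edges")
  if (n_bins < 2) stop("configuration error: n_bins must be >= 2")
  ev <- times[events == 1]
  max_t <- max(times)
  probs <- seq(0, 1, length.out = n_bins + 1)[2:n_bins]
  interior <- unique(stats::quantile(ev, probs = probs, type = 7, names = FALSE))
  interior <- interior[interior > 0 & interior < max_t]
  edges <- c(0, interior, max_t)
  structure(list(bin_edges = edges, n_bins = length(edges) - 1L),
            class = "time_grid")
}

#' Map observed times to time-grid bins
#'
#' Bin j covers the interval `(edge_j, edge_{j+1}]`; times beyond the last
#' edge are clamped into the last bin.
#'
#' @param grid a [make_time_grid()] object.
#' @param times observed times.
#' @return integer bin indices in `1..J`.
#' @export
discretize_times <- function(grid, times) {
  idx <- findInterval(times, grid$bin_edges, left.open = TRUE)
  pmin(pmax(idx, 1L), grid$n_bins)
}

# ---- parameter container and forward/backward passes -----------------

init_params <- function(p, width, n_blocks, J, seed) {
  with_seed(seed, {
    dims_in <- c(p, rep(width, n_blocks - 1), width)
    dims_out <- c(rep(width, n_blocks), J)
    W <- vector("list", n_blocks + 1)
    b <- vector("list", n_blocks + 1)
    for (l in seq_len(n_blocks + 1)) {
      fan_in <- dims_in[l]
      # lecun-normal initialization, the SNN convention
      W[[l]] <- matrix(stats::rnorm(fan_in * dims_out[l], sd = 1 / sqrt(fan_in)),
                       fan_in, dims_out[l])
      b[[l]] <- rep(0, dims_out[l])
    }
    list(W = W, b = b, n_blocks = n_blocks)
  })
}

# Forward pass. Returns hazards plus the per-layer cache needed for
# backprop. Dropout masks are drawn from the current RNG stream when
# training = TRUE; evaluation mode is deterministic.
snn_forward <- function(params, X, training = FALSE, dropout_rate = 0) {
  nb <- params$n_blocks
  A <- vector("list", nb + 1)  # A[[l]]: activation entering layer l
  Z <- vector("list", nb)      # pre-activations of the SELU blocks
  masks <- vector("list", nb)
  A[[1]] <- X
  dc <- if (training && dropout_rate > 0) alpha_dropout_constants(dropout_rate)
  for (l in seq_len(nb)) {
    Zl <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    S <- selu(Zl)
    if (training && dropout_rate > 0) {
      m <- matrix(stats::runif(length(S)) >= dropout_rate, nrow(S), ncol(S))
      S <- dc$a * (S * m + dc$ap * (1 - m)) + dc$b
      masks[[l]] <- m
    }
    Z[[l]] <- Zl
    A[[l + 1]] <- S
  }
  logits <- sweep(A[[nb + 1]] %*% params$W[[nb + 1]], 2, params$b[[nb + 1]], "+")
  h <- stats::plogis(logits)
  list(h = h, logits = logits, A = A, Z = Z, masks = masks,
       dropout_a = if (!is.null(dc)) dc$a else 1)
}

# Backward pass from a gradient w.r.t. the head logits. Returns weight
# and bias gradients plus the gradient w.r.t. the input matrix.
snn_backward <- function(params, cache, d_logits) {
  nb <- params$n_blocks
  gW <- vector("list", nb + 1)
  gb <- vector("list", nb + 1)
  gW[[nb + 1]] <- crossprod(cache$A[[nb + 1]], d_logits)
  gb[[nb + 1]] <- colSums(d_logits)
  dA <- d_logits %*% t(params$W[[nb + 1]])
  for (l in rev(seq_len(nb))) {
    if (!is.null(cache$masks[[l]])) dA <- dA * (cache$dropout_a * cache$masks[[l]])
    dZ <- dA * selu_deriv(cache$Z[[l]])
    gW[[l]] <- crossprod(cache$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(params$W[[l]])
  }
  list(gW = gW, gb = gb, gX = dA)
}

clamp_hazard <- function(h) pmin(pmax(h, 1e-7), 1 - 1e-7)

# Per-sample at-risk / event masks for the discrete-hazard likelihood.
# M_surv[i, l] = 1 where sample i contributes log(1 - h_il): l < bin for
# events, l <= bin for censored. M_event[i, l] = 1 at the event bin.
nll_masks <- function(bin, event, J) {
  n <- length(bin)
  L <- matrix(seq_len(J), n, J, byrow = TRUE)
  M_surv <- (L <= (bin - event)) * 1
  M_event <- (L == bin & event == 1) * 1
  list(surv = M_surv, event = M_event)
}

#' Discrete-hazard negative log-likelihood
#'
#' Mean over samples of the discrete survival NLL: a subject with an
#' event in bin j contributes `-log h_j - sum_{l<j} log(1 - h_l)`; a
#' subject censored in bin j contributes `-sum_{l<=j} log(1 - h_l)`
#' (survival counted through the censoring bin inclusive). Hazards are
#' clamped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param h hazard matrix, samples x J.
#' @param bin integer event/censoring bin per sample (1..J).
#' @param event 0/1 event indicators.
#' @return non-negative scalar loss.
#' @export
nll_loss <- function(h, bin, event) {
  stopifnot(nrow(h) == length(bin), length(bin) == length(event))
  hc <- clamp_hazard(h)
  m <- nll_masks(bin, event, ncol(h))
  -mean(rowSums(m$event * log(hc) + m$surv * log1p(-hc)))
}

# Gradient of nll_loss w.r.t. the head logits (h = plogis(logits)).
nll_logit_gradient <- function(h, bin, event) {
  hc <- clamp_hazard(h)
  m <- nll_masks(bin, event, ncol(h))
  (hc * m$surv - (1 - hc) * m$event) / nrow(h)
}

#' Predicted discrete survival curve
#'
#' `S_ij = prod_{l<=j} (1 - h_il)`: the probability of surviving through
#' bin j. Non-increasing in j and contained in (0, 1) for hazards in
#' (0, 1).
#'
#' @param h hazard matrix, samples x J.
#' @return survival matrix of the same shape.
#' @export
survival_curve <- function(h) {
  S <- 1 - h
  if (ncol(S) > 1) {
    for (j in 2:ncol(S)) S[, j] <- S[, j - 1] * S[, j]
  }
  S
}

#' Risk score: negative cumulative predicted survival
#'
#' `Risk_i = -sum_j S_ij`, a negative proxy for expected survival time;
#' higher values mean shorter predicted survival. Summation is
#' left-to-right over bins.
#'
#' @param S survival matrix from [survival_curve()].
#' @return numeric vector of risks, one per sample.
#' @export
risk_score <- function(S) {
  r <- S[, 1]
  if (ncol(S) > 1) for (j in 2:ncol(S)) r <- r + S[, j]
  -unname(r)
}

#' Harrell's concordance index
#'
#' Over comparable pairs (i usable as the earlier subject only when
#' `event_i = 1` and `time_i < time_j`): a pair is concordant when
#' `risk_i > risk_j`; tied risks earn 0.5 credit. Tied-time pairs are
#' not comparable.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return concordant fraction in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  comp <- outer(time, time, "<")
  comp[event != 1, ] <- FALSE
  n_pairs <- sum(comp)
  if (n_pairs == 0) stop("degenerate input: no comparable pairs")
  conc <- sum(outer(risk, risk, ">") & comp)
  ties <- sum(outer(risk, risk, "==") & comp)
  (conc + 0.5 * ties) / n_pairs
}

# ---- training --------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  list(mW = lapply(params$W, zero_like), vW = lapply(params$W, zero_like),
       mb = lapply(params$b, zero_like), vb = lapply(params$b, zero_like),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

stratified_split <- function(event, val_fraction, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (e in unique(event)) {
      idx <- which(event == e)
      n_val <- round(length(idx) * val_fraction)
      if (length(idx) > 0 && n_val > 0) {
        val <- c(val, sample(idx, n_val))
      }
    }
    sort(val)
  })
}

#' Train the self-normalizing survival network
#'
#' Splits the input 80/20 into internal train/validation sets (stratified
#' on the event indicator), builds the time grid from the full input,
#' and optimizes the penalized discrete-hazard NLL
#' (`nll + l1*sum|w| + l2*sum w^2`) with Adam. Early stopping is not
#' evaluated during the first `warmup_epochs`; training never stops
#' before `min_epochs`; it stops once the validation loss has failed to
#' improve (by more than 1e-6) for `patience` consecutive epochs. Dual
#' checkpoints record the lowest-validation-loss and
#' highest-validation-C-index weights; the selected checkpoint is the
#' best-C-index snapshot when one exists, else the best-loss snapshot.
#' Fully reproducible given the config seed.
#'
#' @param expr samples x genes expression matrix (rownames = sample ids).
#' @param surv data.frame with columns `sample_id`, `time`, `event`.
#' @param config a [training_config()].
#' @return an object of class `survival_net` with the selected weights,
#'   both checkpoints, the time grid, training history, and the
#'   training-set column means (the default attribution reference).
#' @export
train_survival_net <- function(expr, surv, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  ord <- match(rownames(expr), surv$sample_id)
  if (anyNA(ord)) stop("identifier error: clinical rows missing for some samples")
  time <- surv$time[ord]
  event <- as.integer(surv$event[ord])
  n <- nrow(expr)
  if (n < 2) stop("degenerate input: need at least 2 samples")

  grid <- make_time_grid(time, event, config$n_bins)
  bin <- discretize_times(grid, time)
  J <- grid$n_bins

  val_idx <- stratified_split(event, config$internal_val_fraction,
                              child_seed(config$seed, 1L))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (sum(event[tr_idx]) == 0 || sum(event[val_idx]) == 0) {
    stop("degenerate input: an internal split has no events")
  }
  Xt <- expr[tr_idx, , drop = FALSE]
  Xv <- expr[val_idx, , drop = FALSE]

  params <- init_params(ncol(expr), config$hidden_width, config$n_snn_blocks,
                        J, child_seed(config$seed, 2L))
  state <- adam_init(params)

  n_tr <- length(tr_idx)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_cindex = numeric(0))
  best_loss <- Inf
  best_cindex <- -Inf
  ck_loss <- NULL
  ck_cindex <- NULL
  stall <- 0L

  penalty_grads <- function(grads) {
    for (l in seq_along(params$W)) {
      grads$gW[[l]] <- grads$gW[[l]] + config$l1_lambda * sign(params$W[[l]]) +
        2 * config$l2_lambda * params$W[[l]]
    }
    grads
  }

  with_seed(child_seed(config$seed, 3L), {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(n_tr)
      starts <- seq(1, n_tr, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        ii <- perm[s:min(s + config$batch_size - 1, n_tr)]
        Xb <- Xt[ii, , drop = FALSE]
        fw <- snn_forward(params, Xb, training = TRUE,
                          dropout_rate = config$dropout_rate)
        d_logits <- nll_logit_gradient(fw$h, bin[tr_idx][ii], event[tr_idx][ii])
        grads <- penalty_grads(snn_backward(params, fw, d_logits))
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + nll_loss(fw$h, bin[tr_idx][ii], event[tr_idx][ii]) *
          length(ii)
      }
      fv <- snn_forward(params, Xv, training = FALSE)
      val_loss <- nll_loss(fv$h, bin[val_idx], event[val_idx])
      val_c <- tryCatch(
        concordance_index(risk_score(survival_curve(fv$h)),
                          time[val_idx], event[val_idx]),
        error = function(e) NA_real_)
      history[nrow(history) + 1, ] <- list(epoch, ep_loss / n_tr, val_loss, val_c)

      if (epoch > config$warmup_epochs) {
        if (best_loss - val_loss > 1e-6) {
          best_loss <- val_loss
          ck_loss <- params
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        if (!is.na(val_c) && val_c > best_cindex) {
          best_cindex <- val_c
          ck_cindex <- params
        }
        if (epoch >= config$min_epochs && stall >= config$patience) break
      }
    }
  })

  if (is.null(ck_loss)) ck_loss <- params
  selected <- if (!is.null(ck_cindex)) "best_cindex" else "best_loss"
  sel_params <- if (selected == "best_cindex") ck_cindex else ck_loss

  structure(list(params = sel_params,
                 checkpoint_best_loss = ck_loss,
                 checkpoint_best_cindex = ck_cindex,
                 selected_checkpoint = selected,
                 best_val_loss = best_loss,
                 best_val_cindex = if (is.finite(best_cindex)) best_cindex else NA_real_,
                 time_grid = grid, history = history, config = config,
                 feature_names = colnames(expr),
                 training_mean = colMeans(expr)),
            class = "survival_net")
}

#' Predict from a trained survival network
#'
#' @param object a [train_survival_net()] fit.
#' @param newdata samples x genes matrix; columns are matched to the
#'   training features by name when colnames are present.
#' @param type `"risk"` (negative cumulative survival), `"survival"`
#'   (discrete survival curve) or `"hazard"` (conditional hazards).
#' @param ... unused.
#' @return numeric vector (`risk`) or samples x J matrix.
#' @export
predict.survival_net <- function(object, newdata,
                                 type = c("risk", "survival", "hazard"), ...) {
  type <- match.arg(type)
  X <- align_features(object, newdata)
  h <- snn_forward(object$params, X, training = FALSE)$h
  switch(type,
         hazard = h,
         survival = survival_curve(h),
         risk = risk_score(survival_curve(h)))
}

align_features <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (!is.null(colnames(X)) && !is.null(net$feature_names)) {
    if (!all(net$feature_names %in% colnames(X))) {
      stop("shape error: newdata is missing training features")
    }
    X <- X[, net$feature_names, drop = FALSE]
  } else if (ncol(X) != length(net$params$b[[1]]) &&
             ncol(X) != nrow(net$params$W[[1]])) {
    stop("shape error: newdata width does not match the network input")
  }
  X
}

#' @export
print.survival_net <- function(x, ...) {
  cat(sprintf(
    "Self-normalizing survival net: %d features, %d blocks x %d, J = %d bins\n",
    length(x$feature_names), x$params$n_blocks,
    length(x$params$b[[1]]), x$time_grid$n_bins))
  cat(sprintf("  selected checkpoint: %s (val loss %.4f, val C-index %s)\n",
              x$selected_checkpoint, x$best_val_loss,
              ifelse(is.na(x$best_val_cindex), "NA",
                     sprintf("%.4f", x$best_val_cindex))))
  cat(sprintf("  trained %d epochs\n", nrow(x$history)))
  invisible(x)
}

# ---- serialization ---------------------------------------------------

params_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(W = lapply(p$W, function(w) list(dim = dim(w), data = as.vector(w))),
       b = p$b, n_blocks = p$n_blocks)
}

params_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  list(W = lapply(l$W, function(w) matrix(w$data, w$dim[1], w$dim[2])),
       b = lapply(l$b, as.numeric), n_blocks = as.integer(l$n_blocks))
}

#' Save / load a trained survival network as a JSON bundle
#'
#' The bundle stores the training configuration, time grid, both
#' checkpoints, the selected tag and the feature names, with full
#' numeric precision.
#'
#' @param net a `survival_net`.
#' @param path output file.
#' @return `path` (save) or the restored `survival_net` (load).
#' @export
save_survival_net <- function(net, path) {
  bundle <- list(config = unclass(net$config),
                 time_grid = unclass(net$time_grid),
                 selected_checkpoint = net$selected_checkpoint,
                 best_val_loss = net$best_val_loss,
                 best_val_cindex = net$best_val_cindex,
                 feature_names = net$feature_names,
                 training_mean = as.list(net$training_mean),
                 params = params_to_list(net$params),
                 checkpoint_best_loss = params_to_list(net$checkpoint_best_loss),
                 checkpoint_best_cindex = params_to_list(net$checkpoint_best_cindex))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_survival_net
#' @export
load_survival_net <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  grid <- structure(list(bin_edges = as.numeric(b$time_grid$bin_edges),
                         n_bins = as.integer(b$time_grid$n_bins)),
                    class = "time_grid")
  cfg <- do.call(training_config, b$config[names(b$config) %in%
                                             names(formals(training_config))])
  structure(list(params = params_from_list(b$params),
                 checkpoint_best_loss = params_from_list(b$checkpoint_best_loss),
                 checkpoint_best_cindex = params_from_list(b$checkpoint_best_cindex),
                 selected_checkpoint = b$selected_checkpoint,
                 best_val_loss = b$best_val_loss,
                 best_val_cindex = b$best_val_cindex,
                 time_grid = grid,
                 history = NULL, config = cfg,
                 feature_names = as.character(b$feature_names),
                 training_mean = unlist(b$training_mean)),
            class = "survival_net")
}
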