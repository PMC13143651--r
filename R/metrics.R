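# The three evaluation axes — prognostic enrichment via univariate Cox
# regression, gene-set (knowledge-base) consistency, Kuncheva stability
# — and the min-max composite ranking that combines them.

#' Univariate Cox proportional-hazards regression
#'
#' Fits `Surv(time, event) ~ x` by partial likelihood with Efron tie
#' handling (via the survival package) and reports the Wald two-sided
#' p-value. A fit that fails to converge (or yields a non-finite z) is
#' flagged and its p-value set to 1.
#'
#' @param x covariate vector (non-constant).
#' @param time observed times.
#' @param event 0/1 event indicators (>= 2 events required).
#' @return list with `beta`, `standard_error`, `z`, `p_value`,
#'   `converged`.
#' @export
cox_univariate <- function(x, time, event) {
  if (sum(event == 1) < 2) stop("degenerate input: need at least 2 events")
  if (!is.finite(stats::sd(x)) || stats::sd(x) == 0) {
    stop("degenerate covariate: constant input")
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (flagged || !is.finite(z)) {
    p <- 1
    flagged <- TRUE
  }
  list(beta = beta, standard_error = se, z = z,
       p_value = max(p, .Machine$double.xmin), converged = !flagged)
}

#' Count significant prognostic factors among top genes
#'
#' Runs [cox_univariate()] for each top gene on the full cohort and
#' counts genes with two-sided p below `alpha`. Degenerate (constant)
#' covariates count as non-significant; no multiple-testing correction
#' is applied (raw p < alpha, by design).
#'
#' @param top_genes character vector of gene identifiers.
#' @param expr expression matrix containing those genes.
#' @param surv data.frame with `sample_id`, `time`, `event` matching the
#'   expression rows.
#' @param alpha significance threshold.
#' @return integer count.
#' @export
prognostic_enrichment <- function(top_genes, expr, surv, alpha = 0.05) {
  if (length(top_genes) == 0) return(0L)
  missing_genes <- setdiff(top_genes, colnames(expr))
  if (length(missing_genes) > 0) {
    stop("unknown gene identifier: ", paste(missing_genes, collapse = ", "))
  }
  ord <- match(rownames(expr), surv$sample_id)
  time <- surv$time[ord]
  event <- surv$event[ord]
  hits <- vapply(top_genes, function(g) {
    res <- tryCatch(cox_univariate(expr[, g], time, event),
                    error = function(e) NULL)
    !is.null(res) && res$p_value < alpha
  }, logical(1))
  sum(hits)
}

#' Knowledge-base consistency of a top-gene list
#'
#' Three counts against a gene-set collection standing in for curated
#' databases: `aggregate_hits` (sum over sets of top-gene memberships),
#' `unique_validated` (top genes present in at least one set), and
#' `hits_per_validated` (their ratio; 0 when nothing validates).
#'
#' @param top_genes character vector of gene identifiers.
#' @param collection named list of gene-identifier sets (non-empty).
#' @return list with the three fields.
#' @export
consistency_metrics <- function(top_genes, collection) {
  if (length(collection) == 0) stop("degenerate input: empty collection")
  agg <- sum(vapply(collection, function(s) sum(top_genes %in% s), numeric(1)))
  uni <- sum(top_genes %in% unique(unlist(collection)))
  list(aggregate_hits = as.integer(agg),
       unique_validated = as.integer(uni),
       hits_per_validated = if (uni > 0) agg / uni else 0)
}

#' Kuncheva index of two equal-size feature subsets
#'
#' Chance-corrected overlap `(r n - k^2) / (k (n - k))` with
#' `r = |A intersect B|` and `n` the feature-universe size; ranges from
#' -1 (disjoint sets at n = 2k) to 1 (identical sets), and is 0 in
#' expectation for independent random subsets.
#'
#' @param set_a,set_b character vectors of equal size k, 0 < k < n.
#' @param n_features size of the feature universe.
#' @return the index value.
#' @export
kuncheva_index <- function(set_a, set_b, n_features) {
  k <- length(set_a)
  if (length(set_b) != k) stop("undefined index: subsets of unequal size")
  if (k == 0 || k >= n_features) {
    stop("undefined index: k must satisfy 0 < k < n_features")
  }
  r <- length(intersect(set_a, set_b))
  (r * n_features - k^2) / (k * (n_features - k))
}

#' Pairwise Kuncheva stability of top-k sets across folds
#'
#' @param top_sets list of >= 2 equal-size character vectors (the top-k
#'   selections of the cross-validation models).
#' @param n_features size of the feature universe (the post-filter gene
#'   count).
#' @return list of class `stability_result` with `pairwise_values` (all
#'   unordered pairs) and `mean_kuncheva`.
#' @export
stability <- function(top_sets, n_features) {
  if (length(top_sets) < 2) stop("degenerate input: need at least 2 sets")
  pairs <- utils::combn(length(top_sets), 2)
  vals <- apply(pairs, 2, function(ij) {
    kuncheva_index(top_sets[[ij[1]]], top_sets[[ij[2]]], n_features)
  })
  structure(list(pairwise_values = as.numeric(vals),
                 mean_kuncheva = mean(vals)),
            class = "stability_result")
}

#' Min-max composite score and ranking of attribution methods
#'
#' Each of the three metrics (`prognostic_count`, `aggregate_hits`,
#' `stability`) is summarized per method as the median over cohorts of
#' the median over replicates (mean optionally), min-max normalized to
#' `[0, 1]` across methods, and summed into an overall score in
#' `[0, 3]`; rank 1 is the highest overall. A metric with zero range
#' across methods normalizes to 0.5 for every method.
#'
#' @param table data.frame with columns `method`, `prognostic_count`,
#'   `aggregate_hits`, `stability`, and optionally `cohort` and
#'   `replicate`.
#' @param agg `"median"` (default) or `"mean"` summarization.
#' @return data.frame of class `composite_score`: one row per method
#'   with the three normalized metrics, `overall` and `rank`.
#' @export
composite_score <- function(table, agg = c("median", "mean")) {
  agg <- match.arg(agg)
  metrics <- c("prognostic_count", "aggregate_hits", "stability")
  missing_cols <- setdiff(c("method", metrics), names(table))
  if (length(missing_cols) > 0) {
    stop("incomplete table: missing ", paste(missing_cols, collapse = ", "))
  }
  methods <- unique(table$method)
  if (length(methods) < 2) stop("incomplete table: need at least 2 methods")
  if (is.null(table$cohort)) table$cohort <- "cohort"
  f <- if (agg == "median") stats::median else mean

  summarize <- function(m, metric) {
    sub <- table[table$method == m, ]
    per_cohort <- vapply(split(sub[[metric]], sub$cohort), f, numeric(1))
    f(per_cohort)
  }
  summ <- sapply(metrics, function(met) {
    vapply(methods, summarize, numeric(1), metric = met)
  })
  summ <- matrix(summ, nrow = length(methods),
                 dimnames = list(methods, metrics))
  norm <- apply(summ, 2, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
  })
  norm <- matrix(norm, nrow = length(methods),
                 dimnames = list(methods, metrics))
  overall <- rowSums(norm)
  out <- data.frame(method = methods,
                    prognostic_count = norm[, "prognostic_count"],
                    aggregate_hits = norm[, "aggregate_hits"],
                    stability = norm[, "stability"],
                    overall = overall,
                    rank = as.integer(rank(-overall, ties.method = "min")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("composite_score", "data.frame")
  out
}
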