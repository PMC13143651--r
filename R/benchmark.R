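# Orchestration: repeated event-stratified cross-validation, per-fold
# training and explanation, metric collection, and reporting.

#' Repeated, event-stratified cross-validation plan
#'
#' Per repeat, an independent shuffle assigns samples to folds within
#' each event stratum, so every fold retains events; the default 10
#' repeats of 5 folds yield 50 model slots. Deterministic given the
#' seed.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param events 0/1 event indicators aligned with `sample_ids`.
#' @param n_repeats,n_folds plan dimensions.
#' @param seed integer seed.
#' @return object of class `cv_plan`: a list of
#'   `(repeat_index, fold_index, train_ids, test_ids)` entries.
#' @export
repeated_cv_splits <- function(sample_ids, events, n_repeats = 10, n_folds = 5,
                               seed = 1) {
  n <- length(sample_ids)
  if (n < n_folds) stop("too few samples for the requested folds")
  if (sum(events == 1) < n_folds) stop("too few events for the requested folds")
  plan <- list()
  for (r in seq_len(n_repeats)) {
    fold <- integer(n)
    with_seed(child_seed(seed, r), {
      for (e in unique(events)) {
        idx <- which(events == e)
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                      length(idx))
      }
    })
    for (f in seq_len(n_folds)) {
      plan[[length(plan) + 1]] <- list(
        repeat_index = r, fold_index = f,
        train_ids = sample_ids[fold != f],
        test_ids = sample_ids[fold == f])
    }
  }
  structure(plan, class = "cv_plan", n_repeats = as.integer(n_repeats),
            n_folds = as.integer(n_folds), seed = as.integer(seed))
}

ALL_METHODS <- c("integrated_gradients", "gradient_shap", "deeplift",
                 "deepshap", "lrp", "pfi")

#' Run the full attribution benchmark on one cohort
#'
#' For every cross-validation plan entry: train the survival network on
#' the entry's training portion (internally re-split 80/20 for early
#' stopping), record the held-out C-index, run each requested
#' attribution method on the fold's held-out samples (PFI additionally
#' uses the held-out labels; reference/background sets always come from
#' the fold's training portion), aggregate to global importances, take
#' the top-k genes, and score prognostic enrichment (full cohort) and
#' knowledge-base consistency. Per method, stability is the mean
#' pairwise Kuncheva index of its top-k sets over all plan entries.
#'
#' @param expression samples x genes matrix.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @param gene_sets optional named list of gene sets (see [read_gmt()]).
#' @param methods subset of the six method names.
#' @param k top-k size.
#' @param n_repeats,n_folds cross-validation dimensions.
#' @param n_top_genes optional variance-filter size applied once to the
#'   cohort before cross-validation.
#' @param training a [training_config()]; its seed is re-derived per
#'   fold from `seed`.
#' @param attribution an [attribution_config()]-like list of tunables
#'   (`ig_steps`, `gs_n_samples`, `gs_noise_sd`, `lrp_epsilon`,
#'   `pfi_repeats`, `background_max`).
#' @param alpha Cox significance threshold.
#' @param cohort label recorded in the metric table.
#' @param seed global integer seed.
#' @param output_dir optional directory for `metrics.tsv`,
#'   `stability.tsv`, `manifest.json` and per-method top-k lists.
#' @param keep_going log and skip per-(fold, method) errors instead of
#'   aborting.
#' @param verbose log per-fold progress to stderr.
#' @return object of class `benchmark_result`: `metrics` (one record per
#'   method x plan entry with `c_index`, `prognostic_count`,
#'   `aggregate_hits`, `unique_validated`, `hits_per_validated`),
#'   `stability` (per method), `top_sets`, `n_features`, `plan`.
#' @export
run_benchmark <- function(expression, clinical, gene_sets = NULL,
                          methods = ALL_METHODS, k = 100,
                          n_repeats = 10, n_folds = 5, n_top_genes = NULL,
                          training = training_config(),
                          attribution = list(), alpha = 0.05,
                          cohort = "cohort", seed = 1, output_dir = NULL,
                          keep_going = FALSE, verbose = FALSE) {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  if (!is.null(n_top_genes)) expression <- variance_filter(expression, n_top_genes)
  if (k > ncol(expression)) stop("configuration error: k exceeds the gene count")
  ord <- match(rownames(expression), clinical$sample_id)
  if (anyNA(ord)) stop("identifier error: clinical rows missing for some samples")
  clinical <- clinical[ord, ]

  plan <- repeated_cv_splits(rownames(expression), clinical$event,
                             n_repeats, n_folds, child_seed(seed, 1L))
  atr_defaults <- attribution_config()
  atr <- utils::modifyList(unclass(atr_defaults), attribution)

  log_msg <- function(...) if (verbose) message(sprintf(...))
  records <- list()
  top_sets <- stats::setNames(lapply(methods, function(m) list()), methods)

  for (i in seq_along(plan)) {
    entry <- plan[[i]]
    tr <- entry$train_ids
    te <- entry$test_ids
    X_tr <- expression[tr, , drop = FALSE]
    X_te <- expression[te, , drop = FALSE]
    cl_tr <- clinical[match(tr, clinical$sample_id), ]
    cl_te <- clinical[match(te, clinical$sample_id), ]

    tc <- training
    tc$seed <- child_seed(seed, 1000L + i)
    t0 <- Sys.time()
    net <- train_survival_net(X_tr, cl_tr, tc)
    c_idx <- tryCatch(
      concordance_index(predict(net, X_te), cl_te$time, cl_te$event),
      error = function(e) NA_real_)
    log_msg("[repeat %d fold %d] trained %d epochs (%.1fs), test C-index %.3f, checkpoint %s",
            entry$repeat_index, entry$fold_index, nrow(net$history),
            as.numeric(difftime(Sys.time(), t0, units = "secs")), c_idx,
            net$selected_checkpoint)

    for (m in methods) {
      cfg <- do.call(attribution_config,
                     c(list(method = m),
                       atr[setdiff(names(atr), c("method", "seed"))],
                       list(seed = child_seed(seed, 2000L + i * 10L +
                                                match(m, ALL_METHODS)))))
      res <- tryCatch({
        glob <- compute_attribution(net, X_te, cfg, background = X_tr,
                                    time = cl_te$time, event = cl_te$event)
        top <- top_k(glob, k)
        cons <- if (!is.null(gene_sets)) {
          consistency_metrics(top, gene_sets)
        } else {
          list(aggregate_hits = NA_integer_, unique_validated = NA_integer_,
               hits_per_validated = NA_real_)
        }
        list(top = top,
             prog = prognostic_enrichment(top, expression, clinical, alpha),
             cons = cons)
      }, error = function(e) {
        msg <- sprintf("stage error [repeat %d fold %d method %s]: %s",
                       entry$repeat_index, entry$fold_index, m,
                       conditionMessage(e))
        if (!keep_going) stop(msg, call. = FALSE)
        message(msg)
        NULL
      })
      if (is.null(res)) next
      top_sets[[m]][[length(top_sets[[m]]) + 1]] <- res$top
      records[[length(records) + 1]] <- data.frame(
        method = m, cohort = cohort,
        replicate = i, repeat_index = entry$repeat_index,
        fold_index = entry$fold_index, c_index = c_idx,
        prognostic_count = res$prog,
        aggregate_hits = res$cons$aggregate_hits,
        unique_validated = res$cons$unique_validated,
        hits_per_validated = res$cons$hits_per_validated,
        stringsAsFactors = FALSE)
    }
  }

  metrics <- do.call(rbind, records)
  stab <- do.call(rbind, lapply(methods, function(m) {
    if (length(top_sets[[m]]) >= 2) {
      s <- stability(top_sets[[m]], ncol(expression))
      data.frame(method = m, cohort = cohort,
                 mean_kuncheva = s$mean_kuncheva,
                 n_pairs = length(s$pairwise_values),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = m, cohort = cohort, mean_kuncheva = NA_real_,
                 n_pairs = 0L, stringsAsFactors = FALSE)
    }
  }))

  result <- structure(
    list(metrics = metrics, stability = stab, top_sets = top_sets,
         n_features = ncol(expression), k = as.integer(k), plan = plan,
         cohort = cohort, seed = as.integer(seed), methods = methods),
    class = "benchmark_result")

  if (!is.null(output_dir)) write_benchmark(result, output_dir)
  result
}

write_benchmark <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$metrics, file.path(output_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$stability, file.path(output_dir, "stability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(result$top_sets)) {
    sets <- result$top_sets[[m]]
    if (length(sets) > 0) {
      names(sets) <- sprintf("%s_model_%03d", m, seq_along(sets))
      write_gmt(sets, file.path(output_dir, sprintf("top_%s.gmt", m)))
    }
  }
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("survattrib")),
         cohort = result$cohort, seed = result$seed, k = result$k,
         n_features = result$n_features, methods = result$methods,
         n_models = length(result$plan),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(output_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(output_dir)
}

#' Composite scoring and statistical comparison of a benchmark result
#'
#' Computes the min-max composite ranking, Friedman tests (with
#' Kendall's W) per metric across methods (blocks are cohorts when
#' several are present, otherwise the CV replicates), pairwise Wilcoxon
#' signed-rank tests with BH correction within each metric family, and
#' Spearman / partial Spearman correlations of the fold C-index with
#' enrichment and of stability with enrichment adjusting for C-index.
#' With a single method the report degrades to descriptives only.
#'
#' @param result a [run_benchmark()] result, or a metric table
#'   (data.frame) with a matching `stability` attribute/column.
#' @param output_dir optional directory for `composite.json`,
#'   `stats.tsv` and `summary.txt`.
#' @return list with `composite`, `tests` (tidy data.frame),
#'   `correlations`, `summary` (character lines).
#' @export
benchmark_report <- function(result, output_dir = NULL) {
  if (inherits(result, "benchmark_result")) {
    metrics <- result$metrics
    stab <- result$stability
  } else {
    metrics <- result
    stab <- attr(result, "stability")
    if (is.null(stab) && "stability" %in% names(metrics)) {
      stab <- unique(metrics[, c("method", "cohort", "stability")])
      names(stab)[3] <- "mean_kuncheva"
    }
  }
  if (is.null(metrics) || nrow(metrics) == 0) stop("incomplete table")
  methods <- unique(metrics$method)

  merged <- merge(metrics, stab[, c("method", "cohort", "mean_kuncheva")],
                  by = c("method", "cohort"))
  names(merged)[names(merged) == "mean_kuncheva"] <- "stability"

  composite <- NULL
  comp_cols <- c("prognostic_count", "aggregate_hits", "stability")
  if (length(methods) >= 2 && !anyNA(merged[, comp_cols])) {
    composite <- composite_score(merged)
  }

  tests <- data.frame(comparison = character(0), metric = character(0),
                      statistic = numeric(0), p = numeric(0), q = numeric(0),
                      effect_size = numeric(0), stringsAsFactors = FALSE)
  test_metrics <- c("prognostic_count", "aggregate_hits")
  multi_cohort <- length(unique(metrics$cohort)) >= 2
  if (multi_cohort) test_metrics <- c(test_metrics, "stability")
  if (length(methods) >= 2) {
    for (met in test_metrics) {
      src <- if (met == "stability") merged else metrics
      block_col <- if (multi_cohort) "cohort" else "replicate"
      agg <- tapply(src[[met]], list(src$method, src[[block_col]]),
                    function(v) mean(v, na.rm = TRUE))
      M <- matrix(unlist(agg), nrow = length(methods),
                  dimnames = dimnames(agg))
      if (anyNA(M) || ncol(M) < 2 || stats::sd(as.vector(M)) == 0) next
      fr <- tryCatch(friedman_test(M), error = function(e) NULL)
      if (!is.null(fr)) {
        tests[nrow(tests) + 1, ] <- list("friedman", met, fr$statistic,
                                         fr$p_value, NA_real_, fr$kendall_w)
      }
      prs <- utils::combn(rownames(M), 2)
      pw <- apply(prs, 2, function(pr) {
        wt <- tryCatch(wilcoxon_signed_rank(M[pr[1], ], M[pr[2], ]),
                       error = function(e) NULL)
        if (is.null(wt)) c(NA_real_, NA_real_) else c(wt$statistic, wt$p_value)
      })
      ok <- !is.na(pw[2, ])
      if (any(ok)) {
        qv <- rep(NA_real_, ncol(pw))
        qv[ok] <- bh_fdr(pw[2, ok])
        for (j in which(ok)) {
          tests[nrow(tests) + 1, ] <- list(
            paste0("wilcoxon:", prs[1, j], "_vs_", prs[2, j]), met,
            pw[1, j], pw[2, j], qv[j], NA_real_)
        }
      }
    }
  }

  correlations <- list()
  ok_rows <- stats::complete.cases(metrics[, c("c_index", "prognostic_count")])
  if (sum(ok_rows) >= 3 &&
      stats::sd(metrics$c_index[ok_rows]) > 0 &&
      stats::sd(metrics$prognostic_count[ok_rows]) > 0) {
    sp <- spearman_test(metrics$c_index[ok_rows],
                        metrics$prognostic_count[ok_rows])
    ci <- bootstrap_ci(function(d) {
      if (stats::sd(d[, 1]) == 0 || stats::sd(d[, 2]) == 0) return(NA_real_)
      stats::cor(rank(d[, 1]), rank(d[, 2]))
    }, as.matrix(metrics[ok_rows, c("c_index", "prognostic_count")]),
    n_boot = 100, seed = 7)
    correlations$cindex_vs_enrichment <- c(sp, list(boot_ci = ci))
  }
  mg <- merged[stats::complete.cases(
    merged[, c("stability", "prognostic_count", "c_index")]), ]
  if (nrow(mg) >= 4 && stats::sd(mg$stability) > 0 &&
      stats::sd(mg$prognostic_count) > 0 && stats::sd(mg$c_index) > 0) {
    correlations$stability_vs_enrichment <-
      tryCatch(spearman_test(mg$stability, mg$prognostic_count),
               error = function(e) NULL)
    correlations$stability_vs_enrichment_partial <-
      tryCatch(partial_spearman(mg$stability, mg$prognostic_count, mg$c_index),
               error = function(e) NULL)
  }

  summary_lines <- c("Attribution benchmark summary",
                     sprintf("  methods: %s", paste(methods, collapse = ", ")),
                     sprintf("  records: %d", nrow(metrics)))
  if (!is.null(composite)) {
    ordc <- order(composite$rank)
    summary_lines <- c(summary_lines, "  composite ranking (overall in [0,3]):",
                       sprintf("    %d. %-22s %.3f", composite$rank[ordc],
                               composite$method[ordc], composite$overall[ordc]))
  } else {
    summary_lines <- c(summary_lines,
                       "  single method: composite ranking omitted",
                       sprintf("    median prognostic count: %.1f",
                               stats::median(metrics$prognostic_count)))
  }

  out <- list(composite = composite, tests = tests,
              correlations = correlations, summary = summary_lines)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(composite)) {
      jsonlite::write_json(composite, file.path(output_dir, "composite.json"),
                           dataframe = "rows", digits = NA)
    }
    write_test_results(tests, file.path(output_dir, "stats.tsv"))
    writeLines(summary_lines, file.path(output_dir, "summary.txt"))
  }
  out
}
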