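# Synthetic TCGA-like cohorts: block-correlated expression, planted
# log-hazard effects, exponential event times with uniform censoring.
# The block factor model (one latent factor per block, equicorrelated
# within block) is the simplest structure that reproduces the dense
# co-expression collinearity of real transcriptomes, which is exactly
# the regime where permutation importance degrades.

#' Configuration for a synthetic expression/survival cohort
#'
#' Defaults describe a mid-sized TCGA-like cohort: 400 patients, 300
#' genes in 20 co-expression blocks with within-block correlation 0.6,
#' 20 planted prognostic genes of per-gene log-hazard magnitude 1.5,
#' exponential baseline hazard 0.1, and uniform censoring on
#' (0, 32), which yields roughly one third censored subjects under a
#' null linear predictor.
#'
#' @param n_samples number of patients.
#' @param n_genes number of genes (expression matrix columns).
#' @param n_blocks number of co-expression blocks; must not exceed
#'   `n_genes`.
#' @param within_block_corr pairwise Pearson correlation between genes of
#'   the same block, in `[0, 1)`.
#' @param n_prognostic number of planted prognostic genes (drawn without
#'   replacement, spread round-robin across blocks).
#' @param effect_size log-hazard coefficient magnitude per planted gene;
#'   signs alternate so both hazardous and protective genes exist.
#' @param baseline_rate exponential baseline hazard rate.
#' @param censor_horizon upper bound of the uniform censoring-time
#'   distribution.
#' @param seed integer seed; all cohort randomness derives from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 400, n_genes = 300, n_blocks = 20,
                             within_block_corr = 0.6, n_prognostic = 20,
                             effect_size = 1.5, baseline_rate = 0.1,
                             censor_horizon = 32, seed = 1) {
  if (n_samples < 1 || n_genes < 1 || n_blocks < 1) {
    stop("configuration error: n_samples, n_genes and n_blocks must be positive")
  }
  if (n_blocks > n_genes) stop("configuration error: n_blocks must not exceed n_genes")
  if (within_block_corr < 0 || within_block_corr >= 1) {
    stop("configuration error: within_block_corr must lie in [0, 1)")
  }
  if (n_prognostic < 0 || n_prognostic > n_genes) {
    stop("configuration error: n_prognostic must lie in [0, n_genes]")
  }
  if (baseline_rate <= 0) stop("configuration error: baseline_rate must be positive")
  if (censor_horizon <= 0) stop("configuration error: censor_horizon must be positive")
  structure(list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
                 n_blocks = as.integer(n_blocks),
                 within_block_corr = within_block_corr,
                 n_prognostic = as.integer(n_prognostic),
                 effect_size = effect_size, baseline_rate = baseline_rate,
                 censor_horizon = censor_horizon, seed = as.integer(seed)),
            class = "synthetic_config")
}

synthetic_gene_ids <- function(n_genes) sprintf("g%04d", seq_len(n_genes))
synthetic_sample_ids <- function(n_samples) sprintf("s%04d", seq_len(n_samples))

# Contiguous block assignment: block b owns roughly n_genes/n_blocks genes.
block_assignment <- function(config) {
  b <- sort(rep_len(seq_len(config$n_blocks), config$n_genes))
  names(b) <- synthetic_gene_ids(config$n_genes)
  b
}

#' Plant prognostic genes and their coefficients
#'
#' Planted genes are spread round-robin across co-expression blocks (one
#' random unused gene per block, cycling), so the cohort contains both
#' collinear duplicated-signal genes (several planted genes sharing a
#' block's latent factor once `n_prognostic > n_blocks`, or via their
#' correlated block mates) and isolated signals. Coefficient signs
#' alternate `+effect_size, -effect_size, ...`.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `ground_truth` with fields
#'   `prognostic_gene_ids`, `coefficients` (named, nonzero exactly on the
#'   planted genes) and `block_assignment`.
#' @export
make_ground_truth <- function(config) {
  blocks <- block_assignment(config)
  planted <- character(0)
  if (config$n_prognostic > 0) {
    planted <- with_seed(child_seed(config$seed, 11L), {
      chosen <- character(config$n_prognostic)
      used <- character(0)
      for (i in seq_len(config$n_prognostic)) {
        b <- ((i - 1L) %% config$n_blocks) + 1L
        pool <- setdiff(names(blocks)[blocks == b], used)
        if (length(pool) == 0) pool <- setdiff(names(blocks), used)
        pick <- if (length(pool) == 1) pool else sample(pool, 1)
        chosen[i] <- pick
        used <- c(used, pick)
      }
      chosen
    })
  }
  beta <- config$effect_size * (-1)^(seq_along(planted) - 1)
  names(beta) <- planted
  structure(list(prognostic_gene_ids = planted, coefficients = beta,
                 block_assignment = blocks),
            class = "ground_truth")
}

#' Generate a block-correlated expression matrix
#'
#' Gene g in block b is `sqrt(rho) * f_b + sqrt(1 - rho) * e_g` with
#' independent standard-normal latent factor `f_b` per sample and
#' idiosyncratic noise `e_g`; each column is then standardized to mean 0
#' and (sample) variance 1. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return numeric matrix, `n_samples x n_genes`, with sample-id rownames
#'   and gene-id colnames.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  blocks <- block_assignment(config)
  rho <- config$within_block_corr
  X <- with_seed(child_seed(config$seed, 12L), {
    f <- matrix(stats::rnorm(config$n_samples * config$n_blocks),
                config$n_samples, config$n_blocks)
    e <- matrix(stats::rnorm(config$n_samples * config$n_genes),
                config$n_samples, config$n_genes)
    sqrt(rho) * f[, blocks, drop = FALSE] + sqrt(1 - rho) * e
  })
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  dimnames(X) <- list(synthetic_sample_ids(config$n_samples), names(blocks))
  X
}

#' Simulate survival outcomes from planted log-hazard effects
#'
#' The linear predictor is `eta_i = sum_g beta_g x_ig` over planted genes;
#' event times are exponential with rate `baseline_rate * exp(eta_i)`,
#' censoring times uniform on `(0, censor_horizon)`; the observed time is
#' the minimum and `event = 1` iff the event time came first.
#'
#' @param expr expression matrix whose columns cover all planted genes.
#' @param truth a [make_ground_truth()] object.
#' @param config a [synthetic_config()].
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
generate_survival <- function(expr, truth, config) {
  missing_genes <- setdiff(truth$prognostic_gene_ids, colnames(expr))
  if (length(missing_genes) > 0) {
    stop("identifier error: planted genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  n <- nrow(expr)
  eta <- if (length(truth$prognostic_gene_ids) > 0) {
    as.vector(expr[, truth$prognostic_gene_ids, drop = FALSE] %*%
                truth$coefficients[truth$prognostic_gene_ids])
  } else {
    rep(0, n)
  }
  with_seed(child_seed(config$seed, 13L), {
    t_event <- stats::rexp(n, rate = config$baseline_rate * exp(eta))
    t_cens <- stats::runif(n, 0, config$censor_horizon)
    data.frame(sample_id = rownames(expr),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort` with `expression`,
#'   `survival`, `truth` and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  truth <- make_ground_truth(config)
  expr <- generate_expression(config)
  surv <- generate_survival(expr, truth, config)
  structure(list(expression = expr, survival = surv, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a cohort (and simulated knowledge bases) to disk
#'
#' Emits `expression.tsv` (first column `sample_id`), `clinical.tsv`
#' (`sample_id`, `time`, `event`), `ground_truth.json` and
#' `gene_sets.gmt`. The GMT file holds `n_sets` simulated knowledge
#' bases; each set contains every planted gene plus decoys drawn from the
#' non-planted genes so that a fraction `decoy_fraction` of the set is
#' decoys. Numeric values are written with 17 significant digits so a
#' round-trip read reproduces the in-memory cohort exactly.
#'
#' @param cohort a [generate_cohort()] object.
#' @param directory output directory (created if absent).
#' @param n_sets number of simulated knowledge bases.
#' @param decoy_fraction fraction of each emitted set made of decoy
#'   (non-planted) genes, in `[0, 1)`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, directory, n_sets = 4, decoy_fraction = 0.5) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    stop("configuration error: decoy_fraction must lie in [0, 1)")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  paths <- c(expression = file.path(directory, "expression.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             truth = file.path(directory, "ground_truth.json"),
             gene_sets = file.path(directory, "gene_sets.gmt"))

  expr <- cohort$expression
  expr_chr <- matrix(format_full(expr), nrow(expr), ncol(expr))
  lines <- c(paste(c("sample_id", colnames(expr)), collapse = "\t"),
             paste(rownames(expr),
                   apply(expr_chr, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, paths[["expression"]])

  surv <- cohort$survival
  writeLines(c("sample_id\ttime\tevent",
               paste(surv$sample_id, format_full(surv$time), surv$event,
                     sep = "\t")),
             paths[["clinical"]])

  jsonlite::write_json(
    list(prognostic_genes = cohort$truth$prognostic_gene_ids,
         coefficients = as.list(cohort$truth$coefficients),
         blocks = as.list(cohort$truth$block_assignment),
         config = unclass(cfg)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)

  planted <- cohort$truth$prognostic_gene_ids
  if (length(planted) > 0) {
    decoy_pool <- setdiff(colnames(expr), planted)
    set_size <- round(length(planted) / (1 - decoy_fraction))
    n_decoys <- min(set_size - length(planted), length(decoy_pool))
    sets <- with_seed(child_seed(cfg$seed, 14L), {
      lapply(seq_len(n_sets), function(s) {
        decoys <- if (n_decoys > 0) sample(decoy_pool, n_decoys) else character(0)
        c(planted, decoys)
      })
    })
    names(sets) <- sprintf("knowledge_base_%d", seq_len(n_sets))
    write_gmt(sets, paths[["gene_sets"]],
              descriptions = rep("simulated knowledge base", n_sets))
  } else {
    paths <- paths[names(paths) != "gene_sets"]
  }
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param directory directory containing `expression.tsv`, `clinical.tsv`
#'   and optionally `ground_truth.json` / `gene_sets.gmt`.
#' @return list with `expression`, `survival`, and, when present,
#'   `truth` and `gene_sets`.
#' @export
read_cohort <- function(directory) {
  expr_df <- utils::read.delim(file.path(directory, "expression.tsv"),
                               check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df[[1]]
  surv <- utils::read.delim(file.path(directory, "clinical.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  surv$event <- as.integer(surv$event)
  out <- list(expression = expr, survival = surv)
  tj <- file.path(directory, "ground_truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = TRUE)
    out$truth <- structure(
      list(prognostic_gene_ids = as.character(raw$prognostic_genes),
           coefficients = unlist(raw$coefficients),
           block_assignment = unlist(raw$blocks)),
      class = "ground_truth")
  }
  gmt <- file.path(directory, "gene_sets.gmt")
  if (file.exists(gmt)) out$gene_sets <- read_gmt(gmt)
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: `set_name<TAB>description<TAB>gene...`.
#'
#' @param path file path.
#' @return named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
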