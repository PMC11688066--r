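#' Configuration for the synthetic four-group count generator
#'
#' Defines a reduced-scale emulation of the study design the selection
#' method targets: two tumour types plus the two matched normal tissues,
#' with planted gene classes.
#'
#' Gene classes:
#' \describe{
#'   \item{TISSUE}{tissue-specific in both conditions: `fold_tissue`
#'     between tissues in tumours *and* normals.  These are the confounders
#'     the method must discard.}
#'   \item{CANCER_INVARIANT}{the target class: `fold_cancer` between
#'     tissues in tumours only, no tissue effect in normals.}
#'   \item{CANCER_SHARED}{a condition (tumour vs normal) effect identical
#'     in both tissues; carries no between-tissue signal.}
#'   \item{SHARED_NULL}{no effect anywhere.}
#' }
#'
#' Counts are negative binomial with mean
#' `mu = base_mean * lib_factor * fold` and variance
#' `mu + dispersion * mu^2`.  Fold directions are randomised per gene under
#' the seed so selection cannot exploit a fixed sign.
#'
#' @param n_genes number of genes.
#' @param group_sizes named integer vector
#'   `c(tumorA, tumorB, normalA, normalB)`, each >= 2.
#' @param class_fractions proportions over the four gene classes (sum to 1).
#' @param fold_tissue,fold_cancer planted fold changes (> 1).
#' @param base_mean_log_range log10 range of baseline means.
#' @param dispersion common NB dispersion (variance = mu + dispersion*mu^2).
#' @param lib_size_sigma log-normal sd of per-sample library-size factors.
#' @param length_range_bp range of simulated gene lengths in bp.
#' @param seed integer seed; all randomness in [generate_dataset()] derives
#'   from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 400,
                             group_sizes = c(tumorA = 30, tumorB = 30,
                                             normalA = 60, normalB = 60),
                             class_fractions = c(TISSUE = 0.25,
                                                 CANCER_INVARIANT = 0.10,
                                                 CANCER_SHARED = 0.10,
                                                 SHARED_NULL = 0.55),
                             fold_tissue = 4,
                             fold_cancer = 4,
                             base_mean_log_range = c(2, 3.5),
                             dispersion = 0.02,
                             lib_size_sigma = 0.2,
                             length_range_bp = c(500L, 5000L),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              group_sizes = group_sizes,
              class_fractions = class_fractions,
              fold_tissue = fold_tissue,
              fold_cancer = fold_cancer,
              base_mean_log_range = base_mean_log_range,
              dispersion = dispersion,
              lib_size_sigma = lib_size_sigma,
              length_range_bp = length_range_bp,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

gene_classes <- c("TISSUE", "CANCER_INVARIANT", "CANCER_SHARED", "SHARED_NULL")

validate_synthetic_config <- function(cfg) {
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8) {
    stop("class fractions must sum to 1")
  }
  if (!all(gene_classes %in% names(cfg$class_fractions))) {
    stop("class fractions must be named ", paste(gene_classes, collapse = ", "))
  }
  if (length(cfg$group_sizes) != 4L || any(cfg$group_sizes < 2L)) {
    stop("four group sizes, each >= 2, are required")
  }
  if (cfg$fold_tissue <= 1 || cfg$fold_cancer <= 1) {
    stop("planted folds must exceed 1")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$lib_size_sigma < 0) stop("lib_size_sigma must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic four-group dataset with planted gene classes
#'
#' Draws a negative-binomial count matrix over the four sample groups
#' (tumour A, tumour B, normal A, normal B), together with sample metadata,
#' simulated gene lengths, and the ground-truth class of every gene.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `counts` (integer matrix), `meta`
#'   (data.frame: sample_id, tissue, condition), `lengths` (named vector,
#'   bp), `truth` (data.frame: gene_id, class).
#' @export
generate_dataset <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(cfg$seed)
  p <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(p))

  n_class <- floor(cfg$class_fractions[gene_classes] * p)
  n_class["SHARED_NULL"] <- p - sum(n_class[gene_classes != "SHARED_NULL"])
  cls <- rep(gene_classes, times = n_class)

  gs <- cfg$group_sizes
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(sum(gs))),
    tissue = rep(c("A", "B", "A", "B"), times = gs),
    condition = rep(c("tumor", "tumor", "normal", "normal"), times = gs),
    stringsAsFactors = FALSE
  )

  base_mean <- 10^runif(p, cfg$base_mean_log_range[1L],
                        cfg$base_mean_log_range[2L])
  lib_factor <- exp(rnorm(nrow(meta), 0, cfg$lib_size_sigma))
  direction <- sample(c(1, -1), p, replace = TRUE)
  lengths <- sample(seq(cfg$length_range_bp[1L], cfg$length_range_bp[2L]),
                    p, replace = TRUE)
  names(lengths) <- gene_ids

  # per-gene, per-sample fold multiplier encoding the planted class
  is_tumor <- meta$condition == "tumor"
  is_A <- meta$tissue == "A"
  fold <- matrix(1, nrow = p, ncol = nrow(meta))
  for (g in seq_len(p)) {
    boosted <- if (direction[g] > 0) is_A else !is_A
    fold[g, ] <- switch(
      cls[g],
      TISSUE = ifelse(boosted, cfg$fold_tissue, 1),
      CANCER_INVARIANT = ifelse(boosted & is_tumor, cfg$fold_cancer, 1),
      CANCER_SHARED = ifelse(is_tumor, cfg$fold_cancer^direction[g], 1),
      SHARED_NULL = 1
    )
  }

  mu <- outer(base_mean, lib_factor) * fold
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow = p, dimnames = list(gene_ids, meta$sample_id))
  storage.mode(counts) <- "integer"

  list(counts = counts,
       meta = meta,
       lengths = lengths,
       truth = data.frame(gene_id = gene_ids, class = cls,
                          stringsAsFactors = FALSE))
}

#' Attach synthetic survival outcomes to tumour samples
#'
#' Draws exponential event times for tumour samples whose hazard is
#' multiplied by `hazard_ratio` for every effect gene in which the sample
#' sits in the upper expression half (within its tissue cohort), with
#' independent exponential censoring.  Normal samples receive `NA`.
#'
#' @param expr TPM matrix (genes x samples).
#' @param meta sample metadata (`sample_id`, `tissue`, `condition`).
#' @param effect_genes character vector of prognostic genes (subset of
#'   `rownames(expr)`); may be empty for a null cohort.
#' @param hazard_ratio hazard multiplier (> 0) per high-expression gene;
#'   1 means no planted effect.
#' @param censor_rate rate of the independent exponential censoring
#'   process; 0 disables censoring.
#' @param baseline_hazard event rate for samples with no effect gene high.
#' @param seed integer seed.
#' @return `meta` with `time` and `event` columns added.
#' @export
generate_survival <- function(expr, meta, effect_genes, hazard_ratio = 3,
                              censor_rate = 0.05, baseline_hazard = 0.1,
                              seed = 1L) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  missing <- setdiff(effect_genes, rownames(expr))
  if (length(missing) > 0L) stop("effect gene not in matrix: ", missing[1L])
  set.seed(seed)
  meta$time <- NA_real_
  meta$event <- NA_integer_
  t_idx <- which(meta$condition == "tumor")
  if (length(t_idx) == 0L) stop("no tumor samples to attach survival to")

  log_hr <- rep(0, length(t_idx))
  for (g in effect_genes) {
    for (tis in unique(meta$tissue[t_idx])) {
      cohort <- t_idx[meta$tissue[t_idx] == tis]
      vals <- expr[g, meta$sample_id[cohort]]
      high <- vals > median(vals)
      log_hr[match(cohort, t_idx)] <-
        log_hr[match(cohort, t_idx)] + log(hazard_ratio) * high
    }
  }
  hazard <- baseline_hazard * exp(log_hr)
  event_time <- rexp(length(t_idx), rate = hazard)
  censor_time <- if (censor_rate > 0) {
    rexp(length(t_idx), rate = censor_rate)
  } else {
    rep(Inf, length(t_idx))
  }
  meta$time[t_idx] <- pmin(event_time, censor_time)
  meta$event[t_idx] <- as.integer(event_time <= censor_time)
  meta
}

#' Write a synthetic dataset to disk
#'
#' Emits the TSV formats the readers in this package consume:
#' `counts.tsv`, `metadata.tsv`, `gene_lengths.tsv`, `truth.tsv`.
#'
#' @param dataset result of [generate_dataset()] (optionally with survival
#'   columns from [generate_survival()] merged into `$meta`).
#' @param dir output directory, created if needed.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_matrix(dataset$counts, paths["counts"])
  write.table(dataset$meta, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = names(dataset$lengths),
                         length_bp = unname(dataset$lengths)),
              paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
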