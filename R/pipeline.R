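#' Pipeline configuration
#'
#' Collects every stage threshold in one validated object.  Defaults are
#' the published constants of the method: DE screen at `|log2FC| > 1` and
#' FDR `< 0.01`; tumour-side first-component weight cut `1.2e-5`
#' (absolute-value semantics); normal-side invariance cut `|coef| < 0.9`
#' under per-gene correlation scaling; survival alpha 0.05.
#'
#' Note the tumour weight threshold is tied to the weight scaling of the
#' tool that produced it; under this package's unit-norm weights it acts as
#' a floor that removes only non-discriminative genes.  Set `tumor_quantile`
#' to select a fixed top fraction by absolute weight instead.
#'
#' @param lfc_min,fdr_max DE-screen thresholds (strict inequalities).
#' @param tumor_threshold tumour weight cut (strict `>`).
#' @param tumor_mode `"absolute"` or `"signed"`.
#' @param tumor_quantile optional top fraction by absolute weight;
#'   overrides `tumor_threshold` when set.
#' @param pls_normalization `"unit_norm"` or `"raw"`.
#' @param invariance_scaling `"correlation"`, `"unit_norm"` or `"raw"`.
#' @param tau invariance threshold (strict `<` on `|coef|`).
#' @param invariance_method `"coef_shortcut"` or `"sq_sum"`.
#' @param sampler orthosphere sampler for `"sq_sum"`.
#' @param K number of orthosphere samples for `"sq_sum"`.
#' @param survival_alpha per-test significance level of the survival screen.
#' @param log2_transform analyse `log2(TPM + 1)` instead of TPM (off by
#'   default).
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(lfc_min = 1, fdr_max = 0.01,
                            tumor_threshold = 1.2e-5,
                            tumor_mode = "absolute",
                            tumor_quantile = NULL,
                            pls_normalization = "unit_norm",
                            invariance_scaling = "correlation",
                            tau = 0.9,
                            invariance_method = "coef_shortcut",
                            sampler = "gaussian",
                            K = 10000L,
                            survival_alpha = 0.05,
                            log2_transform = FALSE,
                            seed = 1L) {
  cfg <- list(lfc_min = lfc_min, fdr_max = fdr_max,
              tumor_threshold = tumor_threshold, tumor_mode = tumor_mode,
              tumor_quantile = tumor_quantile,
              pls_normalization = pls_normalization,
              invariance_scaling = invariance_scaling, tau = tau,
              invariance_method = invariance_method, sampler = sampler,
              K = as.integer(K), survival_alpha = survival_alpha,
              log2_transform = isTRUE(log2_transform),
              seed = as.integer(seed))
  stopifnot(cfg$lfc_min > 0, cfg$fdr_max > 0, cfg$fdr_max < 1,
            cfg$tau > 0, cfg$K >= 1,
            cfg$survival_alpha > 0, cfg$survival_alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Simulate a dataset and write it to disk
#'
#' Orchestration command: generates the synthetic four-group dataset
#' (optionally with survival outcomes planted on the cancer-specific
#' genes) and writes the TSV inputs the pipeline consumes.
#'
#' @param out_dir output directory.
#' @param cfg a [synthetic_config()].
#' @param with_survival plant survival outcomes on the `CANCER_INVARIANT`
#'   genes?
#' @param hazard_ratio,censor_rate forwarded to [generate_survival()].
#' @return file paths, invisibly; prints a one-line summary.
#' @export
cmd_simulate <- function(out_dir, cfg = synthetic_config(),
                         with_survival = FALSE, hazard_ratio = 3,
                         censor_rate = 0.05) {
  ds <- generate_dataset(cfg)
  if (with_survival) {
    tpm <- counts_to_tpm(ds$counts, ds$lengths)
    effect <- ds$truth$gene_id[ds$truth$class == "CANCER_INVARIANT"]
    ds$meta <- generate_survival(tpm, ds$meta, effect,
                                 hazard_ratio = hazard_ratio,
                                 censor_rate = censor_rate,
                                 seed = cfg$seed + 1L)
  }
  paths <- write_dataset(ds, out_dir)
  message(sprintf("simulated %d genes x %d samples (%s); classes: %s",
                  nrow(ds$counts), ncol(ds$counts),
                  paste(cfg$group_sizes, collapse = "/"),
                  paste(names(table(ds$truth$class)),
                        table(ds$truth$class), sep = "=", collapse = ", ")))
  invisible(paths)
}

#' Run the full selection pipeline
#'
#' Executes: DE screen between the two tumour classes (raw counts) ->
#' TPM conversion -> tumour/normal split -> restriction to screened genes
#' -> tumour PLS-DA weight selection -> normal-sample invariance selection
#' -> intersection; optionally cluster-purity validation and the per-gene
#' survival screen.  Every stage's output sizes are recorded in the
#' returned manifest.
#'
#' @param counts integer count matrix (genes x samples).
#' @param lengths named gene-length vector (bp).
#' @param meta sample metadata.
#' @param config a [pipeline_config()].
#' @param run_purity compute tumour/normal cluster purity over the final
#'   set?
#' @param run_survival run the survival screen (requires `time`/`event`
#'   columns)?
#' @param out_dir if non-`NULL`, write intermediate TSVs, the selection
#'   JSON and the manifest there.
#' @return list of class `pipeline_result`: `selection` (a
#'   `selection_result`), `deg_tumor`, `weights`, `cv`, `purity`,
#'   `survival`, `manifest`.
#' @export
run_pipeline <- function(counts, lengths, meta, config = pipeline_config(),
                         run_purity = TRUE, run_survival = FALSE,
                         out_dir = NULL) {
  validate_count_matrix(counts)
  validate_sample_metadata(meta)
  meta <- meta[match(colnames(counts), meta$sample_id), ]

  # stage 1: DE screen between tumour classes, on raw counts
  t_idx <- meta$condition == "tumor"
  deg_tumor <- nb_wald_screen(counts[, t_idx, drop = FALSE],
                              meta$tissue[t_idx])
  screened <- screen_genes(deg_tumor, config$lfc_min, config$fdr_max)
  if (length(screened) < 2L) {
    stop("stage deg_screen: fewer than 2 genes pass the screen")
  }

  # stage 2: TPM + split, restricted to screened genes
  tpm <- counts_to_tpm(counts, lengths)
  if (config$log2_transform) tpm <- log2(tpm + 1)
  split <- split_and_label(tpm[screened, , drop = FALSE], meta)

  # stage 3: tumour PLS-DA
  w <- plsda_first_component(split$X_T, split$y_T,
                             normalization = config$pls_normalization)
  tumor_sel <- select_by_weight(w, threshold = config$tumor_threshold,
                                mode = config$tumor_mode,
                                quantile = config$tumor_quantile)

  # stage 4: normal-sample invariance
  cv <- covariance_direction(split$X_N, split$y_N,
                             scaling = config$invariance_scaling)
  stats <- NULL
  if (config$invariance_method == "sq_sum") {
    stats <- sample_orthosphere(cv$u, K = config$K,
                                sampler = config$sampler,
                                seed = config$seed + 17L)
  }
  invariant_sel <- select_invariant(cv, tau = config$tau,
                                    method = config$invariance_method,
                                    stats = stats)

  # stage 5: intersection
  selection <- intersect_selections(
    tumor_sel, invariant_sel,
    thresholds = list(lfc_min = config$lfc_min, fdr_max = config$fdr_max,
                      tumor_threshold = config$tumor_threshold,
                      tumor_quantile = config$tumor_quantile,
                      tau = config$tau),
    provenance = list(seed = config$seed, K = config$K,
                      sampler = config$sampler,
                      scaling = config$invariance_scaling,
                      method = config$invariance_method,
                      n_screened = length(screened))
  )

  purity <- NULL
  if (run_purity && length(selection$final) >= 2L) {
    purity <- list(
      tumor = cluster_purity(split$X_T[selection$final, , drop = FALSE],
                             ifelse(split$y_T > 0, "A", "B")),
      normal = cluster_purity(split$X_N[selection$final, , drop = FALSE],
                              ifelse(split$y_N > 0, "A", "B"))
    )
  }

  surv <- NULL
  if (run_survival) {
    if (!all(c("time", "event") %in% colnames(meta))) {
      stop("stage survival: metadata lacks time/event columns")
    }
    surv <- survival_screen(tpm, meta, selection$final,
                            alpha = config$survival_alpha)
  }

  manifest <- list(
    config = unclass(config),
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_screened = length(screened),
    n_tumor_selected = length(selection$tumor_selected),
    n_normal_invariant = length(selection$normal_invariant),
    n_final = length(selection$final),
    purity_tumor = if (!is.null(purity)) as.numeric(purity$tumor) else NULL,
    purity_normal = if (!is.null(purity)) as.numeric(purity$normal) else NULL,
    n_survival_significant = if (!is.null(surv)) sum(surv$significant)
                             else NULL
  )

  out <- list(selection = selection, deg_tumor = deg_tumor,
              screened = screened, weights = w, cv = cv,
              purity = purity, survival = surv, manifest = manifest)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' Run the pipeline from files on disk
#'
#' @param counts_path,lengths_path,meta_path TSV inputs in the formats
#'   written by [write_dataset()].
#' @param ... forwarded to [run_pipeline()].
#' @export
run_pipeline_files <- function(counts_path, lengths_path, meta_path, ...) {
  run_pipeline(read_count_matrix(counts_path),
               read_gene_lengths(lengths_path),
               read_sample_metadata(meta_path), ...)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_deg_result(result$deg_tumor, file.path(out_dir, "deg_tumor.tsv"))
  write.table(data.frame(gene_id = names(result$weights$weights),
                         weight = unname(result$weights$weights)),
              file.path(out_dir, "pls_weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(result$cv$coef),
                         v_raw = unname(result$cv$v),
                         coef = unname(result$cv$coef)),
              file.path(out_dir, "covariance_coefficients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (set in c("tumor_selected", "normal_invariant", "final")) {
    writeLines(result$selection[[set]],
               file.path(out_dir, paste0(set, ".txt")))
  }
  if (!is.null(result$survival)) {
    write.table(result$survival, file.path(out_dir, "survival_screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sel <- result$selection
  jsonlite::write_json(
    list(tumor_selected = sel$tumor_selected,
         normal_invariant = sel$normal_invariant,
         final = sel$final,
         thresholds = sel$thresholds, provenance = sel$provenance),
    file.path(out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Evaluate a selection file against a truth table
#'
#' @param truth_path truth TSV (`gene_id`, `class`).
#' @param selection_path plain list of selected gene ids (one per line).
#' @return the [evaluate_selection()] report.
#' @export
cmd_evaluate <- function(truth_path, selection_path) {
  truth <- read.delim(truth_path, header = TRUE, stringsAsFactors = FALSE)
  selected <- readLines(selection_path)
  selected <- selected[nzchar(selected)]
  evaluate_selection(truth, selected)
}
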