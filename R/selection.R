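#' Intersect tumour-derived and normal-invariant gene sets
#'
#' The final cancer-specific normal-invariant set is the exact intersection
#' of the two procedures' outputs.
#'
#' @param tumor character vector of tumour-selected gene ids.
#' @param invariant character vector of normal-invariant gene ids.
#' @param thresholds optional named list of the thresholds used (recorded
#'   verbatim in the result).
#' @param provenance optional named list (seeds, K, scaling, ...).
#' @return list of class `selection_result` with `tumor_selected`,
#'   `normal_invariant`, `final` (sorted), `thresholds`, `provenance`.
#' @export
intersect_selections <- function(tumor, invariant, thresholds = list(),
                                 provenance = list()) {
  final <- sort(intersect(tumor, invariant))
  if (length(final) == 0L) {
    warning("tumor-selected and normal-invariant sets are disjoint")
  }
  out <- list(tumor_selected = sort(unique(tumor)),
              normal_invariant = sort(unique(invariant)),
              final = final,
              thresholds = thresholds,
              provenance = provenance)
  class(out) <- "selection_result"
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:",
      length(x$tumor_selected), "tumor-selected,",
      length(x$normal_invariant), "normal-invariant,",
      length(x$final), "final (intersection)\n")
  invisible(x)
}

#' Naive DE-based invariance baseline
#'
#' The comparison selection: genes that look invariant to an ordinary
#' differential-expression analysis of the two normal tissues, i.e. small
#' absolute fold change *and* large adjusted p-value (both strict).
#'
#' @param deg_normal a `deg_result` from the normal-vs-normal screen.
#' @param lfc_max keep genes with `|log2_fc| < lfc_max`.
#' @param padj_min keep genes with `p_adj > padj_min`.
#' @return sorted character vector of gene ids.
#' @export
baseline_de_selection <- function(deg_normal, lfc_max = 0.5,
                                  padj_min = 0.6) {
  if (lfc_max <= 0 || padj_min < 0 || padj_min >= 1) {
    stop("invalid baseline thresholds")
  }
  sort(deg_normal$gene_id[abs(deg_normal$log2_fc) < lfc_max &
                            deg_normal$p_adj > padj_min])
}

#' Cluster purity of samples under a gene selection
#'
#' Standardises each selected gene (z-score across samples), clusters
#' samples by average-linkage hierarchical clustering on Euclidean
#' distance, cuts into two clusters, and returns the majority-vote purity:
#' the fraction of samples whose cluster's majority class matches their
#' own.  The adjusted Rand index of the same 2-cut is attached as attribute
#' `"ari"`.
#'
#' @param expr expression matrix restricted to the selected genes
#'   (genes x samples, >= 2 genes).
#' @param labels tissue label per sample (two classes, >= 2 samples each).
#' @return numeric purity in \[0.5, 1\] with attribute `ari`.
#' @export
cluster_purity <- function(expr, labels) {
  if (nrow(expr) < 2L) stop("at least two genes are required")
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) stop("one label per sample is required")
  if (min(table(labels)) < 2L) stop("each class needs >= 2 samples")
  sds <- apply(expr, 1L, sd)
  z <- (expr - rowMeans(expr)) / ifelse(sds > 0, sds, 1)
  hc <- hclust(dist(t(z)), method = "average")
  cl <- cutree(hc, k = 2L)
  purity <- sum(tapply(labels, cl, function(l) max(table(l)))) /
    length(labels)
  ari <- mclust::adjustedRandIndex(cl, labels)
  structure(purity, ari = ari)
}

#' Score a selection against planted truth
#'
#' Precision and recall of a gene set with respect to the planted
#' `CANCER_INVARIANT` class, plus the contamination fraction contributed by
#' each gene class.
#'
#' @param truth data.frame with columns `gene_id`, `class` (the generator's
#'   truth table).
#' @param selected character vector of selected gene ids.
#' @param target_class the class counted as a true positive.
#' @return list with `precision`, `recall`, `n_selected`, `n_target`,
#'   and `contamination` (named fractions of the selection by class).
#' @export
evaluate_selection <- function(truth, selected,
                               target_class = "CANCER_INVARIANT") {
  unknown <- setdiff(selected, truth$gene_id)
  if (length(unknown) > 0L) {
    stop("selected gene absent from truth table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  target <- truth$gene_id[truth$class == target_class]
  tp <- length(intersect(selected, target))
  recall <- if (length(target) > 0L) tp / length(target) else NA_real_
  if (length(selected) == 0L) {
    warning("empty selection; precision undefined")
    precision <- NaN
    contamination <- stats::setNames(rep(NaN, length(gene_classes)),
                                     gene_classes)
  } else {
    precision <- tp / length(selected)
    sel_cls <- truth$class[match(selected, truth$gene_id)]
    contamination <- vapply(gene_classes,
                            function(k) mean(sel_cls == k), numeric(1))
  }
  list(precision = precision, recall = recall,
       n_selected = length(selected), n_target = length(target),
       contamination = contamination)
}
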