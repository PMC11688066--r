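#' First-component PLS-DA weights on tumour samples
#'
#' Mean-centres expression (per gene, across samples) and the class labels,
#' then computes the first PLS weight vector, which for a single response
#' is proportional to \eqn{X_c^T y_c} (the NIPALS first component in closed
#' form).  The sign convention fixes the weight of the gene with the
#' largest absolute covariance to be positive.
#'
#' @param X TPM matrix, genes x samples.
#' @param y numeric class labels (two distinct values, e.g. +1/-1).
#' @param normalization `"unit_norm"` (weights scaled to unit Euclidean
#'   norm, the default) or `"raw"` (the centred covariances themselves).
#' @return list of class `pls_weights` with elements `weights` (named
#'   numeric, one per gene) and `normalization`.
#' @export
plsda_first_component <- function(X, y,
                                  normalization = c("unit_norm", "raw")) {
  normalization <- match.arg(normalization)
  if (length(y) != ncol(X)) stop("one label per sample is required")
  if (ncol(X) < 4L || min(table(y)) < 2L) {
    stop("at least two samples per class are required")
  }
  y_c <- y - mean(y)
  if (all(y_c == 0)) stop("labels are constant; discrimination undefined")
  X_c <- X - rowMeans(X)
  w <- as.numeric(X_c %*% y_c)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("expression matrix is constant; no component exists")
  w <- w * sign(w[which.max(abs(w))])
  if (normalization == "unit_norm") w <- w / sqrt(sum(w^2))
  out <- list(weights = stats::setNames(w, rownames(X)),
              normalization = normalization)
  class(out) <- "pls_weights"
  out
}

#' Select genes by first-component weight
#'
#' Threshold selection on PLS weights.  The default compares absolute
#' weights, since a gene loading strongly in either direction discriminates
#' the classes; `"signed"` mode reproduces a literal one-sided cut.
#' Alternatively a quantile can be given to keep the top fraction of genes
#' by absolute weight.
#'
#' @param w a `pls_weights` object (or named numeric vector).
#' @param threshold positive weight cutoff; genes strictly above it are
#'   kept.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @param quantile if non-`NULL`, overrides `threshold`: keep the top
#'   `quantile` fraction of genes by absolute weight (e.g. 0.16).
#' @return sorted character vector of gene ids.
#' @export
select_by_weight <- function(w, threshold = NULL,
                             mode = c("absolute", "signed"),
                             quantile = NULL) {
  mode <- match.arg(mode)
  weights <- if (inherits(w, "pls_weights")) w$weights else w
  if (!is.null(quantile)) {
    if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
    threshold <- stats::quantile(abs(weights), 1 - quantile, names = FALSE)
    mode <- "absolute"
  }
  if (is.null(threshold) || threshold <= 0) {
    stop("a positive threshold (or a quantile) is required")
  }
  keep <- if (mode == "absolute") abs(weights) > threshold
          else weights > threshold
  sort(names(weights)[keep])
}
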