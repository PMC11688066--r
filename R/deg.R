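#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of the ratio of the sample's count to
#' the gene's geometric mean across samples, computed over genes whose
#' geometric mean is positive.
#'
#' @param counts integer matrix (genes x samples).
#' @return positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  validate_count_matrix(counts)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has nonzero counts in every sample; ",
         "supply a pseudo-reference or filter samples")
  }
  factors <- apply(counts[usable, , drop = FALSE], 2L, function(col) {
    exp(median(log(col) - log_geo[usable]))
  })
  if (any(!is.finite(factors) | factors <= 0)) {
    stop("degenerate size factor; too many zero counts")
  }
  factors
}

#' Negative-binomial Wald screen between two sample classes
#'
#' A transparent moment-based two-class differential-expression test on raw
#' counts: counts are normalised by size factors, per-gene class means are
#' compared on the log2 scale (pseudocount 0.5 keeps one-sided zeros
#' finite), a common within-class moment estimate of the NB dispersion
#' `alpha = max(0, (s^2 - m)/m^2)` propagates into the standard error of
#' each class mean, and the Wald statistic `log2FC / SE` is referred to a
#' standard normal.  P-values are Benjamini-Hochberg adjusted across genes.
#' All-zero genes are kept with `log2_fc = 0`, `p_value = 1`.
#'
#' @param counts integer matrix (genes x samples).
#' @param labels vector with exactly two distinct values over the samples;
#'   fold changes are reported as first (sorted) level over second.
#' @param size_factors optional positive per-sample factors; estimated by
#'   [estimate_size_factors()] when `NULL`.
#' @return data.frame of class `deg_result` with columns `gene_id`,
#'   `base_mean`, `log2_fc`, `p_value`, `p_adj`.
#' @export
nb_wald_screen <- function(counts, labels, size_factors = NULL) {
  validate_count_matrix(counts)
  if (length(labels) != ncol(counts)) {
    stop("one label per sample is required")
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("exactly two classes required")
  labels <- as.character(labels)
  n1 <- sum(labels == lv[1L]); n2 <- sum(labels == lv[2L])
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")

  norm <- sweep(counts, 2L, size_factors, "/")
  x1 <- norm[, labels == lv[1L], drop = FALSE]
  x2 <- norm[, labels == lv[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)

  # pooled within-class moment estimate of the NB dispersion
  m_pool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  s2_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  alpha <- ifelse(m_pool > 0, pmax(0, (s2_pool - m_pool) / m_pool^2), 0)

  log2_fc <- log2((m1 + 0.5) / (m2 + 0.5))
  var_mean1 <- (m1 + alpha * m1^2) / n1
  var_mean2 <- (m2 + alpha * m2^2) / n2
  se <- sqrt(var_mean1 / (m1 + 0.5)^2 + var_mean2 / (m2 + 0.5)^2) / log(2)
  z <- ifelse(se > 0, log2_fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  all_zero <- m1 == 0 & m2 == 0
  log2_fc[all_zero] <- 0
  p[all_zero] <- 1

  res <- data.frame(gene_id = rownames(counts),
                    base_mean = m_pool,
                    log2_fc = log2_fc,
                    p_value = p,
                    p_adj = bh_adjust(p),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("deg_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, clipped to 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes
#'
#' Strict thresholds on absolute log2 fold change and adjusted p-value.
#'
#' @param deg a `deg_result` from [nb_wald_screen()] (or imported TSV with
#'   the same columns, see [read_deg_result()]).
#' @param lfc_min genes must satisfy `|log2_fc| > lfc_min`.
#' @param fdr_max genes must satisfy `p_adj < fdr_max`.
#' @return sorted character vector of gene ids.
#' @export
screen_genes <- function(deg, lfc_min = 1, fdr_max = 0.01) {
  if (lfc_min <= 0 || fdr_max <= 0) stop("thresholds must be positive")
  sort(deg$gene_id[abs(deg$log2_fc) > lfc_min & deg$p_adj < fdr_max])
}

#' Read / write a differential-expression result table
#'
#' The TSV interchange format (`gene_id`, `base_mean`, `log2_fc`,
#' `p_value`, `p_adj`) also serves as the import path for screens computed
#' by external engines.
#'
#' @param path file path.
#' @return a `deg_result` data.frame.
#' @export
read_deg_result <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_fc", "p_value", "p_adj")
  if (!all(need %in% colnames(df))) {
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"base_mean" %in% colnames(df)) df$base_mean <- NA_real_
  class(df) <- c("deg_result", "data.frame")
  df
}

#' @rdname read_deg_result
#' @param deg a `deg_result`.
#' @export
write_deg_result <- function(deg, path) {
  write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
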