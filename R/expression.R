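#' Read a gene-by-sample count matrix
#'
#' Reads raw counts either from a TSV matrix (first column gene identifiers,
#' header row of sample identifiers) or from a MatrixMarket coordinate file
#' accompanied by two sidecar identifier lists (one id per line, genes =
#' rows, samples = columns).  Omitted MTX entries are zeros by the sparse
#' convention.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param gene_ids_path,sample_ids_path sidecar id files, required for
#'   `format = "mtx_triplet"`.  Default to `<path>.genes.txt` and
#'   `<path>.samples.txt`.
#' @return integer matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames, in file order.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx_triplet"),
                              gene_ids_path = paste0(path, ".genes.txt"),
                              sample_ids_path = paste0(path, ".samples.txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     colClasses = "character", stringsAsFactors = FALSE)
    gene_ids <- df[[1L]]
    sample_ids <- colnames(df)[-1L]
    cells <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
    bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric count at gene row %d, sample column %d",
                   bad[1L, 1L], bad[1L, 2L]))
    }
    counts <- num
    dimnames(counts) <- list(gene_ids, sample_ids)
  } else {
    for (f in c(gene_ids_path, sample_ids_path)) {
      if (!file.exists(f)) stop("sidecar id file not found: ", f)
    }
    m <- Matrix::readMM(path)
    counts <- as.matrix(m)
    gene_ids <- readLines(gene_ids_path)
    sample_ids <- readLines(sample_ids_path)
    if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
      stop("sidecar id lists do not match matrix dimensions")
    }
    dimnames(counts) <- list(gene_ids, sample_ids)
  }
  validate_count_matrix(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Validate a count matrix
#'
#' Checks the invariants of the raw-count container: unique gene and sample
#' identifiers, no negative and no non-integer entries.
#'
#' @param counts numeric matrix with dimnames.
#' @return the matrix, invisibly.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  }
  if (anyNA(counts)) stop("counts contain missing values")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) stop("duplicated gene id: ", dup[1L])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0L) stop("duplicated sample id: ", dup[1L])
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  invisible(counts)
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @param id_column header name of the gene-id column.
#' @export
write_count_matrix <- function(counts, path, id_column = "gene_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' TSV with columns `gene_id` and `length_bp`.
#'
#' @param path file path.
#' @return named numeric vector of lengths in base pairs.
#' @export
read_gene_lengths <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% colnames(df))) {
    stop("gene-length table needs columns gene_id, length_bp")
  }
  lengths <- df$length_bp
  names(lengths) <- df$gene_id
  if (any(lengths < 1)) stop("gene lengths must be >= 1 bp")
  lengths
}

#' Read a sample-metadata table
#'
#' TSV with columns `sample_id`, `tissue`, `condition` and optional `time`,
#' `event` (overall survival; `event = 1` means death observed).
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param meta data.frame with at least `sample_id`, `tissue`, `condition`.
#' @return the data.frame, invisibly usable.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "tissue", "condition")
  if (!all(need %in% colnames(meta))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0L) stop("duplicated sample id in metadata: ", dup[1L])
  if (!all(meta$condition %in% c("tumor", "normal"))) {
    stop("condition must be 'tumor' or 'normal'")
  }
  has_time <- "time" %in% colnames(meta)
  has_event <- "event" %in% colnames(meta)
  if (has_time != has_event) stop("time and event must be present together")
  if (has_time && any(stats::complete.cases(meta[, c("time", "event")]) &
                      (meta$time < 0), na.rm = TRUE)) {
    stop("survival times must be non-negative")
  }
  meta
}

#' Convert raw counts to TPM
#'
#' Per sample, each gene's count is divided by its length in kilobases to
#' give a read rate, and rates are rescaled so every sample column sums to
#' one million (transcripts per million).
#'
#' @param counts integer matrix (genes x samples) with dimnames.
#' @param lengths named numeric vector of gene lengths in base pairs,
#'   covering every gene of `counts`.
#' @return numeric matrix of TPM values with the same dimnames.
#' @export
counts_to_tpm <- function(counts, lengths) {
  validate_count_matrix(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L) stop("missing gene length for: ", missing[1L])
  len_kb <- lengths[rownames(counts)] / 1000
  zero_col <- which(colSums(counts) == 0)
  if (length(zero_col) > 0L) {
    stop("sample with all-zero counts, TPM undefined: ",
         colnames(counts)[zero_col[1L]])
  }
  rate <- counts / len_kb
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  tpm
}

#' Split TPM into labelled tumour and normal submatrices
#'
#' Partitions samples by `condition` and attaches the numeric tissue labels
#' used by the PLS stages.  The label convention is fixed: the
#' alphabetically first tissue level is coded +1 and the second -1 (labels
#' are mean-centred again inside the PLS computations, so the coding is
#' symmetric in the two classes even with unequal group sizes).
#'
#' @param tpm TPM matrix (genes x samples).
#' @param meta sample metadata covering every column of `tpm`.
#' @return a list of class `labeled_split` with elements `X_T`, `y_T`,
#'   `X_N`, `y_N` and `tissue_levels`.
#' @export
split_and_label <- function(tpm, meta) {
  validate_sample_metadata(meta)
  samples <- colnames(tpm)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing) > 0L) stop("metadata missing for sample: ", missing[1L])
  meta <- meta[match(samples, meta$sample_id), ]
  tissues <- sort(unique(meta$tissue))
  if (length(tissues) != 2L) stop("exactly two tissue classes required")
  code <- ifelse(meta$tissue == tissues[1L], 1, -1)
  for (cond in c("tumor", "normal")) {
    idx <- meta$condition == cond
    if (!any(idx)) stop("no ", cond, " samples in the input")
    if (length(unique(meta$tissue[idx])) < 2L) {
      stop(cond, " split contains a single tissue class; ",
           "discrimination undefined")
    }
  }
  t_idx <- meta$condition == "tumor"
  out <- list(
    X_T = tpm[, t_idx, drop = FALSE],
    y_T = code[t_idx],
    X_N = tpm[, !t_idx, drop = FALSE],
    y_N = code[!t_idx],
    tissue_levels = tissues
  )
  class(out) <- "labeled_split"
  out
}
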