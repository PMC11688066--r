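#' Median dichotomisation of expression
#'
#' Splits samples at the median: values strictly above it form the
#' high-expression group, ties at the median fall to the low group.
#'
#' @param values numeric expression vector (>= 4 samples).
#' @param method only `"median"` is implemented.
#' @return factor with levels `low`, `high`, same order as input.
#' @export
dichotomize_expression <- function(values, method = c("median")) {
  method <- match.arg(method)
  if (length(values) < 4L) stop("at least 4 samples are required")
  if (length(unique(values)) == 1L) {
    stop("all expression values identical; no split exists")
  }
  high <- values > median(values)
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function as
#' a table.
#'
#' @param times non-negative follow-up times.
#' @param events 1 = event observed, 0 = censored.
#' @return data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `survival` (the estimate just after each listed time).
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-sample log-rank test
#'
#' Standard log-rank statistic (observed minus expected event counts with
#' hypergeometric variance, summed over distinct event times), referred to
#' chi-square with 1 df.  Wraps [survival::survdiff()].
#'
#' @param times,events as in [km_estimate()].
#' @param groups two-level group indicator.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("two non-empty groups required")
  if (sum(events) < 1L) stop("no events observed; log-rank undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chi2 = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE))
}

#' Per-gene survival screen over tumour cohorts
#'
#' For every (gene, tissue cohort) pair among tumour samples with survival
#' data, dichotomises expression at the cohort median and runs the log-rank
#' test between the high- and low-expression groups.  Significance is
#' flagged per test at `p < alpha` without multiplicity correction
#' (per-gene reporting); a BH-adjusted column (`p_bh`, across all tests
#' performed) is emitted alongside for the stricter view.
#'
#' @param expr TPM matrix (genes x samples).
#' @param meta sample metadata including `time` and `event`.
#' @param genes gene ids to screen; ids absent from `expr` are skipped with
#'   a warning.
#' @param alpha per-test significance level.
#' @return data.frame of class `survival_screen` with columns `gene_id`,
#'   `cohort`, `cutpoint`, `n_low`, `n_high`, `chi2`, `p`, `p_bh`,
#'   `significant`; attribute `n_skipped` counts skipped pairs.
#' @export
survival_screen <- function(expr, meta, genes, alpha = 0.05) {
  validate_sample_metadata(meta)
  if (!all(c("time", "event") %in% colnames(meta))) {
    stop("metadata lacks survival columns time/event")
  }
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0L) {
    warning(length(absent), " gene(s) absent from the matrix, skipped")
  }
  genes <- intersect(genes, rownames(expr))
  tum <- meta[meta$condition == "tumor" &
                stats::complete.cases(meta[, c("time", "event")]), ]
  rows <- list()
  n_skipped <- length(absent)
  for (tis in sort(unique(tum$tissue))) {
    cohort <- tum[tum$tissue == tis, ]
    ids <- intersect(cohort$sample_id, colnames(expr))
    cohort <- cohort[match(ids, cohort$sample_id), ]
    for (g in genes) {
      vals <- expr[g, ids]
      res <- tryCatch({
        grp <- dichotomize_expression(vals)
        lr <- logrank_test(cohort$time, cohort$event, grp)
        data.frame(gene_id = g, cohort = tis,
                   cutpoint = median(vals),
                   n_low = sum(grp == "low"), n_high = sum(grp == "high"),
                   chi2 = lr$chi2, p = lr$p,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("skipping gene ", g, " in cohort ", tis, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) n_skipped <- n_skipped + 1L else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (length(rows) == 0L) stop("no survival test could be performed")
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  class(out) <- c("survival_screen", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}
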