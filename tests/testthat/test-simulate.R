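test_that("generator is deterministic and structurally valid", {
  cfg <- synthetic_config(seed = 3)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)

  expect_identical(nrow(a$counts), 400L)
  expect_identical(ncol(a$counts), 180L)
  # truth partitions the gene set
  expect_setequal(a$truth$gene_id, rownames(a$counts))
  expect_false(any(duplicated(a$truth$gene_id)))
  expect_true(all(a$truth$class %in% c("TISSUE", "CANCER_INVARIANT",
                                       "CANCER_SHARED", "SHARED_NULL")))
  expect_error(synthetic_config(class_fractions = c(
    TISSUE = 0.5, CANCER_INVARIANT = 0.5, CANCER_SHARED = 0.5,
    SHARED_NULL = 0.5)), "sum to 1")
})

test_that("null genes match the NB mean and planted folds are recovered", {
  cfg <- synthetic_config(
    n_genes = 60,
    group_sizes = c(tumorA = 200, tumorB = 200, normalA = 200,
                    normalB = 200),
    lib_size_sigma = 0, seed = 9
  )
  ds <- generate_dataset(cfg)
  set.seed(cfg$seed)
  base_mean <- 10^runif(cfg$n_genes, cfg$base_mean_log_range[1],
                        cfg$base_mean_log_range[2])

  null_genes <- ds$truth$gene_id[ds$truth$class == "SHARED_NULL"]
  idx <- match(null_genes, rownames(ds$counts))
  mu <- base_mean[idx]
  se <- sqrt((mu + cfg$dispersion * mu^2) / ncol(ds$counts))
  emp <- rowMeans(ds$counts[null_genes, , drop = FALSE])
  expect_true(all(abs(emp - mu) < 3 * se))

  # planted cancer-invariant genes: ~2 log2 units between tumour tissues,
  # ~0 between normal tissues
  is_t <- ds$meta$condition == "tumor"
  is_A <- ds$meta$tissue == "A"
  ratio <- function(g, cond) {
    log2(mean(ds$counts[g, cond & is_A]) / mean(ds$counts[g, cond & !is_A]))
  }
  ci <- ds$truth$gene_id[ds$truth$class == "CANCER_INVARIANT"]
  tum_r <- abs(vapply(ci, ratio, numeric(1), cond = is_t))
  nor_r <- abs(vapply(ci, ratio, numeric(1), cond = !is_t))
  expect_true(all(abs(tum_r - 2) < 0.15))
  expect_true(all(nor_r < 0.15))

  # tissue genes carry the fold in both conditions
  tg <- ds$truth$gene_id[ds$truth$class == "TISSUE"]
  expect_true(all(abs(abs(vapply(tg, ratio, numeric(1), cond = is_t)) - 2)
                  < 0.15))
  expect_true(all(abs(abs(vapply(tg, ratio, numeric(1), cond = !is_t)) - 2)
                  < 0.15))
})

test_that("synthetic survival respects censoring and planted hazards", {
  ds <- tiny_dataset()
  tpm <- counts_to_tpm(ds$counts, ds$lengths)
  expect_error(generate_survival(tpm, ds$meta, character(0),
                                 hazard_ratio = 0), "positive")

  # censor_rate = 0: every tumour sample has an observed event
  m0 <- generate_survival(tpm, ds$meta, character(0), hazard_ratio = 1,
                          censor_rate = 0, seed = 4)
  tum <- m0$condition == "tumor"
  expect_true(all(m0$event[tum] == 1L))
  expect_true(all(is.na(m0$time[!tum])))

  # planted hazard at HR 3 is detected by log-rank in most replicates
  big <- generate_dataset(synthetic_config(
    n_genes = 20,
    group_sizes = c(tumorA = 100, tumorB = 100, normalA = 2, normalB = 2),
    seed = 5))
  btpm <- counts_to_tpm(big$counts, big$lengths)
  gene <- rownames(btpm)[1]
  hits <- vapply(1:7, function(s) {
    m <- generate_survival(btpm, big$meta, gene, hazard_ratio = 3,
                           censor_rate = 0.02, seed = s)
    tum <- m$condition == "tumor" & m$tissue == "A"
    grp <- dichotomize_expression(btpm[gene, m$sample_id[tum]])
    logrank_test(m$time[tum], m$event[tum], grp)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
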