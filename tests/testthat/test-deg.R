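test_that("size factors reproduce exact library scalings", {
  base <- matrix(c(10L, 20L, 40L, 8L), 4, 1)
  m <- cbind(base, base, 2L * base)
  dimnames(m) <- list(paste0("G", 1:4), paste0("s", 1:3))
  f <- estimate_size_factors(m)
  expect_equal(unname(f[1] / f[2]), 1, tolerance = 1e-12)
  expect_equal(unname(f[3] / f[1]), 2, tolerance = 1e-12)

  # single sample: every ratio is to its own geometric mean
  single <- m[, 1, drop = FALSE]
  expect_equal(unname(estimate_size_factors(single)), 1, tolerance = 1e-12)

  # no gene expressed everywhere
  holes <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
                  dimnames = list(c("G1", "G2"), c("s1", "s2")))
  expect_error(estimate_size_factors(holes), "pseudo-reference")
})

test_that("NB Wald screen recovers planted folds and handles degenerate genes", {
  cfg <- synthetic_config(
    n_genes = 100,
    group_sizes = c(tumorA = 50, tumorB = 50, normalA = 2, normalB = 2),
    seed = 21
  )
  ds <- generate_dataset(cfg)
  tum <- ds$meta$condition == "tumor"
  counts <- ds$counts[, tum]
  # plant an all-zero gene
  counts["G0001", ] <- 0L
  deg <- nb_wald_screen(counts, ds$meta$tissue[tum])
  z <- deg[deg$gene_id == "G0001", ]
  expect_identical(z$log2_fc, 0)
  expect_identical(z$p_value, 1)

  planted <- ds$truth$gene_id[ds$truth$class %in%
                                c("TISSUE", "CANCER_INVARIANT")]
  planted <- setdiff(planted, "G0001")
  lfc <- deg$log2_fc[match(planted, deg$gene_id)]
  expect_true(all(abs(abs(lfc) - 2) < 0.3))
  expect_true(all(deg$p_adj[match(planted, deg$gene_id)] < 0.01))

  # label swap negates fold changes, keeps p-values
  swapped <- nb_wald_screen(counts,
                            ifelse(ds$meta$tissue[tum] == "A", "B", "A"))
  expect_equal(swapped$log2_fc, -deg$log2_fc, tolerance = 1e-12)
  expect_equal(swapped$p_value, deg$p_value, tolerance = 1e-12)
})

test_that("null simulation keeps the screen calibrated", {
  cfg <- synthetic_config(
    n_genes = 500,
    group_sizes = c(tumorA = 20, tumorB = 20, normalA = 2, normalB = 2),
    class_fractions = c(TISSUE = 0, CANCER_INVARIANT = 0,
                        CANCER_SHARED = 0, SHARED_NULL = 1),
    seed = 31
  )
  ds <- generate_dataset(cfg)
  tum <- ds$meta$condition == "tumor"
  deg <- nb_wald_screen(ds$counts[, tum], ds$meta$tissue[tum])
  expect_lte(length(screen_genes(deg, 1, 0.01)) / nrow(ds$counts), 0.02)
  # p-values roughly uniform: no gross inflation in the lower tail
  expect_lt(mean(deg$p_value < 0.05), 0.12)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (n in 1:10) {
    for (rep in 1:20) {
      p <- runif(n)
      expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    }
  }
})

test_that("screen_genes applies strict thresholds", {
  deg <- data.frame(gene_id = c("a", "b", "c"),
                    log2_fc = c(2, 0.5, 2),
                    p_value = c(0.001, 0.001, 0.5),
                    p_adj = c(0.001, 0.001, 0.5))
  expect_identical(screen_genes(deg, 1, 0.01), "a")
  boundary <- data.frame(gene_id = "g", log2_fc = 1, p_value = 0.001,
                         p_adj = 0.001)
  expect_length(screen_genes(boundary, 1, 0.01), 0)
  all_ns <- transform(deg, p_adj = 1)
  expect_length(screen_genes(all_ns, 1, 0.01), 0)
})

test_that("DE tables round-trip through the TSV interchange format", {
  ds <- tiny_dataset()
  tum <- ds$meta$condition == "tumor"
  deg <- nb_wald_screen(ds$counts[, tum], ds$meta$tissue[tum])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_deg_result(deg, path)
  back <- read_deg_result(path)
  expect_equal(back$log2_fc, deg$log2_fc, tolerance = 1e-9)
  expect_identical(back$gene_id, deg$gene_id)
})
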