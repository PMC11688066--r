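test_that("covariance coefficients behave at the extremes", {
  y <- c(1, 1, -1, -1)
  X <- rbind(
    marker = c(1, 1, -1, -1),   # exact copy of the labels
    ortho  = c(1, 0, 1, 0),     # zero covariance with the labels
    flat   = c(3, 3, 3, 3)      # constant
  )
  colnames(X) <- paste0("s", 1:4)
  cv <- covariance_direction(X, y)
  expect_equal(unname(cv$coef["marker"]), 1, tolerance = 1e-12)
  expect_equal(unname(cv$coef["ortho"]), 0, tolerance = 1e-12)
  expect_identical(unname(cv$coef["flat"]), 0)
  expect_true(all(abs(cv$coef) <= 1 + 1e-12))

  cvu <- covariance_direction(X, y, scaling = "unit_norm")
  expect_equal(sum(cvu$coef^2), 1, tolerance = 1e-10)
  expect_error(covariance_direction(X, rep(2, 4)), "constant")
})

test_that("Gram-Schmidt basis is orthonormal and completes the identity", {
  for (p in c(3, 20, 200)) {
    set.seed(p)
    u <- rnorm(p)
    u <- u / sqrt(sum(u^2))
    B <- gram_schmidt_basis(u, seed = 2)
    expect_identical(dim(B), as.integer(c(p, p - 1)))
    expect_lt(max(abs(crossprod(B) - diag(p - 1L))), 1e-10)
    expect_lt(max(abs(crossprod(B, u))), 1e-10)
    expect_lt(max(abs(tcrossprod(u) + tcrossprod(B) - diag(p))), 1e-10)
  }
  # axis-aligned case spans the remaining axes
  B <- gram_schmidt_basis(c(1, 0, 0), seed = 2)
  expect_lt(max(abs(B[1, ])), 1e-12)
  expect_error(gram_schmidt_basis(c(0, 0, 0)), "unit")
})

test_that("expected squared weight is the exact subsphere second moment", {
  expect_equal(expected_squared_weight(c(1, 0, 0)), c(0, 0.5, 0.5))
  set.seed(8)
  for (p in c(5, 50)) {
    u <- rnorm(p)
    u <- u / sqrt(sum(u^2))
    e <- expected_squared_weight(u)
    expect_equal(sum(e), 1, tolerance = 1e-12)
    # strictly decreasing in |u_i|
    o <- order(abs(u))
    expect_true(all(diff(e[o]) < 0))
  }
})

test_that("both samplers satisfy the unit-norm and orthogonality constraints", {
  set.seed(14)
  u <- rnorm(12)
  u <- u / sqrt(sum(u^2))
  for (s in c("gaussian", "angles")) {
    st <- sample_orthosphere(u, K = 500, sampler = s, seed = 6)
    # each w is a unit vector, so the squared weights sum to K over genes
    expect_equal(unname(sum(st$sq_sum)), 500, tolerance = 1e-6 * 500)
    expect_true(all(st$sq_sum >= 0))
  }
  expect_error(sample_orthosphere(u, 0), "at least 1")
  # determinism under the seed
  a <- sample_orthosphere(u, 200, seed = 3)
  b <- sample_orthosphere(u, 200, seed = 3)
  expect_identical(a, b)
})

test_that("gaussian sampler reproduces the analytic circle moments at p = 3", {
  st <- sample_orthosphere(c(1, 0, 0), K = 10000, seed = 19)
  se <- orthosphere_moment_se(c(1, 0, 0), 10000)
  emp <- st$sq_sum / 10000
  expect_lt(abs(emp[1] - 0), 1e-12)
  expect_lt(abs(emp[2] - 0.5), 3 * se[2])
  expect_lt(abs(emp[3] - 0.5), 3 * se[3])
})

test_that("sampled squared weights anticorrelate with |u| (shortcut direction)", {
  # same geometry as the selection stage: a data-derived unit direction
  ds <- generate_dataset(synthetic_config(n_genes = 100, seed = 7))
  tpm <- counts_to_tpm(ds$counts, ds$lengths)
  sp <- split_and_label(tpm, ds$meta)
  cv <- covariance_direction(sp$X_N, sp$y_N, scaling = "unit_norm")
  st <- sample_orthosphere(cv$u, K = 50000, seed = 13)
  expect_lt(cor(st$sq_sum / 50000, abs(cv$u)), -0.9)
})

test_that("gene-order permutation permutes the deterministic outputs", {
  ds <- tiny_dataset(seed = 23)
  tpm <- counts_to_tpm(ds$counts, ds$lengths)
  sp <- split_and_label(tpm, ds$meta)
  set.seed(16)
  perm <- sample(nrow(tpm))
  cv <- covariance_direction(sp$X_N, sp$y_N)
  cvp <- covariance_direction(sp$X_N[perm, ], sp$y_N)
  expect_equal(cvp$coef, cv$coef[perm], tolerance = 1e-12)
  expect_identical(select_invariant(cvp, 0.9), select_invariant(cv, 0.9))
  u <- cv$u
  expect_equal(unname(expected_squared_weight(u[perm])),
               unname(expected_squared_weight(u))[perm], tolerance = 1e-12)
})

test_that("invariant selection applies the strict coefficient rule", {
  cv <- structure(list(coef = c(g1 = 0.95, g2 = 0.5, g3 = 0.0),
                       u = c(g1 = 0.95, g2 = 0.5, g3 = 0.0),
                       scaling = "correlation"),
                  class = "covariant_vector")
  expect_identical(select_invariant(cv, 0.9), c("g2", "g3"))
  cv$coef["g1"] <- 0.9
  expect_identical(select_invariant(cv, 0.9), c("g2", "g3"))
  expect_error(select_invariant(cv, 1.5), "tau")
})
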