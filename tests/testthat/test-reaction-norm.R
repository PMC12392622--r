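test_that("perfectly linear accessions are fit exactly", {
  idx <- stats::setNames(c(1, 2, 4, 7, 9), paste0("E", 1:5))
  ph <- norm_pheno(intercepts = c(3, 10), slopes = c(2, -1), index = idx)
  fits <- fit_reaction_norms(ph, idx)
  expect_equal(fits$slope, c(2, -1), tolerance = 1e-12)
  # intercept at the mean index equals the across-environment mean
  expect_equal(fits$intercept, unname(rowMeans(ph$values[, , 1])),
               tolerance = 1e-12)
  expect_equal(fits$r_squared, c(1, 1))
  expect_equal(fits$abs_slope, c(2, 1))
})

test_that("constant trajectories give zero slope", {
  idx <- stats::setNames(c(1, 2, 4, 7), paste0("E", 1:4))
  ph <- norm_pheno(intercepts = 5, slopes = 0, index = idx)
  fits <- fit_reaction_norms(ph, idx)
  expect_equal(fits$slope, 0)
  expect_equal(fits$intercept, 5)
})

test_that("noiseless synthetic data refit recovers the stored truth", {
  cfg <- tiny_config(residual_sd = 0)
  st <- simulate_study(cfg)
  ei <- st$truth$env_index
  fits <- fit_reaction_norms(st$pheno, ei, "T01", anchor = "global")
  expect_equal(unname(fits$slope), unname(st$truth$slope[, 1]),
               tolerance = 1e-8)
  expect_equal(unname(fits$intercept),
               unname(st$truth$intercept[, 1] +
                        st$truth$slope[, 1] * 0),
               tolerance = 1e-8)
})

test_that("index shifts and rescalings do not leak into the parameters", {
  st <- tiny_study()
  ei <- st$truth$env_index
  f0 <- fit_reaction_norms(st$pheno, ei, "T01", anchor = "global")
  f_shift <- fit_reaction_norms(st$pheno, ei + 100, "T01",
                                anchor = "global")
  expect_equal(f0$slope, f_shift$slope, tolerance = 1e-9)
  expect_equal(f0$intercept, f_shift$intercept, tolerance = 1e-8)
  f_scale <- fit_reaction_norms(st$pheno, ei * 3, "T01", anchor = "global")
  expect_equal(f0$intercept, f_scale$intercept, tolerance = 1e-8)
  expect_equal(f0$slope, f_scale$slope * 3, tolerance = 1e-9)
})

test_that("sparse accessions are marked missing, not fabricated", {
  idx <- stats::setNames(c(1, 2, 4, 7), paste0("E", 1:4))
  ph <- norm_pheno(intercepts = c(1, 2), slopes = c(1, 1), index = idx)
  ph$values[2, 3:4, 1] <- NA
  fits <- fit_reaction_norms(ph, idx)
  expect_true(is.na(fits$slope[2]))
  expect_equal(fits$n_env[2], 2L)
  expect_false(is.na(fits$slope[1]))
  expect_error(fit_reaction_norms(ph, idx * 0 + 1), "degenerate index")
})

test_that("per-accession anchoring kicks in under heavy missingness", {
  idx <- stats::setNames(c(1, 2, 4, 7, 9, 12), paste0("E", 1:6))
  ph <- norm_pheno(intercepts = rep(2, 10), slopes = rep(1.5, 10),
                   index = idx)
  ph$values[1:5, 5:6, 1] <- NA  # > 5% missing -> per-accession anchors
  fits <- fit_reaction_norms(ph, idx, anchor = "auto")
  expect_equal(fits$anchor[1], mean(idx[1:4]))
  expect_equal(fits$anchor[6], mean(idx))
  fg <- fit_reaction_norms(ph, idx, anchor = "global")
  expect_equal(fg$anchor, rep(mean(idx), 10))
})

test_that("parameter correlations see through linear trait links", {
  st <- tiny_study()
  ei <- st$truth$env_index
  # trait T02 replaced by 2 x T01: correlations must be exactly 1
  ph <- st$pheno
  ph$values[, , 2] <- 2 * ph$values[, , 1]
  fits <- fit_reaction_norms(ph, ei)
  pc <- parameter_correlations(fits)
  row <- pc$pairs[pc$pairs$trait1 == "T01" & pc$pairs$trait2 == "T02", ]
  expect_equal(row$intercept_r, 1, tolerance = 1e-9)
  expect_equal(row$abs_slope_r, 1, tolerance = 1e-9)
  expect_true(row$intercept_strong)
  # pair count is choose(n_traits, 2)
  expect_equal(nrow(pc$pairs), 1L)
})

test_that("independent traits correlate near zero across many accessions", {
  set.seed(5)
  idx <- stats::setNames(sort(rnorm(8, 10, 3)), paste0("E", 1:8))
  n <- 406
  v <- array(NA_real_, c(n, 8, 4),
             dimnames = list(sprintf("A%03d", 1:n), names(idx),
                             paste0("T", 1:4)))
  for (t in 1:4) {
    v[, , t] <- outer(rnorm(n), rep(1, 8)) +
      outer(rnorm(n, 1, 0.5), idx - mean(idx)) +
      0.2 * matrix(rnorm(n * 8), n)
  }
  fits <- fit_reaction_norms(pheno_tensor(v), idx)
  pc <- parameter_correlations(fits)
  expect_equal(nrow(pc$pairs), choose(4, 2))
  expect_lt(mean(abs(pc$pairs$intercept_r)), 0.1)
  expect_lt(mean(abs(pc$pairs$abs_slope_r)), 0.1)
})

test_that("trajectory consistency counts and bounds behave", {
  idx <- stats::setNames(c(1, 3, 4, 8, 10), paste0("E", 1:5))
  # shared shape plus offsets: every pair has rho = 1
  ph <- norm_pheno(intercepts = 1:6, slopes = rep(1, 6), index = idx)
  tc <- trajectory_consistency(ph, "T1")
  expect_equal(tc$n_pairs, choose(6, 2))
  expect_equal(tc$mean_rho, 1)
  expect_equal(tc$sd_rho, 0)
  # exactly reversed ranks give rho = -1 for that pair
  ph2 <- norm_pheno(intercepts = c(0, 0), slopes = c(1, -1), index = idx)
  tc2 <- trajectory_consistency(ph2, "T1")
  expect_equal(tc2$mean_rho, -1)
  # pairs with < 3 shared environments are skipped and counted
  ph3 <- norm_pheno(intercepts = c(0, 0, 0), slopes = c(1, 2, 3),
                    index = idx)
  ph3$values[1, 1:2, 1] <- NA
  ph3$values[2, 4:5, 1] <- NA  # pair (1,2) shares only one environment
  tc3 <- trajectory_consistency(ph3, "T1")
  expect_equal(tc3$n_skipped, 1L)
  expect_equal(tc3$n_pairs, 2L)
})
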