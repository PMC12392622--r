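test_that("heritability formulas do their arithmetic", {
  expect_equal(heritability_within(1, 1, 1), 0.5)
  expect_equal(heritability_within(1, 0, 3), 1)
  expect_equal(heritability_within(1, 3, 3), 0.5)
  expect_equal(heritability_across(1, 0, 0, 3, 10), 1)
  expect_equal(heritability_across(1, 10, 0, 3, 10), 0.5)
  # across reduces to within when e = 1 and no GxE
  expect_equal(heritability_across(2, 0, 1.4, 3, 1),
               heritability_within(2, 1.4, 3))
  expect_warning(h <- heritability_within(0, 0, 2), "undefined")
  expect_true(is.na(h))
})

balanced_gxe <- function(n_g = 120, n_e = 8, r = 3, sg = 2, se = 1,
                         sge = 0.7, sres = 0.5, seed = 3) {
  set.seed(seed)
  g <- rnorm(n_g, 0, sg)
  e <- rnorm(n_e, 0, se)
  ge <- matrix(rnorm(n_g * n_e, 0, sge), n_g)
  d <- expand.grid(accession = sprintf("G%03d", 1:n_g),
                   environment = sprintf("E%02d", 1:n_e),
                   replicate = seq_len(r), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  gi <- match(d$accession, sprintf("G%03d", 1:n_g))
  ei <- match(d$environment, sprintf("E%02d", 1:n_e))
  d$value <- 10 + g[gi] + e[ei] + ge[cbind(gi, ei)] + rnorm(nrow(d), 0, sres)
  d
}

test_that("EMS and REML agree on balanced designs", {
  d <- balanced_gxe()
  vc_ems <- partition_variance(d, method = "ems")
  vc_reml <- partition_variance(d, method = "reml")
  expect_equal(vc_ems$variance, vc_reml$variance, tolerance = 1e-6)
  expect_equal(sum(vc_ems$percent), 100, tolerance = 1e-9)
  expect_identical(attr(vc_ems, "method"), "ems")
  expect_identical(attr(vc_reml, "method"), "reml")
})

test_that("variance components recover the generating values", {
  d <- balanced_gxe(n_g = 200, n_e = 10, r = 3, sg = 2, se = 1, sge = 0,
                    sres = 1, seed = 8)
  vc <- suppressWarnings(partition_variance(d, method = "auto"))
  v <- stats::setNames(vc$variance, vc$component)
  expect_lt(abs(v["genotype"] - 4) / 4, 0.15)
  expect_lt(abs(v["environment"] - 1) / 1, 0.35)  # only 10 environment draws
  expect_lt(abs(v["residual"] - 1) / 1, 0.15)
  expect_lt(v["gxe"], 0.15)
})

test_that("pure-noise data attributes nothing to genotype", {
  set.seed(12)
  d <- expand.grid(accession = sprintf("G%03d", 1:200),
                   environment = sprintf("E%02d", 1:6),
                   replicate = 1:2, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  vc <- suppressWarnings(partition_variance(d))
  g_share <- vc$percent[vc$component == "genotype"]
  expect_lt(g_share, 2)
})

test_that("partition is invariant to relabeling", {
  d <- balanced_gxe(n_g = 40, n_e = 5, r = 2)
  vc1 <- partition_variance(d)
  d2 <- d
  perm <- sample(unique(d$accession))
  d2$accession <- perm[match(d$accession, unique(d$accession))]
  vc2 <- partition_variance(d2)
  expect_equal(vc1$variance, vc2$variance, tolerance = 1e-8)
})

test_that("environment-mean input flags GxE as confounded", {
  st <- tiny_study()
  ph <- pheno_tensor(st$pheno$values, replicates = NULL,
                     groups = st$pheno$groups)
  vc <- partition_variance(ph, "T01")
  expect_true(attr(vc, "confounded"))
  expect_true(is.na(vc$variance[vc$component == "gxe"]))
})

test_that("tensor PCA reshapes and normalizes correctly", {
  st <- tiny_study()
  pc <- tensor_pca(st$pheno, "accession")
  expect_equal(length(pc$percent_var),
               min(dim(st$pheno$values)[1],
                   prod(dim(st$pheno$values)[2:3])))
  expect_true(all(diff(pc$percent_var) <= 1e-8))
  expect_equal(sum(pc$percent_var), 100, tolerance = 1e-8)
  # environment mode is bounded by the number of environments
  pce <- tensor_pca(st$pheno, "environment")
  expect_lte(nrow(pce$scores), dim(st$pheno$values)[2])
  # rank-1 structure puts 100% on PC1
  idx <- stats::setNames(c(1, 2, 4, 8, 9), paste0("E", 1:5))
  ph1 <- norm_pheno(intercepts = rep(0, 20), slopes = rnorm(20, 2, 1),
                    index = idx)
  pc1 <- tensor_pca(ph1, "accession")
  expect_equal(pc1$percent_var[1], 100, tolerance = 1e-6)
  # missing values must be imputed first
  phm <- st$pheno
  phm$values[1, 1, 1] <- NA
  expect_error(tensor_pca(phm, "accession"), "impute")
})

test_that("PCA percentages match the eigenvalues of the scaled covariance", {
  st <- tiny_study()
  pc <- tensor_pca(st$pheno, "environment")
  m <- matrix(aperm(st$pheno$values, c(2, 1, 3)),
              dim(st$pheno$values)[2])
  m <- scale(m)
  ev <- svd(m)$d^2
  expect_equal(pc$percent_var, 100 * ev / sum(ev), tolerance = 1e-6)
})

test_that("imputation honours observed cells and is deterministic", {
  st <- tiny_study()
  ph <- st$pheno
  expect_identical(impute_missing(ph)$values, ph$values)
  set.seed(2)
  mask <- cbind(sample(50, 30, TRUE), sample(8, 30, TRUE),
                sample(2, 30, TRUE))
  phm <- ph
  phm$values[mask] <- NA
  imp1 <- impute_missing(phm, method = "ridge")
  imp2 <- impute_missing(phm, method = "ridge")
  expect_identical(imp1$values, imp2$values)
  obs <- !is.na(phm$values)
  expect_equal(imp1$values[obs], phm$values[obs])
  expect_true(all(!is.na(imp1$values)))
})

test_that("the index-regression imputer nails noiseless reaction norms", {
  cfg <- tiny_config(residual_sd = 0, n_traits = 1)
  st <- simulate_study(cfg)
  ph <- st$pheno
  truthv <- ph$values
  set.seed(4)
  holes <- cbind(sample(50, 20, TRUE), sample(8, 20, TRUE), 1L)
  ph$values[holes] <- NA
  imp <- impute_missing(ph, method = "index", index = st$truth$env_index)
  expect_equal(imp$values[holes], truthv[holes], tolerance = 1e-6)
})

test_that("entirely missing slabs stay missing and are flagged", {
  st <- tiny_study()
  ph <- st$pheno
  ph$values[, 2, 2] <- NA
  imp <- impute_missing(ph, method = "ridge")
  expect_true(all(is.na(imp$values[, 2, 2])))
  expect_true(attr(imp, "unimputable")[2, 2])
  expect_true(all(!is.na(imp$values[, , 1])))
})
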