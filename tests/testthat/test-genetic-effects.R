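scan_fixture <- function(n = 120, p = 60, seed = 2, qtl_share = 0) {
  set.seed(seed)
  freq <- runif(p, 0.1, 0.9)
  M <- sapply(freq, function(q) rbinom(n, 1, q) * 2)
  dimnames(M) <- list(sprintf("A%03d", 1:n), sprintf("M%03d", 1:p))
  y <- rnorm(n)
  if (qtl_share > 0) {
    g <- scale(M[, 1])[, 1]
    y <- sqrt(qtl_share) * g + sqrt(1 - qtl_share) * scale(y)[, 1]
  }
  list(M = M, y = stats::setNames(y, rownames(M)))
}

test_that("scan effects equal the full-model partial coefficients", {
  fx <- scan_fixture()
  res <- gwas_scan(fx$M, fx$y, n_pcs = 3)
  Mc <- scale(fx$M, scale = FALSE)
  pcs <- svd(Mc)$u[, 1:3]
  for (m in sample(res$marker, 5)) {
    ref <- stats::lm(fx$y ~ fx$M[, m] + pcs)
    expect_equal(res$effect[res$marker == m],
                 unname(stats::coef(ref)[2]), tolerance = 1e-8)
    expect_equal(res$p[res$marker == m],
                 summary(ref)$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("monomorphic markers are skipped with a reason", {
  fx <- scan_fixture()
  fx$M[, 5] <- 0
  res <- gwas_scan(fx$M, fx$y)
  sk <- attr(res, "skipped")
  expect_true("M005" %in% sk$marker)
  expect_match(sk$reason[sk$marker == "M005"], "monomorphic")
  expect_false("M005" %in% res$marker)
  expect_error(gwas_scan(fx$M[1:30, ], fx$y[1:30]), "at least 50")
})

test_that("a strong planted QTL is found reliably", {
  hits <- vapply(1:20, function(seed) {
    fx <- scan_fixture(n = 400, p = 1000, seed = 100 + seed,
                       qtl_share = 0.2)
    res <- gwas_scan(fx$M, fx$y)
    res$passes_threshold[res$marker == "M001"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("allelic-effect trajectories recover planted dynamics", {
  idx <- stats::setNames(c(2, 4, 5, 8, 10, 13), paste0("E", 1:6))
  n <- 80
  set.seed(9)
  dos <- rbinom(n, 1, 0.5) * 2
  acc <- sprintf("A%03d", 1:n)
  geno <- genotype_matrix(
    matrix(dos, ncol = 1, dimnames = list(acc, "Mq")),
    data.frame(marker = "Mq", chrom = "1A", pos = 1, ref = "A", alt = "T",
               stringsAsFactors = FALSE))
  base_int <- rnorm(n, 10, 0.01)
  # carriers of the alt allele sit exactly +2 higher in every environment
  v <- array(outer(base_int, rep(1, 6)) + 2 * (dos / 2),
             dim = c(n, 6, 1),
             dimnames = list(accession = acc, environment = names(idx),
                             trait = "T1"))
  ph <- pheno_tensor(v)
  tr <- effect_trajectory(geno, ph, "Mq", "T1", idx)
  # the 0.01-SD jitter on the baseline shifts the mean difference a hair
  expect_equal(tr$regression$slope, 0, tolerance = 1e-3)
  expect_equal(tr$regression$intercept, 2, tolerance = 1e-2)
  expect_equal(tr$base_dosage, 0)
  expect_identical(tr$classification, "differential_sensitivity")
  # effect proportional to the index: slope recovered exactly
  v2 <- v
  for (e in 1:6) v2[, e, 1] <- base_int + 0.1 * idx[e] * (dos / 2)
  tr2 <- effect_trajectory(geno, pheno_tensor(v2), "Mq", "T1", idx)
  expect_equal(tr2$regression$slope, 0.1, tolerance = 1e-8)
})

test_that("the base allele is the one with the lower intercept", {
  idx <- stats::setNames(c(1, 3, 6, 9), paste0("E", 1:4))
  n <- 40
  set.seed(11)
  dos <- c(rep(0, 20), rep(2, 20))
  acc <- sprintf("A%03d", 1:n)
  geno <- genotype_matrix(
    matrix(dos, ncol = 1, dimnames = list(acc, "Mq")),
    data.frame(marker = "Mq", chrom = "1A", pos = 1, ref = "A", alt = "T",
               stringsAsFactors = FALSE))
  # dosage-0 carriers are HIGHER: base allele must be dosage 2
  v <- array(outer(10 - 3 * (dos / 2) * -1, rep(1, 4)) + rnorm(n * 4, 0, 0.01),
             dim = c(n, 4, 1),
             dimnames = list(accession = acc, environment = names(idx),
                             trait = "T1"))
  v[, , 1] <- outer(ifelse(dos == 0, 13, 10), rep(1, 4)) +
    rnorm(n * 4, 0, 0.01)
  tr <- effect_trajectory(geno, pheno_tensor(v), "Mq", "T1", idx)
  expect_equal(tr$base_dosage, 2)
  expect_true(all(tr$effects$effect > 2.5))
})

test_that("dynamics classification matches its definitions", {
  mk <- function(effect, p) data.frame(effect = effect, p = p)
  expect_identical(classify_dynamics(mk(c(1, 2, 3), c(0.01, 0.01, 0.01))),
                   "differential_sensitivity")
  expect_identical(classify_dynamics(mk(c(1, 0.05, 2), c(0.01, 0.8, 0.01))),
                   "conditional_neutrality")
  expect_identical(classify_dynamics(mk(c(1, -1), c(0.01, 0.01))),
                   "antagonistic_pleiotropy")
  expect_identical(classify_dynamics(mk(1, 0.01)), "unclassifiable")
  # all-nonsignificant trajectories are magnitude-only variation
  expect_identical(classify_dynamics(mk(c(0.1, -0.1), c(0.5, 0.6))),
                   "differential_sensitivity")
})

test_that("haplotype tables enumerate, count and test correctly", {
  st <- tiny_study()
  ei <- st$truth$env_index
  fits <- fit_reaction_norms(st$pheno, ei, "T01")
  loci <- st$truth$qtl$T01$intercept$marker
  ht <- haplotype_analysis(st$geno, loci, fits)
  expect_equal(attr(ht, "n_possible"), 2^length(loci))
  expect_equal(nrow(ht), 2^length(loci))
  expect_equal(sum(ht$count), nrow(st$geno$dosage))
  expect_equal(sum(ht$freq), 1, tolerance = 1e-12)
  obs <- ht$freq_landrace[!is.na(ht$freq_landrace)]
  expect_equal(sum(obs), 1, tolerance = 1e-12)
  expect_equal(sum(ht$freq_cultivar, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_identical(ht$label, paste0("HAP", 1:8))
  expect_true(all(diff(ht$count) <= 0))
})

test_that("group enrichment folds track planted frequency differences", {
  set.seed(14)
  n <- 400
  acc <- sprintf("A%03d", 1:n)
  groups <- factor(rep(c("landrace", "cultivar"), each = n / 2))
  names(groups) <- acc
  map <- data.frame(marker = "Mq", chrom = "1A", pos = 1, ref = "G",
                    alt = "T", stringsAsFactors = FALSE)
  fits <- structure(data.frame(accession = acc, trait = "T1",
                               intercept = rnorm(n),
                               stringsAsFactors = FALSE),
                    class = c("reaction_norm_fit", "data.frame"))
  # binomial simulation: carrier frequencies 0.2 vs 0.4 give fold ~2
  p_of <- ifelse(groups == "landrace", 0.2, 0.4)
  folds <- replicate(30, {
    dos <- rbinom(n, 1, p_of) * 2
    geno <- genotype_matrix(
      matrix(dos, ncol = 1, dimnames = list(acc, "Mq")), map,
      groups = groups)
    ht <- haplotype_analysis(geno, "Mq", fits)
    ht$enrichment_fold[ht$haplotype == "T"]
  })
  expect_lt(abs(mean(folds) - 2), 0.3)
  dos <- rbinom(n, 1, p_of) * 2
  geno <- genotype_matrix(
    matrix(dos, ncol = 1, dimnames = list(acc, "Mq")), map,
    groups = groups)
  # equal group frequencies give fold ~1 by construction
  dos_eq <- rbinom(n, 1, 0.3) * 2
  geno_eq <- genotype_matrix(
    matrix(dos_eq, ncol = 1, dimnames = list(acc, "Mq")),
    geno$map, groups = groups)
  ht_eq <- haplotype_analysis(geno_eq, "Mq", fits)
  expect_lt(abs(ht_eq$enrichment_fold[1] - 1), 0.25)
  # a haplotype absent from landraces is flagged, not divided by zero
  dos_abs <- ifelse(groups == "landrace", 0, rbinom(n, 1, 0.3) * 2)
  geno_abs <- genotype_matrix(
    matrix(dos_abs, ncol = 1, dimnames = list(acc, "Mq")),
    geno$map, groups = groups)
  ht_abs <- haplotype_analysis(geno_abs, "Mq", fits)
  arow <- ht_abs[ht_abs$haplotype == "T", ]
  expect_true(arow$enrichment_infinite)
  expect_true(is.na(arow$enrichment_fold))
})
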