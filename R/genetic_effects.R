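# Single-marker PC-adjusted association scan, per-environment allelic
# effect trajectories with dynamics classification, and haplotype analysis.

#' PC-adjusted single-marker association scan
#'
#' For each marker, tests the dosage coefficient in
#' `y ~ dosage + PC1 + ... + PCk`, with the principal components computed
#' from the centered dosage matrix to adjust for population structure.
#' Implemented by residualizing both the phenotype and every marker on the
#' covariates (Frisch-Waugh), which reproduces the full-model partial
#' regression coefficient exactly. Monomorphic markers and markers
#' collinear with the covariates are skipped with a reason. Significance
#' uses a Bonferroni threshold `alpha / markers tested` by default.
#'
#' @param geno A [genotype_matrix()] (or dosage matrix).
#' @param y Named numeric vector of the parameter under test
#'   (reaction-norm intercepts or slopes).
#' @param n_pcs Principal components included as fixed effects (default 3).
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_n Minimum sample size (default 50).
#' @return An `association_result` data frame: `marker`, `chrom`, `pos`,
#'   `effect`, `se`, `t`, `p`, `passes_threshold`; attributes `skipped`
#'   (data frame of excluded markers with reasons), `threshold`, `n`.
#' @export
gwas_scan <- function(geno, y, n_pcs = 3, alpha = 0.05, min_n = 50) {
  dosage <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  map <- if (inherits(geno, "genotype_matrix")) geno$map else NULL
  y <- y[!is.na(y)]
  acc <- intersect(rownames(dosage), names(y))
  n <- length(acc)
  if (n < min_n) stop("need at least ", min_n, " accessions", call. = FALSE)
  M <- dosage[acc, , drop = FALSE]
  yv <- as.numeric(y[acc])
  mono <- apply(M, 2, stats::sd) == 0
  skipped <- data.frame(marker = colnames(M)[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  M <- M[, !mono, drop = FALSE]
  Mc <- scale(M, center = TRUE, scale = FALSE)
  k <- min(n_pcs, n - 2, ncol(Mc))
  sv <- svd(Mc, nu = k, nv = 0)
  X <- cbind(1, sv$u[, seq_len(k), drop = FALSE])
  qx <- qr(X)
  ry <- qr.resid(qx, yv)
  RM <- qr.resid(qx, M)
  sxx <- colSums(RM^2)
  tol <- 1e-10 * n
  collinear <- sxx <= tol
  if (any(collinear)) {
    skipped <- rbind(skipped, data.frame(
      marker = colnames(M)[collinear],
      reason = rep("collinear with covariates", sum(collinear)),
      stringsAsFactors = FALSE))
  }
  keep <- !collinear
  eff <- colSums(RM[, keep, drop = FALSE] * ry) / sxx[keep]
  df <- n - ncol(X) - 1
  ssr <- pmax(sum(ry^2) - eff^2 * sxx[keep], 0)
  se <- sqrt(ssr / df / sxx[keep])
  tstat <- ifelse(se > 0, eff / se, Inf * sign(eff))
  p <- 2 * stats::pt(-abs(tstat), df)
  m_tested <- sum(keep)
  thr <- alpha / m_tested
  out <- data.frame(marker = colnames(M)[keep], effect = eff, se = se,
                    t = tstat, p = p, passes_threshold = p < thr,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    mi <- match(out$marker, map$marker)
    out$chrom <- map$chrom[mi]
    out$pos <- map$pos[mi]
    out <- out[, c("marker", "chrom", "pos", "effect", "se", "t", "p",
                   "passes_threshold")]
  }
  structure(out, class = c("association_result", class(out)),
            skipped = skipped, threshold = thr, n = n, df = df)
}

#' Per-environment allelic effects of a marker
#'
#' Splits accessions into the two homozygous allele classes (heterozygotes
#' and missing calls are excluded), sets the base allele as the one whose
#' carriers have the lower mean reaction-norm intercept, and estimates the
#' allelic effect in each environment as the mean phenotypic difference
#' (alternative minus base) with a Welch t-test. The effects are then
#' regressed on the environmental index, and the trajectory is classified
#' with [classify_dynamics()].
#'
#' @param geno A [genotype_matrix()].
#' @param pheno A [pheno_tensor()].
#' @param marker Marker name.
#' @param trait Trait name.
#' @param index Named per-environment environmental index.
#' @param fits Optional `reaction_norm_fit` (computed from `pheno` and
#'   `index` when absent) used to pick the base allele.
#' @param alpha Per-environment significance level (default 0.05,
#'   unadjusted; the classification is descriptive).
#' @param min_carriers Minimum carriers per allele class per environment
#'   for an estimable effect (default 5).
#' @return An `effect_trajectory`: `effects` data frame (environment,
#'   index, effect, p, n_base, n_alt, estimable), `regression`
#'   (intercept, slope of effect on index), `base_dosage`, and
#'   `classification`.
#' @export
effect_trajectory <- function(geno, pheno, marker, trait, index,
                              fits = NULL, alpha = 0.05, min_carriers = 5) {
  dos <- geno$dosage[, marker]
  acc <- accessions(pheno)
  dos <- dos[acc]
  keep <- !is.na(dos) & dos != 1
  if (sum(dos[keep] == 0) < min_carriers ||
      sum(dos[keep] == 2) < min_carriers) {
    stop("both alleles need at least ", min_carriers, " carriers",
         call. = FALSE)
  }
  if (is.null(fits)) {
    fits <- fit_reaction_norms(pheno, index, trait)
  }
  fi <- fits[fits$trait == trait, ]
  ints <- stats::setNames(fi$intercept, fi$accession)[acc]
  mean0 <- mean(ints[keep & dos == 0], na.rm = TRUE)
  mean2 <- mean(ints[keep & dos == 2], na.rm = TRUE)
  base_dosage <- if (mean0 <= mean2) 0 else 2
  envs <- intersect(environments(pheno), names(index))
  eff <- data.frame(environment = envs,
                    index = as.numeric(index[envs]),
                    effect = NA_real_, p = NA_real_,
                    n_base = NA_integer_, n_alt = NA_integer_,
                    estimable = FALSE, stringsAsFactors = FALSE)
  Y <- pheno$values[, envs, trait, drop = TRUE]
  for (i in seq_along(envs)) {
    yb <- Y[keep & dos == base_dosage, envs[i]]
    ya <- Y[keep & dos == (2 - base_dosage), envs[i]]
    yb <- yb[!is.na(yb)]
    ya <- ya[!is.na(ya)]
    eff$n_base[i] <- length(yb)
    eff$n_alt[i] <- length(ya)
    if (length(yb) < min_carriers || length(ya) < min_carriers) next
    eff$effect[i] <- mean(ya) - mean(yb)
    eff$p[i] <- tryCatch(stats::t.test(ya, yb)$p.value,
                         error = function(e) NA_real_)
    eff$estimable[i] <- is.finite(eff$effect[i]) && is.finite(eff$p[i])
  }
  est <- eff[eff$estimable, , drop = FALSE]
  reg <- if (nrow(est) >= 2 && stats::sd(est$index) > 0) {
    co <- stats::coef(stats::lm(effect ~ index, data = est))
    list(intercept = unname(co[1]), slope = unname(co[2]))
  } else {
    list(intercept = NA_real_, slope = NA_real_)
  }
  traj <- structure(list(marker = marker, trait = trait,
                         base_dosage = base_dosage, effects = eff,
                         regression = reg, alpha = alpha),
                    class = "effect_trajectory")
  traj$classification <- classify_dynamics(traj, alpha = alpha)
  traj
}

#' Classify allelic-effect dynamics across environments
#'
#' Mutually exclusive and exhaustive over estimable trajectories:
#' * `antagonistic_pleiotropy` -- significant effects of opposite sign
#'   exist in at least two environments;
#' * `conditional_neutrality` -- significant in at least one environment
#'   and non-significant in at least one, without opposite significant
#'   signs;
#' * `differential_sensitivity` -- otherwise (consistent sign throughout,
#'   magnitudes free to vary).
#' Fewer than two estimable environments is `unclassifiable`.
#'
#' @param traj An `effect_trajectory`, or a data frame / list with
#'   `effect`, `p` and optionally `estimable` columns.
#' @param alpha Significance level per environment.
#' @return One of `"antagonistic_pleiotropy"`, `"conditional_neutrality"`,
#'   `"differential_sensitivity"`, `"unclassifiable"`.
#' @export
classify_dynamics <- function(traj, alpha = 0.05) {
  eff <- if (inherits(traj, "effect_trajectory")) traj$effects else
    as.data.frame(traj)
  if (is.null(eff$estimable)) {
    eff$estimable <- is.finite(eff$effect) & is.finite(eff$p)
  }
  e <- eff[eff$estimable, , drop = FALSE]
  if (nrow(e) < 2) return("unclassifiable")
  sig <- e$p < alpha
  if (any(sig & e$effect > 0) && any(sig & e$effect < 0)) {
    "antagonistic_pleiotropy"
  } else if (any(sig) && any(!sig)) {
    "conditional_neutrality"
  } else {
    "differential_sensitivity"
  }
}

#' Haplotype analysis over a set of loci
#'
#' Builds haplotype strings across `k` biallelic loci for all accessions
#' with homozygous, non-missing calls at every locus (others are excluded
#' and counted), enumerates all `2^k` possible haplotypes, and reports
#' observed counts and frequencies overall and per group, the mean
#' reaction-norm intercept per haplotype with a Welch test against the most
#' frequent haplotype, and the cultivar/landrace frequency enrichment fold.
#'
#' @param geno A [genotype_matrix()] with group labels.
#' @param loci Character vector of marker names.
#' @param fits A `reaction_norm_fit` for the trait of interest.
#' @param trait Trait whose intercept is summarized (default: the single
#'   trait present in `fits`).
#' @param min_carriers Haplotypes with fewer carriers than this are not
#'   tested (counts still reported).
#' @return A `haplotype_table` data frame: `haplotype`, `label`,
#'   `observed`, `count`, `freq`, `freq_landrace`, `freq_cultivar`,
#'   `enrichment_fold`, `enrichment_infinite`, `mean_intercept`,
#'   `p_vs_top`; attributes `n_excluded`, `loci`, `n_possible`.
#' @export
haplotype_analysis <- function(geno, loci, fits, trait = NULL,
                               min_carriers = 3) {
  stopifnot(all(loci %in% colnames(geno$dosage)))
  D <- geno$dosage[, loci, drop = FALSE]
  ok <- rowSums(is.na(D) | D == 1) == 0
  n_excluded <- sum(!ok)
  D <- D[ok, , drop = FALSE]
  mi <- match(loci, geno$map$marker)
  allele_char <- function(dos, j) {
    ifelse(dos == 0, geno$map$ref[mi[j]], geno$map$alt[mi[j]])
  }
  hap_obs <- apply(vapply(seq_along(loci),
                          function(j) allele_char(D[, j], j),
                          character(nrow(D))), 1, paste0, collapse = "")
  combos <- expand.grid(rep(list(c(0, 2)), length(loci)),
                        KEEP.OUT.ATTRS = FALSE)
  all_haps <- apply(vapply(seq_along(loci),
                           function(j) allele_char(combos[[j]], j),
                           character(nrow(combos))), 1, paste0,
                    collapse = "")
  counts <- table(factor(hap_obs, levels = all_haps))
  freq <- as.numeric(counts) / sum(counts)
  groups <- geno$groups[rownames(D)]
  fr_group <- function(g) {
    idx <- which(groups == g)
    if (!length(idx)) return(rep(NA_real_, length(all_haps)))
    as.numeric(table(factor(hap_obs[idx], levels = all_haps))) /
      length(idx)
  }
  fl <- fr_group("landrace")
  fc <- fr_group("cultivar")
  if (is.null(trait)) trait <- unique(fits$trait)[1]
  fi <- fits[fits$trait == trait, ]
  ints <- stats::setNames(fi$intercept, fi$accession)[rownames(D)]
  mean_int <- vapply(all_haps, function(h) {
    mean(ints[hap_obs == h], na.rm = TRUE)
  }, numeric(1))
  ord <- order(-as.numeric(counts))
  top_hap <- all_haps[ord[1]]
  p_vs_top <- rep(NA_real_, length(all_haps))
  for (i in seq_along(all_haps)) {
    h <- all_haps[i]
    if (h == top_hap) next
    a <- ints[hap_obs == h]
    b <- ints[hap_obs == top_hap]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= min_carriers && length(b) >= min_carriers) {
      p_vs_top[i] <- stats::t.test(a, b)$p.value
    }
  }
  fold <- ifelse(is.na(fl) | is.na(fc), NA_real_,
                 ifelse(fl > 0, fc / fl, NA_real_))
  inf_flag <- !is.na(fl) & !is.na(fc) & fl == 0 & fc > 0
  out <- data.frame(
    haplotype = all_haps, observed = as.numeric(counts) > 0,
    count = as.numeric(counts), freq = freq,
    freq_landrace = fl, freq_cultivar = fc,
    enrichment_fold = fold, enrichment_infinite = inf_flag,
    mean_intercept = mean_int, p_vs_top = p_vs_top,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count), , drop = FALSE]
  out$label <- paste0("HAP", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out, class = c("haplotype_table", class(out)),
            n_excluded = n_excluded, loci = loci,
            n_possible = 2^length(loci), trait = trait)
}
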