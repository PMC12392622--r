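# Ridge-regression BLUP on reaction-norm parameters and the three
# prediction scenarios: tested genotypes in untested environments (1to2),
# untested genotypes in tested environments (1to3), and untested genotypes
# in untested environments (1to4).

#' Fit ridge-regression BLUP (GBLUP form)
#'
#' Solves `y = 1 mu + M beta + eps`, `beta ~ N(0, I sigma_b^2)`, through
#' the equivalent GBLUP model with kernel `K = Mc Mc' / c`,
#' `c = sum(2 p (1 - p))`, where `Mc` is the dosage matrix centered by
#' twice the allele frequency. Variance components come from REML profiled
#' over the ratio `delta = sigma_e^2 / sigma_g^2` on the eigendecomposition
#' of `K` (a one-dimensional search). Marker effects are recovered as
#' `beta = Mc' (K + delta I)^{-1} (y - mu) / c`, algebraically identical to
#' the GBLUP breeding values.
#'
#' @param geno A [genotype_matrix()] (or bare dosage matrix) covering the
#'   training accessions.
#' @param y Named numeric vector of the parameter treated as a trait
#'   (e.g. reaction-norm intercepts), names matching accessions.
#' @param min_n Minimum training size (default 20).
#' @return An `rrblup_fit`: `mu`, `beta` (marker effects), `u` (breeding
#'   values), `sigma2_g`, `sigma2_e`, `delta`, `h2`, and the centering
#'   frequencies used for prediction.
#' @export
rrblup_fit <- function(geno, y, min_n = 20) {
  dosage <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  y <- y[!is.na(y)]
  acc <- intersect(rownames(dosage), names(y))
  if (length(acc) < min_n) {
    stop("need at least ", min_n, " training accessions", call. = FALSE)
  }
  M <- dosage[acc, , drop = FALSE]
  y <- as.numeric(y[acc])
  p <- colMeans(M, na.rm = TRUE) / 2
  if (any(is.na(M))) {
    for (j in which(colSums(is.na(M)) > 0)) M[is.na(M[, j]), j] <- 2 * p[j]
  }
  cc <- sum(2 * p * (1 - p))
  if (cc <= 0) stop("all markers monomorphic", call. = FALSE)
  Mc <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Mc) / cc
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  n <- length(y)
  ys <- crossprod(U, y)
  xs <- crossprod(U, rep(1, n))
  neg_reml <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    xwx <- sum(xs^2 * w)
    b <- sum(xs * ys * w) / xwx
    rs <- ys - xs * b
    q <- sum(rs^2 * w)
    0.5 * ((n - 1) * log(q) + sum(log(d + delta)) + log(xwx))
  }
  opt <- stats::optimize(neg_reml, c(log(1e-6), log(1e6)))
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  xwx <- sum(xs^2 * w)
  mu <- sum(xs * ys * w) / xwx
  rs <- ys - xs * mu
  sigma2_g <- sum(rs^2 * w) / (n - 1)
  sigma2_e <- delta * sigma2_g
  resid <- y - mu
  vinv_r <- U %*% (w * crossprod(U, resid))
  u <- as.numeric(K %*% vinv_r)
  names(u) <- acc
  beta <- as.numeric(crossprod(Mc, vinv_r)) / cc
  names(beta) <- colnames(M)
  # realized genetic variance is sigma2_g * mean(diag K); with inbred 0/2
  # dosages mean(diag K) ~ 2, so the raw ratio would understate h2
  kbar <- mean(d)
  structure(list(mu = mu, beta = beta, u = u, sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, delta = delta,
                 h2 = sigma2_g * kbar / (sigma2_g * kbar + sigma2_e),
                 mean_diag_K = kbar,
                 p_freq = p, c = cc, accessions = acc),
            class = "rrblup_fit")
}

#' Predict genetic values for (possibly untested) accessions
#'
#' `mu + Mc_new beta` with the new dosages centered by the training allele
#' frequencies (missing dosages imputed at `2p`). Identical to the kernel
#' form `K_ut (K_tt + delta I)^{-1} (y - mu)`.
#'
#' @param object An `rrblup_fit`.
#' @param geno A `genotype_matrix` (or dosage matrix) containing the
#'   accessions to predict.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.rrblup_fit <- function(object, geno, ...) {
  dosage <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  M <- dosage[, names(object$beta), drop = FALSE]
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- 2 * object$p_freq[j]
  }
  Mc <- sweep(M, 2, 2 * object$p_freq)
  stats::setNames(as.numeric(object$mu + Mc %*% object$beta), rownames(M))
}

pooled_and_per_env <- function(pred, obs) {
  # pred, obs: accession x environment matrices with matching NA pattern
  per_env <- vapply(seq_len(ncol(obs)), function(e) {
    ok <- !is.na(obs[, e]) & !is.na(pred[, e])
    if (sum(ok) < 3 || stats::sd(obs[ok, e]) == 0 ||
        stats::sd(pred[ok, e]) == 0) return(NA_real_)
    stats::cor(pred[ok, e], obs[ok, e])
  }, numeric(1))
  ok <- !is.na(obs) & !is.na(pred)
  pooled <- stats::cor(pred[ok], obs[ok])
  ratio <- ifelse(ok & obs != 0, pred / obs, NA_real_)
  list(per_env = data.frame(environment = colnames(obs), r = per_env,
                            n = colSums(ok), stringsAsFactors = FALSE),
       pooled_r = pooled, ratio = ratio)
}

new_prediction_report <- function(scenario, trait, acc, pooled, extra) {
  structure(c(list(scenario = scenario, trait = trait,
                   per_env = acc$per_env, pooled_r = acc$pooled_r,
                   ratio = acc$ratio), extra),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> scenario ", x$scenario, ", trait ", x$trait,
      sprintf(": pooled r = %.3f", x$pooled_r), "; per-environment r in [",
      sprintf("%.3f", min(x$per_env$r, na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x$per_env$r, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Scenario 1to2: tested genotypes in untested environments
#'
#' Leave-one-environment-out cross-validation: for each held-out
#' environment, reaction norms are refit on the remaining environments and
#' each accession's value at the held-out environment's index is predicted
#' from its own line.
#'
#' @param pheno A [pheno_tensor()].
#' @param index Named per-environment environmental index.
#' @param trait Trait name.
#' @param min_env Minimum training environments per accession within a
#'   fold; accessions below it are excluded from that fold and counted.
#' @return A `prediction_report` with per-environment and pooled Pearson
#'   accuracy and the predicted/observed ratio matrix.
#' @export
predict_1to2 <- function(pheno, index, trait, min_env = 3) {
  envs <- intersect(environments(pheno), names(index))
  if (length(envs) < 4) {
    stop("need at least 4 environments for leave-one-out", call. = FALSE)
  }
  obs <- pheno$values[, envs, trait, drop = TRUE]
  pred <- obs * NA_real_
  excluded <- 0L
  for (e in envs) {
    train <- setdiff(envs, e)
    sub <- pheno_tensor(pheno$values[, train, trait, drop = FALSE],
                        groups = pheno$groups)
    fits <- fit_reaction_norms(sub, index[train], trait,
                               anchor = "global", min_env = min_env)
    ok <- !is.na(fits$slope)
    excluded <- excluded + sum(!ok)
    yhat <- fits$intercept_raw + fits$slope * index[[e]]
    pred[fits$accession[ok], e] <- yhat[ok]
  }
  acc <- pooled_and_per_env(pred, obs)
  new_prediction_report("1to2", trait, acc, acc,
                        list(excluded = excluded, predictions = pred))
}

stratified_folds <- function(acc, groups, folds, min_test = 2) {
  for (try in 1:100) {
    fold_of <- integer(length(acc))
    names(fold_of) <- acc
    if (is.null(groups)) {
      fold_of[] <- sample(rep_len(seq_len(folds), length(acc)))
    } else {
      for (g in levels(droplevels(factor(groups[acc])))) {
        idx <- acc[groups[acc] == g]
        fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    }
    if (min(table(fold_of)) >= min_test) return(fold_of)
  }
  stop("could not build folds with at least ", min_test,
       " test accessions each", call. = FALSE)
}

#' Scenario 1to3: untested genotypes in tested environments
#'
#' Five-fold cross-validation over accessions, repeated. Reaction-norm
#' parameters of the training accessions are fit on all environments; a
#' ridge-regression BLUP model per parameter predicts the test accessions'
#' intercept and slope, which are recombined with the index to reconstruct
#' trait values. Predictions are averaged over iterations before accuracy
#' is computed.
#'
#' @param pheno A [pheno_tensor()].
#' @param index Named per-environment environmental index.
#' @param geno A [genotype_matrix()] covering all accessions.
#' @param trait Trait name.
#' @param folds,iterations Cross-validation design (default 5-fold, 10
#'   iterations). Folds are stratified by group label when available.
#' @param seed Seed for the splits.
#' @return A `prediction_report`; `n_fits` counts rrBLUP fits performed.
#' @export
predict_1to3 <- function(pheno, index, geno, trait, folds = 5,
                         iterations = 10, seed = 1) {
  envs <- intersect(environments(pheno), names(index))
  obs <- pheno$values[, envs, trait, drop = TRUE]
  fits <- fit_reaction_norms(pheno, index[envs], trait, anchor = "global")
  fits <- fits[!is.na(fits$slope), , drop = FALSE]
  acc <- intersect(fits$accession, rownames(geno$dosage))
  fits <- fits[match(acc, fits$accession), , drop = FALSE]
  anchor <- fits$anchor[1]
  set.seed(seed)
  pred_sum <- matrix(0, length(acc), length(envs),
                     dimnames = list(acc, envs))
  n_fits <- 0L
  for (it in seq_len(iterations)) {
    fold_of <- stratified_folds(acc, pheno$groups, folds)
    for (f in seq_len(folds)) {
      test <- acc[fold_of == f]
      train <- setdiff(acc, test)
      fi <- rrblup_fit(geno$dosage[train, , drop = FALSE],
                       stats::setNames(fits$intercept, acc)[train])
      fs <- rrblup_fit(geno$dosage[train, , drop = FALSE],
                       stats::setNames(fits$slope, acc)[train])
      n_fits <- n_fits + 2L
      ihat <- predict(fi, geno$dosage[test, , drop = FALSE])
      shat <- predict(fs, geno$dosage[test, , drop = FALSE])
      pred_sum[test, ] <- pred_sum[test, , drop = FALSE] +
        outer(ihat, rep(1, length(envs))) +
        outer(shat, as.numeric(index[envs]) - anchor)
    }
  }
  pred <- pred_sum / iterations
  pred[is.na(obs[acc, , drop = FALSE])] <- NA_real_
  a <- pooled_and_per_env(pred, obs[acc, , drop = FALSE])
  new_prediction_report("1to3", trait, a, a,
                        list(iterations = iterations, n_fits = n_fits,
                             predictions = pred))
}

#' Scenario 1to4: untested genotypes in untested environments
#'
#' Leave-one-environment-out crossed with repeated 5-fold splits on
#' accessions: models never see the test accessions or the held-out
#' environment. Reaction norms are refit without the held-out environment,
#' ridge-regression BLUP predicts the test accessions' parameters, and the
#' held-out environment's index reconstructs the trait value.
#'
#' @inheritParams predict_1to3
#' @return A `prediction_report`; `n_fits` counts fold-level model fits
#'   (environments x folds x iterations).
#' @export
predict_1to4 <- function(pheno, index, geno, trait, folds = 5,
                         iterations = 10, seed = 1) {
  envs <- intersect(environments(pheno), names(index))
  if (length(envs) < 4) {
    stop("need at least 4 environments for leave-one-out", call. = FALSE)
  }
  obs <- pheno$values[, envs, trait, drop = TRUE]
  set.seed(seed)
  all_acc <- accessions(pheno)
  pred_sum <- matrix(0, length(all_acc), length(envs),
                     dimnames = list(all_acc, envs))
  pred_n <- pred_sum
  n_fits <- 0L
  for (e in envs) {
    train_env <- setdiff(envs, e)
    sub <- pheno_tensor(pheno$values[, train_env, trait, drop = FALSE],
                        groups = pheno$groups)
    fits <- fit_reaction_norms(sub, index[train_env], trait,
                               anchor = "global")
    fits <- fits[!is.na(fits$slope), , drop = FALSE]
    acc <- intersect(fits$accession, rownames(geno$dosage))
    fits <- fits[match(acc, fits$accession), , drop = FALSE]
    anchor <- fits$anchor[1]
    for (it in seq_len(iterations)) {
      fold_of <- stratified_folds(acc, pheno$groups, folds)
      for (f in seq_len(folds)) {
        test <- acc[fold_of == f]
        train <- setdiff(acc, test)
        fi <- rrblup_fit(geno$dosage[train, , drop = FALSE],
                         stats::setNames(fits$intercept, acc)[train])
        fs <- rrblup_fit(geno$dosage[train, , drop = FALSE],
                         stats::setNames(fits$slope, acc)[train])
        n_fits <- n_fits + 1L
        ihat <- predict(fi, geno$dosage[test, , drop = FALSE])
        shat <- predict(fs, geno$dosage[test, , drop = FALSE])
        pred_sum[test, e] <- pred_sum[test, e] + ihat +
          shat * (index[[e]] - anchor)
        pred_n[test, e] <- pred_n[test, e] + 1
      }
    }
  }
  pred <- ifelse(pred_n > 0, pred_sum / pred_n, NA_real_)
  pred[is.na(obs)] <- NA_real_
  a <- pooled_and_per_env(pred, obs)
  new_prediction_report("1to4", trait, a, a,
                        list(iterations = iterations, n_fits = n_fits,
                             predictions = pred))
}
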