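# Variance partition, heritability, tensor PCA and imputation.

#' Broad-sense heritability within one environment
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_res / r)` for `r` replicates.
#'
#' @param sigma2_g Genotypic variance.
#' @param sigma2_res Residual variance.
#' @param r Number of replicates (>= 1).
#' @return Heritability in `[0, 1]`; `NA` with a warning when all variance
#'   components are zero.
#' @export
heritability_within <- function(sigma2_g, sigma2_res, r) {
  stopifnot(r >= 1, sigma2_g >= 0, sigma2_res >= 0)
  denom <- sigma2_g + sigma2_res / r
  if (denom == 0) {
    warning("all variance components zero: heritability undefined")
    return(NA_real_)
  }
  sigma2_g / denom
}

#' Broad-sense heritability across environments
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_ge / e + sigma2_res / (r * e))` for
#' `r` replicates and `e` environments; reduces to
#' [heritability_within()] when `e = 1` and `sigma2_ge = 0`.
#'
#' @param sigma2_g Genotypic variance.
#' @param sigma2_ge Genotype-by-environment variance.
#' @param sigma2_res Residual variance.
#' @param r Number of replicates (>= 1).
#' @param e Number of environments (>= 1).
#' @return Heritability in `[0, 1]`; `NA` with a warning when all variance
#'   components are zero.
#' @export
heritability_across <- function(sigma2_g, sigma2_ge, sigma2_res, r, e) {
  stopifnot(r >= 1, e >= 1, sigma2_g >= 0, sigma2_ge >= 0, sigma2_res >= 0)
  denom <- sigma2_g + sigma2_ge / e + sigma2_res / (r * e)
  if (denom == 0) {
    warning("all variance components zero: heritability undefined")
    return(NA_real_)
  }
  sigma2_g / denom
}

reml_control <- function() {
  # tight optimizer tolerances so balanced-design REML matches the EMS
  # closed form to high precision
  lme4::lmerControl(check.conv.singular = "ignore",
                    optimizer = "bobyqa",
                    optCtrl = list(rhoend = 1e-12, maxfun = 100000))
}

#' Partition phenotypic variance into G, E, GxE and residual
#'
#' Fits the two-way random model `y = mu + G + E + GE + eps` to
#' replicate-level data. Balanced designs are solved in closed form from
#' expected mean squares (EMS); unbalanced designs (or `method = "reml"`)
#' use REML via `lme4::lmer`, the standard mixed-model route for this
#' decomposition. Negative EMS estimates are truncated at zero and
#' flagged. Without replicate-level data the GxE and residual terms are
#' confounded and returned as a single flagged term.
#'
#' @param pheno A [pheno_tensor()] with a `replicates` data frame, or a
#'   long data frame with columns `accession`, `environment`, `value` (and
#'   `trait` if `trait` is given).
#' @param trait Trait to analyse (required for multi-trait input).
#' @param method `"auto"` (EMS when balanced, REML otherwise), `"ems"` or
#'   `"reml"`.
#' @return A `variance_components` data frame: `component`
#'   (genotype/environment/gxe/residual), `variance`, `percent`, with
#'   attributes `truncated` (components clipped at 0), `confounded`,
#'   `method`, `n_replicates`, `n_environments`.
#' @export
partition_variance <- function(pheno, trait = NULL,
                               method = c("auto", "ems", "reml")) {
  method <- match.arg(method)
  confounded <- FALSE
  if (inherits(pheno, "pheno_tensor")) {
    if (!is.null(pheno$replicates)) {
      d <- pheno$replicates
      if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
    } else {
      if (is.null(trait)) stop("`trait` required", call. = FALSE)
      m <- pheno$values[, , trait, drop = TRUE]
      d <- data.frame(
        accession = rep(rownames(m), ncol(m)),
        environment = rep(colnames(m), each = nrow(m)),
        value = as.vector(m), stringsAsFactors = FALSE
      )
      confounded <- TRUE
    }
  } else {
    d <- as.data.frame(pheno)
    if (!is.null(trait) && "trait" %in% names(d)) {
      d <- d[d$trait == trait, , drop = FALSE]
    }
  }
  d <- d[!is.na(d$value), c("accession", "environment", "value")]
  if (length(unique(d$accession)) < 2 || length(unique(d$environment)) < 2) {
    stop("need at least 2 genotypes and 2 environments", call. = FALSE)
  }
  cell_n <- table(d$accession, d$environment)
  r <- unique(as.vector(cell_n))
  balanced <- length(r) == 1 && r[1] >= 1
  n_rep <- if (balanced) r[1] else mean(cell_n[cell_n > 0])
  if (confounded || (balanced && r[1] == 1)) confounded <- TRUE

  if (method == "auto") {
    method <- if (balanced && !confounded) "ems" else "reml"
  }

  truncated <- character(0)
  if (method == "ems") {
    if (!balanced) {
      stop("EMS estimator requires a balanced design; use method = 'reml'",
           call. = FALSE)
    }
    a <- length(unique(d$accession))
    b <- length(unique(d$environment))
    rr <- r[1]
    gbar <- tapply(d$value, d$accession, mean)
    ebar <- tapply(d$value, d$environment, mean)
    cellbar <- tapply(d$value, list(d$accession, d$environment), mean)
    grand <- mean(d$value)
    ms_g <- b * rr * sum((gbar - grand)^2) / (a - 1)
    ms_e <- a * rr * sum((ebar - grand)^2) / (b - 1)
    ge_dev <- sweep(sweep(cellbar, 1, gbar), 2, ebar) + grand
    ms_ge <- rr * sum(ge_dev^2) / ((a - 1) * (b - 1))
    if (rr > 1) {
      cell_of <- cellbar[cbind(d$accession, d$environment)]
      ms_err <- sum((d$value - cell_of)^2) / (a * b * (rr - 1))
      s_res <- ms_err
      s_ge <- (ms_ge - ms_err) / rr
    } else {
      s_res <- ms_ge   # GxE + residual confounded at the cell level
      s_ge <- NA_real_
      confounded <- TRUE
    }
    s_g <- (ms_g - ms_ge) / (b * rr)
    s_e <- (ms_e - ms_ge) / (a * rr)
  } else {
    d$accession <- factor(d$accession)
    d$environment <- factor(d$environment)
    if (confounded) {
      fit <- suppressMessages(lme4::lmer(
        value ~ (1 | accession) + (1 | environment), data = d, REML = TRUE,
        control = reml_control()
      ))
    } else {
      fit <- suppressMessages(lme4::lmer(
        value ~ (1 | accession) + (1 | environment) +
          (1 | accession:environment),
        data = d, REML = TRUE,
        control = reml_control()
      ))
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v)) v else NA_real_
    }
    s_g <- pick("accession")
    s_e <- pick("environment")
    s_ge <- if (confounded) NA_real_ else pick("accession:environment")
    s_res <- pick("Residual")
  }

  clip <- function(x, nm) {
    if (is.na(x)) return(x)
    if (x < 0) {
      truncated <<- c(truncated, nm)
      0
    } else x
  }
  s_g <- clip(s_g, "genotype")
  s_e <- clip(s_e, "environment")
  s_ge <- clip(s_ge, "gxe")
  s_res <- clip(s_res, "residual")
  if (length(truncated)) {
    warning("negative variance estimate(s) truncated at 0: ",
            paste(truncated, collapse = ", "))
  }
  comp <- c(genotype = s_g, environment = s_e, gxe = s_ge,
            residual = s_res)
  tot <- sum(comp, na.rm = TRUE)
  out <- data.frame(
    component = names(comp), variance = unname(comp),
    percent = unname(ifelse(is.na(comp), NA, 100 * comp / tot)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("variance_components", class(out)),
            truncated = truncated, confounded = confounded,
            method = method, n_replicates = n_rep,
            n_environments = length(unique(d$environment)))
}

#' PCA of the phenotype tensor under one reshaping
#'
#' Unfolds the 3D accession x environment x trait array into a 2D matrix
#' with the chosen mode as rows (accessions x (environment * trait),
#' environments x (accession * trait), or traits x (accession *
#' environment)), standardizes columns (traits are on different scales),
#' drops zero-variance columns, and decomposes with `prcomp`.
#'
#' @param pheno A [pheno_tensor()]; must be complete (impute first).
#' @param mode `"accession"`, `"environment"` or `"trait"`.
#' @return A `tensor_pca` list: `scores`, `loadings`, `percent_var`,
#'   `mode`, `dropped` (zero-variance columns removed).
#' @export
tensor_pca <- function(pheno, mode = c("accession", "environment",
                                       "trait")) {
  mode <- match.arg(mode)
  v <- pheno$values
  if (any(is.na(v))) {
    stop("tensor contains missing values: impute first ",
         "(see impute_missing())", call. = FALSE)
  }
  d <- dim(v)
  dn <- dimnames(v)
  m <- switch(
    mode,
    accession = {
      x <- matrix(v, d[1], d[2] * d[3])
      dimnames(x) <- list(dn[[1]], paste(rep(dn[[2]], d[3]),
                                         rep(dn[[3]], each = d[2]),
                                         sep = "."))
      x
    },
    environment = {
      x <- matrix(aperm(v, c(2, 1, 3)), d[2], d[1] * d[3])
      dimnames(x) <- list(dn[[2]], paste(rep(dn[[1]], d[3]),
                                         rep(dn[[3]], each = d[1]),
                                         sep = "."))
      x
    },
    trait = {
      x <- matrix(aperm(v, c(3, 1, 2)), d[3], d[1] * d[2])
      dimnames(x) <- list(dn[[3]], paste(rep(dn[[1]], d[2]),
                                         rep(dn[[2]], each = d[1]),
                                         sep = "."))
      x
    }
  )
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  m <- m[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 percent_var = pv, mode = mode, dropped = dropped),
            class = "tensor_pca")
}

#' Impute missing tensor cells
#'
#' Observed cells are never touched; an `imputed` logical mask is attached.
#' Methods: `"ridge"` (default) runs chained ridge regressions over trait
#' columns within each environment, iterating from trait-mean starts until
#' convergence; `"index"` refits each accession's reaction norm on its
#' observed environments and predicts the missing ones (requires `index`);
#' `"mean"` fills with the trait x environment mean. A trait x environment
#' slab with no observations at all is left missing and flagged.
#'
#' @param pheno A [pheno_tensor()].
#' @param method `"ridge"`, `"index"` or `"mean"`.
#' @param index Named per-environment index (for `method = "index"`).
#' @param lambda Ridge penalty (on standardized predictors).
#' @param max_iter,tol Iteration control for the chained ridge.
#' @param seed Seed (imputation is deterministic given it).
#' @return The imputed `pheno_tensor` with attributes `imputed` (mask) and
#'   `unimputable` (slabs left missing).
#' @export
impute_missing <- function(pheno, method = c("ridge", "index", "mean"),
                           index = NULL, lambda = 0.1, max_iter = 25,
                           tol = 1e-8, seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  v <- pheno$values
  mask <- is.na(v)
  if (!any(mask)) {
    attr(pheno, "imputed") <- mask
    return(pheno)
  }
  d <- dim(v)
  dn <- dimnames(v)
  slab_missing <- matrix(FALSE, d[2], d[3], dimnames = dn[2:3])
  for (e in seq_len(d[2])) {
    for (t in seq_len(d[3])) {
      if (all(is.na(v[, e, t]))) slab_missing[e, t] <- TRUE
    }
  }
  fill_mean <- function(v) {
    for (e in seq_len(d[2])) for (t in seq_len(d[3])) {
      if (slab_missing[e, t]) next
      col <- v[, e, t]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      v[, e, t] <- col
    }
    v
  }
  if (method == "mean") {
    v <- fill_mean(v)
  } else if (method == "index") {
    if (is.null(index)) stop("method 'index' requires `index`",
                             call. = FALSE)
    x <- as.numeric(index[dn[[2]]])
    for (t in seq_len(d[3])) {
      Y <- v[, , t, drop = TRUE]
      for (i in seq_len(d[1])) {
        miss <- is.na(Y[i, ]) & !slab_missing[, t]
        if (!any(miss)) next
        ok <- !is.na(Y[i, ])
        if (sum(ok) >= 3 && stats::sd(x[ok]) > 0) {
          slope <- stats::cov(x[ok], Y[i, ok]) / stats::var(x[ok])
          int <- mean(Y[i, ok]) - slope * mean(x[ok])
          Y[i, miss] <- int + slope * x[miss]
        }
      }
      v[, , t] <- Y
    }
    # cells with too few observed environments fall back to slab means
    v[is.na(v) & !rep(slab_missing, each = d[1])] <-
      fill_mean(pheno$values)[is.na(v) & !rep(slab_missing, each = d[1])]
  } else {
    # chained ridge over trait columns within each environment
    for (e in seq_len(d[2])) {
      X <- v[, e, , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, ncol = d[3])
      miss_e <- is.na(X) & !matrix(slab_missing[e, ], d[1], d[3],
                                   byrow = TRUE)
      if (!any(miss_e)) next
      mu <- colMeans(X, na.rm = TRUE)
      Xf <- X
      for (t in seq_len(d[3])) Xf[is.na(Xf[, t]), t] <- mu[t]
      usable <- which(!slab_missing[e, ])
      if (length(usable) >= 2) {
        for (it in seq_len(max_iter)) {
          delta <- 0
          for (t in usable) {
            rows_miss <- which(miss_e[, t])
            if (!length(rows_miss)) next
            preds <- setdiff(usable, t)
            Z <- scale(Xf[, preds, drop = FALSE])
            Z[, attr(Z, "scaled:scale") == 0] <- 0
            obs <- which(!is.na(X[, t]))
            zo <- Z[obs, , drop = FALSE]
            yo <- X[obs, t] - mean(X[obs, t])
            beta <- solve(crossprod(zo) + lambda * diag(ncol(zo)),
                          crossprod(zo, yo))
            pred <- mean(X[obs, t]) +
              Z[rows_miss, , drop = FALSE] %*% beta
            delta <- max(delta, max(abs(Xf[rows_miss, t] - pred)))
            Xf[rows_miss, t] <- pred
          }
          if (delta < tol) break
        }
      }
      Xf[is.na(X) & !miss_e] <- NA  # keep unimputable slabs missing
      v[, e, ] <- Xf
    }
  }
  v[rep(slab_missing, each = d[1])] <- NA_real_
  out <- pheno_tensor(v, pheno$replicates, pheno$groups)
  attr(out, "imputed") <- mask & !is.na(v)
  attr(out, "unimputable") <- slab_missing
  out
}
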