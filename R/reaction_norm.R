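# Per-accession linear reaction norms on the chosen environmental index.

#' Fit linear reaction norms for every accession
#'
#' Ordinary least squares of each accession's trait values across
#' environments on the environmental index, with the index centered at an
#' anchor so the reported intercept is the expected performance at the mean
#' index (the slope is unaffected by the centering). The raw intercept at
#' index zero is stored alongside.
#'
#' @param pheno A [pheno_tensor()].
#' @param index Named per-environment index values covering the tensor's
#'   environments.
#' @param trait Traits to fit (default: all).
#' @param anchor `"global"` anchors every accession at the mean index over
#'   all environments; `"per_accession"` at the mean over the environments
#'   each accession was observed in; `"auto"` (default) picks global when
#'   at least 95% of accession x environment cells are observed for the
#'   trait, per-accession otherwise.
#' @param min_env Minimum environments required to fit an accession
#'   (default 3); accessions below it get an NA fit, never a fabricated
#'   one.
#' @return A `reaction_norm_fit` data frame: `accession`, `trait`,
#'   `intercept` (at the anchor), `slope`, `abs_slope`, `intercept_raw`
#'   (at index 0), `anchor`, `n_env`, `r_squared`, `residual_sd`.
#' @export
fit_reaction_norms <- function(pheno, index, trait = NULL,
                               anchor = c("auto", "global",
                                          "per_accession"),
                               min_env = 3) {
  anchor <- match.arg(anchor)
  if (is.null(trait)) trait <- traits(pheno)
  envs <- intersect(environments(pheno), names(index))
  if (length(envs) < min_env) {
    stop("insufficient data: fewer than ", min_env,
         " environments with index values", call. = FALSE)
  }
  x_all <- as.numeric(index[envs])
  if (stats::sd(x_all) == 0) {
    stop("degenerate index: zero variance across environments",
         call. = FALSE)
  }
  out <- vector("list", length(trait))
  for (ti in seq_along(trait)) {
    tr <- trait[ti]
    Y <- pheno$values[, envs, tr, drop = TRUE]
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = length(accessions(pheno)),
                                     dimnames = list(accessions(pheno),
                                                     envs))
    completeness <- mean(!is.na(Y))
    mode_t <- if (anchor == "auto") {
      if (completeness >= 0.95) "global" else "per_accession"
    } else anchor
    global_anchor <- mean(x_all)
    n_acc <- nrow(Y)
    fit <- data.frame(
      accession = rownames(Y), trait = tr, intercept = NA_real_,
      slope = NA_real_, abs_slope = NA_real_, intercept_raw = NA_real_,
      anchor = NA_real_, n_env = 0L, r_squared = NA_real_,
      residual_sd = NA_real_, stringsAsFactors = FALSE
    )
    for (i in seq_len(n_acc)) {
      ok <- !is.na(Y[i, ])
      n <- sum(ok)
      fit$n_env[i] <- n
      if (n < min_env) next
      x <- x_all[ok]
      y <- Y[i, ok]
      if (stats::sd(x) == 0) {
        stop("degenerate index: zero variance within accession ",
             rownames(Y)[i], call. = FALSE)
      }
      xm <- mean(x)
      slope <- sum((x - xm) * (y - mean(y))) / sum((x - xm)^2)
      a <- if (mode_t == "global") global_anchor else xm
      fitted <- mean(y) + slope * (x - xm)
      ssr <- sum((y - fitted)^2)
      sst <- sum((y - mean(y))^2)
      fit$slope[i] <- slope
      fit$abs_slope[i] <- abs(slope)
      fit$intercept[i] <- mean(y) + slope * (a - xm)
      fit$intercept_raw[i] <- mean(y) - slope * xm
      fit$anchor[i] <- a
      fit$r_squared[i] <- if (sst < 1e-300) 1 else
        max(0, min(1, 1 - ssr / sst))
      fit$residual_sd[i] <- if (n > 2) sqrt(ssr / (n - 2)) else NA_real_
    }
    out[[ti]] <- fit
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("reaction_norm_fit", class(res))
  attr(res, "groups") <- pheno$groups
  res
}

#' Cross-trait correlations of reaction-norm parameters
#'
#' Pearson correlation across accessions, for every unordered trait pair,
#' of the intercept and of |slope| (the paper-style convention for
#' comparing sensitivity regardless of direction). Pairs with fewer than
#' `min_acc` overlapping fitted accessions are marked missing. A pair is
#' flagged `strong` when |r| > 0.5 and p < 0.05.
#'
#' @param fits A `reaction_norm_fit` from [fit_reaction_norms()].
#' @param min_acc Minimum overlapping accessions per pair.
#' @return A `parameter_correlations` list: `pairs` (long data frame with
#'   one row per trait pair x parameter) and correlation matrices
#'   `intercept_r`, `abs_slope_r`.
#' @export
parameter_correlations <- function(fits, min_acc = 3) {
  trs <- unique(fits$trait)
  wide <- function(col) {
    m <- sapply(trs, function(tr) {
      v <- fits[fits$trait == tr, ]
      stats::setNames(v[[col]], v$accession)[unique(fits$accession)]
    })
    rownames(m) <- unique(fits$accession)
    m
  }
  Wi <- wide("intercept")
  Ws <- wide("abs_slope")
  combs <- utils::combn(trs, 2)
  rows <- vector("list", ncol(combs))
  mk_mat <- function() {
    m <- diag(1, length(trs))
    dimnames(m) <- list(trs, trs)
    m
  }
  Ri <- mk_mat(); Rs <- mk_mat()
  for (j in seq_len(ncol(combs))) {
    t1 <- combs[1, j]; t2 <- combs[2, j]
    one <- function(W) {
      ok <- stats::complete.cases(W[, c(t1, t2)])
      if (sum(ok) < min_acc) return(list(r = NA_real_, p = NA_real_,
                                         n = sum(ok)))
      c(correlation_with_p(W[ok, t1], W[ok, t2]), n = sum(ok))
    }
    ci <- one(Wi); cs <- one(Ws)
    Ri[t1, t2] <- Ri[t2, t1] <- ci$r
    Rs[t1, t2] <- Rs[t2, t1] <- cs$r
    rows[[j]] <- data.frame(
      trait1 = t1, trait2 = t2,
      intercept_r = ci$r, intercept_p = ci$p, intercept_n = ci$n,
      abs_slope_r = cs$r, abs_slope_p = cs$p, abs_slope_n = cs$n,
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows)
  pairs$intercept_strong <- !is.na(pairs$intercept_r) &
    abs(pairs$intercept_r) > 0.5 & pairs$intercept_p < 0.05
  pairs$abs_slope_strong <- !is.na(pairs$abs_slope_r) &
    abs(pairs$abs_slope_r) > 0.5 & pairs$abs_slope_p < 0.05
  structure(list(pairs = pairs, intercept_r = Ri, abs_slope_r = Rs),
            class = "parameter_correlations")
}

#' Pairwise trajectory consistency of a trait
#'
#' Spearman rank correlation of the across-environment value vectors for
#' every unordered pair of accessions: how consistently accessions rank
#' environments. Pairs sharing fewer than 3 environments are skipped and
#' counted separately.
#'
#' @param pheno A [pheno_tensor()].
#' @param trait Trait name.
#' @return List with `mean_rho`, `sd_rho`, `n_pairs` (evaluated pairs) and
#'   `n_skipped`.
#' @export
trajectory_consistency <- function(pheno, trait) {
  if (!trait %in% traits(pheno)) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  Y <- pheno$values[, , trait, drop = TRUE]
  keep_env <- colSums(!is.na(Y)) > 0
  Y <- Y[, keep_env, drop = FALSE]
  n <- nrow(Y)
  if (n < 2 || ncol(Y) < 3) {
    stop("need at least 2 accessions and 3 environments", call. = FALSE)
  }
  complete <- !apply(is.na(Y), 1, any)
  rhos <- numeric(0)
  n_skipped <- 0L
  if (sum(complete) >= 2) {
    R <- t(apply(Y[complete, , drop = FALSE], 1, rank))
    C <- stats::cor(t(R))
    rhos <- C[upper.tri(C)]
  }
  # pairs involving at least one incomplete accession; each such pair is
  # visited exactly once (when the outer index is its smallest incomplete
  # member)
  all_idx <- seq_len(n)
  extra <- numeric(0)
  for (i in which(!complete)) {
    js <- all_idx[all_idx > i | (all_idx < i & complete[all_idx])]
    for (j in js) {
      ok <- !is.na(Y[i, ]) & !is.na(Y[j, ])
      if (sum(ok) < 3) {
        n_skipped <- n_skipped + 1L
        next
      }
      extra <- c(extra, stats::cor(Y[i, ok], Y[j, ok],
                                   method = "spearman"))
    }
  }
  rhos <- c(rhos, extra)
  list(mean_rho = mean(rhos), sd_rho = stats::sd(rhos),
       n_pairs = length(rhos), n_skipped = n_skipped)
}
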