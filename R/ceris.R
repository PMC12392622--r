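# Environmental-index window search (CERIS): exhaustive scan over
# (parameter, growth window) pairs for the index most correlated with the
# per-environment trait means.

#' Environmental mean of a trait
#'
#' The average trait value over all accessions with data in each
#' environment; the response variable of the window scan.
#'
#' @param pheno A [pheno_tensor()].
#' @param trait Trait name.
#' @return Named numeric vector, one mean per environment with at least one
#'   observed accession (environments with no data are dropped).
#' @export
environmental_mean <- function(pheno, trait) {
  if (!trait %in% traits(pheno)) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  m <- pheno$values[, , trait, drop = TRUE]
  out <- colMeans(m, na.rm = TRUE)
  out[is.finite(out)]
}

#' Pearson correlation with a two-sided p-value
#'
#' The t transform with n - 2 degrees of freedom,
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Zero variance in either input is an
#' error, never a silent NaN.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with elements `r` and `p`.
#' @export
correlation_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p)
}

#' Scan growth windows for the best environmental index
#'
#' Scores every (parameter, start day, end day) combination within bounds by
#' the Pearson correlation between the window mean of that parameter across
#' environments and the trait's environmental means. Window means are
#' computed from per-environment prefix sums, so the scan costs O(1) per
#' window. The full score surface is returned, ranked by |r| descending
#' with ties broken by earlier start, then shorter window.
#'
#' @param cube An `env_param_cube` from [derive_parameters()].
#' @param envmean Named per-environment trait means (names must match cube
#'   environments), e.g. from [environmental_mean()].
#' @param min_window Minimum window length in days (default 7; set to 1 to
#'   allow single-day windows).
#' @param max_end Last day after planting the window may touch (default:
#'   all available days, capped at 250). Use a per-trait cap to restrict
#'   the search to a biologically reasonable timeframe.
#' @param parameters Subset of parameters to scan (default: all in cube).
#' @return A `ceris_scan`: list with `results` (data frame `parameter`,
#'   `start`, `end`, `r`, `p`, `rank`, ranked best first), `envmean`, and
#'   `index_values()`-ready metadata. Windows with zero variance across
#'   environments get `r = NA` and sort last.
#' @export
scan_windows <- function(cube, envmean, min_window = 7, max_end = NULL,
                         parameters = NULL) {
  envs <- names(envmean)
  all_envs <- dimnames(cube)$environment
  if (is.null(envs) || !all(envs %in% all_envs)) {
    stop("envmean names must match cube environments", call. = FALSE)
  }
  if (length(envs) < 3) {
    stop("insufficient data: need at least 3 environments", call. = FALSE)
  }
  n_day <- dim(cube)[3]
  if (is.null(max_end)) max_end <- min(n_day, 250L)
  max_end <- min(max_end, n_day)
  if (min_window < 1 || min_window > max_end) {
    stop("min_window must lie in 1..max_end", call. = FALSE)
  }
  if (is.null(parameters)) parameters <- dimnames(cube)$parameter
  y <- as.numeric(envmean)
  if (stats::sd(y) == 0) {
    stop("undefined correlation: environmental means have zero variance",
         call. = FALSE)
  }
  yc <- y - mean(y)
  syy <- sum(yc^2)
  ne <- length(y)

  # all (start, end) pairs with end - start + 1 >= min_window
  ends <- unlist(lapply(min_window:max_end,
                        function(e) rep(e, e - min_window + 1L)))
  starts <- unlist(lapply(min_window:max_end,
                          function(e) seq_len(e - min_window + 1L)))
  len <- ends - starts + 1L

  res <- vector("list", length(parameters))
  for (k in seq_along(parameters)) {
    p <- parameters[k]
    daily <- cube[envs, p, seq_len(max_end), drop = FALSE]
    daily <- matrix(daily, nrow = ne)        # env x day
    pref <- cbind(0, t(apply(daily, 1, cumsum)))  # env x (day + 1)
    W <- (pref[, ends + 1L, drop = FALSE] - pref[, starts, drop = FALSE]) /
      rep(len, each = ne)                     # env x window
    Wc <- W - rep(colMeans(W), each = ne)
    sww <- colSums(Wc^2)
    sxy <- as.numeric(crossprod(Wc, yc))
    r <- ifelse(sww > 1e-24 * pmax(1, colMeans(W)^2), sxy / sqrt(sww * syy),
                NA_real_)
    r <- pmin(1, pmax(-1, r))
    df <- ne - 2
    tt <- r * sqrt(df / pmax(1 - r^2, 1e-300))
    pv <- 2 * stats::pt(-abs(tt), df)
    pv[is.finite(r) & abs(r) >= 1] <- 0
    res[[k]] <- data.frame(parameter = p, start = starts, end = ends,
                           r = r, p = pv, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  ord <- order(-abs(results$r), results$start, results$end - results$start,
               match(results$parameter, parameters), na.last = TRUE)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  results$rank <- seq_len(nrow(results))
  structure(list(results = results, envmean = envmean,
                 min_window = min_window, max_end = max_end,
                 environments = envs),
            class = "ceris_scan")
}

#' @export
print.ceris_scan <- function(x, ...) {
  top <- x$results[1, ]
  cat("<ceris_scan> ", nrow(x$results), " windows over ",
      length(unique(x$results$parameter)), " parameters; top index ",
      top$parameter, "_", top$start, "-", top$end,
      sprintf(" (r = %.3f, p = %.3g)\n", top$r, top$p), sep = "")
  invisible(x)
}

#' Best environmental index from a scan
#'
#' @param scan A `ceris_scan`.
#' @param cube The `env_param_cube` the scan was run on.
#' @param k Rank of the entry to extract (1 = best).
#' @return List with `parameter`, `start`, `end`, `r`, `p` and `values`
#'   (the per-environment index).
#' @export
best_index <- function(scan, cube, k = 1) {
  row <- scan$results[k, ]
  vals <- window_mean(cube, row$parameter, row$start, row$end)
  list(parameter = row$parameter, start = row$start, end = row$end,
       r = row$r, p = row$p, values = vals[scan$environments])
}

#' Leave-one-environment-out re-scan diagnostic
#'
#' Because the index is chosen by maximizing |r| over many candidate
#' windows, the training-set |r| is upward-biased. This diagnostic
#' quantifies the bias: for each held-out environment the scan is re-run on
#' the remaining environments, and the window chosen there is re-scored on
#' the full environment set. The gap between `r_train` and `r_full` shows
#' how much of the headline correlation is selection.
#'
#' @inheritParams scan_windows
#' @return Data frame with one row per held-out environment: `held_out`,
#'   `parameter`, `start`, `end`, `r_train` (on the training
#'   environments), `r_full` (same window re-scored on all environments).
#' @export
loeo_rescan <- function(cube, envmean, min_window = 7, max_end = NULL,
                        parameters = NULL) {
  envs <- names(envmean)
  if (length(envs) < 4) {
    stop("need at least 4 environments to hold one out", call. = FALSE)
  }
  out <- vector("list", length(envs))
  for (i in seq_along(envs)) {
    train <- envs[-i]
    sc <- scan_windows(cube, envmean[train], min_window = min_window,
                       max_end = max_end, parameters = parameters)
    top <- sc$results[1, ]
    w_all <- window_mean(cube, top$parameter, top$start, top$end)[envs]
    r_full <- correlation_with_p(as.numeric(w_all),
                                 as.numeric(envmean))$r
    out[[i]] <- data.frame(held_out = envs[i], parameter = top$parameter,
                           start = top$start, end = top$end,
                           r_train = top$r, r_full = r_full,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
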