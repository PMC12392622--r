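# Landrace-to-cultivar comparison of reaction-norm parameters and the
# 3 x 3 grid of modes of phenotypic plasticity change.

#' Compare a reaction-norm parameter between two accession groups
#'
#' Two-sided rank-sum (Wilcoxon) test of the parameter between cultivars
#' and landraces; the direction is the sign of the cultivar-minus-landrace
#' median difference when significant, `"constant"` otherwise.
#'
#' @param fits A `reaction_norm_fit`.
#' @param trait Trait name.
#' @param parameter `"intercept"` or `"abs_slope"`.
#' @param groups Factor of `landrace` / `cultivar` labels named by
#'   accession; defaults to the groups attached to `fits`.
#' @param alpha Significance level (default 0.05).
#' @param test `"wilcoxon"` (default) or `"ttest"`.
#' @param min_group Minimum accessions per group (default 5); below it the
#'   comparison is flagged untestable.
#' @return List: `direction` (`"decrease"`, `"constant"`, `"increase"`, or
#'   `NA` when untestable), `p`, `effect` (median difference), `n_landrace`,
#'   `n_cultivar`.
#' @export
compare_groups <- function(fits, trait, parameter = c("intercept",
                                                      "abs_slope"),
                           groups = NULL, alpha = 0.05,
                           test = c("wilcoxon", "ttest"), min_group = 5) {
  parameter <- match.arg(parameter)
  test <- match.arg(test)
  if (is.null(groups)) groups <- attr(fits, "groups")
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  fi <- fits[fits$trait == trait & !is.na(fits[[parameter]]), ]
  g <- groups[fi$accession]
  x_land <- fi[[parameter]][g == "landrace"]
  x_cult <- fi[[parameter]][g == "cultivar"]
  if (length(x_land) < min_group || length(x_cult) < min_group) {
    return(list(direction = NA_character_, p = NA_real_,
                effect = NA_real_, n_landrace = length(x_land),
                n_cultivar = length(x_cult), untestable = TRUE))
  }
  p <- if (test == "wilcoxon") {
    stats::wilcox.test(x_cult, x_land, exact = FALSE)$p.value
  } else {
    stats::t.test(x_cult, x_land)$p.value
  }
  effect <- stats::median(x_cult) - stats::median(x_land)
  direction <- if (p < alpha) {
    if (effect > 0) "increase" else "decrease"
  } else "constant"
  list(direction = direction, p = p, effect = effect,
       n_landrace = length(x_land), n_cultivar = length(x_cult),
       untestable = FALSE)
}

#' Mode letter from the two change directions
#'
#' Row-major grid over intercept direction x |slope| direction, each in
#' \{decrease, constant, increase\}: a = (decrease, decrease),
#' b = (decrease, constant), c = (decrease, increase), d = (constant,
#' decrease), e = (constant, constant), f = (constant, increase),
#' g = (increase, decrease), h = (increase, constant),
#' i = (increase, increase).
#'
#' @param intercept_direction,slope_direction Direction strings
#'   (vectorized).
#' @return Mode letters `a`--`i`; `NA` when a direction is unresolved.
#' @export
classify_mode <- function(intercept_direction, slope_direction) {
  lv <- c("decrease", "constant", "increase")
  i <- match(intercept_direction, lv)
  s <- match(slope_direction, lv)
  out <- letters[(i - 1) * 3 + s]
  out[is.na(i) | is.na(s)] <- NA_character_
  out
}

#' Classify every trait's mode of plasticity change
#'
#' Runs [compare_groups()] on intercept and |slope| for each trait and maps
#' the direction pair to a mode letter.
#'
#' @param fits A `reaction_norm_fit` covering the traits of interest.
#' @param groups Optional group factor (defaults to the one in `fits`).
#' @param alpha Significance level per comparison.
#' @param test Test passed to [compare_groups()].
#' @param p_adjust Multiple-testing adjustment applied across traits within
#'   each parameter (a `p.adjust` method; default `"none"`).
#' @return A `mode_table` data frame: `trait`, `intercept_direction`,
#'   `intercept_p`, `intercept_effect`, `slope_direction`, `slope_p`,
#'   `slope_effect`, `mode`.
#' @export
mode_table <- function(fits, groups = NULL, alpha = 0.05,
                       test = "wilcoxon", p_adjust = "none") {
  trs <- unique(fits$trait)
  res_i <- lapply(trs, function(tr)
    compare_groups(fits, tr, "intercept", groups, alpha = 1, test = test))
  res_s <- lapply(trs, function(tr)
    compare_groups(fits, tr, "abs_slope", groups, alpha = 1, test = test))
  p_i <- stats::p.adjust(vapply(res_i, `[[`, numeric(1), "p"), p_adjust)
  p_s <- stats::p.adjust(vapply(res_s, `[[`, numeric(1), "p"), p_adjust)
  dir_of <- function(res, p) {
    if (is.na(p) || isTRUE(res$untestable)) return(NA_character_)
    if (p >= alpha) "constant" else if (res$effect > 0) "increase" else
      "decrease"
  }
  di <- mapply(dir_of, res_i, p_i)
  ds <- mapply(dir_of, res_s, p_s)
  out <- data.frame(
    trait = trs,
    intercept_direction = di, intercept_p = p_i,
    intercept_effect = vapply(res_i, `[[`, numeric(1), "effect"),
    slope_direction = ds, slope_p = p_s,
    slope_effect = vapply(res_s, `[[`, numeric(1), "effect"),
    mode = classify_mode(di, ds),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mode_table", class(out))
  out
}

#' Summarize mode frequencies
#'
#' Per-mode trait lists, counts and percentages over classified traits,
#' plus the share of traits where the two parameters moved in the same
#' direction (modes a + i) and in opposite directions (modes c + g).
#'
#' @param table A `mode_table` (or any data frame with `trait` and `mode`).
#' @param digits Rounding for reported percentages (default 1).
#' @return A `mode_summary` list: `counts` (data frame over all nine
#'   modes), `n_classified`, `top_modes`, `top_share_pct`,
#'   `same_direction_pct`, `opposite_direction_pct`.
#' @export
summarize_modes <- function(table, digits = 1) {
  cl <- table[!is.na(table$mode), , drop = FALSE]
  if (!nrow(cl)) stop("no classified traits", call. = FALSE)
  n <- nrow(cl)
  counts <- data.frame(mode = letters[1:9], stringsAsFactors = FALSE)
  counts$n <- vapply(counts$mode, function(m) sum(cl$mode == m),
                     integer(1))
  counts$percent <- round(100 * counts$n / n, digits)
  counts$traits <- vapply(counts$mode, function(m)
    paste(cl$trait[cl$mode == m], collapse = ","), character(1))
  ord <- order(-counts$n, counts$mode)
  top <- counts$mode[ord][seq_len(min(3, sum(counts$n > 0)))]
  top_share <- round(100 * sum(counts$n[counts$mode %in% top]) / n, digits)
  same <- round(100 * sum(counts$n[counts$mode %in% c("a", "i")]) / n,
                digits)
  opp <- round(100 * sum(counts$n[counts$mode %in% c("c", "g")]) / n,
               digits)
  structure(list(counts = counts, n_classified = n, top_modes = top,
                 top_share_pct = top_share, same_direction_pct = same,
                 opposite_direction_pct = opp),
            class = "mode_summary")
}

#' @export
print.mode_summary <- function(x, ...) {
  obs <- x$counts[x$counts$n > 0, c("mode", "n", "percent")]
  cat("<mode_summary> ", x$n_classified, " classified traits; modes ",
      paste0(obs$mode, ":", obs$n, collapse = " "), "\n",
      "top modes (", paste(x$top_modes, collapse = ", "), ") share ",
      x$top_share_pct, "%; same-direction ", x$same_direction_pct,
      "%; opposite-direction ", x$opposite_direction_pct, "%\n", sep = "")
  invisible(x)
}
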