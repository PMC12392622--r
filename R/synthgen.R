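# Synthetic multi-environment trial generator with known ground truth.
#
# The generator plants a hidden environmental index -- the mean of one
# weather-derived parameter over one growth window -- and builds every
# accession's phenotype as a linear reaction norm on that index, so the
# window scan, the reaction-norm fits, the genomic prediction and the
# group comparisons all have a recoverable target.

#' Simulation configuration
#'
#' Defaults emulate the study design the package is built around: 406 inbred
#' wheat accessions (87 landraces, 319 cultivars), 10 environments from two
#' locations x early/late plantings over consecutive years, 250 days of
#' daily weather per environment, 17 traits in three categories, three
#' replicates, and a hidden dPTT index over days 147--154.
#'
#' @param n_accessions,n_landrace Panel size and how many of them are
#'   landraces (the rest are cultivars).
#' @param n_environments,n_days Number of environments and days of weather
#'   after planting per environment.
#' @param n_traits Number of traits to simulate.
#' @param n_markers Number of biallelic markers (a scaled-down panel).
#' @param n_qtl_intercept,n_qtl_slope Markers with major effects on the
#'   reaction-norm intercept / slope.
#' @param h2_intercept,h2_slope Fraction of intercept / slope variance that
#'   is genetic, in `[0, 1]`.
#' @param residual_sd Replicate-level residual SD, trait units.
#' @param true_parameter One of [env_param_names()]: the weather parameter
#'   carrying the hidden index.
#' @param true_window Integer `c(start, end)`, inclusive days after
#'   planting of the hidden window.
#' @param seed Integer seed; every stage derives its stream from it.
#' @param n_replicates Replicates per accession x environment.
#' @param emit_replicates Emit replicate-level records (tensor cells are
#'   then replicate means)?
#' @param het_rate Probability a dosage call is heterozygous (inbred
#'   default 0, giving dosages in \{0, 2\}).
#' @param weather_noise_sd SD of the autocorrelated day-to-day weather
#'   noise (deg C scale); 0 gives deterministic seasonal series.
#' @param group_diff,group_diff_prop Allele-frequency shift between
#'   landraces and cultivars and the fraction of markers carrying it
#'   (emulates selection during improvement).
#' @param maf_range Range the landrace allele frequencies are drawn from.
#' @param qtl_variance_share Share of the genetic variance carried by the
#'   designated QTL (the rest is polygenic across all markers).
#' @param intercept_mean,intercept_sd Population mean and SD of the
#'   intercept, trait units.
#' @param slope_mean_z,slope_sd_z Mean and SD of the slope expressed in
#'   standardized-index units (trait units per SD of the environmental
#'   index); the emitted slope is divided by the realized index SD so the
#'   G-by-E signal has the same magnitude whichever weather parameter and
#'   window carry the index. A nonzero mean keeps the slope sign consistent
#'   within a trait and makes the environmental mean respond to the index.
#' @param trait_names Optional trait names (defaults `T01`, ...).
#' @param trait_categories Optional per-trait category in
#'   `c("developmental", "architecture", "yield")`; categories scale the
#'   variance mix qualitatively (developmental: environment-dominant;
#'   architecture: genotype-dominant; yield: mixed).
#' @param blank_env,blank_traits Optional environment name and trait names
#'   to blank entirely (emulates traits not measured in one environment).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 406, n_landrace = 87,
                       n_environments = 10, n_days = 250, n_traits = 17,
                       n_markers = 1000, n_qtl_intercept = 5,
                       n_qtl_slope = 5, h2_intercept = 0.8, h2_slope = 0.5,
                       residual_sd = 0.5, true_parameter = "dPTT",
                       true_window = c(147, 154), seed = 1,
                       n_replicates = 3, emit_replicates = TRUE,
                       het_rate = 0, weather_noise_sd = 1.5,
                       group_diff = 0.25, group_diff_prop = 0.2,
                       maf_range = c(0.1, 0.9), qtl_variance_share = 0.5,
                       intercept_mean = 50, intercept_sd = 5,
                       slope_mean_z = 1, slope_sd_z = 0.5,
                       trait_names = NULL, trait_categories = NULL,
                       blank_env = NULL, blank_traits = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_days < 30) {
    stop("invalid config: n_days must be >= 30", call. = FALSE)
  }
  if (cfg$n_landrace >= cfg$n_accessions || cfg$n_landrace < 1) {
    stop("invalid config: need 1 <= n_landrace < n_accessions",
         call. = FALSE)
  }
  if (cfg$n_qtl_intercept + cfg$n_qtl_slope > cfg$n_markers) {
    stop("invalid config: more QTL than markers", call. = FALSE)
  }
  tw <- cfg$true_window
  if (length(tw) != 2 || tw[1] < 1 || tw[1] > tw[2] || tw[2] > cfg$n_days) {
    stop("invalid config: true_window must satisfy 1 <= start <= end <= ",
         "n_days", call. = FALSE)
  }
  for (h in c(cfg$h2_intercept, cfg$h2_slope)) {
    if (h < 0 || h > 1) {
      stop("invalid config: heritabilities must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (!cfg$true_parameter %in% env_param_names()) {
    stop("invalid config: unknown true_parameter ", cfg$true_parameter,
         call. = FALSE)
  }
  if (is.null(cfg$trait_names)) {
    cfg$trait_names <- sprintf("T%02d", seq_len(cfg$n_traits))
  }
  stopifnot(length(cfg$trait_names) == cfg$n_traits)
  if (!is.null(cfg$trait_categories)) {
    stopifnot(length(cfg$trait_categories) == cfg$n_traits,
              all(cfg$trait_categories %in%
                    c("developmental", "architecture", "yield")))
  }
  structure(cfg, class = "sim_config")
}

#' Study-scale configuration
#'
#' [sim_config()] preset at the full design scale: the 17 named traits in
#' their three categories, with the nine traits not measured in the
#' SC-2021-E environment blanked there, so the emitted tensor has
#' 406 x (8 x 10 + 9 x 9) = 65,366 observed cells.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_scale_config <- function(seed = 1, ...) {
  tn <- c("HD", "FT",                                      # developmental
          "PH", "PL", "FLAN", "FLA", "FLL", "FLW", "SL",   # architecture
          "TTN", "PTN", "TSN", "FSN", "KNS", "KL", "KW", "TKW")  # yield
  cat_of <- c(rep("developmental", 2), rep("architecture", 7),
              rep("yield", 8))
  sparse <- c("FLA", "FLAN", "FLL", "FLW", "FT", "HD", "PTN", "SL", "TTN")
  sim_config(seed = seed, trait_names = tn, trait_categories = cat_of,
             blank_env = "SC-2021-E", blank_traits = sparse, ...)
}

# category -> c(intercept_sd multiplier, slope multiplier)
category_scaling <- function(category) {
  switch(category,
         developmental = c(0.3, 3),
         architecture  = c(1.5, 0.6),
         yield         = c(1, 1),
         c(1, 1))
}

ar1_noise <- function(n, phi = 0.7) {
  as.numeric(stats::filter(stats::rnorm(n) * sqrt(1 - phi^2), phi,
                           method = "recursive"))
}

#' Simulate daily weather for every environment
#'
#' Environments combine two locations (differing in latitude and a
#' temperature offset) with early (autumn) and late (winter) plantings over
#' consecutive years. Each daily series is a seasonal sinusoid plus AR(1)
#' noise scaled by `weather_noise_sd`; with zero noise, environments sharing
#' a latitude and planting date produce identical series.
#'
#' @param config A `sim_config`.
#' @return A weather table (see [validate_weather()]).
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  locs <- data.frame(loc = c("YL", "SC"), lat = c(34.27, 30.63),
                     t_off = c(0, 2), stringsAsFactors = FALSE)
  plantings <- data.frame(code = c("E", "L"), doy = c(288, 5),
                          stringsAsFactors = FALSE)
  out <- vector("list", config$n_environments)
  for (i in seq_len(config$n_environments)) {
    li <- (i - 1) %% 2 + 1
    pi_ <- ((i - 1) %/% 2) %% 2 + 1
    year <- 2019 + (i - 1) %/% 4
    env_id <- paste(locs$loc[li], year, plantings$code[pi_], sep = "-")
    n <- config$n_days
    day <- seq_len(n)
    doy <- (plantings$doy[pi_] + day - 2) %% 365 + 1
    s <- config$weather_noise_sd
    tmean <- 14 + locs$t_off[li] + 11 * sin(2 * pi * (doy - 105) / 365) +
      s * ar1_noise(n)
    dtr <- pmax(0.5, 9 + 2 * sin(2 * pi * (doy - 135) / 365) +
                  0.6 * s * ar1_noise(n))
    rh <- pmin(100, pmax(0, 68 + 9 * sin(2 * pi * (doy - 200) / 365) +
                           2.5 * s * ar1_noise(n)))
    prec <- pmax(0, 2.5 + 2 * sin(2 * pi * (doy - 190) / 365) +
                   1.2 * s * ar1_noise(n))
    out[[i]] <- data.frame(
      environment = env_id, latitude = locs$lat[li],
      planting_doy = plantings$doy[pi_], day = day,
      tmax = tmean + dtr / 2, tmin = tmean - dtr / 2,
      prec = prec, rh = rh, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate an inbred genotype panel
#'
#' Dosages are drawn per accession as homozygous calls (0/2) at landrace- or
#' cultivar-specific allele frequencies; a configurable fraction of markers
#' carries a frequency shift between the two groups, emulating selection
#' during improvement. `het_rate > 0` converts calls to heterozygous (1) at
#' that rate.
#'
#' @param config A `sim_config`.
#' @return A [genotype_matrix()] with attributes `p_landrace` and
#'   `p_cultivar` holding the generating allele frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$n_markers
  n <- config$n_accessions
  p_land <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  p_cult <- p_land
  n_diff <- round(config$group_diff_prop * m)
  if (n_diff > 0 && config$group_diff > 0) {
    idx <- sample.int(m, n_diff)
    shift <- sample(c(-1, 1), n_diff, replace = TRUE) * config$group_diff
    p_cult[idx] <- pmin(0.98, pmax(0.02, p_land[idx] + shift))
  }
  acc <- sprintf("A%03d", seq_len(n))
  groups <- factor(c(rep("landrace", config$n_landrace),
                     rep("cultivar", n - config$n_landrace)),
                   levels = c("landrace", "cultivar"))
  names(groups) <- acc
  dosage <- matrix(0, n, m, dimnames = list(acc, sprintf("M%04d",
                                                         seq_len(m))))
  for (i in seq_len(n)) {
    p <- if (groups[i] == "landrace") p_land else p_cult
    dosage[i, ] <- stats::rbinom(m, 1, p) * 2
  }
  if (config$het_rate > 0) {
    het <- matrix(stats::runif(n * m) < config$het_rate, n, m)
    dosage[het] <- 1
  }
  chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  map <- data.frame(marker = colnames(dosage),
                    chrom = sample(chroms, m, replace = TRUE),
                    pos = sample.int(7e8, m), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, map, groups)
  attr(g, "p_landrace") <- p_land
  attr(g, "p_cultivar") <- p_cult
  g
}

#' Simulate reaction-norm phenotypes
#'
#' Recomputes the hidden environmental index from the emitted weather (the
#' mean of `true_parameter` over `true_window`), draws per-accession
#' intercepts and slopes as QTL-plus-polygenic genetic values mixed with
#' non-genetic deviations at the target heritabilities, and emits
#' `y[i, e, t] = intercept + slope * (EI_e - mean(EI)) + eps`,
#' `eps ~ N(0, residual_sd^2)` at replicate level (tensor cells are
#' replicate means when replicates are emitted).
#'
#' @param config A `sim_config`.
#' @param weather Weather table, typically from [simulate_weather()].
#' @param geno A `genotype_matrix`, typically from [simulate_genotypes()].
#' @return List with elements `pheno` (a [pheno_tensor()]) and `truth`
#'   (a `sim_truth` list: intercept/slope matrices, QTL tables, realized
#'   index, groups, config).
#' @export
simulate_phenotypes <- function(config, weather, geno) {
  stopifnot(inherits(config, "sim_config"))
  cube <- derive_parameters(weather)
  tw <- config$true_window
  if (tw[2] > dim(cube)[3]) {
    stop("true_window [", tw[1], ", ", tw[2],
         "] not covered by the weather series", call. = FALSE)
  }
  ei <- window_mean(cube, config$true_parameter, tw[1], tw[2])
  sd_ei <- stats::sd(ei)
  if (!is.finite(sd_ei) || sd_ei == 0) {
    stop("degenerate environmental index: zero variance across environments",
         call. = FALSE)
  }
  ei_dev <- ei - mean(ei)

  set.seed(config$seed + 2L)
  n <- config$n_accessions
  ne <- length(ei)
  nt <- config$n_traits
  acc <- rownames(geno$dosage)
  stopifnot(length(acc) == n)
  Mc <- scale(geno$dosage, center = TRUE, scale = FALSE)

  std <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  genetic_score <- function(qtl_idx) {
    eff <- stats::rnorm(length(qtl_idx))
    qtl_part <- std(as.numeric(Mc[, qtl_idx, drop = FALSE] %*% eff))
    poly_idx <- setdiff(seq_len(ncol(Mc)), qtl_idx)
    poly_part <- std(as.numeric(Mc[, poly_idx, drop = FALSE] %*%
                                  stats::rnorm(length(poly_idx), sd = 0.1)))
    qs <- config$qtl_variance_share
    list(score = sqrt(qs) * qtl_part + sqrt(1 - qs) * poly_part,
         effects = eff)
  }

  intercepts <- matrix(NA_real_, n, nt, dimnames = list(acc,
                                                        config$trait_names))
  slopes <- intercepts
  gen_int <- intercepts
  gen_slo <- intercepts
  qtl <- vector("list", nt)
  names(qtl) <- config$trait_names
  tensor <- array(NA_real_, dim = c(n, ne, nt),
                  dimnames = list(accession = acc,
                                  environment = names(ei),
                                  trait = config$trait_names))
  reps <- if (config$emit_replicates && config$n_replicates >= 1) {
    vector("list", nt)
  } else NULL

  for (t in seq_len(nt)) {
    cs <- category_scaling(
      if (is.null(config$trait_categories)) "" else
        config$trait_categories[t])
    qi <- sample.int(config$n_markers, config$n_qtl_intercept)
    qs <- sample(setdiff(seq_len(config$n_markers), qi),
                 config$n_qtl_slope)
    gi <- genetic_score(qi)
    gs <- genetic_score(qs)
    int_sd <- config$intercept_sd * cs[1]
    h2i <- config$h2_intercept
    gen_int[, t] <- int_sd * sqrt(h2i) * gi$score
    intercepts[, t] <- config$intercept_mean + gen_int[, t] +
      int_sd * stats::rnorm(n, sd = sqrt(1 - h2i))
    h2s <- config$h2_slope
    gen_slo[, t] <- config$slope_sd_z * cs[2] * sqrt(h2s) * gs$score /
      sd_ei
    slopes[, t] <- config$slope_mean_z * cs[2] / sd_ei + gen_slo[, t] +
      config$slope_sd_z * cs[2] *
        stats::rnorm(n, sd = sqrt(1 - h2s)) / sd_ei
    qtl[[t]] <- list(
      intercept = data.frame(marker = colnames(Mc)[qi], effect = gi$effects),
      slope = data.frame(marker = colnames(Mc)[qs], effect = gs$effects)
    )
    mu <- outer(intercepts[, t], rep(1, ne)) + outer(slopes[, t], ei_dev)
    if (!is.null(reps)) {
      r <- config$n_replicates
      z <- array(stats::rnorm(n * ne * r), dim = c(n, ne, r))
      repvals <- array(rep(mu, r), dim = c(n, ne, r)) +
        config$residual_sd * z
      tensor[, , t] <- apply(repvals, c(1, 2), mean)
      reps[[t]] <- data.frame(
        accession = rep(acc, times = ne * r),
        environment = rep(rep(names(ei), each = n), times = r),
        trait = config$trait_names[t],
        replicate = rep(seq_len(r), each = n * ne),
        value = as.vector(repvals),
        stringsAsFactors = FALSE
      )
    } else {
      tensor[, , t] <- mu +
        config$residual_sd * matrix(stats::rnorm(n * ne), n, ne)
    }
  }

  rep_df <- if (!is.null(reps)) do.call(rbind, reps) else NULL
  if (!is.null(config$blank_env) && !is.null(config$blank_traits)) {
    be <- intersect(config$blank_env, names(ei))
    bt <- intersect(config$blank_traits, config$trait_names)
    if (length(be) && length(bt)) {
      tensor[, be, bt] <- NA_real_
      if (!is.null(rep_df)) {
        drop <- rep_df$environment %in% be & rep_df$trait %in% bt
        rep_df <- rep_df[!drop, , drop = FALSE]
      }
    }
  }

  truth <- structure(
    list(intercept = intercepts, slope = slopes,
         genetic_intercept = gen_int, genetic_slope = gen_slo, qtl = qtl,
         env_index = ei, index_center = mean(ei), index_sd = sd_ei,
         groups = geno$groups, config = config),
    class = "sim_truth"
  )
  list(pheno = pheno_tensor(tensor, rep_df, geno$groups), truth = truth)
}

#' Run the full generator
#'
#' Convenience wrapper: weather, genotypes, phenotypes and derived cube in
#' one call.
#'
#' @param config A `sim_config`.
#' @return List with `weather`, `cube`, `geno`, `pheno`, `truth`.
#' @export
simulate_study <- function(config) {
  weather <- simulate_weather(config)
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotypes(config, weather, geno)
  list(weather = weather, cube = derive_parameters(weather),
       geno = geno, pheno = ph$pheno, truth = ph$truth)
}
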