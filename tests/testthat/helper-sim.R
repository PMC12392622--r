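# Small seeded study used across test files.

tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_accessions = 50, n_landrace = 15, n_environments = 8, n_days = 60,
    n_traits = 2, n_markers = 80, n_qtl_intercept = 3, n_qtl_slope = 3,
    h2_intercept = 0.8, h2_slope = 0.6, residual_sd = 0.3,
    true_parameter = "GDD", true_window = c(21, 35), seed = 11
  ), list(...))
  do.call(sim_config, args)
}

tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_config())
    cache
  }
})

# constant-weather table for arithmetic checks on the derived parameters
flat_weather <- function(n_days = 10, tmax = 30, tmin = 10, prec = 1,
                         rh = 60, environment = "E1", latitude = 34,
                         planting_doy = 100) {
  data.frame(
    environment = environment, latitude = latitude,
    planting_doy = planting_doy, day = seq_len(n_days),
    tmax = tmax, tmin = tmin, prec = prec, rh = rh,
    stringsAsFactors = FALSE
  )
}

# direct reaction-norm phenotype builder (bypasses the weather machinery)
norm_pheno <- function(intercepts, slopes, index, residual_sd = 0,
                       groups = NULL, trait = "T1", seed = 99) {
  set.seed(seed)
  n <- length(intercepts)
  acc <- sprintf("A%03d", seq_len(n))
  v <- array(
    outer(intercepts, rep(1, length(index))) +
      outer(slopes, index - mean(index)) +
      residual_sd * matrix(rnorm(n * length(index)), n),
    dim = c(n, length(index), 1),
    dimnames = list(accession = acc,
                    environment = names(index), trait = trait)
  )
  if (!is.null(groups)) names(groups) <- acc
  pheno_tensor(v, groups = groups)
}
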