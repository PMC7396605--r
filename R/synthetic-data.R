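#' Configuration for the synthetic sacrificial-vial assay generator
#'
#' Encodes the study design the analysis assumes: vials sacrificed across a
#' grid of fractions remaining (default nine vials at f = 0.9 ... 0.1),
#' isotope ratios measured in triplicate, independent Gaussian analytical
#' noise with sd 0.5 permil per element per measurement, and exact Rayleigh
#' distillation with per-element enrichment factors as the generating
#' truth. Default initial compositions are delta13C = -30 permil (typical
#' of chlorinated solvents) and delta37Cl = 0 permil; slope estimates are
#' invariant to this choice.
#'
#' @param epsilon_c carbon enrichment factor in permil (generating truth).
#' @param epsilon_cl chlorine enrichment factor in permil; `NA` for a
#'   carbon-only series.
#' @param delta0_c,delta0_cl initial compositions in permil.
#' @param f_grid target fractions remaining, each in (0, 1].
#' @param noise_sd analytical noise standard deviation in permil (>= 0).
#' @param n_replicates measurements per vial (>= 1).
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(epsilon_c, epsilon_cl = NA_real_,
                              delta0_c = -30, delta0_cl = 0,
                              f_grid = seq(0.9, 0.1, by = -0.1),
                              noise_sd = 0.5, n_replicates = 3L,
                              seed = NULL) {
  stopifnot(is.numeric(epsilon_c), length(epsilon_c) == 1L)
  if (any(!is.finite(f_grid)) || any(f_grid <= 0) || any(f_grid > 1)) {
    stop("f_grid values must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(
    epsilon_c = epsilon_c,
    epsilon_cl = as.numeric(epsilon_cl),
    delta0_c = delta0_c,
    delta0_cl = delta0_cl,
    f_grid = as.numeric(f_grid),
    noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "simulation_config")
}

#' Closed-form Rayleigh distillation delta
#'
#' delta_t = (1 + delta_0) f^(epsilon/1000) - 1, in permil: the exact
#' residual-substrate composition after distillation to fraction remaining
#' f with bulk enrichment factor epsilon.
#'
#' @param f fraction(s) remaining, > 0.
#' @param epsilon enrichment factor in permil.
#' @param delta0 initial composition in permil.
#' @return delta in permil.
#' @examples
#' rayleigh_delta(0.5, -27.5)  # 19.24 permil enrichment at half turnover
#' @export
rayleigh_delta <- function(f, epsilon, delta0 = 0) {
  stopifnot(is.numeric(f), all(f > 0))
  ratio_factor_to_delta(delta_to_ratio_factor(delta0) * f^(epsilon / 1000))
}

#' Simulate one sacrificial-vial fractionation assay
#'
#' Generates an [experiment_series] under exact Rayleigh distillation: for
#' every fraction remaining in the config's grid and every replicate, the
#' closed-form delta ([rayleigh_delta()]) plus independent Gaussian
#' analytical noise, for carbon and (if `epsilon_cl` is given) chlorine.
#' Bit-identical output for identical config and seed.
#'
#' @param config a [simulation_config()].
#' @param compound,cultivation_acceptor labels carried into the series.
#' @param series_id optional label.
#' @return An [experiment_series] with the configured delta0 attached.
#' @examples
#' cfg <- simulation_config(epsilon_c = -27.5, epsilon_cl = -5.3, seed = 42)
#' s <- simulate_rayleigh_series(cfg, "1,2-DCA")
#' fit_rayleigh(s, "C")
#' @export
simulate_rayleigh_series <- function(config, compound = "1,2-DCA",
                                     cultivation_acceptor = compound,
                                     series_id = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- length(config$f_grid)
  nr <- config$n_replicates
  f <- rep(config$f_grid, each = nr)
  n <- length(f)
  with_cl <- is.finite(config$epsilon_cl)
  delta_c <- rayleigh_delta(f, config$epsilon_c, config$delta0_c) +
    stats::rnorm(n, 0, config$noise_sd)
  delta_cl <- if (with_cl) {
    rayleigh_delta(f, config$epsilon_cl, config$delta0_cl) +
      stats::rnorm(n, 0, config$noise_sd)
  } else {
    rep(NA_real_, n)
  }
  experiment_series(
    compound = compound,
    cultivation_acceptor = cultivation_acceptor,
    f = f,
    delta_c = delta_c,
    delta_cl = delta_cl,
    sd_c = config$noise_sd,
    sd_cl = if (with_cl) config$noise_sd else NA_real_,
    vial_id = rep(sprintf("vial%02d", seq_len(nf)), each = nr),
    replicate = rep(seq_len(nr), times = nf),
    delta0_c = config$delta0_c,
    delta0_cl = if (with_cl) config$delta0_cl else NULL,
    series_id = series_id
  )
}

# Published dual-element CSIA summary for D. mccartyi strain BTF08
# resting-cell assays: enrichment factors (permil) with 95% CI half-widths
# and R2, per substrate x cultivation-acceptor combination. NA rows mark
# combinations where the substrate was not dehalogenated (no fit possible).
# Used only as generating truth for synthetic fixtures.
BTF08_REFERENCE <- data.frame(
  cultivation_acceptor = rep(c("PCE", "1,2-DCA", "cDCE", "VC"), each = 4),
  compound = rep(c("PCE", "1,2-DCA", "cDCE", "VC"), times = 4),
  epsilon_c    = c(-5.1,    NA, -23.3, -31.7,
                   -9.8, -27.5, -21.2, -18.7,
                   -8.6, -18.5, -24.3, -20.0,
                   -7.7,    NA, -14.7, -23.7),
  epsilon_c_hw = c( 2.1,    NA,   3.0,   3.2,
                    1.4,   4.1,   2.5,   3.4,
                    2.0,   4.2,   3.1,   6.3,
                    1.5,    NA,   5.1,   3.2),
  r2_c          = c(0.92,   NA,  0.97,  0.98,
                    0.97, 0.92,  0.96,  0.91,
                    0.88, 0.80,  0.95,  0.80,
                    0.90,   NA,  0.73,  0.95),
  epsilon_cl    = c(-2.5,   NA,  -1.9,  -1.7,
                    -3.2, -5.3,  -2.5,  -1.0,
                    -1.9, -4.5,  -1.2,  -0.4,
                    -5.6,   NA,  -1.0,  -1.6),
  epsilon_cl_hw = c( 2.6,   NA,   0.4,   0.3,
                     0.7,  0.6,   1.0,   0.5,
                     0.4,  1.6,   0.4,   0.4,
                     1.0,   NA,   0.5,   0.4),
  r2_cl         = c(0.76,   NA,  0.93,  0.98,
                    0.89, 0.96,  0.75,  0.63,
                    0.89, 0.70,  0.74,  0.31,
                    0.94,   NA,  0.56,  0.92),
  lambda        = c( 3.5,   NA,  12.2,  15.1,
                     2.5,  5.3,   7.9,  12.6,
                     3.0,  2.0,   9.6,  10.5,
                     2.7,   NA,  12.0,  11.0),
  lambda_hw     = c( 0.8,   NA,   2.5,   3.6,
                     0.5,  0.6,   2.5,   4.8,
                     0.5,  0.5,   4.4,   6.8,
                     0.5,   NA,   2.0,   2.9),
  r2_lambda     = c(0.88,   NA,  0.90,  0.88,
                    0.95, 0.94,  0.81,  0.69,
                    0.94, 0.89,  0.63,  0.61,
                    0.92,   NA,  0.97,  0.88),
  stringsAsFactors = FALSE
)

#' Published reference values used as generating truth
#'
#' Summary isotope-fractionation results for *Dehalococcoides mccartyi*
#' strain BTF08 resting-cell assays: per-element bulk enrichment factors
#' (permil, with 95% CI half-widths and R2) and dual-element slopes for
#' each substrate x cultivation-acceptor combination. Rows where the
#' substrate was not dehalogenated (1,2-DCA with PCE- or VC-grown cells)
#' carry `NA`. These values serve as generating truth for
#' [make_study_fixture()]; the package does not ship any raw measurement
#' data.
#'
#' @return A data frame with one row per combination.
#' @export
reference_epsilons <- function() {
  BTF08_REFERENCE
}

#' Seeded synthetic stand-in for one study assay
#'
#' Generates a synthetic [experiment_series] whose generating truth is the
#' published enrichment-factor pair for the requested substrate and
#' cultivation acceptor, under the default assay design (nine vials at
#' f = 0.9 ... 0.1, triplicates, 0.5 permil noise). This is a synthetic
#' stand-in for unarchived raw data, not a reconstruction of it.
#'
#' @param compound assay substrate.
#' @param cultivation_acceptor electron acceptor the cells were grown on.
#' @param seed RNG seed (default 1).
#' @param noise_sd analytical noise sd in permil.
#' @return An [experiment_series].
#' @examples
#' s <- make_study_fixture("1,2-DCA", "1,2-DCA", seed = 7)
#' fit_lambda(s)
#' @export
make_study_fixture <- function(compound, cultivation_acceptor,
                               seed = 1L, noise_sd = 0.5) {
  ref <- reference_epsilons()
  hit <- ref$compound == compound &
    ref$cultivation_acceptor == cultivation_acceptor
  if (sum(hit) != 1L) {
    stop(sprintf("unknown combination (%s, %s-grown)", compound,
                 cultivation_acceptor), call. = FALSE)
  }
  row <- ref[hit, ]
  if (is.na(row$epsilon_c)) {
    stop(sprintf(
      "not determined: %s was not dehalogenated by %s-grown cells",
      compound, cultivation_acceptor), call. = FALSE)
  }
  cfg <- simulation_config(
    epsilon_c = row$epsilon_c,
    epsilon_cl = row$epsilon_cl,
    noise_sd = noise_sd,
    seed = seed
  )
  simulate_rayleigh_series(cfg, compound, cultivation_acceptor)
}
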