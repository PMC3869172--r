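#' Packaged synthetic scenarios
#'
#' Ground-truth structures and hand-chosen plausible parameters for the two
#' application systems. The HOG truth uses the output-activation structure
#' with zero-order sensing, Hog1 autoinhibition and mass-action glycerol
#' removal (`delta = (0,1,1,0)`); the p53 truth uses mass-action `f1`,
#' Hill-type feedback `f3` and zero-order Mdm2 removal
#' (`delta = (0,0,1,0,1)`), placed inside the oscillatory regime. Time is in
#' minutes for HOG (2 h horizon) and hours for p53. These parameters are
#' illustrative, not fitted values.
#'
#' @param doses Osmotic-shock step doses (HOG; input units of `k0`).
#' @param times Sampling times.
#' @param noise_abs,noise_rel Additive and proportional Gaussian noise sds;
#'   per-point sd is `noise_abs + noise_rel * |truth|`.
#' @param seed RNG seed for the noise draws.
#' @return A list of class `scenario_config` with `family`, `spec`, `params`,
#'   condition definitions and noise settings.
#' @export
hog_scenario <- function(doses = c(0.1, 0.4, 0.8),
                         times = c(0, 2, 5, 10, 15, 20, 30, 45, 60, 90, 120),
                         noise_abs = 0.02, noise_rel = 0.05, seed = 1) {
  spec <- model_spec("output_activation", f1 = "michaelis_menten",
                     f3 = "linear", h = "mass_action", auto_y = TRUE,
                     mass_conservation = TRUE, family = "hog",
                     delta = c(0, 1, 1, 0))
  params <- default_params(spec)
  params[c("k0", "k1", "k2", "Kx", "k3", "k4", "yT", "kappa_y", "mg",
           "k5", "k6")] <-
    list(0.05, 0.5, 1, 0.01, 1, 0.1, 1, 4, 1, 0.02, 0.002)
  structure(list(family = "hog", spec = spec, params = params,
                 doses = doses, times = times,
                 glycerol_dose = 0.5, inhibitor_time = 10,
                 inhibitor_rate = "k5", inhibitor_factor = 0.1,
                 noise_abs = noise_abs, noise_rel = noise_rel, seed = seed),
            class = "scenario_config")
}

#' @rdname hog_scenario
#' @export
p53_scenario <- function(times = seq(0, 30, by = 0.75),
                         noise_abs = 0.02, noise_rel = 0.05, seed = 1) {
  spec <- model_spec("output_activation", f1 = "mass_action", f3 = "hill",
                     h = "michaelis_menten", mass_conservation = FALSE,
                     family = "p53", delta = c(0, 0, 1, 0, 1))
  params <- default_params(spec)
  params[c("k0", "k1", "k2", "Kf3", "mf3", "k3", "k4", "k5", "k6", "Kz")] <-
    list(1, 0.1, 2, 1, 6, 1, 1, 1, 1, 0.05)
  structure(list(family = "p53", spec = spec, params = params,
                 times = times, noise_abs = noise_abs,
                 noise_rel = noise_rel, seed = seed),
            class = "scenario_config")
}

#' Generate a synthetic HOG-like dataset
#'
#' Simulates the ground-truth model for each condition and adds Gaussian
#' noise with per-point sds. Conditions: one osmotic-shock step per dose
#' (phospho-Hog1 observable `hog1p` -> component `y`), one kinase-inhibitor
#' condition without shock (rate `k5` scaled down at the event time), and
#' one glycerol condition (`glycerol` -> component `z`) at a 0.5 dose.
#' The truth is adaptive: the `y` observable shows a transient rise and
#' decline after each shock.
#'
#' @param config A [hog_scenario()].
#' @return A [ts_dataset()] carrying the condition protocols and observable
#'   map; the noise-free truth is kept in column `truth`.
#' @export
generate_hog_dataset <- function(config = hog_scenario()) {
  stopifnot(inherits(config, "scenario_config"), config$family == "hog")
  spec <- config$spec; params <- config$params
  protos <- list()
  recs <- list()
  eq <- steady_state(spec, params, params$k0)
  init <- c(eq$x, eq$y, eq$z)
  add_cond <- function(cond, proto, observable, component) {
    tr <- simulate_model(spec, params, proto, times = config$times,
                         init = init, pre_equilibrate = FALSE)
    protos[[cond]] <<- proto
    recs[[cond]] <<- tibble::tibble(
      time = config$times, observable = observable,
      truth = tr[[component]], condition = cond)
  }
  for (d in config$doses) {
    add_cond(sprintf("shock_%g", d),
             stimulus_protocol(steps = data.frame(time = 1e-6, input = d)),
             "hog1p", "y")
  }
  add_cond("inhibitor",
           stimulus_protocol(inhibitors = data.frame(
             time = config$inhibitor_time, rate = config$inhibitor_rate,
             factor = config$inhibitor_factor)),
           "hog1p", "y")
  add_cond(sprintf("glycerol_%g", config$glycerol_dose),
           stimulus_protocol(steps = data.frame(time = 1e-6,
                                                input = config$glycerol_dose)),
           "glycerol", "z")
  df <- dplyr::bind_rows(recs)
  df$sd <- config$noise_abs + config$noise_rel * abs(df$truth)
  if (all(df$sd == 0)) {
    # noise-free request: exact truth, weighting falls back to mean levels
    df$sd <- NA_real_
    df$value <- df$truth
  } else {
    df$value <- df$truth +
      with_seed(config$seed, stats::rnorm(nrow(df), sd = df$sd))
  }
  # observables are emitted in absolute model units, so no relative-scale
  # factors are fitted for them
  ts_dataset(df, observable_map = list(
    hog1p = list(component = "y", scale = FALSE),
    glycerol = list(component = "z", scale = FALSE)),
    protocols = protos)
}

#' Generate a synthetic p53-like dataset
#'
#' Simulates the oscillatory ground truth at constant damage stimulus and
#' emits two observables, `p53` (component `x`) and `mdm2` (component `z`),
#' showing sustained oscillations with Mdm2 lagging p53. Refuses to generate
#' when the configured truth is not in the oscillatory regime.
#'
#' @param config A [p53_scenario()].
#' @return A [ts_dataset()]; the noise-free truth is kept in column `truth`.
#' @export
generate_p53_dataset <- function(config = p53_scenario()) {
  stopifnot(inherits(config, "scenario_config"), config$family == "p53")
  spec <- config$spec; params <- config$params
  cls <- classify_state(spec, params)
  if (cls != "oscillatory")
    stop("ground truth is not oscillatory (classified ", cls,
         "); refusing to generate an oscillation dataset")
  # run a transient to land on the limit cycle, then sample
  burn <- simulate_model(spec, params, times = seq(0, 50, 0.5),
                         init = c(1, 1, 0.5), pre_equilibrate = FALSE)
  init <- unlist(burn[nrow(burn), c("x", "y", "z")])
  tr <- simulate_model(spec, params, times = config$times, init = init,
                       pre_equilibrate = FALSE)
  df <- dplyr::bind_rows(
    tibble::tibble(time = config$times, observable = "p53", truth = tr$x,
                   condition = "damage"),
    tibble::tibble(time = config$times, observable = "mdm2", truth = tr$z,
                   condition = "damage"))
  df$sd <- config$noise_abs + config$noise_rel * abs(df$truth)
  if (all(df$sd == 0)) {
    df$sd <- NA_real_
    df$value <- df$truth
  } else {
    df$value <- df$truth +
      with_seed(config$seed, stats::rnorm(nrow(df), sd = df$sd))
  }
  ts_dataset(df, observable_map = list(
    p53 = list(component = "x", scale = FALSE),
    mdm2 = list(component = "z", scale = FALSE)),
    protocols = list(damage = stimulus_protocol()))
}

#' Matched HOG variant pair for robustness comparisons
#'
#' Returns the autoinhibited ground-truth structure and a matched variant
#' without autoinhibition: `kappa_y` is dropped and `k3` is rescaled by
#' `g(ybar)` at the basal equilibrium so that both variants share the same
#' basal steady state (matched dynamics near the operating point).
#'
#' @param config A [hog_scenario()].
#' @return List with `spec_auto`, `params_auto`, `spec_plain`,
#'   `params_plain`.
#' @export
hog_variants <- function(config = hog_scenario()) {
  spec_a <- config$spec; p_a <- config$params
  eq <- steady_state(spec_a, p_a, p_a$k0)
  g_eq <- auto_inhibition(eq$y, p_a$kappa_y, p_a$mg)
  spec_b <- spec_a
  spec_b$auto_y <- FALSE
  spec_b$delta <- c(0, 1, 0, 0)
  spec_b$delta[4] <- spec_a$delta[4]
  p_b <- p_a
  p_b$kappa_y <- 0
  p_b$k3 <- p_a$k3 * g_eq
  list(spec_auto = spec_a, params_auto = p_a,
       spec_plain = spec_b, params_plain = p_b)
}
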