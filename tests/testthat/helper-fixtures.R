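# Shared fixtures: the output-activation configuration used throughout the
# stability tests (zero-order sensing, linear feedback, saturating response
# removal, optional transducer autoinhibition), and random valid model
# generators for property-style tests.

fig_config <- function(kappa_y = 0) {
  spec <- model_spec("output_activation", f1 = "michaelis_menten",
                     f3 = "linear", h = "michaelis_menten",
                     auto_y = kappa_y > 0, mass_conservation = TRUE)
  p <- default_params(spec)
  p$k2 <- 0.3; p$k3 <- 0.1; p$k5 <- 0.1; p$k4 <- 0.02; p$k6 <- 0.02
  p$Kx <- 1e-4; p$Kz <- 0.05; p$mg <- 1; p$mH <- 2; p$yT <- 1
  p$kappa_y <- kappa_y
  list(spec = spec, params = p)
}

# A random structurally valid model with positive rates of plausible
# magnitude; kinetic switches drawn uniformly.
random_model <- function() {
  feedback <- sample(c("output_activation", "input_inhibition"), 1)
  spec <- model_spec(
    feedback = feedback,
    f1 = sample(c("mass_action", "michaelis_menten"), 1),
    f3 = sample(c("linear", "hill"), 1),
    h = sample(c("mass_action", "michaelis_menten"), 1),
    auto_y = runif(1) < 0.5, auto_z = runif(1) < 0.5,
    mass_conservation = runif(1) < 0.5)
  p <- default_params(spec)
  for (nm in c("k0", "k1", "k3", "k4", "k5", "k6"))
    p[[nm]] <- 10^runif(1, -2, 0.5)
  p$k2 <- if (feedback == "input_inhibition") 0 else 10^runif(1, -2, 0.5)
  p$yT <- 10^runif(1, -0.5, 0.5)
  p$Kx <- 10^runif(1, -3, 0); p$Kz <- 10^runif(1, -3, 0)
  p$Kq <- 10^runif(1, -1, 1); p$hq <- sample(1:4, 1)
  p$Kf3 <- 10^runif(1, -1, 1); p$mf3 <- sample(1:4, 1)
  p$kappa_y <- if (spec$auto_y) 10^runif(1, -1, 1.5) else 0
  p$kappa_z <- if (spec$auto_z) 10^runif(1, -1, 1.5) else 0
  p$mg <- sample(1:3, 1); p$mH <- sample(1:3, 1)
  list(spec = spec, params = p)
}

random_state <- function(params, spec) {
  y_hi <- if (spec$mass_conservation) params$yT else 2
  c(runif(1, 0.01, 2), runif(1, 0.01, y_hi * 0.95), runif(1, 0.01, 2))
}
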