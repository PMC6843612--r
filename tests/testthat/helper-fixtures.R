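# Shared fixtures, built in code.

# The six-record individual-level sample (times in years).
sample_records <- function() {
  subject_records(time = c(0.0219, 0.1973, 1.9562, 1.9644, 6.7288, 7.2849),
                  event = c(0, 1, 1, 0, 1, 0))
}

# Constant-hazard cohort with administrative censoring.
constant_cohort <- function(rate = 0.18, n = 686, seed = 1,
                            admin = 7.3) {
  simulate_tte(tte_scenario("constant", list(rate = rate), n = n,
                            seed = seed, admin_censor = admin))
}

# Life table with Poisson counts drawn directly around a known log-hazard
# curve (optionally with interval-level noise), for frailty/GLM checks.
poisson_lifetable <- function(eta, tau, seed = 1, psi = 0) {
  set.seed(seed)
  b <- if (psi > 0) stats::rnorm(length(eta), 0, psi) else 0
  y <- stats::rpois(length(eta), tau * exp(eta + b))
  N <- length(eta)
  width <- 1 / 12
  lt <- data.frame(interval = seq_len(N), start = (seq_len(N) - 1) * width,
                   end = seq_len(N) * width, n = tau, events = y,
                   censorings = 0, at_risk = tau,
                   hazard = ifelse(tau > 0, y / tau, 0))
  structure(lt, class = c("lifetable", "data.frame"), width = width)
}
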