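# Independent numerical oracle: fixed-step RK4 integration of
# dX/dt = beta - alpha*X via deSolve, evaluated at `times`.
# `alpha`, `beta`, `x0` may be vectors (integrated jointly).
ode_oracle <- function(times, alpha, beta, x0, step = 0.01) {
  grid <- sort(unique(c(seq(0, max(times), by = step), times)))
  out <- deSolve::ode(
    y = x0, times = grid,
    func = function(t, y, p) list(p$beta - p$alpha * y),
    parms = list(alpha = alpha, beta = beta),
    method = "rk4")
  out[match(times, out[, 1L]), -1L, drop = FALSE]
}

# fold-scale view of a simulated absolute course (baseline at t = 0)
as_fold_course <- function(tc, condition = tc$condition) {
  time_course(condition, tc$times,
              sweep(tc$values, 2L, tc$values[1L, ], "/"),
              scale = "fold_over_t0")
}

# study conditions for the mechanism-classifier simulations: reporter
# half-life 25 min, strong induction (steady state 300x the pre-stress
# baseline) so fold curves sit in the regime the model assumes
classifier_base_model <- function(beta_scale = 1, alpha_scale = 1) {
  a <- log(2) / 25
  induction_model(alpha = a * alpha_scale,
                  beta = beta_scale * a * 300,
                  x0 = 1)
}
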