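#' Kinetic model of induced mRNA accumulation and decay
#'
#' First-order model of mRNA abundance under constant synthesis and
#' degradation, \eqn{dX/dt = \beta - \alpha X}. At steady state the
#' abundance is \eqn{X_{ss} = \beta/\alpha} and the approach to steady
#' state has half-time \eqn{T_{1/2} = \ln 2 / \alpha}.
#'
#' @param alpha Degradation rate constant, per minute (>= 0).
#' @param beta Transcription rate, abundance units per minute (>= 0).
#' @param x0 Initial mRNA abundance at t = 0 (>= 0).
#' @return An object of class `induction_model` with fields `alpha`,
#'   `beta`, `x0`, and derived `steady_state` (`beta/alpha`, `Inf` when
#'   `alpha == 0` and `beta > 0`) and `half_time` (`log(2)/alpha`).
#' @examples
#' m <- induction_model(alpha = log(2) / 25, beta = log(2) / 25, x0 = 0)
#' m$steady_state   # 1
#' m$half_time      # 25
#' @export
induction_model <- function(alpha, beta, x0 = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(x0), length(x0) == 1L, is.finite(x0))
  if (alpha < 0) stop("'alpha' (degradation constant) must be >= 0")
  if (beta < 0) stop("'beta' (transcription rate) must be >= 0")
  if (x0 < 0) stop("'x0' (initial abundance) must be >= 0")
  ss <- if (alpha > 0) beta / alpha else if (beta > 0) Inf else x0
  structure(
    list(alpha = alpha, beta = beta, x0 = x0,
         steady_state = ss,
         half_time = if (alpha > 0) log(2) / alpha else Inf),
    class = "induction_model"
  )
}

#' @export
print.induction_model <- function(x, ...) {
  cat("Induction model dX/dt = beta - alpha*X\n")
  cat(sprintf("  alpha = %g /min   beta = %g units/min   X0 = %g\n",
              x$alpha, x$beta, x$x0))
  cat(sprintf("  steady state = %g   half-time = %g min\n",
              x$steady_state, x$half_time))
  invisible(x)
}

#' Replicated time-course container
#'
#' Holds replicate abundance (or fold-induction) measurements on a common
#' time grid for one condition.
#'
#' @param condition Condition label.
#' @param times Time points in minutes; strictly increasing, >= 0.
#' @param values Numeric matrix (or vector) of measurements, one row per
#'   time point and one column per replicate.
#' @param scale Either `"absolute"` or `"fold_over_t0"`. Fold-scale values
#'   must be strictly positive.
#' @return A `time_course` object.
#' @export
time_course <- function(condition, times, values,
                        scale = c("absolute", "fold_over_t0")) {
  scale <- match.arg(scale)
  stopifnot(is.character(condition), length(condition) == 1L)
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative time in time course")
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("'values' must have one row per time point")
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (scale == "fold_over_t0" && any(values <= 0, na.rm = TRUE))
    stop("fold-scale time course requires strictly positive values")
  structure(list(condition = condition, times = times,
                 values = values, scale = scale),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course '%s' (%s): %d time points x %d replicate(s)\n",
              x$condition, x$scale, length(x$times), ncol(x$values)))
  invisible(x)
}

# replicate-mean values on log2 scale, one value per time point
.tc_mean_log2 <- function(tc) rowMeans(log2(tc$values))

#' Simulate induced mRNA accumulation
#'
#' Closed-form solution of \eqn{dX/dt = \beta - \alpha X}:
#' \eqn{X(t) = X_0 + (\beta/\alpha - X_0)(1 - e^{-\alpha t})} for
#' \eqn{\alpha > 0}, and the limit \eqn{X(t) = X_0 + \beta t} for
#' \eqn{\alpha = 0}. Returns one noiseless replicate on the absolute scale.
#'
#' @param model An [induction_model()].
#' @param times Sorted, non-negative time points in minutes.
#' @param condition Condition label for the returned course.
#' @return A [time_course()] with `scale = "absolute"`.
#' @export
simulate_induction <- function(model, times, condition = "simulated") {
  stopifnot(inherits(model, "induction_model"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative time passed to simulate_induction")
  if (is.unsorted(times, strictly = TRUE)) times <- sort(times)
  x <- induction_solution(times, model$alpha, model$beta, model$x0)
  time_course(condition, times, matrix(x, ncol = 1L), scale = "absolute")
}

# vectorized closed form; alpha may be 0
induction_solution <- function(t, alpha, beta, x0) {
  if (alpha > 0) x0 + (beta / alpha - x0) * (1 - exp(-alpha * t))
  else x0 + beta * t
}

#' Simulate first-order mRNA decay after transcription shut-off
#'
#' With transcription stopped (beta = 0), abundance follows
#' \eqn{X(t) = X_0 e^{-\alpha t}}; the half-life is \eqn{\ln 2 / \alpha}.
#'
#' @inheritParams simulate_induction
#' @return A [time_course()] with `scale = "absolute"`.
#' @export
simulate_decay <- function(model, times, condition = "decay") {
  stopifnot(inherits(model, "induction_model"))
  if (model$x0 <= 0) stop("decay simulation requires x0 > 0")
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative time passed to simulate_decay")
  if (is.unsorted(times, strictly = TRUE)) times <- sort(times)
  x <- model$x0 * exp(-model$alpha * times)
  time_course(condition, times, matrix(x, ncol = 1L), scale = "absolute")
}

#' Fit the induction model to a fold-induction time course
#'
#' Least-squares fit of the fold-over-baseline solution
#' \eqn{F(t) = 1 + (F_{ss} - 1)(1 - e^{-\alpha t})} on log2-transformed
#' values (multiplicative error model). The course is normalized to its
#' t = 0 baseline if supplied on the absolute scale. The transcription
#' rate beta is not separately identifiable from fold data (it equals
#' `alpha * fss * X0` for unknown absolute `X0`) and is therefore not
#' returned.
#'
#' Optimization uses Levenberg-Marquardt least squares with multi-start
#' from a deterministic grid of decay constants
#' (`log(2)/5`, `log(2)/25`, `log(2)/60` per minute) and box constraints
#' `alpha` in (1e-5, 10], `fss` in [1, 1e6].
#'
#' @param tc A [time_course()] with at least 4 distinct time points.
#' @return An `induction_fit`: `alpha_hat` (/min), `fss_hat`
#'   (steady-state fold), `residual_sse` (log2 scale), `converged`,
#'   and 95% Wald intervals `ci_alpha`, `ci_fss` (NA when unavailable).
#' @export
fit_induction <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if (length(tc$times) < 4L)
    stop("fit_induction needs >= 4 distinct time points")
  vals <- tc$values
  if (any(vals <= 0)) stop("fit_induction requires strictly positive values")
  if (tc$scale == "absolute") {
    if (tc$times[1L] != 0)
      stop("absolute-scale course must include t = 0 to normalize to fold")
    vals <- sweep(vals, 2L, vals[1L, ], "/")
  }
  tt <- rep(tc$times, times = ncol(vals))
  y <- log2(as.vector(vals))

  failed <- structure(
    list(alpha_hat = NA_real_, fss_hat = 1, residual_sse = NA_real_,
         converged = FALSE, ci_alpha = c(NA_real_, NA_real_),
         ci_fss = c(NA_real_, NA_real_)),
    class = "induction_fit")
  # flat input: alpha unidentifiable
  if (stats::sd(y) < 1e-12 || diff(range(rowMeans(log2(vals)))) < 1e-10) {
    failed$residual_sse <- sum((y - mean(y))^2)
    return(failed)
  }

  model_log2 <- function(alpha, fss, t)
    log2(1 + (fss - 1) * (1 - exp(-alpha * t)))
  fss_start <- max(2, max(vals))
  best <- NULL
  for (a0 in c(log(2) / 5, log(2) / 25, log(2) / 60)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model_log2(alpha, fss, tt),
        start = list(alpha = a0, fss = fss_start),
        lower = c(alpha = 1e-5, fss = 1),
        upper = c(alpha = 10, fss = 1e6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(failed)

  est <- stats::coef(best$fit)
  ses <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                  error = function(e) c(NA_real_, NA_real_))
  z <- stats::qnorm(0.975)
  structure(
    list(alpha_hat = unname(est["alpha"]),
         fss_hat = unname(est["fss"]),
         residual_sse = best$sse,
         converged = TRUE,
         ci_alpha = unname(est["alpha"] + c(-1, 1) * z * ses[1L]),
         ci_fss = unname(est["fss"] + c(-1, 1) * z * ses[2L])),
    class = "induction_fit")
}

#' @export
print.induction_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Induction fit: did not converge (alpha unidentifiable)\n")
  } else {
    cat(sprintf(
      "Induction fit: alpha = %.4g /min (T1/2 = %.3g min), Fss = %.4g\n",
      x$alpha_hat, log(2) / x$alpha_hat, x$fss_hat))
    cat(sprintf("  residual SSE (log2) = %.3g\n", x$residual_sse))
  }
  invisible(x)
}

#' Estimate an mRNA half-life from a decay time course
#'
#' Ordinary least-squares regression of log2(abundance) on time, pooling
#' replicates; the half-life is `-1 / slope` minutes. A non-negative slope
#' yields the `+Inf` sentinel (no measurable decay).
#'
#' @param tc A [time_course()] with >= 3 time points and strictly
#'   positive values.
#' @return A `decay_fit`: `slope_log2` (log2 units/min),
#'   `intercept_log2`, `half_life` (min), `r_squared`, `slope_se`.
#' @export
fit_decay <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if (length(tc$times) < 3L) stop("fit_decay needs >= 3 time points")
  bad <- which(tc$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "nonpositive value at time %g min, replicate %d: cannot take log2",
      tc$times[bad[1L, 1L]], bad[1L, 2L]))
  tt <- rep(tc$times, times = ncol(tc$values))
  y <- log2(as.vector(tc$values))
  fit <- stats::lm(y ~ tt)
  sm <- suppressWarnings(summary(fit))
  sl <- unname(stats::coef(fit)[2L])
  structure(
    list(slope_log2 = sl,
         intercept_log2 = unname(stats::coef(fit)[1L]),
         # slopes within numerical noise of zero mean no measurable decay
         half_life = if (sl < -1e-12) -1 / sl else Inf,
         r_squared = sm$r.squared,
         slope_se = sm$coefficients[2L, 2L]),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit: slope = %.4g log2/min, half-life = %.4g min\n",
              x$slope_log2, x$half_life))
  invisible(x)
}

#' Compare decay rates between two conditions
#'
#' Joint linear model of log2(abundance) on time, a condition indicator,
#' and their interaction. The interaction coefficient is the difference
#' in log2-slopes (condition B minus condition A); its t-test p-value
#' tests equal decay rates.
#'
#' @param tcA,tcB [time_course()] objects with distinct condition labels.
#' @return A list with `half_life_a`, `half_life_b`, `interaction`
#'   (log2/min), `interaction_p`, and the underlying per-condition
#'   `decay_fit`s.
#' @export
compare_decay <- function(tcA, tcB) {
  stopifnot(inherits(tcA, "time_course"), inherits(tcB, "time_course"))
  if (identical(tcA$condition, tcB$condition))
    stop("conditions must have distinct labels for comparison")
  fa <- fit_decay(tcA)
  fb <- fit_decay(tcB)
  df <- rbind(
    data.frame(t = rep(tcA$times, ncol(tcA$values)),
               y = log2(as.vector(tcA$values)), cond = tcA$condition),
    data.frame(t = rep(tcB$times, ncol(tcB$values)),
               y = log2(as.vector(tcB$values)), cond = tcB$condition))
  df$cond <- factor(df$cond, levels = c(tcA$condition, tcB$condition))
  fit <- stats::lm(y ~ t * cond, data = df)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  irow <- grep("^t:cond", rownames(co))
  est <- co[irow, 1L]
  p <- co[irow, 4L]
  # an exact fit (residual ~ 0) makes the t statistic numerical noise;
  # resolve by the effect estimate itself
  if (!is.finite(p) || sm$sigma < 1e-8)
    p <- if (abs(est) < 1e-8) 1 else 0
  list(half_life_a = fa$half_life, half_life_b = fb$half_life,
       interaction = unname(est), interaction_p = unname(p),
       fit_a = fa, fit_b = fb)
}

#' Classify a transcription-rate versus decay-rate change
#'
#' Under the first-order model, raising the transcription rate beta at
#' constant alpha shifts the log-scale fold-induction curve up by a
#' constant offset, while lowering alpha at constant beta produces an
#' offset that grows with time (the treated curve approaches a higher
#' steady state more slowly). The classifier computes the per-time
#' offset \eqn{d(t) = \log_2 F_{treated}(t) - \log_2 F_{control}(t)} for
#' `t >= t_min`, regresses d on t by OLS (pairing replicates when the
#' replicate counts match, which carries the replicate scatter into the
#' trend test), and calls:
#' \itemize{
#'   \item `decay_shift` when the trend slope is significant at
#'     `trend_alpha`;
#'   \item `transcription_shift` when the trend is non-significant and
#'     the mean offset magnitude is at least `min_effect_log2`;
#'   \item `indistinguishable` otherwise.
#' }
#'
#' @param tc_control,tc_treated Fold-scale [time_course()] objects on a
#'   common time grid (the treated course is linearly interpolated in
#'   (t, log2 F) onto the control grid if the grids differ).
#' @param t_min Minimum time (min) entering the comparison; t = 0 is
#'   always excluded since fold is 1 there by construction.
#' @param trend_alpha Significance level of the trend test.
#' @param min_effect_log2 Minimum |mean offset| (log2) to call any shift.
#' @return A `mechanism_call`: `call`, `mean_shift_log2`,
#'   `shift_trend_slope` (log2/min), `trend_p`.
#' @export
classify_mechanism <- function(tc_control, tc_treated, t_min = 5,
                               trend_alpha = 0.05, min_effect_log2 = 0.25) {
  stopifnot(inherits(tc_control, "time_course"),
            inherits(tc_treated, "time_course"))
  if (tc_control$scale != "fold_over_t0" || tc_treated$scale != "fold_over_t0")
    stop("classify_mechanism requires fold_over_t0 time courses")
  ctrl <- tc_control
  trt <- tc_treated
  if (!isTRUE(all.equal(ctrl$times, trt$times))) {
    # interpolate treated replicate means onto the control grid,
    # linear in (t, log2 F)
    keep <- ctrl$times >= min(trt$times) & ctrl$times <= max(trt$times)
    gr <- ctrl$times[keep]
    m <- stats::approx(trt$times, .tc_mean_log2(trt), xout = gr)$y
    trt <- time_course(trt$condition, gr, matrix(2^m, ncol = 1L),
                       scale = "fold_over_t0")
    ctrl <- time_course(ctrl$condition, gr,
                        ctrl$values[keep, , drop = FALSE],
                        scale = "fold_over_t0")
  }
  sel <- ctrl$times >= t_min & ctrl$times > 0
  if (sum(sel) < 3L)
    stop("need >= 3 time points at or after t_min for classification")
  tsel <- ctrl$times[sel]
  nr_c <- ncol(ctrl$values)
  nr_t <- ncol(trt$values)
  if (nr_c == nr_t && nr_c >= 1L) {
    # replicate-paired offsets (replicates exchangeable)
    d <- log2(trt$values[sel, , drop = FALSE]) -
      log2(ctrl$values[sel, , drop = FALSE])
    tt <- rep(tsel, times = nr_c)
    dv <- as.vector(d)
  } else {
    dv <- .tc_mean_log2(trt)[sel] - .tc_mean_log2(ctrl)[sel]
    tt <- tsel
  }
  mean_d <- mean(rowMeans(matrix(dv, nrow = length(tsel))))
  fit <- stats::lm(dv ~ tt)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(sm$coefficients[2L, 1L])
  p <- unname(sm$coefficients[2L, 4L])
  # perfectly constant offsets leave no residual to test against
  if (!is.finite(p) || sm$sigma < 1e-8)
    p <- if (abs(slope) < 1e-8) 1 else 0
  call <- if (p < trend_alpha) "decay_shift"
  else if (abs(mean_d) >= min_effect_log2) "transcription_shift"
  else "indistinguishable"
  structure(list(call = call, mean_shift_log2 = mean_d,
                 shift_trend_slope = slope, trend_p = p),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf(
    "Mechanism call: %s (mean shift %.3g log2, trend slope %.3g, p = %.3g)\n",
    x$call, x$mean_shift_log2, x$shift_trend_slope, x$trend_p))
  invisible(x)
}
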