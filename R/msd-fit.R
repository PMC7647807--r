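# Mass-spring-damper identification of pointing strokes.
#
# A goal-directed pointing stroke approximates the step response of a
# single-degree-of-freedom mass-spring-damper (MSD) system. Sampled
# uniformly, that response (minus its steady state) is an exact AR(2)
# sequence, so linear-predictive (LPC) fitting of an order-2 autoregression
# recovers the system's complex pole pair, which maps to the damping ratio
# Gamma and damped frequency omega.

#' Resample a stroke onto a uniform grid and remove the steady state
#'
#' LPC fitting requires uniform sampling but the logger is jittered, so x is
#' linearly interpolated onto a uniform grid. The steady-state level —
#' estimated as the mean of the final 10% of grid samples — is subtracted so
#' that the residual is the decaying oscillatory component of the step
#' response.
#'
#' @param stroke Stroke data frame (columns `t_s`, `x_mm`).
#' @param grid_ms Grid spacing, milliseconds (default 10).
#' @return List with `t_s` (grid, starting at the stroke's first sample),
#'   `x` (detrended series), `steady_state` (subtracted level), `dt_s`.
#' @export
preprocess_stroke <- function(stroke, grid_ms = 10) {
  stopifnot(grid_ms > 0)
  t <- stroke$t_s - stroke$t_s[1]
  dur <- t[length(t)]
  dt <- grid_ms / 1000
  if (dur < 3 * dt) stop("stroke too short", call. = FALSE)
  grid <- seq(0, dur, by = dt)
  x <- stats::approx(t, stroke$x_mm, xout = grid, ties = mean)$y
  n <- length(x)
  tail_idx <- seq.int(max(1L, n - floor(0.1 * n) + 1L), n)
  ss <- mean(x[tail_idx])
  list(t_s = grid + stroke$t_s[1], x = x - ss, steady_state = ss, dt_s = dt)
}

#' Fit an order-2 autoregression by least squares
#'
#' Estimates `x[n] = c0 + a1 x[n-1] + a2 x[n-2] + e[n]` by minimizing the
#' one-step-ahead squared prediction error (the covariance method). The
#' intercept (default on) absorbs any residual steady-state offset left by
#' detrending, so a noiseless sampled step response is fit exactly; it does
#' not affect the pole estimates. The autocorrelation (Yule-Walker) method
#' is available for comparison.
#'
#' @param x Numeric series (>= 8 samples).
#' @param method `"covariance"` (least squares, default) or
#'   `"autocorrelation"` (Yule-Walker).
#' @param intercept Include an intercept term (covariance method only).
#' @return An object of class `"ar2_fit"`: `a1`, `a2`, `c0`,
#'   `residual_rms`, `poles` (complex pair), `n`, `method`.
#' @export
fit_ar2 <- function(x, method = c("covariance", "autocorrelation"),
                    intercept = TRUE) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 8) stop("need at least 8 samples for an AR(2) fit", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant series: AR(2) design is rank-deficient", call. = FALSE)
  if (method == "covariance") {
    y <- x[3:n]
    X1 <- x[2:(n - 1)]
    X2 <- x[1:(n - 2)]
    fm <- if (intercept) stats::lm(y ~ X1 + X2) else stats::lm(y ~ X1 + X2 - 1)
    co <- stats::coef(fm)
    if (anyNA(co))
      stop("rank-deficient AR(2) design", call. = FALSE)
    if (intercept) {
      c0 <- co[[1]]; a1 <- co[[2]]; a2 <- co[[3]]
    } else {
      c0 <- 0; a1 <- co[[1]]; a2 <- co[[2]]
    }
    res <- stats::residuals(fm)
  } else {
    fm <- stats::ar.yw(x, aic = FALSE, order.max = 2, demean = TRUE)
    a1 <- fm$ar[1]; a2 <- fm$ar[2]; c0 <- 0
    res <- fm$resid[!is.na(fm$resid)]
  }
  # poles of z^2 - a1 z - a2 = 0
  poles <- polyroot(c(-a2, -a1, 1))
  structure(list(a1 = a1, a2 = a2, c0 = c0,
                 residual_rms = sqrt(mean(res^2)),
                 poles = poles, n = n, method = method),
            class = "ar2_fit")
}

#' Map AR(2) poles to mass-spring-damper parameters
#'
#' A complex discrete pole pair `z = r exp(+-i theta)` (theta > 0) maps to
#' the continuous pole `s = (ln r +- i theta) / dt`; the damping ratio is
#' `Gamma = -Re(s)/|s|` and the damped frequency `omega = |Im(s)| =
#' theta/dt` rad/s. Real pole pairs indicate an overdamped (non-oscillatory)
#' response and are flagged rather than mapped; non-decaying poles
#' (`|z| >= 1`) are flagged unstable.
#'
#' @param fit An `"ar2_fit"`.
#' @param dt_s Sampling interval of the fitted series, seconds.
#' @return An object of class `"msd_params"`: `gamma`, `omega_rad_s`,
#'   `omega_n_rad_s`, `regime` (`"underdamped"` or `"overdamped_flagged"`),
#'   `stable`.
#' @export
ar2_to_msd <- function(fit, dt_s) {
  stopifnot(dt_s > 0)
  z <- fit$poles
  complex_pair <- abs(Im(z[1])) > 1e-10 * max(1, abs(Re(z[1])))
  if (!complex_pair) {
    return(structure(list(gamma = NA_real_, omega_rad_s = NA_real_,
                          omega_n_rad_s = NA_real_,
                          regime = "overdamped_flagged",
                          stable = all(Mod(z) < 1)),
                     class = "msd_params"))
  }
  r <- Mod(z[1])
  theta <- abs(Arg(z[1]))
  stable <- r < 1
  s_re <- log(r) / dt_s
  s_im <- theta / dt_s
  s_mod <- sqrt(s_re^2 + s_im^2)
  gamma <- if (s_mod > 0) -s_re / s_mod else NA_real_
  structure(list(gamma = gamma, omega_rad_s = s_im,
                 omega_n_rad_s = s_mod,
                 regime = "underdamped", stable = stable),
            class = "msd_params")
}

#' @export
print.msd_params <- function(x, ...) {
  if (x$regime == "underdamped") {
    cat(sprintf("MSD parameters: Gamma = %.4f, omega = %.4f rad/s (omega_n = %.4f)%s\n",
                x$gamma, x$omega_rad_s, x$omega_n_rad_s,
                if (!x$stable) " [unstable fit]" else ""))
  } else {
    cat("MSD parameters: overdamped (real poles) — Gamma/omega not defined\n")
  }
  invisible(x)
}

#' Fit a mass-spring-damper model to a pointing stroke
#'
#' The central estimator: resamples the stroke's horizontal trajectory onto
#' a uniform grid, removes the steady state, fits an AR(2) by the covariance
#' (least-squares) method, and maps the complex pole pair to the damping
#' ratio Gamma and damped frequency omega of the underlying second-order
#' system.
#'
#' @param stroke Stroke data frame with columns `t_s` and `x_mm` (for
#'   example, the output of [select_largest_stroke()]).
#' @param grid_ms Resampling grid, milliseconds.
#' @param method AR estimation method, see [fit_ar2()].
#' @return An object of class `"msd_fit"` with components `params`
#'   ([ar2_to_msd()] output), `ar` ([fit_ar2()] output), `pre`
#'   (preprocessed series), `stroke`, and `call`. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`.
#' @export
#' @examples
#' cfg <- generator_config(position_noise_mm = 0, sampling_sd_ms = 0,
#'                         sampling_mean_ms = 10, gap_probability = 0)
#' tr <- list(condition = "tRelaxed", distance_px = 512, task_type = "click")
#' set.seed(1)
#' fit <- msd_fit(simulate_stroke(tr, cfg))
#' coef(fit)
msd_fit <- function(stroke, grid_ms = 10,
                    method = c("covariance", "autocorrelation")) {
  method <- match.arg(method)
  pre <- preprocess_stroke(stroke, grid_ms)
  ar <- fit_ar2(pre$x, method = method)
  params <- ar2_to_msd(ar, pre$dt_s)
  structure(list(params = params, ar = ar, pre = pre, stroke = stroke,
                 grid_ms = grid_ms, call = match.call()),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("Mass-spring-damper fit (AR(2)/LPC)\n")
  print(x$params)
  cat(sprintf("  AR coefficients: a1 = %.5f, a2 = %.5f (%s method, n = %d, residual RMS %.3g)\n",
              x$ar$a1, x$ar$a2, x$ar$method, x$ar$n, x$ar$residual_rms))
  invisible(x)
}

#' @export
summary.msd_fit <- function(object, ...) {
  p <- object$params
  out <- list(
    regime = p$regime, gamma = p$gamma, omega_rad_s = p$omega_rad_s,
    omega_n_rad_s = p$omega_n_rad_s, stable = p$stable,
    a1 = object$ar$a1, a2 = object$ar$a2,
    pole_modulus = Mod(object$ar$poles[1]),
    residual_rms = object$ar$residual_rms,
    n_samples = object$ar$n, grid_ms = object$grid_ms,
    steady_state_mm = object$pre$steady_state
  )
  class(out) <- "summary.msd_fit"
  out
}

#' @export
print.summary.msd_fit <- function(x, ...) {
  cat("Mass-spring-damper stroke model\n")
  cat(sprintf("  regime: %s%s\n", x$regime,
              if (!x$stable) " (unstable)" else ""))
  if (x$regime == "underdamped")
    cat(sprintf("  Gamma = %.4f   omega = %.4f rad/s   omega_n = %.4f rad/s\n",
                x$gamma, x$omega_rad_s, x$omega_n_rad_s))
  cat(sprintf("  AR(2): a1 = %.5f, a2 = %.5f, |pole| = %.4f\n",
              x$a1, x$a2, x$pole_modulus))
  cat(sprintf("  n = %d grid samples (%g ms), residual RMS = %.3g mm, steady state = %.2f mm\n",
              x$n_samples, x$grid_ms, x$residual_rms, x$steady_state_mm))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(gamma = object$params$gamma, omega_rad_s = object$params$omega_rad_s,
    a1 = object$ar$a1, a2 = object$ar$a2)
}

#' @export
residuals.msd_fit <- function(object, ...) {
  x <- object$pre$x
  n <- length(x)
  pred <- object$ar$c0 + object$ar$a1 * x[2:(n - 1)] + object$ar$a2 * x[1:(n - 2)]
  x[3:n] - pred
}

#' @export
fitted.msd_fit <- function(object, ...) {
  x <- object$pre$x
  n <- length(x)
  object$ar$c0 + object$ar$a1 * x[2:(n - 1)] + object$ar$a2 * x[1:(n - 2)] +
    object$pre$steady_state
}

#' Predict from a fitted stroke model
#'
#' `type = "onestep"` returns the one-step-ahead AR(2) predictions on the
#' fitting grid (steady state added back). `type = "response"` evaluates the
#' continuous-time step response implied by the recovered parameters at
#' `newtimes` (seconds from stroke onset), scaled to the fitted displacement.
#'
#' @param object An `"msd_fit"`.
#' @param type Prediction type.
#' @param newtimes Times (s) for `type = "response"`; defaults to the grid.
#' @param ... Unused.
#' @return Numeric vector of predicted positions (mm).
#' @export
predict.msd_fit <- function(object, type = c("onestep", "response"),
                            newtimes = NULL, ...) {
  type <- match.arg(type)
  if (type == "onestep") return(fitted(object))
  p <- object$params
  if (p$regime != "underdamped")
    stop("step-response prediction requires an underdamped fit", call. = FALSE)
  if (is.null(newtimes)) newtimes <- object$pre$t_s - object$pre$t_s[1]
  x0 <- object$pre$x[1] + object$pre$steady_state
  D <- object$pre$steady_state - x0
  x0 + msd_step_response(newtimes, D, p$gamma, p$omega_rad_s)
}

#' Plot a fitted stroke model
#'
#' Shows the observed (grid) trajectory and the one-step AR(2) prediction,
#' with the implied continuous step response overlaid when the fit is
#' underdamped.
#'
#' @param x An `"msd_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.msd_fit <- function(x, ...) {
  t <- x$pre$t_s - x$pre$t_s[1]
  obs <- x$pre$x + x$pre$steady_state
  graphics::plot(t, obs, type = "p", pch = 16, cex = 0.5,
                 xlab = "time since stroke onset (s)", ylab = "x (mm)", ...)
  graphics::lines(t[3:length(t)], fitted(x), col = "red3")
  if (x$params$regime == "underdamped")
    graphics::lines(t, predict(x, type = "response", newtimes = t),
                    col = "steelblue", lty = 2)
  graphics::legend("bottomright",
                   legend = c("observed", "AR(2) one-step",
                              "implied step response"),
                   col = c("black", "red3", "steelblue"),
                   lty = c(NA, 1, 2), pch = c(16, NA, NA), bty = "n")
  invisible(x)
}

#' Simulate new strokes from a fitted stroke model
#'
#' Draws noiseless strokes from the underdamped step response implied by the
#' fitted Gamma and omega, at the fitting grid spacing.
#'
#' @param object An `"msd_fit"` (underdamped).
#' @param nsim Number of strokes.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of stroke data frames (`t_s`, `x_mm`).
#' @export
simulate.msd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  if (p$regime != "underdamped")
    stop("cannot simulate from an overdamped fit", call. = FALSE)
  t <- object$pre$t_s - object$pre$t_s[1]
  x0 <- object$pre$x[1] + object$pre$steady_state
  D <- object$pre$steady_state - x0
  replicate(nsim, {
    data.frame(t_s = t, x_mm = x0 + msd_step_response(t, D, p$gamma, p$omega_rad_s))
  }, simplify = FALSE)
}

#' Estimate MSD parameters for one trial
#'
#' Runs the per-trial pipeline: select the largest continuous stroke,
#' resample and detrend it, fit the AR(2), and map poles to Gamma/omega.
#' Trials whose largest stroke is too short, constant, or overdamped yield a
#' flagged-absent result (NA parameters with a reason) rather than an error,
#' so batch processing never aborts.
#'
#' @param trial_strokes Stroke list for one trial (from [split_strokes()]).
#' @param grid_ms Resampling grid, ms.
#' @param method AR estimation method.
#' @return A one-row data frame: `gamma`, `omega_rad_s`, `regime`,
#'   `residual_rms`, `n_samples_used`, `flag` (`""` if usable).
#' @export
estimate_trial_msd <- function(trial_strokes, grid_ms = 10,
                               method = "covariance") {
  absent <- function(flag) data.frame(
    gamma = NA_real_, omega_rad_s = NA_real_, regime = NA_character_,
    residual_rms = NA_real_, n_samples_used = NA_integer_, flag = flag,
    stringsAsFactors = FALSE)
  if (length(trial_strokes) == 0) return(absent("no_valid_stroke"))
  fit <- tryCatch(
    msd_fit(select_largest_stroke(trial_strokes), grid_ms = grid_ms,
            method = method),
    error = function(e) conditionMessage(e))
  if (is.character(fit)) return(absent(fit))
  p <- fit$params
  if (p$regime != "underdamped") return(absent("overdamped_flagged"))
  if (!p$stable) return(absent("unstable_fit"))
  data.frame(gamma = p$gamma, omega_rad_s = p$omega_rad_s,
             regime = p$regime, residual_rms = fit$ar$residual_rms,
             n_samples_used = fit$ar$n, flag = "",
             stringsAsFactors = FALSE)
}
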