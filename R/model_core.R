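#' Parameter set for the damped glucose-response model
#'
#' Blood glucose during a tolerance test is modelled as
#' \deqn{G''(t) + 2\alpha G'(t) + \omega_0^2 (G(t) - G_0) = 0,}
#' i.e. the deviation \eqn{g = G - G_0} from the stabilized concentration
#' \eqn{G_0} is a damped linear response. The bolus (glucose load for a GTT,
#' insulin for an ITT) is treated as an impulse absorbed into the initial
#' conditions, so the fitted equation is homogeneous and the five free
#' quantities are the damping coefficient, the squared natural frequency,
#' the stabilized level and the optimal initial condition
#' \eqn{\mu = G(0)}, \eqn{\nu = G'(0)}.
#'
#' @param alpha damping coefficient, 1/min. Must be >= 0; stabilization
#'   (\eqn{G(t) \to G_0}) requires alpha > 0, alpha = 0 is the undamped
#'   oscillator limit.
#' @param omega0_sq squared natural frequency, 1/min^2, > 0.
#' @param g_stab stabilized glucose concentration \eqn{G_0}, mmol/L.
#' @param mu initial glucose \eqn{G(0)}, mmol/L, > 0.
#' @param nu initial rate \eqn{G'(0)}, mmol/L/min (positive for a glucose
#'   load, negative for an insulin bolus).
#'
#' @return An object of class `"model_params"` (a named list).
#' @seealso [classify_regime()], [glucose_curve()], [extract_features()]
#' @examples
#' p <- model_params(alpha = 0.03, omega0_sq = 0.0012, g_stab = 6,
#'                   mu = 5, nu = 0.9)
#' glucose_curve(p, c(0, 30, 120, 240))
#' @export
model_params <- function(alpha, omega0_sq, g_stab, mu, nu) {
  vals <- c(alpha = alpha, omega0_sq = omega0_sq, g_stab = g_stab,
            mu = mu, nu = nu)
  if (length(vals) != 5L || any(!is.finite(vals)))
    stop("model parameters must be five finite numbers", call. = FALSE)
  if (alpha < 0)
    stop("alpha must be non-negative", call. = FALSE)
  if (omega0_sq <= 0)
    stop("omega0_sq must be positive", call. = FALSE)
  if (mu <= 0)
    stop("mu (initial glucose) must be positive", call. = FALSE)
  structure(as.list(vals), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Glucose response parameters:\n")
  cat(sprintf("  alpha     = %.6g 1/min\n", x$alpha))
  cat(sprintf("  omega0^2  = %.6g 1/min^2\n", x$omega0_sq))
  cat(sprintf("  G0 (stab) = %.4g mmol/L\n", x$g_stab))
  cat(sprintf("  mu  G(0)  = %.4g mmol/L\n", x$mu))
  cat(sprintf("  nu  G'(0) = %.4g mmol/L/min\n", x$nu))
  cat(sprintf("  regime    = %s\n", classify_regime(x)$regime))
  invisible(x)
}

#' Classify the characteristic-equation regime
#'
#' The characteristic equation of the model is
#' \eqn{r^2 + 2\alpha r + \omega_0^2 = 0}. Two distinct negative real roots
#' give the overdamped (sum-of-exponentials) branch, conjugate complex roots
#' the underdamped (decaying oscillation) branch. Near-equal roots are
#' classified as critical and evaluated with the confluent solution to avoid
#' catastrophic cancellation.
#'
#' @param params a [model_params()] object.
#' @param tol relative tolerance on \eqn{\alpha^2/\omega_0^2} for declaring
#'   the critical regime. Default `1e-9`.
#' @return An object of class `"root_info"`: list with `regime` (one of
#'   `"overdamped"`, `"underdamped"`, `"critical"`), real roots `r1`, `r2`
#'   (overdamped only) and damped angular frequency
#'   `omega` \eqn{= \sqrt{\omega_0^2 - \alpha^2}} (underdamped only).
#' @examples
#' classify_regime(model_params(0.10, 0.0019, 5, 5, 0))
#' @export
classify_regime <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "model_params"))
  a2 <- params$alpha^2
  w2 <- params$omega0_sq
  if (a2 > w2 * (1 + tol)) {
    s <- sqrt(a2 - w2)
    out <- list(regime = "overdamped",
                r1 = -params$alpha + s, r2 = -params$alpha - s,
                omega = NA_real_)
  } else if (a2 < w2 * (1 - tol)) {
    out <- list(regime = "underdamped", r1 = NA_real_, r2 = NA_real_,
                omega = sqrt(w2 - a2))
  } else {
    out <- list(regime = "critical", r1 = NA_real_, r2 = NA_real_,
                omega = NA_real_)
  }
  structure(out, class = "root_info")
}

# Closed-form solution coefficients for g(t) = G(t) - G0, per regime.
solution_coefs <- function(params, tol = 1e-9) {
  info <- classify_regime(params, tol)
  g0 <- params$mu - params$g_stab
  v0 <- params$nu
  switch(info$regime,
    overdamped = {
      r1 <- info$r1; r2 <- info$r2
      list(regime = "overdamped", r1 = r1, r2 = r2,
           c1 = (v0 - r2 * g0) / (r1 - r2),
           c2 = (r1 * g0 - v0) / (r1 - r2))
    },
    underdamped = {
      om <- info$omega
      list(regime = "underdamped", alpha = params$alpha, omega = om,
           A = g0, B = (v0 + params$alpha * g0) / om)
    },
    critical = {
      list(regime = "critical", alpha = params$alpha,
           c1 = g0, c2 = v0 + params$alpha * g0)
    })
}

#' Evaluate the modelled glucose concentration
#'
#' Closed-form solution of the Cauchy problem
#' \eqn{g'' + 2\alpha g' + \omega_0^2 g = 0}, \eqn{g(0)=\mu-G_0},
#' \eqn{g'(0)=\nu}, in the branch selected by [classify_regime()]:
#' overdamped \eqn{G_0 + C_1 e^{r_1 t} + C_2 e^{r_2 t}}, underdamped
#' \eqn{G_0 + e^{-\alpha t}(A\cos\omega t + B\sin\omega t)}, critical
#' (confluent) \eqn{G_0 + (C_1 + C_2 t)e^{-\alpha t}}.
#'
#' @param params a [model_params()] object.
#' @param t time(s) since the bolus, minutes, >= 0. Vectorized.
#' @param tol regime-classification tolerance, see [classify_regime()].
#' @return Glucose concentration(s), mmol/L.
#' @export
glucose_curve <- function(params, t, tol = 1e-9) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative", call. = FALSE)
  k <- solution_coefs(params, tol)
  g <- switch(k$regime,
    overdamped  = k$c1 * exp(k$r1 * t) + k$c2 * exp(k$r2 * t),
    underdamped = exp(-k$alpha * t) *
      (k$A * cos(k$omega * t) + k$B * sin(k$omega * t)),
    critical    = (k$c1 + k$c2 * t) * exp(-k$alpha * t))
  params$g_stab + g
}

#' Analytic derivatives of the modelled glucose curve
#'
#' First and second derivatives of [glucose_curve()], used to locate the
#' extremum (\eqn{G'(t)=0}) and the inflection (\eqn{G''(t)=0}) of a fitted
#' curve.
#'
#' @inheritParams glucose_curve
#' @param order derivative order, 1 or 2.
#' @return mmol/L/min (order 1) or mmol/L/min^2 (order 2). Vectorized in `t`.
#' @export
glucose_deriv <- function(params, t, order = 1, tol = 1e-9) {
  stopifnot(inherits(params, "model_params"))
  if (!(length(order) == 1L && order %in% c(1, 2)))
    stop("order must be 1 or 2", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative", call. = FALSE)
  k <- solution_coefs(params, tol)
  switch(k$regime,
    overdamped = {
      k$c1 * k$r1^order * exp(k$r1 * t) + k$c2 * k$r2^order * exp(k$r2 * t)
    },
    underdamped = {
      a <- k$alpha; b <- k$omega; A <- k$A; B <- k$B
      for (i in seq_len(order)) {
        tmp <- c(-a * A + b * B, -a * B - b * A)
        A <- tmp[1]; B <- tmp[2]
      }
      exp(-a * t) * (A * cos(b * t) + B * sin(b * t))
    },
    critical = {
      a <- k$alpha; c1 <- k$c1; c2 <- k$c2
      for (i in seq_len(order)) {
        tmp <- c(c2 - a * c1, -a * c2)
        c1 <- tmp[1]; c2 <- tmp[2]
      }
      (c1 + c2 * t) * exp(-a * t)
    })
}

#' Basic oscillation period of the glucose response
#'
#' In the underdamped regime the response rings at the damped angular
#' frequency \eqn{\omega = \sqrt{\omega_0^2 - \alpha^2}} and the basic period
#' is \eqn{T_G = 2\pi/\omega} minutes, reported in hours. Overdamped and
#' critical responses do not oscillate.
#'
#' @inheritParams glucose_curve
#' @return Period in hours, or `NA_real_` when no oscillation exists.
#' @export
glucose_period <- function(params, tol = 1e-9) {
  info <- classify_regime(params, tol)
  if (info$regime != "underdamped") return(NA_real_)
  (2 * pi / info$omega) / 60
}
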