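#' Extract derived curve characteristics from a fitted glucose model
#'
#' Implements the feature workflow on the closed-form curve: the extremum
#' (peak \eqn{G_{max}}/\eqn{t_{max}} for a GTT, nadir \eqn{G_{min}}/
#' \eqn{t_{min}} for an ITT) is the first admissible root of \eqn{G'(t)=0}
#' in (0, horizon]; the inflection \eqn{t_I} is the first root of
#' \eqn{G''(t)=0} after the extremum, where the curve declines (GTT) or
#' recovers (ITT) fastest, with \eqn{G'_I = G'(t_I)}. Roots are localized by
#' a sign-change scan and refined by bracketed root finding; when a root does
#' not exist on the window an `NA` marker is returned, never a fabricated
#' number.
#'
#' @param params a [model_params()] object (typically from [fit_glucose()]).
#' @param test `"GTT"` or `"ITT"`; selects whether the extremum is a maximum
#'   or a minimum and hence the sign conventions of `g_rate_I`.
#' @param horizon analysis window end, minutes; defaults to the protocol end
#'   (240 for GTT, 180 for ITT).
#' @param scan_step sign-scan resolution in minutes (default 0.5).
#' @param root_tol absolute tolerance of the root refinement, minutes.
#' @return An object of class `"curve_features"`: list with `g_init` (G(0)),
#'   `g_rate_init` (G'(0)), `g_extremum`, `t_extremum`, `g_rate_I`, `t_I`,
#'   `g_stab`, `period_h`, `auc_model`, `horizon`, `test` and a `boundary`
#'   flag set when no interior stationary point exists (then
#'   `t_extremum = 0`, `g_extremum = mu`).
#' @examples
#' p <- model_params(0.03, 0.0012, 6, 5, 0.9)
#' extract_features(p, "GTT")
#' @export
extract_features <- function(params, test = c("GTT", "ITT"), horizon = NULL,
                             scan_step = 0.5, root_tol = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  test <- match.arg(test)
  if (is.null(horizon)) horizon <- if (test == "GTT") 240 else 180
  stopifnot(is.finite(horizon), horizon > 0)

  d1 <- function(t) glucose_deriv(params, t, order = 1)
  d2 <- function(t) glucose_deriv(params, t, order = 2)

  grid <- unique(c(seq(0, horizon, by = scan_step), horizon))
  v1 <- d1(grid)

  # extremum: first crossing of G' with the test-appropriate direction
  # (+ -> - is a maximum for GTT, - -> + a minimum for ITT)
  if (test == "GTT") {
    cross <- which(v1[-length(v1)] > 0 & v1[-1] <= 0)
  } else {
    cross <- which(v1[-length(v1)] < 0 & v1[-1] >= 0)
  }
  boundary <- length(cross) == 0L
  if (boundary) {
    t_ext <- 0
    g_ext <- params$mu
  } else {
    i <- cross[1L]
    if (v1[i + 1L] == 0) {
      t_ext <- grid[i + 1L]
    } else {
      t_ext <- stats::uniroot(d1, lower = grid[i], upper = grid[i + 1L],
                              tol = root_tol)$root
    }
    g_ext <- glucose_curve(params, t_ext)
  }

  # inflection: first root of G'' strictly after the extremum
  t_I <- NA_real_
  g_rate_I <- NA_real_
  grid2 <- unique(c(seq(t_ext, horizon, by = scan_step), horizon))
  if (length(grid2) >= 2L) {
    v2 <- d2(grid2)
    cr2 <- which(v2[-length(v2)] * v2[-1] < 0)
    if (length(cr2) > 0L) {
      j <- cr2[1L]
      t_I <- stats::uniroot(d2, lower = grid2[j], upper = grid2[j + 1L],
                            tol = root_tol)$root
      g_rate_I <- d1(t_I)
    } else {
      zero2 <- which(abs(v2[-1]) == 0)
      if (length(zero2) > 0L && any(v2 != 0)) {
        t_I <- grid2[zero2[1L] + 1L]
        g_rate_I <- d1(t_I)
      }
    }
  }

  structure(list(
    g_init = params$mu,
    g_rate_init = params$nu,
    g_extremum = g_ext,
    t_extremum = t_ext,
    g_rate_I = g_rate_I,
    t_I = t_I,
    g_stab = params$g_stab,
    period_h = glucose_period(params),
    auc_model = model_auc(params, horizon),
    horizon = horizon,
    test = test,
    boundary = boundary
  ), class = "curve_features")
}

#' @export
print.curve_features <- function(x, ...) {
  lab <- if (x$test == "GTT") c("G_max", "t_max") else c("G_min", "t_min")
  cat(sprintf("Curve features (%s, horizon %g min):\n", x$test, x$horizon))
  cat(sprintf("  G(0)   = %.3f mmol/L   G'(0) = %.4f mmol/L/min\n",
              x$g_init, x$g_rate_init))
  cat(sprintf("  %s  = %.3f mmol/L   %s = %.2f min%s\n", lab[1],
              x$g_extremum, lab[2], x$t_extremum,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  G'_I   = %.4f mmol/L/min   t_I = %.2f min\n",
              x$g_rate_I, x$t_I))
  cat(sprintf("  G0     = %.3f mmol/L   T_G = %.3f h   AUC = %.1f mmol*min/L\n",
              x$g_stab, x$period_h, x$auc_model))
  invisible(x)
}

#' @export
as.data.frame.curve_features <- function(x, ...) {
  data.frame(test = x$test, g_init = x$g_init, g_rate_init = x$g_rate_init,
             g_extremum = x$g_extremum, t_extremum = x$t_extremum,
             g_rate_I = x$g_rate_I, t_I = x$t_I, g_stab = x$g_stab,
             period_h = x$period_h, auc_model = x$auc_model,
             horizon = x$horizon, boundary = x$boundary,
             stringsAsFactors = FALSE)
}

# Antiderivative of G(t) = g_stab + g(t), closed form per regime.
model_auc_antideriv <- function(params, t, tol = 1e-9) {
  k <- solution_coefs(params, tol)
  base <- params$g_stab * t
  switch(k$regime,
    overdamped = base +
      k$c1 * exp(k$r1 * t) / k$r1 + k$c2 * exp(k$r2 * t) / k$r2,
    underdamped = {
      a <- -k$alpha; b <- k$omega
      base + exp(a * t) *
        (k$A * (a * cos(b * t) + b * sin(b * t)) +
         k$B * (a * sin(b * t) - b * cos(b * t))) / (a^2 + b^2)
    },
    critical = {
      a <- -k$alpha
      base + exp(a * t) * (k$c1 / a + k$c2 * t / a - k$c2 / a^2)
    })
}

#' Area under the modelled glucose curve
#'
#' Computes \eqn{\int_{lower}^{horizon} G(t)\,dt} from the closed-form
#' antiderivative of the fitted curve (exponential or exponential–trig per
#' regime), so the model AUC is directly comparable to the classical
#' trapezoidal AUC on the same window ([trapezoid_auc()]).
#'
#' @inheritParams glucose_curve
#' @param horizon upper integration limit, minutes, > `lower`.
#' @param lower lower integration limit, minutes (default 0).
#' @return AUC in mmol*min/L.
#' @export
model_auc <- function(params, horizon, lower = 0, tol = 1e-9) {
  stopifnot(inherits(params, "model_params"),
            is.finite(horizon), is.finite(lower), horizon > lower, lower >= 0)
  if (params$alpha == 0 && classify_regime(params, tol)$regime != "underdamped")
    stop("alpha = 0 is only integrable in the underdamped regime",
         call. = FALSE)
  model_auc_antideriv(params, horizon, tol) -
    model_auc_antideriv(params, lower, tol)
}
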