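# Independent oracles used across the suite. Each one recomputes a quantity
# by a route that shares no code with the implementation it checks.

# Numerical integration of G'' + 2*alpha*G' + omega0^2*(G - G0) = 0 from the
# same initial data (generic stiff-capable integrator, tight tolerances).
ode_oracle <- function(params, times) {
  rhs <- function(t, state, parms) {
    list(c(state[2],
           -2 * parms$alpha * state[2] -
             parms$omega0_sq * (state[1] - parms$g_stab)))
  }
  out <- deSolve::lsoda(y = c(G = params$mu, dG = params$nu),
                        times = times, func = rhs,
                        parms = params, rtol = 1e-11, atol = 1e-11)
  out[, "G"]
}

# Dense-grid brute force for the extremum and inflection features:
# scan G on a fine grid, locate the first local max (GTT) / min (ITT), then
# the inflection as the interior extremum of the first difference after it
# (the point of steepest decline for GTT / steepest recovery for ITT) — an
# equivalent definition to the first root of G'' that stays well above
# floating-point noise on the fine grid.
dense_feature_oracle <- function(params, test, horizon, step = 0.001) {
  tt <- seq(0, horizon, by = step)
  g <- glucose_curve(params, tt)
  d1 <- diff(g)
  if (test == "GTT") {
    cross <- which(d1[-length(d1)] > 0 & d1[-1] <= 0)
  } else {
    cross <- which(d1[-length(d1)] < 0 & d1[-1] >= 0)
  }
  if (length(cross) == 0L) {
    return(list(t_ext = 0, g_ext = params$mu, t_I = NA_real_,
                g_rate_I = NA_real_, boundary = TRUE))
  }
  i <- cross[1L] + 1L
  t_ext <- tt[i]
  g_ext <- g[i]
  seg <- d1[i:length(d1)]
  j_rel <- if (test == "GTT") which.min(seg) else which.max(seg)
  if (j_rel <= 1L || j_rel >= length(seg)) {
    return(list(t_ext = t_ext, g_ext = g_ext, t_I = NA_real_,
                g_rate_I = NA_real_, boundary = FALSE))
  }
  j <- i + j_rel - 1L   # index into g of the steepest segment start
  t_I <- tt[j] + step / 2
  list(t_ext = t_ext, g_ext = g_ext, t_I = t_I,
       g_rate_I = d1[j] / step, boundary = FALSE)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample (tie-free data only).
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  pooled_ranks <- seq_len(n1 + n2)
  us <- apply(picks, 2, function(ix) sum(pooled_ranks[ix])) -
    n1 * (n1 + 1) / 2
  u_low <- min(u_obs, n1 * n2 - u_obs)
  min(1, (sum(us <= u_low) + sum(us >= n1 * n2 - u_low)) / ncol(picks))
}

# Parameter draws spanning both regimes, GTT-like excursions.
random_valid_params <- function(underdamped = FALSE) {
  a <- exp(stats::runif(1, log(0.008), log(0.08)))
  if (underdamped) {
    alpha <- a
    w2 <- a^2 * stats::runif(1, 1.5, 8)
  } else {
    rho <- stats::runif(1, 2, 6)
    alpha <- a * (1 + rho) / 2
    w2 <- rho * a^2
  }
  g0 <- stats::runif(1, 4, 7)
  model_params(alpha = alpha, omega0_sq = w2, g_stab = g0,
               mu = g0 + stats::runif(1, -0.3, 0.3),
               nu = stats::runif(1, 0.2, 1))
}

make_series <- function(params, test = "GTT", noise_sd = 0,
                        id = "s1", group = "young_male") {
  g <- protocol_grid(test)
  y <- glucose_curve(params, g)
  if (noise_sd > 0) y <- y + stats::rnorm(length(g), 0, noise_sd)
  glucose_series(id, group, test, g, y)
}
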