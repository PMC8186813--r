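#' Instantaneous rate of change of the sRNA amount
#'
#' Right-hand side of the feed-forward production model
#' `dn/dt = (b / (1 + b * n / m) - d) * n + mu`: secondary amplification rises
#' linearly with the template amount `n` when templates are rare and saturates
#' at the maximum rate `m` when they are abundant; transcription `mu` acts
#' independently of `n`. All rates are speed-scaled.
#'
#' @param n sRNA amount per cell (>= 0); vectorised.
#' @param b_now amplification rate currently in effect (>= 0). Defaults to
#'   `params$b`.
#' @param params an [srna_params()] object.
#' @return Rate of change of `n`, in molecules per cell division.
#' @export
srna_rate <- function(n, b_now = params$b, params = srna_params()) {
  if (any(n < 0)) stop("sRNA amount 'n' must be >= 0")
  if (any(b_now < 0)) stop("amplification rate 'b_now' must be >= 0")
  r <- scaled_rates(params)
  b <- b_now * params$speed
  (b / (1 + b * n / r$m) - r$d) * n + r$mu
}

#' Positive steady state of the sRNA dynamics
#'
#' The production model has a single non-negative equilibrium. For `b > 0` it
#' is the positive root of the saturating birth-death balance; for `b = 0` the
#' quadratic degenerates and the equilibrium is the continuous limit `mu / d`.
#' Speed scaling leaves the steady state unchanged.
#'
#' @param params an [srna_params()] object.
#' @return The non-negative fixed point of [srna_rate()].
#' @examples
#' steady_state_level(srna_params(b = 0.5, mu = 6.798))  # ~113.95
#' @export
steady_state_level <- function(params) {
  r <- scaled_rates(params)
  if (r$d <= 0) stop("degradation rate 'd' must be > 0")
  if (r$b == 0) return(r$mu / r$d)
  disc <- r$b * r$m + r$b * r$mu - r$d * r$m
  (disc + sqrt(disc^2 + 4 * r$b * r$d * r$m * r$mu)) / (2 * r$b * r$d)
}

#' Analytic solution of the dynamics without amplification
#'
#' With `b = 0` the model is linear and solves to
#' `n(t) = mu/d + (n0 - mu/d) * exp(-d * t)` (speed-scaled rates). Used as the
#' exact oracle for the numerical integrator.
#'
#' @param n0 initial sRNA amount (>= 0).
#' @param t time in cell divisions (>= 0); vectorised.
#' @param params an [srna_params()] object with `b = 0`.
#' @return sRNA amount at time `t`.
#' @export
closed_form_b0 <- function(n0, t, params = srna_params()) {
  if (params$b != 0)
    stop("closed_form_b0() requires b = 0; got b = ", params$b)
  if (n0 < 0) stop("'n0' must be >= 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  r <- scaled_rates(params)
  nhat <- r$mu / r$d
  nhat + (n0 - nhat) * exp(-r$d * t)
}

#' Amplification-rate profile over development
#'
#' Parametric family `b(t) = b_in + delta * (1 - exp(-a * t))` covering a
#' constant rate (`delta = 0`), a delayed plastic shift towards
#' `b_in + delta` (finite `a`), and an instantaneous shift (`a = Inf`,
#' factor 1 for all `t > 0`).
#'
#' @param b_in rate inherited at the start of development (>= 0).
#' @param delta total plastic shift; `b_in + delta` must be >= 0.
#' @param a delay constant (> 0) or `Inf` for an instantaneous response.
#' @return An object of class `b_profile`; evaluate it with
#'   [profile_value()].
#' @export
b_profile <- function(b_in, delta = 0, a = Inf) {
  stopifnot(is.finite(b_in), is.finite(delta))
  if (b_in < 0) stop("'b_in' must be >= 0")
  if (b_in + delta < 0) stop("profile target 'b_in + delta' must be >= 0")
  if (is.na(a) || a <= 0) stop("'a' must be > 0 (Inf for instantaneous)")
  structure(list(b_in = b_in, delta = delta, a = a), class = "b_profile")
}

#' Evaluate an amplification-rate profile
#'
#' @param profile a [b_profile()] object.
#' @param t time in cell divisions; vectorised.
#' @return The amplification rate in effect at `t`.
#' @export
profile_value <- function(profile, t) {
  stopifnot(inherits(profile, "b_profile"))
  if (is.infinite(profile$a))
    return(profile$b_in + profile$delta * as.numeric(t > 0))
  profile$b_in + profile$delta * (1 - exp(-profile$a * t))
}

#' Integrate the sRNA dynamics over one generation
#'
#' Solves the production model from the zygote amount `n0` across `c_div`
#' cell divisions, with the amplification rate either constant (`params$b`),
#' following a parametric [b_profile()] (fast compiled path), or given by an
#' arbitrary function of time (solved with [deSolve::ode()]). The solution is
#' reported at least at every whole cell division, where fitness is sampled.
#'
#' @param params an [srna_params()] object; `params$b` supplies the constant
#'   rate when `b_prof` is `NULL`.
#' @param n0 zygotic sRNA amount (>= 0).
#' @param c_div number of cell divisions per generation (integer >= 1;
#'   default 20).
#' @param b_prof `NULL`, a [b_profile()] object, or a function `f(t)`
#'   returning the amplification rate at time `t` (unscaled; `speed` is
#'   applied internally).
#' @param times output times; defaults to the integer grid `0:c_div`. Must
#'   start at 0 and end at `c_div`.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return A data frame of class `srna_trajectory` with columns `t`, `n` and
#'   `b_soma` (the unscaled amplification rate in effect at each time).
#' @examples
#' tr <- integrate_generation(srna_params(), n0 = 0)
#' tail(tr, 1)  # n(20) ~ 58.78 at the wildtype optimum mu = 6.798
#' @export
integrate_generation <- function(params, n0, c_div = 20, b_prof = NULL,
                                 times = NULL, rtol = 1e-8, atol = 1e-10) {
  if (n0 < 0) stop("'n0' must be >= 0")
  if (length(c_div) != 1 || c_div < 1 || c_div != round(c_div))
    stop("'c_div' must be a positive integer")
  if (is.null(times)) times <- 0:c_div
  if (times[1] != 0 || times[length(times)] != c_div)
    stop("'times' must start at 0 and end at c_div")
  if (is.unsorted(times)) stop("'times' must be non-decreasing")
  r <- scaled_rates(params)

  if (is.null(b_prof)) b_prof <- b_profile(params$b)

  if (inherits(b_prof, "b_profile")) {
    n <- cpp_integrate_srna(n0, as.numeric(times),
                            b_prof$b_in * params$speed,
                            b_prof$delta * params$speed,
                            b_prof$a, r$d, r$m, r$mu, rtol, atol)
    b_soma <- profile_value(b_prof, times)
  } else if (is.function(b_prof)) {
    bt <- vapply(times, b_prof, numeric(1))
    if (any(bt < 0)) stop("b_prof(t) must be >= 0 on [0, c_div]")
    deriv <- function(t, y, parms) {
      b <- b_prof(t) * params$speed
      list((b / (1 + b * y[1] / r$m) - r$d) * y[1] + r$mu)
    }
    sol <- deSolve::ode(y = c(n = n0), times = as.numeric(times),
                        func = deriv, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    n <- sol[, "n"]
    b_soma <- bt
  } else {
    stop("'b_prof' must be NULL, a b_profile, or a function of time")
  }

  if (any(!is.finite(n)))
    stop("integration produced a non-finite sRNA amount")
  n[n < 0 & n > -atol] <- 0
  structure(data.frame(t = as.numeric(times), n = as.numeric(n),
                       b_soma = as.numeric(b_soma)),
            class = c("srna_trajectory", "data.frame"))
}

#' Write a developmental trajectory to TSV
#'
#' @param traj an `srna_trajectory` from [integrate_generation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "srna_trajectory"))
  write_tsv_12(as.data.frame(traj), path)
  invisible(path)
}
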