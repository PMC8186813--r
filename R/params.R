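#' Within-generation sRNA production parameters
#'
#' Bundles the rates governing small-RNA (sRNA) dynamics inside one organism:
#' transcription from genomic DNA (`mu`), template-driven amplification (`b`,
#' saturating at the maximum rate `m`) and degradation (`d`). Time is measured
#' in cell divisions. The optional `speed` factor multiplies all four rates at
#' once, which leaves the steady-state level untouched but makes the approach
#' to it slower (`speed < 1`) or faster (`speed > 1`).
#'
#' @param b amplification rate per cell division (>= 0).
#' @param d degradation rate per cell division (> 0).
#' @param m maximum amplification rate (> 0); the total birth rate from
#'   templates saturates at `m` when templates are abundant.
#' @param mu transcription rate per cell division (>= 0).
#' @param speed positive scale factor applied multiplicatively to
#'   `b`, `d`, `m` and `mu`. Default 1; 0.75 slows the dynamics, 2 speeds
#'   them up.
#'
#' @return An object of class `srna_params`.
#' @examples
#' p <- srna_params(mu = 6.798)
#' steady_state_level(p)  # mu / d for b = 0
#' @export
srna_params <- function(b = 0, d = 0.1, m = 5, mu = 6.798, speed = 1) {
  stopifnot(length(b) == 1, length(d) == 1, length(m) == 1,
            length(mu) == 1, length(speed) == 1)
  vals <- c(b = b, d = d, m = m, mu = mu, speed = speed)
  if (any(!is.finite(vals)))
    stop("all sRNA rate parameters must be finite")
  if (b < 0) stop("amplification rate 'b' must be >= 0")
  if (mu < 0) stop("transcription rate 'mu' must be >= 0")
  if (speed <= 0) stop("'speed' must be > 0")
  if (d * speed <= 0) stop("degradation rate 'd' must be > 0")
  if (m * speed <= 0) stop("maximum amplification rate 'm' must be > 0")
  structure(list(b = b, d = d, m = m, mu = mu, speed = speed),
            class = "srna_params")
}

# Effective (speed-scaled) rates used by the dynamics routines.
scaled_rates <- function(params) {
  with(params, list(b = b * speed, d = d * speed,
                    m = m * speed, mu = mu * speed))
}

#' @export
print.srna_params <- function(x, ...) {
  cat("sRNA production parameters (per cell division)\n")
  cat(sprintf("  b = %g, d = %g, m = %g, mu = %g", x$b, x$d, x$m, x$mu))
  if (x$speed != 1) cat(sprintf("  [speed x%g]", x$speed))
  cat("\n")
  invisible(x)
}

#' Fitness-function shape constants
#'
#' Constants of the fitness function linking the sRNA amount `n`, the
#' environmental stress `eps` and the plasticity level `P_b` to fitness.
#' Fitness is the product of a cost term `1 / (1 + C_n * n + C_b * P_b)` and a
#' benefit term `exp(-(beta + alpha * eps) * (phenotype(n, h) - eps)^2)`.
#' `h` is the sRNA amount whose phenotype matches an intermediate stress of
#' 0.5; `alpha` makes mismatches costlier in more stressful environments
#' while `beta` sets the baseline penalty.
#'
#' @param alpha stress-steepness constant (default 15).
#' @param beta baseline mismatch penalty (default 0.1).
#' @param h sRNA amount matching stress level 0.5 (default 5, > 0).
#' @param C_n cost per unit of sRNA produced (default 1e-5).
#' @param C_b cost per unit of plasticity (default `50 * C_n`).
#'
#' @return An object of class `fitness_shape`.
#' @export
fitness_shape <- function(alpha = 15, beta = 0.1, h = 5, C_n = 1e-5,
                          C_b = 50 * C_n) {
  vals <- c(alpha = alpha, beta = beta, h = h, C_n = C_n, C_b = C_b)
  if (any(!is.finite(vals))) stop("all fitness-shape constants must be finite")
  if (h <= 0) stop("'h' must be > 0")
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be >= 0")
  if (C_n < 0 || C_b < 0) stop("costs 'C_n' and 'C_b' must be >= 0")
  structure(list(alpha = alpha, beta = beta, h = h, C_n = C_n, C_b = C_b),
            class = "fitness_shape")
}

#' @export
print.fitness_shape <- function(x, ...) {
  cat("Fitness shape: alpha =", x$alpha, "beta =", x$beta, "h =", x$h,
      "C_n =", x$C_n, "C_b =", x$C_b, "\n")
  invisible(x)
}
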