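#' sRNA phenotype: environmental matching level
#'
#' Logistic-shaped map from the sRNA amount to the stress level it matches,
#' `(e^n - 1) / (e^n + e^h - 2)`: 0 with no sRNA, 0.5 at `n = h`, approaching
#' 1 (the match to a maximally stressful environment) for large `n`. Computed
#' on the numerically safe form `(1 - e^-n) / (1 + (e^h - 2) e^-n)` so large
#' `n` cannot overflow.
#'
#' @param n sRNA amount (>= 0); vectorised.
#' @param h amount matching intermediate stress 0.5 (> 0).
#' @return Matching level in `[0, 1)`.
#' @export
phenotype <- function(n, h = 5) {
  if (any(n < 0)) stop("'n' must be >= 0")
  if (h <= 0) stop("'h' must be > 0")
  en <- exp(-n)
  (1 - en) / (1 + (exp(h) - 2) * en)
}

#' Instantaneous fitness of an sRNA level in a given environment
#'
#' Fitness at one moment of development: a production/plasticity cost term
#' `1 / (1 + C_n n + C_b P_b)` times a benefit term penalising the squared
#' mismatch between the phenotype and the environment, with the penalty
#' steepness `beta + alpha * eps` growing with stress so that mismatches are
#' costlier in harsher environments.
#'
#' @param n sRNA amount (>= 0); vectorised.
#' @param eps environmental stress in `[0, 1]`.
#' @param P_b plasticity level in `[0, 1]`.
#' @param shape a [fitness_shape()] object.
#' @return Fitness in `(0, 1]`.
#' @examples
#' optimize(instantaneous_fitness, c(0, 20), eps = 0.1,
#'          maximum = TRUE)$maximum  # ~2.85
#' @export
instantaneous_fitness <- function(n, eps, P_b = 0, shape = fitness_shape()) {
  if (any(n < 0)) stop("'n' must be >= 0")
  if (length(eps) != 1 || eps < 0 || eps > 1)
    stop("'eps' must be a single value in [0, 1]")
  if (length(P_b) != 1 || P_b < 0 || P_b > 1)
    stop("'P_b' must be a single value in [0, 1]")
  cost <- 1 / (1 + shape$C_n * n + shape$C_b * P_b)
  mismatch <- phenotype(n, shape$h) - eps
  cost * exp(-(shape$beta + shape$alpha * eps) * mismatch^2)
}

# log of instantaneous fitness, for geometric means without underflow
log_instantaneous_fitness <- function(n, eps, P_b, shape) {
  mismatch <- phenotype(n, shape$h) - eps
  -log1p(shape$C_n * n + shape$C_b * P_b) -
    (shape$beta + shape$alpha * eps) * mismatch^2
}

#' Lifetime fitness: geometric mean across development
#'
#' Geometric mean of [instantaneous_fitness()] sampled at every whole cell
#' division `t = 0, ..., c` of a developmental trajectory (`c + 1` factors),
#' computed in log space.
#'
#' @param traj an `srna_trajectory` from [integrate_generation()], covering
#'   all integer times from 0 to its final time.
#' @param eps environmental stress of the generation.
#' @param P_b plasticity level of the organism's strategy.
#' @param shape a [fitness_shape()] object.
#' @return Lifetime fitness in `(0, 1]`.
#' @export
lifetime_fitness <- function(traj, eps, P_b = 0, shape = fitness_shape()) {
  stopifnot(inherits(traj, "srna_trajectory") || is.data.frame(traj))
  c_div <- traj$t[nrow(traj)]
  idx <- match(0:c_div, traj$t)
  if (anyNA(idx))
    stop("trajectory must contain every integer time 0..", c_div)
  n <- traj$n[idx]
  if (length(eps) != 1 || eps < 0 || eps > 1)
    stop("'eps' must be a single value in [0, 1]")
  if (P_b < 0 || P_b > 1) stop("'P_b' must be in [0, 1]")
  exp(mean(log_instantaneous_fitness(n, eps, P_b, shape)))
}

#' Geometric mean of per-generation fitnesses
#'
#' Computed in log space so long sequences of very small fitnesses do not
#' underflow.
#'
#' @param w_life vector of per-generation lifetime fitnesses (all > 0).
#' @return `(prod(w_life))^(1/length(w_life))`.
#' @export
geometric_mean_fitness <- function(w_life) {
  if (length(w_life) == 0) stop("'w_life' must be non-empty")
  if (any(!is.finite(w_life)) || any(w_life <= 0))
    stop("all fitness values must be finite and > 0")
  exp(mean(log(w_life)))
}

#' Selection coefficient of a mutant against a resident
#'
#' Relative invasion fitness `w_mut / w_res - 1`; a positive value means the
#' mutant strategy spreads.
#'
#' @param w_mut mutant geometric mean fitness.
#' @param w_res resident geometric mean fitness (> 0).
#' @return Signed selection coefficient.
#' @seealso [is_weak_selection()]
#' @export
selection_coefficient <- function(w_mut, w_res) {
  if (any(w_res <= 0)) stop("'w_res' must be > 0")
  w_mut / w_res - 1
}

#' Is selection effectively neutral?
#'
#' Selection coefficients of magnitude at most 0.001 are classified as weak:
#' drift dominates selection at that strength except in moderately large
#' populations (N > 1000).
#'
#' @param s selection coefficient(s).
#' @param threshold weak-selection cutoff (default 0.001).
#' @return Logical vector.
#' @export
is_weak_selection <- function(s, threshold = 0.001) {
  abs(s) <= threshold
}

#' sRNA amount maximising instantaneous fitness in a given environment
#'
#' @param eps environmental stress in `[0, 1]`.
#' @param shape a [fitness_shape()] object.
#' @param upper upper search bound for `n` (default 20).
#' @return The argmax of [instantaneous_fitness()] over `n in [0, upper]`.
#' @examples
#' optimal_srna_level(0.1)  # ~2.85
#' optimal_srna_level(0.9)  # ~7.19
#' @export
optimal_srna_level <- function(eps, shape = fitness_shape(), upper = 20) {
  stats::optimize(instantaneous_fitness, c(0, upper), eps = eps,
                  shape = shape, maximum = TRUE, tol = 1e-6)$maximum
}
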