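#' Configure an sRNA production/inheritance strategy
#'
#' The six strategies differ in which of three mechanisms they carry beyond
#' plain transcription: a fixed amplification rate, maternal transmission of
#' sRNA transcripts, and plastic adjustment of the amplification rate in the
#' soma and/or germline.
#'
#' \describe{
#'   \item{A}{optimal transcription only (wildtype): `b0 = 0`, `r_germ = 0`,
#'     `P_b = 0`.}
#'   \item{B}{fixed amplification rate `b0 > 0`; no plasticity.}
#'   \item{C}{maternal sRNA transmission `r_germ > 0`; no amplification.}
#'   \item{D}{somatic plasticity: the somatic rate shifts a fraction `P_b`
#'     towards the current environment's optimum; the germline rate stays at
#'     the inherited baseline.}
#'   \item{E}{full plasticity: somatic and germline rates shift together and
#'     the shifted germline rate is inherited.}
#'   \item{F}{germline-only plasticity: the soma keeps the inherited rate; the
#'     germline shifts and is inherited.}
#' }
#'
#' @param id one of `"A"`-`"F"`, or `"custom"` with explicit flags.
#' @param b0 baseline germline amplification rate (must be 0 for A, C, D).
#' @param r_germ fraction of the mother's final sRNA amount deposited in the
#'   zygote, in `[0, 1]`.
#' @param P_b plasticity level in `[0, 1]`: the fraction of the gap to the
#'   per-environment optimal amplification rate closed each generation.
#' @param a plasticity delay constant (> 0), or `Inf` for an instantaneous
#'   response.
#' @param somatic_plastic,germline_plastic only for `id = "custom"`; derived
#'   from `id` otherwise.
#' @return An object of class `strategy_config`.
#' @examples
#' strategy_config("D", P_b = 0.8)
#' strategy_config("C", r_germ = 0.1)
#' @export
strategy_config <- function(id = c("A", "B", "C", "D", "E", "F", "custom"),
                            b0 = 0, r_germ = 0, P_b = 0, a = Inf,
                            somatic_plastic = NULL, germline_plastic = NULL) {
  id <- match.arg(id)
  if (b0 < 0) stop("'b0' must be >= 0")
  if (r_germ < 0 || r_germ > 1) stop("'r_germ' must be in [0, 1]")
  if (P_b < 0 || P_b > 1) stop("'P_b' must be in [0, 1]")
  if (is.na(a) || a <= 0) stop("'a' must be > 0 (Inf for instantaneous)")

  flags <- switch(id,
    A = list(soma = FALSE, germ = FALSE),
    B = list(soma = FALSE, germ = FALSE),
    C = list(soma = FALSE, germ = FALSE),
    D = list(soma = TRUE, germ = FALSE),
    E = list(soma = TRUE, germ = TRUE),
    F = list(soma = FALSE, germ = TRUE),
    custom = list(soma = isTRUE(somatic_plastic),
                  germ = isTRUE(germline_plastic))
  )
  if (id != "custom" && (!is.null(somatic_plastic) ||
                         !is.null(germline_plastic)))
    stop("plasticity flags are derived from 'id'; use id = \"custom\" to set them")

  err <- function(msg) stop("strategy ", id, ": ", msg)
  switch(id,
    A = {
      if (b0 != 0) err("b0 must be 0")
      if (r_germ != 0) err("r_germ must be 0")
      if (P_b != 0) err("P_b must be 0")
    },
    B = {
      if (b0 <= 0) err("b0 must be > 0")
      if (P_b != 0) err("P_b must be 0")
    },
    C = {
      if (b0 != 0) err("b0 must be 0")
      if (r_germ <= 0) err("r_germ must be > 0")
      if (P_b != 0) err("P_b must be 0")
    },
    D = {
      if (b0 != 0) err("b0 must be 0")
      if (P_b <= 0) err("P_b must be > 0")
    },
    E = ,
    F = {
      if (P_b <= 0) err("P_b must be > 0")
    },
    custom = NULL
  )
  if (!flags$soma && !flags$germ && P_b > 0 && id == "custom")
    stop("custom strategy with P_b > 0 needs somatic and/or germline plasticity")

  structure(list(id = id, b0 = b0, r_germ = r_germ, P_b = P_b, a = a,
                 somatic_plastic = flags$soma, germline_plastic = flags$germ),
            class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf("Strategy %s: b0 = %g, r_germ = %g, P_b = %g, a = %s\n",
              x$id, x$b0, x$r_germ, x$P_b,
              if (is.infinite(x$a)) "instant" else format(x$a)))
  cat(sprintf("  plasticity: soma %s, germline %s\n",
              if (x$somatic_plastic) "yes" else "no",
              if (x$germline_plastic) "yes" else "no"))
  invisible(x)
}

# memoisation store for b_wmax
.bwmax_cache <- new.env(parent = emptyenv())

#' Optimal amplification rate for an environment
#'
#' The amplification rate that maximises one-generation lifetime fitness under
#' a constant environment `eps`, for an individual whose development starts at
#' the zygotic sRNA amount `n0` and holds the rate constant throughout. This
#' is the target that plastic strategies shift towards; for lineages that
#' inherit sRNA transcripts (`r_germ > 0`) the target accounts for the head
#' start already present in the zygote. The plasticity cost is excluded from
#' the objective: the cost is charged to the organism's realised fitness, not
#' to the target its response aims at. Results are cached per
#' `(eps, n0, params, shape, c_div)`.
#'
#' @param eps environmental stress in `[0, 1]`.
#' @param params an [srna_params()] object (its `b` field is ignored).
#' @param shape a [fitness_shape()] object.
#' @param c_div cell divisions per generation.
#' @param n0 zygotic sRNA amount of the individual the target is computed for
#'   (default 0, the empty-zygote wildtype context).
#' @param upper upper bound of the search grid for the unscaled rate.
#' @return The fitness-maximising amplification rate (possibly 0).
#' @export
b_wmax <- function(eps, params = srna_params(), shape = fitness_shape(),
                   c_div = 20, n0 = 0, upper = 2) {
  key <- paste(format(c(eps, n0, params$d, params$m, params$mu, params$speed,
                        shape$alpha, shape$beta, shape$h, shape$C_n,
                        c_div, upper), digits = 17), collapse = "|")
  hit <- .bwmax_cache[[key]]
  if (!is.null(hit)) return(hit)

  objective <- function(b) {
    p <- srna_params(b = b, d = params$d, m = params$m, mu = params$mu,
                     speed = params$speed)
    traj <- integrate_generation(p, n0 = n0, c_div = c_div)
    lifetime_fitness(traj, eps = eps, P_b = 0, shape = shape)
  }

  grid <- c(0, exp(seq(log(1e-3), log(upper), length.out = 40)))
  w <- vapply(grid, objective, numeric(1))
  i <- which.max(w)
  if (i == 1 && w[1] >= w[2]) {
    # boundary optimum: amplification never helps in this environment
    res <- 0
  } else {
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(objective, c(lo, hi), maximum = TRUE, tol = 1e-7)
    res <- if (opt$objective >= w[i]) opt$maximum else grid[i]
  }
  .bwmax_cache[[key]] <- res
  res
}

#' Somatic amplification-rate profile for one generation
#'
#' Non-plastic somata (strategies A-C, F) keep the inherited germline rate
#' constant through development. Plastic somata (D, E) shift a fraction `P_b`
#' of the way from the inherited rate towards the current environment's
#' optimum [b_wmax()], with the delay factor `1 - exp(-a t)` (instant when
#' `a = Inf`).
#'
#' @param b_germ_in germline amplification rate inherited at the zygote.
#' @param strategy a [strategy_config()].
#' @param eps_now current environmental stress.
#' @param params,shape,c_div model context passed to [b_wmax()].
#' @param n0 the generation's zygotic sRNA amount, passed to [b_wmax()] so
#'   the plastic target accounts for transmitted transcripts.
#' @return A [b_profile()] object.
#' @export
soma_b_profile <- function(b_germ_in, strategy, eps_now,
                           params = srna_params(), shape = fitness_shape(),
                           c_div = 20, n0 = 0) {
  stopifnot(inherits(strategy, "strategy_config"))
  if (!strategy$somatic_plastic || strategy$P_b == 0)
    return(b_profile(b_germ_in))
  target <- b_wmax(eps_now, params, shape, c_div, n0 = n0)
  b_profile(b_germ_in, delta = strategy$P_b * (target - b_germ_in),
            a = strategy$a)
}

#' Germline amplification rate passed to the next generation
#'
#' Strategies without germline plasticity (A-D) transmit the inherited rate
#' unchanged. Plastic germlines (E, F) shift towards the current environment's
#' optimum, evaluated at the end of development (`t = c_div`).
#'
#' @inheritParams soma_b_profile
#' @return The germline rate inherited by the next generation.
#' @export
germline_b_update <- function(b_germ_in, strategy, eps_now,
                              params = srna_params(),
                              shape = fitness_shape(), c_div = 20, n0 = 0) {
  stopifnot(inherits(strategy, "strategy_config"))
  if (!strategy$germline_plastic || strategy$P_b == 0) return(b_germ_in)
  target <- b_wmax(eps_now, params, shape, c_div, n0 = n0)
  delay <- if (is.infinite(strategy$a)) 1 else 1 - exp(-strategy$a * c_div)
  b_germ_in + strategy$P_b * (target - b_germ_in) * delay
}

#' Maternal sRNA transmission to the zygote
#'
#' @param n_final mother's sRNA amount at the end of development (>= 0).
#' @param r_germ transmitted fraction in `[0, 1]`.
#' @return Zygotic sRNA amount `r_germ * n_final`.
#' @export
transmit_srna <- function(n_final, r_germ) {
  if (any(n_final < 0)) stop("'n_final' must be >= 0")
  if (r_germ < 0 || r_germ > 1) stop("'r_germ' must be in [0, 1]")
  r_germ * n_final
}

#' Simulate one environmental cycle of a lineage
#'
#' Runs `G` consecutive generations through the scenario: build the somatic
#' amplification profile, integrate development, score lifetime fitness,
#' update the germline rate, and transmit sRNA to the next zygote.
#'
#' @param strategy a [strategy_config()].
#' @param params an [srna_params()] object (its `b` field is ignored; the
#'   strategy's `b0` and plastic updates set the rates).
#' @param shape a [fitness_shape()] object.
#' @param scenario a `scenario` from [generate_scenario()].
#' @param state list with the zygotic state entering the cycle: `n_initial`
#'   (sRNA amount) and `b_germ` (germline amplification rate).
#' @param c_div cell divisions per generation.
#' @return List with `records` (data frame: `g`, `eps`, `b_germ_in`,
#'   `b_soma_final`, `b_germ_out`, `n_initial`, `n_final`, `W_LIFE`) and
#'   `state_out` for chaining cycles.
#' @export
simulate_cycle <- function(strategy, params = srna_params(),
                           shape = fitness_shape(), scenario,
                           state = list(n_initial = 0,
                                        b_germ = strategy$b0),
                           c_div = 20) {
  stopifnot(inherits(strategy, "strategy_config"),
            inherits(scenario, "scenario"))
  G <- scenario$G
  n0 <- state$n_initial
  bg <- state$b_germ
  rec <- data.frame(g = seq_len(G), eps = scenario$eps_seq,
                    b_germ_in = NA_real_, b_soma_final = NA_real_,
                    b_germ_out = NA_real_, n_initial = NA_real_,
                    n_final = NA_real_, W_LIFE = NA_real_)
  for (g in seq_len(G)) {
    eps <- scenario$eps_seq[g]
    prof <- soma_b_profile(bg, strategy, eps, params, shape, c_div, n0 = n0)
    traj <- integrate_generation(params, n0 = n0, c_div = c_div,
                                 b_prof = prof)
    w <- lifetime_fitness(traj, eps = eps, P_b = strategy$P_b, shape = shape)
    bg_out <- germline_b_update(bg, strategy, eps, params, shape, c_div,
                                n0 = n0)
    n_final <- traj$n[nrow(traj)]
    rec$b_germ_in[g] <- bg
    rec$b_soma_final[g] <- profile_value(prof, c_div)
    rec$b_germ_out[g] <- bg_out
    rec$n_initial[g] <- n0
    rec$n_final[g] <- n_final
    rec$W_LIFE[g] <- w
    n0 <- transmit_srna(n_final, strategy$r_germ)
    bg <- bg_out
  }
  list(records = rec, state_out = list(n_initial = n0, b_germ = bg))
}

#' Run a lineage to its stationary environmental cycle
#'
#' Lineages that carry state across generations (transmitted sRNA, plastic
#' germline rates) need a burn-in before the repeating scenario produces a
#' repeating trajectory. Cycles are iterated from an empty zygote until the
#' cycle-start state `(n_initial, b_germ)` is unchanged to within `tol`
#' (relative, with an absolute floor for components near zero); the fitness of
#' the final, stationary cycle is reported.
#'
#' @inheritParams simulate_cycle
#' @param tol convergence tolerance on the cycle-start state (default 1e-9).
#' @param max_cycles burn-in cap; exceeding it is an error reporting the
#'   residual.
#' @return An object of class `lineage_result`: `records` of the stationary
#'   cycle, `W_GEO` (geometric mean of `W_LIFE` over the cycle),
#'   `burn_in_cycles`, and the stationary `state`.
#' @export
simulate_to_stationarity <- function(strategy, params = srna_params(),
                                     shape = fitness_shape(), scenario,
                                     c_div = 20, tol = 1e-9,
                                     max_cycles = 200) {
  state <- list(n_initial = 0, b_germ = strategy$b0)
  for (cycle in seq_len(max_cycles)) {
    res <- simulate_cycle(strategy, params, shape, scenario, state, c_div)
    new <- res$state_out
    resid <- max(abs(new$n_initial - state$n_initial) /
                   max(abs(state$n_initial), 1e-6),
                 abs(new$b_germ - state$b_germ) /
                   max(abs(state$b_germ), 1e-6))
    if (resid < tol) {
      return(structure(list(records = res$records,
                            W_GEO = geometric_mean_fitness(res$records$W_LIFE),
                            burn_in_cycles = cycle,
                            state = new),
                       class = "lineage_result"))
    }
    state <- new
  }
  stop("lineage did not reach a stationary cycle in ", max_cycles,
       " cycles (residual ", format(resid, digits = 3), ")")
}

#' @export
print.lineage_result <- function(x, ...) {
  cat(sprintf(
    "Stationary lineage: W_GEO = %.6g after %d burn-in cycle(s)\n",
    x$W_GEO, x$burn_in_cycles))
  cat(sprintf("  cycle-start state: n_initial = %.6g, b_germ = %.6g\n",
              x$state$n_initial, x$state$b_germ))
  invisible(x)
}

#' Write per-generation lineage records to TSV
#'
#' @param result a `lineage_result` (or the `records` data frame itself).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(result, path) {
  rec <- if (inherits(result, "lineage_result")) result$records else result
  write_tsv_12(rec, path)
  invisible(path)
}
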