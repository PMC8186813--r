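#' Optimal transcription rate for the non-amplifying wildtype
#'
#' Maximises the cross-generation geometric mean fitness of strategy A
#' (`b = 0`, no transmission, no plasticity) over the transcription rate.
#' Because strategy A carries no state between generations, its fitness over a
#' balanced scenario is the equally weighted geometric mean of the two
#' per-environment lifetime fitnesses, so no scenario realization is needed —
#' only the composition. Passing a single environment gives the optimum for a
#' constant environment.
#'
#' @param params an [srna_params()] object supplying `d`, `m` and `speed`
#'   (`b` must be 0; `mu` is the optimisation variable).
#' @param shape a [fitness_shape()] object.
#' @param eps_values environments making up the scenario composition
#'   (default the balanced `c(0.1, 0.9)`).
#' @param weights composition weights (default equal).
#' @param c_div cell divisions per generation.
#' @param interval search interval for `mu`.
#' @return List with `mu` (the argmax) and `W_GEO` (the fitness achieved).
#' @examples
#' optimize_transcription()$mu  # ~6.798
#' @export
optimize_transcription <- function(params = srna_params(),
                                   shape = fitness_shape(),
                                   eps_values = c(0.1, 0.9),
                                   weights = NULL, c_div = 20,
                                   interval = c(1e-6, 50)) {
  if (params$b != 0)
    stop("the wildtype transcribes only: 'params$b' must be 0")
  if (is.null(weights)) weights <- rep(1, length(eps_values))
  weights <- weights / sum(weights)

  objective <- function(mu) {
    p <- srna_params(b = 0, d = params$d, m = params$m, mu = mu,
                     speed = params$speed)
    w <- vapply(eps_values, function(eps) {
      traj <- integrate_generation(p, n0 = 0, c_div = c_div)
      log(lifetime_fitness(traj, eps = eps, shape = shape))
    }, numeric(1))
    sum(weights * w)
  }
  # bracket on a coarse grid first, then polish
  grid <- seq(interval[1], interval[2], length.out = 60)
  i <- which.max(vapply(grid, objective, numeric(1)))
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(objective, c(lo, hi), maximum = TRUE, tol = 1e-6)
  list(mu = opt$maximum, W_GEO = exp(opt$objective))
}

#' Invasion of a mutant strategy into a resident population
#'
#' Runs the resident and mutant lineages to their stationary cycles on the
#' same environmental scenario and scores the mutant's selection coefficient
#' `s+ = W_GEO_mut / W_GEO_res - 1`. A mutant invades when `s+ > 0`;
#' `|s+| <= 0.001` is flagged as effectively neutral.
#'
#' @param resident resident [strategy_config()] (typically strategy A at the
#'   optimal transcription rate).
#' @param mutant mutant [strategy_config()].
#' @param params an [srna_params()] object shared by both lineages.
#' @param shape a [fitness_shape()] object.
#' @param scenario a `scenario` from [generate_scenario()].
#' @param c_div cell divisions per generation.
#' @param w_geo_res optional precomputed resident fitness on this scenario,
#'   to avoid recomputation across a sweep.
#' @return An object of class `invasion_result` with `s_plus`, `w_geo_mut`,
#'   `w_geo_res`, `weak` and `scenario_id` (the scenario's seed).
#' @export
invade <- function(resident, mutant, params = srna_params(),
                   shape = fitness_shape(), scenario, c_div = 20,
                   w_geo_res = NULL) {
  if (is.null(w_geo_res))
    w_geo_res <- simulate_to_stationarity(resident, params, shape, scenario,
                                          c_div = c_div)$W_GEO
  w_geo_mut <- simulate_to_stationarity(mutant, params, shape, scenario,
                                        c_div = c_div)$W_GEO
  s <- selection_coefficient(w_geo_mut, w_geo_res)
  structure(list(s_plus = s, w_geo_mut = w_geo_mut, w_geo_res = w_geo_res,
                 weak = is_weak_selection(s), scenario_id = scenario$seed),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Invasion: s+ = %.6g (%s)\n", x$s_plus,
              if (x$weak) "effectively neutral"
              else if (x$s_plus > 0) "mutant favoured"
              else "mutant disfavoured"))
  invisible(x)
}

# rebuild a strategy with some free parameters replaced, keeping its
# plasticity flags (validation relaxed to "custom" so sweep grids may pass
# through boundary values such as P_b = 0)
modify_strategy <- function(strategy, values) {
  fields <- list(b0 = strategy$b0, r_germ = strategy$r_germ,
                 P_b = strategy$P_b, a = strategy$a)
  bad <- setdiff(names(values), names(fields))
  if (length(bad))
    stop("unknown strategy parameter(s): ", paste(bad, collapse = ", "))
  fields[names(values)] <- values
  strategy_config("custom", b0 = fields$b0, r_germ = fields$r_germ,
                  P_b = fields$P_b, a = fields$a,
                  somatic_plastic = strategy$somatic_plastic,
                  germline_plastic = strategy$germline_plastic)
}

#' Selection-coefficient sweep over strategy parameters
#'
#' Evaluates the mutant's selection coefficient on a full factorial grid of
#' strategy parameters, for each scenario realization of an ensemble, plus the
#' arithmetic mean across realizations per grid point. The resident's fitness
#' is computed once per scenario and reused.
#'
#' @param mutant_template a [strategy_config()] whose plasticity flags define
#'   the mutant type; grid axes override its numeric fields.
#' @param axes named list of grids over any of `b0`, `r_germ`, `P_b`, `a`.
#' @param params,shape,c_div model context.
#' @param scenarios a list of `scenario` objects (e.g.
#'   [scenario_ensemble()]), or a single `scenario`.
#' @param resident resident strategy (default strategy A).
#' @return A data frame of class `sweep_table`: one row per grid point and
#'   scenario (`scenario_id`, axes, `s_plus`, `w_geo_mut`, `w_geo_res`), with
#'   the per-point ensemble mean in attribute-free rows flagged by
#'   `scenario_id = NA` appended via `summary_rows`.
#' @export
sweep_selection <- function(mutant_template, axes, params = srna_params(),
                            shape = fitness_shape(), scenarios,
                            c_div = 20, resident = strategy_config("A")) {
  stopifnot(length(axes) >= 1, !is.null(names(axes)))
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  for (g in axes) if (is.unsorted(g, strictly = TRUE))
    stop("each axis grid must be strictly increasing")

  grid <- do.call(expand.grid,
                  c(axes, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  rows <- vector("list", length(scenarios) * nrow(grid))
  ri <- 0L
  for (sc in scenarios) {
    w_res <- simulate_to_stationarity(resident, params, shape, sc,
                                      c_div = c_div)$W_GEO
    for (i in seq_len(nrow(grid))) {
      mut <- modify_strategy(mutant_template, as.list(grid[i, , drop = FALSE]))
      inv <- invade(resident, mut, params, shape, sc, c_div = c_div,
                    w_geo_res = w_res)
      ri <- ri + 1L
      rows[[ri]] <- cbind(data.frame(scenario_id = sc$seed),
                          grid[i, , drop = FALSE],
                          data.frame(s_plus = inv$s_plus,
                                     w_geo_mut = inv$w_geo_mut,
                                     w_geo_res = inv$w_geo_res))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mean_tab <- stats::aggregate(out["s_plus"], out[names(axes)], mean)
  names(mean_tab)[names(mean_tab) == "s_plus"] <- "s_plus_mean"
  structure(out, class = c("sweep_table", "data.frame"),
            mean = mean_tab, axes = names(axes))
}

#' Ensemble-mean selection coefficients of a sweep
#'
#' @param x a `sweep_table` from [sweep_selection()].
#' @return Data frame of grid coordinates and `s_plus_mean`.
#' @export
sweep_mean <- function(x) {
  stopifnot(inherits(x, "sweep_table"))
  attr(x, "mean")
}

#' Optimise a mutant strategy over free parameters
#'
#' Coarse-to-fine grid search of the mean selection coefficient over up to
#' three free strategy parameters: the full fine grid is thinned for a coarse
#' scan, then re-evaluated at fine resolution in the window of one coarse step
#' around the coarse argmax.
#'
#' @param mutant_template a [strategy_config()] defining the mutant type.
#' @param axes named list of fine grids (as in [sweep_selection()]).
#' @param params,shape,scenarios,c_div,resident as in [sweep_selection()].
#' @param coarsen thinning factor for the coarse scan (default 5; 1 disables
#'   the two-stage search).
#' @return List with `argmax` (named list of coordinates), `s_plus` (mean
#'   selection coefficient there), `weak` (TRUE when the whole surface is
#'   within the weak-selection band), and the evaluated `table`.
#' @export
optimize_mutant <- function(mutant_template, axes, params = srna_params(),
                            shape = fitness_shape(), scenarios, c_div = 20,
                            resident = strategy_config("A"), coarsen = 5) {
  if (length(axes) > 3) stop("at most 3 free parameters are supported")
  thin <- function(g) g[unique(c(seq(1, length(g), by = coarsen),
                                 length(g)))]
  coarse_axes <- lapply(axes, thin)
  coarse <- sweep_selection(mutant_template, coarse_axes, params, shape,
                            scenarios, c_div, resident)
  cm <- sweep_mean(coarse)
  best <- cm[which.max(cm$s_plus_mean), , drop = FALSE]

  fine_axes <- axes
  if (coarsen > 1) {
    for (nm in names(axes)) {
      g <- axes[[nm]]
      cg <- coarse_axes[[nm]]
      ci <- which.min(abs(cg - best[[nm]]))
      lo <- cg[max(1, ci - 1)]
      hi <- cg[min(length(cg), ci + 1)]
      fine_axes[[nm]] <- g[g >= lo & g <= hi]
    }
    fine <- sweep_selection(mutant_template, fine_axes, params, shape,
                            scenarios, c_div, resident)
    fm <- sweep_mean(fine)
    tab <- unique(rbind(cm, fm))
  } else {
    tab <- cm
  }
  top <- tab[which.max(tab$s_plus_mean), , drop = FALSE]
  list(argmax = as.list(top[names(axes)]),
       s_plus = top$s_plus_mean,
       weak = all(is_weak_selection(tab$s_plus_mean)),
       table = tab)
}

#' Run a named, preconfigured invasion experiment
#'
#' Binds the parameter settings of the study's figure-level experiments and
#' returns tidy selection-coefficient tables plus a manifest of every
#' parameter and seed used. Available experiments:
#' \describe{
#'   \item{fig3}{strategies B (over `b`) and C (over `r_germ`) at speeds
#'     1, 0.75 and 2.}
#'   \item{fig4}{strategies D, E, F over `P_b`, instant plasticity, scenario
#'     ensembles at k = 2, 9, 17.}
#'   \item{fig5}{strategy D over `P_b` with delayed plasticity (a = 0.15).}
#'   \item{fig6}{strategies D, E, F over `P_b` with a = 0.15.}
#'   \item{s5}{joint (r_germ, b) optimisation of the non-plastic
#'     amplification + transmission mutant.}
#'   \item{s7}{fig4 configuration at the tenfold plasticity cost
#'     (C_b = 500 C_n).}
#'   \item{s8}{fig4 configuration with dynamics slowed to 0.75x.}
#'   \item{s9}{(r_germ, P_b) surfaces of instantly plastic, transmitting
#'     mutants at p_eps = 0.11 and 0.89.}
#' }
#'
#' @param name experiment name.
#' @param overrides named list overriding `speed`, `C_b_factor`, `a`,
#'   `k_values`, `n_realizations`, `seed` or grid axes.
#' @return List with `tables` (named list of data frames) and `manifest`.
#' @export
run_experiment <- function(name = c("fig3", "fig4", "fig5", "fig6",
                                    "s5", "s7", "s8", "s9"),
                           overrides = list()) {
  name <- match.arg(name)
  cfg <- list(seed = 1, n_realizations = 10, speed = 1, C_b_factor = 50,
              a = Inf, k_values = c(2, 9, 17),
              P_b_grid = seq(0.1, 1, by = 0.1),
              r_germ_grid = seq(0, 0.3, by = 0.01),
              b_grid = exp(seq(log(1e-3), log(2), length.out = 40)))
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides

  base <- switch(name, fig5 = , fig6 = list(a = 0.15),
                 s7 = list(C_b_factor = 500),
                 s8 = list(speed = 0.75),
                 list())
  cfg[names(base)] <- base

  shape <- fitness_shape(C_b = cfg$C_b_factor * 1e-5)
  params <- srna_params(speed = cfg$speed)
  resident <- strategy_config("A")
  started <- Sys.time()
  tables <- list()

  if (name == "fig3") {
    sc <- generate_scenario(k = 9, seed = cfg$seed)
    for (sp in c(1, 0.75, 2)) {
      p <- srna_params(speed = sp)
      swB <- sweep_selection(strategy_config("B", b0 = 1),
                             list(b0 = cfg$b_grid), p, shape, sc)
      swC <- sweep_selection(strategy_config("C", r_germ = 0.1),
                             list(r_germ = cfg$r_germ_grid[-1]),
                             p, shape, sc)
      tag <- gsub("[.]", "_", paste0("speed", sp))
      tables[[paste0("strategyB_", tag)]] <- as.data.frame(swB)
      tables[[paste0("strategyC_", tag)]] <- as.data.frame(swC)
    }
  } else if (name %in% c("fig4", "s7", "s8")) {
    for (k in cfg$k_values) {
      scens <- scenario_ensemble(k = k, n_realizations = cfg$n_realizations,
                                 seed = cfg$seed + k)
      swD <- sweep_selection(strategy_config("D", P_b = 0.5, a = cfg$a),
                             list(P_b = cfg$P_b_grid), params, shape,
                             scens[[1]])
      swE <- sweep_selection(strategy_config("E", P_b = 0.5, a = cfg$a),
                             list(P_b = cfg$P_b_grid), params, shape, scens)
      swF <- sweep_selection(strategy_config("F", P_b = 0.5, a = cfg$a),
                             list(P_b = cfg$P_b_grid), params, shape, scens)
      tables[[paste0("strategyD_k", k)]] <- as.data.frame(swD)
      tables[[paste0("strategyE_k", k)]] <- as.data.frame(swE)
      tables[[paste0("strategyF_k", k)]] <- as.data.frame(swF)
    }
  } else if (name == "fig5") {
    sc <- generate_scenario(k = 9, seed = cfg$seed)
    sw <- sweep_selection(strategy_config("D", P_b = 0.5, a = 0.15),
                          list(P_b = cfg$P_b_grid), params, shape, sc)
    tables$strategyD_delayed <- as.data.frame(sw)
  } else if (name == "fig6") {
    for (k in cfg$k_values) {
      scens <- scenario_ensemble(k = k, n_realizations = cfg$n_realizations,
                                 seed = cfg$seed + k)
      for (id in c("D", "E", "F")) {
        strat <- strategy_config(id, P_b = 0.5, a = 0.15)
        use <- if (id == "D") scens[[1]] else scens
        sw <- sweep_selection(strat, list(P_b = cfg$P_b_grid), params,
                              shape, use)
        tables[[paste0("strategy", id, "_k", k)]] <- as.data.frame(sw)
      }
    }
  } else if (name == "s5") {
    sc <- generate_scenario(k = 9, seed = cfg$seed)
    opt <- optimize_mutant(
      strategy_config("custom", b0 = 0.01, r_germ = 0.1),
      list(r_germ = cfg$r_germ_grid, b0 = seq(0, 0.1, by = 0.001)),
      params, shape, sc)
    tables$surface <- opt$table
    tables$optimum <- data.frame(r_germ = opt$argmax$r_germ,
                                 b = opt$argmax$b0, s_plus = opt$s_plus)
  } else if (name == "s9") {
    seeds <- derive_seeds(cfg$seed, 2)
    for (i in 1:2) {
      k <- c(17, 2)[i]
      sc <- generate_scenario(k = k, seed = seeds[i])
      opt <- optimize_mutant(
        strategy_config("E", P_b = 0.5, r_germ = 0.1, a = cfg$a),
        list(r_germ = cfg$r_germ_grid, P_b = seq(0, 1, by = 0.1)),
        params, shape, sc)
      tables[[paste0("surface_k", k)]] <- opt$table
      tables[[paste0("optimum_k", k)]] <-
        data.frame(r_germ = opt$argmax$r_germ, P_b = opt$argmax$P_b,
                   s_plus = opt$s_plus)
    }
  }

  manifest <- list(experiment = name, settings = cfg,
                   resident = unclass(resident)[c("id", "b0", "r_germ",
                                                  "P_b")],
                   runtime_seconds =
                     as.numeric(difftime(Sys.time(), started,
                                         units = "secs")))
  list(tables = tables, manifest = manifest)
}
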