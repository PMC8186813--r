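# Independent numerical oracles used across tests.

# fixed-step classical RK4 for the sRNA dynamics; deliberately independent of
# the package's adaptive integrator
rk4_reference <- function(params, n0, c_div, b_fun = function(t) params$b,
                          dt = 1e-3) {
  sp <- params$speed
  d <- params$d * sp
  m <- params$m * sp
  mu <- params$mu * sp
  f <- function(t, n) {
    b <- b_fun(t) * sp
    (b / (1 + b * n / m) - d) * n + mu
  }
  steps_per_unit <- round(1 / dt)
  out <- numeric(c_div + 1)
  out[1] <- n <- n0
  t <- 0
  for (ti in seq_len(c_div)) {
    for (s in seq_len(steps_per_unit)) {
      k1 <- f(t, n)
      k2 <- f(t + dt / 2, n + dt / 2 * k1)
      k3 <- f(t + dt / 2, n + dt / 2 * k2)
      k4 <- f(t + dt, n + dt * k3)
      n <- n + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
    }
    out[ti + 1] <- n
  }
  out
}

# brute-force lifetime fitness for the b = 0 case, from the analytic solution
product_oracle_b0 <- function(params, n0, c_div, eps, P_b, shape) {
  n <- closed_form_b0(n0, 0:c_div, params)
  w <- instantaneous_fitness(n[1], eps, P_b, shape)
  for (i in 2:(c_div + 1)) w <- w * instantaneous_fitness(n[i], eps, P_b, shape)
  w^(1 / (c_div + 1))
}

# all balanced binary sequences of length G over {0.1, 0.9}
enumerate_balanced <- function(G) {
  idx <- utils::combn(G, G / 2)
  apply(idx, 2, function(pos) {
    s <- rep(0.1, G)
    s[pos] <- 0.9
    s
  })
}

# build a scenario object from an explicit sequence (for permutation tests)
scenario_from_seq <- function(eps_seq, seed = 0L) {
  structure(list(eps_seq = eps_seq, G = length(eps_seq),
                 k = count_switches(eps_seq),
                 p_eps = env_similarity(count_switches(eps_seq),
                                        length(eps_seq)),
                 seed = as.integer(seed)),
            class = "scenario")
}

# permute a scenario's environment order deterministically
permute_scenario <- function(sc, seed) {
  perm <- withr::with_seed(seed, sample(sc$G))
  scenario_from_seq(sc$eps_seq[perm], seed = seed)
}
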