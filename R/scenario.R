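#' Environmental similarity between parents and offspring
#'
#' For a cyclic scenario of `G` generations with `k` switches between the
#' benign and stressful state among the `G - 1` within-cycle adjacent pairs,
#' the probability that a parent and its offspring experience the same
#' environment is `1 - k / (G - 1)`.
#'
#' @param k number of within-cycle environmental switches.
#' @param G cycle length in generations (>= 2).
#' @return Similarity `p_eps` in `[0, 1]`.
#' @examples
#' env_similarity(9, 20)   # ~0.53
#' env_similarity(2, 20)   # ~0.89
#' @export
env_similarity <- function(k, G = 20) {
  if (G < 2 || G != round(G)) stop("'G' must be an integer >= 2")
  if (any(k < 0) || any(k > G - 1) || any(k != round(k)))
    stop("'k' must be an integer in [0, G - 1]")
  1 - k / (G - 1)
}

#' Switch count closest to a target similarity
#'
#' Inverse of [env_similarity()]: the integer `k` whose similarity is nearest
#' the requested `p_eps`. Targets 0.11, 0.53 and 0.89 map to k = 17, 9 and 2
#' at G = 20.
#'
#' @param p_eps target similarity in `[0, 1]`.
#' @param G cycle length.
#' @return Integer switch count.
#' @export
k_from_similarity <- function(p_eps, G = 20) {
  if (any(p_eps < 0) || any(p_eps > 1)) stop("'p_eps' must be in [0, 1]")
  as.integer(round((1 - p_eps) * (G - 1)))
}

# run-length counts for a balanced sequence with k switches: k + 1 runs
# alternate between the two states; the starting state takes ceiling((k+1)/2)
# runs and the other floor((k+1)/2).
scenario_run_counts <- function(G, k) {
  n_first <- ceiling((k + 1) / 2)
  n_second <- floor((k + 1) / 2)
  if (k < 1 || k > G - 1)
    stop("a balanced scenario needs between 1 and G - 1 switches; got k = ", k)
  if (n_first > G / 2 || n_second > G / 2)
    stop("infeasible (G, k): ", k + 1, " runs cannot be filled with G/2 = ",
         G / 2, " generations of each state")
  c(first = n_first, second = n_second)
}

# uniform composition of `total` into `parts` positive integers
sample_composition <- function(total, parts) {
  if (parts == 1) return(total)
  cuts <- sort(sample.int(total - 1, parts - 1))
  diff(c(0L, cuts, total))
}

#' Generate a balanced cyclic environmental scenario
#'
#' Samples uniformly (given `seed`) from the length-`G` sequences over the
#' stress levels {0.1, 0.9} that contain exactly `G/2` generations of each
#' state and exactly `k` switches between adjacent within-cycle generations.
#' The construction is rejection-free: the `k + 1` alternating runs are drawn
#' as uniform compositions of `G/2` per state, and the starting state is
#' chosen uniformly (both starts support equally many sequences).
#'
#' @param G cycle length (even integer, default 20).
#' @param k number of within-cycle switches (`1 <= k <= G - 1`). Exactly one
#'   of `k` and `p_eps` must be given.
#' @param seed integer seed; fixed seeds give identical scenarios.
#' @param p_eps alternatively, a target similarity; converted with
#'   [k_from_similarity()].
#' @param eps_levels the two stress values (benign, stressful).
#' @return An object of class `scenario`: list with `eps_seq`, `G`, `k`,
#'   `p_eps` and `seed`.
#' @examples
#' sc <- generate_scenario(G = 20, k = 9, seed = 42)
#' sc$p_eps  # ~0.53
#' @export
generate_scenario <- function(G = 20, k = NULL, seed = 1, p_eps = NULL,
                              eps_levels = c(0.1, 0.9)) {
  if (G < 2 || G %% 2 != 0) stop("'G' must be an even integer >= 2")
  if (is.null(k) == is.null(p_eps))
    stop("give exactly one of 'k' and 'p_eps'")
  if (is.null(k)) k <- k_from_similarity(p_eps, G)
  if (k != round(k)) stop("'k' must be an integer")
  counts <- scenario_run_counts(G, k)

  eps_seq <- local_seed(seed, {
    start <- sample(1:2, 1)
    lens_first <- sample_composition(G / 2, counts["first"])
    lens_second <- sample_composition(G / 2, counts["second"])
    states <- c(start, 3 - start)
    out <- numeric(0)
    for (i in seq_len(k + 1)) {
      len <- if (i %% 2 == 1) lens_first[(i + 1) / 2] else lens_second[i / 2]
      out <- c(out, rep(eps_levels[states[(i - 1) %% 2 + 1]], len))
    }
    out
  })

  sc <- structure(list(eps_seq = eps_seq, G = G, k = as.integer(k),
                       p_eps = env_similarity(k, G), seed = as.integer(seed)),
                  class = "scenario")
  validate_scenario(sc, eps_levels)
  sc
}

validate_scenario <- function(sc, eps_levels = c(0.1, 0.9)) {
  stopifnot(length(sc$eps_seq) == sc$G)
  tab <- table(factor(sc$eps_seq, levels = eps_levels))
  if (any(tab != sc$G / 2))
    stop("scenario is not balanced: composition ", paste(tab, collapse = "/"))
  k_obs <- count_switches(sc$eps_seq)
  if (k_obs != sc$k)
    stop("scenario has ", k_obs, " switches, expected ", sc$k)
  invisible(sc)
}

#' Count within-cycle environmental switches
#'
#' Number of adjacent positions `i` with `eps_seq[i] != eps_seq[i - 1]`. The
#' wrap-around pair between repeated cycles is not counted, matching the
#' `G - 1` denominator of the similarity statistic.
#'
#' @param eps_seq environment sequence.
#' @return Integer switch count.
#' @export
count_switches <- function(eps_seq) {
  sum(eps_seq[-1] != eps_seq[-length(eps_seq)])
}

#' An ensemble of scenario realizations
#'
#' Distinct-seeded scenarios sharing (`G`, `k`), for averaging invasion
#' results over realizations of the environmental order. Sub-seeds are drawn
#' deterministically from the master `seed`.
#'
#' @param G,k as in [generate_scenario()].
#' @param n_realizations number of scenarios (>= 1).
#' @param seed master seed.
#' @return A list of `scenario` objects.
#' @export
scenario_ensemble <- function(G = 20, k, n_realizations = 10, seed = 1) {
  if (n_realizations < 1) stop("'n_realizations' must be >= 1")
  seeds <- derive_seeds(seed, n_realizations)
  lapply(seeds, function(s) generate_scenario(G = G, k = k, seed = s))
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Environmental scenario: G = %d, k = %d switches, p_eps = %.3f (seed %d)\n",
    x$G, x$k, x$p_eps, x$seed))
  cat("  ", paste(format(x$eps_seq), collapse = " "), "\n")
  invisible(x)
}

#' Write a scenario to CSV
#'
#' Single `eps` column preceded by a comment header carrying
#' `G`, `k`, `p_eps` and `seed`, so a scenario round-trips losslessly.
#'
#' @param sc a `scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  header <- sprintf("# G=%d k=%d p_eps=%.12g seed=%d",
                    sc$G, sc$k, sc$p_eps, sc$seed)
  writeLines(c(header, "eps", format(sc$eps_seq, digits = 12)), path)
  invisible(path)
}

#' Read a scenario written by [write_scenario()]
#'
#' @param path CSV file path.
#' @return A `scenario` object.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  if (!startsWith(header, "#"))
    stop("missing scenario header comment in ", path)
  fields <- regmatches(header,
                       gregexpr("[A-Za-z_]+=[-0-9.eE+]+", header))[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  body <- lines[-1]
  stopifnot(body[1] == "eps")
  eps_seq <- as.numeric(body[-1])
  sc <- structure(list(eps_seq = eps_seq, G = as.integer(meta["G"]),
                       k = as.integer(meta["k"]),
                       p_eps = env_similarity(meta["k"], meta["G"]),
                       seed = as.integer(meta["seed"])),
                  class = "scenario")
  validate_scenario(sc, sort(unique(eps_seq)))
  sc
}
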