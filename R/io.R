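# Deterministic seeding, config files and tabular output.

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible sub-seeds from a master seed
#'
#' One master seed fans out to independent integer sub-seeds (below 2^31) so
#' that components (scenario sampling, ensembles) can be re-run independently
#' without disturbing each other's random streams.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# TSV with fixed column order, '.' decimal separator, 12 significant digits
write_tsv_12 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

config_defaults <- function() {
  list(
    params = list(b = 0, d = 0.1, m = 5, mu = 6.798, speed = 1),
    shape = list(alpha = 15, beta = 0.1, h = 5, C_n = 1e-5, C_b = 5e-4),
    strategy = list(id = "A", b0 = 0, r_germ = 0, P_b = 0, a = Inf),
    scenario = list(G = 20, k = 9, seed = 1, n_realizations = 10),
    c_div = 20,
    outdir = "."
  )
}

#' Load a run configuration from a YAML file
#'
#' Missing fields are filled with the model defaults (d = 0.1, m = 5,
#' mu = 6.798, c = 20, alpha = 15, beta = 0.1, h = 5, C_n = 1e-5,
#' C_b = 50 C_n, G = 20); an empty file yields the full default
#' configuration. Unknown keys are rejected, with the offending field path
#' reported. The parameter, shape and strategy blocks are validated by their
#' constructors.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with elements `params`
#'   ([srna_params()]), `shape` ([fitness_shape()]), `strategy`
#'   ([strategy_config()]), `scenario` (list), `c_div` and `outdir`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()

  unknown_top <- setdiff(names(raw), names(defaults))
  if (length(unknown_top))
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  for (block in c("params", "shape", "strategy", "scenario")) {
    if (!is.null(raw[[block]])) {
      bad <- setdiff(names(raw[[block]]), names(defaults[[block]]))
      if (length(bad))
        stop("unknown config key(s): ",
             paste(paste0(block, "$", bad), collapse = ", "))
    }
  }

  merged <- defaults
  for (nm in names(raw)) {
    if (is.list(defaults[[nm]]))
      merged[[nm]] <- utils::modifyList(defaults[[nm]], raw[[nm]])
    else merged[[nm]] <- raw[[nm]]
  }
  if (is.character(merged$strategy$a)) {
    if (toupper(merged$strategy$a) %in% c("INF", "INSTANT"))
      merged$strategy$a <- Inf
    else stop("strategy$a must be numeric, 'Inf' or 'INSTANT'")
  }

  cfg <- list(
    params = do.call(srna_params, merged$params),
    shape = do.call(fitness_shape, merged$shape),
    strategy = do.call(strategy_config, merged$strategy),
    scenario = merged$scenario,
    c_div = merged$c_div,
    outdir = merged$outdir
  )
  class(cfg) <- "run_config"
  cfg
}

#' Serialize a run configuration back to YAML text
#'
#' `load_config()` and `serialize_config()` round-trip: parsing serialized
#' output reproduces the configuration exactly.
#'
#' @param cfg a `run_config` from [load_config()].
#' @return A YAML string.
#' @export
serialize_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- list(
    params = unclass(cfg$params),
    shape = unclass(cfg$shape),
    strategy = unclass(cfg$strategy)[c("id", "b0", "r_germ", "P_b", "a")],
    scenario = cfg$scenario,
    c_div = cfg$c_div,
    outdir = cfg$outdir
  )
  yaml::as.yaml(plain)
}

#' Write result tables and a manifest to a directory
#'
#' Each table becomes `<name>.tsv` (UTF-8, tab-separated, 12 significant
#' digits, '.' decimal separator); the manifest (parameters, seeds, package
#' version) becomes `manifest.json`. Rewriting identical results is
#' byte-identical.
#'
#' @param tables named list of data frames.
#' @param manifest list of run metadata.
#' @param outdir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, manifest, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    write_tsv_12(tables[[nm]], path)
    files <- c(files, path)
  }
  manifest$package_version <-
    as.character(utils::packageVersion("srnaevol"))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mpath))
}
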