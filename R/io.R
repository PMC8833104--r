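#' Parse a flat key-value run configuration
#'
#' Reads an optional JSON config file of flat keys (`L_max`, `R_max`,
#' `k_on_over_nu`, `K_d`, `k_off`, `nu`, `S_stop`, `t_stop`, `n_reps`,
#' `seed`), applies `overrides` on top (command-line flags beat file
#' values), fills remaining defaults, and validates the result.
#' Exactly one of `k_on_over_nu` and `K_d` may be specified; when both
#' appear the configuration is rejected, and when neither does the
#' default affinity is used.
#'
#' Defaults: `nu = 1e-1` um^2, `R_max = 10`, `k_off = 1` s^-1,
#' `S_stop = 1e4`, `t_stop = 1e4` s, `n_reps = 10` (the measured
#' contact-area parametrization and the replicated-run protocol), plus
#' representative `L_max = 1000` and `K_d = 100`.
#'
#' @param file Path to a JSON file of flat key-value pairs, or `NULL`.
#' @param overrides Named list of values that take precedence over the
#'   file.
#' @return A validated list of class `run_config` with a
#'   [binding_params()] object under `$params` and a
#'   [signalling_config()] under `$run`.
#' @export
parse_config <- function(file = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop("config file not found: ", file, call. = FALSE)
    }
    cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (!is.list(cfg)) stop("config file must be a JSON object", call. = FALSE)
  }
  known <- c("L_max", "R_max", "k_on_over_nu", "K_d", "k_off", "nu",
             "S_stop", "t_stop", "n_reps", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(names(overrides), known)
  if (length(bad) > 0) {
    stop("unknown override key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  if (!is.null(cfg$k_on_over_nu) && !is.null(cfg$K_d)) {
    stop("config error: both 'k_on_over_nu' and 'K_d' given; supply one",
         call. = FALSE)
  }
  defaults <- list(L_max = 1000, R_max = 10, k_off = 1, nu = 1e-1,
                   S_stop = 1e4, t_stop = 1e4, n_reps = 10, seed = NULL)
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$k_on_over_nu) && is.null(cfg$K_d)) cfg$K_d <- 100
  params <- binding_params(cfg$L_max, cfg$R_max, k_off = cfg$k_off,
                           k_on_over_nu = cfg$k_on_over_nu, K_d = cfg$K_d,
                           nu = cfg$nu)
  run <- signalling_config(S_stop = cfg$S_stop, t_stop = cfg$t_stop,
                           n_reps = cfg$n_reps, seed = cfg$seed)
  structure(list(params = params, run = run, raw = cfg),
            class = "run_config")
}

#' Write results with a provenance sidecar
#'
#' Serializes a result table (a data frame, a [summary_measures()]
#' object, or a [sweep_dose()] grid -- the latter two are converted to
#' their canonical data-frame forms) to CSV (RFC 4180) or JSON with a
#' deterministic column order and floats at 12 significant digits.  A
#' JSON sidecar `<path>.meta.json` records the seed, parameter block
#' and package version, sufficient to re-run the computation.
#'
#' @param records Data frame, `summary_measures`, or
#'   `dose_response_grid`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param meta Named list merged into the sidecar (e.g. `seed`,
#'   parameter values).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json"),
                          meta = list()) {
  format <- match.arg(format)
  if (inherits(records, "summary_measures") ||
      inherits(records, "dose_response_grid")) {
    if (inherits(records, "dose_response_grid") && is.null(meta$seed)) {
      meta$seed <- records$seed
    }
    records <- as.data.frame(records)
  }
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame (or coercible object)",
         call. = FALSE)
  }
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], signif, digits = 12)
  ok <- tryCatch({
    if (format == "csv") {
      write.csv(records, path, row.names = FALSE, quote = TRUE)
    } else {
      jsonlite::write_json(records, path, digits = NA, dataframe = "rows",
                           na = "null", auto_unbox = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write results to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  sidecar <- c(list(package = "tcrfluct",
                    version = as.character(packageVersion("tcrfluct")),
                    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    format = format, n_rows = nrow(records),
                    columns = names(records)),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_results <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' Preset parameter grids and brute-force fixtures
#'
#' Packages the measured parameter ranges as ready-made grids:
#'
#' * `"tiny"`: every `(L_max, R_max)` pair with both counts <= 3,
#'   crossed with `K_d` in `{0.1, 1, 10}`, each with the exact
#'   stationary distribution, moments, entropy and adhesion probability
#'   computed by direct (non-log-space) brute-force evaluation --
#'   an independent oracle for testing.
#' * `"table1"`: copy numbers and `K_d` values derived from the
#'   measured surface densities and effective 2D affinities at
#'   `nu = 1e-1` um^2.
#' * `"fig2"`: `L_max = 1000`, `R_max = 10` with `k_on/nu` spanning
#'   `[1e-4, 1e0]` s^-1 and `k_off` in `{1, 10}` s^-1.
#' * `"fig3"`: dose-response axes (`L_max` log-spaced over `[1, 1000]`,
#'   `K_d` in `{10, 1e2, 1e3, 1e4}`, `R_max` in `{10, 100}`,
#'   `k_off = 1` s^-1).
#'
#' @param preset One of `"tiny"`, `"table1"`, `"fig2"`, `"fig3"`.
#' @param seed Seed recorded with the fixture (the grids themselves are
#'   deterministic).
#' @return A list with `preset`, `seed`, `cases` (data frame of
#'   parameter sets) and, for `"tiny"`, `expected` (a list of
#'   brute-force results parallel to the rows of `cases`).
#' @export
generate_fixture_grid <- function(preset = c("tiny", "table1", "fig2", "fig3"),
                                  seed = 1L) {
  preset <- match.arg(preset)
  out <- list(preset = preset, seed = seed)
  if (preset == "tiny") {
    cases <- expand.grid(L_max = 0:3, R_max = 0:3, K_d = c(0.1, 1, 10),
                         k_off = 1, KEEP.OUT.ATTRS = FALSE)
    out$cases <- cases
    out$expected <- lapply(seq_len(nrow(cases)), function(i) {
      brute_force_stationary(cases$L_max[i], cases$R_max[i], cases$K_d[i])
    })
  } else if (preset == "table1") {
    nu <- 1e-1
    out$cases <- expand.grid(
      L_max = round(counts_from_density(c(1e1, 1e2, 1e3), nu)),
      R_max = round(counts_from_density(1e2, nu)),
      K_d = kd_from_effective_affinity(c(1e-3, 1e-4, 1e-5, 1e-6), nu),
      k_off = c(1, 10), nu = nu, KEEP.OUT.ATTRS = FALSE)
  } else if (preset == "fig2") {
    out$cases <- expand.grid(L_max = 1000L, R_max = 10L,
                             kon_over_nu = 10^seq(-4, 0),
                             k_off = c(1, 10), KEEP.OUT.ATTRS = FALSE)
  } else {
    out$cases <- expand.grid(
      L_max = unique(round(10^seq(0, 3, length.out = 13))),
      R_max = c(10L, 100L), K_d = c(10, 1e2, 1e3, 1e4), k_off = 1,
      KEEP.OUT.ATTRS = FALSE)
  }
  out
}

# Direct evaluation of the stationary weights with plain choose() and
# factorial(); safe for the small copy numbers of the tiny preset and
# deliberately independent of the log-space route.
brute_force_stationary <- function(L_max, R_max, K_d) {
  B_max <- min(L_max, R_max)
  U_max <- max(L_max, R_max)
  B <- 0:B_max
  a <- choose(B_max, B) * choose(U_max, B) * K_d^(-B) * factorial(B)
  Z <- sum(a)
  p <- a / Z
  i <- B
  m <- sum(i * p)
  list(L_max = L_max, R_max = R_max, K_d = K_d, p = p, Z = Z,
       mean_B = m, var_B = sum(i^2 * p) - m^2,
       shannon_entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
       adhesion_probability = 1 - p[1])
}
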