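#' Configuration of the sampling-with-replacement simulator
#'
#' The simulator realizes the stochastic account of the verbal-fluency
#' time course: covert retrieval proceeds by repeatedly sampling, with
#' replacement, one tuple from the `2^i` tuple structure, one draw per
#' elementary process of duration `1/r` seconds. A draw succeeds when
#' the sampled tuple is admissible, i.e. disjoint from the already
#' produced words (the empty tuple counts as favorable); after `n`
#' productions the admissible count is `2^(i-n)` of `2^i`, so the
#' per-draw success probability is the geometric sequence `2^-n`. On a
#' success one still-unproduced word is produced (chosen uniformly; by
#' symmetry the choice does not affect the timing law). In `geometric`
#' mode the success probability is `q^n` for an arbitrary decay ratio
#' `q` in (0, 1), generalizing the `uniform_tuple` case `q = 1/2`.
#'
#' @param i number of producible items (word labels `w1..wi`).
#' @param r draws per second, `> 0`.
#' @param mode `"uniform_tuple"` (tuple counting, `q = 1/2`) or
#'   `"geometric"` (explicit `q`).
#' @param q success-decay ratio in `(0, 1)`; required in geometric mode,
#'   fixed at `1/2` in uniform_tuple mode.
#' @param n_runs number of runs for [generate_fixture_set()].
#' @param seed integer seed; every simulator entry point draws all its
#'   randomness from it.
#' @param max_draws per-run draw budget; a run that exhausts it before
#'   producing all words is flagged `truncated` (never silently
#'   clipped).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(i, r = 1, mode = c("uniform_tuple", "geometric"),
                              q = NULL, n_runs = 1L, seed = 1L,
                              max_draws = 1e6) {
  mode <- match.arg(mode)
  if (length(i) != 1L || is.na(i) || i < 1 || i != round(i))
    stop("'i' must be a single integer >= 1")
  .check_pos(r = r)
  if (mode == "uniform_tuple") {
    if (!is.null(q) && abs(q - 0.5) > 1e-12)
      stop("uniform_tuple mode fixes q = 1/2; use mode = 'geometric' for other q")
    q <- 0.5
  } else {
    if (is.null(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
      stop("geometric mode requires 'q' in (0, 1)")
  }
  if (length(n_runs) != 1L || is.na(n_runs) || n_runs < 1 ||
      n_runs != round(n_runs))
    stop("'n_runs' must be a single integer >= 1")
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("'seed' must be a single integer")
  if (length(max_draws) != 1L || !is.finite(max_draws) || max_draws < 1)
    stop("'max_draws' must be >= 1")
  structure(list(i = as.integer(i), r = r, mode = mode, q = q,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 max_draws = max_draws),
            class = "simulation_config")
}

#' Number of admissible tuples after m productions
#'
#' Of the `2^i` tuples over `i` items, those disjoint from an `m`-word
#' produced set number `2^(i-m)` — the "favorable objects" of the
#' sampling model, the empty tuple included. The per-draw retrieval
#' probability at stage `m` is therefore `2^(i-m)/2^i = 2^-m`.
#'
#' @param i total number of items.
#' @param m number of already-produced items, `0 <= m <= i`.
#' @return integer count `2^(i-m)`.
#' @examples
#' admissible_count(3, 0)  # 8
#' admissible_count(3, 3)  # 1 (only the empty tuple)
#' @export
admissible_count <- function(i, m) {
  if (length(i) != 1L || is.na(i) || i < 1 || i != round(i))
    stop("'i' must be a single integer >= 1")
  if (length(m) != 1L || is.na(m) || m < 0 || m != round(m))
    stop("'m' must be a single integer >= 0")
  if (m > i) stop("'m' must not exceed 'i'")
  2^(i - m)
}

#' Ordered production record
#'
#' The unit of observation for curve fitting: the produced word labels
#' in order with their onset times in seconds. Onsets must be strictly
#' increasing and words unique (a verbal-fluency response contains no
#' repetitions).
#'
#' @param words character vector of produced word labels, in order.
#' @param onsets numeric vector of onset times (seconds), strictly
#'   increasing, same length as `words`.
#' @param run_id optional identifier carried in the record.
#' @return object of class `production_record`, a data.frame with
#'   columns `word` and `onset_seconds`.
#' @export
production_record <- function(words, onsets, run_id = NA_integer_) {
  words <- as.character(words)
  onsets <- as.numeric(onsets)
  if (length(words) != length(onsets))
    stop("'words' and 'onsets' must have equal length")
  if (anyDuplicated(words))
    stop("repeated word in production record")
  if (length(onsets) && (any(onsets <= 0) || any(diff(onsets) <= 0)))
    stop("onsets must be positive and strictly increasing")
  structure(
    data.frame(word = words, onset_seconds = onsets,
               stringsAsFactors = FALSE),
    run_id = run_id,
    class = c("production_record", "data.frame")
  )
}

#' Simulate one verbal-fluency production run
#'
#' Runs the sampling-with-replacement process of [simulation_config()]:
#' time advances in elementary steps of `1/r` seconds per draw; at stage
#' `n` each draw succeeds with probability `2^-n` (uniform_tuple) or
#' `q^n` (geometric) — the waiting draws are sampled from the matching
#' geometric distribution — and on success one unproduced word is
#' produced at the current time. The run ends when all `i` words are
#' produced or the draw budget is exhausted (flagged via the
#' `truncated` attribute). The first word always arrives on the first
#' draw, at onset `1/r`, since every tuple is initially admissible.
#'
#' Randomness comes from the session RNG; callers wanting reproducible
#' runs should `set.seed()` first or use [generate_fixture_set()],
#' which seeds from the config.
#'
#' @param config a [simulation_config()].
#' @param run_id identifier stored in the record.
#' @return a [production_record()] with attributes `draws_per_stage`
#'   (draws spent waiting at each stage), `truncated` (logical) and
#'   `config`.
#' @export
simulate_run <- function(config, run_id = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  i <- config$i
  words <- character(0)
  onsets <- numeric(0)
  draws_per_stage <- integer(0)
  remaining <- paste0("w", seq_len(i))
  t <- 0
  total_draws <- 0
  truncated <- FALSE
  for (n in 0:(i - 1L)) {
    p <- config$q^n
    draws <- stats::rgeom(1L, p) + 1L   # draws until (and incl.) success
    if (total_draws + draws > config$max_draws) {
      truncated <- TRUE
      break
    }
    total_draws <- total_draws + draws
    t <- t + draws / config$r
    pick <- if (length(remaining) == 1L) 1L else
      sample.int(length(remaining), 1L)
    words <- c(words, remaining[pick])
    remaining <- remaining[-pick]
    onsets <- c(onsets, t)
    draws_per_stage <- c(draws_per_stage, draws)
  }
  rec <- production_record(words, onsets, run_id = run_id)
  attr(rec, "draws_per_stage") <- draws_per_stage
  attr(rec, "truncated") <- truncated
  attr(rec, "config") <- config
  rec
}

#' Continuum-limit logarithmic parameters of a simulator configuration
#'
#' Averaging the sampling process over draws gives the rate equation
#' `dn/dt = r q^n`, whose solution is the logarithmic time course
#' `n(t) = k ln(1 + r t / k)` with `k = 1/ln(1/q)`: the uniform-tuple
#' structure (`q = 1/2`) implies `k = 1/ln 2` (about 1.4427 words), and
#' the configured draw rate passes through as the curve's `r`.
#'
#' @param config a [simulation_config()].
#' @return a [log_params()].
#' @examples
#' theoretical_curve(simulation_config(i = 12))$k  # 1/log(2)
#' @export
theoretical_curve <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  log_params(k = 1 / log(1 / config$q), r = config$r)
}

#' Write a reproducible set of simulated production records
#'
#' Seeds the RNG from `config$seed`, simulates `config$n_runs` runs, and
#' writes one CSV per run (columns `word`, `onset_seconds`) plus a JSON
#' manifest holding the configuration and file list. Output is
#' byte-identical for identical configurations.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of [production_record()]s.
#' @export
generate_fixture_set <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  records <- lapply(seq_len(config$n_runs), function(j)
    simulate_run(config, run_id = j))
  files <- character(config$n_runs)
  for (j in seq_len(config$n_runs)) {
    files[j] <- file.path(dir, sprintf("run_%04d.csv", j))
    write_production_record(records[[j]], files[j])
  }
  manifest <- list(
    config = unclass(config),
    n_runs = config$n_runs,
    files = basename(files),
    truncated_runs = which(vapply(records, attr, logical(1), "truncated"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(records)
}
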