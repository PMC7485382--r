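test_that("admissible tuple counts halve with every produced word", {
  expect_equal(admissible_count(3, 0), 8)
  expect_equal(admissible_count(3, 3), 1)   # only the empty tuple survives
  expect_equal(admissible_count(4, 1), 8)
  # brute force: enumerate the subsets of 4 items disjoint from one item
  items <- c("A", "B", "C", "D")
  disjoint <- Filter(function(s) !"A" %in% s, enumerate_subsets(items))
  expect_equal(length(disjoint), admissible_count(4, 1))
  for (i in 1:8) for (m in 0:i)
    expect_equal(admissible_count(i, m), 2^(i - m))
  expect_error(admissible_count(3, 4), "exceed")
  expect_error(admissible_count(0, 0), ">= 1")
})

test_that("configurations are validated", {
  expect_error(simulation_config(i = 0), ">= 1")
  expect_error(simulation_config(i = 5, r = 0), "> 0")
  expect_error(simulation_config(i = 5, mode = "geometric"), "requires 'q'")
  expect_error(simulation_config(i = 5, mode = "geometric", q = 1), "requires 'q'")
  expect_error(simulation_config(i = 5, q = 0.3), "fixes q")
  cfg <- simulation_config(i = 5, mode = "geometric", q = 0.5)
  expect_equal(cfg$q, 0.5)
  expect_equal(simulation_config(i = 5)$q, 0.5)
})

test_that("a run produces unique words at increasing onsets, the first at 1/r", {
  set.seed(11)
  cfg <- simulation_config(i = 8, r = 2)
  for (j in 1:25) {
    rec <- simulate_run(cfg, run_id = j)
    expect_equal(nrow(rec), 8)
    expect_equal(rec$onset_seconds[1], 1 / cfg$r)  # p_1 = 1: first draw succeeds
    expect_false(any(duplicated(rec$word)))
    expect_true(all(diff(rec$onset_seconds) > 0))
    expect_false(attr(rec, "truncated"))
    expect_setequal(rec$word, paste0("w", 1:8))
  }
})

test_that("a tight draw budget truncates the run and flags it", {
  set.seed(3)
  cfg <- simulation_config(i = 10, max_draws = 12)
  rec <- simulate_run(cfg)
  expect_true(attr(rec, "truncated"))
  expect_lt(nrow(rec), 10)
  expect_gte(nrow(rec), 1)   # the first word always arrives (p_1 = 1)
})

test_that("stage-wise success frequencies follow the geometric law", {
  set.seed(101)
  cfg <- simulation_config(i = 7, r = 1)
  runs <- lapply(1:3000, function(j) simulate_run(cfg, j))
  draws <- vapply(runs, attr, numeric(7), "draws_per_stage")
  for (n in 0:5) {
    total <- sum(draws[n + 1, ])
    p_hat <- length(runs) / total
    p <- 2^(-n)
    se <- sqrt(p * (1 - p) / total)
    expect_lt(abs(p_hat - p), max(3 * se, 1e-12))
  }
  # mean onsets match the sum of geometric waiting times, within 3 SE
  mt <- mean_onsets(runs)
  for (n in 1:7) {
    expected <- (2^n - 1) / cfg$r
    se <- stats::sd(vapply(runs, function(r) r$onset_seconds[n],
                           numeric(1))) / sqrt(length(runs))
    expect_lt(abs(mt[n] - expected), 3 * se + 1e-9)
  }
})

test_that("geometric mode realizes the configured decay ratio", {
  set.seed(55)
  k <- 3
  cfg <- simulation_config(i = 6, mode = "geometric", q = exp(-1 / k))
  runs <- lapply(1:2000, function(j) simulate_run(cfg, j))
  draws <- vapply(runs, attr, numeric(6), "draws_per_stage")
  for (n in 0:4) {
    total <- sum(draws[n + 1, ])
    p_hat <- length(runs) / total
    p <- exp(-n / k)
    se <- sqrt(p * (1 - p) / total)
    expect_lt(abs(p_hat - p), max(3 * se, 1e-12))
  }
})

test_that("the continuum-limit parameters follow from the decay ratio", {
  expect_equal(theoretical_curve(simulation_config(i = 12))$k, 1 / log(2))
  expect_equal(theoretical_curve(
    simulation_config(i = 5, mode = "geometric", q = exp(-1)))$k, 1)
  expect_equal(theoretical_curve(simulation_config(i = 5, r = 2.5))$r, 2.5)
})

test_that("fixture sets are deterministic and re-readable", {
  cfg <- simulation_config(i = 6, n_runs = 5, seed = 99)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  unlink(c(d1, d2), recursive = TRUE)
  recs1 <- generate_fixture_set(cfg, d1)
  recs2 <- generate_fixture_set(cfg, d2)
  expect_length(recs1, 5)
  for (j in 1:5) {
    f1 <- file.path(d1, sprintf("run_%04d.csv", j))
    f2 <- file.path(d2, sprintf("run_%04d.csv", j))
    expect_identical(readLines(f1), readLines(f2))
    back <- read_production_record(f1)
    expect_equal(back$word, recs1[[j]]$word)
    expect_equal(back$onset_seconds, recs1[[j]]$onset_seconds)
    expect_gte(nrow(back), 1)
  }
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$config$seed, 99)
  expect_length(manifest$files, 5)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("averaged simulated curves recover the theoretical k and are mostly logarithmic", {
  cfg <- simulation_config(i = 10, r = 1, n_runs = 300, seed = 2024)
  recs <- generate_fixture_set(cfg, file.path(tempdir(), "fixK"))
  unlink(file.path(tempdir(), "fixK"), recursive = TRUE)
  mt <- mean_onsets(recs)
  fit <- fit_production(production_record(paste0("w", 1:10), mt),
                        models = c("logarithmic", "fbf"))
  k_hat <- if (fit$model == "logarithmic") fit$params$k else
    fit$params$c / fit$params$alpha
  expect_equal(k_hat, 1 / log(2), tolerance = 0.1)
  # per-run model selection: the logarithmic form wins in the majority
  set.seed(5)
  sel <- vapply(recs[1:60], function(r)
    fit_production(r)$model, "")
  expect_gt(mean(sel == "logarithmic"), 0.5)
})
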