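#' Parameters of the fused Bousfieldian function
#'
#' The fused Bousfieldian function (FBF) unifies the classical
#' exponential and hyperbolic cumulative-recall curves in one
#' three-parameter family,
#' \deqn{n(t) = c\,[1 - (1 + \alpha r t / c)^{-1/\alpha}],}
#' with `c` the asymptote (words), `r` the reciprocal of the elementary
#' process duration (per second) and `alpha` a dimensionless shape
#' factor. `alpha = 1` gives the hyperbolic curve
#' \eqn{crt/(c + rt)}; the limit \eqn{\alpha \to 0} gives the
#' exponential \eqn{c(1 - e^{-rt/c})}; the limit \eqn{\alpha \to \infty}
#' with \eqn{k = c/\alpha} held fixed gives the logarithmic curve of
#' [log_params()].
#'
#' @param c asymptote in words, `> 0`.
#' @param r rate in 1/seconds, `> 0`.
#' @param alpha shape factor, `> 0`.
#' @return object of class `fbf_params`.
#' @export
fbf_params <- function(c, r, alpha) {
  .check_pos(c = c, r = r, alpha = alpha)
  structure(list(c = c, r = r, alpha = alpha), class = "fbf_params")
}

#' Parameters of the logarithmic time-course
#'
#' The logarithmic special case of the fused Bousfieldian function,
#' \deqn{n(t) = k \ln(1 + r t / k),}
#' with `k = c/alpha` the scale (words) and `r` the rate (per second).
#' Its word-retrieval probabilities form the decreasing geometric
#' sequence \eqn{p_{n+1} = e^{-n/k}} (see [retrieval_probabilities()]).
#'
#' @param k scale in words, `> 0`.
#' @param r rate in 1/seconds, `> 0`.
#' @return object of class `log_params`.
#' @export
log_params <- function(k, r) {
  .check_pos(k = k, r = r)
  structure(list(k = k, r = r), class = "log_params")
}

.check_pos <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite value > 0", nm))
  }
  invisible(TRUE)
}

#' Evaluate the fused Bousfieldian curve
#'
#' @param t time(s) in seconds, `>= 0` (vectorized).
#' @param p an [fbf_params()].
#' @return cumulative words produced at each `t`; `n(0) = 0`, monotone
#'   nondecreasing, bounded by `p$c`.
#' @examples
#' fbf_curve(10, fbf_params(c = 20, r = 2, alpha = 1))  # hyperbolic: 10
#' @export
fbf_curve <- function(t, p) {
  stopifnot(inherits(p, "fbf_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  p$c * (1 - (1 + p$alpha * p$r * t / p$c)^(-1 / p$alpha))
}

#' Evaluate the logarithmic curve
#'
#' @param t time(s) in seconds, `>= 0` (vectorized).
#' @param p a [log_params()].
#' @return cumulative words at each `t`; unbounded, concave, increasing.
#' @export
log_curve <- function(t, p) {
  stopifnot(inherits(p, "log_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  p$k * log(1 + p$r * t / p$k)
}

## closed-form curves, derivatives and (where available) time inverses
## for the four candidate models; pars is a named numeric vector
.model_curve <- function(model, pars, t) {
  switch(model,
    logarithmic = pars[["k"]] * log(1 + pars[["r"]] * t / pars[["k"]]),
    exponential = pars[["c"]] * (1 - exp(-pars[["r"]] * t / pars[["c"]])),
    hyperbolic = pars[["c"]] * pars[["r"]] * t / (pars[["c"]] + pars[["r"]] * t),
    fbf = {
      c0 <- pars[["c"]]; r0 <- pars[["r"]]; a0 <- pars[["alpha"]]
      c0 * (1 - (1 + a0 * r0 * t / c0)^(-1 / a0))
    },
    stop("unknown model: ", model)
  )
}

.model_deriv <- function(model, pars, t) {
  switch(model,
    logarithmic = pars[["r"]] / (1 + pars[["r"]] * t / pars[["k"]]),
    exponential = pars[["r"]] * exp(-pars[["r"]] * t / pars[["c"]]),
    hyperbolic = {
      c0 <- pars[["c"]]; r0 <- pars[["r"]]
      r0 * (c0 / (c0 + r0 * t))^2
    },
    fbf = {
      c0 <- pars[["c"]]; r0 <- pars[["r"]]; a0 <- pars[["alpha"]]
      r0 * (1 + a0 * r0 * t / c0)^(-1 / a0 - 1)
    },
    stop("unknown model: ", model)
  )
}

## asymptote of the cumulative curve (Inf for unbounded models)
.model_asymptote <- function(model, pars) {
  switch(model,
    logarithmic = Inf,
    exponential = ,
    hyperbolic = pars[["c"]],
    fbf = pars[["c"]],
    stop("unknown model: ", model)
  )
}

## time t_n at which the curve reaches n words; closed form for the
## logarithmic model, monotone bisection (uniroot) otherwise
.model_invert <- function(model, pars, n) {
  if (n == 0) return(0)
  if (model == "logarithmic") {
    k <- pars[["k"]]; r <- pars[["r"]]
    return((k / r) * (exp(n / k) - 1))
  }
  f <- function(t) .model_curve(model, pars, t) - n
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e12)
      stop(sprintf("curve never reaches n = %g words", n))
  }
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Word-retrieval probabilities from a time-course model
#'
#' The sampling-with-replacement reading of a fitted time course: the
#' probability of retrieving the `n + 1`-th word is
#' \deqn{p_{n+1} = n'(t_n)/r,}
#' the slope of the cumulative curve at the time `t_n` when the `n`-th
#' word is produced (with \eqn{t_0 = 0}), divided by the sampling rate
#' `r`. For the logarithmic model this is exactly the decreasing
#' geometric sequence \eqn{p_{n+1} = e^{-n/k}}, with constant ratio
#' \eqn{e^{-1/k}}; for every model \eqn{p_1 = n'(0)/r = 1}.
#'
#' @param model a [log_params()] or [fbf_params()] object, or a fitted
#'   candidate from [fit_production()] (list with `model` and `pars`).
#' @param n_max number of probabilities `p_1 .. p_{n_max}` to return.
#' @return numeric vector of length `n_max`, values in `(0, 1]`.
#' @examples
#' retrieval_probabilities(log_params(k = 1 / log(2), r = 1), 4)
#' # 1, 1/2, 1/4, 1/8
#' @export
retrieval_probabilities <- function(model, n_max) {
  if (length(n_max) != 1L || is.na(n_max) || n_max < 1 || n_max != round(n_max))
    stop("'n_max' must be a single integer >= 1")
  if (inherits(model, "log_params")) {
    name <- "logarithmic"; pars <- c(k = model$k, r = model$r)
  } else if (inherits(model, "fbf_params")) {
    name <- "fbf"; pars <- c(c = model$c, r = model$r, alpha = model$alpha)
  } else if (inherits(model, "exponential_params")) {
    name <- "exponential"; pars <- c(c = model$c, r = model$r)
  } else if (inherits(model, "hyperbolic_params")) {
    name <- "hyperbolic"; pars <- c(c = model$c, r = model$r)
  } else if (is.list(model) && !is.null(model$model) && !is.null(model$pars)) {
    name <- model$model; pars <- model$pars
  } else {
    stop("'model' must be log_params, fbf_params or a fitted candidate")
  }
  asym <- .model_asymptote(name, pars)
  if (n_max - 1 >= asym)
    stop(sprintf(
      "n_max = %d exceeds the model asymptote (%.3f words): t_n undefined",
      n_max, asym))
  r <- pars[["r"]]
  vapply(seq_len(n_max) - 1L, function(n) {
    tn <- .model_invert(name, pars, n)
    .model_deriv(name, pars, tn) / r
  }, numeric(1))
}

#' Fit time-course models to a production record
#'
#' Least-squares fits of candidate cumulative curves to the points
#' `(t_j, j)`, `j = 1..n` — word index against onset time, the
#' traditional plotting convention for verbal-fluency time courses.
#' Each candidate is fitted by bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) from a small grid of starting values
#' (`r0 = 2/t_2` from the early onsets; `c0 = 1.5 x` word count; an
#' `alpha` grid `{0.01, 0.1, 1, 10}` for the FBF), with all parameters
#' bounded to `(1e-6, 1e6)`; fits ending on a bound are flagged.
#' Candidates are compared by the small-sample-corrected Akaike
#' criterion computed from the Gaussian-SSE likelihood,
#' \eqn{AICc = N\ln(SSE/N) + 2K + 2K(K+1)/(N-K-1)} with
#' `K = #parameters + 1`; the selected model minimizes AICc. With fewer
#' points than `K + 2` a candidate's AICc is infinite and it cannot be
#' selected.
#'
#' @param record a [production_record()] (or any data.frame with
#'   `word` and `onset_seconds` columns) holding at least 4 productions
#'   with strictly increasing onsets.
#' @param models candidate names among `"fbf"`, `"logarithmic"`,
#'   `"exponential"`, `"hyperbolic"`.
#' @return object of class `vf_fit`: list with `model` (selected name),
#'   `params` (parameter object of the selected model), `sse`, `aicc`,
#'   and `candidates` (per-model list with `pars`, `sse`, `aicc`,
#'   `at_bound`, `error`).
#' @examples
#' p <- log_params(k = 1 / log(2), r = 1)
#' tn <- (p$k / p$r) * (exp(seq_len(10) / p$k) - 1)
#' rec <- production_record(paste0("w", 1:10), tn)
#' fit_production(rec)$model  # "logarithmic"
#' @export
fit_production <- function(record,
                           models = c("fbf", "logarithmic",
                                      "exponential", "hyperbolic")) {
  models <- match.arg(models, several.ok = TRUE)
  df <- as.data.frame(record)
  if (!all(c("word", "onset_seconds") %in% names(df)))
    stop("record must have columns 'word' and 'onset_seconds'")
  t <- as.numeric(df$onset_seconds)
  nw <- length(t)
  if (nw < 4L)
    stop("at least 4 productions are required for curve fitting")
  if (any(diff(t) <= 0) || any(t <= 0))
    stop("onsets must be positive and strictly increasing")
  n <- seq_len(nw)
  dat <- data.frame(t = t, n = n)

  r0 <- 2 / (t[2] + 1e-9)
  c0 <- 1.5 * nw
  k_grid <- unique(c(0.5, 1 / log(2), 5, 20, nw / 2))
  alpha_grid <- c(0.01, 0.1, 1, 10)
  lower <- 1e-6; upper <- 1e6

  starts <- list(
    logarithmic = lapply(k_grid, function(k) list(k = k, r = r0)),
    exponential = list(list(c = c0, r = r0), list(c = nw + 0.5, r = r0)),
    hyperbolic = list(list(c = c0, r = r0), list(c = nw + 0.5, r = r0)),
    fbf = unlist(lapply(alpha_grid, function(a)
      list(list(c = c0, r = r0, alpha = a))), recursive = FALSE)
  )
  formulas <- list(
    logarithmic = n ~ k * log(1 + r * t / k),
    exponential = n ~ c * (1 - exp(-r * t / c)),
    hyperbolic = n ~ c * r * t / (c + r * t),
    fbf = n ~ c * (1 - (1 + alpha * r * t / c)^(-1 / alpha))
  )

  candidates <- list()
  for (m in models) {
    best <- NULL
    errs <- character()
    for (st in starts[[m]]) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          formulas[[m]], data = dat, start = st,
          lower = rep(lower, length(st)), upper = rep(upper, length(st)),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        errs <- c(errs, conditionMessage(fit))
        next
      }
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(pars = stats::coef(fit), sse = sse)
    }
    if (is.null(best)) {
      candidates[[m]] <- list(pars = NULL, sse = NA_real_, aicc = Inf,
                              at_bound = NA,
                              error = paste(unique(errs), collapse = "; "))
      next
    }
    K <- length(best$pars) + 1
    aicc <- if (nw - K - 1 >= 1) {
      nw * log(max(best$sse, 1e-300) / nw) + 2 * K +
        2 * K * (K + 1) / (nw - K - 1)
    } else Inf
    at_bound <- any(best$pars <= lower * (1 + 1e-6)) ||
      any(best$pars >= upper * (1 - 1e-6))
    candidates[[m]] <- list(model = m, pars = best$pars, sse = best$sse,
                            aicc = aicc, at_bound = at_bound, error = NULL)
  }

  aiccs <- vapply(candidates, function(x) x$aicc, numeric(1))
  if (all(!is.finite(aiccs))) {
    fails <- vapply(candidates, function(x)
      if (is.null(x$error)) "too few points for AICc" else x$error, "")
    stop("no candidate model could be fitted/selected: ",
         paste(sprintf("%s (%s)", names(candidates), fails), collapse = "; "))
  }
  sel <- names(candidates)[which.min(aiccs)]
  pars <- candidates[[sel]]$pars
  params <- switch(sel,
    logarithmic = log_params(pars[["k"]], pars[["r"]]),
    fbf = fbf_params(pars[["c"]], pars[["r"]], pars[["alpha"]]),
    exponential = ,
    hyperbolic = structure(list(c = pars[["c"]], r = pars[["r"]]),
                           class = paste0(sel, "_params"))
  )
  structure(list(model = sel, params = params,
                 sse = candidates[[sel]]$sse,
                 aicc = candidates[[sel]]$aicc,
                 candidates = candidates),
            class = "vf_fit")
}

#' @export
print.vf_fit <- function(x, ...) {
  cat("Verbal-fluency time-course fit\n")
  cat(sprintf("  selected model: %s (SSE = %.6g, AICc = %.4g)\n",
              x$model, x$sse, x$aicc))
  p <- unlist(x$params[names(x$params) %in% c("c", "r", "alpha", "k")])
  cat("  parameters: ",
      paste(sprintf("%s = %.6g", names(p), p), collapse = ", "), "\n")
  cat("  candidates (AICc):",
      paste(sprintf("%s %.4g", names(x$candidates),
                    vapply(x$candidates, function(z) z$aicc, numeric(1))),
            collapse = ", "), "\n")
  invisible(x)
}
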