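#' Normalized state vector over a tuple basis
#'
#' A state is a real coefficient vector \eqn{(c_k)} over the full
#' \eqn{2^i} tuple basis, subject to the normalization
#' \eqn{\sum_k |c_k|^2 = 1}: producing a word zeroes the coefficients of
#' the tuples that contain it, but the vector's magnitude is preserved
#' because the underlying representations remain part of the network.
#' Coefficients are signed reals; complex phases are out of scope.
#'
#' @param basis a [tuple_basis()] with the empty tuple included.
#' @param coefficients numeric vector of length `2^i`, ordered by
#'   ascending decimal index.
#' @param tol tolerance on the squared-norm check.
#' @return object of class `state_vector` with fields `basis` and
#'   `coefficients`.
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' s <- state_vector(b, rep(1 / sqrt(8), 8))
#' state_norm(s)  # 1
#' @export
state_vector <- function(basis, coefficients, tol = 1e-9) {
  stopifnot(inherits(basis, "tuple_basis"))
  if (!basis$include_empty)
    stop("state vectors are defined over the full basis (include_empty = TRUE)")
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != basis$size)
    stop(sprintf("expected %d coefficients, got %d",
                 basis$size, length(coefficients)))
  if (anyNA(coefficients))
    stop("coefficients must not contain NA")
  n2 <- sum(coefficients^2)
  if (abs(n2 - 1) > tol)
    stop(sprintf("state not normalized: sum of squared coefficients = %.12g", n2))
  structure(list(basis = basis, coefficients = coefficients),
            class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  tab <- basis_table(x$basis)
  cat(sprintf("State vector over %d items (%d tuples):\n",
              x$basis$i, x$basis$size))
  print(data.frame(tuple = tab$tuple_label, ket = tab$bitstring,
                   coefficient = x$coefficients))
  invisible(x)
}

#' Uniform initial state
#'
#' The equal-activation state over all tuples: every coefficient equals
#' \eqn{1/\sqrt{2^i}}. This is the initial state of the logarithmic
#' word-production time course, in which all tuples are admissible and
#' equally weighted.
#'
#' @param basis a [tuple_basis()] with the empty tuple included.
#' @return a [state_vector()].
#' @examples
#' uniform_state(tuple_basis(c("A", "B", "C")))$coefficients  # 8 x 1/sqrt(8)
#' @export
uniform_state <- function(basis) {
  stopifnot(inherits(basis, "tuple_basis"))
  if (!basis$include_empty)
    stop("the uniform initial state requires the empty tuple in the basis")
  state_vector(basis, rep(1 / sqrt(basis$size), basis$size))
}

#' Sign-flipped (inseparable) initial state
#'
#' Identical to [uniform_state()] except that the empty-tuple coefficient
#' is negated. Normalization constrains only the coefficient magnitudes,
#' so this is an equally valid initial state — but unlike the uniform
#' state it admits no tensor factorization into per-item factors
#' (see [is_separable()]): the informational entities no longer exist in
#' separation.
#'
#' @param basis a [tuple_basis()] with the empty tuple included.
#' @return a [state_vector()].
#' @export
xbar_state <- function(basis) {
  s <- uniform_state(basis)
  s$coefficients[1L] <- -s$coefficients[1L]
  s
}

#' State after a set of words has been produced
#'
#' Once the words in `produced` have been uttered, every tuple containing
#' any of them is inadmissible and carries coefficient 0; the remaining
#' \eqn{2^{i-m}} tuples (those disjoint from the produced set, the empty
#' tuple included) stay equally and positively weighted, renormalized to
#' unit squared norm. Producing all `i` words leaves the pure
#' empty-tuple ("inactive") basis state.
#'
#' @param basis a [tuple_basis()] with the empty tuple included.
#' @param produced character vector of already-produced items (possibly
#'   empty).
#' @return a [state_vector()].
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' post_production_state(b, "C")$coefficients  # (1/2, 1/2, 1/2, 1/2, 0, 0, 0, 0)
#' @export
post_production_state <- function(basis, produced) {
  stopifnot(inherits(basis, "tuple_basis"))
  if (!basis$include_empty)
    stop("post-production states require the empty tuple in the basis")
  produced <- as.character(produced)
  pos <- match(produced, basis$items)
  if (anyNA(pos))
    stop("produced item(s) not in the basis item set: ",
         paste(produced[is.na(pos)], collapse = ", "))
  if (anyDuplicated(produced))
    stop("duplicate items in 'produced'")
  mask <- as.integer(sum(2^(pos - 1L)))   # bits of produced items
  keep <- bitwAnd(basis$indices, mask) == 0L
  coef <- numeric(basis$size)
  coef[keep] <- 1 / sqrt(sum(keep))
  state_vector(basis, coef)
}

#' Squared norm of a state's coefficient vector
#'
#' Returns \eqn{\sum_k |c_k|^2}, the conserved quantity of the model:
#' word-production rotations change coefficients but never this sum.
#' Accepts a raw numeric vector as well, so that candidate coefficient
#' vectors can be checked before construction.
#'
#' @param state a [state_vector()] or numeric vector.
#' @return single numeric value.
#' @export
state_norm <- function(state) {
  if (inherits(state, "state_vector")) state <- state$coefficients
  sum(as.numeric(state)^2)
}

#' Tensor-product separability of a state
#'
#' A state over `i` items is separable when its coefficient vector,
#' reshaped as an `i`-way tensor with one binary mode per item,
#' factorizes as an outer product of `i` two-component unit vectors —
#' i.e. when each mode unfolding has rank 1. The test computes the
#' second singular value of every `2 x 2^(i-1)` unfolding and declares
#' separability when all of them fall below `tol`; the factors are the
#' leading left singular vectors, with signs fixed so that each factor's
#' first nonzero entry is non-negative and any residual global sign is
#' absorbed into the last factor.
#'
#' The uniform initial state factorizes into `i` copies of
#' \eqn{(1/\sqrt2)(|0\rangle + |1\rangle)}; the sign-flipped state
#' [xbar_state()] does not factorize at all.
#'
#' @param state a [state_vector()].
#' @param tol singular-value tolerance; default `1e-9` suits
#'   double-precision exact constructions.
#' @return object of class `factorization`: list with `separable`
#'   (logical) and, when separable, `factors` (an `i x 2` matrix, one
#'   row per item giving the weights of digits 0 and 1).
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' is_separable(uniform_state(b))$separable  # TRUE
#' is_separable(xbar_state(b))$separable     # FALSE
#' @export
is_separable <- function(state, tol = 1e-9) {
  stopifnot(inherits(state, "state_vector"))
  i <- state$basis$i
  coef <- state$coefficients
  if (abs(sum(coef^2) - 1) > 1e-6)
    stop("state is not normalized")
  if (i == 1L) {
    f <- matrix(coef, nrow = 1)
    if (f[1, 1] < 0 || (f[1, 1] == 0 && f[1, 2] < 0)) f <- -f
    return(structure(list(separable = TRUE, factors = f),
                     class = "factorization"))
  }
  tens <- array(coef, dim = rep(2L, i))
  factors <- matrix(NA_real_, nrow = i, ncol = 2)
  for (b in seq_len(i)) {
    unfold <- apply(tens, b, identity)      # 2^(i-1) x 2, rows = other modes
    sv <- svd(t(unfold))                    # 2 x 2^(i-1)
    if (sv$d[2] >= tol)
      return(structure(list(separable = FALSE, factors = NULL),
                       class = "factorization"))
    factors[b, ] <- sv$u[, 1]
  }
  # sign convention: first nonzero entry of each factor non-negative,
  # residual global sign absorbed into the last factor
  for (b in seq_len(i)) {
    f <- factors[b, ]
    nz <- which(abs(f) > tol)[1]
    if (!is.na(nz) && f[nz] < 0) factors[b, ] <- -f
  }
  recon <- .outer_coefficients(factors)
  s <- sign(sum(recon * coef))
  if (s < 0) factors[i, ] <- -factors[i, ]
  recon <- .outer_coefficients(factors)
  if (max(abs(recon - coef)) > sqrt(tol) * 10 + 1e-8)
    return(structure(list(separable = FALSE, factors = NULL),
                     class = "factorization"))
  structure(list(separable = TRUE, factors = factors),
            class = "factorization")
}

## coefficient vector of the outer product of i per-item (digit0, digit1)
## factor pairs, in ascending decimal-index order (item 1 = LSB)
.outer_coefficients <- function(factors) {
  i <- nrow(factors)
  coef <- 1
  for (b in seq_len(i)) {
    # item b varies with bit b-1: block structure of the Kronecker order
    coef <- as.vector(outer(coef, factors[b, ]))
  }
  coef
}

#' @export
print.factorization <- function(x, ...) {
  if (x$separable) {
    cat("Separable state; per-item factors (digit 0, digit 1):\n")
    print(x$factors)
  } else {
    cat("Inseparable state (no rank-1 tensor factorization).\n")
  }
  invisible(x)
}
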