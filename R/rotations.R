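#' The minimal rotation matrix
#'
#' Every word-production operator is built from one 2x2 orthogonal
#' matrix,
#' \deqn{\rho = \frac{1}{\sqrt2}\begin{pmatrix} 1 & 1 \\ -1 & 1 \end{pmatrix},}
#' a 45-degree plane rotation (the analogue of an elementary quantum
#' logic gate). Acting on the (without-item, with-item) coordinate pair
#' it sends the equal pair \eqn{(1/\sqrt2, 1/\sqrt2)} to \eqn{(1, 0)}:
#' the with-item coordinate is zeroed and its weight transferred, norm
#' preserved.
#'
#' @return a 2x2 numeric matrix.
#' @examples
#' minimal_matrix() %*% c(1, 1) / sqrt(2)  # (1, 0)
#' @export
minimal_matrix <- function() {
  matrix(c(1, -1, 1, 1), nrow = 2) / sqrt(2)
}

#' Word-production rotation operator
#'
#' The orthogonal \eqn{2^i \times 2^i} operator `R_w` that realizes the
#' production of item `w`: on every index pair (tuple without `w`, same
#' tuple plus `w`) it acts as the minimal matrix [minimal_matrix()], and
#' it mixes no other coordinates. Equivalently, `R_w` is the Kronecker
#' product of identity factors on all other items with `rho` on the
#' factor of `w`. Applied to a state in which the `w`-free and
#' `w`-containing halves carry equal coefficients, it zeroes every tuple
#' containing `w` while conserving the squared norm.
#'
#' All production operators over one basis share the structure and the
#' eigenvalue multiset of `rho` (each eigenvalue \eqn{e^{\pm i\pi/4}}
#' at multiplicity \eqn{2^{i-1}}), hence lie in a single similarity
#' equivalence class: one minimal matrix drives the whole production
#' sequence.
#'
#' Dense entries are materialized for `i <= 12`; beyond that the
#' operator stays matrix-free (application is blockwise either way, and
#' the spectrum is known analytically).
#'
#' @param basis a [tuple_basis()] with the empty tuple included.
#' @param item the produced item label (must be in `basis$items`).
#' @return object of class `production_operator` with fields `basis`,
#'   `item`, `bit` (0-based bit position) and `entries` (dense matrix or
#'   `NULL`).
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' xC <- apply_operator(production_operator(b, "C"), uniform_state(b))
#' xC$coefficients  # (1/2, 1/2, 1/2, 1/2, 0, 0, 0, 0)
#' @export
production_operator <- function(basis, item) {
  stopifnot(inherits(basis, "tuple_basis"))
  if (!basis$include_empty)
    stop("production operators act on the full basis (include_empty = TRUE)")
  item <- as.character(item)
  pos <- match(item, basis$items)
  if (length(item) != 1L || is.na(pos))
    stop("'item' must be a single label from the basis item set")
  bit <- pos - 1L
  entries <- NULL
  if (basis$i <= 12L) {
    rho <- minimal_matrix()
    entries <- matrix(0, basis$size, basis$size)
    lo <- which(bitwAnd(basis$indices, bitwShiftL(1L, bit)) == 0L)
    hi <- lo + 2L^bit  # positions are indices + 1; adding 2^bit sets the bit
    entries[cbind(lo, lo)] <- rho[1, 1]
    entries[cbind(lo, hi)] <- rho[1, 2]
    entries[cbind(hi, lo)] <- rho[2, 1]
    entries[cbind(hi, hi)] <- rho[2, 2]
  }
  structure(list(basis = basis, item = item, bit = bit, entries = entries),
            class = "production_operator")
}

#' @export
print.production_operator <- function(x, ...) {
  cat(sprintf("Production operator R_%s on a %d-item tuple basis (%d x %d)\n",
              x$item, x$basis$i, x$basis$size, x$basis$size))
  invisible(x)
}

#' @export
as.matrix.production_operator <- function(x, ...) {
  if (!is.null(x$entries)) return(x$entries)
  # materialize blockwise for large bases on demand
  n <- x$basis$size
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    out[, j] <- .apply_bitpair(e, x$bit)
  }
  out
}

## blockwise application of rho to every (bit clear, bit set) pair
.apply_bitpair <- function(coef, bit) {
  n <- length(coef)
  idx <- seq_len(n) - 1L
  lo <- which(bitwAnd(idx, bitwShiftL(1L, bit)) == 0L)
  hi <- lo + 2L^bit
  a <- coef[lo]; b <- coef[hi]
  coef[lo] <- (a + b) / sqrt(2)
  coef[hi] <- (b - a) / sqrt(2)
  coef
}

#' Apply a production operator to a state
#'
#' Computes `op %*% state` blockwise (each (without-item, with-item)
#' coordinate pair is rotated by the minimal matrix); the squared norm
#' of the result equals that of the input to machine precision.
#'
#' @param op a [production_operator()].
#' @param state a [state_vector()] over the same basis.
#' @return a [state_vector()].
#' @export
apply_operator <- function(op, state) {
  stopifnot(inherits(op, "production_operator"),
            inherits(state, "state_vector"))
  if (state$basis$size != op$basis$size)
    stop("operator and state dimensions do not match")
  out <- state
  out$coefficients <- .apply_bitpair(state$coefficients, op$bit)
  out
}

#' Apply a sequence of production rotations
#'
#' Rotates `start` by the production operator of each item of `order` in
#' turn and returns the trajectory of intermediate states. Production
#' operators commute (they act on disjoint tensor factors), so the final
#' state of a full production sequence is order-independent: starting
#' from the uniform state and producing all `i` items always ends in the
#' pure empty-tuple ("inactive") state with coefficient +1.
#'
#' @param basis a [tuple_basis()] with the empty tuple included.
#' @param order character vector of distinct items to produce, in order.
#' @param start starting [state_vector()]; default the uniform state.
#' @return list of [state_vector()]s, one per production (empty list for
#'   an empty order).
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' traj <- apply_sequence(b, c("C", "B", "A"))
#' traj[[3]]$coefficients  # (1, 0, 0, 0, 0, 0, 0, 0)
#' @export
apply_sequence <- function(basis, order, start = uniform_state(basis)) {
  stopifnot(inherits(basis, "tuple_basis"))
  order <- as.character(order)
  if (anyDuplicated(order))
    stop("'order' must not repeat items")
  stopifnot(inherits(start, "state_vector"))
  out <- vector("list", length(order))
  s <- start
  for (j in seq_along(order)) {
    s <- apply_operator(production_operator(basis, order[j]), s)
    out[[j]] <- s
  }
  out
}

#' Eigenvalue spectrum of a production operator
#'
#' The eigenvalues as a sorted multiset (ascending by real part, then
#' imaginary part, after rounding to `digits` decimals for stable
#' comparison). Every production operator over an `i`-item basis has the
#' spectrum of the minimal matrix — \eqn{e^{\pm i\pi/4}} — with each
#' eigenvalue at multiplicity \eqn{2^{i-1}}.
#'
#' @param op a [production_operator()], or any square numeric matrix.
#' @param digits rounding used for the multiset ordering (default 9).
#' @return complex vector of eigenvalues, sorted.
#' @export
operator_spectrum <- function(op, digits = 9) {
  m <- if (inherits(op, "production_operator")) {
    if (is.null(op$entries)) {
      # analytic: rho's eigenvalues, each at multiplicity 2^(i-1)
      half <- op$basis$size / 2
      ev <- complex(real = cos(pi / 4) , imaginary = sin(pi / 4))
      vals <- c(rep(Conj(ev), half), rep(ev, half))
      return(vals[order(round(Re(vals), digits), round(Im(vals), digits))])
    }
    op$entries
  } else {
    as.matrix(op)
  }
  vals <- eigen(m, only.values = TRUE)$values
  vals <- as.complex(vals)
  vals[order(round(Re(vals), digits), round(Im(vals), digits))]
}

#' Are two production operators similar?
#'
#' Production operators are orthogonal, hence normal, so equality of
#' eigenvalue multisets (within `tol`) is equivalent to similarity by an
#' invertible `P` with `P R P^-1`. Operators over bases of different
#' dimension are not comparable.
#'
#' @param op1,op2 [production_operator()]s of equal dimension.
#' @param tol numeric tolerance on the sorted spectra.
#' @return `TRUE` or `FALSE`.
#' @export
similar_operators <- function(op1, op2, tol = 1e-9) {
  stopifnot(inherits(op1, "production_operator"),
            inherits(op2, "production_operator"))
  if (op1$basis$size != op2$basis$size)
    stop("operators have different dimensions")
  s1 <- operator_spectrum(op1)
  s2 <- operator_spectrum(op2)
  all(Mod(s1 - s2) < tol)
}
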