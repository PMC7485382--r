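#' Construct the tuple basis over a set of items
#'
#' The state space of the model is spanned by the non-ordered tuples
#' (subsets) of `i` items, written as tensor products
#' \eqn{|\alpha\beta\gamma\ldots\rangle} of per-item binary digits. Each
#' basis vector is identified by a decimal index whose bit `b` is 1 iff
#' the item at position `b + 1` of `items` belongs to the tuple; the first
#' item is the least-significant bit, so with items `A, B, C` the tuple
#' `{A, B}` is the ket `|110>` and carries index 3.
#'
#' With the empty tuple included the basis has \eqn{N = 2^i} vectors, the
#' regime of the fused Bousfieldian word-production model. Dropping the
#' empty ("inactive") tuple gives the \eqn{N = 2^i - 1} counting of neural
#' cliques in a functional connectivity motif; the enumeration is the same
#' minus index 0.
#'
#' @param items character vector of distinct item labels (length
#'   `1 <= i <= 20`; the cap bounds the `2^i` basis size).
#' @param include_empty logical; include the empty tuple (index 0)?
#'   Default `TRUE`.
#' @return An object of class `tuple_basis` with fields `items`,
#'   `include_empty`, `i` (item count), `size` (`2^i` or `2^i - 1`) and
#'   `indices` (ascending decimal indices of the enumerated tuples).
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' b$size               # 8
#' tuple_to_index(b, c("A", "B"))   # 3
#' index_to_tuple(b, 6)             # "B" "C"
#' @seealso [basis_table()], [clique_count()], [render_barcode()]
#' @export
tuple_basis <- function(items, include_empty = TRUE) {
  items <- as.character(items)
  if (length(items) < 1L)
    stop("'items' must contain at least one label")
  if (length(items) > 20L)
    stop("'items' may contain at most 20 labels (basis size 2^i)")
  if (anyDuplicated(items))
    stop("'items' labels must be unique")
  if (any(!nzchar(items)) || anyNA(items))
    stop("'items' labels must be non-empty and non-missing")
  stopifnot(is.logical(include_empty), length(include_empty) == 1L)
  i <- length(items)
  first <- if (include_empty) 0L else 1L
  structure(
    list(
      items = items,
      include_empty = include_empty,
      i = i,
      size = as.integer(2^i - !include_empty),
      indices = as.integer(seq.int(first, 2^i - 1))
    ),
    class = "tuple_basis"
  )
}

#' @export
print.tuple_basis <- function(x, ...) {
  cat(sprintf(
    "Tuple basis over %d item(s): %s\n%s tuples (%s empty tuple)\n",
    x$i, paste(x$items, collapse = ", "), x$size,
    if (x$include_empty) "including" else "excluding"
  ))
  invisible(x)
}

#' Number of tuples / neural cliques over i items
#'
#' `2^i` when the empty tuple is counted (the all-tuples connectivity of
#' the word-production model), `2^i - 1` when it is not (cliques of a
#' functional connectivity motif).
#'
#' @param i number of items (inputs), integer `>= 1`.
#' @param include_empty logical; count the empty tuple?
#' @return integer (double for large `i`).
#' @examples
#' clique_count(3, FALSE)  # 7
#' clique_count(4, TRUE)   # 16
#' @export
clique_count <- function(i, include_empty = TRUE) {
  if (length(i) != 1L || is.na(i) || i < 1 || i != round(i))
    stop("'i' must be a single integer >= 1")
  2^i - !include_empty
}

## bit b (0-based) of index k, for items at positions b+1
.index_bits <- function(k, i) {
  as.integer(bitwAnd(bitwShiftR(as.integer(k), 0:(i - 1L)), 1L))
}

#' Decimal index of a tuple
#'
#' Inverse of [index_to_tuple()]: the index is
#' \eqn{\sum_b 2^{b}} over the 0-based positions `b` of the members in
#' the basis item list.
#'
#' @param basis a [tuple_basis()].
#' @param members character vector, a subset of `basis$items` (may be
#'   empty when the basis includes the empty tuple).
#' @return single integer index.
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' tuple_to_index(b, c("A", "C"))  # 5
#' tuple_to_index(b, character())  # 0
#' @export
tuple_to_index <- function(basis, members) {
  stopifnot(inherits(basis, "tuple_basis"))
  members <- as.character(members)
  pos <- match(members, basis$items)
  if (anyNA(pos))
    stop("member(s) not in the basis item set: ",
         paste(members[is.na(pos)], collapse = ", "))
  if (anyDuplicated(members))
    stop("duplicate members in tuple")
  idx <- as.integer(sum(2^(pos - 1L)))
  if (!basis$include_empty && idx == 0L)
    stop("the empty tuple is not part of this basis")
  idx
}

#' Tuple members at a decimal index
#'
#' @param basis a [tuple_basis()].
#' @param idx integer in `[0, 2^i - 1]` (0 invalid when the basis
#'   excludes the empty tuple).
#' @return character vector of member labels, in item-list order.
#' @examples
#' b <- tuple_basis(c("A", "B", "C"))
#' index_to_tuple(b, 7)  # "A" "B" "C"
#' @export
index_to_tuple <- function(basis, idx) {
  stopifnot(inherits(basis, "tuple_basis"))
  if (length(idx) != 1L || is.na(idx) || idx != round(idx))
    stop("'idx' must be a single integer")
  if (idx < 0 || idx > 2^basis$i - 1)
    stop(sprintf("'idx' out of range [%d, %d]",
                 if (basis$include_empty) 0L else 1L, 2L^basis$i - 1L))
  if (idx == 0 && !basis$include_empty)
    stop("index 0 (empty tuple) is not part of this basis")
  basis$items[.index_bits(idx, basis$i) == 1L]
}

.tuple_label <- function(basis, idx) {
  members <- index_to_tuple(basis, idx)
  paste0("{", paste(members, collapse = ","), "}")
}

.bitstring <- function(basis, idx) {
  paste(.index_bits(idx, basis$i), collapse = "")
}

#' Tabulate a tuple basis
#'
#' One row per basis vector in ascending decimal order, giving the three
#' equivalent notations: tuple label, bitstring (first item leftmost,
#' i.e. the digits of the ket), decimal index. The empty tuple is
#' labelled `{}`.
#'
#' @param basis a [tuple_basis()].
#' @return data.frame with columns `tuple_label`, `bitstring`, `decimal`.
#' @examples
#' basis_table(tuple_basis(c("A", "B", "C")))
#' @export
basis_table <- function(basis) {
  stopifnot(inherits(basis, "tuple_basis"))
  data.frame(
    tuple_label = vapply(basis$indices, function(k) .tuple_label(basis, k), ""),
    bitstring = vapply(basis$indices, function(k) .bitstring(basis, k), ""),
    decimal = basis$indices,
    stringsAsFactors = FALSE
  )
}

#' Barcode rendering of a tuple basis
#'
#' Renders the basis as a barcode: one row per basis vector (ascending
#' decimal order), one cell per item (item-list order). An activated
#' ("permissible") item prints as `#`, a suppressed one as `.`. When a
#' state vector is supplied, each row carries a trailing status column:
#' `+` if the row's coefficient is nonzero, `0` if it has been rotated to
#' zero (the tuple has become inadmissible).
#'
#' @param basis a [tuple_basis()].
#' @param state optional [state_vector()] over `basis`.
#' @param file optional path; the text is written there instead of being
#'   returned invisibly only.
#' @param zero_tol magnitude below which a coefficient counts as zero.
#' @return character vector, one element per row, invisibly when printed.
#' @examples
#' cat(render_barcode(tuple_basis(c("A", "B", "C"))), sep = "\n")
#' @seealso [plot_barcode()] for the image form.
#' @export
render_barcode <- function(basis, state = NULL, file = NULL,
                           zero_tol = 1e-12) {
  stopifnot(inherits(basis, "tuple_basis"))
  cells <- vapply(basis$indices, function(k) {
    paste(c("." , "#")[.index_bits(k, basis$i) + 1L], collapse = "")
  }, "")
  if (!is.null(state)) {
    stopifnot(inherits(state, "state_vector"))
    if (state$basis$i != basis$i || state$basis$size != basis$size)
      stop("state dimension does not match basis size")
    marks <- ifelse(abs(state$coefficients) > zero_tol, "+", "0")
    cells <- paste(cells, marks)
  }
  if (!is.null(file)) writeLines(cells, file)
  cells
}

#' Barcode image of a tuple basis
#'
#' Image form of [render_barcode()]: activated cells orange, suppressed
#' cells green; rows whose state coefficient is zero are greyed out.
#'
#' @inheritParams render_barcode
#' @param file optional PNG path; when given the plot is written there
#'   via [grDevices::png()].
#' @param width,height device size in pixels when `file` is given.
#' @return invisibly, the 0/1 cell matrix that was drawn.
#' @export
plot_barcode <- function(basis, state = NULL, file = NULL,
                         width = 480, height = 480, zero_tol = 1e-12) {
  stopifnot(inherits(basis, "tuple_basis"))
  n <- basis$size
  mat <- t(vapply(basis$indices, .index_bits, integer(basis$i), i = basis$i))
  zero <- rep(FALSE, n)
  if (!is.null(state)) {
    stopifnot(inherits(state, "state_vector"))
    if (length(state$coefficients) != n)
      stop("state dimension does not match basis size")
    zero <- abs(state$coefficients) <= zero_tol
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, basis$i), ylim = c(0, n), asp = NA)
  for (r in seq_len(n)) {
    for (c in seq_len(basis$i)) {
      col <- if (mat[r, c] == 1L) "darkorange" else "forestgreen"
      if (zero[r]) col = grDevices::adjustcolor(col, alpha.f = 0.25)
      graphics::rect(c - 1, n - r, c, n - r + 1, col = col, border = "white")
    }
  }
  graphics::axis(1, at = seq_len(basis$i) - 0.5, labels = basis$items,
                 tick = FALSE)
  graphics::axis(2, at = n - seq_len(n) + 0.5, labels = basis$indices,
                 tick = FALSE, las = 1)
  graphics::title(xlab = "item", ylab = "tuple index")
  invisible(mat)
}
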