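# shared fixtures and independent oracles

abc_basis <- function(include_empty = TRUE)
  tuple_basis(c("A", "B", "C"), include_empty = include_empty)

# independent subset-enumeration oracle: decimal index of a subset as
# a sum of powers of two over member positions, built with combn()
# rather than the package's bit machinery
enumerate_subsets <- function(items) {
  i <- length(items)
  subsets <- list(character(0))
  for (m in seq_len(i))
    subsets <- c(subsets,
                 utils::combn(items, m, simplify = FALSE))
  idx <- vapply(subsets, function(s)
    sum(2^(match(s, items) - 1)), numeric(1))
  subsets[order(idx)]
}

# Kronecker-product oracle for the production operator: identity on
# every factor except rho at the produced item's position (item 1 is
# the fastest-varying, least-significant factor)
kron_operator <- function(items, item) {
  rho <- matrix(c(1, -1, 1, 1), 2) / sqrt(2)
  pos <- match(item, items)
  op <- matrix(1, 1, 1)
  for (b in seq_along(items)) {
    f <- if (b == pos) rho else diag(2)
    op <- kronecker(f, op)   # later items are slower-varying
  }
  op
}

# brute-force separability oracle for coefficient vectors with entries
# +-1/sqrt(2^i): a state is a rank-1 tensor iff its sign pattern is a
# product of per-item signs times a global sign (exhaustive search)
signs_separable_oracle <- function(signs, i) {
  for (g in c(-1, 1)) {
    per_item <- expand.grid(rep(list(c(-1, 1)), i))
    for (rw in seq_len(nrow(per_item))) {
      sig <- as.numeric(per_item[rw, ])
      pat <- vapply(0:(2^i - 1), function(k) {
        bits <- bitwAnd(bitwShiftR(k, 0:(i - 1)), 1L)
        g * prod(sig^bits)
      }, numeric(1))
      if (all(pat == signs)) return(TRUE)
    }
  }
  FALSE
}

# mean onset of each word across a list of production records (all of
# equal length)
mean_onsets <- function(records) {
  onsets <- vapply(records, function(r) r$onset_seconds,
                   numeric(nrow(records[[1]])))
  rowMeans(onsets)
}
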