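test_that("the minimal matrix is the 45-degree rotation sending equal pairs to (1, 0)", {
  rho <- minimal_matrix()
  expect_equal(rho, matrix(c(1, -1, 1, 1), 2) / sqrt(2))
  expect_equal(as.numeric(rho %*% c(1, 1) / sqrt(2)), c(1, 0),
               tolerance = 1e-15)
  expect_equal(t(rho) %*% rho, diag(2), tolerance = 1e-15)
  expect_equal(det(rho), 1, tolerance = 1e-15)
  # eighth root of the identity: eight successive 45-degree rotations
  p <- diag(2)
  for (j in 1:8) p <- rho %*% p
  expect_equal(p, diag(2), tolerance = 1e-12)
  ev <- eigen(rho, only.values = TRUE)$values
  expect_equal(sort(Arg(ev)), c(-pi / 4, pi / 4), tolerance = 1e-12)
})

test_that("the worked three-item production chain holds with unit norms", {
  b <- abc_basis()
  x <- uniform_state(b)
  xC <- apply_operator(production_operator(b, "C"), x)
  expect_equal(xC$coefficients, c(1, 1, 1, 1, 0, 0, 0, 0) / 2,
               tolerance = 1e-15)
  xB <- apply_operator(production_operator(b, "B"), xC)
  expect_equal(xB$coefficients, c(1, 1, 0, 0, 0, 0, 0, 0) / sqrt(2),
               tolerance = 1e-15)
  xA <- apply_operator(production_operator(b, "A"), xB)
  expect_equal(xA$coefficients, c(1, 0, 0, 0, 0, 0, 0, 0),
               tolerance = 1e-15)
  for (s in list(x, xC, xB, xA))
    expect_equal(state_norm(s), 1, tolerance = 1e-12)
  # the post-production constructor agrees with the rotation route
  expect_equal(xC$coefficients, post_production_state(b, "C")$coefficients)
  expect_equal(xB$coefficients,
               post_production_state(b, c("C", "B"))$coefficients)
})

test_that("production operators match the Kronecker-construction oracle", {
  for (i in 2:4) {
    items <- paste0("w", seq_len(i))
    b <- tuple_basis(items)
    for (w in items) {
      expect_equal(as.matrix(production_operator(b, w)),
                   kron_operator(items, w), tolerance = 1e-12)
    }
  }
})

test_that("operators are orthogonal and norm-conserving", {
  for (i in c(2, 4, 6, 8)) {
    b <- tuple_basis(paste0("w", seq_len(i)))
    op <- production_operator(b, "w2")
    m <- as.matrix(op)
    expect_lt(max(abs(t(m) %*% m - diag(2^i))), 1e-12)
  }
  set.seed(7)
  for (i in 2:6) {
    b <- tuple_basis(paste0("w", seq_len(i)))
    ops <- lapply(b$items, production_operator, basis = b)
    for (rep in 1:20) {
      v <- stats::rnorm(2^i); v <- v / sqrt(sum(v^2))
      s <- state_vector(b, v)
      for (op in ops)
        expect_equal(state_norm(apply_operator(op, s)), 1,
                     tolerance = 1e-12)
    }
  }
})

test_that("production operators commute; full sequences end in the inactive state", {
  b <- abc_basis()
  mats <- lapply(b$items, function(w) as.matrix(production_operator(b, w)))
  for (a in 1:3) for (bb in 1:3)
    expect_equal(mats[[a]] %*% mats[[bb]], mats[[bb]] %*% mats[[a]],
                 tolerance = 1e-12)
  # trajectory of the worked order
  traj <- apply_sequence(b, c("C", "B", "A"))
  expect_equal(traj[[1]]$coefficients, c(1, 1, 1, 1, 0, 0, 0, 0) / 2)
  expect_equal(traj[[2]]$coefficients, c(1, 1, 0, 0, 0, 0, 0, 0) / sqrt(2))
  expect_equal(traj[[3]]$coefficients, c(1, rep(0, 7)), tolerance = 1e-12)
  # all six complete orders give the same final state, coefficient +1
  perms <- list(c("A","B","C"), c("A","C","B"), c("B","A","C"),
                c("B","C","A"), c("C","A","B"), c("C","B","A"))
  for (p in perms) {
    fin <- apply_sequence(b, p)[[3]]
    expect_equal(fin$coefficients, c(1, rep(0, 7)), tolerance = 1e-12)
  }
  expect_length(apply_sequence(b, character(0)), 0)
  expect_error(apply_sequence(b, c("A", "A")), "repeat")
})

test_that("all operators over one basis share the spectrum of the minimal matrix", {
  rho_spec <- operator_spectrum(minimal_matrix())
  expect_equal(rho_spec,
               complex(real = cos(pi / 4), imaginary = c(-1, 1) * sin(pi / 4)),
               tolerance = 1e-12)
  for (i in 2:6) {
    b <- tuple_basis(paste0("w", seq_len(i)))
    specs <- lapply(b$items, function(w)
      operator_spectrum(production_operator(b, w)))
    expected <- rep(rho_spec, each = 2^(i - 1))
    expected <- expected[order(Re(expected), Im(expected))]
    for (s in specs) expect_equal(s, expected, tolerance = 1e-9)
    # count of distinct spectra is 1
    expect_equal(length(unique(lapply(specs, function(s) round(s, 9)))), 1)
  }
})

test_that("similarity is decided by spectra and demands equal dimensions", {
  b <- abc_basis()
  RA <- production_operator(b, "A")
  RB <- production_operator(b, "B")
  expect_true(similar_operators(RA, RB))
  expect_true(similar_operators(RA, RA))
  b2 <- tuple_basis(c("A", "B"))
  expect_error(similar_operators(RA, production_operator(b2, "A")),
               "dimension")
  expect_error(production_operator(b, "Z"), "item")
  expect_error(production_operator(abc_basis(FALSE), "A"), "include_empty")
})

test_that("matrix-free application above the dense cap still rotates correctly", {
  b <- tuple_basis(paste0("w", 1:13))   # beyond the dense materialization cap
  op <- production_operator(b, "w13")
  expect_null(op$entries)
  s <- apply_operator(op, uniform_state(b))
  expect_equal(state_norm(s), 1, tolerance = 1e-12)
  half <- 2^12
  expect_equal(s$coefficients[seq_len(half)], rep(1 / sqrt(half), half),
               tolerance = 1e-12)
  expect_equal(s$coefficients[half + seq_len(half)], rep(0, half))
  spec <- operator_spectrum(op)
  expect_equal(unique(round(spec, 9)),
               complex(real = cos(pi / 4), imaginary = c(-1, 1) * sin(pi / 4)))
})
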