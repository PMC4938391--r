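test_that("standardize gives zero mean, unit population variance", {
  f <- standardize(ts_field(rbind(c(1, 2, 3))))
  expect_equal(mean(f$data[1, ]), 0)
  expect_equal(mean(f$data[1, ]^2), 1)
  expect_true(f$standardized)

  # constant series -> zeros, flagged
  g <- standardize(ts_field(rbind(c(5, 5, 5), c(1, 4, 7))))
  expect_equal(g$data[1, ], c(0, 0, 0))
  expect_true(g$zero_var[1])
  expect_false(g$zero_var[2])

  expect_error(standardize(ts_field(rbind(c(1)))), "at least 2")
})

test_that("standardized distance identity (1/T)||ds-dr||^2 = 2 - 2 corr", {
  set.seed(101)
  for (i in 1:20) {
    T_len <- sample(10:400, 1)
    ds <- rand_standardized(T_len)
    dr <- rand_standardized(T_len)
    lhs <- sum((ds - dr)^2) / T_len
    rhs <- 2 - 2 * mean(ds * dr)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("tNLM weights follow the correlation kernel", {
  ds <- rand_standardized(64)
  expect_equal(tnlm_weight(ds, ds, h = 0.72), 1)

  # exactly orthogonal standardized pair: w = exp(-2 / h^2)
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  expect_equal(tnlm_weight(x, y, h = 0.72), exp(-2 / 0.72^2))

  # perfectly anti-correlated: the attainable minimum exp(-4 / h^2)
  expect_equal(tnlm_weight(ds, -ds, h = 1.3), exp(-4 / 1.3^2))
  expect_equal(tnlm_weight(ds, -ds, h = 0.72), exp(-4 / 0.72^2))

  # symmetry and monotonicity in (1 - corr)
  dr <- rand_standardized(64)
  expect_equal(tnlm_weight(ds, dr), tnlm_weight(dr, ds))
  expect_error(tnlm_weight(ds * 3, dr), "not standardized")
})

test_that("tnlm_filter matches the arithmetic oracle on a tiny mesh", {
  set.seed(7)
  T_len <- 30
  X <- t(replicate(3, rand_standardized(T_len)))
  field <- ts_field(X, standardized = TRUE)
  # path-shaped neighborhoods: N(1)={1,2}, N(2)={1,2,3}, N(3)={2,3}
  nbrs <- manual_nbrs(list(c(1, 2), c(1, 2, 3), c(2, 3)))
  out <- tnlm_filter(field, nbrs, h = 0.72)
  for (s in 1:3) {
    w <- vapply(nbrs[[s]], function(r) tnlm_weight(X[s, ], X[r, ], 0.72), 0)
    expected <- colSums(X[nbrs[[s]], , drop = FALSE] * w) / sum(w)
    expect_equal(out$data[s, ], expected, tolerance = 1e-12)
  }
})

test_that("tnlm_filter limiting behaviour and contracts", {
  m <- make_grid_mesh(6)
  set.seed(21)
  base <- rand_standardized(50)
  const_field <- ts_field(matrix(rep(base, each = 36), 36, 50),
                          standardized = TRUE)
  nb <- linked_neighborhoods(m, 2)
  # identical series everywhere -> output equals input
  expect_equal(tnlm_filter(const_field, nb)$data, const_field$data)

  X <- t(replicate(36, rand_standardized(50)))
  f <- ts_field(X, standardized = TRUE)
  # D = 0 -> identity
  expect_equal(tnlm_filter(f, linked_neighborhoods(m, 0))$data, X)
  # h -> 0+: weights of unequal series vanish -> identity
  expect_equal(tnlm_filter(f, nb, h = 1e-3)$data, X, tolerance = 1e-9)
  # h -> Inf: unweighted neighborhood mean
  big <- tnlm_filter(f, nb, h = 1e6)$data
  for (s in c(1, 15, 30))
    expect_equal(big[s, ], colMeans(X[nb[[s]], ]), tolerance = 1e-8)
  # convex combination bounds at every (s, tau)
  out <- tnlm_filter(f, nb, h = 0.72)$data
  for (s in c(2, 17, 33)) {
    lo <- apply(X[nb[[s]], ], 2, min); hi <- apply(X[nb[[s]], ], 2, max)
    expect_true(all(out[s, ] >= lo - 1e-12 & out[s, ] <= hi + 1e-12))
  }
  expect_error(tnlm_filter(ts_field(X), nb), "standardized")
})

test_that("tnlm_filter kernel is time-invariant and nonlinear", {
  m <- make_grid_mesh(5)
  nb <- linked_neighborhoods(m, 2)
  set.seed(31)
  X <- t(replicate(25, rand_standardized(40)))
  f <- ts_field(X, standardized = TRUE)
  perm <- sample(40)
  # permuting the time axis commutes with the filter
  fp <- ts_field(X[, perm], standardized = TRUE)
  expect_equal(tnlm_filter(fp, nb)$data,
               tnlm_filter(f, nb)$data[, perm], tolerance = 1e-12)
  # superposition fails: tNLM is not linear in the field
  Y <- t(replicate(25, rand_standardized(40)))
  g <- ts_field(Y, standardized = TRUE)
  lhs <- tnlm_filter(standardize(ts_field(X + Y)), nb)$data
  rhs <- tnlm_filter(f, nb)$data + tnlm_filter(g, nb)$data
  expect_gt(max(abs(lhs - rhs)), 1e-3)
})

test_that("zero-variance vertices pass through and never serve as neighbors", {
  m <- make_grid_mesh(4)
  nb <- linked_neighborhoods(m, 1)
  X <- matrix(rnorm(16 * 30), 16, 30)
  X[5, ] <- 3  # constant
  f <- standardize(ts_field(X))
  expect_warning(out <- tnlm_filter(f, nb), "zero-variance")
  expect_equal(out$data[5, ], rep(0, 30))
  # neighbor 5's zero rows contribute nothing to vertex 1's average
  nbrs1 <- setdiff(nb[[1]], 5)
  w <- vapply(nbrs1, function(r)
    tnlm_weight(f$data[1, ], f$data[r, ], 0.72), 0)
  expected <- colSums(f$data[nbrs1, , drop = FALSE] * w) / sum(w)
  expect_equal(out$data[1, ], expected, tolerance = 1e-12)
})

test_that("lb_filter: identity at t = 0, surface mean as t -> Inf", {
  m <- make_grid_mesh(6)
  b <- lb_eigenbasis(m, n_modes = m$n_vertices)
  set.seed(41)
  X <- matrix(rnorm(36 * 5), 36, 5)
  f <- ts_field(X)
  expect_equal(lb_filter(f, b, t = 0)$data, X, tolerance = 1e-8)
  # large t: every frame tends to its mass-weighted surface mean
  out <- lb_filter(f, b, t = 1e6)$data
  mmean <- colSums(X * as.vector(b$mass)) / sum(b$mass)
  for (tau in 1:5)
    expect_equal(out[, tau], rep(mmean[tau], 36), tolerance = 1e-8)
  expect_error(lb_filter(ts_field(matrix(0, 10, 3)), b), "10")
})

test_that("lb_filter agrees with the dense matrix-exponential heat kernel", {
  m <- make_grid_mesh(5)  # 25 vertices
  b <- lb_eigenbasis(m, n_modes = m$n_vertices)
  set.seed(51)
  X <- matrix(rnorm(25 * 4), 25, 4)
  for (t in c(0.3, 1.5)) {
    expected <- expm_heat_oracle(m, X, t)
    got <- lb_filter(ts_field(X), b, t = t)$data
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("lb_filter is linear in the field", {
  m <- make_grid_mesh(5)
  b <- lb_eigenbasis(m, n_modes = 10)
  set.seed(61)
  X <- matrix(rnorm(25 * 3), 25, 3); Y <- matrix(rnorm(25 * 3), 25, 3)
  lhs <- lb_filter(ts_field(X + 2 * Y), b, t = 2)$data
  rhs <- lb_filter(ts_field(X), b, t = 2)$data +
    2 * lb_filter(ts_field(Y), b, t = 2)$data
  expect_equal(lhs, rhs, tolerance = 1e-10)
})
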