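test_that("the cube has exactly eight corner equilibria, in canonical order", {
  corners <- corner_equilibria()
  expect_equal(nrow(corners), 8)
  expect_equal(unname(corners[1:3, ]),
               rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(rownames(corners), paste0("V", 0:7))
  expect_equal(nrow(unique(corners)), 8)
  for (p in sample_params(5, seed = 3)) {
    for (i in 1:8)
      expect_equal(max(abs(replicator_rhs(corners[i, ], p))), 0)
  }
})

test_that("analytic Jacobians match central finite differences", {
  params <- sample_params(10, seed = 51)
  states <- rbind(0.05 + 0.9 * random_states(10, seed = 52),
                  corner_equilibria())
  for (p in params) {
    for (i in seq_len(nrow(states))) {
      for (v in c("matrix_derived", "as_printed")) {
        Ja <- jacobian_matrix(states[i, ], p, variant = v)
        Jn <- jacobian_matrix(states[i, ], p, variant = v, method = "numeric")
        expect_lt(max(abs(Ja - Jn)), 1e-6)
      }
    }
  }
})

test_that("corner Jacobians are diagonal with bracket eigenvalues", {
  p <- sample_params(1, seed = 61)[[1]]
  for (nm in rownames(corner_equilibria())) {
    v <- corner_equilibria()[nm, ]
    J <- jacobian_matrix(v, p)
    expect_equal(J[upper.tri(J) | lower.tri(J)], rep(0, 6))
    expect_equal(sort(Re(eigen(J)$values)), sort(unname(diag(J))))
    expect_equal(unname(diag(J)),
                 unname((1 - 2 * v) * replicator_brackets(v, p)))
  }
})

test_that("the all-out corner diagonal matches the frozen example", {
  p <- ohp_params(c1 = 1, c4 = 3, beta = 0.5, h4 = 2, alpha = 0.5,
                  t1 = 1, t2 = 1)
  J <- jacobian_matrix(c(0, 0, 0), p)
  expect_equal(unname(diag(J)), c(-2.5, -1.0, -1.0), tolerance = 1e-9)
})

test_that("universal abandonment is stable for every positive-cost regime", {
  for (p in sample_params(40, seed = 71)) {
    rep <- classify_stability(c(0, 0, 0), p)
    expect_equal(rep$classification, "asymptotically-stable")
    expect_true(all(Re(rep$eigenvalues) < 0))
  }
})

test_that("full cooperation is stable under the baseline inequality regime", {
  p <- baseline_params()
  rep <- classify_stability(c(1, 1, 1), p)
  expect_equal(rep$classification, "asymptotically-stable")
  # the three corner conditions, spelled out
  expect_gt(p$r1 - p$c1 - p$c2, 0)
  expect_gt(p$e1 - p$e2 + p$e3 - p$h1 + p$L, 0)
  expect_gt(p$M + (1 - p$alpha) * p$F1 + (1 - p$beta) * p$F2 + p$N +
              (1 - p$beta) * p$G + (1 - p$beta) * p$F3 -
              (1 - p$alpha) * p$t1 - (1 - p$beta) * p$t2, 0)
})

test_that("classify_stability refuses non-fixed points", {
  expect_error(classify_stability(c(0.5, 0.5, 0.5), baseline_params()),
               "not a fixed point")
})

test_that("patient indifference makes the provide-side x=0 corners non-hyperbolic", {
  # at x = 0, z = 1 the patient bracket vanishes identically, so V5 and V6
  # are non-hyperbolic under every admissible parameter set
  for (p in sample_params(10, seed = 81)) {
    expect_equal(classify_stability(c(0, 1, 1), p)$classification,
                 "non-hyperbolic")
    expect_equal(classify_stability(c(0, 0, 1), p)$classification,
                 "non-hyperbolic")
  }
})

test_that("no interior root exists when joining never pays", {
  p <- update_params(baseline_params(), c1 = 2 * baseline_params()$r1)
  expect_length(interior_equilibrium(p, n_starts = 25), 0)
})

test_that("constructed interior root is found, verified, and grid-confirmed", {
  p <- interior_fixture_params()
  roots <- interior_equilibrium(p)
  expect_equal(length(roots), 1)
  r <- roots[[1]]
  expect_lt(max(abs(r$point - c(0.5, 0.5, 0.5))), 1e-6)
  expect_lt(max(abs(replicator_brackets(r$point, p))), 1e-8)
  expect_lt(r$residual, 1e-8)

  # grid-scan oracle at resolution 0.01: the bracket sup-norm minimiser over
  # the interior grid must sit within one cell of the solver's root
  grid <- seq(0.01, 0.99, by = 0.01)
  n <- length(grid)
  b1 <- outer(grid, grid, function(y, z)
    abs(grid_bracket1(p, y, z)))
  b2 <- outer(grid, grid, function(x, z)
    abs(grid_bracket2(p, x, z)))
  b3 <- outer(grid, grid, function(x, y)
    abs(grid_bracket3(p, x, y)))
  best <- c(NA, NA, NA); best_val <- Inf
  for (ix in seq_len(n)) {
    # sup over the three brackets, vectorized over (y, z) for fixed x
    m <- pmax(b1, matrix(b2[ix, ], n, n, byrow = TRUE),   # varies with z (cols)
              matrix(b3[ix, ], n, n, byrow = FALSE))      # varies with y (rows)
    i <- arrayInd(which.min(m), dim(m))
    if (m[i] < best_val) {
      best_val <- m[i]
      best <- c(grid[ix], grid[i[1]], grid[i[2]])
    }
  }
  expect_lt(max(abs(best - r$point)), 0.011)
})

test_that("equilibria() table is residual-clean and sign-consistent", {
  tab <- equilibria(baseline_params())
  expect_gte(nrow(tab), 8)
  expect_true(all(tab$residual < 1e-8))
  for (i in seq_len(nrow(tab))) {
    re <- unlist(tab[i, c("eig1", "eig2", "eig3")])
    cls <- tab$classification[i]
    if (cls == "asymptotically-stable") expect_true(all(re < 0))
    if (cls == "unstable") expect_true(all(re > 0))
    if (cls == "saddle") expect_true(any(re < 0) && any(re > 0))
    if (cls == "non-hyperbolic") expect_true(any(abs(re) <= 1e-9))
  }
})

test_that("classifications agree with perturbation simulation at hyperbolic corners", {
  set.seed(91)
  p <- baseline_params()
  for (nm in rownames(corner_equilibria())) {
    v <- corner_equilibria()[nm, ]
    cls <- classify_stability(v, p)$classification
    if (cls == "non-hyperbolic") next
    returned <- vapply(1:5, function(i) {
      s0 <- pmin(pmax(v + runif(3, 0, 0.01) * ifelse(v == 0, 1, -1), 0), 1)
      tr <- integrate_trajectory(s0, p, horizon = 30, n_steps = 61)
      final <- unlist(tail(tr, 1)[, c("x", "y", "z")])
      max(abs(final - v)) < max(abs(s0 - v))
    }, logical(1))
    if (cls == "asymptotically-stable") expect_true(all(returned), label = nm)
    else expect_false(all(returned), label = nm)
  }
})
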