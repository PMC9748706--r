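test_that("corners and faces are fixed in their clamped coordinates", {
  params <- sample_params(10, seed = 5)
  corners <- corner_equilibria()
  for (p in params) {
    for (i in seq_len(nrow(corners))) {
      expect_equal(unname(replicator_rhs(corners[i, ], p)), c(0, 0, 0))
    }
    # a face point only pins the coordinate sitting on the face
    v <- replicator_rhs(c(0, 0.3, 0.8), p)
    expect_identical(unname(v[1]), 0)
  }
})

test_that("replicator velocities match the frozen worked example", {
  p <- example_doctor_params()
  s <- c(0.5, 0.5, 0.5)
  v <- replicator_rhs(s, p)
  expect_equal(unname(v[1]), 0.4375, tolerance = 1e-12)   # 0.25 * (P11 - 0)
  vp <- replicator_rhs(s, p, variant = "as_printed")
  expect_equal(unname(vp[1]), 0.3125, tolerance = 1e-12)
  # patient and platform components identical across variants
  expect_equal(v[2:3], vp[2:3])
})

test_that("matrix-derived dynamics equal the enumeration oracle everywhere", {
  params <- sample_params(40, seed = 13)
  states <- random_states(40, seed = 14)
  for (i in seq_along(params)) {
    got <- unname(replicator_rhs(states[i, ], params[[i]]))
    want <- oracle_rhs(params[[i]], states[i, ])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("printed equations agree with the matrix derivation where claimed", {
  params <- sample_params(30, seed = 17)
  states <- random_states(30, seed = 18)
  for (i in seq_along(params)) {
    p <- params[[i]]
    s <- states[i, ]
    m <- replicator_rhs(s, p)
    pr <- replicator_rhs(s, p, variant = "as_printed")
    expect_equal(m[2:3], pr[2:3], tolerance = 1e-12)      # whole cube
    expect_equal(unname(pr), unname(printed_rhs(p, s)), tolerance = 1e-12)
    s0 <- s; s0[3] <- 0                                    # z = 0 slice
    expect_lt(max(abs(replicator_rhs(s0, p) -
                        replicator_rhs(s0, p, "as_printed"))), 1e-12)
  }
  # and a generic interior point exhibits the documented c3 discrepancy
  p <- example_doctor_params()
  s <- c(0.5, 0.5, 0.5)
  expect_gt(abs(replicator_rhs(s, p)[1] -
                  replicator_rhs(s, p, "as_printed")[1]), 0.1)
})

test_that("a share grows exactly when its strategy beats the population mean", {
  params <- sample_params(20, seed = 23)
  states <- 0.02 + 0.96 * random_states(20, seed = 24)
  for (i in seq_along(params)) {
    p <- params[[i]]
    s <- states[i, ]
    v <- replicator_rhs(s, p)
    pt <- payoff_tensor(p)
    diffs <- c(marginal_payoff("doctor", 1, s, pt) -
                 marginal_payoff("doctor", 0, s, pt),
               marginal_payoff("patient", 1, s, pt) -
                 marginal_payoff("patient", 0, s, pt),
               marginal_payoff("platform", 1, s, pt) -
                 marginal_payoff("platform", 0, s, pt))
    expect_equal(sign(unname(v)), sign(diffs))
  }
})

test_that("trajectories stay inside the unit cube", {
  params <- sample_params(15, seed = 29)
  starts <- 0.05 + 0.9 * random_states(45, seed = 30)
  k <- 1
  for (p in params) {
    for (j in 1:3) {
      tr <- integrate_trajectory(starts[k, ], p, horizon = 20, n_steps = 101)
      expect_true(all(tr$x >= 0 & tr$x <= 1 & tr$y >= 0 & tr$y <= 1 &
                        tr$z >= 0 & tr$z <= 1))
      k <- k + 1
    }
  }
})

test_that("corner starts give constant trajectories", {
  p <- baseline_params()
  for (nm in c("V0", "V3", "V7")) {
    v <- corner_equilibria()[nm, ]
    tr <- integrate_trajectory(v, p, horizon = 10, n_steps = 21)
    expect_true(all(abs(tr$x - v[1]) < 1e-12 & abs(tr$y - v[2]) < 1e-12 &
                      abs(tr$z - v[3]) < 1e-12))
    cv <- detect_convergence(tr)
    expect_true(cv$converged)
    expect_equal(unname(cv$limit), unname(v))
    expect_equal(cv$time_to_tol, 0)
  }
})

test_that("adaptive endpoints agree with a small-step Euler cross-check", {
  lib <- scenario_library()
  for (nm in c("fig1_alpha_high", "fig1_alpha_low", "fig8_h1_high")) {
    sc <- lib[[nm]]
    end_ada <- unlist(tail(integrate_trajectory(sc$initial_state, sc$params,
                                                horizon = 40), 1)[, c("x", "y", "z")])
    end_eul <- unlist(tail(integrate_trajectory_euler(sc$initial_state,
                                                      sc$params, horizon = 40,
                                                      dt = 1e-3), 1)[, c("x", "y", "z")])
    expect_lt(max(abs(end_ada - end_eul)), 1e-4)
  }
})

test_that("non-settling trajectories are reported as not converged", {
  fake <- data.frame(t = seq(0, 10, by = 0.1))
  fake$x <- 0.5 + 0.4 * sin(fake$t)
  fake$y <- 0.5
  fake$z <- 0.5
  cv <- detect_convergence(fake, tol = 1e-3)
  expect_false(cv$converged)
  expect_true(is.na(cv$time_to_tol))
})

test_that("states outside the cube are rejected beyond clip tolerance", {
  p <- baseline_params()
  expect_error(replicator_rhs(c(1.1, 0.5, 0.5), p), "unit cube")
  expect_silent(replicator_rhs(c(1 + 1e-12, 0.5, 0.5), p))  # clipped
})

test_that("trajectory files embed the full configuration", {
  tr <- integrate_trajectory(c(0.5, 0.5, 0.5), baseline_params(), horizon = 5,
                             n_steps = 11)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# params: .*alpha=0.9", lines)))
  expect_true(any(grepl("^# variant: matrix_derived", lines)))
  body <- utils::read.csv(f, comment.char = "#")
  expect_named(body, c("t", "x", "y", "z"))
  expect_equal(nrow(body), 11)
})
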