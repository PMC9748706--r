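# Independent oracles used across the suite.
#
# oracle_cell() re-derives every payoff-matrix cell directly from the model
# assumptions (its formulas are written here from scratch, not shared with
# the package), and oracle_marginal() computes conditional expected payoffs
# by brute-force enumeration of the 8 pure-strategy profiles. The package's
# closed forms are tested against these.

# payoff triple (doctor, patient, platform) for the pure profile
# d, u, v in {0, 1}: doctor joins, patient uses, platform provides
oracle_cell <- function(p, d, u, v) {
  a <- p$alpha; b <- p$beta
  if (v == 1) {  # standardized services: no (1-a)/(1-b) losses, full costs
    doctor <- if (d == 1 && u == 1) p$r1 - p$c1 - p$c2
              else if (d == 1) -p$c1 else 0
    patient <- if (d == 1 && u == 1) p$e1 + p$e3 - p$h1 + p$L else p$e2
    platform <- if (d == 1 && u == 1) p$w1 - p$t1 - p$t2 + p$M
                else -p$t1 - p$t2
  } else {
    doctor <- if (d == 1 && u == 1)
        p$r1 - p$c1 - p$c2 - (1 - a) * p$c3 - (1 - b) * p$c4
      else if (d == 1) -p$c1 - (1 - b) * p$c4 else 0
    patient <- if (u == 1 && d == 1)
        p$e1 + p$e3 - p$h1 - (1 - a) * p$h2 - (1 - b) * (p$h3 + p$h4)
      else if (u == 1) p$e2 - (1 - b) * p$h4 else p$e2
    platform <- -a * p$t1 - b * p$t2 +
      (if (d == 1 && u == 1)
         p$w1 - (1 - a) * p$F1 - (1 - b) * (p$F2 + p$F3 + p$G) - p$N
       else if (d == 1) -(1 - b) * p$G
       else if (u == 1) -(1 - b) * p$F3 else 0)
  }
  c(doctor = doctor, patient = patient, platform = platform)
}

# conditional expected payoff of `player` fixed at strategy s (1 = active),
# enumerating the opponents' pure profiles weighted by the state shares
oracle_marginal <- function(p, player, s, state) {
  x <- state[1]; y <- state[2]; z <- state[3]
  w <- list(doctor = c(1 - x, x), patient = c(1 - y, y),
            platform = c(1 - z, z))
  tot <- 0
  for (d in 0:1) for (u in 0:1) for (v in 0:1) {
    prof <- c(doctor = d, patient = u, platform = v)
    if (prof[[player]] != s) next
    others <- setdiff(names(prof), player)
    wt <- w[[others[1]]][prof[[others[1]]] + 1] *
      w[[others[2]]][prof[[others[2]]] + 1]
    tot <- tot + wt * oracle_cell(p, d, u, v)[[player]]
  }
  unname(tot)
}

# replicator velocities via the enumeration oracle
oracle_rhs <- function(p, state) {
  x <- unname(state[1]); y <- unname(state[2]); z <- unname(state[3])
  as.numeric(c(x * (1 - x) * (oracle_marginal(p, "doctor", 1, state) -
                     oracle_marginal(p, "doctor", 0, state)),
    y * (1 - y) * (oracle_marginal(p, "patient", 1, state) -
                     oracle_marginal(p, "patient", 0, state)),
    z * (1 - z) * (oracle_marginal(p, "platform", 1, state) -
                     oracle_marginal(p, "platform", 0, state))))
}

# literal closed-form replicator equations, transcribed independently
printed_rhs <- function(p, state) {
  x <- unname(state[1]); y <- unname(state[2]); z <- unname(state[3])
  a <- p$alpha; b <- p$beta
  dx <- x * (1 - x) *
    (y * (p$r1 - p$c2 - (1 - a) * p$c3) - p$c1 - (1 - b) * p$c4 +
       z * (1 - b) * p$c4)
  dy <- y * (1 - y) *
    (x * (p$e1 - p$e2 + p$e3 - p$h1 - (1 - a) * p$h2 - (1 - b) * p$h3) +
       x * z * ((1 - a) * p$h2 + (1 - b) * p$h3 + p$L) -
       (1 - b) * p$h4 + z * (1 - b) * p$h4)
  dz <- z * (1 - z) *
    (x * y * (p$M + (1 - a) * p$F1 + (1 - b) * p$F2 + p$N) -
       (1 - a) * p$t1 - (1 - b) * p$t2 +
       x * (1 - b) * p$G + y * (1 - b) * p$F3)
  as.numeric(c(dx, dy, dz))
}

# parameter set used by several frozen-value examples
example_doctor_params <- function() {
  ohp_params(r1 = 10, c1 = 1, c2 = 2, c3 = 4, c4 = 3,
             alpha = 0.5, beta = 0.5)
}

# baseline modified so the mixed point (0.5, 0.5, 0.5) is an interior root
interior_fixture_params <- function() {
  update_params(baseline_params(), c1 = 2.1, h1 = 3.4,
                t1 = 12.375, t2 = 12.375)
}

random_states <- function(n, seed) {
  set.seed(seed)
  matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

# vectorized incentive brackets for the grid-scan oracle, transcribed
# independently of the package internals
grid_bracket1 <- function(p, y, z) {
  y * (p$r1 - p$c2) - p$c1 -
    y * (1 - z) * (1 - p$alpha) * p$c3 - (1 - z) * (1 - p$beta) * p$c4
}
grid_bracket2 <- function(p, x, z) {
  k <- (1 - p$alpha) * p$h2 + (1 - p$beta) * p$h3
  x * (p$e1 - p$e2 + p$e3 - p$h1 - k) + x * z * (k + p$L) -
    (1 - p$beta) * p$h4 * (1 - z)
}
grid_bracket3 <- function(p, x, y) {
  A <- p$M + (1 - p$alpha) * p$F1 + (1 - p$beta) * p$F2 + p$N
  x * y * A + x * (1 - p$beta) * p$G + y * (1 - p$beta) * p$F3 -
    (1 - p$alpha) * p$t1 - (1 - p$beta) * p$t2
}
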