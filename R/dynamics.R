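#' Replicator incentive brackets
#'
#' The replicator system factors as `ds/dt = s(1-s) * B(s_others)`: each
#' population's share grows iff its "bracket" -- the fitness advantage of the
#' active strategy over the complement -- is positive. This returns the three
#' brackets `(B1, B2, B3)` for doctors, patients, platforms.
#'
#' Two equation variants are supported. `"matrix_derived"` (default) takes
#' the payoff matrix as the primitive: `B1 = P11 - P12` etc., computed from
#' the tensor cells. `"as_printed"` evaluates the literal closed-form
#' replicator equations of the source model. The two agree identically for
#' the patient and platform components; for the doctor component they differ
#' by the reputation-loss term, `y*(1-z)*(1-alpha)*c3` (matrix) versus
#' `y*(1-alpha)*c3` (printed), and so agree only where `z = 0`, `c3 = 0`
#' or `alpha = 1`.
#'
#' @param state numeric `c(x, y, z)` in the unit cube.
#' @param params an [ohp_params()] object.
#' @param variant `"matrix_derived"` or `"as_printed"`.
#' @return Named numeric `c(doctor =, patient =, platform =)`.
#' @seealso [replicator_rhs()], [jacobian_matrix()]
#' @export
replicator_brackets <- function(state, params,
                                variant = c("matrix_derived", "as_printed")) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  s <- as_ohp_state(state)
  .brackets_core(s[[1]], s[[2]], s[[3]], p, variant)
}

# validation-free bracket evaluation for hot loops (integration, root search)
.brackets_core <- function(x, y, z, p, variant) {
  a <- p$alpha; b <- p$beta

  if (variant == "matrix_derived") {
    # P11 - P12 with the tensor's (1-z)-gated reputation loss
    b1 <- y * (p$r1 - p$c2) - p$c1 -
      y * (1 - z) * (1 - a) * p$c3 - (1 - z) * (1 - b) * p$c4
  } else {
    # literal printed doctor equation: c3 term not gated by (1-z)
    b1 <- y * (p$r1 - p$c2 - (1 - a) * p$c3) - p$c1 -
      (1 - b) * p$c4 + z * (1 - b) * p$c4
  }
  # patient and platform brackets coincide across variants
  b2 <- x * (p$e1 - p$e2 + p$e3 - p$h1 - (1 - a) * p$h2 - (1 - b) * p$h3) +
    x * z * ((1 - a) * p$h2 + (1 - b) * p$h3 + p$L) -
    (1 - b) * p$h4 + z * (1 - b) * p$h4
  A <- p$M + (1 - a) * p$F1 + (1 - b) * p$F2 + p$N
  b3 <- x * y * A + x * (1 - b) * p$G + y * (1 - b) * p$F3 -
    (1 - a) * p$t1 - (1 - b) * p$t2

  c(doctor = b1, patient = b2, platform = b3)
}

#' Replicator right-hand side
#'
#' Velocity of the three adoption shares: `dx/dt = x(1-x)(P11 - P12)`,
#' `dy/dt = y(1-y)(P21 - P22)`, `dz/dt = z(1-z)(P31 - P32)`. Each component
#' vanishes whenever its coordinate is 0 or 1, so all eight cube corners are
#' fixed points and the cube is forward-invariant.
#'
#' @inheritParams replicator_brackets
#' @return Named numeric `c(x =, y =, z =)` of time derivatives.
#' @examples
#' p <- ohp_params(r1 = 10, c1 = 1, c2 = 2, c3 = 4, c4 = 3,
#'                 alpha = 0.5, beta = 0.5)
#' replicator_rhs(c(0.5, 0.5, 0.5), p)                        # matrix-derived
#' replicator_rhs(c(0.5, 0.5, 0.5), p, variant = "as_printed")
#' @export
replicator_rhs <- function(state, params,
                           variant = c("matrix_derived", "as_printed")) {
  variant <- match.arg(variant)
  s <- as_ohp_state(state)
  br <- replicator_brackets(s, params, variant)
  v <- s * (1 - s) * unname(br)
  names(v) <- c("x", "y", "z")
  v
}

#' Integrate a strategy trajectory
#'
#' Solves the autonomous replicator system from `state0` over `[0, horizon]`
#' with an adaptive solver (`deSolve::ode`, lsoda by default). The replicator
#' form keeps the open cube invariant analytically; states are clipped to
#' \[0,1\] at each evaluation and on output to absorb floating-point escape
#' (bounded by the solver's interpolation accuracy, about `atol + rtol`).
#'
#' @param state0 initial state `c(x, y, z)`.
#' @param params an [ohp_params()] object.
#' @param horizon integration horizon in model time units (default 50).
#' @param variant equation variant, see [replicator_brackets()].
#' @param n_steps number of equally spaced output times (default 501, dense
#'   enough for convergence detection).
#' @param method solver passed to [deSolve::ode()].
#' @param atol,rtol solver tolerances.
#' @return An object of class `ohp_trajectory`: a data frame with columns
#'   `t`, `x`, `y`, `z` and attributes `params`, `variant`, `integrator`.
#' @examples
#' tr <- integrate_trajectory(c(0.5, 0.5, 0.5), ohp_params(), horizon = 30)
#' tail(tr, 1)
#' @export
integrate_trajectory <- function(state0, params, horizon = 50,
                                 variant = c("matrix_derived", "as_printed"),
                                 n_steps = 501, method = "lsoda",
                                 atol = 1e-10, rtol = 1e-8) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  s0 <- as_ohp_state(state0)
  stopifnot(is.numeric(horizon), horizon > 0)
  times <- seq(0, horizon, length.out = n_steps)
  deriv <- function(t, s, parms) {
    s <- pmin(pmax(s, 0), 1)
    list(s * (1 - s) * .brackets_core(s[[1]], s[[2]], s[[3]], p, variant))
  }
  out <- tryCatch(
    deSolve::ode(y = s0, times = times, func = deriv, parms = NULL,
                 method = method, atol = atol, rtol = rtol),
    error = function(e) stop("integration failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  df <- as.data.frame(out)
  names(df) <- c("t", "x", "y", "z")
  # pre-clip excursions are bounded by the solver's interpolation accuracy;
  # anything beyond that indicates a genuine integration problem
  esc <- 10 * (atol + rtol)
  if (any(df$x < -esc | df$x > 1 + esc | df$y < -esc | df$y > 1 + esc |
          df$z < -esc | df$z > 1 + esc))
    warning("trajectory escaped the unit cube beyond solver tolerance")
  df$x <- pmin(pmax(df$x, 0), 1)
  df$y <- pmin(pmax(df$y, 0), 1)
  df$z <- pmin(pmax(df$z, 0), 1)
  structure(df,
            params = p, variant = variant,
            integrator = list(method = method, atol = atol, rtol = rtol,
                              n_steps = n_steps, horizon = horizon),
            class = c("ohp_trajectory", "data.frame"))
}

#' Fixed-step explicit Euler integration
#'
#' A deliberately simple first-order integrator used as an independent
#' cross-check of the adaptive solver (and available for exploratory work).
#' @inheritParams integrate_trajectory
#' @param dt fixed step size.
#' @param keep_every thin the stored output to every `keep_every`-th step.
#' @return An `ohp_trajectory` data frame.
#' @export
integrate_trajectory_euler <- function(state0, params, horizon = 50,
                                       variant = c("matrix_derived", "as_printed"),
                                       dt = 1e-3, keep_every = 100L) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  s <- as_ohp_state(state0)
  n <- ceiling(horizon / dt)
  keep <- seq(0L, n, by = keep_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 4)
  ki <- 1L
  for (i in 0:n) {
    if (ki <= length(keep) && i == keep[ki]) {
      out[ki, ] <- c(i * dt, s)
      ki <- ki + 1L
    }
    if (i < n) {
      s <- s + dt * s * (1 - s) * .brackets_core(s[[1]], s[[2]], s[[3]], p, variant)
      s <- pmin(pmax(s, 0), 1)
    }
  }
  df <- as.data.frame(out)
  names(df) <- c("t", "x", "y", "z")
  structure(df, params = p, variant = variant,
            integrator = list(method = "euler", dt = dt, horizon = horizon),
            class = c("ohp_trajectory", "data.frame"))
}

#' Detect convergence of a trajectory to a cube corner
#'
#' Reports the corner nearest the terminal state if the trajectory stays
#' within `tol` (sup-norm) of it over the trailing `window` fraction of the
#' time span; otherwise reports "not converged". `time_to_tol` is the first
#' time from which the distance to the limit stays below `tol` through the
#' end of the trajectory.
#'
#' @param traj an `ohp_trajectory` (or data frame with columns t, x, y, z).
#' @param tol convergence tolerance (default 1e-3).
#' @param window trailing fraction of the horizon that must stay within
#'   `tol` (default 0.1).
#' @return A list with elements `converged` (logical), `limit` (named corner
#'   state, or terminal state if not converged), `time_to_tol` (NA when not
#'   converged) and `terminal` (last state).
#' @export
detect_convergence <- function(traj, tol = 1e-3, window = 0.1) {
  stopifnot(nrow(traj) >= 1)
  S <- as.matrix(traj[, c("x", "y", "z")])
  tt <- traj$t
  terminal <- S[nrow(S), ]
  corner <- round(terminal)
  dist <- apply(abs(sweep(S, 2, corner)), 1, max)
  t_win <- tt[length(tt)] - window * (tt[length(tt)] - tt[1])
  in_window <- tt >= t_win
  converged <- all(dist[in_window] < tol)
  if (!converged) {
    return(list(converged = FALSE, limit = terminal, time_to_tol = NA_real_,
                terminal = terminal))
  }
  ok <- rev(cumprod(rev(dist < tol))) == 1  # suffix where dist stays < tol
  list(converged = TRUE,
       limit = stats::setNames(as.numeric(corner), c("x", "y", "z")),
       time_to_tol = tt[which(ok)[1]],
       terminal = terminal)
}

#' @export
print.ohp_trajectory <- function(x, ...) {
  info <- attr(x, "integrator")
  cat("OHP strategy trajectory: ", nrow(x), " points over t = [",
      min(x$t), ", ", max(x$t), "], ", attr(x, "variant"),
      " variant, ", info$method, " integrator\n", sep = "")
  cv <- detect_convergence(x)
  if (cv$converged) {
    cat("converged to (", paste(cv$limit, collapse = ", "),
        ") by t = ", signif(cv$time_to_tol, 4), "\n", sep = "")
  } else {
    cat("not converged; terminal state (",
        paste(signif(cv$terminal, 4), collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Plot a strategy trajectory
#'
#' Base-graphics evolution paths of the three adoption shares against time.
#' @param x an `ohp_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ohp_trajectory <- function(x, ...) {
  graphics::matplot(x$t, as.matrix(x[, c("x", "y", "z")]), type = "l",
                    lty = 1, lwd = 2, col = c("#1b9e77", "#d95f02", "#7570b3"),
                    xlab = "time", ylab = "adoption share", ylim = c(0, 1), ...)
  graphics::legend("right",
                   legend = c("doctors join (x)", "patients use (y)",
                              "platforms provide (z)"),
                   lty = 1, lwd = 2,
                   col = c("#1b9e77", "#d95f02", "#7570b3"), bty = "n")
  invisible(x)
}

#' Export a trajectory as CSV with a config header
#'
#' Writes `t, x, y, z` rows preceded by `#`-prefixed header lines recording
#' the full parameter set, variant and integrator settings, so the run is
#' reproducible from the file alone.
#' @param traj an `ohp_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  p <- attr(traj, "params")
  info <- attr(traj, "integrator")
  hdr <- c(
    "# ohpgame trajectory",
    paste0("# variant: ", attr(traj, "variant")),
    paste0("# integrator: ", paste(names(info), unlist(info), sep = "=",
                                   collapse = " ")),
    paste0("# params: ", paste(ohp_param_names(),
                               vapply(ohp_param_names(),
                                      function(k) format(p[[k]], digits = 17),
                                      character(1)),
                               sep = "=", collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(traj)[, c("t", "x", "y", "z")], con,
                   row.names = FALSE)
  invisible(path)
}
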