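#' Corner equilibria of the unit cube
#'
#' The replicator form makes every vertex of the cube a fixed point. Returns
#' the eight corners in the conventional order V0(0,0,0), V1(1,0,0),
#' V2(1,1,0), V3(1,0,1), V4(0,1,0), V5(0,1,1), V6(0,0,1), V7(1,1,1).
#'
#' @return A 8 x 3 numeric matrix with rownames `V0` ... `V7` and columns
#'   `x`, `y`, `z`.
#' @export
corner_equilibria <- function() {
  m <- rbind(V0 = c(0, 0, 0), V1 = c(1, 0, 0), V2 = c(1, 1, 0),
             V3 = c(1, 0, 1), V4 = c(0, 1, 0), V5 = c(0, 1, 1),
             V6 = c(0, 0, 1), V7 = c(1, 1, 1))
  colnames(m) <- c("x", "y", "z")
  m
}

# analytic partial derivatives of the three brackets; rows = bracket,
# cols = d/dx, d/dy, d/dz
.bracket_partials <- function(state, params, variant) {
  p <- params
  s <- state
  x <- s[[1]]; y <- s[[2]]; z <- s[[3]]
  a <- p$alpha; b <- p$beta
  if (variant == "matrix_derived") {
    dB1 <- c(0,
             (p$r1 - p$c2) - (1 - z) * (1 - a) * p$c3,
             y * (1 - a) * p$c3 + (1 - b) * p$c4)
  } else {
    dB1 <- c(0,
             p$r1 - p$c2 - (1 - a) * p$c3,
             (1 - b) * p$c4)
  }
  k2 <- (1 - a) * p$h2 + (1 - b) * p$h3 + p$L
  dB2 <- c((p$e1 - p$e2 + p$e3 - p$h1 - (1 - a) * p$h2 - (1 - b) * p$h3) +
             z * k2,
           0,
           x * k2 + (1 - b) * p$h4)
  A <- p$M + (1 - a) * p$F1 + (1 - b) * p$F2 + p$N
  dB3 <- c(y * A + (1 - b) * p$G,
           x * A + (1 - b) * p$F3,
           0)
  rbind(dB1, dB2, dB3)
}

#' Jacobian of the replicator system
#'
#' Matrix of partial derivatives of the replicator right-hand side at a
#' state. With `f_i = s_i (1 - s_i) B_i`, the diagonal is
#' `(1 - 2 s_i) B_i + s_i (1 - s_i) dB_i/ds_i` (the second term vanishes
#' because each bracket is independent of its own coordinate), and
#' off-diagonals are `s_i (1 - s_i) dB_i/ds_j`. At a corner every
#' off-diagonal factor `s_i(1-s_i)` is zero, so the matrix is diagonal and
#' its eigenvalues are the signed brackets `(1 - 2 s_i) B_i`.
#'
#' @inheritParams replicator_brackets
#' @param method `"analytic"` (closed-form partials) or `"numeric"` (central
#'   finite differences, step `fd_step`).
#' @param fd_step finite-difference step for `method = "numeric"`.
#' @return A 3 x 3 numeric matrix with dimnames `x`, `y`, `z`.
#' @examples
#' jacobian_matrix(corner_equilibria()["V0", ], ohp_params())
#' @export
jacobian_matrix <- function(state, params,
                            variant = c("matrix_derived", "as_printed"),
                            method = c("analytic", "numeric"),
                            fd_step = 1e-6) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  p <- as_ohp_params(params)
  s <- as_ohp_state(state)
  if (method == "numeric") {
    # the RHS is polynomial, so central differences may use its smooth
    # extension just outside the cube (second-order accurate at faces too)
    f <- function(v) v * (1 - v) * .brackets_core(v[[1]], v[[2]], v[[3]],
                                                  p, variant)
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      hi <- s; lo <- s
      hi[j] <- s[j] + fd_step; lo[j] <- s[j] - fd_step
      J[, j] <- (f(hi) - f(lo)) / (2 * fd_step)
    }
  } else {
    br <- unname(replicator_brackets(s, p, variant))
    dB <- .bracket_partials(s, p, variant)
    fac <- s * (1 - s)
    J <- diag((1 - 2 * s) * br) + diag(fac) %*% dB
  }
  dimnames(J) <- list(c("x", "y", "z"), c("x", "y", "z"))
  J
}

#' Classify the local stability of a fixed point
#'
#' Linearizes the replicator system at a fixed point and classifies it by
#' the real parts of the Jacobian eigenvalues: all negative -- asymptotically
#' stable (the multi-population reading of an evolutionarily stable
#' strategy), all positive -- unstable (source), mixed signs -- saddle, any
#' real part within `eig_tol` of zero -- non-hyperbolic (linearization
#' inconclusive; no forced label).
#'
#' @param point a fixed point `c(x, y, z)`; a precondition error is raised
#'   if the replicator residual there exceeds `residual_tol`.
#' @inheritParams replicator_brackets
#' @param residual_tol maximum sup-norm of the RHS for `point` to count as a
#'   fixed point.
#' @param eig_tol half-width of the zero band for eigenvalue real parts.
#' @return An object of class `ohp_equilibrium`: a list with `point`,
#'   `residual`, `eigenvalues` (complex), `classification`, `variant`.
#' @examples
#' classify_stability(c(0, 0, 0), ohp_params())   # V0: stable
#' classify_stability(c(1, 1, 1), ohp_params())   # V7 under the baseline
#' @export
classify_stability <- function(point, params,
                               variant = c("matrix_derived", "as_printed"),
                               residual_tol = 1e-8, eig_tol = 1e-9) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  s <- as_ohp_state(point)
  res <- max(abs(replicator_rhs(s, p, variant)))
  if (res > residual_tol)
    stop("point is not a fixed point: replicator residual ", signif(res, 3),
         " exceeds tolerance ", residual_tol, call. = FALSE)
  J <- jacobian_matrix(s, p, variant)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  re <- Re(ev)
  classification <-
    if (any(abs(re) <= eig_tol)) "non-hyperbolic"
    else if (all(re < 0)) "asymptotically-stable"
    else if (all(re > 0)) "unstable"
    else "saddle"
  structure(list(point = s, residual = res, eigenvalues = ev,
                 classification = classification, variant = variant),
            class = "ohp_equilibrium")
}

#' @export
print.ohp_equilibrium <- function(x, ...) {
  cat("Fixed point (", paste(signif(x$point, 6), collapse = ", "),
      "): ", x$classification, "\n", sep = "")
  cat("  residual: ", format(x$residual, digits = 3),
      "   eigenvalue real parts: ",
      paste(signif(Re(x$eigenvalues), 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Search for an interior equilibrium
#'
#' Multi-start root search for a simultaneous zero of the three incentive
#' brackets strictly inside the open cube -- the interior fixed point
#' E(x*, y*, z*) when it exists. Starts are a seeded Latin hypercube over
#' the open cube; roots are accepted at bracket residual below `tol`,
#' deduplicated at radius `dedup`. Absence of a root is a valid result.
#'
#' @inheritParams replicator_brackets
#' @param n_starts number of Latin-hypercube starting points (default 50).
#' @param seed RNG seed for the start design (default 1).
#' @param tol residual tolerance for accepting a root (default 1e-8).
#' @param dedup radius below which two roots are considered identical.
#' @param margin roots within `margin` of a face are discarded (they belong
#'   to the boundary analysis, not the interior point).
#' @return A list of `ohp_equilibrium` objects (possibly empty).
#' @examples
#' # baseline with costs tuned so the mixed point (0.5, 0.5, 0.5) is a root
#' p <- update_params(baseline_params(), c1 = 2.1, h1 = 3.4,
#'                    t1 = 12.375, t2 = 12.375)
#' interior_equilibrium(p)
#' @export
interior_equilibrium <- function(params,
                                 variant = c("matrix_derived", "as_printed"),
                                 n_starts = 50, seed = 1, tol = 1e-8,
                                 dedup = 1e-4, margin = 1e-6) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  fn <- function(s) {
    s <- pmin(pmax(s, 0), 1)
    .brackets_core(s[[1]], s[[2]], s[[3]], p, variant)
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, 3)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  roots <- list()
  for (i in seq_len(n_starts)) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(fn, design[i, ], tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sol)) next
    r <- sol$x
    if (any(r < margin) || any(r > 1 - margin)) next
    if (max(abs(fn(r))) > tol) next
    dup <- any(vapply(roots, function(q) max(abs(q$point - r)) < dedup,
                      logical(1)))
    if (!dup) {
      roots[[length(roots) + 1L]] <-
        classify_stability(r, p, variant, residual_tol = Inf)
    }
  }
  roots
}

# returns the current .Random.seed if one exists (so seeded subroutines can
# restore global RNG state), else NULL
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' Enumerate and classify all equilibria of a parameter set
#'
#' Classifies the eight corner fixed points and appends any interior roots
#' found by [interior_equilibrium()].
#'
#' @inheritParams interior_equilibrium
#' @param interior search for interior roots too? (default TRUE)
#' @return A data frame with one row per equilibrium: `name`, `x`, `y`, `z`,
#'   `residual`, `eig1`, `eig2`, `eig3` (real parts), `classification`.
#' @examples
#' equilibria(baseline_params())
#' @export
equilibria <- function(params, variant = c("matrix_derived", "as_printed"),
                       interior = TRUE, n_starts = 50, seed = 1) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  corners <- corner_equilibria()
  reports <- lapply(rownames(corners), function(nm) {
    r <- classify_stability(corners[nm, ], p, variant)
    c(list(name = nm), r)
  })
  if (interior) {
    ir <- interior_equilibrium(p, variant, n_starts = n_starts, seed = seed)
    for (i in seq_along(ir)) {
      reports[[length(reports) + 1L]] <- c(list(name = paste0("E", i)), ir[[i]])
    }
  }
  do.call(rbind, lapply(reports, function(r) {
    data.frame(name = r$name,
               x = r$point[[1]], y = r$point[[2]], z = r$point[[3]],
               residual = r$residual,
               eig1 = Re(r$eigenvalues[1]), eig2 = Re(r$eigenvalues[2]),
               eig3 = Re(r$eigenvalues[3]),
               classification = r$classification,
               stringsAsFactors = FALSE)
  }))
}
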