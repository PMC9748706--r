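#' Construct a tripartite OHP game
#'
#' The central object of the package: bundles a parameter set, the payoff
#' tensor built from it, and the equation variant used for dynamics and
#' stability work. Methods: [print()], [summary()] (equilibrium
#' classification), [simulate()] (trajectory integration), [plot()]
#' (trajectory from a given start).
#'
#' @param params an [ohp_params()] object (default: the package baseline).
#' @param variant `"matrix_derived"` (payoff matrix as primitive, default)
#'   or `"as_printed"` (literal closed-form equations); see
#'   [replicator_brackets()] for where the two differ.
#' @return An object of class `ohp_game` with elements `params`, `tensor`,
#'   `variant`.
#' @examples
#' g <- ohp_game()
#' summary(g)
#' tr <- simulate(g, init = c(0.5, 0.5, 0.5), horizon = 30)
#' tail(tr, 1)
#' @export
ohp_game <- function(params = baseline_params(),
                     variant = c("matrix_derived", "as_printed")) {
  variant <- match.arg(variant)
  p <- as_ohp_params(params)
  structure(list(params = p, tensor = payoff_tensor(p), variant = variant),
            class = "ohp_game")
}

#' @export
print.ohp_game <- function(x, ...) {
  cat("Tripartite evolutionary game: doctors (join) x patients (use) x",
      "platforms (provide)\n")
  cat("equation variant:", x$variant, "\n\n")
  print(x$params)
  invisible(x)
}

#' Equilibrium summary of an OHP game
#'
#' Classifies the eight corner fixed points (and any interior roots) of the
#' replicator system under the game's parameters.
#'
#' @param object an [ohp_game()].
#' @param interior search for interior equilibria too? (default TRUE)
#' @param ... passed to [equilibria()].
#' @return A `summary.ohp_game` object wrapping the [equilibria()] table.
#' @export
summary.ohp_game <- function(object, interior = TRUE, ...) {
  tab <- equilibria(object$params, variant = object$variant,
                    interior = interior, ...)
  structure(list(table = tab, variant = object$variant,
                 params = object$params),
            class = "summary.ohp_game")
}

#' @export
print.summary.ohp_game <- function(x, ...) {
  cat("Equilibria of the replicator system (", x$variant, " variant)\n\n",
      sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  stable <- x$table$name[x$table$classification == "asymptotically-stable"]
  if (length(stable))
    cat("\nEvolutionarily stable states:", paste(stable, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate strategy-share trajectories of an OHP game
#'
#' Integrates the replicator dynamics from `init` over `[0, horizon]`.
#' The system is deterministic; `seed` and `nsim` exist for generic
#' compatibility (`nsim > 1` returns a list of identical-by-construction
#' runs from possibly multiple `init` rows).
#'
#' @param object an [ohp_game()].
#' @param nsim number of trajectories; if `init` is a matrix its rows are
#'   recycled across simulations.
#' @param seed unused (deterministic dynamics); accepted for the generic.
#' @param init initial state `c(x, y, z)` or a matrix with 3 columns.
#' @param horizon integration horizon.
#' @param ... passed to [integrate_trajectory()].
#' @return One `ohp_trajectory` (when `nsim = 1`) or a list of them.
#' @export
simulate.ohp_game <- function(object, nsim = 1, seed = NULL,
                              init = c(0.5, 0.5, 0.5), horizon = 50, ...) {
  inits <- if (is.matrix(init)) init else matrix(init, nrow = 1)
  runs <- lapply(seq_len(max(nsim, nrow(inits))), function(i) {
    integrate_trajectory(inits[((i - 1) %% nrow(inits)) + 1, ],
                         object$params, horizon = horizon,
                         variant = object$variant, ...)
  })
  if (length(runs) == 1L) runs[[1]] else runs
}

#' @export
plot.ohp_game <- function(x, init = c(0.5, 0.5, 0.5), horizon = 50, ...) {
  plot(simulate(x, init = init, horizon = horizon), ...)
}
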