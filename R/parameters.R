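#' Model parameters of the tripartite OHP game
#'
#' Bundles the 23 scalar parameters of the doctor--patient--platform game.
#' All quantities are unitless payoff magnitudes: replicator dynamics are
#' invariant under a common positive rescaling of any one player's payoffs,
#' so only ratios within a player's payoffs matter.
#'
#' The strength coefficients `alpha` (qualification inspection, QISC) and
#' `beta` (information-protection investment, IPISC) describe the platform's
#' effort in the *not provide* regime; in the *provide* regime both are 1
#' exactly. Loss and compensation bases are realized scaled by `(1 - alpha)`
#' or `(1 - beta)` in the non-providing cells only.
#'
#' Defaults are the package baseline (see [baseline_params()]), a documented
#' admissible set under which full adoption (1,1,1) is locally stable at high
#' `alpha`, `beta` and universal abandonment (0,0,0) is always locally stable.
#'
#' @param r1 doctor's income when doctor joins and patient uses.
#' @param c1 doctor's registration / qualification-certification cost.
#' @param c2 doctor's time cost.
#' @param c3 doctor reputation-loss base, realized as `(1-alpha)*c3`.
#' @param c4 doctor information-leakage loss base, realized as `(1-beta)*c4`.
#' @param e1 patient health benefit from the OHP.
#' @param e2 patient health benefit from a hospital visit; must exceed `e1`.
#' @param e3 patient time/money saved by using the OHP.
#' @param L additional patient benefit when all three parties cooperate.
#' @param h1 patient's cost of using the OHP.
#' @param h2 patient health-loss base, realized as `(1-alpha)*h2`.
#' @param h3 patient disease-information-leakage loss base, `(1-beta)*h3`.
#' @param h4 patient identity-information-leakage loss base, `(1-beta)*h4`.
#' @param w1 platform economic benefit when doctor joins and patient uses.
#' @param M platform social-reputation income when providing.
#' @param N platform social-reputation loss when not providing (join+use cell).
#' @param t1 platform full cost of doctor-qualification inspection.
#' @param t2 platform full cost of information-protection investment.
#' @param F1 compensation base for patient health loss, `(1-alpha)*F1`.
#' @param F2 compensation base for patient disease-information leakage.
#' @param F3 compensation base for patient identity-information leakage.
#' @param G compensation base for doctor information leakage, `(1-beta)*G`.
#' @param alpha qualification inspection strength coefficient, in (0, 1).
#' @param beta information protection investment strength coefficient, in (0, 1).
#'
#' @return An object of class `ohp_params`: a named list of the 23 scalars.
#' @seealso [payoff_tensor()], [ohp_game()], [baseline_params()]
#' @examples
#' p <- ohp_params()
#' p$r1
#' ohp_params(alpha = 0.1) # low inspection strength
#' @export
ohp_params <- function(r1 = 10, c1 = 2, c2 = 3, c3 = 16, c4 = 20,
                       e1 = 6, e2 = 8, e3 = 5, L = 2,
                       h1 = 2, h2 = 4, h3 = 2, h4 = 3,
                       w1 = 10, M = 4, N = 4, t1 = 12, t2 = 12,
                       F1 = 4, F2 = 3, F3 = 3, G = 3,
                       alpha = 0.9, beta = 0.9) {
  p <- list(r1 = r1, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
            e1 = e1, e2 = e2, e3 = e3, L = L,
            h1 = h1, h2 = h2, h3 = h3, h4 = h4,
            w1 = w1, M = M, N = N, t1 = t1, t2 = t2,
            F1 = F1, F2 = F2, F3 = F3, G = G,
            alpha = alpha, beta = beta)
  validate_ohp_params(p)
  structure(p, class = "ohp_params")
}

#' Names of the 23 game parameters
#' @return Character vector of parameter names in canonical order.
#' @export
ohp_param_names <- function() {
  c("r1", "c1", "c2", "c3", "c4", "e1", "e2", "e3", "L",
    "h1", "h2", "h3", "h4", "w1", "M", "N", "t1", "t2",
    "F1", "F2", "F3", "G", "alpha", "beta")
}

# invariants: all scalars finite, non-negative; e1 < e2; alpha, beta strictly
# inside (0,1) because several loss terms degenerate at the endpoints
validate_ohp_params <- function(p) {
  nm <- ohp_param_names()
  extra <- setdiff(names(p), nm)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (k in nm) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", k, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", k, "' must be non-negative (got ", v, ")", call. = FALSE)
  }
  for (k in c("alpha", "beta")) {
    if (p[[k]] <= 0 || p[[k]] >= 1)
      stop("parameter '", k, "' must lie strictly inside (0, 1) (got ",
           p[[k]], ")", call. = FALSE)
  }
  if (p$e1 >= p$e2)
    stop("invariant violated: e1 < e2 required (hospital benefit must exceed ",
         "OHP benefit); got e1 = ", p$e1, ", e2 = ", p$e2, call. = FALSE)
  invisible(p)
}

#' @export
print.ohp_params <- function(x, ...) {
  cat("OHP game parameters (23 scalars)\n")
  cat("  doctor  : r1 =", x$r1, " c1 =", x$c1, " c2 =", x$c2,
      " c3 =", x$c3, " c4 =", x$c4, "\n")
  cat("  patient : e1 =", x$e1, " e2 =", x$e2, " e3 =", x$e3, " L =", x$L,
      "\n            h1 =", x$h1, " h2 =", x$h2, " h3 =", x$h3, " h4 =", x$h4, "\n")
  cat("  platform: w1 =", x$w1, " M =", x$M, " N =", x$N,
      " t1 =", x$t1, " t2 =", x$t2,
      "\n            F1 =", x$F1, " F2 =", x$F2, " F3 =", x$F3, " G =", x$G, "\n")
  cat("  strength: alpha (QISC) =", x$alpha, " beta (IPISC) =", x$beta, "\n")
  invisible(x)
}

#' Coerce a named list or vector to `ohp_params`
#' @param x named list or numeric vector containing exactly the 23 parameters.
#' @return An `ohp_params` object.
#' @export
as_ohp_params <- function(x) {
  if (inherits(x, "ohp_params")) return(x)
  if (is.numeric(x)) x <- as.list(x)
  if (!is.list(x) || is.null(names(x)))
    stop("cannot coerce to ohp_params: need a named list or vector", call. = FALSE)
  x <- lapply(x, as.numeric)
  validate_ohp_params(x)
  structure(x[ohp_param_names()], class = "ohp_params")
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#' @param params an [ohp_params()] object.
#' @param ... `name = value` overrides using the canonical symbol names.
#' @return A new `ohp_params` object.
#' @examples
#' update_params(ohp_params(), alpha = 0.1, c1 = 5)
#' @export
update_params <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 0L) return(params)
  bad <- setdiff(names(ov), ohp_param_names())
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  p[names(ov)] <- lapply(ov, as.numeric)
  as_ohp_params(p)
}

#' Read / write a parameter configuration file
#'
#' The on-disk format is flat YAML keyed by the canonical symbol names
#' (`r1`, `c1` ... `c4`, `e1` ... `e3`, `L`, `h1` ... `h4`, `w1`, `M`, `N`,
#' `t1`, `t2`, `F1` ... `F3`, `G`, `alpha`, `beta`). Unknown keys are hard
#' errors so that typos like `c_3` cannot pass silently.
#'
#' @param path file path.
#' @return `read_ohp_config()` returns an `ohp_params`; `write_ohp_config()`
#'   returns `path` invisibly.
#' @export
read_ohp_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a flat key: value mapping", call. = FALSE)
  as_ohp_params(raw)
}

#' @rdname read_ohp_config
#' @param params an [ohp_params()] object to serialize.
#' @export
write_ohp_config <- function(params, path) {
  params <- as_ohp_params(params)
  # keys are quoted so YAML cannot read symbols like N as booleans
  lines <- vapply(ohp_param_names(), function(k) {
    sprintf("'%s': %s", k, format(params[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
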