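#' Strategy labels
#'
#' Strategy index 1 is the "active" strategy whose population share the state
#' coordinates x, y, z track: doctors join, patients use, platforms provide.
#' Index 0 is the complement.
#' @name strategies
#' @keywords internal
NULL

.players <- c("doctor", "patient", "platform")
.strategy_levels <- list(
  doctor   = c("not_join", "join"),
  patient  = c("not_use", "use"),
  platform = c("not_provide", "provide")
)

# normalize a strategy spec (label or 0/1) to 1 = active, 0 = complement
.strategy_index <- function(player, strategy) {
  lv <- .strategy_levels[[player]]
  if (is.null(lv)) stop("unknown player: ", player, call. = FALSE)
  if (is.numeric(strategy)) {
    if (!strategy %in% c(0, 1))
      stop("numeric strategy must be 0 or 1", call. = FALSE)
    return(as.integer(strategy))
  }
  i <- match(strategy, lv)
  if (is.na(i)) stop("unknown strategy '", strategy, "' for player '", player,
                     "' (expected one of: ", paste(lv, collapse = ", "), ")",
                     call. = FALSE)
  i - 1L
}

#' Build the payoff tensor of the tripartite game
#'
#' Evaluates all 24 payoffs of the game: one triple (doctor, patient,
#' platform) for each of the 8 pure-strategy profiles in the 2x2x2 grid.
#' In the *provide* cells inspection and protection are complete, so no
#' `(1-alpha)` / `(1-beta)` losses arise; in the *not provide* cells the
#' scaled losses and compensations apply. Doctors who do not join earn 0
#' in every cell.
#'
#' @param params an [ohp_params()] object (or coercible named list).
#' @return An object of class `ohp_payoffs`: a numeric array with
#'   `dim = c(2, 2, 2, 3)` and dimnames
#'   `doctor x patient x platform x player`, carrying `params` as an
#'   attribute. Use [as.data.frame()] for the tidy 8-row view.
#' @examples
#' pt <- payoff_tensor(ohp_params())
#' pt["join", "use", "provide", ]    # full-cooperation payoffs
#' as.data.frame(pt)
#' @export
payoff_tensor <- function(params) {
  p <- as_ohp_params(params)
  a <- p$alpha; b <- p$beta
  arr <- array(0, dim = c(2, 2, 2, 3),
               dimnames = c(.strategy_levels, list(player = .players)))

  # provide regime: effective alpha = beta = 1, full costs t1 + t2
  arr["join",     "use",     "provide", ] <- c(
    p$r1 - p$c1 - p$c2,
    p$e1 + p$e3 - p$h1 + p$L,
    p$w1 - p$t1 - p$t2 + p$M)
  arr["not_join", "use",     "provide", ] <- c(0, p$e2, -p$t1 - p$t2)
  arr["join",     "not_use", "provide", ] <- c(-p$c1, p$e2, -p$t1 - p$t2)
  arr["not_join", "not_use", "provide", ] <- c(0, p$e2, -p$t1 - p$t2)

  # not-provide regime: losses scaled by (1-alpha), (1-beta); costs a*t1, b*t2
  arr["join",     "use",     "not_provide", ] <- c(
    p$r1 - p$c1 - p$c2 - (1 - a) * p$c3 - (1 - b) * p$c4,
    p$e1 + p$e3 - p$h1 - (1 - a) * p$h2 - (1 - b) * (p$h3 + p$h4),
    p$w1 - a * p$t1 - b * p$t2 - (1 - a) * p$F1 -
      (1 - b) * (p$F2 + p$F3 + p$G) - p$N)
  arr["not_join", "use",     "not_provide", ] <- c(
    0,
    p$e2 - (1 - b) * p$h4,
    -a * p$t1 - b * p$t2 - (1 - b) * p$F3)
  arr["join",     "not_use", "not_provide", ] <- c(
    -p$c1 - (1 - b) * p$c4,
    p$e2,
    -a * p$t1 - b * p$t2 - (1 - b) * p$G)
  arr["not_join", "not_use", "not_provide", ] <- c(
    0,
    p$e2,
    -a * p$t1 - b * p$t2)

  structure(arr, params = p, class = c("ohp_payoffs", "array"))
}

#' @export
print.ohp_payoffs <- function(x, ...) {
  cat("OHP payoff tensor: 8 pure-strategy profiles x 3 players\n\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Tidy view of a payoff tensor
#' @param x an `ohp_payoffs` array.
#' @param ... unused.
#' @return A data frame with one row per pure-strategy profile and columns
#'   `doctor_strategy`, `patient_strategy`, `platform_strategy`,
#'   `doctor_payoff`, `patient_payoff`, `platform_payoff`.
#' @export
as.data.frame.ohp_payoffs <- function(x, ...) {
  g <- expand.grid(doctor_strategy = .strategy_levels$doctor,
                   patient_strategy = .strategy_levels$patient,
                   platform_strategy = .strategy_levels$platform,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # active strategies first, in doctor > patient > platform precedence
  g <- g[order(g$doctor_strategy != "join",
               g$patient_strategy != "use",
               g$platform_strategy != "provide"), , drop = FALSE]
  rownames(g) <- NULL
  pay <- t(mapply(function(d, pa, pl) x[d, pa, pl, ],
                  g$doctor_strategy, g$patient_strategy, g$platform_strategy))
  g$doctor_payoff <- pay[, "doctor"]
  g$patient_payoff <- pay[, "patient"]
  g$platform_payoff <- pay[, "platform"]
  g
}

#' Export a payoff tensor as a tidy CSV
#' @param tensor an `ohp_payoffs` array from [payoff_tensor()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_payoff_tensor <- function(tensor, path) {
  utils::write.csv(as.data.frame(tensor), path, row.names = FALSE)
  invisible(path)
}

#' Marginal expected payoff of one strategy
#'
#' Expected payoff to a player committed to one pure strategy, averaging the
#' payoff tensor over the other two populations' mixed strategies. These are
#' the conditional fitnesses P11/P12 (doctor join / not join), P21/P22
#' (patient use / not use) and P31/P32 (platform provide / not provide) that
#' drive the replicator dynamics.
#'
#' @param player `"doctor"`, `"patient"` or `"platform"`.
#' @param strategy the player's strategy: a label (e.g. `"join"`,
#'   `"not_use"`) or 1 (active) / 0 (complement).
#' @param state numeric state `c(x, y, z)` of adoption shares in the unit cube.
#' @param tensor an `ohp_payoffs` array, or an [ohp_params()] object from
#'   which one is built.
#' @return A single number.
#' @examples
#' p <- ohp_params()
#' marginal_payoff("doctor", "join", c(0.5, 0.5, 0.5), p)
#' marginal_payoff("patient", "not_use", c(0.2, 0.4, 0.6), p) # always e2
#' @export
marginal_payoff <- function(player, strategy, state, tensor) {
  player <- match.arg(player, .players)
  if (!inherits(tensor, "ohp_payoffs")) tensor <- payoff_tensor(tensor)
  s <- as_ohp_state(state)
  si <- .strategy_index(player, strategy)
  probs <- list(doctor = c(1 - s[1], s[1]),
                patient = c(1 - s[2], s[2]),
                platform = c(1 - s[3], s[3]))
  others <- setdiff(.players, player)
  tot <- 0
  for (i in 0:1) for (j in 0:1) {
    idx <- list(doctor = NA_integer_, patient = NA_integer_,
                platform = NA_integer_)
    idx[[player]] <- si + 1L
    idx[[others[1]]] <- i + 1L
    idx[[others[2]]] <- j + 1L
    w <- probs[[others[1]]][i + 1L] * probs[[others[2]]][j + 1L]
    tot <- tot + w * tensor[idx$doctor, idx$patient, idx$platform, player]
  }
  unname(tot)
}

#' Average expected payoff of a population
#'
#' The population-mean fitness: the share-weighted mean of the player's two
#' marginal expected payoffs, e.g. `P1(x) = x*P11 + (1-x)*P12` for doctors.
#'
#' @inheritParams marginal_payoff
#' @return A single number.
#' @export
average_payoff <- function(player, state, tensor) {
  player <- match.arg(player, .players)
  if (!inherits(tensor, "ohp_payoffs")) tensor <- payoff_tensor(tensor)
  s <- as_ohp_state(state)
  share <- unname(switch(player, doctor = s[1], patient = s[2], platform = s[3]))
  share * marginal_payoff(player, 1, s, tensor) +
    (1 - share) * marginal_payoff(player, 0, s, tensor)
}

# --- state helpers -----------------------------------------------------------

#' Validate a strategy state
#'
#' A state is the point `(x, y, z)` of adoption shares: the fraction of
#' doctors joining, patients using, platforms providing. The solution domain
#' is the closed unit cube.
#'
#' @param state numeric of length 3, optionally named.
#' @param tol how far outside \[0,1\] a coordinate may fall before a domain
#'   error is raised (values within `tol` are clipped back).
#' @return A named numeric vector `c(x =, y =, z =)` inside the unit cube.
#' @export
as_ohp_state <- function(state, tol = 1e-9) {
  s <- as.numeric(state)
  if (length(s) != 3L || any(!is.finite(s)))
    stop("state must be 3 finite numbers (x, y, z)", call. = FALSE)
  if (any(s < -tol) || any(s > 1 + tol))
    stop("state outside the unit cube: (", paste(signif(s, 6), collapse = ", "),
         ")", call. = FALSE)
  s <- pmin(pmax(s, 0), 1)
  names(s) <- c("x", "y", "z")
  s
}
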