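#' Game specifications
#'
#' Constructors for the named social-dilemma games. Each returns a
#' `"game_spec"` carrying per-agent primitives (vectors are recycled to a
#' common length); [payoff_coeffs()] maps them to the linear-marginal
#' coefficients used by the core model.
#'
#' * `coordination_game`: each agent has a personally preferred action
#'   `theta_pref` and pays quadratic costs `c` for deviating from it and `d`
#'   for mismatching the peers' mean action; `b` is the maximum benefit.
#' * `pgg_game`: public goods with quadratic personal costs. Total group
#'   effort Z is multiplied by `b`; agent i receives share `v[i]` of the
#'   product and pays cost `c[i] x^2 / 2`.
#' * `cpr_game`: common pool resource (Tullock-style shares). Group product
#'   is `b Z - d Z^2 / 2`; agent i's share is proportional to its own effort,
#'   and it pays a linear individual cost `c[i] x`. `d` is each agent's
#'   (subjective) diminishing-return coefficient.
#' * `generic_game`: explicit marginal-payoff coefficients `(D0, D1, D2)`,
#'   covering linear (`D1 = D2 = 0`) and quasi-linear (`D2 = 0`) payoffs.
#'
#' @param b,c,d,v,theta_pref,D0,D1,D2 per-agent numeric parameters (recycled).
#' @return an object of class `"game_spec"`.
#' @examples
#' g <- coordination_game(theta_pref = 1, c = 1, d = 1)
#' payoff_coeffs(g, n = 2)
#' @name game_spec
NULL

new_game_spec <- function(game, params) {
  n <- max(vapply(params, length, 1L))
  params <- lapply(params, function(p) rep_len(as.numeric(p), n))
  structure(list(game = game, params = params, n_params = n),
            class = "game_spec")
}

#' @rdname game_spec
#' @export
coordination_game <- function(theta_pref, c = 1, d = 1, b = 1) {
  stopifnot(all(c > 0), all(d >= 0), all(theta_pref >= 0))
  new_game_spec("coordination", list(b = b, c = c, d = d, theta_pref = theta_pref))
}

#' @rdname game_spec
#' @export
pgg_game <- function(v, c = 1, b = 40) {
  stopifnot(all(v >= 0), all(v <= 1), all(b > 0), all(c > 0))
  new_game_spec("pgg_quadratic", list(b = b, v = v, c = c))
}

#' @rdname game_spec
#' @export
cpr_game <- function(c = 1, d = 1, b = 10) {
  stopifnot(all(b > c), all(c >= 0), all(d > 0))
  new_game_spec("cpr", list(b = b, c = c, d = d))
}

#' @rdname game_spec
#' @export
generic_game <- function(D0, D1 = 0, D2 = 0) {
  new_game_spec("generic", list(D0 = D0, D1 = D1, D2 = D2))
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf("<game_spec: %s, %d agent parameter set(s)>\n", x$game, x$n_params))
  invisible(x)
}

game_n <- function(game, n = NULL) {
  if (is.null(n)) n <- game$n_params
  stopifnot(n >= 2 || game$game %in% c("generic", "pgg_quadratic"))
  n
}

rep_params <- function(game, n) lapply(game$params, rep_len, n)

#' Marginal-payoff coefficients of a game
#'
#' Maps a game's per-agent primitives to the `(D0, D1, D2)` coefficients of
#' the linear marginal payoff: coordination `(2 c theta_pref, 2 d, 2(c+d))`;
#' public goods with quadratic costs `(v b, 0, c)`; common pool resource
#' `(b - c, -d (n-1)/2, d)` (the coupling coefficient D1 grows with group
#' size); generic games pass their coefficients through.
#'
#' @param game a [game_spec][game_spec] object.
#' @param n group size (defaults to the number of agent parameter sets;
#'   required by the common pool resource game).
#' @return an n-by-3 coefficient matrix (see [payoff_coeffs_raw()]).
#' @export
payoff_coeffs <- function(game, n = NULL) {
  stopifnot(inherits(game, "game_spec"))
  n <- game_n(game, n)
  p <- rep_params(game, n)
  switch(game$game,
    coordination = payoff_coeffs_raw(2 * p$c * p$theta_pref, 2 * p$d, 2 * (p$c + p$d)),
    pgg_quadratic = payoff_coeffs_raw(p$v * p$b, 0, p$c),
    cpr = {
      if (n < 2) stop("common pool resource game needs n >= 2")
      payoff_coeffs_raw(p$b - p$c, -p$d * (n - 1) / 2, p$d)
    },
    generic = payoff_coeffs_raw(p$D0, p$D1, p$D2),
    stop("unknown game: ", game$game))
}

#' Literal game payoff
#'
#' Evaluates the game's payoff function for each agent at own action `x`
#' given the empirical expectation `x_exp` of the peers' mean action; group
#' effort games use the predicted total effort `Z = x + (n-1) x_exp`. In the
#' common pool resource game, zero predicted effort yields the defined limit
#' of a zero product share (no effort, no payoff, minus the linear cost).
#'
#' @inheritParams payoff_coeffs
#' @param x own action(s), non-negative.
#' @param x_exp expected peers' mean action(s), non-negative.
#' @return numeric vector of payoffs.
#' @export
payoff_value <- function(game, x, x_exp, n = NULL) {
  stopifnot(inherits(game, "game_spec"), all(x >= 0), all(x_exp >= 0))
  n <- game_n(game, n)
  p <- rep_params(game, n)
  Z <- x + (n - 1) * x_exp
  switch(game$game,
    coordination = p$b - p$c * (x - p$theta_pref)^2 - p$d * (x - x_exp)^2,
    pgg_quadratic = p$v * p$b * Z - p$c * x^2 / 2,
    cpr = {
      # x/Z * (bZ - dZ^2/2) simplifies to x (b - dZ/2), which also covers the
      # Z = 0 limit (x = 0 there, so the product share is 0)
      x * (p$b - 0.5 * p$d * Z) - p$c * x
    },
    generic = p$D0 * x + p$D1 * x_exp * x - p$D2 * x^2 / 2,
    stop("unknown game: ", game$game))
}

#' Relative conformity pressure in the coordination game
#'
#' `r = d / (c + d)`: the weight an agent's material best reply puts on the
#' peers' mean action relative to its own preferred action.
#'
#' @param c cost of deviating from the preferred action (positive).
#' @param d miscoordination cost (non-negative).
#' @return numeric vector in `[0, 1]`.
#' @export
conformity_ratio <- function(c, d) {
  if (any(c + d <= 0)) stop("conformity ratio undefined when c + d = 0")
  d / (c + d)
}

#' Nash equilibrium efforts (evolutionary game theory baseline)
#'
#' Solves the simultaneous material best-reply system (normative terms off,
#' each agent best-responding to the others' actual mean action).
#' Public goods with quadratic costs: `x_i = theta_i = v_i b / c_i` exactly.
#' Common pool resource with identical agents: `x = 2 (b - c) / (d (n + 1))`;
#' heterogeneous agents: the linear first-order-condition system is solved
#' directly. Coordination: solves `x_i = (1 - r_i) theta_i + r_i Xbar_{-i}`
#' with the leave-self-out mean.
#'
#' @inheritParams payoff_coeffs
#' @return numeric vector of per-agent Nash efforts.
#' @export
nash_baseline <- function(game, n = NULL) {
  stopifnot(inherits(game, "game_spec"))
  n <- game_n(game, n)
  p <- rep_params(game, n)
  switch(game$game,
    pgg_quadratic = p$v * p$b / p$c,
    cpr = nash_from_coeffs(payoff_coeffs(game, n), n),
    coordination = {
      r <- conformity_ratio(p$c, p$d)
      # x_i = (1 - r_i) theta_i + r_i/(n-1) * sum_{j != i} x_j; the system is
      # diagonally dominant (r < 1) and its solution is non-negative
      M <- diag(n) - (matrix(r / (n - 1), n, n) - diag(r / (n - 1)))
      as.numeric(solve(M, (1 - r) * p$theta_pref))
    },
    generic = {
      if (any(p$D2 <= 0)) stop("generic Nash baseline requires D2 > 0")
      nash_from_coeffs(payoff_coeffs(game, n), n)
    },
    stop("unknown game: ", game$game))
}

# simultaneous best-reply equilibrium with non-negativity constraints:
# try the interior linear solve of the first-order conditions; if any effort
# is negative the equilibrium is at a corner, found by damped projected
# best-reply iteration, and certified by complementarity (effort > 0 implies
# zero marginal payoff; effort = 0 implies non-positive marginal payoff)
nash_from_coeffs <- function(pc, n, tol = 1e-10) {
  D0 <- pc[, "D0"]; D1 <- pc[, "D1"]; D2 <- pc[, "D2"]
  M <- diag(D2) - (matrix(D1 / (n - 1), n, n) - diag(D1 / (n - 1)))
  sol <- tryCatch(as.numeric(solve(M, D0)),
                  error = function(e) stop("singular first-order-condition system"))
  if (all(sol >= -1e-12)) return(pmax(0, sol))
  damp <- 1 / (1 + max(abs(D1) / D2))
  x <- pmax(0, D0 / D2)
  for (t in seq_len(50000)) {
    X <- (sum(x) - x) / (n - 1)
    x_new <- (1 - damp) * x + damp * pmax(0, (D0 + D1 * X) / D2)
    if (max(abs(x_new - x)) < 1e-14 * max(1, max(x))) { x <- x_new; break }
    x <- x_new
  }
  X <- (sum(x) - x) / (n - 1)
  foc <- D0 + D1 * X - D2 * x
  if (any(x > tol & abs(foc) > tol) || any(x <= tol & foc > tol))
    stop("best-reply iteration failed to certify the constrained equilibrium")
  x
}

#' Socially optimal effort in the common pool resource game
#'
#' The symmetric per-agent effort maximising the total group payoff
#' `b Z - d Z^2/2 - c Z`: the optimal total effort is `Z = (b - c)/d`, split
#' equally, so `x_opt = (b - c)/(d n)`. The identical-agent Nash effort is
#' `2n/(n+1)` times larger — the over-extraction factor of the dilemma.
#'
#' @param b linear return coefficient (positive).
#' @param d diminishing-return coefficient (positive).
#' @param c linear individual cost coefficient, with `b > c >= 0`.
#' @param n group size.
#' @return per-agent socially optimal effort (length 1).
#' @export
social_optimum_cpr <- function(b, d, c = 0, n = 2) {
  stopifnot(b >= c, c >= 0, d > 0, n >= 1)
  (b - c) / (d * n)
}
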