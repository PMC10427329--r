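#' Marginal payoff coefficients
#'
#' Bundles the three coefficients of the linear marginal material payoff
#' \eqn{\partial\pi/\partial x = D_0 + D_1 \tilde{x} - D_2 x}, where
#' \eqn{\tilde{x}} is the agent's empirical expectation of the peers' mean
#' action. Any linear, quasi-linear or quadratic game payoff reduces to this
#' form. Vectorised: each argument may be a vector (one element per agent).
#'
#' @param D0 marginal payoff intercept.
#' @param D1 coefficient on the expected peers' mean action (may be negative).
#' @param D2 self-action curvature coefficient; must be positive for a strictly
#'   concave material payoff (zero is allowed for linear/quasi-linear games,
#'   where concavity must then come from the normative terms).
#' @return a numeric matrix with columns `D0`, `D1`, `D2`, one row per agent.
#' @examples
#' payoff_coeffs_raw(2, 2, 4)
#' @export
payoff_coeffs_raw <- function(D0, D1, D2) {
  n <- max(length(D0), length(D1), length(D2))
  pc <- cbind(D0 = rep_len(as.numeric(D0), n),
              D1 = rep_len(as.numeric(D1), n),
              D2 = rep_len(as.numeric(D2), n))
  if (any(!is.finite(pc))) stop("payoff coefficients must be finite")
  pc
}

as_pc_matrix <- function(pc) {
  if (is.matrix(pc)) {
    stopifnot(ncol(pc) == 3)
    colnames(pc) <- c("D0", "D1", "D2")
    pc
  } else {
    stopifnot(length(pc) == 3)
    matrix(as.numeric(pc), 1, dimnames = list(NULL, c("D0", "D1", "D2")))
  }
}

#' Marginal material payoff
#'
#' Evaluates \eqn{D_0 + D_1 \tilde{x} - D_2 x}: the derivative of the material
#' payoff with respect to the agent's own action, given its belief about the
#' peers' mean action.
#'
#' @param pc coefficients from [payoff_coeffs_raw()] or [payoff_coeffs()] (a
#'   length-3 vector or an n-by-3 matrix).
#' @param x own action (non-negative real).
#' @param x_exp empirical expectation of the peers' mean action.
#' @return numeric vector of marginal payoffs.
#' @export
marginal_payoff <- function(pc, x, x_exp) {
  pc <- as_pc_matrix(pc)
  unname(pc[, "D0"] + pc[, "D1"] * x_exp - pc[, "D2"] * x)
}

#' Self-consistent material best response
#'
#' The action \eqn{\theta = D_0/(D_2 - D_1)} solving the material first-order
#' condition under the assumption that peers mirror the agent's own action
#' (\eqn{\tilde{x} = x}). In the games shipped here, theta is a
#' benefit-to-cost summary and in several of them the Nash effort.
#'
#' @inheritParams marginal_payoff
#' @return numeric vector of theta values, one per agent.
#' @export
theta <- function(pc) {
  pc <- as_pc_matrix(pc)
  den <- pc[, "D2"] - pc[, "D1"]
  if (any(den <= 0))
    stop("theta undefined: D2 - D1 must be positive (payoff not concave along x = x_exp)")
  unname(pc[, "D0"] / den)
}

#' External authority
#'
#' An external authority promoting a standard action level `G`. When the
#' authority is inactive, all authority-related weights (`A4` and the third
#' column of the belief-update coefficients) are treated as zero downstream.
#'
#' @param G promoted standard action (non-negative real).
#' @param active logical flag.
#' @return an object of class `"authority"`.
#' @export
authority <- function(G = 0, active = TRUE) {
  stopifnot(is.numeric(G), length(G) == 1, G >= 0)
  structure(list(active = isTRUE(active), G = as.numeric(G)), class = "authority")
}

#' @export
print.authority <- function(x, ...) {
  if (x$active) cat("External authority promoting G =", x$G, "\n")
  else cat("External authority: inactive\n")
  invisible(x)
}

auth_G <- function(auth) {
  if (is.null(auth) || !auth$active) 0 else auth$G
}

auth_active <- function(auth) !is.null(auth) && auth$active

norm_weights_matrix <- function(A, n) {
  if (is.matrix(A)) {
    stopifnot(ncol(A) == 4)
  } else {
    stopifnot(length(A) == 4)
    A <- matrix(A, 1, 4)
  }
  colnames(A) <- paste0("A", 1:4)
  if (any(A < 0)) stop("normative weights A1..A4 must be non-negative")
  A
}

state_matrix <- function(st) {
  if (is.matrix(st)) {
    stopifnot(ncol(st) == 4)
  } else {
    stopifnot(length(st) == 4)
    st <- matrix(st, 1, 4)
  }
  colnames(st) <- c("x", "y", "x_exp", "y_exp")
  st
}

#' Agent state
#'
#' Convenience constructor for an agent state: the action `x`, the personal
#' norm (attitude) `y`, the empirical expectation `x_exp` of the peers' mean
#' action (first-order belief) and the normative expectation `y_exp` of the
#' peers' mean attitude (second-order belief). All components are non-negative.
#'
#' @param x,y,x_exp,y_exp non-negative numeric vectors (recycled).
#' @return numeric matrix with columns `x`, `y`, `x_exp`, `y_exp`.
#' @export
agent_state <- function(x = 0, y = 0, x_exp = 0, y_exp = 0) {
  n <- max(length(x), length(y), length(x_exp), length(y_exp))
  st <- cbind(x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
              x_exp = rep_len(as.numeric(x_exp), n),
              y_exp = rep_len(as.numeric(y_exp), n))
  if (any(st < 0)) stop("state components must be non-negative")
  st
}

#' Subjective utility
#'
#' The utility an agent maximises by myopic best response: the material payoff
#' \eqn{\pi(x,\tilde{x}) = D_0 x + D_1 \tilde{x} x - D_2 x^2/2} (the
#' antiderivative of the marginal payoff in x; the integration constant is
#' irrelevant since only differences in x matter) minus quadratic normative
#' penalties
#' \eqn{A_1 (x-y)^2} (cognitive dissonance),
#' \eqn{A_2 (x-\tilde{y})^2} (expected disapproval by peers),
#' \eqn{A_3 (x-\tilde{x})^2} (conformity with peers' actions) and
#' \eqn{A_4 (x-G)^2} (conformity with the authority's standard).
#'
#' @inheritParams marginal_payoff
#' @param A normative weights `A1..A4` (length-4 vector or n-by-4 matrix).
#' @param st agent state from [agent_state()].
#' @param x candidate action(s) at which to evaluate the utility.
#' @param auth an [authority()] object or `NULL` (inactive).
#' @return numeric vector of utilities (vectorised over `x`).
#' @export
utility <- function(pc, A, st, x, auth = NULL) {
  pc <- as_pc_matrix(pc); A <- norm_weights_matrix(A); st <- state_matrix(st)
  G <- auth_G(auth)
  A4 <- if (auth_active(auth)) A[, "A4"] else 0
  pi_mat <- pc[, "D0"] * x + pc[, "D1"] * st[, "x_exp"] * x - pc[, "D2"] * x^2 / 2
  unname(pi_mat -
    A[, "A1"] * (x - st[, "y"])^2 -
    A[, "A2"] * (x - st[, "y_exp"])^2 -
    A[, "A3"] * (x - st[, "x_exp"])^2 -
    A4 * (x - G)^2)
}

#' Myopic best response
#'
#' Closed-form maximiser of [utility()] over non-negative actions. Since the
#' utility is quadratic and concave in x, the unconstrained maximiser is
#' \deqn{x^* = \frac{D_0 + (D_1 + 2A_3)\tilde{x} + 2A_1 y + 2A_2 \tilde{y} +
#'   2A_4 G}{D_2 + 2(A_1 + A_2 + A_3 + A_4)},}
#' which is clipped at zero. The rescaled coefficients of the equivalent
#' weighted-average form \eqn{x^* = B_0 + B_1 y + B_2 \tilde{y} + B_3 \tilde{x}
#' + B_4 G} are attached as attribute `"B"` when `coefficients = TRUE`.
#'
#' @inheritParams utility
#' @param coefficients if `TRUE`, attach the implied `B0..B4` coefficients.
#' @return numeric vector of best-response actions (one per agent).
#' @export
best_response <- function(pc, A, st, auth = NULL, coefficients = FALSE) {
  pc <- as_pc_matrix(pc); A <- norm_weights_matrix(A); st <- state_matrix(st)
  G <- auth_G(auth)
  A4 <- if (auth_active(auth)) A[, "A4"] else rep(0, nrow(A))
  den <- pc[, "D2"] + 2 * (A[, "A1"] + A[, "A2"] + A[, "A3"] + A4)
  if (any(den <= 0))
    stop("utility not strictly concave: D2 + 2*(A1+A2+A3+A4) must be positive")
  num <- pc[, "D0"] + (pc[, "D1"] + 2 * A[, "A3"]) * st[, "x_exp"] +
    2 * A[, "A1"] * st[, "y"] + 2 * A[, "A2"] * st[, "y_exp"] + 2 * A4 * G
  br <- pmax(0, num / den)
  if (coefficients) {
    attr(br, "B") <- cbind(B0 = pc[, "D0"] / den,
                           B1 = 2 * A[, "A1"] / den,
                           B2 = 2 * A[, "A2"] / den,
                           B3 = (pc[, "D1"] + 2 * A[, "A3"]) / den,
                           B4 = 2 * A4 / den)
  }
  unname(br)
}

belief_weights_matrix <- function(C) {
  if (is.matrix(C) && ncol(C) == 3 && nrow(C) == 3) C <- matrix(t(C), 1, 9)
  if (!is.matrix(C)) { stopifnot(length(C) == 9); C <- matrix(C, 1, 9) }
  stopifnot(ncol(C) == 9)
  colnames(C) <- c("C11", "C12", "C13", "C21", "C22", "C23", "C31", "C32", "C33")
  if (any(C < 0)) stop("belief-update coefficients must be non-negative")
  rs <- cbind(rowSums(C[, 1:3, drop = FALSE]), rowSums(C[, 4:6, drop = FALSE]),
              rowSums(C[, 7:9, drop = FALSE]))
  if (any(rs > 1 + 1e-12))
    stop("each belief-update row must sum to at most 1 (damped convex move)")
  C
}

#' Attitude and belief update
#'
#' One step of the linear recurrences revising the personal norm and the two
#' belief variables after the agent has acted and observed the mean action
#' `X_obs` of its groupmates:
#' \deqn{y' = y + C_{11}(x - y) + C_{12}(X - y) + C_{13}(G - y)}
#' \deqn{\tilde{y}' = \tilde{y} + C_{21}(y - \tilde{y}) + C_{22}(X - \tilde{y})
#'   + C_{23}(G - \tilde{y})}
#' \deqn{\tilde{x}' = \tilde{x} + C_{31}(\tilde{y} - \tilde{x}) +
#'   C_{32}(X - \tilde{x}) + C_{33}(G - \tilde{x})}
#' Row 1 combines cognitive dissonance (justifying the action taken), peer
#' conformity and authority conformity; row 2 social projection, learning
#' about others and authority; row 3 the logic constraint (aligning beliefs
#' about actions with beliefs about attitudes), learning and authority. The
#' action `x` is not changed here; all outputs are clipped at zero.
#'
#' @param C belief-update coefficients: a 3-by-3 matrix (single agent), a
#'   length-9 vector in row-major order, or an n-by-9 matrix. All entries
#'   non-negative, each row summing to at most 1.
#' @param st agent state from [agent_state()].
#' @param X_obs observed mean action of the groupmates (excluding self).
#' @param auth an [authority()] object or `NULL`.
#' @return updated state matrix (same shape as `st`).
#' @export
update_beliefs <- function(C, st, X_obs, auth = NULL) {
  C <- belief_weights_matrix(C); st <- state_matrix(st)
  G <- auth_G(auth)
  x <- unname(st[, "x"]); y <- unname(st[, "y"])
  ye <- unname(st[, "y_exp"]); xe <- unname(st[, "x_exp"])
  X_obs <- unname(X_obs)
  y2 <- y + C[, "C11"] * (x - y) + C[, "C12"] * (X_obs - y) + C[, "C13"] * (G - y)
  ye2 <- ye + C[, "C21"] * (y - ye) + C[, "C22"] * (X_obs - ye) + C[, "C23"] * (G - ye)
  xe2 <- xe + C[, "C31"] * (ye - xe) + C[, "C32"] * (X_obs - xe) + C[, "C33"] * (G - xe)
  out <- cbind(x = x, y = pmax(0, y2), x_exp = pmax(0, xe2), y_exp = pmax(0, ye2))
  out
}

#' Normalised belief-channel weights
#'
#' For each of the three update rows, the relative strengths of the cognitive
#' channel (alpha: cognitive dissonance / social projection / logic
#' constraint), the peer channel (beta: conformity with or learning from
#' peers) and the authority channel (gamma), with alpha + beta + gamma = 1.
#' Rows with zero total weight describe a frozen belief channel; they are
#' legal and returned as `NA` with a `degenerate` flag rather than an error.
#'
#' @inheritParams update_beliefs
#' @return a list with components `alpha`, `beta`, `gamma` (each length 3,
#'   one entry per update row) and logical `degenerate` marking zero-sum rows.
#' @export
normalized_weights <- function(C) {
  C <- belief_weights_matrix(C)
  if (nrow(C) != 1) stop("normalized_weights expects a single agent's coefficients")
  m <- matrix(C, 3, 3, byrow = TRUE)
  rs <- rowSums(m)
  deg <- rs <= 0
  w <- m / ifelse(rs > 0, rs, NA_real_)
  list(alpha = w[, 1], beta = w[, 2], gamma = w[, 3], degenerate = deg)
}
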