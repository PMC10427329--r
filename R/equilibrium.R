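#' Exact fixed point of the deterministic dynamics
#'
#' Substitutes the closed-form best response into the belief recurrences
#' (noise-free, every agent revising, leave-self-out observed means) and
#' solves the resulting 3n-dimensional affine stationarity system directly.
#' The update map is `s' = L s + k` in the stacked coordinates
#' `(y_1..y_n, ytilde_1..ytilde_n, xtilde_1..xtilde_n)`; the fixed point is
#' `solve(I - L, k)`, the actions are recovered through the best response,
#' and the result is certified by applying one noise-free full-revision step
#' and checking the residual. Contraction is verified through the spectral
#' radius of `L`.
#'
#' This exact finite-n solve is the package's single source of analytic
#' truth; it specialises to the known closed forms (every component equal to
#' the common theta in a homogeneous group without authority; every
#' component equal to G when material payoffs vanish under an authority).
#'
#' @param object a [norm_group()] object.
#' @param tol residual tolerance for certification (default `1e-10`).
#' @param ... unused.
#' @return an object of class `"norm_equilibrium"`: list with `states`
#'   (n-by-4 fixed-point matrix), `mean` (group means), `theta_bar`,
#'   `regime` (see [regime_classify()]), `spectral_radius` and `residual`.
#' @seealso [predicted_mean_action()], [regime_classify()]
#' @export
predict.norm_group <- function(object, tol = 1e-10, ...) {
  n <- object$n
  pc <- object$pc; A <- object$A; C <- object$C
  G <- auth_G(object$auth)
  A4 <- if (auth_active(object$auth)) A[, "A4"] else rep(0, n)
  den <- pc[, "D2"] + 2 * (A[, "A1"] + A[, "A2"] + A[, "A3"] + A4)
  if (any(den <= 0)) stop("utility not strictly concave for some agent")

  # x = P s + p0 over s = (y, ytilde, xtilde)
  P <- matrix(0, n, 3 * n)
  idx <- seq_len(n)
  P[cbind(idx, idx)] <- 2 * A[, "A1"] / den
  P[cbind(idx, n + idx)] <- 2 * A[, "A2"] / den
  P[cbind(idx, 2 * n + idx)] <- (pc[, "D1"] + 2 * A[, "A3"]) / den
  p0 <- (pc[, "D0"] + 2 * A4 * G) / den

  # X = Q x, leave-self-out mean
  Q <- matrix(1 / (n - 1), n, n); diag(Q) <- 0

  # s' = base * s + Mx * x + g, with x = P s + p0
  dg <- function(v) diag(v, n)
  rs1 <- rowSums(C[, c("C11", "C12", "C13"), drop = FALSE])
  rs2 <- rowSums(C[, c("C21", "C22", "C23"), drop = FALSE])
  rs3 <- rowSums(C[, c("C31", "C32", "C33"), drop = FALSE])
  Zn <- matrix(0, n, n)
  base <- rbind(
    cbind(dg(1 - rs1), Zn, Zn),
    cbind(dg(C[, "C21"]), dg(1 - rs2), Zn),
    cbind(Zn, dg(C[, "C31"]), dg(1 - rs3)))
  Mx <- rbind(dg(C[, "C11"]) + dg(C[, "C12"]) %*% Q,
              dg(C[, "C22"]) %*% Q,
              dg(C[, "C32"]) %*% Q)
  L <- base + Mx %*% P
  k <- as.numeric(Mx %*% p0) + G * c(C[, "C13"], C[, "C23"], C[, "C33"])

  rho <- max(Mod(eigen(L, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("dynamics are not a contraction (spectral radius %.4f >= 1); no unique stable fixed point", rho))
  s <- solve(diag(3 * n) - L, k)
  st <- cbind(x = 0, y = s[idx], x_exp = s[2 * n + idx], y_exp = s[n + idx])
  st[, "x"] <- best_response(pc, A, st, object$auth)

  # certify by one noise-free full-revision step
  nxt <- step_dynamics(object, st, revision_prob = 1, noise_sd = 0)
  residual <- max(abs(nxt - st))
  if (residual > tol)
    warning(sprintf("fixed-point residual %.2e exceeds tolerance %.0e (clipping active?)", residual, tol))
  structure(list(states = st, mean = colMeans(st),
                 theta_bar = mean(object$theta),
                 regime = regime_classify(object),
                 spectral_radius = rho, residual = residual),
            class = "norm_equilibrium")
}

#' @export
print.norm_equilibrium <- function(x, ...) {
  cat("<norm_equilibrium>\n")
  cat("  regime:", x$regime, "\n")
  cat("  group means:",
      paste(sprintf("%s = %.4f", names(x$mean), x$mean), collapse = ", "), "\n")
  if (is.finite(x$theta_bar)) cat(sprintf("  mean theta: %.4f\n", x$theta_bar))
  cat(sprintf("  spectral radius %.4f, residual %.2e\n",
              x$spectral_radius, x$residual))
  invisible(x)
}

#' Predicted equilibrium mean action
#'
#' Without an external authority, the long-run group-mean action equals the
#' population mean of the individual theta values (a large-n result; the
#' exact solver quantifies the finite-n gap). Warns, rather than fails, when
#' the authority is active, where this prediction does not apply.
#'
#' @param group a [norm_group()] object.
#' @return the mean of the agents' theta values.
#' @export
predicted_mean_action <- function(group) {
  stopifnot(inherits(group, "norm_group"))
  if (auth_active(group$auth))
    warning("authority active: the mean-theta prediction applies only without external influence")
  mean(group$theta)
}

#' Classify the closed-form equilibrium regime
#'
#' Labels an instance by which analytic special case applies:
#' `"authority_only"` (all material coefficients zero, authority active —
#' every variable converges to the promoted standard G),
#' `"homogeneous"` (no authority, no variation in theta — every variable
#' converges to the common theta),
#' `"heterogeneous_no_authority"` (no authority, variation in theta — the
#' mean action converges to mean theta), or `"general"`.
#'
#' @param group a [norm_group()] object.
#' @param tol numerical tolerance for "zero"/"no variation".
#' @return a regime label (character).
#' @export
regime_classify <- function(group, tol = 1e-12) {
  stopifnot(inherits(group, "norm_group"))
  d_zero <- all(abs(group$pc) < tol)
  if (auth_active(group$auth)) {
    if (d_zero) return("authority_only")
    return("general")
  }
  th <- group$theta
  if (all(is.finite(th)) && diff(range(th)) < tol) return("homogeneous")
  "heterogeneous_no_authority"
}
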