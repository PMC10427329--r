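#' Moment-matched log-normal sampling
#'
#' Draws i.i.d. log-normal values whose distribution mean and standard
#' deviation equal the given arguments, via the two-moment inversion
#' `sigma^2 = log(1 + sd^2/mean^2)`, `mu = log(mean) - sigma^2/2`. A zero
#' `sd` returns constants.
#'
#' @param n number of draws.
#' @param mean distribution mean (positive).
#' @param sd distribution standard deviation (non-negative).
#' @return numeric vector of `n` positive draws.
#' @export
sample_lognormal <- function(n, mean = 1, sd = 0.1) {
  stopifnot(n >= 0, mean > 0, sd >= 0, is.finite(mean), is.finite(sd))
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + sd^2 / mean^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Broken-stick shares
#'
#' Splits the unit interval at `n - 1` uniform break points and returns the
#' `n` gap lengths: non-negative shares summing to one, each with expectation
#' `1/n`. Used for the share parameters `v_i` of the public goods game.
#'
#' @param n number of shares (at least 1).
#' @return numeric vector of `n` shares summing to 1.
#' @export
sample_broken_stick <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  diff(c(0, sort(stats::runif(n - 1)), 1))
}

#' Random initial states
#'
#' Initial actions, attitudes and beliefs drawn i.i.d. uniform on
#' `[0, max]` for each agent, emulating a group that starts near inaction
#' with diffuse, weak beliefs.
#'
#' @param n group size.
#' @param max upper bound of the uniform support (default 0.1).
#' @return an n-by-4 state matrix (columns `x`, `y`, `x_exp`, `y_exp`).
#' @export
initial_states <- function(n, max = 0.1) {
  stopifnot(n >= 1, max >= 0)
  m <- matrix(stats::runif(4 * n, 0, max), n, 4)
  colnames(m) <- c("x", "y", "x_exp", "y_exp")
  m
}

#' Assemble a group model from explicit components
#'
#' Low-level constructor for the central model object. Most users will call
#' [sample_group()], which draws heterogeneous components from the standard
#' distributions; this constructor accepts them explicitly (useful for
#' homogeneous or otherwise hand-built instances).
#'
#' When the authority is inactive, the authority weight `A4` and the third
#' column of the belief-update coefficients are forced to zero.
#'
#' @param pc n-by-3 marginal-payoff coefficient matrix ([payoff_coeffs_raw()]).
#' @param A n-by-4 normative weight matrix (columns `A1..A4`).
#' @param C n-by-9 belief-update coefficient matrix (columns `C11..C33`,
#'   row-major within each agent).
#' @param auth an [authority()] object or `NULL`.
#' @param game optionally, the [game_spec][game_spec] the coefficients came from.
#' @param epsilon the normative-weight scale used to build `A` (metadata).
#' @return an object of class `"norm_group"`: a list with elements `n`, `pc`,
#'   `A`, `C`, `theta` (`NA` where undefined), `auth`, `game`, `epsilon`.
#' @export
norm_group <- function(pc, A, C, auth = NULL, game = NULL, epsilon = NA_real_) {
  pc <- as_pc_matrix(pc)
  n <- nrow(pc)
  A <- norm_weights_matrix(A)
  if (nrow(A) == 1) A <- A[rep(1, n), , drop = FALSE]
  C <- belief_weights_matrix(C)
  if (nrow(C) == 1) C <- C[rep(1, n), , drop = FALSE]
  stopifnot(nrow(A) == n, nrow(C) == n)
  if (!auth_active(auth)) {
    A[, "A4"] <- 0
    C[, c("C13", "C23", "C33")] <- 0
  }
  den <- pc[, "D2"] - pc[, "D1"]
  th <- ifelse(den > 0, pc[, "D0"] / den, NA_real_)
  structure(list(n = n, pc = pc, A = A, C = C, theta = unname(th),
                 auth = auth, game = game, epsilon = epsilon),
            class = "norm_group")
}

#' Sample a heterogeneous group
#'
#' Draws a group of `n` agents for one of the named games, following the
#' standard study setups: game primitives are log-normal with the given mean
#' and standard deviation (coordination: `theta_pref`, `c`, `d`; public
#' goods: `c` log-normal, shares `v` broken-stick, `b` fixed; common pool
#' resource: `c`, `d` log-normal, `b` fixed), base normative weights
#' `a1..a4` are log-normal on the same scale and scaled by `epsilon`
#' (`A_k = epsilon * a_k`; at `epsilon = 0` the agents are pure material
#' payoff maximisers, at `epsilon = 1` each normative term carries the same
#' expected weight as the material quadratic terms), and belief-update
#' coefficients are log-normal per cell with each agent's row rescaled to
#' `row_sum` so updates are damped convex moves.
#'
#' @param game `"coordination"`, `"pgg_quadratic"`, `"cpr"`, or a
#'   [game_spec][game_spec] object supplying explicit per-agent primitives
#'   (including `generic_game()` coefficient sets).
#' @param n group size.
#' @param epsilon normative-weight scale in `[0, 1]`.
#' @param auth an [authority()] object or `NULL` for no external influence.
#' @param b benefit parameter held fixed across agents (defaults: 1 for
#'   coordination, 40 for public goods, 10 for common pool resource).
#' @param dist_mean,dist_sd mean and standard deviation of the log-normal
#'   parameter distributions.
#' @param row_sum total per-row weight of the belief-update coefficients
#'   (in `(0, 1]`; default 0.5).
#' @param seed optional integer seed for reproducible sampling.
#' @return a [norm_group()] object.
#' @examples
#' g <- sample_group("coordination", n = 10, epsilon = 1, seed = 1)
#' mean(g$theta)
#' @export
sample_group <- function(game = c("coordination", "pgg_quadratic", "cpr"),
                         n = 100, epsilon = 1, auth = NULL, b = NULL,
                         dist_mean = 1, dist_sd = 0.1, row_sum = 0.5,
                         seed = NULL) {
  stopifnot(n >= 2, epsilon >= 0, epsilon <= 1, row_sum > 0, row_sum <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(game, "game_spec")) {
    spec <- game
  } else {
    game <- match.arg(game)
    spec <- switch(game,
      coordination = coordination_game(
        theta_pref = sample_lognormal(n, dist_mean, dist_sd),
        c = sample_lognormal(n, dist_mean, dist_sd),
        d = sample_lognormal(n, dist_mean, dist_sd),
        b = if (is.null(b)) 1 else b),
      pgg_quadratic = pgg_game(
        v = sample_broken_stick(n),
        c = sample_lognormal(n, dist_mean, dist_sd),
        b = if (is.null(b)) 40 else b),
      cpr = cpr_game(
        c = sample_lognormal(n, dist_mean, dist_sd),
        d = sample_lognormal(n, dist_mean, dist_sd),
        b = if (is.null(b)) 10 else b))
  }
  pc <- payoff_coeffs(spec, n)
  a <- matrix(sample_lognormal(4 * n, dist_mean, dist_sd), n, 4)
  A <- epsilon * a
  Craw <- matrix(sample_lognormal(9 * n, dist_mean, dist_sd), n, 9)
  if (!auth_active(auth)) Craw[, c(3, 6, 9)] <- 0
  C <- Craw
  for (r in 1:3) {
    idx <- (3 * (r - 1) + 1):(3 * r)
    C[, idx] <- Craw[, idx] / rowSums(Craw[, idx, drop = FALSE]) * row_sum
  }
  g <- norm_group(pc, A, C, auth = auth, game = spec, epsilon = epsilon)
  g$seed <- seed
  g
}

#' @export
print.norm_group <- function(x, ...) {
  gname <- if (!is.null(x$game)) x$game$game else "custom"
  cat(sprintf("<norm_group: %d agents, game %s, epsilon = %s>\n",
              x$n, gname, format(x$epsilon)))
  if (auth_active(x$auth)) cat("  authority active, G =", x$auth$G, "\n")
  if (all(is.finite(x$theta)))
    cat(sprintf("  theta: mean %.4f, sd %.4f\n", mean(x$theta), stats::sd(x$theta)))
  invisible(x)
}

#' @export
coef.norm_group <- function(object, ...) {
  cbind(object$pc, object$A, object$C, theta = object$theta)
}

#' @export
as.data.frame.norm_group <- function(x, ...) {
  data.frame(agent = seq_len(x$n), coef(x))
}
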