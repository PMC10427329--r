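#' One step of the coupled stochastic dynamics
#'
#' Each agent is independently marked as revising with probability
#' `revision_prob`. Revising agents post their closed-form best response
#' (computed from their current attitude and beliefs) as their new action,
#' perturbed by additive Gaussian noise and clipped at zero; non-revising
#' agents keep their previous action. All agents then observe the
#' leave-self-out mean `X_i` of the posted actions (posting is simultaneous:
#' every `X_i` uses the same action vector), and revising agents update
#' their attitude and beliefs, again with additive noise per updated
#' component, clipped at zero.
#'
#' @param group a [norm_group()] object.
#' @param states n-by-4 state matrix (columns `x`, `y`, `x_exp`, `y_exp`).
#' @param revision_prob per-agent revision probability per step.
#' @param noise_sd standard deviation of the additive update noise.
#' @param noise_on which channels receive noise: both actions and beliefs
#'   (default), actions only, or beliefs only.
#' @return the new n-by-4 state matrix.
#' @export
step_dynamics <- function(group, states, revision_prob = 0.5, noise_sd = 0.01,
                          noise_on = c("both", "action", "beliefs")) {
  noise_on <- match.arg(noise_on)
  n <- group$n
  states <- state_matrix(states)
  stopifnot(nrow(states) == n, revision_prob >= 0, revision_prob <= 1,
            noise_sd >= 0)
  rev <- if (revision_prob >= 1) rep(TRUE, n) else
    stats::runif(n) < revision_prob
  x_new <- states[, "x"]
  if (any(rev)) {
    br <- best_response(group$pc, group$A, states, group$auth)
    if (noise_sd > 0 && noise_on != "beliefs")
      br <- br + stats::rnorm(n, 0, noise_sd)
    x_new[rev] <- pmax(0, br[rev])
  }
  states[, "x"] <- x_new
  X <- (sum(x_new) - x_new) / (n - 1)
  if (any(rev)) {
    upd <- update_beliefs(group$C, states, X, group$auth)
    if (noise_sd > 0 && noise_on != "action") {
      upd[, c("y", "x_exp", "y_exp")] <-
        pmax(0, upd[, c("y", "x_exp", "y_exp")] + stats::rnorm(3 * n, 0, noise_sd))
    }
    states[rev, c("y", "x_exp", "y_exp")] <- upd[rev, c("y", "x_exp", "y_exp")]
  }
  attr(states, "X") <- X
  states
}

#' Simulate the coupled dynamics of a group
#'
#' Iterates [step_dynamics()] for `steps` time steps from the given (or
#' freshly drawn) initial states, recording every `record_every` steps.
#' With `nsim > 1`, repeats the run with independent randomness (same group)
#' and returns a `"norm_ensemble"`.
#'
#' @param object a [norm_group()] object.
#' @param nsim number of independent runs.
#' @param seed optional integer seed.
#' @param steps number of time steps (default 1000).
#' @param revision_prob per-agent revision probability per step (default 0.5).
#' @param noise_sd additive update noise standard deviation (default 0.01).
#' @param record_every recording stride (default 1).
#' @param init optional n-by-4 initial state matrix; defaults to
#'   [initial_states()] draws on `[0, 0.1]`.
#' @param noise_on noise channel switch, see [step_dynamics()].
#' @param ... unused.
#' @return for `nsim = 1` a `"norm_traj"`: a list with `states` (array of
#'   recorded states, time by agent by variable), `time` (recorded step
#'   numbers, starting at 0), `mean` (matrix of group means per recorded
#'   step) and the `group`. For `nsim > 1`, a `"norm_ensemble"` list of runs.
#' @export
simulate.norm_group <- function(object, nsim = 1, seed = NULL, steps = 1000,
                                revision_prob = 0.5, noise_sd = 0.01,
                                record_every = 1, init = NULL,
                                noise_on = "both", ...) {
  stopifnot(steps >= 0, record_every >= 1, nsim >= 1)
  if (!is.null(seed)) set.seed(seed)
  one_run <- function() {
    st <- if (is.null(init)) initial_states(object$n) else state_matrix(init)
    rec_at <- unique(c(seq(0, steps, by = record_every), steps))
    nrec <- length(rec_at)
    states <- array(NA_real_, c(nrec, object$n, 4),
                    dimnames = list(NULL, NULL, c("x", "y", "x_exp", "y_exp")))
    states[1, , ] <- st
    k <- 2
    if (steps >= 1) for (t in seq_len(steps)) {
      st <- step_dynamics(object, st, revision_prob, noise_sd, noise_on)
      if (k <= nrec && t == rec_at[k]) { states[k, , ] <- st; k <- k + 1 }
    }
    mean_mat <- apply(states, c(1, 3), mean)
    structure(list(states = states, time = rec_at, mean = mean_mat,
                   group = object, steps = steps,
                   revision_prob = revision_prob, noise_sd = noise_sd),
              class = "norm_traj")
  }
  if (nsim == 1) return(one_run())
  runs <- vector("list", nsim)
  for (i in seq_len(nsim)) runs[[i]] <- one_run()
  structure(list(runs = runs, groups = rep(list(object), nsim)),
            class = "norm_ensemble")
}

#' Run an ensemble of independent populations
#'
#' Draws `n_runs` independent groups from the same sampling recipe (fresh
#' agent parameters and initial states each run) and simulates each,
#' deriving one sub-seed per run from `master_seed`. This is the protocol
#' behind the ensemble statistics: between-run variation includes parameter
#' sampling, not just dynamical noise.
#'
#' @param recipe a [norm_recipe()] describing the population and simulation.
#' @param master_seed integer seed controlling all runs.
#' @param n_runs number of independent runs (defaults to the recipe's).
#' @param epsilon optional override of the recipe's normative-weight scale.
#' @return a `"norm_ensemble"`: list with `runs` (trajectories), `groups`,
#'   `seeds` and the `recipe`.
#' @export
run_ensemble <- function(recipe, master_seed = 1, n_runs = NULL, epsilon = NULL) {
  stopifnot(inherits(recipe, "norm_recipe"))
  if (is.null(n_runs)) n_runs <- recipe$n_runs
  if (is.null(epsilon)) epsilon <- recipe$epsilon
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  runs <- vector("list", n_runs)
  groups <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    g <- recipe_group(recipe, epsilon = epsilon, seed = seeds[i])
    groups[[i]] <- g
    runs[[i]] <- simulate(g, nsim = 1, steps = recipe$steps,
                          revision_prob = recipe$revision_prob,
                          noise_sd = recipe$noise_sd,
                          record_every = recipe$record_every,
                          init = initial_states(g$n, recipe$init_max))
  }
  structure(list(runs = runs, groups = groups, seeds = seeds,
                 recipe = recipe, epsilon = epsilon),
            class = "norm_ensemble")
}

#' Observed leave-self-out mean actions along a trajectory
#'
#' For each recorded step and agent, the mean action of the other `n - 1`
#' agents (the quantity each agent observes and learns from).
#'
#' @param traj a `"norm_traj"` object.
#' @return matrix, recorded steps by agents.
#' @export
observed_mean <- function(traj) {
  stopifnot(inherits(traj, "norm_traj"))
  x <- traj$states[, , "x", drop = FALSE][, , 1]
  if (is.null(dim(x))) x <- matrix(x, nrow = length(traj$time))
  n <- ncol(x)
  (rowSums(x) - x) / (n - 1)
}

#' @export
print.norm_traj <- function(x, ...) {
  cat(sprintf("<norm_traj: %d agents, %d steps (%d recorded)>\n",
              dim(x$states)[2], x$steps, length(x$time)))
  last <- x$mean[nrow(x$mean), ]
  cat("  final group means:",
      paste(sprintf("%s = %.4f", colnames(x$mean), last), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.norm_ensemble <- function(x, ...) {
  cat(sprintf("<norm_ensemble: %d runs>\n", length(x$runs)))
  invisible(x)
}

#' @export
as.data.frame.norm_traj <- function(x, ..., run = 1L) {
  d <- dim(x$states)
  data.frame(
    run = run,
    step = rep(x$time, times = d[2]),
    agent = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(x$states[, , "x"]),
    y = as.vector(x$states[, , "y"]),
    x_exp = as.vector(x$states[, , "x_exp"]),
    y_exp = as.vector(x$states[, , "y_exp"]))
}

#' @export
as.data.frame.norm_ensemble <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$runs), function(i)
    as.data.frame(x$runs[[i]], run = i)))
}

#' Plot group-mean trajectories
#'
#' Draws the group means of the action, attitude and the two belief
#' variables against time, the standard diagnostic for convergence to the
#' stochastic equilibrium.
#'
#' @param x a `"norm_traj"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.norm_traj <- function(x, ...) {
  graphics::matplot(x$time, x$mean, type = "l", lty = 1,
                    col = c("purple", "darkgreen", "orange", "steelblue"),
                    xlab = "time step", ylab = "group mean", ...)
  graphics::legend("bottomright",
                   legend = c("x (action)", "y (attitude)",
                              "x~ (empirical exp.)", "y~ (normative exp.)"),
                   col = c("purple", "darkgreen", "orange", "steelblue"),
                   lty = 1, bty = "n")
  invisible(x)
}
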