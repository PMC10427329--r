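# shared fixtures, built in code

# a homogeneous group: every agent identical, common theta
homogeneous_group <- function(n = 5, theta0 = 1, A = c(1, 1, 1, 0),
                              C = c(0.2, 0.2, 0, 0.2, 0.2, 0, 0.2, 0.2, 0),
                              auth = NULL) {
  # coordination coefficients with theta_pref = theta0, c = d = 1
  pc <- payoff_coeffs_raw(rep(2 * theta0, n), rep(2, n), rep(4, n))
  norm_group(pc, matrix(A, n, 4, byrow = TRUE),
             matrix(C, n, 9, byrow = TRUE), auth = auth)
}

# all material payoffs zero, authority promoting G
authority_only_group <- function(n = 5, G = 2,
                                 C = c(0.1, 0.2, 0.2, 0.1, 0.2, 0.2,
                                       0.1, 0.2, 0.2)) {
  pc <- payoff_coeffs_raw(rep(0, n), rep(0, n), rep(0, n))
  norm_group(pc, matrix(c(1, 1, 1, 1), n, 4, byrow = TRUE),
             matrix(C, n, 9, byrow = TRUE), auth = authority(G))
}

random_small_group <- function(seed, n_max = 10) {
  set.seed(seed)
  game <- sample(c("coordination", "pgg_quadratic", "cpr"), 1)
  n <- sample(3:n_max, 1)
  sample_group(game, n = n, epsilon = 1, seed = seed + 1)
}

# independent Kendall tau-b oracle: exhaustive pair enumeration
kendall_enum <- function(a, b) {
  n <- length(a)
  nc <- nd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
  }
  n0 <- choose(n, 2)
  t1 <- sum(choose(table(a), 2))
  t2 <- sum(choose(table(b), 2))
  (nc - nd) / sqrt((n0 - t1) * (n0 - t2))
}

# iterate the noise-free, all-revising dynamics to (near) stationarity
iterate_to_fixed_point <- function(group, init, max_steps = 20000,
                                   tol = 1e-13) {
  st <- init
  for (t in seq_len(max_steps)) {
    st2 <- step_dynamics(group, st, revision_prob = 1, noise_sd = 0)
    if (max(abs(st2 - st)) < tol) return(st2)
    st <- st2
  }
  st
}

last_window_mean <- function(traj, last_k = 100, var = "x") {
  nrec <- dim(traj$states)[1]
  mean(traj$states[(nrec - last_k + 1):nrec, , var])
}

ensemble_run_means <- function(ens, last_k = 100, var = "x") {
  vapply(ens$runs, last_window_mean, numeric(1), last_k = last_k, var = var)
}
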