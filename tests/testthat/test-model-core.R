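test_that("marginal payoff is linear in x and x_exp with the fixed sign convention", {
  # coordination coefficients (c = d = 1, preferred action 1): zero marginal
  # at the preferred consensus
  expect_equal(marginal_payoff(c(2, 2, 4), x = 1, x_exp = 1), 0)
  # x_exp has no effect when D1 = 0
  expect_equal(marginal_payoff(c(1, 0, 1), x = 0, x_exp = 7), 1)
  # CPR coefficients for b = 10, c = 1, d = 1, n = 20
  expect_equal(marginal_payoff(c(9, -9.5, 1), x = 0, x_exp = 0), 9)
})

test_that("theta solves the self-consistent first-order condition", {
  expect_equal(theta(c(1, 0, 1)), 1)        # PGG benefit-to-cost ratio
  expect_equal(theta(c(2, 2, 4)), 1)        # coordination preferred action
  expect_equal(theta(c(9, -9.5, 1)), 18 / 21) # CPR 2(b-c)/(d(n+1))
  # theta is a root of the marginal payoff along x = x_exp
  th <- theta(c(9, -9.5, 1))
  expect_equal(marginal_payoff(c(9, -9.5, 1), th, th), 0)
  # root-finding oracle agrees
  root <- uniroot(function(x) marginal_payoff(c(9, -9.5, 1), x, x),
                  c(0, 10), tol = 1e-12)$root
  expect_equal(th, root, tolerance = 1e-9)
  expect_error(theta(c(1, 2, 1)), "D2 - D1")
})

test_that("utility reduces to the material payoff when normative weights vanish", {
  st <- agent_state(x = 0, y = 0.3, x_exp = 0.7, y_exp = 0.2)
  xg <- seq(0, 3, by = 1e-4)
  u <- utility(c(2, 2, 4), c(0, 0, 0, 0), st, xg)
  pi_only <- 2 * xg + 2 * 0.7 * xg - 4 * xg^2 / 2
  expect_equal(u, pi_only)
  # its argmax is the material best response (D0 + D1 x_exp)/D2
  expect_equal(xg[which.max(u)], (2 + 2 * 0.7) / 4, tolerance = 1e-4)
})

test_that("closed-form best response maximises the utility", {
  # pure authority regime: all D = 0, only A4 active
  st <- agent_state(x = 0, y = 0.1, x_exp = 0.2, y_exp = 0.3)
  expect_equal(
    best_response(c(0, 0, 0), c(0, 0, 0, 1), st, authority(G = 2)), 2)
  # worked heterogeneous case: numerator 12 / denominator 12
  st2 <- agent_state(x = 0, y = 0.5, x_exp = 1, y_exp = 0.5)
  br <- best_response(c(2, 2, 4), c(1, 1, 1, 1), st2, authority(G = 2))
  expect_equal(br, 1)
  u1 <- utility(c(2, 2, 4), c(1, 1, 1, 1), st2, c(0.9, 1, 1.1), authority(G = 2))
  expect_true(u1[2] > u1[1] && u1[2] > u1[3])
  # material optimum when normative terms are off
  g <- coordination_game(theta_pref = 1, c = 1, d = 0)
  expect_equal(
    best_response(payoff_coeffs(g, 2)[1, ], c(0, 0, 0, 0),
                  agent_state(0, 5, 3, 7)), 1)
  expect_error(best_response(c(1, 0, 0), c(0, 0, 0, 0), st), "concave")
})

test_that("best response matches dense grid-search maximisation", {
  set.seed(11)
  for (i in 1:200) {
    pc <- c(runif(1, 0, 3), runif(1, -3, 3), runif(1, 0.5, 3))
    A <- runif(4, 0.25, 1.5)
    st <- agent_state(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2),
                      runif(1, 0, 2))
    auth <- if (i %% 2 == 0) authority(runif(1, 0, 2)) else NULL
    xg <- seq(0, 15, by = 1e-4)
    br <- best_response(pc, A, st, auth)
    xstar <- xg[which.max(utility(pc, A, st, xg, auth))]
    expect_lt(abs(br - xstar), 1e-3)
  }
})

test_that("best response exposes the rescaled weighted-average coefficients", {
  st <- agent_state(0, 0.5, 1, 0.5)
  br <- best_response(c(2, 2, 4), c(1, 1, 1, 1), st, authority(2),
                      coefficients = TRUE)
  B <- attr(br, "B")
  expect_equal(unname(B[1, ]), c(2, 2, 2, 4, 2) / 12)
  # reconstructing the best response from the Bs
  expect_equal(B[1, "B0"] + B[1, "B1"] * 0.5 + B[1, "B2"] * 0.5 +
                 B[1, "B3"] * 1 + B[1, "B4"] * 2, as.numeric(br))
})

test_that("best response is monotone in the authority standard and the attitude", {
  set.seed(21)
  for (i in 1:50) {
    pc <- c(runif(1, 0, 3), runif(1, -2, 2), runif(1, 0.5, 3))
    A <- runif(4, 0.1, 2)
    st <- agent_state(0, runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
    g1 <- runif(1, 0, 1); g2 <- g1 + runif(1, 0, 2)
    expect_gte(best_response(pc, A, st, authority(g2)),
               best_response(pc, A, st, authority(g1)))
    st_hi <- st; st_hi[, "y"] <- st[, "y"] + runif(1, 0, 2)
    expect_gte(best_response(pc, A, st_hi), best_response(pc, A, st))
  }
})

test_that("belief updates follow the linear recurrences and clip at zero", {
  st <- agent_state(x = 2, y = 1, x_exp = 0.5, y_exp = 0.8)
  # zero coefficients: identity
  expect_equal(update_beliefs(rep(0, 9), st, X_obs = 3), st)
  # direct evaluation of the attitude row
  C <- c(0.2, 0.1, 0, 0, 0, 0, 0, 0, 0)
  out <- update_beliefs(C, st, X_obs = 0)
  expect_equal(unname(out[, "y"]), 1 + 0.2 * (2 - 1) + 0.1 * (0 - 1))
  expect_equal(out[, c("x", "x_exp", "y_exp")], st[, c("x", "x_exp", "y_exp")])
  # consensus fixed point: everything at theta
  th <- 0.7
  stc <- agent_state(th, th, th, th)
  Cfull <- c(0.2, 0.2, 0.1, 0.1, 0.2, 0.1, 0.2, 0.2, 0.1)
  expect_equal(update_beliefs(Cfull, stc, X_obs = th, authority(th)), stc)
  # clipping: large downward pull cannot push beliefs below zero
  stn <- agent_state(x = 0, y = 0.01, x_exp = 0.01, y_exp = 0.01)
  out2 <- update_beliefs(rep(1 / 3, 9), stn, X_obs = 0)
  expect_true(all(out2 >= 0))
  expect_error(update_beliefs(rep(0.5, 9), st, 1), "at most 1")
  expect_error(update_beliefs(rep(-0.1, 9), st, 1), "non-negative")
})

test_that("normalised channel weights sum to one and flag frozen rows", {
  w <- normalized_weights(c(0.2, 0.1, 0.1, 1 / 3, 1 / 3, 1 / 3, 0, 0, 0))
  expect_equal(w$alpha[1], 0.5)
  expect_equal(w$beta[1], 0.25)
  expect_equal(w$gamma[1], 0.25)
  expect_equal(w$alpha[2] + w$beta[2] + w$gamma[2], 1)
  expect_true(w$degenerate[3])
  expect_true(is.na(w$alpha[3]))
  # authority disabled: gamma = 0
  w2 <- normalized_weights(c(0.2, 0.1, 0, 0.2, 0.1, 0, 0.2, 0.1, 0))
  expect_equal(unname(w2$gamma), c(0, 0, 0))
})

test_that("consensus states are exact fixed points of action and belief updates", {
  # homogeneous theta, no authority: state at theta is invariant
  g <- homogeneous_group(n = 5, theta0 = 1)
  st <- agent_state(rep(1, 5), 1, 1, 1)
  expect_equal(best_response(g$pc, g$A, st, g$auth), rep(1, 5))
  expect_equal(update_beliefs(g$C, st, X_obs = rep(1, 5), g$auth), st)
  # all material coefficients zero, authority at G: state at G is invariant
  ga <- authority_only_group(n = 4, G = 2)
  stG <- agent_state(rep(2, 4), 2, 2, 2)
  expect_equal(best_response(ga$pc, ga$A, stG, ga$auth), rep(2, 4))
  expect_equal(update_beliefs(ga$C, stG, X_obs = rep(2, 4), ga$auth), stG)
})
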