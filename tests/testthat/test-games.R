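test_that("game coefficients reproduce the printed theta anchors", {
  gc <- coordination_game(theta_pref = 1, c = 1, d = 1)
  expect_equal(unname(payoff_coeffs(gc, 2)[1, ]), c(2, 2, 4))
  expect_equal(theta(payoff_coeffs(gc, 2))[1], 1)

  gp <- pgg_game(v = 1 / 40, c = 1, b = 40)
  expect_equal(unname(payoff_coeffs(gp, 40)[1, ]), c(1, 0, 1))
  expect_equal(theta(payoff_coeffs(gp, 40))[1], 1)

  gr <- cpr_game(c = 1, d = 1, b = 10)
  expect_equal(unname(payoff_coeffs(gr, 20)[1, ]), c(9, -9.5, 1))
  expect_equal(theta(payoff_coeffs(gr, 20))[1], 18 / 21)
})

test_that("theta matches the closed-form game formulas for random parameters", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    th <- runif(n, 0.2, 2); cc <- runif(n, 0.2, 2); dd <- runif(n, 0, 2)
    expect_equal(theta(payoff_coeffs(coordination_game(th, cc, dd), n)), th,
                 tolerance = 1e-12)
    v <- sample_broken_stick(n); b <- runif(1, 5, 50)
    expect_equal(theta(payoff_coeffs(pgg_game(v, cc, b), n)), v * b / cc,
                 tolerance = 1e-12)
    b2 <- runif(1, 5, 20); c2 <- runif(n, 0.2, 2); d2 <- runif(n, 0.5, 2)
    expect_equal(theta(payoff_coeffs(cpr_game(c2, d2, b2), n)),
                 2 * (b2 - c2) / (d2 * (n + 1)), tolerance = 1e-12)
  }
})

test_that("marginal payoff equals the numeric x-derivative of the game payoff", {
  # the central consistency check tying the linear-marginal coefficients
  # to the literal game payoffs
  set.seed(6)
  h <- 1e-6
  for (i in 1:20) {
    n <- sample(2:20, 1)
    games <- list(
      coordination_game(runif(n, 0.5, 1.5), runif(n, 0.5, 1.5),
                        runif(n, 0.5, 1.5)),
      pgg_game(sample_broken_stick(n), runif(n, 0.5, 1.5), runif(1, 10, 50)),
      cpr_game(runif(n, 0.2, 1), runif(n, 0.5, 1.5), runif(1, 5, 15)))
    for (g in games) {
      pc <- payoff_coeffs(g, n)
      for (x in c(0.3, 0.9, 1.7)) for (xe in c(0.2, 1.1)) {
        num_deriv <- (payoff_value(g, x + h, xe, n) -
                        payoff_value(g, x - h, xe, n)) / (2 * h)
        expect_equal(marginal_payoff(pc, x, xe), num_deriv, tolerance = 1e-5)
      }
    }
  }
})

test_that("literal payoffs evaluate the game formulas", {
  g <- coordination_game(theta_pref = 1, c = 1, d = 1, b = 1)
  expect_equal(payoff_value(g, x = 1, x_exp = 1, n = 2)[1], 1)
  gp <- pgg_game(v = 1 / 40, c = 1, b = 40)
  expect_equal(payoff_value(gp, x = 1, x_exp = 1, n = 40)[1], 39.5)
  gr <- cpr_game(c = 1, d = 1, b = 10)
  # no effort, no payoff (defined limit at zero predicted group effort)
  expect_equal(payoff_value(gr, x = 0, x_exp = 0, n = 20)[1], 0)
})

test_that("Nash baselines solve the simultaneous best-reply systems", {
  # PGG: Nash effort equals theta exactly
  gp <- pgg_game(v = 1 / 40, c = 1, b = 40)
  expect_equal(nash_baseline(gp, 40), rep(1, 40))
  # CPR identical agents: closed form 2(b-c)/(d(n+1))
  gr <- cpr_game(c = rep(1, 20), d = rep(1, 20), b = 10)
  expect_equal(nash_baseline(gr, 20), rep(18 / 21, 20), tolerance = 1e-12)
  # coordination without conformity costs: everyone plays their preference
  gc0 <- coordination_game(theta_pref = c(0.5, 1, 1.5), c = 1, d = 0)
  expect_equal(nash_baseline(gc0, 3), c(0.5, 1, 1.5))
  # heterogeneous cases: verify against simultaneous best-reply iteration
  set.seed(7)
  for (g in list(coordination_game(runif(6, 0.5, 1.5), runif(6, 0.5, 1.5),
                                   runif(6, 0.5, 1.5)),
                 cpr_game(runif(6, 0.2, 1), runif(6, 0.8, 1.2), 10))) {
    n <- 6
    pc <- payoff_coeffs(g, n)
    x <- rep(0.5, n)
    for (t in 1:5000) {
      X <- (sum(x) - x) / (n - 1)
      x_new <- pmax(0, (pc[, "D0"] + pc[, "D1"] * X) / pc[, "D2"])
      x <- 0.5 * x + 0.5 * x_new   # damped iteration
    }
    expect_equal(nash_baseline(g, n), x, tolerance = 1e-7)
    # complementarity holds at the reported equilibrium: active efforts have
    # zero marginal payoff, zero efforts non-positive marginal payoff
    xn <- nash_baseline(g, n)
    Xn <- (sum(xn) - xn) / (n - 1)
    foc <- marginal_payoff(pc, xn, Xn)
    expect_true(all(abs(foc[xn > 1e-9]) < 1e-9))
    expect_true(all(foc[xn <= 1e-9] < 1e-9))
  }
})

test_that("CPR social optimum and over-extraction ratio", {
  # b = 10, c = 1, d = 1, n = 20: per-capita optimum 0.45
  expect_equal(social_optimum_cpr(b = 10, d = 1, c = 1, n = 20), 0.45)
  nash <- nash_baseline(cpr_game(c = rep(1, 20), d = rep(1, 20), b = 10), 20)[1]
  expect_equal(nash / 0.45, 40 / 21, tolerance = 1e-12)
  # the identity nash * (n+1)/(2n) = x_opt holds for random parameters
  set.seed(8)
  for (i in 1:20) {
    b <- runif(1, 2, 20); cc <- runif(1, 0, b - 0.1); d <- runif(1, 0.1, 3)
    n <- sample(2:50, 1)
    nash <- 2 * (b - cc) / (d * (n + 1))
    expect_equal(nash * (n + 1) / (2 * n),
                 social_optimum_cpr(b, d, cc, n), tolerance = 1e-12)
  }
  # no externality with one agent; no surplus when b = c
  expect_equal(social_optimum_cpr(b = 10, d = 1, c = 1, n = 1) , 9)
  expect_equal(2 * (10 - 1) / (1 * (1 + 1)), 9)  # n = 1 Nash = optimum
  expect_equal(social_optimum_cpr(b = 1, d = 1, c = 1, n = 5), 0)
})

test_that("conformity ratio", {
  expect_equal(conformity_ratio(1, 1), 0.5)
  expect_equal(conformity_ratio(1, 0), 0)
  expect_equal(conformity_ratio(1, 3), 0.75)
  expect_error(conformity_ratio(0, 0), "undefined")
})
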