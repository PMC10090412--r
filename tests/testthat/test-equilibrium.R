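test_that("expected payoffs reproduce the textbook Hawk-Dove lines", {
  g <- hawk_dove_game()
  ev <- expected_payoffs(g, c(0, 5 / 12, 1))
  # p = 0: pure-hawk column
  expect_equal(ev$ev_other[1], -25)
  expect_equal(ev$ev_focal[1], 0)
  # at the mixed state both strategies earn the same 6.25
  expect_equal(ev$ev_focal[2], 6.25)
  expect_equal(ev$ev_other[2], 6.25)
  # printed migraine game at the worked point
  ev2 <- expected_payoffs(migraine_game_printed(migraine_params(0.3, 0.2)), 0.5)
  expect_equal(ev2$ev_focal, 1.0875)
  expect_equal(ev2$ev_other, 1.05)
  expect_error(expected_payoffs(g, -0.1), class = "sensgame_domain_error")
})

test_that("Hawk-Dove mixed equilibrium is 5/12 doves at payoff 6.25", {
  eq <- mixed_equilibrium(hawk_dove_game())
  expect_equal(eq$p_star, 5 / 12, tolerance = 1e-12)
  expect_equal(eq$payoff_at_eq, 6.25, tolerance = 1e-12)
  expect_true(eq$stable)
  expect_identical(eq$status, "interior")
  expect_lt(eq$residual, 1e-10)
})

test_that("population mean payoff matches the group-vs-equilibrium contrast", {
  g <- hawk_dove_game()
  expect_equal(population_mean_payoff(g, 1), 15)     # all doves
  expect_equal(population_mean_payoff(g, 0), -25)    # all hawks
  expect_equal(population_mean_payoff(g, 5 / 12), 6.25)
  # at any equilibrium the mean equals both strategies' payoff
  eq <- mixed_equilibrium(migraine_game_generalized(
    generalized_game(1.2, 1.1, 1.0, 0.9)))
  ev <- expected_payoffs(migraine_game_generalized(
    generalized_game(1.2, 1.1, 1.0, 0.9)), eq$p_star)
  expect_equal(population_mean_payoff(migraine_game_generalized(
    generalized_game(1.2, 1.1, 1.0, 0.9)), eq$p_star),
    ev$ev_focal, tolerance = 1e-9)
})

test_that("invasion payoffs use exact boundary evaluation", {
  g <- hawk_dove_game()
  expect_equal(invasion_payoff(g, "hawk", resident_p = 1), 50)
  expect_equal(invasion_payoff(g, "dove", resident_p = 0), 0)
  eq <- mixed_equilibrium(g)
  expect_equal(invasion_payoff(g, "dove", eq$p_star), eq$payoff_at_eq,
               tolerance = 1e-9)
  expect_equal(invasion_payoff(g, "hawk", eq$p_star), eq$payoff_at_eq,
               tolerance = 1e-9)
  expect_error(invasion_payoff(g, "pigeon", 0.5),
               class = "sensgame_validation_error")
})

test_that("closed form agrees with the scan oracle on random constant games", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:1000) {
    g <- generate_random_scenario(form = "migraine_general")
    game <- migraine_game_generalized(g)
    eq <- mixed_equilibrium(game, method = "analytic")
    scanned <- scan_root_oracle(game)
    expect_length(scanned, 1)
    expect_equal(eq$p_star, scanned, tolerance = 1e-9)
    expect_equal(eq$p_star, closed_form_p_star(g), tolerance = 1e-9)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 1000L)
})

test_that("every valid generalized game has a unique stable interior ESS", {
  set.seed(202)
  for (i in 1:200) {
    g <- generate_random_scenario(form = "migraine_general")
    eq <- mixed_equilibrium(migraine_game_generalized(g))
    expect_identical(eq$status, "interior")
    expect_identical(nrow(eq$roots), 1L)
    expect_true(eq$stable)
    expect_gt(eq$p_star, 0)
    expect_lt(eq$p_star, 1)
  }
})

test_that("worked generalized example solves to p* = 1/2", {
  eq <- mixed_equilibrium(migraine_game_generalized(
    generalized_game(1.2, 1.1, 1.0, 0.9)))
  expect_equal(eq$p_star, 0.5, tolerance = 1e-12)
  expect_true(eq$stable)
})

test_that("degenerate and boundary games are reported as such", {
  flat <- static_game("a", "b", c(ff = 1, fo = 1, of = 1, oo = 1))
  expect_identical(mixed_equilibrium(flat)$status, "degenerate")
  # printed migraine game: migraineur payoff dominates for p < 1,
  # so the only rest point is the all-migraineur boundary
  eq <- mixed_equilibrium(migraine_game_printed(migraine_params(0.3, 0.2)))
  expect_identical(eq$status, "boundary")
  expect_equal(eq$p_star, 1)
  expect_true(eq$stable)
})

test_that("stability classification follows the sign pattern of the gap", {
  g <- hawk_dove_game()
  expect_identical(classify_stability(g, 5 / 12), "stable")
  # anti-ordered game: gap rises through the interior root -> unstable
  anti <- static_game("m", "n", c(ff = 1.2, fo = 0.9, of = 1.0, oo = 1.1))
  eqa <- mixed_equilibrium(anti)
  expect_identical(eqa$status, "interior")
  expect_false(eqa$stable)
  expect_identical(classify_stability(anti, eqa$p_star), "unstable")
  # boundary p = 0 of the ordered game: migraineurs invade (d_m > d_n)
  ordered <- migraine_game_generalized(generalized_game(1.2, 1.1, 1.0, 0.9))
  expect_identical(classify_stability(ordered, 0), "unstable")
  expect_identical(classify_stability(ordered, 1), "unstable")
})

test_that("the non-migraineur payoff identity is exact, the migraineur one is not", {
  set.seed(303)
  # 10,000 random (c_m, c_n, p) triples: 200 parameter draws x 50 p draws
  pr <- generate_random_scenario(form = "migraine_printed", n = 200)
  d <- purrr::map_dfr(pr, function(par) {
    verify_paper_identity(par, runif(50))
  })
  expect_identical(nrow(d), 10000L)
  expect_lt(max(abs(d$residual_n)), 1e-12)
  # the migraineur residual follows its symbolic closed form ...
  pred_m <- (1 - d$p)^2 * (1 + d$p) * (d$c_m - d$c_n)
  expect_equal(d$residual_m, pred_m, tolerance = 1e-10)
  # ... and is genuinely non-zero away from p = 1
  expect_gt(min(d$residual_m[d$p < 0.9]), 0)
})

test_that("identity residuals vanish in the degenerate directions", {
  pr <- migraine_params(0.2 + 1e-13, 0.2)  # vanishing cost gap
  d <- verify_paper_identity(pr, c(0.2, 0.7))
  expect_equal(d$residual_m, rep(0, 2), tolerance = 1e-12)
  expect_equal(d$residual_n, rep(0, 2), tolerance = 1e-12)
  d1 <- verify_paper_identity(migraine_params(0.3, 0.2), 1)
  expect_equal(d1$residual_m, 0, tolerance = 1e-12)
  # worked point
  d2 <- verify_paper_identity(migraine_params(0.3, 0.2), 0.5)
  expect_equal(d2$residual_m, 0.0375)
  expect_equal(d2$residual_n, 0)
})

test_that("tidy and glance expose the equilibrium result", {
  eq <- mixed_equilibrium(hawk_dove_game())
  td <- generics::tidy(eq)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("p_star", "payoff", "stable", "method", "residual"))
  gl <- generics::glance(eq)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$p_star, 5 / 12, tolerance = 1e-12)
})
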