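spec_alt <- game_spec("alternating")
spec_sim <- game_spec("simultaneous")

test_that("transition matrices follow the turn structure and conserve probability", {
  alld <- named_strategy("ALLD"); tft <- named_strategy("TFT")
  M <- transition_matrix(alld, alld, "alternating")
  expect_equal(unname(M), matrix(rep(c(0, 0, 0, 1), each = 4), 4, 4))
  # from DC, a TFT player 1 repays C, then TFT player 2 reciprocates: CC
  M <- transition_matrix(tft, tft, "alternating")
  expect_equal(unname(M["DC", ]), c(1, 0, 0, 0))
  set.seed(11)
  for (i in 1:20) {
    p <- strategy(runif(4)); q <- strategy(runif(4))
    for (md in c("alternating", "simultaneous"))
      expect_equal(rowSums(transition_matrix(p, q, md)), rep(1, 4),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(transition_matrix(c(1.5, 0, 0, 0), alld, "alternating"))
})

test_that("TFT self-play has 2 invariant sets alternating, 3 simultaneous", {
  tft <- named_strategy("TFT")
  expect_length(closed_classes(transition_matrix(tft, tft, "alternating")), 2)
  expect_length(closed_classes(transition_matrix(tft, tft, "simultaneous")), 3)
})

test_that("stationary outcomes match the defection and cooperation anchors", {
  alld <- named_strategy("ALLD")
  o <- stationary(alld, alld, spec_alt)
  expect_equal(as.numeric(o$v), c(0, 0, 0, 1))
  expect_equal(c(o$pi1, o$pi2), c(0, 0))
  tft <- named_strategy("TFT")
  o <- stationary(tft, tft, spec_alt)     # degenerate chain, first round (C,C)
  expect_equal(as.numeric(o$v), c(1, 0, 0, 0))
  expect_equal(c(o$pi1, o$pi2), rep(spec_alt$b - spec_alt$c, 2))
  # starting from mutual defection, TFT self-play locks into defection
  o <- stationary(tft, tft, game_spec(first_round = c("D", "D")))
  expect_equal(as.numeric(o$v), c(0, 0, 0, 1))
})

test_that("stationary distribution matches a power-iteration oracle", {
  set.seed(21)
  spec <- game_spec("alternating", eps = 0.02)
  for (i in 1:20) {
    p <- strategy(runif(4)); q <- strategy(runif(4))
    o <- stationary(p, q, spec)
    M <- transition_matrix(with_errors(p, 0.02), with_errors(q, 0.02),
                           "alternating")
    expect_equal(as.numeric(o$v), power_iteration_stationary(M),
                 tolerance = 1e-8)
  }
})

test_that("outcome vectors are probability distributions with the payoff identity", {
  set.seed(31)
  for (i in 1:30) {
    # mix fully stochastic and deterministic corners to hit degenerate chains
    p <- if (i %% 3 == 0) strategy(rbinom(4, 1, 0.5)) else strategy(runif(4))
    q <- if (i %% 4 == 0) strategy(rbinom(4, 1, 0.5)) else strategy(runif(4))
    for (spec in list(spec_alt, spec_sim, game_spec(eps = 0.02))) {
      o <- stationary(p, q, spec)
      expect_equal(sum(o$v), 1, tolerance = 1e-12)
      expect_true(all(o$v >= -1e-12))
      expect_equal(o$pi1 + o$pi2, (spec$b - spec$c) * (o$rho1 + o$rho2),
                   tolerance = 1e-10)
      expect_true(o$pi1 >= -spec$c - 1e-10 && o$pi1 <= spec$b + 1e-10)
    }
  }
})

test_that("alternating payoffs are invariant to how moves are grouped into rounds", {
  # shifting the round grouping by one move swaps who "opens" a round, i.e.
  # evaluates the pair with roles exchanged
  set.seed(41)
  for (i in 1:15) {
    p <- strategy(runif(4)); q <- strategy(runif(4))
    o12 <- stationary(p, q, spec_alt)
    o21 <- stationary(q, p, spec_alt)
    expect_equal(o12$pi1, o21$pi2, tolerance = 1e-9)
    expect_equal(o12$rho1, o21$rho2, tolerance = 1e-9)
  }
})

test_that("discounted payoffs use the normalized discounted visit distribution", {
  alld <- named_strategy("ALLD")
  for (d in c(0.3, 0.96)) {
    o <- payoffs_discounted(alld, alld, game_spec(delta = d))
    expect_equal(c(o$pi1, o$pi2), c(0, 0))
  }
  # delta -> 1 recovers the undiscounted stationary payoffs
  set.seed(51)
  p <- strategy(runif(4)); q <- strategy(runif(4))
  o_inf <- stationary(p, q, spec_alt)
  gaps <- sapply(c(0.9, 0.99, 0.999), function(d)
    abs(payoffs_discounted(p, q, game_spec(delta = d))$pi1 - o_inf$pi1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
  expect_error(payoffs_discounted(p, q, spec_alt), "stationary")
  expect_error(stationary(p, q, game_spec(delta = 0.9)), "payoffs_discounted")
})

test_that("a game with delta = 0.96 lasts 25 rounds on average", {
  expect_equal(expected_rounds(game_spec(delta = 0.96)), 25, tolerance = 1e-10)
  expect_equal(expected_rounds(game_spec(delta = 0.5),
                               named_strategy("TFT"), named_strategy("WSLS")),
               2, tolerance = 1e-10)
})

test_that("irregular alternation reduces to strict alternation at s = 1", {
  set.seed(61)
  for (eps in c(0, 0.02)) {
    p <- strategy(runif(4)); q <- strategy(runif(4))
    spec <- game_spec(eps = eps, s = 1)
    o1 <- payoffs_switching(p, q, spec)
    o2 <- stationary(p, q, game_spec(eps = eps))
    expect_equal(o1$pi1, o2$pi1, tolerance = 1e-10)
    expect_equal(o1$pi2, o2$pi2, tolerance = 1e-10)
    expect_equal(o1$rho1, o2$rho1, tolerance = 1e-10)
  }
})

test_that("with a random move order, ALLC pays -c per round and ALLD collects b", {
  o <- payoffs_switching(named_strategy("ALLC"), named_strategy("ALLD"),
                         game_spec(s = 0.5))
  expect_equal(o$pi1, -1)
  expect_equal(o$pi2, 3)
})

test_that("switching-chain frequencies match a direct move simulation", {
  set.seed(71)
  spec <- game_spec(eps = 0.02, s = 0.7)
  p <- runif(4); q <- runif(4)
  o <- payoffs_switching(strategy(p), strategy(q), spec)
  sim <- simulate_switching(p, q, spec, n_moves = 2e5)
  expect_lt(abs(o$rho1 - sim$rho1), 3 * sqrt(0.25 / sim$n1))
  expect_lt(abs(o$rho2 - sim$rho2), 3 * sqrt(0.25 / sim$n2))
  expect_error(payoffs_switching(strategy(p), strategy(q),
                                 game_spec("simultaneous")), "alternating")
  expect_error(game_spec(s = 0.3), "1/2")
})

test_that("cooperation rates read off the outcome distribution", {
  o <- stationary(named_strategy("TFT"), named_strategy("TFT"), spec_alt)
  expect_equal(cooperation_rate(o, 1), 1)
  expect_equal(cooperation_rate(o, 2), 1)
  o <- stationary(named_strategy("ALLC"), named_strategy("ALLD"), spec_alt)
  expect_equal(cooperation_rate(o, 1), 1)
  expect_equal(cooperation_rate(o, 2), 0)
  spec <- game_spec(eps = 0.02)
  g <- gtft(spec)
  o <- stationary(g, g, spec)
  expect_gt(cooperation_rate(o, 1), 0.9)
  expect_equal(cooperation_rate(o, 1), cooperation_rate(o, 2))
})

test_that("game_spec validates its parameter ranges", {
  expect_error(game_spec(b = 1, c = 1), "b > c")
  expect_error(game_spec(eps = 0.7), "eps")
  expect_error(game_spec(delta = 0), "delta")
  expect_error(game_spec("simultaneous", s = 0.7), "alternating")
})
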