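spec0 <- game_spec("alternating", b = 3, c = 1, eps = 0)
spec02 <- game_spec("alternating", b = 3, c = 1, eps = 0.02)

test_that("the reactive reduction preserves payoffs in the alternating game only", {
  # a reactive strategy is its own reduction
  r <- reactive_strategy(0.7, 0.2)
  set.seed(101)
  red <- reactive_reduction(as_memory1(r), strategy(runif(4)), spec0)
  expect_equal(c(red$rC, red$rD), c(0.7, 0.2), tolerance = 1e-12)
  # payoff preservation for random memory-one pairs
  worst <- 0
  for (i in 1:50) {
    p <- strategy(runif(4)); q <- strategy(runif(4))
    red <- reactive_reduction(p, q, spec0)
    o1 <- stationary(p, q, spec0)
    o2 <- stationary(as_memory1(red), q, spec0)
    worst <- max(worst, abs(o1$pi1 - o2$pi1), abs(o1$pi2 - o2$pi2))
  }
  expect_lt(worst, 1e-9)
  # the same construction fails in the simultaneous game for some pair
  sim <- game_spec("simultaneous")
  viol <- 0
  for (i in 1:50) {
    p <- unclass(strategy(runif(4))); q <- strategy(runif(4))
    v <- stationary(strategy(p), q, sim)$v
    rC <- (v[[1]] * p[1] + v[[3]] * p[3]) / (v[[1]] + v[[3]])
    rD <- (v[[2]] * p[2] + v[[4]] * p[4]) / (v[[2]] + v[[4]])
    o1 <- stationary(strategy(p), q, sim)
    o2 <- stationary(strategy(c(rC, rD, rC, rD)), q, sim)
    viol <- max(viol, abs(o1$pi1 - o2$pi1))
  }
  expect_gt(viol, 1e-3)
  expect_error(reactive_reduction(strategy(runif(4)), strategy(runif(4)), sim),
               "alternating")
})

test_that("four-deviation Nash verdicts match the known equilibria", {
  expect_true(nash_check(named_strategy("ALLD"), spec0)$is_nash)
  expect_true(nash_check(named_strategy("ALLD"), spec02)$is_nash)
  expect_true(nash_check(named_strategy("WSLS"), spec0)$is_nash)   # b >= 2c
  expect_false(nash_check(named_strategy("WSLS"),
                          game_spec(b = 1.5))$is_nash)
  expect_true(nash_check(gtft(spec02), spec02)$is_nash)
  expect_true(nash_check(sfbf(spec02), spec02)$is_nash)
  # with errors, no deterministic strategy sustains cooperation
  expect_false(nash_check(named_strategy("WSLS"), spec02)$is_nash)
  expect_false(nash_check(named_strategy("FBF"), spec02)$is_nash)
})

test_that("partner conditions without errors match the polyhedron", {
  expect_true(as.logical(is_partner(named_strategy("WSLS"), spec0)))
  expect_true(as.logical(is_partner(named_strategy("FBF"), spec0)))
  expect_true(as.logical(is_partner(named_strategy("TFT"), spec0)))
  expect_true(as.logical(is_partner(named_strategy("GRIM"), spec0)))
  expect_false(as.logical(is_partner(named_strategy("WSLS"),
                                     game_spec(b = 1.5))))
  # ALLC violates the exploitation bound qCD <= 1 - c/(b-c) qDD outright
  allc <- is_partner(named_strategy("ALLC"), spec0)
  expect_false(as.logical(allc))
  expect_lt(attr(allc, "slack")[["vs_ALLD"]], 0)
  expect_error(is_partner(named_strategy("WSLS"), spec02), "error")
})

test_that("defector conditions accept ALLD and GRIM but not TFT", {
  expect_true(as.logical(is_defector(named_strategy("ALLD"), spec0)))
  expect_true(as.logical(is_defector(named_strategy("GRIM"), spec0)))
  expect_false(as.logical(is_defector(named_strategy("TFT"), spec0)))
  expect_false(as.logical(is_defector(named_strategy("ALLC"), spec0)))
})

test_that("equalizers fix the co-player's payoff", {
  rep_eq <- is_equalizer(named_strategy("Repeat"), spec0)
  expect_true(as.logical(rep_eq))
  expect_equal(unname(attr(rep_eq, "required")), c(1, 0))
  expect_false(as.logical(is_equalizer(named_strategy("ALLD"), spec0)))
  # constructed equalizer: pick qCC, qDD, derive qCD, qDC from the identity
  set.seed(111)
  qCC <- 0.9; qDD <- 0.2
  b <- spec0$b; cc <- spec0$c
  qe <- strategy(qCC, (b * qCC - cc * (1 + qDD)) / (b - cc),
                 (b * qDD + cc * (1 - qCC)) / (b - cc), qDD)
  expect_true(as.logical(is_equalizer(qe, spec0)))
  pays <- sapply(1:50, function(i)
    stationary(strategy(runif(4)), qe, spec0)$pi1)
  expect_lt(sd(pays), 1e-9)
  # an equalizer is a Nash equilibrium: every deviation earns the same
  expect_true(nash_check(qe, spec0)$is_nash)
})

test_that("with errors the partner set is the GTFT-SFBF segment", {
  g <- gtft(spec02); f <- sfbf(spec02)
  expect_equal(as.numeric(g), c(1, 1 - 1 / (0.96 * 3), 1, 1 - 1 / (0.96 * 3)))
  expect_equal(as.numeric(f), c(1, 0, 1, 1.88 / (0.96 * 3.02)),
               tolerance = 1e-12)
  expect_equal(as.numeric(gtft(spec0)), c(1, 2 / 3, 1, 2 / 3))
  expect_true(as.logical(partner_with_errors(g, spec02)))
  expect_true(as.logical(partner_with_errors(f, spec02)))
  # GTFT sits at the maximal allowed qCD, and its qDD solves the equality
  sl <- attr(partner_with_errors(g, spec02), "slack")
  expect_equal(unname(sl[["qCD_max"]]), 0, tolerance = 1e-12)
  # random convex combinations stay partners and Nash
  set.seed(121)
  for (i in 1:10) {
    a <- runif(1)
    qm <- strategy(a * as.numeric(g) + (1 - a) * as.numeric(f))
    expect_true(as.logical(partner_with_errors(qm, spec02)))
    expect_true(nash_check(qm, spec02)$is_nash)
  }
  # perturbing qDD off the segment breaks the partner property
  off <- strategy(1, 0, 1, min(1, as.numeric(f)[4] + 0.05))
  expect_false(as.logical(partner_with_errors(off, spec02)))
})

test_that("partners cease to exist when errors are too frequent", {
  # bound: eps >= (1/2)(1 - c/b) = 1/3 at b = 3, c = 1
  spec_hi <- game_spec(b = 3, c = 1, eps = 0.4)
  expect_error(gtft(spec_hi), "eps")
  expect_error(sfbf(spec_hi), "eps")
  pw <- partner_with_errors(strategy(1, 0, 1, 0.5), spec_hi)
  expect_false(as.logical(pw))
  expect_false(attr(pw, "exists"))
  set.seed(131)
  for (i in 1:20)
    expect_false(as.logical(partner_with_errors(strategy(runif(4)), spec_hi)))
})

test_that("classification labels partners, defectors, equalizers and none", {
  expect_identical(classify_strategy(named_strategy("WSLS"), spec0)$class_label,
                   "partner")
  expect_identical(classify_strategy(named_strategy("ALLD"), spec0)$class_label,
                   "defector")
  b <- spec0$b; cc <- spec0$c
  qe <- strategy(0.9, (b * 0.9 - cc * 1.2) / (b - cc),
                 (b * 0.2 + cc * 0.1) / (b - cc), 0.2)
  expect_identical(classify_strategy(qe, spec0)$class_label, "equalizer")
  set.seed(141)
  rnd <- classify_strategy(strategy(0.5, 0.6, 0.4, 0.3), spec0)
  expect_false(rnd$is_nash)
  expect_identical(rnd$class_label, "none")
  # with errors
  expect_identical(classify_strategy(sfbf(spec02), spec02)$class_label,
                   "partner")
  expect_identical(classify_strategy(named_strategy("ALLD"), spec02)$class_label,
                   "defector")
})

test_that("full reciprocators invade partners neutrally; ALLD cannot", {
  set.seed(151)
  for (q in list(sfbf(spec02), gtft(spec02))) {
    ni <- neutral_invaders(q, spec02, n = 8)
    expect_true(all(abs(ni$gap) < 1e-9))
  }
  alld_pay <- stationary(named_strategy("ALLD"), sfbf(spec02), spec02)$pi1
  self_pay <- stationary(sfbf(spec02), sfbf(spec02), spec02)$pi1
  expect_lt(alld_pay, self_pay - 0.1)
})

test_that("the four extreme deviations find the best memory-one response", {
  set.seed(161)
  for (eps in c(0, 0.02)) {
    spec <- game_spec(eps = eps)
    for (i in 1:8) {
      q <- strategy(runif(4))
      rec <- nash_check(q, spec)
      srch <- best_response_search(q, spec, n = 300)
      expect_lt(srch$payoff - max(rec$deviation_payoffs), 1e-6)
    }
  }
})

test_that("every sampled Nash strategy is a partner, defector or equalizer", {
  set.seed(171)
  b <- spec0$b; cc <- spec0$c
  make_partner <- function() {
    qDD <- runif(1); qDC <- runif(1)
    qCD <- runif(1) * min(1 - cc / (b - cc) * qDD, 1 - cc / b * qDC)
    c(1, qCD, qDC, qDD)
  }
  make_defector <- function() {
    qCD <- runif(1); qCC <- runif(1)
    qDC <- runif(1) * min(cc / b * (1 - qCD), cc / (b - cc) * (1 - qCC))
    c(qCC, qCD, qDC, 0)
  }
  make_equalizer <- function() {
    repeat {
      qCC <- runif(1); qDD <- runif(1)
      qCD <- (b * qCC - cc * (1 + qDD)) / (b - cc)
      qDC <- (b * qDD + cc * (1 - qCC)) / (b - cc)
      if (qCD >= 0 && qCD <= 1 && qDC >= 0 && qDC <= 1)
        return(c(qCC, qCD, qDC, qDD))
    }
  }
  samples <- c(replicate(15, make_partner(), simplify = FALSE),
               replicate(15, make_defector(), simplify = FALSE),
               replicate(10, make_equalizer(), simplify = FALSE),
               replicate(40, runif(4), simplify = FALSE))
  for (qq in samples) {
    q <- strategy(qq)
    in_class <- as.logical(is_partner(q, spec0, tol = 1e-9)) ||
      as.logical(is_defector(q, spec0, tol = 1e-9)) ||
      as.logical(is_equalizer(q, spec0, tol = 1e-7))
    expect_identical(nash_check(q, spec0)$is_nash, in_class,
                     label = paste(round(qq, 3), collapse = ","))
  }
})

test_that("no Nash strategy concentrates self-play on the CD/DC cycle", {
  set.seed(181)
  qs <- c(list(unclass(named_strategy("WSLS")), unclass(named_strategy("ALLD")),
               unclass(named_strategy("TFT")), unclass(named_strategy("GRIM"))),
          replicate(30, runif(4), simplify = FALSE))
  for (qq in qs) {
    q <- strategy(qq)
    if (nash_check(q, spec0)$is_nash) {
      v <- stationary(q, q, spec0)$v
      expect_lt(v[["CD"]] + v[["DC"]], 0.5)
    }
  }
})
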