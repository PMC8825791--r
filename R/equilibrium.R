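# Nash machinery for the alternating donation game: the reactive reduction,
# the four-deviation equilibrium recipe, and the closed-form partner /
# defector / equalizer characterizations with and without errors.
#
# A memory-one strategy q is a Nash equilibrium when no memory-one deviation
# p earns more against q than q earns against itself.  For alternating
# games this reduces to checking the four extreme reactive deviations
# ALLD, ALLC, TFT and ATFT.

NASH_TOL <- 1e-9

#' Reactive strategy equivalent to a memory-one strategy (alternating game)
#'
#' Against a fixed memory-one co-player `q` in the alternating game, any
#' memory-one strategy `p` can be replaced by a reactive strategy — a
#' stationary-distribution-weighted average of `p`'s entries conditioned on
#' the co-player's last action — without changing the outcome distribution
#' or either payoff:
#' `rC = (vCC pCC + vDC pDC) / (vCC + vDC)`,
#' `rD = (vCD pCD + vDD pDD) / (vCD + vDD)`.
#' This is specific to alternating moves; the same construction in the
#' simultaneous game does not preserve payoffs in general.
#'
#' @param p,q Memory-one strategies of players 1 and 2.
#' @param spec An alternating [game_spec()].
#' @return A `"reactive"` strategy; attribute `"unconstrained"` names any
#'   entry whose conditioning event has zero stationary mass (that entry is
#'   set to the plain average of the two contributing probabilities).
#' @export
reactive_reduction <- function(p, q, spec = game_spec()) {
  if (spec$mode != "alternating")
    stop("the reactive reduction is defined for the alternating game")
  p <- unclass(as_memory1(p))
  out <- stationary(p, q, spec)
  v <- out$v
  unconstrained <- character(0)
  wC <- v[[1]] + v[[3]]
  rC <- if (wC > 0) (v[[1]] * p[1] + v[[3]] * p[3]) / wC
        else { unconstrained <- c(unconstrained, "rC"); (p[1] + p[3]) / 2 }
  wD <- v[[2]] + v[[4]]
  rD <- if (wD > 0) (v[[2]] * p[2] + v[[4]] * p[4]) / wD
        else { unconstrained <- c(unconstrained, "rD"); (p[2] + p[4]) / 2 }
  r <- reactive_strategy(min(max(rC, 0), 1), min(max(rD, 0), 1))
  attr(r, "unconstrained") <- unconstrained
  r
}

#' Four-deviation Nash check
#'
#' Tests whether `q` is a Nash equilibrium among memory-one strategies by
#' comparing its self-payoff with the payoff of the four extreme reactive
#' deviations ALLD, ALLC, TFT and ATFT (sufficient in the alternating
#' game). Deviations are passed through the same error transform as the
#' resident; degenerate chains are resolved through `spec$first_round`.
#'
#' @param q A memory-one strategy.
#' @param spec A [game_spec()].
#' @param tol Payoff tolerance for the weak Nash inequality.
#' @return A list of class `"equilibrium_report"`: `is_nash`,
#'   `self_payoff`, `deviation_payoffs` (named), `best_deviation` and its
#'   payoff.
#' @export
nash_check <- function(q, spec = game_spec(), tol = NASH_TOL) {
  q <- unname(unclass(as_memory1(q)))
  self <- .pay(q, q, spec)[1]
  devs <- c("ALLD", "ALLC", "TFT", "ATFT")
  payoff <- vapply(devs, function(nm)
    .pay(unclass(named_strategy(nm)), q, spec)[1], numeric(1))
  best <- which.max(payoff)
  structure(list(is_nash = payoff[[best]] <= self + tol,
                 self_payoff = self,
                 deviation_payoffs = payoff,
                 best_deviation = devs[best],
                 best_deviation_payoff = payoff[[best]],
                 class_label = NA_character_,
                 binding_constraints = NULL,
                 spec = spec),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Nash: %s (self payoff %.6f)\n",
              if (x$is_nash) "yes" else "no", x$self_payoff))
  cat(sprintf("best deviation: %s with payoff %.6f\n",
              x$best_deviation, x$best_deviation_payoff))
  if (!is.na(x$class_label)) cat("class:", x$class_label, "\n")
  invisible(x)
}

# Closed-form conditions (no errors). Each returns verdict + slack values;
# nonnegative slack means the condition holds.

#' Partner conditions without errors
#'
#' A strategy is a *partner* — fully cooperative against itself and a Nash
#' equilibrium — exactly when `qCC = 1`,
#' `qCD <= 1 - (c/(b-c)) qDD` and `qCD <= 1 - (c/b) qDC`.
#'
#' @param q A memory-one strategy.
#' @param spec A [game_spec()] with `eps = 0`.
#' @param tol Tolerance for the `qCC = 1` equality and the inequalities.
#' @return Logical verdict with attribute `"slack"` (named numeric; the
#'   equality slack is `-(1 - qCC)`).
#' @export
is_partner <- function(q, spec = game_spec(), tol = 1e-12) {
  if (spec$eps > 0)
    stop("is_partner() is the error-free characterization; see partner_with_errors()")
  q <- unname(unclass(as_memory1(q)))
  b <- spec$b; cc <- spec$c
  slack <- c(qCC_eq = -(1 - q[1]),
             vs_ALLD = (1 - cc / (b - cc) * q[4]) - q[2],
             vs_ATFT = (1 - cc / b * q[3]) - q[2])
  ok <- abs(q[1] - 1) <= tol && slack[2] >= -tol && slack[3] >= -tol
  structure(ok, slack = slack)
}

#' Defector conditions without errors
#'
#' A strategy is a *defector* — mutually defecting against itself and a
#' Nash equilibrium — exactly when `qDD = 0`,
#' `qDC <= (c/b)(1 - qCD)` and `qDC <= (c/(b-c))(1 - qCC)`.
#'
#' @inheritParams is_partner
#' @return Logical verdict with attribute `"slack"`.
#' @export
is_defector <- function(q, spec = game_spec(), tol = 1e-12) {
  if (spec$eps > 0)
    stop("is_defector() is the error-free characterization")
  q <- unname(unclass(as_memory1(q)))
  b <- spec$b; cc <- spec$c
  slack <- c(qDD_eq = -q[4],
             cond2 = cc / b * (1 - q[2]) - q[3],
             cond3 = cc / (b - cc) * (1 - q[1]) - q[3])
  ok <- abs(q[4]) <= tol && slack[2] >= -tol && slack[3] >= -tol
  structure(ok, slack = slack)
}

#' Equalizer conditions without errors
#'
#' An *equalizer* unilaterally fixes the co-player's payoff. In the
#' alternating game these are the strategies with
#' `qCD = (b qCC - c (1 + qDD)) / (b - c)` and
#' `qDC = (b qDD + c (1 - qCC)) / (b - c)`.
#'
#' @inheritParams is_partner
#' @param tol Tolerance for the two equalities.
#' @return Logical verdict with attributes `"required"` (the two computed
#'   right-hand sides), `"feasible"` (whether they lie in `[0, 1]`), and
#'   `"enforced_payoff"` (the constant co-player payoff, measured against a
#'   probe opponent, when the verdict is `TRUE`).
#' @export
is_equalizer <- function(q, spec = game_spec(), tol = 1e-9) {
  if (spec$eps > 0)
    stop("is_equalizer() is the error-free characterization")
  q <- unname(unclass(as_memory1(q)))
  b <- spec$b; cc <- spec$c
  req <- c(qCD = (b * q[1] - cc * (1 + q[4])) / (b - cc),
           qDC = (b * q[4] + cc * (1 - q[1])) / (b - cc))
  feasible <- all(req >= -tol & req <= 1 + tol)
  ok <- feasible && abs(q[2] - req[1]) <= tol && abs(q[3] - req[2]) <= tol
  enforced <- NA_real_
  if (ok) enforced <- .pay(c(0.3, 0.8, 0.6, 0.1), q, spec)[1]
  structure(ok, required = req, feasible = feasible,
            enforced_payoff = enforced)
}

#' Partner conditions with errors
#'
#' With error rate `0 < eps < 1/2` the partner polyhedron degenerates to a
#' line segment: `qCC = qDC = 1`, `qCD <= 1 - c / ((1 - 2 eps) b)`, and
#' `qDD = ((1 - 2 eps)(b + eps c qCD) - c) / ((1 - 2 eps)(b + eps c))`.
#' Partners exist only when `eps < (1/2)(1 - c/b)`.
#'
#' @param q A memory-one strategy.
#' @param spec A [game_spec()] with `eps > 0`.
#' @param tol Tolerance for the equalities.
#' @return Logical verdict with attribute `"slack"` (named numeric) and
#'   `"exists"` (whether any partner exists at this error rate).
#' @export
partner_with_errors <- function(q, spec, tol = 1e-9) {
  e <- spec$eps
  if (e <= 0 || e >= 0.5)
    stop("partner_with_errors() needs 0 < eps < 1/2; see is_partner() for eps = 0")
  q <- unname(unclass(as_memory1(q)))
  b <- spec$b; cc <- spec$c
  exists <- e < 0.5 * (1 - cc / b)
  qCD_max <- 1 - cc / ((1 - 2 * e) * b)
  qDD_req <- ((1 - 2 * e) * (b + e * cc * q[2]) - cc) /
             ((1 - 2 * e) * (b + e * cc))
  slack <- c(qCC_eq = -(1 - q[1]),
             qDC_eq = -(1 - q[3]),
             qCD_max = qCD_max - q[2],
             qDD_eq = -abs(q[4] - qDD_req))
  ok <- exists &&
    abs(q[1] - 1) <= tol && abs(q[3] - 1) <= tol &&
    slack[3] >= -tol && abs(q[4] - qDD_req) <= tol
  structure(ok, slack = slack, exists = exists)
}

#' Generous Tit-for-Tat and Stochastic Firm-but-Fair
#'
#' The two endpoints of the partner segment in the alternating game with
#' errors: `GTFT = (1, g, 1, g)` with `g = 1 - c/((1 - 2 eps) b)`, and
#' `SFBF = (1, 0, 1, f)` with
#' `f = ((1 - 2 eps) b - c) / ((1 - 2 eps)(b + eps c))`.
#' Both are partners whenever `eps < (1/2)(1 - c/b)`.
#'
#' @param spec A [game_spec()]; needs `eps` below the partner existence
#'   bound.
#' @return A `"memory1"` strategy.
#' @export
gtft <- function(spec = game_spec()) {
  g <- 1 - spec$c / ((1 - 2 * spec$eps) * spec$b)
  if (g < 0 || g > 1)
    stop("no GTFT partner exists at these parameters (eps too large)")
  strategy(1, g, 1, g)
}

#' @rdname gtft
#' @export
sfbf <- function(spec = game_spec()) {
  f <- ((1 - 2 * spec$eps) * spec$b - spec$c) /
       ((1 - 2 * spec$eps) * (spec$b + spec$eps * spec$c))
  if (f < 0 || f > 1)
    stop("no SFBF partner exists at these parameters (eps too large)")
  strategy(1, 0, 1, f)
}

#' Classify a strategy as partner, defector, equalizer or none
#'
#' Runs the four-deviation [nash_check()]; when the strategy is a Nash
#' equilibrium, assigns its class. Without errors the closed forms
#' ([is_partner()], [is_defector()], [is_equalizer()]) are used; with
#' errors, partners are identified by the closed-form segment
#' ([partner_with_errors()]) while defector-like (self-cooperation below
#' 1%) and equalizer-like (co-player payoff numerically invariant across
#' probe opponents) labels are assigned numerically.
#'
#' @param q A memory-one strategy.
#' @param spec A [game_spec()].
#' @return An `"equilibrium_report"` with `class_label` in
#'   `{"partner", "defector", "equalizer", "none"}` and
#'   `binding_constraints` holding the slack values of the matched class.
#' @export
classify_strategy <- function(q, spec = game_spec()) {
  rep <- nash_check(q, spec)
  rep$class_label <- "none"
  if (!rep$is_nash) return(rep)
  if (spec$eps == 0) {
    pa <- is_partner(q, spec)
    de <- is_defector(q, spec)
    eq <- is_equalizer(q, spec)
    if (isTRUE(as.logical(pa))) {
      rep$class_label <- "partner"; rep$binding_constraints <- attr(pa, "slack")
    } else if (isTRUE(as.logical(de))) {
      rep$class_label <- "defector"; rep$binding_constraints <- attr(de, "slack")
    } else if (isTRUE(as.logical(eq))) {
      rep$class_label <- "equalizer"
      rep$binding_constraints <- attr(eq, "required")
    }
  } else {
    pa <- partner_with_errors(q, spec)
    selfc <- .pay(unclass(as_memory1(q)), unclass(as_memory1(q)), spec)[3]
    if (isTRUE(as.logical(pa))) {
      rep$class_label <- "partner"; rep$binding_constraints <- attr(pa, "slack")
    } else if (selfc < spec$eps + 0.01) {
      # errors alone force a self-cooperation rate of about eps, so
      # "defector-like" means no cooperation beyond that floor
      rep$class_label <- "defector"
      rep$binding_constraints <- c(self_cooperation = selfc)
    } else {
      probes <- matrix(stats::runif(4 * 25), ncol = 4)
      pays <- apply(probes, 1, function(pp)
        .pay(pp, unclass(as_memory1(q)), spec)[1])
      if (stats::var(pays) < 1e-12) {
        rep$class_label <- "equalizer"
        rep$binding_constraints <- c(probe_payoff_var = stats::var(pays))
      }
    }
    rep$classification_method <- "numeric"
  }
  rep
}

#' Neutral invasion of a partner by full reciprocators
#'
#' In the game with errors, every partner strategy can be invaded
#' neutrally: any strategy with `pCC = pDC = 1` (e.g. ALLC or TFT) earns
#' exactly the partner's self-payoff against it. This function samples such
#' invaders and verifies payoff equality.
#'
#' @param q A partner strategy (see [partner_with_errors()]).
#' @param spec A [game_spec()] with `eps > 0`.
#' @param n Number of sampled invaders (ALLC and TFT are always included).
#' @return A data frame with one row per invader: its entries, its payoff
#'   against `q`, the resident self-payoff, the payoff gap, and whether the
#'   invader is itself a partner.
#' @export
neutral_invaders <- function(q, spec, n = 20) {
  q <- unname(unclass(as_memory1(q)))
  self <- .pay(q, q, spec)[1]
  inv <- unname(rbind(c(1, 1, 1, 1), c(1, 0, 1, 0),
                      cbind(1, stats::runif(n), 1, stats::runif(n))))
  res <- apply(inv, 1, function(pp) .pay(pp, q, spec)[1])
  partner <- apply(inv, 1, function(pp)
    isTRUE(as.logical(partner_with_errors(strategy(pp), spec))))
  data.frame(pCC = inv[, 1], pCD = inv[, 2], pDC = inv[, 3], pDD = inv[, 4],
             payoff = res, resident_self_payoff = self, gap = res - self,
             is_partner = partner)
}

#' Best deviation by random search with local refinement
#'
#' Independent numeric search for the best memory-one response to `q`:
#' `n` uniform random deviations plus L-BFGS-B hill climbing from the best
#' candidate (and from the best of the four extreme deviations). Used as an
#' oracle against the four-deviation recipe.
#'
#' @param q A memory-one strategy.
#' @param spec A [game_spec()].
#' @param n Number of random starting deviations.
#' @return A list with `payoff` (the best payoff found) and `strategy`.
#' @export
best_response_search <- function(q, spec = game_spec(), n = 500) {
  q <- unname(unclass(as_memory1(q)))
  f <- function(pp) .pay(pp, q, spec)[1]
  cand <- rbind(matrix(stats::runif(4 * n), ncol = 4),
                c(0, 0, 0, 0), c(1, 1, 1, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))
  pays <- apply(cand, 1, f)
  best <- cand[which.max(pays), ]
  opt <- stats::optim(best, f, method = "L-BFGS-B", lower = 1e-9,
                      upper = 1 - 1e-9,
                      control = list(fnscale = -1, factr = 1e4))
  if (opt$value >= max(pays))
    list(payoff = opt$value, strategy = strategy(opt$par))
  else
    list(payoff = max(pays), strategy = strategy(cand[which.max(pays), ]))
}
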