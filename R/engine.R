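# Exact long-run payoffs for pairs of memory-one strategies in the
# alternating and the simultaneous donation game.
#
# Donation-game payoffs: cooperation costs the donor c and gives the
# recipient b, so per round R = b - c, S = -c, T = b, P = 0.  Player 1's
# long-run payoff from the outcome distribution v = (vCC, vCD, vDC, vDD) is
#   pi1 = (vCC + vDC) b - (vCC + vCD) c
# and symmetrically for player 2 (first index = player 1's last action).

#' Specify a donation game
#'
#' @param mode `"alternating"` (players move in turns) or `"simultaneous"`.
#' @param b Benefit of cooperation to the recipient; must exceed `c`.
#' @param c Cost of cooperation to the donor; must be positive.
#' @param eps Implementation-error rate in `[0, 1/2]`: each intended action
#'   is flipped with this probability.
#' @param delta Continuation probability per round; `1` is the undiscounted
#'   (infinitely repeated) game.
#' @param s Switching probability (alternating mode): after each move, the
#'   other player moves next with probability `s`. `1` is strict
#'   alternation; `1/2` makes the next mover completely random.
#' @param first_round Length-2 character vector of initial actions
#'   `c("C","C")` by default; only matters for degenerate (reducible)
#'   chains, e.g. deterministic strategies without errors.
#' @return An object of class `"game_spec"`.
#' @export
game_spec <- function(mode = c("alternating", "simultaneous"),
                      b = 3, c = 1, eps = 0, delta = 1, s = 1,
                      first_round = c("C", "C")) {
  mode <- match.arg(mode)
  if (!(b > c && c > 0)) stop("need b > c > 0")
  if (eps < 0 || eps > 0.5) stop("eps must lie in [0, 1/2]")
  if (delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  if (s < 0.5 || s > 1) stop("switching probability s must lie in [1/2, 1]")
  if (s < 1 && mode != "alternating")
    stop("the switching probability applies to the alternating game only")
  first_round <- toupper(first_round)
  if (length(first_round) != 2 || !all(first_round %in% c("C", "D")))
    stop("first_round must be two actions from {C, D}")
  structure(list(mode = mode, b = b, c = c, eps = eps, delta = delta, s = s,
                 first_round = first_round),
            class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf(
    "%s donation game: b = %g, c = %g, eps = %g, delta = %g, s = %g, first round (%s, %s)\n",
    x$mode, x$b, x$c, x$eps, x$delta, x$s, x$first_round[1], x$first_round[2]))
  invisible(x)
}

# -- transition matrices (plain-vector fast paths) ---------------------------

# Alternating rounds: from state (i, j), player 1 acts on (i, j) giving i',
# then player 2 acts on (j, i') giving j'.
.tm_alt <- function(p, q) {
  matrix(c(
    p[1] * q[1], p[1] * (1 - q[1]), (1 - p[1]) * q[2], (1 - p[1]) * (1 - q[2]),
    p[2] * q[3], p[2] * (1 - q[3]), (1 - p[2]) * q[4], (1 - p[2]) * (1 - q[4]),
    p[3] * q[1], p[3] * (1 - q[1]), (1 - p[3]) * q[2], (1 - p[3]) * (1 - q[2]),
    p[4] * q[3], p[4] * (1 - q[3]), (1 - p[4]) * q[4], (1 - p[4]) * (1 - q[4])
  ), nrow = 4, byrow = TRUE, dimnames = list(STATE_NAMES, STATE_NAMES))
}

# Simultaneous rounds: both act on the previous round's outcome; player 2
# reads state (i, j) as (own, co-player) = (j, i).
.tm_sim <- function(p, q) {
  qq <- q[c(1, 3, 2, 4)]
  m <- cbind(p * qq, p * (1 - qq), (1 - p) * qq, (1 - p) * (1 - qq))
  dimnames(m) <- list(STATE_NAMES, STATE_NAMES)
  m
}

#' Round-to-round transition matrix of a strategy pair
#'
#' States are ordered (CC, CD, DC, DD) where the first letter is player 1's
#' last action. In alternating mode, a transition is one full round: player
#' 1 acts on the current state, then player 2 responds to player 1's new
#' action (read together with player 2's own last action).
#'
#' @param p,q Memory-one strategies of players 1 and 2 (error transform, if
#'   any, is the caller's responsibility — see [with_errors()]).
#' @param mode `"alternating"` or `"simultaneous"`.
#' @return A 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(p, q, mode = c("alternating", "simultaneous")) {
  mode <- match.arg(mode)
  p <- unclass(as_memory1(p)); q <- unclass(as_memory1(q))
  M <- if (mode == "alternating") .tm_alt(p, q) else .tm_sim(p, q)
  .check_stochastic(M)
  M
}

# Distribution of the first round's outcome state under the
# phantom-history convention: both players act on (a1, a2) as if it were
# the previous state.  Alternating: player 1 moves i' with probability
# p[a1, a2], then player 2 responds to (a2, i').  Simultaneous: i' and j'
# are drawn independently from p[a1, a2] and q[a2, a1].  This makes TFT
# and GRIM open cooperatively from the default (C, C) while ALLD always
# opens with defection.
.first_round_dist <- function(p, q, spec) {
  a1 <- spec$first_round[1] == "D"; a2 <- spec$first_round[2] == "D"
  pc <- p[2L * a1 + a2 + 1L]
  if (spec$mode == "alternating") {
    qC <- q[2L * a2 + 1L]        # q_{a2, C}
    qD <- q[2L * a2 + 2L]        # q_{a2, D}
    c(pc * qC, pc * (1 - qC), (1 - pc) * qD, (1 - pc) * (1 - qD))
  } else {
    qc <- q[2L * a2 + a1 + 1L]   # q_{a2, a1}
    c(pc * qc, pc * (1 - qc), (1 - pc) * qc, (1 - pc) * (1 - qc))
  }
}

.outcome <- function(v, rho1, rho2, spec) {
  v <- unname(as.numeric(v)); rho1 <- unname(rho1); rho2 <- unname(rho2)
  names(v) <- STATE_NAMES
  structure(list(v = v,
                 pi1 = (v[[1]] + v[[3]]) * spec$b - (v[[1]] + v[[2]]) * spec$c,
                 pi2 = (v[[1]] + v[[2]]) * spec$b - (v[[1]] + v[[3]]) * spec$c,
                 rho1 = rho1, rho2 = rho2, spec = spec),
            class = "stationary_outcome")
}

#' @export
print.stationary_outcome <- function(x, ...) {
  cat("long-run outcome distribution (CC, CD, DC, DD):\n")
  print(round(x$v, 6))
  cat(sprintf("payoffs: pi1 = %.6f, pi2 = %.6f; cooperation: rho1 = %.6f, rho2 = %.6f\n",
              x$pi1, x$pi2, x$rho1, x$rho2))
  invisible(x)
}

#' Long-run outcome of a strategy pair (undiscounted)
#'
#' Solves for the stationary distribution of the round chain. For
#' degenerate chains (several closed communicating classes, possible for
#' deterministic strategies without errors) the result is the
#' absorption-weighted mixture of each closed class's time-average
#' distribution, started from the first round implied by
#' `spec$first_round`.
#'
#' @param p,q Memory-one strategies of players 1 and 2. The error transform
#'   `spec$eps` is applied to both automatically.
#' @param spec A [game_spec()] with `delta = 1`.
#' @return A `"stationary_outcome"`: outcome distribution `v`, payoffs
#'   `pi1`, `pi2`, and cooperation rates `rho1 = vCC + vCD`,
#'   `rho2 = vCC + vDC`.
#' @export
stationary <- function(p, q, spec = game_spec()) {
  if (spec$delta < 1)
    stop("spec has delta < 1; use payoffs_discounted()")
  if (spec$s < 1)
    return(payoffs_switching(p, q, spec))
  p <- .effective(p, spec); q <- .effective(q, spec)
  M <- if (spec$mode == "alternating") .tm_alt(p, q) else .tm_sim(p, q)
  v <- .long_run_distribution(M, .first_round_dist(p, q, spec))
  .outcome(v, v[1] + v[2], v[1] + v[3], spec)
}

.effective <- function(p, spec) {
  p <- unclass(as_memory1(p))
  if (spec$eps > 0) (1 - spec$eps) * p + spec$eps * (1 - p) else p
}

#' Per-round outcome of a discounted game
#'
#' With continuation probability `delta < 1` per round, the per-round
#' expected outcome frequencies are the normalized discounted visit
#' distribution `(1 - delta) v0 (I - delta M)^-1`, where `v0` is the first
#' round's outcome distribution. Payoffs apply the donation-game payoff map
#' to that distribution.
#'
#' @inheritParams stationary
#' @param spec A [game_spec()] with `0 < delta < 1`.
#' @return A `"stationary_outcome"`.
#' @export
payoffs_discounted <- function(p, q, spec) {
  if (spec$delta >= 1)
    stop("spec has delta = 1 (undiscounted); use stationary()")
  p <- .effective(p, spec); q <- .effective(q, spec)
  M <- if (spec$mode == "alternating") .tm_alt(p, q) else .tm_sim(p, q)
  v0 <- .first_round_dist(p, q, spec)
  v <- (1 - spec$delta) * solve(t(diag(4) - spec$delta * M), v0)
  v <- pmax(v, 0); v <- v / sum(v)
  .outcome(v, v[1] + v[2], v[1] + v[3], spec)
}

#' Expected number of rounds of a discounted game
#'
#' Computed as the total (undiscounted-by-normalization) mass of the
#' discounted visit vector, `sum(v0 (I - delta M)^-1)`; for any strategy
#' pair this equals the geometric mean game length `1 / (1 - delta)`.
#'
#' @param spec A [game_spec()] with `delta < 1`.
#' @param p,q Strategies used to build the round chain (any pair gives the
#'   same length); defaults to uniform-random behavior.
#' @return Expected number of rounds.
#' @export
expected_rounds <- function(spec, p = strategy(rep(0.5, 4)), q = p) {
  if (spec$delta >= 1) return(Inf)
  pe <- .effective(p, spec); qe <- .effective(q, spec)
  M <- if (spec$mode == "alternating") .tm_alt(pe, qe) else .tm_sim(pe, qe)
  v0 <- .first_round_dist(pe, qe, spec)
  sum(solve(t(diag(4) - spec$delta * M), v0))
}

#' Long-run outcome under irregular alternation
#'
#' With switching probability `s < 1`, after each single move the *other*
#' player moves next with probability `s` (strict alternation at `s = 1`).
#' The game is tracked as an 8-state chain over (player 1's last action,
#' player 2's last action, who moves next); the mover acts on (own last,
#' other's last). Payoffs are normalized per round (= two moves) so that
#' `s = 1` reproduces [stationary()] payoffs; cooperation rates `rho1`,
#' `rho2` are per-move cooperation frequencies of each player.
#'
#' @inheritParams stationary
#' @param spec An alternating [game_spec()] with `1/2 <= s <= 1`.
#' @return A `"stationary_outcome"`; `v` is the joint distribution of the
#'   two players' last actions (marginalized over whose turn it is).
#' @export
payoffs_switching <- function(p, q, spec) {
  if (spec$mode != "alternating")
    stop("irregular alternation is defined for the alternating game")
  s <- spec$s
  p <- .effective(p, spec); q <- .effective(q, spec)
  # states 1..4: (CC, CD, DC, DD) with player 1 to move; 5..8: same, player 2
  M <- matrix(0, 8, 8)
  for (st in 1:4) {
    i <- (st - 1) %/% 2          # 0 = C, 1 = D (player 1's last)
    j <- (st - 1) %% 2           # player 2's last
    pc <- p[st]                  # p_{ij}: player 1 acts on (own, other)
    for (inew in 0:1) {
      pr <- if (inew == 0) pc else 1 - pc
      tgt <- 2 * inew + j + 1
      M[st, tgt + 4] <- M[st, tgt + 4] + pr * s        # turn passes to 2
      M[st, tgt]     <- M[st, tgt] + pr * (1 - s)
    }
    qc <- q[2 * j + i + 1]       # q_{ji}: player 2 acts on (own, other)
    for (jnew in 0:1) {
      pr <- if (jnew == 0) qc else 1 - qc
      tgt <- 2 * i + jnew + 1
      M[st + 4, tgt]     <- M[st + 4, tgt] + pr * s    # turn passes to 1
      M[st + 4, tgt + 4] <- M[st + 4, tgt + 4] + pr * (1 - s)
    }
  }
  # opening: player 1 acts on the phantom history (a1, a2); then the next
  # mover is player 2 with probability s
  a1 <- spec$first_round[1] == "D"; a2 <- spec$first_round[2] == "D"
  pc <- p[2 * a1 + a2 + 1]
  stC <- (0 + a2) + 1; stD <- (2 + a2) + 1   # states (C, a2), (D, a2)
  v0 <- numeric(8)
  v0[stC + 4] <- pc * s;       v0[stC] <- pc * (1 - s)
  v0[stD + 4] <- (1 - pc) * s; v0[stD] <- (1 - pc) * (1 - s)
  w <- .long_run_distribution(M, v0)
  w1 <- w[1:4]; w2 <- w[5:8]
  m1 <- sum(w1)                  # long-run fraction of moves made by player 1
  m2 <- sum(w2)
  rho1 <- if (m1 > 0) sum(w1 * p) / m1 else NA_real_
  qq <- q[c(1, 3, 2, 4)]         # q_{ji} aligned with state order
  rho2 <- if (m2 > 0) sum(w2 * qq) / m2 else NA_real_
  # per-round payoffs: two moves per round
  pi1 <- 2 * (spec$b * sum(w2 * qq) - spec$c * sum(w1 * p))
  pi2 <- 2 * (spec$b * sum(w1 * p) - spec$c * sum(w2 * qq))
  v <- w1 + w2
  names(v) <- STATE_NAMES
  structure(list(v = v, pi1 = pi1, pi2 = pi2, rho1 = rho1, rho2 = rho2,
                 spec = spec),
            class = "stationary_outcome")
}

#' Cooperation rate of one player
#'
#' @param outcome A `"stationary_outcome"`.
#' @param player `1` or `2`.
#' @return The player's long-run cooperation frequency.
#' @export
cooperation_rate <- function(outcome, player = 1) {
  stopifnot(player %in% c(1, 2))
  if (player == 1) outcome$rho1 else outcome$rho2
}

#' Payoffs of a strategy pair under any game specification
#'
#' Dispatches to [stationary()], [payoffs_discounted()] or
#' [payoffs_switching()] according to `spec`.
#'
#' @inheritParams stationary
#' @return A `"stationary_outcome"`.
#' @export
pair_payoffs <- function(p, q, spec = game_spec()) {
  if (spec$delta < 1) payoffs_discounted(p, q, spec)
  else if (spec$s < 1) payoffs_switching(p, q, spec)
  else stationary(p, q, spec)
}

# Lean internal payoff path used in hot loops: plain numeric p, q, no class
# dressing.  Returns c(pi1, pi2, rho1, rho2).  The compiled kernel handles
# ergodic chains; degenerate ones fall back to the class decomposition.
.pay <- function(p, q, spec) {
  if (spec$delta < 1 || spec$s < 1) {
    o <- pair_payoffs(strategy(p), strategy(q), spec)
    return(c(o$pi1, o$pi2, o$rho1, o$rho2))
  }
  res <- .pay_kernel(p, q, spec$mode == "alternating", spec$b, spec$c,
                     spec$eps)
  if (!anyNA(res)) return(res)
  if (spec$eps > 0) {
    e <- spec$eps
    p <- (1 - e) * p + e * (1 - p)
    q <- (1 - e) * q + e * (1 - q)
  }
  M <- if (spec$mode == "alternating") .tm_alt(p, q) else .tm_sim(p, q)
  v <- .stationary_solve(M)
  if (is.null(v)) v <- .long_run_distribution(M, .first_round_dist(p, q, spec))
  v <- unname(v)
  c((v[1] + v[3]) * spec$b - (v[1] + v[2]) * spec$c,
    (v[1] + v[2]) * spec$b - (v[1] + v[3]) * spec$c,
    v[1] + v[2], v[1] + v[3])
}
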