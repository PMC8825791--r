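# Independent oracles used across the test suite.  These deliberately take
# different computational routes than the package internals they check.

# Long-run distribution by repeated matrix squaring (high-power iteration);
# valid for chains with a unique stationary distribution.
power_iteration_stationary <- function(M, squarings = 17) {
  P <- M
  for (i in seq_len(squarings)) P <- P %*% P
  as.numeric(P[1, ])
}

# Fixation probability of a single mutant via absorption probabilities of
# the explicit (N+1)-state birth-death chain of the pairwise-comparison
# process, solved by linear algebra on the full transition matrix.
birth_death_fixation <- function(p, q, spec, N, beta) {
  pay <- function(a, b) {
    o <- pair_payoffs(strategy(a), strategy(b), spec)
    c(o$pi1, o$pi2)
  }
  p <- unclass(as_memory1(p)); q <- unclass(as_memory1(q))
  pp <- pay(p, p); pq <- pay(p, q); qq <- pay(q, q)
  P <- matrix(0, N + 1, N + 1)  # states 0..N mutants
  P[1, 1] <- 1; P[N + 1, N + 1] <- 1
  for (j in 1:(N - 1)) {
    pi_p <- ((j - 1) * pp[1] + (N - j) * pq[1]) / (N - 1)
    pi_q <- (j * pq[2] + (N - 1 - j) * qq[1]) / (N - 1)
    up <- (N - j) / N * j / (N - 1) * plogis(beta * (pi_p - pi_q))
    dn <- j / N * (N - j) / (N - 1) * plogis(-beta * (pi_p - pi_q))
    P[j + 1, j + 2] <- up
    P[j + 1, j] <- dn
    P[j + 1, j + 1] <- 1 - up - dn
  }
  # absorption at state N starting from 1 mutant
  trans <- 2:N
  Q <- P[trans, trans, drop = FALSE]
  R <- P[trans, N + 1]
  as.numeric(solve(diag(N - 1) - Q, R))[1]
}

# Direct stochastic simulation of the irregular-alternation move process;
# returns per-move cooperation frequencies and per-round payoffs.
simulate_switching <- function(p, q, spec, n_moves = 2e5) {
  p <- with_errors(strategy(p), spec$eps); q <- with_errors(strategy(q), spec$eps)
  p <- unclass(p); q <- unclass(q)
  i <- 0L; j <- 0L       # last actions, 0 = C, 1 = D (start from (C, C))
  turn <- 1L
  u_act <- runif(n_moves); u_turn <- runif(n_moves)
  c1 <- 0L; n1 <- 0L; c2 <- 0L; n2 <- 0L
  for (t in seq_len(n_moves)) {
    if (turn == 1L) {
      pc <- p[2L * i + j + 1L]
      i <- if (u_act[t] < pc) 0L else 1L
      n1 <- n1 + 1L; c1 <- c1 + (i == 0L)
      if (u_turn[t] < spec$s) turn <- 2L
    } else {
      pc <- q[2L * j + i + 1L]
      j <- if (u_act[t] < pc) 0L else 1L
      n2 <- n2 + 1L; c2 <- c2 + (j == 0L)
      if (u_turn[t] < spec$s) turn <- 1L
    }
  }
  rho1 <- c1 / n1; rho2 <- c2 / n2
  list(rho1 = rho1, rho2 = rho2, n1 = n1, n2 = n2,
       pi1 = 2 * (spec$b * c2 - spec$c * c1) / n_moves,
       pi2 = 2 * (spec$b * c1 - spec$c * c2) / n_moves)
}

rand_strategies <- function(n) matrix(runif(4 * n), ncol = 4)
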