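# Pairwise-comparison evolutionary dynamics in well-mixed populations:
# Fermi imitation, uniform strategy exploration, the rare-mutation embedded
# chain with analytic fixation probabilities, and recorders for
# self-cooperative / self-defecting residents.

#' Fermi imitation probability
#'
#' Probability that a focal player with payoff `pi_f` adopts a role model's
#' strategy with payoff `pi_r`: `1 / (1 + exp(-beta (pi_r - pi_f)))`.
#' At `beta = 0` (or equal payoffs) the probability is 1/2.
#'
#' @param pi_r Role model's payoff.
#' @param pi_f Focal player's payoff.
#' @param beta Selection strength, `>= 0`.
#' @return Imitation probability in `(0, 1)`; overflow-safe.
#' @export
fermi <- function(pi_r, pi_f, beta) {
  if (beta < 0) stop("selection strength beta must be >= 0")
  stats::plogis(beta * (pi_r - pi_f))
}

#' Fixation probability of a mutant in the pairwise-comparison process
#'
#' For a single `p`-mutant in a resident `q`-population of size `N`, the
#' imitation dynamics form a birth-death chain on the number of mutants
#' `j`. With payoffs (excluding self-interaction)
#' `pi_p(j) = ((j-1) pi(p,p) + (N-j) pi(p,q)) / (N-1)` and
#' `pi_q(j) = (j pi(q,p) + (N-1-j) pi(q,q)) / (N-1)`,
#' the fixation probability is
#' `rho = 1 / (1 + sum_k prod_{j<=k} exp(-beta (pi_p(j) - pi_q(j))))`.
#' Neutral mutants (`beta = 0` or `p = q`) fix with probability `1/N`.
#'
#' @param p Mutant strategy.
#' @param q Resident strategy.
#' @param spec A [game_spec()] (the error transform is applied inside the
#'   payoff engine).
#' @param N Population size, `>= 2`.
#' @param beta Selection strength.
#' @return Fixation probability in `(0, 1)`.
#' @export
fixation_probability <- function(p, q, spec = game_spec(), N = 100, beta = 1) {
  if (N < 2) stop("population size N must be >= 2")
  p <- unclass(as_memory1(p)); q <- unclass(as_memory1(q))
  pp <- .pay(p, p, spec); pq <- .pay(p, q, spec); qq <- .pay(q, q, spec)
  .fixation_from_payoffs(pp[1], pq[1], pq[2], qq[1], N, beta)
}

# pi_pp = pi(p,p), pi_pq = pi(p vs q), pi_qp = pi(q vs p), pi_qq = pi(q,q)
.fixation_from_payoffs <- function(pi_pp, pi_pq, pi_qp, pi_qq, N, beta) {
  j <- seq_len(N - 1)
  dpi <- ((j - 1) * pi_pp + (N - j) * pi_pq - j * pi_qp -
            (N - 1 - j) * pi_qq) / (N - 1)
  if (beta == 0 || max(abs(dpi)) == 0) return(1 / N)
  S <- cumsum(-beta * dpi)           # log of the running product
  m <- max(0, S)
  1 / exp(m + log(exp(-m) + sum(exp(S - m))))
}

#' Evolution parameters
#'
#' @param N Population size.
#' @param beta Selection strength.
#' @param mu Mutation probability per revision (explicit regime only; the
#'   rare-mutation regime is the limit `mu -> 0`).
#' @param steps Number of time steps (explicit regime) or of introduced
#'   mutants (rare-mutation regime).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class `"evolution_params"`.
#' @export
evolution_params <- function(N = 100, beta = 1, mu = 0.01, steps = 1e4,
                             seed = NULL) {
  if (N < 2) stop("N must be >= 2")
  if (beta < 0) stop("beta must be >= 0")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  structure(list(N = N, beta = beta, mu = mu, steps = as.integer(steps),
                 seed = seed),
            class = "evolution_params")
}

#' Rare-mutation evolutionary dynamics
#'
#' In the rare-mutation limit the population is monomorphic between
#' mutations: each step introduces one uniformly random mutant which either
#' fixes (with the analytic [fixation_probability()]) or goes extinct
#' before the next mutation. The population starts from unconditional
#' defectors. Time is measured in introduced mutants; residents are
#' weighted by their dwell time.
#'
#' @param spec A [game_spec()].
#' @param params An [evolution_params()] (`mu` is ignored in this regime).
#' @param mutant_pool Optional matrix (rows = strategies) to draw mutants
#'   from uniformly instead of the full strategy cube.
#' @return A data frame of class `"evolution_trace"` with one row per
#'   resident epoch: entries `qCC..qDD`, `self_coop` (self-play cooperation
#'   rate under the game's error rate), `self_payoff`, `dwell` (introduced
#'   mutants survived, including the one that finally fixed), and
#'   `censored` for the final resident. Attributes: `mean_cooperation`
#'   (dwell-weighted), `params`, `spec`, `seed`.
#' @export
run_rare_mutation <- function(spec = game_spec(), params = evolution_params(),
                              mutant_pool = NULL) {
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- params$N; beta <- params$beta; steps <- params$steps
  res <- c(0, 0, 0, 0)                 # ALLD founders
  qq <- .pay(res, res, spec)
  epochs_q <- list(); epochs_dwell <- integer(0)
  epochs_coop <- numeric(0); epochs_pay <- numeric(0)
  dwell <- 0L
  for (t in seq_len(steps)) {
    mut <- if (is.null(mutant_pool)) stats::runif(4)
           else mutant_pool[sample.int(nrow(mutant_pool), 1), ]
    dwell <- dwell + 1L
    pp <- .pay(mut, mut, spec)
    pq <- .pay(mut, res, spec)
    rho <- .fixation_from_payoffs(pp[1], pq[1], pq[2], qq[1], N, beta)
    if (stats::runif(1) < rho) {
      epochs_q[[length(epochs_q) + 1]] <- res
      epochs_dwell <- c(epochs_dwell, dwell)
      epochs_coop <- c(epochs_coop, qq[3])
      epochs_pay <- c(epochs_pay, qq[1])
      res <- mut; qq <- pp; dwell <- 0L
    }
  }
  censored <- c(rep(FALSE, length(epochs_q)), TRUE)
  epochs_q[[length(epochs_q) + 1]] <- res
  epochs_dwell <- c(epochs_dwell, dwell)
  epochs_coop <- c(epochs_coop, qq[3])
  epochs_pay <- c(epochs_pay, qq[1])
  m <- do.call(rbind, epochs_q)
  trace <- data.frame(qCC = m[, 1], qCD = m[, 2], qDC = m[, 3], qDD = m[, 4],
                      self_coop = epochs_coop, self_payoff = epochs_pay,
                      dwell = epochs_dwell, censored = censored)
  attr(trace, "mean_cooperation") <-
    sum(trace$self_coop * trace$dwell) / sum(trace$dwell)
  attr(trace, "params") <- params
  attr(trace, "spec") <- spec
  class(trace) <- c("evolution_trace", "data.frame")
  trace
}

#' Explicit agent-based pairwise-comparison process
#'
#' Full finite-`mu` dynamics: each time step one random player either
#' explores (probability `mu`: draws a uniformly random strategy) or picks
#' a random role model and imitates it with the Fermi probability of their
#' payoff difference. A player's payoff is the average game payoff against
#' all other population members; pairwise payoffs are cached per strategy
#' pair.
#'
#' @param spec A [game_spec()].
#' @param params An [evolution_params()] with `mu > 0`.
#' @param record_every Record the population census every this many steps.
#' @return A list of class `"explicit_trace"`: `mean_cooperation`
#'   (time-averaged population cooperation rate), `census` (data frame of
#'   recorded snapshots: step, mean self-cooperation, number of distinct
#'   strategies), and `final` (matrix of the final population's
#'   strategies).
#' @export
run_explicit <- function(spec = game_spec(),
                         params = evolution_params(mu = 0.01),
                         record_every = 100) {
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- params$N; beta <- params$beta; mu <- params$mu
  strat <- list(c(0, 0, 0, 0))         # unique strategies by id
  self_coop <- c(.pay(strat[[1]], strat[[1]], spec)[3])
  pop <- rep(1L, N)
  paymat <- matrix(NA_real_, 1, 1)     # paymat[i, j] = payoff of i against j
  paymat[1, 1] <- .pay(strat[[1]], strat[[1]], spec)[1]
  get_pay <- function(i, j) {
    if (is.na(paymat[i, j])) {
      pij <- .pay(strat[[i]], strat[[j]], spec)
      paymat[i, j] <<- pij[1]; paymat[j, i] <<- pij[2]
    }
    paymat[i, j]
  }
  avg_payoff <- function(id, counts, ids) {
    tot <- 0
    for (k in seq_along(ids)) tot <- tot + counts[k] * get_pay(id, ids[k])
    (tot - get_pay(id, id)) / (N - 1)  # exclude self-interaction
  }
  coop_sum <- 0
  rec_step <- integer(0); rec_coop <- numeric(0); rec_k <- integer(0)
  for (t in seq_len(params$steps)) {
    focal <- sample.int(N, 1)
    if (stats::runif(1) < mu) {
      ns <- stats::runif(4)
      id <- length(strat) + 1L
      strat[[id]] <- ns
      self_coop <- c(self_coop, .pay(ns, ns, spec)[3])
      if (id > nrow(paymat)) {         # grow the cache geometrically
        newn <- max(2 * nrow(paymat), id)
        pm <- matrix(NA_real_, newn, newn)
        pm[seq_len(nrow(paymat)), seq_len(nrow(paymat))] <- paymat
        paymat <- pm
      }
      pop[focal] <- id
    } else {
      model <- sample.int(N - 1, 1)
      if (model >= focal) model <- model + 1L
      if (pop[model] != pop[focal]) {
        tab <- table(pop)
        ids <- as.integer(names(tab)); counts <- as.integer(tab)
        pi_f <- avg_payoff(pop[focal], counts, ids)
        pi_r <- avg_payoff(pop[model], counts, ids)
        if (stats::runif(1) < fermi(pi_r, pi_f, beta))
          pop[focal] <- pop[model]
      } else {
        stats::runif(1)                # imitation among equals: no-op draw
      }
    }
    coop_sum <- coop_sum + mean(self_coop[pop])
    if (t %% record_every == 0) {
      rec_step <- c(rec_step, t)
      rec_coop <- c(rec_coop, mean(self_coop[pop]))
      rec_k <- c(rec_k, length(unique(pop)))
    }
  }
  structure(list(mean_cooperation = coop_sum / params$steps,
                 census = data.frame(step = rec_step, mean_self_coop = rec_coop,
                                     n_strategies = rec_k),
                 final = do.call(rbind, strat[pop]),
                 params = params, spec = spec),
            class = "explicit_trace")
}

#' Dwell-weighted marginals of self-cooperative residents
#'
#' Selects residents whose self-play cooperation rate is at least
#' `threshold` (self-cooperators) or below `defector_threshold`
#' (self-defectors) and returns dwell-weighted marginal distributions of
#' their four cooperation probabilities on a fixed 50-bin grid.
#'
#' @param trace An `"evolution_trace"` from [run_rare_mutation()].
#' @param threshold Self-cooperation threshold (default 0.8).
#' @param defector_threshold Self-defection threshold (default 0.2).
#' @param bins Number of histogram bins on `[0, 1]`.
#' @return A list with `cooperators` and `defectors`, each holding `n`
#'   (number of qualifying epochs), `weight` (total dwell), `means`
#'   (dwell-weighted means of qCC..qDD) and `marginals` (bins x 4 matrix of
#'   dwell-weighted probabilities); empty sets are flagged via `n = 0`.
#' @export
self_cooperator_marginals <- function(trace, threshold = 0.8,
                                      defector_threshold = 0.2, bins = 50) {
  one <- function(sel) {
    sub <- trace[sel, , drop = FALSE]
    if (nrow(sub) == 0)
      return(list(n = 0L, weight = 0, means = rep(NA_real_, 4),
                  marginals = matrix(0, bins, 4,
                                     dimnames = list(NULL, STATE_NAMES))))
    w <- sub$dwell / sum(sub$dwell)
    qm <- as.matrix(sub[, c("qCC", "qCD", "qDC", "qDD")])
    marg <- sapply(1:4, function(k) {
      idx <- pmin(pmax(ceiling(qm[, k] * bins), 1L), bins)
      vapply(seq_len(bins), function(bb) sum(w[idx == bb]), numeric(1))
    })
    colnames(marg) <- STATE_NAMES
    means <- colSums(w * qm)
    names(means) <- STATE_NAMES
    list(n = nrow(sub), weight = sum(sub$dwell),
         means = means, marginals = marg)
  }
  list(cooperators = one(trace$self_coop >= threshold),
       defectors = one(trace$self_coop < defector_threshold))
}

#' Robustness of self-cooperative residents
#'
#' For each self-cooperative resident in a rare-mutation trace, the number
#' of mutants that had to be introduced until one reached fixation (its
#' dwell time). The final resident is right-censored and excluded from the
#' mean by default.
#'
#' @param trace An `"evolution_trace"`.
#' @param threshold Self-cooperation threshold.
#' @param include_censored Include the right-censored final resident.
#' @return A list with `counts` (per qualifying resident), `censored`
#'   (logical, parallel to `counts`), and `mean_count` (over uncensored
#'   residents unless `include_censored`).
#' @export
resident_robustness <- function(trace, threshold = 0.8,
                                include_censored = FALSE) {
  sub <- trace[trace$self_coop >= threshold, , drop = FALSE]
  counts <- sub$dwell
  cens <- sub$censored
  keep <- if (include_censored) rep(TRUE, length(counts)) else !cens
  list(counts = counts, censored = cens,
       mean_count = if (any(keep)) mean(counts[keep]) else NA_real_)
}
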