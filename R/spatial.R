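# Lattice model: players on a periodic LxL grid play the repeated donation
# game with each of their eight neighbors and imitate their most successful
# neighbor (imitate-the-best), with rare global mutation.

#' Initialize a lattice population
#'
#' @param L Side length of the periodic square lattice (population `L^2`).
#' @param init Strategy every cell starts with (default ALLD).
#' @return A list of class `"lattice_state"`: `strategies` (list of unique
#'   strategies), `grid` (LxL integer matrix of strategy ids), `L`,
#'   `generation`.
#' @export
lattice_init <- function(L = 50, init = named_strategy("ALLD")) {
  structure(list(strategies = list(unclass(as_memory1(init))),
                 grid = matrix(1L, L, L), L = L, generation = 0L),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("%d x %d periodic lattice, generation %d, %d distinct strategies\n",
              x$L, x$L, x$generation, length(unique(as.vector(x$grid)))))
  invisible(x)
}

# offsets of the 8-cell Moore neighborhood
.NB_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                     dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# (L^2) x 8 matrix of flat neighbor indices, column-major cell order
.neighbor_index <- function(L) {
  rows <- rep(seq_len(L), L); cols <- rep(seq_len(L), each = L)
  sapply(seq_len(8), function(k) {
    r <- (rows + .NB_OFFSETS[k, 1] - 1) %% L + 1
    cc <- (cols + .NB_OFFSETS[k, 2] - 1) %% L + 1
    (cc - 1) * L + r
  })
}

# payoff (and cooperation-rate) lookup for ordered id pairs, cached in an
# environment across calls within one run
.pair_cache <- function(spec) {
  env <- new.env(parent = emptyenv())
  env$spec <- spec
  env
}

.cached_pay <- function(cache, strategies, i, j) {
  key <- paste0(i, ":", j)
  val <- cache[[key]]
  if (is.null(val)) {
    p4 <- .pay(strategies[[i]], strategies[[j]], cache$spec)
    cache[[key]] <- p4
    cache[[paste0(j, ":", i)]] <- p4[c(2, 1, 4, 3)]
    val <- p4
  }
  val
}

#' One synchronous lattice generation
#'
#' Every player's payoff is the sum of its pairwise repeated-game payoffs
#' (long-run, from the engine) against its eight neighbors. Then all
#' players update independently from that pre-update payoff field: with
#' probability `mu` a player adopts a uniformly random strategy (global
#' mutation); otherwise it adopts the strategy of its best-paid neighbor,
#' but only if that neighbor's payoff strictly exceeds its own (ties among
#' best neighbors broken uniformly at random).
#'
#' @param state A `"lattice_state"`.
#' @param spec A [game_spec()].
#' @param mu Mutation probability per player per generation.
#' @param cache Optional payoff cache (reused across generations by
#'   [run_lattice()]).
#' @return The updated `"lattice_state"`; attribute `"mean_cooperation"`
#'   holds the grid-average per-pair cooperation rate of the pre-update
#'   population, attribute `"payoffs"` the pre-update payoff field.
#' @export
lattice_step <- function(state, spec = game_spec(), mu = 0.002,
                         cache = NULL) {
  L <- state$L; n <- L * L
  if (is.null(cache)) cache <- .pair_cache(spec)
  nb <- .neighbor_index(L)
  ids <- as.vector(state$grid)
  payoff <- numeric(n); coop <- numeric(n)
  for (cell in seq_len(n)) {
    for (k in seq_len(8)) {
      p4 <- .cached_pay(cache, state$strategies, ids[cell], ids[nb[cell, k]])
      payoff[cell] <- payoff[cell] + p4[1]
      coop[cell] <- coop[cell] + p4[3]
    }
  }
  newids <- ids
  mut <- stats::runif(n) < mu
  for (cell in seq_len(n)) {
    if (mut[cell]) {
      state$strategies[[length(state$strategies) + 1L]] <- stats::runif(4)
      newids[cell] <- length(state$strategies)
    } else {
      nbp <- payoff[nb[cell, ]]
      best <- max(nbp)
      if (best > payoff[cell]) {
        cand <- which(nbp == best)
        pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
        newids[cell] <- ids[nb[cell, pick]]
      }
    }
  }
  state$grid <- matrix(newids, L, L)
  state$generation <- state$generation + 1L
  attr(state, "mean_cooperation") <- mean(coop) / 8
  attr(state, "payoffs") <- matrix(payoff, L, L)
  state
}

#' Run the lattice model
#'
#' Repeats [lattice_step()] for a number of generations, starting from an
#' all-ALLD population, and records the grid-average cooperation rate per
#' generation.
#'
#' @param spec A [game_spec()].
#' @param L Lattice side length.
#' @param generations Number of synchronous generations.
#' @param mu Mutation probability per player per generation.
#' @param seed Optional RNG seed.
#' @param snapshot_every Keep a copy of the grid every this many
#'   generations (`Inf` = none).
#' @return A list of class `"lattice_run"`: `cooperation` (length
#'   `generations + 1` trajectory, entry 1 = initial population),
#'   `final` (final `"lattice_state"`), `snapshots`, and `coexistence`
#'   (`TRUE` when the final grid holds both self-cooperative (>= 0.8) and
#'   self-defecting (< 0.2) cells).
#' @export
run_lattice <- function(spec = game_spec(), L = 50, generations = 20000,
                        mu = 0.002, seed = NULL, snapshot_every = Inf) {
  if (!is.null(seed)) set.seed(seed)
  state <- lattice_init(L)
  cache <- .pair_cache(spec)
  coop <- numeric(generations + 1)
  self0 <- .pay(state$strategies[[1]], state$strategies[[1]], spec)[3]
  coop[1] <- self0
  snapshots <- list()
  for (g in seq_len(generations)) {
    state <- lattice_step(state, spec, mu, cache)
    coop[g + 1] <- attr(state, "mean_cooperation")
    if (is.finite(snapshot_every) && g %% snapshot_every == 0)
      snapshots[[as.character(g)]] <- state$grid
  }
  ids <- unique(as.vector(state$grid))
  selfc <- vapply(ids, function(i)
    .cached_pay(cache, state$strategies, i, i)[3], numeric(1))
  cellcoop <- selfc[match(as.vector(state$grid), ids)]
  structure(list(cooperation = coop, final = state, snapshots = snapshots,
                 coexistence = any(cellcoop >= 0.8) && any(cellcoop < 0.2),
                 spec = spec, seed = seed),
            class = "lattice_run")
}
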