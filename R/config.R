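# Configuration plumbing, figure-level reproduction runs, and the built-in
# validation battery.  The command-line entry point in
# inst/scripts/altgame is a thin wrapper over these functions.

#' Build, read and write run configurations
#'
#' A run configuration bundles the game specification, evolution
#' parameters, lattice settings, a seed and output paths. It round-trips
#' losslessly through YAML; [resolve_config()] fills in every default so
#' the emitted config is self-contained.
#'
#' @param game,evolution,lattice,output Named lists overriding defaults.
#' @param seed Integer seed.
#' @return A list of class `"run_config"` with every default applied.
#' @export
run_config <- function(game = list(), evolution = list(), lattice = list(),
                       output = list(), seed = 1L) {
  defaults <- list(
    game = list(mode = "alternating", b = 3, c = 1, eps = 0, delta = 1,
                s = 1, first_round = c("C", "C")),
    evolution = list(N = 100, beta = 1, mu = 0.01, steps = 10000,
                     regime = "rare_mutation"),
    lattice = list(L = 50, mu = 0.002, generations = 20000),
    output = list(dir = ".", json = TRUE),
    seed = seed)
  cfg <- defaults
  cfg$game[names(game)] <- game
  cfg$evolution[names(evolution)] <- evolution
  cfg$lattice[names(lattice)] <- lattice
  cfg$output[names(output)] <- output
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(game = raw$game %||% list(),
             evolution = raw$evolution %||% list(),
             lattice = raw$lattice %||% list(),
             output = raw$output %||% list(),
             seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_config
#' @param cfg A `"run_config"`.
#' @export
resolve_config <- function(cfg) {
  spec <- game_spec(mode = cfg$game$mode, b = cfg$game$b, c = cfg$game$c,
                    eps = cfg$game$eps, delta = cfg$game$delta,
                    s = cfg$game$s, first_round = cfg$game$first_round)
  params <- evolution_params(N = cfg$evolution$N, beta = cfg$evolution$beta,
                             mu = cfg$evolution$mu,
                             steps = cfg$evolution$steps, seed = cfg$seed)
  list(spec = spec, params = params, lattice = cfg$lattice,
       output = cfg$output, seed = cfg$seed)
}

#' Reproduce a figure-level experiment
#'
#' Runs one of the package's standard experiments at a configurable
#' (default: strongly scaled-down) size and writes its artifacts.
#'
#' * `"fig4"`: rare-mutation evolution in the alternating game with errors
#'   (`beta = 5`); records the dwell-weighted marginal distributions of
#'   self-cooperative residents.
#' * `"fig5"`: rare-mutation cooperation rates of the alternating vs the
#'   simultaneous game, with and without errors (`beta = 1`).
#' * `"fig6"`: the lattice model trajectory.
#'
#' @param name One of `"fig4"`, `"fig5"`, `"fig6"`.
#' @param overrides Named list merged over the experiment's defaults
#'   (`steps`, `seed`, `eps`, `L`, `generations`, ...).
#' @param out_dir Output directory (`NULL` = return results only).
#' @return A list with the experiment's summary and, when `out_dir` is
#'   given, the paths written (trace CSV, summary JSON, resolved config).
#' @export
reproduce_figure <- function(name = c("fig4", "fig5", "fig6"),
                             overrides = list(), out_dir = NULL) {
  name <- match.arg(name)
  ov <- function(key, default) overrides[[key]] %||% default
  seed <- ov("seed", 1L)
  result <- switch(name,
    fig4 = {
      spec <- game_spec("alternating", b = ov("b", 3), c = ov("c", 1),
                        eps = ov("eps", 0.02))
      tr <- run_rare_mutation(spec, evolution_params(
        N = ov("N", 100), beta = ov("beta", 5),
        steps = ov("steps", 10000), seed = seed))
      list(trace = tr,
           marginals = self_cooperator_marginals(tr),
           summary = list(mean_cooperation = attr(tr, "mean_cooperation")))
    },
    fig5 = {
      steps <- ov("steps", 10000)
      runs <- lapply(c(alternating = "alternating",
                       simultaneous = "simultaneous"), function(md) {
        spec <- game_spec(md, b = ov("b", 3), c = ov("c", 1),
                          eps = ov("eps", 0))
        attr(run_rare_mutation(spec, evolution_params(
          N = ov("N", 100), beta = ov("beta", 1), steps = steps,
          seed = seed)), "mean_cooperation")
      })
      list(summary = c(runs, gap = runs$simultaneous - runs$alternating))
    },
    fig6 = {
      spec <- game_spec(ov("mode", "alternating"), b = ov("b", 3),
                        c = ov("c", 1), eps = ov("eps", 0.02))
      lr <- run_lattice(spec, L = ov("L", 10),
                        generations = ov("generations", 200),
                        mu = ov("mu", 0.002), seed = seed)
      list(run = lr,
           summary = list(final_cooperation = utils::tail(lr$cooperation, 1),
                          coexistence = lr$coexistence))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(summary = file.path(out_dir, paste0(name, "_summary.json")),
                  config = file.path(out_dir, paste0(name, "_config.yaml")))
    jsonlite::write_json(result$summary, paths$summary, auto_unbox = TRUE,
                         digits = NA)
    write_config(run_config(seed = seed), paths$config)
    if (!is.null(result$trace)) {
      paths$trace <- file.path(out_dir, paste0(name, "_trace.csv"))
      utils::write.csv(as.data.frame(result$trace), paths$trace,
                       row.names = FALSE)
    }
    if (name == "fig6") {
      paths$trajectory <- file.path(out_dir, "fig6_cooperation.csv")
      utils::write.csv(data.frame(generation = seq_along(result$run$cooperation) - 1,
                                  cooperation = result$run$cooperation),
                       paths$trajectory, row.names = FALSE)
    }
    result$paths <- paths
  }
  result
}

#' Run the built-in validation battery
#'
#' Exercises the package's core numerical guarantees on freshly sampled
#' inputs: probability conservation of the round chains, the payoff
#' identity `pi1 + pi2 = (b - c)(rho1 + rho2)`, payoff preservation of the
#' reactive reduction, soundness of the four-deviation recipe against a
#' random best-response search, and agreement of the analytic fixation
#' probability with a birth-death absorption solve.
#'
#' @param n Number of random cases per check.
#' @param seed RNG seed.
#' @param tolerance Override the per-check tolerances (single number
#'   applied everywhere; mainly for negative controls).
#' @return A data frame with columns `check`, `pass`, `worst` (worst
#'   observed discrepancy or slack).
#' @export
validate_suite <- function(n = 20, seed = 1, tolerance = NULL) {
  set.seed(seed)
  spec0 <- game_spec("alternating", eps = 0)
  spec2 <- game_spec("alternating", eps = 0.02)
  tol <- function(x) tolerance %||% x
  checks <- list()

  worst <- 0
  for (i in seq_len(n)) {
    p <- stats::runif(4); q <- stats::runif(4)
    for (md in c("alternating", "simultaneous")) {
      M <- transition_matrix(strategy(p), strategy(q), md)
      worst <- max(worst, abs(rowSums(M) - 1))
    }
  }
  checks$conservation <- c(worst, tol(1e-12))

  worst <- 0
  for (i in seq_len(n)) {
    p <- strategy(stats::runif(4)); q <- strategy(stats::runif(4))
    o <- stationary(p, q, spec2)
    worst <- max(worst, abs(o$pi1 + o$pi2 -
                              (spec2$b - spec2$c) * (o$rho1 + o$rho2)))
  }
  checks$payoff_identity <- c(worst, tol(1e-10))

  worst <- 0
  for (i in seq_len(n)) {
    p <- strategy(stats::runif(4)); q <- strategy(stats::runif(4))
    r <- reactive_reduction(p, q, spec0)
    o1 <- stationary(p, q, spec0); o2 <- stationary(as_memory1(r), q, spec0)
    worst <- max(worst, abs(o1$pi1 - o2$pi1), abs(o1$pi2 - o2$pi2))
  }
  checks$reactive_reduction <- c(worst, tol(1e-9))

  worst <- 0
  for (i in seq_len(max(3, n %/% 4))) {
    q <- strategy(stats::runif(4))
    rep <- nash_check(q, spec2)
    srch <- best_response_search(q, spec2, n = 200)
    worst <- max(worst, srch$payoff - max(rep$deviation_payoffs))
  }
  checks$recipe_soundness <- c(worst, tol(1e-6))

  worst <- 0
  for (i in seq_len(n)) {
    p <- strategy(stats::runif(4)); q <- strategy(stats::runif(4))
    N <- sample(3:6, 1)
    rho <- fixation_probability(p, q, spec2, N = N, beta = 1)
    worst <- max(worst, abs(rho - .fixation_birth_death(p, q, spec2, N, 1)))
  }
  checks$fixation_oracle <- c(worst, tol(1e-12))

  data.frame(check = names(checks),
             worst = vapply(checks, `[`, numeric(1), 1),
             tolerance = vapply(checks, `[`, numeric(1), 2),
             pass = vapply(checks, function(x) x[1] <= x[2], logical(1)),
             row.names = NULL)
}

# Independent birth-death absorption solve of the mutant-count chain,
# used by validate_suite (the test suite carries its own copy).
.fixation_birth_death <- function(p, q, spec, N, beta) {
  p <- unclass(as_memory1(p)); q <- unclass(as_memory1(q))
  pp <- .pay(p, p, spec); pq <- .pay(p, q, spec); qq <- .pay(q, q, spec)
  j <- seq_len(N - 1)
  pi_p <- ((j - 1) * pp[1] + (N - j) * pq[1]) / (N - 1)
  pi_q <- (j * pq[2] + (N - 1 - j) * qq[1]) / (N - 1)
  Tplus <- (N - j) / N * j / (N - 1) * stats::plogis(beta * (pi_p - pi_q))
  Tminus <- j / N * (N - j) / (N - 1) * stats::plogis(-beta * (pi_p - pi_q))
  # absorption probability at N starting from 1 mutant
  n_t <- N - 1
  A <- diag(n_t)
  for (k in seq_len(n_t)) {
    A[k, k] <- Tplus[k] + Tminus[k]
    if (k > 1) A[k, k - 1] <- -Tminus[k]
    if (k < n_t) A[k, k + 1] <- -Tplus[k]
  }
  rhs <- numeric(n_t); rhs[n_t] <- Tplus[n_t]
  solve(A, rhs)[1]
}
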