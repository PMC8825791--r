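# Memory-one strategies for the repeated donation game.
#
# A memory-one strategy is a vector of four conditional cooperation
# probabilities (pCC, pCD, pDC, pDD): the probability to cooperate given
# (own last action, co-player's last action).  All engine code uses this
# fixed order.

STATE_NAMES <- c("CC", "CD", "DC", "DD")

#' Construct a memory-one strategy
#'
#' A memory-one strategy conditions the next cooperation probability on the
#' pair (own last action, co-player's last action).
#'
#' @param pCC,pCD,pDC,pDD Cooperation probabilities in `[0, 1]`, conditional
#'   on the previous joint action. Alternatively `pCC` may be a numeric
#'   vector of length 4 giving all four entries in the order
#'   (CC, CD, DC, DD).
#' @return A named numeric vector of class `"memory1"`.
#' @examples
#' strategy(1, 0, 0, 1)       # Win-Stay Lose-Shift
#' strategy(c(1, 0, 1, 0))    # Tit-for-Tat
#' @export
strategy <- function(pCC, pCD = NULL, pDC = NULL, pDD = NULL) {
  p <- if (length(pCC) == 4 && is.null(pCD)) as.numeric(pCC)
       else c(pCC, pCD, pDC, pDD)
  if (length(p) != 4 || anyNA(p))
    stop("a memory-one strategy needs 4 non-missing cooperation probabilities")
  if (any(p < 0) || any(p > 1))
    stop("cooperation probabilities must lie in [0, 1]")
  names(p) <- STATE_NAMES
  class(p) <- "memory1"
  p
}

#' @export
print.memory1 <- function(x, ...) {
  cat("memory-one strategy (pCC, pCD, pDC, pDD):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a reactive strategy
#'
#' Reactive strategies ignore the player's own previous action and condition
#' only on what the co-player last did.
#'
#' @param rC Cooperation probability after the co-player cooperated.
#' @param rD Cooperation probability after the co-player defected.
#' @return An object of class `"reactive"` with fields `rC`, `rD`.
#' @seealso [as_memory1()] for the embedding (rC, rD, rC, rD).
#' @export
reactive_strategy <- function(rC, rD) {
  if (anyNA(c(rC, rD)) || rC < 0 || rC > 1 || rD < 0 || rD > 1)
    stop("reactive probabilities must lie in [0, 1]")
  structure(list(rC = rC, rD = rD), class = "reactive")
}

#' @export
print.reactive <- function(x, ...) {
  cat(sprintf("reactive strategy: rC = %g, rD = %g\n", x$rC, x$rD))
  invisible(x)
}

#' Embed a strategy into the memory-one representation
#'
#' @param x A `"reactive"` strategy, a `"memory1"` strategy (returned
#'   unchanged), or a numeric vector of length 4.
#' @return A `"memory1"` strategy.
#' @export
as_memory1 <- function(x) {
  if (inherits(x, "memory1")) return(x)
  if (inherits(x, "reactive")) return(strategy(x$rC, x$rD, x$rC, x$rD))
  if (is.character(x) && length(x) == 1) return(named_strategy(x))
  strategy(as.numeric(x))
}

#' Is a strategy reactive / deterministic?
#'
#' A memory-one strategy is *reactive* when it ignores its own last action
#' (pCC = pDC and pCD = pDD) and *deterministic* when every entry is 0 or 1.
#'
#' @param p A memory-one strategy (anything accepted by [as_memory1()]).
#' @param tol Comparison tolerance.
#' @return Logical scalar.
#' @export
is_reactive <- function(p, tol = 1e-12) {
  p <- as_memory1(p)
  abs(p[[1]] - p[[3]]) <= tol && abs(p[[2]] - p[[4]]) <= tol
}

#' @rdname is_reactive
#' @export
is_deterministic <- function(p, tol = 1e-12) {
  p <- as_memory1(p)
  all(pmin(abs(unclass(p)), abs(unclass(p) - 1)) <= tol)
}

# Named catalog.  Tuples are exact constants; GRIM = (1,0,0,0) is the
# standard "defect forever after any defection" reading.
.STRATEGY_CATALOG <- list(
  ALLD   = c(0, 0, 0, 0),
  ALLC   = c(1, 1, 1, 1),
  TFT    = c(1, 0, 1, 0),
  ATFT   = c(0, 1, 0, 1),
  WSLS   = c(1, 0, 0, 1),
  FBF    = c(1, 0, 1, 1),
  GRIM   = c(1, 0, 0, 0),
  Repeat = c(1, 1, 0, 0)
)

#' Look up a named memory-one strategy
#'
#' Catalog of classic strategies: `ALLD`, `ALLC`, `TFT` (Tit-for-Tat),
#' `ATFT` (Anti-Tit-for-Tat), `WSLS` (Win-Stay Lose-Shift), `FBF`
#' (Firm-but-Fair), `GRIM` (defect forever after any defection) and
#' `Repeat` (repeat own last action).
#'
#' @param name Strategy name (case-insensitive except `Repeat`).
#' @return A `"memory1"` strategy with the exact published tuple.
#' @examples
#' named_strategy("WSLS")  # (1, 0, 0, 1)
#' @export
named_strategy <- function(name) {
  key <- match(toupper(name), toupper(names(.STRATEGY_CATALOG)))
  if (is.na(key))
    stop(sprintf("unknown strategy name '%s'; known: %s", name,
                 paste(names(.STRATEGY_CATALOG), collapse = ", ")))
  strategy(.STRATEGY_CATALOG[[key]])
}

#' Names of all catalog strategies
#' @return Character vector.
#' @export
strategy_names <- function() names(.STRATEGY_CATALOG)

#' Apply the implementation-error transform
#'
#' With probability `eps` an intended action is replaced by its opposite, so
#' a strategy `p` acts like the effective strategy
#' `(1 - eps) * p + eps * (1 - p)`.
#'
#' @param p A memory-one strategy.
#' @param eps Error probability in `[0, 1/2]`.
#' @return The effective `"memory1"` strategy.
#' @export
with_errors <- function(p, eps) {
  if (eps < 0 || eps > 0.5)
    stop("error rate eps must lie in [0, 1/2]")
  p <- as_memory1(p)
  strategy((1 - eps) * unclass(p) + eps * (1 - unclass(p)))
}

#' Count deterministic strategies of a given memory length
#'
#' A memory-k strategy maps each of the `4^k` joint histories to an action,
#' so there are `2^(4^k)` deterministic (pure) strategies.
#'
#' @param memory_length Integer in `{1, 2, 3}`.
#' @return The count, as a double (exact for these inputs).
#' @examples
#' count_pure_strategies(1)  # 16
#' count_pure_strategies(2)  # 65536
#' @export
count_pure_strategies <- function(memory_length) {
  if (!memory_length %in% c(1, 2, 3))
    stop("memory_length must be 1, 2 or 3")
  2^(4^memory_length)
}

#' Sample memory-one strategies uniformly at random
#'
#' Draws each of the four cooperation probabilities independently from
#' `U(0, 1)`, i.e. uniformly from the strategy cube.
#'
#' @param n Number of strategies.
#' @return If `n == 1` a `"memory1"` strategy, otherwise an `n x 4` matrix
#'   with one strategy per row.
#' @export
sample_strategy <- function(n = 1) {
  m <- matrix(stats::runif(4 * n), nrow = n, ncol = 4,
              dimnames = list(NULL, STATE_NAMES))
  if (n == 1) strategy(m[1, ]) else m
}

#' Serialize / deserialize strategies as JSON
#'
#' @param p A memory-one strategy.
#' @param txt A JSON string of the form
#'   `{"pCC": ..., "pCD": ..., "pDC": ..., "pDD": ...}`.
#' @return `strategy_to_json()` a JSON string; `strategy_from_json()` a
#'   `"memory1"` strategy.
#' @export
strategy_to_json <- function(p) {
  p <- as_memory1(p)
  jsonlite::toJSON(list(pCC = p[[1]], pCD = p[[2]], pDC = p[[3]], pDD = p[[4]]),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname strategy_to_json
#' @export
strategy_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  strategy(obj$pCC, obj$pCD, obj$pDC, obj$pDD)
}
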