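# Internal finite-Markov-chain utilities shared by the game engine.
#
# Chains are row-stochastic matrices over a handful of states (4 for the
# round chain, 8 for the irregular-alternation move chain).  The long-run
# outcome is the unique stationary distribution when the chain has a single
# closed communicating class; otherwise the chain is decomposed into
# communicating classes and the result is the absorption-weighted mixture
# of each closed class's time-average (Cesaro) distribution, started from
# an initial distribution v0.

.check_stochastic <- function(M, tol = 1e-12) {
  if (any(M < -tol) || any(M > 1 + tol))
    stop("transition matrix entries must lie in [0, 1]")
  bad <- which(abs(rowSums(M) - 1) > 1e-9)
  if (length(bad))
    stop(sprintf("transition matrix rows %s do not sum to 1",
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

# Stationary distribution by direct linear solve; NULL when the solve is
# singular (>= 2 closed classes) or yields an invalid vector.  Fast path:
# replace one balance equation with the normalization row; fall back to the
# overdetermined least-squares system when that happens to be singular.
.stationary_solve <- function(M) {
  n <- nrow(M)
  A <- t(M) - diag(n)
  A[n, ] <- 1
  rhs <- c(rep(0, n - 1), 1)
  v <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(v) || min(v) < -1e-9 ||
      max(abs(as.vector(v %*% M) - v)) > 1e-8) {
    A2 <- rbind(t(M) - diag(n), rep(1, n))
    v <- tryCatch(qr.solve(A2, c(rep(0, n), 1)), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    if (min(v) < -1e-9 || max(abs(as.vector(v %*% M) - v)) > 1e-8) return(NULL)
  }
  v <- pmax(v, 0)
  v / sum(v)
}

# Communicating classes of the support graph (edges with mass > tol).
# Returns list(membership = integer class id per state,
#              closed = logical per class id).
.chain_classes <- function(M, tol = 1e-12) {
  n <- nrow(M)
  A <- (M > tol)
  diag(A) <- TRUE
  R <- A
  for (k in seq_len(ceiling(log2(n)) + 1)) R <- (R %*% R) > 0  # reachability
  membership <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      cid <- cid + 1L
      membership[R[i, ] & R[, i]] <- cid
    }
  }
  closed <- vapply(seq_len(cid), function(k) {
    inside <- membership == k
    all(M[inside, !inside] <= tol)
  }, logical(1))
  list(membership = membership, closed = closed)
}

#' Closed communicating classes of a transition matrix
#'
#' Decomposes the support graph of a row-stochastic matrix into
#' communicating classes and returns the closed (invariant) ones, i.e. the
#' minimal state sets the chain can never leave.
#'
#' @param M A row-stochastic matrix.
#' @param tol Edges with transition mass `<= tol` are treated as absent.
#' @return A list of integer vectors, one per closed class, giving state
#'   indices.
#' @examples
#' M <- transition_matrix(named_strategy("TFT"), named_strategy("TFT"),
#'                        mode = "alternating")
#' closed_classes(M)  # two invariant sets: {CC} and {DD}
#' @export
closed_classes <- function(M, tol = 1e-12) {
  .check_stochastic(M)
  cl <- .chain_classes(M, tol)
  lapply(which(cl$closed), function(k) which(cl$membership == k))
}

# Long-run distribution of an arbitrary finite chain started from v0.
# Unique-stationary fast path, then class decomposition.
.long_run_distribution <- function(M, v0) {
  v <- .stationary_solve(M)
  if (!is.null(v)) return(v)
  n <- nrow(M)
  cl <- .chain_classes(M)
  closed_ids <- which(cl$closed)
  # time-average distribution within each closed class (unique stationary of
  # the restriction, also for periodic classes)
  stat_k <- lapply(closed_ids, function(k) {
    idx <- which(cl$membership == k)
    if (length(idx) == 1) return(structure(1, idx = idx))
    sub <- M[idx, idx, drop = FALSE]
    sub <- sub / rowSums(sub)  # guard against stray mass <= tol
    structure(.stationary_solve(sub), idx = idx)
  })
  closed_states <- unlist(lapply(stat_k, attr, "idx"))
  transient <- setdiff(seq_len(n), closed_states)
  absorb <- numeric(length(closed_ids))
  for (j in seq_along(closed_ids)) {
    idx <- attr(stat_k[[j]], "idx")
    absorb[j] <- sum(v0[idx])
  }
  if (length(transient) && sum(v0[transient]) > 0) {
    Q <- M[transient, transient, drop = FALSE]
    H <- solve(diag(length(transient)) - Q)  # expected visits
    for (j in seq_along(closed_ids)) {
      idx <- attr(stat_k[[j]], "idx")
      into <- rowSums(M[transient, idx, drop = FALSE])
      absorb[j] <- absorb[j] + sum((v0[transient] %*% H) * into)
    }
  }
  v <- numeric(n)
  for (j in seq_along(closed_ids)) {
    idx <- attr(stat_k[[j]], "idx")
    v[idx] <- v[idx] + absorb[j] * as.numeric(stat_k[[j]])
  }
  v / sum(v)
}
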