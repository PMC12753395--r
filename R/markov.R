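#' Run a Markov cohort trace
#'
#' Propagates a cohort through a row-stochastic transition matrix for
#' `n_cycles` monthly cycles. Membership fractions are tracked at cycle
#' boundaries (`n_cycles + 1` rows, starting from `initial`); per-cycle state
#' occupancy is, with the half-cycle correction, the trapezoid of consecutive
#' boundary memberships, `(membership[t] + membership[t+1]) / 2`, crediting
#' transitions as occurring mid-cycle on average. Without it, occupancy is the
#' end-of-cycle membership.
#'
#' @param mat Row-stochastic transition matrix (e.g. from
#'   [build_transition_matrix()]).
#' @param n_cycles Number of cycles; default 120 (10 years of monthly cycles).
#' @param initial Initial state distribution; defaults to everyone in the
#'   first state (DFS).
#' @param half_cycle Apply the half-cycle correction to occupancy?
#'   Default `TRUE`.
#' @return A `markov_trace`: list with `membership` ((n_cycles+1) x k matrix),
#'   `occupancy` (n_cycles x k), `n_cycles`, `half_cycle`, `states`.
#' @examples
#' tr <- run_trace(build_transition_matrix(14, 22))
#' tail(tr$membership, 1)  # almost everyone absorbed by 10 years
#' @export
run_trace <- function(mat, n_cycles = 120, initial = c(1, 0, 0),
                      half_cycle = TRUE) {
  m <- unclass(mat)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`mat` must be a square matrix", call. = FALSE)
  }
  k <- nrow(m)
  if (any(m < -1e-12) || any(m > 1 + 1e-12) ||
      any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("`mat` is not row-stochastic", call. = FALSE)
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1) {
    stop("`n_cycles` must be at least 1", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (length(initial) != k || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("`initial` must be a length-", k,
         " non-negative vector summing to 1", call. = FALSE)
  }
  states <- colnames(m) %||% paste0("S", seq_len(k))
  membership <- matrix(0, n_cycles + 1L, k,
                       dimnames = list(cycle = 0:n_cycles, state = states))
  membership[1L, ] <- initial
  for (t in seq_len(n_cycles)) {
    membership[t + 1L, ] <- membership[t, ] %*% m
  }
  occupancy <- if (half_cycle) {
    (membership[-(n_cycles + 1L), , drop = FALSE] +
       membership[-1L, , drop = FALSE]) / 2
  } else {
    membership[-1L, , drop = FALSE]
  }
  dimnames(occupancy) <- list(cycle = seq_len(n_cycles), state = states)
  structure(
    list(membership = membership, occupancy = occupancy,
         n_cycles = n_cycles, half_cycle = half_cycle, states = states),
    class = "markov_trace"
  )
}

#' @export
print.markov_trace <- function(x, ...) {
  cat("Markov cohort trace:", x$n_cycles, "cycles,",
      if (x$half_cycle) "half-cycle corrected" else "end-of-cycle occupancy",
      "\n")
  cat("Final membership:",
      paste(sprintf("%s %.4f", x$states, x$membership[nrow(x$membership), ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Patient-level microsimulation of a transition matrix
#'
#' Simulates `n_individuals` independent patients through the chain with
#' categorical draws and returns the empirical state-membership fractions at
#' each cycle boundary. Used as a stochastic oracle for the deterministic
#' cohort trace: at large `n_individuals` the empirical fractions agree with
#' [run_trace()] membership to within binomial sampling error.
#'
#' @param mat Row-stochastic transition matrix.
#' @param n_individuals Number of simulated patients, at least 1.
#' @param n_cycles Number of cycles.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @param initial Initial state distribution; default all in the first state.
#' @return A `(n_cycles + 1) x k` matrix of empirical membership fractions.
#' @export
microsim_oracle <- function(mat, n_individuals, n_cycles, seed,
                            initial = c(1, 0, 0)) {
  m <- unclass(mat)
  k <- nrow(m)
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("`n_individuals` must be at least 1", call. = FALSE)
  }
  n_individuals <- as.integer(n_individuals)
  if (length(initial) != k || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("`initial` must be a length-", k, " distribution", call. = FALSE)
  }
  set.seed(seed)
  states <- colnames(m) %||% paste0("S", seq_len(k))
  cum <- t(apply(m, 1, cumsum))
  state <- sample.int(k, n_individuals, replace = TRUE, prob = initial)
  memb <- matrix(0, n_cycles + 1L, k,
                 dimnames = list(cycle = 0:n_cycles, state = states))
  memb[1L, ] <- tabulate(state, k) / n_individuals
  absorbing <- which(diag(m) == 1)
  for (t in seq_len(n_cycles)) {
    live <- which(!(state %in% absorbing))
    if (length(live)) {
      u <- runif(length(live))
      s_live <- state[live]
      nxt <- s_live
      for (s in unique(s_live)) {
        idx <- s_live == s
        nxt[idx] <- findInterval(u[idx], cum[s, -k]) + 1L
      }
      state[live] <- nxt
    }
    memb[t + 1L, ] <- tabulate(state, k) / n_individuals
  }
  memb
}

#' Undiscounted person-months per state
#'
#' Column sums of a trace's (half-cycle-corrected) occupancy: the expected
#' undiscounted person-months spent in each state per index patient, plus the
#' total time alive (all states except death).
#'
#' @param trace A `markov_trace`.
#' @return Named vector of per-state person-months with an `alive` total.
#' @export
life_months <- function(trace) {
  stopifnot(inherits(trace, "markov_trace"))
  per_state <- colSums(trace$occupancy)
  alive <- sum(per_state[setdiff(trace$states, "D")])
  c(per_state, alive = alive)
}

#' Export a trace as a delimited table
#'
#' Writes cycle-by-cycle membership and occupancy as CSV with columns
#' `cycle,p_dfs,p_pd,p_dead,occ_dfs,occ_pd` at 10-decimal precision.
#' Cycle 0 has no occupancy entry (occupancy spans cycles, not boundaries).
#'
#' @param trace A `markov_trace` over the DFS/PD/D states.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "markov_trace"))
  n <- trace$n_cycles
  df <- data.frame(
    cycle = 0:n,
    p_dfs = sprintf("%.10f", trace$membership[, "DFS"]),
    p_pd = sprintf("%.10f", trace$membership[, "PD"]),
    p_dead = sprintf("%.10f", trace$membership[, "D"]),
    occ_dfs = c("", sprintf("%.10f", trace$occupancy[, "DFS"])),
    occ_pd = c("", sprintf("%.10f", trace$occupancy[, "PD"]))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
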