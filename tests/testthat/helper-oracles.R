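# Independent oracles used to check the implementation. These deliberately
# reimplement the quantities with the most direct method available
# (dynamic programming, exhaustive enumeration, plain summation) and stay
# separate from the package's computation paths.

# Exact Poisson-binomial pmf by dynamic programming over the Bernoulli
# success probabilities p.
poisbin_pmf <- function(p) {
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  f
}

# Total variation distance between two pmfs on 0..n (shorter one padded).
tv_dist <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}

# All feasible candidates (ward, day) of one patient, with costs from the
# public single-candidate cost path. Dismissal is always a candidate.
oracle_candidates <- function(patient, hospital, ledger, k, weights,
                              mode = "inverted", penalty = 1e6) {
  nd <- hospital$wards[!hospital$wards$is_dummy, ]
  out <- list(tibble::tibble(ward_id = NA_integer_, t = NA_integer_,
                             alpha = 0, beta = 0, gamma = 0, delta = 0,
                             total = penalty))
  for (w in nd$id) {
    if (hospital$wards[[patient$preference]][match(w, hospital$wards$id)] == 0) next
    if (affinity(hospital, patient$clinic_id, w) == 0) next
    for (t in priority_window_oracle(patient$priority, k)) {
      cb <- assignment_cost(patient, w, t, ledger, weights = weights,
                            mode = mode, penalty = penalty)
      out[[length(out) + 1L]] <- tibble::tibble(ward_id = w, t = t,
                                                alpha = cb$alpha,
                                                beta = cb$beta,
                                                gamma = cb$gamma,
                                                delta = cb$delta,
                                                total = cb$total)
    }
  }
  dplyr::bind_rows(out)
}

priority_window_oracle <- function(priority, k) {
  if (priority <= 1) 1L else if (priority == 2) seq_len(min(7L, k)) else
    seq_len(k)
}

# Direct check of the windowed capacity constraints for a full assignment:
# for every preference class, ward and day t, the number of collective
# admissions within [t - l_max, t] must not exceed the floored expected free
# contingent.
oracle_feasible <- function(assign, patients, hospital, ledger, k, l_max) {
  ok <- TRUE
  for (b in unique(patients$preference)) {
    idx <- which(patients$preference == b & !is.na(assign$ward_id))
    if (!length(idx)) next
    for (w in unique(assign$ward_id[idx])) {
      kk <- hospital$wards[[b]][match(w, hospital$wards$id)]
      for (t in 1:k) {
        used <- sum(assign$ward_id[idx] == w &
                      assign$t[idx] >= max(1, t - l_max) &
                      assign$t[idx] <= t)
        free <- max(0, kk - expected_usage(ledger, w, b,
                                           ledger$current_day + t - 1))
        if (used > free + 1e-9) ok <- FALSE
      }
    }
  }
  ok
}

# Exhaustive minimum-cost assignment: enumerate the full cartesian product
# of per-patient candidates (including dismissal), order by total cost and
# return the first feasible combination. Only usable when the product is
# small.
oracle_optimum <- function(patients, hospital, ledger, k, weights,
                           mode = "inverted", penalty = 1e6,
                           max_combos = 3e5) {
  n <- nrow(patients)
  cands <- lapply(seq_len(n), function(i) {
    oracle_candidates(patients[i, ], hospital, ledger, k, weights, mode,
                      penalty)
  })
  sizes <- vapply(cands, nrow, integer(1))
  stopifnot(prod(sizes) <= max_combos)
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  tot_mat <- vapply(seq_len(n), function(i) {
    cands[[i]]$total[grid[, i]]
  }, numeric(nrow(grid)))
  if (is.null(dim(tot_mat))) tot_mat <- matrix(tot_mat, nrow = nrow(grid))
  totals <- rowSums(tot_mat)
  l_max <- max(ceiling(patients$mean_days))
  for (ri in order(totals)) {
    assign <- tibble::tibble(
      ward_id = vapply(seq_len(n), function(i) cands[[i]]$ward_id[grid[ri, i]],
                       integer(1)),
      t = vapply(seq_len(n), function(i) cands[[i]]$t[grid[ri, i]],
                 integer(1))
    )
    if (oracle_feasible(assign, patients, hospital, ledger, k, l_max)) {
      return(list(total = totals[ri], assign = assign))
    }
  }
  stop("no feasible combination found (dismissal should always be feasible)")
}
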