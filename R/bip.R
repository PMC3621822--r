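# Binary integer program for one planning cycle. One binary variable x_ijt
# per feasible (patient, ward, admission day); the objective is the summed
# four-factor assignment cost; constraint families, per preference class b:
#   (A) completeness: every patient of class b is assigned somewhere
#       (the dummy ward guarantees feasibility; a dummy assignment is a
#       dismissal at penalty cost),
#   (B) uniqueness: at most one (ward, day) per patient,
#   (C) capacity: for every (ward, day), the admissions of the last l_max
#       days may not exceed the expected free contingent K_jb - E[U_jtb],
#       floored at zero.

#' Build the assignment BIP for a planning cycle
#'
#' @param query A [planning_query()].
#' @param hospital A `ward_hospital`.
#' @param ledger A `ward_ledger`; its expected usage supplies the constant
#'   cost coefficients and capacity right-hand sides.
#' @param weights A [cost_weights()].
#' @param mode Affinity cost mode, see [alpha_cost()].
#' @param penalty Dismissal (dummy ward) penalty.
#' @param dense If `TRUE`, build the dense counting configuration used for
#'   sizing arithmetic: a single preference class, every non-dummy ward and
#'   every admission day eligible for every patient, and no dummy-ward
#'   variables. Not meant for solving.
#' @return A `ward_bip` object with the variable table, sparse constraint
#'   triplets, senses, right-hand sides and bookkeeping metadata.
#' @export
build_bip <- function(query, hospital, ledger, weights = cost_weights(),
                      mode = c("inverted", "literal"), penalty = 1e6,
                      dense = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "ward_query"), inherits(hospital, "ward_hospital"),
            inherits(ledger, "ward_ledger"))
  k <- query$timeframe_days
  l_max <- query$l_max
  if (ledger$horizon < k + l_max + 2L) {
    abort(sprintf(
      "ledger horizon (%d) too short: need at least k + l_max + 2 = %d days",
      ledger$horizon, k + l_max + 2L))
  }
  pats <- query$patients
  if (dense) pats$preference <- "single"
  H <- k + l_max + 2L
  days_abs <- ledger$current_day + 0:(H - 1L)
  eu <- usage_matrix(ledger, days_abs)
  caps <- capacity_vector(hospital)
  dummy_id <- hospital$wards$id[hospital$wards$is_dummy]

  vars <- build_vars(pats, hospital, eu, caps, k, weights, mode, penalty,
                     dense, dummy_id)
  if (!nrow(vars)) {
    return(structure(list(
      vars = vars, obj = numeric(), triplets = tibble(row = integer(),
      col = integer(), val = numeric()), sense = character(),
      rhs = numeric(), n_var = 0L, n_cons = 0L, query = query,
      penalty = penalty, meta = list(k = k, l_max = l_max)
    ), class = "ward_bip"))
  }

  classes <- unique(pats$preference)
  pat_ids <- pats$patient_id

  # (A) completeness, one equality per preference class present
  comp_row <- match(vars$preference, classes)
  comp_rhs <- vapply(classes, function(b) sum(pats$preference == b),
                     numeric(1))
  # (B) uniqueness, one row per patient
  uni_off <- length(classes)
  uni_row <- uni_off + match(vars$patient_id, pat_ids)
  # (C) capacity, one row per (class-eligible ward, day)
  cap_off <- uni_off + length(pat_ids)
  pairs <- dplyr::distinct(vars, .data$preference, .data$ward_id)
  pairs <- arrange(pairs, match(.data$preference, classes), .data$ward_id)
  pair_key <- key_wb(pairs$ward_id, pairs$preference)
  vars$pair_idx <- match(key_wb(vars$ward_id, vars$preference), pair_key)
  wlen <- pmin(1:k, l_max + 1L)
  win <- tibble(
    t_row = rep.int(1:k, wlen),
    t1 = unlist(lapply(1:k, function(t) seq.int(max(1L, t - l_max), t)))
  )
  cap <- inner_join(
    tibble(col = vars$var_id, pair_idx = vars$pair_idx, t1 = vars$t),
    win, by = "t1", relationship = "many-to-many"
  )
  cap_row <- cap_off + (cap$pair_idx - 1L) * k + cap$t_row
  # rhs: expected free contingent per (pair, day), floored at 0
  eu_t <- eu[pair_key, seq_len(k), drop = FALSE]
  free_t <- pmax(caps[pair_key] - eu_t, 0)  # pairs x k, floored at 0
  cap_rhs <- as.vector(t(free_t))           # row index (pair - 1) * k + t

  triplets <- tibble(
    row = c(comp_row, uni_row, cap_row),
    col = c(vars$var_id, vars$var_id, cap$col),
    val = 1
  )
  n_cons <- cap_off + nrow(pairs) * k
  structure(list(
    vars = vars,
    obj = vars$total,
    triplets = triplets,
    sense = c(rep("E", length(classes)), rep("L", length(pat_ids)),
              rep("L", nrow(pairs) * k)),
    rhs = c(comp_rhs, rep(1, length(pat_ids)), cap_rhs),
    n_var = nrow(vars),
    n_cons = n_cons,
    query = query,
    penalty = penalty,
    meta = list(k = k, l_max = l_max, classes = classes, pairs = pairs,
                cap_off = cap_off,
                cap_rhs = `dimnames<-`(free_t, list(pair_key, NULL)))
  ), class = "ward_bip")
}

# variable table: one row per feasible (patient, ward, admission day)
build_vars <- function(pats, hospital, eu, caps, k, weights, mode, penalty,
                       dense, dummy_id) {
  if (!nrow(pats)) {
    return(tibble(var_id = integer(), patient_id = character(),
                  preference = character(), ward_id = integer(),
                  t = integer(), alpha = numeric(), beta = numeric(),
                  gamma = numeric(), delta = numeric(), total = numeric(),
                  is_dummy = logical()))
  }
  nd <- hospital$wards[!hospital$wards$is_dummy, ]
  rows <- vector("list", nrow(pats) * 4L)
  r <- 0L
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    tt <- if (dense) seq_len(k) else priority_window(p$priority, k)
    if (dense) {
      wids <- nd$id
      affs <- affinity(hospital, p$clinic_id, wids)
    } else {
      ok <- nd[[p$preference]] > 0
      wids <- nd$id[ok]
      affs <- affinity(hospital, p$clinic_id, wids)
      wids <- wids[affs > 0]
      affs <- affs[affs > 0]
    }
    for (wi in seq_along(wids)) {
      key <- key_wb(wids[wi], p$preference)
      cc <- candidate_cost_curve(eu[key, ] / max(caps[key], 1L), k,
                                 p$mean_days, p$priority, affs[wi],
                                 weights, mode)
      r <- r + 1L
      rows[[r]] <- tibble(
        patient_id = p$patient_id, preference = p$preference,
        ward_id = wids[wi], t = as.integer(tt),
        alpha = cc["alpha", tt], beta = cc["beta", tt],
        gamma = cc["gamma", tt], delta = cc["delta", tt],
        total = cc["total", tt], is_dummy = FALSE
      )
    }
    if (!dense) {
      r <- r + 1L
      rows[[r]] <- tibble(
        patient_id = p$patient_id, preference = p$preference,
        ward_id = dummy_id, t = as.integer(tt),
        alpha = 0, beta = 0, gamma = 0, delta = 0,
        total = penalty, is_dummy = TRUE
      )
    }
  }
  vars <- bind_rows(rows[seq_len(r)])
  vars$var_id <- seq_len(nrow(vars))
  vars[c("var_id", setdiff(names(vars), "var_id"))]
}

#' @export
print.ward_bip <- function(x, ...) {
  cat(sprintf("<ward_bip> %s binary variables, %s constraints\n",
              format(x$n_var, big.mark = ","),
              format(x$n_cons, big.mark = ",")))
  invisible(x)
}

python_binary <- function() {
  p <- Sys.getenv("WARDOPT_PYTHON", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  ""
}

backend_script <- function() {
  system.file("python", "milp_backend.py", package = "wardopt")
}

#' Solve an assignment BIP
#'
#' Solves the program with a pluggable MILP backend under a time limit.
#' `"highs"` hands the model to the HiGHS solver through the system `python`
#' (`scipy.optimize.milp`); `"dfs"` is a pure-R depth-first branch-and-bound
#' suitable for small instances; `"auto"` picks HiGHS when a python
#' interpreter is available and falls back to `"dfs"`. Hitting the time
#' limit dismisses the whole collective: the planning cycle is abandoned
#' rather than executed from a possibly poor incumbent.
#'
#' @param model A `ward_bip` from [build_bip()].
#' @param time_limit Wall-clock limit in seconds.
#' @param backend `"auto"`, `"highs"` or `"dfs"`.
#' @return A `ward_solution`: list with `status` (`"optimal"`, `"timeout"`
#'   or `"error"`), `decisions` (one row per patient: `patient_id`,
#'   `status`, `ward_id`, `t`, cost breakdown), `objective_value` and
#'   `solve_seconds`.
#' @export
solve_bip <- function(model, time_limit = 300,
                      backend = c("auto", "highs", "dfs")) {
  stopifnot(inherits(model, "ward_bip"))
  backend <- match.arg(backend)
  check_scalar_number(time_limit, "time_limit", min = 0)
  t0 <- proc.time()[["elapsed"]]
  if (model$n_var == 0L) {
    return(new_solution("optimal", decisions_for(model, integer()), model,
                        0))
  }
  if (backend == "auto") {
    backend <- if (nzchar(python_binary())) "highs" else "dfs"
  }
  res <- switch(backend,
    highs = solve_highs(model, time_limit),
    dfs = solve_dfs(model, time_limit)
  )
  res$solve_seconds <- proc.time()[["elapsed"]] - t0
  res
}

new_solution <- function(status, decisions, model, seconds,
                         solver_objective = NULL) {
  obj <- if (is.null(decisions)) NA_real_ else sum(decisions$total)
  if (!is.null(solver_objective) && !is.null(decisions) &&
      abs(solver_objective - obj) > 1e-6 * max(1, abs(obj))) {
    abort(sprintf(
      "solver objective %.8g does not match decoded assignment cost %.8g",
      solver_objective, obj))
  }
  structure(list(status = status, decisions = decisions,
                 objective_value = obj, solve_seconds = seconds),
            class = "ward_solution")
}

# translate selected variable ids into one decision row per patient
decisions_for <- function(model, selected) {
  pats <- model$query$patients
  v <- model$vars[model$vars$var_id %in% selected & !model$vars$is_dummy, ]
  m <- match(pats$patient_id, v$patient_id)
  tibble(
    patient_id = pats$patient_id,
    status = ifelse(is.na(m), "dismissed", "assigned"),
    ward_id = ifelse(is.na(m), NA_integer_, v$ward_id[m]),
    t = ifelse(is.na(m), NA_integer_, v$t[m]),
    alpha = ifelse(is.na(m), 0, v$alpha[m]),
    beta = ifelse(is.na(m), 0, v$beta[m]),
    gamma = ifelse(is.na(m), 0, v$gamma[m]),
    delta = ifelse(is.na(m), 0, v$delta[m]),
    total = ifelse(is.na(m), model$penalty, v$total[m])
  )
}

all_dismissed <- function(model) {
  pats <- model$query$patients
  tibble(
    patient_id = pats$patient_id, status = "dismissed",
    ward_id = NA_integer_, t = NA_integer_,
    alpha = 0, beta = 0, gamma = 0, delta = 0, total = model$penalty
  )
}

solve_highs <- function(model, time_limit) {
  py <- python_binary()
  if (!nzchar(py)) abort("no python interpreter found for the HiGHS backend")
  script <- backend_script()
  if (!nzchar(script)) abort("milp_backend.py not found in the installed package")
  dir <- tempfile("wardopt-milp-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  model_file <- file.path(dir, "model.json")
  out_file <- file.path(dir, "solution.json")
  jsonlite::write_json(
    list(obj = model$obj, ncons = model$n_cons,
         row = model$triplets$row, col = model$triplets$col,
         val = model$triplets$val, sense = model$sense, rhs = model$rhs,
         time_limit = time_limit),
    model_file, digits = NA
  )
  status <- system2(py, c(script, model_file, out_file),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out_file)) {
    return(new_solution("error", NULL, model, NA_real_))
  }
  res <- jsonlite::fromJSON(out_file)
  if (res$status == 0) {
    sel <- as.integer(res$x %||% integer())
    new_solution("optimal", decisions_for(model, sel), model, NA_real_,
                 solver_objective = res$objective)
  } else if (res$status == 1) {
    # time limit reached: abandon the cycle, dismiss everyone
    new_solution("timeout", all_dismissed(model), model, NA_real_)
  } else {
    new_solution("error", NULL, model, NA_real_)
  }
}

# Depth-first branch and bound over patients; candidates per patient sorted
# by cost, capacity tracked through the same windowed rows as the BIP.
solve_dfs <- function(model, time_limit) {
  vars <- model$vars
  pats <- model$query$patients$patient_id
  k <- model$meta$k
  l_max <- model$meta$l_max
  rhs <- model$meta$cap_rhs
  by_pat <- lapply(pats, function(pid) {
    v <- vars[vars$patient_id == pid, ]
    v[order(v$total, v$t, v$ward_id), ]
  })
  min_cost <- vapply(by_pat, function(v) min(v$total), numeric(1))
  suffix_min <- rev(cumsum(rev(min_cost)))
  W <- matrix(0L, nrow = nrow(rhs), ncol = k,
              dimnames = dimnames(rhs))
  best <- list(cost = Inf, sel = NULL)
  deadline <- Sys.time() + time_limit
  timed_out <- FALSE

  recurse <- function(i, cost, sel) {
    if (timed_out) return()
    if (Sys.time() > deadline) {
      timed_out <<- TRUE
      return()
    }
    if (i > length(by_pat)) {
      if (cost < best$cost - 1e-12) best <<- list(cost = cost, sel = sel)
      return()
    }
    if (cost + suffix_min[i] >= best$cost - 1e-12) return()
    v <- by_pat[[i]]
    for (ci in seq_len(nrow(v))) {
      key <- key_wb(v$ward_id[ci], v$preference[ci])
      t0 <- v$t[ci]
      rows <- t0:min(t0 + l_max, k)
      if (any(W[key, rows] + 1 > rhs[key, rows])) next
      W[key, rows] <<- W[key, rows] + 1L
      recurse(i + 1L, cost + v$total[ci], c(sel, v$var_id[ci]))
      W[key, rows] <<- W[key, rows] - 1L
    }
  }
  recurse(1L, 0, integer())
  if (timed_out) {
    new_solution("timeout", all_dismissed(model), model, NA_real_)
  } else if (!is.finite(best$cost)) {
    new_solution("error", NULL, model, NA_real_)
  } else {
    new_solution("optimal", decisions_for(model, best$sel), model, NA_real_)
  }
}

#' Extract assignment decisions from a solved BIP
#'
#' One decision per patient of the underlying query; dummy-ward selections
#' appear as dismissals carrying the penalty cost.
#'
#' @param solution A `ward_solution` from [solve_bip()].
#' @param query The `ward_query` the model was built from (consistency
#'   check).
#' @return The decision tibble.
#' @export
decode_solution <- function(solution, query) {
  stopifnot(inherits(solution, "ward_solution"))
  if (solution$status == "error") abort("cannot decode a failed solve")
  d <- solution$decisions
  if (!setequal(d$patient_id, query$patients$patient_id)) {
    abort("solution does not cover the query's patients")
  }
  d
}

#' @export
print.ward_solution <- function(x, ...) {
  cat(sprintf(
    "<ward_solution> status %s, objective %.6g, %d/%d assigned, %.2fs\n",
    x$status, x$objective_value,
    if (is.null(x$decisions)) 0L else sum(x$decisions$status == "assigned"),
    if (is.null(x$decisions)) 0L else nrow(x$decisions),
    x$solve_seconds
  ))
  invisible(x)
}

# capacity-row replay used by tests and the simulation consistency audit:
# TRUE when `decisions` respect every windowed capacity row of `model`
replay_capacity <- function(model, decisions) {
  k <- model$meta$k
  l_max <- model$meta$l_max
  rhs <- model$meta$cap_rhs
  W <- matrix(0L, nrow = nrow(rhs), ncol = k, dimnames = dimnames(rhs))
  d <- decisions[decisions$status == "assigned", ]
  pref <- model$query$patients$preference[
    match(d$patient_id, model$query$patients$patient_id)]
  for (i in seq_len(nrow(d))) {
    key <- key_wb(d$ward_id[i], pref[i])
    rows <- d$t[i]:min(d$t[i] + l_max, k)
    W[key, rows] <- W[key, rows] + 1L
  }
  all(W <= rhs + 1e-9)
}

#' Export a BIP in LP-format text
#'
#' Writes the model in the plain LP text format understood by most MILP
#' tools, mainly for debugging model construction.
#'
#' @param model A `ward_bip`.
#' @param path Output file path.
#' @export
write_lp <- function(model, path) {
  stopifnot(inherits(model, "ward_bip"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("\\* wardopt admission assignment BIP *\\", con)
  writeLines("Minimize", con)
  obj_terms <- sprintf("%.12g x%d", model$obj, seq_len(model$n_var))
  writeLines(paste(" obj:", paste(obj_terms, collapse = " + ")), con)
  writeLines("Subject To", con)
  if (model$n_cons > 0L) {
    by_row <- split(model$triplets$col, model$triplets$row)
    for (r in seq_len(model$n_cons)) {
      cols <- by_row[[as.character(r)]]
      if (is.null(cols)) cols <- integer()
      lhs <- if (length(cols)) {
        paste(sprintf("x%d", sort(cols)), collapse = " + ")
      } else {
        "0 x1"
      }
      rel <- if (model$sense[r] == "E") "=" else "<="
      writeLines(sprintf(" c%d: %s %s %.12g", r, lhs, rel, model$rhs[r]),
                 con)
    }
  }
  writeLines("Binaries", con)
  writeLines(paste("", paste(sprintf("x%d", seq_len(model$n_var)),
                             collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}
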