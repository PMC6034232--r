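markov_states <- c("stable", "progression", "transplant", "dead")

# weight of one stream component in cycle c, given occupancies/flows
stream_weight <- function(comp, c, occ, flows) {
  if (c < comp$cycle_from || c > comp$cycle_to) return(0)
  if (!is.na(comp$every) && (c - comp$cycle_from) %% comp$every != 0)
    return(0)
  s0 <- occ[c, "stable"]; s1 <- occ[c + 1, "stable"]
  p0 <- occ[c, "progression"]; p1 <- occ[c + 1, "progression"]
  tr0 <- occ[c, "transplant"]; tr1 <- occ[c + 1, "transplant"]
  switch(comp$basis,
         entry_fixed = 1,
         stable_cont = (s0 + s1) / 2,
         alive_cont = (s0 + p0 + s1 + p1) / 2,
         alive_point = s1 + p1,
         prog_inflow = flows[c, "stable_prog"],
         transplant_inflow = flows[c, "stable_transplant"],
         transplant_cont = (tr0 + tr1) / 2,
         stop("unknown cost basis: ", comp$basis, call. = FALSE))
}

#' Run the cohort Markov model
#'
#' Propagates a hypothetical cohort that enters entirely in the stable-disease
#' state through the per-cycle transition schedule, accumulating state
#' occupancies and undiscounted costs by category. Death and transplant are
#' absorbing. One-off costs are charged on state inflow (subsequent
#' treatments on entry into progression, the transplant tariff on entry into
#' transplant; first-line treatment on cohort entry); continuously accruing
#' costs (drug, decompensation, post-transplant maintenance) use mid-cycle
#' (trapezoid) occupancy; scheduled point costs (quarterly follow-up) use
#' end-of-cycle alive occupancy. Life-months are end-of-cycle alive
#' occupancy sums (no half-cycle correction).
#'
#' @param schedule A [transition_schedule()].
#' @param streams A `cost_streams` table (see [build_cost_streams()]); may be
#'   `NULL` for a cost-free run.
#' @param horizon_cycles Defaults to the schedule horizon; must not exceed it.
#' @return An object of class `markov_trace`: `occupancy` (rows `0:H`),
#'   `flows`, `costs` (rows `1:H`, one column per category), `cycle_months`.
#' @export
run_cohort <- function(schedule, streams = NULL, horizon_cycles = NULL) {
  stopifnot(inherits(schedule, "transition_schedule"))
  H <- schedule$horizon_cycles
  if (!is.null(horizon_cycles)) {
    if (horizon_cycles > H)
      stop("horizon exceeds the schedule length", call. = FALSE)
    H <- as.integer(horizon_cycles)
  }
  if (!is.null(streams) && max(streams$cycle_from) > H)
    stop("cost stream starts beyond the model horizon", call. = FALSE)
  q <- schedule$schedule
  occ <- matrix(0, H + 1, 4, dimnames = list(NULL, markov_states))
  occ[1, "stable"] <- 1
  flows <- matrix(0, H, 4, dimnames = list(NULL, c(
    "stable_prog", "stable_death", "stable_transplant", "prog_death")))
  for (c in seq_len(H)) {
    s <- occ[c, "stable"]; p <- occ[c, "progression"]
    f_sp <- s * q$q_stable_prog[c]
    f_sd <- s * q$q_stable_death[c]
    f_st <- s * q$q_stable_transplant[c]
    f_pd <- p * q$q_prog_death[c]
    occ[c + 1, "stable"] <- s - f_sp - f_sd - f_st
    occ[c + 1, "progression"] <- p + f_sp - f_pd
    occ[c + 1, "transplant"] <- occ[c, "transplant"] + f_st
    occ[c + 1, "dead"] <- occ[c, "dead"] + f_sd + f_pd
    flows[c, ] <- c(f_sp, f_sd, f_st, f_pd)
  }
  if (max(abs(rowSums(occ) - 1)) > 1e-9)
    stop("occupancy not conserved", call. = FALSE)
  costs <- matrix(0, H, length(cost_categories),
                  dimnames = list(NULL, cost_categories))
  if (!is.null(streams)) {
    for (r in seq_len(nrow(streams))) {
      comp <- streams[r, ]
      lo <- comp$cycle_from
      hi <- min(comp$cycle_to, H)
      if (lo > hi) next
      for (c in lo:hi) {
        w <- stream_weight(comp, c, occ, flows)
        if (w != 0)
          costs[c, comp$category] <- costs[c, comp$category] +
            comp$amount * w
      }
    }
  }
  structure(list(occupancy = occ, flows = flows, costs = costs,
                 cycle_months = schedule$cycle_months),
            class = "markov_trace")
}

trace_alive <- function(trace) {
  rowSums(trace$occupancy[, c("stable", "progression", "transplant")])
}

#' Per-patient outcomes from a cohort trace
#'
#' Sums costs (total and by category) and life-months up to a horizon.
#' `horizon_months = Inf` uses the full trace (the lifetime horizon).
#' A zero horizon yields zero cost and zero life-months: entry charges are
#' booked in cycle 1, so they are included in any horizon of at least one
#' cycle.
#'
#' @param trace A `markov_trace`.
#' @param horizon_months Months (a multiple of the cycle length) or `Inf`.
#' @return List of class `per_patient_outcomes`: `horizon_months`,
#'   `life_months`, `cost_total`, `cost_by_category`.
#' @export
outcomes <- function(trace, horizon_months = Inf) {
  stopifnot(inherits(trace, "markov_trace"), horizon_months >= 0)
  H <- nrow(trace$costs)
  h <- if (is.infinite(horizon_months)) H else
    as.integer(round(horizon_months / trace$cycle_months))
  if (h > H) stop("horizon exceeds the trace length", call. = FALSE)
  idx <- seq_len(h)
  by_cat <- if (h > 0) colSums(trace$costs[idx, , drop = FALSE]) else
    stats::setNames(numeric(length(cost_categories)), cost_categories)
  alive <- trace_alive(trace)
  life <- if (h > 0) sum(alive[1 + idx]) * trace$cycle_months else 0
  structure(list(horizon_months = horizon_months, life_months = life,
                 cost_total = sum(by_cat), cost_by_category = by_cat),
            class = "per_patient_outcomes")
}

#' Patient-level microsimulation of the same process
#'
#' Simulates individual patients through the transition schedule and cost
#' streams, mirroring the cohort engine's charging conventions exactly, and
#' reports the mean and standard deviation of per-patient cost and
#' life-months. Serves as the Monte-Carlo oracle for the cohort engine: the
#' cohort trace is the `n -> Inf` limit of these means.
#'
#' @param schedule A [transition_schedule()].
#' @param streams A `cost_streams` table (may be `NULL`).
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @param horizon_months Horizon for the reported outcomes (default: full
#'   schedule).
#' @return List of class `microsim_outcomes`: `n`, `cost_mean`, `cost_sd`,
#'   `cost_by_category` (means), `life_months_mean`, `life_months_sd`.
#' @export
microsimulate <- function(schedule, streams = NULL, n_patients = 10000L,
                          seed = 1L, horizon_months = Inf) {
  stopifnot(inherits(schedule, "transition_schedule"), n_patients >= 1)
  set.seed(as.integer(seed))
  H <- schedule$horizon_cycles
  h <- if (is.infinite(horizon_months)) H else
    as.integer(round(horizon_months / schedule$cycle_months))
  stopifnot(h <= H)
  q <- schedule$schedule
  n <- as.integer(n_patients)
  state <- rep.int(1L, n)  # 1 stable, 2 progression, 3 transplant, 4 dead
  cost <- numeric(n)
  by_cat <- stats::setNames(numeric(length(cost_categories)),
                            cost_categories)
  life <- numeric(n)
  active <- !is.null(streams) && nrow(streams) > 0
  if (active) {
    # entry_fixed components do not depend on the state path: add once
    for (r in which(streams$basis == "entry_fixed")) {
      comp <- streams[r, ]
      cyc <- seq(comp$cycle_from, min(comp$cycle_to, h),
                 by = if (is.na(comp$every)) 1L else comp$every)
      cyc <- cyc[cyc >= 1]
      add <- comp$amount * length(cyc)
      cost <- cost + add
      by_cat[comp$category] <- by_cat[comp$category] + add * n
    }
    streams <- streams[streams$basis != "entry_fixed", , drop = FALSE]
    active <- nrow(streams) > 0
  }
  for (c in seq_len(h)) {
    prev <- state
    st <- which(prev == 1L)
    if (length(st)) {
      u <- stats::runif(length(st))
      p1 <- q$q_stable_prog[c]
      p2 <- p1 + q$q_stable_transplant[c]
      p3 <- p2 + q$q_stable_death[c]
      state[st[u < p1]] <- 2L
      state[st[u >= p1 & u < p2]] <- 3L
      state[st[u >= p2 & u < p3]] <- 4L
    }
    pr <- which(prev == 2L)
    if (length(pr)) {
      u <- stats::runif(length(pr))
      state[pr[u < q$q_prog_death[c]]] <- 4L
    }
    life <- life + (state != 4L) * schedule$cycle_months
    if (active) {
      for (r in seq_len(nrow(streams))) {
        comp <- streams[r, ]
        if (c < comp$cycle_from || c > comp$cycle_to) next
        if (!is.na(comp$every) &&
            (c - comp$cycle_from) %% comp$every != 0) next
        w <- switch(comp$basis,
                    stable_cont = ((prev == 1L) + (state == 1L)) / 2,
                    alive_cont = ((prev <= 2L) + (state <= 2L)) / 2,
                    alive_point = as.numeric(state <= 2L),
                    prog_inflow = as.numeric(prev == 1L & state == 2L),
                    transplant_inflow = as.numeric(prev == 1L &
                                                     state == 3L),
                    transplant_cont = ((prev == 3L) + (state == 3L)) / 2)
        add <- comp$amount * w
        cost <- cost + add
        by_cat[comp$category] <- by_cat[comp$category] + sum(add)
      }
    }
    if (all(state == 4L)) break
  }
  structure(list(n = n,
                 cost_mean = mean(cost), cost_sd = stats::sd(cost),
                 cost_by_category = by_cat / n,
                 life_months_mean = mean(life),
                 life_months_sd = stats::sd(life)),
            class = "microsim_outcomes")
}

#' Export a Markov trace as CSV
#' @param trace A `markov_trace`.
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  H <- nrow(trace$costs)
  df <- data.frame(cycle = 0:H, trace$occupancy,
                   rbind(0, trace$costs), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
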