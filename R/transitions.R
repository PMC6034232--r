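#' Per-cycle transition probabilities from OS and PFS curves
#'
#' Partitioned-survival conversion: at each cycle boundary the target
#' occupancies are stable = PFS, dead = 1 - OS, progressed = OS - PFS
#' (before any transplant adjustment). The per-cycle probabilities are chosen
#' so the cohort propagated by them reproduces those targets exactly. Deaths
#' within a cycle are attributed to the progression state first, up to its
#' occupancy, with the remainder taken from stable
#' (`death_attribution = "progression_first"`, the default), or split
#' proportionally to occupancy (`"proportional"`).
#'
#' Liver transplantation (intermediate-stage TARE) is modelled as an extra
#' absorbing state fed from stable by a uniform inflow of
#' `transplant_cum_share / 12` per cycle over the first 12 cycles, so the
#' cumulative transplanted share after one year equals
#' `transplant_cum_share` exactly.
#'
#' @param os_fit,pfs_fit `parametric_fit` objects. PFS is clipped to OS where
#'   it exceeds it (a warning is logged when the excess is material).
#' @param cycle_months Cycle length in months (default 1).
#' @param horizon_cycles Number of cycles (default 480, i.e. 40 years).
#' @param transplant_cum_share Cumulative transplanted share over the first
#'   year (0 disables the state).
#' @param death_attribution `"progression_first"` or `"proportional"`.
#' @return Object of class `transition_schedule`: data.frame `schedule` with
#'   columns `cycle`, `q_stable_prog`, `q_stable_death`,
#'   `q_stable_transplant`, `q_prog_death`, plus the boundary `os`/`pfs`
#'   values and settings as attributes.
#' @export
transition_schedule <- function(os_fit, pfs_fit, cycle_months = 1,
                                horizon_cycles = 480L,
                                transplant_cum_share = 0,
                                death_attribution = c("progression_first",
                                                      "proportional")) {
  death_attribution <- match.arg(death_attribution)
  stopifnot(cycle_months > 0, horizon_cycles >= 1,
            transplant_cum_share >= 0, transplant_cum_share < 1)
  H <- as.integer(horizon_cycles)
  tt <- (0:H) * cycle_months
  os <- surv_prob(os_fit, tt)
  pfs <- surv_prob(pfs_fit, tt)
  excess <- max(pfs - os)
  if (excess > 1e-6)
    warning(sprintf("PFS exceeds OS by up to %.3g; clipping PFS to OS",
                    excess))
  pfs <- pmin(pfs, os)
  s <- pfs
  p <- os - pfs
  d <- 1 - os
  q_sp <- q_sd <- q_pd <- q_st <- numeric(H)
  s_adj <- 1  # stable occupancy including the transplant drain
  tol <- 1e-12
  for (c in seq_len(H)) {
    s0 <- s[c]; p0 <- p[c]
    D <- os[c] - os[c + 1]  # deaths this cycle; 1-OS differences lose
    Os <- s[c] - s[c + 1]   # precision once OS is near machine epsilon
    if (death_attribution == "progression_first") {
      Dp <- min(D, p0)
    } else {
      Dp <- if (s0 + p0 > 0) D * p0 / (s0 + p0) else 0
    }
    Ds <- D - Dp
    sp <- Os - Ds
    if (Ds < -tol || sp < -tol)
      stop("transition probabilities out of range at cycle ", c, call. = FALSE)
    Ds <- min(max(Ds, 0), Os)
    sp <- Os - Ds
    q_sd[c] <- if (s0 > 0) Ds / s0 else 0
    q_sp[c] <- if (s0 > 0) sp / s0 else 0
    q_pd[c] <- if (p0 > 0) min(Dp / p0, 1) else 0
    if (transplant_cum_share > 0 && c <= 12) {
      inflow <- transplant_cum_share / 12
      if (s_adj <= inflow)
        stop("transplant share exhausts the stable state at cycle ", c,
             call. = FALSE)
      q_st[c] <- inflow / s_adj
      if (q_st[c] + q_sp[c] + q_sd[c] > 1)
        stop("transition probabilities out of range at cycle ", c,
             call. = FALSE)
    }
    s_adj <- s_adj * (1 - q_sp[c] - q_sd[c] - q_st[c])
  }
  bad <- which(q_sp < -tol | q_sd < -tol | q_pd < -tol | q_st < -tol |
                 q_sp + q_sd + q_st > 1 + 1e-9 | q_pd > 1 + 1e-9)
  if (length(bad))
    stop("transition probabilities out of range at cycle ", bad[1],
         call. = FALSE)
  clamp01 <- function(q) pmin(pmax(q, 0), 1)
  q_sp <- clamp01(q_sp); q_sd <- clamp01(q_sd)
  q_pd <- clamp01(q_pd); q_st <- clamp01(q_st)
  structure(list(
    schedule = data.frame(cycle = seq_len(H), q_stable_prog = q_sp,
                          q_stable_death = q_sd, q_stable_transplant = q_st,
                          q_prog_death = q_pd),
    os = os, pfs = pfs,
    cycle_months = cycle_months, horizon_cycles = H,
    transplant_cum_share = transplant_cum_share,
    death_attribution = death_attribution
  ), class = "transition_schedule")
}

#' Export a transition schedule as CSV
#' @param schedule A `transition_schedule`.
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule$schedule, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
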