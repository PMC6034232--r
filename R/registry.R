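#' Published per-arm, per-stage overall-survival summaries
#'
#' Mean and median overall survival (months) of the matched TARE and sorafenib
#' cohorts by BCLC stage, as reported for the three-centre Italian series that
#' the model is calibrated to.
#'
#' @return A data.frame with columns `arm`, `stage`, `mean`, `median`.
#' @export
default_survival_targets <- function() {
  data.frame(
    arm    = c("TARE", "sorafenib", "TARE", "sorafenib"),
    stage  = c("intermediate", "intermediate", "advanced", "advanced"),
    mean   = c(24.0, 18.4, 14.9, 16.1),
    median = c(18.5, 13.0, 11.2, 11.3),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic patient registry
#'
#' Bundles everything the generator needs: per-centre cohort sizes, covariate
#' prevalences, the treatment-assignment log-odds that induce confounding,
#' the per-arm/per-stage overall-survival targets, the Beta law for the
#' PFS/OS fraction, and the administrative censoring horizon.
#'
#' Stage is deterministic from covariates: portal-vein thrombosis (macrovascular
#' invasion) defines the advanced (BCLC C) stage. The PFS fraction means default
#' to the observed sorafenib treatment durations divided by the sorafenib mean
#' overall survival of the same stage, so that mean PFS in the sorafenib arms
#' matches the published 7.5 / 8.1 month treatment durations.
#'
#' @param centers List of per-centre cohort sizes. Each element is a named
#'   vector `c(tare = ..., sorafenib = ...)`. Defaults to the three published
#'   centre sizes (288/125, 38/42, 63/74).
#' @param pvt_prevalence Probability of portal-vein thrombosis.
#' @param child_pugh_b_prevalence Probability of Child-Pugh class B.
#' @param multinodular_prevalence Probability of multinodular disease.
#' @param assignment Named log-odds of receiving TARE:
#'   `intercept`, `pvt`, `child_pugh_b`, `multinodular`.
#' @param fixed_arm_counts If `TRUE` (default) the per-centre arm counts are
#'   hit exactly by weighted sampling without replacement with weights
#'   `exp(covariate log-odds)`; if `FALSE` treatment is Bernoulli with
#'   probability `plogis(intercept + covariate log-odds)` and `centers` only
#'   fixes the per-centre totals.
#' @param survival_targets Data frame as in [default_survival_targets()].
#' @param pfs_fraction_mean Named per-stage mean of the Beta-distributed
#'   PFS/OS fraction.
#' @param pfs_fraction_concentration Beta concentration (a + b).
#' @param censor_horizon Administrative censoring time in months.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    centers = list(c(tare = 288, sorafenib = 125),
                   c(tare = 38, sorafenib = 42),
                   c(tare = 63, sorafenib = 74)),
    pvt_prevalence = 0.40,
    child_pugh_b_prevalence = 0.25,
    multinodular_prevalence = 0.60,
    assignment = c(intercept = 0.5, pvt = -1.4,
                   child_pugh_b = -0.5, multinodular = -0.3),
    fixed_arm_counts = TRUE,
    survival_targets = default_survival_targets(),
    pfs_fraction_mean = c(intermediate = 7.5 / 18.4, advanced = 8.1 / 16.1),
    pfs_fraction_concentration = 10,
    censor_horizon = 84) {
  cfg <- structure(list(
    centers = centers,
    pvt_prevalence = pvt_prevalence,
    child_pugh_b_prevalence = child_pugh_b_prevalence,
    multinodular_prevalence = multinodular_prevalence,
    assignment = assignment,
    fixed_arm_counts = fixed_arm_counts,
    survival_targets = survival_targets,
    pfs_fraction_mean = pfs_fraction_mean,
    pfs_fraction_concentration = pfs_fraction_concentration,
    censor_horizon = censor_horizon
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- character(0)
  prob_ok <- function(p) is.numeric(p) && length(p) == 1 && p >= 0 && p <= 1
  if (!is.list(cfg$centers) ||
      !all(vapply(cfg$centers, function(x) {
        is.numeric(x) && length(x) == 2 && all(x >= 0) &&
          all(x == round(x)) && all(c("tare", "sorafenib") %in% names(x))
      }, logical(1))))
    bad <- c(bad, "centers")
  for (f in c("pvt_prevalence", "child_pugh_b_prevalence",
              "multinodular_prevalence"))
    if (!prob_ok(cfg[[f]])) bad <- c(bad, f)
  if (!is.numeric(cfg$assignment) ||
      !all(c("intercept", "pvt", "child_pugh_b", "multinodular") %in%
             names(cfg$assignment)))
    bad <- c(bad, "assignment")
  st <- cfg$survival_targets
  if (!is.data.frame(st) || !all(c("arm", "stage", "mean", "median") %in%
                                 names(st)) ||
      any(st$mean <= 0) || any(st$median <= 0) || any(st$mean <= st$median))
    bad <- c(bad, "survival_targets")
  if (!is.numeric(cfg$pfs_fraction_mean) ||
      !all(c("intermediate", "advanced") %in% names(cfg$pfs_fraction_mean)) ||
      any(cfg$pfs_fraction_mean <= 0) || any(cfg$pfs_fraction_mean > 1))
    bad <- c(bad, "pfs_fraction_mean")
  if (!is.numeric(cfg$pfs_fraction_concentration) ||
      cfg$pfs_fraction_concentration <= 0)
    bad <- c(bad, "pfs_fraction_concentration")
  if (!is.numeric(cfg$censor_horizon) || cfg$censor_horizon <= 0)
    bad <- c(bad, "censor_horizon")
  if (length(bad))
    stop("invalid cohort_config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(cfg)
}

empty_registry <- function() {
  data.frame(patient_id = character(0), center = integer(0),
             stage = character(0), child_pugh = character(0),
             nodules = character(0), pvt = logical(0), arm = character(0),
             pfs_months = numeric(0), os_months = numeric(0),
             prog_event = logical(0), death_event = logical(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic patient registry
#'
#' Draws one patient-level registry: covariates per centre, confounded
#' treatment assignment, overall survival from the per-arm/per-stage calibrated
#' Weibull laws, progression-free survival as OS times a Beta-distributed
#' fraction (so PFS <= OS by construction), and administrative censoring at
#' the configured horizon. Each centre uses its own sub-stream derived from the
#' run seed, so regenerating a single centre is reproducible.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical `(config, seed)` give an identical
#'   registry.
#' @return A data.frame (class `hcc_registry`) with one row per patient:
#'   `patient_id`, `center`, `stage`, `child_pugh` (A/B), `nodules`
#'   (single/multinodular), `pvt`, `arm`, `pfs_months`, `os_months`,
#'   `prog_event`, `death_event`. Times are months; event flags are logical
#'   (`FALSE` means administratively censored at the horizon).
#' @export
generate_registry <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  params <- calibrate_targets(config$survival_targets)
  out <- vector("list", length(config$centers))
  for (i in seq_along(config$centers)) {
    set.seed(as.integer(seed) + 7919L * i)  # per-centre sub-stream
    out[[i]] <- generate_center(config, params, i)
  }
  reg <- do.call(rbind, out)
  if (is.null(reg)) reg <- empty_registry()
  rownames(reg) <- NULL
  class(reg) <- c("hcc_registry", "data.frame")
  reg
}

calibrate_targets <- function(targets) {
  params <- vector("list", nrow(targets))
  for (r in seq_len(nrow(targets))) {
    params[[r]] <- weibull_from_mean_median(
      targets$mean[r], targets$median[r],
      label = paste(targets$arm[r], targets$stage[r]))
  }
  names(params) <- paste(targets$arm, targets$stage, sep = ".")
  params
}

generate_center <- function(cfg, params, i) {
  sizes <- cfg$centers[[i]]
  n_t <- as.integer(sizes[["tare"]])
  n_s <- as.integer(sizes[["sorafenib"]])
  n <- n_t + n_s
  if (n == 0L) return(NULL)
  pvt <- stats::rbinom(n, 1L, cfg$pvt_prevalence) == 1L
  cpb <- stats::rbinom(n, 1L, cfg$child_pugh_b_prevalence) == 1L
  multi <- stats::rbinom(n, 1L, cfg$multinodular_prevalence) == 1L
  a <- cfg$assignment
  eta <- a[["pvt"]] * pvt + a[["child_pugh_b"]] * cpb +
    a[["multinodular"]] * multi
  if (isTRUE(cfg$fixed_arm_counts)) {
    arm <- rep("sorafenib", n)
    if (n_t > 0L)
      arm[sample.int(n, n_t, prob = exp(eta))] <- "TARE"
  } else {
    arm <- ifelse(stats::rbinom(n, 1L, stats::plogis(a[["intercept"]] + eta)) ==
                    1L, "TARE", "sorafenib")
  }
  stage <- ifelse(pvt, "advanced", "intermediate")
  key <- paste(arm, stage, sep = ".")
  os_true <- numeric(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    p <- params[[k]]
    os_true[idx] <- stats::rweibull(length(idx), shape = p$shape,
                                    scale = p$scale)
  }
  kappa <- cfg$pfs_fraction_concentration
  m <- cfg$pfs_fraction_mean[stage]
  frac <- stats::rbeta(n, m * kappa, (1 - m) * kappa)
  pfs_true <- os_true * frac
  h <- cfg$censor_horizon
  data.frame(
    patient_id = sprintf("C%d-%04d", i, seq_len(n)),
    center = i,
    stage = stage,
    child_pugh = ifelse(cpb, "B", "A"),
    nodules = ifelse(multi, "multinodular", "single"),
    pvt = pvt,
    arm = arm,
    pfs_months = pmin(pfs_true, h),
    os_months = pmin(os_true, h),
    prog_event = pfs_true <= h,
    death_event = os_true <= h,
    stringsAsFactors = FALSE
  )
}

#' Summarize a registry by arm and stage
#'
#' One row per (arm, stage) group with covariate frequencies and
#' Kaplan-Meier overall-survival summaries (the restricted mean up to the
#' largest observed time, and the KM median). When a group has no observed
#' deaths the summaries are `NA`.
#'
#' @param registry An `hcc_registry` data.frame.
#' @return A data.frame with columns `arm`, `stage`, `n`, `child_pugh_b`,
#'   `multinodular`, `pvt`, `os_mean`, `os_median`.
#' @export
summarize_registry <- function(registry) {
  if (!is.data.frame(registry) || nrow(registry) == 0L)
    stop("registry is empty", call. = FALSE)
  groups <- unique(registry[, c("arm", "stage")])
  groups <- groups[order(groups$arm, groups$stage), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- registry[registry$arm == groups$arm[g] &
                      registry$stage == groups$stage[g], ]
    if (any(sub$death_event)) {
      sf <- survival::survfit(
        survival::Surv(sub$os_months, sub$death_event) ~ 1)
      tab <- summary(sf, rmean = max(sub$os_months))$table
      os_mean <- unname(tab[grep("rmean", names(tab))[1]])
      os_median <- unname(tab[["median"]])
    } else {
      os_mean <- NA_real_
      os_median <- NA_real_
    }
    data.frame(arm = groups$arm[g], stage = groups$stage[g], n = nrow(sub),
               child_pugh_b = mean(sub$child_pugh == "B"),
               multinodular = mean(sub$nodules == "multinodular"),
               pvt = mean(sub$pvt),
               os_mean = os_mean, os_median = os_median,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a registry as CSV
#'
#' Booleans are stored as 0/1 and times in months with 6-decimal fixed format,
#' so identical registries export to byte-identical files.
#'
#' @param registry An `hcc_registry`.
#' @param path File path.
#' @return `write_registry` returns `path` invisibly; `read_registry` returns
#'   the `hcc_registry`.
#' @export
write_registry <- function(registry, path) {
  out <- registry
  out$pvt <- as.integer(out$pvt)
  out$prog_event <- as.integer(out$prog_event)
  out$death_event <- as.integer(out$death_event)
  out$pfs_months <- sprintf("%.6f", registry$pfs_months)
  out$os_months <- sprintf("%.6f", registry$os_months)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$pvt <- df$pvt == 1L
  df$prog_event <- df$prog_event == 1L
  df$death_event <- df$death_event == 1L
  class(df) <- c("hcc_registry", "data.frame")
  df
}
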