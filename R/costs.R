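lab_items <- c("blood_count", "creatinine", "sodium", "potassium", "calcium",
               "prothrombin_time", "albumin", "bilirubin",
               "alpha_fetoprotein", "alt", "ggt", "alkaline_phosphatase")

cost_categories <- c("first_line", "followup", "subsequent", "adverse_event",
                     "transplant")

extdata <- function(file) {
  path <- system.file("extdata", file, package = "tarebia")
  if (path == "") {
    # during development (package not installed)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged fixture not found: ", file,
                               call. = FALSE)
  path
}

#' Cost catalogue of unit tariffs
#'
#' Loads the packaged DRG/price-list catalogue (2018 euros, Lombardy Region
#' tariffs) and applies optional overrides. All amounts are unit costs:
#' visits, lab exams and CT per occurrence, sorafenib per month, procedures
#' per administration, transplantation per intervention plus a yearly
#' maintenance cost.
#'
#' @param overrides Named list/vector of replacement costs (must be known
#'   items and non-negative).
#' @return Named numeric vector of class `cost_catalog`.
#' @export
default_cost_catalog <- function(overrides = NULL) {
  df <- utils::read.csv(extdata("cost_catalog.csv"), stringsAsFactors = FALSE)
  cat <- stats::setNames(df$cost_eur, df$item)
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    unknown <- setdiff(names(ov), names(cat))
    if (length(unknown))
      stop("unknown cost catalogue items: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(ov < 0))
      stop("cost overrides must be non-negative", call. = FALSE)
    cat[names(ov)] <- ov
  }
  class(cat) <- "cost_catalog"
  cat
}

catalog_get <- function(catalog, items) {
  missing <- setdiff(items, names(catalog))
  if (length(missing))
    stop("missing cost catalogue item(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(catalog[items])
}

#' Treatment protocol: utilisation, durations, second-line shares, rates
#'
#' Loads the packaged treatment-protocol table: mean number of TARE
#' procedures per patient (1.1 intermediate / 1.02 advanced), mean sorafenib
#' treatment duration (7.5 / 8.1 months), second-line treatment shares after
#' each first-line option, the one-year cumulative transplant share after
#' intermediate-stage TARE (3.7%), and first-year liver-decompensation rates.
#'
#' @param overrides Named list; supported keys: `tare_procedures` (single
#'   value applied to both stages, or named per-stage vector),
#'   `sorafenib_duration` (likewise), `second_line_sorafenib_duration`
#'   (months; default `NULL` means the stage's first-line duration).
#' @return List of class `treatment_protocol`.
#' @export
default_protocol <- function(overrides = NULL) {
  df <- utils::read.csv(extdata("protocol.csv"), stringsAsFactors = FALSE)
  get1 <- function(par, arm, stage)
    df$value[df$parameter == par & df$arm == arm & df$stage == stage &
               (df$item == "" | is.na(df$item))]
  shares <- function(arm, stage) {
    sub <- df[df$parameter == "second_line_share" & df$arm == arm &
                df$stage == stage, ]
    stats::setNames(sub$value, sub$item)
  }
  proto <- list(
    tare_procedures = c(intermediate = get1("tare_procedures", "TARE",
                                            "intermediate"),
                        advanced = get1("tare_procedures", "TARE",
                                        "advanced")),
    sorafenib_duration = c(intermediate = get1("sorafenib_duration",
                                               "sorafenib", "intermediate"),
                           advanced = get1("sorafenib_duration", "sorafenib",
                                           "advanced")),
    second_line = list(
      TARE = list(intermediate = shares("TARE", "intermediate"),
                  advanced = shares("TARE", "advanced")),
      sorafenib = list(intermediate = shares("sorafenib", "intermediate"),
                       advanced = shares("sorafenib", "advanced"))),
    transplant_share = c(intermediate = get1("transplant_share", "TARE",
                                             "intermediate")),
    decompensation = list(
      TARE = c(intermediate = get1("decompensation_rate", "TARE",
                                   "intermediate"),
               advanced = get1("decompensation_rate", "TARE", "advanced")),
      sorafenib = c(intermediate = get1("decompensation_rate", "sorafenib",
                                        "intermediate"),
                    advanced = get1("decompensation_rate", "sorafenib",
                                    "advanced"))),
    second_line_sorafenib_duration = NULL
  )
  if (!is.null(overrides)) {
    known <- c("tare_procedures", "sorafenib_duration",
               "second_line_sorafenib_duration")
    unknown <- setdiff(names(overrides), known)
    if (length(unknown))
      stop("unknown protocol overrides: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in intersect(names(overrides), c("tare_procedures",
                                            "sorafenib_duration"))) {
      v <- overrides[[k]]
      if (length(v) == 1 && is.null(names(v)))
        v <- c(intermediate = unname(v), advanced = unname(v))
      proto[[k]][names(v)] <- v
    }
    if ("second_line_sorafenib_duration" %in% names(overrides))
      proto$second_line_sorafenib_duration <-
        overrides$second_line_sorafenib_duration
  }
  class(proto) <- "treatment_protocol"
  proto
}

check_arm_stage <- function(arm, stage) {
  if (!arm %in% c("TARE", "sorafenib"))
    stop("unknown arm: ", arm, call. = FALSE)
  if (!stage %in% c("intermediate", "advanced"))
    stop("unknown stage: ", stage, call. = FALSE)
}

#' Cost of one quarterly follow-up round
#'
#' Control visit + abdomen CT + the full 12-item lab panel, repeated every
#' three months for patients alive under either treatment.
#'
#' @param catalog A `cost_catalog`.
#' @return Euros per follow-up round.
#' @export
quarterly_followup_cost <- function(catalog = default_cost_catalog()) {
  sum(catalog_get(catalog, c("control_visit", "ct", lab_items)))
}

#' Cost of the lab panel drawn at visits
#' @param catalog A `cost_catalog`.
#' @return Euros per panel.
#' @export
lab_panel_cost <- function(catalog = default_cost_catalog()) {
  sum(catalog_get(catalog, lab_items))
}

#' Expected payment-by-result refund for sorafenib
#'
#' Under the Italian risk-sharing scheme the manufacturer refunds the first
#' two monthly packages for each patient not responding within two months.
#' Non-response is proxied by progression or death within two months:
#' refund = (1 - PFS(2)) x 2 x monthly cost.
#'
#' @param pfs Either a `parametric_fit` for PFS or the numeric value of
#'   PFS at 2 months.
#' @param monthly_cost Sorafenib monthly cost in euros.
#' @return Expected refund in euros per patient starting sorafenib.
#' @export
expected_refund <- function(pfs, monthly_cost) {
  pfs2 <- if (inherits(pfs, "parametric_fit")) surv_prob(pfs, 2) else pfs
  stopifnot(is.numeric(pfs2), pfs2 >= 0, pfs2 <= 1)
  (1 - pfs2) * 2 * monthly_cost
}

new_cost_stream <- function(category, basis, from, to, amount, every = NA) {
  data.frame(category = category, basis = basis, cycle_from = from,
             cycle_to = to, amount = amount, every = every,
             stringsAsFactors = FALSE)
}

#' First-line treatment cost stream
#'
#' TARE: procedure simulation + mean procedures x TARE tariff + first visit
#' and labs at cycle 1, plus the one-month check (visit, labs, CT) at
#' cycle 2 - all fixed per entering patient. Sorafenib: first visit and labs
#' at cycle 1, the two-month CT, the drug charged monthly while the patient
#' remains in the stable (pre-progression) state, minus the expected
#' payment-by-result refund.
#'
#' @param arm `"TARE"` or `"sorafenib"`.
#' @param stage `"intermediate"` or `"advanced"`.
#' @param catalog A `cost_catalog`.
#' @param protocol A `treatment_protocol`.
#' @param pfs_fit PFS law, required for the sorafenib refund.
#' @param horizon_cycles Stream length.
#' @return A cost-stream component table (category `first_line`).
#' @export
first_line_cost_stream <- function(arm, stage,
                                   catalog = default_cost_catalog(),
                                   protocol = default_protocol(),
                                   pfs_fit = NULL, horizon_cycles = 480L) {
  check_arm_stage(arm, stage)
  labs <- lab_panel_cost(catalog)
  if (arm == "TARE") {
    entry <- catalog_get(catalog, "tare_simulation") +
      protocol$tare_procedures[[stage]] * catalog_get(catalog, "tare") +
      catalog_get(catalog, "first_visit") + labs
    check1m <- catalog_get(catalog, "control_visit") + labs +
      catalog_get(catalog, "ct")
    rbind(new_cost_stream("first_line", "entry_fixed", 1L, 1L, entry),
          new_cost_stream("first_line", "entry_fixed", 2L, 2L, check1m))
  } else {
    if (is.null(pfs_fit))
      stop("pfs_fit is required for the sorafenib refund", call. = FALSE)
    monthly <- catalog_get(catalog, "sorafenib_monthly")
    entry <- catalog_get(catalog, "first_visit") + labs
    refund <- expected_refund(pfs_fit, monthly)
    rbind(
      new_cost_stream("first_line", "entry_fixed", 1L, 1L, entry),
      new_cost_stream("first_line", "entry_fixed", 2L, 2L,
                      catalog_get(catalog, "ct") - refund),
      new_cost_stream("first_line", "stable_cont", 1L, horizon_cycles,
                      monthly))
  }
}

#' Expected one-off cost on entry into the progression state
#'
#' Sum over the second-line options of share x tariff; the sorafenib share
#' (after TARE) is costed as duration x monthly cost, the duration defaulting
#' to the stage's first-line duration. Shares are not mutually exclusive in
#' the source data, so sums above 1 only raise a warning and are not
#' normalized.
#'
#' @inheritParams first_line_cost_stream
#' @param include_second_line_sorafenib Set `FALSE` to drop the sorafenib
#'   component (useful for reporting the procedure-only part).
#' @return Euros per patient entering progression.
#' @export
progression_entry_cost <- function(arm, stage,
                                   catalog = default_cost_catalog(),
                                   protocol = default_protocol(),
                                   include_second_line_sorafenib = TRUE) {
  check_arm_stage(arm, stage)
  shares <- protocol$second_line[[arm]][[stage]]
  if (length(shares) == 0) return(0)
  if (sum(shares) > 1)
    warning("second-line shares sum to more than 1; no normalization applied")
  total <- 0
  for (item in names(shares)) {
    if (item == "sorafenib") {
      if (!include_second_line_sorafenib) next
      dur <- protocol$second_line_sorafenib_duration
      if (is.null(dur)) dur <- protocol$sorafenib_duration[[stage]]
      total <- total + shares[[item]] * dur *
        catalog_get(catalog, "sorafenib_monthly")
    } else {
      total <- total + shares[[item]] * catalog_get(catalog, item)
    }
  }
  total
}

#' Adverse-event (liver decompensation) cost stream
#'
#' Decompensation is assumed to occur in the first year of treatment and to
#' always lead to hospitalization: rate x hospitalization tariff, spread
#' uniformly over cycles 1-12 and charged to alive occupancy. The nominal
#' (mortality-unweighted) total is attached as attribute `nominal_total`.
#'
#' @inheritParams first_line_cost_stream
#' @return A cost-stream component table (category `adverse_event`).
#' @export
adverse_event_cost <- function(arm, stage,
                               catalog = default_cost_catalog(),
                               protocol = default_protocol()) {
  check_arm_stage(arm, stage)
  rate <- protocol$decompensation[[arm]][[stage]]
  total <- rate * catalog_get(catalog, "decompensation_hosp")
  out <- new_cost_stream("adverse_event", "alive_cont", 1L, 12L, total / 12)
  attr(out, "nominal_total") <- total
  out
}

#' Transplant cost stream
#'
#' Transplant tariff charged on entry into the transplant state;
#' post-transplant maintenance charged per cycle (yearly cost / 12) while
#' occupying it. Only active for intermediate-stage TARE.
#'
#' @param catalog A `cost_catalog`.
#' @param horizon_cycles Stream length.
#' @return A cost-stream component table (category `transplant`).
#' @export
transplant_cost_stream <- function(catalog = default_cost_catalog(),
                                   horizon_cycles = 480L) {
  rbind(
    new_cost_stream("transplant", "transplant_inflow", 1L, horizon_cycles,
                    catalog_get(catalog, "transplant")),
    new_cost_stream("transplant", "transplant_cont", 1L, horizon_cycles,
                    catalog_get(catalog, "transplant_yearly") / 12))
}

#' Assemble all cost-stream components for one arm/stage
#'
#' Categories: `first_line` (treatment itself), `followup` (quarterly visit,
#' labs, CT while alive), `subsequent` (one-off on entry into progression),
#' `adverse_event` (first-year decompensation), `transplant` (intermediate
#' TARE only).
#'
#' @inheritParams first_line_cost_stream
#' @return A cost-stream component table of class `cost_streams`.
#' @export
build_cost_streams <- function(arm, stage,
                               catalog = default_cost_catalog(),
                               protocol = default_protocol(),
                               pfs_fit = NULL, horizon_cycles = 480L) {
  check_arm_stage(arm, stage)
  comp <- list(
    first_line_cost_stream(arm, stage, catalog, protocol, pfs_fit,
                           horizon_cycles),
    new_cost_stream("followup", "alive_point", 3L, horizon_cycles,
                    quarterly_followup_cost(catalog), every = 3L),
    new_cost_stream("subsequent", "prog_inflow", 1L, horizon_cycles,
                    progression_entry_cost(arm, stage, catalog, protocol)),
    adverse_event_cost(arm, stage, catalog, protocol))
  if (arm == "TARE" && stage == "intermediate")
    comp <- c(comp, list(transplant_cost_stream(catalog, horizon_cycles)))
  out <- do.call(rbind, comp)
  rownames(out) <- NULL
  class(out) <- c("cost_streams", "data.frame")
  out
}
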