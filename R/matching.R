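default_ps_covariates <- c("child_pugh", "nodules", "pvt")

ps_design <- function(registry, covariates) {
  X <- matrix(0, nrow(registry), length(covariates),
              dimnames = list(NULL, covariates))
  for (v in covariates) {
    col <- registry[[v]]
    if (is.null(col)) stop("covariate not present in registry: ", v,
                           call. = FALSE)
    X[, v] <- switch(v,
                     child_pugh = as.numeric(col == "B"),
                     nodules = as.numeric(col == "multinodular"),
                     pvt = as.numeric(col),
                     as.numeric(col))
  }
  X
}

#' Fit a propensity-score model for treatment assignment
#'
#' Logistic regression of TARE assignment on the matching covariates
#' (Child-Pugh class, nodule count, portal-vein thrombosis), fitted by
#' iteratively reweighted least squares via [stats::glm()]. Fitted
#' probabilities are the propensity scores used for matching.
#'
#' @param registry An `hcc_registry` with both arms represented (at least two
#'   patients per arm).
#' @param covariates Character vector of covariate names.
#' @return An object of class `propensity_model` with elements
#'   `coefficients`, `score` (fitted probabilities), `logit`, `patient_id`,
#'   `arm`.
#' @export
fit_propensity <- function(registry, covariates = default_ps_covariates) {
  if (!is.data.frame(registry) || nrow(registry) == 0L)
    stop("registry is empty", call. = FALSE)
  y <- as.numeric(registry$arm == "TARE")
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least two patients per arm to fit a propensity model",
         call. = FALSE)
  X <- ps_design(registry, covariates)
  dat <- data.frame(y = y, X)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (any(is.na(stats::coef(fit))))
    stop("singular propensity design: drop collinear covariates",
         call. = FALSE)
  p <- stats::fitted(fit)
  if (any(p < 1e-8) || any(p > 1 - 1e-8))
    stop(paste("perfect separation in the propensity model;",
               "match exactly on covariates instead of using a caliper"),
         call. = FALSE)
  structure(list(coefficients = stats::coef(fit),
                 score = as.numeric(p),
                 logit = as.numeric(stats::qlogis(p)),
                 patient_id = registry$patient_id,
                 arm = registry$arm),
            class = "propensity_model")
}

#' 1:1 greedy propensity matching with a caliper
#'
#' Greedy nearest-neighbour matching without replacement on the logit of the
#' propensity score. Treated (TARE) candidates are processed in descending
#' score order; each takes the closest available sorafenib patient whose
#' logit distance is within the caliper. All tie-breaks are by `patient_id`,
#' so the result does not depend on the input row order.
#'
#' @param model A `propensity_model`.
#' @param caliper Maximum |logit difference| allowed within a pair. Default
#'   0.2 standard deviations of the logit scores; `Inf` disables the caliper.
#' @param seed Unused (matching is fully deterministic); accepted for
#'   interface symmetry with the stochastic stages.
#' @return An object of class `matched_cohorts`: `pairs` (data.frame
#'   `tare_id`, `sorafenib_id`, `distance`), `caliper`, `discarded` ids.
#' @export
match_pairs <- function(model, caliper = NULL, seed = NULL) {
  stopifnot(inherits(model, "propensity_model"))
  if (is.null(caliper)) caliper <- 0.2 * stats::sd(model$logit)
  if (!is.numeric(caliper) || length(caliper) != 1 || is.na(caliper) ||
      caliper <= 0)
    stop("caliper must be a positive number (use Inf to disable)",
         call. = FALSE)
  trt <- which(model$arm == "TARE")
  ctl <- which(model$arm != "TARE")
  if (length(trt) == 0L || length(ctl) == 0L)
    stop("both arms must be non-empty", call. = FALSE)
  # descending score, ties by id
  trt <- trt[order(-model$logit[trt], model$patient_id[trt])]
  avail <- ctl[order(model$patient_id[ctl])]
  pairs <- vector("list", length(trt))
  np <- 0L
  for (i in trt) {
    if (length(avail) == 0L) break
    d <- abs(model$logit[avail] - model$logit[i])
    j <- which(d == min(d))[1L]  # avail id-sorted: first minimum = smallest id
    if (d[j] <= caliper) {
      np <- np + 1L
      pairs[[np]] <- data.frame(tare_id = model$patient_id[i],
                                sorafenib_id = model$patient_id[avail[j]],
                                distance = d[j], stringsAsFactors = FALSE)
      avail <- avail[-j]
    }
  }
  pairs <- if (np > 0L) do.call(rbind, pairs[seq_len(np)]) else
    data.frame(tare_id = character(0), sorafenib_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  matched <- c(pairs$tare_id, pairs$sorafenib_id)
  structure(list(pairs = pairs, caliper = caliper,
                 discarded = setdiff(model$patient_id, matched)),
            class = "matched_cohorts")
}

#' Subset a registry to the matched patients
#' @param registry The registry the matching was run on.
#' @param matched A `matched_cohorts` object.
#' @return The matched rows of `registry`.
#' @export
matched_registry <- function(registry, matched) {
  ids <- c(matched$pairs$tare_id, matched$pairs$sorafenib_id)
  registry[registry$patient_id %in% ids, , drop = FALSE]
}

smd_binary <- function(x_t, x_c) {
  m1 <- mean(x_t); m0 <- mean(x_c)
  s2 <- (stats::var(x_t) + stats::var(x_c)) / 2
  if (s2 == 0 || is.na(s2)) {
    if (isTRUE(all.equal(m1, m0))) return(0)
    return(Inf)
  }
  abs(m1 - m0) / sqrt(s2)
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (pooled-SD formula) between the TARE and
#' sorafenib groups, computed on the full registry and on the matched subset.
#' Covariates with post-match SMD above 0.1 are flagged.
#'
#' @param registry The registry the matching was run on.
#' @param matched A `matched_cohorts` with at least one pair.
#' @param covariates Covariates to report.
#' @return Data frame with `covariate`, `smd_before`, `smd_after`, `flagged`.
#' @export
balance_table <- function(registry, matched,
                          covariates = default_ps_covariates) {
  stopifnot(inherits(matched, "matched_cohorts"))
  if (nrow(matched$pairs) == 0L)
    stop("no matched pairs", call. = FALSE)
  sub <- matched_registry(registry, matched)
  Xb <- ps_design(registry, covariates)
  Xa <- ps_design(sub, covariates)
  tb <- registry$arm == "TARE"
  ta <- sub$arm == "TARE"
  out <- data.frame(
    covariate = covariates,
    smd_before = vapply(covariates,
                        function(v) smd_binary(Xb[tb, v], Xb[!tb, v]),
                        numeric(1)),
    smd_after = vapply(covariates,
                       function(v) smd_binary(Xa[ta, v], Xa[!ta, v]),
                       numeric(1)),
    stringsAsFactors = FALSE)
  out$flagged <- out$smd_after > 0.1
  rownames(out) <- NULL
  out
}

#' Export matched pairs as CSV
#' @param matched A `matched_cohorts`.
#' @param path File path.
#' @export
write_matched_pairs <- function(matched, path) {
  out <- matched$pairs
  out$distance <- sprintf("%.6f", out$distance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
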