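#' Specification of a synthetic response cohort
#'
#' Emulates the statistical structure the response analysis assumes:
#' patients fall into latent response classes (PR, SD, PD by burden
#' increase, PD by new metastases), baseline whole-body burden is
#' log-normal at the magnitudes seen in heavily pre-treated mCRPC
#' cohorts (TLP roughly 7e2 to 1.4e4 mL x SUV), MTV is TLP divided by a
#' burden-weighted mean lesion SUV, baseline PSA is log-normal and by
#' default independent of burden, per-class percent changes are drawn
#' inside the corresponding response bands, and survival is exponential
#' with a class-dependent hazard plus independent exponential censoring.
#'
#' @param n_patients cohort size.
#' @param weights mixture weights over classes `PR`, `SD`, `PD`,
#'   `PD_new`; must sum to 1.
#' @param delta_ranges named list of `c(lo, hi)` percent ranges for the
#'   latent burden change per class (defaults lie strictly inside the
#'   PERCIST bands: PR (-90,-40), SD (-25,25), PD (40,250),
#'   PD_new (-25,25)).
#' @param psa_ranges named list of `c(lo, hi)` percent ranges for the
#'   PSA change per class (defaults PR (-90,-55), SD (-45,20),
#'   PD (30,300), PD_new (-20,20)).
#' @param tlp_meanlog,tlp_sdlog log-normal parameters of baseline TLP.
#' @param tlp_range truncation bounds for baseline TLP (mL x SUV).
#' @param psa_meanlog,psa_sdlog log-normal parameters of baseline PSA.
#' @param psa_range truncation bounds for baseline PSA (ng/mL).
#' @param uptake_range range of the burden-weighted mean lesion SUV
#'   (TLP / MTV).
#' @param psa_coupling rank correlation between log baseline TLP and log
#'   baseline PSA (Gaussian copula); default 0, i.e. independent.
#' @param hazards per-class exponential hazards per month (named PR,
#'   SD, PD, PD_new).
#' @param censoring_rate expected fraction of censored follow-ups.
#' @param seed integer; fixes the cohort.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(
    n_patients = 17L,
    weights = c(PR = 5 / 17, SD = 7 / 17, PD = 4 / 17, PD_new = 1 / 17),
    delta_ranges = list(PR = c(-90, -40), SD = c(-25, 25),
                        PD = c(40, 250), PD_new = c(-25, 25)),
    psa_ranges = list(PR = c(-90, -55), SD = c(-45, 20),
                      PD = c(30, 300), PD_new = c(-20, 20)),
    tlp_meanlog = log(3700), tlp_sdlog = 0.75,
    tlp_range = c(700, 14000),
    psa_meanlog = log(150), psa_sdlog = 1.3, psa_range = c(5, 2600),
    uptake_range = c(6, 9),
    psa_coupling = 0,
    hazards = c(PR = 0.03, SD = 0.10, PD = 0.10, PD_new = 0.10),
    censoring_rate = 0.2, seed = 1L) {
  classes <- c("PR", "SD", "PD", "PD_new")
  if (!setequal(names(weights), classes)) stop("weights must be named ",
                                               paste(classes, collapse = ", "))
  weights <- weights[classes]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1")
  for (cl in classes) {
    r <- delta_ranges[[cl]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("delta_ranges must give an ordered range for every class")
    band <- switch(cl, PR = c(-Inf, -30), SD = c(-30, 30),
                   PD = c(30, Inf), PD_new = c(-30, 30))
    if (r[1] < band[1] || r[2] > band[2])
      stop("delta range for class ", cl,
           " lies outside its response band: the mixture is contradictory")
  }
  if (!setequal(names(hazards), classes)) stop("hazards must be named ",
                                               paste(classes, collapse = ", "))
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (abs(psa_coupling) > 1) stop("psa_coupling must be in [-1, 1]")
  structure(list(
    n_patients = as.integer(n_patients), weights = weights,
    delta_ranges = delta_ranges, psa_ranges = psa_ranges,
    tlp_meanlog = tlp_meanlog, tlp_sdlog = tlp_sdlog,
    tlp_range = tlp_range, psa_meanlog = psa_meanlog,
    psa_sdlog = psa_sdlog, psa_range = psa_range,
    uptake_range = uptake_range, psa_coupling = psa_coupling,
    hazards = hazards[classes], censoring_rate = censoring_rate,
    seed = as.integer(seed)), class = "scenario_spec")
}

# Truncated log-normal via inverse-CDF on the normal quantile scale.
rlnorm_trunc <- function(z, meanlog, sdlog, range) {
  plo <- stats::pnorm((log(range[1]) - meanlog) / sdlog)
  phi <- stats::pnorm((log(range[2]) - meanlog) / sdlog)
  u <- plo + stats::pnorm(z) * (phi - plo)
  exp(meanlog + sdlog * stats::qnorm(u))
}

#' Generate a synthetic response cohort with ground truth
#'
#' @param spec a [scenario_spec()].
#' @return List with `records` (the cohort table contract:
#'   `patient_id`, `tlp_pre`, `tlp_post`, `mtv_pre`, `mtv_post`,
#'   `psa_pre`, `psa_post`, `new_metastases`), `survival` (`patient_id`,
#'   `time_months`, `event`, `group` with PR vs SD_or_PD), and `truth`
#'   (`patient_id`, latent `class`, the drawn deltas).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_patients
  classes <- names(spec$weights)
  with_seed(spec$seed, {
    cls <- sample(classes, n, replace = TRUE, prob = spec$weights)

    z_t <- stats::rnorm(n)
    z_p <- spec$psa_coupling * z_t +
      sqrt(1 - spec$psa_coupling^2) * stats::rnorm(n)
    tlp_pre <- rlnorm_trunc(z_t, spec$tlp_meanlog, spec$tlp_sdlog,
                            spec$tlp_range)
    psa_pre <- rlnorm_trunc(z_p, spec$psa_meanlog, spec$psa_sdlog,
                            spec$psa_range)
    uptake <- stats::runif(n, spec$uptake_range[1], spec$uptake_range[2])
    mtv_pre <- tlp_pre / uptake

    draw_range <- function(ranges) {
      lo <- vapply(ranges[cls], `[`, numeric(1), 1L)
      hi <- vapply(ranges[cls], `[`, numeric(1), 2L)
      stats::runif(n, lo, hi)
    }
    d_latent <- draw_range(spec$delta_ranges)
    # TLP and MTV changes jitter around the latent burden change but are
    # clamped to stay strictly inside the class band (the two imaging
    # measures are concordant by construction, as observed clinically)
    clamp <- function(d) {
      lo <- vapply(spec$delta_ranges[cls], `[`, numeric(1), 1L)
      hi <- vapply(spec$delta_ranges[cls], `[`, numeric(1), 2L)
      pmin(pmax(d, lo), hi)
    }
    d_tlp <- clamp(d_latent + stats::runif(n, -4, 4))
    d_mtv <- clamp(d_latent + stats::runif(n, -4, 4))
    d_psa <- draw_range(spec$psa_ranges)

    new_met <- cls == "PD_new"
    tlp_post <- tlp_pre * (1 + d_tlp / 100)
    mtv_post <- mtv_pre * (1 + d_mtv / 100)
    psa_post <- psa_pre * (1 + d_psa / 100)

    lam <- spec$hazards[cls]
    t_event <- stats::rexp(n, rate = lam)
    if (spec$censoring_rate > 0) {
      cr <- spec$censoring_rate
      t_cens <- stats::rexp(n, rate = lam * cr / (1 - cr))
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    pid <- sprintf("S%03d", seq_len(n))
    list(
      records = data.frame(
        patient_id = pid, tlp_pre = tlp_pre, tlp_post = tlp_post,
        mtv_pre = mtv_pre, mtv_post = mtv_post, psa_pre = psa_pre,
        psa_post = psa_post, new_metastases = new_met),
      survival = data.frame(
        patient_id = pid, time_months = time, event = event,
        group = ifelse(cls == "PR", "PR", "SD_or_PD")),
      truth = data.frame(
        patient_id = pid, class = cls, delta_tlp_pct = d_tlp,
        delta_mtv_pct = d_mtv, delta_psa_pct = d_psa)
    )
  })
}
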