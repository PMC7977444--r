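#' Percent change between two measurements
#'
#' @param pre baseline value(s); must be strictly positive.
#' @param post follow-up value(s); non-negative.
#' @return `100 * (post - pre) / pre`, vectorised.
#' @export
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("percent change is undefined for non-positive baseline values")
  if (any(!is.finite(post)) || any(post < 0))
    stop("follow-up values must be finite and non-negative")
  100 * (post - pre) / pre
}

RESPONSE_LEVELS <- c("PR", "SD", "PD")

#' Modified PERCIST imaging response
#'
#' Classification on a whole-body burden change (delta-TLP or delta-MTV,
#' in percent): partial remission (PR) for a decrease of more than 30%,
#' progressive disease (PD) for an increase of more than 30% *or* the
#' appearance of new metastases (which overrides any burden change), and
#' stable disease (SD) otherwise. Band edges are strict: exactly -30% or
#' +30% is SD.
#'
#' @param delta_pct percent change(s) in TLP or MTV.
#' @param new_metastases logical, recycled against `delta_pct`.
#' @param band half-width of the stable-disease band in percent.
#' @return Factor with levels PR, SD, PD.
#' @export
classify_imaging <- function(delta_pct, new_metastases = FALSE, band = 30) {
  if (any(!is.finite(delta_pct))) stop("delta_pct must be finite")
  n <- max(length(delta_pct), length(new_metastases))
  delta_pct <- rep_len(delta_pct, n)
  new_metastases <- rep_len(as.logical(new_metastases), n)
  out <- ifelse(new_metastases | delta_pct > band, "PD",
                ifelse(delta_pct < -band, "PR", "SD"))
  factor(out, levels = RESPONSE_LEVELS)
}

#' PCWG3 biochemical response
#'
#' Classification on the serum PSA change: PR for a decrease of more
#' than 50%, PD for an increase of more than 25%, SD in between (both
#' edges strict). Following the source workflow, classification is made
#' on a single follow-up measurement without the confirmatory second
#' PSA measurement that full PCWG3 recommends.
#'
#' @param delta_pct percent change(s) in PSA.
#' @param pr_cut,pd_cut band edges in percent (defaults -50 / +25).
#' @return Factor with levels PR, SD, PD.
#' @export
classify_psa <- function(delta_pct, pr_cut = -50, pd_cut = 25) {
  if (any(!is.finite(delta_pct))) stop("delta_pct must be finite")
  out <- ifelse(delta_pct > pd_cut, "PD",
                ifelse(delta_pct < pr_cut, "PR", "SD"))
  factor(out, levels = RESPONSE_LEVELS)
}

#' Assess a response cohort
#'
#' Computes per-patient percent changes in TLP, MTV and PSA, classifies
#' each by modified PERCIST (imaging) and PCWG3 (PSA), and tabulates
#' PR/SD/PD frequencies per method. Records whose baseline values are
#' not strictly positive cannot yield a percent change; they are
#' rejected individually (with identification) and the run continues.
#'
#' @param records data frame with columns `patient_id`, `tlp_pre`,
#'   `tlp_post`, `mtv_pre`, `mtv_post`, `psa_pre`, `psa_post`,
#'   `new_metastases` (logical).
#' @return An object of class `cohort_assessment`: `calls` (one row per
#'   accepted patient with unrounded deltas and the three response
#'   factors), `frequencies` (counts and percentages of PR/SD/PD per
#'   method), `rejected` (patient ids with reasons), `n`.
#' @export
assess_cohort <- function(records) {
  need <- c("patient_id", "tlp_pre", "tlp_post", "mtv_pre", "mtv_post",
            "psa_pre", "psa_post", "new_metastases")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(records) < 1L) stop("cohort must contain at least one record")

  pre_cols <- c("tlp_pre", "mtv_pre", "psa_pre")
  bad <- !stats::complete.cases(records[need]) |
    Reduce(`|`, lapply(records[pre_cols], function(v) !is.finite(v) | v <= 0))
  rejected <- data.frame(
    patient_id = as.character(records$patient_id[bad]),
    reason = rep("non-positive or missing baseline value", sum(bad)))
  if (any(bad))
    warning("rejected ", sum(bad), " record(s) with non-positive baseline: ",
            paste(records$patient_id[bad], collapse = ", "))
  rec <- records[!bad, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no assessable records remain")

  calls <- data.frame(
    patient_id = rec$patient_id,
    delta_tlp_pct = percent_change(rec$tlp_pre, rec$tlp_post),
    delta_mtv_pct = percent_change(rec$mtv_pre, rec$mtv_post),
    delta_psa_pct = percent_change(rec$psa_pre, rec$psa_post),
    new_metastases = as.logical(rec$new_metastases)
  )
  calls$tlp_response <- classify_imaging(calls$delta_tlp_pct, calls$new_metastases)
  calls$mtv_response <- classify_imaging(calls$delta_mtv_pct, calls$new_metastases)
  calls$psa_response <- classify_psa(calls$delta_psa_pct)

  freq <- do.call(rbind, lapply(
    c(tlp = "tlp_response", mtv = "mtv_response", psa = "psa_response"),
    function(col) {
      tab <- table(calls[[col]])
      data.frame(response = names(tab), count = as.integer(tab),
                 percent = 100 * as.integer(tab) / nrow(calls))
    }))
  freq <- cbind(method = rep(c("tlp", "mtv", "psa"), each = 3L), freq)
  rownames(freq) <- NULL

  structure(list(calls = calls, frequencies = freq, rejected = rejected,
                 n = nrow(calls)),
            class = "cohort_assessment")
}

#' @export
print.cohort_assessment <- function(x, ...) {
  cat("<cohort_assessment> n = ", x$n, "\n", sep = "")
  print(x$frequencies, row.names = FALSE)
  if (nrow(x$rejected)) cat("rejected:", nrow(x$rejected), "record(s)\n")
  invisible(x)
}

#' Waterfall ordering of percent changes
#'
#' Returns the cohort deltas of one measure ordered for a waterfall
#' plot (largest increase first), with the new-metastasis flag carried
#' along for annotation.
#'
#' @param assessment a `cohort_assessment`.
#' @param measure one of "tlp", "mtv", "psa".
#' @return Data frame `patient_id`, `delta_pct`, `new_metastases`,
#'   ordered by decreasing delta.
#' @export
waterfall_data <- function(assessment, measure = c("tlp", "mtv", "psa")) {
  stopifnot(inherits(assessment, "cohort_assessment"))
  measure <- match.arg(measure)
  col <- paste0("delta_", measure, "_pct")
  out <- data.frame(patient_id = assessment$calls$patient_id,
                    delta_pct = assessment$calls[[col]],
                    new_metastases = assessment$calls$new_metastases)
  out[order(-out$delta_pct), , drop = FALSE]
}

#' Response table in reporting precision
#'
#' The export twin of the cohort response table: deltas rounded to one
#' decimal place, PR/SD/PD response columns, and an asterisk marking
#' patients with new metastases. Classification itself always uses the
#' unrounded deltas.
#'
#' @param assessment a `cohort_assessment`.
#' @return Data frame ready for `write.csv`.
#' @export
response_table <- function(assessment) {
  stopifnot(inherits(assessment, "cohort_assessment"))
  ca <- assessment$calls
  data.frame(
    patient_id = ca$patient_id,
    delta_tlp_pct = round(ca$delta_tlp_pct, 1),
    delta_mtv_pct = round(ca$delta_mtv_pct, 1),
    delta_psa_pct = round(ca$delta_psa_pct, 1),
    tlp_response = as.character(ca$tlp_response),
    mtv_response = as.character(ca$mtv_response),
    psa_response = as.character(ca$psa_response),
    new_metastases = ifelse(ca$new_metastases, "*", "")
  )
}

#' Read a cohort table from CSV
#'
#' Header contract: `patient_id, tlp_pre, tlp_post, mtv_pre, mtv_post,
#' psa_pre, psa_post, new_metastases` with `new_metastases` as
#' true/false.
#'
#' @param path CSV path.
#' @return Data frame suitable for [assess_cohort()].
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("new_metastases" %in% names(x) && !is.logical(x$new_metastases))
    x$new_metastases <- tolower(trimws(as.character(x$new_metastases))) %in%
      c("true", "t", "1", "yes")
  x
}
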