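#' Packaged 17-patient mCRPC tandem-therapy cohort
#'
#' The published per-patient pre/post tandem-therapy values of
#' whole-body TLP (mL x SUV), MTV (mL) and serum PSA (ng/mL) for the
#' 17-patient mCRPC cohort, together with the new-metastasis flags and
#' the published response calls and percent changes, carried for
#' regression testing. Note the published table rounds values over 15 to
#' full values, so percent changes recomputed from these inputs can
#' differ from the published (unrounded-source) changes by up to ~0.3
#' percentage points; the PR/SD/PD calls are unaffected.
#'
#' @return List with `records` (the [assess_cohort()] input contract)
#'   and `reference` (`patient_id`, published `delta_*_pct` and
#'   `*_response` columns).
#' @export
table2_fixture <- function() {
  records <- data.frame(
    patient_id = as.character(1:17),
    tlp_pre  = c(934, 13679, 5412, 9717, 4290, 4365, 9070, 4282, 1448,
                 723, 8547, 2142, 3685, 1447, 1959, 1153, 1594),
    tlp_post = c(1874, 5113, 7750, 9888, 4363, 2026, 35819, 726, 72,
                 664, 9059, 2446, 3123, 1242, 596, 1166, 2289),
    mtv_pre  = c(187, 2581, 838, 1197, 617, 784, 1263, 588, 303, 153,
                 1348, 372, 452, 259, 368, 265, 214),
    mtv_post = c(342, 1184, 1159, 1413, 672, 421, 4542, 171, 13, 130,
                 1442, 477, 513, 228, 119, 293, 335),
    psa_pre  = c(191, 1277, 60, 152, 258, 10.1, 103, 123, 98, 251,
                 2570, 508, 115, 13.0, 311, 968, 5.9),
    psa_post = c(344, 367, 77, 129, 379, 6.8, 750, 7.0, 26, 290, 1251,
                 496, 101, 9.0, 135, 1091, 6.1),
    new_metastases = as.character(1:17) %in% c("1", "3", "7", "13")
  )
  reference <- data.frame(
    patient_id = as.character(1:17),
    delta_tlp_pct = c(100.7, -62.6, 43.2, 1.8, 1.7, -53.6, 294.9, -83.0,
                      -95.1, -8.1, 6.0, 14.2, -15.3, -14.1, -69.6, 1.1,
                      43.6),
    delta_mtv_pct = c(82.7, -54.1, 38.3, 18.1, 8.9, -46.2, 259.8, -70.9,
                      -95.5, -15.0, 7.0, 28.3, 13.3, -12.0, -67.6, 10.3,
                      56.8),
    delta_psa_pct = c(80.1, -71.3, 28.3, -15.1, 46.9, -32.7, 628.2,
                      -94.3, -73.5, 15.5, -51.3, -2.4, -12.2, -30.8,
                      -56.6, 12.7, 3.2),
    tlp_response = c("PD", "PR", "PD", "SD", "SD", "PR", "PD", "PR",
                     "PR", "SD", "SD", "SD", "PD", "SD", "PR", "SD",
                     "PD"),
    mtv_response = c("PD", "PR", "PD", "SD", "SD", "PR", "PD", "PR",
                     "PR", "SD", "SD", "SD", "PD", "SD", "PR", "SD",
                     "PD"),
    psa_response = c("PD", "PR", "PD", "SD", "PD", "SD", "PD", "PR",
                     "PR", "SD", "PR", "SD", "SD", "SD", "PR", "SD",
                     "SD")
  )
  list(records = records, reference = reference)
}
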