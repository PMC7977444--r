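test_that("the same seed reproduces phantoms and cohorts bit-for-bit", {
  sp <- sphere_spec(volume_ml = 10, noise_sd = 0.5, seed = 71)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image$values, p2$image$values)
  p3 <- generate_phantom(sphere_spec(volume_ml = 10, noise_sd = 0.5,
                                     seed = 72))
  expect_false(identical(p1$image$values, p3$image$values))

  sc <- scenario_spec(n_patients = 40, seed = 9)
  c1 <- generate_cohort(sc)
  c2 <- generate_cohort(sc)
  expect_identical(c1, c2)
})

test_that("a noise-free 20 mL lesion is recovered in volume and uptake", {
  ph <- generate_phantom(sphere_spec(volume_ml = 20, suv = 8))
  seg <- segment_lesions(ph$image, ph$masks)
  expect_length(seg$lesions, 1L)
  b <- total_burden(seg)
  expect_lt(abs(b$mtv - 20) / 20, 0.15)
  expect_lt(abs(seg$lesions[[1]]$suv_mean - 8) / 8, 0.05)
})

test_that("a sub-threshold lesion stays in the ground truth only", {
  sp <- phantom_spec(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                     background_suv = 1,
                     lesions = list(list(center_mm = c(23, 23, 23),
                                         radii_mm = c(8, 8, 8), suv = 2.5)))
  ph <- generate_phantom(sp)
  expect_equal(nrow(ph$truth), 1L)
  expect_length(segment_lesions(ph$image, ph$masks)$lesions, 0L)
})

test_that("a lesion outside the grid is rejected", {
  sp <- phantom_spec(shape = c(10, 10, 10), spacing = c(2, 2, 2),
                     lesions = list(list(center_mm = c(100, 10, 10),
                                         radii_mm = c(4, 4, 4), suv = 8)))
  expect_error(generate_phantom(sp), "outside the grid")
})

test_that("organ masks align with painted organs and exclude them", {
  sp <- phantom_spec(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                     organs = list(list(name = "bladder",
                                        center_mm = c(23, 23, 23),
                                        radii_mm = c(8, 8, 8), suv = 25)),
                     lesions = list(list(center_mm = c(38, 38, 38),
                                         radii_mm = c(5, 5, 5), suv = 8)))
  ph <- generate_phantom(sp)
  expect_named(ph$masks$masks, "bladder")
  seg <- segment_lesions(ph$image, ph$masks)
  expect_length(seg$lesions, 1L)
  expect_lt(seg$lesions[[1]]$suv_max, 25)
})

test_that("a 60% volume reduction classifies as PR end to end", {
  sp <- sphere_spec(volume_ml = 15, suv = 8, shape = c(40, 40, 40))
  study <- generate_paired_study(sp, volume_mult = 0.4)
  expect_equal(study$truth$delta_mtv_pct, -60, tolerance = 1e-9)
  res <- assess_paired_study(study$pre$image, study$post$image,
                             study$pre$masks, study$post$masks)
  expect_equal(as.character(res$mtv_response), "PR")
  expect_equal(as.character(res$tlp_response), "PR")
  expect_lt(abs(res$delta_mtv_pct - (-60)), 10)
})

test_that("an identity change classifies as SD with matching lesions", {
  sp <- sphere_spec(volume_ml = 12, suv = 7)
  study <- generate_paired_study(sp, volume_mult = 1, uptake_mult = 1)
  expect_equal(study$truth$delta_tlp_pct, 0)
  res <- assess_paired_study(study$pre$image, study$post$image)
  expect_equal(as.character(res$tlp_response), "SD")
  expect_false(res$new_metastases)
  expect_equal(nrow(res$matching$pairs), 1L)
})

test_that("a distant new lesion forces PD through the override", {
  sp <- sphere_spec(volume_ml = 12, suv = 7, shape = c(50, 50, 30))
  new_l <- list(list(center_mm = c(88, 88, 40), radii_mm = c(10.6, 10.6, 10.6),
                     suv = 6))
  study <- generate_paired_study(sp, volume_mult = 1, uptake_mult = 1,
                                 new_lesions = new_l)
  res <- assess_paired_study(study$pre$image, study$post$image)
  expect_true(res$new_metastases)
  expect_equal(as.character(res$tlp_response), "PD")
  # the manual flag takes precedence over the matcher
  res2 <- assess_paired_study(study$pre$image, study$post$image,
                              new_metastases = FALSE)
  expect_false(res2$new_metastases)
})

test_that("pipeline deltas track analytic deltas and refine with spacing", {
  sp2 <- sphere_spec(volume_ml = 18, suv = 9, spacing = c(2, 2, 2),
                     shape = c(40, 40, 40))
  sp1 <- sphere_spec(volume_ml = 18, suv = 9, spacing = c(1, 1, 1),
                     shape = c(72, 72, 72),
                     center_mm = c(39, 39, 39) * 1)
  err <- vapply(list(sp2, sp1), function(sp) {
    study <- generate_paired_study(sp, volume_mult = 0.5, uptake_mult = 0.9)
    res <- assess_paired_study(study$pre$image, study$post$image)
    abs(res$delta_tlp_pct - study$truth$delta_tlp_pct)
  }, numeric(1))
  expect_lt(err[1], 8)
  expect_lt(err[2], err[1] + 1e-9)
})

test_that("generated cohorts recover their mixture frequencies", {
  sc <- scenario_spec(n_patients = 1000,
                      weights = c(PR = 0.3, SD = 0.4, PD = 0.3, PD_new = 0),
                      seed = 77)
  coh <- generate_cohort(sc)
  a <- assess_cohort(coh$records)
  f <- a$frequencies
  for (m in c("tlp", "mtv")) {
    pr <- f$count[f$method == m & f$response == "PR"]
    sd_ <- f$count[f$method == m & f$response == "SD"]
    pd <- f$count[f$method == m & f$response == "PD"]
    # binomial 95% bounds around the requested weights at n = 1000
    expect_lt(abs(pr / 1000 - 0.3), 1.96 * sqrt(0.3 * 0.7 / 1000) + 0.01)
    expect_lt(abs(sd_ / 1000 - 0.4), 1.96 * sqrt(0.4 * 0.6 / 1000) + 0.01)
    expect_lt(abs(pd / 1000 - 0.3), 1.96 * sqrt(0.3 * 0.7 / 1000) + 0.01)
  }
  # classification recovers the latent class labels exactly by design
  expect_identical(as.character(a$calls$tlp_response),
                   ifelse(coh$truth$class == "PD_new", "PD",
                          sub("_new", "", coh$truth$class)))
})

test_that("PD-by-new-lesion patients carry the flag and classify PD", {
  sc <- scenario_spec(n_patients = 200,
                      weights = c(PR = 0.25, SD = 0.25, PD = 0.25,
                                  PD_new = 0.25), seed = 78)
  coh <- generate_cohort(sc)
  a <- assess_cohort(coh$records)
  sel <- coh$truth$class == "PD_new"
  expect_true(all(coh$records$new_metastases[sel]))
  expect_true(all(a$calls$tlp_response[sel] == "PD"))
  # their burden change alone would have been stable
  expect_true(all(abs(coh$truth$delta_tlp_pct[sel]) < 30))
})

test_that("baseline log-burden / log-PSA coupling matches the request", {
  for (rho in c(0, 0.6)) {
    sc <- scenario_spec(n_patients = 1000, psa_coupling = rho, seed = 79)
    coh <- generate_cohort(sc)
    r <- spearman_cor(log(coh$records$tlp_pre), log(coh$records$psa_pre))$r
    expect_lt(abs(r - rho), 0.1)
  }
})

test_that("contradictory scenario specifications are rejected", {
  expect_error(scenario_spec(weights = c(PR = 0.5, SD = 0.5, PD = 0,
                                         PD_new = 0.2)), "sum to 1")
  expect_error(scenario_spec(
    delta_ranges = list(PR = c(-20, -10), SD = c(-25, 25),
                        PD = c(40, 250), PD_new = c(-25, 25))),
    "outside its response band")
  expect_error(scenario_spec(hazards = c(PR = -1, SD = 0.1, PD = 0.1,
                                         PD_new = 0.1)), "positive")
})

test_that("cohort output matches the 17-patient table schema", {
  sc <- scenario_spec(n_patients = 17, seed = 80)
  coh <- generate_cohort(sc)
  expect_named(coh$records,
               c("patient_id", "tlp_pre", "tlp_post", "mtv_pre", "mtv_post",
                 "psa_pre", "psa_post", "new_metastases"))
  expect_named(coh$survival,
               c("patient_id", "time_months", "event", "group"))
  expect_equal(nrow(coh$records), 17L)
  expect_true(all(coh$records$tlp_pre >= 700 &
                    coh$records$tlp_pre <= 14000))
})
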