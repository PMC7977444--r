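test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(21)
  for (conn in c(6, 26)) {
    for (rep in 1:4) {
      mask <- array(runif(8 * 8 * 8) < 0.25, dim = c(8, 8, 8))
      got <- label_components(mask, connectivity = conn)
      want <- flood_label(mask, connectivity = conn)
      # same partition: component id maps must be a bijection
      expect_equal(max(got), max(want))
      expect_true(all((got > 0) == mask))
      key <- paste(got[mask], want[mask])
      expect_equal(length(unique(key)), max(want))
    }
  }
})

test_that("diagonal voxels connect under 26- but not 6-connectivity", {
  mask <- array(FALSE, dim = c(4, 4, 4))
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE
  expect_equal(max(label_components(mask, 26)), 1L)
  expect_equal(max(label_components(mask, 6)), 2L)
})

test_that("a sub-threshold image yields an empty lesion set", {
  img <- mk_image(c(10, 10, 10), background = 1)
  seg <- segment_lesions(img)
  expect_length(seg$lesions, 0L)
  b <- total_burden(seg)
  expect_equal(b$mtv, 0)
  expect_equal(b$tlp, 0)
})

test_that("two disjoint hot cubes give two lesions with exact MTV", {
  img <- mk_image(c(12, 12, 12), background = 1)
  img <- paint_box(img, 2:4, 2:4, 2:4, 6)
  img <- paint_box(img, 8:10, 8:10, 8:10, 6)
  seg <- segment_lesions(img)
  expect_length(seg$lesions, 2L)
  for (l in seg$lesions) {
    expect_equal(l$mtv_ml, 27 * 0.008)
    expect_equal(l$suv_mean, 6)
    expect_equal(l$suv_max, 6)
  }
})

test_that("the inclusive threshold keeps voxels at exactly SUV 3.0", {
  img <- mk_image(c(8, 8, 8), background = 1)
  img <- paint_box(img, 3:4, 3:4, 3:4, 3.0)
  seg <- segment_lesions(img)
  expect_length(seg$lesions, 1L)
  expect_equal(seg$lesions[[1]]$n_voxels, 8L)
})

test_that("uptake inside an exclusion mask is not reported as lesion", {
  img <- mk_image(c(12, 12, 12), background = 1)
  img <- paint_box(img, 2:4, 2:4, 2:4, 15)    # bladder
  img <- paint_box(img, 8:10, 8:10, 8:10, 6)  # true lesion
  bladder <- array(FALSE, dim = c(12, 12, 12))
  bladder[2:4, 2:4, 2:4] <- TRUE
  masks <- organ_mask_set(list(bladder = bladder), frame_id = "t")
  seg <- segment_lesions(img, masks)
  expect_length(seg$lesions, 1L)
  expect_equal(seg$lesions[[1]]$suv_mean, 6)
  # exclusion is invariant to mask naming/order
  masks2 <- organ_mask_set(list(a = bladder), frame_id = "t")
  seg2 <- segment_lesions(img, masks2)
  expect_equal(seg2$lesions[[1]]$voxel_indices,
               seg$lesions[[1]]$voxel_indices)
})

test_that("misaligned masks are an error, not a warning", {
  img <- mk_image(c(8, 8, 8))
  m <- organ_mask_set(list(bladder = array(FALSE, dim = c(6, 6, 6))),
                      frame_id = "t")
  expect_error(segment_lesions(img, m), "grid")
  m2 <- organ_mask_set(list(bladder = array(FALSE, dim = c(8, 8, 8))),
                       frame_id = "other")
  expect_error(segment_lesions(img, m2), "frame")
})

test_that("liver lesions use the relative healthy-liver threshold", {
  img <- mk_image(c(14, 14, 14), background = 0.5)
  liver <- array(FALSE, dim = c(14, 14, 14))
  liver[2:12, 2:12, 2:6] <- TRUE
  healthy <- array(FALSE, dim = c(14, 14, 14))
  healthy[2:6, 2:6, 2:6] <- TRUE
  img$values[liver] <- 1.6                     # healthy liver tissue
  img$values[8:9, 8:9, 3:4] <- 2.6             # liver metastasis
  liver <- liver | healthy
  masks <- organ_mask_set(list(liver = liver, healthy_liver = healthy),
                          frame_id = "t")
  # threshold = 1.5 x 1.6 = 2.4 < 2.6 < 3.0: only the relative rule finds it
  expect_equal(liver_threshold(img, healthy, 1.5), 2.4)
  seg <- segment_lesions(img, masks)
  expect_length(seg$lesions, 1L)
  expect_equal(seg$lesions[[1]]$compartment, "liver")
  expect_equal(seg$lesions[[1]]$n_voxels, 8L)

  # the relative threshold is undefined without the reference mask
  masks_bad <- organ_mask_set(list(liver = liver), frame_id = "t")
  expect_error(segment_lesions(img, masks_bad), "healthy_liver")
  empty <- array(FALSE, dim = c(14, 14, 14))
  expect_error(liver_threshold(img, empty), "empty")
})

test_that("liver threshold on heterogeneous tissue equals 1.5 x brute mean", {
  set.seed(22)
  img <- mk_image(c(8, 8, 8), background = 0.5)
  healthy <- array(runif(8^3) < 0.3, dim = c(8, 8, 8))
  vals <- runif(sum(healthy), 1, 3)
  img$values[healthy] <- vals
  acc <- 0; n <- 0
  for (v in vals) { acc <- acc + v; n <- n + 1 }   # brute-force mean
  expect_equal(liver_threshold(img, healthy, 1.5), 1.5 * acc / n,
               tolerance = 1e-12)
})

test_that("raising the global threshold never increases total MTV", {
  ph <- generate_phantom(sphere_spec(volume_ml = 12, suv = 6,
                                     noise_sd = 0.8, seed = 33))
  mtvs <- vapply(c(3, 4, 5, 5.8, 7), function(thr) {
    cfg <- segmentation_config(global_threshold = thr)
    total_burden(segment_lesions(ph$image, ph$masks, cfg))$mtv
  }, numeric(1))
  expect_true(all(diff(mtvs) <= 1e-12))
})

test_that("segmented MTV approaches the analytic ellipsoid volume", {
  coarse <- generate_phantom(sphere_spec(volume_ml = 20,
                                         spacing = c(2, 2, 2),
                                         shape = c(40, 40, 40)))
  fine <- generate_phantom(sphere_spec(volume_ml = 20,
                                       spacing = c(1, 1, 1),
                                       shape = c(72, 72, 72)))
  mtv_c <- total_burden(segment_lesions(coarse$image))$mtv
  mtv_f <- total_burden(segment_lesions(fine$image))$mtv
  expect_lt(abs(mtv_c - 20) / 20, 0.15)
  expect_lt(abs(mtv_f - 20), abs(mtv_c - 20) + 1e-9)
})

test_that("lesion matching pairs by centroid and flags new lesions", {
  img <- mk_image(c(20, 20, 10), background = 1)
  img <- paint_box(img, 2:4, 2:4, 2:4, 6)
  img <- paint_box(img, 12:14, 12:14, 2:4, 6)
  seg <- segment_lesions(img)
  # identical sets: full pairing, no new candidates
  m <- match_lesions(seg, seg)
  expect_equal(nrow(m$pairs), 2L)
  expect_length(m$new_candidates, 0L)

  # a post lesion far from every pre lesion is a new-metastasis candidate
  img2 <- paint_box(img, 2:4, 2:4, 8:10, 6)
  seg2 <- segment_lesions(img2)
  m2 <- match_lesions(seg, seg2, segmentation_config(matching_radius_mm = 11))
  expect_equal(nrow(m2$pairs), 2L)
  expect_length(m2$new_candidates, 1L)

  # shrinking a lesion about its centre keeps the pairing
  img3 <- mk_image(c(20, 20, 10), background = 1)
  img3 <- paint_box(img3, 3, 3, 3, 6)           # cube shrunk to centre voxel
  img3 <- paint_box(img3, 12:14, 12:14, 2:4, 6)
  seg3 <- segment_lesions(img3)
  m3 <- match_lesions(seg, seg3)
  expect_equal(nrow(m3$pairs), 2L)
  expect_length(m3$new_candidates, 0L)

  # empty sets are allowed
  empty <- segment_lesions(mk_image(c(6, 6, 6), background = 1))
  m4 <- match_lesions(empty, seg)
  expect_equal(nrow(m4$pairs), 0L)
  expect_length(m4$new_candidates, 2L)
})

test_that("every reported voxel meets its compartment threshold", {
  ph <- generate_phantom(sphere_spec(volume_ml = 8, suv = 5, noise_sd = 1,
                                     seed = 44))
  seg <- segment_lesions(ph$image, ph$masks)
  for (l in seg$lesions)
    expect_true(all(ph$image$values[l$voxel_indices] >= 3.0))
})
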