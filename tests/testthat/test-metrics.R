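test_that("Dice matches its overlap definition and boundary cases", {
  a <- make_cube(c(32, 32, 32), c(5, 5, 5), c(14, 14, 14))
  b <- make_cube(c(32, 32, 32), c(20, 20, 20), c(27, 27, 27))
  expect_equal(dsc(a, a), 1)   # complete consistency
  expect_equal(dsc(a, b), 0)   # no overlap
  # 1000-voxel cubes overlapping in 500 voxels
  p <- make_cube(c(32, 32, 32), c(1, 1, 1), c(10, 10, 10))
  g <- make_cube(c(32, 32, 32), c(6, 1, 1), c(15, 10, 10))
  expect_equal(dsc(p, g), 0.5)
  expect_error(dsc(empty_volume(c(4, 4, 4)), empty_volume(c(4, 4, 4))),
               "empty")
  expect_equal(dsc(empty_volume(c(32, 32, 32)), a), 0)
})

test_that("Dice is symmetric and translation invariant", {
  set.seed(3)
  for (rep in 1:10) {
    a <- random_mask(c(10, 10, 10), 0.3)
    b <- random_mask(c(10, 10, 10), 0.3)
    if (sum(a$data) + sum(b$data) == 0) next
    expect_equal(dsc(a, b), dsc(b, a))
    # translate both by the same offset
    ta <- empty_volume(c(14, 14, 14)); ta$data[3:12, 3:12, 3:12] <- a$data
    tb <- empty_volume(c(14, 14, 14)); tb$data[3:12, 3:12, 3:12] <- b$data
    expect_equal(dsc(label_volume(ta$data), label_volume(tb$data)),
                 dsc(a, b))
  }
})

test_that("Dice decreases monotonically as overlap erodes on nested cubes", {
  g <- make_cube(c(24, 24, 24), c(5, 5, 5), c(14, 14, 14))
  prev <- Inf
  for (shift in 0:5) {
    p <- make_cube(c(24, 24, 24), c(5 + shift, 5, 5), c(14 + shift, 14, 14))
    cur <- dsc(p, g)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("RVD follows the scalar volume-difference definition, unclamped", {
  expect_equal(rvd(1, 1), 0)
  expect_equal(rvd(3, 1), 100)    # 2*(2V)/(4V)*100
  expect_equal(rvd(0, 2.5), 200)  # missed lesion exceeds the nominal bound
  expect_error(rvd(0, 0), "undefined")
  # symmetry and scale invariance
  set.seed(5)
  for (rep in 1:20) {
    v <- stats::runif(2, 0.1, 10)
    expect_equal(rvd(v[1], v[2]), rvd(v[2], v[1]))
    expect_equal(rvd(7 * v[1], 7 * v[2]), rvd(v[1], v[2]))
  }
  # volume-based call on masks
  p <- make_cube(c(16, 16, 16), c(1, 1, 1), c(10, 5, 5))
  g <- make_cube(c(16, 16, 16), c(1, 1, 1), c(10, 5, 5))
  expect_equal(rvd(p, g), 0)
})

test_that("ASD is zero for identical masks and directed as printed", {
  a <- make_cube(c(14, 14, 14), c(2, 2, 2), c(11, 11, 11))
  expect_equal(asd(a, a), 0)
  # 10^3 cube against itself shifted by one voxel: frozen brute-force value
  b <- make_cube(c(14, 14, 14), c(3, 2, 2), c(12, 11, 11))
  expect_equal(asd(b, a), 0.3360656, tolerance = 1e-6)
  expect_equal(asd(a, b, symmetric = TRUE), 0.3360656, tolerance = 1e-6)
  expect_warning(res <- asd(empty_volume(c(14, 14, 14)), a), "undefined")
  expect_true(is.na(res))
})

test_that("ASD equals the exhaustive all-pairs oracle on random masks", {
  set.seed(17)
  checked <- 0
  while (checked < 25) {
    pv <- random_mask(c(8, 8, 8), 0.25, spacing = stats::runif(3, 0.5, 2))
    gv <- random_mask(c(8, 8, 8), 0.25, spacing = pv$geometry$spacing)
    if (sum(pv$data) == 0 || sum(gv$data) == 0) next
    expect_equal(asd(pv, gv), oracle_asd(pv, gv), tolerance = 1e-6)
    checked <- checked + 1
  }
  # directedness: ASD(A,B) != ASD(B,A) for an asymmetric pair
  big <- make_cube(c(16, 16, 16), c(2, 2, 2), c(13, 13, 13))
  small <- make_cube(c(16, 16, 16), c(6, 6, 6), c(9, 9, 9))
  expect_false(isTRUE(all.equal(asd(big, small), asd(small, big))))
})

test_that("confusion counts match exhaustive enumeration on a toy grid", {
  # hand-laid 4x4x1 masks
  p <- array(0L, c(4, 4, 1)); p[1:2, 1:3, 1] <- 1L
  g <- array(0L, c(4, 4, 1)); g[2:3, 2:4, 1] <- 1L
  pv <- label_volume(p); gv <- label_volume(g)
  cc <- voxel_confusion(pv, gv)
  # brute force truth table
  tp <- sum(p == 1 & g == 1); fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1); tn <- sum(p == 0 & g == 0)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = tp, fp = fp, fn = fn, tn = tn))
  expect_equal(cc$region_voxels, 16L)
  # region must contain the ground truth
  bad_region <- label_volume(array(0L, c(4, 4, 1)))
  expect_error(voxel_confusion(pv, gv, bad_region), "region")
})

test_that("sensitivity, specificity and MCC follow their formulas", {
  perfect <- voxel_confusion(make_cube(c(8, 8, 8), c(2, 2, 2), c(5, 5, 5)),
                             make_cube(c(8, 8, 8), c(2, 2, 2), c(5, 5, 5)))
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(mcc(perfect), 1)
  # complement within the region: perfect anticorrelation
  g <- array(0L, c(4, 4, 2)); g[1:2, , ] <- 1L
  comp <- label_volume(1L - g)
  anti <- voxel_confusion(comp, label_volume(g))
  expect_equal(mcc(anti), -1)
  # direct arithmetic case
  cc <- structure(list(tp = 8, fp = 2, fn = 2, tn = 88, region_voxels = 100),
                  class = "confusion_counts")
  expect_equal(sensitivity(cc), 0.8)
  expect_equal(specificity(cc), 88 / 90)
  expect_equal(mcc(cc), (8 * 88 - 2 * 2) / sqrt(10 * 10 * 90 * 90))
  # undefined denominators flag as NA
  none <- structure(list(tp = 0, fp = 0, fn = 0, tn = 10, region_voxels = 10),
                    class = "confusion_counts")
  expect_true(is.na(sensitivity(none)))
  expect_true(is.na(mcc(none)))
})

test_that("MCC stays within [-1, 1] and rates within [0, 1] on random pairs", {
  set.seed(29)
  for (rep in 1:30) {
    p <- random_mask(c(6, 6, 6), stats::runif(1, 0.1, 0.9))
    g <- random_mask(c(6, 6, 6), stats::runif(1, 0.1, 0.9))
    cc <- voxel_confusion(p, g)
    m <- mcc(cc)
    if (!is.na(m)) expect_true(m >= -1 && m <= 1)
    s <- sensitivity(cc)
    if (!is.na(s)) expect_true(s >= 0 && s <= 1)
    sp <- specificity(cc)
    if (!is.na(sp)) expect_true(sp >= 0 && sp <= 1)
  }
})

test_that("patient-wise Dice pools lesions as one union mask", {
  # one perfectly segmented 1000-voxel lesion, one missed 1000-voxel lesion
  gt <- empty_volume(c(32, 32, 32))
  gt$data[1:10, 1:10, 1:10] <- 1L
  gt$data[15:24, 15:24, 15:24] <- 1L
  gt <- label_volume(gt$data)
  pred <- empty_volume(c(32, 32, 32))
  pred$data[1:10, 1:10, 1:10] <- 1L
  pred <- label_volume(pred$data)
  expect_equal(patient_dsc(gt, pred), 2 * 1000 / (1000 + 2000))
  # single-lesion patient: equals the lesion Dice
  single <- make_cube(c(32, 32, 32), c(1, 1, 1), c(10, 10, 10))
  expect_equal(patient_dsc(single, pred), dsc(pred, single))
  expect_equal(patient_dsc(gt, empty_volume(c(32, 32, 32))), 0)
  expect_error(patient_dsc(empty_volume(c(4, 4, 4)), pred), "empty")
})

test_that("evaluate_masks assembles a flagged metric record", {
  gt <- make_cube(c(24, 24, 24), c(6, 6, 6), c(15, 15, 15))
  pred <- make_cube(c(24, 24, 24), c(7, 6, 6), c(16, 15, 15))
  rec <- evaluate_masks(gt, pred, unit = "lesion-1")
  expect_s3_class(rec, "tbl_df")
  expect_equal(rec$dsc, dsc(pred, gt))
  expect_equal(rec$rvd, 0)  # equal volumes
  expect_false(rec$missed_lesion)
  expect_equal(rec$region_policy, "bbox")
  # an empty prediction flags and yields NA surface distance
  rec2 <- evaluate_masks(gt, empty_volume(c(24, 24, 24)))
  expect_true(rec2$missed_lesion)
  expect_equal(rec2$dsc, 0)
  expect_equal(rec2$rvd, 200)
  expect_true(is.na(rec2$asd_mm))
})
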