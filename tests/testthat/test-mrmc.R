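test_that("session randomization is balanced and seed-deterministic", {
  plan <- assign_sessions(sprintf("R%d", 1:10), seed = 5)
  expect_equal(as.integer(table(plan$readers$session_order)), c(5L, 5L))
  plan2 <- assign_sessions(sprintf("R%d", 1:10), seed = 5)
  expect_identical(plan$readers, plan2$readers)
  # odd reader count: arms differ by at most one
  plan3 <- assign_sessions(sprintf("R%d", 1:7), seed = 1)
  expect_lte(abs(diff(table(plan3$readers$session_order))), 1)
  expect_error(assign_sessions(character(0)), "1 reader")
  solo <- assign_sessions("R1", seed = 3)
  expect_true(solo$readers$session_order %in%
                c("assisted_first", "unassisted_first"))
  # case order: both sessions cover all cases, in their own order
  plan4 <- assign_sessions(sprintf("R%d", 1:4), seed = 2,
                           case_ids = sprintf("P%d", 1:6))
  orders <- split(plan4$case_order$case, plan4$case_order$session)
  expect_setequal(orders[[1]], sprintf("P%d", 1:6))
  expect_setequal(orders[[2]], sprintf("P%d", 1:6))
})

test_that("arm assignment is unbiased across reseeded draws", {
  hits <- vapply(1:1000, function(s) {
    plan <- assign_sessions(sprintf("R%d", 1:10), seed = s)
    plan$readers$session_order[1] == "assisted_first"
  }, logical(1))
  expect_gt(mean(hits), 0.45)
  expect_lt(mean(hits), 0.55)
})

test_that("time saving is a plain percent reduction, negative allowed", {
  expect_equal(time_saving(100, 100), 0)
  expect_equal(time_saving(100, 58), 42)
  expect_equal(time_saving(80, 92), -15)
  expect_error(time_saving(0, 10), "> 0")
})

test_that("analysis refuses silently partial crossover tables", {
  st <- toy_study()
  expect_silent(validate_study(st))
  expect_error(validate_study(st[-1, ]), "incomplete crossover")
  dup <- dplyr::bind_rows(st, st[1, ])
  expect_error(validate_study(dup), "incomplete crossover")
  broken <- st
  broken$time_s[3] <- -1
  expect_error(validate_study(broken), "time_s")
})

test_that("identical modes give zero improvement and a degenerate test", {
  st <- toy_study(effect = 0)
  assisted <- dplyr::filter(st, mode == "assisted")
  unassisted <- dplyr::mutate(assisted, mode = "unassisted",
                              session = 3L - session)
  same <- dplyr::bind_rows(assisted, unassisted)
  cmp <- compare_modes(same, "dsc", n_boot = 200, seed = 1)
  expect_equal(cmp$improvement$median, 0)
  expect_equal(cmp$wilcoxon$p_value, 1)
  expect_equal(cmp$wilcoxon$flag, "degenerate")
})

test_that("mode medians equal an independent group-by oracle", {
  st <- toy_study(effect = 0.04, seed = 8)
  cmp <- compare_modes(st, "dsc", n_boot = 200, seed = 3)
  oracle <- tapply(st$dsc, st$mode, stats::median)
  expect_equal(cmp$per_mode$median[cmp$per_mode$mode == "assisted"],
               unname(oracle["assisted"]))
  expect_equal(cmp$per_mode$median[cmp$per_mode$mode == "unassisted"],
               unname(oracle["unassisted"]))
  # improvement is the median of per-pair differences
  wide <- tidyr::pivot_wider(
    st[, c("reader", "patient", "lesion", "mode", "dsc")],
    names_from = "mode", values_from = "dsc")
  expect_equal(cmp$improvement$median,
               stats::median(wide$assisted - wide$unassisted))
  # tidy/glance round out the broom-style surface
  td <- tidy(cmp)
  expect_equal(nrow(td), 3L)
  expect_equal(glance(cmp)$n_pairs, nrow(wide))
})

test_that("time comparison summarizes per-pair savings, not ratio of medians", {
  st <- toy_study(seed = 4)
  cmp <- compare_modes(st, "time", n_boot = 200, seed = 1)
  wide <- tidyr::pivot_wider(
    st[, c("reader", "patient", "lesion", "mode", "time_s")],
    names_from = "mode", values_from = "time_s")
  expect_equal(cmp$improvement$median,
               stats::median(time_saving(wide$unassisted, wide$assisted)))
})

test_that("stratified comparison recovers group ordering and label symmetry", {
  st <- toy_study(seed = 6)
  # inject a larger assisted effect for residents
  st$dsc <- st$dsc + ifelse(st$mode == "assisted" &
                              st$experience_group == "resident", 0.04, 0)
  grp <- compare_groups(st, "experience_group", "dsc", n_boot = 200, seed = 2)
  med <- stats::setNames(grp$per_stratum$median, grp$per_stratum$stratum)
  expect_gt(med["resident"], med["attending"])
  # relabeling strata swaps the sign of the median difference
  flipped <- st
  flipped$experience_group <- ifelse(st$experience_group == "resident",
                                     "attending", "resident")
  grp2 <- compare_groups(flipped, "experience_group", "dsc",
                         n_boot = 200, seed = 2)
  med2 <- stats::setNames(grp2$per_stratum$median, grp2$per_stratum$stratum)
  expect_equal(unname(med["resident"] - med["attending"]),
               -unname(med2["resident"] - med2["attending"]))
  expect_error(compare_groups(st, "nonsense"), "arg")
})

test_that("patient rollup pools voxel counts, volumes and times", {
  st <- toy_study(seed = 2)
  roll <- patient_level_rollup(st)
  # completeness: readers x patients x modes
  expect_equal(nrow(roll),
               dplyr::n_distinct(st$reader) * dplyr::n_distinct(st$patient) * 2)
  # times sum over lesions within patient
  one <- dplyr::filter(st, reader == "R1", patient == 1, mode == "assisted")
  r1 <- dplyr::filter(roll, reader == "R1", patient == 1, mode == "assisted")
  expect_equal(r1$time_s, sum(one$time_s))
  expect_equal(r1$n_lesions, nrow(one))
  # patient-wise Dice from pooled counts
  expect_equal(r1$dsc, 2 * sum(one$n_overlap) /
                 (sum(one$n_pred) + sum(one$n_gt)))
  # single-lesion patients reduce to the lesion-level values
  single <- dplyr::filter(st, lesion == 1)
  single$patient <- 999
  roll1 <- patient_level_rollup(single)
  expect_equal(nrow(roll1), dplyr::n_distinct(st$reader) * 2)
  expect_equal(roll1$dsc,
               rep(2 * single$n_overlap[1] / (single$n_pred[1] +
                                                single$n_gt[1]),
                   nrow(roll1)))
  expect_equal(sort(roll1$time_s), sort(single$time_s))
  expect_equal(roll1$n_lesions, rep(1L, nrow(roll1)))
})

test_that("quality-time correlations are rank-based and self-consistent", {
  st <- toy_study(seed = 3)
  # a metric equal to time has rho exactly 1
  st$mcc <- st$time_s
  out <- correlate_quality_time(st, metrics = c("mcc"))
  expect_equal(out$rho[out$pair == "mcc vs time"], 1)
  # rescaling time to minutes leaves rho unchanged
  st2 <- st
  st2$time_s <- st2$time_s / 60
  out2 <- correlate_quality_time(st2, metrics = c("dsc"))
  out1 <- correlate_quality_time(st, metrics = c("dsc"))
  expect_equal(out1$rho[1], out2$rho[1])
})

test_that("independent metric and time give small correlations under the null", {
  set.seed(77)
  ps <- replicate(20, {
    n <- 100
    spearman(stats::rnorm(n), stats::rnorm(n))$p_value
  })
  expect_gt(mean(ps > 0.05), 0.7)  # roughly uniform p under the null
})
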