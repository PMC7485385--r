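test_that("fold-change classification uses strict asymmetric thresholds", {
  expect_equal(classify_fc(6.66), "up")
  expect_equal(classify_fc(0.27), "down")
  expect_equal(classify_fc(c(1.5, 1.0, 0.6)), rep("unchanged", 3))
  expect_equal(classify_fc(c(1.5001, 0.5999)), c("up", "down"))
  expect_error(classify_fc(0), "> 0")
  expect_error(classify_fc(2, up_threshold = 0.5, down_threshold = 0.6),
               "below")
})

test_that("group fold changes come from differences of group-mean delta-Ct", {
  sim <- generate_ct_dataset(
    simulation_config(n_features = 50, bio_sd = 0, noise_sd = 0,
                      n_planted = 1, planted_log2fc = 2,
                      baseline_mean = 22, baseline_sd = 1),
    seed = 2)
  norm <- global_mean_normalize(sim$ct,
                                filter_detected(sim$ct)$detected)
  # self-comparison: every fold change exactly 1
  self <- group_fold_change(norm, sim$sheet, "wt.KA", "wt.KA")
  expect_equal(self$fc, rep(1, nrow(self)))

  fc <- group_fold_change(norm, sim$sheet, "ko.KA", "wt.vehicle")
  planted <- sim$truth$planted_features
  # noiseless planted log2FC +2 passes through the pipeline as FC 4;
  # GMN introduces a known offset of (planted effect)/n_detected shared
  # by all features
  gmn_offset <- 2 / length(filter_detected(sim$ct)$detected)
  expect_equal(fc$fc[fc$feature_id == planted], 4 * 2^-gmn_offset,
               tolerance = 1e-9)
  others <- fc$fc[fc$feature_id != planted]
  expect_equal(others, rep(2^-gmn_offset, length(others)),
               tolerance = 1e-9)
  expect_error(group_fold_change(norm, sim$sheet, "nope", "wt.vehicle"),
               "unknown group")
})

test_that("fold changes are invariant to per-sample additive Ct offsets", {
  sim <- generate_ct_dataset(simulation_config(n_features = 40,
                                               baseline_mean = 22,
                                               baseline_sd = 1),
                             seed = 4)
  det <- filter_detected(sim$ct)$detected
  fc1 <- group_fold_change(global_mean_normalize(sim$ct, det),
                           sim$sheet, "ko.KA", "wt.vehicle")
  shifted <- unclass(sim$ct)
  shifted[, "ko.KA_2"] <- shifted[, "ko.KA_2"] + 3.7
  ct2 <- ct_matrix(shifted, negative_controls = "ath-miR159a",
                   endogenous_controls = c("RNU44", "RNU48", "U6-snRNA"))
  fc2 <- group_fold_change(global_mean_normalize(ct2, det),
                           sim$sheet, "ko.KA", "wt.vehicle")
  expect_equal(fc2$fc, fc1$fc, tolerance = 1e-12)
})

test_that("swapping test and reference inverts fc; asymmetric cuts do not swap sets", {
  sim <- generate_ct_dataset(simulation_config(
    n_features = 200, n_planted = 30,
    planted_log2fc = runif(30, -2, 2), baseline_mean = 22,
    baseline_sd = 1.5), seed = 8)
  norm <- global_mean_normalize(sim$ct,
                                filter_detected(sim$ct)$detected)
  ab <- group_fold_change(norm, sim$sheet, "ko.KA", "wt.vehicle")
  ba <- group_fold_change(norm, sim$sheet, "wt.vehicle", "ko.KA")
  m <- match(ab$feature_id, ba$feature_id)
  expect_equal(ba$fc[m], 1 / ab$fc, tolerance = 1e-12)
  # up under (test, ref) is exactly fc < 1/1.5 under the swap
  expect_setequal(ab$feature_id[ab$class == "up"],
                  ba$feature_id[ba$fc < 1 / 1.5])
  # classes partition the detected features
  expect_equal(sum(ab$class == "up") + sum(ab$class == "down") +
                 sum(ab$class == "unchanged"), nrow(ab))
})

test_that("regulated sets split one comparison and refuse mixed ones", {
  rec <- data.frame(feature_id = c("a", "b", "c"),
                    comparison = "x vs y",
                    fc = c(2.0, 0.5, 1.2),
                    class = classify_fc(c(2.0, 0.5, 1.2)),
                    stringsAsFactors = FALSE)
  sets <- regulated_sets(rec)
  expect_equal(sets$up, "a")
  expect_equal(sets$down, "b")
  expect_equal(regulated_sets(transform(rec, class = "unchanged")),
               list(up = character(), down = character()))
  rec$comparison[2] <- "y vs z"
  expect_error(regulated_sets(rec), "multiple comparisons")
})

test_that("per-feature t-tests on delta-Ct attach to the fold-change table", {
  sim <- generate_ct_dataset(simulation_config(
    n_features = 60, n_planted = 3, planted_log2fc = 3,
    baseline_mean = 22, baseline_sd = 1), seed = 12)
  norm <- global_mean_normalize(sim$ct,
                                filter_detected(sim$ct)$detected)
  fc <- group_fold_change(norm, sim$sheet, "ko.KA", "wt.vehicle",
                          with_p = TRUE)
  expect_true(all(fc$p >= 0 & fc$p <= 1))
  planted <- intersect(sim$truth$planted_features, fc$feature_id)
  expect_lt(max(fc$p[fc$feature_id %in% planted]), 0.01)
})
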