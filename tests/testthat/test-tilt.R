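test_that("supine average uses the 5-20 min readings and drops the 0-min one", {
  expect_equal(
    supine_average(c(0, 5, 10, 15, 20), c(130, 120, 122, 118, 120),
                   c(80, 70, 72, 68, 70)),
    c(sbp = 120, dbp = 70))
  expect_equal(
    supine_average(c(5, 10, 15, 20), rep(120, 4), rep(70, 4)),
    c(sbp = 120, dbp = 70))
  expect_equal(
    supine_average(c(5, 10, 15, 20), c(121, 123, 119, 125), c(71, 69, 73, 67)),
    c(sbp = 122, dbp = 70))
  expect_error(
    supine_average(c(5, 10, 20), c(120, 120, 120), c(70, 70, 70)),
    "15")
})

test_that("supine hypertension is >=140 systolic and/or >=90 diastolic, inclusive", {
  expect_true(classify_sh(140, 80))
  expect_false(classify_sh(139.9, 89.9))
  expect_true(classify_sh(130, 90))
  expect_equal(classify_sh(c(140, 120), c(70, 95)), c(TRUE, TRUE))
})

test_that("delta_min takes the per-channel minimum over the 3/5-min pool", {
  expect_equal(
    delta_min(c(3, 5), c(100, 105), c(65, 66), c(sbp = 120, dbp = 70)),
    c(sbp = 20, dbp = 5))
  expect_equal(
    suppressWarnings(delta_min(3, 120, 70, c(sbp = 120, dbp = 70))),
    c(sbp = 0, dbp = 0))
  # a BP rise gives a negative drop: lowest tilted SBP/DBP are 125 and 72
  expect_equal(
    delta_min(c(3, 5), c(130, 125), c(75, 72), c(sbp = 120, dbp = 70)),
    c(sbp = -5, dbp = -2))
  # channels are selected independently: SBP min at 3 min, DBP min at 5 min
  expect_equal(
    delta_min(c(3, 5), c(100, 110), c(68, 60), c(sbp = 120, dbp = 70)),
    c(sbp = 20, dbp = 10))
  # 10-20-min readings never enter the pool
  expect_equal(
    delta_min(c(3, 5, 10), c(100, 105, 60), c(65, 66, 40),
              c(sbp = 120, dbp = 70)),
    c(sbp = 20, dbp = 5))
  expect_error(delta_min(c(10, 15), c(100, 100), c(60, 60),
                         c(sbp = 120, dbp = 70)),
               "3 or 5")
  expect_warning(delta_min(3, 100, 65, c(sbp = 120, dbp = 70)), "incomplete")
})

test_that("OH thresholds are 20/10 mmHg, raised to 30/15 under supine hypertension", {
  expect_true(classify_oh(20, 5, sh = FALSE))
  expect_false(classify_oh(25, 10, sh = TRUE))
  expect_false(classify_oh(0, 0, sh = FALSE))
  expect_true(classify_oh(0, 10, sh = FALSE))
  expect_true(classify_oh(30, 0, sh = TRUE))
  expect_true(classify_oh(0, 15, sh = TRUE))
})

test_that("delta_max takes the per-channel maximum over the 3-20-min pool", {
  expect_equal(
    delta_max(c(3, 5, 10, 15, 20), c(125, 130, 128, 126, 124),
              c(72, 75, 74, 73, 71), c(sbp = 120, dbp = 70)),
    c(sbp = -10, dbp = -5))
  expect_equal(
    delta_max(c(3, 5, 10, 15, 20), rep(120, 5), rep(70, 5),
              c(sbp = 120, dbp = 70)),
    c(sbp = 0, dbp = 0))
  expect_equal(
    suppressWarnings(delta_max(3, 100, 60, c(sbp = 120, dbp = 70))),
    c(sbp = 20, dbp = 10))
  # the tilted 0-min reading is excluded from the pool
  expect_equal(
    suppressWarnings(
      delta_max(c(0, 3), c(160, 125), c(100, 72), c(sbp = 120, dbp = 70))),
    c(sbp = -5, dbp = -2))
  expect_error(delta_max(0, 150, 90, c(sbp = 120, dbp = 70)), "3-20")
})

test_that("OHT needs a 20/10 rise, or (without SH) a tilted BP of 140/90", {
  expect_true(classify_oht(-20, -5, 138, 85, sh = FALSE))
  expect_true(classify_oht(-5, -2, 142, 80, sh = FALSE))
  expect_false(classify_oht(-15, -8, 150, 95, sh = TRUE))
  expect_true(classify_oht(-15, -10, 130, 80, sh = TRUE))
  expect_true(classify_oht(-5, -2, 130, 90, sh = FALSE))
  expect_false(classify_oht(-19.9, -9.9, 139.9, 89.9, sh = FALSE))
})

test_that("tilt_profiles composes the classification end to end", {
  # drop of 20/5 at 3 min, rise to 130/75 later: OH without SH, no OHT
  tilt <- make_tilt(
    supine = list("0" = c(130, 80), "5" = c(120, 70), "10" = c(122, 72),
                  "15" = c(118, 68), "20" = c(120, 70)),
    tilted = list("0" = c(120, 70), "3" = c(100, 65), "5" = c(105, 66),
                  "10" = c(128, 74), "15" = c(130, 75), "20" = c(124, 71)))
  p <- tilt_profiles(tilt)
  expect_equal(p$supine_avg_sbp, 120)
  expect_equal(p$supine_avg_dbp, 70)
  expect_equal(p$delta_sbp_min, 20)
  expect_equal(p$delta_dbp_min, 5)
  expect_equal(p$delta_sbp_max, -10)
  expect_equal(p$delta_dbp_max, -5)
  expect_false(p$sh)
  expect_true(p$oh)
  expect_false(p$oht)

  # flat series: all deltas zero, all flags false
  flat <- make_tilt(
    supine = as.list(setNames(rep(list(c(120, 70)), 5), c(0, 5, 10, 15, 20))),
    tilted = as.list(setNames(rep(list(c(120, 70)), 6), c(0, 3, 5, 10, 15, 20))))
  pf <- tilt_profiles(flat)
  expect_equal(unlist(pf[c("delta_sbp_min", "delta_dbp_min",
                           "delta_sbp_max", "delta_dbp_max")]),
               c(delta_sbp_min = 0, delta_dbp_min = 0,
                 delta_sbp_max = 0, delta_dbp_max = 0))
  expect_false(any(unlist(pf[c("sh", "oh", "oht")])))

  # supine hypertensive whose tilted peak (150/85) is below the 20/10 rise:
  # SH yes, and the 140/90 tilted-BP arm does not apply under SH
  sh_series <- make_tilt(
    supine = as.list(setNames(rep(list(c(145, 80)), 4), c(5, 10, 15, 20))),
    tilted = list("3" = c(140, 78), "5" = c(142, 79), "10" = c(145, 80),
                  "15" = c(150, 85), "20" = c(147, 82)))
  ps <- tilt_profiles(sh_series)
  expect_true(ps$sh)
  expect_equal(ps$delta_sbp_max, -5)
  expect_false(ps$oht)
})

test_that("OH and OHT can co-exist in one patient", {
  # big 3-min drop plus a late rise past the thresholds
  tilt <- make_tilt(
    supine = as.list(setNames(rep(list(c(130, 80)), 4), c(5, 10, 15, 20))),
    tilted = list("3" = c(100, 65), "5" = c(110, 70), "10" = c(140, 85),
                  "15" = c(152, 92), "20" = c(135, 82)))
  p <- tilt_profiles(tilt)
  expect_true(p$oh)
  expect_true(p$oht)
})

test_that("subset-pool monotonicity and order invariance hold on random series", {
  set.seed(421)
  for (i in 1:50) {
    tilt <- random_tilt("r1", full_pools = TRUE)
    p <- tilt_profiles(tilt)
    expect_gte(p$delta_sbp_min, p$delta_sbp_max)
    expect_gte(p$delta_dbp_min, p$delta_dbp_max)
    shuffled <- tilt[sample(nrow(tilt)), ]
    expect_equal(tilt_profiles(shuffled), p)
  }
})

test_that("extra late tilted readings never change delta_min", {
  set.seed(77)
  for (i in 1:20) {
    tilt <- suppressWarnings(random_tilt("r1", full_pools = FALSE))
    has_pool <- any(tilt$time_min[tilt$phase == "tilt"] %in% c(3, 5))
    if (!has_pool) next
    p0 <- suppressWarnings(tilt_profiles(tilt))
    extra <- data.frame(patient_id = "r1", phase = "tilt",
                        time_min = setdiff(c(10, 15, 20),
                                           tilt$time_min[tilt$phase == "tilt"])[1],
                        sbp = 150, dbp = 95)
    if (is.na(extra$time_min)) next
    p1 <- suppressWarnings(tilt_profiles(rbind(tilt, extra)))
    expect_equal(p1$delta_sbp_min, p0$delta_sbp_min)
    expect_equal(p1$delta_dbp_min, p0$delta_dbp_min)
    # a new pool member can only raise the pool maximum (lower delta_max)
    expect_lte(p1$delta_sbp_max, p0$delta_sbp_max)
  }
})

test_that("tilt validation rejects malformed series", {
  tilt <- make_tilt(
    supine = as.list(setNames(rep(list(c(120, 70)), 4), c(5, 10, 15, 20))),
    tilted = list("3" = c(110, 68), "5" = c(112, 69)))
  dup <- rbind(tilt, tilt[1, ])
  expect_error(tilt_profiles(dup), "duplicate")
  bad_bp <- tilt; bad_bp$dbp[1] <- 130
  expect_error(tilt_profiles(bad_bp), "0 < dbp < sbp")
  bad_phase <- tilt; bad_phase$phase[1] <- "standing"
  expect_error(tilt_profiles(bad_phase), "phase")
  expect_error(tilt_profiles(tilt[, -5]), "dbp")
  # errors carry the patient id
  missing_supine <- tilt[tilt$time_min != 10 | tilt$phase != "supine", ]
  expect_error(tilt_profiles(missing_supine), "p1")
})
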