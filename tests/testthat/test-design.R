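test_that("changes are follow-up minus baseline, missing-propagating", {
  ch <- generate_cohort(small_config(n = 25, seed = 4), missingness = FALSE)
  ch$comm_cog[ch$wave == 0 & ch$participant_id == 1] <- 43.0
  ch$comm_cog[ch$wave == 2 & ch$participant_id == 1] <- 43.4
  ch$mood[ch$wave == 1 & ch$participant_id == 2] <- NA
  ch$csi[ch$wave == 3 & ch$participant_id == 3] <-
    ch$csi[ch$wave == 0 & ch$participant_id == 3]
  d <- compute_changes(ch)
  expect_equal(d$comm_cog_change[d$participant_id == 1 & d$wave == 2], 0.4)
  expect_true(is.na(d$mood_change[d$participant_id == 2 & d$wave == 1]))
  expect_equal(d$csi_change[d$participant_id == 3 & d$wave == 3], 0)
  # a participant without a baseline row is a structural error
  expect_error(compute_changes(ch[ch$wave > 0 | ch$participant_id != 5, ]),
               "baseline")
})

test_that("scaling uses observed-entry sample moments and spares indicators", {
  X <- cbind(a = c(1, 2, 3, NA), b = c(0, 1, 1, 0))
  sc <- fit_scaling(X, c("baseline", "indicator"))
  expect_equal(unname(sc$center["a"]), 2)
  expect_equal(unname(sc$scale["a"]), 1)
  Xs <- standardize(X, sc)
  expect_equal(Xs[1:3, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(Xs[, "b"], X[, "b"], ignore_attr = TRUE) # untouched
  expect_equal(unstandardize(Xs, sc)[1:3, ], X[1:3, ], ignore_attr = TRUE)
  expect_error(fit_scaling(cbind(z = c(NA, NA, NA)), "baseline"), "fewer than 2")
  expect_error(fit_scaling(cbind(z = c(1, 1, 1)), "baseline"), "zero-variance")
})

test_that("designs standardize observed entries and keep the mask consistent", {
  ch <- generate_cohort(small_config(n = 400, seed = 6))
  d <- build_design(ch, "full", m_max = 21)
  cont <- d$column_kind %in% c("baseline", "change")
  mu <- colMeans(d$X, na.rm = TRUE)[cont]
  sds <- apply(d$X, 2, sd, na.rm = TRUE)[cont]
  expect_lt(max(abs(mu)), 1e-8)
  expect_lt(max(abs(sds - 1)), 1e-8)
  expect_identical(is.na(d$X), !d$mask)
  expect_true(all(d$y %in% 0:1))
  expect_true(all(d$wave %in% 1:3))
})

test_that("predictor sets nest and the demographic set has no score columns", {
  ch <- generate_cohort(small_config(n = 250, seed = 8))
  cols <- lapply(c(demographic = "demographic",
                   fun = "demographic+function",
                   med = "demographic+medical",
                   full = "full"),
                 function(s) colnames(build_design(ch, s, m_max = 21)$X))
  expect_true(all(cols$demographic %in% cols$fun))
  expect_true(all(cols$demographic %in% cols$med))
  expect_true(all(cols$fun %in% cols$full))
  expect_true(all(cols$med %in% cols$full))
  expect_false(any(grepl("comm_cog|csi|has_drive", cols$demographic)))
  expect_false(any(grepl("csi|bmi|dast", cols$fun)))
  expect_false(any(grepl("comm_cog|has_drive", cols$med)))
  # full columns = union of the three restricted sets
  expect_setequal(cols$full, union(cols$fun, cols$med))
  expect_error(build_design(ch, "everything"), "unknown predictor set")
})

test_that("the missing-functioning filter is monotone in m_max", {
  ch <- generate_cohort(small_config(n = 500, seed = 10))
  kept <- lapply(c(0, 7, 14, 21), function(m) {
    unique(build_design(ch, "demographic", m_max = m)$participant)
  })
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
  expect_true(all(kept[[3]] %in% kept[[4]]))
  expect_length(kept[[4]], 500)
  expect_error(build_design(ch, "full", m_max = 3), "m_max")
})

test_that("a participant with 14 missing measurements is kept at 14, dropped at 7", {
  cfg <- small_config(n = 40)
  ch <- generate_cohort(cfg, missingness = FALSE)
  # blank waves 1 and 2 of all seven scales for participant 1: 14 missing
  idx <- ch$participant_id == 1 & ch$wave %in% 1:2
  ch[idx, steadywork:::FUNCTION_SCALES] <- NA_real_
  d14 <- build_design(ch, "full", m_max = 14)
  d7 <- build_design(ch, "full", m_max = 7)
  expect_true(1 %in% d14$participant)
  expect_false(1 %in% d7$participant)
  expect_equal(d7$n_dropped, 1)
})

test_that("designs round-trip through CSV with a JSON sidecar", {
  ch <- generate_cohort(small_config(n = 60, seed = 12))
  d <- build_design(ch, "demographic+function", m_max = 21)
  tmp <- tempfile(fileext = ".csv")
  write_design(d, tmp)
  back <- utils::read.csv(tmp, na.strings = "")
  expect_equal(nrow(back), nrow(d$X))
  expect_equal(back$comm_cog_change, unname(d$X[, "comm_cog_change"]))
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(side$predictor_set, "demographic+function")
  expect_equal(side$scaling$center$age_baseline,
               unname(d$scaling$center["age_baseline"]))
})
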