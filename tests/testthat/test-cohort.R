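test_that("equal configs generate byte-identical cohorts", {
  cfg <- small_config(n = 120, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cfg
  cfg2$seed <- 8L
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("zero change noise makes every follow-up score equal its baseline", {
  cfg <- small_config(n = 50)
  cfg$scales <- lapply(cfg$scales, function(s) {
    s$change_mean_by_wave <- rep(0, 3)
    s$change_sd_by_wave <- rep(0, 3)
    s
  })
  names(cfg$scales) <- vapply(cfg$scales, `[[`, "", "name")
  ch <- generate_cohort(cfg, missingness = FALSE)
  base <- ch[ch$wave == 0, ]
  for (w in 1:3) {
    fw <- ch[ch$wave == w, ]
    for (s in names(cfg$scales)) expect_equal(fw[[s]], base[[s]])
  }
})

test_that("with zero slopes the prevalence matches the inverse-logit intercept", {
  a <- log(0.173 / 0.827)
  cfg <- config_with_coefficients(c(), n = 1500, seed = 3,
                                  random_intercept_sd = 0)
  cfg$true_coefficients[paste0("intercept_wave", 1:3)] <- a
  ch <- generate_cohort(cfg, missingness = FALSE)
  prev <- mean(ch$steady_work[ch$wave > 0])
  n_obs <- 3 * 1500
  half <- 2.576 * sqrt(0.173 * 0.827 / n_obs)
  expect_lt(abs(prev - plogis(a)), half)
  # zero intercept: symmetric logit -> prevalence about one half
  cfg$true_coefficients[paste0("intercept_wave", 1:3)] <- 0
  ch0 <- generate_cohort(cfg, missingness = FALSE)
  expect_lt(abs(mean(ch0$steady_work[ch0$wave > 0]) - 0.5),
            2.576 * sqrt(0.25 / n_obs))
})

test_that("generated moments recover every configured mean and SD", {
  n <- 2500
  cfg <- small_config(n = n, seed = 11)
  ch <- generate_cohort(cfg, missingness = FALSE)
  mom <- empirical_moments(ch)
  get <- function(v, w, st) mom$value[mom$variable == v & mom$stat == st &
                                        !is.na(mom$wave) & mom$wave == w]
  for (s in cfg$scales) {
    expect_lt(abs(get(s$name, 0, "value_mean") - s$baseline_mean),
              3 * s$baseline_sd / sqrt(n))
    expect_lt(abs(get(s$name, 0, "value_sd") - s$baseline_sd),
              0.1 * s$baseline_sd)
    for (w in 1:3) {
      expect_lt(abs(get(s$name, w, "change_mean") - s$change_mean_by_wave[w]),
                3 * s$change_sd_by_wave[w] / sqrt(n))
      expect_lt(abs(get(s$name, w, "change_sd") - s$change_sd_by_wave[w]),
                0.1 * s$change_sd_by_wave[w])
    }
  }
  for (m in cfg$medical) {
    for (w in 0:3) {
      expect_lt(abs(get(m$name, w, "value_mean") - m$wave_means[w + 1]),
                3 * m$wave_sds[w + 1] / sqrt(n) + 1e-9)
      # heavily overdispersed counts need a Monte Carlo allowance on top of
      # the 10% band: delta-method SE of the sample SD from the 4th moment
      x <- ch[[m$name]][ch$wave == w]
      s <- sd(x)
      se_s <- sqrt(max(mean((x - mean(x))^4) - s^4, 0) / n) / (2 * s)
      expect_lt(abs(get(m$name, w, "value_sd") - m$wave_sds[w + 1]),
                0.1 * m$wave_sds[w + 1] + 3 * se_s)
    }
  }
})

test_that("changes exceed the MDC90 threshold at the normal-tail rate", {
  n <- 3000
  cfg <- small_config(n = n, seed = 13)
  ch <- generate_cohort(cfg, missingness = FALSE)
  base <- ch[ch$wave == 0, ]
  fw <- ch[ch$wave == 1, ]
  for (s in cfg$scales) {
    d <- fw[[s$name]] - base[[s$name]]
    emp <- mean(abs(d) > s$mdc90)
    mu <- s$change_mean_by_wave[1]; sd <- s$change_sd_by_wave[1]
    theo <- 1 - (pnorm((s$mdc90 - mu) / sd) - pnorm((-s$mdc90 - mu) / sd))
    expect_lt(abs(emp - theo), 4 * sqrt(theo * (1 - theo) / n) + 0.005)
  }
})

test_that("block missingness marginals match the configured pattern", {
  cfg <- small_config(n = 2000, seed = 17)
  ch <- generate_cohort(cfg) # default pattern 0.55/0.20/0.15/0.10
  nmiss <- rowsum(rowSums(is.na(ch[, steadywork:::FUNCTION_SCALES])) + 0,
                  ch$participant_id)[, 1]
  expect_true(all(nmiss %in% c(0, 7, 14, 21)))
  probs <- cfg$missingness$block_pattern_probs
  for (k in names(probs)) {
    emp <- mean(nmiss == as.numeric(k))
    expect_lt(abs(emp - probs[[k]]),
              4 * sqrt(probs[[k]] * (1 - probs[[k]]) / 2000))
  }
})

test_that("apply_missingness honors degenerate block patterns", {
  cfg <- small_config(n = 60)
  ch <- generate_cohort(cfg, missingness = FALSE)
  none <- apply_missingness(
    ch, missingness_spec(block_pattern_probs = c(`0` = 1, `7` = 0, `14` = 0, `21` = 0)),
    seed = 5, redraw_presence = FALSE
  )
  expect_false(anyNA(none[, steadywork:::FUNCTION_SCALES]))
  all21 <- apply_missingness(
    ch, missingness_spec(block_pattern_probs = c(`0` = 0, `7` = 0, `14` = 0, `21` = 1)),
    seed = 5, redraw_presence = FALSE
  )
  fu <- all21[all21$wave > 0, steadywork:::FUNCTION_SCALES]
  expect_true(all(is.na(fu)))
  expect_false(anyNA(all21[all21$wave == 0, steadywork:::FUNCTION_SCALES]))
  # 7 scales x 3 blanked waves = 21 missing measurements per participant
  nmiss <- rowsum(rowSums(is.na(all21[, steadywork:::FUNCTION_SCALES])) + 0,
                  all21$participant_id)[, 1]
  expect_true(all(nmiss == 21))
  # applying to an already-blanked cohort is an error
  expect_error(apply_missingness(all21, cfg$missingness), "complete")
})

test_that("presence probabilities drive the Community Mobility missing rate", {
  cfg <- small_config(n = 2500)
  ch <- generate_cohort(cfg, missingness = FALSE)
  spec <- missingness_spec(drive_presence_by_wave = rep(0.40, 4))
  ch2 <- apply_missingness(ch, spec, seed = 9)
  expect_lt(abs(mean(ch2$has_drive == 0) - 0.60), 0.02)
})

test_that("empirical moments match a hand-computed table", {
  ch <- generate_cohort(small_config(n = 30), missingness = FALSE)
  mom <- empirical_moments(ch)
  mood0 <- ch$mood[ch$wave == 0]
  expect_equal(mom$value[mom$variable == "mood" & mom$stat == "value_mean" &
                           mom$wave %in% 0], mean(mood0))
  expect_equal(mom$value[mom$variable == "mood" & mom$stat == "value_sd" &
                           mom$wave %in% 0], sd(mood0))
  d2 <- ch$csi[ch$wave == 2] - ch$csi[ch$wave == 0]
  expect_equal(mom$value[mom$variable == "csi" & mom$stat == "change_mean" &
                           mom$wave %in% 2], mean(d2))
  # constant scores -> SD exactly 0 (two participants, no dispersion)
  two <- ch[ch$participant_id %in% 1:2, ]
  two$mood <- 42
  m1 <- empirical_moments(two)
  expect_equal(m1$value[m1$variable == "mood" & m1$stat == "value_sd" &
                          m1$wave %in% 0], 0)
  expect_equal(m1$value[m1$variable == "mood" & m1$stat == "change_sd" &
                          m1$wave %in% 1], 0)
  # a single observed value leaves the SD undefined, never zero
  one <- ch[ch$participant_id == 1, ]
  m1b <- empirical_moments(one)
  expect_true(is.na(m1b$value[m1b$variable == "mood" & m1b$stat == "value_sd" &
                                m1b$wave %in% 0]))
  # a variable that is entirely missing reports NA, never zero
  ch$audit <- NA_real_
  m2 <- empirical_moments(ch)
  expect_true(all(is.na(m2$value[m2$variable == "audit"])))
  expect_error(empirical_moments(ch[0, ]), "empty")
})

test_that("cohorts round-trip through tidy CSV with explicit missing cells", {
  ch <- generate_cohort(small_config(n = 40, seed = 2))
  tmp <- tempfile(fileext = ".csv")
  write_cohort(ch, tmp)
  expect_false(any(grepl("NA", readLines(tmp)[-1], fixed = TRUE)))
  ch2 <- read_cohort(tmp)
  expect_equal(as.data.frame(ch)$mood, ch2$mood, tolerance = 1e-12)
  expect_identical(ch$steady_work, ch2$steady_work)
  expect_identical(is.na(ch$comm_cog), is.na(ch2$comm_cog))
})
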