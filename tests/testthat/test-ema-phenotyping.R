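# Diary ingestion, window filtering, variability metrics and the
# phenotype classification rules.

test_that("read_diary keeps valid rows and rejects bad ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,timestamp,scale,score",
    "P1,2019-01-07T08:05:00,pain,4",
    "P1,2019-01-07T14:02:00,pain,5",
    "P1,2019-01-07T20:01:00,pain,11",
    "P1,not-a-time,pain,3",
    "P2,2019-01-07T08:00:00,pain,0"), path)
  suppressMessages(d <- read_diary(path))
  expect_equal(nrow(d), 3)
  rej <- attr(d, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$row, c(3, 4))
})

test_that("read_diary errors on missing columns, warns on empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,timestamp,score", path)
  expect_error(read_diary(path), "scale")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,timestamp,scale,score", path2)
  expect_warning(d <- read_diary(path2), "no entries")
  expect_equal(nrow(d), 0)
})

test_that("window filter keeps entries within +/-1 h, closest wins", {
  mk <- function(ts, score) data.frame(
    participant_id = "P1", timestamp = ts, scale = "pain", score = score,
    stringsAsFactors = FALSE)
  entries <- rbind(
    mk("2019-01-07T08:45:00", 4),   # within the 08:00 window
    mk("2019-01-07T09:15:00", 9),   # 75 min away: discarded
    mk("2019-01-08T07:30:00", 2),   # 30 min before 08:00
    mk("2019-01-08T08:10:00", 6),   # closer: wins the slot
    mk("2019-01-08T20:30:00", 7))
  g <- window_filter(entries, scale = "pain")[["P1"]]
  expect_equal(g[1, "08:00"], 4)
  expect_true(all(is.na(g[1, 2:3])))
  expect_equal(g[2, "08:00"], 6)
  expect_equal(g[2, "20:00"], 7)
})

test_that("daily stats match closed forms", {
  g <- matrix(NA_real_, 7, 3)
  g[1, ] <- c(2, 4, 6)
  s <- daily_stats(g)
  expect_equal(s$day_mean[1], 4)
  expect_equal(s$day_sd[1], 2)
  expect_equal(s$n_evaluable_days, 1L)
  g2 <- matrix(5, 7, 3)
  s2 <- daily_stats(g2)
  expect_equal(s2$variability, 0)
  expect_equal(s2$mean_intensity, 5)
  g3 <- matrix(NA_real_, 7, 3); g3[1, 1] <- 4   # no SD-evaluable day
  expect_false(daily_stats(g3)$classifiable)
})

test_that("variability and intensity splits follow the median rules", {
  expect_equal(split_variability(c(0.5, 1.0, 1.5, 2.0)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_warning(all_low <- split_variability(rep(1.3, 5)), "identical")
  expect_false(any(all_low))
  expect_equal(classify_constant(c(2, 3, 6, 7)),
               c("constant_low", "constant_low", "constant_high",
                 "constant_high"))
  expect_true(all(classify_constant(rep(4, 3)) == "constant_low"))
})

test_that("rhythm detection applies the relative 30% rule on 4/7 days", {
  g <- matrix(rep(c(4, 5, 6), each = 7), 7, 3)   # +50% every day
  r <- detect_rhythmic(g)
  expect_equal(r$label, "rhythmic_up")
  expect_equal(r$n_increase_days, 7)
  g2 <- matrix(rep(c(5, 5, 6), each = 7), 7, 3)  # +20% < 30%
  expect_equal(detect_rhythmic(g2)$label, "none")
  # zero-denominator convention: 0 -> positive counts as increasing
  g3 <- matrix(rep(c(0, 1, 2), each = 7), 7, 3)
  expect_equal(detect_rhythmic(g3)$label, "rhythmic_up")
  g4 <- matrix(0, 7, 3)                          # 0 -> 0 is no change
  expect_equal(detect_rhythmic(g4)$label, "none")
  # days missing an anchor cannot qualify
  g5 <- matrix(rep(c(4, 5, 6), each = 7), 7, 3); g5[1:4, 3] <- NA
  expect_equal(detect_rhythmic(g5)$label, "none")
  expect_equal(detect_rhythmic(g5)$n_increase_days, 3)
})

test_that("phenotyping partitions the cohort and is order-invariant", {
  set.seed(42)
  grids <- setNames(replicate(8, random_grid(), simplify = FALSE),
                    sprintf("P%02d", 1:8))
  diary <- grids_to_diary(grids)
  ph <- phenotype_cohort(diary)
  expect_setequal(ph$participant_id, names(grids))
  expect_true(all(!is.na(ph$label)))
  expect_true(all(table(ph$participant_id) == 1))
  # permutation invariance
  diary2 <- diary[rev(seq_len(nrow(diary))), ]
  ph2 <- phenotype_cohort(diary2)
  expect_identical(ph[order(ph$participant_id), "label"],
                   ph2[order(ph2$participant_id), "label"])
})

test_that("raising the threshold never creates new rhythmic labels", {
  set.seed(7)
  for (rep in 1:20) {
    grids <- setNames(replicate(6, random_grid(), simplify = FALSE),
                      sprintf("P%02d", 1:6))
    diary <- grids_to_diary(grids)
    lo <- phenotype_cohort(diary, rel_threshold = 0.30)
    hi <- phenotype_cohort(diary, rel_threshold = 0.60)
    was_rhythmic <- lo$label %in% c("rhythmic_up", "rhythmic_down")
    is_rhythmic <- hi$label %in% c("rhythmic_up", "rhythmic_down")
    expect_true(all(!is_rhythmic | was_rhythmic))
  }
})

test_that("labels equal the straight-line oracle on random small cohorts", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    grids <- setNames(replicate(n, random_grid(), simplify = FALSE),
                      sprintf("P%02d", seq_len(n)))
    diary <- grids_to_diary(grids)
    ph <- phenotype_cohort(diary)
    want <- oracle_phenotype(grids)
    got <- setNames(ph$label, ph$participant_id)[names(want)]
    expect_identical(unname(got), unname(want))
  }
})

test_that("the classifier applies unchanged to the mood scale", {
  cfg <- cohort_config(seed = 3, n_per_phenotype = c(
    constant_low = 4, rhythmic_up = 4, mixed = 4))
  sim <- gen_diaries(cfg)
  ph <- phenotype_cohort(sim$diary, scale = "mood")
  expect_equal(nrow(ph), 12)
  expect_true(all(ph$label %in% c("constant_low", "constant_high",
                                  "rhythmic_up", "rhythmic_down", "mixed",
                                  "unclassifiable")))
})

test_that("generated cohorts are recovered at >= 95% under low noise", {
  cfg <- cohort_config(seed = 11, low_noise = TRUE, n_per_phenotype = c(
    constant_low = 25, constant_high = 25, rhythmic_up = 25, mixed = 25))
  sim <- gen_diaries(cfg)
  ph <- phenotype_cohort(sim$diary)
  m <- merge(ph, sim$truth, by = "participant_id")
  expect_gte(mean(m$label == m$phenotype), 0.95)
})
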