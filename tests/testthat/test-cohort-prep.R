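test_that("exclusion drops exactly the incomplete records", {
  # missingness calibrated so a 959-record cohort loses 407 participants
  cfg <- synthetic_config(seed = 1, n_autistic = 538, n_nonautistic = 421,
                          missing_rate = 407 / 959)
  co <- generate_cohort(cfg)
  kept <- suppressMessages(exclude_incomplete(co))
  expect_equal(nrow(kept), 552)
  expect_equal(attr(kept, "n_excluded"), 407)
  expect_identical(kept$participant_id,
                   co$participant_id[complete.cases(co[, cohort_feature_names(co)])])

  complete <- generate_cohort(synthetic_config(seed = 2, n_autistic = 5,
                                               n_nonautistic = 5))
  kept_all <- suppressMessages(exclude_incomplete(complete))
  expect_equal(attr(kept_all, "n_excluded"), 0)
  attr(kept_all, "n_excluded") <- NULL
  expect_identical(as.data.frame(kept_all), as.data.frame(complete))

  all_missing <- complete
  all_missing[, cohort_feature_names(complete)[1]] <- NA_real_
  expect_warning(suppressMessages(exclude_incomplete(all_missing)),
                 "no complete records")
})

test_that("forced matching returns every pair with identical marginals", {
  ages <- c(25, 30, 35, 40)
  co <- data.frame(
    participant_id = sprintf("P%02d", 1:8),
    group = factor(rep(c("autistic", "nonautistic"), each = 4),
                   levels = c("autistic", "nonautistic")),
    age = c(ages, ages),
    gender = factor(rep(c("w", "w", "m", "m"), 2), levels = c("w", "m")),
    aq_total = 70, icar = 0.5, mcg_01 = rnorm(8))
  attr(co, "task_blocks") <- c(mcg = 1L)
  m <- suppressMessages(match_age_gender(co, seed = 4))
  expect_equal(attr(m, "n_pairs"), 4)
  expect_equal(mean(m$age[m$group == "autistic"]),
               mean(m$age[m$group == "nonautistic"]))
  expect_identical(table(m$gender[m$group == "autistic"]),
                   table(m$gender[m$group == "nonautistic"]))
})

test_that("matching fails loudly when no pairs are feasible", {
  co <- data.frame(
    participant_id = sprintf("P%02d", 1:6),
    group = factor(rep(c("autistic", "nonautistic"), each = 3),
                   levels = c("autistic", "nonautistic")),
    age = c(20, 21, 22, 60, 61, 62),
    gender = factor(rep("w", 6), levels = c("w", "m")),
    aq_total = 70, icar = 0.5)
  expect_error(suppressMessages(match_age_gender(co, seed = 1)),
               "no feasible")
})

test_that("matching the realistic cohort yields equal balanced groups", {
  co <- generate_cohort(synthetic_config(seed = 11))
  m <- suppressMessages(match_age_gender(co, seed = 2))
  n_pairs <- attr(m, "n_pairs")
  expect_lte(n_pairs, 266)
  expect_equal(sum(m$group == "autistic"), n_pairs)
  expect_equal(sum(m$group == "nonautistic"), n_pairs)
  expect_identical(table(m$gender[m$group == "autistic"]),
                   table(m$gender[m$group == "nonautistic"]))
  expect_equal(mean(round(m$age[m$group == "autistic"])),
               mean(round(m$age[m$group == "nonautistic"])))
  # every reported pair is genuinely feasible: verified by exhaustive check
  aut <- m[m$group == "autistic", ]
  ctl <- m[m$group == "nonautistic", ]
  expect_true(all(ctl$gender == aut$gender &
                    round(ctl$age) == round(aut$age)))
  expect_false(any(duplicated(m$participant_id)))

  # idempotence: re-matching a matched cohort preserves size and marginals
  m2 <- suppressMessages(match_age_gender(m, seed = 9))
  expect_equal(attr(m2, "n_pairs"), n_pairs)
  expect_equal(sort(round(m2$age)), sort(round(m$age)))
})

test_that("train/test split sizes follow the rounding convention", {
  s <- split_train_test(n = 552, train_fraction = 0.8)
  expect_equal(length(s$train_indices), 442)
  expect_equal(length(s$test_indices), 110)
  s <- split_train_test(n = 250, train_fraction = 0.8)
  expect_equal(length(s$train_indices), 200)
  expect_equal(length(s$test_indices), 50)

  for (n in c(2:40, sample(41:1000, 40))) {
    s <- split_train_test(n = n, train_fraction = 0.8, seed = n)
    expect_equal(sort(c(s$train_indices, s$test_indices)), seq_len(n))
    expected_test <- max(1, min(n - 1, round(n * 0.2)))
    expect_length(s$test_indices, expected_test)
  }
  expect_error(split_train_test(n = 1), "at least 2")
  expect_error(split_train_test(n = 10, train_fraction = 1), "between 0 and 1")
})

test_that("split specs survive a JSON round trip", {
  s <- split_train_test(n = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(s, path)
  expect_identical(read_split(path), s)
})

test_that("feature matrix has the expected columns and guards", {
  co <- generate_cohort(synthetic_config(seed = 3, n_autistic = 30,
                                         n_nonautistic = 30))
  fm <- build_feature_matrix(co)
  expect_length(fm$feature_names, 56)
  expect_identical(tail(fm$feature_names, 2), c("age", "gender"))
  expect_identical(fm$labels, as.integer(co$group == "autistic"))

  fm57 <- build_feature_matrix(co, include_aq = TRUE)
  expect_length(fm57$feature_names, 57)
  expect_error(append_aq(fm57, co$aq_total), "already present")

  with_missing <- generate_cohort(synthetic_config(
    seed = 4, n_autistic = 30, n_nonautistic = 30, missing_rate = 0.5))
  expect_error(build_feature_matrix(with_missing), "exclude_incomplete")
})

test_that("cohort summary flags large group shifts and only those", {
  base <- generate_cohort(synthetic_config(seed = 6, n_autistic = 125,
                                           n_nonautistic = 125))
  # identical groups: copy the autistic rows into the comparison group
  same <- base
  ctl_rows <- which(same$group == "nonautistic")
  aut_rows <- which(same$group == "autistic")
  same[ctl_rows, setdiff(names(same), c("participant_id", "group"))] <-
    same[aut_rows[seq_along(ctl_rows)],
         setdiff(names(same), c("participant_id", "group"))]
  tab_same <- cohort_summary(same)
  expect_false(any(tab_same$significant))

  # a 23-point AQ shift at n = 125 per group must be flagged
  shifted <- base
  shifted$aq_total[shifted$group == "autistic"] <-
    shifted$aq_total[shifted$group == "nonautistic"][1:125] + 23
  tab <- cohort_summary(shifted)
  expect_true(tab$significant[tab$variable == "aq_total"])

  one_each <- base[c(1, 300), ]
  expect_error(cohort_summary(one_each), "at least two")

  const <- base
  const$icar <- 0.5
  expect_warning(tab_const <- cohort_summary(const), "constant")
  expect_equal(tab_const$p_value[tab_const$variable == "icar"], 1)
})
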