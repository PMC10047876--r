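test_that("a perfect study yields a report of ones and top bands", {
  perfect <- lapply(1:4, function(i) rater_profile(paste0("p", i), 1, 1, 0))
  sim <- simulate_study(study_config(n_subjects = 15, raters = perfect,
                                     seed = 3))
  rpt <- run_pipeline(sim$occasion1, sim$occasion2)
  expect_equal(rpt$intra$ac1, rep(1, 4))
  expect_equal(rpt$intra$wac1, rep(1, 4))
  expect_equal(rpt$intra_groups$ac1, 1, tolerance = 1e-9)
  expect_true(all(rpt$intra$band == "almost perfect"))
  expect_true(all(rpt$intra$adequate))
  expect_equal(rpt$inter$ac1, rep(1, nrow(rpt$inter)), tolerance = 1e-9)
})

test_that("group rows pool exactly their member rows", {
  sim <- simulate_study(study_config(seed = 12))
  rpt <- run_pipeline(sim$occasion1, sim$occasion2,
                      rater_groups = default_groups())
  expect_setequal(rpt$intra_groups$group,
                  c("all", "experienced", "well-trained"))
  members <- list(
    all = rpt$intra$rater,
    experienced = c("experienced1", "experienced2"),
    `well-trained` = c("experienced1", "experienced2", "trained1",
                       "trained2", "trained3", "trained4")
  )
  for (g in names(members)) {
    rows <- rpt$intra[rpt$intra$rater %in% members[[g]], ]
    grow <- rpt$intra_groups[rpt$intra_groups$group == g, ]
    expect_equal(grow$n_raters, nrow(rows))
    for (col in c("ac1", "wac1", "pct", "wpct")) {
      expect_equal(grow[[col]], fisher_pool(rows[[col]])$estimate,
                   tolerance = 1e-9)
    }
  }
  # pooled inter-rater row pools the two occasion rows
  for (g in names(members)) {
    occ <- rpt$inter[rpt$inter$group == g & rpt$inter$occasion != "pooled", ]
    pooled <- rpt$inter[rpt$inter$group == g & rpt$inter$occasion == "pooled", ]
    expect_equal(pooled$ac1, fisher_pool(occ$ac1)$estimate,
                 tolerance = 1e-9)
  }
})

test_that("the pipeline is deterministic and rejects unknown raters", {
  sim <- simulate_study(study_config(seed = 8))
  r1 <- run_pipeline(sim$occasion1, sim$occasion2,
                     rater_groups = default_groups())
  r2 <- run_pipeline(sim$occasion1, sim$occasion2,
                     rater_groups = default_groups())
  expect_identical(r1, r2)
  expect_error(
    run_pipeline(sim$occasion1, sim$occasion2,
                 rater_groups = data.frame(rater_id = "ghost",
                                           group = "experienced")),
    "unknown rater"
  )
})

test_that("ratings validation reports every violation with row numbers", {
  df <- data.frame(
    subject_id = c("s1", "s1", "s2", "s2", "s1"),
    rater_id = c("r1", "r2", "r1", "r2", "r1"),
    occasion = c(1, 1, 1, "one", 1),
    rating = c("3c", "5c", "", "4cp", "3cp"),
    stringsAsFactors = FALSE
  )
  v <- validate_ratings(df)
  expect_null(v$data)
  expect_true(any(grepl("row 3: rating '5c'", v$errors)))
  expect_true(any(grepl("3c, 3cp, 4c, 4cp", v$errors)))
  expect_true(any(grepl("row 5: occasion 'one'", v$errors)))
  expect_true(any(grepl("row 6: duplicate", v$errors)))
  # the empty cell on row 4 is missing data, not an error
  expect_false(any(grepl("row 4", v$errors)))

  clean <- validate_ratings(df[c(1, 3), ])
  expect_equal(length(clean$errors), 0L)
  expect_true(is.na(clean$data$rating[2]))
})

test_that("ratings round-trip losslessly through the long CSV format", {
  sim <- simulate_study(study_config(seed = 44))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(list(`1` = sim$occasion1, `2` = sim$occasion2), path)
  back <- read_ratings(path)
  expect_equal(unclass(back[["1"]]), unclass(sim$occasion1),
               ignore_attr = TRUE)
  expect_equal(unclass(back[["2"]]), unclass(sim$occasion2),
               ignore_attr = TRUE)
  expect_true(anyNA(unclass(back[["1"]])))  # missing cells survived
})

test_that("report CSVs round-trip and the default study matches the golden file", {
  sim <- simulate_study(study_config(seed = 423))
  rpt <- run_pipeline(sim$occasion1, sim$occasion2,
                      rater_groups = default_groups())
  prefix <- withr::local_tempfile()
  paths <- write_report(rpt, prefix)
  back <- read.csv(paths[1], stringsAsFactors = FALSE)
  expect_equal(back$ac1, rpt$intra$ac1, tolerance = 1e-12)
  expect_equal(back$rater, rpt$intra$rater)

  golden <- read.csv(test_path("golden-report.csv"),
                     stringsAsFactors = FALSE)
  got <- rpt$intra[, c("rater", "ac1", "pct", "wac1", "wpct")]
  rownames(got) <- NULL
  expect_equal(got$rater, golden$rater)
  for (col in c("ac1", "pct", "wac1", "wpct")) {
    expect_equal(got[[col]], golden[[col]], tolerance = 1e-8)
  }
})
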