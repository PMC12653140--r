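test_that("load_cohort maps columns, preserves rows, and handles empties", {
  df <- rbind(base_record(id = "A"), base_record(id = "B", waist = 110),
              base_record(id = "C", glucose = NA))
  path <- write_cohort_csv(df)
  rec <- load_cohort(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$id, c("A", "B", "C"))
  expect_equal(rec$waist, c(95, 110, 95))
  expect_true(is.na(rec$glucose[3]))

  # header-only file
  path0 <- write_cohort_csv(df[0, , drop = FALSE])
  expect_equal(nrow(load_cohort(path0)), 0)

  # renamed source columns via the map
  df2 <- df
  names(df2)[names(df2) == "waist"] <- "WAISTCM"
  names(df2)[names(df2) == "sex"] <- "GENDER"
  rec2 <- load_cohort(write_cohort_csv(df2),
                      column_map = c(waist = "WAISTCM", sex = "GENDER"))
  expect_equal(rec2$waist, rec$waist)
  expect_equal(rec2$sex, rec$sex)
})

test_that("rows with PHQ items outside 0..3 are rejected with a logged reason", {
  df <- rbind(base_record(id = "A"), base_record(id = "B", phq3 = 5),
              base_record(id = "C", phq1 = 1.5))
  expect_message(rec <- load_cohort(write_cohort_csv(df)), "rejected 2")
  expect_equal(rec$id, "A")
  rej <- attr(rec, "rejections")
  expect_equal(rej$id, c("B", "C"))
  expect_match(rej$reason[1], "phq3")
})

test_that("unparseable numerics become missing and duplicate ids error", {
  df <- base_record(id = "A", hdl = "not-a-number")
  expect_true(is.na(load_cohort(write_cohort_csv(df))$hdl))
  dup <- rbind(base_record(id = "A"), base_record(id = "A"))
  expect_error(load_cohort(write_cohort_csv(dup)), "duplicated")
})

test_that("inclusion requires medication AND diagnosis code AND complete data", {
  df <- rbind(
    base_record(id = "keep", icd_codes = "F33.9"),
    base_record(id = "bipolar", icd_codes = "F31.0"),
    base_record(id = "no_med", on_psychotropic = FALSE),
    base_record(id = "no_glucose", glucose = NA),
    base_record(id = "no_phq", phq7 = NA),
    base_record(id = "other_f32", icd_codes = "F32.1"))  # no prefix matching
  kept <- apply_inclusion(df)
  expect_equal(kept$id, "keep")
  # code normalisation: whitespace and case
  df2 <- base_record(id = "x", icd_codes = " f32.9 ;E11.9")
  expect_equal(nrow(apply_inclusion(df2)), 1)
  # nothing passes -> empty, not an error
  expect_equal(nrow(apply_inclusion(df[2:3, ])), 0)
})

test_that("3-of-5 classification matches the published rule at its boundaries", {
  # male at the MetS-group mean panel: waist, TG, glucose flagged -> status
  m <- base_record(sex = "male", waist = 113.984, triglycerides = 192.397,
                   hdl = 43.914, sbp = 128.671, dbp = 73.967,
                   glucose = 134.025)
  cls <- classify_mets(m)
  expect_true(cls$flag_waist && cls$flag_triglycerides && cls$flag_glucose)
  expect_false(cls$flag_hdl || cls$flag_bp)
  expect_equal(cls$mets_count, 3L)
  expect_true(cls$mets_status)

  # all below thresholds
  f0 <- base_record(sex = "female", waist = 80, triglycerides = 100,
                    hdl = 60, sbp = 110, dbp = 70, glucose = 90)
  expect_equal(classify_mets(f0)$mets_count, 0L)
  expect_false(classify_mets(f0)$mets_status)

  # boundary semantics: >= everywhere except HDL, which is strict <
  fb <- base_record(sex = "female", waist = 88.0, triglycerides = 149.9,
                    hdl = 50.0, sbp = 129, dbp = 80.0, glucose = 100.0)
  cls <- classify_mets(fb)
  expect_true(cls$flag_waist)        # 88.0 >= 88
  expect_false(cls$flag_triglycerides)  # 149.9 < 150
  expect_false(cls$flag_hdl)         # 50.0 is NOT < 50
  expect_true(cls$flag_bp)           # dbp 80.0 >= 80
  expect_true(cls$flag_glucose)      # 100.0 >= 100
  expect_equal(cls$mets_count, 3L)
  expect_true(cls$mets_status)
})

test_that("classification errors name the missing field", {
  expect_error(classify_mets(base_record(glucose = NA)), "glucose")
  bad <- base_record(); bad$sex <- "unknown"
  expect_error(classify_mets(bad), "sex")
})

test_that("group split is a partition with the engineered sizes", {
  recs <- do.call(rbind, c(
    lapply(1:4, function(i) mets_k_record(3 + (i %% 3), paste0("M", i))),
    lapply(1:6, function(i) mets_k_record(i %% 3, paste0("N", i)))))
  g <- split_groups(recs)
  expect_equal(nrow(g$mets), 4)
  expect_equal(nrow(g$non_mets), 6)
  expect_equal(nrow(g$mets) + nrow(g$non_mets), nrow(recs))

  allnorm <- do.call(rbind, lapply(1:5, function(i)
    mets_k_record(0, paste0("Z", i))))
  g0 <- split_groups(allnorm)
  expect_equal(nrow(g0$mets), 0)
  one <- split_groups(mets_k_record(4))
  expect_equal(c(nrow(one$mets), nrow(one$non_mets)), c(1, 0))
})

test_that("crossing any single criterion threshold never lowers the count", {
  set.seed(42)
  for (rep in 1:20) {
    rec <- base_record(sex = sample(c("male", "female"), 1),
                       waist = runif(1, 70, 130),
                       triglycerides = runif(1, 50, 300),
                       hdl = runif(1, 25, 80), sbp = runif(1, 100, 160),
                       dbp = runif(1, 60, 100), glucose = runif(1, 70, 160))
    base_count <- classify_mets(rec)$mets_count
    up <- rec; up$waist <- 140; up$triglycerides <- 300; up$sbp <- 170
    up$glucose <- 200; up$hdl <- 10  # HDL crosses by LOWERING
    for (f in c("waist", "triglycerides", "sbp", "glucose", "hdl")) {
      mod <- rec; mod[[f]] <- up[[f]]
      expect_gte(classify_mets(mod)$mets_count, base_count)
    }
    # purity: same record classifies identically
    expect_identical(classify_mets(rec), classify_mets(rec))
  }
})
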