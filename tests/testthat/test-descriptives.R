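test_that("pooled Cohen's d reproduces published group contrasts", {
  # waist circumference and PHQ total rows of the sample-characteristics table
  expect_equal(round(pooled_cohens_d(113.984, 15.114, 315,
                                     105.225, 18.059, 1464), 3), 0.498)
  expect_equal(round(pooled_cohens_d(9.463, 5.857, 315,
                                     8.769, 5.800, 1464), 3), 0.119)
  expect_equal(pooled_cohens_d(5, 2, 10, 5, 3, 10), 0)
  expect_error(pooled_cohens_d(1, 0, 10, 2, 0, 10), "pooled variance")
})

test_that("odds ratio uses the female-in-MetS orientation and plain arithmetic", {
  expect_equal(round(odds_ratio(207, 108, 991, 473), 2), 0.91)
  expect_equal(odds_ratio(10, 10, 20, 20), 1)
  expect_equal(odds_ratio(10, 10, 5, 20), 4)
  expect_error(odds_ratio(10, 0, 5, 20), "zero cell")
})

test_that("pooled t test matches hand computation and relates to d", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  ht <- student_t(x, y)
  expect_equal(ht$statistic, -3.674, tolerance = 1e-3)
  expect_equal(ht$p_value, 0.0214, tolerance = 1e-2)
  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # algebraic identity t = d * sqrt(n1 n2 / (n1 + n2)), any inputs
  set.seed(5)
  for (i in 1:10) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3)); y <- rnorm(n2, 1)
    d <- pooled_cohens_d(mean(x), sd(x), n1, mean(y), sd(y), n2)
    expect_equal(student_t(x, y)$statistic, d * sqrt(n1 * n2 / (n1 + n2)),
                 tolerance = 1e-10)
  }
})

test_that("chi-square is the uncorrected Pearson statistic and is symmetric", {
  prop <- rbind(c(10, 30), c(20, 60))
  expect_equal(chi_square(prop)$statistic, 0)
  expect_equal(chi_square(prop)$p_value, 1)
  ht <- chi_square(rbind(c(10, 20), c(20, 10)))
  expect_equal(ht$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(ht$p_value, 0.0098, tolerance = 1e-2)
  tab <- rbind(c(3, 9, 5), c(8, 2, 7))
  expect_equal(chi_square(tab)$statistic, chi_square(tab[, 3:1])$statistic)
  expect_equal(chi_square(tab)$statistic, chi_square(tab[2:1, ])$statistic)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "expected")
})

test_that("effect sizes are antisymmetric under group swap", {
  d12 <- pooled_cohens_d(10, 2, 30, 8, 3, 50)
  d21 <- pooled_cohens_d(8, 3, 50, 10, 2, 30)
  expect_equal(d12, -d21)
  expect_equal(odds_ratio(207, 108, 991, 473),
               1 / odds_ratio(991, 473, 207, 108))
})

test_that("summary_table reports groups, effects and stars per variable", {
  set.seed(9)
  g1 <- data.frame(sex = sample(c("female", "male"), 60, TRUE),
                   age = rnorm(60, 55, 10), waist = rnorm(60, 114, 15))
  g2 <- data.frame(sex = sample(c("female", "male"), 80, TRUE),
                   age = rnorm(80, 53, 12), waist = rnorm(80, 95, 15))
  spec <- data.frame(variable = c("sex", "age", "waist"),
                     kind = c("categorical", "continuous", "continuous"))
  tbl <- summary_table(g1, g2, spec)
  expect_equal(tbl$variable, spec$variable)
  expect_equal(tbl$effect_type, c("odds_ratio", "cohens_d", "cohens_d"))
  expect_equal(tbl$n_mets, rep(60L, 3))
  waist_row <- tbl[tbl$variable == "waist", ]
  expect_gt(waist_row$effect, 0.5)
  expect_equal(waist_row$stars, "***")
  expect_true(all(tbl$p_value[tbl$stars == ""] >= 0.05))
  # identical groups: d exactly 0
  same <- summary_table(g1, g1, spec[2, , drop = FALSE])
  expect_equal(same$effect, 0)
  expect_error(summary_table(g1, g2, data.frame(variable = "bmi",
                                                kind = "continuous")), "bmi")
})

test_that("under equal group distributions effects are null-sized", {
  # both groups drawn from one distribution: significant rows should occur
  # at roughly the alpha rate and |d| should be small at n = 1000/group
  set.seed(31)
  n_sig <- 0; n_rows <- 0
  for (rep in 1:3) {
    pool <- data.frame(age = rnorm(2000, 50, 10), bmi = rnorm(2000, 30, 6),
                       hdl = rnorm(2000, 50, 14))
    g1 <- pool[1:1000, ]; g2 <- pool[1001:2000, ]
    spec <- data.frame(variable = names(pool),
                       kind = rep("continuous", 3))
    tbl <- summary_table(g1, g2, spec)
    expect_lt(max(abs(tbl$effect)), 0.15)
    n_sig <- n_sig + sum(tbl$p_value < 0.05)
    n_rows <- n_rows + nrow(tbl)
  }
  expect_lte(n_sig / n_rows, 0.2)
})

test_that("summary tables serialise to TSV and JSON", {
  g1 <- data.frame(age = rnorm(20, 50)); g2 <- data.frame(age = rnorm(20, 50))
  tbl <- summary_table(g1, g2, data.frame(variable = "age",
                                          kind = "continuous"))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_summary_table(tbl, tsv, js)
  back <- read.delim(tsv)
  expect_equal(back$effect, tbl$effect, tolerance = 1e-6)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$variable, "age")
})
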