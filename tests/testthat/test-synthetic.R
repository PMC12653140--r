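test_that("preset ground-truth networks have the published arc sets", {
  gm <- make_preset_dag("mets")
  gn <- make_preset_dag("non_mets")
  expect_equal(narcs(gm), 11)
  expect_equal(narcs(gn), 21)
  expect_true(is_acyclic(gm))
  expect_true(is_acyclic(gn))
  am <- arcs(gm)
  expect_setequal(paste(am$from, am$to),
                  c("PHQ1 PHQ4", "PHQ2 PHQ1", "PHQ2 PHQ6", "PHQ2 PHQ9",
                    "PHQ3 PHQ7", "PHQ4 PHQ3", "PHQ4 PHQ5", "PHQ4 PHQ10",
                    "PHQ5 PHQ6", "PHQ5 PHQ7", "PHQ10 PHQ8"))
  # the central somatic hub radiates to sleep, appetite and function
  expect_setequal(arcs(gm)$to[arcs(gm)$from == "PHQ4"],
                  c("PHQ3", "PHQ5", "PHQ10"))
})

test_that("symptom sampling is seed-deterministic and respects the item scale", {
  g <- make_preset_dag("mets")
  s1 <- sample_symptoms(g, n = 500, seed = 9)
  s2 <- sample_symptoms(g, n = 500, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_symptoms(g, n = 500, seed = 10)))
  expect_true(all(as.matrix(s1) %in% 0:3))
  expect_equal(names(s1), paste0("PHQ", 1:10))
})

test_that("zero coefficients give independent columns; a single arc matches its coefficient", {
  g0 <- make_preset_dag("mets")
  cf0 <- default_arc_coefficients(g0); cf0$coef <- 0
  s <- sample_symptoms(g0, cf0, n = 10000, seed = 11, keep_latent = TRUE)
  lat <- attr(s, "latent")
  cors <- cor(lat)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)

  g1 <- dag_from_arcs(c("A", "B"), "A", "B")
  s1 <- sample_symptoms(g1, data.frame(from = "A", to = "B", coef = 0.9),
                        n = 5000, seed = 12, keep_latent = TRUE)
  lat1 <- attr(s1, "latent")
  expect_equal(cor(lat1[, "A"], lat1[, "B"]), 0.9, tolerance = 0.03 / 0.9)
  expect_equal(unname(apply(lat1, 2, var)), c(1, 1), tolerance = 0.06)
})

test_that("infeasible standardisation is refused", {
  g <- dag_from_arcs(c("A", "B", "C"), "A", "C", "B", "C")
  cf <- data.frame(from = c("A", "B"), to = "C", coef = c(0.9, 0.9))
  expect_error(sample_symptoms(g, cf, n = 10), "variance >= 1")
  expect_error(sample_symptoms(g, cf[1, , drop = FALSE], n = 10),
               "coefficients missing")
})

test_that("generated cohorts round-trip through the classifier exactly", {
  sp <- synthetic_spec(n_total = 300, prevalence = 0.2, seed = 5)
  co <- generate_cohort(sp)
  expect_equal(nrow(co), 300)
  expect_true(all(cohort_fields() %in% names(co)))
  cls <- classify_mets(co)
  expect_identical(cls$mets_status, co$group == "mets")
  g <- split_groups(co)
  expect_equal(nrow(g$mets), 60)
  # all records are inclusion-eligible MDD cases
  expect_equal(nrow(apply_inclusion(co)), 300)
  expect_true(all(co$icd_codes %in% c("F32.9", "F33.9")))
  # zero prevalence: everyone in the comparison group
  co0 <- generate_cohort(synthetic_spec(n_total = 50, prevalence = 0,
                                        seed = 6))
  expect_true(all(co0$group == "non_mets"))
})

test_that("generated metabolic contrasts preserve the preset waist direction and scale", {
  # enforcing the 3-of-5 class by rejection conditions the metabolic
  # marginals (MetS members are selected towards criterion-exceeding values),
  # so the generated contrast is somewhat larger than the unconditional
  # preset value of ~0.5; the group ordering and rough magnitude must hold
  sp <- synthetic_spec(seed = 13)  # published n and prevalence
  g <- split_groups(generate_cohort(sp))
  tbl <- summary_table(g$mets, g$non_mets,
                       data.frame(variable = "waist", kind = "continuous"))
  expect_gt(tbl$effect, 0.3)
  expect_lt(tbl$effect, 1.1)
  expect_equal(tbl$stars, "***")
  # HDL must run the other way (lower in the MetS group)
  hdl <- summary_table(g$mets, g$non_mets,
                       data.frame(variable = "hdl", kind = "continuous"))
  expect_lt(hdl$effect, -0.3)
})

test_that("spec files round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_total = 120, prevalence = 0.25, seed = 3,
                            arcs_mets = data.frame(from = "PHQ1",
                                                   to = "PHQ2", coef = 0.6)),
                       path, auto_unbox = TRUE, digits = NA)
  sp <- read_synthetic_spec(path)
  expect_equal(sp$n_total, 120)
  expect_equal(sp$prevalence, 0.25)
  expect_equal(narcs(sp$dag_mets), 1)
  expect_equal(sp$coefficients_mets$coef, 0.6)
  expect_equal(narcs(sp$dag_non_mets), 21)  # untouched default
})
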