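test_that("agreement tables count every surveyed person exactly once", {
  gp <- data.frame(patient_id = c("a", "b", "c"),
                   status = c("SMOKER", "SMOKER", "SMOKER"))
  survey <- data.frame(patient_id = c("a", "b", "c"),
                       status = c("SMOKER", "SMOKER", "SMOKER"))
  tab <- build_agreement_table(gp, survey)
  expect_equal(unclass(tab)["smoker", "smoker"], 3L)
  expect_equal(sum(tab), 3)

  # a surveyed person with no GP record lands in the GP-missing row
  survey2 <- rbind(survey, data.frame(patient_id = "d",
                                      status = "NEVER_SMOKER"))
  tab2 <- build_agreement_table(gp, survey2)
  expect_equal(unclass(tab2)["missing", "never_smoker"], 1L)
  expect_equal(sum(tab2), 4)

  expect_error(build_agreement_table(gp, rbind(survey, survey[1, ])),
               "duplicate")
})

test_that("survey items map to statuses and disagreements are caught", {
  expect_equal(survey_status_from_item(c(1, 2, 3, 4, 5, NA)),
               c("SMOKER", "SMOKER", "EX_SMOKER", "EX_SMOKER",
                 "NEVER_SMOKER", "MISSING"))
  expect_error(survey_status_from_item(6), "1..5")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,survey_date,item",
               "a,2013-05-01,2", "b,2013-05-02,5", "c,2013-05-03,"), path)
  sv <- read_survey(path)
  expect_equal(sv$status, c("SMOKER", "NEVER_SMOKER", "MISSING"))

  writeLines(c("patient_id,survey_date,item,status",
               "a,2013-05-01,2,never_smoker"), path)
  expect_error(read_survey(path), "disagree")
})

test_that("complete pairs and two-status amalgamation preserve structure", {
  tabs <- reference_tables()
  g3 <- complete_pairs(tabs$full)
  expect_equal(sum(g3), 6356)
  g2 <- collapse_two_status(g3)
  expect_equal(g2["smoker", "smoker"], 1040)
  expect_equal(sum(g2), sum(g3))
  expect_equal(g2["smoker", ], c(smoker = unname(g3[1, 1]),
                                 non_smoker = unname(sum(g3[1, 2:3]))))
  # smoker marginals survive the collapse on both axes
  expect_equal(sum(g2["smoker", ]), sum(g3[1, ]))
  expect_equal(sum(g2[, "smoker"]), sum(g3[, 1]))

  zeros <- as_agreement_table(matrix(0L, 4, 4))
  expect_equal(sum(complete_pairs(zeros)), 0)
  diag3 <- diag(c(3, 4, 5))
  expect_equal(collapse_two_status(diag3),
               matrix(c(3, 0, 0, 9), 2, 2, byrow = TRUE,
                      dimnames = dimnames(collapse_two_status(diag3))))
})

test_that("kappa matches the brute-force oracle and known fixed points", {
  set.seed(5)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    g <- matrix(rpois(k * k, sample(3:40, 1)), k, k)
    if (sum(diag(g)) == 0 || sum(g) == 0) next
    res <- cohen_kappa(g)
    expect_equal(res$kappa, oracle_kappa(g), tolerance = 1e-12)
    # symmetry and scale invariance
    expect_equal(cohen_kappa(t(g))$kappa, res$kappa, tolerance = 1e-12)
    expect_equal(cohen_kappa(g * 7)$kappa, res$kappa, tolerance = 1e-12)
    expect_true(res$ci_low <= res$kappa && res$kappa <= res$ci_high)
  }
  # perfect agreement and pure chance
  expect_equal(cohen_kappa(diag(c(10, 20, 30)))$kappa, 1)
  indep <- outer(c(2, 3, 5), c(4, 1, 5))  # rows proportional to col marginals
  expect_equal(cohen_kappa(indep)$kappa, 0, tolerance = 1e-12)

  expect_error(cohen_kappa(matrix(0, 3, 3)), "empty")
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)), "degenerate")
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(6)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    g <- matrix(rpois(k * k, 15), k, k)
    expect_equal(cohen_kappa(g)$kappa,
                 e1071::classAgreement(g)$kappa, tolerance = 1e-10)
  }
})

test_that("agreement bands follow the conventional cut points", {
  expect_equal(vapply(c(0.10, 0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80,
                        0.81, 1.00), altman_band, character(1)),
               c("poor", "poor", "fair", "fair", "moderate", "moderate",
                 "good", "good", "very good", "very good"))
})

test_that("discordance percentages use full survey-column denominators", {
  tabs <- reference_tables()
  d <- discordance_summary(tabs$full)
  get <- function(m) d[d$measure == m, ]
  expect_equal(get("survey_never_gp_ex")$numerator, 1104)
  expect_equal(get("survey_never_gp_ex")$denominator, 3282)
  expect_equal(round(get("survey_never_gp_ex")$percent), 34)
  expect_equal(round(get("survey_ex_gp_smoker")$percent), 20)
  expect_equal(round(get("gp_excess_smokers")$percent), 30)
  # the two published prose figures that disagree with their own tables:
  # the cells give 8.5% (full, survey-ex as never) and 4.4% (nearest,
  # survey-never as ex); the table-derived values are reported
  expect_equal(round(get("survey_ex_gp_never")$percent, 1), 8.5)
  dn <- discordance_summary(tabs$nearest)
  expect_equal(round(dn[dn$measure == "survey_never_gp_ex", "percent"], 1),
               4.4)

  all_missing <- discordance_summary(as_agreement_table(matrix(0L, 4, 4)))
  expect_true(all(is.na(all_missing$percent)))
})

test_that("tables round-trip through CSV, with optional small-count masking", {
  tab <- reference_tables("full")
  path <- withr::local_tempfile(fileext = ".csv")
  write_agreement_table(tab, path)
  back <- read_agreement_table(path)
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  expect_equal(cohen_kappa(complete_pairs(back))$kappa,
               cohen_kappa(complete_pairs(tab))$kappa)

  counts <- matrix(c(3L, 10L, 10L, 10L,
                     10L, 50L, 4L, 10L,
                     10L, 10L, 50L, 10L,
                     10L, 10L, 10L, 50L), 4, 4, byrow = TRUE)
  write_agreement_table(as_agreement_table(counts), path,
                        suppress_small = TRUE)
  txt <- readLines(path)
  expect_true(any(grepl("<5", txt)))
  masked <- read_agreement_table(path)
  expect_equal(sum(attr(masked, "suppressed")), 2)
})

test_that("packaged reference tables have the published marginals", {
  tabs <- reference_tables()
  expect_equal(sum(tabs$full), 6836)
  expect_equal(sum(tabs$no_temporal), 6836)
  expect_equal(sum(tabs$nearest), 6836)
  for (tab in tabs) {
    expect_equal(unname(colSums(unclass(tab))), c(72, 1301, 2181, 3282))
    expect_true(attr(tab, "suppressed")[1, 1])
  }
  expect_equal(unname(rowSums(unclass(tabs$full))),
               c(413, 1692, 2717, 2014))
  expect_equal(unname(rowSums(unclass(tabs$no_temporal))),
               c(423, 1721, 1368, 3324))
  # the nearest table's missing row is stored cell-consistently (432, not
  # the published 423 whose total contradicts its own column marginals)
  expect_equal(unname(rowSums(unclass(tabs$nearest))),
               c(432, 1209, 1624, 3571))
})
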