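test_that("tooth classification follows the coding convention", {
  expect_identical(classify_tooth(11, "2", "0")$component, "decayed")
  expect_identical(classify_tooth(11, "1", "0")$component, "decayed")
  expect_identical(classify_tooth(11, "3", "0")$component, "filled")
  expect_identical(classify_tooth(11, "4", "0")$component, "missing")
  expect_identical(classify_tooth(11, "0", "0")$component, "none")
  # non-caries states contribute to no component
  for (code in c("5", "6", "7", "8", "T", "9")) {
    expect_identical(classify_tooth(11, code, "0")$component, "none")
  }
  cls <- classify_tooth(11, "1", "6")
  expect_identical(cls$component, "decayed")
  expect_true(cls$extraction_indicated)
  # deciduous column maps symbol-for-symbol
  expect_identical(classify_tooth(51, "B", "0")$component, "decayed")
  expect_identical(classify_tooth(51, "D", "0")$component, "filled")
  expect_identical(classify_tooth(51, "E", "0")$component, "missing")
  expect_identical(classify_tooth(51, "F", "0")$component, "none")
})

test_that("component counts match worked examples", {
  expect_equal(unclass(count_components(normalize_odontogram(NULL)))[1:4],
               list(x = 0L, y = 0L, z = 0L, w = 0L),
               ignore_attr = TRUE)
  odo <- normalize_odontogram(data.frame(
    tooth = c(11, 12, 21, 36), crown = c("1", "2", "3", "4"),
    treatment = "0"))
  cc <- count_components(odo)
  expect_identical(c(cc$x, cc$y, cc$z, cc$w), c(2L, 1L, 1L, 0L))
  expect_identical(cpo_individual(cc), 4L)

  odo2 <- normalize_odontogram(data.frame(tooth = 46, crown = "1",
                                          treatment = "6"))
  cc2 <- count_components(odo2)
  expect_identical(c(cc2$x, cc2$y, cc2$z, cc2$w), c(1L, 0L, 0L, 1L))
})

test_that("CPO and ceo reject the wrong dentition and ceo excludes z", {
  perm <- count_components(normalize_odontogram(NULL), "permanent")
  expect_error(ceo_individual(perm), "deciduous")
  dec_odo <- normalize_odontogram(
    data.frame(tooth = c(51, 52, 53), crown = c("B", "D", "E"),
               treatment = "0"),
    teeth = fdi_teeth("deciduous"))
  dec <- count_components(dec_odo, "deciduous")
  expect_error(cpo_individual(dec), "permanent")
  expect_identical(ceo_individual(dec), 2L)  # E (missing) not counted
})

test_that("mean, literal percentage and prevalence behave as defined", {
  expect_identical(mean_index(c(0, 2, 4)), 2)
  expect_identical(mean_index(5), 5)
  expect_error(mean_index(numeric()), "no examined persons")
  expect_identical(index_percent(2, 100), 2)
  expect_identical(index_percent(0, 50), 0)
  expect_identical(index_percent(4, 4), 100)
  expect_error(index_percent(2, 0), "positive")
  expect_identical(prevalence(c(0, 0, 0)), 0)
  expect_identical(prevalence(c(0, 1, 3, 0)), 0.5)
  expect_identical(prevalence(c(1, 2)), 1)
  expect_error(prevalence(numeric()), "no examined persons")
})

test_that("adding one decayed tooth raises CPO by exactly one", {
  set.seed(202)
  for (i in 1:20) {
    odo <- random_odontogram()
    healthy_pos <- which(odo$crown == "0" & odo$treatment != "6")
    if (length(healthy_pos) == 0L) next
    pos <- healthy_pos[sample.int(length(healthy_pos), 1L)]
    before <- cpo_individual(count_components(odo))
    odo$crown[pos] <- "1"
    after <- cpo_individual(count_components(odo))
    expect_identical(after, before + 1L)
  }
})

test_that("index values stay within the dentition bounds", {
  set.seed(303)
  teeth_all <- c(fdi_teeth("permanent"), fdi_teeth("deciduous"))
  for (i in 1:50) {
    odo <- random_odontogram(teeth_all)
    cpo <- cpo_individual(count_components(odo, "permanent"))
    ceo <- ceo_individual(count_components(odo, "deciduous"))
    expect_gte(cpo, 0L); expect_lte(cpo, 2L * 32L)  # x/y/z + w can overlap
    expect_gte(ceo, 0L); expect_lte(ceo, 2L * 20L)
    # crown components alone never exceed the tooth count
    cc <- count_components(odo, "permanent")
    expect_lte(cc$x + cc$y + cc$z, 32L)
  }
})

test_that("component counting agrees with the brute-force oracle", {
  set.seed(404)
  for (i in 1:200) {
    odo <- random_odontogram()
    cc <- count_components(odo)
    orc <- oracle_count(odo, "permanent")
    expect_identical(c(cc$x, cc$y, cc$z, cc$w),
                     as.integer(c(orc$x, orc$y, orc$z, orc$w)))
    expect_identical(cpo_individual(cc), as.integer(oracle_cpo(odo)))
  }
})

test_that("per-exam indices and aggregation partition the exams", {
  sim <- tiny_survey(seed = 99, n_schools = 2L, students = 15L)
  per <- exam_index(sim$exams)
  expect_identical(nrow(per), 30L)
  by_school <- aggregate_index(sim$exams, sim$students, sim$schools, "school")
  expect_identical(sum(by_school$N), nrow(per))
  overall <- aggregate_index(sim$exams, sim$students, sim$schools,
                             "municipality")
  expect_identical(overall$N, nrow(per))
  expect_equal(overall$mean, mean_index(per$index))
  # weighted decomposition across every grouping key
  for (key in c("school", "territory", "sex", "age")) {
    g <- aggregate_index(sim$exams, sim$students, sim$schools, key)
    expect_equal(sum(g$N * g$mean) / sum(g$N), overall$mean,
                 tolerance = 1e-12)
  }
})

test_that("aggregation names orphan references", {
  sim <- tiny_survey(seed = 5, n_schools = 1L, students = 3L)
  exams <- sim$exams
  exams$secret_code[1:32] <- "GHOST"
  exams$exam_id[1:32] <- "GHOST#1"
  expect_error(aggregate_index(exams, sim$students, sim$schools, "school"),
               "GHOST")
})
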