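unit_square <- function() matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2,
                                 byrow = TRUE)

test_that("explicit school-territory mapping takes precedence", {
  reg <- load_school_register()
  tmap <- territory_map(mapping = data.frame(school_id = reg$id,
                                             territory = reg$territory))
  jobim <- reg[reg$name == "Escola Municipal Antonio Carlos Jobim", ]
  expect_identical(assign_territory(jobim, tmap), "Krahô")
  expect_identical(
    assign_territory(reg[reg$name == "Escola Municipal Darcy Ribeiro", ],
                     tmap),
    "Xambioá")
})

test_that("point-in-polygon assignment covers interior, boundary, outside", {
  tmap <- territory_map(polygons = list(
    A = unit_square(),
    B = unit_square() + matrix(rep(c(1, 0), each = 4), ncol = 2)))
  mk <- function(lon, lat) list(id = "X", longitude = lon, latitude = lat)
  expect_identical(assign_territory(mk(0.5, 0.5), tmap), "A")
  expect_identical(assign_territory(mk(1.5, 0.5), tmap), "B")
  # the shared edge x = 1 belongs to the first-listed territory
  expect_identical(assign_territory(mk(1, 0.5), tmap), "A")
  # a polygon vertex is still a boundary point
  expect_identical(assign_territory(mk(0, 0), tmap), "A")
  expect_error(assign_territory(mk(5, 5), tmap), "no territory")
})

test_that("GeoJSON territory polygons load and assign", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(territory = "Khraô"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(0, 0), list(1, 0), list(1, 1), list(0, 1),
                list(0, 0)))))))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  tmap <- read_territory_geojson(f)
  # alias spelling canonicalizes to the register form
  expect_identical(names(tmap$polygons), "Krahô")
  expect_identical(
    assign_territory(list(id = "s", longitude = 0.3, latitude = 0.3), tmap),
    "Krahô")
})

test_that("territory report emits three consistent levels", {
  sim <- tiny_survey(seed = 13, n_schools = 4L, students = 12L)
  rep <- territory_index_report(sim$exams, sim$students, sim$schools)
  expect_named(rep, c("school", "territory", "municipal"))
  expect_identical(sum(rep$school$N), rep$municipal$N)
  expect_identical(sum(rep$territory$N), rep$municipal$N)
  # municipal mean is the exam-count-weighted mean of territory means
  expect_equal(sum(rep$territory$N * rep$territory$mean) /
                 sum(rep$territory$N),
               rep$municipal$mean, tolerance = 1e-12)
})

test_that("territory prevalence differences show up in the means", {
  base <- simulation_config(n_schools = 2L, students_per_school = 250L,
                            territories = c("A", "B"),
                            territory_probs = c(0.5, 0.5), seed = 77,
                            p_decayed = 0.05, p_filled = 0.02,
                            p_missing = 0.01)
  sim <- simulate_survey(base)
  # zero out pathology for every student of school 2 -> territory contrast
  sim$schools$territory <- c("A", "B")
  b_codes <- sim$students$secret_code[sim$students$school_id == "SIM02"]
  sel <- sim$exams$secret_code %in% b_codes
  sim$exams$crown[sel] <- "0"
  sim$exams$treatment[sel] <- "0"
  terr <- aggregate_index(sim$exams, sim$students, sim$schools, "territory")
  expect_gt(terr$mean[terr$group == "A"], terr$mean[terr$group == "B"])
  expect_identical(terr$mean[terr$group == "B"], 0)
})

test_that("participation percentages handle zero enrollment and overflows", {
  sch <- schools(c("a", "b", "c"), c("A", "B", "C"),
                 enrollment_grade9 = c(100, 70, 0))
  rep <- participation_report(
    sch,
    questionnaires = c(a = 90L, b = 70L, c = 0L),
    exams = c(a = 80L, b = 60L, c = 0L))
  expect_equal(rep$pct_exam[1], 80)
  expect_equal(rep$pct_questionnaire[2], 100)
  expect_true(rep$flagged[3])
  expect_true(is.na(rep$pct_exam[3]))
  expect_warning(
    participation_report(sch, questionnaires = c(a = 120L),
                         exams = c(a = 80L)),
    "exceed")
})

test_that("desk summary counts store contents and tracks merges", {
  st <- new_store()
  empty <- desk_summary(st)
  expect_identical(unlist(unclass(empty)), c(campaigns = 0L,
                                             schools_visited = 0L,
                                             students_registered = 0L,
                                             questionnaires_answered = 0L,
                                             exams_performed = 0L))
  sim <- tiny_survey(seed = 21, n_schools = 2L, students = 5L)
  batches <- survey_to_batches(sim)
  ins_exams <- 0L
  for (b in batches) {
    before <- desk_summary(st)$exams_performed
    rep <- merge_batch(st, b)
    n_exam_records <- sum(vapply(b$records, function(r)
      r$record_type == "exam", logical(1)))
    expect_identical(desk_summary(st)$exams_performed,
                     before + n_exam_records)
  }
  ds <- desk_summary(st)
  expect_identical(ds$schools_visited, 2L)
  expect_identical(ds$students_registered, 10L)
  # report generation is read-only
  n_before <- length(st$records)
  invisible(desk_summary(st))
  invisible(territory_index_report(sim$exams, sim$students, sim$schools))
  expect_identical(length(st$records), n_before)
})

test_that("the territory plot writes a file", {
  sim <- tiny_survey(seed = 3, n_schools = 2L, students = 5L)
  rep <- territory_index_report(sim$exams, sim$students, sim$schools)
  f <- file.path(tempdir(), "territories.png")
  plot_territory_index(rep, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
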