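test_that("FDI tooth codes classify by quadrant and reject unknowns", {
  expect_identical(dentition_of(14), "permanent")
  expect_identical(dentition_of(55), "deciduous")
  expect_identical(dentition_of(c(11, 48, 51, 85)),
                   c("permanent", "permanent", "deciduous", "deciduous"))
  expect_error(dentition_of(49), "49")
  expect_error(dentition_of(0), "invalid")
  expect_length(fdi_teeth("permanent"), 32L)
  expect_length(fdi_teeth("deciduous"), 20L)
})

test_that("crown alphabets are closed per dentition", {
  for (code in crown_alphabet("permanent")) {
    expect_identical(check_crown(11, code), code)
  }
  for (code in crown_alphabet("deciduous")) {
    expect_identical(check_crown(51, code), code)
  }
  # cross-dentition symbols are rejected, except the shared trauma code
  for (code in setdiff(crown_alphabet("deciduous"), "T")) {
    expect_error(check_crown(11, code), "not valid for permanent tooth 11")
  }
  expect_length(treatment_alphabet(), 10L)
  expect_error(check_treatment("X"), "invalid treatment")
})

test_that("letter codes parse case-insensitively to upper case", {
  odo <- normalize_odontogram(
    data.frame(tooth = 51, crown = "b", treatment = "0"),
    teeth = fdi_teeth("deciduous"))
  expect_identical(odo$crown[odo$tooth == 51], "B")
})

test_that("normalization fills unset teeth with the healthy default", {
  odo <- normalize_odontogram(NULL)
  expect_s3_class(odo, "odontogram")
  expect_identical(nrow(odo), 32L)
  expect_true(all(odo$crown == "0"))
  expect_true(all(odo$treatment == "0"))

  odo2 <- normalize_odontogram(
    data.frame(tooth = 14, crown = "7", treatment = "3"))
  expect_identical(nrow(odo2), 32L)
  expect_identical(odo2$crown[odo2$tooth == 14], "7")
  expect_identical(odo2$treatment[odo2$tooth == 14], "3")
  expect_identical(sum(odo2$crown == "0"), 31L)

  mixed <- c(11, 21, 51, 61)
  odo3 <- normalize_odontogram(NULL, teeth = mixed)
  expect_identical(odo3$crown, c("0", "0", "A", "A"))
})

test_that("normalization rejects wrong-dentition codes and is idempotent", {
  expect_error(
    normalize_odontogram(data.frame(tooth = 11, crown = "B", treatment = "0")),
    "'B' is not valid for permanent tooth 11")
  set.seed(11)
  odo <- random_odontogram()
  renorm <- normalize_odontogram(as.data.frame(odo))
  expect_identical(as.data.frame(renorm), as.data.frame(odo))
  # always exactly |dentition set| records
  for (teeth in list(fdi_teeth("permanent"), fdi_teeth("deciduous"),
                     c(fdi_teeth("permanent"), fdi_teeth("deciduous")))) {
    expect_identical(nrow(normalize_odontogram(NULL, teeth = teeth)),
                     length(teeth))
  }
})

test_that("exam validation reports structure instead of aborting", {
  healthy <- exam("ABC123", "2018-09-01", normalize_odontogram(NULL))
  rep <- validate_exam(healthy)
  expect_identical(nrow(rep), 0L)
  expect_false(has_errors(rep))

  noinfo <- normalize_odontogram(
    data.frame(tooth = 11, crown = "1", treatment = "9"))
  rep2 <- validate_exam(exam("ABC123", "2018-09-01", noinfo))
  expect_identical(sum(rep2$severity == "warning"), 1L)
  expect_identical(sum(rep2$severity == "error"), 0L)

  holed <- as.data.frame(normalize_odontogram(NULL))
  holed$crown[3] <- NA
  class(holed) <- c("odontogram", "data.frame")
  rep3 <- validate_exam(holed)
  expect_true(has_errors(rep3))
  expect_match(rep3$message[rep3$severity == "error"][1], "null")

  dated <- validate_exam(
    exam("ABC123", "2019-03-01", normalize_odontogram(NULL)),
    action_dates = c("2018-08-01", "2018-12-01"))
  expect_identical(dated$severity, "warning")
})

test_that("age is completed years at the reference date", {
  expect_identical(age_at("2003-05-01", "2018-05-01"), 15L)
  expect_identical(age_at("2003-05-02", "2018-05-01"), 14L)
  expect_error(age_at("2018-05-01", "2003-05-01"), "after")
  # leap-day births age on 1 March in non-leap years
  expect_identical(age_at("2004-02-29", "2018-02-28"), 13L)
  expect_identical(age_at("2004-02-29", "2018-03-01"), 14L)
})

test_that("questionnaire definitions enforce contiguous ranges from 1", {
  def <- questionnaire_def(c("a", "b"), c(1, 6), c(5, 9))
  expect_identical(n_questions(def), 9L)
  expect_error(questionnaire_def("a", 2, 5), "start at question 1")
  expect_error(questionnaire_def(c("a", "b"), c(1, 7), c(5, 9)), "contiguous")
  expect_error(questionnaire_def(c("a", "b"), c(1, 5), c(5, 9)), "contiguous")
})

test_that("responses validate against the definition", {
  def <- load_student_questionnaire()
  full <- questionnaire_response(
    "ABC123", "2018-09-01",
    stats::setNames(as.list(rep("1", n_questions(def))),
                    seq_len(n_questions(def))))
  expect_false(has_errors(validate_response(full, def)))

  over <- questionnaire_response("ABC123", "2018-09-01", list(`147` = "1"))
  rep <- validate_response(over, def)
  expect_identical(sum(rep$severity == "error"), 1L)

  empty <- questionnaire_response("ABC123", "2018-09-01")
  expect_identical(nrow(validate_response(empty, def)), 0L)
  withm <- validate_response(empty, def, mandatory = 1:3)
  expect_identical(sum(withm$severity == "warning"), 3L)
})

test_that("entity constructors enforce their invariants", {
  expect_error(schools(c("a", "a"), c("x", "y")), "duplicated")
  expect_error(schools("a", "x", latitude = 95), "latitude")
  expect_error(schools("a", "x", enrollment_total = -1), "negative")
  expect_error(students(c("c1", "c1"), c("2003-01-01", "2003-01-02")),
               "duplicated")
  stu <- students("c1", "2003-01-01", sex = "F", school_id = "a")
  expect_false("name" %in% names(stu))
})
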