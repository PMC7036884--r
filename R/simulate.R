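#' Seedable synthetic survey generator
#'
#' Generates complete synthetic surveys — schools, students, odontogram
#' exams and questionnaire responses — with known ground-truth parameters,
#' so the whole pipeline (capture, merge, index, report) can be exercised
#' offline and recovered estimates compared against closed-form
#' expectations. Per-tooth states are independent draws from a multinomial
#' (healthy, decayed, filled, missing), which makes the expected per-person
#' index exactly `n_teeth * (p_decayed + p_filled + p_missing)` when no
#' extraction-indicated marks are simulated; real caries clusters within
#' mouths, so the generator is a test harness, not an epidemiological
#' model.
#'
#' @name synthetic
NULL

#' Configuration of a synthetic survey
#'
#' Defaults emulate a municipal school survey of adolescents: 26 schools
#' across eight health territories (the bundled register's territory
#' frequencies), school sizes spanning the register's 9th-grade range,
#' ages uniform on 13-19, and low per-tooth pathology rates typical of
#' adolescent permanent dentition.
#'
#' @param n_schools Number of schools.
#' @param students_per_school Fixed count or length-2 inclusive range.
#' @param territories Territory label set.
#' @param territory_probs School-to-territory assignment probabilities.
#' @param p_decayed,p_filled,p_missing Per-tooth state probabilities; the
#'   remainder is healthy. Must sum to at most 1.
#' @param p_extraction_indicated Probability a decayed tooth is marked for
#'   extraction (treatment code `"6"`).
#' @param p_answer Probability each questionnaire item is answered.
#' @param questionnaire A [questionnaire_def()]; default the bundled
#'   student questionnaire.
#' @param examiner_error_rate Rating perturbation rate for calibration
#'   replicas (see [simulate_examiner_ratings()]).
#' @param age_range Inclusive completed-years range at exam time.
#' @param seed Integer seed fixing the full output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_schools = 26L,
                              students_per_school = c(14L, 176L),
                              territories = default_territories(),
                              territory_probs = c(5, 3, 4, 2, 2, 3, 3, 4) / 26,
                              p_decayed = 0.05, p_filled = 0.02,
                              p_missing = 0.01,
                              p_extraction_indicated = 0.1,
                              p_answer = 0.9,
                              questionnaire = NULL,
                              examiner_error_rate = 0.05,
                              age_range = c(13L, 19L),
                              seed = 1L) {
  p <- c(p_decayed, p_filled, p_missing, p_extraction_indicated, p_answer,
         examiner_error_rate)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_decayed + p_filled + p_missing > 1) {
    stop("per-tooth state probabilities exceed 1", call. = FALSE)
  }
  if (length(territory_probs) != length(territories) ||
      abs(sum(territory_probs) - 1) > 1e-9) {
    stop("territory_probs must match territories and sum to 1", call. = FALSE)
  }
  structure(list(n_schools = as.integer(n_schools),
                 students_per_school = as.integer(students_per_school),
                 territories = territories,
                 territory_probs = territory_probs,
                 p_decayed = p_decayed, p_filled = p_filled,
                 p_missing = p_missing,
                 p_extraction_indicated = p_extraction_indicated,
                 p_answer = p_answer, questionnaire = questionnaire,
                 examiner_error_rate = examiner_error_rate,
                 age_range = as.integer(age_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic survey
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_survey`: tables `schools`,
#'   `students`, `exams` (long), `responses` (wide), plus `config`. Every
#'   generated exam passes [validate_exam()]; identical seeds give
#'   identical output.
#' @examples
#' sim <- simulate_survey(simulation_config(n_schools = 2,
#'                                          students_per_school = 5,
#'                                          seed = 7))
#' nrow(sim$students) # 10
#' @export
simulate_survey <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  ns <- config$n_schools
  sch <- schools(
    id = sprintf("SIM%02d", seq_len(ns)),
    name = sprintf("Synthetic school %02d", seq_len(ns)),
    latitude = stats::runif(ns, -10.4, -10.1),
    longitude = stats::runif(ns, -48.45, -48.25),
    territory = sample(config$territories, ns, replace = TRUE,
                       prob = config$territory_probs),
    enrollment_total = NA_integer_, enrollment_grade9 = NA_integer_)

  rng <- config$students_per_school
  n_per <- if (length(rng) == 2L) sample(rng[1L]:rng[2L], ns, replace = TRUE)
           else rep(rng[1L], ns)
  sch$enrollment_grade9 <- n_per
  sch$enrollment_total <- as.integer(round(n_per * stats::runif(ns, 4, 9)))

  n_students <- sum(n_per)
  gen <- secret_code_generator(seed = config$seed + 1L)
  codes <- vapply(seq_len(n_students), function(i) issue_secret_code(gen),
                  character(1L))
  exam_date <- as.Date("2018-08-01") + sample(0:120, n_students, replace = TRUE)
  age_days <- sample(config$age_range[1L]:config$age_range[2L], n_students,
                     replace = TRUE) * 365L + sample(0:364, n_students,
                                                     replace = TRUE)
  stu <- students(secret_code = codes,
                  birth_date = exam_date - age_days,
                  sex = sample(c("M", "F"), n_students, replace = TRUE),
                  race = sample(c("1", "2", "3", "4", "5"), n_students,
                                replace = TRUE),
                  school_id = rep(sch$id, n_per),
                  class_label = "9th grade")

  teeth <- fdi_teeth("permanent")
  nt <- length(teeth)
  states <- sample(c("healthy", "decayed", "filled", "missing"),
                   n_students * nt, replace = TRUE,
                   prob = c(1 - config$p_decayed - config$p_filled -
                              config$p_missing,
                            config$p_decayed, config$p_filled,
                            config$p_missing))
  crown <- c(healthy = "0", decayed = "1", filled = "3", missing = "4")[states]
  treatment <- rep("0", length(states))
  dec <- states == "decayed"
  treatment[dec] <- ifelse(
    stats::runif(sum(dec)) < config$p_extraction_indicated, "6", "0")
  exams <- data.frame(
    exam_id = rep(sprintf("EX%05d", seq_len(n_students)), each = nt),
    secret_code = rep(codes, each = nt),
    date = rep(exam_date, each = nt),
    examiner_id = rep(sprintf("E%02d", sample(1:16, n_students,
                                              replace = TRUE)), each = nt),
    tooth = rep(teeth, times = n_students),
    crown = unname(crown), treatment = treatment,
    stringsAsFactors = FALSE)

  qdef <- config$questionnaire
  if (is.null(qdef)) qdef <- load_student_questionnaire()
  nq <- n_questions(qdef)
  answered <- matrix(stats::runif(n_students * nq) < config$p_answer,
                     nrow = n_students)
  ans <- matrix(as.character(sample(1:5, n_students * nq, replace = TRUE)),
                nrow = n_students)
  ans[!answered] <- NA_character_
  responses <- data.frame(secret_code = codes, date = exam_date,
                          stringsAsFactors = FALSE)
  for (q in seq_len(nq)) responses[[paste0("q", q)]] <- ans[, q]

  structure(list(schools = sch, students = stu, exams = exams,
                 responses = responses, config = config),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("<synthetic survey> %d school(s), %d student(s), seed %d\n",
              nrow(x$schools), nrow(x$students), x$config$seed))
  invisible(x)
}

#' Pack a synthetic survey into sealed field batches
#'
#' One batch per school, as a field device would produce: the school
#' record, its students, their exams and questionnaire responses, all
#' with deterministic ids and timestamps under the simulation seed.
#'
#' @param sim A [simulate_survey()] result.
#' @param device_label Device label stamped on the batches.
#' @return List of sealed `local_batch` objects, one per school.
#' @export
survey_to_batches <- function(sim, device_label = "sim-device") {
  stopifnot(inherits(sim, "synthetic_survey"))
  lapply(seq_len(nrow(sim$schools)), function(i) {
    sc <- sim$schools[i, ]
    b <- open_batch(device_label,
                    batch_id = sprintf("simbatch-%d-%s", sim$config$seed,
                                       sc$id),
                    created_at = as.POSIXct("2018-12-01 12:00:00", tz = "UTC"))
    ts <- "2018-12-01T12:00:00"
    b <- append_record(b, new_record(
      "school", as.list(sc), record_uid = paste0("school-", sc$id),
      created_at = ts))
    stu <- sim$students[sim$students$school_id == sc$id, , drop = FALSE]
    for (j in seq_len(nrow(stu))) {
      s <- stu[j, ]
      b <- append_record(b, new_record(
        "student",
        list(secret_code = s$secret_code,
             birth_date = format(s$birth_date), sex = s$sex, race = s$race,
             school_id = s$school_id, class_label = s$class_label),
        record_uid = paste0("student-", s$secret_code), created_at = ts))
      ex <- sim$exams[sim$exams$secret_code == s$secret_code, , drop = FALSE]
      if (nrow(ex) > 0L) {
        b <- append_record(b, new_record(
          "exam",
          list(secret_code = s$secret_code, date = format(ex$date[1L]),
               examiner_id = ex$examiner_id[1L],
               odontogram = list(tooth = as.integer(ex$tooth),
                                 crown = ex$crown,
                                 treatment = ex$treatment)),
          record_uid = paste0("exam-", ex$exam_id[1L]), created_at = ts))
      }
      resp <- sim$responses[sim$responses$secret_code == s$secret_code, ,
                            drop = FALSE]
      if (nrow(resp) > 0L) {
        acols <- grep("^q[0-9]+$", names(resp), value = TRUE)
        vals <- unlist(resp[1L, acols], use.names = FALSE)
        keep <- !is.na(vals)
        answers <- stats::setNames(as.list(vals[keep]),
                                   sub("^q", "", acols[keep]))
        b <- append_record(b, new_record(
          "response",
          list(secret_code = s$secret_code, date = format(resp$date[1L]),
               answers = answers),
          record_uid = paste0("response-", s$secret_code), created_at = ts))
      }
    }
    seal_batch(b)
  })
}

#' Perturb ratings to emulate an imperfect examiner
#'
#' Each rating is independently replaced, with probability `error_rate`,
#' by a category drawn uniformly from the other categories. Drives the
#' calibration tests: kappa against the true ratings decreases
#' monotonically in `error_rate`.
#'
#' @param true_ratings Character vector of reference ratings.
#' @param error_rate Probability of perturbing each rating, in `[0, 1]`.
#' @param categories Category set; default the distinct true ratings.
#' @param seed Optional seed for a self-contained draw.
#' @return Character vector of perturbed ratings.
#' @export
simulate_examiner_ratings <- function(true_ratings, error_rate,
                                      categories = NULL, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(categories)) categories <- sort(unique(true_ratings))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  out <- true_ratings
  flip <- stats::runif(length(out)) < error_rate
  if (any(flip) && length(categories) > 1L) {
    out[flip] <- vapply(out[flip], function(tr)
      sample(setdiff(categories, tr), 1L), character(1L))
  }
  out
}
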