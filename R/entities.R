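#' Survey entity tables
#'
#' Campaigns group field actions; each action visits a set of schools;
#' students are registered per school under an opaque anonymized code (no
#' name or direct identifier is ever stored). Entities are plain
#' data.frames so they merge and export naturally; the constructors below
#' validate the invariants once at the boundary.
#'
#' @name entities
NULL

#' Construct/validate a school table
#'
#' @param id,name,latitude,longitude,territory Vectors, recycled per row.
#' @param enrollment_total,enrollment_grade9 Non-negative counts.
#' @return data.frame with one row per school.
#' @export
schools <- function(id, name, latitude = NA_real_, longitude = NA_real_,
                    territory = NA_character_,
                    enrollment_total = NA_integer_,
                    enrollment_grade9 = NA_integer_) {
  n <- length(id)
  rec <- function(x) rep(x, length.out = n)
  out <- data.frame(id = as.character(id), name = rec(as.character(name)),
                    latitude = rec(as.numeric(latitude)),
                    longitude = rec(as.numeric(longitude)),
                    territory = rec(as.character(territory)),
                    enrollment_total = rec(as.integer(enrollment_total)),
                    enrollment_grade9 = rec(as.integer(enrollment_grade9)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicated school ids", call. = FALSE)
  lat <- out$latitude[!is.na(out$latitude)]
  lon <- out$longitude[!is.na(out$longitude)]
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  cnt <- c(out$enrollment_total, out$enrollment_grade9)
  if (any(cnt < 0, na.rm = TRUE)) stop("negative enrollment counts", call. = FALSE)
  out
}

#' Construct/validate a student table
#'
#' Students carry only an opaque `secret_code` (unique within a campaign),
#' demographic codes and a school reference — never a name.
#'
#' @param secret_code Opaque anonymized tokens, unique.
#' @param birth_date Dates or ISO-8601 strings.
#' @param sex,race Coded categories.
#' @param school_id School references.
#' @param class_label Free-text class/grade label.
#' @return data.frame with one row per student.
#' @export
students <- function(secret_code, birth_date, sex = NA_character_,
                     race = NA_character_, school_id = NA_character_,
                     class_label = NA_character_) {
  n <- length(secret_code)
  rec <- function(x) rep(x, length.out = n)
  out <- data.frame(secret_code = as.character(secret_code),
                    birth_date = rec(as.Date(birth_date)),
                    sex = rec(as.character(sex)), race = rec(as.character(race)),
                    school_id = rec(as.character(school_id)),
                    class_label = rec(as.character(class_label)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$secret_code)) {
    stop("duplicated student secret codes", call. = FALSE)
  }
  out
}

#' Construct a campaign with its actions
#'
#' A campaign is a broad survey effort (e.g. an annual state-level caries
#' survey); actions are the occasional school visits it comprises. Every
#' action belongs to exactly one campaign and every surveyed school to at
#' least one action.
#'
#' @param id,name Campaign identifier and label.
#' @param period Length-2 date vector covering the campaign.
#' @param actions List of [action()] results.
#' @return A list of class `campaign`.
#' @export
campaign <- function(id, name, period, actions = list()) {
  period <- as.Date(period)
  stopifnot(length(period) == 2L)
  structure(list(id = as.character(id), name = as.character(name),
                 period = period, actions = actions),
            class = "campaign")
}

#' @rdname campaign
#' @param dates Length-2 date vector of the action's field window.
#' @param school_ids Schools visited by the action.
#' @export
action <- function(id, name, dates, school_ids) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == 2L)
  structure(list(id = as.character(id), name = as.character(name),
                 dates = dates, school_ids = as.character(school_ids)),
            class = "action")
}

#' Define a questionnaire as ordered classes of question ranges
#'
#' A questionnaire is partitioned into ordered thematic classes, each
#' covering an inclusive, contiguous range of question numbers starting at
#' 1 with no gaps or overlaps.
#'
#' @param class_label Class names in order.
#' @param first,last Inclusive question-number range per class.
#' @return data.frame of class `questionnaire_def`.
#' @export
questionnaire_def <- function(class_label, first, last) {
  def <- data.frame(class_label = as.character(class_label),
                    first = as.integer(first), last = as.integer(last),
                    stringsAsFactors = FALSE)
  if (nrow(def) == 0L) stop("empty questionnaire definition", call. = FALSE)
  if (def$first[1L] != 1L) stop("class ranges must start at question 1", call. = FALSE)
  if (any(def$last < def$first)) stop("class range with last < first", call. = FALSE)
  if (nrow(def) > 1L && any(def$first[-1L] != def$last[-nrow(def)] + 1L)) {
    stop("class ranges must be contiguous and non-overlapping", call. = FALSE)
  }
  class(def) <- c("questionnaire_def", "data.frame")
  def
}

#' Number of items in a questionnaire definition
#' @param def A [questionnaire_def()].
#' @return Integer total question count.
#' @export
n_questions <- function(def) as.integer(max(def$last))

#' Construct a questionnaire response
#'
#' @param secret_code Student token.
#' @param date Response date.
#' @param answers Named list/vector: names are question numbers, values
#'   coded answers.
#' @return A list of class `questionnaire_response`.
#' @export
questionnaire_response <- function(secret_code, date, answers = list()) {
  structure(list(secret_code = as.character(secret_code),
                 date = as.Date(date), answers = as.list(answers)),
            class = "questionnaire_response")
}

#' Validate a response against a questionnaire definition
#'
#' Flags answers to undefined question numbers as errors and missing
#' mandatory items as warnings. No item is mandatory by default, matching
#' self-administered field practice where blanks are legitimate.
#'
#' @param resp A [questionnaire_response()].
#' @param def A [questionnaire_def()].
#' @param mandatory Integer vector of question numbers that must be
#'   answered (default none).
#' @return A `validation_report` data.frame.
#' @export
validate_response <- function(resp, def, mandatory = integer()) {
  qs <- suppressWarnings(as.integer(names(resp$answers)))
  probs <- list()
  if (anyNA(qs)) {
    probs[[length(probs) + 1L]] <- data.frame(
      severity = "error", locus = "answers",
      message = "non-numeric question keys", stringsAsFactors = FALSE)
    qs <- qs[!is.na(qs)]
  }
  out_of_range <- qs[qs < 1L | qs > n_questions(def)]
  for (q in out_of_range) {
    probs[[length(probs) + 1L]] <- data.frame(
      severity = "error", locus = as.character(q),
      message = "answer to undefined question number", stringsAsFactors = FALSE)
  }
  missing <- setdiff(as.integer(mandatory), qs)
  for (q in missing) {
    probs[[length(probs) + 1L]] <- data.frame(
      severity = "warning", locus = as.character(q),
      message = "mandatory question unanswered", stringsAsFactors = FALSE)
  }
  rep <- if (length(probs) > 0L) do.call(rbind, probs) else
    data.frame(severity = character(), locus = character(),
               message = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}
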