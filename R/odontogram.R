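#' Build a complete odontogram from partial field records
#'
#' Field capture records only the teeth with findings; the remaining teeth
#' of the examined dentition set are auto-filled with the healthy default
#' (crown `"0"` for permanent, `"A"` for deciduous, treatment `"0"`), so a
#' stored exam never contains null entries. Mixed dentition is allowed:
#' `teeth` may contain permanent and deciduous positions, each validated
#' against its own crown alphabet.
#'
#' @param partial `NULL`, or a data.frame with columns `tooth`, `crown`,
#'   `treatment` carrying the recorded findings. Letter codes are
#'   case-insensitive and canonicalized to upper case.
#' @param teeth Integer vector of FDI tooth codes making up the examined
#'   dentition set; defaults to the full 32-tooth permanent mouth.
#' @return A data.frame of class `odontogram` with one row per tooth in
#'   `teeth` and columns `tooth`, `crown`, `treatment`.
#' @examples
#' odo <- normalize_odontogram(data.frame(tooth = 14, crown = "7",
#'                                        treatment = "3"))
#' nrow(odo) # 32
#' @export
normalize_odontogram <- function(partial = NULL,
                                 teeth = fdi_teeth("permanent")) {
  teeth <- as.integer(teeth)
  if (anyDuplicated(teeth)) stop("duplicated teeth in dentition set", call. = FALSE)
  dent <- dentition_of(teeth)  # also validates codes
  out <- data.frame(tooth = teeth,
                    crown = healthy_crown(dent),
                    treatment = "0",
                    stringsAsFactors = FALSE)
  if (!is.null(partial) && nrow(as.data.frame(partial)) > 0L) {
    partial <- as.data.frame(partial)
    req <- c("tooth", "crown", "treatment")
    if (!all(req %in% names(partial))) {
      stop("partial records need columns tooth, crown, treatment", call. = FALSE)
    }
    pt <- as.integer(partial$tooth)
    if (anyDuplicated(pt)) stop("duplicated tooth entries in partial records", call. = FALSE)
    extra <- setdiff(pt, teeth)
    if (length(extra) > 0L) {
      stop("recorded teeth outside the dentition set: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    crown <- check_crown(pt, partial$crown)
    treatment <- check_treatment(partial$treatment)
    idx <- match(pt, out$tooth)
    out$crown[idx] <- crown
    out$treatment[idx] <- treatment
  }
  class(out) <- c("odontogram", "data.frame")
  out
}

#' @export
print.odontogram <- function(x, ...) {
  findings <- x[x$crown != healthy_crown(dentition_of(x$tooth)) |
                  x$treatment != "0", , drop = FALSE]
  cat(sprintf("<odontogram> %d teeth, %d with findings\n",
              nrow(x), nrow(findings)))
  if (nrow(findings) > 0L) print.data.frame(findings, row.names = FALSE)
  invisible(x)
}

is_odontogram <- function(x) inherits(x, "odontogram")

#' Construct an exam record
#'
#' An exam links an anonymized student code to an odontogram, the exam
#' date and the two-surgeon team that produced it (an examiner who reads
#' the mouth and an annotator who keys the codes).
#'
#' @param secret_code Opaque anonymized student token.
#' @param date Exam date (`Date` or ISO-8601 string).
#' @param odontogram An [normalize_odontogram()] result.
#' @param examiner_id,annotator_id Identifiers of the examining team.
#' @return A list of class `exam`.
#' @export
exam <- function(secret_code, date, odontogram,
                 examiner_id = NA_character_, annotator_id = NA_character_) {
  structure(list(secret_code = as.character(secret_code),
                 date = as.Date(date),
                 odontogram = odontogram,
                 examiner_id = as.character(examiner_id),
                 annotator_id = as.character(annotator_id)),
            class = "exam")
}

#' Validate an exam against the odontogram coding rules
#'
#' Returns a structured report rather than aborting, so field batches with
#' sporadic errors can be partially merged (invalid records are quarantined
#' by [merge_batch()], not inserted). Treatment code `"9"` (no information)
#' is syntactically valid but reported as a warning. An odontogram whose
#' tooth set has unset (NA) entries violates the no-null rule and is an
#' error; run [normalize_odontogram()] first.
#'
#' @param x An `exam` or a bare `odontogram`.
#' @param action_dates Optional length-2 Date vector; an exam dated outside
#'   this range yields a warning entry (field work occasionally runs over).
#' @return A data.frame of class `validation_report` with columns
#'   `severity` (`"error"`/`"warning"`), `locus`, `message`.
#' @export
validate_exam <- function(x, action_dates = NULL) {
  odo <- if (inherits(x, "exam")) x$odontogram else x
  probs <- list()
  add <- function(severity, locus, message) {
    probs[[length(probs) + 1L]] <<- data.frame(
      severity = severity, locus = locus, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(odo) ||
      !all(c("tooth", "crown", "treatment") %in% names(odo))) {
    add("error", "odontogram", "not an odontogram (tooth/crown/treatment)")
  } else {
    if (anyNA(odo$crown) || anyNA(odo$treatment)) {
      na_teeth <- odo$tooth[is.na(odo$crown) | is.na(odo$treatment)]
      add("error", paste(na_teeth, collapse = ","),
          "null code entries; odontograms must be normalized")
    }
    ok_rows <- !is.na(odo$crown) & !is.na(odo$treatment)
    for (i in which(ok_rows)) {
      ti <- as.integer(odo$tooth[i])
      if (!(ti %in% c(.PERMANENT_TEETH, .DECIDUOUS_TEETH))) {
        add("error", as.character(odo$tooth[i]), "invalid FDI tooth code")
        next
      }
      d <- dentition_of(ti)
      ci <- canon_code(odo$crown[i])
      if (!(ci %in% crown_alphabet(d))) {
        add("error", as.character(ti),
            sprintf("crown code '%s' not in the %s alphabet", ci, d))
      }
      tr <- canon_code(odo$treatment[i])
      if (!(tr %in% .TREATMENT_CODES)) {
        add("error", as.character(ti),
            sprintf("invalid treatment code '%s'", tr))
      } else if (tr == "9") {
        add("warning", as.character(ti), "treatment '9': no information")
      }
    }
    if (anyDuplicated(odo$tooth)) {
      add("error", "odontogram", "duplicated tooth entries")
    }
  }
  if (inherits(x, "exam") && !is.null(action_dates)) {
    rng <- as.Date(action_dates)
    if (x$date < min(rng) || x$date > max(rng)) {
      add("warning", "date",
          sprintf("exam date %s outside action range %s..%s",
                  x$date, min(rng), max(rng)))
    }
  }
  rep <- if (length(probs) > 0L) do.call(rbind, probs) else
    data.frame(severity = character(), locus = character(),
               message = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation report> %d error(s), %d warning(s)\n",
              sum(x$severity == "error"), sum(x$severity == "warning")))
  if (nrow(x) > 0L) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Does a validation report contain errors?
#' @param report A [validate_exam()] / [validate_response()] report.
#' @return `TRUE` if any row has severity `"error"`.
#' @export
has_errors <- function(report) any(report$severity == "error")

#' Completed years between two dates
#'
#' Age in completed years at a reference date (the usual survey
#' stratification variable): the anniversary day itself counts.
#'
#' @param birth_date,reference_date `Date` or ISO-8601 strings.
#' @return Integer completed years (vectorized).
#' @examples
#' age_at("2003-05-01", "2018-05-01") # 15
#' age_at("2003-05-02", "2018-05-01") # 14
#' @export
age_at <- function(birth_date, reference_date) {
  b <- as.Date(birth_date); r <- as.Date(reference_date)
  if (any(b > r)) stop("birth_date after reference_date", call. = FALSE)
  bl <- as.POSIXlt(b); rl <- as.POSIXlt(r)
  yrs <- rl$year - bl$year
  before <- rl$mon < bl$mon | (rl$mon == bl$mon & rl$mday < bl$mday)
  as.integer(yrs - before)
}
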