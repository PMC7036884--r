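#' Import/export of survey tables and the bundled registers
#'
#' A survey set is the quartet of entity tables — schools, students,
#' exams (long, one row per tooth) and questionnaire responses (wide, one
#' column per question) — that external statistics tools consume. Exports
#' to CSV, JSON and XML are lossless: re-importing reproduces the source
#' tables exactly. The bundled registers (the 2017 Palmas municipal
#' school enrollment and the two questionnaire structures) are
#' checksummed so an accidental edit of a transcription fails loudly.
#'
#' @name io-formats
NULL

.FIXTURE_MD5 <- c(
  palmas_schools_2017.csv = "0eb5bb93c67e751165f5b72b5ca8e9c3",
  student_questionnaire_classes.csv = "e626c411a23b73822623a4552dbc1432",
  principal_questionnaire_classes.csv = "f50fd59fb0b0bb9319a538466b5f0a13")

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "odontosurvey")
  if (!nzchar(p)) stop("bundled fixture not found: ", name, call. = FALSE)
  actual <- unname(tools::md5sum(p))
  if (!identical(actual, unname(.FIXTURE_MD5[[name]]))) {
    stop("fixture checksum mismatch for ", name,
         "; the transcription has been edited", call. = FALSE)
  }
  p
}

#' The 2017 Palmas municipal school register
#'
#' The 26 municipal schools with a 9th grade, with their health territory
#' and enrollment (total and 9th-grade) as published by the municipal
#' education secretariat for 2017. School coordinates are not part of the
#' register; latitude/longitude are `NA`.
#'
#' @return A [schools()] table (26 rows).
#' @examples
#' reg <- load_school_register()
#' sum(reg$enrollment_total)  # 16321
#' sum(reg$enrollment_grade9) # 2014
#' @export
load_school_register <- function() {
  raw <- utils::read.csv(fixture_path("palmas_schools_2017.csv"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  schools(id = raw$id, name = raw$name, territory = raw$territory,
          enrollment_total = raw$enrollment_total,
          enrollment_grade9 = raw$enrollment_grade9)
}

#' The bundled questionnaire definitions
#'
#' The student questionnaire has 146 questions in 12 thematic classes
#' (adapted from the Brazilian national school-health survey); the school
#' principal's characterization questionnaire has 84 questions, published
#' only as a total, so it is bundled as a single class.
#'
#' @return A [questionnaire_def()].
#' @export
load_student_questionnaire <- function() {
  raw <- utils::read.csv(fixture_path("student_questionnaire_classes.csv"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  questionnaire_def(raw$class_label, raw$first, raw$last)
}

#' @rdname load_student_questionnaire
#' @export
load_principal_questionnaire <- function() {
  raw <- utils::read.csv(fixture_path("principal_questionnaire_classes.csv"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  questionnaire_def(raw$class_label, raw$first, raw$last)
}

# ---- exam layout conversions ------------------------------------------

#' Convert between the two exam layouts
#'
#' Long layout: one row per (exam, tooth), the analysis-friendly form.
#' Wide layout: one row per exam with `t<FDI>_crown` / `t<FDI>_treatment`
#' column pairs, the spreadsheet-friendly form. The conversion is
#' lossless both ways.
#'
#' @param exams A long exam table (see [exams_table()]).
#' @return The wide data.frame.
#' @export
exams_to_wide <- function(exams) {
  ids <- unique(exams$exam_id)
  teeth <- sort(unique(as.integer(exams$tooth)))
  head <- exams[match(ids, exams$exam_id),
                c("exam_id", "secret_code", "date", "examiner_id"),
                drop = FALSE]
  rownames(head) <- NULL
  for (t in teeth) {
    sub <- exams[exams$tooth == t, , drop = FALSE]
    m <- match(ids, sub$exam_id)
    head[[sprintf("t%d_crown", t)]] <- sub$crown[m]
    head[[sprintf("t%d_treatment", t)]] <- sub$treatment[m]
  }
  head
}

#' @rdname exams_to_wide
#' @param wide A wide exam data.frame produced by [exams_to_wide()].
#' @return The long exam table.
#' @export
exams_to_long <- function(wide) {
  crown_cols <- grep("^t[0-9]+_crown$", names(wide), value = TRUE)
  teeth <- as.integer(sub("^t([0-9]+)_crown$", "\\1", crown_cols))
  rows <- lapply(seq_along(teeth), function(i) {
    t <- teeth[i]
    cr <- wide[[sprintf("t%d_crown", t)]]
    tr <- wide[[sprintf("t%d_treatment", t)]]
    keep <- !is.na(cr)
    data.frame(exam_id = wide$exam_id[keep],
               secret_code = wide$secret_code[keep],
               date = as.Date(wide$date[keep]),
               examiner_id = wide$examiner_id[keep],
               tooth = t, crown = cr[keep], treatment = tr[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$exam_id, wide$exam_id), out$tooth), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- survey-set export/import -----------------------------------------

.SURVEY_TABLES <- c("schools", "students", "exams", "responses")

empty_survey_set <- function() {
  list(schools = schools(character(), character())[0L, ],
       students = students(character(), as.Date(character()))[0L, ],
       exams = data.frame(exam_id = character(), secret_code = character(),
                          date = as.Date(character()),
                          examiner_id = character(), tooth = integer(),
                          crown = character(), treatment = character(),
                          stringsAsFactors = FALSE),
       responses = data.frame(secret_code = character(),
                              date = as.Date(character()),
                              stringsAsFactors = FALSE))
}

# Coerce freshly parsed tables back to the canonical column types so a
# round trip restores the source exactly.
canonicalize_survey_set <- function(x) {
  ref <- empty_survey_set()
  out <- list()
  for (tb in .SURVEY_TABLES) {
    df <- x[[tb]]
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0L &&
                        ncol(df) == 0L)) {
      out[[tb]] <- ref[[tb]]
      next
    }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (ncol(df) == 0L) { out[[tb]] <- ref[[tb]]; next }
    for (col in names(df)) {
      proto <- ref[[tb]][[col]]
      if (!is.null(proto)) {
        df[[col]] <- if (inherits(proto, "Date")) as.Date(df[[col]])
                     else { storage.mode(df[[col]]) <- storage.mode(proto); df[[col]] }
      } else if (tb == "responses" && grepl("^q[0-9]+$", col)) {
        df[[col]] <- as.character(df[[col]])
      }
    }
    if (nrow(df) == 0L && ncol(ref[[tb]]) == ncol(df)) df <- ref[[tb]]
    # canonical column order: reference columns first, then extras
    # (question columns numerically) so import order never depends on
    # which record happened to be serialized first
    extras <- setdiff(names(df), names(ref[[tb]]))
    qs <- grep("^q[0-9]+$", extras, value = TRUE)
    extras <- c(sort(setdiff(extras, qs)),
                qs[order(as.integer(sub("^q", "", qs)))])
    df <- df[, c(intersect(names(ref[[tb]]), names(df)), extras),
             drop = FALSE]
    rownames(df) <- NULL
    out[[tb]] <- df
  }
  out
}

#' Export a survey set
#'
#' Writes the four entity tables plus a metadata file to `dir`. CSV
#' dialect is fixed (UTF-8, comma, quoted strings, ISO dates); JSON is a
#' single document; XML is flat, one element per record with one
#' attribute per field. The `layout` option controls whether exams are
#' written long (per tooth) or wide (per exam).
#'
#' @param survey A list with `schools`, `students`, `exams` (long),
#'   `responses` tables (missing tables are written empty).
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"json"` or `"xml"`.
#' @param layout Exam layout, `"per_tooth"` or `"per_exam"`.
#' @return The directory path, invisibly.
#' @export
export_survey <- function(survey, dir, format = c("csv", "json", "xml"),
                          layout = c("per_tooth", "per_exam")) {
  format <- match.arg(format)
  layout <- match.arg(layout)
  survey <- canonicalize_survey_set(survey)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- survey
  if (layout == "per_exam" && nrow(tables$exams) > 0L) {
    tables$exams <- exams_to_wide(tables$exams)
  }
  meta <- list(schema_version = 1L, layout = layout, format = format,
               exported_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  switch(format,
    csv = for (tb in .SURVEY_TABLES) {
      utils::write.csv(tables[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE, fileEncoding = "UTF-8", na = "")
    },
    json = jsonlite::write_json(tables, file.path(dir, "survey.json"),
                                dataframe = "rows", digits = NA,
                                na = "null", Date = "ISO8601"),
    xml = write_survey_xml(tables, file.path(dir, "survey.xml")))
  invisible(dir)
}

write_survey_xml <- function(tables, path) {
  doc <- xml2::xml_new_root("survey", schema_version = "1")
  for (tb in .SURVEY_TABLES) {
    node <- xml2::xml_add_child(doc, tb)
    df <- tables[[tb]]
    for (i in seq_len(nrow(df))) {
      vals <- lapply(df[i, , drop = FALSE], function(v)
        if (is.na(v)) NULL else as.character(v))
      vals <- vals[!vapply(vals, is.null, logical(1L))]
      do.call(xml2::xml_add_child, c(list(node, "record"), vals))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_survey_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML import: ", conditionMessage(e), call. = FALSE))
  out <- list()
  for (tb in .SURVEY_TABLES) {
    node <- xml2::xml_find_first(doc, paste0("./", tb))
    recs <- xml2::xml_find_all(node, "./record")
    if (length(recs) == 0L) { out[[tb]] <- data.frame(); next }
    rows <- lapply(recs, function(r) as.list(xml2::xml_attrs(r)))
    cols <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(stats::setNames(lapply(cols, function(cl)
      vapply(rows, function(r) if (is.null(r[[cl]])) NA_character_
             else r[[cl]], character(1L))), cols),
      stringsAsFactors = FALSE, check.names = FALSE)
    out[[tb]] <- df
  }
  out
}

#' Import a survey set written by [export_survey()]
#'
#' @param dir Directory containing the export.
#' @return A survey-set list with canonical column types; exams are
#'   returned in the long layout regardless of the exported layout.
#' @export
import_survey <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("no metadata.json in ", dir, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  tables <- switch(meta$format,
    csv = stats::setNames(lapply(.SURVEY_TABLES, function(tb) {
      f <- file.path(dir, paste0(tb, ".csv"))
      if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
      utils::read.csv(f, stringsAsFactors = FALSE, encoding = "UTF-8",
                      na.strings = "", check.names = FALSE,
                      colClasses = "character")
    }), .SURVEY_TABLES),
    json = jsonlite::fromJSON(file.path(dir, "survey.json"),
                              simplifyDataFrame = TRUE),
    xml = read_survey_xml(file.path(dir, "survey.xml")),
    stop("unknown export format: ", meta$format, call. = FALSE))
  if (identical(meta$layout, "per_exam") &&
      is.data.frame(tables$exams) && nrow(tables$exams) > 0L) {
    tables$exams <- exams_to_long(tables$exams)
  }
  canonicalize_survey_set(tables)
}

# ---- store <-> survey-set bridge --------------------------------------

#' Extract the survey tables from a central store
#'
#' @param store A `central_store`.
#' @return A survey-set list (`schools`, `students`, `exams` long,
#'   `responses` wide).
#' @export
store_to_survey <- function(store) {
  out <- empty_survey_set()
  grab <- function(type) store_records(store, type)
  sc <- grab("school")
  if (length(sc) > 0L) {
    out$schools <- do.call(rbind, lapply(sc, function(r) {
      p <- r$payload
      schools(p$id, p$name,
              latitude = p$latitude %||% NA_real_,
              longitude = p$longitude %||% NA_real_,
              territory = p$territory %||% NA_character_,
              enrollment_total = p$enrollment_total %||% NA_integer_,
              enrollment_grade9 = p$enrollment_grade9 %||% NA_integer_)
    }))
  }
  st <- grab("student")
  if (length(st) > 0L) {
    out$students <- do.call(rbind, lapply(st, function(r) {
      p <- r$payload
      data.frame(secret_code = p$secret_code,
                 birth_date = as.Date(p$birth_date),
                 sex = p$sex %||% NA_character_,
                 race = p$race %||% NA_character_,
                 school_id = p$school_id %||% NA_character_,
                 class_label = p$class_label %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  ex <- grab("exam")
  if (length(ex) > 0L) {
    out$exams <- do.call(rbind, lapply(ex, function(r) {
      p <- r$payload
      data.frame(exam_id = r$record_uid, secret_code = p$secret_code,
                 date = as.Date(p$date),
                 examiner_id = p$examiner_id %||% NA_character_,
                 tooth = as.integer(unlist(p$odontogram$tooth)),
                 crown = as.character(unlist(p$odontogram$crown)),
                 treatment = as.character(unlist(p$odontogram$treatment)),
                 stringsAsFactors = FALSE)
    }))
  }
  rs <- grab("response")
  if (length(rs) > 0L) {
    qmax <- max(vapply(rs, function(r)
      max(c(0L, as.integer(names(r$payload$answers)))), integer(1L)))
    out$responses <- do.call(rbind, lapply(rs, function(r) {
      p <- r$payload
      row <- data.frame(secret_code = p$secret_code, date = as.Date(p$date),
                        stringsAsFactors = FALSE)
      for (q in seq_len(qmax)) {
        a <- p$answers[[as.character(q)]]
        row[[paste0("q", q)]] <- if (is.null(a)) NA_character_
                                 else as.character(a)
      }
      row
    }))
  }
  for (tb in .SURVEY_TABLES) rownames(out[[tb]]) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
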