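#' Caries index components and the CPO-D / ceo-d indices
#'
#' Each examined tooth is classified into at most one of the index
#' components from its crown code — decayed (x), filled/crowned (y),
#' missing because of caries (z) — and, independently, a treatment code of
#' `"6"` marks the tooth as extraction-indicated (w). The per-person
#' permanent-dentition index is CPO = x + y + z + w; the deciduous
#' analogue is ceo = x + y + w, which by definition excludes the missing
#' component because exfoliation makes primary-tooth loss uninterpretable.
#'
#' @name indices
NULL

#' Crown-code to index-component mapping
#'
#' The per-dentition classification table. The convention follows WHO
#' basic-methods practice: caries and restored-with-caries count as
#' decayed; restored-without-caries as filled; lost-because-of-caries as
#' missing; loss for other reasons, sealant, bridge, unerupted, trauma and
#' not-considered contribute to no component. The table is data, not code,
#' so an alternate convention is a one-argument change to
#' [classify_tooth()] and [count_components()].
#'
#' @param dentition `"permanent"` or `"deciduous"`.
#' @return data.frame with columns `crown`, `component`.
#' @export
caries_component_map <- function(dentition = c("permanent", "deciduous")) {
  dentition <- match.arg(dentition)
  if (dentition == "permanent") {
    data.frame(crown = .CROWN_PERMANENT,
               component = c("none", "decayed", "decayed", "filled",
                             "missing", "none", "none", "none", "none",
                             "none", "none"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(crown = .CROWN_DECIDUOUS,
               component = c("none", "decayed", "decayed", "filled",
                             "missing", "none", "none", "none", "none",
                             "none", "none"),
               stringsAsFactors = FALSE)
  }
}

#' Classify tooth records into index components
#'
#' @param tooth Integer FDI codes (determines the dentition and so the
#'   crown alphabet).
#' @param crown,treatment Code symbols.
#' @param map Optional override of [caries_component_map()]; a function of
#'   `dentition` returning a crown/component table.
#' @return data.frame with columns `component` (one of `decayed`,
#'   `filled`, `missing`, `none`) and `extraction_indicated` (logical,
#'   reported alongside the crown component, not instead of it).
#' @examples
#' classify_tooth(11, "2", "0") # decayed
#' classify_tooth(46, "1", "6") # decayed + extraction indicated
#' @export
classify_tooth <- function(tooth, crown, treatment,
                           map = caries_component_map) {
  crown <- check_crown(tooth, crown)
  treatment <- check_treatment(treatment)
  dent <- dentition_of(tooth)
  comp <- character(length(crown))
  for (d in unique(dent)) {
    m <- map(d)
    sel <- dent == d
    comp[sel] <- m$component[match(crown[sel], m$crown)]
  }
  data.frame(component = comp,
             extraction_indicated = treatment == "6",
             stringsAsFactors = FALSE)
}

#' Tally index components over an odontogram
#'
#' Counts x (decayed), y (filled/crowned), z (missing) and w (extraction
#' indicated) over the teeth of the requested dentition; each tooth
#' contributes to at most one of x/y/z and at most once to w.
#'
#' @param odontogram A normalized [normalize_odontogram()] result.
#' @param dentition Which dentition's teeth to tally.
#' @param map See [classify_tooth()].
#' @return A list of class `component_count` with fields `x`, `y`, `z`,
#'   `w`, `n_teeth`, `dentition`.
#' @export
count_components <- function(odontogram,
                             dentition = c("permanent", "deciduous"),
                             map = caries_component_map) {
  dentition <- match.arg(dentition)
  sel <- odontogram[dentition_of(odontogram$tooth) == dentition, , drop = FALSE]
  if (nrow(sel) == 0L) {
    cls <- data.frame(component = character(), extraction_indicated = logical())
  } else {
    cls <- classify_tooth(sel$tooth, sel$crown, sel$treatment, map = map)
  }
  structure(list(x = sum(cls$component == "decayed"),
                 y = sum(cls$component == "filled"),
                 z = sum(cls$component == "missing"),
                 w = sum(cls$extraction_indicated),
                 n_teeth = nrow(sel),
                 dentition = dentition),
            class = "component_count")
}

#' @export
print.component_count <- function(x, ...) {
  cat(sprintf("<component count, %s> x=%d y=%d z=%d w=%d over %d teeth\n",
              x$dentition, x$x, x$y, x$z, x$w, x$n_teeth))
  invisible(x)
}

#' Per-person permanent-dentition caries index (CPO-D / DMFT)
#'
#' CPO = x + y + z + w: decayed + filled + missing-for-caries +
#' extraction-indicated permanent teeth.
#'
#' @param counts A `component_count` for the permanent dentition.
#' @return Integer index value.
#' @export
cpo_individual <- function(counts) {
  stopifnot(inherits(counts, "component_count"))
  if (counts$dentition != "permanent") {
    stop("CPO is defined on permanent-dentition counts", call. = FALSE)
  }
  counts$x + counts$y + counts$z + counts$w
}

#' Per-person deciduous-dentition caries index (ceo-d)
#'
#' ceo = x + y + w. The missing component z is excluded by definition:
#' a primary tooth absent at exam time cannot be attributed to caries
#' rather than normal exfoliation.
#'
#' @param counts A `component_count` for the deciduous dentition.
#' @return Integer index value.
#' @export
ceo_individual <- function(counts) {
  stopifnot(inherits(counts, "component_count"))
  if (counts$dentition != "deciduous") {
    stop("ceo is defined on deciduous-dentition counts", call. = FALSE)
  }
  counts$x + counts$y + counts$w
}

#' Mean caries index over examined persons
#'
#' @param values Numeric vector of individual index values.
#' @return Arithmetic mean.
#' @export
mean_index <- function(values) {
  if (length(values) == 0L) stop("no examined persons", call. = FALSE)
  mean(values)
}

#' Literal per-person index percentage
#'
#' Evaluates `value * 100 / N` for an individual's index against the
#' number of persons examined. This is the per-person percentage as the
#' source survey system printed it; its epidemiological meaning is thin
#' (it is not a prevalence), so [prevalence()] is provided separately as
#' the conventional companion statistic.
#'
#' @param value Individual index value(s).
#' @param n Number of persons examined.
#' @return Numeric percentage(s).
#' @export
index_percent <- function(value, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be positive", call. = FALSE)
  value * 100 / n
}

#' Caries prevalence: fraction of persons with a positive index
#'
#' @param values Numeric vector of individual index values.
#' @return Fraction in `[0, 1]`.
#' @export
prevalence <- function(values) {
  if (length(values) == 0L) stop("no examined persons", call. = FALSE)
  mean(values > 0)
}

#' Flatten exam objects to a long per-tooth table
#'
#' @param exam_list List of [exam()] objects.
#' @return data.frame with one row per (exam, tooth): `exam_id`,
#'   `secret_code`, `date`, `examiner_id`, `tooth`, `crown`, `treatment`.
#' @export
exams_table <- function(exam_list) {
  if (length(exam_list) == 0L) {
    return(data.frame(exam_id = character(), secret_code = character(),
                      date = as.Date(character()), examiner_id = character(),
                      tooth = integer(), crown = character(),
                      treatment = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(exam_list), function(i) {
    e <- exam_list[[i]]
    odo <- e$odontogram
    data.frame(exam_id = sprintf("%s#%d", e$secret_code, i),
               secret_code = e$secret_code, date = e$date,
               examiner_id = e$examiner_id,
               tooth = as.integer(odo$tooth), crown = odo$crown,
               treatment = odo$treatment, stringsAsFactors = FALSE)
  }))
}

#' Per-exam index values from a long exam table
#'
#' @param exams Long per-tooth exam table (see [exams_table()]).
#' @param dentition Dentition whose index to compute (`CPO` for permanent,
#'   `ceo` for deciduous).
#' @param map See [classify_tooth()].
#' @return data.frame, one row per exam: `exam_id`, `secret_code`, `x`,
#'   `y`, `z`, `w`, `index`.
#' @export
exam_index <- function(exams, dentition = c("permanent", "deciduous"),
                       map = caries_component_map) {
  dentition <- match.arg(dentition)
  sel <- exams[dentition_of(exams$tooth) == dentition, , drop = FALSE]
  ids <- unique(exams$exam_id)
  if (nrow(sel) > 0L) {
    cls <- classify_tooth(sel$tooth, sel$crown, sel$treatment, map = map)
    f <- factor(sel$exam_id, levels = ids)
    x <- as.integer(tapply(cls$component == "decayed", f, sum, default = 0L))
    y <- as.integer(tapply(cls$component == "filled", f, sum, default = 0L))
    z <- as.integer(tapply(cls$component == "missing", f, sum, default = 0L))
    w <- as.integer(tapply(cls$extraction_indicated, f, sum, default = 0L))
    x[is.na(x)] <- 0L; y[is.na(y)] <- 0L; z[is.na(z)] <- 0L; w[is.na(w)] <- 0L
  } else {
    x <- rep(0L, length(ids)); y <- x; z <- x; w <- x
  }
  idx <- if (dentition == "permanent") x + y + z + w else x + y + w
  first <- exams[match(ids, exams$exam_id), , drop = FALSE]
  data.frame(exam_id = ids, secret_code = first$secret_code,
             x = x, y = y, z = z, w = w, index = idx,
             stringsAsFactors = FALSE)
}

#' Grouped index summaries
#'
#' Aggregates per-exam index values by school, health territory,
#' municipality, sex or age. Each exam is counted in exactly one group per
#' grouping key; unresolvable student or school references are an error
#' naming the orphan codes.
#'
#' @param exams Long per-tooth exam table.
#' @param students Student table (see [students()]).
#' @param schools School table (see [schools()]); must carry `territory`
#'   when grouping by territory.
#' @param group_by One of `"school"`, `"territory"`, `"municipality"`,
#'   `"sex"`, `"age"`.
#' @param dentition Index dentition, as in [exam_index()].
#' @return data.frame, one row per group: `group_by`, `group`, `N`, `x`,
#'   `y`, `z`, `w`, `mean`, `prevalence`.
#' @export
aggregate_index <- function(exams, students, schools,
                            group_by = c("school", "territory",
                                         "municipality", "sex", "age"),
                            dentition = "permanent") {
  group_by <- match.arg(group_by)
  per <- exam_index(exams, dentition)
  orphans <- setdiff(per$secret_code, students$secret_code)
  if (length(orphans) > 0L) {
    stop("exams reference unknown student codes: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  si <- match(per$secret_code, students$secret_code)
  school_id <- students$school_id[si]
  bad_school <- setdiff(school_id, schools$id)
  if (length(bad_school) > 0L) {
    stop("students reference unknown schools: ",
         paste(bad_school, collapse = ", "), call. = FALSE)
  }
  ki <- match(school_id, schools$id)
  first_date <- exams$date[match(per$exam_id, exams$exam_id)]
  key <- switch(group_by,
                school = school_id,
                territory = schools$territory[ki],
                municipality = rep("municipal", nrow(per)),
                sex = students$sex[si],
                age = as.character(age_at(students$birth_date[si], first_date)))
  f <- factor(key)
  agg <- data.frame(group_by = group_by, group = levels(f),
                    N = as.integer(table(f)),
                    x = as.integer(tapply(per$x, f, sum)),
                    y = as.integer(tapply(per$y, f, sum)),
                    z = as.integer(tapply(per$z, f, sum)),
                    w = as.integer(tapply(per$w, f, sum)),
                    mean = as.numeric(tapply(per$index, f, mean)),
                    prevalence = as.numeric(tapply(per$index > 0, f, mean)),
                    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg
}
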