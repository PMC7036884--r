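#' Health-territory assignment and report surfaces
#'
#' Municipal health systems partition a city into named territories, each
#' served by specific health units; relating schools to territories lets
#' caries indices be read as demands on those units. Assignment uses an
#' explicit school-to-territory mapping when available (the usual case:
#' the municipality publishes the register), falling back to
#' point-in-polygon against territory boundaries supplied as GeoJSON.
#'
#' @name geo-reports
NULL

#' The default territory label set
#'
#' The eight health territories of the Palmas municipal network. One
#' territory circulates under two spellings; [territory_alias()]
#' canonicalizes.
#' @return Character vector of territory labels.
#' @export
default_territories <- function() {
  c("Apinajé", "Javaé", "Kanela", "Karajá",
    "Krahô", "Xambioá", "Xerente", "Pankararu")
}

#' Canonicalize territory spellings
#' @param x Territory labels.
#' @return Labels with known alias spellings replaced by the canonical
#'   register form (e.g. `"Khraô"` -> `"Krahô"`).
#' @export
territory_alias <- function(x) {
  aliases <- c("Khraô" = "Krahô")
  hit <- x %in% names(aliases)
  x[hit] <- aliases[x[hit]]
  x
}

#' Build a territory map
#'
#' @param mapping Optional data.frame `school_id`, `territory` (explicit
#'   register; takes precedence).
#' @param polygons Optional named list of two-column (lon, lat) matrices,
#'   one closed, non-self-intersecting ring per territory.
#' @return A list of class `territory_map`.
#' @export
territory_map <- function(mapping = NULL, polygons = NULL) {
  if (is.null(mapping) && is.null(polygons)) {
    stop("need an explicit mapping or polygons", call. = FALSE)
  }
  if (!is.null(mapping)) {
    stopifnot(all(c("school_id", "territory") %in% names(mapping)))
    mapping$territory <- territory_alias(mapping$territory)
    if (any(!nzchar(mapping$territory))) stop("empty territory label", call. = FALSE)
  }
  if (!is.null(polygons)) {
    if (is.null(names(polygons)) || any(!nzchar(names(polygons)))) {
      stop("polygons must be named by territory", call. = FALSE)
    }
    polygons <- lapply(polygons, function(p) {
      p <- as.matrix(p)
      stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
      # drop an explicitly repeated closing vertex; rings close implicitly
      if (all(p[1L, ] == p[nrow(p), ]) && nrow(p) > 3L) p <- p[-nrow(p), , drop = FALSE]
      p
    })
    names(polygons) <- territory_alias(names(polygons))
  }
  structure(list(mapping = mapping, polygons = polygons),
            class = "territory_map")
}

#' Read territory polygons from a GeoJSON FeatureCollection
#'
#' Each feature must carry a `territory` property and a Polygon geometry
#' (outer ring used; holes unsupported at municipal-territory scale).
#'
#' @param path GeoJSON file path.
#' @return A `territory_map` with polygons only.
#' @export
read_territory_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  polys <- list()
  for (f in gj$features) {
    lab <- f$properties$territory
    if (is.null(lab)) stop("feature without a 'territory' property", call. = FALSE)
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported", call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    polys[[lab]] <- m
  }
  territory_map(polygons = polys)
}

# Is point (x, y) on the boundary of ring `p` (closed implicitly)?
on_ring <- function(p, x, y, eps = 1e-12) {
  n <- nrow(p)
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    if (abs(cross) > eps * max(1, abs(b[1] - a[1]), abs(b[2] - a[2]))) next
    if (x >= min(a[1], b[1]) - eps && x <= max(a[1], b[1]) + eps &&
        y >= min(a[2], b[2]) - eps && y <= max(a[2], b[2]) + eps) return(TRUE)
  }
  FALSE
}

point_in_territory <- function(p, x, y) {
  if (on_ring(p, x, y)) return(TRUE)
  ring <- rbind(p, p[1L, ])
  as.logical(mgcv::in.out(ring, matrix(c(x, y), nrow = 1L)))
}

#' Assign a school to a health territory
#'
#' The explicit mapping takes precedence; otherwise the school's
#' longitude/latitude point is located in the territory polygons, with
#' boundary points assigned to the first-listed containing territory.
#'
#' @param school One row of a [schools()] table (or a list with `id`,
#'   `longitude`, `latitude`).
#' @param tmap A [territory_map()].
#' @return Territory label.
#' @export
assign_territory <- function(school, tmap) {
  stopifnot(inherits(tmap, "territory_map"))
  id <- as.character(school$id)
  if (!is.null(tmap$mapping)) {
    hit <- match(id, tmap$mapping$school_id)
    if (!is.na(hit)) return(tmap$mapping$territory[hit])
  }
  if (!is.null(tmap$polygons) &&
      !is.na(school$longitude) && !is.na(school$latitude)) {
    for (lab in names(tmap$polygons)) {
      if (point_in_territory(tmap$polygons[[lab]],
                             school$longitude, school$latitude)) {
        return(lab)
      }
    }
  }
  stop(sprintf("school '%s' has no territory: not in the mapping and in no polygon", id),
       call. = FALSE)
}

#' Three-level caries index report: school, territory, municipality
#'
#' The report surface behind the territory map view: for each school the
#' mean index, the mean of its health territory and the overall municipal
#' mean. Each exam contributes once per level, so the municipal mean is
#' the exam-count-weighted mean of territory means.
#'
#' @param exams Long per-tooth exam table (see [exams_table()]).
#' @param students,schools Entity tables.
#' @param tmap A [territory_map()]; when `NULL`, the `territory` column of
#'   `schools` is used.
#' @param dentition Index dentition.
#' @return A list of class `territory_report` with data.frames `school`,
#'   `territory`, `municipal`.
#' @export
territory_index_report <- function(exams, students, schools, tmap = NULL,
                                   dentition = "permanent") {
  if (!is.null(tmap)) {
    schools$territory <- vapply(seq_len(nrow(schools)), function(i)
      assign_territory(schools[i, ], tmap), character(1L))
  }
  if (anyNA(schools$territory)) {
    stop("schools without territory: ",
         paste(schools$id[is.na(schools$territory)], collapse = ", "),
         call. = FALSE)
  }
  schools$territory <- territory_alias(schools$territory)
  out <- list(
    school = aggregate_index(exams, students, schools, "school", dentition),
    territory = aggregate_index(exams, students, schools, "territory", dentition),
    municipal = aggregate_index(exams, students, schools, "municipality", dentition))
  class(out) <- "territory_report"
  out
}

#' @export
print.territory_report <- function(x, ...) {
  cat(sprintf("<territory report> municipal mean %.2f over %d exam(s)\n",
              x$municipal$mean[1L], x$municipal$N[1L]))
  print.data.frame(x$territory, row.names = FALSE)
  invisible(x)
}

#' Per-school participation report
#'
#' Questionnaire and exam days differ in the field, so the two counts
#' legitimately disagree; both are reported as percentages of enrollment.
#' Zero-enrollment schools are kept and flagged (percentages undefined),
#' and counts exceeding enrollment raise a data-quality warning (student
#' transfers make this possible) rather than an error.
#'
#' @param schools School table with `enrollment_grade9` (the surveyed
#'   grade's enrollment).
#' @param questionnaires,exams Named integer vectors (names = school ids)
#'   or data.frames with `school_id`, `n`.
#' @return data.frame: `school_id`, `name`, `enrolled`, `questionnaires`,
#'   `exams`, `pct_questionnaire`, `pct_exam`, `flagged`.
#' @export
participation_report <- function(schools, questionnaires, exams) {
  as_counts <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$n, x$school_id) else x
  }
  q <- as_counts(questionnaires); e <- as_counts(exams)
  enrolled <- schools$enrollment_grade9
  qn <- ifelse(is.na(match(schools$id, names(q))), 0L,
               as.integer(q[match(schools$id, names(q))]))
  en <- ifelse(is.na(match(schools$id, names(e))), 0L,
               as.integer(e[match(schools$id, names(e))]))
  if (any(qn > enrolled, na.rm = TRUE) || any(en > enrolled, na.rm = TRUE)) {
    warning("participation counts exceed enrollment for some schools ",
            "(possible transfers); check the register")
  }
  out <- data.frame(school_id = schools$id, name = schools$name,
                    enrolled = enrolled, questionnaires = qn, exams = en,
                    pct_questionnaire = ifelse(enrolled > 0,
                                               100 * qn / enrolled, NA_real_),
                    pct_exam = ifelse(enrolled > 0,
                                      100 * en / enrolled, NA_real_),
                    flagged = is.na(enrolled) | enrolled == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Desk overview of a central store
#'
#' The at-a-glance counters of the coordinator's work area: campaigns,
#' schools visited, students registered, questionnaires answered, exams
#' performed. A pure read of the store contents.
#'
#' @param store A `central_store`.
#' @return A list of class `desk_summary`.
#' @export
desk_summary <- function(store) {
  types <- vapply(store$records, function(r) r$record_type, character(1L))
  n_of <- function(t) sum(types == t)
  structure(list(campaigns = n_of("campaign"),
                 schools_visited = n_of("school"),
                 students_registered = n_of("student"),
                 questionnaires_answered = n_of("response"),
                 exams_performed = n_of("exam")),
            class = "desk_summary")
}

#' @export
print.desk_summary <- function(x, ...) {
  cat(sprintf(paste0("<desk> %d campaign(s), %d school(s), %d student(s), ",
                     "%d questionnaire(s), %d exam(s)\n"),
              x$campaigns, x$schools_visited, x$students_registered,
              x$questionnaires_answered, x$exams_performed))
  invisible(x)
}

#' Static territory-index bar chart
#'
#' A simple per-territory bar chart of the mean index (not an interactive
#' map: boundary data are user-supplied and plotting stays offline).
#'
#' @param report A [territory_index_report()] result.
#' @param file Optional PNG/SVG path; plots to the active device when
#'   `NULL`.
#' @return The territory data.frame, invisibly.
#' @export
plot_territory_index <- function(report, file = NULL) {
  terr <- report$territory
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file) else grDevices::png(file)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(terr$mean, names.arg = terr$group, las = 2,
                    ylab = "mean caries index",
                    main = "Mean index by health territory")
  graphics::abline(h = report$municipal$mean[1L], lty = 2)
  invisible(terr)
}
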