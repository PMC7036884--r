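#' Offline field batches and central-store synchronization
#'
#' Field teams capture records on a device with no connectivity; records
#' accumulate in a local batch which is sealed (checksummed and frozen)
#' and later merged into the central store. Merging is idempotent and, for
#' batches with disjoint records, order-independent: re-sending a batch
#' after a dropped connection can never duplicate data. Records that fail
#' domain validation are quarantined, never inserted, so the central store
#' only ever holds valid records.
#'
#' @name collection-sync
NULL

# ---- canonical serialization & checksums -------------------------------

# Recursively sort names so serialization is key-order independent.
sort_keys <- function(x) {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    x <- lapply(x, sort_keys)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
  }
  x
}

#' Canonical JSON serialization
#'
#' Deterministic, platform-independent serialization (sorted keys, fixed
#' separators, ISO dates, full numeric precision) so checksums over the
#' same content always agree.
#'
#' @param x A record or list of records.
#' @return Length-1 character of minified JSON.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null",
                                Date = "ISO8601", POSIXt = "ISO8601"))
}

# md5 of a string, via a temp file (tools::md5sum is file-based).
md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(enc2utf8(s)), f)
  unname(tools::md5sum(f))
}

# ---- records and batches ----------------------------------------------

#' Construct a typed field record
#'
#' Every captured entity travels as a record with a globally unique
#' `record_uid` assigned at capture time (content hashing would mis-file
#' legitimate corrections as new records) and a capture timestamp used for
#' conflict resolution.
#'
#' @param type Entity type, e.g. `"student"`, `"exam"`, `"response"`,
#'   `"school"`.
#' @param payload A list of entity fields (data.frames allowed; they are
#'   canonicalized on serialization).
#' @param record_uid Unique id; generated when `NULL`.
#' @param created_at Capture timestamp (ISO-8601 string or POSIXct).
#' @return A list of class `sync_record`.
#' @export
new_record <- function(type, payload, record_uid = NULL,
                       created_at = Sys.time()) {
  if (is.null(record_uid)) {
    record_uid <- md5_string(paste(type, canonical_json(payload),
                                   format(created_at, "%Y-%m-%dT%H:%M:%OS6"),
                                   stats::runif(1L)))
  }
  structure(list(record_uid = as.character(record_uid),
                 record_type = as.character(type),
                 created_at = format(as.POSIXct(created_at, tz = "UTC"),
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 payload = payload),
            class = "sync_record")
}

#' Open a local field batch
#'
#' @param device_label Free-text label of the capturing device.
#' @param batch_id Unique id; generated when `NULL`.
#' @param created_at Creation timestamp.
#' @return A list of class `local_batch` (unsealed, empty).
#' @export
open_batch <- function(device_label, batch_id = NULL,
                       created_at = Sys.time()) {
  if (is.null(batch_id)) {
    batch_id <- md5_string(paste(device_label,
                                 format(created_at, "%Y-%m-%dT%H:%M:%OS6"),
                                 stats::runif(1L)))
  }
  structure(list(batch_id = as.character(batch_id),
                 device_label = as.character(device_label),
                 created_at = format(as.POSIXct(created_at, tz = "UTC"),
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 records = list(), sealed = FALSE, checksum = NA_character_),
            class = "local_batch")
}

#' @rdname open_batch
#' @param batch An unsealed `local_batch`.
#' @param record A [new_record()] result.
#' @return The batch with the record appended.
#' @export
append_record <- function(batch, record) {
  stopifnot(inherits(batch, "local_batch"))
  if (batch$sealed) stop("cannot append to a sealed batch", call. = FALSE)
  if (!inherits(record, "sync_record")) stop("not a sync_record", call. = FALSE)
  batch$records[[length(batch$records) + 1L]] <- record
  batch
}

batch_checksum <- function(batch) {
  md5_string(paste(vapply(batch$records, function(r)
    canonical_json(unclass(r)), character(1L)), collapse = "\n"))
}

#' @rdname open_batch
#' @details Sealing computes the content checksum and freezes the batch;
#'   sealing an already-sealed batch is a no-op returning the same
#'   checksum.
#' @export
seal_batch <- function(batch) {
  stopifnot(inherits(batch, "local_batch"))
  if (batch$sealed) return(batch)
  batch$checksum <- batch_checksum(batch)
  batch$sealed <- TRUE
  batch
}

#' @export
print.local_batch <- function(x, ...) {
  cat(sprintf("<local batch %s> device '%s', %d record(s), %s\n",
              substr(x$batch_id, 1, 8), x$device_label, length(x$records),
              if (x$sealed) paste0("sealed (", substr(x$checksum, 1, 8), ")")
              else "open"))
  invisible(x)
}

# ---- at-rest codec hook ------------------------------------------------

#' At-rest payload codec hook
#'
#' Batch files can pass through a reversible codec before hitting disk
#' (the production deployment encrypts records at rest; key management is
#' outside this package). Any supplied codec must satisfy the round-trip
#' law `decode(encode(x)) == x`, which is verified with probe payloads at
#' registration; a codec failing the probe is rejected. The default codec
#' is the identity.
#'
#' @param encode,decode Functions character -> character.
#' @return A list of class `codec`.
#' @export
make_codec <- function(encode, decode) {
  probes <- c("", "abc", "{\"k\":[1,2,3],\"u\":\"café\"}")
  for (p in probes) {
    r <- tryCatch(decode(encode(p)), error = function(e) NULL)
    if (!identical(r, p)) {
      stop("codec fails the round-trip probe", call. = FALSE)
    }
  }
  structure(list(encode = encode, decode = decode), class = "codec")
}

#' @rdname make_codec
#' @export
identity_codec <- function() make_codec(identity, identity)

# ---- batch files (JSON Lines) -----------------------------------------

#' Write a sealed batch to a JSON Lines file
#'
#' One header line, one line per record, and a footer checksum line; the
#' canonical serialization makes the checksum reproducible across
#' platforms. Record lines pass through the codec.
#'
#' @param batch A sealed `local_batch`.
#' @param path Output file path.
#' @param codec A [make_codec()] result; identity by default.
#' @return `path`, invisibly.
#' @export
write_batch <- function(batch, path, codec = identity_codec()) {
  stopifnot(inherits(batch, "local_batch"))
  if (!batch$sealed) stop("seal the batch before writing", call. = FALSE)
  header <- canonical_json(list(kind = "batch_header", schema_version = 1L,
                                batch_id = batch$batch_id,
                                device_label = batch$device_label,
                                created_at = batch$created_at,
                                n_records = length(batch$records)))
  body <- vapply(batch$records, function(r)
    codec$encode(canonical_json(unclass(r))), character(1L))
  footer <- canonical_json(list(kind = "batch_checksum",
                                md5 = batch$checksum))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body, footer), con, useBytes = TRUE)
  invisible(path)
}

record_from_list <- function(x) {
  structure(list(record_uid = x$record_uid, record_type = x$record_type,
                 created_at = x$created_at, payload = x$payload),
            class = "sync_record")
}

#' Read and verify a batch file
#'
#' Recomputes the content checksum and refuses tampered or truncated
#' files.
#'
#' @param path Batch file path.
#' @param codec The codec the file was written with.
#' @return A sealed `local_batch`.
#' @export
read_batch <- function(path, codec = identity_codec()) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("malformed batch file: too short", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1L], simplifyVector = TRUE)
  if (!identical(header$kind, "batch_header")) {
    stop("malformed batch file: missing header (line 1)", call. = FALSE)
  }
  footer <- jsonlite::fromJSON(lines[length(lines)], simplifyVector = TRUE)
  if (!identical(footer$kind, "batch_checksum")) {
    stop("malformed batch file: missing checksum footer", call. = FALSE)
  }
  body <- lines[-c(1L, length(lines))]
  records <- lapply(seq_along(body), function(i) {
    x <- tryCatch(
      jsonlite::fromJSON(codec$decode(body[i]), simplifyVector = FALSE),
      error = function(e) stop(sprintf("malformed record at line %d: %s",
                                       i + 1L, conditionMessage(e)),
                               call. = FALSE))
    record_from_list(x)
  })
  batch <- structure(list(batch_id = header$batch_id,
                          device_label = header$device_label,
                          created_at = header$created_at,
                          records = records, sealed = TRUE,
                          checksum = footer$md5),
                     class = "local_batch")
  actual <- batch_checksum(batch)
  if (!identical(actual, footer$md5)) {
    stop("batch checksum mismatch: file tampered or truncated", call. = FALSE)
  }
  batch
}

# ---- central store -----------------------------------------------------

#' Create an empty central store
#'
#' A single-file embedded document store behind a small interface:
#' records keyed by `record_uid`, plus an audit trail of conflict
#' resolutions. The store is an environment, so merges mutate it in
#' place, matching database semantics.
#'
#' @return An environment of class `central_store`.
#' @export
new_store <- function() {
  st <- new.env(parent = emptyenv())
  st$records <- list()
  st$audit <- list()
  class(st) <- "central_store"
  st
}

#' @export
print.central_store <- function(x, ...) {
  types <- vapply(x$records, function(r) r$record_type, character(1L))
  cat(sprintf("<central store> %d record(s)\n", length(x$records)))
  if (length(types) > 0L) print(table(types))
  invisible(x)
}

#' All records of one type as a list
#' @param store A `central_store`.
#' @param type Entity type filter; `NULL` for all.
#' @return List of `sync_record`s.
#' @export
store_records <- function(store, type = NULL) {
  recs <- store$records
  if (is.null(type)) return(recs)
  recs[vapply(recs, function(r) r$record_type == type, logical(1L))]
}

# Domain validation applied before insertion; quarantined records never
# reach the store.
validate_record <- function(record) {
  p <- record$payload
  if (record$record_type == "exam") {
    odo <- tryCatch({
      o <- data.frame(tooth = as.integer(unlist(p$odontogram$tooth)),
                      crown = as.character(unlist(p$odontogram$crown)),
                      treatment = as.character(unlist(p$odontogram$treatment)),
                      stringsAsFactors = FALSE)
      class(o) <- c("odontogram", "data.frame")
      o
    }, error = function(e) NULL)
    if (is.null(odo) || is.null(p$secret_code)) {
      rep <- data.frame(severity = "error", locus = "exam",
                        message = "missing secret_code or odontogram",
                        stringsAsFactors = FALSE)
      class(rep) <- c("validation_report", "data.frame")
      return(rep)
    }
    return(validate_exam(odo))
  }
  if (record$record_type == "student") {
    probs <- character()
    if (is.null(p$secret_code) || !nzchar(p$secret_code)) {
      probs <- c(probs, "student without secret_code")
    }
    if (is.null(p$birth_date) ||
        is.na(suppressWarnings(as.Date(p$birth_date)))) {
      probs <- c(probs, "student without parseable birth_date")
    }
    rep <- data.frame(severity = rep("error", length(probs)),
                      locus = rep("student", length(probs)),
                      message = probs, stringsAsFactors = FALSE)
    class(rep) <- c("validation_report", "data.frame")
    return(rep)
  }
  rep <- data.frame(severity = character(), locus = character(),
                    message = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Merge a sealed batch into the central store
#'
#' Each batch record lands in exactly one bucket: `inserted` (new uid),
#' `duplicates_skipped` (same uid, identical content), `conflicts` (same
#' uid, different content — resolved last-write-wins by capture timestamp,
#' with an audit entry either way), or `quarantined` (failed domain
#' validation; never inserted). Re-merging a batch is therefore a no-op,
#' and merge order does not matter for batches with disjoint uids.
#'
#' @param store A [new_store()] environment (mutated in place).
#' @param batch A sealed, checksum-valid `local_batch`.
#' @param validate Apply domain validation (default `TRUE`).
#' @return A list of class `merge_report`: counts `inserted`,
#'   `duplicates_skipped`, plus `conflicts` and `quarantined` detail
#'   data.frames.
#' @export
merge_batch <- function(store, batch, validate = TRUE) {
  stopifnot(inherits(store, "central_store"), inherits(batch, "local_batch"))
  if (!batch$sealed) stop("batch must be sealed before merging", call. = FALSE)
  if (!identical(batch_checksum(batch), batch$checksum)) {
    stop("batch checksum mismatch", call. = FALSE)
  }
  inserted <- 0L; dups <- 0L
  conflicts <- list(); quarantined <- list()
  for (r in batch$records) {
    if (validate) {
      vrep <- validate_record(r)
      if (has_errors(vrep)) {
        quarantined[[length(quarantined) + 1L]] <- data.frame(
          record_uid = r$record_uid,
          errors = paste(vrep$message[vrep$severity == "error"],
                         collapse = "; "),
          stringsAsFactors = FALSE)
        next
      }
    }
    uid <- r$record_uid
    central <- store$records[[uid]]
    if (is.null(central)) {
      store$records[[uid]] <- r
      inserted <- inserted + 1L
    } else if (identical(canonical_json(unclass(central)),
                         canonical_json(unclass(r)))) {
      dups <- dups + 1L
    } else {
      keep_batch <- r$created_at > central$created_at
      resolution <- if (keep_batch) "batch_version_kept" else "central_version_kept"
      if (keep_batch) store$records[[uid]] <- r
      entry <- data.frame(record_uid = uid,
                          central_created_at = central$created_at,
                          batch_created_at = r$created_at,
                          resolution = resolution, stringsAsFactors = FALSE)
      conflicts[[length(conflicts) + 1L]] <- entry
      store$audit[[length(store$audit) + 1L]] <-
        c(as.list(entry), batch_id = batch$batch_id)
    }
  }
  bind <- function(l, proto) if (length(l) > 0L) do.call(rbind, l) else proto
  structure(list(
    inserted = inserted, duplicates_skipped = dups,
    conflicts = bind(conflicts, data.frame(
      record_uid = character(), central_created_at = character(),
      batch_created_at = character(), resolution = character(),
      stringsAsFactors = FALSE)),
    quarantined = bind(quarantined, data.frame(
      record_uid = character(), errors = character(),
      stringsAsFactors = FALSE)),
    n_records = length(batch$records)),
    class = "merge_report")
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(paste0("<merge report> %d record(s): %d inserted, ",
                     "%d duplicate(s), %d conflict(s), %d quarantined\n"),
              x$n_records, x$inserted, x$duplicates_skipped,
              nrow(x$conflicts), nrow(x$quarantined)))
  invisible(x)
}

#' Persist / load the central store as a single JSON file
#'
#' @param store A `central_store`.
#' @param path File path.
#' @param codec Optional at-rest codec, as in [write_batch()].
#' @return `path` / the loaded store.
#' @export
write_store <- function(store, path, codec = identity_codec()) {
  payload <- canonical_json(list(
    kind = "central_store", schema_version = 1L,
    records = lapply(unname(store$records), unclass),
    audit = store$audit))
  writeBin(charToRaw(enc2utf8(codec$encode(payload))), path)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path, codec = identity_codec()) {
  raw <- rawToChar(readBin(path, "raw", file.size(path)))
  Encoding(raw) <- "UTF-8"
  x <- jsonlite::fromJSON(codec$decode(raw), simplifyVector = FALSE)
  if (!identical(x$kind, "central_store")) {
    stop("not a central store file", call. = FALSE)
  }
  st <- new_store()
  for (r in x$records) {
    rec <- record_from_list(r)
    st$records[[rec$record_uid]] <- rec
  }
  st$audit <- x$audit
  st
}

# ---- anonymized secret codes ------------------------------------------

#' Seedable generator of anonymized student codes
#'
#' Codes are short opaque tokens drawn from an unambiguous alphabet
#' (letters and digits, minus 0/O/1/I), carry no personal information by
#' construction, and are unique per generator (i.e. per campaign). The
#' generator owns an isolated RNG stream, so issuing codes neither
#' disturbs nor is disturbed by the caller's RNG, and a fixed seed
#' reproduces the full sequence.
#'
#' @param seed Integer seed.
#' @param nchar Code length (default 8; code space ~ 1.1e12).
#' @return An environment of class `code_generator`.
#' @export
secret_code_generator <- function(seed = 1L, nchar = 8L) {
  gen <- new.env(parent = emptyenv())
  gen$issued <- character()
  gen$nchar <- as.integer(nchar)
  gen$alphabet <- setdiff(c(LETTERS, 2:9), c("O", "I"))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  gen$rng_state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  class(gen) <- "code_generator"
  gen
}

#' @rdname secret_code_generator
#' @param gen A `code_generator`.
#' @return A single new unique code.
#' @export
issue_secret_code <- function(gen) {
  stopifnot(inherits(gen, "code_generator"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", gen$rng_state, envir = globalenv())
  on.exit({
    gen$rng_state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  limit <- 10000L
  for (i in seq_len(limit)) {
    code <- paste(sample(gen$alphabet, gen$nchar, replace = TRUE),
                  collapse = "")
    if (!(code %in% gen$issued)) {
      gen$issued <- c(gen$issued, code)
      return(code)
    }
  }
  stop("secret code space exhausted", call. = FALSE)
}
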