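make_exam_record <- function(code, findings = NULL, created_at = "2018-09-01T10:00:00") {
  odo <- normalize_odontogram(findings)
  new_record("exam",
             list(secret_code = code, date = "2018-09-01",
                  examiner_id = "E01",
                  odontogram = list(tooth = as.integer(odo$tooth),
                                    crown = odo$crown,
                                    treatment = odo$treatment)),
             record_uid = paste0("exam-", code), created_at = created_at)
}

test_that("batches open, append, seal and freeze", {
  b <- open_batch("tablet-1")
  for (i in 1:3) b <- append_record(b, make_exam_record(paste0("C", i)))
  expect_false(b$sealed)
  b <- seal_batch(b)
  expect_true(b$sealed)
  expect_length(b$records, 3L)
  expect_match(b$checksum, "^[0-9a-f]{32}$")
  b2 <- seal_batch(b)  # idempotent
  expect_identical(b2$checksum, b$checksum)
  expect_error(append_record(b, make_exam_record("C4")), "sealed")
})

test_that("batch files round-trip and detect tampering", {
  b <- seal_batch(Reduce(append_record, lapply(1:3, function(i)
    make_exam_record(paste0("C", i))), open_batch("tablet-1")))
  f <- tempfile(fileext = ".jsonl")
  write_batch(b, f)
  b2 <- read_batch(f)
  expect_identical(b2$checksum, b$checksum)
  expect_identical(length(b2$records), 3L)
  expect_identical(canonical_json(unclass(b2$records[[2]])),
                   canonical_json(unclass(b$records[[2]])))
  # flip one byte in a record line
  lines <- readLines(f)
  lines[2] <- sub("2018-09-01", "2018-09-02", lines[2])
  writeLines(lines, f)
  expect_error(read_batch(f), "checksum mismatch")
})

test_that("merge is idempotent and conserves every record", {
  st <- new_store()
  b <- seal_batch(Reduce(append_record, lapply(1:5, function(i)
    make_exam_record(paste0("C", i))), open_batch("tablet-1")))
  r1 <- merge_batch(st, b)
  expect_identical(r1$inserted, 5L)
  expect_identical(r1$duplicates_skipped, 0L)
  r2 <- merge_batch(st, b)
  expect_identical(r2$inserted, 0L)
  expect_identical(r2$duplicates_skipped, 5L)
  expect_length(store_records(st), 5L)
  for (r in list(r1, r2)) {
    expect_identical(r$inserted + r$duplicates_skipped +
                       nrow(r$conflicts) + nrow(r$quarantined), r$n_records)
  }
})

test_that("conflicting versions resolve last-write-wins in either order", {
  early <- make_exam_record("C1", created_at = "2018-09-01T10:00:00")
  late <- make_exam_record(
    "C1", findings = data.frame(tooth = 11, crown = "1", treatment = "0"),
    created_at = "2018-09-02T10:00:00")
  b_early <- seal_batch(append_record(open_batch("t1"), early))
  b_late <- seal_batch(append_record(open_batch("t2"), late))
  final_crown <- function(st)
    unlist(store_records(st, "exam")[[1]]$payload$odontogram$crown)[1]

  st1 <- new_store()
  merge_batch(st1, b_early)
  rep1 <- merge_batch(st1, b_late)
  expect_identical(nrow(rep1$conflicts), 1L)
  expect_identical(rep1$conflicts$resolution, "batch_version_kept")

  st2 <- new_store()
  merge_batch(st2, b_late)
  rep2 <- merge_batch(st2, b_early)
  expect_identical(rep2$conflicts$resolution, "central_version_kept")
  # both orders converge on the later version
  expect_identical(final_crown(st1), "1")
  expect_identical(final_crown(st2), "1")
  expect_length(st1$audit, 1L)
})

test_that("merge order does not matter for disjoint batches", {
  mk <- function(ids) seal_batch(Reduce(append_record,
    lapply(ids, make_exam_record), open_batch("t")))
  ba <- mk(c("A1", "A2")); bb <- mk(c("B1", "B2", "B3"))
  st1 <- new_store(); merge_batch(st1, ba); merge_batch(st1, bb)
  st2 <- new_store(); merge_batch(st2, bb); merge_batch(st2, ba)
  key <- function(st) sort(names(st$records))
  expect_identical(key(st1), key(st2))
  expect_identical(
    canonical_json(lapply(st1$records[key(st1)], unclass)),
    canonical_json(lapply(st2$records[key(st2)], unclass)))
})

test_that("invalid records are quarantined, never inserted", {
  bad <- new_record("exam",
                    list(secret_code = "C9", date = "2018-09-01",
                         odontogram = list(tooth = 11L, crown = "B",
                                           treatment = "0")),
                    record_uid = "exam-C9")
  b <- open_batch("t")
  for (i in 1:5) b <- append_record(b, make_exam_record(paste0("C", i)))
  b <- seal_batch(append_record(b, bad))
  st <- new_store()
  rep <- merge_batch(st, b)
  expect_identical(rep$inserted, 5L)
  expect_identical(nrow(rep$quarantined), 1L)
  expect_false("exam-C9" %in% names(st$records))
  # the store only ever holds valid records
  for (r in store_records(st)) expect_false(has_errors(validate_record(r)))
})

test_that("store files persist and reload", {
  st <- new_store()
  merge_batch(st, seal_batch(append_record(open_batch("t"),
                                           make_exam_record("C1"))))
  f <- tempfile(fileext = ".json")
  write_store(st, f)
  st2 <- read_store(f)
  expect_identical(sort(names(st2$records)), sort(names(st$records)))
})

test_that("secret codes are seeded, unique and opaque", {
  g1 <- secret_code_generator(seed = 123)
  g2 <- secret_code_generator(seed = 123)
  s1 <- vapply(1:50, function(i) issue_secret_code(g1), character(1))
  s2 <- vapply(1:50, function(i) issue_secret_code(g2), character(1))
  expect_identical(s1, s2)
  g3 <- secret_code_generator(seed = 9)
  many <- vapply(1:2000, function(i) issue_secret_code(g3), character(1))
  expect_identical(anyDuplicated(many), 0L)
  expect_true(all(nchar(many) == 8L))
  # issuing codes must not disturb the caller's RNG stream
  set.seed(55); a <- runif(3)
  set.seed(55); invisible(issue_secret_code(secret_code_generator(1)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("codecs must satisfy the round-trip law", {
  ident <- identity_codec()
  expect_identical(ident$decode(ident$encode("payload")), "payload")
  rev_codec <- make_codec(
    function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
    function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  expect_identical(rev_codec$decode(rev_codec$encode("abc{1}")), "abc{1}")
  expect_error(make_codec(function(x) substr(x, 1, 1), identity),
               "round-trip")
  # a reversing codec works end-to-end on batch files
  b <- seal_batch(append_record(open_batch("t"), make_exam_record("C1")))
  f <- tempfile()
  write_batch(b, f, codec = rev_codec)
  expect_identical(read_batch(f, codec = rev_codec)$checksum, b$checksum)
  expect_error(read_batch(f), "malformed|checksum")
})
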