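#' Examiner calibration against team consensus
#'
#' Before field work, every examiner repeats examinations on the same
#' subjects and their per-tooth ratings are compared with the rating the
#' team reaches by consensus. Agreement is measured by weighted Cohen's
#' kappa, computed per examiner (optionally stratified by age group and
#' condition); an examiner passes calibration when kappa reaches the
#' minimum acceptable limit, 0.65 in school-survey practice.
#'
#' @name calibration
NULL

#' Consensus rating per item from multiple examiners' votes
#'
#' Majority category per item; ties are broken toward the more severe
#' category under the supplied ordering (conservative screening: when the
#' team splits, the worse finding is retained). Severity order is the
#' position in `categories` (later = more severe).
#'
#' @param votes A list, one element per item, each a character vector of
#'   category votes.
#' @param categories Ordered category vector, least to most severe;
#'   defaults to the union of observed votes in sorted order.
#' @return Character vector of consensus categories, one per item.
#' @export
consensus_rating <- function(votes, categories = NULL) {
  if (!is.list(votes)) votes <- as.list(votes)
  if (any(lengths(votes) == 0L)) stop("item with no votes", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(unlist(votes)))
  unknown <- setdiff(unlist(votes), categories)
  if (length(unknown) > 0L) {
    stop("votes outside the category set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vapply(votes, function(v) {
    tab <- table(factor(v, levels = categories))
    top <- which(tab == max(tab))
    categories[max(top)]   # ties -> most severe among the tied
  }, character(1L))
}

#' Cross-tabulate paired ratings into an agreement table
#'
#' @param examiner,reference Equal-length rating vectors (examiner vs the
#'   consensus/reference rating of the same items).
#' @param categories Ordered category vector defining the table axes.
#' @return A K x K integer matrix of class `agreement_table`; entry (i, j)
#'   counts items rated `categories[i]` by the examiner and
#'   `categories[j]` by the reference.
#' @export
build_agreement_table <- function(examiner, reference, categories = NULL) {
  if (length(examiner) != length(reference)) {
    stop("rating vectors differ in length", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- sort(unique(c(examiner, reference)))
  }
  unknown <- setdiff(c(examiner, reference), categories)
  if (length(unknown) > 0L) {
    stop("ratings outside the category set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(examiner, levels = categories),
               factor(reference, levels = categories))
  m <- matrix(as.integer(tab), nrow = length(categories),
              dimnames = list(examiner = categories, reference = categories))
  structure(m, class = c("agreement_table", class(m)))
}

# Disagreement weight matrix for a K-category ordered scale.
kappa_weights <- function(k, scheme = c("linear", "quadratic", "unweighted")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), `-`))
  switch(scheme,
         linear = d / (k - 1),
         quadratic = (d / (k - 1))^2,
         unweighted = (d > 0) + 0)
}

#' Weighted Cohen's kappa from an agreement table
#'
#' Chance-corrected agreement on an ordered category scale:
#' `kappa = 1 - D_obs / D_exp`, where `D_obs = sum(w_ij * p_ij)` is the
#' weighted observed disagreement, `D_exp = sum(w_ij * p_i. * p_.j)` the
#' disagreement expected under marginal independence, and the
#' disagreement weights are `|i-j|/(K-1)` (linear), its square
#' (quadratic), or 0/1 (unweighted). A degenerate table with all mass in
#' one cell has `D_exp = 0`; agreement is then perfect by construction and
#' kappa is defined as 1 with a warning.
#'
#' @param table An [build_agreement_table()] result (or any K x K count
#'   matrix, K >= 2, with positive total).
#' @param scheme `"linear"` (default), `"quadratic"` or `"unweighted"`.
#' @return A list of class `kappa_result`: `kappa`,
#'   `observed_disagreement`, `expected_disagreement`, `scheme`,
#'   `n_items`.
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic",
                                             "unweighted")) {
  scheme <- match.arg(scheme)
  m <- unclass(table)
  storage.mode(m) <- "double"
  k <- nrow(m)
  if (k < 2L || ncol(m) != k) stop("need a square table, K >= 2", call. = FALSE)
  n <- sum(m)
  if (n <= 0) stop("empty agreement table", call. = FALSE)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  p <- m / n
  w <- kappa_weights(k, scheme)
  d_obs <- sum(w * p)
  d_exp <- sum(w * outer(rowSums(p), colSums(p)))
  if (d_exp == 0) {
    warning("degenerate table (all mass in one category); kappa = 1")
    kap <- 1
  } else {
    kap <- 1 - d_obs / d_exp
  }
  structure(list(kappa = kap, observed_disagreement = d_obs,
                 expected_disagreement = d_exp, scheme = scheme,
                 n_items = as.integer(n)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<weighted kappa (%s)> %.4f  (n = %d items)\n",
              x$scheme, x$kappa, x$n_items))
  invisible(x)
}

#' Apply the calibration acceptance gate
#'
#' Marks each (examiner, age group, condition) kappa as pass/fail against
#' the minimum acceptable limit; the boundary is inclusive (kappa equal to
#' the threshold passes).
#'
#' @param results data.frame with a `kappa` column and any identifying
#'   columns (`examiner`, `age_group`, `condition`, ...), or a list of
#'   `kappa_result` objects.
#' @param threshold Minimum acceptable kappa, in `[-1, 1]`; default 0.65.
#' @return data.frame of class `calibration_report`: the input columns
#'   plus `threshold` and logical `pass`.
#' @export
calibration_gate <- function(results, threshold = 0.65) {
  if (length(threshold) != 1L || threshold < -1 || threshold > 1) {
    stop("threshold must be a single value in [-1, 1]", call. = FALSE)
  }
  if (is.list(results) && !is.data.frame(results)) {
    results <- data.frame(
      kappa = vapply(results, function(r) r$kappa, numeric(1L)))
  }
  if (!"kappa" %in% names(results)) stop("results need a kappa column", call. = FALSE)
  out <- results
  out$threshold <- threshold
  out$pass <- out$kappa >= threshold
  class(out) <- c("calibration_report", "data.frame")
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration report> threshold %.2f: %d/%d pass\n",
              x$threshold[1L], sum(x$pass), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Calibrate examiners from a long ratings table
#'
#' Convenience wrapper over the consensus / agreement-table / kappa / gate
#' chain: given one rating per (item, examiner), computes the consensus
#' reference and one gated kappa per examiner.
#'
#' @param ratings data.frame with columns `item_id`, `examiner_id`,
#'   `category` (one rated tooth or condition per row).
#' @param categories Ordered category vector (severity order for the
#'   consensus tie-break and the weighting).
#' @param scheme Kappa weighting scheme, see [weighted_kappa()].
#' @param threshold Gate threshold, see [calibration_gate()].
#' @return A `calibration_report` with one row per examiner.
#' @export
calibrate_examiners <- function(ratings, categories = NULL,
                                scheme = "linear", threshold = 0.65) {
  stopifnot(all(c("item_id", "examiner_id", "category") %in% names(ratings)))
  items <- unique(ratings$item_id)
  votes <- split(ratings$category, factor(ratings$item_id, levels = items))
  if (is.null(categories)) categories <- sort(unique(ratings$category))
  ref <- consensus_rating(votes, categories)
  examiners <- unique(ratings$examiner_id)
  kap <- vapply(examiners, function(ex) {
    sub <- ratings[ratings$examiner_id == ex, , drop = FALSE]
    idx <- match(sub$item_id, items)
    tab <- build_agreement_table(sub$category, ref[idx], categories)
    weighted_kappa(tab, scheme)$kappa
  }, numeric(1L))
  calibration_gate(data.frame(examiner = examiners, kappa = kap,
                              stringsAsFactors = FALSE),
                   threshold = threshold)
}
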