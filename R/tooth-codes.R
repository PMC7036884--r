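#' Tooth numbering and odontogram code alphabets
#'
#' Teeth are labelled in FDI two-digit notation: the first digit is the
#' quadrant (1-4 permanent, 5-8 deciduous), the second the position within
#' the quadrant (1-8 permanent, 1-5 deciduous). The examined crown condition
#' and the treatment need are recorded as two complementary single-symbol
#' codes per tooth; the crown alphabet differs between dentitions (letters
#' for deciduous, digits for permanent) while the treatment alphabet is
#' shared.
#'
#' @name tooth-codes
NULL

.PERMANENT_TEETH <- as.integer(outer(1:8, c(10L, 20L, 30L, 40L), `+`))
.DECIDUOUS_TEETH <- as.integer(outer(1:5, c(50L, 60L, 70L, 80L), `+`))

.CROWN_PERMANENT <- c("0", "1", "2", "3", "4", "5", "6", "7", "8", "T", "9")
.CROWN_DECIDUOUS <- c("A", "B", "C", "D", "E", "F", "G", "H", "K", "T", "L")
.TREATMENT_CODES <- as.character(0:9)

#' Enumerate the tooth set of a dentition
#'
#' @param dentition `"permanent"` (32 teeth) or `"deciduous"` (20 teeth).
#' @return Integer vector of FDI tooth codes.
#' @examples
#' fdi_teeth("permanent")
#' fdi_teeth("deciduous")
#' @export
fdi_teeth <- function(dentition = c("permanent", "deciduous")) {
  dentition <- match.arg(dentition)
  if (dentition == "permanent") .PERMANENT_TEETH else .DECIDUOUS_TEETH
}

#' Classify a tooth code by dentition
#'
#' Deterministic classification by the FDI quadrant digit: quadrants 1-4 are
#' permanent, 5-8 deciduous. Vectorized.
#'
#' @param tooth Integer FDI tooth code(s).
#' @return Character vector, `"permanent"` or `"deciduous"`.
#' @examples
#' dentition_of(14) # permanent
#' dentition_of(55) # deciduous
#' @export
dentition_of <- function(tooth) {
  tooth <- as.integer(tooth)
  bad <- !(tooth %in% c(.PERMANENT_TEETH, .DECIDUOUS_TEETH))
  if (any(bad)) {
    stop("invalid FDI tooth code(s): ", paste(tooth[bad], collapse = ", "),
         call. = FALSE)
  }
  ifelse(tooth %in% .PERMANENT_TEETH, "permanent", "deciduous")
}

#' Crown-condition alphabet of a dentition
#'
#' The eleven crown states in their conventional severity-proxy order
#' (healthy first). Both alphabets share the trauma symbol `T`.
#'
#' @param dentition `"permanent"` or `"deciduous"`.
#' @return Character vector of the eleven valid crown symbols.
#' @export
crown_alphabet <- function(dentition = c("permanent", "deciduous")) {
  dentition <- match.arg(dentition)
  if (dentition == "permanent") .CROWN_PERMANENT else .CROWN_DECIDUOUS
}

#' Treatment-need alphabet
#'
#' Symbols `0`-`9`; `9` ("no information") is syntactically valid but is
#' flagged as a warning by [validate_exam()].
#'
#' @return Character vector of the ten valid treatment symbols.
#' @export
treatment_alphabet <- function() .TREATMENT_CODES

#' Healthy crown default for a dentition
#'
#' `"0"` for permanent teeth, `"A"` for deciduous teeth; used when
#' normalizing a partially recorded odontogram.
#'
#' @param dentition `"permanent"` or `"deciduous"` (vectorized).
#' @return Character vector of healthy crown symbols.
#' @export
healthy_crown <- function(dentition) {
  ifelse(dentition == "permanent", "0", "A")
}

# Canonicalize a user-supplied code symbol: trimmed, upper-cased character.
canon_code <- function(x) toupper(trimws(as.character(x)))

#' Validate crown codes against a tooth's dentition
#'
#' @param tooth Integer FDI tooth codes.
#' @param crown Crown symbols (case-insensitive).
#' @return Canonicalized crown symbols, invisibly validated; errors name the
#'   offending tooth and code.
#' @export
check_crown <- function(tooth, crown) {
  crown <- canon_code(crown)
  dent <- dentition_of(tooth)
  ok <- mapply(function(c, d) c %in% crown_alphabet(d), crown, dent)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop(sprintf("crown code '%s' is not valid for %s tooth %d",
                 crown[i], dent[i], as.integer(tooth)[i]), call. = FALSE)
  }
  crown
}

#' Validate treatment codes
#'
#' @param treatment Treatment symbols (case-insensitive).
#' @return Canonicalized treatment symbols.
#' @export
check_treatment <- function(treatment) {
  treatment <- canon_code(treatment)
  bad <- !(treatment %in% .TREATMENT_CODES)
  if (any(bad)) {
    stop("invalid treatment code(s): ",
         paste(unique(treatment[bad]), collapse = ", "), call. = FALSE)
  }
  treatment
}
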