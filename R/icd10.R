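# ICD-10 code handling: parsing/validation, display rendering, truncation.
#
# Codes are represented as plain character vectors in *normalized* form:
# uppercase alphanumeric, dot removed, 3-7 characters, first character a
# letter. The grammar is deliberately permissive (letter + alphanumerics)
# rather than the full ICD-10-CM character-class rules, so that placeholder
# letters such as the "X" in S06.2X9A validate.

#' Parse and validate ICD-10 codes
#'
#' Converts display strings such as `"I63.512"` into normalized form
#' (`"I63512"`): case folded to upper, the single optional dot (which must
#' follow the 3-character category) removed, the multiplication glyph
#' `×` -- seen in some typeset renderings of placeholder codes --
#' mapped to the placeholder letter `"X"`, and internal whitespace dropped.
#'
#' @param x Character vector of ICD-10 codes, with or without the dot.
#' @return Character vector of normalized codes (3-7 uppercase
#'   alphanumerics starting with a letter).
#' @examples
#' icd10_normalize(c("I63.512", "G08"))
#' @seealso [icd10_display()], [icd10_truncate()]
#' @export
icd10_normalize <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (!is.character(x)) stop("ICD-10 codes must be character strings")
  vapply(x, icd10_normalize1, character(1), USE.NAMES = FALSE)
}

icd10_normalize1 <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    stop("invalid ICD-10 code: empty input")
  }
  y <- toupper(gsub("×", "X", x))
  y <- gsub("[[:space:]]+", "", y)
  ndot <- lengths(regmatches(y, gregexpr(".", y, fixed = TRUE)))
  if (ndot > 1L) {
    stop(sprintf("invalid ICD-10 code '%s': more than one dot", x))
  }
  if (ndot == 1L && regexpr(".", y, fixed = TRUE) != 4L) {
    stop(sprintf(
      "invalid ICD-10 code '%s': dot must follow the 3-character category", x
    ))
  }
  y <- gsub(".", "", y, fixed = TRUE)
  if (nchar(y) < 3L || nchar(y) > 7L) {
    stop(sprintf(
      "invalid ICD-10 code '%s': length %d after dot removal (must be 3-7)",
      x, nchar(y)
    ))
  }
  if (!grepl("^[A-Z]", y)) {
    stop(sprintf("invalid ICD-10 code '%s': first character must be a letter", x))
  }
  if (!grepl("^[A-Z][A-Z0-9]+$", y)) {
    stop(sprintf(
      "invalid ICD-10 code '%s': characters after the first must be alphanumeric", x
    ))
  }
  y
}

#' Render normalized codes for display
#'
#' Re-inserts the conventional dot after the 3-character category for codes
#' longer than three characters; 3-character codes are returned unchanged.
#'
#' @param x Character vector of codes (normalized or display form).
#' @return Character vector of display strings, e.g. `"I63.512"`.
#' @export
icd10_display <- function(x) {
  y <- icd10_normalize(x)
  ifelse(nchar(y) > 3L, paste0(substr(y, 1L, 3L), ".", substr(y, 4L, 7L)), y)
}

#' Category (first three characters) of a code
#'
#' @param x Character vector of codes.
#' @return Character vector of 3-character category codes.
#' @export
icd10_category <- function(x) {
  substr(icd10_normalize(x), 1L, 3L)
}

#' Truncate codes to a comparison length
#'
#' Codes are compared in the validation framework at lengths 3 ("3L", the
#' category level), 4 ("4L"), and 7 ("7L", full length), always on the
#' dot-free normalized form. Codes shorter than `L` are returned unchanged.
#'
#' @param x Character vector of codes.
#' @param L Comparison length, one of 3, 4, or 7.
#' @return Character vector of truncated normalized codes.
#' @examples
#' icd10_truncate("S06.2X9A", 4) # "S062"
#' icd10_truncate("G08", 7)      # "G08"
#' @export
icd10_truncate <- function(x, L) {
  L <- check_length_l(L)
  y <- icd10_normalize(x)
  substr(y, 1L, pmin(L, nchar(y)))
}

check_length_l <- function(L) {
  if (length(L) != 1L || !is.numeric(L) || !(L %in% c(3, 4, 7))) {
    stop("comparison length L must be one of 3, 4, 7")
  }
  as.integer(L)
}

#' Distinct truncations of a code set
#'
#' Deduplicates the truncations of a set of codes at a comparison length;
#' used, e.g., to count the distinct category-level codes behind a list of
#' full-length unanimity codes.
#'
#' @inheritParams icd10_truncate
#' @param x Character vector of codes (may contain duplicates).
#' @return Sorted character vector of distinct truncated codes.
#' @export
distinct_truncations <- function(x, L) {
  if (length(x) == 0L) return(character(0))
  sort(unique(icd10_truncate(x, L)))
}
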