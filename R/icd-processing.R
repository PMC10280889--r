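# ICD-10 discharge-code preprocessing: lexical parsing, truncation to the
# 3-character category, capital-letter chapter grouping (A and B merged),
# Z-chapter exclusion, and surgical/medical roster classification.

# Lexical shape only (no catalogue lookup): one letter, two digits, then
# optionally up to two more alphanumerics or a dot plus detail characters.
ICD10_PATTERN <- "^[A-Z][0-9]{2}([0-9A-Z]{0,2}|\\.[0-9A-Z]{1,4})$"

#' Parse and normalize raw ICD-10 code strings
#'
#' Uppercases, strips surrounding whitespace, and checks the ICD-10 lexical
#' shape (letter + two digits, optional dot + detail characters). Only the
#' shape is checked, not membership in the official catalogue.
#'
#' @param raw Character vector of raw code strings.
#' @param strict If `TRUE` (default), any malformed code raises an error
#'   naming the offending string(s). If `FALSE`, malformed entries become
#'   `NA` with a warning, so the caller can drop them with a log — the
#'   behaviour registry extracts with occasional typos need.
#' @return Character vector of normalized codes (with `NA` for malformed
#'   entries when `strict = FALSE`).
#' @examples
#' parse_icd10(" i21.0 ")        # "I21.0"
#' parse_icd10("21I", strict = FALSE)  # NA with a warning
#' @export
parse_icd10 <- function(raw, strict = TRUE) {
  x <- toupper(trimws(as.character(raw)))
  bad <- is.na(x) | !grepl(ICD10_PATTERN, x)
  if (any(bad)) {
    offending <- unique(as.character(raw)[bad])
    msg <- sprintf("malformed ICD-10 code(s): %s",
                   paste(sprintf("'%s'", head(offending, 5L)), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(sprintf("%s (%d record(s) set to NA)", msg, sum(bad)), call. = FALSE)
    x[bad] <- NA_character_
  }
  x
}

#' Truncate an ICD-10 code to its 3-character category
#'
#' Drops the trailing detail characters (which encode sub-site or variant
#' information, e.g. where in the breast a tumour sits) and keeps the
#' letter + two-digit category, the level at which emergency diagnosis
#' mixes are analyzed. Idempotent.
#'
#' @param code Parsed ICD-10 code vector (see [parse_icd10()]).
#' @return 3-character category codes.
#' @examples
#' truncate_icd10(c("I21.0", "I21", "C50.1"))  # "I21" "I21" "C50"
#' @export
truncate_icd10 <- function(code) {
  substr(code, 1L, 3L)
}

#' Capital-letter chapter group of a diagnosis category
#'
#' Groups categories by the first letter of the code, except that A and B
#' (both infectious/parasitic disease) are merged into the single group
#' `"A/B"`. This is letter grouping, not the official ICD-10 chapter
#' ranges: C and D, for example, remain separate groups.
#'
#' @param category 3-character category codes.
#' @return Character vector of group labels (`"A/B"`, `"C"`, `"D"`, ...).
#' @examples
#' chapter_group(c("A09", "B15", "G40", "I63"))  # "A/B" "A/B" "G" "I"
#' @export
chapter_group <- function(category) {
  first <- substr(category, 1L, 1L)
  ifelse(first %in% c("A", "B"), "A/B", first)
}

#' Exclude Z-chapter (non-emergency) records
#'
#' Z-chapter codes ("factors influencing health status and contact with
#' health services") are by definition not emergencies and are removed
#' before any frequency analysis.
#'
#' @param records Admission `data.frame` with an `icd10_code` column.
#' @return A list with `records` (retained rows) and `excluded` (count of
#'   removed Z rows); retained + excluded always equals the input count.
#' @export
exclude_z <- function(records) {
  is_z <- substr(records$icd10_code, 1L, 1L) == "Z"
  list(records = records[!is_z, , drop = FALSE],
       excluded = sum(is_z))
}

#' Default surgical/medical roster mapping
#'
#' Reads a roster mapping YAML with a `chapters:` section (chapter-group
#' label to roster) and an optional `categories:` override section
#' (3-character category to roster). The default mapping shipped with the
#' package reflects a typical split in small/medium hospitals (injuries and
#' digestive surgery to the surgical team; cardiovascular, neurological,
#' respiratory, infectious and metabolic disease to the medical team);
#' local policies differ, so the file is meant to be edited.
#'
#' @param path YAML file path; default is the mapping shipped with the
#'   package.
#' @return A list with elements `chapters` and `categories` (named
#'   character vectors with values `"surgical"` or `"medical"`).
#' @export
read_roster_mapping <- function(path = system.file("extdata", "roster_mapping.yaml",
                                                   package = "emfreq")) {
  m <- yaml::read_yaml(path)
  chapters <- unlist(m$chapters %||% list())
  categories <- unlist(m$categories %||% list())
  ok <- c("surgical", "medical")
  if (length(chapters) && !all(chapters %in% ok))
    stop_config("roster mapping", "chapter values must be 'surgical' or 'medical'")
  if (length(categories) && !all(categories %in% ok))
    stop_config("roster mapping", "category values must be 'surgical' or 'medical'")
  list(chapters = chapters, categories = categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify diagnosis categories into duty-roster arms
#'
#' Category-level mapping entries override chapter-level entries; a category
#' with no entry at either level is labelled `"unassigned"` with a warning,
#' never silently dropped.
#'
#' @param category 3-character category codes.
#' @param mapping A mapping list as returned by [read_roster_mapping()].
#' @return Character vector with values `"surgical"`, `"medical"` or
#'   `"unassigned"`.
#' @examples
#' m <- list(chapters = c(S = "surgical", I = "medical"), categories = character(0))
#' classify_roster(c("S72", "I21"), m)
#' @export
classify_roster <- function(category, mapping = read_roster_mapping()) {
  grp <- chapter_group(category)
  out <- unname(mapping$chapters[grp])
  if (length(mapping$categories)) {
    hit <- category %in% names(mapping$categories)
    out[hit] <- unname(mapping$categories[category[hit]])
  }
  unassigned <- is.na(out)
  if (any(unassigned)) {
    out[unassigned] <- "unassigned"
    warning(sprintf("no roster mapping for %d categor%s (e.g. %s); labelled 'unassigned'",
                    sum(unassigned), if (sum(unassigned) == 1) "y" else "ies",
                    paste(head(unique(category[unassigned]), 3L), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Preprocess raw admission records
#'
#' Runs the full preprocessing chain: parse and normalize codes (dropping
#' malformed ones with a warning, or aborting in strict mode), truncate to
#' the 3-character category, attach the chapter group, exclude Z-chapter
#' records, and (optionally) attach roster labels.
#'
#' @param records Raw admission `data.frame` with columns `patient_id`,
#'   `icd10_code`, `year`.
#' @param roster_mapping Mapping list from [read_roster_mapping()], or
#'   `NULL` to skip roster classification.
#' @param strict If `TRUE`, malformed codes abort; if `FALSE` (default)
#'   they are dropped and counted.
#' @return A list with `records` (retained rows, with added `category`,
#'   `chapter_group` and possibly `roster` columns) and `counts`, a named
#'   vector with `input`, `malformed`, `z_excluded`, `retained`
#'   (`input = malformed + z_excluded + retained`, always).
#' @export
preprocess_records <- function(records, roster_mapping = NULL, strict = FALSE) {
  n_input <- nrow(records)
  parsed <- suppressWarnings(parse_icd10(records$icd10_code, strict = strict))
  keep <- !is.na(parsed)
  n_malformed <- sum(!keep)
  if (n_malformed > 0)
    message(sprintf("dropped %d record(s) with malformed ICD-10 codes", n_malformed))
  records <- records[keep, , drop = FALSE]
  records$icd10_code <- parsed[keep]
  records$category <- truncate_icd10(records$icd10_code)

  zres <- exclude_z(records)
  records <- zres$records
  records$chapter_group <- chapter_group(records$category)
  if (!is.null(roster_mapping))
    records$roster <- classify_roster(records$category, roster_mapping)
  rownames(records) <- NULL
  list(records = records,
       counts = c(input = n_input, malformed = n_malformed,
                  z_excluded = zres$excluded, retained = nrow(records)))
}
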