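#' @title Harmonization of drug names, MedDRA terms, and demographic units
#' @name harmonize
NULL

# case-fold + collapse internal runs of whitespace + trim
normalize_string <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Build a drug synonym map
#'
#' A dictionary mapper standing in for NLP-based drug-name standardization:
#' case- and whitespace-insensitive exact lookup from raw spellings to
#' canonical names.  Canonical names always map to themselves.
#'
#' @param raw character vector of raw spellings.
#' @param canonical character vector of canonical names, same length.
#' @return named character vector of class `drug_synonym_map` (names are
#'   normalized raw spellings).
#' @export
synonym_map <- function(raw, canonical) {
  stopifnot(length(raw) == length(canonical))
  canonical <- normalize_string(canonical)
  key <- normalize_string(raw)
  entries <- c(stats::setNames(canonical, key),
               stats::setNames(unique(canonical), unique(canonical)))
  conflict <- tapply(entries, names(entries), function(v) length(unique(v)) > 1)
  if (any(conflict)) {
    stop(sprintf("conflicting synonym entries for: %s",
                 paste(names(conflict)[conflict], collapse = ", ")))
  }
  entries <- entries[!duplicated(names(entries))]
  structure(entries, class = "drug_synonym_map")
}

#' Read a two-column TSV synonym map (raw, canonical)
#'
#' @param path TSV path; a header line `raw<TAB>canonical` is optional.
#' @return a `drug_synonym_map`.
#' @export
read_synonym_map <- function(path) {
  lines <- read_lines_fallback(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("synonym map '%s': line(s) %s do not have exactly 2 tab-separated fields",
                 path, paste(bad, collapse = ", ")))
  }
  mat <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  if (nrow(mat) > 0L && normalize_string(mat[1, 1]) == "raw") {
    mat <- mat[-1, , drop = FALSE]
  }
  synonym_map(mat[, 1], mat[, 2])
}

#' Standardize raw drug strings against a synonym map
#'
#' @param raw character vector of raw drug strings.
#' @param map a `drug_synonym_map`.
#' @return data.frame with columns `canonical` (unmatched inputs pass through
#'   in normalized form) and `matched` (logical).
#' @export
standardize_drug <- function(raw, map) {
  norm <- normalize_string(raw)
  hit <- unname(map[norm])
  matched <- !is.na(hit)
  data.frame(canonical = ifelse(matched, hit, norm),
             matched = matched,
             stringsAsFactors = FALSE)
}

#' Attach canonical drug names to the DRUG table
#'
#' @param data a `faers_data` object.
#' @param map a `drug_synonym_map`.
#' @return the `faers_data` with `drugname_canonical` and `drug_matched`
#'   columns added to its DRUG table.
#' @export
harmonize_drugs <- function(data, map) {
  std <- standardize_drug(data$drug$drugname, map)
  data$drug$drugname_canonical <- std$canonical
  data$drug$drug_matched <- std$matched
  data
}

#' Build a PT to SOC term map
#'
#' Every preferred term maps to exactly one system organ class (MedDRA
#' multi-axiality collapsed to a single primary SOC).
#'
#' @param pt character vector of preferred terms.
#' @param soc character vector of system organ classes, same length.
#' @return named character vector of class `pt_soc_map`.
#' @export
pt_soc_map <- function(pt, soc) {
  stopifnot(length(pt) == length(soc))
  key <- normalize_string(pt)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop(sprintf("duplicate PT entries in term map: %s",
                 paste(dup, collapse = ", ")))
  }
  structure(stats::setNames(normalize_string(soc), key), class = "pt_soc_map")
}

#' Read a two-column TSV PT to SOC map (pt, soc)
#'
#' @param path TSV path; a header line `pt<TAB>soc` is optional.
#' @return a `pt_soc_map`.
#' @export
read_pt_soc_map <- function(path) {
  lines <- read_lines_fallback(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("PT->SOC map '%s': line(s) %s do not have exactly 2 tab-separated fields",
                 path, paste(bad, collapse = ", ")))
  }
  mat <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  if (nrow(mat) > 0L && normalize_string(mat[1, 1]) == "pt") {
    mat <- mat[-1, , drop = FALSE]
  }
  pt_soc_map(mat[, 1], mat[, 2])
}

#' Map preferred terms to system organ classes
#'
#' @param pt character vector of preferred terms.
#' @param map a `pt_soc_map`.
#' @return character vector of SOC names; `NA` for unmapped PTs (excluded
#'   from SOC-level tabulation only, never dropped from PT-level analysis).
#' @export
map_pt_to_soc <- function(pt, map) {
  unname(map[normalize_string(pt)])
}

AGE_FACTORS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                 DY = 1 / 365.25, HR = 1 / 8766)

#' Convert reported age + unit code to years
#'
#' Conversion factors: DEC x10, YR x1, MON /12, WK /52.1775, DY /365.25,
#' HR /8766.  A missing unit code is treated as years and flagged; negative
#' or absurd (>120 y) results become `NA` and are flagged.
#'
#' @param age numeric vector of reported ages.
#' @param age_cod character vector of unit codes (DEC, YR, MON, WK, DY, HR).
#' @return data.frame with `years` (numeric, `NA` when undefined),
#'   `provenance` (the original code, `"YR*"` when the code was assumed) and
#'   `flagged` (logical).
#' @export
normalize_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  age_cod <- toupper(trimws(as.character(age_cod)))
  missing_cod <- is.na(age_cod) | age_cod == ""
  cod <- ifelse(missing_cod, "YR", age_cod)
  factor <- AGE_FACTORS[cod]
  years <- age * unname(factor)
  bad <- !is.na(years) & (years < 0 | years > 120)
  unknown_cod <- !missing_cod & !(cod %in% names(AGE_FACTORS))
  years[bad | unknown_cod] <- NA_real_
  data.frame(years = years,
             provenance = ifelse(missing_cod & !is.na(age), "YR*", age_cod),
             flagged = (missing_cod & !is.na(age)) | bad | unknown_cod,
             stringsAsFactors = FALSE)
}
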