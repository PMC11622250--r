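#' @title FAERS quarterly ASCII input/output
#' @description Readers and writers for the "$"-delimited FAERS quarterly
#'   dialect: one header line naming the fields (case-insensitive), "$" as the
#'   field delimiter, newline-terminated rows, no quoting.
#' @name faers_io
NULL

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")

# Columns that must be present for a table to be usable downstream.
MANDATORY_COLUMNS <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  rpsr = "primaryid",
  ther = c("primaryid", "dsg_drug_seq"),
  indi = "primaryid"
)

OUTC_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
ROLE_CODES <- c("PS", "SS", "C", "I")
AGE_CODES <- c("DEC", "YR", "MON", "WK", "DY", "HR")

# Read a text file as UTF-8; if any line fails UTF-8 validation, fall back to
# latin-1 for the whole file (real FAERS archives mix encodings).
read_lines_fallback <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (any(!validUTF8(raw))) {
    raw <- readLines(path, warn = FALSE, encoding = "latin1")
    raw <- iconv(raw, from = "latin1", to = "UTF-8")
  }
  raw
}

#' Read one FAERS-style "$"-delimited table
#'
#' Malformed rows (wrong field count, or an empty `primaryid`) are rejected
#' and counted, never fatal; a missing mandatory column is a hard error
#' naming the file and the column.  Field values are stripped of surrounding
#' whitespace and empty strings become `NA`.  Unknown columns are preserved.
#'
#' @param path path to the file.
#' @param table one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"rpsr"`,
#'   `"ther"`, `"indi"` (case-insensitive).
#' @return list with `records` (a data.frame of character columns, names
#'   lower-cased) and `report` (rows_read, rows_rejected, reject_reasons).
#' @export
read_faers_table <- function(path, table) {
  table <- match.arg(tolower(table), FAERS_TABLES)
  lines <- read_lines_fallback(path)
  if (length(lines) == 0L) {
    stop(sprintf("file '%s' is empty (no header line)", path))
  }
  header <- tolower(trimws(strsplit(lines[1L], "$", fixed = TRUE)[[1L]]))
  missing_cols <- setdiff(MANDATORY_COLUMNS[[table]], header)
  if (length(missing_cols) > 0L) {
    stop(sprintf("file '%s' (%s): missing mandatory column(s): %s",
                 path, toupper(table), paste(missing_cols, collapse = ", ")))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  nfield <- length(header)

  parts <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; restore it
  lens <- lengths(parts)
  trail <- endsWith(body, "$") & lens == nfield - 1L
  if (any(trail)) {
    parts[trail] <- lapply(parts[trail], function(p) c(p, ""))
    lens[trail] <- nfield
  }
  good <- lens == nfield

  reasons <- integer(0)
  if (any(!good)) {
    reasons <- c(reasons, stats::setNames(sum(!good), "wrong_field_count"))
  }

  if (any(good)) {
    mat <- matrix(unlist(parts[good], use.names = FALSE),
                  ncol = nfield, byrow = TRUE)
    mat <- trimws(mat)
    mat[mat == ""] <- NA_character_
    records <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(records) <- header
  } else {
    records <- as.data.frame(
      stats::setNames(rep(list(character(0)), nfield), header),
      stringsAsFactors = FALSE)
  }

  # rows with an empty primaryid are unusable
  bad_pid <- is.na(records$primaryid)
  if (any(bad_pid)) {
    reasons <- c(reasons, stats::setNames(sum(bad_pid), "empty_primaryid"))
    records <- records[!bad_pid, , drop = FALSE]
    rownames(records) <- NULL
  }

  list(records = records,
       report = list(rows_read = length(body),
                     rows_kept = nrow(records),
                     rows_rejected = length(body) - nrow(records),
                     reject_reasons = as.list(reasons)))
}

#' Read a set of FAERS quarterly files
#'
#' @param paths named character vector or list mapping table names (DEMO,
#'   DRUG, REAC, OUTC, RPSR, THER, INDI; case-insensitive) to file paths.
#'   Unknown table names are ignored with a warning.
#' @return A `faers_data` object: a list with one data.frame per table
#'   (missing tables are empty data.frames) and a `parse_report` attribute.
#' @export
read_quarter <- function(paths) {
  nm <- tolower(names(paths))
  unknown <- setdiff(nm, FAERS_TABLES)
  if (length(unknown) > 0L) {
    warning(sprintf("ignoring unknown table name(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  tables <- list()
  reports <- list()
  for (tab in FAERS_TABLES) {
    i <- match(tab, nm)
    if (is.na(i)) {
      tables[[tab]] <- empty_faers_table(tab)
    } else {
      res <- read_faers_table(paths[[i]], tab)
      tables[[tab]] <- res$records
      reports[[tab]] <- res$report
    }
  }
  faers_data(tables, parse_report = reports)
}

empty_faers_table <- function(table) {
  cols <- MANDATORY_COLUMNS[[table]]
  as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                stringsAsFactors = FALSE)
}

#' Construct a faers_data object from table data.frames
#'
#' @param tables named list with elements among demo, drug, reac, outc, rpsr,
#'   ther, indi.
#' @param parse_report optional list of per-table parse reports.
#' @return object of class `faers_data`.
#' @export
faers_data <- function(tables, parse_report = NULL) {
  out <- lapply(FAERS_TABLES, function(tab) {
    if (!is.null(tables[[tab]])) tables[[tab]] else empty_faers_table(tab)
  })
  names(out) <- FAERS_TABLES
  structure(out, class = "faers_data", parse_report = parse_report)
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data>\n")
  for (tab in FAERS_TABLES) {
    cat(sprintf("  %s: %d rows\n", toupper(tab), nrow(x[[tab]])))
  }
  invisible(x)
}

#' Write one table back to the "$"-delimited dialect
#'
#' `NA` values are written as empty fields, so a read/write/read cycle is an
#' identity on the typed records.
#'
#' @param records data.frame of character columns.
#' @param path output path.
#' @export
write_faers_table <- function(records, path) {
  header <- paste(names(records), collapse = "$")
  if (nrow(records) > 0L) {
    mat <- as.matrix(records)
    mat[is.na(mat)] <- ""
    rows <- do.call(paste, c(as.data.frame(mat, stringsAsFactors = FALSE),
                             list(sep = "$")))
  } else {
    rows <- character(0)
  }
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Deduplicate case versions by CASEID and FDA_DT
#'
#' FAERS distributes successive versions of one case (same `caseid`) across
#' quarters; only the most recent version should be analyzed.  Within each
#' `caseid` group the record with the latest `fda_dt` is kept.  Ties on
#' `fda_dt` keep the lexicographically greatest `primaryid` (FAERS primaryids
#' embed the case version, so this is version-monotone).  An unparseable
#' `fda_dt` sorts before any parseable date and is never preferred.
#'
#' @param demo data.frame with columns `primaryid`, `caseid`, `fda_dt`.
#' @return list with `kept` (data.frame, canonically ordered by caseid),
#'   `removed_count`, and `report` (raw, kept, removed, and the number of
#'   records with unparseable fda_dt inside duplicate groups).
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  n <- nrow(demo)
  if (n == 0L) {
    return(list(kept = demo, removed_count = 0L,
                report = list(raw = 0L, kept = 0L, removed = 0L,
                              unparseable_fda_dt_in_groups = 0L)))
  }
  key <- partial_date_key(demo$fda_dt)
  ord <- order(demo$caseid, key, demo$primaryid, method = "radix")
  cid_sorted <- demo$caseid[ord]
  keep_last <- !duplicated(cid_sorted, fromLast = TRUE)
  kept_idx <- ord[keep_last]
  kept <- demo[kept_idx, , drop = FALSE]
  rownames(kept) <- NULL

  dup_cids <- unique(cid_sorted[duplicated(cid_sorted)])
  n_unparse <- sum(!is.finite(key) & demo$caseid %in% dup_cids)
  if (n_unparse > 0L) {
    warning(sprintf("%d record(s) in duplicate groups have unparseable fda_dt",
                    n_unparse))
  }
  list(kept = kept,
       removed_count = n - nrow(kept),
       report = list(raw = n, kept = nrow(kept), removed = n - nrow(kept),
                     unparseable_fda_dt_in_groups = n_unparse))
}

#' Deduplicate a full faers_data object
#'
#' Applies [deduplicate_cases()] to the DEMO table and restricts every other
#' table to the surviving `primaryid`s.
#'
#' @param data a `faers_data` object.
#' @return list with `data` (deduplicated `faers_data`) and `report`.
#' @export
dedupe_faers <- function(data) {
  res <- deduplicate_cases(data$demo)
  keep_ids <- res$kept$primaryid
  tables <- list(demo = res$kept)
  for (tab in setdiff(FAERS_TABLES, "demo")) {
    tbl <- data[[tab]]
    tables[[tab]] <- tbl[tbl$primaryid %in% keep_ids, , drop = FALSE]
    rownames(tables[[tab]]) <- NULL
  }
  list(data = faers_data(tables), report = res$report)
}

#' Restrict a dataset to reports with a given primary-suspect drug
#'
#' Keeps exactly the cases containing at least one DRUG entry with
#' `role_cod == "PS"` whose harmonized name equals `drug`.  Row order within
#' each table is preserved.
#'
#' @param data a `faers_data` object whose DRUG table carries a
#'   `drugname_canonical` column (see [harmonize_drugs()]); falls back to
#'   `drugname` if absent.
#' @param drug canonical drug name.
#' @return `faers_data` restricted to the matching reports.
#' @export
filter_primary_suspect <- function(data, drug) {
  d <- data$drug
  namecol <- if ("drugname_canonical" %in% names(d)) "drugname_canonical" else "drugname"
  hit <- !is.na(d$role_cod) & d$role_cod == "PS" &
    !is.na(d[[namecol]]) & d[[namecol]] == drug
  ids <- unique(d$primaryid[hit])
  if (length(ids) == 0L) {
    warning(sprintf("no primary-suspect reports found for drug '%s'", drug))
  }
  tables <- lapply(unclass(data), function(tbl) {
    out <- tbl[tbl$primaryid %in% ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  faers_data(tables)
}
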