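# In-code fixtures shared across test files.

# Write a "$"-delimited table to a temp file and return the path.
write_dollar <- function(lines, name = "TABLE.txt") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# A hand-written ten-report dataset: four reports with lorazepam as PS,
# one with lorazepam only as concomitant, five with other PS drugs.
tiny_cases <- function() {
  demo <- data.frame(
    primaryid = paste0("P", 1:10),
    caseid = paste0("C", 1:10),
    fda_dt = sprintf("2019%02d15", 1:10),
    event_dt = c("20190110", "20190205", "201903", "20190405", "20190505",
                 "20190605", "20190705", "20190805", "20190905", "20191005"),
    sex = c("F", "F", "F", "F", "F", "F", "M", "M", "M", ""),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("P1", "P2", "P3", "P4", "P5", "P5", "P6", "P7", "P8", "P9", "P10"),
    drug_seq = c("1", "1", "1", "1", "1", "2", "1", "1", "1", "1", "1"),
    role_cod = c("PS", "PS", "PS", "PS", "PS", "C", "PS", "PS", "PS", "PS", "PS"),
    drugname = c("lorazepam", "lorazepam", "lorazepam", "lorazepam",
                 "ibuprofen", "lorazepam", "ibuprofen", "ibuprofen",
                 "metformin", "metformin", "metformin"),
    route = "ORAL",
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("P1", "P1", "P2", "P3", "P4", "P5", "P5", "P6", "P7",
                  "P8", "P9", "P10", "P10"),
    pt = c("sopor", "nausea", "sopor", "headache", "nausea", "sopor",
           "nausea", "headache", "sopor", "nausea", "headache", "sopor",
           "headache"),
    stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = c("P1", "P1", "P2"),
                     outc_cod = c("HO", "DE", "HO"),
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = paste0("P", 1:10),
                     dsg_drug_seq = "1",
                     start_dt = c("20190101", "20190101", "201901", "20190301",
                                  "20190401", "20190501", "20190601",
                                  "20190701", "20190801", "20190901"),
                     end_dt = NA_character_,
                     stringsAsFactors = FALSE)
  faers_data(list(demo = demo, drug = drug, reac = reac, outc = outc,
                  ther = ther))
}

# Independent nested-loop fourfold count over raw records -- the brute-force
# oracle for build_table.  Deliberately naive: iterates report by report.
oracle_table <- function(data, drug, event, soc_map = NULL) {
  namecol <- if ("drugname_canonical" %in% names(data$drug))
    "drugname_canonical" else "drugname"
  a <- b <- c_ <- d <- 0L
  norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  for (pid in unique(data$demo$primaryid)) {
    drows <- data$drug[data$drug$primaryid == pid, , drop = FALSE]
    is_target <- any(drows$role_cod == "PS" & !is.na(drows[[namecol]]) &
                       drows[[namecol]] == drug)
    evs <- norm(data$reac$pt[data$reac$primaryid == pid])
    evs <- evs[!is.na(evs) & nzchar(evs)]
    if (!is.null(soc_map)) {
      evs <- map_pt_to_soc(evs, soc_map)
      evs <- evs[!is.na(evs)]
    }
    evs <- unique(evs)
    for (ev in evs) {
      hit <- ev == norm(event)
      if (is_target && hit) a <- a + 1L
      else if (is_target) b <- b + 1L
      else if (hit) c_ <- c_ + 1L
      else d <- d + 1L
    }
  }
  c(a = a, b = b, c = c_, d = d)
}

# Random strictly-positive 2x2 tables for property tests.
random_tables <- function(n, max_cell = 500) {
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE),
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(max_cell, n, replace = TRUE))
}

# Small simulation config used by several suites.
small_config <- function(seed = 1, n = 400, ...) {
  sim_config(seed = seed, n_reports = n, ...)
}
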