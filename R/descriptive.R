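#' @title Descriptive profile of a drug's spontaneous reports
#' @name descriptive
NULL

#' Time to onset for each report
#'
#' Days from the earliest complete therapy start date of the target drug's
#' primary-suspect entries to the report's event date.  Undefined (`NA`) when
#' either date is partial or absent, or when the difference is negative;
#' negative differences are counted separately.
#'
#' @param data a deduplicated, PS-filtered `faers_data` object with canonical
#'   drug names.
#' @param drug canonical drug name.
#' @return data.frame with `primaryid`, `days` (numeric, `NA` when
#'   undefined) and a `n_negative` attribute.
#' @export
time_to_onset <- function(data, drug) {
  demo <- data$demo
  d <- data$drug
  namecol <- if ("drugname_canonical" %in% names(d)) "drugname_canonical" else "drugname"
  ps <- d[!is.na(d$role_cod) & d$role_cod == "PS" &
            !is.na(d[[namecol]]) & d[[namecol]] == drug, , drop = FALSE]

  ther <- data$ther
  if (nrow(ps) == 0L || nrow(ther) == 0L ||
      !all(c("drug_seq") %in% names(ps)) ||
      !all(c("dsg_drug_seq", "start_dt") %in% names(ther))) {
    return(structure(data.frame(primaryid = demo$primaryid,
                                days = rep(NA_real_, nrow(demo)),
                                stringsAsFactors = FALSE),
                     n_negative = 0L))
  }
  ther <- merge(ther, ps[, c("primaryid", "drug_seq")],
                by.x = c("primaryid", "dsg_drug_seq"),
                by.y = c("primaryid", "drug_seq"))
  ther$start_days <- partial_date_days(ther$start_dt)
  ther <- ther[!is.na(ther$start_days), , drop = FALSE]
  first_start <- if (nrow(ther) > 0L) {
    stats::aggregate(start_days ~ primaryid, data = ther, FUN = min)
  } else {
    data.frame(primaryid = character(0), start_days = numeric(0))
  }

  event_days <- partial_date_days(demo$event_dt)
  idx <- match(demo$primaryid, first_start$primaryid)
  days <- event_days - first_start$start_days[idx]
  n_negative <- sum(!is.na(days) & days < 0)
  days[!is.na(days) & days < 0] <- NA_real_
  structure(data.frame(primaryid = demo$primaryid, days = days,
                       stringsAsFactors = FALSE),
            n_negative = n_negative)
}

count_block <- function(x, n_reports, unknown_label = "unknown") {
  x <- as.character(x)
  x[is.na(x) | !nzchar(trimws(x))] <- unknown_label
  tab <- table(x)
  if (length(tab) == 0L) {
    return(data.frame(category = character(0), count = integer(0),
                      share = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- tab[order(-as.integer(tab), names(tab), method = "radix")]
  data.frame(category = names(tab), count = as.integer(tab),
             share = as.integer(tab) / max(n_reports, 1L),
             stringsAsFactors = FALSE)
}

#' Descriptive profile of the target drug's reports
#'
#' Computes nine tabulations over deduplicated, PS-filtered cases: report
#' year, reporter country, sex, age bins, reporter occupation, outcomes,
#' indications, administration routes and time-to-onset bins.  Single-valued
#' blocks (year, country, sex, age, occupation) count reports; multi-valued
#' blocks (outcomes, indications, routes) count code occurrences, with one
#' contribution per distinct code per report.  Shares in every block use the
#' number of reports as denominator.  Unknown/missing values form their own
#' category, never silently dropped.
#'
#' @param data a deduplicated, PS-filtered `faers_data` object.
#' @param drug canonical drug name (used for route and onset, which are read
#'   off the target drug's PS entries).
#' @param age_breaks bin edges in years (default decades 0 to 120).
#' @param onset_breaks upper edges of the onset-day bins, in days (default
#'   30, 60, 80, 180, 360, Inf, so the cumulative share at 80 days is
#'   directly readable).
#' @return list of class `faers_profile`, one data.frame per block, plus
#'   `n_reports`.
#' @export
descriptive_profile <- function(data, drug,
                                age_breaks = seq(0, 120, by = 10),
                                onset_breaks = c(30, 60, 80, 180, 360, Inf)) {
  demo <- data$demo
  n <- nrow(demo)

  year <- substr(ifelse(is.na(demo$fda_dt), "", demo$fda_dt), 1, 4)
  year[nchar(year) < 4 | !grepl("^[0-9]{4}$", year)] <- NA
  annual <- count_block(year, n)

  country <- count_block(if ("reporter_country" %in% names(demo))
    demo$reporter_country else rep(NA, n), n)

  sexv <- if ("sex" %in% names(demo)) toupper(demo$sex) else rep(NA, n)
  sexv[!sexv %in% c("F", "M")] <- NA
  sex <- count_block(sexv, n, unknown_label = "UNK")

  agey <- if (all(c("age", "age_cod") %in% names(demo))) {
    normalize_age(demo$age, demo$age_cod)$years
  } else rep(NA_real_, n)
  age_bin <- cut(agey, breaks = age_breaks, right = FALSE,
                 include.lowest = TRUE)
  age <- count_block(as.character(age_bin), n)

  occupation <- count_block(if ("occp_cod" %in% names(demo))
    toupper(demo$occp_cod) else rep(NA, n), n)

  outc <- unique(data$outc[, c("primaryid", "outc_cod")])
  outcomes <- count_block(toupper(outc$outc_cod), n)

  indi <- data$indi
  indication <- if ("indi_pt" %in% names(indi) && nrow(indi) > 0L) {
    count_block(normalize_string(indi$indi_pt), n)
  } else count_block(character(0), n)

  dtab <- data$drug
  namecol <- if ("drugname_canonical" %in% names(dtab)) "drugname_canonical" else "drugname"
  ps <- dtab[!is.na(dtab$role_cod) & dtab$role_cod == "PS" &
               !is.na(dtab[[namecol]]) & dtab[[namecol]] == drug, , drop = FALSE]
  route <- if ("route" %in% names(ps)) {
    rt <- unique(ps[, c("primaryid", "route")])
    count_block(normalize_string(rt$route), n)
  } else count_block(character(0), n)

  tto <- time_to_onset(data, drug)
  defined <- tto$days[!is.na(tto$days)]
  edges <- c(-0.5, onset_breaks)
  labels <- {
    lo <- c(0, utils::head(onset_breaks, -1) + 1)
    hi <- onset_breaks
    ifelse(is.infinite(hi), sprintf(">%.0f", lo - 1), sprintf("%.0f-%.0f", lo, hi))
  }
  bin <- cut(defined, breaks = edges, labels = labels, right = TRUE)
  cnt <- as.integer(table(bin))
  onset <- data.frame(bin = labels, count = cnt,
                      share = if (length(defined) > 0) cnt / length(defined) else 0,
                      cumulative_share = if (length(defined) > 0)
                        cumsum(cnt) / length(defined) else 0,
                      stringsAsFactors = FALSE)
  onset <- rbind(onset,
                 data.frame(bin = "undefined", count = n - length(defined),
                            share = NA_real_, cumulative_share = NA_real_))

  structure(list(n_reports = n, annual_counts = annual,
                 country_counts = country, sex_counts = sex, age_bins = age,
                 occupation_counts = occupation, outcome_counts = outcomes,
                 indication_top = indication, route_top = route,
                 onset_bins = onset,
                 n_onset_defined = length(defined),
                 n_onset_negative = attr(tto, "n_negative")),
            class = "faers_profile")
}

#' @export
print.faers_profile <- function(x, ...) {
  cat(sprintf("<faers_profile> %d reports\n", x$n_reports))
  cat("blocks:", paste(setdiff(names(x),
                               c("n_reports", "n_onset_defined",
                                 "n_onset_negative")), collapse = ", "), "\n")
  invisible(x)
}
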