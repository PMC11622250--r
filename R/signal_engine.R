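#' @title Disproportionality statistics on drug-event fourfold tables
#'
#' @description The counting unit throughout is the unique (deduplicated
#'   report, event) pair: a preferred term repeated inside one report counts
#'   once, and `N` is the total pair count over the database at the chosen
#'   level.  For one drug-event pair the fourfold table is
#'   \preformatted{
#'                  target event   other events
#'     target drug       a              b
#'     other drugs       c              d
#'   }
#'   Four statistics are computed, each with its conventional positivity
#'   threshold:
#'   \itemize{
#'     \item ROR = ad/bc, 95\% CI = exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d));
#'       positive when a >= 3 and the CI lower limit > 1.
#'     \item PRR = (a/(a+b)) / (c/(c+d)) with the uncorrected Pearson
#'       chi-squared (a+b+c+d)(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)); positive
#'       when PRR >= 2, chi2 >= 4 (the df = 1 critical value at p < 0.05 is
#'       3.84) and a >= 3.
#'     \item IC = log2(aN / ((a+b)(a+c))), the information component;
#'       IC025 = IC - 2 SE_IC with SE_IC = sqrt(1/a+1/b+1/c+1/d)/ln 2 (the
#'       delta-method transfer of the log-scale SE to base 2); positive when
#'       IC025 > 0.
#'     \item EBGM = aN / ((a+c)(a+b)), the observed-to-expected relative
#'       reporting ratio (identically 2^IC), with
#'       95\% CI = exp(ln EBGM +/- 1.96 sqrt(1/a+1/b+1/c+1/d)); positive when
#'       EBGM05 > 2.
#'   }
#'   These are the unshrunk relative-reporting quantities; no gamma-Poisson
#'   (MGPS) shrinkage and no Bayesian posterior IC is applied.
#' @name signal_engine
NULL

#' Construct a fourfold (2x2) drug-event table
#'
#' @param a,b,c,d non-negative integer cell counts: a = target-drug pairs
#'   with the event, b = target-drug pairs without it, c = other-drug pairs
#'   with it, d = the remainder.
#' @param event_name,drug_name optional labels.
#' @param level `"pt"` or `"soc"`.
#' @return list of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, event_name = NA_character_,
                       drug_name = NA_character_, level = c("pt", "soc")) {
  level <- match.arg(level)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("empty dataset: a+b+c+d must be > 0")
  structure(list(a = a, b = b, c = c, d = d, event_name = event_name,
                 drug_name = drug_name, level = level),
            class = "two_by_two")
}

#' All four disproportionality statistics, vectorized over tables
#'
#' Zero-cell policy: the `a >= 3` screen removes `a = 0` rows from analyses;
#' for a row where `b`, `c` or `d` is 0 (and `a > 0`), 0.5 is added to all
#' four cells of that row only (Haldane-Anscombe) and `zero_cell_corrected`
#' is set, keeping the intervals finite.  With `correct_zero = FALSE`, rows
#' with any zero cell get `NA` statistics and a reason code.
#'
#' @param a,b,c,d numeric vectors of cell counts (recycled to equal length).
#' @param correct_zero apply the 0.5 continuity correction (default TRUE).
#' @return data.frame with columns a, b, c, d, n_reported, ror, ror_low,
#'   ror_high, prr, prr_low, prr_high, chi2, ic, ic025, ebgm, ebgm05, ebgm95,
#'   zero_cell_corrected, undefined_reason.
#' @export
signal_stats <- function(a, b, c, d, correct_zero = TRUE) {
  k <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), k); b <- rep_len(as.numeric(b), k)
  c <- rep_len(as.numeric(c), k); d <- rep_len(as.numeric(d), k)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("negative cell count")

  out <- data.frame(a = a, b = b, c = c, d = d, n_reported = a)
  zero_a <- a == 0
  zero_other <- !zero_a & (b == 0 | c == 0 | d == 0)

  undefined <- rep(NA_character_, k)
  undefined[zero_a] <- "zero_a"
  corrected <- rep(FALSE, k)

  aa <- a; bb <- b; cc <- c; dd <- d
  if (correct_zero) {
    corrected <- zero_other
    aa[corrected] <- a[corrected] + 0.5
    bb[corrected] <- b[corrected] + 0.5
    cc[corrected] <- c[corrected] + 0.5
    dd[corrected] <- d[corrected] + 0.5
  } else {
    undefined[zero_other] <- "zero_cell_uncorrected"
  }
  ok <- is.na(undefined)

  N <- aa + bb + cc + dd
  se_log <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)

  ror <- (aa * dd) / (bb * cc)
  ror_low <- exp(log(ror) - 1.96 * se_log)
  ror_high <- exp(log(ror) + 1.96 * se_log)

  prr <- (aa / (aa + bb)) / (cc / (cc + dd))
  se_prr <- sqrt(1 / aa - 1 / (aa + bb) + 1 / cc - 1 / (cc + dd))
  prr_low <- exp(log(prr) - 1.96 * se_prr)
  prr_high <- exp(log(prr) + 1.96 * se_prr)

  chi2 <- (aa * dd - bb * cc)^2 * N /
    ((aa + bb) * (cc + dd) * (aa + cc) * (bb + dd))

  ebgm <- aa * N / ((aa + cc) * (aa + bb))
  ic <- log2(ebgm)
  se_ic <- se_log / log(2)
  ic025 <- ic - 2 * se_ic
  ebgm05 <- exp(log(ebgm) - 1.96 * se_log)
  ebgm95 <- exp(log(ebgm) + 1.96 * se_log)

  blank <- function(x) { x[!ok] <- NA_real_; x }
  out$ror <- blank(ror); out$ror_low <- blank(ror_low); out$ror_high <- blank(ror_high)
  out$prr <- blank(prr); out$prr_low <- blank(prr_low); out$prr_high <- blank(prr_high)
  out$chi2 <- blank(chi2)
  out$ic <- blank(ic); out$ic025 <- blank(ic025)
  out$ebgm <- blank(ebgm); out$ebgm05 <- blank(ebgm05); out$ebgm95 <- blank(ebgm95)
  out$zero_cell_corrected <- corrected
  out$undefined_reason <- undefined
  out
}

stats_for <- function(t, correct_zero = TRUE) {
  stopifnot(inherits(t, "two_by_two"))
  signal_stats(t$a, t$b, t$c, t$d, correct_zero = correct_zero)
}

#' Reporting odds ratio with 95\% CI
#' @param t a `two_by_two`.
#' @param correct_zero apply the 0.5 zero-cell correction.
#' @return one-row data.frame with ror, ror_low, ror_high.
#' @export
compute_ror <- function(t, correct_zero = TRUE) {
  stats_for(t, correct_zero)[, c("ror", "ror_low", "ror_high")]
}

#' Proportional reporting ratio with 95\% CI and Pearson chi-squared
#' @inheritParams compute_ror
#' @return one-row data.frame with prr, prr_low, prr_high, chi2.
#' @export
compute_prr_chi2 <- function(t, correct_zero = TRUE) {
  stats_for(t, correct_zero)[, c("prr", "prr_low", "prr_high", "chi2")]
}

#' Information component (BCPNN) with IC025
#' @inheritParams compute_ror
#' @return one-row data.frame with ic, ic025.
#' @export
compute_ic <- function(t, correct_zero = TRUE) {
  stats_for(t, correct_zero)[, c("ic", "ic025")]
}

#' Empirical Bayes geometric mean with 90\% interval bounds
#' @inheritParams compute_ror
#' @return one-row data.frame with ebgm, ebgm05, ebgm95.
#' @export
compute_ebgm <- function(t, correct_zero = TRUE) {
  stats_for(t, correct_zero)[, c("ebgm", "ebgm05", "ebgm95")]
}

#' Apply the four positivity rules and their conjunction
#'
#' ROR: a >= 3 and ror_low > 1.  PRR: PRR >= 2, chi2 >= 4 and a >= 3.
#' BCPNN: IC025 > 0.  EBGM: EBGM05 > 2.  Every flag is false whenever
#' a < `min_cases` (default 3, the reported-frequency screen), and all flags
#' are false for rows with undefined statistics.
#'
#' @param stats data.frame from [signal_stats()].
#' @param min_cases minimum reported case count (default 3).
#' @return data.frame with logical columns ror_positive, prr_positive,
#'   bcpnn_positive, ebgm_positive, all_four.
#' @export
classify_signal <- function(stats, min_cases = 3) {
  ok <- is.na(stats$undefined_reason) & stats$n_reported >= min_cases
  fl <- function(x) ok & !is.na(x) & x
  out <- data.frame(
    ror_positive = fl(stats$ror_low > 1),
    prr_positive = fl(stats$prr >= 2 & stats$chi2 >= 4),
    bcpnn_positive = fl(stats$ic025 > 0),
    ebgm_positive = fl(stats$ebgm05 > 2)
  )
  out$all_four <- out$ror_positive & out$prr_positive &
    out$bcpnn_positive & out$ebgm_positive
  out
}

#' Build the unique report-event pair table
#'
#' One pair per distinct (report, event) at the chosen level; at SOC level
#' the PTs are first collapsed through the term map (one pair per report per
#' SOC; unmapped PTs are counted and excluded from SOC tabulation only).
#'
#' @param data a deduplicated `faers_data` object with canonical drug names
#'   (see [harmonize_drugs()]).
#' @param level `"pt"` or `"soc"`.
#' @param soc_map a `pt_soc_map`, required for `level = "soc"`.
#' @return object of class `faers_pairs`: list with `pairs` (data.frame
#'   primaryid, event), `ps` (data.frame primaryid, drug: the PS drug
#'   assignments), `level`, `n_unmapped_pt`.
#' @export
pair_table <- function(data, level = c("pt", "soc"), soc_map = NULL) {
  level <- match.arg(level)
  reac <- data$reac
  event <- normalize_string(reac$pt)
  keep <- !is.na(event) & nzchar(event)
  pid <- reac$primaryid[keep]
  event <- event[keep]
  n_unmapped <- 0L
  if (level == "soc") {
    if (is.null(soc_map)) stop("soc_map is required at SOC level")
    soc <- map_pt_to_soc(event, soc_map)
    n_unmapped <- sum(is.na(soc))
    pid <- pid[!is.na(soc)]
    event <- soc[!is.na(soc)]
  }
  pairs <- unique(data.frame(primaryid = pid, event = event,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL

  d <- data$drug
  namecol <- if ("drugname_canonical" %in% names(d)) "drugname_canonical" else "drugname"
  is_ps <- !is.na(d$role_cod) & d$role_cod == "PS" & !is.na(d[[namecol]])
  ps <- unique(data.frame(primaryid = d$primaryid[is_ps],
                          drug = d[[namecol]][is_ps],
                          stringsAsFactors = FALSE))
  rownames(ps) <- NULL
  structure(list(pairs = pairs, ps = ps, level = level,
                 n_unmapped_pt = n_unmapped),
            class = "faers_pairs")
}

#' Build the fourfold table for one drug-event pair
#'
#' @param pairs a `faers_pairs` object.
#' @param drug canonical drug name.
#' @param event event name (PT or SOC, matching the pair table's level).
#' @return a `two_by_two`.
#' @export
build_table <- function(pairs, drug, event) {
  stopifnot(inherits(pairs, "faers_pairs"))
  p <- pairs$pairs
  if (nrow(p) == 0L) stop("empty dataset")
  target_ids <- unique(pairs$ps$primaryid[pairs$ps$drug == drug])
  is_t <- p$primaryid %in% target_ids
  is_e <- p$event == normalize_string(event)
  two_by_two(a = sum(is_t & is_e), b = sum(is_t & !is_e),
             c = sum(!is_t & is_e), d = sum(!is_t & !is_e),
             event_name = event, drug_name = drug, level = pairs$level)
}

#' Screen preferred terms by reported frequency
#'
#' @param pairs a `faers_pairs` object.
#' @param drug canonical drug name.
#' @param min_count minimum target-drug pair count (default 3).
#' @return data.frame (event, a) with `a >= min_count`, descending in a,
#'   ties broken by event name.
#' @export
screen_pts <- function(pairs, drug, min_count = 3) {
  counts <- event_margins(pairs, drug)
  keep <- counts$a >= min_count
  out <- counts[keep, c("event", "a"), drop = FALSE]
  out <- out[order(-out$a, out$event, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-event a and c margins for one target drug, plus totals.
event_margins <- function(pairs, drug) {
  p <- pairs$pairs
  target_ids <- unique(pairs$ps$primaryid[pairs$ps$drug == drug])
  is_t <- p$primaryid %in% target_ids
  events <- sort(unique(p$event), method = "radix")
  a <- as.integer(table(factor(p$event[is_t], levels = events)))
  tot <- as.integer(table(factor(p$event, levels = events)))
  df <- data.frame(event = events, a = a, c = tot - a,
                   stringsAsFactors = FALSE)
  attr(df, "target_total") <- sum(is_t)
  attr(df, "N") <- nrow(p)
  df
}

#' Full signal table for one drug at one level
#'
#' Builds every per-event fourfold table from the margins (b = target total
#' minus a, d = remainder), applies the frequency screen, computes the four
#' statistics and the positivity decisions.
#'
#' @param pairs a `faers_pairs` object.
#' @param drug canonical drug name.
#' @param min_cases reported-frequency screen (default 3).
#' @param correct_zero zero-cell policy, see [signal_stats()].
#' @return data.frame with event, a..d, all statistics, the four positivity
#'   flags and `all_four`; one row per screened event.
#' @export
signal_table <- function(pairs, drug, min_cases = 3, correct_zero = TRUE) {
  m <- event_margins(pairs, drug)
  A <- attr(m, "target_total")
  N <- attr(m, "N")
  if (N == 0L) stop("empty dataset")
  m <- m[m$a >= min_cases, , drop = FALSE]
  b <- A - m$a
  d <- N - m$a - b - m$c
  st <- signal_stats(m$a, b, m$c, d, correct_zero = correct_zero)
  dec <- classify_signal(st, min_cases = min_cases)
  out <- cbind(data.frame(event = m$event, stringsAsFactors = FALSE), st, dec)
  out <- out[order(-out$a, out$event, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank a signal table by case count or by EBGM
#'
#' Stable descending sort with ties broken by event name ascending; an
#' optional minimum-case filter (strict: `a > min_cases`) supports "case
#' count above a cut" style tables.
#'
#' @param results data.frame from [signal_table()].
#' @param by `"case_count"` or `"ebgm"`.
#' @param top_k optional row limit applied after sorting.
#' @param min_cases optional strict minimum on `a` (rows with `a > min_cases`
#'   are kept).
#' @return the reordered (and possibly truncated) data.frame.
#' @export
rank_results <- function(results, by = c("case_count", "ebgm"), top_k = NULL,
                         min_cases = NULL) {
  by <- match.arg(by)
  if (!is.null(min_cases)) {
    results <- results[results$a > min_cases, , drop = FALSE]
  }
  key <- if (by == "case_count") results$a else results$ebgm
  ord <- order(-key, results$event, method = "radix")
  out <- results[ord, , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Write a signal table as TSV at fixed precision
#'
#' @param results data.frame from [signal_table()].
#' @param path output path.
#' @param digits decimal places for the statistics (default 2, matching the
#'   conventional presentation of disproportionality tables).
#' @export
write_signal_table <- function(results, path, digits = 2) {
  num <- vapply(results, is.numeric, logical(1)) &
    !(names(results) %in% c("a", "b", "c", "d", "n_reported"))
  results[num] <- lapply(results[num], function(x) round(x, digits))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
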