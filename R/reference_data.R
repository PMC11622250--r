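#' Published reference values for the lorazepam FAERS analysis
#'
#' A subset of signal rows (reported cases, ROR, PRR, IC, EBGM with interval
#' bounds) and the report-count totals from a published large-scale
#' disproportionality analysis of lorazepam in FAERS (2004 Q1 to 2023 Q3).
#' These are used as worked examples: in particular, the printed IC and EBGM
#' of each row must satisfy EBGM = 2^IC at table precision, since both
#' statistics are transformations of the same observed-to-expected ratio.
#'
#' @return list with `totals` (raw_reports, duplicate_reports,
#'   retained_reports, ps_reports, pt_pairs, all_four_signals) and `signals`
#'   (data.frame of published rows).
#' @export
published_reference <- function() {
  path <- system.file("extdata", "lorazepam_published_signals.tsv",
                      package = "faersignal")
  signals <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(
    totals = list(raw_reports = 20750364, duplicate_reports = 3367326,
                  retained_reports = 17383038, ps_reports = 174145,
                  pt_pairs = 931661, all_four_signals = 552),
    signals = signals
  )
}

#' Retained-report bookkeeping identity
#'
#' @param raw total report count before deduplication.
#' @param removed number of duplicate reports removed.
#' @return `raw - removed`; errors if the result would be negative.
#' @export
dedup_retained <- function(raw, removed) {
  if (removed > raw) stop("removed count exceeds raw count")
  raw - removed
}
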