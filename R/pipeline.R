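#' @title End-to-end signal-detection pipeline
#' @name pipeline
NULL

#' Synonym map implied by a simulation config
#'
#' @param config a `sim_config`.
#' @return a `drug_synonym_map` covering every spelling the generator emits.
#' @export
sim_synonym_map <- function(config) {
  sp <- config$drug_vocab$spellings
  synonym_map(c(sp$spelling, config$drug_vocab$drugs$canonical),
              c(sp$canonical, config$drug_vocab$drugs$canonical))
}

#' PT to SOC map implied by a simulation config
#'
#' @param config a `sim_config`.
#' @return a `pt_soc_map` over the generator's vocabulary.
#' @export
sim_pt_soc_map <- function(config) {
  pt_soc_map(config$pt_vocab$pt, config$pt_vocab$soc)
}

#' Run the full pipeline: ingest, dedup, harmonize, screen, signal, describe
#'
#' Stages: (1) ingest a directory of quarterly files or generate a synthetic
#' dataset in memory; (2) deduplicate case versions by CASEID/FDA_DT;
#' (3) harmonize drug names; (4) restrict to primary-suspect reports of the
#' target drug for the descriptive profile; (5) build PT- and SOC-level pair
#' tables over the full deduplicated database, screen PTs at the minimum
#' reported frequency, and compute all four disproportionality statistics
#' with positivity decisions; (6) rank results by case count (with an
#' optional strict minimum) and by EBGM (top k); (7) tabulate the
#' descriptive profile.  A manifest records the seed and every stage's row
#' counts.
#'
#' @param input a `sim_config` (generate on the fly) or a directory path of
#'   quarterly FAERS-style files.
#' @param target_drug canonical drug name (default "lorazepam").
#' @param synonym_map a `drug_synonym_map`; defaults to the generator's map
#'   when `input` is a `sim_config`.
#' @param soc_map a `pt_soc_map`; same default.
#' @param min_pt_frequency reported-frequency screen (default 3).
#' @param rank_min_cases strict case-count cut for the by-cases ranking
#'   (default 300).
#' @param rank_top_k row limit for the by-EBGM ranking (default 30).
#' @param out_dir optional directory for TSV/JSON outputs.
#' @param digits table precision for written TSVs (default 2).
#' @return list of class `faers_run`: manifest, dedup_report, signal_pt,
#'   signal_soc, ranked_by_cases, ranked_by_ebgm, profile, screened_pts.
#' @export
run_pipeline <- function(input, target_drug = "lorazepam",
                         synonym_map = NULL, soc_map = NULL,
                         min_pt_frequency = 3, rank_min_cases = 300,
                         rank_top_k = 30, out_dir = NULL, digits = 2) {
  stopifnot(min_pt_frequency >= 1)
  if (inherits(input, "sim_config")) {
    sim <- generate_faers(input)
    raw <- sim$tables
    if (is.null(synonym_map)) synonym_map <- sim_synonym_map(input)
    if (is.null(soc_map)) soc_map <- sim_pt_soc_map(input)
    seed <- input$seed
  } else if (is.character(input) && dir.exists(input)) {
    raw <- read_faers_dir(input)
    seed <- NA_integer_
  } else {
    stop("input must be a sim_config or an existing directory")
  }
  if (is.null(synonym_map) || is.null(soc_map)) {
    stop("synonym_map and soc_map are required when reading from files")
  }

  dd <- dedupe_faers(raw)
  data <- harmonize_drugs(dd$data, synonym_map)
  std <- standardize_drug(target_drug, synonym_map)
  target <- std$canonical

  ps_data <- suppressWarnings(filter_primary_suspect(data, target))
  n_ps <- nrow(ps_data$demo)

  pairs_pt <- pair_table(data, level = "pt")
  pairs_soc <- pair_table(data, level = "soc", soc_map = soc_map)

  screened <- screen_pts(pairs_pt, target, min_count = min_pt_frequency)
  sig_pt <- signal_table(pairs_pt, target, min_cases = min_pt_frequency)
  sig_pt$soc <- map_pt_to_soc(sig_pt$event, soc_map)
  sig_soc <- signal_table(pairs_soc, target, min_cases = min_pt_frequency)

  ranked_cases <- rank_results(sig_pt, by = "case_count",
                               min_cases = rank_min_cases)
  ranked_ebgm <- rank_results(sig_pt[sig_pt$all_four, , drop = FALSE],
                              by = "ebgm", top_k = rank_top_k)

  profile <- descriptive_profile(ps_data, target)

  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = seed,
    target_drug = target,
    raw_reports = dd$report$raw,
    duplicates_removed = dd$report$removed,
    kept_reports = dd$report$kept,
    ps_reports = n_ps,
    pt_pairs = nrow(pairs_pt$pairs),
    soc_pairs = nrow(pairs_soc$pairs),
    target_pt_pairs = attr(event_margins(pairs_pt, target), "target_total"),
    screened_pts = nrow(screened),
    all_four_signals = sum(sig_pt$all_four),
    min_pt_frequency = min_pt_frequency
  )

  run <- structure(list(manifest = manifest, dedup_report = dd$report,
                        screened_pts = screened, signal_pt = sig_pt,
                        signal_soc = sig_soc,
                        ranked_by_cases = ranked_cases,
                        ranked_by_ebgm = ranked_ebgm, profile = profile),
                   class = "faers_run")
  if (!is.null(out_dir)) write_run(run, out_dir, digits = digits)
  run
}

#' @export
print.faers_run <- function(x, ...) {
  m <- x$manifest
  cat("<faers_run>\n")
  cat(sprintf("  raw %d -> kept %d (removed %d duplicates)\n",
              m$raw_reports, m$kept_reports, m$duplicates_removed))
  cat(sprintf("  %s PS reports: %d; PT pairs: %d; screened PTs: %d; all-four signals: %d\n",
              m$target_drug, m$ps_reports, m$pt_pairs, m$screened_pts,
              m$all_four_signals))
  invisible(x)
}

write_run <- function(run, out_dir, digits = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_table(run$signal_pt, file.path(out_dir, "signal_pt.tsv"), digits)
  write_signal_table(run$signal_soc, file.path(out_dir, "signal_soc.tsv"), digits)
  write_signal_table(run$ranked_by_cases,
                     file.path(out_dir, "ranked_by_cases.tsv"), digits)
  write_signal_table(run$ranked_by_ebgm,
                     file.path(out_dir, "ranked_by_ebgm.tsv"), digits)
  for (block in c("annual_counts", "country_counts", "sex_counts", "age_bins",
                  "occupation_counts", "outcome_counts", "indication_top",
                  "route_top", "onset_bins")) {
    utils::write.table(run$profile[[block]],
                       file.path(out_dir, paste0("profile_", block, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(run$dedup_report, file.path(out_dir, "dedup_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
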