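# Descriptive profile of the target drug's primary-suspect reports:
# report year, country, sex, age, reporter occupation, outcomes,
# indications, routes and time to onset.

source("analysis/00_config.R")

cfg <- study_config()
raw <- if (dir.exists(RAW_DIR)) read_faers_dir(RAW_DIR) else
  generate_faers(cfg)$tables
data <- harmonize_drugs(dedupe_faers(raw)$data, sim_synonym_map(cfg))
ps <- filter_primary_suspect(data, TARGET_DRUG)
cat(sprintf("%d deduplicated %s primary-suspect reports\n",
            nrow(ps$demo), TARGET_DRUG))

prof <- descriptive_profile(ps, TARGET_DRUG)

cat("\nsex distribution:\n"); print(prof$sex_counts)
cat("\ntop countries:\n"); print(head(prof$country_counts, 5))
cat("\noutcome counts (occurrences, shares of reports):\n")
print(prof$outcome_counts)
i80 <- which(prof$onset_bins$bin == "61-80")
cat(sprintf("\ncumulative share of defined onsets within 80 days: %.3f (%d defined)\n",
            prof$onset_bins$cumulative_share[i80], prof$n_onset_defined))

dir.create(file.path(OUT_DIR, "descriptive"), showWarnings = FALSE)
for (block in c("annual_counts", "country_counts", "sex_counts", "age_bins",
                "occupation_counts", "outcome_counts", "indication_top",
                "route_top", "onset_bins")) {
  write.table(prof[[block]],
              file.path(OUT_DIR, "descriptive", paste0(block, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
cat(sprintf("\nwrote nine blocks to %s/descriptive/\n", OUT_DIR))
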