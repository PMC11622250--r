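# Shared study configuration for the analysis scripts.
#
# One synthetic study emulating a lorazepam pharmacovigilance extraction:
# 20,000 reports over eight quarters, a 5% case-version duplication rate,
# and one planted safety signal -- lorazepam x sopor at a reporting-rate
# multiplier of 5.

library(faersignal)

STUDY_SEED <- 20260922L
N_REPORTS <- 20000L
TARGET_DRUG <- "lorazepam"
PLANTED <- data.frame(drug = "lorazepam", pt = "sopor", rho = 5)

study_config <- function(signal = PLANTED) {
  sim_config(seed = STUDY_SEED, n_reports = N_REPORTS, signal_spec = signal)
}

RAW_DIR <- "scratch/synthetic_faers"   # bulky ASCII quarters
OUT_DIR <- "results"                   # small summary tables
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)
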