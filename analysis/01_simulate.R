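# Generate the synthetic FAERS-style study data.
#
# Writes eight quarters of "$"-delimited DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI
# files plus the generator's ground-truth ledger, and prints what was
# planted so later scripts can be judged against it.

source("analysis/00_config.R")

cfg <- study_config()
sim <- generate_faers(cfg, dir = RAW_DIR)

cat(sprintf("wrote %d quarterly files to %s\n", length(sim$files), RAW_DIR))
cat(sprintf("reports: %d distinct cases, %d emitted as two versions\n",
            sim$truth$n_reports, sim$truth$n_duplicates))
cat("planted signal(s):\n")
print(sim$truth$planted)

et <- expected_table(cfg, PLANTED$drug, PLANTED$pt)
N <- et$a + et$b + et$c + et$d
cat(sprintf("closed-form expectation for %s x %s: a = %.1f, EBGM = %.2f\n",
            PLANTED$drug, PLANTED$pt, et$a,
            et$a * N / ((et$a + et$c) * (et$a + et$b))))

expected <- sim$truth$expected
num <- vapply(expected, is.numeric, logical(1))
expected[num] <- lapply(expected[num], round, 2)
write.table(expected, file.path(OUT_DIR, "truth_expected.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$realized, file.path(OUT_DIR, "truth_realized.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("truth ledger written to %s/truth_*.tsv\n", OUT_DIR))
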