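---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-reporting databases such as the FDA Adverse Event Reporting
System (FAERS) collect unsolicited reports of suspected adverse drug
events.  Because there is no denominator of exposed patients, safety
signals are sought by *disproportionality*: a drug–event pair is suspicious
when the pair is reported more often than the drug's overall reporting
volume and the event's overall reporting volume would predict under
independence.  `faersignal` implements that workflow end to end for the
FAERS quarterly ASCII distribution: ingestion, case-version deduplication,
drug-name and MedDRA harmonization, contingency-table construction at the
preferred-term (PT) and system-organ-class (SOC) levels, four
disproportionality statistics with positivity thresholds, and the
descriptive profile of a target drug's reports.  A synthetic-FAERS
generator with closed-form expected tables makes the whole chain testable
without the multi-gigabyte FAERS download or the licensed MedDRA
dictionary.

## Data model and deduplication

FAERS quarters are "$"-delimited text tables (DEMO, DRUG, REAC, OUTC, RPSR,
THER, INDI) keyed by `primaryid`, with `caseid` identifying the underlying
case across successive versions.  The reader accepts a header line naming
the fields, rejects malformed rows (wrong field count, empty `primaryid`)
with counted reasons rather than failing, treats empty fields as missing,
and falls back to latin-1 per file when UTF-8 validation fails, since real
FAERS archives mix encodings.

Only the most recent version of each case should be analyzed.
`deduplicate_cases()` keeps, within each `caseid` group, the record with
the latest `fda_dt`.  Two in-group rules had to be fixed by design because
the convention only specifies the CASEID/FDA_DT key:

* **ties on `fda_dt`** keep the lexicographically greatest `primaryid` —
  FAERS primaryids embed the case-version number, so this is
  version-monotone and deterministic under any input ordering;
* **unparseable `fda_dt`** sorts before every parseable date and is never
  preferred: records with auditable dates win.

The bookkeeping identity `retained = raw − removed` is asserted on every
run.

## Harmonization

Raw drug strings are mapped to canonical names by a case- and
whitespace-insensitive dictionary (a two-column TSV); unmatched strings
pass through in normalized form with a flag, and the lookup is idempotent.
This deliberately replaces NLP-based name normalization with a curated
dictionary: for pipeline purposes only the raw-spelling → ingredient map
matters, and a dictionary is auditable.  No fuzzy matching is attempted.

PTs map to exactly one SOC through a user-supplied TSV; MedDRA's
multi-axiality is collapsed to a single primary SOC because the tabulations
being reproduced are single-SOC.  Unmapped PTs are counted and excluded
from SOC-level tabulation only — they remain in PT-level analyses.  Ages
convert to years with fixed factors (DEC ×10, YR ×1, MON /12, WK /52.1775,
DY /365.25, HR /8766; the week/day constants are calendar-exact, and the
differences are immaterial at decade-bin resolution); ages above 120 years
are flagged and treated as missing.

## The fourfold table and the counting unit

The counting unit is the unique **(deduplicated report, event) pair**: a PT
repeated inside one report counts once, and `N` is the total pair count in
the database at the chosen level.  For target drug and target event,

|             | target event | other events |
|-------------|--------------|--------------|
| target drug | a            | b            |
| other drugs | c            | d            |

where "target drug" means the report lists the drug as primary suspect
(PS).  The pair convention (rather than counting reports) was adopted
because published pair totals exceed report totals by a factor of ~5.3 per
report; it is isolated inside `pair_table()`/`build_table()` so it could be
switched.  At SOC level the same machinery runs on PT→SOC-collapsed pairs
(one pair per report per SOC).

## The four statistics

With `N = a+b+c+d` and the shared log-scale standard error
`s = sqrt(1/a + 1/b + 1/c + 1/d)`:

* **ROR** `= ad/bc`, 95% CI `= exp(ln ROR ± 1.96 s)`.  Positive:
  `a ≥ 3` and lower CI limit `> 1`.
* **PRR** `= [a/(a+b)] / [c/(c+d)]` with the uncorrected Pearson
  chi-squared `χ² = (ad−bc)² N / [(a+b)(c+d)(a+c)(b+d)]`.  Positive:
  `PRR ≥ 2`, `χ² ≥ 4`, `a ≥ 3`.  The `χ² ≥ 4` cut operationalizes
  `p < 0.05` (the df = 1 critical value is 3.84).  The PRR interval is the
  standard log-scale one, `exp(ln PRR ± 1.96 sqrt(1/a − 1/(a+b) + 1/c −
  1/(c+d)))`.
* **IC** `= log2( aN / ((a+b)(a+c)) )`, the BCPNN information component,
  with `IC025 = IC − 2·SE_IC` and `SE_IC = s / ln 2`.  Positive:
  `IC025 > 0` (strict).  The `±2×SE` form with the delta-method transfer of
  the log-scale SE to base 2 was chosen because the convention in published
  tables prints `±2√V(IC)` without defining `V`; this choice reproduces the
  shipped reference rows' IC025 to two decimals for the headline row, but
  is not guaranteed to match every published second decimal.
* **EBGM** `= aN / ((a+c)(a+b))`, with 95% CI `= exp(ln EBGM ± 1.96 s)`.
  Positive: `EBGM05 > 2`.

Note the identity `EBGM = 2^IC`: both are the observed-to-expected relative
reporting ratio.  The package asserts it to 1e−12 relative error, and uses
it to check published rows (the printed EBGM must equal `2^printed-IC` at
table precision).  These are the **unshrunk** quantities — no gamma-Poisson
(MGPS) shrinkage, no Bayesian posterior IC, and no multiple-testing
adjustment.  An algebraic consequence that makes a useful invariant:
`sign(ad − bc)` determines the whole ordering — `ROR > PRR > EBGM > 1` when
`ad > bc`, all equal to 1 (with `IC = 0`, `χ² = 0`) at independence, and
reversed when `ad < bc`.

### Numerical policies

* **Frequency screen**: only events with `a ≥ 3` for the target drug enter
  the signal table, and every positivity flag is false below the screen.
* **Zero cells**: `a = 0` rows never survive the screen; when `b`, `c` or
  `d` is 0, 0.5 is added to all four cells of that table only
  (Haldane–Anscombe) and the row is flagged `zero_cell_corrected`, keeping
  the intervals finite.  With the correction disabled such rows return `NA`
  with a reason code.
* **Thresholds** are applied exactly as stated (`≥ 3`, `> 1`, `≥ 2`, `≥ 4`,
  `> 0`, `> 2`): `IC025 = 0` is *not* positive.
* **Ranking** sorts descending with ties broken by event name ascending;
  the by-case-count view supports a strict minimum (`a > cut`), the
  by-EBGM view a top-k limit.

## The synthetic-FAERS generator

`generate_faers()` emits a full quarterly file set from a report-level
model:

* each report receives exactly one PS drug; per-drug counts are exact
  largest-remainder quotas of the configured shares, shuffled across
  reports.  Quota allocation rather than iid sampling removes one layer of
  Monte-Carlo noise from calibration experiments while leaving the
  per-report assignment exchangeable;
* each PT `j` fires independently with probability `min(1, ρ_Dj · p_j)`,
  where `p_j` is the baseline occurrence probability and `ρ_Dj` the planted
  multiplier for the report's PS drug (1 everywhere under the null);
  reports with no PT are redrawn, so the per-report PT count is
  Poisson-binomial with mean `Σp = 5.3`, truncated at one;
* a configurable fraction of caseids is emitted as two versions with
  distinct `fda_dt` (the later version is the ground-truth keeper), drug
  names are written in mixed synonym spellings, a fraction of event and
  therapy dates is truncated to year-month or year, and therapy start
  precedes the event date by an exponential lag (mean 40 days by default,
  making the 80-day onset share tunable);
* generation is a pure function of the config (including its seed) and
  leaves the caller's RNG state untouched.

Because draws are independent Bernoulli, the expected fourfold table of
every (drug, PT) pair has a closed form, including the at-least-one-PT
conditioning (each probability rescales by `1/(1 − P0_D)` with
`P0_D = Π(1−q)`): `expected_table()` is an exact oracle, and the
generator's realized emission ledger must agree with the pipeline's pair
counts exactly, row for row.

### Default study conditions

The defaults describe one fixed synthetic study, chosen once by design and
not tuned: a 60-PT vocabulary over 15 SOCs with baseline probabilities in
six tiers (0.25, 0.12, 0.08, 0.06, 0.045, 0.013) summing to 5.30 — the
pair-to-report ratio of large published extractions; twelve drugs with the
target benzodiazepine at a 1.5% PS share (the order of lorazepam's observed
share); a 5% case-duplication rate; a 10% partial-date rate.  Recovery
experiments plant (lorazepam, sopor) at `ρ = 5` on a baseline of 0.08.
Under those conditions the closed-form expected EBGM of the planted pair is
4.45, not 5: the planted pair inflates the event's own margin (the
"contaminated comparator"), a bias intrinsic to disproportionality
statistics that the oracle quantifies exactly.  A power calculation at
these settings gives the planted `a` an expectation near 300 at 50,000
reports, so the estimated EBGM falls within ±25% of 5 with high
probability per replicate.

Problem sizes used by the validation suite, chosen as the smallest that
make each property sharp: 10,000 random tables for the algebraic
identities; 50 datasets of ≤ 200 reports for brute-force oracle agreement;
one 50,000-report null run for false-positive calibration (binomial bound
`0.05 + 3·SE`); twenty 50,000-report replicates for planted-signal
recovery.

## What the synthetic data does and does not show

The generator reproduces the *structural* features the pipeline must
handle: multi-table case structure, case-version duplicates, role codes,
synonym spelling noise, multi-PT reports, partial dates, and planted
rate multipliers with known expectations.  It does not attempt real
co-prescription correlation structure, free-text drug noise beyond the
listed spellings, event-event dependence within a report, or reporting
trends over time.  Passing tests therefore demonstrate correctness of the
machinery and calibration under the model — not that any particular real
drug–event association is true, which additionally depends on reporting
biases no disproportionality statistic can remove.

## Known limitations

* Statistics are unshrunk; for very small `a` the EBGM here is far more
  variable than shrinkage-based MGPS values published elsewhere.
* The IC interval is a delta-method approximation, not the BCPNN
  posterior; second-decimal disagreement with some published IC025 values
  is expected.
* Deduplication implements the CASEID/FDA_DT rule only — no probabilistic
  record linkage across caseids.
* Percentages in the descriptive profile use all reports as denominator,
  including unknowns, and multi-valued blocks (outcomes, routes,
  indications) count occurrences against that same denominator, so their
  shares can exceed 1 in total.
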