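#' @title Synthetic FAERS-style data with known ground truth
#'
#' @description Generates quarterly "$"-delimited file sets (DEMO, DRUG,
#'   REAC, OUTC, RPSR, THER, INDI) from a configurable report-level model:
#'   each report receives one primary-suspect drug (exact per-drug quotas,
#'   shuffled), draws each preferred term independently with probability
#'   `min(1, rho * p)` — where `p` is the PT's baseline occurrence
#'   probability and `rho` the planted reporting-rate multiplier for that
#'   drug-PT pair — and is redrawn if no PT fires (reports always carry at
#'   least one reaction).  The per-report PT count is then Poisson-binomial
#'   with mean `sum(p)`, truncated at one.  A configurable fraction of cases
#'   is emitted as two versions (same CASEID, distinct FDA_DT), exercising
#'   deduplication.  Expected contingency tables are available in closed
#'   form, so planted signals have an exact oracle.
#' @name synthetic_faers
NULL

#' Default preferred-term vocabulary
#'
#' 60 PTs over 15 system organ classes, with baseline per-report occurrence
#' probabilities in six tiers (0.25, 0.12, 0.08, 0.06, 0.045, 0.013) summing
#' to 5.30 — so a report carries 5.3 distinct PTs on average, matching the
#' pair-to-report ratio observed in large spontaneous-report extractions.
#'
#' @return data.frame with columns `pt`, `soc`, `p`.
#' @export
default_pt_vocab <- function() {
  tier <- function(p, pts, soc) data.frame(pt = pts, soc = soc, p = p,
                                           stringsAsFactors = FALSE)
  psy <- "psychiatric disorders"; nrv <- "nervous system disorders"
  gen <- "general disorders and administration site conditions"
  gi <- "gastrointestinal disorders"; ski <- "skin and subcutaneous tissue disorders"
  rsp <- "respiratory, thoracic and mediastinal disorders"
  crd <- "cardiac disorders"; mus <- "musculoskeletal and connective tissue disorders"
  met <- "metabolism and nutrition disorders"; inv <- "investigations"
  inf <- "infections and infestations"
  inj <- "injury, poisoning and procedural complications"
  vocab <- rbind(
    tier(0.25, c("somnolence", "dizziness", "headache"), nrv),
    tier(0.25, c("nausea", "vomiting"), gi),
    tier(0.25, c("fatigue", "drug ineffective"), gen),
    tier(0.25, "anxiety", psy),
    tier(0.12, c("insomnia", "depression"), psy),
    tier(0.12, "tremor", nrv),
    tier(0.12, "diarrhoea", gi),
    tier(0.12, "rash", ski),
    tier(0.12, "dyspnoea", rsp),
    tier(0.12, "hypertension", "vascular disorders"),
    tier(0.12, "fall", inj),
    tier(0.12, c("pyrexia", "pain"), gen),
    tier(0.08, c("sopor", "confusional state"), psy),
    tier(0.08, "sedation", nrv),
    tier(0.08, "palpitations", crd),
    tier(0.08, "pruritus", ski),
    tier(0.08, "constipation", gi),
    tier(0.08, "weight increased", inv),
    tier(0.08, "asthenia", gen),
    tier(0.08, "myalgia", mus),
    tier(0.08, "cough", rsp),
    tier(0.06, c("drug abuse", "suicide attempt", "delirium",
                 "psychotic disorder", "hallucination"), psy),
    tier(0.06, "memory impairment", nrv),
    tier(0.06, "muscle rigidity", mus),
    tier(0.06, "respiratory depression", rsp),
    tier(0.06, "decreased appetite", met),
    tier(0.06, c("chills", "oedema peripheral"), gen),
    tier(0.06, "hyperhidrosis", ski),
    tier(0.045, c("neuroleptic malignant syndrome", "seizure"), nrv),
    tier(0.045, c("catatonia", "bradyphrenia"), psy),
    tier(0.045, c("sinus tachycardia", "pericarditis"), crd),
    tier(0.045, "atelectasis", rsp),
    tier(0.045, "pneumonia aspiration", inf),
    tier(0.045, "muscle injury", inj),
    tier(0.045, "acute kidney injury", "renal and urinary disorders"),
    tier(0.013, c("obesity", "hypercholesterolaemia"), met),
    tier(0.013, "pemphigus", ski),
    tier(0.013, c("folliculitis", "urinary tract infection"), inf),
    tier(0.013, "duodenal ulcer perforation", gi),
    tier(0.013, "deep vein thrombosis postoperative", "vascular disorders"),
    tier(0.013, c("c-reactive protein abnormal", "blood pressure increased"), inv),
    tier(0.013, "anaemia", "blood and lymphatic system disorders")
  )
  rownames(vocab) <- NULL
  vocab
}

#' Default drug vocabulary with synonym spellings
#'
#' Twelve canonical drugs; the target benzodiazepine holds a 1.5\% share of
#' primary-suspect reports, of the order of its observed share in FAERS.
#'
#' @return list with `drugs` (data.frame canonical, ps_prob) and `spellings`
#'   (data.frame canonical, spelling, weight).
#' @export
default_drug_vocab <- function() {
  drugs <- data.frame(
    canonical = c("lorazepam", "diazepam", "alprazolam", "sertraline",
                  "metformin", "atorvastatin", "ibuprofen", "omeprazole",
                  "amoxicillin", "lisinopril", "adalimumab", "paracetamol"),
    ps_prob = c(0.015, 0.05, 0.05, 0.08, 0.12, 0.11, 0.10, 0.09,
                0.08, 0.09, 0.12, 0.095),
    stringsAsFactors = FALSE)
  spellings <- data.frame(
    canonical = c("lorazepam", "lorazepam", "lorazepam",
                  "diazepam", "diazepam", "alprazolam", "alprazolam",
                  "sertraline", "sertraline", "metformin", "metformin",
                  "atorvastatin", "atorvastatin", "ibuprofen", "ibuprofen",
                  "omeprazole", "omeprazole", "amoxicillin", "amoxicillin",
                  "lisinopril", "lisinopril", "adalimumab", "adalimumab",
                  "paracetamol", "paracetamol", "paracetamol"),
    spelling = c("LORAZEPAM", "Ativan", "lorazepam tab",
                 "DIAZEPAM", "Valium", "ALPRAZOLAM", "Xanax",
                 "SERTRALINE", "Zoloft", "METFORMIN", "Glucophage",
                 "ATORVASTATIN", "Lipitor", "IBUPROFEN", "Advil",
                 "OMEPRAZOLE", "Prilosec", "AMOXICILLIN", "Amoxil",
                 "LISINOPRIL", "Zestril", "ADALIMUMAB", "Humira",
                 "PARACETAMOL", "Tylenol", "acetaminophen"),
    weight = c(0.5, 0.3, 0.2, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.7, 0.3,
               0.6, 0.4, 0.7, 0.3, 0.7, 0.3, 0.8, 0.2, 0.8, 0.2, 0.5, 0.5,
               0.5, 0.3, 0.2),
    stringsAsFactors = FALSE)
  list(drugs = drugs, spellings = spellings)
}

#' Simulation configuration
#'
#' @param seed integer seed; generation is a pure function of the config.
#' @param n_reports number of distinct cases to emit.
#' @param quarters data.frame with columns `year`, `quarter`.
#' @param drug_vocab list as returned by [default_drug_vocab()].
#' @param pt_vocab data.frame as returned by [default_pt_vocab()].
#' @param signal_spec data.frame with columns `drug`, `pt`, `rho`: planted
#'   reporting-rate multipliers (rho = 1 is the null; an empty frame plants
#'   nothing).
#' @param duplicate_rate fraction of caseids emitted as two versions.
#' @param partial_date_rate fraction of event/therapy dates truncated to
#'   year-month or year only.
#' @param onset_mean_days mean of the exponential therapy-start-to-event lag.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reports = 1000L,
                       quarters = expand.grid(quarter = 1:4, year = 2022:2023),
                       drug_vocab = default_drug_vocab(),
                       pt_vocab = default_pt_vocab(),
                       signal_spec = data.frame(drug = character(0),
                                                pt = character(0),
                                                rho = numeric(0)),
                       duplicate_rate = 0.05,
                       partial_date_rate = 0.10,
                       onset_mean_days = 40) {
  stopifnot(n_reports >= 1, is.data.frame(pt_vocab),
            all(c("pt", "soc", "p") %in% names(pt_vocab)),
            all(c("canonical", "ps_prob") %in% names(drug_vocab$drugs)),
            all(c("drug", "pt", "rho") %in% names(signal_spec)))
  if (any(pt_vocab$p <= 0 | pt_vocab$p > 1)) {
    stop("pt_vocab baseline probabilities must lie in (0, 1]")
  }
  if (anyDuplicated(pt_vocab$pt)) stop("duplicate PTs in pt_vocab")
  if (abs(sum(drug_vocab$drugs$ps_prob) - 1) > 1e-8) {
    stop("drug ps_prob must sum to 1")
  }
  if (any(signal_spec$rho < 0)) stop("rho must be >= 0")
  if (nrow(signal_spec) > 0) {
    if (!all(signal_spec$drug %in% drug_vocab$drugs$canonical)) {
      stop("signal_spec names a drug not in the vocabulary")
    }
    if (!all(signal_spec$pt %in% pt_vocab$pt)) {
      stop("signal_spec names a PT not in the vocabulary")
    }
  }
  if (sum(pt_vocab$p) > nrow(pt_vocab)) {
    stop("infeasible config: mean PTs per report exceeds vocabulary size")
  }
  if (duplicate_rate < 0 || duplicate_rate > 0.5) {
    stop("duplicate_rate must lie in [0, 0.5]")
  }
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 quarters = quarters, drug_vocab = drug_vocab,
                 pt_vocab = pt_vocab, signal_spec = signal_spec,
                 duplicate_rate = duplicate_rate,
                 partial_date_rate = partial_date_rate,
                 onset_mean_days = onset_mean_days),
            class = "sim_config")
}

# largest-remainder allocation of n among probabilities p (exact quotas)
quota_counts <- function(n, p) {
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    add <- order(-frac, seq_along(p))[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# per-drug PT inclusion probability matrix: q[j, d] = min(1, rho * p_j)
q_matrix <- function(config) {
  pts <- config$pt_vocab
  drugs <- config$drug_vocab$drugs$canonical
  q <- matrix(pts$p, nrow = nrow(pts), ncol = length(drugs),
              dimnames = list(pts$pt, drugs))
  ss <- config$signal_spec
  if (nrow(ss) > 0) {
    for (i in seq_len(nrow(ss))) {
      q[ss$pt[i], ss$drug[i]] <- min(1, ss$rho[i] * pts$p[pts$pt == ss$pt[i]])
    }
  }
  q
}

#' Closed-form expected contingency tables for every drug-PT pair
#'
#' Exact expectations under the generator's mechanics: per-drug quotas
#' `n_d`, inclusion probabilities `q = min(1, rho p)`, and the at-least-one-PT
#' condition, which rescales each probability to `q / (1 - P0_d)` where
#' `P0_d = prod(1 - q)` is the all-empty probability for drug `d`.
#'
#' @param config a `sim_config`.
#' @return data.frame with one row per (drug, pt): expected `a`, `b`, `c`,
#'   `d` and a `planted` flag (rho != 1).
#' @export
expected_table_grid <- function(config) {
  q <- q_matrix(config)
  n_d <- quota_counts(config$n_reports, config$drug_vocab$drugs$ps_prob)
  p0 <- apply(q, 2, function(col) prod(1 - col))
  ea <- sweep(sweep(q, 2, 1 - p0, "/"), 2, n_d, "*")  # E[a] per (pt, drug)
  row_tot <- colSums(ea)                              # per-drug pair totals
  N <- sum(ea)
  pt_tot <- rowSums(ea)
  grid <- expand.grid(pt = rownames(q), drug = colnames(q),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$a <- as.vector(ea)
  grid$b <- rep(row_tot, each = nrow(q)) - grid$a
  grid$c <- rep(pt_tot, times = ncol(q)) - grid$a
  grid$d <- N - grid$a - grid$b - grid$c
  ss <- config$signal_spec
  grid$planted <- paste(grid$drug, grid$pt) %in%
    paste(ss$drug[ss$rho != 1], ss$pt[ss$rho != 1])
  grid
}

#' Expected fourfold table for one drug-PT pair
#'
#' @param config a `sim_config`.
#' @param drug canonical drug name.
#' @param pt preferred term.
#' @return list with expected (non-integer) `a`, `b`, `c`, `d`.
#' @export
expected_table <- function(config, drug, pt) {
  grid <- expected_table_grid(config)
  row <- grid[grid$drug == drug & grid$pt == pt, ]
  if (nrow(row) != 1L) stop(sprintf("unknown drug/pt pair: %s / %s", drug, pt))
  as.list(row[, c("a", "b", "c", "d")])
}

# sample a categorical with given probabilities, returning labels
sample_cat <- function(n, labels, prob) {
  labels[sample.int(length(labels), n, replace = TRUE, prob = prob)]
}

#' Generate a synthetic FAERS dataset
#'
#' @param config a `sim_config`.
#' @param dir optional output directory; when given, quarterly files
#'   (DEMOyyQq.txt, ...) are written there.
#' @return object of class `faers_sim`: list with `tables` (a `faers_data`),
#'   `truth` (expected grid, realized per-pair counts on the kept case
#'   versions, planted pairs, duplicate count), `quarter_of` (primaryid ->
#'   quarter label) and `files` (paths, when `dir` was given).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_reports
  drugs <- config$drug_vocab$drugs
  pts <- config$pt_vocab
  J <- nrow(pts)

  # --- primary-suspect drug: exact quotas, shuffled assignment ------------
  n_d <- quota_counts(n, drugs$ps_prob)
  drug_idx <- sample(rep.int(seq_len(nrow(drugs)), n_d))

  # --- PT incidence: independent Bernoulli, redraw empty reports ---------
  q <- q_matrix(config)                      # J x D
  qrep <- t(q)[drug_idx, , drop = FALSE]     # n x J, row = report
  inc <- matrix(stats::runif(n * J), n, J) < qrep
  empty <- which(rowSums(inc) == 0L)
  while (length(empty) > 0L) {
    redraw <- matrix(stats::runif(length(empty) * J), length(empty), J) <
      qrep[empty, , drop = FALSE]
    inc[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0L]
  }

  # realized per-(drug, PT) counts on the kept case versions
  realized_mat <- rowsum(inc + 0L, group = drug_idx)
  realized <- expand.grid(pt = pts$pt, drug = drugs$canonical,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rmat <- matrix(0L, nrow(drugs), J)
  rmat[as.integer(rownames(realized_mat)), ] <- realized_mat
  realized$a <- as.vector(t(rmat))

  # --- identifiers and dates ---------------------------------------------
  caseid <- as.character(10000000 + seq_len(n))
  dup <- rep(FALSE, n)
  m_dup <- round(config$duplicate_rate * n)
  if (m_dup > 0) dup[sample.int(n, m_dup)] <- TRUE
  version <- ifelse(dup, "2", "1")
  primaryid <- paste0(caseid, version)

  qt <- config$quarters
  qi <- sample.int(nrow(qt), n, replace = TRUE)
  q_start <- as.Date(sprintf("%d-%02d-01", qt$year, (qt$quarter - 1) * 3 + 1))
  q_end <- as.Date(sprintf("%d-%02d-01",
                           qt$year + (qt$quarter == 4),
                           ifelse(qt$quarter == 4, 1, qt$quarter * 3 + 1))) - 1
  q_len <- as.integer(q_end - q_start) + 1L
  fda_days <- as.numeric(q_start[qi]) +
    floor(stats::runif(n) * q_len[qi])
  event_days <- fda_days - sample(0:30, n, replace = TRUE)
  lag <- round(stats::rexp(n, rate = 1 / config$onset_mean_days))
  start_days <- event_days - lag
  end_days <- start_days + sample(1:90, n, replace = TRUE)

  truncate_dates <- function(stamp) {
    u <- stats::runif(length(stamp))
    r <- config$partial_date_rate
    stamp[u < r / 2] <- substr(stamp[u < r / 2], 1, 6)
    stamp[u >= r / 2 & u < r] <- substr(stamp[u >= r / 2 & u < r], 1, 4)
    stamp
  }
  event_dt <- truncate_dates(days_to_stamp(event_days))
  start_dt <- truncate_dates(days_to_stamp(start_days))
  end_dt <- truncate_dates(days_to_stamp(end_days))
  fda_dt <- days_to_stamp(fda_days)

  # --- demographics -------------------------------------------------------
  sex <- sample_cat(n, c("F", "M", NA), c(0.58, 0.34, 0.08))
  country <- sample_cat(n, c("US", "CA", "IT", "DE", "GB", "FR", "JP", "BR"),
                        c(0.60, 0.10, 0.05, 0.04, 0.03, 0.03, 0.03, 0.12))
  occp <- sample_cat(n, c("CN", "MD", "PH", "HP", "OT", NA),
                     c(0.30, 0.28, 0.18, 0.16, 0.04, 0.04))
  age_years <- pmin(round(stats::rlnorm(n, log(50), 0.45), 1), 110)
  age_missing <- stats::runif(n) < 0.10
  cod <- sample_cat(n, c("YR", "DEC", "MON"), c(0.92, 0.04, 0.04))
  age_val <- ifelse(cod == "YR", age_years,
                    ifelse(cod == "DEC", round(age_years / 10, 1),
                           round(age_years * 12)))
  age_val[age_missing] <- NA
  cod[age_missing] <- NA

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = version,
    fda_dt = fda_dt, event_dt = event_dt,
    age = as.character(age_val), age_cod = cod, sex = sex,
    reporter_country = country, occp_cod = occp,
    stringsAsFactors = FALSE)

  # --- DRUG: one PS row per report plus concomitant noise -----------------
  sp <- config$drug_vocab$spellings
  pick_spelling <- function(canon_idx) {
    out <- character(length(canon_idx))
    for (dn in unique(canon_idx)) {
      rows <- which(canon_idx == dn)
      opts <- sp[sp$canonical == drugs$canonical[dn], , drop = FALSE]
      if (nrow(opts) == 0L) {
        out[rows] <- drugs$canonical[dn]
      } else {
        out[rows] <- sample_cat(length(rows), opts$spelling, opts$weight)
      }
    }
    out
  }
  route <- sample_cat(n, c("ORAL", "INTRAVENOUS", "INTRAMUSCULAR", NA),
                      c(0.875, 0.06, 0.03, 0.035))
  drug_ps <- data.frame(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = pick_spelling(drug_idx), route = route,
    stringsAsFactors = FALSE)
  ncon <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  con_rep <- rep.int(seq_len(n), ncon)
  con_seq <- as.character(unlist(lapply(ncon[ncon > 0], seq_len)) + 1L)
  con_idx <- sample.int(nrow(drugs), length(con_rep), replace = TRUE)
  drug_con <- data.frame(
    primaryid = primaryid[con_rep], drug_seq = con_seq, role_cod = "C",
    drugname = pick_spelling(con_idx),
    route = sample_cat(length(con_rep), c("ORAL", NA), c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  drug_tab <- rbind(drug_ps, drug_con)

  # --- REAC ----------------------------------------------------------------
  hit <- which(inc, arr.ind = TRUE)
  pt_names <- pts$pt[hit[, 2]]
  cap <- stats::runif(nrow(hit)) < 0.5
  pt_out <- ifelse(cap, paste0(toupper(substr(pt_names, 1, 1)),
                               substr(pt_names, 2, nchar(pt_names))),
                   pt_names)
  reac <- data.frame(primaryid = primaryid[hit[, 1]], pt = pt_out,
                     stringsAsFactors = FALSE)

  # --- OUTC: independent per-code draws ------------------------------------
  outc_codes <- c(HO = 0.38, OT = 0.25, DE = 0.124, LT = 0.058,
                  DS = 0.02, RI = 0.01, CA = 0.005)
  outc_list <- lapply(names(outc_codes), function(code) {
    sel <- stats::runif(n) < outc_codes[[code]]
    data.frame(primaryid = primaryid[sel],
               outc_cod = rep(code, sum(sel)),
               stringsAsFactors = FALSE)
  })
  outc <- do.call(rbind, outc_list)

  rpsr <- data.frame(primaryid = primaryid,
                     rpsr_cod = sample_cat(n, c("FGN", "SDY", "LIT", "CSM",
                                                "HP", "OTH"),
                                           c(0.1, 0.05, 0.05, 0.35, 0.35, 0.1)),
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                     start_dt = start_dt, end_dt = end_dt,
                     stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = primaryid, indi_drug_seq = "1",
                     indi_pt = sample_cat(n, c("anxiety", "insomnia",
                                               "status epilepticus",
                                               "agitation", "depression",
                                               "sedation"),
                                          c(0.40, 0.25, 0.10, 0.10, 0.10, 0.05)),
                     stringsAsFactors = FALSE)

  # --- stale earlier versions for the duplicated caseids -------------------
  quarter_label <- sprintf("%02dQ%d", qt$year[qi] %% 100, qt$quarter[qi])
  if (m_dup > 0) {
    di <- which(dup)
    old_pid <- paste0(caseid[di], "1")
    delta <- sample(1:180, m_dup, replace = TRUE)
    old_demo <- demo[di, , drop = FALSE]
    old_demo$primaryid <- old_pid
    old_demo$caseversion <- "1"
    old_demo$fda_dt <- days_to_stamp(fda_days[di] - delta)
    demo <- rbind(demo, old_demo)
    clone <- function(tbl) {
      sub <- tbl[tbl$primaryid %in% primaryid[di], , drop = FALSE]
      sub$primaryid <- old_pid[match(sub$primaryid, primaryid[di])]
      rbind(tbl, sub)
    }
    drug_tab <- clone(drug_tab); reac <- clone(reac); outc <- clone(outc)
    rpsr <- clone(rpsr); ther <- clone(ther); indi <- clone(indi)
    quarter_of <- c(stats::setNames(quarter_label, primaryid),
                    stats::setNames(quarter_label[di], old_pid))
  } else {
    quarter_of <- stats::setNames(quarter_label, primaryid)
  }

  # deterministic shuffle within each table so ingestion order carries no
  # information
  shuffle <- function(tbl) {
    out <- tbl[sample.int(nrow(tbl)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  tables <- faers_data(list(demo = shuffle(demo), drug = shuffle(drug_tab),
                            reac = shuffle(reac), outc = shuffle(outc),
                            rpsr = shuffle(rpsr), ther = shuffle(ther),
                            indi = shuffle(indi)))

  ss <- config$signal_spec
  sim <- structure(
    list(tables = tables,
         truth = list(expected = expected_table_grid(config),
                      realized = realized,
                      planted = ss[ss$rho != 1, , drop = FALSE],
                      n_duplicates = m_dup, n_reports = n),
         quarter_of = quarter_of,
         config = config),
    class = "faers_sim")
  if (!is.null(dir)) sim$files <- write_faers_files(sim, dir)
  sim
}

#' Write a synthetic dataset as quarterly FAERS-style files
#'
#' @param sim a `faers_sim` object.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_faers_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tab in FAERS_TABLES) {
    tbl <- sim$tables[[tab]]
    qlab <- sim$quarter_of[tbl$primaryid]
    for (ql in sort(unique(qlab))) {
      path <- file.path(dir, sprintf("%s%s.txt", toupper(tab), ql))
      write_faers_table(tbl[qlab == ql, , drop = FALSE], path)
      files[sprintf("%s_%s", tab, ql)] <- path
    }
  }
  files
}

#' Read back a directory of quarterly files written by the generator
#'
#' @param dir directory containing `DEMOyyQq.txt` style files.
#' @param pattern regular expression extracting table name from file names.
#' @return a `faers_data` object pooling all quarters.
#' @export
read_faers_dir <- function(dir, pattern = "^(DEMO|DRUG|REAC|OUTC|RPSR|THER|INDI)") {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  m <- regmatches(basename(files), regexpr(pattern, basename(files)))
  keep <- lengths(regmatches(basename(files), gregexpr(pattern, basename(files)))) > 0
  tabs <- tolower(m)
  pooled <- list()
  reports <- list()
  for (tab in FAERS_TABLES) {
    fs <- files[keep & tabs == tab]
    if (length(fs) == 0L) next
    parts <- lapply(fs, read_faers_table, table = tab)
    pooled[[tab]] <- do.call(rbind, lapply(parts, `[[`, "records"))
    reports[[tab]] <- list(
      rows_read = sum(vapply(parts, function(p) p$report$rows_read, 0)),
      rows_rejected = sum(vapply(parts, function(p) p$report$rows_rejected, 0)))
  }
  faers_data(pooled, parse_report = reports)
}
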