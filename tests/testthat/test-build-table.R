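test_that("the fixture fourfold table matches a nested-loop hand count", {
  data <- tiny_cases()
  pairs <- pair_table(data, level = "pt")
  t <- build_table(pairs, "lorazepam", "sopor")
  oracle <- oracle_table(data, "lorazepam", "sopor")
  expect_equal(c(a = t$a, b = t$b, c = t$c, d = t$d), oracle)
  # hand count: P1, P2 carry sopor under lorazepam PS; P3, P4 do not
  expect_equal(t$a, 2)
  expect_equal(t$a + t$b + t$c + t$d, nrow(pairs$pairs))
})

test_that("an absent event gives a = c = 0 with margins conserved", {
  data <- tiny_cases()
  pairs <- pair_table(data, level = "pt")
  t <- build_table(pairs, "lorazepam", "no such event")
  expect_equal(t$a, 0)
  expect_equal(t$c, 0)
  expect_equal(t$a + t$b + t$c + t$d, nrow(pairs$pairs))
})

test_that("a single report with the drug and the event gives (1,0,0,0)", {
  data <- faers_data(list(
    demo = data.frame(primaryid = "P1", caseid = "C1", fda_dt = "20200101",
                      stringsAsFactors = FALSE),
    drug = data.frame(primaryid = "P1", drug_seq = "1", role_cod = "PS",
                      drugname = "lorazepam", stringsAsFactors = FALSE),
    reac = data.frame(primaryid = "P1", pt = "sopor", stringsAsFactors = FALSE)))
  pairs <- pair_table(data, level = "pt")
  t <- build_table(pairs, "lorazepam", "sopor")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 0, 0, 0))
})

test_that("a PT repeated inside one report counts once", {
  data <- tiny_cases()
  data$reac <- rbind(data$reac,
                     data.frame(primaryid = "P1", pt = "SOPOR"),
                     data.frame(primaryid = "P1", pt = " sopor "))
  pairs <- pair_table(data, level = "pt")
  t <- build_table(pairs, "lorazepam", "sopor")
  expect_equal(t$a, 2)  # unchanged by in-report repetition
})

test_that("SOC-level tables collapse PTs to one pair per report per SOC", {
  data <- tiny_cases()
  map <- pt_soc_map(c("sopor", "nausea", "headache"),
                    c("psychiatric disorders", "gastrointestinal disorders",
                      "nervous system disorders"))
  pairs <- pair_table(data, level = "soc", soc_map = map)
  t <- build_table(pairs, "lorazepam", "psychiatric disorders")
  oracle <- oracle_table(data, "lorazepam", "psychiatric disorders",
                         soc_map = map)
  expect_equal(c(a = t$a, b = t$b, c = t$c, d = t$d), oracle)
  # unmapped PTs are excluded from SOC pairs only
  map2 <- pt_soc_map(c("sopor", "nausea"),
                     c("psychiatric disorders", "gastrointestinal disorders"))
  pairs2 <- pair_table(data, level = "soc", soc_map = map2)
  expect_gt(pairs2$n_unmapped_pt, 0)
})

test_that("build_table equals the brute-force oracle on synthetic datasets", {
  set.seed(808)
  for (rep in 1:5) {
    sim <- generate_faers(small_config(seed = 7000 + rep, n = 60,
                                       duplicate_rate = 0))
    data <- harmonize_drugs(sim$tables, sim_synonym_map(sim$config))
    pairs <- pair_table(data, level = "pt")
    drugs <- sample(sim$config$drug_vocab$drugs$canonical, 2)
    events <- sample(sim$config$pt_vocab$pt, 4)
    for (dg in drugs) for (ev in events) {
      t <- build_table(pairs, dg, ev)
      oracle <- oracle_table(data, dg, ev)
      expect_equal(c(a = t$a, b = t$b, c = t$c, d = t$d), oracle)
    }
  }
})

test_that("screening keeps PTs at the frequency boundary and drops below it", {
  ids <- paste0("P", 1:10)
  data <- faers_data(list(
    demo = data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101",
                      stringsAsFactors = FALSE),
    drug = data.frame(primaryid = ids, drug_seq = "1", role_cod = "PS",
                      drugname = "lorazepam", stringsAsFactors = FALSE),
    reac = data.frame(primaryid = c(ids[1:3], ids[1:2], ids[1:4]),
                      pt = c(rep("exactly three", 3), rep("only two", 2),
                             rep("four hits", 4)),
                      stringsAsFactors = FALSE)))
  pairs <- pair_table(data, level = "pt")
  screened <- screen_pts(pairs, "lorazepam", min_count = 3)
  expect_setequal(screened$event, c("exactly three", "four hits"))
  expect_equal(screened$a[screened$event == "exactly three"], 3)
})

test_that("signal_table agrees with per-pair build_table plus signal_stats", {
  sim <- generate_faers(small_config(seed = 11, n = 300))
  data <- harmonize_drugs(dedupe_faers(sim$tables)$data,
                          sim_synonym_map(sim$config))
  pairs <- pair_table(data, level = "pt")
  st <- signal_table(pairs, "metformin", min_cases = 3)
  for (ev in utils::head(st$event, 5)) {
    t <- build_table(pairs, "metformin", ev)
    row <- st[st$event == ev, ]
    expect_equal(c(row$a, row$b, row$c, row$d), c(t$a, t$b, t$c, t$d))
    expect_equal(row$ebgm, signal_stats(t$a, t$b, t$c, t$d)$ebgm)
  }
})

test_that("ranking sorts descending with alphabetical tie-break and filters", {
  res <- data.frame(event = c("zeta", "alpha", "mid", "small"),
                    a = c(400, 400, 350, 10),
                    ebgm = c(2, 8, 4, 9), stringsAsFactors = FALSE)
  by_cases <- rank_results(res, by = "case_count", min_cases = 300)
  expect_equal(by_cases$event, c("alpha", "zeta", "mid"))  # tie -> alphabetical
  expect_true(all(by_cases$a > 300))
  by_ebgm <- rank_results(res, by = "ebgm", top_k = 2)
  expect_equal(by_ebgm$event, c("small", "alpha"))
  expect_true(all(diff(by_ebgm$ebgm) <= 0))
})
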