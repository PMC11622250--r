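test_that("generation is a pure function of the config", {
  cfg <- small_config(seed = 7, n = 100, duplicate_rate = 0.1)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  generate_faers(cfg, dir = dir1)
  generate_faers(cfg, dir = dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(3)
  set.seed(1); invisible(generate_faers(cfg)); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("generated files round-trip through the reader with zero rejects", {
  cfg <- small_config(seed = 3, n = 120, duplicate_rate = 0.1)
  dir <- withr::local_tempdir()
  sim <- generate_faers(cfg, dir = dir)
  back <- read_faers_dir(dir)
  for (tab in c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")) {
    rep_tab <- attr(back, "parse_report")[[tab]]
    expect_equal(rep_tab$rows_rejected, 0)
    expect_equal(nrow(back[[tab]]), nrow(sim$tables[[tab]]))
  }
  # pooled records identical up to row order
  ord <- function(df) {
    df <- df[do.call(order, c(unname(df), list(method = "radix"))), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(back$demo), ord(sim$tables$demo))
})

test_that("every duplicated caseid appears with two fda_dt values and dedup removes the ledgered count", {
  cfg <- small_config(seed = 5, n = 200, duplicate_rate = 0.1)
  sim <- generate_faers(cfg)
  demo <- sim$tables$demo
  expect_equal(nrow(demo), 200 + sim$truth$n_duplicates)
  dup_cids <- names(which(table(demo$caseid) > 1))
  expect_length(dup_cids, sim$truth$n_duplicates)
  for (cid in utils::head(dup_cids, 5)) {
    expect_length(unique(demo$fda_dt[demo$caseid == cid]), 2)
  }
  res <- deduplicate_cases(demo)
  expect_equal(res$removed_count, sim$truth$n_duplicates)
  # the kept record is always the later version
  expect_true(all(res$kept$caseversion[res$kept$caseid %in% dup_cids] == "2"))
})

test_that("generator emission counts equal pipeline pair counts exactly", {
  cfg <- small_config(seed = 13, n = 300, duplicate_rate = 0.08)
  sim <- generate_faers(cfg)
  data <- harmonize_drugs(dedupe_faers(sim$tables)$data,
                          sim_synonym_map(cfg))
  pairs <- pair_table(data, level = "pt")
  realized <- sim$truth$realized
  for (dg in unique(realized$drug)) {
    st <- screen_pts(pairs, dg, min_count = 1)
    for (pt in cfg$pt_vocab$pt) {
      want <- realized$a[realized$drug == dg & realized$pt == pt]
      got <- st$a[st$event == pt]
      if (length(got) == 0) got <- 0L
      expect_equal(got, want,
                   label = sprintf("pair count for %s/%s", dg, pt))
    }
  }
})

test_that("expected tables match pencil-and-paper arithmetic on a 2x2 config", {
  vocab <- data.frame(pt = c("ptA", "ptB"), soc = c("s1", "s2"),
                      p = c(0.5, 0.25), stringsAsFactors = FALSE)
  dv <- list(drugs = data.frame(canonical = c("d1", "d2"),
                                ps_prob = c(0.5, 0.5),
                                stringsAsFactors = FALSE),
             spellings = data.frame(canonical = character(0),
                                    spelling = character(0),
                                    weight = numeric(0)))
  cfg <- sim_config(seed = 1, n_reports = 80, drug_vocab = dv,
                    pt_vocab = vocab,
                    signal_spec = data.frame(drug = "d1", pt = "ptB",
                                             rho = 2))
  # by hand: q(d1) = (0.5, 0.5), P0 = 0.25, scale 1/0.75
  #          E a(d1, ptA) = 40 * 0.5 / 0.75 = 26.666...
  #          q(d2) = (0.5, 0.25), P0 = 0.375, scale 1/0.625
  #          E a(d2, ptA) = 40 * 0.5 / 0.625 = 32
  et <- expected_table(cfg, "d1", "ptA")
  expect_equal(et$a, 40 * 0.5 / 0.75, tolerance = 1e-12)
  expect_equal(et$c, 32, tolerance = 1e-12)
  et2 <- expected_table(cfg, "d1", "ptB")
  expect_equal(et2$a, 40 * 0.5 / 0.75, tolerance = 1e-12)
  expect_equal(et2$c, 40 * 0.25 / 0.625, tolerance = 1e-12)
  # margin identities
  grid <- expected_table_grid(cfg)
  expect_equal(unique(round(grid$a + grid$b + grid$c + grid$d, 9)),
               round(sum(grid$a[grid$drug == "d1"]) +
                       sum(grid$a[grid$drug == "d2"]), 9))
  expect_error(expected_table(cfg, "d1", "nope"), "unknown")
})

test_that("a rho = 1 pair has independent expectations (ad = bc)", {
  cfg <- small_config(seed = 1, n = 1000)
  et <- expected_table(cfg, "metformin", "sopor")
  # all drugs share identical q vectors under the null, so ad = bc
  expect_equal(et$a * et$d, et$b * et$c, tolerance = 1e-6 * et$a * et$d)
})

test_that("the expected EBGM of a planted rho = 5 pair is close to 5 when the drug share is small", {
  cfg <- small_config(seed = 1, n = 50000,
                      signal_spec = data.frame(drug = "lorazepam",
                                               pt = "sopor", rho = 5))
  et <- expected_table(cfg, "lorazepam", "sopor")
  N <- et$a + et$b + et$c + et$d
  ebgm <- et$a * N / ((et$a + et$c) * (et$a + et$b))
  expect_gt(ebgm, 4)
  expect_lt(ebgm, 5)
})

test_that("infeasible or invalid configs are rejected before generation", {
  expect_error(sim_config(n_reports = 0), "n_reports")
  expect_error(small_config(signal_spec = data.frame(drug = "lorazepam",
                                                     pt = "nope", rho = 2)),
               "PT not in|not in the vocabulary")
  expect_error(small_config(signal_spec = data.frame(drug = "lorazepam",
                                                     pt = "sopor", rho = -1)),
               "rho")
  bad_vocab <- default_pt_vocab(); bad_vocab$p[1] <- 1.5
  expect_error(small_config(pt_vocab = bad_vocab), "probabilities")
})
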