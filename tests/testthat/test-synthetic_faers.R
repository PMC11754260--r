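test_that("generation is deterministic: same seed, byte-identical files", {
  cfg <- synthetic_config(n_cases = 400, seed = 77)
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_faers(cfg, outdir = d1)
  generate_faers(cfg, outdir = d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "gen_c")
  unlink(d3, recursive = TRUE)
  generate_faers(synthetic_config(n_cases = 400, seed = 78), outdir = d3)
  md <- function(dir) unname(tools::md5sum(file.path(dir, "ground_truth_pairs.csv")))
  expect_false(identical(md(d1), md(d3)))
})

test_that("duplicate_rate produces the exact number of two-version cases", {
  cfg <- synthetic_config(n_cases = 1000, seed = 5, duplicate_rate = 0.1)
  x <- generate_faers(cfg)
  two_versions <- x$demo[, .N, by = caseid][N == 2L]
  expect_equal(nrow(two_versions), 100L)
  expect_equal(nrow(x$demo), 1100L)
  # versions differ only in fda_dt, caseversion, primaryid
  dups <- x$demo[caseid %in% two_versions$caseid]
  same <- dups[, lapply(.SD, data.table::uniqueN), by = caseid,
               .SDcols = c("sex", "age", "age_cod", "occp_cod", "occr_country")]
  expect_true(all(same[, -1] == 1L))
  expect_true(all(x$demo[caseversion == 1L & caseid %in% two_versions$caseid, fda_dt] <
                  x$demo[caseversion == 2L, setNames(fda_dt, caseid)][two_versions$caseid]))
})

test_that("round-trip through quarterly files preserves the extract", {
  cfg <- synthetic_config(n_cases = 300, seed = 9)
  dir <- file.path(tempdir(), "gen_rt")
  unlink(dir, recursive = TRUE)
  x <- generate_faers(cfg, outdir = dir)
  back <- read_faers_extract(dir)
  for (s in c("demo", "drug", "reac")) {
    cols <- faers_schema(toupper(s))
    orig <- data.table::setorderv(x[[s]][, cols, with = FALSE], cols)
    got <- data.table::setorderv(back[[s]][, cols, with = FALSE], cols)
    expect_equal(as.data.frame(got), as.data.frame(orig), info = s)
  }
})

test_that("null world: target and background PT profiles are homogeneous", {
  cfg <- synthetic_config(
    n_cases = 50000, seed = 13,
    injected_signals = data.table::data.table(ingredient = character(0),
                                              pt = character(0), rr = numeric(0)))
  x <- generate_faers(cfg)
  cs <- deduplicate_cases(x$demo)
  suppressMessages(ev <- build_events(x$reac, cs, fixture_map(cfg)))
  tgt <- x$truth$cases[ingredient == "BUD/GLY/FOR", caseid]
  ev[, grp := caseid %in% tgt]
  m <- data.table::dcast(ev[, .N, by = .(grp, pt)], pt ~ grp, value.var = "N", fill = 0L)
  p <- suppressWarnings(stats::chisq.test(as.matrix(m[, -1]))$p.value)
  expect_gt(p, 0.001)
})

test_that("expected_table: null pairs have odds ratio 1, zero-share drugs empty cells", {
  cfg0 <- synthetic_config(
    injected_signals = data.table::data.table(ingredient = character(0),
                                              pt = character(0), rr = numeric(0)))
  et <- expected_table(cfg0, "BUD/GLY/FOR", "Pneumonia")
  expect_equal(et$ror, 1, tolerance = 1e-12)
  expect_equal(et$rr, 1)

  drugs0 <- list(list(ingredient = "NOSHARE", share = 0, names = "NOTHING"),
                 list(ingredient = "X", share = 0.2, names = "XDRUG"))
  cfg1 <- synthetic_config(drugs = drugs0,
                           injected_signals = data.table::data.table(
                             ingredient = "X", pt = "Pneumonia", rr = 2))
  expect_equal(expected_table(cfg1, "NOSHARE", "Cough")$a, 0)
  expect_error(expected_table(cfg0, "BUD/GLY/FOR", "Not a PT"), "unknown PT")
  expect_error(expected_table(cfg0, "NOPE", "Cough"), "unknown ingredient")
})

test_that("expected_table matches exact enumeration on a small vocabulary", {
  m <- 16
  vocab <- data.table::data.table(
    pt = c("RarePT", sprintf("Common%d", 1:(m - 1))),
    soc = "S",
    background_rate = c(0.008, rep((1 - 0.008) / (m - 1), m - 1)))
  cfg <- synthetic_config(
    n_cases = 1000, pt_vocabulary = vocab,
    drugs = list(list(ingredient = "A", share = 0.2, names = "ADRUG")),
    injected_signals = data.table::data.table(ingredient = "A", pt = "RarePT", rr = 5),
    pts_per_report = list(lambda = 2, max = 4),
    duplicate_rate = 0)
  et <- expected_table(cfg, "A", "RarePT")

  # oracle: exact inclusion probabilities by enumeration of ordered draws
  w_bg <- vocab$background_rate / sum(vocab$background_rate)
  w_tg <- w_bg * c(5, rep(1, m - 1))
  pi_tg <- incl_exact(w_tg / sum(w_tg), 2, 4)
  pi_bg <- incl_exact(w_bg, 2, 4)
  ek <- sum((1:4) * dpois(1:4, 2)) / sum(dpois(1:4, 2))
  a <- 200 * pi_tg[1]; b <- 200 * ek - a
  cc <- 800 * pi_bg[1]; d <- 800 * ek - cc
  oracle_ror <- (a * d) / (b * cc)

  expect_equal(et$ror, oracle_ror, tolerance = 0.02)
  expect_equal(et$a, a, tolerance = 0.02)
  # rare-event regime: implied odds ratio tracks the injected relative risk
  expect_equal(et$ror / 5, 1, tolerance = 0.05)
})

test_that("infeasible or malformed configurations are rejected before generation", {
  expect_error(synthetic_config(duplicate_rate = 1.2), "duplicate_rate")
  expect_error(synthetic_config(injected_signals = data.table::data.table(
    ingredient = "BUD/GLY/FOR", pt = "Nope", rr = 3)), "unknown PT")
  expect_error(synthetic_config(injected_signals = data.table::data.table(
    ingredient = "GHOST", pt = "Cough", rr = 3)), "unknown ingredient")
  expect_error(synthetic_config(injected_signals = data.table::data.table(
    ingredient = "BUD/GLY/FOR", pt = "Cough", rr = -1)), "positive")
  bad_drugs <- list(list(ingredient = "A", share = 0.7, names = "A1"),
                    list(ingredient = "B", share = 0.5, names = "B1"))
  expect_error(synthetic_config(drugs = bad_drugs), "sum to at most 1")
  # a single overwhelming weight makes expected inclusion exceed one
  v <- data.table::data.table(pt = c("Huge", "Tiny"), soc = "S",
                              background_rate = c(0.99, 0.01))
  expect_error(synthetic_config(pt_vocabulary = v,
                                injected_signals = data.table::data.table(
                                  ingredient = character(0), pt = character(0),
                                  rr = numeric(0)),
                                pts_per_report = list(lambda = 2, max = 2)),
               "infeasible")
})

test_that("end-to-end conservation: pipeline pair total equals ground truth", {
  x <- default_fixture()
  cs <- deduplicate_cases(x$demo)
  suppressMessages(ev <- build_events(x$reac, cs, fixture_map()))
  expect_equal(nrow(ev), sum(x$truth$pairs$count))
})
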