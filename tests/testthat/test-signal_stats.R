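# A small grid of 2x2 tables reused across statistic tests
.grid_tables <- data.table::data.table(
  a = c(3, 10, 25, 100, 8, 50, 5, 200),
  b = c(97, 90, 75, 900, 2, 450, 15, 1800),
  c = c(100, 100, 75, 1000, 10, 500, 100, 2000),
  d = c(9800, 900, 825, 98000, 980, 9000, 880, 16000))

test_that("ROR closed form and Wald interval", {
  r <- ror_stat(10, 90, 100, 900)
  expect_equal(r$ror, 1)
  # frozen from direct evaluation: se = sqrt(1/10+1/90+1/100+1/900) = 0.349603
  expect_equal(r$se_ln_ror, 0.349603, tolerance = 1e-5)
  expect_equal(r$ror_ci_low, 0.50398, tolerance = 1e-4)
  expect_equal(r$ror_ci_high, 1.98421, tolerance = 1e-4)
  expect_true(r$evaluable)

  z <- ror_stat(0, 90, 100, 900)
  expect_false(z$evaluable)
  expect_true(is.na(z$ror))
  zc <- ror_stat(0, 90, 100, 900, continuity = TRUE)
  expect_true(zc$evaluable)
  expect_equal(zc$ror, (0.5 * 900.5) / (90.5 * 100.5))
})

test_that("PRR closed form, interval and chi-square", {
  p <- prr_stat(10, 90, 100, 900)
  expect_equal(p$prr, 1)
  p2 <- prr_stat(20, 80, 100, 1900)
  expect_equal(p2$prr, 4)  # 0.2 / 0.05
  # chi-square cross-checked against an independent routine
  expect_equal(p2$chisq, 37.03736, tolerance = 1e-5)
  p2u <- prr_stat(20, 80, 100, 1900, yates = FALSE)
  expect_equal(p2u$chisq, 39.77273, tolerance = 1e-5)
  # independence table has zero uncorrected chi-square
  expect_equal(prr_stat(10, 90, 100, 900, yates = FALSE)$chisq, 0)
})

test_that("chi-square matches stats::chisq.test across the grid", {
  for (i in seq_len(nrow(.grid_tables))) {
    t <- .grid_tables[i]
    m <- matrix(unlist(t), 2, byrow = TRUE)
    expect_equal(chisq_2x2(t$a, t$b, t$c, t$d, yates = TRUE),
                 suppressWarnings(unname(stats::chisq.test(m, correct = TRUE)$statistic)),
                 tolerance = 1e-10)
    expect_equal(chisq_2x2(t$a, t$b, t$c, t$d, yates = FALSE),
                 suppressWarnings(unname(stats::chisq.test(m, correct = FALSE)$statistic)),
                 tolerance = 1e-10)
  }
})

test_that("IC is log2 observed/expected; a = 0 gives -Inf with finite EIC/VIC", {
  b <- bcpnn_stat(10, 90, 90, 810)  # a*N = (a+b)(a+c): exact independence
  expect_equal(b$ic, 0)
  z <- bcpnn_stat(0, 100, 100, 800)
  expect_equal(z$ic, -Inf)
  expect_true(is.finite(z$eic) && is.finite(z$vic))
})

test_that("VIC is nonnegative on random tables", {
  set.seed(901)
  n <- 1000
  tabs <- matrix(rpois(4 * n, lambda = rep(c(20, 200, 300, 5000), each = n)), ncol = 4)
  v <- bcpnn_stat(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])$vic
  expect_true(all(v >= 0))
})

test_that("EIC converges to IC as N grows with proportions fixed", {
  s <- 1e7 / 1100
  b <- bcpnn_stat(25 * s, 75 * s, 75 * s, 925 * s)
  expect_lt(abs(b$eic - b$ic), 0.01)
})

test_that("posterior-moment method matches its Monte-Carlo oracle", {
  # independent-Beta posterior model: exact digamma/trigamma moments must sit
  # within 3 MC standard errors of simulated moments of the log2 ratio
  set.seed(311)
  pri <- bcpnn_priors()
  n <- 2e5
  for (i in c(1L, 3L, 5L)) {
    t <- .grid_tables[i]
    N <- t[, a + b + c + d]
    g <- pri$gamma11 * (N + pri$alpha) * (N + pri$beta) /
      ((t$a + t$b + pri$alpha1) * (t$a + t$c + pri$beta1))
    pxy <- rbeta(n, t$a + pri$gamma11, N - t$a + g - pri$gamma11)
    px <- rbeta(n, t$a + t$b + pri$alpha1, N - (t$a + t$b) + pri$alpha - pri$alpha1)
    py <- rbeta(n, t$a + t$c + pri$beta1, N - (t$a + t$c) + pri$beta - pri$beta1)
    ic_draws <- log2(pxy / (px * py))
    post <- bcpnn_stat(t$a, t$b, t$c, t$d, method = "posterior")
    expect_lt(abs(post$eic - mean(ic_draws)), 3 * sd(ic_draws) / sqrt(n))
    expect_lt(abs(post$vic - var(ic_draws)),
              3 * var(ic_draws) * sqrt(2 / n))
  }
})

test_that("ROR and PRR are strictly increasing in a (b, c, d fixed)", {
  a <- 1:50
  r <- ror_stat(a, 500, 300, 5000)$ror
  p <- prr_stat(a, 500, 300, 5000)$prr
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
})

test_that("threshold flags follow the printed rules", {
  mk <- function(a, ror_lo, prr_lo, chisq, ic025)
    data.table::data.table(a = a, ror_ci_low = ror_lo, prr_ci_low = prr_lo,
                           chisq = chisq, ic025 = ic025)
  # a below 3 blocks ROR/PRR signals regardless of effect size
  f <- apply_thresholds(mk(2, 50, 50, 100, 3))
  expect_false(f$ror_signal || f$prr_signal)
  expect_true(f$bcpnn_signal)  # IC025 has no case-count condition
  # all three fire together
  g <- apply_thresholds(mk(50, 1.01, 1.01, 10, 0.1))
  expect_true(g$ror_signal && g$prr_signal && g$bcpnn_signal && g$all_three)
  # strict inequalities at every boundary
  h <- apply_thresholds(mk(3, 1, 1, 4, 0))
  expect_false(h$ror_signal || h$prr_signal || h$bcpnn_signal || h$all_three)
  # NA statistics never signal
  k <- apply_thresholds(mk(10, NA, NA, NA, NA))
  expect_false(k$ror_signal || k$prr_signal || k$bcpnn_signal)
})

test_that("signal_table is coherent on real contingency rows", {
  x <- default_fixture()
  cs <- deduplicate_cases(x$demo)
  suppressMessages(ev <- build_events(merge_device_pts(x$reac), cs, fixture_map()))
  tgt <- x$truth$cases[ingredient == "BUD/GLY/FOR", caseid]
  st <- signal_table(tabulate_events(ev, cs, tgt, "pt"))
  ok <- st[ror_evaluable == TRUE]
  expect_true(all(ok$ror_ci_low <= ok$ror & ok$ror <= ok$ror_ci_high))
  expect_true(all(st$vic >= 0))
  expect_true(all(st$ic025 <= st$eic))
})

test_that("rank_by_ic orders, breaks ties and excludes as documented", {
  res <- data.table::data.table(
    event = c("B", "A", "C", "Excluded one"),
    a = c(3, 5, 9, 100), ic = c(2, 2, 1, 9),
    all_three = c(TRUE, TRUE, FALSE, TRUE))
  top <- rank_by_ic(res, k = 10, exclude = "EXCLUDED ONE")
  expect_equal(top$event, c("A", "B", "C"))  # ic desc, then a desc
  expect_equal(nrow(rank_by_ic(res, k = 2, exclude = "Excluded one")), 2L)
  expect_equal(rank_by_ic(res, k = 10, exclude = "Excluded one",
                          require_all_three = TRUE)$event, c("A", "B"))
})

test_that("an injected strong signal ranks first by IC", {
  x <- default_fixture()
  cs <- deduplicate_cases(x$demo)
  suppressMessages(ev <- build_events(merge_device_pts(x$reac), cs, fixture_map()))
  tgt <- x$truth$cases[ingredient == "FF/UMEC/VI", caseid]
  st <- signal_table(tabulate_events(ev, cs, tgt, "pt"))
  top <- rank_by_ic(st, k = 1)
  # RR-5 candida infection dominates this drug's signal list
  expect_equal(top$event, "Candida infection")
})
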