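test_that("tolerance rounding is half-away-from-zero at the metric's digits", {
  expect_equal(round_half_away(6.2), 6)
  expect_equal(round_half_away(15.8), 16)
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(0.42, 1), 0.4)
  expect_equal(round_half_away(0.845, 2), 0.85)
})

test_that("2 x max-SD derivation from raw histories matches hand-computed SDs", {
  # two groups with known sample SDs sqrt(2) and 2*sqrt(2)
  h <- data.frame(machine = rep(c("A", "B"), each = 2),
                  protocol = "p", metric = "hu_water",
                  value = c(0, 2, 0, 4), segment = 1L)
  ts <- derive_tolerances(h)
  expect_equal(ts$bound, round_half_away(2 * sd(c(0, 4))))  # = 6
  expect_equal(ts$mode, "delta")
  expect_equal(ts$provenance, "derived-2xmaxSD")
  # permutation invariance
  ts2 <- derive_tolerances(h[sample(nrow(h)), ])
  expect_equal(ts2$bound, ts$bound)
  # scale equivariance before rounding (values chosen so the rounded
  # bound is exact at both scales: SD 1 -> band 2, SD 10 -> band 20)
  h3 <- data.frame(machine = "A", protocol = "p", metric = "hu_water",
                   value = c(0, sqrt(2)), segment = 1L)
  t3 <- derive_tolerances(h3)
  h3$value <- h3$value * 10
  t3s <- derive_tolerances(h3)
  expect_equal(t3s$bound, 10 * t3$bound)
  expect_equal(t3$bound, 2)
})

test_that("degenerate and short histories are handled explicitly", {
  h <- data.frame(machine = "A", protocol = "p", metric = "hu_water",
                  value = c(5, 5, 5), segment = 1L)
  ts <- derive_tolerances(h)
  expect_equal(ts$bound, 0)
  expect_true(ts$degenerate)
  # a metric whose every group has one record is skipped with a reason
  h2 <- rbind(h, data.frame(machine = "A", protocol = "p",
                            metric = "distance", value = 100,
                            segment = 1L))
  ts2 <- derive_tolerances(h2)
  expect_false("distance" %in% ts2$metric)
  expect_equal(attr(ts2, "skipped")$metric, "distance")
  # duplicates of identical values add nothing
  expect_equal(derive_tolerances(rbind(h, h))$bound, 0)
  expect_error(derive_tolerances(h2[4, ]), "no group")
})

test_that("segments split SD groups: a reset isolates a step change", {
  h <- data.frame(machine = "A", protocol = "p", metric = "hu_acrylic",
                  value = c(100, 101, 100, 125, 126, 125),
                  segment = rep(1:2, each = 3))
  ts <- derive_tolerances(h)
  # within-segment SDs are small; without segments the SD would be ~13
  expect_lte(ts$bound, 2)
})

test_that("baselines: first session, first-k mean, and segment retirement", {
  seg <- data.frame(metric = rep(c("hu_water", "uniformity"), 3),
                    value = c(0, 10, 2, 12, 4, 14),
                    date = rep(c("20200101", "20200401", "20200701"),
                               each = 2))
  b1 <- establish_baseline(seg)
  expect_equal(b1$baseline[b1$metric == "hu_water"], 0)
  b3 <- establish_baseline(seg, k = 3)
  expect_equal(b3$baseline[b3$metric == "hu_water"], mean(c(0, 2, 4)))
  expect_equal(b3$baseline[b3$metric == "uniformity"], 12)
  expect_error(establish_baseline(seg[0, ]), "empty")
  # new segment: baselines re-established from its own first session
  seg2 <- data.frame(metric = "hu_water", value = 25, date = "20210101")
  b_new <- establish_baseline(seg2, reason = "maintenance")
  expect_equal(b_new$baseline, 25)
  expect_equal(b_new$reason, "maintenance")
})

test_that("evaluation: boundary-inclusive pass, action outside, idempotent", {
  ses <- data.frame(metric = c("hu_acrylic", "distance",
                               "highcontrast_lpcm", "uniformity"),
                    value = c(133, 100.8, 5, 4),
                    evaluable = TRUE)
  base <- data.frame(metric = c("hu_acrylic", "distance",
                                "highcontrast_lpcm"),
                     baseline = c(120, 100.0, 6))
  tol <- tolerance_from_sds(data.frame(
    metric = c("hu_acrylic", "distance", "highcontrast_lpcm"),
    sd = c(6, 0.5, 0.5)))             # bands 12, 1.0, 1
  rep1 <- evaluate_session(ses, base, tol)
  # 13 HU drift against +/-12 -> action
  expect_equal(rep1$status[rep1$metric == "hu_acrylic"], "action")
  # 100.8 vs nominal within +/-1.0 -> pass
  expect_equal(rep1$status[rep1$metric == "distance"], "pass")
  # a 1 lp/cm drop equals the band -> boundary passes
  expect_equal(rep1$status[rep1$metric == "highcontrast_lpcm"], "pass")
  # idempotent and side-effect free
  expect_identical(evaluate_session(ses, base, tol), rep1)
  # missing baseline -> not-evaluable
  rep2 <- evaluate_session(ses, base[-1, ], tol)
  expect_equal(rep2$status[rep2$metric == "hu_acrylic"], "not-evaluable")
  # absolute mode, boundary inclusive
  abs_tol <- acr_absolute_limits()
  rep3 <- evaluate_session(ses, NULL, abs_tol)
  expect_equal(rep3$status[rep3$metric == "uniformity"], "pass")
  ses$value[ses$metric == "uniformity"] <- 5
  expect_equal(evaluate_session(ses, NULL, abs_tol)$status[
    abs_tol$metric == "uniformity"], "pass")
  ses$value[ses$metric == "uniformity"] <- 5.2
  expect_equal(evaluate_session(ses, NULL, abs_tol)$status[
    abs_tol$metric == "uniformity"], "action")
})

test_that("history CSV round-trips and malformed rows are skipped", {
  ses <- run_session(series_ct())
  f <- tempfile(fileext = ".csv")
  append_history(ses, f, segment = 1L)
  append_history(ses, f, segment = 2L)
  h <- read_history(f)
  expect_equal(nrow(h), 2 * sum(ses$metrics$evaluable))
  expect_setequal(unique(h$segment), 1:2)
  cat("machX,CT,p,20200101,hu_water,notanumber,1\n", file = f,
      append = TRUE)
  expect_warning(h2 <- read_history(f), "1 malformed")
  expect_equal(nrow(h2), nrow(h))
  unlink(f)
})

test_that("tolerance sets round-trip through YAML", {
  ts <- tolerances_cbct()
  f <- tempfile(fileext = ".yaml")
  write_tolerances(ts, f)
  ts2 <- read_tolerances(f)
  expect_equal(ts2$metric, ts$metric)
  expect_equal(ts2$bound, ts$bound)
  expect_equal(ts2$mode, ts$mode)
  unlink(f)
})

test_that("trend report segments a stepped history and plots it", {
  set.seed(31)
  vals <- c(rnorm(4, 120, 1), rnorm(4, 145, 1))
  h <- data.frame(machine = "linac1", modality = "CBCT", protocol = "p",
                  date = sprintf("202%d0%d01", rep(0:1, each = 4),
                                 c(1, 4, 7, 9)),
                  metric = "hu_acrylic", value = vals,
                  segment = rep(1:2, each = 4))
  tr <- trend_report(h)
  expect_equal(nrow(tr$summary), 2)      # one row per segment
  expect_true(all(tr$summary$sd < 3))    # each segment internally tight
  expect_equal(tr$summary$n, c(4, 4))
  # two machines produce separate series rows
  h2 <- h; h2$machine <- "linac2"
  tr2 <- trend_report(rbind(h, h2))
  expect_equal(nrow(tr2$summary), 4)
  grDevices::pdf(NULL)
  expect_silent(plot(tr2, metric = "hu_acrylic"))
  grDevices::dev.off()
  expect_error(trend_report(h[0, ]), "empty")
  expect_error(plot(tr, metric = "absent_metric"), "no records")
})
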