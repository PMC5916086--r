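test_that("nuclear enrichment is the per-frame nucleus-cytoplasm difference", {
  df <- makeTraceDf(cells = "a", times = c(-2, 0, 5), channels = "RFP",
                    nuclear = function(c, ch, t) c(10, 12, 15)[match(t, c(-2, 0, 5))],
                    cyto = function(c, ch, t) 10)
  e <- nuclearEnrichment(TraceTable(df), "RFP")
  expect_equal(e$enrichment, c(0, 2, 5))
  # identical compartments give an all-zero series
  df0 <- makeTraceDf(cells = "a", times = c(-2, 0, 5), channels = "RFP",
                     nuclear = function(c, ch, t) 7, cyto = function(c, ch, t) 7)
  expect_equal(nuclearEnrichment(TraceTable(df0), "RFP")$enrichment,
               rep(0, 3))
  # channel without cytoplasmic means errors by name
  dfn <- df; dfn$cytoplasmic_mean <- NA_real_
  expect_error(nuclearEnrichment(TraceTable(dfn), "RFP"), "RFP")
})

test_that("preprocessing smooths, subtracts basal, and is offset-invariant", {
  times <- c(-6, -4, -2, 0, 5, 10, 15, 20, 25)
  # constant series corrects to all zeros
  pp <- preprocessTrace(rep(4, 9), times)
  expect_equal(pp$corrected, rep(0, 9))
  # step of 3 at the second post-stimulus frame, hand-computed moving average:
  # smoothed = 0,0,0,0,1,2,3,3,3; basal = mean over frames -4,-2,0 = 0
  x <- c(0, 0, 0, 0, 0, 3, 3, 3, 3)
  pp2 <- preprocessTrace(x, times)
  expect_equal(pp2$smoothed, c(0, 0, 0, 0, 1, 2, 3, 3, 3))
  expect_equal(pp2$basal, 0)
  expect_equal(pp2$corrected[7:9], rep(3, 3))
  # adding a constant to the raw series leaves the corrected trace unchanged
  pp3 <- preprocessTrace(x + 11.5, times)
  expect_equal(pp3$corrected, pp2$corrected)
  # too few pre-stimulus frames
  expect_error(preprocessTrace(1:5, c(-2, 0, 5, 10, 15)),
               "insufficient baseline")
})

test_that("expression output is the post-stimulation maximum, unclamped", {
  times <- c(-4, -2, 0, 5, 10, 15)
  ct <- makeCorrected(rbind(c(0, 0, 0, 2, 5, 7),
                            c(0, 0, 0, -1, -3, -2)), times)
  out <- expressionOutput(ct)
  expect_equal(unname(out), c(7, -1))   # negative max not clamped
})

test_that("population output uses the mean trace, bounded by Jensen", {
  times <- c(-4, -2, 0, 5, 10)
  # identical cells: population output equals the single-cell output
  ct1 <- makeCorrected(rbind(c(0, 0, 0, 1, 6), c(0, 0, 0, 1, 6)), times)
  expect_equal(populationOutput(ct1), 6)
  # aligned peaks 10 and 0 average to 5
  ct2 <- makeCorrected(rbind(c(0, 0, 0, 2, 10), c(0, 0, 0, 0, 0)), times)
  expect_equal(populationOutput(ct2), 5)
  # cells peaking at different frames: population output below mean of outputs
  ct3 <- makeCorrected(rbind(c(0, 0, 0, 8, 0), c(0, 0, 0, 0, 8)), times)
  expect_lt(populationOutput(ct3),
            mean(expressionOutput(ct3)))
})

test_that("expressing flag uses an inclusive 20% boundary", {
  expect_false(classifyExpressing(c(a = 0.19 * 10), 10)[["a"]])
  expect_true(classifyExpressing(c(a = 0.20 * 10), 10)[["a"]])
  expect_error(classifyExpressing(c(a = 1), 0), "non-responsive")
  # flag counts equal a brute recount on a simulated population
  sim <- simulatePopulation(simPreset("fig1f", n_cells = 80, seed = 5))
  ct <- correctTraces(sim$traces, "YFP")
  out <- expressionOutput(ct); pop <- populationOutput(ct)
  flags <- classifyExpressing(out, pop)
  expect_equal(sum(flags), sum(out >= 0.2 * pop))
})

test_that("response time is the first post-stimulus frame exceeding 0.2", {
  times <- c(-4, -2, 0, 5, 10, 15, 20, 25)
  # normalized trace crosses 0.2 strictly between frames 15 and 20
  corr <- c(0, 0, 0, 0.05, 0.1, 0.19, 0.3, 1) * 10
  expect_equal(responseTime(corr, times, 10), 20)
  # exceeding only before stimulation gives no response time
  corr2 <- c(3, 3, 3, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_true(is.na(responseTime(corr2, times, 10)))
  # non-positive output is a contract error
  expect_error(responseTime(corr, times, 0), "expressing")
})

test_that("gain and time-shift behave as the relative threshold implies", {
  sim <- simulatePopulation(simPreset("fig1f", n_cells = 50, seed = 11))
  tab <- sim$traces
  g <- 3.7
  df <- traceData(tab)
  sel <- df$channel == "YFP"
  df$nuclear_mean[sel] <- df$nuclear_mean[sel] * g
  df$cytoplasmic_mean[sel] <- df$cytoplasmic_mean[sel] * g
  scaled <- TraceTable(df)
  t1 <- computeTiming(correctTraces(tab, "YFP"))
  t2 <- computeTiming(correctTraces(scaled, "YFP"))
  expect_equal(t2$expression_output, g * t1$expression_output)
  expect_equal(t2$expressing, t1$expressing)
  expect_equal(t2$response_time, t1$response_time)

  # shifting a corrected trace by one frame shifts the response time with it
  times <- c(-4, -2, 0, 5, 10, 15, 20, 25)
  corr <- c(0, 0, 0, 0.1, 0.3, 0.8, 1, 1) * 8
  shifted <- c(0, 0, 0, 0, 0.1, 0.3, 0.8, 1) * 8
  expect_equal(responseTime(shifted, times, 8),
               responseTime(corr, times, 8) + 5)
})

test_that("paired delays carry the test-minus-reference sign convention", {
  mk <- function(ids, rt) data.frame(cell_id = ids, channel = "x",
                                     expression_output = 1,
                                     expressing = TRUE, response_time = rt)
  d <- pairedDelay(mk(c("a", "b", "c"), c(20, 45, NA)),
                   mk(c("a", "b", "c"), c(20, 20, 15)))
  expect_equal(d$n_dual, 2)              # cell c lacks a test RT
  expect_equal(sort(d$deltas$delta), c(0, 25))
  expect_equal(d$fraction_positive, 1)   # tie excluded from both sides
  # zero dual-expressing cells yield an explicitly empty set
  d0 <- pairedDelay(mk("a", NA), mk("a", 10))
  expect_true(d0$empty)
})

test_that("sign test matches its closed forms", {
  expect_equal(signTest(c(rep(1, 5), rep(-1, 5))), 1.0)
  expect_equal(signTest(rep(1, 10)), 0.001953125)
  expect_equal(signTest(c(rep(1, 8), rep(-1, 2))), 0.109375)
  expect_warning(p0 <- signTest(rep(0, 4)), "zero")
  expect_equal(p0, 1)
})

test_that("kinase activity is the cytoplasm-to-nucleus ratio", {
  df <- makeTraceDf(cells = "a", times = c(-2, 0, 5), channels = "YFP",
                    nuclear = function(c, ch, t) 10,
                    cyto = function(c, ch, t) c(5, 10, 20)[match(t, c(-2, 0, 5))])
  act <- kinaseActivity(TraceTable(df), "YFP")
  expect_equal(act$activity, c(0.5, 1, 2))
})
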