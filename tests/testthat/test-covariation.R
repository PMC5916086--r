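test_that("mean-trace normalization divides by the population peak", {
  times <- c(-4, -2, 0, 5, 10)
  # single cell is its own mean: peak normalizes to 1
  ct1 <- makeCorrected(rbind(c(0, 0, 0, 4, 8)), times)
  expect_equal(max(normalizeByMeanTrace(ct1)), 1)
  # aligned peaks 4 and 12: mean-trace peak 8, normalized peaks 0.5 and 1.5
  ct2 <- makeCorrected(rbind(c(0, 0, 0, 2, 4), c(0, 0, 0, 6, 12)), times)
  nm <- normalizeByMeanTrace(ct2)
  expect_equal(nm[, 5], c(c01 = 0.5, c02 = 1.5))
  # scaling every cell by g leaves normalized values unchanged
  ct3 <- makeCorrected(2.5 * ct2@corrected, times)
  expect_equal(normalizeByMeanTrace(ct3), normalizeByMeanTrace(ct2))
})

test_that("min-max normalization is affine-invariant with open range", {
  times <- c(-4, -2, 0, 5, 10)
  mat <- rbind(c(2, 2, 2, 6, 10), c(2, 2, 2, 6, 10))
  ct <- makeCorrected(mat, times)
  nm <- minmaxNormalize(ct, use = "corrected")
  expect_equal(nm[1, 4], 0.5)            # midpoint of population span [2,10]
  # a cell below the population minimum maps to a negative value
  ct2 <- makeCorrected(rbind(mat, c(0, 0, 0, 0, 0)), times)
  expect_lt(min(minmaxNormalize(ct2, use = "corrected")), 0)
  # affine transform of all raw values cancels
  ct3 <- makeCorrected(3 * mat + 7, times)
  expect_equal(minmaxNormalize(ct3, use = "corrected"), nm)
  # constant population trace is degenerate
  ct4 <- makeCorrected(matrix(1, 2, 5), times)
  expect_error(minmaxNormalize(ct4, use = "corrected"), "degenerate")
})

test_that("correlation trajectory runs along the diagonal for twin channels", {
  sim <- simulatePopulation(simPreset("early_pair", n_cells = 150, seed = 2))
  tab <- applyQC(sim$traces)$table
  ctr <- correctTraces(tab, "RFP"); cty <- correctTraces(tab, "YFP")
  tr <- correlationTrajectory(cty, ctr)
  expect_equal(tr$time, cty@times)
  expect_lt(max(abs(tr$y - tr$x)), 0.1)  # same promoter: x = y within noise
  expect_gt(tr$x[nrow(tr)], 0.9)         # ends near (1,1)
  # a delayed test reporter bows the trajectory below the diagonal
  siml <- simulatePopulation(simPreset("late_pair", n_cells = 150, seed = 2))
  tabl <- applyQC(siml$traces)$table
  trl <- correlationTrajectory(correctTraces(tabl, "YFP"),
                               correctTraces(tabl, "RFP"))
  mid <- trl$time > 10 & trl$time < 50
  expect_true(all(trl$y[mid] < trl$x[mid]))
})

test_that("diagonal-offset test equals a hand-computed Welch test", {
  # offsets d = (y - x)/sqrt(2) for two hand-sized strains; the frozen
  # p-value was computed from the explicit Welch t and Welch-Satterthwaite
  # df formulas
  res <- diagonalOffsetTest(test_x = c(0.10, 0.30, 0.20),
                            test_y = c(0.50, 0.40, 0.60),
                            ref_x = c(1.1, 2.3, 3.0),
                            ref_y = c(2.0, 4.1, 8.6))
  expect_equal(res$p, 0.2284773646, tolerance = 1e-9)
  expect_equal(res$tier, "none")
  # constant identical offsets in both strains: zero variance, p = 1
  expect_warning(same <- diagonalOffsetTest(c(0, 1), c(1, 2),
                                            c(5, 6), c(6, 7)),
                 "zero variance")
  expect_equal(same$p, 1)
  # shift far beyond the pooled sd reaches the strongest tier
  set.seed(1)
  x <- rnorm(50, 0, 0.01)
  res2 <- diagonalOffsetTest(x, x + 1 + rnorm(50, 0, 0.01),
                             x, x + rnorm(50, 0, 0.01))
  expect_lt(res2$p, 1e-6)
  expect_equal(res2$tier, "p<1e-6")
})

test_that("CPV matches its algebra and the loop-based moments oracle", {
  set.seed(7)
  r <- rlnorm(400, 0, 0.4)
  expect_equal(cpv(r, r), 0)             # identical reporters
  # independent draws from one distribution approach CPV = 1
  y_ind <- rlnorm(4000, 0, 0.4)
  r_ind <- rlnorm(4000, 0, 0.4)
  expect_equal(cpv(r_ind, y_ind), 1, tolerance = 0.1)
  # shared affine transform cancels exactly
  y <- r * exp(rnorm(400, 0, 0.1))
  base <- cpv(r, y)
  expect_equal(cpv(2.3 * r + 0.7, 2.3 * y + 0.7), base,
               tolerance = 1e-12)
  expect_equal(cpv(y, r), base)          # symmetry
  # oracle equivalence on random fixtures
  for (k in 1:5) {
    rr <- rnorm(60, 5, 2); yy <- rr + rnorm(60, 0, 1)
    expect_equal(cpv(rr, yy), bruteCPV(rr, yy), tolerance = 1e-12)
  }
})

test_that("CPV series aggregates replicates and flags grid mismatches", {
  sim <- simulatePopulation(simPreset("early_pair", n_cells = 80, seed = 9))
  tab <- applyQC(sim$traces)$table
  rep1 <- list(r = correctTraces(tab, "RFP"), y = correctTraces(tab, "YFP"))
  cs <- cpvSeries(list(rep1, rep1, rep1))
  expect_s4_class(cs, "CPVSeries")
  expect_equal(cpvSummary(cs)$sd_cpv, rep(0, length(rep1$r@times)))
  bad <- rep1
  bad$r@times <- bad$r@times + 1; bad$y@times <- bad$y@times + 1
  expect_error(cpvSeries(list(rep1, bad)), "grids")
})

test_that("raising intrinsic noise raises pre-stimulus CPV monotonically", {
  pre_cpv <- vapply(c(0.05, 0.15, 0.4), function(si) {
    p <- simPreset("early_pair", n_cells = 800, seed = 31)
    p$sigma_I <- si
    sim <- simulatePopulation(p)
    tab <- applyQC(sim$traces)$table
    s <- cpvSummary(cpvSeries(list(list(r = correctTraces(tab, "RFP"),
                                        y = correctTraces(tab, "YFP")))))
    s$mean_cpv[s$time == 0]
  }, numeric(1))
  expect_true(all(diff(pre_cpv) > 0))
})
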