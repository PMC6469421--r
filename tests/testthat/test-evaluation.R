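bigIdx <- function(n = 1087, sy = "2016-17:Optimal Bed") {
  buildRecordIndex(data.frame(site_year = sy,
                              line_id = sprintf("L%04d", seq_len(n))))
}

test_that("within-site-year partitions have floor(0.8 n) training records", {
  idx <- bigIdx(1087)
  parts <- makePartitions("within_site_year", idx, nPartitions = 3,
                          masterSeed = 99)
  expect_length(parts, 3)
  for (p in parts) {
    expect_equal(length(p$trn), 869)   # floor(0.8 * 1087)
    expect_equal(length(p$tst), 218)
    expect_length(intersect(p$trn, p$tst), 0)
    expect_setequal(c(p$trn, p$tst), recordTable(idx)$record_id)
  }
  # determinism: same (scheme, focal, replicate, master seed) twice
  parts2 <- makePartitions("within_site_year", idx, nPartitions = 3,
                           masterSeed = 99)
  expect_identical(parts, parts2)
  # different master seed gives different splits
  parts3 <- makePartitions("within_site_year", idx, nPartitions = 3,
                           masterSeed = 100)
  expect_false(identical(parts[[1]]$tst, parts3[[1]]$tst))
})

test_that("cross schemes hold out exactly the focal unit", {
  ph <- expand.grid(cycle = c("2013-14", "2014-15"),
                    treatment = c("Optimal Bed", "Severe Drought", "Heat"),
                    line_id = sprintf("L%03d", 1:30),
                    stringsAsFactors = FALSE)
  ph$site_year <- siteYearLabel(ph$cycle, ph$treatment)
  idx <- buildRecordIndex(ph)
  pAcross <- makePartitions("within_cycle_across_treatments", idx,
                            nPartitions = 2, masterSeed = 4,
                            focal = "2013-14:Heat")
  for (p in pAcross) {
    tstSy <- unique(splitSiteYear(sub("/.*$", "", p$tst))$treatment)
    expect_equal(tstSy, "Heat")
    expect_equal(length(p$tst), 30 - floor(0.2 * 30))
    # training includes all records of the other treatments in the cycle
    expect_true(all(recordTable(idx)$record_id[
      grepl("^2013-14:(Optimal Bed|Severe Drought)/", recordTable(idx)$record_id)] %in% p$trn))
    # other cycles appear nowhere
    expect_false(any(grepl("^2014-15", c(p$trn, p$tst))))
  }
  pCycle <- makePartitions("across_cycles_within_treatment", idx,
                           nPartitions = 2, masterSeed = 4,
                           focal = "2014-15:Heat")
  for (p in pCycle) {
    expect_true(all(grepl("^2014-15:Heat/", p$tst)))
    expect_true(all(recordTable(idx)$record_id[
      grepl("^2013-14:Heat/", recordTable(idx)$record_id)] %in% p$trn))
    expect_false(any(grepl("Optimal Bed|Severe Drought", c(p$trn, p$tst))))
  }
  # check lines never enter the test set
  pChk <- makePartitions("within_site_year", idx, nPartitions = 2,
                         masterSeed = 4, focal = "2013-14:Heat",
                         checkLines = c("L001", "L002"))
  for (p in pChk)
    expect_false(any(grepl("/L00[12]$", p$tst)))
})

test_that("prediction accuracy is Pearson r with the documented edge cases", {
  v <- c(a = 1, b = 2, c = 4, d = 3, e = 5)
  expect_equal(predictionAccuracy(v, v), 1.0)
  expect_equal(predictionAccuracy(-v, v), -1.0)
  # hand-computed 5-pair oracle
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1); y <- c(0.8, 2.9, 2.6, 4.2, 4.9)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(predictionAccuracy(setNames(x, letters[1:5]),
                                  setNames(y, letters[1:5])), byHand)
  # affine invariance
  expect_equal(predictionAccuracy(setNames(2 * x + 10, letters[1:5]),
                                  setNames(y, letters[1:5])), byHand)
  expect_error(predictionAccuracy(setNames(rep(1, 5), letters[1:5]),
                                  setNames(y, letters[1:5])),
               "constant")
  expect_error(predictionAccuracy(setNames(x[1:2], letters[1:2]),
                                  setNames(y[1:2], letters[1:2])),
               "at least 3")
})

test_that("battery bookkeeping: rows, determinism, and absent scopes with reasons", {
  sim <- smallSim()
  bundle <- suppressMessages(prepareBundleFromSim(sim, scopes = c("ALL", "VEG")))
  res <- suppressMessages(runBattery(bundle, c("G", "A"),
    scheme = "within_site_year", nPartitions = 2, masterSeed = 6,
    method = "em_reml", focal = c("2013-14:Optimal Bed")))
  expect_equal(nrow(res), 2 * 2 * 2)  # models x partitions x variants
  expect_true(all(is.finite(res$r)))
  res2 <- suppressMessages(runBattery(bundle, c("G", "A"),
    scheme = "within_site_year", nPartitions = 2, masterSeed = 6,
    method = "em_reml", focal = c("2013-14:Optimal Bed")))
  expect_identical(res, res2)
  smry <- summarizeAccuracy(res)
  expect_equal(nrow(smry), 4)
  expect_equal(unique(smry$n_partitions), 2)
  # a missing spectral stage is reported as an absent cell with its reason
  noVeg <- names(bundle$kernels$H$VEG)
  sansVeg <- bundle
  sansVeg$kernels$H$VEG <- bundle$kernels$H$VEG[0]
  resVeg <- suppressMessages(runBattery(sansVeg, "H.VEG",
    scheme = "within_site_year", nPartitions = 2, masterSeed = 6,
    method = "em_reml", focal = "2013-14:Optimal Bed"))
  expect_true(all(is.na(resVeg$r)))
  expect_match(resVeg$reason[1], "coverage|scope|H")
})

test_that("band-yield and treatment-treatment correlations behave as documented", {
  set.seed(12)
  gy <- setNames(rnorm(60, 4), sprintf("L%02d", 1:60))
  B <- cbind(b1 = gy + rnorm(60, 0, 1e-8), b2 = rnorm(60))
  rownames(B) <- names(gy)
  r <- bandYieldCorrelations(B, gy)
  expect_equal(unname(r["b1"]), 1, tolerance = 1e-6)
  expect_lt(abs(r["b2"]), 0.5)
  expect_error(bandYieldCorrelations(B[1:2, ], gy[1:2]), "coverage")
  # default simulated band set yields one correlation per band (62)
  sim <- smallSim()
  bundle <- suppressMessages(prepareBundleFromSim(sim, scopes = "ALL"))
  sy <- "2013-14:Optimal Bed"
  gyB <- bundle$gyBlues[grep(paste0("^", sy, "/"), names(bundle$gyBlues))]
  names(gyB) <- sub("^.*/", "", names(gyB))
  rr <- bandYieldCorrelations(bundle$bandBlues[[paste(sy, "ALL", sep = "|")]],
                              gyB)
  expect_length(rr, 62)
  # treatment-by-treatment matrix is symmetric with unit diagonal
  byTrt <- list(
    "Optimal Bed" = gyB,
    "Severe Drought" = setNames(0.6 * gyB + rnorm(length(gyB), 0, 0.5),
                                names(gyB)))
  tc <- treatmentCorrelations(byTrt)
  expect_equal(diag(tc), c("Optimal Bed" = 1, "Severe Drought" = 1))
  expect_equal(tc[1, 2], tc[2, 1])
  expect_gt(tc[1, 2], 0.2)
})

test_that("configured band-yield signal is recovered from generated spectra", {
  # spectra built to carry a known structural correlation with genetic value
  # per-plot-date band noise sd 3 averages over 3 reps x 3 dates to sd 1,
  # so the structural loading below targets r ~ 0.4 at the peak band
  cfg <- makeScenario("baseline", nFamilies = 150, sibsPerFamily = 2,
                      nFounders = 40, nMarkers = 400, cycles = "2013-14",
                      treatments = "Optimal Bed", masterSeed = 77,
                      nBands = 12, gyDthdSlope = 0,
                      stageLoadings = list(
                        VEG = c(a = 0.44, b = 0, c = 0),
                        HEAD = c(a = 0.44, b = 0, c = 0),
                        GF = c(a = 0.44, b = 0, c = 0)),
                      bandNoiseSd = 3, nDatesPerStage = c(VEG = 1, HEAD = 1,
                                                          GF = 1))
  sim <- suppressMessages(simulateDataset(cfg))
  plots <- sim$phenotypes
  bb <- suppressMessages(fitBandBlues(sim$spectra, plots, scope = "ALL"))
  gy <- suppressMessages(fitTraitBlues(plots, "gy", "fixed"))$blues
  r <- bandYieldCorrelations(bb, gy)
  wG <- sim$truth$bandLoadings$wG
  gyCor <- cor(gy, sim$truth$breedingValues[names(gy)])
  target <- 0.44 * max(wG) / sqrt((0.44 * max(wG))^2 + 1) * gyCor
  expect_lt(abs(max(r) - target), 0.1)
})
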