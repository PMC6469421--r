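#' Configuration for the synthetic multi-environment trial generator
#'
#' Defaults emulate the structure of a large bread-wheat yield evaluation:
#' four breeding cycles by five managed treatments (20 site-years), full-sib
#' families averaging two sibs, alpha-lattice trials with three replicates
#' and six incomplete blocks per replicate and about 28 lines per trial,
#' biallelic markers on inbred-derived lines, treatment-level yield means
#' with genotype-by-environment deviations correlated across treatments, a
#' phenology layer (days to heading/maturity), and per-time-point
#' hyperspectral reflectance in 62 bands whose loadings on genetic value and
#' G-by-E deviations grow over developmental stages.
#'
#' Yield variance layers default to sigma2_g = 0.2 (t/ha)^2 with residual
#' sigma2_e = 0.15 at three replicates (entry-mean heritability 0.8, inside
#' the 0.58-0.94 range typical of such trials) and modest trial/replicate/
#' block variances.
#'
#' @param nFamilies full-sib families per breeding cycle.
#' @param sibsPerFamily sibs per family (default 2).
#' @param nFounders founder pool size per cycle.
#' @param nMarkers biallelic markers.
#' @param selfingGenerations selfing generations after the biparental cross
#'   (residual heterozygosity 0.5^s at segregating loci).
#' @param cycles breeding-cycle labels.
#' @param treatments managed-treatment labels.
#' @param reps,blocksPerRep,linesPerTrial alpha-lattice layout.
#' @param sigma2_g,sigma2_gE,sigma2_t,sigma2_r,sigma2_b,sigma2_e yield
#'   variance components ((t/ha)^2).
#' @param gxeCor correlation of G-by-E deviations between treatments.
#' @param treatmentMeans named mean yields (t/ha).
#' @param dthdMean named mean days to heading per treatment.
#' @param dthdGenSd,dthdEnvSd genetic and plot-level sd of days to heading.
#' @param dtmtOffset,dtmtSd days from heading to maturity (mean, sd).
#' @param gyDthdSlope regression of yield on the standardized genetic
#'   days-to-heading deviation (t/ha per sd); nonzero values couple yield to
#'   phenology as under terminal stress.
#' @param nBands number of reflectance bands.
#' @param stageLoadings per-stage loadings (a = genetic value, b = G-by-E
#'   deviation, c = phenology) of the spectral signal.
#' @param bandCorLength squared-exponential correlation length of the band
#'   noise (band-index units).
#' @param bandNoiseSd band noise sd (standardized scale).
#' @param specAmp amplitude converting standardized spectral signal to
#'   reflectance units.
#' @param nDatesPerStage named integer vector: phenotyping time-points per
#'   stage.
#' @param dropVegCycle optional cycle label whose VEG time-points are dropped
#'   (emulating a season with no early flights).
#' @param masterSeed master seed; the full dataset is reproducible from it.
#' @param ... overrides ignored by name matching are an error.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(nFamilies = 546, sibsPerFamily = 2, nFounders = 200,
                      nMarkers = 8519, selfingGenerations = 4,
                      cycles = c("2013-14", "2014-15", "2015-16", "2016-17"),
                      treatments = defaultTreatments(),
                      reps = 3, blocksPerRep = 6, linesPerTrial = 28,
                      sigma2_g = 0.2, sigma2_gE = 0.08, sigma2_t = 0.05,
                      sigma2_r = 0.02, sigma2_b = 0.02, sigma2_e = 0.15,
                      gxeCor = 0.5,
                      treatmentMeans = c("Optimal Bed" = 6.0,
                                         "Optimal Flat" = 5.8,
                                         "Moderate Drought" = 3.5,
                                         "Severe Drought" = 2.0,
                                         "Heat" = 3.0),
                      dthdMean = c("Optimal Bed" = 80, "Optimal Flat" = 80,
                                   "Moderate Drought" = 75,
                                   "Severe Drought" = 70, "Heat" = 65),
                      dthdGenSd = 4, dthdEnvSd = 1,
                      dtmtOffset = 35, dtmtSd = 2, gyDthdSlope = -0.05,
                      nBands = 62,
                      stageLoadings = list(
                        VEG = c(a = 0.25, b = 0.15, c = 0.35),
                        HEAD = c(a = 0.55, b = 0.45, c = 0.35),
                        GF = c(a = 0.85, b = 0.70, c = 0.35)),
                      bandCorLength = 8, bandNoiseSd = 1, specAmp = 0.05,
                      nDatesPerStage = c(VEG = 2, HEAD = 1, GF = 1),
                      dropVegCycle = NULL, masterSeed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$nFamilies >= 1, cfg$sibsPerFamily >= 1, cfg$nMarkers >= 1,
            cfg$reps >= 1, cfg$blocksPerRep >= 1)
  vars <- c("sigma2_g", "sigma2_gE", "sigma2_t", "sigma2_r", "sigma2_b",
            "sigma2_e")
  if (any(unlist(cfg[vars]) < 0)) stop("variances must be >= 0")
  missTrt <- setdiff(cfg$treatments, names(cfg$treatmentMeans))
  if (length(missTrt))
    stop("treatmentMeans missing for: ", paste(missTrt, collapse = ", "))
  class(cfg) <- "SimConfig"
  cfg
}

#' Named simulation scenarios
#'
#' \describe{
#'   \item{baseline}{four cycles by five treatments, moderate G-by-E.}
#'   \item{strong_gxe}{inflated G-by-E variance, weaker between-treatment
#'     G-by-E correlation, and stronger spectral loading on the G-by-E
#'     deviations, so interaction-aware models have a clear advantage.}
#'   \item{phenology_confounded}{yield strongly coupled to genetic earliness
#'     and spectra strongly loaded on phenology, so correcting validation
#'     BLUPs for days to heading reduces the accuracy of reflectance-based
#'     models.}
#'   \item{missing_stage}{baseline but with all vegetative-stage time-points
#'     dropped from the first cycle.}
#' }
#'
#' @param name scenario name.
#' @param ... overrides passed to \code{\link{simConfig}} (e.g. scale
#'   reductions for testing).
#' @return a \code{SimConfig}.
#' @export
makeScenario <- function(name = c("baseline", "strong_gxe",
                                  "phenology_confounded", "missing_stage"),
                         ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    baseline = list(),
    strong_gxe = list(sigma2_gE = 0.25, gxeCor = 0.45, bandNoiseSd = 2,
                      stageLoadings = list(
                        VEG = c(a = 0.15, b = 0.45, c = 0.35),
                        HEAD = c(a = 0.33, b = 0.90, c = 0.35),
                        GF = c(a = 0.51, b = 1.10, c = 0.35))),
    phenology_confounded = list(gyDthdSlope = -0.25,
                      stageLoadings = list(
                        VEG = c(a = 0.20, b = 0.10, c = 1.00),
                        HEAD = c(a = 0.35, b = 0.25, c = 1.30),
                        GF = c(a = 0.45, b = 0.35, c = 1.30))),
    missing_stage = list(dropVegCycle = "2013-14"))
  args <- utils::modifyList(base, over)
  do.call(simConfig, args)
}

#' Simulate the breeding population: markers, pedigree, breeding values
#'
#' Founders are inbred lines with allele frequencies drawn Uniform(0.1,
#' 0.9); each full-sib family descends from a biparental cross followed by
#' \code{selfingGenerations} generations of selfing (per-locus Mendelian
#' sampling, residual heterozygosity 0.5^s). Additive breeding values are
#' sums of normal marker effects rescaled so the line variance equals
#' \code{sigma2_g}. Cycles share no lines.
#'
#' @param cfg a \code{SimConfig}.
#' @return list with \code{markers} (a \code{MarkerMatrix} over all progeny
#'   lines), \code{pedigree} (a \code{Pedigree} including founders),
#'   \code{truth} (breeding values, line-to-cycle map, genetic
#'   days-to-heading deviations).
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(mixSeed(cfg$masterSeed, "population"))
  nLines <- cfg$nFamilies * cfg$sibsPerFamily
  hetProb <- 0.5^cfg$selfingGenerations
  allLines <- character(0)
  lineCycle <- character(0)
  codes <- NULL
  pedRows <- list()
  for (cy in cfg$cycles) {
    p <- runif(cfg$nMarkers, 0.1, 0.9)
    founders <- matrix(2 * rbinom(cfg$nFounders * cfg$nMarkers, 1, rep(p, each = cfg$nFounders)),
                       nrow = cfg$nFounders)
    fNames <- sprintf("F%s_%03d", gsub("-", "", cy), seq_len(cfg$nFounders))
    rownames(founders) <- fNames
    for (f in fNames)
      pedRows[[length(pedRows) + 1L]] <-
        data.frame(line_id = f, parent1 = NA_character_,
                   parent2 = NA_character_, stringsAsFactors = FALSE)
    cyCodes <- matrix(NA_real_, nLines, cfg$nMarkers)
    cyNames <- character(nLines)
    row <- 0L
    for (fam in seq_len(cfg$nFamilies)) {
      par <- sample(cfg$nFounders, 2)
      g1 <- founders[par[1], ]
      g2 <- founders[par[2], ]
      seg <- g1 != g2
      for (sib in seq_len(cfg$sibsPerFamily)) {
        row <- row + 1L
        child <- g1
        if (any(seg)) {
          u <- runif(sum(seg))
          child[seg] <- ifelse(u < hetProb, 1,
                               ifelse(runif(sum(seg)) < 0.5, 0, 2))
        }
        cyCodes[row, ] <- child
        nm <- sprintf("L%s_%04d_%d", gsub("-", "", cy), fam, sib)
        cyNames[row] <- nm
        pedRows[[length(pedRows) + 1L]] <-
          data.frame(line_id = nm, parent1 = fNames[par[1]],
                     parent2 = fNames[par[2]], stringsAsFactors = FALSE)
      }
    }
    rownames(cyCodes) <- cyNames
    codes <- rbind(codes, cyCodes)
    allLines <- c(allLines, cyNames)
    lineCycle <- c(lineCycle, rep(cy, nLines))
  }
  effects <- rnorm(cfg$nMarkers, 0, 1)
  bvRaw <- as.numeric(codes %*% effects)
  sdRaw <- sd(bvRaw)
  bv <- if (sdRaw > 0) (bvRaw - mean(bvRaw)) / sdRaw * sqrt(cfg$sigma2_g)
        else rep(0, length(bvRaw))
  names(bv) <- allLines
  dthdGen <- setNames(rnorm(length(allLines), 0, cfg$dthdGenSd), allLines)
  markers <- list(line_ids = allLines,
                  marker_ids = sprintf("M%05d", seq_len(cfg$nMarkers)),
                  codes = codes)
  class(markers) <- "MarkerMatrix"
  colnames(markers$codes) <- markers$marker_ids
  ped <- validatePedigree(do.call(rbind, pedRows))
  truth <- list(breedingValues = bv, lineCycle = setNames(lineCycle, allLines),
                dthdGen = dthdGen)
  list(markers = markers, pedigree = ped, truth = truth)
}

# sowing date of a site-year: optimal/drought late November of the cycle's
# first year; heat late February of the second year
sowingDateFor <- function(cycle, treatment) {
  y1 <- as.integer(substr(cycle, 1, 4))
  if (treatment == "Heat") sprintf("%d-02-20", y1 + 1)
  else sprintf("%d-11-25", y1)
}

#' Simulate the field trials: plots, phenology and hyperspectral time-points
#'
#' Plot yield = treatment mean + breeding value + G-by-E deviation + trial +
#' replicate + block + residual, all drawn at the configured variances; the
#' G-by-E deviations are multivariate normal over treatments with the
#' configured correlation. Days to heading/maturity are recorded for the
#' first replicate only. Per time-point, per band, plot reflectance is a
#' date offset plus stage-dependent loadings on the standardized breeding
#' value, G-by-E deviation and genetic days-to-heading, plus band-correlated
#' noise; time-points are placed from the realized phenology so the
#' configured number falls in each developmental stage. G-by-E deviations
#' are genetic: within a cycle they carry the marker-kinship covariance
#' across lines and the configured correlation across treatments (a
#' Kronecker structure), the generative model assumed by the Hadamard
#' interaction kernel.
#'
#' @param pop output of \code{\link{simulatePopulation}}.
#' @param cfg the same \code{SimConfig}.
#' @return list with \code{phenotypes}, \code{spectra} (validated tables),
#'   \code{sowingDates} (named by site-year), \code{stageTruth} (date-stage
#'   map per site-year), and \code{truth} (breeding values, record-level
#'   G-by-E deviations, noise-free record means, band loadings).
#' @export
simulateTrials <- function(pop, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(mixSeed(cfg$masterSeed, "trials"))
  truth <- pop$truth
  wl <- round(seq(398, 847, length.out = cfg$nBands))
  bandCols <- paste0("b", wl)
  # smooth band loading profiles; blue region attenuated
  att <- pmin(1, pmax(0.15, (wl - 398) / 110))
  wG <- att * exp(-((wl - 730) / 160)^2)
  wGE <- att * exp(-((wl - 560) / 130)^2)
  wD <- att * exp(-((wl - 680) / 110)^2)
  bandIdx <- seq_len(cfg$nBands)
  corBand <- exp(-outer(bandIdx, bandIdx, "-")^2 / (2 * cfg$bandCorLength^2))
  cholBand <- chol(corBand + diag(1e-8, cfg$nBands))
  nT <- length(cfg$treatments)
  Rge <- (1 - cfg$gxeCor) * diag(nT) + cfg$gxeCor
  cholGe <- chol(Rge)
  phenoRows <- list()
  specRows <- list()
  geTruth <- numeric(0)
  recordMean <- numeric(0)
  stageTruth <- list()
  sowingDates <- character(0)
  plotCounter <- 0L
  for (cy in cfg$cycles) {
    lines <- names(truth$lineCycle)[truth$lineCycle == cy]
    nL <- length(lines)
    nTrials <- max(1L, ceiling(nL / cfg$linesPerTrial))
    trialOf <- setNames(sort(rep(seq_len(nTrials), length.out = nL)), lines)
    bvStd <- (truth$breedingValues[lines] - mean(truth$breedingValues[lines]))
    bvStd <- if (sd(bvStd) > 0) bvStd / sd(bvStd) else bvStd
    dthdStd <- (truth$dthdGen[lines] - mean(truth$dthdGen[lines]))
    dthdStd <- if (sd(dthdStd) > 0) dthdStd / sd(dthdStd) else dthdStd
    # kinship-structured G-by-E: cov = sigma2_gE * Kstd (x) Rge
    Kcy <- tcrossprod(scale(pop$markers$codes[lines, , drop = FALSE],
                            scale = FALSE))
    Kcy <- Kcy / max(mean(diag(Kcy)), 1e-12) + diag(1e-6, nL)
    cholK <- chol(Kcy)
    geDev <- t(cholK) %*% matrix(rnorm(nL * nT), nL, nT) %*% cholGe *
      sqrt(cfg$sigma2_gE)
    dimnames(geDev) <- list(lines, cfg$treatments)
    for (trt in cfg$treatments) {
      sy <- siteYearLabel(cy, trt)
      sowing <- sowingDateFor(cy, trt)
      sowingDates[sy] <- sowing
      dthdLine <- cfg$dthdMean[[trt]] + truth$dthdGen[lines]
      trialEff <- rnorm(nTrials, 0, sqrt(cfg$sigma2_t))
      syMean <- cfg$treatmentMeans[[trt]] +
        truth$breedingValues[lines] + geDev[lines, trt] +
        cfg$gyDthdSlope * dthdStd
      names(syMean) <- lines
      geTruth <- c(geTruth,
                   setNames(geDev[lines, trt], paste(sy, lines, sep = "/")))
      recordMean <- c(recordMean,
                      setNames(syMean, paste(sy, lines, sep = "/")))
      plotsOfLine <- vector("list", nL)
      names(plotsOfLine) <- lines
      for (rep_ in seq_len(cfg$reps)) {
        repEff <- rnorm(nTrials, 0, sqrt(cfg$sigma2_r))
        for (tr in seq_len(nTrials)) {
          trLines <- lines[trialOf == tr]
          nB <- min(cfg$blocksPerRep, length(trLines))
          blockOf <- sample(rep(seq_len(nB), length.out = length(trLines)))
          blockEff <- rnorm(nB, 0, sqrt(cfg$sigma2_b))
          gy <- pmax(0, syMean[trLines] + trialEff[tr] + repEff[tr] +
                       blockEff[blockOf] +
                       rnorm(length(trLines), 0, sqrt(cfg$sigma2_e)))
          firstRep <- rep_ == 1
          dthdPlot <- if (firstRep)
            round(dthdLine[trLines] + rnorm(length(trLines), 0, cfg$dthdEnvSd))
          else rep(NA_real_, length(trLines))
          dtmtPlot <- if (firstRep)
            round(dthdPlot + cfg$dtmtOffset +
                    rnorm(length(trLines), 0, cfg$dtmtSd))
          else rep(NA_real_, length(trLines))
          ids <- sprintf("P%07d", plotCounter + seq_along(trLines))
          plotCounter <- plotCounter + length(trLines)
          phenoRows[[length(phenoRows) + 1L]] <- data.frame(
            plot_id = ids, line_id = trLines, cycle = cy, treatment = trt,
            trial = tr, replicate = rep_, block = blockOf, gy = unname(gy),
            lodging = 0, dthd = unname(dthdPlot), dtmt = unname(dtmtPlot),
            is_check = FALSE, stringsAsFactors = FALSE)
          for (i in seq_along(trLines))
            plotsOfLine[[trLines[i]]] <- c(plotsOfLine[[trLines[i]]],
                                           ids[i])
        }
      }
      # phenotyping dates from realized phenology
      headDates <- as.Date(sowing) + dthdLine
      nd <- cfg$nDatesPerStage
      if (!is.null(cfg$dropVegCycle) && cy == cfg$dropVegCycle)
        nd["VEG"] <- 0L
      dates <- c(
        if (nd[["VEG"]] > 0)
          as.Date(quantile(as.numeric(headDates),
                           seq(0.1, 0.35, length.out = nd[["VEG"]])),
                  origin = "1970-01-01") - 2,
        if (nd[["HEAD"]] > 0)
          as.Date(quantile(as.numeric(headDates),
                           seq(0.6, 0.9, length.out = nd[["HEAD"]])),
                  origin = "1970-01-01"),
        if (nd[["GF"]] > 0)
          max(headDates) + seq(5, by = 8, length.out = nd[["GF"]]))
      dates <- sort(unique(as.Date(dates)))
      stageOf <- vapply(dates, function(d) {
        fh <- mean(headDates <= d)
        if (fh < 0.5) "VEG" else if (fh < 1) "HEAD" else "GF"
      }, "")
      stageTruth[[sy]] <- data.frame(date = as.character(dates),
                                     stage = stageOf,
                                     stringsAsFactors = FALSE)
      allPlots <- do.call(rbind, phenoRows[vapply(phenoRows, function(d)
        d$cycle[1] == cy && d$treatment[1] == trt, TRUE)])
      scorePlots <- data.frame(
        plot_id = allPlots$plot_id,
        bv = bvStd[allPlots$line_id],
        ge = (geDev[allPlots$line_id, trt] -
                mean(geDev[, trt])) / max(sd(geDev[, trt]), 1e-12),
        dt = dthdStd[allPlots$line_id], stringsAsFactors = FALSE)
      for (di in seq_along(dates)) {
        load <- cfg$stageLoadings[[stageOf[di]]]
        dateOffset <- rnorm(1, 0, 0.03)
        signal <- outer(scorePlots$bv, wG * load[["a"]]) +
          outer(scorePlots$ge, wGE * load[["b"]]) +
          outer(scorePlots$dt, wD * load[["c"]])
        noise <- matrix(rnorm(nrow(scorePlots) * cfg$nBands), ncol = cfg$nBands) %*%
          cholBand * cfg$bandNoiseSd
        refl <- 0.25 + dateOffset + cfg$specAmp * (signal + noise)
        sdf <- data.frame(plot_id = scorePlots$plot_id,
                          date = as.character(dates[di]),
                          stringsAsFactors = FALSE)
        sdf[bandCols] <- as.data.frame(refl)
        specRows[[length(specRows) + 1L]] <- sdf
      }
    }
  }
  phenotypes <- do.call(rbind, phenoRows)
  spectra <- do.call(rbind, specRows)
  phenotypes <- validatePhenotypes(phenotypes, treatments = cfg$treatments)
  attr(spectra, "wavelengths") <- wl
  attr(spectra, "bandCols") <- bandCols
  simTruth <- list(breedingValues = truth$breedingValues,
                   dthdGen = truth$dthdGen,
                   gxeDeviations = geTruth, recordMeans = recordMean,
                   bandLoadings = list(wG = wG, wGE = wGE, wD = wD))
  list(phenotypes = phenotypes, spectra = spectra,
       sowingDates = sowingDates, stageTruth = stageTruth,
       truth = simTruth, config = cfg)
}

#' Simulate a complete dataset from a configuration
#'
#' Convenience wrapper: population plus trials.
#'
#' @param cfg a \code{SimConfig}.
#' @return the \code{\link{simulateTrials}} output with \code{markers} and
#'   \code{pedigree} added.
#' @export
simulateDataset <- function(cfg) {
  pop <- simulatePopulation(cfg)
  sim <- simulateTrials(pop, cfg)
  sim$markers <- pop$markers
  sim$pedigree <- pop$pedigree
  sim
}

#' Write a simulated dataset as the four standard CSVs plus truth tables
#'
#' Emits phenotypes.csv, spectra.csv, markers.csv, pedigree.csv (readable by
#' the package loaders) and truth_* CSVs with the generator's ground truth.
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTable(sim$phenotypes, file.path(dir, "phenotypes.csv"))
  sdf <- sim$spectra
  write.csv(sdf, file.path(dir, "spectra.csv"), row.names = FALSE, na = "")
  mk <- data.frame(line_id = sim$markers$line_ids,
                   sim$markers$codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(mk, file.path(dir, "markers.csv"), row.names = FALSE, na = "")
  write.csv(as.data.frame(sim$pedigree), file.path(dir, "pedigree.csv"),
            row.names = FALSE, na = "")
  write.csv(data.frame(line_id = names(sim$truth$breedingValues),
                       bv = sim$truth$breedingValues,
                       dthd_gen = sim$truth$dthdGen[names(sim$truth$breedingValues)]),
            file.path(dir, "truth_lines.csv"), row.names = FALSE)
  write.csv(data.frame(record_id = names(sim$truth$gxeDeviations),
                       gxe = sim$truth$gxeDeviations,
                       record_mean = sim$truth$recordMeans[names(sim$truth$gxeDeviations)]),
            file.path(dir, "truth_records.csv"), row.names = FALSE)
  write.csv(data.frame(site_year = names(sim$sowingDates),
                       sowing_date = sim$sowingDates),
            file.path(dir, "sowing_dates.csv"), row.names = FALSE)
  invisible(dir)
}
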