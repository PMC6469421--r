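#' Prepare the full stage-one bundle for prediction batteries
#'
#' Runs the complete stage-wise pipeline on the four input tables:
#' per-site-year grain-yield BLUEs (training responses), grain-yield BLUPs
#' with and without the days-to-heading correction (validation responses,
#' with a lodging covariate whenever lodging was observed), marker QC and the
#' genomic relationship matrix, the pedigree numerator relationship matrix,
#' growth-stage classification of the phenotyping time-points, per-band
#' BLUEs for the requested scopes and the per-site-year spectral
#' relationship matrices, and the site-year-by-genotype record index.
#'
#' @param phenotypes validated plot-record table (all site-years).
#' @param spectra spectral-record table.
#' @param markers a \code{MarkerMatrix}.
#' @param pedigree a \code{Pedigree}.
#' @param sowingDates named character (by site-year) of sowing dates for the
#'   growth-stage classification.
#' @param scopes spectral scopes to prepare ("ALL" and/or "VEG", "HEAD",
#'   "GF"); site-years without dates in a stage simply lack that H block.
#' @param inbredFounders treat pedigree founders as fully inbred.
#' @param hScale standardization denominator for H ("sample" or
#'   "population").
#' @return list (the "bundle") with \code{idx}, \code{gyBlues},
#'   \code{gyBlupsUncorrected}, \code{gyBlupsCorrected} (named by record
#'   id), \code{kernels} (G, A, H by scope), \code{bandBlues},
#'   \code{stageLabels}, \code{qcReport}, \code{checkLines},
#'   \code{heritability} (per site-year GY H2).
#' @export
prepareBundle <- function(phenotypes, spectra, markers, pedigree,
                          sowingDates, scopes = "ALL",
                          inbredFounders = FALSE, hScale = "sample") {
  qc <- qcMarkers(markers)
  G <- genomicRelationship(qc$markers)
  A <- pedigreeRelationship(pedigree, inbredFounders = inbredFounders)
  siteYears <- sort(unique(phenotypes$site_year))
  gyBlues <- numeric(0)
  gyBlupU <- numeric(0)
  gyBlupC <- numeric(0)
  h2 <- setNames(numeric(length(siteYears)), siteYears)
  stageLabels <- list()
  bandBlues <- list()
  H <- lapply(setNames(scopes, scopes), function(s) list())
  bandCols <- attr(spectra, "bandCols")
  for (sy in siteYears) {
    plots <- phenotypes[phenotypes$site_year == sy, , drop = FALSE]
    blue <- fitTraitBlues(plots, "gy", "fixed")
    gyBlues <- c(gyBlues, setNames(blue$blues,
                                   paste(sy, names(blue$blues), sep = "/")))
    blupU <- fitTraitBlues(plots, "gy", "random", covariates = "lodging")
    gyBlupU <- c(gyBlupU, setNames(blupU$blups,
                                   paste(sy, names(blupU$blups), sep = "/")))
    blupC <- fitTraitBlues(plots, "gy", "random",
                           covariates = c("lodging", "dthd"))
    gyBlupC <- c(gyBlupC, setNames(blupC$blups,
                                   paste(sy, names(blupC$blups), sep = "/")))
    h2[sy] <- heritability(blupU$varComp[["sigma2_g"]],
                           blupU$varComp[["sigma2_e"]],
                           nreps = length(unique(plots$replicate)))
    syDates <- sort(unique(spectra$date[spectra$plot_id %in% plots$plot_id]))
    if (length(syDates) == 0) next
    stg <- classifyTimePoints(plots, syDates, sowingDates[[sy]])
    stageLabels[[sy]] <- stg
    for (scope in scopes) {
      bb <- tryCatch(
        fitBandBlues(restoreSpecAttrs(
          spectra[spectra$plot_id %in% plots$plot_id, , drop = FALSE],
          bandCols), plots, scope, stageLabels = stg),
        error = function(e) e)
      if (inherits(bb, "error")) {
        specMessage("site-year %s: scope %s unavailable (%s)", sy, scope,
                    conditionMessage(bb))
        next
      }
      bandBlues[[paste(sy, scope, sep = "|")]] <- bb
      H[[scope]][[sy]] <- spectralRelationship(bb$blues, scale = hScale)
    }
  }
  idx <- buildRecordIndex(
    data.frame(site_year = sub("/[^/]*$", "", names(gyBlues)),
               line_id = sub("^.*/", "", names(gyBlues)),
               stringsAsFactors = FALSE))
  list(idx = idx, gyBlues = gyBlues, gyBlupsUncorrected = gyBlupU,
       gyBlupsCorrected = gyBlupC,
       kernels = list(G = G, A = A, H = H),
       bandBlues = bandBlues, stageLabels = stageLabels,
       qcReport = qc$report,
       checkLines = unique(phenotypes$line_id[phenotypes$is_check]),
       heritability = h2)
}

restoreSpecAttrs <- function(df, bandCols) {
  attr(df, "bandCols") <- bandCols
  attr(df, "wavelengths") <- as.numeric(sub("^b", "", bandCols))
  df
}

#' Prepare a bundle directly from a simulated dataset
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param scopes spectral scopes to prepare.
#' @param ... passed to \code{\link{prepareBundle}}.
#' @return a bundle list.
#' @export
prepareBundleFromSim <- function(sim, scopes = "ALL", ...) {
  prepareBundle(sim$phenotypes, sim$spectra, sim$markers, sim$pedigree,
                sim$sowingDates, scopes = scopes, ...)
}
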