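# run expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Train-test partitions for the three prediction schemes
#'
#' \describe{
#'   \item{within_site_year}{focal unit = site-year; TRN is a random
#'     floor(0.8 n) of its records, TST the remainder.}
#'   \item{within_cycle_across_treatments}{focal unit = one managed treatment
#'     within a breeding cycle; TRN = all records of the other treatments in
#'     that cycle plus floor(0.2 n_focal) records of the focal treatment, TST
#'     = the remaining focal-treatment records.}
#'   \item{across_cycles_within_treatment}{focal unit = one breeding cycle
#'     within a managed treatment; TRN = all records of the other cycles in
#'     that treatment plus floor(0.2 n_focal) of the focal cycle, TST = the
#'     remainder.}
#' }
#' Partitions are deterministic given (scheme, focal unit, replicate, master
#' seed) regardless of call order, so the same splits can be reused across
#' all models. Check lines are kept in TRN and never drawn into TST.
#'
#' @param scheme one of the three scheme names.
#' @param idx a \linkS4class{RecordIndex} (all records of the study).
#' @param nPartitions number of random partitions per focal unit (default 20).
#' @param masterSeed master seed.
#' @param focal optional character vector restricting the focal units
#'   (site-year labels, or "cycle:treatment" labels for the cross schemes).
#' @param checkLines line ids of repeated checks (excluded from TST).
#' @return list of \code{Partition} lists with elements \code{scheme},
#'   \code{focal}, \code{replicate}, \code{seed}, \code{trn}, \code{tst}
#'   (record ids).
#' @export
makePartitions <- function(scheme = c("within_site_year",
                                      "within_cycle_across_treatments",
                                      "across_cycles_within_treatment"),
                           idx, nPartitions = 20, masterSeed = 1,
                           focal = NULL, checkLines = character()) {
  scheme <- match.arg(scheme)
  recs <- recordTable(idx)
  cyTr <- splitSiteYear(recs$site_year)
  recs$cycle <- cyTr$cycle
  recs$treatment <- cyTr$treatment
  units <- switch(scheme,
    within_site_year = sort(unique(recs$site_year)),
    within_cycle_across_treatments = ,
    across_cycles_within_treatment =
      sort(unique(siteYearLabel(recs$cycle, recs$treatment))))
  if (!is.null(focal)) {
    missingU <- setdiff(focal, units)
    if (length(missingU))
      stop("configuration error: focal unit(s) not present: ",
           paste(missingU, collapse = ", "))
    units <- focal
  }
  out <- list()
  for (u in units) {
    parts <- splitSiteYear(u)
    if (scheme == "within_site_year") {
      focalRecs <- recs[recs$site_year == u, , drop = FALSE]
      ctxRecs <- focalRecs[0, ]
    } else if (scheme == "within_cycle_across_treatments") {
      inCycle <- recs[recs$cycle == parts$cycle, , drop = FALSE]
      focalRecs <- inCycle[inCycle$treatment == parts$treatment, ,
                           drop = FALSE]
      ctxRecs <- inCycle[inCycle$treatment != parts$treatment, ,
                         drop = FALSE]
    } else {
      inTreat <- recs[recs$treatment == parts$treatment, , drop = FALSE]
      focalRecs <- inTreat[inTreat$cycle == parts$cycle, , drop = FALSE]
      ctxRecs <- inTreat[inTreat$cycle != parts$cycle, , drop = FALSE]
    }
    nFocal <- nrow(focalRecs)
    if (nFocal < 10)
      stop("configuration error: focal unit ", u, " has fewer than 10 records")
    trnShare <- if (scheme == "within_site_year") 0.8 else 0.2
    nTrnFocal <- floor(trnShare * nFocal)
    nTst <- nFocal - nTrnFocal
    pool <- which(!focalRecs$line_id %in% checkLines)
    if (length(pool) < nTst)
      stop("not enough non-check records in ", u, " for the test set")
    for (r in seq_len(nPartitions)) {
      s <- mixSeed(masterSeed, scheme, u, r)
      tstIdx <- withSeed(s, sort(sample(pool, nTst)))
      tst <- focalRecs$record_id[tstIdx]
      trn <- c(setdiff(focalRecs$record_id, tst), ctxRecs$record_id)
      part <- list(scheme = scheme, focal = u, replicate = r, seed = s,
                   trn = sort(trn), tst = tst)
      class(part) <- "Partition"
      out[[length(out) + 1L]] <- part
    }
  }
  out
}

#' Pearson prediction accuracy on a test set
#'
#' Accuracy is the Pearson correlation between predicted values and the
#' validation GY BLUPs over the test records.
#'
#' @param predictions numeric predictions (named by record id, or aligned to
#'   \code{validation}).
#' @param validation numeric GY BLUPs (named by record id).
#' @return Pearson r.
#' @export
predictionAccuracy <- function(predictions, validation) {
  if (!is.null(names(predictions)) && !is.null(names(validation))) {
    common <- intersect(names(predictions), names(validation))
    predictions <- predictions[common]
    validation <- validation[common]
  }
  ok <- is.finite(predictions) & is.finite(validation)
  predictions <- predictions[ok]
  validation <- validation[ok]
  if (length(predictions) < 3)
    stop("need at least 3 paired records for accuracy")
  if (sd(predictions) == 0 || sd(validation) == 0)
    stop("undefined correlation: constant vector")
  cor(predictions, validation)
}

# record sets entering the fit for one focal unit of a scheme
schemeRecordSet <- function(scheme, idx, focal) {
  recs <- recordTable(idx)
  parts <- splitSiteYear(focal)
  cyTr <- splitSiteYear(recs$site_year)
  switch(scheme,
    within_site_year = recs$site_year[recs$site_year == focal][1],
    within_cycle_across_treatments =
      sort(unique(recs$site_year[cyTr$cycle == parts$cycle])),
    across_cycles_within_treatment =
      sort(unique(recs$site_year[cyTr$treatment == parts$treatment])))
}

#' Run a battery of prediction models over shared partitions
#'
#' For every model and focal unit of the scheme, fits the model on each of
#' the shared train-test partitions and records the Pearson accuracy on the
#' test set against both validation variants (GY BLUPs with and without the
#' days-to-heading correction). Model/unit combinations whose spectral scope
#' is unavailable in a required site-year are recorded as absent with a
#' reason. Identical partitions (same master seed) are used for every model.
#'
#' @param bundle a prepared data bundle from \code{\link{prepareBundle}}.
#' @param models character vector of model names (see
#'   \code{\link{assembleModel}}).
#' @param scheme partition scheme (see \code{\link{makePartitions}}).
#' @param nPartitions partitions per focal unit.
#' @param masterSeed master seed shared by all models.
#' @param method "gibbs" or "em_reml".
#' @param focal optional restriction of focal units.
#' @param nIter,burnIn,thin Gibbs settings.
#' @return data.frame with one row per (model, focal, replicate, variant):
#'   columns model, scheme, focal, replicate, variant, r, reason.
#' @export
runBattery <- function(bundle, models, scheme = "within_cycle_across_treatments",
                       nPartitions = 20, masterSeed = 1,
                       method = c("gibbs", "em_reml"), focal = NULL,
                       nIter = 1500, burnIn = 300, thin = 3) {
  method <- match.arg(method)
  idx <- bundle$idx
  partitions <- makePartitions(scheme, idx, nPartitions, masterSeed,
                               focal = focal,
                               checkLines = bundle$checkLines %||% character())
  units <- unique(vapply(partitions, function(p) p$focal, ""))
  variants <- c(uncorrected = "gyBlupsUncorrected",
                dthd_corrected = "gyBlupsCorrected")
  rows <- list()
  for (u in units) {
    sys <- schemeRecordSet(scheme, idx, u)
    subIdx <- subsetRecordIndex(idx, sys)
    uParts <- Filter(function(p) p$focal == u, partitions)
    for (mod in models) {
      gm <- tryCatch(
        assembleModel(mod, bundle$kernels, subIdx, bundle$gyBlues),
        error = function(e) e)
      if (inherits(gm, "error")) {
        for (v in names(variants))
          rows[[length(rows) + 1L]] <- data.frame(
            model = mod, scheme = scheme, focal = u, replicate = NA_integer_,
            variant = v, r = NA_real_, reason = conditionMessage(gm),
            stringsAsFactors = FALSE)
        next
      }
      for (p in uParts) {
        masked <- maskResponse(gm, p$tst)
        fitSeed <- mixSeed(masterSeed, "fit", mod, u, p$replicate)
        fit <- fitGblup(masked, method = method, nIter = nIter,
                        burnIn = burnIn, thin = thin, seed = fitSeed)
        preds <- predictMasked(fit)
        yhat <- setNames(preds$yhat, preds$record_id)[p$tst]
        for (v in names(variants)) {
          valid <- bundle[[variants[[v]]]][p$tst]
          r <- tryCatch(predictionAccuracy(yhat, valid),
                        error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            model = mod, scheme = scheme, focal = u,
            replicate = p$replicate, variant = v, r = r, reason = "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a battery result table
#'
#' Mean and standard deviation of the per-partition accuracies for each
#' (model, focal unit, validation variant); undefined accuracies are dropped
#' from the mean with their count reported.
#'
#' @param results output of \code{\link{runBattery}}.
#' @return data.frame with columns model, scheme, focal, variant, mean_r,
#'   sd_r, n_partitions, n_missing, reason.
#' @export
summarizeAccuracy <- function(results) {
  key <- interaction(results$model, results$focal, results$variant,
                     drop = TRUE)
  out <- lapply(split(results, key), function(g) {
    ok <- is.finite(g$r)
    data.frame(model = g$model[1], scheme = g$scheme[1], focal = g$focal[1],
               variant = g$variant[1],
               mean_r = if (any(ok)) mean(g$r[ok]) else NA_real_,
               sd_r = if (sum(ok) > 1) sd(g$r[ok]) else NA_real_,
               n_partitions = sum(ok), n_missing = sum(!ok),
               reason = g$reason[which(g$reason != "")[1]] %||% "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$reason[is.na(res$reason)] <- ""
  res[order(res$model, res$focal, res$variant), , drop = FALSE]
}

#' Correlations between per-band BLUEs and grain-yield BLUEs
#'
#' @param bandBlues a \code{BandBlueTable} (or lines x bands matrix).
#' @param gyBlues named numeric of GY BLUEs by line.
#' @return named numeric vector, one Pearson r per band.
#' @export
bandYieldCorrelations <- function(bandBlues, gyBlues) {
  B <- if (inherits(bandBlues, "BandBlueTable")) bandBlues$blues
       else as.matrix(bandBlues)
  common <- intersect(rownames(B), names(gyBlues))
  if (length(common) < 3)
    stop("coverage error: fewer than 3 lines shared between tables")
  apply(B[common, , drop = FALSE], 2, cor, y = gyBlues[common])
}

#' Between-treatment grain-yield correlations within a cycle
#'
#' @param gyBluesByTreatment named list (one element per managed treatment)
#'   of named numeric GY BLUEs by line.
#' @return treatment x treatment Pearson correlation matrix.
#' @export
treatmentCorrelations <- function(gyBluesByTreatment) {
  trts <- names(gyBluesByTreatment)
  n <- length(trts)
  out <- matrix(NA_real_, n, n, dimnames = list(trts, trts))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- gyBluesByTreatment[[i]]
    b <- gyBluesByTreatment[[j]]
    common <- intersect(names(a), names(b))
    if (length(common) < 3)
      stop("coverage error: fewer than 3 lines shared between treatments ",
           trts[i], " and ", trts[j])
    out[i, j] <- cor(a[common], b[common])
  }
  out
}
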