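#' Fit a plot-level variance-component mixed model by REML
#'
#' The stage-one model for agronomic traits and per-band reflectance within a
#' site-year: trait = genotype (fixed or random) + optional numeric
#' covariates + independent scalar-variance random grouping factors (trial,
#' replicate-in-trial, block-in-replicate, phenotyping time-point) + residual.
#' Genotype-as-fixed yields BLUEs reported directly on the trait scale (the
#' no-intercept genotype coding); genotype-as-random yields shrunken BLUPs
#' around a common intercept.
#'
#' Random grouping factors with fewer than two levels are dropped with a
#' message. If the fixed part saturates the data (no residual degrees of
#' freedom, as for single-replicate traits with genotype fixed), the fit
#' degenerates to per-genotype means.
#'
#' @param response numeric response vector.
#' @param genotype genotype identifier per observation.
#' @param genotypeRole "fixed" (BLUEs) or "random" (BLUPs).
#' @param covariates named list/data.frame of numeric fixed covariates.
#' @param random named list of grouping factors; names become variance
#'   component labels (e.g. \code{trial}, \code{replicate}, \code{block},
#'   \code{date}). Each factor must already encode its full nesting (e.g.
#'   replicate = interaction(trial, rep)).
#' @return object of class \code{remlFit}: list with \code{blues} or
#'   \code{blups} (+ \code{intercept}), \code{varComp} (named, includes
#'   \code{sigma2_e} and, for random genotypes, \code{sigma2_g}),
#'   \code{converged}, \code{logLik}, \code{nObs} and the underlying engine
#'   fit.
#' @export
remlFit <- function(response, genotype, genotypeRole = c("fixed", "random"),
                    covariates = list(), random = list()) {
  genotypeRole <- match.arg(genotypeRole)
  keep <- !is.na(response)
  df <- data.frame(.y = response[keep],
                   .geno = factor(as.character(genotype)[keep]))
  for (nm in names(covariates)) df[[nm]] <- as.numeric(covariates[[nm]])[keep]
  dropped <- character(0)
  randNames <- character(0)
  for (nm in names(random)) {
    f <- factor(as.character(random[[nm]])[keep])
    if (nlevels(f) < 2) { dropped <- c(dropped, nm); next }
    df[[paste0(".r_", nm)]] <- f
    randNames <- c(randNames, nm)
  }
  if (length(dropped))
    specMessage("dropping random term(s) with < 2 levels: %s",
                paste(dropped, collapse = ", "))
  covPart <- if (length(covariates)) paste("+", paste(names(covariates),
                                                      collapse = " + ")) else ""
  fixPart <- if (genotypeRole == "fixed") paste("0 + .geno", covPart)
             else paste("1", covPart)
  ranPart <- paste(sprintf("(1 | .r_%s)", randNames), collapse = " + ")
  if (genotypeRole == "random")
    ranPart <- paste(c("(1 | .geno)",
                       if (nzchar(ranPart)) ranPart), collapse = " + ")
  nFixed <- (genotypeRole == "fixed") * nlevels(df$.geno) +
    (genotypeRole == "random") + length(covariates)
  useLmer <- nzchar(ranPart) && nrow(df) > nFixed + 1
  if (useLmer) {
    fml <- as.formula(paste(".y ~", fixPart, "+", ranPart))
    fit <- lme4::lmer(fml, data = df, REML = TRUE,
                      control = lme4::lmerControl(
                        calc.derivs = FALSE,
                        check.nobs.vs.nRE = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varComp <- setNames(vc$vcov, sub("^\\.r_", "", vc$grp))
    names(varComp)[names(varComp) == ".geno"] <- "sigma2_g"
    names(varComp)[names(varComp) == "Residual"] <- "sigma2_e"
    fe <- lme4::fixef(fit)
    converged <- length(fit@optinfo$conv$lme4) == 0
    ll <- as.numeric(logLik(fit))
  } else {
    # OLS limit (no usable random structure, or fixed part saturates)
    fml <- as.formula(paste(".y ~", fixPart))
    fit <- stats::lm(fml, data = df)
    s2 <- mean(fit$residuals^2)
    varComp <- c(sigma2_e = s2)
    fe <- coef(fit)
    converged <- TRUE
    ll <- as.numeric(logLik(fit))
  }
  out <- list(varComp = varComp, converged = converged, logLik = ll,
              nObs = nrow(df), genotypeRole = genotypeRole, engine = fit)
  if (genotypeRole == "fixed") {
    bl <- fe[grep("^\\.geno", names(fe))]
    names(bl) <- sub("^\\.geno", "", names(bl))
    out$blues <- bl[levels(df$.geno)]
    names(out$blues) <- levels(df$.geno)
    out$covarCoef <- fe[names(covariates)]
  } else {
    out$intercept <- unname(fe["(Intercept)"])
    re <- lme4::ranef(fit)$.geno
    bp <- setNames(re[["(Intercept)"]], rownames(re))
    out$blups <- out$intercept + bp[levels(df$.geno)]
    names(out$blups) <- levels(df$.geno)
    out$covarCoef <- fe[names(covariates)]
  }
  class(out) <- "remlFit"
  out
}

#' @export
print.remlFit <- function(x, ...) {
  cat(sprintf("remlFit (%s genotype): %d obs, logLik %.2f, converged: %s\n",
              x$genotypeRole, x$nObs, x$logLik, x$converged))
  cat("  variance components:",
      paste(sprintf("%s=%.4f", names(x$varComp), x$varComp),
            collapse = ", "), "\n")
  invisible(x)
}

# Nested design factors of the alpha-lattice: block in replicate in trial,
# optionally nested within a phenotyping date.
designFactors <- function(df, withDate = FALSE) {
  pre <- if (withDate) paste0(df$date, "/") else ""
  out <- list()
  if (withDate) out$date <- df$date
  out$trial <- paste0(pre, df$trial)
  out$replicate <- paste0(out$trial, "/", df$replicate)
  out$block <- paste0(out$replicate, "/", df$block)
  out
}

#' Trait BLUEs or BLUPs within one site-year
#'
#' Fits the plot-level alpha-lattice model (genotype + random trial +
#' replicate-in-trial + block-in-replicate) for one agronomic trait within a
#' single site-year. For single-replicate traits (days to heading/maturity)
#' the replicate and block terms are excluded. A lodging covariate is
#' included only when lodging was actually observed (> 0) in the site-year;
#' a days-to-heading covariate can be added to correct for phenology.
#'
#' @param plots plot-record table of one site-year.
#' @param trait one of "gy", "lodging", "dthd", "dtmt".
#' @param genotypeRole "fixed" for BLUEs, "random" for BLUPs.
#' @param covariates character subset of c("lodging", "dthd").
#' @return a \code{remlFit}.
#' @export
fitTraitBlues <- function(plots, trait = "gy",
                          genotypeRole = c("fixed", "random"),
                          covariates = character()) {
  genotypeRole <- match.arg(genotypeRole)
  if (length(unique(plots$site_year)) > 1)
    stop("fitTraitBlues expects plots from a single site-year")
  keep <- !is.na(plots[[trait]])
  if (sum(keep) == 0 || length(unique(plots$line_id[keep])) < 2)
    stop("trait ", trait, " observed for fewer than 2 lines")
  plots <- plots[keep, , drop = FALSE]
  singleRep <- trait %in% c("dthd", "dtmt") ||
    length(unique(plots$replicate)) < 2
  fac <- designFactors(plots)
  random <- if (singleRep) fac["trial"] else fac
  covs <- list()
  if ("lodging" %in% covariates) {
    if (all(is.na(plots$lodging)))
      stop("configuration error: lodging covariate requested but never recorded")
    if (any(plots$lodging > 0, na.rm = TRUE)) {
      covs$lodging <- ifelse(is.na(plots$lodging), 0, plots$lodging)
    } else {
      specMessage("no lodging observed in %s; covariate omitted",
                  plots$site_year[1])
    }
  }
  if ("dthd" %in% covariates) {
    dthdByLine <- tapply(plots$dthd, plots$line_id, mean, na.rm = TRUE)
    dv <- dthdByLine[plots$line_id]
    if (all(is.na(dv)))
      stop("configuration error: dthd covariate requested but entirely missing")
    covs$dthd <- ifelse(is.na(dv), mean(dv, na.rm = TRUE), dv)
  }
  remlFit(plots[[trait]], plots$line_id, genotypeRole,
          covariates = covs, random = random)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_e / nreps).
#'
#' @param sigma2_g genetic variance.
#' @param sigma2_e residual variance.
#' @param nreps number of replicates (default 3).
#' @return H2 in [0, 1].
#' @export
heritability <- function(sigma2_g, sigma2_e, nreps = 3) {
  stopifnot(sigma2_g >= 0, sigma2_e >= 0, nreps >= 1)
  if (sigma2_g == 0 && sigma2_e == 0)
    stop("undefined heritability: both variances are zero")
  sigma2_g / (sigma2_g + sigma2_e / nreps)
}

#' Classify phenotyping time-points into developmental growth stages
#'
#' A date is VEG while fewer than 50% of plots have headed, HEAD from 50%
#' until all plots have headed, and GF once all plots have headed but not all
#' matured. Heading/maturity dates are sowing date + days to heading /
#' maturity.
#'
#' @param plots plot-record table of one site-year (needs dthd; dtmt for the
#'   grain-fill boundary).
#' @param dates character/Date vector of phenotyping dates (ISO-8601).
#' @param sowingDate sowing (or first-irrigation) date of the site-year.
#' @param strict error on dates after 100% maturity (default: label GF with a
#'   warning).
#' @return data.frame with columns \code{date}, \code{stage},
#'   \code{frac_headed}, \code{frac_mature}.
#' @export
classifyTimePoints <- function(plots, dates, sowingDate, strict = FALSE) {
  hd <- plots$dthd[!is.na(plots$dthd)]
  if (length(hd) < 0.5 * length(unique(plots$line_id)))
    stop("coverage error: days-to-heading available for fewer than 50% of plots")
  md <- plots$dtmt[!is.na(plots$dtmt)]
  sowing <- as.Date(sowingDate)
  dates <- as.Date(as.character(dates))
  headDates <- sowing + hd
  matDates <- if (length(md)) sowing + md else as.Date(character(0))
  out <- data.frame(date = as.character(dates), stage = NA_character_,
                    frac_headed = NA_real_, frac_mature = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(dates)) {
    fh <- mean(headDates <= dates[i])
    fm <- if (length(matDates)) mean(matDates <= dates[i]) else 0
    stage <- if (fh < 0.5) "VEG" else if (fh < 1) "HEAD" else "GF"
    if (fh >= 1 && length(matDates) && fm >= 1) {
      if (strict) stop("time-point ", out$date[i],
                       " falls after 100% maturity")
      warning("time-point ", out$date[i],
              " falls after 100% maturity; labeled GF")
      stage <- "GF"
    }
    out$stage[i] <- stage
    out$frac_headed[i] <- fh
    out$frac_mature[i] <- fm
  }
  out[order(out$date), , drop = FALSE]
}

#' Per-band BLUEs for a time-point, growth stage, or all time-points
#'
#' Single-date scope fits the alpha-lattice model per band; stage and ALL
#' scopes add a random time-point effect with trial/replicate/block nested
#' within time-point. All bands share the same design, so the variance
#' components are estimated once per band by REML under the genotype-random
#' form of the model (a fast refit across bands) and the genotype-fixed
#' BLUEs are then obtained from a sparse mixed-model-equation solve at those
#' variances — the standard two-step used when hundreds of correlated
#' responses share one field design.
#'
#' @param spectra spectral-record table (see \code{\link{loadSpectra}}).
#' @param plots plot-record table of the same site-year.
#' @param scope a single date (ISO string), a stage name ("VEG", "HEAD",
#'   "GF") together with \code{stageLabels}, or "ALL".
#' @param stageLabels output of \code{\link{classifyTimePoints}} for this
#'   site-year (required for stage scopes).
#' @param genotypeRole "fixed" for BLUEs (default); "random" yields per-band
#'   BLUPs and genetic variances (used for band heritabilities).
#' @return list of class \code{BandBlueTable}: \code{site_year},
#'   \code{scope}, \code{blues} (lines x bands matrix), \code{varComp}
#'   (bands x components matrix).
#' @export
fitBandBlues <- function(spectra, plots, scope = "ALL", stageLabels = NULL,
                         genotypeRole = c("fixed", "random")) {
  genotypeRole <- match.arg(genotypeRole)
  bandCols <- attr(spectra, "bandCols") %||%
    grep("^b[0-9]+(\\.[0-9]+)?$", names(spectra), value = TRUE)
  joined <- merge(spectra, plots[, c("plot_id", "line_id", "trial",
                                     "replicate", "block", "site_year")],
                  by = "plot_id")
  if (nrow(joined) == 0) stop("no spectral records match the plot table")
  allDates <- sort(unique(joined$date))
  if (scope %in% c("VEG", "HEAD", "GF")) {
    if (is.null(stageLabels))
      stop("stage scope requires stageLabels from classifyTimePoints")
    useDates <- stageLabels$date[stageLabels$stage == scope]
  } else if (scope == "ALL") {
    useDates <- allDates
  } else {
    useDates <- intersect(scope, allDates)
  }
  useDates <- intersect(useDates, allDates)
  if (length(useDates) == 0)
    stop("empty scope: no phenotyping dates for scope '", scope,
         "' in this site-year")
  joined <- joined[joined$date %in% useDates, , drop = FALSE]
  multiDate <- length(useDates) > 1
  fac <- designFactors(joined, withDate = multiDate)
  lines <- sort(unique(joined$line_id))
  # per-band nuisance variance components under the genotype-random model;
  # the shared engine is fit on a red-edge band (typically well inside the
  # parameter space) so refits of other bands start from an interior optimum
  anchor <- bandCols[min(length(bandCols), ceiling(0.72 * length(bandCols)))]
  first <- remlFit(joined[[anchor]], joined$line_id, "random", random = fac)
  vcNames <- names(first$varComp)
  blues <- matrix(NA_real_, length(lines), length(bandCols),
                  dimnames = list(lines, bandCols))
  vcs <- matrix(NA_real_, length(bandCols), length(vcNames),
                dimnames = list(bandCols, vcNames))
  vcs[anchor, ] <- first$varComp[vcNames]
  blues[, anchor] <- first$blups[lines]
  engine <- first$engine
  fast <- inherits(engine, "lmerMod")
  for (bc in setdiff(bandCols, anchor)) {
    yj <- joined[[bc]]
    fitj <- if (fast) refitBand(engine, yj) else NULL
    # a refit that collapses the genotype variance onto the boundary may be
    # trapped by its starting value; redo those bands from scratch
    if (is.null(fitj) || isTRUE(fitj$genoBoundary)) {
      fj <- remlFit(yj, joined$line_id, "random", random = fac)
      blues[, bc] <- fj$blups[lines]
      vcs[bc, ] <- fj$varComp[vcNames]
    } else {
      blues[, bc] <- fitj$blups[lines]
      common <- intersect(names(fitj$varComp), vcNames)
      vcs[bc, common] <- fitj$varComp[common]
    }
  }
  if (genotypeRole == "fixed") {
    nuis <- setdiff(vcNames, c("sigma2_g", "sigma2_e"))
    blues <- glsBandBlues(joined, bandCols, lines, fac[nuis], vcs)
  }
  out <- list(site_year = joined$site_year[1], scope = scope,
              dates = useDates, blues = blues, varComp = vcs)
  class(out) <- "BandBlueTable"
  out
}

# Refit an lmer band model with a new response; returns BLUPs on the
# genotype scale plus renamed variance components.
refitBand <- function(engine, y) {
  fit <- suppressWarnings(lme4::refit(engine, newresp = y))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varComp <- setNames(vc$vcov, sub("^\\.r_", "", vc$grp))
  names(varComp)[names(varComp) == ".geno"] <- "sigma2_g"
  names(varComp)[names(varComp) == "Residual"] <- "sigma2_e"
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$.geno
  blups <- unname(fe["(Intercept)"]) +
    setNames(re[["(Intercept)"]], rownames(re))
  theta <- lme4::getME(fit, "theta")
  genoBoundary <- any(theta[grep("\\.geno", names(theta))] < 1e-4)
  list(blups = blups, varComp = varComp, genoBoundary = genoBoundary)
}

# Genotype-fixed BLUEs per band from a sparse mixed-model-equation solve at
# the per-band nuisance variances. The design is shared across bands, so
# only the shrinkage diagonal changes per band.
glsBandBlues <- function(joined, bandCols, lines, nuisFac, vcs) {
  n <- nrow(joined)
  geno <- factor(joined$line_id, levels = lines)
  Xg <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(geno), x = 1,
                             dims = c(n, length(lines)))
  nuisFac <- Filter(function(f) length(unique(f)) >= 2, nuisFac)
  blues <- matrix(NA_real_, length(lines), length(bandCols),
                  dimnames = list(lines, bandCols))
  if (length(nuisFac) == 0) {
    # OLS limit: per-line means
    for (j in seq_along(bandCols))
      blues[, j] <- tapply(joined[[bandCols[j]]], geno, mean)[lines]
    return(blues)
  }
  Zs <- lapply(nuisFac, function(f) {
    ff <- factor(f)
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(ff), x = 1,
                         dims = c(n, nlevels(ff)))
  })
  W <- do.call(cbind, Zs)
  levCount <- vapply(Zs, ncol, 1L)
  facOf <- rep(names(nuisFac), levCount)
  XtX <- Matrix::crossprod(Xg)
  XtW <- Matrix::crossprod(Xg, W)
  WtW <- Matrix::crossprod(W)
  q <- length(lines)
  for (j in seq_along(bandCols)) {
    y <- joined[[bandCols[j]]]
    s2e <- max(vcs[j, "sigma2_e"], 1e-12)
    lam <- s2e / pmax(vcs[j, facOf], s2e * 1e-10)
    lam <- pmin(lam, 1e10)
    C <- rbind(cbind(XtX, XtW),
               cbind(Matrix::t(XtW), WtW + Matrix::Diagonal(x = lam)))
    rhs <- c(as.numeric(Matrix::crossprod(Xg, y)),
             as.numeric(Matrix::crossprod(W, y)))
    sol <- as.numeric(Matrix::solve(C, rhs))
    blues[, j] <- sol[seq_len(q)]
  }
  blues
}

#' @export
print.BandBlueTable <- function(x, ...) {
  cat(sprintf("BandBlueTable %s [%s]: %d lines x %d bands (%d date(s))\n",
              x$site_year, x$scope, nrow(x$blues), ncol(x$blues),
              length(x$dates)))
  invisible(x)
}

#' Per-band broad-sense heritabilities
#'
#' Fits the genotype-as-random band model for each band and applies the
#' entry-mean heritability formula.
#'
#' @inheritParams fitBandBlues
#' @param nreps number of replicates.
#' @return named numeric vector of H2 per band.
#' @export
bandHeritabilities <- function(spectra, plots, scope = "ALL",
                               stageLabels = NULL, nreps = 3) {
  bb <- fitBandBlues(spectra, plots, scope, stageLabels,
                     genotypeRole = "random")
  vapply(rownames(bb$varComp), function(b) {
    heritability(bb$varComp[b, "sigma2_g"], bb$varComp[b, "sigma2_e"], nreps)
  }, numeric(1))
}

#' Solve Henderson's mixed-model equations at fixed variances
#'
#' Direct dense solve of the MME for y = X b + sum_m Z_m u_m + e with
#' var(u_m) = sigma2_m K_m and var(e) = sigma2_e I. Used as the fixed-variance
#' BLUP engine and as a numerical cross-check for the iterative fitters.
#'
#' @param y response.
#' @param X fixed design matrix.
#' @param Z list of random-effect design matrices.
#' @param K list of covariance matrices (same length as Z).
#' @param sigma2 numeric vector of variances, one per random term.
#' @param sigma2e residual variance.
#' @return list with \code{beta}, \code{u} (list) and \code{yhat}.
#' @export
solveMME <- function(y, X, Z, K, sigma2, sigma2e) {
  stopifnot(length(Z) == length(K), length(Z) == length(sigma2))
  W <- do.call(cbind, Z)
  # block-diagonal inverse of G = diag(sigma2_m K_m); jitter vs singular K
  blocks <- lapply(seq_along(K), function(m) {
    Km <- K[[m]] + diag(1e-10, nrow(K[[m]]))
    solve(Km) / sigma2[m]
  })
  q <- vapply(K, nrow, 1L)
  Ginv <- matrix(0, sum(q), sum(q))
  off <- 0
  for (m in seq_along(blocks)) {
    iidx <- off + seq_len(q[m])
    Ginv[iidx, iidx] <- blocks[[m]]
    off <- off + q[m]
  }
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + sigma2e * Ginv))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(C, rhs)
  p <- ncol(X)
  beta <- sol[seq_len(p)]
  uAll <- sol[-seq_len(p)]
  u <- list(); off <- 0
  for (m in seq_along(q)) {
    u[[m]] <- uAll[off + seq_len(q[m])]
    off <- off + q[m]
  }
  yhat <- as.numeric(X %*% beta + W %*% uAll)
  list(beta = beta, u = u, yhat = yhat)
}
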