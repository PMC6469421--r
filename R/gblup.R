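#' Assemble a single- or multi-kernel GBLUP model
#'
#' Builds the record-level mixed model y = mu + E + sum(u_m) + e over the
#' records of \code{idx} from a model name in the standard vocabulary:
#' \describe{
#'   \item{"G", "A"}{single genetic main-effect kernel.}
#'   \item{"H.<scope>"}{single block-diagonal spectral kernel (e.g.
#'     "H.ALL", "H.VEG", "H.GF"), one H block per site-year.}
#'   \item{"G+G_GxE", "A+A_GxE"}{genetic main effect plus the Hadamard
#'     interaction kernel (Z_g K Z_g') * (Z_E Z_E') over the same K.}
#'   \item{"G+H.<scope>_GxE", "A+H.<scope>_GxE"}{genetic main effect plus a
#'     block-diagonal spectral interaction kernel.}
#' }
#' Site-year fixed effects use drop-first dummy coding with an intercept and
#' are omitted when the index holds a single site-year. Each kernel term is
#' carried as the eigendecomposition of its record-level covariance
#' (eigenvalues below \code{truncate} dropped), computed once here so the
#' same assembled model can be refit under many response maskings.
#'
#' @param modelName model label (see above).
#' @param kernels list with entries \code{G}, \code{A}
#'   (\linkS4class{RelationshipMatrix}) and/or \code{H} (list keyed by scope,
#'   each a list of per-site-year \linkS4class{RelationshipMatrix} objects).
#' @param idx a \linkS4class{RecordIndex}.
#' @param y response named by record id (GY BLUEs); records absent from
#'   \code{y} or NA are treated as to-predict.
#' @param truncate eigenvalue truncation threshold.
#' @return a \linkS4class{GblupModel}.
#' @export
assembleModel <- function(modelName, kernels, idx, y, truncate = 1e-10) {
  recs <- recordTable(idx)
  n <- nrow(recs)
  yv <- setNames(rep(NA_real_, n), recs$record_id)
  common <- intersect(names(y), recs$record_id)
  yv[common] <- y[common]
  nSy <- length(unique(recs$site_year))
  X <- if (nSy > 1) {
    sy <- factor(recs$site_year)
    model.matrix(~sy)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  parts <- strsplit(modelName, "+", fixed = TRUE)[[1]]
  terms <- lapply(parts, function(p) {
    gxe <- grepl("_GxE$", p)
    src <- sub("_GxE$", "", p)
    if (src %in% c("G", "A")) {
      k <- kernels[[src]]
      if (is.null(k)) stop("kernel ", src, " not available")
      mode <- if (gxe) "gxe" else "main"
      M <- expandKernel(k, idx, mode)
    } else if (grepl("^H\\.", src)) {
      scope <- sub("^H\\.", "", src)
      hset <- kernels$H[[scope]]
      if (is.null(hset))
        stop("coverage error: no H matrices for scope ", scope)
      mode <- "block_h"
      M <- expandKernel(hset, idx, "block_h")
    } else stop("unrecognized kernel term: ", p)
    eg <- eigen(M, symmetric = TRUE)
    keep <- eg$values > truncate
    if (!any(keep)) stop("kernel term ", p, " is numerically zero")
    list(name = p, source = src, mode = mode,
         vectors = eg$vectors[, keep, drop = FALSE],
         values = eg$values[keep])
  })
  names(terms) <- parts
  new("GblupModel", name = modelName, index = idx, y = unname(yv), X = X,
      terms = terms)
}

#' Mask responses of selected records
#'
#' Returns a copy of the model with the response set to NA for the given
#' record ids (the test set of a partition); kernel eigendecompositions are
#' reused unchanged.
#'
#' @param model a \linkS4class{GblupModel}.
#' @param recordIds record ids to mask.
#' @return a \linkS4class{GblupModel}.
#' @export
maskResponse <- function(model, recordIds) {
  recs <- recordTable(model@index)
  y <- model@y
  y[recs$record_id %in% recordIds] <- NA_real_
  initialize(model, y = y)
}

#' Fit a multi-kernel GBLUP
#'
#' Two engines over the same model:
#' \describe{
#'   \item{gibbs}{Blocked Gibbs sampler in the eigenbasis of each kernel term
#'     (the rotated effects have independent full conditionals), with
#'     scaled-inverse-chi-square full conditionals for the variance
#'     components and data augmentation of missing responses each sweep.
#'     Default priors give each variance term (including the residual) an
#'     equal prior share of the training-response variance, with
#'     \code{priorDf} prior degrees of freedom. Predictions are posterior
#'     means of the systematic part mu + E + sum(u_m).}
#'   \item{em_reml}{EM-REML on the observed records; variance components
#'     maximize the restricted likelihood, predictions solve Henderson's
#'     mixed-model equations at the converged variances.}
#' }
#' \code{varFixed} freezes named variance components at given values (all of
#' them frozen turns em_reml into a single direct MME solve).
#'
#' @param model a \linkS4class{GblupModel}.
#' @param method "gibbs" or "em_reml".
#' @param nIter,burnIn,thin Gibbs sampler settings.
#' @param seed RNG seed (Gibbs only); required for reproducibility.
#' @param priorDf prior degrees of freedom for the variance components.
#' @param varFixed optional named numeric of variances to hold fixed
#'   (term names and/or "sigma2_e").
#' @param maxIter,tol EM-REML iteration cap and relative-change tolerance.
#' @return a \linkS4class{GblupFit}.
#' @export
fitGblup <- function(model, method = c("gibbs", "em_reml"), nIter = 10000,
                     burnIn = 2000, thin = 5, seed = 1, priorDf = 5,
                     varFixed = NULL, maxIter = 300, tol = 1e-6) {
  method <- match.arg(method)
  if (method == "gibbs")
    gibbsGblup(model, nIter, burnIn, thin, seed, priorDf, varFixed)
  else
    emRemlGblup(model, maxIter, tol, varFixed)
}

gibbsGblup <- function(model, nIter, burnIn, thin, seed, priorDf, varFixed) {
  set.seed(seed)
  y <- model@y
  obs <- !is.na(y)
  if (sum(obs) < 2) stop("need at least 2 training records")
  n <- length(y)
  X <- model@X
  p <- ncol(X)
  terms <- model@terms
  M <- length(terms)
  vy <- var(y[obs])
  nVar <- M + 1
  S0 <- vy * (priorDf + 2) / (priorDf * nVar)
  XtXinv <- solve(crossprod(X) + diag(1e-10, p))
  cholXtXinv <- chol(XtXinv)
  yCur <- y
  yCur[!obs] <- mean(y[obs])
  beta <- as.numeric(XtXinv %*% crossprod(X, yCur))
  sigma2 <- setNames(rep(vy / nVar, nVar), c(names(terms), "sigma2_e"))
  fixedMask <- setNames(rep(FALSE, nVar), names(sigma2))
  if (!is.null(varFixed)) {
    bad <- setdiff(names(varFixed), names(sigma2))
    if (length(bad)) stop("unknown variance name(s) in varFixed: ",
                          paste(bad, collapse = ", "))
    sigma2[names(varFixed)] <- varFixed
    fixedMask[names(varFixed)] <- TRUE
  }
  a <- lapply(terms, function(tm) numeric(length(tm$values)))
  eta <- lapply(terms, function(tm) numeric(n))
  sumFit <- numeric(n)
  sumFit2 <- numeric(n)
  varDraws <- NULL
  nKept <- 0L
  keepAt <- seq(burnIn + thin, nIter, by = thin)
  varDraws <- matrix(NA_real_, length(keepAt), nVar,
                     dimnames = list(NULL, names(sigma2)))
  for (it in seq_len(nIter)) {
    etaSum <- Reduce(`+`, eta)
    # fixed effects
    r <- yCur - etaSum
    bm <- as.numeric(XtXinv %*% crossprod(X, r))
    beta <- bm + sqrt(sigma2["sigma2_e"]) *
      as.numeric(t(cholXtXinv) %*% rnorm(p))
    xb <- as.numeric(X %*% beta)
    s2e <- sigma2[["sigma2_e"]]
    # kernel terms in their eigenbases
    for (m in seq_len(M)) {
      tm <- terms[[m]]
      rm <- yCur - xb - (etaSum - eta[[m]])
      v <- as.numeric(crossprod(tm$vectors, rm))
      s2m <- sigma2[[m]]
      cj <- 1 / (1 / s2e + 1 / (s2m * tm$values))
      am <- cj * v / s2e + sqrt(cj) * rnorm(length(v))
      a[[m]] <- am
      etaNew <- as.numeric(tm$vectors %*% am)
      etaSum <- etaSum - eta[[m]] + etaNew
      eta[[m]] <- etaNew
      if (!fixedMask[[m]]) {
        ss <- sum(am^2 / tm$values)
        sigma2[[m]] <- (ss + priorDf * S0) /
          rchisq(1, length(am) + priorDf)
      }
    }
    fitted <- xb + etaSum
    if (!fixedMask[["sigma2_e"]]) {
      e <- yCur - fitted
      sigma2[["sigma2_e"]] <- (sum(e^2) + priorDf * S0) /
        rchisq(1, n + priorDf)
    }
    if (any(!is.finite(sigma2)))
      stop("divergent sampler: non-finite variance draw at iteration ", it)
    # data augmentation of masked responses
    if (any(!obs))
      yCur[!obs] <- fitted[!obs] +
        sqrt(sigma2[["sigma2_e"]]) * rnorm(sum(!obs))
    if (it > burnIn && (it - burnIn) %% thin == 0) {
      nKept <- nKept + 1L
      sumFit <- sumFit + fitted
      sumFit2 <- sumFit2 + fitted^2
      varDraws[nKept, ] <- sigma2
    }
  }
  pred <- sumFit / nKept
  mcse <- sqrt(pmax(sumFit2 / nKept - pred^2, 0) / nKept)
  vc <- colMeans(varDraws[seq_len(nKept), , drop = FALSE])
  new("GblupFit", model = model, method = "gibbs", varComp = vc,
      predictions = pred, beta = beta,
      diagnostics = list(nSamples = nKept, mcse = mcse,
                         varDraws = varDraws[seq_len(nKept), , drop = FALSE],
                         seed = seed))
}

emRemlGblup <- function(model, maxIter, tol, varFixed) {
  y <- model@y
  obs <- !is.na(y)
  yo <- y[obs]
  no <- length(yo)
  X <- model@X
  Xo <- X[obs, , drop = FALSE]
  p <- qr(Xo)$rank
  terms <- model@terms
  M <- length(terms)
  Wo <- do.call(cbind, lapply(terms, function(tm)
    tm$vectors[obs, , drop = FALSE]))
  q <- vapply(terms, function(tm) length(tm$values), 1L)
  dAll <- unlist(lapply(terms, function(tm) tm$values), use.names = FALSE)
  idxTerm <- rep(seq_len(M), q)
  vy <- var(yo)
  sigma2 <- setNames(rep(vy / (M + 1), M + 1), c(names(terms), "sigma2_e"))
  fixedMask <- setNames(rep(FALSE, M + 1), names(sigma2))
  if (!is.null(varFixed)) {
    sigma2[names(varFixed)] <- varFixed
    fixedMask[names(varFixed)] <- TRUE
  }
  allFixed <- all(fixedMask)
  XtX <- crossprod(Xo)
  XtW <- crossprod(Xo, Wo)
  WtW <- crossprod(Wo)
  Xty <- crossprod(Xo, yo)
  Wty <- crossprod(Wo, yo)
  floorVar <- vy * 1e-10
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    s2e <- sigma2[["sigma2_e"]]
    gdiag <- sigma2[idxTerm] * dAll
    Cmat <- rbind(cbind(XtX / s2e, XtW / s2e),
                  cbind(t(XtW) / s2e, WtW / s2e + diag(1 / gdiag)))
    rhs <- c(Xty, Wty) / s2e
    Cinv <- solve(Cmat)
    sol <- as.numeric(Cinv %*% rhs)
    beta <- sol[seq_len(ncol(Xo))]
    aAll <- sol[-seq_len(ncol(Xo))]
    if (allFixed || iter > maxIter) {
      converged <- allFixed
      break
    }
    newSigma <- sigma2
    caa <- diag(Cinv)[-seq_len(ncol(Xo))]
    for (m in seq_len(M)) {
      if (fixedMask[[m]]) next
      sel <- idxTerm == m
      am <- aAll[sel]
      dm <- dAll[sel]
      newSigma[[m]] <- max((sum(am^2 / dm) + sum(caa[sel] / dm)) / q[m],
                           floorVar)
    }
    if (!fixedMask[["sigma2_e"]]) {
      fittedObs <- as.numeric(Xo %*% beta + Wo %*% aAll)
      newSigma[["sigma2_e"]] <- max(
        sum(yo * (yo - fittedObs)) / (no - p), floorVar)
    }
    delta <- max(abs(newSigma - sigma2) / (abs(sigma2) + 1e-12))
    sigma2 <- newSigma
    if (delta < tol) { converged <- TRUE; break }
  }
  predTerm <- Reduce(`+`, lapply(seq_len(M), function(m) {
    sel <- idxTerm == m
    as.numeric(model@terms[[m]]$vectors %*% aAll[sel])
  }))
  pred <- as.numeric(X %*% beta) + predTerm
  if (!converged)
    specMessage("EM-REML did not converge in %d iterations", maxIter)
  new("GblupFit", model = model, method = "em_reml", varComp = sigma2,
      predictions = pred, beta = beta,
      diagnostics = list(iterations = iter, converged = converged))
}

#' Extract predictions for every record
#'
#' One predicted value per record, masked or not; for training records the
#' value is the fitted systematic part.
#'
#' @param fit a \linkS4class{GblupFit}.
#' @return data.frame with \code{record_id}, \code{site_year},
#'   \code{line_id}, \code{yhat}, \code{masked}.
#' @export
predictMasked <- function(fit) {
  recs <- recordTable(fit@model@index)
  data.frame(record_id = recs$record_id, site_year = recs$site_year,
             line_id = recs$line_id, yhat = fit@predictions,
             masked = is.na(fit@model@y), stringsAsFactors = FALSE)
}
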