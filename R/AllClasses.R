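#' @import methods
#' @importFrom stats var cor sd rnorm rchisq runif rbinom quantile setNames
#'   as.formula logLik coef model.matrix aggregate complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' Relationship matrix among genotypes or site-year records
#'
#' Container for a symmetric positive semi-definite similarity matrix used as a
#' covariance kernel in GBLUP: a genomic relationship matrix (\code{kind =
#' "G"}), a pedigree numerator relationship matrix (\code{kind = "A"}), or a
#' hyperspectral reflectance-derived matrix (\code{kind = "H"}). \code{scope}
#' records whether rows index unique genotypes or site-year-by-genotype
#' records (H matrices are built within a site-year).
#'
#' @slot ids character vector of unique row/column identifiers.
#' @slot values symmetric numeric matrix, \code{length(ids)} square.
#' @slot kind one of \code{"G"}, \code{"A"}, \code{"H"}.
#' @slot scope one of \code{"genotype"}, \code{"record"}.
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(ids = "character", values = "matrix",
                 kind = "character", scope = "character"))

setValidity("RelationshipMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (!all(dim(object@values) == c(n, n)))
    msg <- c(msg, "values must be square with one row per id")
  if (!object@kind %in% c("G", "A", "H"))
    msg <- c(msg, "kind must be one of G, A, H")
  if (!object@scope %in% c("genotype", "record"))
    msg <- c(msg, "scope must be genotype or record")
  if (n > 0 && max(abs(object@values - t(object@values))) > 1e-10)
    msg <- c(msg, "values must be symmetric within 1e-10")
  if (length(msg)) msg else TRUE
})

#' Construct a RelationshipMatrix
#'
#' @param values symmetric numeric matrix.
#' @param ids identifiers; defaults to the rownames of \code{values}.
#' @param kind matrix family ("G", "A" or "H").
#' @param scope "genotype" or "record".
#' @return A \linkS4class{RelationshipMatrix}.
#' @export
RelationshipMatrix <- function(values, ids = rownames(values),
                               kind = "G", scope = "genotype") {
  if (is.null(ids)) stop("ids are required (or rownames on values)")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  new("RelationshipMatrix", ids = as.character(ids), values = values,
      kind = kind, scope = scope)
}

#' @describeIn RelationshipMatrix identifiers of the rows/columns.
#' @param x,object a \code{RelationshipMatrix}.
#' @export
setGeneric("kernelIds", function(x) standardGeneric("kernelIds"))
setMethod("kernelIds", "RelationshipMatrix", function(x) x@ids)

#' @describeIn RelationshipMatrix the numeric matrix.
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))
setMethod("kernelValues", "RelationshipMatrix", function(x) x@values)

#' @describeIn RelationshipMatrix the matrix family ("G", "A", "H").
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))
setMethod("kernelKind", "RelationshipMatrix", function(x) x@kind)

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix (kind %s, scope %s): %d x %d\n",
              object@kind, object@scope, length(object@ids),
              length(object@ids)))
  if (length(object@ids) > 0) {
    d <- diag(object@values)
    cat(sprintf("  diagonal mean %.3f, off-diagonal mean %.3f\n",
                mean(d),
                if (length(d) > 1)
                  (sum(object@values) - sum(d)) /
                    (length(d)^2 - length(d)) else NA_real_))
  }
})

#' Check positive semi-definiteness of a kernel
#'
#' Smallest eigenvalue must be no less than \code{-tol}. Symmetry is already
#' enforced by the class validity.
#'
#' @param x a \linkS4class{RelationshipMatrix} or plain symmetric matrix.
#' @param tol negative-eigenvalue tolerance.
#' @return logical.
#' @export
isPSD <- function(x, tol = 1e-8) {
  m <- if (is(x, "RelationshipMatrix")) kernelValues(x) else x
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol
}

#' Index of site-year-by-genotype response records
#'
#' One record per distinct (site-year, genotype) combination observed in the
#' phenotypes, in a deterministic order (site-year, then genotype). The
#' integer maps \code{geno} and \code{env} are the incidence maps record ->
#' genotype (Z_g) and record -> site-year (Z_E).
#'
#' @slot records data.frame with columns \code{site_year}, \code{line_id},
#'   \code{record_id}.
#' @slot lineLevels character, ordered genotype levels.
#' @slot siteYearLevels character, ordered site-year levels.
#' @slot geno integer index of each record into \code{lineLevels}.
#' @slot env integer index of each record into \code{siteYearLevels}.
#' @exportClass RecordIndex
setClass("RecordIndex",
  representation(records = "data.frame", lineLevels = "character",
                 siteYearLevels = "character", geno = "integer",
                 env = "integer"))

setValidity("RecordIndex", function(object) {
  msg <- character()
  n <- nrow(object@records)
  if (length(object@geno) != n || length(object@env) != n)
    msg <- c(msg, "incidence maps must have one entry per record")
  if (n > 0) {
    if (any(object@geno < 1 | object@geno > length(object@lineLevels)))
      msg <- c(msg, "geno indices out of range")
    if (any(object@env < 1 | object@env > length(object@siteYearLevels)))
      msg <- c(msg, "env indices out of range")
    if (anyDuplicated(object@records$record_id))
      msg <- c(msg, "record_id must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RecordIndex number of records.
#' @param x,object a \code{RecordIndex}.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
setMethod("nRecords", "RecordIndex", function(x) nrow(x@records))

#' @describeIn RecordIndex the records data.frame.
#' @export
setGeneric("recordTable", function(x) standardGeneric("recordTable"))
setMethod("recordTable", "RecordIndex", function(x) x@records)

setMethod("show", "RecordIndex", function(object) {
  cat(sprintf("RecordIndex: %d records, %d genotypes, %d site-years\n",
              nrow(object@records), length(object@lineLevels),
              length(object@siteYearLevels)))
})

#' Assembled multi-kernel GBLUP model
#'
#' The response (with NA marking records to predict), the fixed design
#' (intercept plus site-year effects), and one or more random kernel terms,
#' each carried as an eigendecomposition of its record-level covariance.
#'
#' @slot name model label (e.g. "G+H.ALL_GxE").
#' @slot index the \linkS4class{RecordIndex} the model is defined over.
#' @slot y numeric response (GY BLUEs); NA = record to predict.
#' @slot X fixed-effect design matrix.
#' @slot terms list; one entry per kernel term with elements \code{name},
#'   \code{source}, \code{mode}, \code{vectors}, \code{values}.
#' @exportClass GblupModel
setClass("GblupModel",
  representation(name = "character", index = "RecordIndex", y = "numeric",
                 X = "matrix", terms = "list"))

setValidity("GblupModel", function(object) {
  msg <- character()
  n <- nRecords(object@index)
  if (length(object@y) != n) msg <- c(msg, "y must have one entry per record")
  if (nrow(object@X) != n) msg <- c(msg, "X must have one row per record")
  if (length(object@terms) < 1) msg <- c(msg, "at least one kernel term")
  for (tm in object@terms) {
    if (!all(c("name", "mode", "vectors", "values") %in% names(tm)))
      msg <- c(msg, "malformed kernel term")
    else if (nrow(tm$vectors) != n)
      msg <- c(msg, "kernel term dimension must equal record count")
  }
  if (sum(!is.na(object@y)) < 2)
    msg <- c(msg, "need at least 2 training records")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GblupModel", function(object) {
  cat(sprintf("GblupModel '%s': %d records (%d training), %d kernel term(s)\n",
              object@name, length(object@y), sum(!is.na(object@y)),
              length(object@terms)))
  for (tm in object@terms)
    cat(sprintf("  term %-12s mode %-8s rank %d\n", tm$name, tm$mode,
                length(tm$values)))
})

#' Fitted multi-kernel GBLUP
#'
#' @slot model the \linkS4class{GblupModel} that was fit.
#' @slot method "gibbs" or "em_reml".
#' @slot varComp named numeric: one variance per kernel term plus
#'   \code{sigma2_e}.
#' @slot predictions numeric, fitted/predicted systematic part for every
#'   record (posterior mean under Gibbs, MME solution under EM-REML).
#' @slot beta fixed-effect estimates.
#' @slot diagnostics list (MC standard errors, iterations, convergence).
#' @exportClass GblupFit
setClass("GblupFit",
  representation(model = "GblupModel", method = "character",
                 varComp = "numeric", predictions = "numeric",
                 beta = "numeric", diagnostics = "list"))

setValidity("GblupFit", function(object) {
  msg <- character()
  if (any(!is.finite(object@predictions)))
    msg <- c(msg, "predictions must be finite")
  if (any(object@varComp < 0)) msg <- c(msg, "variance estimates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn GblupFit named variance-component estimates.
#' @param x,object a \code{GblupFit}.
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
setMethod("varComp", "GblupFit", function(x) x@varComp)

setMethod("show", "GblupFit", function(object) {
  cat(sprintf("GblupFit '%s' (%s)\n", object@model@name, object@method))
  vc <- object@varComp
  cat("  variance components:\n")
  for (nm in names(vc)) cat(sprintf("    %-14s %.4f\n", nm, vc[nm]))
})
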