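#' Marker quality control and mean imputation
#'
#' Removes markers with a missing-data share above \code{maxMissing}
#' (assessed first), then markers with minor allele frequency below
#' \code{minMaf} computed on the observed codes; remaining missing cells are
#' imputed with the column mean of the observed values (kept as real numbers,
#' not re-rounded to dosages).
#'
#' @param m a \code{MarkerMatrix} (see \code{\link{loadMarkers}}).
#' @param maxMissing maximum tolerated missing share per marker (default 0.70;
#'   strictly greater is removed).
#' @param minMaf minimum minor allele frequency (default 0.05; strictly less
#'   is removed).
#' @return list with elements \code{markers} (imputed \code{MarkerMatrix}
#'   without missing values) and \code{report} (a \code{MarkerQCReport} list:
#'   counts by removal reason and per-marker allele frequencies of the
#'   retained markers).
#' @export
qcMarkers <- function(m, maxMissing = 0.70, minMaf = 0.05) {
  codes <- m$codes
  if (is.null(codes) || ncol(codes) == 0) stop("empty marker matrix")
  missShare <- colMeans(is.na(codes))
  keepMiss <- missShare <= maxMissing
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keepMaf <- keepMiss & !is.na(maf) & maf >= minMaf
  nRemovedMissing <- sum(!keepMiss)
  nRemovedMaf <- sum(keepMiss & !keepMaf)
  keep <- keepMaf
  if (!any(keep))
    stop("degenerate input: all markers removed by QC")
  codes <- codes[, keep, drop = FALSE]
  colMean <- colMeans(codes, na.rm = TRUE)
  for (j in which(colSums(is.na(codes)) > 0)) {
    nas <- is.na(codes[, j])
    codes[nas, j] <- colMean[j]
  }
  report <- list(n_input_markers = length(missShare),
                 n_removed_missing = nRemovedMissing,
                 n_removed_maf = nRemovedMaf,
                 n_retained = sum(keep),
                 allele_freq = colMean / 2)
  class(report) <- "MarkerQCReport"
  specMessage("marker QC: %d in, %d removed (missing), %d removed (MAF), %d retained",
              report$n_input_markers, report$n_removed_missing,
              report$n_removed_maf, report$n_retained)
  out <- list(line_ids = m$line_ids, marker_ids = m$marker_ids[keep],
              codes = codes)
  class(out) <- "MarkerMatrix"
  list(markers = out, report = report)
}

#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 * sum_k p_k (1 - p_k)) where Z holds the marker codes
#' centered by twice the observed allele frequency (VanRaden method 1, with
#' frequencies computed from the post-QC data themselves).
#'
#' @param m an imputed \code{MarkerMatrix} (no missing values).
#' @return a \linkS4class{RelationshipMatrix} of kind "G".
#' @export
genomicRelationship <- function(m) {
  codes <- m$codes
  if (nrow(codes) < 2) stop("need at least 2 lines for G")
  if (any(is.na(codes))) stop("marker matrix still has missing values; run qcMarkers first")
  p <- colMeans(codes) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("degenerate input: all markers monomorphic (zero VanRaden denominator)")
  Z <- sweep(codes, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  RelationshipMatrix(G, ids = m$line_ids, kind = "G", scope = "genotype")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Twice the coefficient of parentage, computed by the tabular recursion on a
#' topologically sorted pedigree: A_ii = 1 + 0.5 * A(sire, dam) for
#' non-founders, A_ii = 1 + F for founders with inbreeding coefficient F, and
#' A_ij = 0.5 * (A(j, sire(i)) + A(j, dam(i))); an unknown parent contributes
#' zero.
#'
#' @param ped a \code{Pedigree} (see \code{\link{loadPedigree}}), or a
#'   data.frame with line_id/parent1/parent2 (validated and sorted here).
#' @param founderInbreeding inbreeding coefficient F of pedigree founders in
#'   [0, 1]; default 0 (non-inbred, diagonal 1).
#' @param inbredFounders convenience flag; TRUE sets F = 1 so founder
#'   diagonals are 2 (fully inbred lines).
#' @return a \linkS4class{RelationshipMatrix} of kind "A".
#' @export
pedigreeRelationship <- function(ped, founderInbreeding = 0,
                                 inbredFounders = FALSE) {
  if (!inherits(ped, "Pedigree")) ped <- validatePedigree(ped)
  if (inbredFounders) founderInbreeding <- 1
  stopifnot(founderInbreeding >= 0, founderInbreeding <= 1)
  ids <- ped$line_id
  known <- function(p) !is.na(p) & p %in% ids
  badRef <- c(ped$parent1[!is.na(ped$parent1) & !ped$parent1 %in% ids],
              ped$parent2[!is.na(ped$parent2) & !ped$parent2 %in% ids])
  if (length(badRef))
    stop("pedigree integrity error: unknown line referenced as parent: ",
         paste(unique(badRef), collapse = ", "))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  s <- match(ped$parent1, ids)
  d <- match(ped$parent2, ids)
  isFounder <- is.na(s) & is.na(d)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      js <- seq_len(i - 1)
      rel <- numeric(i - 1)
      if (!is.na(si)) rel <- rel + A[js, si]
      if (!is.na(di)) rel <- rel + A[js, di]
      A[js, i] <- A[i, js] <- 0.5 * rel
    }
    if (isFounder[i]) {
      A[i, i] <- 1 + founderInbreeding
    } else {
      Asd <- if (!is.na(si) && !is.na(di)) A[si, di] else 0
      A[i, i] <- 1 + 0.5 * Asd
    }
  }
  RelationshipMatrix(A, ids = ids, kind = "A", scope = "genotype")
}

#' Hyperspectral reflectance-derived relationship matrix
#'
#' H = SS'/nbands, where S holds the per-band BLUEs of one site-year centered
#' and scaled to unit sample standard deviation (n - 1 denominator by
#' default) across lines, and nbands is the number of retained bands.
#' Constant bands (zero variance) are dropped with a warning and the divisor
#' adjusted. With all bands retained, H has zero row sums and trace n - 1.
#'
#' @param bandBlues numeric matrix, lines x bands, rownames = line ids (as
#'   produced by \code{\link{fitBandBlues}}).
#' @param scale "sample" (n - 1, default) or "population" (n); this rescales
#'   H globally without changing prediction ranks.
#' @return a \linkS4class{RelationshipMatrix} of kind "H".
#' @export
spectralRelationship <- function(bandBlues, scale = c("sample", "population")) {
  scale <- match.arg(scale)
  S <- as.matrix(bandBlues)
  n <- nrow(S)
  if (n < 2) stop("degenerate input: need at least 2 lines for H")
  ctr <- sweep(S, 2, colMeans(S), "-")
  sds <- apply(ctr, 2, function(x) {
    ss <- sum(x^2)
    if (scale == "sample") sqrt(ss / (n - 1)) else sqrt(ss / n)
  })
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant band(s) from H", sum(!keep)))
    ctr <- ctr[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  nb <- ncol(ctr)
  if (nb == 0) {
    H <- matrix(0, n, n)
  } else {
    Sstd <- sweep(ctr, 2, sds, "/")
    H <- tcrossprod(Sstd) / nb
  }
  RelationshipMatrix(H, ids = rownames(S) %||% as.character(seq_len(n)),
                     kind = "H", scope = "genotype")
}

#' Write a relationship matrix as CSV with an id header row and column
#'
#' @param k a \linkS4class{RelationshipMatrix}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeRelationshipMatrix <- function(k, path) {
  df <- data.frame(id = kernelIds(k), kernelValues(k),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix written by \code{writeRelationshipMatrix}
#'
#' @param path CSV path.
#' @param kind matrix family ("G", "A", "H").
#' @param scope "genotype" or "record".
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
readRelationshipMatrix <- function(path, kind = "G", scope = "genotype") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$id)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (!identical(colnames(m), ids))
    stop("kernel CSV ids and columns disagree")
  RelationshipMatrix(m, ids = ids, kind = kind, scope = scope)
}

#' Expand a genotype-level kernel to the record level
#'
#' Builds the record-level covariance over a \linkS4class{RecordIndex}:
#' \describe{
#'   \item{main}{Z_g K Z_g' — genetic main effect shared across site-years.}
#'   \item{gxe}{(Z_g K Z_g') Hadamard (Z_E Z_E') — the interaction kernel;
#'     entries between records from different site-years are exactly zero.}
#'   \item{block_h}{block-diagonal assembly of per-site-year H matrices
#'     aligned to the index (\code{k} must then be a named list of
#'     \linkS4class{RelationshipMatrix} objects keyed by site-year).}
#' }
#'
#' @param k a \linkS4class{RelationshipMatrix} (modes main/gxe) or a named
#'   list of per-site-year H matrices (mode block_h).
#' @param idx a \linkS4class{RecordIndex}.
#' @param mode "main", "gxe" or "block_h".
#' @return record-level covariance matrix (records x records, dimnames =
#'   record ids).
#' @export
expandKernel <- function(k, idx, mode = c("main", "gxe", "block_h")) {
  mode <- match.arg(mode)
  recs <- recordTable(idx)
  if (mode %in% c("main", "gxe")) {
    stopifnot(is(k, "RelationshipMatrix"))
    pos <- match(recs$line_id, kernelIds(k))
    if (any(is.na(pos)))
      stop("coverage error: genotype(s) in index absent from kernel: ",
           paste(head(unique(recs$line_id[is.na(pos)]), 5), collapse = ", "))
    M <- kernelValues(k)[pos, pos, drop = FALSE]
    if (mode == "gxe") {
      same <- outer(idx@env, idx@env, "==")
      M <- M * same
    }
  } else {
    stopifnot(is.list(k))
    n <- nrow(recs)
    M <- matrix(0, n, n)
    for (sy in unique(recs$site_year)) {
      if (is.null(k[[sy]]))
        stop("coverage error: no H block for site-year ", sy)
      block <- k[[sy]]
      rows <- which(recs$site_year == sy)
      pos <- match(recs$line_id[rows], kernelIds(block))
      if (any(is.na(pos)))
        stop("coverage error: genotype(s) missing from H block of ", sy)
      M[rows, rows] <- kernelValues(block)[pos, pos, drop = FALSE]
    }
  }
  dimnames(M) <- list(recs$record_id, recs$record_id)
  M
}
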