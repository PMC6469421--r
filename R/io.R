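#' Default managed-treatment vocabulary
#'
#' The five differentially managed irrigation/planting regimes used in the
#' multi-environment yield trials. Treatment labels in phenotype files must
#' come from this (configurable) set.
#'
#' @return character vector of treatment labels.
#' @export
defaultTreatments <- function() {
  c("Optimal Bed", "Optimal Flat", "Moderate Drought",
    "Severe Drought", "Heat")
}

#' Compose a site-year label
#'
#' A site-year is one managed treatment in one breeding cycle.
#'
#' @param cycle breeding-cycle label (e.g. "2013-14").
#' @param treatment managed-treatment label.
#' @return character label "cycle:treatment".
#' @export
siteYearLabel <- function(cycle, treatment) paste(cycle, treatment, sep = ":")

#' Split site-year labels back into cycle and treatment
#'
#' @param siteYear character vector of "cycle:treatment" labels.
#' @return data.frame with columns \code{cycle} and \code{treatment}.
#' @export
splitSiteYear <- function(siteYear) {
  parts <- strsplit(as.character(siteYear), ":", fixed = TRUE)
  data.frame(cycle = vapply(parts, `[`, "", 1),
             treatment = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

phenoRequired <- c("plot_id", "line_id", "cycle", "treatment", "trial",
                   "replicate", "block")
phenoTraits <- c("gy", "lodging", "dthd", "dtmt")

#' Load and validate the plot-level phenotype table
#'
#' Long-format CSV with one row per field plot. Required columns:
#' \code{plot_id}, \code{line_id}, \code{cycle}, \code{treatment},
#' \code{trial}, \code{replicate}, \code{block}. Trait columns (\code{gy}
#' grain yield t/ha, \code{lodging} ordinal 0-5, \code{dthd} days to heading,
#' \code{dtmt} days to maturity) are nullable and preserved as NA. An optional
#' \code{is_check} column flags repeated checks; if absent all plots are
#' non-checks.
#'
#' @param path CSV file path.
#' @param treatments closed treatment vocabulary.
#' @return validated data.frame of plot records with a \code{site_year}
#'   column added.
#' @export
loadPhenotypes <- function(path, treatments = defaultTreatments()) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validatePhenotypes(df, treatments = treatments)
}

#' Validate an in-memory phenotype table
#'
#' Applies the same schema and integrity checks as \code{\link{loadPhenotypes}}.
#'
#' @param df data.frame of plot records.
#' @param treatments closed treatment vocabulary.
#' @return the validated (and typed) data.frame.
#' @export
validatePhenotypes <- function(df, treatments = defaultTreatments()) {
  missingCols <- setdiff(phenoRequired, names(df))
  if (length(missingCols))
    stop("phenotype schema error: missing column(s) ",
         paste(missingCols, collapse = ", "))
  if (anyDuplicated(df$plot_id))
    stop("phenotype integrity error: duplicate plot_id ",
         df$plot_id[duplicated(df$plot_id)][1])
  bad <- setdiff(unique(df$treatment), treatments)
  if (length(bad))
    stop("phenotype vocabulary error: unknown treatment label(s) ",
         paste(bad, collapse = ", "))
  for (cl in intersect(phenoTraits, names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  for (cl in setdiff(phenoTraits, names(df))) df[[cl]] <- NA_real_
  if (!"is_check" %in% names(df)) df$is_check <- FALSE
  df$is_check <- as.logical(df$is_check)
  df$trial <- as.integer(df$trial)
  df$replicate <- as.integer(df$replicate)
  df$block <- as.integer(df$block)
  both <- !is.na(df$dthd) & !is.na(df$dtmt)
  if (any(both & df$dtmt < df$dthd)) {
    row <- which(both & df$dtmt < df$dthd)[1]
    stop("phenotype integrity error: dtmt < dthd for plot_id ",
         df$plot_id[row])
  }
  if (any(!is.na(df$gy) & df$gy < 0))
    stop("phenotype integrity error: negative grain yield")
  df$site_year <- siteYearLabel(df$cycle, df$treatment)
  specMessage("loaded %d plot records (%d site-years, %d lines)",
              nrow(df), length(unique(df$site_year)),
              length(unique(df$line_id)))
  df
}

#' Load the plot-by-time-point hyperspectral reflectance table
#'
#' CSV with columns \code{plot_id}, \code{date} (ISO-8601), and one column
#' per band named by wavelength (e.g. \code{b398}). All rows must share the
#' same band set and (plot_id, date) must be unique.
#'
#' @param path CSV file path.
#' @param expectedNBands expected number of band columns (default 62).
#' @return data.frame of spectral records; band wavelengths (nm) are attached
#'   as the \code{"wavelengths"} attribute.
#' @export
loadSpectra <- function(path, expectedNBands = 62) {
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("plot_id", "date") %in% names(df)))
    stop("spectra schema error: need plot_id and date columns")
  bandCols <- grep("^b[0-9]+(\\.[0-9]+)?$", names(df), value = TRUE)
  if (length(bandCols) != expectedNBands)
    stop(sprintf("spectra format error: %d band columns found, %d expected",
                 length(bandCols), expectedNBands))
  key <- paste(df$plot_id, df$date)
  if (anyDuplicated(key))
    stop("spectra integrity error: duplicate (plot_id, date) ",
         key[duplicated(key)][1])
  for (cl in bandCols) {
    df[[cl]] <- as.numeric(df[[cl]])
    if (any(!is.finite(df[[cl]])))
      stop("spectra format error: non-finite reflectance in ", cl)
  }
  attr(df, "wavelengths") <- as.numeric(sub("^b", "", bandCols))
  attr(df, "bandCols") <- bandCols
  specMessage("loaded %d spectral records x %d bands", nrow(df),
              length(bandCols))
  df
}

#' Load a biallelic marker matrix
#'
#' CSV with a \code{line_id} column and one column per marker coded
#' \{0, 1, 2\} (minor-allele dosage); blanks are missing.
#'
#' @param path CSV file path.
#' @return list with elements \code{line_ids}, \code{marker_ids} and
#'   \code{codes} (lines x markers integer matrix, NA allowed), of class
#'   \code{MarkerMatrix}.
#' @export
loadMarkers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"line_id" %in% names(df))
    stop("marker schema error: need line_id column")
  codes <- as.matrix(df[, setdiff(names(df), "line_id"), drop = FALSE])
  mode(codes) <- "numeric"
  if (any(!is.na(codes) & !codes %in% c(0, 1, 2)))
    stop("marker format error: codes must be in {0, 1, 2} or missing")
  rownames(codes) <- df$line_id
  out <- list(line_ids = df$line_id,
              marker_ids = colnames(codes),
              codes = codes)
  class(out) <- "MarkerMatrix"
  specMessage("loaded markers: %d lines x %d markers", nrow(codes),
              ncol(codes))
  out
}

#' Load a two-column parentage pedigree
#'
#' CSV with columns \code{line_id}, \code{parent1}, \code{parent2}; empty
#' cells denote unknown parents. The pedigree must be acyclic; entries are
#' returned topologically sorted (parents before offspring).
#'
#' @param path CSV file path.
#' @return data.frame of class \code{Pedigree}, topologically ordered.
#' @export
loadPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validatePedigree(df)
}

#' Validate and topologically sort a pedigree table
#'
#' @param df data.frame with line_id, parent1, parent2.
#' @return topologically ordered data.frame of class \code{Pedigree}.
#' @export
validatePedigree <- function(df) {
  need <- c("line_id", "parent1", "parent2")
  if (!all(need %in% names(df)))
    stop("pedigree schema error: need columns ", paste(need, collapse = ", "))
  for (cl in c("parent1", "parent2")) {
    df[[cl]] <- as.character(df[[cl]])
    df[[cl]][is.na(df[[cl]]) | df[[cl]] == ""] <- NA_character_
  }
  if (anyDuplicated(df$line_id))
    stop("pedigree integrity error: duplicate line_id")
  # Kahn topological sort; a leftover residue means a cycle
  ids <- df$line_id
  order <- character(0)
  placed <- character(0)
  remaining <- df
  repeat {
    ready <- with(remaining,
                  (is.na(parent1) | parent1 %in% placed |
                     !parent1 %in% ids) &
                  (is.na(parent2) | parent2 %in% placed |
                     !parent2 %in% ids))
    if (!any(ready)) break
    order <- c(order, remaining$line_id[ready])
    placed <- c(placed, remaining$line_id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
    if (nrow(remaining) == 0) break
  }
  if (nrow(remaining) > 0)
    stop("pedigree integrity error: cycle involving ",
         paste(remaining$line_id, collapse = ", "))
  df <- df[match(order, df$line_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("Pedigree", "data.frame")
  df
}

#' Build the site-year-by-genotype record index
#'
#' One response record per distinct (site-year, genotype) combination present
#' in the phenotypes, ordered deterministically (site-year, then genotype),
#' with incidence maps to genotype and site-year levels.
#'
#' @param phenotypes validated plot-record table (needs \code{site_year} and
#'   \code{line_id}), or any data.frame with those two columns.
#' @return a \linkS4class{RecordIndex}.
#' @export
buildRecordIndex <- function(phenotypes) {
  if (nrow(phenotypes) == 0) stop("cannot index an empty phenotype table")
  if (!"site_year" %in% names(phenotypes))
    phenotypes$site_year <- siteYearLabel(phenotypes$cycle,
                                          phenotypes$treatment)
  recs <- unique(phenotypes[, c("site_year", "line_id")])
  recs <- recs[order(recs$site_year, recs$line_id), , drop = FALSE]
  rownames(recs) <- NULL
  recs$record_id <- paste(recs$site_year, recs$line_id, sep = "/")
  lineLevels <- sort(unique(recs$line_id))
  syLevels <- sort(unique(recs$site_year))
  new("RecordIndex", records = recs, lineLevels = lineLevels,
      siteYearLevels = syLevels,
      geno = match(recs$line_id, lineLevels),
      env = match(recs$site_year, syLevels))
}

#' Subset a record index to selected site-years
#'
#' @param idx a \linkS4class{RecordIndex}.
#' @param siteYears site-year labels to keep.
#' @return a new \linkS4class{RecordIndex} over the kept records.
#' @export
subsetRecordIndex <- function(idx, siteYears) {
  recs <- recordTable(idx)
  keep <- recs$site_year %in% siteYears
  if (!any(keep)) stop("no records in the requested site-years")
  buildRecordIndex(recs[keep, c("site_year", "line_id")])
}

#' Write a table in the package's CSV conventions
#'
#' Plain CSV, no row names; NA written as empty cells so tables round-trip
#' through the loaders field-for-field.
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTable <- function(df, path) {
  df <- df[, setdiff(names(df), "site_year"), drop = FALSE]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
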