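#' @import methods
NULL

## Canonical trait schema: the 14 quantitative leaf traits and their modules.
## Colour name (CN, chart-matched) is deliberately absent: it is categorical and
## measured against a physical colour chart, not from the image.
.LEAF_TRAITS <- data.frame(
  trait  = c("LA", "LP", "LL", "LW",
             "LLo", "AR", "P_L", "P_LW", "Rect", "Cir",
             "R", "G", "B", "CV"),
  module = c(rep("size", 4), rep("shape", 6), rep("color", 4)),
  units  = c("cm2", "cm", "cm", "cm",
             "count", "ratio", "ratio", "ratio", "ratio", "ratio",
             "0-255", "0-255", "0-255", "composite"),
  stringsAsFactors = FALSE
)

## Genotype class labels per segregation type. In a pseudo-testcross F1,
## markers heterozygous in one parent segregate into two classes (1:1) and
## markers heterozygous in both parents into three (1:2:1).
.SEG_LABELS <- list(
  testcross2 = c("aa", "ab"),
  intercross3 = c("AA", "Aa", "aa")
)

#' LinkageMap: ordered markers on linkage groups
#'
#' Holds marker identifiers with their linkage group and genetic position in
#' centimorgans. Markers are kept sorted by (linkage group, position).
#'
#' @slot map data.frame with columns \code{marker}, \code{lg}, \code{pos}.
#' @exportClass LinkageMap
setClass("LinkageMap", slots = c(map = "data.frame"))

setValidity("LinkageMap", function(object) {
  m <- object@map
  msgs <- character()
  if (!all(c("marker", "lg", "pos") %in% names(m)))
    msgs <- c(msgs, "map must have columns marker, lg, pos")
  else {
    if (anyDuplicated(m$marker))
      msgs <- c(msgs, sprintf("duplicate marker ids: %s",
                              paste(unique(m$marker[duplicated(m$marker)]), collapse = ", ")))
    if (any(m$pos < 0)) msgs <- c(msgs, "positions must be >= 0 cM")
    by_lg <- split(m$pos, m$lg)
    if (any(vapply(by_lg, is.unsorted, logical(1))))
      msgs <- c(msgs, "positions must be non-decreasing within each linkage group")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: per-marker genotype class calls
#'
#' Individuals by markers character matrix of genotype class labels, together
#' with the declared segregation type of each marker. Missing calls are NA.
#'
#' @slot calls character matrix, rows = individuals, columns = markers.
#' @slot segType named character vector, "testcross2" or "intercross3" per marker.
#' @slot classLabels named list of ordered class-label sets per marker.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         slots = c(calls = "matrix", segType = "character", classLabels = "list"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  calls <- object@calls
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    return("calls must have individual (row) and marker (column) names")
  if (anyDuplicated(rownames(calls)))
    msgs <- c(msgs, "duplicate individual ids")
  if (anyDuplicated(colnames(calls)))
    msgs <- c(msgs, "duplicate marker ids")
  if (!identical(names(object@segType), colnames(calls)))
    msgs <- c(msgs, "segType must be named by marker, in column order")
  if (!identical(names(object@classLabels), colnames(calls)))
    msgs <- c(msgs, "classLabels must be named by marker, in column order")
  bad_type <- !object@segType %in% names(.SEG_LABELS)
  if (any(bad_type))
    msgs <- c(msgs, sprintf("unknown segregation type for: %s",
                            paste(names(object@segType)[bad_type], collapse = ", ")))
  n_lab <- lengths(object@classLabels)
  want <- ifelse(object@segType == "testcross2", 2L, 3L)
  if (any(n_lab != want, na.rm = TRUE))
    msgs <- c(msgs, "testcross2 markers need exactly 2 class labels, intercross3 exactly 3")
  for (j in seq_len(ncol(calls))) {
    v <- calls[, j]
    bad <- !is.na(v) & !v %in% object@classLabels[[j]]
    if (any(bad)) {
      msgs <- c(msgs, sprintf("marker %s: undeclared class label(s) %s",
                              colnames(calls)[j], paste(unique(v[bad]), collapse = ", ")))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PhenotypeTable: individuals by traits
#'
#' Numeric trait values per individual, with each trait tagged by its module
#' (size, shape or color) and units. Missing values allowed.
#'
#' @slot values numeric matrix, rows = individuals, columns = traits.
#' @slot traitInfo data.frame with columns \code{trait}, \code{module}, \code{units}.
#' @exportClass PhenotypeTable
setClass("PhenotypeTable",
         slots = c(values = "matrix", traitInfo = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  msgs <- character()
  v <- object@values
  ti <- object@traitInfo
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (is.null(rownames(v))) msgs <- c(msgs, "values must have individual row names")
  if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate individual ids")
  if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate trait names")
  if (!identical(ti$trait, colnames(v)))
    msgs <- c(msgs, "traitInfo$trait must match value columns in order")
  if (!all(ti$module %in% c("size", "shape", "color")))
    msgs <- c(msgs, "trait modules must be size, shape or color")
  if (length(msgs)) msgs else TRUE
})

#' FpkmExperiment: genes by tissue samples expression container
#'
#' A SummarizedExperiment subclass with a single "fpkm" assay holding
#' non-negative normalized expression (FPKM) values.
#'
#' @exportClass FpkmExperiment
#' @import SummarizedExperiment
setClass("FpkmExperiment", contains = "SummarizedExperiment")

setValidity("FpkmExperiment", function(object) {
  msgs <- character()
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    return("must carry an assay named 'fpkm'")
  x <- SummarizedExperiment::assay(object, "fpkm")
  if (any(x < 0, na.rm = TRUE)) msgs <- c(msgs, "FPKM values must be non-negative")
  if (anyDuplicated(colnames(object))) msgs <- c(msgs, "duplicate sample labels")
  if (anyDuplicated(rownames(object))) msgs <- c(msgs, "duplicate gene ids")
  if (length(msgs)) msgs else TRUE
})

#' MarkerFit: single-marker likelihood fit
#'
#' Maximum-likelihood fit of the genotype-class normal model at one marker:
#' class means and pooled ML variance under the alternative, grand mean and ML
#' variance under the null, the log-likelihood-ratio statistic, phenotypic
#' variance explained, and the genetic effect(s).
#'
#' @slot marker marker id.
#' @slot segType declared segregation type.
#' @slot n number of individuals used (non-missing phenotype and genotype).
#' @slot counts per-class counts.
#' @slot means per-class phenotype means.
#' @slot mu0 grand mean under the null.
#' @slot sigma2 pooled ML residual variance under the alternative (divisor n).
#' @slot sigma20 ML variance under the null (divisor n).
#' @slot LR log-likelihood-ratio statistic, 2*(l1 - l0) = n*log(RSS0/RSS1).
#' @slot pve phenotypic variance explained, percent: 100*(1 - RSS1/RSS0).
#' @slot effects named vector: \code{delta} for two classes; \code{a} (additive)
#'   and \code{d} (dominance) for three.
#' @exportClass MarkerFit
setClass("MarkerFit",
         slots = c(marker = "character", segType = "character", n = "integer",
                   counts = "numeric", means = "numeric", mu0 = "numeric",
                   sigma2 = "numeric", sigma20 = "numeric", LR = "numeric",
                   pve = "numeric", effects = "numeric"))

#' ScanResult: genome scan for one trait
#'
#' Per-marker likelihood-ratio profile for a single trait, optionally with the
#' permutation genome-wide threshold and the permutation maxima it came from.
#'
#' @slot trait trait name.
#' @slot fits data.frame with one row per eligible marker: marker, lg, pos,
#'   segType, n, LR, pve and genetic effects.
#' @slot skipped data.frame of markers excluded from the scan, with a reason.
#' @slot threshold genome-wide LR cutoff (NA until \code{permutationThreshold}).
#' @slot permMax the permutation genome-wide maxima.
#' @slot alpha significance level used for the threshold.
#' @exportClass ScanResult
setClass("ScanResult",
         slots = c(trait = "character", fits = "data.frame", skipped = "data.frame",
                   threshold = "numeric", permMax = "numeric", alpha = "numeric"))

setValidity("ScanResult", function(object) {
  f <- object@fits
  need <- c("marker", "lg", "pos", "segType", "n", "LR", "pve")
  if (!all(need %in% names(f)))
    return(sprintf("fits must have columns %s", paste(need, collapse = ", ")))
  if (nrow(f) && any(f$LR < -1e-8, na.rm = TRUE)) return("LR must be >= 0")
  if (length(object@permMax) && !is.na(object@threshold) && length(object@alpha)) {
    np <- length(object@permMax)
    expect <- sort(object@permMax)[ceiling((1 - object@alpha) * np)]
    if (!isTRUE(all.equal(expect, object@threshold)))
      return("threshold is not reproducible from permMax and alpha")
  }
  TRUE
})
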