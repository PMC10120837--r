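#' Construct a LinkageMap
#'
#' @param marker character vector of marker ids.
#' @param lg linkage-group labels (coerced to character).
#' @param pos genetic positions in centimorgans.
#' @return A \linkS4class{LinkageMap}, sorted by (lg, pos).
#' @examples
#' lm <- LinkageMap(c("m1", "m2"), c(1, 1), c(0, 10))
#' nMarkers(lm)
#' @export
LinkageMap <- function(marker, lg, pos) {
  m <- data.frame(marker = as.character(marker), lg = as.character(lg),
                  pos = as.numeric(pos), stringsAsFactors = FALSE)
  m <- m[order(m$lg, m$pos, method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  new("LinkageMap", map = m)
}

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix (individuals x markers) of genotype class
#'   labels; NA or "" for missing.
#' @param segType character vector ("testcross2"/"intercross3") per marker.
#' @param classLabels optional list of label sets per marker; defaults to the
#'   canonical labels aa/ab (testcross) and AA/Aa/aa (intercross).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(calls, segType, classLabels = NULL) {
  calls <- as.matrix(calls)
  calls[!is.na(calls) & calls == ""] <- NA_character_
  storage.mode(calls) <- "character"
  segType <- stats::setNames(as.character(segType), colnames(calls))
  if (is.null(classLabels))
    classLabels <- lapply(segType, function(t) .SEG_LABELS[[t]])
  names(classLabels) <- colnames(calls)
  new("GenotypeMatrix", calls = calls, segType = segType, classLabels = classLabels)
}

#' Construct a PhenotypeTable
#'
#' Trait modules are looked up in the canonical leaf-trait schema (LA, LP, LL,
#' LW = size; LLo, AR, P_L, P_LW, Rect, Cir = shape; R, G, B, CV = color)
#' unless supplied explicitly.
#'
#' @param values numeric matrix (individuals x traits) with dimnames.
#' @param module optional character vector of modules per trait.
#' @param units optional character vector of units per trait.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(values, module = NULL, units = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  traits <- colnames(values)
  idx <- match(traits, .LEAF_TRAITS$trait)
  if (is.null(module)) {
    if (anyNA(idx))
      stop("unknown trait(s) with no module tag: ",
           paste(traits[is.na(idx)], collapse = ", "),
           " (supply `module` explicitly)")
    module <- .LEAF_TRAITS$module[idx]
  }
  if (is.null(units))
    units <- ifelse(is.na(idx), "", .LEAF_TRAITS$units[idx])
  ti <- data.frame(trait = traits, module = module, units = units,
                   stringsAsFactors = FALSE)
  new("PhenotypeTable", values = values, traitInfo = ti)
}

#' Construct an FpkmExperiment
#'
#' @param fpkm numeric matrix (genes x samples) of non-negative FPKM values.
#' @param ... further arguments to \code{SummarizedExperiment}, e.g. rowData.
#' @return An \linkS4class{FpkmExperiment}.
#' @export
FpkmExperiment <- function(fpkm, ...) {
  fpkm <- as.matrix(fpkm)
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(fpkm = fpkm), ...)
  new("FpkmExperiment", se)
}

## ---- generics ----

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @rdname accessors
#' @export
setGeneric("traitModules", function(x) standardGeneric("traitModules"))
#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("segregationType", function(x) standardGeneric("segregationType"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))
#' @rdname accessors
#' @export
setGeneric("lrProfile", function(x) standardGeneric("lrProfile"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("permutationMaxima", function(x) standardGeneric("permutationMaxima"))
#' @rdname accessors
#' @export
setGeneric("qtlCalls", function(x) standardGeneric("qtlCalls"))

## ---- methods ----

#' Accessors for leafqtl data classes
#'
#' \code{mapTable}, \code{genotypeCalls}, \code{traitValues} and \code{fpkm}
#' return the underlying tables; the remaining accessors return ids, counts,
#' module tags, LR profiles, thresholds and QTL calls.
#'
#' @name accessors
#' @aliases nMarkers markerIds nIndividuals individualIds traitNames
#'   traitModules traitValues mapTable genotypeCalls segregationType
#'   classLabels fpkm lrProfile threshold permutationMaxima qtlCalls
NULL

#' @rdname accessors
setMethod("nMarkers", "LinkageMap", function(x) nrow(x@map))
#' @rdname accessors
setMethod("markerIds", "LinkageMap", function(x) x@map$marker)
#' @rdname accessors
setMethod("mapTable", "LinkageMap", function(x) x@map)

#' @rdname accessors
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@calls))
#' @rdname accessors
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@calls))
#' @rdname accessors
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@calls))
#' @rdname accessors
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@calls))
#' @rdname accessors
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("segregationType", "GenotypeMatrix", function(x) x@segType)
#' @rdname accessors
setMethod("classLabels", "GenotypeMatrix", function(x) x@classLabels)

#' @rdname accessors
setMethod("nIndividuals", "PhenotypeTable", function(x) nrow(x@values))
#' @rdname accessors
setMethod("individualIds", "PhenotypeTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("traitNames", "PhenotypeTable", function(x) colnames(x@values))
#' @rdname accessors
setMethod("traitModules", "PhenotypeTable",
          function(x) stats::setNames(x@traitInfo$module, x@traitInfo$trait))
#' @rdname accessors
setMethod("traitValues", "PhenotypeTable", function(x) x@values)

#' @rdname accessors
setMethod("fpkm", "FpkmExperiment",
          function(x) SummarizedExperiment::assay(x, "fpkm"))

#' @rdname accessors
setMethod("lrProfile", "ScanResult", function(x) x@fits)
#' @rdname accessors
setMethod("threshold", "ScanResult", function(x) x@threshold)
#' @rdname accessors
setMethod("permutationMaxima", "ScanResult", function(x) x@permMax)

#' @rdname accessors
#' @details \code{qtlCalls} returns the rows of the LR profile at or above the
#'   genome-wide threshold; it errors if no threshold has been attached.
setMethod("qtlCalls", "ScanResult", function(x) {
  if (is.na(x@threshold))
    stop("no threshold attached; run permutationThreshold() first")
  x@fits[!is.na(x@fits$LR) & x@fits$LR >= x@threshold, , drop = FALSE]
})

## ---- show ----

setMethod("show", "LinkageMap", function(object) {
  m <- object@map
  cat(sprintf("LinkageMap: %d markers on %d linkage group(s), span %.1f cM\n",
              nrow(m), length(unique(m$lg)),
              sum(vapply(split(m$pos, m$lg), function(p) diff(range(p)), 0))))
})

setMethod("show", "GenotypeMatrix", function(object) {
  tab <- table(object@segType)
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%s); %.2f%% missing\n",
              nrow(object@calls), ncol(object@calls),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              100 * mean(is.na(object@calls))))
})

setMethod("show", "PhenotypeTable", function(object) {
  tab <- table(factor(object@traitInfo$module, c("size", "shape", "color")))
  cat(sprintf("PhenotypeTable: %d individuals x %d traits (size %d, shape %d, color %d)\n",
              nrow(object@values), ncol(object@values), tab["size"], tab["shape"],
              tab["color"]))
})

setMethod("show", "MarkerFit", function(object) {
  cat(sprintf("MarkerFit %s [%s]: n = %d, LR = %.3f, PVE = %.2f%%\n",
              object@marker, object@segType, object@n, object@LR, object@pve))
  cat("  class means:",
      paste(sprintf("%s = %.3f", names(object@means), object@means), collapse = ", "),
      "\n  effects:",
      paste(sprintf("%s = %.3f", names(object@effects), object@effects), collapse = ", "),
      "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult for trait '%s': %d markers scanned, %d skipped\n",
              object@trait, nrow(object@fits), nrow(object@skipped)))
  if (!is.na(object@threshold))
    cat(sprintf("  genome-wide threshold (alpha = %.3g, %d permutations): LR = %.3f; %d call(s)\n",
                object@alpha, length(object@permMax), object@threshold,
                sum(object@fits$LR >= object@threshold, na.rm = TRUE)))
})
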