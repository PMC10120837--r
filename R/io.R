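## Readers and writers for the package's plain-text dialects.
##
## Dialects: linkage map / genotype / phenotype tables are comma-separated,
## expression matrices tab-separated; all carry a header row. The genotype file
## has a second header row declaring each marker's segregation type. Floats are
## serialized at 6 significant digits, so a read -> write -> read cycle is
## idempotent (the second file is bit-identical).

.drop_bad_ids <- function(ids, file, header_lines) {
  bad <- is.na(ids) | trimws(ids) == ""
  if (any(bad)) {
    lines <- which(bad) + header_lines
    warning(sprintf("%s: rejected %d row(s) with unparseable ids (file line %s)",
                    basename(file), sum(bad), paste(lines, collapse = ", ")),
            call. = FALSE)
  }
  !bad
}

.need_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", basename(file),
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read a linkage map (CSV: marker, lg, pos)
#'
#' @param path file path.
#' @return A \linkS4class{LinkageMap}.
#' @export
readLinkageMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .need_cols(df, c("marker", "lg", "pos"), path)
  keep <- .drop_bad_ids(df$marker, path, 1L)
  df <- df[keep, , drop = FALSE]
  LinkageMap(df$marker, df$lg, df$pos)
}

#' @rdname readLinkageMap
#' @param x object to write.
#' @export
writeLinkageMap <- function(x, path) {
  stopifnot(is(x, "LinkageMap"))
  m <- x@map
  m$pos <- signif(m$pos, 6)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' CSV with a two-row header: row 1 holds marker ids, row 2 the segregation
#' type of each marker (testcross2 / intercross3). Cells are genotype class
#' labels ("aa"/"ab" for test-cross markers, "AA"/"Aa"/"aa" for inter-cross);
#' missing calls are empty cells or "NA".
#'
#' @param path file path.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 2,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(hdr) < 2 || ncol(hdr) < 2)
    stop(sprintf("%s: expected a two-row header (marker ids, segregation types)",
                 basename(path)), call. = FALSE)
  markers <- as.character(hdr[1, -1])
  segType <- as.character(hdr[2, -1])
  body <- utils::read.csv(path, header = FALSE, skip = 2,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  ids <- as.character(body[[1]])
  keep <- .drop_bad_ids(ids, path, 2L)
  body <- body[keep, , drop = FALSE]
  calls <- as.matrix(body[, -1, drop = FALSE])
  dimnames(calls) <- list(as.character(body[[1]]), markers)
  GenotypeMatrix(calls, segType)
}

#' @rdname readGenotypes
#' @param x object to write.
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", markerIds(x)), collapse = ","), con)
  writeLines(paste(c("segtype", unname(x@segType)), collapse = ","), con)
  body <- cbind(individualIds(x), x@calls)
  body[is.na(body)] <- ""
  utils::write.table(body, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a phenotype table (CSV: id column then one column per trait)
#'
#' Trait modules are inferred from the canonical leaf-trait schema when not
#' supplied.
#'
#' @param path file path.
#' @param module optional module tags per trait.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path, module = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .need_cols(df, "id", path)
  keep <- .drop_bad_ids(as.character(df$id), path, 1L)
  df <- df[keep, , drop = FALSE]
  v <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df$id)
  PhenotypeTable(v, module = module)
}

#' @rdname readPhenotypes
#' @param x object to write.
#' @export
writePhenotypes <- function(x, path) {
  stopifnot(is(x, "PhenotypeTable"))
  df <- data.frame(id = individualIds(x), signif(x@values, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an FPKM expression matrix (TSV: gene column then one column per sample)
#'
#' Negative values are a validation error.
#'
#' @param path file path.
#' @return An \linkS4class{FpkmExperiment}.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .need_cols(df, "gene", path)
  keep <- .drop_bad_ids(as.character(df$gene), path, 1L)
  df <- df[keep, , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$gene)
  FpkmExperiment(m)
}

#' @rdname readExpression
#' @param x object to write.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "FpkmExperiment"))
  df <- data.frame(gene = rownames(x), signif(fpkm(x), 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read any pipeline input by schema
#'
#' Thin dispatcher over the typed readers.
#'
#' @param path file path.
#' @param schema one of "map", "genotype", "phenotype", "expression".
#' @param ... passed to the schema's reader.
#' @return The validated typed object for the schema.
#' @export
readDataset <- function(path, schema = c("map", "genotype", "phenotype", "expression"),
                        ...) {
  schema <- match.arg(schema)
  switch(schema,
         map = readLinkageMap(path),
         genotype = readGenotypes(path),
         phenotype = readPhenotypes(path, ...),
         expression = readExpression(path))
}

#' Write results tables
#'
#' Serializes scan results, summary tables and edge lists with deterministic
#' column order and 6-significant-digit floats, as TSV or JSON.
#'
#' @param obj a \linkS4class{ScanResult} or a data.frame.
#' @param path output file.
#' @param format "tsv" or "json".
#' @export
setGeneric("writeResults", function(obj, path, format = c("tsv", "json"))
  standardGeneric("writeResults"))

.signif_df <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' @rdname writeResults
setMethod("writeResults", "data.frame", function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  obj <- .signif_df(obj)
  if (format == "tsv")
    utils::write.table(obj, path, sep = "\t", row.names = FALSE, quote = FALSE)
  else
    jsonlite::write_json(obj, path, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
})

#' @rdname writeResults
setMethod("writeResults", "ScanResult", function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- cbind(trait = obj@trait, .signif_df(obj@fits),
                threshold = signif(obj@threshold, 6), alpha = obj@alpha)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(trait = obj@trait, fits = .signif_df(obj@fits),
                    skipped = obj@skipped, threshold = signif(obj@threshold, 6),
                    permMax = signif(obj@permMax, 6), alpha = obj@alpha)
    jsonlite::write_json(payload, path, digits = NA, na = "null", auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
})

#' Read back a serialized ScanResult
#'
#' @param path file written by \code{writeResults}.
#' @param format "tsv" or "json".
#' @return A \linkS4class{ScanResult} (TSV files carry no permutation maxima).
#' @export
readScanResult <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    thr <- if (nrow(df)) df$threshold[1] else NA_real_
    alpha <- if (nrow(df)) df$alpha[1] else NA_real_
    trait <- if (nrow(df)) df$trait[1] else NA_character_
    fits <- df[, setdiff(names(df), c("trait", "threshold", "alpha")), drop = FALSE]
    new("ScanResult", trait = trait, fits = fits,
        skipped = data.frame(marker = character(), reason = character()),
        threshold = thr, permMax = numeric(), alpha = alpha)
  } else {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    fits <- as.data.frame(p$fits, stringsAsFactors = FALSE)
    skipped <- if (length(p$skipped)) as.data.frame(p$skipped, stringsAsFactors = FALSE)
               else data.frame(marker = character(), reason = character())
    new("ScanResult", trait = p$trait, fits = fits, skipped = skipped,
        threshold = if (is.null(p$threshold)) NA_real_ else p$threshold,
        permMax = as.numeric(p$permMax %||% numeric()), alpha = p$alpha)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the stage name, parameter values, seed and input dimensions of a
#' pipeline stage as JSON (and echoes a one-line summary to stderr).
#'
#' @param dir output directory.
#' @param stage stage name.
#' @param params named list of parameters.
#' @param seed integer seed used.
#' @param dims named list of input dimensions.
#' @return Invisibly, the manifest path.
#' @export
writeManifest <- function(dir, stage, params = list(), seed = NA, dims = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("manifest-%s.json", stage))
  payload <- list(stage = stage, seed = seed, params = params, dims = dims,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[%s] seed=%s %s", stage, seed,
                  paste(sprintf("%s=%s", names(dims), unlist(dims)), collapse = " ")))
  invisible(path)
}
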