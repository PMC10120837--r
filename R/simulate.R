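#' Haldane map function
#'
#' Recombination fraction for a genetic distance of \code{d} centimorgans under
#' no interference: r = (1 - exp(-2d/100))/2.
#'
#' @param d distance in cM (vectorized).
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

#' Deterministic per-stage sub-seed
#'
#' One global seed drives a per-stage seed sequence, so pipeline stages are
#' independently reproducible. The combined (seed, stage) value is scrambled
#' through one Mersenne-Twister draw: a plain linear hash would leave fixed
#' arithmetic offsets between the seeds of different stages, which can
#' correlate their streams across replicates. The caller's RNG state is left
#' untouched.
#'
#' @param seed integer master seed.
#' @param stage stage name.
#' @return An integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer((as.numeric(seed) * 131071 + h) %% 2147483629))
  sample.int(2147483646L, 1)
}

#' Simulate meiotic gametes along one linkage group
#'
#' Each gamete is a chain of haplotype indicators (0 = first parental
#' haplotype, 1 = second); crossovers between adjacent markers occur with the
#' Haldane probability implied by their cM spacing.
#'
#' @param nGametes number of gametes.
#' @param positions marker positions in cM (non-decreasing).
#' @param seed integer seed.
#' @return Integer matrix, gametes x markers, entries 0/1.
#' @export
simulateGametes <- function(nGametes, positions, seed = 1) {
  stopifnot(nGametes > 0, length(positions) >= 1, !is.unsorted(positions))
  set.seed(seed)
  m <- length(positions)
  H <- matrix(0L, nGametes, m)
  H[, 1] <- stats::rbinom(nGametes, 1, 0.5)
  if (m > 1) {
    r <- haldane(diff(positions))
    for (j in 2:m) {
      switch_ <- stats::rbinom(nGametes, 1, r[j - 1])
      H[, j] <- bitwXor(H[, j - 1], switch_)
    }
  }
  H
}

#' Specification of a simulated outbred F1 cross
#'
#' Defaults describe a desk-scale version of a full-sib mapping population:
#' 179 progeny, 20 linkage groups, evenly spaced markers, and an equal split of
#' test-cross (1:1) and inter-cross (1:2:1) markers.
#'
#' @param nProgeny number of F1 individuals.
#' @param linkageGroups number of linkage groups.
#' @param markersPerGroup markers per linkage group.
#' @param markerSpacing spacing between adjacent markers, cM.
#' @param testcrossFraction proportion of markers segregating 1:1.
#' @param seed integer seed.
#' @return A list of class \code{CrossSpec}.
#' @export
crossSpec <- function(nProgeny = 179, linkageGroups = 20, markersPerGroup = 100,
                      markerSpacing = 1.5, testcrossFraction = 0.5, seed = 1) {
  stopifnot(nProgeny > 0, linkageGroups > 0, markersPerGroup > 0,
            markerSpacing >= 0, testcrossFraction >= 0, testcrossFraction <= 1)
  structure(list(nProgeny = as.integer(nProgeny),
                 linkageGroups = as.integer(linkageGroups),
                 markersPerGroup = as.integer(markersPerGroup),
                 markerSpacing = markerSpacing,
                 testcrossFraction = testcrossFraction,
                 seed = as.integer(seed)),
            class = "CrossSpec")
}

#' Simulate an outbred F1 mapping population
#'
#' Simulates two parental meioses per linkage group with Haldane recombination
#' (coupling phase throughout). Test-cross markers are heterozygous in one
#' randomly chosen parent and segregate aa:ab = 1:1; inter-cross markers are
#' heterozygous in both parents and segregate AA:Aa:aa = 1:2:1.
#'
#' @param spec a \code{\link{crossSpec}}.
#' @return list(map = \linkS4class{LinkageMap}, geno = \linkS4class{GenotypeMatrix}).
#' @examples
#' cx <- simulateCross(crossSpec(nProgeny = 50, linkageGroups = 2,
#'                               markersPerGroup = 10, markerSpacing = 5))
#' cx$geno
#' @export
simulateCross <- function(spec = crossSpec()) {
  stopifnot(inherits(spec, "CrossSpec"))
  if (spec$markersPerGroup * spec$linkageGroups == 0) stop("zero markers")
  n <- spec$nProgeny
  mpg <- spec$markersPerGroup
  pos1 <- (seq_len(mpg) - 1) * spec$markerSpacing

  set.seed(stageSeed(spec$seed, "cross-types"))
  total <- spec$linkageGroups * mpg
  is_tc <- stats::runif(total) < spec$testcrossFraction
  tc_parent <- stats::rbinom(total, 1, 0.5)  # informative parent for testcross

  calls <- matrix(NA_character_, n, total)
  markers <- character(total)
  lgs <- character(total)
  poss <- numeric(total)

  for (g in seq_len(spec$linkageGroups)) {
    Hm <- simulateGametes(n, pos1, seed = stageSeed(spec$seed, sprintf("gamete-m-%d", g)))
    Hf <- simulateGametes(n, pos1, seed = stageSeed(spec$seed, sprintf("gamete-f-%d", g)))
    cols <- (g - 1) * mpg + seq_len(mpg)
    markers[cols] <- sprintf("lg%02d_m%03d", g, seq_len(mpg))
    lgs[cols] <- sprintf("LG%02d", g)
    poss[cols] <- pos1
    for (j in seq_len(mpg)) {
      cj <- cols[j]
      if (is_tc[cj]) {
        hinf <- if (tc_parent[cj] == 0) Hm[, j] else Hf[, j]
        calls[, cj] <- .SEG_LABELS$testcross2[hinf + 1L]
      } else {
        # coupling phase: haplotype 0 carries 'A', haplotype 1 carries 'a'
        calls[, cj] <- .SEG_LABELS$intercross3[Hm[, j] + Hf[, j] + 1L]
      }
    }
  }
  dimnames(calls) <- list(sprintf("ind%03d", seq_len(n)), markers)
  segType <- ifelse(is_tc, "testcross2", "intercross3")
  list(map = LinkageMap(markers, lgs, poss),
       geno = GenotypeMatrix(calls, segType))
}

#' Specification of one planted QTL
#'
#' @param trait trait name the QTL acts on.
#' @param marker marker id it is planted at.
#' @param classMeans one phenotype mean per genotype class of the marker, in
#'   declared label order.
#' @param residualSd residual standard deviation of the trait.
#' @param module trait module tag.
#' @return A list of class \code{QTLSpec}.
#' @export
qtlSpec <- function(trait, marker, classMeans, residualSd = 1, module = "size") {
  stopifnot(residualSd > 0, length(classMeans) %in% c(2L, 3L))
  structure(list(trait = trait, marker = marker, classMeans = classMeans,
                 residualSd = residualSd, module = module), class = "QTLSpec")
}

## Expected genotype-class frequencies for a marker.
.class_freq <- function(segType) {
  if (segType == "testcross2") c(0.5, 0.5) else c(0.25, 0.5, 0.25)
}

#' Simulate phenotypes with planted QTLs
#'
#' Each individual's trait value is the sum of the planted class means at its
#' genotypes plus Normal(0, residualSd^2) noise. The truth record carries the
#' planted markers, class means, and the theoretical PVE
#' (between-class variance over total variance, using the expected segregation
#' frequencies and treating multiple planted QTLs as independent).
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param qtls list of \code{\link{qtlSpec}} objects (one or more per trait).
#' @param seed integer seed.
#' @return list(pheno = \linkS4class{PhenotypeTable}, truth = list per trait).
#' @export
simulatePhenotypes <- function(geno, qtls, seed = 1) {
  if (inherits(qtls, "QTLSpec")) qtls <- list(qtls)
  traits <- unique(vapply(qtls, `[[`, "", "trait"))
  n <- nIndividuals(geno)
  vals <- matrix(0, n, length(traits),
                 dimnames = list(individualIds(geno), traits))
  truth <- stats::setNames(vector("list", length(traits)), traits)
  set.seed(stageSeed(seed, "phenotypes"))
  for (tr in traits) {
    specs <- Filter(function(q) q$trait == tr, qtls)
    varB_total <- 0
    y <- numeric(n)
    for (q in specs) {
      j <- match(q$marker, markerIds(geno))
      if (is.na(j)) stop("QTL references unknown marker: ", q$marker)
      labs <- classLabels(geno)[[j]]
      if (length(q$classMeans) != length(labs))
        stop("classMeans length must match marker class count for ", q$marker)
      freq <- .class_freq(segregationType(geno)[j])
      cls <- match(genotypeCalls(geno)[, j], labs)
      mu <- ifelse(is.na(cls), sum(freq * q$classMeans), q$classMeans[cls])
      y <- y + mu
      mbar <- sum(freq * q$classMeans)
      varB_total <- varB_total + sum(freq * (q$classMeans - mbar)^2)
    }
    sd_r <- specs[[1]]$residualSd
    vals[, tr] <- y + stats::rnorm(n, 0, sd_r)
    truth[[tr]] <- list(
      markers = vapply(specs, `[[`, "", "marker"),
      classMeans = lapply(specs, `[[`, "classMeans"),
      residualSd = sd_r,
      module = specs[[1]]$module,
      theoreticalPVE = 100 * varB_total / (varB_total + sd_r^2))
  }
  modules <- vapply(traits, function(tr) truth[[tr]]$module, "")
  list(pheno = PhenotypeTable(vals, module = modules,
                              units = rep("", length(traits))),
       truth = truth)
}

#' Simulate a block-structured FPKM matrix
#'
#' Genes in a cluster share a tissue-profile template (high FPKM in the
#' cluster's up-tissues, low in its down-tissues, intermediate elsewhere) with
#' multiplicative log-normal noise. Genes beyond the cluster sizes get the flat
#' intermediate template ("noise" genes). The generating cluster of each gene
#' is stored in \code{rowData(x)$cluster}.
#'
#' The defaults emulate a heat-map panel of 75 candidate genes across five
#' tissues falling into three co-expression clusters (14 genes up in
#' xylem/phloem, 16 phloem-high/xylem-low, 45 leaf-upregulated).
#'
#' @param nGenes number of genes.
#' @param samples tissue labels.
#' @param clusterSpec list of list(size, up, down) cluster templates.
#' @param noiseSd standard deviation of the log-normal noise (natural-log scale).
#' @param seed integer seed.
#' @param baseFpkm,foldUp intermediate template level and up/down fold factor.
#' @return An \linkS4class{FpkmExperiment} with rowData column \code{cluster}.
#' @export
simulateExpression <- function(nGenes = 75,
                               samples = c("leaf", "petiole", "stem", "xylem", "phloem"),
                               clusterSpec = list(
                                 list(size = 14, up = c("xylem", "phloem"),
                                      down = c("leaf", "petiole")),
                                 list(size = 16, up = "phloem", down = "xylem"),
                                 list(size = 45, up = "leaf", down = character())),
                               noiseSd = 0.3, seed = 1,
                               baseFpkm = 10, foldUp = 10) {
  sizes <- vapply(clusterSpec, `[[`, 0, "size")
  if (sum(sizes) > nGenes) stop("cluster sizes exceed nGenes")
  stopifnot(!anyDuplicated(samples), noiseSd >= 0)
  set.seed(stageSeed(seed, "expression"))
  templates <- lapply(clusterSpec, function(cs) {
    tpl <- rep(baseFpkm, length(samples))
    tpl[samples %in% cs$up] <- baseFpkm * foldUp
    tpl[samples %in% cs$down] <- baseFpkm / foldUp
    tpl
  })
  cluster <- rep("noise", nGenes)
  if (length(sizes))
    cluster[seq_len(sum(sizes))] <- rep(sprintf("C%d", seq_along(sizes)), sizes)
  x <- matrix(baseFpkm, nGenes, length(samples))
  for (i in seq_along(clusterSpec))
    x[cluster == sprintf("C%d", i), ] <-
      matrix(templates[[i]], sum(cluster == sprintf("C%d", i)),
             length(samples), byrow = TRUE)
  x <- x * exp(matrix(stats::rnorm(length(x), 0, noiseSd), nrow(x)))
  dimnames(x) <- list(sprintf("gene%04d", seq_len(nGenes)), samples)
  FpkmExperiment(x, rowData = S4Vectors::DataFrame(cluster = cluster))
}
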