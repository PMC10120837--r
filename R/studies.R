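## Simulation studies: genome-wide type-I error calibration of the permutation
## threshold, and recovery of a planted QTL. Both regenerate a fresh cross per
## replicate so that threshold and scan see independent data each time.

#' Null calibration of the permutation genome-wide threshold
#'
#' Simulates \code{nDatasets} crosses with a pure-noise phenotype, computes
#' each dataset's permutation threshold, and records whether the unpermuted
#' scan's maximum LR exceeds its own threshold. The exceedance fraction
#' estimates the genome-wide type-I error and should match \code{alpha} up to
#' Monte-Carlo error.
#'
#' @param nDatasets number of replicate datasets.
#' @param spec a \code{\link{crossSpec}} template (its seed is re-derived per
#'   replicate).
#' @param nPerm permutations per dataset.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data.frame with one row per dataset: maxLR, threshold, exceeds.
#' @export
nullCalibrationStudy <- function(nDatasets = 200,
                                 spec = crossSpec(nProgeny = 179,
                                                  linkageGroups = 20,
                                                  markersPerGroup = 20,
                                                  markerSpacing = 5),
                                 nPerm = 300, alpha = 0.05, seed = 1) {
  rows <- lapply(seq_len(nDatasets), function(i) {
    si <- stageSeed(seed, sprintf("null-calib-%d", i))
    spec_i <- spec
    spec_i$seed <- si
    cx <- simulateCross(spec_i)
    mk <- markerIds(cx$geno)[1]
    sim <- simulatePhenotypes(cx$geno,
                              qtlSpec("y", mk, rep(0, length(classLabels(cx$geno)[[1]])),
                                      residualSd = 1, module = "size"),
                              seed = si)
    sc <- genomeScan(sim$pheno, cx$geno, cx$map, "y")
    sc <- permutationThreshold(sc, sim$pheno, cx$geno, cx$map, nPerm = nPerm,
                               alpha = alpha, seed = si)
    mx <- max(lrProfile(sc)$LR[is.finite(lrProfile(sc)$LR)])
    data.frame(maxLR = mx, threshold = threshold(sc),
               exceeds = mx >= threshold(sc))
  })
  do.call(rbind, rows)
}

#' Recovery of a planted QTL
#'
#' Plants one test-cross QTL of a given theoretical PVE in the middle of a
#' linkage group, scans, and records whether the scan maximum falls on the
#' planted marker or an immediate map neighbour, together with the estimated
#' PVE at the planted marker.
#'
#' @param nDatasets number of replicate datasets.
#' @param spec a \code{\link{crossSpec}} template.
#' @param pve theoretical phenotypic variance explained, percent.
#' @param seed integer seed.
#' @return data.frame with one row per dataset: peakOffset (markers between
#'   the scan maximum and the planted marker; NA if on another linkage group),
#'   hit (|peakOffset| <= 1), pveAtPlanted, theoreticalPVE.
#' @export
qtlRecoveryStudy <- function(nDatasets = 100,
                             spec = crossSpec(nProgeny = 179,
                                              linkageGroups = 20,
                                              markersPerGroup = 20,
                                              markerSpacing = 5),
                             pve = 20, seed = 1) {
  stopifnot(pve > 0, pve < 100)
  # testcross with equal classes: varB = (delta/2)^2; pick delta for the target
  sd_r <- 2
  delta <- 2 * sd_r * sqrt(pve / (100 - pve))
  rows <- lapply(seq_len(nDatasets), function(i) {
    si <- stageSeed(seed, sprintf("recovery-%d", i))
    spec_i <- spec
    spec_i$seed <- si
    spec_i$testcrossFraction <- 0.5
    cx <- simulateCross(spec_i)
    # plant at an interior (non-terminal) testcross marker near the middle
    seg <- segregationType(cx$geno)
    idx_in_lg <- rep(seq_len(spec_i$markersPerGroup), spec_i$linkageGroups)
    cand <- which(seg == "testcross2" & idx_in_lg > 1 &
                  idx_in_lg < spec_i$markersPerGroup)
    planted <- markerIds(cx$geno)[cand[ceiling(length(cand) / 2)]]
    sim <- simulatePhenotypes(cx$geno,
                              qtlSpec("y", planted, c(0, delta), residualSd = sd_r,
                                      module = "size"),
                              seed = si)
    sc <- genomeScan(sim$pheno, cx$geno, cx$map, "y")
    prof <- lrProfile(sc)
    peak <- which.max(prof$LR)
    planted_row <- match(planted, prof$marker)
    offset <- if (prof$lg[peak] == prof$lg[planted_row]) peak - planted_row
              else NA_integer_
    data.frame(peakOffset = offset,
               hit = !is.na(offset) && abs(offset) <= 1,
               pveAtPlanted = prof$pve[planted_row],
               theoreticalPVE = sim$truth$y$theoreticalPVE)
  })
  do.call(rbind, rows)
}
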