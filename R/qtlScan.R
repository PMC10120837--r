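## Single-marker likelihood-ratio QTL scan.
##
## At each marker the phenotype is modelled as a mixture of genotype-class
## normals with common variance: under the alternative each class j has its
## own mean mu_j (ML estimate: class mean; pooled ML variance RSS1/n), under
## the null all classes share the grand mean (ML variance RSS0/n). The
## statistic is LR = 2*(l1 - l0) = n*log(RSS0/RSS1), the marker-based
## equivalent of n*log(1/(1 - R^2)) for the one-way between-class R^2.
## Genome-wide significance comes from permuting the phenotype vector against
## individual ids and taking an upper order statistic of the per-permutation
## genome-wide maximum LR.

#' Maximum-likelihood genotype-class fit at one marker
#'
#' @param y numeric phenotype values.
#' @param classes genotype class labels, parallel to \code{y}; NA allowed.
#' @param labels declared class-label order (drives the sign convention of the
#'   effects); defaults to the sorted observed labels.
#' @param minClassN minimum per-class count; a smaller class makes the marker
#'   ineligible (condition class \code{leafqtl_sparse_class}).
#' @return A \linkS4class{MarkerFit}. Effects are \code{delta} = mu2 - mu1 for
#'   two classes, and additive \code{a} = (mu3 - mu1)/2 with dominance
#'   \code{d} = mu2 - (mu1 + mu3)/2 for three.
#' @examples
#' f <- fitMarkerModel(c(1, 2, 1, 2, 3, 4, 3, 4),
#'                     rep(c("aa", "ab"), each = 4), minClassN = 4)
#' f@LR  # 8 * log(5)
#' @export
fitMarkerModel <- function(y, classes, labels = NULL, minClassN = 5) {
  ok <- !is.na(y) & !is.na(classes)
  y <- as.numeric(y[ok])
  classes <- as.character(classes[ok])
  if (is.null(labels)) labels <- sort(unique(classes))
  cls <- factor(classes, levels = labels)
  counts <- table(cls)
  observed <- counts > 0
  if (sum(observed) < 2 || any(counts[observed] < minClassN))
    stop(errorCondition(
      sprintf("sparse_class: class counts (%s) below minClassN = %d or < 2 classes",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
              minClassN),
      class = c("leafqtl_sparse_class", "error", "condition")))
  labels <- labels[observed]
  cls <- factor(classes, levels = labels)
  counts <- as.numeric(table(cls))
  n <- length(y)
  mu <- tapply(y, cls, mean)
  mu0 <- mean(y)
  RSS1 <- sum((y - mu[cls])^2)
  RSS0 <- sum((y - mu0)^2)
  if (RSS0 == 0) stop("phenotype has zero variance")
  LR <- if (RSS1 == 0) Inf else n * log(RSS0 / RSS1)
  pve <- 100 * (1 - RSS1 / RSS0)
  effects <- if (length(labels) == 2)
    c(delta = unname(mu[2] - mu[1]))
  else
    c(a = unname((mu[3] - mu[1]) / 2), d = unname(mu[2] - (mu[1] + mu[3]) / 2))
  new("MarkerFit",
      marker = NA_character_,
      segType = if (length(labels) == 2) "testcross2" else "intercross3",
      n = n, counts = stats::setNames(counts, labels),
      means = stats::setNames(as.numeric(mu), labels),
      mu0 = mu0, sigma2 = RSS1 / n, sigma20 = RSS0 / n,
      LR = LR, pve = pve, effects = effects)
}

## Build the sparse scan design for a trait: class-indicator matrix Z
## (individuals x (marker, class) columns), marker membership Zm, class
## counts, and marker eligibility under minClassN.
.prepare_scan <- function(pheno, geno, map, trait, minClassN = 5) {
  stopifnot(is(pheno, "PhenotypeTable"), is(geno, "GenotypeMatrix"),
            is(map, "LinkageMap"))
  if (!trait %in% traitNames(pheno)) stop("unknown trait: ", trait)
  ids <- intersect(individualIds(pheno), individualIds(geno))
  if (!length(ids)) stop("no overlapping individuals between tables")
  y <- traitValues(pheno)[ids, trait]
  keep <- !is.na(y)
  ids <- ids[keep]
  y <- y[keep]
  n <- length(ids)

  mt <- mapTable(map)
  markers <- mt$marker[mt$marker %in% markerIds(geno)]
  mt <- mt[match(markers, mt$marker), , drop = FALSE]
  calls <- genotypeCalls(geno)[ids, markers, drop = FALSE]
  labs <- classLabels(geno)[markers]
  seg <- segregationType(geno)[markers]
  M <- length(markers)
  if (!M) stop("no mapped markers present in the genotype matrix")

  nlab <- lengths(labs)
  offset <- c(0, cumsum(nlab))[seq_len(M)]
  cls_idx <- matrix(NA_integer_, n, M)
  for (j in seq_len(M))
    cls_idx[, j] <- match(calls[, j], labs[[j]])

  obs <- which(!is.na(cls_idx), arr.ind = TRUE)
  col_j <- offset[obs[, 2]] + cls_idx[obs]
  K <- sum(nlab)
  Z <- Matrix::sparseMatrix(i = obs[, 1], j = col_j, x = 1, dims = c(n, K))
  markerOf <- rep(seq_len(M), nlab)
  nj <- Matrix::colSums(Z)

  # eligibility: every declared class observed with >= minClassN individuals
  min_count <- vapply(split(nj, markerOf), min, 0)
  n_classes_obs <- vapply(split(nj > 0, markerOf), sum, 0)
  eligible <- min_count >= minClassN & n_classes_obs >= 2

  list(ids = ids, y = y, n = n, markers = markers, mt = mt, seg = seg,
       labs = labs, Z = Z, markerOf = markerOf, nj = nj, eligible = eligible,
       minCount = min_count)
}

## Vectorized LR over markers for one or many phenotype columns.
## Y: n x P matrix. Returns list(LR, pve, ess, rss0, nm) with M x P matrices.
.scan_core <- function(prep, Y) {
  Y <- as.matrix(Y)
  Z <- prep$Z
  S <- as.matrix(Matrix::crossprod(Z, Y))            # class sums, K x P
  ESS <- rowsum(S^2 / pmax(prep$nj, 1), prep$markerOf)  # sum_j S_j^2 / n_j
  Tm <- rowsum(S, prep$markerOf)                     # per-marker totals
  Zm <- Z %*% Matrix::sparseMatrix(i = seq_along(prep$markerOf),
                                   j = prep$markerOf, x = 1,
                                   dims = c(length(prep$markerOf),
                                            max(prep$markerOf)))
  Q <- as.matrix(Matrix::crossprod(Zm, Y^2))         # per-marker sum y^2
  nm <- Matrix::colSums(Zm)
  RSS0 <- Q - Tm^2 / nm
  RSS1 <- Q - ESS
  tol <- pmax(RSS0, 0) * 1e-12
  RSS1 <- pmax(RSS1, 0)
  LR <- matrix(NA_real_, nrow(RSS0), ncol(RSS0))
  zero1 <- RSS1 <= tol
  pos <- RSS0 > 0 & !zero1
  LR[pos] <- (nm * log(pmax(RSS0, .Machine$double.xmin) /
                       pmax(RSS1, .Machine$double.xmin)))[pos]
  LR[zero1 & RSS0 > 0] <- Inf
  LR[RSS0 <= 0] <- 0
  pve <- ifelse(RSS0 > 0, 100 * (1 - RSS1 / RSS0), 0)
  pve[zero1 & RSS0 > 0] <- 100
  list(LR = LR, pve = pve, nm = nm)
}

#' Genome scan for one trait
#'
#' Fits the genotype-class likelihood model at every eligible mapped marker
#' (QTLs are assumed to sit at marker positions; no interval imputation) and
#' returns the LR profile ordered by linkage group and position. Markers with
#' a class below \code{minClassN}, or fewer than two observed classes, are
#' listed in \code{skipped} with reason \code{sparse_class}.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param map a \linkS4class{LinkageMap}.
#' @param trait trait name to scan.
#' @param minClassN minimum per-class count for marker eligibility.
#' @return A \linkS4class{ScanResult} without a threshold.
#' @export
genomeScan <- function(pheno, geno, map, trait, minClassN = 5) {
  prep <- .prepare_scan(pheno, geno, map, trait, minClassN)
  el <- prep$eligible
  skipped <- data.frame(marker = prep$markers[!el],
                        reason = rep("sparse_class", sum(!el)),
                        stringsAsFactors = FALSE)
  M <- length(prep$markers)
  core <- .scan_core(prep, matrix(prep$y, ncol = 1))

  # per-class means for effect estimates
  S <- as.numeric(Matrix::crossprod(prep$Z, prep$y))
  mu <- S / pmax(prep$nj, 1)
  mu_by_marker <- split(mu, prep$markerOf)
  nj_by_marker <- split(prep$nj, prep$markerOf)

  eff <- t(vapply(seq_len(M), function(j) {
    m <- mu_by_marker[[j]]
    nj <- nj_by_marker[[j]]
    m[nj == 0] <- NA
    if (length(m) == 2)
      c(delta = m[2] - m[1], a = NA_real_, d = NA_real_,
        mu1 = m[1], mu2 = m[2], mu3 = NA_real_)
    else
      c(delta = NA_real_, a = (m[3] - m[1]) / 2, d = m[2] - (m[1] + m[3]) / 2,
        mu1 = m[1], mu2 = m[2], mu3 = m[3])
  }, numeric(6)))

  fits <- data.frame(marker = prep$markers, lg = prep$mt$lg, pos = prep$mt$pos,
                     segType = unname(prep$seg), n = as.integer(core$nm),
                     LR = core$LR[, 1], pve = core$pve[, 1],
                     delta = eff[, "delta"], a = eff[, "a"], d = eff[, "d"],
                     mu1 = eff[, "mu1"], mu2 = eff[, "mu2"], mu3 = eff[, "mu3"],
                     stringsAsFactors = FALSE)
  fits <- fits[el, , drop = FALSE]
  rownames(fits) <- NULL
  new("ScanResult", trait = trait, fits = fits, skipped = skipped,
      threshold = NA_real_, permMax = numeric(), alpha = NA_real_)
}

#' Genome-wide threshold from permutation maxima
#'
#' The ceiling((1 - alpha) * N)-th order statistic of the N permutation
#' genome-wide maxima.
#'
#' @param maxima numeric vector of per-permutation genome-wide maximum LRs.
#' @param alpha significance level in (0, 1].
#' @return The threshold.
#' @examples
#' thresholdFromMaxima(1:100, alpha = 0.05)  # 95
#' @export
thresholdFromMaxima <- function(maxima, alpha = 0.05) {
  stopifnot(length(maxima) >= 1, alpha > 0, alpha <= 1)
  sort(maxima)[max(1L, ceiling((1 - alpha) * length(maxima)))]
}

#' Permutation genome-wide threshold
#'
#' Shuffles the phenotype vector against individual ids \code{nPerm} times,
#' records the genome-wide maximum LR of each permuted scan (markers flagged
#' with infinite LR are excluded from the maxima), and sets the threshold to
#' the ceiling((1 - alpha) * nPerm)-th order statistic of the maxima.
#'
#' @param scan a \linkS4class{ScanResult} from \code{\link{genomeScan}}.
#' @param pheno,geno,map the inputs the scan was built from.
#' @param nPerm number of permutations (>= 100).
#' @param alpha genome-wide significance level.
#' @param seed integer seed.
#' @param minClassN must match the scan's value.
#' @return The scan with \code{threshold}, \code{permMax} and \code{alpha} set.
#' @export
permutationThreshold <- function(scan, pheno, geno, map, nPerm = 1000,
                                 alpha = 0.05, seed = 1, minClassN = 5) {
  stopifnot(is(scan, "ScanResult"), nPerm >= 100, alpha > 0, alpha <= 1)
  prep <- .prepare_scan(pheno, geno, map, scan@trait, minClassN)
  if (!any(prep$eligible)) stop("no eligible markers for permutation")
  set.seed(stageSeed(seed, paste0("perm-", scan@trait)))
  n <- prep$n
  P <- as.integer(nPerm)
  Yp <- vapply(seq_len(P), function(i) prep$y[sample.int(n)], numeric(n))
  core <- .scan_core(prep, Yp)
  LR <- core$LR[prep$eligible, , drop = FALSE]
  LR[!is.finite(LR)] <- NA
  maxima <- apply(LR, 2, max, na.rm = TRUE)
  thr <- thresholdFromMaxima(maxima, alpha)
  scan@permMax <- maxima
  scan@alpha <- alpha
  scan@threshold <- thr
  methods::validObject(scan)
  scan
}

#' QTL calling and cross-module co-location
#'
#' Calls a QTL at every marker whose LR reaches its trait's genome-wide
#' threshold, tabulates co-located calls across traits (same marker, or
#' markers within \code{colocWindow} cM on the same linkage group), and
#' counts distinct QTL markers per trait module with their pairwise and
#' triple intersections (Venn counts; intersections use marker identity).
#'
#' @param scans list of thresholded \linkS4class{ScanResult} objects.
#' @param modules named character vector mapping trait -> module.
#' @param colocWindow co-location window in cM (0 = same marker only).
#' @return list(calls, coloc, venn).
#' @export
callAndColocate <- function(scans, modules, colocWindow = 0) {
  traits <- vapply(scans, function(s) s@trait, "")
  miss <- setdiff(traits, names(modules))
  if (length(miss)) stop("traits missing module tags: ", paste(miss, collapse = ", "))
  calls <- do.call(rbind, lapply(scans, function(s) {
    q <- qtlCalls(s)
    if (!nrow(q)) return(NULL)
    data.frame(trait = s@trait, module = unname(modules[s@trait]),
               q[, c("marker", "lg", "pos", "segType", "LR", "pve")],
               threshold = s@threshold, stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(trait = character(), module = character(),
                        marker = character(), lg = character(), pos = numeric(),
                        segType = character(), LR = numeric(), pve = numeric(),
                        threshold = numeric(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  coloc <- NULL
  if (nrow(calls) > 1) {
    idx <- utils::combn(nrow(calls), 2)
    a <- calls[idx[1, ], ]; b <- calls[idx[2, ], ]
    hit <- a$trait != b$trait & a$lg == b$lg & abs(a$pos - b$pos) <= colocWindow
    if (any(hit))
      coloc <- data.frame(trait_a = a$trait[hit], trait_b = b$trait[hit],
                          marker_a = a$marker[hit], marker_b = b$marker[hit],
                          lg = a$lg[hit], dist_cM = abs(a$pos - b$pos)[hit],
                          module_a = a$module[hit], module_b = b$module[hit],
                          stringsAsFactors = FALSE)
  }
  if (is.null(coloc))
    coloc <- data.frame(trait_a = character(), trait_b = character(),
                        marker_a = character(), marker_b = character(),
                        lg = character(), dist_cM = numeric(),
                        module_a = character(), module_b = character(),
                        stringsAsFactors = FALSE)

  mk <- function(mod) unique(calls$marker[calls$module == mod])
  sz <- mk("size"); sh <- mk("shape"); co <- mk("color")
  venn <- list(size = length(sz), shape = length(sh), color = length(co),
               size_shape = length(intersect(sz, sh)),
               size_color = length(intersect(sz, co)),
               shape_color = length(intersect(sh, co)),
               size_shape_color = length(Reduce(intersect, list(sz, sh, co))))
  list(calls = calls, coloc = coloc, venn = venn)
}
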