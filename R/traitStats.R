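#' Summary statistics per trait
#'
#' Mean, median, sample (n-1) standard deviation, variance, max, min, range,
#' coefficient of variation (percent), standard error, g1 skewness
#' (m3/m2^1.5) and excess kurtosis (m4/m2^2 - 3), computed per trait with
#' missing values excluded. Constant traits are flagged as degenerate and
#' report 0 skewness/kurtosis/CV.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @return data.frame, one row per trait.
#' @export
summarizeTraits <- function(pheno) {
  stopifnot(is(pheno, "PhenotypeTable"))
  v <- traitValues(pheno)
  mods <- traitModules(pheno)
  out <- lapply(colnames(v), function(tr) {
    y <- v[, tr]
    y <- y[!is.na(y)]
    n <- length(y)
    if (n < 3)
      stop(sprintf("trait %s has %d non-missing value(s); need >= 3", tr, n))
    m <- mean(y)
    s <- stats::sd(y)
    mx <- max(y); mn <- min(y)
    degenerate <- s == 0
    if (degenerate) {
      skew <- kurt <- cv <- 0
    } else {
      m2 <- mean((y - m)^2)
      m3 <- mean((y - m)^3)
      m4 <- mean((y - m)^4)
      skew <- m3 / m2^1.5
      kurt <- m4 / m2^2 - 3
      cv <- 100 * s / m
    }
    data.frame(trait = tr, module = unname(mods[tr]), n = n, mean = m,
               median = stats::median(y), sd = s, variance = s^2,
               max = mx, min = mn, range = mx - mn, cv_percent = cv,
               se = s / sqrt(n), skewness = skew, kurtosis = kurt,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Pairwise-complete Pearson correlations of the columns of `m` with two-sided
## p-values from the t transform (t = r*sqrt(n-2)/sqrt(1-r^2), df = n-2).
## Returns the edge table over all pairs with >= minN complete observations,
## with node_a < node_b. Zero-variance columns are skipped with a warning.
.cor_edges <- function(m, minN = 4) {
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  zv <- !is.na(sds) & sds == 0
  if (any(zv)) {
    warning("zero-variance column(s) skipped: ",
            paste(colnames(m)[zv], collapse = ", "), call. = FALSE)
    m <- m[, !zv, drop = FALSE]
  }
  if (ncol(m) < 2)
    return(data.frame(node_a = character(), node_b = character(),
                      r = numeric(), p = numeric(), n = integer()))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(m))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  a <- colnames(m)[ut[, 1]]
  b <- colnames(m)[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  rv <- r[ut]
  nv <- n[ut]
  keep <- !is.na(rv) & nv >= minN
  rv <- rv[keep]; nv <- nv[keep]; a <- a[keep]; b <- b[keep]
  p <- ifelse(abs(rv) >= 1, 0,
              2 * stats::pt(-abs(rv) * sqrt(nv - 2) / sqrt(1 - rv^2), nv - 2))
  data.frame(node_a = a, node_b = b, r = rv, p = p, n = as.integer(nv),
             stringsAsFactors = FALSE)[order(a, b), , drop = FALSE]
}

#' Thresholded trait-correlation network
#'
#' Pearson correlations on pairwise-complete observations between all trait
#' pairs; an edge is kept iff |r| >= rMin and p <= pMax (two-sided t-transform
#' p-value). Each edge is annotated with its module pair, and a per-module-pair
#' edge count summary is returned.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param rMin minimum |r| for an edge.
#' @param pMax maximum p-value for an edge.
#' @return list(edges, moduleSummary).
#' @export
correlationNetwork <- function(pheno, rMin = 0.10, pMax = 0.05) {
  stopifnot(is(pheno, "PhenotypeTable"))
  all_edges <- .cor_edges(traitValues(pheno), minN = 4)
  mods <- traitModules(pheno)
  pair_mod <- function(a, b) {
    ma <- mods[a]; mb <- mods[b]
    ifelse(ma == mb, paste0("within-", ma), "between")
  }
  all_edges$modulePair <- if (nrow(all_edges)) pair_mod(all_edges$node_a, all_edges$node_b)
                          else character()
  edges <- all_edges[abs(all_edges$r) >= rMin & all_edges$p <= pMax, , drop = FALSE]
  rownames(edges) <- NULL
  ms <- as.data.frame(table(factor(edges$modulePair,
                                   c("within-size", "within-shape", "within-color",
                                     "between"))),
                      stringsAsFactors = FALSE)
  names(ms) <- c("modulePair", "edges")
  list(edges = edges, moduleSummary = ms)
}
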