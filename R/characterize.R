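# Count-table preprocessing and per-taxon characterization of zero inflation
# and overdispersion.

.checkCountMatrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("count matrix must contain non-negative integers")
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
  counts
}

#' Rarefy a count table to a fixed depth
#'
#' Each sample (column) is subsampled without replacement to exactly `depth`
#' reads, equalizing library size across samples. Samples with fewer reads
#' than `depth` cannot be rarefied and are dropped; their ids are attached
#' as attribute `dropped`. Subsampling is delegated to [vegan::rrarefy()].
#'
#' @param counts taxa-by-samples integer matrix.
#' @param depth target reads per sample (default 5000).
#' @param seed optional integer seed.
#' @return rarefied taxa-by-samples matrix (retained samples only) with
#'   attribute `dropped`.
#' @export
rarefyCounts <- function(counts, depth = 5000, seed = NULL) {
  if (length(depth) != 1L || depth <= 0) stop("'depth' must be positive")
  counts <- .checkCountMatrix(counts)
  totals <- colSums(counts)
  keep <- totals >= depth
  dropped <- colnames(counts)[!keep]
  if (is.null(dropped)) dropped <- which(!keep)
  sub <- counts[, keep, drop = FALSE]
  # rrarefy warns when every positive entry exceeds 1 (heuristic for
  # non-count data); genuine deep count tables trip it, so muffle it
  out <- .withSeed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(sub), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  dimnames(out) <- dimnames(sub)
  structure(out, dropped = dropped)
}

#' Drop taxa below a cohort-wide total count
#'
#' Removes taxa (rows) whose total count over all samples is strictly less
#' than `minTotal`; row order of survivors is preserved. The two thresholds
#' used in the workflow are 15 (count characterization) and 30 (per-taxon
#' regression, where rarer taxa provoke sampling errors).
#'
#' @param counts taxa-by-samples integer matrix.
#' @param minTotal minimum cohort-wide total to retain a taxon.
#' @return the filtered matrix, with attribute `removed` naming dropped taxa.
#' @export
filterLowAbundance <- function(counts, minTotal) {
  stopifnot(minTotal >= 0)
  counts <- .checkCountMatrix(counts)
  keep <- rowSums(counts) >= minTotal
  structure(counts[keep, , drop = FALSE], removed = rownames(counts)[!keep])
}

#' Moment-based ZINB characterization of one taxon
#'
#' Matches the first two moments and the zero fraction of the counts to the
#' ZINB moment system
#' `E[Y] = (1-phi) mu`,
#' `Var[Y] = (1-phi) mu (1 + mu/theta + phi mu)`,
#' `P(0) = phi + (1-phi) (theta/(theta+mu))^theta`,
#' eliminating `mu` and root-solving for `phi` (and hence `theta`) by
#' monotone bracketing to tolerance 1e-8. When the observed zero fraction is
#' no larger than the negative binomial alone predicts, `phi` is 0 and
#' `theta` is the plain NB moment estimate; when the variance does not
#' exceed the mean, the Poisson limit (`1/theta = 0`) is used. The NB-part
#' dispersion `invThetaNbHat` re-estimates `1/theta` after removing
#' `floor(phi_hat * n)` zeros, isolating the count component from the
#' structural zeros.
#'
#' @param y non-negative integer count vector, length at least 30 with at
#'   least one positive and non-constant value.
#' @param zeroInflatedCutoff flag a taxon as zero inflated when `phi_hat`
#'   exceeds this (default 0.05).
#' @return list with `mean`, `sd`, `zeroFraction`, `phiHat`, `muHat`,
#'   `invThetaHat`, `invThetaNbHat`, `zeroInflated`.
#' @export
estimateZinbMoments <- function(y, zeroInflatedCutoff = 0.05) {
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integers")
  if (length(y) < 30) stop("need at least 30 observations")
  if (all(y == 0)) stop("'y' is all zeros")
  if (stats::var(y) == 0) stop("'y' has zero variance")
  m <- mean(y); v <- stats::var(y); p0 <- mean(y == 0)
  n <- length(y)

  nbZeroProb <- function(mu, theta) {
    if (!is.finite(theta)) exp(-mu) else exp(theta * (log(theta) - log(theta + mu)))
  }
  thetaAt <- function(phi) {
    mu <- m / (1 - phi)
    d <- v / m - 1 - phi * mu
    if (d <= 0) Inf else mu / d
  }
  g <- function(phi) {
    mu <- m / (1 - phi)
    phi + (1 - phi) * nbZeroProb(mu, thetaAt(phi)) - p0
  }

  eps <- 1e-12
  if (g(0) >= 0) {
    phiHat <- 0
  } else {
    # largest admissible phi: just below the zero-fraction ceiling
    hi <- min(p0, 1 - 1e-9) - eps
    if (hi <= 0 || g(hi) < 0) {
      phiHat <- max(hi, 0)   # even maximal inflation cannot reach p0
    } else {
      phiHat <- stats::uniroot(g, c(0, hi), tol = 1e-8)$root
    }
  }
  phiHat <- min(max(phiHat, 0), 1)
  muHat <- m / (1 - phiHat)
  thetaHat <- thetaAt(phiHat)
  invThetaHat <- if (is.finite(thetaHat)) 1 / thetaHat else 0

  # NB component after removing the estimated structural zeros
  nz <- sum(y == 0)
  drop0 <- min(floor(phiHat * n), nz)
  yNb <- if (drop0 > 0) y[-which(y == 0)[seq_len(drop0)]] else y
  mNb <- mean(yNb); vNb <- stats::var(yNb)
  invThetaNbHat <- if (is.na(vNb) || vNb <= mNb) 0 else (vNb - mNb) / mNb^2

  list(mean = m, sd = sqrt(v), zeroFraction = p0, phiHat = phiHat,
       muHat = muHat, invThetaHat = invThetaHat,
       invThetaNbHat = invThetaNbHat,
       zeroInflated = phiHat > zeroInflatedCutoff)
}

#' Parse SINTAX-style lineage strings
#'
#' Splits strings of the form `"d:Bacteria,p:Firmicutes,...,g:Genus"` into a
#' data.frame of ranks. Missing ranks are `NA`.
#'
#' @param lineage character vector of lineage strings.
#' @return data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
parseSintaxLineage <- function(lineage) {
  prefixes <- c(domain = "d", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g")
  out <- lapply(prefixes, function(pf) {
    vapply(strsplit(lineage, ","), function(parts) {
      hit <- grep(paste0("^", pf, ":"), trimws(parts), value = TRUE)
      if (length(hit)) sub("^[a-z]:", "", hit[1]) else NA_character_
    }, "")
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Aggregate a count table to a taxonomic rank
#'
#' Sums counts over taxa sharing the same label at `rank`; taxa without an
#' assignment at that rank are pooled into `"unclassified"`. `rank = "asv"`
#' is the identity. Per-sample totals are conserved exactly.
#'
#' @param counts taxa-by-samples matrix with taxon ids as rownames.
#' @param taxonomy data.frame with columns `taxon` and `lineage`
#'   (SINTAX-style string), covering every taxon in `counts`.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"asv"`.
#' @return aggregated matrix with rank labels as rownames.
#' @export
aggregateToRank <- function(counts, taxonomy, rank) {
  rank <- match.arg(rank, c("domain", "phylum", "class", "order", "family",
                            "genus", "asv"))
  counts <- .checkCountMatrix(counts)
  if (rank == "asv") return(counts)
  missing <- setdiff(rownames(counts), taxonomy$taxon)
  if (length(missing))
    stop("no lineage entry for: ", paste(missing, collapse = ", "))
  lin <- parseSintaxLineage(
    taxonomy$lineage[match(rownames(counts), taxonomy$taxon)])
  labels <- lin[[rank]]
  labels[is.na(labels) | labels == ""] <- "unclassified"
  agg <- rowsum(counts, group = labels)
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Cohort-wide characterization of count complexity
#'
#' Applies [estimateZinbMoments()] to every taxon and summarizes: the
#' fraction of taxa flagged zero inflated, the mean extra-zero probability
#' among flagged taxa, the fraction with overdispersion `1/theta` above
#' `overdispersedCutoff`, and the per-taxon mean/sd table used for the
#' dispersion diagnostic. Expects a table already filtered for very rare
#' taxa (cohort total at least 15).
#'
#' @param counts taxa-by-samples integer matrix.
#' @param zeroInflatedCutoff `phi_hat` threshold for the zero-inflated flag.
#' @param overdispersedCutoff `1/theta` threshold for the overdispersed flag
#'   (default 10).
#' @return list with `taxa` (per-taxon data.frame), `zeroInflatedFraction`,
#'   `meanPhiFlagged`, `overdispersedFraction`, `nTaxa`, `nSkipped`.
#' @export
characterizeCohort <- function(counts, zeroInflatedCutoff = 0.05,
                               overdispersedCutoff = 10) {
  counts <- .checkCountMatrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  res <- lapply(seq_len(nrow(counts)), function(i)
    tryCatch(estimateZinbMoments(counts[i, ], zeroInflatedCutoff),
             error = function(e) NULL))
  ok <- !vapply(res, is.null, TRUE)
  tab <- do.call(rbind, lapply(which(ok), function(i)
    data.frame(taxon = rownames(counts)[i], mean = res[[i]]$mean,
               sd = res[[i]]$sd, zeroFraction = res[[i]]$zeroFraction,
               phiHat = res[[i]]$phiHat, invThetaHat = res[[i]]$invThetaHat,
               invThetaNbHat = res[[i]]$invThetaNbHat,
               zeroInflated = res[[i]]$zeroInflated,
               stringsAsFactors = FALSE)))
  if (is.null(tab)) stop("no taxon could be characterized")
  flagged <- tab$zeroInflated
  list(taxa = tab,
       zeroInflatedFraction = mean(flagged),
       meanPhiFlagged = if (any(flagged)) mean(tab$phiHat[flagged]) else NA_real_,
       overdispersedFraction = mean(tab$invThetaHat > overdispersedCutoff),
       nTaxa = nrow(tab), nSkipped = sum(!ok))
}
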