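#' Estimate an empirical genetic map from a recombinant panel
#'
#' For each adjacent marker pair, the interval length in cM is 100 times
#' the fraction of (complete-case) strains whose calls switch between the
#' two markers; cumulative sums per chromosome give marker positions. In an
#' advanced-intercross panel these switch fractions already reflect the
#' accumulated (expanded) recombination, so no map-function correction is
#' applied.
#'
#' @param geno a `geno_matrix` (>= 2 strains).
#' @return Data frame of class `genetic_map`: `marker`, `chrom`, `pos_cM`
#'   (estimated, cumulative per chromosome).
#' @export
estimate_genetic_map <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  G <- geno$calls
  if (nrow(G) < 2) stop("need at least 2 strains")
  mk <- geno$map
  pos <- numeric(nrow(mk))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    p <- 0
    pos[idx[1L]] <- 0
    for (k in seq_along(idx)[-1L]) {
      a <- G[, idx[k - 1L]]
      b <- G[, idx[k]]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) {
        warning("all-missing interval at ", mk$marker[idx[k]], "; 0 cM assumed")
        d <- 0
      } else {
        d <- 100 * sum(a[ok] != b[ok]) / sum(ok)
      }
      p <- p + d
      pos[idx[k]] <- p
    }
  }
  out <- data.frame(marker = mk$marker, chrom = mk$chrom, pos_cM = pos,
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Divide a genetic map into equal-centimorgan bins
#'
#' Consecutive half-open bins `[start, end)` of `bin_size_cM` are laid per
#' chromosome from 0; a terminal partial bin (when the chromosome length is
#' not a multiple of the bin size) is retained and flagged. Bins never span
#' chromosome boundaries.
#'
#' @param map a [estimate_genetic_map()] result or any data frame with
#'   `chrom` and `pos_cM`.
#' @param bin_size_cM bin width. Default 26.
#' @return Data frame of class `bin_set`: `chrom`, `start_cM`, `end_cM`,
#'   `partial`.
#' @export
bin_genome <- function(map, bin_size_cM = 26) {
  stopifnot(bin_size_cM > 0)
  if (!nrow(map)) stop("empty map")
  out <- do.call(rbind, lapply(split(map, map$chrom)[unique(map$chrom)],
                               function(m) {
    len <- max(m$pos_cM)
    if (len == 0) {
      starts <- 0
    } else {
      starts <- seq(0, by = bin_size_cM,
                    length.out = ceiling(len / bin_size_cM))
    }
    ends <- pmin(starts + bin_size_cM, max(len, bin_size_cM))
    data.frame(chrom = m$chrom[1L], start_cM = starts, end_cM = ends,
               partial = ends - starts < bin_size_cM,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("bin_set", "data.frame")
  out
}

#' Detect QTL hotspots by Poisson binning
#'
#' Each QTL is assigned to the bin containing its peak position (half-open
#' bins). Under the null of uniform scattering, per-bin counts are Poisson
#' with mean lambda = total QTL / total bins; bins whose count strictly
#' exceeds the smallest integer q with Poisson CDF(q; lambda) >=
#' `percentile` are flagged as hotspots (lambda is used exactly, never
#' rounded). QTL whose peak falls outside the binned territory are dropped
#' with a warning.
#'
#' @param qtl data frame with columns `chrom` and `peak_pos` (cM on the
#'   binning map).
#' @param bins a [bin_genome()] result.
#' @param percentile Poisson quantile for the threshold. Default 0.99.
#' @return `bins` with added `count` and `hotspot` columns; attributes
#'   `lambda`, `threshold` (the count q), `n_dropped`.
#' @export
detect_hotspots <- function(qtl, bins, percentile = 0.99) {
  stopifnot(nrow(qtl) >= 1, inherits(bins, "data.frame"))
  counts <- integer(nrow(bins))
  dropped <- 0L
  for (i in seq_len(nrow(qtl))) {
    hit <- which(bins$chrom == qtl$chrom[i] &
                 qtl$peak_pos[i] >= bins$start_cM &
                 qtl$peak_pos[i] < bins$end_cM)
    if (length(hit) == 0L) {
      # a peak exactly at the chromosome end belongs to the terminal bin
      hit <- which(bins$chrom == qtl$chrom[i] &
                   qtl$peak_pos[i] == bins$end_cM &
                   bins$end_cM == max(bins$end_cM[bins$chrom == qtl$chrom[i]]))
    }
    if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
    else dropped <- dropped + 1L
  }
  if (dropped) warning(dropped, " QTL outside the binned map were dropped")
  lambda <- sum(counts) / nrow(bins)
  q <- as.integer(stats::qpois(percentile, lambda))
  bins$count <- counts
  bins$hotspot <- counts > q
  attr(bins, "lambda") <- lambda
  attr(bins, "threshold") <- q
  attr(bins, "n_dropped") <- dropped
  bins
}

#' QTL whose confidence interval overlaps a genomic region
#'
#' Lists the QTL whose 1.5-LOD-drop interval overlaps (or spans) the given
#' region on the same chromosome -- the membership rule used to tie mapped
#' QTL to an introgressed interval. Intervals are treated as half-open on
#' the right; a point interval at the region edge still counts.
#'
#' @param qtl data frame with `chrom`, `ci_l_pos`, `ci_r_pos`.
#' @param chrom,start_cM,end_cM the region.
#' @return The overlapping rows of `qtl`.
#' @export
hotspot_membership <- function(qtl, chrom, start_cM, end_cM) {
  stopifnot(end_cM >= start_cM)
  hit <- qtl$chrom == chrom & qtl$ci_l_pos < end_cM & qtl$ci_r_pos >= start_cM
  qtl[hit, , drop = FALSE]
}

#' Bookkeeping over a per-hotspot QTL count table
#'
#' Given counts of mapped components per toxin per hotspot region (plus the
#' number of QTL whose intervals span more than one region, which would
#' otherwise be double-counted), computes the per-region totals, the number
#' of toxins hitting any region, and the number of unique QTL in hotspots.
#'
#' @param counts data frame: one row per toxin, one integer column per
#'   hotspot region.
#' @param n_spanning number of QTL counted in two regions. Default 0.
#' @return List: `per_hotspot` (named colSums), `toxins_in_hotspots`,
#'   `n_toxins`, `unique_qtl`.
#' @export
hotspot_bookkeeping <- function(counts, n_spanning = 0L) {
  num <- vapply(counts, is.numeric, logical(1))
  M <- as.matrix(counts[, num, drop = FALSE])
  per <- colSums(M)
  list(per_hotspot = per,
       toxins_in_hotspots = sum(rowSums(M) > 0),
       n_toxins = nrow(M),
       unique_qtl = sum(per) - n_spanning)
}
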