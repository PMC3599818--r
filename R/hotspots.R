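# Historical-hotspot concordance: overlap of well-resolved prediction
# intervals with a population (LD-based) hotspot list, the chance-overlap
# rate from random re-placement, and the discounted true-usage estimate.

#' Read a hotspot interval list
#'
#' BED input (0-based, half-open) is converted to the package's internal
#' 1-based closed convention; TSV input (chrom, start, end columns, 1-based
#' closed) is taken as is. A leading "chr" on chromosome labels is dropped.
#'
#' @param path file path.
#' @param format "bed" (default) or "tsv".
#' @return data.frame with `chrom`, `startBp`, `endBp` (1-based closed).
#' @export
readHotspots <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("hotspot file needs 3 columns: chrom, start, end")
  chrom <- .normChrom(sub("^chr", "", as.character(df[[1]])))
  start <- as.numeric(df[[2]])
  end <- as.numeric(df[[3]])
  if (format == "bed") start <- start + 1
  if (any(end < start)) stop("hotspot with negative length")
  data.frame(chrom = chrom, startBp = start, endBp = end,
             stringsAsFactors = FALSE)
}

#' Select well-resolved events
#'
#' Keeps events whose prediction interval is strictly smaller than the
#' threshold (default: smaller than 30 kb).
#'
#' @param events event data.frame with a `resolutionBp` column.
#' @param maxResolutionBp strict upper bound (default 30000).
#' @return the subset of rows.
#' @export
selectResolved <- function(events, maxResolutionBp = 30000) {
  events[events$resolutionBp < maxResolutionBp, , drop = FALSE]
}

# logical: does each interval overlap (>= 1 bp) any hotspot?
.overlapsAny <- function(intervals, hotspots) {
  hit <- logical(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    hs <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    if (!nrow(hs)) {
      warning("no hotspots on chromosome ", ch,
              "; its intervals counted as non-overlapping")
      next
    }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(intervals$startBp[ii], intervals$endBp[ii]),
      IRanges::IRanges(hs$startBp, hs$endBp))
    hit[ii[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

#' Hotspot concordance of prediction intervals
#'
#' Proportion of intervals overlapping (>= 1 bp) at least one hotspot; each
#' interval counts once however many hotspots it hits.
#'
#' @param intervals data.frame with `chrom`, `startBp`, `endBp`.
#' @param hotspots hotspot data.frame (1-based closed; see [readHotspots()]).
#' @return list with `concordance` (proportion) and `overlaps` (per-interval
#'   logical).
#' @export
hotspotConcordance <- function(intervals, hotspots) {
  if (!nrow(intervals)) return(list(concordance = NaN, overlaps = logical()))
  hit <- .overlapsAny(intervals, hotspots)
  list(concordance = mean(hit), overlaps = hit)
}

#' Chance overlap rate from random interval placement
#'
#' Each replicate re-places every interval uniformly at random on its own
#' chromosome, preserving its length, and measures hotspot concordance; the
#' rate is the mean over replicates.
#'
#' @param intervals data.frame with `chrom`, `startBp`, `endBp`.
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param hotspots hotspot data.frame.
#' @param nReps number of replicates (default 10).
#' @param seed optional seed.
#' @return mean overlap proportion across replicates.
#' @export
randomOverlapRate <- function(intervals, chromLengths, hotspots,
                              nReps = 10, seed = NULL) {
  stopifnot(nReps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(intervals)) return(NaN)
  len <- intervals$endBp - intervals$startBp
  L <- chromLengths[intervals$chrom]
  if (anyNA(L)) stop("missing chromosome length for: ",
                     paste(unique(intervals$chrom[is.na(L)]), collapse = ", "))
  if (any(len >= L)) stop("interval longer than its chromosome")
  rates <- numeric(nReps)
  for (r in seq_len(nReps)) {
    newStart <- floor(runif(nrow(intervals), 1, L - len + 1))
    shuf <- data.frame(chrom = intervals$chrom, startBp = newStart,
                       endBp = newStart + len, stringsAsFactors = FALSE)
    rates[r] <- mean(suppressWarnings(.overlapsAny(shuf, hotspots)))
  }
  mean(rates)
}

#' Estimate true hotspot usage by discounting chance overlap
#'
#' Solves observed = true + (1 - true) * random for the true usage: some
#' intervals overlap a hotspot only because of limited resolution, at the
#' rate seen for randomly placed intervals, so
#' estimate = (observed - random) / (1 - random).
#'
#' @param observed observed concordance (proportion).
#' @param random chance concordance from [randomOverlapRate()]; must satisfy
#'   0 <= random < 1.
#' @return the estimated true usage, clamped at 0 (with a warning) when
#'   observed < random.
#' @examples
#' estimateTrueUsage(0.82, 0.35)  # ~0.72
#' estimateTrueUsage(0.83, 0.36)  # ~0.73
#' @export
estimateTrueUsage <- function(observed, random) {
  stopifnot(all(random >= 0), all(random < 1), all(observed <= 1))
  est <- (observed - random) / (1 - random)
  if (any(est < 0)) {
    warning("observed concordance below chance rate; estimate clamped to 0")
    est <- pmax(est, 0)
  }
  est
}

#' Clusters of non-concordant well-resolved crossovers
#'
#' Exploratory scan for candidate novel hotspots: among resolved intervals
#' that do not overlap any known hotspot, reports maximal groups of more
#' than `minSize - 1` mutually overlapping intervals (for intervals, mutual
#' pairwise overlap is equivalent to sharing a common point, so groups are
#' found where interval coverage reaches `minSize`).
#'
#' @param intervals resolved, non-concordant intervals (data.frame with
#'   `chrom`, `startBp`, `endBp`), e.g. filtered with [hotspotConcordance()].
#' @param minSize minimum cluster size (default 3, i.e. more than two).
#' @return data.frame with `chrom`, `startBp`, `endBp` (span of the cluster's
#'   intervals) and `n` (cluster size).
#' @export
findNovelClusters <- function(intervals, minSize = 3) {
  out <- list()
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    ir <- IRanges::IRanges(intervals$startBp[ii], intervals$endBp[ii])
    cov <- IRanges::slice(IRanges::coverage(ir), lower = minSize)
    if (!length(cov)) next
    for (k in seq_along(cov)) {
      core <- IRanges::IRanges(IRanges::start(cov)[k], IRanges::end(cov)[k])
      members <- ii[S4Vectors::queryHits(IRanges::findOverlaps(ir, core))]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, startBp = min(intervals$startBp[members]),
        endBp = max(intervals$endBp[members]), n = length(members),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), startBp = numeric(),
                      endBp = numeric(), n = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
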