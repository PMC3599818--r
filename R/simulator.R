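# Synthetic haplotype panels and family quartets with known crossover truth,
# plus sensitivity/precision scoring of detector output. The generator
# mirrors the validation protocol: parents drawn as pairs of panel
# haplotypes, a fixed number of crossovers placed uniformly at random in
# each of the four meioses, and optional symmetric genotyping error.

#' Generate a synthetic haplotype panel
#'
#' Linkage-equilibrium haplotypes: each marker's allele frequency is drawn
#' from a symmetric Beta distribution truncated to a minor-allele-frequency
#' floor (mimicking genotyping-array ascertainment), and alleles are drawn
#' independently per site. Marker positions are sampled uniformly (without
#' replacement) over the chromosome span. Because sites are independent,
#' markers are at least as informative as real LD-structured haplotypes.
#'
#' @param nHaplotypes number of haplotypes (default 340).
#' @param nMarkers number of markers (default 50000, >= 2).
#' @param spanBp chromosome span in bp (default 100 Mb).
#' @param mafShape1,mafShape2 Beta shape parameters for the allele-frequency
#'   draw (default 0.8, 0.8).
#' @param mafFloor minimum minor allele frequency (default 0.05).
#' @param chrom chromosome label for the panel (default "1").
#' @param seed optional integer seed for reproducibility.
#' @return a [HaplotypePanel-class] object.
#' @export
generatePanel <- function(nHaplotypes = 340, nMarkers = 50000,
                          spanBp = 1e8, mafShape1 = 0.8, mafShape2 = 0.8,
                          mafFloor = 0.05, chrom = "1", seed = NULL) {
  stopifnot(nMarkers >= 2, nHaplotypes >= 4)
  if (mafShape1 <= 0 || mafShape2 <= 0 || mafFloor < 0 || mafFloor >= 0.5)
    stop("invalid allele-frequency distribution parameters")
  if (!is.null(seed)) set.seed(seed)
  drawP <- function(n) {                      # rejection-sample the floor
    out <- numeric(0)
    while (length(out) < n) {
      d <- rbeta(n, mafShape1, mafShape2)
      out <- c(out, d[pmin(d, 1 - d) >= mafFloor])
    }
    out[seq_len(n)]
  }
  p <- drawP(nMarkers)
  pos <- sort(sample.int(spanBp, nMarkers))
  H <- matrix(rbinom(nHaplotypes * nMarkers, 1L, rep(p, each = nHaplotypes)),
              nrow = nHaplotypes)
  # the floor is a property of the panel, not just of the frequency draw:
  # redraw markers whose realised MAF still falls below it
  repeat {
    f <- colMeans(H)
    bad <- which(pmin(f, 1 - f) < mafFloor)
    if (!length(bad)) break
    pb <- drawP(length(bad))
    H[, bad] <- rbinom(nHaplotypes * length(bad), 1L,
                       rep(pb, each = nHaplotypes))
  }
  new("HaplotypePanel", positionsBp = as.numeric(pos), haplotypes = H,
      spanBp = spanBp, chrom = as.character(chrom))
}

# transmit one gamete: recombine the parent's two haplotypes with the given
# crossover breakpoints (bp), starting from a random homolog
.meiosis <- function(h1, h2, pos, breaks) {
  seg <- findInterval(pos, breaks)
  use2 <- (sample.int(2L, 1L) - 1L + seg) %% 2L == 1L
  ifelse(use2, h2, h1)
}

#' Simulate one family quartet with known crossover truth
#'
#' Each parent is two panel haplotypes sampled without replacement; each of
#' the four meioses (father to child1/child2, mother to child1/child2) places
#' `crossoversPerMeiosis` breakpoints uniformly at random over the span, and
#' the transmitted haplotype switches source at every breakpoint. Child
#' genotypes are the sum of the transmitted alleles. Each genotype call is
#' then independently corrupted to a uniformly chosen different call with
#' probability `errorRate`. Uses the current RNG state; seed the caller for
#' reproducibility.
#'
#' @param panel a [HaplotypePanel-class] object.
#' @param crossoversPerMeiosis non-negative integer (default 3).
#' @param errorRate per-call miscall probability (default 0).
#' @param quartetId identifier for the quartet.
#' @param childSexes child sexes recorded on the quartet (default "F","F").
#' @return list with `quartet` (a [QuartetGenotypes-class]) and `truth`
#'   (data.frame: quartetId, parent, child, posBp — the true crossover
#'   positions of each meiosis).
#' @export
simulateQuartet <- function(panel, crossoversPerMeiosis = 3, errorRate = 0,
                            quartetId = "q1", childSexes = c("F", "F")) {
  stopifnot(is(panel, "HaplotypePanel"))
  if (crossoversPerMeiosis < 0) stop("crossoversPerMeiosis must be >= 0")
  pos <- panel@positionsBp
  H <- panel@haplotypes
  hap <- sample.int(nrow(H), 4L)   # father: 1,2; mother: 3,4
  meio <- expand.grid(child = c("c1", "c2"),
                      parent = c("paternal", "maternal"),
                      stringsAsFactors = FALSE)
  gam <- vector("list", 4L)
  truth <- vector("list", 4L)
  for (i in seq_len(4L)) {
    ph <- if (meio$parent[i] == "paternal") hap[1:2] else hap[3:4]
    breaks <- sort(runif(crossoversPerMeiosis, 0, panel@spanBp))
    gam[[i]] <- .meiosis(H[ph[1], ], H[ph[2], ], pos, breaks)
    truth[[i]] <- if (crossoversPerMeiosis > 0)
      data.frame(quartetId = quartetId, parent = meio$parent[i],
                 child = meio$child[i], posBp = breaks,
                 stringsAsFactors = FALSE)
  }
  c1 <- gam[[which(meio$child == "c1" & meio$parent == "paternal")]] +
    gam[[which(meio$child == "c1" & meio$parent == "maternal")]]
  c2 <- gam[[which(meio$child == "c2" & meio$parent == "paternal")]] +
    gam[[which(meio$child == "c2" & meio$parent == "maternal")]]
  geno <- rbind(H[hap[1], ] + H[hap[2], ], H[hap[3], ] + H[hap[4], ], c1, c2)
  if (errorRate > 0) {
    flip <- which(runif(length(geno)) < errorRate)
    if (length(flip)) {
      old <- geno[flip]
      geno[flip] <- (old + sample.int(2L, length(flip), replace = TRUE)) %% 3L
    }
  }
  markers <- data.frame(chrom = panel@chrom,
                        rsId = paste0("sim", seq_along(pos)), posBp = pos,
                        stringsAsFactors = FALSE)
  q <- quartetGenotypes(markers, geno[1, ], geno[2, ], geno[3, ], geno[4, ],
                        childSexes = childSexes, quartetId = quartetId)
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(quartetId = character(), parent = character(),
                        child = character(), posBp = numeric(),
                        stringsAsFactors = FALSE)
  list(quartet = q, truth = truth)
}

#' Score detected events against simulated truth
#'
#' A true crossover is localised when some reported interval of the same
#' meiosis (same quartet and parent) contains its position; a reported
#' interval is correct when it contains at least one true crossover of its
#' meiosis. Sensitivity is the localised fraction of truths (1 when there is
#' no truth); precision the correct fraction of intervals (1 when nothing is
#' reported).
#'
#' @param events event data.frame from [detectEvents()].
#' @param truth truth data.frame from [simulateQuartet()].
#' @return list with `sensitivity`, `precision`, `nIntervals`, `nTruth`,
#'   `nLocalized`, `nCorrect`.
#' @export
scoreDetection <- function(events, truth) {
  if (nrow(events) && nrow(truth)) {
    unknown <- setdiff(unique(events$quartetId), unique(truth$quartetId))
    if (length(unknown))
      stop("events refer to quartet(s) absent from truth: ",
           paste(unknown, collapse = ", "))
  }
  evKey <- paste(events$quartetId, events$parent)
  trKey <- paste(truth$quartetId, truth$parent)
  evSplit <- split(seq_len(nrow(events)), evKey)
  localized <- logical(nrow(truth))
  correct <- logical(nrow(events))
  for (k in unique(trKey)) {
    ti <- which(trKey == k)
    ei <- evSplit[[k]]
    if (is.null(ei)) next
    s <- events$startBp[ei]; e <- events$endBp[ei]
    for (t in ti) {
      hit <- s <= truth$posBp[t] & truth$posBp[t] <= e
      if (any(hit)) {
        localized[t] <- TRUE
        correct[ei[hit]] <- TRUE
      }
    }
  }
  list(sensitivity = if (nrow(truth)) mean(localized) else 1,
       precision = if (nrow(events)) mean(correct) else 1,
       nIntervals = nrow(events), nTruth = nrow(truth),
       nLocalized = sum(localized), nCorrect = sum(correct))
}

#' Run the simulation-based validation of the detector
#'
#' Generates a haplotype panel, simulates `nQuartets` family quartets with
#' known crossover truth, runs the detector on each and scores sensitivity
#' and precision. Quartets are processed one at a time, so memory stays flat
#' at panel size.
#'
#' @param nQuartets number of quartets (default 1000).
#' @param crossoversPerMeiosis crossovers placed per meiosis (default 3).
#' @param errorRate per-call genotyping error rate (default 0).
#' @param params detector parameters ([HmmParams-class]).
#' @param seed integer seed governing the panel and every quartet.
#' @param ... passed to [generatePanel()] (nHaplotypes, nMarkers, spanBp...).
#' @return list with `score` (from [scoreDetection()]), `events` and `truth`
#'   data.frames.
#' @export
runValidation <- function(nQuartets = 1000, crossoversPerMeiosis = 3,
                          errorRate = 0, params = hmmParams(), seed = 1,
                          ...) {
  set.seed(seed)
  panel <- generatePanel(...)
  evs <- vector("list", nQuartets)
  trs <- vector("list", nQuartets)
  for (i in seq_len(nQuartets)) {
    sim <- simulateQuartet(panel, crossoversPerMeiosis, errorRate,
                           quartetId = sprintf("q%04d", i))
    evs[[i]] <- detectEvents(sim$quartet, params)
    trs[[i]] <- sim$truth
  }
  events <- do.call(rbind, evs)
  truth <- do.call(rbind, trs)
  list(score = scoreDetection(events, truth), events = events, truth = truth)
}
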