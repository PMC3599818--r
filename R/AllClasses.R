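#' @import methods
#' @importFrom stats runif rbinom rbeta lm t.test pchisq setNames
#'   complete.cases sd coef ave
#' @importFrom utils read.table write.table
#' @useDynLib quartetHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters of the transmission-state hidden Markov model
#'
#' Holds the per-marker-step state-switch probabilities for each parent and
#' the total probability mass assigned to genotype configurations consistent
#' with a transmission state.
#'
#' @slot tauPaternal per-marker-step probability that the paternal
#'   transmission mode switches; must lie in (0, 0.5).
#' @slot tauMaternal per-marker-step switch probability for the mother.
#' @slot consistentMass total emission probability assigned to the genotype
#'   configurations consistent with a state; the remaining mass absorbs
#'   genotyping error. Must lie in (0.5, 1].
#' @seealso [hmmParams()]
#' @export
setClass("HmmParams",
  representation(
    tauPaternal = "numeric",
    tauMaternal = "numeric",
    consistentMass = "numeric"
  )
)

setValidity("HmmParams", function(object) {
  msg <- character()
  for (s in c("tauPaternal", "tauMaternal")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0 || v >= 0.5)
      msg <- c(msg, sprintf("%s must be a single value in (0, 0.5)", s))
  }
  cm <- object@consistentMass
  if (length(cm) != 1 || !is.finite(cm) || cm <= 0.5 || cm > 1)
    msg <- c(msg, "consistentMass must be a single value in (0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct HMM parameters
#'
#' @param tauPaternal,tauMaternal per-marker-step transmission-state switch
#'   probability for each parent. The default 1e-4 corresponds roughly to
#'   genome-wide recombination rates: with two observed meioses per parent per
#'   quartet and array-scale marker density (several hundred thousand
#'   markers), tens of crossovers per meiosis translate to about one switch
#'   per ten thousand marker steps.
#' @param consistentMass total emission mass on state-consistent genotype
#'   configurations (default 0.9995); the complement 0.0005 is spread over
#'   inconsistent configurations so isolated genotyping errors are absorbed
#'   rather than forcing spurious double transitions.
#' @return An [HmmParams-class] object.
#' @examples
#' hmmParams()
#' hmmParams(tauPaternal = 5e-5)
#' @export
hmmParams <- function(tauPaternal = 1e-4, tauMaternal = 1e-4,
                      consistentMass = 0.9995) {
  new("HmmParams", tauPaternal = tauPaternal, tauMaternal = tauMaternal,
      consistentMass = consistentMass)
}

setMethod("show", "HmmParams", function(object) {
  cat("HmmParams\n")
  cat("  tauPaternal:   ", object@tauPaternal, "\n")
  cat("  tauMaternal:   ", object@tauMaternal, "\n")
  cat("  consistentMass:", object@consistentMass,
      " (error mass", format(1 - object@consistentMass), ")\n")
})

#' Genotypes of one family quartet
#'
#' Ordered genotype calls for father, mother and two children across a set of
#' markers. Genotypes are stored as B-allele dosage: 0 (AA), 1 (AB), 2 (BB),
#' NA (missing). Allele symbols are per-marker labels, not nucleotides.
#'
#' @slot markers data.frame with columns `chrom` (character; "1".."22","X"),
#'   `rsId` (character) and `posBp` (integer, 1-based physical position),
#'   sorted by chromosome then position, strictly increasing within a
#'   chromosome.
#' @slot geno integer matrix with 4 rows (father, mother, child1, child2) and
#'   one column per marker; entries in 0:2 or NA.
#' @slot childSexes character of length 2, "M"/"F" per child (may be NA;
#'   required for X-chromosome decoding).
#' @slot childIds character of length 2, identifiers of the two children
#'   (carried into detected events for cross-quartet reconciliation).
#' @slot quartetId character scalar identifying the quartet.
#' @export
setClass("QuartetGenotypes",
  representation(
    markers = "data.frame",
    geno = "matrix",
    childSexes = "character",
    childIds = "character",
    quartetId = "character"
  )
)

setValidity("QuartetGenotypes", function(object) {
  msg <- character()
  m <- object@markers
  if (!all(c("chrom", "posBp") %in% names(m)))
    msg <- c(msg, "markers must have columns chrom and posBp")
  if (nrow(object@geno) != 4)
    msg <- c(msg, "geno must have 4 rows (father, mother, child1, child2)")
  if (ncol(object@geno) != nrow(m))
    msg <- c(msg, "geno columns must match marker rows")
  g <- object@geno
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (length(object@childSexes) != 2)
    msg <- c(msg, "childSexes must have length 2")
  if (length(object@childIds) != 2)
    msg <- c(msg, "childIds must have length 2")
  if (nrow(m) > 1) {
    bad <- vapply(split(m$posBp, m$chrom),
                  function(p) any(diff(p) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, paste("positions not strictly increasing on chromosome",
                          paste(names(bad)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QuartetGenotypes object
#'
#' @param markers data.frame with columns `chrom`, `posBp` and optionally
#'   `rsId`; rows are sorted by (chromosome, position) if not already.
#' @param father,mother,child1,child2 integer vectors of B-allele dosages
#'   (0/1/2/NA), one per marker.
#' @param childSexes character of length 2 ("M"/"F"), used by the
#'   X-chromosome model; defaults to unknown.
#' @param childIds identifiers of the two children; default "c1", "c2".
#' @param quartetId identifier carried into detected events.
#' @return A [QuartetGenotypes-class] object.
#' @export
quartetGenotypes <- function(markers, father, mother, child1, child2,
                             childSexes = c(NA_character_, NA_character_),
                             childIds = c("c1", "c2"),
                             quartetId = "q1") {
  markers <- as.data.frame(markers)
  if (is.null(markers$rsId))
    markers$rsId <- paste0("m", seq_len(nrow(markers)))
  markers$chrom <- .normChrom(markers$chrom)
  ord <- order(.chromRank(markers$chrom), markers$posBp)
  geno <- rbind(father = as.integer(father), mother = as.integer(mother),
                child1 = as.integer(child1), child2 = as.integer(child2))
  new("QuartetGenotypes", markers = markers[ord, , drop = FALSE],
      geno = geno[, ord, drop = FALSE],
      childSexes = as.character(childSexes),
      childIds = as.character(childIds), quartetId = quartetId)
}

setMethod("show", "QuartetGenotypes", function(object) {
  cat("QuartetGenotypes", object@quartetId, "\n")
  cat("  markers:", nrow(object@markers), "on chromosome(s)",
      paste(unique(object@markers$chrom), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(object@geno)), "\n")
})

#' A panel of phased haplotypes for simulation
#'
#' @slot positionsBp numeric, strictly increasing marker positions (bp).
#' @slot haplotypes integer matrix (haplotypes x markers) of 0/1 alleles.
#' @slot spanBp numeric chromosome span in bp.
#' @slot chrom chromosome label the panel represents.
#' @export
setClass("HaplotypePanel",
  representation(
    positionsBp = "numeric",
    haplotypes = "matrix",
    spanBp = "numeric",
    chrom = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  if (any(diff(object@positionsBp) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (ncol(object@haplotypes) != length(object@positionsBp))
    msg <- c(msg, "haplotype columns must match positions")
  if (!all(object@haplotypes %in% 0:1))
    msg <- c(msg, "haplotype alleles must be 0/1")
  if (length(object@positionsBp) &&
      max(object@positionsBp) > object@spanBp)
    msg <- c(msg, "positions exceed spanBp")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypePanel", function(object) {
  p <- colMeans(object@haplotypes)
  cat("HaplotypePanel:", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "markers over",
      format(object@spanBp / 1e6), "Mb\n")
  cat("  mean MAF:", round(mean(pmin(p, 1 - p)), 3), "\n")
})

#' A genetic map built from crossover events
#'
#' Per-gap and cumulative centimorgan distances between ordered markers.
#'
#' @slot gaps data.frame with columns `chrom`, `startBp`, `endBp` (the two
#'   flanking marker positions), `cm` (genetic length of the gap) and
#'   `cumCm` (cumulative within chromosome).
#' @slot sex one of "male", "female", "averaged".
#' @slot nMeioses number of meioses the event counts are normalised by.
#' @export
setClass("GeneticMap",
  representation(
    gaps = "data.frame",
    sex = "character",
    nMeioses = "numeric"
  )
)

setValidity("GeneticMap", function(object) {
  msg <- character()
  if (!all(c("chrom", "startBp", "endBp", "cm") %in% names(object@gaps)))
    msg <- c(msg, "gaps must have columns chrom, startBp, endBp, cm")
  if (any(object@gaps$cm < 0)) msg <- c(msg, "gap cM must be >= 0")
  if (!object@sex %in% c("male", "female", "averaged"))
    msg <- c(msg, "sex must be male, female or averaged")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap (", object@sex, ", ", object@nMeioses, " meioses)\n",
      sep = "")
  tot <- tapply(object@gaps$cm, object@gaps$chrom, sum)
  cat("  chromosomes:", length(tot), " total length:",
      round(sum(object@gaps$cm), 2), "cM\n")
})

#' Total genetic length of a map
#' @param map a [GeneticMap-class] object
#' @param byChrom if TRUE, return a named vector of per-chromosome totals
#' @return total length in centimorgans
#' @export
mapLength <- function(map, byChrom = FALSE) {
  stopifnot(is(map, "GeneticMap"))
  if (byChrom) {
    v <- tapply(map@gaps$cm, map@gaps$chrom, sum)
    v[order(.chromRank(names(v)))]
  } else {
    sum(map@gaps$cm)
  }
}

#' Per-gap table of a genetic map
#' @param map a [GeneticMap-class] object
#' @return the gap data.frame (chrom, startBp, endBp, cm, cumCm)
#' @export
mapGaps <- function(map) {
  stopifnot(is(map, "GeneticMap"))
  map@gaps
}

# chromosome ordering 1..22 then X
.chromRank <- function(chrom) {
  chrom <- as.character(chrom)
  r <- suppressWarnings(as.integer(chrom))
  r[chrom %in% c("X", "x", "23")] <- 23L
  if (any(is.na(r)))
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[is.na(r)]), collapse = ", "))
  r
}

.normChrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom %in% c("x", "23")] <- "X"
  chrom
}
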