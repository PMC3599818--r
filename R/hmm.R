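# The crossover detector: emission/transition construction, Viterbi
# decoding of the transmission-state path, and the deterministic
# prediction-interval scan around each state change.

#' Emission probability table of the transmission-state HMM
#'
#' For each hidden state, a probability distribution over the no-missing
#' quartet genotype configurations. Configurations consistent with a state
#' share `consistentMass` (default 0.9995), weighted by the number of
#' transmission assignments that produce them (uniform over parent genotype
#' pairs and over each state's allowed transmissions); this makes the
#' probability of a configuration identical under every state it is
#' consistent with, so shared configurations never favour one state.
#' Inconsistent configurations share the remaining error mass uniformly.
#' Configurations containing a missing call are emission-neutral (probability
#' 1 under every state) and do not appear in the table.
#'
#' @param params an [HmmParams-class] object.
#' @param model "autosome" (4 states, 81 configurations) or "chrX" (2
#'   maternal states; the alphabet excludes impossible hemizygous calls).
#' @param childSexes for `model = "chrX"`, the two child sexes ("M"/"F").
#' @return numeric matrix, states in rows (rownames from
#'   [transmissionStates()]), configurations in columns (named
#'   "father/mother/child1/child2"). Each row sums to 1 and its
#'   state-consistent entries sum to `consistentMass`.
#' @examples
#' E <- emissionTable(hmmParams())
#' rowSums(E)
#' @export
emissionTable <- function(params = hmmParams(), model = c("autosome", "chrX"),
                          childSexes = c("F", "F")) {
  stopifnot(is(params, "HmmParams"))
  model <- match.arg(model)
  cm <- params@consistentMass
  gtStr <- c("AA", "AB", "BB")
  if (model == "autosome") {
    tab <- .autoTables()
    keep <- rep(TRUE, 81L)
    nStates <- 4L
    base <- 1 / 9
    stateNames <- paste0("pat_", substr(.STATE_DF$paternal, 1, 1),
                         "/mat_", substr(.STATE_DF$maternal, 1, 1))
  } else {
    tab <- .xTables(childSexes)
    keep <- tab$valid
    nStates <- 2L
    base <- 1 / 6
    stateNames <- paste0("mat_", .TX_MODES)
  }
  nSym <- sum(keep)
  E <- matrix(0, nStates, nSym)
  A <- tab$assign[keep, , drop = FALSE]
  Z <- tab$total[keep, , drop = FALSE]
  cons <- tab$cons[keep, , drop = FALSE]
  for (s in seq_len(nStates)) {
    E[s, cons[, s]] <- cm * base * A[cons[, s], s] / Z[cons[, s], s]
    E[s, !cons[, s]] <- (1 - cm) / (nSym - sum(cons[, s]))
  }
  cfg <- tab$cfg[keep, ]
  colnames(E) <- paste(gtStr[cfg$f + 1], gtStr[cfg$m + 1],
                       gtStr[cfg$c1 + 1], gtStr[cfg$c2 + 1], sep = "/")
  rownames(E) <- stateNames
  E
}

# log-emission lookup: nStates x 82 matrix; columns 1..81 index the full
# config grid (invalid/absent symbols get the neutral 0 log-probability, as
# does column 82, used for missing calls)
.logEmissionLookup <- function(params, model, childSexes = NULL) {
  cm <- params@consistentMass
  if (model == "autosome") {
    tab <- .autoTables()
    keep <- rep(TRUE, 81L)
    nStates <- 4L
    base <- 1 / 9
  } else {
    tab <- .xTables(childSexes)
    keep <- tab$valid
    nStates <- 2L
    base <- 1 / 6
  }
  nSym <- sum(keep)
  L <- matrix(0, nStates, 82L)
  for (s in seq_len(nStates)) {
    cons <- which(tab$cons[, s] & keep)
    incons <- which(!tab$cons[, s] & keep)
    L[s, cons] <- log(cm * base) + log(tab$assign[cons, s]) -
      log(tab$total[cons, s])
    L[s, incons] <- log((1 - cm) / (nSym - length(cons)))
  }
  L
}

#' Per-step transition matrix of the transmission-state HMM
#'
#' Parental modes switch independently: staying costs
#' (1 - tau_p)(1 - tau_m), a single-parent switch tau_p(1 - tau_m) or
#' (1 - tau_p)tau_m, and a simultaneous double switch tau_p * tau_m. With the
#' default tau = 1e-4 a double switch costs 1e-8, far below the 5e-4 error
#' mass, so isolated mistyped markers cannot force a spurious double
#' transition.
#'
#' @inheritParams emissionTable
#' @return stochastic matrix (4 x 4 for autosomes, 2 x 2 maternal for X).
#' @examples
#' transitionMatrix(hmmParams())
#' @export
transitionMatrix <- function(params = hmmParams(),
                             model = c("autosome", "chrX")) {
  stopifnot(is(params, "HmmParams"))
  model <- match.arg(model)
  tp <- params@tauPaternal
  tm <- params@tauMaternal
  if (model == "chrX") {
    M <- matrix(c(1 - tm, tm, tm, 1 - tm), 2, 2, byrow = TRUE)
    dimnames(M) <- list(.TX_MODES, .TX_MODES)
    return(M)
  }
  M <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    d <- bitwXor(a - 1L, b - 1L)
    pSwitch <- bitwAnd(d, 2L) > 0
    mSwitch <- bitwAnd(d, 1L) > 0
    M[a, b] <- (if (pSwitch) tp else 1 - tp) * (if (mSwitch) tm else 1 - tm)
  }
  nm <- paste0(substr(.STATE_DF$paternal, 1, 1),
               substr(.STATE_DF$maternal, 1, 1))
  dimnames(M) <- list(nm, nm)
  M
}

# config-grid index per marker (NA where any call missing)
.cfgIdxVec <- function(geno) {
  .cfgIndex(geno[1, ], geno[2, ], geno[3, ], geno[4, ])
}

# extract one chromosome's slice of a quartet
.chromSlice <- function(quartet, chrom) {
  sel <- quartet@markers$chrom == chrom
  list(pos = quartet@markers$posBp[sel],
       geno = quartet@geno[, sel, drop = FALSE])
}

.resolveChrom <- function(quartet, chrom) {
  chroms <- unique(quartet@markers$chrom)
  if (is.null(chrom)) {
    if (length(chroms) != 1)
      stop("quartet spans several chromosomes; supply chrom=")
    chroms
  } else {
    chrom <- .normChrom(chrom)
    if (!chrom %in% chroms) stop("no markers on chromosome ", chrom)
    chrom
  }
}

#' Viterbi decoding of the transmission-state path
#'
#' Decodes the most likely sequence of transmission states along one
#' chromosome of a quartet, in log space with a uniform initial distribution.
#' Ties are broken in favour of not changing state, then by state order, so
#' uninformative stretches never generate spurious changes.
#'
#' @param quartet a [QuartetGenotypes-class] object.
#' @param params an [HmmParams-class] object.
#' @param chrom chromosome to decode (default: the quartet's single
#'   chromosome). "X" selects the two-state maternal model, which requires
#'   known child sexes.
#' @return list with `path` (integer state per marker; see
#'   [transmissionStates()], or 1 = identical / 2 = distinct maternal mode on
#'   X), `changePoints` (marker indices whose state differs from the previous
#'   marker), `logProb`, `model` and `chrom`.
#' @export
viterbiDecode <- function(quartet, params = hmmParams(), chrom = NULL) {
  stopifnot(is(quartet, "QuartetGenotypes"), is(params, "HmmParams"))
  chrom <- .resolveChrom(quartet, chrom)
  sl <- .chromSlice(quartet, chrom)
  if (length(sl$pos) < 2)
    stop("need at least 2 markers on chromosome ", chrom)
  model <- if (chrom == "X") "chrX" else "autosome"
  if (model == "chrX") {
    if (anyNA(quartet@childSexes))
      stop("X-chromosome decoding requires childSexes")
    lk <- .logEmissionLookup(params, model, quartet@childSexes)
  } else {
    lk <- .logEmissionLookup(params, model)
  }
  idx <- .cfgIdxVec(sl$geno)
  idx[is.na(idx)] <- 82L
  logE <- lk[, idx, drop = FALSE]
  logT <- log(transitionMatrix(params, model))
  vt <- .viterbi_cpp(logE, logT)
  path <- vt$path
  list(path = path,
       changePoints = which(diff(path) != 0) + 1L,
       logProb = vt$logProb, model = model, chrom = chrom)
}

# flip one parent's mode in a state index (autosome: bit 1 = paternal,
# bit 0 = maternal; X: single bit)
.flipState <- function(state, parent, model) {
  bit <- if (model == "chrX") 1L else if (parent == "paternal") 2L else 1L
  bitwXor(state - 1L, bit) + 1L
}

#' Prediction interval around one Viterbi state change
#'
#' Walks 5' and 3' from a decoded state change to delimit the maximal region
#' in which the crossover may have occurred. Walking 5', the left bound is
#' the nearest marker that pins the switching parent's old sharing mode —
#' every transmission state its genotype configuration is consistent with
#' carries that mode — and symmetrically the right bound is the nearest 3'
#' marker pinning the new mode. Judging bounds by the parent's marginal mode
#' rather than the two decoded states keeps the interval correct even when
#' the other parent's phase is itself ambiguous (as happens when crossovers
#' of the two parents fall close together). If no informative marker exists
#' before the chromosome end, the terminal marker bounds the interval.
#' Bounds are reported as the physical positions of those markers (1-based,
#' closed).
#'
#' @inheritParams viterbiDecode
#' @param path decoded path as returned by [viterbiDecode()].
#' @param changePoint marker index of the state change (state differs from
#'   the marker before).
#' @param parent "paternal" or "maternal" — the switching parent. For a
#'   double change (both parents switch at one step) call once per parent;
#'   the scan then compares the old state with the old state having only that
#'   parent's mode flipped.
#' @return one-row data.frame: `chrom`, `startBp`, `endBp`, `startMarker`,
#'   `endMarker`, `parent`, `resolutionBp`.
#' @export
scanPredictionInterval <- function(quartet, path, changePoint,
                                   parent = c("maternal", "paternal"),
                                   params = hmmParams(), chrom = NULL) {
  parent <- match.arg(parent)
  chrom <- .resolveChrom(quartet, chrom)
  model <- if (chrom == "X") "chrX" else "autosome"
  if (is.list(path)) path <- path$path
  sl <- .chromSlice(quartet, chrom)
  codes <- .markerCodes(sl$geno, model,
                        if (model == "chrX") quartet@childSexes else NULL)
  .scanPI(codes, sl$pos, path, changePoint, parent, model, chrom)
}

# core scan on precomputed consistent-set bitmask codes: a marker bounds the
# interval only when every state it is consistent with pins the switching
# parent's mode (the parent-marginal reading), so the bound does not depend
# on the jointly decoded phase of the other parent — which can itself be
# ambiguous when two crossovers of different parents fall close together
.scanPI <- function(codes, pos, path, cp, parent, model, chrom) {
  stopifnot(cp >= 2, cp <= length(path))
  sOld <- path[cp - 1L]
  if (model == "chrX") {
    oldMask <- bitwShiftL(1L, sOld - 1L)
    newMask <- bitwXor(3L, oldMask)
  } else {
    distinctMask <- if (parent == "paternal") 12L else 10L  # states {3,4}/{2,4}
    oldMask <- if (bitwAnd(bitwShiftL(1L, sOld - 1L), distinctMask) > 0L)
      distinctMask else bitwXor(15L, distinctMask)
    newMask <- bitwXor(15L, oldMask)
  }
  pinsOld <- codes != 0L & bitwAnd(codes, newMask) == 0L
  pinsNew <- codes != 0L & bitwAnd(codes, oldMask) == 0L
  leftC <- which(pinsOld)
  leftC <- leftC[leftC <= cp - 1L]
  left <- if (length(leftC)) max(leftC) else 1L
  rightC <- which(pinsNew)
  rightC <- rightC[rightC >= cp]
  right <- if (length(rightC)) min(rightC) else length(path)
  data.frame(chrom = chrom, startBp = pos[left], endBp = pos[right],
             startMarker = left, endMarker = right, parent = parent,
             resolutionBp = pos[right] - pos[left],
             stringsAsFactors = FALSE)
}

#' Detect crossover events in family quartets
#'
#' Runs the full detector on one or more quartets: per chromosome, classify
#' each marker's genotype configuration, Viterbi-decode the transmission-state
#' path, split each state change into per-parent events (a double change
#' yields one paternal and one maternal event) and delimit every event with
#' the prediction-interval scan. Autosomes use the four-state model; "X" uses
#' the two-state maternal model (no paternal events are ever emitted on X,
#' and X is skipped with a message when child sexes are unknown).
#'
#' @param quartets a [QuartetGenotypes-class] object or a list of them.
#' @param params an [HmmParams-class] object.
#' @return data.frame of crossover events with columns `quartetId`, `parent`,
#'   `chrom`, `startBp`, `endBp`, `startMarker`, `endMarker`, `resolutionBp`,
#'   `child1`, `child2`, `attributedChild` (NA until reconciliation).
#' @seealso [scanPredictionInterval()], [mergeQuintet()], [attributeTriple()]
#' @export
detectEvents <- function(quartets, params = hmmParams()) {
  if (is(quartets, "QuartetGenotypes")) quartets <- list(quartets)
  out <- vector("list", length(quartets))
  for (i in seq_along(quartets)) {
    q <- quartets[[i]]
    stopifnot(is(q, "QuartetGenotypes"))
    evs <- list()
    for (ch in unique(q@markers$chrom)) {
      model <- if (ch == "X") "chrX" else "autosome"
      if (model == "chrX" && anyNA(q@childSexes)) {
        message("quartet ", q@quartetId,
                ": skipping X (child sexes unknown)")
        next
      }
      sl <- .chromSlice(q, ch)
      if (length(sl$pos) < 2) {
        message("quartet ", q@quartetId, ": <2 markers on chromosome ", ch,
                ", skipped")
        next
      }
      vt <- viterbiDecode(q, params, chrom = ch)
      if (!length(vt$changePoints)) next
      codes <- .markerCodes(sl$geno, model,
                            if (model == "chrX") q@childSexes else NULL)
      for (cp in vt$changePoints) {
        sOld <- vt$path[cp - 1L]
        sNew <- vt$path[cp]
        d <- bitwXor(sOld - 1L, sNew - 1L)
        parents <- if (model == "chrX") "maternal" else
          c("paternal", "maternal")[c(bitwAnd(d, 2L) > 0, bitwAnd(d, 1L) > 0)]
        for (par in parents)
          evs[[length(evs) + 1L]] <-
            .scanPI(codes, sl$pos, vt$path, cp, par, model, ch)
      }
    }
    if (length(evs)) {
      df <- do.call(rbind, evs)
      df$quartetId <- q@quartetId
      df$child1 <- q@childIds[1]
      df$child2 <- q@childIds[2]
      out[[i]] <- df
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyEvents())
  df <- do.call(rbind, out)
  df$attributedChild <- NA_character_
  rownames(df) <- NULL
  df[, c("quartetId", "parent", "chrom", "startBp", "endBp", "startMarker",
         "endMarker", "resolutionBp", "child1", "child2", "attributedChild")]
}

.emptyEvents <- function() {
  data.frame(quartetId = character(), parent = character(),
             chrom = character(), startBp = numeric(), endBp = numeric(),
             startMarker = integer(), endMarker = integer(),
             resolutionBp = numeric(), child1 = character(),
             child2 = character(), attributedChild = character(),
             stringsAsFactors = FALSE)
}
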