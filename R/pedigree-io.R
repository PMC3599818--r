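# PLINK text-format input, marker QC filters, Mendelian checking and the
# decomposition of families into the quartet/triple structures the detector
# consumes.

#' Read PLINK-style PED/MAP genotype files
#'
#' Whitespace-delimited text PED (6 metadata columns, then two allele columns
#' per marker; missing allele "0"; sex 1 = male, 2 = female) and MAP
#' (chromosome, rs id, genetic position — ignored — and physical position).
#' Alleles at each marker are abstracted to per-marker symbols A/B in order
#' of first appearance and stored as B-allele dosage (0/1/2, NA missing).
#' Markers are sorted by (chromosome, position).
#'
#' @param pedPath,mapPath file paths.
#' @return list with `pedigree` (data.frame: famId, id, fatherId, motherId,
#'   sex "M"/"F"/NA), `markers` (data.frame: chrom, rsId, posBp) and
#'   `genotypes` (integer matrix individuals x markers, rownames = ids,
#'   colnames = rs ids).
#' @seealso [writePlink()], [qcFilterMarkers()]
#' @export
readPlink <- function(pedPath, mapPath) {
  mp <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) stop("MAP file needs 4 columns")
  markers <- data.frame(chrom = .normChrom(mp[[1]]), rsId = as.character(mp[[2]]),
                        posBp = as.numeric(mp[[4]]), stringsAsFactors = FALSE)
  M <- nrow(markers)

  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf != 6 + 2 * M)
  if (length(bad))
    stop("PED row ", bad[1], " has ", nf[bad[1]], " fields; expected ",
         6 + 2 * M, " (truncated or malformed row)")
  N <- length(toks)
  tm <- matrix(unlist(toks), nrow = N, byrow = TRUE)
  ids <- tm[, 2]
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1])
  sexRaw <- tm[, 5]
  pedigree <- data.frame(
    famId = tm[, 1], id = ids,
    fatherId = ifelse(tm[, 3] == "0", NA_character_, tm[, 3]),
    motherId = ifelse(tm[, 4] == "0", NA_character_, tm[, 4]),
    sex = ifelse(sexRaw == "1", "M", ifelse(sexRaw == "2", "F",
                                            NA_character_)),
    stringsAsFactors = FALSE)

  a1 <- tm[, 6 + 2 * seq_len(M) - 1, drop = FALSE]
  a2 <- tm[, 6 + 2 * seq_len(M), drop = FALSE]
  G <- matrix(NA_integer_, N, M, dimnames = list(ids, markers$rsId))
  for (j in seq_len(M)) {
    al <- c(rbind(a1[, j], a2[, j]))  # interleaved: first-seen order
    seen <- unique(al[al != "0"])
    if (length(seen) > 2)
      stop("marker ", markers$rsId[j], " has ", length(seen),
           " alleles; expected at most 2")
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == seen[2]) + (a2[, j] == seen[2])
    if (length(seen) < 2) d <- rep(0L, N)   # monomorphic: all reference
    d[miss] <- NA_integer_
    if (length(seen) == 0) d <- rep(NA_integer_, N)
    G[, j] <- as.integer(d)
  }
  ord <- order(.chromRank(markers$chrom), markers$posBp)
  list(pedigree = pedigree, markers = markers[ord, , drop = FALSE],
       genotypes = G[, ord, drop = FALSE])
}

#' Write genotypes as PLINK PED/MAP text files
#'
#' Inverse of [readPlink()]: dosage 0 becomes "A A", 1 "A B", 2 "B B" and NA
#' "0 0".
#'
#' @param pedigree data.frame as returned by [readPlink()].
#' @param markers data.frame with chrom, rsId, posBp.
#' @param genotypes integer dosage matrix (individuals x markers).
#' @param pedPath,mapPath output paths.
#' @return invisibly, the two paths.
#' @export
writePlink <- function(pedigree, markers, genotypes, pedPath, mapPath) {
  stopifnot(nrow(genotypes) == nrow(pedigree),
            ncol(genotypes) == nrow(markers))
  mp <- data.frame(markers$chrom, markers$rsId, 0, markers$posBp)
  write.table(mp, mapPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gt <- c("A A", "A B", "B B")
  gstr <- matrix("0 0", nrow(genotypes), ncol(genotypes))
  ok <- !is.na(genotypes)
  gstr[ok] <- gt[genotypes[ok] + 1L]
  meta <- cbind(pedigree$famId, pedigree$id,
                ifelse(is.na(pedigree$fatherId), "0", pedigree$fatherId),
                ifelse(is.na(pedigree$motherId), "0", pedigree$motherId),
                ifelse(is.na(pedigree$sex), "0",
                       ifelse(pedigree$sex == "M", "1", "2")),
                "0")
  writeLines(apply(cbind(meta, gstr), 1, paste, collapse = " "), pedPath)
  invisible(c(pedPath, mapPath))
}

#' Mendelian-inheritance check for one nuclear family
#'
#' Flags child genotypes that no combination of parental allele
#' transmissions can produce. Requires both parents genotyped at the marker;
#' any missing call is never a violation.
#'
#' @param family list with `fatherId`, `motherId`, `childIds`.
#' @param genotypes dosage matrix with individual ids as rownames.
#' @return logical matrix (children x markers) of violation flags.
#' @examples
#' G <- rbind(f = c(0L, 0L), m = c(0L, 1L), k = c(1L, 2L))
#' colnames(G) <- c("s1", "s2")
#' mendelCheck(list(fatherId = "f", motherId = "m", childIds = "k"), G)
#' @export
mendelCheck <- function(family, genotypes) {
  f <- genotypes[family$fatherId, ]
  m <- genotypes[family$motherId, ]
  # transmissible-allele dosage range of a parent: {0}->0..0, {0,1}->0..1,
  # {1}->1..1; child dosage must fall in the summed range
  lo <- (f == 2) + (m == 2)
  hi <- (f > 0) + (m > 0)
  viol <- matrix(FALSE, length(family$childIds), ncol(genotypes),
                 dimnames = list(family$childIds, colnames(genotypes)))
  for (k in seq_along(family$childIds)) {
    cg <- genotypes[family$childIds[k], ]
    v <- cg < lo | cg > hi
    v[is.na(v)] <- FALSE
    viol[k, ] <- v
  }
  viol
}

# nuclear families (father, mother, >=1 typed child) present in a pedigree
.nuclearFamilies <- function(pedigree) {
  key <- paste(pedigree$fatherId, pedigree$motherId)
  has <- !is.na(pedigree$fatherId) & !is.na(pedigree$motherId) &
    pedigree$fatherId %in% pedigree$id & pedigree$motherId %in% pedigree$id
  fams <- list()
  for (k in unique(key[has])) {
    rows <- pedigree[has & key == k, ]
    fams[[k]] <- list(fatherId = rows$fatherId[1], motherId = rows$motherId[1],
                      childIds = rows$id, famId = rows$famId[1])
  }
  fams
}

#' Marker quality-control filters
#'
#' Applies the standard pre-detection marker filters: call rate, Mendelian
#' error rate, minor allele frequency and Hardy-Weinberg equilibrium. MAF and
#' HWE are computed on founders only (individuals without genotyped parents)
#' to avoid inflation by relatedness; the Mendelian error rate is the number
#' of violations over the number of informative family tests (child and both
#' parents genotyped). When the pedigree has no founders the MAF/HWE filters
#' are disabled with a warning; with no nuclear families the Mendelian filter
#' is disabled.
#'
#' @param genotypes dosage matrix (individuals x markers, rownames = ids).
#' @param pedigree data.frame as from [readPlink()].
#' @param minCallRate minimum fraction of non-missing calls (default 0.99).
#' @param maxMendelErrorRate maximum Mendelian error rate (default 0.01).
#' @param minMaf minimum founder minor allele frequency (default 0.01).
#' @param minHweP minimum founder Hardy-Weinberg chi-square p (default 0.001).
#' @return list with `keep` (integer indices of retained markers) and
#'   `report` (per-marker data.frame of metric values, pass flag and
#'   comma-separated failure reasons).
#' @export
qcFilterMarkers <- function(genotypes, pedigree,
                            minCallRate = 0.99, maxMendelErrorRate = 0.01,
                            minMaf = 0.01, minHweP = 0.001) {
  M <- ncol(genotypes)
  callRate <- colMeans(!is.na(genotypes))

  founders <- pedigree$id[is.na(pedigree$fatherId) & is.na(pedigree$motherId)]
  founders <- intersect(founders, rownames(genotypes))
  if (length(founders) == 0) {
    warning("no founders in pedigree: MAF and HWE filters disabled")
    maf <- hweP <- rep(NA_real_, M)
  } else {
    FG <- genotypes[founders, , drop = FALSE]
    p <- colMeans(FG, na.rm = TRUE) / 2
    p[is.nan(p)] <- NA
    maf <- pmin(p, 1 - p)
    n0 <- colSums(FG == 0, na.rm = TRUE)
    n1 <- colSums(FG == 1, na.rm = TRUE)
    n2 <- colSums(FG == 2, na.rm = TRUE)
    n <- n0 + n1 + n2
    q <- 1 - p
    e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
    x2 <- rep(0, M)
    poly <- !is.na(p) & p > 0 & p < 1 & n > 0
    x2[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
      (n1[poly] - e1[poly])^2 / e1[poly] +
      (n2[poly] - e2[poly])^2 / e2[poly]
    hweP <- pchisq(x2, df = 1, lower.tail = FALSE)
    hweP[!poly] <- 1   # monomorphic: MAF filter is the relevant one
    hweP[is.na(p)] <- NA
  }

  fams <- .nuclearFamilies(pedigree)
  if (length(fams) == 0) {
    mendelRate <- rep(NA_real_, M)
  } else {
    nViol <- nTest <- rep(0, M)
    for (fam in fams) {
      v <- mendelCheck(fam, genotypes)
      informative <- !is.na(genotypes[fam$fatherId, ]) &
        !is.na(genotypes[fam$motherId, ])
      for (k in seq_along(fam$childIds)) {
        t <- informative & !is.na(genotypes[fam$childIds[k], ])
        nTest <- nTest + t
        nViol <- nViol + (v[k, ] & t)
      }
    }
    mendelRate <- ifelse(nTest > 0, nViol / nTest, NA_real_)
  }

  fail <- function(x, bad) !is.na(x) & bad
  reasons <- matrix(FALSE, M, 4,
                    dimnames = list(NULL, c("call_rate", "mendel_error",
                                            "maf", "hwe")))
  reasons[, "call_rate"] <- fail(callRate, callRate < minCallRate)
  reasons[, "mendel_error"] <- fail(mendelRate,
                                    mendelRate > maxMendelErrorRate)
  reasons[, "maf"] <- fail(maf, maf < minMaf)
  reasons[, "hwe"] <- fail(hweP, hweP < minHweP)
  pass <- rowSums(reasons) == 0
  report <- data.frame(
    rsId = colnames(genotypes), callRate = callRate,
    mendelErrorRate = mendelRate, maf = maf, hweP = hweP, pass = pass,
    reasons = apply(reasons, 1, function(r)
      paste(colnames(reasons)[r], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
  list(keep = which(pass), report = report)
}

#' Decompose a family's children into quartet pairs and triples
#'
#' Two children form a single quartet. Three children a, b, c form one
#' triple, expanded into the three overlapping pairs (a,b), (a,c), (b,c).
#' More than three children are covered by sliding triples that share one
#' child — (c1,c2,c3), (c3,c4,c5), ... — with a final triple over the last
#' three children when the count is even, so every child appears in at least
#' one quartet and adjacent triples overlap for cross-quartet consistency
#' checks.
#'
#' @param childIds character vector of children (birth order).
#' @return list with `quartets` (list of child-id pairs, deduplicated) and
#'   `triples` (list of child-id triples; empty for 2 children). A
#'   single-child family yields empty lists with a message.
#' @examples
#' decomposeFamily(c("a", "b", "c"))
#' decomposeFamily(c("a", "b", "c", "d", "e"))
#' @export
decomposeFamily <- function(childIds) {
  k <- length(childIds)
  if (k < 2) {
    message("family with ", k, " child(ren) skipped: need at least 2")
    return(list(quartets = list(), triples = list()))
  }
  if (k == 2)
    return(list(quartets = list(childIds), triples = list()))
  starts <- seq(1, k - 2, by = 2)
  triples <- lapply(starts, function(s) childIds[s:(s + 2)])
  if (starts[length(starts)] + 2 < k)
    triples[[length(triples) + 1]] <- childIds[(k - 2):k]
  pairs <- list()
  seen <- character()
  for (tr in triples) {
    for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {
      pr <- tr[ij]
      key <- paste(pr, collapse = "\r")
      if (!key %in% seen) {
        seen <- c(seen, key)
        pairs[[length(pairs) + 1]] <- pr
      }
    }
  }
  list(quartets = pairs, triples = triples)
}

#' Read a child/mother age table
#'
#' Tab-separated file with columns childId, motherId, motherAgeYears (the
#' mother's age at the child's birth, floored to whole years).
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
readAgeTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("childId", "motherId", "motherAgeYears")
  if (!all(need %in% names(df)))
    stop("age table needs columns: ", paste(need, collapse = ", "))
  df$motherAgeYears <- as.integer(floor(df$motherAgeYears))
  out <- df[, need]
  bad <- out$motherAgeYears < 12 | out$motherAgeYears > 60
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE), " mother age(s) outside 12-60 years")
  out
}
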