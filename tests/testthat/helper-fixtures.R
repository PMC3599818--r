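# Fixture builders shared across the tests. Everything is generated in code;
# no data files.

# Build a quartet directly from parental haplotypes and per-meiosis homolog
# choices. hapF/hapM: list of two 0/1 allele vectors. trans: list with
# elements pat1, pat2, mat1, mat2 — integer vectors (1 or 2) giving, per
# marker, which parental homolog each child's gamete carries.
quartetFromTransmissions <- function(pos, hapF, hapM, trans,
                                     chrom = "1", quartetId = "t1",
                                     childSexes = c("F", "F")) {
  pick <- function(haps, idx) ifelse(idx == 1L, haps[[1]], haps[[2]])
  c1 <- pick(hapF, trans$pat1) + pick(hapM, trans$mat1)
  c2 <- pick(hapF, trans$pat2) + pick(hapM, trans$mat2)
  quartetGenotypes(
    data.frame(chrom = chrom, posBp = pos),
    hapF[[1]] + hapF[[2]], hapM[[1]] + hapM[[2]], c1, c2,
    childSexes = childSexes, quartetId = quartetId)
}

# fully informative doubly heterozygous parents over n markers
hetHaps <- function(n) list(rep(0L, n), rep(1L, n))

# exhaustive max-log-probability over all S^n state paths (the independent
# Viterbi oracle); grows all path prefixes one marker at a time, so it never
# shares the dynamic-programming shortcut with the decoder it checks
bruteForcePathMax <- function(logE, logT) {
  S <- nrow(logE)
  n <- ncol(logE)
  lp <- log(1 / S) + logE[, 1]
  last <- seq_len(S)
  for (t in seq_len(n)[-1]) {
    L <- length(lp)
    newLp <- numeric(S * L)
    for (s in seq_len(S))
      newLp[(s - 1L) * L + seq_len(L)] <- lp + logT[last, s] + logE[s, t]
    lp <- newLp
    last <- rep(seq_len(S), each = L)
  }
  max(lp)
}

# random quartet genotype matrix (with occasional missing calls)
randomQuartet <- function(n, pMissing = 0.1, chrom = "1") {
  p <- (1 - pMissing) / 3
  geno <- matrix(sample(c(0:2, NA), 4 * n, replace = TRUE,
                        prob = c(p, p, p, pMissing)), 4, n)
  quartetGenotypes(data.frame(chrom = chrom, posBp = seq_len(n) * 1000),
                   geno[1, ], geno[2, ], geno[3, ], geno[4, ])
}

# three siblings from one parent pair, with crossovers placed in disjoint
# genome slots so no two events' prediction intervals can collide across
# children (exact per-child recovery is only defined without collisions)
simTripleSeparated <- function(panel, perMeiosis = 2) {
  H <- panel@haplotypes
  pos <- panel@positionsBp
  hap <- sample(nrow(H), 4)
  nSlots <- 6 * perMeiosis
  slotW <- panel@spanBp / nSlots
  slotIdx <- matrix(sample(nSlots), nrow = 6)
  mkBreaks <- function(i) sort((slotIdx[i, ] - 0.5) * slotW +
                                 runif(perMeiosis, -0.2, 0.2) * slotW)
  gam <- function(ph, breaks) {
    seg <- findInterval(pos, breaks)
    start <- sample(2, 1)
    ifelse((start - 1 + seg) %% 2 == 1, H[ph[2], ], H[ph[1], ])
  }
  kids <- lapply(1:3, function(i) {
    pb <- mkBreaks(2 * i - 1)
    mb <- mkBreaks(2 * i)
    list(patBreaks = pb, matBreaks = mb,
         geno = gam(hap[1:2], pb) + gam(hap[3:4], mb))
  })
  list(father = H[hap[1], ] + H[hap[2], ],
       mother = H[hap[3], ] + H[hap[4], ],
       kids = kids,
       markers = data.frame(chrom = panel@chrom, posBp = pos))
}

# the three overlapping child-pair quartets of a simulated triple
tripleQuartets <- function(tri, ids = c("a", "b", "c")) {
  lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr)
    quartetGenotypes(tri$markers, tri$father, tri$mother,
                     tri$kids[[pr[1]]]$geno, tri$kids[[pr[2]]]$geno,
                     childIds = ids[pr],
                     quartetId = paste(ids[pr], collapse = "+")))
}

# seeded synthetic maternal-age records: per-mother baseline plus a linear
# age effect and Gaussian noise
simAgeRecords <- function(nMothers = 150, slope = -0.3, sigma = 5,
                          seed = 51) {
  set.seed(seed)
  rec <- list()
  for (m in seq_len(nMothers)) {
    k <- sample(2:4, 1)
    firstAge <- sample(18:35, 1)
    ages <- firstAge + sort(sample(0:12, k))
    offset <- rnorm(1, 40, 4)
    rec[[m]] <- data.frame(
      childId = paste0("m", m, "_c", seq_len(k)),
      motherId = paste0("m", m), motherAgeYears = ages,
      count = offset + slope * ages + rnorm(k, 0, sigma),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}

# events table row for consistency-module tests
evRow <- function(start, end, parent = "maternal", chrom = "1",
                  child1 = "a", child2 = "b", quartetId = NULL) {
  data.frame(quartetId = if (is.null(quartetId))
    paste0("f:", child1, "+", child2) else quartetId,
    parent = parent, chrom = chrom, startBp = start, endBp = end,
    startMarker = NA_integer_, endMarker = NA_integer_,
    resolutionBp = end - start, child1 = child1, child2 = child2,
    attributedChild = NA_character_, stringsAsFactors = FALSE)
}
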