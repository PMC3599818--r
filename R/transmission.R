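# Transmission-state machinery: enumeration of which allele-sharing modes of
# each parent are consistent with an observed quartet genotype configuration.
#
# A parent transmits one allele to each of the two children. At a locus the
# transmission is in one of two modes: "identical" (both children received
# the same homolog) or "distinct" (each received a different homolog). The
# paternal and maternal modes combine to four autosomal hidden states, in
# fixed order:
#   1 (identical, identical)   2 (identical, distinct)
#   3 (distinct,  identical)   4 (distinct,  distinct)

.TX_MODES <- c("identical", "distinct")

.STATE_DF <- data.frame(
  state = 1:4,
  paternal = c("identical", "identical", "distinct", "distinct"),
  maternal = c("identical", "distinct", "identical", "distinct"),
  stringsAsFactors = FALSE
)

# package-local cache for enumeration tables
.qhmmCache <- new.env(parent = emptyenv())

#' The four transmission states
#'
#' @return data.frame with columns `state` (index used throughout), and the
#'   `paternal` and `maternal` sharing modes ("identical"/"distinct").
#' @examples
#' transmissionStates()
#' @export
transmissionStates <- function() .STATE_DF

# transmitted-allele pairs (child1, child2) a parent with dosage g can
# produce under a sharing mode; alleles coded 0/1
.transChoices <- function(g, mode) {
  if (g == 0L) return(list(c(0L, 0L)))
  if (g == 2L) return(list(c(1L, 1L)))
  if (mode == "identical") list(c(0L, 0L), c(1L, 1L)) else
    list(c(0L, 1L), c(1L, 0L))
}

# 1-based index of a no-missing config (f, m, c1, c2), dosages 0:2
.cfgIndex <- function(f, m, c1, c2) 27L * f + 9L * m + 3L * c1 + c2 + 1L

.cfgGrid <- function() {
  g <- expand.grid(c2 = 0:2, c1 = 0:2, m = 0:2, f = 0:2)
  g[, c("f", "m", "c1", "c2")]
}

# Autosomal enumeration tables over all 81 no-missing configs:
#   assign : 81 x 4 count of transmission assignments producing the config
#   total  : 81 x 4 total assignments available for the (f, m) pair
#   cons   : 81 x 4 logical consistency mask
#   code   : 81 bitmask of consistent states (bit s-1 = state s)
#   nCons  : per-state count of consistent configs
.autoTables <- function() {
  if (!is.null(.qhmmCache$auto)) return(.qhmmCache$auto)
  cfg <- .cfgGrid()
  A <- Z <- matrix(0L, 81L, 4L)
  for (i in seq_len(81L)) {
    for (s in 1:4) {
      tps <- .transChoices(cfg$f[i], .STATE_DF$paternal[s])
      tms <- .transChoices(cfg$m[i], .STATE_DF$maternal[s])
      Z[i, s] <- length(tps) * length(tms)
      n <- 0L
      for (tp in tps) for (tm in tms)
        if (tp[1] + tm[1] == cfg$c1[i] && tp[2] + tm[2] == cfg$c2[i])
          n <- n + 1L
      A[i, s] <- n
    }
  }
  cons <- A > 0L
  out <- list(cfg = cfg, assign = A, total = Z, cons = cons,
              code = as.integer(cons %*% bitwShiftL(1L, 0:3)),
              nCons = colSums(cons))
  .qhmmCache$auto <- out
  out
}

# X-chromosome enumeration for a fixed pair of child sexes. The father is
# hemizygous (valid calls: 0 or 2, the array's homozygous coding); sons are
# hemizygous and carry only a maternal allele (also coded homozygous);
# daughters carry the paternal allele plus one maternal allele. Only the two
# maternal modes are hidden states. Configs with a heterozygous father or a
# heterozygous son are impossible calls and are treated as emission-neutral,
# like missing data; the emission alphabet is the remaining valid configs.
.xTables <- function(sexes) {
  key <- paste0("x", paste(sexes, collapse = ""))
  if (!is.null(.qhmmCache[[key]])) return(.qhmmCache[[key]])
  cfg <- .cfgGrid()
  A <- Z <- matrix(0L, 81L, 2L)
  valid <- rep(TRUE, 81L)
  for (i in seq_len(81L)) {
    if (cfg$f[i] == 1L ||
        (sexes[1] == "M" && cfg$c1[i] == 1L) ||
        (sexes[2] == "M" && cfg$c2[i] == 1L)) {
      valid[i] <- FALSE
      next
    }
    fAllele <- cfg$f[i] %/% 2L
    for (s in 1:2) {
      tms <- .transChoices(cfg$m[i], .TX_MODES[s])
      Z[i, s] <- length(tms)
      n <- 0L
      for (tm in tms) {
        exp1 <- if (sexes[1] == "M") 2L * tm[1] else fAllele + tm[1]
        exp2 <- if (sexes[2] == "M") 2L * tm[2] else fAllele + tm[2]
        if (exp1 == cfg$c1[i] && exp2 == cfg$c2[i]) n <- n + 1L
      }
      A[i, s] <- n
    }
  }
  cons <- A > 0L & valid
  out <- list(cfg = cfg, assign = A, total = Z, cons = cons, valid = valid,
              code = as.integer(cons %*% bitwShiftL(1L, 0:1)),
              nCons = colSums(cons), nValid = sum(valid))
  .qhmmCache[[key]] <- out
  out
}

# convert genotype spellings to dosage 0/1/2/NA
.gtToInt <- function(g) {
  if (is.numeric(g)) {
    g <- as.integer(g)
    stopifnot(all(g[!is.na(g)] %in% 0:2))
    return(g)
  }
  g <- as.character(g)
  out <- rep(NA_integer_, length(g))
  out[g %in% "AA"] <- 0L
  out[g %in% c("AB", "BA")] <- 1L
  out[g %in% "BB"] <- 2L
  bad <- !is.na(g) & !g %in% c("AA", "AB", "BA", "BB", "missing", "NN", "00")
  if (any(bad)) stop("unrecognised genotype call: ", g[bad][1])
  out
}

#' Transmission states consistent with a quartet genotype configuration
#'
#' Enumerates, over all transmission-allele assignments allowed by each
#' state's sharing modes, which of the four autosomal transmission states can
#' produce the observed genotypes. A missing call anywhere makes the
#' configuration fully uninformative (all four states). Mendelian-impossible
#' configurations return no state.
#'
#' @param father,mother,child1,child2 single genotype calls, either dosages
#'   (0/1/2/NA) or strings ("AA","AB","BB","missing").
#' @return subset of [transmissionStates()] rows.
#' @examples
#' consistentStates("AA", "AB", "AA", "AB")  # maternal mode pinned: distinct
#' consistentStates("AA", "AA", "AA", "AA")  # uninformative: all four
#' consistentStates("AA", "AA", "AB", "AA")  # Mendelian violation: none
#' @export
consistentStates <- function(father, mother, child1, child2) {
  g <- .gtToInt(c(father, mother, child1, child2))
  if (anyNA(g)) return(.STATE_DF)
  tab <- .autoTables()
  .STATE_DF[tab$cons[.cfgIndex(g[1], g[2], g[3], g[4]), ], , drop = FALSE]
}

#' Maternal transmission modes consistent with an X-chromosome configuration
#'
#' The X model has two hidden states, the maternal sharing modes. The father
#' is hemizygous (his call, coded homozygous, fixes the allele every daughter
#' receives from him); sons carry only a maternal allele. Missing calls and
#' impossible hemizygous calls (heterozygous father or son) make the
#' configuration uninformative.
#'
#' @inheritParams consistentStates
#' @param childSexes character of length 2, "M" or "F" per child.
#' @return character vector, a subset of `c("identical", "distinct")`; both
#'   modes if uninformative, `character(0)` if inconsistent with either.
#' @examples
#' consistentStatesX("AA", "AB", "AA", "AB", c("F", "F"))  # distinct
#' consistentStatesX("AA", "AB", "AA", "BB", c("M", "M"))  # distinct
#' consistentStatesX("AA", "AA", "AA", "AA", c("M", "F"))  # both
#' @export
consistentStatesX <- function(father, mother, child1, child2, childSexes) {
  stopifnot(length(childSexes) == 2, all(childSexes %in% c("M", "F")))
  g <- .gtToInt(c(father, mother, child1, child2))
  if (anyNA(g)) return(.TX_MODES)
  tab <- .xTables(childSexes)
  i <- .cfgIndex(g[1], g[2], g[3], g[4])
  if (!tab$valid[i]) return(.TX_MODES)
  .TX_MODES[tab$cons[i, ]]
}

# per-marker consistent-state bitmask codes for a quartet's genotype matrix;
# markers with any missing call get the all-states code. model "autosome"
# uses 4-state codes (missing -> 15), "chrX" 2-state codes (missing or
# invalid hemizygous call -> 3).
.markerCodes <- function(geno, model = "autosome", childSexes = NULL) {
  idx <- .cfgIndex(geno[1, ], geno[2, ], geno[3, ], geno[4, ])
  if (model == "autosome") {
    tab <- .autoTables()
    code <- rep(15L, ncol(geno))
    ok <- !is.na(idx)
    code[ok] <- tab$code[idx[ok]]
    code
  } else {
    tab <- .xTables(childSexes)
    code <- rep(3L, ncol(geno))
    ok <- !is.na(idx)
    code[ok] <- ifelse(tab$valid[idx[ok]], tab$code[idx[ok]], 3L)
    code
  }
}
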