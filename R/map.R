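# Genetic-map construction: crossover events -> per-gap and cumulative
# centimorgan distances, sex-averaged maps, and windowed rate profiles.

#' Build a genetic map from crossover events
#'
#' Each event contributes 100 / nMeioses centimorgans. With
#' `placement = "midpoint"` the whole event is assigned to the marker gap
#' containing the midpoint of its prediction interval; with
#' `placement = "uniform_spread"` it is distributed across the gaps its
#' interval covers, proportional to each gap's physical length. Both modes
#' conserve total mass: total map length = 100 * nEvents / nMeioses.
#'
#' @param events event data.frame (one parent sex; see [detectEvents()]).
#' @param markers data.frame with `chrom` and `posBp` defining the map's
#'   marker axis (sorted; >= 2 markers per chromosome).
#' @param nMeioses number of meioses observed for this sex (> 0).
#' @param sex map label: "male", "female" or "averaged".
#' @param placement "midpoint" (default) or "uniform_spread".
#' @return a [GeneticMap-class] object.
#' @export
buildMap <- function(events, markers, nMeioses,
                     sex = c("averaged", "male", "female"),
                     placement = c("midpoint", "uniform_spread")) {
  sex <- match.arg(sex)
  placement <- match.arg(placement)
  stopifnot(nMeioses > 0)
  markers <- as.data.frame(markers)
  markers$chrom <- .normChrom(markers$chrom)
  ord <- order(.chromRank(markers$chrom), markers$posBp)
  markers <- markers[ord, , drop = FALSE]

  gapList <- list()
  for (ch in unique(markers$chrom)) {
    pos <- markers$posBp[markers$chrom == ch]
    if (length(pos) < 2) stop("chromosome ", ch, " has < 2 markers")
    nGap <- length(pos) - 1L
    w <- numeric(nGap)
    ei <- which(events$chrom == ch)
    for (e in ei) {
      s <- events$startBp[e]; en <- events$endBp[e]
      if (s < pos[1] || en > pos[length(pos)])
        stop("event ", rownames(events)[e], " at ", ch, ":", s, "-", en,
             " lies outside the marker range")
      if (placement == "uniform_spread" && en > s) {
        gs <- findInterval(s, pos)
        ge <- findInterval(en, pos, left.open = TRUE)
        cover <- gs:ge
        len <- pos[cover + 1L] - pos[cover]
        w[cover] <- w[cover] + len / sum(len)
      } else {
        mid <- (s + en) / 2
        g <- findInterval(mid, pos)
        g <- min(max(g, 1L), nGap)
        w[g] <- w[g] + 1
      }
    }
    cm <- 100 * w / nMeioses
    gapList[[ch]] <- data.frame(chrom = ch, startBp = pos[-length(pos)],
                                endBp = pos[-1], cm = cm, cumCm = cumsum(cm),
                                stringsAsFactors = FALSE)
  }
  badChrom <- setdiff(unique(events$chrom), unique(markers$chrom))
  if (length(badChrom))
    stop("events on chromosome(s) without markers: ",
         paste(badChrom, collapse = ", "))
  gaps <- do.call(rbind, gapList)
  rownames(gaps) <- NULL
  new("GeneticMap", gaps = gaps, sex = sex, nMeioses = nMeioses)
}

#' Sex-averaged genetic map
#'
#' Per-gap average of a male and a female map sharing the same marker axis.
#'
#' @param mapMale,mapFemale [GeneticMap-class] objects on identical axes.
#' @return an averaged [GeneticMap-class].
#' @examples
#' # Per-chromosome totals average the same way: a male map of 48.13 cM and
#' # a female map of 64.93 cM give (48.13 + 64.93) / 2 = 56.53 cM.
#' @export
sexAverage <- function(mapMale, mapFemale) {
  stopifnot(is(mapMale, "GeneticMap"), is(mapFemale, "GeneticMap"))
  g1 <- mapMale@gaps; g2 <- mapFemale@gaps
  if (nrow(g1) != nrow(g2) ||
      !all(g1$chrom == g2$chrom & g1$startBp == g2$startBp &
             g1$endBp == g2$endBp))
    stop("maps are not on the same marker axis")
  g <- g1
  g$cm <- (g1$cm + g2$cm) / 2
  g$cumCm <- ave(g$cm, g$chrom, FUN = cumsum)
  new("GeneticMap", gaps = g, sex = "averaged",
      nMeioses = (mapMale@nMeioses + mapFemale@nMeioses) / 2)
}

#' Windowed recombination-rate profile
#'
#' Bins events into fixed physical windows and reports cM per Mb. Events
#' whose prediction interval is worse-resolved than `maxResolutionBp`
#' (default 5 Mb) are excluded first; each remaining event contributes
#' 100 / nMeioses cM at the midpoint of its interval.
#'
#' @param events event data.frame.
#' @param nMeioses number of meioses (> 0).
#' @param windowBp window size in bp (default 1 Mb).
#' @param maxResolutionBp exclusion threshold on interval resolution.
#' @return data.frame with `chrom`, `windowStartBp`, `cm`, `cmPerMb`.
#' @export
rateProfile <- function(events, nMeioses, windowBp = 1e6,
                        maxResolutionBp = 5e6) {
  stopifnot(windowBp > 0, nMeioses > 0)
  ev <- events[events$resolutionBp <= maxResolutionBp, , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(chrom = character(), windowStartBp = numeric(),
                      cm = numeric(), cmPerMb = numeric()))
  mid <- (ev$startBp + ev$endBp) / 2
  win <- floor(mid / windowBp)
  key <- paste(ev$chrom, win)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  cm <- 100 * as.numeric(tab) / nMeioses
  out <- data.frame(chrom = parts[, 1],
                    windowStartBp = as.numeric(parts[, 2]) * windowBp,
                    cm = cm, cmPerMb = cm / (windowBp / 1e6),
                    stringsAsFactors = FALSE)
  out[order(.chromRank(out$chrom), out$windowStartBp), , drop = FALSE]
}

#' Export a genetic map as text files
#'
#' Writes, per chromosome, an ordered marker (rs id) list and the per-gap
#' centimorgan distances between consecutive markers.
#'
#' @param map a [GeneticMap-class].
#' @param markers marker data.frame (chrom, rsId, posBp) on the map's axis.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
exportMap <- function(map, markers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (ch in unique(map@gaps$chrom)) {
    mk <- markers[markers$chrom == ch, ]
    mk <- mk[order(mk$posBp), ]
    snpF <- file.path(dir, paste0("chr", ch, "_snps.txt"))
    mapF <- file.path(dir, paste0("chr", ch, "_map.txt"))
    writeLines(mk$rsId, snpF)
    writeLines(format(map@gaps$cm[map@gaps$chrom == ch], trim = TRUE),
               mapF)
    files <- c(files, snpF, mapF)
  }
  invisible(files)
}
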