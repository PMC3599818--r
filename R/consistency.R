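# Reconciliation of events across overlapping quartets: quintet
# deduplication, per-child attribution within child triples, and exclusion
# of meioses that fail the consistency checks.

# 1 bp or more of shared closed interval
.overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) <= pmin(e1, e2)

#' Merge events from two quartets sharing one child (a quintet)
#'
#' A crossover in the shared child is visible in both quartets; where a
#' prediction interval in one quartet overlaps (>= 1 bp) an interval of the
#' same parent and chromosome in the other, the two detections are assumed
#' to be the same event in the shared child and are merged into a single
#' event whose interval is the intersection. Events seen in only one quartet
#' are attributed to that quartet's non-shared child. Matching is greedy in
#' genomic order.
#'
#' @param eventsQ1,eventsQ2 event data.frames (from [detectEvents()]) of the
#'   two quartets.
#' @param sharedChild id of the child present in both quartets.
#' @return merged event data.frame with `attributedChild` filled in.
#' @export
mergeQuintet <- function(eventsQ1, eventsQ2, sharedChild) {
  for (ev in list(eventsQ1, eventsQ2)) {
    if (nrow(ev) && !all(sharedChild == ev$child1 | sharedChild == ev$child2))
      stop("sharedChild must belong to both quartets")
  }
  other <- function(ev) {
    if (!nrow(ev)) return(character())
    ifelse(ev$child1 == sharedChild, ev$child2, ev$child1)
  }
  o1 <- other(eventsQ1); o2 <- other(eventsQ2)
  out <- list()
  used2 <- rep(FALSE, nrow(eventsQ2))
  keys <- unique(rbind(eventsQ1[, c("parent", "chrom")],
                       eventsQ2[, c("parent", "chrom")]))
  for (k in seq_len(nrow(keys))) {
    i1 <- which(eventsQ1$parent == keys$parent[k] &
                  eventsQ1$chrom == keys$chrom[k])
    i1 <- i1[order(eventsQ1$startBp[i1])]
    i2 <- which(eventsQ2$parent == keys$parent[k] &
                  eventsQ2$chrom == keys$chrom[k])
    i2 <- i2[order(eventsQ2$startBp[i2])]
    for (i in i1) {
      cand <- i2[!used2[i2] &
                   .overlaps(eventsQ1$startBp[i], eventsQ1$endBp[i],
                             eventsQ2$startBp[i2], eventsQ2$endBp[i2])]
      if (length(cand)) {
        j <- cand[1]
        used2[j] <- TRUE
        m <- eventsQ1[i, ]
        m$startBp <- max(eventsQ1$startBp[i], eventsQ2$startBp[j])
        m$endBp <- min(eventsQ1$endBp[i], eventsQ2$endBp[j])
        m$resolutionBp <- m$endBp - m$startBp
        m$attributedChild <- sharedChild
        out[[length(out) + 1]] <- m
      } else {
        m <- eventsQ1[i, ]
        m$attributedChild <- o1[i]
        out[[length(out) + 1]] <- m
      }
    }
  }
  for (j in which(!used2)) {
    m <- eventsQ2[j, ]
    m$attributedChild <- o2[j]
    out[[length(out) + 1]] <- m
  }
  if (!length(out)) return(.emptyEvents())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attribute triple events to individual children
#'
#' For three children a, b, c observed as the overlapping quartet pairs
#' (a,b), (a,c), (b,c): a crossover in child x must be visible in both pairs
#' containing x and absent from the third, so every event should match (>= 1
#' bp interval overlap, same parent and chromosome) an event in exactly one
#' other pair. Matching is greedy in genomic order and consumes events; a
#' matched pair of detections becomes one event attributed to the common
#' child, with the intersected interval. Any unmatched event makes the
#' triple `inconsistent`.
#'
#' @param events event data.frame containing the three pairs' events
#'   (child1/child2 columns identify the pair).
#' @param triple character vector of the three child ids.
#' @return list with `events` (attributed data.frame), `status`
#'   ("consistent"/"inconsistent"), `nUnmatched`, and `triple`.
#' @export
attributeTriple <- function(events, triple) {
  stopifnot(length(triple) == 3)
  pairKey <- function(x, y) paste(sort(c(x, y)), collapse = "|")
  pairs <- list(triple[c(1, 2)], triple[c(1, 3)], triple[c(2, 3)])
  keys <- vapply(pairs, function(p) pairKey(p[1], p[2]), character(1))
  evKey <- if (nrow(events))
    mapply(pairKey, events$child1, events$child2) else character()
  idx <- lapply(keys, function(k) which(evKey == k))

  used <- rep(FALSE, nrow(events))
  out <- list()
  nUnmatched <- 0L
  sharedChild <- function(p1, p2) intersect(p1, p2)
  # match events of pair pi against pairs pj (j > i)
  for (i in 1:2) {
    for (e in idx[[i]][order(events$startBp[idx[[i]]])]) {
      if (used[e]) next
      matched <- FALSE
      for (j in (i + 1):3) {
        cand <- idx[[j]]
        cand <- cand[!used[cand] &
                       events$parent[cand] == events$parent[e] &
                       events$chrom[cand] == events$chrom[e] &
                       .overlaps(events$startBp[e], events$endBp[e],
                                 events$startBp[cand], events$endBp[cand])]
        if (length(cand)) {
          cand <- cand[order(events$startBp[cand])]
          f <- cand[1]
          used[c(e, f)] <- TRUE
          m <- events[e, ]
          m$startBp <- max(events$startBp[e], events$startBp[f])
          m$endBp <- min(events$endBp[e], events$endBp[f])
          m$resolutionBp <- m$endBp - m$startBp
          m$attributedChild <- sharedChild(pairs[[i]], pairs[[j]])
          out[[length(out) + 1]] <- m
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        used[e] <- TRUE
        nUnmatched <- nUnmatched + 1L
      }
    }
  }
  nUnmatched <- nUnmatched + sum(!used[idx[[3]]])
  attributed <- if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else .emptyEvents()
  list(events = attributed,
       status = if (nUnmatched == 0) "consistent" else "inconsistent",
       nUnmatched = nUnmatched, triple = triple)
}

#' Filter meioses by triple consistency
#'
#' A child implicated only in inconsistent triples is excluded; a child that
#' is a member of at least one fully consistent triple is retained even when
#' another of its triples failed (rescued).
#'
#' @param reports list of results from [attributeTriple()].
#' @return list with `retained`, `excluded` (character vectors of child ids)
#'   and `log` (data.frame: childId, status "ok"/"rescued"/"excluded").
#' @export
filterMeioses <- function(reports) {
  children <- unique(unlist(lapply(reports, `[[`, "triple")))
  inCons <- unique(unlist(lapply(reports, function(r)
    if (r$status == "consistent") r$triple)))
  inIncons <- unique(unlist(lapply(reports, function(r)
    if (r$status == "inconsistent") r$triple)))
  status <- setNames(rep("ok", length(children)), children)
  status[children %in% inIncons & children %in% inCons] <- "rescued"
  status[children %in% inIncons & !children %in% inCons] <- "excluded"
  list(retained = children[status != "excluded"],
       excluded = children[status == "excluded"],
       log = data.frame(childId = children, status = unname(status),
                        stringsAsFactors = FALSE))
}
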