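# Cross-quartet reconciliation: quintet merging, triple attribution,
# meiosis filtering.

test_that("quintet merging counts shared-child events once", {
  # same event seen in both quartets -> one event, intersected interval,
  # attributed to the shared child
  e1 <- evRow(100, 300, child1 = "a", child2 = "b")
  e2 <- evRow(150, 400, child1 = "b", child2 = "c")
  m <- mergeQuintet(e1, e2, "b")
  expect_equal(nrow(m), 1L)
  expect_equal(m$attributedChild, "b")
  expect_equal(c(m$startBp, m$endBp), c(150, 300))

  # event only in q1 -> the non-shared child of q1
  m2 <- mergeQuintet(e1, e1[0, ], "b")
  expect_equal(m2$attributedChild, "a")
  expect_equal(c(m2$startBp, m2$endBp), c(100, 300))

  # non-overlapping events stay separate with their own attribution
  e3 <- evRow(1000, 1200, child1 = "b", child2 = "c")
  m3 <- mergeQuintet(e1, e3, "b")
  expect_equal(nrow(m3), 2L)
  expect_setequal(m3$attributedChild, c("a", "c"))

  # different parents never merge
  e4 <- evRow(100, 300, parent = "paternal", child1 = "b", child2 = "c")
  m4 <- mergeQuintet(e1, e4, "b")
  expect_equal(nrow(m4), 2L)

  expect_equal(nrow(mergeQuintet(e1[0, ], e1[0, ], "b")), 0L)
})

test_that("counting is conserved through quintet merging", {
  set.seed(19)
  for (r in 1:10) {
    n1 <- sample(0:4, 1); n2 <- sample(0:4, 1)
    mk <- function(n, c1, c2) {
      if (n == 0) return(evRow(1, 2, child1 = c1, child2 = c2)[0, ])
      s <- sort(sample(1e6, n))
      do.call(rbind, lapply(s, function(x)
        evRow(x, x + sample(5e4, 1), child1 = c1, child2 = c2)))
    }
    e1 <- mk(n1, "a", "b"); e2 <- mk(n2, "b", "c")
    m <- mergeQuintet(e1, e2, "b")
    expect_lte(nrow(m), n1 + n2)
    expect_gte(nrow(m), max(n1, n2))
  }
})

test_that("triple attribution assigns events to the common child", {
  # one crossover in child a: visible in (a,b) and (a,c), absent from (b,c)
  ev <- rbind(evRow(100, 300, child1 = "a", child2 = "b"),
              evRow(120, 350, child1 = "a", child2 = "c"))
  res <- attributeTriple(ev, c("a", "b", "c"))
  expect_equal(res$status, "consistent")
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$attributedChild, "a")
  expect_equal(c(res$events$startBp, res$events$endBp), c(120, 300))

  # crossover in c: seen in (a,c) and (b,c)
  ev2 <- rbind(evRow(500, 700, child1 = "a", child2 = "c"),
               evRow(520, 800, child1 = "b", child2 = "c"))
  res2 <- attributeTriple(ev2, c("a", "b", "c"))
  expect_equal(res2$status, "consistent")
  expect_equal(res2$events$attributedChild, "c")

  # unmatched event -> inconsistent
  ev3 <- evRow(100, 300, child1 = "a", child2 = "b")
  res3 <- attributeTriple(ev3, c("a", "b", "c"))
  expect_equal(res3$status, "inconsistent")
  expect_equal(res3$nUnmatched, 1L)

  # no events anywhere -> consistent, nothing attributed
  res4 <- attributeTriple(ev3[0, ], c("a", "b", "c"))
  expect_equal(res4$status, "consistent")
  expect_equal(nrow(res4$events), 0L)
})

test_that("triple attribution is invariant to the listing order of pairs", {
  ev <- rbind(evRow(100, 300, child1 = "a", child2 = "b"),
              evRow(120, 350, child1 = "a", child2 = "c"),
              evRow(900, 1000, child1 = "b", child2 = "c"),
              evRow(880, 950, child1 = "a", child2 = "b"))
  base <- attributeTriple(ev, c("a", "b", "c"))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    res <- attributeTriple(ev[sample(nrow(ev)), ],
                           c("a", "b", "c")[perm])
    expect_equal(res$status, base$status)
    o1 <- base$events[order(base$events$startBp), ]
    o2 <- res$events[order(res$events$startBp), ]
    expect_equal(o2$attributedChild, o1$attributedChild)
    expect_equal(o2$startBp, o1$startBp)
  }
})

test_that("error-free simulated triples recover per-child crossovers", {
  set.seed(29)
  panel <- generatePanel(nHaplotypes = 60, nMarkers = 4000, spanBp = 2e7)
  ids <- c("a", "b", "c")
  for (r in 1:3) {
    tri <- simTripleSeparated(panel, perMeiosis = 2)
    ev <- detectEvents(tripleQuartets(tri, ids))
    res <- attributeTriple(ev, ids)
    expect_equal(res$status, "consistent")
    # each child's true crossovers (paternal + maternal) come back exactly
    for (i in 1:3) {
      truthPos <- sort(c(tri$kids[[i]]$patBreaks, tri$kids[[i]]$matBreaks))
      got <- res$events[res$events$attributedChild == ids[i], ]
      got <- got[order(got$startBp), ]
      expect_equal(nrow(got), 4L)
      expect_true(all(got$startBp <= truthPos & truthPos <= got$endBp))
    }
  }
})

test_that("meiosis filtering excludes and rescues children correctly", {
  rep1 <- list(status = "consistent", triple = c("a", "b", "c"))
  rep2 <- list(status = "inconsistent", triple = c("c", "d", "e"))
  rep3 <- list(status = "consistent", triple = c("d", "e", "f"))
  all3 <- filterMeioses(list(rep1, rep2, rep3))
  # c, d, e appear in the failing triple, but all are members of a passing
  # one -> rescued; nobody is excluded
  expect_equal(length(all3$excluded), 0L)
  expect_setequal(all3$log$status[all3$log$childId %in% c("c", "d", "e")],
                  "rescued")

  only <- filterMeioses(list(rep1, rep2))
  expect_setequal(only$excluded, c("d", "e"))   # c rescued via rep1
  expect_true("c" %in% only$retained)

  fine <- filterMeioses(list(rep1, rep3))
  expect_equal(length(fine$excluded), 0L)
  expect_true(all(fine$log$status == "ok"))
})
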