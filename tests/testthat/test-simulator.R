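# Haplotype-panel generation, quartet simulation and detection scoring.

test_that("panel generation is seeded, floored and Beta-distributed", {
  p1 <- generatePanel(nHaplotypes = 50, nMarkers = 500, spanBp = 1e6,
                      seed = 101)
  p2 <- generatePanel(nHaplotypes = 50, nMarkers = 500, spanBp = 1e6,
                      seed = 101)
  expect_identical(p1@haplotypes, p2@haplotypes)
  expect_identical(p1@positionsBp, p2@positionsBp)
  expect_true(all(diff(p1@positionsBp) > 0))

  freq <- colMeans(p1@haplotypes)
  expect_true(all(pmin(freq, 1 - freq) >= 0.05))  # realised MAF floor

  # empirical heterozygosity matches the closed form for the truncated
  # Beta(0.8, 0.8) draw, E[2p(1-p)], within Monte-Carlo error
  big <- generatePanel(nHaplotypes = 400, nMarkers = 4000, spanBp = 1e7,
                       seed = 202)
  pdraw <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      d <- rbeta(n, 0.8, 0.8)
      out <- c(out, d[pmin(d, 1 - d) >= 0.05])
    }
    out[1:n]
  }
  set.seed(7)
  d <- pdraw(2e5)
  expected <- mean(2 * d * (1 - d))
  het <- mean(big@haplotypes[1:200, ] != big@haplotypes[201:400, ])
  expect_equal(het, expected, tolerance = 0.02)

  expect_error(generatePanel(nMarkers = 500, mafShape1 = -1), "invalid")
  expect_error(generatePanel(nMarkers = 1), "nMarkers")
})

test_that("quartet simulation produces Mendelian-consistent children", {
  panel <- generatePanel(nHaplotypes = 30, nMarkers = 800, spanBp = 5e6,
                         seed = 5)
  set.seed(55)
  sim <- simulateQuartet(panel, crossoversPerMeiosis = 3, errorRate = 0)
  expect_equal(nrow(sim$truth), 12L)
  expect_true(all(sim$truth$posBp > 0 & sim$truth$posBp < panel@spanBp))
  v <- mendelCheck(list(fatherId = "father", motherId = "mother",
                        childIds = c("child1", "child2")),
                   sim$quartet@geno)
  expect_false(any(v))

  # with zero crossovers children are unrecombined haplotypes: no events
  set.seed(56)
  sim0 <- simulateQuartet(panel, crossoversPerMeiosis = 0)
  expect_equal(nrow(sim0$truth), 0L)
  expect_equal(nrow(detectEvents(sim0$quartet)), 0L)

  expect_error(simulateQuartet(panel, crossoversPerMeiosis = -1), ">= 0")
})

test_that("genotyping error injection corrupts calls at the given rate", {
  panel <- generatePanel(nHaplotypes = 30, nMarkers = 5000, spanBp = 5e6,
                         seed = 6)
  set.seed(66)
  clean <- simulateQuartet(panel, 0, errorRate = 0)
  set.seed(66)
  noisy <- simulateQuartet(panel, 0, errorRate = 0.02)
  frac <- mean(clean$quartet@geno != noisy$quartet@geno)
  expect_equal(frac, 0.02, tolerance = 0.25)
})

test_that("scoring follows the localisation and correctness conventions", {
  ev <- evRow(100, 300, quartetId = "q1")
  truth <- data.frame(quartetId = "q1", parent = "maternal", child = "c1",
                      posBp = 200)
  sc <- scoreDetection(ev, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$precision, 1)

  # wrong parent: neither localised nor correct
  truthP <- transform(truth, parent = "paternal")
  sc2 <- scoreDetection(ev, truthP)
  expect_equal(sc2$sensitivity, 0)
  expect_equal(sc2$precision, 0)

  # conventions at the empty edges
  expect_equal(scoreDetection(ev[0, ], truth)$sensitivity, 0)
  expect_equal(scoreDetection(ev[0, ], truth)$precision, 1)
  expect_equal(scoreDetection(ev[0, ], truth[0, ])$sensitivity, 1)

  expect_error(scoreDetection(evRow(1, 2, quartetId = "zz"), truth),
               "absent from truth")
})

test_that("shuffled children destroy precision (negative control)", {
  panel <- generatePanel(nHaplotypes = 40, nMarkers = 2500, spanBp = 1e7,
                         seed = 8)
  set.seed(88)
  usedHaps <- sample.int(nrow(panel@haplotypes), 4)  # same draw as below
  set.seed(88)
  sim <- simulateQuartet(panel, 3, 0)
  # replace the children with unrelated panel haplotype pairs
  free <- setdiff(seq_len(nrow(panel@haplotypes)), usedHaps)
  fake <- sim$quartet
  fake@geno[3, ] <- panel@haplotypes[free[1], ] + panel@haplotypes[free[2], ]
  fake@geno[4, ] <- panel@haplotypes[free[3], ] + panel@haplotypes[free[4], ]
  ev <- suppressMessages(detectEvents(fake))
  sc <- scoreDetection(ev, sim$truth)
  expect_gt(sc$nIntervals, 20)     # unrelated children look like many events
  expect_lt(sc$precision, 0.3)
})

test_that("sensitivity does not decrease with marker density", {
  sens <- numeric(0)
  medRes <- numeric(0)
  for (nm in c(500, 2000, 8000)) {
    res <- runValidation(nQuartets = 8, seed = 99, nHaplotypes = 40,
                         nMarkers = nm, spanBp = 2e7)
    sens <- c(sens, res$score$sensitivity)
    medRes <- c(medRes, median(res$events$resolutionBp))
  }
  expect_true(all(diff(sens) >= -0.02))        # non-decreasing up to noise
  expect_true(all(diff(medRes) < 0))           # intervals tighten
  expect_gte(sens[3], 0.95)
})

test_that("the validation pipeline is reproducible bit for bit", {
  r1 <- runValidation(nQuartets = 3, seed = 77, nHaplotypes = 30,
                      nMarkers = 1000, spanBp = 5e6)
  r2 <- runValidation(nQuartets = 3, seed = 77, nHaplotypes = 30,
                      nMarkers = 1000, spanBp = 5e6)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$truth, r2$truth)
  r3 <- runValidation(nQuartets = 3, seed = 78, nHaplotypes = 30,
                      nMarkers = 1000, spanBp = 5e6)
  expect_false(identical(r1$truth$posBp, r3$truth$posBp))
})
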