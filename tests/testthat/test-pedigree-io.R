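# PLINK reading/writing, marker QC, Mendelian checks, family decomposition.

writeTestPed <- function(lines, mapLines) {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(lines, ped)
  writeLines(mapLines, map)
  list(ped = ped, map = map)
}

test_that("PED/MAP parsing recodes alleles per marker by first appearance", {
  f <- writeTestPed(
    c("f1 dad 0 0 1 0  1 1  C T",
      "f1 mum 0 0 2 0  1 1  T T",
      "f1 kid dad mum 2 0  1 1  C T"),
    c("1 rs1 0 100", "1 rs2 0 200"))
  d <- readPlink(f$ped, f$map)
  expect_equal(unname(d$genotypes[, "rs1"]), c(0L, 0L, 0L))  # monomorphic: AA
  # at rs2 C is first seen -> A; "C T" = AB, "T T" = BB
  expect_equal(unname(d$genotypes[, "rs2"]), c(1L, 2L, 1L))
  expect_equal(d$pedigree$sex, c("M", "F", "F"))
  expect_equal(d$pedigree$fatherId, c(NA, NA, "dad"))
})

test_that("markers are sorted by chromosome and position on load", {
  f <- writeTestPed(
    c("f1 a 0 0 1 0  1 1  2 2  1 2"),
    c("2 rsB 0 50", "1 rsA 0 900", "1 rsC 0 100"))
  d <- readPlink(f$ped, f$map)
  expect_equal(d$markers$rsId, c("rsC", "rsA", "rsB"))
  expect_equal(colnames(d$genotypes), c("rsC", "rsA", "rsB"))
})

test_that("malformed PED input is rejected with a clear error", {
  f <- writeTestPed(
    c("f1 a 0 0 1 0  1 1  1 2",
      "f1 b 0 0 1 0  1 1  1"),        # truncated row
    c("1 rs1 0 100", "1 rs2 0 200"))
  expect_error(readPlink(f$ped, f$map), "row 2.*truncated|truncated")

  f2 <- writeTestPed(
    c("f1 a 0 0 1 0  A C", "f1 b 0 0 1 0  G A"),  # 3 alleles at rs1
    c("1 rs1 0 100"))
  expect_error(readPlink(f2$ped, f2$map), "rs1.*alleles")

  f3 <- writeTestPed(
    c("f1 a 0 0 1 0  1 1", "f1 a 0 0 1 0  1 1"),
    c("1 rs1 0 100"))
  expect_error(readPlink(f3$ped, f3$map), "duplicate individual id")
})

test_that("round trip through writePlink preserves genotypes", {
  set.seed(3)
  ped <- data.frame(famId = "f1", id = c("p1", "p2", "k1"),
                    fatherId = c(NA, NA, "p1"), motherId = c(NA, NA, "p2"),
                    sex = c("M", "F", "F"), stringsAsFactors = FALSE)
  markers <- data.frame(chrom = "1", rsId = paste0("rs", 1:30),
                        posBp = sort(sample(1e6, 30)))
  G <- matrix(sample(c(0:2, NA), 90, replace = TRUE), 3, 30,
              dimnames = list(ped$id, markers$rsId))
  # writePlink labels dosage with A/B and readPlink recodes by first-seen
  # allele, so anchor the first individual at dosage 0/1 to keep the
  # labelling aligned (recoding is otherwise only defined up to relabel)
  G[1, ] <- rep(c(0L, 1L), 15)
  pedF <- tempfile(); mapF <- tempfile()
  writePlink(ped, markers, G, pedF, mapF)
  d <- readPlink(pedF, mapF)
  expect_equal(d$genotypes, G)
  expect_equal(d$pedigree$id, ped$id)
  expect_equal(d$markers$posBp, markers$posBp)
})

test_that("Mendelian check flags impossible child genotypes only", {
  G <- rbind(dad = c(0L, 0L, 1L, 0L, NA),
             mum = c(0L, 1L, 1L, 2L, 0L),
             kid = c(1L, 2L, 0L, 1L, 2L))
  colnames(G) <- paste0("s", 1:5)
  v <- mendelCheck(list(fatherId = "dad", motherId = "mum",
                        childIds = "kid"), G)
  # AA x AA -> AB impossible; AA x AB -> BB impossible; AB x AB -> anything;
  # AA x BB -> AB required (ok); missing parent -> never a violation
  expect_equal(unname(v["kid", ]), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("QC filters remove low call rate, low MAF and HWE failures", {
  set.seed(9)
  nF <- 100
  ids <- paste0("ind", 1:nF)
  ped <- data.frame(famId = ids, id = ids, fatherId = NA_character_,
                    motherId = NA_character_, sex = "F",
                    stringsAsFactors = FALSE)
  # m1: clean 50/50 HWE; m2: 2% missing; m3: monomorphic;
  # m4: extreme HWE failure (all heterozygous)
  m1 <- rep(c(0L, 1L, 1L, 2L), nF / 4)
  m2 <- m1; m2[1:2] <- NA
  m3 <- rep(0L, nF)
  m4 <- rep(1L, nF)
  G <- cbind(m1 = m1, m2 = m2, m3 = m3, m4 = m4)
  rownames(G) <- ids
  res <- qcFilterMarkers(G, ped)
  expect_equal(res$keep, 1L)
  expect_equal(res$report$reasons[2], "call_rate")
  expect_match(res$report$reasons[3], "maf")
  expect_match(res$report$reasons[4], "hwe")
  # exact Hardy-Weinberg proportions give chi-square p = 1
  expect_equal(res$report$hweP[1], 1)
})

test_that("QC is order-independent: joint filter equals any sequential order", {
  set.seed(13)
  nF <- 60
  ids <- paste0("i", 1:nF)
  ped <- data.frame(famId = ids, id = ids, fatherId = NA_character_,
                    motherId = NA_character_, sex = "F",
                    stringsAsFactors = FALSE)
  # mixed marker panel: per-marker allele frequencies spanning the MAF
  # threshold, occasional missingness spanning the call-rate threshold
  G <- sapply(1:40, function(j) {
    p <- runif(1, 0, 0.3)
    g <- rbinom(nF, 2, p)
    g[runif(nF) < sample(c(0, 0.03), 1, prob = c(.7, .3))] <- NA
    g
  })
  dimnames(G) <- list(ids, paste0("m", 1:40))
  storage.mode(G) <- "integer"
  joint <- qcFilterMarkers(G, ped)
  # sequential: call-rate filter first, then MAF/HWE on the survivors
  s1 <- qcFilterMarkers(G, ped, minMaf = 0, minHweP = 0)
  G2 <- G[, s1$keep, drop = FALSE]
  s2 <- qcFilterMarkers(G2, ped, minCallRate = 0)
  expect_equal(colnames(G2)[s2$keep], colnames(G)[joint$keep])
})

test_that("QC without founders disables MAF/HWE with a warning", {
  ids <- c("k1", "k2")
  ped <- data.frame(famId = "f", id = ids, fatherId = "dad",
                    motherId = "mum", sex = "F", stringsAsFactors = FALSE)
  G <- matrix(c(0L, 0L, 1L, 1L), 2, 2, dimnames = list(ids, c("m1", "m2")))
  expect_warning(res <- qcFilterMarkers(G, ped), "founders")
  expect_equal(res$keep, c(1L, 2L))
})

test_that("family decomposition follows the overlapping-triples rule", {
  expect_equal(decomposeFamily(c("a", "b"))$quartets, list(c("a", "b")))
  expect_equal(decomposeFamily(c("a", "b"))$triples, list())

  d3 <- decomposeFamily(c("a", "b", "c"))
  expect_equal(d3$quartets,
               list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(d3$triples, list(c("a", "b", "c")))

  d5 <- decomposeFamily(c("a", "b", "c", "d", "e"))
  expect_equal(d5$triples, list(c("a", "b", "c"), c("c", "d", "e")))
  expect_equal(length(d5$quartets), 6L)  # c shared between the triples

  d4 <- decomposeFamily(c("a", "b", "c", "d"))
  expect_equal(d4$triples, list(c("a", "b", "c"), c("b", "c", "d")))

  # every child is covered by at least one quartet
  for (k in 2:8) {
    ch <- paste0("c", 1:k)
    expect_setequal(unique(unlist(decomposeFamily(ch)$quartets)), ch)
  }

  expect_message(d1 <- decomposeFamily("only"), "skipped")
  expect_equal(d1$quartets, list())
})
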