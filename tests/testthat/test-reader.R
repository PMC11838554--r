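# Random access, traversal, string tables, site aggregation, frequencies.

# A small phased fixture written once per test via the writer.
writePhasedFixture <- function(p, seed = 31, n = 25, NInd = 20) {
  set.seed(seed)
  w <- createIgdWriter(p, numIndividuals = NInd, ploidy = 2)
  NH <- 2 * NInd
  truth <- list()
  pos <- sort(sample.int(1000, n))
  for (i in seq_len(n)) {
    s <- sort(sample(0:(NH - 1), sample(0:NH, 1)))
    writeVariantRow(w, pos[i], "A", "C", s)
    truth[[i]] <- list(pos = pos[i], samples = as.numeric(s))
  }
  finalizeIgd(w, individualIds = paste0("ind", seq_len(NInd)))
  truth
}

test_that("opening validates magic, finalization, and index bounds", {
  p <- tmpPath(".igd")
  writePhasedFixture(p)
  igd <- openIgd(p)
  expect_equal(igdHeader(igd)@numRows, 25)
  expect_equal(igdHeader(igd)@numIndividuals, 20)
  closeIgd(igd)
  # zero out the first 8 bytes -> bad magic
  b <- readBin(p, "raw", file.size(p))
  bad <- tmpPath(".igd")
  b0 <- b; b0[1:8] <- as.raw(0)
  writeBin(b0, bad)
  expect_error(openIgd(bad), "bad magic")
  # truncate inside the index
  short <- tmpPath(".igd")
  h <- decodeHeader(b)
  writeBin(b[1:(h@indexOffset + 5)], short)
  expect_error(openIgd(short), "truncated")
})

test_that("strict open rejects a set dense-padding bit, lenient masks it", {
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 3, ploidy = 2)   # NH = 6
  writeVariantRow(w, 5, "A", "C", c(0, 1, 2, 3))            # dense, 1 byte
  finalizeIgd(w)
  igd <- openIgd(p)
  off <- igdio:::.igdEntry(igd, 0)$genotypeOffset
  closeIgd(igd)
  b <- readBin(p, "raw", file.size(p))
  b[off + 1] <- as.raw(bitwOr(as.integer(b[off + 1]), 0x01))  # bit of sample 7
  corrupt <- tmpPath(".igd")
  writeBin(b, corrupt)
  expect_error(openIgd(corrupt, strict = TRUE), "padding")
  igd <- openIgd(corrupt, strict = FALSE)
  expect_equal(getVariant(igd, 0)$row@samples, c(0, 1, 2, 3))
  closeIgd(igd)
})

test_that("random access equals sequential traversal for every row", {
  p <- tmpPath(".igd")
  truth <- writePhasedFixture(p)
  igd <- openIgd(p, strict = TRUE)
  seqRows <- igdVariants(igd)
  expect_length(seqRows, length(truth))
  for (i in seq_along(truth) - 1L) {
    v <- getVariant(igd, i)
    expect_equal(v$meta@rowIndex, i)
    expect_equal(v$meta@position, seqRows[[i + 1]]$meta@position)
    expect_equal(v$row@samples, seqRows[[i + 1]]$row@samples)
    expect_equal(v$row@samples, truth[[i + 1]]$samples)
  }
  expect_error(getVariant(igd, length(truth)), "out of range")
  expect_error(getVariant(igd, -1), "out of range")
  closeIgd(igd)
})

test_that("range traversal equals the filtered full scan", {
  p <- tmpPath(".igd")
  truth <- writePhasedFixture(p, seed = 32)
  igd <- openIgd(p)
  full <- igdVariants(igd)
  pos <- vapply(full, function(v) v$meta@position, numeric(1))
  for (rg in list(c(0, 1e9), c(200, 600), c(1, 1), c(5000, 9000),
                  c(pos[7], pos[7] + 1))) {
    got <- igdVariants(igd, range = rg)
    want <- full[pos >= rg[1] & pos < rg[2]]
    expect_equal(lapply(got, function(v) v$row@samples),
                 lapply(want, function(v) v$row@samples))
    # locateRange agrees with the linear-scan bounds
    lr <- locateRange(igd, rg[1], rg[2])
    expect_equal(lr[2] - lr[1], length(want))
    if (length(want))
      expect_equal(full[[lr[1] + 1]]$meta@position, want[[1]]$meta@position)
  }
  expect_equal(locateRange(igd, 0, 1e9), c(0, igdHeader(igd)@numRows))
  closeIgd(igd)
})

test_that("locateRange falls back to a linear scan on unsorted positions", {
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 4, ploidy = 2)
  pos <- c(100, 20, 300, 40, 250)
  for (q in pos) writeVariantRow(w, q, "A", "C", 0)
  finalizeIgd(w)
  igd <- openIgd(p)
  lr <- locateRange(igd, 30, 260)
  hit <- which(pos >= 30 & pos < 260)
  expect_equal(lr, c(min(hit) - 1, max(hit)))
  # and range traversal still yields exactly the in-range rows
  got <- vapply(igdVariants(igd, range = c(30, 260)),
                function(v) v$meta@position, numeric(1))
  expect_equal(sort(got), sort(pos[hit]))
  closeIgd(igd)
})

test_that("string tables round trip and strict mode cross-checks counts", {
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 3, ploidy = 1)
  writeVariantRow(w, 4, "AT", "A", 0:1)
  writeVariantRow(w, 9, "C", "CGG", 2)
  finalizeIgd(w, individualIds = c("x", "y", "z"))
  igd <- openIgd(p, strict = TRUE)
  al <- igdAlleles(igd)
  expect_equal(al$ref, c("AT", "C"))
  expect_equal(al$alt, c("A", "CGG"))
  expect_equal(individualIds(igd), c("x", "y", "z"))
  closeIgd(igd)
  # corrupt the individual-ID count: strict open fails, lenient reads
  b <- readBin(p, "raw", file.size(p))
  h <- decodeHeader(b)
  b[h@individualIdsOffset + 1] <- as.raw(2)
  bad <- tmpPath(".igd")
  writeBin(b, bad)
  expect_error(openIgd(bad, strict = TRUE), "count mismatch")
  igd <- openIgd(bad)
  expect_equal(individualIds(igd), c("x", "y"))
  closeIgd(igd)
})

test_that("aggregateSite recovers multi-allelic sites and missing rows", {
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 3, ploidy = 2)   # NH = 6
  writeVariantRow(w, 50, "A", "C", c(1))
  writeVariantRow(w, 50, "A", "G", c(2, 3))
  writeVariantRow(w, 50, "A", "", c(0), isMissing = TRUE)
  writeVariantRow(w, 99, "T", "G", c(4))
  finalizeIgd(w)
  igd <- openIgd(p, strict = TRUE)
  site <- aggregateSite(igd, 50)
  expect_equal(site$ref, "A")
  expect_length(site$alts, 2)
  expect_equal(site$alts[[1]]$alt, "C")
  expect_equal(site$alts[[1]]$samples, 1)
  expect_equal(site$alts[[2]]$alt, "G")
  expect_equal(site$alts[[2]]$samples, c(2, 3))
  expect_equal(site$missing, 0)
  # carrier sets of distinct alts are disjoint
  expect_length(intersect(site$alts[[1]]$samples, site$alts[[2]]$samples), 0)
  empty <- aggregateSite(igd, 1234)
  expect_length(empty$alts, 0)
  expect_true(is.na(empty$ref))
  closeIgd(igd)
})

test_that("allele frequencies always come from the decoded sample data", {
  # phased: NH = 4, carriers {0, 2} -> 0.5
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 2, ploidy = 2)
  writeVariantRow(w, 1, "A", "C", c(0, 2))
  writeVariantRow(w, 2, "A", "G", numeric(0))
  finalizeIgd(w)
  igd <- openIgd(p)
  expect_equal(alleleFrequency(igd, 0), 0.5)
  expect_equal(alleleFrequency(igd, 1), 0)
  closeIgd(igd)

  # unphased diploid N = 3: numCopies=1 on {0}, numCopies=2 on {1}
  p2 <- tmpPath(".igd")
  w <- createIgdWriter(p2, numIndividuals = 3, ploidy = 2, phased = FALSE)
  writeVariantRow(w, 7, "A", "C", 0, numCopies = 1)
  writeVariantRow(w, 7, "A", "C", 1, numCopies = 2)
  finalizeIgd(w)
  igd <- openIgd(p2)
  expect_equal(alleleFrequency(igd, 0) + alleleFrequency(igd, 1),
               (1 + 2) / 6)
  closeIgd(igd)
})

test_that("frequency on a missing row errors; excludeMissing shrinks the denominator", {
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 4, ploidy = 2)   # NH = 8
  writeVariantRow(w, 5, "A", "C", c(0, 1))
  writeVariantRow(w, 5, "A", "", c(6, 7), isMissing = TRUE)
  finalizeIgd(w)
  igd <- openIgd(p)
  expect_equal(alleleFrequency(igd, 0), 2 / 8)
  expect_equal(alleleFrequency(igd, 0, excludeMissing = TRUE), 2 / 6)
  expect_error(alleleFrequency(igd, 1), "missing-data row")
  closeIgd(igd)
})

test_that("decoded content is identical across stored representations", {
  set.seed(33)
  NH <- 40
  rows <- lapply(1:20, function(i) sort(sample(0:(NH - 1), sample(0:NH, 1))))
  freqs <- list()
  for (f in c("auto", "sparse", "dense")) {
    p <- tmpPath(".igd")
    w <- createIgdWriter(p, numIndividuals = NH / 2, ploidy = 2,
                         forceRepresentation = f)
    for (i in seq_along(rows)) writeVariantRow(w, i, "A", "C", rows[[i]])
    finalizeIgd(w)
    igd <- openIgd(p, strict = TRUE)
    freqs[[f]] <- vapply(seq_along(rows) - 1L,
                         function(i) alleleFrequency(igd, i), numeric(1))
    expect_equal(lapply(igdVariants(igd), function(v) v$row@samples),
                 lapply(rows, as.numeric))
    closeIgd(igd)
  }
  expect_equal(freqs$sparse, freqs$auto)
  expect_equal(freqs$dense, freqs$auto)
})
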