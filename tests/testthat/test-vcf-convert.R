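# Multi-allelic expansion, VCF <-> IGD conversion, round trips.

writeVcfText <- function(lines, path, samples = NULL) {
  if (!is.null(samples))
    lines <- c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               lines)
  writeLines(lines, path)
  path
}

test_that("phased expansion gives one row per alt plus a missing row", {
  # diploid phased, REF A, ALT C,G; GTs [0|1, 2|0]
  g <- matrix(c(0L, 1L, 2L, 0L), nrow = 2)
  rows <- expandSite(100, "A", c("C", "G"), g, phased = TRUE)
  expect_length(rows, 2)
  expect_equal(rows[[1]]$alt, "C")
  expect_equal(rows[[1]]$samples, 1)       # haplotype slot 1 of individual 0
  expect_equal(rows[[2]]$alt, "G")
  expect_equal(rows[[2]]$samples, 2)       # haplotype slot 0 of individual 1
  expect_false(any(vapply(rows, `[[`, logical(1), "isMissing")))

  # all 0|0: k empty rows, no missing row
  g0 <- matrix(0L, nrow = 2, ncol = 3)
  rows0 <- expandSite(5, "A", c("C", "G"), g0, phased = TRUE)
  expect_length(rows0, 2)
  expect_true(all(lengths(lapply(rows0, `[[`, "samples")) == 0))

  # .|1 for individual 0: missing row holds haploid 0, alt row holds 1
  gm <- matrix(c(NA, 1L), nrow = 2)
  rowsm <- expandSite(7, "A", c("C"), gm, phased = TRUE)
  expect_length(rowsm, 2)
  expect_equal(rowsm[[1]]$samples, 1)
  expect_true(rowsm[[2]]$isMissing)
  expect_equal(rowsm[[2]]$samples, 0)
})

test_that("unphased expansion groups individuals by exact copy count", {
  # diploid unphased, GTs: 0/1, 1/1, 0/0, 1/2, ./1
  g <- matrix(c(0L, 1L,  1L, 1L,  0L, 0L,  1L, 2L,  NA, 1L), nrow = 2)
  rows <- expandSite(9, "A", c("C", "G"), g, phased = FALSE)
  tags <- vapply(rows, function(r)
    paste0(r$alt, ":", r$numCopies, if (r$isMissing) ":M" else ""),
    character(1))
  expect_equal(tags, c("C:1", "C:2", "G:1", ":0:M"))
  expect_equal(rows[[1]]$samples, c(0, 3))   # exactly one C copy
  expect_equal(rows[[2]]$samples, 1)         # two C copies
  expect_equal(rows[[3]]$samples, 3)         # one G copy
  # the half-missing individual 4 is only in the missing row
  expect_equal(rows[[4]]$samples, 4)
  expect_false(4 %in% unlist(lapply(rows[1:3], `[[`, "samples")))
})

test_that("expansion rejects allele indexes beyond the alt list", {
  g <- matrix(c(0L, 3L), nrow = 2)
  expect_error(expandSite(1, "A", c("C", "G"), g, phased = TRUE),
               "allele index")
})

test_that("a bi-allelic VCF without missing data converts to M rows, Q = 0", {
  vcf <- tmpPath(".vcf")
  writeVcfText(c("1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0|0",
                 "1\t20\t.\tG\tT\t.\t.\t.\tGT\t1|1\t0|1"),
               vcf, samples = c("sA", "sB"))
  out <- tmpPath(".igd")
  rep <- vcfToIgd(vcf, out)
  s <- rep$summaries[[1]]
  expect_equal(s$numRows, 2)
  expect_equal(s$missingRows, 0)
  igd <- openIgd(out, strict = TRUE)
  expect_true(isPhased(igdHeader(igd)))
  expect_equal(individualIds(igd), c("sA", "sB"))
  expect_equal(getVariant(igd, 0)$row@samples, 1)
  expect_equal(getVariant(igd, 1)$row@samples, c(0, 1, 3))
  closeIgd(igd)
})

test_that("a tri-allelic site expands to two rows at the same position", {
  vcf <- tmpPath(".vcf")
  writeVcfText("1\t300\trs1\tA\tC,G\t.\t.\t.\tGT\t0|1\t2|0",
               vcf, samples = c("sA", "sB"))
  out <- tmpPath(".igd")
  vcfToIgd(vcf, out, storeVariantIds = TRUE)
  igd <- openIgd(out, strict = TRUE)
  expect_equal(igdHeader(igd)@numRows, 2)
  al <- igdAlleles(igd)
  expect_equal(al$ref, c("A", "A"))
  expect_equal(al$alt, c("C", "G"))
  expect_equal(vapply(igdVariants(igd), function(v) v$meta@position,
                      numeric(1)), c(300, 300))
  expect_equal(variantIds(igd), c("rs1", "rs1"))
  closeIgd(igd)
})

test_that("conversion preserves the genotype matrix exactly (phased grid)", {
  for (ploidy in c(1, 2, 3)) {
    for (mr in c(0, 0.05)) {
      ds <- simulateGenotypes(15, numSites = 25, ploidy = ploidy,
                              phased = TRUE, missingRate = mr,
                              multiallelicFraction = 0.2,
                              seed = 100 + ploidy * 10 + mr * 100)
      vcf <- tmpPath(".vcf")
      writeVcfFixture(ds, vcf)
      out <- tmpPath(".igd")
      vcfToIgd(vcf, out, phased = TRUE)
      expect_identical(igdPhasedMatrix(out, ds), datasetGenotypeMatrix(ds))
      # Q = number of sites with any missing call
      igd <- openIgd(out)
      q <- sum(bitwAnd(igdio:::.igdIndex(igd)$flags, IGD_MISSING) != 0)
      expect_equal(q, sum(vapply(ds@sites,
                                 function(s) length(s$missing) > 0,
                                 logical(1))))
      closeIgd(igd)
    }
  }
})

test_that("IGD frequencies equal an independent vcfR count for every variant", {
  ds <- simulateGenotypes(30, numSites = 40, ploidy = 2, phased = TRUE,
                          missingRate = 0.1, multiallelicFraction = 0.25,
                          seed = 41)
  vcf <- tmpPath(".vcf")
  writeVcfFixture(ds, vcf)
  out <- tmpPath(".igd")
  vcfToIgd(vcf, out)
  oracle <- vcfrSiteFreqs(vcf)
  igd <- openIgd(out)
  idx <- igdio:::.igdIndex(igd)
  al <- igdAlleles(igd)
  NH <- numHaploidSamples(igdHeader(igd))
  for (i in seq_len(igdHeader(igd)@numRows) - 1L) {
    if (bitwAnd(idx$flags[i + 1], IGD_MISSING) != 0) next
    o <- oracle[oracle$position == idx$position[i + 1] &
                oracle$alt == al$alt[i + 1], ]
    expect_equal(alleleFrequency(igd, i), o$count / NH)
  }
  closeIgd(igd)
})

test_that("VCF -> IGD -> VCF -> IGD is idempotent, phased and unphased", {
  for (phased in c(TRUE, FALSE)) {
    ds <- simulateGenotypes(12, numSites = 30, ploidy = 2, phased = phased,
                            missingRate = 0.08, multiallelicFraction = 0.2,
                            seed = if (phased) 51 else 52)
    vcf <- tmpPath(".vcf")
    writeVcfFixture(ds, vcf)
    igd1 <- tmpPath(".igd")
    vcfToIgd(vcf, igd1)
    vcf2 <- tmpPath(".vcf")
    igdToVcf(igd1, vcf2)
    igd2 <- tmpPath(".igd")
    vcfToIgd(vcf2, igd2)
    # identical site-wise genotypes (up to unphased entry order) ...
    expect_equal(igdSiteGenotypes(igd1), truthSiteGenotypes(ds))
    expect_equal(igdSiteGenotypes(igd2), igdSiteGenotypes(igd1))
    # ... and identical stored rows
    rows <- function(p) {
      h <- openIgd(p, strict = TRUE)
      on.exit(closeIgd(h))
      lapply(igdVariants(h), function(v)
        list(pos = v$meta@position, alt = v$meta@alt,
             nc = v$meta@numCopies, miss = v$row@isMissing,
             samples = v$row@samples))
    }
    expect_equal(rows(igd2), rows(igd1))
    # phased files export with "|", unphased with "/"
    body <- grep("^[^#]", readLines(vcf2), value = TRUE)
    if (phased) {
      expect_true(all(grepl("|", body, fixed = TRUE)))
      expect_false(any(grepl("/", body, fixed = TRUE)))
    } else {
      expect_false(any(grepl("|", body, fixed = TRUE)))
    }
  }
})

test_that("an empty IGD exports to a header-only VCF", {
  p <- tmpPath(".igd")
  w <- createIgdWriter(p, numIndividuals = 2, ploidy = 2)
  finalizeIgd(w, individualIds = c("a", "b"))
  vcf <- tmpPath(".vcf")
  igdToVcf(p, vcf)
  lines <- readLines(vcf)
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[length(lines)], "^#CHROM.*\ta\tb$")
})

test_that("gzip-compressed VCF input converts identically to plain", {
  ds <- simulateGenotypes(10, numSites = 15, ploidy = 2, seed = 61,
                          missingRate = 0.05)
  plain <- tmpPath(".vcf")
  gz <- tmpPath(".vcf.gz")
  writeVcfFixture(ds, plain)
  writeVcfFixture(ds, gz)
  o1 <- tmpPath(".igd"); o2 <- tmpPath(".igd")
  vcfToIgd(plain, o1)
  vcfToIgd(gz, o2)
  # identical except for the embedded source-file name: compare contents
  expect_equal(igdSiteGenotypes(o2), igdSiteGenotypes(o1))
})

test_that("malformed or unsupported VCF input fails with clear errors", {
  s2 <- c("sA", "sB")
  mixed <- writeVcfText(c("1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0|0",
                          "1\t20\t.\tG\tT\t.\t.\t.\tGT\t1/1\t0/1"),
                        tmpPath(".vcf"), samples = s2)
  expect_error(vcfToIgd(mixed, tmpPath(".igd")), "mixed phasedness")

  ragged <- writeVcfText("1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0|0|1",
                         tmpPath(".vcf"), samples = s2)
  expect_error(vcfToIgd(ragged, tmpPath(".igd")), "ploidy")

  nogt <- writeVcfText("1\t10\t.\tA\tC\t.\t.\t.\tDP\t10\t12",
                       tmpPath(".vcf"), samples = s2)
  expect_error(vcfToIgd(nogt, tmpPath(".igd")), "GT")

  multichrom <- writeVcfText(c("1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0|0",
                               "2\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0|0"),
                             tmpPath(".vcf"), samples = s2)
  expect_error(vcfToIgd(multichrom, tmpPath(".igd")), "chromosome")
})

test_that("split = TRUE writes one IGD per chromosome", {
  vcf <- writeVcfText(c("1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0|0",
                        "2\t15\t.\tA\tG\t.\t.\t.\tGT\t1|1\t0|0"),
                      tmpPath(".vcf"), samples = c("sA", "sB"))
  base <- file.path(withr::local_tempdir(), "out.igd")
  rep <- vcfToIgd(vcf, base, split = TRUE)
  expect_setequal(names(rep$files), c("1", "2"))
  for (f in rep$files) {
    igd <- openIgd(f, strict = TRUE)
    expect_equal(igdHeader(igd)@numRows, 1)
    closeIgd(igd)
  }
})

test_that("GT is extracted from multi-field FORMAT columns", {
  vcf <- writeVcfText("1\t10\t.\tA\tC\t.\t.\t.\tDP:GT\t7:0|1\t9:1|1",
                      tmpPath(".vcf"), samples = c("sA", "sB"))
  out <- tmpPath(".igd")
  vcfToIgd(vcf, out)
  igd <- openIgd(out)
  expect_equal(getVariant(igd, 0)$row@samples, c(1, 2, 3))
  closeIgd(igd)
})

test_that("haploid data uses the explicit phasedness override", {
  vcf <- writeVcfText("1\t10\t.\tA\tC\t.\t.\t.\tGT\t1\t0\t1",
                      tmpPath(".vcf"), samples = c("a", "b", "c"))
  o1 <- tmpPath(".igd"); o2 <- tmpPath(".igd")
  vcfToIgd(vcf, o1)                      # defaults to phased
  vcfToIgd(vcf, o2, phased = FALSE)
  h1 <- openIgd(o1); h2 <- openIgd(o2)
  expect_true(isPhased(igdHeader(h1)))
  expect_false(isPhased(igdHeader(h2)))
  expect_equal(igdHeader(h1)@ploidy, 1)
  e <- igdio:::.igdEntry(h2, 0)
  expect_equal(e$numCopies, 1)           # unphased rows carry copy counts
  closeIgd(h1); closeIgd(h2)
})
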