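# Shared helpers: independent oracles and canonical genotype views used to
# compare IGD contents against ground truth without going through the
# package's own decoding logic more than once.

tmpPath <- function(ext) withr::local_tempfile(fileext = ext,
                                               .local_envir = parent.frame())

# Independent little-endian byte oracle: digit arithmetic only.
leBytesOracle <- function(value, nbytes) {
  out <- integer(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- value %% 256
    value <- value %/% 256
  }
  as.raw(out)
}

# Independent hex-word oracle: "0x0100000000000064" -> 8 raw bytes, LE.
hexWordBytes <- function(hex) {
  hex <- sub("^0x", "", hex)
  pairs <- substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2))
  rev(as.raw(strtoi(pairs, 16L)))
}

# Canonical per-individual genotype strings for one site, from allele
# letters. Phased genotypes keep slot order; unphased are sorted so the
# comparison ignores entry order.
canonGt <- function(letters, ploidy, phased) {
  m <- matrix(letters, nrow = ploidy)
  apply(m, 2, function(g) {
    if (!phased) g <- sort(g)
    paste(g, collapse = "/")
  })
}

# Ground truth: named list position -> canonical genotype vector.
truthSiteGenotypes <- function(ds) {
  ploidy <- ds@ploidy
  out <- list()
  for (s in seq_along(ds@sites)) {
    site <- ds@sites[[s]]
    a <- siteAlleleVector(ds, s)
    letters <- c(site$ref, site$alts)[a + 1]
    letters[is.na(a)] <- "."
    out[[as.character(site$pos)]] <- canonGt(letters, ploidy, ds@phased)
  }
  out
}

# Same view decoded from an IGD file (grouping rows by position).
igdSiteGenotypes <- function(path) {
  igd <- openIgd(path, strict = TRUE)
  on.exit(closeIgd(igd))
  h <- igdHeader(igd)
  ploidy <- h@ploidy
  N <- h@numIndividuals
  phased <- isPhased(h)
  out <- list()
  positions <- unique(unlist(igdVariants(igd, FUN = function(m, r)
    m@position)))
  for (pos in positions) {
    site <- aggregateSite(igd, pos)
    if (phased) {
      a <- integer(N * ploidy)
      alts <- character(0)
      for (al in site$alts) {
        alts <- c(alts, al$alt)
        a[al$samples + 1] <- length(alts)
      }
      letters <- c(site$ref, alts)[a + 1]
      letters[site$missing + 1] <- "."
    } else {
      letters <- matrix(site$ref, nrow = ploidy, ncol = N)
      fill <- rep(1L, N)           # next slot to fill, per individual
      for (al in site$alts) {
        for (ind in al$samples) {
          sl <- fill[ind + 1]
          letters[sl:(sl + al$numCopies - 1), ind + 1] <- al$alt
          fill[ind + 1] <- sl + al$numCopies
        }
      }
      letters[, site$missing + 1] <- "."
      letters <- as.vector(letters)
    }
    out[[as.character(pos)]] <- canonGt(letters, ploidy, phased)
  }
  out
}

# Frequency oracle computed directly from the dataset truth, mirroring one
# record per stored variant row: phased sites give one row per alt;
# unphased sites one row per (alt, exact copy count) with individuals
# having any missing call excluded from the counts.
truthFreqRows <- function(ds, excludeMissing = FALSE) {
  N <- ds@numIndividuals
  ploidy <- ds@ploidy
  NH <- N * ploidy
  recs <- list()
  for (site in ds@sites) {
    nMissSamples <- length(site$missing)
    nMissInd <- length(unique(site$missing %/% ploidy))
    for (j in seq_along(site$alts)) {
      if (ds@phased) {
        denom <- if (excludeMissing) NH - nMissSamples else NH
        recs[[length(recs) + 1]] <- data.frame(
          position = site$pos, alt = site$alts[j], num_copies = 0,
          carrier_count = length(site$carriers[[j]]),
          frequency = length(site$carriers[[j]]) / denom)
      } else {
        ind <- site$carriers[[j]] %/% ploidy
        cnt <- tabulate(tabulate(ind + 1, nbins = N), nbins = ploidy)
        denom <- (if (excludeMissing) N - nMissInd else N) * ploidy
        for (cc in which(cnt > 0)) {
          recs[[length(recs) + 1]] <- data.frame(
            position = site$pos, alt = site$alts[j], num_copies = cc,
            carrier_count = cnt[cc], frequency = cc * cnt[cc] / denom)
        }
      }
    }
  }
  do.call(rbind, recs)
}

# Frequency oracle from a VCF file via vcfR (an independent VCF parser),
# aggregated per (position, alt): total alt copies over called alleles.
vcfrSiteFreqs <- function(vcfPath) {
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.numeric(vcfR::getPOS(v))
  alts <- vcfR::getALT(v)
  recs <- list()
  for (s in seq_len(nrow(gt))) {
    alleles <- unlist(strsplit(gt[s, ], "[|/]"))   # vcfR NAs fully-missing GTs
    called <- alleles[!is.na(alleles) & alleles != "."]
    aset <- strsplit(alts[s], ",", fixed = TRUE)[[1]]
    for (j in seq_along(aset)) {
      recs[[length(recs) + 1]] <- data.frame(
        position = pos[s], alt = aset[j],
        count = sum(called == as.character(j)),
        denom = length(alleles))
    }
  }
  do.call(rbind, recs)
}

# Reconstruct the phased NH x M allele-index matrix from an IGD file,
# using the dataset's site order and alt letter order for the columns.
igdPhasedMatrix <- function(path, ds) {
  igd <- openIgd(path, strict = TRUE)
  on.exit(closeIgd(igd))
  NH <- ds@numIndividuals * ds@ploidy
  pos <- vapply(ds@sites, `[[`, numeric(1), "pos")
  M <- matrix(0L, NH, length(pos))
  for (v in igdVariants(igd)) {
    s <- which(pos == v$meta@position)
    if (v$row@isMissing) {
      M[rowSamples(v$row) + 1, s] <- NA
    } else {
      M[rowSamples(v$row) + 1, s] <- match(v$meta@alt, ds@sites[[s]]$alts)
    }
  }
  M
}
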