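# Seeded synthetic genotype datasets with known truth. The generator is a
# statistical stand-in for population-genetic simulation: per-site carrier
# counts are drawn from a discretized 1/x^alpha site-frequency spectrum
# (alpha = 1 approximates the neutral spectrum, rich in rare variants) and
# carriers are placed uniformly at random, so no linkage structure is
# produced -- IGD stores rows independently and never exploits LD, so none
# is needed for correctness testing.

#' SyntheticDataset: a simulated genotype dataset with known truth
#'
#' Produced by [simulateGenotypes()]. Each site is a list with elements
#' `pos`, `ref`, `alts` (1 or 2 alternate alleles), `carriers` (a list,
#' per alt, of 0-based haploid-sample indexes carrying it) and `missing`
#' (0-based haploid-sample indexes with no call; for unphased datasets
#' these always cover whole individuals).
#'
#' @slot numIndividuals N.
#' @slot ploidy haploid genomes per individual.
#' @slot phased phasedness of the dataset.
#' @slot sites list of site records, positions strictly increasing.
#' @slot params the generator parameters, including the seed.
#' @export
setClass("SyntheticDataset", representation(
  numIndividuals = "numeric", ploidy = "numeric", phased = "logical",
  sites = "list", params = "list"))

setValidity("SyntheticDataset", function(object) {
  pos <- vapply(object@sites, `[[`, numeric(1), "pos")
  if (length(pos) > 1 && any(diff(pos) <= 0))
    return("site positions must be strictly increasing")
  TRUE
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@sites), "sites, N =",
      object@numIndividuals, ", ploidy", object@ploidy, ",",
      if (object@phased) "phased" else "unphased", "\n")
  q <- sum(vapply(object@sites, function(s) length(s$missing) > 0,
                  logical(1)))
  cat("  sites with missing calls (Q):", q, "\n")
})

#' Simulate a genotype dataset
#'
#' Draws, for each site, a carrier count from the discrete spectrum
#' `P(count = x) proportional to x^(-sfsAlpha)` over `x in 1..NH-1`, places
#' the carriers uniformly without replacement among the NH haploid samples,
#' optionally splits a site's carriers between two alternate alleles (a
#' multi-allelic site), and assigns missing calls per haploid sample
#' (phased) or per individual (unphased) at `missingRate`. Missing samples
#' are removed from carrier sets (a sample cannot both carry an allele and
#' lack a call). Positions are drawn as sorted distinct integers in
#' `[1, 10 * numSites]`. Fully reproducible from `seed`; the global RNG
#' state is restored afterwards.
#'
#' @param numIndividuals N (NH = N * ploidy must be at least 2).
#' @param numSites number of polymorphic sites.
#' @param ploidy haploid genomes per individual.
#' @param phased phasedness.
#' @param missingRate per-haploid-sample (phased) or per-individual
#'   (unphased) missing-call probability, in `[0, 1]`.
#' @param multiallelicFraction fraction of sites carrying two alternate
#'   alleles (only sites with >= 2 carriers can split), in `[0, 1]`.
#' @param sfsAlpha exponent of the site-frequency spectrum.
#' @param seed RNG seed.
#' @return a [SyntheticDataset-class].
#' @export
simulateGenotypes <- function(numIndividuals, numSites = 1000, ploidy = 2,
                              phased = TRUE, missingRate = 0,
                              multiallelicFraction = 0, sfsAlpha = 1,
                              seed = 1) {
  NH <- numIndividuals * ploidy
  if (NH < 2) stop("need at least 2 haploid samples", call. = FALSE)
  if (missingRate < 0 || missingRate > 1 ||
      multiallelicFraction < 0 || multiallelicFraction > 1)
    stop("rates must be in [0, 1]", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(10 * numSites, numSites))
  counts <- sample.int(NH - 1, numSites, replace = TRUE,
                       prob = (seq_len(NH - 1))^(-sfsAlpha))
  multi <- runif(numSites) < multiallelicFraction & counts >= 2

  sites <- vector("list", numSites)
  for (s in seq_len(numSites)) {
    carriers <- sample.int(NH, counts[s]) - 1      # random order
    ref <- sample(bases, 1)
    if (multi[s]) {
      alts <- sample(setdiff(bases, ref), 2)
      cut <- sample.int(counts[s] - 1, 1)
      carr <- list(sort(carriers[seq_len(cut)]),
                   sort(carriers[-seq_len(cut)]))
    } else {
      alts <- sample(setdiff(bases, ref), 1)
      carr <- list(sort(carriers))
    }
    if (missingRate > 0) {
      if (phased) {
        miss <- which(runif(NH) < missingRate) - 1
      } else {
        mi <- which(runif(numIndividuals) < missingRate) - 1
        miss <- rep(mi * ploidy, each = ploidy) + seq_len(ploidy) - 1
      }
      carr <- lapply(carr, setdiff, miss)
    } else miss <- numeric(0)
    sites[[s]] <- list(pos = pos[s], ref = ref, alts = alts,
                       carriers = carr, missing = miss)
  }
  new("SyntheticDataset", numIndividuals = as.numeric(numIndividuals),
      ploidy = as.numeric(ploidy), phased = phased, sites = sites,
      params = list(seed = seed, numSites = numSites,
                    missingRate = missingRate,
                    multiallelicFraction = multiallelicFraction,
                    sfsAlpha = sfsAlpha))
}

#' Ground-truth views of a synthetic dataset
#'
#' `siteAlleleVector()` returns site `s` as a length-NH integer vector of
#' allele indexes (0 = ref, 1.. = alts, NA = missing), ordered so that
#' haplotype slot j of individual n sits at haploid index `n * ploidy + j`.
#' `datasetGenotypeMatrix()` stacks these as an NH x numSites matrix.
#' `trueFrequencies()` tabulates, per variant, the carrier count and the
#' allele frequency `count / NH`.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param s 1-based site number.
#' @return see above; `trueFrequencies()` returns a data.frame with
#'   columns `site`, `pos`, `ref`, `alt`, `count`, `freq`.
#' @export
siteAlleleVector <- function(dataset, s) {
  NH <- dataset@numIndividuals * dataset@ploidy
  site <- dataset@sites[[s]]
  a <- integer(NH)
  for (j in seq_along(site$carriers)) a[site$carriers[[j]] + 1] <- j
  a[site$missing + 1] <- NA
  a
}

#' @rdname siteAlleleVector
#' @export
datasetGenotypeMatrix <- function(dataset) {
  vapply(seq_along(dataset@sites), function(s) siteAlleleVector(dataset, s),
         integer(dataset@numIndividuals * dataset@ploidy))
}

#' @rdname siteAlleleVector
#' @export
trueFrequencies <- function(dataset) {
  NH <- dataset@numIndividuals * dataset@ploidy
  recs <- lapply(seq_along(dataset@sites), function(s) {
    site <- dataset@sites[[s]]
    data.frame(site = s, pos = site$pos, ref = site$ref, alt = site$alts,
               count = lengths(site$carriers),
               freq = lengths(site$carriers) / NH)
  })
  do.call(rbind, recs)
}

#' Write a synthetic dataset as a VCF fixture
#'
#' Emits a syntactically valid VCF 4.2 with a GT-only FORMAT, sample names
#' `s0..s(N-1)`, `|` or `/` genotype separators per phasedness, and `.` for
#' missing alleles.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param path output path; gzip-compressed if it ends in `.gz` or if
#'   `gzip = TRUE`.
#' @param gzip force gzip output.
#' @param chrom chromosome name for the CHROM column.
#' @return `path`, invisibly.
#' @export
writeVcfFixture <- function(dataset, path, gzip = grepl("\\.gz$", path),
                            chrom = "1") {
  N <- dataset@numIndividuals
  ploidy <- dataset@ploidy
  sep <- if (dataset@phased) "|" else "/"
  con <- if (gzip) gzfile(path, open = "w") else file(path, open = "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=igdio simulateGenotypes",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("s", seq_len(N) - 1)),
                     collapse = "\t")), con)
  idx <- seq_along(dataset@sites)
  for (block in split(idx, ceiling(idx / 512))) {
    lines <- vapply(block, function(s) {
      site <- dataset@sites[[s]]
      a <- siteAlleleVector(dataset, s)
      ch <- as.character(a)
      ch[is.na(a)] <- "."
      gt <- if (ploidy == 1) ch
            else do.call(paste, c(lapply(seq_len(ploidy), function(r)
              ch[seq(r, length(ch), by = ploidy)]), list(sep = sep)))
      paste(chrom, site$pos, ".", site$ref,
            paste(site$alts, collapse = ","), ".", ".", ".", "GT",
            paste(gt, collapse = "\t"), sep = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a synthetic dataset directly as an IGD file
#'
#' Expands each site into its IGD rows (per-alt carrier rows, then one
#' missing-data row when the site has missing calls) straight from the
#' dataset's truth, without going through VCF text.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param path output IGD path.
#' @param forceRepresentation,sparsityDivisor passed to
#'   [createIgdWriter()].
#' @return invisibly, the [finalizeIgd()] summary.
#' @export
datasetToIgd <- function(dataset, path, forceRepresentation = "auto",
                         sparsityDivisor = 32) {
  N <- dataset@numIndividuals
  ploidy <- dataset@ploidy
  w <- createIgdWriter(path, numIndividuals = N, ploidy = ploidy,
                       phased = dataset@phased,
                       sparsityDivisor = sparsityDivisor,
                       source = "igdio simulateGenotypes",
                       forceRepresentation = forceRepresentation)
  for (site in dataset@sites) {
    if (dataset@phased) {
      for (j in seq_along(site$alts))
        writeVariantRow(w, site$pos, site$ref, site$alts[j],
                        site$carriers[[j]])
      if (length(site$missing))
        writeVariantRow(w, site$pos, site$ref, "", site$missing,
                        isMissing = TRUE)
    } else {
      for (j in seq_along(site$alts)) {
        ind <- site$carriers[[j]] %/% ploidy
        cnt <- table(ind)
        for (cc in seq_len(ploidy)) {
          sel <- as.numeric(names(cnt)[cnt == cc])
          if (length(sel))
            writeVariantRow(w, site$pos, site$ref, site$alts[j], sel,
                            numCopies = cc)
        }
      }
      if (length(site$missing))
        writeVariantRow(w, site$pos, site$ref, "",
                        unique(site$missing %/% ploidy), isMissing = TRUE)
    }
  }
  invisible(finalizeIgd(w, individualIds = paste0("s", seq_len(N) - 1)))
}
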