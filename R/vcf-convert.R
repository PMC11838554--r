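# VCF <-> IGD conversion. The VCF side consumes only CHROM, POS, ID, REF,
# ALT and the GT FORMAT field; QUAL/FILTER/INFO and all other FORMAT data
# are dropped (genotype metadata belongs in general-purpose formats). The
# converter is single-pass and never holds more than one site's genotypes
# in memory.

#' Expand one site into IGD genotype rows
#'
#' A site with k alternate alleles becomes k variant rows sharing its
#' position and reference allele, plus at most one missing-data row
#' (emitted last) when any call at the site is missing.
#'
#' For phased data, each alt's row lists the haploid samples carrying it,
#' numbering haplotype slot j of individual n as `n * ploidy + j`; the
#' missing row lists haploid samples without a call. For unphased data,
#' each (alt, copy-count c) combination with at least one individual
#' carrying exactly c copies of that alt becomes a row (numCopies = c)
#' listing those individuals; an individual with any missing allele goes
#' into the missing row only and is excluded from every copy-count row
#' (copy counts are undefined when one allele is unknown).
#'
#' @param position base-pair position.
#' @param ref reference allele string.
#' @param alts character vector of k alternate alleles.
#' @param geno integer matrix `ploidy x N` of allele indexes (0 = ref,
#'   1..k = alts, NA = missing call); column n is individual n.
#' @param phased whether the genotypes are phased.
#' @return a list of row descriptors
#'   `list(position=, ref=, alt=, samples=, numCopies=, isMissing=)`,
#'   alts in input order, missing row last.
#' @export
expandSite <- function(position, ref, alts, geno, phased) {
  stopifnot(is.matrix(geno))
  k <- length(alts)
  if (k < 1) stop("a site must have at least one alternate allele",
                  call. = FALSE)
  if (any(geno > k, na.rm = TRUE))
    stop("allele index exceeds the number of alternate alleles",
         call. = FALSE)
  ploidy <- nrow(geno)
  rows <- list()
  if (phased) {
    a <- as.vector(geno)            # haploid index = n * ploidy + j
    for (j in seq_len(k)) {
      rows[[length(rows) + 1]] <- list(
        position = position, ref = ref, alt = alts[j],
        samples = which(a == j) - 1, numCopies = 0, isMissing = FALSE)
    }
    miss <- which(is.na(a)) - 1
    if (length(miss))
      rows[[length(rows) + 1]] <- list(
        position = position, ref = ref, alt = "",
        samples = miss, numCopies = 0, isMissing = TRUE)
  } else {
    anyMiss <- colSums(is.na(geno)) > 0
    for (j in seq_len(k)) {
      cnt <- colSums(geno == j, na.rm = TRUE)
      cnt[anyMiss] <- 0
      for (cc in seq_len(ploidy)) {
        inds <- which(cnt == cc) - 1
        if (length(inds))
          rows[[length(rows) + 1]] <- list(
            position = position, ref = ref, alt = alts[j],
            samples = inds, numCopies = cc, isMissing = FALSE)
      }
    }
    if (any(anyMiss))
      rows[[length(rows) + 1]] <- list(
        position = position, ref = ref, alt = "",
        samples = which(anyMiss) - 1, numCopies = 0, isMissing = TRUE)
  }
  rows
}

# Parse the genotype columns of one VCF record into a ploidy x N integer
# matrix (NA = missing). Returns list(geno=, phased=) where phased is NA
# when no separator is present (haploid calls).
.parseGts <- function(gts, ploidy, lineNo) {
  if (ploidy == 1) {
    al <- suppressWarnings(as.integer(gts))
    return(list(geno = matrix(al, nrow = 1), phased = NA))
  }
  n1 <- 2L * ploidy - 1L
  if (all(nchar(gts) == n1)) {        # single-character alleles, fixed layout
    seps <- substr(gts, 2, 2)
    m <- matrix(NA_integer_, nrow = ploidy, ncol = length(gts))
    for (j in seq_len(ploidy))
      m[j, ] <- suppressWarnings(as.integer(substr(gts, 2L * j - 1L,
                                                   2L * j - 1L)))
    phased <- if (seps[1] == "|") TRUE else if (seps[1] == "/") FALSE else NA
    if (is.na(phased))
      stop("malformed GT field on data line ", lineNo, call. = FALSE)
    other <- if (phased) "/" else "|"
    if (any(grepl(other, gts, fixed = TRUE)))
      stop("mixed phasedness on data line ", lineNo,
           ": all records must be consistently phased or unphased",
           call. = FALSE)
    return(list(geno = m, phased = phased))
  }
  sp <- strsplit(gts, "[|/]")
  len <- lengths(sp)
  if (any(len != ploidy))
    stop("ragged ploidy on data line ", lineNo, ": expected ", ploidy,
         " alleles per genotype", call. = FALSE)
  phased <- if (grepl("|", gts[1], fixed = TRUE)) TRUE else FALSE
  other <- if (phased) "/" else "|"
  if (any(grepl(other, gts, fixed = TRUE)))
    stop("mixed phasedness on data line ", lineNo, call. = FALSE)
  al <- suppressWarnings(as.integer(unlist(sp)))
  list(geno = matrix(al, nrow = ploidy), phased = phased)
}

#' Convert a VCF file to IGD
#'
#' Streams a VCF 4.x file (plain or gzip-compressed) into one IGD file,
#' expanding multi-allelic sites into one row per alternate allele and
#' emitting one missing-data row per site that has any missing call.
#' Positions are copied verbatim (1-based, as in VCF). Individual IDs are
#' taken from the header sample names; variant IDs from the ID column when
#' `storeVariantIds = TRUE`. Ploidy and phasedness are detected from the
#' first record's GT field and must be uniform throughout the file.
#'
#' IGD has no chromosome field, so multi-chromosome input is an error
#' unless `split = TRUE`, which writes one file per chromosome named
#' `sub(".igd$", ".<chrom>.igd", igdPath)`.
#'
#' @param vcfPath input VCF path (`.vcf` or `.vcf.gz`).
#' @param igdPath output IGD path.
#' @param phased override for phasedness when it cannot be detected (ploidy
#'   1 has no genotype separator; default phased). Ignored, with an error
#'   on conflict, when the GT separators disagree with it.
#' @param storeVariantIds store the VCF ID column as the variant-ID table
#'   (every expanded row of a site, including its missing row, carries the
#'   site's ID).
#' @param split write one IGD per chromosome instead of erroring on
#'   multi-chromosome input.
#' @param forceRepresentation,sparsityDivisor passed to
#'   [createIgdWriter()].
#' @param description free-text description stored in the file.
#' @return invisibly, a report list: `files` (named per-chromosome output
#'   paths), `sites`, `skippedMonomorphic`, and per-file writer summaries
#'   (`numRows`, `sparseRows`, `denseRows`, `missingRows`, `bytes`).
#' @export
vcfToIgd <- function(vcfPath, igdPath, phased = NULL,
                     storeVariantIds = FALSE, split = FALSE,
                     forceRepresentation = "auto", sparsityDivisor = 32,
                     description = "") {
  con <- if (grepl("\\.gz$", vcfPath)) gzfile(vcfPath, open = "r")
         else file(vcfPath, open = "r")
  on.exit(close(con), add = TRUE)

  sampleNames <- NULL
  writers <- list()
  on.exit({  # close any writer left open by an error mid-conversion
    for (wr in writers)
      if (!wr@state$finalized) try(close(wr@state$con), silent = TRUE)
  }, add = TRUE)
  summaries <- list()
  curChrom <- NULL
  ploidy <- NULL
  filePhased <- NULL
  nSites <- 0L
  nMono <- 0L
  lineNo <- 0L

  mkWriter <- function(chrom) {
    path <- if (split) sub("\\.igd$", paste0(".", chrom, ".igd"), igdPath)
            else igdPath
    createIgdWriter(path, numIndividuals = length(sampleNames),
                    ploidy = ploidy, phased = filePhased,
                    sparsityDivisor = sparsityDivisor,
                    source = paste0("converted from ", basename(vcfPath)),
                    description = description,
                    forceRepresentation = forceRepresentation)
  }

  repeat {
    lines <- readLines(con, n = 512L)
    if (!length(lines)) break
    for (line in lines) {
      lineNo <- lineNo + 1L
      if (startsWith(line, "##")) next
      if (startsWith(line, "#CHROM")) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1]]
        if (length(f) < 10)
          stop("VCF has no sample columns", call. = FALSE)
        if (toupper(f[9]) != "FORMAT")
          stop("VCF #CHROM line lacks a FORMAT column", call. = FALSE)
        sampleNames <- f[-(1:9)]
        next
      }
      if (!nzchar(line)) next
      if (is.null(sampleNames))
        stop("VCF data before #CHROM header line", call. = FALSE)
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) != 9 + length(sampleNames))
        stop("malformed VCF data line ", lineNo, call. = FALSE)
      chrom <- f[1]
      pos <- as.numeric(f[2])
      if (is.na(pos) || pos >= 2^48)
        stop("bad or out-of-range POS on data line ", lineNo, call. = FALSE)
      altStr <- f[5]
      alts <- if (altStr == "." || altStr == "") character(0)
              else strsplit(altStr, ",", fixed = TRUE)[[1]]
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gi <- which(fmt == "GT")
      if (!length(gi))
        stop("record without GT in FORMAT on data line ", lineNo,
             call. = FALSE)
      gts <- f[-(1:9)]
      if (length(fmt) > 1)
        gts <- vapply(strsplit(gts, ":", fixed = TRUE), `[[`, "", gi[1])

      if (is.null(ploidy)) {
        ploidy <- length(strsplit(gts[1], "[|/]")[[1]])
        if (ploidy < 1 || ploidy > IGD_MAX_PLOIDY)
          stop("unsupported ploidy ", ploidy, call. = FALSE)
      }
      pg <- .parseGts(gts, ploidy, lineNo)
      recPhased <- pg$phased
      if (is.null(filePhased)) {
        if (!is.na(recPhased) && !is.null(phased) && phased != recPhased)
          stop("phased = ", phased, " conflicts with the GT separators ",
               "in the VCF", call. = FALSE)
        filePhased <- if (!is.na(recPhased)) recPhased
                      else if (!is.null(phased)) phased else TRUE
      } else if (!is.na(recPhased) && recPhased != filePhased) {
        stop("mixed phasedness at ", chrom, ":", pos,
             ": all records must be consistently phased or unphased",
             call. = FALSE)
      }

      if (is.null(curChrom) || chrom != curChrom) {
        if (!is.null(curChrom) && !split)
          stop("multiple chromosomes in input (", curChrom, ", ", chrom,
               "); IGD stores one chromosome per file -- use split = TRUE",
               call. = FALSE)
        if (is.null(writers[[chrom]])) writers[[chrom]] <- mkWriter(chrom)
        curChrom <- chrom
      }
      w <- writers[[chrom]]
      vid <- if (storeVariantIds) (if (f[3] == ".") "" else f[3]) else NULL
      if (length(alts) == 0) {
        # no alternate allele: keep the site's missing-data row (if any) so
        # Q survives a round trip; otherwise the record is monomorphic
        miss <- if (filePhased) which(is.na(as.vector(pg$geno))) - 1
                else which(colSums(is.na(pg$geno)) > 0) - 1
        if (length(miss)) {
          writeVariantRow(w, pos, f[4], "", miss, isMissing = TRUE,
                          variantId = vid)
          nSites <- nSites + 1L
        } else nMono <- nMono + 1L
        next
      }
      for (r in expandSite(pos, f[4], alts, pg$geno, filePhased))
        writeVariantRow(w, r$position, r$ref, r$alt, r$samples,
                        numCopies = r$numCopies, isMissing = r$isMissing,
                        variantId = vid)
      nSites <- nSites + 1L
    }
  }

  if (is.null(sampleNames))
    stop("no #CHROM header line found: not a VCF?", call. = FALSE)
  files <- character(0)
  if (!length(writers)) {             # zero data lines: emit a valid empty IGD
    ploidy <- if (is.null(ploidy)) 2 else ploidy
    filePhased <- if (is.null(filePhased))
      (if (is.null(phased)) TRUE else phased) else filePhased
    writers[["(empty)"]] <- mkWriter("(empty)")
    if (!split) names(writers) <- "(empty)"
  }
  for (chrom in names(writers)) {
    summaries[[chrom]] <- finalizeIgd(writers[[chrom]],
                                      individualIds = sampleNames)
    files[chrom] <- writers[[chrom]]@path
  }
  invisible(list(files = files, sites = nSites,
                 skippedMonomorphic = nMono, summaries = summaries))
}

#' Export an IGD file to a minimal VCF
#'
#' Re-aggregates rows by position (consecutive runs of equal positions form
#' one site), reconstructs GT fields, and writes a minimal VCF 4.2 with a
#' GT-only FORMAT. Phased files use `|` separators, unphased `/`; samples
#' listed in a site's missing-data row export as missing (`.`) calls. For
#' unphased data the allele order within a genotype is not stored, so
#' genotypes are emitted with alt copies first (e.g. `1/0`); the genotype
#' multiset is exact.
#'
#' @param igdPath input IGD path.
#' @param vcfPath output VCF path (gzip-compressed if it ends in `.gz`).
#' @param chrom chromosome name for the CHROM column (IGD stores none).
#' @return invisibly, `list(sites=, rows=, path=)`.
#' @export
igdToVcf <- function(igdPath, vcfPath, chrom = "1") {
  igd <- openIgd(igdPath)
  on.exit(closeIgd(igd), add = TRUE)
  h <- igd@header
  N <- h@numIndividuals
  ploidy <- h@ploidy
  phased <- isPhased(h)
  sep <- if (phased) "|" else "/"
  ids <- individualIds(igd)
  if (is.null(ids)) ids <- paste0("s", seq_len(N) - 1)

  out <- if (grepl("\\.gz$", vcfPath)) gzfile(vcfPath, open = "w")
         else file(vcfPath, open = "w")
  on.exit(close(out), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=igdio export of ", basename(igdPath)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), out)

  idx <- .igdIndex(igd)
  alleles <- igdAlleles(igd)
  vids <- variantIds(igd)
  n <- h@numRows
  nSites <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && idx$position[j + 1] == idx$position[i]) j <- j + 1L
    rows <- i:j
    refs <- alleles$ref[rows]
    missRow <- rows[bitwAnd(idx$flags[rows], IGD_MISSING) != 0]
    altRows <- setdiff(rows, missRow)
    ref <- if (length(altRows)) refs[match(altRows[1], rows)] else refs[1]
    siteAlts <- unique(alleles$alt[altRows])
    vid <- if (!is.null(vids) && nzchar(vids[rows[1]])) vids[rows[1]] else "."

    readRow <- function(r) .igdReadRowAt(igd, list(
      position = idx$position[r], numCopies = idx$numCopies[r],
      flags = idx$flags[r], genotypeOffset = idx$genotypeOffset[r]))

    if (phased) {
      a <- integer(N * ploidy)
      for (r in altRows) {
        s <- rowSamples(readRow(r))
        a[s + 1] <- match(alleles$alt[r], siteAlts)
      }
      for (r in missRow) a[rowSamples(readRow(r)) + 1] <- NA
      ch <- as.character(a)
      ch[is.na(a)] <- "."
      cm <- matrix(ch, nrow = ploidy)
    } else {
      cnt <- matrix(0L, nrow = max(1L, length(siteAlts)), ncol = N)
      for (r in altRows) {
        s <- rowSamples(readRow(r))
        ai <- match(alleles$alt[r], siteAlts)
        cnt[ai, s + 1] <- cnt[ai, s + 1] + idx$numCopies[r]
      }
      missInd <- if (length(missRow)) rowSamples(readRow(missRow[1])) + 1
                 else integer(0)
      tot <- colSums(cnt)
      if (any(tot > ploidy))
        stop("corrupt input: individual assigned more than ploidy copies at ",
             "position ", idx$position[i], call. = FALSE)
      cm <- matrix("0", nrow = ploidy, ncol = N)
      for (nn in which(tot > 0)) {
        gt <- rep(0L, ploidy)
        p <- 1L
        for (ai in which(cnt[, nn] > 0)) {
          gt[p:(p + cnt[ai, nn] - 1L)] <- ai
          p <- p + cnt[ai, nn]
        }
        cm[, nn] <- as.character(gt)
      }
      cm[, missInd] <- "."
    }
    gt <- do.call(paste, c(lapply(seq_len(ploidy), function(r) cm[r, ]),
                           list(sep = sep)))
    writeLines(paste(chrom, format(idx$position[i], scientific = FALSE),
                     vid, ref,
                     if (length(siteAlts)) paste(siteAlts, collapse = ",")
                     else ".",
                     ".", ".", ".", "GT",
                     paste(gt, collapse = "\t"), sep = "\t"), out)
    nSites <- nSites + 1L
    i <- j + 1L
  }
  invisible(list(sites = nSites, rows = n, path = vcfPath))
}
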