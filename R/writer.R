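# One-pass streaming IGD writer. Genotype rows go to disk as they arrive;
# only the 16-byte index entries and the allele/ID strings are buffered.
# The header is written up front with zeroed section offsets and patched in
# place at finalization (one backward seek), so a single output file is
# produced in one pass over the input.

#' IGDWriter: a streaming handle for constructing an IGD file
#'
#' Created by [createIgdWriter()]; fed with [writeVariantRow()]; completed
#' by [finalizeIgd()]. The handle's mutable state (connection, buffered
#' index columns, allele strings, counters) lives in an environment slot,
#' so the object can be passed by value as usual in R.
#'
#' @slot path output file path.
#' @slot state internal environment.
#' @export
setClass("IGDWriter", representation(path = "character", state = "environment"))

setMethod("show", "IGDWriter", function(object) {
  st <- object@state
  cat("IGDWriter:", object@path, "\n  rows so far:", st$n,
      if (st$finalized) "(finalized)" else "(open)", "\n")
})

#' Create a streaming IGD writer
#'
#' Writes the 128-byte header (with placeholder offsets) and the two
#' description strings immediately; the genotype-data region starts right
#' after, at `128 + 4 + nchar(source) + 4 + nchar(description)` bytes.
#'
#' @param path output file path.
#' @param numIndividuals number of individuals N (>= 1).
#' @param ploidy haploid genomes per individual, 1..255.
#' @param phased whether rows store haploid-sample lists (TRUE) or
#'   individual lists with per-row copy counts (FALSE).
#' @param sparsityDivisor divisor d of the representation rule: rows with
#'   `carriers * d < width` are stored sparsely. Recorded in the header.
#' @param source free-text provenance string (e.g. "converted from x.vcf").
#' @param description free-text description string.
#' @param forceRepresentation `"auto"` picks per row by the sparsity rule;
#'   `"sparse"`/`"dense"` force one representation for every row (both are
#'   valid IGD).
#' @return an [IGDWriter-class].
#' @export
createIgdWriter <- function(path, numIndividuals, ploidy = 2, phased = TRUE,
                            sparsityDivisor = 32, source = "",
                            description = "",
                            forceRepresentation = c("auto", "sparse", "dense")) {
  forceRepresentation <- match.arg(forceRepresentation)
  if (ploidy < 1 || ploidy > IGD_MAX_PLOIDY)
    stop("ploidy must be in 1..255", call. = FALSE)
  if (numIndividuals < 1) stop("numIndividuals must be >= 1", call. = FALSE)
  if (sparsityDivisor < 1) stop("sparsityDivisor must be >= 1", call. = FALSE)

  st <- new.env(parent = emptyenv())
  st$header <- IGDHeader(ploidy = ploidy, numIndividuals = numIndividuals,
                         phased = phased, sparsityThreshold = sparsityDivisor)
  st$width <- rowWidth(st$header)
  st$force <- forceRepresentation
  st$con <- file(path, open = "w+b")
  writeBin(encodeHeader(st$header), st$con)
  writeBin(encodeIgdString(source), st$con)
  writeBin(encodeIgdString(description), st$con)
  st$offset <- IGD_HEADER_BYTES + 8 +
    length(charToRaw(enc2utf8(source))) +
    length(charToRaw(enc2utf8(description)))
  st$genotypeStart <- st$offset
  st$n <- 0L
  cap <- 1024L
  st$pos <- numeric(cap); st$nc <- integer(cap); st$flags <- integer(cap)
  st$goff <- numeric(cap); st$ref <- character(cap); st$alt <- character(cap)
  st$vid <- character(cap)
  st$anyVid <- FALSE
  st$nSparse <- 0L; st$nDense <- 0L; st$nMissing <- 0L
  st$finalized <- FALSE
  new("IGDWriter", path = path, state = st)
}

.writerGrow <- function(st) {
  cap <- 2L * length(st$pos)
  for (nm in c("pos", "goff")) length(st[[nm]]) <- cap
  for (nm in c("nc", "flags")) length(st[[nm]]) <- cap
  for (nm in c("ref", "alt", "vid")) {
    v <- st[[nm]]; length(v) <- cap; v[is.na(v)] <- ""; st[[nm]] <- v
  }
  invisible(NULL)
}

#' Append one genotype row to an IGD file under construction
#'
#' The row's payload is encoded (sparse list32 or dense bit-vector, per the
#' writer's representation policy) and streamed to disk immediately; its
#' index entry and allele pair are buffered until [finalizeIgd()].
#'
#' @param writer an [IGDWriter-class].
#' @param position base-pair position (< 2^48). Rows are written in the
#'   order given; the writer does not sort.
#' @param ref,alt allele strings. A missing-data row conventionally stores
#'   an empty `alt`.
#' @param samples 0-based sample indexes: haploid-sample indexes
#'   (< NH) for phased files, individual indexes (< N) for unphased files.
#'   For a missing-data row these are the samples WITHOUT a call.
#' @param numCopies for unphased, non-missing rows: the exact number of
#'   copies (1..ploidy) of `alt` carried by each listed individual. Must be
#'   0 for phased files; ignored (stored as given, conventionally 0) for
#'   missing rows.
#' @param isMissing marks a missing-data row.
#' @param variantId optional variant identifier; if any row receives one, a
#'   variant-ID table is written at finalization (rows without one get "").
#' @return the row's 0-based row index, invisibly.
#' @export
writeVariantRow <- function(writer, position, ref, alt, samples,
                            numCopies = 0, isMissing = FALSE,
                            variantId = NULL) {
  st <- writer@state
  if (st$finalized) stop("writer already finalized", call. = FALSE)
  if (position < 0 || position >= 2^48)
    stop("position out of range: must be < 2^48", call. = FALSE)
  phased <- isPhased(st$header)
  samples <- sort(as.numeric(samples))
  if (length(samples) &&
      (samples[1] < 0 || samples[length(samples)] >= st$width))
    stop("sample index out of range for width ", st$width, call. = FALSE)
  if (phased && numCopies != 0)
    stop("numCopies must be 0 for phased files", call. = FALSE)
  if (!phased && !isMissing &&
      (numCopies < 1 || numCopies > st$header@ploidy))
    stop("numCopies must be in 1..ploidy for unphased rows", call. = FALSE)

  kind <- switch(st$force,
    auto = chooseRepresentation(length(samples), st$width,
                                st$header@sparsityThreshold),
    sparse = "sparse", dense = "dense")
  payload <- if (kind == "sparse") encodeList32(samples)
             else encodeBitVector(samples, st$width)
  flags <- if (kind == "sparse") IGD_SPARSE else 0L
  if (isMissing) flags <- bitwOr(flags, IGD_MISSING)

  i <- st$n
  if (i + 1L > length(st$pos)) .writerGrow(st)
  j <- i + 1L
  st$pos[j] <- position
  st$nc[j] <- as.integer(numCopies)
  st$flags[j] <- as.integer(flags)
  st$goff[j] <- st$offset
  st$ref[j] <- ref
  st$alt[j] <- alt
  st$vid[j] <- if (is.null(variantId)) "" else variantId
  if (!is.null(variantId)) st$anyVid <- TRUE
  if (isMissing) st$nMissing <- st$nMissing + 1L
  else if (kind == "sparse") st$nSparse <- st$nSparse + 1L
  else st$nDense <- st$nDense + 1L

  writeBin(payload, st$con)
  st$offset <- st$offset + length(payload)
  st$n <- j
  invisible(i)
}

#' Finalize an IGD file
#'
#' Appends the index (16 bytes per row), the allele-string table, and the
#' optional individual-ID and variant-ID tables, then rewrites the header
#' in place with the true section offsets, counts and flags and closes the
#' file. The result passes `openIgd(strict = TRUE)`.
#'
#' @param writer an [IGDWriter-class].
#' @param individualIds optional character vector of length N.
#' @param variantIds optional character vector of length numRows; overrides
#'   any per-row IDs given to [writeVariantRow()].
#' @return invisibly, a summary list: `numRows`, `sparseRows`, `denseRows`,
#'   `missingRows`, `bytes` (total file size) and `sections` (named byte
#'   sizes of each file section).
#' @export
finalizeIgd <- function(writer, individualIds = NULL, variantIds = NULL) {
  st <- writer@state
  if (st$finalized) stop("writer already finalized", call. = FALSE)
  n <- st$n
  idx <- seq_len(n)
  h <- st$header

  if (!is.null(individualIds) && length(individualIds) != h@numIndividuals)
    stop("individualIds must have length N = ", h@numIndividuals,
         call. = FALSE)
  if (is.null(variantIds) && st$anyVid) variantIds <- st$vid[idx]
  if (!is.null(variantIds) && length(variantIds) != n)
    stop("variantIds must have length numRows = ", n, call. = FALSE)

  indexOffset <- st$offset
  if (n > 0) {
    entries <- rbind(
      matrix(packUints(st$pos[idx], 6L), nrow = 6L),
      matrix(packUints(st$nc[idx], 1L), nrow = 1L),
      matrix(packUints(st$flags[idx], 1L), nrow = 1L),
      matrix(packUints(st$goff[idx], 8L), nrow = 8L))
    writeBin(as.raw(entries), st$con)
  }
  st$offset <- indexOffset + IGD_INDEX_ENTRY_BYTES * n

  allelesOffset <- st$offset
  if (n > 0) {
    ab <- unlist(lapply(idx, function(j)
      c(encodeIgdString(st$ref[j]), encodeIgdString(st$alt[j]))))
    writeBin(ab, st$con)
    st$offset <- st$offset + length(ab)
  }

  individualIdsOffset <- 0
  if (!is.null(individualIds)) {
    individualIdsOffset <- st$offset
    ib <- c(uint64(length(individualIds)),
            unlist(lapply(individualIds, encodeIgdString)))
    writeBin(ib, st$con)
    st$offset <- st$offset + length(ib)
  }

  variantIdsOffset <- 0
  if (!is.null(variantIds)) {
    variantIdsOffset <- st$offset
    vb <- c(uint64(length(variantIds)),
            unlist(lapply(variantIds, encodeIgdString)))
    writeBin(vb, st$con)
    st$offset <- st$offset + length(vb)
  }

  final <- initialize(h, numRows = as.numeric(n),
                      indexOffset = indexOffset,
                      allelesOffset = allelesOffset,
                      individualIdsOffset = individualIdsOffset,
                      variantIdsOffset = variantIdsOffset)
  seek(st$con, where = 0, origin = "start", rw = "write")
  writeBin(encodeHeader(final), st$con)
  close(st$con)
  st$finalized <- TRUE

  sections <- c(
    header = IGD_HEADER_BYTES,
    descriptions = st$genotypeStart - IGD_HEADER_BYTES,
    genotypes = indexOffset - st$genotypeStart,
    index = IGD_INDEX_ENTRY_BYTES * n,
    alleles = (if (individualIdsOffset > 0) individualIdsOffset
               else if (variantIdsOffset > 0) variantIdsOffset
               else st$offset) - allelesOffset,
    individualIds = if (individualIdsOffset > 0)
      (if (variantIdsOffset > 0) variantIdsOffset else st$offset) -
        individualIdsOffset else 0,
    variantIds = if (variantIdsOffset > 0) st$offset - variantIdsOffset else 0)
  invisible(list(numRows = n, sparseRows = st$nSparse,
                 denseRows = st$nDense, missingRows = st$nMissing,
                 bytes = st$offset, sections = sections))
}
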