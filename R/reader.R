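# Random-access and sequential reading of IGD files. Two access patterns
# are supported: direct access to row i through the index (one seek into
# the index at indexOffset + 16*i, one seek to the row's genotype payload),
# and traversal, which walks the index in row order and only touches the
# genotype payload of rows whose position is of interest.

#' IGDFile: an open, validated IGD file
#'
#' Returned by [openIgd()]. Header and description strings are decoded on
#' open; the index and string tables are read lazily on first use and then
#' cached. Close with [closeIgd()] (also triggered by garbage collection
#' of the connection).
#'
#' @slot path file path.
#' @slot header the decoded [IGDHeader-class].
#' @slot source,description the file's two free-text description strings.
#' @slot strict whether strict validation (sorted sample lists, zero
#'   padding bits, table count cross-checks) applies to reads.
#' @slot state internal environment (connection and caches).
#' @export
setClass("IGDFile", representation(
  path = "character", header = "IGDHeader", source = "character",
  description = "character", strict = "logical", state = "environment"))

setMethod("show", "IGDFile", function(object) {
  h <- object@header
  cat("IGDFile:", object@path, "\n")
  show(h)
  cat("  NH =", numHaploidSamples(h),
      "| row width =", rowWidth(h),
      "| individual IDs:", if (h@individualIdsOffset > 0) "yes" else "no",
      "| variant IDs:", if (h@variantIdsOffset > 0) "yes" else "no", "\n")
})

#' Open an IGD file
#'
#' Decodes and validates the header and the two description strings, and
#' checks that the index (and in strict mode every string table) lies
#' within the file. No genotype data is read.
#'
#' @param path path to an IGD file.
#' @param strict if TRUE, the index and string tables are parsed up front
#'   and cross-checked (allele-pair count and variant-ID count must equal
#'   numRows; individual-ID count must equal N), and subsequent row reads
#'   validate sample ordering and padding bits. Default FALSE: anything
#'   structurally decodable is accepted.
#' @param versions accepted file format versions.
#' @return an [IGDFile-class].
#' @export
openIgd <- function(path, strict = FALSE, versions = IGD_VERSION) {
  size <- file.size(path)
  if (is.na(size)) stop("cannot read ", path, call. = FALSE)
  con <- file(path, open = "rb")
  hb <- readBin(con, "raw", n = IGD_HEADER_BYTES)
  header <- tryCatch(decodeHeader(hb, versions = versions),
                     error = function(e) { close(con); stop(e) })
  # description strings follow the header immediately
  sdec <- tryCatch({
    buf <- readBin(con, "raw", n = min(size - IGD_HEADER_BYTES, 2^20))
    s1 <- decodeIgdString(buf, 1)
    s2 <- decodeIgdString(buf, s1$at)
    list(source = s1$text, description = s2$text)
  }, error = function(e) { close(con); stop(e) })

  if (header@indexOffset == 0 || header@allelesOffset == 0) {
    close(con)
    stop("not a finalized IGD file: zero index or allele offset",
         call. = FALSE)
  }
  if (header@indexOffset + IGD_INDEX_ENTRY_BYTES * header@numRows > size) {
    close(con)
    stop("truncated file: index extends past end of file", call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$con <- con
  st$size <- size
  st$open <- TRUE
  igd <- new("IGDFile", path = path, header = header,
             source = sdec$source, description = sdec$description,
             strict = strict, state = st)
  if (strict) {
    tryCatch({
      idx <- .igdIndex(igd)
      igdAlleles(igd); individualIds(igd); variantIds(igd)
      if (header@numRows > 0) {
        if (any(idx$genotypeOffset < 128 |
                idx$genotypeOffset >= header@indexOffset))
          stop("corrupt index: genotype offset outside the genotype region",
               call. = FALSE)
        if (any(bitwAnd(idx$flags,
                        bitwNot(bitwOr(IGD_SPARSE, IGD_MISSING))) != 0))
          stop("corrupt index: unknown flag bits", call. = FALSE)
        # strict mode also decodes every row payload (ordering/padding checks)
        for (i in seq_len(header@numRows) - 1L) .igdReadRow(igd, i)
      }
    }, error = function(e) { closeIgd(igd); stop(e) })
  }
  igd
}

#' @rdname openIgd
#' @param igd an [IGDFile-class].
#' @export
closeIgd <- function(igd) {
  st <- igd@state
  if (isTRUE(st$open)) { close(st$con); st$open <- FALSE }
  invisible(NULL)
}

#' @describeIn openIgd the file's decoded header.
#' @export
igdHeader <- function(igd) igd@header

.igdSeekRead <- function(igd, where, n) {
  st <- igd@state
  if (!isTRUE(st$open)) stop("IGD file is closed", call. = FALSE)
  seek(st$con, where = where, origin = "start", rw = "read")
  b <- readBin(st$con, "raw", n = n)
  if (length(b) < n) stop("truncated file: unexpected end of file",
                          call. = FALSE)
  b
}

# Load and cache the whole index as four parallel vectors.
.igdIndex <- function(igd) {
  st <- igd@state
  if (is.null(st$index)) {
    h <- igd@header
    n <- h@numRows
    if (n == 0) {
      st$index <- list(position = numeric(0), numCopies = integer(0),
                       flags = integer(0), genotypeOffset = numeric(0))
    } else {
      b <- .igdSeekRead(igd, h@indexOffset, IGD_INDEX_ENTRY_BYTES * n)
      m <- matrix(b, nrow = IGD_INDEX_ENTRY_BYTES)
      st$index <- list(
        position = unpackUints(as.raw(m[1:6, ]), 6L),
        numCopies = as.integer(m[7, ]),
        flags = as.integer(m[8, ]),
        genotypeOffset = unpackUints(as.raw(m[9:16, ]), 8L))
    }
    st$sorted <- !is.unsorted(st$index$position)
  }
  st$index
}

# Read and decode the genotype payload of row i (0-based) given its index
# entry; one seek into the genotype region.
.igdReadRowAt <- function(igd, entry) {
  h <- igd@header
  w <- rowWidth(h)
  if (bitwAnd(entry$flags, IGD_SPARSE) != 0) {
    lb <- .igdSeekRead(igd, entry$genotypeOffset, 4)
    k <- unpackUints(lb, 4L)
    body <- if (k > 0) .igdSeekRead(igd, entry$genotypeOffset + 4, 4 * k)
            else raw(0)
    dec <- decodeList32(c(lb, body), strict = igd@strict)
  } else {
    nb <- ceiling(w / 8)
    dec <- decodeBitVector(.igdSeekRead(igd, entry$genotypeOffset, nb), w,
                           strict = igd@strict)
  }
  new("GenotypeRow",
      kind = if (bitwAnd(entry$flags, IGD_SPARSE) != 0) "sparse" else "dense",
      samples = dec$samples,
      isMissing = bitwAnd(entry$flags, IGD_MISSING) != 0,
      width = as.numeric(w))
}

.igdReadRow <- function(igd, i) {
  .igdReadRowAt(igd, .igdEntry(igd, i))
}

# Read row i's 16-byte index entry directly (one seek).
.igdEntry <- function(igd, i) {
  h <- igd@header
  if (i < 0 || i >= h@numRows)
    stop("row index out of range: ", i, " (file has ", h@numRows, " rows)",
         call. = FALSE)
  b <- .igdSeekRead(igd, h@indexOffset + IGD_INDEX_ENTRY_BYTES * i, 16)
  unpackIndexEntry(b)
}

#' VariantMeta: per-row metadata
#'
#' @slot rowIndex 0-based row number i.
#' @slot position base-pair position.
#' @slot ref,alt allele strings (a missing-data row's alt is "").
#' @slot numCopies the row's copy count (0 in phased files).
#' @slot isMissing whether the row is a missing-data row.
#' @slot variantId the row's identifier, or NA if the file stores none.
#' @export
setClass("VariantMeta", representation(
  rowIndex = "numeric", position = "numeric", ref = "character",
  alt = "character", numCopies = "integer", isMissing = "logical",
  variantId = "character"))

setMethod("show", "VariantMeta", function(object) {
  cat("Variant row", object@rowIndex, "@", object@position,
      paste0(object@ref, ">", object@alt),
      if (object@isMissing) "[missing-data row]" else "",
      if (object@numCopies > 0) paste0("numCopies=", object@numCopies) else "",
      "\n")
})

.igdMeta <- function(igd, i, entry, alleles = NULL, vids = NULL) {
  if (is.null(alleles)) alleles <- igdAlleles(igd)
  if (is.null(vids)) vids <- variantIds(igd)
  new("VariantMeta", rowIndex = as.numeric(i),
      position = entry$position,
      ref = alleles$ref[i + 1], alt = alleles$alt[i + 1],
      numCopies = as.integer(entry$numCopies),
      isMissing = bitwAnd(entry$flags, IGD_MISSING) != 0,
      variantId = if (is.null(vids)) NA_character_ else vids[i + 1])
}

#' Randomly access one variant row
#'
#' Row i is located directly at `indexOffset + 16 * i`; exactly two seeks
#' are performed (the index entry, then the genotype payload). The row is
#' returned in its stored representation.
#'
#' @param igd an [IGDFile-class].
#' @param i 0-based row index, `0 <= i < numRows`.
#' @return `list(meta = VariantMeta, row = GenotypeRow)`.
#' @export
getVariant <- function(igd, i) {
  entry <- .igdEntry(igd, i)
  row <- .igdReadRowAt(igd, entry)
  list(meta = .igdMeta(igd, i, entry), row = row)
}

#' Traverse an IGD file in row order
#'
#' Walks the index from row 0, decoding the genotype payload only of rows
#' whose position falls in `range` (half-open, `start <= position < end`);
#' out-of-range rows' genotype data is never read.
#'
#' @param igd an [IGDFile-class].
#' @param range optional numeric `c(start, end)` base-pair interval,
#'   half-open; NULL traverses every row.
#' @param FUN optional callback `function(meta, row)`; when given, rows are
#'   streamed through it and its results are returned (useful to avoid
#'   holding all rows in memory).
#' @return a list with one element per yielded row: `FUN`'s value, or
#'   `list(meta=, row=)` when `FUN` is NULL.
#' @export
igdVariants <- function(igd, range = NULL, FUN = NULL) {
  h <- igd@header
  idx <- .igdIndex(igd)
  alleles <- igdAlleles(igd)
  vids <- variantIds(igd)
  keep <- if (is.null(range)) seq_len(h@numRows)
          else which(idx$position >= range[1] & idx$position < range[2])
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j] - 1L
    entry <- list(position = idx$position[keep[j]],
                  numCopies = idx$numCopies[keep[j]],
                  flags = idx$flags[keep[j]],
                  genotypeOffset = idx$genotypeOffset[keep[j]])
    row <- .igdReadRowAt(igd, entry)
    meta <- .igdMeta(igd, i, entry, alleles, vids)
    out[[j]] <- if (is.null(FUN)) list(meta = meta, row = row)
                else FUN(meta, row)
  }
  out
}

#' Locate the row interval covering a base-pair range
#'
#' If the index positions are non-decreasing (checked once per handle),
#' binary search over the 16-byte index entries yields the half-open row
#' interval `[first, lastExclusive)` of rows with
#' `start <= position < end`. Otherwise a linear scan returns the tightest
#' interval bounding all matching rows (correctness never depends on
#' sortedness).
#'
#' @param igd an [IGDFile-class].
#' @param start,end base-pair bounds, half-open.
#' @return numeric `c(first, lastExclusive)`, 0-based; `first ==
#'   lastExclusive` for an empty interval.
#' @export
locateRange <- function(igd, start, end) {
  idx <- .igdIndex(igd)
  n <- length(idx$position)
  if (n == 0 || start >= end) return(c(0, 0))
  if (igd@state$sorted) {
    first <- findInterval(start - 0.5, idx$position)
    lastx <- findInterval(end - 0.5, idx$position)
    c(first, lastx)
  } else {
    hit <- which(idx$position >= start & idx$position < end)
    if (!length(hit)) c(0, 0) else c(min(hit) - 1, max(hit))
  }
}

## string tables -----------------------------------------------------------

.decodeStringRun <- function(bytes, count, what) {
  out <- character(count)
  at <- 1
  for (i in seq_len(count)) {
    d <- tryCatch(decodeIgdString(bytes, at),
                  error = function(e)
                    stop("truncated ", what, " table", call. = FALSE))
    out[i] <- d$text
    at <- d$at
  }
  out
}

#' Read the file's string tables
#'
#' The allele table holds one (ref, alt) pair per row, in row order; the
#' two ID tables are present only when their header offsets are nonzero.
#' All three are cached on the handle after the first read.
#'
#' @param igd an [IGDFile-class].
#' @return `igdAlleles()`: a data.frame with character columns `ref` and
#'   `alt`, one row per genotype row. `individualIds()`, `variantIds()`:
#'   a character vector, or NULL if the file stores none.
#' @export
igdAlleles <- function(igd) {
  st <- igd@state
  if (is.null(st$alleles)) {
    h <- igd@header
    n <- h@numRows
    if (n == 0) {
      st$alleles <- data.frame(ref = character(0), alt = character(0))
    } else {
      endOff <- min(c(h@individualIdsOffset, h@variantIdsOffset,
                      st$size)[c(h@individualIdsOffset, h@variantIdsOffset,
                                 st$size) > 0])
      b <- .igdSeekRead(igd, h@allelesOffset, endOff - h@allelesOffset)
      flat <- .decodeStringRun(b, 2 * n, "allele")
      st$alleles <- data.frame(ref = flat[seq(1, 2 * n, 2)],
                               alt = flat[seq(2, 2 * n, 2)])
    }
  }
  st$alleles
}

.readIdTable <- function(igd, offset, what, expected) {
  if (offset == 0) return(NULL)
  st <- igd@state
  b <- .igdSeekRead(igd, offset, st$size - offset)
  count <- unpackUints(b[1:8], 8L)
  if (igd@strict && count != expected)
    stop(what, " count mismatch: table has ", count, ", expected ",
         expected, call. = FALSE)
  .decodeStringRun(b[-(1:8)], count, what)
}

#' @rdname igdAlleles
#' @export
individualIds <- function(igd) {
  st <- igd@state
  if (is.null(st$iids))
    st$iids <- list(v = .readIdTable(igd, igd@header@individualIdsOffset,
                                     "individual ID",
                                     igd@header@numIndividuals))
  st$iids$v
}

#' @rdname igdAlleles
#' @export
variantIds <- function(igd) {
  st <- igd@state
  if (is.null(st$vids))
    st$vids <- list(v = .readIdTable(igd, igd@header@variantIdsOffset,
                                     "variant ID", igd@header@numRows))
  st$vids$v
}

## site-level views --------------------------------------------------------

#' Re-aggregate the variant rows of one site
#'
#' Multi-allelic sites are stored expanded, one row per alternate allele
#' (plus at most one missing-data row); the original site is recovered by
#' grouping rows by position.
#'
#' @param igd an [IGDFile-class].
#' @param position base-pair position of the site.
#' @return a list: `position`; `ref` (NA if the position is absent);
#'   `alts`, a list of `list(alt=, samples=, numCopies=, rowIndex=)` in row
#'   order; `missing`, the site's missing-sample index vector (length 0 if
#'   no missing-data row).
#' @export
aggregateSite <- function(igd, position) {
  idx <- .igdIndex(igd)
  rows <- which(idx$position == position)
  out <- list(position = position, ref = NA_character_, alts = list(),
              missing = numeric(0))
  if (!length(rows)) return(out)
  alleles <- igdAlleles(igd)
  for (j in rows) {
    entry <- list(position = idx$position[j], numCopies = idx$numCopies[j],
                  flags = idx$flags[j], genotypeOffset = idx$genotypeOffset[j])
    row <- .igdReadRowAt(igd, entry)
    if (row@isMissing) {
      out$missing <- row@samples
      if (is.na(out$ref)) out$ref <- alleles$ref[j]
    } else {
      out$ref <- alleles$ref[j]
      out$alts[[length(out$alts) + 1]] <-
        list(alt = alleles$alt[j], samples = row@samples,
             numCopies = as.integer(entry$numCopies), rowIndex = j - 1)
    }
  }
  out
}

#' Allele frequency of one variant row
#'
#' Always decodes the full genotype payload (the format stores no counts
#' for dense rows; for sparse rows the stored count is re-derived from the
#' decoded list). For phased files the frequency is
#' `carriers / NH`; for unphased files it is
#' `numCopies * individuals / (N * ploidy)`. With `excludeMissing = TRUE`
#' the denominator drops the site's missing samples: `NH - missing` for
#' phased files, `(N - missing individuals) * ploidy` for unphased files.
#'
#' @param igd an [IGDFile-class].
#' @param i 0-based row index of a non-missing row.
#' @param excludeMissing drop the site's missing samples from the
#'   denominator.
#' @return frequency in `[0, 1]`.
#' @export
alleleFrequency <- function(igd, i, excludeMissing = FALSE) {
  entry <- .igdEntry(igd, i)
  if (bitwAnd(entry$flags, IGD_MISSING) != 0)
    stop("row ", i, " is a missing-data row and has no allele frequency",
         call. = FALSE)
  row <- .igdReadRowAt(igd, entry)
  h <- igd@header
  phased <- isPhased(h)
  nMiss <- 0
  if (excludeMissing) {
    idx <- .igdIndex(igd)
    mrows <- which(idx$position == entry$position &
                   bitwAnd(idx$flags, IGD_MISSING) != 0)
    for (j in mrows) {
      e <- list(position = idx$position[j], numCopies = idx$numCopies[j],
                flags = idx$flags[j], genotypeOffset = idx$genotypeOffset[j])
      nMiss <- nMiss + length(.igdReadRowAt(igd, e)@samples)
    }
  }
  if (phased) {
    denom <- numHaploidSamples(h) - nMiss
    if (denom <= 0) return(0)
    length(row@samples) / denom
  } else {
    denom <- (h@numIndividuals - nMiss) * h@ploidy
    if (denom <= 0) return(0)
    entry$numCopies * length(row@samples) / denom
  }
}
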