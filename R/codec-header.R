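# The fixed 128-byte header. Layout (byte offset, little-endian):
#   0  uint64 magic          8  uint64 version
#   16 uint32 ploidy         20 uint32 sparsity threshold
#   24 uint64 number of rows 32 uint32 number of individuals N
#   36 4B reserved           40 uint64 flags (bit 0 = phased)
#   48 uint64 index offset   56 uint64 allele-strings offset
#   64 uint64 individual-ID offset   72 uint64 variant-ID offset
#   80 48B reserved

#' IGDHeader: the fixed-size IGD file preamble
#'
#' Holds the counts, ploidy, flags and section file offsets stored in the
#' first 128 bytes of an IGD file. `numRows` counts all stored genotype rows
#' (variants plus missing-data rows, M + Q); `NH = numIndividuals * ploidy`
#' is derived, never stored. Offsets of 0 for the two optional ID sections
#' mean the section is absent.
#'
#' @slot version file format version (this package writes 1).
#' @slot ploidy haploid genome copies per individual, 1..255.
#' @slot sparsityThreshold the writer's sparse/dense divisor (informational;
#'   default 32).
#' @slot numRows total stored rows M + Q.
#' @slot numIndividuals number of individuals N.
#' @slot flags 64-bit flag field held as a double; bit 0 set = phased.
#' @slot indexOffset,allelesOffset,individualIdsOffset,variantIdsOffset
#'   absolute file offsets of the sections following the genotype data.
#' @export
setClass("IGDHeader", representation(
  version = "numeric",
  ploidy = "numeric",
  sparsityThreshold = "numeric",
  numRows = "numeric",
  numIndividuals = "numeric",
  flags = "numeric",
  indexOffset = "numeric",
  allelesOffset = "numeric",
  individualIdsOffset = "numeric",
  variantIdsOffset = "numeric"
))

setValidity("IGDHeader", function(object) {
  msg <- character(0)
  scl <- c("version", "ploidy", "sparsityThreshold", "numRows",
           "numIndividuals", "flags", "indexOffset", "allelesOffset",
           "individualIdsOffset", "variantIdsOffset")
  for (s in scl) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v != floor(v))
      msg <- c(msg, paste0(s, " must be a single non-negative integer"))
  }
  if (length(msg) == 0) {
    if (object@ploidy < 1 || object@ploidy > IGD_MAX_PLOIDY)
      msg <- c(msg, "ploidy must be in 1..255")
    if (object@numIndividuals < 0)
      msg <- c(msg, "numIndividuals must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IGDHeader
#'
#' @param ploidy,numIndividuals,numRows,phased,sparsityThreshold,version
#'   header fields; see [IGDHeader-class].
#' @param indexOffset,allelesOffset,individualIdsOffset,variantIdsOffset
#'   section offsets (0 while a file is being written; the index and allele
#'   offsets must be nonzero in a finalized file).
#' @return an [IGDHeader-class] object.
#' @export
IGDHeader <- function(ploidy, numIndividuals, numRows = 0, phased = TRUE,
                      sparsityThreshold = 32, version = IGD_VERSION,
                      indexOffset = 0, allelesOffset = 0,
                      individualIdsOffset = 0, variantIdsOffset = 0) {
  new("IGDHeader", version = version, ploidy = ploidy,
      sparsityThreshold = sparsityThreshold, numRows = numRows,
      numIndividuals = numIndividuals, flags = if (phased) 1 else 0,
      indexOffset = indexOffset, allelesOffset = allelesOffset,
      individualIdsOffset = individualIdsOffset,
      variantIdsOffset = variantIdsOffset)
}

#' @describeIn IGDHeader number of haploid samples NH = N * ploidy.
#' @param header an [IGDHeader-class].
#' @export
numHaploidSamples <- function(header) header@numIndividuals * header@ploidy

#' @describeIn IGDHeader TRUE if bit 0 of the flags field is set.
#' @export
isPhased <- function(header) (header@flags %% 2) == 1

#' @describeIn IGDHeader width of a genotype row's sample universe:
#'   NH for phased files, N for unphased files.
#' @export
rowWidth <- function(header) {
  if (isPhased(header)) numHaploidSamples(header) else header@numIndividuals
}

setMethod("show", "IGDHeader", function(object) {
  cat("IGDHeader: version", object@version,
      "|", if (isPhased(object)) "phased" else "unphased",
      "| ploidy", object@ploidy,
      "| N =", object@numIndividuals,
      "| rows =", object@numRows, "\n")
  cat("  offsets: index", object@indexOffset,
      "alleles", object@allelesOffset,
      "individualIds", object@individualIdsOffset,
      "variantIds", object@variantIdsOffset, "\n")
})

#' Encode or decode the 128-byte IGD header
#'
#' `encodeHeader()` serializes an [IGDHeader-class] to exactly 128 bytes,
#' writing the magic number and zeroed reserved regions. `decodeHeader()`
#' is the exact inverse; it fails with distinct errors on a short buffer,
#' a wrong magic number, or an unrecognized version.
#'
#' @param header an [IGDHeader-class].
#' @param bytes a raw vector of at least 128 bytes.
#' @param versions versions accepted on decode.
#' @return `encodeHeader()`: 128 raw bytes. `decodeHeader()`: an
#'   [IGDHeader-class].
#' @export
encodeHeader <- function(header) {
  stopifnot(is(header, "IGDHeader"))
  validObject(header)
  b <- c(IGD_MAGIC,
         uint64(header@version),
         uint32(header@ploidy),
         uint32(header@sparsityThreshold),
         uint64(header@numRows),
         uint32(header@numIndividuals),
         raw(4),
         uint64(header@flags),
         uint64(header@indexOffset),
         uint64(header@allelesOffset),
         uint64(header@individualIdsOffset),
         uint64(header@variantIdsOffset),
         raw(48))
  stopifnot(length(b) == IGD_HEADER_BYTES)
  b
}

#' @rdname encodeHeader
#' @export
decodeHeader <- function(bytes, versions = IGD_VERSION) {
  if (length(bytes) < IGD_HEADER_BYTES)
    stop("short header: need 128 bytes, have ", length(bytes), call. = FALSE)
  if (!identical(bytes[1:8], IGD_MAGIC))
    stop("bad magic: not an IGD file", call. = FALSE)
  f <- function(at, n) unpackUints(bytes[(at + 1):(at + n)], n)
  version <- f(8, 8)
  if (!version %in% versions)
    stop("unsupported version: ", version, call. = FALSE)
  new("IGDHeader",
      version = version,
      ploidy = f(16, 4),
      sparsityThreshold = f(20, 4),
      numRows = f(24, 8),
      numIndividuals = f(32, 4),
      flags = f(40, 8),
      indexOffset = f(48, 8),
      allelesOffset = f(56, 8),
      individualIdsOffset = f(64, 8),
      variantIdsOffset = f(72, 8))
}
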