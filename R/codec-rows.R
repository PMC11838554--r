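# Genotype rows and the 16-byte index entries that address them.

#' GenotypeRow: one variant's carrier set
#'
#' A genotype row records which samples carry a variant's alternate allele
#' (or, for missing-data rows, which samples have no call at the site). On
#' disk the set is stored either sparsely as a list32 of sample indexes or
#' densely as a bit-vector of width `w`; `w` is NH for phased files and N
#' for unphased files. In memory the samples are always held as a strictly
#' ascending 0-based index vector; `kind` records the (intended) on-disk
#' representation only.
#'
#' @slot kind `"sparse"` or `"dense"`.
#' @slot samples strictly ascending 0-based sample indexes, each < `width`.
#' @slot isMissing TRUE for a missing-data row, whose samples are those
#'   WITHOUT a call, not carriers.
#' @slot width size of the sample universe (NH phased, N unphased).
#' @export
setClass("GenotypeRow", representation(
  kind = "character",
  samples = "numeric",
  isMissing = "logical",
  width = "numeric"
))

setValidity("GenotypeRow", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("sparse", "dense"))
    msg <- c(msg, "kind must be 'sparse' or 'dense'")
  if (length(object@samples)) {
    if (any(diff(object@samples) <= 0))
      msg <- c(msg, "samples must be strictly ascending")
    if (object@samples[1] < 0 ||
        object@samples[length(object@samples)] >= object@width)
      msg <- c(msg, "samples must lie in [0, width)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeRow
#' @param samples 0-based sample indexes (any order; sorted internally).
#' @param width sample universe size w.
#' @param kind on-disk representation tag.
#' @param isMissing missing-data row marker.
#' @return a [GenotypeRow-class].
#' @export
GenotypeRow <- function(samples, width, kind = c("sparse", "dense"),
                        isMissing = FALSE) {
  new("GenotypeRow", kind = match.arg(kind),
      samples = sort(as.numeric(samples)), isMissing = isMissing,
      width = as.numeric(width))
}

#' @describeIn GenotypeRow the row's sample index vector.
#' @param row a [GenotypeRow-class].
#' @export
rowSamples <- function(row) row@samples

#' @describeIn GenotypeRow number of samples in the row.
#' @export
carrierCount <- function(row) length(row@samples)

setMethod("show", "GenotypeRow", function(object) {
  cat("GenotypeRow (", object@kind,
      if (object@isMissing) ", missing-data" else "",
      "): ", length(object@samples), " of ", object@width, " samples\n",
      sep = "")
})

#' Toggle a row's on-disk representation
#'
#' The stored representation of a row is orthogonal to its content:
#' converting preserves the sample set and the missing-data marker exactly
#' and only flips the `kind` tag (and hence how the row would be encoded).
#'
#' @param row a [GenotypeRow-class].
#' @return a [GenotypeRow-class] with the opposite `kind`.
#' @export
sparseToDense <- function(row) {
  stopifnot(row@kind == "sparse")
  initialize(row, kind = "dense")
}

#' @rdname sparseToDense
#' @export
denseToSparse <- function(row) {
  stopifnot(row@kind == "dense")
  initialize(row, kind = "sparse")
}

#' Choose the more compact row representation
#'
#' A sparse row costs 4 bytes per carrier (32-bit sample numbers); a dense
#' row costs `ceiling(w/8)` bytes regardless of the carrier count. The rule
#' is frequency-based: a row is stored sparsely iff its allele frequency is
#' below `1/divisor`, i.e. `carrierCount * divisor < w` (strict; ties go
#' dense). The 4-byte list32 length prefix is deliberately ignored, so at
#' the boundary the chosen representation may exceed the alternative by at
#' most those 4 bytes.
#'
#' @param carrierCount number of samples in the row.
#' @param w sample universe size.
#' @param divisor sparsity divisor (default 32, matching 32-bit sample
#'   numbers vs 1 bit per sample).
#' @return `"sparse"` or `"dense"`.
#' @export
chooseRepresentation <- function(carrierCount, w, divisor = 32) {
  stopifnot(carrierCount >= 0, carrierCount <= w)
  if (carrierCount * divisor < w) "sparse" else "dense"
}

#' Encode or decode a genotype row payload
#'
#' `encodeGenotypeRow()` emits the row's on-disk payload per its `kind`:
#' a list32 for sparse rows, a `bv(width)` for dense rows.
#' `decodeGenotypeRow()` reads one back given the flags that the index
#' entry stores for the row.
#'
#' @param row a [GenotypeRow-class].
#' @param bytes raw vector holding the payload.
#' @param w sample universe size.
#' @param flags the row's index-entry flag byte.
#' @param at 1-based payload position within `bytes`.
#' @param strict validate sample order and padding bits.
#' @return `encodeGenotypeRow()`: raw vector. `decodeGenotypeRow()`:
#'   `list(row=, at=)`.
#' @export
encodeGenotypeRow <- function(row) {
  validObject(row)
  if (row@kind == "sparse") encodeList32(row@samples)
  else encodeBitVector(row@samples, row@width)
}

#' @rdname encodeGenotypeRow
#' @export
decodeGenotypeRow <- function(bytes, w, flags, at = 1, strict = FALSE) {
  sparse <- bitwAnd(as.integer(flags), IGD_SPARSE) != 0
  dec <- if (sparse) decodeList32(bytes, at, strict = strict)
         else decodeBitVector(bytes, w, at, strict = strict)
  row <- new("GenotypeRow",
             kind = if (sparse) "sparse" else "dense",
             samples = dec$samples,
             isMissing = bitwAnd(as.integer(flags), IGD_MISSING) != 0,
             width = as.numeric(w))
  list(row = row, at = dec$at)
}

## index entries -----------------------------------------------------------

#' Pack and unpack 16-byte index entries
#'
#' An index entry is two little-endian uint64 words. The first packs the
#' variant's base-pair position into the least-significant 48 bits, then an
#' 8-bit numCopies (0 for phased data, 1..ploidy for unphased), then the
#' flag bits ([IGD_SPARSE], [IGD_MISSING]) in the most-significant 8 bits:
#' `(flags << 56) | (numCopies << 48) | position`. The second word is the
#' absolute file offset of the row's genotype payload. Row i of the index
#' lives at `indexOffset + 16 * i`.
#'
#' @param position base-pair position, < 2^48.
#' @param numCopies copy count for unphased rows (0 for phased).
#' @param flags flag byte; only bits 0x01 and 0x02 may be set.
#' @param genotypeOffset absolute file offset of the genotype payload.
#' @param bytes 16 raw bytes (or more, with `at`).
#' @param at 1-based entry position within `bytes`.
#' @return `packIndexEntry()`: 16 raw bytes. `unpackIndexEntry()`: a list
#'   with elements `position`, `numCopies`, `flags`, `genotypeOffset`.
#' @export
packIndexEntry <- function(position, numCopies = 0, flags = 0,
                           genotypeOffset = 0) {
  if (position < 0 || position >= 2^48)
    stop("position out of range: must be < 2^48", call. = FALSE)
  if (numCopies < 0 || numCopies > 255)
    stop("numCopies out of range: must be <= 255", call. = FALSE)
  if (bitwAnd(as.integer(flags),
              bitwNot(bitwOr(IGD_SPARSE, IGD_MISSING))) != 0)
    stop("unknown flag bits set", call. = FALSE)
  c(packUints(position, 6L), packUints(numCopies, 1L),
    packUints(flags, 1L), uint64(genotypeOffset))
}

#' @rdname packIndexEntry
#' @export
unpackIndexEntry <- function(bytes, at = 1) {
  if (length(bytes) < at + 15)
    stop("truncated index entry", call. = FALSE)
  b <- bytes[at:(at + 15)]
  list(position = unpackUints(b[1:6], 6L),
       numCopies = as.integer(b[7]),
       flags = as.integer(b[8]),
       genotypeOffset = unpackUints(b[9:16], 8L))
}
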