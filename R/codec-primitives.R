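# On-disk storage primitives: uint32/uint64 (little-endian), length-prefixed
# strings, list32 sample lists, and MSB-first bit-vectors. Integers are held
# as doubles in R; every quantity the format stores (positions < 2^48, file
# offsets, counts) is exactly representable below 2^53.

#' Flag bits used in IGD index entries
#'
#' `IGD_SPARSE` (0x01) marks a genotype row stored as a list32 of sample
#' indexes; `IGD_MISSING` (0x02) marks a row whose sample list is the set of
#' samples with no call at the site.
#' @export
IGD_SPARSE <- 0x01

#' @rdname IGD_SPARSE
#' @export
IGD_MISSING <- 0x02

# Magic number 0x3a0c6fd7945a3481, little-endian byte order.
IGD_MAGIC <- as.raw(c(0x81, 0x34, 0x5a, 0x94, 0xd7, 0x6f, 0x0c, 0x3a))

IGD_VERSION <- 1
IGD_HEADER_BYTES <- 128L
IGD_INDEX_ENTRY_BYTES <- 16L
IGD_MAX_PLOIDY <- 255L

## little-endian integer packing ------------------------------------------

packUints <- function(x, nbytes) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x >= 2^(8 * nbytes)))
    stop("value out of range for uint", 8 * nbytes, call. = FALSE)
  if (any(x != floor(x))) stop("non-integer value", call. = FALSE)
  m <- outer(256^(0:(nbytes - 1)), x, function(d, v) floor(v / d) %% 256)
  as.raw(m)  # column-major: per-value bytes, least-significant first
}

unpackUints <- function(bytes, nbytes) {
  stopifnot(length(bytes) %% nbytes == 0)
  m <- matrix(as.numeric(bytes), nrow = nbytes)
  as.vector(256^(0:(nbytes - 1)) %*% m)
}

uint32 <- function(x) packUints(x, 4L)
uint64 <- function(x) packUints(x, 8L)

## strings -----------------------------------------------------------------

#' Encode and decode length-prefixed strings
#'
#' The on-disk `string` type is a uint32 byte length k followed by k raw
#' bytes. Byte content is uninterpreted by the format; this package
#' encodes and decodes R character strings as UTF-8.
#'
#' @param text a single character string (or raw vector of bytes).
#' @param bytes a raw vector to decode from.
#' @param at 1-based position of the length prefix within `bytes`.
#' @return `encodeIgdString()` returns a raw vector of `4 + k` bytes.
#'   `decodeIgdString()` returns `list(text=, at=)` where `at` is the position
#'   just past the string.
#' @examples
#' encodeIgdString("A")                     # 01 00 00 00 41
#' decodeIgdString(encodeIgdString("ACGT"))   # $text "ACGT", $at 9
#' @export
encodeIgdString <- function(text) {
  b <- if (is.raw(text)) text else charToRaw(enc2utf8(as.character(text)))
  c(uint32(length(b)), b)
}

#' @rdname encodeIgdString
#' @export
decodeIgdString <- function(bytes, at = 1) {
  if (length(bytes) < at + 3) stop("truncated string: no length prefix", call. = FALSE)
  k <- unpackUints(bytes[at:(at + 3)], 4L)
  at <- at + 4
  if (length(bytes) < at + k - 1)
    stop("truncated string: declared length ", k, " exceeds remaining bytes",
         call. = FALSE)
  txt <- if (k == 0) "" else rawToChar(bytes[at:(at + k - 1)])
  list(text = txt, at = at + k)
}

## list32 ------------------------------------------------------------------

#' Encode and decode sparse sample lists (list32)
#'
#' A `list32` is a uint32 count k followed by k uint32 sample indexes. The
#' writer always emits strictly ascending indexes; `strict = TRUE` rejects
#' lists violating that order on decode.
#'
#' @param samples numeric vector of 0-based sample indexes, strictly
#'   ascending, each < 2^32.
#' @param bytes raw vector to decode from.
#' @param at 1-based position of the length prefix within `bytes`.
#' @param strict reject out-of-order sample lists on decode.
#' @return `encodeList32()` returns `4 + 4k` raw bytes; `decodeList32()`
#'   returns `list(samples=, at=)`.
#' @export
encodeList32 <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) && any(diff(samples) <= 0))
    stop("sample list must be strictly ascending", call. = FALSE)
  c(uint32(length(samples)), if (length(samples)) uint32(samples))
}

#' @rdname encodeList32
#' @export
decodeList32 <- function(bytes, at = 1, strict = FALSE) {
  if (length(bytes) < at + 3) stop("truncated list32: no length prefix", call. = FALSE)
  k <- unpackUints(bytes[at:(at + 3)], 4L)
  at <- at + 4
  if (length(bytes) < at + 4 * k - 1)
    stop("truncated list32: declared length ", k, " exceeds remaining bytes",
         call. = FALSE)
  s <- if (k == 0) numeric(0) else unpackUints(bytes[at:(at + 4 * k - 1)], 4L)
  if (strict && length(s) > 1 && any(diff(s) <= 0))
    stop("unsorted sample list", call. = FALSE)
  list(samples = s, at = at + 4 * k)
}

## bit-vectors -------------------------------------------------------------

#' Encode and decode dense genotype rows (bit-vectors)
#'
#' A `bv(w)` stores w bits in `ceiling(w/8)` bytes. Sample index b occupies
#' byte `floor(b/8)`, bit `7 - (b %% 8)` counting from the least significant
#' bit -- i.e. the first sample of each byte sits in the most significant
#' bit. Padding bits past w are written as zero; `strict = TRUE` rejects set
#' padding bits on decode, otherwise they are masked.
#'
#' @param samples numeric vector of 0-based sample indexes, each < `w`.
#' @param w bit-vector width (number of samples in the row's universe).
#' @param bytes raw vector of exactly `ceiling(w/8)` bytes (or more; only
#'   the first `ceiling(w/8)` are consumed when `at` is given).
#' @param at 1-based position of the bit-vector within `bytes`.
#' @param strict reject nonzero padding bits.
#' @return `encodeBitVector()` returns `ceiling(w/8)` raw bytes;
#'   `decodeBitVector()` returns `list(samples=, at=)` with ascending
#'   indexes.
#' @examples
#' encodeBitVector(0, w = 10)   # 80 00
#' encodeBitVector(9, w = 10)   # 00 40
#' @export
encodeBitVector <- function(samples, w) {
  samples <- as.numeric(samples)
  if (length(samples) && (any(samples < 0) || any(samples >= w)))
    stop("sample index out of range for bit-vector of width ", w, call. = FALSE)
  nb <- ceiling(w / 8)
  bytes <- raw(nb)
  if (length(samples)) {
    agg <- rowsum(2^(7 - (samples %% 8)), group = samples %/% 8)
    bytes[as.numeric(rownames(agg)) + 1] <- as.raw(agg)
  }
  bytes
}

#' @rdname encodeBitVector
#' @export
decodeBitVector <- function(bytes, w, at = 1, strict = FALSE) {
  nb <- ceiling(w / 8)
  if (length(bytes) < at + nb - 1)
    stop("truncated bit-vector: need ", nb, " bytes", call. = FALSE)
  chunk <- bytes[at:(at + nb - 1)]
  bits <- rawToBits(chunk)                   # index 1 = LSB of byte 1
  pos0 <- which(bits == as.raw(1)) - 1
  s <- sort((pos0 %/% 8) * 8 + (7 - pos0 %% 8))
  pad <- s >= w
  if (any(pad)) {
    if (strict) stop("nonzero padding bits in bit-vector", call. = FALSE)
    s <- s[!pad]
  }
  list(samples = s, at = at + nb)
}
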