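---
title: "The IGD genotype format: model, layout, and design choices"
author: "igdio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IGD genotype format: model, layout, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igdio)
```

## The data model

Reference-aligned polymorphism data for `N` individuals at fixed ploidy is a
matrix over `NH = N * ploidy` haploid genome copies ("samples"). Each
polymorphic *site* has a position, a reference allele, and one or more
alternate alleles; each *variant* is one (position, alternate allele) pair.
IGD (Indexable Genotype Data) stores hard calls only — discrete carrier
states, not dosages or likelihoods — and always in bi-allelic form: a site
with `k` alternate alleles is expanded into `k` rows sharing the position
and reference allele. A site with any missing call gets one extra row whose
sample list holds the samples *without* a call. With `M` variant rows and
`Q` missing-data rows, the file stores `M + Q` rows in total.

Each row records the set of samples carrying its allele in one of two
representations:

* **sparse** (`list32`): a uint32 count followed by that many uint32 sample
  indexes — 4 bytes per carrier;
* **dense** (`bv(w)`): a bit-vector of `ceiling(w/8)` bytes, sample `b`
  occupying byte `floor(b/8)`, bit `7 - (b mod 8)` (MSB-first within each
  byte).

The row width `w` is `NH` for phased files. Unphased files instead store
*individual* lists (`w = N`): each row carries a `numCopies` value in
`1..ploidy`, and lists the individuals carrying exactly that many copies of
the alternate allele. A file is entirely phased or entirely unphased
(header flag bit 0).

A row with carrier frequency `p` costs `4·p·w` bytes sparsely versus `w/8`
bytes densely, so the writer stores a row sparsely iff
`carriers * 32 < w` — i.e. frequency below 1/32, ties dense. The 4-byte
list prefix is deliberately ignored in this comparison (the stored payload
can exceed the alternative by at most those 4 bytes at the boundary); any
mixture of representations is a valid file, and `forceRepresentation`
exposes the two pure forms. Because content is independent of
representation, converting between the two (`sparseToDense()`,
`denseToSparse()`) never touches the sample set.

Random access comes from an internal index of 16 bytes per row: one uint64
packing `(flags << 56) | (numCopies << 48) | position` (48-bit positions;
flags `SPARSE = 0x01`, `IS_MISSING = 0x02`) and one uint64 file offset of
the row's payload. Row `i` lives at `indexOffset + 16 * i`, so both access
patterns — direct access by row number and positional traversal that skips
payloads outside a base-pair window — need no external index and no
compression library.

## File layout

A file is: a fixed 128-byte header (magic `0x3a0c6fd7945a3481`, version,
ploidy, sparsity divisor, row count, `N`, flags, and the offsets of every
later section); two length-prefixed description strings; the `M + Q`
genotype payloads; the index; the allele-string table (one ref/alt pair per
row); then optional individual-ID and variant-ID tables whose absence is
signalled by a zero header offset. Readers must locate sections by the
header offsets, never by assumed order. All multi-byte integers are
little-endian; the format itself never states a byte order in prose, so
this package fixes it once, in the codec, to the dominant machine
convention.

Two reserved header regions (4 bytes at offset 36, 48 bytes at offset 80)
are written as zero and ignored on read. The header's row count covers all
`M + Q` rows, matching the index length. The `sparsityThreshold` field
records the writer's divisor (default 32) and is informational on read.

## Reading, writing, converting

`createIgdWriter()` + `writeVariantRow()` + `finalizeIgd()` build a file in
one pass: payloads stream to disk as they arrive; only the 16-byte index
entries and the strings are buffered; at finalization the sections are
appended and the header is rewritten in place with the true offsets (one
backward seek). Identical input streams give byte-identical files. Row
order is preserved as given — sortedness is the converter's concern, and
`locateRange()` checks monotonicity once per handle, using binary search on
sorted indexes and falling back to a linear scan otherwise (correctness
never depends on order).

`openIgd()` validates the header eagerly and reads nothing else until
asked. Two validation levels exist because malformed files in the wild are
usually still usable: the default lenient mode accepts anything
structurally decodable (masking set padding bits, ignoring unsorted sample
lists), while `strict = TRUE` — the mode used throughout this package's
tests — additionally cross-checks table counts against the header, rejects
unknown flag bits, out-of-region offsets, set padding bits and unsorted
sparse rows.

`vcfToIgd()` consumes only CHROM, POS, ID, REF, ALT and GT from VCF 4.x
(plain or gzip), streaming one site at a time. Haplotype slot `j` of
individual `n` becomes haploid sample `n * ploidy + j`. One missing-data
row is emitted per site with any missing call (not per expanded variant:
the site's missing list is identical for every alt, and duplicating it `k`
times would store the same bytes `k` times). A half-missing unphased
genotype such as `./1` places the individual in the missing row only — a
copy count is undefined when one allele is unknown. Positions are copied
verbatim (1-based); IGD itself is coordinate-convention-agnostic. IGD has
no chromosome field, so multi-chromosome input errors unless `split = TRUE`
writes one file per chromosome. Records with `ALT="."` keep their
missing-data row (if any) so `Q` survives round trips; otherwise they are
skipped and counted. `igdToVcf()` re-aggregates rows by position into
minimal GT-only VCF; for unphased data the within-genotype allele order was
never stored, so genotypes are emitted in a canonical order and compare
equal as multisets.

One genuine ambiguity: a haploid GT field has no `|`/`/` separator, so
phasedness cannot be detected from ploidy-1 VCF. `vcfToIgd(phased =)`
overrides the default (phased); for ploidy ≥ 2 a conflicting override is an
error rather than a silent coercion, as is any phasedness switch
mid-file.

## Allele frequency

`alleleFrequency()` and `igdtools freq` always decode the full sample list
— never a stored count — so traversal cost is what is measured. Phased rows
give `carriers / NH`; unphased rows `numCopies * individuals /
(N * ploidy)`, so a site's alt frequency is the sum over its copy-count
rows. The format does not define frequency under missingness, so both
conventions are exposed: the default denominator is the full `NH` (or
`N * ploidy`), and `excludeMissing` subtracts the site's missing samples
(phased) or missing individuals (unphased) from it.

## The synthetic generator

`simulateGenotypes()` produces datasets with known truth for testing every
layer without external data. Per site it draws a carrier count from the
discrete spectrum `P(x) ∝ x^(-sfsAlpha)` over `x in 1..NH-1` — `sfsAlpha =
1` approximates the neutral site-frequency spectrum, skewed toward rare
variants as biobank-scale sequencing cohorts are — places carriers
uniformly, optionally splits a site's carriers between two alternate
alleles (`multiallelicFraction`), and assigns missing calls per haploid
sample (phased) or per whole individual (unphased) at `missingRate`.
Positions are sorted distinct integers in `[1, 10 * numSites]` so region
extraction has meaningful targets. Defaults are `missingRate = 0`,
`multiallelicFraction = 0`, `sfsAlpha = 1`.

It is a statistical stand-in, not a coalescent simulator: carriers are
exchangeable across sites, so there is no linkage disequilibrium, no
population structure, and no realistic allele-length distribution (alleles
are single bases). IGD stores rows independently and exploits none of
those features, so their absence does not weaken correctness testing — but
passing tests say nothing about LD-dependent tooling downstream, and the
generator's file-size behaviour tracks real data only through the shape of
its frequency spectrum.

## Numerical and degenerate-input choices

R holds the format's integers as doubles; every stored quantity (48-bit
positions, file offsets, counts) is exactly representable below 2^53, and
the only value beyond that — the 64-bit magic number — is handled as raw
bytes. Sample lists are written strictly ascending (deterministic output,
binary-searchable rows) though the format does not require it; dense
padding bits are written zero. Empty rows, empty files (`numRows = 0`),
empty strings and empty ranges are all valid and tested. The writer emits
version 1; the reader's accepted-version set is a parameter. Unphased
missing-data rows store `numCopies = 0` (the copy-count constraint applies
to variant rows only).

Test and acceptance problem sizes are chosen to exercise the properties at
desk scale: codec properties run on 10,000 random instances per structure
plus an exhaustive bit-placement scan for widths up to 64; conversion runs
over the full grid {phased, unphased} × ploidy {1, 2, 3} × missing rate
{0, 0.05} × multi-allelic fraction {0, 0.2}; and the size comparison uses
N = 2,000 diploid individuals at 20,000 sites with the neutral-like
spectrum, where roughly 61% of rows fall below the 1/32 sparsity threshold
(the harmonic mass of `1/x` below `NH/32`), so the frequency-adaptive file
undercuts both the uncompressed VCF and its own all-dense form.

## Known limitations

* No compression, checksums, or memory-mapped access — by design of the
  format.
* Byte-order and version conventions of other IGD implementations are not
  documented in the format description this package implements; bit
  compatibility with files they produce is expected (little-endian is the
  shared platform convention) but cannot be guaranteed.
* `igdToVcf()` exports minimal VCF: QUAL/FILTER/INFO and non-GT FORMAT data
  are not representable in IGD and are dropped at import.
* Multi-allelic aggregation groups rows by position; rows of one site are
  assumed contiguous in row order, as the converter writes them.
* BCF/PGEN/BGEN/BED are out of scope; convert through VCF.
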