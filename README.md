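# igdio — the Indexable Genotype Data (IGD) format in R

Large genotype matrices are usually shipped as VCF, which is flexible but
slow to parse and expensive to store, or as heavily compressed binary
formats that need dedicated libraries and external index files. IGD is the
opposite trade: a *simple, uncompressed* binary format for hard-call
genotype data that any language can read with a few hundred lines of code,
yet is compact on the rare-variant-rich data that modern sequencing cohorts
produce, and randomly accessible through an index that is part of the file
itself. `igdio` implements the format end to end for R: a bit-exact codec,
a validating random-access reader, a one-pass streaming writer, VCF ↔ IGD
converters, allele-frequency and region-extraction tools with a command
line interface, and a seeded synthetic-genotype simulator for testing. It
is aimed at statistical- and population-genetics tool builders who want
genotype storage they can fully understand and reimplement.

## The format in brief

For `N` individuals at ploidy `p` there are `NH = N·p` haploid samples.
Every polymorphic site is stored bi-allelically: a site with `k` alternate
alleles becomes `k` rows (same position and REF, different ALT), plus one
missing-data row listing the samples without a call if any. Each of the
`M + Q` rows stores its carrier set either

* **sparsely** — a `list32`: uint32 count, then uint32 sample indexes
  (4 bytes per carrier), or
* **densely** — a bit-vector of `ceil(w/8)` bytes, sample `b` at byte
  `⌊b/8⌋`, bit `7 − (b mod 8)`,

where `w = NH` (phased) or `w = N` (unphased; each row then carries
`numCopies ∈ 1..p`, the exact copy count of its listed individuals). A row
is written sparse iff `carriers · 32 < w`, i.e. allele frequency < 1/32 —
32-bit sample numbers against 1 bit per sample. The per-row index entry is
two uint64 words, `(flags ≪ 56) | (numCopies ≪ 48) | position` and the
payload's file offset, so row `i` is found at `indexOffset + 16·i` with two
seeks and no decompression. All integers are little-endian; the 128-byte
header starts with the magic number `0x3a0c6fd7945a3481`.

## Worked example

```r
library(igdio)

ds <- simulateGenotypes(numIndividuals = 50, numSites = 500, ploidy = 2,
                        phased = TRUE, missingRate = 0.02,
                        multiallelicFraction = 0.1, seed = 11)
ds
#> SyntheticDataset: 500 sites, N = 50 , ploidy 2 , phased
#>   sites with missing calls (Q): 441

writeVcfFixture(ds, "example.vcf")
rep <- vcfToIgd("example.vcf", "example.igd")
str(rep$summaries[[1]])
#> List of 6
#>  $ numRows    : int 984
#>  $ sparseRows : int 196
#>  $ denseRows  : int 347
#>  $ missingRows: int 441
#>  $ bytes      : num 37368
```

The 500 sites expand to 984 rows: 543 variant rows (multi-allelic sites
contribute one row per alternate allele) and 441 missing-data rows — with a
2% per-call missing rate, most 100-haplotype sites have at least one
missing call. Variant rows below 1/32 frequency (fewer than 4 of 100
carriers) were stored as sparse sample lists, the rest as 13-byte
bit-vectors.

```r
igd <- openIgd("example.igd", strict = TRUE)
igd
#> IGDFile: example.igd
#> IGDHeader: version 1 | phased | ploidy 2 | N = 50 | rows = 984
#>   offsets: index 11877 alleles 27621 individualIds 37020 variantIds 0
#>   NH = 100 | row width = 100 | individual IDs: yes | variant IDs: no

getVariant(igd, 2)$meta        # random access to row 2
#> Variant row 2 @ 23 A>G
alleleFrequency(igd, 2)        # decoded from the full sample list
#> [1] 0.04
locateRange(igd, 1000, 2000)   # half-open row interval, binary search
#> [1] 203 389
str(aggregateSite(igd, 23), max.level = 2)   # site view of row 2's position
#> List of 4
#>  $ position: num 23
#>  $ ref     : chr "A"
#>  $ alts    :List of 1
#>   ..$ :List of 4
#>  $ missing : num [1:2] 77 87
closeIgd(igd)
```

`alleleFrequency` reports 4 carriers among the 100 haploid samples; the
site record shows the same row as part of its position group together with
the two haplotypes lacking a call there (`excludeMissing = TRUE` would use
98 as the denominator instead).

The same operations are available from a shell:

```sh
exec/igdtools convert example.vcf example.igd
exec/igdtools info example.igd --json
exec/igdtools freq example.igd --range 1000-2000 -o freq.tsv
exec/igdtools extract example.igd region.igd --range 1000-2000
exec/igdtools simulate --seed 7 -n 100 --sites 2000 --vcf sim.vcf --igd sim.igd
```

## Package layout

* `R/codec-*.R` — storage primitives, header, rows, index entries
* `R/writer.R`, `R/reader.R` — one-pass writer; random-access reader
* `R/vcf-convert.R` — streaming VCF ↔ IGD conversion
* `R/fixtures.R` — synthetic dataset generator and fixture writers
* `R/cli.R`, `exec/igdtools` — command line interface
* `vignettes/igd-format.Rmd` — the format, its design choices and limits
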