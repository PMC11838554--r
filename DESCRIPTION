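Package: igdio
Title: Read, Write and Convert Indexable Genotype Data (IGD) Files
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An implementation of the Indexable Genotype Data (IGD) binary
    file format for reference-aligned genotype matrices. IGD stores one row
    per (position, alternate allele) variant, either sparsely as a list of
    carrier sample indexes or densely as a bit-vector, with a 16-byte
    per-variant internal index enabling random access without compression
    libraries. The package provides a bit-exact codec for every on-disk
    structure, a validating random-access reader, a one-pass streaming
    writer, converters between VCF (plain or gzip) and IGD with
    multi-allelic expansion and missing-data rows, allele-frequency
    traversal and region-extraction tools, a command line interface, and a
    seeded synthetic genotype simulator with a configurable site-frequency
    spectrum for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, vcfR, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'igdio-package.R'
    'codec-primitives.R'
    'codec-header.R'
    'codec-rows.R'
    'writer.R'
    'reader.R'
    'vcf-convert.R'
    'fixtures.R'
    'cli.R'
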