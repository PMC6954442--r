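# dominsert

Design engine and analysis toolkit for **programmed domain-insertion
libraries**: saturated insertional mutagenesis of a target gene via
synthesized oligo pools and two-step Golden Gate (type-IIS) cloning, plus
the statistics used to judge library quality and to score domain-insertion
permissibility from sorted-population sequencing.

## The problem and the approach

Inserting a donor protein domain after *every* residue of a target protein
is the insertional analogue of deep mutational scanning. Transposase-based
libraries are sequence-biased, incomplete and 5/6 out-of-frame. `dominsert`
instead programs the library:

1. **Fragmentation** — the target ORF is divided into codon-aligned
   fragments (≤ 55 codons under the 230-nt synthesis limit), consecutive
   fragments sharing one codon. Each fragment's two 4-nt Golden Gate
   overhangs are wildtype subsequences at its junctions; all overhangs in a
   plan are mutually unique, non-palindromic and reverse-complement-free.
2. **Oligo pool** — one oligo per insertion position:
   `[barcode 12] [CGTCTC+spacer] [payload with 24-nt handle] [spacer+GAGACG]
   [barcode 12]`, all ≤ 230 nt. The handle (`SG…GS` linkers around two
   outward-facing BsaI sites) is later replaced by any in-frame domain.
3. **Primers** — inverse-PCR backbone primers (BsmBI tails recreating the
   junction overhangs) and subpool amplification primers (3' end pinned at
   the cut site), all with combined nearest-neighbor melting temperature in
   [55, 61] °C and no off-target annealing above 35 °C.
4. **QC** — every oligo is audited for unintended BsaI/BsmBI sites
   (repaired by frame-base flips, barcode swaps or silent codon swaps) and
   every subpool primer re-checked for pool-wide specificity.
5. **Verification** — an in silico digestion/ligation simulator proves that
   every oligo reconstitutes the plasmid-with-handle and that replacing the
   handle yields the in-frame domain insertion, for all positions.

The per-position permissibility score from sorted populations is

    F(i) = r_SE(i)/t_SE − r_NSE(i)/t_NSE,     z_i = (F_i − μ)/σ

computed only where both populations observed reads, z-scored per
replicate, and averaged across replicates.

## Worked example

```r
library(dominsert)

p <- make_synthetic_plasmid(300, seed = 1)   # circular plasmid, 300-codon ORF
d <- design_insertion_library(p, seed = 1)
d
#> <insertion_design 'syngene1'>
#>   gene: 300 codons, 6 fragments, 299 oligos (positions 1..299)
#>   oligo length max 217 nt (budget 230)
#>   primers: 24; combined Tm 55.1-60.9 C; max off-target 25.6 C
#>   QC: 0 action(s), 0 unresolved

domain <- orf_sequence(make_synthetic_plasmid(30, backbone_len = 400, seed = 99))
v <- verify_pool(d, domain)
mean(v$verdict)
#> [1] 1
```

299 oligos — one per interior inter-codon junction of the 300-codon ORF —
every one of which assembles into the intended handle product and then into
the in-frame domain insertion. `write_design(d, "out/")` exports the oligo
pool FASTA, a primer order sheet (both melting-temperature models per
primer), the fragment plan and the QC report.

Permissibility scoring from sorted counts:

```r
truth <- rep(c(0.9, 0.1), each = 25)                    # permissive vs not
sim <- simulate_sort_counts(truth, reads_per_position = 250, seed = 1)
pr <- zscore_profile(enrichment_profile(sim$se, sim$nse))
range(pr$z[1:25]); range(pr$z[26:50])
#> [1] 0.7947981 1.1172958
#> [1] -1.1266705 -0.8548885
```

A command-line front end is installed with the package
(`system.file("cli", "dominsert", package = "dominsert")`) with `design`
and `simulate` subcommands.

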