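---
title: "Programmed domain-insertion library design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Programmed domain-insertion library design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominsert)
```

## The problem

Measuring how a target protein tolerates insertion of a donor domain at
every one of its residues requires a library with exactly one insertion
variant per inter-codon junction — saturated, unbiased and in frame.
Transposase-mediated insertion cannot deliver this: it is sequence-biased,
leaves some regions empty, and places five of six insertions out of frame or
backwards. `dominsert` instead *programs* the library: the target ORF is cut
into fragments, each fragment is replaced by a pool of synthesized oligos
that carry a 24-nt genetic handle at one position each, and two rounds of
Golden Gate (type-IIS) cloning first install the handle library and then
swap the handle for the actual domain. Because every sequence is designed,
the library is saturated by construction, and the package proves it *in
silico* by simulating both cloning steps for every single oligo.

## Fragmentation geometry

A fragment spans codons $[s, e]$ (1-based). Its two 4-nt Golden Gate
overhangs are read from the wildtype plasmid asymmetrically:

* left overhang: the base *preceding* codon $s$, then codon $s$;
* right overhang: codon $e$, then the base *following* it.

Both overhangs are therefore wildtype subsequences, and the handle can sit
after any codon $j \in \{s, \dots, e-1\}$ without touching either overhang.
Consecutive fragments share exactly one codon ($s_{f+1} = e_f$), so the
per-fragment insertion ranges tile all $N-1$ interior junctions of an
$N$-codon ORF exactly once — the saturation guarantee. An alternative
geometry with both extension bases pointing into the fragment would lose one
junction per fragment boundary; we chose the asymmetric reading precisely to
avoid those gaps.

The gene payload of a $c$-codon fragment is $3c + 2$ nt (codons plus the two
junction extension bases). With the default 230-nt synthesis limit and fixed
costs of two 12-nt barcodes, two 7-nt enzyme blocks (6-nt recognition plus a
1-nt spacer that keeps the cut codon-aligned) and the 24-nt handle, the
payload budget is $230 - 24 - 24 - 14 = 168$ nt, so fragments hold at most
55 codons. A 300-codon gene yields 6 fragments of about 51 codons and 299
oligos, the longest 217 nt.

### Overhang uniqueness

All $2F$ overhangs of a plan must be pairwise distinct, distinct from each
other's reverse complements, and non-palindromic (a palindromic overhang
ligates to itself). Clashing internal boundaries are moved by whole codons,
greedily and leftmost-first ($0, \pm 1, \dots, \pm 10$ codons), rejecting
moves that push a fragment over the budget; if fragments sit at the size cap
(no boundary can move), the gene is re-split over one extra fragment and the
search repeated. The two *edge* overhangs are pinned to the gene ends and
are repaired in sequence space instead: a palindromic left edge (always
`xATG`; `CATG` is the palindrome) by substituting the non-coding base before
the ORF, a clashing right edge by a synonymous swap of the last codon. In
multi-gene pools, overhangs committed to earlier genes are reserved: later
genes' movable overhangs avoid them because a shared overhang would put an
identical 11-nt `CGTCTCA`+overhang 3' end into two subpools' primers, which
for GC-rich overhangs anneals above the specificity ceiling. Left edges are
exempt (only three non-palindromic `xATG` overhangs exist, and their
11-mers stay below the ceiling).

## The genetic handle

The handle is `AGCGGCGAGACCGGTCTCGGCTCT`: Ser–Gly linker codons, two
outward-facing BsaI sites, Gly–Ser linker codons, reading `SGETGLGS` in
frame. BsaI digestion cuts inside the linker codons, leaving the 4-nt
overhangs `GCGG` and `GCTC`, so replacing the handle interior with any
in-frame domain leaves `SG…GS` linker scars and nothing else. Linker codons
are chosen by human codon-usage rank, subject to a *junction-safety*
condition: because the handle is spliced between arbitrary gene codons, no
suffix of the handle may be a prefix of a BsaI/BsmBI recognition motif (or
vice versa at the handle start) — otherwise a downstream codon could
complete a spurious site. That is why the 3' Ser falls back from `AGC`
(whose trailing `C` can complete `CGTCTC`) to `TCT`.

## Oligos, barcodes, primers

Each oligo reads: forward barcode (12 nt) — `CGTCTC` + spacer — payload with
handle — spacer + `GAGACG` — reverse barcode. BsmBI digestion releases the
payload with exactly the fragment's junction overhangs. Barcodes are random
12-mers with pairwise Hamming distance ≥ 4, 30–70% GC, no homopolymer runs
of 5, and no recognition motif alone or joined to the fixed oligo context;
the generator is seeded and a user-supplied list is accepted instead.
Subpools must use pairwise-distinct barcodes; duplicates in a supplied list
are replaced from the remaining pool.

Backbone (inverse-PCR) primers carry a `CGTCTCN` tail so that digestion of
the amplicon leaves the fragment's own overhangs on the vector side. Their
annealing length grows one base at a time until the *combined* melting
temperature — the mean of the two nearest-neighbor estimates, see below —
lies in [55, 61] °C and the primer has no off-target annealing above 35 °C
anywhere else in the plasmid. The annealing-length search runs to 45 nt:
AT-rich junctions at gene edges (where the boundary cannot move) can need
well over 30 nt to reach 55 °C. Subpool amplification primers cover the
barcode + `CGTCTC` + spacer + overhang block; their 3' end is pinned at the
cut site, so the melting temperature is tuned by trimming the 5' end, and
specificity is enforced against the complete oligo pool and the plasmid.
When no trim length works, the subpool's barcode is swapped for a spare and
the design retried.

## Melting temperature model

$T_m = \dfrac{1000\,\Delta H}{\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+] +
R \ln(C_T/4)} - 273.15$

with $\Delta H, \Delta S$ summed over dinucleotide stacks plus initiation
terms, $R = 1.987$ cal mol⁻¹ K⁻¹, and the $C_T/4$ convention for
non-self-complementary duplexes. Both published parameter sets (Sugimoto et
al. 1996; SantaLucia & Hicks 2004) are shipped as TSV tables and both values
are always reported; accept/reject decisions use their mean, which is a
single decidable rule given that the two sets bracket each other. Defaults
are 500 nM total strand and 50 mM monovalent salt, applied identically to
both sets; all three are configurable. Secondary structure and divalent-ion
corrections are out of scope.

Off-target annealing is operationalized as the longest contiguous exact
match anchored at the primer's 3' end (minimum 6 nt) at each register of
each template strand, scored as the combined $T_m$ of the matched stretch;
3'-anchoring is what licenses polymerase extension. A primer is flagged
non-specific when any such stretch outside its intended footprint melts
*above* 35 °C (exactly 35 °C is still specific).

## In silico quality control

After assembly of the pool, every oligo is scanned for BsaI/BsmBI
recognition sites beyond the intended four (two BsmBI at the ends, the
handle's two BsaI). An unintended site is removed, in order of preference,
by flipping the frame (spacer) base, replacing the offending barcode from
the spare pool, or a silent codon swap inside the gene payload (boundary
codons are never swapped — their bases sit inside assembly overhangs).
Codon swaps follow a fixed human codon-usage ranking, ties broken by GC
content then alphabetically. Subpool-primer specificity is then re-checked
across the corrected pool; a non-specific primer triggers a barcode swap and
the audit repeats (bounded, with an explicit failure listing any site that
cannot be silenced — e.g. one covering only Met/Trp codons). On a default
design the audit finds nothing: the frame bases, barcode junctions and
handle junctions are constructed so that no motif can span them.

## Assembly simulation

Fragments are modelled on the top strand with their 4-nt 5' extensions;
both enzymes cut one nucleotide downstream of recognition with a 4-nt
stagger, so every cut is "position $a$, overhang $[a, a+4)$" regardless of
strand. Ligation requires exact 4/4 overhang identity (design verification,
not fidelity simulation); one-, two- and three-part circularizations are
enumerated, and products that retain a recognition site are flagged
re-cuttable, as they would be re-digested in a one-pot reaction.
`verify_pool()` runs, for every oligo: (1) BsmBI assembly of the oligo with
its fragment's backbone amplicon, which must yield exactly the plasmid with
the handle after the oligo's residue; (2) BsaI replacement of the handle
with a domain amplicon, which must yield the plasmid with
linker–domain–linker at that residue and translate to the wildtype protein
with the insertion — the in-frame guarantee. Comparisons are
rotation-invariant string equality on the circular product.

## Library statistics and permissibility scoring

Per-position read counts are normalized as $(r_i / t)\cdot N$ (mean exactly
1; a perfectly even library is 1 everywhere). Library bias is compared by
two-sample Kolmogorov–Smirnov distance between normalized-count
distributions (asymptotic p-values; exact enumeration is pointless at
library scale). Coverage curves resample a table to a common depth — 300
reads per position as a gene-wide multinomial total, the identity when the
table is already on target — then report the covered fraction at increasing
thresholds. Frame/direction calls are partitioned into six classes; class
frequencies divide by total reads, enrichments divide sorted by control
frequencies, and a zero-frequency control class yields a missing value, not
infinity. Duplicated calls (the same event reported by both read mates) are
removed before normalization. Single-base deletion rates count reads whose
CIGAR contains a deletion op of length exactly 1 (multi-deletion reads count
once) over all aligned reads. Insertion-context matrices count bases in ±5
nt windows (configurable) around insertion sites against a background over
all positions, the standard input of background-corrected sequence logos.

Permissibility per position is $F(i) = r^i_{SE}/t_{SE} - r^i_{NSE}/t_{NSE}$
between surface-expressed and non-surface-expressed sorted populations,
defined only where both populations have reads (NA elsewhere); profiles are
z-scored with the sample ($n-1$) standard deviation, and replicates are
z-scored first, then averaged per position over non-NA values — z-then-mean
keeps replicates on a common scale regardless of their sequencing depth,
which is why we chose it over averaging raw $F$. In rank-correlation
comparisons between datasets, NA positions are set to 0 rather than dropped,
because deleting them discards most positions at sparse coverage. The
two-proportion z-test (pooled variance, two-sided normal p) covers the
false-call comparison between library technologies.

## What the generators emulate — and what they do not

The synthetic-data module generates every input class the package reads:
circular plasmids with embedded ORFs (scrubbed of BsaI/BsmBI sites, or
salted with a stated number); insertion count/call tables under uniform,
hotspot, or trinucleotide-preference bias (the latter up-weights positions
whose codon matches CGG by default, mimicking transposase target bias, with
frame/direction drawn uniformly over the six classes as true random
insertion would); sorted-population counts that split each position's reads
binomially by a known permissibility; and SAM records in which a stated
fraction of reads carries exactly one 1-bp deletion. All generators are pure
functions of their configuration and seed.

What they do *not* model: sequencing error beyond 1-nt deletions, FACS
gating noise, transfection multiplicity (multiple variants per cell),
PCR jackpotting, or oligo synthesis errors other than by their summary
rate. Passing tests therefore demonstrate the correctness of the design
engine and of the statistical machinery on data matching these generative
assumptions — not that a wet-lab library will be error-free.

## Problem sizes and determinism

The shipped tests run the full pipeline on ten synthetic genes of 200–600
codons plus a four-gene shared pool, verify every oligo through both
assembly steps, and exercise the statistics at $10^4$–$10^6$ simulated
reads; permissibility recovery uses four planted tiers (0.9 / 0.65 / 0.35 /
0.1) at 250 reads per position over three replicates, the coverage regime of
the underlying assay. Every randomized step takes an explicit seed; a design
is a pure function of (plasmid, configuration, seed) and reruns are
byte-identical.

## Known limitations

* Only BsaI and BsmBI are registered (the registry is extensible; nothing
  else is tested).
* Ligation fidelity is binary — near-complementary overhang mispairing is
  not modelled, so overhang sets that a ligase-bias model would reject can
  pass.
* Off-target annealing considers contiguous 3'-anchored matches only;
  gapped or internally mismatched duplexes are invisible to it.
* Concatemers beyond three parts are not enumerated.
* The greedy boundary search is not exhaustive; pathological genes (e.g.
  long homopolymer runs) are reported as infeasible rather than solved.
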