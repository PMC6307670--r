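---
title: "Methods: detecting and dating an active, horizontally transferred DNA transposon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and dating an active, horizontally transferred DNA transposon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`activeTE` implements two workflows. The *activity screen* asks whether a
transposable element (TE) is mobilizing now: germline expression above the
reference third quartile, an autonomous element structure (intact
transposase ORF, terminal inverted repeats, DD34D catalytic motif),
many near-identical genomic copies, and non-reference insertion
polymorphism between haploid brothers. The *horizontal-transfer analysis*
asks how the element arrived: patchy presence across a clade, interspecies
synonymous divergence far below that of the host's own genes, phylogenetic
incongruence, and an invasion date from neutral-rate calibration. A
forward simulator generates every input with recorded ground truth, so all
of this is validated by parameter recovery rather than by fixtures.

# The generative model behind the simulator

**Host genes.** Nuclear single-copy orthologs evolve along an ultrametric
species tree (branch lengths in My) under Jukes–Cantor substitution at a
per-lineage rate `r` (substitutions/site/year). Terminal branches use the
tip's rate; internal branches use the mean of their descendant tips'
rates. Coding sequences reject substitutions that would create an
in-frame stop codon. This mirrors the downstream analysis, which — like
the study design it follows — restricts Ks estimation to intact reading
frames; the induced deficit in realized divergence is below ~2% (stop
codons are 3/64 of codon space) and is absorbed by the tolerances of the
recovery tests.

**Horizontal entry and proliferation.** An unsampled donor lineage carries
the element between hosts, evolving at `donor_rate` between transfer
events; each event copies the donor's current sequence into the recipient.
Within a recipient, proliferation follows a *master-element* model: a
linear birth process at rate λ per extant copy per My, restricted to
active windows, in which every new insertion instantiates the conserved
founding sequence and then evolves neutrally. Under this model a copy's
divergence from the ancestral state equals `r × age`, which is precisely
the assumption that makes consensus-referenced dating meaningful and
burst structure identifiable in the age distribution. The alternative —
copying the *current* sequence of a random extant copy — makes every
extant copy carry `r × t_entry` divergence regardless of its own age (the
molecular clock runs along the whole lineage), erasing all age signal;
we therefore model the active source as maintained by selection, which is
the standard master-gene picture for DNA-transposon amplification and
matches the empirical observation of many exactly identical young copies.

`burst_on_arrival_my` gives each recipient one active window covering the
first interval after its own entry — the classic invasion burst — while
`burst_schedule` specifies absolute windows shared by all recipients
(used to emulate burst/quiescence/re-burst histories).

**Element anatomy.** The source element is `te_length` nt (default
1,324): terminal inverted repeats (default 28 bp), spacers, and an
internal transposase ORF (default 1,059 nt, ATG-initiated, stop-flanked).
The ORF evolves in stop-avoiding coding mode, the rest as plain neutral
DNA. A configurable fraction of emitted copies is truncated to emulate
assembly-fragmented or decayed copies.

**Brother pairs.** Each family is a pair of haploid brothers. The genome
is partitioned into alternating identical-by-descent (IBD) and non-IBD
blocks with geometric lengths (mean IBD block 300 kb) and the stationary
IBD fraction set by `ibd_fraction` (default 0.62). SNP counts per 10-kb
window are Poisson at 0.3 (IBD; residual error) vs. 30 (non-IBD) — a
100-fold separation consistent with maternal-haplotype heterozygosity
against sequencing error. Insertions carry a TA-type target-site
duplication (default 2 bp) and are supported by junction reads from both
flanks (anchor 30–70 bp, 2–15 reads/side, mapq 20–60), plus 5% random
noise reads, some below the mapq floor. One family-specific locus also
receives element-absent spanning reads in one brother, planting a somatic
excision signature.

**What the simulator does not emulate** — and hence what passing recovery
tests do *not* establish about real data: sequencing error at the read
level, indel evolution within the element, selection on copies
(all copies are dead-on-arrival except the implicit master), GC/codon-usage
heterogeneity, assembly collapse of near-identical copies, and
mapping ambiguity in repetitive regions. On real genomes the copy tables,
SNP tables and junction reads come from upstream tools (BLAST-style hit
tables, VCF, BED), and those tools' error modes are outside this
package's scope.

# Estimators and conventions

**NG86.** Synonymous site counts per codon treat changes to stop codons
as nonsynonymous; difference counts average over all substitution
pathways that avoid stop codons (falling back to all pathways when every
ordering is blocked); proportions are Jukes–Cantor corrected.
`pS ≥ 3/4` flags `saturated`, zero synonymous sites flags `S_zero`; both
yield `NA` rather than a number. The implementation is table-driven
(64×64 pathway-averaged difference tables built once per session); the
test suite checks it for exact agreement against an independently coded
recursive pathway enumerator on 500 random alignments.

**Codon alignment.** Protein-level global alignment (BLOSUM62, gap open
10, extend 0.5) threaded back to codons; every gap-containing codon
column is removed. Equal-length pairs skip the aligner, since the
gap-free alignment is optimal for equal-length homologs; this is also the
fast path that makes thousand-fold cross-set comparisons cheap. An
optional conserved-block filter drops codon columns inside 15-column
windows with under 50% conserved residues (off by default; intended for
deep cross-species element comparisons).

**Games–Howell.** `q = |mᵢ - mⱼ| / sqrt((sᵢ²/nᵢ + sⱼ²/nⱼ)/2)` with
Welch–Satterthwaite degrees of freedom and p-values from the studentized
range (`ptukey`). Two numerical edge cases are handled explicitly: both
variances zero gives p = 1 (equal means) or a flagged p = 0 (unequal);
and for extreme `q` at low df, where `ptukey` underflows to `NaN`, the
two-group case falls back on the exact identity `Q = √2·|t|` and k > 2
cases report 0 when `q > 50` (the tail is far below machine precision).

**Contrast modes.** The historical practice of treating every copy×copy
Ks value as an observation pseudo-replicates massively (each copy enters
hundreds of pairs). The pipeline's default is `disjoint_pairs`: each copy
enters at most one cross-species pair, giving independent observations;
`per_copy_mean` and `all_pairs` are available for comparability. Groups
smaller than `min_te_group = 5` are reported untestable rather than
tested: with 2–3 observations the Welch df collapse toward 1 and no
effect, however large, can reach small p-values — reporting such a pair
"non-significant" would be misleading in both directions.

**Trees.** Neighbor joining (`ape::nj`) on K2P distances for genes and on
mean cross-species copy distances for the element. The element tree is
built from genomic copies rather than from species consensi: consensus
sequences collapse within-host divergence and retain only the (few)
donor-lineage substitutions between transfer events, whereas copy-based
distances include each lineage's divergence since entry and therefore
carry the transfer-order signal at usable strength. Incongruence is the
Robinson–Foulds distance to the species tree restricted to the carrier
taxa.

**Presence.** Seeded 12-mer matching on both strands, candidate loci
locally aligned (match 2, mismatch −3, gap open 5, extend 2); presence
requires a hit strictly longer than 100 bp at strictly above 90%
identity. Overlapping same-strand hits merge (> 50% reciprocal overlap)
before copy counting, so an internal deletion cannot double-count; copy
counts use coverage ≥ 60% within a genome and ≥ 40% across species.

**Expression.** Quartiles use linear interpolation between closest ranks
(R type 7); "highly expressed" is *strictly* above the reference third
quartile, "lowly" strictly below the first; values equal to a threshold
are `mid`. The transcript filter keeps masked length ≥ 200 bp and
divergence ≤ 20%, both inclusive at the boundary.

**Consensus.** Center-star alignment anchored on the longest fragment
(ties broken lexicographically on the canonical strand, making the result
invariant to input order and per-fragment strand flips), majority rule
per column, ties by fixed base order A < C < G < T, columns with fewer
than two supporting fragments emit N. Fragments shorter than 100 bp are
dropped; fewer than two surviving fragments yields a `remnant_only`
status rather than a consensus. At most 60 fragments (longest first)
enter the alignment — beyond that the consensus is numerically settled
and additional fragments only add cost.

**TIRs.** Best local alignment between the 5′ terminal window and the
reverse complement of the 3′ terminal window (default 100 bp each),
reported at ≥ 10 bp and ≥ 80% identity. These defaults are deliberately
permissive; the measured null rate on random 600-bp sequence is ≈ 0.25
at defaults and ≈ 0.1 at 90% identity, so TIR presence is supporting —
not sufficient — evidence, and the autonomy flag requires the ORF and
catalytic motif as well.

**Dating.** `neutral_rate()` returns a unit-tagged object
(`substitutions/site/year`); `copy_ages()` refuses a bare number, so a
per-My rate can never silently enter the formula. Per-copy dates follow
the two-branch convention `T = k/2r` of the dating literature, with
`branches = 1` available; since divergence from an ancestral consensus
accrues on a single branch, the *entry-time* estimate always uses `k/r`.
Three entry estimators are provided: `p95` (robust upper quantile;
ongoing proliferation), `max` (oldest copy; biased upward by Poisson
noise on `k`), and `mean` (efficient when proliferation is
burst-on-arrival, so that every copy dates the invasion and per-copy
noise cancels instead of inflating the upper tail). The recovery tests
use burst-on-arrival worlds with the `mean` estimator; per-copy age
noise has standard deviation `sqrt(k/L)/r` (≈ 0.5 My at 1,324 sites and
ants-like rates), which is why upper-quantile estimators carry several
times the error of the mean under a burst history. Burst profiling is
single-linkage clustering on the age axis: any spacing at least
`gap_threshold_my` (default 0.1) splits bursts and is reported as a
quiescence gap. Note that per-copy ages are quantized at
`1/(L·r·10⁶)` My (one substitution), so thresholds below that spacing
describe the noise, not the biology.

**IBD and insertions.** Windows are classified by a two-component
Poisson mixture (EM, 200 iterations, degenerate fits fall back to a
fixed ≤ 2 SNPs/window rule). Insertion calls need ≥ 2 reads per side at
mapq ≥ 10 (the floor cannot be lowered), breakpoint clusters within 2 bp,
and a left/right overlap inside the TSD range (default 2–10 bp);
overlaps outside the range become low-confidence records. Calls within
10 bp merge across families; ≥ 2 families makes a locus `common`. The
de novo rate bound divides observed new insertions (or 1, when none) by
`n_individuals × mean IBD fraction`.

# Problem sizes used by the test suite

Recovery tests run at sizes chosen so the full suite completes in a few
minutes while every estimator operates in its asymptotically meaningful
regime: transfer-recovery worlds use 5 species, 200 orthologs × 300
codons, 200 element copies in the focal recipient (burst-on-arrival,
entry 2.5 Mya, r = 3.5×10⁻⁹); the null (vertically inherited) worlds use
2 species, 30 orthologs × 120 codons, 12 ancestral element copies, 100
replicates; the brother-pair survey uses 7 families on an 8-Mb
pseudochromosome with ~50 planted insertions and 5% read noise. The
NG86 oracle comparison covers 500 random alignments up to 200 codons;
the studentized-range oracle integrates over a grid of (q, k, df) with
Gauss–Legendre quadrature.

# Known limitations

* The Ks engine implements NG86 with Jukes–Cantor correction only; model
  averaging and ML codon models are out of scope, and the method label is
  recorded in every record so mixed analyses cannot be confused.
* Nucleotide diversity uses standard pairwise corrected distances
  (p/JC/K2P) with pairwise deletion, not composite-likelihood distances;
  near zero and for ordering across elements the two agree, which is the
  regime in which π is used here.
* The consensus stage substitutes deterministic majority-rule for
  assembly-based reconstruction; for heavily rearranged or nested copies
  an assembler may differ.
* Presence scanning is a seeded-alignment heuristic adequate for
  clean assemblies and the simulator's genomes; it is not a replacement
  for a full local-alignment search engine on gigabase genomes.
* The insertion caller consumes junction-read tables; it does not
  realign reads, and its precision on real data depends on the upstream
  mapper's mapq calibration.
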