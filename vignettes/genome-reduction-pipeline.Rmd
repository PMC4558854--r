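---
title: "Classifying genome-reduced symbionts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying genome-reduced symbionts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panevo)
```

## The problem

Host-associated bacteria shed genes as they adapt to a symbiotic
lifestyle.  Placing such genome-reduced lineages relative to their
free-living relatives, and quantifying what they have lost, is a
comparative-genomics exercise with a standard shape: define orthologs
between annotated CDS sets, reconstruct the core genome of each candidate
genus, intersect those cores into a proxy for the gene repertoire of the
genera's last common ancestor (LCA), and count which ancestral core genes
the symbiont still carries.  In parallel, a reference pan-genome over all
isolates supports presence/absence scans (including targeted queries for
virulence and secretion-system genes), a concatenated gene-by-gene
alignment supports a whole-genome phylogeny, and pairwise dN/dS over
ortholog pairs summarizes the mode and depth of sequence divergence.

`panevo` implements this pipeline end to end for desk-scale data, plus a
codon-level genome-evolution simulator with recorded ground truth so that
every stage has a parameter-recovery test.

## Orthology and cores

**Similarity search.** Database search heuristics are replaced by exact
affine-gap local dynamic programming (match +2, mismatch −3, gap open 5,
gap extend 2, so a gap of length $L$ costs $5 + 2L$), computed in
compiled code.  Hits below a minimum score (default 50, the stand-in for
an E-value cutoff) are discarded.  Percent identity is matches over
aligned columns, gap columns included; query coverage is the fraction of
the query spanned by the local alignment.  Both orientations of the
subject are tried and the better kept.  Non-ACGT characters are accepted
and score as universal mismatches, so draft-genome Ns never abort a run.

**Seeding.** All-vs-all search aligns only pairs that share at least
`min_words` (default 4) distinct 11-mer words, with low-complexity words
(fewer than three distinct bases) masked — the same idea as BLAST's word
seeding plus DUST masking.  The margin is wide: in simulations at ~6%
nucleotide divergence true ortholog pairs share at least ~33 words while
unrelated CDS essentially never reach 4 (codon-usage bias makes one or
two chance collisions common, which is why the threshold is not 1).  The
trade-off to know about: beyond roughly 25–30% nucleotide divergence the
seed filter, like any word-based heuristic, starts losing genuinely
alignable pairs.  `align_params(min_words = 1)` restores exhaustive
sensitivity at quadratic cost.

**Reciprocal best hits.** A pair $(x, y)$ is an ortholog pair iff $y$ is
$x$'s single best hit and vice versa; ties break by higher identity, then
lexicographically smallest subject locus, making tables deterministic.
The construction is one-to-one by definition, which is also how paralogy
is deliberately flattened: presence/absence of an ortholog is recorded,
copy number is not.

**Cores and the LCA.** A genus core is anchored on a caller-designated
reference genome: the loci with an RBH partner in every member.  Anchoring
on a reference keeps intersections well defined without multi-genome
ortholog clustering (which is out of scope).  The LCA core of two genera
intersects the two cores through a single RBH "bridge" table between the
two reference genomes and is expressed in the first genus's reference
coordinates.  Loss accounting then splits the LCA core into retained and
lost loci for any target genome, tallying losses by functional category
(uncategorized loci count under the reserved label `"hypothetical"`).
Two invariants are enforced by construction and checked in the tests:
`retained + lost = LCA core` exactly, and the LCA core never exceeds the
smaller genus core.

## Pan-genome

Genes from all genomes are clustered greedily in decreasing length order
(ties broken lexicographically): a gene joins the first existing locus
whose representative it matches at ≥ 70% identity over ≥ 10% of the
*longer* of the two sequences, else it founds a new locus.  Representatives
are therefore maximal-length exemplars, the clustering is a deterministic
partition, and raising either threshold can only split, never merge.
Measuring coverage on the longer sequence is a deliberate choice: it makes
a 30%-length truncated copy merge under a 10% coverage threshold but found
its own locus under a 70% one, which is the behaviour a coverage sweep is
meant to probe; measuring on the shorter would make every perfect fragment
merge at any threshold.  Threshold boundaries are inclusive (≥), so
results are bit-stable at the criterion edge.

Presence/absence scanning re-matches every genome's genes against the
locus representatives under the same criterion, so genomes that did not
contribute to the pan-genome can be scanned too; core loci are those
present in at least `ceiling(prevalence × n_genomes)` genomes (default
prevalence 0.90).  `query_scan()` applies the identical criterion to named
query genes — the virulence-factor use case — reporting best identity and
coverage per genome alongside the presence call.

## Phylogeny

Per-gene multiple alignments are center-star progressive: the center
minimizes the sum of pairwise edit distances, every other sequence is
globally aligned to it, and gaps merge under "once a gap, always a gap".
Center-star is exact for the pairwise steps, deterministic, and entirely
adequate for the within-criterion divergences this pipeline aligns; it is
not a replacement for a general MSA tool on deep or indel-rich data.

Concatenation records a partition map (0-based half-open column
intervals).  The `drop-incomplete` policy keeps only taxa present in every
gene — the gap-free-supermatrix convention for MLSA — while `pad-gaps`
keeps everything.  Distances support p, Jukes–Cantor and Kimura
2-parameter models for nucleotides and p/Poisson for amino acids, always
with pairwise deletion of columns where either taxon is gapped or
ambiguous (pairwise deletion maximizes usable signal in gene-by-gene
matrices).  A correction whose logarithm argument is non-positive is
reported at a configurable cap (default 5) and flagged saturated rather
than propagating `NaN`.

Trees are canonical Saitou–Nei neighbor joining.  A negative pendant
branch length arising at a join is clamped to zero with the deficit moved
to its sister, so path lengths at that join are preserved and all branch
lengths are non-negative; on additive matrices no clamping triggers and
the generating tree is recovered exactly (topology and branch lengths),
which the tests assert for 4–6 taxa and which also pins down the final
three-cluster closure.  Bootstrap support resamples supermatrix columns
with replacement (gene-wise resampling behind a flag), rebuilds the NJ
tree per pseudoreplicate, and reports the percentage of replicates
containing each internal bipartition of the point tree.  ML and Bayesian
inference are out of scope by design; the NJ engine is the package's tree
method and says so.

## dN/dS

Ortholog pairs are aligned codon-aware: translate under the bacterial
genetic code (table 11), align the proteins globally (BLOSUM62, gap open
10, extend 1), back-map gaps onto codons, and drop any codon column
containing a gap, a stop, or an ambiguous base.  Pairs with fewer than 30
surviving codon columns are rejected — a declared, mechanical stand-in for
the usual manual removal of gap-rich, low-quality alignments; genes with
an internal in-frame stop are skipped and logged.

Counting follows Nei–Gojobori (1986).  Per codon, each position
contributes a synonymous-site fraction equal to the number of its three
possible changes that preserve the amino acid, divided by 3; changes to
stop codons count as nonsynonymous, so $S + N = 3 \times$ codons exactly.
Observed differences at codons differing at 2–3 positions are averaged
with equal weights over all minimal mutational pathways, excluding
pathways through stop codons (if every pathway crosses a stop, all are
averaged).  Proportions are Jukes–Cantor corrected,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and a pair is flagged
saturated when $d_S$ exceeds 3.0 or the correction is undefined; $\omega$
is reported only for unsaturated pairs with $d_S > 0$.  The genome-wide
summary reports mean $d_S$ over unsaturated pairs, the saturated
fraction, and the fraction of pairs with $\omega > 1$.

NG86 is a counting method: it ignores transition/transversion bias and
codon frequencies.  Against simulations with κ = 2 the median
$\hat\omega$ is biased downward by roughly 15–20% (transitions are more
often synonymous than the equal-rates site counting assumes); at κ = 1
recovery is within ~10%.  The estimator-validation runs therefore use
κ = 1, isolating the pathway-counting machinery from that known model
misspecification, while the clade-level simulations keep the realistic
κ = 2 default.  A maximum-likelihood codon model would remove the bias
and is deliberately not implemented.

## The simulator

`simulate_ancestor()` draws a repertoire of genes: `ATG` start, no
internal stops, lengths geometric with mean 300 codons (floor 50, cap
1500 — spanning the realistic bacterial CDS range while bounding pairwise
DP memory), codons sampled i.i.d. from the 61 sense codons with
nucleotide weights solved numerically so realized G+C hits the target
(default 0.52, enterobacterial); COG-like category labels are drawn with
"function unknown" most frequent.  `evolve_clade()` then walks a rooted
tree: per branch, each codon evolves under a 61-state continuous-time
Markov chain built from single-nucleotide exchanges (transitions weighted
by κ, nonsynonymous changes by ω, stops unreachable), sampled exactly via
the matrix exponential of the symmetrized generator — no per-event
simulation, so multiple hits are handled exactly.  The chain is scaled so
one branch-length unit is one expected accepted substitution per codon at
the ancestral codon composition; `expected_pairwise_ds()` converts a path
length into expected synonymous substitutions per NG86 synonymous site,
the scale on which saturation is declared.  Start codons are held fixed.
Whole genes are lost per branch with a per-edge probability and gained as
de-novo sequences (never homologous to ancestral loci, so truth labels
stay clean).  Defaults — loss 0.05/branch, gain 10/branch, ω = 0.2,
κ = 2 — describe a mildly reducing, mostly purifying clade.

What the simulator deliberately does not model: intragenic recombination,
rearrangement and synteny, pseudogenization, within-gene indels, GC drift
along branches (the substitution chain's stationary composition is
uniform over sense codons, a second-order effect at the divergences
simulated), and annotation error.  Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is correct under its
own assumptions — not that real draft genomes, with fragmented and
mis-called CDS, will be handled with the same accuracy.

The truth table records, per leaf gene, its provenance (ancestral locus
or branch of gain), and per named clade the true ancestral core — exactly
the intersection of leaf inventories restricted to ancestral loci, which
tests re-derive independently.

## Problem sizes and study conditions

The recovery analyses simulate two genera of three genomes each from a
1,500-gene ancestor (mean length 150 codons in these runs, keeping a full
pipeline execution in the minutes range) with 3% gene loss per branch,
gain 15, ω = 0.2, κ = 2, and a seventh, gene-poor target lineage held at
zero sequence divergence with 12% loss — the configuration under which
core recovery is asserted within ±3% and the target's loss ledger
exactly.  dN/dS recovery uses 300 ortholog pairs of 150 codons at total
divergence 0.6 substitutions/codon for ω ∈ {0.1, 0.5, 1.0} (κ = 1, see
above), and a deep replicate at divergence 3.2 — beyond three expected
synonymous substitutions per synonymous site — where the majority of
pairs must flag saturated.  Oracle checks cover all 61 × 61 codon pairs
exhaustively and 100 random alignments against a naive full-matrix DP
implementation.

## Degenerate inputs and numerical conventions

Empty FASTA files read as empty gene sets; empty genomes scan as all-absent
columns.  A genome pair with no comparable alignment columns is an error in
distance computation, not a silent zero.  All internal coordinates are
0-based half-open; FASTA and TSV output are 1-based where the format
expects it.  Newick output quotes taxa containing metacharacters.  Every
stochastic operation takes an explicit integer seed and restores the
caller's RNG state, so library use never perturbs a session's randomness;
`run_full_pipeline()` is byte-for-byte reproducible from its config, which
the test suite asserts by rerunning and hashing the output bundle.

## Known limitations

Reproducing published counts from deposited draft genomes additionally
depends on the annotation pipeline and search-tool versions used there;
with a different (exact) aligner standing in for a heuristic search, locus
counts on real accessions are expected to land near, not on, published
values.  The RBH definition collapses in-paralogs; the LCA bridge through
a single reference pair can drop loci absent from either reference; the
seed filter bounds sensitivity at deep divergence; and center-star
alignment is a pairwise-exact heuristic, not an ML aligner.  Each of these
is a documented convention rather than a tunable — changing them changes
what the package computes.
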