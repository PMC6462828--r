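---
title: "Constructing full-length allele reference panels from multiplexed long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing full-length allele reference panels from multiplexed long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Highly polymorphic multi-gene loci — the HLA class I genes are the
motivating case — are poorly served by short-read typing: alleles differ by
dense substitutions and indels over several kilobases, and reference
databases catalogue many alleles only partially (often just the cDNA).
Long-read amplicon sequencing can capture each allele end-to-end, but three
practical failure modes stand between raw reads and a reliable allele
panel:

1. **Nested co-amplification.** One gene's primer pair can anneal inside
   another gene's amplicon. Reads from the inner product then dominate a
   naive per-sample assembly and the outer gene's consensus is truncated to
   the inner interval. Separating reads by primer set *before* assembly
   removes the competition.
2. **Excess contigs.** Per-sample assemblies routinely emit more consensus
   sequences than the 1–2 true haplotypes; near-duplicates and truncated
   inner amplicons must be fused and weakly supported artifacts discarded.
3. **Residual consensus errors.** Even deep long-read consensus retains
   occasional errors (mostly in indel-dense or repetitive windows). Each
   sample, however, usually also has accurate short-read (WGS) data, which
   can arbitrate every position where the assembled alleles disagree.

`allelepanel` implements this pipeline — primer-separated assembly,
short-read refinement, and likelihood-based filtering — together with a
synthetic-data generator that reproduces the statistical structure of the
problem, so every stage is testable without access-controlled human data.

## Pipeline model

### Demultiplexing

Each long read carries a 16 bp sample index plus a 5 bp universal linker
ligated to the 5' ends of both primers. A read is assigned to a primer set
only when the set's forward primer hits its 5' window *and* the reverse
primer (reverse-complemented) hits its 3' window in the same orientation;
requiring both primers is what keeps nested inner amplicons out of the
outer gene's bin. Primer presence in a *polished contig* uses the classic
edit-distance < 2 rule (`max_edit = 1`). Raw reads are a different regime:
with indel-dominated errors around 10% per base, a 25 bp primer
accumulates ~2.75 edits on average, so demultiplexing uses its own
tolerance (`read_max_edit = 7`). Unrelated 25-mers sit ~19 edits apart, so
this threshold is permissive to sequencing error yet unambiguous between
sets; ties across sets are broken by total edit distance, then by total
primer length, and remaining ties are left unassigned.

### Assembly

Within each (sample, primer set) bin, reads are first grouped coarsely by
k-mer containment in the longest unassigned read — different genes
co-amplified by one primer set (the deletable pseudogene in the A bin, the
nested inner product in the B bin) separate here because unrelated genes
share almost no 11-mers. Each group is then split into at most two
haplotype clusters: candidate heterozygous columns need a minor-symbol
fraction of at least 0.25 with three or more reads, and a split happens
only when two or more such columns are *linked* (their minor-read sets
overlap at Jaccard ≥ 0.5). Error columns are unlinked, so homozygous
groups are protected; true heterozygotes at ~1% divergence have dozens of
linked columns. A pair of alleles differing at a single position may or
may not split — either way the consensus matches one of the two true
haplotypes, and the genotyping stage can still call both alleles from the
short reads.

Consensus polishing is iterative column-majority voting (deletions count
as symbols, ties keep the template base, insertions carried by a majority
of spanning reads are added) until a fixed point. Column voting has a
known blind spot: in indel-dense windows the votes scatter across
neighbouring columns and junctions, and the iteration can converge to a
self-consistent but wrong local representation. We therefore finish with a
window re-polish: the template is tiled with 16 bp windows (two offset
phases), each window's covered read substrings are extracted (insertions
spliced back in), and the window is replaced by the *center string* — the
candidate minimizing the total edit distance to all observations — when it
strictly beats the current template. Few reads are error-free across a
whole window at 10% error, so plurality voting is fragile there; the
center-string criterion is robust exactly because every noisy observation
still votes for its neighbourhood.

Consensus ends whose coverage falls below `min_coverage_fraction` (default
0.3) of the cluster are trimmed. This is deliberately the mechanism that
reproduces the truncation failure when primer separation is bypassed: with
the nested product at 3× depth, full-length flank coverage sits at ~25% of
a pooled cluster and the flanks are trimmed away, whereas separated bins
keep uniform coverage and assemble full length.

Contigs of one sample and gene are fused by single-linkage at identity
≥ 0.995 over the shorter contig's span, so a truncated inner amplicon is
contained by — and always merges into — its full-length container. The
representative is the preferred member (full-length first, then most
support, longest, lexicographic) with supports summed; the default
identity threshold keeps true heterozygous pairs (~1% apart) separate
while fusing error-bearing duplicates (≤0.5% apart). The deduplicated
survivors across samples form the **draft allele set**.

### Refinement

Draft alleles of each gene are multiply aligned; every maximal run of
columns where any two alleles disagree is a *variant*. Each (allele,
carrier, position) observation is then examined in the carrier's short
reads: reads are mapped to the sample's candidate alleles (ties split
0.5/0.5), the read strings over the position's ungapped footprint are
piled up (a deletion footprint is the flanking-junction; read insertions
are spliced back in), and the observation is **supported** when weighted
depth ≥ `min_depth` (5) and the agreeing fraction ≥ `support_fraction`
(0.8); below `min_depth` it is *unexamined*. A position is corrected only
when every examinable carrier finds it unsupported, all carriers agree on
the same plurality alternative, and the replacement strictly increases
total read support. Corrected alleles that become identical are merged,
carriers united — the **refined allele set** — and per-gene accuracy
(supported / examined) is recomputed; the pipeline treats a decrease as a
hard error. "Examined variants" are counted as (allele, carrier, position)
triples with examinable depth, the only reading under which tens of
thousands of examinations arise from a few hundred variant positions.

The built-in MSA is a center-star alignment to the longest allele
(anchored banded pairwise alignments, insertion columns merged). At ~1%
within-gene divergence a star alignment is effectively optimal, it is
fully deterministic, and its sum-of-pairs score is never below the
star-to-longest baseline; `mafft` can be substituted via
`refine_params(engine = "mafft")` when it is on the PATH.

### Copy number, genotyping and filtering

Short reads are assigned to genes by k-mer containment (orientation
canonicalized — mates arrive on both strands). At deletable loci the
locus-to-normalizer depth ratio is thresholded at 0.25 / 0.75 into 0, 1 or
2 copies; diploid, hemizygous and deleted samples sit near ratios 1, 0.5
and 0, so the midpoint thresholds tolerate ±25% depth noise.

Each sample and gene is genotyped against the refined alleles plus the
database entries: every read is aligned to every candidate (anchored,
banded), a read's likelihood under a genotype is `exp(-λ·d)` with `d` the
smaller of its edit distances to the two alleles (λ = 1; unalignable
reads are capped at a quarter of the read length), and all allele
multisets of the called copy number are scored exhaustively over the
`top_k = 20` pre-pruned candidates. Under this max-over-pair model a
homozygous truth `(a,a)` ties with `(a,x)` for any `x`, since every read
already sits on `a`; ties are broken toward the pair whose alleles
*individually* explain the reads best (smaller summed per-allele total
distance), then lexicographically. In addition, heterozygous genotypes
carry a small penalty (`het_penalty`, 3 edit units): without it a single
error read that happens to coincide with another allele's variant
strictly flips a homozygote to a spurious heterozygote, while a true
heterozygote's minor allele is supported by hundreds of units of
likelihood and is unaffected. For tractability at scale a
deterministic subset of ~400 reads per sample and gene is scored —
at 162 bp that is ~12× coverage of a 5 kb gene, which saturates the
discriminative positions.

A refined allele is kept in the **panel** when it appears in at least one
sample's best genotype; never-genotyped alleles are dropped, and when all
of a dropped allele's carriers were called with one common other allele,
that allele is recorded as its alteration. Panel carriers follow the
genotype calls, and panel-stage variant accuracy lets each sample's reads
compete over its full called pair (database alleles included) — the same
semantics under which filtering improves accuracy rather than merely
shrinking the denominator.

### Characterization

Every panel allele is compared with the same-gene database entries by
overlap alignment (global on the entry, free panel ends). The closest
entry minimizes the edit distance over its own span — cDNA-only entries
are compared on the projected exon concatenation — with ties broken by
fewer exonic edits, then name. Differences within the span are split into
exonic and non-coding using the entry's exon annotation projected through
the alignment; exon haplotypes are translated (standard nuclear code) to
separate nonsynonymous from synonymous changes. The novelty flags then
follow the naming convention: any genomic difference (8-digit), any exonic
difference (6-digit), any nonsynonymous difference (4-digit), with a
cDNA-only closest entry additionally marking the allele as newly
contributing intron sequence. Exon positions are reported 1-based within
the exon and amino acids 1-based in the protein; internal coordinates are
0-based half-open throughout. Flank extension lengths, per-gene means and
counts of variant positions falling outside every database entry's span
(the newly covered regulatory sequence) form the extension report;
genotype calls yield the allele frequency distribution, and population
coverage at 4/6/8-digit resolution counts population calls whose
truncated name matches a panel allele's assigned name.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline is designed for.

* **Gene models.** Four genes (A, B, C and the deletable pseudogene H)
  with the class I eight-exon structure (CDS 1098 bp) embedded between
  regulatory flanks; amplicons span 4.1–5.2 kb. H carries the A set's
  terminal annealing sites (it is co-amplified by the A primers), and the
  C ancestor carries the B set's sites 310 bp inside each end — the nested
  geometry that truncates naive assembly of C.
* **Allele pools.** One random ancestor per gene mutated into the
  requested number of alleles: substitutions at 1% per base plus
  occasional 1–4 bp indels confined to non-exonic regions (expressed
  alleles rarely carry frameshifts, and this keeps the translation frame
  intact for novelty classification). 40% of alleles are *derived*: they
  copy an existing allele and add only a handful of non-coding — or, for
  about a third of them, additionally synonymous exonic — substitutions,
  so the pool contains genuine 4/6/8-digit families the way real allele
  databases do (several alleles per protein, several genomic subtypes per
  coding sequence); without families, name truncation is structureless
  and population coverage would not vary with resolution. Primer
  annealing sites are masked from mutation, emulating primers designed on
  conserved regions. Frequencies are symmetric-Dirichlet; names follow
  `GENE*gg:pp:ss:nn` with fields assigned from protein /
  exonic-nucleotide / genomic equivalence classes.
* **Database.** 70% of pool alleles are cataloged; genomic entries keep
  only short regulatory stubs (280/250 bp), and 15% of entries are
  cDNA-only — panel alleles therefore extend every entry and some
  contribute new introns, as in real reference databases.
* **Long reads.** Full amplicon copies (index + universal + insert +
  reverse-complemented adapter) with per-base mismatch/insertion/deletion
  probabilities 0.01/0.06/0.04 — indel-dominated, assemblable at depth
  ~30 — at 30 reads per amplicon, random strand; the nested inner product
  is emitted at 3× depth.
* **Short reads.** 162 bp pairs at 16× per haplotype (~32× diploid),
  substitution errors at 0.001, Gaussian inserts (350 ± 50). Fragments
  start uniformly across and beyond the locus and reads are clipped at its
  boundary (≥50 bp overlap kept), modeling reads extracted from a WGS
  alignment around the locus: coverage stays uniform through the termini,
  which matters because terminal consensus errors are only correctable if
  the termini are examinable.
* **Deletions.** Each H haplotype is deleted independently with
  probability 0.3 (close to the haplotype frequency implied by ~12%
  homozygous deletions among samples).

What the generator deliberately does *not* model: PCR chimeras, quality
score structure (flat profiles; the pipeline ignores qualities), barcode
cross-contamination, and homology between different genes (ancestors are
independent, so gene classification is easier than for real paralogs).
Passing tests therefore demonstrate the pipeline's logic under the
assumed error model, not performance on real paralogous loci.

## Numerical choices and determinism

* All coordinates are 0-based half-open internally; BED on disk.
* Every stochastic step takes an explicit seed; a fixed seed yields
  byte-identical outputs (the compiled error process draws from R's RNG).
* Alignment is anchored banded edit distance: exact k-mer anchors give the
  diagonal (interpolated between read halves), the band (60 for long
  reads, 20 for short) only absorbs the random-walk part of indel drift.
  Ties in the dynamic program prefer diagonal, then read-insertion, then
  deletion; hit selection is leftmost; all downstream tie-breaks (cluster
  representatives, fuse survivors, genotype pairs, closest entries) are
  by explicit deterministic keys, so identical inputs give identical
  panels.
* Scale: the bundled analyses use 30 samples × 20-allele pools at depth
  30 (the zero-error reference run and the acceptance script) and 12
  samples × 12-allele pools for the three-seed noisy recovery suite;
  these sizes exercise every code path (nesting, deletions, homozygotes,
  cDNA-only entries) while keeping a full run in minutes on one core.

## Known limitations

* Gene ancestors are independent random sequences; real class I paralogs
  are ~85–95% similar, which would stress gene classification and
  short-read gene assignment more than the simulation does.
* The refinement can only correct positions where assembled alleles
  disagree; an error made identically by *every* allele of a gene is
  invisible to it (the same blind spot the examined-variant definition
  implies).
* Base qualities are ignored throughout (flat pileup weights).
* The exhaustive diploid likelihood is a transparent stand-in for a full
  variational genotyper; margins are meaningful for ranking, not
  calibrated probabilities.
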