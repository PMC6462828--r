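# allelepanel

Builds full-length, quality-refined allele reference panels for
multi-gene loci — modeled on the HLA class I genes — from multiplexed
long-read amplicon sequencing plus per-sample short-read (WGS) data, and
characterizes the resulting panel against a known-allele database.

It is aimed at groups producing locus-specific reference panels from
amplicon long reads: the kind of project where each sample contributes
one or two 4–5 kb haplotypes per gene, primer sets cross-amplify each
other's loci, the allele database is incomplete (some entries cDNA-only),
and per-sample short reads are available to validate the assembled
sequences.

## The method

The pipeline has three parts:

1. **Primer-separated assembly.** Long reads are demultiplexed by sample
   index (16 bp, edit distance ≤ 2) and by primer set — a read must carry
   the set's forward *and* reverse primer. Separating reads by primer set
   before assembly prevents nested co-amplified products (one gene's
   primers annealing inside another gene's amplicon) from truncating the
   outer gene's consensus. Within each bin, reads are clustered into
   haplotype groups (linked heterozygous columns), polished into consensus
   contigs (iterative column majority plus a center-string window
   re-polish), classified to genes by longest mapped fragment against the
   database, fused per sample and gene (identity ≥ 0.995; contained
   truncations always merge into their full-length container), and
   deduplicated across samples into the **draft allele set**.

2. **Short-read refinement.** For each gene, variants are the maximal
   multiple-alignment column runs where draft alleles disagree. Every
   (allele, carrier, position) observation is examined in the carrier's
   short reads; an observation is *supported* when weighted depth ≥ 5 and
   ≥ 80% of reads agree. Positions unsupported in every examinable
   carrier, with a common alternative that strictly increases read
   support, are corrected; alleles made identical are merged into the
   **refined allele set**, and per-gene variant accuracy
   (supported/examined) must not decrease.

3. **Likelihood filtering and characterization.** Copy number at
   deletable loci comes from locus/normalizer depth ratios (0/1/2 at
   thresholds 0.25/0.75). Each sample is genotyped by exhaustive diploid
   likelihood over refined + database alleles: a read's likelihood under
   a genotype is `exp(-λ·d)` with `d` its smaller edit distance to the
   two alleles. Refined alleles appearing in at least one best genotype
   form the **panel**; each panel allele is then aligned to its closest
   database entry and classified as novel at 8/6/4-digit resolution
   (genomic / exonic / nonsynonymous differences, with cDNA-only closest
   entries marking newly contributed introns), and flank extensions,
   allele frequencies and population coverage are reported.

A first-class synthetic-data module generates allele pools, an incomplete
reference database, diploid truth genotypes, indel-dominated long reads
(with the nested co-amplification geometry and a deletable locus) and
boundary-clipped short reads, so the whole pipeline is testable end to
end without restricted human data.

## Worked example

Simulate the default study conditions — 30 diploid samples, four genes
(A, B, C and the deletable pseudogene H) with 20-allele pools at 1%
divergence, long reads at depth 30 with mismatch/insertion/deletion rates
0.01/0.06/0.04, 162 bp short-read pairs at ~32x diploid — and run the
full pipeline:

```r
library(allelepanel)

ds  <- simulate_dataset(sim_config(), seed = 1)
run <- run_simulated(ds)
run
#> <panel_run>
#>   draft alleles:   125
#>   refined alleles: 84
#>   panel alleles:   54
#>   draft    mean variant accuracy: 99.9% (121091 examined)
#>   refined  mean variant accuracy: 100.0% (119404 examined)
#>   panel    mean variant accuracy: 100.0% (99978 examined)

evaluate_run(run, ds)
#> # A tibble: 1 x 4
#>   truth_recovery panel_exact genotype_concordance copy_number_accuracy
#>            <dbl>       <dbl>                <dbl>                <dbl>
#> 1              1           1                    1                    1
```

Reading the numbers: per-sample consensus errors make the draft set much
larger than the set of distinct true alleles (125 drafts); short-read
correction collapses it to 84 refined alleles, and the genotype filter
selects the 54-allele panel — exactly the set of distinct truth alleles
carried by the cohort, every one recovered base-perfect. All sample/gene
genotype calls match the truth pair, and every copy-number call at the
deletable locus is correct. Variant accuracy — the fraction of examined
(allele, carrier, position) observations supported by the carrier's short
reads — rises from 99.9% (draft) to 100% (refined and panel), the
monotone improvement the refinement stage is designed to produce.

Downstream summaries are ordinary tibbles:

```r
generics::tidy(run)        # one row per panel allele: closest database
                           # entry, exonic/non-coding distances, flank
                           # extensions, 8/6/4-digit novelty flags
generics::glance(run)      # one-row run summary
run$extension_stats        # per-gene mean lengths + novel flank variants
plot_accuracy(run$accuracy)
plot_allele_distribution(run$distribution, run$entries)
```

A thin command-line front end (`inst/cli/allelepanel.R`) exposes `sim`
(write a dataset directory: FASTA/BED/FASTQ/TSV) and `run` (run the
pipeline on such a directory and write the panel FASTA, genotype TSV and
JSON reports).

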