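# scattervc

Scatter-gather parallel small-variant calling for whole genomes, in R.

Variant calling is local — a call at one position depends only on the reads
covering it — yet standard callers walk whole alignment files serially.
`scattervc` turns the locality into parallelism the way large-cohort
pipelines do:

1. **split the reference** into pieces: each chromosome is tiled by
   disjoint *core* intervals of `core_size` bases, and each piece carries a
   flanking *pad* of overlap longer than the sequencing reads;
2. **split the alignment files** to match: a sorted SAM is partitioned into
   one file per (piece, sample), keeping every read whose reference span is
   fully contained in the padded window, with positions remapped to
   piece-relative coordinates;
3. **call variants per piece**, concurrently, with a deterministic built-in
   pileup SNV caller or any external caller invoked through a
   `{ref} {bams} {out}` command template;
4. **lift and merge**: per-piece VCFs are lifted back to absolute
   coordinates, overlap-zone duplicates are resolved by *core ownership*
   (a variant is kept only by the piece whose core contains its start), and
   everything is merged into one sorted VCF.

Because the pad is at least as long as a read span, the pileup at every
core position is byte-identical to the unsplit pileup, so the pipeline is
**transparent**: the merged VCF equals the VCF from calling the unsplit
inputs record for record — same positions, alleles, qualities, genotypes.
That identity is the package's central tested property, not an
approximation.

The built-in caller genotypes from allele fractions (`0/1` for alternate
fraction in [0.2, 0.8), `1/1` at ≥ 0.8, `./.` below 4 reads) and scores
each site with a Phred-scaled binomial tail, QUAL =
−10·log₁₀ P(X ≥ k), X ~ Bin(d, 0.01), for k alternate bases in depth d.

The package also implements callset-concordance metrics for comparing two
VCFs matched on (chrom, pos, ref, alt): **missing rate** (different
variants / |A|), **difference rate** (share of shared sites whose relative
QUAL difference is ≥ 5%), and the Pearson **score correlation** over the
concordant shared sites — plus a synthetic-data module (random reference,
planted diploid SNVs, error-bearing uniform-coverage reads, truth VCF) so
everything above is testable offline.

## Worked example

Simulate a 50 kb sample (40 planted SNVs, 30x coverage, 1% base error),
run the scatter-gather pipeline with 10 kb cores and a 300 bp pad, and
compare against the unsplit baseline:

```r
library(scattervc)

dir <- tempfile("demo")
sim <- simulate_dataset(dir, lengths = c(chr1 = 50000L), n_snvs = 40L,
                        het_fraction = 0.5, coverage = 30, read_len = 100L,
                        err_rate = 0.01, samples = "s1", seed = 42)
cfg <- pipeline_config(overrides = list(core_size = 10000L, pad = 300L))
out <- run_pipeline(sim$reference, sim$sams, file.path(dir, "run"), cfg)

print(out$table)
#> piece_table: 5 piece(s) over 1 chromosome(s) (core_size=10000, pad=300)
#>           piece_id chrom core_start core_end padded_start padded_end
#> 1     chr1:0-10000  chr1          0    10000            0      10300
#> 2 chr1:10000-20000  chr1      10000    20000         9700      20300
#> ...

print(out$partition[[1]])
#> partition_report [s1]: 15000 records; 15000 assigned, 0 unmapped,
#>   0 unassignable; 5 piece file(s)

print(out$variants)
#> variant_set: 41 variant(s), 1 sample(s) [s1]
#>   chrom  pos1 ref alt qual gt_s1 dp_s1
#> 1  chr1   282   C   G  201   0/1    37
#> 2  chr1  3148   A   G  232   0/1    26
#> 3  chr1  3269   A   G  255   1/1    23
#> ...
```

Reads in overlap zones are assigned to both neighbouring pieces (here all
15000 reads were assignable; the per-piece counts sum to slightly more),
and QUAL 255 is the configured cap. Comparing against a single unsplit
calling run over the same inputs:

```r
base <- call_unsplit(sim$reference, sim$sams)
rep <- concordance_report(out$variants, base)
#> missing_rate=0 difference_rate=0 correlation=1
```

— the split pipeline missed nothing, changed no score, and 40/40 planted
sites were recovered (the 41st call is a coincidental error-pileup site,
identical in both callsets).

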