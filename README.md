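# dinuscape

Structural properties of the DNA double helix — Roll, Twist, Slide, Rise,
groove geometry, step stiffness, persistence length — are largely determined by
the local dinucleotide content, and local dinucleotide content is in turn
shaped by sequence repeats: tandem repeats (short units repeated head-to-tail)
and interspersed transposon families (Alu/SINE, L1/LINE). `dinuscape` is for
genome biologists who want to quantify this chain of influence around
functional annotations — CTCF binding sites, promoters, enhancers, genes, TAD
borders — on any genome they can supply as FASTA/GenBank plus interval
annotations (BED, GTF, RepeatMasker `.out`).

## What it computes

1. **Binned genomic maps** (default resolution 1000 bp): overlapping
   dinucleotide counts `n_XY` per bin (forward strand, a step spanning a bin
   boundary belongs to the left bin), nucleotide counts `n_X`, tandem-repeat
   and annotation base coverage, with per-bin valid fractions that flag
   assembly gaps.

2. **Property tracks.** A dinucleotide property model is a vector of 16 step
   values `m_XY`. Per bin, the property is `sum_XY m_XY * n_XY` (or its mean,
   `... / sum_XY n_XY`, the default). A small table of representative models
   ships with the package (`load_model_table()`); any DiProDB-style TSV can be
   substituted.

3. **Null references.** Zero-order (nucleotide-shuffled) expectation per bin

       E[n_XY] = n_X * n_Y / L_seq

   and the first-order Markov expectation for two-unit tandem repeats

       E[n_XY, n >= 2] = n_XY^2 * n_YX / (n_X * n_Y),

   both computed from each bin's own empirical content, plus the genomic
   mean/SD reference.

4. **Environment profiles**: distance-indexed weighted mean and variance of a
   track around anchor annotations, with all annotation interiors masked
   (bins > 50 % masked are discarded; the rest are weighted by their unmasked
   fraction), so clustering of annotations does not bias the profile.

5. **Peak calling**: a far-distance baseline (> 800 kb by default), a central
   z statistic, outward expansion until significance is lost, height and
   width — and a significance *relative to the null-model profile*, which
   cancels peaks that mere nucleotide composition gradients already explain.

6. **Bootstrap map correlation** (50 repetitions x 50 positions, Pearson) with
   a position-shuffled null and a sigma significance level.

7. **Influence decomposition**: each property peak is split exactly into
   per-dinucleotide contributions `m_XY * (f_XY(apex) - f_XY(baseline))` and,
   via repeat-partitioned counts, into per-repeat-class contributions
   (tandem-repeat classes, Alu-like and L1-like families, outside-any-repeat).

A synthetic-genome generator (`genome_spec()`, `insert_repeats()`,
`place_anchors()`) produces genomes with programmable repeat content and
anchor-flank dinucleotide enrichment, together with machine-readable ground
truth — every stage of the pipeline is validated against it.

## Worked example

The bundled toy design: a 2 x 300 kb uniform genome, 40 CTCF-like anchors
whose 3 kb flanks carry a CC/GG enrichment (x1.5, decaying triangularly),
60 AluLike insertions biased into the flanks, and uniformly placed (CA)n and
(A)n tandem repeats.

```r
library(dinuscape)
bundle <- run_pipeline(list(seed = 1))
bundle$peak_table
#>       model detected sign height width_lo width_hi z_center sigma_rel
#> 1 Roll (94)     TRUE    1  0.191     -500     1300    3.205     4.708
#> 2 Twist (1)    FALSE    0  0.000       NA       NA   -0.647     0.497
```

The Roll model shows a positive central peak around the anchors (height 0.191
degrees above the far-distance baseline, central z = 3.2) that the zero-order
reference does not explain (sigma_rel = 4.7); the Twist model, whose CC/GG
steps sit near its average, shows none.

```r
head(bundle$influences[["Roll (94)"]]$dinucleotides, 4)
#>   feature contribution rel_abs_pct pct_of_peak
#> 1      GG       0.1688       39.86       88.24
#> 2      CC       0.1217       28.74       63.64
#> 3      CA      -0.0376        8.88      -19.67
#> 4      TG      -0.0192        4.53      -10.04
```

The decomposition recovers the programmed drivers: CC and GG carry the two
largest influences on the Roll peak (signed contributions sum exactly to the
peak height), while the chain's stationary redistribution gives CA/TG small
opposing contributions. In the repeat table the flank-biased AluLike family
outranks every tandem-repeat class:

```r
head(bundle$influences[["Roll (94)"]]$repeats, 4)
#>   feature contribution rel_abs_pct pct_of_peak
#> 1 outside       0.0762       17.99        39.8
#> 2 AluLike       0.0485       11.46        25.4
#> 3    (G)n       0.0374        8.83        19.5
#> 4    (C)n       0.0334        7.89        17.5
```

`run_pipeline()` also accepts a YAML config (see `default_config()`), writes
all tables as TSV plus a JSON manifest when `outdir` is set, and a thin
command-line wrapper lives at `inst/scripts/dinuscape-run.R`.

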