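# strainmatch

Identify inbred strains (accessions) from sparse, low-coverage SNP genotype
calls by matching them against a panel genotype database — and identify the
two parents of F1/F2 hybrids by windowed matching across the genome.

Germplasm collections accumulate mislabelled, contaminated and replaced
stocks; at ~10% error rates in real collections, routine verification by
cheap, highly multiplexed resequencing pays for itself. At 1–2X coverage a
sample yields only a few thousand reliable SNP calls. strainmatch is built
for exactly that regime: it identifies a strain from a few thousand random
markers, reports *how sure* it is, and degrades gracefully into an explicit
set of statistically indistinguishable candidates when the panel contains
near-identical strains.

## The statistic

For each database strain *a*, over the *n<sub>a</sub>* informative sites
(both sample and strain called), the match probability is the
confidence-weighted fraction of agreeing calls,
*p<sub>a</sub>* = Σ<sub>match</sub> *c<sub>j</sub>* / *n<sub>a</sub>*,
with *c<sub>j</sub>* from normalized Phred-scaled genotype likelihoods (PL)
when present. Under the null "the sample *is* strain *a*", mismatches are
genotyping errors at rate *p* = 0.001, giving the binomial
log-likelihood-ratio statistic

```
L_a = n_a [ p_a ln( p_a / (1 − p) ) + (1 − p_a) ln( (1 − p_a) / p ) ]
```

which is zero when the observed mismatch rate equals the error rate and
grows with evidence against the null. Ratios against the best strain,
*LR<sub>a</sub>* = *L<sub>a</sub>* / *L<sub>best</sub>*, are compared to the
95% chi-squared(1) quantile **3.841**: every strain within the cutoff joins
the reported **ambiguity set** — the strains not significantly different
from the top hit. Samples with many heterozygous calls are flagged as
likely hybrids, and a windowed analysis (default 300 kb tiles) exposes their
mosaic of parental blocks and infers the parent pair.

## Worked example

Everything below is synthetic and reproducible — the package ships its own
panel/query/F2 generator.

```r
library(strainmatch)

# a 50-strain x 50,000-SNP panel containing one near-identical pair
# (S010 and S011 differ at just 10 sites)
panel  <- simulate_panel(panel_spec(n_strains = 50, n_snps = 50000, seed = 11,
            near_duplicate_pairs = list(list(pair = c("S010", "S011"), distance = 10))))
groups <- closeness_groups(panel$db, threshold = 1000)

# a sparse, error-prone query from S010: 2,000 SNPs at error rate 0.001
q      <- simulate_inbred_query(panel$db, "S010", query_spec(n_query_snps = 2000, seed = 99))
scores <- score_sample(q$sample, panel$db)
ambiguity_set(scores)
#>   strain    n         p         L LR
#> 1   S010 2000 0.9993001 0.1008451  1
#> 2   S011 2000 0.9993001 0.1008451  1

interpret_match(scores, q$sample, groups)
#> Verdict: ambiguous_group
#>   calls: 2000  best p: 0.9993  het: 5e-04
#>   ambiguity set (2): S010, S011
```

The query matched its strain — but the 2,000 sampled markers happened to
include none of the 10 sites separating S010 from its near-clone, so both
are reported, with identical statistics: the honest answer at this
resolution. The verdict also notes the set lies within one *closeness
group* (strains below 1,000 pairwise differences), i.e. the identification
is as correct as the panel permits.

An F2 individual is resolved by windowed matching:

```r
f2 <- simulate_f2(panel$db, "S003", "S027", query_spec(n_query_snps = 20000, seed = 5))
infer_parents(window_scores(f2$sample, panel$db, make_windows()), db_groups = groups)
#> Inferred cross: S003 x S027
#>   windows: 135 parent A, 98 parent B, of 399 informative
#>   note: best pair explains 58% of informative windows (heterozygous F2 blocks
#>         are ambiguous by design)
```

135 windows match S003 alone and 98 match S027 alone — the homozygous
parental blocks; the remaining windows are the F2's heterozygous blocks,
which match both parents closely and equally.

## Command line

A thin launcher (installed under `exec/strainmatch`) mirrors the library:

```sh
strainmatch makedb -i panel.vcf -o db            # build both database stores
strainmatch inbred -d db.snpdb.rds -i sample.vcf -o result
strainmatch cross  -d db.snpdb.rds -i f2.vcf -b 300000 -o result
strainmatch simulate -o sim --n-strains 50 --seed 1
```

`makedb` parses the `GT` field of every sample (alleles `0`/`1`, separators
`/` or `|`), skips non-biallelic records, and writes a position-major and a
strain-major store. `inbred` writes a JSON-lines score table and a verdict;
`cross` writes a per-window TSV (plottable as parental-block tracks) and the
inferred parents. Queries may be a single-sample VCF (GT, optional PL) or a
3-column table `chromosome  position(1-based)  genotype` — note this is VCF
coordinates, not 0-based BED. Chromosome lengths default to the *A.
thaliana* TAIR10 assembly and are replaceable with `--chrlen` for any
species.

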