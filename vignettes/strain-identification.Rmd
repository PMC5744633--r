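---
title: "Identifying inbred strains from sparse SNP calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying inbred strains from sparse SNP calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmatch)
```

## The problem

Germplasm collections of inbred lines — *Arabidopsis thaliana* accessions,
*Medicago* HapMap lines, rice or maize landraces — accumulate labelling and
contamination mistakes: tubes get swapped, seeds cross-contaminate during
harvest, stocks get replaced. Low-coverage resequencing is now cheap enough
(hundreds of samples per lane) that every stock can be genotype-verified, but
at 1–2X coverage a sample yields only a sparse, error-prone subset of SNP
calls. strainmatch answers the question: *which strain in a reference panel
is this sample*, with a statistical statement of confidence, from a few
thousand SNPs.

## The matching model

The database holds genotype codes $a_j \in \{0, 1, 2\}$ (homozygous
reference, homozygous alternate, heterozygous; $-1$ missing) for each strain
$a$ at each panel position $j$. A query sample contributes codes $g_j$ with a
per-call confidence $c_j \in (0, 1]$ — the normalized Phred-scaled genotype
likelihood of the called genotype when the VCF has PL fields
($c_j = 10^{-PL_{called}/10} / \sum_i 10^{-PL_i/10}$), and $1$ otherwise.

For each strain the *informative sites* are the shared positions where both
calls are non-missing; over the $n_a$ informative sites the match
probability is

$$p_a = \frac{1}{n_a} \sum_{j:\,g_j = a_j} c_j .$$

Under the null hypothesis that the sample *is* strain $a$, mismatches arise
only from genotyping error at rate $p$ (default $0.001$), so the mismatch
count is Binomial$(n_a, p)$. The likelihood statistic

$$L_a = n_a\left[ p_a \ln\frac{p_a}{1-p} +
   (1 - p_a)\ln\frac{1-p_a}{p}\right]$$

is the log-likelihood ratio of the observed mismatch rate against that null
(binomial coefficients cancel), equal to $n_a$ times the Kullback–Leibler
divergence of Bernoulli($p_a$) from Bernoulli($1-p$). It is non-negative and
zero exactly at $p_a = 1 - p$; boundary values use the $0\ln 0 = 0$
convention, and the implementation returns an exact zero at the null to
avoid a rounding artifact in $1 - p_a$.

Likelihood ratios are taken against the best (smallest) statistic,
$LR_a = L_a / L_{best}$, so the top hit has $LR = 1$. Treating the
log-likelihood-ratio as asymptotically $\chi^2_1$, every strain with
$LR_a \le \chi^2_{1,0.95} = 3.841$ is reported in the **ambiguity set**: the
strains not significantly different from the top hit at 95% confidence. A
well-behaved sample of a database strain yields a singleton set; a pair of
near-identical strains yields a two-strain set, which is the honest answer.

### Flooring the ratio denominator

$L_{best}$ vanishes *continuously* as the top hit's realized mismatch rate
approaches the model error rate, so a raw ratio can explode on differences
far smaller than a single genotype call. Both sides of the ratio are
therefore floored at $L\!\left(\frac{n_a - 1}{n_a}, n_a\right)$ — the
statistic of one mismatched call out of the top hit's $n_a$ sites, the
smallest imperfection the data can resolve. The floor leaves the top hit at
$LR = 1$, is inactive whenever $L_{best}$ amounts to at least one call's
worth of evidence, and (because the floor would itself be scaled) the set is
invariant under replacing $L$ by any positive multiple such as the $2\times$
deviance. At $n_a = 1/p$ exactly, one mismatch *is* the null expectation and
the floor degenerates to zero; the implementation then falls back to two
mismatches. A consequence worth knowing: in small genomic windows (tens of
sites) the floor is large, so window-level ambiguity sets are deliberately
broad — with 15 sites you genuinely cannot tell apart strains that differ at
one of them.

## Verdicts

`interpret_match()` applies, in order:

1. **insufficient_snps** below `min_snps` (default 2,000) sample calls —
   below this, panels with closely related strains are not reliably resolved;
2. **likely_hybrid** when the heterozygosity fraction reaches `het_threshold`
   (default 0.10) — inbred samples are nearly homozygous, so widespread
   heterozygous calls indicate an F1/F2 or an outcross, and the windowed
   cross analysis should be run;
3. **no_match** when the best $p_a$ falls below `match_prob_floor` (default
   0.90) — the sample resembles no database strain (an unknown accession or
   a replaced stock);
4. otherwise **unique_match** or **ambiguous_group** by the size of the
   ambiguity set, the latter annotated with whether the set lies inside one
   *closeness group*.

The paper-facing defaults that have a principled origin are the error rate
($0.001$), the $\chi^2_1$ cutoff ($3.841$), the 2,000-SNP minimum and the
300 kb window; the hybrid trigger (0.10) and the match floor (0.90) are
operational defaults with no canonical value — both are exposed as
parameters everywhere they appear.

## Closeness groups

Two strains that differ at very few sites are mutually confusable at any
realistic query depth. The database builder computes all pairwise difference
counts over jointly non-missing sites and partitions the panel into
connected components of the graph linking pairs below a threshold —
transitive closure, because confusability chains. For the ~10.7-million-site
*A. thaliana* panel the conventional cutoff is 6,000 pairwise SNPs; the
cutoff should be scaled with the marker count of the database at hand (the
synthetic studies below use 1,000 of 50,000 sites). An ambiguity set
contained in one closeness group is still a *correct* identification at the
resolution the panel permits.

## Hybrids and windowed matching

An F2 individual's genome is a mosaic: homozygous-parent-A blocks,
homozygous-parent-B blocks, and heterozygous blocks, expected 1:2:1 per
segregating site across meioses. Genome-wide matching cannot resolve such a
sample — both parents score closely and equally. `window_scores()` therefore
tiles the genome (default: TAIR10 chromosome lengths, 300 kb windows,
non-overlapping half-open intervals) and runs the full matcher independently
in each window. Windows inside a homozygous block match one parent
unambiguously; heterozygous blocks match neither parent exactly and come out
as broad, ambiguous sets — an expected signature, not a failure.

`infer_parents()` selects the pair $(A, B)$ maximizing the number of
informative windows whose ambiguity set intersects $\{A, B\}$ in exactly one
strain, breaking ties towards balanced per-parent support. Candidates are
the union of window-set members and the genome-wide top hits, so the search
stays quadratic in a small candidate list. For a typical F2 roughly half the
informative windows are explained (the het blocks are ambiguous), which the
result notes explicitly. If the weaker parent explains under
`min_parent_fraction` (default 5%) of informative windows the sample is
flagged *not a cross* — the degenerate "pair" of an inbred sample. Windows
need enough informative sites to be stable: below `min_window_snps` (default
10) a window is skipped, and several tens of sites per window are
recommended (at 300 kb that means a query of roughly 15,000+ genome-wide
markers on the *A. thaliana* genome).

When a parent has a near-duplicate in the database, windowed matching cannot
tell them apart; passing the closeness groups to `infer_parents()` reports
the duplicate as an explicit alternative.

## The synthetic-data generator

All tests and the acceptance study run on fully synthetic data from
`simulate_panel()`, `simulate_inbred_query()` and `simulate_f2()`,
reproducible from their seeds.

* **Panels.** Positions are uniform along the chromosomes; per-site
  alternate-allele frequencies are Beta(0.5, 0.5) — a U-shaped spectrum with
  both common and rare variants — and strains are independent draws, giving
  an expected pairwise difference at ~25% of sites. Near-duplicate pairs are
  engineered by copying a strain and mutating an exact number of sites. The
  default study panel is 200 strains × 50,000 SNPs, which keeps every
  statistic's behaviour at genome scale while fitting in seconds of compute;
  at that size a confusable near-clone corresponds to ~10 differing sites
  (the truly confusable pairs in real panels differ at 0.002–0.05% of
  sites).
* **Queries.** Coverage thinning is emulated by subsampling sites — the
  quantity that matters to the matcher is the marker count, which
  subsampling controls directly. Each call is flipped to a uniformly chosen
  other code with probability $\varepsilon$ (default 0.001) and annotated
  with PL triples (called genotype 0, others `pl_alt`, default 40). The
  `variant_only` option restricts subsampling to sites where the individual
  carries an alternate allele, emulating a single-sample variant caller's
  output, which reports no homozygous-reference positions; this matters for
  the hybrid screen, because hom-ref calls dilute the heterozygosity
  fraction.
* **F2s.** Per chromosome, two gametes are built independently with
  Poisson-distributed crossovers (default mean 1.5 per chromosome, positions
  uniform, no interference) alternating parental origin. The diplotype state
  is the number of gametes carrying parent A; genotypes follow the state and
  the parents' codes, with heterozygous calls only at segregating sites.

What the generator does **not** model: linkage disequilibrium and population
structure among panel strains (real confusable groups are geographic, not
random), read-level error (quality-dependent, strand-biased), reference
bias, crossover interference, and segregation distortion. Consequently the
synthetic studies demonstrate the statistics' behaviour under their own
assumptions; the error rate realized in real low-coverage calls should be
checked against the `error_rate` parameter rather than assumed.

### Variability of F2 heterozygosity

Because the heterozygous state flips at every crossover breakpoint of either
gamete, a *single* F2 genome consists of a few large alternating blocks per
chromosome. The genome-wide heterozygous fraction at segregating sites is
therefore 0.5 only in expectation; across individuals it varies widely (a
standard deviation around 0.1 with five chromosomes and ~1.5 crossovers
each), and individual genomes commonly land anywhere between 0.3 and 0.7.
This is real biology, not generator noise: Mendelian 1:2:1 holds across
meioses, not along one linked genome. Two practical consequences: the
hybrid-screen threshold must stay permissive (0.10 on variant-only calls),
and any per-individual check of "heterozygosity ≈ 0.5" needs a wide
tolerance, while across-individual averages converge quickly.

## Numerical and format choices

* Genotype codes are fixed integers (0/1/2/−1); VCF `GT` values accept `/`
  and `|` separators identically; multi-allelic and non-SNP records are
  skipped and counted; duplicate positions keep the first record.
* The positional-table query dialect is **1-based** (chromosome, position,
  genotype), matching VCF coordinates — deliberately *not* 0-based half-open
  BED, since the tool matches VCF positions.
* Chromosome names are normalized by stripping a `chr`/`Chr` prefix on both
  database and query — naming mismatches are the most common cause of "no
  shared positions".
* The database persists as two serialized stores with complementary layouts
  (position-major for positional scans, strain-major for per-strain access);
  either store alone reconstructs the database, persisting is deterministic,
  and a persist–load–persist cycle is byte-identical.
* Heterozygous sample calls match only heterozygous database codes — exact
  code equality, no half-credit — the simplest auditable rule, with marginal
  impact on inbred panels.
* Ties in $L$ keep database order; tied strains appear in the ambiguity set
  together regardless.

## Problem sizes

The bundled studies use: a 200-strain × 50,000-SNP panel with 200 queries of
2,000 SNPs for self-identification; a 50-strain panel with one engineered
near-duplicate pair (10 differing sites) and 100 queries for ambiguity
behaviour; and 20 simulated F2s on the TAIR10 chromosome lengths (~399
windows at 300 kb, 20,000-SNP queries) for parent recovery. Each study runs
in seconds to a couple of minutes on one CPU; the sizes were chosen as the
smallest at which every statistic operates in its asymptotic regime.

## Known limitations

* Diploid, biallelic markers only; the binomial model does not extend to
  polyploids without changing the likelihood.
* Contaminated (mixed) DNA is not deconvolved; it typically surfaces as
  `no_match` or `likely_hybrid`.
* F1 vs F2 discrimination is not attempted beyond the heterozygosity
  heuristic.
* Very sparse queries in small windows produce deliberately broad sets (see
  the floor discussion); window-level conclusions need adequate density.
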