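---
title: "Methods: phasing, divergence and dosage compensation on a neo-sex chromosome"
author: "neosexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasing, divergence and dosage compensation on a neo-sex chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosexr)
```

## The scientific setting

In birds, females are the heterogametic sex (ZW). Once a chromosomal region
stops recombining between Z and W — for instance after an autosome fuses to
the ancestral sex chromosome and becomes a *neo-sex chromosome* — the
W-linked copies of its genes (the W *gametologs*) start to degenerate:
deleterious amino-acid changes accumulate, GC-biased gene conversion no
longer counteracts AT-drift, and eventually W copies are deleted outright.
Because avian dosage compensation is incomplete, a female whose W copy is
degraded or lost does not automatically double her Z expression; the
female-to-male expression ratio of such genes is expected to decline toward
the no-compensation floor of 50%.

`neosexr` implements the full inference chain for this question from
sex-labelled data — diploid genotype calls of ZZ males and ZW females
against an outgroup reference, per-exon DNA read counts, and an RNA-seq
count matrix — and couples it to a generative model with recorded ground
truth so that every stage is testable end to end without external data.

## The generative model

Each gene starts as a random coding sequence (ATG plus sense codons) and
evolves along the three-taxon topology (outgroup, (Z, W)): first the
outgroup branch (`t_outgroup` expected proposals/site) and the shared
proto-gametolog branch (`t_outgroup - t_sexlinked`), then Z and W
independently for `t_sexlinked`. Substitutions are *proposed* uniformly per
site with a transition/transversion weight `kappa` and *accepted* with
probability 1 when synonymous and `omega_<lineage>` when non-synonymous;
proposals creating stop codons are rejected. On the Z branch only, A/T to
G/C proposals are up-weighted by `gc_bias_Z`, standing in for GC-biased
gene conversion on the still-recombining Z. The proposal–acceptance design
was chosen over full likelihood machinery because it gives direct control
of the realized dN/dS and an event log that downstream estimators can be
scored against exactly.

Two deliberate simplifications: no indels are simulated (the inference path
masks and removes affected codons anyway, so alignment software adds
nothing but noise), and codon frequencies are not parameterized — the
equilibrium base composition is whatever the GC-bias process produces.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `t_outgroup`, `t_sexlinked` | 0.029, 0.025 /site | 22 vs 19 My chronology of the outgroup split vs recombination stop, scaled so the realized Z–W dS is near 0.05 |
| `omega_Z`, `omega_W` | 0.1, 0.5 | strong purifying selection on Z; substantially relaxed, but not free, constraint on the degenerating W |
| `kappa` | 2 | typical avian nuclear transition bias |
| `gc_bias_Z` | 3 | GC-biased gene conversion restricted to the recombining lineage |
| `rate_shape` | 1 (exponential) | per-gene rate multipliers; divergence in such gene sets spans roughly two orders of magnitude across loci, which a constant rate cannot produce |
| `w_loss_fraction` | 0.2 | a minority of genes have lost the W copy outright |
| `mean_depth` | 30 | resequencing-scale coverage; makes the per-sample DP filter a live constraint |
| `expr_mean`, `expr_dispersion` | 500, 0.05 | moderately expressed genes with biological replicate noise |
| `beta_link`, `d_cap` | 1, 0.05 | female suppression fully coupled to W divergence, saturating at the no-compensation floor once dN reaches `d_cap` |
| corruption probabilities | 4 × 0.0125 | ~5% of VCF records corrupted, one probability per masking rule so each rule is separately exercisable |

The expression link is
`female_expr_ratio = 1 − beta_link · min(true_dN_ZW / d_cap, 1) / 2` for
W-present genes and exactly 0.5 for W-deleted genes: one expressed Z copy,
no compensatory up-regulation.

### What the generator does not emulate

Reads and alignment (genotypes are drawn directly from the ZW copy model),
genotyping error beyond the injected record corruption, within-population
polymorphism segregating on Z, gene conversion between gametologs,
expression differences between tissues, and correlated expression across
genes. Passing tests therefore demonstrate that the *inference chain* is
correct under a faithful copy-number and substitution model — not that any
particular biological dataset will meet the model's assumptions.

## Phasing rules

`classify_site()` turns one sex-labelled VCF record into a Z and a W
allele call, applying in order: quality/depth/missing masking (site QUAL
and every per-sample DP are filtered jointly at the same threshold, default
20 — the conservative reading when a single "quality or depth" rule is
stated); indel masking over a reference-length span without coordinate
shift; tri-allelic masking; and the genotype truth table (homozygous
reference everywhere; males homozygous `a` with females identically
heterozygous `a/b` in either orientation; homozygous-by-sex splits).
Females must agree exactly for a W call — with only two W haplotypes in a
2+2 design there is no majority to fall back on — while the Z allele is a
consensus over male alleles plus the alleles of *homozygous* females only:
a female whose W allele is unresolved never votes, so an uncertain W cannot
contaminate Z. Consensus ties mask Z (`z_tie`); any unmatched configuration
masks both. Every call records the rule that fired, and
`phase_transcripts()` aggregates the audit per transcript.

## Coverage-based W-loss detection

Libraries are scaled to the largest library by total aligned reads
(`factor = max(total)/total`), per-exon depth is `factor · count / length`,
and the transcript value is the *unweighted* mean over its exons (the
plain-language reading of a "mean coverage between exons"; length-weighted
means change nothing qualitative at these exon sizes). A transcript whose
female mean is strictly below 70% of the male mean is flagged W-absent —
the expectation for hemizygous females is 50%, so 70% splits the two
hypotheses with room for Poisson noise on both sides. A ratio of exactly
0.70 is retained.

## Divergence estimation

The estimator is counting-based (NG86 style): per-codon synonymous site
fractions enumerate the three single-base changes at each position,
excluding changes to stops from the denominator so `S + N = 3` always
holds; pairwise differences average over all minimal substitution paths
with stop-passing paths excluded (if every path is blocked — possible only
for triple differences — all paths are used and steps are scored by
amino-acid identity); proportions are Jukes–Cantor corrected,
`d = −3/4 · ln(1 − 4p/3)`. A proportion at or above 0.75 flags saturation
and the gene is excluded rather than given a NaN rate; dS = 0 flags the
ratio as undefined rather than infinite. Codon columns containing N, a gap
or a stop in any sequence are removed before counting. This replaces
maximum-likelihood machinery deliberately: every number it produces is
reproducible by exhaustive enumeration at desk scale, and the test suite
holds it to that oracle at 1e-9.

Transcript selection mirrors standard practice for counting estimates:
at least 500 bp of retained alignment, Z–W dS of at least 0.01 (counting
estimates need some silent divergence to anchor the ratio), and the
longest transcript per gene.

The outgroup contrast exploits the topology: Z and W split from each other
*after* the outgroup split, so absent selection both are equidistant from
the outgroup. Equal paired dS with elevated paired dN on the W side is the
signature of functional W degeneration rather than Z adaptation.

## Expression analysis

Counts are normalized with median-of-ratios size factors. Each gene gets a
Wald test of the log2 female/male ratio of normalized group means, with a
pooled method-of-moments negative-binomial dispersion and the delta-method
standard error — a deliberate simplification of shrinkage-based empirical
Bayes machinery, guarded by a null-calibration property test. The p-value
uses a *t* reference with the within-group degrees of freedom: with six
samples per sex the dispersion estimate is noisy, and a normal reference is
measurably anticonservative (about 7.8% of null genes below p = 0.05),
which would violate the calibration guardrail. Genes with all-zero counts
are dropped; genes with a zero mean in one sex are reported with an
infinite fold change but excluded from testing. BH adjustment and the 0.05
significance threshold follow standard step-up FDR control. The log2 ratio
uses a 0.5 pseudocount on both group means so sparse genes stay finite and
deterministic.

One practical caveat surfaced by testing and worth stating: median-of-ratios
normalization assumes most genes are not sex-biased. If the simulated gene
set is *entirely* sex-linked and suppressed, the normalization absorbs the
signal. `emit_expression_counts(background_genes = )` therefore appends
unchanged autosomal background genes, emulating the rest of the genome; the
dosage-baseline experiment below uses a background of 39,000 genes
(sex-linked genes ≈ 2.5% of the genome) where the residual normalization
bias is about one percentage point.

## Integrated statistics

Spearman correlations use average ranks and the t approximation with
`n − 2` df for p-values (the common software default; full permutation
enumeration is available for n ≤ 8). The Wilcoxon signed-rank test drops
zero differences — the conventional default, stated explicitly because no
single convention is universal — and is exact for n ≤ 25 without ties,
tie-corrected normal otherwise. Rank-sum and paired/Welch t-tests are
two-sided throughout. `run_pipeline()` chains all stages with one seed
(each stage draws from a named substream, so stages are individually
reproducible) and writes per-stage artifacts plus a JSON summary that is
byte-identical across reruns of the same configuration.

## Experiment operating points used by the test suite

Problem sizes are chosen so each experiment resolves the effect it is
designed for:

* **Dosage baseline**: 1000 fully W-lost genes embedded in 39,000
  background genes, NB dispersion 0.05, 6+6 samples; the mean normalized
  female/male ratio of the sex-linked set is checked against 50 ± 2%.
* **Phasing**: the 81-configuration genotype truth table is enumerated
  exhaustively against an independent oracle; sequence recovery is checked
  on 50 genes × 500 codons at ~5% record corruption.
* **Outgroup contrast**: 20 replicate simulations of 200 genes at
  `omega_W = 0.5 > omega_Z = 0.1` with `gc_bias_Z = 1`, isolating the
  selective asymmetry from the compositional one.
* **GC erosion**: 20 replicates of 300 genes at a strong-conversion,
  longer-divergence operating point (`gc_bias_Z = 6`,
  `t_sexlinked = 0.05`). At the package defaults the effect has the right
  sign but a 20-replicate experiment would be underpowered for the
  ratio–divergence correlation; the experiment is therefore run where its
  a priori power is adequate, and the defaults are left untouched.
* **Expression–divergence coupling**: 20 replicates at n = 64 W-present
  genes, the scale at which the negative Spearman correlation between
  log2 F/M and dN must be detectable.
* **FDR control**: 20 replicate null simulations of 2000 genes.

## Known limitations

The phaser assumes fixed differences between Z and W within the sampled
individuals; segregating Z polymorphism would appear as discordance and be
masked (conservative, but it discards sites). The counting dN/dS estimator
ignores the transition bias when counting sites, which compresses ratio
estimates by roughly 10% at `kappa = 2`; parameter-recovery tests bound
this bias. The coverage filter reads copy number from the female/male depth
ratio only and will misclassify genes with strong mappability artefacts.
The expression model tests each gene marginally; correlated expression or
batch structure is out of scope.
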