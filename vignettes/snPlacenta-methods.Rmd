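---
title: "snPlacenta: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snPlacenta: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `snPlacenta`, the
tunable parameters with their defaults and rationale, what the
synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The scientific setting

Placentas of cloned (SCNT) mouse conceptuses at mid-gestation differ
from IVF controls in several reproducible ways: the immune and
erythrocyte compartments shift while the trophoblast share is stable;
sinusoidal trophoblast giant cells (S-TGC) are over-represented among
trophoblasts; chromatin-modifier genes are upregulated in fetal-lineage
clusters but not in the maternal decidua; non-canonical
(H3K27me3-dependent) imprinted genes are stably upregulated while
canonical (DNA-methylation-dependent) imprinted genes change only
sporadically; X-linked expression is globally reduced in fetal cells
(aberrant Xist expression, X inactivation defect) with a panel of
X-linked genes severely repressed in every fetal cluster; and decidual
stromal cells communicate more strongly with pericytes and endothelial
cells. The package implements each of these analyses against sparse
nucleus × gene count matrices plus strain-informative SNP allele
counts, and ships a generator that plants all of these effects with
known truth.

## The synthetic-data generator

Counts are negative binomial: for gene $g$ and nucleus $i$,
$y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi)$ with dispersion $\phi = 0.3$
(`nb_dispersion`; the standard droplet-UMI noise model) and

$$\mu_{gi} = \beta_g \cdot s_i \cdot \prod_k f_k(g, i),$$

where $\beta_g$ is a log-normal baseline (meanlog 0.5, sdlog 1), $s_i$
a log-normal library factor (`libsize_lognorm`, default meanlog 0,
sdlog 0.3, i.e. ±30% depth variation), and the $f_k$ are the planted
multiplicative effects:

| parameter | default | effect |
|---|---|---|
| `marker_fold` | 8 | marker genes of a nucleus's (sub)type |
| `lr_marker_fold` | 8 | ligand/receptor genes in their home type |
| `x_repression_factor` | 0.7 | X-linked genes (not Xist) in SCNT fetal-origin nuclei |
| `planted_x_fold` | 0.4 | the `n_planted_x_degs` = 30 planted X genes, same nuclei |
| `xist_scnt_fold` | 4 | Xist in SCNT trophoblast nuclei |
| `noncanonical_imprint_fold` | 2 | non-canonical imprinted panel, SCNT non-decidual clusters |
| `canonical_imprint_fold` | 1.5 | a random 30% of the canonical panel, same clusters |
| `chromatin_fold` | 1.5 | chromatin-modifier panel, same clusters |
| `interaction_fold` | 3 | `boost_ligands` (Igf1, Angpt1) in SCNT decidua |

Effect scope follows the biology: X dosage effects are properties of
fetal *nuclei* (so only the fetal half of the mixed immune compartment
is affected), whereas the imprint/chromatin folds are applied at
cluster level to all non-decidual clusters. Composition defaults place
45% of nuclei in trophoblast in both groups, shift immune (8% → 13%)
and erythrocyte (7% → 3%) in SCNT, and give the giant-cell subtypes a
combined 50% of trophoblasts with the S-TGC:P-TGC split moving from
22:28 (IVF) to 30:20 (SCNT).

Allele counts at `n_snps` = 200 informative SNPs have per-SNP Poisson
coverage (`snp_coverage_mean` = 0.1, about 20 informative reads per
nucleus, a realistic yield for strain demultiplexing) and binomial
allele assignment with error `allele_error` = 0.01. Both strains are
treated as homozygous at informative sites (inbred donor vs CD-1-like
surrogate); decidual nuclei are maternal, immune nuclei fetal with
probability `fetal_immune_fraction` = 0.5, all other lineages fetal.
All nuclei are female (cumulus-cell donors are female and the relevant
control comparison is to female IVF placentas), so no sex-inference
stage exists.

Three generator choices deserve explicit defense:

* **Planted X genes have a baseline floor of 2.5, imprinted panels a
  floor of 2.** The planted X panel emulates a set of *detected*
  differential genes, which are by construction expressed, and
  imprinted genes such as H19 and Igf2 are among the most abundant
  placental transcripts; under a raw lognormal draw an essentially
  silent gene can be planted and is then undetectable in the smallest
  cluster, making recovery a lottery over baselines rather than a
  property of the planted fold.
* **Ligand/receptor genes have a fixed low baseline of 0.1 with
  `lr_marker_fold` 8 in their home type.** Signalling genes are
  expression-specific in reality; modelling them as such keeps the
  permutation null cleanly separated from home-pair scores (no
  borderline "half-home" pairs whose significance flips between
  groups) and keeps the SCNT decidual ligand boost a negligible share
  (~0.2%) of the decidual library, so the decidual X:A ratio stays
  unaffected, as it must.
* **One pooled sample per group, no replicate structure.** The number
  of pooled placentas per group is not part of the stated design;
  consequently all between-group tests are nucleus-level and
  pseudoreplication is a documented caveat (see Limitations).

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, spliced/unspliced layers, per-SNP genotyping error structure,
or biological replicate variance. A green test therefore establishes
that the pipeline recovers planted parameters under idealized sampling
noise — not that it is robust to artefacts the generator never
produces.

## Annotation

Cell types are assigned by direct marker scoring rather than graph
clustering plus manual annotation: published cluster labels enter an
analysis only through their annotations, so reimplementing
Leiden/UMAP would add no testable content. The score of nucleus $i$
for panel $T$ is the mean over panel genes of the gene-wise z-scored
log-normalized expression; the label is the arg-max panel, with
`"ambiguous"` returned when the top two scores are within `margin`
(default 0.1 z-units) and lexicographic tie-breaking for exact ties.
z-scores are computed across all nuclei pooled over groups, so group
effects shift scores without reordering nuclei within a type.
Trophoblast subtypes are scored the same way, restricted to
trophoblast nuclei (z re-centred within the compartment, where the
subtype contrasts live). Ambiguous nuclei are excluded from all
composition denominators and reported separately. Fixture panels carry
10 markers per major type and 6 per subtype — with 4–5 markers the
assignment noise leaks a few percent of the dominant trophoblast class
into the small erythrocyte cluster, which measurably dilutes that
cluster's fold changes.

## Origin classification

Maternal/fetal origin uses pooled per-nucleus allele totals and a
uniform-prior two-hypothesis binomial likelihood (see README for the
formula). `min_coverage` = 5 and τ = 0.99 balance call rate against
error on the synthetic benchmark; both are CLI-exposed. With ε = 0 the
likelihoods are degenerate and the classifier returns truth whenever
any read is observed; nuclei with reads from both strains under ε = 0
are ambiguous by construction.

## Differential expression

The Wilcoxon rank-sum test is implemented in the package (the
figure-level statistic of the emulated study): midranks for ties,
exact two-sided p by complete enumeration when both samples have ≤ 10
observations without ties, otherwise a normal approximation with
tie-corrected variance and 0.5 continuity correction. BH adjustment is
applied within cluster, matching the per-panel presentation of such
results. Fold changes are `log2((mean_SCNT + 1)/(mean_IVF + 1))` on
the CP10K scale; the pseudocount stabilises zero means. Tests are
two-sided throughout. Significance stars use the conventional ladder
(0.05, 0.01, 0.001, 0.0001); the emulated study's legend prints the
same symbol for two thresholds, which is an apparent typo.

## X dosage

The X:A ratio is computed on raw counts ("reads"), making it invariant
to depth; Xist is included by default (no exclusion is part of the
emulated computation) with `exclude = "Xist"` available because Xist
upregulation inflates the X sum against the repression signal. The
"consistently changed X genes" summary requires, in every fetal
cluster (trophoblast, erythrocyte, endothelial, pericyte,
mesenchymal), q < 0.05 **and** |log2FC| ≥ 0.5 with a common direction.
The effect-size term is essential, not cosmetic: a chromosome-wide
dosage factor of 0.7 is a real effect at every X gene, and with
thousands of nuclei the rank-sum test detects it everywhere, so a
q-only criterion would return the whole chromosome; the 1.4-fold
threshold (a standard single-cell DEG convention) separates severe
gene-level repression (log2FC ≈ −1 for the planted panel) from the
mild global shift (≈ −0.4). The decidua is maternal and the immune
cluster is a maternal/fetal mixture, so neither belongs in the
required-cluster set. Positional spread along X is a KS test of gene
starts against uniform over the chromosome length (mm10-like
constant).

## Interactions

Communication scores are mean normalized ligand expression in the
sender times mean normalized receptor expression in the receiver — a
deliberate, documented simplification of published communication
tools; the package's claims are about this scoring, not about
reproducing any tool's numerics. The null permutes type labels across
nuclei (`n_perm` = 1000), giving `p = (1 + #{perm ≥ obs})/(1 + n_perm)`
with minimum `1/(n_perm+1)`; significance is p < 0.05 without
multiplicity correction (common practice in the genre; `bh_adjust` can
be applied to the p column). Pairs need ≥ 10 nuclei per type.
Information flow per pathway is the sum of its significant scores;
relative flow normalizes to 1 within group. Differential networks
difference the per-(sender, receiver) significant-pair counts and
summed strengths.

## Quality control and normalization

QC removes nuclei with < 200 detected genes or totals outside
[500, 50000] — ordinary snRNA-seq practice; the thresholds behind the
emulated study's nucleus counts are unstated, so its printed post-QC
numbers are not reproducible and are not a target. No
mitochondrial-fraction filter is applied: nuclei contain few
mitochondrial transcripts and the generator produces none; a mito
panel parameter is accepted but inert. Normalization is CP10K + log1p.

## Numerical choices and degenerate inputs

Zero-variance genes contribute zero to marker scores; zero-coverage
nuclei have undefined allele fraction and posterior 0.5; a zero
autosomal sum flags the X:A ratio `NA`; all-identical Wilcoxon input
returns p = 1 with a warning; clusters under `min_cells` = 20 per
group are skipped from DE with a warning; an empty dataset
(`n_nuclei_per_group = 0`) is valid everywhere upstream of the tests.
BH preserves input order and propagates `NA`. All randomness flows
from a single config seed through a private RNG scope, so equal seeds
give byte-identical datasets and pipeline outputs.

## Calibration

Under a null configuration (all folds 1, identical composition
vectors) the group label is exchangeable by construction: per-gene
Wilcoxon p-values are uniform (KS-tested in the acceptance suite), and
composition and interaction false-positive rates sit at the nominal
5% ± 3% over replicate simulations. The generator-consistency check
for the X:A statistic runs with `planted_x_fold = x_repression_factor`:
with the default 30-gene 0.4× panel the chromosome aggregate is pulled
to ≈ 0.61 by construction, so the global factor is only recoverable
from the ratio when it is the only X effect.

## Known limitations

* Nucleus-level composition and DE tests treat nuclei as independent;
  with pooled placentas this is pseudoreplication and p-values are
  anti-conservative with respect to biological replication. A
  replicate-aware (e.g. Dirichlet-multinomial or pseudobulk) model is
  out of scope because the data model has no replicate structure.
* Marker-score annotation assumes marker panels are informative for
  every type present; novel or absent types surface only as ambiguity.
* The interaction score ignores multi-subunit receptors, mass-action
  kinetics and spatial constraints.
* ICR methylation handling is a threshold classifier on supplied beta
  values (0.25/0.75, conventional); bisulfite processing is out of
  scope.
* The allele model assumes homozygous strains; heterozygous informative
  sites and doublet detection via mixed allele fractions are possible
  extensions, not implemented.
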