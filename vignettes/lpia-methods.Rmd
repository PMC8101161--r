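---
title: "Latent pathway identification: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent pathway identification: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpianet)
```

## The problem

Classical overrepresentation analysis ranks a pathway by how many
differentially expressed genes (DEGs) it contains relative to its size.
That view misses *latent* pathways: gene sets whose members are not
unusually enriched, but which sit at the center of the transcriptional
response because they share responding genes with many biological
processes. lpianet implements latent pathway identification analysis
(LPIA), which ranks pathways by their position in a DE-weighted
pathway–pathway network instead of by raw enrichment, alongside the
classical hypergeometric enrichment statistics for comparison.

## The model

Three inputs define the analysis: a collection of pathways $P$ (e.g.
KEGG), a collection of biological-process terms $G$ (GO-BP), and a DEG
table assigning each gene $x$ a differential-expression magnitude
$\mathrm{DE}_x$ (by default $|\log_2 \mathrm{FC}|$). Both collections are
first restricted to the DEG universe, so set sizes, intersections and
unions below count DEGs only; sets sharing no DEG drop out. This follows
from the construction rule that a pathway–term pair enters the graph only
when it shares at least one DEG, and it makes the weights independent of
how many non-responding genes an annotation happens to carry.

**Bipartite weighting.** Every pathway $p$ and term $g$ with
$g \cap p \neq \emptyset$ is joined by an edge of weight

$$W_{gp} \;=\; \frac{|g \cap p|}{|g \cup p|} \;\times\;
\mathrm{median}\{\mathrm{DE}_x : x \in g \cap p\},$$

the Jaccard overlap of the two gene sets scaled by the typical response
strength of their shared genes. The median of an even-sized multiset is
the mean of its two middle values. Because the Jaccard index is at most 1,
no weight can exceed the largest DE magnitude.

**Projection.** The two-mode graph is collapsed onto pathways:

$$A_{ij} \;=\; \sum_{g} W_{g p_i}\, W_{g p_j}, \qquad A_{ii} = 0 .$$

Two pathways are strongly coupled when they co-occur with the same
GO terms through strongly responding shared genes. $A$ is symmetric and
nonnegative by construction; multiplying all DE magnitudes by $c$ scales
$W$ by $c$ and $A$ by $c^2$ without changing anything downstream.

**Centrality.** Pathway importance is the principal eigenvector of $A$,
computed by power iteration on $A + I$. The unit shift leaves the
eigenvectors unchanged but guarantees convergence for symmetric
nonnegative matrices by breaking potential $\pm\lambda$ oscillation. The
iteration starts from a uniform positive vector, is L2-normalized each
step, and stops when the L2 residual falls below `power_tol`
(default 1e-10, `power_max_iter` 10000); non-convergence is an error, not
a silent result. Eigenvector centrality is only defined up to connected
components, so scores are computed on the largest component (ties broken
by total edge weight); the remaining pathways score 0 and are flagged
`off_component` rather than dropped.

**Significance.** The observed scores are compared against a bootstrap
null: the multiset of DE magnitudes is resampled with replacement and
reassigned to the gene ids while every gene-set membership stays fixed,
and the whole weight–projection–centrality pipeline is rerun per
replicate. This null preserves the annotation topology — how sets overlap
— and asks specifically whether the *placement* of strong responses
drives a pathway's centrality. (Resampling the gene universe instead is
available as `resample = "genes"`; the default is the magnitude
resampling because it isolates the quantity LPIA adds on top of
topology.) Raw p-values use the add-one estimator
$(1 + \#\{b\colon e^{(b)}_i \ge e^{\mathrm{obs}}_i\})/(B+1)$, so the
smallest reportable value is $1/(B+1)$ and a printed `0.00` can never be
a literal zero; `format_pvalue()` renders values at the resolution floor
as `"<..."`. Multiplicity is controlled familywise with step-down
max-statistic adjustment over the joint replicates (the
resampling-based framework of Westfall–Young as formalized by Dudoit and
van der Laan): pathways are ordered by decreasing observed score, each is
compared with the running maximum of the null scores over itself and all
lower-ranked pathways, and monotonicity is enforced down the ranking.
Benjamini–Hochberg on the raw p-values is available as `adjust = "BH"`.
A pathway is called latent when its adjusted p-value is at or below
`alpha` (default 0.05); the selection is ordered by descending score with
id tie-breaks.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `deg_q_threshold` | 0.001 | FDR cut defining the DEG universe |
| `n_boot` | 1000 | bootstrap replicates $B$ |
| `edge_threshold` | 0.1 | strict `>` cut when exporting the network |
| `alpha` | 0.05 | adjusted-p level for calling a pathway latent |
| `de_value` | `abs_log2fc` | per-gene statistic $\mathrm{DE}_x$ |
| `resample` | `magnitudes` | bootstrap null construction |
| `adjust` | `maxT` | multiplicity adjustment |
| `seed` | 20210505 | governs all resampling |

Two defaults deserve comment. DEG calling supports both the permissive
q ≤ 0.05 convention and the stringent FDR ≤ 0.001 one; the package
defaults to 0.001, the stricter convention for deep bulk designs, and the
threshold is an explicit argument everywhere because the choice is a
study-level decision, not a property of the method. The per-gene
statistic defaults to the magnitude $|\log_2\mathrm{FC}|$ because a
pathway's involvement is indifferent to the direction of its members'
regulation; signed `log2fc` (edges with non-positive weight are dropped)
and `neglog10_q` are provided for sensitivity analyses.

For the enrichment module, the background defaults to the union of genes
annotated to at least one set in the tested collection, overridable with
an explicit universe; the chosen background and its size are recorded in
the result's attributes and in the run manifest, since the background is
the single most consequential hidden choice in overrepresentation
statistics. The enrichment p-value is the inclusive upper tail
$P(X \ge k)$, thresholds compare inclusively (`<=`), and the network
export threshold compares strictly (`>`), each matching the convention
its quantity is normally reported with.

## The synthetic-data generator

`synthetic_scenario()` emulates the data structure the pipeline consumes:
a gene universe (default 2000 genes) with a DEG subset (400), pathway
annotations (40 sets of 10–30 DEGs drawn uniformly from the DEG pool) and
GO-BP annotations (120 sets of 8–25 genes). Each GO term adopts a random
parent pathway with probability `base_overlap = 0.6` and takes 30–70% of
its members from it — this co-membership is what gives the projected
network its edges. DE magnitudes are $|N(0, 2)|$, a spread consistent
with the 1–4 absolute log2 fold changes typical of DEGs passing a
stringent FDR cut; q-values are uniforms paired to the magnitudes by rank
within (0, 0.001], plus a 10% margin of above-threshold rows so the DEG
filter is exercised. One pathway is *planted* as latent: it gets an
unexceptional size and no enrichment advantage, but `planted_go_links
= 10` GO terms are forced to overlap it and the shared genes' magnitudes
are multiplied by `planted_lfc_boost = 3`. This realizes the scenario the
method exists for — a pathway whose GO-mediated coupling, not its DEG
count, carries the signal — at a moderate strength: the boost is within
the range of real fold-change variation, and 10 of 120 terms is a minor
fraction of the annotation. `null_scenario()` switches the effect off
(boost 1, links 0), which makes the DE magnitudes exchangeable across
genes — exactly the null the bootstrap resamples, so familywise error
calibration can be measured honestly.

What the generator does *not* emulate: correlated expression noise,
hierarchical GO structure (terms are flat sets, not a DAG), annotation
bias toward well-studied genes, and count-level variance. Passing the
recovery tests therefore shows the statistical machinery works under the
stated generative model, not that any particular biological claim
transfers to real data.

## Verification strategy and problem sizes

Every numerical component is checked against an independent oracle: the
bipartite weights and projection against plain set-algebra/triple-loop
enumeration on random instances (≤ 10 pathways, ≤ 10 GO terms, ≤ 30
genes, 100 seeds), the hypergeometric tail against exact support
enumeration for every parameter tuple with N ≤ 25, and the power
iteration against dense `eigen()` (and igraph's components) on 100 random
symmetric nonnegative matrices up to n = 50, at 1e-8. Bootstrap
calibration uses a 4-gene toy whose $4^4 = 256$ magnitude reassignments
are enumerated exhaustively, so the Monte-Carlo raw p-values can be
compared with their exact values; familywise error is measured over 20
null scenarios at B = 199, and planted recovery over 20 seeds at B = 200.
These sizes keep the full suite at roughly two minutes while leaving each
estimate enough resolution to fail loudly if the machinery breaks.

## Numerical and degenerate-input choices

Ties in the latent ranking break by ascending pathway id, making every
output deterministically ordered. Gene-id matching is exact and
case-sensitive; no alias resolution is attempted. Empty intersections
mean no edge, never a zero-weight edge; a gene set left empty by
restriction is removed. A member gene without a DE record is an error
(it indicates the restriction step was skipped) rather than an implicit
zero. Networks with fewer than two edge-bearing pathways are rejected as
degenerate. All exported files are byte-deterministic: stable orderings,
floats at 6 significant digits, missing annotations as literal `NA`.
Bootstrap and generator RNG state is saved and restored, so library calls
never perturb a session's random stream.

## Known limitations

- Eigenvector centrality on the largest component ignores structure in
  smaller components; flagged, not scored.
- The magnitude-resampling null conditions on the observed annotation
  topology; pathways that are hubs purely by annotation (many forced GO
  links but no magnitude signal) are treated as null, which is the
  intended contrast but not the only defensible one.
- The max-statistic adjustment assumes the null scores are comparable
  across pathways; centrality scores share a common unit-norm scale,
  which supports but does not prove subset pivotality.
- With B replicates no adjusted p-value can fall below $1/(B+1)$;
  at B = 1000 the floor is ~0.001.
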