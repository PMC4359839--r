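---
title: "Predicting lncRNA functions from expression-derived regulatory networks"
author: "lncFunNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA functions from expression-derived regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncFunNet)
```

## The problem

Most long noncoding RNAs (lncRNAs) have no experimentally established
function. A widely used strategy is guilt by association: infer which
protein-coding genes a lncRNA's expression depends on, and transfer the
coherent functions of those genes to the lncRNA. lncFunNet implements this
strategy end to end for RNA-seq derived abundance profiles:

1. **Transcript catalog** — assembled genes are classified against reference
   annotation (pseudogene / noncoding RNA / lincRNA / protein-coding /
   unannotated) by exonic overlap; lncRNAs are the noncoding genes longer
   than 200 bp plus the lincRNAs.
2. **Filtering** — genes expressed in at least 50 samples are retained;
   absent measurements are treated as zero abundance.
3. **Discretization** — each profile is reduced to high/low by a
   mutual-information-preserving collapse of initial quantile bins
   (Hartemink's method).
4. **Network learning** — a Bayesian network over all lncRNAs and coding
   genes is learned by greedy hill climbing with random restarts under the
   BIC score,
   \deqn{\mathrm{BIC}(G, D) = \log L - \frac{d}{2}\log n,}
   where the likelihood factorizes over families
   \eqn{p(u_1,\dots,u_N) = \prod_i p(u_i \mid \mathrm{Pa}(u_i))} and
   \eqn{d} counts free multinomial parameters
   \eqn{d_i = (r_i - 1)\,q_i}.
5. **Regulatory network** — the learned edges touching at least one lncRNA,
   with degree, cis/trans (100 kb window) and differential-expression edge
   statistics.
6. **Function assignment** — for each lncRNA, its linked coding genes are
   mapped onto the maximum component of a protein-protein interaction
   network; pairwise shortest-path distances feed average-linkage (UPGMA)
   clustering; branches of at least 3 genes below a static cut become
   modules; each module is tested for GO-term over-representation with the
   one-sided hypergeometric test, and the lncRNA inherits all terms with
   raw p < 0.05.

All inputs are plain text: GTF annotation, a genes-by-samples FPKM TSV, a
two-column PPI edge list, and a flat gene-to-GO table.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `overlap_*` | 0.90 / 0.90 / 0.90 / 0.60 | inclusive exonic-overlap thresholds of the four ordered classification rules |
| `min_lnc_length` | 200 bp | exclusive length rule for noncoding RNAs (lincRNAs are exempt) |
| `min_samples` | 50 | presence filter; "expressed" means abundance strictly above `min_fpkm` (default 0) |
| `ibreaks` | 4 | initial quantile bins before the information-preserving collapse |
| `target_levels` | 2 | final levels (high/low) |
| `restarts`, `perturbations` | 10, 5 | random-restart schedule of the hill climber |
| `max_parents` | 8 | parent-set bound, capping the \eqn{q_i} blow-up |
| `cis_window` | 100 kb | inclusive midpoint-distance window for calling a link cis |
| `min_module` | 3 | minimum PPI module size |
| `alpha` | 0.05 | enrichment threshold on raw p-values (no multiplicity correction, by design; `adjust = "BH"` is available) |

### Why `ibreaks = 4`

The collapse chooses, per variable, which adjacent initial bins to merge by
maximizing the retained total pairwise mutual information with all other
variables. That criterion is estimated from pairwise joint tables with
`ibreaks`² cells. With cohort-scale sample sizes (n ≈ 60) a 10×10 table has
fewer than one observation per cell; the MI estimate is then dominated by
variance (the spurious-MI scale df/2n approaches ln 2) and early merges are
effectively random, which can lock a variable into a badly placed final cut.
Four initial bins keep roughly n/16 ≈ 4 observations per cell, which is the
smallest table the plug-in estimate supports. With hundreds of samples a
larger `ibreaks` (e.g. 10) is preferable and remains available. A
shrinkage-MI criterion was evaluated as an alternative and discarded: at
this n the shrinkage needed to tame the variance also suppresses the real
signal.

Two further numerical properties of the collapse are worth knowing. The cut
of a profile can only fall on an initial quantile-bin edge, so a profile
whose true high/low proportion is far from every bin edge will carry a few
forced mislabels; and ties in merge loss are broken toward the lower level
pair, making the procedure deterministic. Levels keep their value order
throughout, so level 1 is always "high".

### Search determinism and tie-breaking

Score deltas are computed from the one or two affected families only, and
family scores are memoized across the entire run keyed by (variable, parent
set). Among equal-gain moves the search picks the lexicographically first by
(ADD < DELETE < REVERSE, source id, target id); restarts perturb the
incumbent with seeded random legal moves. Given the data and a seed the
result is fully reproducible. The BIC is likelihood-equivalent, so a single
strong dependency can be returned in either orientation; downstream linkage
is deliberately direction-agnostic.

### Degenerate inputs

Constant expression profiles cannot be discretized and are dropped with a
warning before network learning. lncRNAs whose linked genes do not reach the
PPI network, or number fewer than `min_module`, are reported unannotated
with the reason (`no module`); lncRNAs whose modules hit no term at `alpha`
are reported as `no enrichment`. A flat dendrogram — all linked genes
mutually adjacent in the PPI — is treated as a single candidate branch
rather than cut into singletons, which is the behavior the all-adjacent
case requires.

## The synthetic study conditions

`simulateBundle()` generates every pipeline input with planted ground truth
at the reference scale: 20 lncRNA regulators, 80 protein-coding genes (one
block of 4 per lncRNA), and 60 samples, so the 50-sample presence filter is
exercised near its boundary.

* **Cohort structure.** Each regulator is high in exactly half the samples
  (a balanced permutation), emulating condition-driven regulators in a
  balanced case/control cohort. This also places each true component
  boundary on a quantile-bin edge; with unbalanced marginals the
  quantile-restricted cut would mislabel the binomial imbalance
  (≈ √n/2 cells) per profile, which is a property of the discretization,
  not of the generator.
* **Regulation strength.** Each block gene disagrees with its regulator on
  ε = 10% of samples, stratified half-and-half in each direction so class
  balance is preserved (balanced up/down perturbation). At ε = 0.05 and
  n = 60 a child is an exact copy of its regulator in ~5% of cases, which
  makes regulator and sibling statistically indistinguishable; ε = 0.1
  avoids that degeneracy.
* **Emission.** Levels emit Gaussian FPKM-like values (means 3 and 9,
  sd 1, truncated at zero). Truncation reproduces the zero-inflation of
  FPKM qualitatively; the two components are ~6 sd apart, so emission
  overlap contributes essentially no label error.
* **Annotation.** lncRNAs are 300 bp single-exon genes alternately matching
  the noncoding-RNA and lincRNA annotation; coding genes are 1 kb with full
  coding overlap. Genes are laid out across four chromosomes at 200 kb
  spacing, giving the cis/trans statistics something nontrivial to measure.
* **PPI and GO.** The PPI is a planted-partition graph whose modules are
  exactly the regulator blocks (within-module cliques by default, plus a
  deterministic spanning path per module and bridges between consecutive
  modules, so the graph is connected for every seed). Each module carries
  one dedicated GO term; other background genes are annotated at a 1%
  noise rate — at a background of 80 genes, a 5% noise rate would make two
  co-annotated noise genes inside a 4-gene module hypergeometric-significant
  by construction, i.e. planted-truth precision could not be 1 even with a
  perfect network.

What the generator does **not** emulate: library-size variation, continuous
dosage effects, overlapping modules, hub regulators shared between blocks,
unbalanced cohorts, and annotation incompleteness. Passing the planted-truth
tests therefore demonstrates correctness of the machinery under clean,
identifiable conditions — not expected accuracy on real tissue data, where
networks learned at transcriptome scale are far noisier.

## Problem sizes used in the checks

The package's validation suite runs at desk scale by design: exhaustive
DAG enumeration up to 4 variables (543 DAGs), structure recovery on
10-node networks at n = 2000, UPGMA oracle comparisons up to 12 leaves,
and the full pipeline on the 100-variable default bundle. Learning at the
scale of the motivating application (~10⁴ variables) requires restricting
candidate parents; the search API exposes a blacklist for that purpose but
no automatic restriction heuristic.

## Known limitations

* BIC at small n admits spurious edges (the penalty does not account for
  searching ~N² candidate arcs); the learned network is therefore denser
  than the true dependency structure, and function assignment relies on the
  module stage to shed isolated false links.
* The basic static tree cut is used, not the Dynamic Hybrid variant (no
  PAM-like reassignment of unassigned leaves).
* Enrichment uses raw p-values by default, matching the method this package
  operationalizes; for real analyses the `adjust = "BH"` option is
  recommended.
* GO terms are treated as a flat table; no true-path propagation.
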