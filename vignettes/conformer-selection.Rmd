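---
title: "Selecting protein conformational states against NMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting protein conformational states against NMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConformerSelect)
```

## The problem

AI structure predictors with enhanced sampling can generate thousands of
plausible conformers of a protein, but they cannot say which of them the
molecule actually visits in solution. Solution NMR provides two
complementary, assignment-level observables that can arbitrate:

* **NOESY cross-peaks** report proton pairs closer than roughly 5--6
  Angstrom. The *recall* of a model set is the fraction of observed peaks
  explained by a short interproton distance somewhere in the set.
* **Chemical shifts** encode per-residue flexibility through the random
  coil index (RCI): the closer a residue's shifts sit to their random-coil
  values, the more mobile the residue.

ConformerSelect scores candidate conformers against both observables with a
Bayesian metric, clusters them into putative states, greedily assembles a
single- or multi-state ensemble that maximises concordance with the
shift-derived flexibility profile, and cross-validates the states by
identifying NOESY peaks that only one of them can explain (Double Recall).
Everything downstream of model generation is covered; generating the
conformers themselves (AlphaFold or otherwise) is out of scope.

## The model

### Shift side: RCI and its fluctuation estimate

Per residue, the secondary shifts `|ddelta_X| = |delta_obs - delta_rc|` of up
to six backbone resonances (Calpha, CO, Cbeta, N, amide H, Halpha) are
combined as a weighted mean, and

```
RCI_raw = 1 / weighted_mean(|ddelta|),   capped at 0.6,
RCI     = three-point sliding mean of the capped profile,
RMSF_RCI = RCI x 12.7 Angstrom,          RCI0.6 = RCI / 0.6 in (0, 1].
```

The weighting coefficients and the random-coil reference table are package
defaults (`defaultRciCoeffs()`, `randomCoilTable()`), both user-replaceable;
the weights emphasise the carbon shifts, which carry most of the structural
information. The weights are renormalised over the resonances actually
present for a residue, so a missing Cbeta (glycine, sparse assignments) does
not bias the value. A residue whose secondary shifts are all zero has an
infinite raw RCI and is capped to 0.6 -- maximal apparent flexibility -- not
treated as an error. The cap is applied before smoothing, in that order.
Exact parity with any particular RCI web-server implementation is not
promised: those pipelines include additional corrections (neighbour effects,
gap filling) that are deliberately out of scope here.

### NOE side: matching and recall

A 3D NOESY peak (w1, w2, w3) = (H donor, bonded heavy atom X, H acceptor) is
matched against the assignment table: candidate donor protons must agree
with w1 within `hPpm` (default 0.05 ppm) and their bonded 15N/13C with w2
within `nPpm`/`cPpm` (defaults 0.5/0.4 ppm); acceptors must agree with w3
within `hPpm`. Equivalent protons (methyl rotors, Phe/Tyr ring pairs)
collapse to one site, with the minimum distance over members (an r^-6 sum is
available via `matchTolerances(equivalentMethod = "r6sum")`). A peak is
*explained* when any candidate pair is within the distance cutoff (default
5.0 Angstrom) after summarising distances across the ensemble -- the
*midrange* (min+max)/2 by default; for a set of states, the minimum of the
per-state summaries, so a peak is explained if **any** state explains it.
Precision is the fraction of the model's short, observable, inter-residue
proton distances supported by at least one matching peak, and F is the
harmonic mean of recall and precision. Matching tolerances are documented
package defaults: published recall values for real proteins depend on the
specific matching engine used there, so parity with them is a replication
exercise, not a test.

### The per-model selection score

With `recall_min`/`recall_max` the extremes over the scored model set:

```
P(NOE | model)   = (recall - recall_min) / (recall_max - recall_min)
P(model | NOE)   = sqrt(P(NOE | model) x pTM)
P(model | RCI)   = sqrt(|SCC(pLDDT, RCI)| x <pLDDT>/100)
P(model | NMR)   = (P(model | NOE) + P(model | RCI)) / 2
```

pTM weights the NOE term because both are global quantities; the per-residue
pLDDT profile is compared to the per-residue RCI by Spearman correlation
(they are anti-correlated for a good model: confident residues are rigid).
Both the SCC and the pLDDT mean are restricted to residues where RCI exists.
The RCI term is written here as a geometric mean, symmetric with the NOE
term; an alternative reading that applies the square root to `<pLDDT>` alone
is selectable (`variant = "plddt-sqrt"`), and the two coincide whenever
|SCC| = 1. A constant pLDDT profile leaves the SCC undefined and scores 0
with a warning. When every model has equal recall, the scaled NOE likelihood
is uninformative and every model receives 0.5, again with a warning.

### Clustering and state combination

Models are embedded by their flattened Calpha--Calpha distance vectors
(superposition-free), column-centred and decomposed by SVD; agglomerative
clustering (Ward) runs on the first three principal components. Per cluster,
the `kTop = 5` highest-scoring models form a candidate single-state
ensemble; candidates are ranked by mean score (alpha5, beta5, ...) and the
top one is state 1.

Combination is greedy on Lin's concordance correlation coefficient (CCC,
population moments) between the pooled ensemble RMSF and `RMSF_RCI`:

* if CCC(state 1) <= 0 the combination aborts with a failure flag;
* otherwise each remaining candidate is pooled (equal model weights) with
  the accepted states; candidates that do not strictly improve the CCC are
  permanently eliminated, and the best improver is accepted;
* the process stops when nothing improves; a final CCC below 0.4 flags the
  result as an inadequate structural representation.

CCC rather than Pearson correlation is used because it penalises scale and
location disagreement, not just shape: `-1 <= -|PCC| <= CCC <= |PCC| <= 1`.

### Comparison intervals

Flexibility-concordance plots combine `RCI0.6 + pLDDT/100` (or
`RMSF_RCI - RMSF_ENS`) per residue and flag residues outside
`mean +/- SEM x Z_p`, with `SEM = SD / sqrt(N - 1)` and `Z_p` the two-sided
t critical value at **one** degree of freedom (12.71 at 95%) -- a very
conservative band reflecting that each residue is treated as a single
replicate of the profile-level comparison. Residues with pLDDT <= 50 are
excluded from N.

## Superposition choices

Ensemble RMSF superposes every model on the iterated mean structure (two
refinement passes), removing any dependence on model order. Which residues
drive the superposition matters more than how: with a genuine multi-state
mixture, fitting on **all** residues distributes the inter-state motion
across the chain and dilutes the apparent RMSF -- in the packaged two-state
fixture the pooled RMSF maximum drops from the true 4.6 Angstrom to 1.9
when globally aligned, below any reasonable well-defined cutoff, so a purely
structural criterion cannot find the rigid core. `wellDefinedRanges()`
(RMSF <= 2.0 Angstrom after global superposition, gaps <= 2 bridged, ranges
< 4 residues dropped, user override wins) is therefore complemented in the
pipeline's `alignRanges: auto` mode by the shift data: the superposition
set is the intersection of the well-defined ranges with residues whose
`RMSF_RCI` is at most 2 Angstrom. Residues the experiment itself calls
mobile are never used for alignment. An explicit range string in the
configuration overrides all of this.

## Physical-sanity filtering

Aggressively sampled models can be physically impossible. Three checks are
applied before scoring, each per model: D-amino-acid chirality via the
N-CA-C-CB improper dihedral (about +122 degrees for L-residues; negative
flags D), cis peptide bonds (|omega| < 30 degrees) at non-proline residues,
and missing backbone atoms. Flagged models are removed; if everything is
flagged the run stops. These three checks are a stated approximation of the
filtering applied to enhanced-sampling model sets elsewhere; they catch the
egregious failures, not subtle packing errors.

## The synthetic study

`makeTwoStateEnsemble()` plants a fully known two-state system so that every
stage has a ground truth without downloading anything:

* a 30-residue helix--loop--helix peptide (alternating Ala/Leu, backbone plus
  amide H, Halpha and the Ala methyls -- enough protons to exercise
  equivalent-group matching);
* state 2 rotates everything past the hinge (residue 16) by 25 degrees;
* 20 models per state add a per-residue random displacement with sigma =
  0.3 Angstrom, amplified at the termini by `1 + exp(-(i-1)/2)` at each end
  (flexible tails -- both study systems in this field have them, and without
  residue-dependent noise a single state has a flat RMSF profile and the
  entry concordance of the combination step would be a coin flip);
* the displacement field is smoothed along the chain (Gaussian kernel,
  sd 1.25 residues) and renormalised to keep the per-residue variance exact:
  independent neighbour displacements of ~0.9 Angstrom would destroy
  peptide-bond geometry and trip the sanity filter, while collective motion
  preserves it. The tail amplitude is kept at 1x the base noise so that
  coherent tail swings do not mask the hinge separation in distance-feature
  space;
* the true pooled RMSF has the closed form `sqrt(d_i^2/4 + 3 sigma_i^2)`
  (`d_i` = displacement between state means), pLDDT is assigned
  anti-monotone to it on [50, 100], and the states carry pTM 0.85/0.80;
* `makeSyntheticNmr()` plants secondary shifts of magnitude `1/RCI_target`
  per resonance so that the RCI engine approximately recovers the true
  pooled RMSF (three-point smoothing blurs the correspondence slightly --
  the generator self-check is a concordance bound, CCC > 0.8, not equality),
  and back-calculates 15N- and 13C-resolved peak lists from the merged true
  states;
* `makeDecoyEnsemble()` rotates the hinge the wrong way: its specific
  contacts are absent from the peak lists, so its recall is strictly lower
  than either true state. Note that the RMSF-based combination step alone
  cannot reject such a decoy (opposite rotations produce identical pooled
  RMSF); it is the NOE side -- recall and Double Recall -- that discriminates
  direction.

What passing on this fixture does **not** show: performance on real,
incomplete, ambiguous assignments; chemical-shift physics (the planted
shifts are internally consistent, not predictions); rotamer-level detail
(the proton set is minimal); peak-list artefacts (noise peaks, unpicked weak
peaks). The fixture validates the machinery, not the spectroscopy.

## Numerical choices

* Kabsch superposition via SVD with a determinant correction (always a
  proper rotation); degenerate (collinear) references are an error.
* Score ties in candidate construction break by higher pTM, then lower
  model id; ties in state combination break by candidate rank.
* Strict CCC improvement is tested beyond a 1e-9 round-off guard.
* PCA component signs are fixed (largest-magnitude loading positive) so
  results do not depend on the LAPACK sign convention; clustering is
  deterministic given the inputs, and the seed is recorded for provenance.
* TM-score uses `d0 = 1.24 (L-15)^(1/3) - 1.8`, floored at 0.5 (with a
  warning below 16 residues), maximised over contiguous seeds with
  iterative extension, normalised by the reference length.
* Protons missing from a model (e.g. hydrogen-free ensembles) fall back to
  the bonded heavy atom position with a 1.0 Angstrom correction, floored so
  distances stay positive, with a warning.
* A missing pTM becomes the neutral prior 1.0, with a warning, so models
  without confidence metadata are ranked by data fit alone.

## Problem sizes

The packaged studies run 40-model ensembles of 30 residues (about 100
proton sites, ~500 simulated peaks); a full pipeline run takes a few
seconds, and the ten-seed recovery study under a minute. Real applications
(150+ residues, thousands of models) scale linearly in models for scoring
and quadratically in residues for the distance features; per-model recall
scoring reuses one peak-candidate table across models.

## Known limitations

* The DP (discriminating-power) normalisation of the F-measure against a
  random-coil baseline is not computed; F is reported raw.
* No RDC/PRE/PCS likelihood terms; the Bayesian combination currently uses
  NOE recall and RCI concordance only.
* State populations are not estimated: pooling uses equal model weights
  (fast-exchange assumption).
* No sequence alignment: compared structures must share residue numbering.
  Insertion codes and NEF files are unsupported; mmCIF is read, not
  written.
* Ambiguous peaks are counted once: a peak is explained if any candidate
  pair is short, never multiply.
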