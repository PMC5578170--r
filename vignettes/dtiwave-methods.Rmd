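---
title: "Predicting drug-target interactions from wavelet, fingerprint and network features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from wavelet, fingerprint and network features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiwave)
```

## The prediction problem

Experimentally confirming that a small molecule binds a protein is slow and
expensive, so computational screens that rank candidate drug-target
interactions (DTIs) are used to prioritize assays. `dtiwave` implements a
feature-vector DTI classifier: every (drug, target) pair becomes one sample
whose feature vector concatenates a compressed description of the protein
sequence, a substructure fingerprint of the drug, and the pair's position in
the known bipartite interaction network. A support vector machine with an
RBF kernel separates interacting from non-interacting pairs.

## Target encoding: physicochemical signals and the wavelet transform

A protein of length $L$ is mapped to an $L \times 6$ signal matrix: residue
$i$ contributes the six scale values of its amino-acid type — hydrophobicity
(H), side-chain volume (VSC), polarity (P1), polarizability (P2),
solvent-accessible surface area (SASA) and the net charge index of the side
chain (NCISC). Each scale is normalized over the 20 standard types,

$$P'_{ij} = \frac{P_{ij} - \bar P_j}{S_j},$$

so all six channels are dimensionless with zero mean and unit spread across
the alphabet. Because the normalization runs over a complete, fixed
20-letter alphabet rather than a sample, $S_j$ is the population standard
deviation (divisor 20) by default; the sample convention is available via
`sd_method = "sample"`.

Each channel is then compressed by a 4-level discrete wavelet transform
(DWT): at every level the current approximation band is passed through a
low-pass/high-pass analysis filter pair and downsampled by two, and the next
level recurses on the approximation band only. Per channel, level and band
the features are the four summary statistics (max, min, mean, SD), and the
leading five orthonormal DCT-II coefficients of each approximation band add
a compact description of the smooth component. Under the defaults this
yields $6 \times 4 \times 2 \times 4 + 6 \times 4 \times 5 = 312$ features
per target, independent of sequence length.

Several choices here are genuinely open and are therefore explicit,
recorded parameters rather than silent constants:

* **Mother wavelet.** No single wavelet is canonical for protein signals.
  The default is Daubechies with four vanishing moments (`db4`, 8-tap
  filter), a common choice in biological signal work; `db2` and `haar` are
  selectable (`wavelet =`). Changing the wavelet changes the features, so
  the choice is stored in run manifests.
* **Boundary handling.** Half-point symmetric extension is the default; it
  treats the sequence ends gracefully. A `periodization` mode is provided
  that makes the transform exactly orthogonal — coefficient energy equals
  signal energy (Parseval) — at the price of requiring an even band length
  at every level; it exists mainly so that energy-conservation properties
  can be verified exactly. Zero padding is also available.
* **DCT scope.** "Leading DCT coefficients of the approximation
  coefficients" can be read per level or for the deepest level only. The
  default takes all four levels (120 DCT features); `dct_scope = "last"`
  gives the 30-feature variant. Both are tested.
* **Band SD convention.** Sample SD ($n-1$); one-coefficient bands get 0.
* **Short sequences.** A sequence that cannot support four levels (shorter
  than 16 residues with `db4`) is decomposed to the feasible depth and the
  missing bands' features are zero-filled with a warning, keeping feature
  matrices rectangular. A band shorter than five coefficients zero-fills
  its missing DCT entries likewise.
* **Non-standard residues.** Ambiguity codes and rare residues (B, Z, J, X,
  U, O) are dropped with a warning by default; a `map` policy substitutes
  conventional stand-ins (B→N, Z→Q, J→L, U→C, O→K), and `error` aborts.

## Drug encoding: MACCS keys

Drugs are encoded as the 166 MDL MACCS substructure keys, computed from
SMILES via OpenBabel (`ChemmineOB`). OpenBabel stores the keys in a 256-bit
container indexed by key number; the package returns exactly keys 1–166.
Key 166 (fragment count) is not SMARTS-expressible and OpenBabel leaves it
0. Bit-level parity across toolkits is close but not guaranteed, so the
computing toolkit is recorded with each fingerprint and precomputed
fingerprint tables can be supplied instead (`load_fingerprint_table()`).

## Network features and leakage

For a pair $(D_i, T_j)$ in a network of $n_d$ drugs and $n_t$ targets, the
net feature is the binary interaction profile of $D_i$ over all targets
except $T_j$, concatenated with the profile of $T_j$ over all drugs except
$D_i$: $(n_t - 1) + (n_d - 1)$ bits. Excluding the query row and column
keeps a pair's own label out of its own feature, but during
cross-validation the *other* test-fold edges could still leak through
training-pair profiles. The evaluator therefore masks all positive
test-fold edges out of the adjacency before computing any features for that
fold (`mask_test_net = TRUE`). The permissive variant, in which profiles
see the full network, is available (`mask_test_net = FALSE`, CLI flag
`--oracle-network`) because published network-feature results do not always
state which protocol they used; the strict variant is the defensible
default.

## Feature selection: SVM-RFE with correlation bias reduction

Features are ranked by recursive feature elimination: a linear SVM is fit
on the surviving features, feature $j$ is scored by $w_j^2$, and the
lowest-scoring 10% are removed per iteration. Because the SVM spreads
weight across mutually correlated features, a group of redundant but
informative features can be eliminated one by one. The correlation bias
reduction step counters this: surviving features whose absolute pairwise
correlation exceeds 0.9 are grouped (transitively) and every member is
scored by the group's best member, so the group stands or falls together.
This group-max correction is one reasonable reading of "correlation bias
reduction"; the threshold and elimination step are configurable and logged.
The ranking SVM is linear even though the final classifier is kernelized —
the explicit weight vector is what the criterion needs. Selection is always
fit inside the training fold, never on pooled data.

`select_top_k()` takes the best $k$ ranked features; `k = "auto"` compares
sizes on a log2 grid by inner cross-validated AUC and picks the smallest
size within one SD of the best (a parsimony rule).

## Classifier and evaluation

The classifier is a C-SVM with RBF kernel
$K(x, x') = \exp(-\gamma\|x - x'\|^2)$ (LIBSVM via `e1071`). All features —
including the binary fingerprint and profile bits, for uniformity — are
z-scored with training-fold statistics; zero-variance columns pass through
unscaled. Defaults $C = 8$, $\gamma = 1/p$; `"grid"` runs an inner
cross-validated search over powers of four, $C \in 2^{-5..15}$,
$\gamma \in 2^{-15..3}$.

Two regimes mirror common benchmark practice: **balanced-5fold** draws
datasets of all known interactions plus an equal uniform sample of unknown
pairs (ten such subsets by default; negatives are drawn independently per
subset, so subsets share positives and may overlap in negatives) and
cross-validates each with five stratified folds; **imbalanced-10fold** uses
every pair once with ten folds. ACC, sensitivity and specificity come from
the confusion counts at decision threshold 0; AUC is trapezoidal ROC
integration (equal to the Mann-Whitney statistic); AUPR is step-wise
average precision *without* linear interpolation, since interpolated PR
curves overstate the area. Fold metrics are aggregated as mean ± SD; folds
whose test part degenerates to one class are skipped with a warning and
counted.

Novel-pair ranking trains on one balanced dataset built from all known
interactions and scores unknown pairs by Platt-scaled probability (or raw
decision value); ties break deterministically by (drug, target) id order.
By default pairs used as training negatives are excluded from the ranked
list, since the model has seen their (presumed negative) labels.

## The synthetic benchmark

Large gold-standard DTI collections must be downloaded from external
databases, so the package ships a generator whose output exercises every
pipeline stage with a planted, tunable signal. Drugs and targets belong to
`n_groups = 4` ordered latent groups with graded interaction propensity
$\eta_g$ (normal quantiles), emulating the strong degree heterogeneity of
real DTI networks — a few heavily-drugged target families and promiscuous
chemotypes account for many interactions. A drug expresses its group
through a 12-bit signature block of its fingerprint (bit rate
$0.15 + 0.85 s$ against a 0.15 background); a target expresses it through
amino-acid composition (mixing weight $0.6 s$ toward five group residues);
sequence lengths are uniform on 100–600. Edges are drawn without
replacement with weight $\exp(s \cdot \text{tilt} \cdot (\eta_d + \eta_t))$,
`tilt = 2.5`; at signal strength $s = 0$ this is exactly uniform random
wiring, the null condition. The generator is fully seeded: one seed
reproduces files byte-for-byte.

What the benchmark does *not* emulate: real chemical similarity structure
(fingerprint bits are independent given the group), homology families and
domain architecture in sequences, and the curation biases of real
interaction databases. Passing the planted-signal test therefore shows the
pipeline can extract a signal that is genuinely present in all three
feature blocks and does not hallucinate one under permuted labels — it does
not certify accuracy figures on any real collection. Replicating published
gold-standard numbers requires downloading those datasets and running the
documented external workflow (`read_adjacency_matrix()`,
`read_protein_fasta()`, `fingerprint_smiles_file()` accept the distributed
formats).

## Problem sizes and numerical tolerances

The shipped validation uses desk-scale problem sizes chosen so the entire
suite runs in minutes on one core: the planted benchmark is 100 drugs x 80
targets with 400 interactions; balanced evaluation uses 2 of the 10
default subsets (5 folds each, all other protocol elements unchanged); the
elimination-recovery check uses 200 samples x 50 features with 5 planted
informative features. Filter-bank coefficients are checked against a
brute-force convolution oracle at 1e-10, orthogonal-mode energy
conservation at 1e-8, normalization identities at 1e-10, and the two AUC
formulations against each other at 1e-10.

## Known limitations

* Class imbalance is not specially treated; on strongly imbalanced data the
  SVM favours the majority class, and AUPR on small sparse networks is
  accordingly modest.
* MACCS bit definitions differ subtly between toolkits; models trained on
  fingerprints from one toolkit should be applied to fingerprints from the
  same toolkit.
* The wavelet family is a free parameter with no canonical value; feature
  vectors from different wavelets are not comparable.
* `svm_rfe_cbr()` refits an SVM per elimination round; for feature counts
  far beyond ~10^3 a larger `step_fraction` is advisable.
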