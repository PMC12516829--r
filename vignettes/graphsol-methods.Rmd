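---
title: "GraphSol: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GraphSol: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GraphSol)
```

GraphSol estimates the intrinsic aqueous solubility S0 — the equilibrium
solubility of the fully un-ionized species — of drug-like molecules, and
reconstructs how their solubility changes with pH. It does this in three
stages: (1) derive S0 from pH-dependent assay measurements and predicted
pKa values, (2) learn to predict S0 (plus seven related physicochemical
properties) from molecular structure with a multi-task graph transformer,
and (3) turn a predicted S0 and pKa set back into a full pH 0–12
solubility profile. This vignette explains the model behind each stage,
the tunable parameters, the numerical choices, and what the synthetic
data generator does and does not emulate.

## 1. Henderson–Hasselbalch speciation

For an ionizable compound, total solubility at a given pH is the
intrinsic solubility of the neutral species multiplied by an ionization
factor:

$$S(\mathrm{pH}) = S_0 \cdot \Phi(\mathrm{pH}), \qquad \Phi \ge 1 .$$

With relevant acidic pKa's $a_1 \le \dots \le a_{n_a}$ and basic pKa's
$b_1 \ge \dots \ge b_{n_b}$, we use the cumulative speciation expansion

$$\Phi(\mathrm{pH}) = 1
  + \sum_{k=1}^{n_a} 10^{\,k\,\mathrm{pH} - \sum_{j \le k} a_j}
  + \sum_{k=1}^{n_b} 10^{\,\sum_{j \le k} b_j - k\,\mathrm{pH}},$$

which reproduces the classical mono-, di- and triprotic acid and base
equations and the ordinary-ampholyte case. Cross terms for
simultaneously zwitterionic microspecies are *not* modelled; zwitterions
are excluded during curation (below), so no downstream consumer relies
on them. All solubilities are log10 molar internally; micromolar values
convert only at the I/O boundary.

**Numerical stability.** `ionizationFactor()` evaluates
$\log_{10}\Phi$ in log-sum-exp form (factor out the largest exponent,
which is $\ge 0$ because of the leading 1), so pH − pKa differences of
20 and more are exact in log space where the naive sum would overflow.
The naive direct summation exists only as a test oracle.

**Relevant pKa's.** A pKa influences solubility at a pH only if its
group is appreciably ionized there. `relevantPkas()` keeps a pKa when
its ionized fraction — $1/(1+10^{pK_a-\mathrm{pH}})$ for acids,
$1/(1+10^{\mathrm{pH}-pK_a})$ for bases — is at least a threshold
(default 0.01, i.e. 1% ionized; boundary kept on $\ge$). If more than
three pass, the three largest fractions are kept and the pre-cap count
is reported; the forward map refuses (with a typed error) to evaluate a
point where more than three pKa's are simultaneously relevant, because
small pKa errors are amplified exponentially with the extent of
ionization. The fraction-based rule is this package's design choice; a
pH-window rule would behave similarly near the default threshold
(1% ionization corresponds to |pH − pKa| = 2).

## 2. Curation: from assay records to the S0 dataset

Raw records are high-throughput solubility measurements at pH 2 and
pH 7 with a dynamic range of 0.1–600 µM, a solid-state label for the
residual solid, and a replicate spread. The pipeline:

1. **Filter**: keep only crystalline, uncensored records; drop salt
   forms (an explicit input flag; no desalting chemistry is attempted).
   Censored records are dropped entirely rather than used as bounds —
   interval information is real but the assay tails are exactly where
   solid-state confirmation is least reliable.
2. **Choose the derivation pH** per compound: acid-only compounds use
   pH 2 (least ionized), base-only use pH 7; compounds with both group
   types use the record closest to the midpoint of min(acidic pKa) and
   max(basic pKa) provided the gap exceeds 2 pH units, and are
   discarded otherwise — this removes zwitterions. When the two record
   pHs are equidistant from the midpoint the lower pH wins
   (deterministic tie-break). Compounds with no pKa take the measured
   value as S0 directly.
3. **Back-calculate** S0 = measured − $\log_{10}\Phi$ at the record pH.
4. **Merge duplicates**: if multiple S0 values for a compound span less
   than 0.7 log units, keep the smallest (assumed to reflect the most
   stable polymorph); otherwise drop the compound. The same rule covers
   no-pKa compounds measured at both pHs.
5. **Flag high quality**: crystalline, uncensored, replicate spread
   ≤ 0.5 log units (configurable). The protocol behind the published
   high-quality subset is not fully public; this package's rule
   operationalizes its stated aims (crystalline-confirmed, minimized
   analytical variability). S0 test-set performance is always reported
   on this subset only.

The eight-task table (`buildTaskTable()`) is an outer union over
compounds of S0, solubility at pH 2 / pH 7 / FaSSIF, logP, and logD at
pH 2.6 / 7.4 / 10.5, with an observation mask; missing entries are
never imputed.

## 3. Molecular graphs

`buildGraph()` parses SMILES with OpenBabel (via
ChemmineR/ChemmineOB): one node per heavy atom, one edge per bond.
Node features: element one-hot (C, N, O, S, P, F, Cl, Br, I, other),
degree, formal charge, implied hydrogen count, hybridization one-hot,
aromaticity, ring membership. Edge features: bond-order one-hot
(single/double/triple/aromatic), conjugation, ring membership, stereo
flag. Because the kekulized SDF that OpenBabel emits carries no
implicit-H or hybridization fields, those are reconstructed from
standard valences and the bond table, and conjugation is approximated
(aromatic bonds, multiple bonds, and single bonds joining two multiply
bonded atoms). Aromaticity comes from ring perception on rings up to 8
atoms. The feature set is configurable (`molgraphFeatures()`) so a
different featurization can be swapped in without touching the model.

Two structural summaries accompany each graph. Hop distances are
all-pairs shortest-path bond counts (infinite across disconnected
components). The random-walk structural encoding is the per-node
probability of returning to the start in exactly $k$ steps of a
uniform random walk, $k = 1..K$ (default $K = 20$): the diagonal of
$(D^{-1}A)^k$. Both are permutation-equivariant, which makes the whole
model permutation-invariant after pooling.

## 4. The multi-task graph transformer

Each block runs two branches in parallel on the node states:

* **Local message passing** (GINE-style): per directed bond, the
  message is $\mathrm{relu}(h_j + W_e\,e_{ij})$, summed at the
  receiving atom, then passed through a two-layer MLP with the atom's
  own state; residual connection and layer normalization follow. A
  bond-free molecule simply keeps its self path.
* **Global attention with an exponential decay mask**: standard
  multi-head scaled dot-product attention, after whose softmax the row
  weights are multiplied elementwise by $\gamma^{d(i,j)}$ ($d$ = hop
  distance, $\gamma^\infty = 0$) and renormalized to sum to one.
  Masking *post*-softmax keeps every row an exact convex combination
  and makes both limits exact: $\gamma = 1$ is vanilla unmasked
  attention, $\gamma = 0$ collapses to self-attention only. (Whether
  the original decay-mask formulation multiplies pre- or post-softmax
  is ambiguous; pre-softmax multiplication of already-signed scores
  would not even preserve ordering for negative scores, so the
  post-softmax reading is adopted.) $\gamma$ is fixed, default 0.6,
  not learned.

The branch outputs are summed and passed through a feed-forward stage,
again with residual and normalization. The random-walk encoding enters
at the input projection alongside the atom features. Mean pooling over
atoms gives the graph embedding (the paper-level architecture is
silent on readout; mean pooling is the GraphGPS default for molecular
regression); eight independent linear heads produce the task outputs.

**Loss.** Per-task masked mean squared error $L_t$ combined with a
learnable log-variance $s_t$ per task:
$\mathcal{L} = \sum_t e^{-s_t} L_t + r(s_t)$, summed over tasks with at
least one observed entry in the batch. The default regularizer is the
Kendall form $r(s) = s/2$; a softplus variant
$r(s) = \log(1+e^{s})$ is selectable for robustness to initialization.
Unobserved entries contribute *exactly* zero gradient.

**Training.** Adam (learning rate 0.005) for up to 200 epochs over
seeded-order minibatches; after each epoch the validation loss is
evaluated and training stops once it has not improved for 30 epochs
(patience), returning the best-epoch weights. Targets are standardized
per task on the training split (solubilities and partition
coefficients live on offset scales; standardization lets a shared
trunk serve all heads from the first epochs) and predictions are
mapped back to native units. Training is bitwise-reproducible for a
fixed seed and thread configuration.

Default architecture: 4 blocks, hidden width 96, 4 heads, minibatch
16. The blocks/width/heads are a desk-scale CPU configuration; every
value is a `modelConfig()` argument. The minibatch default is chosen
for the dataset sizes this package targets (tens to a few thousand
compounds): smaller batches give proportionally more optimization
steps per epoch within the fixed 200-epoch budget, which matters far
more at these sizes than gradient-noise reduction (a batch of 64
degenerates to one full-batch step per epoch on a 50-compound set).

**Initialization.** Input projections, Q/K/V maps and MLP first layers
are Glorot-uniform; every branch's *output* projection starts at zero,
so an untrained block is the identity on its node states and the
residual paths grow only as training shapes them. This
residual-friendly start markedly shortens the optimization path on
small datasets, where the fixed epoch budget, not model capacity, is
the binding constraint. `initGraphSolModel(identityStart = FALSE)` restores fully
random projections (used by tests that probe the untrained forward
pass itself).

Gradients come from a small reverse-mode autodiff tape on matrices
written for this package (the environment has no neural-network
autodiff library); its gradients are verified against central finite
differences in the test suite.

**Evaluation protocol.** Stratified 70/15/15 split on high-quality
membership (per-stratum rounding, remainder to train; strata smaller
than three go entirely to train with a warning). RMSE and $R^2$; the
repeated protocol runs five independent splits and reports mean with
sample SD ($n-1$ denominator — the paper-level protocol does not
specify the denominator).

## 5. pH-solubility profiles

`computeProfile()` evaluates the forward map on a pH grid (default
0–12, step 0.1 — the range is standard, the step is this package's
choice; fine enough to resolve a 0.1-pH-unit pKa error visually).
At each grid point the relevance filter runs first; points with more
than three relevant pKa's are marked undetermined and serialize as
empty fields, never as sentinel numbers.

A useful exact identity: for fixed pKa's, profiles built from $S_0$
and $S_0 + \delta$ differ by exactly $\delta$ at every determined
point, because $\log S = \log S_0 + \log\Phi$ is linear in
$\log S_0$. So an S0 prediction error translates into a constant
vertical offset of the whole profile — `profileOffset()` measures
exactly this, and `evaluateProfiles()` applies it cohort-wide.

## 6. The synthetic-data generator

Real training data of this kind is proprietary, so `simulateDataset()`
emulates its statistical structure: pH 2 and pH 7 assays with a
0.1–600 µM dynamic range and boundary censoring; a compound population
mixing neutrals (25%), acids (25%), bases (25%), ordinary ampholytes
(15%, pKa gap forced > 2) and zwitterions (10%, gap ≤ 2) with up to
four pKa's; salt forms (5%), non-crystalline solid-state labels (10%),
duplicate records (20%); true S0 ~ N(−5, 1.2) log molar; measurement
noise 0.3 log units per record (between the ~0.15 inter-laboratory
reproducibility of potentiometric methods and the ~0.34 shake-flask
comparison error reported for such assays). Each compound's structure
is unique: class-specific drug-like scaffolds decorated with alkyl
homolog chains. True S0 is planted partly linear in molecular size
(80% of its spread) so that structure actually carries signal; the
logP/logD/FaSSIF targets are noisy linear functions of true S0 and
size. Task sparsity is exact by construction (each task observes
exactly `round(n * sparsity)` compounds).

What the generator does *not* emulate — and what passing tests on it
therefore cannot show: pKa's are assigned from the ionization class,
not perceived from the structure, so the structure–pKa link of real
chemistry is absent; logP/logD follow planted linear physics, not
partition chemistry; there are no polymorph effects, no salt-to-free
conversions, and homolog decoration narrows chemical diversity far
below a real screening deck. Tests on synthetic data validate the
*pipeline machinery* (filters, equations, masks, optimization), not
chemical-space generalization.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance script run the full stack at
reduced scale — hundreds of synthetic compounds for curation checks,
50 compounds for the training-capacity check, five trials of a reduced
architecture for the protocol check — sizes chosen so the whole suite
runs on a single desktop CPU in minutes while still exercising every
code path at non-trivial n. All randomness flows from explicit seeds;
every reported number is recomputed at run time.

## 8. Known limitations

* Speciation ignores activity corrections, ionic strength, temperature
  and common-ion effects; profiles have no solubility-product plateau
  at extreme pH.
* The >3-relevant-pKa refusal is a hard rule; compounds needing four
  simultaneous ionization states are out of scope rather than
  approximated.
* Feature reconstruction from kekulized SDF approximates implicit-H,
  hybridization and conjugation; molecules with unusual valences may
  be featurized imperfectly (they still parse and train).
* The transformer is CPU-oriented and desk-scale; it makes no attempt
  at GPU-scale pretraining or hyperparameter search.
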