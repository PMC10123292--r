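---
title: "Multi-task fingerprint + graph-attention models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task fingerprint + graph-attention models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Five cytochrome P450 isoforms (1A2, 2C9, 2C19, 2D6, 3A4) metabolize the
large majority of approved drugs; predicting whether a candidate molecule
inhibits them is a routine early filter against drug–drug interactions.
The isoform inhibition tasks are strongly related — their assay datasets
share thousands of compounds and the binding sites are structurally
similar — which makes them a natural target for multi-task learning: one
shared network trunk with a per-task output head, trained on all tasks
simultaneously with labels that are missing for many (molecule, task)
pairs.

`fpgnn` implements this workflow end to end: dataset curation and
structure-based splitting, a hybrid fingerprint + graph-attention network
trained with a masked multi-task cross-entropy, Y-scrambling validation, a
distance-based applicability domain, and attention/fingerprint-bit
interpretation. Everything is exercised on synthetic molecules with known
structure–label rules, so the whole pipeline is testable without any
download.

# The model

A molecule enters the network along two branches.

**Fingerprint branch (FPN).** The molecule's mixed fingerprint is the
concatenation, in fixed order, of

* MACCS keys (166 bits),
* a PubChem-style substructure key set (881 slots; the shipped rule table
  `pubchem_key_table()` — element counts, ring counts, bonded element-pair
  counts and SMARTS keys — is the definition; unassigned slots are always
  zero),
* a pharmacophore ErG descriptor (315 nonnegative reals): six atom
  properties (donor, acceptor, positive, negative, hydrophobic, aromatic)
  assigned by rule, counted over property pairs at topological distances
  1–15 with a fuzz increment of 0.3 on the two neighbouring distance bins.
  The ring-collapse ("reduced graph") step of the original ErG formulation
  is not applied; distances are shortest paths on the heavy-atom graph.

The branch is a fully connected ReLU network. At its input the ErG count
block passes through `log1p` so count features enter on the same scale as
the binary keys; this is part of the model architecture, not of the
fingerprint definition — applicability-domain distances always use the raw
vectors.

**Graph branch (GNN).** The heavy-atom molecular graph carries atom
features (element, degree, formal charge, implicit hydrogen count,
hybridization, aromaticity, ring membership) and bond features (bond type
with aromatic as its own type, conjugation, ring membership); the exact
schema is returned by `graph_schema()` and versioned into every
checkpoint. Each message-passing layer computes, per attention head,

$$\alpha_{ij} = \mathrm{softmax}_{j \in N(i) \cup \{i\}}
  \big(\mathrm{LeakyReLU}(a_d^\top W h_i + a_s^\top (W h_j + W_b e_{ij}))\big),
\qquad
h_i' = \mathrm{ReLU}\Big(\sum_j \alpha_{ij} (W h_j + W_b e_{ij})\Big),$$

with heads concatenated. Self-loops (zero bond features) are included in
every neighbourhood, so single-atom molecules are handled by the same
code path. A molecule embedding is read out by a second attention over
atoms ($\beta_v = \mathrm{softmax}_v(w^\top \tanh(U h_v))$, embedding
$\sum_v \beta_v h_v$).

**Fusion and multi-task head.** The two embeddings are concatenated and
passed through shared fully connected ReLU layers; one linear output per
task followed by a sigmoid yields the T inhibition probabilities. All
branch and trunk weights are shared across tasks; only the output columns
are task-specific (perturbing head *j* provably changes only task *j*).
Calls use the 0.5 threshold, with a tie at exactly 0.5 called positive.

**Loss.** Per task, the mean binary cross-entropy over the molecules whose
label is present; the total loss is the unweighted mean over tasks with at
least one labelled molecule in the batch. Probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ before the logarithm (the raw formula is undefined
at 0/1); molecules fully masked in a batch provably do not affect the
loss. This masked-exclusion treatment is the only reading consistent with
a per-subtask loss average when the task datasets overlap only partially.

**Optimization.** Adam (defaults: learning rate 5e-3, batch 64) with
dropout on the fingerprint-branch and trunk activations during training
only. The forward and backward passes are written as vectorized matrix
operations over a disjoint-union batch graph; the analytic gradients are
checked against central finite differences to 1e-4 relative error in the
test suite. Model selection keeps the epoch with the highest averaged
validation AUC; ties keep the later epoch (same AUC, more training), and
early stopping triggers after `patience` epochs without strict
improvement. All randomness (initialization, shuffling, dropout,
scrambling) derives from explicit integer seeds, so training is
reproducible bit for bit.

# Dataset handling

Cleaning applies, in order: removal of molecules with no carbon atom;
for multi-fragment SMILES, retention of the largest carbon-containing
fragment by heavy-atom count (a deterministic salt/mixture rule);
canonicalization (OpenBabel); deduplication by canonical SMILES, with
conflicting duplicate labels conservatively set to missing.

Splitting is structure-based: k-means (10 restarts, best within-cluster
sum of squares kept) on the mixed fingerprint vectors, with k chosen by
the elbow criterion (`elbow_curve()`); validation and test sets are drawn
proportionally from each cluster with a fixed seed. The canonical
configuration uses k = 6. Profiling reports molecular weight, LogP,
per-task label counts, and the Bemis–Murcko scaffold fraction (unique
scaffolds / molecules). Scaffolds are obtained by iteratively pruning
terminal atoms, so exocyclic substituents — including double-bonded ones —
are removed; acyclic molecules share the empty scaffold. Both conventions
are fixed so the fraction is well defined.

# Applicability domain

For each training compound, the mean Euclidean distance to its k nearest
other training compounds is computed on the raw mixed fingerprints;
d_ave and θ are the mean and population standard deviation (divisor n) of
those per-compound means, and the domain threshold is

$$D_T = d_{ave} + Z\,\theta .$$

A query is outside the domain (OD) iff the distance to its single nearest
training compound exceeds D_T. The asymmetry — k-NN averaging on the
training side, single nearest neighbour on the query side — is
implemented as stated in the method description; ties in neighbour
ranking break by training index. The default grid includes the operating
point (k = 3, Z = 0.2). At fixed k the OD count is nonincreasing in Z by
construction.

# Y-scrambling

The response is permuted *within each task* over the molecules whose
label is present (masks untouched, so class balance per task is
preserved), across the whole modeling set — training and validation
alike, since scrambling the response before the entire pipeline is what
rules out chance correlation. The model is retrained from scratch with
fresh seeds and the completed retrain's test AUC recorded per round,
alongside the unscrambled reference. Recording the completed retrain
matters: under a permuted response, validation-based epoch selection is
pure noise and systematically favours barely-trained snapshots, and a
randomly initialized network can rank a substructure label far from 0.5
by accident — the label-bearing fingerprint block shifts the input
magnitude, and any fixed random weight draw turns that into a common
logit offset. Fitting the permuted labels to completion washes this
offset out, and performance collapses toward AUC 0.5 as it should.

# Interpretation

**Attention maps.** Directed attention coefficients are captured during a
forward pass; heads are aggregated by mean, the symmetric bond score is
the mean of the two directed coefficients, and per-atom aggregates (sum of
incident bond scores) are min–max normalized per molecule for rendering
only. Because the coefficients are functions of atom/bond features alone,
symmetry-equivalent bonds (e.g. benzene's six) receive identical scores.

**Fingerprint-bit importance.** The attribution method is occlusion: the
importance of bit b for a task is the mean absolute change in that task's
predicted probability when column b is zeroed, averaged over a dataset;
a gradient-times-input alternative is available. Occlusion is
model-agnostic and deterministic, and a bit absent from every molecule has
importance exactly zero. Two practical caveats shaped the validation
study: (i) on a perfectly separable task the sigmoid saturates and all
occlusion deltas collapse toward zero, so the study task carries 15%
label noise to keep probabilities calibrated; (ii) when a substructure's
presence also shifts many correlated descriptor bins (as a nitro group
does, through its charges and acceptors), single-bit occlusion spreads
over those bins. The study label is therefore halogen presence, whose
defining keys are essentially the label's sole fingerprint determinants;
with it the defining keys occupy the top occlusion ranks.

# The synthetic generator

`generate_molecules()` assembles molecules from a scaffold × substituent
grammar: seven templates (benzene, pyridine, cyclohexane, piperidine,
thiophene, furan, and an aliphatic chain, with 3–5 substitution slots)
and fragments for the five default tasks (nitro, sulfonamide, carboxyl,
halogen, nitrile) plus neutral decoys. Each task's label is a SMARTS
match on the assembled molecule — so with zero noise a perfect classifier
exists by construction — optionally XOR-ed with seeded label noise and
masked at a per-task missing rate. Task-defining fragments attach with
probability equal to the class-balance target; a correlation knob
attaches a shared trifluoromethyl latent substructure that every task's
rule also matches, emulating related tasks. Generation is deterministic
given the spec, emits unique canonical molecules, and every emitted
SMILES round-trips through canonicalization unchanged.

`generate_od_probe()` builds structurally disjoint repeat-unit families
(polyphosphates, perfluoroalkyl chains, siloxanes) that sit far from the
grammar's output in fingerprint space, for applicability-domain tests.

What the generator does *not* emulate: drug-like property distributions,
tautomerism, stereochemistry-dependent activity, assay noise structure,
or the scale of public bioassay data. Tests passing on these fixtures
demonstrate the correctness of the machinery and the qualitative behavior
of the method (learnability, scrambling collapse, domain separation), not
predictive performance on real chemistry.

# Study sizes and numerical choices

The validation studies use dataset sizes chosen to exercise every code
path at desk scale: 500 molecules (single-task learnability, AUC ≥ 0.95
within 30 epochs, and 5 Y-scrambling rounds), 400 molecules (occlusion
study; multi-task benefit with a 50-label starved task over 5 seeded
repeats), 600 molecules for the five-task reproduction script. With the
grammar's fully informative fingerprints, both the multi-task and the
single-task model typically saturate on the starved task, so the
directional multi-task comparison holds with ties; the benefit is
structural (shared trunks train on all labels at once), not always
visible as an AUC gap at these sizes.

Other numerical conventions, fixed and tested: probability clamping at
1e-7; attention softmax stabilized by per-neighbourhood maxima; Glorot
uniform initialization seeded from the model config; k-means ties and
degenerate cases (k ≥ number of distinct fingerprints) resolved by
assigning identical points to one cluster with zero within-cluster sum of
squares; F1 undefined (excluded from averages, with a warning) when
2TP+FP+FN = 0; MCC 0 when any marginal is zero; AUC by midranks
(Mann–Whitney, ties 0.5).

# Known limitations

* Chemistry perception (aromaticity, implicit hydrogens, hybridization)
  follows the OpenBabel/ChemmineR toolchain plus a standard valence
  model; exotic chemistry (organometallics, mesoionics) is outside the
  fixed feature schema and falls into "other" one-hot slots.
* The PubChem-style key table is a documented CACTVS-style subset, not
  the official 881-key dialect; the shipped table is the ground truth.
* The ErG descriptor measures distances on the full heavy-atom graph
  rather than the reduced ring-collapsed graph.
* The checkpoint format is an R serialization; it round-trips bit-exactly
  but is not portable to other languages.
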