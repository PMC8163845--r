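---
title: "Multi-dimensional retention-time prediction and CSM rescoring: models and design"
author: "xlinkRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dimensional retention-time prediction and CSM rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crosslinking mass spectrometry identifies pairs of covalently linked
peptides (crosslink spectrum matches, CSMs) from fragmentation spectra.
Spectral evidence alone is often ambiguous — typically one peptide of a pair
is matched well and the other poorly, which is exactly what a half-wrong
match looks like. Chromatographic behaviour is an orthogonal line of
evidence: the retention of a crosslinked peptide depends on *both* of its
peptides. xlinkRT predicts retention in up to three separation dimensions —
continuous reversed-phase retention time (RP, minutes) and discrete fraction
numbers from strong cation exchange (SCX) and hydrophilic strong anion
exchange (hSAX) — and folds prediction errors into a rescoring of CSMs under
target–decoy plus entrapment FDR control.

## The model

The predictor is a Siamese multi-task recurrent network. Each peptide is
tokenised (one token per residue; a modified or crosslinked residue is a
distinct token, e.g. `Mox`, `Kxl`), label-encoded against a corpus alphabet
(code 0 reserved for padding) and right-padded to `max_len`. Both peptides
pass through one shared embedding layer and one shared recurrent layer (GRU
by default, LSTM available). The two branch outputs are combined — additively
by default, which makes every prediction exactly invariant to peptide order —
and feed three pyramid-shaped dense subnetworks (defaults 50/20/10 units,
batch normalisation and dropout 0.1 between layers):

* **RP head**: one linear unit, squared-error loss. Targets are standardised
  internally (centre/scale stored in the model) so the loss scale does not
  depend on gradient length; predictions are back-transformed.
* **SCX / hSAX heads**: ordinal regression. Fraction $f$ of $n$ is encoded
  as $f-1$ leading ones in an $n$-vector ($f_1 = [0,0,0]$, $f_2 = [1,0,0]$,
  $f_3 = [1,1,0]$ for $n = 3$); the head has $n$ sigmoid units trained with
  binary cross-entropy, and a prediction is decoded as the first position
  whose probability falls below 0.5 (if none does, fraction $n$ — this cap
  is what keeps encode/decode an exact round trip, including $f = n$).

The total loss is the weighted sum
$w_{RP}\,\mathrm{MSE} + w_{SCX}\,\mathrm{BCE} + w_{hSAX}\,\mathrm{BCE}$, all
weights 1 by default (single-task configurations simply omit terms). The
last ordinal position is structurally zero; we keep it in the loss, where it
is harmless under binary cross-entropy, rather than dropping it.

Training is minibatch Adam (learning rate 3e-3, batch 128, 50 epochs by
default) with best-checkpoint selection on the total validation loss. One
master seed drives weight initialisation, shuffling and dropout, so training
is exactly reproducible. The forward and backward passes (including
backpropagation through time for both recurrent cell types and through the
batch-norm statistics) are implemented in vectorised base R and are verified
against central finite differences in the test suite.

Batch normalisation is applied in the dense subnetworks only, not after the
recurrent layer; with masked padded timesteps the final recurrent state is
already well-scaled, and this keeps the recurrent backward pass simple.

## Cross-validation and prediction strategy

RT learning never sees decoys. Confident CSMs — target–target matches with
q-value below 1%, deduplicated by the RT-level uniqueness key (the unordered
pair of modified sequences, ignoring link sites and charge) — are split into
k = 3 folds. Each fold model trains on the other folds, minus a 10%
validation subset used only to pick the best epoch, and predicts its own
held-out fold. Every other CSM (decoys, entrapment matches, low-confidence
TTs) is predicted by the fold model with the lowest total validation loss.

Split sizes follow a floor/ceiling convention: the test fold holds
$\lfloor N/k \rfloor$ keys, and $\lceil 0.1\,(N - \lfloor N/k\rfloor)\rceil$
of the remaining keys form the validation set. This is the unique convention
consistent with all three published split-size triples at N = 645, 3226 and
6453; when k does not divide N the remainder keys stay in every fold's
training portion and are predicted by the best fold, like out-of-confidence
CSMs.

## RT features and rescoring

For each CSM, three predictions per dimension: the pair (Siamese path) and
each single peptide alone (the same shared weights; the branch output goes
to the heads as if paired with an empty peptide). Alpha is the longer
peptide, ties broken lexicographically — a deterministic convention that
only fixes feature naming, since the model is order-invariant. Schema v1
derives 13 features per dimension (predictions, signed errors against the
observation, absolute errors, the squared pair error, and sum/min/max of the
two single-peptide absolute errors) plus, with all three dimensions, 4
aggregates (summed absolute and squared pair errors, summed single-peptide
absolute errors, Euclidean norm of the pair errors): 43 in total. Ordinal
errors are computed on decoded fractions, so they are in fraction units.
The exact published feature list is not public; schema v1 is chosen to
satisfy both published counts using only the named transform families, and
is versioned so alternative schemas can be plugged in.

Rescoring trains k = 3 linear SVMs. Positives: TTs passing the 1% cutoff
(entrapment TTs included — that is what later makes the entrapment rate a
valid overfitting alarm). Negatives: all TD and DD CSMs. Below-cutoff TTs
are unlabeled: each is scored by the average of the k models, while labeled
CSMs are scored only by the model that held them out. Folds are stratified
by score percentile so each fold spans the score range. Feature
standardisation (and optional SMOTE balancing, off by default and intended
for small datasets) is fit strictly inside the training folds. The
regularisation constant is picked from {0.01, 0.1, 1, 10} by an internal
3-fold CV; linear SVMs need standardised inputs for this grid to be
meaningful, which is why scaling is built in despite not being part of the
original description. The final score is
$xi_{rescored} = xi_{score} + xi_{score}\cdot SVM_{score}$, and q-values on
the rescored scores use the same machinery as before, so gains are read off
at constant estimated FDR.

## FDR machinery

CSM-level FDR is decoy-corrected: $(TD - DD)/TT$, clamped at zero when DD
exceeds TD by chance. Q-values monotonize the threshold sweep
($q(t)=\min_{s\le t}\mathrm{FDR}(s)$), with decoys counted before targets at
tied scores (conservative). Self and heteromeric links are thresholded as
independent populations; their search spaces differ by orders of magnitude,
so pooling them would let the abundant self-link signal mask heteromeric
error. Roll-up proceeds CSM → peptide pair → residue pair → PPI, each level
keyed order-independently, scored by its best member, and filtered at its
configured threshold (defaults 5%/5%/5%/1%) before the next level is formed.

## The entrapment builder

Entrapment proteins are known-irrelevant sequences searched alongside the
targets to measure error independently of decoys. Candidates sharing any
identical tryptic peptide (1 missed cleavage, maximum length 100, minimum
length 6) with a target are removed — exact peptide sharing is the event
that actually creates ambiguous CSMs, and for full-peptide alignments 100%
identity coincides with exact equality, so no alignment engine is needed.
Each target then receives its nearest unused candidate, greedily, targets
processed in descending length order (ties by accession): Euclidean distance
on z-score-standardised (K/R count, length) by default, or on the
20-dimensional residue composition for small databases. The combined
database is always exactly twice the target count.

## The synthetic-data generator

The generator emulates the statistical structure the method relies on, with
every latent label recorded:

* **Retention model.** Additive residue coefficients per dimension:
  Kyte–Doolittle hydropathy for RP; positive weights on K/R/H for SCX with
  the crosslinked K attenuated to a quarter weight (the linker consumes the
  charged amine); positive weights on D/E/Y/F/W for hSAX. Pair retention is
  the sum over both peptides. For RP the sum passes through a monotone
  gradient-shaped transform (a scaled normal CDF) so elution spreads nearly
  uniformly over a 20–110 min window — the profile a gradient optimised for
  even elution produces, and the regime in which a 5%-of-range noise floor
  still leaves the retention signal dominant. Gaussian noise defaults:
  4.5 min RP (5% of the 90-min window), 0.25 SCX, 0.30 hSAX — placing the
  generator's noise-only accuracy ceilings (about 50%/92% exact/relaxed for
  SCX, 73%/99% for hSAX) in the range reported for real multi-dimensional
  crosslink fractionation.
* **Fractions.** Continuous SCX/hSAX values are quantile-binned into 9 and
  10 fractions (the study design this emulates), with edges returned for
  reuse.
* **Classes.** 70% of CSMs are latent-true target–target matches (self
  links with probability 0.4). False matches draw their two peptides
  independently: decoy with probability 0.5 each (so TD − DD is an unbiased
  estimate of false TTs), entrapment origin with probability 1/3. False
  retention values are an even mixture of "one peptide correct" (the
  retention of a different pairing sharing one peptide) and a fully random
  draw — the two typical faces of a false CSM.
* **Scores.** Overlapping Gaussians (true: mean 11, sd 3.5; false: mean 5,
  sd 2.5), so a meaningful set of true matches hides below the 1% cutoff —
  the headroom rescoring is supposed to recover.

What the generator does *not* emulate: spectrum-level effects (fragmentation
quality, charge, precursor interference), correlated noise across
dimensions, ambiguous multi-fraction elution, and real peptide abundance
structure. Passing tests therefore demonstrate that the machinery is correct
and that the method behaves as designed *when its premise holds* — they are
not evidence about any particular real dataset.

## Numerical and degenerate-input choices

* Ordinal decode threshold fixed at 0.5 but configurable; the all-above-
  threshold case decodes to fraction $n$.
* Negative estimated FDR (DD > TD) clamps to 0; q-values cap at 1.
* FDR at zero accepted targets is treated as infinite during the sweep, so
  it can never be the minimising threshold.
* A CSM with an empty second peptide is rejected in crosslink mode (use
  linear mode); empty validation sets are rejected because best-checkpoint
  selection would be undefined.
* SMOTE falls back to duplication, with a warning, when the minority class
  is not larger than the neighbour count.
* Batch-norm running statistics use momentum 0.9 and are part of the model
  checkpoint, so inference is batch-independent and deterministic.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use 5000 simulated CSMs (about
2600 unique confident pairs), 3-fold CV at 40 epochs, and the full
feature/rescore/FDR chain; the negative-control experiment uses five
1600-CSM replicates. These sizes give stable estimates of every reported
quantity (binomial 95% intervals on the calibration checks) while keeping a
complete run in the minutes range on one CPU.

## Known limitations

* The recurrent encoder is trained from scratch per dataset; no pre-trained
  weights ship with the package (transfer learning is supported via
  `transferModel()`).
* Protein-group FDR and score boosting are not implemented.
* The SVM uses RT features (plus optionally the search score); fragment- or
  spectrum-level features are out of scope.
* The 43-feature schema is a reconstruction (v1) consistent with the
  published counts and transform families, not the verbatim published list.
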