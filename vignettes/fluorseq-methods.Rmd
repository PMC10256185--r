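---
title: "Models and methods in fluorseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fluorseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the generative model, the classifiers, and the
design and numerical choices behind `fluorseq`, in the spirit of a methods
section. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The generative model of a fluorosequencing experiment

A labeled peptide is summarized by its *dye sequence*: one character per
residue, `'.'` for unlabeled, a channel digit for labeled. Trailing
unlabeled residues are trimmed, because no imaging step can distinguish
peptides that differ only after their last fluorophore; peptides whose
trimmed codes coincide are merged into one reference class, with full
(peptide, protein) provenance retained. Peptides with no labelable residue
are dropped from the reference: they are dark at every timestep and can
never be observed, which mirrors the simulator's discarding of all-dark
reads.

Sequencing is simulated per molecule. Before cycle 0 each fluorophore is
independently a *dud* with probability `m_c` (units: probability per
molecule). Counts are logged at each of `T` timesteps; between logs the
molecule experiences, in order: detachment with probability `d`
(per cycle), an Edman removal of the N-terminal residue with probability
`1 - e`, and independent photobleaching of each surviving fluorophore with
probability `p_c` (per cycle). Raw reads add Gaussian radiometry noise:
a count of `Lambda` fluorophores in channel `c` is observed as
`N(Lambda * mu_c, sigma'_c^2 + Lambda * sigma_c^2)` — the variance grows
linearly in the count because each fluorophore's brightness fluctuates
independently on top of a fixed background.

Defaults (`seq_params()`): `p = 0.05`, `m = 0.07`, `e = 0.06`, `d = 0.05`,
`mu = 1.0` (arbitrary intensity units), `sigma = 0.16`,
`sigma_bg = 0.00667`, all identical across channels, following prior
single-dye characterizations (Atto647N). The number of timesteps is not
dictated by the error model; we default to `T = 10`, a typical imaging
run length that gives every labeled position a chance to be degraded past.

Internally the simulator draws, per molecule, a geometric detachment
lifetime, a geometric bleaching lifetime per fluorophore, and Bernoulli
Edman successes per cycle; this is distributionally identical to looping
cycle-by-cycle through the three events in their stated order, keeps the
per-position physical state explicit, and vectorizes across molecules. A
total-variation test against exact trajectory probabilities from the HMM
transition chain confirms the equivalence.

## The reduced-state HMM

The naive "physical" state of a molecule specifies which residue carries
which live fluorophore — exponentially many states in the number of
labels. The reduced model tracks only `(e*, l_1, ..., l_C)`: the number of
successfully removed residues and the surviving count per channel, plus
one absorbing DETACHED state, giving `1 + sum_e prod_c (n_c(e) + 1)`
states, where `n_c(e)` counts channel-`c` labels strictly after the first
`e` residues. Collapsing physical states loses no information because
duds and bleaching act i.i.d. across positions: conditional on the counts,
the surviving fluorophores are exchangeable over the remaining labeled
positions. The one place this matters is the Edman transition: when the
removed residue is labeled with channel `c`, the count drops by one with
probability `l_c / n_c(e*)` and is otherwise unchanged. We verify the
reduction against a brute-force physical-state HMM (explicit per-position
booleans) rather than assuming it: likelihoods agree to better than 1e-9
relative over random small dye sequences.

The one-step transition matrix is never formed for classification.
Instead it is kept as a product of sparse factors — detachment, Edman, and
one binomial dye-loss factor per channel — applied in the simulator's
event order. Any consistent order is model-equivalent (Edman and dye loss
commute in distribution; detachment is absorbing); one order is fixed for
bit-reproducibility. A test asserts that the composed factors equal an
independently constructed dense one-step matrix elementwise to 1e-12.

Timestep convention: `T` observations indexed `0..T-1` with `T-1`
transition applications between them, and `f(0)` already includes the
`t = 0` emission. `E_max = min(len, T - 1)` since no more residues can be
removed than cycles occur.

### Emissions, pruning, and numerics

Emission weights are products of per-channel Gaussian densities; DETACHED
emits background in every channel (it is emission-identical to an all-dark
attached state; we keep the two distinct, which leaves likelihoods
unchanged and only affects the bookkeeping of state counts). Observations
are densities, not probabilities, so forward values may exceed 1; the
forward vector is rescaled to unit sum at every step and the log scale
factors are accumulated, which avoids under- and overflow for any `T`.

Pruning zeroes the emission weight of any state whose count `l` in some
channel fails `|y_c - l mu_c| <= cutoff * sqrt(sigma'_c^2 + l sigma_c^2)`.
We include the background term in the per-count standard deviation — the
cutoff is a z-score against the state's own emission distribution. The
kept counts are completed to a contiguous range per channel, and a
nearest-count fallback guarantees the kept set is never empty, so pruning
alone can never zero the likelihood of every state in a channel. The
default cutoff of 5 makes pruned and unpruned log-likelihoods agree within
0.01 for ≥ 99% of default-parameter reads (asserted by the test suite);
a read's likelihood can still be legitimately zero under a model that
cannot plausibly generate it, which is the point of pruning.

The forward pass is implemented in C++ (RcppArmadillo sparse operators)
because it is the inner loop of every classifier; a pure-R reference
implementation (`fluorseq:::forward_likelihood_r`) is kept as the readable
specification, and tests pin the two to each other and to the dense,
unfactored forward at 1e-12 relative.

### Priors and observability

The default prior weights each dye sequence by its number of unique source
peptides. This was a genuinely open design choice: a uniform prior over
dye sequences looks natural, but reads are generated by *peptides* — an
experiment samples molecules, and a merged dye sequence backed by twenty
peptides is a priori twenty times more likely than a singleton. With the
uniform-over-dye-seqs prior the posterior scores are systematically
miscalibrated against peptide-uniform data (heavily merged classes are
under-weighted); with source-peptide-count weights the scores match
empirical accuracy closely, which the calibration test asserts. Explicit
`priors` (e.g. abundance estimates) can always be passed instead, and the
truncated hybrid posterior uses the same weights restricted to the
shortlist.

We do not condition likelihoods on a read's being observable
(retained-read bias): discarded all-dark reads are a property of the
data-collection process that the classifier never sees. For a retained
read the dark-track component of the likelihood is negligible, so the
omission has no practical effect on ranking; the calibration test bounds
any residual miscalibration.

## The kNN classifier

Training data are dye tracks, not raw reads: coarser, four times smaller,
and — after merging bit-identical tracks — massively deduplicated, with
each unique track carrying its multiplicity and per-peptide production
counts. The KD-tree (median split on the widest-spread dimension, static
after build) returns exact Euclidean nearest neighbors; a linear-scan
oracle in the tests asserts exactness, not approximation. Distances
compare raw-read intensities against track counts scaled by `mu_c` (with
`mu = 1` the two coincide; the scaling keeps the metric meaningful if
`mu` is recalibrated). Votes are weighted `multiplicity *
exp(-delta^2 / 2 sigma_kNN^2)` and split across producing peptides
proportionally to production counts. `k` counts merged entries rather
than underlying simulated reads — the tree contains merged points, and a
test shows scores are invariant to re-expanding duplicates when `k` covers
the same mass.

## The hybrid classifier

The kNN stage reduces the reference to at most `h` candidates per read,
ranked by vote weight (the selection criterion the vote already induces);
the HMM rescores the shortlist with the posterior normalized over the
shortlist only. Defaults `k = 10000`, `sigma_kNN = 0.5`, `h = 1000`,
cutoff 5 are the operating point at which parameter sweeps plateau:
larger `h` or `k` stops improving precision/recall while costing runtime
(the `sweep` CLI subcommand reproduces such sweeps at small scale). kNN vote
weights are used only for shortlisting, never as priors: the truncated
posterior stays uniform-prior, consistent with the full classifier.
Because the Gaussian kernel is strictly positive, every dye sequence voted
for by a retrieved neighbor is a legitimate candidate even when its weight
underflows to zero in double precision; keeping such candidates makes the
hybrid bit-identical to full Bayes in the exhaustive limit
(`k >=` index size, `h >=` reference size), which the tests assert.
Truncation shrinks the posterior denominator, so a candidate's hybrid
score is never below its full-Bayes score — also asserted per read.

## Evaluation machinery

PR sweeps process tied scores as a block, making curves independent of
sort order. At read level every retained read counts in the recall
denominator; at peptide and protein level the denominator is the set of
entities truly present among the sampled reads. Roll-up scoring divides a
read's score by the number of peptides sharing its winning dye sequence
(we use the merged dye-seq multiplicity as the ambiguity trigger, the one
sharply defined notion of "identifying more than one peptide") and a
peptide's score by its number of parent proteins, taking maxima at each
level. Calibration uses equal-count buckets sorted by score, remainders
assigned one-per-bucket to the leading buckets, deterministically.

The error-rate recovery estimators (`recover_error_rates()`) are designed
experiments, each isolating one parameter: dud rate from the dark fraction
at `t = 0`; Edman failure from first-cycle survival with other rates off;
detachment from a censored geometric MLE with Edman disabled (`e = 1`);
dye loss from one-cycle survival; `mu` and `sigma` from the mean and
excess variance of single-fluorophore intensities. Standard errors are
binomial, geometric-MLE, or delta-method as appropriate.

## Synthetic data and what the tests do and do not show

Test fixtures are synthetic random proteomes: i.i.d. residues at average
natural amino-acid frequencies, lognormal lengths around 300 residues.
This reproduces the combinatorics of real references (tryptic peptide
length distribution, label-count distribution, dye-seq collisions) but not
homology structure — real proteomes contain near-duplicate proteins and
shared peptides far beyond chance, which makes protein inference harder
than these tests suggest. Simulated reads come from the same error model
the classifiers assume, so the tests certify correctness of the
implementation and internal consistency (likelihoods, calibration,
classifier agreement), not robustness to model misspecification on real
instrument data.

Problem sizes used by the test suite were chosen to exercise the full
protocols at desk scale: 20-protein references with 1,000 training tracks
per peptide and 1,000–10,000 test reads for classifier comparisons and
calibration, a 100-protein reference with 2,500 reads for the
read/peptide/protein ordering experiment, and 100,000 molecules per
designed experiment for parameter recovery.

## Known limitations

* No missed cleavages, no proline blocking for trypsin, no terminal
  special cases: digestion is purely by residue identity.
* No FRET or dye–dye interactions (measured elsewhere to be negligible at
  these imaging conditions), no PTM-specific chemistry, no I/L handling.
* No decoy-database FDR; the predicted-PR machinery provides a model-based
  alternative but does not account for contaminants or modifications.
* Error rates are inputs, not fitted: Baum–Welch-style parameter fitting
  from real reads is out of scope.
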