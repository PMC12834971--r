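---
title: "Bidirectional molecular string generation: models, guards, and the RL loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional molecular string generation: models, guards, and the RL loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the string
encodings and the derivation automaton, the network variants and their
emission schedules, the constraint-preservation guard, the REINFORCE
fine-tuning loop, the reachable-space counting, and the choices made where
the design was genuinely open.

## Molecular strings and windows

Molecules enter the package as SMILES or SELFIES strings. Tokenization is
multi-character: bracket atoms, two-letter halogens and `%nn` ring closures
are atomic SMILES tokens; SELFIES tokens are the bracketed units. A
vocabulary is the sorted set of corpus tokens plus two specials: a dummy
start token (`G` / `[G]`) marking the generation origin, and a pad token
(`A` / `[A]`) that aligns all training strings to one window length
`m_total`. The start token is inserted at the middle of the string
(`placement = "fixed"`) or at a uniformly random position (`"random"`),
and pads fill the window symmetrically. The unidirectional variants use the
two natural edge placements instead (start token first or last, pads on the
far side), because a left-to-right generator must be trained on windows
whose core begins where its rollouts begin. Post-processing is exact
trimming: strip the start and pad tokens, concatenate the rest.

There is no end-of-string token. Generation always runs to the window
length under a *pad-freeze* rule — once a reading direction emits a pad,
that direction is forced to pad from then on — so pads form a contiguous
prefix and suffix and stripping is the exact inverse of windowing. Models
learn termination by predicting pads, which are ordinary emission targets
during training.

## The SELFIES derivation automaton

The SELFIES codec is implemented in the package (no R or Python SELFIES
library is assumed). The decoder is a derivation automaton over the achiral
organic subset (`B C N O P S F Cl Br I`, bond prefixes `=`/`#`,
`Branch1..3`, `Ring1..2`) with the standard overloading rules: the `L`
symbols after a `BranchL`/`RingL` symbol are re-read as base-16 index
symbols; a branch derives its `Q+1`-symbol content from the branching atom
under a capped derivation state; a ring bonds the current atom to the atom
`Q+1` places back, capped by both remaining valences. Bond orders are
always capped by remaining valence, which is what makes every token string
decode to a chemically valid molecule — the property the SELFIES variants'
100% validity rests on, and which the tests check on 10,000 random token
strings.

Two conventions deserve mention because the automaton's behaviour on
degenerate inputs is underdetermined:

* an *infeasible* special symbol (a branch with no spare valence, a ring
  before any atom, a truncated index window) is dropped singly; the symbols
  after it are re-examined as ordinary symbols. Under this convention,
  "the string contains an atom token" implies "the decode is non-empty",
  which makes the validity guarantee total rather than merely typical;
* a ring between already-bonded atoms raises the existing bond order
  (capped at a triple bond and by remaining valences), and rings formed
  inside a branch re-synchronise the branching atom's derivation state with
  its true remaining capacity, so valence accounting is exact across
  nesting levels.

The encoder walks a kekulized SMILES string in its own traversal order and
emits atoms with incoming-bond prefixes, `RingL` + index symbols at ring
closures, and `BranchL` blocks whose index symbols encode the content
length. Aromatic (lower-case) SMILES must be kekulized first
(`kekulize_smiles()` does this through the RDKit worker). The encodings of
the bundled seed fragments round-trip to the same canonical structures, and
five of the six match the reference token strings byte for byte.

## Network variants

All variants share one LSTM cell, the standard gate equations
(`i, f, o` sigmoid gates, `tanh` candidate, `c_t = f∘c_{t-1} + i∘c̃_t`,
`h_t = o∘tanh c_t`), implemented in batched base-R matrix code with
hand-derived backpropagation. The test suite checks the cell against an
independent scalar evaluation (1e-6) and every variant's full training
gradient against central finite differences (1e-4).

* **forward / backward**: BatchNorm over the one-hot inputs, two stacked
  LSTM layers, BatchNorm, Linear to vocabulary logits. The backward variant
  is the same machinery on reversed windows.
* **FB-RNN**: the BatchNorm input dimension and the Linear output dimension
  are doubled. Reading expands outward from the start position `g`: step
  `s` consumes the one-hot pair at window positions `(g+s-1, g-s+1)` and
  the output halves `y₊`/`y₋` predict positions `(g+s, g-s)`. Positions
  outside the window read and predict pads.
* **BIMODAL**: separate forward-reading and backward-reading stacks share
  the input BatchNorm; the logits for insertion position `p` are one linear
  map over the concatenated hidden states (forward state at `p−1`,
  backward state at `p+1`), i.e. `y = W₊h₊ + W₋h₋ + b`. Training computes
  one full pass per direction per window and supervises every non-start
  position; generation alternates sides (right on odd steps, left on even)
  and re-reads the full current window — unwritten slots read as pads —
  before each emission.

Batch-normalization statistics are pooled over batch and time in training
mode; generation and all RL computations run in eval mode (running
statistics), so sampling is a pure function of the weights and rollouts
never mutate normalization state. Inputs are one-hot vectors; there is no
learned embedding table. Weights initialize uniform with fan-in scaling
under the configured seed.

Defaults: maximum-likelihood training uses Adam at `1e-3` for 10 epochs
with minibatches of 32, window length `max core length + 3`, and 5-fold
cross-validation in `molgen_cv()` (deterministic splits; one checkpoint per
fold and epoch). The hidden size defaults to 64; the desk-scale experiments
in the tests use 24–256 units and corpora of a few hundred molecules, in
place of the hundreds of thousands of drug-like molecules and 1024 hidden
units a production run of this architecture would use.

## Constrained generation and the preservation guard

A seed constraint replaces the lone start token: the window is initialized
with the seed token run (centered, or uniformly placed under random
placement) and generation grows both sides under each variant's schedule.
`validate_seed()` checks the three preconditions for a usable seed: it
decodes to a molecule, both terminal attachment atoms have an open valence,
and the token list is not a whole-number repetition of a shorter substring
(the aperiodicity assumption of the counting argument below).

Left context can rewrite the meaning of SELFIES seed tokens: a
`Branch`/`Ring` symbol emitted left of the seed may consume seed tokens as
index symbols, a declared branch may end inside the seed run, and a
saturated left chain truncates derivation before the seed is reached.
Rather than hoping a trained model avoids these, the sampler masks them
out. Leftward emissions are screened in two layers:

1. a static scope check excludes special symbols whose index window covers
   seed positions, and branch symbols whose declared content would overlap
   the seed only partially (full containment is harmless: the seed then
   derives, intact, inside the branch);
2. each atom candidate is checked by *simulating the derivation* of
   `[candidate, already-written suffix]` up to the seed end in a
   valence-cap domain, and rejecting candidates whose fragment fails to
   derive the seed with exactly its reference internal bonds, external
   bonds only at the two terminal atoms (one each), and no outside path
   connecting the two attachment partners (a new ring through seed atoms
   would re-aromatize them and break substructure identity). Because the
   pad token is always admissible and a special symbol at the core's left
   edge is a no-op, every final core has been validated by the guard of its
   leftmost emission — preservation is a structural invariant, not a
   statistical tendency.

Rightward emissions need only one rare guard: a token that lands in the
index window of a pending ring symbol (which can sit at most two positions
back) is checked by the same fragment simulation, collapsed over index
classes. For SMILES seeds the left guard is simpler — ring-closure digits
used inside the seed are excluded, everything else either leaves the seed's
parse intact or produces an invalid string that the validity filter
removes.

The cost is a masked sampling distribution: the policy is the renormalized
softmax over admissible tokens, and the RL machinery uses exactly that
distribution (masks are recorded per emission and replayed in the gradient
computation).

## Reinforcement learning

Fine-tuning maximizes the expected terminal reward of complete rollouts
with a variance-reduced policy-gradient update: advantage = terminal reward
minus the batch-mean baseline; surrogate objective
`(1/K) Σᵢ (Σₜ log π(aₜⁱ)) (Rⁱ − R̄) + β (1/K) Σᵢ Σₜ H(π(·|sₜⁱ))`;
optimizer AdamW (decoupled weight decay). Per-trajectory log-probabilities
are summed over emission steps; forced pad emissions after a freeze are not
actions and contribute neither log-probability nor entropy. Gradients are
computed by replaying the recorded rollout computation graph (exact for the
sampled masked policy, including BIMODAL's partial-window passes), and the
tests verify them against finite differences of an independently
recomputed surrogate.

The composite reward is `R = w_q·QED + w_s·p_s` with
`p_s = −(SA − 1)/9 ∈ [−1, 0]`; QED and the SA score come from RDKit, raw SA
values are clamped to `[1, 10]` before rescaling, and invalid molecules
(possible only under SMILES) receive terminal reward 0 — a neutral value on
the same scale, rather than an extra penalty the reward definition does not
contain. Defaults follow the reference protocol: `K = 32`, `T = 1.0`,
learning rate `1e-4`, weight decay `1e-2`, `β = 1e-4`, 120 episodes, with
an optional early stop when a 10-episode moving average of the batch reward
stalls (patience 20 episodes, tolerance 1e-3; disabled by default since the
reference protocol runs a fixed budget).

One caveat worth stating precisely: the batch-mean baseline includes each
trajectory's own reward, so the estimator's expectation is scaled by
`(K−1)/K` relative to the no-baseline estimator — a shrinkage, not a
direction change, and far below sampling noise at `K = 32` for the reward
scales involved. The test exercises the regime the baseline exists for
(rewards sharing a large common offset), where the variance reduction is
large and the shrinkage is within noise.

The RL demonstration in the acceptance tests pretrains an FB-RNN SELFIES
model with 256 hidden units for 10 epochs on a 500-molecule synthetic
corpus and fine-tunes for 100 episodes on `w = (1, 1)`. The width matters:
under AdamW each coordinate moves at most about the learning rate per step,
so the achievable logit displacement over a fixed episode budget scales
with the hidden dimension; very small models move in the right direction
but by less than a standard error in 100 episodes.

## Counting the reachable space

For an alphabet of `L` tokens, constraint length `N` and total length `M`,
the package reports three numbers: the unidirectional count `L^(M−N)`; the
dominant bidirectional term `L^(M−N)(M−N+1)` (offsets × completions, before
correcting for strings that contain the constraint more than once); and the
exact number of length-`M` strings containing the constraint, computed by a
dynamic program over the KMP failure-function automaton of the pattern
(`L^M` minus the avoiding strings). The exact count is the quantity the
closed-form correction series approximates; the printed form of that series
is ambiguous as typeset, so the package owns the exact automaton count —
verifiable against brute-force enumeration, which the acceptance tests do
for every pattern of length ≤ 3 over alphabets of size ≤ 3 and `M ≤ 10` —
and reports the dominant term alongside. All counts use an internal
base-1e7 big-integer arithmetic, since `L^(M−N)` overflows doubles at
drug-like sizes. The sandwich `uni ≤ exact ≤ dominant` and the exact ratio
`dominant/uni = M−N+1` hold for every query.

## Evaluation battery

`compute_uvn()` reports the chained percentages: unique among sampled
(distinct raw strings), valid among unique, novel among valid. Uniqueness
is at the raw-string level; novelty compares RDKit canonical structures
against the canonicalized training set, since string-level novelty would
credit trivially rewritten duplicates. `mw_test()` / `ks_test()` wrap the
two-sided Mann–Whitney and Kolmogorov–Smirnov tests (degenerate identical
constant samples return p = 1); no multiple-testing correction is applied,
matching the raw-p-value reporting convention the tables follow.
Fingerprints are 2048-bit Morgan, radius 2 (the bit length is prescribed,
the radius is the common ECFP4-equivalent choice), and `embed_2d()`
delegates t-SNE (default perplexity 30) to scikit-learn with a fixed seed.

## What the synthetic corpus does and does not show

`make_toy_corpus()` draws random SELFIES token strings over a small
C/N/O alphabet (first token an atom token), decodes, canonicalizes, and
de-duplicates. This emulates the *format* and the statistical machinery of
a drug-like training set — variable lengths, branches, rings, a nontrivial
property distribution — but not its chemistry: molecules are small
(roughly 1–12 heavy atoms), QED centers near 0.3 rather than 0.55, and the
corpus carries no bioactivity signal. Green tests therefore certify the
mechanics (encoding, training dynamics, guarantee-level invariants,
gradient correctness, the direction of RL effects), not the
pharmacological quality of generated libraries; headline distributional
metrics of a production corpus (e.g. latent-space distances against
reference sets) are out of scope, though an adapter can plug any external
scorer in as a named reward.

## Numerical notes and limitations

* Ties and degenerate inputs: empty strings are invalid; a seed that is a
  pure repetition is flagged rather than rejected (the counting argument,
  not generation, needs aperiodicity); saturated chains stop deriving, as
  in the reference automaton.
* BatchNorm uses ε = 1e-5 and momentum 0.1 (biased batch variance for
  normalization, unbiased for the running estimate).
* Sampling uses inverse-CDF draws from the masked temperature softmax;
  all randomness flows through R's RNG, so a single seed reproduces
  corpora, training, rollouts and fine-tuning bit for bit.
* The SELFIES subset is achiral and ignores isotopes/charges; stereo-aware
  encodings and alternative encodings of the same seed structure (which
  would let constraints attach at other atoms) are not implemented.
* The exact-count module treats tokens as opaque symbols; it does not
  condition on chemical validity of the completions.
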