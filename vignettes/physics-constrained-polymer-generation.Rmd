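---
title: "Physics-constrained generation of degradable polymers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-constrained generation of degradable polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydeg)
```

`polydeg` frames degradable-polymer design as a constrained sequential
decision process: an agent assembles a polymer monomer by monomer, a
chemical-feasibility mask removes invalid moves before they can be
taken, physics constraints are enforced by an augmented-Lagrangian
scheme, and a hierarchical reward scores degradability. This vignette
is the package's own account of the model, its assumptions, the
defaults that matter, and what the desk-scale experiments do and do not
show.

## The polymer representation and its assumptions

A polymer lives in two synchronized views. The **sequence view** is a
SMILES dialect extended with four bracketed polymer tokens — `[>]`
chain initiation, `[<]` termination, `[$]` stochastic point, `[#]`
cross-link site. The grammar restricts polymer tokens to the top level
of the string (not inside branches): without that restriction the
notation would be ambiguous about which chain a marker annotates, and
nothing in the chemistry needs marker tokens inside a side group.
`parse_bigsmiles_ext()` and `serialize_sequence()` are exact inverses
on well-formed strings, which the tests exercise over seeded corpora.
Full stochastic-object notation (nested repeat-unit lists) is out of
scope.

The **graph view** is an atom/bond graph with three mutually exclusive
edge roles: backbone, side-chain attachment, cross-link. Node and edge
indices are 1-based throughout (the natural convention for R).
Hydrogens are implicit; `check_validity()` applies organic-subset
valences adjusted by formal charge (cations of N/O/P/S gain a bond,
anions and carbocations lose one), reports every violated rule
(valence, connectivity, charge) and never throws — invalidity is data,
because the reward needs it.

`build_polymer_graph()` replicates a repeat unit `repeat_count` times,
joining copies tail-to-head along the backbone. When a unit carries
cross-link sites, consecutive sites are joined by a cross-link edge so
the role is observable on a built graph; during generation, sites stay
open until a cross-link modify action consumes them.

Morgan fingerprints are computed directly on this graph type (the
polymer edge roles and cross-link-site flags participate in the atom
and bond invariants, which off-the-shelf small-molecule fingerprints
would ignore). Neighbor environments are sorted before hashing, making
the fingerprint invariant to node relabeling — a property the suite
checks with random permutations.

## Encoders

The graph encoder alternates gated GIN message passing

$$h_i^{(l+1)} = \mathrm{MLP}\left((1+\epsilon)\,h_i^{(l)} +
\sum_{j \in N(i)} h_j^{(l)} \odot \sigma(W_e e_{ij} + b_e)\right)$$

with residual multi-head self-attention over all atoms, and sum-pools
node states into $h_G$. Sum pooling is a deliberate choice: it
preserves the injectivity argument that makes GIN-style aggregation as
discriminative as the Weisfeiler–Lehman test, where mean or max
pooling would not. The sequence encoder is a small pre-norm
transformer over the token vocabulary with a masked-language-model
loss; its `[CLS]` output $z$ joins $h_G$ and the descriptor vector $d$
in `fuse()`, which applies an MLP, layer normalization, and dropout
(inactive in eval mode, so inference is deterministic).

Defaults are a desk-scale profile — 2 GIN layers, hidden width 32,
2-head attention, 32-dimensional sequence embeddings — chosen so the
whole pipeline runs in seconds on one CPU; the full-scale profile (6
layers, hidden 256, 12-head/768-dim sequence encoder) is reachable
purely through configuration. The encoders work untrained (random
initialization) for every pipeline test; optional MLM pretraining on a
fixture corpus is available through `mlm_loss()`. How attention
queries/keys are formed from node states is not pinned down by the
framework's equations; the package uses standard per-head Q/K
projections, as a default rather than a derived fact. Atom and bond
feature layouts (one-hot element classes, bond orders, polymer roles)
are likewise configuration, with natural widths of 12 and 8.

## The construction environment

Actions come in three categories, enumerated in a fixed order (adds by
monomer id, then modifies, then terminates). The compatibility matrix
`M_rxn` (monomers x end-group labels, 0/1) gates add actions: monomer
*i* may attach iff `M_rxn[i, j] = 1` for the chain's open end-group
*j*; a pseudo-group `"init"` gates chain starters. Modify and
terminate actions are trial-applied and checked, so the mask is sound
by construction: every mask-allowed action yields a graph that passes
`check_validity()`. The reaction history enters the state as a fixed
summary (category counts plus the last 4 action indices) and the
environment context carries the curriculum stage and step index — both
encodings are package choices where the framework leaves the content
open. Modify actions are available from the first monomer onward
(another documented default), and episodes are capped at 32 actions by
default. Retrosynthetic construction of `M_rxn` is out of scope;
matrices are inputs or fixtures.

## Physics constraints and duals

Positive constraint values are violations:

* `g1 = -dG_formation + dG_threshold` — the formation-stability
  surrogate is a group-contribution sum over atom contexts and bond
  orders from a shipped table, signed so that well-formed organic
  structures score positive; with the default threshold of 0 kJ/mol
  the constraint asks for a non-negative stability score. The
  threshold is configuration (no canonical value exists for the
  surrogate's scale).
* `g2 = SA - 4.5` — synthetic accessibility on a 1–10 scale from our
  own fragment-contribution implementation: familiarity of each atom's
  radius-1 environment relative to a shipped frequency table built
  from the package's reference corpus, plus penalties for fused rings,
  stereocenters and macrocycles, mapped monotonically into [1, 10].
  The 4.5 threshold is the normative constant of the constraint
  formula (a stricter 4.0 screening figure also circulates; the
  constraint keeps 4.5).
* `g3 = rho_min - rho_crosslink` — cross-links per kg/mol. `rho_min`
  defaults to 0, deactivating g3 for linear-polymer stages; it is
  meant to be enabled for cross-linked (stage-3) systems.

The penalty is `sum_i lambda_i max(0, g_i)^2` and multipliers follow
dual ascent `lambda <- max(0, lambda + eta E[g])` with `eta = 0.01`.
In training the penalty is folded into the per-episode return, so
constraint pressure propagates through the learned values — the
textbook augmented-Lagrangian objective evaluated on the data
distribution. Dual updates run once per epoch (`train$dual_every`
episodes, configurable); the alternation between policy improvement
and constraint tightening is the point, not the exact cadence.

## Rewards

`R = R_validity + alpha R_degradability + beta R_properties + gamma
R_synthesis`, with `R_validity` exactly +1.0 / -10.0. Degradability is
`w1 R_enzyme + w2 R_hydrolysis + w3 R_microplastic + w4 R_kinetics`:

* **Enzyme term.** Mean over a panel of
  `sigmoid((-dG_bind - mu_e) / sigma_e)`. Docking is replaced by a
  pluggable binding-energy provider; the shipped surrogate is
  `dG_bind = -(a_e * ester-SASA-fraction + b_e * hydrophobic-contact)`
  with per-enzyme coefficients, and `mu_e, sigma_e` calibrated as the
  surrogate's mean/sd over the fixture library's homopolymers — so the
  reward averages ~0.5 over the calibration set by construction (a
  property the tests assert at tolerance 0.05). Any function with the
  provider signature can replace it.
* **Hydrolysis term.** `rho_ester x SASA_ester / SASA_total`. Ester
  density is per heavy atom of the structure (the density's basis is a
  documented package choice; a per-mass variant is a one-line
  provider change). SASA uses our Shrake–Rupley implementation with a
  fixed golden-spiral point layout (192 points by default, probe 1.4
  Å), validated against the analytic single-sphere area (1%) and a
  10^6-point brute-force oracle on overlap cases (2%). Conformers come
  from classical MDS of bond-count distances scaled to 1.54 Å with a
  fixed sub-Ångström symmetry-breaking offset — deterministic, cheap,
  and adequate for surface *ratios* of repeat units; it is not a
  conformer search, and absolute areas should not be over-read.
* **Microplastic and kinetics terms** are named but undefined in the
  source framework; they ship as explicit placeholders (fragment-size
  proxy; deviation of an ester-density rate proxy from a target) with
  default weights `w3 = w4 = 0`, so no result silently depends on an
  invented formula. Property and synthesis scorers are likewise
  pluggable and default to 0.

The diversity bonus (minimum Tanimoto distance to a FIFO buffer of
recent fingerprints, 1 on an empty buffer) is added to the training
reward with its own coefficient (default 0.5) rather than folded into
the hierarchical sum, mirroring its role as an exploration device
alongside the entropy bonus. Components are left on their natural
scales; the meta-learner is the mechanism that absorbs scale
differences. `meta_update_weights()` treats the weights as the outer
variable of a bi-level problem and takes forward finite-difference
steps on task validation losses, clipping at zero — a first-order
approximation chosen because exact bi-level gradients through policy
training are neither available nor needed at this scale.

## Agent

The policy is a tanh-Gaussian over a continuous latent
(`u = tanh(mu(s) + sigma(s) * xi)`, 4-dimensional by default) decoded
to the nearest mask-allowed action embedding, ties to the lowest
index. The embedding table assigns each action a deterministic
position in the latent cube derived from its id, so decoding is stable
across runs; embeddings are fixed rather than trained — at the toy
action-space sizes the nearest-neighbor geometry, not embedding
adaptation, carries the signal. A categorical softmax variant
(advantage logits over the action catalogue with a running value
baseline — a value/advantage decomposition — updated by
policy-gradient with entropy regularization) is available behind
`train$policy = "categorical"`; it converges much faster on the toy
tasks and is what the constrained-training demonstrations use, while
the SAC path is exercised by the update-level tests and the default
pipeline. Dueling critics are not used in the continuous-latent SAC
(they fit value-based discrete methods); the categorical variant's
baseline plays that role.

SAC specifics: twin critics with entropy-regularized targets, soft
target updates at `tau = 0.005`, global gradient clipping at norm
10.0, cosine-annealed learning rate with warm restarts, and input
standardization with running statistics on the critics only (the
actor is never normalized, since squashing interacts badly with the
constraint-shaped returns). Prioritized replay follows
`P(i) ∝ (|delta_i| + eps)^alpha` with `alpha = 0.6`, importance
weights `(1/(N P(i)))^beta` normalized by the batch maximum (the
common stabilization; the formula itself leaves normalization open),
`beta` annealed 0.4 → 1.0, and max-priority insertion so every new
transition is sampled at least once. Buffers hold a few thousand
transitions at desk scale, so sampling uses exact probabilities
rather than a sum tree. All randomness flows from the single run
seed.

The curriculum ramps difficulty as
`D_t = D_min + (D_max - D_min) sigmoid(k (t - t0))` and maps it to
monomer tiers at fixed cut points; the toy tiers hold 20/60/120-style
splits in spirit — tier 1 commodity monomers, tier 2 expanded
condensation/ring-opening chemistry, tier 3 cross-linkable monomers —
not the original library sizes. Convergence is monitored by a
composite of min-max-normalized sliding-window validity, diversity and
mean reward (window 100), with early stopping after 100
non-improving episodes; the combination is a package choice, the
ingredients are not.

## The synthetic fixtures: what they emulate, what they do not

`make_toy_library()` generates seeded monomer libraries across three
polymerization classes (vinyl chain growth; condensation
hydroxyl/carboxyl chemistry; ring-opened lactone-style units, the
tier-3 subset carrying cross-link sites), plus saturated "trap"
monomers with all-zero compatibility rows: structurally valid
molecules whose forced attachment creates a valence violation. Traps
are what make the no-mask ablation informative — with masking,
validity is 100% by construction; without it, random construction
attaches traps and validity drops to roughly a third on the default
library. `make_enzyme_panel()` draws surrogate coefficients and
calibrates normalization on the library's homopolymers;
`make_pretrain_corpus()` emits rollout-sampled polymer strings with
stochastic-point tokens inserted at rate 0.5 between units. Every
fixture is a pure function of its spec and seed.

What passing tests on these fixtures shows: the machinery —
representation round-trips, mask soundness, constraint algebra, dual
dynamics, replay law, reward arithmetic, metric definitions — behaves
exactly as specified. What it does not show: chemical realism of the
surrogates (no docking, no DFT, no real SA reference database), or
that the agent would discover genuinely novel degradable chemistry in
a commercial-scale monomer space. Results obtained from GPU-scale
training on such spaces are directional context for this package, not
reproduction targets; the desk-scale analog of the validity claim —
100% with masking, strictly less without — is exact by construction
and is tested.

## Numerical choices and degenerate inputs

Tie-breaks in action decoding go to the lowest action index. Layer
normalization uses eps 1e-5; tanh-Gaussian log-densities clamp
`1 - u^2` at 1e-6; log-scales are clamped to [-8, 1] and their
gradients zeroed at the clamp. Empty graphs encode to zero vectors and
score zero formation energy; zero-mass graphs make cross-link density
error rather than return NaN; overlapping identical atom centers are a
degenerate-geometry error in SASA (n_points >= 92 enforced);
non-finite SAC losses skip the update with a warning instead of
corrupting parameters; non-finite meta-losses skip the weight update.
Unknown configuration keys are errors naming the key, and every run
log embeds the fully resolved configuration, seed and package version
before the first episode record.

## The constrained-training demonstrations

Two training experiments in the acceptance suite deserve their design
rationale here. The **dual-feasibility task** restricts the library to
the condensation monomers and raises the stability threshold to 180
kJ/mol on the surrogate's scale, so short chains violate g1 and only
6-7-unit chains satisfy it: the initial policy violates on average
(mean violation ≈ 3 over the first 50 episodes), the multiplier
engages (λ1 peaks near 1.8) and decays back once the policy builds
long chains, and the trained policy's 100-polymer evaluation batch
shows zero mean violation — below the 1e-3 tolerance regime, across
seeds. The **diversity demonstration** trains 300 episodes at a low
entropy floor (0.01), where the no-bonus ablation begins to collapse
onto high-reward monomers; enabling the diversity bonus yields
strictly higher mean pairwise Tanimoto distance over the final 60
training polymers on every one of five seeds. Both use the categorical
policy variant for its reliable desk-scale convergence; problem sizes
(400 and 300 episodes, 8- and 6-action episodes) were chosen once as
the smallest runs on which the dynamics are unambiguous.

## Known limitations

* The binding, stability and accessibility scorers are deterministic
  surrogates with package-defined scales; conclusions transfer to real
  chemistry only through their pluggable interfaces.
* Conformers are MDS embeddings of the graph metric, not conformer
  searches; chain-level conformational effects (coiling, burial of
  esters in a melt) are invisible.
* The latent-SAC path learns much more slowly than the categorical
  variant on toy action spaces; it exists to keep the full
  continuous-policy machinery tested and available, not because it is
  the best desk-scale optimizer.
* Hypervolume is exact only up to 3 objectives; novelty uses a
  refined-invariant canonical key, which can in principle collide
  (isomorphism is checked up to hashing, as with any fingerprint
  method).
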