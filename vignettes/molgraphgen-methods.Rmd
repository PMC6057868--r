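---
title: "Sequential molecular graph generation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential molecular graph generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative model

`molgraphgen` implements sequential generative models over molecular
graphs. A molecule is a labeled graph $G = (V, E)$: nodes carry atom types
— the triple (element symbol, number of explicit hydrogens, formal charge)
— and edges carry one of four bond types (single, double, triple,
aromatic). Generation starts from the empty graph $G_0$ and repeatedly
samples a *transition* $t_i \sim p_\theta(t_i \mid G_i, \ldots, G_0)$ from
a learned *decoding policy*, applying it to obtain $G_{i+1} = t_i(G_i)$
until a termination action is drawn.

The decoding scheme restricts transitions to four kinds:

* **initialization** — place the first atom (only on the empty graph);
* **append** — add a new atom and bond it to an existing atom; the new
  atom becomes the *latest atom* $v^*$;
* **connect** — add a bond between $v^*$ and another existing atom
  (ring closure); connects may only start from $v^*$;
* **terminate** — stop.

Because an append carries its bond with it, a molecule with $|E|$ bonds is
produced in exactly $|E| + 2$ steps (initialization and termination
included) — a property the test suite asserts exactly, molecule by
molecule. Chemical validity is deliberately *not* enforced during
decoding: the policy is expected to learn valence and aromaticity rules,
and validity is assessed only on finished graphs.

## Decoding policies

At each step the policy must emit a jointly normalized distribution over
every admissible action: a per-atom *append* matrix $\mathbf{p}^A_v$ of
size $|A| \times |B|$ (append an atom of each type with each bond type at
atom $v$), a per-atom *connect* vector $\mathbf{p}^C_v$ of length $|B|$,
and a termination scalar $p^*$. Unnormalized scores come from
exponential-activation heads and are divided by their total mass $P$; in
this implementation all head arithmetic is kept in log space and the
normalizer is a log-sum-exp over the full action set, so the normalization
identity holds to machine precision and underflow cannot occur on long
routes.

Two architectures share the same trunk:

* **MolMP** treats generation as a Markov process: the policy sees only
  the current graph.
* **MolRNN** adds a molecule-level recurrent unit: a stack of GRU layers
  is updated with the representation of the latest atom $h_{v^*}$ and the
  pooled graph representation $h_{G_i}$, and its state replaces $h_{G_i}$
  in the action heads. This is the package default: the recurrent state
  lets the policy remember decisions across steps at almost no extra cost.

The trunk embeds each atom (type + a latest-atom flag; default width 16)
and applies $L$ graph-convolution layers. Each layer computes

$$ h_v^{l} = W^l h_v^{l-1}
   + \sum_{b \in B} \Theta_b^l \sum_{u \in N_b(v)} h_u^{l-1}
   + \sum_{1 < d \le D} \Phi_d^l \sum_{u \in N_d(v)} h_u^{l-1}
   \;(+\, \Psi^l \mathbf{c}), $$

i.e. an edge-type-conditioned aggregation of bonded neighbors plus
distance-binned aggregation of remote neighbors up to the receptive field
$D$ (default 3, shortest-path distances recomputed on the partial graph at
every step), plus an optional linear injection of the conditional code
$\mathbf{c}$ at every layer. Layer outputs are concatenated (a dense skip
connection), passed through a two-layer fully connected trunk, and pooled
by an atom-wise mean to give $h_G$.

Reference widths are 6 convolution layers of 32–256 units, a 256/512
trunk, 128-unit heads and three 512-unit GRU layers (`molgen_config()`
defaults); all experiments in the tests use much smaller desk-scale
configurations (2 convolution layers, 64-unit GRU), which train in
minutes on one CPU.

Two deliberate architectural deviations, both documented here as package
design choices:

* **No batch normalization.** The reference trunk interleaves BN with the
  convolutions. At desk scale a graph state has 1–20 atoms and training
  proceeds molecule-by-molecule, so per-state batch statistics are
  degenerate and running estimates would be dominated by tiny early
  states. The layers here are plain ReLU–convolution; every learning
  experiment in the test suite converges without BN.
* **Initialization head.** The graph network cannot produce a
  distribution on the empty graph, so the first atom type is drawn from a
  learned categorical (linearly shifted by the conditional code when one
  is present).

All gradients are derived and implemented by hand in base R (there is no
autodiff here) and are validated against central finite differences for
both architectures in the test suite.

## Routes, $q_\alpha$, and the likelihood

Many decoding routes $r$ produce the same molecule, so the exact
likelihood $\log p_\theta(G) = \log \sum_{r \in R(G)} p_\theta(G, r)$ is
intractable in general. Training instead maximizes an importance-weighted
lower bound: routes are drawn from a proposal $q_\alpha(r \mid G)$ and

$$ \log p_\theta(G) \ge
   \log \tfrac1k \sum_{i=1}^k
   \frac{p_\theta(G, r_i)}{q_\alpha(r_i \mid G)}. $$

$q_\alpha$ follows the canonical depth-first route but makes a "random
mistake" with probability $1 - \alpha$ at each step. The package makes
this precise as follows:

* The canonical route starts at the atom of canonical rank 1, appends
  tree edges depth-first in ascending rank order, and emits every ring
  closure as soon as the closing atom is the latest atom (ascending
  target rank). Canonical ranks come from an iterative Morgan-style
  refinement of (symbol, explicit H, charge, degree) with an index
  tie-break — deterministic by construction. (The toolkit bound to this
  package does not expose its canonical atom ranking, so the ranking is
  implemented in-package.)
* A *mistake* is a uniform draw over the alternative actions that are
  still consistent with eventually producing $G$. Consistency is tracked
  through the set of live embeddings of the partial graph into the
  target; an embedding dies when an unbuilt edge between already-placed
  atoms loses its chance to be emitted (both endpoints old, neither is
  $v^*$). Enumerating actions — not target-atom choices — makes
  symmetric choices collapse, so $q_\alpha$ is an exact, properly
  normalized distribution over distinct routes and `log_q` is its exact
  log-probability. The tests verify that the realized route masses sum
  to one and that the empirical mistake rate converges to $1 - \alpha$.
* $\alpha = 1$ recovers deterministic canonical decoding with
  $\log q = 0$ and $k = 1$; the loss collapses to the exact negative
  log-likelihood of the canonical route. Defaults follow the reference
  setup: $\alpha = 0.8$ with $k = 5$ routes per molecule, and
  $\alpha \in \{1.0, 0.8, 0.6\}$ are the supported study settings.

For molecules of at most five atoms the package can enumerate $R(G)$
exhaustively (`enumerate_logp()`), again over distinct action sequences
via the embedding machinery. This oracle anchors the acceptance test: on
ten tiny molecules, the $k = 10^4$, $\alpha = 0.6$ importance-weighted
estimate must match enumeration within three Monte-Carlo standard errors.

## Training

Adam (beta1 0.9, beta2 0.999, eps 1e-8) with initial learning rate 0.001
and a decay of 0.001 applied every 100 iterations; 5 epochs with
mini-batches of 200 molecules are the configured defaults. The decay
phrase admits two readings, so both are implemented:
inverse-time $\mathrm{lr}_t = \mathrm{lr}_0 / (1 + \gamma \lfloor t/100
\rfloor)$ (the default) and exponential
$\mathrm{lr}_0 (1-\gamma)^{\lfloor t/100 \rfloor}$. Fine-tuning on a
focused sub-corpus uses learning rate 1e-4, decay 0.002, 10 epochs
(`fine_tune_config()`). With $\alpha = 1$ the canonical routes and their
per-step graph featurizations are computed once and reused across epochs,
which is what makes the desk-scale experiments fast; training at
$\alpha = 1$ under a fixed seed is bitwise deterministic.

At sampling time, connects targeting $v^*$ itself or an atom already
bonded to $v^*$ are masked before renormalization. These are structural
impossibilities (the transition could not be applied), not chemistry:
chemically invalid actions remain available, exactly as during training.
A step cap (default 100 transitions, covering molecules up to roughly 50
heavy atoms) guards against non-terminating samples; capped samples are
reported with status `step_cap`, finished-but-unsanitizable ones as
`invalid_chemistry`.

## Chemistry model

SMILES parsing, canonicalization, substructure matching, fingerprints and
MW/logP descriptors are delegated to Open Babel (via ChemmineOB). Aromatic
bonds are kept aromatic — not kekulized — because "aromatic" is one of the
four bond types; aromatic flags are read from the MOL2 representation and
accepted only on ring bonds (Open Babel also flags delocalized acyclic
groups such as carboxylates, which the parser demotes to their integer
orders). Explicit-hydrogen counts follow SMILES reader semantics: an atom
carries explicit hydrogens only when a bracket atom would be required to
write it (so the pyrrole nitrogen is ("N", 1, 0) while benzene carbons are
("C", 0, 0)).

Validity of a finished graph is decided by an in-package sanitization
model: a valence check against an allowed-valence table (charge-adjusted),
and an aromaticity check requiring every aromatic bond to lie in a ring
and every aromatic system to admit a Kekulé assignment, computed as a
perfect matching over the atoms that must carry a ring double bond. This
matches sanitizer semantics — any kekulizable system is accepted — and the
suite verifies exact agreement with an independent toolkit's verdict on
random graphs and valence-violating perturbations. Failures are classified
as `valence`, `aromaticity` or `other`, the taxonomy used when inspecting
generated samples.

Two scores have no R implementation and are computed through a batched
bridge to the Python RDKit toolkit shipped with the package
(`inst/python/props.py`): QED (drug-likeness, 0–1) and the SA score
(synthetic accessibility, 1–10, higher = harder). Everything else runs
in-process.

## Conditional generation

A conditional code $\mathbf{c}$ enters every convolution layer through
$\Psi^l \mathbf{c}$ and the initialization head through a linear shift.
Three code families are provided:

* **Scaffold fingerprints** — binary substructure membership over a
  scaffold set built from Bemis–Murcko scaffolds (iterative removal of
  terminal atoms) plus ring assemblies (connected components of the
  ring-bond subgraph), deduplicated by canonical SMILES. Hydrogen counts
  are repaired when a substituent is stripped, so e.g. an N-methyl
  pyrrole nitrogen becomes an explicit-H pyrrole nitrogen.
* **(QED, SA) property codes**, via the RDKit bridge. Requirement
  regions ("QED above 0.84, SA below 1.9") are expressed as per-dimension
  interval boxes; codes are sampled from the empirical distribution of a
  reference set restricted to the box.
* **Activity codes** — bits from random-forest classifiers on circular
  (ECFP6-style, radius 3) fingerprints folded to 2048 positions, with a
  0.5 probability threshold and class weighting for imbalanced labels.

## Evaluation metrics

* **Validity** — fraction of samples that sanitize; **novelty** —
  fraction of valid canonical SMILES absent from the training set.
* **Property divergences** — $D_{KL}$ and $D_{JS}$ between generated and
  reference distributions of MW, logP and QED, via Gaussian kernel
  densities with Scott's-rule bandwidth ($h = \hat\sigma n^{-1/5}$),
  integrated on a 2048-point grid spanning both samples extended by three
  bandwidths, with densities floored at $10^{-12}$ before the logarithm.
  The closed-form checks (zero for identical distributions, $\delta^2/2$
  for unit-variance Gaussians shifted by $\delta$) hold to the accuracy
  the kernel estimate allows, which is the tolerance the tests use.
* **Conditional control** — $K_{cc'}$, the fraction of the sample set
  generated under $c$ that satisfies $c'$; its diagonal $R_c$; and the
  enrichment over random $EOR_c = R_c / R^0_c$ against the training-set
  base rate (reported as undefined when $R^0_c = 0$).
* **Reproduction rate** — the fraction of a known-active test set
  recovered by the union of two conditional sample sets, all as
  canonical-SMILES sets.
* **Internal diversity** — mean Tanimoto distance of ECFP6-style
  fingerprints over the full $M \times M$ pair set. The definition as
  written includes self-pairs (distance zero), and that is the default;
  conventions differ, so a diagonal-excluded variant is available via
  `include_self = FALSE`.

## The synthetic data generator

`random_molecules()` grows random bond trees with valence-respecting bond
orders (85/12/3 percent single/double/triple, elements weighted toward
C/N/O with some S and halogens, up to 20 heavy atoms) plus occasional
single-bond ring closures, rejecting any draft that fails sanitization.
`synthetic_conditional_corpus()` attaches a benzene ring to roughly half
of the molecules and labels each with a rule (by default the
benzene-substructure bit), producing a two-class corpus with an
unambiguous structural signal. These fixtures emulate the *combinatorial*
structure of small organic molecules — valence-correct trees with
occasional rings, a balanced conditional signal — but not the property
distributions, aromatic ring diversity, functional-group chemistry or
size profile of a real compound collection. Tests passing on them
demonstrate that the machinery (decoding, likelihood, optimization,
conditioning, metrics) is correct at desk scale; they say nothing about
sample quality achievable on a real corpus, which requires training at
the reference scale.

Desk-scale problem sizes used by the test suite, chosen so the whole
suite runs in minutes on one CPU: ten-molecule corpora of up to eight
heavy atoms for the overfit experiment (tiny MolRNN, two convolution
layers, 64-unit GRU, 300 iterations, 500 samples); a thirty-molecule
two-class corpus for conditional control (250 iterations, 250 samples per
code); $10^4$ sampled routes for the likelihood and calibration checks.
The learning rate for these experiments is the configured default 0.001.

## Known limitations

* Stereochemistry, isotopes and multi-fragment molecules are out of
  scope; SMILES output ignores stereo descriptors.
* The allowed-valence table covers the organic subset plus common
  hetero-elements; exotic elements are accepted without a valence
  constraint.
* Canonical ranks use index tie-breaks, so routes are canonical with
  respect to the package's own ranking, stable for a given atom order
  but not an isomorphism invariant in the strict sense.
* Training is single-process; the multi-GPU synchronous setup of the
  reference configuration is not reproduced.
* `enumerate_logp()` is capped at five atoms by design; it is a test
  oracle, not a user-facing likelihood.
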