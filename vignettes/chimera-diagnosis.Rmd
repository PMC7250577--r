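---
title: "Diagnosing chimeric gene origin: models, parameters and design choices"
author: "chimeraTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing chimeric gene origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

Some genes are chimeras: their protein domains descend from different
source lineages. The canonical signature of a eukaryotic gene that acquired
one domain from a bacterium by horizontal gene transfer (HGT) is a split
phylogenetic affinity — one domain groups with eukaryotic homologs, while
the other is *nested inside* a bacterial gene family rather than branching
as a sister group to it. Nesting matters: a sister-group placement is
compatible with deep vertical ancestry plus loss, whereas a placement
inside the bacterial radiation, flanked on both sides by bacterial clades,
is parsimonious only under transfer.

`chimeraTrace` turns that reading into a tested computation with five
stages:

1. **Iterative two-domain ortholog discovery.** Position-specific scoring
   profiles of the two domains are searched against a protein database; a
   record is accepted only if both domains match at E ≤ 0.01 with the
   N-terminal domain strictly before the C-terminal one. No length,
   composition or conservation requirement is placed on the inter-domain
   linker. Newly found domain segments are aligned back to the profiles,
   the profiles are rebuilt, and the search repeats until the accepted set
   reaches a fixed point.
2. **Sliding-window provenance profiling.** Overlapping 60-column windows
   of the ortholog alignment are each turned into a profile and searched
   against the database; hits are counted by domain of life (eukaryotes
   split into the focal family and the rest). A horizontally acquired
   domain shows up as a contiguous run of windows dominated by donor-domain
   hits. Two readings of the stacked counts are distinguished: a category
   *leads* a window when it holds the plurality of hits (the signature of
   the transferred domain), and the transfer-like configuration proper is a
   *sustained majority* — consecutive windows in which one foreign domain
   of life holds more than half of the hits. Raw counts inherit database
   composition: a bacteria-rich family legitimately out-counts a handful of
   eukaryotic homologs in isolated windows even under pure vertical
   descent, so single-window majorities are not evidence of transfer.
3. **Similarity networks.** All-vs-all global alignment of the domain
   segments; edges connect pairs at ≥ 30% identity (and positive alignment
   score). Cross-taxon edge fractions summarize which domain of life the
   focal segments actually touch.
4. **Per-domain maximum-likelihood trees** on profile-aligned,
   occupancy-trimmed segments, with nonparametric bootstrap on request.
5. **Constrained-topology testing and classification.** The focal clade's
   placement is read from the rooted tree (nested / outgroup / unresolved),
   and any cross-domain `nested_in` call must survive a SOWH
   parametric-bootstrap test against the vertical-inheritance alternative
   before it is reported.

## Models

### Substitution model

All sequence evolution — simulation and inference — uses reversible
amino-acid models specified by symmetric exchangeabilities and equilibrium
frequencies, rescaled so one unit of branch length equals one expected
substitution per site. Two instances ship with the package:

* `lgModel()` — the LG exchangeabilities, optionally with observed
  frequencies (the "+F" convention used when fitting trees); the default
  generator model with a discrete-gamma rate mixture (shape 1, 4
  categories).
* `poissonModel()` — equal rates, uniform frequencies. Under this model
  the two-sequence divergence has the closed form
  *P(differ) = (19/20)(1 − e^(−20t/19))*, which the test suite exploits as
  an independent oracle for both the simulator and the likelihood engine.

The likelihood is computed by Felsenstein pruning with per-pattern
rescaling; transition matrices come from the spectral decomposition of the
symmetrized rate matrix. Branch lengths are optimized one edge at a time by
safeguarded Newton iterations on the exponential-mixture form of the
per-edge likelihood, and the topology search is NNI hill-climbing from a
neighbor-joining start. Gaps and `X` are missing data. The engine is
validated against exhaustive summation over internal-node states (≤ 5
tips) and against an independent pruning implementation.

### Profiles and E-values

A profile column stores log2-odds scores
`log2((counts + w·background) / (n + w) / background)` with a
background-proportional pseudocount (weight `w = 1` by default). This is a
deliberate reduction of a full profile HMM: the discovery logic needs
ranking and envelopes, not per-state transition estimates; affine gap
penalties (4 bits open, 0.5 bits extend) stand in for insert/delete states.
Columns under 50% occupancy are excluded so gap-dominated windows cannot
carry signal.

E-values are calibrated per profile by scoring residue-shuffled,
length-matched decoys drawn from the database itself and fitting a Gumbel
law by moments to the per-sequence maximum scores. `E(s) = N · P(S ≥ s)`
is then an expected hit count: strictly decreasing in the score and linear
in the database size, which the tests assert, along with the defining
property that a database of decoys yields about one hit at E ≤ 1.

The two thresholds used throughout are the field's conventions: 0.01 for
stringent searches (discovery, tree and network membership, provenance
windows) and 10 for deliberately permissive domain scans (available via
configuration).

### The SOWH test

The statistic is `δ = lnL(unconstrained ML) − lnL(best constraint-compliant
ML)`. The null distribution is obtained parametrically: alignments are
simulated on the constrained ML tree under the fitted model and re-analyzed
identically; the p-value uses the add-one rule `(1 + #{δ* ≥ δ}) / (1 + n)`,
which can never reach zero. Two constraints are used by the pipeline:

* **domain-of-life monophyly** (every domain with ≥ 2 tips must form a
  clade) for cross-domain `nested_in` calls. This is the
  vertical-inheritance alternative. A plain "eukaryote monophyly"
  constraint is strictly weaker: the constrained search can satisfy it
  cheaply by dragging the handful of eukaryotic homologs *into* the
  bacterial radiation next to the focal clade, which defeats the test.
* **focal monophyly** for within-domain calls, attaching support without
  gating the call.

Hill-climb failures inflate δ on either side, so both searches are
multi-start: the constrained search starts from a data-informed resolution
of the constraint and from a constraint-repaired copy of the free ML tree
(and, inside the bootstrap, from the generating tree); starts are screened
by branch-length optimization and the full NNI search runs from the best.
Without the multi-start guard, roughly a quarter of null replicates showed
spuriously inflated δ from one failed constrained search.

When the free ML tree already satisfies the constraint the statistic is
exactly zero and the test cannot reject — the p-value is then conservative
by construction; rejections arise from the genuinely violated replicates,
which keeps the type-I error at its nominal level (the test suite verifies
the 5% level within its exact binomial 95% interval over 200 replicates of
a 6-taxon, 300-site null).

### Classification

`classifyDomainAffinity()` operationalizes the qualitative tree reading:
`nested_in X` requires the focal clade's sister group *and* the next
outgroup to be ≥ 80% from domain X while the sister group is not the set of
all X sequences jointly; sister-to-all-X is `outgroup_to X`; everything
else — including a non-monophyletic focal set — is `unresolved`. The 80%
threshold is exposed in the configuration. Trees are rooted on a
user-specified outgroup domain (archaea by default for the transferred
domain, mirroring the practice of rooting on the deepest available
outgroup) and by midpoint otherwise.

## The synthetic scenario generator

Because the real databases behind any published case are far beyond desk
scale, validation runs on seeded, ground-truthed simulations
(`generateScenario()`):

* a eukaryote taxon tree (10 taxa by default) carrying family A — the
  vertically inherited, eukaryote-restricted domain (80 aa) — in every
  taxon, with the fusion clade (4 taxa) built in by construction;
* a bacteria-dominated family B (180 aa, the size class of a hydrolase
  domain) on a bacterial tree (8 taxa), with archaeal (3) and eukaryotic
  (3) homolog subfamilies attached at stems of 0.45–0.55 expected
  substitutions per site — far enough that cross-domain homologs sit near
  the stringent E-value threshold, close enough that a family-wide profile
  recovers them;
* fusion genes `M + domainA + linker + domainB`: domain A is a paralog
  duplicated at the fusion-clade ancestor; the linker evolves 3× faster
  with per-lineage lengths (15–40 aa) and carries all indels, domains being
  indel-free so that window and envelope arithmetic stays exact;
* in the `chimera` scenario the fusion B domain descends from a point
  *inside* the bacterial tree; in `null_vertical` it descends from the
  eukaryotic family-B ancestor alongside the carrier taxa;
* unrelated background proteins drawn i.i.d. from the equilibrium
  frequencies, and nucleotide transcripts of each fusion gene embedded in
  random UTRs on a random strand, with an in-frame upstream stop so that
  six-frame translation plus longest-ORF extraction recovers the protein
  exactly.

Taxon trees are Yule trees rescaled to 0.7 expected substitutions per site
root-to-tip. The donor branch is drawn uniformly among internal branches of
the bacterial tree **not incident to its root**: a root-adjacent donor
differs from a sister-group attachment by a fraction of one branch length,
which is not the nested configuration the scenario exists to emulate (this
is the one deliberate narrowing of the "uniform over internal branches"
idea, and the reason is exactly the identifiability argument above). The
transfer stem is 0.15 substitutions per site.

What the generator does **not** emulate: genome assembly or gene-structure
prediction, codon usage, alignment uncertainty from true indel processes
inside domains, compositional heterogeneity across lineages, and the sheer
taxon breadth of real databases. Passing tests therefore demonstrate that
the pipeline's logic and statistics behave correctly when its assumptions
hold — not that any particular empirical gene family will be as clean.

## Numerical and design choices worth knowing

* **Tie-breaking** in all dynamic-programming tracebacks is fixed (pair >
  consume-first-sequence > consume-second), so outputs are bit-stable.
* **Occupancy trimming** keeps columns at exactly the threshold (≥ 0.70);
  the boundary is inclusive by our convention.
* **Identity edges** additionally require a positive alignment score:
  percent identity over doubly-ungapped columns is spuriously high for
  unrelated sequences aligned mostly through gaps.
* **Membership is iterated.** The discovery profiles know only the
  orthologs, so the tree/network membership search runs twice: once with
  the discovery profile, once with a profile rebuilt from all first-pass
  family hits (recalibrated), which recovers remote outgroups and removes
  ortholog-specific alignment bias. The second pass made the difference
  between losing and keeping the archaeal outgroups in roughly one run in
  ten.
* **Analysis model defaults**: LG with observed frequencies and a
  2-category discrete gamma (shape 1). Two categories capture most of the
  rate-variation misfit at a quarter of the 4-category cost; the category
  count is a configuration knob, and `fitGammaShape()` is available when
  the shape itself is of interest.
* **Pipeline problem sizes**: the validation suite runs 20 chimera and 20
  null scenarios at the generator defaults with 40 SOWH simulations per
  test, and the SOWH calibration uses 200 replicates of a 6-taxon,
  300-site Poisson null with 100 simulations each. These sizes were chosen
  so that each estimate's Monte-Carlo error is small relative to the margin
  the corresponding test asserts.
* **Calibration lives at the boundary.** When the generating tree carries
  the constrained split on a well-supported branch, the ML tree virtually
  always satisfies the constraint, the statistic is identically zero and
  the test is degenerately conservative — nothing about its level can be
  learned there. The calibration fixture therefore draws the constrained
  split at a fraction of one expected substitution, the regime where the
  constraint is actually contested; the measured type-I error is then at
  its nominal 5% level.
* **Determinism**: every stochastic stage derives its seed from the run
  seed via a fixed integer mix (`splitSeed()`); rerunning a configuration
  reproduces `report.json` byte for byte.

## Known limitations

* The tree search is NNI-only hill-climbing; at the package's intended
  problem sizes (≤ ~30 tips) multi-starts compensate, but very large trees
  would need SPR-class moves.
* The profile model has no insert/delete states, no glocal mode and no
  multi-hit statistics; envelopes of severely fragmented homologs can be
  truncated (mitigated by padding envelopes to the profile span before
  re-alignment).
* The SOWH test inherits the usual parametric-bootstrap caveats: its
  calibration is exact only when the analysis model matches the generating
  process; model misspecification makes it anticonservative.
* `nested_in` calls require a rootable tree; when no outgroup-domain tips
  survive the membership threshold, midpoint rooting is used and calls are
  correspondingly less reliable (such calls are gated by the SOWH test).
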