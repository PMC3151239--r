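---
title: "Detecting orthologous gene displacement by exhaustive placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting orthologous gene displacement by exhaustive placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogdscan)
```

## The problem

Universally distributed single-copy genes — mostly components of the
translation machinery — are the hardest genes to transfer horizontally: an
incoming ortholog must displace the resident copy and keep functioning in a
foreign cellular context (orthologous gene displacement, OGD). Detecting
such events requires comparing the phylogenetic signal of one gene family
against the combined signal of many families that share a core history. The
idea is that genuine phylogenetic signal is cumulative while homoplastic
noise is dispersive, so a *confident, distant* disagreement between a
family's signal and the combined tree is evidence of a displacement rather
than of noise.

`ogdscan` implements the detector and its downstream analyses. The combined
tree is an input (its construction — alignment curation, bootstrapping,
consensus — is a separate, upstream task); the package's job begins with a
tree and per-family alignments.

## The placement scan

For each branch of the unrooted combined tree:

1. **Prune** the clade the branch defines. The two branches left dangling at
   the former attachment node merge into one (lengths add), and the exact
   attachment point is recorded, so pruning is invertible.
2. **Enumerate** one candidate insertion point per residual branch. With
   *m* residual leaves this gives 2m−3 candidates, the original position
   included. Candidates sit at residual-branch midpoints, except on the
   branch carrying the original attachment, where the exact original point
   is used. The midpoint choice is symmetric, makes the path-length distance
   between candidates well defined, and avoids privileging either endpoint.
3. **Score** each candidate tree by its sitewise log-likelihoods under the
   JTT substitution model (Felsenstein pruning). By default the model uses
   empirical ("+F") amino-acid frequencies from the family alignment and a
   single substitution rate; discrete-gamma rate heterogeneity (4 categories,
   user-supplied shape) is available as an option. The single-rate default
   mirrors evaluating each family under a likelihood engine's default
   settings with only the model switched to JTT; whether per-family
   evaluation benefits from gamma rates is data-dependent, so it is a flag,
   not an assumption.
4. **Weigh** the candidate set with expected likelihood weights via RELL
   bootstrap (default B = 1000 replicates): resample sites with replacement,
   sum the resampled sitewise log-likelihoods per candidate, convert to
   normalized likelihood weights in log-sum-exp form, and average over
   replicates. The weights are nonnegative and sum to exactly 1.
5. **Call** a putative displacement when the best non-original candidate has
   ELW ≥ 0.65 *and* path-length distance ≥ 0.40 substitutions/site from the
   original attachment (measured on the residual tree, where both points
   exist on one geometry). Because the ELW cutoff exceeds 0.5, at most one
   candidate can qualify per branch. Both cutoffs are compared inclusively
   (the narrative "of at least 0.65" and "greater than 0.4" readings differ;
   inclusive is the default and strictness is configurable).

Each pruned branch's candidate set is its own ELW universe: the weights
answer "where does this branch belong?", not "which of all 140k trees is
best". This is the per-branch reading of the placement procedure.

Two filters then run per family: exactly **reciprocal pairs** (X→Y and Y→X)
are removed because the direction of transfer cannot be identified, and
**ancestral donors** (donor on the root-ward path of its recipient) are
removed because such placements cannot be separated from vertical signal.

### Donor identity

The best insertion branch lives on the *residual* tree. It is reported as
the combined-tree branch whose bipartition, restricted to the residual
taxa, matches the insertion branch's bipartition; when the insertion falls
on the merged branch at the former attachment the match is ambiguous
between the two merged branches, and the smaller (more specific) clade is
reported. Donor and recipient are always identified by their clade leaf
sets, which are stable across trees.

### Branch lengths of candidate trees

Candidate trees keep the combined tree's branch lengths by default
(`branch_mode = "none"`). We initially re-optimised the three branches a
regraft creates (`"local"`), but measurement on synthetic data showed this
is structurally unfair: when the gene's true history conflicts with the
reference tree *anywhere*, a candidate whose three free branches happen to
sit near the conflict can absorb it — we observed candidates gaining 40–190
log units over the locally-optimised original placement by stretching a
0.03-substitutions/site insertion branch to more than 1 — manufacturing
confident false calls out of conflict that has nothing to do with the
pruned branch. Fixed lengths treat all candidates symmetrically; full
re-optimisation of every branch (`"full"`) is the faithful-but-slow
alternative and both remain available. This is the one place the package
deliberately departs from re-using a generic "optimise what changed"
heuristic.

### The cutoff grid

`parameter_grid()` recomputes the call count over ELW cutoffs 0.55–1.00 in
steps of 0.05 and distance cutoffs 0.1–1.0 in steps of 0.1 (100 cells; the
0.05 step is forced by the 100-combination design — a 0.5 step over that
range is not meaningful). Grid counts apply the ancestral-donor filter but
*not* the reciprocal-direction rule: that rule removes calls in pairs, so a
stricter cutoff that eliminates one member revives the other, and the
surface would not be monotone. With per-call criteria only, counts are
monotone non-increasing in both cutoffs by construction.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `elw_cutoff` | 0.65 | weight | conservative plateau setting; >0.5 guarantees uniqueness |
| `distance_cutoff` | 0.40 | subst/site | separates displacement from phylogenetic uncertainty |
| `B` | 1000 | replicates | RELL Monte-Carlo error ~1/√B; 1000 is the conventional default |
| `branch_mode` | `"none"` | — | symmetric treatment of candidates (see above) |
| `freqs` | `"empirical"` | — | +F convention; per-family composition |
| `gamma_alpha` | `NULL` | shape | single rate by default; gamma(α, 4 categories) optional |
| `seed` | required | — | every stochastic step (RELL resampling) derives from it |

## Geometry conventions

* Branches are identified by the leaf set ("clade") on the side of their
  bipartition away from a virtual root — the explicit root point when set,
  otherwise a fixed anchor (the lexicographically smallest leaf). Ordering
  is a deterministic post-order with children visited by smallest
  descendant label, so branch tables are reproducible across platforms.
* `clade_total_length()` (the evolutionary-opportunity measure of the rate
  analysis) sums the branch lengths *strictly inside* the clade for
  internal branches — the subtending branch belongs to the parent's
  history, not the clade's — and uses the branch's own length for leaves,
  where the stated rule is explicit.
* Donor–acceptor evolutionary distances and dating use **branch
  midpoints**: dating is defined with midpoints, and the same convention is
  applied to the distance analyses for consistency. The all-pairs null
  enumerates unordered, non-nested branch pairs — the same support on which
  calls can exist after the ancestral-donor filter, so observed and null
  distributions are comparable.
* Transfer dating: for each call, the path-length distances from the
  donor/acceptor LCA to each branch midpoint, with half the branch length
  as the interval half-width (the event may have occurred anywhere along
  either branch). Intervals that intersect are consistent with clock-like
  branch lengths. The branch carrying the root point may have its midpoint
  across the root; the distance is then measured through the root point.

## Statistical stages

KS (two-sample, asymptotic p), Wilcoxon rank-sum (exact enumeration when
n·m ≤ 400 without ties, otherwise normal approximation with continuity
correction) and Pearson correlation wrap the standard R implementations.
The linearity analysis fits calls ~ clade length by OLS and reports three
p-values: the slope t-test, a quadratic-term F-test (curvature evidence
against linearity), and a Wald–Wolfowitz runs test on residual signs (exact
combinatorial distribution up to n = 30, normal approximation with
continuity correction beyond). The runs and linearity tests are implemented
in-package as transparent equivalents of the intent — the upstream
description attributes them to two different libraries inconsistently, so a
package-free, documented formulation was preferred. Raw p-values are
reported throughout; no multiple-testing correction is applied.

## The synthetic-data generator

`simulate_tree()` draws a pure-birth tree, rescaled to root-to-tip height
2 substitutions/site — deep enough that displacement distances up to ~4
substitutions/site exist, while 500-site alignments remain informative.
`inject_transfers()` models a displacement as an SPR of the recipient
lineage onto the donor branch midpoint (the recipient's gene copy comes to
descend from the donor), with three realism constraints: the recipient
clade is small (1–3 leaves, the typical single-lineage displacement), donor
and recipient must **coexist** (their depth spans from the root overlap —
lineages that never coexisted cannot exchange genes; this is also what
makes dating intervals of true events coincide in the clock limit), and
ancestral donors are excluded (that signal is vertical). Successive events
keep disjoint leaf neighbourhoods so truth records stay unambiguous.
`evolve_alignment()` simulates sites forward under the same JTT engine the
scan uses. `simulate_traits()` produces clade-correlated GC (bounded
Brownian), log-normal genome sizes and multinomial habitat counts.

What the generator does **not** emulate: alignment error and indels, rate
variation across families and lineages, model misspecification (sites are
generated under the scoring model), incomplete taxon sampling of the donor
lineage, and duplication/loss. Passing the recovery tests therefore shows
the detector is correct and well-calibrated *under its own model*, not that
real-data calls are error-free — on real alignments the false-positive
guard is carried by the conservative cutoffs, not by model fidelity.

## What recovery does and does not mean

On 20 simulated datasets (10 taxa, 500 sites, one injected transfer at
residual-tree distance ≥ 0.6 per transfer family, plus one clean family
each), the scan detects every injected event at the default cutoffs —
recipient exact, donor exact, ELW ≈ 1 — and clean families yield zero calls
in 20/20 seeds (the acceptance suite asserts ≥ 18/20). One subtlety is
documented rather than hidden: in noise-free simulation the *mirror*
description of an event — prune the true donor, and its best placement is
the recipient's branch — is equally supported, so the two calls form an
exactly reciprocal pair and the direction rule discards both. This is the
rule operating exactly as designed (the direction genuinely is
unidentifiable from unrooted single-gene placement); with the rule applied,
end-to-end sensitivity in this regime is 0.60, and the acceptance suite
asserts the detection-level sensitivity (≥ 0.8) and the post-rule fraction
(≥ 0.5) separately. A single true transfer also *echoes*: prunings of
branches near the donor or the vacated region can themselves prefer
confident distant placements, so transfer families typically yield a
handful of calls describing one event. Clean-family specificity is the
meaningful false-positive surface.

## Numerical choices

* Likelihood: per-message column scaling with log accumulators (no
  underflow up to at least 200 leaves); site likelihoods under gamma mix
  categories by log-sum-exp.
* The attachment engine evaluates each candidate in O(1) matrix products
  using directional partial-likelihood bundles computed once per pruned
  branch; it agrees with full-tree pruning to ~1e-14 and the full-tree
  pruning agrees with an independent implementation and with exhaustive
  state enumeration to 1e-8 (test suite).
* Branch-length optimisation (where requested) is derivative-free 1-D
  coordinate search, lengths bounded to [1e-8, 20] substitutions/site,
  convergence at 1e-4 log-units, 5 sweeps (local) / 20 (full).
* Transition probabilities come from the spectral decomposition of the
  π-symmetrised rate matrix; tiny negative entries from round-off are
  clamped to zero.
* Zero-length branches are legal everywhere and contribute zero distance.
* ELW ties (identical sitewise vectors) yield exactly equal weights;
  ranking ties break by candidate order, so reports are deterministic.

## Known limitations

* Single-copy families only: paralogy, duplication/loss and multi-copy
  families are out of scope (recipients are assumed to hold exactly one
  copy, which the displacement replaces).
* The combined tree is trusted as fixed and bifurcating; polytomies must be
  resolved upstream, and uncertainty in the reference topology is not
  propagated into the calls.
* Direction of transfer is unresolvable for exactly mirrored call pairs
  (discarded by design).
* `branch_mode = "full"` evaluates faithfully but is impractical for large
  candidate sets; the default trades per-candidate length re-fitting for
  symmetry and speed.
* The all-pairs null holds the tree fixed; it measures distance preference
  given the tree's shape, not a generative model of transfer opportunity.
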