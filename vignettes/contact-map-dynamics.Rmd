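---
title: "Contact-map dynamics: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-map dynamics: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactdyn)
```

# The model

A molecular-dynamics trajectory samples conformations of a biomolecule
through time. Most summaries of such trajectories (RMSD, RMSF, coordinate
PCA) require superimposing frames onto a reference, which becomes
ill-defined when the molecule unfolds or switches states — average
coordinates can be physically meaningless. This package works instead in
*contact space*: the matrix of interresidue distances, which is invariant
to rotation and translation by construction, so no fitting is ever
performed.

For residues $i$ and $j$ the working quantity is the clamped minimum
distance over a selected atom class,

$$ r_{ij}(t) \;=\; \begin{cases} r_{ij}^{\min}(t) & r_{ij}^{\min}(t) < r_\mathrm{cut} \\ r_\mathrm{cut} & \text{otherwise,} \end{cases} $$

where $r_{ij}^{\min}(t)$ is the minimum over all selected-atom pairs of
the Euclidean distance. Distances are plain Euclidean: the trajectory is
expected to be pre-processed so molecules are whole across periodic
boundaries; the package applies no minimum-image correction (a documented
assumption, not a silent one — see Limitations).

A pair is **live** once its distance falls strictly below
$r_\mathrm{cut}$ in at least one frame; all other pairs are disregarded
and never stored, which keeps memory proportional to the number of
residue pairs that ever interact rather than to $N_\mathrm{res}^2$.
Live-pair discovery is single-pass: frames before a pair's first
sub-cutoff encounter are backfilled with exactly $r_\mathrm{cut}$, which
is the value those frames hold by the definition of first encounter, so
one pass loses nothing.

**Contact state with hysteresis.** A contact forms when
$r_{ij} < r_\mathrm{inter}$ and breaks only when
$r_{ij} > r_\mathrm{inter}^\mathrm{high}$; between the two thresholds the
previous state is carried. This dual-cutoff rule (a standard device in
native-contact analysis) prevents a few outlier frames from fragmenting a
stable interaction into many short lifetimes. With
$r_\mathrm{inter} = r_\mathrm{inter}^\mathrm{high}$ it reduces exactly to
single-threshold detection. The dual rule can only remove break events,
never add them — a property the test suite checks on random walks.

# Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `r_cut` | 1.0 | nm | main cutoff; storage clamp and live-pair gate |
| `r_inter` | 0.5 | nm | contact formation threshold |
| `r_inter_high` | `r_inter` | nm | contact breaking threshold (hysteresis when larger) |
| `atom_class` | `heavy` | — | atoms entering the minimum distance |
| `min_seq_separation` | 1 | residues | excludes only the diagonal, keeping near-diagonal secondary-structure signal |
| `stride`, `begin`, `end` | 1, −∞, ∞ | —, ps | frame subsampling window |
| `mode` | `full` | — | `full` stores every frame; `economy` streams aggregates |
| `dt` | 1.0 | ps | synthesized frame spacing for formats without time stamps |

Heavy atoms are the default class because hydrogens roughly quadruple the
atom-pair search space while adding little structural information. Strict
inequalities define both cutoff comparisons ("within cutoff" means
$r < r_\mathrm{cut}$, matching the clamp's case split); a first frame
lying inside $[r_\mathrm{inter}, r_\mathrm{inter}^\mathrm{high}]$ starts
*off*, a choice the run log records since either convention is
defensible.

# Derived statistics

- **Aggregate maps.** Mean, standard deviation (population convention,
  $1/N$ — $N$ is the frame count and typically large; the choice is
  stated because no standard fixes it), minimum, and hysteretic contact
  fraction per pair. Streaming accumulation uses Welford's update, so
  economy mode is numerically equivalent to the two-pass computation
  (checked to 1e-10).
- **Encounter maps.** First/last time each pair's state is on. In pulling
  runs the last-encounter map is the rupture-time map. Pairs still in
  contact at the final frame are *persistent* and carry the sentinel −2
  in matrix output (never-on pairs carry −1), so an unbroken contact
  cannot be misread as a late rupture. The hysteretic state (not the raw
  threshold) defines encounters, consistent with the stability rationale
  of the dual cutoff; `contact_states()` with a single cutoff recovers
  the raw-threshold variant if wanted.
- **Correlation maps.** Pearson $r$ between each pair's clamped distance
  series and time, or an external observable. Negative $r$ against time
  means approach (formation), positive means separation (rupture).
  Correlations use the clamped series — the values the store actually
  holds — with an option to restrict to frames strictly below
  $r_\mathrm{cut}$. Zero-variance series are reported as *undefined*
  (`NA`), never as 0, so flat pairs do not masquerade as "no trend".
- **Cross-correlation.** $C_{ij} = \mathrm{cor}(n_i(t), n_j(t))$ with
  $n_i(t)$ the number of contacts of residue $i$ under the hysteretic
  state. This captures, e.g., competition of two residues for the same
  partner as a negative entry, without any interframe fitting.
- **Inter-frame contact RMSD.**
  $D_{ab} = \sqrt{\tfrac1P \sum_p (r_p(a) - r_p(b))^2}$ over the $P$ live
  pairs. This is the natural contact-space analogue of coordinate RMSD
  and, being a scaled Euclidean norm of pair-vector differences, a true
  metric — symmetry, identity and the triangle inequality are verified in
  the tests rather than assumed.
- **Clustering.** Agglomerative clustering (average linkage by default)
  on $D$, cut at $k$ or at a height; labels renumbered by first frame
  occurrence (0-based); each cluster represented by its medoid, the
  member minimizing total in-cluster distance, ties broken by the lowest
  frame index. `stats::hclust` performs the agglomeration, so runs are
  deterministic; its internal ordering of equal-height merges is the one
  documented by base R.
- **PCA.** Eigendecomposition of the covariance (again $1/N$) of the
  mean-centered pair-distance vectors — or of 0/1 contact states via
  `features = "state"`; distances are the default because they carry
  strictly more information, and both readings of "contact-map-based"
  are available. When live pairs outnumber frames the frames × frames
  Gram matrix is decomposed instead; both routes are implemented and
  tested to give identical spectra, loadings and projections. Signs are
  fixed by making each component's largest-magnitude loading positive.

# The synthetic-data generator

`make_fixture()` builds the desk-scale study systems used throughout the
tests and the acceptance script. Residues are rigid point clusters whose
atoms share the residue center's x/z and spread along y on a fixed
0.05 nm ladder; since every residue uses the same ladder, the minimum
interresidue atom distance *equals the center distance exactly*, so each
scenario's distance schedule is exact before noise. Noise, when
requested, is per-axis Gaussian displacement of every atom (default 0);
to first order this inflates a pair distance by $\sqrt2\,\sigma$, the
bound `reference_stats()` uses for its tolerances. A single explicit seed
determines every fixture byte-for-byte, and generation never touches the
global RNG stream.

Scenario defaults are the study conditions used by the acceptance
checks: contacts sit at 0.4–0.45 nm (comfortably inside the 0.5 nm
interaction cutoff), non-contact live pairs at 0.8 nm, excluded pairs at
1.2 nm; the drift scenario moves one pair from 0.9 to 0.5 nm over 100 ps
(slope −0.004 nm/ps); the two-state scenario separates states by 0.3 nm
in three switch pairs under σ = 0.01 nm noise (a 30:1
separation-to-noise ratio); the unfolding schedule breaks pair $k$ at
frame $10k$ with one persistent pair. These are idealized kinetics: real
trajectories have correlated, anisotropic fluctuations, gradual ruptures
and re-formation events, so passing tests demonstrate the machinery is
exact on known ground truth, not that any biological system behaves this
simply.

Problem sizes were chosen at desk scale on purpose — 10–12 residues,
3–4 atoms per residue, 60–2000 frames, 100 seeds where stability across
realizations matters; they keep the full suite under a minute while
still exercising every code path, and all scale linearly upward.

# Numerical choices and degenerate inputs

- Stored distances keep 4 significant digits (a storage-economy contract
  guaranteeing at least 3; mirroring half-precision storage without
  binding the code to a binary layout); all aggregates accumulate at full
  precision, and `precision = NULL` disables the reduction.
- The distance kernel evaluates the difference-based form
  $(x_a-x_b)^2 + \dots$ so it is bit-identical to an exhaustive atom-pair
  loop — "accelerate but never approximate" is a testable contract here.
- Ties: a distance exactly at $r_\mathrm{cut}$ is *not* within the
  cutoff; exactly at $r_\mathrm{inter}$ or $r_\mathrm{inter}^\mathrm{high}$
  preserves state.
- Degenerate inputs error loudly rather than guess: empty topologies,
  insertion codes, atom-count mismatches, non-increasing times, empty
  differential windows, `k` out of range, all-identical residue features
  with `k > 1`. Residues with no selected atoms (glycine under
  `side_chain`) become inert and join no pair; never-live pairs appear in
  full matrices only as documented sentinels (distance $r_\mathrm{cut}$,
  fraction 0, encounter −1).
- Economy mode is contractually streaming: an instrumented counter
  records the maximum number of simultaneously resident per-pair frames
  and the suite asserts it is 1.

# Output conventions

All user-facing files use 1-based residue indices (0-based frame indices
and cluster labels, as is conventional for trajectory tooling). Matrices
are written in the three-column gnuplot text layout with a `#` header
naming size, semantics and sentinels, and round-trip through
`read_matrix()`. Sequential data (distances, times) render with a
sequential colormap; divergent data (correlations, differentials) with an
orange–white–purple ramp whose midpoint is anchored exactly at the null
value. Video encoding is a thin optional wrapper over an external
encoder probed at run time; its absence is a logged warning, never a
failure. Text outputs contain no timestamps, so identical configurations
reproduce identical bytes.

# Limitations

- No periodic-boundary handling: trajectories must be made whole first.
- Contacts are residue-level; per-atom maps are out of scope.
- XTC/TRR readers are not bundled; multi-model PDB, DCD (via `bio3d`)
  and the plain text frame format cover the reader seam, and any format
  can be converted to those.
- The hysteretic state machine is Markovian in the distance series; it
  cannot distinguish a true rupture from a long excursion that ends after
  the trajectory does (such pairs are flagged persistent instead).
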