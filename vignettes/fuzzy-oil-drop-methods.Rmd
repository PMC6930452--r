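---
title: "Hydrophobicity organization in globular proteins and amyloid fibrils: methods"
author: "oildrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrophobicity organization in globular proteins and amyloid fibrils: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oildrop)
```

## The model

A water-soluble globular protein behaves like a spherical micelle: the
aqueous solvent drives hydrophobic side chains inward, producing a single
centralized hydrophobic core with a smooth density gradient toward the
polar surface. `oildrop` formalizes this intuition as the fuzzy-oil-drop
model. The idealized density is a 3D Gaussian fitted to the structure:
each residue $j$, reduced to its *effective atom* (the mean position of
its heavy atoms), receives the theoretical value

$$T_j \propto
  \exp\!\Big(-\tfrac{(x_j-\bar x)^2}{2\sigma_x^2}\Big)
  \exp\!\Big(-\tfrac{(y_j-\bar y)^2}{2\sigma_y^2}\Big)
  \exp\!\Big(-\tfrac{(z_j-\bar z)^2}{2\sigma_z^2}\Big),$$

normalized so $\sum_j T_j = 1$. The capsule is oriented along the
principal axes of the residue cloud; along each axis $\sigma$ is $1/6$ of
the span between the most distal effective atoms (three-sigma rule), and
the center is the bounding-box midpoint. The orientation step matters:
the "axis-aligned" capsule is only well defined after a rotation
convention is chosen, and we use principal axes (descending eigenvalue
order, right-handed, deterministic signs), which makes $T$ invariant
under rigid-body motion of the input.

The *observed* distribution collects actual hydrophobic contacts. With
intrinsic hydrophobicities $h_i$ (an amino-acid scale) and inter-residue
distances $r_{ij}$,

$$O_j \propto \sum_{i}\,(h_i + h_j)\, w(r_{ij}), \qquad
  w(r) = 1-\tfrac12\!\left(7\rho^2-9\rho^4+5\rho^6-\rho^8\right),\;
  \rho = r/c,$$

for $r \le c$ and $w = 0$ beyond; the cutoff $c$ defaults to 9 Å. The
polynomial is 1 at contact and reaches 0 exactly at the cutoff, so $O$
is continuous in the coordinates. The self term ($i = j$, $w = 1$) is
included, which also gives the correct limit: as $c \to 0^+$ only self
terms survive and $O$ reduces to the normalized intrinsic distribution.

Two reference distributions complete the picture: $R_j = 1/N$ (no core
at all) and $H_j \propto h_j$ (structure dictated purely by residue
identity). Distributions are compared by Kullback–Leibler divergence
$D_{KL}(p\|p_0)=\sum_i p_i\log_2(p_i/p_{0i})$ (bits), and combined into
the relative distance

$$RD = \frac{D_{KL}(O\|T)}{D_{KL}(O\|T)+D_{KL}(O\|R)}.$$

$RD < 0.5$ means $O$ is closer to the Gaussian ideal than to the flat
reference: a prominent hydrophobic core exists. Substituting $H$ for $R$
gives the second variant, where $RD > 0.5$ flags a structure dominated
by intrinsic residue properties. Pearson correlations between the
profile pairs (HvT, TvO, HvO) complete the per-unit fingerprint.

Amyloid fibrils fail the 3D model in a specific way: their hydrophobic
residues form a *band* along the fibril axis rather than a point-like
core — a ribbon-like micelle. This is captured by the 2D variant of the
field (`kind = "gauss2d"`): the axis of largest span (the fibril long
axis) is suppressed and density depends only on the cross-sectional
plane, the limiting case of a Gaussian whose long-axis sigma tends to
infinity. For a translationally repeated fibril every cross-section then
carries the same theoretical distribution, which
`cross_section_profiles()` exposes directly. Headline scores always
normalize over the whole scope; the per-cross-section view is a
diagnostic only.

## Analysis levels

A chain can be scored against its own field (`chain_alone`) or against
the field of the protofibril or superfibril it belongs to
(`chain_in_protofibril`, `chain_in_superfibril`): the *subset* whose
status is reported is distinguished from the *field scope* that defines
the Gaussian and the interaction sums, and subset profiles are
renormalized after restriction. Where the scored chain is not named
explicitly, the centrally located chain of the stack is used — the
median chain after sorting chain centroids along the first principal
axis, ties toward the lower index — as the most representative sample of
an arbitrarily long fibril. Interfaces are scored the same way: field
and contacts from the whole complex, profiles restricted to the listed
interface residues; an interface with $RD < 0.5$ is *stabilizing* (its
hydrophobicity is consistent with the complex-wide core, which is what
holds protofibrils together). A fragment restriction (for chains where
only part of the sequence fibrillizes, such as residues 30–100 of
α-synuclein) is applied before field fitting at every level.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 9 Å | hydrophobic contact range in $O$; the polynomial vanishes there |
| `scale` | Kyte–Doolittle, rescaled to $[0,1]$ | intrinsic hydrophobicity; any nonnegative scale can be loaded |
| `sigma_floor` | 1 Å | substituted for a zero span so planar/collinear toys stay analyzable |
| `tau` (categories) | median $|T-O|$ | accordance tolerance; adapts to the unit's overall discordance |
| `q` (core) | 0.75 | joint T/O quantile defining hydrophobic-core membership |

The choice of intrinsic scale shifts individual numbers slightly but not
the qualitative classification; conclusions should be checked against a
second scale when they sit near $RD = 0.5$.

## Synthetic ground truth

`make_globule()` places residues quasi-uniformly in a sphere (default
200 residues, radius $3.2\,n^{1/3}$ Å, matching typical protein packing)
and, at `core_bias = 1`, draws hydrophobic residue types inside half the
radius and polar types outside — an idealized spherical micelle.
`make_fibril()` stacks identical serpentine chain motifs (two extended
strands, 3.5 Å residue spacing) along the stacking axis at a 4.7 Å rise
(cross-beta-like; default 12 chains of 24 residues) and draws one shared
sequence with hydrophobic types inside an 8 Å axial band. Residue types
are real amino acids binned into hydrophobic/neutral/polar tertiles of
the scale, so synthetic structures exercise the same machinery as real
ones. The motif carries small (0.3 Å) thermal jitter, identical in every
chain: a mathematically planar chain would have a degenerate capsule of
its own, and finite thickness is what lets the chain-alone versus
chain-in-context contrast emerge the way it does in real fibrils. The
out-of-plane jitter is orthogonalized against the in-plane coordinates
so the stacking axis remains an exact principal axis for any chain
count, keeping the per-cross-section invariance exact.

`scramble_hydrophobicity()` permutes residue identities over fixed
coordinates: geometry and composition are preserved, so any score change
isolates the effect of hydrophobicity *placement*.

What the generators do not emulate: backbone connectivity and sterics,
hydrogen-bond registry, side-chain packing, sequence correlations along
the chain, and solvent structure. Passing the synthetic recovery tests
therefore shows that the statistics respond correctly to the spatial
organization of hydrophobicity at effective-atom resolution — not that
any particular real deposit will score identically; real-structure
values also depend on the deposited coordinates and the scale chosen.

```{r example}
glob <- make_globule(seed = 1)
fib  <- make_fibril(seed = 1)
analyze_unit(glob, selection_spec("chain_alone"))$scores[c("rd_tor", "rd_toh")]
analyze_unit(fib, selection_spec("protofibril"))$scores[c("rd_tor", "rd_toh")]
analyze_unit(fib, selection_spec("protofibril"),
             kind = "gauss2d")$scores["rd_tor"]
```

## Numerical choices and degenerate inputs

* **KL zero handling.** Reference profiles are floored at $10^{-10}$ and
  renormalized; target zeros contribute 0. Divergences are reported in
  bits; $RD$ itself is base-invariant.
* **Degenerate geometry.** Fewer than two distinct positions is an
  error; a zero span along an axis gets the 1 Å sigma floor with a
  warning. Principal-axis signs are fixed deterministically and the
  third axis is the cross product of the first two, so the rotation is
  always right-handed and reproducible.
* **Elimination.** `eliminate_discordant()` repeatedly removes the
  residue with the largest renormalized $|O-T|$ gap (ties toward the
  lower index), renormalizes all profiles over the survivors and
  recomputes $RD$, stopping below 0.5 or at 3 survivors (then flagged
  irreducible). For locally discordant structures — the intended use,
  where a few culprits carry the deviation — the $RD$ trace decreases
  monotonically. The greedy rule does not guarantee monotonicity in
  general: on strongly anti-correlated profiles individual steps can
  raise $RD$ by a few parts in a thousand before the trend resumes.
* **Ties in quantiles.** Core membership uses $\ge$ comparisons, so a
  degenerate (constant) profile puts every residue in the core rather
  than none.
* **Effective atoms.** Heavy atoms only, unweighted mean. NMR deposits
  include hydrogens and X-ray deposits usually do not; including them
  would shift centroids between the two and break comparability. Only
  model 1 of multi-model files is used, first alternate locations kept.

## Problem sizes used in validation

The shipped validation runs 50 generator seeds per architecture at the
default sizes (200-residue globules, 12 × 24-residue fibrils), 20
scrambled nulls, and 10 interface analyses on split 12-chain fibrils.
These sizes keep every quantity's Monte-Carlo error well below the
effect sizes being tested (the globule/fibril $RD$ gap is ≈ 0.2–0.4)
while remaining quick to recompute.

## Known limitations

* Single-point residue representation: no side-chain directionality, so
  interfaces defined by specific side-chain contacts are represented
  only through their effective-atom geometry.
* The 2D field suppresses the axis of largest span. For very short,
  wide fibrils the long axis is not the stacking axis and the 2D variant
  then describes a different section than intended — check
  `suppressed_axis` when working with stubby oligomers.
* The `analyze_interface()` negative control is statistical, not
  per-instance: an arbitrary thin-shell surface patch of a globule is
  discordant on average, but a single patch can fall just under
  $RD = 0.5$ because the theoretical profile is nearly constant across a
  thin shell.
* Structure files are parsed via bio3d; exotic mmCIF deposits that
  bio3d cannot read are out of scope.
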