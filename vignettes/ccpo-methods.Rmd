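---
title: "Designing and analysing coiled-coil protein origami cages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing coiled-coil protein origami cages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccporigami)
```

## The design problem

Coiled-coil protein origami (CCPO) programs a polypeptide chain to fold into
a polyhedral cage. Each edge of the target polyhedron is realised as one
coiled-coil (CC) dimer; the chain visits the polyhedron as a **closed double
trace** — a closed walk that traverses every edge exactly twice — so that the
two traversals of an edge contribute the two helices of that edge's dimer.
The sequential order of the concatenated CC-forming peptides therefore
encodes the three-dimensional fold. The flagship design in this package is a
trigonal bipyramid: 5 vertices, 9 edges, hence 18 CC-forming segments in the
single chain.

This vignette documents the models, conventions, defaults and known
limitations of every stage; it states no empirical result that the package's
tests and acceptance script do not themselves compute.

## Double traces and their admissibility

The enumerator (`enumerate_double_traces()`) performs a depth-first search
over closed walks that cover each edge exactly twice. Admissibility adds a
*non-backtracking* rule: a step `u -> v` is never followed immediately by
`v -> u`, applied cyclically. Such a reversal would fold a dimer onto a
zero-length loop. The rule is waived at degree-1 vertices, where turning
back is the only continuation — this makes the 2-segment hairpin on a
single edge (one antiparallel homodimer) a valid design, as it must be.
Deeper stability conditions of the full double-trace theory are not
re-derived here; `prefix_filter` exposes a pluggable predicate so such
constraints (or design constraints, as used for the bipyramid search) can
prune the enumeration.

Each trace is reported once per cyclic equivalence class, as the
lexicographically smallest rotation of its vertex sequence. Traversal
reversal and graph automorphisms are *not* collapsed by default so that raw
counts are reproducible; `reduce_symmetry = TRUE` collapses both.

## Topological contact order and circular permutations

Opening the closed trace at any of its `2|E|` steps fixes the N- and
C-termini and gives one candidate single-chain topology
(`circular_permutations()`). Candidates are ranked by **topological contact
order** (`tco()`): the mean separation `|i - j|` between the two segment
slots of each intra-chain dimer, divided by the total number of segments.
Lower TCO means edge-forming modules sit closer in the primary structure,
which favours efficient folding. Inter-chain (interface) pairs have no
intra-chain separation; they are excluded from the mean and counted
separately. Whether the original design software normalises by chain length
or by segment count is not documented anywhere we can check; since only the
*ranking* is ever used, the segment-count normalisation is adopted and
fixed. Ties are broken by enumeration order.

## The bipyramid design

`design_bipyramid()` reconstructs the single-chain bipyramid topology from
its design constraints rather than from a published trace table:

1. the walk decomposes into two tetrahedral halves of nine segments each
   (each apex's three edges twice plus the three equatorial edges once);
2. the halves are pseudo-mirror images under the apex-swapping graph
   symmetry;
3. the three equatorial (interface) edges form **parallel** heterodimers,
   so the cage can later be split into two self-contained subunits meeting
   at a trigonal interface;
4. among the admissible traces, the seam-opened permutation with minimal
   TCO wins; remaining ties are resolved by using as few antiparallel
   dimers as possible, because orthogonal antiparallel modules are the
   scarce resource in the toolkit (they are homodimers).

The selected design uses seven parallel and two antiparallel dimers.
`split_topology()` then derives the experimentally studied variants: the
asymmetric 16+2 trim, the pseudo-symmetric 9+9 split with exactly three
interface pairs, and the maskable 11+11 switch in which two terminal
masking segments occupy two of the three interface segments of each
subunit, with a TEV protease site annotated between the 9th and 10th
segments. `design_split_bipyramid()` chooses the circular permutation of
each 9-segment subunit: termini at the interface (the permutation that
leaves interfacial segments free) or at the opposite apex (interfacial
segments constrained in loops).

## Sequence assembly

`assign_segments()` maps CC pairs from a library onto edges by backtracking
search under three constraints: orientation match, complementary roles for
the two traversals, and orthogonality — within one *folding scope* no
orthogonality group may appear twice. Scopes default to chains; giving the
two tetrahedral halves separate scopes reproduces the mirrored module reuse
of the pseudo-symmetric design. Interface edges belong to both scopes and
may prefer the higher-helicity SH variants (`interface_variant = "SH"`).

The packaged library (`cc_fixture_library()`) is **synthetic**: idealised
32-residue four-heptad peptides with Ile/Asn cores and Glu/Lys
electrostatic specificity, named after the published toolkit so designs
read naturally. The real peptide sequences live in supplementary material
that is not redistributed here; consequently the theoretical masses of the
assembled constructs (for example 68.07 kDa for the His-tagged single-chain
cage) are properties of the synthetic library, not the published proteins.
`molecular_weight()` uses average isotopic residue masses with one water
(18.0153 Da), the convention at which designed-protein masses are quoted to
0.1 kDa; a monoisotopic toggle is provided. `tev_cleave()` cuts after the
Gln of `ENLYFQ(G|S)`, configurable at the annotation level.

## Coarse-grained model building

`build_model()` works at one bead per residue. Each CC-forming segment is a
rigid ideal helix (1.5 Å rise, 2.3 Å radius, 100°/residue — consecutive CA
distance 3.83 Å). The energy has three terms:

* **pairing restraints** — one harmonic per aligned residue pair at a 10 Å
  target (a typical CC interhelical CA–CA distance), index-reversed for
  antiparallel dimers; force constant 1 /Å²;
* **junction springs** — flat-bottomed springs between the C-end of a
  segment and the N-start of its chain successor. The admissible span is
  `linker_residues x 3.8 Å` (default 5 residues, 19 Å); the spring engages
  at 70% of that bound so pairing tension cannot stretch a junction past
  it;
* **soft-sphere repulsion** — quadratic below 5.5 Å between beads of
  segments that are neither chain neighbours nor dimer partners (a dimer's
  own interface is attractive by design). Clashes are *counted* at the 4 Å
  hard-core radius.

Optimisation is staged, seeded Metropolis annealing: segments start at
random non-clashing poses, one dimer's restraint set is activated per
stage, and each stage runs a geometric temperature ladder (default 8 steps,
T = 30 to 0.25, 40 moves per segment per step). A deterministic rigid-fit
polish follows: each segment is repeatedly superposed (weighted Kabsch)
onto the positions implied by its restraints and junction anchors, a move
being kept only when the restraint energy drops and any clash increase
stays below half the gain. Two short low-temperature shake/polish cycles
free frustrated local minima. The entire build is a pure function of its
inputs and seed. A model is `converged` when every pair's restraint RMS is
within tolerance (1.0 Å) *and* every junction respects the connectivity
bound.

`generate_ensemble()` repeats the build (default 30 replicas, matching the
30–60 used to capture cage flexibility) with replica seeds derived from the
master seed, and tabulates energy, residuals, clashes, Rg, Dmax and cavity
radius. `cavity_radius()` is the centroid-to-nearest-bead distance minus a
probe radius (default 2 Å), floored at zero, with degenerate (collinear)
bead sets reporting no cavity.

Two limitations are worth stating plainly. First, an ideal wireframe
bipyramid with ~4.7 nm edges has Rg ≈ 2.5 nm; experimentally measured
values for the real cage are larger (~4.6 nm) because tags, linker
disorder and hydration contribute — a CG wireframe cannot and should not
reproduce that number. Second, the open faces of the polyhedron allow
restraint-satisfying conformations whose cavity is collapsed; ensembles
therefore mix open and collapsed states, as the experimental modelling of
these cages also found. The tests assert the *direction* of structural
effects (for example, that constraining interfacial segments in loops
yields smaller mean cavities than leaving them terminal), not absolute
cavity sizes.

## Scattering analysis

`debye_intensity()` computes the orientationally averaged Debye double sum
over CA beads with a uniform dummy-residue form factor, so `I(0) = (N f)^2`
exactly. At coarse-grained resolution the missing side chains, excluded
volume and hydration shell bias the curve above roughly 2 nm^-1;
comparisons with experiment there are brackets, not fits.

`guinier_rg()` fits `ln I` against `q^2`, weighted by `(I/sigma)^2`, over a
window shrunk automatically until `qmax x Rg <= 1.3` (the conventional
globular-particle limit). For an ideal sphere this estimator carries a
small positive truncation bias (~2%, from the `q^4` term of the form
factor); it is visible in the test suite's recovery studies and is the
reason sphere recoveries are asserted at 2–2.5%.

`ift()` estimates `p(r)` by sigma-weighted non-negative least squares on a
`[0, dmax]` grid with zero endpoints and a second-difference smoothness
penalty; uncertainties are floored at 1e-4 of the window maximum so deep
form-factor minima of low-noise synthetic data do not receive unbounded
weight. `dmax` is scanned and selected as the *smallest* value whose
misfit comes within 5% of the scan minimum — the start of the misfit
plateau, which stabilises the estimate to roughly the scan step.

`chi_fit()` uses the closed-form scale
`c = sum(Ie Im / s^2) / sum(Im^2 / s^2)` and
`chi = sqrt(sum(((Ie - c Im)/s)^2) / (N - 1))`, with the model
interpolated onto the experimental grid linearly in `(q, log I)`. No
constant background term is fitted.

`volatility_ratio()` forms the ratio of two profiles over 0.15–1.5 nm^-1,
averages it in bins of width `pi/40 nm` (17 full bins plus the final
partial bin, which is included), and sums the normalised bin-to-bin
fluctuation times 100. Two conventions are fixed deliberately: the per-bin
average is the **geometric** mean of the point ratios, and both profiles
pass through the same positive log-linear interpolation — together these
make `V_r(a, b) = V_r(b, a)` exact and keep the statistic invariant under
separate rescaling of either profile, so no pre-scaling is applied.

## Thermodynamic fits

Helical content uses
`alpha(%) = 100 MRE222 / (-39500 (1 - 2.57/n))`, with the chain length `n`
(not `n - 1`) in both the correction and the raw-ellipticity conversion
`MRE = theta / (10 c l n)`; values are reported unclamped.

`fit_melting()` fits a two-state equilibrium model
(`K = exp(-dH (1 - T/Tm) / RT)`, delta-Cp fixed at 0, linear folded and
unfolded baselines) or a sequential three-state model N–I–D with two
`(Tm, dH)` transitions; the intermediate's signal is a fitted mixing
fraction of the two baselines, logistic-constrained to [0, 1]. Fitting is
Levenberg–Marquardt with seeded multi-start initialisation guided by the
steepest-derivative temperature; temperatures are Kelvin internally and
Celsius in all interfaces.

`fit_itc()` fits the exact 1:1 bound-fraction quadratic root with stepwise
displaced-volume dilution bookkeeping: each injection dilutes the cell by
`dV/V0` before the complex concentration is recomputed, and the heat of
injection i is `V0 dH ([ML]_i - [ML]_{i-1}(1 - dV/V0))` plus a constant
offset. Free parameters are (n, Kd, dH, offset), with multi-start on log
Kd; the first (small priming) injection is excluded by default and the
Wiseman c-value is flagged when outside 1–1000.

`fret_ratio()` reads the acceptor (668 nm) over donor (566 nm) emission by
linear interpolation on the spectrum grid.

## Synthetic data

Every generator in the package is a pure function of its parameters and a
seed, and attaches a manifest holding the generating truth — recovery tests
read the truth from the manifest, never from the data. Noise is Gaussian
with a relative component and an absolute floor; scattering generators add
a floor tied to the forward intensity, emulating the counting-statistics
floor of real detectors, which keeps sigma-weighted analyses well
conditioned at form-factor minima. What the generators deliberately do not
emulate: detector artefacts, buffer-subtraction errors, inter-injection
baseline drift, photobleaching. Passing recovery tests therefore show the
estimators are correct and well-calibrated under the stated noise model,
not that they are robust to every experimental pathology.

## Problem sizes used by the shipped tests

The test suite and acceptance script run at sizes chosen to exercise the
study conditions faithfully while remaining desk-scale: 20 seeded
replicates for the titration and melting recovery studies (at the reported
Kd = 4.7 nM and transitions of 41/62 °C), full-schedule single builds and
5-replica ensembles for the cage-structure comparisons, and brute-force
oracle comparisons on all graphs with up to 4 edges. Mechanical tests
(determinism, schemas, export formats) use a shortened annealing schedule
since they assert reproducibility rather than model quality.
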