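---
title: "Methods: interface mutation design and biophysical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface mutation design and biophysical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affidesign)
```

This vignette documents the models, conventions and numerical choices behind
`affidesign`, in the spirit of a methods section: what each stage assumes,
which parameters matter and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open and a choice had to be made.

## The design protocol

The pipeline targets a common protein-engineering setting: a receptor-ligand
complex with known crystal structures (here, the extracellular domain of
interferon-γ receptor 1 bound to IFN-γ, with four crystallographically
independent copies of the complex), a multiple sequence alignment of receptor
orthologs, and per-mutation free-energy changes (ΔΔG) computed by an external
empirical force field. The stages are:

1. **Interface extraction.** A receptor residue is an interface residue when
   the minimum distance from any of its non-hydrogen atoms to any
   non-hydrogen ligand atom is ≤ 6.0 Å. The boundary is read as a closed
   interval ("within 6 Å" includes 6.0 Å exactly); the cutoff is a parameter.
   Hydrogens are excluded because crystal structures at ~3 Å resolution carry
   none, and excluding them makes the selection independent of whether a
   deposition was protonated. Waters and other HETATM records are excluded by
   default (configurable). Interfaces from crystallographically independent
   copies are unioned after remapping onto one reference chain; since all
   copies are the same molecule with identical author numbering, remapping is
   a chain relabeling, and a residue key that maps to two different residue
   names is treated as an incompatible-numbering error.
2. **Conservation veto.** Conservation is measured as *identity to the
   reference sequence* (the molecule being mutated), not identity to the
   column consensus: the veto exists to protect the reference residue, and a
   position can be >65% identical to a consensus that differs from the
   reference. The consensus residue is still reported for display. The
   reference sequence counts in the denominator (n-of-n convention,
   configurable), gaps count as mismatches, and alignment columns where the
   reference is gapped are skipped. A position is vetoed when its fraction is
   *strictly greater* than the threshold (default 0.65); a fraction of
   exactly 0.65 stays mutable. Reference (UniProt-style) and structure
   numbering differ by a constant offset — 17 for this receptor — handled by
   `map_numbering()`.
3. **Candidate selection.** In stabilize mode a mutation passes when its
   affinity ΔΔG and its stability ΔΔG are below their thresholds (default 0
   kJ/mol: strictly negative, i.e. favorable) on **every** interface, and its
   position is not vetoed. Demanding all four interfaces rather than an
   average is deliberate: the four matrices are computed independently and
   unanimity is the conservative reading. The criteria are applied to
   whichever matrix set is supplied — single-structure matrices or
   snapshot-ensemble averages from `ensemble_average()` — the machinery does
   not care about their provenance. Destabilize mode (negative controls)
   requires affinity ΔΔG > 0 and stability ΔΔG < 0 on every interface; no
   conservation veto is applied there, since the listed criteria for control
   mutants are purely energetic. Ranking is by best (most negative) affinity
   ΔΔG ascending in stabilize mode, descending in destabilize mode, with
   ties broken by position then mutant residue alphabetically — a documented
   total order where none was prescribed. Energies are kept in kJ/mol; a
   kcal/mol import flag converts by 4.184.
4. **Multi-mutant design.** Singles are combined into doubles/triples only
   when every pair is ≥ 25 residues apart in sequence and > 20 Å apart in
   space. Spatial separation is measured between Cα atoms of the wild-type
   residues: "apart in 3D space" needs an atom convention, and Cα is the
   stable choice for positions whose side chains will be replaced. Three
   mutually compatible singles give three doubles and one triple — together
   with the singles, the seven possible combinations. Second-generation
   combinations chosen in the light of experiments (e.g. pairing a
   high-affinity single with a neutral one) are user input, not
   auto-generated.

## Thermodynamics and statistics

Free-energy changes come from dissociation constants via
ΔΔG = −RT ln[(K~d~)~WT~/(K~d~)~mut~] with R = 8.314 J/(mol·K) and T
defaulting to 298.15 K (the 25 °C at which the SPR affinities are measured);
negative values mean tighter binding. K~d~ = k~d~/k~a~ links the equilibrium
and kinetic descriptions. Replicate uncertainty is summarized as Student-t
confidence half-widths t~(1+γ)/2,N−1~ · esd/√N, treating the esd as the
standard deviation of replicate K~d~ values; with esd 0.49 nM and N = 4 this
gives ±0.78 nM at 95%. Half-widths computed from a *rounded* esd input are
themselves only accurate to that rounding, which is visible for large N.
Additivity records compare a multi-mutant's measured ΔΔG with the sum of its
constituent singles; the deviation is defined as measured − sum, so 0 means
perfectly additive energetics. ΔΔG comparisons are most reliable within one
analyte batch; the report functions operate on whatever table they are
given, and batch bookkeeping is left to the caller's table.

## SPR: the 1:1 Langmuir-with-drift model

The response model is pseudo-first-order 1:1 binding plus a linear baseline
drift:

- association (0 ≤ t ≤ t~assoc~):
  R(t) = R~eq~(1 − e^−(k~a~C+k~d~)t^) + drift·t, with
  R~eq~ = k~a~C·R~max~/(k~a~C + k~d~);
- dissociation: R(t) = R~end~·e^−k~d~(t−t~assoc~)^ + drift·t, where R~end~
  is the binding component at the end of association, making the curve
  continuous at the phase boundary.

Vendor implementations of "Langmuir with drift" are proprietary; one linear
drift slope per curve, continuous across phases, is the minimal
interpretation and is the model's definition here. Double referencing
subtracts the uncoated interspot and the (interspot-corrected) reference
channel, which cancels any bulk artifact shared by all channels exactly.

Fitting is global nonlinear least squares: k~a~, k~d~ and R~max~ are shared
across the concentration series (per-curve fitting is available behind a
flag), drift is per-curve, and the rate/capacity parameters are optimized on
the log scale to keep them positive and well-scaled. Initial guesses are
data-driven — k~d~ from a log-linear regression of the dissociation tail of
the highest concentration, k~a~ from the regression of observed association
rates (half-rise times) on concentration, R~max~ from the largest observed
response — and additional starts jitter these log-uniformly within half a
decade under a fixed seed. Standard errors come from the Jacobian at the
optimum (delta method back to the linear scale). Defaults mirror a
short-contact experiment: 90 s association, 10 min dissociation, 0.1 s
sampling, and a three-fold dilution series from 99 nM to 1.2 nM. Mass
transport limitation is *not* modeled; at high flow rates the 1:1 model is
adequate, but strongly transport-limited data will bias k~a~ downward.

## Thermal shift analysis

Melt curves are reference-subtracted (dye in buffer without protein),
min-max normalized per curve (plate-level normalization is not attempted),
differentiated by central differences on the measured grid (default 0.5 °C
steps over 20-75 °C), and Tm taken as the derivative maximum refined by the
vertex of a parabola through the peak and its two neighbours. No smoothing
is applied by default: on the 0.5 °C grid the discretization error of the
refined estimate is well below the grid spacing. Central differences
amplify noise as spacing shrinks, so for noisy data on fine grids the
optional moving-average window should be used. A derivative maximum on the
grid boundary yields a warning and the unrefined grid maximum (the
transition midpoint is then outside or at the edge of the scanned range); a
curve with no positive derivative anywhere has no unfolding transition and
is an error rather than a number.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of (seed, parameters); a master seed fans
out to per-generator child seeds by fixed offsets so datasets are
individually reproducible, and each dataset carries its planted truth.

- `make_toy_complex()` lays the receptor out as an idealized backbone trace
  (3.8 Å Cα spacing with N, C, O at fixed local offsets) and plants an exact
  interface: chosen residues sit at the requested contact distance from a
  ligand atom, all others are kept > 8 Å (a guard band) from every ligand
  atom. This exercises distance, union, superposition and RMSF logic
  completely, but it is *not* a physically plausible protein: no side
  chains, no secondary structure, no packing.
- `make_msa()` realizes planted per-column identities as exact counts
  (`round(fraction × n_seq)`, at least the reference itself), so recovered
  fractions match planted rates deterministically. Real alignments have
  phylogenetic correlation between sequences; none is simulated, and no
  sequence weighting is applied.
- `make_ddg_matrix()` plants stabilizing mutations strictly negative on both
  energy types on all interfaces with a margin of at least 3× the
  interface-to-interface noise, destabilizing ones with the opposing-sign
  pattern, against a mildly destabilizing Gaussian background (most random
  mutations hurt). The scanned mutation subset depends only on a separate
  subset seed, so snapshot ensembles generated with different noise seeds
  share one key set. Planted energies have no force-field plausibility.
- `make_sensorgram_set()` and `make_melt_curve()` add i.i.d. Gaussian noise
  to the closed-form models above. Real sensorgrams also contain
  regeneration artifacts, injection spikes and transport effects; real melt
  curves have sloping baselines (supported via the baseline parameter) and
  post-transition aggregation decays (not simulated).

Passing tests on these generators therefore demonstrates correctness of the
*computational* pipeline — recovery of planted truth under the stated noise
— not accuracy on any particular experimental system.

## Numerical choices and problem sizes

Superposition uses the standard SVD solution of the orthogonal Procrustes
problem with the determinant correction that excludes reflections; the fit
is computed on the same atom set the RMSD is evaluated on by default (the
natural reading when an RMSD "over the interface residues" is quoted), with
a flag to fit on all common residues and evaluate on the selection only.
Multi-model files contribute model 1 only; among alternate locations the
highest occupancy wins, ties broken by altloc letter. PDB coordinates carry
three decimals, so comparisons against independently computed references are
meaningful only to about 10⁻³ Å per atom.

The test suite and the acceptance script keep simulation sizes modest by
choice: interface-oracle sweeps use 30-60-residue toy complexes over 20-100
seeds; kinetic Monte-Carlo studies use 25 noise realizations of five-curve
concentration series sampled at 0.5-1 s (the model is smooth; denser
sampling changes nothing but runtime); melt-curve recovery uses the default
0.5 °C grid. The published kinetic table bundled under `inst/extdata/` is
used as-is for the thermodynamic worked examples; its force-field and
MD-averaged ΔΔG columns are carried as input data only and are never
recomputed — energy calculation engines are outside this package's scope.

## Known limitations

- No structure repair, loop building or protonation: input structures are
  used as deposited.
- No alignment construction and no phylogenetic weighting: the conservation
  module consumes an existing alignment.
- The kinetic model excludes mass transport, heterogeneous-ligand and
  biphasic behavior; the drift parameterization is this package's
  definition, and fits from vendor software with a different drift model
  can differ in the drift estimate (the rate constants are robust to this
  in practice).
- Tm estimation is a derivative-peak method, not a two-state thermodynamic
  fit: it reports the transition midpoint, not ΔH or ΔCp.
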