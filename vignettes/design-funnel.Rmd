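---
title: "The active-site design funnel: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The active-site design funnel: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`enzdes` implements a complete in-silico funnel for engineering MHET
hydrolases: geometric matching of a serine-hydrolase catalytic motif into a
scaffold, transition-state (TS) conformer placement, rotamer-based sequence
redesign with certified global-minimum search, catalytic-indicator screening
of trajectory frames, and downstream kinetics/product accounting. This
vignette records the models behind each stage, the tunable parameters and
why their defaults are what they are, what the synthetic-data generators do
and do not emulate, and the numerical decisions a maintainer would want
written down.

## The active-site model

MHET hydrolysis by a serine hydrolase proceeds by nucleophilic attack of the
catalytic serine (deprotonated by the histidine of a Ser-His-Asp charge
relay) on the ester carbon, through a tetrahedral intermediate whose
developing oxyanion is stabilized by two backbone N-H donors. The shipped
model (`inst/extdata/active_site_mhet.yaml`) declares six catalytic roles --
nucleophile Ser, base His, acid Asp/Glu, two oxyanion N-H donors (any amino
acid except proline, because proline has no amide H), and a Ser/Thr hydroxyl
that hydrogen-bonds the substrate's terminal carboxylate -- and nine
distance/angle constraints between their anchor atoms and the TS
pseudo-molecule.

The constraint windows encode canonical serine-hydrolase geometry as
observed in natural MHET-hydrolase and serine-protease active sites:
nucleophile O-gamma to ester carbon 2.0-3.0 Å (target 2.3), His
N-epsilon2 to Ser O-gamma 2.5-3.5 Å, Asp carboxylate O to His N-delta1
2.4-3.5 Å, each oxyanion N to the oxyanion O 2.0-4.0 Å, and binder hydroxyl
to a carboxylate O 2.0-4.0 Å, plus three soft angular constraints (attack
angle at the sp3 carbon near tetrahedral, 109.5°; His-O-gamma-C alignment;
donor approach angle at the oxyanion). Every number is config-overridable:
the machinery is deliberately independent of the exact constraint table, so
a user with a different reaction can supply their own YAML.

The TS pseudo-molecule is a minimal tetrahedral-intermediate model of MHET:
the sp3 ester carbon with its four substituents (oxyanion O, nucleophile-side
O, ethylene-glycol ester O, aromatic ring), the para carboxylate, and the
glycol arm, with partial-charge-like weights on the polar atoms. It is a
geometric and electrostatic stand-in, not a quantum-mechanical TS; the
deacylation intermediate is intentionally out of scope because designs are
evaluated against the acylation step.

**Penalty.** A placed geometry is scored `sum_i w_i * excess_i^2` where
`excess_i` is how far constraint `i`'s measured value lies outside its
window (zero inside). The quadratic out-of-window form is smooth, standard
in matching, and makes the zero set exactly "all constraints satisfied";
distance terms carry weight 1 (Å²), angle terms small weights (0.005-0.01)
so that a degree of angular violation counts far less than an angstrom of
distance violation. Where a constraint references an alias (either
carboxylate oxygen; Asp OD1/OD2 vs Glu OE1/OE2), the best-scoring candidate
is used, deterministically.

## Matching

`matchActiveSite()` enumerates triads under identical-type anchoring
(nucleophile at native Ser, base at native His, acid at native Asp or Glu)
and uses the native side-chain conformations as the catalytic rotamers:
anchoring at identical types means the crystal conformation is available and
matching needs feasibility, not side-chain optimality. Triads whose fixed
geometry alone (His-Ser and Asp-His hydrogen-bond terms, which do not depend
on the TS) already exceeds the penalty cutoff are pruned; this pruning is
sound because the total penalty is a sum of non-negative terms, so the
matcher provably returns the same set as exhaustive triple enumeration --
the property the test suite checks on 50 seeded fixtures.

The TS pose is optimized in two stages: the sp3 carbon starts on the
continuation of the C-beta to O-gamma direction at the attack-distance
target, with the nucleophile-side TS oxygen aligned back toward O-gamma and
a deterministic grid of 8 spins about that axis; each start is refined by
Nelder-Mead on the 6 rigid-body degrees of freedom against the triad-only
constraints, the best 2 are kept, oxyanion donors and the binder hydroxyl
are selected greedily (lowest window cost, ties by chain/residue number),
and selection and full-constraint refinement alternate to a fixed point
(at most 3 cycles). With no random restarts requested the whole procedure
is deterministic; seeded random restarts exist for rugged cases
(`matchConfig(nRandomStarts =, seed =)`).

`detectPockets()` is a LIGSITE-style buriedness scan (1 Å grid, 2 Å
occupancy radius, 7 scan lines, enclosure on >= 5 lines within 8 Å, 26-
connected clustering, up to 100 lining positions per pocket). The published
cavity detector it stands in for is unpublished; only its contract -- the
largest pockets, each with a bounded position set -- matters downstream, and
all parameters are exposed.

## TS conformer libraries

`generateTSLibrary()` enumerates a torsion grid (default: the first two
rotatable torsions at 12 steps) times optional seeded rigid-body jitter
around the match's anchored pose, screens each pose with placing rules
(clash: heavy-atom pair closer than 0.8 x summed van der Waals radii;
constraint penalty <= 1.0; an oxyanion H-bond partner in range), and
de-duplicates at 0.3 Å heavy-atom RMSD. De-duplication is canonical --
survivors sorted by (penalty, torsion-vector lexicographic) and kept
greedily -- so the library is independent of enumeration order, and the
kept representative of each cluster is its lowest-penalty member. When
nothing survives, the per-rule rejection histogram is reported so the user
can see which rule dominated.

## Redesign energetics and search

The packing energy is a deliberately simple, fully documented decomposable
surrogate: 12-6 Lennard-Jones (`4*eps*((sigma/r)^12 - (sigma/r)^6)`,
per-element radii/depths, repulsion capped at +50 kcal/mol to keep tables
finite), screened Coulomb with distance-dependent dielectric (eps = 4r) on
partial-charge-like weights, a -2 kcal/mol geometric hydrogen-bond bonus per
donor/acceptor pair passing the H-bond test (idealized polar hydrogens where
explicit ones are absent), and an optional per-amino-acid reference energy
(zero by default). Absolute kcal/mol values are not claimed to match any
force field; what the pipeline tests is the logic -- tables, elimination,
enumeration, energy bookkeeping, selection -- which is independent of the
functional form.

Rotamers come from a coarse backbone-independent chi-angle table shipped
with the package, built on each position's native backbone with ideal
internal coordinates (NeRF construction; L-chirality C-beta placement). The
crystal conformation is always appended for the native type, and Ser, Thr
and Tyr are expanded over a 60/180/-60° hydroxyl-hydrogen grid, because the
hydroxyl proton's position decides hydrogen bonds that the design is
explicitly trying to build.

`searchGmec()` runs Goldstein singles dead-end elimination to a fixed point,
then exact depth-first branch-and-bound with an admissible lower bound; the
result is the certified global minimum of the decomposed energy, verified
against vectorized exhaustive enumeration on 100 seeded random instances in
the tests. There are no silent heuristics: a search space that remains too
large after elimination raises an error. The unbound (apo) state is the same
optimization with the rotamer-TS terms dropped, which gives the
binding/folding split `G_bind = G_bound - G_unbound`, `G_fold = G_unbound`
and the mutant-minus-wild-type `ddG` fields; the wild-type reference is the
all-native sequence with rotamers re-optimized in both states.
`enumerateDesigns()` enumerates sequences (exact per-sequence solves) in
energy order under a minimum-difference diversity constraint, equivalent to
successive exact solves with exclusion constraints. `selectCandidates()`
applies the two-clause admission rule -- (`ddG_bind < 0` and
`ddG_fold < 8 kcal/mol`) or `ddG_total` rank <= 30 -- with rank ties broken
by mutation-string order so the filter is deterministic, order-invariant and
idempotent; mutation-diversity or manual-inspection criteria plug in as
extra filters.

## Catalytic indicators and the screening funnel

Four per-trajectory statistics screen designs: fraction of frames with TS
heavy-atom RMSD < 2.5 Å against the first frame after protein-backbone
superposition; fraction with nucleophilic attack distance < 3.0 Å (the
catalytically productive range); and the two oxyanion hydrogen-bond
frequencies (donor-acceptor < 3.5 Å and donor-H-acceptor > 120°, strict
inequalities). "Better attack distance" is operationalized as a higher
below-cutoff fraction -- the quantity reported for designs -- with the mean
distance kept as a diagnostic. Replicates pool frame-weighted (identical to
the mean of fractions at equal frame counts). The funnel's default shape is
10 x 1 ns replicates (100 frames at 10 ps) in round 1 and 5 x 5 ns (500
frames) in round 2, and a design survives a round only if all four pooled
indicators are strictly better than the wild type's. Superposing on the
protein backbone before the TS RMSD is a choice (the reference frame is
otherwise arbitrary); it is configurable in the sense that the FrameSet's
backbone flags decide the fit set. Trajectory input is multi-model PDB only:
the analysis, not the MD engine or its binary formats, is in scope.

## Kinetics and product accounting

`fitMichaelisMenten()` fits `v0/[E] = kcat*[S]/(Km + [S])` by bounded
nonlinear least squares started from a Lineweaver-Burk linear fit, with
standard errors from the fit covariance; replicates enter individually and
unweighted. `petConversion()` converts cumulative BHET/MHET/TPA
concentrations to conversion, TPA yield and product composition against the
theoretical monomer amount `mass / 192.17 g/mol` (each aromatic species
counts one repeat-unit equivalent); composition is undefined, not zero, when
no product is present. `crystallinity()` is the DSC formula
`(dHm - dHcc) / dHm100 * 100` with the 140.1 J/g crystalline-PET reference.

**Precision of Km recovery.** The synthetic assay emulates a 2-20 mM
substrate series in triplicate (18 points) with 5% multiplicative log-normal
noise. Under those conditions the Fisher information bounds the relative
standard error of Km at about 6-7% for the default grid (about 5.8% even at
the D-optimal two-level design within the same range), so the median
absolute Km error across repeated assays is about 4-5% and individual runs
can miss by 20% or more. kcat is much better determined (about 2-3%
relative). This is a property of the assay design, not of the fitting code:
tighter Km recovery requires lower noise, more points, or substrate
coverage below 2 mM. The acceptance suite asserts a stricter recovery
target than this bound allows and therefore documents the shortfall
honestly rather than relaxing the assay.

## The synthetic-data generators

`makeToyScaffold()` plants a complete active site exactly at the constraint
targets (or displaced a stated amount beyond a tolerance edge), surrounds it
with seeded decoy residues in a 12-25 Å shell, and ships the planted truth
(positions, geometry, expected penalty), so matching and penalty scoring
have an end-to-end oracle. `synthFrames()` constructs frame ensembles in
which each indicator's defining event occurs in exactly `round(p*n)` frames
(deterministic mode; randomized order) or by per-frame Bernoulli draws;
event toggles move only side-chain, hydrogen or TS atoms so the backbone
superposition is exactly the identity and realized fractions are exact by
construction. Deterministic event counts were chosen over sampling because
exact expected outputs make tests sharp; the Bernoulli mode exists for
statistical checks. `makeFunnelCohort()` builds planted screening cohorts
(improvers gain +0.2 on every indicator; non-improvers tie the wild type on
exactly one, which the strict test rejects). `synthKinetics()` draws
multiplicative log-normal noise around the exact rate law.

What these fixtures do **not** emulate: real protein flexibility and
correlated frame-to-frame motion, real MD force-field physics, crystal-
structure disorder, or the chemistry of MHET beyond labelled pseudo-atoms.
Tests passing on them demonstrate that the algorithms are correct --
matching equals exhaustive enumeration, the GMEC is certified, fractions and
folds are computed right -- not that any particular real scaffold will yield
an active enzyme.

## Degenerate inputs, tie-breaks and problem sizes

Degenerate geometry (coincident points in angles/dihedrals) errors rather
than returning NaN. Matching with no admissible triad returns an empty list,
not an error; a TS library with no survivors returns an empty library with
the rejection histogram. All ranking ties break deterministically:
matches by (penalty, triad compactness, position order), conformers by
(penalty, torsion vector), selection ranks by mutation string. The default
validation scales are: 50 toy scaffolds of at most 40 residues for the
matcher oracle, 100 random instances of at most 5 positions x 6 rotamers
for the search oracle, planted cohorts of 237 (round 1) and 118 (round 2)
designs at the funnel's native replicate/frame counts, and 200 simulated
kinetic assays -- sizes at which every oracle is exact and the whole suite
runs in a few minutes on one core.

## Known limitations

The backbone is rigid throughout (matching, packing, and the design states);
the energy model is a documented surrogate, so ddG values rank designs but
are not comparable across force fields; pocket detection is a contract-level
stand-in for an unpublished cavity detector; hydrogen placement is
idealized when explicit hydrogens are absent; and mmCIF, NMR ensembles and
binary trajectory formats are out of scope.
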