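---
title: "Computing electric fields along a carbonyl Stark probe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing electric fields along a carbonyl Stark probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starkfield)
```

## The problem

Vibrational Stark effect (VSE) spectroscopy turns a carbonyl group into a
local electric-field meter: the C=O stretching frequency shifts linearly
with the field projected on the bond,

$$ h c \,\Delta\tilde\nu = -\,\Delta\vec\mu \cdot \Delta\vec F, $$

where the Stark tuning rate $|\Delta\vec\mu|/(hc)$ (cm$^{-1}$ per MV/cm) is
calibrated experimentally. In enzymes such as ketosteroid isomerase (KSI),
whose active site imposes fields of order $-100$ MV/cm on a bound carbonyl
probe, this links measurable spectra to the electrostatic-preorganization
picture of catalysis: a larger field along the C=O stabilizes the
charge-rearranged intermediate and lowers the activation free energy.

`starkfield` implements the computational side of that protocol:

1. **Classical fields.** The potential at a point is the unscreened Coulomb
   sum $\varphi(\vec r) = \frac{1}{\varepsilon_\mathrm{eff}} k \sum_j
   q_j/|\vec r - \vec r_j|$ with $k = 14.399645$ V·Å/e, and the mean field
   along the bond is $F = (\varphi_C - \varphi_O)/|\vec r_{CO}|$, reported
   in MV/cm (1 V/Å = 100 MV/cm). The probe C=O and the ring it is bonded to
   are excluded from every sum — their own charges at the evaluation points
   would produce non-physical self-terms.
2. **Fragment-based potentials.** A generalized molecular fractionation
   with conjugate caps (GMFCC) assembly replaces the whole-system quantum
   calculation by capped single-residue fragments (+), conjugate caps
   (−) that cancel the double-counted overlap, and two-body corrections
   for residue pairs in spatial contact (generalized concaps), each
   embeddable in the point charges of the rest of the system (EE-GMFCC).
3. **Analytics.** Eyring inversion of rate constants
   ($\Delta G^\ddagger = -RT\ln[k_\mathrm{cat}/(k_BT/h)]$, $T$ = 293 K by
   default), least-squares field–energy correlations, H-bond occupancy
   with the 3.5 Å break criterion, and per-residue field decompositions.

## The assembly and its exactness oracle

For a chain of $N$ residues the assembled potential is

$$ V = \sum_{i=2}^{N-1} V(\mathrm{Cap}_{i-1}A_i\mathrm{Cap}_{i+1})
     - \sum_{i=2}^{N-2} V(\mathrm{Cap}_i\mathrm{Cap}_{i+1})
     + \sum_{\substack{j>i+2\\ d_{ij}\le\lambda}}
       \left[V_{ij} - V_i - V_j\right], $$

with $\lambda = 4.0$ Å. Terminal residues are absorbed whole into the caps
of fragments 2 and $N-1$ — this is forced by the index ranges above.

**Cap recipe.** The cap taken from residue $i-1$ is its backbone carbonyl
unit {CA, C, O} with a hydrogen link atom replacing its N; the cap from
residue $i+1$ is its {N, CA} with a link atom replacing its C. Link
hydrogens sit on the cut-bond axis at 1.09 Å from a kept carbon and 1.01 Å
from a kept nitrogen. Cap pieces are constructed once and shared between
capped fragments and concaps, so the overlap cancellation is exact by
construction, not merely to numerical tolerance. The telescoping algebra
holds for *any* consistent cap recipe; this one is the smallest that
satisfies the shared-cap requirement, and it is isolated in one function so
a richer cap chemistry can be swapped in. Side-centroid pseudo-atoms of
the toy residues are not valence-saturated when a cap cuts near them; this
is irrelevant for additive backends and documented here for QM ones.

**Why a surrogate backend.** The production backend contract targets an
external quantum-chemistry engine (documented defaults M06-2X/6-31G**).
The package also ships an *additive point-charge surrogate*: the fragment
potential is the Coulomb sum of its own atoms, link atoms carry zero
charge, and the embedding background is ignored. Because this model is
exactly additive over atoms, the assembled potential must telescope to the
direct whole-system Coulomb potential at machine precision, and every
two-body correction must vanish identically. That identity is the
package's central oracle: it exercises every piece of fragmentation
bookkeeping (index ranges, terminal absorption, shared caps, link-atom
placement, gconcap signs) with a known exact answer. The test suite
asserts it on randomized folded peptides at a relative tolerance of
1e-10; observed errors are at the 1e-14 level.

**Gconcap singles** are hydrogen-capped isolated residues (both flanking
peptide bonds cut and saturated), and the pair term is the union of the
two capped singles, implementing $V_{ij} - V_i - V_j$ literally. Ligand
pairs treat the whole ligand as one partner with no link atoms. Contact
distances use all atoms by default ("closest distance" taken
conservatively); a heavy-atom-only switch exists.

**Embedding backgrounds** contain protein and ligand atoms only by
default; solvent is handled classically outside the fragment machinery
(a flag includes it). Link atoms never appear in backgrounds.

## The single-snapshot protocol

Converged time averages of a quantum-level field are out of reach, so the
protocol averages the *classical* per-frame field over the trajectory,
selects the frame whose field lies closest to that mean (ties break to the
earliest frame), and runs the fragment assembly on that single snapshot.
The ligand and solvent contributions remain classical *time averages* over
all frames — not the selected frame's instantaneous values — and are added
to the assembled protein field; the three components are reported
separately. Evaluation points sit 0.1 Å off the atomic centers toward the
bond midpoint (for the assembled and the classical amended components
alike): far enough from nuclei to avoid density singularities in real QM
backends, while perturbing the projection of a uniform field by well under
1% on the benchmark scenes. Both the offset and the choice to evaluate the
protein assembly off-center are configurable, since reasonable
implementations differ on whether only the ligand sums use off-center
points.

## What the synthetic generators emulate

The generators stand in for the molecular-dynamics sampling and the
protein/ligand chemistry that a production study would take from
simulations of a real structure:

* `make_toy_polypeptide()` — a single chain of five-atom model residues
  (N, CA, C, O, side centroid) with fixed internal coordinates, in three
  folds: `extended` (no long-range contacts, so no gconcap pairs form at
  λ = 4 Å), `helixlike` (a tight coil with i/i+3 contacts inside λ), and
  `hairpin` (sequence-distant residues at van-der-Waals contact). The
  five-atom template is the smallest that supports peptide-bond cutting
  with the cap recipe above while staying cheap enough for brute-force
  oracles. Designed per-residue net charges are placed on the side
  centroid, so charge sums are recovered exactly.
* `make_probe_ligand()` — a C=O pair 1.23 Å apart, optionally bonded to a
  neutral six-membered ring; the returned exclusion set (8 atoms with the
  ring) is the canonical probe exclusion.
* `make_trajectory()` — frames are reference coordinates plus i.i.d.
  Gaussian jitter. The two-state H-bond model repositions a designated
  donor each frame to exactly `r_bound` (probability `p_bound`) or
  `r_broken`, with *independent* frames, so occupancy estimators are
  exactly binomial and test bounds are sharp (±0.02 is 3σ at 5000 frames
  and p = 0.7). Real H-bond dynamics are autocorrelated and their
  distances continuous; passing these tests validates the estimator, not
  any force field.
* `make_field_benchmark()` — scenes with closed-form fields: a single
  charge (119.997 MV/cm along the standard probe), a mirror-symmetric
  dipole (projection exactly zero), and a parallel-plate capacitor whose
  discrete lattice approaches the uniform-field value $4\pi k\sigma$; at
  the default geometry (400 Å plates, 6 Å gap) the finite-plate deviation
  is ≈1.3%, within the 2% acceptance band.

Everything is deterministic given the spec seed; per-stream seeds are
derived by fixed offsets so jitter and H-bond switching are independent.

## Numerical choices

* Coulomb constant pinned at 14.399645 V·Å/e for bit-stable tests;
  $\varepsilon_\mathrm{eff} = 1$ by default (explicit solvent assumed).
* No cutoffs, no periodic images: the sums run over all atoms supplied;
  trajectories are expected to be already imaged.
* The field sign is literal, $(\varphi_C-\varphi_O)/|r_{CO}|$: negative
  values mean the field points O→C, matching the convention in which
  active-site fields on a bound carbonyl are negative. No hidden flips.
* Time averages are plain means over saved frames (no timestep weights).
* Singular evaluation points (within 1e-6 Å of an included atom) are
  errors naming the clashing atom, never silent large numbers.
* Fragment net charges are rounded to integers for QM engines; the QM
  adapter warns when the raw sum is more than 0.01 e from an integer.
  The additive surrogate uses raw charges and is unaffected.
* Contribution percentages round half away from zero to integers, the
  granularity at which such decompositions are usually quoted.
* R² is reported as 1 − RSS/TSS (equal to the squared Pearson correlation
  of observed vs fitted for simple regression), computed in closed form.

## Design decisions that were genuinely open

* **Trajectory format.** Multi-model PDB only: no binary-format
  dependency, adequate at the scales this package targets, and each MODEL
  block is validated against the topology with errors naming the model.
* **PQR as charge interchange.** A whitespace-separated PQR dialect
  written at six decimals is the canonical charged-structure format,
  keeping the package independent of any force-field toolchain; plain PDB
  input takes charges from a separate table (`assign_charges()`).
  Alternate locations keep altloc A with a note.
* **Config format.** The run configuration is YAML — a plain-text
  key–value format with a robust parser available everywhere this package
  runs.
* **QM backend as contract.** No electronic-structure code is bundled or
  required; the adapter defines the request/result contract, errors
  explicitly when no engine is registered (never a silent surrogate
  fallback), and caches results on disk keyed by a content hash with
  hex-float replay so repeated calls are bit-identical.
* **Solvent in backgrounds.** Default protein+ligand only; the wording
  "remaining atoms of the protein" reads most naturally as protein-side
  embedding, and solvent is amended classically. A flag includes solvent
  for sensitivity checks.

## Problem sizes

The shipped tests and the acceptance script run: telescoping on 20 random
peptides of 3–15 residues; 5000-frame occupancy recovery; 1000 random
series for snapshot selection; n = 200 OLS recovery; a 5-frame end-to-end
pipeline on a 6-residue peptide with a ringed probe ligand. These sizes
give sharp statistical bounds while completing in seconds.

## A worked example

```{r}
spec <- toy_spec(n_residues = 6, seed = 17, jitter_sigma = 0.04,
                 n_frames = 5, residue_net_charges = c(0, -1, 0, 1, 0, -1))
prot <- make_toy_polypeptide(spec)
lig <- make_probe_ligand(position = c(10, 1.5, 0.3),
                         direction = c(0, 1, 0), ring = TRUE,
                         serial_offset = max(prot$atoms$serial))
sys <- merge_systems(prot, lig$system)
probe <- probe_bond(sys, lig$probe$c_serial, lig$probe$o_serial)
excl <- exclusion_set(sys, lig$exclusion)
traj <- make_trajectory(sys, spec)

gm <- gmfcc_bond_field(sys, traj, probe, excl, backend = "surrogate")
gm
```

The surrogate total equals the classical protein-plus-amendments field
exactly — the oracle the whole package is built around.

## Known limitations

* The classical engine is unscreened point-charge electrostatics: no
  reaction field, no Ewald summation, no induced dipoles.
* Fragmentation covers peptide-bond cuts only — no disulfides, no
  cofactor fragmentation beyond the single-ligand rule, no mmCIF input.
* The linear Stark relation omits higher-order terms; experimentally
  derived fields may carry ≈10% overestimation from that truncation, and
  no correction is applied here.
* The toy generators make no claim of physical realism; they exist to
  make every stage falsifiable against closed forms and brute force.
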