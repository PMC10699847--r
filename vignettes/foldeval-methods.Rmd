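---
title: "Methods: structure losses and assessment statistics in foldeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure losses and assessment statistics in foldeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldeval)
```

`foldeval` computes the geometric losses used to train modern protein
structure predictors, and the statistics used to assess the resulting
models, as ordinary functions of coordinates. This vignette records the
mathematical definitions, the conventions the package fixes where the field
leaves a choice open, and what the synthetic test data do and do not
establish.

## The sequentially conditioned torsion loss

Side-chain torsions χ1…χ4 are defined by residue-specific atom quadruples
(e.g. ARG χ1 = N–CA–CB–CG) and are serially dependent in Cartesian space: a
residue whose χ1 is wrong has every atom beyond CB misplaced, regardless of
how accurate its later torsions are. The loss therefore measures each
torsion on the unit circle,

$$E_{\chi_k} = \lVert (\cos\chi_k, \sin\chi_k) - (\cos\hat\chi_k,
\sin\hat\chi_k) \rVert_2 \in [0, 2],$$

and conditions later errors on earlier ones through

$$\tilde E_{\chi_k} = \tilde E_{\chi_{k-1}} + E_{\chi_k} -
\tfrac{1}{2}\,\tilde E_{\chi_{k-1}} E_{\chi_k}, \qquad
\tilde E_{\chi_1} = E_{\chi_1}.$$

The map $f(a, b) = a + b - ab/2$ on $[0,2]^2$ stays in $[0, 2]$, is monotone
in both arguments, dominates both ($f \ge \max(a, b)$), and has 2 as an
absorbing fixed point: once a torsion is maximally wrong, every deeper
torsion inherits the maximal error even when its own angle difference is
zero. These properties are exercised on $10^5$ random points in the test
suite. The loss sums $E_{\chi_1}$ and $\tilde E_{\chi_2 \ldots 4}$ over the
residues possessing each torsion and divides by the total residue count
$N$, so torsion-free residues (GLY, ALA) dilute the average — a per-protein,
not per-rotamer, quantity.

Torsions with a π-periodic ambiguity (the terminal torsions of ASP, GLU and
the ring torsions of PHE, TYR) are flagged in every `torsion_set`. Whether
training pipelines fold that ambiguity into the loss is not standardized,
so both behaviours are provided: `angle_loss(..., symmetry_correct = FALSE)`
(default) penalizes the raw difference, evaluation functions default to the
corrected difference. This split — strict for losses, forgiving for
assessment — is the package's own choice and is controlled by one flag at
each call site.

## FAPE and the distogram weighting

Every residue with a complete backbone defines a rigid frame by
Gram–Schmidt: origin at CA, first axis along CA→C, second axis CA→N
orthogonalized, third their cross product. This is the de-facto standard
backbone-frame convention; the package states it explicitly because the
frame-aligned point error is meaningless without one. FAPE is

$$L_{\mathrm{FAPE}}(T_i, x_j) = \min\left( \lVert T_i^{-1} x_j -
T_i^{(\mathrm{true})-1} x_j^{(\mathrm{true})} \rVert_2,\; 10\,\text{Å}
\right),$$

the clamp (default 10 Å) washing out errors beyond it. The implementation
follows this formula literally — no additional distance normalization — and
reports both the full per-(frame, point) matrix and its unweighted mean.
Because both prediction and truth are expressed in their own local frames,
the scalar is invariant under any common global rigid motion of either
side, a property tested to 1e-9 Å over random motions.

The weighted variant multiplies each term by a sigmoid of the mode distance
$d_{ij}$ between Cβ atoms taken from a distogram:

$$w_{ij} = \frac{1}{1 + e^{-2(v - d_{ij})}} + h,$$

with defaults $v = 12.0$ Å (inflection) and $h = 1.5$ (offset), giving
weights in $(h, 1+h)$: pairs predicted to be in contact are up-weighted
roughly 5/3 relative to distant pairs. Three aggregation details are not
dictated by the formula and are package decisions:

- the aggregate is the plain mean of weighted terms by default, with
  `normalize_by_weight_sum = TRUE` switching to $\sum w\,l / \sum w$;
- each atom inherits the weight of its owning residue pair, since the
  weight is defined on residue pairs while the error runs over atoms;
- self-pairs use $d_{ii} = 0$ and hence the near-maximal weight
  $\approx 1 + h$; glycine, lacking Cβ, falls back to CA.

## Distogram conventions

A distogram stores, per residue pair, a probability distribution over
binned distances. Edges $e_1 < \dots < e_m$ define $m+1$ bins including the
two unbounded tails; the default layout is 64 bins spanning 2.3125–21.6875 Å
in 0.3125 Å steps, the convention of standard distogram prediction heads.
The mode distance of a pair is the representative of its argmax bin:
interior bins use midpoints, the open-ended last bin extrapolates by half
the previous width, ties break toward the lower bin. These representatives
are package decisions (nothing in the loss definition fixes them); with the
default bin width the choice moves $d_{ij}$ by at most 0.16 Å, which changes
$w_{ij}$ by under 2 %.

`distogram_from_structure()` synthesizes distograms for testing by
integrating a Gaussian (sd = 1/sharpness Å) centred on the true Cβ distance
over each bin; as sharpness grows this converges to a one-hot on the true
bin, and the round trip through `mode_distance()` recovers true distances
to half a bin width.

## Cross-entropy losses and the confidence score

The secondary-structure loss is the mean categorical cross-entropy over the
DSSP 8-state alphabet {H, G, I, E, B, T, S, -}. The side-chain confidence of
a residue is

$$s_i = \frac{1}{1 + (\delta_i / \delta_0)^2},$$

on the circular χ1 difference $\delta_i$, with $\delta_0 = 12°$: 1 for a
perfect χ1, exactly 0.5 at $\delta = \delta_0$. For the loss, $s_i$ is
discretized into 50 uniform bins on $[0, 1]$ (half-open, last bin closed;
indices are 1-based as is idiomatic in R) and scored by one-hot
cross-entropy over residues with an available χ1. Both cross-entropies
floor probabilities at 1e-8 before the log; the uniform-prediction values
ln 8 ≈ 2.0794 and ln 50 ≈ 3.9120 are reproduced to 1e-6 and results are
insensitive to the floor above 1e-12. The per-sequence confidence reported
by `sequence_confidence()` is the mean $s_i$ over χ1-bearing residues.

The combined objective is the linear combination
$L = c_1 L_{\mathrm{angle}} + c_2 L_{\mathrm{WFAPE}} + c_3
L_{\mathrm{secondary}} + c_4 L_{\mathrm{sc}} + c^\top L_{\mathrm{others}}$.
The six auxiliary losses of the base network enter as caller-supplied
scalars with published default weights (0.5, 0.3, 2.0, 0.01, 0.01, 1.0).
The component weights $c_1 \ldots c_4$ are **library defaults of 1.0
each** — the values used in actual training runs are not published in the
main literature this package draws on, so the defaults are deliberately
neutral and prominently configurable (YAML `weights:` block).

## Assessment statistics

**χ accuracy** is the fraction of residues possessing χk whose circular
difference is *strictly* below the criterion (default 10°); the strict
inequality makes the boundary case deterministic. π-symmetry correction is
on by default here. An empty residue set is an undefined result (error),
never silently 0.

**Template alignment quality** collects native residue pairs with author
sequence separation > 3 (i.e. |i − j| ≥ 4) and Cβ distance < 8 Å, and
counts a pair similar when the template distance at the aligned positions
differs by < 3 Å. Unaligned pairs stay in the denominator and count as
failures, so the ratio reflects both alignment coverage and geometric
fidelity — removing matched columns can never raise it (a tested
monotonicity). Cβ with CA fallback is used for distances, matching the
distogram convention; the atom choice is a package decision.

**Z-scores** standardize each (domain, metric) across groups with the
sample standard deviation, after negating lower-is-better metrics
(SCerror, Molprobity, BBerror, DipDiff). The default two-pass procedure
mirrors long-standing CASP practice: discard first-pass Z < −2, restandardize
against the remainder, floor the final Z at −2; one-pass mode is available
since assessor pipelines vary. The assessor aggregation
$\tfrac16(\text{GDT-HA}+\text{reLLG}+\text{ASE}) +
\tfrac1{16}(\text{LDDT}+\text{AA}+\text{SG}+\text{SCerror}) +
\tfrac1{12}(\text{Molprb}+\text{BBerror}+\text{DipDiff})$ has weights
summing to exactly 1, so unit Z everywhere scores the domain count — the
package's normalization check. Computing the eleven underlying metrics is
out of scope; the package aggregates values produced by external assessors.

## Synthetic data

`make_peptide()` builds peptides from ideal internal geometry
(Engh–Huber-style bond lengths and angles embedded as constants) at
canonical backbone torsions (helix −57/−47, extended −139/135, ω = 180) and
grows side chains by natural-extension-reference-frame placement with χ
angles drawn uniformly per residue (seed-reproducible, recorded on the
object). `perturb_chi()` re-grows side chains after wrapped-Gaussian χ
noise, recording the exact applied deltas; `perturb_rigid()` jitters each
residue's rigid placement, with the translation component calibrated to the
requested coordinate RMSD.

These generators make every quantity testable against exact ground truth:
build/extract torsion round trips close to 1e-6 rad, recorded deltas
reproduce confidence and accuracy statistics to 1e-12, and uniform χ noise
drives the 10° χ1 accuracy to its circular-null value 20/360 = 1/18
(checked within 3 binomial standard deviations at n = 2000 residues). What
they do **not** emulate: rotamer statistics, steric clashes, correlated
backbone/side-chain errors, missing density, or crystallographic artifacts.
Passing tests establish the correctness of the formulas and conventions,
not the behaviour of the losses on the error distributions of real
predictors.

Test problem sizes — peptides of 10–30 residues for geometry and loss
properties, 2000 residues for the circular-null accuracy check, $10^5$
points for the recursion grid, 100–1000 random instances for oracle
equivalence — were chosen so the full suite runs in well under a minute
while keeping sampling error far below the tested tolerances.

## Numerical choices and degenerate inputs

- Angles live in (−π, π] (trans = +π, never −π); all internal computation is
  in radians, the CLI surfaces degrees.
- Dihedrals with zero-length or collinear bond vectors raise a geometry
  error (threshold 1e-9 on intermediate norms) rather than returning 0.
- Rotations are validated orthonormal with det +1 to 1e-6 at construction.
- Distogram rows must be symmetric and normalized to 1e-6; probability
  floors are 1e-8.
- Zero standard deviation in a Z-score cell yields Z = 0 for all groups
  rather than an error, so degenerate all-equal tables rank neutrally.
- Missing χ-defining atoms mask that torsion (with a parse/extract warning)
  instead of zero-filling; masked entries are never read downstream.
- Alternate locations resolve to highest occupancy, ties to the lowest
  altloc letter; MSE maps to MET (SE → SD); other HETATM records are
  skipped. Every such decision leaves a record in the `parse_report`.

## Known limitations

- The alignment-quality pair enumeration is O(n²) in plain R; adequate for
  domains (seconds for n ≈ 500), not tuned for full-proteome sweeps.
- `perturb_chi()` assumes side chains that follow the package's growth
  recipes (only the χ-path atoms are rebuilt); applying it to arbitrary
  experimental structures would silently drop atoms outside the recipe.
- PDB parsing is single-model and single-chain per call; mmCIF is not
  parsed.
- The package computes losses, not gradients: it is an analysis and
  evaluation tool, not a training framework.
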