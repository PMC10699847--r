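# foldeval

Loss functions and assessment statistics for protein structure models.

Deep-learning structure predictors are trained against geometric losses and
judged by community assessment statistics, but those quantities are usually
buried inside training code and assessor pipelines. `foldeval` implements
them as a standalone R library and command-line tool, computable on any pair
of structures (real PDB files or the package's deterministic synthetic
peptides) without a neural network:

- **Sequentially conditioned side-chain torsion loss.** Side-chain torsions
  χ1…χ4 are serially dependent in 3D: an error in χ1 displaces every later
  atom no matter how accurate χ2…χ4 are. Each χ error is the chord distance
  E_χ = ‖(cos χ, sin χ) − (cos χ̂, sin χ̂)‖ ∈ [0, 2], and errors are
  propagated down the chain by Ẽ_χk = Ẽ_χk−1 + E_χk − Ẽ_χk−1·E_χk/2
  (Ẽ_χ1 = E_χ1), a recursion that is bounded in [0, 2], monotone, and
  absorbing at 2. The loss is the mean over residues of the summed
  conditioned errors.
- **Frame-aligned point error (FAPE) and its distogram weighting.** Each
  atom is expressed in the local backbone frame of every residue
  (Gram–Schmidt on N, CA, C with CA origin), and the loss is the clamped
  local-coordinate distance min(‖T_i⁻¹x_j − T_i⁻¹⁽ᵗʳᵘᵉ⁾x_j⁽ᵗʳᵘᵉ⁾‖, 10 Å).
  The weighted variant multiplies each (i, j) term by
  w_ij = 1/(1 + exp(−2(v − d_ij))) + h, where d_ij is the mode Cβ–Cβ
  distance from a distogram and v = 12.0 Å, h = 1.5 — more weight on residue
  pairs predicted to be close.
- **Secondary-structure and side-chain-confidence cross-entropies.** Mean
  cross-entropy over DSSP 8-state labels, and over a 50-bin discretization
  of the per-residue side-chain confidence s_i = 1/(1 + (δ_i/δ₀)²) on the
  χ1 difference δ_i, with δ₀ = 12°.
- **Combined objective.** L = c1·L_angle + c2·L_WFAPE + c3·L_secondary +
  c4·L_sc + cᵀ·L_others, the six auxiliary losses entering as caller
  scalars.
- **Assessment statistics.** χ accuracy at the 10° criterion of
  correctness, per-sequence side-chain confidence, a contact-based template
  alignment-quality ratio (native pairs with sequence separation > 3 and
  distance < 8 Å, similar when the template distance differs by < 3 Å), and
  CASP-style Z-scores with the assessor aggregation
  sum Z = 1/6(GDT-HA + reLLG + ASE) + 1/16(LDDT + AA + SG + SCerror) +
  1/12(Molprb + BBerror + DipDiff).

## Worked example

```r
library(foldeval)

native <- make_peptide("SRLFKMEDQW", "helix", seed = 7)
model  <- perturb_chi(perturb_rigid(native, 1.0, seed = 8),
                      sigma_deg = 20, seed = 9)
dg <- distogram_from_structure(native, sharpness = 10)

structure_losses(native, model, mode_dist = mode_distance(dg))
#> $l_angle   1.1085     # mean conditioned chi error per residue
#> $fape      1.3404     # mean clamped local-coordinate error (A)
#> $l_wfape   3.2731     # FAPE re-weighted toward close residue pairs
#> $combined  4.3816     # weighted sum (unit c1..c4 defaults)

tsn <- structure_torsions(native); tsm <- structure_torsions(model)
chi_accuracy(tsn, tsm, k = 1)        # 0.6  : 6/10 chi1 within 10 degrees
sequence_confidence(tsn, tsm)        # 0.6146 : mean 1/(1+(delta/12deg)^2)
```

With 20° χ noise, 6 of the 10 residues keep χ1 within the 10° criterion,
and the mean confidence drops from 1 to about 0.61; the weighted FAPE
exceeds the plain FAPE because most pairs in a 10-residue peptide are close
(w > 1), while `l_angle` accumulates the chord errors of all four χ levels.

The same numbers are available from the shell:

```sh
Rscript inst/cli/foldeval.R simulate --sequence SRLFKMEDQW --chi-noise 20 \
    --seed 7 --out fixtures/
Rscript inst/cli/foldeval.R losses --native fixtures/native.pdb \
    --model fixtures/model.pdb
Rscript inst/cli/foldeval.R casp-score --metrics metrics.csv
```

Exit codes: 0 success, 2 usage error, 3 input-format error, 4 undefined
result. Angle-valued CLI options are in degrees; the library works in
radians.

## Documentation

The methods vignette (`vignettes/foldeval-methods.Rmd`) describes the loss
definitions, the conventions the package fixes where the field leaves a
choice open (frame construction, bin representatives, aggregation,
π-symmetry handling), the synthetic-data generators, and known limitations.
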