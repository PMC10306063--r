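# seqregister

Sequence-register validation for crystallographic protein models.

Register shifts — regions where a model's backbone is right but the residue
identities are offset along the sequence by a fixed number of positions —
survive refinement and are among the hardest model errors to spot by eye.
`seqregister` re-derives the sequence assignment of a model directly from the
electron density and flags places where the density disagrees with what the
model claims.

For every modelled residue a 20-class residue-type probability profile is
estimated from the map (a transparent density-shell classifier ships as the
reference; any classifier can be plugged in, and precomputed profile tables
are accepted). Each chain is assigned to a target sequence, then fixed-length
windows (default L = 20) are re-aligned, without gaps, against the target.
A window at offset *o* scores

    S(o) = sum_i log( P_i(a_{o+i}) / q(a_{o+i}) )

and its significance is an exact p-value: the per-position score
distributions under an i.i.d. background are convolved on a 0.01-nat lattice,
and the best-of-M-offsets correction `p = 1 - (1 - tail)^M` is applied. A
window with `p < 0.14` whose best offset differs from the model's claimed
register indicates a register error. Confident shifted windows are merged
into regions categorized as **register_shift**, **indexing_issue** (numbering
wrong, identities right), **sequence_mismatch**, or **unassigned_chain**.

Inputs: mmCIF/PDB coordinates, FASTA target sequences, and density as either
a CCP4/MRC map or 2mFo−DFc map coefficients in MTZ format (synthesized by
FFT). A full synthetic benchmark generator with ground-truth scoring makes
every stage testable without downloading any structure.

## Worked example

Generate a 300-residue synthetic benchmark whose claimed assignment carries
a +2 register shift over residues 121–180 (classifier accuracy 0.9), and
validate it:

```r
library(seqregister)

spec  <- synthetic_spec(chain_length = 300, accuracy = 0.9,
                        shifts = list(c(121, 180, 2)), seed = 42)
bench <- make_benchmark(spec)
model <- structure(list(chains = list(A = bench$chain),
                        cell = list(a = 50, b = 50, c = 50, alpha = 90,
                                    beta = 90, gamma = 90),
                        spacegroup = "P 1"), class = "structure_model")

report <- check_sequence(model, list(bench$target),
                         profiles = list(A = bench$profile), seed = 42)
print(report)
#> seqregister validation report
#>   chain A: 300 residues, assigned to target (p = 1e-300)
#>   chain A, residues 123-180, register shift +2, p < 1e-300
summary(report)
#> issue regions by category:
#>   register_shift     1
#>   indexing_issue     0
#>   sequence_mismatch  0
#>   unassigned_chain   0
```

The injected region was 121–180 with offset +2; the detected region 123–180
recovers the offset exactly and localizes both boundaries within the
half-window accuracy of the scan (ground truth comparison:
`evaluate_regions(report$regions, bench$truth)`).

With real files the same pipeline runs from disk, either in R —

```r
report <- run_validation("model.pdb", "targets.fasta", map_path = "map.ccp4")
```

— or from the shell via the thin CLI installed in `exec/`:

```sh
seqregister --modelin model.pdb --seqin targets.fasta --mtzin coeffs.mtz \
            --labin FWT,PHWT --jsonout report.json
```

Exit code 0 means the scan ran (issues are results, not failures); 1 is a
usage error, 2 an input error.

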