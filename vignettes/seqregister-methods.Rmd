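---
title: "Detecting sequence-register errors with seqregister"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sequence-register errors with seqregister}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqregister)
```

## The problem

A register shift is a protein-model error in which the backbone trace is
essentially correct but the residue identities are systematically offset
along the sequence by a fixed number of positions. Such errors are easy to
make during manual or automated building — an insertion or deletion in a
poorly resolved loop propagates down the chain — and hard to spot, because
refinement will happily fit the wrong side chains into the density.
Related pathologies are residue-indexing issues (the numbering silently
skips or absorbs an unmodelled stretch while the identities stay right),
point sequence mismatches and UNK residues, and whole chains that cannot be
reconciled with any target sequence at all.

seqregister re-derives the sequence assignment of a deposited model
directly from the experimental density and compares it with what the model
claims. The pipeline is:

1. **Profile**: for every modelled residue, estimate a 20-class probability
   vector over amino-acid types from the density around its side chain
   (`extract_profile()`; any classifier obeying the contract can be plugged
   in).
2. **Assign**: align each chain's profile, without gaps, against every
   target sequence and keep the best match if its p-value clears the
   threshold (`assign_chain()`).
3. **Scan**: slide fixed-length windows along the chain, re-align each
   window against the assigned target, and compare the detected register
   with the model's claimed register (`scan_chain()`).
4. **Categorize**: merge confident, consistently shifted windows into issue
   regions labelled register shift / indexing issue / sequence mismatch /
   unassigned chain (`categorize_calls()`).

## The alignment statistic and its null

A window is an $L \times 20$ matrix of per-residue type probabilities
$P_i(a)$. Its gapless alignment to target letters
$a_{o+1}, \dots, a_{o+L}$ at offset $o$ scores

$$ S(o) = \sum_{i=1}^{L} \log \frac{P_i(a_{o+i})}{q(a_{o+i})}, $$

a log-odds against a background composition $q$ (uniform by default; rows
are floored at $10^{-4}$ and renormalized before the logarithm so scores
stay finite). An `X` in the target contributes zero.

Significance is computed exactly rather than by asymptotics. Under the
null that the window faces an i.i.d. background sequence, the
per-position score is a 20-atom discrete distribution
($\log(P_i(a)/q(a))$ with probability $q(a)$). Atoms are binned onto a
lattice of 0.01 nats (rounding down) and the $L$ positions are convolved —
an exact, finite computation (`null_score_distribution()`, implemented in
C++; windows identical up to within-row and across-row permutation share a
cached result). The tail $P(S \ge s)$ is read from the convolution with
the lookup threshold lowered by $L-1$ lattice bins: since each per-atom
floor loses less than one bin, $\sum_i \lfloor v_i \rfloor \ge
\lfloor \sum_i v_i \rfloor - (L-1)$, so the reported tail provably bounds
the exact tail from above. The binning direction alone would be
anti-conservative; the guard restores a one-sided guarantee.

The best alignment is searched over $M$ candidate offsets (all positions
of all targets), so the reported p-value is

$$ p = 1 - (1 - \text{tail})^{M}. $$

Offsets of overlapping windows are not independent, but their correlation
is weak (neighbouring offsets combine the same letters with different
profile rows) and the approximation errs conservative. With the 0.14
decision threshold, a window is *shifted* when $p < 0.14$ **and** its best
offset differs from the model's claimed register; *consistent* when the
offsets agree; *inconclusive* otherwise. The 0.14 operating point is the
established choice for this family of methods and is exposed as
`pvalue_threshold`.

Because the p-value machinery is exact-by-construction, its unit tests can
demand strong agreement: the $L = 2$ null must equal brute-force
enumeration over all 400 residue pairs, and convolution tails must match
Monte-Carlo best-score frequencies (binned identically) within binomial
error.

## Claimed register, categories and boundaries

The model's claimed register is anchored once per continuous
residue-numbering segment: the claimed one-letter string is placed in the
target at the minimum-Hamming offset (`X` acts as a wildcard; ties prefer
the offset implied by the author numbering). Exact-match anchoring was
rejected as too brittle — a single point mutation or UNK residue would
unanchor every window covering it, contradicting the goal of reporting
such residues as isolated mismatches *inside* consistent stretches.
Anchors with more than 50% mismatches are treated as undefined.

Merged shifted runs (equal offset, separations up to `merge_gap` = 5
residues) become regions. The category split follows the evidence: if the
claimed residues *match* the target at the detected offset, the identities
are right and only the numbering is off — an indexing issue; otherwise a
register shift. Residues inside consistent coverage whose claimed letter
disagrees with the target (or is `X`) are reported as sequence mismatches.
Chains whose best whole-chain alignment never clears the threshold are
reported as unassigned; chains shorter than ten residues are skipped
outright, and chains between ten residues and the window length are
scanned as a single truncated window.

Region boundaries use a midpoint rule: a window straddling a shift
boundary flips verdict roughly when half its residues support each
register, so the first and last shifted windows each contribute their
midpoints. On the synthetic benchmark (length 300, one +2 shift spanning
residues 121–180, profile accuracy 0.9) the median boundary error over 200
replicates is about 1 residue, well within the five-residue localization
the scan geometry implies; single-window regions collapse to one residue.

## The synthetic benchmark generator

Real maps and deposited models cannot ship with a package, so every stage
is exercised against a generator with known ground truth:

* `gen_sequence()` draws i.i.d. target sequences.
* `inject_errors()` builds a claimed chain from a target and perturbs it:
  register shifts change which target position each residue's density
  *truly* represents (positive offset = truth ahead of claim); numbering
  gaps change author numbers only; mismatches change claimed types only.
* `gen_profile()` emulates a residue-type classifier with accuracy
  $\alpha$: each residue's *predicted* type is the true type with
  probability $\alpha$, otherwise a confusion draw (uniform by default, or
  a similarity-weighted kernel that confuses D/N, E/Q, V/T/I and F/Y);
  the row then places mass $\alpha$ on the prediction. The stochastic
  prediction is essential: it reproduces a classifier's error *rate*, not
  just its confidence.
* `sample_fragments()` mirrors the fragment-sampling protocol used to
  benchmark this family of methods: up to three fragments per chain per
  length (10 and 20 by default), rejecting fragments that contain unknown
  residues or whose residue count disagrees with the flanking residue
  numbers (insertion codes also disqualify).
* `evaluate_regions()` scores detector output: a detected region matches a
  true one when category and offset agree and the spans overlap at least
  half of the true span; boundary error is the larger endpoint
  discrepancy.

What the generator does **not** emulate: crystallographic noise, model
bias, resolution dependence, or correlated classifier errors along the
chain. $\alpha$ is an abstract accuracy knob. Passing the synthetic suite
therefore demonstrates the statistics and the scanning logic, not
performance on real maps; on real data everything hinges on the plugged-in
classifier's accuracy.

One consequence worth noting: with jitter 0 the generated rows take only
two distinct values, so null scores live on a coarse lattice of
match-counts and the attainable p-values are discrete. Calibration checks
accordingly assert the one-sided (conservative) bound — the fraction of
null windows with $p < t$ stays below $t + 0.02$ but can undershoot $t$
substantially. Real classifier output is continuous and does not show this
atomization.

## The reference classifier

The residue-type classifier that motivated this package is a trained
neural network and is out of scope; seqregister instead defines the
profile contract and ships a transparent geometric baseline
(`classify_residue()`):

* Features: mean interpolated density over deterministic Fibonacci-sphere
  sample points in radial shells around the side-chain anchor (CB, or an
  ideal pseudo-CB built from N/CA/C for glycine), minus the mean density
  at the residue's backbone atoms. Default shells span 0–6.5 Å with edges
  at 1.5/2.5/3.5/4.5/5.5/6.5; the outermost shell exists because the
  terminal heavy atoms of arginine, tryptophan and tyrosine (5.8–6.1 Å
  from CB) carry most of the large-residue signal. Sample points within
  3 Å of another chain are masked to avoid packing contamination.
* Templates: for each type, the expected shell-*mean density* — ideal
  side-chain atom distances from CB smeared by a Gaussian of width
  `blur_sigma` (default 1.0 Å, roughly a 2.4 Å-resolution blur) and
  averaged over the shell volume, plus a common backbone term. Raw atom
  counts would anti-correlate with the features because shell volume grows
  as $r^2$.
* Scoring: per-type least-squares fit of the template with a free scale
  (clamped non-negative) and intercept; the intercept absorbs the local
  baseline level, which sigma-scaling and baseline subtraction make
  arbitrary. Probabilities are a tempered softmax of negative residuals,
  floored and renormalized.

On maps simulated from synthetic 50-residue models with unit-weight
Gaussian atoms (`simulate_map()`), the baseline places the true type in
the top 5 for roughly 70–90% of residues with at least four side-chain
heavy atoms. That is far below a trained classifier and is intended as a
working reference implementation of the contract, not a competitive
classifier; `extract_profile()` accepts any replacement, and precomputed
profile tables can be supplied instead of a map.

## Numerical and design choices

* Grid step 0.01 nats for the null lattice; convolution tails below
  1e-12 are trimmed per step. Total mass stays within 1e-9 of 1.
* Probability floor 1e-4 on profile rows before logs.
* Map synthesis from MTZ coefficients uses grid spacing of at most
  $d_{\min}/3$ and sigma-scales the map (zero mean, unit variance over the
  cell); the Fourier convention was cross-checked against an independent
  crystallographic FFT implementation during development. Only P1
  periodic interpolation of the unit-cell map is supported — no symmetry
  expansion, anisotropic scaling or free-set handling.
* Coordinates are handled in orthogonal angstroms; fractionalization uses
  the standard orthogonalization matrix. Alternate conformations keep
  altloc 'A' or blank. Author numbering is used in all reports.
* Chain-to-sequence assignment aligns the longest continuous segment,
  truncated to 100 residues — the assignment p-value saturates long before
  that, and the cap keeps the exact convolution cheap.
* Window step 1 for maximal boundary resolution; scan cost is quadratic in
  chain length but small at protein scale (about 0.1 s for a 300-residue
  chain).
* Ties in the best alignment break by sequence order, then lowest offset;
  opposite-sign shifts in adjacent runs are reported as separate regions.
* Study sizes used by the shipped checks: 200 replicates for boundary
  accuracy, 20,000 null windows for calibration, 10^5 Monte-Carlo draws
  for the oracle comparison in the acceptance script (2 x 10^4 in the unit
  tests), 1,000 shift-free chains for the false-positive rate.

## Known limitations

* Gapless alignment only: insertions/deletions are inferred from shifted
  flanking registers, not modelled explicitly; a short indel inside one
  window can only lower that window's confidence.
* The offset-independence correction is approximate for overlapping
  offsets (conservative in practice).
* The indexing-versus-register distinction relies on identity matching at
  the detected offset; for very short regions in low-complexity sequence
  the two categories can be genuinely ambiguous.
* The baseline classifier ignores B-factors, occupancies, element weights
  and rotamer directionality; it is a stand-in for a real classifier.
* Maps are treated in P1; models crossing symmetry contacts get no
  symmetry-mate masking beyond the other chains present in the file.
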