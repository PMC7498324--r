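---
title: "Methods: tail calling, composition statistics and anisotropy binding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tail calling, composition statistics and anisotropy binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racetails)
```

# Scope

`racetails` implements two independent quantitative analyses used to
characterise template-independent terminal ribonucleotidyltransferases
(TENTs) such as the fungal C/U-tailing enzyme CutA:

1. **Tail profiling from 3'-RACE-seq reads.** Amplicon reads of the form
   *substrate prefix + substrate-encoded terminal run + added tail + 3'
   adapter* are filtered, the added tail is extracted, and tail length and
   per-position nucleotide composition are summarised.
2. **Binding affinity from fluorescence anisotropy.** A one-site saturation
   fit yields the dissociation constant Kd of a fluorescent nucleotide
   probe; a global competition fit yields the IC50 of unlabeled NTPs
   displacing that probe.

Because raw sequencing reads and raw titrations for this kind of study are
frequently not deposited, the package carries a first-class synthetic-data
module that generates both inputs with known ground truth, so every stage of
the pipeline is testable at desk scale.

# Tail calling

## Procedure and assumptions

A read is accepted only if it

* begins with an **entirely correct** copy of the substrate prefix (exact
  matching, zero mismatches, zero indels) — otherwise it is rejected as
  `PREFIX_MISSING`;
* contains an **entirely correct** copy of the full 3' adapter downstream of
  the prefix — otherwise `ADAPTER_MISSING`. The leftmost occurrence is used,
  a deterministic tie-break for pathological reads; bases after the adapter
  (read-through) are ignored;
* has an insert (the stretch between prefix end and adapter start) of at
  most `max_insert = 100` nt — longer inserts are artefacts of mispriming or
  concatamers and are rejected as `INSERT_TOO_LONG`.

Exact matching is a deliberate assumption: the selection criteria being
re-implemented demand fully correct flanking sequences, so no mismatch or
quality-based tolerance is applied (and base qualities are ignored
throughout). The cost is a conservative pass rate — any sequencing error in
the 22-nt prefix or 21-nt adapter discards the read — which is acceptable
because composition statistics are computed on the surviving reads only and
the error process is not base-specific to first order.

## Attributing substrate-encoded nucleotides

The substrate ends in a known homopolymer (e.g. four adenosines for an
ss22-A4-type oligo). Up to `terminal_count` leading copies of the terminal
base are trimmed from the **substrate-proximal (5') side** of the insert;
the remainder is the added tail. Anchoring the trim at the substrate side is
equivalent to the reversal construction (reverse the insert so the ultimate
3' end comes first, then right-trim), and it makes the attribution exact for
synthetic reads: when the enzyme itself adds the terminal base, those added
copies extend the leading run, the trim is capped at `terminal_count`, and
the added bases are retained as tail. Reads whose leading run is shorter
than `terminal_count` (a partially degraded substrate) are retained and
counted in a QC field rather than rejected, since "up to N" is the stated
semantics.

An optional low-complexity ("junk") rule can relabel prefixless reads whose
pre-adapter stretch is very short. It is **off by default**: its published
definition is ambiguous, and untailed products — insert exactly equal to the
substrate run — are legitimate reaction products that must never be
discarded. With exact prefix matching the rule only changes the rejection
label, never the accept/reject decision, so the default is safe.

# Composition statistics

Positions along the tail are indexed from the 3' terminus (position 1 = last
added nucleotide), because terminal-transferase preferences are expressed at
the growing end. For position *p*:

* **coverage(p)** = fraction of tailed reads whose tail length is ≥ *p*;
* the frequency of base *b* at *p* is computed over exactly those reads.

Two display rules with defaults taken from the conventions of the assay:
positions are reported only while coverage ≥ `min_coverage` (default 5%),
and at most `max_positions` (default 25) positions are shown. Both are
display filters only — coverage is recorded for every position and the
overall base frequencies pool **all** tail nucleotides, so conservation
holds: the per-position counts sum to the total number of added nucleotides.

Denominators: rejected reads are excluded everywhere; the tailed fraction is
tailed / (tailed + untailed). Length mean and median are reported both with
and without untailed (length-0) reads because published summaries do not
always state the convention; the default includes them. All user-facing
composition output uses the RNA alphabet (U, not T); sequences are handled
in DNA alphabet internally.

# The synthetic-data generator

## What it emulates

The generator reproduces the structural features of a 3'-RACE-seq library
made from an in-vitro tailing reaction:

* clean reads: `prefix + terminal_base × terminal_count + tail + adapter`,
  with constant qualities (the pipeline ignores them);
* four contaminant classes keyed to the caller's filters (`no_prefix`,
  `no_adapter`, `long_insert`, `junk`), allocated in **exact counts**
  `round(fraction × n_reads)` so that rejection counts can be asserted
  exactly;
* a tail model: a length distribution plus per-position base distributions
  with an override at fixed distances from the 3' end.

`default_tail_model()` encodes what a wild-type C/U-tailing TENT does when
offered an equimolar NTP mix, as a scientist would summarise it: tails of
0–7 nt (30% untailed, mean ≈ 2 nt), overall composition ≈ 49% C / 41% A /
9% U / 0.8% G (C dominant in the 40–50% band, G below 1%, U a minor
fraction), and a strengthened cytidine preference at the last (60% C) and
penultimate (50% C) positions. These defaults are fixed model constants,
not tuning knobs. The default substrate prefix and adapter are documented
**placeholders** of the correct lengths (22 and 21 nt) — supplying the true
oligonucleotide sequences is mandatory when analysing real libraries; no
real sequence is invented here.

`expected_composition()` computes, by exact summation over the finite
length support, the per-position and overall frequencies the empirical
statistics estimate — the analytic oracle used in testing. Positions no
tail can reach are reported as `NA` (undefined), never as zero.

## What it does not emulate

No per-base sequencing-error model (errors would only convert clean reads
into rejects under exact matching, shrinking *n* without biasing the
composition of survivors), no PCR amplification bias across tail lengths,
no quality-score structure, no paired-end artefacts. Passing tests on
synthetic data therefore demonstrate the correctness of the *calling and
accounting logic*, not robustness to instrument-specific error modes.

# Binding fits

## Models

Saturation (one-site specific binding, probe depletion ignored):
$$A([P]) = A_\mathrm{free} + (A_\mathrm{max} - A_\mathrm{free})
  \frac{[P]}{K_d + [P]}$$

Competition (displacement of the probe by unlabeled NTP):
$$A([\mathrm{NTP}]) = A_\mathrm{free} +
  \frac{A_\mathrm{bound} - A_\mathrm{free}}{1 + [\mathrm{NTP}]/IC_{50}}$$

The simple hyperbolic saturation form is used deliberately even though the
probe concentration (50 nM) is not negligible against Kd (~250 nM); a
depletion-aware quadratic model is an explicit non-goal, keeping the
estimate comparable with the standard one-site analysis the assay uses.
No Cheng–Prusoff conversion of IC50 to Ki is performed.

## Fitting scheme and numerical choices

Both fits are unweighted nonlinear least squares (no weighting scheme is
assumed for the raw anisotropies), solved by Levenberg–Marquardt with
analytic Jacobians. Kd and IC50 are parameterised as log10 values — this
enforces positivity and conditions the problem across the five decades a
competition titration spans — and reported on the linear nM scale.

The **global competition fit** shares one log10(IC50) across all
experiments while each experiment keeps its own (A_free, A_bound) pair,
reflecting plate-to-plate plateau variation with a common displacement
midpoint. To avoid local minima, fits are multi-started over a log-spaced
grid of the midpoint parameter spanning one decade beyond the concentration
range on each side (9 starts; 7 for saturation); the lowest-RSS solution
wins.

Uncertainty is asymptotic: covariance `s²(JᵀJ)⁻¹` at the optimum, standard
errors transported to the nM scale by the delta method, and pointwise
delta-method confidence bands (default 95%, normal quantile) for the fitted
curve. A singular `JᵀJ` (flat data) falls back to a pseudo-inverse and the
fit is flagged rather than erroring. The fit is marked non-identifiable
when the midpoint lands within 5% (log scale) of the search bounds, when
the IC50 confidence interval spans more than two orders of magnitude, or
when the covariance is singular. Degenerate saturation data (no anisotropy
change) are reported with `converged = FALSE` and `degenerate = TRUE`.

Whether published "±" values of this kind are asymptotic standard errors or
some other interval is rarely stated; asymptotic SEs are assumed, as that
is the default of the common fitting software.

# Problem sizes and verification

The test suite verifies, among others: exact round-trip of every clean
read's tail on 10,000 simulated reads with 10% contaminants; agreement of
empirical composition with the analytic oracle within 4 multinomial
standard errors at n = 50,000 tails for three models (and agreement of the
analytic oracle with exhaustive enumeration to 1e-12); the 4%/5% coverage
boundary; noiseless parameter recovery to relative error < 1e-6 for both
fits (and agreement with an independent variable-projection fit to 1e-8);
and a 200-replicate Monte-Carlo calibration of the global competition fit
(noise SD 0.002, 12 log-spaced concentrations, 3 experiments) checking
median relative IC50 error < 5% and 95%-CI coverage within [90%, 99%].
These sizes were chosen as the smallest that make the statistical
assertions sharp.

# Known limitations

* Exact-match filtering cannot be relaxed per-read; a mismatch-tolerant
  mode would require revisiting the exactness guarantees of the round-trip
  contract.
* The contaminant taxonomy covers the classes the filters can detect;
  chimeric reads that still satisfy prefix+adapter with a short insert are
  indistinguishable from genuine products by construction.
* Asymptotic confidence intervals can undercover at very low replicate
  counts; the bootstrap is the recommended alternative when a titration has
  fewer than ~10 distinct concentrations per experiment.
* The anisotropy simulator draws i.i.d. Gaussian noise; correlated
  within-plate effects are not modelled.
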