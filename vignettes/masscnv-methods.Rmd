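---
title: "Dosage model and design notes for masscnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage model and design notes for masscnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masscnv)
```

## The dosage model

A multiplex iPLEX dosage assay interrogates each exon with one or more PCR
fragments. Each fragment is co-amplified with a competitor oligo that differs
from the genomic template by a single base, is input at two copies, and uses
the same primers. Peak intensities of the extension products are therefore
related by

$$
r(f) \;=\; \frac{I_\mathrm{temp}(f)}{I_\mathrm{comp}(f)}
\;\approx\; \frac{d_T(f)}{2},
$$

where $d_T$ is the template copy number: whatever multiplicative efficiency a
fragment suffers (primer quality, multiplexing interference, spot-to-spot
variation) applies to both numerator and denominator and cancels. A second
calibration removes sample-level effects by dividing by the mean raw ratio of
assumed-diploid reference fragments (*ALB*, *EIF2C1*, *RNaseP*) in the same
multiplex well:

$$
\mathrm{TR}(f) = \frac{r(f)}{\tfrac1k \sum_{i=1}^{k} r(R_i)}.
$$

Under the model's assumptions — diploid references, competitor input of
exactly two copies, no allele-specific amplification failure — TR equals
copy number / 2 exactly in the noise-free limit, which the test suite asserts
(`TR = 0.5 / 1.0 / 1.5 / 2.0` for 1/2/3/4 copies, `0` for homozygous loss).

Two aspects of the reference aggregation are genuinely open choices:

* **Aggregate type.** The arithmetic mean is the default; median and
  geometric mean are selectable (`norm = "median" | "geomean"`). The mean
  matches how dosage quotients are usually formed in iPLEX CNV assays; the
  median is more robust when a reference fragment misbehaves; the geometric
  mean is natural on ratio-scale data. The choice is exposed rather than
  hidden because no single form is canonical.
* **Normalisation scope.** References are aggregated within the multiplex
  well by default, because co-amplified fragments share well-level effects.
  A pooled mode (`pooled_normalization`) exists for panels that cannot place
  references in every well.

A ratio-of-ratios TR was chosen over an allele-fraction form
$I_\mathrm{temp}/(I_\mathrm{temp}+I_\mathrm{comp})$ because it makes
TR $= c/2$ exact rather than approximate; the allele-fraction variant would
compress the scale nonlinearly and move the natural cutoffs.

## Cutoffs and calibration

The shipped defaults call deletion at $\mathrm{TR} \le 0.65$ and duplication
at $\mathrm{TR} \ge 1.30$, boundaries inclusive. `calibrate_cutoffs()` is
opt-in and places cutoffs at $\bar x \pm k\,s$ of diploid-control TR values
(default $k = 5$; with a diploid TR spread of roughly 0.07 this lands near
the shipped 0.65/1.30). When CNV-positive standards are supplied, a cutoff
that fails to separate the label sets is replaced by the midpoint between
the controls' extreme 0.1%/99.9% quantile and the nearest standard, provided
that midpoint does separate them; calibration refuses (with the offending
values listed) rather than return cutoffs that misclassify any supplied
sample. At least 20 negative controls are required — below that, $s$ is too
unstable to anchor a $\pm 5s$ band.

A TR of exactly zero (template peak absent with a healthy competitor peak)
is treated as a valid homozygous-deletion observation, not an error; only
negative or non-finite TR values are rejected. QC is deliberately minimal by
default: `min_intensity = 0` accepts any positive peak, because no universal
intensity floor exists across instruments; the knob and the `low_intensity`
flag are there for labs that have one. A zero competitor peak is always a
`missing_peak` no-call, and a well whose references all fail QC no-calls its
targets (`no_reference`) rather than borrowing references from another well.

## Event merging

Per-fragment calls are merged into events as maximal runs of equal,
non-normal calls along the gene's fragment order. Three conservative rules:
gene boundaries always split; adjacent deletion and duplication runs stay
separate events; and a `no_call` fragment splits a run rather than being
imputed — the gap is visible in the per-fragment table. Single-fragment
events are reported by default (`min_fragments = 1`): whether a pipeline
should require two concordant fragments is a lab policy, so it is a flag,
not a hard-coded rule. Exon labels are opaque strings with an explicit
`order_index`, because a large exon may be subdivided into several fragments
("ex11_part3") and exon number alone cannot order them; a run covering a
strict subset of a subdivided exon is labelled "part of exon 11 deletion".

## What the simulator emulates — and what it does not

`simulate_intensities()` draws, per sample × fragment,

* a shared lognormal efficiency $a \sim \mathrm{LogNormal}(0,
  \sigma_\mathrm{eff}^2)$ applied to template and competitor alike
  ($\sigma_\mathrm{eff} = 0.3$ by default — large, precisely because the
  competitor design should cancel it);
* independent multiplicative measurement noise $e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma_\mathrm{noise}^2)$, on each peak. Noise is
  multiplicative because peak heights are positive, ratio-scale quantities.
  The default $\sigma_\mathrm{noise} = 0.05$ puts the diploid TR standard
  deviation near $\sqrt{2}\,\sigma_\mathrm{noise} \approx 0.07$, so the
  deletion cutoff at $1 - 0.35$ sits about five diploid SDs out;
* an optional allele-dropout artifact: the template dosage of an affected
  fragment is reduced by `dropout_fraction` of one allele while the
  competitor is untouched, exactly the geometry of an SNV under a primer
  binding site. Full dropout on a diploid fragment is indistinguishable from
  a heterozygous deletion *by construction*, so the evaluator must count
  these samples as false positives — that asymmetry, not any tuning, is what
  produces the cohort's specificity structure;
* optionally, zeroed competitor peaks at `missing_peak_prob`.

`make_study_fixture()` instantiates a 293-sample cohort: 8 true carriers
(two BRCA1 exon 1-2 deletions, one exon 1 deletion, one exon 1-2 duplication,
one exon 5-10 deletion, one BRCA2 exon 17-18 deletion, two part-of-exon-11
deletions), 4 artifact samples, 281 diploids, on a four-well panel with all
three reference genes in every well (the real well assignment of references
is not fixed by the assay description; placing all three everywhere is the
configurable default).

The simulator does **not** emulate raw spectra, adduct or salt peaks,
extension-efficiency chemistry, inter-well correlation (wells are
independent), degraded-DNA behaviour, or tumor-content mosaicism. Passing
tests on simulated data therefore demonstrate the correctness of the
*algorithmic* pipeline under the stated noise model, not instrument-level
robustness: on real spectra the diploid TR spread, and hence the effective
number of SDs to the cutoffs, must be established from controls. Note also
that with lognormal noise the duplication cutoff at 1.30 is closer to the
diploid cloud in log space than the deletion cutoff at 0.65, so
false-positive duplication fragments dominate the simulator's residual error
at default noise — one more reason real deployments calibrate on controls.

## Breakpoint characterisation

HGVS g. coordinates are parsed as 1-based inclusive; BED inputs are 0-based
half-open; the conversion lives in one place. Junction homology is defined
operationally as breakpoint ambiguity: the number of alternative (start,
end) placements of the same-size deletion producing an identical mutant
sequence, minus one. This equals the forward match length between the
sequence inside the proximal breakpoint and past the distal one, plus the
mirrored backward match — an identity the tests verify against a brute-force
enumeration oracle on a thousand random deletions. Tandem duplications have
the same junction ambiguity, so the identical computation serves both kinds.

Mechanism classes follow field convention: extended junction identity is the
NAHR signature, blunt or few-bp junctions indicate NHEJ, and intermediate
microhomology MMEJ. The thresholds (`nahr_min = 30`, `nhej_max = 3` bp) are
defaults, not published criteria — Alu-mediated junctions typically show
tens of bp of identity and end-joining a few — and both are exposed. Repeat
annotations provide a second line of NAHR evidence: both breakpoints inside
repeats of the same family (AluSx/AluSz both count as Alu). When the two
lines conflict — same-family repeats but an end-joining-sized junction of
≤ `nhej_max` bp — the call is `ambiguous` rather than letting either rule
win silently. For fixed repeat evidence the classification is monotone in
homology. When several repeats contain a breakpoint (a 1-bp position), every
containing interval "overlaps" it equally, so the tie-break is the longest
interval, then file order.

Primer screening folds allele frequency to MAF = min(AF, 1 − AF) and flags a
primer when any overlapping variant exceeds `maf_max = 0.005`; the
comparison is strict, so a variant at exactly 0.5% is tolerated.

## Display rounding and degenerate inputs

Percentages are displayed rounded half-up to one decimal (281/285 → 98.6;
banker's rounding would differ on exact halves like 0.25%); full precision
is retained in the `value` column. A metric with a zero denominator is `NA`
("undefined"), never 0. Empty event lists are valid and write header-only
tables; an empty sample set is a confusion-matrix error, not a silent zero.

## Problem sizes used by the shipped tests

The test suite and the reproduction script run the full 293-sample cohort
(66 fragments per sample) once in the deterministic limit and twenty times
under default noise, 200-sample batches for the noise-model checks, and
1000 random deletions for the homology oracle — sizes chosen to make the
Monte-Carlo assertions stable at fixed seeds while keeping a full run in the
order of half a minute.

## Known limitations

* The assay is semi-quantitative: it resolves 1/2/3 copies in high-quality
  germline DNA but is unsuited to low tumor purity or mosaic states, and the
  package deliberately offers no tumor-fraction model.
* Specificity is structurally limited by primer-site SNVs; orthogonal
  confirmation of positives is assumed, and `screen_primers()` only reduces,
  never eliminates, the risk (population frequency databases are
  ethnicity-dependent).
* `calibrate_cutoffs()` assumes unimodal, roughly symmetric diploid control
  TR; heavy contamination or batch effects violate that silently.
* Real TYPER exports are instrument-specific; the long-format TSV is the
  package's interchange format and an adapter is expected upstream.
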