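---
title: "Methods: mass modelling, annotation and statistics for brain glycomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass modelling, annotation and statistics for brain glycomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycobrain)
```

## The problem

MALDI-TOF glycomics of permethylated glycans reduces a tissue's protein
glycome to a centroided peak list: one singly charged sodiated ion
(`[M+Na]+`) per glycan mass, with relative quantification by peak intensity.
Turning such peak lists into biology requires a chain of small, exactly
specifiable steps — theoretical mass calculation, peak annotation,
relative-abundance normalisation, structural classification, enzymatic
corroboration, MS/MS isomer resolution, and group statistics. `glycobrain`
implements that chain for the brain protein glycome, where the N-glycan
repertoire is dominated by high-mannose and fucosylated/bisected structures
and the O-glycome by sialylated O-GalNAc and O-mannose cores.

## Mass model

Every mass is derived from five in-chain permethylated residue units (Hex,
HexNAc, dHex, NeuAc, NeuGc) plus a terminal adjustment and the sodium
adduct:

$$m/z = \sum_r n_r \, m_r + A_{\text{end}} + m_{\text{Na}}$$

The residue masses are computed at load time from atomic monoisotopic
masses (C 12, H 1.007825, N 14.003074, O 15.994915, Na 22.989770) through
molecular formulas, never copied from tables; the electron mass is ignored
as it is orders of magnitude below the matching tolerance. The bookkeeping
is exactly additive because a standalone permethylated monosaccharide
equals its residue unit plus C2H6O and each glycosidic bond costs C2H6O, so
branching topology never moves a composition mass. Terminal adjustments:
free reducing end (PNGase F release) +46.0419 Da; alditol (reductive
beta-elimination) +62.0732 Da; Endo H products reuse the free-reducing
adjustment because the retained distal core GlcNAc becomes the new reducing
end.

Printed peak labels in the figures this package reproduces follow a dual
convention which `mz_label()` mirrors: N-glycan labels truncate the
fractional part (1579.78 is printed 1579) while alditol labels round to the
nearest integer (1256.64 is printed 1257). Labels are display-only; all
matching uses exact masses. A handful of literature labels do not fit
either convention (e.g. 1836 for a glycan at 1835.93), which is why the
package never matches on labels.

## Nomenclature and classification

`parse_short_name()` reads the compact field nomenclature: `Man-k` for the
high-mannose/paucimannose series and `[Fx][Ay][Gz][Sw][B][Hn]` otherwise
(F fucose, A antennae, G galactose, S sialic acid with an optional `Gc`
suffix for NeuGc, B bisecting GlcNAc, H hybrid mannose count); O-glycans
use a core prefix (`C1`, `C2`, `M1`, `M2`) followed by F/G/S tokens. The
name does not encode fucose placement, so the parser defaults the first
fucose to the core position; library entries may override this (the
fixture library does so for F1A1G1BH4, whose antenna placement is forced by
the digestion evidence discussed below).

Classification assigns exactly one mutually exclusive main class —
paucimannose (HexNAc2, Hex 1–4, optional core fucose), high-mannose
(HexNAc2, Hex 5–9, no fucose or sialic acid), or an antennarity class
counting GlcNAc-initiated antennae with the bisecting GlcNAc excluded —
plus independent cross-cutting flags (hybrid, bisected, galactose, fucose,
NeuAc, NeuGc). Hybrids are absorbed into the antennary classes and flagged
cross-cuttingly; with that convention the published per-region class totals
sum to ~100%, which is the arithmetic that fixed the rule table. The hybrid
boundary (H-number ≥ 4 by default) is exposed as `hybrid_min_mannose`
because the cutoff between a trimmed hybrid and a complex structure is a
convention, not a fact of the spectrum.

## The fixture library

`builtin_glycan_library()` covers every glycan named in the figures and
tables the package reproduces, plus enough structures to populate all
categories: 29 N-glycan masses and 15 O-glycan masses. Entries are keyed by
exact mass; isomers share an entry, with the first structure acting as the
representative assignment. Candidate structures containing the alpha-Gal
epitope are excluded, matching the absence of its synthetic enzyme in
brain. Two O-glycan masses (1345 and 1070 under the rounding convention)
are flagged `ambiguous_subtype` because their compositions fit both an
O-GalNAc and an O-Man structure; they count toward modification categories
but to neither subtype.

## Annotation and profiles

A peak is annotated when its S/N is at least 6 (the acquisition-software
threshold the study design assumes; `estimate_snr()` provides a
MAD-of-neighbours fallback when a file carries no S/N column) and its m/z
lies within ±0.5 Da of a library mass. The tolerance default reflects the
integer-label regime of externally calibrated TOF data, where residual
calibration error of a few tenths of a Da is expected; it is a parameter,
not a constant. Among several library masses in tolerance the nearest wins,
with exact ties broken to the lower mass; among several peaks in tolerance
of one mass the most intense wins, so a noise spike cannot displace the
analyte peak. Only the monoisotopic peak is used — no isotope-envelope
summation — mirroring the acquisition convention and its stated caveat that
large glycans are slightly underestimated.

Relative abundance is peak intensity over summed annotated intensity, in
percent. Category profiles sum the abundances of all masses carrying a
category; the default `"representative"` policy gives each mass's full
abundance to its primary structure's categories (an optional
`"fractional"` policy splits equally across isomers). For O-glycans,
within-subtype tables renormalise core 1 vs core 2 (and M1 vs M2) to 100%
over the unambiguous masses of each subtype.

## Endo H differential digestion

Endo H cleaves between the two core GlcNAc residues of high-mannose and
hybrid N-glycans only. The released product is the parent minus one HexNAc
and minus its core fucose (which stays on the peptide), so products of a
core-fucosylated parent and its unfucosylated counterpart coincide — the
placeholder case in the digestion figure, reproduced exactly by
`endoh_product_table()`.

`infer_sensitivity()` reads the three-spectrum experiment: PNGase F release
before Endo H (`pre`), the Endo H release itself (`endoh`), and PNGase F
after Endo H (`post`). Because separate spots are not on a common intensity
scale, `post` is rescaled so that a designated Endo H *insensitive*
reference glycan (default FA1B, selected by short name) matches `pre`. The
removal fraction `r = 1 − post/pre` is clamped to [0, 1] and thresholded:
`r ≥ 0.9` sensitive, `r ≤ 0.1` insensitive, otherwise mixed. The middle
band exists because one brain mass (2040) is a genuine hybrid/complex
mixture and is only partially removed; the 0.9/0.1 cutoffs are a repository
decision — the source experiment treated removal versus persistence
qualitatively — and are configurable. The `post` spectrum is annotated
without the S/N cutoff: which parents are assessed is decided by `pre`, and
a weak surviving peak must not masquerade as complete removal. Product
masses detected in the `endoh` spectrum are reported as corroboration, not
used in the call.

## MS/MS fragment enumeration

Structures expand to a canonical residue tree (deterministic antenna
placement; linkage positions never affect permethylated fragment masses).
`enumerate_fragments()` cuts every combination of up to three glycosidic
bonds and prices each connected piece by atom bookkeeping: a non-reducing
(B-type) piece is its residue sum +CH2 +Na, a reducing (Y-type) piece is
its residue sum plus the terminal adjustment −CH2 per severed child (each
cut leaves one demethylated hydroxyl scar), +Na. This convention satisfies
the complementarity identity `m/z(B) + m/z(Y) = m/z(parent) + m(Na)`
exactly for every single-cleavage pair — asserted to 1e-6 Da in the tests —
and reproduces the standard sodiated oxonium masses of permethylated
glycans (e.g. HexNAc B1 at 282.13). C and Z companions (±H2O) are available
behind a flag; cross-ring A/X ions are out of scope. Candidate isomers at a
shared parent mass are ranked by matched *diagnostic* fragments (fragments
unique to one candidate within the isomer set); two candidates each
matching diagnostic evidence yield a "co-present" verdict, which is how the
2040 mixture is confirmed.

## Statistics

Regional comparisons use single-factor ANOVA (equal-variance decomposition
via `stats::oneway.test`), sex comparisons use Welch's unequal-variance
two-tailed t-test (`stats::t.test`), and the fucose-sialic relationship
uses ordinary least squares (`stats::lm`). `anova_from_summary()`
recomputes F from per-group means, SDs/SEMs and n — the algebraic identity
that lets published mean ± SEM tables be checked without raw data; it
matches the raw-data ANOVA exactly, for equal and unequal n. Significance
stars follow the 0.05/0.01/0.001 convention and no multiple-testing
correction is applied by default (a Benjamini–Hochberg option exists),
mirroring per-category ANOVA practice. Group sizes of 2 are permitted with
a warning, because one published O-glycan group has n = 2.

Recomputing the paucimannose ANOVA from the published summary statistics
(means 3.1/2.6/2.6/1.2, SEMs 0.2/0.3/0.3/0.1, n = 6) gives F ≈ 11.6 against
a printed 13.23; the gap is expected from one-decimal rounding of the
summary statistics and stays well within ±30%.

## The synthetic-spectrum generator

The generator exists so that every stage is testable without instrument
data; its defaults are the study conditions, not tuning knobs.

* **Truth templates.** Per-mass abundances underlying the published
  category tables are not in the main text, so the templates allocate the
  printed per-category totals onto the fixture library. The allocation was
  derived once, by hand, so that the mutually exclusive N classes match the
  printed values exactly and every cross-cutting category (hybrid,
  bisected, galactose, fucose, NeuAc/NeuGc, O-glycan subtypes and cores)
  lands within one percentage point; Man-5 carries ~45% of total N-glycan
  signal, matching its description as nearly half. Templates:
  `cortexN`, `cerebellumN`, `plasmaN` (complex, NeuGc-dominated), and
  `cortexO`.
* **Noise model.** Intensities receive multiplicative log-normal noise
  (log-SD 0.15), m/z a uniform ±0.2 Da calibration error, and
  Poisson-placed noise peaks (0.05/Da) whose intensities sit below S/N 3.
  Injected S/N divides intensity by the robust noise floor of the
  noise-peak distribution (1.4826 × MAD), the same quantity
  `estimate_snr()` estimates — which is what makes "estimates within a
  factor of two of truth" a meaningful check rather than a definitional
  accident. These are plausible reflectron-TOF figures chosen once; real
  replicate variance structure is not published at per-mass resolution, so
  they are stated, not fitted.
* **Recovery scoring.** Each simulated spectrum records its *realized*
  composition (after intensity noise, before jitter, thresholding and
  noise peaks). Pipeline recovery is scored per sample against that
  realized truth: deviations then measure annotation errors (jitter,
  threshold losses, noise misassignment) rather than the sampling noise of
  a finite cohort, which is the statistics layer's business, not the
  annotation layer's. In the noise-free limit realized truth equals the
  template and recovery is exact to numerical precision.
* **Endo H triplets** route the sensitive fraction of each mass into the
  Endo H product spectrum and the resistant fraction into the post-digest
  spectrum; the post digest gets its own spotting-efficiency scale (0.7) so
  that reference rescaling is genuinely exercised. The 2040-type mixture
  keeps a designated resistant fraction (0.5 by default).
* **What passing does not show.** The generator emulates centroided peak
  lists with well-behaved noise; it does not model isotope envelopes,
  matrix adducts, detector saturation, profile-mode baselines, or real
  biological covariance between glycans. Green tests certify the analysis
  chain, not instrument behaviour.

## Problem sizes and numerical choices

The test suite runs cohorts of 4 regions × 6 replicates (~24 spectra of
~20–40 peaks), 2000 null ANOVA draws for type-I calibration, and 200
seeded cohort simulations for the power check of the cerebellum
paucimannose difference (3.1 → 1.2 at table-scale noise), sizes chosen to
make the binomial error of the estimated rates small relative to the
asserted bands. Fragment enumeration is exhaustively cross-checked against
a brute-force edge-cut oracle for all fixture structures up to 12 residues
and up to three simultaneous cleavages. Degenerate inputs are handled by
convention where a convention is needed: zero-variance groups give F = 0,
p = 1; identical groups give a Welch p of 1; a flat spectrum yields no S/N
estimate; annotation ties break to the lower mass with a warning.

## Known limitations

Linkage positions and anomericity are not represented — masses and the
categories above do not need them, but isomers differing only in linkage
are indistinguishable here. Quantification uses the monoisotopic peak only.
Multiply charged ions, in-source decay and cross-ring MS/MS fragments are
out of scope. The per-mass truth templates are calibrated reconstructions
of published category totals, not the deposited per-mass tables; analyses
that depend on the identity of minor masses should treat the templates as
synthetic stand-ins.
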