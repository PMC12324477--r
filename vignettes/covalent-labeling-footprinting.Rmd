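---
title: "Covalent-labeling footprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent-labeling footprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clfootprint)
```

## The measurement model

Carbodiimide/GEE labeling converts solvent-accessible Asp/Glu carboxyl side
chains into a mass-shifted adduct (+85.0522 Da) that partially hydrolyses to
a second product (+57.0209 Da).  After tryptic digestion, extracted-ion
chromatogram (XIC) integration yields one intensity per peptide form.  The
per-residue readout is the modification fraction

$$\%\,\mathrm{modified} \;=\; 100 \cdot
  \frac{I_\mathrm{mod}}{I_\mathrm{mod} + I_\mathrm{unmod}},$$

with both label channels summed into $I_\mathrm{mod}$.  Differential
exposure is $\Delta\% = \overline{\%}_\mathrm{bound} -
\overline{\%}_\mathrm{unbound}$ (means over replicates); negative values
mean protection — interface burial or conformational change on binding.

Three quantification conventions are deliberate choices, fixed here and
pinned by tests:

* **Aggregation order.** Fractions are computed per replicate, then
  averaged.  Ratios within a replicate cancel loading differences, so a
  global scale factor on any replicate leaves every fraction unchanged (a
  tested invariance).
* **Pooling.** When several peptide species cover a site within a replicate,
  their intensities are pooled (sum/sum) before the ratio — XIC-summing —
  rather than averaging per-peptide fractions, which would overweight
  low-abundance species.
* **Ambiguity splitting.** A label whose site MS/MS cannot localize among
  $m$ candidate D/E residues contributes $I/m$ to each candidate.  This
  conserves total modified intensity (tested) but is a biased estimator: a
  site's own signal is kept with weight $(1-q) + q/m$ and it receives $1/m$
  of each ambiguous neighbour's signal in *both* states.  On a planted
  −30-point change with ambiguity probability $q = 0.2$ and $m \in
  \{2,3\}$, this compresses the recovered delta by roughly 3–6 points —
  visible in the worked examples, and the reason very large deltas are
  reported slightly shrunk.  Sites with any ambiguous contribution carry an
  `ambiguous` flag so downstream analyses can treat them cautiously.

Sites with zero total intensity in a condition are *missing*, never imputed
or reported as 0%.  C-terminal carboxyl labeling is ignored: only D/E side
chains are quantified.

## Structural projection

Point measurements become spatial tracks by extending each label's delta
over a window of 11 aa centered on the label (truncated at chain ends) and
averaging the deltas of all windows covering a residue, each label weighted
equally.  A brute-force per-residue enumeration oracle pins this definition
in the tests.  Ambiguous labels are first split into one observation per
candidate site, each carrying the full delta — at the mapping stage
observations are split, not intensity.

For structure rendering, labels observed on paralogs absent from the model
(e.g. a SMARCD2 label when only SMARCD1 is resolved) are remapped onto the
resolved paralog and pooled before windowing.  Position translation defaults
to identity numbering — justified for closely colinear paralogs such as
SMARCD1/2, which share residue numbering at their common sites — with an
optional explicit residue table for non-colinear pairs (positions absent
from the table are dropped with a warning).  Schematic 1-D profiles skip the
remapping so paralog-specific effects stay visible.

B-factor export clamps values to ±30% *at export only* (stored profiles stay
unclipped), writes two decimals, and byte-preserves everything outside
columns 61–66 of ATOM/HETATM records; the fixed-column PDB dialect is the
target because downstream colouring scripts read that column.  PDB has no
missing-value encoding, so residues without a profile value get the sentinel
`0.00` and are listed in a sidecar report — a rendering-neutral value under
a blue-white-red map centered at zero.

## Site calling

Merging of nearby windows replaces a by-eye step with a deterministic rule:
maximal same-signed runs are seeds; same-signed seeds at most `gap` residues
apart merge unless an opposite-signed seed *whose own peak reaches the noise
floor* intervenes; merged sites with peak |value| below `noise` (default 1%)
are discarded.  Two refinements are worth stating:

* `gap` defaults to 20 aa, the upper (most inclusive) end of the 10–20 aa
  range a manual analysis would use; it is exposed as a parameter.
* A sub-noise opposite-signed blip neither merges nor breaks: to the eye it
  is noise, not a separating effect.  With this rule, calling is idempotent
  (re-calling on a track rebuilt from the called intervals returns the same
  intervals) and the site count is non-increasing in both `gap` and `noise`
  — both properties are tested over parameter sweeps.  If sub-noise
  opposite seeds broke merges, idempotence would fail whenever such a blip
  was the only separator between two same-signed sites.

The noise filter applies to the *peak* within a merged site, not its mean,
so a sharp strong signal inside a broad weak site survives.  Overlap between
two bound states requires the same subunit, at least one shared residue and
the same sign (consistent effects); no fractional-overlap threshold is
imposed.  Each site lands in exactly one bin — overlapped, A-exclusive or
B-exclusive — the partition a Venn diagram summarises.  Module summaries
keep sites with $|\Delta| \ge 5\%$ and report (module × direction) counts as
proportions normalised over all cells; the Core/ATPase subunit table ships
as an editable default.

## Contact-probability aggregation for SLiM mapping

A disordered transactivation domain is tiled into all consecutive 10-mers
(142 tiles for a 151-residue region); each tile is co-folded with the
receptor externally, and the package consumes the per-tile peptide×receptor
contact-probability matrices through a documented JSON schema.  Per
prediction, a peptide residue's contact to the pocket (default: the six
SWIFT hydrophobic-cage residues) is scored as $\log_2(\max(\bar p,
\varepsilon))$ with $\varepsilon = 10^{-6}$ keeping zero-contact scores
finite; per full-sequence residue, scores are averaged over all tiles
covering it.

Two readings of "log2 mean probability" exist: $\log_2(\bar p)$ and
$\overline{\log_2 p}$.  The default is $\log_2(\bar p)$ — robust to a single
zero entry and monotone in every probability (tested); `log_mode =
"mean_log2"` selects the alternative.  Similarly the pocket reduction is the
mean by default, with `pocket_stat = "max"` available.  Aggregation is
permutation-invariant in prediction order and exactly matches a brute-force
recomputation in the tests.  Predicted-alignment-error weighting is out of
scope: contact probabilities are used as given.

## The synthetic-data generator

The generator emulates the study design end to end: a miniature two-module
complex (core-like subunits CORE1A — with paralog CORE1B — and CORE2, plus
ATPase-like ATP1; 300/300/250/400 aa, D+E density 15%), trypsin/Lys-C digest
(cleave after K/R except before P, ≤ 2 missed cleavages, peptide length
6–30), triplicate labeling (`n_replicates = 3`), an unbound reference and
two bound states (nominal molar ratios 1:5 and 1:8 recorded as metadata
only), per-site baseline fractions uniform on 1–60%, planted changes of ±30
points, 10% multiplicative lognormal intensity noise, and ambiguity
probability 0.2.

Model structure, and why:

* **Intensities.** Each peptide species draws one lognormal abundance $U$
  (sdlog 0.5) — abundance is a property of the digest, held fixed across
  replicates and conditions — and each observation multiplies it by
  mean-one lognormal noise at the configured CV, the only per-observation
  variation.  The modified species of site $s$ has intensity
  $U f_s/(100-f_s)$, the unique completion of the ratio formula that makes
  noise-free recovery exact at *every* site of a multi-D/E peptide (a tested
  invariant).
* **Ambiguity.** Whether a site's label is ambiguous (candidate set = all
  D/E of the peptide) is drawn once per peptide species × site and held
  fixed across replicates and conditions, because localization ambiguity
  arises from the species' fragmentation behaviour, not from the run.  If it
  were redrawn per observation, candidate sets would flip between
  conditions and manufacture spurious deltas of ~10 points even in a null
  experiment.
* **Planted sites.** Defaults plant three −30-point protections on CORE1A
  (near residues 60/150/240) for one bound state, sharing one site with the
  other bound state plus a +30 gain on ATP1, so overlap classification and
  module summaries are exercised.  Planted positions are restricted to D/E
  sites covered by at least one digest peptide — an uncovered site cannot be
  quantified — and draw their baselines from 35–60%, since a −30-point
  protection is only observable where baseline exposure exceeds 30%.
* **Channels.** The GEE/hydrolyzed split of each modified intensity is a
  uniform draw; only their sum is meaningful downstream.

Everything is byte-deterministic under the config seed (tested by comparing
written TSVs).  What the generator does *not* emulate: retention-time or
charge-state structure, identification error, digestion kinetics,
correlated noise between channels, and real subunit sequences.  Passing
tests therefore validate the arithmetic and the calling logic, not
instrument-level behaviour.

## Problem sizes and numerical choices

The default experiment yields roughly 400 peptide species and 12,000
observation rows across 3 conditions × 3 replicates — small enough that the
full pipeline runs in seconds while exercising every code path (paralogs,
ambiguity, multi-peptide pooling, both bound states).  Oracle comparisons
use tolerance 1e-12 (floating-point reassociation only); fractions at
$f = 100\%$ are avoided by clamping planted truth to 99%.  Window width must
be odd (the center is otherwise undefined); even widths are rejected rather
than rounded.

## Known limitations

* Equal-split ambiguity quantification is biased toward zero for large
  deltas (see above); under the default ambiguity rate the recovered
  magnitude of a −30-point change is typically compressed by 2–6 points,
  occasionally more when an ambiguous high-baseline neighbour dominates a
  site's peptide pool.  The bias vanishes as $q \to 0$ and is flagged per
  site.
* Merged-site extents depend on the windowed track, so two experiments with
  different label coverage are compared via overlap classification, not by
  interval equality.
* The B-factor sentinel `0.00` is indistinguishable from a true zero change
  in the PDB itself; consult the sidecar report when that distinction
  matters.
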