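---
title: "Methods: caries indices, examiner calibration and field-batch synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caries indices, examiner calibration and field-batch synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontosurvey)
```

This vignette documents the scientific and numerical choices behind the
package: the odontogram coding model, the caries indices, the calibration
statistic, the synchronization contract, and what the synthetic generator
does and does not emulate.

## The odontogram model

A mouth is charted as one record per tooth in FDI two-digit notation
(quadrants 1–4 permanent with positions 1–8; quadrants 5–8 deciduous with
positions 1–5). Each record carries a crown-condition code and a
treatment-need code. The two dentitions use distinct crown alphabets —
digits for permanent teeth, letters for deciduous — that map
symbol-for-symbol to the same clinical states; the trauma symbol `T` is
shared. Treatment codes `0`–`9` are common to both dentitions.

Field capture records only findings. `normalize_odontogram()` completes the
examined tooth set with the healthy default (`"0"` permanent / `"A"`
deciduous, treatment `"0"`), so a stored exam never contains null entries;
this mirrors the field convention of entering `0` for wholesome teeth and
makes downstream tallies well-defined. Normalization is idempotent and
always yields exactly one record per tooth of the examined set. Mixed
dentition is supported: each position validates against its own alphabet.
Letter codes parse case-insensitively and canonicalize to upper case.

The default examined set is the full 32-tooth permanent mouth. Third molars
are included because adolescent surveys chart them; restricting to 28 teeth
is a caller-side choice of the `teeth` argument, not a package switch, which
keeps one source of truth for the tooth set per exam.

`validate_exam()` returns a structured report (errors and warnings) rather
than aborting. Treatment `"9"` ("no information") is syntactically valid but
warned about, and an exam dated outside its action's window is a warning,
not an error — field corrections are routine and batches with sporadic
problems must remain partially mergeable.

## Index components and the CPO / ceo indices

Crown codes classify each tooth into at most one component: decayed
(*x*: caries, or restored-but-with-caries), filled (*y*:
restored-without-caries), missing-for-caries (*z*). Independently, treatment
code `"6"` marks a tooth extraction-indicated (*w*). This mapping is the WHO
basic-methods convention; the deliberate consequences are:

- loss *not* attributable to caries (`5`/`F`), sealants, bridges, unerupted
  teeth, trauma and not-considered states contribute to no component;
- *y* covers both fillings and crowns — survey prose sometimes says
  "crowned teeth" for this component, and the package treats the two as one
  state (crown code `3`/`D`);
- the deciduous "not considered" (`L`) is treated as semantically identical
  to the permanent `9`; nothing in the coding table distinguishes them;
- whether treatment codes 1–5 on a *healthy* crown should imply decay is
  genuinely underdetermined; the package uses crown codes alone for
  *x*/*y*/*z*, which keeps the two code tracks orthogonal. The mapping lives
  in one editable table (`caries_component_map()`), so an alternate
  convention is a one-argument change, not a code change.

The per-person indices are `CPO = x + y + z + w` (permanent) and
`ceo = x + y + w` (deciduous). The deciduous index excludes *z* by
definition — an absent primary tooth cannot be attributed to caries rather
than exfoliation — and the package enforces the dentition of the counts it
is given. Note that a decayed tooth also marked for extraction contributes
to both *x* and *w*: the index is the printed sum of the four components,
not a count of affected teeth, so individual values can exceed the tooth
count in principle. The per-person "percentage" `value * 100 / N` is
provided as `index_percent()` because the source survey system printed it,
but its epidemiological meaning is thin; `prevalence()` (fraction of persons
with a positive index) is the conventional companion statistic and is what
reports should quote.

Aggregation (`aggregate_index()`) groups per-exam indices by school,
territory, municipality, sex or age (completed years at exam date). Each
exam lands in exactly one group per key, which yields the decomposition
identity — the overall mean equals the group-size-weighted mean of group
means — exactly, to floating tolerance; the test suite asserts it at 1e-12.

## Examiner calibration

Calibration compares each examiner's per-tooth ratings with the team's
consensus on the same items. Rating units are individual teeth: one rating
per tooth examined, which is the granularity of the odontogram itself.

**Consensus** is the per-item majority; ties break toward the more severe
category under the configured ordering (default: the crown alphabet in its
printed order, a severity proxy). The conservative tie-break suits
screening — when a team splits, the worse finding is retained. A caveat the
test suite documents: with only two raters, every disagreement is a tie, so
the severity tie-break systematically adopts the more severe (often the
noisier) examiner's vote. Consensus calibration needs a team, and the tests
use one (four reliable raters plus one noisy).

**Weighted kappa** is `1 − D_obs/D_exp` with disagreement weights
`|i−j|/(K−1)` (linear, the default), its square (quadratic), or 0/1
(unweighted); `D_obs = Σ w_ij p_ij`, `D_exp = Σ w_ij p_i· p_·j`. Linear is
the default because the calibration protocol names a weighted kappa without
specifying weights, and linear is the weaker (more conservative) correction;
the scheme is an argument everywhere. For K = 2 all three schemes coincide.
A degenerate table with all mass in one cell has `D_exp = 0`; agreement is
then vacuously perfect and the package defines κ = 1 with a warning rather
than returning NaN. Both disagreement sums cover *all* off-diagonal mass —
for the uniform-independence 2×2 table they each equal 0.5 (two cells of
0.25) and κ is exactly 0.

**The gate** passes an examiner at κ ≥ threshold, default 0.65, boundary
inclusive — a *minimum acceptable* limit admits the value itself.

## Field batches and synchronization

Devices capture typed records (`record_uid` assigned at capture, not
content-derived: a corrected record is the *same* record) into a local
batch. Sealing computes an MD5 checksum over the canonical serialization —
recursively key-sorted, minified JSON with ISO dates — and freezes the
batch; the JSON Lines batch file repeats the checksum in a footer so
tampering and truncation are detected on read. Sealing twice is a no-op.

`merge_batch()` files every record into exactly one bucket: inserted,
duplicate (same uid, identical canonical content), conflict (same uid,
different content — resolved last-write-wins by capture timestamp, with an
audit entry either way), or quarantined (failed domain validation). The
resulting laws — idempotent re-merge, order-independence for disjoint
batches, bucket conservation, and a store that never holds an invalid
record — are asserted directly by the test suite. Duplicate student exams
within an action are deliberately *not* conflated: they have distinct
record uids and both are kept, surfacing in reports rather than being
silently dropped.

The at-rest codec hook (`make_codec()`) accepts any reversible
encode/decode pair, verified with probe payloads at registration; the
default is the identity. Key management is out of scope by design.

Anonymized student codes come from a seedable generator with an isolated
RNG stream (issuing codes neither disturbs nor depends on the caller's RNG)
over an unambiguous 32-symbol alphabet; 8 symbols give a code space near
10^12, so collisions are retried and exhaustion is unreachable in practice.

## Territories and reports

Territory assignment prefers an explicit school-to-territory register (the
usual case; the bundled 2017 Palmas register names eight territories) and
falls back to point-in-polygon against GeoJSON boundaries. Interior tests
use `mgcv::in.out`; an explicit on-edge test assigns boundary points to the
first-listed containing territory, making shared borders deterministic.
One territory circulates under two spellings; an alias table canonicalizes
to the register form.

The three report surfaces are pure reads of the store: the three-level
index report (school / territory / municipal, each exam counted once per
level, so the municipal mean is the exam-weighted mean of territory means),
the per-school participation report (questionnaire and exam counts differ
legitimately because they happen on different days; zero-enrollment schools
are flagged, counts above enrollment warn — transfers happen — rather than
error), and the desk summary of store counts.

## Bundled registers

Two discrepancies in the source material were resolved as follows and are
left visible rather than silently fixed:

- The student questionnaire is bundled with **146** items in 12 classes
  (the final class being a single opinion item), following the published
  class table; a requirements summary elsewhere in the source system said
  145. The class table is the operative definition.
- The school register lists **26** schools (totals 16,321 enrolled, 2,014
  in 9th grade — the columns sum exactly to the printed totals); narrative
  text mentions 29 schools. The register is the operative list.
- The principal questionnaire is published only as a total of **84** items,
  so its bundled definition is a single class spanning 1–84.

The register files are checksummed; loaders refuse edited transcriptions.

## The synthetic generator

`simulate_survey()` draws, per tooth, one of (healthy, decayed, filled,
missing) from a multinomial with configurable probabilities; decayed teeth
receive treatment `"6"` with probability `p_extraction_indicated`. Defaults
emulate a municipal adolescent survey: 26 schools, school sizes spanning
the register's 9th-grade range (14–176), territory frequencies matching the
register, ages uniform on 13–19, and per-tooth rates
(p_decayed, p_filled, p_missing) = (0.05, 0.02, 0.01) — low-pathology
adolescent permanent dentition. Every generated exam passes validation, and
a fixed seed reproduces the full output including batch checksums.

Per-tooth independence is chosen deliberately: it makes the expected index
closed-form, `E[CPO] = 32·(p_d + p_f + p_m) + 32·p_d·p_ext`, so parameter
recovery is checkable. The recovery test runs 2,000 exams at the default
rates with `p_extraction_indicated = 0` — isolating the crown-only
expectation 32·0.08 = 2.56 — and requires the sample mean within three
standard errors (±0.10). What the generator does **not** emulate: caries
clustering within mouths and between neighbouring teeth, socioeconomic
gradients, spatial autocorrelation across territories, or realistic
questionnaire response patterns (answers are uniform over codes). Passing
tests therefore demonstrate correctness of the *computations*, not
calibration of the generator to any real population.

## Problem sizes and tolerances

The suite uses 1,000 random odontograms for the index-oracle equivalence
check (exact integer agreement required), 500 mutations for the ceo
z-exclusion law, 2,000 exams for parameter recovery (3-SE band), 10,000
paired ratings for the null-kappa check (|κ| < 0.05), and a few hundred
records for the synchronization laws — sizes at which the stochastic checks
have comfortable margins while the whole suite runs in well under a minute.
Algebraic identities (decomposition, kappa symmetry and scale invariance)
are asserted at 1e-12; exact anchors (register totals, κ = 1 and κ = 0
tables, gate boundary) are asserted exactly.

## Known limitations

- No surface-level (DMFS) index: the data model records one code pair per
  tooth, not per surface.
- No design-weighted variance estimation (complex-survey standard errors);
  exports feed external statistics packages for that.
- Kappa confidence intervals are not computed.
- Polygon territory support handles simple rings only (no holes,
  no multipolygons), which suffices for municipal health territories.
- The store is in-memory with JSON persistence — desk-scale by design, not
  a concurrent multi-user database.
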