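---
title: "Privacy-preserving record linkage with field-level Bloom filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving record linkage with field-level Bloom filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Linking a hospital morbidity collection to a death-registration file asks
which records, within and across the two files, belong to the same person.
When the custodian cannot release clear-text identifiers, linkage must run
on *encoded* data: each party encodes its file with a shared secret key,
and the linkage unit sees only the encodings. The question this package
addresses is operational: can such a privacy-preserving linkage, run
blind — no truth set, parameters chosen from the encoded data alone —
deliver the same person groupings as a conventional clear-text linkage?

`bloomlink` implements the full working apparatus: the custodian-side
encoder, pre-linkage validation, the probabilistic linker, post-linkage
quality assurance, a clear-text comparator, the grouping-comparison
evaluation protocol, and a synthetic data generator with known truth so the
whole system can be exercised and audited without restricted data.

## Encoding model

Identifiers are split into two classes.

**Approximate fields** (given names, surname, address, suburb) are encoded
as *field-level Bloom filters*. A cleaned value is decomposed into its set
of unpadded bigrams; each bigram is hashed $k$ times with HMAC-SHA-256
under the shared key, and the resulting positions are set in a bit vector
of length $\ell$. Defaults: $\ell = 512$, $k = 30$ for name fields, 20 for
address and 25 for suburb — fewer hashes for the longer fields so their
filters do not saturate. The $i$-th index for bigram $g$ of field $f$ is

$$h_i(f, g) = \mathrm{HMAC}_{key}(f \,\|\, g \,\|\, i) \bmod \ell,$$

taking the first 24 bits of the digest (exact modulo for power-of-two
$\ell$). Including the field label makes equal values in different fields
non-comparable, blocking cross-field frequency attacks on shared values.
Distinct bigrams are used (a multiset would set identical bits anyway
under deterministic hashing). Cleaning — lower-case, strip whitespace and
non-alphanumerics, truncate to the first 20 characters — happens before
bigram extraction and must be byte-identical on both sides.

**Exact fields** (sex, date of birth, postcode) are encoded as a single
keyed hash token $\mathrm{HMAC}_{key}(f \,\|\, v)$, with dates normalised
to `yyyymmdd` first so token equality coincides with date equality.

A missing value encodes to the all-zero filter or an absent token; the
encoded record also carries hashed blocking keys (below). Encoding is
fully deterministic given (record, key, configuration).

## Comparison and scoring

Bloom-encoded fields are compared with the Sørensen–Dice coefficient on
set bits,

$$D(a, b) = \frac{2\,|a \wedge b|}{|a| + |b|},$$

which approximates the Dice similarity of the underlying bigram sets:
shared bigrams set identical bits. The approximation is tight near
agreement but *overestimates* for dissimilar strings — with $k = 30$
hashes into 512 bits, two unrelated names share roughly a quarter of their
bits by collision alone, so unrelated pairs score about 0.25 rather than
0. This floor sits far below the decision region and is absorbed by the
partial-agreement floor described next; the package's oracle tests verify
the approximation over name-variant pairs, the population where the
coefficient actually decides matches.

Scoring is classical Fellegi–Sunter. Each field carries an
$m$-probability (chance a true match agrees) and a $u$-probability
(chance a random non-match agrees), giving log-weights
$w^+ = \log_2(m/u) > 0$ and $w^- = \log_2\!\big((1-m)/(1-u)\big) < 0$.
A token field contributes $w^+$ on equality and $w^-$ on inequality. A
Bloom field with similarity $s$ contributes

$$w(s) = \begin{cases}
w^+ & s = 1\\
w^- + \dfrac{s - s_0}{1 - s_0}\,(w^+ - w^-) & s_0 \le s < 1\\
w^- & s < s_0,
\end{cases}$$

a standard linear partial-agreement interpolation with per-field floor
$s_0$ (default 0.7). A missing field contributes exactly 0 — neither
evidence for nor against. The pair score is the sum over fields, and a
pair is accepted when the score reaches the threshold (inclusive; default
20, the operational value for this weight scale).

The default $m/u$ table ships in `default_weights()`. Operational weight
tables are developed per-collection and are deliberately overridable; the
defaults were chosen once so that a pair agreeing on first name, surname,
sex, date of birth and the address triple scores ≈ 44, a pair agreeing
only by block-level chance stays far below 20, and — importantly — a
male–female twin pattern (all but first name and sex agreeing) scores
≈ 28. Twins *should* cross the threshold here: distinguishing them is the
job of post-linkage quality assurance, not of the weights, mirroring
operational practice.

## Blocking

Comparing all pairs is quadratic and unnecessary. Records are partitioned
into blocks by cheap keys and only pairs sharing a key in at least one
pass are compared. Because Bloom filters cannot be blocked on directly,
keys are derived clear-side at the custodian from cleaned field fragments
(e.g. first two letters of surname + year of birth), hash-encoded under
the key, and shipped with the encoded record. Both pipelines (encoded and
clear-text) use the same recipes and the same key derivation, so their
candidate sets are identical by construction — differences in results then
reflect comparison behaviour only, never comparison opportunity.

Default passes: full date of birth; surname[1:2] + year of birth;
given1[1:2] + year of birth + sex. A pass with any missing component emits
no key for that record. Operational blocking strategies are
custodian-specific; the defaults are fully configurable via `block_on()`.

## Pre-linkage validation

The linkage unit never sees clear text, so validation works on structure:
record and field counts, per-field missingness, frequency tables of
encoded values, and Bloom-cardinality histograms. Two checks matter
operationally:

* **Cross-encoding consistency** — identical clear values encode
  identically under one key, so two correctly co-encoded files must share
  tokens on common values (dates of birth, postcodes). Zero overlap on a
  populated field indicates a key or configuration mismatch; empty fields
  are *indeterminate*, not inconsistent.
* **Placeholder screening** — placeholder identifiers ("NO FIXED
  ADDRESS", postcode "9999") are shared by many unrelated people and
  survive encoding as anomalously frequent values. A value is flagged when
  its count exceeds 10× the median of the field's top-20 counts (the
  median of top ranks is a robust estimate of ordinary household-level
  repetition); companion-field values co-occurring with a flagged value in
  ≥ 90% of their occurrences are flagged as associated dummies. Flagged
  values are blanked — records are kept, mirroring operational cleaning.
  Both the multiplier and the association bound are judgement calls the
  operational literature does not formalise; they are parameters, and the
  frequency rule needs the placeholder to dominate ordinary repetition, so
  it is a large-sample instrument (at a few hundred records a genuine
  placeholder is statistically indistinguishable from a large household).

## Grouping and quality assurance

Accepted pairs are closed transitively: person groups are the connected
components of the accepted-pair graph, labelled deterministically by their
lexicographically smallest member so results are independent of pair
order. QA then applies two corrections, the only modifications made:

* **Twin splitting** — a pair agreeing fully on surname, date of birth,
  address, suburb and postcode, with differing sex tokens and given-name
  Dice below 0.8, matches the male–female twin signature (detectable even
  on encoded data). Such pairs are removed and the components recomputed.
* **Multiple-death separation** — a person dies once, so a group holding
  two or more death records is split at its weakest internal pair,
  repeatedly, until no group holds more than one. "Weakest pair" is the
  natural suspect under Fellegi–Sunter scoring; the operational rule is a
  reviewer judgement with no published formula.

Splits only refine the partition; QA never merges. Groups with
low-weighted internal pairs (score in [20, 22)) or more than 10 members
are flagged for review but not modified.

## The clear-text baseline

The comparator linker runs on un-encoded records with the same cleaning,
blocking, weights and threshold, substituting exact bigram-set Dice for
Bloom Dice, plus one *inversion comparison*: each pair is also scored with
first name and surname swapped and the better orientation kept. Production
clear-text engines add many per-block bespoke rules; this baseline
deliberately implements only the shared core plus the name-swap check — it
is a credible comparator, not a clone of any particular engine. Following
the operational evaluation design, the baseline applies no post-linkage
QA (it accepts every automated link), while the encoded pipeline does.

## Evaluation protocol

Evaluation looks at the morbidity-to-mortality linkage only. For each
mortality record, the set of morbidity records in its group is read off
both linkages and compared: `identical`, `pprl_extra` (encoded linkage
found more), `ct_extra` (clear-text found more), or `both_extra` (each
side found records the other missed — tallied on *both* sides, so side
counts can exceed the number of differing records). "Identical" means
equality of the morbidity sets, not of any finer structure. With synthetic
truth, each extra link is classified correct (same true person) or
incorrect, a mortality record counting in both tallies when it has both.
`pairwise_quality()` complements this with pair-level precision, recall
and F-measure against the truth partition.

## The synthetic generator

`synth_config()` defines a population and two extracts with known truth.
What it emulates, and why:

* **Shape** — every person has ≥ 1 morbidity record
  (zero-truncated-geometric count, mean 4 — administrative totals suggest a
  few records per person but publish no distribution) and at most one
  mortality record (default fraction 0.1, a plausible five-year mortality
  for a hospital-using population).
* **Missingness** — per-field, per-dataset rates matching the published
  profile of such extracts: second given name missing in 50.6% / 23.2%
  (morbidity / mortality), third in 99.0% / 93.5%, first given name 1.9% /
  0.1%, surname and sex complete, small mortality-side rates for date of
  birth (0.1%), address (0.3%), suburb (0.5%), postcode (1.3%).
* **Error modes** — the discrepancy causes reported from operational
  review, each at a rate chosen once as plausible: single-character typos
  (2% per name/address field), diminutive first-name forms such as
  ELIZABETH→LIZ (5% of eligible records), UNIT/LOT/FLAT address-keyword
  variants (10%), facility-name address prefixes (2%), swapped first/last
  names (0.5%), male–female twin pairs (0.5% of persons), placeholder
  addresses with paired dummy postcodes (2%).

Generation is deterministic under a fixed seed, and every corruption is
logged per record (`corruption_report()`), so any downstream disagreement
can be traced to its cause. What it does **not** emulate: realistic name
and address frequency distributions (lexicons are small, uniform in-repo
pools, so field $u$-probabilities are somewhat larger than in a real
population), correlated data-entry error, household structure beyond
twins, within-person identifier drift over time, and region-specific
address conventions. Passing tests therefore demonstrate the machinery
and its calibration on these error modes, not performance on any real
collection.

## Numerical and design choices

* Hash indices take the first 24 bits of the HMAC digest modulo $\ell$
  (unbiased for power-of-two lengths); filters are stored hex-encoded,
  most-significant bit first, 4 hex characters per 16-bit word.
* SHA-256 is the SHA-2 variant used throughout; the HMAC message layouts
  are `field|bigram|i`, `field|value`, and `block|pass|keystring`.
* Dice on an all-zero (missing) filter is `NA`, never 0; score
  contributions for `NA` similarities are exactly 0.
* The acceptance threshold is inclusive (score ≥ threshold). Weights use
  log base 2; any base works if the threshold is scaled accordingly.
* Group labels are the smallest member id; death-record separation removes
  weakest pairs with deterministic tie-breaking (first in canonical pair
  order), so the whole pipeline is reproducible bit-for-bit.
* A one-character value has no bigrams and is treated as missing on both
  the encoded and the clear-text side, keeping the two pipelines exactly
  comparable.

## Problem sizes used in the checks

The package's own test suite exercises the end-to-end system at 5,000
persons (≈ 20,000 morbidity and ≈ 500 mortality records) for the headline
grouping-agreement comparison; oracle equivalences (Dice, blocking,
closure) run on samples of 200–1,000 units; generator calibration is
checked at ≈ 10,000 records per dataset. These sizes were chosen as the
smallest at which the measured proportions are stable; all conclusions the
tests draw are recomputed at run time, never stored.

## Limitations

Bloom-filter encodings are not information-theoretically secure; frequency
and pattern attacks on field-level filters exist, and hardening schemes
(salting, balancing, record-level folding) trade linkage quality for
resistance. This package implements the plain field-level scheme and
treats governance — who may hold the encodings, under what safeguards — as
out of scope. The clear-text baseline is intentionally simple; real
engines with per-block bespoke rules will differ from it in ways this
package does not model. The default $m/u$ weights and blocking recipes are
stand-ins for unpublished operational tables and should be re-estimated
for any real collection.
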