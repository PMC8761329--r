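# bloomlink

Privacy-preserving probabilistic record linkage with field-level Bloom
filters, for linking person-level health datasets — typified by a hospital
morbidity collection (many records per person) and a death-registration
file (at most one record per person) — when clear-text identifiers cannot
leave the data custodian.

**Who it is for.** Data-linkage units and biostatisticians who need to (a)
encode identifier extracts at source so that linkage can be run blind on
the encodings, (b) run a Fellegi–Sunter linkage on those encodings, and
(c) quantify how an encoded linkage compares with a conventional
clear-text linkage of the same data.

## The method

Each identifier field is encoded separately. Approximate fields (names,
address, suburb) become **Bloom filters**: the cleaned value's unpadded
bigrams are each hashed *k* times with HMAC-SHA-256 under a shared secret
key into an ℓ-bit vector (defaults ℓ = 512; *k* = 30 for names, 20 for
address, 25 for suburb). Exact fields (sex, date of birth, postcode)
become single keyed hash tokens. Encoded fields are compared with the
Sørensen–Dice coefficient

    D(a, b) = 2·|a ∧ b| / (|a| + |b|)

and scored with Fellegi–Sunter log-weights: each field contributes
log₂(m/u) on agreement, log₂((1−m)/(1−u)) on disagreement, 0 when
missing, with linear partial-agreement interpolation above a per-field
Dice floor (default 0.7). Pairs scoring ≥ 20 (default) are accepted;
blocking (clear-side key recipes, hashed before shipping) keeps the
comparison space linear; person groups are the connected components of
the accepted pairs. Post-linkage QA splits male–female twin patterns (all
identifiers agreeing except first name and sex) and groups holding more
than one death record.

The package also provides: pre-linkage validation of encoded files
(frequency profiles, cross-encoding consistency, placeholder/dummy-value
detection and removal), a clear-text baseline linker with identical
blocking plus a first/last-name inversion comparison, a per-mortality-
record grouping-comparison evaluation protocol with truth-based
correctness classification, and a synthetic morbidity/mortality generator
(configurable missingness profile, typos, diminutive names, address
keyword variants, twins, placeholders) with full corruption provenance.
See the methods vignette (`vignettes/bloom-filter-linkage.Rmd`) for the
model details and design rationale.

## Worked example

```r
library(bloomlink)

synth <- synthesize_linkage_data(synth_config(n_persons = 500, seed = 42))
synth
#> <synth_linkage_data> 500 persons, 1945 morbidity records, 46 mortality records, 397 corruptions

cfg <- encoding_config(key = "shared-secret")
pp  <- pprl_pipeline(synth$morbidity, synth$mortality, cfg)       # encoded linkage + QA
ct  <- cleartext_pipeline(synth$morbidity, synth$mortality, cfg)  # clear-text baseline

glance(pp)
#> # A tibble: 1 × 7
#>   method n_records n_candidates n_accepted n_groups n_multi_groups threshold
#>   <chr>      <int>        <int>      <int>    <int>          <int>     <dbl>
#> 1 pprl        1991         6741       5894      503            369        20

cmp <- compare_linkages(morbidity_sets(pp$groups), morbidity_sets(ct$groups))
tidy(classify_with_truth(cmp, synth$truth))
#> # A tibble: 9 × 3
#>   quantity                 n   pct
#>   <chr>                <int> <dbl>
#> 1 mortality_records       46 100
#> 2 identical               45  97.8
#> 3 pprl_extra               0   0
#> 4 ct_extra                 1   2.2
#> 5 both_extra               0   0
#> 6 pprl_extra_correct       0   0
#> 7 pprl_extra_incorrect     0   0
#> 8 ct_extra_correct         1   2.2
#> 9 ct_extra_incorrect       0   0

pairwise_quality(pp$groups, synth$truth)
#> # A tibble: 1 × 6
#>      tp    fp    fn precision recall f_measure
#>   <dbl> <dbl> <dbl>     <dbl>  <dbl>     <dbl>
#> 1  5900    16    21     0.997  0.996     0.997
```

Reading the output: of the 46 death records, the encoded and clear-text
linkages assembled identical morbidity-record sets for 45 (97.8%); for
one, the clear-text linker found an additional morbidity record, which the
truth map confirms is a correct link (an error mode — here a swapped
first/last name — that the baseline's inversion comparison catches and the
encoded comparison cannot). Against ground truth the encoded linkage
resolves record pairs with precision 0.997 and recall 0.996.
`autoplot(pp)` shows the bimodal pair-score distribution around the
threshold, and `autoplot(cmp)` the comparison categories.

A thin command-line wrapper over the same functions is installed as
`exec/pprl` (subcommands `synth`, `encode`, `validate`, `link`,
`link-cleartext`, `group`, `evaluate`).

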