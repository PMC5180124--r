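# kinbias

Do fathers in a promiscuous fission–fusion society bias their behaviour
toward their own offspring?  In eastern chimpanzees, females mate with
most of the community's males, yet genetic paternity is concentrated, and
a father that can recognize his infant might protect it when infanticide
risk is highest — or might instead be courting the mother for future
matings.  `kinbias` implements the complete analysis chain used to
separate these two hypotheses from long-term observational data, plus a
community simulator so the whole chain can be validated end to end.

The package is written for behavioural ecologists working with
focal-follow and family-follow observation tables: every user-facing
function takes a data frame and returns a tibble, so stages compose with
the pipe.

## The statistics at the core

* **Dyadic association index.**  For male *m*, mother–infant pair *p* and
  six-month infant-age window *w*:
  `A(m,p,w) = (minutes p was in m's party) / (minutes m was followed)`,
  z-standardized per male across all MI pairs present throughout the same
  window.  Infancy is binned `[0,6), [6,12), …, [36,42)` months from each
  infant's birth (calendar-month arithmetic).  Males need 30 h of follow
  time in a window to count.
* **Within- and between-period comparisons.**  A father's standardized
  association with the mother of his offspring is contrasted with his
  associations with mothers of non-kin infants, either in the same
  calendar window or in windows where the non-kin infant occupied the
  same age bin of its own life.  Both are modelled as
  `z ~ kin * age_bin + (1|male) + (1|mother) + (1|infant)` (Gaussian,
  REML, Satterthwaite type-III F), with Tukey-style within-bin contrasts.
* **Interaction proportions.**  Per-infant groom/play rates with each
  adult male are summed into a total interaction strength; each kin
  category's observed share is compared with its demographic expectation
  (its share of living adult males) by a one-sample sign-flip permutation
  test (exact when `2^n` fits in the iteration budget).
* **Elo ranks.**  Sequential Elo ratings (start 1000, k = 100, logistic
  400-point curve) over the decided-interaction log; ordinal rank at any
  date.
* **Association → subsequent paternity.**  Whether the same male sires
  the mother's next offspring, as a binomial mixed model on the father's
  18-month standardized association (90 h filter) and his Elo rank at
  conception, with a Firth-penalized fallback under separation.

## Worked example

Simulate a small community with a father bias of 3 (odds scale, six-month
half-life) and run the whole pipeline:

```r
library(kinbias)

cfg <- sim_config(n_adult_males = 10, n_mothers = 8, years = 6,
                  follow_days_per_month = 2, family_days_per_month = 1,
                  family_minutes = 120, seed = 42)
report <- run_pipeline(cfg, B = 2000)
report
```

```
-- within period association --
  term        num_df den_df f_value  p_value
1 kin              1   188.   46.1  1.41e-10
2 age_bin          6   188.    7.79 1.68e- 7
3 kin:age_bin      6   188.    8.26 6.03e- 8
```

The kin × age-bin interaction says the father/non-kin contrast changes
over infancy.  The within-bin contrasts show where:

```r
report$association$within$contrasts
```

```
  age_bin estimate    se    df t_ratio p_unadjusted p_adjusted
1 0         1.08   0.138  188.   7.81      4.04e-13  3.21 e-12
2 1         0.625  0.136  189.   4.60      7.62e- 6  5.36 e- 5
3 2         0.352  0.126  188.   2.80      5.66e- 3  3.88 e- 2
4 3         0.284  0.128  186.   2.23      2.72e- 2  1.74 e- 1
5 4        -0.101  0.125  187.  -0.813     4.17e- 1  9.76 e- 1
6 5        -0.0496 0.136  188.  -0.366     7.15e- 1  1.000e+ 0
7 6         0.183  0.147  188.   1.25      2.14e- 1  8.11 e- 1
```

Fathers associate far more with their own mother–infant pair in bins 0–2
(the first 18 months; estimates are standardized-association
differences), and indistinguishably thereafter — the injected early-life
bias, recovered.  The mating-effort side comes back null, as simulated
(`paternity_link = 0`):

```
-- subsequent paternity --
  term  estimate    se chisq    df p_value
1 z        1.99  2.65  0.564     1   0.452
2 rank    -0.338 0.536 0.398     1   0.528
```

`plot_association_bins(report$association$within$dataset)` and
`plot_interaction_differences(report$interactions$summaries)` draw the
two headline figures; `tidy()`/`glance()` methods give the model tables.
Real data enter through `read_bundle("dir/")` with six CSVs (roster,
pedigree, follows, point samples, dominance log, conceptions); see
`?read_roster` for the schemas.

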