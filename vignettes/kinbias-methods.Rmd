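---
title: "Methods: kin-biased association and interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kin-biased association and interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

In fission–fusion societies with promiscuous mating — eastern chimpanzees
are the motivating case — females mate with many males, yet fathers may
still recognize and invest in their own offspring.  Two hypotheses compete
for any observed affiliation between a male and a lactating mother:

* **paternal effort** — the male biases association and interaction toward
  his *own* infant, most strongly in early infancy when infanticide risk
  peaks;
* **mating effort** — the male courts the *mother*, expecting improved
  odds of siring her next offspring.

The package implements the full analysis chain that separates these:
dyadic association indices with per-male standardization, observed-versus-
expected interaction proportions with a permutation null, Elo dominance
ranks, and a binomial model linking early association to subsequent
paternity — plus a configurable community simulator so that every stage
can be validated end to end without field data.

# The association index and its standardization

For an adult male $m$ and a mother–infant (MI) pair $p$ in a calendar
window $w$, the association index is

$$ A_{m,p,w} \;=\; \frac{\text{minutes } p \text{ was in } m\text{'s party during his focal follows in } w}
                        {\text{minutes } m \text{ was followed in } w}, $$

where a minute counts only when mother *and* infant are both recorded in
the party (the MI pair is the analytic unit).  Windows are anchored at
each focal infant's birth and advance in six-month calendar steps up to
3.5 years (seven half-open bins; an infant born 1 January has its first
window end 30 June).  Month arithmetic is calendar-exact with end-of-month
rollback.

Raw proportions confound paternal bias with demography and gregariousness,
so each male's proportions are z-standardized across all MI pairs present
in the community in the same window:
$z_{m,p,w} = (A_{m,p,w} - \bar A_{m,\cdot,w}) / s_{m,\cdot,w}$ (sample
standard deviation).  Degenerate sets (one pair, or zero variance) get
$z = 0$ and a flag.

**Equal-exposure membership.** A pair present for only a fraction $f$ of a
window can co-occur with the male for at most that fraction of his follow
minutes, so its proportion is mechanically scaled by roughly $f$ and its
z-score driven far negative regardless of any social preference.  Because
the anchor infant is — by construction — fully exposed in every one of its
own windows, including partially-present pairs in the comparison biases
the father-versus-non-kin contrast upward, and does so most strongly in
the first and last age bins (the anchor's own birth and age-out
boundaries), which masquerades as a kin-by-age interaction.  The package
therefore requires full-window presence (infant alive and under 42
months, mother alive, throughout the window) for a pair to enter a
window's standardization and comparison sets.  The permissive rule —
any-day presence with the diluted proportions — remains available as
`presence = "any_day"` for sensitivity analyses.

**Comparison datasets.** The *within-period* dataset contrasts, inside
each window of each father's offspring, the father's z-score with the
mother of his offspring (kin category FATHER) against his z-scores with
mothers of non-kin infants in the same window (NON_KIN), tagging every row
with the offspring's age bin.  The *between-period* dataset instead takes
non-kin comparisons from windows in which the non-kin infant occupied the
same age bin *of its own life*, whatever the calendar period, which
controls for attraction to infants of a particular age.  Both datasets
apply a 30-hour (1800-minute, boundary-inclusive) follow-time filter per
male and window, and keep a male's window (or bin) only when both a
FATHER and at least one NON_KIN row survive.  Maternal-kin dyads (adult
maternal brothers, maternal uncles, maternal cousins, identified purely
through mother-links in the pedigree), unknown-paternity dyads, and a
father's other-aged own offspring take part in the standardization but
never in the contrast.

# Kin classification

Kin category is a pure function of (male, infant, pedigree): FATHER when
the pedigree names the male as sire (taking precedence over any
coincidental maternal relation); MATERNAL_KIN for the three named
maternal relations up to grandmother-sharing; UNKNOWN when the infant's
paternity is unassigned and no maternal relation holds; NON_KIN
otherwise.  Deeper matrilineal relatives are NON_KIN by default; a
`widen` switch extends MATERNAL_KIN to the full matriline.  The paternal-
side kinship of males to mothers is deliberately not modelled: such
assignments are scarcer and their behavioural relevance unresolved, so
only the maternal-side rules are exposed.

# Interaction rates and the permutation test

From family-follow point samples (one record per minute), the dyadic
interaction rate of infant $i$ with male $m$ in an infancy period is
grooming-or-playing minutes with $m$ divided by minutes in the same party
as $m$; direction is ignored.  Infancy is split into EARLY ($[0,6)$
months) and LATE ($[6,42)$ months), with 10-hour and 60-hour
observation-time filters respectively.  Rates are summed over adult males
into the infant's total interaction strength; the observed proportion of
a kin category is its rate sum over the total strength.  The expected
proportion is purely demographic: the fraction of adult males alive (and
adult, i.e. at least 12 years old) in that category on the reference
date, which is the period start (birth for EARLY, the six-month
anniversary for LATE; a mid-period option exists because the choice is
anchored only by a single birthday example).  Maternal-kin and unknown
dyads count toward total strength but not the contrasts.

Observed-minus-expected differences across infants are tested with a
one-sample sign-flip permutation test: each difference's sign is flipped
independently, the statistic is the mean (sum and mean are equivalent
under sign-flips), and the two-sided p-value is the fraction of permuted
$|\bar d|$ at least the observed one.  When $2^n \le B$ the $2^n$
patterns are enumerated exhaustively — the test is then exact — otherwise
$B$ random patterns are drawn (default $B = 10000$, seed mandatory).
Numerically, the comparison uses a $10^{-12}$ tolerance so the identity
permutation always counts, making $p \ge 2^{1-n} > 0$.

# Dominance ranks

Elo ratings are replayed over the decided-interaction log in date order:
expected winner score $E_w = 1/(1 + 10^{(R_l - R_w)/400})$, winner gains
$k(1 - E_w)$, loser loses the same, so rating mass is conserved exactly.
Start rating 1000 and $k = 100$ are the common conventions in the
animal-dominance literature; nothing in the analysis fixes them, so both
are arguments.  Ordinal rank at a date is the rating order among adult
males alive then; unseen males sit at the start rating, and ties break
deterministically by earlier first interaction, then id.

# The mixed models

*Association*: $z \sim \text{kin} * \text{age bin}$ with crossed random
intercepts for male, mother and infant; Gaussian errors, identity link,
REML, type-III F-tests with Satterthwaite denominator degrees of freedom
(lme4/lmerTest).  Infant sex is an optional covariate, off by default.
Within each age bin a FATHER−NON_KIN contrast is computed with a
single-step multivariate-$t$ adjustment over the family of seven within-
bin comparisons (the Tukey-style generalization for a non-pairwise
family; emmeans `adjust = "mvt"`, with a fixed local seed because the
multivariate-$t$ integral is quasi-Monte-Carlo).  Random factors with a
single sampled level are dropped; with none left the model reduces to the
fixed-effects linear model, and a singular mixed fit is returned with a
warning rather than an error.

*Subsequent paternity*: one case per (mother, prior infant) with known
prior paternity and known next sire; response: whether the same male
sired the next offspring; predictors: the father–mother z-standardized
association over the prior infant's first 18 months (90-hour filter) and
the father's ordinal Elo rank at the next conception; random intercepts
for mother and father; binomial errors, logit link (Laplace); Wald
chi-square tests per term.  Under complete separation (or a failed mixed
fit) the package refits with its own Firth-penalized (Jeffreys-prior
score-adjusted) logistic regression and warns; with brglm2-style
penalization the estimates stay finite.

# The community simulator

`simulate_study()` draws, from one master seed (stage-specific derived
streams keep every stage independently reproducible, and identical seeds
give byte-identical CSV bundles):

* a roster of `n_adult_males` (default 12) with a fixed latent dominance
  hierarchy, `n_mothers` (default 12) with per-mother baseline
  gregariousness uniform on 0.3–0.6 (mothers alone 40–70% of their
  time), grandmother links so that a configurable share of mothers has an
  adult maternal brother (maternal uncle of her infants), and infants
  born across the span with truncated-normal interbirth intervals
  (4.5 ± 0.7 years, clipped to 3–6.5);
* paternities from a rank-skewed lottery (weight $e^{-0.4(r-1)}$ for rank
  $r$, giving a repeat-sire probability near the observed one-in-five), a
  10% unknown-paternity mask, and a conception table of consecutive-
  infant cases (gestation 230 days);
* male focal follows in piecewise-constant 30-minute party segments: the
  odds an MI pair shares the male's party are the mother's gregariousness
  odds times $\beta_f^{2^{-a/\tau}}$ when the male is the infant's true
  father ($a$ = infant age in months; defaults $\beta_f = 3$, half-life
  $\tau = 6$ months — chosen to reproduce the qualitative early-infancy
  bias pattern, as no effect size on the odds scale is available to
  match);
* family follows at 1-minute point samples with adult-male co-presence at
  baseline 0.15 (same paternal decay), per-minute groom/play interaction
  probability $5\times10^{-4}$ per co-present male in late infancy
  (times $\beta_i = 3$ for fathers), and $2\times10^{-5}$ for everyone in
  early infancy, so early-infancy interaction is near-absent and the
  late-infancy mean total strength lands near 0.005;
* a dominance log decided by a logistic contest on the latent hierarchy.

With a non-null paternity link $\gamma$, next-infant sires are redrawn
with the prior father's lottery odds multiplied by $e^{\gamma z}$, where
$z$ is the father–mother 18-month association computed by the package's
own association code on the simulated follows; the follows are then
re-simulated on the same random stream so paternal party bias reflects
the final pedigree.  With $\gamma = 0$ (the default null) the redraw
never happens and the lottery stands.

**What the simulator does not emulate.** Space and travel (bias acts
directly on co-presence odds), inter-community encounters, infant and
adult mortality within the span, observation-effort gaps, and behaviour
codes beyond groom/play.  Passing tests on simulated data therefore
validate the *computational chain and its statistical calibration under
the stated generative assumptions*, not the field conclusions.

# Replicate study conditions

Monte-Carlo experiments in the test suite use scaled-down but
demographically coherent conditions, chosen once:

* permutation-test calibration: 10 adult males, 12 mothers, 5 years,
  family follows 120 min/month per infant, per-minute interaction rate
  0.01 (large enough that per-dyad event counts keep the per-infant
  differences near-symmetric, the regime in which a sign-flip null is
  appropriate and which matched the reported normality of the observed
  samples), 1000 replicates at $B = 2000$;
* association-model calibration and recovery: 12 males, 12 mothers,
  8 years (a rolling birth flow keeps window membership stationary),
  one 720-minute follow day per male-month, 200 null and 100 biased
  replicates;
* paternity-model calibration and recovery: 10 males, 25 mothers,
  12 years, one 360-minute follow day per male-month (~30 cases per
  replicate, comparable to the 27 in the motivating study), 200 null and
  100 $\gamma = 2$ replicates.

# Known limitations

* **The kin-by-bin interaction F-test is intrinsically anticonservative
  on this response.**  A male's z-scores in a window form a zero-sum set:
  the father row equals minus the sum of the others, and window
  membership drifts with births and age-outs.  This induces negative
  within-window and positive within-pair-across-bin correlations that the
  three crossed random intercepts cannot represent, and the type-III
  Satterthwaite F for kin × age bin rejects a true null somewhat above
  its nominal level — increasingly so as observation effort and community
  size grow (the fixed-effects-only fit is, conversely, conservative).
  The calibration block in the test suite measures this directly; readers
  should treat borderline interaction p-values from this model with
  caution and lean on the within-bin contrasts, whose family-wise
  adjustment is computed at the cell level.
* **Wald tests on few binary cases are conservative.**  At the study's
  realistic scale (tens of conception cases), the Wald chi-square for the
  association term rejects a true null well below 5%; the calibration
  block measures this too.  This is the familiar small-sample behaviour
  of Wald statistics in logistic models, not a defect of the pipeline.
* Kin classification covers maternal kin to cousin depth only, and the
  equal-exposure membership rule discards pairs present for part of a
  window rather than re-weighting them; an exposure-adjusted denominator
  (male follow minutes intersected with pair presence) would retain them
  but changes the published index and is deliberately not the default.
* The degenerate-z convention (set to 0, flagged, retained) keeps
  heavily-filtered males in the datasets; dropping them instead is a
  one-line sensitivity switch on the flag.
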