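---
title: "Patient-sharing networks from visit-level registries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-sharing networks from visit-level registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnet)
```

## The problem

Collaboration between health care professionals is hard to measure with
surveys. Patient-sharing networks offer an administrative alternative: two
professionals are taken to be connected when they treated a sufficient
number of common patients within a study window. `psnet` implements a
complete analysis pipeline of this kind for visit-level primary-care
registries, oriented at mental-health and substance-use cohorts: cohort
identification, exclusion cascades with audit reports, bipartite
patient-professional graph construction, thresholded one-mode projection,
descriptive network statistics, size-matched resampling comparisons
between diagnosis-group networks and the all-patients cohort, and
dyad-independent exponential random graph models (ERGMs) with
simulation-based goodness-of-fit. Because real registries of this kind are
confidential, the package also ships a synthetic registry generator that
emulates their statistical structure; it is first-class, tested code, and
every stochastic method in the package is validated against it.

## Cohort identification and exclusions

A patient enters the cohort when at least one visit carries any of

1. an ICD-10 chapter-F diagnosis outside the exclusion ranges
   (defaults F00–F03 dementia, F70–F79 mental retardation, F80–F83
   specific developmental disorders),
2. an ICPC-2 chapter-P code outside an exclusion list
   (defaults P70, P85, P24), or
3. a service-type flag marking the visit as mental-health or
   substance-abuse related.

The exclusion code ranges are configurable: the underlying concepts
("excluding dementia, mental retardation, and specific developmental
disorders") map to code ranges in more than one defensible way, so the
defaults are surfaced in the audit report rather than hard-wired.

Once identified, *all* of a patient's visits are retained, on the view
that the resulting network should reflect everything the cohort's care
touches. Visits are then excluded in a fixed narrative order — home care,
undefined service type, occupational health, rows with missing
professional id / occupation / visit type, then visits to non-care
occupations (secretaries, managers, pharmacists, opticians) — followed by
two patient-level rules: patients with a single remaining visit, then
patients whose visits all went to one professional. The patient rules are
applied once, sequentially, not to a fixed point: a patient reduced to one
visit *by* the single-professional rule is not re-dropped. This mirrors a
single pass of accounting and keeps the audit report interpretable; a
fixed-point variant would change counts only in pathological corners.

Diagnosis subgroups (substance use F10–F19, psychotic F20–F29, depressive
F30–F39) take all visits of patients with at least one in-range code, and
patients may belong to several subgroups. The depressive range is
implemented exactly as printed even though F30–F31 are manic/bipolar
codes; the label follows the published convention, not nosology.

## Networks and statistics

The bipartite patient-professional graph has one tie per (patient,
professional) pair, weighted by visit count. The one-mode projection
connects professionals sharing at least `min_shared = 5` distinct patients
(the threshold below which shared patients are a poor proxy for an actual
working relationship), with the shared-patient count as edge weight.

Two policy choices deserve note:

* **Isolates are kept** as degree-0 nodes by default. Node counts are
  "number of professionals", and dropping isolates would silently inflate
  density. The resampling module applies the same policy on both sides of
  every comparison, so the choice cannot bias a comparison.
* **Small-component pruning** (components under 5 nodes) applies to the
  force-directed layout export only. A Fruchterman–Reingold drawing warps
  with many tiny components; statistics, however, are always computed on
  the unpruned network.

Statistics are computed on the unweighted simple graph: density
$2E/(N(N-1))$; mean geodesic distance over reachable pairs only (the
unreachable-pair count is reported alongside; a largest-component mode
would be the alternative, and relative comparisons are insensitive to the
choice); global transitivity (3 × triangles / connected triples);
unnormalized shortest-path betweenness averaged over nodes. Relative
group metrics divide the in-group mean degree (or betweenness) by the
out-group mean; a zero denominator yields `NA` — the dash convention of
published tables. Because the ratios are scale-invariant, the
unnormalized-betweenness choice is immaterial for them.

## Size-matched resampling comparison

Each diagnosis-group statistic is compared against `M = 100` statistics
computed from uniform down-samples of the all-patients cohort at the
group's patient count. Professional attributes are frozen from the full
cohort; what varies across draws is which professionals clear the sharing
threshold — the intended source of null variability. Patient-level
exclusions are not re-run inside draws (sampled patients already satisfy
them).

Two tests are reported per statistic: a two-sided one-sample Wilcoxon
signed-rank test of the M resampled values against the observed value as
hypothesized location (zero differences dropped), and an exact sign test
(binomial on values above/below the observed), our reading of a
"nonparametric median test" in a one-sample design — Mood's median test
is a two-sample procedure and does not apply.

**A caveat the user should understand.** This procedure treats the
observed group statistic as a *fixed* hypothesized location. When the
observed network is itself subject to sampling variability comparable to
the null draws — which is exactly the situation when group membership is
unrelated to network structure — the test is strongly anticonservative:
the M null values concentrate around their own mean at rate
$\sigma/\sqrt{M}$ while the observed value sits $O(\sigma)$ away. In a
null simulation (the "group" drawn as a uniform subsample of the same
cohort) we measure a rejection rate near 0.7 at nominal $\alpha = 0.05$
with $M = 50$. The package reports the tests as published, but their
p-values should be read as "the observed value is not a plausible draw
from the size-matched resampling distribution", not as a calibrated
test of the group-vs-cohort hypothesis. A Monte-Carlo tail probability of
the observed value within the resampled distribution would be the
calibrated alternative.

## Dyad-independent ERGMs

With only dyad-independent terms, an ERGM factorizes over the
$N(N-1)/2$ dyads:

$$\operatorname{logit} P(Y_{ij}=1) = \theta^\top x_{ij},$$

where $x_{ij}$ collects the change statistics: `edges` (intercept),
`nodefactor` main effects (count of endpoints at each non-reference
level), uniform homophily (`nodematch`, indicator of equal attributes)
and differential homophily (per-level both-endpoints indicators).
Estimation is exact maximum likelihood on the dyad table via
Newton–Raphson with step halving (gradient max-norm tolerance `1e-8`) —
no MCMC is involved, and none is needed; dyad-dependent terms are out of
scope by design. Wald 95% intervals come from the inverse Hessian.

Model steps follow the published hierarchy: step 1 uses edges,
municipality main effects and uniform municipality homophily, occupation
main effects and uniform occupation homophily; step 2 replaces the
uniform occupation term with differential homophily, keeping the
municipality terms uniform. Reference levels are physician and the
lowest-coded municipality. Edge weights are ignored in fitting (ties are
binary). The BIC sample size is the dyad count $N(N-1)/2$ — a documented,
configurable choice; the literature also uses the edge count, and nothing
downstream depends on the constant.

**Separation.** Structurally separated indicator terms (e.g. a
differential homophily level with no within-level edge at all) are
detected, fixed at $\pm\infty$, and reported with a one-sided 95%
profile-likelihood bound instead of a Wald interval — this mirrors the
empty cells that such tables show for sparse categories. Because those
dyads contribute likelihood exactly 1 at the limit, the remaining
coefficients are still exact MLEs. Joint quasi-separation (coefficients
diverging in tandem, e.g. when every observed edge is a within-municipality
dyad) is flagged on the affected coefficients.

Goodness-of-fit simulates `n_sim = 100` networks from the fitted dyadic
probabilities and compares the observed degree distribution, edgewise
shared partners (common neighbors per existing edge) and minimum geodesic
distance distribution (with an unreachable category) against per-bin
2.5/97.5% envelopes.

On five-node graphs the dyadic likelihood is verified against the
exponential-family form with the normalizing constant summed explicitly
over all $2^{10}$ graphs (agreement to machine precision), and fitted
coefficients against the enumerated-likelihood argmax. One caveat found
during that exercise: with five nodes, any two-level attribute split
leaves an attribute class with a single dyad, so the corresponding
saturated models never have an interior MLE — the argmax comparison is
only possible for the occupation spec, and the boundary specs are checked
at the likelihood-value level.

## The synthetic registry: what it emulates, what it does not

The generator's stated world follows the printed marginals of a
seven-municipality primary-care setting: occupation mix 26/62/12
(physician/nurse/other), median 14 visits/patient overall with medians
20/21/17 in the substance/psychotic/depressive groups, group sizes
10.6%/6.2%/26.6% of the cohort, service-type mix 43/30/10/17 over
general care / mental-health-substance / routine / other, and one
calendar year of uniformly distributed dates. Visit counts are negative
binomial, parameterized by median with dispersion 2.5 — chosen once so
that interquartile ranges resemble the printed ones (e.g. median 14 gives
an IQR near 8–23); only medians are printed with full precision, so
IQR matching is approximate by design.

Each patient samples a care team of size
$\lceil \text{visits}^{0.6} \rceil$, biased toward the patient's home
municipality (within-municipality probability 0.85), toward an anchor
occupation (`occupational_assortativity`, log-scale 0.5 per group), and —
two knobs the package adds — toward *popular* professionals
(`popularity_dispersion = 0.3`, a gamma-shape skew of professional visit
volume) and toward the patient's *diagnosis-group team*
(`group_concentration = 0.3`). The last two encode the empirical facts
that visit volume across professionals is heavily skewed and that
specialized teams treat each diagnosis group. Without them, uniformly
spread visits essentially never clear a shared-patient threshold of 5 at
desk scale; with them, diagnosis-group networks come out denser than
size-matched all-patient samples — the central qualitative pattern of
interest. Deliberate dirt (home-care rows, undefined service types,
occupational-health rows, non-care occupations, missing fields,
single-visit and single-professional patients) exercises every exclusion
step.

What the generator does **not** attempt: the joint distribution of a real
register (visit-level correlation in time, referral sequences, true
comorbidity structure), realistic ICD-10 code frequencies beyond group
membership, or reproduction of any published table's numeric values —
the source data are confidential, and only printed marginals are
targeted. A green test therefore establishes that the *methods* behave
as specified on data with the right coarse structure, not that the
package reproduces any particular cohort's numbers.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds; stage seeds are derived from
  the master seed by hashing stage tags (`derive_seed`), so changing one
  stage's iteration count never perturbs another stage, and a full
  pipeline run is byte-identical under a fixed master seed (manifest MD5
  hashes included).
* Modal attribute ties (occupation, municipality) are broken by a seeded
  draw keyed on the professional's id, so results do not depend on row
  order.
* Newton–Raphson uses step halving and declares convergence on the
  gradient max-norm at `1e-8`; degenerate fits (empty graphs) drift to
  large negative edge coefficients, are flagged as quasi-separated, and
  still simulate correctly (probabilities underflow to 0).
* Undefined quantities (statistics of empty networks, ratios with zero
  denominators, distances in edgeless graphs) are `NA` with a reported
  count where relevant — never exceptions.

## Known limitations

* The resampling comparison's published test is anticonservative under
  the null (see above); both tests are reported, but an empirical-tail
  alternative should be preferred for calibrated inference.
* Only dyad-independent ERGM terms are supported; clustering beyond what
  attributes explain (e.g. transitivity) is visible in the GOF panels but
  cannot be absorbed by these models.
* Networks are cross-sectional within one window; no temporal or
  visit-sequence structure is modeled.
* The generator assigns one primary diagnosis group per patient plus an
  optional comorbid second group; real comorbidity is richer.
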