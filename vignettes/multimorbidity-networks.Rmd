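---
title: "Methods: sex- and age-stratified multimorbidity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex- and age-stratified multimorbidity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimorbnet)
```

# The model

A *multimorbidity pattern* is an unordered pair of distinct diseases
co-occurring on the same inpatient record. Diseases are 3-character
ICD-10 categories (e.g. `E11`, `I10`), restricted to Chapters 1–14 —
the somatic-disease chapters, excluding pregnancy, perinatal,
congenital, symptom, injury, external-cause and special-purpose codes.
Each patient contributes one baseline record: the earliest admission by
date (ties broken by record identifier).

A stratum's *complete multimorbidity network* has one node per disease
observed in the stratum and one edge per accepted pattern. For each
candidate pair $(x, y)$ with co-occurrence table
$(a, b, c, d)$ — both, $x$ only, $y$ only, neither — the association is
the single-binary-predictor logistic model of $y$ on $x$. The model is
saturated on a $2\times2$ table, so the maximum-likelihood odds ratio
is exactly the cross-product ratio

$$\widehat{OR} = \frac{a\,d}{b\,c},$$

with Wald standard error of the log odds ratio
$\sqrt{1/a + 1/b + 1/c + 1/d}$.

## The three edge criteria

A pattern becomes an edge exactly when all three hold (all inequalities
strict):

1. $\widehat{OR} > 1$;
2. two-sided p-value $< \alpha/N$ with $\alpha = 0.05$ and $N$ the
   number of candidate patterns in the stratum with $\widehat{OR} > 1$
   (per-stratum Bonferroni correction);
3. pattern prevalence $a/n > 1/10\,000$.

Pairs with an empty $b$ or $c$ cell have a non-finite estimate
(separation) and are never accepted; pairs with $a = 0$ have
$\widehat{OR} = 0$ and are never candidates.

**Definition of $N$.** The odds-ratio floor in criterion 1 is
configurable (`network_criteria(or_floor = ...)`), but $N$ is always
the count of patterns with $\widehat{OR} > 1$. If $N$ shrank with the
floor, the threshold $\alpha/N$ would loosen as the floor tightens and
a stricter criterion could admit new edges, breaking the monotonicity
that tightening any criterion can only remove edges.

## The p-value: likelihood-ratio, not Wald

The edge p-value is the two-sided likelihood-ratio (deviance) test of
the logistic slope. On a $2\times2$ table it has the closed form of the
$G$-test of independence,

$$G^2 = 2\sum_{\text{cells}} O \log(O/E), \qquad p = P(\chi^2_1 > G^2),$$

with $E$ the margin-product expectations. The more conventional Wald
test is also computed (`estimate_association()$p_wald`) but is **not**
used for edge selection: when the expected co-occurrence count is small
(a few counts, as for pairs of rare diseases), the Wald p-value is
anti-conservative by an order of magnitude or more in the far tail.
For example, a table with $a = 13$ observed against $3.5$ expected
($n = 50\,000$) has Wald $p \approx 2\times10^{-6}$ — past a Bonferroni
threshold of $3\times10^{-6}$ — while the deviance and exact tests give
$p \approx 10^{-4}$. With tens of thousands of candidate pairs per
stratum, using the Wald test produces systematic false edges among
independent rare diseases and defeats the family-wise control the
Bonferroni correction is meant to provide; the likelihood-ratio test
restores it (verified on seeded synthetic studies with 20\,000+
independent background pairs: 0–1 false edges per run at nominal
level). The odds ratio itself is unaffected — it is the same MLE under
either test.

# Network algebra

For the sex comparison within an age range, three levels are built from
the same criteria:

- **complete** networks per stratum (overall, each sex, each sex–age
  band — the bands 40–44, 45–49, 50–54, 55–59 are built independently);
- **sex-overlapped**: the intersection of the male and female edge sets
  (patterns significant in both);
- **sex-specific**: the difference (patterns significant in one sex
  only).

Edge identity is the unordered code pair, so the decomposition identity
$|\text{complete}| = |\text{specific}| + |\text{overlapped}|$ holds
exactly for each sex; `run_pipeline()` audits it.

# Node metrics and hubs

Seven metrics are computed on the *unweighted* simple graph (odds
ratios are display attributes only): degree; maximal clique centrality
(MCC, $\sum_{C \ni v} (|C|-1)!$ over maximal cliques, with an isolated
node counting its singleton clique, $0! = 1$); closeness
(within-component closeness scaled by
$(\text{comp}-1)/(n-1)$, hence in $[0,1]$ and $0$ for isolates); local
clustering coefficient ($0$ for degree $< 2$); betweenness (connected
pairs only); PageRank (damping $0.85$, sums to 1); eigencentrality
(largest component, max-normalised to 1, $0$ elsewhere).

*Hub diseases* are the top 10 nodes by degree; ties at the cut are
broken by descending MCC, then ascending code, so the hub set is
deterministic. The *hub network* keeps edges with both endpoints among
hubs; the *hub-associated network* keeps edges with at least one hub
endpoint. Coverage reports the share of the parent network's nodes,
edges, and total pattern frequency (sum of edge co-occurrence counts)
that a subnetwork retains.

# Chapter attribution

Chapter frequency percentages attribute each edge's frequency to the
ICD-10 chapters of its endpoints. Under the default *dual* attribution
a cross-chapter edge credits **both** chapters its full frequency (a
within-chapter edge counts once), and the denominator is the network's
total pattern frequency — so percentages can sum to more than 100%.
The *half* option splits cross-chapter credit. Chapters are ranked by
descending percentage (ties by ascending chapter number); a chapter
absent from a network has rank `NA`. Rank trajectories track these
ranks across the four age bands per sex.

# The synthetic generator

`synth_config()` defines a study: strata with record counts, a disease
catalog with marginal prevalences, and planted pairs with target odds
ratios scoped to `both_sexes`, `male_only`, or `female_only`.

- **Strata.** Default: eight sex–age strata with realistic inpatient
  cohort sizes (about 184,000 records in total, males
  30167/31655/25402/16110 and females 20956/24751/21550/13542 across
  the bands 40–44 to 55–59).
- **Catalog.** 150 diseases with power-law prevalences
  $p_k = 0.18\,k^{-0.7}$, giving roughly 2.3 diagnoses per record.
- **Planted pairs.** Disease-disjoint pairs are drawn by a
  Plackett-style coupling: given marginals $p_x, p_y$ and target odds
  ratio $\psi$, `joint_from_or()` solves the quadratic
  $(\psi-1)p_{11}^2 - [1 + (p_x+p_y)(\psi-1)]p_{11} + \psi p_x p_y = 0$
  for the joint cell inside the Fréchet bounds, and the four cells are
  sampled per record. Sex-scoped pairs are coupled only in the matching
  sex and independent in the other. All other diseases are independent
  Bernoulli draws.
- **Redraw-on-empty.** An inpatient record must carry at least one
  code, so empty draws are redrawn. Emitted records are therefore iid
  *conditioned on non-emptiness*, which slightly inflates marginals and
  shifts pairwise odds ratios: the conditional odds ratio of a planted
  pair is $\psi(1 - q)$, where $q$ is the probability that everything
  else on the record is absent. `planted_truth()` computes these
  conditioned cells and conditional odds ratios exactly, and the test
  suite validates empirical estimates against them (not against the
  nominal targets).

What the generator does **not** emulate: within-patient correlation
beyond the planted pairs (no comorbidity clusters, no per-patient
frailty), so diagnosis counts are near-Poisson rather than
overdispersed. Consequently synthetic multimorbidity prevalence
(~73% of records with ≥ 2 diseases under the default catalog) is higher
than typical real inpatient cohorts at the same mean diagnosis count,
and background networks are sparser. It also fixes one admission per
patient and a constant admission date, since baseline selection is
exercised separately on constructed fixtures.

# A small end-to-end example

```{r example}
cfg <- synth_config(strata = data.frame(
  sex = c("male", "female"), age_band = "50-54", n_records = 5000))
sim <- generate_cohort(cfg, seed = 7)
net <- build_network(stratify(sim$records, "all")$all)
net
head(node_metrics(net)[order(-node_metrics(net)$degree), ])
```

Problem sizes: the default study (184k records, 150 diseases, ~11,000
candidate pairs per stratum) runs the full pipeline in about two
minutes; pairwise counting is a single sparse cross-product of the
record-by-disease incidence matrix, so cost scales with total
diagnoses, not with records × diseases.
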