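---
title: "Methods: the pedscreen filter cascade and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pedscreen filter cascade and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscreen)
```

# The model

`pedscreen` targets one specific study design: a family in which a rare
cancer (or another late-onset phenotype) recurs across generations in a
pattern suggestive of autosomal-dominant inheritance, a handful of members
have been sequenced, and the goal is to reduce the germline variant list to
a shortlist compatible with Mendelian segregation and enriched for
functional impact. The package is a *prioritizer*, not a test: it produces
candidates and a stage-by-stage accounting (the funnel), not p-values.

The cascade assumes:

* **a single dominant causal variant per family** — carriers are
  heterozygous or homozygous alternate; recessive and X-linked models are
  declared extension points and not implemented;
* **incomplete observability of carrier state** — affection status is the
  observable; carrier probability is encoded through the five-level status
  model rather than a penetrance likelihood;
* **per-family analysis** — each family is filtered independently;
  cross-family recurrence is a reporting concern, not a filter.

## The five-level status model

The binary case/control dichotomy is too coarse for real counseling data:
a member diagnosed at 83 in a family whose cases cluster in their fifties
may well be a phenocopy, and a young unaffected sibling of three cases may
still carry the variant. Each sequenced member therefore gets one of:

| status | segregation constraint (defaults) |
|---|---|
| `CASE_DEFINITE` | must carry (`max_missing_definite_cases = 0`) |
| `CASE_POSSIBLE_PHENOCOPY` | unconstrained (`max_missing_phenocopy_cases = Inf`) |
| `CONTROL_NONCARRIER` | must not carry (`max_carrier_noncarrier_controls = 0`) |
| `CONTROL_POSSIBLE_CARRIER` | unconstrained (`max_carrier_possible_controls = Inf`) |
| `UNINFORMATIVE` | never constrains |

The tolerances are numeric slack, not probabilities: the underlying rule of
thumb — "a maximum number of cases and a minimum number of controls must
carry the variant" — is a counting rule, and we expose it as exactly that.
A likelihood-based treatment (penetrance models, LOD scores) is a
non-goal. Missing genotypes count toward no constraint by default
(`missing_genotype_rule = "noninformative"`); the `"strict"` rule makes a
missing genotype fail a `CASE_DEFINITE` / `CONTROL_NONCARRIER` member's
constraint, which is the conservative choice when genotyping dropout is
suspected of hiding discordance.

## Thresholds

All thresholds live in one flat config (`pipeline_config()`,
template via `write_config_template()`), with strict-inequality readings
throughout — a value *exactly at* a threshold fails:

| parameter | default | meaning |
|---|---|---|
| `min_qual` | 20 | Phred site quality, `qual > 20` |
| `min_depth` | 5 | carrier read depth, `dp > 5` |
| `maf_cutoff` | 0.001 | rare means `MAF < 0.1%` in every resource with data |
| `cadd_min` | 10 | scaled CADD `> 10` = top 10% tier; `> 20`, `> 30` = top 1%, 0.1% |
| `gerp_min` | 2.0 | conserved by GERP when `> 2.0` |
| `phastcons_min` | 0.3 | conserved by PhastCons when `> 0.3` |
| `vote_min` | 3 | deleterious calls of 4 predictors |
| `mirsvr_cutoff` | −0.1 | good miRNA target when `< −0.1` |

Design choices where the operating point was genuinely open:

* **Depth is enforced on carrier samples** (`depth_scope = "carrier"`): a
  deeply covered non-carrier adds nothing to a segregation call, while an
  under-covered carrier can fake one. A site-wide switch
  (`depth_scope = "all"`) exists because the stricter reading is also
  defensible.
* **Strand support is pooled across carriers**, because the rule is stated
  per variant, not per sample; a variant seen forward-only in one carrier
  and reverse-only in another has two-strand support overall.
* **Missing MAF counts as rare.** Novel variants absent from population
  catalogues are the prime candidates; imputing 0.5 or dropping them would
  invert the analysis's purpose. Missing CADD, by contrast, *fails* the
  CADD gate by default — a variant cannot be rank-gated without its
  ranking score (`cadd_missing_passes` overrides).
* **Conservation is a flag, not a gate, by default** (`conservation_action
  = "flag"`, `conservation_mode = "either"`): the scores are described as
  "considered in the screening" rather than as a hard filter, and the
  either/both combination is not specified upstream, so both are config
  switches and the default drops nothing.
* **Intolerance is supplementary** (`intolerance_action = "flag"`): the
  funnel reports with- and without-intolerance counts side by side (the
  parenthetical convention in the summary table); genes missing from the
  intolerance resources pass with an `unassessed` flag rather than being
  excluded, since absence from a resource is not evidence of tolerance.
  The percentile ceiling (25) and `min_sources` (1) are this package's
  defaults; no canonical cutoffs exist.
* **Non-missense coding classes**: the 4-predictor vote is defined for
  missense variants only. Splicing variants bypass the vote with a
  high-impact flag (missense predictors cannot score them, but they are
  too consequential to drop); `other_coding` (synonymous and similar) is
  rejected with an explicit manual-review reason, never auto-passed. The
  region vocabulary cannot distinguish nonsense/frameshift from synonymous
  inside `other_coding`; annotators that call them should map them to
  `splicing`-like handling via the key map, and this is a documented
  limitation.
* **Intronic variants route to the intergenic (regulatory) branch**, since
  both are evaluated with the same regulatory-evidence machinery.
* **Regulatory evidence is lexicographic**: RegulomeDB-style category
  first ("1a" strongest … "7" weakest, mapped to an ordinal), HaploReg
  flag count as a tiebreaker (`ordinal = 100 * rank_ordinal +
  flag_count`). No published combination formula exists; rank-dominates
  was chosen because the categories already integrate multiple evidence
  types. The default minimum evidence level is 0: the non-coding branches
  *rank* rather than drop, and a 3′UTR miRNA-target call promotes a
  variant in the ranking without being a hard requirement (a 3′UTR variant
  can act through non-miRNA mechanisms; `mirna_action = "gate"` hardens
  it).

## Relatedness QC

Sample swaps are fatal to segregation filtering, so before segregation the
package compares, for every pair of sequenced members, the Jaccard index of
their rare-variant carrier sets against the pedigree kinship coefficient.
There is no closed-form map from rare-variant Jaccard to φ without
population parameters, so concordance is *rank-based*: a pair is flagged
when

* it takes part in more than `rank_tolerance` (default 0) kinship-rank
  inversions — a pair with higher expected kinship (by more than
  `kinship_gap = 0.05`) showing lower sharing (by more than `sharing_gap =
  0.02` plus `noise_z = 4` binomial standard errors of the Jaccard
  difference) — or
* its expected kinship is 0 but it shares more than
  `unrelated_max_sharing = 0.10` (plus the same noise guard).

The standard-error guard makes the check self-calibrating across cohort
sizes: with a few dozen rare variants per sample the statistic is too
noisy to rank and the check stays silent; with hundreds of rare variants
per sample (the regime where swap detection is meaningful) the guard is
tight and inversions flag reliably. The whole check is advisory — it warns
and continues unless `strict_relatedness` is set — because its false
positives must never silently delete variants.

# The simulator: what it emulates, what it does not

`simulate_cohort()` generates the package's entire test world:

* a **three-generation pedigree** (founder couple, sibships of three, the
  first two children of each sibship marry in new founders) — the shape of
  a family that would plausibly qualify as Mendelian;
* one **causal variant** entering through a designated founder and
  gene-dropped by Mendel's laws, with `causal_penetrance = 1` and
  `phenocopy_rate = 0` by default (the clean stated world; both are
  parameters);
* **statuses derived from observable phenotype only**: affected members
  diagnosed at ≥ 78 become `CASE_POSSIBLE_PHENOCOPY`, younger affecteds
  `CASE_DEFINITE`; unaffected members younger than 55 or with ≥ 3 affected
  first-degree relatives become `CONTROL_POSSIBLE_CARRIER`, the rest
  `CONTROL_NONCARRIER`. Hidden carrier truth is never consulted —
  otherwise every segregation test would be circular;
* **ascertainment**: the causal drop is redrawn until the family has ≥ 3
  sequenced cases and ≥ 4 informative meioses, because real families enter
  sequencing *because* they look Mendelian; penetrance is treated as
  lifetime risk realized at simulation time;
* **200 decoy variants** by default: 70 % rare family-private variants
  (one heterozygous founder copy, catalogue MAF uniform below 5×10⁻⁴ or
  absent for the 30 % "novel" fraction) and 30 % common variants
  (founder frequency uniform on 0.05–0.5, catalogue MAF tracking it);
  8 % of decoys are indels; designed technical failures (low quality, thin
  carrier coverage, one-strand support, non-PASS indels) are planted at
  5 % / 5 % / 5 % / 30 %-of-indels rates, and a handful of decoys sit at
  *exactly* the strict thresholds (CADD 10/20/30, MAF 0.001, GERP 2.0 with
  PhastCons 0.3, mirSVR −0.1) to exercise boundary behaviour;
* **annotation scores** from stated background distributions (decoy CADD
  uniform 0–35, per-predictor deleterious probability 0.3 with 10 %
  missing calls, intolerance percentiles uniform with 20 % missing) and a
  deleterious parameter set for the causal variant (CADD uniform 30–45,
  all four predictors deleterious, conserved, catalogue-absent).

What the simulator deliberately does **not** model: linkage disequilibrium
(decoys are independent across loci — sufficient for record-wise filters,
wrong for haplotype analyses), realistic site-frequency spectra,
recombination, sequencing-error models beyond missing-genotype injection,
and polygenic or two-locus architectures. A green test therefore
establishes that the *cascade logic* is correct under Mendelian
transmission, not that the pipeline's operating characteristics transfer
to any particular sequencing platform or population.

# Numerical and degenerate-input choices

* All threshold comparisons are strict; "one ulp past" a threshold passes.
  The boundary suite in the tests pins this down for every gate.
* Multi-allelic sites are decomposed into one record per alt allele, with
  the per-sample genotype recomputed as the dosage of that alt allele
  only; allele count is conserved.
* Jaccard sharing of two empty rare-variant sets is undefined and reported
  as missing, never as 0 or 1.
* Ranking is a total preorder with stable ties (input order preserved);
  candidates sort by CADD tier, then predictor vote count, then raw CADD.
* A cohort with a single sequenced sample skips the relatedness check
  (no pairs exist); a single pair is checked by the absolute rule only
  (no ranking is possible).
* Funnel invariants (non-negative, per-class non-increasing) are asserted
  after every run, not just in tests.

# Known limitations

* Only the autosomal-dominant carrier model is implemented.
* The five-status model deliberately collapses carrier probability to
  three effective levels (must / may / must-not); families needing finer
  gradations need a likelihood model out of this package's scope.
* The relatedness statistic is a QC heuristic, not a kinship estimator: it
  orders pairs, it does not estimate φ, and it is blind to swaps between
  members with identical expected kinship to everyone else (e.g. two
  siblings swapped with each other — which is also harmless to
  segregation).
* CADD is applied to all regions at one default threshold even though its
  discrimination is weaker outside coding sequence; per-region overrides
  of the gate exist in the config for users who want region-specific
  thresholds.
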