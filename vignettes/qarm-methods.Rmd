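---
title: "Constraint-based rule mining for clinical yes/no data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based rule mining for clinical yes/no data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large clinical studies distribute patient-level CSV exports in which
hundreds of yes/no variables — medical history items, medications, sleep
and other symptoms — are described by a data dictionary and harmonized
across studies by a canonical mapping: each study-specific *dataset
variable* maps to at most one *canonical variable*, while one canonical
variable (say, stroke history) may be measured by several dataset
variables (a physician-reported and a self-reported stroke item).
These variables are heavily imbalanced: typically only a few percent of
patients answer "yes".

Classical association rule mining on such data is unrewarding.  Mining
the full cohort returns rules that describe the population at large;
mining "no" values floods the output with trivially co-occurring
negations; and sibling variables that measure the same fact generate
rules that merely relate a variable to its near-duplicate.  The approach
implemented here mines rules *within the sub-cohort of patients
satisfying a query constraint* — one canonical variable answered "yes" —
and then prunes the result down to rules specific to that sub-cohort.

## The pipeline

For a query constraint $q$ the pipeline runs these stages, in a fixed
order:

1. **Variable selection.** Keep categorical variables with a yes/no
   domain whose dictionary category is medical history, medication,
   sleep symptom or other symptom.  Multi-valued categorical variables
   and numerical variables are excluded (discretizing numerical
   variables is out of scope).
2. **Visit combination.** Multi-visit records collapse to one record per
   patient: yes if any visit says yes, otherwise no if any visit says
   no, otherwise unknown.
3. **Variable merging** (merged mode only). Sibling dataset variables
   collapse into their canonical variable by the same yes > no > unknown
   vote.
4. **Transformation.** Patients satisfying $q$ become transactions
   holding their "yes" items; the constraint's own item is dropped from
   the universe (it is "yes" for every retained patient by
   construction).  Queries with fewer than `min_patients` (default 20)
   satisfying patients are skipped.
5. **Mining.** The top-$k$ non-redundant rules $X \to Y$ with
   $\mathrm{conf} \ge$ `minconf` are mined on the sub-cohort
   (rule set $O$), and likewise on the complement cohort (rule set $N$).
6. **General-rule removal.** $O \leftarrow O \setminus (O \cap N)$ under
   rule identity $(X, Y)$: a rule that also holds among patients *not*
   satisfying $q$ is not specific to the query.
7. **Subsumption removal.** A rule is dropped when another rule says at
   least as much from weaker premises: $X_1 \subseteq X$ and
   $Y \subseteq Y_1$.  Unlike the miner's redundancy relation, no metric
   equality is required here.
8. **Sorting.** Descending support, then descending confidence, then a
   lexicographic tie-break for reproducibility.

Support and confidence are the standard measures
$\mathrm{supp}(X \to Y) = |\{t : X \cup Y \subseteq t\}| / |D|$ and
$\mathrm{conf}(X \to Y) = |\{t : X \cup Y \subseteq t\}| /
|\{t : X \subseteq t\}|$, both computed on the sub-cohort, not the full
dataset.  Internally they are held as integer count pairs; equality
comparisons (for the redundancy relation) cross-multiply counts, so
floating-point noise cannot create or destroy ties.

## Top-k non-redundant mining

A user-chosen minimum support is hard to calibrate per query, so the
miner instead returns the $k$ highest-support rules above a confidence
floor.  A rule $r_a$ is *redundant* with respect to $r_b$ when both have
exactly equal support and confidence and $r_b$ has a smaller-or-equal
antecedent and larger-or-equal consequent; redundant rules are removed
before truncation to $k$.

Two modes are implemented:

* **`exact`** enumerates every rule with support > 0, at most
  `max_rule_size` items and confidence above the floor, removes
  redundant rules, sorts and truncates.  It is the correctness reference
  and entirely practical for small universes, but on a cohort of
  thousands of patients the $k$-th rule legitimately reaches support
  counts of 3–5, where the number of valid rules explodes
  combinatorially.
* **`tnr_search`** (the default, and the parameterization the pipeline
  is designed around: $k = 100$, `minconf` $= 0.6$, $\Delta = 10$) runs
  the same depth-first enumeration with a rising support threshold.
  The candidate buffer is periodically *compacted*: redundant candidates
  are removed — safe because the redundancy relation is transitive, so a
  dropped rule's victims are also dominated by its dominator — and the
  threshold rises to the support of the $(k + \Delta)$-th best
  non-redundant candidate.  Ties with the threshold are kept.
  Thresholding on non-redundant candidates (rather than raw candidates)
  is what makes the search agree with exact enumeration in practice; a
  divergence is only possible when more than $\Delta$ top-stratum
  candidates are invalidated by dominating rules discovered later, which
  we have not observed on any tested instance.  The oracle-equivalence
  test compares both modes against an independently written brute-force
  enumerator on hundreds of random databases.

The enumeration itself carries shrinking transaction-id lists down each
branch (Eclat-style), so per-node cost tracks the sparse co-occurrence
counts rather than the cohort size.  For item universes of at most 62
items the search runs in compiled code with itemsets as 64-bit masks —
the same division of labour as the established mining packages — with a
pure-R engine handling larger universes.

`max_rule_size` (antecedent plus consequent items) defaults to 5.
Published constraint-specific rule lists rarely exceed two antecedent
and four consequent items; the cap bounds the otherwise exponential rule
space and is configurable.  Rules tied at the $k$-th position are
resolved by the deterministic ordering rather than all included, so
output size is predictable and runs are byte-reproducible.

## Handling "unknown"

Cell values are normalized to yes/no/unknown through a configurable
token map.  Unknown is treated as absence of information throughout:

* it never generates an item (only "yes" cells do);
* it is the identity of both the visit-combination and the merging vote
  — a patient whose answers are all missing stays unknown rather than
  being fabricated into a "no";
* a patient whose constraint status is unknown is placed in the
  complement cohort (they are not known to satisfy the query);
* the imbalance rate of a variable, $100 \cdot n_{yes} / (n_{yes} +
  n_{no})$, excludes unknowns from the denominator.

The second and third points are genuine design choices: a literal
"otherwise no" reading of visit combination would coerce pure
missingness to "no", and complement membership for unknown-status
patients is not dictated by the method definition.  Both choices are the
conservative ones (no information invented) and are asserted by tests.

## The synthetic cohort generator

Real sleep-study datasets of this kind are access-restricted, so the
package ships a generator that emulates their structure: many imbalanced
yes/no canonical traits, each expressed through one or more dataset
variables, over one or more visits, with missingness and *planted*
constraint-specific associations.  Per patient, each trait is drawn
Bernoulli with its imbalance rate; for each planted rule
(constraint $c$, antecedent $A$, consequent $Y$, `conf_in`, `conf_out`),
patients carrying all of $A$ have $Y$ rewritten: with probability
`conf_in` (inside the $c$-cohort) or `conf_out` (outside) all consequent
traits are set yes, otherwise one uniformly chosen consequent trait is
forced no — so the realised conditional probability equals the requested
confidence, and a "general" rule is planted by setting
`conf_in = conf_out`.  A yes trait is expressed by a uniformly chosen
non-empty subset of its (dataset variable, visit) cells, which exercises
the merging and visit-combination logic with partial signals; masking to
unknown happens last, independently per cell.

Beyond the planted rules, traits are independent.  Real clinical data
has correlated comorbidities, informative missingness and visit-level
drift, none of which the generator emulates — passing tests demonstrate
that the pipeline recovers what was planted under known conditions, not
that it will find only true associations in real data.

The shipped fixture freezes one such cohort: 2000 patients, 2 visits,
40 canonical variables expressed through 56 dataset variables, mean
imbalance rate 5.16% by construction (matching the scale of a large
multi-visit sleep study), 2% missingness, and three planted rules.  The
planted constraints (13%) and antecedents (14%) sit at the common end of
the imbalance spectrum so that each constrained cohort of roughly 240
patients holds 30-odd antecedent carriers — enough for a stable
confidence estimate; rarer antecedents would leave the planted
confidence statistically unrecoverable at this cohort size.  The fixture
is regenerated deterministically from its spec and seed rather than
stored, and its full 40-query pipeline run takes well under a minute.

## Numerical and degenerate-input choices

* Confidence-floor comparisons allow a $10^{-9}$ absolute slack so that
  a rule at exactly `minconf` is kept regardless of the floating-point
  representation of the floor.
* An empty transaction database cannot be mined (error); an empty
  complement cohort simply skips general-rule removal; a complement
  smaller than the patient gate still participates, with a warning —
  the gate applies to the query cohort only.
* Patients whose transaction is empty are retained: they deflate
  support, as they should.
* The subsumption scan runs against the full input set; because
  structural domination is transitive this yields the same survivors as
  scanning against maximal rules only (asserted by the idempotence
  test).
* Merged-vs-unmerged comparison first canonicalizes unmerged rule items
  through the mapping; items appearing on both sides of a canonicalized
  rule stay on the antecedent side, and rules whose consequent empties
  out (sibling-to-sibling rules) are dropped before counting common and
  distinct rules.

## Worked example

```{r, eval = FALSE}
library(qarm)

fx <- shipped_fixture()
res <- qarm(fx$table, fx$dictionary, fx$mapping, query = "cv10")
res
res$rules

run <- qarm_all(fx$table, fx$dictionary, fx$mapping, out_dir = "out")
run
```

The per-query result reports the cohort size, the number of top-k rules
mined and how many were removed as general or subsumed; the count
identity `n_top_k = nrow(rules) + n_general_removed +
n_subsumed_removed` holds for every run.

## Known limitations

* Single-variable query constraints only; conjunctive constraints are a
  natural generalization the data structures already admit.
* No discretization of numerical variables.
* The search's $\Delta$-buffer gives top-k exactness in practice but not
  by proof; exact mode exists precisely to audit it on any instance
  small enough to enumerate.
* Interestingness is support/confidence only — no lift, leverage or
  statistical significance correction; the output is an exploratory
  shortlist, not a set of validated associations.
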