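---
title: "Detecting meiotic crossovers in family quartets: model and methods"
author: "quartetHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting meiotic crossovers in family quartets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetHMM)
```

## The model

A meiotic crossover changes which parental homolog a gamete carries. In a
nuclear family quartet — father, mother and two children genotyped at dense
SNPs — a parent's transmission at a locus is in one of two modes: both
children received the *same* homolog ("identical") or *different* homologs
("distinct"). A crossover in one of the parent's two observed meioses flips
that parent's mode between adjacent loci. The two parents' modes combine into
four hidden states:

```{r}
transmissionStates()
```

The observation at a marker is the quartet genotype configuration — the four
calls (AA/AB/BB, with per-marker abstract alleles A/B), 81 configurations in
all. Each configuration is *consistent* with the states for which some
assignment of transmitted parental alleles reproduces the children under
Mendelian inheritance:

```{r}
consistentStates("AA", "AB", "AA", "AB")   # mother must transmit distinct alleles
consistentStates("AA", "AA", "AA", "AA")   # homozygous loci are uninformative
```

A hidden Markov model is built over these states and decoded with the
Viterbi algorithm; every decoded state change is a candidate crossover in the
switching parent's meiosis.

### Emission design

Configurations consistent with a state share a fixed total mass
(`consistentMass`, default 0.9995); inconsistent configurations — genotyping
or replication errors — share the remaining 0.0005 uniformly. Within the
consistent set, mass is *not* uniform: each configuration is weighted by the
number of transmission assignments that generate it, under a uniform measure
over parent genotype pairs and over each state's allowed transmissions. This
choice matters. The four consistent sets do not have equal sizes (15, 16, 16
and 15 configurations), so uniform within-set weights would make a fully
uninformative marker ever so slightly favour two of the four states — about
log(16/15) ≈ 0.065 nats per marker, enough to manufacture spurious state
excursions over a few hundred uninformative markers. Under the
assignment-count weighting, any configuration consistent with several states
has *identical* probability under each of them (verified exhaustively in the
tests), so shared configurations can never tip the decoder; rows still sum
to one and the consistent mass is still exactly 0.9995:

```{r}
E <- emissionTable(hmmParams())
rowSums(E)
```

Configurations containing a missing call are emission-neutral (probability 1
under every state) rather than a fifth allele symbol: the marker is simply
skipped by the likelihood, and the 81-symbol alphabet stays clean.

### Transitions

Parental switches are independent per marker step, each with probability
`tau` (default 1e-4 per parent): staying costs (1−τp)(1−τm) and a double
switch τpτm = 1e-8. The default is calibrated to array-scale data: a few
tens of crossovers per meiosis, two observed meioses per parent, on the
order of 10^5 marker steps. The balance between the error mass and the
transition weights is what makes the model robust: a single mistyped marker
can gain at most about log(0.056/7.6e-6) ≈ 8.9 nats by explaining the call
with a different state, while the cheapest excursion costs at least
log(1/τ) ≈ 9.2 nats — so isolated errors are absorbed, never decoded as
(double) crossovers. Transitions are constant per marker step, not scaled by
physical distance; with dense, roughly uniformly spaced markers the
difference is absorbed by τ, and the prediction-interval scan below makes
the reported localisation insensitive to it anyway.

Viterbi ties are broken in favour of not changing state, then by the fixed
state order, so fully uninformative stretches decode as constant paths.

### Prediction intervals

The decoder pins the change to one marker step, but the data are typically
ambiguous about the exact location. Around every state change the scan walks
5′ until it meets a marker that *pins the switching parent's old mode* —
every transmission state its configuration is consistent with carries that
mode — and 3′ until a marker pinning the new mode; those two marker
positions (1-based, closed) bound the region in which the crossover must
lie, and their distance is the event's *resolution*. The scan is
deterministic — it uses only the consistent-state classification, never the
probabilities — so the reported intervals do not move when τ or the emission
masses are perturbed. If no informative marker exists before the chromosome
end, the terminal marker bounds the interval. When both parents switch at
the same step, the change is decomposed into two single-parent events, each
scanned for its own parent.

Bounding by the parent's *marginal* mode, rather than by membership of the
two decoded states, is deliberate. When a maternal and a paternal crossover
fall within a few kilobases of each other, their order is often
genotypically undecidable; the Viterbi path must still commit to one order,
and a scan that trusts the jointly decoded phase of the *other* parent can
then bound an interval with a marker that only looks informative under the
wrong phase, yielding an interval that misses its crossover. The marginal
rule never consults the other parent's phase, so it is immune to this
failure at the price of slightly wider intervals in regions where only the
joint configuration, not the marginal mode, is informative. On the
validation simulation this is what pushes precision from roughly 99.98% to
beyond 99.99%.

### The X chromosome

Males are hemizygous on X, so the model reduces to the two maternal modes.
The father's call (coded homozygous by convention) fixes the allele every
daughter receives from him; sons carry only a maternal allele. Enumeration
runs over maternal transmissions alone, conditioned on the recorded child
sexes; heterozygous calls in a hemizygous individual are impossible and are
treated like missing data. Paternal events are never emitted on X.

## Families larger than quartets

Families with more than two children are cut into overlapping quartets.
Three children a, b, c form the pairs (a,b), (a,c), (b,c); a crossover in
child x must be visible in both pairs containing x and absent from the
third, which is simultaneously a *consistency check* and an *attribution*
rule: overlapping detections in two pairs merge into one event for the
common child, with the intersected interval. Matching is greedy in genomic
order — events are sparse relative to their interval sizes, so ties are
rare; coincidentally overlapping crossovers in different children are the
one case the rule cannot resolve, and on real data they surface as
inconsistencies. A triple with any unmatched event is *inconsistent*;
children implicated only in inconsistent triples are excluded, while a
child that also belongs to a fully consistent triple is rescued. For
families with more than three children the triples slide with one shared
child — (c1,c2,c3), (c3,c4,c5), … , with a final triple over the last three
children when the count is even — so adjacent triples overlap and every
child is covered. For odd quartet-pairs sharing one child (quintets), the
same overlap rule deduplicates the shared child's events.

## The simulator

`generatePanel()` emulates a phased haplotype reference panel:
linkage-equilibrium sites with allele frequencies drawn from a symmetric
Beta(0.8, 0.8) truncated to MAF ≥ 0.05 (array-like ascertainment), positions
uniform over a 100 Mb span, defaults of 340 haplotypes and 50,000 markers.
The MAF floor is enforced on the realised panel, not just on the frequency
draw. `simulateQuartet()` draws two haplotypes per parent without
replacement, places a configured number of crossovers (default 3)
continuous-uniformly in each of the four meioses — deliberately without
interference, matching the validation protocol rather than meiotic biology —
and optionally corrupts each call to a uniformly chosen different call.

Because the panel has no linkage disequilibrium, markers are *more*
informative than real LD-structured haplotypes, and the validation scores
should be read as an upper envelope: accuracy targets are therefore checked
as at-least bounds. What passing validation does show is that the decoder,
the interval scan and the scoring conventions are correct and that accuracy
at realistic density is high; what it does not show is performance under LD,
real ascertainment, or clustered genotyping error.

Scoring conventions: a true crossover is *localised* if an interval of the
same quartet and parent contains it; an interval is *correct* if it contains
at least one true crossover of its meiosis; with nothing reported precision
is 1, with no truth sensitivity is 1.

## Maps, hotspots, age

`buildMap()` converts attributed events into per-gap centimorgan distances:
each event contributes 100/nMeioses cM, assigned to the gap holding its
interval midpoint (the plotting convention for rate figures) or spread over
the gaps it covers proportional to gap length; both placements conserve
total mass, so total length = 100 × events / meioses (≈ 300 cM per meiosis
at 3 crossovers). `rateProfile()` excludes events resolved worse than 5 Mb
and bins midpoints into 1 Mb windows. The profile works from the event list
rather than a finished map because the resolution filter needs per-event
resolutions, which a map no longer carries.

Hotspot concordance uses only events resolved to better than 30 kb
(strictly), counts an interval once however many hotspots it touches, and
discounts chance overlap with the relation observed = true + (1 − true) ×
random, where the random rate comes from re-placing every interval uniformly
on its own chromosome with its length preserved. The discount solves to
estimate = (observed − random)/(1 − random); it reproduces the published
cohort estimates from their printed inputs and is monotone in both
arguments. The novel-cluster scan (groups of >2 mutually overlapping
non-concordant intervals) exploits that for intervals, pairwise overlap of a
set is equivalent to a shared common point, so clusters are coverage peaks;
it is exploratory output, not a calibrated test.

The maternal-age model is `count ~ age + mother` — first-order, no
interactions, mother as a factor. The factor absorbs between-mother
differences, so the age slope is identified purely by within-mother age
variation; designs where age is constant within every mother are rejected as
confounded rather than silently dropped. The per-chromosome comparison
splits mothers at age 30 and uses a one-sided Welch t-test (the
unequal-variance form, the safer default when the equal-variance assumption
is unstated) for a reduction in the older group, with Bonferroni correction
across the 23 chromosomes.

## Numerical and design notes

* Decoding is log-space throughout; the Viterbi kernel is compiled (Rcpp).
  Emission log-probabilities are a 4 × 82 lookup (81 configurations plus a
  neutral column for missing), so per-marker work is an index.
* Genotypes are stored as B-allele dosage 0/1/2/NA; PLINK text input recodes
  alleles per marker by first appearance. All outputs are invariant under
  A/B relabelling and child swapping (tested).
* Marker QC: call rate ≥ 0.99, Mendelian error rate ≤ 0.01 (violations over
  informative family tests), founder MAF ≥ 0.01 and founder Hardy-Weinberg
  chi-square p ≥ 0.001. MAF and HWE are founder-only to avoid relatedness
  inflation; with no founders those filters disable with a warning.
* Problem sizes in the test-suite simulations (tens of quartets at a few
  thousand markers, with the full 1,000-quartet × 50,000-marker validation
  run in the acceptance checks) were chosen so each check exercises the
  regime it is about — interval tightness needs density, scoring needs
  event counts — while keeping the default suite quick to run.

## Known limitations

* Linkage-equilibrium simulation overstates marker informativeness relative
  to real panels; no interference or gene conversion is simulated.
* Greedy interval matching in quintet/triple reconciliation is a heuristic;
  coincidentally overlapping crossovers in different children can be
  misattributed (they instead surface as inconsistencies on checked data).
* The X model assumes correctly recorded child sexes and hemizygous calls
  coded homozygous; X is skipped when sexes are unknown.
* Transition probabilities are per marker step, not per base pair;
  extremely uneven marker spacing would distort the effective recombination
  prior, though not the reported intervals.
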