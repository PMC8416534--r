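---
title: "Selecting function-specific tryptic peptides with pepscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting function-specific tryptic peptides with pepscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscout)
```

## The problem

Targeted LC-MS/MS assays (e.g. selected reaction monitoring) track a small
number of predefined peptides with high sensitivity and dynamic range. In a
single sequenced organism, choosing those peptides is straightforward; in a
mixed microbial community, one enzymatic function is typically carried by
hundreds or thousands of homologous proteins with divergent sequences.
A useful target peptide must then satisfy several conditions at once:

* it must be a clean tryptic product within the mass range the instrument
  handles well (8-25 residues by default);
* it should recur across as many of the taxa encoding the function as
  possible, so a short panel covers the community;
* it should avoid residues prone to chemical modification (which split the
  signal across mass shifts);
* it should be predicted detectable by LC-MS/MS; and
* it must be *functionally specific*: exact database matches of the peptide
  should come from proteins with the intended function, not from unrelated
  proteins that happen to share the subsequence.

pepscout automates this screen: it ingests a homolog set (a UniProt-style
reference download, a custom metagenome-derived FASTA, or both), digests it
in silico, indexes every peptide against its parent proteins and taxa,
applies the property filters, and emits shortlists that greedily maximize
genus- and species-level coverage.

## The procedure and its assumptions

### Pre-processing

Records are parsed from amino-acid FASTA. UniProt-style headers supply the
organism via the `OS=` field; genus is its first whitespace token and
species its first two. Organisms beginning with "uncultured",
"unidentified" or "bacterium" carry no usable binomial and are treated as
taxonomy-absent (they still contribute to peptide occurrence counts, but
never to species/genus coverage). Entries deviating from the median length
by more than a tolerance (default 25%, boundary inclusive) are removed as
likely fragments or erroneous entries; the median is computed on the full
parsed set before any removal, and the filter is a single pass (it is not
idempotent in general, because removing outliers can shift the median).
Optionally, records described as "putative" are removed. Length summary
statistics use the sample (n-1) standard deviation.

### Digestion and indexing

Trypsin cleaves C-terminal to K or R; cleavage before proline is suppressed
by default (the standard trypsin definition in digestion libraries), with a
flag to disable it. Missed cleavages default to 0; with `m` allowed, every
run of up to `m + 1` consecutive fully-cleaved fragments is reported. No
special treatment is given to N-terminal methionine, semi-tryptic products
or I/L equivalence. Each unique peptide within the length bounds is indexed
with its parent proteins, copy-weighted occurrence (custom datasets may
carry `copies=<int>` or SPAdes-style `_cov_<float>` abundance tokens;
coverage values are rounded up to at least 1), and the species/genus sets of
its parents. Peptides containing ambiguity codes (B, J, O, U, X, Z) are
indexed, so totals stay complete, but barred from shortlists.

When both a custom and a reference dataset are supplied, only peptides
present in both (exact sequence match at equal length bounds) continue:
the intersection carries the reference's taxonomy and the custom side's
copy weighting, reflecting site-specific abundance with database-verified
identity.

Candidates are ranked by species count (taxonomy-aware input) or
copy-weighted occurrence (taxonomy-free input); the top 400 by default
proceed to property calculations. Ties break by occurrence (descending)
then sequence (ascending) - an invented but documented total order that
makes every report reproducible.

### Peptide properties

*Chemical modifications.* The default rule set counts M and W (oxidation),
C (reactivity), N and Q (deamidation), plus one site when the peptide
starts with Q (pyro-Glu). The rules are configuration data, not code;
motif-weighted schemes (e.g. NG deamidation hotspots) can be substituted.
Candidates with more than 3 sites (default) are rejected.

*Detectability.* Four transparent rule voters preserve the four-voter
contract of published ensemble predictors: length in 8-20, mean
Kyte-Doolittle hydropathy in [-2.0, +1.5], one to three basic residues
(K/R/H), and no homopolymer run of 4+ with proline fraction at most 0.3.
These are deliberately simple physicochemical heuristics - no parity with
any trained model is claimed - and external verdict tables (four binary
votes, or a detection probability in [0, 1] thresholded at 0.5) override
them per peptide when supplied. One vote (default) is required to pass;
ambiguous residues make the hydropathy voter abstain.

*Specificity.* Exact hits - full-length, gapless, mismatch-free alignments
from a BLASTP run of the candidate peptides against a protein database -
are inspected by name. Because equivalent nr records are named
inconsistently, names are normalized (lowercase; commas, hyphens,
underscores, slashes to spaces; leading database tags stripped) and
compared by bidirectional substring containment, which tolerates shortened
forms of the full target name. Synonyms are inferred in a single pass:
whenever a multi-name defline bundle contains the target, its other names
join the synonym set. The score is the percentage of exact hits matching
the target or a synonym; 90% (default) is required, boundary passing.
Peptides with no exact hits cannot be scored: they are reported with a
caution and exempted from the filter rather than silently discarded, since
their absence from the database is itself informative. An allowlist exempts
chosen peptides, and scoring can be disabled wholesale when a different
specificity tool is preferred. Running BLASTP itself, and any taxonomy
restriction of that search, is the caller's responsibility; only the result
file is consumed.

The filters are applied in a fixed order - ambiguity, detectability,
modifications, specificity - and each rejected peptide is labelled with its
first failing reason (plus the full reason set), so category counts are
reproducible and sum with the passing set to the candidate total.

### Shortlists

"Decreasing contribution to coverage" is implemented as greedy maximum
coverage with marginal gains recomputed at each step - the only reading
under which a panel "collectively covers as many taxa as possible" is
meaningful; a flag switches to a single static sort by set size for
comparison. The greedy algorithm guarantees at least `1 - 1/e` of the
optimal coverage for every panel size, and the test suite verifies this
bound against exhaustive search on 500 random instances. When every
remaining candidate adds nothing, the list is still padded (gain 0) to the
requested length (default 50) so downstream assay design sees a stable
panel. The coverage denominator is the taxa of the ranked candidates (the
set actually subjected to property calculations), not of the full input
dataset; for taxonomy-free input a single occurrence-ranked list replaces
the two coverage lists.

## What the synthetic generator emulates

`generate_homolog_family()` builds a backbone of tryptic blocks and derives
one variant per species, so that a homolog family with known ground truth
can be generated offline. Design choices worth knowing:

* Interior backbone residues are drawn from a 12-letter alphabet that
  excludes K/R/P - so tryptic boundaries coincide exactly with construction
  blocks - and the modification-prone residues M/W/C/N/Q - so planted
  peptides are the only source of modification-filter violations and
  per-category rejection counts have exact expected values.
* Every non-planted block receives at least one species-specific
  substitution (plus extra substitutions at the configured rate, default
  0.02 per residue), which makes a fully conserved planted peptide the
  unique top-coverage candidate with overwhelming probability.
* Planted peptides must be valid tryptic products (end in K/R, no internal
  cleavage site, not starting with P); carriers are the first
  `ceiling(fraction * n_species)` species, and non-carriers receive a
  knockout substitution inside the planted block.
* Length outliers are lengthened by about 50%, clearly beyond the default
  25% tolerance; putative entries get a "Putative" description prefix; the
  two sets are disjoint so removal counts are unambiguous.
* All randomness flows from one seed, echoed in every FASTA header, and
  generation is byte-reproducible.

The default family (60 proteins, 20 species, 8 genera, 3 phyla, ~300-residue
backbone) mirrors a small, well-conserved bacterial enzyme family. What it
does **not** emulate: realistic mutational processes or phylogenetic
correlation, indels and partial sequences, paralogs, or the database-scale
name heterogeneity of nr. Passing tests on these fixtures therefore
demonstrate the correctness of the bookkeeping, ranking, scoring and
selection machinery - not the field performance of the detectability
heuristics, which depends on instrument and sample properties no synthetic
family can represent.

Similarly, `generate_blast_fixture()` writes standard-schema BLAST XML with
chosen exact-hit counts, on-target fractions, near-miss hits and bundled
multi-name deflines, so specificity scores have constructed expected values
and synonym inference is exercised end to end.

## Numerical and degenerate-input choices

* Even-count medians are the mean of the two middle values; all length
  comparisons are boundary-inclusive on the keeping side.
* All string orderings use radix (C-locale) sorting, so outputs are
  byte-identical across platforms and locales.
* Empty inputs error early (empty FASTA, empty record set, empty candidate
  set); a disjoint intersection or an empty shortlist produces an empty
  output with a warning rather than an error.
* Plotting failures are warnings, never fatal.
* Figures aside, two runs with identical configuration and inputs produce
  byte-identical outputs; the run manifest records every file written,
  every parameter value and every warning.

## Problem sizes used in the test suite

The shipped tests run the digestion oracle on 1,000 random sequences (six
rule combinations each), the greedy-versus-brute-force comparison on 500
random instances of up to 12 candidates and 10 taxa, and complete pipeline
runs on families of 40-500 proteins; the whole suite completes in well
under a minute on a single CPU. These sizes were chosen so that exhaustive
oracles (full subset enumeration, position-by-position digestion) remain
feasible while still exercising every code path.

## Known limitations

* The built-in detectability voters are heuristics; for production assay
  design, supply verdicts from a trained predictor via
  `detectability_file`.
* Specificity scoring is only as good as the BLAST database and the naming
  it contains; the synonym report exists precisely so that low scores can
  be audited by eye, and the threshold (or the allowlist) adjusted.
* Retention-time and SRM-transition prediction are out of scope; dedicated
  tools cover that step.
* Copy-number weighting treats assembly coverage as an abundance proxy,
  which is reasonable within one metagenome but not across datasets.
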