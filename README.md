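# pepscout

Selection of function-specific tryptic peptides for targeted
metaproteomics.

## The problem

In mixed microbial communities, one enzymatic function (say,
catechol-1,2-dioxygenase in an aromatic-degradation pathway) is carried by
many homologous proteins with divergent sequences. Designing a targeted
LC-MS/MS (SRM) assay for such a function means finding a *small panel of
tryptic peptides* that together:

* recur across as many of the genera/species encoding the function as
  possible,
* are LC-MS/MS-detectable and within the useful length range (8–25
  residues),
* carry few chemically modifiable residues (M, W, C, N, Q, N-terminal Q),
* and are *functionally specific* — their exact database matches come from
  proteins with the intended function.

pepscout automates the whole screen. Given a homolog set as amino-acid
FASTA (a UniProt-style reference download, a custom metagenome-derived set
with copy-number tokens, or both), it:

1. filters entries deviating > 25% (default) from the median length and,
   optionally, "putative" annotations, and summarizes the dataset;
2. digests every protein in silico with trypsin (cleavage after K/R,
   suppressed before P) and indexes each peptide against its parent
   proteins, species and genera — intersecting custom against reference
   peptides when both are given;
3. ranks the top 400 (default) candidates by species coverage (or
   copy-weighted occurrence for taxonomy-free input);
4. counts modification-prone sites, collects detectability votes (built-in
   physicochemical voters, overridable by external predictor tables) and
   scores functional specificity from a BLASTP result file as the
   percentage of exact full-length hits whose (synonym-normalized) name
   matches the target;
5. applies all filters and emits shortlists of 50 (default) peptides by
   greedy maximum coverage of genera and of species, plus a comprehensive
   per-peptide report.

The core selection step is classic greedy maximum coverage: at each step
the peptide covering the most not-yet-covered taxa is picked, which
guarantees ≥ (1 − 1/e) of the optimal coverage for every panel size.
A synthetic-fixture module generates homolog families and BLAST XML with
known ground truth, so everything is testable offline.

## Worked example

```r
library(pepscout)

# A synthetic 60-protein / 20-species / 8-genus homolog family with one
# fully conserved planted tryptic peptide:
fam <- generate_homolog_family(family_spec(
  n_proteins = 60, n_species = 20, n_genera = 8,
  planted_peptides = c(ELDSAGVITHIK = 1.0), seed = 7))
fa <- tempfile(fileext = ".faa"); writeLines(fam$fasta_text, fa)

cfg <- pipeline_config("synthetic dioxygenase", reference_fasta = fa,
                       no_bsearch = TRUE, output_dir = tempfile())
res <- run_pipeline(cfg)

res$summary
#> Protein dataset summary
#>   entries: 60 before filtering, 60 after (0 removed by length, 0 putative)
#>   length before: median 320.0, mean 320.0, sd 0.0 (range 320-320)
#>   length after:  median 320.0, mean 320.0, sd 0.0 (range 320-320)
#>   taxa after filtering: 3 phyla, 8 genera, 20 species, 0 of unknown taxonomy

res$index
#> Peptide index (reference): 462 unique peptides, length 8-25 AA, 0 missed cleavage(s)

res$selections$species
#> Peptide shortlist (species coverage): 50 picks, universe 20
#>   cumulative coverage: 20 / 20 (100.0%)

head(res$selections$species$picks[, 1:4], 3)
#>          peptide marginal_gain cumulative_covered cumulative_pct
#> 1   ELDSAGVITHIK            20                 20            100
#> 2  ISSLHYHFAFYIR             0                 20            100
#> 3 LAVTDYEFGDIYDK             0                 20            100
```

The planted peptide, present in all 20 species, is ranked first and alone
covers 100% of the species universe; every later pick has marginal gain 0
(the list is padded to the requested length for stable assay design).
The output directory now contains `initial_info.txt`, the retained-set
FASTA, `peptide_candidates_for_calculations.txt`/`.faa` (the BLASTP query
set), `possible_chemical_modifications.txt`,
`peptide_blastp_specificity.txt`, `Selected_peptides.genera`,
`Selected_peptides.species`, `Peptides_complete_info.txt`, summary figures
and a run manifest.

A thin command-line wrapper is installed as `exec/pepscout`
(`pepscout -m "catechol-1,2-dioxygenase" -i proteins.faa --stats-only`,
`--no-bsearch`, `-n`, `-l`, `-s`, `-a`, `--cd`, … mirror the function
arguments).

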