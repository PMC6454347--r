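---
title: "The genomic common data model: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genomic common data model: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdm)
```

## The problem this package addresses

Clinical NGS variant reports are heterogeneous: every hospital pipeline
emits its own file dialects, gene-symbol spellings, and variant
nomenclature, which blocks both pooled analysis and the privacy-preserving
alternative — distributed research, where analysis code travels to the
data and only aggregate statistics travel back. This package implements a
relational common data model for somatic variant data that extends an
OMOP-style clinical schema (person, condition, procedure, specimen, care
site) with four genomic tables:

* **genomic_test** — the assay: name, version, device, pipeline, reference
  databases and genome build, linked to a care site;
* **target_gene** — the genes the assay covers, as canonical HGNC symbols;
* **variant_occurrence** — one observed alteration in one patient's test:
  links to the procedure, a target specimen and an optional reference
  (normal) specimen, the gene, HGVS at DNA and protein level, read depth,
  exon, and a two-level variant typing;
* **variant_annotation** — interpretations attached to an occurrence
  (annotation database and version, somatic/germline origin,
  pathogenicity, allele frequency, medication), kept in a separate table
  so annotations can be re-issued as knowledge bases evolve without
  touching the observation itself.

Two specimen links exist because tumor/normal paired testing is the
common case; the reference link is nullable for single-specimen settings.

## Vocabulary standardization

**Gene symbols** are canonicalized against an HGNC table
(case-insensitive, alias-aware). The package bundles a subset covering
its 49-gene panel plus ~30 common aliases (`HER2` resolves to `ERBB2`,
`ERBB1` to `EGFR`); `load_hgnc_table()` accepts a full HGNC TSV when one
is available. Canonicalization is idempotent, and an alias is never
allowed to collide with a different canonical symbol.

**Protein HGVS** is stored in three-letter residue form only
(`p.Leu858Arg`, never `p.L858R`), so that string-level queries behave the
same across sites. Legacy one-letter input is accepted at the ETL
boundary and expanded by `expand_protein_hgvs()` — a deliberate design
choice: rejecting legacy spellings outright would make most public MAF
files unloadable. The supported grammar covers substitutions (including
`Ter` and the synonymous `=`), deletions, duplications, insertions,
`delins`, and frameshifts with an optional `Ter` offset, over single
positions and ranges. Anything beyond that (mosaicism, phasing,
uncertain breakpoints, stop-loss) is rejected with a positioned error
rather than misparsed. A short frameshift such as `p.Leu858Argfs` is
valid under this grammar; `fsTer` without an offset digit is not.

**The `Xaa` wildcard** is a query-side construct: `p.Gly12Xaa` groups all
single-residue substitutions at codon 12, the way actionable-mutation
registries group KRAS codon-12 hotspots. Three decisions pin its
semantics down so it is testable:

1. `Xaa` is legal only as the alternate residue of a substitution
   pattern; it is rejected in stored observations.
2. A wildcard matches missense substitutions only — not nonsense (`Ter`),
   not synonymous, and not indel or frameshift events at that codon,
   which are profiled as their own classes. The `Ter` exclusion is this
   package's own call (a codon-12 stop gain is biologically a different
   event class from the activating substitutions the pattern intends).
3. Wildcard matches are always a superset of any literal specialization
   at the same codon, which the test suite asserts as a law.

**Variant typing** is two-level: a DNA-structural class
(`sequence_alteration`: SNP, insertion, deletion, MNP, CNV,
translocation) and a protein-functional class (`variant_feature`:
missense, nonsense, frameshift, inframe, splice, synonymous, intron,
other). Source consequence terms (MAF `Variant_Classification`, Sequence
Ontology terms) map through an editable JSON asset; the mapping is total,
with unmapped terms routed to `other` under a warning rather than an
error, because a single unrecognized term should never abort a cohort
load.

## ETL conventions

* **Coordinates** are 1-based inclusive throughout (the MAF convention).
  VCF input is converted at load: the shared anchor base of an indel is
  stripped, a deletion then spans the deleted bases
  (`pos=100 REF=AT ALT=A` is stored as 101..101), and an insertion is
  flanked by the base before and after. Same-length alleles are SNP
  (length 1) or MNP.
* **FILTER policy**: VCF records pass with `PASS` or `.`; everything else
  is skipped and counted under `filter_failed`. The annotation INFO field
  and its sub-field order are configuration, not code, because pipelines
  disagree about them.
* **One sample per patient**: when several tumor samples map to one
  person, the sample with the earliest specimen collection date is kept
  (ties and missing dates broken lexicographically by barcode) and the
  rest are skipped under `duplicate_sample`, so that per-patient
  frequencies are well defined.
* **Panel restriction** drops records whose canonicalized gene is not on
  the panel (`off_panel`). Restriction commutes with loading — filtering
  the record stream first yields the same variant multiset — which the
  tests assert as a projection law.
* **CNV and translocation** cannot be expressed in plain MAF; they enter
  through a dedicated `sv_class` column recognized in panel exports, or
  directly through the synthetic generator.
* Every loader returns a report with
  `rows_read = rows_loaded + rows_skipped` and per-reason skip counts,
  and commits all-or-nothing: a constraint failure rolls the batch back.
* MAF files are read whole rather than streamed; at targeted-panel and
  panel-restricted-WES scale (thousands to tens of thousands of rows)
  this is well inside desk-machine memory.

Every committed load leaves the database in a state where
`validate_database()` returns zero violations; the validator re-checks
column domains, controlled vocabularies, primary and composite keys,
referential integrity, specimen-role consistency and protein-HGVS
re-parseability, and returns violations as data in deterministic order
rather than throwing.

## Profiling definitions

* **Demographics** are binned (age: `<=49`, decades, `>=80`, unknown)
  and reported as counts with percentages of the *full* cohort,
  including unknown categories in the denominator, rounded half-up to
  one decimal — the conventions under which the reference cohort tables
  are reproduced exactly. (One known artifact of those reference tables:
  their WES-cohort gender percentages are not consistent with the full-N
  denominator; this package always computes over full N and does not
  attempt to reproduce those two cells.)
* **Gene variant frequency** counts each patient at most once per gene,
  with the full cohort (including variant-free patients) as denominator.
  The `protein_altering_only` flag restricts to missense, nonsense,
  frameshift, inframe and splice variants.
* **Variant-type proportions** are proportions of variant rows, not of
  patients, at either typing level; they sum to 1 by construction. (The
  reference report is ambiguous about whether its intron+synonymous
  figure counts variants or patients; this package implements the
  variant-row reading.)
* **Actionable profiling** matches stored protein HGVS against a
  registry of patterns (JSON asset; the bundled default covers EGFR
  p.Leu858Arg/p.Thr790Met, KRAS codon 12/13 wildcards, and conventional
  BRAF/NRAS/PIK3CA hotspots, the latter labeled as beyond the named
  set). A patient counts once per pattern and once per gene across
  patterns; optional stratification by condition uses per-condition
  denominators.
* **The waterfall matrix** orders genes by frequency (non-increasing)
  and patients hierarchically by mutation presence in gene order
  (memo-sort, ties by person id), and fills each cell with the single
  highest-priority class among that patient's variants in that gene.
  The priority order — nonsense > frameshift > splice > inframe >
  missense > synonymous > intron > other — is documented configuration:
  upstream tooling never states one, but the cell rule must be explicit
  to be testable. The order is a total order, so adding a lower-priority
  variant never changes a cell.

## Aggregate export and two-site comparison

`export_aggregate()` emits counts and denominators only — demographics,
per-gene patient counts, variant-type counts, actionable counts overall
and per condition, the panel list and a schema version — with
deterministic key order. No person, specimen or per-patient row appears
in the output, and the test suite scans the serialized report for
identifier leakage. Export is a homomorphism: the export of a pooled
database equals the element-wise sum of the per-site exports, which is
what makes "merge the site summaries" a sound distributed workflow.

Re-identification risk from small cells is mitigated by *k*-suppression:
with `suppression_k = k`, any count strictly between 0 and k is masked
as `"<k"`. Zero stays visible (it reveals no individual), and comparison
refuses to operate on suppressed cells rather than silently treating
them as numbers. Noise-injection differential privacy is out of scope.

Between-site contrasts use the Pearson chi-squared statistic without
continuity correction on the 2x2 table `[[a, n1-a], [b, n2-b]]`, df = 1,
delegated to `stats::chisq.test`; a table with a zero margin is a
degenerate-table error, not a silent zero. The significance threshold is
fixed at 0.05 with no multiplicity correction by default, matching the
reference analysis; a Bonferroni option exists but is off. Frequency
ratios are reported to two decimals.

## The synthetic generator: what it emulates and what it does not

The generator exists so that every analytic path can be exercised
without any access to protected patient data.

`table1_fixture()` reproduces the demographic *margins* of the two
reference cohorts exactly (N=114 panel site; N=1060 WES site), assigning
categories blockwise with deterministic person ids and representative
in-bin ages. Only margins are modeled — no age-by-stage joint structure.

`generate_cohort()` draws, per patient, each gene independently with its
`gene_probs` probability; a mutated patient-gene receives `1 +
Poisson(0.3)` variants (the extra-variant rate is configuration; its
purpose is to exercise deduplication and cell-priority rules, not to
model biology). Functional and structural classes are drawn
independently from two weight tables, and HGVS strings are generated
consistently with the functional class. `pattern_probs` carriers are
drawn independently of the background and receive a concrete variant
matching the pattern, with wildcards instantiated uniformly over the 19
non-reference residues.

`two_site_fixture()` fixes the study conditions of the two-site
comparison: site A (n=114) uses the panel cohort's published actionable
frequencies (p.Leu858Arg 0.175, p.Thr790Met 0.018, KRAS codon 12/13
totalling 0.097), an intron+synonymous-dominated functional mix (0.83
combined weight), and the full structural vocabulary including CNV and
translocation; site B (n=1060) uses the WES cohort's frequencies
(p.Leu858Arg 0.0264, KRAS codon 12/13 totalling 0.202), a
missense-dominated mix (0.73), and SNP/INDEL only. Because background
gene mutation and pattern carriage are independent draws, the EGFR
*background* probabilities are set so that the *marginal* EGFR frequency
matches the published site frequencies (0.870 at site A gives a marginal
of 1 − (1−0.870)(1−0.175)(1−0.018) = 0.895; 0.091 at site B gives
0.115). Per-gene probabilities beyond the handful printed in the
reference results are not knowable and are filled with a deterministic
spread; the fixtures are motivated by the reference cohorts, not
replicas of them. Site B's surrogate keys are offset by 10^6 so the two
sites can be pooled.

What the generator does *not* model: mutational signatures, positional
hotspot structure beyond `pattern_probs`, sequence context,
gene–gene or gene–demographic correlation, and panel-specific coverage
gaps. Tests passing on these cohorts therefore demonstrate the
correctness of the data model, ETL and analytics — not the biological
realism of any particular cohort.

## Numerical and reproducibility choices

* Percentages round half away from zero (half-up) to one decimal, and
  ratios to two decimals, matching the printed precision of the
  reference tables; base R's `round()` (half-even) is deliberately not
  used for these.
* All randomness flows through a single integer seed per cohort spec;
  generation saves and restores the caller's RNG state, and identical
  spec + seed yields byte-identical table dumps.
* Degenerate inputs fail loudly and specifically: empty cohorts, zero
  variants, degenerate 2x2 margins, unparseable HGVS (with the position
  of the first offending character), unknown gene symbols.
* Protein-HGVS parsing is memoized over distinct expressions, since
  database validation re-parses every stored expression on each load.
* Problem sizes used by the test suite — cohorts of 5–1060 patients,
  recovery checks at n=1000 over 5 seeds, pooling checks over 20 seeds,
  and a 100-replicate two-site simulation in the acceptance script — were
  chosen to keep statistical checks at 3-standard-error resolution while
  running comfortably on a laptop.

## Known limitations

* The OMOP `concept_id` machinery is intentionally replaced by
  string-coded controlled vocabularies; a mapping hook (the vocabulary
  tables in the schema asset) is the integration point for a real OMOP
  vocabulary service.
* No transcript-aware projection between `c.` and `p.` descriptions, no
  liftover between genome builds, and no coverage of the full variant
  nomenclature standard beyond the grammar above.
* Survival analysis is out of scope, as is any GUI; the command-line
  interface and the R API are the surfaces.
* The clinical tables carry only the fields this package reads; they are
  not a full OMOP implementation.
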