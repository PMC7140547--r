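---
title: "Measuring concordance across microbial reference genome databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concordance across microbial reference genome databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbconcord)
```

## The problem

Metagenomic classifiers identify organisms by comparing reads against a
reference database, and the major microbial reference databases (Ensembl,
RefSeq, JGI's 1000 fungal genomes project, FungiDB, PATRIC, ...) disagree
substantially about which taxa they contain. A researcher's choice of
database therefore changes which species can be detected at all. dbconcord
quantifies that disagreement: it harmonizes each database's catalogue to
NCBI taxonomic identifiers (taxIDs) at a chosen rank, partitions the union
of taxa by database membership, and summarizes how complete each database's
assemblies are.

All comparisons run on *catalogue manifests* — plain tables listing each
reference's accession, taxid and sequences — never on the sequence data
itself, so the analysis is cheap and reproducible.

## Harmonization model

Each reference's taxid is passed through three steps:

1. **Resolution.** Old taxids are redirected through the taxdump's merged
   map, applied transitively (`a -> b`, `b -> c` resolves `a` to `c`); a
   cycle in the merged map is treated as a corrupt dump. Taxids present in
   `delnodes.dmp` are *deleted*, taxids absent everywhere are *unknown* —
   both are excluded with a machine-readable reason rather than silently
   dropped.
2. **Rank projection.** The lineage is climbed from the node itself toward
   the root and the first node whose rank equals the requested label
   (case-insensitive, trimmed) is taken. Strains thereby collapse into
   their species, which is the only way to compare catalogues that
   disagree about strain labelling: NCBI does not assign strain-level
   taxIDs universally, so strain-level concordance is not computed at all.
   A node whose lineage contains *no* node at the requested rank (e.g. an
   isolate attached directly under a genus) is excluded with reason
   `no_ancestor_at_rank`.
3. **Set collapse.** Surviving taxids form the database's taxon set;
   duplicates (several references of one species) collapse under set
   semantics.

Every input record thus contributes to exactly one of the taxon set or the
exclusion report, so nothing is lost between input and output counts.

## Overlap partition statistics

For N databases with taxon sets $S_1,\dots,S_N$, every taxon in
$U=\bigcup_i S_i$ belongs to exactly one of the $2^N-1$ cells indexed by
the non-empty subset of databases containing it. From the cell sizes
follow:

* **exactly-k counts** $c_k = \sum_{|A|=k} |\text{cell}_A|$, with
  $\sum_k c_k = |U|$;
* **coverage** of database $i$: $100\,|S_i|/|U|$, reported both unrounded
  and rounded to the nearest integer percent (published figures print
  integers; tests compare the rounded value);
* the **consensus set**, the cell indexed by all N databases.

Cell keys are semicolon-joined database labels in input order, making
output deterministic and label-permutation equivariant (permuting the
inputs permutes keys but changes no count). The implementation assigns
each union element by a membership-matrix lookup; the test suite checks it
cell-by-cell against an independent per-element brute-force enumeration on
randomized instances, and the partition invariants (cells pairwise
disjoint, sizes summing to the union) on every run.

## Completeness classification

A reference with explicit sequence records is classified from its roles:
all chromosomes = COMPLETE, none = FRAGMENTED, both = MIXED. Scaffolds
count with contigs throughout — fragmented assemblies are treated as a set
of contigs without separating scaffolding state, and gap runs inside
scaffolds are not subtracted (lengths are raw residue counts). Catalogues
known only through assembly-level metadata (NCBI `assembly_summary`) map
"Complete Genome" to COMPLETE, "Chromosome" to MIXED (full chromosomes
present but the assembly is not closed), and "Scaffold"/"Contig" to
FRAGMENTED. When both are available, per-sequence roles win, since they
carry more information. Records with neither are counted as
unclassifiable and reported separately; percentages are over classified
records only.

Percentages default to *per reference*; `by = "taxon"` aggregates to taxa
first (a taxon is complete if any of its references is, else mixed if any
is mixed, else fragmented). Both conventions appear in published
comparisons of this kind, so both are offered, with per-reference as the
default unit of the profile figures.

Contig length statistics cover the contig and scaffold sequences of
FRAGMENTED and MIXED references; chromosomes are excluded. The default
histogram uses 50 equal-width bins from 0 to the observed maximum;
explicit breaks can be supplied.

## The synthetic generator

`simulationDesign()` + `simulateStudy()` emit a complete miniature study —
a taxdump in the exact NCBI dialect, one manifest TSV per database, and
the planted ground truth — so the entire pipeline can be validated by
recovery rather than by re-deriving expected values by hand.

What it emulates:

* a rank-structured taxonomy (genus -> species -> strain), with species
  per genus 1 + Poisson and strains per species Poisson;
* a planted overlap partition, specified either cell-by-cell or as an
  exactly-k vector whose cells are drawn uniformly among the size-k
  subsets;
* per-database completeness fractions (each reference's class is an
  independent categorical draw);
* lognormal contig lengths with per-database means;
* the messiness of real catalogues: a fraction of records cite strain
  children instead of species, a fraction cite old taxids redirected
  through `merged.dmp`, and (optionally) a fraction cite genus-attached
  "no rank" isolates that cannot be projected to species rank.

The defaults are the fungal study conditions: four databases, the
published exactly-k species partition (48/175/189/993, union 1405),
published complete/contig percentages per database with the remainder as
mixed, and published mean contig lengths (322/513/426/548 kbp). Values no
published figure pins down were chosen once as field-realistic and are not
tuned: log-scale standard deviation 1.2 (contig lengths in fungal
assemblies span several orders of magnitude), 30 contigs per fragmented
reference and 8 chromosomes per complete genome (keeps manifests at
realistic shape while small enough for fast tests), scaffold fraction
0.15, strain-emission probability 0.5, merged-id fraction 0.05. The
default taxonomy (786 genera, species per genus 1 + Poisson(1)) comfortably
exceeds the 1405 planted species; a design whose partition outgrows its
species pool is a usage error.

What it does **not** emulate: real nucleotide content (no sequences are
generated, only lengths), real per-database size imbalance (exactly-k
cells are assigned uniformly, so simulated coverage percentages do not
mirror any particular database's), database-specific accession schemes, or
taxonomies deeper than genus/species/strain. Passing recovery tests
therefore demonstrates that the pipeline's bookkeeping is exact under
realistic structure — not that any real database has a particular overlap.

All draws are ordered deterministically (databases, then records, then
sequences) from a single seeded stream, so emission is byte-identical
given a seed, and the random vectors have fixed shape so that changing one
fraction (e.g. `mergedFraction`) perturbs nothing downstream — that is
what makes the invariance tests exact rather than statistical.

## Numerical and design choices

* Rank labels compare case-insensitively after trimming: dump files are
  lowercase, user manifests often are not.
* Coverage keeps the unrounded value alongside the integer percent.
* An empty union makes coverage undefined (error), as does a profile with
  no classifiable record or a length summary with no contig/scaffold.
* Duplicate accessions within one manifest are an error; across manifests
  they are allowed (different databases legitimately reuse accessions).
* Exclusions never enter taxon sets: a taxon excluded in one database but
  present in another counts toward the union through the including
  databases only.
* FASTA scans read sequences as raw strings so that records with
  characters outside the IUPAC nucleotide codes are kept (with a warning)
  rather than rejected; header-keyword rules are applied in order, first
  match wins, default role contig.

## Validation problem sizes

The test suite validates the partition machinery against brute-force
enumeration on 100+ random instances (up to 5 sets, unions up to 500),
recovers the planted fungal-scale partition (1405 species, four
databases) exactly, recovers planted composition fractions within
binomial 99% bounds at 2000 references per database, and planted
lognormal length means within 3 standard errors at ~12,000 contigs. These
sizes make the full suite run in seconds while leaving the statistical
checks well-powered.

## Limitations

* Concordance is presence/absence of taxids; references sharing a taxid
  are not compared by sequence identity.
* Strain-level comparison is out of scope for the reason above.
* Published per-database composition percentages and contig means depend
  on database snapshots that are not part of any printed table, so they
  are validated by synthetic recovery, not reproduced.
* Only the NCBI taxonomy is supported; other taxonomy systems would need
  a mapping layer.
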