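---
title: "generepo: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{generepo: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generepo)
```

generepo is a headless repository for genomics experiments: it stores
structured experiment metadata next to uniformly processed molecular data so
that gene-centric questions ("how does GATA1 behave across every experiment,
in any species, under any condition?") can be answered across microarray and
sequencing assays alike. This vignette documents the models the package
implements, the parameters that matter, and the design decisions taken where
more than one defensible choice existed.

## The metadata model

Three content types carry the experiment metadata:

* **Experiment** — title, researcher, study design, publications, and a
  visibility level.
* **Bioassay** — one measured assay: measurement type (gene expression,
  histone modification, transcription-factor binding, RNA-seq; the registry
  is extensible at runtime), technology (microarray or sequencing), platform,
  and a reference to the raw data file. Platforms are mandatory for
  microarray assays because they anchor probeset identity.
* **Biomaterial** — the biological sample: organism (mandatory), development
  stage, tissue, cell type and disease state as controlled-vocabulary terms;
  sorting markers with polarity normalized to `{+, -, high, low}`; genetic
  modifications; age, sex, and free-text notes. Treatment is accepted either
  as a vocabulary term or free text, since real submissions use both.

Vocabularies are flat, editable term tables seeded with hematopoietic and
neurodegeneration terms (GMP, L-GMP, CMP, MEP, HSC, dopamine neuron,
Parkinson's disease, ...). There are no live ontology lookups; `term_id`
holds an external ontology identifier when known.

Accessions are sequential zero-padded identifiers (`EXP-0001`, `ASY-0001`,
`BIO-0001`, `CMP-0001`): stable, sortable, and independent of any external
scheme. Persistence is a directory of plain-text TSV tables behind
`repo_save()`/`repo_open()`; the schema is relational in shape (one row per
entity, one row per (assay, feature) value) while staying trivially
inspectable and diff-able.

### Visibility

Each experiment is `private` (default), `metadata_public`, or `public`. The
enforcement point is central: every query, fetch and export routine asks the
same two predicates (may this viewer see metadata? may it see data values?).
`metadata_public` lets collaborators discover that an experiment exists —
design, samples, assays — while fold changes, expression values and locus
scores stay hidden until publication. Exports follow suit: SOFT emits sample
blocks without data tables at `metadata_public`, and ISA-Tab (which carries
no data values) is available from `metadata_public` upward.

## The genomic data model

Genes carry a symbol, aliases, organism and an optional ortholog-group id
(HomoloGene-style: one group per gene at most). Transcripts belong to genes
and carry chromosome, strand, transcript bounds and exon models. Probesets
belong to a platform and map to at most one transcript; the same probeset id
may recur on different platforms. All coordinates are **0-based half-open**
(BED convention) throughout the core; any 1-based source must be converted at
the boundary. A single internal convention was chosen over per-format
handling to make off-by-one drift structurally impossible.

The transcription start site is `tx_start` on the `+` strand and `tx_end` on
the `-` strand. Windows "upstream/downstream of the TSS" are therefore
strand-oriented: upstream means 5' of the TSS in transcript orientation.

Symbol resolution is case-insensitive over symbols and aliases — human
`GATA1` and mouse `Gata1` must co-resolve — and optionally expands across
ortholog groups, returning the union of all genes sharing a group with any
directly matched gene. A matched-via field records which string matched;
alias and canonical matches are not ranked differently. Interval queries run
through an IRanges overlap index per chromosome.

## Processing

### Expression summarization

`summarize_expression()` is RMA-style: log2 transform, quantile
normalization across assays, then a median-polish collapse of each
probeset's probes (summarized value = fitted overall + column effect;
single-probe probesets pass through unchanged). A probe-sequence affinity
background model is deliberately absent: it would require the probe
sequences themselves, which the package does not ship, and the downstream
statistics only assume log2-scale summarized values.

### Differential statistics

For each feature, with case values $x$ ($n_1 \ge 2$) and control values $y$
($n_2 \ge 2$) on the log2 scale:

$$\text{log2FC} = \bar x - \bar y, \qquad
t = \frac{\bar x - \bar y}{s_p \sqrt{1/n_1 + 1/n_2}}, \qquad
s_p^2 = \frac{(n_1-1)s_x^2 + (n_2-1)s_y^2}{n_1+n_2-2}$$

with a two-sided p-value on $n_1+n_2-2$ degrees of freedom, a confidence
interval on the mean difference at `ci_level` (default 0.95), group means
and SDs, and Benjamini–Hochberg FDR computed jointly across all features of
the comparison. The pooled-variance Student t was chosen as the most
transparent classical default; the confidence level is configurable.
Degenerate inputs are pinned down explicitly: when both groups have zero
variance, equal means give $t = 0, p = 1$ and unequal means give an infinite
$t$ with $p = 0$. Because values are log2, the stored `log2_fc` equals
`mean_case - mean_control` exactly, and the store refuses records violating
that identity, the CI bracketing, or `fdr >= p` (step-up adjustment can only
raise a p-value).

A consequence worth stating plainly: at 3 vs 3 replicates the t reference
distribution has 4 degrees of freedom, and BH-corrected discovery of even
large effects is weak. With a planted effect of 2 log2 units and replicate
noise SD 0.5, the noncentrality is $2/(0.5\sqrt{2/3}) \approx 4.9$, but
recovering a 5% planted fraction among 1000 features at FDR < 0.05 requires
roughly $p \le 0.0025$, i.e. $|t| \ge 7.2$ at df 4 — an event of probability
only ~0.2 per planted feature. The package's own recovery simulations
reproduce this: sensitivity at FDR < 0.05 lands in the 0–15% range across
seeds (with essentially no false discoveries). High recovery at such depths
is the province of variance-moderated statistics, which pool information
across features; the plain t is kept as the default because it is exactly
checkable against classical references, and the limitation is documented
rather than papered over.

### FPKM scores

Both FPKM variants count a fragment by its **midpoint**: each alignment
belongs to exactly one window, so counts are additive, permutation-stable
and trivially checkable by a per-read loop. For a region of length $L$ bp
with $c$ in-window midpoints out of $N$ total alignments:

$$\text{FPKM} = \frac{c}{(L/1000) \cdot (N/10^6)}.$$

`window_fpkm()` scores the strand-oriented TSS window (default ±1 kb — the
standard promoter histone-mark window, configurable); `transcript_fpkm()`
counts midpoints falling in any exon and divides by the summed exon length.
A midpoint inside exons of several transcripts counts for each. Zero total
alignments and zero-length windows are errors, not silent zeros. Each BED
interval counts once; multi-mapping and duplicate-read handling are out of
model.

### Peak assignment

Each peak is anchored at its summit when present, else its midpoint. If the
anchor lies in one or more promoter windows (TSS ±1 kb by default), the peak
goes to the contained transcript whose TSS is nearest; otherwise to the
nearest TSS on the chromosome. Distance ties break on the lexicographically
smallest transcript id, and output rows are canonically sorted, so
assignment is invariant under any permutation of the inputs. Peaks on
chromosomes without transcripts are reported as unassigned, never fatal.
The per-gene peak score is the **maximum** over the gene's assigned peaks —
with no aggregation rule dictated by the data model, the max preserves "the
strongest binding signal at this gene" and is insensitive to peak-calling
granularity.

## Query and visualization tables

`gene_query()` resolves the symbol (ortholog-expanded by default), collects
fold-change records of the resolved genes' features across every experiment
whose visibility permits data access, attaches the sample context of each
comparison (taken from its first case assay's biomaterial), applies the
filters, and orders hits by `|log2_fc|` descending, then experiment id — a
convention chosen for reproducible pagination. Every filter is intersective:
adding one can only shrink the result.

`quantile_normalize()` replaces each column by rank-wise means of the
columns' sorted values; ties within a column receive the mean of the tied
ranks' reference values. Note the precise consequence of that tie rule:
on tie-free matrices the transform is idempotent and leaves all columns with
identical sorted values, but tied entries necessarily collapse to one shared
value, which perturbs the shared distribution — both behaviors are asserted
in the test suite. Heatmap rows are one per probeset, labeled
`symbol|probeset`; probesets of the same gene are never silently averaged.

`scatter_table()` joins up to four gene-keyed channels: inner join on x and
y, left join for color and size. Expression and FPKM channels aggregate to
the gene by the mean over the gene's probesets/transcripts; peak channels
use the per-gene max, consistent with the peak-score rule. Errors
distinguish a channel that is *hidden* (visibility) from one that is
*absent* (no gene-linked values). Rendering is deliberately out of scope:
the correctness surface is the table, and any plotting layer is a thin
consumer of it.

## Interoperability

* **SOFT** (GEO family-file dialect): `^SERIES`/`^SAMPLE`/`^PLATFORM`
  entities, `!key = value` attributes (order-preserving, unknown keys pass
  through verbatim), `#column` descriptions, and
  `!*_table_begin`/`!*_table_end` data tables. Import maps
  `!Sample_characteristics_ch1 = key: value` lines onto biomaterial fields
  through an editable YAML table (`cell type`, `tissue`, `disease state`,
  `age`, `sex`/`gender`, ...); unmapped characteristics land in the notes so
  imports are loss-tolerant, and organism is the one mandatory mapping.
  Numeric values are printed with 17 significant digits, so doubles
  round-trip exactly.
* **ISA-Tab v1**: investigation/study/assay triplet targeting structural
  validity — required investigation sections, one study row per biomaterial
  with `Characteristics[...]` columns, one assay row per bioassay,
  rectangular tab-separated tables with quoting. Running an external
  validator remains a manual check, not a test dependency.
* **GCT 1.2**: `#1.2`, dims line, `Name`/`Description`/assay columns, gene
  symbol as description (`NA` when unannotated). A small independent reader
  (`read_gct()`) exists for verification.
* **BED**: 3+ columns, 0-based half-open, strand from column 6 when present,
  user-flagged score and summit columns, per-line parse errors. All text I/O
  is UTF-8 with Unix line endings on write; both line-ending styles are
  accepted on read.

## The synthetic-data generators

The generators exist so that every downstream computation can be validated
against planted truth without any external download. They are pure functions
of `(spec, seed)`: identical inputs give byte-identical outputs.

* **Toy genome**: one chromosome per organism, TSS every 10 kb (so default
  promoter windows never overlap), alternating strands, one 2 kb transcript
  with two 800 bp exons per gene, one probeset per transcript per
  per-organism platform, and one cross-organism ortholog group per gene
  index. Symbols are organism-cased variants of a shared family name with
  per-organism aliases, exercising case-insensitive and alias resolution.
* **Expression**: per-gene baselines uniform on [4, 12] log2 (the bulk of a
  typical summarized array's dynamic range), planted effects of ±2 log2
  units on 50 of 1000 genes by default, replicate noise Normal(0, 0.5) —
  a clean two-group design at 3 vs 3 replicates.
* **ChIP**: fragments uniform over the chromosome except in enriched TSS
  windows, where density is `enrichment_factor` (default 10) times
  background; fragment length 200 bp; default library 300,000 fragments,
  sized so an enriched window expects on the order of 100 fragments. That
  depth keeps the Poisson noise on a window's log2 count near
  $1/(\lambda \ln^2 2) \approx 0.03$, small against the planted per-gene
  mark variance of 1.
* **Coupling**: per-gene expression effects and log2 mark changes are drawn
  from a Gaussian copula with latent correlation $r = 2\sin(\pi\rho/6)$,
  which makes the *population* Spearman correlation exactly the requested
  $\rho$. The expression effects are scaled to SD 2 log2 units and the mark
  change splits symmetrically around an 8x baseline enrichment between the
  two chromatin states. With those scales, estimation noise attenuates the
  pipeline-recovered Spearman by a factor of roughly
  $\sqrt{R^2_x R^2_y} \approx 0.96$ (effect variance 4 against a
  squared standard error of ~0.17 on the fold change; mark variance 1
  against ~0.06 of Poisson log-count noise across two libraries), so a
  planted $\rho = 0.7$ is recovered near 0.66–0.67 at 2000 genes.

What the simulations deliberately do **not** model: probe-level affinity
structure, batch and lab effects, GC and mappability bias, multi-mapping
reads, overdispersed (non-Poisson) fragment counts, correlated genes, and
isoform mixtures. Passing recovery tests on these fixtures therefore
demonstrates that the implementations compute what they claim on data
matching their assumptions — not that those assumptions hold on any
particular real dataset.

## Validation problem sizes

The shipped checks run oracle comparisons at sizes chosen to balance
coverage against a single-CPU run: 1000-feature sweeps against classical
t-test/BH references (agreement to 1e-9), 100 seeded random fixtures for
the FPKM and peak-assignment brute-force oracles, 50 random matrices for
the quantile-normalization oracle, a 10,000-feature null simulation for CI
coverage, the 1000-gene planted-recovery study, the 2000-gene coupled
simulation, and 100 randomized SOFT round-trip experiments.

## Known limitations

* One transcript per probeset; many-to-many probeset mappings are not
  modeled.
* Paralogs beyond the one-group-per-gene ortholog model are out of scope.
* Sequencing fold changes reuse the same two-sample statistics on
  `log2(FPKM + 1)`; count-based models (negative binomial) are not
  provided.
* The plain Student t is underpowered at 2–3 replicates per group (see
  above); users needing sensitive small-n discovery should export the
  matrices and use a variance-moderated method.
* ISA-Tab export targets structural validity, not semantic ontology
  annotation; SOFT support covers the family-file dialect subset described
  above, not MINiML.
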