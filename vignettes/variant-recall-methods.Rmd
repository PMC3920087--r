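---
title: "Measuring recovery of curated variants from article sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring recovery of curated variants from article sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varminer)
```

## The question the package addresses

Curated variant databases link each catalogued mutation to the
publication it was curated from. If a pattern-based mention extractor
is run over those same publications, what fraction of the curated
(article, gene, variant) triples does it recover — and from which part
of the publication: the abstract, the narrative full text, the tables,
or the supplementary files? `varminer` implements the full measurement
apparatus for that question: document ingestion, mention extraction,
HGVS normalization, triple matching with four recall metrics, a
MeSH-based high-throughput classifier, and a synthetic corpus generator
that makes every metric analytically checkable at desk scale.

Real corpora of this kind (bulk MEDLINE/PMC retrieval, database dumps
with hundreds of thousands of rows) are deliberately out of scope; the
package consumes local files in simplified, fixed formats and ships a
generator that emulates the statistical structure of such corpora.

## Matching model

The unit of comparison is the triple (article id, gene, variant). A
curated record carries a DNA variant (HGVS `c.` notation), a protein
variant (one-letter `A140T` notation), or both; it counts as recovered
when some extracted triple from the same article matches the gene and
is equivalent to *either* variant. Gene identity prefers HGNC-id
equality when both sides carry an id, otherwise case-folded symbol
equality. Four metrics are reported:

* **recall** — matched records over all curated records;
* **recall NG** — the gene requirement dropped, absorbing gene-name
  normalization failures;
* **recall common** — the denominator restricted to *common articles*:
  articles the extractor actually processed that have at least one
  curated record and at least one extracted triple;
* **recall common NG** — both relaxations.

The first two differ only in the numerator test, the last two only in
the denominator, which gives the invariants `recall <= recall_ng` and
`recall <= recall_common` that the test suite asserts on every
generated corpus.

Duplicate curated rows (identical article, gene and variants) are
deduplicated before any denominator is computed: recall is over
distinct curated facts. Whether the original studies deduplicated
repeated database rows is not documented anywhere we could rely on;
deduplication is this package's recorded choice.

## Variant equivalence and its relaxations

Canonical forms are `c.<pos><wt>><mut>` for cDNA substitutions,
`c.<start>_<end><op><payload>` for indels (hyphen range separators are
rewritten to underscores), and `<wt1><pos><mut1>` for protein
substitutions with `*` for stop codons. Equivalence between two
normalized variants is string equality plus, under configuration flags
(`match_config()`):

* `del_length_equivalence` — a deletion written with its base string
  equals one written with the base count at the same position(s):
  `c.482_483delGA` ≡ `c.482_483del2`. Off by default, because the two
  spellings are not interchangeable in the strict nomenclature.
* `codon_expansion` — a substitution located only by codon number
  expands to its three candidate nucleotide positions
  (`3c-2, 3c-1, 3c`) with the stated alleles; matching succeeds when a
  candidate coincides with the curated string. Expansion produces
  positions *and* alleles when the alleles are stated, and the
  implementation matches on the full candidate strings; a
  position-only interpretation would over-match.
* `rsid_expansion` — dbSNP rs-numbers expand through a local lookup
  table into their candidate DNA/protein variants. A live dbSNP query
  is out of scope by design.
* `ignore_gene` — implements the NG metrics.

All relaxations are monotone: enabling a flag can only turn non-matches
into matches, never the reverse.

Two equivalences are deliberately **not** implemented. Insertion-to-
duplication canonicalization (`840insT` versus `c.839dupT`) requires
the reference sequence, which the package does not have; such pairs do
not match. Curator-corrected positions (an offset fixed by hand in the
database) likewise do not match. Intronic-offset positions such as
`1410-54` are carried verbatim as opaque tokens and compared as
strings; offset arithmetic is out of scope.

## Mention patterns

The extractor is a deterministic pattern scanner, not a statistical
tagger. Its classes (`pattern_config()`, each independently
toggleable): canonical cDNA substitutions tolerant of a missing dot, a
missing `c.` prefix and spaces around `>` (`c.676C>T`, `c580G > T`,
`676C>T`); the legacy letter–digits–letter form, read as cDNA when both
letters are nucleotides and differ (`C676T`) and as a one-letter
protein substitution otherwise; three-letter and `p.`-prefixed protein
substitutions (`Ala140Thr`, `p.G12D`); cDNA indels with base-string or
count payloads (`c.597_598delGA`, `c.501del1`, `840insT`); extended
protein indels (`p.Glu554_Val559del`, `delins`); rs-numbers; natural-
language substitutions ("C > T mutation at nucleotide 2131", also with
"codon" positioning); and imprecise exon/intron-level deletions ("Del
exon 3", "entire gene deletion"), which are recognized but dropped at
normalization because no precise position can be derived from them.

Overlapping candidate matches are resolved leftmost-start first, then
longest — a deterministic rule standard for pattern scanners. One-letter
amino-acid and nucleotide codes are matched uppercase-only for
precision; three-letter codes case-insensitively. Scanning is monotone
in the enabled class set, which the tests assert.

Gene mentions come from case-insensitive, longest-match dictionary
lookup over word-boundary tokens. The dictionary constructor removes
stop-listed surface forms (gene names colliding with codon names) and
guarantees the alias `P53` for TP53, which the usual source
dictionaries lack. An optional flag additionally resolves legacy
`h`-prefixed names (`hMLH1`); it is off by default so that both the
stricter and the more permissive behaviour can be reproduced.

Mentions and genes are associated at document scope: within one source
kind of one article, every mention pairs with every distinct gene
symbol, so one mutation may yield several triples and a mention with no
co-occurring gene keeps an absent gene. Sentence-scope association
exists for comparison and uses a deliberately naive splitter (terminal
punctuation followed by whitespace), since document scope is the
operating mode.

## Document ingestion

Abstracts arrive as MEDLINE-style XML (entities decoded, inline tags
stripped, whitespace collapsed), full text as a simplified JATS-style
subset: `article`/`body`/`p` paragraphs, `table-wrap` with `caption`
and `tr`/`td` rows, `ref-list` excluded, anything else ignored with a
warning. A fixed subset keeps the format testable; documents with an
abstract but no body paragraphs are flagged rather than silently
processed. Tables are linearized caption-first, cells row-major, joined
by tab characters — a separator that cannot occur inside any supported
mention, so linearization can neither create nor destroy mentions. How
multi-row-header tables should be linearized is genuinely open; the
row-major rule is this package's recorded choice.

Footnote marks on table cells (superscript characters such as
`1704_1705delᵉAGᵇ`) are declared per table — in the XML as a
`footnote-marks` attribute — and stripped from cell payloads before
scanning. Auto-detection of marks is under-specified and not attempted.
Supplementary files are consumed as TSV/CSV with field boundaries
preserved as tabs; PDF-only full text is consumed as pre-extracted
plain text (`pdf_text`), never as PDF bytes.

## High-throughput classification

An article is high-throughput (HT) when any of its MeSH descriptors
lies at or below one of six seed positions (Computational biology
H01.158.273.180, Genetic techniques E05.393, Genome G05.360.340,
Molecular sequence data L01.453.245.667, Proteome D12.776.817,
Proteomics H01.181.122.738). The descendant test is a dotted-prefix
test on tree codes, which is equivalent to walking the materialized
hierarchy by construction of MeSH tree numbers; the tests assert that
equivalence against an independent closure oracle over the shipped
synthetic descriptor table. Articles with no headings are `UNINDEXED`
and can be excluded from the split denominators by flag. Historical
MeSH vintages (headings introduced after an article was indexed) are
documented behaviour of real MeSH, not modelled here.

## The synthetic corpus generator

The generator (`generator_config()`, `generate_corpus()`) defines the
study conditions under which the package is exercised:

* **Per-article mutation counts** follow a two-group mixture: non-HT
  articles draw from Poisson(λ = 7), matching the scale of small
  curation-driven studies; HT articles draw from a log-normal
  (meanlog 4.6, sdlog 1.1, median ≈ 100, mean ≈ 180), so that a small
  fraction of articles carries the large majority of mutations — the
  defining feature of somatic-mutation corpora, where a handful of
  genome-scale studies dominates the database while conventional
  articles contribute a few mutations each. The default HT article
  fraction is 0.2.
* **Placement**: each mutation is rendered in exactly one source,
  drawn as abstract 0.15 / body 0.25 / table 0.10 / supplement 0.50 —
  supplementary material dominating, as observed for curated somatic
  variants. `pdf_text` has weight 0 by default and is exercised by
  dedicated tests.
* **Format mix**: canonical HGVS 0.55, legacy no-dot 0.10, natural
  language 0.05, codon-positioned 0.05, exon/intron-level 0.05,
  field-split 0.15, deletion-by-count 0.05 — mirroring the variety of
  spellings found when curated mentions are traced back to their
  articles, including the two classes that are unrecoverable by
  construction (exon-level mentions carry no position; field-split
  supplement rows spread position, wild-type and alternate allele over
  separate TSV columns, so no scannable mention string exists).
* **Noise**: declared footnote marks decorate table cells at rate 0.2;
  optional `h`-prefixed gene renderings; distractor mentions
  (true-but-uncurated variants, mean 0.3 per article) drawn from a
  position space disjoint from curated records so they can change
  diagnostic precision but never recall.
* **Consistency**: each gene gets a synthetic random coding sequence
  (2000 codons); DNA substitutions take their wild-type base from it
  and their protein consequence through the standard genetic code, so
  DNA and protein forms of a record cohere. Positions are drawn without
  replacement within an article, so no two records of one article share
  a variant string and per-record recovery is analytically exact.

Everything is a pure function of the configuration, including its seed;
two runs produce byte-identical files.

The companion oracle `expected_recall()` computes, from the truth
manifest alone — no rendering, no scanning — the recall report the
pipeline must produce: a record is recovered from a source set when
some planted mention of an equivalent variant in a recognizable format
occurs there in the same article and the record's gene is mentioned in
the same source (sources never share gene–mention association, so a
set matches when a member source does). The acceptance tests require
*exact* equality between the measured pipeline and this oracle, with
and without noise and across relaxation flags.

What passing these tests shows — and does not show. The generator
produces template prose, single-source placement and a closed gene
dictionary. It does not emulate real biomedical narrative, OCR noise,
abstract/full-text redundancy (each mention exists in exactly one
source, so the abstract-versus-full-text precision diagnostic is near
zero on synthetic corpora, unlike on real articles where abstracts
mostly repeat full-text content), genome-build discrepancies, or
chromosome-offset variant reporting. Exactness on synthetic corpora
validates the machinery, not extraction performance on real text.

## Numerical and engineering choices

* Matching is implemented as a key join on (article, variant-key)
  pairs, with alternate and deletion-length keys generated per
  relaxation flag; an exhaustive double-loop matcher in the test suite
  serves as the independent oracle on instances up to 100 records.
* Degenerate substitutions (wild type equal to mutant) are rejected at
  normalization; unparseable or unknown tokens drop the mention rather
  than abort a corpus run.
* Problem sizes in the tests: oracle equivalence uses 20 corpora of 12
  articles; parameter-recovery and heavy-tail checks use 500-article
  corpora, the size at which all distributional statements stabilize
  while a full run stays in tens of seconds.
* Thresholded reporting groups articles at ≤10, ≤20, ≤30 and >30
  curated mutations, the grouping conventional for separating
  conventional from high-throughput contributions.

## Command-line use

`inst/cli/varminer` is a thin Rscript over the exported functions with
subcommands `generate`, `evaluate` and `classify-ht`, a single YAML
configuration file (all flags overridable on the command line), and
exit codes 0 (success), 2 (configuration error), 3 (data error).
`scripts/acceptance.R` regenerates the default corpus and reports the
headline quantities as JSON.

## Known limitations

Beyond the explicit non-goals (no statistical NER, no live database
queries, no PDF/Office binary parsing, no genome liftover): the
full-HGVS grammar is not covered, only the constructs catalogued above;
the sentence splitter is naive; the gene dictionary shipped for
synthetic use is small, and real analyses should load a full
HGNC-derived table; and recall against real databases would require the
corpus-collection machinery this package intentionally replaces with
fixtures.
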