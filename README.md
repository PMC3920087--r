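# varminer

Curated variant databases (COSMIC-style somatic catalogues,
locus-specific databases such as the mismatch-repair gene registries)
link every catalogued mutation to the publication it was curated from.
`varminer` measures how much of such a database a pattern-based text
miner can recover from each part of those publications — the abstract,
the narrative full text, the tables, pre-extracted PDF text, and the
supplementary files — and quantifies why the remainder is missed.

It is aimed at biocuration and text-mining researchers who want a
reproducible, desk-scale testbed for variant-recovery experiments
rather than a production curation system.

## What it computes

The matching unit is the triple *(article id, gene, variant)*. A
curated record — gene plus a DNA variant `c.676C>T` and/or a protein
variant `A140T` — counts as recovered when an extracted triple from the
same article matches the gene and is equivalent to either variant.
Per source set *S* the package reports

```
recall        = |matched records| / |curated records|
recall_NG     = same, gene requirement dropped
recall_common = numerator unchanged, denominator restricted to articles
                with >= 1 curated record and >= 1 extracted triple in S
recall_cmnNG  = both relaxations
```

Variant equivalence is canonical-string equality plus configurable,
monotone relaxations: deletion-length equivalence
(`c.482_483delGA` ≡ `c.482_483del2`), codon-position expansion (codon
*c* → nucleotide positions 3c−2..3c), and rs-number expansion through a
local lookup. Articles are additionally labelled high-throughput (HT)
when any of their MeSH descriptors descends from six seed tree codes
(e.g. Genetic techniques, `E05.393`), and all statistics can be split
by that label or by per-article mutation-count thresholds.

A synthetic corpus generator renders a curated database into article
bundles with controlled placement, format mix and noise, together with
a ground-truth manifest from which `expected_recall()` computes the
exact report the pipeline must reproduce.

## Worked example

```r
library(varminer)

normalize_protein_sub("Ala", 140, "Thr")$hgvs
#> [1] "A140T"
normalize_indel("c.597-598delGA")$hgvs
#> [1] "c.597_598delGA"

corpus <- generate_corpus(generator_config(n_articles = 100, seed = 42))
corpus
#> <variant_corpus> 100 articles, 3343 curated records, 17 HT articles

res <- evaluate_corpus(corpus$bundles, corpus$curated)
res$per_source[, c("source_set", "matched", "recall", "recall_common")]
#>   source_set matched recall recall_common
#> 1   abstract     396 0.1185        0.1226
#> 2       body     644 0.1926        0.1978
#> 3   pdf_text       0 0.0000            NA
#> 4      table     236 0.0706        0.0808
#> 5 body+table     880 0.2632        0.2676
#> 6 supplement    1274 0.3811        0.3847
#> 7        all    2549 0.7625        0.7625
```

Supplementary material recovers more curated variants than every other
source combined, and the union of all sources reaches 0.76 — the
shortfall being exactly the mentions rendered in unrecoverable formats
(exon-level positions, variants split across supplement columns). The
report is certified against the analytic oracle:

```r
exp <- expected_recall(corpus$manifest)
all.equal(as.data.frame(res$per_source),
          as.data.frame(exp)[, names(res$per_source)])
#> [1] TRUE
```

The high-throughput split shows the count concentration the generator
emulates — 17% of articles carry 82% of the mutations:

```r
labels <- label_corpus(corpus$mesh, default_mesh_descriptors())
split_corpus(corpus$curated, labels)[, c("label", "n_docs_with_mut",
                                         "n_mutations", "mutation_share")]
#>   label n_docs_with_mut n_mutations mutation_share
#> 1   NHT              83         610          0.182
#> 2    HT              17        2733          0.818
```

## Command line

```sh
inst/cli/varminer generate    --config cfg.yaml --out corpus/
inst/cli/varminer evaluate    --config cfg.yaml --corpus corpus/ --out reports/
inst/cli/varminer classify-ht --config cfg.yaml --corpus corpus/ --out reports/
```

Reports are written as TSV and JSON; exit codes are 0 (success),
2 (configuration error), 3 (data error).

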