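---
title: "Promoter and flank extraction: model, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter and flank extraction: model, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promex)
```

## What the engine computes

`promex` operationalizes "promoter" as a fixed-length flank of the annotated
gene interval: for a gene occupying the 1-based inclusive interval
$[s, e]$ on a chromosome of length $N$, with upstream window length $L$ and
downstream window length $M$,

* plus strand: upstream $= [s-L,\; s-1]$, downstream $= [e+1,\; e+M]$, both
  read from the forward strand;
* minus strand (with strand orientation on, the default): upstream
  $= [e+1,\; e+L]$ and downstream $= [s-M,\; s-1]$, each reverse-complemented,
  so that "upstream" is always the 5′ side of the gene on its own strand —
  the biologically meaningful reading for promoters.

This is deliberately an *annotation-anchored* definition. Flanks are anchored
at the representative record's start/end coordinates, not at an inferred
transcription start site: for most plant annotations the `gene`/`mRNA`
interval begins at the TSS anyway (UTRs included), and inferring a TSS from
child features would make the result depend on annotation completeness in a
way the user cannot audit. Users who want TSS-anchored windows can supply an
annotation whose `gene` rows are TSS-anchored; the arithmetic is unchanged.

The per-run accuracy statistic is the per-side **error rate**

$$\mathrm{error\ rate} = \frac{\text{total genes} - \text{flanks extracted}}{\text{total genes}} \times 100\,[\%],$$

the percentage of requested genes for which a given side's flank was not
extracted. A flank counts as extracted when its status is `complete` or
`truncated`.

## The pipeline, stage by stage

1. **Identifier normalization.** Requested ids are whitespace-trimmed; with
   version stripping on (default), a terminal `.<digits>` suffix is removed
   to form a fallback key. Both keys participate in matching. This absorbs
   the ubiquitous mismatch between transcript-versioned gene lists
   (`Glyma.01G000100.1`) and unversioned annotation `ID`s.
2. **Feature filtering.** Only rows whose type is in `feature_types`
   (default `gene`, `mRNA`) are considered; a feature's identifier is the
   value under the first present key of `id_attribute_keys` (default `ID`,
   `Name`, `gene_id`, `locus_tag` — covering GFF3, GTF and GenBank-derived
   annotations). A feature is a candidate for a gene when either side
   matches exactly or after version-stripping of either side.
3. **Representative selection.** When several rows match one gene, the rule
   is: prefer the earliest type in `feature_types` (so `gene` beats
   `mRNA`), then the earliest row in file order. The paper-level requirement
   is only that *one* record is chosen; determinism demands a total order,
   and file order is the only one every annotation carries.
4. **Flank extraction.** All interval arithmetic and all sequence slicing
   run as vectorized column operations over the table of representative
   records — one batch pass over in-memory chromosome strings, no per-gene
   re-read of any input file.
5. **Summary.** Per-side status counts, the two error rates, unmatched-id
   and missing-chromosome counts.

Per-gene failures never abort a run: they become statuses
(`skipped_boundary`, `missing_chromosome`) and summary counts. Only fatal
I/O or parse errors (missing file, empty FASTA, duplicate chromosome ids,
an annotation with zero well-formed lines) stop the program.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `up_len` | 2000 | bp | standard promoter-scan window; the common default in regulatory-genomics practice |
| `down_len` | 2000 | bp | independently settable: downstream elements do occur, but users often want asymmetric windows |
| `boundary_policy` | `skip` | — | a short flank is *not* the promoter the user asked for; failures are counted, not silently shortened. `truncate` is offered for users who prefer partial sequence |
| `feature_types` | `gene,mRNA` | — | the two types that carry gene-level coordinates in practice; order doubles as selection preference |
| `id_attribute_keys` | `ID,Name,gene_id,locus_tag` | — | covers GFF3, GTF and GenBank-style attribute vocabularies |
| `strip_version_suffix` | `TRUE` | — | transcript-versioned ids are the rule, not the exception, in downloaded gene sets |
| `orient_by_strand` | `TRUE` | — | 5′-orientation is what "promoter" means; the flag exists because some downstream tools expect raw forward-strand windows |

## Numerical and convention choices

* **Coordinates** are 1-based inclusive throughout — the GFF3 convention —
  including in the output CSV. Internal arithmetic never converts to
  0-based/half-open, eliminating the most common off-by-one source.
* **Zero-length windows** (`L = 0` or `M = 0`) yield the empty string with
  status `complete`, even flush against a chromosome end: an empty request
  cannot fail.
* **Truncation to an empty window**: under `truncate`, a window lying
  entirely outside the chromosome (a gene starting at position 1, say)
  clips to the empty string with status `truncated`. The status, not the
  sequence length, is the reliable failure signal.
* **Strand `.` or `?`** is treated as `+` with a logged note — a window must
  still be computable, and forward-strand is the only neutral choice.
* **Unmatched ids** are reported in the summary and excluded from the CSV:
  the output stays purely positive results, and the conservation identity
  `complete + truncated + skipped_boundary + missing_chromosome + unmatched
  = total requested` holds per side on every run.
* **Gene coordinates in the CSV** are the representative record's, never
  modified by flank clipping.
* **Sequence case and ambiguity codes** are preserved verbatim end-to-end
  (soft-masked lowercase survives extraction and reverse complement), which
  is why chromosomes are held as raw strings rather than a coerced
  DNA alphabet.
* **Error-rate reporting**: summaries print rates to 2 decimal places. The
  bundled eight-dataset validation counts reproduce their published summary
  statistics (means 3.07% / 3.05%, maxima 9.61% / 9.50%) when the mean is
  truncated — not rounded — to 2 d.p.; the exact means are 3.0780% and
  3.0578%. The acceptance machinery states both.

## The annotation parser

The GFF3 reader is deliberately tolerant: comment and blank lines are
skipped, malformed data lines (wrong column count, non-numeric or inverted
coordinates) are counted and skipped with a warning rather than aborting,
and attributes are accepted in both GFF3 `key=value` and GTF `key "value"`
syntax with URL-percent-decoding and first-occurrence-wins duplicate keys.
Real-world annotations — especially for the non-model genomes this tool
targets — routinely contain all of these defects; a parser that aborts on
line 400,000 of a 60,000-gene annotation helps no one. The accounting is
lossless: parsed + malformed + comment lines sum to the file's line count.

## The synthetic fixture generator

`generate_fixture()` emulates the full input triple at desk scale with
planted ground truth, so the entire pipeline is testable with no downloads:

* i.i.d. uniform A/C/G/T chromosomes (default two of 15 kb);
* non-overlapping genes (default 50 of 100–400 bp) with full flank
  clearance, a configurable minus-strand fraction, and 0–2 `mRNA` child
  rows per `gene` row;
* a configurable number of **boundary genes** planted closer than
  `flank_len` to a chromosome end on their upstream-oriented side (left end
  for `+`, right end for `-`), so under the `skip` policy exactly the
  planted number of upstream extractions fail;
* decoy annotation rows (`exon`, `CDS`, `tRNA`, UTR) — half reusing real
  gene ids — to exercise the type filter;
* version-suffixed requested ids with configurable probability, to exercise
  fallback matching;
* recorded true flanks computed by direct string slicing (with
  `Biostrings::reverseComplement` as an independent reverse-complement
  path), making the generator its own oracle.

The same seed produces byte-identical files (the RNG kind is pinned).

What the generator does **not** emulate: realistic base composition (GC
skew, repeats, isochores), gene structure (introns, UTRs), overlapping or
nested gene models, and annotation defects beyond those the parser tests
construct directly. Passing the fixture suite therefore demonstrates
coordinate, strand, matching and boundary correctness — not robustness to
every pathology of real annotations, which is covered separately by the
parser's unit tests and by the tolerant-parsing design above.

## Verification strategy and problem sizes

The test suite checks the engine against an independent naive oracle — a
character-by-character slicer with a lookup-table reverse complement,
sharing no code with the vectorized path — across 1,120 randomized cases
(genomes up to 5 kb; both strands; both boundary policies; window lengths
0, 1, 7 and 100 bp), and verifies 100% byte-identical recovery of planted
flanks across five fixture seeds (40 genes each), the conservation
identity, exact boundary-failure accounting, byte-level determinism of
repeated runs, and the 2,000 bp default-window contract. Fixture sizes were
chosen as the smallest at which every code path (both strands, both ends,
decoys, version suffixes, multiple chromosomes) is exercised with
comfortable margins.

## Known limitations

* Chromosomes are held in memory as R strings; genomes of several Gb will
  want a machine with commensurate RAM (the batch design keeps only one
  copy).
* One representative record per gene means genes with several well-separated
  isoform TSSs yield one window, anchored at the chosen record.
* The error-rate statistic counts extraction failures only; it says nothing
  about annotation quality (a wrong gene model extracts "successfully").
* No motif scanning, TFBS prediction, or primer design — the output CSV is
  designed to feed such tools, not replace them.
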