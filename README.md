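# promex

Batch extraction of gene promoter and flanking sequences from genome
assemblies.

## The problem

Promoters — the regulatory regions immediately 5′ of a gene that recruit the
transcriptional machinery — are the usual starting point for studies of gene
regulation: motif and transcription-factor-binding-site scans, primer design,
comparative analyses of regulatory conservation. Getting the sequences is
conceptually trivial and practically fiddly: genome browsers and web
databases only cover annotated model organisms and work one gene at a time,
while general interval tools require manual preprocessing and leave the
strand and chromosome-edge bookkeeping to the user.

`promex` does the whole job in one pass for arbitrary gene lists against
user-supplied assemblies, including newly sequenced or fragmented genomes.
Given three inputs —

1. a **genome FASTA** (multi-record, any line wrapping, `.gz` accepted),
2. a **gene FASTA** whose headers carry the identifiers of interest, and
3. a **GFF3 annotation** (GTF-style attributes are also tolerated),

it extracts, for every requested gene, an upstream and a downstream flanking
window (default 2,000 bp each, independently configurable) and writes a
structured CSV plus a run summary.

## The method

For each requested identifier the engine:

1. normalizes the id (whitespace trim, optional `.<digits>` version-suffix
   fallback, so `Glyma.01G000100.1` still matches an annotation row whose
   `ID` is `Glyma.01G000100`);
2. matches it against `gene`/`mRNA` annotation rows via the first present
   attribute key among `ID`, `Name`, `gene_id`, `locus_tag`;
3. selects a single representative record (`gene` preferred over `mRNA`,
   then earliest in file order);
4. extracts strand-aware flanks by pure coordinate arithmetic on the
   1-based inclusive GFF3 convention. With window lengths *L* (upstream) and
   *M* (downstream), gene interval *[s, e]* on a chromosome of length *N*:
   - `+` strand: upstream = `[s−L, s−1]`, downstream = `[e+1, e+M]`;
   - `−` strand: upstream = `[e+1, e+L]`, downstream = `[s−M, s−1]`, both
     reverse-complemented so "upstream" always means 5′ of the gene on its
     own strand (disable with `--no-strand-orient`);
   - windows crossing a chromosome end are either **skipped** (that side is
     reported as a failure; the default) or **truncated** to `[1, N]`.

All window arithmetic and sequence slicing run as vectorized column
operations over the matched record table — a single batch pass, with no
per-gene rescan of the genome.

The run summary reports, per side, the extraction **error rate**

```
error rate (%) = (total genes − flanks extracted) / total genes × 100
```

i.e. the percentage of requested genes whose flank could not be extracted
(typically genes too close to a chromosome or scaffold end to fit the
requested window).

## Worked example

The package includes a deterministic fixture generator that emulates the
input triple with planted, recorded ground-truth flanks (used throughout the
test suite):

```r
library(promex)

fx     <- generate_fixture(fixture_spec(seed = 11), "example_fixture")
store  <- read_genome(fx$paths$genome)     # 2 chromosomes, 15 kb each
ids    <- read_gene_ids(fx$paths$genes)    # 50 requested gene ids
feats  <- read_gff(fx$paths$gff)           # gene/mRNA rows + decoys

res <- extract_promoters(store, ids, feats,
                         extraction_params(up_len = 200, down_len = 200))
print(res$summary)
#> Promoter extraction summary
#>   Total genes requested     : 50
#>   Upstream flanks extracted : 47
#>   Downstream flanks extracted: 50
#>   Upstream error rate       : 6.00%
#>   Downstream error rate     : 0.00%
#>   Unmatched gene ids        : 0
#>   Missing chromosomes       : 0

head(res$promoters[, c("gene_id", "chromosome", "start", "end", "strand", "status")], 4)
#>      gene_id chromosome start   end strand                            status
#> 1   SYNG0001       chr1    34   382      + up=skipped_boundary;down=complete
#> 2 SYNG0002.2       chr1 14566 14848      - up=skipped_boundary;down=complete
#> 3   SYNG0003       chr1   468   710      +         up=complete;down=complete
#> 4   SYNG0004       chr1   781   992      -         up=complete;down=complete

write_promoter_csv(res$promoters, "promoters.csv")
```

This fixture plants 3 genes deliberately closer than 200 bp to a chromosome
end, so exactly 3 of 50 upstream windows fail under the default `skip`
policy: an upstream error rate of 6.00%. Every other flank is recovered
byte-identical to the generator's recorded ground truth.

The same run from a shell:

```sh
Rscript inst/scripts/promex.R \
  --genome example_fixture/genome.fa \
  --genes  example_fixture/genes.fa \
  --gff    example_fixture/annot.gff3 \
  --out    promoters.csv \
  --upstream 200 --downstream 200
```

Omitting `--upstream`/`--downstream` uses the 2,000 bp defaults. See
`Rscript inst/scripts/promex.R --help` for the remaining flags
(`--boundary-policy`, `--feature-types`, `--no-strand-orient`,
`--keep-version-suffix`, `--log`, `--log-level`).

## Scope

`promex` extracts sequences; it does not scan motifs, predict binding sites,
or design primers. Output columns are
`gene_id, chromosome, start, end, strand, upstream_seq, downstream_seq, status`
with gene coordinates reported 1-based inclusive, unchanged by any flank
clipping. See `vignettes/promoter-extraction.Rmd` for the full account of
the model, parameter semantics, and design decisions.
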