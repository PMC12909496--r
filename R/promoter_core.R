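#' Extraction parameter set
#'
#' Bundles the tunable parameters of the promoter-extraction engine. The
#' defaults reproduce the standard configuration: 2,000 bp windows on each
#' side of the gene, skip-on-boundary semantics, and 5'-oriented flanks.
#'
#' @param up_len Upstream window length in bp (>= 0). Default 2000.
#' @param down_len Downstream window length in bp (>= 0), settable
#'   independently of `up_len`. Default 2000.
#' @param boundary_policy What to do when a window extends past a chromosome
#'   end: `"skip"` (report a failure for that side, the default) or
#'   `"truncate"` (clip the window to the chromosome).
#' @param feature_types Annotation feature types considered gene records, in
#'   preference order. Default `c("gene", "mRNA")`.
#' @param id_attribute_keys Attribute keys probed (first present wins) for the
#'   identifier of a feature. Default `c("ID", "Name", "gene_id", "locus_tag")`.
#' @param strip_version_suffix Match identifiers also after removing a
#'   terminal `.<digits>` version suffix (on both the requested id and the
#'   annotation value). Default TRUE.
#' @param orient_by_strand If TRUE (default), "upstream" means 5' of the gene
#'   on its own strand: minus-strand windows are taken from the high-coordinate
#'   side and reverse-complemented. If FALSE, plain forward-strand windows are
#'   returned for every gene.
#' @return A list of class `extraction_params`.
#' @export
extraction_params <- function(up_len = 2000L,
                              down_len = 2000L,
                              boundary_policy = c("skip", "truncate"),
                              feature_types = c("gene", "mRNA"),
                              id_attribute_keys = c("ID", "Name", "gene_id", "locus_tag"),
                              strip_version_suffix = TRUE,
                              orient_by_strand = TRUE) {
  boundary_policy <- match.arg(boundary_policy)
  up_len <- as.integer(up_len)
  down_len <- as.integer(down_len)
  if (is.na(up_len) || up_len < 0L) stop("up_len must be >= 0", call. = FALSE)
  if (is.na(down_len) || down_len < 0L) stop("down_len must be >= 0", call. = FALSE)
  if (length(feature_types) == 0L) stop("feature_types must be non-empty", call. = FALSE)
  structure(
    list(
      up_len = up_len, down_len = down_len, boundary_policy = boundary_policy,
      feature_types = as.character(feature_types),
      id_attribute_keys = as.character(id_attribute_keys),
      strip_version_suffix = isTRUE(strip_version_suffix),
      orient_by_strand = isTRUE(orient_by_strand)
    ),
    class = "extraction_params"
  )
}

#' Normalize requested gene identifiers
#'
#' Whitespace-trims each requested identifier and, when version stripping is
#' on, derives a fallback key with any terminal `.<digits>` suffix removed.
#' Both keys are used downstream for annotation matching (exact key first).
#' Identifiers that are empty after trimming are dropped with a logged
#' warning.
#'
#' @param ids Character vector of raw gene identifiers.
#' @param strip_version_suffix Derive version-stripped fallback keys
#'   (default TRUE).
#' @return Data frame with columns `raw`, `exact` (trimmed id) and `fallback`
#'   (version-stripped; equal to `exact` when stripping is off or no suffix
#'   exists), one row per retained input id in input order.
#' @examples
#' normalize_gene_ids(c("Glyma.01G000100.1", " g1 "))
#' @export
normalize_gene_ids <- function(ids, strip_version_suffix = TRUE) {
  if (length(ids) == 0L) stop("no gene identifiers supplied", call. = FALSE)
  trimmed <- trimws(ids)
  drop <- !nzchar(trimmed)
  if (any(drop)) {
    promex_log("warn", sum(drop), " empty gene identifier(s) dropped")
  }
  raw <- ids[!drop]
  exact <- trimmed[!drop]
  fallback <- if (isTRUE(strip_version_suffix)) strip_version(exact) else exact
  data.frame(raw = raw, exact = exact, fallback = fallback, stringsAsFactors = FALSE)
}

#' Match annotation features to requested genes
#'
#' Restricts the annotation to the configured feature types (gene/mRNA by
#' default) and groups the remaining features by requested gene. A feature is
#' a candidate for a gene when its identifier — the value under the first
#' present key of `params$id_attribute_keys` — equals the gene's exact key,
#' or (with version stripping) when the version-stripped forms of either side
#' match. File order is preserved within each candidate group.
#'
#' @param features Data frame from [read_gff()].
#' @param gene_keys Data frame from [normalize_gene_ids()].
#' @param params An [extraction_params()] object.
#' @return List with `candidates` (named list, one integer vector of feature
#'   row indices per matched raw gene id) and `unmatched` (character vector of
#'   raw ids with zero candidates).
#' @export
filter_gene_features <- function(features, gene_keys, params = extraction_params()) {
  keep <- features$type %in% params$feature_types
  idx <- which(keep)
  idval <- rep(NA_character_, length(idx))
  for (key in params$id_attribute_keys) {
    need <- is.na(idval)
    if (!any(need)) break
    v <- vapply(features$attributes[idx[need]], function(a) {
      if (key %in% names(a)) a[[key]] else NA_character_
    }, character(1))
    idval[need] <- v
  }
  has_id <- !is.na(idval)
  idx <- idx[has_id]
  idval <- idval[has_id]
  idval_stripped <- if (params$strip_version_suffix) strip_version(idval) else idval

  # hashed lookup: attribute value (exact and stripped) -> feature positions
  lut <- split(seq_along(idx), idval)
  lut_stripped <- split(seq_along(idx), idval_stripped)

  candidates <- list()
  unmatched <- character(0)
  for (i in seq_len(nrow(gene_keys))) {
    exact <- gene_keys$exact[i]
    hits <- c(lut[[exact]], if (params$strip_version_suffix) lut_stripped[[exact]])
    if (params$strip_version_suffix && gene_keys$fallback[i] != exact) {
      fb <- gene_keys$fallback[i]
      hits <- c(hits, lut[[fb]], lut_stripped[[fb]])
    }
    hits <- sort(unique(hits))
    if (length(hits) == 0L) {
      unmatched <- c(unmatched, gene_keys$raw[i])
    } else {
      candidates[[gene_keys$raw[i]]] <- idx[hits]
    }
  }
  if (length(unmatched)) {
    promex_log("warn", length(unmatched), " requested gene id(s) not found in annotation")
  }
  list(candidates = candidates, unmatched = unmatched)
}

#' Choose the single representative annotation record for a gene
#'
#' Deterministic rule: prefer the earliest feature type in
#' `params$feature_types` (so `gene` beats `mRNA` by default); among equal
#' types, the record earliest in file order wins.
#'
#' @param features Data frame from [read_gff()].
#' @param candidate_idx Integer vector of candidate row indices (file order),
#'   length >= 1.
#' @param params An [extraction_params()] object.
#' @return The index (into `features`) of the representative record.
#' @export
select_representative <- function(features, candidate_idx, params = extraction_params()) {
  if (length(candidate_idx) == 0L) stop("no candidate features", call. = FALSE)
  pref <- match(features$type[candidate_idx], params$feature_types)
  candidate_idx[order(pref, candidate_idx)][1L]
}

# Vectorized flank-window arithmetic and slicing over a table of
# representative records. Returns per-side sequences and statuses. This is
# the single batch pass at the heart of the engine: all interval arithmetic
# and all substring extraction are column operations, never a per-gene rescan
# of the genome.
flank_batch <- function(store, reps, params) {
  n <- nrow(reps)
  L <- params$up_len
  M <- params$down_len

  strand <- reps$strand
  odd <- !strand %in% c("+", "-")
  if (any(odd)) {
    promex_log("info", sum(odd), " record(s) with strand '.' or '?' treated as '+'")
  }
  minus <- params$orient_by_strand & strand == "-"

  chrlen <- store$lengths[reps$seqid]
  known <- !is.na(chrlen)

  # oriented windows, 1-based inclusive
  up_lo <- ifelse(minus, reps$end + 1, reps$start - L)
  up_hi <- ifelse(minus, reps$end + L, reps$start - 1)
  dn_lo <- ifelse(minus, reps$start - M, reps$end + 1)
  dn_hi <- ifelse(minus, reps$start - 1, reps$end + M)

  side <- function(lo, hi, len) {
    seq <- rep(NA_character_, n)
    status <- rep(NA_character_, n)
    status[!known] <- "missing_chromosome"
    if (len == 0L) {
      seq[known] <- ""
      status[known] <- "complete"
      return(list(seq = seq, status = status))
    }
    inside <- known & lo >= 1 & hi <= chrlen
    status[inside] <- "complete"
    out <- known & !inside
    if (params$boundary_policy == "skip") {
      status[out] <- "skipped_boundary"
    } else {
      status[out] <- "truncated"
      lo <- pmax(lo, 1)
      hi <- pmin(hi, ifelse(known, chrlen, hi))
    }
    take <- known & status %in% c("complete", "truncated")
    emptied <- take & lo > hi  # fully clipped window under truncate
    seq[take] <- substr(store$sequences[reps$seqid[take]],
                        lo[take], pmax(hi[take], lo[take] - 1))
    seq[emptied] <- ""
    if (params$orient_by_strand) {
      rc <- take & minus & !is.na(seq) & nzchar(seq)
      seq[rc] <- revcomp(seq[rc])
    }
    list(seq = seq, status = status)
  }

  up <- side(up_lo, up_hi, L)
  dn <- side(dn_lo, dn_hi, M)
  data.frame(
    upstream_seq = up$seq, downstream_seq = dn$seq,
    upstream_status = up$status, downstream_status = dn$status,
    stringsAsFactors = FALSE
  )
}

#' Extract the flanking windows of a single gene record
#'
#' Computes the strand-aware upstream and downstream sequences for one gene.
#' With window lengths `L = up_len` and `M = down_len` and chromosome length
#' `N`:
#' \itemize{
#'   \item plus strand (`.`/`?` treated as plus): upstream is the forward
#'     window `[start-L, start-1]`, downstream `[end+1, end+M]`;
#'   \item minus strand with strand orientation on: upstream is
#'     `[end+1, end+L]` reverse-complemented, downstream `[start-M, start-1]`
#'     reverse-complemented;
#'   \item a window extending past `[1, N]` is skipped (status
#'     `skipped_boundary`) or clipped (status `truncated`) per the boundary
#'     policy; a zero-length window is the empty string with status
#'     `complete`.
#' }
#' An unknown chromosome yields status `missing_chromosome` on both sides.
#'
#' @param store A `genome_store`.
#' @param rec A list or one-row data frame with fields `gene_id`, `seqid`,
#'   `start`, `end` (1-based inclusive) and `strand`.
#' @param params An [extraction_params()] object.
#' @return One-row data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`, `upstream_seq`, `downstream_seq`, `upstream_status`,
#'   `downstream_status`, `status`. Sequences are `NA` when extraction failed
#'   on that side. `status` is the combined token
#'   `"up=<upstream_status>;down=<downstream_status>"`.
#' @examples
#' g <- structure(list(sequences = c(C1 = "AAAACCCCGGGGTTTT"),
#'                     lengths = c(C1 = 16L)), class = "genome_store")
#' rec <- list(gene_id = "g1", seqid = "C1", start = 9, end = 12, strand = "+")
#' extract_flanks(g, rec, extraction_params(up_len = 4, down_len = 4))
#' @export
extract_flanks <- function(store, rec, params = extraction_params()) {
  reps <- data.frame(
    gene_id = rec$gene_id, seqid = rec$seqid,
    start = as.numeric(rec$start), end = as.numeric(rec$end),
    strand = rec$strand, stringsAsFactors = FALSE
  )
  if (reps$start > reps$end || reps$start < 1) {
    stop("invalid gene interval [", reps$start, ", ", reps$end, "]", call. = FALSE)
  }
  res <- flank_batch(store, reps, params)
  assemble_promoter_rows(reps, res)
}

assemble_promoter_rows <- function(reps, res) {
  data.frame(
    gene_id = reps$gene_id, chromosome = reps$seqid,
    start = reps$start, end = reps$end, strand = reps$strand,
    upstream_seq = res$upstream_seq, downstream_seq = res$downstream_seq,
    upstream_status = res$upstream_status, downstream_status = res$downstream_status,
    status = paste0("up=", res$upstream_status, ";down=", res$downstream_status),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Flank-extraction error rate (percent)
#'
#' The per-run accuracy statistic: the percentage of requested genes for
#' which a given side's flank was not extracted,
#' `(total_genes - n_extracted) / total_genes * 100`.
#'
#' @param total_genes Total number of requested genes (> 0).
#' @param n_extracted Number of successfully extracted flanks on one side
#'   (`0 <= n_extracted <= total_genes`).
#' @return Error rate in percent, in `[0, 100]`.
#' @examples
#' error_rate(24255, 24252)  # ~0.0124
#' @export
error_rate <- function(total_genes, n_extracted) {
  if (length(total_genes) != length(n_extracted)) {
    stop("total_genes and n_extracted must have equal length", call. = FALSE)
  }
  if (any(total_genes <= 0)) stop("total_genes must be > 0", call. = FALSE)
  if (any(n_extracted < 0 | n_extracted > total_genes)) {
    stop("n_extracted must lie in [0, total_genes]", call. = FALSE)
  }
  (total_genes - n_extracted) / total_genes * 100
}

#' Run the full promoter-extraction pipeline on loaded inputs
#'
#' Applies the complete engine as one batch: identifier normalization,
#' annotation matching, representative-record selection, and vectorized
#' strand-aware flank extraction, followed by the summary statistics.
#' Per-gene failures (unmatched ids, unknown chromosomes, boundary overruns)
#' become statuses and counts, never errors.
#'
#' @param store A `genome_store` from [read_genome()].
#' @param gene_ids Character vector of requested gene identifiers (e.g. from
#'   [read_gene_ids()]); duplicates are dropped keeping the first.
#' @param features Annotation data frame from [read_gff()].
#' @param params An [extraction_params()] object.
#' @return List with elements:
#'   \describe{
#'     \item{promoters}{data frame of extracted records (one row per matched
#'       gene, input order; unmatched ids are excluded), with the columns of
#'       [extract_flanks()].}
#'     \item{summary}{an `extraction_summary`: `total_genes`,
#'       `n_upstream_extracted`, `n_downstream_extracted`,
#'       `upstream_error_rate_pct`, `downstream_error_rate_pct`,
#'       `n_unmatched_ids`, `n_missing_chromosome`, plus per-side status
#'       count tables.}
#'   }
#' @details A flank counts as extracted when its status is `complete` or
#'   `truncated`. For each side,
#'   `complete + truncated + skipped_boundary + missing_chromosome +
#'   unmatched = total_genes`.
#' @export
extract_promoters <- function(store, gene_ids, features, params = extraction_params()) {
  gene_ids <- unique(gene_ids)
  keys <- normalize_gene_ids(gene_ids, params$strip_version_suffix)
  total <- nrow(keys)
  matched <- filter_gene_features(features, keys, params)

  matched_raw <- keys$raw[keys$raw %in% names(matched$candidates)]
  if (length(matched_raw)) {
    rep_idx <- vapply(matched_raw, function(g) {
      select_representative(features, matched$candidates[[g]], params)
    }, integer(1))
    reps <- data.frame(
      gene_id = matched_raw,
      seqid = features$seqid[rep_idx],
      start = features$start[rep_idx],
      end = features$end[rep_idx],
      strand = features$strand[rep_idx],
      stringsAsFactors = FALSE
    )
    res <- flank_batch(store, reps, params)
    promoters <- assemble_promoter_rows(reps, res)
  } else {
    promoters <- assemble_promoter_rows(
      data.frame(gene_id = character(0), seqid = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0),
                 stringsAsFactors = FALSE),
      data.frame(upstream_seq = character(0), downstream_seq = character(0),
                 upstream_status = character(0), downstream_status = character(0),
                 stringsAsFactors = FALSE)
    )
  }

  lv <- c("complete", "truncated", "skipped_boundary", "missing_chromosome")
  up_counts <- table(factor(promoters$upstream_status, levels = lv))
  dn_counts <- table(factor(promoters$downstream_status, levels = lv))
  n_up <- sum(up_counts[c("complete", "truncated")])
  n_dn <- sum(dn_counts[c("complete", "truncated")])
  n_missing <- sum(promoters$upstream_status == "missing_chromosome")
  if (length(matched$unmatched)) {
    promex_log("info", "unmatched ids: ", length(matched$unmatched))
  }
  if (n_missing > 0) {
    promex_log("warn", n_missing, " matched gene(s) on chromosomes absent from the genome")
  }
  n_skip <- sum(up_counts["skipped_boundary"], dn_counts["skipped_boundary"])
  if (n_skip > 0) {
    promex_log("info", n_skip, " flank window(s) skipped at chromosome boundaries")
  }

  summary <- structure(list(
    total_genes = total,
    n_upstream_extracted = as.integer(n_up),
    n_downstream_extracted = as.integer(n_dn),
    upstream_error_rate_pct = error_rate(total, n_up),
    downstream_error_rate_pct = error_rate(total, n_dn),
    n_unmatched_ids = length(matched$unmatched),
    n_missing_chromosome = as.integer(n_missing),
    upstream_status_counts = up_counts,
    downstream_status_counts = dn_counts,
    unmatched_ids = matched$unmatched
  ), class = "extraction_summary")

  list(promoters = promoters, summary = summary)
}

#' @export
print.extraction_summary <- function(x, ...) {
  cat("Promoter extraction summary\n")
  cat("  Total genes requested     :", x$total_genes, "\n")
  cat("  Upstream flanks extracted :", x$n_upstream_extracted, "\n")
  cat("  Downstream flanks extracted:", x$n_downstream_extracted, "\n")
  cat(sprintf("  Upstream error rate       : %.2f%%\n", x$upstream_error_rate_pct))
  cat(sprintf("  Downstream error rate     : %.2f%%\n", x$downstream_error_rate_pct))
  cat("  Unmatched gene ids        :", x$n_unmatched_ids, "\n")
  cat("  Missing chromosomes       :", x$n_missing_chromosome, "\n")
  invisible(x)
}
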