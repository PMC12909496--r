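#' Load a reference genome FASTA into a random-access store
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file and returns a
#' `genome_store`: a named set of chromosome sequences supporting random
#' access by identifier and 1-based inclusive coordinates. The identifier of
#' each record is the token before the first whitespace in its header, the
#' universal FASTA convention. Sequences are stored verbatim — case and any
#' IUPAC ambiguity codes are preserved.
#'
#' @param path Path to the genome FASTA file (`.gz` accepted).
#' @return An object of class `genome_store`: a list with elements
#'   `sequences` (named character vector, one element per chromosome) and
#'   `lengths` (named integer vector of sequence lengths in bp).
#' @details Duplicate identifiers are a fatal input error (the two offending
#'   record indices are named), as is an empty file or a file whose first
#'   non-empty byte is not `>`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 assembly x", "ACGT", "ACGT"), fa)
#' g <- read_genome(fa)
#' g$lengths            # chr1: 8
#' genome_slice(g, "chr1", 3, 6)
#' @seealso [genome_slice()], [extract_promoters()]
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  con <- open_text(path)
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("genome FASTA is empty: ", path, call. = FALSE)
  if (!startsWith(first, ">")) {
    stop("not a FASTA file (first byte is not '>'): ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("genome FASTA contains no records: ", path, call. = FALSE)
  ids <- first_token(names(set))
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    at <- which(ids == d)
    stop(sprintf(
      "duplicate chromosome identifier '%s' in %s (records %d and %d)",
      d, path, at[1L], at[2L]
    ), call. = FALSE)
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("genome FASTA contains an empty sequence record: ", path, call. = FALSE)
  }
  names(seqs) <- ids
  structure(
    list(sequences = seqs, lengths = stats::setNames(nchar(seqs), ids)),
    class = "genome_store"
  )
}

#' @export
print.genome_store <- function(x, ...) {
  cat("genome_store:", length(x$sequences), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  n <- min(6L, length(x$lengths))
  for (i in seq_len(n)) {
    cat("  ", names(x$lengths)[i], ": ", x$lengths[[i]], " bp\n", sep = "")
  }
  if (length(x$lengths) > n) cat("  ...\n")
  invisible(x)
}

#' Slice a chromosome from a genome store
#'
#' Returns the subsequence of chromosome `seqid` between 1-based inclusive
#' positions `start` and `end`. A zero-length interval (`end == start - 1`)
#' yields the empty string.
#'
#' @param store A `genome_store` from [read_genome()].
#' @param seqid Chromosome identifier.
#' @param start,end 1-based inclusive coordinates; must satisfy
#'   `1 <= start` and `end <= lengths[seqid]` (and `end >= start - 1`).
#' @return Single character string.
#' @export
genome_slice <- function(store, seqid, start, end) {
  stopifnot(inherits(store, "genome_store"))
  if (!seqid %in% names(store$sequences)) {
    stop("unknown chromosome identifier: ", seqid, call. = FALSE)
  }
  n <- store$lengths[[seqid]]
  if (end < start - 1 || start < 1 || end > n) {
    stop(sprintf("slice [%s, %s] out of bounds for %s (1..%d)", start, end, seqid, n),
         call. = FALSE)
  }
  if (end < start) return("")
  substr(store$sequences[[seqid]], start, end)
}

#' Extract gene identifiers from a gene FASTA file
#'
#' Scans the headers of a (possibly gzipped) FASTA file and returns the gene
#' identifiers in file order: one per record, the token before the first
#' whitespace. Sequence lines are ignored. Duplicate identifiers are removed
#' keeping the first occurrence; the number removed is logged.
#'
#' @param path Path to the gene FASTA file.
#' @return Character vector of unique gene identifiers in order of first
#'   appearance.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">GeneA some description", "ATG", ">GeneB", "ATG"), fa)
#' read_gene_ids(fa)  # "GeneA" "GeneB"
#' @export
read_gene_ids <- function(path) {
  if (!file.exists(path)) stop("gene FASTA not found: ", path, call. = FALSE)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  headers <- lines[startsWith(lines, ">")]
  if (length(headers) == 0L) {
    stop("no gene IDs: no FASTA headers found in ", path, call. = FALSE)
  }
  ids <- first_token(substring(headers, 2L))
  ndup <- sum(duplicated(ids))
  if (ndup > 0L) {
    promex_log("warn", ndup, " duplicate gene ID(s) in ", path,
               " removed (first occurrence kept)")
  }
  ids[!duplicated(ids)]
}

#' Parse a GFF3 (or GTF-attribute) annotation file
#'
#' Reads a 9-column tab-separated annotation file into a data frame of
#' features with a parsed attribute map per row. Comment lines (`#`-prefixed)
#' and blank lines are skipped. Malformed data lines — wrong column count,
#' non-numeric or inverted coordinates — are skipped with a counted warning
#' rather than aborting, tolerating the imperfect annotations common in
#' practice.
#'
#' Attributes (column 9) are parsed as semicolon-separated pairs in either
#' GFF3 `key=value` or GTF `key "value"` syntax; keys and values are
#' URL-percent-decoded, and when a key repeats within one row the first
#' occurrence wins.
#'
#' @param path Path to the GFF3/GTF file (`.gz` accepted).
#' @return A data frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase` and a list-column `attributes` (named
#'   character vector per row), in file order. Attributes of the data frame
#'   itself: `n_malformed` (skipped data lines) and `n_comments` (comment or
#'   blank lines).
#' @details Coordinates are 1-based inclusive as in the GFF3 standard. A file
#'   with zero well-formed data lines is a fatal error.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  is_comment <- startsWith(lines, "#") | !nzchar(trimws(lines))
  data_lines <- lines[!is_comment]
  n_comments <- sum(is_comment)

  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  ok_ncol <- lengths(fields) == 9L
  start <- rep(NA_real_, length(fields))
  end <- rep(NA_real_, length(fields))
  suppressWarnings({
    start[ok_ncol] <- as.numeric(vapply(fields[ok_ncol], `[[`, "", 4L))
    end[ok_ncol] <- as.numeric(vapply(fields[ok_ncol], `[[`, "", 5L))
  })
  ok <- ok_ncol & !is.na(start) & !is.na(end) & start >= 1 & start <= end
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    promex_log("warn", n_malformed, " malformed annotation line(s) skipped in ", path)
  }
  if (!any(ok)) {
    stop("no well-formed annotation lines in ", path, call. = FALSE)
  }

  f <- fields[ok]
  col <- function(i) vapply(f, `[[`, "", i)
  out <- data.frame(
    seqid = col(1L), source = col(2L), type = col(3L),
    start = start[ok], end = end[ok],
    score = col(6L), strand = col(7L), phase = col(8L),
    stringsAsFactors = FALSE
  )
  out$attributes <- lapply(col(9L), parse_gff_attributes)
  attr(out, "n_malformed") <- n_malformed
  attr(out, "n_comments") <- n_comments
  out
}

# Parse one GFF3/GTF column-9 string into a named character vector.
# Accepts `key=value` (GFF3, preferred) and `key "value"` (GTF). First
# occurrence wins for repeated keys.
parse_gff_attributes <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(stats::setNames(character(0), character(0)))
  keys <- character(length(parts))
  vals <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0L) {
      keys[i] <- substr(p, 1L, eq - 1L)
      vals[i] <- substring(p, eq + 1L)
    } else if (grepl('^\\S+\\s+".*"$', p)) {
      sp <- regexpr("\\s", p)
      keys[i] <- substr(p, 1L, sp - 1L)
      vals[i] <- sub('^"(.*)"$', "\\1", trimws(substring(p, sp + 1L)))
    } else {
      keys[i] <- p
      vals[i] <- ""
    }
  }
  keys <- vapply(keys, url_decode, character(1), USE.NAMES = FALSE)
  vals <- vapply(vals, url_decode, character(1), USE.NAMES = FALSE)
  keep <- !duplicated(keys)
  stats::setNames(vals[keep], keys[keep])
}

# Percent-decode, leaving the input untouched if it is not valid URL encoding.
url_decode <- function(x) {
  if (!grepl("%", x, fixed = TRUE)) return(x)
  tryCatch(utils::URLdecode(x), error = function(e) x, warning = function(w) x)
}

#' Look up one attribute key across parsed annotation features
#'
#' @param features Data frame from [read_gff()].
#' @param key Attribute key, e.g. `"ID"`.
#' @return Character vector (NA where the key is absent), one element per row.
#' @export
gff_attr <- function(features, key) {
  vapply(features$attributes, function(a) {
    if (key %in% names(a)) a[[key]] else NA_character_
  }, character(1))
}

#' Write extracted promoter records to CSV
#'
#' Writes the structured per-gene output table: one header line then one line
#' per record, RFC-4180 quoting, columns exactly `gene_id`, `chromosome`,
#' `start`, `end`, `strand`, `upstream_seq`, `downstream_seq`, `status`.
#' Missing sequences (failed extractions) are written as empty fields.
#'
#' @param rows Data frame of promoter records, e.g. the `promoters` element
#'   of [extract_promoters()]; may have zero rows. Extra columns (the
#'   per-side status columns) are dropped from the file.
#' @param path Output CSV path.
#' @return Number of data rows written, invisibly.
#' @export
write_promoter_csv <- function(rows, path) {
  cols <- c("gene_id", "chromosome", "start", "end", "strand",
            "upstream_seq", "downstream_seq", "status")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols)) {
    stop("promoter table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- rows[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, file = path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write output CSV to ", path, ": ", conditionMessage(ok), call. = FALSE)
  }
  invisible(nrow(out))
}
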