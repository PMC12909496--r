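#' Reverse-complement nucleotide sequences
#'
#' Vectorized reverse complement over the full IUPAC nucleotide alphabet.
#' Case is preserved: lowercase (soft-masked) bases stay lowercase in the
#' complement, so extracted sequences round-trip masking information intact.
#'
#' @param x Character vector of nucleotide sequences. `NA` elements are
#'   propagated; empty strings map to empty strings.
#' @return Character vector of the same length with each element reversed and
#'   complemented.
#' @examples
#' revcomp("ACCT")          # "AGGT"
#' revcomp(c("acgtn", NA))  # "nacgt", NA
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr(
    "ACGTURYSWKMBDHVNacgturyswkmbdhvn",
    "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn",
    x
  )
  out <- vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
  out[is.na(x)] <- NA_character_
  out
}

# Open a text connection, transparently decompressing .gz paths.
open_text <- function(path) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, "rt") else file(path, "rt")
}

# First whitespace-delimited token of a string (FASTA identifier convention).
first_token <- function(x) sub("[ \t].*$", "", x)

# Strip a terminal ".<digits>" version suffix, e.g. "Glyma.01G000100.1" ->
# "Glyma.01G000100". Leaves ids without such a suffix untouched.
strip_version <- function(x) sub("\\.[0-9]+$", "", x)

# ---- minimal run logger -----------------------------------------------------
# Messages go to stderr via message(); an optional log file (set per run by the
# CLI) receives a copy. Levels: debug < info < warn.

.promex_env <- new.env(parent = emptyenv())
.promex_env$log_level <- "info"
.promex_env$log_file <- NULL

.level_num <- c(debug = 1L, info = 2L, warn = 3L)

set_log <- function(level = "info", file = NULL) {
  level <- match.arg(level, names(.level_num))
  .promex_env$log_level <- level
  .promex_env$log_file <- file
  invisible(NULL)
}

promex_log <- function(level, ...) {
  if (.level_num[[level]] < .level_num[[.promex_env$log_level]]) return(invisible(NULL))
  line <- paste0(toupper(level), ": ", paste0(..., collapse = ""))
  message(line)
  if (!is.null(.promex_env$log_file)) {
    cat(line, "\n", sep = "", file = .promex_env$log_file, append = TRUE)
  }
  invisible(NULL)
}
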