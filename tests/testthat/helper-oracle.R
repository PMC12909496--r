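# Naive character-by-character flank slicer: the independent oracle the
# vectorized engine is checked against. Works on one gene at a time, splits
# the chromosome into single characters, and uses a lookup-table reverse
# complement — no code shared with the package's substr/chartr path.

oracle_rc <- function(s) {
  if (!nzchar(s)) return(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            a = "t", c = "g", g = "c", t = "a", n = "n")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[ch])), collapse = "")
}

oracle_flanks <- function(chrseq, start, end, strand, L, M,
                          policy = "skip", orient = TRUE) {
  ch <- strsplit(chrseq, "", fixed = TRUE)[[1]]
  N <- length(ch)
  minus <- orient && identical(strand, "-")

  one_side <- function(lo, hi, len) {
    if (len == 0) return(list(seq = "", status = "complete"))
    if (lo >= 1 && hi <= N) {
      return(list(seq = paste(ch[lo:hi], collapse = ""), status = "complete"))
    }
    if (policy == "skip") return(list(seq = NA_character_, status = "skipped_boundary"))
    lo2 <- max(1, lo); hi2 <- min(N, hi)
    s <- if (lo2 <= hi2) paste(ch[lo2:hi2], collapse = "") else ""
    list(seq = s, status = "truncated")
  }

  if (minus) {
    up <- one_side(end + 1, end + L, L)
    dn <- one_side(start - M, start - 1, M)
    if (!is.na(up$seq)) up$seq <- oracle_rc(up$seq)
    if (!is.na(dn$seq)) dn$seq <- oracle_rc(dn$seq)
  } else {
    up <- one_side(start - L, start - 1, L)
    dn <- one_side(end + 1, end + M, M)
  }
  list(up_seq = up$seq, up_status = up$status,
       dn_seq = dn$seq, dn_status = dn$status)
}

# genome_store built directly from named strings (no file round-trip)
make_store <- function(seqs) {
  structure(
    list(sequences = seqs,
         lengths = stats::setNames(nchar(seqs), names(seqs))),
    class = "genome_store"
  )
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
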