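test_that("normalize_gene_ids trims and derives version-stripped fallback keys", {
  k <- normalize_gene_ids("Glyma.01G000100.1")
  expect_equal(k$exact, "Glyma.01G000100.1")
  expect_equal(k$fallback, "Glyma.01G000100")

  expect_equal(normalize_gene_ids(" g1 ")$exact, "g1")
  expect_equal(normalize_gene_ids("g1", strip_version_suffix = FALSE)$fallback, "g1")
  expect_message(k2 <- normalize_gene_ids(c("g1", "  ")), "empty")
  expect_equal(nrow(k2), 1L)
  expect_error(normalize_gene_ids(character(0)), "no gene identifiers")
})

test_that("filter_gene_features applies the type filter and version fallback", {
  rows <- c(
    "c1\ts\texon\t1\t50\t.\t+\t.\tID=g1",          # wrong type, same id
    "c1\ts\tgene\t100\t200\t.\t+\t.\tID=g1",
    "c1\ts\tmRNA\t100\t200\t.\t+\t.\tID=g1.1;Parent=g1",
    "c1\ts\tgene\t300\t400\t.\t-\t.\tID=g2",
    "c1\ts\ttRNA\t300\t400\t.\t-\t.\tID=g2"
  )
  feats <- read_gff(write_tmp(rows, ".gff3"))
  keys <- normalize_gene_ids(c("g1", "g2", "missing"))
  suppressMessages(m <- filter_gene_features(feats, keys))
  expect_equal(m$candidates$g1, c(2L, 3L))   # gene + versioned mRNA, not the exon
  expect_equal(m$candidates$g2, 4L)          # not the tRNA
  expect_equal(m$unmatched, "missing")

  # requested id itself carries the version suffix: fallback matches both rows
  keys2 <- normalize_gene_ids("g1.2")
  m2 <- filter_gene_features(feats, keys2)
  expect_equal(m2$candidates[["g1.2"]], c(2L, 3L))

  # with stripping off, only exact matches survive
  p <- extraction_params(strip_version_suffix = FALSE)
  m3 <- suppressMessages(filter_gene_features(feats, normalize_gene_ids("g1.1", FALSE), p))
  expect_equal(m3$candidates[["g1.1"]], 3L)
})

test_that("select_representative prefers gene over mRNA, then file order", {
  rows <- c(
    "c1\ts\tmRNA\t5\t100\t.\t+\t.\tID=g1.1;Parent=g1",
    "c1\ts\tgene\t1\t120\t.\t+\t.\tID=g1",
    "c1\ts\tgene\t1\t100\t.\t+\t.\tID=g2",
    "c1\ts\tgene\t1\t100\t.\t+\t.\tID=g2"
  )
  feats <- read_gff(write_tmp(rows, ".gff3"))
  expect_equal(select_representative(feats, c(1L, 2L)), 2L)   # gene beats mRNA
  expect_equal(select_representative(feats, c(3L, 4L)), 3L)   # earliest in file
  expect_error(select_representative(feats, integer(0)), "no candidate")
})

test_that("extract_flanks matches the worked plus/minus-strand examples", {
  g <- make_store(c(C1 = "AAAACCCCGGGGTTTT"))
  p <- extraction_params(up_len = 4, down_len = 4)
  r <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 9, end = 12, strand = "+"), p)
  expect_equal(r$upstream_seq, "CCCC")
  expect_equal(r$downstream_seq, "TTTT")
  expect_equal(r$upstream_status, "complete")
  expect_equal(r$downstream_status, "complete")
  expect_equal(r$status, "up=complete;down=complete")
  expect_equal(r$start, 9)   # gene coordinates unchanged by flank arithmetic
  expect_equal(r$end, 12)

  g2 <- make_store(c(C1 = "TTTTACGGACCTAAAA"))
  r2 <- extract_flanks(g2, list(gene_id = "x", seqid = "C1", start = 5, end = 8, strand = "-"), p)
  expect_equal(r2$upstream_seq, "AGGT")   # reverse complement of positions 9-12 "ACCT"
  expect_equal(r2$downstream_seq, revcomp("TTTT"))
})

test_that("boundary policy: skip marks the offending side, truncate clips", {
  g <- make_store(c(C1 = "AAAACCCCGGGGTTTT"))
  p <- extraction_params(up_len = 4, down_len = 4, boundary_policy = "skip")
  r <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 2, end = 6, strand = "+"), p)
  expect_equal(r$upstream_status, "skipped_boundary")
  expect_true(is.na(r$upstream_seq))
  expect_equal(r$downstream_status, "complete")       # its own interval fits
  expect_equal(r$downstream_seq, "CCGG")

  pt <- extraction_params(up_len = 4, down_len = 4, boundary_policy = "truncate")
  rt <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 2, end = 6, strand = "+"), pt)
  expect_equal(rt$upstream_status, "truncated")
  expect_equal(rt$upstream_seq, "A")                  # clipped to [1, 1]
  expect_equal(nchar(rt$upstream_seq), 1L)

  # downstream overrun on the right end
  rr <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 9, end = 14, strand = "+"), pt)
  expect_equal(rr$downstream_status, "truncated")
  expect_equal(rr$downstream_seq, "TT")
})

test_that("zero-length windows, unknown strand and missing chromosomes", {
  g <- make_store(c(C1 = "AAAACCCCGGGGTTTT"))
  p0 <- extraction_params(up_len = 0, down_len = 0)
  r0 <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 1, end = 16, strand = "+"), p0)
  expect_equal(r0$upstream_seq, "")      # empty window is still complete,
  expect_equal(r0$upstream_status, "complete")  # even flush with the boundary
  expect_equal(r0$downstream_status, "complete")

  p <- extraction_params(up_len = 4, down_len = 4)
  rdot <- suppressMessages(
    extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 9, end = 12, strand = "."), p)
  )
  rplus <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 9, end = 12, strand = "+"), p)
  expect_equal(rdot$upstream_seq, rplus$upstream_seq)  # '.' treated as '+'

  rmiss <- extract_flanks(g, list(gene_id = "x", seqid = "nope", start = 9, end = 12, strand = "+"), p)
  expect_equal(rmiss$upstream_status, "missing_chromosome")
  expect_equal(rmiss$downstream_status, "missing_chromosome")
  expect_true(is.na(rmiss$upstream_seq))
})

test_that("orientation flag off yields plain forward-strand windows", {
  g <- make_store(c(C1 = "TTTTACGGACCTAAAA"))
  p <- extraction_params(up_len = 4, down_len = 4, orient_by_strand = FALSE)
  r <- extract_flanks(g, list(gene_id = "x", seqid = "C1", start = 5, end = 8, strand = "-"), p)
  expect_equal(r$upstream_seq, "TTTT")   # [1,4] forward, no reverse complement
  expect_equal(r$downstream_seq, "ACCT") # [9,12] forward
})

test_that("engine agrees exactly with the naive slicer oracle on random cases", {
  set.seed(42)
  for (i in 1:60) {
    N <- sample(30:3000, 1)
    chr <- random_dna(N)
    g <- make_store(c(K1 = chr))
    start <- sample.int(N, 1)
    end <- min(N, start + sample.int(200, 1) - 1)
    strand <- sample(c("+", "-"), 1)
    for (policy in c("skip", "truncate")) {
      L <- sample(c(0L, 1L, 7L, 100L), 1)
      M <- sample(c(0L, 1L, 7L, 100L), 1)
      p <- extraction_params(up_len = L, down_len = M, boundary_policy = policy)
      got <- extract_flanks(g, list(gene_id = "t", seqid = "K1",
                                    start = start, end = end, strand = strand), p)
      want <- oracle_flanks(chr, start, end, strand, L, M, policy)
      expect_identical(got$upstream_seq, want$up_seq,
                       label = sprintf("up seq (case %d %s %s)", i, strand, policy))
      expect_identical(got$upstream_status, want$up_status)
      expect_identical(got$downstream_seq, want$dn_seq)
      expect_identical(got$downstream_status, want$dn_status)
    }
  }
})

test_that("plus-strand concatenation identity and reverse-complement involution", {
  set.seed(7)
  for (i in 1:25) {
    N <- sample(500:2000, 1)
    chr <- random_dna(N)
    g <- make_store(c(K1 = chr))
    L <- sample(c(1L, 7L, 100L), 1); M <- sample(c(1L, 7L, 100L), 1)
    start <- sample(seq(L + 1, N - M - 50), 1)
    end <- start + sample.int(50, 1) - 1
    p <- extraction_params(up_len = L, down_len = M)
    r <- extract_flanks(g, list(gene_id = "t", seqid = "K1",
                                start = start, end = end, strand = "+"), p)
    expect_equal(r$upstream_status, "complete")
    expect_identical(
      paste0(r$upstream_seq, substr(chr, start, end), r$downstream_seq),
      substr(chr, start - L, end + M)
    )
    expect_identical(revcomp(revcomp(r$upstream_seq)), r$upstream_seq)
  }
  # revcomp itself: known value, case preservation, library cross-check
  expect_identical(revcomp("ACCT"), "AGGT")
  expect_identical(revcomp("acgTN"), "NAcgt")
  set.seed(8)
  for (i in 1:10) {
    s <- random_dna(80)
    expect_identical(revcomp(s),
                     as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("error_rate reproduces worked values and is strictly monotone", {
  expect_equal(error_rate(24255, 24252), 3 / 24255 * 100, tolerance = 1e-12)
  expect_equal(round(error_rate(24255, 24252), 4), 0.0124)
  expect_equal(error_rate(500, 500), 0)
  expect_equal(error_rate(10, 0), 100)
  # strictly decreasing in n_extracted at fixed total
  rates <- error_rate(rep(137, 138), 0:137)
  expect_true(all(diff(rates) < 0))
  expect_true(all(rates >= 0 & rates <= 100))
  expect_error(error_rate(0, 0), "total_genes")
  expect_error(error_rate(10, 11), "n_extracted")
  expect_error(error_rate(10, -1), "n_extracted")
})

test_that("extract_promoters conserves statuses and is order-invariant", {
  fx <- generate_fixture(fixture_spec(seed = 23, n_genes = 30, n_boundary_genes = 2),
                         file.path(tempdir(), "fx-core"))
  store <- read_genome(fx$paths$genome)
  ids <- read_gene_ids(fx$paths$genes)
  feats <- read_gff(fx$paths$gff)
  p <- extraction_params(up_len = fx$spec$flank_len, down_len = fx$spec$flank_len)
  res <- suppressMessages(extract_promoters(store, ids, feats, p))
  s <- res$summary

  for (counts in list(s$upstream_status_counts, s$downstream_status_counts)) {
    expect_equal(sum(counts) + s$n_unmatched_ids, s$total_genes)
  }
  expect_equal(nrow(res$promoters) + s$n_unmatched_ids, s$total_genes)
  expect_equal(s$n_upstream_extracted,
               sum(res$promoters$upstream_status %in% c("complete", "truncated")))

  # permuting the requested ids permutes rows but changes nothing else
  set.seed(1)
  res2 <- suppressMessages(extract_promoters(store, sample(ids), feats, p))
  a <- res$promoters[order(res$promoters$gene_id), ]
  b <- res2$promoters[order(res2$promoters$gene_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  expect_equal(res2$summary$n_upstream_extracted, s$n_upstream_extracted)

  # an id on a chromosome missing from the genome becomes a counted status
  feats2 <- feats
  feats2$seqid[feats2$attributes |> vapply(function(a) a[["ID"]], "") == "SYNG0001"] <- "chrZ"
  res3 <- suppressMessages(extract_promoters(store, ids, feats2, p))
  expect_equal(res3$summary$n_missing_chromosome, 1L)
})
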