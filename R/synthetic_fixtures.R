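#' Specification for a synthetic genome/annotation fixture
#'
#' Describes a deterministic desk-scale triple of inputs — genome FASTA, gene
#' FASTA and GFF3 annotation — with planted, recorded ground-truth flanks, so
#' that every stage of the extraction pipeline can be validated without any
#' external downloads. The same seed always produces byte-identical files.
#'
#' Boundary genes are deliberately placed closer than `flank_len` to a
#' chromosome end on their upstream-oriented side (the left end for a
#' plus-strand gene, the right end for a minus-strand gene), so under the
#' `skip` boundary policy exactly `n_boundary_genes` upstream extractions
#' fail. At most two boundary genes fit per chromosome (one per end).
#'
#' @param seed Integer RNG seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Integer vector of chromosome lengths in bp
#'   (recycled to `n_chromosomes`).
#' @param n_genes Total genes to plant (non-overlapping within a chromosome).
#' @param gene_length_range Length-2 integer vector, min/max gene length (bp).
#' @param flank_len Flank length (bp) used when recording ground-truth
#'   upstream/downstream sequences; also the clearance kept around interior
#'   genes.
#' @param fraction_minus_strand Probability that an interior gene is on the
#'   minus strand.
#' @param n_boundary_genes Genes planted with insufficient upstream flank.
#' @param n_decoy_features Non-gene/mRNA annotation rows (exon, CDS, tRNA,
#'   UTR) interleaved as distractors; half reuse a real gene id to exercise
#'   the feature-type filter.
#' @param version_suffix_probability Probability that a requested gene id in
#'   the gene FASTA carries a `.<digits>` version suffix absent from the
#'   annotation's gene row (exercising fallback matching).
#' @param n_blocks If TRUE, a short run of `N` bases is inserted into each
#'   chromosome outside all gene/flank regions, to exercise ambiguity-code
#'   handling.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_chromosomes = 2L,
                         chromosome_lengths = 15000L,
                         n_genes = 50L,
                         gene_length_range = c(100L, 400L),
                         flank_len = 200L,
                         fraction_minus_strand = 0.5,
                         n_boundary_genes = 3L,
                         n_decoy_features = 10L,
                         version_suffix_probability = 0.3,
                         n_blocks = FALSE) {
  chromosome_lengths <- rep_len(as.integer(chromosome_lengths), n_chromosomes)
  spec <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths = chromosome_lengths,
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    flank_len = as.integer(flank_len),
    fraction_minus_strand = fraction_minus_strand,
    n_boundary_genes = as.integer(n_boundary_genes),
    n_decoy_features = as.integer(n_decoy_features),
    version_suffix_probability = version_suffix_probability,
    n_blocks = isTRUE(n_blocks)
  )
  stopifnot(
    spec$n_chromosomes >= 1L,
    all(spec$chromosome_lengths > 0L),
    spec$n_genes >= 1L,
    length(spec$gene_length_range) == 2L,
    spec$gene_length_range[1] >= 1L,
    spec$gene_length_range[1] <= spec$gene_length_range[2],
    spec$flank_len >= 0L,
    spec$fraction_minus_strand >= 0, spec$fraction_minus_strand <= 1,
    spec$n_boundary_genes >= 0L,
    spec$n_boundary_genes <= spec$n_genes,
    spec$version_suffix_probability >= 0, spec$version_suffix_probability <= 1
  )
  if (spec$n_boundary_genes > 2L * spec$n_chromosomes) {
    stop("at most 2 boundary genes per chromosome (one per end)", call. = FALSE)
  }
  if (spec$n_boundary_genes > 0L && spec$flank_len == 0L) {
    stop("boundary genes require flank_len >= 1", call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic input triple with planted ground truth
#'
#' Writes `genome.fa`, `genes.fa`, `annot.gff3` and `ground_truth.csv` into
#' `out_dir` according to a [fixture_spec()] and returns the ground truth:
#' per planted gene, its id as written in the gene FASTA, coordinates,
#' strand, the true upstream and downstream flank of length `flank_len`
#' (5'-oriented, reverse-complemented on the minus strand), and whether each
#' side is expected to fail at a chromosome boundary. Ground-truth flanks are
#' computed directly from the simulated chromosome strings (independently of
#' the extraction engine), so the generator doubles as an oracle.
#'
#' Each gene gets one `gene` annotation row plus 0--2 `mRNA` rows sharing its
#' coordinates (ids `<gene>.1`, `<gene>.2`); decoy rows of other feature
#' types are interleaved. Nucleotides are i.i.d. uniform over A/C/G/T.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory, created if needed.
#' @return A list of class `promoter_fixture`: `truth` (data frame),
#'   `paths` (named list: genome, genes, gff, truth), `spec`.
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 7, n_genes = 10), tempfile())
#' head(fx$truth)
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  K <- spec$flank_len
  lens <- spec$chromosome_lengths
  chrom_ids <- sprintf("chr%d", seq_len(spec$n_chromosomes))

  # --- plan gene placement ---------------------------------------------------
  # boundary genes: one per chromosome end, alternating left (+) / right (-)
  n_bnd <- spec$n_boundary_genes
  bnd_plan <- if (n_bnd > 0L) {
    ends <- data.frame(
      chrom = rep(seq_len(spec$n_chromosomes), 2L),
      side = rep(c("left", "right"), each = spec$n_chromosomes)
    )
    ends[order(ends$chrom, ends$side), ][seq_len(n_bnd), ]
  } else {
    data.frame(chrom = integer(0), side = character(0))
  }

  n_int <- spec$n_genes - n_bnd
  int_chrom <- rep_len(seq_len(spec$n_chromosomes), n_int)

  genes <- list()
  gi <- 0L
  rand_len <- function(n) {
    if (spec$gene_length_range[1] == spec$gene_length_range[2]) {
      rep(spec$gene_length_range[1], n)
    } else {
      sample(spec$gene_length_range[1]:spec$gene_length_range[2], n, replace = TRUE)
    }
  }

  for (c_i in seq_len(spec$n_chromosomes)) {
    N <- lens[c_i]
    left <- any(bnd_plan$chrom == c_i & bnd_plan$side == "left")
    right <- any(bnd_plan$chrom == c_i & bnd_plan$side == "right")
    region_lo <- K + 1L   # interior genes keep full flank clearance
    region_hi <- N - K

    if (left) {
      len <- rand_len(1L)
      # start within K of the left end: upstream window [start-K, start-1]
      # crosses position 1 (K >= 1 required for a boundary gene to make sense)
      start <- if (K > 1L) sample(seq_len(K), 1L) else 1L
      end <- start + len - 1L
      if (end > N - K) stop("chromosome too short for requested genes", call. = FALSE)
      gi <- gi + 1L
      genes[[gi]] <- list(chrom = c_i, start = start, end = end,
                          strand = "+", boundary = TRUE)
      region_lo <- max(region_lo, end + 1L)
    }
    if (right) {
      len <- rand_len(1L)
      end <- N - (if (K > 1L) sample(seq_len(K), 1L) else 1L) + 1L
      start <- end - len + 1L
      if (start < K + 1L) stop("chromosome too short for requested genes", call. = FALSE)
      gi <- gi + 1L
      genes[[gi]] <- list(chrom = c_i, start = start, end = end,
                          strand = "-", boundary = TRUE)
      region_hi <- min(region_hi, start - 1L)
    }

    k <- sum(int_chrom == c_i)
    if (k > 0L) {
      glens <- rand_len(k)
      avail <- region_hi - region_lo + 1L
      slack <- avail - sum(glens)
      if (slack < k) stop("chromosome too short for requested genes", call. = FALSE)
      offs <- sort(sample.int(slack - k + 1L, k, replace = TRUE))
      starts <- region_lo - 1L + offs + c(0L, cumsum(glens))[seq_len(k)] + seq_len(k) - 1L
      ends <- starts + glens - 1L
      strands <- ifelse(stats::runif(k) < spec$fraction_minus_strand, "-", "+")
      for (j in seq_len(k)) {
        gi <- gi + 1L
        genes[[gi]] <- list(chrom = c_i, start = starts[j], end = ends[j],
                            strand = strands[j], boundary = FALSE)
      }
    }
  }

  # --- simulate chromosomes --------------------------------------------------
  chrom_seq <- vapply(lens, function(N) {
    paste(sample(c("A", "C", "G", "T"), N, replace = TRUE), collapse = "")
  }, character(1))
  names(chrom_seq) <- chrom_ids

  if (spec$n_blocks) {
    # drop a 10 bp N run into unoccupied, flank-free space on each chromosome
    occ <- lapply(seq_len(spec$n_chromosomes), function(c_i) {
      g <- Filter(function(x) x$chrom == c_i, genes)
      if (!length(g)) return(cbind(lo = integer(0), hi = integer(0)))
      cbind(lo = vapply(g, function(x) max(1L, x$start - K), integer(1)),
            hi = vapply(g, function(x) min(lens[c_i], x$end + K), integer(1)))
    })
    for (c_i in seq_len(spec$n_chromosomes)) {
      N <- lens[c_i]
      if (N < 20L) next
      cand <- setdiff(seq_len(N - 9L), unlist(lapply(seq_len(nrow(occ[[c_i]])), function(r) {
        seq(max(1L, occ[[c_i]][r, "lo"] - 9L), occ[[c_i]][r, "hi"])
      })))
      if (length(cand)) {
        pos <- cand[sample.int(length(cand), 1L)]
        substr(chrom_seq[c_i], pos, pos + 9L) <- strrep("N", 10L)
      }
    }
  }

  # --- ground truth ----------------------------------------------------------
  ng <- length(genes)
  gene_id <- sprintf("SYNG%04d", seq_len(ng))
  truth <- data.frame(
    id = gene_id,
    seqid = chrom_ids[vapply(genes, `[[`, integer(1), "chrom")],
    start = vapply(genes, function(g) as.integer(g$start), integer(1)),
    end = vapply(genes, function(g) as.integer(g$end), integer(1)),
    strand = vapply(genes, `[[`, character(1), "strand"),
    boundary = vapply(genes, `[[`, logical(1), "boundary"),
    stringsAsFactors = FALSE
  )

  rc_oracle <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  flank_truth <- function(i) {
    N <- lens[match(truth$seqid[i], chrom_ids)]
    s <- truth$start[i]; e <- truth$end[i]
    chr <- chrom_seq[[truth$seqid[i]]]
    if (truth$strand[i] == "+") {
      up_ok <- s - K >= 1
      dn_ok <- e + K <= N
      up <- if (up_ok && K > 0) substr(chr, s - K, s - 1) else ""
      dn <- if (dn_ok && K > 0) substr(chr, e + 1, e + K) else ""
    } else {
      up_ok <- e + K <= N
      dn_ok <- s - K >= 1
      up <- if (up_ok && K > 0) rc_oracle(substr(chr, e + 1, e + K)) else ""
      dn <- if (dn_ok && K > 0) rc_oracle(substr(chr, s - K, s - 1)) else ""
    }
    list(up = up, dn = dn, up_fail = !up_ok, dn_fail = !dn_ok)
  }
  ft <- lapply(seq_len(ng), flank_truth)
  truth$true_upstream <- vapply(ft, `[[`, character(1), "up")
  truth$true_downstream <- vapply(ft, `[[`, character(1), "dn")
  truth$expect_upstream_fail <- vapply(ft, `[[`, logical(1), "up_fail")
  truth$expect_downstream_fail <- vapply(ft, `[[`, logical(1), "dn_fail")
  if (sum(truth$expect_upstream_fail | truth$expect_downstream_fail) != n_bnd) {
    stop("internal fixture error: planted boundary count mismatch", call. = FALSE)
  }

  # requested ids: sometimes version-suffixed relative to the annotation
  suffixed <- stats::runif(ng) < spec$version_suffix_probability
  truth$requested_id <- ifelse(
    suffixed, paste0(gene_id, ".", sample(1:3, ng, replace = TRUE)), gene_id
  )

  # --- annotation rows -------------------------------------------------------
  gff_rows <- character(0)
  for (i in seq_len(ng)) {
    base <- sprintf("%s\tpromexsim\t%%s\t%d\t%d\t.\t%s\t.\t%%s",
                    truth$seqid[i], truth$start[i], truth$end[i], truth$strand[i])
    gff_rows <- c(gff_rows, sprintf(base, "gene",
                                    sprintf("ID=%s;Name=%s", gene_id[i], gene_id[i])))
    for (m in seq_len(sample(0:2, 1L))) {
      gff_rows <- c(gff_rows, sprintf(base, "mRNA",
                                      sprintf("ID=%s.%d;Parent=%s", gene_id[i], m, gene_id[i])))
    }
  }
  if (spec$n_decoy_features > 0L) {
    decoy_types <- sample(c("exon", "CDS", "tRNA", "five_prime_UTR"),
                          spec$n_decoy_features, replace = TRUE)
    for (d in seq_len(spec$n_decoy_features)) {
      host <- sample.int(ng, 1L)
      did <- if (d %% 2L == 0L) gene_id[host] else sprintf("DECOY%03d", d)
      row <- sprintf("%s\tpromexsim\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     truth$seqid[host], decoy_types[d],
                     truth$start[host], truth$end[host], truth$strand[host], did)
      at <- sample.int(length(gff_rows) + 1L, 1L)
      gff_rows <- append(gff_rows, row, after = at - 1L)
    }
  }

  # --- write files -----------------------------------------------------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    genes = file.path(out_dir, "genes.fa"),
    gff = file.path(out_dir, "annot.gff3"),
    truth = file.path(out_dir, "ground_truth.csv")
  )

  fa <- character(0)
  for (c_i in seq_len(spec$n_chromosomes)) {
    body <- gsub("(.{70})", "\\1\n", chrom_seq[[c_i]])
    fa <- c(fa, paste0(">", chrom_ids[c_i], " synthetic"), strsplit(body, "\n")[[1L]])
  }
  writeLines(fa, paths$genome)

  gene_fa <- character(0)
  for (i in seq_len(ng)) {
    seq_i <- substr(chrom_seq[[truth$seqid[i]]], truth$start[i], truth$end[i])
    if (truth$strand[i] == "-") seq_i <- rc_oracle(seq_i)
    gene_fa <- c(gene_fa, paste0(">", truth$requested_id[i], " synthetic gene"), seq_i)
  }
  writeLines(gene_fa, paths$genes)

  writeLines(c("##gff-version 3", gff_rows), paths$gff)
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = TRUE)

  structure(list(truth = truth, paths = paths, spec = spec),
            class = "promoter_fixture")
}

#' @export
print.promoter_fixture <- function(x, ...) {
  cat("promoter_fixture: seed", x$spec$seed, "—", nrow(x$truth), "genes on",
      x$spec$n_chromosomes, "chromosome(s),", sum(x$truth$boundary),
      "boundary gene(s)\n")
  cat("  files:", dirname(x$paths$genome), "\n")
  invisible(x)
}
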