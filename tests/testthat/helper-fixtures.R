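# Hand-built fixtures and independent oracles, all generated in code.

# Three genes on two chromosomes; geneB has overlapping exon records.
#   geneA chr1:101-200        (100 bp)
#   geneB chr1:301-400 + 351-450 -> union 301-450 (150 bp)
#   geneC chr2:51-250         (200 bp)
write_three_gene_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id \"geneA\";",
    "chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id \"geneB\";",
    "chr1\ttest\texon\t351\t450\t.\t+\t.\tgene_id \"geneB\";",
    "chr2\ttest\texon\t51\t250\t.\t-\t.\tgene_id \"geneC\";"
  ), path)
  path
}

sam_header <- function(chrom_lengths = c(chr1 = 1000L, chr2 = 1000L)) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths)))
}

sam_record <- function(qname, rname, pos, cigar = "10M", flag = 0L) {
  rl <- sum(as.integer(
    regmatches(cigar, gregexpr("[0-9]+(?=[MIS=X])", cigar, perl = TRUE))[[1]]
  ))
  if (bitwAnd(flag, 4L)) {
    sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t*", qname, flag,
            strrep("A", max(rl, 1L)))
  } else {
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*", qname, flag, rname,
            pos, cigar, strrep("A", max(rl, 1L)))
  }
}

write_sam_fixture <- function(records,
                              chrom_lengths = c(chr1 = 1000L, chr2 = 1000L),
                              path = tempfile(fileext = ".sam")) {
  writeLines(c(sam_header(chrom_lengths), records), path)
  path
}

# SAM with n single-end fragments, all inside geneA, one record each.
write_flat_sam <- function(n, path = tempfile(fileext = ".sam")) {
  recs <- vapply(seq_len(n), function(i) {
    sam_record(sprintf("frag%05d", i), "chr1", 101L + (i %% 80L), "10M")
  }, character(1L))
  write_sam_fixture(recs, path = path)
}

# Independent brute-force counter: explicit per-base sets, no interval
# package, no shared code with count_fragments().
brute_force_counts <- function(sam_path, gtf_path, min_overlap = 1L,
                               ambiguous_policy = "discard") {
  gtf <- read.delim(gtf_path, header = FALSE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", gtf$V9)
  gene_ids <- unique(gid)
  gene_bases <- lapply(gene_ids, function(g) {
    rows <- which(gid == g)
    paste0(gtf$V1[rows[1L]], ":",
           unique(unlist(Map(seq, gtf$V4[rows], gtf$V5[rows]))))
  })
  names(gene_bases) <- gene_ids

  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- setNames(integer(length(gene_ids)), gene_ids)
  frags <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) || bitwAnd(flag, 256L) || bitwAnd(flag, 2048L)) {
      next
    }
    # walk the CIGAR: M/=/X/D cover reference, N skips, I/S consume none
    ops <- regmatches(f[6L], gregexpr("[0-9]+[MIDNSHP=X]", f[6L]))[[1L]]
    pos <- as.integer(f[4L])
    covered <- integer(0)
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X", "D")) {
        covered <- c(covered, seq(pos, pos + n - 1L))
        pos <- pos + n
      } else if (type == "N") {
        pos <- pos + n
      }
    }
    key <- paste0(f[3L], ":", covered)
    frags[[f[1L]]] <- unique(c(frags[[f[1L]]], key))
  }
  assigned <- 0L; ambiguous <- 0L; unassigned <- 0L
  for (bases in frags) {
    hits <- gene_ids[vapply(gene_ids, function(g) {
      length(intersect(bases, gene_bases[[g]])) >= min_overlap
    }, logical(1L))]
    if (length(hits) == 0L) {
      unassigned <- unassigned + 1L
    } else if (length(hits) == 1L) {
      counts[hits] <- counts[hits] + 1L
      assigned <- assigned + 1L
    } else {
      ambiguous <- ambiguous + 1L
      if (ambiguous_policy == "count_all") {
        counts[hits] <- counts[hits] + 1L
      }
    }
  }
  list(counts = counts, assigned = assigned, ambiguous = ambiguous,
       unassigned = unassigned)
}

# Gompertz curve sampler for fitting tests.
gompertz_points <- function(a, b, c, fractions = seq(0.1, 1, 0.1),
                            replicates = 1L, noise_sd = 0) {
  x <- rep(fractions, each = replicates)
  y <- a * exp(-b * exp(-c * x))
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  data.frame(fraction = x, expressed_genes = y)
}
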