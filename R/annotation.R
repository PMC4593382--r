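#' Gene annotations for counting and normalization
#'
#' A `gene_annotation` holds one record per gene: its chromosome, strand,
#' and the union of its exon intervals. Overlapping exons of a gene are
#' merged so that the per-gene length (in kilobases) counts every exonic
#' base exactly once; this length is the `L_i` used by RPKM.
#'
#' Coordinates follow the GTF convention: 1-based, inclusive at both ends.
#'
#' @param path Path to an annotation file.
#' @param format `"gtf"` (attribute key `gene_id`) or `"saf"` (tab-separated
#'   with header columns `GeneID`, `Chr`, `Start`, `End`, `Strand`).
#'
#' @return A `gene_annotation` object: a list with
#'   \describe{
#'     \item{genes}{`data.frame` with one row per gene in file order:
#'       `gene_id`, `chrom`, `strand`, `n_exons`, `length_kb`.}
#'     \item{exons}{`GRanges` of merged exon intervals, one or more per
#'       gene, with metadata column `gene_id`.}
#'   }
#'   Gene order is the order of first appearance in the file, so re-reading
#'   the same file reproduces the same annotation.
#'
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   "chr1\tsrc\texon\t1\t1000\t.\t+\t.\tgene_id \"g1\";",
#'   "chr1\tsrc\texon\t501\t1500\t.\t+\t.\tgene_id \"g1\";"
#' ), gtf)
#' ann <- read_annotation(gtf, format = "gtf")
#' ann$genes$length_kb  # 1.5: overlapping exons are not double-counted
#' @export
read_annotation <- function(path, format = c("gtf", "saf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_user("annotation file not found: %s", path)
  tab <- switch(format,
    gtf = parse_gtf_exons(path),
    saf = parse_saf(path)
  )
  if (nrow(tab) == 0L) stop_user("no gene records found in %s", path)
  build_annotation(tab)
}

# Returns data.frame(gene_id, chrom, start, end, strand), one row per exon
# record, in file order.
parse_gtf_exons <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop_user("malformed GTF record at line %d of %s: expected 9 tab-separated fields, got %d",
              bad, path, nf[which(nf != 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  feature <- m[, 3L]
  use <- feature == "exon"
  if (!any(use)) stop_user("no exon records found in %s", path)
  m <- m[use, , drop = FALSE]
  idx <- idx[use]
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < start)
  if (length(bad)) {
    stop_user("malformed GTF record at line %d of %s: invalid start/end (%s, %s)",
              idx[bad[1L]], path, m[bad[1L], 4L], m[bad[1L], 5L])
  }
  gid <- gtf_attribute(m[, 9L], "gene_id")
  bad <- which(is.na(gid))
  if (length(bad)) {
    stop_user("malformed GTF record at line %d of %s: no gene_id attribute",
              idx[bad[1L]], path)
  }
  data.frame(gene_id = gid, chrom = m[, 1L], start = start, end = end,
             strand = m[, 7L], stringsAsFactors = FALSE)
}

gtf_attribute <- function(attr, key) {
  # 'gene_id "g1";' or 'gene_id g1;'
  pat <- paste0("(^|;)\\s*", key, "\\s+\"?([^\";]+)\"?")
  m <- regexec(pat, attr)
  vapply(regmatches(attr, m), function(x) {
    if (length(x) >= 3L) x[3L] else NA_character_
  }, character(1L))
}

parse_saf <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("GeneID", "Chr", "Start", "End", "Strand")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_user("SAF file %s lacks required column(s): %s",
              path, paste(missing, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(tab$Start))
  end <- suppressWarnings(as.integer(tab$End))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < start)
  if (length(bad)) {
    # +1 for the header line
    stop_user("malformed SAF record at line %d of %s: invalid Start/End",
              bad[1L] + 1L, path)
  }
  data.frame(gene_id = as.character(tab$GeneID), chrom = as.character(tab$Chr),
             start = start, end = end, strand = as.character(tab$Strand),
             stringsAsFactors = FALSE)
}

build_annotation <- function(tab) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(tab)))
  tab$strand[!tab$strand %in% c("+", "-")] <- "*"
  gene_ids <- unique(tab$gene_id)
  # each gene must live on one chromosome
  chrom_per_gene <- tapply(tab$chrom, tab$gene_id, function(x) length(unique(x)))
  multi <- names(chrom_per_gene)[chrom_per_gene > 1L]
  if (length(multi)) {
    stop_user("gene '%s' has exon records on multiple chromosomes", multi[1L])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  gr$gene_id <- tab$gene_id
  # merge overlapping/adjacent exons per gene (strand-blind union)
  grl <- GenomicRanges::split(GenomicRanges::granges(gr), tab$gene_id)
  merged <- GenomicRanges::reduce(grl, ignore.strand = TRUE)
  merged <- merged[gene_ids]  # restore file order
  exons <- unlist(merged, use.names = FALSE)
  exons$gene_id <- rep(gene_ids, lengths(merged))
  len_bp <- vapply(as.list(merged), function(x) sum(IRanges::width(x)),
                   numeric(1L))
  first <- !duplicated(tab$gene_id)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = tab$chrom[first][match(gene_ids, tab$gene_id[first])],
    strand = tab$strand[first][match(gene_ids, tab$gene_id[first])],
    n_exons = as.integer(lengths(merged)[gene_ids]),
    length_kb = unname(len_bp[gene_ids]) / 1000,
    stringsAsFactors = FALSE
  )
  stopifnot(all(genes$length_kb > 0))
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d sequence(s), %d merged exon(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom)), length(x$exons)))
  invisible(x)
}

#' Number of genes in an annotation
#'
#' @param annotation A `gene_annotation`.
#' @return Integer gene count `G`.
#' @export
n_genes <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  nrow(annotation$genes)
}

#' Per-gene merged exon lengths in kilobases
#'
#' @param annotation A `gene_annotation`.
#' @return Named numeric vector of exon-union lengths (kb), in annotation
#'   order.
#' @export
gene_lengths_kb <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  setNames(annotation$genes$length_kb, annotation$genes$gene_id)
}
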