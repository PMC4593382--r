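#' Summarize mapped fragments into gene-level counts
#'
#' A minimal featureCounts-style counter. Every mapped fragment is
#' assigned at most once: the reference bases covered by its primary
#' alignment records (junction-aware — the aligned blocks of the CIGAR,
#' not the full span) are intersected with each gene's merged exon
#' intervals, and a fragment whose exonic overlap with exactly one gene
#' reaches `min_overlap` bases increments that gene. Fragments reaching
#' the threshold for two or more genes are handled by `ambiguous_policy`.
#' Counting is unstranded and invariant to record order.
#'
#' @param alignments SAM/BAM path or an [alignment_set()].
#' @param annotation A [read_annotation()] result.
#' @param min_overlap Minimum exon-overlap (bases) required for
#'   assignment; default 1.
#' @param ambiguous_policy `"discard"` (default: a fragment overlapping
#'   several genes counts for none) or `"count_all"` (it increments each).
#' @return A `count_vector`: list with `sample_id`, `counts` (named
#'   integer vector in annotation order), `library_size`
#'   (`sum(counts)`), and an `assignment` breakdown
#'   (`assigned`/`ambiguous`/`unassigned` fragments; these sum to the
#'   mapped-fragment total).
#' @export
count_fragments <- function(alignments, annotation, min_overlap = 1L,
                            ambiguous_policy = c("discard", "count_all")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!is_count(min_overlap)) stop_user("min_overlap must be a positive integer")
  if (!inherits(alignments, "alignment_set")) {
    alignments <- alignment_set(alignments)
  }
  sample_id <- sub("\\.(sam|bam)$", "", basename(alignments$source),
                   ignore.case = TRUE)
  rec <- parse_sam_records(alignments$records)
  # primary mapped records only
  keep <- !bitwAnd(rec$flag, FLAG_UNMAPPED) &
    !bitwAnd(rec$flag, FLAG_SECONDARY) &
    !bitwAnd(rec$flag, FLAG_SUPPLEMENTARY)
  rec <- rec[keep, , drop = FALSE]
  gene_ids <- annotation$genes$gene_id
  counts <- setNames(integer(length(gene_ids)), gene_ids)
  n_mapped_frag <- length(unique(rec$qname))
  if (nrow(rec) == 0L) {
    return(new_count_vector(sample_id, counts, assigned = 0L,
                            ambiguous = 0L, unassigned = 0L))
  }

  # aligned reference blocks per record (N gaps excluded)
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    rec$cigar, pos = rec$pos, drop.D.ranges = FALSE
  )
  frag <- match(rec$qname, unique(rec$qname))
  bl <- unlist(blocks, use.names = FALSE)
  bl_gr <- GenomicRanges::GRanges(
    seqnames = rep(rec$rname, lengths(blocks)),
    ranges = bl
  )
  bl_frag <- rep(frag, lengths(blocks))

  # overlap with merged exons; chroms absent from the annotation simply
  # produce no hits and leave those fragments unassigned
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(bl_gr, annotation$exons,
                                        ignore.strand = TRUE)
  )
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(IRanges::ranges(bl_gr)[qh],
                              IRanges::ranges(annotation$exons)[sh])
    dt <- data.table::data.table(
      frag = bl_frag[qh],
      gene = annotation$exons$gene_id[sh],
      w = IRanges::width(ov)
    )
    per <- dt[, list(w = sum(w)), by = c("frag", "gene")]
    per <- per[per$w >= min_overlap]
  } else {
    per <- data.table::data.table(frag = integer(), gene = character(),
                                  w = integer())
  }

  if (nrow(per)) {
    ngenes <- per[, list(k = data.table::uniqueN(gene)), by = "frag"]
    uni_frags <- ngenes$frag[ngenes$k == 1L]
    amb_frags <- ngenes$frag[ngenes$k > 1L]
    inc <- if (ambiguous_policy == "count_all") {
      per
    } else {
      per[per$frag %in% uni_frags]
    }
    tab <- inc[, list(n = data.table::uniqueN(frag)), by = "gene"]
    counts[tab$gene] <- as.integer(tab$n)
    assigned <- length(uni_frags)
    ambiguous <- length(amb_frags)
  } else {
    assigned <- 0L
    ambiguous <- 0L
  }
  unassigned <- n_mapped_frag - assigned - ambiguous
  new_count_vector(sample_id, counts, assigned = assigned,
                   ambiguous = ambiguous, unassigned = unassigned)
}

new_count_vector <- function(sample_id, counts, assigned, ambiguous,
                             unassigned) {
  stopifnot(all(counts >= 0L))
  structure(list(
    sample_id = sample_id,
    counts = counts,
    library_size = sum(as.numeric(counts)),
    assignment = c(assigned = assigned, ambiguous = ambiguous,
                   unassigned = unassigned)
  ), class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  cat(sprintf("count_vector '%s': %d genes, library size %.0f\n",
              x$sample_id, length(x$counts), x$library_size))
  invisible(x)
}

#' Assemble count vectors into a gene-by-sample count matrix
#'
#' @param count_vectors List of `count_vector` objects over the same
#'   annotation (identical gene sets, same order).
#' @param condition_labels Optional named character vector mapping
#'   sample_id to group label.
#' @return A `count_matrix`: list with `values` (G x S integer matrix,
#'   rownames gene ids, colnames sample ids), `samples`, and
#'   `condition_labels`.
#' @export
count_matrix <- function(count_vectors, condition_labels = NULL) {
  stopifnot(length(count_vectors) >= 1L,
            all(vapply(count_vectors, inherits, logical(1L), "count_vector")))
  genes <- names(count_vectors[[1L]]$counts)
  for (cv in count_vectors) {
    if (!identical(names(cv$counts), genes)) {
      stop_user("count vectors are not over the same annotation")
    }
  }
  values <- vapply(count_vectors, function(cv) cv$counts,
                   numeric(length(genes)))
  if (all(values == floor(values))) storage.mode(values) <- "integer"
  samples <- vapply(count_vectors, function(cv) cv$sample_id, character(1L))
  colnames(values) <- samples
  structure(list(values = values, samples = samples,
                 condition_labels = condition_labels),
            class = "count_matrix")
}

#' Write / read gene-level counts as TSV
#'
#' Plain tab-separated text: a `gene_id` column followed by one integer
#' column per sample. Round-trips bit-exactly.
#'
#' @param x A `count_vector` or `count_matrix`.
#' @param path TSV path.
#' @return `write_counts` returns `path` invisibly; `read_counts` a
#'   `count_matrix`.
#' @export
write_counts <- function(x, path) {
  if (inherits(x, "count_vector")) {
    tab <- data.frame(gene_id = names(x$counts), x$counts,
                      check.names = FALSE)
    names(tab)[2L] <- x$sample_id
  } else if (inherits(x, "count_matrix")) {
    tab <- data.frame(gene_id = rownames(x$values), x$values,
                      check.names = FALSE)
  } else {
    stop_user("x must be a count_vector or count_matrix")
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param condition_labels Optional sample-to-group mapping attached on
#'   read.
#' @export
read_counts <- function(path, condition_labels = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id") {
    stop_user("count file %s must start with a gene_id column", path)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$gene_id
  structure(list(values = values, samples = colnames(values),
                 condition_labels = condition_labels),
            class = "count_matrix")
}

# Pull one sample out of a count_matrix as a count_vector.
matrix_column <- function(cm, sample_id) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$values[, sample_id]
  new_count_vector(sample_id, counts, assigned = NA_integer_,
                   ambiguous = NA_integer_, unassigned = NA_integer_)
}
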