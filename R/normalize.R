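#' Counts-per-million normalization
#'
#' CPM rescales raw gene counts by the library size:
#' `cpm_i = counts_i * 1e6 / N_lib`, where `N_lib` is the sum of all gene
#' counts in the sample. Per sample the CPM values always sum to 1e6, so
#' their mean over a full annotation of G genes is the constant `1e6 / G`
#' regardless of sequencing depth.
#'
#' @param counts A `count_vector` (see [count_fragments()]).
#' @return A `normalized_vector`: list with `sample_id`, `values` (named
#'   numeric vector), and `method`.
#' @export
cpm <- function(counts) {
  stopifnot(inherits(counts, "count_vector"))
  if (counts$library_size <= 0) stop_user("empty library: library_size is 0")
  values <- counts$counts * 1e6 / counts$library_size
  structure(list(sample_id = counts$sample_id, values = values,
                 method = "cpm"), class = "normalized_vector")
}

#' Reads-per-kilobase-per-million normalization
#'
#' RPKM additionally divides by the gene's merged exon length in
#' kilobases: `rpkm_i = counts_i * 1e6 / (N_lib * L_i)`. With all lengths
#' equal to 1 kb, RPKM coincides with CPM.
#'
#' @param counts A `count_vector`.
#' @param annotation The [read_annotation()] the counts were made against
#'   (supplies `L_i`).
#' @return A `normalized_vector` with `method = "rpkm"`.
#' @export
rpkm <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_vector"),
            inherits(annotation, "gene_annotation"))
  if (counts$library_size <= 0) stop_user("empty library: library_size is 0")
  len <- gene_lengths_kb(annotation)
  if (!identical(names(len), names(counts$counts))) {
    stop_user("annotation gene order does not match the count vector")
  }
  if (any(len <= 0)) stop_user("zero gene length in annotation")
  values <- counts$counts * 1e6 / (counts$library_size * len)
  structure(list(sample_id = counts$sample_id, values = values,
                 method = "rpkm"), class = "normalized_vector")
}

#' @export
print.normalized_vector <- function(x, ...) {
  cat(sprintf("normalized_vector '%s' (%s): %d genes, mean %.4f\n",
              x$sample_id, x$method, length(x$values), mean(x$values)))
  invisible(x)
}

#' Direct scaling of a count matrix
#'
#' The computational shortcut contrasted with read subsampling: every
#' entry `c_ij` is multiplied by the depth fraction `f`, so the ratio of
#' total scaled counts to total counts equals `f` exactly. Scaled entries
#' are real-valued by default; `rounding = "nearest"` returns integers.
#' Because scaling is a per-sample constant, CPM of a scaled matrix
#' equals CPM of the original — scaling never changes which genes are
#' nonzero, which is precisely how it diverges from true subsampling on
#' threshold-based statistics.
#'
#' @param matrix A `count_matrix`.
#' @param fraction Depth fraction in (0, 1].
#' @param rounding `"none"` (default) or `"nearest"`.
#' @return A `count_matrix`-shaped object with scaled `values`.
#' @export
scale_count_matrix <- function(matrix, fraction,
                               rounding = c("none", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(matrix, "count_matrix"))
  if (!is_fraction(fraction)) stop_user("fraction must lie in (0, 1]")
  values <- matrix$values * fraction
  if (rounding == "nearest") values <- round(values)
  structure(list(values = values, samples = matrix$samples,
                 condition_labels = matrix$condition_labels,
                 fraction = fraction),
            class = "count_matrix")
}
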