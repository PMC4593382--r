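#' Subsampling specification
#'
#' Bundles the parameters of a depth-reduction experiment: the grid of
#' depth fractions, the number of replicates per depth, and the base seed.
#' The defaults mirror the reference protocol: fractions
#' `{0.1, ..., 0.9, 1.0}` with `R = 24` replicates each, i.e. 240
#' subsampled datasets per biological sample.
#'
#' @param depth_grid Numeric vector of depth fractions, each in (0, 1].
#' @param replicates Positive integer `R`, replicates per depth.
#' @param base_seed Integer; replicate `r` at any depth uses seed
#'   `base_seed + r`.
#' @return A `subsample_spec` object.
#' @export
subsample_spec <- function(depth_grid = seq(0.1, 1.0, by = 0.1),
                           replicates = 24L, base_seed = 1L) {
  if (!length(depth_grid) || !all(vapply(depth_grid, is_fraction, logical(1L)))) {
    stop_user("depth_grid fractions must all lie in (0, 1]")
  }
  if (!is_count(replicates)) stop_user("replicates must be a positive integer")
  structure(list(depth_grid = as.numeric(depth_grid),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "subsample_spec")
}

#' Draw a depth-reduced subsample of aligned fragments
#'
#' Implements one DESIRE draw: selects `round(fraction * n_fragments)`
#' fragments uniformly at random *without replacement* (an m-out-of-n
#' bootstrap) and writes every alignment record of each selected fragment
#' to a new SAM file, header preserved verbatim. Selecting by fragment
#' keeps both mates of a pair, and any unmapped mate, together. The drawn
#' count is exact, not binomial; `fraction = 1` reproduces the input
#' fragment set.
#'
#' The selection depends only on the fragment-id set, the fraction, and
#' the seed — never on record order in the file.
#'
#' @param alignments An [alignment_set()].
#' @param fraction Depth fraction in (0, 1].
#' @param seed Integer seed for this draw.
#' @param out Output SAM path.
#' @return The [alignment_set()] of the written file, invisibly carrying
#'   attribute `selected` (the selected fragment ids).
#' @export
subsample_alignments <- function(alignments, fraction, seed, out) {
  stopifnot(inherits(alignments, "alignment_set"))
  if (!is_fraction(fraction)) stop_user("fraction must lie in (0, 1]")
  n <- alignments$n_fragments
  n_draw <- as.integer(round(fraction * n))  # round-half-even
  # sort ids so the draw is independent of file ordering
  pool <- sort(alignments$fragment_ids)
  selected <- if (fraction == 1) {
    pool
  } else {
    with_seed(seed, sample(pool, n_draw, replace = FALSE))
  }
  keep <- alignments$qname %in% selected
  write_sam(alignments$header, alignments$records[keep], out)
  res <- alignment_set(out)
  attr(res, "selected") <- selected
  res
}

#' Generate the full grid of subsampled replicates for one sample
#'
#' For each fraction in `spec$depth_grid`, draws `R` independent
#' subsamples (replicate `r` uses seed `base_seed + r`) and writes each to
#' `out_dir`. At `fraction = 1` every replicate is a degenerate "draw all",
#' so the full grid still yields `|depth_grid| * R` files.
#'
#' @param alignments An [alignment_set()].
#' @param spec A [subsample_spec()].
#' @param out_dir Output directory (created if needed).
#' @param sample_id Sample label recorded in the manifest; defaults to the
#'   source file name.
#' @param overwrite Overwrite an existing manifest in `out_dir`?
#' @return The manifest `data.frame` (also written to
#'   `out_dir/manifest.tsv`): columns `sample`, `fraction`, `replicate`,
#'   `seed`, `path`, `n_fragments`.
#' @export
generate_replicates <- function(alignments, spec, out_dir,
                                sample_id = NULL, overwrite = FALSE) {
  stopifnot(inherits(alignments, "alignment_set"),
            inherits(spec, "subsample_spec"))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(alignments$source),
                     ignore.case = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite) {
    stop_user("manifest already exists at %s (use overwrite = TRUE)",
              manifest_path)
  }
  rows <- vector("list", length(spec$depth_grid) * spec$replicates)
  k <- 0L
  for (f in spec$depth_grid) {
    for (r in seq_len(spec$replicates)) {
      seed <- spec$base_seed + r
      out <- file.path(out_dir, sprintf("%s_f%s_r%02d.sam",
                                        sample_id, format(f), r))
      sub <- subsample_alignments(alignments, f, seed, out)
      k <- k + 1L
      rows[[k]] <- data.frame(sample = sample_id, fraction = f,
                              replicate = r, seed = seed, path = out,
                              n_fragments = sub$n_fragments,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, manifest_path)
  manifest
}

#' Write / read a subsampling manifest
#'
#' @param manifest Manifest `data.frame` from [generate_replicates()].
#' @param path TSV path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_user("manifest not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}
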