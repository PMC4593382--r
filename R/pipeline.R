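#' Validated run configuration for the end-to-end pipeline
#'
#' Collects everything one depth-reduction experiment needs: input
#' alignment files (or a precomputed count matrix), the annotation, the
#' depth grid and replicate count, thresholds, normalization, seeds,
#' group labels, and the output directory. The configuration is validated
#' up front (fail-fast: a missing annotation aborts before any
#' subsampling) and serialized verbatim as YAML into the run directory.
#'
#' @param samples Named character vector of SAM/BAM paths
#'   (names = sample ids), or `NULL` when starting from `count_matrix_path`.
#' @param annotation_path Annotation file path.
#' @param annotation_format `"gtf"` or `"saf"`.
#' @param count_matrix_path Optional TSV count matrix to analyze directly.
#' @param depth_grid,replicates,base_seed As in [subsample_spec()].
#' @param theta_grid Expression thresholds.
#' @param normalization `"cpm"`, `"rpkm"`, or `"raw"` for the moment
#'   analysis.
#' @param group_labels Named character vector sample id -> group.
#' @param out_dir Run output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(samples = NULL, annotation_path,
                       annotation_format = c("gtf", "saf"),
                       count_matrix_path = NULL,
                       depth_grid = seq(0.1, 1.0, by = 0.1),
                       replicates = 24L, base_seed = 1L,
                       theta_grid = c(1L, 10L, 50L, 100L),
                       normalization = c("cpm", "rpkm", "raw"),
                       group_labels = NULL, out_dir = "desire_run") {
  annotation_format <- match.arg(annotation_format)
  normalization <- match.arg(normalization)
  if (!file.exists(annotation_path)) {
    stop_user("annotation not found: %s", annotation_path)
  }
  if (is.null(samples) && is.null(count_matrix_path)) {
    stop_user("provide sample alignment files or a count matrix")
  }
  if (!is.null(samples)) {
    if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
      stop_user("samples must be a named vector (names = sample ids)")
    }
    missing <- samples[!file.exists(samples)]
    if (length(missing)) {
      stop_user("alignment file not found: %s", missing[1L])
    }
  }
  spec <- subsample_spec(depth_grid, replicates, base_seed)  # validates
  cfg <- structure(list(
    samples = samples, annotation_path = annotation_path,
    annotation_format = annotation_format,
    count_matrix_path = count_matrix_path,
    depth_grid = spec$depth_grid, replicates = spec$replicates,
    base_seed = spec$base_seed, theta_grid = as.integer(theta_grid),
    normalization = normalization, group_labels = group_labels,
    out_dir = out_dir
  ), class = "run_config")
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys matching the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  samples <- if (!is.null(y$samples)) unlist(y$samples) else NULL
  group_labels <- if (!is.null(y$group_labels)) unlist(y$group_labels)
                  else NULL
  run_config(
    samples = samples,
    annotation_path = y$annotation_path,
    annotation_format = y$annotation_format %||% "gtf",
    count_matrix_path = y$count_matrix_path,
    depth_grid = y$depth_grid %||% seq(0.1, 1.0, by = 0.1),
    replicates = y$replicates %||% 24L,
    base_seed = y$base_seed %||% 1L,
    theta_grid = y$theta_grid %||% c(1L, 10L, 50L, 100L),
    normalization = y$normalization %||% "cpm",
    group_labels = group_labels,
    out_dir = y$out_dir %||% "desire_run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

save_run_config <- function(config, dir) {
  serializable <- config
  class(serializable) <- NULL
  yaml::write_yaml(serializable, file.path(dir, "run_config.yaml"))
}

run_log <- function(dir, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  cat(msg, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
}

#' Subsample every sample of a run configuration
#'
#' Wraps [generate_replicates()] per sample: each sample gets its own
#' subdirectory of subsampled SAM files plus a manifest; the combined
#' manifest (all samples) is written to `out_dir/manifest.tsv`. Inputs
#' are never mutated; rerunning with the same config reproduces the same
#' fragment selections.
#'
#' @param config A [run_config()].
#' @param overwrite Overwrite existing per-sample manifests?
#' @return The combined manifest `data.frame`.
#' @export
run_subsample <- function(config, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$samples)) {
    stop_user("run_subsample needs alignment files, not a count matrix")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_run_config(config, config$out_dir)
  spec <- subsample_spec(config$depth_grid, config$replicates,
                         config$base_seed)
  manifests <- lapply(names(config$samples), function(id) {
    aln <- alignment_set(config$samples[[id]])
    run_log(config$out_dir, "subsampling %s: %d fragments", id,
            aln$n_fragments)
    generate_replicates(aln, spec,
                        out_dir = file.path(config$out_dir, id),
                        sample_id = id, overwrite = overwrite)
  })
  manifest <- do.call(rbind, manifests)
  write_manifest(manifest, file.path(config$out_dir, "manifest.tsv"))
  run_log(config$out_dir, "wrote %d subsampled files", nrow(manifest))
  manifest
}

#' Count every file of a manifest and the full-depth samples
#'
#' @param config A [run_config()].
#' @param manifest Combined manifest from [run_subsample()]; defaults to
#'   `out_dir/manifest.tsv`.
#' @return List with `full` (named list of full-depth `count_vector`s)
#'   and `annotation`.
#' @export
run_count <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "run_config"))
  annotation <- read_annotation(config$annotation_path,
                                config$annotation_format)
  full <- lapply(names(config$samples), function(id) {
    count_fragments(config$samples[[id]], annotation)
  })
  names(full) <- names(config$samples)
  counts_dir <- file.path(config$out_dir, "counts")
  dir.create(counts_dir, recursive = TRUE, showWarnings = FALSE)
  cm <- count_matrix(full, condition_labels = config$group_labels)
  write_counts(cm, file.path(counts_dir, "full_depth_counts.tsv"))
  list(full = full, annotation = annotation)
}

#' Run the downstream analysis over a subsampling manifest
#'
#' Produces, under `out_dir/report/`: per-sample saturation-curve tables
#' for both the subsampling and the direct-scaling route, Gompertz fits
#' per (sample, theta), the optimal-depth estimate, per-group moment
#' tables, and (when two groups are labelled) the expressed-gene,
#' growth-rate, and moment comparison tables. Files are plain TSV and
#' deterministic for a given manifest.
#'
#' @param config A [run_config()] with `group_labels` for group
#'   comparisons.
#' @param manifest Manifest `data.frame`; defaults to
#'   `out_dir/manifest.tsv`.
#' @return Invisibly, a list of the computed tables.
#' @export
run_analyze <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(manifest)) {
    manifest <- read_manifest(file.path(config$out_dir, "manifest.tsv"))
  }
  missing <- !file.exists(manifest$path)
  if (any(missing)) {
    warning(sprintf("%d manifest file(s) missing; analyzing the rest",
                    sum(missing)))
    manifest <- manifest[!missing, , drop = FALSE]
  }
  annotation <- read_annotation(config$annotation_path,
                                config$annotation_format)
  report_dir <- file.path(config$out_dir, "report")
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)

  curves <- build_saturation_curves(manifest, annotation,
                                    theta_grid = config$theta_grid,
                                    method = "desire")
  write.table(curves, file.path(report_dir, "saturation_desire.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sample_ids <- unique(manifest$sample)
  full <- lapply(sample_ids, function(id) {
    if (!is.null(config$samples) && id %in% names(config$samples)) {
      count_fragments(config$samples[[id]], annotation)
    } else {
      NULL
    }
  })
  names(full) <- sample_ids
  full <- Filter(Negate(is.null), full)

  scaled <- NULL
  if (length(full)) {
    scaled <- do.call(rbind, lapply(full, function(cv) {
      build_saturation_curves(manifest, annotation,
                              theta_grid = config$theta_grid,
                              method = "scaled", counts_full = cv)
    }))
    write.table(scaled, file.path(report_dir, "saturation_scaled.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fits <- list()
  fit_rows <- list()
  for (th in config$theta_grid) {
    fits[[as.character(th)]] <- list()
    for (id in sample_ids) {
      sub <- curves[curves$theta == th & curves$sample == id, ]
      fit <- fit_gompertz(sub)
      fits[[as.character(th)]][[id]] <- fit
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        sample = id, theta = th, a = fit$a, b = fit$b, c = fit$c,
        se_a = fit$se[["a"]], se_b = fit$se[["b"]], se_c = fit$se[["c"]],
        converged = fit$converged)
    }
  }
  fit_tab <- do.call(rbind, fit_rows)
  write.table(fit_tab, file.path(report_dir, "gompertz_fits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  depth <- NULL
  if (length(full)) {
    lib <- vapply(full, function(cv) cv$library_size, numeric(1L))
    th1 <- as.character(config$theta_grid[1L])
    ok <- Filter(function(f) isTRUE(f$converged), fits[[th1]])
    ok <- ok[names(ok) %in% names(lib)]
    if (length(ok)) {
      depth <- estimate_optimal_depth(ok, lib)
      write.table(
        data.frame(estimator = c("I_mean_reads", "II_max_reads"),
                   reads = c(depth$mean_reads_bound, depth$max_reads_bound),
                   lower_bound = depth$is_lower_bound),
        file.path(report_dir, "optimal_depth.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  moments <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    cv <- count_fragments(manifest$path[i], annotation)
    vals <- switch(config$normalization,
                   cpm = cpm(cv), rpkm = rpkm(cv, annotation), raw = cv)
    distribution_moments(vals, sample_id = manifest$sample[i],
                         fraction = manifest$fraction[i],
                         replicate = manifest$replicate[i])
  }))
  write.table(moments, file.path(report_dir, "moments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  comparisons <- list()
  if (!is.null(config$group_labels)) {
    groups <- unique(config$group_labels)
    if (length(groups) == 2L) {
      ga <- names(config$group_labels)[config$group_labels == groups[1L]]
      gb <- names(config$group_labels)[config$group_labels == groups[2L]]
      th1 <- config$theta_grid[1L]
      ca <- curves[curves$sample %in% ga & curves$theta == th1, ]
      cb <- curves[curves$sample %in% gb & curves$theta == th1, ]
      if (length(unique(ca$sample)) >= 2L &&
          length(unique(cb$sample)) >= 2L) {
        comparisons$expressed <- compare_expressed_gene_medians(ca, cb)
        write.table(comparisons$expressed,
                    file.path(report_dir, "test_expressed_genes.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        fa <- fit_tab[fit_tab$sample %in% ga & fit_tab$converged, ]
        fb <- fit_tab[fit_tab$sample %in% gb & fit_tab$converged, ]
        comparisons$growth <- compare_growth_rates(fa, fb)
        write.table(comparisons$growth,
                    file.path(report_dir, "test_growth_rates.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        ma <- moments[moments$sample_id %in% ga & moments$fraction < 1, ]
        mb <- moments[moments$sample_id %in% gb & moments$fraction < 1, ]
        comparisons$moments <- compare_moments(ma, mb,
                                               pool_across_depths = TRUE)
        write.table(comparisons$moments,
                    file.path(report_dir, "test_moments.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        for (grp in groups) {
          ids <- names(config$group_labels)[config$group_labels == grp]
          mt <- moment_table(moments[moments$sample_id %in% ids &
                                       moments$fraction < 1, ])
          write.table(mt, file.path(report_dir,
                                    sprintf("moments_group_%s.tsv", grp)),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  run_log(config$out_dir, "analysis report written to %s", report_dir)
  invisible(list(curves = curves, scaled = scaled, fits = fit_tab,
                 depth = depth, moments = moments,
                 comparisons = comparisons))
}
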