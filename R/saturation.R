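#' Number of expressed genes at a threshold
#'
#' A gene is "expressed" at threshold `theta` when its raw count reaches
#' `theta` (`counts_i >= theta`). Thresholds act on raw counts, never on
#' normalized values.
#'
#' @param counts A `count_vector` or a bare numeric vector of raw counts.
#' @param theta Positive integer threshold (reference grid:
#'   1, 10, 50, 100).
#' @return Integer count of expressed genes.
#' @export
expressed_gene_count <- function(counts, theta) {
  if (inherits(counts, "count_vector")) counts <- counts$counts
  if (!is_count(theta)) stop_user("theta must be a positive integer")
  sum(counts >= theta)
}

#' Expressed-gene saturation curves across a depth grid
#'
#' Builds (depth, expressed-gene-count) points per threshold, by one of
#' two routes sharing the same depth grid:
#' \describe{
#'   \item{desire}{count each subsampled alignment file listed in a
#'     [generate_replicates()] manifest, then threshold the raw counts;}
#'   \item{scaled}{multiply the full-depth counts by each fraction
#'     ([scale_count_matrix()] with no rounding), then threshold.}
#' }
#'
#' For the scaled route the expression threshold is, by default, scaled
#' along with the counts (`scaled_value >= theta * fraction`, equivalent
#' to thresholding the full-depth counts): a threshold calibrated for
#' full depth must move with the unit change, and under this
#' depth-consistent reading direct scaling can never silence a gene —
#' whereas true subsampling loses low-count genes stochastically, which
#' is exactly the divergence between the two routes.
#' `scaled_threshold = "literal"` instead compares the real-valued scaled
#' counts against `theta` unchanged.
#'
#' @param manifest Manifest `data.frame` (desire route) or `NULL`.
#' @param annotation A [read_annotation()] result.
#' @param theta_grid Integer thresholds; default `c(1, 10, 50, 100)`.
#' @param method `"desire"` or `"scaled"`.
#' @param counts_full Full-depth `count_vector` (scaled route).
#' @param depth_grid Fractions for the scaled route; defaults to the
#'   manifest's grid or `seq(0.1, 1, 0.1)`.
#' @param scaled_threshold `"depth_adjusted"` (default) or `"literal"`,
#'   see Details.
#' @param min_overlap,ambiguous_policy Passed to [count_fragments()].
#' @return A `data.frame` of class `saturation_curves`: columns `sample`,
#'   `method`, `theta`, `fraction`, `replicate`, `expressed_genes`.
#' @export
build_saturation_curves <- function(manifest = NULL, annotation,
                                    theta_grid = c(1L, 10L, 50L, 100L),
                                    method = c("desire", "scaled"),
                                    counts_full = NULL, depth_grid = NULL,
                                    scaled_threshold = c("depth_adjusted",
                                                         "literal"),
                                    min_overlap = 1L,
                                    ambiguous_policy = "discard") {
  method <- match.arg(method)
  scaled_threshold <- match.arg(scaled_threshold)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!all(vapply(theta_grid, is_count, logical(1L)))) {
    stop_user("theta_grid must contain positive integers")
  }
  if (method == "desire") {
    if (is.null(manifest)) stop_user("desire curves require a manifest")
    missing <- !file.exists(manifest$path)
    if (any(missing)) {
      i <- which(missing)[1L]
      stop_user("manifest file missing for sample %s, fraction %s, replicate %d: %s",
                manifest$sample[i], format(manifest$fraction[i]),
                manifest$replicate[i], manifest$path[i])
    }
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      cv <- count_fragments(manifest$path[i], annotation,
                            min_overlap = min_overlap,
                            ambiguous_policy = ambiguous_policy)
      data.frame(sample = manifest$sample[i], method = "desire",
                 theta = as.integer(theta_grid),
                 fraction = manifest$fraction[i],
                 replicate = manifest$replicate[i],
                 expressed_genes = vapply(theta_grid, function(th) {
                   expressed_gene_count(cv, th)
                 }, integer(1L)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    if (is.null(counts_full)) {
      stop_user("scaled curves require the full-depth counts")
    }
    stopifnot(inherits(counts_full, "count_vector"))
    if (is.null(depth_grid)) {
      depth_grid <- if (!is.null(manifest)) sort(unique(manifest$fraction))
                    else seq(0.1, 1.0, by = 0.1)
    }
    rows <- lapply(depth_grid, function(f) {
      scaled <- counts_full$counts * f
      thr <- if (scaled_threshold == "depth_adjusted") theta_grid * f
             else theta_grid
      data.frame(sample = counts_full$sample_id, method = "scaled",
                 theta = as.integer(theta_grid), fraction = f,
                 replicate = 1L,
                 expressed_genes = vapply(seq_along(theta_grid),
                                          function(k) {
                   sum(scaled >= thr[k])
                 }, integer(1L)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  class(out) <- c("saturation_curves", "data.frame")
  out
}

#' Fit a Gompertz growth function to a saturation curve
#'
#' Fits `f(x) = a * exp(-b * exp(-c * x))` by nonlinear least squares
#' (Levenberg-Marquardt) to all replicate points pooled — not to per-depth
#' medians. `a` is the asymptotic number of expressed genes, `c` the
#' growth rate. Starting values: `a0` = max observed count (nudged up),
#' `c0 = 1`, and `b0` solved from the value at the smallest depth; on
#' failure a small multi-start grid over `c0` is tried. A degenerate or
#' non-convergent fit returns `converged = FALSE` instead of garbage.
#'
#' @param curve A `saturation_curves` data.frame restricted to one
#'   (sample, theta, method), or any data.frame with columns `fraction`
#'   (or `x`) and `expressed_genes` (or `y`).
#' @param x_scale `"fraction"` (default) fits against the depth fraction;
#'   `"reads"` multiplies x by `library_size`.
#' @param library_size Reads at full depth, required for
#'   `x_scale = "reads"`.
#' @return A `gompertz_fit`: list with `a`, `b`, `c`, `se` (named
#'   standard errors from the least-squares covariance), `converged`,
#'   `residual_sd`, `n_points`, and the data used.
#' @export
fit_gompertz <- function(curve, x_scale = c("fraction", "reads"),
                         library_size = NULL) {
  x_scale <- match.arg(x_scale)
  x <- if (!is.null(curve$fraction)) curve$fraction else curve$x
  y <- if (!is.null(curve$expressed_genes)) curve$expressed_genes else curve$y
  if (length(unique(x)) < 3L) {
    stop_user("Gompertz fit needs >= 3 distinct depths; got %d",
              length(unique(x)))
  }
  if (x_scale == "reads") {
    if (is.null(library_size)) {
      stop_user("x_scale = 'reads' requires library_size")
    }
    x <- x * library_size
  }
  dat <- data.frame(x = as.numeric(x), y = as.numeric(y))

  failed <- structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                           se = c(a = NA_real_, b = NA_real_, c = NA_real_),
                           converged = FALSE, residual_sd = NA_real_,
                           n_points = nrow(dat), data = dat),
                      class = "gompertz_fit")
  if (max(dat$y) <= 0 || stats::sd(dat$y) == 0) return(failed)

  a0 <- max(dat$y) * 1.05
  xmin <- min(dat$x)
  ymin <- max(mean(dat$y[dat$x == xmin]), 1e-8)
  starts_c <- c(1, 0.3, 3, 10, 0.1) / ifelse(x_scale == "reads",
                                             max(dat$x), 1)
  fit <- NULL
  for (c0 in starts_c) {
    b0 <- -log(min(ymin / a0, 0.999)) / exp(-c0 * xmin)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-b * exp(-c * x)), data = dat,
        start = list(a = a0, b = b0, c = c0),
        lower = c(a = 1e-8, b = 1e-8, c = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failed)
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) {
                   c(a = NA_real_, b = NA_real_, c = NA_real_)
                 })
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 c = unname(co["c"]),
                 se = c(a = unname(se["a"]), b = unname(se["b"]),
                        c = unname(se["c"])),
                 converged = TRUE,
                 residual_sd = stats::sigma(fit),
                 n_points = nrow(dat), data = dat),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("gompertz_fit: a = %.3f (%.3f), b = %.3f (%.3f), c = %.3f (%.3f); %d points\n",
                x$a, x$se["a"], x$b, x$se["b"], x$c, x$se["c"], x$n_points))
  } else {
    cat("gompertz_fit: not converged\n")
  }
  invisible(x)
}

#' Evaluate a fitted Gompertz function
#'
#' @param fit A `gompertz_fit`.
#' @param x Depths at which to evaluate.
#' @return `f(x) = a exp(-b exp(-c x))`.
#' @export
predict_gompertz <- function(fit, x) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!fit$converged) stop_user("fit did not converge")
  fit$a * exp(-fit$b * exp(-fit$c * x))
}

# relative slope (df/dx)/a of the fitted curve at depth x (fraction units)
gompertz_relative_slope <- function(fit, x = 1) {
  with(fit, b * c * exp(-c * x) * exp(-b * exp(-c * x)))
}

#' Estimate the optimal sequencing depth from saturation fits
#'
#' A sample's curve counts as *saturated* when its fitted relative slope
#' at full depth, `(df/dx)/a`, drops below `saturation_tolerance`. For a
#' saturated sample the required depth is the point where the relative
#' slope first reaches the tolerance, converted to reads; for an
#' unsaturated sample the full library size itself is only a *lower
#' bound* on the required depth. Two estimators are reported:
#' Estimator I (average depth) aggregates by the mean over samples,
#' Estimator II (individual depth) by the maximum.
#'
#' @param fits Named list of `gompertz_fit` objects, one per sample
#'   (names = sample ids).
#' @param library_sizes Named numeric vector of full-depth read counts
#'   per sample.
#' @param saturation_tolerance Relative slope per unit depth fraction
#'   below which a curve counts as saturated; default `1e-3`.
#' @return A `depth_estimate`: list with `mean_reads_bound` (Estimator I),
#'   `max_reads_bound` (Estimator II), `is_lower_bound` (TRUE when no
#'   sample saturated), per-sample `saturated` flags, and per-sample
#'   `required_reads`.
#' @export
estimate_optimal_depth <- function(fits, library_sizes,
                                   saturation_tolerance = 1e-3) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1L))
  if (!any(ok)) stop_user("no Gompertz fit converged; cannot estimate depth")
  ids <- names(fits)
  if (is.null(ids)) stop_user("fits must be a named list (sample ids)")
  libs <- library_sizes[ids]
  if (anyNA(libs)) stop_user("library_sizes missing for some samples")

  saturated <- setNames(logical(length(ids)), ids)
  required <- setNames(as.numeric(libs), ids)
  for (id in ids[ok]) {
    fit <- fits[[id]]
    slope1 <- gompertz_relative_slope(fit, 1)
    if (is.finite(slope1) && slope1 < saturation_tolerance) {
      saturated[id] <- TRUE
      # depth fraction at which the curve flattens to tolerance
      g <- function(x) gompertz_relative_slope(fit, x) - saturation_tolerance
      xstar <- if (g(0) <= 0) 0 else {
        tryCatch(stats::uniroot(g, c(0, 1))$root, error = function(e) 1)
      }
      required[id] <- xstar * libs[id]
    }
  }
  structure(list(
    mean_reads_bound = mean(required),
    max_reads_bound = max(required),
    is_lower_bound = !any(saturated),
    saturated = saturated,
    required_reads = required,
    saturation_tolerance = saturation_tolerance
  ), class = "depth_estimate")
}

#' @export
print.depth_estimate <- function(x, ...) {
  kind <- if (x$is_lower_bound) "lower bounds (no sample saturated)"
          else "estimates"
  cat(sprintf("depth_estimate (%s):\n  Estimator I  (average depth): %.0f reads\n  Estimator II (individual depth): %.0f reads\n",
              kind, x$mean_reads_bound, x$max_reads_bound))
  invisible(x)
}

# two-sample t test reported with all three alternatives; two groups that
# are both (numerically) constant carry no evidence: p = 1 when their
# means agree, 0/1 directional when they differ
three_sided_t <- function(a, b, var_equal = FALSE) {
  tol <- 1e-9 * max(abs(c(a, b)), 1)
  if (sd(a) <= tol && sd(b) <= tol) {
    d <- mean(a) - mean(b)
    eq <- abs(d) <= tol
    return(c(p_two_sided = as.numeric(eq),
             p_left_sided = as.numeric(eq || d > 0),
             p_right_sided = as.numeric(eq || d < 0)))
  }
  p <- vapply(c("two.sided", "less", "greater"), function(alt) {
    t.test(a, b, alternative = alt, var.equal = var_equal)$p.value
  }, numeric(1L))
  c(p_two_sided = p[[1L]], p_left_sided = p[[2L]], p_right_sided = p[[3L]])
}

#' Compare expressed-gene medians between two groups per depth
#'
#' For each depth fraction: take, per sample, the median expressed-gene
#' count over its replicates, then run a two-sample t test of the group
#' means of those medians (null: equal group means, conditioned on the
#' depth). All three alternatives are reported; "left-sided" tests
#' group A < group B.
#'
#' @param groupA,groupB `saturation_curves` data.frames restricted to one
#'   theta each (>= 2 samples per group).
#' @param var_equal Use the pooled-variance Student test instead of the
#'   Welch default?
#' @return `data.frame` with columns `fraction`, `p_two_sided`,
#'   `p_left_sided`, `p_right_sided`, `mean_A`, `mean_B`.
#' @export
compare_expressed_gene_medians <- function(groupA, groupB,
                                           var_equal = FALSE) {
  for (g in list(groupA, groupB)) {
    if (length(unique(g$sample)) < 2L) {
      stop_user("each group needs >= 2 samples")
    }
    if (length(unique(g$theta)) > 1L) {
      stop_user("restrict curves to a single theta before comparing")
    }
  }
  fractions <- sort(intersect(unique(groupA$fraction),
                              unique(groupB$fraction)))
  per_sample_median <- function(g, f) {
    sub <- g[g$fraction == f, ]
    tapply(sub$expressed_genes, sub$sample, median)
  }
  rows <- lapply(fractions, function(f) {
    a <- per_sample_median(groupA, f)
    b <- per_sample_median(groupB, f)
    p <- three_sided_t(a, b, var_equal = var_equal)
    data.frame(fraction = f, p_two_sided = p[["p_two_sided"]],
               p_left_sided = p[["p_left_sided"]],
               p_right_sided = p[["p_right_sided"]],
               mean_A = mean(a), mean_B = mean(b))
  })
  do.call(rbind, rows)
}

#' Compare Gompertz growth rates between two groups per threshold
#'
#' One fitted growth rate `c` per sample and threshold; per theta the
#' group means of `c` are compared by a two-sample t test, all three
#' alternatives reported.
#'
#' @param fitsA,fitsB `data.frame`s with columns `sample`, `theta`, `c`
#'   (one row per converged per-sample fit), or named lists of
#'   `gompertz_fit` grouped as `fits[[theta]][[sample]]`.
#' @param var_equal Pooled-variance Student test instead of Welch?
#' @return `data.frame` with columns `theta`, `p_two_sided`,
#'   `p_left_sided`, `p_right_sided`, `mean_A`, `mean_B`.
#' @export
compare_growth_rates <- function(fitsA, fitsB, var_equal = FALSE) {
  tab <- function(fits) {
    if (is.data.frame(fits)) return(fits)
    rows <- list()
    for (th in names(fits)) {
      for (id in names(fits[[th]])) {
        f <- fits[[th]][[id]]
        if (isTRUE(f$converged)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = id, theta = as.integer(th), c = f$c)
        }
      }
    }
    do.call(rbind, rows)
  }
  a <- tab(fitsA); b <- tab(fitsB)
  thetas <- sort(intersect(unique(a$theta), unique(b$theta)))
  rows <- lapply(thetas, function(th) {
    ca <- a$c[a$theta == th]
    cb <- b$c[b$theta == th]
    if (length(ca) < 2L || length(cb) < 2L) {
      stop_user("theta %d: each group needs >= 2 fitted samples", th)
    }
    p <- three_sided_t(ca, cb, var_equal = var_equal)
    data.frame(theta = th, p_two_sided = p[["p_two_sided"]],
               p_left_sided = p[["p_left_sided"]],
               p_right_sided = p[["p_right_sided"]],
               mean_A = mean(ca), mean_B = mean(cb))
  })
  do.call(rbind, rows)
}
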