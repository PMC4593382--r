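#' Moments of the per-sample expression distribution
#'
#' Summarizes the distribution of expression values *across genes within
#' one sample* (not the count distribution of a gene across samples) by
#' its first four moments: arithmetic mean, unbiased variance (n-1),
#' skewness `m3 / m2^(3/2)`, and plain (non-excess) kurtosis `m4 / m2^2`,
#' where `m_k` are central moments with denominator `n`. A normal
#' distribution therefore has kurtosis 3, not 0.
#'
#' By default the moments run over the full annotation vector, zeros
#' included — this preserves the CPM identity mean = 1e6/G. An optional
#' expression filter restricts to genes whose *raw* count reaches
#' `filter_theta` before the (possibly normalized) values are selected.
#'
#' @param values A `normalized_vector`, `count_vector`, or bare numeric
#'   vector.
#' @param filter_theta Optional positive integer threshold applied to
#'   `raw_counts`.
#' @param raw_counts Raw counts aligned with `values`; required when
#'   `filter_theta` is given and `values` is not itself a `count_vector`.
#' @param sample_id,fraction,replicate Optional labels carried into the
#'   summary row.
#' @return A one-row `data.frame` (class `moment_summary`): `sample_id`,
#'   `fraction`, `replicate`, `normalization`, `filter_theta`, `n_genes`,
#'   `mean`, `variance`, `skewness`, `kurtosis`. With zero variance the
#'   shape moments are `NA` (undefined), never an error.
#' @export
distribution_moments <- function(values, filter_theta = NULL,
                                 raw_counts = NULL, sample_id = NULL,
                                 fraction = NA_real_,
                                 replicate = NA_integer_) {
  normalization <- "raw"
  if (inherits(values, "normalized_vector")) {
    normalization <- values$method
    if (is.null(sample_id)) sample_id <- values$sample_id
    v <- values$values
  } else if (inherits(values, "count_vector")) {
    if (is.null(sample_id)) sample_id <- values$sample_id
    if (is.null(raw_counts)) raw_counts <- values$counts
    v <- as.numeric(values$counts)
  } else {
    v <- as.numeric(values)
  }
  if (!is.null(filter_theta)) {
    if (!is_count(filter_theta)) {
      stop_user("filter_theta must be a positive integer")
    }
    if (is.null(raw_counts)) {
      stop_user("filter_theta requires the raw counts the filter acts on")
    }
    if (length(raw_counts) != length(v)) {
      stop_user("raw_counts and values differ in length")
    }
    v <- v[raw_counts >= filter_theta]
  }
  if (length(v) < 2L) {
    stop_user("moments need >= 2 values after filtering (got %d)", length(v))
  }
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  if (m2 > 0) {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    skew <- NA_real_  # undefined on a degenerate distribution
    kurt <- NA_real_
  }
  out <- data.frame(
    sample_id = if (is.null(sample_id)) NA_character_ else sample_id,
    fraction = fraction, replicate = replicate,
    normalization = normalization,
    filter_theta = if (is.null(filter_theta)) NA_integer_
                   else as.integer(filter_theta),
    n_genes = n, mean = mu, variance = var(v),
    skewness = skew, kurtosis = kurt,
    stringsAsFactors = FALSE
  )
  class(out) <- c("moment_summary", "data.frame")
  out
}

#' Compare distribution moments between two phenotype groups
#'
#' Runs, per moment (mean, variance, skewness, kurtosis), a two-sample
#' t test between the groups, reporting two-, left- and right-sided
#' p values ("left-sided" tests group A < group B).
#'
#' With `pool_across_depths = TRUE` the test samples are the per-depth
#' medians over replicates (and samples) within each group — one value
#' per depth fraction, so a 9-fraction grid yields n = 9 per group.
#' Otherwise each row of the input is one observation.
#'
#' @param groupA,groupB `moment_summary` rows (rbind-ed data.frames).
#' @param pool_across_depths Pool to per-depth medians first?
#' @param var_equal Pooled-variance Student test instead of Welch?
#' @return `data.frame` with columns `moment`, `p_two_sided`,
#'   `p_left_sided`, `p_right_sided`, `n_A`, `n_B`. Degenerate
#'   zero-variance inputs on both sides give p = 1 by convention.
#' @export
compare_moments <- function(groupA, groupB, pool_across_depths = TRUE,
                            var_equal = FALSE) {
  moments <- c("mean", "variance", "skewness", "kurtosis")
  pool <- function(g, m) {
    x <- g[[m]]
    if (pool_across_depths) {
      if (all(is.na(g$fraction))) {
        stop_user("pool_across_depths needs a fraction column")
      }
      as.numeric(tapply(x, g$fraction, median, na.rm = TRUE))
    } else {
      x[!is.na(x)]
    }
  }
  rows <- lapply(moments, function(m) {
    a <- pool(groupA, m)
    b <- pool(groupB, m)
    if (length(a) < 2L || length(b) < 2L) {
      stop_user("moment '%s': each group needs >= 2 observations", m)
    }
    p <- if (sd(a) == 0 && sd(b) == 0) {
      # both groups constant: no evidence either way
      c(p_two_sided = 1, p_left_sided = 1, p_right_sided = 1)
    } else {
      three_sided_t(a, b, var_equal = var_equal)
    }
    data.frame(moment = m, p_two_sided = p[["p_two_sided"]],
               p_left_sided = p[["p_left_sided"]],
               p_right_sided = p[["p_right_sided"]],
               n_A = length(a), n_B = length(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-depth moment table for one group
#'
#' Aggregates `moment_summary` rows into the reporting layout used for
#' phenotype groups: one row per depth fraction with the mean and SD of
#' each moment over replicates (and samples).
#'
#' @param summaries rbind-ed `moment_summary` rows.
#' @return `data.frame` with `fraction` and, for each moment, `<m>_mean`
#'   and `<m>_sd` columns.
#' @export
moment_table <- function(summaries) {
  moments <- c("mean", "variance", "skewness", "kurtosis")
  fr <- sort(unique(summaries$fraction))
  rows <- lapply(fr, function(f) {
    sub <- summaries[summaries$fraction == f, ]
    out <- data.frame(fraction = f)
    for (m in moments) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- sd(sub[[m]], na.rm = TRUE)
    }
    out
  })
  do.call(rbind, rows)
}
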