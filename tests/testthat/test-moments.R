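test_that("moment definitions follow the stated conventions", {
  m <- distribution_moments(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$variance, 1)        # unbiased, n-1
  expect_equal(m$skewness, 0)        # symmetric
  # plain kurtosis of a two-point distribution {0,1} is 1
  m2 <- distribution_moments(c(0, 1, 0, 1))
  expect_equal(m2$kurtosis, 1)
  # large normal sample: kurtosis ~ 3, skewness ~ 0
  set.seed(10)
  z <- rnorm(1e5)
  mz <- distribution_moments(z)
  expect_lt(abs(mz$kurtosis - 3), 0.1)
  expect_lt(abs(mz$skewness), 0.05)
})

test_that("degenerate distributions yield NA shape moments, not errors", {
  m <- distribution_moments(rep(5, 10))
  expect_equal(m$variance, 0)
  expect_true(is.na(m$skewness))
  expect_true(is.na(m$kurtosis))
  expect_error(distribution_moments(c(1)), ">= 2 values")
})

test_that("moments are invariant to gene ordering", {
  set.seed(11)
  v <- rlnorm(500, 3, 1)
  a <- distribution_moments(v)
  b <- distribution_moments(sample(v))
  expect_equal(a[c("mean", "variance", "skewness", "kurtosis")],
               b[c("mean", "variance", "skewness", "kurtosis")])
})

test_that("CPM mean over the full annotation is exactly 1e6 / G", {
  G <- 23648L
  set.seed(12)
  counts <- setNames(rnbinom(G, mu = 1400, size = 0.4),
                     sprintf("g%05d", 1:G))
  cv <- desire:::new_count_vector("s", counts, sum(counts), 0L, 0L)
  m <- distribution_moments(cpm(cv))
  expect_equal(m$mean, 1e6 / G)
  expect_equal(round(m$mean, 2), 42.29)
})

test_that("the theta filter selects on raw counts before normalization", {
  counts <- setNames(c(0L, 1L, 5L, 50L), paste0("g", 1:4))
  cv <- desire:::new_count_vector("s", counts, sum(counts), 0L, 0L)
  nv <- cpm(cv)
  m_all <- distribution_moments(nv, raw_counts = counts)
  expect_equal(m_all$n_genes, 4L)
  m_f <- distribution_moments(nv, filter_theta = 5L, raw_counts = counts)
  expect_equal(m_f$n_genes, 2L)
  expect_equal(m_f$mean, mean(nv$values[3:4]))
  expect_error(distribution_moments(nv, filter_theta = 5L), "raw counts")
})

test_that("CPM moments are depth-stable while raw moments scale with depth", {
  cfg <- simulation_config(n_genes = 100, library_size = 8000, seed = 14,
                           noise_fraction = 0)
  sim <- simulate_annotation(cfg, gtf_path = tempfile(fileext = ".gtf"))
  res <- simulate_reads(sim, cfg, tempfile(fileext = ".sam"))
  ann <- read_annotation(sim$gtf_path, "gtf")
  aln <- alignment_set(res$sam)
  rows <- lapply(c(0.1, 0.5, 0.9), function(f) {
    sub <- subsample_alignments(aln, f, 5, tempfile(fileext = ".sam"))
    cv <- count_fragments(sub, ann)
    data.frame(f = f, raw_mean = distribution_moments(cv)$mean,
               cpm_mean = distribution_moments(cpm(cv))$mean)
  })
  tab <- do.call(rbind, rows)
  cv_of <- function(x) sd(x) / mean(x)
  expect_lt(cv_of(tab$cpm_mean), 1e-6)
  expect_gt(cv_of(tab$raw_mean), 0.1)
})

sample_moments <- function(gen, ids, fractions = 1:3 / 4) {
  do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(fractions, function(f) {
      distribution_moments(gen(), sample_id = id, fraction = f,
                           replicate = 1L)
    }))
  }))
}

test_that("equal-mean groups give p near 1 for the mean moment", {
  # CPM-style construction: both groups share an analytically fixed mean
  set.seed(15)
  gen <- function() {
    v <- rlnorm(1000, 3, 1)
    v * 1e6 / sum(v)  # mean pinned to 1e6/1000 in every sample
  }
  a <- sample_moments(gen, paste0("a", 1:4))
  b <- sample_moments(gen, paste0("b", 1:4))
  out <- compare_moments(a, b, pool_across_depths = FALSE)
  expect_equal(out$p_two_sided[out$moment == "mean"], 1, tolerance = 1e-6)
})

test_that("a variance shift is detected directionally at n = 9 per group", {
  set.seed(16)
  n_sim <- 40
  hits <- 0
  meanlog <- 3; sdlog <- 1
  s2 <- sdlog^2
  s2b <- log1p(2 * expm1(s2))          # doubled variance, equal mean
  mlb <- meanlog + (s2 - s2b) / 2
  for (i in seq_len(n_sim)) {
    a <- do.call(rbind, lapply(1:9, function(j) {
      distribution_moments(rlnorm(2000, meanlog, sdlog), sample_id = "a",
                           fraction = j, replicate = 1L)
    }))
    b <- do.call(rbind, lapply(1:9, function(j) {
      distribution_moments(rlnorm(2000, mlb, sqrt(s2b)), sample_id = "b",
                           fraction = j, replicate = 1L)
    }))
    out <- compare_moments(a, b, pool_across_depths = FALSE)
    if (out$p_left_sided[out$moment == "variance"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("two-sided p values are uniform under permuted labels", {
  set.seed(17)
  p <- replicate(1000, {
    vals <- matrix(rnorm(8 * 4), nrow = 8)  # 8 samples x 4 moments
    rows <- do.call(rbind, lapply(1:8, function(i) {
      data.frame(sample_id = paste0("s", i), fraction = NA_real_,
                 replicate = 1L, normalization = "raw",
                 filter_theta = NA_integer_, n_genes = 100L,
                 mean = vals[i, 1], variance = abs(vals[i, 2]),
                 skewness = vals[i, 3], kurtosis = abs(vals[i, 4]))
    }))
    pick <- sample(8, 4)
    out <- compare_moments(rows[pick, ], rows[-pick, ],
                           pool_across_depths = FALSE, var_equal = TRUE)
    out$p_two_sided[out$moment == "mean"]
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("per-depth moment tables report mean and SD per moment", {
  set.seed(18)
  rows <- do.call(rbind, lapply(c(0.1, 0.2), function(f) {
    do.call(rbind, lapply(1:5, function(r) {
      distribution_moments(rlnorm(200, 3, 1), sample_id = "s",
                           fraction = f, replicate = r)
    }))
  }))
  tab <- moment_table(rows)
  expect_equal(tab$fraction, c(0.1, 0.2))
  expect_true(all(c("mean_mean", "mean_sd", "variance_mean", "variance_sd",
                    "skewness_mean", "skewness_sd", "kurtosis_mean",
                    "kurtosis_sd") %in% names(tab)))
  sub <- rows[rows$fraction == 0.1, ]
  expect_equal(tab$variance_mean[1L], mean(sub$variance))
  expect_equal(tab$variance_sd[1L], sd(sub$variance))
})
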