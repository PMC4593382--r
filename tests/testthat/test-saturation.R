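test_that("expressed_gene_count thresholds raw counts", {
  expect_equal(expressed_gene_count(c(0, 1, 10, 100), 10), 2L)
  expect_equal(expressed_gene_count(rep(0, 5), 1), 0L)
  set.seed(1)
  v <- rnbinom(500, mu = 20, size = 0.5)
  for (th in c(1, 10, 50, 100)) {
    expect_equal(expressed_gene_count(v, th), sum(v >= th))
  }
  # nonincreasing in theta
  counts <- rnbinom(300, mu = 40, size = 1)
  e <- vapply(c(1, 5, 10, 50, 100), function(th) {
    expressed_gene_count(counts, th)
  }, integer(1L))
  expect_true(all(diff(e) <= 0))
})

make_desire_setup <- function(n_genes = 150, library_size = 3000, seed = 21,
                              depth_grid = c(0.1, 0.3, 0.6, 1.0),
                              replicates = 6) {
  cfg <- simulation_config(n_genes = n_genes, library_size = library_size,
                           seed = seed)
  sim <- simulate_annotation(cfg, gtf_path = tempfile(fileext = ".gtf"))
  res <- simulate_reads(sim, cfg, tempfile(fileext = ".sam"),
                        sample_id = "s1")
  dir <- tempfile("reps")
  man <- generate_replicates(alignment_set(res$sam),
                             subsample_spec(depth_grid, replicates, seed),
                             dir, sample_id = "s1")
  ann <- read_annotation(sim$gtf_path, "gtf")
  list(cfg = cfg, sim = sim, res = res, man = man, ann = ann)
}

test_that("desire and scaled curves agree at full depth and diverge below it", {
  su <- make_desire_setup()
  full_cv <- count_fragments(su$res$sam, su$ann)
  curves <- build_saturation_curves(su$man, su$ann, theta_grid = c(1L, 10L),
                                    method = "desire")
  scaled <- build_saturation_curves(su$man, su$ann, theta_grid = c(1L, 10L),
                                    method = "scaled",
                                    counts_full = full_cv)
  for (th in c(1L, 10L)) {
    d1 <- curves$expressed_genes[curves$fraction == 1 & curves$theta == th]
    s1 <- scaled$expressed_genes[scaled$fraction == 1 & scaled$theta == th]
    expect_true(all(d1 == s1[1L]))
  }
  # desire at theta >= 1 never exceeds the full-depth count, per replicate
  full_expr <- expressed_gene_count(full_cv, 1L)
  expect_true(all(curves$expressed_genes[curves$theta == 1L] <= full_expr))
  # subsampling silences low-count genes; depth-consistent scaling cannot
  d_low <- curves$expressed_genes[curves$fraction == 0.1 &
                                    curves$theta == 1L]
  s_low <- scaled$expressed_genes[scaled$fraction == 0.1 &
                                    scaled$theta == 1L]
  expect_true(all(d_low < s_low))
})

test_that("the literal scaled threshold is available and behaves as stated", {
  su <- make_desire_setup()
  full_cv <- count_fragments(su$res$sam, su$ann)
  lit <- build_saturation_curves(NULL, su$ann, theta_grid = c(10L),
                                 method = "scaled", counts_full = full_cv,
                                 depth_grid = c(0.1, 1.0),
                                 scaled_threshold = "literal")
  expect_equal(lit$expressed_genes[lit$fraction == 0.1],
               sum(full_cv$counts * 0.1 >= 10))
  expect_equal(lit$expressed_genes[lit$fraction == 1.0],
               sum(full_cv$counts >= 10))
})

test_that("median expressed-gene count rises with depth", {
  su <- make_desire_setup()
  curves <- build_saturation_curves(su$man, su$ann, theta_grid = 1L,
                                    method = "desire")
  med <- tapply(curves$expressed_genes, curves$fraction, median)
  expect_equal(unname(cor(as.numeric(names(med)), med,
                          method = "spearman")), 1)
})

test_that("a missing manifest file is reported with its replicate", {
  su <- make_desire_setup()
  man <- su$man
  unlink(man$path[2L])
  expect_error(build_saturation_curves(man, su$ann, method = "desire"),
               "replicate")
})

test_that("noise-free Gompertz parameters are recovered to high accuracy", {
  truth <- c(a = 20000, b = 2, c = 3)
  pts <- gompertz_points(truth["a"], truth["b"], truth["c"])
  fit <- fit_gompertz(pts)
  expect_true(fit$converged)
  rel <- abs(c(fit$a, fit$b, fit$c) - truth) / truth
  expect_true(all(rel < 1e-4))
  expect_equal(predict_gompertz(fit, 0.5),
               20000 * exp(-2 * exp(-1.5)), tolerance = 1e-4)
})

test_that("degenerate saturation inputs do not crash the fitter", {
  flat <- data.frame(fraction = rep(c(0.1, 0.5, 1.0), each = 3),
                     expressed_genes = 500)
  fit <- fit_gompertz(flat)
  expect_false(fit$converged)
  expect_error(fit_gompertz(data.frame(fraction = c(0.5, 1),
                                       expressed_genes = c(1, 2))),
               "3 distinct")
})

test_that("fitted curves are nondecreasing over nonnegative depth", {
  set.seed(33)
  pts <- gompertz_points(15000, 1.5, 2.5, replicates = 5, noise_sd = 150)
  fit <- fit_gompertz(pts)
  expect_true(fit$converged)
  expect_true(all(fit$a > 0, fit$b > 0, fit$c > 0))
  y <- predict_gompertz(fit, seq(0, 2, by = 0.01))
  expect_true(all(diff(y) >= 0))
})

test_that("unsaturated growth turns the depth estimators into lower bounds", {
  libs <- c(34974017, 46677107, 17574408, 24440340,
            25900791, 43454785, 31426867, 33517581)
  names(libs) <- sprintf("s%d", 1:8)
  pts <- gompertz_points(20000, 2, 3)  # rel. slope at x=1 ~ 0.27
  fits <- setNames(replicate(8, fit_gompertz(pts), simplify = FALSE),
                   names(libs))
  est <- estimate_optimal_depth(fits, libs)
  expect_true(est$is_lower_bound)
  expect_false(any(est$saturated))
  expect_equal(est$mean_reads_bound, mean(libs))
  expect_equal(est$max_reads_bound, max(libs))
})

test_that("a saturated curve yields an estimate below the library size", {
  libs <- c(sA = 1e6)
  fit <- fit_gompertz(gompertz_points(20000, 2, 20))
  est <- estimate_optimal_depth(list(sA = fit), libs)
  expect_true(est$saturated[["sA"]])
  expect_false(est$is_lower_bound)
  expect_lt(est$mean_reads_bound, 1e6)
  expect_gt(est$mean_reads_bound, 0)

  # infinite tolerance declares everything saturated
  est2 <- estimate_optimal_depth(list(sA = fit), libs,
                                 saturation_tolerance = Inf)
  expect_true(all(est2$saturated))
})

test_that("all-unconverged fits are an error", {
  flat <- data.frame(fraction = rep(c(0.1, 0.5, 1), 2),
                     expressed_genes = 1)
  bad <- fit_gompertz(flat)
  expect_error(estimate_optimal_depth(list(s1 = bad), c(s1 = 100)),
               "no Gompertz fit converged")
})

fake_curves <- function(medians_by_sample, fraction = 0.5, theta = 1L,
                        jitter = 0) {
  rows <- lapply(names(medians_by_sample), function(id) {
    data.frame(sample = id, method = "desire", theta = theta,
               fraction = fraction, replicate = 1:3,
               expressed_genes = medians_by_sample[[id]] + jitter * (-1:1))
  })
  do.call(rbind, rows)
}

test_that("expressed-gene median comparison reports all three alternatives", {
  a <- fake_curves(list(s1 = 100, s2 = 110, s3 = 95), jitter = 2)
  b <- fake_curves(list(t1 = 300, t2 = 290, t3 = 310), jitter = 2)
  out <- compare_expressed_gene_medians(a, b)
  expect_named(out, c("fraction", "p_two_sided", "p_left_sided",
                      "p_right_sided", "mean_A", "mean_B"))
  # A well below B: left-sided p tiny, right-sided near 1
  expect_lt(out$p_left_sided, 0.01)
  expect_lt(out$p_left_sided, out$p_right_sided)
  expect_gt(out$p_right_sided, 0.9)
  # identical groups carry no signal
  same <- compare_expressed_gene_medians(a, a)
  expect_equal(same$p_two_sided, 1)
  expect_error(compare_expressed_gene_medians(a[a$sample == "s1", ], b),
               ">= 2 samples")
})

test_that("random group labels make left- and right-sided p symmetric", {
  set.seed(8)
  vals <- rnorm(8, mean = 50, sd = 5)
  p_left <- replicate(200, {
    pick <- sample(8, 4)
    a <- fake_curves(as.list(setNames(vals[pick], paste0("a", 1:4))))
    b <- fake_curves(as.list(setNames(vals[-pick], paste0("b", 1:4))))
    compare_expressed_gene_medians(a, b)$p_left_sided
  })
  expect_gt(mean(p_left), 0.4)
  expect_lt(mean(p_left), 0.6)
})

test_that("growth-rate comparison detects separated groups per threshold", {
  set.seed(9)
  mk <- function(cs, prefix) {
    do.call(rbind, lapply(seq_along(cs), function(i) {
      data.frame(sample = paste0(prefix, i), theta = 1L, c = cs[i],
                 converged = TRUE)
    }))
  }
  a <- mk(rnorm(4, 3.0, 0.05), "a")
  b <- mk(rnorm(4, 3.0, 0.05) + 0.25, "b")  # 5 SD apart
  out <- compare_growth_rates(a, b)
  expect_named(out, c("theta", "p_two_sided", "p_left_sided",
                      "p_right_sided", "mean_A", "mean_B"))
  expect_lt(out$p_two_sided, 0.01)
  # identical fits in both groups: p = 1 by the no-evidence convention
  same <- compare_growth_rates(mk(rep(3, 4), "a"), mk(rep(3, 4), "b"))
  expect_equal(same$p_two_sided, 1)
})
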