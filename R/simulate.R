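#' Configuration for the synthetic RNA-seq generator
#'
#' Bundles the ground-truth parameters of a simulated experiment: an
#' artificial genome of non-overlapping genes, a per-gene expression
#' profile with log-normal spread across genes and negative-binomial-style
#' overdispersion across samples, single-end aligned reads placed
#' uniformly within exons, and a configurable fraction of intergenic
#' noise reads. Two phenotype groups can differ by a multiplicative
#' factor on the across-gene expression variance while the across-gene
#' mean is held fixed (the contrast the moment comparison is designed to
#' detect).
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Exon-union length range per gene, in kb.
#' @param n_chroms Number of artificial chromosomes (`chrS1`, ...).
#' @param library_size Reads per sample (exact: gene assignment is
#'   multinomial conditioned on this total).
#' @param nb_mean_distribution `list(meanlog=, sdlog=)` of the log-normal
#'   across-gene expression profile.
#' @param nb_dispersion Negative-binomial dispersion of per-gene counts
#'   across samples (variance `mu + disp * mu^2` before conditioning).
#' @param group_effect Multiplicative factor on the across-gene expression
#'   variance in group B (1 = identical groups).
#' @param noise_fraction Fraction of reads placed in intergenic space.
#' @param read_length Read length in bp (single-end).
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000L,
                              gene_length_range = c(0.3, 3),
                              n_chroms = 3L,
                              library_size = 100000L,
                              nb_mean_distribution = list(meanlog = 3,
                                                          sdlog = 1.5),
                              nb_dispersion = 0.2,
                              group_effect = 1,
                              noise_fraction = 0.03,
                              read_length = 75L,
                              seed = 1L) {
  stopifnot(is_count(n_genes), is_count(n_chroms), is_count(library_size),
            is_count(read_length), length(gene_length_range) == 2L,
            all(gene_length_range > 0),
            gene_length_range[1L] <= gene_length_range[2L],
            nb_dispersion > 0, group_effect > 0,
            noise_fraction >= 0, noise_fraction < 1)
  if (gene_length_range[1L] * 1000 < read_length) {
    stop_user("minimum gene length (%.0f bp) must fit a read (%d bp)",
              gene_length_range[1L] * 1000, read_length)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.numeric(gene_length_range),
    n_chroms = as.integer(n_chroms),
    library_size = as.integer(library_size),
    nb_mean_distribution = nb_mean_distribution,
    nb_dispersion = nb_dispersion,
    group_effect = group_effect,
    noise_fraction = noise_fraction,
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

INTERGENIC_GAP <- 500L
INTRON_GAP <- 200L

#' Simulate a gene annotation over an artificial genome
#'
#' Places `n_genes` pairwise-disjoint genes round-robin on `n_chroms`
#' chromosomes. Each gene has 1-3 exons, every exon long enough to hold a
#' read, and an exon-union length drawn uniformly from
#' `gene_length_range`. Neighbouring genes are separated by intergenic
#' gaps that later receive noise reads. Deterministic given
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param gtf_path Optional path; when given, the annotation is also
#'   written as GTF.
#' @return A `sim_annotation`: list with `annotation`
#'   (a `gene_annotation`), `chrom_lengths` (named), `intergenic`
#'   (`GRanges` of gene-free intervals wide enough for a read), and
#'   `gtf_path` (or `NA`).
#' @export
simulate_annotation <- function(config, gtf_path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  rl <- config$read_length
  with_seed(config$seed * 1000L + 1L, {
    len_bp <- as.integer(round(runif(config$n_genes,
                                     config$gene_length_range[1L] * 1000,
                                     config$gene_length_range[2L] * 1000)))
    max_exons <- pmax(1L, pmin(3L, len_bp %/% rl))
    n_exons <- vapply(max_exons, function(k) sample.int(k, 1L), integer(1L))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  })
  chrom_of <- rep_len(seq_len(config$n_chroms), config$n_genes)
  cursor <- rep(INTERGENIC_GAP + 1L, config$n_chroms)
  rows <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    ch <- chrom_of[i]
    k <- n_exons[i]
    w <- rep(len_bp[i] %/% k, k)
    w[1L] <- w[1L] + len_bp[i] - sum(w)
    starts <- integer(k)
    ends <- integer(k)
    pos <- cursor[ch]
    for (e in seq_len(k)) {
      starts[e] <- pos
      ends[e] <- pos + w[e] - 1L
      pos <- ends[e] + INTRON_GAP + 1L
    }
    cursor[ch] <- ends[k] + INTERGENIC_GAP + 1L
    rows[[i]] <- data.frame(gene_id = sprintf("gene%05d", i),
                            chrom = sprintf("chrS%d", ch),
                            start = starts, end = ends,
                            strand = strand[i], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  annotation <- build_annotation(tab)
  chrom_lengths <- setNames(cursor + INTERGENIC_GAP,
                            sprintf("chrS%d", seq_len(config$n_chroms)))

  gene_gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    seqlengths = chrom_lengths
  )
  intergenic <- GenomicRanges::gaps(GenomicRanges::reduce(gene_gr))
  intergenic <- intergenic[GenomicRanges::strand(intergenic) == "*"]
  intergenic <- intergenic[IRanges::width(intergenic) >= rl]

  if (!is.null(gtf_path)) {
    lines <- sprintf("%s\tdesire_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                     tab$chrom, tab$start, tab$end, tab$strand, tab$gene_id)
    writeLines(lines, gtf_path)
  }
  structure(list(annotation = annotation, chrom_lengths = chrom_lengths,
                 intergenic = intergenic,
                 gtf_path = if (is.null(gtf_path)) NA_character_
                            else gtf_path),
            class = "sim_annotation")
}

# Across-gene expression profile. Group B's profile is a deterministic
# monotone remap of group A's that multiplies the across-gene variance of
# the log-normal by `group_effect` while keeping its mean fixed, so
# group_effect = 1 makes the groups exchangeable.
simulate_expression_profile <- function(config) {
  ml <- config$nb_mean_distribution$meanlog
  sl <- config$nb_mean_distribution$sdlog
  mu <- with_seed(config$seed * 1000L + 2L,
                  rlnorm(config$n_genes, meanlog = ml, sdlog = sl))
  list(mu = mu, meanlog = ml, sdlog = sl)
}

apply_group_effect <- function(profile, group_effect) {
  if (group_effect == 1) return(profile$mu)
  s2 <- profile$sdlog^2
  # choose sdlog' so (e^{s'^2}-1) = k (e^{s^2}-1), then shift meanlog to
  # keep the log-normal mean exp(m + s^2/2) unchanged
  s2p <- log1p(group_effect * expm1(s2))
  mlp <- profile$meanlog + (s2 - s2p) / 2
  exp(mlp + sqrt(s2p / s2) * (log(profile$mu) - profile$meanlog))
}

# Per-sample true counts: gamma-distributed gene weights with mean mu_i
# and variance disp*mu_i^2 (the NB gamma-Poisson mixing weights), then a
# multinomial conditioned on the exact library size. Marginally this is
# Dirichlet-multinomial-like with super-Poisson per-gene variance.
draw_true_counts <- function(mu, config, seed, n_reads) {
  with_seed(seed, {
    shape <- 1 / config$nb_dispersion
    g <- rgamma(length(mu), shape = shape, scale = mu / shape)
    g[g <= 0] <- min(g[g > 0]) * 1e-6
    as.integer(rmultinom(1L, n_reads, prob = g))
  })
}

#' Simulate aligned single-end reads with known ground truth
#'
#' Draws per-gene true counts (negative-binomial-style overdispersion,
#' conditioned on the exact library size), places each read uniformly
#' within one exon of its gene, adds `noise_fraction` intergenic reads,
#' and writes a SAM file whose header lists the artificial chromosomes.
#' Returns the true count vector so downstream counting can be checked
#' against ground truth.
#'
#' @param sim A `sim_annotation` from [simulate_annotation()].
#' @param config A [simulation_config()].
#' @param out_sam Output SAM path.
#' @param sample_id Sample label (defaults to the file name).
#' @param seed Seed for this sample's draws; defaults to `config$seed`.
#' @param mu Optional across-gene expression profile (defaults to the
#'   profile implied by `config`).
#' @return List with `sam` (path), `truth` (a `count_vector` of true
#'   per-gene counts), and `n_noise`.
#' @export
simulate_reads <- function(sim, config, out_sam, sample_id = NULL,
                           seed = NULL, mu = NULL) {
  stopifnot(inherits(sim, "sim_annotation"),
            inherits(config, "simulation_config"))
  if (config$library_size < 1L) stop_user("library_size must be positive")
  if (is.null(sample_id)) {
    sample_id <- sub("\\.sam$", "", basename(out_sam), ignore.case = TRUE)
  }
  if (is.null(seed)) seed <- config$seed
  if (is.null(mu)) mu <- simulate_expression_profile(config)$mu
  ann <- sim$annotation
  G <- n_genes(ann)
  stopifnot(length(mu) == G)
  rl <- config$read_length

  n_noise <- as.integer(round(config$noise_fraction * config$library_size))
  if (n_noise > 0L && length(sim$intergenic) == 0L) {
    stop_user("no intergenic interval can hold a read; lower noise_fraction")
  }
  n_gene_reads <- config$library_size - n_noise
  counts <- draw_true_counts(mu, config, seed * 7L + 11L, n_gene_reads)
  names(counts) <- ann$genes$gene_id

  exon_gene <- match(ann$exons$gene_id, ann$genes$gene_id)
  exon_start <- GenomicRanges::start(ann$exons)
  exon_placeable <- pmax(IRanges::width(ann$exons) - rl + 1L, 0L)
  with_seed(seed * 7L + 12L, {
    # choose an exon (weighted by placeable width) and a uniform start
    read_gene <- rep.int(seq_len(G), counts)
    exon_idx <- unlist(lapply(seq_len(G), function(i) {
      ex <- which(exon_gene == i & exon_placeable > 0L)
      if (!length(ex)) stop_user("gene %s has no exon long enough for a read",
                                 ann$genes$gene_id[i])
      if (length(ex) == 1L) rep.int(ex, counts[i])
      else sample(ex, counts[i], replace = TRUE,
                  prob = exon_placeable[ex])
    }))
    offs <- floor(runif(length(exon_idx)) * exon_placeable[exon_idx])
    gene_pos <- exon_start[exon_idx] + as.integer(offs)
    gene_chrom <- as.character(GenomicRanges::seqnames(ann$exons))[exon_idx]

    if (n_noise > 0L) {
      ig_placeable <- IRanges::width(sim$intergenic) - rl + 1L
      ig_idx <- sample(length(sim$intergenic), n_noise, replace = TRUE,
                       prob = ig_placeable)
      noise_pos <- GenomicRanges::start(sim$intergenic)[ig_idx] +
        as.integer(floor(runif(n_noise) * ig_placeable[ig_idx]))
      noise_chrom <- as.character(
        GenomicRanges::seqnames(sim$intergenic))[ig_idx]
    } else {
      noise_pos <- integer(); noise_chrom <- character()
    }
    chrom <- c(gene_chrom, noise_chrom)
    pos <- c(gene_pos, noise_pos)
    ord <- sample.int(length(pos))  # shuffle record order
  })
  chrom <- chrom[ord]
  pos <- pos[ord]
  n_reads <- length(pos)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sim$chrom_lengths),
                      as.integer(sim$chrom_lengths)))
  seq_str <- strrep("A", rl)
  records <- sprintf("%s_frag%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     sample_id, seq_len(n_reads), chrom, pos, rl, seq_str)
  write_sam(header, records, out_sam)
  truth <- new_count_vector(sample_id, counts,
                            assigned = sum(counts), ambiguous = 0L,
                            unassigned = n_noise)
  list(sam = out_sam, truth = truth, n_noise = n_noise)
}

#' Simulate a two-group cohort of aligned samples
#'
#' Generates `n_per_group` samples per phenotype group over one shared
#' annotation. Both groups share the same across-gene expression profile;
#' group B's profile has its across-gene variance multiplied by
#' `config$group_effect` (mean held fixed), so `group_effect = 1` yields
#' exchangeable groups for null calibration.
#'
#' @param config A [simulation_config()].
#' @param n_per_group Samples per group (>= 2).
#' @param out_dir Output directory.
#' @return List with `sim` (the `sim_annotation`), `manifest`
#'   (`data.frame`: `sample`, `group`, `path`, `seed`, `library_size`),
#'   and `truth` (named list of true `count_vector`s).
#' @export
simulate_cohort <- function(config, n_per_group, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(n_per_group) || n_per_group < 2L) {
    stop_user("n_per_group must be an integer >= 2")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_annotation(config,
                             gtf_path = file.path(out_dir, "annotation.gtf"))
  profile <- simulate_expression_profile(config)
  mu_by_group <- list(A = profile$mu,
                      B = apply_group_effect(profile, config$group_effect))
  rows <- list()
  truth <- list()
  for (grp in c("A", "B")) {
    for (j in seq_len(n_per_group)) {
      idx <- (match(grp, c("A", "B")) - 1L) * n_per_group + j
      sample_id <- sprintf("%s%02d", grp, j)
      path <- file.path(out_dir, paste0(sample_id, ".sam"))
      res <- simulate_reads(sim, config, path, sample_id = sample_id,
                            seed = config$seed + 97L * idx,
                            mu = mu_by_group[[grp]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, group = grp, path = path,
        seed = config$seed + 97L * idx,
        library_size = config$library_size, stringsAsFactors = FALSE)
      truth[[sample_id]] <- res$truth
    }
  }
  list(sim = sim, manifest = do.call(rbind, rows), truth = truth)
}
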