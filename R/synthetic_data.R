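# Synthetic-data generator: annotation, insertion catalogs, gel band
# tables, qPCR Ct tables and genotype panels with the statistical
# structure the analysis assumes, each emitted alongside its ground truth
# so parameter recovery can be tested without external data.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. All randomness
#' flows from `seed`; there is no implicit RNG state.
#'
#' @param seed Integer seed (mandatory).
#' @param n_genes Number of genes to simulate.
#' @param exons_per_gene Integer range (lo, hi) of exons per gene.
#' @param exon_length Integer range of exon lengths in bp; under a uniform
#'   draw about 2/3 of exon lengths are not divisible by 3.
#' @param intron_length Integer range of intron lengths in bp.
#' @param alt_exon_fraction Fraction of internal exons given a
#'   skipping isoform.
#' @param n_variants Number of insertion variants to place.
#' @param depletion_window Window (bp) near exons where insertions are
#'   depleted (default 100).
#' @param retention Retention probability r in [0, 1]: candidate intronic
#'   positions within the window are kept with probability r.
#' @param true_psi_skip True fraction of transcripts skipping the target
#'   exon in reporter simulations.
#' @param gel_noise_sigma Multiplicative log-normal sigma on band
#'   intensities (default 0.1).
#' @param maf Insertion-allele frequency for genotype sampling under
#'   Hardy-Weinberg (default 0.285).
#' @param beta0 Logit-scale intercept of the dose model: baseline
#'   log-odds of skipping on the pre-insertion background (default -1.22,
#'   i.e. about 23% skipping with no insertion allele).
#' @param beta1 Logit-scale slope per insertion-allele dose (default 1.0).
#' @param logit_sigma Residual SD on the logit scale (default 0.3).
#' @param n_samples Samples in the genotype panel (default 50).
#' @param subfamily_freqs Named probability vector for element subfamily
#'   labels; the default is skewed toward the young, commonly polymorphic
#'   subfamilies (AluYa5/Yb8/Yb9 together 57.5%).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_genes = 20L,
                              exons_per_gene = c(4L, 10L),
                              exon_length = c(50L, 300L),
                              intron_length = c(500L, 3000L),
                              alt_exon_fraction = 0.3,
                              n_variants = 500L,
                              depletion_window = 100L,
                              retention = 0.3,
                              true_psi_skip = 0.452,
                              gel_noise_sigma = 0.1,
                              maf = 0.285,
                              beta0 = -1.22,
                              beta1 = 1.0,
                              logit_sigma = 0.3,
                              n_samples = 50L,
                              subfamily_freqs = c(AluYa5 = 0.35,
                                                  AluYb8 = 0.15,
                                                  AluYb9 = 0.075,
                                                  AluY = 0.275,
                                                  AluYc = 0.15)) {
  if (missing(seed)) stop("a seed is mandatory")
  fracs <- c(alt_exon_fraction = alt_exon_fraction, retention = retention,
             true_psi_skip = true_psi_skip, maf = maf)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (exons_per_gene[1] < 2L) stop("genes need >= 2 exons")
  if (any(exon_length < 1L) || any(intron_length < 1L))
    stop("length ranges must be positive")
  if (abs(sum(subfamily_freqs) - 1) > 1e-8)
    stop("subfamily_freqs must sum to 1")
  structure(mget(names(formals())), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> seed %d: %d genes, %d variants (retention %.2f within %d bp), %d samples (MAF %.3f, beta1 %.2f)\n",
    x$seed, x$n_genes, x$n_variants, x$retention, x$depletion_window,
    x$n_samples, x$maf, x$beta1))
  invisible(x)
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample.int(range[2] - range[1] + 1L, n, replace = TRUE) + range[1] - 1L
}

#' Simulate a multi-isoform gene annotation
#'
#' Lays genes head to tail on one synthetic chromosome, each with a
#' canonical isoform containing every exon; a configured fraction of
#' internal exons additionally get an isoform that skips them, making them
#' alternatively used.
#'
#' @param config A [simulation_config].
#' @param path Optional path; when given, the annotation is also written
#'   as GFF3.
#' @return List with `genes` (list of [gene_model]) and `truth`, a data
#'   frame of exon-level ground truth (`gene_id`, `start`, `end`,
#'   `internal`, `alternative`).
#' @export
simulate_annotation <- function(config, path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  res <- withr::with_seed(config$seed, {
    genes <- vector("list", config$n_genes)
    truth <- vector("list", config$n_genes)
    cursor <- 10000L
    for (g in seq_len(config$n_genes)) {
      n_ex <- runif_int(1L, config$exons_per_gene)
      ex_len <- runif_int(n_ex, config$exon_length)
      in_len <- runif_int(n_ex - 1L, config$intron_length)
      starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      gene_id <- sprintf("geneS%03d", g)
      strand <- sample(c("+", "-"), 1L)
      canonical <- data.frame(start = starts, end = ends)
      isoforms <- stats::setNames(list(canonical),
                                  paste0(gene_id, ".iso1"))
      internal <- seq_len(n_ex) > 1L & seq_len(n_ex) < n_ex
      alt <- internal & stats::runif(n_ex) < config$alt_exon_fraction
      for (i in which(alt)) {
        isoforms[[sprintf("%s.iso_skip%d", gene_id, i)]] <-
          canonical[-i, , drop = FALSE]
      }
      genes[[g]] <- gene_model(gene_id, "chrS", strand, isoforms)
      truth[[g]] <- data.frame(gene_id = gene_id, start = starts,
                               end = ends, internal = internal,
                               alternative = alt)
      cursor <- max(ends) + 50000L
    }
    list(genes = stats::setNames(genes, vapply(genes, `[[`, character(1),
                                               "gene_id")),
         truth = do.call(rbind, truth))
  })
  if (!is.null(path)) write_annotation_gff3(res$genes, path)
  res
}

#' Simulate an insertion-variant catalog with depletion near exons
#'
#' Candidate insertion points are drawn uniformly over intronic base
#' pairs; candidates whose nearest-exon distance is within the depletion
#' window are retained with probability `retention` (rejection sampling),
#' reproducing purifying selection against insertions near exons.
#' Subfamily labels are drawn from `config$subfamily_freqs`, element
#' strands are fair coins, and element lengths are drawn uniformly from
#' 260-320 bp (mostly full-length elements including polyA tails).
#'
#' @param config A [simulation_config].
#' @param genes Gene models from [simulate_annotation].
#' @param path Optional path; when given, the catalog is also written as
#'   extended BED.
#' @param pool Optional precomputed intronic-position pool from
#'   [intronic_position_pool]; useful when drawing many catalogs from one
#'   annotation.
#' @return List with `variants` (catalog data frame), `truth`
#'   (per-variant `gene_id`, `true_distance`, `inside_window`) and `pool`.
#' @export
simulate_insertions <- function(config, genes, path = NULL, pool = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(pool)) pool <- intronic_position_pool(genes)
  if (nrow(pool) == 0L)
    stop("simulated genes contain no intronic space")
  res <- withr::with_seed(config$seed + 1L, {
    kept <- integer(0)
    while (length(kept) < config$n_variants) {
      draw <- sample.int(nrow(pool), config$n_variants, replace = TRUE)
      inside <- pool$dist[draw] <= config$depletion_window
      keep <- !inside | stats::runif(length(draw)) < config$retention
      kept <- c(kept, draw[keep])
    }
    kept <- kept[seq_len(config$n_variants)]
    n <- length(kept)
    variants <- data.frame(
      chrom = "chrS",
      pos = pool$pos[kept],
      subfamily = sample(names(config$subfamily_freqs), n, replace = TRUE,
                         prob = config$subfamily_freqs),
      element_length = runif_int(n, c(260L, 320L)),
      element_strand = sample(c("+", "-"), n, replace = TRUE),
      allele_frequency = round(stats::runif(n, 0.01, 0.5), 4),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      chrom = "chrS", pos = pool$pos[kept], gene_id = pool$gene_id[kept],
      true_distance = pool$dist[kept],
      inside_window = pool$dist[kept] <= config$depletion_window,
      stringsAsFactors = FALSE)
    ord <- order(variants$pos)
    list(variants = variants[ord, , drop = FALSE],
         truth = truth[ord, , drop = FALSE])
  })
  rownames(res$variants) <- rownames(res$truth) <- NULL
  if (!is.null(path)) write_variants(res$variants, path)
  res$pool <- pool
  res
}

#' Enumerate the intronic position pool of an annotation
#'
#' All base positions intronic in at least one isoform and inside no exon
#' of any isoform, with each position's nearest-exon distance. This is the
#' sampling space of [simulate_insertions].
#'
#' @param genes List of [gene_model] objects.
#' @return Data frame with `gene_id`, `pos`, `dist`.
#' @export
intronic_position_pool <- function(genes) {
  pool <- do.call(rbind, lapply(genes, function(gm) {
    sp <- gene_span(gm)
    pos <- seq.int(sp["start"], sp["end"] - 1L)
    pos <- pos[is_intronic(pos, gm) & !in_any_exon(pos, gm)]
    if (length(pos) == 0L) return(NULL)
    d <- min_exon_distance(pos, gm$exons)
    data.frame(gene_id = gm$gene_id, pos = pos, dist = d,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool)) pool <- data.frame(gene_id = character(0),
                                        pos = integer(0), dist = numeric(0))
  rownames(pool) <- NULL
  pool
}

#' Simulate a gel/fragment-analyzer band table
#'
#' Renders a true skip fraction into band intensities under the signal
#' model intensity = fragment_length x molar_abundance x exp(noise), with
#' independent Gaussian noise of SD `sigma` on the log scale per band and
#' replicate.
#'
#' @param true_psi_skip True fraction of transcripts skipping the exon.
#' @param isoform_lengths Numeric vector of fragment lengths (bp), named
#'   by isoform.
#' @param contains_target_exon Logical vector matching `isoform_lengths`.
#' @param molar_fractions Optional explicit molar fractions (must sum
#'   to 1); by default a two-isoform mix is built from `true_psi_skip`
#'   (skipping mass split evenly across flagged isoforms when more than
#'   one lacks the exon).
#' @param n_replicates Number of replicate lanes/samples.
#' @param sigma Log-scale noise SD (0 gives exact recovery).
#' @param seed Integer seed (required).
#' @return List with `bands` (stacked band table with `sample_id`
#'   `rep1..repN`) and `truth` (`true_psi_skip`, `molar_fractions`).
#' @export
simulate_gel <- function(true_psi_skip, isoform_lengths,
                         contains_target_exon, molar_fractions = NULL,
                         n_replicates = 1L, sigma = 0.1, seed) {
  if (missing(seed)) stop("a seed is required")
  if (true_psi_skip < 0 || true_psi_skip > 1)
    stop("true_psi_skip must lie in [0, 1]")
  if (any(isoform_lengths <= 0)) stop("isoform lengths must be > 0")
  stopifnot(length(contains_target_exon) == length(isoform_lengths))
  if (is.null(molar_fractions)) {
    molar_fractions <- numeric(length(isoform_lengths))
    n_skip <- sum(!contains_target_exon)
    n_incl <- sum(contains_target_exon)
    if (n_skip == 0L || n_incl == 0L)
      stop("need at least one skip and one include isoform")
    molar_fractions[!contains_target_exon] <- true_psi_skip / n_skip
    molar_fractions[contains_target_exon] <- (1 - true_psi_skip) / n_incl
  } else {
    if (abs(sum(molar_fractions) - 1) > 1e-8)
      stop("molar_fractions must sum to 1")
  }
  iso_ids <- if (is.null(names(isoform_lengths)))
    sprintf("iso%d", seq_along(isoform_lengths)) else names(isoform_lengths)
  k <- length(isoform_lengths)
  bands <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      eps <- stats::rnorm(k, 0, sigma)
      data.frame(sample_id = sprintf("rep%d", r),
                 isoform_id = iso_ids,
                 fragment_length = unname(isoform_lengths),
                 intensity = unname(isoform_lengths * molar_fractions *
                                      exp(eps)),
                 contains_target_exon = contains_target_exon,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(bands) <- NULL
  list(bands = bands,
       truth = list(true_psi_skip = true_psi_skip,
                    molar_fractions = stats::setNames(molar_fractions,
                                                      iso_ids)))
}

#' Simulate a genotype panel with a logit-linear dose effect
#'
#' Samples insertion-allele doses as Binomial(2, maf) under Hardy-Weinberg
#' and generates per-sample skipping as
#' `logit(psi) = beta0 + beta1 * dose + N(0, logit_sigma^2)`. Measures are
#' either passed through noiselessly (percent = 100 * psi) or rendered as
#' gel band tables and re-quantified, adding measurement noise on top of
#' the biological noise.
#'
#' @param config A [simulation_config].
#' @param render `"noiseless"` or `"gel"`.
#' @param isoform_lengths,contains_target_exon Fragment structure used
#'   when `render = "gel"` (defaults: 394/251 bp include/skip fragments).
#' @return List with `panel` (data frame `sample_id`, `dose`,
#'   `percent_skipping`) and `truth` (`true_psi`, `dose`, parameters).
#' @export
simulate_genotype_panel <- function(config, render = c("noiseless", "gel"),
                                    isoform_lengths = c(include = 394,
                                                        skip = 251),
                                    contains_target_exon = c(TRUE, FALSE)) {
  stopifnot(inherits(config, "simulation_config"))
  render <- match.arg(render)
  if (config$n_samples < 3L) stop("need >= 3 samples")
  out <- withr::with_seed(config$seed + 2L, {
    dose <- stats::rbinom(config$n_samples, 2L, config$maf)
    eta <- config$beta0 + config$beta1 * dose +
      stats::rnorm(config$n_samples, 0, config$logit_sigma)
    psi <- stats::plogis(eta)
    list(dose = dose, psi = psi,
         gel_seeds = sample.int(.Machine$integer.max - 10L,
                                config$n_samples))
  })
  pct <- if (render == "noiseless") 100 * out$psi else
    vapply(seq_len(config$n_samples), function(i) {
      sim <- simulate_gel(out$psi[i], isoform_lengths,
                          contains_target_exon,
                          n_replicates = 1L,
                          sigma = config$gel_noise_sigma,
                          seed = out$gel_seeds[i])
      percent_skipping(sim$bands)$percent_skipping
    }, numeric(1))
  panel <- data.frame(sample_id = sprintf("s%03d", seq_len(config$n_samples)),
                      dose = out$dose, percent_skipping = pct,
                      stringsAsFactors = FALSE)
  list(panel = panel,
       truth = list(true_psi = out$psi, dose = out$dose,
                    beta0 = config$beta0, beta1 = config$beta1,
                    logit_sigma = config$logit_sigma, maf = config$maf,
                    render = render))
}

#' Simulate isoform-specific qPCR Ct tables
#'
#' Two isoform-specific primer pairs plus a reference gene, in
#' `n_replicates` technical replicates. The skip-assay Ct sits
#' `log2(true_isoform_ratio)` cycles below the include-assay Ct (a
#' twofold excess of the skip isoform lowers its Ct by one cycle);
#' Gaussian noise of SD `ct_sigma` cycles is added per replicate.
#'
#' @param true_isoform_ratio True skip/include isoform ratio (> 0).
#' @param ct_reference_level Mean reference-gene Ct (default 20).
#' @param ct_include_level Mean include-assay Ct (default 25).
#' @param n_replicates Technical replicates per primer pair (default 3).
#' @param ct_sigma Ct noise SD in cycles (default 0.2).
#' @param seed Integer seed (required).
#' @param sample_id Sample label (default "s1").
#' @return List with `ct` (data frame `sample_id`, `primer_pair`, `ct`)
#'   and `truth`.
#' @export
simulate_qpcr <- function(true_isoform_ratio, ct_reference_level = 20,
                          ct_include_level = 25, n_replicates = 3L,
                          ct_sigma = 0.2, seed, sample_id = "s1") {
  if (missing(seed)) stop("a seed is required")
  if (true_isoform_ratio <= 0) stop("true_isoform_ratio must be > 0")
  ct <- withr::with_seed(seed, {
    lev <- c(reference = ct_reference_level,
             include_isoform = ct_include_level,
             skip_isoform = ct_include_level - log2(true_isoform_ratio))
    do.call(rbind, lapply(names(lev), function(pp) {
      data.frame(sample_id = sample_id, primer_pair = pp,
                 ct = lev[[pp]] + stats::rnorm(n_replicates, 0, ct_sigma),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(ct) <- NULL
  list(ct = ct, truth = list(true_isoform_ratio = true_isoform_ratio,
                             ct_sigma = ct_sigma))
}
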