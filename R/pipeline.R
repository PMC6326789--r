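# Pipeline orchestration: simulate -> screen -> quantify -> sqtl, with a
# run manifest recording the configuration, file hashes and per-stage row
# counts so a run can be audited and reproduced.

make_manifest <- function(config, files, counts, seed) {
  list(tool = "mobsplice",
       version = as.character(utils::packageVersion("mobsplice")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config = config,
       counts = counts,
       files = as.list(tools::md5sum(files)))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Run the proximity-and-candidate screen
#'
#' Composes the screening stages over either simulated or user-supplied
#' inputs: nearest-exon distances for every variant, the intronic distance
#' profile with depletion estimate, and the candidate set near
#' alternatively used exons. Writes TSV outputs plus a JSON run manifest
#' with md5 hashes of every file.
#'
#' @param config A [simulation_config]; ignored when both `annotation` and
#'   `variants` are supplied.
#' @param out_dir Output directory (created if needed).
#' @param annotation,variants Optional paths to a GFF3/BED12 annotation
#'   and an extended-BED variant catalog; when omitted, inputs are
#'   simulated from `config` and written alongside the results.
#' @param window Candidate window in bp (default
#'   `config$depletion_window`).
#' @param n_boot Bootstrap replicates for the depletion CI.
#' @return List with `candidates`, `distances`, `profile`, `depletion`,
#'   `counts` and `manifest` (also written to `out_dir`).
#' @export
run_screen <- function(config = NULL, out_dir, annotation = NULL,
                       variants = NULL, window = NULL, n_boot = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(annotation) || is.null(variants)
  if (simulated && is.null(config))
    stop("supply either a simulation config or annotation + variants paths")
  if (simulated) {
    annotation <- file.path(out_dir, "annotation.gff3")
    variants <- file.path(out_dir, "variants.bed")
    ann <- simulate_annotation(config, path = annotation)
    sim <- simulate_insertions(config, ann$genes, path = variants)
    genes <- ann$genes
    var_df <- sim$variants
  } else {
    genes <- read_annotation(annotation)
    var_df <- read_variants(variants)
  }
  if (is.null(window))
    window <- if (!is.null(config)) config$depletion_window else 100L
  seed <- if (!is.null(config)) config$seed else 1L

  nd <- nearest_exon_distance(var_df, genes)
  intronic <- nd[!is.na(nd$distance) & nd$intronic & nd$distance >= 1L, ,
                 drop = FALSE]
  if (nrow(intronic) == 0L) stop("screen stage: no intronic variants")
  profile <- bin_distances(intronic$distance)
  expo <- intronic_exposure(genes, window = window)
  depl <- depletion_estimate(intronic$distance, window = window,
                             bp_inside = expo["bp_inside"],
                             bp_outside = expo["bp_outside"],
                             n_boot = n_boot, seed = seed)
  cand <- screen_candidates(var_df, genes, window = window,
                            require_alternative = TRUE)
  counts <- list(n_variants = nrow(var_df),
                 n_intronic = nrow(intronic),
                 n_within_window = sum(intronic$distance <= window),
                 n_near_alternative = nrow(cand),
                 n_frameshifting = sum(cand$frameshift_flag))
  message(sprintf(
    "screen: %d variants; %d intronic, %d within %d bp, %d near alternative exons, %d frameshifting",
    counts$n_variants, counts$n_intronic, counts$n_within_window, window,
    counts$n_near_alternative, counts$n_frameshifting))

  dist_path <- file.path(out_dir, "distances.tsv")
  cand_path <- file.path(out_dir, "candidates.tsv")
  prof_path <- file.path(out_dir, "profile.tsv")
  write_distance_table(nd, dist_path)
  write_distance_table(cand, cand_path)
  write_profile(profile, prof_path)
  cfg <- if (!is.null(config)) unclass(config) else
    list(annotation = annotation, variants = variants, window = window)
  manifest <- make_manifest(cfg, c(annotation, variants, dist_path,
                                   cand_path, prof_path), counts, seed)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  list(candidates = cand, distances = nd, profile = profile,
       depletion = depl, counts = counts, manifest = manifest)
}

#' Run the splicing-QTL statistics stage
#'
#' Joins per-sample splicing measures to insertion genotypes and runs the
#' genotype one-way ANOVA plus all pairwise dose t-tests, writing a
#' summary table and JSON report with a run manifest.
#'
#' @param measures Data frame (`sample_id`, `percent_skipping`) or path to
#'   a TSV with those columns.
#' @param genotypes Data frame (`sample_id`, `dose`) or path to a TSV.
#' @param out_dir Output directory.
#' @param alpha Family-wise alpha for the dose-test family (default 0.05).
#' @param family_size Declared number of tests for the Bonferroni
#'   threshold; defaults to the number of dose pairs present.
#' @param welch Use Welch t-tests (default FALSE).
#' @return List with `anova`, `dose_tests` (data frame), `group_summary`
#'   and `manifest`.
#' @export
run_sqtl <- function(measures, genotypes, out_dir, alpha = 0.05,
                     family_size = NULL, welch = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(measures)) measures <- utils::read.delim(measures)
  if (is.character(genotypes)) genotypes <- utils::read.delim(genotypes)
  if (!all(c("sample_id", "percent_skipping") %in% names(measures)))
    stop("measures need columns sample_id, percent_skipping")
  if (!all(c("sample_id", "dose") %in% names(genotypes)))
    stop("genotypes need columns sample_id, dose")
  missing_geno <- setdiff(measures$sample_id, genotypes$sample_id)
  if (length(missing_geno))
    stop("samples without genotype: ", paste(missing_geno, collapse = ", "))
  panel <- merge(measures[, c("sample_id", "percent_skipping")],
                 genotypes[, c("sample_id", "dose")], by = "sample_id")
  check_panel(panel)

  anova_res <- genotype_anova(panel)
  doses <- sort(unique(panel$dose))
  pairs <- utils::combn(doses, 2L)
  testable <- vapply(seq_len(ncol(pairs)), function(i)
    sum(panel$dose == pairs[1, i]) >= 2L &&
      sum(panel$dose == pairs[2, i]) >= 2L, logical(1))
  if (is.null(family_size)) family_size <- sum(testable)
  thr <- bonferroni_threshold(alpha, max(family_size, 1L))
  dose_tests <- do.call(rbind, lapply(which(testable), function(i) {
    dt <- dose_test(panel, pairs[2, i], pairs[1, i], welch = welch)
    data.frame(dose_a = pairs[2, i], dose_b = pairs[1, i],
               n_a = sum(panel$dose == pairs[2, i]),
               n_b = sum(panel$dose == pairs[1, i]),
               statistic = dt$statistic, df = dt$df[1], p = dt$p,
               direction = dt$direction,
               alpha_adjusted = thr$threshold,
               significant = is.finite(dt$p) & dt$p < thr$threshold)
  }))
  group_summary <- do.call(rbind, lapply(split(panel, panel$dose),
    function(g) data.frame(dose = g$dose[1], n = nrow(g),
                           mean_percent_skipping = mean(g$percent_skipping),
                           sd_percent_skipping = stats::sd(g$percent_skipping))))
  rownames(group_summary) <- NULL

  report <- list(
    anova = list(statistic = anova_res$statistic, df = anova_res$df,
                 p = anova_res$p),
    dose_tests = dose_tests, group_summary = group_summary,
    alpha = alpha, family_size = family_size,
    alpha_adjusted = thr$threshold)
  tsv_path <- file.path(out_dir, "sqtl_dose_tests.tsv")
  json_path <- file.path(out_dir, "sqtl_report.json")
  utils::write.table(dose_tests, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  manifest <- make_manifest(list(alpha = alpha, family_size = family_size,
                                 welch = welch),
                            c(tsv_path, json_path),
                            list(n_samples = nrow(panel),
                                 n_dose_groups = length(doses)),
                            seed = NA)
  write_manifest(manifest, file.path(out_dir, "sqtl_manifest.json"))
  list(anova = anova_res, dose_tests = dose_tests,
       group_summary = group_summary, manifest = manifest)
}
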