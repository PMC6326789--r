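# Length-normalized splice-isoform quantification from band tables (gel
# densitometry or fragment-analyzer peaks) and from qPCR Ct tables.
#
# A band's signal is proportional to fragment length times molar
# abundance, so molar isoform fractions are recovered by dividing each
# band's intensity by its fragment length before normalizing.

check_bands <- function(bands) {
  stopifnot(is.data.frame(bands))
  need <- c("isoform_id", "fragment_length", "intensity")
  if (!all(need %in% names(bands)))
    stop("band table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(bands$isoform_id))
    stop("duplicate isoform_id within one sample's band set")
  if (any(bands$fragment_length <= 0)) stop("fragment_length must be > 0")
  if (any(bands$intensity < 0)) stop("negative band intensity")
  invisible(bands)
}

#' Length-normalized molar fractions from band intensities
#'
#' Converts band intensities to molar isoform fractions:
#' `molar_i = (intensity_i / length_i) / sum_j(intensity_j / length_j)`.
#' Works identically for gel densitometry and fragment-analyzer peak
#' height or area; the intensity column simply carries whichever signal
#' was measured.
#'
#' @param bands Data frame for one sample with columns `isoform_id`,
#'   `fragment_length` (bp) and `intensity` (arbitrary units); >= 2 bands.
#' @return Named numeric vector of molar fractions summing to 1.
#' @export
molar_normalize <- function(bands) {
  check_bands(bands)
  if (nrow(bands) < 2L) stop("need >= 2 bands to compute fractions")
  w <- bands$intensity / bands$fragment_length
  total <- sum(w)
  if (total <= 0) stop("total band intensity is zero")
  stats::setNames(w / total, bands$isoform_id)
}

#' Percent of transcripts skipping the target exon
#'
#' Sums the molar fractions of isoforms lacking the target exon
#' (`contains_target_exon == FALSE`) and reports it as a percentage.
#' Handles loci with more than two bands (e.g. isoforms including both of
#' two exons, only one, or neither: every band lacking the target exon
#' counts toward skipping).
#'
#' @param bands Data frame for one sample with the [molar_normalize]
#'   columns plus logical `contains_target_exon`.
#' @param method Label recorded on the result: `"gel"`,
#'   `"fragment_analyzer_peak_height"`, `"fragment_analyzer_peak_area"` or
#'   `"qpcr"`.
#' @return A `splicing_measure` list: `sample_id` (if present in `bands`),
#'   `percent_skipping` in [0, 100], `percent_inclusion`, `n_isoforms`,
#'   `method`. A warning is raised when every band has the same
#'   exon-content flag (degenerate 0 or 100).
#' @export
percent_skipping <- function(bands, method = "gel") {
  check_bands(bands)
  if (!"contains_target_exon" %in% names(bands))
    stop("band table needs a logical 'contains_target_exon' column")
  if (anyNA(bands$contains_target_exon))
    stop("contains_target_exon must be TRUE/FALSE for every band")
  frac <- molar_normalize(bands)
  if (all(bands$contains_target_exon) || all(!bands$contains_target_exon))
    warning("all bands share the same exon-content flag; ",
            "percent skipping is degenerate (0 or 100)")
  pct <- 100 * sum(frac[!bands$contains_target_exon])
  structure(list(
    sample_id = if ("sample_id" %in% names(bands)) bands$sample_id[1]
                else NA_character_,
    percent_skipping = pct, percent_inclusion = 100 - pct,
    n_isoforms = nrow(bands), method = method,
    molar_fractions = frac),
    class = "splicing_measure")
}

#' @export
print.splicing_measure <- function(x, ...) {
  cat(sprintf("<splicing_measure> %s: %.2f%% skipping (%d isoforms, %s)\n",
              x$sample_id, x$percent_skipping, x$n_isoforms, x$method))
  invisible(x)
}

#' Percent skipping for every sample in a band table
#'
#' @param bands Data frame with columns `sample_id`, `isoform_id`,
#'   `fragment_length`, `intensity`, `contains_target_exon` (several
#'   samples stacked).
#' @param method Measurement method label (see [percent_skipping]).
#' @return Data frame with one row per sample: `sample_id`,
#'   `percent_skipping`, `n_isoforms`, `method`.
#' @export
percent_skipping_by_sample <- function(bands, method = "gel") {
  stopifnot("sample_id" %in% names(bands))
  parts <- split(bands, bands$sample_id)
  rows <- lapply(parts, function(b) {
    m <- percent_skipping(b, method = method)
    data.frame(sample_id = b$sample_id[1],
               percent_skipping = m$percent_skipping,
               n_isoforms = m$n_isoforms, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- qPCR ------------------------------------------------------------------

#' Relative expression from qPCR Ct replicates (2^-dCt)
#'
#' Replicate Ct values are averaged at the Ct level, then
#' `dCt = mean(Ct_target) - mean(Ct_reference)` and relative expression is
#' `2^-dCt`. Undetermined (NA or non-finite) Ct values are rejected:
#' records containing them must be excluded upstream with a logged reason
#' rather than silently averaged.
#'
#' @param ct_target Numeric vector of target-assay Ct replicates.
#' @param ct_reference Numeric vector of reference-gene Ct replicates.
#' @param sample_id Optional sample label carried on the result.
#' @return A `qpcr_measurement` list: `ct_mean_target`,
#'   `ct_mean_reference`, `delta_ct`, `rel_expr`.
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference,
                                     sample_id = NA_character_) {
  if (length(ct_target) < 1L || length(ct_reference) < 1L)
    stop("need >= 1 Ct replicate for target and reference")
  if (anyNA(ct_target) || anyNA(ct_reference) ||
      any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("undetermined Ct value; exclude the record before quantification")
  mt <- mean(ct_target)
  mr <- mean(ct_reference)
  dct <- mt - mr
  structure(list(sample_id = sample_id, ct_mean_target = mt,
                 ct_mean_reference = mr, delta_ct = dct,
                 rel_expr = 2^(-dct)),
            class = "qpcr_measurement")
}

#' @export
print.qpcr_measurement <- function(x, ...) {
  cat(sprintf("<qpcr_measurement> %s: dCt = %.3f, 2^-dCt = %.4g\n",
              x$sample_id, x$delta_ct, x$rel_expr))
  invisible(x)
}

#' Isoform ratio from two qPCR measurements
#'
#' Ratio of the skip-isoform to the include-isoform relative expression
#' within one sample. Because both assays share the same reference gene,
#' the ratio reduces to `2^(Ct_include - Ct_skip)`: the reference cancels.
#'
#' @param skip,include `qpcr_measurement` objects for the two
#'   isoform-specific assays of the same sample.
#' @return The skip/include expression ratio (positive scalar).
#' @export
qpcr_isoform_ratio <- function(skip, include) {
  stopifnot(inherits(skip, "qpcr_measurement"),
            inherits(include, "qpcr_measurement"))
  if (!identical(skip$sample_id, include$sample_id))
    stop("isoform measurements come from different samples (",
         skip$sample_id, " vs ", include$sample_id, ")")
  skip$rel_expr / include$rel_expr
}

## ---- TSV readers -----------------------------------------------------------

#' Read a band-quantification table
#'
#' Tab-separated with header; required columns `sample_id`, `isoform_id`,
#' `fragment_length`, `intensity`, `contains_target_exon` (TRUE/FALSE).
#'
#' @param path Input TSV path.
#' @return Data frame.
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stop("band table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "isoform_id", "fragment_length", "intensity",
            "contains_target_exon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("band table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df$contains_target_exon <- as.logical(df$contains_target_exon)
  df
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header; required columns `sample_id`, `primer_pair`
#' (e.g. skip_isoform / include_isoform / reference) and `ct`. Rows whose
#' Ct is undetermined (`NA`, empty, or the literal `Undetermined`) are
#' dropped with a message naming them.
#'
#' @param path Input TSV path.
#' @return Data frame of usable replicates.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "primer_pair", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- is.na(ct) | !is.finite(ct)
  if (any(bad))
    message("dropping ", sum(bad), " replicate(s) with undetermined Ct: ",
            paste(utils::head(paste0(df$sample_id[bad], "/",
                                     df$primer_pair[bad]), 5),
                  collapse = ", "))
  df <- df[!bad, , drop = FALSE]
  df$ct <- ct[!bad]
  rownames(df) <- NULL
  df
}

#' Write per-sample splicing measures as TSV
#'
#' @param measures Data frame from [percent_skipping_by_sample].
#' @param path Output path. Percentages are written at two decimals.
#' @return The path, invisibly.
#' @export
write_splicing_measures <- function(measures, path) {
  out <- measures
  out$percent_skipping <- sprintf("%.2f", out$percent_skipping)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
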