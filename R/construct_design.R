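# Control-sequence design for minigene splicing reporters: scrambled
# elements, GC-matched randomized spacers, and simple sequence descriptors
# (GC content, pairwise divergence).

DNA_ALPHABET <- c("A", "C", "G", "T")

check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || !nzchar(seq))
    stop(what, " must be a non-empty DNA string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!all(chars %in% DNA_ALPHABET))
    stop(what, " contains characters outside {A,C,G,T}; ",
         "ambiguity codes are not supported")
  chars
}

new_construct <- function(label, chars, seed = NA_integer_) {
  seq <- paste(chars, collapse = "")
  structure(list(label = label, sequence = seq, length = length(chars),
                 gc = sum(chars %in% c("G", "C")) / length(chars),
                 seed = as.integer(seed)),
            class = "construct_sequence")
}

#' @export
print.construct_sequence <- function(x, ...) {
  cat(sprintf("<construct_sequence> %s: %d bp, GC %.1f%%%s\n", x$label,
              x$length, 100 * x$gc,
              if (!is.na(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

#' Scramble a sequence (uniform random permutation)
#'
#' Returns an exact multiset permutation of the input: every base,
#' including any polyA tail, enters the permutation pool, so base
#' composition and GC content are preserved exactly. Deterministic given
#' the seed.
#'
#' @param seq DNA string over \{A,C,G,T\} (polyA tail included).
#' @param seed Integer seed (required).
#' @return A `construct_sequence` with `label = "scrambled"`.
#' @export
scramble_sequence <- function(seq, seed) {
  chars <- check_dna(seq)
  if (missing(seed)) stop("a seed is required")
  perm <- withr::with_seed(seed, sample.int(length(chars)))
  new_construct("scrambled", chars[perm], seed = seed)
}

#' Random sequence with an exact GC count
#'
#' Generates a random sequence of the requested length containing exactly
#' `round(length * gc_target)` G or C bases (round half up), placed
#' uniformly at random; G vs C and A vs T are each fair coin flips.
#' Intended to replace an element with a spacer matching the GC content of
#' the pre-insertion integration site.
#'
#' @param length Sequence length in bp (>= 1); for element replacement this
#'   is the element length including the polyA tail.
#' @param gc_target Target GC fraction in [0, 1].
#' @param seed Integer seed (required).
#' @return A `construct_sequence` with `label = "gc_matched_random"`.
#' @export
random_gc_matched <- function(length, gc_target, seed) {
  if (length < 1) stop("length must be >= 1")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must lie in [0, 1]")
  if (missing(seed)) stop("a seed is required")
  n_gc <- floor(length * gc_target + 0.5)  # round half up
  chars <- withr::with_seed(seed, {
    at <- sample(c("A", "T"), length - n_gc, replace = TRUE)
    gc <- sample(c("G", "C"), n_gc, replace = TRUE)
    out <- character(length)
    gc_pos <- sample.int(length, n_gc)
    out[gc_pos] <- gc
    out[setdiff(seq_len(length), gc_pos)] <- at
    out
  })
  new_construct("gc_matched_random", chars, seed = seed)
}

#' GC content of a sequence
#'
#' @param seq DNA string over \{A,C,G,T\}.
#' @return Fraction of G or C bases.
#' @export
gc_content <- function(seq) {
  chars <- check_dna(seq)
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Pairwise divergence between two aligned sequences
#'
#' Hamming count of mismatching positions between two equal-length
#' sequences. Gapped alignment is out of scope: align first, then compare.
#'
#' @param a,b DNA strings of equal length.
#' @return List with `n_diff` and `percent` (fraction of positions).
#' @export
pairwise_divergence <- function(a, b) {
  ca <- check_dna(a, "first sequence")
  cb <- check_dna(b, "second sequence")
  if (length(ca) != length(cb))
    stop("sequences differ in length (", length(ca), " vs ", length(cb),
         "); align them before computing divergence")
  n_diff <- sum(ca != cb)
  list(n_diff = n_diff, percent = n_diff / length(ca))
}

#' Assemble a reporter insert from flanks and a payload
#'
#' Concatenates the 5' flank, an optional payload (the natural element, a
#' scrambled element, a GC-matched spacer, ...) and the 3' flank. An empty
#' payload yields the pre-insertion allele.
#'
#' @param flank5,flank3 Non-empty DNA strings.
#' @param payload A `construct_sequence`, a DNA string, or NULL for the
#'   pre-insertion (empty) allele.
#' @return List with `sequence`, `length` and a `parts` length bookkeeping
#'   vector (flank5, payload, flank3).
#' @export
build_reporter_insert <- function(flank5, payload = NULL, flank3) {
  c5 <- check_dna(flank5, "flank5")
  c3 <- check_dna(flank3, "flank3")
  pay <- if (is.null(payload)) character(0)
         else if (inherits(payload, "construct_sequence"))
           strsplit(payload$sequence, "", fixed = TRUE)[[1]]
         else check_dna(payload, "payload")
  chars <- c(c5, pay, c3)
  list(sequence = paste(chars, collapse = ""), length = length(chars),
       parts = c(flank5 = length(c5), payload = length(pay),
                 flank3 = length(c3)))
}

#' Design the control-construct series for one locus
#'
#' Produces the standard replacement series used to dissect whether an
#' element's effect on splicing is sequence specific: the natural element,
#' a consensus-subfamily substitution (if supplied), `k` independent
#' scrambles of the element, `k` GC-matched random spacers of the same
#' length, and the empty (pre-insertion) allele. Distinct seeds are derived
#' per construct and recorded in the output metadata.
#'
#' @param element DNA string of the natural element including polyA tail.
#' @param gc_site GC fraction of the pre-insertion integration site, used
#'   for the random spacers.
#' @param consensus Optional DNA string of a consensus element to
#'   substitute (not generated by the package; supply from a FASTA).
#' @param k Number of independent scrambles and spacers (default 2).
#' @param seed Base integer seed; construct i uses `seed + i`.
#' @return Named list of `construct_sequence` objects (`no_insert` is NULL
#'   payload marker with an empty sequence).
#' @export
design_construct_series <- function(element, gc_site, consensus = NULL,
                                    k = 2L, seed) {
  chars <- check_dna(element, "element")
  if (missing(seed)) stop("a seed is required")
  out <- list(natural_alu = new_construct("natural_alu", chars))
  if (!is.null(consensus))
    out$consensus_sub <- new_construct("consensus_sub",
                                       check_dna(consensus, "consensus"))
  for (i in seq_len(k)) {
    out[[sprintf("scrAlu-%d", i)]] <- scramble_sequence(element, seed + i)
    out[[sprintf("rGC-%d", i)]] <-
      random_gc_matched(length(chars), gc_site, seed + k + i)
  }
  out$no_insert <- structure(
    list(label = "no_insert", sequence = "", length = 0L, gc = NA_real_,
         seed = NA_integer_),
    class = "construct_sequence")
  out
}

#' Write a construct series as multi-FASTA with a TSV manifest
#'
#' @param series Named list from [design_construct_series].
#' @param fasta_path Output FASTA path (the empty `no_insert` record is
#'   omitted from the FASTA but listed in the manifest).
#' @param manifest_path Output TSV path (label, length, gc, seed).
#' @return Invisibly, the manifest data frame.
#' @export
write_construct_series <- function(series, fasta_path, manifest_path) {
  keep <- vapply(series, function(s) s$length > 0L, logical(1))
  seqs <- Biostrings::DNAStringSet(
    vapply(series[keep], `[[`, character(1), "sequence"))
  names(seqs) <- names(series)[keep]
  Biostrings::writeXStringSet(seqs, fasta_path)
  manifest <- data.frame(
    label = names(series),
    length = vapply(series, `[[`, integer(1), "length"),
    gc = vapply(series, `[[`, numeric(1), "gc"),
    seed = vapply(series, `[[`, integer(1), "seed"),
    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

#' Read a FASTA file as plain character sequences
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}
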