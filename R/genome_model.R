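# Annotation and variant data model.
#
# All coordinates are handled internally as 0-based half-open intervals
# [start, end), the BED convention. GFF3 input (1-based inclusive) is
# converted on read. An insertion variant is a single base position `pos`
# (0-based): the base immediately 3' of the integration junction on the
# plus strand.

#' Construct a gene model
#'
#' A gene model holds the isoform structures of one gene: an ordered exon
#' list per isoform plus a deduplicated exon table in which every exon is
#' classified as constitutive or alternatively used.
#'
#' @param gene_id Gene identifier (non-empty string).
#' @param chrom Chromosome name.
#' @param strand Gene strand, `"+"` or `"-"`.
#' @param isoforms Named list; each element a data frame with integer
#'   columns `start`, `end` giving exon intervals in 0-based half-open
#'   coordinates. Exons within an isoform must not overlap.
#'
#' @return An object of class `gene_model` with elements `gene_id`,
#'   `chrom`, `strand`, `isoforms` (exons sorted by genomic start) and
#'   `exons`, a data frame of deduplicated exons with columns `exon_id`,
#'   `start`, `end`, `length`, `exon_class` and `isoform_ids`
#'   (comma-separated).
#'
#' @details An exon is *constitutive* when it is present with identical
#' boundaries in every isoform of the gene. It is *skipped* when at least
#' one isoform spans its locus without any exon overlapping it, and
#' *alt5*/*alt3* when another isoform uses an overlapping exon with a
#' different 5' or 3' boundary (boundaries read in transcription
#' orientation). Skipping combined with alternative ends is reported as
#' `"skipped+alt-ends"`.
#'
#' @export
gene_model <- function(gene_id, chrom, strand, isoforms) {
  stopifnot(is.character(gene_id), nzchar(gene_id), length(gene_id) == 1L)
  stopifnot(is.character(chrom), nzchar(chrom))
  if (!strand %in% c("+", "-"))
    stop("gene strand must be '+' or '-'")
  if (!is.list(isoforms) || length(isoforms) == 0L || is.null(names(isoforms)))
    stop("'isoforms' must be a non-empty named list")
  iso_names <- names(isoforms)
  if (anyDuplicated(iso_names)) stop("duplicate isoform ids")
  isoforms <- stats::setNames(lapply(iso_names, function(id) {
    ex <- as.data.frame(isoforms[[id]])
    if (!all(c("start", "end") %in% names(ex)))
      stop("isoform '", id, "': exon table needs 'start' and 'end' columns")
    ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
    if (any(ex$start >= ex$end))
      stop("isoform '", id, "': exon with start >= end")
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("isoform '", id, "': overlapping exons")
    rownames(ex) <- NULL
    ex
  }), iso_names)
  gm <- structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         isoforms = isoforms, exons = NULL),
    class = "gene_model")
  gm$exons <- classify_gene_exons(gm)
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s:%s) %d isoform(s), %d distinct exon(s)\n",
              x$gene_id, x$chrom, x$strand, length(x$isoforms),
              nrow(x$exons)))
  invisible(x)
}

gene_span <- function(gm) {
  s <- min(vapply(gm$isoforms, function(e) min(e$start), numeric(1)))
  e <- max(vapply(gm$isoforms, function(e) max(e$end), numeric(1)))
  c(start = s, end = e)
}

#' Classify one exon against the isoform set of its gene
#'
#' @param start,end Exon boundaries, 0-based half-open.
#' @param isoforms Named list of isoform exon tables (`start`, `end`).
#' @param strand Gene strand (orients which boundary is 5' vs 3').
#'
#' @return One of `"constitutive"`, `"skipped"`, `"alt5"`, `"alt3"`,
#'   `"alt5+alt3"`, `"skipped+alt-ends"`.
#'
#' @details Classification rules: present with identical boundaries in all
#' isoforms gives `"constitutive"`; absent from an isoform whose span covers
#' the exon locus gives skipped status; an overlapping exon in another
#' isoform with a different transcription-5' (resp. 3') boundary gives
#' alt5 (resp. alt3) status. Absence only from isoforms that do not span
#' the locus (alternative first/last segments) does not count as skipping.
#'
#' @export
classify_exon <- function(start, end, isoforms, strand = "+") {
  found <- FALSE
  in_all <- TRUE
  skipped <- FALSE
  alt_start <- FALSE  # genomic-left boundary differs in some isoform
  alt_end <- FALSE    # genomic-right boundary differs
  for (ex in isoforms) {
    identical_here <- any(ex$start == start & ex$end == end)
    if (identical_here) found <- TRUE
    overlapping <- ex$start < end & ex$end > start
    if (any(overlapping)) {
      ov <- ex[overlapping, , drop = FALSE]
      if (any(ov$start != start)) alt_start <- TRUE
      if (any(ov$end != end)) alt_end <- TRUE
      if (!identical_here) in_all <- FALSE
    } else {
      in_all <- FALSE
      spans <- min(ex$start) <= start && max(ex$end) >= end
      if (spans) skipped <- TRUE
    }
  }
  if (!found)
    stop("exon [", start, ",", end, ") not found in any isoform")
  if (in_all) return("constitutive")
  alt5 <- if (strand == "+") alt_start else alt_end
  alt3 <- if (strand == "+") alt_end else alt_start
  if (skipped && (alt5 || alt3)) return("skipped+alt-ends")
  if (skipped) return("skipped")
  if (alt5 && alt3) return("alt5+alt3")
  if (alt5) return("alt5")
  if (alt3) return("alt3")
  # present in several but not all isoforms, absent only from isoforms that
  # do not span the locus: constitutive within the covered region
  "constitutive"
}

is_alternative_class <- function(exon_class) exon_class != "constitutive"

classify_gene_exons <- function(gm) {
  all_ex <- do.call(rbind, lapply(names(gm$isoforms), function(id) {
    cbind(gm$isoforms[[id]], isoform_id = id)
  }))
  key <- paste(all_ex$start, all_ex$end)
  uniq <- !duplicated(key)
  ex <- all_ex[uniq, c("start", "end"), drop = FALSE]
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  iso_ids <- vapply(seq_len(nrow(ex)), function(i) {
    hit <- all_ex$start == ex$start[i] & all_ex$end == ex$end[i]
    paste(sort(unique(all_ex$isoform_id[hit])), collapse = ",")
  }, character(1))
  cls <- vapply(seq_len(nrow(ex)), function(i) {
    classify_exon(ex$start[i], ex$end[i], gm$isoforms, gm$strand)
  }, character(1))
  data.frame(
    exon_id = sprintf("%s:%d-%d", gm$gene_id, ex$start, ex$end),
    start = ex$start, end = ex$end, length = ex$end - ex$start,
    exon_class = cls, isoform_ids = iso_ids,
    stringsAsFactors = FALSE, row.names = NULL)
}

## ---- readers ---------------------------------------------------------------

#' Read a gene annotation (GFF3 or BED12)
#'
#' @param path Path to a GFF3 file (`gene`/`mRNA`/`exon` features linked by
#'   `ID`/`Parent`) or a BED12 file. Format is chosen by file extension
#'   (`.gff`, `.gff3` vs `.bed`), overridable via `format`.
#' @param format `"auto"`, `"gff3"` or `"bed12"`.
#'
#' @return A named list of [gene_model] objects, one per gene.
#'
#' @details For BED12, each line is one isoform; names of the form
#' `"gene|isoform"` group isoforms into genes, otherwise each line becomes
#' a single-isoform gene. GFF3 coordinates are converted from 1-based
#' inclusive to the package's 0-based half-open convention.
#'
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "gff3") read_annotation_gff3(path) else read_annotation_bed12(path)
}

read_annotation_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path,
                                          "': ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) md$Parent else NULL
  parent1 <- if (is.null(parents)) rep(NA_character_, length(gr)) else
    vapply(as.list(parents), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))

  tx_sel <- type %in% c("mRNA", "transcript", "ncRNA", "lnc_RNA")
  ex_sel <- type == "exon"
  gene_sel <- type == "gene"
  if (!any(tx_sel)) stop("no transcript features in '", path, "'")
  tx_id <- ids[tx_sel]
  tx_gene <- parent1[tx_sel]
  gene_strand <- stats::setNames(as.character(BiocGenerics::strand(gr))[gene_sel],
                                 ids[gene_sel])
  gene_chrom <- stats::setNames(
    as.character(GenomicRanges::seqnames(gr))[gene_sel], ids[gene_sel])

  ex_parent <- parent1[ex_sel]
  ex_start <- BiocGenerics::start(gr)[ex_sel] - 1L  # to 0-based
  ex_end <- BiocGenerics::end(gr)[ex_sel]
  if (anyNA(ex_parent)) stop("exon without Parent in '", path, "'")

  genes <- unique(tx_gene)
  out <- lapply(genes, function(g) {
    iso_ids <- tx_id[tx_gene == g]
    isoforms <- lapply(iso_ids, function(t) {
      sel <- ex_parent == t
      data.frame(start = ex_start[sel], end = ex_end[sel])
    })
    names(isoforms) <- iso_ids
    strand <- if (g %in% names(gene_strand)) gene_strand[[g]] else "+"
    chrom <- if (g %in% names(gene_chrom)) gene_chrom[[g]] else
      as.character(GenomicRanges::seqnames(gr))[ex_sel][ex_parent == iso_ids[1]][1]
    gene_model(g, chrom, strand, isoforms)
  })
  stats::setNames(out, genes)
}

read_annotation_bed12 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (!"blocks" %in% names(S4Vectors::mcols(gr)))
    stop("'", path, "' is not BED12 (no block structure)")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) stop("BED12 records need names")
  gene_of <- ifelse(grepl("|", nm, fixed = TRUE),
                    sub("\\|.*$", "", nm), nm)
  iso_of <- ifelse(grepl("|", nm, fixed = TRUE),
                   sub("^[^|]*\\|", "", nm), nm)
  out <- lapply(unique(gene_of), function(g) {
    idx <- which(gene_of == g)
    isoforms <- lapply(idx, function(i) {
      bl <- S4Vectors::mcols(gr)$blocks[[i]]
      # blocks are 1-based relative to the feature start
      off <- BiocGenerics::start(gr)[i] - 1L
      data.frame(start = off + BiocGenerics::start(bl) - 1L,
                 end = off + BiocGenerics::end(bl))
    })
    names(isoforms) <- make.unique(iso_of[idx])
    gene_model(g, as.character(GenomicRanges::seqnames(gr))[idx[1]],
                   as.character(BiocGenerics::strand(gr))[idx[1]], isoforms)
  })
  stats::setNames(out, unique(gene_of))
}

#' Read an insertion-variant catalog (extended BED)
#'
#' Expects tab-separated columns: chrom, pos, pos+1, subfamily,
#' element_length, element_strand and optionally allele_frequency. `pos` is
#' the 0-based single-base insertion point.
#'
#' @param path Path to the catalog file. Lines starting with `#` or
#'   `track` are skipped.
#' @return A data frame with columns `chrom`, `pos`, `subfamily`,
#'   `element_length`, `element_strand`, `allele_frequency`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^(#|track|browser)", ln) & nzchar(ln)]
  if (length(ln) == 0L) stop("variant file '", path, "' contains no records")
  fields <- strsplit(ln, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6L))
    stop("variant file '", path, "': line ", which(ncol < 6L)[1],
         " has fewer than 6 columns")
  df <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    subfamily = vapply(fields, `[[`, character(1), 4L),
    element_length = as.integer(vapply(fields, `[[`, character(1), 5L)),
    element_strand = vapply(fields, `[[`, character(1), 6L),
    allele_frequency = vapply(fields, function(f) {
      if (length(f) < 7L || f[[7L]] %in% c(".", "", "NA")) return(NA_real_)
      af <- suppressWarnings(as.numeric(f[[7L]]))
      if (is.na(af)) stop("non-numeric allele_frequency: ", f[[7L]])
      af
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (anyNA(df$pos)) stop("variant file '", path, "': non-integer position")
  if (any(df$end != df$pos + 1L))
    stop("variant file '", path, "': end column must equal pos + 1")
  if (any(df$pos < 0L)) stop("variant positions must be >= 0")
  if (any(!df$element_strand %in% c("+", "-")))
    stop("element_strand must be '+' or '-'")
  if (any(df$element_length <= 0L, na.rm = TRUE))
    stop("element_length must be positive")
  af <- df$allele_frequency
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele_frequency must lie in [0, 1]")
  df$end <- NULL
  df
}

## ---- variant-to-exon geometry ---------------------------------------------

# Distance from insertion point p to exon [s, e), 0-based half-open.
# Inside the exon: 0. Adjacent base: 1 (bedtools closest -d convention).
point_exon_distance <- function(p, s, e) {
  ifelse(p >= s & p < e, 0L, ifelse(p < s, s - p, p - e + 1L))
}

# Is each position inside any deduplicated exon of the gene?
in_any_exon <- function(pos, gm) {
  ex <- gm$exons
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(ex)))
    hit <- hit | (pos >= ex$start[i] & pos < ex$end[i])
  hit
}

# Minimum distance from each position in `pos` to any exon in `exons`
# (data frame with start/end), vectorized over positions.
min_exon_distance <- function(pos, exons) {
  d <- rep(Inf, length(pos))
  for (i in seq_len(nrow(exons)))
    d <- pmin(d, point_exon_distance(pos, exons$start[i], exons$end[i]))
  d
}

#' Is an insertion point intronic within a gene?
#'
#' TRUE when the position falls between two exons of at least one isoform
#' and inside no exon of that isoform.
#'
#' @param pos 0-based insertion point (vectorized).
#' @param gene A [gene_model].
#' @return Logical vector.
#' @export
is_intronic <- function(pos, gene) {
  stopifnot(inherits(gene, "gene_model"))
  out <- logical(length(pos))
  for (ex in gene$isoforms) {
    within_span <- pos >= min(ex$start) & pos < max(ex$end)
    in_exon <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(ex)))
      in_exon <- in_exon | (pos >= ex$start[i] & pos < ex$end[i])
    out <- out | (within_span & !in_exon)
  }
  out
}

#' Distance from insertion variants to the nearest exon
#'
#' For every variant and every gene whose body contains it, reports the
#' nearest deduplicated exon, the distance in bp and the variant's position
#' relative to that exon in transcription orientation. Distance follows the
#' `bedtools closest -d` convention: 0 inside an exon, 1 for the base
#' adjacent to an exon edge. When a variant is exactly equidistant from two
#' exons the transcriptionally downstream exon is reported and the row is
#' flagged `tie = TRUE`. Variants contained in no gene body are reported
#' with `relative_position = "intergenic"` rather than dropped.
#'
#' @param variants Data frame as returned by [read_variants] (columns
#'   `chrom`, `pos`; other columns carried through).
#' @param genes List of [gene_model] objects.
#' @return Data frame with one row per (variant, containing gene):
#'   `chrom`, `pos`, `subfamily`, `element_strand`, `element_length`,
#'   `allele_frequency`, `gene_id`, `gene_strand`, `exon_id`, `exon_class`,
#'   `exon_length`, `distance`, `relative_position` (`upstream`,
#'   `downstream`, `within_exon` or `intergenic`), `intronic`, `tie`.
#' @export
nearest_exon_distance <- function(variants, genes) {
  stopifnot(is.data.frame(variants), all(c("chrom", "pos") %in% names(variants)))
  carry <- intersect(c("subfamily", "element_strand", "element_length",
                       "allele_frequency"), names(variants))
  rows <- vector("list", nrow(variants) * 2L)
  k <- 0L
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    chrom <- variants$chrom[i]
    hit_any <- FALSE
    for (gm in genes) {
      if (gm$chrom != chrom) next
      sp <- gene_span(gm)
      if (p < sp["start"] || p >= sp["end"]) next
      hit_any <- TRUE
      ex <- gm$exons
      d <- point_exon_distance(p, ex$start, ex$end)
      dmin <- min(d)
      at_min <- which(d == dmin)
      tie <- length(at_min) > 1L
      j <- if (!tie) at_min else {
        # downstream exon in transcription order
        if (gm$strand == "+") at_min[which.max(ex$start[at_min])]
        else at_min[which.min(ex$start[at_min])]
      }
      relpos <- if (dmin == 0L) "within_exon" else {
        genomic_left <- p < ex$start[j]
        if (gm$strand == "+") {
          if (genomic_left) "upstream" else "downstream"
        } else {
          if (genomic_left) "downstream" else "upstream"
        }
      }
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(chrom = chrom, pos = p, stringsAsFactors = FALSE),
        variants[i, carry, drop = FALSE],
        data.frame(gene_id = gm$gene_id, gene_strand = gm$strand,
                   exon_id = ex$exon_id[j], exon_class = ex$exon_class[j],
                   exon_length = ex$length[j], distance = dmin,
                   relative_position = relpos,
                   intronic = is_intronic(p, gm), tie = tie,
                   stringsAsFactors = FALSE))
    }
    if (!hit_any) {
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(chrom = chrom, pos = p, stringsAsFactors = FALSE),
        variants[i, carry, drop = FALSE],
        data.frame(gene_id = NA_character_, gene_strand = NA_character_,
                   exon_id = NA_character_, exon_class = NA_character_,
                   exon_length = NA_integer_, distance = NA_integer_,
                   relative_position = "intergenic", intronic = FALSE,
                   tie = FALSE, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Write gene models as GFF3
#'
#' Emits a `gene` / `mRNA` / `exon` hierarchy linked by `ID`/`Parent`,
#' converting the package's 0-based half-open coordinates back to GFF3's
#' 1-based inclusive convention.
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (gm in genes) {
    sp <- gene_span(gm)
    lines <- c(lines, sprintf(
      "%s\tmobsplice\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      gm$chrom, sp["start"] + 1L, sp["end"], gm$strand, gm$gene_id))
    for (iso in names(gm$isoforms)) {
      ex <- gm$isoforms[[iso]]
      lines <- c(lines, sprintf(
        "%s\tmobsplice\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        gm$chrom, min(ex$start) + 1L, max(ex$end), gm$strand, iso,
        gm$gene_id))
      lines <- c(lines, sprintf(
        "%s\tmobsplice\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        gm$chrom, ex$start + 1L, ex$end, gm$strand, iso,
        seq_len(nrow(ex)), iso))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an insertion-variant catalog as extended BED
#'
#' Columns: chrom, pos, pos+1, subfamily, element_length, element_strand,
#' allele_frequency.
#'
#' @param variants Data frame as from [read_variants].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variants <- function(variants, path) {
  af <- variants$allele_frequency
  af <- ifelse(is.na(af), ".", format(af, trim = TRUE))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s",
                     variants$chrom, variants$pos, variants$pos + 1L,
                     variants$subfamily, variants$element_length,
                     variants$element_strand, af), path)
  invisible(path)
}

#' Write a variant-to-exon distance table as TSV
#'
#' @param distances Data frame from [nearest_exon_distance].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_table <- function(distances, path) {
  utils::write.table(distances, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
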