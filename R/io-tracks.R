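#' Read per-sample splice-junction tables (STAR SJ.out.tab dialect)
#'
#' Each file has nine tab-separated columns and no header: chrom, 1-based
#' first intron base, 1-based last intron base, strand code (0 undefined,
#' 1 `+`, 2 `-`), motif, annotated flag, unique-read count, multi-read count,
#' overhang. Coordinates convert to internal 0-based half-open intron keys.
#' A strand code of 0 registers the junction on both strands. Duplicate
#' junctions within one sample have their read counts summed (with a
#' warning). Files may be gzip-compressed.
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_names Sample identifiers (default: file base names without
#'   extension).
#' @param min_unique_reads Per-sample unique-read threshold for a junction to
#'   count as detected in that sample (default 1).
#' @return An object of class `junction_evidence`: per-sample read-count maps
#'   plus the aggregate per-junction sample counts.
#' @export
read_junction_tables <- function(paths,
                                 sample_names = NULL,
                                 min_unique_reads = 1L) {
  if (is.null(sample_names)) {
    sample_names <- sub("\\.gz$", "", basename(paths))
    sample_names <- sub("\\.[^.]*$", "", sample_names)
  }
  stopifnot(length(sample_names) == length(paths),
            !anyDuplicated(sample_names))
  per_sample <- vector("list", length(paths))
  names(per_sample) <- sample_names
  for (k in seq_along(paths)) {
    p <- paths[k]
    df <- tryCatch(
      read.table(p, sep = "\t", header = FALSE, colClasses = c(
        "character", rep("integer", 8L))),
      error = function(e) stop("malformed junction table ", p, ": ",
                               conditionMessage(e)))
    if (ncol(df) != 9L) stop("malformed junction table ", p, ": expected 9 columns, got ", ncol(df))
    bad <- which(is.na(df[[2L]]) | is.na(df[[3L]]) | is.na(df[[7L]]) |
                   df[[2L]] > df[[3L]] | !(df[[4L]] %in% 0:2))
    if (length(bad)) stop("malformed junction table ", p, ": row ", bad[1L])
    # 1-based [first, last] intron base -> 0-based half-open [first-1, last)
    s0 <- df[[2L]] - 1L
    e0 <- df[[3L]]
    strand <- c("0" = NA, "1" = "+", "2" = "-")[as.character(df[[4L]])]
    reads <- df[[7L]]
    keys <- character(0); vals <- integer(0)
    defined <- !is.na(strand)
    if (any(defined)) {
      keys <- sprintf("%s:%s:%d-%d", df[[1L]][defined], strand[defined],
                      s0[defined], e0[defined])
      vals <- reads[defined]
    }
    if (any(!defined)) {
      i <- which(!defined)
      keys <- c(keys,
                sprintf("%s:+:%d-%d", df[[1L]][i], s0[i], e0[i]),
                sprintf("%s:-:%d-%d", df[[1L]][i], s0[i], e0[i]))
      vals <- c(vals, reads[i], reads[i])
    }
    if (anyDuplicated(keys)) {
      warning("duplicate junctions in ", p, "; read counts summed")
      agg <- tapply(vals, keys, sum)
      keys <- names(agg); vals <- as.integer(agg)
    }
    per_sample[[k]] <- setNames(as.integer(vals), keys)
  }
  junction_evidence(per_sample, min_unique_reads = min_unique_reads)
}

#' Build a junction-evidence set from per-sample read-count maps
#'
#' @param per_sample Named list; each element a named integer vector mapping
#'   intron key (`chrom:strand:start-end`, internal coordinates) to
#'   unique-read count for that sample.
#' @param min_unique_reads Per-sample detection threshold (default 1).
#' @return `junction_evidence` object with `$aggregate`, the per-junction
#'   count of supporting samples.
#' @export
junction_evidence <- function(per_sample, min_unique_reads = 1L) {
  stopifnot(min_unique_reads >= 0L)
  detected <- lapply(per_sample, function(m) names(m)[m >= min_unique_reads])
  tab <- table(unlist(detected, use.names = FALSE))
  aggregate <- setNames(as.integer(tab), names(tab))
  structure(list(per_sample = per_sample,
                 min_unique_reads = as.integer(min_unique_reads),
                 aggregate = aggregate),
            class = "junction_evidence")
}

#' @export
print.junction_evidence <- function(x, ...) {
  cat(sprintf("<junction_evidence> %d sample(s), %d distinct junction(s)\n",
              length(x$per_sample), length(x$aggregate)))
  invisible(x)
}

#' Number of samples supporting each queried junction
#'
#' @param evidence A `junction_evidence`.
#' @param keys Character vector of intron keys.
#' @return Integer vector (0 for junctions never observed).
#' @export
junction_support <- function(evidence, keys) {
  out <- evidence$aggregate[keys]
  out[is.na(out)] <- 0L
  setNames(as.integer(out), keys)
}

#' Construct an annotation track
#'
#' A named set of genomic intervals (internal 0-based half-open) with optional
#' labels, used for TSS/TTS feature overlap (transposable elements, CAGE
#' peaks, polyA sites).
#'
#' @param name Track name (e.g. `"TE"`).
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param strand Optional strand vector; `"*"` for unstranded intervals.
#' @param label Optional per-interval labels (e.g. TE family `"L1PA2"`).
#' @param stranded Whether overlap queries should require matching strand.
#' @return Object of class `annotation_track` (a sorted data.frame).
#' @export
annotation_track <- function(name, chrom, start, end, strand = NULL,
                             label = NULL, stranded = FALSE) {
  n <- length(chrom)
  if (is.null(strand)) strand <- rep("*", n)
  if (is.null(label)) label <- rep(NA_character_, n)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   label = as.character(label), stringsAsFactors = FALSE)
  stopifnot(all(df$start < df$end))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, stranded = stranded,
            class = c("annotation_track", "data.frame"))
}

#' Read a BED file as an annotation track
#'
#' BED intervals are already 0-based half-open, matching the internal
#' convention. The BED `name` column (if present) becomes the interval label.
#'
#' @param path BED path (BED3-BED6; gzip accepted).
#' @param name Track name.
#' @param stranded Whether overlap queries should be strand-aware.
#' @return An [annotation_track].
#' @export
read_bed_track <- function(path, name = basename(path), stranded = FALSE) {
  gr <- rtracklayer::import(path, format = "bed")
  annotation_track(
    name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    label = if (!is.null(gr$name)) gr$name else NULL,
    stranded = stranded)
}

#' Read a genome FASTA
#'
#' @param path FASTA path (gzip accepted). Sequence names are truncated at the
#'   first whitespace.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced transcript sequence
#'
#' Concatenates the exonic genome sequence in genomic order and
#' reverse-complements for minus-strand transcripts, yielding the 5'-3'
#' transcript sequence.
#'
#' @param t A `transcript_model`.
#' @param genome A `DNAStringSet` keyed by chromosome name.
#' @return Character scalar (uppercase DNA).
#' @export
transcript_sequence <- function(t, genome) {
  if (!t$chrom %in% names(genome)) {
    stop("transcript ", t$transcript_id, ": chromosome '", t$chrom,
         "' not in genome")
  }
  chr <- genome[[t$chrom]]
  if (t$ends[length(t$ends)] > length(chr)) {
    stop("transcript ", t$transcript_id, ": coordinates exceed contig '",
         t$chrom, "' length ", length(chr))
  }
  pieces <- Biostrings::DNAStringSet(
    lapply(seq_along(t$starts),
           function(i) Biostrings::subseq(chr, t$starts[i] + 1L, t$ends[i])))
  seq <- do.call(Biostrings::xscat, as.list(pieces))
  if (t$strand == "-") seq <- Biostrings::reverseComplement(seq)
  toupper(as.character(seq))
}
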