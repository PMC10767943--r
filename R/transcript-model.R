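#' Construct a transcript model
#'
#' A transcript model is one spliced transcript: an ordered set of exons on a
#' single chromosome and strand, with identity and sample provenance. Exon
#' coordinates use the package-internal 0-based half-open convention; exons
#' are stored in ascending genomic order regardless of strand (transcription
#' order is derived from the strand when needed).
#'
#' @param transcript_id Character scalar, unique transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`. The undetermined strand `"."` is not a valid
#'   transcript strand: antisense/intergenic classification is strand-aware.
#' @param starts,ends Integer vectors of exon starts/ends (0-based half-open),
#'   equal length, pairwise `start < end`, non-overlapping.
#' @param gene_id Optional gene identifier (`NA` if unassigned).
#' @param source_samples Character vector of sample identifiers the model was
#'   observed in (may be empty).
#' @return An object of class `transcript_model`.
#' @examples
#' t1 <- transcript_model("tx1", "chr1", "+", c(100L, 300L), c(200L, 400L))
#' transcript_length(t1)  # 200
#' @export
transcript_model <- function(transcript_id, chrom, strand, starts, ends,
                             gene_id = NA_character_,
                             source_samples = character()) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            length(chrom) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("transcript ", transcript_id, ": strand must be '+' or '-', got '",
         strand, "'")
  }
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("transcript ", transcript_id, ": needs >=1 exon with matching starts/ends")
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts >= ends)) {
    stop("transcript ", transcript_id, ": exon start must be < end (0-based half-open)")
  }
  n <- length(starts)
  if (n > 1L && any(starts[-1L] < ends[-n])) {
    stop("transcript ", transcript_id, ": exons overlap or touch")
  }
  structure(
    list(transcript_id = transcript_id,
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         starts = starts,
         ends = ends,
         source_samples = unique(as.character(source_samples))),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s  %s:%s  %d exon(s), %d bp\n",
              x$transcript_id, x$chrom, x$strand,
              length(x$starts), transcript_length(x)))
  invisible(x)
}

#' Total exonic length of a transcript (bp)
#' @param t A `transcript_model`.
#' @return Integer, sum of exon lengths.
#' @export
transcript_length <- function(t) sum(t$ends - t$starts)

#' Number of exons
#' @param t A `transcript_model`.
#' @export
n_exons <- function(t) length(t$starts)

#' Strand-aware transcription start and termination sites
#'
#' The TSS and TTS are the outer genomic coordinates of the transcript in
#' transcription order: on `+` the TSS is the leftmost coordinate and the TTS
#' the rightmost; on `-` the reverse.
#'
#' @param t A `transcript_model`.
#' @return Named numeric vector `c(tss=, tts=)` of genomic coordinates
#'   (0-based positions of the first/last transcribed base).
#' @export
transcript_ends <- function(t) {
  n <- length(t$starts)
  if (t$strand == "+") {
    c(tss = t$starts[1L], tts = t$ends[n] - 1L)
  } else {
    c(tss = t$ends[n] - 1L, tts = t$starts[1L])
  }
}

#' Intron chain of a transcript
#'
#' Returns the ordered introns (splice junctions) of a spliced transcript in
#' genomic order, in internal 0-based half-open coordinates: each intron spans
#' `[start, end)` between two consecutive exons. Donor and acceptor positions
#' are derived from the strand (donor = 5' side of the intron in transcription
#' orientation). A mono-exonic transcript yields a zero-row chain.
#'
#' @param t A `transcript_model`.
#' @return A data.frame with columns `chrom`, `strand`, `start`, `end`,
#'   `donor`, `acceptor`.
#' @examples
#' t1 <- transcript_model("tx", "chr1", "+", c(100L, 300L, 500L), c(200L, 400L, 600L))
#' intron_chain(t1)  # introns [200,300) and [400,500)
#' @export
intron_chain <- function(t) {
  n <- length(t$starts)
  if (n < 2L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      donor = integer(), acceptor = integer(),
                      stringsAsFactors = FALSE))
  }
  s <- t$ends[-n]; e <- t$starts[-1L]
  if (t$strand == "+") { donor <- s; acceptor <- e } else { donor <- e; acceptor <- s }
  data.frame(chrom = rep(t$chrom, n - 1L), strand = rep(t$strand, n - 1L),
             start = s, end = e, donor = donor, acceptor = acceptor,
             stringsAsFactors = FALSE)
}

#' Intron keys of a transcript
#'
#' Canonical string keys for each intron: `chrom:strand:start-end` in internal
#' coordinates. Keys on opposite strands at identical coordinates are distinct
#' junctions. Used for junction-evidence lookup and intron-chain comparison.
#'
#' @param t A `transcript_model`.
#' @return Character vector of length `n_exons(t) - 1` (empty if mono-exonic).
#' @export
intron_keys <- function(t) {
  n <- length(t$starts)
  if (n < 2L) return(character())
  sprintf("%s:%s:%d-%d", t$chrom, t$strand, t$ends[-n], t$starts[-1L])
}

#' Splice-site keys of a transcript
#'
#' One key per donor/acceptor position: `chrom:strand:pos`. Donors and
#' acceptors share one positional site space.
#'
#' @param t A `transcript_model`.
#' @return Character vector (empty if mono-exonic).
#' @export
splice_site_keys <- function(t) {
  n <- length(t$starts)
  if (n < 2L) return(character())
  pos <- c(t$ends[-n], t$starts[-1L])
  sprintf("%s:%s:%d", t$chrom, t$strand, pos)
}

chain_key <- function(t) {
  k <- intron_keys(t)
  if (length(k) == 0L) return(NA_character_)
  paste(k, collapse = "|")
}

#' Construct a transcript set
#'
#' @param transcripts A list of `transcript_model` objects (unique ids).
#' @return An object of class `transcript_set`: a named list of transcripts,
#'   preserving input order.
#' @export
transcript_set <- function(transcripts = list()) {
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(transcripts) <- ids
  structure(transcripts, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcript(s)\n", length(x)))
  invisible(x)
}

#' @export
`[.transcript_set` <- function(x, i, ...) {
  transcript_set(unclass(x)[i])
}

#' Summarize a transcript set as a data.frame
#'
#' @param object A `transcript_set`.
#' @param ... Unused.
#' @return data.frame with one row per transcript: id, gene_id, chrom, strand,
#'   span start/end, exon count and length.
#' @method summary transcript_set
#' @export
summary.transcript_set <- function(object, ...) {
  data.frame(
    transcript_id = vapply(object, function(t) t$transcript_id, character(1)),
    gene_id = vapply(object, function(t) t$gene_id, character(1)),
    chrom = vapply(object, function(t) t$chrom, character(1)),
    strand = vapply(object, function(t) t$strand, character(1)),
    start = vapply(object, function(t) t$starts[1L], integer(1)),
    end = vapply(object, function(t) t$ends[length(t$ends)], integer(1)),
    n_exons = vapply(object, n_exons, integer(1)),
    length = vapply(object, transcript_length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# GRanges of all exons of a transcript set, with transcript_id metadata
exons_granges <- function(ts) {
  if (length(ts) == 0L) {
    return(GenomicRanges::GRanges())
  }
  nex <- vapply(ts, n_exons, integer(1))
  GenomicRanges::GRanges(
    seqnames = rep(vapply(ts, function(t) t$chrom, character(1)), nex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(ts, function(t) t$starts)) + 1L,
      end = unlist(lapply(ts, function(t) t$ends))),
    strand = rep(vapply(ts, function(t) t$strand, character(1)), nex),
    transcript_id = rep(names(ts), nex))
}

#' Build a reference index from a transcript set
#'
#' Precomputes the lookup structures classification needs: the set of all
#' reference splice sites, the set of all reference junctions, a map from full
#' intron-chain keys to reference transcript ids, a per-junction map for
#' sub-chain (ISM) search, per-gene spans and per-gene exon unions for locus
#' assignment.
#'
#' @param ts A `transcript_set` whose transcripts carry `gene_id`s.
#' @return An object of class `reference_index`.
#' @export
reference_index <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  gene_ids <- vapply(ts, function(t) t$gene_id, character(1))
  if (any(is.na(gene_ids))) {
    # fall back to transcript-as-gene for unassigned entries
    gene_ids[is.na(gene_ids)] <- names(ts)[is.na(gene_ids)]
  }
  site_set <- unique(unlist(lapply(ts, splice_site_keys), use.names = FALSE))
  junc_set <- unique(unlist(lapply(ts, intron_keys), use.names = FALSE))
  chains <- vapply(ts, chain_key, character(1))
  spliced <- !is.na(chains)
  chain_map <- split(names(ts)[spliced], chains[spliced])
  # junction -> data.frame(ref_id, pos within that ref chain)
  jl <- lapply(which(spliced), function(i) {
    k <- intron_keys(ts[[i]])
    data.frame(ref_id = names(ts)[i], pos = seq_along(k), key = k,
               stringsAsFactors = FALSE)
  })
  jtab <- if (length(jl)) do.call(rbind, jl) else
    data.frame(ref_id = character(), pos = integer(), key = character())
  junction_index <- split(jtab[c("ref_id", "pos")], jtab$key)

  # gene spans and per-gene exon unions
  chroms <- vapply(ts, function(t) t$chrom, character(1))
  strands <- vapply(ts, function(t) t$strand, character(1))
  gstart <- tapply(vapply(ts, function(t) t$starts[1L], integer(1)), gene_ids, min)
  gend <- tapply(vapply(ts, function(t) t$ends[n_exons(t)], integer(1)), gene_ids, max)
  gchrom <- tapply(chroms, gene_ids, function(x) x[1L])
  gstrand <- tapply(strands, gene_ids, function(x) x[1L])
  genes <- data.frame(gene_id = names(gstart),
                      chrom = as.character(gchrom[names(gstart)]),
                      strand = as.character(gstrand[names(gstart)]),
                      start = as.integer(gstart),
                      end = as.integer(gend[names(gstart)]),
                      row.names = NULL, stringsAsFactors = FALSE)
  exg <- exons_granges(ts)
  exg$gene_id <- rep(gene_ids, vapply(ts, n_exons, integer(1)))
  exon_gr <- GenomicRanges::reduce(S4Vectors::split(exg, exg$gene_id))
  gene_span_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, gene_id = genes$gene_id)

  structure(
    list(transcripts = ts,
         gene_of = setNames(gene_ids, names(ts)),
         genes = genes,
         splice_sites = site_set,
         junctions = junc_set,
         chain_map = chain_map,
         junction_index = junction_index,
         gene_exons = exon_gr,        # GRangesList by gene_id, reduced
         gene_spans = gene_span_gr),
    class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d transcripts, %d genes, %d splice sites, %d junctions\n",
              length(x$transcripts), nrow(x$genes),
              length(x$splice_sites), length(x$junctions)))
  invisible(x)
}
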