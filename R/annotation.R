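#' Map a transcript-coordinate interval to genomic blocks
#'
#' Transcript coordinates are 0-based half-open along the spliced 5'-3'
#' sequence. The interval is projected onto the genome through the exon
#' structure, yielding one block per exon touched, in genomic order.
#'
#' @param t A `transcript_model`.
#' @param t_start,t_end Interval in transcript coordinates.
#' @return data.frame `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
transcript_to_genomic <- function(t, t_start, t_end) {
  total <- transcript_length(t)
  stopifnot(t_start >= 0L, t_end <= total, t_start < t_end)
  widths <- t$ends - t$starts
  n <- length(widths)
  # exon order in transcription direction
  ord <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
  offs <- cumsum(c(0L, widths[ord]))[seq_len(n)]
  blocks <- list()
  for (k in seq_len(n)) {
    i <- ord[k]
    lo <- max(t_start, offs[k]); hi <- min(t_end, offs[k] + widths[i])
    if (lo >= hi) next
    if (t$strand == "+") {
      gs <- t$starts[i] + (lo - offs[k]); ge <- t$starts[i] + (hi - offs[k])
    } else {
      ge <- t$ends[i] - (lo - offs[k]); gs <- t$ends[i] - (hi - offs[k])
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(chrom = t$chrom, start = gs, end = ge, strand = t$strand,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# longest ATG..stop ORF in the 3 forward frames of `seq` (character DNA).
# Returns list(start, end) in 0-based half-open nt coords (end incl. stop),
# or NULL. Ties: 5'-most start wins.
find_longest_orf <- function(seq, min_len_nt = 300L) {
  L <- nchar(seq)
  best <- NULL
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 2L) next
    cod <- substring(seq, f + 1L + 3L * (seq_len(ncod) - 1L),
                     f + 3L * seq_len(ncod))
    is_stop <- cod %in% STOP_CODONS
    is_atg <- cod == "ATG"
    prev_stop <- 0L  # codon index of the last stop seen
    for (s in which(is_stop)) {
      atgs <- which(is_atg[(prev_stop + 1L):(s - 1L)])
      if (length(atgs)) {
        a <- prev_stop + atgs[1L]
        len <- 3L * (s - a + 1L)
        start_nt <- f + 3L * (a - 1L)
        if (len >= min_len_nt &&
            (is.null(best) || len > best$len ||
               (len == best$len && start_nt < best$start))) {
          best <- list(start = start_nt, end = start_nt + len, len = len)
        }
      }
      prev_stop <- s
    }
  }
  if (is.null(best)) NULL else best[c("start", "end")]
}

#' Predict the ORF of a transcript
#'
#' Finds the longest open reading frame (ATG to TAA/TAG/TGA, inclusive of the
#' stop codon) of at least `min_len_nt` nucleotides in the three forward
#' frames of the spliced transcript sequence. Ties on length are resolved
#' toward the 5'-most start. External ORF calls (e.g. from a dedicated gene
#' predictor) can be used in place of this built-in finder anywhere an ORF
#' object is accepted: construct one with [orf_record].
#'
#' @param t A `transcript_model`.
#' @param genome A `DNAStringSet` (see [read_genome]).
#' @param min_len_nt Minimum ORF length in nt, stop included (default 300).
#' @return An `orf_record` or `NULL` when no qualifying ORF exists.
#' @export
predict_orf <- function(t, genome, min_len_nt = 300L) {
  seq <- transcript_sequence(t, genome)
  hit <- find_longest_orf(seq, min_len_nt)
  if (is.null(hit)) return(NULL)
  orf_record(t, hit$start, hit$end)
}

#' Construct an ORF record in transcript coordinates
#'
#' @param t The host `transcript_model`.
#' @param t_start,t_end ORF span in 0-based half-open transcript coordinates;
#'   `t_end` includes the stop codon; length must be divisible by 3.
#' @return Object of class `orf_record`: transcript id, transcript-coordinate
#'   span, genomic blocks, protein length (aa, stop excluded).
#' @export
orf_record <- function(t, t_start, t_end) {
  len <- t_end - t_start
  stopifnot(len > 0L, len %% 3L == 0L)
  structure(list(transcript_id = t$transcript_id,
                 t_start = as.integer(t_start), t_end = as.integer(t_end),
                 blocks = transcript_to_genomic(t, t_start, t_end),
                 protein_length = as.integer(len %/% 3L - 1L)),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("<orf_record> %s [%d,%d) %d aa\n", x$transcript_id,
              x$t_start, x$t_end, x$protein_length))
  invisible(x)
}

#' Predict nonsense-mediated decay (50-nt rule)
#'
#' A coding transcript is predicted to elicit NMD when its stop codon lies
#' strictly more than 50 nt upstream of the last exon-exon junction: the
#' distance `junction_position - stop_codon_end` (both in transcript
#' coordinates) must exceed 50. A stop at exactly 50 nt, or in the last exon,
#' is not NMD.
#'
#' @param t A spliced `transcript_model`.
#' @param orf The transcript's `orf_record`.
#' @param min_distance_nt The rule's threshold (default 50, strict).
#' @return Logical scalar.
#' @export
predict_nmd <- function(t, orf, min_distance_nt = 50L) {
  if (is.null(orf)) stop("predict_nmd requires a coding transcript (ORF present)")
  n <- n_exons(t)
  if (n < 2L) stop("predict_nmd requires a spliced transcript")
  widths <- t$ends - t$starts
  last_exon_len <- if (t$strand == "+") widths[n] else widths[1L]
  junction_pos <- transcript_length(t) - last_exon_len
  (junction_pos - orf$t_end) > min_distance_nt
}

#' Test overlap of a transcript end with an annotation track
#'
#' The strand-aware anchor (TSS or TTS) is dilated by `window` bp on each
#' side (closed window: a feature ending exactly `window` bp away still
#' overlaps) and intersected with the track. For stranded tracks only
#' same-strand intervals are considered.
#'
#' @param t A `transcript_model`.
#' @param track An [annotation_track].
#' @param window Half-width of the window in bp (default 100).
#' @param anchor `"tss"` (default) or `"tts"`.
#' @return Logical scalar with attribute `label`: the overlapping interval's
#'   label (first in genomic order on ties), or `NA`.
#' @export
tss_feature_overlap <- function(t, track, window = 100L,
                                anchor = c("tss", "tts")) {
  anchor <- match.arg(anchor)
  p <- transcript_ends(t)[[anchor]]
  cand <- track[track$chrom == t$chrom, , drop = FALSE]
  if (isTRUE(attr(track, "stranded"))) {
    cand <- cand[cand$strand %in% c(t$strand, "*"), , drop = FALSE]
  }
  # window covers bases [p-window, p+window] inclusive
  hit <- cand$start <= p + window & cand$end > p - window
  if (!any(hit)) return(structure(FALSE, label = NA_character_))
  structure(TRUE, label = cand$label[which(hit)[1L]])
}

#' Scan the transcript 3' end for a polyadenylation motif
#'
#' Searches the last `search_len` nt of the spliced transcript sequence for
#' the 3'-most occurrence of any motif in `motifs` (default the canonical
#' AATAAA and the common variant ATTAAA).
#'
#' @param t A `transcript_model`.
#' @param genome A `DNAStringSet`.
#' @param motifs Character vector of motifs, in priority order for ties at
#'   the same position.
#' @param search_len Number of terminal nt to scan (default 50).
#' @return The motif found, or `NA_character_`.
#' @export
polya_motif_scan <- function(t, genome, motifs = c("AATAAA", "ATTAAA"),
                             search_len = 50L) {
  seq <- transcript_sequence(t, genome)
  tail_seq <- substr(seq, max(1L, nchar(seq) - search_len + 1L), nchar(seq))
  best_pos <- -1L; best <- NA_character_
  for (m in motifs) {
    pos <- gregexpr(m, tail_seq, fixed = TRUE)[[1L]]
    pos <- pos[pos > 0L]
    if (length(pos) && max(pos) > best_pos) {
      best_pos <- max(pos); best <- m
    }
  }
  best
}

#' Annotate a catalog of transcripts with functional features
#'
#' Runs ORF prediction (unless precomputed ORFs are supplied), NMD
#' prediction, TSS overlap with transposable elements and CAGE peaks, TTS
#' overlap with polyA sites, and the polyA-motif scan, producing the
#' per-transcript feature table.
#'
#' @param transcripts A `transcript_set`.
#' @param genome A `DNAStringSet`, or `NULL` to skip sequence-based fields.
#' @param te_track,cage_track,polya_track Optional [annotation_track]s.
#' @param orfs Optional named list of precomputed `orf_record`s (overrides
#'   the built-in finder).
#' @param window TSS/TTS overlap window in bp (default 100).
#' @param min_orf_len_nt Minimum ORF length (default 300).
#' @param motifs PolyA motifs (default AATAAA, ATTAAA).
#' @return List with `table` (data.frame: transcript_id, length, n_exons,
#'   coding, nmd, te_tss, te_label, cage_tss, polya_site, polya_motif,
#'   orf_protein_length) and `orfs` (named list of `orf_record`s).
#' @export
annotate_catalog <- function(transcripts, genome = NULL,
                             te_track = NULL, cage_track = NULL,
                             polya_track = NULL, orfs = NULL,
                             window = 100L, min_orf_len_nt = 300L,
                             motifs = c("AATAAA", "ATTAAA")) {
  ids <- names(transcripts)
  n <- length(ids)
  out <- data.frame(
    transcript_id = ids,
    length = vapply(transcripts, transcript_length, integer(1)),
    n_exons = vapply(transcripts, n_exons, integer(1)),
    coding = rep(FALSE, n), nmd = rep(FALSE, n),
    te_tss = rep(FALSE, n), te_label = rep(NA_character_, n),
    cage_tss = rep(FALSE, n), polya_site = rep(FALSE, n),
    polya_motif = rep(NA_character_, n),
    orf_protein_length = rep(NA_integer_, n),
    row.names = NULL, stringsAsFactors = FALSE)
  orfs_out <- list()
  for (i in seq_len(n)) {
    t <- transcripts[[i]]
    orf <- if (!is.null(orfs)) orfs[[t$transcript_id]]
      else if (!is.null(genome)) predict_orf(t, genome, min_orf_len_nt)
      else NULL
    if (!is.null(orf)) {
      orfs_out[[t$transcript_id]] <- orf
      out$coding[i] <- TRUE
      out$orf_protein_length[i] <- orf$protein_length
      if (n_exons(t) >= 2L) out$nmd[i] <- predict_nmd(t, orf)
    }
    if (!is.null(te_track)) {
      hit <- tss_feature_overlap(t, te_track, window, "tss")
      out$te_tss[i] <- c(hit); out$te_label[i] <- attr(hit, "label")
    }
    if (!is.null(cage_track)) {
      out$cage_tss[i] <- c(tss_feature_overlap(t, cage_track, window, "tss"))
    }
    if (!is.null(polya_track)) {
      out$polya_site[i] <- c(tss_feature_overlap(t, polya_track, window, "tts"))
    }
    if (!is.null(genome)) {
      out$polya_motif[i] <- polya_motif_scan(t, genome, motifs)
    }
  }
  list(table = out, orfs = orfs_out)
}
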