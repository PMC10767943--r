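#' Assign a transcript to a reference locus
#'
#' A transcript is assigned to the same-strand reference gene whose exons
#' share the most exonic bp with the transcript's exons. Ties are broken by
#' larger overlap of the gene span with the transcript span, then by
#' lexicographic gene id, so assignment is deterministic. If no same-strand
#' gene overlaps exonically but an opposite-strand gene span overlaps the
#' transcript span, the transcript is `antisense`; otherwise `intergenic`.
#'
#' @param t A `transcript_model`.
#' @param ref A `reference_index`.
#' @return A list with `status` (`"gene"`, `"antisense"` or `"intergenic"`)
#'   and `gene_id` (`NA` unless status is `"gene"`).
#' @export
assign_locus <- function(t, ref) {
  span_s <- t$starts[1L]; span_e <- t$ends[length(t$ends)]
  genes <- ref$genes
  same <- genes[genes$chrom == t$chrom & genes$strand == t$strand, , drop = FALSE]
  if (nrow(same)) {
    # candidate genes whose span overlaps the transcript span at all
    cand <- same[same$start < span_e & same$end > span_s, , drop = FALSE]
    if (nrow(cand)) {
      exon_bp <- vapply(cand$gene_id, function(g) {
        ge <- ref$gene_exons[[g]]
        gs <- GenomicRanges::start(ge) - 1L; gee <- GenomicRanges::end(ge)
        tot <- 0L
        for (i in seq_along(t$starts)) {
          ov <- pmin(gee, t$ends[i]) - pmax(gs, t$starts[i])
          tot <- tot + sum(ov[ov > 0L])
        }
        tot
      }, numeric(1))
      if (any(exon_bp > 0)) {
        cand <- cand[exon_bp > 0, , drop = FALSE]
        exon_bp <- exon_bp[exon_bp > 0]
        span_bp <- pmin(cand$end, span_e) - pmax(cand$start, span_s)
        o <- order(-exon_bp, -span_bp, cand$gene_id)
        return(list(status = "gene", gene_id = cand$gene_id[o[1L]]))
      }
    }
  }
  opp <- genes[genes$chrom == t$chrom & genes$strand != t$strand &
                 genes$start < span_e & genes$end > span_s, , drop = FALSE]
  if (nrow(opp)) {
    return(list(status = "antisense", gene_id = NA_character_))
  }
  list(status = "intergenic", gene_id = NA_character_)
}

# ISM test: is `keys` a contiguous run inside some reference intron chain
# (and not equal to a full chain)? Returns the matched reference id or NA.
match_subchain <- function(keys, ref) {
  hits <- ref$junction_index[[keys[1L]]]
  if (is.null(hits)) return(NA_character_)
  m <- length(keys)
  for (j in seq_len(nrow(hits))) {
    rid <- hits$ref_id[j]; pos <- hits$pos[j]
    rk <- intron_keys(ref$transcripts[[rid]])
    # proper contiguous sub-chain; full-chain equality is handled upstream (FSM)
    if (m < length(rk) && pos + m - 1L <= length(rk) &&
        identical(rk[pos:(pos + m - 1L)], keys)) {
      return(rid)
    }
  }
  NA_character_
}

#' Classify one spliced transcript against the reference
#'
#' Decision cascade: (1) full intron chain equals a reference chain: FSM;
#' (2) chain is a contiguous sub-chain of a reference chain: ISM; (3) locus
#' assignment is antisense or intergenic: that category; (4) every donor and
#' acceptor position is a known reference splice site: NIC, reporting the
#' junctions absent from the reference; (5) otherwise NNC, reporting the
#' novel splice sites.
#'
#' @param t A spliced (>= 2 exon) `transcript_model`.
#' @param ref A `reference_index`.
#' @return A one-row data.frame: `transcript_id`, `category`, `assigned_gene`,
#'   `matched_reference_transcript`, `n_novel_sites`, `n_novel_junctions`,
#'   with the novel site/junction keys in attributes `novel_sites` and
#'   `novel_junctions`.
#' @export
classify_transcript <- function(t, ref) {
  if (n_exons(t) < 2L) {
    stop("classify_transcript requires a spliced transcript; ",
         t$transcript_id, " is mono-exonic")
  }
  keys <- intron_keys(t)
  ck <- paste(keys, collapse = "|")
  res <- list(transcript_id = t$transcript_id, category = NA_character_,
              assigned_gene = NA_character_,
              matched_reference_transcript = NA_character_,
              novel_sites = character(), novel_junctions = character())

  fsm <- ref$chain_map[[ck]]
  if (!is.null(fsm)) {
    res$category <- "FSM"
    res$matched_reference_transcript <- sort(fsm)[1L]
    res$assigned_gene <- unname(ref$gene_of[res$matched_reference_transcript])
  } else {
    ism <- match_subchain(keys, ref)
    if (!is.na(ism)) {
      res$category <- "ISM"
      res$matched_reference_transcript <- ism
      res$assigned_gene <- unname(ref$gene_of[ism])
    } else {
      loc <- assign_locus(t, ref)
      if (loc$status != "gene") {
        res$category <- loc$status
      } else {
        res$assigned_gene <- loc$gene_id
        sites <- splice_site_keys(t)
        novel_sites <- setdiff(sites, ref$splice_sites)
        if (length(novel_sites) == 0L) {
          res$category <- "NIC"
          res$novel_junctions <- setdiff(keys, ref$junctions)
        } else {
          res$category <- "NNC"
          res$novel_sites <- novel_sites
          res$novel_junctions <- setdiff(keys, ref$junctions)
        }
      }
    }
  }
  out <- data.frame(transcript_id = res$transcript_id,
                    category = res$category,
                    assigned_gene = res$assigned_gene,
                    matched_reference_transcript = res$matched_reference_transcript,
                    n_novel_sites = length(res$novel_sites),
                    n_novel_junctions = length(res$novel_junctions),
                    stringsAsFactors = FALSE)
  attr(out, "novel_sites") <- res$novel_sites
  attr(out, "novel_junctions") <- res$novel_junctions
  out
}

#' Classify every transcript of a set
#'
#' @param transcripts A `transcript_set` of spliced transcripts.
#' @param ref A `reference_index`.
#' @return data.frame with one row per transcript (input order), columns as in
#'   [classify_transcript].
#' @export
classify_transcripts <- function(transcripts, ref) {
  rows <- lapply(transcripts, classify_transcript, ref = ref)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), category = character(),
                      assigned_gene = character(),
                      matched_reference_transcript = character(),
                      n_novel_sites = integer(), n_novel_junctions = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Classify a transcript set and remove ISM truncation artifacts
#'
#' Every transcript is classified; ISM transcripts (truncations attributable
#' to RNA degradation or incomplete reverse transcription) are removed from
#' the catalog but counted in the tally. The remaining five categories (FSM,
#' NIC, NNC, antisense, intergenic) are retained.
#'
#' @param transcripts A `transcript_set` of spliced transcripts.
#' @param ref A `reference_index`.
#' @return List with `transcripts` (ISM-pruned set, input order),
#'   `classification` (full table including ISM rows) and `tally` (named
#'   integer vector over all six categories).
#' @export
classify_and_prune <- function(transcripts, ref) {
  cls <- classify_transcripts(transcripts, ref)
  cats <- c("FSM", "ISM", "NIC", "NNC", "antisense", "intergenic")
  tally <- setNames(integer(length(cats)), cats)
  tb <- table(cls$category)
  tally[names(tb)] <- as.integer(tb)
  keep <- cls$transcript_id[cls$category != "ISM"]
  list(transcripts = transcripts[keep], classification = cls, tally = tally)
}
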