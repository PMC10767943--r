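#' Read transcript models from GTF
#'
#' Parses exon features of one or more GTF files (Ensembl/GENCODE attribute
#' dialect, optionally gzip-compressed) into a [transcript_set] or, for
#' reference mode, a fully indexed [reference_index]. GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' Transcripts on the undetermined strand `"."` are rejected with a warning
#' (their count is attached as attribute `n_rejected_unstranded`). An exon
#' strand conflict within one transcript is an error. In query mode a
#' transcript_id seen in more than one input file is suffixed with an
#' occurrence index (`id.2`, `id.3`, ...) and reported.
#'
#' @param path Character vector of GTF paths (reference mode accepts one).
#' @param kind `"query"` (default) or `"reference"`.
#' @return A `transcript_set` (query) or `reference_index` (reference).
#' @export
read_gtf <- function(path, kind = c("query", "reference")) {
  kind <- match.arg(kind)
  if (kind == "reference" && length(path) != 1L) {
    stop("reference mode takes a single GTF path")
  }
  all_tx <- list()
  n_unstranded <- 0L
  for (p in path) {
    gr <- rtracklayer::import(p, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon features in ", p)
    tid <- gr$transcript_id
    if (is.null(tid) || anyNA(tid)) {
      bad <- if (is.null(tid)) 1L else which(is.na(tid))[1L]
      stop("GTF parse error in ", p, ": exon feature ", bad,
           " has no transcript_id attribute")
    }
    gid <- if (!is.null(gr$gene_id)) gr$gene_id else rep(NA_character_, length(gr))
    src <- if (!is.null(gr$source_samples)) gr$source_samples else
      rep(NA_character_, length(gr))
    st <- as.character(GenomicRanges::strand(gr))
    starts <- GenomicRanges::start(gr) - 1L
    ends <- GenomicRanges::end(gr)
    chroms <- as.character(GenomicRanges::seqnames(gr))
    for (id in unique(tid)) {
      i <- which(tid == id)
      ustrand <- unique(st[i])
      if (length(ustrand) > 1L) {
        stop("transcript ", id, " in ", p, " has conflicting exon strands")
      }
      if (ustrand == "*") {
        n_unstranded <- n_unstranded + 1L
        next
      }
      samples <- src[i][!is.na(src[i])]
      samples <- unique(unlist(strsplit(samples, ",", fixed = TRUE)))
      tx <- transcript_model(id, chroms[i[1L]], ustrand,
                             starts[i], ends[i],
                             gene_id = gid[i[1L]],
                             source_samples = samples)
      if (!is.null(all_tx[[id]])) {
        k <- 2L
        while (!is.null(all_tx[[paste0(id, ".", k)]])) k <- k + 1L
        tx$transcript_id <- paste0(id, ".", k)
        message("duplicate transcript_id '", id, "' renamed to '",
                tx$transcript_id, "'")
        all_tx[[tx$transcript_id]] <- tx
      } else {
        all_tx[[id]] <- tx
      }
    }
  }
  if (n_unstranded > 0L) {
    warning(n_unstranded, " transcript(s) on strand '.' rejected")
  }
  ts <- transcript_set(all_tx)
  attr(ts, "n_rejected_unstranded") <- n_unstranded
  if (kind == "reference") reference_index(ts) else ts
}

gtf_attr <- function(key, value) sprintf('%s "%s";', key, value)

#' Write a transcript set (or curated catalog) to GTF
#'
#' Emits one `transcript` feature plus one `exon` feature per exon, converting
#' internal 0-based half-open coordinates back to 1-based inclusive GTF.
#' Per-transcript curation attributes (structural category, coding and NMD
#' flags, TE/CAGE/polyA flags) are written when an annotation table is
#' supplied, so the emitted file round-trips through [read_gtf].
#'
#' @param x A `transcript_set` or `curated_catalog`.
#' @param path Output path.
#' @param annotations Optional data.frame keyed by `transcript_id` with any of
#'   the columns `category`, `coding`, `nmd`, `te_tss`, `te_label`,
#'   `cage_tss`, `polya_site`, `polya_motif`. For a `curated_catalog` these
#'   are filled from the catalog itself.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(x, path, annotations = NULL) {
  if (inherits(x, "curated_catalog")) {
    if (is.null(annotations)) annotations <- x$annotation
    x <- x$transcripts
  }
  stopifnot(inherits(x, "transcript_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## isocurate curated transcript models", con)
  if (length(x) == 0L) return(invisible(path))
  ann_row <- function(id) {
    if (is.null(annotations)) return(NULL)
    i <- match(id, annotations$transcript_id)
    if (is.na(i)) NULL else annotations[i, , drop = FALSE]
  }
  lines <- character()
  for (t in x) {
    attrs <- c(gtf_attr("gene_id", ifelse(is.na(t$gene_id), "NA", t$gene_id)),
               gtf_attr("transcript_id", t$transcript_id))
    if (length(t$source_samples)) {
      attrs <- c(attrs, gtf_attr("source_samples",
                                 paste(t$source_samples, collapse = ",")))
    }
    a <- ann_row(t$transcript_id)
    if (!is.null(a)) {
      for (f in intersect(c("category", "coding", "nmd", "te_tss", "te_label",
                            "cage_tss", "polya_site", "polya_motif"),
                          names(a))) {
        v <- a[[f]]
        if (!is.na(v)) attrs <- c(attrs, gtf_attr(f, as.character(v)))
      }
    }
    astr <- paste(attrs, collapse = " ")
    n <- length(t$starts)
    lines <- c(lines,
               sprintf("%s\tisocurate\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       t$chrom, t$starts[1L] + 1L, t$ends[n], t$strand, astr),
               sprintf("%s\tisocurate\texon\t%d\t%d\t.\t%s\t.\t%s",
                       t$chrom, t$starts + 1L, t$ends, t$strand, astr))
  }
  writeLines(lines, con)
  invisible(path)
}
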