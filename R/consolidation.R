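#' Consolidation tolerances
#'
#' Two isoforms are "comparable" (near-duplicates eligible for merging) when
#' their structures differ only within these tolerances: at most
#' `max_exonic_variations` exons may have any internal-boundary shift, each
#' exon's summed internal-boundary shift is capped at `max_bp_per_exon`, the
#' transcription start and termination sites may each differ by at most
#' `max_end_dissimilarity` bp, and coding transcripts must carry identical
#' predicted ORFs.
#'
#' @param max_exonic_variations Maximum number of exons with any boundary
#'   shift (default 3).
#' @param max_bp_per_exon Maximum shift in bp per exon (default 4). By
#'   default the cap applies to the sum of both internal boundaries of the
#'   exon; set `per_boundary = TRUE` to cap each boundary independently.
#' @param max_end_dissimilarity Maximum TSS and TTS displacement in bp
#'   (default 100).
#' @param require_identical_orf Require identical ORF genomic coordinates
#'   when both transcripts are coding (default TRUE).
#' @param per_boundary Apply `max_bp_per_exon` per boundary instead of per
#'   exon sum.
#' @return A `consolidation_params` list.
#' @export
consolidation_params <- function(max_exonic_variations = 3L,
                                 max_bp_per_exon = 4L,
                                 max_end_dissimilarity = 100L,
                                 require_identical_orf = TRUE,
                                 per_boundary = FALSE) {
  stopifnot(max_exonic_variations >= 0L, max_bp_per_exon >= 0L,
            max_end_dissimilarity >= 0L)
  structure(list(max_exonic_variations = as.integer(max_exonic_variations),
                 max_bp_per_exon = as.integer(max_bp_per_exon),
                 max_end_dissimilarity = as.integer(max_end_dissimilarity),
                 require_identical_orf = isTRUE(require_identical_orf),
                 per_boundary = isTRUE(per_boundary)),
            class = "consolidation_params")
}

orf_coords_equal <- function(orf_a, orf_b) {
  identical(orf_a$blocks$chrom, orf_b$blocks$chrom) &&
    identical(orf_a$blocks$start, orf_b$blocks$start) &&
    identical(orf_a$blocks$end, orf_b$blocks$end) &&
    identical(orf_a$blocks$strand, orf_b$blocks$strand)
}

#' Test whether two isoforms are comparable
#'
#' Evaluates the tolerance clauses in order — locus, exon count, per-exon bp
#' cap, exonic-variation count, end dissimilarity, ORF identity — and reports
#' the first failure.
#'
#' @param a,b `transcript_model`s.
#' @param params A [consolidation_params].
#' @param orf_a,orf_b Predicted ORFs of `a` and `b` (objects from
#'   [predict_orf], or `NULL` for non-coding).
#' @return Logical scalar with attribute `reason`: `"ok"` when comparable,
#'   otherwise one of `"locus"`, `"exon count"`, `"bp per exon"`,
#'   `"exonic variations"`, `"end dissimilarity"`, `"orf"`.
#' @export
comparable_isoforms <- function(a, b, params = consolidation_params(),
                                orf_a = NULL, orf_b = NULL) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (a$chrom != b$chrom || a$strand != b$strand) return(fail("locus"))
  n <- length(a$starts)
  if (n != length(b$starts)) return(fail("exon count"))
  if (n < 2L) return(fail("unspliced"))  # consolidation is defined on spliced models
  # internal boundaries: start of exons 2..n, end of exons 1..(n-1)
  ds <- abs(a$starts - b$starts); de <- abs(a$ends - b$ends)
  int_start <- ds; int_start[1L] <- 0L
  int_end <- de; int_end[n] <- 0L
  if (params$per_boundary) {
    over <- (int_start > params$max_bp_per_exon) |
      (int_end > params$max_bp_per_exon)
  } else {
    over <- (int_start + int_end) > params$max_bp_per_exon
  }
  if (any(over)) return(fail("bp per exon"))
  n_var <- sum((int_start + int_end) > 0L)
  if (n_var > params$max_exonic_variations) return(fail("exonic variations"))
  ea <- transcript_ends(a); eb <- transcript_ends(b)
  if (abs(ea["tss"] - eb["tss"]) > params$max_end_dissimilarity ||
      abs(ea["tts"] - eb["tts"]) > params$max_end_dissimilarity) {
    return(fail("end dissimilarity"))
  }
  if (params$require_identical_orf && !is.null(orf_a) && !is.null(orf_b) &&
      !orf_coords_equal(orf_a, orf_b)) {
    return(fail("orf"))
  }
  structure(TRUE, reason = "ok")
}

#' Consolidate comparable isoforms, keeping the longest representative
#'
#' Greedy clustering: candidates are sorted by decreasing exonic length
#' (ties: smaller genomic start, then lexicographic transcript id); the first
#' unassigned transcript seeds a group and absorbs every remaining transcript
#' comparable to it. The seed — the longest member by construction — is the
#' representative, and the merged model inherits the union of all members'
#' source samples. When `bins` is supplied (e.g. paste of assigned locus and
#' structural category), clustering runs independently within each bin so
#' that structurally unrelated categories are never merged.
#'
#' @param transcripts A `transcript_set`.
#' @param params A [consolidation_params].
#' @param orfs Named list of ORFs ([predict_orf] results) keyed by
#'   transcript id; missing/`NULL` entries mean non-coding.
#' @param bins Optional named character vector (transcript id -> bin label).
#' @return List with `transcripts` (representatives, ordered by the greedy
#'   sort key) and `groups`, a data.frame (`representative`, `members`
#'   comma-joined, `n_members`).
#' @export
consolidate_isoforms <- function(transcripts, params = consolidation_params(),
                                 orfs = list(), bins = NULL) {
  stopifnot(inherits(transcripts, "transcript_set"))
  ids <- names(transcripts)
  if (length(ids) == 0L) {
    return(list(transcripts = transcripts,
                groups = data.frame(representative = character(),
                                    members = character(),
                                    n_members = integer(),
                                    stringsAsFactors = FALSE)))
  }
  lens <- vapply(transcripts, transcript_length, integer(1))
  starts <- vapply(transcripts, function(t) t$starts[1L], integer(1))
  o <- order(-lens, starts, ids)
  ordered_ids <- ids[o]
  bin_of <- if (is.null(bins)) setNames(rep("", length(ids)), ids) else bins
  assigned <- setNames(rep(FALSE, length(ids)), ids)
  reps <- character(); members_l <- list()
  for (seed in ordered_ids) {
    if (assigned[seed]) next
    assigned[seed] <- TRUE
    grp <- seed
    for (cand in ordered_ids) {
      if (assigned[cand] || bin_of[cand] != bin_of[seed]) next
      cmp <- comparable_isoforms(transcripts[[seed]], transcripts[[cand]],
                                 params,
                                 orf_a = orfs[[seed]], orf_b = orfs[[cand]])
      if (isTRUE(c(cmp))) {
        assigned[cand] <- TRUE
        grp <- c(grp, cand)
      }
    }
    reps <- c(reps, seed)
    members_l[[seed]] <- grp
  }
  merged <- lapply(reps, function(r) {
    t <- transcripts[[r]]
    t$source_samples <- sort(unique(unlist(
      lapply(members_l[[r]], function(m) transcripts[[m]]$source_samples))))
    t
  })
  list(transcripts = transcript_set(merged),
       groups = data.frame(
         representative = reps,
         members = vapply(members_l[reps], paste, character(1), collapse = ","),
         n_members = vapply(members_l[reps], length, integer(1)),
         row.names = NULL, stringsAsFactors = FALSE))
}
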