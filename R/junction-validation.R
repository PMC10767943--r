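#' Validation parameters for the junction-support filter
#'
#' @param min_samples Minimum number of distinct samples that must support
#'   every splice junction of a transcript for it to be retained (default 5).
#' @param min_unique_reads Per-sample unique-read threshold for a junction to
#'   count as detected in a sample (default 1; applied when aggregating
#'   evidence).
#' @return A `validation_params` list.
#' @export
validation_params <- function(min_samples = 5L, min_unique_reads = 1L) {
  stopifnot(min_samples >= 1L, min_unique_reads >= 0L)
  structure(list(min_samples = as.integer(min_samples),
                 min_unique_reads = as.integer(min_unique_reads)),
            class = "validation_params")
}

#' Filter transcripts by short-read junction support
#'
#' A spliced transcript is retained if and only if every intron in its chain
#' is supported by at least `min_samples` distinct samples in the evidence
#' set. Mono-exonic transcripts are dropped (reason `"unspliced"`) unless
#' `keep_monoexonic = TRUE`: the curated catalog is restricted to spliced
#' isoforms, and the junction criterion is vacuous for unspliced models.
#'
#' @param transcripts A `transcript_set`.
#' @param evidence A `junction_evidence`.
#' @param params A [validation_params] object.
#' @param keep_monoexonic Pass mono-exonic transcripts through untouched.
#' @return A list with `transcripts` (the kept `transcript_set`, in input
#'   order) and `report`, a `validation_report` holding `kept` ids, a
#'   `dropped` data.frame (`transcript_id`, `reason`, `failing_junctions`)
#'   and the per-junction aggregate counts consulted.
#' @export
filter_by_junction_support <- function(transcripts, evidence,
                                       params = validation_params(),
                                       keep_monoexonic = FALSE) {
  stopifnot(inherits(transcripts, "transcript_set"),
            inherits(evidence, "junction_evidence"))
  if (evidence$min_unique_reads != params$min_unique_reads) {
    evidence <- junction_evidence(evidence$per_sample,
                                  min_unique_reads = params$min_unique_reads)
  }
  any_spliced <- any(vapply(transcripts, n_exons, integer(1)) > 1L)
  if (length(evidence$aggregate) == 0L && any_spliced) {
    warning("empty junction evidence: all spliced transcripts will be dropped")
  }
  kept <- character()
  dropped_id <- character(); dropped_reason <- character()
  dropped_junc <- character()
  counts_used <- list()
  for (t in transcripts) {
    keys <- intron_keys(t)
    if (length(keys) == 0L) {
      if (keep_monoexonic) {
        kept <- c(kept, t$transcript_id)
      } else {
        dropped_id <- c(dropped_id, t$transcript_id)
        dropped_reason <- c(dropped_reason, "unspliced")
        dropped_junc <- c(dropped_junc, "")
      }
      next
    }
    supp <- junction_support(evidence, keys)
    counts_used[[t$transcript_id]] <- supp
    failing <- keys[supp < params$min_samples]
    if (length(failing) == 0L) {
      kept <- c(kept, t$transcript_id)
    } else {
      dropped_id <- c(dropped_id, t$transcript_id)
      dropped_reason <- c(dropped_reason, "unsupported_junction")
      dropped_junc <- c(dropped_junc, paste(failing, collapse = ","))
    }
  }
  report <- structure(
    list(kept = kept,
         dropped = data.frame(transcript_id = dropped_id,
                              reason = dropped_reason,
                              failing_junctions = dropped_junc,
                              stringsAsFactors = FALSE),
         params = params,
         junction_counts = counts_used),
    class = "validation_report")
  list(transcripts = transcripts[kept], report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> kept %d, dropped %d (min_samples=%d)\n",
              length(x$kept), nrow(x$dropped), x$params$min_samples))
  invisible(x)
}

#' Write a validation report as TSV plus a JSON summary
#'
#' @param report A `validation_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_validation_report <- function(report, tsv_path = NULL, json_path = NULL) {
  tab <- rbind(
    data.frame(transcript_id = report$kept, status = "kept",
               failing_junctions = "", stringsAsFactors = FALSE),
    data.frame(transcript_id = report$dropped$transcript_id,
               status = paste0("dropped:", report$dropped$reason),
               failing_junctions = report$dropped$failing_junctions,
               stringsAsFactors = FALSE))
  if (!is.null(tsv_path)) {
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(n_in = length(report$kept) + nrow(report$dropped),
                  n_kept = length(report$kept),
                  n_dropped = nrow(report$dropped))
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(summary)
}
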