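#' Expression ratios of a transcript across tissue types
#'
#' `p_i = x_i / sum(x)`: the fraction of a transcript's total expression
#' contributed by each tissue type. An all-zero profile returns all-zero
#' ratios flagged `unexpressed` (such transcripts are excluded from
#' specificity scoring rather than given a fake score).
#'
#' @param x Non-negative numeric vector of expression values (one per tissue
#'   type, length >= 2).
#' @return Numeric vector summing to 1 (or all zeros, with attribute
#'   `unexpressed = TRUE`).
#' @export
expression_ratios <- function(x) {
  if (any(is.na(x)) || any(x < 0)) stop("expression values must be non-negative")
  if (length(x) < 2L) stop("need at least two tissue types")
  s <- sum(x)
  if (s == 0) return(structure(x * 0, unexpressed = TRUE))
  x / s
}

#' Entropy-based specificity score
#'
#' `S = log2(N) - H(p)` where `H` is the Shannon entropy (bits) of the
#' expression-ratio vector `p` over `N` tissue types. Terms with `p_i = 0`
#' contribute zero. The score ranges from 0 (uniform expression) to
#' `log2(N)` (expression confined to a single tissue type).
#'
#' @param p Expression-ratio vector (must sum to 1 within `1e-9`).
#' @param N Number of tissue types (default `length(p)`).
#' @return Numeric scalar in `[0, log2(N)]`.
#' @export
specificity_score <- function(p, N = length(p)) {
  if (abs(sum(p) - 1) > 1e-9) stop("ratios must sum to 1 (got ", sum(p), ")")
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  log2(N) - entropy
}

#' Aggregate an expression matrix by sample group
#'
#' Collapses sample columns to one column per group label using the given
#' statistic (default median), e.g. samples to tissue types before
#' specificity scoring.
#'
#' @param mat Numeric matrix, transcripts x samples.
#' @param groups Character vector of group labels, one per column.
#' @param fun Aggregation statistic (default [stats::median]).
#' @return Matrix transcripts x groups (columns in sorted group order).
#' @export
aggregate_by_group <- function(mat, groups, fun = stats::median) {
  stopifnot(ncol(mat) == length(groups))
  levels <- sort(unique(groups))
  out <- vapply(levels, function(g) {
    apply(mat[, groups == g, drop = FALSE], 1L, fun)
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(mat), levels))
  out
}

#' Call tissue-specific transcripts
#'
#' For each transcript the expression-ratio vector and specificity score are
#' computed over tissue types; a transcript is tissue-specific when the
#' largest ratio exceeds twice the second largest AND the specificity score
#' exceeds 1. When the second-largest ratio is zero and the largest is
#' positive the ratio condition passes. Input must carry one value per
#' (transcript, tissue type): aggregate per-sample matrices with
#' [aggregate_by_group] first.
#'
#' @param tissue_matrix Numeric matrix, transcripts x tissue types (named
#'   rows and columns).
#' @param min_ratio_fold Fold between largest and second-largest ratio
#'   (default 2, strict).
#' @param min_score Specificity-score threshold (default 1, strict).
#' @return data.frame: transcript_id, N, S, top_tissue, p_top, p_second,
#'   unexpressed, is_tissue_srt.
#' @export
call_tissue_srt <- function(tissue_matrix, min_ratio_fold = 2, min_score = 1) {
  N <- ncol(tissue_matrix)
  if (N < 2L) stop("need at least two tissue types")
  ids <- rownames(tissue_matrix)
  res <- lapply(seq_len(nrow(tissue_matrix)), function(i) {
    x <- tissue_matrix[i, ]
    p <- expression_ratios(x)
    if (isTRUE(attr(p, "unexpressed"))) {
      return(data.frame(transcript_id = ids[i], N = N, S = NA_real_,
                        top_tissue = NA_character_, p_top = NA_real_,
                        p_second = NA_real_, unexpressed = TRUE,
                        is_tissue_srt = FALSE, stringsAsFactors = FALSE))
    }
    S <- specificity_score(p, N)
    o <- order(p, decreasing = TRUE)
    p1 <- p[o[1L]]; p2 <- p[o[2L]]
    ratio_ok <- if (p2 == 0) p1 > 0 else p1 > min_ratio_fold * p2
    data.frame(transcript_id = ids[i], N = N, S = S,
               top_tissue = colnames(tissue_matrix)[o[1L]],
               p_top = unname(p1), p_second = unname(p2), unexpressed = FALSE,
               is_tissue_srt = ratio_ok && S > min_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Parameters for tumor-specific transcript calling
#'
#' @param fold Required ratio of tumor median to the maximum normal
#'   expression (default 10; "at least", i.e. `>=`).
#' @param tpm_min TPM floor for counting a tumor sample as expressing the
#'   transcript (default 0.5, strict `>`).
#' @param frac_expressed Required fraction of expressing tumor samples in at
#'   least one cancer type (default 0.05, strict `>`).
#' @param excluded_normals Normal tissue types excluded from the maximum
#'   (default `"testis"`, whose permissive transcription would otherwise mask
#'   tumor-restricted expression).
#' @param aggregate_normals Aggregate normal samples per tissue/group (by
#'   `normal_fun`) before taking the maximum (default TRUE: the criterion is
#'   over normal tissues, not individual samples). Set FALSE to take the max
#'   over raw normal samples.
#' @param normal_fun Per-tissue aggregation statistic (default median).
#' @return A `tumor_srt_params` list.
#' @export
tumor_srt_params <- function(fold = 10, tpm_min = 0.5, frac_expressed = 0.05,
                             excluded_normals = "testis",
                             aggregate_normals = TRUE,
                             normal_fun = stats::median) {
  stopifnot(fold > 1, frac_expressed > 0, frac_expressed < 1)
  structure(list(fold = fold, tpm_min = tpm_min,
                 frac_expressed = frac_expressed,
                 excluded_normals = excluded_normals,
                 aggregate_normals = isTRUE(aggregate_normals),
                 normal_fun = normal_fun),
            class = "tumor_srt_params")
}

#' Call tumor-specific transcripts from expression matrices
#'
#' For each transcript and cancer type `c` two criteria are evaluated:
#' (A) the median TPM over tumor samples of `c` is at least `fold` times the
#' maximum expression over all normal tissues (healthy-cohort tissues minus
#' `excluded_normals`, pooled with adjacent-normal tissues; when that maximum
#' is zero, criterion A requires a positive tumor median); (B) the fraction
#' of tumor samples of `c` with TPM strictly above `tpm_min` strictly exceeds
#' `frac_expressed`. A transcript is a tumor-SRT when some cancer type
#' satisfies both.
#'
#' @param tumor_matrix Transcripts x tumor samples TPM matrix.
#' @param tumor_groups Cancer-type label per tumor column.
#' @param normal_matrix Transcripts x normal samples TPM matrix (healthy
#'   cohort, e.g. GTEx-style, pooled with adjacent normals), sharing row
#'   order with `tumor_matrix`.
#' @param normal_groups Tissue-type label per normal column.
#' @param params A [tumor_srt_params].
#' @return List with `calls` (data.frame of qualifying transcript x
#'   cancer-type pairs: transcript_id, cancer_type, median_tumor, max_normal,
#'   fold, frac_expressed) and `srt_ids` (character vector of tumor-SRT
#'   transcript ids).
#' @export
call_tumor_srt <- function(tumor_matrix, tumor_groups,
                           normal_matrix, normal_groups,
                           params = tumor_srt_params()) {
  stopifnot(nrow(tumor_matrix) == nrow(normal_matrix),
            identical(rownames(tumor_matrix), rownames(normal_matrix)),
            ncol(tumor_matrix) == length(tumor_groups),
            ncol(normal_matrix) == length(normal_groups))
  keep <- !(normal_groups %in% params$excluded_normals)
  nm <- normal_matrix[, keep, drop = FALSE]
  ng <- normal_groups[keep]
  if (ncol(nm) == 0L) stop("no normal columns after exclusions; the fold criterion is undefined")
  if (params$aggregate_normals) {
    nm <- aggregate_by_group(nm, ng, params$normal_fun)
  }
  max_normal <- apply(nm, 1L, max)
  ctypes <- sort(unique(tumor_groups))
  rows <- list()
  for (ct in ctypes) {
    tm <- tumor_matrix[, tumor_groups == ct, drop = FALSE]
    med <- apply(tm, 1L, stats::median)
    frac <- rowMeans(tm > params$tpm_min)
    passA <- ifelse(max_normal == 0, med > 0, med >= params$fold * max_normal)
    passB <- frac > params$frac_expressed
    hit <- which(passA & passB)
    if (length(hit)) {
      rows[[ct]] <- data.frame(
        transcript_id = rownames(tumor_matrix)[hit],
        cancer_type = ct,
        median_tumor = unname(med[hit]),
        max_normal = unname(max_normal[hit]),
        fold = unname(ifelse(max_normal[hit] > 0,
                             med[hit] / max_normal[hit], Inf)),
        frac_expressed = unname(frac[hit]),
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(transcript_id = character(), cancer_type = character(),
                    median_tumor = numeric(), max_normal = numeric(),
                    fold = numeric(), frac_expressed = numeric(),
                    stringsAsFactors = FALSE)
  list(calls = calls, srt_ids = sort(unique(calls$transcript_id)))
}

#' Long-read tumor-specific transcripts by cohort exclusivity
#'
#' The long-read definition of a tumor-specific transcript: present (by
#' source-sample provenance) in tumor samples and in no normal sample.
#'
#' @param transcripts A `transcript_set` whose models carry
#'   `source_samples`.
#' @param sample_cohort Named character vector: sample id -> `"tumor"` or
#'   `"normal"`.
#' @return Character vector of transcript ids found exclusively in tumor
#'   samples.
#' @export
lr_tumor_srt <- function(transcripts, sample_cohort) {
  ids <- names(transcripts)
  hit <- vapply(transcripts, function(t) {
    co <- sample_cohort[t$source_samples]
    length(co) > 0L && all(!is.na(co)) && all(co == "tumor")
  }, logical(1))
  ids[hit]
}

#' Read a TPM matrix and its sample metadata
#'
#' @param tpm_path TSV with a `transcript_id` first column and one column per
#'   sample.
#' @param samples_path TSV with columns `sample_id`, `group`, `cohort`
#'   (cohort in `tumor`, `adjacent_normal`, `normal`).
#' @return List with `tpm` (numeric matrix) and `samples` (data.frame), with
#'   columns matched and ordered as in the metadata.
#' @export
read_expression <- function(tpm_path, samples_path) {
  tpm <- read.table(tpm_path, sep = "\t", header = TRUE, row.names = 1L,
                    check.names = FALSE)
  tpm <- as.matrix(tpm)
  samples <- read.table(samples_path, sep = "\t", header = TRUE,
                        colClasses = "character")
  need <- c("sample_id", "group", "cohort")
  if (!all(need %in% names(samples))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(samples$sample_id, colnames(tpm))
  if (length(missing)) stop("samples absent from TPM matrix: ",
                            paste(head(missing, 5L), collapse = ", "))
  list(tpm = tpm[, samples$sample_id, drop = FALSE], samples = samples)
}
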