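#' Specification of a synthetic fixture
#'
#' Parameters of the deterministic toy-transcriptome generator used to test
#' every pipeline stage against planted truth. Defaults emulate the
#' statistical structure the pipeline assumes at desk scale: multi-exon genes
#' on both strands, every structural category planted by construction,
#' junction support drawn around the 5-sample validation threshold, and
#' expression matrices with tumor- and tissue-specific transcripts planted at
#' a 20-fold effect size under multiplicative log-normal noise.
#'
#' @param seed Integer seed; identical specs produce identical fixtures.
#' @param n_genes Number of reference genes (default 12).
#' @param exons_per_gene Integer range (default 4-8).
#' @param exon_len,intron_len Length ranges in bp.
#' @param planted Named integer vector of per-category query counts (FSM,
#'   ISM, NIC, NNC, antisense, intergenic).
#' @param coding_fraction Fraction of reference transcripts carrying an
#'   embedded ORF in the genome sequence (default 0.5).
#' @param n_sj_samples Number of short-read samples emitting junction tables
#'   (default 8).
#' @param min_support_samples The validation threshold the support
#'   distribution straddles (default 5): supported junctions appear in
#'   `min_support_samples..n_sj_samples` samples, unsupported in fewer.
#' @param frac_unsupported Fraction of query transcripts planted with
#'   insufficient junction support (default 0.25).
#' @param n_cancer_types,n_tumor_per_type,n_adjacent_per_type Tumor cohort
#'   shape (defaults 2 types x 30 tumor + 10 adjacent-normal samples).
#' @param normal_tissues Healthy-cohort tissue names (default 22 tissues
#'   including testis).
#' @param n_per_tissue Samples per healthy tissue (default 5).
#' @param n_tumor_srt,n_tissue_srt Number of planted specific transcripts.
#' @param srt_fold Planted tumor/normal fold (default 20).
#' @param background_tpm,normal_floor_tpm Background and planted-SRT normal
#'   expression levels (defaults 5 and 0.5 TPM).
#' @param noise_sdlog Log-normal noise sigma on TPM (default 0.5; 0 for
#'   noise-free matrices).
#' @param dropout Probability a background measurement is zeroed (default
#'   0.05).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_genes = 12L,
                         exons_per_gene = c(4L, 8L),
                         exon_len = c(80L, 300L),
                         intron_len = c(60L, 400L),
                         planted = c(FSM = 2L, ISM = 2L, NIC = 2L, NNC = 2L,
                                     antisense = 2L, intergenic = 2L),
                         coding_fraction = 0.5,
                         n_sj_samples = 8L,
                         min_support_samples = 5L,
                         frac_unsupported = 0.25,
                         n_cancer_types = 2L,
                         n_tumor_per_type = 30L,
                         n_adjacent_per_type = 10L,
                         normal_tissues = c(
                           "adipose", "adrenal_gland", "bladder", "brain",
                           "breast", "colon", "esophagus", "heart", "kidney",
                           "liver", "lung", "muscle", "nerve", "ovary",
                           "pancreas", "pituitary", "prostate", "skin",
                           "spleen", "stomach", "testis", "thyroid"),
                         n_per_tissue = 5L,
                         n_tumor_srt = 10L,
                         n_tissue_srt = 10L,
                         srt_fold = 20,
                         background_tpm = 5,
                         normal_floor_tpm = 0.5,
                         noise_sdlog = 0.5,
                         dropout = 0.05) {
  plant_names <- c("FSM", "ISM", "NIC", "NNC", "antisense", "intergenic")
  stopifnot(all(names(planted) %in% plant_names), all(planted >= 0L),
            exons_per_gene[1L] >= 4L,
            seed == as.integer(seed))
  full <- setNames(integer(6L), plant_names)
  full[names(planted)] <- as.integer(planted)
  if (n_genes < sum(full[c("FSM", "ISM", "NIC", "NNC")])) {
    stop("chain-derived plants need one distinct gene each: increase n_genes")
  }
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               exons_per_gene = as.integer(exons_per_gene),
               exon_len = as.integer(exon_len),
               intron_len = as.integer(intron_len),
               planted = full, coding_fraction = coding_fraction,
               n_sj_samples = as.integer(n_sj_samples),
               min_support_samples = as.integer(min_support_samples),
               frac_unsupported = frac_unsupported,
               n_cancer_types = as.integer(n_cancer_types),
               n_tumor_per_type = as.integer(n_tumor_per_type),
               n_adjacent_per_type = as.integer(n_adjacent_per_type),
               normal_tissues = normal_tissues,
               n_per_tissue = as.integer(n_per_tissue),
               n_tumor_srt = as.integer(n_tumor_srt),
               n_tissue_srt = as.integer(n_tissue_srt),
               srt_fold = srt_fold, background_tpm = background_tpm,
               normal_floor_tpm = normal_floor_tpm,
               noise_sdlog = noise_sdlog, dropout = dropout)
  structure(spec, class = "fixture_spec")
}

# run expr under a local RNG seeded with `seed`, restoring the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all_cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_cod, c("TAA", "TAG", "TGA"))
}

#' Generate a toy reference: genome plus annotation
#'
#' Lays `n_genes` non-overlapping multi-exon genes (one transcript each,
#' random strand) along a single synthetic chromosome, followed by an empty
#' region reserved for intergenic plants. A `coding_fraction` of reference
#' transcripts have an ORF (ATG, stop-free codons, stop) written into their
#' exonic genome sequence, spanning most of the spliced length.
#'
#' @param spec A [fixture_spec].
#' @return List: `genome` (`DNAStringSet`, one synthetic chromosome),
#'   `reference` (a `transcript_set` with gene ids), `ref_index`
#'   (its [reference_index]), `empty_region` (start/end of the unannotated
#'   tail).
#' @export
make_reference <- function(spec) with_seed(spec$seed, {
  chrom <- "chrS1"
  pos <- 1000L
  txs <- list()
  for (g in seq_len(spec$n_genes)) {
    n_ex <- sample(spec$exons_per_gene[1L]:spec$exons_per_gene[2L], 1L)
    elen <- sample(spec$exon_len[1L]:spec$exon_len[2L], n_ex, replace = TRUE)
    ilen <- sample(spec$intron_len[1L]:spec$intron_len[2L], n_ex - 1L,
                   replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- pos
    for (i in seq_len(n_ex)) {
      starts[i] <- p; ends[i] <- p + elen[i]
      p <- ends[i] + if (i < n_ex) ilen[i] else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("GENE%03d", g)
    txs[[g]] <- transcript_model(sprintf("REF%03d.1", g), chrom, strand,
                                 starts, ends, gene_id = gid)
    pos <- ends[n_ex] + sample(800:2000, 1L)
  }
  empty_start <- pos + 5000L
  genome_len <- empty_start + 30000L
  seq <- random_dna(genome_len)
  # embed ORFs into a fraction of reference transcripts
  n_coding <- round(spec$coding_fraction * spec$n_genes)
  coding_idx <- if (n_coding > 0) sort(sample(spec$n_genes, n_coding)) else integer()
  for (g in coding_idx) {
    t <- txs[[g]]
    L <- transcript_length(t)
    orf_len <- 3L * ((L - 60L) %/% 3L)
    if (orf_len < 300L) next
    n_mid <- orf_len %/% 3L - 2L
    orf_seq <- paste0("ATG",
                      paste(sample(NONSTOP_CODONS, n_mid, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    spliced <- paste0(random_dna(30L), orf_seq,
                      random_dna(L - 30L - orf_len))
    # write spliced sequence back through the exon structure
    genomic <- if (t$strand == "+") spliced else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
    off <- 0L
    for (i in seq_along(t$starts)) {
      w <- t$ends[i] - t$starts[i]
      substr(seq, t$starts[i] + 1L, t$ends[i]) <-
        substr(genomic, off + 1L, off + w)
      off <- off + w
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(seq, chrom))
  ref <- transcript_set(txs)
  list(genome = genome, reference = ref, ref_index = reference_index(ref),
       empty_region = c(start = empty_start, end = genome_len))
})

# build a query transcript of a given planted category from a reference gene
plant_transcript <- function(category, qid, ref_t, empty_region, offset = 0L) {
  s <- ref_t$starts; e <- ref_t$ends; n <- length(s)
  switch(category,
    FSM = {
      # jitter the outer ends inward (chain unchanged)
      s2 <- s; e2 <- e
      s2[1L] <- s[1L] + sample(0:20, 1L)
      e2[n] <- e[n] - sample(0:20, 1L)
      transcript_model(qid, ref_t$chrom, ref_t$strand, s2, e2)
    },
    ISM = {
      # drop the first exon: chain becomes a proper contiguous sub-chain
      transcript_model(qid, ref_t$chrom, ref_t$strand, s[-1L], e[-1L])
    },
    NIC = {
      # skip one internal exon: all sites known, one junction novel
      j <- sample(2:(n - 1L), 1L)
      transcript_model(qid, ref_t$chrom, ref_t$strand, s[-j], e[-j])
    },
    NNC = {
      # shift one donor/acceptor 10 bp into the intron: novel splice site
      j <- sample(seq_len(n - 1L), 1L)
      e2 <- e; e2[j] <- e[j] + 10L
      transcript_model(qid, ref_t$chrom, ref_t$strand, s, e2)
    },
    antisense = {
      strand <- if (ref_t$strand == "+") "-" else "+"
      a <- s[1L] + 10L
      transcript_model(qid, ref_t$chrom, strand,
                       c(a, a + 200L), c(a + 100L, a + 300L))
    },
    intergenic = {
      a <- empty_region[["start"]] + offset
      transcript_model(qid, ref_t$chrom, sample(c("+", "-"), 1L),
                       c(a, a + 250L, a + 600L),
                       c(a + 150L, a + 400L, a + 800L))
    },
    stop("unknown category ", category))
}

#' Generate a query transcript set with planted structural categories
#'
#' Each planted transcript is constructed so that its category is guaranteed
#' by construction (not by running the classifier): FSM copies a reference
#' intron chain, ISM drops a terminal exon, NIC skips an internal exon
#' (recombining known sites into a novel junction), NNC shifts one splice
#' site into an intron, antisense mirrors a gene region to the opposite
#' strand, intergenic lands in the reserved empty region. FSM/ISM/NIC/NNC
#' plants use distinct genes, so every query transcript's intron set is
#' disjoint from every other's. A `frac_unsupported` subset is flagged for
#' the junction-evidence generator to starve of support.
#'
#' @param spec A [fixture_spec].
#' @param reference The [make_reference] result.
#' @return List: `query` (a `transcript_set`) and `truth` (data.frame:
#'   transcript_id, true_category, source_gene, supported).
#' @export
make_query_set <- function(spec, reference) with_seed(spec$seed + 1L, {
  ref <- reference$reference
  cats <- rep(names(spec$planted), spec$planted)
  n_chain <- sum(spec$planted[c("FSM", "ISM", "NIC", "NNC")])
  chain_genes <- sample(length(ref), n_chain)  # distinct genes for chain-derived plants
  other_genes <- sample(length(ref), sum(spec$planted[c("antisense", "intergenic")]),
                        replace = TRUE)
  gi <- 1L; oi <- 1L; inter_off <- 0L
  txs <- list(); truth <- list()
  for (k in seq_along(cats)) {
    cat_k <- cats[k]
    qid <- sprintf("TX%03d", k)
    if (cat_k %in% c("FSM", "ISM", "NIC", "NNC")) {
      ref_t <- ref[[chain_genes[gi]]]; gi <- gi + 1L
    } else {
      ref_t <- ref[[other_genes[oi]]]; oi <- oi + 1L
    }
    t <- plant_transcript(cat_k, qid, ref_t, reference$empty_region,
                          offset = inter_off)
    if (cat_k == "intergenic") inter_off <- inter_off + 2000L
    t$source_samples <- sprintf("LR%02d", sample(6L, sample(2:4, 1L)))
    txs[[k]] <- t
    truth[[k]] <- data.frame(transcript_id = qid, true_category = cat_k,
                             source_gene = if (cat_k %in% c("antisense", "intergenic"))
                               NA_character_ else ref_t$gene_id,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  n_uns <- floor(spec$frac_unsupported * nrow(truth))
  uns <- if (n_uns > 0) sample(nrow(truth), n_uns) else integer()
  truth$supported <- TRUE
  truth$supported[uns] <- FALSE
  list(query = transcript_set(txs), truth = truth)
})

#' Generate per-sample junction-evidence tables with planted support
#'
#' Every intron of a supported query transcript is detected in at least
#' `min_support_samples` of the `n_sj_samples` samples; introns belonging
#' only to unsupported transcripts are detected in fewer. Because planted
#' transcripts use disjoint intron sets, the validation filter's kept/dropped
#' partition equals the planted `supported` flag by construction.
#'
#' @param spec A [fixture_spec].
#' @param query,truth The [make_query_set] outputs.
#' @return List: `evidence` (a `junction_evidence`), `tables` (named list of
#'   SJ.out.tab-dialect data.frames, one per sample).
#' @export
make_junction_evidence <- function(spec, query, truth) with_seed(spec$seed + 2L, {
  nS <- spec$n_sj_samples; minS <- spec$min_support_samples
  supp_ids <- truth$transcript_id[truth$supported]
  supported_keys <- unique(unlist(lapply(query[supp_ids], intron_keys)))
  all_keys <- unique(unlist(lapply(query, intron_keys)))
  unsupported_keys <- setdiff(all_keys, supported_keys)
  n_samples_of <- c(
    setNames(sample(minS:nS, length(supported_keys), replace = TRUE),
             supported_keys),
    setNames(sample(0:(minS - 1L), length(unsupported_keys), replace = TRUE),
             unsupported_keys))
  rows_per_sample <- vector("list", nS)
  for (key in names(n_samples_of)) {
    k <- n_samples_of[[key]]
    if (k == 0L) next
    in_samples <- sample(nS, k)
    m <- regmatches(key, regexec("^(.+):([+-]):(\\d+)-(\\d+)$", key))[[1L]]
    for (s in in_samples) {
      rows_per_sample[[s]][[length(rows_per_sample[[s]]) + 1L]] <- data.frame(
        V1 = m[2L], V2 = as.integer(m[4L]) + 1L, V3 = as.integer(m[5L]),
        V4 = if (m[3L] == "+") 1L else 2L, V5 = 0L, V6 = 0L,
        V7 = sample(1:50, 1L), V8 = 0L, V9 = 20L,
        stringsAsFactors = FALSE)
    }
  }
  tables <- lapply(seq_len(nS), function(s) {
    if (is.null(rows_per_sample[[s]])) {
      data.frame(V1 = character(), V2 = integer(), V3 = integer(),
                 V4 = integer(), V5 = integer(), V6 = integer(),
                 V7 = integer(), V8 = integer(), V9 = integer())
    } else {
      df <- do.call(rbind, rows_per_sample[[s]])
      df[order(df$V1, df$V2, df$V3), , drop = FALSE]
    }
  })
  names(tables) <- sprintf("SR%02d", seq_len(nS))
  per_sample <- lapply(tables, function(df) {
    strand <- ifelse(df$V4 == 1L, "+", "-")
    setNames(as.integer(df$V7),
             sprintf("%s:%s:%d-%d", df$V1, strand, df$V2 - 1L, df$V3))
  })
  list(evidence = junction_evidence(per_sample), tables = tables)
})

#' Generate TPM matrices with planted tumor- and tissue-specific transcripts
#'
#' Background transcripts express at `background_tpm` in every cohort under
#' multiplicative log-normal noise with dropout. Planted tumor-SRTs are
#' absent from every normal tissue and express at `srt_fold` times the
#' `normal_floor_tpm` expression floor in every tumor sample of one
#' designated cancer type. Planted tissue-SRTs express only in one designated
#' healthy tissue. Plants are drawn from
#' `ids` in order; supply at least `n_tumor_srt + n_tissue_srt` ids.
#'
#' @param spec A [fixture_spec].
#' @param ids Character vector of transcript ids to simulate.
#' @return List: `tpm` (transcripts x samples matrix), `samples` (data.frame:
#'   sample_id, group, cohort), `planted_tumor_srt`, `planted_tissue_srt`
#'   (named character vectors: id -> designated cancer type / tissue).
#' @export
make_expression <- function(spec, ids) with_seed(spec$seed + 3L, {
  ctypes <- sprintf("CANCER%02d", seq_len(spec$n_cancer_types))
  samples <- rbind(
    do.call(rbind, lapply(ctypes, function(ct) data.frame(
      sample_id = sprintf("%s_T%03d", ct, seq_len(spec$n_tumor_per_type)),
      group = ct, cohort = "tumor", stringsAsFactors = FALSE))),
    do.call(rbind, lapply(ctypes, function(ct) data.frame(
      sample_id = sprintf("%s_N%03d", ct, seq_len(spec$n_adjacent_per_type)),
      group = paste0(ct, "_adj"), cohort = "adjacent_normal",
      stringsAsFactors = FALSE))),
    do.call(rbind, lapply(spec$normal_tissues, function(ti) data.frame(
      sample_id = sprintf("%s_%03d", ti, seq_len(spec$n_per_tissue)),
      group = ti, cohort = "normal", stringsAsFactors = FALSE))))
  nS <- nrow(samples); nT <- length(ids)
  n_plant <- spec$n_tumor_srt + spec$n_tissue_srt
  stopifnot(nT >= n_plant)
  noise <- function(n) {
    if (spec$noise_sdlog == 0) rep(1, n) else rlnorm(n, 0, spec$noise_sdlog)
  }
  tumor_srt <- if (spec$n_tumor_srt > 0) ids[seq_len(spec$n_tumor_srt)] else character()
  tissue_srt <- if (spec$n_tissue_srt > 0)
    ids[spec$n_tumor_srt + seq_len(spec$n_tissue_srt)] else character()
  tumor_ct <- setNames(sample(ctypes, length(tumor_srt), replace = TRUE), tumor_srt)
  tissue_of <- setNames(sample(spec$normal_tissues, length(tissue_srt),
                               replace = TRUE), tissue_srt)
  tpm <- matrix(0, nT, nS, dimnames = list(ids, samples$sample_id))
  is_tumor <- samples$cohort == "tumor"
  is_normal <- samples$cohort %in% c("normal", "adjacent_normal")
  for (i in seq_len(nT)) {
    id <- ids[i]
    if (id %in% tumor_srt) {
      # tumor-restricted: absent from every normal tissue, expressed at
      # srt_fold times the TPM floor in one cancer type
      tgt <- is_tumor & samples$group == tumor_ct[[id]]
      tpm[i, tgt] <- spec$normal_floor_tpm * spec$srt_fold * noise(sum(tgt))
    } else if (id %in% tissue_srt) {
      tgt <- samples$group == tissue_of[[id]]
      tpm[i, tgt] <- 4 * spec$background_tpm * noise(sum(tgt))
    } else {
      v <- spec$background_tpm * noise(nS)
      if (spec$dropout > 0) v[runif(nS) < spec$dropout] <- 0
      tpm[i, ] <- v
    }
  }
  list(tpm = tpm, samples = samples,
       planted_tumor_srt = tumor_ct, planted_tissue_srt = tissue_of)
})

#' Generate a complete fixture, optionally writing it to disk
#'
#' Runs all generators and, when `dir` is given, writes `genome.fa`,
#' `reference.gtf`, `query.gtf`, `truth.tsv`, `sj/SRxx.tab`, `tpm.tsv` and
#' `samples.tsv` — the full input set for [run_curation].
#'
#' @param spec A [fixture_spec].
#' @param dir Output directory (created), or `NULL` for in-memory only.
#' @return List with all generator outputs plus `paths` when written.
#' @export
simulate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  reference <- make_reference(spec)
  qs <- make_query_set(spec, reference)
  je <- make_junction_evidence(spec, qs$query, qs$truth)
  catalog_ids <- qs$truth$transcript_id[qs$truth$supported &
                                          qs$truth$true_category != "ISM"]
  n_plant <- spec$n_tumor_srt + spec$n_tissue_srt
  # distribute catalog ids across both plant blocks (plants are taken from
  # the head of the id vector), padding with background-only ids
  bg <- sprintf("BG%03d", seq_len(n_plant + 20L))
  odd <- catalog_ids[seq_along(catalog_ids) %% 2L == 1L]
  even <- catalog_ids[seq_along(catalog_ids) %% 2L == 0L]
  tumor_slots <- head(c(odd, bg), spec$n_tumor_srt)
  tissue_slots <- head(c(even, setdiff(bg, tumor_slots)), spec$n_tissue_srt)
  expr_ids <- unique(c(tumor_slots, tissue_slots, catalog_ids, bg))
  ex <- make_expression(spec, expr_ids)
  out <- list(spec = spec, genome = reference$genome,
              reference = reference$reference,
              ref_index = reference$ref_index,
              empty_region = reference$empty_region,
              query = qs$query, truth = qs$truth,
              evidence = je$evidence, sj_tables = je$tables,
              tpm = ex$tpm, samples = ex$samples,
              planted_tumor_srt = ex$planted_tumor_srt,
              planted_tissue_srt = ex$planted_tissue_srt)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "sj"), showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      reference_gtf = file.path(dir, "reference.gtf"),
      query_gtf = file.path(dir, "query.gtf"),
      truth = file.path(dir, "truth.tsv"),
      sj = file.path(dir, "sj", paste0(names(je$tables), ".tab")),
      tpm = file.path(dir, "tpm.tsv"),
      samples = file.path(dir, "samples.tsv"))
    Biostrings::writeXStringSet(reference$genome, paths$genome)
    write_gtf(reference$reference, paths$reference_gtf)
    write_gtf(qs$query, paths$query_gtf)
    write.table(qs$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (k in seq_along(je$tables)) {
      write.table(je$tables[[k]], paths$sj[k], sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    tpm_df <- data.frame(transcript_id = rownames(ex$tpm), ex$tpm,
                         check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tpm_df, paths$tpm, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ex$samples, paths$samples, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
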