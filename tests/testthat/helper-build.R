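# terse transcript builder for tests
tx <- function(id, starts, ends, strand = "+", chrom = "chr1",
               gene_id = NA_character_, samples = character()) {
  transcript_model(id, chrom, strand, starts, ends, gene_id = gene_id,
                   source_samples = samples)
}

# write a GTF from raw 1-based inclusive exon coordinates
write_raw_gtf <- function(path, rows) {
  # rows: data.frame chrom,start,end,strand,transcript_id,gene_id
  lines <- sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                   rows$chrom, rows$start, rows$end, rows$strand,
                   rows$gene_id, rows$transcript_id)
  writeLines(lines, path)
  path
}

# write an SJ.out.tab-dialect file from a data.frame of rows
write_sj <- function(path, chrom, start1, end1, strand_code, unique_reads) {
  df <- data.frame(chrom, start1, end1, strand_code, 0L, 0L, unique_reads,
                   0L, 20L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# genome from explicit chromosome sequences
genome_of <- function(...) {
  Biostrings::DNAStringSet(unlist(list(...)))
}

# build a transcript plus genome such that the spliced sequence equals `seq`
# (single chromosome, exons split at the given widths, strand-aware)
tx_with_seq <- function(id, seq, widths = NULL, strand = "+") {
  L <- nchar(seq)
  if (is.null(widths)) widths <- L
  stopifnot(sum(widths) == L)
  gap <- 100L
  starts <- integer(length(widths)); ends <- integer(length(widths))
  p <- 10L
  for (i in seq_along(widths)) {
    starts[i] <- p; ends[i] <- p + widths[i]; p <- ends[i] + gap
  }
  t <- transcript_model(id, "chrT", strand, starts, ends)
  glen <- ends[length(ends)] + 50L
  g <- paste(rep("A", glen), collapse = "")
  genomic <- if (strand == "+") seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  off <- 0L
  for (i in seq_along(starts)) {
    w <- ends[i] - starts[i]
    substr(g, starts[i] + 1L, ends[i]) <- substr(genomic, off + 1L, off + w)
    off <- off + w
  }
  list(t = t, genome = Biostrings::DNAStringSet(c(chrT = g)))
}

random_codons <- function(n, rng_seed) {
  b <- c("A", "C", "G", "T")
  all_cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  ok <- setdiff(all_cod, c("TAA", "TAG", "TGA", "ATG"))
  withr::with_seed(rng_seed, paste(sample(ok, n, replace = TRUE), collapse = ""))
}
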