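test_that("GTF 1-based inclusive coordinates convert to internal half-open", {
  p <- withr::local_tempfile(fileext = ".gtf")
  write_raw_gtf(p, data.frame(chrom = "chr1", start = c(100L, 301L),
                              end = c(200L, 400L), strand = "+",
                              transcript_id = "t1", gene_id = "g1"))
  ts <- read_gtf(p)
  t1 <- ts[["t1"]]
  expect_equal(t1$starts, c(99L, 300L))
  expect_equal(t1$ends, c(200L, 400L))
  ic <- intron_chain(t1)
  expect_equal(ic$start, 200L)
  expect_equal(ic$end, 300L)
  expect_equal(ic$donor, 200L)
  expect_equal(ic$acceptor, 300L)
})

test_that("minus-strand transcripts reverse transcription order, not storage", {
  p <- withr::local_tempfile(fileext = ".gtf")
  write_raw_gtf(p, data.frame(chrom = "chr1", start = c(100L, 301L),
                              end = c(200L, 400L), strand = "-",
                              transcript_id = "t1", gene_id = "g1"))
  t1 <- read_gtf(p)[["t1"]]
  expect_equal(t1$starts, c(99L, 300L))  # genomic order preserved
  expect_equal(unname(transcript_ends(t1)["tss"]), 399L)
  expect_equal(unname(transcript_ends(t1)["tts"]), 99L)
  # rank-1 exon (transcription order) is the genomically last one
  first_exon <- transcript_to_genomic(t1, 0L, 100L)
  expect_equal(first_exon$start, 300L)
  expect_equal(first_exon$end, 400L)
  # minus intron donor is the right boundary
  ic <- intron_chain(t1)
  expect_equal(ic$donor, 300L)
  expect_equal(ic$acceptor, 200L)
})

test_that("GTF round-trip is the identity on ids, coordinates and order", {
  fx <- simulate_fixture(fixture_spec(seed = 11))
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(fx$query, p)
  back <- read_gtf(p)
  expect_identical(names(back), names(fx$query))
  for (id in names(back)) {
    expect_identical(back[[id]]$starts, fx$query[[id]]$starts)
    expect_identical(back[[id]]$ends, fx$query[[id]]$ends)
    expect_identical(back[[id]]$strand, fx$query[[id]]$strand)
    expect_identical(back[[id]]$chrom, fx$query[[id]]$chrom)
    expect_setequal(back[[id]]$source_samples, fx$query[[id]]$source_samples)
  }
})

test_that("write_gtf emits transcript+exon features and parseable attributes", {
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(transcript_set(), p)
  expect_equal(sum(!grepl("^#", readLines(p))), 0L)

  t1 <- tx("t1", c(0L, 200L, 500L), c(100L, 300L, 600L), gene_id = "g1")
  ann <- data.frame(transcript_id = "t1", category = "NIC", coding = TRUE,
                    nmd = FALSE, te_tss = TRUE, te_label = "L1PA2",
                    cage_tss = FALSE, polya_site = TRUE,
                    polya_motif = "AATAAA", stringsAsFactors = FALSE)
  write_gtf(transcript_set(list(t1)), p, annotations = ann)
  lines <- readLines(p)
  feats <- lines[!grepl("^#", lines)]
  expect_length(feats, 4L)  # 1 transcript + 3 exons
  expect_equal(sum(grepl("\ttranscript\t", feats)), 1L)
  gr <- rtracklayer::import(p, format = "gtf")
  expect_true(all(gr$category == "NIC"))
  expect_true(all(gr$te_label == "L1PA2"))
  expect_true(all(gr$polya_motif == "AATAAA"))
})

test_that("GTF reader rejects missing transcript_id, strand conflicts and '.'", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1";', p)
  expect_error(read_gtf(p), "transcript_id")

  write_raw_gtf(p, data.frame(chrom = "chr1", start = c(1L, 301L),
                              end = c(100L, 400L), strand = c("+", "-"),
                              transcript_id = "t1", gene_id = "g1"))
  expect_error(read_gtf(p), "strand")

  write_raw_gtf(p, data.frame(chrom = "chr1", start = c(1L, 301L, 1L, 301L),
                              end = c(100L, 400L, 100L, 400L),
                              strand = c(".", ".", "+", "+"),
                              transcript_id = c("t0", "t0", "t1", "t1"),
                              gene_id = "g1"))
  expect_warning(ts <- read_gtf(p), "rejected")
  expect_identical(names(ts), "t1")
  expect_equal(attr(ts, "n_rejected_unstranded"), 1L)
})

test_that("intron_chain yields n-1 introns inside the span; mono-exonic none", {
  t3 <- tx("a", c(100L, 300L, 500L), c(200L, 400L, 600L))
  ic <- intron_chain(t3)
  expect_equal(nrow(ic), 2L)
  expect_equal(ic$start, c(200L, 400L))
  expect_equal(ic$end, c(300L, 500L))
  expect_equal(nrow(intron_chain(tx("b", 0L, 100L))), 0L)

  fx <- simulate_fixture(fixture_spec(seed = 3))
  for (t in fx$query) {
    ic <- intron_chain(t)
    expect_equal(nrow(ic), n_exons(t) - 1L)
    if (nrow(ic)) {
      expect_true(all(ic$start > t$starts[1L]))
      expect_true(all(ic$end < t$ends[n_exons(t)]))
    }
  }
})

test_that("junction tables aggregate per-sample detections", {
  d <- withr::local_tempdir()
  # junction at internal [200,300): 1-based first/last intron base 201..300
  for (i in 1:3) {
    write_sj(file.path(d, sprintf("s%d.tab", i)), "chr1", 201L, 300L, 1L,
             unique_reads = c(5L, 10L, 1L)[i])
  }
  ev <- read_junction_tables(file.path(d, sprintf("s%d.tab", 1:3)))
  expect_equal(unname(junction_support(ev, "chr1:+:200-300")), 3L)

  # zero unique reads does not count toward the aggregate
  write_sj(file.path(d, "s4.tab"), "chr1", 201L, 300L, 1L, unique_reads = 0L)
  ev <- read_junction_tables(file.path(d, sprintf("s%d.tab", 1:4)))
  expect_equal(unname(junction_support(ev, "chr1:+:200-300")), 3L)
})

test_that("strand code 0 registers the junction on both strands", {
  d <- withr::local_tempdir()
  write_sj(file.path(d, "s1.tab"), "chr1", 201L, 300L, 0L, unique_reads = 7L)
  ev <- read_junction_tables(file.path(d, "s1.tab"))
  # matches a minus-strand transcript intron at the same coordinates
  tneg <- tx("t", c(100L, 300L), c(200L, 400L), strand = "-")
  expect_equal(unname(junction_support(ev, intron_keys(tneg))), 1L)
  expect_equal(unname(junction_support(ev, "chr1:+:200-300")), 1L)
})

test_that("duplicate junctions within a sample are summed with a warning", {
  d <- withr::local_tempdir()
  p <- write_sj(file.path(d, "s1.tab"), "chr1", c(201L, 201L), c(300L, 300L),
                1L, unique_reads = c(3L, 4L))
  expect_warning(ev <- read_junction_tables(p), "summed")
  expect_equal(unname(ev$per_sample[[1]]["chr1:+:200-300"]), 7L)
})

test_that("malformed junction rows raise an error naming the file", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.tab")
  writeLines("chr1\t100", p)
  expect_error(read_junction_tables(p), "bad.tab")
  writeLines("chr1\t300\t200\t1\t0\t0\t5\t0\t20", p)  # start > end
  expect_error(read_junction_tables(p), "bad.tab")
})

test_that("aggregate counts are invariant under input file permutation", {
  fx <- simulate_fixture(fixture_spec(seed = 5))
  d <- withr::local_tempdir()
  paths <- vapply(names(fx$sj_tables), function(nm) {
    p <- file.path(d, paste0(nm, ".tab"))
    write.table(fx$sj_tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  a <- read_junction_tables(paths)
  b <- read_junction_tables(rev(paths))
  expect_identical(a$aggregate[sort(names(a$aggregate))],
                   b$aggregate[sort(names(b$aggregate))])
})

test_that("transcript_model validates its invariants", {
  expect_error(tx("t", 100L, 100L), "start")
  expect_error(tx("t", c(100L, 150L), c(200L, 300L)), "overlap")
  expect_error(transcript_model("t", "chr1", ".", 1L, 10L), "strand")
  t1 <- tx("t", c(300L, 100L), c(400L, 200L))  # unsorted input sorted
  expect_equal(t1$starts, c(100L, 300L))
  expect_equal(transcript_length(t1), 200L)
})
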