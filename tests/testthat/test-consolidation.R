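# base 4-exon transcript and shifted variants
base_tx <- function(id = "a", dstarts = c(0L, 0L, 0L, 0L),
                    dends = c(0L, 0L, 0L, 0L)) {
  tx(id, c(1000L, 1500L, 2000L, 2500L) + dstarts,
     c(1200L, 1700L, 2200L, 2800L) + dends)
}

test_that("end dissimilarity within 100 bp is comparable; beyond is not", {
  a <- base_tx("a")
  b <- base_tx("b", dstarts = c(50L, 0L, 0L, 0L), dends = c(0L, 0L, 0L, 80L))
  cmp <- comparable_isoforms(a, b)
  expect_true(c(cmp))
  expect_identical(attr(cmp, "reason"), "ok")

  b2 <- base_tx("b2", dstarts = c(150L, 0L, 0L, 0L))
  cmp2 <- comparable_isoforms(a, b2)
  expect_false(c(cmp2))
  expect_identical(attr(cmp2, "reason"), "end dissimilarity")
})

test_that("an internal boundary shifted 5 bp fails the per-exon bp cap", {
  a <- base_tx("a")
  b <- base_tx("b", dends = c(0L, 5L, 0L, 0L))
  cmp <- comparable_isoforms(a, b)
  expect_false(c(cmp))
  expect_identical(attr(cmp, "reason"), "bp per exon")
  # 4 bp passes the cap
  b4 <- base_tx("b4", dends = c(0L, 4L, 0L, 0L))
  expect_true(c(comparable_isoforms(a, b4)))
  # per-exon sum: 3 bp at each internal boundary of one exon = 6 > 4
  b6 <- base_tx("b6", dstarts = c(0L, 3L, 0L, 0L), dends = c(0L, 3L, 0L, 0L))
  expect_false(c(comparable_isoforms(a, b6)))
  expect_identical(attr(comparable_isoforms(a, b6), "reason"), "bp per exon")
  # the per-boundary switch re-admits it
  expect_true(c(comparable_isoforms(a, b6,
                                    consolidation_params(per_boundary = TRUE))))
})

test_that("more than three exons with boundary shifts fails exonic variations", {
  a <- base_tx("a")
  b <- base_tx("b", dends = c(2L, 2L, 2L, 0L), dstarts = c(0L, 0L, 0L, 2L))
  cmp <- comparable_isoforms(a, b)  # 4 exons changed, each within 4 bp
  expect_false(c(cmp))
  expect_identical(attr(cmp, "reason"), "exonic variations")
  b3 <- base_tx("b3", dends = c(2L, 2L, 2L, 0L))
  expect_true(c(comparable_isoforms(a, b3)))  # 3 exons changed
})

test_that("locus, exon count and ORF clauses gate comparability", {
  a <- base_tx("a")
  expect_identical(attr(comparable_isoforms(a, tx("c", c(1000L, 1500L),
                                                  c(1200L, 1700L),
                                                  strand = "-")), "reason"),
                   "locus")
  expect_identical(attr(comparable_isoforms(a, tx("d", c(1000L, 1500L, 2000L),
                                                  c(1200L, 1700L, 2200L))),
                        "reason"), "exon count")
  b <- base_tx("b", dends = c(0L, 0L, 0L, 50L))
  orf_a <- orf_record(a, 30L, 630L)
  orf_b <- orf_record(b, 33L, 633L)
  cmp <- comparable_isoforms(a, b, orf_a = orf_a, orf_b = orf_b)
  expect_identical(attr(cmp, "reason"), "orf")
  # identical ORFs pass; so does disabling the requirement
  expect_true(c(comparable_isoforms(a, b, orf_a = orf_a,
                                    orf_b = orf_record(b, 30L, 630L))))
  expect_true(c(comparable_isoforms(
    a, b, consolidation_params(require_identical_orf = FALSE),
    orf_a = orf_a, orf_b = orf_b)))
})

test_that("the longest member represents each consolidation group", {
  long <- tx("long", c(1000L, 1500L), c(1210L, 2871L))   # 1581 bp
  short <- tx("short", c(1050L, 1500L), c(1210L, 2800L)) # 1460 bp
  res <- consolidate_isoforms(transcript_set(list(short, long)))
  expect_equal(nrow(res$groups), 1L)
  expect_identical(res$groups$representative, "long")
  expect_setequal(strsplit(res$groups$members, ",")[[1]], c("long", "short"))
})

test_that("pairwise non-comparable transcripts stay singletons", {
  ts <- transcript_set(lapply(1:4, function(i) {
    tx(paste0("t", i), c(1000L, 1500L) + 5000L * i, c(1200L, 1700L) + 5000L * i)
  }))
  res <- consolidate_isoforms(ts)
  expect_equal(nrow(res$groups), 4L)
  expect_true(all(res$groups$n_members == 1L))
})

test_that("non-transitive A~B, B~C, A!~C resolves by the greedy longest-first rule", {
  # TSS chain: A at 1000, B at 1090, C at 1180; A-B and B-C within 100 bp,
  # A-C 180 bp apart. A is longest, so A seeds {A, B}; C stays singleton.
  A <- tx("A", c(1000L, 1500L), c(1200L, 1800L))  # 500 bp
  B <- tx("B", c(1090L, 1500L), c(1200L, 1790L))  # 400 bp
  C <- tx("C", c(1180L, 1500L), c(1200L, 1730L))  # 250 bp
  expect_true(c(comparable_isoforms(A, B)))
  expect_true(c(comparable_isoforms(B, C)))
  expect_false(c(comparable_isoforms(A, C)))
  res <- consolidate_isoforms(transcript_set(list(A, B, C)))
  expect_identical(res$groups$representative, c("A", "C"))
  expect_identical(res$groups$members, c("A,B", "C"))
})

test_that("consolidation is idempotent and conserves transcript counts", {
  fx <- simulate_fixture(fixture_spec(seed = 71))
  # add jittered near-duplicates of several query transcripts
  dups <- lapply(seq_along(fx$query)[1:6], function(i) {
    t <- fx$query[[i]]
    t$transcript_id <- paste0(t$transcript_id, "dup")
    t$starts[1L] <- t$starts[1L] + 30L
    t
  })
  ts <- transcript_set(c(unclass(fx$query), dups))
  res1 <- consolidate_isoforms(ts)
  expect_equal(sum(res1$groups$n_members), length(ts))
  res2 <- consolidate_isoforms(res1$transcripts)
  expect_identical(names(res2$transcripts), names(res1$transcripts))
  expect_identical(res2$groups$representative, res1$groups$representative)
  expect_true(all(res2$groups$n_members == 1L))
})

test_that("consolidation output is invariant under input permutation", {
  fx <- simulate_fixture(fixture_spec(seed = 72))
  ts <- fx$query
  res_a <- consolidate_isoforms(ts)
  res_b <- consolidate_isoforms(ts[rev(seq_along(ts))])
  expect_identical(res_a$groups, res_b$groups)
  expect_identical(names(res_a$transcripts), names(res_b$transcripts))
})

test_that("zero tolerances collapse exactly the structurally identical duplicates", {
  a1 <- tx("a1", c(1000L, 1500L), c(1200L, 1800L))
  a2 <- tx("a2", c(1000L, 1500L), c(1200L, 1800L))
  b <- tx("b", c(1001L, 1500L), c(1200L, 1800L))
  zero <- consolidation_params(max_exonic_variations = 0L, max_bp_per_exon = 0L,
                               max_end_dissimilarity = 0L)
  res <- consolidate_isoforms(transcript_set(list(a1, a2, b)), zero)
  expect_equal(sort(res$groups$n_members), c(1L, 2L))
  grp2 <- res$groups$members[res$groups$n_members == 2L]
  expect_setequal(strsplit(grp2, ",")[[1]], c("a1", "a2"))
})

test_that("bins prevent merging across locus/category boundaries", {
  a <- tx("a", c(1000L, 1500L), c(1200L, 1800L))
  b <- tx("b", c(1000L, 1500L), c(1200L, 1800L))
  res <- consolidate_isoforms(transcript_set(list(a, b)),
                              bins = c(a = "FSM GA", b = "NNC GA"))
  expect_equal(nrow(res$groups), 2L)
})

test_that("merged representatives inherit the union of source samples", {
  a <- tx("a", c(1000L, 1500L), c(1200L, 1805L), samples = c("s1", "s2"))
  b <- tx("b", c(1000L, 1500L), c(1200L, 1800L), samples = c("s2", "s3"))
  res <- consolidate_isoforms(transcript_set(list(a, b)))
  expect_identical(res$transcripts[["a"]]$source_samples, c("s1", "s2", "s3"))
})
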