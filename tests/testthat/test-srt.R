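test_that("expression ratios divide by the row total", {
  expect_equal(expression_ratios(c(8, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(expression_ratios(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(expression_ratios(c(4, 2, 1, 1)), c(0.5, 0.25, 0.125, 0.125))
  z <- expression_ratios(c(0, 0, 0))
  expect_true(attr(z, "unexpressed"))
  expect_equal(c(z), c(0, 0, 0))
  expect_error(expression_ratios(c(-1, 2)), "non-negative")
  expect_error(expression_ratios(5), "two tissue")
})

test_that("specificity score closed forms: point mass, uniform, hand case", {
  expect_equal(specificity_score(c(1, 0, 0, 0)), 2, tolerance = 1e-12)
  expect_equal(specificity_score(rep(0.25, 4)), 0, tolerance = 1e-12)
  # p = (0.5, 0.25, 0.125, 0.125): entropy 1.75 bits, score 0.25
  expect_equal(specificity_score(c(0.5, 0.25, 0.125, 0.125)), 0.25,
               tolerance = 1e-12)
  expect_error(specificity_score(c(0.5, 0.4)), "sum")
})

test_that("score is bounded by [0, log2 N] with equality at the extremes", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      N <- sample(2:30, 1L)
      p <- expression_ratios(rlnorm(N))
      S <- specificity_score(p)
      expect_gte(S, 0)
      expect_lte(S, log2(N) + 1e-12)
    }
  })
})

test_that("specificity is invariant under positive rescaling of expression", {
  withr::with_seed(8, {
    x <- rlnorm(12)
    for (k in c(1e-3, 0.5, 7, 1e4)) {
      expect_equal(specificity_score(expression_ratios(k * x)),
                   specificity_score(expression_ratios(x)), tolerance = 1e-9)
    }
  })
})

test_that("tissue-SRT calls need ratio dominance and score above 1", {
  m <- rbind(
    single = c(9, rep(0, 21)),          # one of 22 tissues
    uniform = rep(3, 22),
    dominant = c(0.6, 0.4, rep(0, 20)) * 10,
    silent = rep(0, 22))
  rownames(m) <- c("single", "uniform", "dominant", "silent")
  colnames(m) <- paste0("tis", 1:22)
  res <- call_tissue_srt(m)
  expect_equal(res$S[res$transcript_id == "single"], log2(22),
               tolerance = 1e-9)
  expect_true(res$is_tissue_srt[res$transcript_id == "single"])
  expect_false(res$is_tissue_srt[res$transcript_id == "uniform"])
  # 0.6 < 2 x 0.4: ratio clause fails regardless of the score
  expect_false(res$is_tissue_srt[res$transcript_id == "dominant"])
  expect_true(res$unexpressed[res$transcript_id == "silent"])
  expect_true(is.na(res$S[res$transcript_id == "silent"]))
  expect_error(call_tissue_srt(m[, 1, drop = FALSE]), "two tissue")
})

test_that("tumor-SRT criterion A compares tumor median to the normal maximum", {
  # 10 tumor samples at 5 TPM median vs normal tissue max 0.4: 12.5-fold
  tum <- matrix(5, 1, 10, dimnames = list("t1", paste0("T", 1:10)))
  nrm <- matrix(0.4, 1, 6, dimnames = list("t1", paste0("N", 1:6)))
  res <- call_tumor_srt(tum, rep("C1", 10), nrm, rep(c("liver", "lung"), 3),
                        tumor_srt_params(excluded_normals = character()))
  expect_identical(res$srt_ids, "t1")
  expect_equal(res$calls$fold, 12.5)
  # 9.9-fold fails
  nrm2 <- nrm; nrm2[] <- 5 / 9.9
  res2 <- call_tumor_srt(tum, rep("C1", 10), nrm2, rep(c("liver", "lung"), 3),
                         tumor_srt_params(excluded_normals = character()))
  expect_length(res2$srt_ids, 0L)
  # exactly 10-fold passes ("at least")
  nrm3 <- nrm; nrm3[] <- 0.5
  res3 <- call_tumor_srt(tum, rep("C1", 10), nrm3, rep(c("liver", "lung"), 3),
                         tumor_srt_params(excluded_normals = character()))
  expect_identical(res3$srt_ids, "t1")
})

test_that("criterion B needs strictly more than 5% of tumor samples expressed", {
  nrm <- matrix(0, 1, 4, dimnames = list("t1", paste0("N", 1:4)))
  mk_tum <- function(n_expr) {
    v <- c(rep(5, n_expr), rep(0, 100 - n_expr))
    matrix(v, 1, 100, dimnames = list("t1", paste0("T", 1:100)))
  }
  grp <- rep("C1", 100)
  # 5/100 = 5%: not >5%
  res5 <- call_tumor_srt(mk_tum(5), grp, nrm, rep("liver", 4),
                         tumor_srt_params(excluded_normals = character()))
  expect_length(res5$srt_ids, 0L)
  # 6/100 passes (and median 0 is fine only for criterion B; A needs median>0)
  res51 <- call_tumor_srt(mk_tum(51), grp, nrm, rep("liver", 4),
                          tumor_srt_params(excluded_normals = character()))
  expect_identical(res51$srt_ids, "t1")
  # TPM exactly at the 0.5 floor does not count as expressed
  tum_at_floor <- mk_tum(0); tum_at_floor[] <- 0.5
  res_fl <- call_tumor_srt(tum_at_floor, grp, nrm, rep("liver", 4),
                           tumor_srt_params(excluded_normals = character()))
  expect_length(res_fl$srt_ids, 0L)
})

test_that("testis is excluded from the normal maximum by default", {
  tum <- matrix(2, 1, 20, dimnames = list("t1", paste0("T", 1:20)))
  nrm <- matrix(c(rep(50, 3), rep(0, 3)), 1, 6,
                dimnames = list("t1", paste0("N", 1:6)))
  groups <- c(rep("testis", 3), rep("liver", 3))
  res <- call_tumor_srt(tum, rep("C1", 20), nrm, groups)
  expect_identical(res$srt_ids, "t1")   # normal max 0 after exclusion
  res2 <- call_tumor_srt(tum, rep("C1", 20), nrm, groups,
                         tumor_srt_params(excluded_normals = character()))
  expect_length(res2$srt_ids, 0L)
  expect_error(call_tumor_srt(tum, rep("C1", 20), nrm[, 0, drop = FALSE],
                              character()), "normal")
})

test_that("raising fold or prevalence thresholds never adds tumor-SRT calls", {
  fx <- simulate_fixture(fixture_spec(seed = 91))
  s <- fx$samples
  tum <- s$cohort == "tumor"; nrm <- !tum
  base <- call_tumor_srt(fx$tpm[, tum], s$group[tum], fx$tpm[, !tum],
                         s$group[!tum], tumor_srt_params(fold = 5,
                                                         frac_expressed = 0.02))
  for (f in c(10, 20, 40)) {
    res <- call_tumor_srt(fx$tpm[, tum], s$group[tum], fx$tpm[, !tum],
                          s$group[!tum], tumor_srt_params(fold = f))
    expect_true(all(res$srt_ids %in% base$srt_ids))
  }
})

test_that("noise-free planted SRTs are recovered with perfect precision and recall", {
  fx <- simulate_fixture(fixture_spec(seed = 92, noise_sdlog = 0, dropout = 0))
  s <- fx$samples
  tum <- s$cohort == "tumor"
  res <- call_tumor_srt(fx$tpm[, tum], s$group[tum], fx$tpm[, !tum],
                        s$group[!tum])
  expect_setequal(res$srt_ids, names(fx$planted_tumor_srt))
  nrm <- s$cohort == "normal"
  tis <- call_tissue_srt(aggregate_by_group(fx$tpm[, nrm], s$group[nrm]))
  called <- tis$transcript_id[tis$is_tissue_srt]
  expect_setequal(called, names(fx$planted_tissue_srt))
  # and the qualifying cancer types match the plant
  for (id in res$srt_ids) {
    expect_true(fx$planted_tumor_srt[[id]] %in%
                  res$calls$cancer_type[res$calls$transcript_id == id])
  }
})

test_that("long-read tumor-SRTs are the tumor-exclusive transcripts", {
  cohort <- c(s1 = "tumor", s2 = "tumor", s3 = "normal")
  ts <- transcript_set(list(
    tx("only_tumor", c(0L, 200L), c(100L, 300L), samples = c("s1", "s2")),
    tx("mixed", c(1000L, 1200L), c(1100L, 1300L), samples = c("s1", "s3")),
    tx("orphan", c(2000L, 2200L), c(2100L, 2300L))))
  expect_identical(lr_tumor_srt(ts, cohort), "only_tumor")
})
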