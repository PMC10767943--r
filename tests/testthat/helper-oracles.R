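# Brute-force structural classifier: enumerates reference chains, sub-chains,
# splice sites and junctions directly from the reference transcript list, and
# computes exonic overlaps with plain interval arithmetic. Independent of the
# package's index structures and cascade implementation.

brute_keys <- function(t) {
  n <- length(t$starts)
  if (n < 2L) return(character())
  sprintf("%s|%s|%d|%d", t$chrom, t$strand, t$ends[-n], t$starts[-1L])
}

brute_sites <- function(t) {
  n <- length(t$starts)
  if (n < 2L) return(character())
  sprintf("%s|%s|%d", t$chrom, t$strand, c(t$ends[-n], t$starts[-1L]))
}

brute_classify <- function(t, ref_ts) {
  keys <- brute_keys(t)
  ref_chains <- lapply(ref_ts, brute_keys)
  # FSM: exact chain equality with any reference transcript
  for (rc in ref_chains) if (identical(rc, keys)) return("FSM")
  # ISM: contiguous sub-chain (proper) of some reference chain
  for (rc in ref_chains) {
    m <- length(keys)
    if (m < length(rc)) {
      for (p in seq_len(length(rc) - m + 1L)) {
        if (identical(rc[p:(p + m - 1L)], keys)) return("ISM")
      }
    }
  }
  # locus by exhaustive per-gene interval arithmetic
  genes <- split(unclass(ref_ts),
                 vapply(ref_ts, function(r) r$gene_id, character(1)))
  exonic_overlap <- function(members) {
    tot <- 0L
    for (r in members) {
      if (r$chrom != t$chrom) next
      for (i in seq_along(r$starts)) for (j in seq_along(t$starts)) {
        ov <- min(r$ends[i], t$ends[j]) - max(r$starts[i], t$starts[j])
        if (ov > 0L) tot <- tot + ov
      }
    }
    tot
  }
  # note: summing overlaps across member transcripts can double-count shared
  # exons, but for same-strand detection only positivity matters
  same_gene <- FALSE; opp_gene <- FALSE
  tspan <- c(t$starts[1L], t$ends[length(t$ends)])
  for (g in genes) {
    strands <- vapply(g, function(r) r$strand, character(1))
    chroms <- vapply(g, function(r) r$chrom, character(1))
    if (all(chroms != t$chrom)) next
    gspan <- c(min(vapply(g, function(r) r$starts[1L], integer(1))),
               max(vapply(g, function(r) r$ends[length(r$ends)], integer(1))))
    span_ov <- gspan[1L] < tspan[2L] && gspan[2L] > tspan[1L]
    if (strands[1L] == t$strand) {
      if (exonic_overlap(g) > 0L) same_gene <- TRUE
    } else if (span_ov) {
      opp_gene <- TRUE
    }
  }
  if (!same_gene) {
    return(if (opp_gene) "antisense" else "intergenic")
  }
  all_sites <- unique(unlist(lapply(ref_ts, brute_sites)))
  if (all(brute_sites(t) %in% all_sites)) "NIC" else "NNC"
}

# brute-force junction filter: checks every intron of every transcript
# independently against a flat table of per-sample detections
brute_filter <- function(ts, per_sample_maps, min_samples, min_reads = 1L) {
  detected <- lapply(per_sample_maps, function(m) names(m)[m >= min_reads])
  kept <- character()
  for (t in ts) {
    keys <- intron_keys(t)
    if (length(keys) == 0L) next
    ok <- TRUE
    for (k in keys) {
      n_sup <- sum(vapply(detected, function(d) k %in% d, logical(1)))
      if (n_sup < min_samples) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, t$transcript_id)
  }
  kept
}

# exhaustive longest-ORF scan: every ATG position, extend codon by codon
brute_longest_orf <- function(seq, min_len = 300L) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (a in seq_len(L - 5L)) {
    if (substr(seq, a, a + 2L) != "ATG") next
    p <- a
    while (p + 2L <= L) {
      cod <- substr(seq, p, p + 2L)
      if (p > a && cod %in% stops) {
        len <- p + 3L - a
        if (len >= min_len && (is.null(best) || len > best$len)) {
          best <- list(start = a - 1L, end = a - 1L + len, len = len)
        }
        break
      }
      p <- p + 3L
    }
  }
  best
}
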