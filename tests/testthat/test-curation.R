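# motif scan, pairwise identity, dedup, the full filter chain

test_that("a protein built from the canonical motifs passes; a deleted motif fails", {
  set.seed(51)
  motifs <- default_motifs()
  prot <- planted_protein(motifs)
  res <- motif_scan(prot, motifs)
  expect_true(res$pass)
  expect_identical(res$hits$motif_id, c("I", "II", "III", "IV", "V", "VI"))
  expect_true(all(diff(res$hits$start) > 0))

  # knock out motif IV's span
  hit4 <- res$hits[res$hits$motif_id == "IV", ]
  k4 <- nchar(hit4$matched)
  broken <- prot
  substr(broken, hit4$start, hit4$start + k4 - 1L) <- strrep("A", k4)
  res2 <- motif_scan(broken, motifs)
  expect_false(res2$pass)
  expect_true("IV" %in% res2$missing)
})

test_that("mismatch budget applies to fixed letters only", {
  m0 <- motif_def("I", "KXW[LIVM]DG", max_mismatch = 0L)
  m1 <- motif_def("I", "KXW[LIVM]DG", max_mismatch = 1L)
  # one mismatch at fixed K
  expect_false(motif_scan("QAWLDG", list(m0))$pass)
  expect_true(motif_scan("QAWLDG", list(m1))$pass)
  # bracket positions are never relaxed
  expect_false(motif_scan("KAWADG", list(m1))$pass)
  # wildcard always matches
  expect_true(motif_scan("KZWLDG", list(m0))$pass)
})

test_that("motif order enforcement matches shuffled-order constructions", {
  set.seed(52)
  motifs <- default_motifs()
  shuffled <- planted_protein(motifs, order = c(2, 1, 3, 4, 6, 5))
  expect_false(motif_scan(shuffled, motifs, order_enforced = TRUE)$pass)
  expect_true(motif_scan(shuffled, motifs, order_enforced = FALSE)$pass)
})

test_that("motif scan agrees with a regex oracle on random proteins", {
  set.seed(53)
  motifs <- default_motifs()
  got <- logical(1000); want <- logical(1000)
  for (k in 1:1000) {
    prot <- if (k <= 900) random_protein(500) else planted_protein(motifs)
    got[k] <- motif_scan(prot, motifs)$pass
    want[k] <- oracle_motif_pass(prot, motifs)
  }
  expect_identical(got, want)
  expect_identical(mean(got), mean(want))
  expect_true(all(got[901:1000]))
})

test_that("pairwise identity reproduces the fixed-scoring examples", {
  expect_equal(as.numeric(pairwise_identity("ACGU", "ACGU")), 100)
  expect_equal(as.numeric(pairwise_identity("AAAA", "CCCC")), 0)
  # one substitution in four columns, no gaps: 3/4 identical columns
  expect_equal(as.numeric(pairwise_identity("ACGU", "ACGA")), 75)
  expect_error(pairwise_identity("", "ACGU"), "empty")
})

test_that("pairwise identity is symmetric and 100 iff identical", {
  set.seed(54)
  for (k in 1:25) {
    a <- random_rna(sample(5:120, 1))
    b <- if (k %% 3 == 0) a else random_rna(sample(5:120, 1))
    expect_equal(as.numeric(pairwise_identity(a, b)),
                 as.numeric(pairwise_identity(b, a)))
    idy <- as.numeric(pairwise_identity(a, b))
    if (identical(a, b)) expect_equal(idy, 100) else
      if (idy == 100) expect_identical(a, b)
  }
  # non-identical pairs never reach 100 under this scoring
  expect_lt(as.numeric(pairwise_identity("ACGUACGU", "ACGUACGA")), 100)
})

test_that("alignment scores match an independent aligner", {
  mat <- matrix(0L, 4, 4, dimnames = list(RNA4, RNA4))
  diag(mat) <- 1L
  set.seed(55)
  for (k in 1:25) {
    a <- random_rna(sample(5:80, 1))
    b <- random_rna(sample(5:80, 1))
    ours <- mitoscreen:::align_score_cpp(a, b)
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
      type = "global"
    )
    expect_equal(ours, Biostrings::score(ref), info = paste(a, b))
    # the traceback pass reports the same optimal score
    full <- mitoscreen:::align_identity_cpp(a, b)
    expect_equal(full$score, ours)
  }
})

test_that("dedup keeps one representative per high-identity group", {
  r <- function(id, s) nuc_seq(id, s)
  twin <- random_rna(80)
  dd <- dedup(list(r("b", twin), r("a", twin)), threshold_pct = 90)
  expect_identical(dd$representatives, "a")  # id ascending at equal length
  expect_setequal(dd$clusters[["a"]], c("a", "b"))

  set.seed(56)
  trio <- list(r("x", random_rna(100)), r("y", random_rna(100)),
               r("z", random_rna(100)))
  dd3 <- dedup(trio, threshold_pct = 90)
  expect_length(dd3$representatives, 3L)
})

test_that("dedup equals the all-pairs single-linkage oracle on planted duplicates", {
  set.seed(57)
  for (rep in 1:5) {
    base <- replicate(5, random_rna(sample(120:180, 1)))
    recs <- list()
    for (i in seq_along(base)) {
      recs[[length(recs) + 1L]] <- nuc_seq(sprintf("s%02d", i), base[[i]])
      # plant 0-2 mutated copies at ~2% substitutions (identity > 95%)
      for (d in seq_len(sample(0:2, 1))) {
        chars <- strsplit(base[[i]], "")[[1]]
        mut <- sample(length(chars), max(1L, round(0.02 * length(chars))))
        chars[mut] <- vapply(chars[mut], function(ch)
          sample(setdiff(RNA4, ch), 1), character(1))
        recs[[length(recs) + 1L]] <-
          nuc_seq(sprintf("s%02d_dup%d", i, d), paste(chars, collapse = ""))
      }
    }
    got <- dedup(recs, threshold_pct = 90)
    want <- oracle_single_linkage(recs, threshold_pct = 90)
    expect_identical(as_partition(got$clusters), as_partition(want))
    # representatives are the longest (then lexicographically first) members
    for (rp in got$representatives) {
      members <- got$clusters[[rp]]
      lens <- nchar(vapply(recs, `[[`, "", "residues"))[
        match(members, vapply(recs, `[[`, "", "id"))]
      expect_identical(rp, members[order(-lens, members)][1])
    }
  }
})

test_that("the filter chain short-circuits with auditable reason codes", {
  co <- generate_cohort(generator_preset("arkeo"), n = 10, seed = 58,
                        decoys = list(short_orf = 1, motif_deleted = 1,
                                      near_duplicate = 2))
  report <- curate(co$genomes)
  expect_setequal(report$kept, co$truth$id[co$truth$keepable])
  out <- report$outcomes
  short_row <- out[out$id == "decoy_short_01", ]
  expect_identical(short_row$orf_filter, "fail")
  expect_identical(short_row$motif_filter, "skipped")  # never motif-scanned
  expect_identical(short_row$dedup, "skipped")
  motif_row <- out[out$id == "decoy_motif_01", ]
  expect_identical(motif_row$orf_filter, "pass")
  expect_identical(motif_row$motif_filter, "fail")
  dup_rows <- out[grepl("^decoy_dup", out$id), ]
  expect_true(all(dup_rows$dedup == "redundant"))
  expect_true(all(grepl("^redundant:duplicate_of_", dup_rows$reason)))
  # every input id appears exactly once; kept and eliminated are disjoint
  expect_setequal(out$id, co$truth$id)
  expect_identical(anyDuplicated(out$id), 0L)
  eliminated <- out$id[nzchar(out$reason)]
  expect_length(intersect(report$kept, eliminated), 0L)
  # kept set is invariant under input shuffling
  set.seed(59)
  report2 <- curate(sample(co$genomes))
  expect_setequal(report2$kept, report$kept)
})

test_that("curation handles empty input and writes its report files", {
  empty <- curate(list())
  expect_identical(nrow(empty$outcomes), 0L)
  expect_identical(empty$kept, character())

  co <- generate_cohort(generator_preset("arkeo"), n = 2, seed = 60)
  report <- curate(co$genomes)
  dir <- withr::local_tempdir()
  write_curation_report(report, dir)
  expect_true(all(file.exists(file.path(
    dir, c("curation_report.tsv", "classification.tsv", "clusters.tsv",
           "kept.fasta")))))
  cls <- read.delim(file.path(dir, "classification.tsv"))
  expect_identical(nrow(cls), 2L)
  expect_true(all(cls$label == "UGA_FREE"))
})

test_that("YAML configuration overrides the curation defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "min_orf_nt: 600",
    "identity_threshold_pct: 80",
    "table_order: [1, 4]",
    "dedup_level: protein",
    "motifs:",
    "  - motif_id: I",
    "    pattern: GDD",
    "  - motif_id: II",
    "    pattern: 'SG[ST]'",
    "    max_mismatch: 1"
  ), f)
  cfg <- read_curation_config(f)
  expect_identical(cfg$min_orf_nt, 600L)
  expect_identical(cfg$identity_threshold_pct, 80)
  expect_identical(cfg$table_order, c(1L, 4L))
  expect_identical(cfg$dedup_level, "protein")
  expect_length(cfg$motifs, 2L)
  expect_identical(cfg$motifs[[2]]$max_mismatch, 1L)
})
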