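# sequence records, genetic codes, composition, translation, FASTA I/O

test_that("nuc_seq normalizes DNA input and rejects bad symbols", {
  expect_identical(nuc_seq("x", "ATGaaa")$residues, "AUGAAA")
  expect_error(nuc_seq("x", ""), "non-empty")
  expect_error(nuc_seq("x", "AUGR"), "invalid symbol 'R'")
})

test_that("FASTA round trip preserves records and normalizes T to U", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "ATGAAA", ">y", "GGG", "CCC"), f)
  recs <- load_fasta(f)
  expect_length(recs, 2L)
  expect_identical(recs[[1]]$residues, "AUGAAA")
  expect_identical(recs[[1]]$description, "some description")
  expect_identical(recs[[2]]$residues, "GGGCCC")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  again <- load_fasta(out)
  expect_identical(vapply(again, `[[`, "", "residues"),
                   vapply(recs, `[[`, "", "residues"))
  write_fasta(recs, out, dna = TRUE)
  expect_true(any(grepl("T", readLines(out)[2])))
})

test_that("FASTA loader enforces the unique-id invariant and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "AAA", ">x", "CCC"), f)
  expect_error(load_fasta(f), "duplicate")
  writeLines(character(), f)
  expect_identical(load_fasta(f), list())
  expect_error(load_fasta(file.path(tempdir(), "nope.fa")), "no such file")
})

test_that("reverse complement maps A<->U, G<->C, keeps N, and is an involution", {
  expect_identical(reverse_complement(nuc_seq("x", "AUGC"))$residues, "GCAU")
  expect_identical(reverse_complement(nuc_seq("x", "NNN"))$residues, "NNN")
  set.seed(11)
  for (k in 1:40) {
    s <- nuc_seq("r", random_rna(sample(1:200, 1), c(RNA4, "N")))
    expect_identical(reverse_complement(reverse_complement(s))$residues,
                     s$residues)
  }
})

test_that("AU content excludes N and errors on all-N input", {
  expect_equal(au_content(nuc_seq("a", "AUAU"))$au_fraction, 1.0)
  expect_equal(au_content(nuc_seq("b", "GCGC"))$au_fraction, 0.0)
  expect_equal(au_content(nuc_seq("c", "AUGC"))$au_fraction, 0.5)
  st <- au_content(nuc_seq("d", "AUGCNN"))
  expect_identical(st$counted_bases, 4L)
  expect_identical(st$ambiguous_bases, 2L)
  expect_error(au_content(nuc_seq("e", "NNNN")), "undefined")
})

test_that("AU content is invariant under reverse complement", {
  set.seed(12)
  for (k in 1:25) {
    s <- nuc_seq("r", random_rna(sample(4:300, 1)))
    expect_equal(au_content(reverse_complement(s))$au_fraction,
                 au_content(s)$au_fraction)
  }
})

test_that("genetic codes carry the NCBI stop/tryptophan assignments", {
  # frozen expected values for the diagnostic codons in all six tables
  expected <- list(
    `1`  = c(UGA = "*", UGG = "W", UAA = "*", UAG = "*"),
    `4`  = c(UGA = "W", UGG = "W", UAA = "*", UAG = "*"),
    `11` = c(UGA = "*", UGG = "W", UAA = "*", UAG = "*"),
    `16` = c(UGA = "*", UGG = "W", UAA = "*", UAG = "L"),
    `22` = c(UGA = "*", UGG = "W", UAA = "*", UAG = "L"),
    `23` = c(UGA = "*", UGG = "W", UAA = "*", UAG = "*")
  )
  for (id in names(expected)) {
    code <- genetic_code(as.integer(id))
    expect_length(code$codon_to_aa, 64L)
    expect_identical(code$codon_to_aa[names(expected[[id]])],
                     expected[[id]], info = paste("table", id))
  }
  # the two extra idiosyncrasies of tables 22 and 23
  expect_identical(genetic_code(22)$codon_to_aa[["UCA"]], "*")
  expect_identical(genetic_code(23)$codon_to_aa[["UUA"]], "*")
  expect_error(genetic_code(2), "unsupported")
})

test_that("translation truncates at the first stop and flags N codons", {
  t4 <- translate_nt("AUGUGAUGGUAA", genetic_code(4))
  expect_identical(t4$aa, "MWW")
  expect_true(t4$terminal_stop)
  t1 <- translate_nt("AUGUGAUGGUAA", genetic_code(1))
  expect_identical(t1$aa, "M")
  expect_true(t1$terminal_stop)
  t_open <- translate_nt("AUGAAA", genetic_code(1))
  expect_identical(t_open$aa, "MK")
  expect_false(t_open$terminal_stop)
  tn <- translate_nt("AUGANAUAA", genetic_code(1))
  expect_identical(tn$aa, "MX")
  expect_true(tn$had_n)
  expect_error(translate_nt("AU", genetic_code(1)), "at least one codon")
  expect_error(
    translate_nt("AUGAAA", genetic_code(1), "require_terminal_stop"),
    "no stop codon"
  )
})

test_that("tables 1 and 4 translate differently iff UGA precedes the first UAA/UAG", {
  set.seed(13)
  for (k in 1:60) {
    nt <- random_rna(3L * sample(3:40, 1))
    codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
    first_uaag <- match(TRUE, codons %in% c("UAA", "UAG"),
                        nomatch = length(codons) + 1L)
    first_uga <- match("UGA", codons, nomatch = length(codons) + 2L)
    differs <- first_uga < first_uaag
    expect_identical(
      !identical(translate_nt(nt, genetic_code(1))$aa,
                 translate_nt(nt, genetic_code(4))$aa),
      differs, info = nt
    )
  }
})
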