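# seqcore: nucleotide records, genetic codes, composition, FASTA I/O.
#
# The internal alphabet is RNA (A, C, G, U, N): mitovirus genomes are +ssRNA
# and the codon architecture of interest is stated in terms of UGA/UGG.
# DNA input (T) is normalized to U on construction/load.

NUC_ALPHABET <- c("A", "C", "G", "U", "N")

#' Construct a nucleotide sequence record
#'
#' @param id Unique record identifier.
#' @param residues Nucleotide string over `A,C,G,U,N`; `T` is accepted and
#'   normalized to `U`, lower case is upcased.
#' @param description Optional free-text description.
#' @param source_tag Either `"input"` (real data) or `"synthetic"`.
#' @return An object of class `nuc_seq`.
#' @examples
#' nuc_seq("x", "ATGaaa")$residues  # "AUGAAA"
#' @export
nuc_seq <- function(id, residues, description = "",
                    source_tag = c("input", "synthetic")) {
  source_tag <- match.arg(source_tag)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- chartr("Tt", "Uu", residues)
  res <- toupper(res)
  if (!nzchar(res)) stop("nuc_seq '", id, "': residues must be non-empty")
  bad <- regmatches(res, regexpr("[^ACGUN]", res))
  if (length(bad) && nzchar(bad)) {
    stop("nuc_seq '", id, "': invalid symbol '", bad,
         "' (allowed: A, C, G, U/T, N)")
  }
  structure(
    list(id = id, residues = res, description = description,
         source_tag = source_tag),
    class = "nuc_seq"
  )
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s (%d nt, %s)\n", x$id, nchar(x$residues),
              x$source_tag))
  cat(" ", substr(x$residues, 1L, 60L),
      if (nchar(x$residues) > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

# reverse complement of a plain RNA string (A<->U, G<->C, N->N)
revcomp_chr <- function(s) {
  comp <- chartr("ACGUN", "UGCAN", s)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Reverse complement of a nucleotide record
#'
#' A<->U, G<->C, N->N, order reversed. Applying it twice returns the input.
#'
#' @param seq A [nuc_seq] object.
#' @return A `nuc_seq` with the same id and reverse-complemented residues.
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "nuc_seq"))
  out <- seq
  out$residues <- revcomp_chr(seq$residues)
  out
}

base_counts <- function(res) {
  r <- charToRaw(res)
  counts <- viapply(NUC_ALPHABET, function(b) sum(r == charToRaw(b)))
  names(counts) <- NUC_ALPHABET
  counts
}

#' Genome AU (UA) content
#'
#' Fraction of A plus U among unambiguous bases; `N` is excluded from both
#' numerator and denominator.
#'
#' @param seq A [nuc_seq] object.
#' @return An object of class `composition_stats` with fields `au_fraction`,
#'   `counted_bases` and `ambiguous_bases`.
#' @examples
#' au_content(nuc_seq("g", "AUGC"))$au_fraction  # 0.5
#' @export
au_content <- function(seq) {
  stopifnot(inherits(seq, "nuc_seq"))
  n <- base_counts(seq$residues)
  counted <- sum(n[c("A", "C", "G", "U")])
  if (counted == 0L) {
    stop("au_content '", seq$id, "': composition undefined (all bases are N)")
  }
  structure(
    list(au_fraction = (n[["A"]] + n[["U"]]) / counted,
         counted_bases = as.integer(counted),
         ambiguous_bases = n[["N"]]),
    class = "composition_stats"
  )
}

SUPPORTED_TABLES <- c(1L, 4L, 11L, 16L, 22L, 23L)

TABLE_NAMES <- c(
  "1"  = "Standard",
  "4"  = "Mold, Protozoan, and Coelenterate Mitochondrial",
  "11" = "Bacterial, Archaeal and Plant Plastid",
  "16" = "Chlorophycean Mitochondrial",
  "22" = "Scenedesmus obliquus Mitochondrial",
  "23" = "Thraustochytrium Mitochondrial"
)

#' Genetic-code table
#'
#' Wraps the NCBI translation tables relevant to mitovirus screening: the
#' standard code (1), the mold/protozoan mitochondrial code (4, UGA encodes
#' tryptophan), and the UGA-as-stop alternative codes 11, 16, 22 and 23.
#' Codons are keyed in RNA (U, not T).
#'
#' @param table_id One of 1, 4, 11, 16, 22, 23. Other tables are rejected.
#' @return An object of class `genetic_code` with fields `table_id`, `name`,
#'   `codon_to_aa` (named character of 64 codons, `"*"` = stop) and
#'   `start_codons`.
#' @examples
#' genetic_code(4)$codon_to_aa[["UGA"]]  # "W"
#' genetic_code(1)$codon_to_aa[["UGA"]]  # "*"
#' @export
genetic_code <- function(table_id) {
  table_id <- as.integer(table_id)
  if (length(table_id) != 1L || !table_id %in% SUPPORTED_TABLES) {
    stop("unsupported genetic-code table ", table_id,
         " (supported: ", paste(SUPPORTED_TABLES, collapse = ", "), ")")
  }
  gc <- Biostrings::getGeneticCode(as.character(table_id))
  map <- setNames(unname(gc), chartr("T", "U", names(gc)))
  alt <- attr(gc, "alt_init_codons")
  starts <- union("AUG", chartr("T", "U", alt %||% character()))
  structure(
    list(table_id = table_id,
         name = TABLE_NAMES[[as.character(table_id)]],
         codon_to_aa = map,
         start_codons = starts),
    class = "genetic_code"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> table %d (%s); UGA=%s UGG=%s\n", x$table_id,
              x$name, x$codon_to_aa[["UGA"]], x$codon_to_aa[["UGG"]]))
  invisible(x)
}

stop_codons <- function(code) names(code$codon_to_aa)[code$codon_to_aa == "*"]

# split a nucleotide string into complete triplets starting at `offset` (0-2)
codon_split <- function(nt, offset = 0L) {
  L <- nchar(nt)
  n <- (L - offset) %/% 3L
  if (n < 1L) return(character())
  starts <- offset + 3L * (seq_len(n) - 1L) + 1L
  substring(nt, starts, starts + 2L)
}

# map codons to amino acids; codons containing N translate to X
codons_to_aa <- function(codons, code) {
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a nucleotide string in frame 0
#'
#' Codons are read 5'->3' from the first position of `nt`; translation stops
#' at the first stop codon of the chosen code. Codons containing `N`
#' translate to `X`. Trailing bases that do not fill a codon are ignored.
#'
#' @param nt Nucleotide string (RNA or DNA letters), length >= 3.
#' @param code A [genetic_code].
#' @param stop_policy `"truncate_at_stop"` (default) truncates silently at the
#'   first stop (or end of sequence); `"require_terminal_stop"` raises an
#'   error if no stop codon is reached.
#' @return A list with `aa` (translated protein, stop excluded),
#'   `terminal_stop` (was a stop codon reached?) and `had_n` (did any
#'   translated codon contain `N`?).
#' @examples
#' translate_nt("AUGUGAUGGUAA", genetic_code(4))$aa  # "MWW"
#' translate_nt("AUGUGAUGGUAA", genetic_code(1))$aa  # "M"
#' @export
translate_nt <- function(nt, code,
                         stop_policy = c("truncate_at_stop",
                                         "require_terminal_stop")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(code, "genetic_code"))
  nt <- toupper(chartr("Tt", "Uu", nt))
  if (nchar(nt) < 3L) stop("translate_nt: need at least one codon (3 nt)")
  codons <- codon_split(nt)
  aa <- codons_to_aa(codons, code)
  first_stop <- match("*", aa)
  if (!is.na(first_stop)) {
    keep <- seq_len(first_stop - 1L)
    terminal <- TRUE
  } else {
    keep <- seq_along(aa)
    terminal <- FALSE
  }
  if (!terminal && stop_policy == "require_terminal_stop") {
    stop("translate_nt: no stop codon reached under table ", code$table_id)
  }
  list(aa = paste(aa[keep], collapse = ""),
       terminal_stop = terminal,
       had_n = any(aa[keep] == "X" & grepl("N", codons[keep])))
}

#' Read a FASTA file into nucleotide records
#'
#' Multi-record FASTA, wrapped or unwrapped. `T` is normalized to `U`;
#' duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param source_tag Tag stored on each record (`"input"` by default).
#' @return A list of [nuc_seq] objects (empty list for an empty file).
#' @export
load_fasta <- function(path, source_tag = c("input", "synthetic")) {
  source_tag <- match.arg(source_tag)
  if (!file.exists(path)) stop("load_fasta: no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("load_fasta: malformed FASTA in '", path,
                             "': ", conditionMessage(e))
  )
  if (length(set) == 0L) return(list())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("load_fasta: duplicate record id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  lapply(seq_along(set), function(i) {
    nuc_seq(ids[[i]], as.character(set[[i]]), description = descs[[i]],
            source_tag = source_tag)
  })
}

#' Write nucleotide records to FASTA
#'
#' @param seqs A list of [nuc_seq] objects.
#' @param path Output path.
#' @param dna If `TRUE`, emit T instead of U.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, dna = FALSE, width = 70L) {
  stopifnot(all(vapply(seqs, inherits, logical(1L), "nuc_seq")))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (s in seqs) {
    header <- if (nzchar(s$description)) {
      paste(s$id, s$description)
    } else s$id
    res <- if (dna) chartr("U", "T", s$residues) else s$residues
    writeLines(paste0(">", header), con)
    L <- nchar(res)
    starts <- seq(1L, L, by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, L)), con)
  }
  invisible(path)
}
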