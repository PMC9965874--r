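# orf_scan: six-frame ORF deduction, the single-long-ORF criterion, and the
# reverse-strand (ambigrammatic) scan.
#
# Conventions (documented on the OrfRecord columns below):
#   * coordinates are 1-based inclusive on the *scanned* strand (for "-" ORFs
#     that is the reverse complement of the input record);
#   * nt_len includes the terminal stop codon when one is present;
#   * one ORF per stop-free segment, starting at the first permitted start
#     codon (ORFfinder-style "longest ORF per stop"); nested ORFs are not
#     emitted.

empty_orf_frame <- function() {
  data.frame(seq_id = character(), strand = character(), frame = integer(),
             start = integer(), end = integer(), nt_len = integer(),
             aa_len = integer(), aa_seq = character(), table_id = integer(),
             has_terminal_stop = logical(), stringsAsFactors = FALSE)
}

scan_strand_frame <- function(s, seq_id, strand, frame, code, start_rule) {
  codons <- codon_split(s, offset = frame)
  n <- length(codons)
  if (n == 0L) return(NULL)
  stops <- which(codons %in% stop_codons(code))
  seg_start <- c(1L, stops + 1L)
  seg_end <- c(stops - 1L, n)            # stop-free span, stop excluded
  closing <- c(stops, NA_integer_)       # index of the closing stop, if any
  rows <- vector("list", length(seg_start))
  for (k in seq_along(seg_start)) {
    a <- seg_start[[k]]; b <- seg_end[[k]]
    if (a > b) next                       # empty segment (adjacent stops)
    first <- if (start_rule == "AUG_only") {
      hit <- match("AUG", codons[a:b])
      if (is.na(hit)) next
      a + hit - 1L
    } else a
    has_stop <- !is.na(closing[[k]])
    last_codon <- if (has_stop) closing[[k]] else b
    nt_len <- (last_codon - first + 1L) * 3L
    start_nt <- frame + (first - 1L) * 3L + 1L
    aa <- codons_to_aa(codons[first:b], code)
    rows[[k]] <- data.frame(
      seq_id = seq_id, strand = strand, frame = frame,
      start = start_nt, end = start_nt + nt_len - 1L, nt_len = nt_len,
      aa_len = length(aa), aa_seq = paste(aa, collapse = ""),
      table_id = code$table_id, has_terminal_stop = has_stop,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) NULL else do.call(rbind, rows)
}

#' Deduce open reading frames under a genetic code
#'
#' Each requested strand is scanned in its three frames; every frame is
#' partitioned by in-frame stop codons and one ORF is emitted per stop-free
#' segment (from the first permitted start codon to the closing stop,
#' included in `nt_len`). Segments reaching the 3' end without a stop are
#' emitted with `has_terminal_stop = FALSE`. Codons containing `N` are never
#' stops and translate to `X`.
#'
#' @param seq A [nuc_seq].
#' @param code A [genetic_code].
#' @param min_nt Minimum ORF length in nt (inclusive); shorter ORFs are
#'   suppressed. Must be >= 3.
#' @param strands Subset of `c("+", "-")`.
#' @param start_rule `"AUG_only"` (segments without AUG yield no ORF) or
#'   `"any_codon"` (the segment itself is the ORF).
#' @return A data frame of ORF records sorted by `nt_len` descending, ties by
#'   strand then start ascending. Coordinates are 1-based inclusive on the
#'   scanned strand.
#' @examples
#' s <- nuc_seq("x", "AUGAAAUAA")
#' find_orfs(s, genetic_code(1), min_nt = 3, strands = "+")$aa_seq  # "MK"
#' @export
find_orfs <- function(seq, code, min_nt = 3L, strands = c("+", "-"),
                      start_rule = c("AUG_only", "any_codon")) {
  stopifnot(inherits(seq, "nuc_seq"), inherits(code, "genetic_code"))
  start_rule <- match.arg(start_rule)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  min_nt <- as.integer(min_nt)
  if (min_nt < 3L) stop("find_orfs: min_nt must be >= 3")
  out <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq$residues else revcomp_chr(seq$residues)
    for (frame in 0:2) {
      out[[length(out) + 1L]] <-
        scan_strand_frame(s, seq$id, strand, frame, code, start_rule)
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  orfs <- if (length(out)) do.call(rbind, out) else empty_orf_frame()
  orfs <- orfs[orfs$nt_len >= min_nt, , drop = FALSE]
  ord <- order(-orfs$nt_len, orfs$strand, orfs$start)
  orfs <- orfs[ord, , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' The single-long-ORF criterion
#'
#' Tries each genetic code in order on the + strand (candidate contigs are
#' oriented transcripts) and returns, for the first code yielding at least
#' one AUG-initiated ORF strictly longer than `min_nt`, the longest such ORF.
#' The `single` flag records whether exactly one + strand ORF exceeded
#' `min_nt` under that code.
#'
#' @param seq A [nuc_seq].
#' @param codes List of [genetic_code] objects, tried in order. Default:
#'   table 4 then table 1.
#' @param min_nt Exclusive length threshold in nt (default 1000: the filter
#'   keeps ORFs of **more than** 1000 nt).
#' @return `NULL` when no code yields a long ORF, otherwise a list with
#'   `orf` (one-row ORF data frame), `table_id`, `single` and `n_long`.
#' @export
single_long_orf <- function(seq,
                            codes = list(genetic_code(4L), genetic_code(1L)),
                            min_nt = 1000L) {
  stopifnot(length(codes) >= 1L)
  for (code in codes) {
    orfs <- find_orfs(seq, code, min_nt = 3L, strands = "+",
                      start_rule = "AUG_only")
    long <- orfs[orfs$nt_len > min_nt, , drop = FALSE]
    if (nrow(long) >= 1L) {
      return(list(orf = long[1L, , drop = FALSE],
                  table_id = code$table_id,
                  single = nrow(long) == 1L,
                  n_long = nrow(long)))
    }
  }
  NULL
}

#' Reverse-strand (ambigrammatic) ORF scan
#'
#' Scans the reverse complement for long uninterrupted ORFs, the hallmark of
#' ambigrammatic narnavirus-like genomes. Any codon can open the ORF and the
#' length threshold is inclusive (an ORF of exactly `min_nt` nt counts).
#'
#' @param seq A [nuc_seq].
#' @param code A [genetic_code]; default table 1.
#' @param min_nt Inclusive threshold in nt (default 1000).
#' @return A list with `ambigrammatic` (flag), `max_nt` (longest reverse ORF,
#'   0 if none) and `n` (number of reverse ORFs >= `min_nt`).
#' @export
reverse_orf_scan <- function(seq, code = genetic_code(1L), min_nt = 1000L) {
  orfs <- find_orfs(seq, code, min_nt = min_nt, strands = "-",
                    start_rule = "any_codon")
  list(ambigrammatic = nrow(orfs) > 0L,
       max_nt = if (nrow(orfs)) max(orfs$nt_len) else 0L,
       n = nrow(orfs))
}

#' Write an ORF report as TSV
#'
#' @param orfs A data frame from [find_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_report <- function(orfs, path) {
  cols <- c("seq_id", "strand", "frame", "start", "end", "nt_len",
            "table_id", "has_terminal_stop", "aa_len")
  write.table(orfs[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
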