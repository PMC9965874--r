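# codon_arch: per-ORF UGA/UGG profiling and the genome-architecture call
# (UGA-free vs UGA-containing vs ambigrammatic).
#
# "Internal" codons are all codons of the deduced ORF except the terminal
# stop; the start codon is included, since the distinguishing feature is the
# absence of in-frame UGA anywhere within the coding span.

ARCH_LABELS <- c("UGA_FREE", "UGA_CONTAINING", "AMBIGRAMMATIC", "UNCLASSIFIED")

#' Codon-usage profile of a deduced ORF
#'
#' Counts internal in-frame UGA and UGG codons (the two tryptophan codons
#' under the mold mitochondrial code), tabulates all internal codons
#' (excluding codons containing `N`), and attaches the genome-wide AU
#' fraction. The UGA/UGG ratio is undefined (`NA`) when no UGG is present.
#'
#' @param orf A one-row ORF data frame from [find_orfs()] /
#'   [single_long_orf()].
#' @param genome The [nuc_seq] the ORF was deduced from.
#' @return An object of class `codon_profile`.
#' @export
codon_profile <- function(orf, genome) {
  stopifnot(inherits(genome, "nuc_seq"), is.data.frame(orf), nrow(orf) == 1L)
  if (orf$seq_id != genome$id) {
    stop("codon_profile: ORF belongs to '", orf$seq_id,
         "', not to genome '", genome$id, "'")
  }
  s <- if (orf$strand == "+") genome$residues else revcomp_chr(genome$residues)
  if (orf$end > nchar(s)) stop("codon_profile: ORF coordinates exceed genome")
  nt <- substr(s, orf$start, orf$end)
  codons <- codon_split(nt)
  code <- genetic_code(orf$table_id)
  internal <- if (orf$has_terminal_stop) {
    codons[-length(codons)]
  } else codons
  aa_check <- paste(codons_to_aa(internal, code), collapse = "")
  if (!identical(aa_check, orf$aa_seq)) {
    stop("codon_profile: ORF record does not match genome '", genome$id,
         "' (translation differs)")
  }
  has_n <- grepl("N", internal, fixed = TRUE)
  counted <- internal[!has_n]
  uga <- sum(counted == "UGA")
  ugg <- sum(counted == "UGG")
  structure(
    list(seq_id = genome$id,
         uga_count = uga,
         ugg_count = ugg,
         trp_total = uga + ugg,
         uga_ugg_ratio = if (ugg > 0L) uga / ugg else NA_real_,
         au_fraction = au_content(genome)$au_fraction,
         codon_counts = table(factor(counted, levels = names(code$codon_to_aa))),
         table_id = orf$table_id,
         n_excluded_codons = sum(has_n),
         orf_nt_len = orf$nt_len,
         aa_len = orf$aa_len),
    class = "codon_profile"
  )
}

#' @export
print.codon_profile <- function(x, ...) {
  cat(sprintf(
    "<codon_profile> %s: UGA=%d UGG=%d ratio=%s AU=%.1f%% (table %d)\n",
    x$seq_id, x$uga_count, x$ugg_count,
    ifelse(is.na(x$uga_ugg_ratio), "NA", sprintf("%.2f", x$uga_ugg_ratio)),
    100 * x$au_fraction, x$table_id))
  invisible(x)
}

#' Classify the coding architecture of a candidate genome
#'
#' Decision order: (1) a reverse ORF of >= `reverse_min_nt` makes the genome
#' `AMBIGRAMMATIC`; (2) no single long forward ORF means `UNCLASSIFIED`;
#' (3) no internal UGA with at least one UGG is `UGA_FREE` (tryptophan
#' encoded only by UGG); (4) any internal UGA is `UGA_CONTAINING`;
#' (5) otherwise (no tryptophan codon at all) `UNCLASSIFIED`.
#'
#' @param genome A [nuc_seq].
#' @param config A [curation_config()]; supplies the table order, the long-ORF
#'   threshold and the reverse-scan threshold.
#' @return An object of class `arch_call`: `label`, `evidence` (reason
#'   codes), `profile` (a [codon_profile] or `NULL`) and `reverse_max_nt`.
#' @export
classify_architecture <- function(genome, config = curation_config()) {
  stopifnot(inherits(genome, "nuc_seq"))
  rev <- reverse_orf_scan(genome, genetic_code(1L),
                          min_nt = config$reverse_min_nt)
  slo <- single_long_orf(genome,
                         codes = lapply(config$table_order, genetic_code),
                         min_nt = config$min_orf_nt)
  profile <- if (!is.null(slo)) codon_profile(slo$orf, genome) else NULL
  if (rev$ambigrammatic) {
    label <- "AMBIGRAMMATIC"
    evidence <- sprintf("reverse_orf_%dnt", rev$max_nt)
  } else if (is.null(slo)) {
    label <- "UNCLASSIFIED"
    evidence <- "no_single_long_orf"
  } else if (profile$uga_count == 0L && profile$ugg_count >= 1L) {
    label <- "UGA_FREE"
    evidence <- c("no_internal_uga", sprintf("ugg_count_%d", profile$ugg_count))
  } else if (profile$uga_count >= 1L) {
    label <- "UGA_CONTAINING"
    evidence <- sprintf("internal_uga_count_%d", profile$uga_count)
  } else {
    label <- "UNCLASSIFIED"
    evidence <- "no_tryptophan_codon"
  }
  structure(
    list(seq_id = genome$id, label = label, evidence = evidence,
         profile = profile, reverse_max_nt = rev$max_nt),
    class = "arch_call"
  )
}

#' @export
print.arch_call <- function(x, ...) {
  cat(sprintf("<arch_call> %s: %s [%s]\n", x$seq_id, x$label,
              paste(x$evidence, collapse = "; ")))
  invisible(x)
}

profile_of <- function(x) {
  if (inherits(x, "arch_call")) x$profile else x
}

#' Summarize codon architecture over a cohort
#'
#' @param profiles A list of [codon_profile] objects and/or `arch_call`
#'   objects (labels are tallied when available).
#' @return A list with `n`, `label_counts`, `au_mean_pct`, `au_sd_pct`
#'   (sample SD, `NA` when n < 2) and `ratios` (UGA/UGG ratio per record,
#'   `NA` where undefined).
#' @examples
#' # two genomes at 50% and 60% AU -> mean 55, SD ~7.071
#' @export
summarize_cohort <- function(profiles) {
  if (length(profiles) == 0L) stop("summarize_cohort: empty cohort")
  labels <- vcapply(profiles, function(x) {
    if (inherits(x, "arch_call")) x$label else NA_character_
  })
  profs <- lapply(profiles, profile_of)
  keep <- !vapply(profs, is.null, logical(1L))
  au <- 100 * vdapply(profs[keep], function(p) p$au_fraction)
  ratios <- vdapply(profs[keep], function(p) p$uga_ugg_ratio)
  list(n = length(profiles),
       label_counts = table(factor(labels[!is.na(labels)],
                                   levels = ARCH_LABELS)),
       au_mean_pct = mean(au),
       au_sd_pct = if (length(au) >= 2L) stats::sd(au) else NA_real_,
       ratios = ratios)
}
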