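# curation: the filter chain that turns raw candidate contigs into a curated,
# non-redundant set — single long ORF, ordered RdRp motif presence, then
# >threshold-identity deduplication — with a per-record audit trail.

MOTIF_IDS <- c("I", "II", "III", "IV", "V", "VI")

#' Define a degenerate amino-acid motif
#'
#' Pattern syntax: fixed letters match themselves, `X` matches any residue,
#' `[ABC]` matches any listed residue. `max_mismatch` mismatches are
#' tolerated at fixed-letter positions only (wildcards and bracketed
#' positions are not relaxed).
#'
#' @param motif_id One of `"I".."VI"`.
#' @param pattern Degenerate pattern, length >= 3 positions.
#' @param max_mismatch Allowed mismatches at fixed-letter positions.
#' @return An object of class `motif_def`.
#' @export
motif_def <- function(motif_id, pattern, max_mismatch = 0L) {
  motif_id <- match.arg(motif_id, MOTIF_IDS)
  toks <- parse_motif_pattern(pattern)
  if (length(toks) < 3L) stop("motif ", motif_id, ": pattern too short (<3)")
  structure(
    list(motif_id = motif_id, pattern = pattern,
         tokens = toks, max_mismatch = as.integer(max_mismatch)),
    class = "motif_def"
  )
}

# tokens: list, one per position; NULL = wildcard X, character vector =
# allowed letters; attribute "fixed" marks single fixed letters
parse_motif_pattern <- function(pattern) {
  raw <- regmatches(pattern,
                    gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  if (!length(raw) || sum(nchar(raw)) != nchar(pattern)) {
    stop("cannot parse motif pattern: ", pattern)
  }
  lapply(raw, function(tok) {
    if (tok == "X") return(NULL)
    if (startsWith(tok, "[")) {
      strsplit(gsub("\\[|\\]", "", tok), "")[[1]]
    } else {
      structure(tok, fixed = TRUE)
    }
  })
}

# canonical instance: first listed letter for brackets, A for wildcards
motif_canonical <- function(motif) {
  paste(vcapply(motif$tokens, function(t) if (is.null(t)) "A" else t[[1]]),
        collapse = "")
}

#' Default RdRp motif set
#'
#' Six ordered degenerate patterns standing in for the conserved mitovirus
#' RdRp domain motifs I-VI. These defaults are a *synthetic fixture*: they
#' carry the canonical RdRp flavor (including the universal `GDD` catalytic
#' core in motif IV and an invariant tryptophan in motif I) but are not a
#' curated alignment-derived profile; override them via
#' [curation_config()] / the YAML config for real screens.
#'
#' @return A list of six [motif_def] objects, in order I-VI.
#' @export
default_motifs <- function() {
  list(
    motif_def("I",   "KXW[LIVM]DG"),
    motif_def("II",  "P[DE]XXRG"),
    motif_def("III", "[ST]GXPXE"),
    motif_def("IV",  "[LIVMF]YGDD"),
    motif_def("V",   "GX[QN]KXE"),
    motif_def("VI",  "[KR]FX[LIVM]SR")
  )
}

# leftmost match of one motif at window positions from..(n-k+1); returns the
# 1-based start or NA
motif_leftmost <- function(chars, motif, from) {
  k <- length(motif$tokens)
  n <- length(chars)
  if (from > n - k + 1L) return(NA_integer_)
  starts <- from:(n - k + 1L)
  mism <- integer(length(starts))
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    tok <- motif$tokens[[j]]
    if (is.null(tok)) next
    cj <- chars[starts + j - 1L]
    if (isTRUE(attr(tok, "fixed"))) {
      mism <- mism + (cj != as.character(tok))
    } else {
      ok <- ok & cj %in% tok
    }
  }
  hit <- which(ok & mism <= motif$max_mismatch)
  if (!length(hit)) NA_integer_ else starts[hit[[1L]]]
}

#' Scan a protein for ordered motifs
#'
#' Finds the leftmost match of each motif; with `order_enforced` each motif
#' is searched only after the end of the previous motif's hit. The scan
#' passes when all motifs are found (in order).
#'
#' @param protein Amino-acid string.
#' @param motifs List of [motif_def] objects (default [default_motifs()]).
#' @param order_enforced Require hits in motif order.
#' @param require_all Pass only if every motif matched.
#' @return A list with `hits` (data frame: motif_id, start, matched),
#'   `pass` and `missing` (motif ids without a hit).
#' @export
motif_scan <- function(protein, motifs = default_motifs(),
                       order_enforced = TRUE, require_all = TRUE) {
  stopifnot(length(motifs) >= 1L)
  chars <- strsplit(protein, "")[[1]]
  pos <- 0L
  hits <- list(); missing <- character()
  for (m in motifs) {
    from <- if (order_enforced) pos + 1L else 1L
    at <- motif_leftmost(chars, m, from)
    if (is.na(at)) {
      missing <- c(missing, m$motif_id)
      next
    }
    k <- length(m$tokens)
    hits[[length(hits) + 1L]] <- data.frame(
      motif_id = m$motif_id, start = at,
      matched = paste(chars[at:(at + k - 1L)], collapse = ""),
      stringsAsFactors = FALSE
    )
    if (order_enforced) pos <- at + k - 1L
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif_id = character(), start = integer(),
               matched = character(), stringsAsFactors = FALSE)
  pass <- if (require_all) length(missing) == 0L else nrow(hits) > 0L
  list(hits = hits, pass = pass, missing = missing)
}

#' Pairwise percent identity by global alignment
#'
#' End-to-end dynamic-programming alignment with fixed, reproducible scoring
#' (match +1, mismatch 0, gap -1, linear gaps; deterministic traceback
#' preferring diagonal moves, then a gap in `a`, then a gap in `b`).
#' Identity is 100 x identical columns / alignment length, gap columns
#' counted in the denominator. Symmetric, and 100 exactly iff the sequences
#' are identical.
#'
#' @param a,b Sequences: plain strings or [nuc_seq] objects.
#' @param level `"nucleotide"` or `"protein"` (bookkeeping only; both
#'   sequences must be at the same level).
#' @return Percent identity (numeric scalar) with attributes `matches` and
#'   `alignment_length`.
#' @examples
#' pairwise_identity("ACGU", "ACGA")  # 75
#' @export
pairwise_identity <- function(a, b, level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  sa <- if (inherits(a, "nuc_seq")) a$residues else a
  sb <- if (inherits(b, "nuc_seq")) b$residues else b
  stopifnot(is.character(sa), is.character(sb),
            length(sa) == 1L, length(sb) == 1L)
  if (!nzchar(sa) || !nzchar(sb)) stop("pairwise_identity: empty sequence")
  res <- align_identity_cpp(sa, sb)
  structure(res$identity_pct, matches = res$matches,
            alignment_length = res$alignment_length)
}

#' Greedy single-linkage deduplication at an identity threshold
#'
#' Records are visited by decreasing sequence length (ties: id ascending);
#' each record joins the first existing cluster whose *representative* it
#' exceeds `threshold_pct` identity with, otherwise it founds a new cluster.
#' The representative is always the founding (longest) member. An exact
#' length-ratio bound (identity <= 100 x min/max length) is used to skip
#' alignments that cannot reach the threshold; this cannot change the
#' result.
#'
#' @param records List of [nuc_seq] objects, or a named character vector of
#'   sequences (names = ids).
#' @param threshold_pct Strict identity threshold (default 90: records
#'   sharing **more than** 90% identity are merged).
#' @return A list with `clusters` (named list representative -> member ids),
#'   `representatives` and `membership` (data frame id, representative).
#' @export
dedup <- function(records, threshold_pct = 90) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    ids <- names(records); seqs <- unname(records)
  } else {
    ids <- vcapply(records, function(r) r$id)
    seqs <- vcapply(records, function(r) r$residues)
  }
  if (anyDuplicated(ids)) stop("dedup: duplicate ids")
  if (!length(ids)) {
    return(list(clusters = list(), representatives = character(),
                membership = data.frame(id = character(),
                                        representative = character())))
  }
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  lens <- nchar(seqs)
  rep_idx <- integer()
  assign_rep <- character(length(ids))
  for (i in seq_along(ids)) {
    joined <- NA_integer_
    for (r in rep_idx) {
      lmin <- min(lens[[i]], lens[[r]]); lmax <- max(lens[[i]], lens[[r]])
      if (100 * lmin / lmax <= threshold_pct) next
      if (identical(seqs[[i]], seqs[[r]])) { joined <- r; break }
      # exact score-based bound: identity along any optimal-score alignment
      # cannot exceed 2*lmin/(la+lb+lmin-score); skip the traceback pass
      # (which fixes the reported identity) when the bound cannot clear the
      # threshold
      score <- align_score_cpp(seqs[[i]], seqs[[r]])
      bound <- 200 * lmin / (lmin + lmax + lmin - score)
      if (bound <= threshold_pct) next
      idy <- as.numeric(pairwise_identity(seqs[[i]], seqs[[r]]))
      if (idy > threshold_pct) { joined <- r; break }
    }
    if (is.na(joined)) {
      rep_idx <- c(rep_idx, i)
      assign_rep[[i]] <- ids[[i]]
    } else {
      assign_rep[[i]] <- ids[[joined]]
    }
  }
  reps <- ids[rep_idx]
  clusters <- lapply(setNames(reps, reps),
                     function(r) ids[assign_rep == r])
  list(clusters = clusters, representatives = reps,
       membership = data.frame(id = ids, representative = assign_rep,
                               stringsAsFactors = FALSE))
}

#' Curation configuration
#'
#' @param min_orf_nt Exclusive forward-ORF length threshold (nt); default
#'   1000 (keep ORFs > 1000 nt).
#' @param identity_threshold_pct Strict dedup threshold; default 90.
#' @param table_order Genetic-code tables tried in order; default `c(4, 1)`.
#' @param require_all_motifs All six motifs must match.
#' @param motif_order_enforced Motifs must appear in order I-VI.
#' @param dedup_level Deduplicate on `"nucleotide"` contigs (default) or on
#'   deduced `"protein"` sequences.
#' @param motifs Motif set (default [default_motifs()]).
#' @param reverse_min_nt Inclusive reverse-ORF threshold (nt); default 1000.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(min_orf_nt = 1000L,
                            identity_threshold_pct = 90,
                            table_order = c(4L, 1L),
                            require_all_motifs = TRUE,
                            motif_order_enforced = TRUE,
                            dedup_level = c("nucleotide", "protein"),
                            motifs = default_motifs(),
                            reverse_min_nt = 1000L) {
  dedup_level <- match.arg(dedup_level)
  identity_threshold_pct <- as.numeric(identity_threshold_pct)
  stopifnot(identity_threshold_pct > 0, identity_threshold_pct <= 100)
  stopifnot(all(table_order %in% SUPPORTED_TABLES))
  structure(
    list(min_orf_nt = as.integer(min_orf_nt),
         identity_threshold_pct = identity_threshold_pct,
         table_order = as.integer(table_order),
         require_all_motifs = isTRUE(require_all_motifs),
         motif_order_enforced = isTRUE(motif_order_enforced),
         dedup_level = dedup_level,
         motifs = motifs,
         reverse_min_nt = as.integer(reverse_min_nt)),
    class = "curation_config"
  )
}

#' Read a curation configuration from YAML
#'
#' Recognized keys mirror [curation_config()] arguments; `motifs` is a list
#' of `{motif_id, pattern, max_mismatch}` entries. Missing keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `curation_config`.
#' @export
read_curation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("min_orf_nt", "identity_threshold_pct",
                          "table_order", "require_all_motifs",
                          "motif_order_enforced", "dedup_level",
                          "reverse_min_nt"))]
  if (!is.null(raw$motifs)) {
    args$motifs <- lapply(raw$motifs, function(m) {
      motif_def(m$motif_id, m$pattern, m$max_mismatch %||% 0L)
    })
  }
  do.call(curation_config, args)
}

#' Run the full curation filter chain
#'
#' Applies, in order and with short-circuiting per record: the single-long-ORF
#' filter, the ordered motif scan on the deduced protein, and identity
#' deduplication among the survivors. Kept records are then profiled and
#' architecture-classified. Deterministic for a fixed input order.
#'
#' @param genomes List of [nuc_seq] objects.
#' @param config A [curation_config()].
#' @return An object of class `curation_report`: `outcomes` (per-record data
#'   frame with filter results and reason codes), `clusters`, `kept`
#'   (character ids), `calls` (named list of `arch_call` for kept records),
#'   `kept_seqs` and `config`.
#' @export
curate <- function(genomes, config = curation_config()) {
  stopifnot(all(vapply(genomes, inherits, logical(1L), "nuc_seq")))
  ids <- vcapply(genomes, function(g) g$id)
  if (anyDuplicated(ids)) stop("curate: duplicate genome ids")
  n <- length(genomes)
  outcomes <- data.frame(
    id = ids,
    orf_filter = rep("fail", n), motif_filter = rep("skipped", n),
    dedup = rep("skipped", n), reason = rep("", n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(structure(list(outcomes = outcomes, clusters = list(),
                          kept = character(), calls = list(),
                          kept_seqs = list(), config = config),
                     class = "curation_report"))
  }
  codes <- lapply(config$table_order, genetic_code)
  survivors <- character()
  proteins <- character()
  for (i in seq_len(n)) {
    slo <- single_long_orf(genomes[[i]], codes = codes,
                           min_nt = config$min_orf_nt)
    if (is.null(slo)) {
      outcomes$reason[i] <- sprintf("orf_absent:no_orf_gt_%dnt",
                                    config$min_orf_nt)
      next
    }
    if (!slo$single) {
      outcomes$reason[i] <- sprintf("orf_absent:%d_long_orfs", slo$n_long)
      next
    }
    outcomes$orf_filter[i] <- "pass"
    scan <- motif_scan(slo$orf$aa_seq, motifs = config$motifs,
                       order_enforced = config$motif_order_enforced,
                       require_all = config$require_all_motifs)
    if (!scan$pass) {
      outcomes$motif_filter[i] <- "fail"
      outcomes$reason[i] <- paste0("motif_absent:",
                                   paste(scan$missing, collapse = ","))
      next
    }
    outcomes$motif_filter[i] <- "pass"
    survivors <- c(survivors, ids[[i]])
    proteins <- c(proteins, slo$orf$aa_seq)
  }
  names(proteins) <- survivors
  dd_input <- if (config$dedup_level == "nucleotide") {
    genomes[match(survivors, ids)]
  } else proteins
  dd <- dedup(dd_input, threshold_pct = config$identity_threshold_pct)
  kept <- dd$representatives
  for (id in survivors) {
    i <- match(id, ids)
    if (id %in% kept) {
      outcomes$dedup[i] <- "kept"
    } else {
      rep_id <- dd$membership$representative[dd$membership$id == id]
      outcomes$dedup[i] <- "redundant"
      outcomes$reason[i] <- paste0("redundant:duplicate_of_", rep_id)
    }
  }
  kept_seqs <- genomes[match(kept, ids)]
  calls <- lapply(kept_seqs, classify_architecture, config = config)
  names(calls) <- kept
  structure(
    list(outcomes = outcomes, clusters = dd$clusters, kept = kept,
         calls = calls, kept_seqs = kept_seqs, config = config),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d records in, %d kept\n",
              nrow(x$outcomes), length(x$kept)))
  elim <- x$outcomes$reason[nzchar(x$outcomes$reason)]
  if (length(elim)) {
    tab <- table(sub(":.*$", "", elim))
    for (k in names(tab)) cat(sprintf("  eliminated %s: %d\n", k, tab[[k]]))
  }
  invisible(x)
}

#' Write curation outputs as TSV/FASTA
#'
#' Writes `curation_report.tsv`, `classification.tsv`, `clusters.tsv` and
#' `kept.fasta` into `dir`.
#'
#' @param report A `curation_report` from [curate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_curation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$outcomes, file.path(dir, "curation_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- do.call(rbind, lapply(report$calls, function(cl) {
    p <- cl$profile
    data.frame(
      seq_id = cl$seq_id, label = cl$label,
      uga_count = if (is.null(p)) NA_integer_ else p$uga_count,
      ugg_count = if (is.null(p)) NA_integer_ else p$ugg_count,
      ratio = if (is.null(p)) NA_real_ else p$uga_ugg_ratio,
      au_pct = if (is.null(p)) NA_real_ else 100 * p$au_fraction,
      orf_nt_len = if (is.null(p)) NA_integer_ else p$orf_nt_len,
      table_id = if (is.null(p)) NA_integer_ else p$table_id,
      reverse_orf_max_nt = cl$reverse_max_nt,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(cls)) cls <- data.frame()
  write.table(cls, file.path(dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clus <- do.call(rbind, lapply(names(report$clusters), function(r) {
    data.frame(representative = r,
               member = report$clusters[[r]], stringsAsFactors = FALSE)
  }))
  if (is.null(clus)) clus <- data.frame()
  write.table(clus, file.path(dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(report$kept_seqs, file.path(dir, "kept.fasta"))
  invisible(dir)
}
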