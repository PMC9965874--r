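# Shared fixtures and independent oracles. Oracles deliberately use a
# different route than the implementation: plain per-codon loops for ORF
# enumeration, R's regex engine for motif scanning, all-pairs connected
# components for deduplication.

RNA4 <- c("A", "C", "G", "U")

random_rna <- function(len, alphabet = RNA4) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# --- brute-force six-frame ORF oracle ---------------------------------------
# Enumerates every candidate start codon in every frame of every strand,
# keeps only first-in-segment starts, walks forward to the next in-frame
# stop. Plain loops, no shared scanning code.
oracle_find_orfs <- function(seq, code, min_nt = 3L, strands = c("+", "-"),
                             start_rule = "AUG_only") {
  stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq$residues else
      reverse_complement(seq)$residues
    L <- nchar(s)
    for (frame in 0:2) {
      n <- (L - frame) %/% 3L
      if (n < 1L) next
      codons <- character(n)
      for (k in seq_len(n)) {
        p <- frame + 3L * (k - 1L) + 1L
        codons[[k]] <- substr(s, p, p + 2L)
      }
      is_stop <- codons %in% stops
      for (k in seq_len(n)) {
        if (is_stop[[k]]) next
        if (start_rule == "AUG_only" && codons[[k]] != "AUG") next
        # first permitted start of its segment?
        first <- TRUE
        j <- k - 1L
        while (j >= 1L && !is_stop[[j]]) {
          if (start_rule != "AUG_only" || codons[[j]] == "AUG") {
            first <- FALSE; break
          }
          j <- j - 1L
        }
        if (!first) next
        m <- k
        while (m <= n && !is_stop[[m]]) m <- m + 1L
        has_stop <- m <= n
        last <- if (has_stop) m else n
        nt_len <- 3L * (last - k + 1L)
        if (nt_len < min_nt) next
        aa <- unname(code$codon_to_aa[codons[k:(if (has_stop) m - 1L else n)]])
        aa[is.na(aa)] <- "X"
        start_nt <- frame + 3L * (k - 1L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq$id, strand = strand, frame = frame,
          start = start_nt, end = start_nt + nt_len - 1L, nt_len = nt_len,
          aa_len = length(aa), aa_seq = paste(aa, collapse = ""),
          table_id = code$table_id, has_terminal_stop = has_stop,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    mitoscreen:::empty_orf_frame()
  out <- out[order(-out$nt_len, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- regex motif oracle ------------------------------------------------------
# Valid only for max_mismatch = 0 motifs: the degenerate pattern maps
# directly onto a regular expression (X -> ., brackets kept).
oracle_motif_pass <- function(protein, motifs, order_enforced = TRUE) {
  pos <- 1L
  for (m in motifs) {
    stopifnot(m$max_mismatch == 0L)
    rex <- gsub("X", ".", m$pattern, fixed = TRUE)
    tail_str <- substr(protein, pos, nchar(protein))
    hit <- regexpr(rex, tail_str)
    if (hit < 0L) return(FALSE)
    if (order_enforced) {
      pos <- pos + as.integer(hit) - 1L + attr(hit, "match.length")
    }
  }
  TRUE
}

# protein carrying the canonical instance of each motif, in the given order,
# separated by fixed-length random linkers
planted_protein <- function(motifs, linker = 10L, order = seq_along(motifs)) {
  canon <- vapply(motifs, mitoscreen:::motif_canonical, character(1L))
  paste0(
    paste0(vapply(order, function(k) {
      paste0(random_protein(linker), canon[[k]])
    }, character(1L)), collapse = ""),
    random_protein(linker)
  )
}

# --- all-pairs single-linkage dedup oracle ----------------------------------
oracle_single_linkage <- function(records, threshold_pct) {
  ids <- vapply(records, function(r) r$id, character(1L))
  n <- length(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        idy <- as.numeric(pairwise_identity(records[[i]], records[[j]]))
        adj[i, j] <- adj[j, i] <- idy > threshold_pct
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[[i]])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(ids, comp)
}

# partition comparison helper: set of sorted member sets
as_partition <- function(clusters) {
  unname(lapply(clusters, sort)) |> (\(x) x[order(vapply(x, paste,
    character(1L), collapse = ","))])()
}
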