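# synthetic_data: generator of mitovirus-like genomes and fixture trees with
# the statistical structure the analysis assumes, plus per-record ground
# truth. Every emitted genome is self-verified against the package's own
# pipeline at generation time; violations are an error, never silent.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# forward codons whose reverse complement is a standard-code stop; excluding
# them from a codon stretch guarantees a stop-free reverse-frame run there
REV_STOP_FORWARD <- c("UUA", "CUA", "UCA")

#' Generator presets
#'
#' Bundles the study conditions each cohort emulates:
#' * `arkeo` — basal "clade B"-like genomes: standard code (table 1), no
#'   internal UGA, AU target Normal(54.6, 4.1) truncated to \[45, 59.9\] so
#'   the cohort stays below 60% AU.
#' * `mitovirinae` — formal-mitovirus-like genomes: mold mitochondrial code
#'   (table 4), AU Uniform(60, 70), half of the tryptophans written as UGA.
#' * `kvara` — Kvaramitovirus-like genomes: table 4, AU Uniform(67, 73).
#' * `ambigram` — narnavirus-like control: as `arkeo` but with a forced
#'   reverse-strand stop-free stretch of >= 1200 nt.
#'
#' @param name Preset name.
#' @param genome_len_range Genome length range in nt (default 2151-4955).
#' @param utr_len_range Per-side UTR length range in nt.
#' @param uga_w_fraction Fraction of tryptophan codons written as UGA
#'   (table-4 presets; forced to 0 under table 1).
#' @param motif_set Motif definitions planted in order I-VI
#'   (default [default_motifs()]).
#' @param ... Overrides for `table_id`, `au` (a list describing the AU target
#'   distribution), `force_reverse_orf`.
#' @return An object of class `generator_preset`.
#' @export
generator_preset <- function(name = c("arkeo", "mitovirinae", "kvara",
                                      "ambigram"),
                             genome_len_range = c(2151L, 4955L),
                             utr_len_range = c(30L, 150L),
                             uga_w_fraction = NULL,
                             motif_set = default_motifs(),
                             ...) {
  name <- match.arg(name)
  defaults <- switch(
    name,
    arkeo = list(table_id = 1L, uga_w_fraction = 0,
                 au = list(kind = "truncnorm", mean = 54.6, sd = 4.1,
                           lower = 45, upper = 59.9),
                 force_reverse_orf = FALSE, linker_bias = 0),
    mitovirinae = list(table_id = 4L, uga_w_fraction = 0.5,
                       au = list(kind = "uniform", min = 60, max = 70),
                       force_reverse_orf = FALSE, linker_bias = 3),
    kvara = list(table_id = 4L, uga_w_fraction = 0.5,
                 au = list(kind = "uniform", min = 67, max = 73),
                 force_reverse_orf = FALSE, linker_bias = 3),
    ambigram = list(table_id = 1L, uga_w_fraction = 0,
                    au = list(kind = "truncnorm", mean = 54.6, sd = 4.1,
                              lower = 45, upper = 59.9),
                    force_reverse_orf = TRUE, linker_bias = 0)
  )
  over <- list(...)
  bad <- setdiff(names(over),
                 c("table_id", "au", "force_reverse_orf", "linker_bias"))
  if (length(bad)) stop("unknown preset override(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (!is.null(uga_w_fraction)) defaults$uga_w_fraction <- uga_w_fraction
  if (defaults$table_id == 1L && defaults$uga_w_fraction != 0) {
    stop("uga_w_fraction must be 0 under table 1 (UGA is a stop)")
  }
  structure(
    c(list(name = name,
           genome_len_range = as.integer(genome_len_range),
           utr_len_range = as.integer(utr_len_range),
           motif_set = motif_set),
      defaults),
    class = "generator_preset"
  )
}

draw_au_target <- function(preset) {
  au <- preset$au
  if (au$kind == "uniform") return(runif(1L, au$min, au$max))
  repeat {
    x <- rnorm(1L, au$mean, au$sd)
    if (x >= au$lower && x <= au$upper) return(x)
  }
}

# synonymous codons per amino acid under a code (stops excluded)
syn_codons <- function(code) {
  map <- code$codon_to_aa
  split(names(map)[map != "*"], map[map != "*"])
}

codon_au_fraction <- function(codons) {
  vdapply(codons, function(cd) {
    sum(strsplit(cd, "")[[1]] %in% c("A", "U")) / 3
  })
}

# Linker residue weights: presets targeting AU-rich genomes (>60%) draw
# linker residues preferentially from amino acids owning all-A/U codons
# (F, I, K, L, N, Y), mirroring the residue bias of AU-rich viral proteomes;
# without this the back-translation tilt cannot reach the upper AU targets.
linker_weights <- function(preset, code) {
  if (preset$linker_bias == 0) return(NULL)   # uniform draw
  syn <- syn_codons(code)
  max_au <- vdapply(AA20, function(a) max(codon_au_fraction(syn[[a]])))
  setNames(exp(preset$linker_bias * max_au), AA20)
}

# protein scaffold: canonical motif instances I-VI in order, separated by
# random linkers (leading M excluded here)
build_scaffold <- function(scaffold_len, motifs, aa_weights = NULL) {
  canon <- vcapply(motifs, motif_canonical)
  motif_aa <- sum(nchar(canon))
  n_link <- length(motifs) + 1L
  min_link <- 4L
  free <- scaffold_len - motif_aa - n_link * min_link
  if (free < 0L) stop("scaffold too short for motif set")
  extra <- as.vector(stats::rmultinom(1L, free, rep(1 / n_link, n_link)))
  link_len <- extra + min_link
  draw_aa <- if (is.null(aa_weights)) {
    function(n) sample(AA20, n, replace = TRUE)
  } else {
    function(n) sample(AA20, n, replace = TRUE, prob = aa_weights)
  }
  aa <- character(); motif_pos <- integer(length(motifs))
  for (k in seq_along(motifs)) {
    aa <- c(aa, draw_aa(link_len[[k]]))
    motif_pos[[k]] <- length(aa) + 2L      # +1 leading M, +1 next position
    aa <- c(aa, strsplit(canon[[k]], "")[[1]])
  }
  aa <- c(aa, draw_aa(link_len[[n_link]]))
  names(motif_pos) <- vcapply(motifs, function(m) m$motif_id)
  list(aa = aa, motif_pos = motif_pos)
}

# Back-translate a protein under exponential AU tilting: synonymous codons
# are chosen with weight exp(beta * codon AU fraction); beta is bisected per
# genome so the realized ORF AU lands within `tol` percentage points of the
# target. Positions with a fixed codon (start, stop, tryptophans with a
# drawn UGA/UGG state) are constants of the bisection; `restricted`
# positions additionally exclude REV_STOP_FORWARD codons.
tilt_backtranslate <- function(protein, code, fixed, restricted,
                               target_au_pct, tol = 0.4, max_iter = 100L) {
  syn <- syn_codons(code)
  n <- length(protein)
  free <- which(is.na(fixed))
  allowed <- lapply(free, function(i) {
    cods <- syn[[protein[[i]]]]
    if (is.null(cods)) stop("no codon for residue '", protein[[i]], "'")
    if (restricted[[i]]) cods <- setdiff(cods, REV_STOP_FORWARD)
    if (!length(cods)) stop("no admissible codon at position ", i)
    au <- codon_au_fraction(cods)
    ord <- order(au, cods)
    list(codons = cods[ord], au = au[ord])
  })
  u <- runif(length(free))
  sig <- vcapply(allowed, function(a) paste(a$codons, collapse = ","))
  groups <- split(seq_along(free), sig)
  fixed_au <- sum(codon_au_fraction(fixed[!is.na(fixed)]) * 3)
  n_nt <- 3L * n
  realize <- function(beta) {
    chosen <- character(length(free))
    au_sum <- 0
    for (g in groups) {
      a <- allowed[[g[[1L]]]]
      w <- exp(beta * a$au)
      cw <- cumsum(w) / sum(w)
      idx <- findInterval(u[g], cw, left.open = TRUE) + 1L
      idx[idx > length(cw)] <- length(cw)
      chosen[g] <- a$codons[idx]
      au_sum <- au_sum + sum(a$au[idx]) * 3
    }
    list(chosen = chosen, au_pct = 100 * (au_sum + fixed_au) / n_nt)
  }
  lo <- -30; hi <- 30
  flo <- realize(lo); fhi <- realize(hi)
  if (target_au_pct < flo$au_pct - tol || target_au_pct > fhi$au_pct + tol) {
    stop(sprintf(
      "AU target %.1f%% unachievable for this scaffold (range %.1f-%.1f%%)",
      target_au_pct, flo$au_pct, fhi$au_pct))
  }
  res <- NULL
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- realize(mid)
    if (abs(fm$au_pct - target_au_pct) <= tol) { res <- fm; break }
    if (fm$au_pct < target_au_pct) lo <- mid else hi <- mid
  }
  if (is.null(res)) {
    stop(sprintf("AU tuning failed after %d iterations (target %.1f%%)",
                 max_iter, target_au_pct))
  }
  out <- fixed
  out[free] <- res$chosen
  list(codons = out, orf_au_pct = res$au_pct)
}

# UTR of length `len` with a prescribed number of A/U bases
make_utr <- function(len, n_au) {
  if (len == 0L) return("")
  n_au <- max(0L, min(len, n_au))
  base <- c(sample(c("A", "U"), n_au, replace = TRUE),
            sample(c("G", "C"), len - n_au, replace = TRUE))
  paste(sample(base), collapse = "")
}

# assemble one genome attempt for a fixed protein/AU draw; returns residues
# plus planted annotation
assemble_genome <- function(protein, preset, code, len, utr5, utr3,
                            au_target, stretch = NULL) {
  n_codons_protein <- length(protein)
  fixed <- rep(NA_character_, n_codons_protein)
  fixed[[1L]] <- "AUG"
  w_pos <- which(protein == "W")
  uga_count <- 0L
  if (code$table_id == 4L) {
    is_uga <- rbinom(length(w_pos), 1L, preset$uga_w_fraction) == 1L
    if (preset$uga_w_fraction > 0 && length(w_pos) && !any(is_uga)) {
      is_uga[sample.int(length(w_pos), 1L)] <- TRUE
    }
    fixed[w_pos] <- ifelse(is_uga, "UGA", "UGG")
    uga_count <- sum(is_uga)
  } else {
    fixed[w_pos] <- "UGG"
  }
  restricted <- rep(FALSE, n_codons_protein)
  if (!is.null(stretch)) restricted[stretch] <- TRUE
  stop_codon <- sample(c("UAA", "UAG"), 1L)
  orf_nt_len <- 3L * (n_codons_protein + 1L)
  # ORF-level AU target equals the genome target; the UTRs absorb the residual
  bt <- tilt_backtranslate(protein, code, fixed, restricted, au_target)
  orf <- paste(c(bt$codons, stop_codon), collapse = "")
  orf_au <- sum(strsplit(orf, "")[[1]] %in% c("A", "U"))
  # 5' UTR ends with an in-frame UAA guard so the deduced ORF starts at the
  # planted AUG; remaining UTR composition closes the gap to the AU target
  guard <- "UAA"
  free_utr <- utr5 + utr3 - 3L
  need <- round(au_target / 100 * len) - orf_au - 3L
  n_au5 <- max(0L, min(utr5 - 3L, round(need * (utr5 - 3L) / free_utr)))
  n_au3 <- max(0L, min(utr3, need - n_au5))
  res <- paste0(make_utr(utr5 - 3L, n_au5), guard, orf, make_utr(utr3, n_au3))
  list(residues = res,
       orf_start = utr5 + 1L, orf_end = utr5 + orf_nt_len,
       uga_count = uga_count,
       ugg_count = length(w_pos) - uga_count,
       stop_codon = stop_codon)
}

expected_label_for <- function(preset, ann) {
  if (preset$force_reverse_orf) return("AMBIGRAMMATIC")
  if (ann$uga_count >= 1L) return("UGA_CONTAINING")
  if (ann$ugg_count >= 1L) return("UGA_FREE")
  "UNCLASSIFIED"
}

gen_valid_genome <- function(preset, id, max_attempts = 50L) {
  code <- genetic_code(preset$table_id)
  len <- sample(preset$genome_len_range[[1L]]:preset$genome_len_range[[2L]], 1L)
  au_target <- draw_au_target(preset)
  utr5 <- sample(preset$utr_len_range[[1L]]:preset$utr_len_range[[2L]], 1L)
  utr3 <- sample(preset$utr_len_range[[1L]]:preset$utr_len_range[[2L]], 1L)
  orf_nt <- len - utr5 - utr3
  orf_nt <- orf_nt - orf_nt %% 3L
  utr3 <- len - utr5 - orf_nt
  n_codons <- orf_nt %/% 3L             # incl. start and stop codons
  scaffold <- build_scaffold(n_codons - 2L, preset$motif_set,
                             aa_weights = linker_weights(preset, code))
  protein <- c("M", scaffold$aa)
  stretch <- NULL
  if (preset$force_reverse_orf) {
    span <- 400L                         # 1200 nt reverse stop-free stretch
    if (length(protein) < span + 2L) stop("genome too short for ambigram")
    p0 <- sample.int(length(protein) - span, 1L)
    stretch <- p0:(p0 + span - 1L)
  }
  for (attempt in seq_len(max_attempts)) {
    ann <- assemble_genome(protein, preset, code, len, utr5, utr3,
                           au_target, stretch)
    genome <- nuc_seq(id, ann$residues, source_tag = "synthetic")
    rev <- reverse_orf_scan(genome, genetic_code(1L), min_nt = 1000L)
    if (!preset$force_reverse_orf) {
      # resample on the (rare) accidental second long off-frame ORF
      slo <- single_long_orf(genome)
      if (is.null(slo) || !slo$single) next
    }
    if (rev$ambigrammatic == preset$force_reverse_orf) {
      truth <- list(
        seq_id = id, category = "valid",
        genome_len = len, orf_start = ann$orf_start, orf_end = ann$orf_end,
        aa_len = length(protein), motif_pos = scaffold$motif_pos,
        uga_count = ann$uga_count, ugg_count = ann$ugg_count,
        au_target_pct = au_target,
        au_realized_pct = 100 * au_content(genome)$au_fraction,
        table_id = preset$table_id,
        expected_label = expected_label_for(preset, ann),
        keepable = !preset$force_reverse_orf, parent = NA_character_
      )
      verify_genome(genome, truth, preset)
      return(list(genome = genome, truth = truth))
    }
  }
  stop("failed to produce genome without spurious reverse ORF for '", id, "'")
}

# run the emitted genome through the public pipeline and check the planted
# ground truth; any disagreement is a generation error
verify_genome <- function(genome, truth, preset) {
  cfg <- curation_config(motifs = preset$motif_set)
  if (abs(truth$au_realized_pct - truth$au_target_pct) > 0.5) {
    stop("generator: realized AU off target for '", genome$id, "'")
  }
  call <- classify_architecture(genome, cfg)
  if (call$label != truth$expected_label) {
    stop("generator: label mismatch for '", genome$id, "' (got ",
         call$label, ", planted ", truth$expected_label, ")")
  }
  if (!is.null(call$profile) && truth$expected_label != "AMBIGRAMMATIC") {
    if (call$profile$uga_count != truth$uga_count ||
        call$profile$ugg_count != truth$ugg_count) {
      stop("generator: UGA/UGG bookkeeping mismatch for '", genome$id, "'")
    }
    slo <- single_long_orf(genome, lapply(cfg$table_order, genetic_code),
                           cfg$min_orf_nt)
    if (!slo$single) stop("generator: ORF not unique for '", genome$id, "'")
    if (slo$orf$start != truth$orf_start || slo$orf$end != truth$orf_end) {
      stop("generator: ORF coordinates drifted for '", genome$id, "'")
    }
    if (!motif_scan(slo$orf$aa_seq, preset$motif_set)$pass) {
      stop("generator: motif scan fails for '", genome$id, "'")
    }
  }
  invisible(TRUE)
}

#' Generate one synthetic mitovirus-like genome
#'
#' Builds a protein scaffold carrying the six motifs in order, back-translates
#' it under the preset's genetic code with exponential AU tilting (per-genome
#' bisection of the tilt so realized AU lands within 0.5 percentage points of
#' the drawn target), writes tryptophans as UGA with the preset probability
#' (table 4), adds an AUG start, a terminal stop and composition-matched
#' UTRs, and rejection-samples until the reverse strand carries no >= 1000 nt
#' ORF (or, for the `ambigram` preset, embeds a >= 1200 nt reverse stop-free
#' stretch). The result is verified against the package's own classifier
#' before it is returned.
#'
#' @param preset A [generator_preset()].
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param id Record id.
#' @return A list with `genome` (a [nuc_seq]) and `truth` (planted ground
#'   truth: ORF coordinates, motif positions, UGA/UGG counts, realized AU,
#'   expected architecture label).
#' @export
generate_genome <- function(preset, seed = NULL, id = paste0(preset$name, "_001")) {
  stopifnot(inherits(preset, "generator_preset"))
  with_seed(seed, gen_valid_genome(preset, id))
}

decoy_short_orf <- function(preset, id, max_attempts = 50L) {
  code <- genetic_code(preset$table_id)
  for (attempt in seq_len(max_attempts)) {
    n_codons <- sample(120:330, 1L)      # ORF <= 990 nt, stop included
    utr5 <- sample(20:40, 1L); utr3 <- sample(20:40, 1L)
    len <- utr5 + 3L * n_codons + utr3
    w <- linker_weights(preset, code)
    protein <- c("M", if (is.null(w)) sample(AA20, n_codons - 2L, TRUE) else
      sample(AA20, n_codons - 2L, TRUE, prob = w))
    au_target <- draw_au_target(preset)
    ann <- assemble_genome(protein, preset, code, len, utr5, utr3, au_target)
    genome <- nuc_seq(id, ann$residues, source_tag = "synthetic")
    if (is.null(single_long_orf(genome)) &&
        !reverse_orf_scan(genome)$ambigrammatic) {
      truth <- list(seq_id = id, category = "short_orf", keepable = FALSE,
                    expected_label = "UNCLASSIFIED", parent = NA_character_)
      return(list(genome = genome, truth = truth))
    }
  }
  stop("failed to build short-ORF decoy '", id, "'")
}

decoy_motif_deleted <- function(preset, id, max_attempts = 50L) {
  code <- genetic_code(preset$table_id)
  syn <- syn_codons(code)
  for (attempt in seq_len(max_attempts)) {
    v <- gen_valid_genome(preset, id)
    m_idx <- sample.int(length(preset$motif_set), 1L)
    motif <- preset$motif_set[[m_idx]]
    k <- length(motif$tokens)
    p0 <- v$truth$motif_pos[[motif$motif_id]]
    res <- v$genome$residues
    # randomize the motif's aa span, re-encoding with uniform synonymous codons
    new_aa <- sample(setdiff(AA20, "W"), k, replace = TRUE)
    new_codons <- vcapply(new_aa, function(a) sample(syn[[a]], 1L))
    nt0 <- v$truth$orf_start + 3L * (p0 - 1L)
    substr(res, nt0, nt0 + 3L * k - 1L) <- paste(new_codons, collapse = "")
    genome <- nuc_seq(id, res, source_tag = "synthetic")
    slo <- single_long_orf(genome)
    if (!is.null(slo) && slo$single &&
        !motif_scan(slo$orf$aa_seq, preset$motif_set)$pass &&
        !reverse_orf_scan(genome)$ambigrammatic) {
      truth <- list(seq_id = id, category = "motif_deleted", keepable = FALSE,
                    expected_label = NA_character_, parent = NA_character_)
      return(list(genome = genome, truth = truth))
    }
  }
  stop("failed to build motif-deleted decoy '", id, "'")
}

decoy_near_duplicate <- function(parent, preset, id, sub_rate = 0.02,
                                 threshold_pct = 90, max_attempts = 50L) {
  tr <- parent$truth
  res0 <- parent$genome$residues
  L <- nchar(res0)
  # nt spans that must stay intact: start codon, terminal stop, motif spans,
  # the 5' UTR in-frame stop guard
  protect <- c(tr$orf_start:(tr$orf_start + 2L),
               (tr$orf_end - 2L):tr$orf_end,
               (tr$orf_start - 3L):(tr$orf_start - 1L))
  for (m in preset$motif_set) {
    p0 <- tr$motif_pos[[m$motif_id]]
    nt0 <- tr$orf_start + 3L * (p0 - 1L)
    protect <- c(protect, nt0:(nt0 + 3L * length(m$tokens) - 1L))
  }
  stops1 <- c("UAA", "UAG", "UGA")
  for (attempt in seq_len(max_attempts)) {
    chars <- strsplit(res0, "")[[1]]
    n_mut <- ceiling(sub_rate * L)
    cand <- sample(setdiff(which(chars != "N"), protect), n_mut)
    for (p in cand) {
      alts <- sample(setdiff(c("A", "C", "G", "U"), chars[[p]]))
      in_orf <- p >= tr$orf_start && p <= tr$orf_end
      for (alt in alts) {
        if (in_orf) {
          cstart <- tr$orf_start + 3L * ((p - tr$orf_start) %/% 3L)
          codon <- chars[cstart:(cstart + 2L)]
          codon[[p - cstart + 1L]] <- alt
          if (paste(codon, collapse = "") %in% stops1) next
        }
        chars[[p]] <- alt
        break
      }
    }
    genome <- nuc_seq(id, paste(chars, collapse = ""),
                      source_tag = "synthetic")
    slo <- single_long_orf(genome)
    ok <- !is.null(slo) && slo$single &&
      motif_scan(slo$orf$aa_seq, preset$motif_set)$pass &&
      !reverse_orf_scan(genome)$ambigrammatic &&
      as.numeric(pairwise_identity(genome, parent$genome)) > threshold_pct
    if (ok) {
      truth <- list(seq_id = id, category = "near_duplicate", keepable = FALSE,
                    expected_label = NA_character_, parent = tr$seq_id)
      return(list(genome = genome, truth = truth))
    }
  }
  stop("failed to build near-duplicate decoy '", id, "'")
}

#' Generate a synthetic cohort with optional decoys
#'
#' Produces `n` valid genomes under `preset` plus the requested decoys:
#' `short_orf` (no ORF > 1000 nt), `motif_deleted` (long ORF present, one
#' motif span randomized), `near_duplicate` (a copy of a valid member with
#' ~2% substitutions, still > 90% identity and sharing its parent's filter
#' behavior up to the dedup stage). Ground truth marks exactly the valid
#' genomes as keepable. Deterministic for a fixed seed.
#'
#' @param preset A [generator_preset()].
#' @param n Number of valid genomes.
#' @param seed Optional integer seed.
#' @param decoys Named list `list(short_orf =, motif_deleted =,
#'   near_duplicate =)` of decoy counts.
#' @return A list with `genomes` (list of [nuc_seq], valid records first)
#'   and `truth` (data frame with one row per record: category, keepable,
#'   expected label, AU, UGA/UGG counts, parent id for duplicates).
#' @export
generate_cohort <- function(preset, n, seed = NULL,
                            decoys = list(short_orf = 0L, motif_deleted = 0L,
                                          near_duplicate = 0L)) {
  stopifnot(inherits(preset, "generator_preset"), n >= 1L)
  dec <- list(short_orf = 0L, motif_deleted = 0L, near_duplicate = 0L)
  dec[names(decoys)] <- decoys
  with_seed(seed, {
    valid <- lapply(seq_len(n), function(i) {
      gen_valid_genome(preset, sprintf("%s_%03d", preset$name, i))
    })
    out <- valid
    if (dec$short_orf > 0L) {
      out <- c(out, lapply(seq_len(dec$short_orf), function(i) {
        decoy_short_orf(preset, sprintf("decoy_short_%02d", i))
      }))
    }
    if (dec$motif_deleted > 0L) {
      out <- c(out, lapply(seq_len(dec$motif_deleted), function(i) {
        decoy_motif_deleted(preset, sprintf("decoy_motif_%02d", i))
      }))
    }
    if (dec$near_duplicate > 0L) {
      parents <- sample.int(n, dec$near_duplicate,
                            replace = dec$near_duplicate > n)
      out <- c(out, lapply(seq_len(dec$near_duplicate), function(i) {
        decoy_near_duplicate(valid[[parents[[i]]]], preset,
                             sprintf("decoy_dup_%02d", i))
      }))
    }
    truth <- do.call(rbind, lapply(out, function(x) {
      tr <- x$truth
      data.frame(
        id = tr$seq_id, category = tr$category, keepable = tr$keepable,
        expected_label = tr$expected_label %||% NA_character_,
        uga_count = tr$uga_count %||% NA_integer_,
        ugg_count = tr$ugg_count %||% NA_integer_,
        au_realized_pct = tr$au_realized_pct %||% NA_real_,
        orf_start = tr$orf_start %||% NA_integer_,
        orf_end = tr$orf_end %||% NA_integer_,
        parent = tr$parent, stringsAsFactors = FALSE
      )
    }))
    list(genomes = lapply(out, `[[`, "genome"), truth = truth,
         details = lapply(out, `[[`, "truth"))
  })
}

#' Generate a fixture tree with planted clade depths
#'
#' Builds a rooted binary backbone carrying one ultrametric random-topology
#' subtree per requested clade (tip depth below the clade MRCA exactly the
#' requested depth) plus one outgroup leaf attached below the root. Useful
#' as ground truth for [clade_metrics()] and [is_monophyletic()].
#'
#' @param clade_spec List of `list(name =, n_leaves =, depth =)` entries.
#' @param seed Optional integer seed.
#' @param stem_length Branch length subtending each clade MRCA.
#' @param outgroup_length Root-to-outgroup branch length.
#' @return A list with `newick` (text), `tree` (parsed `phylo`) and `clades`
#'   (named list of leaf labels per clade).
#' @export
generate_fixture_tree <- function(clade_spec = list(
                                    list(name = "shallow", n_leaves = 10L,
                                         depth = 0.1),
                                    list(name = "deep", n_leaves = 10L,
                                         depth = 0.5)),
                                  seed = NULL, stem_length = 0.05,
                                  outgroup_length = 1.0) {
  with_seed(seed, {
    parts <- character(); clades <- list()
    for (cl in clade_spec) {
      labs <- sprintf("%s_%02d", cl$name, seq_len(cl$n_leaves))
      clades[[cl$name]] <- labs
      if (cl$n_leaves == 1L) {
        parts <- c(parts, sprintf("%s:%.12f", labs, stem_length))
        next
      }
      sub <- ape::rcoal(cl$n_leaves, tip.label = labs)
      d <- max(ape::node.depth.edgelength(sub))
      sub$edge.length <- sub$edge.length * (cl$depth / d)
      txt <- sub(";$", "", ape::write.tree(sub, digits = 15L))
      parts <- c(parts, sprintf("%s:%.12f", txt, stem_length))
    }
    backbone <- parts[[1L]]
    for (k in seq_along(parts)[-1L]) {
      backbone <- sprintf("(%s,%s):%.12f", backbone, parts[[k]], stem_length)
    }
    newick <- sprintf("(%s,outgroup:%.12f);", backbone, outgroup_length)
    tree <- read_newick(text = newick)
    list(newick = newick, tree = tree, clades = clades)
  })
}
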