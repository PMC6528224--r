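# Per-SNV motif alteration calling: score the reference and alternative
# allele of every window overlapping an SNV against each PWM under a
# local second-order Markov background, and call a disruption when the
# reference allele is a binding site (p <= binding_p), the alternative
# is not, AND the p-value changes at least `fold`-fold; creation is the
# symmetric case.  Both conditions of this dual criterion are required.

#' Read SNV calls from VCF or 5-column TSV
#'
#' VCF input keeps only biallelic SNV records (single-base REF and ALT);
#' multiallelic records and indels are skipped and their count reported
#' as attribute `n_skipped` (and via a message).  The TSV fallback
#' expects columns chrom, pos, ref, alt and optionally sample_id /
#' cohort_id.
#'
#' @param path Path to a `.vcf` file or a tab-separated table.
#' @return An `snv_tbl`: tibble with `contig`, `pos` (1-based), `ref`,
#'   `alt`, `sample_id`, `cohort_id`.
#' @export
read_snvs <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES & !grepl(",", fix$ALT)
    n_skipped <- sum(!keep)
    if (n_skipped > 0L) {
      message(n_skipped, " non-SNV or multiallelic record(s) skipped")
    }
    fix <- fix[keep, , drop = FALSE]
    out <- tibble::tibble(
      contig = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      sample_id = NA_character_,
      cohort_id = NA_character_
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(raw) <- tolower(names(raw))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(raw))) {
      stop("TSV must have columns chrom, pos, ref, alt")
    }
    out <- tibble::tibble(
      contig = as.character(raw$chrom),
      pos = as.integer(raw$pos),
      ref = toupper(raw$ref),
      alt = toupper(raw$alt),
      sample_id = if ("sample_id" %in% names(raw))
        as.character(raw$sample_id) else NA_character_,
      cohort_id = if ("cohort_id" %in% names(raw))
        as.character(raw$cohort_id) else NA_character_
    )
    n_skipped <- 0L
  }
  bad <- out$ref == out$alt | !(out$ref %in% DNA_BASES) |
    !(out$alt %in% DNA_BASES)
  if (any(bad)) stop(sum(bad), " record(s) with invalid ref/alt alleles")
  class(out) <- c("snv_tbl", class(out))
  attr(out, "n_skipped") <- n_skipped
  out
}

# ---- order-2 Markov background ----------------------------------------------

#' Estimate a strand-symmetric order-2 Markov background
#'
#' Counts monomers, dimers and trimers in the given sequence pooled with
#' its reverse complement (so the model, and hence every p-value built
#' on it, is invariant under reverse-complementing the input), with a
#' pseudocount of 1 per cell.
#'
#' @param seq A single DNA string (ambiguity codes allowed; windows
#'   containing them are skipped).
#' @param pseudocount Pseudocount per cell (default 1).
#' @return A `markov_background`: list with `p0` (4), `p1` (4 x 4,
#'   rows = preceding base), `p2` (16 x 4, rows = preceding dimer).
#' @export
markov_background <- function(seq, pseudocount = 1) {
  stopifnot(length(seq) == 1L, pseudocount > 0)
  seq <- toupper(seq)
  # split on ambiguity codes so no n-gram spans a masked position
  runs <- unlist(strsplit(seq, "[^ACGT]+"))
  runs <- runs[nzchar(runs)]
  pool <- c(runs, revcomp(runs))
  count_grams <- function(n) {
    keys <- enumerate_kmers(n)
    counts <- stats::setNames(rep(pseudocount, length(keys)), keys)
    wins <- unlist(lapply(pool, contig_windows, k = n), use.names = FALSE)
    if (length(wins) > 0L) {
      tab <- table(wins)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
    counts
  }
  c1 <- count_grams(1L)
  c2 <- count_grams(2L)
  c3 <- count_grams(3L)
  p0 <- c1 / sum(c1)
  p1 <- matrix(c2, nrow = 4L, byrow = TRUE,
               dimnames = list(DNA_BASES, DNA_BASES))
  p1 <- sweep(p1, 1L, rowSums(p1), "/")
  ctx <- enumerate_kmers(2L)
  p2 <- matrix(c3, nrow = 16L, byrow = TRUE,
               dimnames = list(ctx, DNA_BASES))
  p2 <- sweep(p2, 1L, rowSums(p2), "/")
  structure(list(p0 = p0, p1 = p1, p2 = p2,
                 n_bases = sum(nchar(runs))),
            class = "markov_background")
}

#' Local background around one SNV
#'
#' Extracts the reference sequence in a `window`-bp neighborhood on each
#' side of the SNV and estimates the strand-symmetric order-2 Markov
#' model from it.  If fewer than `min_bases` unambiguous bases remain
#' (e.g. truncated at a contig edge), falls back to a genome-wide
#' background with a warning.
#'
#' @param contigs Named character vector of contig sequences.
#' @param contig,pos SNV location (1-based).
#' @param window Half-width of the neighborhood in bp (default 500).
#' @param min_bases Minimum usable bases before falling back (default
#'   100).
#' @return A `markov_background`.
#' @export
build_background <- function(contigs, contig, pos, window = 500L,
                             min_bases = 100L) {
  seq <- contigs[[contig]]
  n <- nchar(seq)
  lo <- max(1L, pos - window)
  hi <- min(n, pos + window)
  local <- substr(seq, lo, hi)
  usable <- nchar(gsub("[^ACGT]", "", toupper(local)))
  if (usable < min_bases) {
    warning("fewer than ", min_bases, " usable bases around ", contig, ":",
            pos, "; falling back to genome-wide background")
    local <- paste(contigs, collapse = "N")
  }
  markov_background(local)
}

# Integerized score increments of a PWM against an order-2 Markov
# background.  Positions 1 and 2 condition on shorter contexts (p0, p1).
markov_score_grid <- function(pwm, bg, n_bins) {
  w <- pwm$width
  lp <- log(pwm$prob)              # 4 x w
  inc1 <- lp[, 1L] - log(bg$p0)                     # by b1
  inc2 <- sweep(-log(bg$p1), 2L, lp[, 2L], "+")     # rows b1, cols b2
  inc3 <- vector("list", w)       # position >= 3: 16 x 4 (ctx x base)
  if (w >= 3L) {
    for (j in 3:w) {
      inc3[[j]] <- sweep(-log(bg$p2), 2L, lp[, j], "+")
    }
  }
  lo <- min(inc1) + min(inc2) +
    sum(vapply(3:w, function(j) min(inc3[[j]]), numeric(1)))
  hi <- max(inc1) + max(inc2) +
    sum(vapply(3:w, function(j) max(inc3[[j]]), numeric(1)))
  delta <- if (hi > lo) (hi - lo) / n_bins else 1
  list(inc1 = round(inc1 / delta), inc2 = round(inc2 / delta),
       inc3 = lapply(inc3, function(m) if (is.null(m)) NULL
                     else round(m / delta)),
       delta = delta, width = w)
}

#' Exact score tail distribution under an order-2 Markov background
#'
#' Dynamic programming over positions with 16 context states (the last
#' two bases), on an integerized score grid: the exact probability that
#' a width-w sequence generated by the background Markov chain scores at
#' least each achievable log-likelihood-ratio score.
#'
#' @param pwm A `pwm_model` of width >= 3.
#' @param bg A `markov_background`.
#' @param n_bins Score-grid resolution (default 2000).
#' @return A `markov_score_distribution` usable with
#'   [markov_pvalue()].
#' @export
markov_pvalue_distribution <- function(pwm, bg, n_bins = 2000L) {
  if (n_bins < 1000L) stop("n_bins must be >= 1000")
  w <- pwm$width
  grid <- markov_score_grid(pwm, bg, n_bins)
  ctx <- enumerate_kmers(2L)
  int_lo <- min(grid$inc1) + min(grid$inc2) +
    if (w >= 3L) sum(vapply(3:w, function(j) min(grid$inc3[[j]]),
                            numeric(1))) else 0L
  int_hi <- max(grid$inc1) + max(grid$inc2) +
    if (w >= 3L) sum(vapply(3:w, function(j) max(grid$inc3[[j]]),
                            numeric(1))) else 0L
  n <- int_hi - int_lo + 1L
  # M[bin, state]: P(partial score = int_lo_partial + bin - 1, last two
  # bases = state); anchored at the running minimum like the i.i.d. DP
  M <- matrix(0, nrow = n, ncol = 16L, dimnames = list(NULL, ctx))
  base2 <- min(grid$inc1) + min(grid$inc2)
  for (b1 in 1:4) {
    for (b2 in 1:4) {
      s <- grid$inc1[b1] + grid$inc2[b1, b2] - base2
      st <- paste0(DNA_BASES[b1], DNA_BASES[b2])
      M[s + 1L, st] <- M[s + 1L, st] + bg$p0[b1] * bg$p1[b1, b2]
    }
  }
  if (w >= 3L) {
    for (j in 3:w) {
      inc <- grid$inc3[[j]]
      mn <- min(inc)
      Mn <- matrix(0, nrow = n, ncol = 16L, dimnames = list(NULL, ctx))
      for (ci in 1:16) {
        prev <- ctx[ci]
        colv <- M[, ci]
        if (all(colv == 0)) next
        for (b in 1:4) {
          s <- inc[ci, b] - mn
          st <- paste0(substr(prev, 2L, 2L), DNA_BASES[b])
          src <- colv[seq_len(n - s)]
          Mn[(s + 1L):n, st] <- Mn[(s + 1L):n, st] +
            bg$p2[prev, b] * src
        }
      }
      M <- Mn
    }
  }
  pmf <- rowSums(M)
  structure(
    list(score = (int_lo:int_hi) * grid$delta,
         tail_prob = rev(cumsum(rev(pmf))),
         int_lo = int_lo, grid = grid, width = w,
         motif_id = pwm$motif_id),
    class = "markov_score_distribution"
  )
}

# integer grid score of sequences under the Markov grid's rounding
markov_int_score <- function(dist, seqs) {
  g <- dist$grid
  enc <- encode_seqs(seqs, g$width)
  sc <- g$inc1[enc[, 1L]] +
    g$inc2[cbind(enc[, 1L], enc[, 2L])]
  if (g$width >= 3L) {
    for (j in 3:g$width) {
      ci <- (enc[, j - 2L] - 1L) * 4L + enc[, j - 1L]
      sc <- sc + g$inc3[[j]][cbind(ci, enc[, j])]
    }
  }
  sc
}

#' Tail p-value under the Markov background distribution
#' @param dist A `markov_score_distribution`.
#' @param seqs Width-w sequences.
#' @return Numeric vector of p-values.
#' @export
markov_pvalue <- function(dist, seqs) {
  sc <- markov_int_score(dist, seqs)
  idx <- pmin(pmax(sc - dist$int_lo + 1L, 1L), length(dist$tail_prob))
  dist$tail_prob[idx]
}

# best (minimum) p-value over all windows overlapping `pos` and both
# orientations; returns list(p, offset, orientation)
best_window_pvalue <- function(dist, contig_seq, pos, w, replace_base = NULL) {
  n <- nchar(contig_seq)
  starts <- max(1L, pos - w + 1L):min(pos, n - w + 1L)
  if (length(starts) == 0L || starts[1] > pos) {
    return(list(p = 1, offset = NA_integer_, orientation = NA_character_))
  }
  wins <- substring(contig_seq, starts, starts + w - 1L)
  if (!is.null(replace_base)) {
    at <- pos - starts + 1L
    substr(wins, at, at) <- rep(replace_base, length(wins))
  }
  ok <- grepl("^[ACGT]+$", wins)
  if (!any(ok)) {
    return(list(p = 1, offset = NA_integer_, orientation = NA_character_))
  }
  wins <- wins[ok]
  starts <- starts[ok]
  p_fwd <- markov_pvalue(dist, wins)
  p_rev <- markov_pvalue(dist, revcomp(wins))
  p <- pmin(p_fwd, p_rev)
  i <- which.min(p)
  list(p = p[i], offset = starts[i] - pos,
       orientation = if (p_fwd[i] <= p_rev[i]) "+" else "-")
}

#' Call motif creation/disruption events for SNVs
#'
#' For every SNV and every PWM: estimates the local strand-symmetric
#' order-2 Markov background, computes exact p-values for the best
#' window/orientation of the reference and the alternative allele, and
#' applies the dual criterion -- a binding-state change at
#' `p <= binding_p` plus at least a `fold`-fold p-value change.  SNVs
#' whose stated reference allele disagrees with the genome are an error.
#'
#' @param fasta Genome FASTA path or named character vector of contigs.
#' @param snvs An `snv_tbl` from [read_snvs()] (or any tibble with
#'   `contig`, `pos`, `ref`, `alt` and optionally `sample_id`,
#'   `cohort_id`).
#' @param pwms Named list of `pwm_model` objects.
#' @param binding_p Binding-site p-value threshold (default 1e-4, the
#'   SNV-pipeline convention).
#' @param fold Minimum p-value fold change (default 10).
#' @param window Background half-window in bp (default 500).
#' @param n_bins Score-grid resolution (default 2000).
#' @return An `alteration_calls_tbl`: one row per called event with
#'   `contig`, `pos`, `ref`, `alt`, `sample_id`, `cohort_id`,
#'   `motif_id`, `event`, `p_ref`, `p_alt`, `best_window_offset`,
#'   `orientation`.
#' @export
call_snvs <- function(fasta, snvs, pwms, binding_p = 1e-4, fold = 10,
                      window = 500L, n_bins = 2000L) {
  stopifnot(binding_p > 0, binding_p < 1, fold >= 1)
  contigs <- if (is.character(fasta) && length(fasta) == 1L &&
                 file.exists(fasta)) read_genome(fasta) else toupper(fasta)
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, function(p) p$motif_id, character(1))
  }
  if (!"sample_id" %in% names(snvs)) snvs$sample_id <- NA_character_
  if (!"cohort_id" %in% names(snvs)) snvs$cohort_id <- NA_character_
  calls <- vector("list", nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    s <- snvs[i, ]
    if (!s$contig %in% names(contigs)) {
      stop("SNV contig not in genome: ", s$contig)
    }
    genome_ref <- substr(contigs[[s$contig]], s$pos, s$pos)
    if (genome_ref != s$ref) {
      stop("reference allele mismatch at ", s$contig, ":", s$pos,
           " (genome ", genome_ref, ", SNV ", s$ref, ")")
    }
    bg <- suppressWarnings(
      build_background(contigs, s$contig, s$pos, window = window))
    for (pwm in pwms) {
      dist <- markov_pvalue_distribution(pwm, bg, n_bins = n_bins)
      pr <- best_window_pvalue(dist, contigs[[s$contig]], s$pos, pwm$width)
      pa <- best_window_pvalue(dist, contigs[[s$contig]], s$pos, pwm$width,
                               replace_base = s$alt)
      event <- NULL
      if (pr$p <= binding_p && pa$p > binding_p && pa$p / pr$p >= fold) {
        event <- "disrupt"
        best <- pr
      } else if (pa$p <= binding_p && pr$p > binding_p &&
                 pr$p / pa$p >= fold) {
        event <- "create"
        best <- pa
      }
      if (!is.null(event)) {
        calls[[i]] <- dplyr::bind_rows(calls[[i]], tibble::tibble(
          contig = s$contig, pos = s$pos, ref = s$ref, alt = s$alt,
          sample_id = s$sample_id,
          cohort_id = s$cohort_id,
          motif_id = pwm$motif_id, event = event,
          p_ref = pr$p, p_alt = pa$p,
          best_window_offset = best$offset, orientation = best$orientation
        ))
      }
    }
  }
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      contig = character(0), pos = integer(0), ref = character(0),
      alt = character(0), sample_id = character(0),
      cohort_id = character(0), motif_id = character(0),
      event = character(0), p_ref = numeric(0), p_alt = numeric(0),
      best_window_offset = integer(0), orientation = character(0))
  }
  class(out) <- c("alteration_calls_tbl", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write alteration calls as BED-like TSV
#'
#' Coordinates are converted from the 1-based inclusive internal
#' convention to BED 0-based half-open.
#'
#' @param calls An `alteration_calls_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  bed <- tibble::tibble(
    contig = calls$contig,
    start = calls$pos - 1L,
    end = calls$pos,
    motif_id = calls$motif_id,
    event = calls$event,
    p_ref = calls$p_ref,
    p_alt = calls$p_alt
  )
  readr::write_tsv(bed, path)
  invisible(path)
}

#' Normalize call counts per cohort
#'
#' Detection probability of each (cohort, motif, event) combination:
#' the number of calls divided by the cohort's total SNV count.
#'
#' @param calls An `alteration_calls_tbl` with `cohort_id` filled in.
#' @param snv_totals Tibble with `cohort_id`, `total` (total SNVs
#'   screened per cohort; must be >= the call counts and > 0).
#' @return A tibble: `cohort_id`, `motif_id`, `event`, `count`,
#'   `probability`.
#' @export
cohort_normalize <- function(calls, snv_totals) {
  if (any(snv_totals$total <= 0)) stop("cohort total must be positive")
  counts <- tibble::as_tibble(calls) |>
    dplyr::count(.data$cohort_id, .data$motif_id, .data$event,
                 name = "count")
  grid <- tidyr::expand_grid(
    cohort_id = snv_totals$cohort_id,
    motif_id = unique(calls$motif_id),
    event = c("create", "disrupt")
  )
  out <- grid |>
    dplyr::left_join(counts, by = c("cohort_id", "motif_id", "event")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(snv_totals, by = "cohort_id")
  if (any(out$count > out$total)) {
    stop("call count exceeds cohort SNV total")
  }
  out$probability <- out$count / out$total
  out[, c("cohort_id", "motif_id", "event", "count", "probability")]
}

#' Observed log-ratio of creation vs disruption counts
#'
#' Natural log of (creation count / disruption count) per group; when
#' either count is zero a pseudocount of 1 is added to both (reported
#' via a message).
#'
#' @param calls An `alteration_calls_tbl`.
#' @param groups Optional tibble with `sample_id`, `group`; when
#'   omitted, all calls form one group.
#' @return A tibble: `group`, `motif_id`, `n_create`, `n_disrupt`,
#'   `log_ratio`.
#' @export
observed_log_ratio <- function(calls, groups = NULL) {
  tab <- tibble::as_tibble(calls)
  if (is.null(groups)) {
    tab$group <- "all"
  } else {
    tab <- dplyr::left_join(tab, groups, by = "sample_id")
  }
  out <- tab |>
    dplyr::group_by(.data$group, .data$motif_id) |>
    dplyr::summarise(
      n_create = sum(.data$event == "create"),
      n_disrupt = sum(.data$event == "disrupt"),
      .groups = "drop"
    )
  zero <- out$n_create == 0L | out$n_disrupt == 0L
  if (any(zero)) {
    message("pseudocount 1 applied to ", sum(zero),
            " group(s) with a zero count")
  }
  out$log_ratio <- ifelse(
    zero,
    log((out$n_create + 1) / (out$n_disrupt + 1)),
    log(out$n_create / out$n_disrupt)
  )
  out
}
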