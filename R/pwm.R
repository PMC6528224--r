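# PWM representation, log-likelihood scoring and exact score p-values.
#
# A PWM is a list with class "pwm_model": motif_id, tf_name, width,
# prob (4 x w matrix, rows A/C/G/T, columns sum to 1, entries > 0) and
# background (length-4 probability vector).  Scores are log-likelihood
# ratios sum_i log(P(b_i | i) / bg(b_i)); the binding decision compares
# the exact tail p-value of the better-scoring orientation against a
# threshold (inclusive).

new_pwm <- function(motif_id, tf_name, prob, background = rep(0.25, 4),
                    tf_family = NA_character_) {
  stopifnot(is.matrix(prob), nrow(prob) == 4L)
  rownames(prob) <- DNA_BASES
  w <- ncol(prob)
  if (w < 3L) stop("PWM width must be >= 3 (one interior trinucleotide)")
  csum <- colSums(prob)
  if (any(abs(csum - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (any(prob <= 0)) stop("PWM probabilities must be strictly positive")
  background <- background / sum(background)
  if (any(background <= 0)) stop("background probabilities must be positive")
  names(background) <- DNA_BASES
  structure(
    list(motif_id = motif_id, tf_name = tf_name, tf_family = tf_family,
         width = w, prob = prob, background = background),
    class = "pwm_model"
  )
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("<pwm_model> ", x$motif_id, " (", x$tf_name, "), width ", x$width,
      ", consensus ", pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm A `pwm_model`.
#' @return The per-column argmax base string.
#' @export
pwm_consensus <- function(pwm) {
  paste0(DNA_BASES[apply(pwm$prob, 2L, which.max)], collapse = "")
}

#' Read JASPAR PFM files
#'
#' Parses the JASPAR position frequency matrix text format: a `>ID NAME`
#' header followed by four base rows, either bare counts or the
#' bracketed `A [ 1 2 3 ]` dialect.  Counts are regularized with a
#' per-cell pseudocount before column normalization.
#'
#' @param path Path to a PFM file (one or more motifs).
#' @param pseudocount Pseudocount added to every cell (default 1).
#' @param background Background base probabilities, length 4 (default
#'   uniform).
#' @return A named list of `pwm_model` objects (names = motif ids).
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  stopifnot(pseudocount > 0)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' header found in ", path)
  out <- list()
  for (i in seq_along(headers)) {
    from <- headers[i] + 1L
    to <- if (i < length(headers)) headers[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L) {
      stop("motif block must have exactly 4 base rows, got ", length(block),
           " (header line ", headers[i], ")")
    }
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- parts[1]
    tf_name <- if (length(parts) > 1L) parts[2] else parts[1]
    counts <- matrix(NA_real_, nrow = 4L, ncol = 0L)
    rows <- vector("list", 4L)
    row_bases <- character(4L)
    for (j in 1:4) {
      row <- block[j]
      m <- regmatches(row, regexec("^([ACGT])?\\s*\\[?([^]]*)\\]?\\s*$", row))[[1]]
      row_bases[j] <- ifelse(is.na(m[2]) || m[2] == "", DNA_BASES[j], m[2])
      nums <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (any(is.na(nums))) stop("non-numeric entry in row '", row, "'")
      rows[[j]] <- nums
    }
    if (length(unique(lengths(rows))) != 1L) {
      stop("rows of motif ", motif_id, " have unequal lengths")
    }
    counts <- do.call(rbind, rows)[order(match(row_bases, DNA_BASES)), ,
                                   drop = FALSE]
    if (any(colSums(counts) == 0)) {
      stop("zero-total column in motif ", motif_id)
    }
    if (any(counts < 0)) stop("negative count in motif ", motif_id)
    reg <- counts + pseudocount
    prob <- sweep(reg, 2L, colSums(reg), "/")
    out[[motif_id]] <- new_pwm(motif_id, tf_name, prob, background)
  }
  out
}

#' Write PWMs as a JASPAR PFM file
#'
#' Inverse of [read_jaspar()] for count matrices: writes the bracketed
#' JASPAR dialect.  Used by the fixture generator.
#'
#' @param counts Named list of 4 x w count matrices (rows A/C/G/T).
#' @param path Output path.
#' @param tf_names Optional TF names (defaults to the motif ids).
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(counts, path, tf_names = names(counts)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(counts)) {
    m <- counts[[i]]
    writeLines(paste0(">", names(counts)[i], " ", tf_names[i]), con)
    for (j in 1:4) {
      writeLines(paste0(DNA_BASES[j], " [ ",
                        paste(format(m[j, ], trim = TRUE), collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}

# integer-encode sequences of equal length as an n x w matrix of base
# indices 1..4
encode_seqs <- function(seqs, width) {
  if (any(nchar(seqs) != width)) {
    stop("sequence length must equal PWM width ", width)
  }
  idx <- match(strsplit(paste(seqs, collapse = ""), "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop("ambiguity code in sequence")
  matrix(idx, ncol = width, byrow = TRUE)
}

#' Log-likelihood-ratio score of sequences against a PWM
#'
#' `sum_i log(P(base_i | position i) / background(base_i))`, natural log.
#' Vectorized over sequences; each must have length `pwm$width`.
#'
#' @param pwm A `pwm_model`.
#' @param seqs Character vector of sequences of length `pwm$width`.
#' @return Numeric vector of scores.
#' @export
score_sequence <- function(pwm, seqs) {
  enc <- encode_seqs(seqs, pwm$width)
  llr <- log(pwm$prob / pwm$background)   # 4 x w
  sc <- numeric(nrow(enc))
  for (j in seq_len(pwm$width)) {
    sc <- sc + llr[enc[, j], j]
  }
  unname(sc)
}

# ---- exact score distribution -----------------------------------------------

# Integerized per-position score increments shared by the distribution
# and the per-sequence lookup: rounding must be identical on both sides
# so a query score falls exactly on its grid bin.
pwm_score_grid <- function(pwm, n_bins) {
  llr <- log(pwm$prob / pwm$background)
  rng <- sum(apply(llr, 2L, max)) - sum(apply(llr, 2L, min))
  delta <- if (rng > 0) rng / n_bins else 1
  list(increments = round(llr / delta), delta = delta)
}

#' Exact PWM score tail distribution by dynamic programming
#'
#' Computes, on an integerized score grid, the exact probability that a
#' random width-w sequence drawn from the (i.i.d.) background model
#' scores at least each achievable score: a convolution across positions
#' of the per-position score increments weighted by the background.
#'
#' @param pwm A `pwm_model`.
#' @param n_bins Number of grid bins spanning the score range
#'   (default 4000; must be >= 1000).
#' @return A list with class `"score_distribution"`: `score` (ascending
#'   grid values on the original score scale), `tail_prob`
#'   (non-increasing, `P(S >= score)`), plus the integer grid internals
#'   used for lookups.
#' @export
score_pvalue_distribution <- function(pwm, n_bins = 4000L) {
  if (n_bins < 1000L) stop("n_bins must be >= 1000")
  grid <- pwm_score_grid(pwm, n_bins)
  inc <- grid$increments   # 4 x w integer matrix
  w <- ncol(inc)
  lo <- sum(apply(inc, 2L, min))
  hi <- sum(apply(inc, 2L, max))
  n <- hi - lo + 1L
  # pmf indexed relative to the running minimum partial sum: after
  # processing positions 1..j, index i holds P(partial score = running_min
  # + i - 1); after all w positions the anchor is lo.
  pmf <- numeric(n)
  first <- inc[, 1L] - min(inc[, 1L])
  for (b in 1:4) {
    pmf[first[b] + 1L] <- pmf[first[b] + 1L] + pwm$background[b]
  }
  if (w > 1L) {
    for (j in 2:w) {
      nxt <- numeric(n)
      for (b in 1:4) {
        s <- inc[b, j] - min(inc[, j])   # non-negative relative shift
        src <- pmf[seq_len(n - s)]
        nxt[(s + 1L):n] <- nxt[(s + 1L):n] + pwm$background[b] * src
      }
      pmf <- nxt
    }
  }
  tail_prob <- rev(cumsum(rev(pmf)))
  structure(
    list(score = (lo:hi) * grid$delta,
         tail_prob = tail_prob,
         int_lo = lo, int_hi = hi,
         increments = inc, delta = grid$delta,
         width = w, motif_id = pwm$motif_id),
    class = "score_distribution"
  )
}

# integer grid score of sequences under a distribution's rounding
dist_int_score <- function(dist, seqs) {
  enc <- encode_seqs(seqs, dist$width)
  sc <- integer(nrow(enc))
  for (j in seq_len(dist$width)) {
    sc <- sc + dist$increments[enc[, j], j]
  }
  sc
}

#' Exact tail p-value of sequences under a PWM score distribution
#'
#' The p-value of a sequence is `P(S >= score(seq))` under the background
#' model, evaluated on the distribution's integer grid (identical
#' rounding on both sides, so no boundary drift).
#'
#' @param dist A `score_distribution` from [score_pvalue_distribution()].
#' @param seqs Character vector of width-w sequences.
#' @return Numeric vector of p-values in (0, 1].
#' @export
pwm_pvalue <- function(dist, seqs) {
  sc <- dist_int_score(dist, seqs)
  idx <- pmin(pmax(sc - dist$int_lo + 1L, 1L), length(dist$tail_prob))
  dist$tail_prob[idx]
}

#' Orientation-free binding p-value
#'
#' The p-value of the better-scoring orientation:
#' `min(p(seq), p(revcomp(seq)))`.  Strand-symmetric by construction.
#'
#' @inheritParams pwm_pvalue
#' @return Numeric vector of binding p-values.
#' @export
binding_pvalue <- function(dist, seqs) {
  pmin(pwm_pvalue(dist, seqs), pwm_pvalue(dist, revcomp(seqs)))
}

#' Binding decision at a p-value threshold
#'
#' A sequence is called binding when its orientation-free p-value is at
#' most `threshold_p` (inclusive comparison).
#'
#' @param pwm A `pwm_model`.
#' @param seqs Character vector of width-w sequences.
#' @param threshold_p Binding p-value threshold in (0, 1] (default 0.001,
#'   the enumeration-phase convention).
#' @param dist Optional precomputed `score_distribution` for `pwm`.
#' @return A tibble with columns `seq`, `pvalue`, `binding`.
#' @export
is_binding <- function(pwm, seqs, threshold_p = 0.001, dist = NULL) {
  stopifnot(threshold_p > 0, threshold_p <= 1)
  if (is.null(dist)) dist <- score_pvalue_distribution(pwm)
  p <- binding_pvalue(dist, seqs)
  tibble::tibble(seq = seqs, pvalue = p, binding = p <= threshold_p)
}
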