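# The counting core: partition the canonical k-mer space of a motif into
# binding and non-binding sequences, tally single-base creation and
# disruption events by trinucleotide mutation class weighted by genomic
# occurrence of the pre-mutation (reference) k-mer, and normalize into
# the motif alteration probability matrix Phi:
#
#   Pr(a | tf, m) = c(a | tf, m) / (c_genome(m_ref) * (w - 2))
#
# Only interior positions 2..w-1 are mutated (a mutation at a k-mer end
# has no complete in-window trinucleotide context), which is what the
# (w - 2) factor in the denominator counts: each genomic trinucleotide
# is tested w - 2 times per motif.

#' Partition the canonical k-mer space into binding and non-binding sets
#'
#' Enumerates all canonical k-mers of the motif's width and splits them
#' by the orientation-free binding p-value at `threshold_p`.
#'
#' @param pwm A `pwm_model`.
#' @param threshold_p Binding p-value threshold (default 0.001).
#' @param max_exhaustive_k Widest motif for which the full k-mer space is
#'   enumerated (default 13); beyond this an explicit error asks for the
#'   genome-restricted path.
#' @param dist Optional precomputed `score_distribution`.
#' @return A list with character vectors `binding` and `non_binding`
#'   (disjoint, union = canonical space) and the `threshold_p` used.
#' @export
partition_kmers <- function(pwm, threshold_p = 0.001,
                            max_exhaustive_k = 13L, dist = NULL) {
  if (pwm$width > max_exhaustive_k) {
    stop("PWM width ", pwm$width, " exceeds the exhaustive enumeration ",
         "limit (", max_exhaustive_k, "); restrict to genomic k-mers")
  }
  if (is.null(dist)) dist <- score_pvalue_distribution(pwm)
  kmers <- enumerate_canonical_kmers(pwm$width)
  p <- binding_pvalue(dist, kmers)
  b <- p <= threshold_p
  list(binding = kmers[b], non_binding = kmers[!b], threshold_p = threshold_p)
}

# all (kmer, interior position, alt) single-base mutants of a set of
# k-mers, with the mutation class of each; long tibble
interior_mutants <- function(kmers, w) {
  if (length(kmers) == 0L) {
    return(tibble::tibble(kmer = character(0), pos = integer(0),
                          alt = character(0), mutant = character(0),
                          class = character(0)))
  }
  pos <- 2:(w - 1L)
  g <- tidyr::expand_grid(kmer = kmers, pos = pos, alt = DNA_BASES)
  ref_base <- substr(g$kmer, g$pos, g$pos)
  g <- g[g$alt != ref_base, ]
  g$mutant <- paste0(substr(g$kmer, 1L, g$pos - 1L), g$alt,
                     substr(g$kmer, g$pos + 1L, w))
  g$class <- classify_mutation(substr(g$kmer, g$pos - 1L, g$pos + 1L), g$alt)
  g
}

#' Tally creation and disruption events for one motif
#'
#' For every binding canonical k-mer, every interior position and every
#' alternative center base, a disruption event is recorded when the
#' mutated k-mer is non-binding; creation events are the symmetric case
#' starting from non-binding k-mers.  Each event is weighted by the
#' genomic occurrence count of the pre-mutation (reference) k-mer;
#' k-mers absent from the genome carry weight 0 but are still
#' classified, so the event catalog is complete.
#'
#' @param pwm A `pwm_model` of width w.
#' @param partition A list from [partition_kmers()].
#' @param genome_kmers A k-mer count tibble from [count_genome_kmers()]
#'   with `attr(, "k") == w`.
#' @return A tibble with 192 rows: `motif_id`, `event` (create/disrupt),
#'   `class` (96 catalog classes each), and integer `count`.
#' @export
count_alteration_events <- function(pwm, partition, genome_kmers) {
  w <- pwm$width
  if (!identical(as.integer(attr(genome_kmers, "k")), as.integer(w))) {
    stop("genome k-mer table width (", attr(genome_kmers, "k"),
         ") does not match PWM width (", w, ")")
  }
  counts <- stats::setNames(genome_kmers$count, genome_kmers$kmer)
  binding <- partition$binding
  tally <- function(from_set, to_set, event) {
    m <- interior_mutants(from_set, w)
    if (nrow(m) > 0L) {
      changed <- canonical_kmer(m$mutant) %in% to_set
      m <- m[changed, ]
    }
    weight <- counts[m$kmer]
    weight[is.na(weight)] <- 0L
    agg <- tapply(as.integer(weight), m$class, sum)
    out <- stats::setNames(integer(96L), mutation_catalog()$class)
    out[names(agg)] <- as.integer(agg)
    tibble::tibble(motif_id = pwm$motif_id, event = event,
                   class = names(out), count = unname(out))
  }
  dplyr::bind_rows(
    tally(binding, partition$non_binding, "disrupt"),
    tally(partition$non_binding, binding, "create")
  )
}

#' Tally events for wide motifs by genome-restricted enumeration
#'
#' For motifs too wide to enumerate the full k-mer space, only the
#' k-mers that occur in the genome are visited: every other k-mer has
#' genomic weight 0 and cannot contribute to either event count (the
#' exhaustive path classifies them but at weight 0), so this
#' restriction is exact, not an approximation.  Binding of each genomic
#' k-mer and of each of its single-base interior mutants is decided on
#' the fly from the exact score p-value.
#'
#' @inheritParams count_alteration_events
#' @param threshold_p Binding p-value threshold.
#' @param dist Optional precomputed `score_distribution`.
#' @return Same shape as [count_alteration_events()].
#' @export
count_alteration_events_restricted <- function(pwm, genome_kmers,
                                               threshold_p = 0.001,
                                               dist = NULL) {
  w <- pwm$width
  if (!identical(as.integer(attr(genome_kmers, "k")), as.integer(w))) {
    stop("genome k-mer table width (", attr(genome_kmers, "k"),
         ") does not match PWM width (", w, ")")
  }
  if (is.null(dist)) dist <- score_pvalue_distribution(pwm)
  empty <- function(event) {
    tibble::tibble(motif_id = pwm$motif_id, event = event,
                   class = mutation_catalog()$class, count = 0L)
  }
  if (nrow(genome_kmers) == 0L) {
    return(dplyr::bind_rows(empty("disrupt"), empty("create")))
  }
  ref_binding <- binding_pvalue(dist, genome_kmers$kmer) <= threshold_p
  m <- interior_mutants(genome_kmers$kmer, w)
  mut_binding <- binding_pvalue(dist, m$mutant) <= threshold_p
  m$weight <- genome_kmers$count[match(m$kmer, genome_kmers$kmer)]
  m$ref_binding <- ref_binding[match(m$kmer, genome_kmers$kmer)]
  tally <- function(sel, event) {
    agg <- tapply(as.integer(m$weight[sel]), m$class[sel], sum)
    out <- stats::setNames(integer(96L), mutation_catalog()$class)
    out[names(agg)] <- as.integer(agg)
    tibble::tibble(motif_id = pwm$motif_id, event = event,
                   class = names(out), count = unname(out))
  }
  dplyr::bind_rows(
    tally(m$ref_binding & !mut_binding, "disrupt"),
    tally(!m$ref_binding & mut_binding, "create")
  )
}

#' Normalize event counts into alteration probabilities
#'
#' Divides each event count by the genomic abundance of the mutation
#' class's reference trinucleotide times (w - 2), the number of times
#' each genomic trinucleotide occurrence is tested for a width-w motif.
#'
#' @param events Event count tibble from [count_alteration_events()].
#' @param trinuc_counts Tibble from [count_genome_trinucleotides()].
#' @param width Motif width w.
#' @return `events` with an added `prob` column in `[0, 1]`.
#' @export
normalize_counts <- function(events, trinuc_counts, width) {
  cat96 <- mutation_catalog()
  ref <- stats::setNames(cat96$ref_trinucleotide, cat96$class)
  denom_tab <- stats::setNames(trinuc_counts$count, trinuc_counts$trinucleotide)
  denom <- denom_tab[ref[events$class]] * (width - 2L)
  bad <- events$count > 0 & denom == 0
  if (any(bad)) {
    stop("nonzero event count for class(es) with zero genomic reference ",
         "trinucleotides: ", paste(unique(events$class[bad]), collapse = ", "))
  }
  events$prob <- unname(ifelse(denom > 0, events$count / denom, 0))
  events
}

#' Build the motif alteration probability matrix Phi
#'
#' Orchestrates, per motif: canonical k-mer partition at the binding
#' threshold, event tallying weighted by genomic k-mer counts, and
#' normalization by reference trinucleotide abundance.  Motifs wider
#' than `max_exhaustive_k` are counted by the exact genome-restricted
#' path ([count_alteration_events_restricted()]).  Deterministic given
#' its inputs.
#'
#' @param pwms A named list of `pwm_model` objects (see [read_jaspar()]).
#' @param fasta Path to the genome FASTA, or a named character vector of
#'   contig sequences.
#' @param threshold_p Binding p-value threshold (default 0.001).
#' @param max_exhaustive_k Widest motif enumerated exhaustively
#'   (default 13).
#' @param n_bins Score-grid resolution for the exact p-values.
#' @return A tibble of class `phi_tbl` in long format: `motif_id`,
#'   `event` (create/disrupt), `class` (96 mutation classes), `count`,
#'   `prob`.  Attributes record widths, threshold and the trinucleotide
#'   denominators.
#' @export
build_phi <- function(pwms, fasta, threshold_p = 0.001,
                      max_exhaustive_k = 13L, n_bins = 4000L) {
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  contigs <- if (is.character(fasta) && length(fasta) == 1L &&
                 file.exists(fasta)) read_genome(fasta) else toupper(fasta)
  trinuc <- count_genome_trinucleotides(contigs)
  widths <- vapply(pwms, function(p) p$width, integer(1))
  kmer_tables <- lapply(unique(widths), function(k) {
    count_genome_kmers(contigs, k)
  })
  names(kmer_tables) <- as.character(unique(widths))
  rows <- lapply(pwms, function(pwm) {
    dist <- score_pvalue_distribution(pwm, n_bins = n_bins)
    ktab <- kmer_tables[[as.character(pwm$width)]]
    events <- if (pwm$width > max_exhaustive_k) {
      count_alteration_events_restricted(pwm, ktab,
                                         threshold_p = threshold_p,
                                         dist = dist)
    } else {
      part <- partition_kmers(pwm, threshold_p = threshold_p,
                              max_exhaustive_k = max_exhaustive_k,
                              dist = dist)
      count_alteration_events(pwm, part, ktab)
    }
    normalize_counts(events, trinuc, pwm$width)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phi_tbl", class(out))
  attr(out, "widths") <- stats::setNames(
    widths, vapply(pwms, function(p) p$motif_id, character(1)))
  attr(out, "threshold_p") <- threshold_p
  attr(out, "trinucleotide_counts") <- trinuc
  out
}

#' Write Phi as TSV
#'
#' Long format: one row per (motif, mutation class) with creation and
#' disruption probabilities side by side.
#'
#' @param phi A `phi_tbl` from [build_phi()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phi <- function(phi, path) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(phi)[, c("motif_id", "event", "class", "prob")],
    names_from = "event", values_from = "prob", names_glue = "{event}_prob")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a Phi TSV back into a `phi_tbl`
#' @param path TSV written by [write_phi()].
#' @return A `phi_tbl` (without count columns).
#' @export
read_phi <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tidyr::pivot_longer(wide, dplyr::ends_with("_prob"),
                             names_to = "event", values_to = "prob")
  out$event <- sub("_prob$", "", out$event)
  class(out) <- c("phi_tbl", class(out))
  out
}
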