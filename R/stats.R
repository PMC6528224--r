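# Summary statistics over alteration signatures: absolute relative
# difference between creation and disruption, binding-set trinucleotide
# entropy, creation-disruption correlation, the SOM grid-width
# criterion, and cohort-level differential medians.

#' Absolute relative difference between creation and disruption
#'
#' `|RD| = 2 |p_create - p_disrupt| / (p_create + p_disrupt)`, bounded
#' in `[0, 2]` and invariant under common rescaling of both inputs.
#' The degenerate case `p_create = p_disrupt = 0` is defined as 0 (with
#' a warning): the two one-sided limits disagree, so a convention is
#' required.
#'
#' @param p_create,p_disrupt Non-negative numeric vectors.
#' @return Numeric vector in `[0, 2]`.
#' @examples
#' absolute_relative_difference(0.3, 0.1)  # 1
#' absolute_relative_difference(0.3, 0)    # 2
#' @export
absolute_relative_difference <- function(p_create, p_disrupt) {
  stopifnot(length(p_create) == length(p_disrupt))
  if (any(p_create < 0 | p_disrupt < 0)) {
    stop("alteration probabilities must be non-negative")
  }
  tot <- p_create + p_disrupt
  both_zero <- tot == 0
  if (any(both_zero)) {
    warning("|RD| at (0, 0) defined as 0 by convention (",
            sum(both_zero), " case(s))")
  }
  out <- numeric(length(tot))
  out[!both_zero] <- 2 * abs(p_create[!both_zero] - p_disrupt[!both_zero]) /
    tot[!both_zero]
  out
}

#' Trinucleotide entropy of a motif's binding sequences
#'
#' Pools the interior trinucleotides (positions 2..w-1) of every binding
#' k-mer with equal weight, collapses them to the 32 pyrimidine-centered
#' classes, and returns the Shannon entropy (bits) of the resulting
#' composition.  Low entropy marks motifs whose binding sequences
#' concentrate on few trinucleotides; maximal entropy is log2(32) = 5.
#'
#' @param binding_set Non-empty character vector of binding k-mers of a
#'   common width w >= 3.
#' @param motif_id Optional motif id carried into the result.
#' @return A one-row tibble: `motif_id`, `entropy` (bits), `n_binding`.
#' @export
motif_entropy <- function(binding_set, motif_id = NA_character_) {
  if (length(binding_set) == 0L) stop("empty binding set")
  w <- unique(nchar(binding_set))
  if (length(w) != 1L || w < 3L) {
    stop("binding k-mers must share one width >= 3")
  }
  tris <- unlist(lapply(2:(w - 1L), function(p) {
    substr(binding_set, p - 1L, p + 1L)
  }), use.names = FALSE)
  freq <- table(pyrimidine_collapse(tris))
  p <- as.numeric(freq) / sum(freq)
  tibble::tibble(
    motif_id = motif_id,
    entropy = -sum(p * log2(p)),
    n_binding = length(binding_set)
  )
}

#' Correlation between creation and disruption across signatures
#'
#' Pearson correlation of the per-signature creation and disruption
#' probabilities, per motif, plus the pooled correlation over all
#' (motif, signature) pairs.  Motifs whose creation or disruption vector
#' has zero variance get `NA` (correlation undefined).
#'
#' @param stf A `motif_signature_tbl` from [project_signatures()] with
#'   at least 3 signatures.
#' @return A list with `per_motif` (tibble `motif_id`, `r`, `n`) and
#'   `global` (pooled Pearson r).
#' @export
creation_disruption_correlation <- function(stf) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(stf),
                             names_from = "event", values_from = "prob")
  if (length(unique(wide$signature_id)) < 3L) {
    stop("at least 3 signatures are required")
  }
  per_motif <- wide |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(
      r = if (stats::sd(.data$create) == 0 || stats::sd(.data$disrupt) == 0)
        NA_real_ else stats::cor(.data$create, .data$disrupt),
      n = dplyr::n(),
      .groups = "drop"
    )
  global <- if (stats::sd(wide$create) == 0 || stats::sd(wide$disrupt) == 0)
    NA_real_ else stats::cor(wide$create, wide$disrupt)
  list(per_motif = per_motif, global = global)
}

#' SOM grid width for a motif collection
#'
#' The largest integer `w` whose square grid holds strictly fewer cells
#' than items: `argmax_w {w^2} < n_items`, so every item can occupy its
#' own cell with the grid as fine as that constraint allows.
#'
#' @param n_items Integer number of items (>= 2).
#' @return Integer grid width.
#' @examples
#' som_grid_width(512)  # 22
#' @export
som_grid_width <- function(n_items) {
  if (length(n_items) != 1L || is.na(n_items) || n_items != round(n_items) ||
      n_items < 2) {
    stop("n_items must be a single integer >= 2")
  }
  w <- floor(sqrt(n_items))
  if (w * w >= n_items) w <- w - 1L
  as.integer(w)
}

#' Cohort-level differential alteration summaries
#'
#' For each (sample group, motif group): the median over all member
#' samples and motifs of the per-entry difference creation minus
#' disruption probability.
#'
#' @param psi A `patient_prediction_tbl` from [predict_patients()].
#' @param sample_groups Tibble with `sample_id`, `group` covering every
#'   sample in `psi`.
#' @param motif_groups Tibble with `motif_id`, `family` covering every
#'   motif in `psi`.
#' @return A tibble: `group`, `family`, `differential` (median of
#'   create - disrupt, in `[-1, 1]`), `n` (entries pooled).
#' @export
cohort_differential <- function(psi, sample_groups, motif_groups) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(psi),
                             names_from = "event", values_from = "prob")
  miss_s <- setdiff(unique(wide$sample_id), sample_groups$sample_id)
  miss_m <- setdiff(unique(wide$motif_id), motif_groups$motif_id)
  if (length(miss_s) > 0L) {
    stop("sample(s) without group: ", paste(miss_s, collapse = ", "))
  }
  if (length(miss_m) > 0L) {
    stop("motif(s) without family: ", paste(miss_m, collapse = ", "))
  }
  wide |>
    dplyr::left_join(sample_groups, by = "sample_id") |>
    dplyr::left_join(motif_groups, by = "motif_id") |>
    dplyr::group_by(.data$group, .data$family) |>
    dplyr::summarise(
      differential = stats::median(.data$create - .data$disrupt),
      n = dplyr::n(),
      .groups = "drop"
    )
}
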