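# Signature matrix I/O and the projection algebra:
#   S_TF = S_M %*% t(Phi)        per event kind  (signatures x motifs)
#   Psi  = t(S_TF) %*% E         per event kind  (motifs x samples)
# plus mapping one signature set onto another by Pearson correlation
# over the 96 mutation classes and collapsing exposures through that map.

#' Read a COSMIC-style mutational signature TSV
#'
#' Accepts both circulating dialects: a combined mutation-class label
#' column (`A[C>A]A` style, any column name or row names) or the
#' "Substitution Type" + "Trinucleotide" column pair.  Rows are
#' reordered to catalog order and renormalized to sum exactly 1 when
#' within `1e-3` of 1 (otherwise an error).
#'
#' @param path TSV path: 96 rows, one column per signature.
#' @return A `signature_tbl`: long tibble with `signature_id`, `class`,
#'   `prob`; per-signature probabilities sum to 1.
#' @export
read_signatures <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cat96 <- mutation_catalog()
  nm <- tolower(names(raw))
  sub_col <- which(nm %in% c("substitution type", "substitution_type"))
  tri_col <- which(nm == "trinucleotide")
  if (length(sub_col) == 1L && length(tri_col) == 1L) {
    sub <- raw[[sub_col]]
    tri <- raw[[tri_col]]
    labels <- paste0(substr(tri, 1, 1), "[", sub, "]", substr(tri, 3, 3))
    value_cols <- setdiff(seq_along(raw), c(sub_col, tri_col))
  } else {
    # first non-numeric column holds combined labels
    is_lab <- vapply(raw, function(x) is.character(x) &&
                       any(grepl("\\[[CT]>[ACGT]\\]", x)), logical(1))
    if (!any(is_lab)) stop("no mutation-class labels found in ", path)
    lab_col <- which(is_lab)[1]
    labels <- raw[[lab_col]]
    value_cols <- setdiff(seq_along(raw), lab_col)
    value_cols <- value_cols[vapply(raw[value_cols], is.numeric, logical(1))]
  }
  missing <- setdiff(cat96$class, labels)
  if (length(missing) > 0L) {
    stop("signature file lacks mutation class(es): ",
         paste(utils::head(missing, 4), collapse = ", "))
  }
  ord <- match(cat96$class, labels)
  vals <- as.matrix(raw[ord, value_cols])
  if (any(vals < 0)) stop("negative signature probabilities in ", path)
  sums <- colSums(vals)
  if (any(abs(sums - 1) > 1e-3)) {
    stop("signature column(s) deviate from sum 1 by more than 1e-3: ",
         paste(colnames(vals)[abs(sums - 1) > 1e-3], collapse = ", "))
  }
  vals <- sweep(vals, 2L, sums, "/")
  out <- tibble::tibble(
    signature_id = rep(colnames(vals), each = 96L),
    class = rep(cat96$class, times = ncol(vals)),
    prob = as.vector(vals)
  )
  class(out) <- c("signature_tbl", class(out))
  out
}

#' Write signatures as a COSMIC-style TSV
#' @param signatures A `signature_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(signatures),
                             names_from = "signature_id",
                             values_from = "prob")
  names(wide)[1] <- "Mutation Type"
  readr::write_tsv(wide, path)
  invisible(path)
}

# signature_tbl -> signatures x 96 matrix in catalog order
signature_matrix <- function(signatures) {
  cat96 <- mutation_catalog()$class
  ids <- unique(signatures$signature_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = 96L,
              dimnames = list(ids, cat96))
  m[cbind(match(signatures$signature_id, ids),
          match(signatures$class, cat96))] <- signatures$prob
  if (anyNA(m)) stop("signature table is not complete over the 96 classes")
  m
}

# phi_tbl -> list of motifs x 96 matrices, one per event kind
phi_matrices <- function(phi) {
  cat96 <- mutation_catalog()$class
  motifs <- unique(phi$motif_id)
  lapply(stats::setNames(c("create", "disrupt"), c("create", "disrupt")),
         function(ev) {
    sub <- phi[phi$event == ev, ]
    m <- matrix(0, nrow = length(motifs), ncol = 96L,
                dimnames = list(motifs, cat96))
    m[cbind(match(sub$motif_id, motifs), match(sub$class, cat96))] <- sub$prob
    m
  })
}

#' Project Phi through mutational signatures: the motif alteration signature
#'
#' For each event kind, computes `S_TF = S_M %*% t(Phi)`:
#' `Pr(a | tf, s) = sum_k Pr(a | tf, m_k) Pr(m_k | s)`, a convex
#' combination of the motif's per-class alteration probabilities
#' weighted by the signature.
#'
#' @param phi A `phi_tbl` from [build_phi()].
#' @param signatures A `signature_tbl` from [read_signatures()].
#' @return A `motif_signature_tbl`: long tibble with `signature_id`,
#'   `motif_id`, `event`, `prob`.
#' @export
project_signatures <- function(phi, signatures) {
  sm <- signature_matrix(signatures)
  phis <- phi_matrices(phi)
  rows <- lapply(names(phis), function(ev) {
    stf <- sm %*% t(phis[[ev]])   # signatures x motifs
    tibble::tibble(
      signature_id = rep(rownames(stf), times = ncol(stf)),
      motif_id = rep(colnames(stf), each = nrow(stf)),
      event = ev,
      prob = as.vector(stf)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("motif_signature_tbl", class(out))
  out
}

#' Map one signature set onto another by Pearson correlation
#'
#' Each source signature is assigned the target signature with the
#' highest Pearson correlation across the 96 mutation classes.  Ties are
#' broken by target file order (first wins) and reported via a message.
#'
#' @param source,target `signature_tbl` objects on the same 96-class
#'   axis.
#' @return A tibble with `source_id`, `target_id`, `correlation`.
#' @export
map_signature_sets <- function(source, target) {
  sm <- signature_matrix(source)
  tm <- signature_matrix(target)
  const <- apply(sm, 1L, stats::sd) == 0
  if (any(const)) {
    stop("constant signature vector(s), correlation undefined: ",
         paste(rownames(sm)[const], collapse = ", "))
  }
  const_t <- apply(tm, 1L, stats::sd) == 0
  if (any(const_t)) {
    stop("constant signature vector(s), correlation undefined: ",
         paste(rownames(tm)[const_t], collapse = ", "))
  }
  cc <- stats::cor(t(sm), t(tm))   # source x target
  best <- apply(cc, 1L, function(r) {
    hits <- which(r == max(r))
    if (length(hits) > 1L) {
      message("correlation tie broken by file order: ",
              paste(colnames(cc)[hits], collapse = ", "))
    }
    hits[1]
  })
  tibble::tibble(
    source_id = rownames(cc),
    target_id = colnames(cc)[best],
    correlation = cc[cbind(seq_len(nrow(cc)), best)]
  )
}

#' Read a per-sample signature exposure TSV
#'
#' Expects signatures in rows (first column = signature id) and samples
#' in columns.  Raw (count-scale) exposures are preserved in `raw` and
#' normalized to per-sample probabilities in `exposure`.
#'
#' @param path TSV path.
#' @return An `exposure_tbl`: long tibble with `signature_id`,
#'   `sample_id`, `raw`, `exposure` (per-sample columns sum to 1).
#' @export
read_exposures <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (any(vals < 0)) stop("negative exposures in ", path)
  rownames(vals) <- ids
  normalize_exposure_matrix(vals)
}

normalize_exposure_matrix <- function(vals) {
  tot <- colSums(vals)
  if (any(tot == 0)) {
    stop("sample(s) with zero total exposure: ",
         paste(colnames(vals)[tot == 0], collapse = ", "))
  }
  norm <- sweep(vals, 2L, tot, "/")
  out <- tibble::tibble(
    signature_id = rep(rownames(vals), times = ncol(vals)),
    sample_id = rep(colnames(vals), each = nrow(vals)),
    raw = as.vector(vals),
    exposure = as.vector(norm)
  )
  class(out) <- c("exposure_tbl", class(out))
  out
}

#' Collapse exposures through a signature mapping
#'
#' Sums each sample's exposures over source signatures that map to the
#' same target signature, then renormalizes per sample.
#'
#' @param exposures An `exposure_tbl` over the source signature ids.
#' @param mapping A tibble from [map_signature_sets()] (`source_id`,
#'   `target_id`).
#' @return An `exposure_tbl` over the target signature ids.
#' @export
collapse_exposures <- function(exposures, mapping) {
  unmapped <- setdiff(unique(exposures$signature_id), mapping$source_id)
  if (length(unmapped) > 0L) {
    stop("exposure signature(s) missing from the mapping: ",
         paste(unmapped, collapse = ", "))
  }
  joined <- dplyr::left_join(tibble::as_tibble(exposures),
                             mapping[, c("source_id", "target_id")],
                             by = c(signature_id = "source_id"))
  agg <- joined |>
    dplyr::group_by(.data$target_id, .data$sample_id) |>
    dplyr::summarise(raw = sum(.data$raw), .groups = "drop")
  samples <- unique(exposures$sample_id)
  targets <- unique(mapping$target_id)
  vals <- matrix(0, nrow = length(targets), ncol = length(samples),
                 dimnames = list(targets, samples))
  vals[cbind(match(agg$target_id, targets),
             match(agg$sample_id, samples))] <- agg$raw
  normalize_exposure_matrix(vals)
}

#' Predict per-sample motif alteration probabilities: Psi
#'
#' For each event kind, computes `Psi = t(S_TF) %*% E`: each sample's
#' motif alteration probability is the exposure-weighted convex
#' combination of the per-signature values.
#'
#' @param stf A `motif_signature_tbl` from [project_signatures()].
#' @param exposures An `exposure_tbl` on the same signature ids.
#' @return A `patient_prediction_tbl`: long tibble with `motif_id`,
#'   `sample_id`, `event`, `prob`.
#' @export
predict_patients <- function(stf, exposures) {
  sig_ids <- unique(stf$signature_id)
  if (!setequal(sig_ids, unique(exposures$signature_id))) {
    stop("signature ids of S_TF and exposures do not match")
  }
  samples <- unique(exposures$sample_id)
  emat <- matrix(0, nrow = length(sig_ids), ncol = length(samples),
                 dimnames = list(sig_ids, samples))
  emat[cbind(match(exposures$signature_id, sig_ids),
             match(exposures$sample_id, samples))] <- exposures$exposure
  motifs <- unique(stf$motif_id)
  rows <- lapply(c("create", "disrupt"), function(ev) {
    sub <- stf[stf$event == ev, ]
    smat <- matrix(0, nrow = length(sig_ids), ncol = length(motifs),
                   dimnames = list(sig_ids, motifs))
    smat[cbind(match(sub$signature_id, sig_ids),
               match(sub$motif_id, motifs))] <- sub$prob
    psi <- t(smat) %*% emat   # motifs x samples
    tibble::tibble(
      motif_id = rep(rownames(psi), times = ncol(psi)),
      sample_id = rep(colnames(psi), each = nrow(psi)),
      event = ev,
      prob = as.vector(psi)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("patient_prediction_tbl", class(out))
  out
}
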