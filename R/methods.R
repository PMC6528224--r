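# broom-style tidy()/glance() and ggplot2 autoplot() methods for the
# package's result tables.

#' @rdname tidy_sigmotif
#' @title Tidy sigmotif result tables
#' @description `tidy()` returns the plain long tibble underlying a
#'   result (attributes and subclass stripped); `glance()` returns a
#'   one-row summary.
#' @param x A `phi_tbl`, `motif_signature_tbl` or
#'   `patient_prediction_tbl`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phi_tbl <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @rdname tidy_sigmotif
#' @export
tidy.motif_signature_tbl <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @rdname tidy_sigmotif
#' @export
tidy.patient_prediction_tbl <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "widths") <- NULL
  attr(x, "threshold_p") <- NULL
  attr(x, "trinucleotide_counts") <- NULL
  x
}

#' @rdname tidy_sigmotif
#' @export
glance.phi_tbl <- function(x, ...) {
  tibble::tibble(
    n_motifs = length(unique(x$motif_id)),
    n_classes = length(unique(x$class)),
    threshold_p = attr(x, "threshold_p") %||% NA_real_,
    max_prob = max(x$prob),
    mean_create = mean(x$prob[x$event == "create"]),
    mean_disrupt = mean(x$prob[x$event == "disrupt"])
  )
}

#' @rdname tidy_sigmotif
#' @export
glance.motif_signature_tbl <- function(x, ...) {
  tibble::tibble(
    n_signatures = length(unique(x$signature_id)),
    n_motifs = length(unique(x$motif_id)),
    mean_create = mean(x$prob[x$event == "create"]),
    mean_disrupt = mean(x$prob[x$event == "disrupt"])
  )
}

#' @rdname tidy_sigmotif
#' @export
glance.patient_prediction_tbl <- function(x, ...) {
  tibble::tibble(
    n_motifs = length(unique(x$motif_id)),
    n_samples = length(unique(x$sample_id)),
    mean_create = mean(x$prob[x$event == "create"]),
    mean_disrupt = mean(x$prob[x$event == "disrupt"])
  )
}

#' Heatmap of a motif alteration probability matrix
#'
#' Mutation classes (catalog order) on the x axis, motifs on the y
#' axis, faceted by event kind.
#'
#' @param object A `phi_tbl` from [build_phi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phi_tbl <- function(object, ...) {
  d <- tidy(object)
  d$class <- factor(d$class, levels = mutation_catalog()$class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$motif_id,
                                  fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~event, ncol = 1L) +
    ggplot2::scale_fill_viridis_c(name = "Pr(a | tf, m)") +
    ggplot2::labs(x = "trinucleotide mutation class", y = NULL,
                  title = "Motif alteration probabilities") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, hjust = 1, size = 4))
}

#' Heatmap of a motif alteration signature (S_TF)
#'
#' @param object A `motif_signature_tbl` from [project_signatures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_signature_tbl <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$motif_id,
                                  y = .data$signature_id,
                                  fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~event, ncol = 1L) +
    ggplot2::scale_fill_viridis_c(name = "Pr(a | tf, s)") +
    ggplot2::labs(x = NULL, y = NULL, title = "Motif alteration signature") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, hjust = 1))
}

#' Differential alteration (creation minus disruption) per sample
#'
#' @param object A `patient_prediction_tbl` from [predict_patients()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.patient_prediction_tbl <- function(object, ...) {
  d <- tidyr::pivot_wider(tidy(object), names_from = "event",
                          values_from = "prob")
  d$differential <- d$create - d$disrupt
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$motif_id,
                                  fill = .data$differential)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "create - disrupt") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-sample differential motif alteration") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, hjust = 1))
}
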