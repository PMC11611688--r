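# ggplot2 views of the result objects.

#' Plot a training loss history
#'
#' @param object the `history` tibble returned by [train()].
#' @param ... ignored.
#' @return a ggplot object: one line per loss component over epochs, phases
#'   separated by facet.
#' @export
plot_loss_history <- function(object, ...) {
  stopifnot(all(c("epoch", "phase", "total") %in% names(object)))
  long <- do.call(rbind, lapply(c("rec", "con", "adv_g", "adv_d", "total"),
                                function(cmp) {
    tibble::tibble(phase = object$phase,
                   epoch = unlist(object$epoch),
                   component = cmp,
                   value = as.numeric(unlist(object[[cmp]])))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL)
}

#' @importFrom rlang .data
NULL

#' Plot an attribution result
#'
#' Bars for the `top_n` highest-scoring peaks of an `attribution_result`.
#'
#' @param object an `attribution_result`.
#' @param top_n peaks shown (default 10).
#' @param ... ignored.
#' @method autoplot attribution_result
#' @export
autoplot.attribution_result <- function(object, top_n = 10, ...) {
  top <- rank_peaks(object, top_n = top_n)
  top$peak_id <- factor(top$peak_id, levels = rev(top$peak_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$score, y = .data$peak_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = paste("peak attribution for", object$gene),
                  x = "integrated-gradient score", y = NULL)
}

#' Plot a joint embedding
#'
#' First two latent coordinates of a [bind_embeddings()] result, coloured by
#' modality or by a supplied label vector.
#'
#' @param joint a [bind_embeddings()] result.
#' @param colour_by `"modality"` or a vector of labels.
#' @export
plot_joint_embedding <- function(joint, colour_by = "modality") {
  lab <- if (identical(colour_by, "modality")) joint$modality else colour_by
  df <- tibble::tibble(dim1 = joint$values[, 1], dim2 = joint$values[, 2],
                       label = as.character(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::labs(x = "latent 1", y = "latent 2", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
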