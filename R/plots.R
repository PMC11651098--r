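#' Plot an Elo trajectory
#'
#' Permutation-mean rating per genus against cycle; ribbons show +-1 SD
#' across microcosm-order permutations.
#'
#' @param object An `elo_trajectory`.
#' @param top_n Label/colour only the `top_n` genera by final rating
#'   (default 10); the rest are drawn in grey.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elo_trajectory <- function(object, top_n = 10, ...) {
  tr <- object$trajectory
  last <- max(tr$cycle)
  top <- tr |> dplyr::filter(.data$cycle == last) |>
    dplyr::slice_max(.data$rating, n = top_n) |> dplyr::pull("genus")
  tr$highlight <- ifelse(tr$genus %in% top, tr$genus, NA)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cycle, y = .data$rating,
                                   group = .data$genus)) +
    ggplot2::geom_line(data = tr[is.na(tr$highlight), ], colour = "grey80") +
    ggplot2::geom_ribbon(data = tr[!is.na(tr$highlight), ],
                         ggplot2::aes(ymin = .data$rating - .data$sd,
                                      ymax = .data$rating + .data$sd,
                                      fill = .data$highlight), alpha = 0.15,
                         colour = NA) +
    ggplot2::geom_line(data = tr[!is.na(tr$highlight), ],
                       ggplot2::aes(colour = .data$highlight)) +
    ggplot2::labs(x = "growth cycle", y = "Elo rating",
                  colour = "genus", fill = "genus") +
    ggplot2::theme_minimal()
}

#' Plot Raup-Crick bin fractions across cycles
#'
#' Stacked per-cycle fractions of microcosm pairs more similar than chance,
#' indistinguishable from stochastic assembly, or more dissimilar than
#' chance.
#'
#' @param bins_by_cycle Named list of [classify_beta()] tibbles (names =
#'   cycle ids) or a single tibble.
#' @return A ggplot object.
#' @export
plot_beta_bins <- function(bins_by_cycle) {
  if (is.data.frame(bins_by_cycle)) bins_by_cycle <- list(all = bins_by_cycle)
  d <- purrr::imap_dfr(bins_by_cycle, function(b, id) dplyr::mutate(b, cycle = id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$fraction,
                                  fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(similar = "#2166ac",
                                          stochastic = "grey70",
                                          dissimilar = "#b2182b")) +
    ggplot2::labs(x = "growth cycle", y = "fraction of microcosm pairs",
                  fill = expression(beta[RC] ~ bin)) +
    ggplot2::theme_minimal()
}

#' Plot local and regional richness across cycles
#'
#' Boxplots of per-microcosm richness with the regional (gamma) richness
#' overlaid as a line, from per-cycle [alpha_gamma()] tibbles.
#'
#' @param alpha_by_cycle Named list of [alpha_gamma()] tibbles (names = cycle
#'   ids).
#' @return A ggplot object.
#' @export
plot_richness <- function(alpha_by_cycle) {
  d <- purrr::imap_dfr(alpha_by_cycle, function(a, id) dplyr::mutate(a, cycle = id))
  g <- d |> dplyr::distinct(.data$cycle, .data$gamma)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$richness)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_line(data = g, ggplot2::aes(y = .data$gamma, group = 1),
                       colour = "#b2182b") +
    ggplot2::geom_point(data = g, ggplot2::aes(y = .data$gamma), colour = "#b2182b") +
    ggplot2::labs(x = "growth cycle",
                  y = "richness (boxes: per microcosm; red: regional)") +
    ggplot2::theme_minimal()
}

#' Plot observed post-coalescence abundances against both model predictions
#'
#' Genera ordered by neutral prediction; observed per-microcosm relative
#' abundances as points coloured by assigned category, the two model
#' predictions as lines.
#'
#' @param object A `coalescence_prediction`.
#' @param observed The post-coalescence abundance table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coalescence_prediction <- function(object, observed = NULL, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::arrange(dplyr::desc(.data$pred_neutral)) |>
    dplyr::mutate(genus = factor(.data$genus, levels = .data$genus))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genus)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_neutral, group = 1,
                                    linetype = "neutral"), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_competitive, group = 1,
                                    linetype = "competitiveness"), colour = "#e08214") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_mean, colour = .data$category)) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = NULL, y = "relative abundance (sqrt scale)",
                  linetype = "model", colour = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
  if (!is.null(observed)) {
    m <- count_matrix(observed)
    rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
    long <- tibble::as_tibble(rel, rownames = "genus") |>
      tidyr::pivot_longer(-"genus", names_to = "microcosm", values_to = "rel") |>
      dplyr::mutate(genus = factor(.data$genus, levels = levels(d$genus)))
    p <- p + ggplot2::geom_point(data = long,
                                 ggplot2::aes(y = .data$rel), alpha = 0.2, size = 0.5)
  }
  p
}
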