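# Tidiers and plots for fitted agents and reward breakdowns.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the episode log of a trained agent
#'
#' @param x A `polydeg_fit`.
#' @param ... Unused.
#' @return The per-episode log as a tibble (one row per episode).
#' @export
tidy.polydeg_fit <- function(x, ...) {
  x$episodes
}

#' One-row summary of a training run
#'
#' Metrics over the final sliding window: validity rate, mean total
#' reward, mean diversity bonus, mean positive constraint violation
#' and the final multipliers.
#'
#' @param x A `polydeg_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.polydeg_fit <- function(x, ...) {
  ep <- x$episodes
  win <- x$config$train$window
  tail_ep <- ep[max(1, nrow(ep) - win + 1):nrow(ep), ]
  tibble::tibble(
    episodes = nrow(ep),
    validity_rate = mean(tail_ep$valid),
    mean_reward = mean(tail_ep$r_total),
    mean_diversity = mean(tail_ep$r_diversity),
    mean_violation = mean(pmax(0, tail_ep$g1) + pmax(0, tail_ep$g2) +
                            pmax(0, tail_ep$g3)),
    lambda1 = x$duals$lambda[1], lambda2 = x$duals$lambda[2],
    lambda3 = x$duals$lambda[3]
  )
}

#' Training curves for a fitted agent
#'
#' Faceted episode traces: total reward, validity, diversity bonus
#' and the summed positive constraint violation.
#'
#' @param object A `polydeg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polydeg_fit <- function(object, ...) {
  ep <- object$episodes
  long <- tidyr::pivot_longer(
    dplyr::transmute(ep,
                     episode = .data$episode,
                     reward = .data$r_total,
                     validity = as.numeric(.data$valid),
                     diversity = .data$r_diversity,
                     violation = pmax(0, .data$g1) + pmax(0, .data$g2) +
                       pmax(0, .data$g3)),
    -"episode", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$episode, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "episode", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a reward breakdown
#'
#' @param breakdown A `reward_breakdown` (or the tibble from
#'   [as_tibble_breakdown()]).
#' @return A ggplot object.
#' @export
plot_reward_breakdown <- function(breakdown) {
  df <- if (inherits(breakdown, "reward_breakdown")) {
    as_tibble_breakdown(breakdown)
  } else tibble::as_tibble(breakdown)
  long <- tidyr::pivot_longer(df, dplyr::everything(),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$component,
                                                        .data$value),
                                     y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reward") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
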