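#' @exportS3Method
autoplot.sigmoid_fit <- function(object, n = 200, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
                         length.out = n))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "inducer concentration (% w/v)", y = "signal",
                  title = sprintf("sigmoid dose-response (f_max=%.3g, x_half=%.3g)",
                                  object$f_max, object$x_half))
}

#' @exportS3Method
autoplot.gamma_fit <- function(object, bins = 40, ...) {
  dat <- tibble(value = object$values)
  grid <- tibble(value = seq(min(dat$value), max(dat$value), length.out = 300))
  grid$density <- stats::dgamma(grid$value, shape = object$shape,
                                scale = object$scale)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$density), colour = "firebrick") +
    ggplot2::labs(x = "per-cell fluorescence", y = "density",
                  title = sprintf("gamma fit: shape=%.3g, scale=%.3g, CV=%.2g",
                                  object$shape, object$scale, object$cv_predicted))
}

#' @exportS3Method
autoplot.decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = exp(stats::fitted(object$fit))),
                       colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "signal (log scale)",
                  title = sprintf("exponential dilution: half-life %.3g",
                                  object$half_time))
}

#' Log-log scatter of uninduced vs induced expression
#'
#' Mirrors the standard paired-culture audit view: each gene at its uninduced
#' (x) and induced (y) abundance, with off-target subset members highlighted
#' and an optional target gene labelled.
#'
#' @param table Expression tibble (see [load_expression()]).
#' @param memberships Optional membership tibble from [build_subsets()].
#' @param target_gene Optional gene to label.
#' @return A ggplot object.
#' @export
plot_expression_audit <- function(table, memberships = NULL,
                                  target_gene = NULL) {
  tb <- dplyr::filter(table, .data$abundance_uninduced > 0,
                      .data$abundance_induced > 0)
  tb$subset <- "all genes"
  if (!is.null(memberships) && nrow(memberships)) {
    m <- dplyr::distinct(memberships, .data$gene, .data$tier)
    first_tier <- m[!duplicated(m$gene), ]
    tb$subset[match(first_tier$gene, tb$gene)] <- first_tier$tier
  }
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$abundance_uninduced,
                                        y = .data$abundance_induced,
                                        colour = .data$subset)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "uninduced abundance (RPKM)",
                  y = "induced abundance (RPKM)")
  if (!is.null(target_gene) && target_gene %in% tb$gene) {
    tg <- tb[tb$gene == target_gene, ]
    p <- p + ggplot2::geom_point(data = tg, colour = "red", size = 2) +
      ggplot2::geom_text(data = tg, ggplot2::aes(label = .data$gene),
                         colour = "red", vjust = -1)
  }
  p
}

#' Off-target tier counts of profiled candidates
#'
#' One bar panel per candidate offset, showing the abundance in each screen
#' tier; useful for eyeballing why a candidate was removed or ranked low.
#'
#' @param profiled Tibble from [off_target_profile()], typically one gene.
#' @return A ggplot object.
#' @export
plot_candidate_profiles <- function(profiled) {
  long <- tidyr::pivot_longer(
    dplyr::select(profiled, "gene", "offset_nt", dplyr::starts_with("n_")),
    dplyr::starts_with("n_"), names_to = "tier", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tier, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~ gene + offset_nt, labeller = ggplot2::label_both) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genomic sites")
}
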