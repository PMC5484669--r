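# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.noise_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$mean, y = .data$cv2, colour = .data$dm)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    scale_colour_gradient2(low = "steelblue", mid = "grey80", high = "firebrick") +
    labs(x = "mean normalized count", y = expression(CV^2), colour = "DM")
}

#' @exportS3Method ggplot2::autoplot
autoplot.neighborhood_noise <- function(object, ...) {
  ggplot(object, aes(x = .data$window_bp)) +
    geom_ribbon(aes(ymin = -log10(.data$rand_hi), ymax = -log10(.data$rand_lo)),
                fill = "grey85") +
    geom_line(aes(y = -log10(.data$p_noise))) +
    geom_point(aes(y = -log10(.data$p_noise))) +
    scale_x_log10() +
    labs(x = "neighborhood half-width (bp)", y = expression(-log[10](p)),
         title = "flanking noise vs randomized-genome band")
}

#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fits <- function(object, ...) {
  df <- object[object$identifiable & is.finite(object$burst_size), ]
  ggplot(df, aes(x = .data$burst_freq, y = .data$burst_size)) +
    geom_point(size = 0.7, alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "burst frequency (k_on, per mRNA lifetime)",
         y = "burst size (s / k_off)")
}

#' Bar chart of contact enrichments
#'
#' @param enrichments named list of `contact_enrichment` objects (e.g. one
#'   per chromatin class).
#' @return A ggplot.
#' @export
plot_contact_enrichment <- function(enrichments) {
  df <- bind_rows(lapply(names(enrichments), function(nm) {
    e <- enrichments[[nm]]
    tibble(set = nm, enrichment = e$enrichment_mean, sd = e$enrichment_sd)
  }))
  ggplot(df, aes(x = .data$set, y = .data$enrichment)) +
    geom_col(fill = "grey60") +
    geom_errorbar(aes(ymin = .data$enrichment - .data$sd,
                      ymax = .data$enrichment + .data$sd), width = 0.2) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = NULL, y = "contact enrichment (obs / expected)")
}
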