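# ggplot2 views of the result tables. Each autoplot() mirrors the figure a
# structural immunologist would sketch for that statistic: per-residue bars
# for B-factors and contact shares, a profile line for RMSF, occupancy
# bars, and cluster populations.

#' @export
autoplot.pfr_bfactor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$res_seq, y = .data$mean_b,
                                       fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(40, 80), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Residue", y = expression("Mean B-factor" ~ (ring(A)^2)),
                  fill = NULL,
                  title = paste0("B-factor profile, chain ",
                                 attr(object, "chain", exact = TRUE))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pfr_contact_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("vdw", "hbond"),
                              names_to = "kind", values_to = "n")
  long$kind <- factor(long$kind, levels = c("vdw", "hbond"),
                      labels = c("vdW", "H-bond"))
  long$label <- factor(paste0(long$aa, " P", long$p_pos),
                       levels = paste0(object$aa, " P", object$p_pos))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$n,
                                     fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Peptide residue (register)", y = "Contacts", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.pfr_rmsf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$res_seq, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Residue",
                  y = expression(RMSF[C * alpha] ~ (ring(A)))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pfr_contact_fraction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$res_seq, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Peptide residue", y = "% of total contacts") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pfr_occupancy <- function(object, ...) {
  fr <- object$fractions
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$state, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Trajectory fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pfr_clusters <- function(object, ...) {
  s <- attr(object, "summary", exact = TRUE)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$cluster), y = .data$n_members)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Cluster", y = "Frames") +
    ggplot2::theme_minimal()
}
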