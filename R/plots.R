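#' Plot a log2 enrichment track
#'
#' @param object An `nap_enrichment`.
#' @param peaks Optional peaks tibble to shade.
#' @param region Optional length-2 vector of 0-based positions to zoom to.
#' @param threshold_log2 Horizontal reference line (default 2, the 4-fold
#'   rule).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nap_enrichment <- function(object, peaks = NULL, region = NULL,
                                    threshold_log2 = 2, ...) {
  d <- as_tibble(object)
  if (!is.null(region)) {
    d <- filter(d, .data$position >= region[1], .data$position <= region[2])
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                       y = .data$log2_ratio)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold_log2, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "genome position (bp)", y = "log2(IP / input)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    pk <- peaks
    if (!is.null(region)) {
      pk <- filter(pk, .data$end >= region[1], .data$start <= region[2])
    }
    p <- p + ggplot2::geom_rect(
      data = pk,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a fitted ITC isotherm
#'
#' Integrated injection heats against molar ratio with the fitted one-site
#' curve.
#'
#' @param object An `nap_itc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nap_itc_fit <- function(object, ...) {
  d <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_ucal)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_ucal),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "molar ratio (ligand / macromolecule)",
      y = "injection heat (ucal)",
      title = sprintf("one-site fit: n = %.2f, Kd = %.0f nM",
                      object$params$n, object$params$kd_nM)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fraction-bound binding curve fit
#'
#' @param object An `nap_emsa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nap_emsa_fit <- function(object, ...) {
  d <- object$fitted
  grid <- tibble(
    protein_uM = exp(seq(log(max(min(d$protein_uM), 1e-3)),
                         log(max(d$protein_uM)), length.out = 100))
  )
  grid$fraction_bound <- grid$protein_uM / (object$kd_uM + grid$protein_uM)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein_uM,
                                  y = .data$fraction_bound)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (uM)", y = "fraction bound",
                  title = sprintf("Kd = %.2g uM", object$kd_uM)) +
    ggplot2::theme_minimal()
}

#' Plot the Monte-Carlo null score distribution
#'
#' @param object An `nap_null`.
#' @param threshold Optional score threshold to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nap_null <- function(object, threshold = NULL, ...) {
  d <- tibble(score = object$scores)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 100, fill = "grey70") +
    ggplot2::labs(x = "motif score (bits)", y = "null samples") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' Plot a ligand-competition curve
#'
#' Fraction of the protein-DNA complex retained as a function of competitor
#' concentration under the mutually exclusive binding model.
#'
#' @param protein_uM Protein concentration (uM).
#' @param kd_dna_uM,kd_ligand_uM Dissociation constants (uM).
#' @param hill_m Ligand cooperativity exponent.
#' @param ligand_range_uM Range of ligand concentrations to draw.
#' @return A ggplot object.
#' @export
plot_competition <- function(protein_uM, kd_dna_uM, kd_ligand_uM,
                             hill_m = 1, ligand_range_uM = c(0.01, 100)) {
  d <- tibble(
    ligand_uM = exp(seq(log(ligand_range_uM[1]), log(ligand_range_uM[2]),
                        length.out = 200))
  )
  d$retained <- competition_occupancy(protein_uM, d$ligand_uM, kd_dna_uM,
                                      kd_ligand_uM, hill_m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ligand_uM, y = .data$retained)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "competing ligand (uM)",
                  y = "protein-DNA complex retained") +
    ggplot2::theme_minimal()
}
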