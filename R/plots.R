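# ggplot2 lives in Suggests; every plot helper checks for it
need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Plot species-resolved MSD curves
#'
#' @param msd Data frame from [msd_by_species()].
#' @return A ggplot object.
#' @export
plot_msd <- function(msd) {
  need_ggplot()
  ggplot2::ggplot(msd, ggplot2::aes(x = .data$lag_ps, y = .data$msd,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ps)", y = expression(MSD ~ (ring(A)^2)),
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot species counts over the update cycles
#'
#' Visualises the composition feedback: counts fluctuate around the
#' reference partitioning.
#'
#' @param cycles `cycles` data frame from [run_dynamics()].
#' @return A ggplot object.
#' @export
plot_species_counts <- function(cycles) {
  need_ggplot()
  ggplot2::ggplot(cycles, ggplot2::aes(x = .data$time_ps, y = .data$count,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "molecules", colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot a collective dipole series (raw vs corrected)
#'
#' @param dipole A `dipole_series` (see [collective_dipole()]).
#' @param component Cartesian component to show (1, 2 or 3).
#' @return A ggplot object.
#' @export
plot_dipole <- function(dipole, component = 1) {
  need_ggplot()
  df <- data.frame(time_ps = dipole$times, series = "raw",
                   M = dipole$raw[, component])
  if (!is.null(dipole$corrected))
    df <- rbind(df, data.frame(time_ps = dipole$times, series = "corrected",
                               M = dipole$corrected[, component]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$M,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)",
                  y = sprintf("M_J[%d] (e %s)", component, "Å"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of a shell PMF (or delta-PMF) matrix
#'
#' @param pmf A `pmf_matrix`.
#' @param unit `"kJ"` (default, matching the common reporting convention)
#'   or `"kcal"`.
#' @return A ggplot object.
#' @export
plot_pmf <- function(pmf, unit = c("kJ", "kcal")) {
  need_ggplot()
  unit <- match.arg(unit)
  df <- as.data.frame(pmf)
  df$value <- if (unit == "kJ") df$pmf_kJ_mol else df$pmf_kcal_mol
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neighbor_species,
                                   y = .data$center_species,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "neighbor species l", y = "central species k",
                  fill = sprintf("PMF (%s/mol)", unit)) +
    ggplot2::theme_minimal()
}
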