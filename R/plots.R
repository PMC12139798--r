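# ggplot2 helpers for trajectories and phase diagrams (ggplot2 in Suggests).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Plot network and membrane tension time courses
#'
#' Global network (red) and membrane (blue) tension versus time, in pN/um.
#'
#' @param traj A `cortosim_trajectory`.
#' @return A ggplot object.
#' @export
plot_tension <- function(traj) {
  need_ggplot()
  s <- traj$series
  df <- rbind(
    data.frame(t = s$t, tension = s$T_net_global, which = "network"),
    data.frame(t = s$t, tension = s$T_mem_global, which = "membrane"))
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = tension,
                                   colour = which)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(network = "#c0392b",
                                            membrane = "#2980b9")) +
    ggplot2::labs(x = "time (s)", y = "tension (pN/um)", colour = NULL)
}

#' Plot bleb growth
#'
#' Bleb count and largest bleb diameter versus time.
#'
#' @param traj A `cortosim_trajectory`.
#' @return A ggplot object.
#' @export
plot_blebs <- function(traj) {
  need_ggplot()
  s <- traj$series
  ggplot2::ggplot(s, ggplot2::aes(x = t, y = max_bleb_diameter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "largest bleb diameter (um)")
}

#' Plot a mechanism phase diagram
#'
#' Tile map of the predicted initiation mechanism over the
#' (connectivity, coupling) grid from [phase_diagram()].
#'
#' @param pd Output of [phase_diagram()].
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(pd) {
  need_ggplot()
  ggplot2::ggplot(pd, ggplot2::aes(x = R_X, y = R_C,
                                   fill = mechanism)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(Detachment = "#7fb3d5",
                                          Rupture = "#f1948a")) +
    ggplot2::labs(x = expression(R[X]), y = expression(R[C]), fill = NULL)
}

#' Autoplot method for trajectories
#' @param object A `cortosim_trajectory`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.cortosim_trajectory <- function(object, ...) plot_tension(object)
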