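# Multi-panel clinical-course rendering for one patient.

#' Render a patient's clinical course
#'
#' Stacks the standard monitoring panels for one patient: AMI-21 with days
#' inside exacerbation events highlighted in red, the REI with the threshold
#' line, MaxBAC, omitted-test counts, MTBT, and (when recorded) DDD and
#' PEth. Panels with entirely missing covariates are omitted.
#'
#' @param bundle Pipeline bundle from [run_pipeline()].
#' @param patient_id Patient to render.
#' @param threshold REI threshold drawn as the red reference line.
#' @return A patchwork object (printable / saveable with
#'   [ggplot2::ggsave()]).
#' @export
render_course <- function(bundle, patient_id, threshold = 0.8) {
  if (!patient_id %in% bundle$days$patient_id) {
    stop_validation("unknown patient: %s", patient_id)
  }
  days <- bundle$days[bundle$days$patient_id == patient_id, ]
  ami <- bundle$ami[bundle$ami$patient_id == patient_id, ]
  rei <- bundle$rei[bundle$rei$patient_id == patient_id, ]
  events <- bundle$events[bundle$events$patient_id == patient_id, ]

  base_x <- ggplot2::xlab("treatment day")
  ami_col <- if ("ami_21" %in% names(ami)) "ami_21" else grep("^ami_", names(ami), value = TRUE)[1]
  d_ami <- data.frame(t = ami$treatment_day, ami = ami[[ami_col]])
  p_ami <- ggplot2::ggplot(d_ami, ggplot2::aes(x = .data$t, y = .data$ami)) +
    ggplot2::geom_line(linewidth = 0.3)
  if (nrow(events) > 0) {
    p_ami <- p_ami + ggplot2::geom_rect(
      data = data.frame(xmin = events$start_day - 0.5, xmax = events$end_day + 0.5),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.25
    )
  }
  p_ami <- p_ami + ggplot2::ylab(toupper(sub("_", "-", ami_col))) +
    ggplot2::ylim(0, 100) + base_x

  p_rei <- ggplot2::ggplot(data.frame(t = rei$treatment_day, rei = rei$rei),
                           ggplot2::aes(x = .data$t, y = .data$rei)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red") +
    ggplot2::ylab("REI") + base_x

  panel <- function(y, lab, type = "col") {
    d <- data.frame(t = days$treatment_day, y = days[[y]])
    g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$y))
    g <- if (type == "col") g + ggplot2::geom_col(width = 1) else
      g + ggplot2::geom_point(size = 0.4)
    g + ggplot2::ylab(lab) + base_x
  }
  panels <- list(
    p_ami, p_rei,
    panel("max_bac_permille", "MaxBAC (permille)", "point"),
    panel("n_omitted", "omitted tests"),
    panel("mtbt_hours", "MTBT (h)", "point")
  )
  if (any(!is.na(days$ddd))) panels <- c(panels, list(panel("ddd", "DDD")))
  if (any(!is.na(days$peth_umol_l))) {
    panels <- c(panels, list(panel("peth_umol_l", "PEth (umol/L)", "point")))
  }
  patchwork::wrap_plots(panels, ncol = 1) +
    patchwork::plot_annotation(title = paste("Clinical course:", patient_id))
}
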