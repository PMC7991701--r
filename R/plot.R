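#' Panel plots of a stenosis sweep
#'
#' Draws the standard four-panel summary of a [run_cea_sweep()]
#' result: stump pressure, communicating-artery flows, cerebral bed
#' pressures, and the signed ipsilateral A1 flow, each against the
#' contralateral stenosis ratio.  Requires ggplot2.
#'
#' @param sweep a `sweep_result`
#' @return a ggplot object (panels via facets)
#' @export
plot_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep requires the ggplot2 package")
  }
  long <- rbind(
    data.frame(panel = "stump pressure [mmHg]", series = "CSP",
               ratio = sweep$ratio, value = sweep$csp_mmhg),
    data.frame(panel = "communicating flows [mL/min]", series = "Acom",
               ratio = sweep$ratio, value = sweep$q_acom_ml_min),
    data.frame(panel = "communicating flows [mL/min]", series = "Pcom (ipsi)",
               ratio = sweep$ratio, value = sweep$q_pcom_ipsi_ml_min),
    data.frame(panel = "communicating flows [mL/min]", series = "Pcom (contra)",
               ratio = sweep$ratio, value = sweep$q_pcom_contra_ml_min),
    data.frame(panel = "bed pressures [mmHg]", series = "ACA",
               ratio = sweep$ratio, value = sweep$p_aca_ipsi_mmhg),
    data.frame(panel = "bed pressures [mmHg]", series = "MCA",
               ratio = sweep$ratio, value = sweep$p_mca_ipsi_mmhg),
    data.frame(panel = "bed pressures [mmHg]", series = "PCA",
               ratio = sweep$ratio, value = sweep$p_pca_ipsi_mmhg),
    data.frame(panel = "A1 flow [mL/min]", series = "A1 (ipsi)",
               ratio = sweep$ratio, value = sweep$q_a1_ipsi_ml_min))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = 100 * .data$ratio, y = .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "contralateral stenosis ratio [%]", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
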