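# Cosmetic rendering of the waterfall matrix; the matrix itself (and its
# ordering contracts) is the tested artifact, the plot is presentation.

#' Plot a waterfall matrix
#'
#' Renders a [waterfall_matrix()] as a gene-by-patient tile plot with a
#' clinical strip, in the style of the usual mutation-landscape figures.
#' Requires ggplot2.
#'
#' @param wf A `gcdm_waterfall`.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(wf) {
  stopifnot(inherits(wf, "gcdm_waterfall"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_waterfall requires the ggplot2 package", call. = FALSE)
  long <- expand.grid(gene = rev(wf$genes),
                      patient = as.character(wf$patients),
                      stringsAsFactors = FALSE)
  long$patient <- factor(long$patient, levels = as.character(wf$patients))
  long$gene <- factor(long$gene, levels = rev(wf$genes))
  long$feature <- wf$matrix[cbind(as.character(long$gene),
                                  as.character(long$patient))]
  long$feature[long$feature == "none"] <- NA
  pal <- c(nonsense = "#d62728", frameshift = "#9467bd", splice = "#8c564b",
           inframe = "#e377c2", missense = "#1f77b4", synonymous = "#2ca02c",
           intron = "#bcbd22", other = "#7f7f7f")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient, y = .data$gene,
                                     fill = .data$feature)) +
    ggplot2::geom_tile(color = "grey90", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = pal, na.value = "grey97",
                               name = "variant feature") +
    ggplot2::labs(x = "patient", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
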