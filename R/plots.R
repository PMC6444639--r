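# ggplot2 views of scans, candidates and the genome-level superposition.

#' Plot an mQTL scan
#'
#' LOD (or -log10 p) track along the genome, faceted by chromosome, with the
#' significance threshold drawn when the scan carries one.
#'
#' @param object An `mqtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mqtl_scan
#' @export
autoplot.mqtl_scan <- function(object, ...) {
  tr <- object$track
  if (object$stat_type == "pvalue") {
    tr$y <- -log10(pmax(tr$stat, 1e-300))
    ylab <- expression(-log[10](p))
    thr <- NULL
  } else {
    tr$y <- tr$stat
    ylab <- "LOD"
    thr <- object$threshold
  }
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$pos / 1e6, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab,
                  title = sprintf("mQTL scan: %s", object$trait_id)) +
    ggplot2::theme_bw()
  if (!is.null(thr) && !is.na(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot ranked candidates
#'
#' Evidence score per candidate cluster, coloured by classification, in rank
#' order.
#'
#' @param object A `bgc_candidates` tibble from [build_candidates()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bgc_candidates
#' @export
autoplot.bgc_candidates <- function(object, ...) {
  d <- as_tibble(object)
  d$bgc_id <- factor(d$bgc_id, levels = rev(d$bgc_id[order(d$rank)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$bgc_id,
                                  fill = .data$class_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "evidence score", y = NULL, fill = "classification",
                  title = "Ranked BGC-mQTL candidates") +
    ggplot2::theme_bw()
}

#' Genome overview of clusters and mQTL intervals
#'
#' Draws each chromosome's mQTL support intervals above its predicted
#' clusters so the superpositions driving the candidate list are visible at
#' a glance.
#'
#' @param mqtls mQTL tibble.
#' @param bgcs BGC tibble.
#' @return A ggplot.
#' @export
plot_genome_overlaps <- function(mqtls, bgcs) {
  segs <- bind_rows(
    tibble(chrom = mqtls$chrom, start = mqtls$start, end = mqtls$end,
           what = "mQTL", id = mqtls$trait_id, y = 1),
    tibble(chrom = bgcs$chrom, start = bgcs$start, end = bgcs$end,
           what = "BGC", id = bgcs$bgc_id, y = 0)
  )
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$what),
                          linewidth = 3, lineend = "butt") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c("BGC", "mQTL"),
                                limits = c(-0.5, 1.5)) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL,
                  title = "mQTL / predicted-cluster superposition") +
    ggplot2::theme_bw()
}
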