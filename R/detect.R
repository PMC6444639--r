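# Enzyme-class annotation and simplified cluster detection.  The chaining
# rule (>= 3 enzyme genes, >= 2 distinct classes, <= 10 kb between
# consecutive enzyme-gene intervals) is an explicit proxy for a full
# plant-cluster predictor; externally predicted clusters can be supplied via
# read_cluster_table() instead.

#' Assign enzyme classes to genes from domain hits
#'
#' Joins a tabular domain-hit set (e.g. from a profile-HMM scan of the
#' proteome) against an enzyme-class map and fills `enzyme_classes` for every
#' gene with at least one qualifying hit (score >= `min_score`).  Class sets
#' have set semantics: two hits mapping to the same class count once.  Genes
#' without qualifying hits keep their current (typically empty) class set.
#'
#' @param genes Annotation tibble.
#' @param domain_hits Tibble with `gene_id`, `domain_id`, `score`.
#' @param class_map Enzyme-class map (`domain_id`, `class`), default
#'   [default_enzyme_class_map()].
#' @param min_score Minimum hit score.
#' @return The annotation with `enzyme_classes` filled.
#' @export
assign_enzyme_classes <- function(genes, domain_hits,
                                  class_map = default_enzyme_class_map(),
                                  min_score = 20) {
  genes <- validate_genes(genes)
  unknown <- setdiff(unique(domain_hits$gene_id), genes$gene_id)
  if (length(unknown)) {
    stop_validation(sprintf("domain hit references unknown gene: %s", unknown[1]))
  }
  hits <- domain_hits |>
    filter(.data$score >= min_score) |>
    left_join(class_map, by = "domain_id") |>
    filter(!is.na(.data$class)) |>
    distinct(.data$gene_id, .data$class) |>
    group_by(.data$gene_id) |>
    summarise(classes = list(sort(unique(.data$class))))
  idx <- match(hits$gene_id, genes$gene_id)
  genes$enzyme_classes[idx] <- hits$classes
  genes
}

#' Detect candidate biosynthetic gene clusters
#'
#' Greedy chaining along each chromosome: consecutive enzyme-class-bearing
#' genes whose intervals lie at most `max_gap` bp apart (gap measured from
#' the end of one enzyme gene to the start of the next) join one chain.  A
#' chain becomes a cluster iff it holds at least `min_biosynthetic_genes`
#' class-bearing genes spanning at least `min_distinct_classes` distinct
#' classes.  Class-free genes lying inside the chain span are included as
#' members but neither extend nor break the chain.  Cluster ids are assigned
#' in genomic order; the cluster interval is the span of its member genes.
#'
#' @param genes Annotation tibble, sorted by position within chromosomes
#'   (unsorted input is an error).
#' @param min_biosynthetic_genes Minimum class-bearing genes per cluster.
#' @param min_distinct_classes Minimum distinct enzyme classes.
#' @param max_gap Maximum enzyme-gene gap in bp.
#' @return A BGC tibble (`bgc_id`, `chrom`, `start`, `end`, `product_label`,
#'   `n_genes`, `gene_ids`, `classes`).
#' @export
detect_bgcs <- function(genes, min_biosynthetic_genes = 3,
                        min_distinct_classes = 2, max_gap = 10000) {
  genes <- validate_genes(genes)
  if (!nrow(genes)) return(empty_bgc_table())
  sorted_ok <- genes |>
    group_by(.data$chrom) |>
    summarise(ok = n() == 1 || all(diff(.data$start) >= 0)) |>
    pull(.data$ok)
  if (!all(sorted_ok)) {
    stop_validation("annotation must be sorted by start position within chromosomes")
  }
  out <- list()
  for (cc in sort(unique(genes$chrom))) {
    g <- genes[genes$chrom == cc, ]
    enz <- which(lengths(g$enzyme_classes) > 0)
    if (!length(enz)) next
    # chain enzyme genes by the end -> next-start gap
    breaks <- if (length(enz) > 1) {
      g$start[enz[-1]] - g$end[enz[-length(enz)]] > max_gap
    } else logical(0)
    chain_id <- cumsum(c(TRUE, breaks))
    for (ch in unique(chain_id)) {
      members_enz <- enz[chain_id == ch]
      if (length(members_enz) < min_biosynthetic_genes) next
      classes <- unlist(g$enzyme_classes[members_enz])
      if (length(unique(classes)) < min_distinct_classes) next
      span_start <- min(g$start[members_enz])
      span_end <- max(g$end[members_enz])
      members <- which(g$start <= span_end & g$end >= span_start)
      out[[length(out) + 1L]] <- tibble(
        chrom = cc,
        start = min(g$start[members]), end = max(g$end[members]),
        product_label = NA_character_,
        n_genes = length(members),
        gene_ids = list(g$gene_id[members]),
        classes = list(sort(classes))
      )
    }
  }
  if (!length(out)) return(empty_bgc_table())
  bgcs <- bind_rows(out)
  bgcs <- bgcs[genomic_order(bgcs$chrom, bgcs$start), ]
  bgcs$bgc_id <- sprintf("bgc_%03d", seq_len(nrow(bgcs)))
  bgcs[, c("bgc_id", "chrom", "start", "end", "product_label", "n_genes",
           "gene_ids", "classes")]
}

#' List enzyme genes intersecting a genomic region
#'
#' The non-cluster-centric scan: every gene whose interval intersects the
#' region, with its enzyme-class set, in genomic order.  A chromosome absent
#' from the annotation yields an empty table (with a message), not an error.
#'
#' @param genes Annotation tibble.
#' @param chrom,start,end Region (1-based inclusive).
#' @param classes_only Keep only class-bearing genes.
#' @return Tibble of intersecting genes with `enzyme_classes`.
#' @export
annotate_region <- function(genes, chrom, start, end, classes_only = FALSE) {
  genes <- validate_genes(genes)
  check_interval(start, end, "region")
  if (!chrom %in% genes$chrom) {
    inform(sprintf("annotate_region: chromosome '%s' not in annotation", chrom))
    return(genes[0, ])
  }
  hit <- genes$chrom == chrom & genes$start <= end & genes$end >= start
  out <- genes[hit, ]
  if (classes_only) out <- out[lengths(out$enzyme_classes) > 0, ]
  out[order(out$start), ]
}
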