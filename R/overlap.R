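# Superimposition of mQTL intervals on clusters, plus the evidence layers:
# marker-to-gene assignment, coexpression support, mass-difference linkage.

#' Superimpose mQTLs on predicted clusters
#'
#' One link per (mQTL, BGC) pair sharing a chromosome with intersecting
#' 1-based closed intervals; `overlap_bp` is the intersection length.  Any
#' positive intersection counts by default (`min_overlap_bp = 1`): the
#' superposition itself is the candidate-generating event.  Output is
#' deterministic (BGC genomic order, then trait id).  Interval lookup uses
#' an [IRanges::findOverlaps()] index per chromosome; its correctness is
#' oracle-tested against a brute-force all-pairs scan.
#'
#' @param mqtls mQTL tibble ([call_mqtls_ril()] / [call_mqtls_gwas()]).
#' @param bgcs BGC tibble ([detect_bgcs()] / [read_cluster_table()]).
#' @param min_overlap_bp Minimum intersection length to report.
#' @return A link tibble: `bgc_id`, `trait_id`, `chrom`, `overlap_bp`,
#'   `mqtl_start`, `mqtl_end`, `bgc_start`, `bgc_end`, `peak_stat`,
#'   `stat_type`, `markers` (member markers of the mQTL).
#' @export
find_overlaps <- function(mqtls, bgcs, min_overlap_bp = 1) {
  if (min_overlap_bp < 1) stop_validation("min_overlap_bp must be >= 1")
  empty <- tibble(bgc_id = character(), trait_id = character(),
                  chrom = character(), overlap_bp = integer(),
                  mqtl_start = integer(), mqtl_end = integer(),
                  bgc_start = integer(), bgc_end = integer(),
                  peak_stat = double(), stat_type = character(),
                  markers = list())
  if (!nrow(mqtls) || !nrow(bgcs)) return(empty)
  shared <- intersect(unique(mqtls$chrom), unique(bgcs$chrom))
  out <- list()
  for (cc in sort(shared)) {
    q <- mqtls[mqtls$chrom == cc, ]
    s <- bgcs[bgcs$chrom == cc, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q$start, q$end),
      IRanges::IRanges(s$start, s$end),
      minoverlap = min_overlap_bp
    )
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out[[length(out) + 1L]] <- tibble(
      bgc_id = s$bgc_id[si], trait_id = q$trait_id[qi], chrom = cc,
      overlap_bp = interval_overlap_bp(q$start[qi], q$end[qi],
                                       s$start[si], s$end[si]),
      mqtl_start = q$start[qi], mqtl_end = q$end[qi],
      bgc_start = s$start[si], bgc_end = s$end[si],
      peak_stat = q$peak_stat[qi], stat_type = q$stat_type[qi],
      markers = q$markers[qi]
    )
  }
  if (!length(out)) return(empty)
  res <- bind_rows(out)
  res[order(as.character(res$chrom), res$bgc_start, res$bgc_id,
            res$trait_id, res$mqtl_start), ]
}

#' Assign an mQTL's member markers to genes
#'
#' Returns the ids of genes whose interval, expanded by `flank` bp on both
#' sides, contains at least one member marker — the GWAS-style resolution of
#' an association to individual genes.  Deduplicated, genomic order.
#'
#' @param markers Tibble of member markers (`chrom`, `pos`).
#' @param genes Annotation tibble.
#' @param flank Flank in bp (default 2000).
#' @return Character vector of gene ids.
#' @export
assign_markers_to_genes <- function(markers, genes, flank = 2000) {
  genes <- validate_genes(genes)
  if (is.null(markers) || !nrow(markers)) return(character(0))
  hit <- logical(nrow(genes))
  for (cc in unique(markers$chrom)) {
    pos <- markers$pos[markers$chrom == cc]
    gi <- which(genes$chrom == cc)
    if (!length(gi)) next
    hit[gi] <- hit[gi] | map_lgl(gi, function(i) {
      any(pos >= genes$start[i] - flank & pos <= genes$end[i] + flank)
    })
  }
  g <- genes[hit, ]
  g$gene_id[genomic_order(g$chrom, g$start)]
}

#' Pearson product-moment correlation
#'
#' Plain Pearson r with the guards the evidence layer needs: vectors must be
#' equal-length (>= 3) and finite; a zero-variance input yields `NA` with a
#' warning rather than an error, so degenerate expression profiles flow
#' through as missing evidence.
#'
#' @param x,y Numeric vectors.
#' @return A single correlation, or `NA_real_` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 3) stop_validation("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_validation("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance input: correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(x, y)
}

#' Coexpression support for a cluster
#'
#' All pairwise Pearson correlations among the class-bearing member genes of
#' a cluster that are present in the expression matrix; the cluster is
#' flagged when the maximum pairwise r reaches `r_min` (default 0.79, the
#' level at which coexpression of cluster enzymes is conventionally called
#' strong).  Fewer than two usable genes yields `n_pairs = 0`, unflagged.
#'
#' @param member_genes Annotation rows of the cluster's member genes.
#' @param expr Genes x samples expression matrix.
#' @param r_min Flagging threshold on the maximum pairwise r.
#' @param classes_only Restrict to class-bearing members (default TRUE).
#' @return One-row tibble: `n_genes_used`, `n_genes_missing`, `n_pairs`,
#'   `max_r`, `mean_r`, `flagged`.
#' @export
coexpression_support <- function(member_genes, expr, r_min = 0.79,
                                 classes_only = TRUE) {
  g <- member_genes
  if (classes_only) g <- g[lengths(g$enzyme_classes) > 0, ]
  present <- intersect(g$gene_id, rownames(expr))
  n_missing <- nrow(g) - length(present)
  if (length(present) < 2) {
    return(tibble(n_genes_used = length(present), n_genes_missing = n_missing,
                  n_pairs = 0L, max_r = NA_real_, mean_r = NA_real_,
                  flagged = FALSE))
  }
  sub <- t(expr[present, , drop = FALSE])
  keep <- apply(sub, 2, sd) > 0
  sub <- sub[, keep, drop = FALSE]
  if (ncol(sub) < 2) {
    return(tibble(n_genes_used = ncol(sub), n_genes_missing = n_missing,
                  n_pairs = 0L, max_r = NA_real_, mean_r = NA_real_,
                  flagged = FALSE))
  }
  cm <- cor(sub)
  rs <- cm[upper.tri(cm)]
  tibble(n_genes_used = ncol(sub), n_genes_missing = n_missing,
         n_pairs = length(rs), max_r = max(rs), mean_r = mean(rs),
         flagged = max(rs) >= r_min)
}

#' Mass-difference edges among metabolite features
#'
#' For every unordered feature pair, emits an edge when the absolute m/z
#' difference matches a biotransformation delta within
#' `max(tolerance_abs, tolerance_ppm * mean(mz) * 1e-6)`; ties across table
#' entries resolve to the smallest absolute deviation.  Feature m/z is
#' treated as a neutral-mass proxy (no adduct handling), so deltas operate
#' directly on m/z differences.  Symmetric and invariant to input order.
#'
#' @param features Feature tibble (`trait_id`, `mz`).
#' @param table Biotransformation table (`name`, `delta_da`), default
#'   [default_biotransformations()].
#' @param tolerance_ppm,tolerance_abs Matching tolerances (ppm of the pair's
#'   mean m/z; absolute Da floor).
#' @return Edge tibble: `trait_a`, `trait_b` (sorted within pair),
#'   `transformation`, `delta_obs`, `deviation_da`.
#' @export
massdiff_edges <- function(features, table = default_biotransformations(),
                           tolerance_ppm = 10, tolerance_abs = 0.005) {
  if (!nrow(table)) stop_validation("biotransformation table must be non-empty")
  if (any(table$delta_da <= 0)) stop_validation("deltas must be positive")
  n <- nrow(features)
  empty <- tibble(trait_a = character(), trait_b = character(),
                  transformation = character(), delta_obs = double(),
                  deviation_da = double())
  if (n < 2) return(empty)
  feats <- features[order(features$trait_id), ]
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      dmz <- abs(feats$mz[i] - feats$mz[j])
      tol <- max(tolerance_abs,
                 tolerance_ppm * mean(c(feats$mz[i], feats$mz[j])) * 1e-6)
      dev <- abs(dmz - table$delta_da)
      k <- which.min(dev)
      if (dev[k] <= tol) {
        out[[length(out) + 1L]] <- tibble(
          trait_a = feats$trait_id[i], trait_b = feats$trait_id[j],
          transformation = table$name[k], delta_obs = dmz,
          deviation_da = dev[k]
        )
      }
    }
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Connected components of the mass-difference graph
#'
#' Restricts the edge set to the given traits (typically those whose mQTLs
#' hit one cluster) and returns the connected components, singletons
#' included.  Components and members are deterministically ordered.
#'
#' @param edges Edge tibble from [massdiff_edges()].
#' @param traits Character vector of trait ids defining the vertex set.
#' @return List of character vectors (each sorted), ordered by first member.
#' @export
linked_components <- function(edges, traits) {
  traits <- sort(unique(traits))
  if (!length(traits)) return(list())
  e <- edges[edges$trait_a %in% traits & edges$trait_b %in% traits, ]
  gr <- igraph::graph_from_data_frame(
    e[, c("trait_a", "trait_b")], directed = FALSE,
    vertices = data.frame(name = traits)
  )
  comp <- igraph::components(gr)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  groups[order(map_chr(groups, first))]
}
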