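# Evidence classification, scoring and ranking of BGC-mQTL candidates.

#' Default evidence weights
#'
#' Unit weights over the five evidence flags.  The weighting is an explicit,
#' configurable operationalization of an otherwise qualitative evidence
#' hierarchy; calibrate to taste.
#'
#' @return Named numeric vector.
#' @export
default_evidence_weights <- function() {
  c(multi_mqtl = 1, multi_gene = 1, massdiff = 1, coexpression = 1,
    compatibility = 1)
}

#' Classify a cluster's mQTL evidence
#'
#' The qualitative taxonomy of a cluster's overlapping metabolite traits:
#' * `discovery_candidate` — every overlapping trait is unannotated, the
#'   most interesting case for novel-chemistry bioprospecting;
#' * `known_compatible` — at least one annotated trait whose compound class
#'   is pathway-compatible with an enzyme class in the cluster, and no
#'   unannotated traits;
#' * `mixed` — at least one compatible annotated trait alongside unknowns;
#' * `known_incompatible_or_false_positive` — annotated traits exist but
#'   none is compatible (e.g. a glucosinolate trait over a cluster with no
#'   glucosinolate-pathway enzymes): likely an indirect effect or a spurious
#'   cluster prediction.
#'
#' @param bgc_classes Character vector: the cluster's enzyme classes.
#' @param trait_features Feature tibble rows for the overlapping traits
#'   (columns `annotated`, `compound_class`).
#' @param compatibility Compatibility map (`compound_class`, `enzyme_class`),
#'   default [default_compatibility_map()].
#' @return One of the four labels above.
#' @export
classify_bgc <- function(bgc_classes, trait_features,
                         compatibility = default_compatibility_map()) {
  if (!nrow(trait_features)) {
    stop_validation("classify_bgc requires at least one overlapping trait")
  }
  annotated <- trait_features[trait_features$annotated %in% TRUE, ]
  n_unknown <- sum(!trait_features$annotated)
  if (!nrow(annotated)) return("discovery_candidate")
  compat <- map_lgl(annotated$compound_class, function(cls) {
    if (is.na(cls)) return(FALSE)
    ok <- compatibility$enzyme_class[compatibility$compound_class == cls]
    length(intersect(ok, bgc_classes)) > 0
  })
  if (any(compat)) {
    if (n_unknown > 0) "mixed" else "known_compatible"
  } else {
    "known_incompatible_or_false_positive"
  }
}

#' Score a candidate's evidence flags
#'
#' Weighted sum of the satisfied evidence flags; adding a satisfied flag can
#' never lower the score (weights must be non-negative).
#'
#' @param flags Named logical vector with elements `multi_mqtl`,
#'   `multi_gene`, `massdiff`, `coexpression`, `compatibility`.
#' @param weights Named non-negative weights, default
#'   [default_evidence_weights()].
#' @return Numeric score.
#' @export
score_bgc <- function(flags, weights = default_evidence_weights()) {
  if (any(weights < 0)) stop_validation("evidence weights must be non-negative")
  nm <- names(default_evidence_weights())
  missing_w <- setdiff(nm, names(weights))
  if (length(missing_w)) {
    stop_validation(sprintf("missing weight(s): %s", paste(missing_w, collapse = ", ")))
  }
  sum(weights[nm] * as.numeric(flags[nm] %in% TRUE))
}

#' Rank scored candidates
#'
#' Strict total order: score descending, number of supporting mQTLs
#' descending, then chromosome and start ascending, then `bgc_id`.
#'
#' @param candidates Scored candidate tibble.
#' @return The tibble re-ordered with `rank` = 1..n.
#' @export
rank_candidates <- function(candidates) {
  if (!nrow(candidates)) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  ord <- order(-candidates$score, -candidates$n_mqtls,
               as.character(candidates$chrom), candidates$start,
               candidates$bgc_id)
  out <- candidates[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Build, classify, score and rank BGC-mQTL candidates
#'
#' The full evidence stage: superimposes mQTLs on clusters, then for every
#' cluster with at least one link computes the five evidence flags —
#' multiple mQTLs on the cluster; markers resolving to two or more distinct
#' cluster genes (marker-level evidence only exists for p-value mQTLs, i.e.
#' association panels); a mass-difference family of size two or more among
#' the cluster's traits; coexpression among the cluster's enzyme genes; and
#' a compound-class/enzyme-class compatibility match — classifies the
#' cluster, scores it, and ranks the candidates.
#'
#' @param mqtls mQTL tibble.
#' @param bgcs BGC tibble.
#' @param genes Annotation tibble.
#' @param features Feature metadata tibble.
#' @param expr Optional expression matrix (genes x samples).
#' @param compatibility Compatibility map, default
#'   [default_compatibility_map()].
#' @param biotransformations Mass-delta table, default
#'   [default_biotransformations()].
#' @param weights Evidence weights, default [default_evidence_weights()].
#' @param r_min Coexpression flag threshold.
#' @param flank Marker-to-gene assignment flank (bp).
#' @param min_overlap_bp Minimum overlap to link.
#' @param tolerance_ppm,tolerance_abs Mass-matching tolerances.
#' @return A ranked candidate tibble of class `bgc_candidates`.
#' @export
build_candidates <- function(mqtls, bgcs, genes, features, expr = NULL,
                             compatibility = default_compatibility_map(),
                             biotransformations = default_biotransformations(),
                             weights = default_evidence_weights(),
                             r_min = 0.79, flank = 2000, min_overlap_bp = 1,
                             tolerance_ppm = 10, tolerance_abs = 0.005) {
  genes <- validate_genes(genes)
  links <- find_overlaps(mqtls, bgcs, min_overlap_bp = min_overlap_bp)
  empty <- tibble(
    bgc_id = character(), chrom = character(), start = integer(),
    end = integer(), trait_ids = list(), class_label = character(),
    n_mqtls = integer(), n_genes_hit = integer(),
    massdiff_component_size = integer(),
    multi_mqtl = logical(), multi_gene = logical(),
    massdiff_family = logical(), coexpression_flagged = logical(),
    compatibility_match = logical(), max_r = double(),
    score = double(), rank = integer(), evidence_note = character()
  )
  if (!nrow(links)) return(structure(empty, class = c("bgc_candidates", class(empty))))
  edges <- massdiff_edges(features, biotransformations,
                          tolerance_ppm = tolerance_ppm,
                          tolerance_abs = tolerance_abs)
  rows <- list()
  for (bid in unique(links$bgc_id)) {
    lb <- links[links$bgc_id == bid, ]
    b <- bgcs[bgcs$bgc_id == bid, ]
    trait_ids <- sort(unique(lb$trait_id))
    n_mqtls <- nrow(lb)
    # marker-level gene resolution: p-value (association) links only
    genes_hit <- character(0)
    for (li in which(lb$stat_type == "pvalue")) {
      hit <- assign_markers_to_genes(lb$markers[[li]], genes, flank = flank)
      genes_hit <- union(genes_hit, intersect(hit, b$gene_ids[[1]]))
    }
    comps <- linked_components(edges, trait_ids)
    comp_size <- if (length(comps)) max(lengths(comps)) else 0L
    coex <- if (!is.null(expr)) {
      coexpression_support(genes[genes$gene_id %in% b$gene_ids[[1]], ],
                           expr, r_min = r_min)
    } else {
      tibble(n_pairs = 0L, max_r = NA_real_, mean_r = NA_real_, flagged = FALSE)
    }
    tf <- features[features$trait_id %in% trait_ids, ]
    missing_traits <- setdiff(trait_ids, features$trait_id)
    if (length(missing_traits)) {
      warn(sprintf("%d overlapping trait(s) absent from the feature table treated as unannotated",
                   length(missing_traits)))
      tf <- bind_rows(tf, tibble(trait_id = missing_traits, mz = NA_real_,
                                 rt = NA_real_, annotation = NA_character_,
                                 compound_class = NA_character_,
                                 annotated = FALSE))
    }
    label <- classify_bgc(unique(unlist(b$classes)), tf, compatibility)
    flags <- c(multi_mqtl = n_mqtls >= 2,
               multi_gene = length(genes_hit) >= 2,
               massdiff = comp_size >= 2,
               coexpression = isTRUE(coex$flagged),
               compatibility = label %in% c("known_compatible", "mixed"))
    note <- paste(c(
      sprintf("%d mQTL(s) from %d trait(s) overlap %s", n_mqtls,
              length(trait_ids), bid),
      if (flags[["multi_gene"]]) sprintf("markers resolve to %d distinct cluster genes",
                                         length(genes_hit)),
      if (flags[["massdiff"]]) sprintf("%d traits form one mass-difference family",
                                       comp_size),
      if (flags[["coexpression"]]) sprintf("cluster enzymes coexpressed (max r = %.2f)",
                                           coex$max_r),
      if (flags[["compatibility"]]) "compound class matches cluster enzyme content",
      sprintf("label: %s", label)
    ), collapse = "; ")
    rows[[length(rows) + 1L]] <- tibble(
      bgc_id = bid, chrom = b$chrom, start = b$start, end = b$end,
      trait_ids = list(trait_ids), class_label = label,
      n_mqtls = n_mqtls, n_genes_hit = length(genes_hit),
      massdiff_component_size = as.integer(comp_size),
      multi_mqtl = flags[["multi_mqtl"]], multi_gene = flags[["multi_gene"]],
      massdiff_family = flags[["massdiff"]],
      coexpression_flagged = flags[["coexpression"]],
      compatibility_match = flags[["compatibility"]],
      max_r = coex$max_r,
      score = score_bgc(flags, weights), rank = NA_integer_,
      evidence_note = note
    )
  }
  out <- rank_candidates(bind_rows(rows))
  structure(out, class = c("bgc_candidates", class(empty)))
}
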