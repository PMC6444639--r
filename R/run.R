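# File-level pipeline stages and the run-everything driver.  Every stage is
# deterministic given its inputs and seed: identical re-runs produce
# byte-identical files.

write_gene_classes <- function(genes, path) {
  rows <- tidyr::unnest(
    tibble(gene_id = genes$gene_id, class = genes$enzyme_classes),
    "class"
  )
  readr::write_tsv(rows, path)
  invisible(path)
}

read_gene_classes <- function(genes, path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), class = readr::col_character()
  ))
  unknown <- setdiff(unique(tab$gene_id), genes$gene_id)
  if (length(unknown)) {
    stop_validation(sprintf("gene-class table references unknown gene: %s",
                            unknown[1]))
  }
  by_gene <- split(tab$class, tab$gene_id)
  genes$enzyme_classes <- map(genes$gene_id, function(g) {
    sort(unique(by_gene[[g]] %||% character(0)))
  })
  genes
}

write_truth_json <- function(truth, params, path) {
  planted <- truth$planted
  obj <- list(
    planted = lapply(seq_len(nrow(planted)), function(i) list(
      bgc_id = planted$bgc_id[i], chrom = planted$chrom[i],
      start = planted$start[i], end = planted$end[i],
      causal = isTRUE(planted$causal[i]),
      gene_ids = planted$gene_ids[[i]]
    )),
    causal_map = truth$causal_map,
    decorations = truth$decorations,
    params = params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

write_study_inputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_gff3(study$genes, p("genes.gff3"))
  write_gene_classes(study$genes, p("gene_classes.tsv"))
  readr::write_tsv(study$map, p("marker_map.tsv"))
  write_genotype_matrix(study$geno, p("genotypes.tsv"), p("marker_map.tsv"))
  write_trait_matrix(study$traits, p("traits.tsv"))
  write_feature_table(study$features, p("features.tsv"))
  write_expression_matrix(study$expr, p("expression.tsv"))
  write_truth_json(study$truth, study$params, p("truth.json"))
  invisible(out_dir)
}

#' Run the complete bioprospecting pipeline on a synthetic study
#'
#' Simulates a study, writes its inputs, detects clusters, maps mQTLs
#' (RIL LOD scans or GWAS marker regression according to the study design),
#' superimposes, builds evidence, and writes the ranked candidate report.
#' All outputs land in `out_dir` as the package's TSV/JSON/BED dialects.
#'
#' @param seed Integer seed driving all randomness.
#' @param out_dir Output directory (created if needed).
#' @param study_args Named list of overrides for [simulate_study()].
#' @param config A [mapping_config()].
#' @param weights Evidence weights.
#' @return Invisibly, a list with the in-memory stage results
#'   (`study`, `bgcs`, `mqtls`, `links`, `candidates`).
#' @export
run_pipeline <- function(seed = 1, out_dir = ".", study_args = list(),
                         config = mapping_config(),
                         weights = default_evidence_weights()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  study <- do.call(simulate_study, c(list(seed = seed), study_args))
  write_study_inputs(study, out_dir)

  bgcs <- detect_bgcs(study$genes)
  write_cluster_table(bgcs, p("bgcs.tsv"))

  if (study$params$population == "ril") {
    mqtls <- call_mqtls_ril(study$geno, study$traits, config, seed = seed)
  } else {
    scans <- lapply(colnames(study$traits), function(id) {
      gwas_scan(study$geno, study$traits[, id], n_pcs = config$n_pcs,
                trait_id = id)
    })
    cl <- attr(study$map, "chrom_length")
    lens <- if (!is.null(cl)) setNames(rep(cl, length(unique(study$map$chrom))),
                                       unique(study$map$chrom))
    mqtls <- call_mqtls_gwas(scans, config, chrom_lengths = lens)
  }
  write_mqtl_table(mqtls, p("mqtls.tsv"))
  write_mqtl_bed(mqtls, p("mqtls.bed"))

  links <- find_overlaps(mqtls, bgcs)
  readr::write_tsv(
    links |> select(-"markers"),
    p("overlaps.tsv")
  )

  candidates <- build_candidates(mqtls, bgcs, study$genes, study$features,
                                 expr = study$expr, weights = weights,
                                 flank = config$flank)
  write_candidate_report(candidates, p("candidates.tsv"), "tsv")
  write_candidate_report(candidates, p("candidates.json"), "json")

  meta <- list(
    seed = seed, population = study$params$population,
    config = unclass(config), weights = as.list(weights),
    note = paste("GWAS mapping uses fixed-effect marker regression with",
                 "principal-component structure covariates, an explicit",
                 "approximation to a kinship mixed model.")
  )
  jsonlite::write_json(meta, p("run_meta.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(list(study = study, bgcs = bgcs, mqtls = mqtls, links = links,
                 candidates = candidates))
}
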