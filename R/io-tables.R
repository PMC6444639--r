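# Tabular I/O: metabolite feature metadata, genotype matrices + marker maps,
# trait and expression matrices, mQTL tables (TSV and BED), candidate report.

#' Read metabolite feature metadata
#'
#' TSV with columns `trait_id`, `mz`, `rt`, `annotation`, `compound_class`
#' (the last two may be empty).  An empty annotation marks the feature as an
#' unknown, which drives the discovery-candidate classification downstream.
#'
#' @param path Path to the feature TSV.
#' @return A tibble with the five columns above plus `annotated` (logical).
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    trait_id = readr::col_character(), mz = readr::col_character(),
    rt = readr::col_double(), annotation = readr::col_character(),
    compound_class = readr::col_character()
  ), na = character())
  mz <- suppressWarnings(as.numeric(tab$mz))
  if (any(is.na(mz) & nzchar(tab$mz)) || any(!nzchar(tab$mz))) {
    bad <- which(is.na(mz) | !nzchar(tab$mz))[1]
    stop_parse(sprintf("non-numeric m/z for trait '%s': '%s'",
                       tab$trait_id[bad], tab$mz[bad]))
  }
  if (anyDuplicated(tab$trait_id)) {
    stop_validation(sprintf("duplicate trait_id in feature table: %s",
                            tab$trait_id[duplicated(tab$trait_id)][1]))
  }
  if (any(mz <= 0)) stop_validation("feature m/z must be positive")
  tibble(
    trait_id = tab$trait_id, mz = mz, rt = tab$rt,
    annotation = ifelse(nzchar(tab$annotation), tab$annotation, NA_character_),
    compound_class = ifelse(nzchar(tab$compound_class), tab$compound_class, NA_character_),
    annotated = nzchar(tab$annotation)
  )
}

#' Write metabolite feature metadata
#' @param features Feature tibble (see [read_feature_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- tibble(
    trait_id = features$trait_id,
    mz = sprintf("%.5f", features$mz),
    rt = features$rt,
    annotation = ifelse(is.na(features$annotation), "", features$annotation),
    compound_class = ifelse(is.na(features$compound_class), "", features$compound_class)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# ---- genotype matrices -----------------------------------------------------

#' Construct a genotype matrix object
#'
#' Couples a numeric calls matrix (individuals x markers; RIL coding `{0,1}`,
#' GWAS additive dosage `{0,1,2}`, `NA` for missing) with its marker map.
#' Markers must appear in map order with strictly increasing positions per
#' chromosome, and no marker may exceed the missing-call cap.
#'
#' @param calls Numeric matrix, individuals in rows (rownames = ids),
#'   markers in columns (colnames = marker ids).
#' @param map Marker map tibble: `marker_id`, `chrom`, `pos` and, for RIL
#'   maps, `gen_pos` (cM).
#' @param coding `"ril"` or `"gwas"`.
#' @param max_missing Maximum tolerated per-marker missing fraction.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, coding = c("ril", "gwas"),
                            max_missing = 0.1) {
  coding <- match.arg(coding)
  if (!is.matrix(calls)) stop_validation("calls must be a matrix")
  if (is.null(colnames(calls)) || !identical(colnames(calls), map$marker_id)) {
    stop_validation("colnames(calls) must equal map$marker_id, in order")
  }
  validate_marker_map(map)
  miss <- colMeans(is.na(calls))
  if (any(miss > max_missing)) {
    stop_validation(sprintf("marker %s exceeds the %.0f%% missing-call cap",
                            map$marker_id[which(miss > max_missing)[1]],
                            100 * max_missing))
  }
  vals <- calls[!is.na(calls)]
  allowed <- if (coding == "ril") c(0, 1) else c(0, 1, 2)
  if (length(vals) && !all(vals %in% allowed)) {
    stop_validation(sprintf("%s calls must be in {%s}", coding,
                            paste(allowed, collapse = ",")))
  }
  structure(list(calls = calls, map = map, coding = coding),
            class = "genotype_matrix")
}

validate_marker_map <- function(map) {
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(map))) {
    stop_validation("marker map needs columns marker_id, chrom, pos")
  }
  if (anyDuplicated(map$marker_id)) stop_validation("duplicate marker_id in map")
  ok <- map |>
    group_by(.data$chrom) |>
    summarise(sorted = all(diff(.data$pos) > 0) || n() == 1) |>
    pull(.data$sorted)
  if (!all(ok)) {
    stop_validation("marker positions must be strictly increasing within each chromosome")
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%s coding), %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), x$coding,
              length(unique(x$map$chrom))))
  invisible(x)
}

#' Write / read a genotype matrix (calls TSV + marker map TSV)
#'
#' The calls file has one `individual` id column followed by one column per
#' marker; the map file has `marker_id`, `chrom`, `pos` and optionally
#' `gen_pos`.
#'
#' @param geno A `genotype_matrix`.
#' @param calls_path,map_path File paths.
#' @return Paths, invisibly.
#' @export
write_genotype_matrix <- function(geno, calls_path, map_path) {
  calls <- as_tibble(geno$calls)
  calls <- dplyr::bind_cols(tibble(individual = rownames(geno$calls)), calls)
  readr::write_tsv(calls, calls_path, na = "NA")
  readr::write_tsv(geno$map, map_path)
  invisible(c(calls_path, map_path))
}

#' @rdname write_genotype_matrix
#' @param coding `"ril"` or `"gwas"` (coding is not stored in the files).
#' @export
read_genotype_matrix <- function(calls_path, map_path, coding = c("ril", "gwas")) {
  coding <- match.arg(coding)
  map <- readr::read_tsv(map_path, col_types = readr::cols(
    marker_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), .default = readr::col_double()
  ))
  tab <- readr::read_tsv(calls_path, col_types = readr::cols(
    individual = readr::col_character(), .default = readr::col_double()
  ), na = "NA")
  calls <- as.matrix(tab[, -1, drop = FALSE])
  rownames(calls) <- tab$individual
  genotype_matrix(calls, map, coding)
}

#' Write / read a trait (or expression) abundance matrix
#'
#' Trait matrices are individuals x traits with an `individual` id column;
#' expression matrices are genes x samples with a `gene_id` column.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return The path (write) or the matrix (read), invisibly for writes.
#' @export
write_trait_matrix <- function(mat, path) {
  out <- dplyr::bind_cols(tibble(individual = rownames(mat)), as_tibble(mat))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), .default = readr::col_double()
  ))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$individual
  mat
}

#' @rdname write_trait_matrix
#' @export
write_expression_matrix <- function(mat, path) {
  out <- dplyr::bind_cols(tibble(gene_id = rownames(mat)), as_tibble(mat))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  if (anyDuplicated(tab$gene_id)) stop_validation("duplicate gene_id in expression matrix")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$gene_id
  mat
}

# ---- mQTL tables -----------------------------------------------------------

#' Write / read an mQTL table
#'
#' TSV with one row per mQTL: trait, interval (1-based inclusive), peak
#' position and statistic, statistic type, and the member marker ids.
#' [write_mqtl_bed()] exports the intervals as BED (0-based half-open) for
#' genome-browser interoperability.
#'
#' @param mqtls mQTL tibble from [call_mqtls_ril()] / [call_mqtls_gwas()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mqtl_table <- function(mqtls, path) {
  out <- tibble(
    trait_id = mqtls$trait_id, chrom = mqtls$chrom,
    start = as.integer(mqtls$start), end = as.integer(mqtls$end),
    peak_pos = as.integer(mqtls$peak_pos), peak_stat = mqtls$peak_stat,
    stat_type = mqtls$stat_type,
    marker_ids = collapse_ids(map(mqtls$markers, function(m) m$marker_id))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_mqtl_table
#' @param map Marker map used to restore member marker positions.
#' @export
read_mqtl_table <- function(path, map) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    trait_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    peak_pos = readr::col_integer(), peak_stat = readr::col_double(),
    stat_type = readr::col_character(), marker_ids = readr::col_character()
  ))
  ids <- split_ids(tab$marker_ids)
  tab$markers <- map(ids, function(v) {
    map[match(v, map$marker_id), c("marker_id", "chrom", "pos")]
  })
  tab$marker_ids <- NULL
  tab
}

#' @rdname write_mqtl_table
#' @export
write_mqtl_bed <- function(mqtls, path) {
  # BED is 0-based half-open: start-1, end unchanged
  rows <- sprintf("%s\t%d\t%d\t%s\t%g",
                  mqtls$chrom, as.integer(mqtls$start) - 1L,
                  as.integer(mqtls$end), mqtls$trait_id, mqtls$peak_stat)
  readr::write_lines(rows, path)
  invisible(path)
}

# ---- candidate report ------------------------------------------------------

.report_cols <- c("bgc_id", "trait_ids", "class_label", "score", "rank",
                  "multi_mqtl", "multi_gene", "massdiff_family",
                  "coexpression_flagged", "compatibility_match",
                  "n_mqtls", "n_genes_hit", "massdiff_component_size",
                  "chrom", "start", "end", "evidence_note")

#' Write the ranked candidate report
#'
#' Deterministic export of a ranked candidate table ([build_candidates()]):
#' fixed column order, rows in rank order, 1-based coordinates.  The JSON
#' mirror carries the identical fields.
#'
#' @param candidates Ranked candidate tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- candidate_report_frame(candidates)
  ok <- tryCatch({
    if (format == "tsv") {
      readr::write_tsv(flat, path, na = "")
    } else {
      jsonlite::write_json(flat, path, auto_unbox = FALSE, digits = 10,
                           na = "null", pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write report to '%s': %s",
                                   path, conditionMessage(ok)))
  invisible(path)
}

candidate_report_frame <- function(candidates) {
  if (!nrow(candidates)) {
    flat <- as_tibble(setNames(rep(list(character(0)), length(.report_cols)),
                               .report_cols))
    return(flat)
  }
  flat <- tibble(
    bgc_id = candidates$bgc_id,
    trait_ids = collapse_ids(candidates$trait_ids),
    class_label = candidates$class_label,
    score = candidates$score,
    rank = as.integer(candidates$rank),
    multi_mqtl = candidates$multi_mqtl,
    multi_gene = candidates$multi_gene,
    massdiff_family = candidates$massdiff_family,
    coexpression_flagged = candidates$coexpression_flagged,
    compatibility_match = candidates$compatibility_match,
    n_mqtls = as.integer(candidates$n_mqtls),
    n_genes_hit = as.integer(candidates$n_genes_hit),
    massdiff_component_size = as.integer(candidates$massdiff_component_size),
    chrom = candidates$chrom,
    start = as.integer(candidates$start),
    end = as.integer(candidates$end),
    evidence_note = candidates$evidence_note
  )
  flat[order(flat$rank), ]
}

#' @rdname write_candidate_report
#' @export
read_candidate_report <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    bgc_id = readr::col_character(), trait_ids = readr::col_character(),
    class_label = readr::col_character(), score = readr::col_double(),
    rank = readr::col_integer(),
    multi_mqtl = readr::col_logical(), multi_gene = readr::col_logical(),
    massdiff_family = readr::col_logical(),
    coexpression_flagged = readr::col_logical(),
    compatibility_match = readr::col_logical(),
    n_mqtls = readr::col_integer(), n_genes_hit = readr::col_integer(),
    massdiff_component_size = readr::col_integer(),
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), evidence_note = readr::col_character()
  ))
  tab$trait_ids <- split_ids(tab$trait_ids)
  tab
}
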