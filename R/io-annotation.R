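# Gene annotation and cluster-table I/O.  GFF3 is 1-based inclusive, as are
# all coordinates in this package; BED export (see write_mqtl_bed) converts.

#' Read gene annotation from a GFF3 file
#'
#' Extracts one feature kind (genes by default) into a tidy annotation
#' tibble.  Coordinates are kept 1-based inclusive, strand is preserved,
#' and `enzyme_classes` starts empty (fill it with
#' [assign_enzyme_classes()]).  Parsing is delegated to
#' [rtracklayer::readGFF()] after a line-level sanity scan so that a
#' malformed row is reported with its line number.
#'
#' @param path Path to a GFF3 file.
#' @param feature_kind Feature type to extract (column 3), default `"gene"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `protein_id`, `enzyme_classes` (list-column of character).
#' @export
read_gff3 <- function(path, feature_kind = "gene") {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body)) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  protein_id = character(), enzyme_classes = list()))
  }
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfields < 9L]
  if (length(bad)) {
    stop_parse(sprintf("malformed GFF3 record at line %d: expected 9 tab-separated columns, found %d",
                       bad[1], nfields[match(bad[1], body)]))
  }
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[as.character(gff$type) == feature_kind, , drop = FALSE]
  if (!nrow(gff)) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  protein_id = character(), enzyme_classes = list()))
  }
  pick <- function(col) if (col %in% names(gff)) as.character(gff[[col]]) else rep(NA_character_, nrow(gff))
  gene_id <- dplyr::coalesce(pick("ID"), pick("Name"),
                             paste0(feature_kind, "_", seq_len(nrow(gff))))
  strand <- as.character(gff$strand)
  strand[is.na(strand) | strand == "*"] <- "."
  out <- tibble(
    gene_id = gene_id,
    chrom = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = strand,
    protein_id = pick("protein_id")
  )
  check_interval(out$start, out$end, "GFF3 feature")
  if (anyDuplicated(out$gene_id)) {
    stop_validation(sprintf("duplicate gene id in annotation: %s",
                            out$gene_id[duplicated(out$gene_id)][1]))
  }
  out <- out[genomic_order(out$chrom, out$start), ]
  ensure_class_col(out)
}

#' Write gene annotation as GFF3
#'
#' Inverse of [read_gff3()]; writes one `feature_kind` row per gene with the
#' gene id in the `ID` attribute.  Deterministic output (rows in genomic
#' order) so identical annotations produce byte-identical files.
#'
#' @param genes Annotation tibble (see [read_gff3()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @param feature_kind Feature type to write.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "bgcqtl", feature_kind = "gene") {
  genes <- validate_genes(genes)
  genes <- genes[genomic_order(genes$chrom, genes$start), ]
  strand <- if ("strand" %in% names(genes)) genes$strand else rep(".", nrow(genes))
  strand[is.na(strand)] <- "."
  rows <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$chrom, source, feature_kind,
                  as.integer(genes$start), as.integer(genes$end),
                  strand, genes$gene_id)
  readr::write_lines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a predicted-cluster table
#'
#' Ingests externally predicted biosynthetic gene clusters from the package's
#' minimal TSV dialect (columns `bgc_id`, `chrom`, `start`, `end`,
#' `product_label`, `gene_ids` with comma-separated ids).  Member genes are
#' resolved against the annotation and the enzyme-class inventory is
#' recomputed from it; a gene id missing from the annotation, or a cluster
#' interval that does not cover all its genes, is an error.
#'
#' @param path Path to the cluster TSV.
#' @param genes Annotation tibble the gene ids resolve against.
#' @return A BGC tibble: `bgc_id`, `chrom`, `start`, `end`, `product_label`,
#'   `n_genes`, `gene_ids` (list), `classes` (list; multiset of enzyme
#'   classes across member genes).
#' @export
read_cluster_table <- function(path, genes) {
  genes <- validate_genes(genes)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    bgc_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    product_label = readr::col_character(), gene_ids = readr::col_character()
  ))
  if (!nrow(tab)) return(empty_bgc_table())
  check_interval(tab$start, tab$end, "cluster interval")
  gene_ids <- split_ids(tab$gene_ids)
  classes <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ids <- gene_ids[[i]]
    unknown <- setdiff(ids, genes$gene_id)
    if (length(unknown)) {
      stop_validation(sprintf("cluster %s lists unknown gene id: %s",
                              tab$bgc_id[i], unknown[1]))
    }
    g <- genes[match(ids, genes$gene_id), ]
    if (any(g$chrom != tab$chrom[i])) {
      stop_validation(sprintf("cluster %s has member genes on a different chromosome",
                              tab$bgc_id[i]))
    }
    outside <- g$start < tab$start[i] | g$end > tab$end[i]
    if (any(outside)) {
      stop_validation(sprintf("cluster %s interval does not cover member gene %s",
                              tab$bgc_id[i], g$gene_id[outside][1]))
    }
    classes[[i]] <- sort(unlist(g$enzyme_classes))
  }
  out <- tibble(
    bgc_id = tab$bgc_id, chrom = tab$chrom,
    start = tab$start, end = tab$end,
    product_label = tab$product_label,
    n_genes = lengths(gene_ids),
    gene_ids = gene_ids, classes = classes
  )
  out[genomic_order(out$chrom, out$start), ]
}

empty_bgc_table <- function() {
  tibble(bgc_id = character(), chrom = character(), start = integer(),
         end = integer(), product_label = character(), n_genes = integer(),
         gene_ids = list(), classes = list())
}

#' Write a BGC tibble in the cluster-table dialect
#'
#' @param bgcs BGC tibble (see [detect_bgcs()] / [read_cluster_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(bgcs, path) {
  out <- tibble(
    bgc_id = bgcs$bgc_id, chrom = bgcs$chrom,
    start = as.integer(bgcs$start), end = as.integer(bgcs$end),
    product_label = if ("product_label" %in% names(bgcs)) bgcs$product_label else NA_character_,
    gene_ids = collapse_ids(bgcs$gene_ids)
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
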