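# Internal helpers: error classes, seeding, interval arithmetic.

stop_validation <- function(msg, ...) {
  abort(msg, class = "bgcqtl_validation_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = c("bgcqtl_parse_error", "bgcqtl_validation_error"), ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "bgcqtl_io_error", ...)
}

# Fixed per-stage offsets so one global seed drives reproducible,
# independently re-runnable stages.
.stage_offsets <- c(
  genome = 1L, ril = 2L, gwas = 3L, traits = 4L, features = 5L,
  expression = 6L, perm = 7L, pipeline = 8L, misc = 9L
)

child_seed <- function(seed, stage, index = 0L) {
  off <- .stage_offsets[[stage]]
  # keep well under 2^31 - 1 (R integers are 32-bit)
  as.integer((as.numeric(seed) * 48271 + off * 1000003 + index) %% 2147483629)
}

# Closed-interval intersection length (1-based inclusive coordinates).
interval_overlap_bp <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2) + 1L)
}

check_interval <- function(start, end, what = "interval") {
  if (any(start > end)) {
    stop_validation(sprintf("%s has start > end", what))
  }
  if (any(start < 1)) {
    stop_validation(sprintf("%s has start < 1 (coordinates are 1-based)", what))
  }
  invisible(TRUE)
}

# Deterministic genomic ordering: chromosome as plain character sort, then
# start position.  Consistency, not karyotype aesthetics, is the contract.
genomic_order <- function(chrom, start) {
  order(as.character(chrom), start)
}

collapse_ids <- function(x) {
  map_chr(x, function(v) paste(v, collapse = ","))
}

split_ids <- function(x) {
  map(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ",", fixed = TRUE)[[1]]
  })
}

ensure_class_col <- function(genes) {
  if (!"enzyme_classes" %in% names(genes)) {
    genes$enzyme_classes <- map(seq_len(nrow(genes)), function(i) character(0))
  }
  genes
}

validate_genes <- function(genes, arg = "genes") {
  need <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols)) {
    stop_validation(sprintf("%s is missing column(s): %s", arg,
                            paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_validation(sprintf("duplicate gene_id in %s: %s", arg,
                            genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  if (nrow(genes)) check_interval(genes$start, genes$end, "gene interval")
  ensure_class_col(genes)
}
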