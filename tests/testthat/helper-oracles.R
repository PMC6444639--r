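# Independent oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately naive (brute force / direct normal equations) and
# never call the code paths they check.

# Brute-force all-pairs interval intersection (1-based closed intervals).
oracle_overlaps <- function(mqtls, bgcs, min_overlap_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(mqtls))) {
    for (j in seq_len(nrow(bgcs))) {
      if (mqtls$chrom[i] != bgcs$chrom[j]) next
      ov <- min(mqtls$end[i], bgcs$end[j]) - max(mqtls$start[i], bgcs$start[j]) + 1L
      if (ov >= min_overlap_bp) {
        out[[length(out) + 1L]] <- data.frame(
          bgc_id = bgcs$bgc_id[j], trait_id = mqtls$trait_id[i],
          overlap_bp = ov, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(bgc_id = character(), trait_id = character(),
                      overlap_bp = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$bgc_id, res$trait_id), , drop = FALSE]
}

# Direct normal-equations least squares: LOD for a single marker.
oracle_lod_marker <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  n <- length(y)
  if (length(unique(g)) < 2) return(0)
  X0 <- matrix(1, n, 1)
  X1 <- cbind(1, g)
  b0 <- solve(crossprod(X0), crossprod(X0, y))
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  rss0 <- sum((y - X0 %*% b0)^2)
  rss1 <- max(sum((y - X1 %*% b1)^2), 1e-12)
  max((n / 2) * log10(max(rss0, 1e-12) / rss1), 0)
}

# Brute-force transitive closure into connected components.
oracle_components <- function(edges, traits) {
  traits <- sort(unique(traits))
  comp <- seq_along(traits)
  names(comp) <- traits
  e <- edges[edges$trait_a %in% traits & edges$trait_b %in% traits, ]
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      a <- comp[[e$trait_a[k]]]; b <- comp[[e$trait_b[k]]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(names(comp), comp)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, "", 1))])
}

# Small deterministic genotype fixture: n lines x markers on the given map.
tiny_map <- function(n_chrom = 1, m = 5, spacing = 10000) {
  dplyr::bind_rows(lapply(seq_len(n_chrom), function(c) {
    tibble::tibble(
      marker_id = sprintf("c%d_m%d", c, seq_len(m)),
      chrom = paste0("chr", c),
      pos = as.integer(spacing * seq_len(m)),
      gen_pos = seq_len(m) * 2
    )
  }))
}

tiny_geno <- function(calls, map = NULL, coding = "ril") {
  if (is.null(map)) map <- tiny_map(1, ncol(calls))
  rownames(calls) <- sprintf("i%d", seq_len(nrow(calls)))
  colnames(calls) <- map$marker_id
  genotype_matrix(calls, map, coding)
}

# Random mQTL/BGC interval tables for overlap property tests.
random_intervals <- function(n, n_chrom, max_pos, id_prefix, is_mqtl) {
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(200000, n, replace = TRUE)
  tab <- tibble::tibble(
    chrom = chrom, start = start, end = start + width
  )
  if (is_mqtl) {
    tab$trait_id <- sprintf("%s%04d", id_prefix, seq_len(n))
    tab$peak_pos <- tab$start
    tab$peak_stat <- runif(n, 3, 10)
    tab$stat_type <- "LOD"
    tab$markers <- lapply(seq_len(n), function(i) {
      tibble::tibble(marker_id = character(), chrom = character(),
                     pos = integer())
    })
  } else {
    tab$bgc_id <- sprintf("%s%04d", id_prefix, seq_len(n))
    tab$gene_ids <- lapply(seq_len(n), function(i) character(0))
    tab$classes <- lapply(seq_len(n), function(i) character(0))
  }
  tab
}

# Genomic inflation factor from p-values (median chi-square / 0.456).
lambda_gc <- function(p) {
  median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}
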