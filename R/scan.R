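# mQTL mapping: RIL single-marker LOD scans with permutation thresholds and
# LOD-drop support intervals; GWAS marker regression with principal-component
# structure covariates and Benjamini-Hochberg FDR, merged into window mQTLs.

#' Mapping configuration
#'
#' Bundles the tunable parameters of the mapping stage: the LOD-drop used
#' for RIL support intervals (1.5 by classical convention), the permutation
#' count and genome-wide alpha for RIL significance, the per-trait FDR level
#' and merge window for GWAS calls, and the number of principal components
#' used as structure covariates.
#'
#' @param lod_drop LOD drop defining RIL support intervals.
#' @param n_permutations Permutations for the genome-wide LOD threshold.
#' @param alpha Genome-wide type-I error for the permutation threshold.
#' @param fdr_q Benjamini-Hochberg FDR level for GWAS calls.
#' @param gwas_window Merge window (bp) for significant GWAS markers.
#' @param n_pcs Principal components used as GWAS covariates.
#' @param flank Flank (bp) for marker-to-gene assignment.
#' @return A named list of class `mapping_config`.
#' @export
mapping_config <- function(lod_drop = 1.5, n_permutations = 1000,
                           alpha = 0.05, fdr_q = 0.05, gwas_window = 10000,
                           n_pcs = 3, flank = 2000) {
  if (lod_drop <= 0 || n_permutations <= 0 || gwas_window <= 0 ||
      n_pcs < 0 || flank < 0) {
    stop_validation("mapping_config parameters must be positive")
  }
  if (alpha <= 0 || alpha >= 1 || fdr_q <= 0 || fdr_q >= 1) {
    stop_validation("alpha and fdr_q must lie in (0, 1)")
  }
  structure(list(lod_drop = lod_drop, n_permutations = n_permutations,
                 alpha = alpha, fdr_q = fdr_q, gwas_window = gwas_window,
                 n_pcs = n_pcs, flank = flank),
            class = "mapping_config")
}

new_mqtl_scan <- function(trait_id, track, stat_type,
                          threshold = NA_real_, threshold_kind = NA_character_) {
  structure(list(trait_id = trait_id, track = track, stat_type = stat_type,
                 threshold = threshold, threshold_kind = threshold_kind),
            class = "mqtl_scan")
}

#' @export
print.mqtl_scan <- function(x, ...) {
  pk <- scan_peak(x)
  cat(sprintf("<mqtl_scan> trait %s: %d markers, %s; peak %s = %.4g at %s:%d",
              x$trait_id, nrow(x$track), x$stat_type,
              if (x$stat_type == "LOD") "LOD" else "p",
              pk$stat, pk$chrom, pk$pos))
  if (!is.na(x$threshold)) cat(sprintf(" (threshold %.4g, %s)", x$threshold,
                                       x$threshold_kind))
  cat("\n")
  invisible(x)
}

scan_peak <- function(scan, chrom = NULL) {
  tr <- scan$track
  if (!is.null(chrom)) tr <- tr[tr$chrom == chrom, ]
  best <- if (scan$stat_type == "LOD") {
    # ties broken by lowest genomic coordinate
    ord <- order(-tr$stat, as.character(tr$chrom), tr$pos)
    tr[ord[1], ]
  } else {
    ord <- order(tr$stat, as.character(tr$chrom), tr$pos)
    tr[ord[1], ]
  }
  best
}

# Vectorized single-marker LOD engine.
# calls: n x m genotype matrix (NA = missing, dropped pairwise);
# Y: n x k matrix of complete trait vectors (columns).
# Returns an m x k LOD matrix: LOD = (n_j/2) log10(RSS0 / RSS1) with RSS1
# floored at 1e-12 and monomorphic (or fully masked) markers fixed at 0.
lod_engine <- function(calls, Y) {
  Y <- as.matrix(Y)
  if (!anyNA(calls)) return(lod_engine_complete(calls, Y))
  M <- !is.na(calls)
  storage.mode(M) <- "double"
  G0 <- calls
  G0[is.na(G0)] <- 0
  n_j <- colSums(M)
  Sy <- crossprod(M, Y)            # m x k
  Syy <- crossprod(M, Y * Y)
  Sg <- colSums(G0)
  Sgg <- colSums(G0 * G0)
  Sgy <- crossprod(G0, Y)
  rss0 <- Syy - Sy * Sy / n_j
  sxx <- Sgg - Sg * Sg / n_j
  sxy <- Sgy - (Sg / n_j) * Sy
  rss1 <- rss0 - (sxy * sxy) / sxx
  rss1 <- pmax(rss1, 1e-12)
  lod <- (n_j / 2) * log10(pmax(rss0, 1e-12) / rss1)
  lod[sxx <= 1e-12, ] <- 0
  lod[rss0 <= 1e-12] <- 0
  pmax(lod, 0)
}

# Complete-data fast path: with no missing calls the null-model sums depend
# only on the trait, so one cross-product per scan suffices.
lod_engine_complete <- function(calls, Y) {
  n <- nrow(calls)
  m <- ncol(calls)
  k <- ncol(Y)
  sy <- colSums(Y)
  rss0 <- colSums(Y * Y) - sy * sy / n       # length k
  Sg <- colSums(calls)
  sxx <- colSums(calls * calls) - Sg * Sg / n  # length m
  sxy <- crossprod(calls, Y) - tcrossprod(Sg, sy) / n
  rss0_mat <- matrix(rss0, m, k, byrow = TRUE)
  rss1 <- pmax(rss0_mat - (sxy * sxy) / sxx, 1e-12)
  lod <- (n / 2) * log10(pmax(rss0_mat, 1e-12) / rss1)
  lod[sxx <= 1e-12, ] <- 0
  lod[rss0_mat <= 1e-12] <- 0
  pmax(lod, 0)
}

#' Single-marker LOD scan for a RIL trait
#'
#' At every marker, fits the trait on the `{0,1}` genotype by least squares
#' and reports `LOD = (n/2) log10(RSS0 / RSS1)`, the log10 likelihood ratio
#' of the one-QTL model against the intercept-only model (RSS1 floored at
#' 1e-12).  Individuals missing the tested genotype are dropped pairwise;
#' monomorphic markers score 0.  LOD is invariant to affine rescaling of the
#' trait.
#'
#' @param geno A `genotype_matrix` (RIL coding).
#' @param trait Numeric trait vector, one value per line.
#' @param trait_id Label carried into the result.
#' @return An `mqtl_scan` object; its `track` tibble holds `marker_id`,
#'   `chrom`, `pos`, `stat` (LOD) in map order.
#' @export
lod_scan <- function(geno, trait, trait_id = "trait") {
  if (length(trait) != nrow(geno$calls)) {
    stop_validation("trait length must equal the number of lines")
  }
  if (all(is.na(trait))) stop_validation("trait is all-missing")
  if (sd(trait, na.rm = TRUE) == 0) stop_validation("trait is constant")
  if (anyNA(trait)) {
    keep <- !is.na(trait)
    lod <- lod_engine(geno$calls[keep, , drop = FALSE],
                      matrix(trait[keep], ncol = 1))
  } else {
    lod <- lod_engine(geno$calls, matrix(trait, ncol = 1))
  }
  track <- tibble(marker_id = geno$map$marker_id, chrom = geno$map$chrom,
                  pos = geno$map$pos, stat = as.numeric(lod))
  new_mqtl_scan(trait_id, track, "LOD")
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the trait across lines `n_permutations` times, records the
#' genome-wide maximum LOD of each permuted scan, and returns the empirical
#' `1 - alpha` quantile — the classical genome-wide significance threshold
#' for single-trait QTL scans.
#'
#' @inheritParams lod_scan
#' @param n_permutations Number of permutations.
#' @param alpha Genome-wide type-I error rate in (0, 1).
#' @param seed Integer seed for the permutation draws.
#' @return The threshold (a single LOD value).
#' @export
permutation_threshold <- function(geno, trait, n_permutations = 1000,
                                  alpha = 0.05, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")
  if (all(is.na(trait))) stop_validation("trait is all-missing")
  keep <- !is.na(trait)
  y <- trait[keep]
  calls <- geno$calls[keep, , drop = FALSE]
  set.seed(child_seed(seed, "perm"))
  Y <- vapply(seq_len(n_permutations), function(i) sample(y),
              numeric(length(y)))
  lod <- lod_engine(calls, Y)
  maxima <- apply(lod, 2, max)
  as.numeric(quantile(maxima, 1 - alpha, names = FALSE))
}

#' LOD-drop support interval
#'
#' From the scan peak on the given chromosome, extends left and right to the
#' first marker whose LOD falls below `peak - lod_drop`; that boundary marker
#' is included, and the chromosome's terminal marker is used when no marker
#' drops.  With a set (or supplied) threshold, a peak below it is an error —
#' there is no mQTL to delimit.
#'
#' @param scan An `mqtl_scan` with LOD statistics.
#' @param chrom Chromosome to delimit on (default: the peak chromosome).
#' @param lod_drop LOD drop (default 1.5).
#' @param threshold Optional significance threshold; defaults to the one
#'   stored in the scan.
#' @return One-row tibble: `chrom`, `start`, `end`, `peak_pos`, `peak_stat`.
#' @export
lod_support_interval <- function(scan, chrom = NULL, lod_drop = 1.5,
                                 threshold = scan$threshold) {
  if (scan$stat_type != "LOD") stop_validation("support intervals require a LOD scan")
  if (is.null(chrom)) chrom <- scan_peak(scan)$chrom
  tr <- scan$track[scan$track$chrom == chrom, ]
  if (!nrow(tr)) stop_validation(sprintf("chromosome '%s' not in scan", chrom))
  peak_i <- order(-tr$stat, tr$pos)[1]
  peak <- tr$stat[peak_i]
  if (!is.null(threshold) && !is.na(threshold) && peak < threshold) {
    stop_validation(sprintf("peak LOD %.3f on %s is below the threshold %.3f: no mQTL to delimit",
                            peak, chrom, threshold))
  }
  cut <- peak - lod_drop
  below <- tr$stat < cut
  left <- which(below & seq_len(nrow(tr)) < peak_i)
  right <- which(below & seq_len(nrow(tr)) > peak_i)
  lo <- if (length(left)) max(left) else 1L
  hi <- if (length(right)) min(right) else nrow(tr)
  tibble(chrom = chrom, start = tr$pos[lo], end = tr$pos[hi],
         peak_pos = tr$pos[peak_i], peak_stat = peak)
}

empty_mqtl_table <- function() {
  tibble(trait_id = character(), chrom = character(), start = integer(),
         end = integer(), peak_pos = integer(), peak_stat = double(),
         stat_type = character(), threshold = double(), markers = list())
}

#' Call RIL mQTLs across a trait matrix
#'
#' Per trait: LOD scan, per-trait permutation threshold (seeded
#' deterministically from the global seed and the trait index), then one
#' mQTL per chromosome whose local peak exceeds the threshold, delimited by
#' the LOD-drop rule.  Member markers are those inside the support interval.
#'
#' @param geno A `genotype_matrix` (RIL coding).
#' @param traits Individuals x traits numeric matrix (column names are trait
#'   ids).
#' @param config A [mapping_config()].
#' @param seed Integer seed.
#' @return An mQTL tibble: `trait_id`, `chrom`, `start`, `end`, `peak_pos`,
#'   `peak_stat`, `stat_type` (`"LOD"`), `threshold`, `markers` (list of
#'   member-marker tibbles).
#' @export
call_mqtls_ril <- function(geno, traits, config = mapping_config(), seed = 1) {
  traits <- as.matrix(traits)
  ids <- colnames(traits) %||% paste0("trait_", seq_len(ncol(traits)))
  out <- list()
  for (j in seq_len(ncol(traits))) {
    y <- traits[, j]
    scan <- lod_scan(geno, y, ids[j])
    thr <- permutation_threshold(geno, y, config$n_permutations,
                                 config$alpha,
                                 seed = child_seed(seed, "perm", j))
    scan$threshold <- thr
    scan$threshold_kind <- "permutation_LOD"
    for (cc in unique(scan$track$chrom)) {
      tr <- scan$track[scan$track$chrom == cc, ]
      if (max(tr$stat) <= thr) next
      iv <- lod_support_interval(scan, cc, config$lod_drop, threshold = NULL)
      members <- geno$map[geno$map$chrom == cc &
                            geno$map$pos >= iv$start &
                            geno$map$pos <= iv$end,
                          c("marker_id", "chrom", "pos")]
      out[[length(out) + 1L]] <- tibble(
        trait_id = ids[j], chrom = cc, start = iv$start, end = iv$end,
        peak_pos = iv$peak_pos, peak_stat = iv$peak_stat,
        stat_type = "LOD", threshold = thr, markers = list(members)
      )
    }
  }
  if (!length(out)) return(empty_mqtl_table())
  res <- bind_rows(out)
  res[order(res$trait_id, as.character(res$chrom), res$start), ]
}

#' Principal components of a genotype matrix
#'
#' Leading principal components of the column-centered calls matrix (missing
#' calls imputed to the marker mean for this decomposition only), used as
#' population-structure covariates in [gwas_scan()].
#'
#' @param geno A `genotype_matrix`.
#' @param n_pcs Number of components.
#' @return Accessions x `n_pcs` score matrix.
#' @export
genotype_pcs <- function(geno, n_pcs = 3) {
  n <- nrow(geno$calls)
  if (n_pcs >= n - 2) stop_validation("n_pcs must be < number of accessions - 2")
  if (n_pcs == 0) return(matrix(numeric(0), n, 0))
  X <- geno$calls
  mu <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, mu)
  X[is.na(X)] <- 0
  sv <- svd(X, nu = n_pcs, nv = 0)
  sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
}

#' GWAS single-marker scan with structure covariates
#'
#' Fixed-effect approximation to a structured association scan: the leading
#' principal components of the centered genotype matrix enter as covariates
#' and each marker's additive dosage is tested by least squares
#' (`trait ~ intercept + PCs + genotype`), reporting the two-sided p-value
#' of the genotype coefficient.  Monomorphic markers, and markers collinear
#' with the covariates, report p = 1.  Individuals missing the tested call
#' are dropped pairwise.
#'
#' @param geno A `genotype_matrix` (dosage coding).
#' @param trait Numeric trait vector.
#' @param n_pcs Number of structure covariates.
#' @param trait_id Label carried into the result.
#' @return An `mqtl_scan` with `stat_type = "pvalue"`.
#' @export
gwas_scan <- function(geno, trait, n_pcs = 3, trait_id = "trait") {
  n <- nrow(geno$calls)
  if (length(trait) != n) stop_validation("trait length must equal the panel size")
  if (all(is.na(trait))) stop_validation("trait is all-missing")
  if (sd(trait, na.rm = TRUE) == 0) stop_validation("trait is constant")
  pcs <- genotype_pcs(geno, n_pcs)
  keep <- !is.na(trait)
  y <- trait[keep]
  C <- cbind(1, pcs)[keep, , drop = FALSE]
  calls <- geno$calls[keep, , drop = FALSE]
  m <- ncol(calls)
  p <- rep(1, m)
  complete <- !colSums(is.na(calls))
  df <- length(y) - ncol(C) - 1L
  if (any(complete) && df >= 1) {
    qrC <- qr(C)
    yr <- qr.resid(qrC, y)
    Gr <- qr.resid(qrC, calls[, complete, drop = FALSE])
    sxx <- colSums(Gr * Gr)
    sxy <- colSums(Gr * yr)
    syy <- sum(yr * yr)
    rss <- pmax(syy - (sxy * sxy) / sxx, 1e-12)
    tval <- (sxy / sxx) / sqrt(rss / df / sxx)
    pj <- 2 * pt(-abs(tval), df)
    pj[sxx <= 1e-10] <- 1
    p[complete] <- pj
  }
  for (j in which(!complete)) {
    ok <- !is.na(calls[, j])
    dfj <- sum(ok) - ncol(C) - 1L
    if (dfj < 1) next
    qrCj <- qr(C[ok, , drop = FALSE])
    yrj <- qr.resid(qrCj, y[ok])
    grj <- qr.resid(qrCj, calls[ok, j])
    sxx <- sum(grj^2)
    if (sxx <= 1e-10) next
    sxy <- sum(grj * yrj)
    rss <- max(sum(yrj^2) - sxy^2 / sxx, 1e-12)
    tval <- (sxy / sxx) / sqrt(rss / dfj / sxx)
    p[j] <- 2 * pt(-abs(tval), dfj)
  }
  track <- tibble(marker_id = geno$map$marker_id, chrom = geno$map$chrom,
                  pos = geno$map$pos, stat = p)
  new_mqtl_scan(trait_id, track, "pvalue")
}

#' Call GWAS mQTLs from per-marker p-values
#'
#' Per trait, Benjamini-Hochberg across that trait's markers at `fdr_q`;
#' significant markers on one chromosome lying within `gwas_window` bp of
#' each other merge into one mQTL whose interval is
#' `[min pos - window/2, max pos + window/2]`, clipped to the chromosome.
#' The peak is the most significant member (ties to the lowest coordinate).
#'
#' @param scans One `mqtl_scan` or a list of them (`stat_type = "pvalue"`).
#' @param config A [mapping_config()].
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   clipping; intervals are always clipped at 1 on the left.
#' @param global_fdr Apply BH across all traits' markers jointly instead of
#'   per trait.
#' @return An mQTL tibble as in [call_mqtls_ril()], with
#'   `stat_type = "pvalue"` and `threshold` = the BH p-value cutoff actually
#'   attained for that trait.
#' @export
call_mqtls_gwas <- function(scans, config = mapping_config(),
                            chrom_lengths = NULL, global_fdr = FALSE) {
  if (inherits(scans, "mqtl_scan")) scans <- list(scans)
  stopifnot(all(map_lgl(scans, function(s) s$stat_type == "pvalue")))
  if (global_fdr) {
    all_p <- unlist(map(scans, function(s) s$track$stat))
    adj_all <- p.adjust(all_p, "BH")
    offsets <- cumsum(c(0, head(map_int(scans, function(s) nrow(s$track)), -1)))
  }
  half <- config$gwas_window / 2
  out <- list()
  for (si in seq_along(scans)) {
    s <- scans[[si]]
    padj <- if (global_fdr) {
      adj_all[offsets[si] + seq_len(nrow(s$track))]
    } else {
      p.adjust(s$track$stat, "BH")
    }
    sig <- which(padj <= config$fdr_q)
    if (!length(sig)) next
    thr <- max(s$track$stat[sig])
    tr <- s$track[sig, ]
    for (cc in unique(tr$chrom)) {
      pos <- tr$pos[tr$chrom == cc]
      pv <- tr$stat[tr$chrom == cc]
      ord <- order(pos)
      pos <- pos[ord]; pv <- pv[ord]
      grp <- cumsum(c(TRUE, diff(pos) > config$gwas_window))
      for (gg in unique(grp)) {
        gp <- pos[grp == gg]; gv <- pv[grp == gg]
        lo <- max(1, floor(min(gp) - half))
        hi <- ceiling(max(gp) + half)
        if (!is.null(chrom_lengths) && cc %in% names(chrom_lengths)) {
          hi <- min(hi, chrom_lengths[[cc]])
        }
        pk <- order(gv, gp)[1]
        members <- s$track[s$track$chrom == cc & s$track$pos %in% gp,
                           c("marker_id", "chrom", "pos")]
        out[[length(out) + 1L]] <- tibble(
          trait_id = s$trait_id, chrom = cc,
          start = as.integer(lo), end = as.integer(hi),
          peak_pos = gp[pk], peak_stat = gv[pk],
          stat_type = "pvalue", threshold = thr, markers = list(members)
        )
      }
    }
  }
  if (!length(out)) return(empty_mqtl_table())
  res <- bind_rows(out)
  res[order(res$trait_id, as.character(res$chrom), res$start), ]
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy an mQTL scan
#'
#' `tidy()` returns the per-marker statistic track; `glance()` a one-row
#' summary (trait, marker count, peak location and statistic, threshold).
#'
#' @param x An `mqtl_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mqtl_scan
#' @export
tidy.mqtl_scan <- function(x, ...) {
  out <- x$track
  out$trait_id <- x$trait_id
  out$stat_type <- x$stat_type
  out[, c("trait_id", "marker_id", "chrom", "pos", "stat", "stat_type")]
}

#' @rdname tidy.mqtl_scan
#' @method glance mqtl_scan
#' @export
glance.mqtl_scan <- function(x, ...) {
  pk <- scan_peak(x)
  tibble(trait_id = x$trait_id, n_markers = nrow(x$track),
         stat_type = x$stat_type, peak_chrom = pk$chrom, peak_pos = pk$pos,
         peak_stat = pk$stat, threshold = x$threshold,
         threshold_kind = x$threshold_kind)
}
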