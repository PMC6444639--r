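# LOD scans, permutation thresholds, support intervals, GWAS regression and
# FDR-based calling.

test_that("LOD scan reproduces the closed-form least-squares ratio", {
  geno <- tiny_geno(matrix(c(0, 0, 1, 1), 4, 1), tiny_map(1, 1))
  y <- c(1.0, 1.2, 2.0, 2.1)
  s <- lod_scan(geno, y)
  # RSS0 = 0.9275, RSS1 = 0.025 -> LOD = 2 log10(37.1)
  expect_equal(s$track$stat, 2 * log10(0.9275 / 0.025), tolerance = 1e-9)
  expect_equal(s$track$stat, 3.139, tolerance = 1e-3 / 3.139)

  # identical group means -> no signal
  s0 <- lod_scan(geno, c(1, 2, 1, 2))
  expect_equal(s0$track$stat, 0)

  # monomorphic marker scores zero
  mono <- tiny_geno(matrix(1, 4, 1), tiny_map(1, 1))
  expect_equal(lod_scan(mono, y)$track$stat, 0)

  expect_error(lod_scan(geno, rep(3, 4)), "constant",
               class = "bgcqtl_validation_error")
  expect_error(lod_scan(geno, rep(NA_real_, 4)),
               class = "bgcqtl_validation_error")
})

test_that("LOD matches the normal-equations oracle and is affine-invariant", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    m <- sample(2:6, 1)
    calls <- matrix(rbinom(n * m, 1, 0.5), n, m)
    if (i %% 3 == 0) calls[sample(length(calls), ceiling(n * m * 0.05))] <- NA
    calls <- calls[, colMeans(is.na(calls)) <= 0.1, drop = FALSE]
    if (!ncol(calls)) next
    geno <- tiny_geno(calls, tiny_map(1, ncol(calls)))
    y <- rnorm(n) + calls[, 1] * rnorm(1) * (is.na(calls[, 1]) == FALSE)
    y[is.na(y)] <- 0
    s <- lod_scan(geno, y)
    want <- vapply(seq_len(ncol(calls)),
                   function(j) oracle_lod_marker(calls[, j], y), numeric(1))
    expect_equal(s$track$stat, want, tolerance = 1e-9)
    # affine rescaling of the trait leaves LOD unchanged
    s2 <- lod_scan(geno, 3.7 * y - 11)
    expect_equal(s2$track$stat, s$track$stat, tolerance = 1e-8)
  }
})

test_that("LOD-drop support interval follows the boundary-marker rule", {
  mk_scan <- function(lods, pos = NULL, chrom = "chr1") {
    pos <- pos %||% seq(10, by = 10, length.out = length(lods))
    bgcqtl:::new_mqtl_scan("t", tibble::tibble(
      marker_id = sprintf("m%d", seq_along(lods)), chrom = chrom,
      pos = as.integer(pos), stat = lods
    ), "LOD")
  }
  # walk-through: peak 4 at pos 30, boundary = first marker < 2.5 each side
  iv <- lod_support_interval(mk_scan(c(1, 2, 4, 2, 1)), lod_drop = 1.5)
  expect_equal(c(iv$start, iv$end), c(20L, 40L))
  expect_equal(iv$peak_pos, 30L)

  # peak at the chromosome's first marker
  iv2 <- lod_support_interval(mk_scan(c(5, 4, 1)), lod_drop = 1.5)
  expect_equal(iv2$start, 10L)
  expect_equal(iv2$end, 30L)

  # flat track: whole chromosome
  iv3 <- lod_support_interval(mk_scan(c(3, 3, 3, 3)), lod_drop = 1.5)
  expect_equal(c(iv3$start, iv3$end), c(10L, 40L))

  # widening the drop never shrinks the interval; peak always inside
  sc <- mk_scan(c(0.5, 2, 3.5, 5, 4, 2.5, 1))
  prev <- c(Inf, -Inf)
  for (drop in c(0.5, 1, 1.5, 2, 3)) {
    ivd <- lod_support_interval(sc, lod_drop = drop)
    expect_lte(ivd$start, prev[1] + 0)
    expect_gte(ivd$end, prev[2] + 0)
    expect_true(ivd$start <= ivd$peak_pos && ivd$peak_pos <= ivd$end)
    prev <- c(ivd$start, ivd$end)
  }

  # a peak below the stored threshold is not an mQTL
  sc$threshold <- 10
  expect_error(lod_support_interval(sc), "threshold",
               class = "bgcqtl_validation_error")
})

test_that("permutation threshold is deterministic and degenerate-safe", {
  map <- tiny_map(1, 6)
  geno <- simulate_ril_population(map, 60, seed = 2)
  y <- rnorm(60)
  t1 <- permutation_threshold(geno, y, 200, 0.05, seed = 5)
  t2 <- permutation_threshold(geno, y, 200, 0.05, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, permutation_threshold(geno, y, 200, 0.05, seed = 6)))
  expect_error(permutation_threshold(geno, y, 100, 1.5, seed = 1),
               class = "bgcqtl_validation_error")

  # constant-genotype genome: every scan is flat zero, threshold 0
  mono <- tiny_geno(matrix(1, 30, 4), tiny_map(1, 4))
  expect_equal(permutation_threshold(mono, rnorm(30), 100, 0.05, seed = 1), 0)
})

test_that("RIL mQTL calls recover a planted locus reproducibly", {
  st <- simulate_study(seed = 21, h2 = 0.5, n_null_traits = 0,
                       n_causal_traits = 2)
  mq1 <- call_mqtls_ril(st$geno, st$traits, seed = 21)
  mq2 <- call_mqtls_ril(st$geno, st$traits, seed = 21)
  expect_identical(mq1, mq2)
  truth <- st$truth$causal_map
  for (tid in truth$trait_id) {
    rows <- mq1[mq1$trait_id == tid, ]
    expect_equal(nrow(rows), 1) # one mQTL, on the causal chromosome
    expect_equal(rows$chrom, truth$chrom[truth$trait_id == tid][1])
    expect_true(rows$start <= truth$pos[truth$trait_id == tid][1] &&
                  rows$end >= truth$pos[truth$trait_id == tid][1])
    expect_gt(rows$peak_stat, rows$threshold)
  }
})

test_that("GWAS marker regression matches the hand-solved fit", {
  geno <- tiny_geno(matrix(c(0, 0, 1, 1), 4, 1), tiny_map(1, 1), coding = "gwas")
  y <- c(1.0, 1.2, 2.0, 2.1)
  s <- gwas_scan(geno, y, n_pcs = 0)
  # slope 0.95, t = 8.497 on 2 df
  tval <- 0.95 / sqrt((0.025 / 2) / 1)
  expect_equal(tval, 8.497, tolerance = 1e-3)
  expect_equal(s$track$stat, 2 * pt(-tval, 2), tolerance = 1e-6)
  expect_equal(s$track$stat, 0.0136, tolerance = 0.0005 / 0.0136)

  mono <- tiny_geno(matrix(2, 4, 1), tiny_map(1, 1), coding = "gwas")
  expect_equal(gwas_scan(mono, y, n_pcs = 0)$track$stat, 1)

  expect_error(gwas_scan(geno, y, n_pcs = 5),
               class = "bgcqtl_validation_error")
})

test_that("null GWAS p-values are uniform without structure", {
  map <- tiny_map(2, 150, spacing = 10000)
  geno <- simulate_gwas_population(map, 120, 1, 0, seed = 8)
  set.seed(42)
  y <- rnorm(120)
  s <- gwas_scan(geno, y, n_pcs = 0)
  ks <- suppressWarnings(stats::ks.test(s$track$stat, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("structure covariates deflate confounded null scans", {
  map <- tiny_map(2, 150, spacing = 10000)
  lams <- vapply(1:3, function(s) {
    geno <- simulate_gwas_population(map, 120, 2, 0.3, seed = s)
    sub <- attr(geno, "subpop")
    set.seed(s)
    y <- as.numeric(sub == 1) * 1.5 + rnorm(120) # confounded null trait
    p0 <- gwas_scan(geno, y, n_pcs = 0)$track$stat
    p3 <- gwas_scan(geno, y, n_pcs = 3)$track$stat
    c(lambda_gc(p0), lambda_gc(p3))
  }, numeric(2))
  expect_lt(median(abs(lams[2, ] - 1)), median(abs(lams[1, ] - 1)))
})

test_that("GWAS calling applies BH step-up and the merge window", {
  mk_pscan <- function(p, pos, chrom = "chr1", trait = "t") {
    bgcqtl:::new_mqtl_scan(trait, tibble::tibble(
      marker_id = sprintf("m%d", seq_along(p)), chrom = chrom,
      pos = as.integer(pos), stat = p
    ), "pvalue")
  }
  # BH at q = 0.05 on (0.001, 0.01, 0.02, 0.9): three significant
  s <- mk_pscan(c(0.001, 0.01, 0.02, 0.9), c(10000, 20000, 30000, 40000))
  mq <- call_mqtls_gwas(s, mapping_config())
  expect_equal(nrow(mq), 1) # contiguous significant markers merge
  expect_equal(nrow(mq$markers[[1]]), 3)
  expect_equal(mq$peak_pos, 10000L)
  expect_equal(mq$peak_stat, 0.001)
  expect_equal(mq$stat_type, "pvalue")

  # two significant markers 5 kb apart with a 10 kb window merge into one
  s2 <- mk_pscan(c(1e-5, 1e-5, 0.9), c(10000, 15000, 90000))
  mq2 <- call_mqtls_gwas(s2, mapping_config())
  expect_equal(nrow(mq2), 1)
  expect_equal(c(mq2$start, mq2$end), c(5000L, 20000L))

  # but split when farther apart than the window
  s3 <- mk_pscan(c(1e-5, 1e-5), c(10000, 40000))
  expect_equal(nrow(call_mqtls_gwas(s3, mapping_config())), 2)

  # nothing significant -> empty call set
  s4 <- mk_pscan(c(0.4, 0.6, 0.9), c(10000, 20000, 30000))
  expect_equal(nrow(call_mqtls_gwas(s4, mapping_config())), 0)
})

test_that("scan objects expose tidy, glance and autoplot views", {
  st <- simulate_study(seed = 12, h2 = 0.5, n_null_traits = 0,
                       n_causal_traits = 1)
  s <- lod_scan(st$geno, st$traits[, 1], colnames(st$traits)[1])
  td <- tidy(s)
  expect_equal(nrow(td), nrow(st$map))
  expect_named(td, c("trait_id", "marker_id", "chrom", "pos", "stat",
                     "stat_type"))
  gl <- glance(s)
  expect_equal(gl$peak_stat, max(td$stat))
  expect_s3_class(autoplot(s), "ggplot")
})
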