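# Generators: determinism, RIL recombination model, GWAS structure,
# heritability scaling, mass decoration, coexpression targets.

test_that("all generators are seed-deterministic and seed-sensitive", {
  g1 <- simulate_genome(2, 20, 2, seed = 7)
  g2 <- simulate_genome(2, 20, 2, seed = 7)
  g3 <- simulate_genome(2, 20, 2, seed = 8)
  expect_identical(g1$genes, g2$genes)
  expect_false(identical(g1$genes$start, g3$genes$start))

  map <- tiny_map(2, 20, spacing = 100000)
  expect_identical(simulate_ril_population(map, 30, seed = 5)$calls,
                   simulate_ril_population(map, 30, seed = 5)$calls)
  expect_identical(simulate_gwas_population(map, 40, 2, 0.2, seed = 5)$calls,
                   simulate_gwas_population(map, 40, 2, 0.2, seed = 5)$calls)
  fm1 <- simulate_feature_metadata(list(c("a", "b")), seed = 5)
  fm2 <- simulate_feature_metadata(list(c("a", "b")), seed = 5)
  expect_identical(fm1$features, fm2$features)
})

test_that("RIL switch probability follows the selfing-expanded Haldane rate", {
  # zero map distance: never switch
  map0 <- tiny_map(1, 3)
  map0$gen_pos <- c(0, 0, 0)
  g0 <- simulate_ril_population(map0, 100, seed = 2)
  expect_true(all(g0$calls[, 1] == g0$calls[, 2]))
  expect_true(all(g0$calls[, 2] == g0$calls[, 3]))

  # d -> Inf gives r = 1/2 and R = 2r/(1+2r) = 1/2
  # moderate d = 10 cM: r = (1 - exp(-0.2))/2, R = 2r/(1+2r)
  d <- 10
  r <- (1 - exp(-2 * d / 100)) / 2
  R <- 2 * r / (1 + 2 * r)
  map1 <- tiny_map(1, 11)
  map1$gen_pos <- seq(0, 100, by = d)
  n <- 400
  g <- simulate_ril_population(map1, n, seed = 11)
  sw <- mean(g$calls[, -1] != g$calls[, -11])
  n_int <- n * 10
  se <- sqrt(R * (1 - R) / n_int)
  expect_lt(abs(sw - R), 4 * se)

  # marker allele frequency ~ Binomial(n, 1/2): inside the 99% CI at n=200
  g2 <- simulate_ril_population(tiny_map(1, 5), 200, seed = 3)
  freq <- mean(g2$calls[, 1])
  ci <- qbinom(c(0.005, 0.995), 200, 0.5) / 200
  expect_gte(freq, ci[1])
  expect_lte(freq, ci[2])

  # unordered genetic map is rejected
  bad <- tiny_map(1, 3)
  bad$gen_pos <- c(0, 5, 2)
  expect_error(simulate_ril_population(bad, 10, seed = 1),
               class = "bgcqtl_validation_error")
})

test_that("GWAS panel structure tracks the divergence parameter", {
  map <- tiny_map(2, 100, spacing = 10000)
  expect_error(simulate_gwas_population(map, 20, 2, 1.5, seed = 1),
               class = "bgcqtl_validation_error")
  expect_error(simulate_gwas_population(map, 20, 2, -0.1, seed = 1),
               class = "bgcqtl_validation_error")

  # divergence 0.3, 2 subpops: PC1 separates the labels
  rs <- vapply(1:5, function(s) {
    g <- simulate_gwas_population(map, 80, 2, 0.3, seed = s)
    pc1 <- genotype_pcs(g, 1)[, 1]
    abs(cor(pc1, as.numeric(attr(g, "subpop") == 1)))
  }, numeric(1))
  expect_gt(mean(rs), 0.8)

  # panmictic panel: leading PC no stronger than under column permutation
  g0 <- simulate_gwas_population(map, 80, 1, 0, seed = 4)
  share <- function(m) {
    x <- scale(m, scale = FALSE)
    d <- svd(x, nu = 0, nv = 0)$d^2
    d[1] / sum(d)
  }
  obs <- share(g0$calls)
  set.seed(99)
  null_share <- replicate(20, share(apply(g0$calls, 2, sample)))
  expect_lte(obs, max(null_share) * 1.05)
})

test_that("trait generator hits the requested heritability", {
  map <- tiny_map(1, 5)
  geno <- simulate_ril_population(map, 200, seed = 1)
  causal <- tibble::tibble(trait_id = "t", chrom = "chr1", pos = 30000L, h2 = 0.3)

  # h2 = 1: trait is a deterministic function of the causal genotype
  t1 <- simulate_traits(geno, dplyr::mutate(causal, h2 = 1), seed = 1)
  g <- geno$calls[, t1$causal_map$marker_id]
  expect_equal(abs(cor(t1$traits[, 1], g)), 1)

  # h2 = 0: squared correlation stays within its null sampling range
  t0 <- simulate_traits(geno, dplyr::mutate(causal, h2 = 0), seed = 1)
  expect_lt(cor(t0$traits[, 1], g)^2, 0.05)

  # h2 = 0.3, n = 200: mean realized R^2 over 100 seeds within +/- 0.05
  r2 <- vapply(1:100, function(s) {
    tt <- simulate_traits(geno, causal, seed = s)
    cor(tt$traits[, 1], g)^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.3), 0.05)

  # causal chromosome absent from the map is an error
  expect_error(
    simulate_traits(geno, dplyr::mutate(causal, chrom = "chr9"), seed = 1),
    class = "bgcqtl_validation_error"
  )
})

test_that("feature families encode exact biotransformation deltas", {
  glyco <- default_biotransformations()
  glyco <- glyco[glyco$name == "glycosylation", ]
  fm <- simulate_feature_metadata(list(c("x", "y")), deltas = glyco, seed = 2)
  dmz <- diff(fm$features$mz[match(c("x", "y"), fm$features$trait_id)])
  expect_equal(dmz, 162.05282, tolerance = 1e-4 / 162)
  expect_equal(fm$decorations$transformation, "glycosylation")

  # annotation fraction 0 -> all unknown
  expect_false(any(fm$features$annotated))
  fm2 <- simulate_feature_metadata(list(c("x", "y")), extra_traits = c("u", "v"),
                                   annotation_fraction = 1, seed = 2)
  expect_true(all(fm2$features$annotated))
})

test_that("expression generator hits the target within-cluster correlation", {
  genome <- simulate_genome(1, 30, 1, cluster_size = 4, seed = 5)
  ids <- genome$planted$gene_ids[[1]]
  mean_r <- vapply(1:100, function(s) {
    e <- simulate_expression(genome$genes, list(ids), n_samples = 50,
                             within_cluster_r = 0.8, seed = s)
    cm <- cor(t(e[ids, ]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_lt(abs(mean(mean_r) - 0.8), 0.1)

  # r = 0: cluster genes behave like background
  e0 <- simulate_expression(genome$genes, list(ids), n_samples = 200,
                            within_cluster_r = 0, seed = 1)
  cm0 <- cor(t(e0[ids, ]))
  expect_lt(abs(mean(cm0[upper.tri(cm0)])), 0.15)

  expect_error(simulate_expression(genome$genes, list(ids),
                                   within_cluster_r = 1, seed = 1),
               class = "bgcqtl_validation_error")
})

test_that("genome generator plants recoverable clusters", {
  genome <- simulate_genome(3, 40, 3, cluster_size = 4, seed = 9)
  expect_equal(nrow(genome$planted), 3)
  # planted runs carry at least two distinct classes
  expect_true(all(vapply(genome$planted$classes,
                         function(cl) length(unique(cl)) >= 2, logical(1))))
  # genes never overlap within a chromosome
  by_chrom <- split(genome$genes, genome$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # no planted clusters -> no run of >= 3 enzyme genes within the gap rule
  g0 <- simulate_genome(2, 40, 0, seed = 9)
  expect_equal(nrow(detect_bgcs(g0$genes)), 0)
})
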