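# Interval superposition and the evidence layers.

mqtl_row <- function(trait, chrom, start, end) {
  tibble::tibble(
    trait_id = trait, chrom = chrom, start = as.integer(start),
    end = as.integer(end), peak_pos = as.integer(start),
    peak_stat = 5, stat_type = "LOD", threshold = 3,
    markers = list(tibble::tibble(marker_id = character(),
                                  chrom = character(), pos = integer()))
  )
}

bgc_row <- function(id, chrom, start, end, gene_ids = character(0),
                    classes = character(0)) {
  tibble::tibble(
    bgc_id = id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), product_label = NA_character_,
    n_genes = length(gene_ids), gene_ids = list(gene_ids),
    classes = list(classes)
  )
}

test_that("superposition computes closed-interval overlap lengths", {
  # the predicted cluster span against a broad mQTL interval around it
  bgc <- bgc_row("c1", "chr1", 14059096, 14124875)
  mq <- mqtl_row("lehmbachol_A", "chr1", 13900000, 14500000)
  links <- find_overlaps(mq, bgc)
  expect_equal(nrow(links), 1)
  expect_equal(links$overlap_bp, 65780L) # full cluster span contained

  # identical intervals overlap over their whole length
  mq2 <- mqtl_row("t2", "chr1", 14059096, 14124875)
  expect_equal(find_overlaps(mq2, bgc)$overlap_bp,
               14124875L - 14059096L + 1L)

  # different chromosomes never link
  mq3 <- mqtl_row("t3", "chr2", 14059096, 14124875)
  expect_equal(nrow(find_overlaps(mq3, bgc)), 0)
})

test_that("superposition equals the brute-force all-pairs scan", {
  set.seed(7)
  for (rep in 1:5) {
    mq <- random_intervals(300, 5, 4e6, "t", is_mqtl = TRUE)
    bg <- random_intervals(80, 5, 4e6, "b", is_mqtl = FALSE)
    got <- find_overlaps(mq, bg)
    want <- oracle_overlaps(mq, bg)
    got_key <- paste(got$bgc_id, got$trait_id, got$overlap_bp)
    want_key <- paste(want$bgc_id, want$trait_id, want$overlap_bp)
    expect_setequal(got_key, want_key)
    expect_equal(nrow(got), nrow(want))
  }
})

test_that("markers resolve to flanked genes without arbitration", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(10000L, 11500L, 80000L), end = c(12000L, 13000L, 82000L),
    strand = "+", protein_id = NA_character_,
    enzyme_classes = list(character(0), character(0), character(0))
  )
  mk <- function(pos) tibble::tibble(marker_id = "m", chrom = "chr1",
                                     pos = as.integer(pos))
  # 1 kb upstream with a 2 kb flank: assigned
  expect_equal(assign_markers_to_genes(mk(9000), genes), "gA")
  # 50 kb away: not assigned
  expect_equal(assign_markers_to_genes(mk(132000), genes), character(0))
  # inside two overlapping genes: both assigned
  expect_setequal(assign_markers_to_genes(mk(11800), genes), c("gA", "gB"))
})

test_that("pearson_r handles the textbook and degenerate cases", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(r))
  expect_error(pearson_r(1:3, 1:4), class = "bgcqtl_validation_error")
  expect_error(pearson_r(1:2, 1:2), class = "bgcqtl_validation_error")
})

test_that("coexpression support flags correlated cluster enzymes", {
  genes <- tibble::tibble(
    gene_id = c("e1", "e2", "bg"), chrom = "chr1",
    start = c(1L, 1000L, 2000L), end = c(500L, 1500L, 2500L), strand = "+",
    protein_id = NA_character_,
    enzyme_classes = list("synthase", "oxidase", character(0))
  )
  prof <- rnorm(30)
  expr <- rbind(e1 = prof, e2 = prof, bg = rnorm(30))
  sup <- coexpression_support(genes, expr)
  expect_equal(sup$max_r, 1)
  expect_true(sup$flagged)
  expect_equal(sup$n_pairs, 1L) # class-free member excluded

  # independent profiles almost never reach the threshold at n = 50
  set.seed(5)
  flags <- replicate(50, {
    e <- rbind(e1 = rnorm(50), e2 = rnorm(50))
    coexpression_support(genes[1:2, ], e)$flagged
  })
  expect_lt(mean(flags), 0.1)

  # a single usable gene yields no pairs and no flag
  sup1 <- coexpression_support(genes[c(1, 3), ], expr)
  expect_equal(sup1$n_pairs, 0L)
  expect_false(sup1$flagged)
})

test_that("mass-difference edges respect deltas and tolerances", {
  feats <- tibble::tibble(trait_id = c("m1", "m2"),
                          mz = c(287.0550, 449.1078))
  e <- massdiff_edges(feats)
  expect_equal(nrow(e), 1)
  expect_equal(e$transformation, "glycosylation")
  expect_lt(e$deviation_da, 1e-3)

  # identical masses match no positive delta
  same <- tibble::tibble(trait_id = c("a", "b"), mz = c(300, 300))
  expect_equal(nrow(massdiff_edges(same)), 0)

  # 0.05 Da off at 10 ppm / 0.005 Da: rejected
  off <- tibble::tibble(trait_id = c("a", "b"), mz = c(287.0550, 449.1578))
  expect_equal(nrow(massdiff_edges(off)), 0)

  # symmetric and invariant to feature order
  e2 <- massdiff_edges(feats[2:1, ])
  expect_equal(e2, e)
})

test_that("linked components equal the brute-force transitive closure", {
  edges <- tibble::tibble(trait_a = c("a", "b"), trait_b = c("b", "c"),
                          transformation = "x", delta_obs = 1,
                          deviation_da = 0)
  comp <- linked_components(edges, c("a", "b", "c", "d"))
  expect_equal(unname(comp), list(c("a", "b", "c"), "d"))

  # no edges: all singletons
  none <- edges[0, ]
  expect_length(linked_components(none, c("x", "y", "z")), 3)

  set.seed(23)
  for (rep in 1:10) {
    traits <- sprintf("t%d", 1:12)
    n_e <- sample(0:15, 1)
    e <- tibble::tibble(
      trait_a = sample(traits, n_e, replace = TRUE),
      trait_b = sample(traits, n_e, replace = TRUE),
      transformation = "x", delta_obs = 1, deviation_da = 0
    )
    e <- e[e$trait_a != e$trait_b, ]
    got <- unname(linked_components(e, traits))
    want <- oracle_components(e, traits)
    expect_equal(got, want)
  }
})
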