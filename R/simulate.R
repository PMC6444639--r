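# Seeded synthetic-data generators: genomes with planted clusters, RIL and
# structured GWAS populations, heritable metabolite traits, mass-decorated
# feature metadata, and coexpressed expression matrices.  One global seed
# drives fixed per-stage child seeds (see child_seed) so stages are
# independently re-runnable and byte-reproducible.

#' Simulate an evenly spaced marker map
#'
#' Physical positions are placed at regular intervals along each chromosome;
#' genetic positions (cM) scale linearly with physical position, so the
#' default genome has a uniform recombination landscape.
#'
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param genetic_length_cm Genetic length of each chromosome in cM.
#' @return A marker map tibble (`marker_id`, `chrom`, `pos`, `gen_pos`) with
#'   a `chrom_length` attribute.
#' @export
simulate_marker_map <- function(n_chrom = 5, markers_per_chrom = 50,
                                chrom_length = 5e6, genetic_length_cm = 100) {
  spacing <- chrom_length / markers_per_chrom
  per_chrom <- function(c) {
    pos <- as.integer(round(spacing * (seq_len(markers_per_chrom) - 0.5)))
    tibble(
      marker_id = sprintf("chr%d_m%03d", c, seq_len(markers_per_chrom)),
      chrom = paste0("chr", c),
      pos = pos,
      gen_pos = genetic_length_cm * pos / chrom_length
    )
  }
  map <- bind_rows(lapply(seq_len(n_chrom), per_chrom))
  attr(map, "chrom_length") <- chrom_length
  map
}

#' Simulate a genome annotation with planted biosynthetic gene clusters
#'
#' Genes are placed in non-overlapping slots along each chromosome
#' (one gene per slot, jittered within it).  Each planted cluster compresses
#' `cluster_size` consecutive genes into a tight run (gaps `cluster_gap` bp,
#' well inside the default 10 kb chaining gap of [detect_bgcs()]) and assigns
#' them enzyme classes cycled from a pathway template, guaranteeing at least
#' two distinct classes.  Background genes are mostly class-free; a
#' configurable fraction carry a single lone enzyme class.  Because the slot
#' spacing far exceeds the chaining gap, lone background enzymes cannot form
#' spurious chains of three.
#'
#' @param n_chrom,genes_per_chrom Genome layout.
#' @param n_planted_bgcs Number of planted clusters (spread round-robin over
#'   chromosomes).
#' @param cluster_size Genes per planted cluster (must be >= 3).
#' @param seed Integer seed.
#' @param chrom_length Chromosome length (bp).
#' @param gene_length,cluster_gap Gene span and intra-cluster gap (bp).
#' @param lone_enzyme_fraction Fraction of background genes given one class.
#' @param class_template Ordered enzyme classes cycled over cluster genes.
#' @return A list with `genes` (annotation tibble), `planted` (tibble of
#'   planted clusters: `bgc_id`, `chrom`, `start`, `end`, `gene_ids`,
#'   `classes`), and `params`.
#' @export
simulate_genome <- function(n_chrom = 5, genes_per_chrom = 50,
                            n_planted_bgcs = 1, cluster_size = 4,
                            seed = 1, chrom_length = 5e6,
                            gene_length = 3000, cluster_gap = 3000,
                            lone_enzyme_fraction = 0.02,
                            class_template = c("synthase", "oxidase",
                                               "glycosyltransferase")) {
  if (cluster_size < 3) stop_validation("cluster_size must be >= 3")
  if (gene_length <= 0 || cluster_gap <= 0) {
    stop_validation("gene spacing parameters must be positive")
  }
  slot_w <- floor(chrom_length / genes_per_chrom)
  if (slot_w <= gene_length + 2) {
    stop_validation("genome too small for the requested gene density")
  }
  span_needed <- cluster_size * gene_length + (cluster_size - 1) * cluster_gap
  if (span_needed > slot_w * cluster_size) {
    stop_validation("genome too small to place the requested clusters")
  }
  per_chrom_clusters <- tabulate(((seq_len(n_planted_bgcs) - 1L) %% n_chrom) + 1L,
                                 nbins = n_chrom)
  if (any(per_chrom_clusters * (cluster_size + 2L) > genes_per_chrom)) {
    stop_validation("genome too small to place the requested clusters")
  }
  set.seed(child_seed(seed, "genome"))

  genes_list <- vector("list", n_chrom)
  planted_list <- list()
  bgc_counter <- 0L
  for (c in seq_len(n_chrom)) {
    n_cl <- per_chrom_clusters[c]
    slot_start <- slot_w * (seq_len(genes_per_chrom) - 1L)
    jitter <- floor(runif(genes_per_chrom, 0, slot_w - gene_length - 1))
    start <- as.integer(slot_start + jitter + 1L)
    end <- as.integer(start + gene_length - 1L)
    classes <- map(seq_len(genes_per_chrom), function(i) character(0))
    lone <- runif(genes_per_chrom) < lone_enzyme_fraction
    for (i in which(lone)) {
      classes[[i]] <- sample(class_template, 1)
    }
    cluster_first <- integer(0)
    if (n_cl > 0) {
      # disjoint slot runs, one per cluster, spread over the chromosome
      seg <- floor(genes_per_chrom / n_cl)
      cluster_first <- vapply(seq_len(n_cl), function(k) {
        lo <- (k - 1L) * seg + 1L
        hi <- k * seg - cluster_size
        if (hi < lo) stop_validation("genome too small to place the requested clusters")
        as.integer(sample(seq(lo, hi), 1))
      }, integer(1))
      for (k in seq_len(n_cl)) {
        idx <- cluster_first[k] + seq_len(cluster_size) - 1L
        s0 <- as.integer(slot_w * (cluster_first[k] - 1L) + 1L)
        st <- s0 + (seq_len(cluster_size) - 1L) * (gene_length + cluster_gap)
        start[idx] <- as.integer(st)
        end[idx] <- as.integer(st + gene_length - 1L)
        cl <- rep_len(class_template, cluster_size)
        for (j in seq_along(idx)) classes[[idx[j]]] <- cl[j]
        bgc_counter <- bgc_counter + 1L
        planted_list[[bgc_counter]] <- tibble(
          bgc_id = sprintf("planted_%d", bgc_counter),
          chrom = paste0("chr", c),
          start = min(start[idx]), end = max(end[idx]),
          gene_ids = list(sprintf("chr%d_g%03d", c, idx)),
          classes = list(sort(cl))
        )
      }
    }
    genes_list[[c]] <- tibble(
      gene_id = sprintf("chr%d_g%03d", c, seq_len(genes_per_chrom)),
      chrom = paste0("chr", c),
      start = start, end = end,
      strand = rep_len(c("+", "-"), genes_per_chrom),
      protein_id = NA_character_,
      enzyme_classes = classes
    )
  }
  genes <- bind_rows(genes_list)
  genes <- genes[genomic_order(genes$chrom, genes$start), ]
  planted <- if (length(planted_list)) bind_rows(planted_list) else
    tibble(bgc_id = character(), chrom = character(), start = integer(),
           end = integer(), gene_ids = list(), classes = list())
  list(genes = genes, planted = planted,
       params = list(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
                     chrom_length = chrom_length, cluster_size = cluster_size,
                     class_template = class_template,
                     lone_enzyme_fraction = lone_enzyme_fraction))
}

#' Simulate a recombinant inbred line population
#'
#' RIL-by-selfing model: every line is fully homozygous, coded `{0,1}` per
#' marker.  Along each chromosome the genotype switches between adjacent
#' markers with probability `R = 2r / (1 + 2r)`, the selfing-expanded
#' recombination rate, where `r` is the meiotic recombination fraction
#' obtained from the genetic map distance via Haldane's map function
#' `r = (1 - exp(-2d/100)) / 2` (d in cM).
#'
#' @param map Marker map with a `gen_pos` column (cM), monotone per
#'   chromosome.
#' @param n_lines Number of lines.
#' @param seed Integer seed.
#' @return A `genotype_matrix` with RIL coding.
#' @export
simulate_ril_population <- function(map, n_lines = 200, seed = 1) {
  if (!"gen_pos" %in% names(map)) {
    stop_validation("RIL simulation needs a genetic map (gen_pos column, cM)")
  }
  validate_marker_map(map)
  bad <- map |>
    group_by(.data$chrom) |>
    summarise(ok = n() == 1 || all(diff(.data$gen_pos) >= 0)) |>
    pull(.data$ok)
  if (!all(bad)) stop_validation("genetic map must be monotone within chromosomes")
  set.seed(child_seed(seed, "ril"))
  chroms <- unique(map$chrom)
  blocks <- lapply(chroms, function(cc) {
    d <- map$gen_pos[map$chrom == cc]
    m <- length(d)
    r <- (1 - exp(-2 * diff(d) / 100)) / 2
    R <- 2 * r / (1 + 2 * r)
    first <- rbinom(n_lines, 1, 0.5)
    if (m == 1) return(matrix(first, ncol = 1))
    sw <- matrix(rbinom(n_lines * (m - 1), 1, rep(R, each = n_lines)),
                 nrow = n_lines)
    t(apply(cbind(first, sw), 1, cumsum)) %% 2
  })
  calls <- do.call(cbind, blocks)
  storage.mode(calls) <- "double"
  rownames(calls) <- sprintf("line_%03d", seq_len(n_lines))
  colnames(calls) <- map$marker_id
  genotype_matrix(calls, map, coding = "ril")
}

#' Simulate a structured association panel
#'
#' Balding-Nichols-style model: per marker an ancestral allele frequency is
#' drawn uniformly in `[0.05, 0.95]`; each subpopulation perturbs it with a
#' Beta draw whose concentration is set by the divergence parameter (an
#' Fst-like quantity); diploid dosages `{0,1,2}` are then binomial draws.
#' `fst_like_divergence = 0` collapses to a panmictic panel.
#'
#' @param map Marker map.
#' @param n_accessions Panel size.
#' @param n_subpops Number of subpopulations (accessions split evenly).
#' @param fst_like_divergence Divergence in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `genotype_matrix` with GWAS (dosage) coding; the subpopulation
#'   assignment is attached as attribute `subpop`.
#' @export
simulate_gwas_population <- function(map, n_accessions = 349, n_subpops = 3,
                                     fst_like_divergence = 0.1, seed = 1) {
  if (n_subpops < 1) stop_validation("n_subpops must be >= 1")
  Fd <- fst_like_divergence
  if (!is.numeric(Fd) || length(Fd) != 1 || is.na(Fd) || Fd < 0 || Fd >= 1) {
    stop_validation("fst_like_divergence must lie in [0, 1)")
  }
  validate_marker_map(map)
  set.seed(child_seed(seed, "gwas"))
  m <- nrow(map)
  p_anc <- runif(m, 0.05, 0.95)
  subpop <- sort(rep_len(seq_len(n_subpops), n_accessions))
  calls <- matrix(NA_real_, n_accessions, m)
  for (k in seq_len(n_subpops)) {
    pk <- if (Fd > 0) {
      pmin(pmax(rbeta(m, p_anc * (1 - Fd) / Fd, (1 - p_anc) * (1 - Fd) / Fd),
                1e-3), 1 - 1e-3)
    } else p_anc
    idx <- which(subpop == k)
    calls[idx, ] <- matrix(rbinom(length(idx) * m, 2, rep(pk, each = length(idx))),
                           nrow = length(idx))
  }
  rownames(calls) <- sprintf("acc_%03d", seq_len(n_accessions))
  colnames(calls) <- map$marker_id
  geno <- genotype_matrix(calls, map, coding = "gwas")
  attr(geno, "subpop") <- subpop
  geno
}

#' Simulate metabolite traits with controlled heritability
#'
#' Each causal trait is `a * g + e` where `g` is the genotype at the marker
#' nearest the stated causal position, `e` is standard Gaussian noise, and
#' the effect `a` is scaled against the realized genotype variance so that
#' `var(a g) / (var(a g) + var(e))` equals the requested heritability.
#' `h2 = 0` yields pure noise, `h2 = 1` the standardized genotype itself.
#'
#' @param geno A `genotype_matrix`.
#' @param causal Tibble with `trait_id`, `chrom`, `pos`, `h2` (one causal
#'   locus per trait).
#' @param n_null_traits Additional pure-noise traits (`null_1`, ...).
#' @param seed Integer seed.
#' @return A list: `traits` (individuals x traits matrix) and `causal_map`
#'   (tibble `trait_id`, `marker_id`, `chrom`, `pos`, `h2`, `effect`).
#' @export
simulate_traits <- function(geno, causal, n_null_traits = 0, seed = 1) {
  set.seed(child_seed(seed, "traits"))
  map <- geno$map
  n <- nrow(geno$calls)
  cols <- list()
  truth <- list()
  if (!is.null(causal) && nrow(causal)) {
    if (any(causal$h2 < 0 | causal$h2 > 1)) {
      stop_validation("heritability h2 must lie in [0, 1]")
    }
    for (i in seq_len(nrow(causal))) {
      on_chr <- which(map$chrom == causal$chrom[i])
      if (!length(on_chr)) {
        stop_validation(sprintf("causal locus for %s: chromosome %s has no markers in the map",
                                causal$trait_id[i], causal$chrom[i]))
      }
      j <- on_chr[which.min(abs(map$pos[on_chr] - causal$pos[i]))]
      g <- geno$calls[, j]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      sg <- sd(g)
      if (sg == 0) {
        stop_validation(sprintf("causal marker %s is monomorphic", map$marker_id[j]))
      }
      h2 <- causal$h2[i]
      if (h2 >= 1) {
        a <- 1 / sg
        y <- a * g
      } else if (h2 <= 0) {
        a <- 0
        y <- rnorm(n)
      } else {
        a <- sqrt(h2 / (1 - h2)) / sg
        y <- a * g + rnorm(n)
      }
      cols[[causal$trait_id[i]]] <- y
      truth[[i]] <- tibble(trait_id = causal$trait_id[i],
                           marker_id = map$marker_id[j],
                           chrom = map$chrom[j], pos = map$pos[j],
                           h2 = h2, effect = a)
    }
  }
  if (n_null_traits > 0) {
    for (k in seq_len(n_null_traits)) {
      cols[[paste0("null_", k)]] <- rnorm(n)
    }
  }
  if (!length(cols)) stop_validation("no traits requested")
  traits <- do.call(cbind, cols)
  rownames(traits) <- rownames(geno$calls)
  list(traits = traits,
       causal_map = if (length(truth)) bind_rows(truth) else
         tibble(trait_id = character(), marker_id = character(),
                chrom = character(), pos = integer(), h2 = double(),
                effect = double()))
}

#' Simulate mass-decorated metabolite feature metadata
#'
#' Traits inside a family form a biotransformation chain: the first member
#' gets a base mass, and each subsequent member adds the monoisotopic delta
#' of a decoration drawn from the table, so mass-difference networking
#' ([massdiff_edges()]) can reconnect the family.  Remaining traits get
#' unrelated random masses.  A configurable fraction of features carry
#' annotations; the rest are unknowns.
#'
#' @param families List of character vectors, each an ordered chain of trait
#'   ids (e.g. the traits of one causal cluster).
#' @param extra_traits Trait ids outside any family.
#' @param base_masses Optional numeric base masses (Da), one per family;
#'   drawn uniformly in `[150, 500]` when `NULL`.
#' @param deltas Biotransformation table (`name`, `delta_da`), default
#'   [default_biotransformations()].
#' @param annotation_fraction Fraction of features annotated (in `[0, 1]`).
#' @param annotation_classes Compound classes sampled for annotated features.
#' @param seed Integer seed.
#' @return A list: `features` (tibble as in [read_feature_table()]) and
#'   `decorations` (tibble `from`, `to`, `transformation`).
#' @export
simulate_feature_metadata <- function(families = list(), extra_traits = character(),
                                      base_masses = NULL,
                                      deltas = default_biotransformations(),
                                      annotation_fraction = 0,
                                      annotation_classes = c("lignan", "flavonoid",
                                                             "terpene"),
                                      seed = 1) {
  if (!nrow(deltas)) stop_validation("biotransformation table must be non-empty")
  if (annotation_fraction < 0 || annotation_fraction > 1) {
    stop_validation("annotation_fraction must lie in [0, 1]")
  }
  set.seed(child_seed(seed, "features"))
  rows <- list()
  deco <- list()
  for (fi in seq_along(families)) {
    chain <- families[[fi]]
    base <- if (!is.null(base_masses)) base_masses[fi] else runif(1, 150, 500)
    mz <- base
    for (k in seq_along(chain)) {
      rows[[chain[k]]] <- tibble(trait_id = chain[k], mz = mz,
                                 rt = runif(1, 1, 20))
      if (k < length(chain)) {
        step <- deltas[sample(nrow(deltas), 1), ]
        deco[[length(deco) + 1L]] <- tibble(from = chain[k], to = chain[k + 1],
                                            transformation = step$name)
        mz <- mz + step$delta_da
      }
    }
  }
  for (tr in extra_traits) {
    rows[[tr]] <- tibble(trait_id = tr, mz = runif(1, 150, 800),
                         rt = runif(1, 1, 20))
  }
  features <- bind_rows(rows)
  nfeat <- nrow(features)
  n_annot <- floor(annotation_fraction * nfeat)
  ann_idx <- if (n_annot > 0) sample(nfeat, n_annot) else integer(0)
  features$annotation <- NA_character_
  features$compound_class <- NA_character_
  if (length(ann_idx)) {
    features$annotation[ann_idx] <- paste0("compound_", features$trait_id[ann_idx])
    features$compound_class[ann_idx] <- sample(annotation_classes,
                                               length(ann_idx), replace = TRUE)
  }
  features$annotated <- !is.na(features$annotation)
  list(features = features,
       decorations = if (length(deco)) bind_rows(deco) else
         tibble(from = character(), to = character(),
                transformation = character()))
}

#' Simulate an expression matrix with coexpressed cluster genes
#'
#' Genes of each planted cluster share a latent per-sample profile plus
#' independent noise, scaled so that the expected pairwise Pearson
#' correlation within a cluster equals `within_cluster_r`
#' (`x = sqrt(r) z + sqrt(1 - r) e`).  Background genes are independent
#' standard normal.
#'
#' @param genes Annotation tibble (all gene ids appear as rows).
#' @param cluster_gene_ids List of character vectors, one per cluster.
#' @param n_samples Number of samples.
#' @param within_cluster_r Target within-cluster correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return Genes x samples numeric matrix with dimnames.
#' @export
simulate_expression <- function(genes, cluster_gene_ids = list(),
                                n_samples = 50, within_cluster_r = 0.8,
                                seed = 1) {
  r <- within_cluster_r
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r >= 1) {
    stop_validation("within_cluster_r must lie in [0, 1)")
  }
  set.seed(child_seed(seed, "expression"))
  expr <- matrix(rnorm(nrow(genes) * n_samples), nrow(genes), n_samples)
  rownames(expr) <- genes$gene_id
  colnames(expr) <- sprintf("sample_%03d", seq_len(n_samples))
  for (ids in cluster_gene_ids) {
    ids <- intersect(ids, rownames(expr))
    if (!length(ids)) next
    z <- rnorm(n_samples)
    for (g in ids) {
      expr[g, ] <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_samples)
    }
  }
  expr
}

#' Simulate a complete genetical-metabolomics study
#'
#' Chains all generators into one coherent study: a genome with planted
#' clusters (the first `n_causal_bgcs` of which are causal), a mapping
#' population, metabolite traits whose causal loci sit at the causal
#' clusters' midpoints, a mass-decorated feature table whose causal traits
#' form one biotransformation family per causal cluster, and an expression
#' matrix in which all planted-cluster genes are coexpressed.  The returned
#' `truth` element records everything a recovery test needs.
#'
#' @param seed Integer seed driving all stages.
#' @param population `"ril"` or `"gwas"`.
#' @param n_chrom,genes_per_chrom,markers_per_chrom,chrom_length,genetic_length_cm
#'   Genome and map layout.
#' @param n_planted_bgcs Planted clusters (causal first, remainder decoys).
#' @param n_causal_bgcs How many planted clusters drive traits.
#' @param cluster_size Genes per planted cluster.
#' @param n_causal_traits Decoration-family size per causal cluster.
#' @param n_null_traits Pure-noise traits.
#' @param h2 Heritability of each causal trait.
#' @param n_lines,n_accessions,n_subpops,fst_like_divergence Population
#'   parameters for the chosen design.
#' @param n_samples,within_cluster_r Expression-matrix parameters.
#' @param annotation_fraction Fraction of features annotated.
#' @return A list: `genes`, `map`, `geno`, `traits`, `features`,
#'   `decorations`, `expr`, `truth`, `params`.
#' @export
simulate_study <- function(seed = 1, population = c("ril", "gwas"),
                           n_chrom = 5, genes_per_chrom = 50,
                           markers_per_chrom = 50, chrom_length = 5e6,
                           genetic_length_cm = 100,
                           n_planted_bgcs = 6, n_causal_bgcs = 1,
                           cluster_size = 4, n_causal_traits = 3,
                           n_null_traits = 5, h2 = 0.3,
                           n_lines = 200, n_accessions = 349, n_subpops = 3,
                           fst_like_divergence = 0.1,
                           n_samples = 50, within_cluster_r = 0.8,
                           annotation_fraction = 0) {
  population <- match.arg(population)
  if (n_causal_bgcs > n_planted_bgcs) {
    stop_validation("n_causal_bgcs cannot exceed n_planted_bgcs")
  }
  map <- simulate_marker_map(n_chrom, markers_per_chrom, chrom_length,
                             genetic_length_cm)
  genome <- simulate_genome(n_chrom, genes_per_chrom, n_planted_bgcs,
                            cluster_size, seed = seed,
                            chrom_length = chrom_length)
  geno <- if (population == "ril") {
    simulate_ril_population(map, n_lines = n_lines, seed = seed)
  } else {
    simulate_gwas_population(map, n_accessions = n_accessions,
                             n_subpops = n_subpops,
                             fst_like_divergence = fst_like_divergence,
                             seed = seed)
  }
  planted <- genome$planted
  planted$causal <- seq_len(nrow(planted)) <= n_causal_bgcs
  causal <- NULL
  families <- list()
  if (n_causal_bgcs > 0 && n_causal_traits > 0) {
    causal_rows <- list()
    for (b in seq_len(n_causal_bgcs)) {
      mid <- floor((planted$start[b] + planted$end[b]) / 2)
      ids <- sprintf("%s_trait_%d", planted$bgc_id[b], seq_len(n_causal_traits))
      families[[b]] <- ids
      causal_rows[[b]] <- tibble(trait_id = ids, chrom = planted$chrom[b],
                                 pos = mid, h2 = h2)
    }
    causal <- bind_rows(causal_rows)
  }
  tr <- simulate_traits(geno, causal, n_null_traits = n_null_traits, seed = seed)
  fm <- simulate_feature_metadata(
    families = families,
    extra_traits = setdiff(colnames(tr$traits), unlist(families)),
    annotation_fraction = annotation_fraction, seed = seed
  )
  expr <- simulate_expression(genome$genes, planted$gene_ids,
                              n_samples = n_samples,
                              within_cluster_r = within_cluster_r, seed = seed)
  list(
    genes = genome$genes, map = map, geno = geno, traits = tr$traits,
    features = fm$features, decorations = fm$decorations, expr = expr,
    truth = list(planted = planted, causal_map = tr$causal_map,
                 decorations = fm$decorations),
    params = list(seed = seed, population = population, h2 = h2,
                  n_planted_bgcs = n_planted_bgcs,
                  n_causal_bgcs = n_causal_bgcs,
                  n_causal_traits = n_causal_traits,
                  n_null_traits = n_null_traits,
                  within_cluster_r = within_cluster_r,
                  annotation_fraction = annotation_fraction)
  )
}
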