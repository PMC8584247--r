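## small fixtures shared across the integration tests
fake_de <- function(mirnas, log2fc, p = rep(0.001, length(mirnas))) {
  data.frame(mirna = mirnas, log2fc = log2fc, t = 1, p = p,
             q = p, significant = TRUE, stringsAsFactors = FALSE)
}

fake_loci <- function(mirnas, chrom, start) {
  data.frame(feature_id = mirnas, feature_type = "miRNA", chrom = chrom,
             start = start, end = start + 80, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("mapping honors the frequency threshold and the region intervals", {
  regions <- data.frame(label = "1q21.1-q44", chrom = "chr1", start = 45e6,
                        end = 100e6, direction = "gain",
                        stringsAsFactors = FALSE)
  freq <- data.frame(label = "1q21.1-q44", direction = "gain",
                     group = c("QNBC", "TNBC"), n_affected = c(12, 5),
                     n_samples = c(19, 14), frequency = c(63.2, 35.7),
                     stringsAsFactors = FALSE)
  de <- fake_de("miR-up", 1.2)
  loci <- fake_loci("miR-up", "chr1", 50e6)
  rec <- map_de_mirnas_to_cna_cytobands(de, loci, freq, regions,
                                        group = "QNBC",
                                        min_frequency = 0.30)
  expect_equal(nrow(rec), 1L)
  expect_true(rec$concordant)
  ## same miRNA with a 70% threshold is excluded
  rec2 <- map_de_mirnas_to_cna_cytobands(de, loci, freq, regions,
                                         group = "QNBC",
                                         min_frequency = 0.70)
  expect_equal(nrow(rec2), 0L)
  ## a significant miRNA without a locus is excluded with a warning
  de2 <- fake_de(c("miR-up", "miR-nowhere"), c(1.2, 1))
  expect_warning(
    rec3 <- map_de_mirnas_to_cna_cytobands(de2, loci, freq, regions,
                                           group = "QNBC",
                                           min_frequency = 0.30),
    "no locus")
  expect_equal(attr(rec3, "n_unmapped"), 1L)
})

test_that("mapping equals a brute-force cross-join filter on random cohorts", {
  set.seed(21)
  for (rep_i in 1:10) {
    n_r <- sample(3:6, 1)
    regions <- data.frame(
      label = sprintf("R%d", seq_len(n_r)),
      chrom = sample(c("chr1", "chr2"), n_r, TRUE),
      start = s <- sample.int(50e6, n_r),
      end = s + sample.int(30e6, n_r),
      direction = sample(c("gain", "loss"), n_r, TRUE),
      stringsAsFactors = FALSE
    )
    freq <- data.frame(label = regions$label, direction = regions$direction,
                       group = "QNBC", n_affected = 0, n_samples = 19,
                       frequency = round(runif(n_r, 0, 100), 1),
                       stringsAsFactors = FALSE)
    n_m <- sample(4:8, 1)
    de <- fake_de(sprintf("m%d", seq_len(n_m)), runif(n_m, -2, 2))
    loci <- fake_loci(de$mirna, sample(c("chr1", "chr2"), n_m, TRUE),
                      sample.int(80e6, n_m))
    rec <- map_de_mirnas_to_cna_cytobands(de, loci, freq, regions,
                                          group = "QNBC",
                                          min_frequency = 0.30)
    ## brute force: every (miRNA, region) combination checked directly
    expected <- 0L
    for (i in seq_len(n_m)) for (k in seq_len(n_r)) {
      ok <- freq$frequency[k] >= 30 &&
        loci$chrom[i] == regions$chrom[k] &&
        loci$start[i] < regions$end[k] && loci$end[i] > regions$start[k]
      if (ok) {
        expected <- expected + 1L
        row <- rec[rec$mirna == de$mirna[i] & rec$label == regions$label[k], ]
        expect_equal(nrow(row), 1L)
        expect_equal(row$concordant,
                     (regions$direction[k] == "gain" && de$log2fc[i] > 0) ||
                       (regions$direction[k] == "loss" && de$log2fc[i] < 0))
      }
    }
    expect_equal(nrow(rec), expected)
  }
})

test_that("concordance keeps matching directions and drops zero fold changes", {
  rec <- data.frame(
    mirna = c("a", "b", "c", "d"),
    label = "R", direction = c("gain", "gain", "loss", "gain"),
    frequency = 50, log2fc = c(1.2, -1.2, -0.5, 0), p = 0.01,
    stringsAsFactors = FALSE
  )
  rec$concordant <- (rec$direction == "gain" & rec$log2fc > 0) |
    (rec$direction == "loss" & rec$log2fc < 0)
  kept <- concordance_filter(rec)
  expect_setequal(kept$mirna, c("a", "c"))
})

test_that("consensus equals the union of pairwise intersections", {
  set.seed(31)
  for (rep_i in 1:10) {
    mk <- function() {
      data.frame(mirna = sample(sprintf("m%d", 1:4), 30, TRUE),
                 gene = sample(sprintf("G%02d", 1:25), 30, TRUE),
                 stringsAsFactors = FALSE)
    }
    t1 <- unique(mk()); t2 <- unique(mk()); t3 <- unique(mk())
    cons <- consensus_targets(list(t1, t2, t3), min_db = 2)
    key <- function(t) paste(t$mirna, t$gene)
    oracle <- union(union(intersect(key(t1), key(t2)),
                          intersect(key(t1), key(t3))),
                    intersect(key(t2), key(t3)))
    expect_setequal(paste(cons$mirna, cons$gene), oracle)
  }
  ## pair in 2 of 3 kept, pair in 1 dropped
  a <- data.frame(mirna = "m", gene = c("X", "Y"))
  b <- data.frame(mirna = "m", gene = "X")
  c3 <- data.frame(mirna = "m", gene = "Z")
  cons <- consensus_targets(list(a, b, c3))
  expect_equal(cons$gene, "X")
  ## duplicate rows in a single table warn on read
  path <- tempfile()
  utils::write.table(data.frame(mirna = c("m", "m"), gene = c("X", "X")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tt <- read_target_table(path), "duplicate")
  expect_equal(nrow(tt), 1L)
})

test_that("target intersection reports the reduction percentage", {
  cons <- data.frame(mirna = "m", gene = sprintf("G%04d", 1:4050),
                     n_db = 2, stringsAsFactors = FALSE)
  res <- intersect_targets_with_cna_genes(cons, sprintf("G%04d", 1:1239))
  expect_equal(res$n_before, 4050L)
  expect_equal(res$n_after, 1239L)
  expect_equal(round(res$reduction_pct, 1), 69.4)

  disjoint <- intersect_targets_with_cna_genes(cons, "ZZZ")
  expect_equal(disjoint$n_after, 0L)
  expect_equal(disjoint$reduction_pct, 100)

  empty <- intersect_targets_with_cna_genes(cons[0, ], "G0001")
  expect_true(is.na(empty$reduction_pct))

  ## random sets equal a brute-force membership scan
  set.seed(41)
  for (rep_i in 1:5) {
    genes <- sprintf("G%03d", sample(300, 80))
    cons2 <- data.frame(mirna = "m", gene = genes, n_db = 2)
    cna <- sprintf("G%03d", sample(300, 120))
    res2 <- intersect_targets_with_cna_genes(cons2, cna)
    expect_setequal(res2$genes, unique(genes[genes %in% cna]))
  }
})

test_that("hypergeometric overlap matches explicit combinatorics on a small universe", {
  universe <- sprintf("U%02d", 1:20)
  set.seed(51)
  sets <- list(S1 = sample(universe, 6), S2 = sample(universe, 10),
               S3 = sample(universe, 4))
  gene_list <- sample(universe, 7)
  res <- gene_set_overlap(gene_list, sets, universe)
  for (k in seq_len(nrow(res))) {
    K <- res$set_size[k]; kk <- res$overlap[k]
    expect_equal(res$p[k], oracle_hyper_upper(kk, K, 20, 7),
                 tolerance = 1e-12)
  }
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)

  ## empty overlap: upper tail at k = 0 is 1
  res0 <- gene_set_overlap(universe[1:3], list(S = universe[10:12]), universe)
  expect_equal(res0$p, 1)

  ## the fully recovered set has the smallest p among equal-size sets
  sets2 <- list(hit = universe[1:5], miss = universe[10:14])
  res2 <- gene_set_overlap(universe[1:5], sets2, universe)
  expect_lt(res2$p[res2$set == "hit"], res2$p[res2$set == "miss"])

  expect_error(gene_set_overlap(c("U01", "XX"), sets, universe), "universe")
  expect_warning(gene_set_overlap(gene_list,
                                  list(S = c(universe[1:3], "OUT")),
                                  universe), "outside universe")
})

test_that("PPI filtering drops weak edges and isolated nodes", {
  edges <- data.frame(node_a = c("A", "B", "C", "D", "E"),
                      node_b = c("B", "C", "A", "E", "F"),
                      score = c(0.95, 0.92, 0.91, 0.85, 0.40),
                      stringsAsFactors = FALSE)
  g <- filter_ppi_edges(edges, min_score = 0.9)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 3L)

  expect_error(filter_ppi_edges(data.frame(node_a = "A", node_b = "B",
                                           score = "high")),
               "malformed")

  ## miRNA edges attach only to surviving genes
  g2 <- filter_ppi_edges(edges, min_score = 0.9,
                         mirna_edges = data.frame(mirna = c("miR-1", "miR-1"),
                                                  gene = c("A", "F")))
  expect_true("miR-1" %in% igraph::V(g2)$name)
  expect_false("F" %in% igraph::V(g2)$name)
  expect_setequal(unique(igraph::E(g2)$type), c("ppi", "mirna_target"))

  ## random graphs: surviving nodes equal a brute-force degree filter
  set.seed(61)
  for (rep_i in 1:8) {
    e <- data.frame(node_a = sample(LETTERS[1:12], 25, TRUE),
                    node_b = sample(LETTERS[1:12], 25, TRUE),
                    score = round(runif(25), 2), stringsAsFactors = FALSE)
    g3 <- filter_ppi_edges(e, min_score = 0.7)
    keep <- e[e$score >= 0.7 & e$node_a != e$node_b, ]
    expect_setequal(igraph::V(g3)$name, unique(c(keep$node_a, keep$node_b)))
  }
})

test_that("per-sample alteration counts follow the k-SD reference rule", {
  mat <- matrix(0, 8, 10,
                dimnames = list(sprintf("m%d", 1:8), sprintf("s%02d", 1:10)))
  set.seed(71)
  mat[] <- rnorm(80, 5, 1)
  groups <- setNames(rep(c("QNBC", "TNBC"), each = 5), colnames(mat))
  conc <- data.frame(mirna = rownames(mat), log2fc = rep(c(1, -1), 4),
                     stringsAsFactors = FALSE)
  ## a sample pinned exactly at the reference means counts zero
  ref_mean <- rowMeans(mat[, groups == "TNBC"])
  mat[, "s01"] <- ref_mean
  res <- per_sample_alteration_count(mat, conc, groups, "TNBC")
  expect_equal(res$per_sample$n_altered[res$per_sample$sample_id == "s01"], 0)
  ## a sample shifted +10 reference SDs on every upregulated miRNA
  up <- conc$mirna[conc$log2fc > 0]
  ref_sd <- apply(mat[, groups == "TNBC"], 1, sd)
  mat[, "s02"] <- ref_mean
  mat[up, "s02"] <- ref_mean[up] + 10 * ref_sd[up]
  res2 <- per_sample_alteration_count(mat, conc, groups, "TNBC")
  expect_equal(res2$per_sample$n_altered[res2$per_sample$sample_id == "s02"],
               length(up))
  ## zero-SD reference miRNAs are skipped with a warning
  mat2 <- mat; mat2["m1", groups == "TNBC"] <- 3
  expect_warning(res3 <- per_sample_alteration_count(mat2, conc, groups,
                                                     "TNBC"), "skipped")
  expect_equal(res3$skipped, "m1")
})

test_that("effect-carrying groups show higher alteration counts across seeds", {
  diffs <- numeric(5)
  for (seed in 1:5) {
    set.seed(seed)
    groups <- setNames(rep(c("QNBC", "TNBC"), c(12, 12)),
                       sprintf("s%02d", 1:24))
    mat <- matrix(rnorm(8 * 24, 6, 0.5), 8, 24,
                  dimnames = list(sprintf("m%d", 1:8), names(groups)))
    fc <- rep(c(1.5, -1.5), 4)
    mat[, groups == "QNBC"] <- mat[, groups == "QNBC"] + fc
    conc <- data.frame(mirna = rownames(mat), log2fc = fc)
    res <- per_sample_alteration_count(mat, conc, groups, "TNBC")
    gs <- res$group_stats
    diffs[seed] <- gs$mean[gs$group == "QNBC"] - gs$mean[gs$group == "TNBC"]
  }
  expect_true(all(diffs > 0))
})

test_that("raising thresholds never enlarges the mapped or consensus sets", {
  set.seed(81)
  regions <- data.frame(label = c("Ra", "Rb"), chrom = "chr1",
                        start = c(0, 50e6), end = c(40e6, 90e6),
                        direction = c("gain", "loss"),
                        stringsAsFactors = FALSE)
  freq <- data.frame(label = c("Ra", "Rb"), direction = c("gain", "loss"),
                     group = "QNBC", n_affected = c(8, 6), n_samples = 19,
                     frequency = c(42.1, 31.6), stringsAsFactors = FALSE)
  de <- fake_de(sprintf("m%d", 1:6), runif(6, -2, 2))
  loci <- fake_loci(de$mirna, "chr1", seq(5e6, 85e6, length.out = 6))
  sizes <- vapply(c(0.25, 0.32, 0.45), function(f) {
    nrow(map_de_mirnas_to_cna_cytobands(de, loci, freq, regions,
                                        group = "QNBC", min_frequency = f))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  t1 <- data.frame(mirna = "m", gene = sprintf("G%d", 1:10))
  t2 <- data.frame(mirna = "m", gene = sprintf("G%d", 4:12))
  t3 <- data.frame(mirna = "m", gene = sprintf("G%d", 7:15))
  n2 <- nrow(consensus_targets(list(t1, t2, t3), min_db = 2))
  n3 <- nrow(consensus_targets(list(t1, t2, t3), min_db = 3))
  expect_lte(n3, n2)
})
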