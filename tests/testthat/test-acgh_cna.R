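test_that("probe reader sorts and rejects non-finite ratios", {
  path <- tempfile(fileext = ".tsv")
  tab <- make_probes(c(0.1, -0.2, 0.3, 0))[c(3, 1, 4, 2), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- read_probe_table(path)
  expect_equal(rd$probe_id, sprintf("P%04d", 1:4))
  expect_true(!is.unsorted(rd$start))

  bad <- tab
  bad$log2_ratio[2] <- "NaN"
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_probe_table(path), "non-finite")
})

test_that("caller honors the probe-count and amplitude filters", {
  set.seed(1)
  ## flat zero profile: no aberration
  expect_equal(nrow(call_aberrations(make_probes(rep(0, 50)))), 0L)

  ## two consecutive probes at +1.0 in noiseless background: blocked by the
  ## three-probe minimum
  x <- rep(0, 50); x[20:21] <- 1
  expect_equal(nrow(call_aberrations(make_probes(x))), 0L)
  ## ...but three probes are enough
  x[22] <- 1
  calls <- call_aberrations(make_probes(x))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_probes, 3L)
  expect_equal(calls$direction, "gain")

  ## high-score segment whose mean is below the 0.25 amplitude floor
  set.seed(2)
  y <- rnorm(100, 0, 0.05); y[40:49] <- y[40:49] - mean(y[40:49]) + 0.20
  out <- call_aberrations(make_probes(y))
  expect_false(any(out$start < 49e5 & out$end > 39e5))
  expect_true(all(abs(out$mean_log2) > 0.25))
})

test_that("caller matches the exhaustive interval-score oracle", {
  set.seed(42)
  for (rep_i in 1:12) {
    n <- sample(50:200, 1)
    x <- rnorm(n, 0, 0.1)
    ## plant 1-2 segments
    for (s in seq_len(sample(1:2, 1))) {
      w <- sample(5:25, 1)
      i <- sample(n - w, 1)
      x[i:(i + w)] <- x[i:(i + w)] + sample(c(-1, 1), 1) * runif(1, 0.5, 1)
    }
    calls <- call_aberrations(make_probes(x))
    oracle <- oracle_call_aberrations(x)
    if (is.null(oracle)) {
      expect_equal(nrow(calls), 0L)
    } else {
      expect_equal(nrow(calls), nrow(oracle))
      expect_equal(calls$start, (oracle$i - 1) * 1e5)
      expect_equal(calls$n_probes, as.integer(oracle$w))
      expect_equal(calls$mean_log2, oracle$mu, tolerance = 1e-12)
    }
  }
})

test_that("calls never overlap, satisfy all filters, and shrink with threshold", {
  set.seed(7)
  params6 <- caller_params(score_threshold = 6)
  params10 <- caller_params(score_threshold = 10)
  for (rep_i in 1:8) {
    x <- rnorm(150, 0, 0.1)
    w <- sample(8:30, 1); i <- sample(100, 1)
    x[i:(i + w)] <- x[i:(i + w)] + runif(1, 0.4, 0.9)
    calls <- call_aberrations(make_probes(x), params6)
    if (nrow(calls) > 1) {
      o <- order(calls$start)
      expect_true(all(calls$start[o][-1] >= calls$end[o][-nrow(calls)]))
    }
    expect_true(all(calls$n_probes >= 3))
    expect_true(all(abs(calls$mean_log2) > 0.25))
    expect_true(all(calls$score >= 6))
    expect_true(all(calls$direction == ifelse(calls$mean_log2 > 0,
                                              "gain", "loss")))
    ## monotonicity in the score threshold
    expect_lte(nrow(call_aberrations(make_probes(x), params10)), nrow(calls))
  }
})

test_that("chromosomes with fewer than 4 probes are skipped with a warning", {
  p <- make_probes(c(1, 1, 1), chrom = "chr21")
  expect_warning(out <- call_aberrations(p), "fewer than 4")
  expect_equal(nrow(out), 0L)
})

test_that("call summaries report group means and a Student t-test", {
  ## counts 10 and 14 in group A; 3 and 5 in group B
  calls <- data.frame(
    sample_id = c(rep("a1", 10), rep("a2", 14), rep("b1", 3), rep("b2", 5)),
    chrom = "chr1", start = 0, end = 1, n_probes = 3L, mean_log2 = 0.5,
    direction = "gain", score = 10, stringsAsFactors = FALSE
  )
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  s <- summarize_calls(calls, groups)
  expect_equal(s$group_stats$mean, c(12, 4))
  expect_equal(s$group_stats$total_calls, c(24, 8))
  expect_equal(s$t_test$p.value,
               t.test(c(10, 14), c(3, 5), var.equal = TRUE)$p.value)

  ## identical count vectors in both groups -> p = 1
  counts2 <- c(a1 = 10, a2 = 3, b1 = 10, b2 = 3)
  calls2 <- data.frame(
    sample_id = rep(names(counts2), counts2), chrom = "chr1", start = 0,
    end = 1, n_probes = 3L, mean_log2 = 0.5, direction = "gain", score = 10,
    stringsAsFactors = FALSE
  )
  s2 <- summarize_calls(calls2, groups)
  expect_equal(s2$t_test$p.value, 1, tolerance = 1e-12)

  expect_error(summarize_calls(calls, c(a1 = "A", a2 = "A", b1 = "B")),
               "2 samples")
})

test_that("cytoband frequencies match a brute-force per-sample overlap count", {
  cb <- toy_cytoband_table()
  set.seed(9)
  samples <- sprintf("s%02d", 1:12)
  groups <- setNames(rep(c("QNBC", "TNBC"), each = 6), samples)
  calls <- do.call(rbind, lapply(samples, function(s) {
    n <- sample(0:4, 1)
    if (n == 0) return(NULL)
    start <- sample.int(80e6, n)
    data.frame(sample_id = s, chrom = sample(c("chr4", "chr8"), n, TRUE),
               start = start, end = start + sample.int(20e6, n),
               n_probes = 5L, mean_log2 = 0.5,
               direction = sample(c("gain", "loss"), n, TRUE), score = 10,
               stringsAsFactors = FALSE)
  }))
  regions <- derive_cna_regions(calls, cb)
  freq <- cytoband_frequency(calls, regions, groups)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 100))
  expect_true(all(freq$n_affected <= freq$n_samples))
  for (k in seq_len(nrow(freq))) {
    r <- regions[regions$label == freq$label[k] &
                   regions$direction == freq$direction[k], ]
    hits <- 0
    for (s in samples[groups == freq$group[k]]) {
      cc <- calls[calls$sample_id == s, ]
      ov <- any(cc$direction == r$direction & cc$chrom == r$chrom &
                  cc$start < r$end & cc$end > r$start)
      hits <- hits + ov
    }
    expect_equal(freq$n_affected[k], hits)
  }
  ## no calls at all -> frequency 0 everywhere
  none <- cytoband_frequency(calls[0, ], regions, groups)
  expect_true(all(none$frequency == 0))
})

test_that("gene-level copy number follows the mean-probe and interval conventions", {
  probes <- make_probes(c(rep(0, 5), rep(0.6, 5), rep(0, 5)), chrom = "chr4")
  loci <- data.frame(feature_id = c("G1", "G2"), feature_type = "protein_coding",
                     chrom = "chr4", start = c(5e5, 13e5), end = c(9.5e5, 14e5),
                     strand = "+", stringsAsFactors = FALSE)
  mp <- gene_copy_number(probes_by_sample = list(s1 = probes),
                         gene_loci = loci, mode = "mean_probe")
  expect_equal(unname(mp["G1", "s1"]), 0.6)  # five probes all at 0.6
  loci2 <- rbind(loci, data.frame(feature_id = "G3",
                                  feature_type = "protein_coding",
                                  chrom = "chr7", start = 0, end = 100,
                                  strand = "+"))
  mp2 <- gene_copy_number(probes_by_sample = list(s1 = probes),
                          gene_loci = loci2, mode = "mean_probe")
  expect_true(is.na(mp2["G3", "s1"]))  # no probe coverage -> missing

  calls <- data.frame(sample_id = "s1", chrom = "chr4", start = 5e5,
                      end = 9.6e5, n_probes = 5L, mean_log2 = 0.6,
                      direction = "gain", score = 12, stringsAsFactors = FALSE)
  iv <- gene_copy_number(calls = calls, gene_loci = loci, mode = "interval",
                         samples = "s1")
  expect_equal(unname(iv["G1", "s1"]), 0.6)
  expect_equal(unname(iv["G2", "s1"]), 0)  # outside all calls -> neutral
})

test_that("per-gene group comparison matches the pooled-variance closed form", {
  x <- c(0.61, 0.55, 0.72, 0.66)   # group A
  y <- c(0.02, -0.05, 0.10)        # group B
  cn <- matrix(c(x, y), nrow = 1,
               dimnames = list("G1", sprintf("s%d", 1:7)))
  groups <- setNames(rep(c("A", "B"), c(4, 3)), colnames(cn))
  res <- compare_group_gene_cn(cn, groups)
  sp2 <- ((4 - 1) * var(x) + (3 - 1) * var(y)) / (4 + 3 - 2)
  t_closed <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(res$t, t_closed, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_closed), df = 5), tolerance = 1e-12)

  ## identical distributions -> p ~ 1
  cn2 <- matrix(rep(c(0.1, 0.2, 0.3), 2), nrow = 1,
                dimnames = list("G1", sprintf("s%d", 1:6)))
  res2 <- compare_group_gene_cn(cn2, setNames(rep(c("A", "B"), each = 3),
                                              colnames(cn2)))
  expect_equal(res2$p, 1, tolerance = 1e-9)

  ## genes with insufficient data are flagged, not tested
  cn3 <- rbind(cn2, G2 = c(NA, NA, NA, 1, 2, 3))
  res3 <- compare_group_gene_cn(cn3, setNames(rep(c("A", "B"), each = 3),
                                              colnames(cn2)))
  expect_false(res3$tested[res3$gene == "G2"])
})
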