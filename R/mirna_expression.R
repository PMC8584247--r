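#' Read a raw miRNA count matrix
#'
#' First column is the miRNA/probe id, one column per sample, plus a
#' `probe_class` column labelling each row as `endogenous`, `pos_ctrl`,
#' `neg_ctrl`, `housekeeping` or `spike_in`. Separator (comma or tab) is
#' sniffed from the header line.
#'
#' @param path Path to the CSV/TSV count file.
#' @return List of class `raw_counts` with `counts` (numeric matrix, probes x
#'   samples) and `probe_class` (character vector aligned with rows).
#' @export
read_count_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!"probe_class" %in% names(tab)) {
    stop("count matrix must carry a probe_class column")
  }
  ids <- tab[[1]]
  cls <- tab$probe_class
  num <- tab[, setdiff(names(tab), c(names(tab)[1], "probe_class")),
             drop = FALSE]
  counts <- as.matrix(num)
  mode(counts) <- "numeric"
  rownames(counts) <- ids
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  known <- c("endogenous", "pos_ctrl", "neg_ctrl", "housekeeping", "spike_in")
  if (any(!cls %in% known)) {
    stop("unknown probe_class: ", paste(setdiff(cls, known), collapse = ", "))
  }
  if (!any(cls == "neg_ctrl") || !any(cls == "pos_ctrl")) {
    stop("count matrix needs at least one negative and one positive control")
  }
  structure(list(counts = counts, probe_class = cls), class = "raw_counts")
}

#' Write a raw count matrix in the dialect read by [read_count_matrix()]
#' @param raw A `raw_counts` object.
#' @param path Output CSV path.
#' @export
write_count_matrix <- function(raw, path) {
  df <- data.frame(mirna = rownames(raw$counts), raw$counts,
                   probe_class = raw$probe_class, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Geometric mean with values below 1 floored to 1, so that zero counts do
## not annihilate the mean. On all-positive counts this is the plain
## geometric mean, which keeps per-sample scale factors exactly removable.
geo_mean <- function(x) exp(mean(log(pmax(x, 1))))

#' Three-stage geometric-mean normalization of panel counts
#'
#' Per sample, in order: (1) background subtraction — subtract the sample's
#' geometric mean of negative-control counts from every count, flooring at 0;
#' (2) technical normalization — multiply by the grand mean (across samples)
#' of per-sample positive-control geometric means divided by this sample's
#' positive-control geometric mean; (3) codeset content normalization — the
#' same factor construction computed on the endogenous rows of the current
#' (background-subtracted, technically normalized) matrix; (4) log2(x + 1).
#' Geometric means floor their inputs at 1 (see details in the vignette), so
#' a global per-sample scale factor on all rows cancels exactly.
#'
#' @param raw A `raw_counts` object.
#' @return List of class `normalized_matrix` with `log2` (endogenous miRNA x
#'   sample matrix of log2 values) and `audit` (per-sample background level,
#'   positive-control factor, content factor).
#' @export
normalize_counts <- function(raw) {
  stopifnot(inherits(raw, "raw_counts"))
  counts <- raw$counts
  neg <- counts[raw$probe_class == "neg_ctrl", , drop = FALSE]
  pos <- counts[raw$probe_class == "pos_ctrl", , drop = FALSE]
  endo_idx <- raw$probe_class == "endogenous"

  background <- apply(neg, 2, geo_mean)
  work <- sweep(counts, 2, background, `-`)
  work[work < 0] <- 0

  pos_geo <- apply(pos, 2, geo_mean)
  if (any(pos_geo <= 0)) stop("uncorrectable lane: positive-control geometric mean is 0")
  f_pos <- mean(pos_geo) / pos_geo
  work <- sweep(work, 2, f_pos, `*`)

  content_geo <- apply(work[endo_idx, , drop = FALSE], 2, geo_mean)
  f_content <- mean(content_geo) / content_geo
  work <- sweep(work, 2, f_content, `*`)

  log2mat <- log2(work[endo_idx, , drop = FALSE] + 1)
  audit <- data.frame(sample = colnames(counts), background = background,
                      pos_factor = f_pos, content_factor = f_content,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(log2 = log2mat, audit = audit), class = "normalized_matrix")
}

#' Differential expression between two groups of samples
#'
#' Per endogenous miRNA: log2 fold change as mean(case group) minus
#' mean(reference group) of log2 values; two-sided unpaired Student t-test
#' (Welch by flag); Benjamini-Hochberg q-values over all tested miRNAs.
#' A miRNA is flagged significant when `p < p_threshold` and
#' `q < fdr_threshold` (defaults 0.05 and 0.25). miRNAs constant in both
#' groups with equal means get p = 1.
#'
#' @param norm A `normalized_matrix` (or a plain log2 matrix).
#' @param groups Named character vector sample -> group.
#' @param case Group treated as the case (its mean enters with + sign);
#'   defaults to the first group in sorted order.
#' @param p_threshold,fdr_threshold Dual significance thresholds.
#' @param var.equal Student (TRUE, default) or Welch test.
#' @return `data.frame` sorted by p: `mirna`, `log2fc`, `t`, `p`, `q`,
#'   `significant`.
#' @export
differential_expression <- function(norm, groups, case = NULL,
                                    p_threshold = 0.05, fdr_threshold = 0.25,
                                    var.equal = TRUE) {
  mat <- if (inherits(norm, "normalized_matrix")) norm$log2 else norm
  groups <- groups[names(groups) %in% colnames(mat)]
  glev <- sort(unique(unname(groups)))
  stopifnot(length(glev) == 2L)
  if (is.null(case)) case <- glev[1]
  ref <- setdiff(glev, case)
  sc <- names(groups)[groups == case]
  sr <- names(groups)[groups == ref]
  if (length(sc) < 2L || length(sr) < 2L) stop("need >= 2 samples per group")
  res <- lapply(rownames(mat), function(m) {
    x <- mat[m, sc]; y <- mat[m, sr]
    tt <- safe_t_test(x, y, var.equal = var.equal)
    data.frame(mirna = m, log2fc = mean(x) - mean(y), t = tt$statistic,
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < p_threshold & out$q < fdr_threshold
  out <- out[order(out$p, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "case") <- case
  attr(out, "reference") <- ref
  out
}

#' Supervised hierarchical clustering of the significant miRNAs
#'
#' Average-linkage hierarchical clustering with Pearson correlation distance
#' (1 - r) on both axes, restricted to the supplied miRNAs. Constant rows
#' (undefined correlation) are dropped with a warning. Leaf ordering is the
#' deterministic `hclust` order with ties broken by input order.
#'
#' @param norm A `normalized_matrix` or log2 matrix.
#' @param mirnas miRNAs (rows) to cluster on; default all rows.
#' @return List of class `clustering_result`: `sample_hclust`,
#'   `mirna_hclust`, `sample_order`, `mirna_order`, `metric`.
#' @export
supervised_clustering <- function(norm, mirnas = NULL) {
  mat <- if (inherits(norm, "normalized_matrix")) norm$log2 else norm
  if (!is.null(mirnas)) mat <- mat[rownames(mat) %in% mirnas, , drop = FALSE]
  constant <- apply(mat, 1, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant row(s) with undefined correlation")
    mat <- mat[!constant, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("need at least 2 non-constant miRNAs to cluster")
  d_samples <- stats::as.dist(1 - stats::cor(mat))
  d_mirnas <- stats::as.dist(1 - stats::cor(t(mat)))
  hs <- stats::hclust(d_samples, method = "average")
  hm <- stats::hclust(d_mirnas, method = "average")
  structure(list(sample_hclust = hs, mirna_hclust = hm,
                 sample_order = colnames(mat)[hs$order],
                 mirna_order = rownames(mat)[hm$order],
                 metric = "pearson/average"),
            class = "clustering_result")
}
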