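#' Aberration caller parameters
#'
#' Parameters of the interval-score aberration caller. The defaults mirror
#' the conventional Agilent-style analysis settings: interval score threshold
#' 6.0, at least three probes per aberration, and a minimum average absolute
#' log2 ratio of 0.25.
#'
#' @param score_threshold Minimum interval score `S = |mean| * sqrt(n) / sigma`.
#' @param min_probes Minimum number of probes in a reported aberration.
#' @param min_abs_mean_log2 Minimum `|mean log2 ratio|` of a reported
#'   aberration (gains `> +0.25`, losses `< -0.25` at the default).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(score_threshold = 6.0, min_probes = 3L,
                          min_abs_mean_log2 = 0.25) {
  stopifnot(score_threshold > 0, min_probes > 0, min_abs_mean_log2 > 0)
  structure(list(score_threshold = score_threshold,
                 min_probes = as.integer(min_probes),
                 min_abs_mean_log2 = min_abs_mean_log2),
            class = "caller_params")
}

#' Read a probe-level aCGH table
#'
#' Expects a header row and columns `probe_id`, `chrom`, `start`, `end`,
#' `log2_ratio` (tab- or comma-separated, sniffed from the header line).
#' `log2_ratio` is log2(Cy5/Cy3), tumor over reference.
#'
#' @param path Path to the probe table.
#' @return `data.frame` sorted by (chrom, start) with normalized chromosome
#'   names. Non-finite log2 ratios are an error naming the offending line.
#' @export
read_probe_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("probe_id", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(tab))) {
    stop("probe table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  lr <- suppressWarnings(as.numeric(tab$log2_ratio))
  bad <- which(!is.finite(lr))
  if (length(bad)) {
    stop("non-finite log2_ratio at data line ", bad[1], " of ", path)
  }
  tab$log2_ratio <- lr
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  if (anyDuplicated(tab[, c("chrom", "start")])) {
    message("duplicate probe positions in ", basename(path), " (kept)")
  }
  rownames(tab) <- NULL
  tab[, need]
}

## Derivative-MAD noise estimate: MAD of successive probe differences with
## the 1/0.6745 normal-consistency constant, rescaled by sqrt(2) because
## differencing doubles the variance.
derivative_mad_sigma <- function(x) {
  d <- diff(x)
  stats::median(abs(d - stats::median(d))) / (0.6745 * sqrt(2))
}

## All maximal-score candidate intervals on one chromosome: every interval
## with score >= threshold, vectorized over widths via cumulative sums.
score_candidate_intervals <- function(x, sigma, threshold) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  out <- vector("list", n)
  for (w in seq_len(n)) {
    i <- seq_len(n - w + 1L)
    mu <- (cs[i + w] - cs[i]) / w
    sc <- abs(mu) * sqrt(w) / sigma
    keep <- which(sc >= threshold)
    if (length(keep)) {
      out[[w]] <- data.frame(i = i[keep], j = i[keep] + w - 1L,
                             n_probes = w, mean_log2 = mu[keep],
                             score = sc[keep])
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Call copy-number aberrations from probe log2 ratios
#'
#' Interval-score caller. Per chromosome the noise level `sigma` is estimated
#' as the median absolute deviation of successive probe differences divided
#' by `0.6745 * sqrt(2)` (derivative MAD). Every interval `I` whose score
#' `S(I) = |mean(I)| * sqrt(|I|) / sigma` reaches `score_threshold` is a
#' candidate; overlapping candidates are resolved greedily by descending
#' score (ties: leftmost start, then longest interval), and survivors are
#' filtered by `min_probes` and `min_abs_mean_log2`. Aberration direction is
#' the sign of the interval mean.
#'
#' Chromosomes with fewer than 4 probes are skipped with a warning (the
#' derivative-MAD noise estimate is undefined there). A chromosome whose
#' probes are noise-free gets a floor of `1e-8` on `sigma` so that planted
#' constant segments remain callable.
#'
#' @param probes Probe table as returned by [read_probe_table()].
#' @param params A [caller_params()] object.
#' @param sample_id Sample label attached to each call.
#' @return `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `mean_log2`, `direction` (`"gain"`/`"loss"`), `score`.
#'   Calls never overlap within a sample.
#' @export
call_aberrations <- function(probes, params = caller_params(),
                             sample_id = "sample") {
  stopifnot(inherits(params, "caller_params"))
  out <- list()
  for (chr in unique(probes$chrom)) {
    p <- probes[probes$chrom == chr, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) < 4L) {
      warning("chromosome ", chr, " has fewer than 4 probes; skipped")
      next
    }
    sigma <- max(derivative_mad_sigma(p$log2_ratio), 1e-8)
    cand <- score_candidate_intervals(p$log2_ratio, sigma,
                                      params$score_threshold)
    if (is.null(cand) || nrow(cand) == 0L) next
    ## greedy non-overlap resolution: repeatedly accept the best remaining
    ## candidate (score desc, ties leftmost start then longest) and drop
    ## everything overlapping it; survivors are then filtered
    cand <- cand[order(-cand$score, cand$i, -cand$n_probes), , drop = FALSE]
    while (nrow(cand) > 0L) {
      a <- cand[1L, ]
      cand <- cand[cand$j < a$i | cand$i > a$j, , drop = FALSE]
      if (a$n_probes < params$min_probes) next
      if (abs(a$mean_log2) <= params$min_abs_mean_log2) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = chr,
        start = p$start[a$i], end = p$end[a$j],
        n_probes = a$n_probes, mean_log2 = a$mean_log2,
        direction = if (a$mean_log2 > 0) "gain" else "loss",
        score = a$score, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty_callset(sample_id))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_callset <- function(sample_id = character()) {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), n_probes = integer(), mean_log2 = numeric(),
             direction = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

## Student t with a deterministic degenerate-data convention: both groups
## constant -> p = 1 when means agree, p = 0 otherwise.
safe_t_test <- function(x, y, var.equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                p.value = if (eq) 1 else 0,
                estimate = mean(x) - mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var.equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       estimate = unname(mean(x) - mean(y)))
}

#' Summarize aberration calls per sample and compare groups
#'
#' Counts calls per sample, reports group mean and sample SD of the counts,
#' and compares the two groups with a two-sided unpaired Student t-test.
#'
#' @param calls Combined call table (rows from [call_aberrations()], any
#'   number of samples). Samples with zero calls must still appear in
#'   `groups` to be counted as zero.
#' @param groups Named character vector mapping `sample_id` to group label
#'   (exactly two groups, each with at least 2 samples).
#' @return List with `per_sample` (`sample_id`, `group`, `n_calls`),
#'   `group_stats` (`group`, `n_samples`, `total_calls`, `mean`, `sd`), and
#'   `t_test` (`statistic`, `p.value`).
#' @export
summarize_calls <- function(calls, groups) {
  stopifnot(length(unique(groups)) == 2L)
  counts <- vapply(names(groups),
                   function(s) sum(calls$sample_id == s), numeric(1))
  per_sample <- data.frame(sample_id = names(groups),
                           group = unname(groups),
                           n_calls = unname(counts),
                           stringsAsFactors = FALSE)
  gs <- split(per_sample$n_calls, per_sample$group)
  if (any(lengths(gs) < 2L)) stop("each group needs at least 2 samples")
  group_stats <- data.frame(
    group = names(gs),
    n_samples = lengths(gs),
    total_calls = vapply(gs, sum, numeric(1)),
    mean = vapply(gs, mean, numeric(1)),
    sd = vapply(gs, stats::sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(group_stats) <- NULL
  tt <- safe_t_test(gs[[1]], gs[[2]])
  list(per_sample = per_sample, group_stats = group_stats,
       t_test = list(statistic = tt$statistic, p.value = tt$p.value))
}

#' Derive recurrent CNA regions from a cohort's calls
#'
#' For each aberration direction, takes the union (interval merge) of all
#' calls across samples and renders every merged region as a cytoband range
#' (first to last overlapped band). This reproduces the "affected cytobands"
#' summarization of aberration interval reports.
#'
#' @param calls Combined call table.
#' @param cytobands A `cytoband_table`.
#' @return `data.frame` with columns `label`, `chrom`, `start`, `end`,
#'   `direction`; `start`/`end` are the extent of the band run.
#' @export
derive_cna_regions <- function(calls, cytobands) {
  out <- list()
  for (dir in c("gain", "loss")) {
    cc <- calls[calls$direction == dir, , drop = FALSE]
    if (nrow(cc) == 0L) next
    merged <- GenomicRanges::reduce(as_granges0(cc$chrom, cc$start, cc$end))
    md <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                     start = GenomicRanges::start(merged) - 1,
                     end = GenomicRanges::end(merged))
    for (k in seq_len(nrow(md))) {
      hit <- locate_feature(md$chrom[k], md$start[k], md$end[k], cytobands)
      if (!length(hit)) next
      b <- cytobands[cytobands$chrom == md$chrom[k], ]
      run <- b[b$label %in% hit, ]
      out[[length(out) + 1L]] <- data.frame(
        label = render_cytoband_range(md$chrom[k], run$band[1],
                                      run$band[nrow(run)]),
        chrom = md$chrom[k], start = min(run$start), end = max(run$end),
        direction = dir, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(label = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-group frequency of samples affected by each CNA region
#'
#' A sample is "affected" for a (region, direction) pair when any of its
#' calls of that direction overlaps the region interval.
#'
#' @param calls Combined call table.
#' @param regions Region table with `label`, `chrom`, `start`, `end`,
#'   `direction` (e.g. from [derive_cna_regions()] or supplied cytoband
#'   ranges resolved through [bands_in_range()]).
#' @param groups Named character vector sample_id -> group.
#' @return Long-format `data.frame`: `label`, `direction`, `group`,
#'   `n_affected`, `n_samples`, `frequency` (percent).
#' @export
cytoband_frequency <- function(calls, regions, groups) {
  samples <- names(groups)
  out <- list()
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    affected <- vapply(samples, function(s) {
      cc <- calls[calls$sample_id == s & calls$direction == r$direction &
                    calls$chrom == r$chrom, , drop = FALSE]
      any(cc$start < r$end & cc$end > r$start)
    }, logical(1))
    for (g in sort(unique(unname(groups)))) {
      in_g <- unname(groups) == g
      out[[length(out) + 1L]] <- data.frame(
        label = r$label, direction = r$direction, group = g,
        n_affected = sum(affected[in_g]), n_samples = sum(in_g),
        frequency = 100 * sum(affected[in_g]) / sum(in_g),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-level copy number per sample
#'
#' Two reporting modes. `mean_probe`: mean log2 ratio of the probes
#' overlapping the gene span (`NA` when no probe overlaps). `interval`: the
#' `mean_log2` of the called aberration overlapping the gene, or 0 (copy
#' neutral) when the gene lies outside all calls of that sample.
#'
#' @param probes_by_sample Named list of probe tables, one per sample
#'   (required for `mean_probe` mode).
#' @param calls Combined call table (required for `interval` mode).
#' @param gene_loci Feature locus table from [read_feature_loci()].
#' @param mode `"mean_probe"` or `"interval"`.
#' @param samples Sample ids defining the column order; defaults to the names
#'   of `probes_by_sample` or the samples present in `calls`.
#' @return Numeric matrix, genes x samples.
#' @export
gene_copy_number <- function(probes_by_sample = NULL, calls = NULL, gene_loci,
                             mode = c("mean_probe", "interval"),
                             samples = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean_probe") {
    if (is.null(probes_by_sample)) stop("mean_probe mode needs probe tables")
    if (is.null(samples)) samples <- names(probes_by_sample)
    out <- matrix(NA_real_, nrow(gene_loci), length(samples),
                  dimnames = list(gene_loci$feature_id, samples))
    for (s in samples) {
      p <- probes_by_sample[[s]]
      for (k in seq_len(nrow(gene_loci))) {
        g <- gene_loci[k, ]
        hit <- p$chrom == g$chrom & p$start < g$end & p$end > g$start
        if (any(hit)) out[k, s] <- mean(p$log2_ratio[hit])
      }
    }
  } else {
    if (is.null(calls)) stop("interval mode needs a call table")
    if (is.null(samples)) samples <- unique(calls$sample_id)
    out <- matrix(0, nrow(gene_loci), length(samples),
                  dimnames = list(gene_loci$feature_id, samples))
    for (s in samples) {
      cc <- calls[calls$sample_id == s, , drop = FALSE]
      for (k in seq_len(nrow(gene_loci))) {
        g <- gene_loci[k, ]
        hit <- which(cc$chrom == g$chrom & cc$start < g$end & cc$end > g$start)
        if (length(hit)) out[k, s] <- mean(cc$mean_log2[hit])
      }
    }
  }
  out
}

#' Per-gene two-group comparison of copy number
#'
#' Two-sided Student t-test (Welch by flag) on each gene's per-sample copy
#' number between the two groups. Genes with fewer than 2 non-missing values
#' in either group are flagged `tested = FALSE` and not tested.
#'
#' @param gene_cn Gene x sample matrix from [gene_copy_number()].
#' @param groups Named character vector sample_id -> group.
#' @param var.equal `TRUE` for the pooled-variance Student test (default).
#' @return `data.frame`: `gene`, per-group means, `t`, `p`, `tested`.
#' @export
compare_group_gene_cn <- function(gene_cn, groups, var.equal = TRUE) {
  glev <- sort(unique(unname(groups)))
  stopifnot(length(glev) == 2L)
  s1 <- names(groups)[groups == glev[1]]
  s2 <- names(groups)[groups == glev[2]]
  res <- lapply(rownames(gene_cn), function(g) {
    x <- gene_cn[g, s1]; y <- gene_cn[g, s2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(gene = g, mean_1 = NA_real_, mean_2 = NA_real_,
                        t = NA_real_, p = NA_real_, tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    tt <- safe_t_test(x, y, var.equal = var.equal)
    data.frame(gene = g, mean_1 = mean(x), mean_2 = mean(y),
               t = tt$statistic, p = tt$p.value, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", glev)
  out
}
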