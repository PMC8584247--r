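#' Map significant miRNAs to frequent CNA cytoband ranges
#'
#' First integration step: each significant differentially expressed miRNA
#' is located on the genome and paired with every (cytoband range, direction)
#' whose frequency in the chosen group reaches `min_frequency`. miRNAs
#' without a locus are excluded with a warning and counted.
#'
#' @param de `data.frame` from [differential_expression()]; only rows with
#'   `significant == TRUE` are used.
#' @param mirna_loci Locus table from [read_feature_loci()].
#' @param freq Frequency table from [cytoband_frequency()].
#' @param regions Region table giving the interval of each frequency label
#'   (columns `label`, `chrom`, `start`, `end`, `direction`).
#' @param group Group whose frequency column is thresholded.
#' @param min_frequency Minimum frequency as a proportion in \[0, 1\]
#'   (default 0.25, i.e. CNAs present in more than a quarter of the group).
#' @return `data.frame` of concordance records: `mirna`, `label`,
#'   `direction`, `frequency`, `log2fc`, `p`, `concordant`. The `n_unmapped`
#'   attribute counts significant miRNAs without a locus.
#' @export
map_de_mirnas_to_cna_cytobands <- function(de, mirna_loci, freq, regions,
                                           group, min_frequency = 0.25) {
  stopifnot(min_frequency >= 0, min_frequency <= 1)
  sig <- de[de$significant, , drop = FALSE]
  fr <- freq[freq$group == group &
               freq$frequency >= 100 * min_frequency, , drop = FALSE]
  keep <- merge(fr, regions, by = c("label", "direction"))
  out <- list()
  unmapped <- 0L
  for (k in seq_len(nrow(sig))) {
    m <- sig$mirna[k]
    loc <- mirna_loci[mirna_loci$feature_id == m, , drop = FALSE]
    if (nrow(loc) == 0L) {
      warning("no locus for significant miRNA ", m, "; excluded")
      unmapped <- unmapped + 1L
      next
    }
    hit <- keep$chrom == loc$chrom[1] &
      keep$start < loc$end[1] & keep$end > loc$start[1]
    for (r in which(hit)) {
      dirn <- keep$direction[r]
      lfc <- sig$log2fc[k]
      out[[length(out) + 1L]] <- data.frame(
        mirna = m, label = keep$label[r], direction = dirn,
        frequency = keep$frequency[r], log2fc = lfc, p = sig$p[k],
        concordant = (dirn == "gain" && lfc > 0) ||
          (dirn == "loss" && lfc < 0),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(), label = character(),
               direction = character(), frequency = numeric(),
               log2fc = numeric(), p = numeric(), concordant = logical(),
               stringsAsFactors = FALSE)
  res <- res[order(res$mirna, res$label), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_unmapped") <- unmapped
  res
}

#' Keep concordant miRNA/CNA pairings
#'
#' Concordance means expression moving with copy number: a gain range paired
#' with an upregulated miRNA (`log2fc > 0`) or a loss range with a
#' downregulated one (`log2fc < 0`). A log2 fold change of exactly 0 is
#' non-concordant by definition.
#'
#' @param records Output of [map_de_mirnas_to_cna_cytobands()].
#' @return The concordant subset (same columns).
#' @export
concordance_filter <- function(records) {
  records[records$concordant, , drop = FALSE]
}

#' Read a miRNA target-prediction table
#'
#' Two tab-separated columns `mirna`, `gene` with a header row; duplicate
#' pairs within one table are deduplicated with a warning.
#'
#' @param path Path to the table.
#' @param database Database name attached to the rows.
#' @return `data.frame`: `database`, `mirna`, `gene`.
#' @export
read_target_table <- function(path, database = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("mirna", "gene") %in% names(tab)))
  dup <- duplicated(tab[, c("mirna", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) in ", database, "; deduplicated")
    tab <- tab[!dup, , drop = FALSE]
  }
  data.frame(database = database, mirna = tab$mirna, gene = tab$gene,
             stringsAsFactors = FALSE)
}

#' Consensus predicted targets across databases
#'
#' Keeps a (miRNA, gene) pair when it appears in at least `min_db` of the
#' supplied prediction tables.
#'
#' @param tables List of target tables (each from [read_target_table()], or
#'   any `data.frame` with `mirna` and `gene`).
#' @param min_db Minimum number of supporting databases (default 2).
#' @return `data.frame` `mirna`, `gene`, `n_db`, with attributes
#'   `n_pairs` (consensus pairs) and `n_genes` (unique consensus genes).
#' @export
consensus_targets <- function(tables, min_db = 2L) {
  stopifnot(length(tables) >= min_db)
  pairs <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- unique(tables[[i]][, c("mirna", "gene")])
    t$db <- i
    t
  }))
  key <- paste(pairs$mirna, pairs$gene, sep = "\r")
  n_db <- tapply(pairs$db, key, function(d) length(unique(d)))
  keep <- names(n_db)[n_db >= min_db]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  res <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    n_db = as.integer(n_db[keep]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$mirna, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_pairs") <- nrow(res)
  attr(res, "n_genes") <- length(unique(res$gene))
  res
}

#' Intersect consensus targets with genes in CNA regions
#'
#' Second integration step: restricts the consensus target genes to those
#' also lying in copy-number-altered regions, and reports the percent
#' reduction of the target list.
#'
#' @param consensus Consensus table from [consensus_targets()].
#' @param cna_genes Character vector of genes located in the retained CNA
#'   cytoband ranges.
#' @return List of class `integration_summary`: `n_before` (unique consensus
#'   genes), `n_after`, `reduction_pct` (`NA` when `n_before` is 0), `genes`
#'   (the surviving gene set) and `pairs` (surviving miRNA-gene rows).
#' @export
intersect_targets_with_cna_genes <- function(consensus, cna_genes) {
  before <- unique(consensus$gene)
  surviving <- consensus[consensus$gene %in% cna_genes, , drop = FALSE]
  after <- unique(surviving$gene)
  reduction <- if (length(before) == 0L) NA_real_ else
    100 * (length(before) - length(after)) / length(before)
  structure(list(n_before = length(before), n_after = length(after),
                 reduction_pct = reduction, genes = sort(after),
                 pairs = surviving),
            class = "integration_summary")
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric overlap of a gene list with gene sets
#'
#' Upper-tail hypergeometric test per set (probability of an overlap at
#' least as large under random draws from the universe), with
#' Benjamini-Hochberg correction across sets. Set members outside the
#' universe are dropped with a warning.
#'
#' @param gene_list Character vector of query genes (must lie in the
#'   universe).
#' @param gmt_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @return `data.frame`: `set`, `set_size`, `overlap`, `p`, `q`.
#' @export
gene_set_overlap <- function(gene_list, gmt_sets, universe) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe)) {
    stop("gene_list contains genes outside the universe")
  }
  N <- length(universe)
  n <- length(gene_list)
  res <- lapply(names(gmt_sets), function(s) {
    set <- unique(gmt_sets[[s]])
    out <- setdiff(set, universe)
    if (length(out)) {
      warning("set ", s, ": ", length(out), " gene(s) outside universe dropped")
      set <- intersect(set, universe)
    }
    K <- length(set)
    k <- length(intersect(gene_list, set))
    ## P(X >= k); at k = 0 this is 1 by convention
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Filter a protein-interaction edge table into a network
#'
#' Drops edges below `min_score` and nodes left without connections, then
#' optionally attaches miRNA-to-target edges (a second edge class) from a
#' consensus mapping restricted to the surviving genes.
#'
#' @param edges `data.frame` with `node_a`, `node_b`, `score` in \[0, 1\].
#' @param min_score Minimum interaction score (default 0.9, highest
#'   confidence).
#' @param mirna_edges Optional `data.frame` with `mirna`, `gene` rows to add
#'   as `"mirna_target"` edges (only for genes kept in the protein network).
#' @return An `igraph` graph whose edges carry a `type` attribute
#'   (`"ppi"` or `"mirna_target"`) and, for PPI edges, the `score`.
#' @export
filter_ppi_edges <- function(edges, min_score = 0.9, mirna_edges = NULL) {
  stopifnot(all(c("node_a", "node_b", "score") %in% names(edges)))
  score <- suppressWarnings(as.numeric(edges$score))
  if (any(is.na(score) | score < 0 | score > 1)) {
    stop("malformed interaction score (need numeric in [0, 1])")
  }
  mask <- score >= min_score & edges$node_a != edges$node_b
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$node_a[mask], to = edges$node_b[mask],
               score = score[mask], type = "ppi", stringsAsFactors = FALSE),
    directed = FALSE
  )
  g <- igraph::simplify(g, edge.attr.comb = "first")
  iso <- igraph::V(g)[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, iso)
  if (!is.null(mirna_edges) && nrow(mirna_edges)) {
    me <- mirna_edges[mirna_edges$gene %in% igraph::V(g)$name, , drop = FALSE]
    if (nrow(me)) {
      g <- igraph::add_vertices(g, length(setdiff(me$mirna, igraph::V(g)$name)),
                                name = setdiff(me$mirna, igraph::V(g)$name))
      g <- igraph::add_edges(g, rbind(match(me$mirna, igraph::V(g)$name),
                                      match(me$gene, igraph::V(g)$name)),
                             attr = list(type = "mirna_target",
                                         score = NA_real_))
    }
  }
  g
}

#' Per-sample count of altered concordant miRNAs
#'
#' A miRNA counts as altered in a sample when its log2 expression deviates
#' from the reference group's mean by more than `k_sd` reference-group
#' standard deviations in the direction of that miRNA's group-level log2
#' fold change. Counts are compared between groups with an unpaired Student
#' t-test.
#'
#' @param norm A `normalized_matrix` or log2 matrix.
#' @param concordant `data.frame` with `mirna` and `log2fc` (the distinct
#'   concordant miRNAs; duplicated rows are collapsed).
#' @param groups Named character vector sample -> group.
#' @param reference_group Group providing the reference mean and SD.
#' @param k_sd Deviation threshold in reference SD units (default 1).
#' @return List: `per_sample` (`sample_id`, `group`, `n_altered`),
#'   `group_stats`, `t_test`, `skipped` (miRNAs with zero reference SD).
#' @export
per_sample_alteration_count <- function(norm, concordant, groups,
                                        reference_group, k_sd = 1.0) {
  mat <- if (inherits(norm, "normalized_matrix")) norm$log2 else norm
  groups <- groups[names(groups) %in% colnames(mat)]
  info <- unique(concordant[, c("mirna", "log2fc")])
  info <- info[info$mirna %in% rownames(mat), , drop = FALSE]
  ref_samples <- names(groups)[groups == reference_group]
  altered <- matrix(FALSE, nrow(info), length(groups),
                    dimnames = list(info$mirna, names(groups)))
  skipped <- character()
  for (k in seq_len(nrow(info))) {
    m <- info$mirna[k]
    ref <- mat[m, ref_samples]
    if (stats::sd(ref) == 0) {
      warning("reference SD is 0 for ", m, "; skipped")
      skipped <- c(skipped, m)
      next
    }
    dev <- (mat[m, names(groups)] - mean(ref)) / stats::sd(ref)
    altered[k, ] <- if (info$log2fc[k] > 0) dev > k_sd else dev < -k_sd
  }
  counts <- colSums(altered[!rownames(altered) %in% skipped, , drop = FALSE])
  per_sample <- data.frame(sample_id = names(groups),
                           group = unname(groups), n_altered = unname(counts),
                           stringsAsFactors = FALSE)
  gs <- split(per_sample$n_altered, per_sample$group)
  group_stats <- data.frame(group = names(gs), n_samples = lengths(gs),
                            mean = vapply(gs, mean, numeric(1)),
                            sd = vapply(gs, stats::sd, numeric(1)),
                            stringsAsFactors = FALSE)
  rownames(group_stats) <- NULL
  tt <- safe_t_test(gs[[1]], gs[[2]])
  list(per_sample = per_sample, group_stats = group_stats,
       t_test = list(statistic = tt$statistic, p.value = tt$p.value),
       skipped = skipped)
}
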