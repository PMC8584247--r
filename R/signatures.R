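#' Gene signatures: centrosome amplification (CA20) and chromosomal
#' instability (CIN25)
#'
#' `ca20_signature()` returns the 20 genes of the centrosome-amplification
#' expression signature; `cin25_signature()` the 25 genes of the
#' chromosomal-instability signature, as historically printed. Several CIN25
#' symbols are legacy nomenclature; `signature_aliases()` maps them to
#' current HGNC symbols and `resolve_signature()` applies the mapping.
#'
#' @return Character vector of gene symbols.
#' @export
ca20_signature <- function() {
  c("AURKA", "CCNA2", "CCND1", "CCNE2", "CDK1", "CEP63", "CEP152", "E2F1",
    "E2F2", "LMO4", "MDM2", "MYCN", "NDRG1", "NEK2", "PIN1", "PLK1", "PLK4",
    "SASS6", "STIL", "TUBG1")
}

#' @rdname ca20_signature
#' @export
cin25_signature <- function() {
  c("TPX2", "PRC1", "FOXM1", "CDC2", "C20orf24-TGIF2", "MCM2", "H2AFZ",
    "TOP2A", "PCNA", "UBE2C", "MELK", "TRIP13", "CNAP1", "MCM7", "RNASEH2A",
    "RAD51AP1", "KIF20A", "CDC45L", "MAD2L1", "ESPL1", "CCNB2", "FEN1",
    "TTK", "CCT5", "RFC4")
}

#' @rdname ca20_signature
#' @export
signature_aliases <- function() {
  data.frame(
    printed = c("CDC2", "CNAP1", "C20orf24-TGIF2", "CDC45L", "H2AFZ"),
    current = c("CDK1", "NCAPD2", "TGIF2", "CDC45", "H2AZ1"),
    stringsAsFactors = FALSE
  )
}

#' Resolve legacy signature symbols to current nomenclature
#'
#' @param symbols Character vector of gene symbols as printed.
#' @return Character vector with legacy symbols replaced per
#'   [signature_aliases()]; unknown symbols pass through unchanged.
#' @export
resolve_signature <- function(symbols) {
  al <- signature_aliases()
  i <- match(symbols, al$printed)
  ifelse(is.na(i), symbols, al$current[i])
}

#' Per-gene copy-number comparison for a signature
#'
#' Restricts a gene-level copy-number matrix (from [gene_copy_number()]) to
#' the signature genes and compares the two groups gene by gene with
#' [compare_group_gene_cn()]. Signature genes absent from the matrix are
#' reported in `missing`, never silently dropped.
#'
#' @param gene_cn Gene x sample copy-number matrix.
#' @param signature Character vector of gene symbols (legacy symbols are
#'   resolved through the alias table first).
#' @param groups Named character vector sample -> group.
#' @param var.equal Student (default) or Welch t-test.
#' @return List with `results` (per-gene comparison table) and `missing`
#'   (symbols not found in the matrix).
#' @export
signature_cn_comparison <- function(gene_cn, signature, groups,
                                    var.equal = TRUE) {
  genes <- resolve_signature(signature)
  present <- genes[genes %in% rownames(gene_cn)]
  missing <- genes[!genes %in% rownames(gene_cn)]
  if (!length(present)) stop("no signature gene present in the matrix")
  res <- compare_group_gene_cn(gene_cn[present, , drop = FALSE], groups,
                               var.equal = var.equal)
  list(results = res, missing = missing)
}

#' Summed median-centered signature expression score
#'
#' Per gene, subtracts the across-sample median of its log2 expression; the
#' score of a sample is the unweighted sum of these centered values over the
#' signature genes. A sample sitting at every gene's median scores exactly 0.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param signature Character vector of gene symbols (aliases resolved).
#' @return `data.frame`: `sample_id`, `score`, `n_genes_used`. Genes absent
#'   from the matrix are excluded and reflected in `n_genes_used`.
#' @export
signature_expression_score <- function(expr, signature) {
  genes <- resolve_signature(signature)
  present <- intersect(genes, rownames(expr))
  if (!length(present)) stop("no signature gene present in expression matrix")
  sub <- expr[present, , drop = FALSE]
  centered <- sweep(sub, 1, apply(sub, 1, stats::median), `-`)
  data.frame(sample_id = colnames(expr),
             score = colSums(centered),
             n_genes_used = length(present),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify samples by a percentile of one gene's expression
#'
#' Labels a sample "low" when its value is strictly below the empirical
#' percentile (linear-interpolation quantile); ties at the threshold go to
#' "high". Used e.g. to call AR-low tumors as below the 10th percentile of
#' AR expression.
#'
#' @param values Named numeric vector (names = samples).
#' @param percentile Percentile in (0, 100); default 10.
#' @return List with `labels` (named character vector `"low"`/`"high"`) and
#'   `threshold` (the quantile value used).
#' @export
stratify_by_gene_percentile <- function(values, percentile = 10) {
  stopifnot(length(values) >= 10L, percentile > 0, percentile < 100)
  thr <- unname(stats::quantile(values, percentile / 100, type = 7))
  labels <- ifelse(values < thr, "low", "high")
  names(labels) <- names(values)
  list(labels = labels, threshold = thr)
}

#' Compare signature scores between two label classes
#'
#' Two-sided unpaired Student t-test of the scores between the two classes.
#'
#' @param scores Numeric vector of signature scores.
#' @param labels Class labels aligned with `scores` (exactly two levels,
#'   each with >= 2 members).
#' @return List with `t`, `p`, and the per-class means.
#' @export
compare_scores <- function(scores, labels) {
  lev <- sort(unique(labels))
  stopifnot(length(lev) == 2L)
  x <- scores[labels == lev[1]]
  y <- scores[labels == lev[2]]
  if (length(x) < 2L || length(y) < 2L) stop("each class needs >= 2 members")
  tt <- safe_t_test(x, y)
  list(t = tt$statistic, p = tt$p.value,
       means = stats::setNames(c(mean(x), mean(y)), lev))
}
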