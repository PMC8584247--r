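#' @importFrom GenomicRanges GRanges findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats setNames
NULL

#' Normalize chromosome names to the "chr"-prefixed form
#'
#' Annotation sources disagree on whether chromosome names carry the "chr"
#' prefix; all internal coordinate handling uses the prefixed form.
#'
#' @param x Character vector of chromosome names (e.g. `"8"`, `"chr8"`).
#' @return Character vector with a `"chr"` prefix on every element.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

## Compact band label as printed in cytogenetic reports: "8p12" for
## (chr8, band "p12").
band_full_label <- function(chrom, band) {
  paste0(sub("^chr", "", chrom), band)
}

#' Read a cytoband table (cytoBand.txt dialect)
#'
#' Expects the five tab-separated columns of the UCSC cytoBand.txt format:
#' chromosome, start, end, band label (e.g. "p12"), Giemsa stain. Coordinates
#' are 0-based half-open. Lines starting with `#` are ignored.
#'
#' @param path Path to the tab-separated cytoband file (no header row).
#' @return A `data.frame` of class `cytoband_table` with columns `chrom`,
#'   `start`, `end`, `band`, `stain`, `arm` and `label` (the rendered
#'   chromosome+band label such as `"8p12"`), sorted by chromosome then start.
#' @export
read_cytoband_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_cytoband_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("cytoband parse error at line ", lineno[which(nf < 5L)[1]],
         ": expected 5 tab-separated columns")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop("cytoband parse error at line ", lineno[bad[1]],
         ": non-integer coordinates or start >= end")
  }
  tab <- data.frame(
    chrom = normalize_chrom(m[, 1]),
    start = start, end = end,
    band = m[, 4], stain = m[, 5],
    stringsAsFactors = FALSE
  )
  tab$arm <- substr(tab$band, 1L, 1L)
  if (!all(tab$arm %in% c("p", "q"))) {
    stop("cytoband parse error: band label must begin with 'p' or 'q'")
  }
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  ## bands on one chromosome must tile without overlap
  for (chr in unique(tab$chrom)) {
    b <- tab[tab$chrom == chr, ]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
      stop("overlapping cytobands on ", chr)
    }
  }
  tab$label <- band_full_label(tab$chrom, tab$band)
  rownames(tab) <- NULL
  class(tab) <- c("cytoband_table", "data.frame")
  tab
}

empty_cytoband_table <- function() {
  tab <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    band = character(), stain = character(), arm = character(),
                    label = character(), stringsAsFactors = FALSE)
  class(tab) <- c("cytoband_table", "data.frame")
  tab
}

#' Read feature loci from a BED3+ file
#'
#' Coordinates are kept 0-based half-open as in BED. Column 4 (feature name)
#' is required; column 6 (strand) is used when present, otherwise strand is
#' set to `"."`. Comment lines starting with `#` are skipped.
#'
#' @param path Path to a BED file with at least 4 columns.
#' @param feature_type One of `"miRNA"`, `"protein_coding"`, `"lncRNA"`,
#'   `"other"`; attached to every record.
#' @return A `data.frame` with columns `feature_id`, `feature_type`, `chrom`,
#'   `start`, `end`, `strand`, sorted by chromosome and start. Duplicate
#'   feature ids are an error.
#' @export
read_feature_loci <- function(path,
                              feature_type = c("miRNA", "protein_coding",
                                               "lncRNA", "other")) {
  feature_type <- match.arg(feature_type)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(feature_id = character(), feature_type = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("BED locus file needs a name in column 4: ", path)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:6][1:6]))
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  if (any(is.na(start) | is.na(end) | start >= end)) {
    stop("invalid BED coordinates (need numeric start < end) in ", path)
  }
  loci <- data.frame(
    feature_id = m[, 4],
    feature_type = feature_type,
    chrom = normalize_chrom(m[, 1]),
    start = start, end = end,
    strand = ifelse(is.na(m[, 6]) | !(m[, 6] %in% c("+", "-")), ".", m[, 6]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(loci$feature_id)) {
    stop("duplicate feature_id in ", path, ": ",
         loci$feature_id[duplicated(loci$feature_id)][1])
  }
  loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

## GRanges from 0-based half-open columns (IRanges is 1-based closed).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Map a feature locus to the cytobands it overlaps
#'
#' Overlap is strand-blind on 0-based half-open intervals: a locus whose end
#' equals a band's start does not overlap that band, and a locus straddling a
#' band boundary reports both bands.
#'
#' @param chrom,start,end Locus coordinates (0-based half-open).
#' @param cytobands A `cytoband_table` from [read_cytoband_table()].
#' @return Character vector of overlapped band labels (e.g. `"8q24.21"`), in
#'   coordinate order. Errors if the chromosome is absent from the table.
#' @export
locate_feature <- function(chrom, start, end, cytobands) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% cytobands$chrom) {
    stop("chromosome ", chrom, " absent from cytoband table")
  }
  b <- cytobands[cytobands$chrom == chrom, ]
  hit <- b$start < end & b$end > start
  b$label[hit]
}

#' Parse a cytoband range label
#'
#' Accepts the compact report form `"8p12-p11.11"` (arm prefix collapsed),
#' the fully repeated form `"8p12-8p12"`, and single bands `"8p12"`.
#'
#' @param label Range label string.
#' @return List with `chrom` (prefixed), `first_band`, `last_band`.
#' @export
parse_cytoband_range <- function(label) {
  label <- trimws(label)
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) > 2L) stop("malformed cytoband range label: ", label)
  m <- regmatches(parts[1], regexec("^([0-9XYM]+)([pq].*)$", parts[1]))[[1]]
  if (length(m) != 3L) stop("malformed cytoband range label: ", label)
  chrom <- normalize_chrom(m[2])
  first_band <- m[3]
  if (length(parts) == 1L) {
    last_band <- first_band
  } else {
    p2 <- sub(paste0("^", m[2]), "", parts[2])  # tolerate repeated chrom
    if (!grepl("^[pq]", p2)) stop("malformed cytoband range label: ", label)
    last_band <- p2
  }
  list(chrom = chrom, first_band = first_band, last_band = last_band)
}

#' Render a contiguous band run as a compact range label
#'
#' @param chrom Chromosome of the run.
#' @param first_band,last_band Band labels (e.g. `"p12"`, `"p11.11"`).
#' @return A label like `"8p12-p11.11"`, or `"8p12"` for a single band.
#' @export
render_cytoband_range <- function(chrom, first_band, last_band) {
  n <- sub("^chr", "", chrom)
  if (first_band == last_band) {
    paste0(n, first_band)
  } else {
    paste0(n, first_band, "-", last_band)
  }
}

#' Expand a cytoband range into its constituent bands
#'
#' @param label Range label, e.g. `"4p16.3-p12"`.
#' @param cytobands A `cytoband_table`.
#' @return List with `chrom`, `bands` (labels of the inclusive run in
#'   coordinate order), `start` and `end` (the union extent, 0-based
#'   half-open), and `label` (re-rendered range label).
#' @export
bands_in_range <- function(label, cytobands) {
  rng <- parse_cytoband_range(label)
  b <- cytobands[cytobands$chrom == rng$chrom, ]
  if (nrow(b) == 0L) stop("chromosome ", rng$chrom, " absent from cytoband table")
  i <- match(rng$first_band, b$band)
  j <- match(rng$last_band, b$band)
  if (is.na(i)) stop("band ", rng$first_band, " not found on ", rng$chrom)
  if (is.na(j)) stop("band ", rng$last_band, " not found on ", rng$chrom)
  if (i > j) stop("first band after last band in coordinate order: ", label)
  run <- b[i:j, ]
  list(chrom = rng$chrom,
       bands = run$label,
       start = min(run$start),
       end = max(run$end),
       label = render_cytoband_range(rng$chrom, run$band[1], run$band[nrow(run)]))
}
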