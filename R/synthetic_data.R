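#' Toy genome used by the synthetic cohort generator
#'
#' A reduced genome of 11 chromosomes with a coarse cytoband grid. Bands are
#' named after the regions whose copy-number behavior the simulation
#' emulates (e.g. the 8q gain block hosting miR-1204 at 8q24.21, the 12p
#' gain block hosting RAD51AP1). Coordinates are 0-based half-open base
#' pairs. chr2 and chr5 are "filler" chromosomes reserved for private
#' per-sample segments and carry no miRNA or gene loci.
#'
#' @return `data.frame` with columns `chrom`, `band`, `start`, `end`.
#' @export
default_toy_genome <- function() {
  Mb <- 1e6
  mk <- function(chrom, band, bounds) {
    data.frame(chrom = chrom, band = band,
               start = bounds[-length(bounds)] * Mb, end = bounds[-1] * Mb,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("chr1", c("p36", "p22", "p11", "q21.1", "q25", "q32", "q44"),
       c(0, 15, 30, 45, 60, 75, 90, 100)),
    mk("chr2", c("p11", "q11"), c(0, 30, 60)),
    mk("chr3", c("p11", "q11.1", "q26", "q29"), c(0, 30, 45, 60, 75)),
    mk("chr4", c("p16.3", "p15", "p12", "q12"), c(0, 10, 20, 30, 60)),
    mk("chr5", c("p11", "q11"), c(0, 30, 60)),
    mk("chr6", c("p25.3", "p22", "p12.1", "q16"), c(0, 10, 20, 30, 60)),
    mk("chr8", c("p23", "p12", "p11.11", "q11.1", "q21", "q24.21", "q24.3"),
       c(0, 12, 20, 27, 35, 60, 70, 80)),
    mk("chr10", c("p15.3", "p13", "p11.1", "q21"), c(0, 10, 20, 28, 60)),
    mk("chr12", c("p13.33", "p13.1", "p11.1", "q14"), c(0, 8, 15, 25, 60)),
    mk("chr19", c("p13", "q13"), c(0, 30, 60)),
    mk("chrX", c("p22.33", "p21", "p11.21", "q21"), c(0, 10, 20, 30, 60))
  )
}

#' Planted copy-number regions of the default synthetic cohort
#'
#' One region per chromosome (so calls from distinct regions can never merge
#' into one interval), each spanning a full cytoband run, with
#' group-specific carrier frequencies and a gain/loss direction. The four
#' regions hosting the eight concordant miRNAs (`host = TRUE`) use a strong
#' QNBC/TNBC frequency contrast so that the carrier-linked expression effect
#' of the hosted miRNAs is a detectable group difference; the remaining
#' regions use frequency contrasts typical of recurrent-CNA tables.
#'
#' @return `data.frame` with columns `label`, `chrom`, `first_band`,
#'   `last_band`, `direction`, `amplitude` (mean log2 ratio of the segment),
#'   `freq_qnbc`, `freq_tnbc`, `host`.
#' @export
default_planted_regions <- function() {
  data.frame(
    label = c("1q21.1-q44", "3q11.1-q29", "4p16.3-p12", "6p25.3-p12.1",
              "8q21-q24.3", "10p15.3-p11.1", "12p13.33-p11.1",
              "Xp22.33-p11.21"),
    chrom = c("chr1", "chr3", "chr4", "chr6", "chr8", "chr10", "chr12",
              "chrX"),
    first_band = c("q21.1", "q11.1", "p16.3", "p25.3", "q21", "p15.3",
                   "p13.33", "p22.33"),
    last_band = c("q44", "q29", "p12", "p12.1", "q24.3", "p11.1", "p11.1",
                  "p11.21"),
    direction = c("gain", "gain", "loss", "gain", "gain", "gain", "gain",
                  "loss"),
    amplitude = c(0.7, 0.6, -0.8, 0.7, 0.8, 0.6, 0.8, -0.7),
    freq_qnbc = c(0.632, 0.421, 0.895, 0.895, 0.895, 0.526, 0.895, 0.421),
    freq_tnbc = c(0.357, 0.429, 0.143, 0.214, 0.214, 0.214, 0.143, 0.214),
    host = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' miRNA panel of the default synthetic cohort
#'
#' 827 endogenous probes mirroring the size of a NanoString-style human
#' miRNA codeset: eight concordant miRNAs located inside planted CNA
#' regions whose expression effect is carrier-linked and matches the region
#' direction; seven discordant miRNAs located inside CNA regions but with a
#' group-wide effect of the opposite sign; 169 further differentially
#' expressed miRNAs and 643 null miRNAs, all on the copy-neutral chr19.
#' Planted effects total 112 down- and 72 upregulated miRNAs in QNBC.
#'
#' @return `data.frame` with columns `mirna`, `chrom`, `start`, `end`,
#'   `log2fc` (planted QNBC - TNBC effect), `concordant` (carrier-linked),
#'   `region` (host region label or `NA`), `baseline` (log2 mean count).
#' @export
default_mirna_panel <- function() {
  Mb <- 1e6
  conc <- data.frame(
    mirna = c("hsa-miR-1204", "hsa-miR-1265", "hsa-miR-548ai",
              "hsa-miR-1267", "hsa-miR-613", "hsa-miR-567",
              "hsa-miR-23c", "hsa-miR-943"),
    chrom = c("chr8", "chr8", "chr6", "chr6", "chr12", "chr12", "chr4",
              "chr4"),
    start = c(65, 50, 5, 22, 3, 18, 12, 2) * Mb,
    log2fc = c(2.2, 1.8, 2.0, 1.7, 2.4, 1.9, -2.0, -2.3),
    concordant = TRUE,
    region = c("8q21-q24.3", "8q21-q24.3", "6p25.3-p12.1", "6p25.3-p12.1",
               "12p13.33-p11.1", "12p13.33-p11.1", "4p16.3-p12",
               "4p16.3-p12"),
    stringsAsFactors = FALSE
  )
  disc <- data.frame(
    mirna = sprintf("hsa-miR-d%02d", 1:7),
    chrom = c(rep("chr1", 4), rep("chr4", 3)),
    start = c(55, 65, 78, 92, 5, 18, 25) * Mb,
    log2fc = c(-1.6, -1.4, -1.8, -1.3, 1.5, 1.3, 1.7),
    concordant = FALSE,
    region = c(rep("1q21.1-q44", 4), rep("4p16.3-p12", 3)),
    stringsAsFactors = FALSE
  )
  n_other_de <- 169L
  n_null <- 643L
  n19 <- n_other_de + n_null
  ## 106 further down + 63 up => 112 down / 72 up overall
  fc_other <- c(-seq(1.2, 2.6, length.out = 106),
                seq(1.2, 2.6, length.out = 63))
  rest <- data.frame(
    mirna = sprintf("hsa-miR-s%03d", seq_len(n19)),
    chrom = "chr19",
    start = round(seq(0.5 * Mb, 59 * Mb, length.out = n19)),
    log2fc = c(fc_other, rep(0, n_null)),
    concordant = FALSE,
    region = NA_character_,
    stringsAsFactors = FALSE
  )
  panel <- rbind(conc, disc, rest)
  panel$end <- panel$start + 80
  panel$baseline <- 5 + 6 * ((seq_len(nrow(panel)) * 7) %% 97) / 97
  panel[, c("mirna", "chrom", "start", "end", "log2fc", "concordant",
            "region", "baseline")]
}

#' Build and validate a simulation configuration
#'
#' The defaults reproduce the study conditions the cohort stands in for:
#' 33 QNBC/TNBC tumors profiled by array-CGH (19 vs 14) and 32 by miRNA
#' panel (20 vs 12), recurrent planted CNA regions with group-specific
#' frequencies, private per-sample segments confined to two filler
#' chromosomes so that per-sample call counts average near 25 (QNBC) and 15
#' (TNBC), and an 827-probe miRNA panel with 184 planted group effects, of
#' which eight are carrier-linked and direction-concordant with their host
#' CNA region.
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param n_qnbc,n_tnbc Total samples per group.
#' @param n_acgh_qnbc,n_acgh_tnbc Samples with an aCGH probe table.
#' @param n_expr_qnbc,n_expr_tnbc Samples with miRNA counts.
#' @param probe_spacing_bp Array probe spacing in bp.
#' @param probe_noise_sd SD of i.i.d. Gaussian noise on probe log2 ratios.
#' @param dispersion SD of the log2 count noise of endogenous probes
#'   (must be >= 0; 0 gives the exact noiseless limit).
#' @param lane_sd SD (log2) of the per-sample lane scale factor.
#' @param control_sd SD (log2) of control-probe noise.
#' @param private_lambda Named vector `c(qnbc=, tnbc=)`: Poisson mean of
#'   private segments per sample on the filler chromosomes.
#' @param met_delta Log2 shift added to metastasis-associated miRNAs in
#'   metastatic samples.
#' @param genome,regions,mirna_panel Toy genome / planted regions / panel
#'   tables; see the `default_*` constructors.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_qnbc = 20L, n_tnbc = 14L,
                              n_acgh_qnbc = 19L, n_acgh_tnbc = 14L,
                              n_expr_qnbc = 20L, n_expr_tnbc = 12L,
                              probe_spacing_bp = 2e5,
                              probe_noise_sd = 0.1,
                              dispersion = 0.5,
                              lane_sd = 0.15,
                              control_sd = 0.1,
                              private_lambda = c(qnbc = 20, tnbc = 12.5),
                              met_delta = 0.8,
                              genome = default_toy_genome(),
                              regions = default_planted_regions(),
                              mirna_panel = default_mirna_panel()) {
  stopifnot(n_acgh_qnbc <= n_qnbc, n_acgh_tnbc <= n_tnbc,
            n_expr_qnbc <= n_qnbc, n_expr_tnbc <= n_tnbc,
            probe_spacing_bp > 0, probe_noise_sd >= 0, lane_sd >= 0,
            control_sd >= 0, all(private_lambda >= 0))
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (any(regions$freq_qnbc < 0 | regions$freq_qnbc > 1) ||
      any(regions$freq_tnbc < 0 | regions$freq_tnbc > 1)) {
    stop("planted frequencies must lie in [0, 1]")
  }
  if (any(sign(regions$amplitude) !=
          ifelse(regions$direction == "gain", 1, -1))) {
    stop("amplitude sign must match direction")
  }
  ## resolve each region to its band-run extent on the toy genome
  regions$start <- regions$end <- NA_real_
  for (k in seq_len(nrow(regions))) {
    b <- genome[genome$chrom == regions$chrom[k], ]
    i <- match(regions$first_band[k], b$band)
    j <- match(regions$last_band[k], b$band)
    if (is.na(i) || is.na(j) || i > j) {
      stop("planted region outside toy genome: ", regions$label[k])
    }
    regions$start[k] <- b$start[i]
    regions$end[k] <- b$end[j]
  }
  ## concordant miRNAs must sit inside a planted region of matching direction
  conc <- mirna_panel[mirna_panel$concordant, , drop = FALSE]
  for (k in seq_len(nrow(conc))) {
    r <- regions[regions$label == conc$region[k], , drop = FALSE]
    if (nrow(r) != 1L ||
        conc$start[k] < r$start || conc$end[k] > r$end ||
        sign(conc$log2fc[k]) != ifelse(r$direction == "gain", 1, -1)) {
      stop("concordant miRNA ", conc$mirna[k],
           " is not inside a matching planted segment")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_qnbc = n_qnbc, n_tnbc = n_tnbc,
                 n_acgh_qnbc = n_acgh_qnbc, n_acgh_tnbc = n_acgh_tnbc,
                 n_expr_qnbc = n_expr_qnbc, n_expr_tnbc = n_expr_tnbc,
                 probe_spacing_bp = probe_spacing_bp,
                 probe_noise_sd = probe_noise_sd,
                 dispersion = dispersion, lane_sd = lane_sd,
                 control_sd = control_sd,
                 private_lambda = private_lambda, met_delta = met_delta,
                 genome = genome, regions = regions,
                 mirna_panel = mirna_panel),
            class = "simulation_config")
}

#' Noiseless preset of the simulation configuration
#'
#' All noise sources set to zero, host-region carrier frequencies set to
#' 1 (QNBC) and 0 (TNBC), and no private segments: every pipeline stage
#' output is then predictable from the ground-truth manifest in closed form.
#'
#' @param seed Integer seed (still used for the remaining Bernoulli carrier
#'   draws and the combinatorial table construction).
#' @param probe_spacing_bp Array probe spacing in bp.
#' @return A `simulation_config`.
#' @export
noiseless_config <- function(seed = 1L, probe_spacing_bp = 2e5) {
  regions <- default_planted_regions()
  regions$freq_qnbc[regions$host] <- 1
  regions$freq_tnbc[regions$host] <- 0
  simulation_config(seed = seed, probe_noise_sd = 0, dispersion = 0,
                    lane_sd = 0, control_sd = 0,
                    private_lambda = c(qnbc = 0, tnbc = 0),
                    probe_spacing_bp = probe_spacing_bp,
                    regions = regions)
}

## metastasis-associated miRNAs and the sign of their association
met_assoc_table <- function(met_delta) {
  data.frame(mirna = c("hsa-miR-548ai", "hsa-miR-567", "hsa-miR-1265",
                       "hsa-miR-1267", "hsa-miR-23c"),
             delta = c(met_delta, met_delta, met_delta, met_delta,
                       -met_delta),
             stringsAsFactors = FALSE)
}

#' Generate raw miRNA panel counts for given carrier states
#'
#' Counts are log-normal: an endogenous probe's count in sample `s` is
#' `lane_s * 2^(baseline + effect_s + N(0, dispersion))`, where `effect_s`
#' is the planted log2 fold change applied either group-wide (ordinary
#' planted miRNAs, QNBC samples only) or in carrier samples of the host
#' region (concordant miRNAs), plus any metastasis-linked shift. Negative
#' controls sit near a low constant (2), positive controls on a fixed
#' 6-step ladder, housekeeping and spike-in probes at constant levels; all
#' probes share the per-sample lane factor `lane_s = 2^N(0, lane_sd)`.
#' Counts are kept continuous so the noiseless limit is exact.
#'
#' @param config A `simulation_config`.
#' @param samples `data.frame` with `sample_id`, `group` (`"QNBC"`/`"TNBC"`)
#'   and logical `metastasis`.
#' @param carriers Logical matrix regions x samples (rownames = region
#'   labels, colnames = sample ids).
#' @return List with `counts` (probes x samples matrix) and `probe_class`.
#' @export
generate_mirna_counts <- function(config, samples, carriers) {
  panel <- config$mirna_panel
  met <- met_assoc_table(config$met_delta)
  n_s <- nrow(samples)
  lane <- 2^stats::rnorm(n_s, 0, config$lane_sd)
  effect <- matrix(0, nrow(panel), n_s,
                   dimnames = list(panel$mirna, samples$sample_id))
  for (k in seq_len(nrow(panel))) {
    if (panel$concordant[k]) {
      effect[k, ] <- panel$log2fc[k] * carriers[panel$region[k],
                                                samples$sample_id]
    } else if (panel$log2fc[k] != 0) {
      effect[k, samples$group == "QNBC"] <- panel$log2fc[k]
    }
  }
  for (k in seq_len(nrow(met))) {
    if (met$mirna[k] %in% rownames(effect)) {
      effect[met$mirna[k], samples$metastasis] <-
        effect[met$mirna[k], samples$metastasis] + met$delta[k]
    }
  }
  noise <- matrix(stats::rnorm(nrow(panel) * n_s, 0, config$dispersion),
                  nrow(panel), n_s)
  endo <- sweep(2^(panel$baseline + effect + noise), 2, lane, `*`)
  rownames(endo) <- panel$mirna

  ctrl_block <- function(ids, nominal) {
    m <- nominal * 2^matrix(stats::rnorm(length(ids) * n_s, 0,
                                         config$control_sd),
                            length(ids), n_s)
    m <- sweep(m, 2, lane, `*`)
    rownames(m) <- ids
    m
  }
  pos <- ctrl_block(sprintf("POS_%s", LETTERS[1:6]),
                    c(8192, 2048, 512, 128, 32, 8))
  neg <- ctrl_block(sprintf("NEG_%s", LETTERS[1:8]), rep(2, 8))
  hk <- ctrl_block(c("ACTB", "B2M", "GAPDH", "RPL19", "RPLP0"), rep(1024, 5))
  spk <- ctrl_block(c("ath-miR-159a", "cel-miR-248", "cel-miR-254",
                      "osa-miR-414", "osa-miR-442"), rep(256, 5))
  counts <- rbind(endo, pos, neg, hk, spk)
  colnames(counts) <- samples$sample_id
  probe_class <- c(rep("endogenous", nrow(endo)), rep("pos_ctrl", 6),
                   rep("neg_ctrl", 8), rep("housekeeping", 5),
                   rep("spike_in", 5))
  list(counts = counts, probe_class = probe_class)
}

## gene loci of the synthetic cohort: 20 universe genes inside each planted
## region, 240 on the copy-neutral chr19, and the CA20/CIN25 signature genes
## (three of them inside the 12p gain region).
synthetic_gene_loci <- function(config) {
  regions <- config$regions
  gene_rows <- list()
  idx <- 0L
  region_genes <- list()
  for (k in seq_len(nrow(regions))) {
    ids <- sprintf("GENE%03d", idx + 1:20)
    idx <- idx + 20L
    pos <- regions$start[k] +
      (seq_len(20) / 21) * (regions$end[k] - regions$start[k])
    gene_rows[[length(gene_rows) + 1L]] <-
      data.frame(feature_id = ids, chrom = regions$chrom[k],
                 start = round(pos), end = round(pos) + 5e4,
                 stringsAsFactors = FALSE)
    region_genes[[regions$label[k]]] <- ids
  }
  ids19 <- sprintf("GENE%03d", idx + 1:240)
  pos19 <- round(seq(2e5, 5.9e7, length.out = 240))
  gene_rows[[length(gene_rows) + 1L]] <-
    data.frame(feature_id = ids19, chrom = "chr19", start = pos19,
               end = pos19 + 5e4, stringsAsFactors = FALSE)
  sig <- unique(resolve_signature(c(ca20_signature(), cin25_signature())))
  in12p <- c("RAD51AP1", "FOXM1", "NCAPD2")
  rest <- setdiff(sig, in12p)
  r12 <- regions[regions$label == "12p13.33-p11.1", ]
  gene_rows[[length(gene_rows) + 1L]] <-
    data.frame(feature_id = in12p, chrom = "chr12",
               start = r12$start + c(2e6, 9e6, 16e6),
               end = r12$start + c(2e6, 9e6, 16e6) + 5e4,
               stringsAsFactors = FALSE)
  posr <- round(seq(3e5, 2.9e7, length.out = length(rest)))
  gene_rows[[length(gene_rows) + 1L]] <-
    data.frame(feature_id = rest, chrom = "chr19", start = posr,
               end = posr + 5e4, stringsAsFactors = FALSE)
  region_genes[["12p13.33-p11.1"]] <-
    c(region_genes[["12p13.33-p11.1"]], in12p)
  loci <- do.call(rbind, gene_rows)
  list(loci = loci, region_genes = region_genes,
       universe_genes = c(loci$feature_id))
}

#' Generate target-prediction tables, gene sets and a PPI edge table
#'
#' Builds three prediction tables over the synthetic gene universe so the
#' consensus and intersection results are known by construction: every
#' planted target pair appears in 2 or 3 tables, decoy pairs in exactly 1.
#' Gene sets (GMT) are seeded with planted surviving genes so enrichment is
#' detectable; the PPI edge table gives a connected high-confidence core and
#' deliberately isolated genes.
#'
#' @param config A `simulation_config`.
#' @param genes Output of the internal gene placement (region gene lists and
#'   universe); computed from `config` when `NULL`.
#' @return List: `target_tables` (named list of three `data.frame`s),
#'   `planted_pairs`, `gmt` (named list), `edges`, `network_genes` (genes
#'   with at least one edge at score >= 0.9).
#' @export
generate_target_tables <- function(config, genes = NULL) {
  if (is.null(genes)) genes <- synthetic_gene_loci(config)
  conc <- config$mirna_panel[config$mirna_panel$concordant, , drop = FALSE]
  cna_genes <- unlist(genes$region_genes, use.names = FALSE)
  neutral_genes <- setdiff(genes$universe_genes, cna_genes)
  dbs <- c("microt", "mirdb", "targetscan")
  rows <- list(microt = list(), mirdb = list(), targetscan = list())
  planted <- list()
  for (k in seq_len(nrow(conc))) {
    m <- conc$mirna[k]
    tg <- c(sample(cna_genes, 10), sample(neutral_genes, 14))
    n_db <- sample(2:3, length(tg), replace = TRUE)
    for (i in seq_along(tg)) {
      chosen <- sample(dbs, n_db[i])
      for (d in chosen) {
        rows[[d]][[length(rows[[d]]) + 1L]] <- c(m, tg[i])
      }
    }
    planted[[k]] <- data.frame(mirna = m, gene = tg, n_db = n_db,
                               stringsAsFactors = FALSE)
    decoys <- sample(setdiff(genes$universe_genes, tg), 12)
    d_db <- sample(dbs, length(decoys), replace = TRUE)
    for (i in seq_along(decoys)) {
      rows[[d_db[i]]][[length(rows[[d_db[i]]]) + 1L]] <- c(m, decoys[i])
    }
  }
  target_tables <- lapply(rows, function(r) {
    m <- do.call(rbind, r)
    data.frame(mirna = m[, 1], gene = m[, 2], stringsAsFactors = FALSE)
  })
  planted_pairs <- do.call(rbind, planted)
  surviving <- sort(unique(planted_pairs$gene[planted_pairs$gene %in%
                                                cna_genes]))
  gmt <- list(
    GENOMIC_INSTABILITY_RESPONSE = unique(c(utils::head(surviving, 12),
                                            sample(neutral_genes, 8))),
    CELL_CYCLE_CORE = unique(c(utils::head(rev(surviving), 12),
                               sample(neutral_genes, 8)))
  )
  for (i in 1:4) {
    gmt[[sprintf("RANDOM_SET_%d", i)]] <- sample(genes$universe_genes, 25)
  }
  ## PPI: a connected high-confidence core over ~3/4 of the surviving genes
  n_core <- max(2L, ceiling(0.75 * length(surviving)))
  core <- utils::head(surviving, n_core)
  iso <- setdiff(surviving, core)
  edges <- data.frame(node_a = core,
                      node_b = c(core[-1], core[1]),
                      score = round(stats::runif(length(core), 0.91, 0.99), 3),
                      stringsAsFactors = FALSE)
  extra <- data.frame(
    node_a = sample(core, max(1L, length(core) %/% 2), replace = TRUE),
    node_b = sample(core, max(1L, length(core) %/% 2), replace = TRUE),
    score = round(stats::runif(max(1L, length(core) %/% 2), 0.91, 0.99), 3),
    stringsAsFactors = FALSE
  )
  low <- if (length(iso)) data.frame(
    node_a = iso, node_b = sample(core, length(iso), replace = TRUE),
    score = round(stats::runif(length(iso), 0.30, 0.85), 3),
    stringsAsFactors = FALSE
  ) else NULL
  noise <- data.frame(node_a = sample(neutral_genes, 20),
                      node_b = sample(neutral_genes, 20),
                      score = round(stats::runif(20, 0.2, 0.95), 3),
                      stringsAsFactors = FALSE)
  edges <- rbind(edges, extra, low, noise)
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  high <- edges[edges$score >= 0.9, , drop = FALSE]
  network_genes <- sort(unique(c(high$node_a, high$node_b)))
  list(target_tables = target_tables, planted_pairs = planted_pairs,
       gmt = gmt, edges = edges, network_genes = network_genes)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes, under `dir`: a cytoband table (`cytobands.txt`), miRNA and gene
#' locus BED files, one probe-level aCGH table per profiled sample
#' (`acgh/<sample>.tsv`), the raw miRNA count matrix (`mirna_counts.csv`),
#' three target-prediction tables (`targets/`), a GMT file, a PPI edge
#' table, the clinical table, a `groups.tsv` sample sheet, and the
#' ground-truth manifest (`manifest.json`). The same configuration always
#' produces byte-identical files.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if missing).
#' @return The ground-truth manifest, invisibly; also serialized as JSON.
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dir.create(file.path(dir, "acgh"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "targets"), showWarnings = FALSE)

  samples <- data.frame(
    sample_id = c(sprintf("QNBC_%02d", seq_len(config$n_qnbc)),
                  sprintf("TNBC_%02d", seq_len(config$n_tnbc))),
    group = c(rep("QNBC", config$n_qnbc), rep("TNBC", config$n_tnbc)),
    stringsAsFactors = FALSE
  )
  samples$has_acgh <- c(seq_len(config$n_qnbc) <= config$n_acgh_qnbc,
                        seq_len(config$n_tnbc) <= config$n_acgh_tnbc)
  samples$has_expression <- c(seq_len(config$n_qnbc) <= config$n_expr_qnbc,
                              seq_len(config$n_tnbc) <= config$n_expr_tnbc)

  ## 1. carriers of the planted regions
  regions <- config$regions
  carriers <- matrix(FALSE, nrow(regions), nrow(samples),
                     dimnames = list(regions$label, samples$sample_id))
  for (k in seq_len(nrow(regions))) {
    p <- ifelse(samples$group == "QNBC", regions$freq_qnbc[k],
                regions$freq_tnbc[k])
    carriers[k, ] <- stats::runif(nrow(samples)) < p
  }

  ## 2. private segments on the filler chromosomes
  filler <- c("chr2", "chr5")
  chrom_len <- tapply(config$genome$end, config$genome$chrom, max)
  sp <- config$probe_spacing_bp
  lam <- ifelse(samples$group == "QNBC", config$private_lambda[["qnbc"]],
                config$private_lambda[["tnbc"]])
  private <- list()
  for (s in seq_len(nrow(samples))) {
    k <- stats::rpois(1, lam[s])
    segs <- list()
    used <- list(chr2 = integer(), chr5 = integer())
    tries <- 0L
    while (length(segs) < k && tries < 20L * max(k, 1L)) {
      tries <- tries + 1L
      chr <- sample(filler, 1)
      n_probe <- sample(5:12, 1)
      max_i <- floor(chrom_len[[chr]] / sp) - n_probe
      i <- sample(max_i, 1)
      idx <- i:(i + n_probe)  # one-probe buffer on each side
      if (any(idx %in% used[[chr]])) next
      used[[chr]] <- c(used[[chr]], (i - 1L):(i + n_probe + 1L))
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr, start = (i - 1L) * sp, end = (i - 1L + n_probe) * sp,
        amplitude = sample(c(-0.6, 0.6), 1), stringsAsFactors = FALSE
      )
    }
    private[[samples$sample_id[s]]] <-
      if (length(segs)) do.call(rbind, segs) else NULL
  }

  ## 3. probe tables for the aCGH samples
  probe_grid <- do.call(rbind, lapply(names(chrom_len), function(chr) {
    starts <- seq(0, chrom_len[[chr]] - sp, by = sp)
    data.frame(chrom = chr, start = starts, end = starts + 60,
               stringsAsFactors = FALSE)
  }))
  probe_grid <- probe_grid[order(probe_grid$chrom, probe_grid$start), ]
  probe_grid$probe_id <- sprintf("P%05d", seq_len(nrow(probe_grid)))
  for (s in which(samples$has_acgh)) {
    sid <- samples$sample_id[s]
    lr <- stats::rnorm(nrow(probe_grid), 0, config$probe_noise_sd)
    for (k in seq_len(nrow(regions))) {
      if (!carriers[k, sid]) next
      hit <- probe_grid$chrom == regions$chrom[k] &
        probe_grid$start >= regions$start[k] &
        probe_grid$start < regions$end[k]
      lr[hit] <- lr[hit] + regions$amplitude[k]
    }
    pv <- private[[sid]]
    if (!is.null(pv)) {
      for (k in seq_len(nrow(pv))) {
        hit <- probe_grid$chrom == pv$chrom[k] &
          probe_grid$start >= pv$start[k] & probe_grid$start < pv$end[k]
        lr[hit] <- lr[hit] + pv$amplitude[k]
      }
    }
    tab <- data.frame(probe_id = probe_grid$probe_id,
                      chrom = probe_grid$chrom,
                      start = probe_grid$start, end = probe_grid$end,
                      log2_ratio = sprintf("%.6f", lr),
                      stringsAsFactors = FALSE)
    write_tsv(tab, file.path(dir, "acgh", paste0(sid, ".tsv")))
  }

  ## 4. clinical table
  n_s <- nrow(samples)
  clinical <- data.frame(
    sample_id = samples$sample_id, group = samples$group,
    age = round(stats::rnorm(n_s, 52, 10.2), 1),
    tumor_size = round(pmax(stats::rnorm(n_s, 3, 1.8), 0.3), 1),
    race = ifelse(stats::runif(n_s) < 0.1, NA,
                  ifelse(stats::runif(n_s) < 0.45, "AA", "EA")),
    node_status = stats::rbinom(n_s, 1, 0.45),
    metastasis = stats::rbinom(n_s, 1, 0.25),
    recurrence = stats::rbinom(n_s, 1, 0.12),
    stringsAsFactors = FALSE
  )
  samples$metastasis <- clinical$metastasis == 1

  ## 5. miRNA counts for the expression samples
  expr_samples <- samples[samples$has_expression, , drop = FALSE]
  cm <- generate_mirna_counts(config, expr_samples,
                              carriers[, expr_samples$sample_id,
                                       drop = FALSE])
  counts_df <- data.frame(mirna = rownames(cm$counts),
                          matrix(sprintf("%.4f", cm$counts),
                                 nrow = nrow(cm$counts),
                                 dimnames = list(NULL,
                                                 colnames(cm$counts))),
                          probe_class = cm$probe_class, check.names = FALSE,
                          stringsAsFactors = FALSE)
  utils::write.csv(counts_df, file.path(dir, "mirna_counts.csv"),
                   row.names = FALSE, quote = FALSE)

  ## 6. annotation files
  cyto <- data.frame(chrom = config$genome$chrom,
                     start = format(config$genome$start, scientific = FALSE,
                                    trim = TRUE),
                     end = format(config$genome$end, scientific = FALSE,
                                  trim = TRUE),
                     band = config$genome$band, stain = "gneg")
  utils::write.table(cyto, file.path(dir, "cytobands.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  panel <- config$mirna_panel
  mirna_bed <- data.frame(chrom = panel$chrom,
                          start = format(panel$start, scientific = FALSE,
                                         trim = TRUE),
                          end = format(panel$end, scientific = FALSE,
                                       trim = TRUE),
                          name = panel$mirna, score = 0, strand = "+")
  utils::write.table(mirna_bed, file.path(dir, "mirna_loci.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  genes <- synthetic_gene_loci(config)
  gene_bed <- data.frame(chrom = genes$loci$chrom,
                         start = format(genes$loci$start,
                                        scientific = FALSE, trim = TRUE),
                         end = format(genes$loci$end, scientific = FALSE,
                                      trim = TRUE),
                         name = genes$loci$feature_id, score = 0,
                         strand = "+")
  utils::write.table(gene_bed, file.path(dir, "gene_loci.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## 7. target tables, gene sets, PPI edges
  tt <- generate_target_tables(config, genes)
  for (d in names(tt$target_tables)) {
    write_tsv(tt$target_tables[[d]],
              file.path(dir, "targets", paste0(d, ".tsv")))
  }
  gmt_lines <- vapply(names(tt$gmt), function(s) {
    paste(c(s, "synthetic", tt$gmt[[s]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, file.path(dir, "gene_sets.gmt"))
  write_tsv(tt$edges, file.path(dir, "ppi_edges.tsv"))
  utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tsv(samples, file.path(dir, "groups.tsv"))

  ## 8. ground-truth manifest
  acgh_q <- samples$sample_id[samples$has_acgh & samples$group == "QNBC"]
  acgh_t <- samples$sample_id[samples$has_acgh & samples$group == "TNBC"]
  regions$realized_freq_qnbc <-
    100 * rowMeans(carriers[, acgh_q, drop = FALSE])
  regions$realized_freq_tnbc <-
    100 * rowMeans(carriers[, acgh_t, drop = FALSE])
  manifest <- list(
    seed = config$seed,
    samples = samples,
    regions = regions[, c("label", "chrom", "start", "end", "direction",
                          "amplitude", "freq_qnbc", "freq_tnbc",
                          "realized_freq_qnbc", "realized_freq_tnbc")],
    carriers = as.data.frame(carriers),
    mirnas = panel[panel$log2fc != 0,
                   c("mirna", "chrom", "start", "end", "log2fc",
                     "concordant", "region")],
    region_genes = genes$region_genes,
    planted_pairs = tt$planted_pairs,
    network_genes = tt$network_genes,
    clinical_assoc = met_assoc_table(config$met_delta),
    n_private_segments = vapply(samples$sample_id, function(s) {
      p <- private[[s]]; if (is.null(p)) 0L else nrow(p)
    }, integer(1))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(manifest)
}

#' Closed-form expected integration output in the noiseless limit
#'
#' From a ground-truth manifest, computes which planted regions pass the
#' frequency filter (realized QNBC carrier frequency among aCGH samples),
#' hence which concordant miRNAs and which surviving target genes a
#' noiseless pipeline run must return exactly.
#'
#' @param manifest Manifest returned by [generate_cohort()].
#' @param min_frequency Frequency threshold as a proportion (default 0.25).
#' @return List: `retained_regions`, `concordant_mirnas`,
#'   `surviving_genes`.
#' @export
expected_integration <- function(manifest, min_frequency = 0.25) {
  retained <- manifest$regions$label[
    manifest$regions$realized_freq_qnbc >= 100 * min_frequency]
  conc <- manifest$mirnas[manifest$mirnas$concordant &
                            manifest$mirnas$region %in% retained, ]
  cna_genes <- unlist(manifest$region_genes[retained], use.names = FALSE)
  surviving <- sort(unique(
    manifest$planted_pairs$gene[manifest$planted_pairs$gene %in% cna_genes]))
  list(retained_regions = retained,
       concordant_mirnas = sort(conc$mirna),
       surviving_genes = surviving)
}
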