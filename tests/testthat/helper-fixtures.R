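## Shared fixtures and independent oracles. Every oracle here is written as
## a direct, naive computation so it shares no code path with the package
## implementation it checks.

write_toy_cytobands <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

## a small three-chromosome cytoband table
toy_cytoband_table <- function() {
  read_cytoband_table(write_toy_cytobands(list(
    c("chr4", "0", "10000000", "p16.3", "gneg"),
    c("chr4", "10000000", "20000000", "p15", "gpos50"),
    c("chr4", "20000000", "30000000", "p12", "gneg"),
    c("chr4", "30000000", "60000000", "q12", "gneg"),
    c("chr8", "0", "36500000", "p12", "gneg"),
    c("chr8", "36500000", "45000000", "p11.11", "gneg"),
    c("chr8", "45000000", "60000000", "q11.1", "gneg"),
    c("chr8", "60000000", "90000000", "q24.21", "gneg"),
    c("chr9", "0", "20000000", "p24", "gneg"),
    c("chr9", "20000000", "40000000", "q13", "gneg")
  )))
}

## probe table straight from vectors (already the reader's output shape)
make_probes <- function(log2, chrom = "chr1", spacing = 1e5) {
  n <- length(log2)
  data.frame(probe_id = sprintf("P%04d", seq_len(n)), chrom = chrom,
             start = (seq_len(n) - 1) * spacing,
             end = (seq_len(n) - 1) * spacing + 60,
             log2_ratio = log2, stringsAsFactors = FALSE)
}

## ---- oracle: exhaustive interval-score aberration caller -----------------
## Scores every interval with a double loop, resolves overlaps by repeatedly
## accepting the best remaining candidate (score desc, leftmost, longest),
## then filters survivors.
oracle_call_aberrations <- function(log2, score_threshold = 6,
                                    min_probes = 3, min_abs = 0.25) {
  n <- length(log2)
  d <- log2[-1] - log2[-n]
  sigma <- max(stats::median(abs(d - stats::median(d))) / 0.6745 / sqrt(2),
               1e-8)
  cand <- list()
  cs <- c(0, cumsum(log2))
  for (i in seq_len(n)) {
    for (j in i:n) {
      w <- j - i + 1L
      mu <- (cs[j + 1] - cs[i]) / w
      sc <- abs(mu) * sqrt(w) / sigma
      if (sc >= score_threshold) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j, w = w, mu = mu, sc = sc)
      }
    }
  }
  if (!length(cand)) return(NULL)
  cand <- as.data.frame(do.call(rbind, cand))
  cand <- cand[order(-cand$sc, cand$i, -cand$w), ]
  picked <- list()
  while (nrow(cand) > 0) {
    a <- cand[1, ]
    cand <- cand[cand$j < a$i | cand$i > a$j, , drop = FALSE]
    if (a$w >= min_probes && abs(a$mu) > min_abs) {
      picked[[length(picked) + 1L]] <- a
    }
  }
  if (!length(picked)) return(NULL)
  res <- do.call(rbind, picked)
  res[order(res$i), , drop = FALSE]
}

## ---- oracle: AUC by exhaustive pair counting -----------------------------
oracle_auc <- function(values, labels) {
  lev <- sort(unique(as.character(labels)))
  x <- values[labels == lev[1]]
  y <- values[labels == lev[2]]
  conc <- 0
  for (a in x) for (b in y) {
    conc <- conc + if (b > a) 1 else if (b == a) 0.5 else 0
  }
  p <- conc / (length(x) * length(y))
  max(p, 1 - p)  # orientation-free
}

## ---- oracle: Benjamini-Hochberg step-up ----------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## ---- oracle: upper-tail hypergeometric by explicit combinatorics ---------
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## ---- oracle: two-sided Fisher exact p for a 2x2 table --------------------
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- choose(r1, support) * choose(N - r1, c1 - support) / choose(N, c1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## ---- oracle: naive average-linkage agglomeration heights -----------------
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

## small raw count matrix with controls, for normalization tests
make_raw_counts <- function(endo, pos, neg) {
  counts <- rbind(endo, pos, neg)
  structure(list(counts = counts,
                 probe_class = c(rep("endogenous", nrow(endo)),
                                 rep("pos_ctrl", nrow(pos)),
                                 rep("neg_ctrl", nrow(neg)))),
            class = "raw_counts")
}
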