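#' Library-size normalization to the median depth
#'
#' Scales every cell's counts so that all cells have the median library
#' size: counts-per-median-depth. Cells with zero depth are left at zero.
#'
#' @param counts Genes x cells count matrix.
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts) {
  depth <- colSums(counts)
  target <- stats::median(depth[depth > 0])
  factors <- ifelse(depth > 0, target / depth, 0)
  sweep(counts, 2, factors, `*`)
}

# internal: vectorized two-sided Mann-Whitney rank-sum test per gene row,
# normal approximation with tie correction and continuity correction
# (cross-checked against stats::wilcox.test in the test suite)
ranksum_rows <- function(x, in_a) {
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  n <- n_a + n_b
  res <- t(apply(x, 1, function(row) {
    r <- rank(row)
    u <- sum(r[in_a]) - n_a * (n_a + 1) / 2
    ties <- table(row)
    tie_term <- sum(ties^3 - ties)
    c(u = u, tie = tie_term)
  }))
  u <- res[, "u"]
  mu <- n_a * n_b / 2
  sigma2 <- n_a * n_b / 12 * ((n + 1) - res[, "tie"] / (n * (n - 1)))
  z <- numeric(length(u))
  ok <- sigma2 > 0
  # continuity correction toward the mean
  z[ok] <- (u[ok] - mu - sign(u[ok] - mu) * 0.5) / sqrt(sigma2[ok])
  z[abs(u - mu) <= 0.5] <- 0
  p <- ifelse(ok, 2 * stats::pnorm(-abs(z)), 1)
  p <- pmin(p, 1)
  data.frame(stat = z, p = p)
}

#' Rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on library-size-normalized
#' counts (normal approximation with tie and continuity corrections),
#' Benjamini-Hochberg correction across genes, and log2 fold-changes of
#' pseudocounted group means (first group over second). Genes with all-zero
#' counts are carried through with `p = fdr = 1` and `log2fc = 0`.
#'
#' @param counts Genes x cells integer matrix.
#' @param groups Factor of length `ncol(counts)` with exactly two levels;
#'   fold-changes are level 1 over level 2.
#' @return Data frame (one row per gene): `gene`, `log2fc`, `stat`, `p`,
#'   `fdr`.
#' @export
differential_expression <- function(counts, groups) {
  stopifnot(is.matrix(counts), ncol(counts) == length(groups))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2) {
    stop("need at least 2 cells per group", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  norm <- normalize_counts(counts)
  in_a <- groups == levels(groups)[1]
  mean_a <- rowMeans(norm[, in_a, drop = FALSE])
  mean_b <- rowMeans(norm[, !in_a, drop = FALSE])
  log2fc <- log2((mean_a + 1) / (mean_b + 1))
  ts <- ranksum_rows(norm, in_a)
  zero <- rowSums(counts) == 0
  ts$p[zero] <- 1
  ts$stat[zero] <- 0
  log2fc[zero] <- 0
  fdr <- stats::p.adjust(ts$p, method = "BH")
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(counts)))
  data.frame(gene = genes, log2fc = log2fc, stat = ts$stat, p = ts$p,
             fdr = fdr, row.names = NULL)
}

#' Derive a dormancy signature from differential-expression results
#'
#' Genes passing both the FDR and the absolute log2 fold-change thresholds,
#' split by direction (up = higher in the first group) and ranked by
#' significance. When two DE tables are supplied (e.g. a bulk and a
#' single-cell analysis), a gene must pass the thresholds in both with a
#' consistent fold-change direction, and is ranked by its worse p-value.
#'
#' @param de A DE table from [differential_expression()], or a list of two
#'   such tables for the integrated mode.
#' @param fdr_max Maximum FDR (inclusive).
#' @param min_abs_log2fc Minimum absolute log2 fold-change (strict `>`).
#' @return Data frame of class `"signature"`: `gene`, `direction`
#'   (`up`/`down`), `log2fc`, `fdr`, `rank`. May be empty.
#' @export
derive_signature <- function(de, fdr_max = 0.05, min_abs_log2fc = 1) {
  stopifnot(fdr_max >= 0, min_abs_log2fc >= 0)
  pass <- function(tab) {
    tab[tab$fdr <= fdr_max & abs(tab$log2fc) > min_abs_log2fc, ,
        drop = FALSE]
  }
  if (is.data.frame(de)) {
    hits <- pass(de)
    hits <- hits[order(hits$p, -abs(hits$log2fc)), , drop = FALSE]
  } else {
    stopifnot(is.list(de), length(de) == 2)
    a <- pass(de[[1]])
    b <- pass(de[[2]])
    common <- intersect(a$gene, b$gene)
    a <- a[match(common, a$gene), , drop = FALSE]
    b <- b[match(common, b$gene), , drop = FALSE]
    same_dir <- sign(a$log2fc) == sign(b$log2fc)
    a <- a[same_dir, , drop = FALSE]
    b <- b[same_dir, , drop = FALSE]
    a$p <- pmax(a$p, b$p)
    a$fdr <- pmax(a$fdr, b$fdr)
    hits <- a[order(a$p, -abs(a$log2fc)), , drop = FALSE]
  }
  out <- data.frame(
    gene = hits$gene,
    direction = ifelse(hits$log2fc > 0, "up", "down"),
    log2fc = hits$log2fc,
    fdr = hits$fdr,
    rank = seq_len(nrow(hits)),
    row.names = NULL
  )
  class(out) <- c("signature", "data.frame")
  out
}

# internal: extract gene (and direction) vectors from a signature or
# character vector
signature_genes <- function(sig) {
  if (is.data.frame(sig)) {
    list(genes = sig$gene,
         up = sig$gene[sig$direction == "up"],
         down = sig$gene[sig$direction == "down"])
  } else {
    list(genes = as.character(sig), up = NULL, down = NULL)
  }
}

#' Hypergeometric test of signature overlap
#'
#' Exact upper-tail hypergeometric probability of observing at least the
#' realized overlap between two gene signatures drawn from a common
#' universe. With `directional = TRUE` only matching-direction overlaps
#' (up-with-up plus down-with-down) are counted as hits.
#'
#' @param sig_a,sig_b `"signature"` objects or character vectors of genes.
#' @param universe_size Size of the gene universe, or a character vector of
#'   universe genes (membership then checked).
#' @param directional Count only matching-direction overlaps.
#' @return A list: `overlap`, `size_a`, `size_b`, `universe_size`,
#'   `p_value`.
#' @export
overlap_test <- function(sig_a, sig_b, universe_size, directional = FALSE) {
  a <- signature_genes(sig_a)
  b <- signature_genes(sig_b)
  if (anyDuplicated(a$genes) || anyDuplicated(b$genes)) {
    stop("signature genes must be unique", call. = FALSE)
  }
  if (is.character(universe_size)) {
    universe <- universe_size
    outside <- setdiff(c(a$genes, b$genes), universe)
    if (length(outside)) {
      stop("genes outside the universe: ",
           paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    }
    universe_size <- length(universe)
  }
  n_union <- length(union(a$genes, b$genes))
  if (universe_size < n_union) {
    stop("universe smaller than the union of the signatures", call. = FALSE)
  }
  overlap <- if (directional) {
    if (is.null(a$up) || is.null(b$up)) {
      stop("directional overlap requires signatures with directions",
           call. = FALSE)
    }
    length(intersect(a$up, b$up)) + length(intersect(a$down, b$down))
  } else {
    length(intersect(a$genes, b$genes))
  }
  n_a <- length(a$genes)
  n_b <- length(b$genes)
  p <- stats::phyper(overlap - 1, n_a, universe_size - n_a, n_b,
                     lower.tail = FALSE)
  list(overlap = overlap, size_a = n_a, size_b = n_b,
       universe_size = universe_size, p_value = p)
}

#' Fold-change sign concordance between two DE analyses
#'
#' Over a gene set present in both DE tables, the fraction of genes whose
#' fold-changes agree in sign, with a two-sided binomial test against
#' chance agreement (0.5). Genes with a zero fold-change in either table
#' are excluded.
#'
#' @param de_a,de_b DE tables (see [differential_expression()]).
#' @param gene_set Character vector of genes to compare.
#' @return A list: `agreement`, `n_agree`, `n`, `p_value`.
#' @export
concordance <- function(de_a, de_b, gene_set) {
  common <- intersect(intersect(gene_set, de_a$gene), de_b$gene)
  if (length(common) == 0) {
    stop("empty intersection of gene set and DE tables", call. = FALSE)
  }
  fa <- de_a$log2fc[match(common, de_a$gene)]
  fb <- de_b$log2fc[match(common, de_b$gene)]
  keep <- fa != 0 & fb != 0
  fa <- fa[keep]
  fb <- fb[keep]
  if (length(fa) == 0) {
    stop("no genes with nonzero fold-changes in both tables", call. = FALSE)
  }
  n_agree <- sum(sign(fa) == sign(fb))
  bt <- stats::binom.test(n_agree, length(fa), p = 0.5)
  list(agreement = n_agree / length(fa), n_agree = n_agree,
       n = length(fa), p_value = bt$p.value)
}

# internal: signed running-sum enrichment score of a hit indicator over a
# ranked list; value at the maximum absolute deviation
running_sum_es <- function(hit, weights, weighted) {
  n <- length(hit)
  n_set <- sum(hit)
  incr <- if (weighted) {
    w <- abs(weights)
    sw <- sum(w[hit])
    if (sw == 0) rep(1 / n_set, n) else w / sw
  } else {
    rep(1 / n_set, n)
  }
  step <- ifelse(hit, incr, -1 / (n - n_set))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Rank enrichment of a signature in an ordered gene list
#'
#' Weighted running-sum enrichment: walking down the ranked list, signature
#' hits increment the running sum proportionally to the absolute ranking
#' statistic (or uniformly in unweighted mode) and misses decrement it
#' uniformly; the enrichment score is the running sum at its maximum
#' absolute deviation. Significance comes from a gene-label permutation
#' null: signature positions are re-drawn at random and the p-value counts
#' permuted scores whose magnitude reaches the observed magnitude
#' (two-sided, so the p-value is uniform under a randomly placed
#' signature).
#'
#' @param signature A `"signature"` object or character vector, a subset of
#'   the ranked list.
#' @param ranked_stats Named numeric vector of per-gene ranking statistics;
#'   ordered by decreasing statistic before scoring.
#' @param n_perm Number of gene-set permutations (>= 100 recommended).
#' @param weighted Weight hits by the absolute statistic.
#' @param seed Optional RNG seed for the permutation null.
#' @return A list: `es`, `p_value`, `n_set`, `n_list`, `n_perm`.
#' @export
rank_enrichment <- function(signature, ranked_stats, n_perm = 1000,
                            weighted = TRUE, seed = NULL) {
  genes <- signature_genes(signature)$genes
  stopifnot(!is.null(names(ranked_stats)), n_perm >= 1)
  ranked_stats <- sort(ranked_stats, decreasing = TRUE)
  gene_order <- names(ranked_stats)
  if (length(genes) >= length(gene_order)) {
    stop("signature must be smaller than the ranked list", call. = FALSE)
  }
  if (!all(genes %in% gene_order)) {
    stop("signature genes missing from the ranked list", call. = FALSE)
  }
  hit <- gene_order %in% genes
  es <- running_sum_es(hit, ranked_stats, weighted)
  if (!is.null(seed)) set.seed(seed)
  n <- length(gene_order)
  n_set <- length(genes)
  es_perm <- vapply(seq_len(n_perm), function(i) {
    h <- logical(n)
    h[sample.int(n, n_set)] <- TRUE
    running_sum_es(h, ranked_stats, weighted)
  }, numeric(1))
  extreme <- sum(abs(es_perm) >= abs(es))
  list(es = es, p_value = (1 + extreme) / (n_perm + 1),
       n_set = n_set, n_list = n, n_perm = n_perm)
}
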