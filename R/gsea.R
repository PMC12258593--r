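#' Rank genes by log2 fold change
#'
#' Orders a named score vector by decreasing score, breaking ties by gene id
#' so the ranking is deterministic.
#'
#' @param scores named numeric vector (names = gene ids).
#' @return the reordered named vector.
#' @export
rank_genes <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be named by unique gene ids")
  }
  scores[order(-scores, names(scores))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating |score|^p / sum(|score|^p over hits)
#' at gene-set hits and -1/(N - N_hits) at misses. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero; the
#' leading edge ("core enrichment") holds the set members at or before the
#' peak for positive ES, and at or after it for negative ES.
#'
#' @param ranked named score vector already ordered (see \code{rank_genes}).
#' @param gene_set character vector of gene ids.
#' @param p weight exponent (1 = classic weighted statistic).
#' @return list: es, peak (position), running_sum, leading_edge, hits.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no overlap with the ranked list")
  if (nh == length(ranked)) stop("gene set covers the entire ranked list")
  w <- abs(ranked)^p
  wh <- sum(w[hit])
  step <- ifelse(hit,
                 if (wh > 0) w / wh else 1 / nh,   # all-zero scores: flat weights
                 -1 / (length(ranked) - nh))
  if (wh == 0) step[!hit] <- -1 / (length(ranked) - nh)
  rs <- cumsum(step)
  # first position attaining the maximal |deviation| (1e-9 tie tolerance,
  # so floating-point noise cannot flip between +/- ties)
  peak <- which(abs(rs) >= max(abs(rs)) - 1e-9)[1]
  es <- rs[peak]
  le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
        else genes[peak:length(genes)][hit[peak:length(genes)]]
  list(es = es, peak = peak, running_sum = rs, leading_edge = le,
       hits = which(hit))
}

# ES for a hit-index set without materializing the full running sum.
# The running sum is linear between hits, so its extrema occur just before
# or at hit positions (and at the final position).
es_from_hits <- function(w_all, hit_idx, n) {
  k <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  wh <- w_all[hit_idx]
  sw <- sum(wh)
  inc <- if (sw > 0) wh / sw else rep(1 / k, k)
  miss_step <- 1 / (n - k)
  at_hit <- cumsum(inc) - (hit_idx - seq_len(k)) * miss_step
  before_hit <- at_hit - inc
  # interleave so candidate order follows list position (before hit i comes
  # just before at hit i), matching the full running sum's first-tie rule
  cand <- as.numeric(rbind(before_hit, at_hit))
  cand[which(abs(cand) >= max(abs(cand)) - 1e-9)[1]]
}

#' Permutation-normalized enrichment score and p-value
#'
#' Gene-label permutations preserving the set size: random sets of the same
#' size are drawn from the ranked list. NES = ES divided by the mean |ES| of
#' same-sign permutations; p = (1 + #{same-sign |perm ES| >= |ES|}) /
#' (1 + #same-sign permutations).
#'
#' @param ranked named, ordered score vector.
#' @param gene_set gene ids.
#' @param n_perm number of permutations (>= 100).
#' @param p weight exponent.
#' @param seed RNG seed.
#' @return list: es, nes, p_value, leading_edge, n_perm_same_sign.
#' @export
normalize_es <- function(ranked, gene_set, n_perm = 1000, p = 1, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  res <- enrichment_score(ranked, gene_set, p)
  n <- length(ranked)
  k <- length(res$hits)
  w_all <- abs(ranked)^p
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_hits(w_all, sample.int(n, k), n)
    }, numeric(1))
  })
  if (res$es == 0) {
    return(list(es = 0, nes = 0, p_value = 1,
                leading_edge = res$leading_edge, n_perm_same_sign = 0L))
  }
  same <- perm[sign(perm) == sign(res$es)]
  if (!length(same)) {
    warning("no same-sign permutation ES; p reported as 1")
    return(list(es = res$es, nes = NA_real_, p_value = 1,
                leading_edge = res$leading_edge, n_perm_same_sign = 0L))
  }
  nes <- res$es / mean(abs(same))
  pval <- (1 + sum(abs(same) >= abs(res$es))) / (1 + length(same))
  list(es = res$es, nes = nes, p_value = pval,
       leading_edge = res$leading_edge, n_perm_same_sign = length(same))
}

#' GSEA over a gene-set collection
#'
#' @param ranked named, ordered score vector (use \code{rank_genes}).
#' @param gene_sets named list of gene-id vectors (e.g. from
#'   \code{read_gmt}).
#' @inheritParams normalize_es
#' @return data.frame: set_id, size, es, nes, p_value, leading_edge
#'   (comma-joined).
#' @export
gsea <- function(ranked, gene_sets, n_perm = 1000, p = 1, seed = 1) {
  rows <- lapply(names(gene_sets), function(id) {
    gs <- intersect(gene_sets[[id]], names(ranked))
    if (!length(gs) || length(gs) == length(ranked)) return(NULL)
    r <- normalize_es(ranked, gs, n_perm = n_perm, p = p,
                      seed = substream_seed(seed, match(id, names(gene_sets))))
    data.frame(set_id = id, size = length(gs), es = r$es, nes = r$nes,
               p_value = r$p_value,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each set's overlap with the foreground
#' against the background universe, with fold enrichment (k/n)/(K/N) and BH
#' adjustment across sets.
#'
#' @param foreground character vector of genes of interest (subset of
#'   background).
#' @param background universe of genes.
#' @param gene_sets named list of gene-id vectors.
#' @return data.frame: set_id, overlap k, set size K (in universe),
#'   fold_enrichment, p_value, q_value.
#' @export
ora_hypergeometric <- function(foreground, background, gene_sets) {
  if (!length(foreground)) stop("empty foreground")
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background")
  }
  N <- length(unique(background))
  n <- length(unique(foreground))
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], background)
    K <- length(set)
    k <- length(intersect(set, foreground))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(set_id = id, k = k, K = K, fold_enrichment = fold,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: set id, description, then member genes, tab-separated.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}
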