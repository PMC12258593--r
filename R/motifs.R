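DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' Builds a PWM from a probability or count matrix (4 x width, rows A,C,G,T).
#' Count matrices are regularized with a background-distributed pseudocount
#' (JASPAR-style, default 0.8) and converted to column-stochastic
#' probabilities.
#'
#' @param mat 4 x width numeric matrix, rows in A,C,G,T order.
#' @param id motif identifier.
#' @param background background base probabilities (length 4, sums to 1).
#' @param pseudocount total pseudocount added per column for count input.
#' @param is_counts treat \code{mat} as counts (default: TRUE when any
#'   entry exceeds 1).
#' @return object of class \code{pwm}: id, width, probs, background,
#'   score_matrix (log2 probability/background).
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.8, is_counts = any(mat > 1)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 2) stop("PWM width must be >= 2")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (!is_counts && pseudocount > 0) {
    # treat probabilities as unit-total counts for regularization
    mat <- sweep(mat, 2, colSums(mat), "/")
  }
  probs <- mat + pseudocount * matrix(background, 4, ncol(mat))
  probs <- sweep(probs, 2, colSums(probs), "/")
  dimnames(probs) <- list(DNA_BASES, NULL)
  structure(list(id = id, width = ncol(probs), probs = probs,
                 background = setNames(background, DNA_BASES),
                 score_matrix = log2(probs / background)),
            class = "pwm")
}

#' Synthetic TATA-box PWM
#'
#' A consensus-derived TATA-box matrix (consensus TATAAAAG with moderate
#' degeneracy), standing in for a core-promoter TATA motif. This matrix is
#' synthetic: it is generated from the consensus, not taken from a motif
#' database.
#'
#' @param conc concentration of the consensus base (probability mass).
#' @return a \code{pwm}.
#' @export
tata_pwm <- function(conc = 0.85) {
  cons <- strsplit(tata_consensus(), "")[[1]]
  mat <- sapply(cons, function(b) {
    p <- rep((1 - conc) / 3, 4)
    p[match(b, DNA_BASES)] <- conc
    p
  })
  rownames(mat) <- DNA_BASES
  pwm(mat, id = "TATA_synthetic", is_counts = FALSE, pseudocount = 0)
}

#' Exact PWM score distribution and p-values
#'
#' Dynamic programme over motif positions: scores are discretized to
#' \code{bin}-width bins and the distribution of the window score under the
#' background model is built by convolution. The returned function maps a
#' score to P(score' >= score) under the null.
#'
#' @param x a \code{pwm}.
#' @param bin score bin width in bits.
#' @return list: breaks (bin left edges), pmf, pval_fun (score -> p).
#' @export
pwm_score_distribution <- function(x, bin = 0.01) {
  sm <- x$score_matrix
  smi <- round(sm / bin)                      # integer bin indices
  lo <- sum(apply(smi, 2, min))
  hi <- sum(apply(smi, 2, max))
  pmf <- c(1, numeric(hi - lo))               # offset: index 1 == lo
  off <- 0
  cur_lo <- 0
  for (j in seq_len(ncol(smi))) {
    new <- numeric(length(pmf) + max(smi[, j]) - min(smi[, j]))
    new_lo <- cur_lo + min(smi[, j])
    for (b in 1:4) {
      sh <- smi[b, j] - min(smi[, j])
      idx <- seq_along(pmf) + sh
      new[idx] <- new[idx] + pmf * x$background[b]
    }
    pmf <- new
    cur_lo <- new_lo
  }
  sf <- rev(cumsum(rev(pmf)))                 # survival: P(S >= bin)
  pval_fun <- function(score) {
    k <- round(score / bin) - lo + 1
    k <- pmin(pmax(k, 1), length(sf) + 1)
    ifelse(k > length(sf), 0, sf[k])
  }
  list(breaks = (seq_along(pmf) - 1 + lo) * bin, pmf = pmf,
       pval_fun = pval_fun)
}

seq_to_chars <- function(s) strsplit(toupper(as.character(s)), "")[[1]]

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Log-odds scores of every window of one strand of one sequence; windows
# containing non-ACGT characters are NA.
window_scores <- function(chars, x) {
  w <- x$width
  n <- length(chars)
  if (n < w) return(numeric(0))
  idx <- match(chars, DNA_BASES)              # NA for N etc.
  sc <- numeric(n - w + 1)
  for (j in seq_len(w)) {
    v <- x$score_matrix[cbind(idx[j:(j + n - w)], j)]
    sc <- sc + v
  }
  sc
}

#' Scan sequences with a PWM at an exact p-value threshold
#'
#' Log-odds scoring of every window with exact p-values from
#' \code{pwm_score_distribution}. Windows containing N are skipped. Strand
#' "+" scans the given sequence only (use for directional elements such as
#' the TATA box on pre-oriented promoters); "both" also scans the reverse
#' complement and reports mirrored offsets.
#'
#' @param sequences named character vector or DNAStringSet.
#' @param x a \code{pwm}.
#' @param p_threshold report windows with p <= this (default 1e-4).
#' @param strand "+" or "both".
#' @param bin DP score discretization (bits).
#' @return data.frame: sequence_id, offset (0-based on the input sequence),
#'   strand, score, p_value.
#' @export
pwm_scan <- function(sequences, x, p_threshold = 1e-4, strand = c("+", "both"),
                     bin = 0.01) {
  strand <- match.arg(strand)
  stopifnot(p_threshold > 0, p_threshold <= 1)
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  dist <- pwm_score_distribution(x, bin = bin)
  rows <- list()
  for (id in names(sequences)) {
    s <- toupper(sequences[[id]])
    strands <- if (strand == "both") c("+", "-") else "+"
    for (st in strands) {
      chars <- seq_to_chars(if (st == "+") s else revcomp_chr(s))
      sc <- window_scores(chars, x)
      if (!length(sc)) next
      pv <- dist$pval_fun(sc)
      keep <- which(!is.na(sc) & pv <= p_threshold)
      if (!length(keep)) next
      off <- keep - 1L
      if (st == "-") off <- nchar(s) - x$width - off
      rows[[length(rows) + 1]] <- data.frame(
        sequence_id = id, offset = off, strand = st,
        score = sc[keep], p_value = pv[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric()))
  }
  do.call(rbind, rows)
}

#' Composition-preserving shuffled background sequences
#'
#' Mononucleotide permutation of each sequence: identical base composition,
#' disrupted motif structure. Deterministic given the seed.
#'
#' @param sequences named character vector or DNAStringSet.
#' @param seed RNG seed.
#' @return shuffled sequences (character, same names).
#' @export
shuffle_background <- function(sequences, seed = 1) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!length(sequences)) stop("no sequences to shuffle")
  with_seed(seed, {
    vapply(sequences, function(s) {
      paste(sample(seq_to_chars(s)), collapse = "")
    }, "")
  })
}

#' AME-style motif enrichment by Fisher's exact test
#'
#' For each motif, counts foreground and background sequences carrying at
#' least one match at the p-value threshold, tests the 2x2 table one-sided
#' (greater) by Fisher's exact test, and BH-adjusts across motifs. A motif is
#' called enriched at q < 0.05. Motifs wider than every sequence are skipped
#' with a warning.
#'
#' @param foreground,background sequence sets (character or DNAStringSet).
#' @param motifs list of \code{pwm} objects.
#' @param p_threshold match threshold passed to \code{pwm_scan}.
#' @param strand scanning strand mode.
#' @return data.frame: motif_id, fg_hits, fg_total, bg_hits, bg_total,
#'   fisher_p, bh_q, significant.
#' @export
ame_enrichment <- function(foreground, background, motifs,
                           p_threshold = 1e-4, strand = "both") {
  if (!length(foreground) || !length(background)) {
    stop("foreground and background must both be non-empty")
  }
  as_chr <- function(x) {
    if (methods::is(x, "XStringSet")) setNames(as.character(x), names(x)) else x
  }
  foreground <- as_chr(foreground); background <- as_chr(background)
  if (is.null(names(foreground))) names(foreground) <- paste0("fg", seq_along(foreground))
  if (is.null(names(background))) names(background) <- paste0("bg", seq_along(background))
  rows <- list()
  for (m in motifs) {
    if (m$width > max(nchar(c(foreground, background)))) {
      warning("motif ", m$id, " wider than every sequence; skipped")
      next
    }
    fg_hit <- length(unique(pwm_scan(foreground, m, p_threshold, strand)$sequence_id))
    bg_hit <- length(unique(pwm_scan(background, m, p_threshold, strand)$sequence_id))
    tab <- matrix(c(fg_hit, length(foreground) - fg_hit,
                    bg_hit, length(background) - bg_hit), 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "greater")$p.value
    rows[[length(rows) + 1]] <- data.frame(
      motif_id = m$id, fg_hits = fg_hit, fg_total = length(foreground),
      bg_hits = bg_hit, bg_total = length(background), fisher_p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$bh_q <- p.adjust(out$fisher_p, method = "BH")
  out$significant <- out$bh_q < 0.05
  out
}

#' Conservation of motif match sites, compared between groups
#'
#' Means the conservation track over each match interval and compares the
#' per-site means between two groups (e.g. divergence classes) with an
#' equal-variance Student's t-test. Matches falling outside track coverage
#' are skipped. Zero overall variance yields p = 1 with a warning.
#'
#' @param matches data.frame from \code{pwm_scan} plus columns chrom and
#'   start (genomic 0-based position of offset 0) and group.
#' @param track bedGraph-like data.frame: chrom, start, end, score.
#' @param width motif width (match interval length).
#' @return list: sites (per-match mean score and group), p_value, t.
#' @export
motif_site_conservation <- function(matches, track, width) {
  gr_t <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1, track$end))
  means <- vapply(seq_len(nrow(matches)), function(i) {
    s <- matches$start[i] + matches$offset[i]
    gr <- GenomicRanges::GRanges(matches$chrom[i],
                                 IRanges::IRanges(s + 1, s + width))
    ov <- GenomicRanges::findOverlaps(gr, gr_t)
    if (!length(ov)) return(NA_real_)
    hit <- S4Vectors::subjectHits(ov)
    w <- pmin(track$end[hit], s + width) - pmax(track$start[hit], s)
    sum(track$score[hit] * w) / sum(w)
  }, numeric(1))
  sites <- data.frame(matches, cons_mean = means)
  ok <- !is.na(means)
  g <- unique(matches$group[ok])
  if (length(g) != 2) stop("exactly two groups are required")
  x <- means[ok & matches$group == g[1]]
  y <- means[ok & matches$group == g[2]]
  if (var(c(x, y)) == 0) {
    warning("zero variance in site conservation; p = 1")
    return(list(sites = sites, p_value = 1, t = 0))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(sites = sites, p_value = tt$p.value, t = unname(tt$statistic))
}
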