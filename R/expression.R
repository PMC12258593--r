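#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-of-ratios method: a
#' pseudo-reference sample is built as the per-gene geometric mean across
#' samples (over genes with all-positive counts), and each sample's factor is
#' the median of its count-to-reference ratios. Factors are rescaled to have
#' geometric mean 1 so normalized counts stay on the raw-count scale.
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("median-of-ratios size factors are undefined: no gene has ",
         "all-positive counts across samples")
  }
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)                       # log geometric mean
  sf <- apply(logc, 2, function(x) exp(median(x - ref)))
  sf <- sf / exp(mean(log(sf)))               # geometric mean 1
  names(sf) <- colnames(counts)
  sf
}

#' Transcripts per million
#'
#' Length-normalizes counts to reads-per-kilobase and rescales each sample to
#' sum to 1e6. An all-zero sample is returned as all-zero with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @param lengths effective lengths in bp, named by gene or in row order.
#' @return TPM matrix of the same dimensions.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing)) {
      stop("missing effective lengths for genes: ",
           paste(head(missing, 5), collapse = ", "))
    }
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) stop("lengths do not match genes")
  if (any(!is.finite(lengths) | lengths <= 0)) stop("lengths must be positive")
  rpk <- counts / (lengths / 1000)
  tot <- colSums(rpk)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "),
            "; TPM set to zero")
    tot[zero] <- 1
  }
  sweep(rpk, 2, tot, "/") * 1e6
}

#' Remove a single batch factor by per-gene mean centering
#'
#' Equalizes per-gene batch means to the gene's grand mean on the (log)
#' expression matrix, preserving within-batch deviations. With a single batch
#' the matrix is returned unchanged. The adjustment is idempotent.
#'
#' @param log_expr numeric matrix, genes x samples (log scale).
#' @param batch batch labels, one per sample.
#' @param condition optional condition labels; used only to warn when a batch
#'   is perfectly confounded with condition.
#' @return adjusted matrix.
#' @export
remove_batch <- function(log_expr, batch, condition = NULL) {
  log_expr <- as.matrix(log_expr)
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(log_expr))
  ub <- unique(batch)
  if (length(ub) < 2) return(log_expr)
  if (!is.null(condition)) {
    tab <- table(batch, as.character(condition))
    if (all(rowSums(tab > 0) == 1)) {
      warning("batch is perfectly confounded with condition; ",
              "mean-centering applied anyway")
    }
  }
  grand <- rowMeans(log_expr)
  out <- log_expr
  for (b in ub) {
    idx <- batch == b
    bm <- rowMeans(log_expr[, idx, drop = FALSE])
    out[, idx] <- log_expr[, idx, drop = FALSE] - bm + grand
  }
  out
}

#' Raw log2 fold change with a delta-method standard error
#'
#' log2fc = log2((mean_obese + c) / (mean_lean + c)) on normalized counts,
#' with pseudocount c guarding zeros. The standard error comes from the
#' delta method under a negative-binomial model with dispersion phi:
#' se^2 = (1/ln 2)^2 * [(1/mu_o + phi)/n_o + (1/mu_l + phi)/n_l].
#'
#' @param norm_counts normalized count matrix, genes x samples.
#' @param groups factor/character with two levels; the first of
#'   \code{sort(unique(groups))} is... see \code{numerator}.
#' @param numerator group label used as the ratio numerator (obese).
#' @param pseudocount pseudocount c on the normalized-count scale.
#' @param dispersion optional per-gene dispersion vector; estimated by
#'   moderated method-of-moments when NULL.
#' @return data.frame with log2fc_raw and se_log2fc per gene.
#' @export
log2fc <- function(norm_counts, groups, numerator = "obese",
                   pseudocount = 0.5, dispersion = NULL) {
  norm_counts <- as.matrix(norm_counts)
  groups <- as.character(groups)
  if (!numerator %in% groups) stop("numerator group not present")
  io <- groups == numerator
  il <- !io
  if (!any(io) || !any(il)) stop("both groups must be non-empty")
  mo <- rowMeans(norm_counts[, io, drop = FALSE])
  ml <- rowMeans(norm_counts[, il, drop = FALSE])
  lfc <- log2((mo + pseudocount) / (ml + pseudocount))
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(norm_counts, groups)
  }
  no <- sum(io); nl <- sum(il)
  se2 <- (1 / log(2))^2 *
    ((1 / pmax(mo, pseudocount) + dispersion) / no +
     (1 / pmax(ml, pseudocount) + dispersion) / nl)
  data.frame(gene_id = rownames(norm_counts) %||% seq_len(nrow(norm_counts)),
             log2fc_raw = lfc, se_log2fc = sqrt(se2),
             mean_num = mo, mean_den = ml,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tagwise method-of-moments NB dispersion, squeezed toward the mean
# dispersion with prior weight d0 (in residual-df units).
estimate_dispersion <- function(norm_counts, groups, d0 = 10) {
  groups <- as.character(groups)
  ug <- unique(groups)
  n <- length(groups)
  mu <- 0; s2w <- 0
  # pooled within-group moments
  phi_g <- rep(0, nrow(norm_counts))
  num <- rep(0, nrow(norm_counts)); den <- rep(0, nrow(norm_counts))
  for (g in ug) {
    idx <- groups == g
    m <- rowMeans(norm_counts[, idx, drop = FALSE])
    v <- apply(norm_counts[, idx, drop = FALSE], 1, var)
    # variance = mu + phi mu^2  =>  phi = (v - mu)/mu^2
    w <- sum(idx) - 1
    num <- num + w * (v - m)
    den <- den + w * pmax(m, 1e-8)^2
  }
  phi_g <- pmax(num / pmax(den, 1e-12), 0)
  df_g <- n - length(ug)
  phi_bar <- mean(phi_g)
  (df_g * phi_g + d0 * phi_bar) / (df_g + d0)
}

#' Negative-binomial two-group Wald test
#'
#' Two-sided Wald test on the raw log2 fold change with its delta-method
#' standard error under moderated tagwise dispersion (standard normal
#' reference). Degenerate genes whose counts are identical across all
#' samples get p = 1.
#'
#' @inheritParams log2fc
#' @return data.frame with log2fc_raw, se_log2fc and p_value per gene.
#' @export
nb_two_group_test <- function(norm_counts, groups, numerator = "obese",
                              pseudocount = 0.5) {
  norm_counts <- as.matrix(norm_counts)
  groups <- as.character(groups)
  if (sum(groups == numerator) < 2 || sum(groups != numerator) < 2) {
    stop("at least 2 replicates per group are required")
  }
  fc <- log2fc(norm_counts, groups, numerator, pseudocount)
  z <- fc$log2fc_raw / fc$se_log2fc
  p <- 2 * pnorm(-abs(z))
  degenerate <- apply(norm_counts, 1, function(x) all(x == x[1]))
  p[degenerate | !is.finite(z)] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fc$p_value <- p
  fc
}

#' Low-expression flag
#'
#' A gene is expressed in a group when TPM exceeds \code{threshold} in at
#' least \code{min_fraction} of that group's replicates. The gene is flagged
#' low-expressed only when it fails this rule in both groups, so genes
#' switched on or off by the condition are kept.
#'
#' @param tpm_mat TPM matrix, genes x samples.
#' @param groups two-level group labels per sample.
#' @param threshold TPM threshold (default 0.25).
#' @param min_fraction minimum fraction of replicates above threshold
#'   (default 0.5, i.e. at least half).
#' @return logical vector, TRUE = low-expressed.
#' @export
low_expression_mask <- function(tpm_mat, groups, threshold = 0.25,
                                min_fraction = 0.5) {
  tpm_mat <- as.matrix(tpm_mat)
  groups <- as.character(groups)
  ok <- rep(FALSE, nrow(tpm_mat))
  for (g in unique(groups)) {
    idx <- groups == g
    npass <- rowSums(tpm_mat[, idx, drop = FALSE] > threshold)
    ok <- ok | (npass >= min_fraction * sum(idx))
  }
  !ok
}

#' DEG calls
#'
#' A gene is differentially expressed when p < 0.05, |log2FC| > 1 (both
#' strict), and it is not low-expressed.
#'
#' @param p_value,log2fc_raw,is_low_expr per-gene vectors.
#' @param p_cut,lfc_cut thresholds (strict inequalities).
#' @return logical DEG flags.
#' @export
call_degs <- function(p_value, log2fc_raw, is_low_expr,
                      p_cut = 0.05, lfc_cut = 1) {
  (p_value < p_cut) & (abs(log2fc_raw) > lfc_cut) & !is_low_expr
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Normal-normal posterior mean toward 0: the prior variance tau^2 is
#' estimated by moments as max(0, var(lfc) - mean(se^2)), and each gene's
#' shrunken value is lfc * tau^2 / (tau^2 + se^2). High-noise (low-count)
#' genes are pulled hardest; se = 0 returns the raw value. When every lfc is
#' identical tau^2 = 0 and all shrunken values collapse to 0.
#'
#' @param lfc raw log2 fold changes.
#' @param se standard errors of lfc.
#' @return shrunken log2 fold changes.
#' @export
shrink_log2fc <- function(lfc, se) {
  if (length(lfc) < 10) stop("need >= 10 genes to estimate the prior variance")
  stopifnot(length(lfc) == length(se))
  tau2 <- max(0, var(lfc) - mean(se^2))
  lfc * tau2 / (tau2 + se^2)
}

#' Cross-group Euclidean distances
#'
#' All pairwise Euclidean distances between obese and lean samples in
#' log2(TPM + 1) space.
#'
#' @param expr matrix, genes x samples (log2(TPM+1) scale, see
#'   \code{already_log}).
#' @param groups two-level labels per sample.
#' @param numerator label of the first group (obese).
#' @param already_log set TRUE when \code{expr} is already log-transformed.
#' @return numeric vector of n_obese * n_lean distances.
#' @export
group_distance <- function(expr, groups, numerator = "obese",
                           already_log = FALSE) {
  expr <- as.matrix(expr)
  if (!already_log) expr <- log2(expr + 1)
  groups <- as.character(groups)
  io <- which(groups == numerator)
  il <- which(groups != numerator)
  if (!length(io) || !length(il)) stop("both groups must be non-empty")
  out <- numeric(0)
  for (i in io) for (j in il) {
    out <- c(out, sqrt(sum((expr[, i] - expr[, j])^2)))
  }
  out
}

#' Per-species expression-change table
#'
#' Runs the full expression stage for one species: size factors (or TPM-based
#' normalization), optional batch centering, the NB Wald test, TPM means, the
#' low-expression rule, empirical-Bayes shrinkage and DEG calls.
#'
#' @param counts integer count matrix, genes x samples.
#' @param samples data.frame with columns condition (obese/lean) and
#'   optionally batch.
#' @param lengths effective gene lengths (bp), named by gene.
#' @param normalization "median_of_ratios" (counts divided by size factors)
#'   or "tpm" (TPM values used as the normalized expression).
#' @param pseudocount pseudocount for log2fc, on the count scale (rescaled
#'   to the expression scale per gene for the TPM route).
#' @return data.frame: gene_id, mean_tpm_obese, mean_tpm_lean, log2fc_raw,
#'   se_log2fc, log2fc_shrunk, p_value, is_deg, is_low_expr.
#' @details The NB error model (dispersion and the delta-method standard
#'   error) is always estimated on count-scale normalized counts: the se of
#'   a log ratio is invariant to per-gene constant rescaling, so TPM's
#'   per-gene length factor must not enter the Poisson term 1/mu. The
#'   normalization route determines the expression values the fold change
#'   is computed from.
#' @export
expression_changes <- function(counts, samples, lengths,
                               normalization = c("median_of_ratios", "tpm"),
                               pseudocount = 0.5) {
  normalization <- match.arg(normalization)
  counts <- as.matrix(counts)
  cond <- as.character(samples$condition)
  stopifnot(all(cond %in% c("obese", "lean")))
  if (sum(cond == "obese") < 2 || sum(cond == "lean") < 2) {
    stop("at least 2 replicates per group are required")
  }
  tpm_mat <- tpm(counts, lengths)
  norm_mor <- sweep(counts, 2, size_factors_median_of_ratios(counts), "/")
  expr <- switch(normalization, median_of_ratios = norm_mor, tpm = tpm_mat)
  if (!is.null(samples$batch) && length(unique(samples$batch)) > 1) {
    expr <- pmax(2^remove_batch(log2(expr + 1), samples$batch, cond) - 1, 0)
    norm_mor <- pmax(2^remove_batch(log2(norm_mor + 1), samples$batch, cond) - 1, 0)
  }
  io <- cond == "obese"
  # fold change on the route's expression scale; pseudocount kept on the
  # count scale via the per-gene expression-to-count ratio
  scale_g <- rowMeans(expr) / pmax(rowMeans(norm_mor), 1e-8)
  scale_g[rowMeans(expr) == 0] <- 1
  pc <- pseudocount * scale_g
  mo <- rowMeans(expr[, io, drop = FALSE])
  ml <- rowMeans(expr[, !io, drop = FALSE])
  lfc <- log2((mo + pc) / (ml + pc))
  # error model on the count scale
  cnt <- log2fc(norm_mor, cond, numerator = "obese", pseudocount = pseudocount)
  se <- cnt$se_log2fc
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  degenerate <- apply(counts, 1, function(x) all(x == x[1]))
  p[degenerate | !is.finite(z)] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  low <- low_expression_mask(tpm_mat, cond)
  shrunk <- shrink_log2fc(lfc, se)
  data.frame(
    gene_id = rownames(counts),
    mean_tpm_obese = rowMeans(tpm_mat[, io, drop = FALSE]),
    mean_tpm_lean = rowMeans(tpm_mat[, !io, drop = FALSE]),
    log2fc_raw = lfc,
    se_log2fc = se,
    log2fc_shrunk = shrunk,
    p_value = p,
    is_low_expr = low,
    is_deg = call_degs(p, lfc, low),
    stringsAsFactors = FALSE)
}
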