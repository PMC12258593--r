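#' Candidate ortholog triples
#'
#' Keeps the 1:1:1 ortholog triples that are differentially expressed between
#' obese and lean individuals in at least one species.
#'
#' @param orthologs data.frame with one gene-id column per species.
#' @param deg_flags named list (by species) of named logical vectors
#'   (by gene id) of DEG flags.
#' @return the retained rows of \code{orthologs}.
#' @export
select_candidates <- function(orthologs, deg_flags) {
  species <- names(deg_flags)
  stopifnot(all(species %in% names(orthologs)))
  any_deg <- rep(FALSE, nrow(orthologs))
  for (sp in species) {
    f <- deg_flags[[sp]][orthologs[[sp]]]
    f[is.na(f)] <- FALSE
    any_deg <- any_deg | f
  }
  if (!any(any_deg)) stop("no ortholog triple is differentially expressed in any species")
  orthologs[any_deg, , drop = FALSE]
}

#' Divergence SD of a triple of log2 fold changes
#'
#' Standard deviation across the three species of the (shrunken) log2 fold
#' changes, after zeroing values of species where the gene is low-expressed.
#' Sample SD (denominator n - 1 = 2) by default; population SD behind a flag.
#'
#' @param lfc numeric matrix genes x species of log2 fold changes (shrunken
#'   by default upstream), or length-3 vector for a single triple.
#' @param low logical matrix (or vector) of low-expression flags, same shape.
#' @param population use the population SD (denominator n) instead.
#' @return numeric vector of SDs.
#' @export
divergence_sd <- function(lfc, low = NULL, population = FALSE) {
  if (is.null(dim(lfc))) lfc <- matrix(lfc, nrow = 1)
  if (ncol(lfc) != 3) stop("exactly 3 species values per triple are required")
  if (!is.null(low)) {
    if (is.null(dim(low))) low <- matrix(low, nrow = 1)
    stopifnot(all(dim(low) == dim(lfc)))
    lfc[low] <- 0
  }
  m <- rowMeans(lfc)
  ss <- rowSums((lfc - m)^2)
  if (population) sqrt(ss / 3) else sqrt(ss / 2)
}

#' High / medium / low divergence classes
#'
#' Nearest-rank quartiles of the SD distribution: high when SD > Q75
#' (top 25%), low when SD <= Q25 (bottom 25%), medium otherwise. With all-
#' distinct SDs and n divisible by 4 this yields exactly 25/50/25. Ties share
#' the class of their value; identical SDs throughout give all-medium with a
#' warning.
#'
#' @param sd_values numeric vector of divergence SDs (>= 4 values).
#' @return factor with levels low, medium, high.
#' @export
classify_divergence <- function(sd_values) {
  n <- length(sd_values)
  if (n < 4) stop("need >= 4 genes to form quartile classes")
  s <- sort(sd_values)
  q25 <- s[ceiling(0.25 * n)]
  q75 <- s[ceiling(0.75 * n)]
  if (q25 == q75 && s[1] == s[n]) {
    warning("all SDs identical; every gene classified medium")
    return(factor(rep("medium", n), levels = c("low", "medium", "high")))
  }
  cls <- ifelse(sd_values > q75, "high",
                ifelse(sd_values <= q25, "low", "medium"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Sign pattern of a log2FC triple
#'
#' Per species: "+" when lfc > t, "-" when lfc < -t, "0" otherwise, with the
#' magnitude threshold t = 0.3 marking an obvious expression change. Returns
#' labels like "pig+/mouse0/human0".
#'
#' @param lfc matrix genes x species (columns named by species) or length-3
#'   vector.
#' @param species species names (taken from columns when present).
#' @param threshold magnitude threshold t.
#' @return character vector of pattern labels.
#' @export
sign_pattern <- function(lfc, species = NULL, threshold = 0.3) {
  if (is.null(dim(lfc))) lfc <- matrix(lfc, nrow = 1)
  if (is.null(species)) species <- colnames(lfc) %||% paste0("sp", seq_len(ncol(lfc)))
  sym <- matrix("0", nrow(lfc), ncol(lfc))
  sym[lfc > threshold] <- "+"
  sym[lfc < -threshold] <- "-"
  apply(sym, 1, function(r) paste0(species, r, collapse = "/"))
}

#' Divergence table over candidate triples
#'
#' Joins per-species expression-change tables on the ortholog map, zeroes
#' low-expressed species, and computes the divergence SD, class and sign
#' pattern for the candidate (DEG in >= 1 species) triples.
#'
#' @param changes named list (by species) of \code{expression_changes}
#'   tables; the first species is the focal one.
#' @param orthologs data.frame of 1:1:1 triples, one column per species.
#' @param use_shrunk feed shrunken (default) or raw log2 fold changes.
#' @param population population-SD flag passed to \code{divergence_sd}.
#' @return data.frame with per-species ids and lfcs used, sd_log2fc,
#'   divergence_class and sign_pattern.
#' @export
divergence_table <- function(changes, orthologs, use_shrunk = TRUE,
                             population = FALSE) {
  species <- names(changes)
  stopifnot(length(species) == 3, all(species %in% names(orthologs)))
  deg <- lapply(changes, function(tb) setNames(tb$is_deg, tb$gene_id))
  cand <- select_candidates(orthologs, deg)
  col <- if (use_shrunk) "log2fc_shrunk" else "log2fc_raw"
  lfc <- sapply(species, function(sp) {
    tb <- changes[[sp]]
    setNames(tb[[col]], tb$gene_id)[cand[[sp]]]
  })
  low <- sapply(species, function(sp) {
    tb <- changes[[sp]]
    setNames(tb$is_low_expr, tb$gene_id)[cand[[sp]]]
  })
  lfc <- matrix(lfc, ncol = 3, dimnames = list(NULL, species))
  low <- matrix(as.logical(low), ncol = 3, dimnames = list(NULL, species))
  used <- lfc
  used[low] <- 0
  sdv <- divergence_sd(used, population = population)
  out <- cand
  for (sp in species) out[[paste0("lfc_", sp)]] <- used[, sp]
  out$sd_log2fc <- sdv
  out$divergence_class <- classify_divergence(sdv)
  out$sign_pattern <- sign_pattern(used, species)
  rownames(out) <- NULL
  out
}

#' Normalization robustness of the divergence SD
#'
#' Runs the expression + divergence stages under median-of-ratios and under
#' TPM-based normalization and reports the Pearson correlation of the two
#' per-gene SD vectors over the union of candidate genes (missing candidates
#' in one route are dropped; counts reported).
#'
#' @param counts named list (by species) of count matrices.
#' @param samples named list of sample sheets.
#' @param lengths named list of length vectors.
#' @param orthologs ortholog map.
#' @return list with r (Pearson), n (genes compared), and the two tables.
#' @export
normalization_robustness <- function(counts, samples, lengths, orthologs) {
  run <- function(norm) {
    ch <- lapply(names(counts), function(sp) {
      expression_changes(counts[[sp]], samples[[sp]], lengths[[sp]],
                         normalization = norm)
    })
    names(ch) <- names(counts)
    divergence_table(ch, orthologs)
  }
  a <- run("median_of_ratios")
  b <- run("tpm")
  key <- names(counts)[1]
  common <- intersect(a[[key]], b[[key]])
  if (length(common) < 3) stop("fewer than 3 shared candidate genes")
  r <- cor(a$sd_log2fc[match(common, a[[key]])],
           b$sd_log2fc[match(common, b[[key]])])
  list(r = r, n = length(common), median_of_ratios = a, tpm = b)
}
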