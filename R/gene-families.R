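#' Flag expanded / contracted gene families
#'
#' A family is expanded in the focal species when the external birth-death
#' p-value is below alpha and the focal copy number strictly exceeds the
#' median copy number of the other species; contracted when strictly below.
#'
#' @param families data.frame with family_id, one copy-number column per
#'   species, and a p_value column.
#' @param focal focal species column name.
#' @param species species column names (all copy columns when NULL).
#' @param alpha p-value gate.
#' @return factor vector in {expanded, contracted, neither}.
#' @export
flag_family_evolution <- function(families, focal, species = NULL,
                                  alpha = 0.05) {
  if (!focal %in% names(families)) stop("missing focal species column: ", focal)
  if (is.null(species)) {
    species <- setdiff(names(families),
                       c("family_id", "p_value", "true_evo"))
  }
  if (length(species) < 3) stop("need >= 3 species columns")
  others <- setdiff(species, focal)
  med <- apply(as.matrix(families[, others, drop = FALSE]), 1, median)
  sig <- families$p_value < alpha
  cls <- ifelse(sig & families[[focal]] > med, "expanded",
                ifelse(sig & families[[focal]] < med, "contracted", "neither"))
  factor(cls, levels = c("expanded", "contracted", "neither"))
}

#' Direction and magnitude-tertile bins of gene copies
#'
#' Splits copies into up (lfc > 0) and down (lfc < 0); zero fold changes are
#' excluded. Within each direction, copies are binned into tertiles of |lfc|
#' by nearest-rank percentiles (33.3 / 66.7).
#'
#' @param log2fc per-copy log2 fold changes.
#' @return data.frame: log2fc, direction, tertile (NA for lfc = 0).
#' @export
direction_percentile_bins <- function(log2fc) {
  if (all(log2fc == 0)) {
    warning("all fold changes are zero; no bins formed")
    return(data.frame(log2fc = log2fc, direction = NA_character_,
                      tertile = NA_integer_))
  }
  direction <- ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", NA))
  tertile <- rep(NA_integer_, length(log2fc))
  for (d in c("up", "down")) {
    idx <- which(direction %in% d)
    if (!length(idx)) next
    a <- abs(log2fc[idx])
    s <- sort(a)
    q1 <- s[ceiling(length(s) / 3)]
    q2 <- s[ceiling(2 * length(s) / 3)]
    tertile[idx] <- ifelse(a <= q1, 1L, ifelse(a <= q2, 2L, 3L))
  }
  data.frame(log2fc = log2fc, direction = direction, tertile = tertile,
             stringsAsFactors = FALSE)
}

#' Fisher enrichment of expression direction in flagged families
#'
#' Builds the 2x2 table membership-in-flagged-families x direction-of-change
#' over the universe of gene copies with measured fold change, and tests it
#' one-sided (greater) by Fisher's exact test. Fold enrichment is the
#' observed proportion of the direction among flagged-family copies over the
#' proportion in the whole universe.
#'
#' @param in_flagged logical: copy belongs to a flagged (e.g. expanded)
#'   family.
#' @param in_direction logical: copy changed in the tested direction
#'   (e.g. upregulated).
#' @param alternative passed to \code{fisher.test} ("greater" by default).
#' @return list: table, fold_enrichment, p_value.
#' @export
family_direction_enrichment <- function(in_flagged, in_direction,
                                        alternative = "greater") {
  stopifnot(length(in_flagged) == length(in_direction))
  a <- sum(in_flagged & in_direction)
  b <- sum(in_flagged & !in_direction)
  cc <- sum(!in_flagged & in_direction)
  d <- sum(!in_flagged & !in_direction)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(flagged = c("yes", "no"),
                                direction = c("yes", "no")))
  if (a + b == 0 || a + cc == 0) {
    return(list(table = tab, fold_enrichment = NA_real_, p_value = 1))
  }
  fold <- (a / (a + b)) / ((a + cc) / sum(tab))
  p <- fisher.test(tab, alternative = alternative)$p.value
  list(table = tab, fold_enrichment = fold, p_value = p)
}
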