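# Standard genetic code keyed by codon; stops are "*".
genetic_code <- function() Biostrings::GENETIC_CODE

# Fraction of synonymous sites in a codon: for each position, the fraction
# of the 3 possible single-nucleotide changes that preserve the amino acid
# (changes to stop codons count as nonsynonymous).
codon_syn_sites <- function(codon, code = genetic_code()) {
  aa <- code[codon]
  if (is.na(aa) || aa == "*") return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    for (alt in setdiff(DNA_BASES, base)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (!is.na(code[mut]) && code[mut] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Synonymous/nonsynonymous difference counts between two codons, averaged
# with equal weights over all orderings of the differing positions.
# Pathway steps through stop codons are excluded; if every pathway passes
# through a stop, all pathways are used.
codon_diff_counts <- function(c1, c2, code = genetic_code()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  paths <- if (nd == 1) list(pos) else {
    perms <- if (nd == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
    perms
  }
  eval_path <- function(ord) {
    cur <- c1
    syn <- 0; nonsyn <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[nxt] == "*") valid <- FALSE
      if (code[cur] == code[nxt]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, valid = valid)
  }
  ev <- lapply(paths, eval_path)
  ok <- vapply(ev, `[[`, TRUE, "valid")
  use <- if (any(ok)) ev[ok] else ev
  c(syn = mean(vapply(use, `[[`, 0, "syn")),
    nonsyn = mean(vapply(use, `[[`, 0, "nonsyn")))
}

# Lazily built lookup tables: per-codon synonymous site fractions and the
# pathway-averaged difference counts for every sense-codon pair.
.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$syn)) return(.ng86_cache)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  syn <- vapply(sense, codon_syn_sites, numeric(1), code = code)
  nsen <- length(sense)
  sd_m <- matrix(0, nsen, nsen, dimnames = list(sense, sense))
  nd_m <- sd_m
  for (i in seq_len(nsen)) {
    for (j in seq_len(nsen)) {
      if (i == j) next
      d <- codon_diff_counts(sense[i], sense[j], code)
      sd_m[i, j] <- d["syn"]
      nd_m[i, j] <- d["nonsyn"]
    }
  }
  .ng86_cache$syn <- syn
  .ng86_cache$sd <- sd_m
  .ng86_cache$nd <- nd_m
  .ng86_cache
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (equal-weight multiple-pathway averaging for
#' codons differing at 2-3 positions), then applies the Jukes-Cantor
#' correction d = -3/4 log(1 - 4p/3). Codons containing gaps, ambiguity
#' characters or stops are dropped pairwise. Omega is dN/dS, missing when
#' dS = 0; when a proportion reaches 3/4 the correction is undefined and
#' the estimate is returned missing with a reason.
#'
#' @param seq1,seq2 aligned CDS strings of equal length divisible by 3
#'   (gaps as "-").
#' @return list: dN, dS, omega, S, N, Sd, Nd, reason (NA when estimable).
#' @export
ng86_dnds <- function(seq1, seq2) {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned (equal length)")
  if (nchar(seq1) %% 3 != 0) stop("alignment length must be divisible by 3")
  if (nchar(seq1) == 0) stop("empty alignment")
  tab <- ng86_tables()
  starts <- seq(1, nchar(seq1), by = 3)
  c1 <- substring(seq1, starts, starts + 2)
  c2 <- substring(seq2, starts, starts + 2)
  ok <- c1 %in% rownames(tab$sd) & c2 %in% rownames(tab$sd)
  c1 <- c1[ok]; c2 <- c2[ok]
  used <- length(c1)
  if (used == 0) stop("no usable codons in the alignment")
  s_pair <- (tab$syn[c1] + tab$syn[c2]) / 2
  S <- sum(s_pair)
  N <- 3 * used - S
  Sd <- sum(tab$sd[cbind(c1, c2)])
  Nd <- sum(tab$nd[cbind(c1, c2)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  reason <- NA_character_
  if (is.na(dS) || is.na(dN)) reason <- "proportion >= 3/4; Jukes-Cantor undefined"
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  if (is.na(omega) && is.na(reason) && !is.na(dS) && dS == 0) {
    reason <- "dS = 0; omega undefined"
  }
  list(dN = unname(dN), dS = unname(dS), omega = unname(omega),
       S = S, N = N, Sd = unname(Sd), Nd = unname(Nd), reason = reason)
}

#' dN/dS over paired CDS sets
#'
#' @param cds1,cds2 DNAStringSet or named character vectors with matching
#'   order (gene pairs).
#' @param gene_ids ids for the output (default: names of cds1).
#' @return data.frame: gene_id, dN, dS, omega, reason.
#' @export
dnds_table <- function(cds1, cds2, gene_ids = NULL) {
  as_chr <- function(x) if (methods::is(x, "XStringSet"))
    setNames(as.character(x), names(x)) else x
  cds1 <- as_chr(cds1); cds2 <- as_chr(cds2)
  stopifnot(length(cds1) == length(cds2))
  gene_ids <- gene_ids %||% names(cds1) %||% paste0("g", seq_along(cds1))
  rows <- lapply(seq_along(cds1), function(i) {
    r <- ng86_dnds(cds1[[i]], cds2[[i]])
    data.frame(gene_id = gene_ids[i], dN = r$dN, dS = r$dS, omega = r$omega,
               reason = r$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare omega between divergence classes
#'
#' Equal-variance two-sample Student's t-test of dN/dS between every pair of
#' classes; missing omegas are excluded and usable counts reported. A class
#' with fewer than 2 usable values is skipped with a message.
#'
#' @param omega named numeric vector (gene ids).
#' @param classes named factor per gene id.
#' @param welch use Welch's t-test instead.
#' @return data.frame: class_a, class_b, n_a, n_b, t, p_value.
#' @export
compare_omega_by_class <- function(omega, classes, welch = FALSE) {
  keep <- intersect(names(omega)[!is.na(omega)], names(classes))
  om <- omega[keep]
  cls <- factor(classes[keep])
  lv <- levels(cls)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    x <- om[cls == lv[i]]; y <- om[cls == lv[j]]
    if (length(x) < 2 || length(y) < 2) {
      message("class pair ", lv[i], "/", lv[j], " skipped: < 2 usable values")
      next
    }
    if (var(c(x, y)) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        class_a = lv[i], class_b = lv[j], n_a = length(x), n_b = length(y),
        t = 0, p_value = 1, stringsAsFactors = FALSE)
      next
    }
    tt <- t.test(x, y, var.equal = !welch)
    rows[[length(rows) + 1]] <- data.frame(
      class_a = lv[i], class_b = lv[j], n_a = length(x), n_b = length(y),
      t = unname(tt$statistic), p_value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
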