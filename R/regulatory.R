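#' Promoter window around a TSS
#'
#' Coordinates are 0-based half-open. "Upstream a / downstream b" follows the
#' transcription orientation: on the plus strand the window is
#' [tss - a, tss + b); on the minus strand it is mirrored to
#' [tss - b, tss + a).
#'
#' @param tss 0-based TSS positions.
#' @param strand "+" or "-" per gene.
#' @param upstream,downstream window extents in bp (upstream + downstream
#'   must be > 0).
#' @param chrom_len optional chromosome length for clipping (with warning).
#' @return list of vectors start, end (0-based half-open).
#' @export
promoter_window <- function(tss, strand, upstream, downstream,
                            chrom_len = NULL) {
  if (upstream + downstream <= 0) stop("empty window (upstream + downstream = 0)")
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  if (!is.null(chrom_len)) {
    if (any(tss < 0 | tss >= chrom_len)) stop("TSS outside the chromosome")
    if (any(start < 0 | end > chrom_len)) {
      warning("promoter window(s) clipped at chromosome edges")
      start <- pmax(start, 0)
      end <- pmin(end, chrom_len)
    }
  }
  list(start = start, end = end)
}

# Extract oriented window sequences from a genome (DNAStringSet of
# chromosomes); minus-strand windows are reverse-complemented so position 1
# of the result is the window's most upstream transcribed base.
extract_windows <- function(genome, chrom, start, end, strand) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(start), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]], start[i] + 1, end[i]))
  }, ""))
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  seqs
}

#' TATA-box promoter fraction by divergence class
#'
#' Scans each gene's TSS-proximal window (+200/-50, transcribed strand only:
#' the TATA box is directional) with a TATA PWM at the exact-p threshold and
#' reports, per divergence class and species, the fraction of genes with at
#' least one match. Classes are compared by an equal-variance Student's
#' t-test across the per-species fractions.
#'
#' @param promoters named list (by species) of named oriented promoter
#'   sequences; names are gene ids, position 1 = most upstream base of the
#'   +2200/-500 record (see \code{simulate_annotation_and_sequences}).
#' @param classes named list (by species) of named factors: divergence class
#'   per gene id.
#' @param tata a TATA \code{pwm} (default \code{tata_pwm()}).
#' @param p_threshold match threshold.
#' @param record_upstream,record_downstream extent of the promoter records,
#'   used to cut the +200/-50 scan window out of them.
#' @return list: fractions (data.frame class x species), tests (pairwise
#'   class t-test p-values).
#' @export
tata_promoter_fraction <- function(promoters, classes, tata = tata_pwm(),
                                   p_threshold = 1e-4,
                                   record_upstream = 2200,
                                   record_downstream = 501) {
  species <- names(promoters)
  res <- list()
  for (sp in species) {
    prom <- promoters[[sp]]
    if (methods::is(prom, "XStringSet")) {
      prom <- setNames(as.character(prom), names(prom))
    }
    cls <- classes[[sp]]
    keep <- intersect(names(prom), names(cls))
    skipped <- setdiff(names(cls), names(prom))
    if (length(skipped)) {
      message(length(skipped), " gene(s) without promoter sequence skipped")
    }
    # cut the [+200, -50] window out of the oriented record
    a <- record_upstream - 200 + 1
    b <- record_upstream + 50
    sub <- substr(prom[keep], a, b)
    hits <- pwm_scan(setNames(sub, keep), tata, p_threshold, strand = "+")
    has <- names(sub) %in% hits$sequence_id
    res[[sp]] <- tapply(has, cls[keep], mean)
  }
  frac <- do.call(rbind, res)                 # species x class
  lv <- colnames(frac)
  tests <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i < j) {
      p <- tryCatch(t.test(frac[, i], frac[, j], var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      tests[[paste(lv[i], lv[j], sep = "_vs_")]] <- p
    }
  }
  list(fractions = frac, tests = unlist(tests))
}

#' CpG-island promoter fraction by divergence class
#'
#' A gene is a CGI gene when its +300/-100 TSS window overlaps a CpG island
#' by at least 1 bp (half-open coordinates: abutting intervals do not
#' overlap).
#'
#' @param genes data.frame: gene_id, chrom, tss (1-based), strand.
#' @param cgi BED-like data.frame: chrom, start, end (0-based half-open).
#' @param classes named factor of divergence class per gene id.
#' @param upstream,downstream window extents.
#' @return list: is_cgi (named logical), fractions (per class).
#' @export
cgi_overlap_fraction <- function(genes, cgi, classes,
                                 upstream = 300, downstream = 100) {
  tss0 <- genes$tss - 1
  win <- promoter_window(tss0, genes$strand, upstream, downstream)
  gr_w <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(win$start + 1, win$end))
  gr_c <- GenomicRanges::GRanges(cgi$chrom,
                                 IRanges::IRanges(cgi$start + 1, cgi$end))
  is_cgi <- GenomicRanges::countOverlaps(gr_w, gr_c) > 0
  names(is_cgi) <- genes$gene_id
  keep <- intersect(genes$gene_id, names(classes))
  fractions <- tapply(is_cgi[keep], classes[keep], mean)
  list(is_cgi = is_cgi, fractions = fractions)
}

#' TSS-anchored conservation profile and class comparison
#'
#' Aligns per-base conservation scores on the TSS (position 1 = the first
#' base upstream of the TSS, strand-aware), computes each gene's median over
#' covered bases (missing bases are excluded, not imputed), and compares
#' classes by a two-sided Wilcoxon rank-sum test.
#'
#' @param genes data.frame: gene_id, chrom, tss (1-based), strand.
#' @param track bedGraph-like data.frame: chrom, start, end, score.
#' @param classes named factor per gene id.
#' @param upstream profile depth in bp (default 200, downstream 0).
#' @return list: medians (named), profile (genes x position matrix),
#'   tests (pairwise Wilcoxon p-values).
#' @export
conservation_tss_profile <- function(genes, track, classes, upstream = 200) {
  gr_t <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1, track$end))
  n <- nrow(genes)
  prof <- matrix(NA_real_, n, upstream,
                 dimnames = list(genes$gene_id, NULL))
  tss0 <- genes$tss - 1
  # oriented upstream positions 1..upstream per gene, one overlap query
  off <- rep(seq_len(upstream), times = n)
  gi <- rep(seq_len(n), each = upstream)
  gpos <- ifelse(genes$strand[gi] == "+", tss0[gi] - off, tss0[gi] + off)
  gr <- GenomicRanges::GRanges(genes$chrom[gi],
                               IRanges::IRanges(gpos + 1, gpos + 1))
  ov <- GenomicRanges::findOverlaps(gr, gr_t)
  q <- S4Vectors::queryHits(ov)
  prof[cbind(gi[q], off[q])] <- track$score[S4Vectors::subjectHits(ov)]
  med <- apply(prof, 1, function(x) {
    if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  })
  excl <- sum(is.na(med))
  if (excl) message(excl, " gene(s) with zero covered bases excluded")
  keep <- intersect(genes$gene_id[!is.na(med)], names(classes))
  cls <- classes[keep]
  lv <- levels(factor(cls))
  tests <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i < j) {
      x <- med[keep][cls == lv[i]]
      y <- med[keep][cls == lv[j]]
      p <- if (length(x) && length(y)) {
        suppressWarnings(wilcox.test(x, y)$p.value)
      } else NA_real_
      if (length(x) && length(y) && is.na(p)) p <- 1  # all-tied degenerate case
      tests[[paste(lv[i], lv[j], sep = "_vs_")]] <- p
    }
  }
  list(medians = med, profile = prof, tests = unlist(tests))
}
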