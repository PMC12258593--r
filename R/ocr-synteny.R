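#' Normalize ATAC peaks to 501-bp open-chromatin regions
#'
#' Each peak is anchored on its summit (narrowPeak column 10 semantics) when
#' present, else its midpoint, and extended 250 bp on both sides to a
#' uniform 501-bp interval. Intervals clipped by a chromosome edge are
#' shifted inward to preserve the 501-bp length; peaks on chromosomes
#' shorter than 501 bp are dropped with a warning.
#'
#' @param peaks data.frame: chrom, start, end (0-based half-open), optional
#'   name and summit (offset from start, -1 / NA = absent).
#' @param chrom_len named chromosome lengths (optional; no clipping
#'   when absent).
#' @return data.frame: chrom, start, end, peak_id, anchor; every interval
#'   has length exactly 501.
#' @export
normalize_peak <- function(peaks, chrom_len = NULL) {
  if (!nrow(peaks)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      anchor = integer()))
  }
  summit <- peaks$summit
  if (is.null(summit)) summit <- rep(NA_real_, nrow(peaks))
  summit[!is.na(summit) & summit < 0] <- NA
  anchor <- ifelse(is.na(summit),
                   floor((peaks$start + peaks$end) / 2),
                   peaks$start + summit)
  start <- anchor - 250
  end <- anchor + 251
  keep <- rep(TRUE, nrow(peaks))
  if (!is.null(chrom_len)) {
    len <- chrom_len[peaks$chrom]
    short <- !is.na(len) & len < 501
    if (any(short)) {
      warning(sum(short), " peak(s) on chromosomes shorter than 501 bp dropped")
      keep <- !short
    }
    shift <- pmax(0, -start) - pmax(0, end - ifelse(is.na(len), Inf, len))
    start <- start + shift
    end <- end + shift
  }
  out <- data.frame(chrom = peaks$chrom, start = start, end = end,
                    peak_id = peaks$name %||% paste0("peak", seq_len(nrow(peaks))),
                    anchor = anchor, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign OCRs to divergent-gene promoters
#'
#' Retains OCRs overlapping (>= 1 bp) the +2200/-500 promoter window of any
#' gene; an OCR overlapping several promoters goes to the gene with the
#' nearest TSS, ties broken by lexicographic gene id.
#'
#' @param ocrs output of \code{normalize_peak}.
#' @param genes data.frame: gene_id, chrom, tss (1-based), strand.
#' @param upstream,downstream promoter window extents.
#' @return \code{ocrs} rows retained, with an assigned_gene column.
#' @export
assign_promoter_ocrs <- function(ocrs, genes, upstream = 2200,
                                 downstream = 500) {
  tss0 <- genes$tss - 1
  win <- promoter_window(tss0, genes$strand, upstream, downstream)
  gr_w <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(win$start + 1, win$end))
  gr_o <- GenomicRanges::GRanges(ocrs$chrom,
                                 IRanges::IRanges(ocrs$start + 1, ocrs$end))
  ov <- GenomicRanges::findOverlaps(gr_o, gr_w)
  if (!length(ov)) {
    out <- ocrs[0, , drop = FALSE]
    out$assigned_gene <- character(0)
    return(out)
  }
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  mid <- floor((ocrs$start[qh] + ocrs$end[qh]) / 2)
  cand <- data.frame(q = qh, gene = genes$gene_id[sh],
                     dist = abs(mid - tss0[sh]), stringsAsFactors = FALSE)
  cand <- cand[order(cand$q, cand$dist, cand$gene), ]
  best <- cand[!duplicated(cand$q), ]
  out <- ocrs[best$q, , drop = FALSE]
  out$assigned_gene <- best$gene
  rownames(out) <- NULL
  out
}

#' Load and validate a synteny-block map
#'
#' @param x data.frame or TSV path with columns src_chrom, src_start,
#'   src_end, dst_chrom, dst_start, dst_end, orientation.
#' @return validated data.frame of class \code{synteny_map}.
#' @export
read_synteny <- function(x) {
  map <- if (is.character(x)) read_tsv(x) else x
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start",
            "dst_end", "orientation")
  if (!all(need %in% names(map))) stop("synteny map missing columns")
  if (any((map$src_end - map$src_start) != (map$dst_end - map$dst_start))) {
    stop("malformed synteny block: src and dst lengths differ")
  }
  class(map) <- c("synteny_map", class(map))
  map
}

#' Lift an interval through a synteny-block map
#'
#' The interval maps when a single block covers at least \code{min_cover} of
#' it; coordinates are transformed affinely within the block
#' (orientation-aware: minus blocks reverse the interval). Returns NULL when
#' no block qualifies.
#'
#' @param chrom,start,end interval (0-based half-open) on the source genome.
#' @param map a \code{synteny_map}.
#' @param min_cover minimum covered fraction (default 0.95, mirroring
#'   liftOver's default minMatch).
#' @return list(chrom, start, end) on the target genome, or NULL.
#' @export
map_interval_synteny <- function(chrom, start, end, map, min_cover = 0.95) {
  cand <- map[map$src_chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cov <- overlap_width(cand$src_start, cand$src_end, start, end)
  i <- which(cov >= min_cover * (end - start))
  if (!length(i)) return(NULL)
  i <- i[which.max(cov[i])]
  b <- cand[i, ]
  if (b$orientation == "+") {
    list(chrom = b$dst_chrom,
         start = b$dst_start + (start - b$src_start),
         end = b$dst_start + (end - b$src_start))
  } else {
    list(chrom = b$dst_chrom,
         start = b$dst_start + (b$src_end - end),
         end = b$dst_start + (b$src_end - start))
  }
}

#' Classify OCR usage against a reference species
#'
#' species_specific: the OCR's interval cannot be lifted through the synteny
#' map; usage_specific: it lifts but overlaps no reference OCR;
#' usage_conserved: it lifts onto (>= 1 bp overlap) a reference OCR.
#'
#' @param ocrs normalized focal-species OCRs (\code{normalize_peak} output).
#' @param ref_ocrs normalized reference-species OCRs.
#' @param map \code{synteny_map} from focal to reference coordinates.
#' @param min_cover passed to \code{map_interval_synteny}.
#' @return character vector of usage labels, one per OCR.
#' @export
classify_ocr_usage <- function(ocrs, ref_ocrs, map, min_cover = 0.95) {
  if (!nrow(ocrs)) return(character(0))
  gr_r <- GenomicRanges::GRanges(ref_ocrs$chrom,
                                 IRanges::IRanges(ref_ocrs$start + 1,
                                                  ref_ocrs$end))
  vapply(seq_len(nrow(ocrs)), function(i) {
    m <- map_interval_synteny(ocrs$chrom[i], ocrs$start[i], ocrs$end[i], map,
                              min_cover)
    if (is.null(m)) return("species_specific")
    if (!nrow(ref_ocrs)) return("usage_specific")
    gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start + 1, m$end))
    if (GenomicRanges::countOverlaps(gr, gr_r) > 0) "usage_conserved"
    else "usage_specific"
  }, "")
}

#' Mean OCR count per promoter by divergence class
#'
#' @param assigned OCRs with assigned_gene (\code{assign_promoter_ocrs}).
#' @param classes named factor of divergence class per gene id.
#' @return data.frame: class, n_genes, n_ocrs, density (missing classes get
#'   NA density).
#' @export
ocr_density_by_class <- function(assigned, classes) {
  lv <- levels(classes)
  rows <- lapply(lv, function(cl) {
    g <- names(classes)[classes == cl]
    n_ocr <- sum(assigned$assigned_gene %in% g)
    data.frame(class = cl, n_genes = length(g), n_ocrs = n_ocr,
               density = if (length(g)) n_ocr / length(g) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation test of eQTL overlap with promoter OCRs
#'
#' Observed statistic: fraction of OCRs containing at least one eQTL that
#' targets the OCR's assigned gene. Null: per permutation, each OCR is
#' replaced by a uniformly random 501-bp window inside the same gene's
#' +2200/-500 promoter window; p = (1 + #(null >= observed)) / (1 + n_perm).
#'
#' @param assigned OCRs with assigned_gene.
#' @param eqtl data.frame: chrom, pos (0-based), target_gene.
#' @param genes data.frame: gene_id, chrom, tss (1-based), strand.
#' @param upstream,downstream promoter extents (window must fit 501 bp).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: observed, null (vector), p_value.
#' @export
permutation_overlap_test <- function(assigned, eqtl, genes,
                                     upstream = 2200, downstream = 500,
                                     n_perm = 1000, seed = 1) {
  if (upstream + downstream < 501) {
    stop("promoter window shorter than 501 bp")
  }
  gi <- match(assigned$assigned_gene, genes$gene_id)
  if (anyNA(gi)) stop("assigned gene(s) missing from the gene table")
  tss0 <- genes$tss[gi] - 1
  win <- promoter_window(tss0, genes$strand[gi], upstream, downstream)
  # per-OCR eQTL positions for the OCR's own target gene
  pos_by_gene <- split(eqtl$pos, eqtl$target_gene)
  qtl <- lapply(assigned$assigned_gene, function(g) pos_by_gene[[g]])
  hit_in <- function(starts, i) {
    q <- qtl[[i]]
    if (is.null(q)) return(rep(FALSE, length(starts)))
    vapply(starts, function(s) any(q >= s & q < s + 501), logical(1))
  }
  observed <- mean(vapply(seq_len(nrow(assigned)), function(i) {
    hit_in(assigned$start[i], i)
  }, logical(1)))
  null <- with_seed(seed, {
    maxs <- win$end - 501
    starts <- matrix(0, n_perm, nrow(assigned))
    for (i in seq_len(nrow(assigned))) {
      starts[, i] <- floor(runif(n_perm, win$start[i], maxs[i] + 1))
    }
    vapply(seq_len(n_perm), function(p) {
      mean(vapply(seq_len(nrow(assigned)), function(i) {
        hit_in(starts[p, i], i)
      }, logical(1)))
    }, numeric(1))
  })
  list(observed = observed,
       null = null,
       p_value = (1 + sum(null >= observed)) / (1 + n_perm))
}
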