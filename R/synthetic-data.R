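#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package: three
#' species (pig, mouse, human), 2000 ortholog triples, 10 obese + 10 lean
#' replicates per species, negative-binomial counts with dispersion 0.05,
#' baseline log2 mean counts uniform on [0, 11], and a planted effect-class
#' mix in which most obesity responses are conserved across species and a
#' minority are species-specific or of inverted sign.
#'
#' @param n_genes number of ortholog triples.
#' @param n_reps_per_group replicates per condition per species.
#' @param species three species labels; the first is the focal species.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param baseline_logmean_range range of per-gene baseline log2 mean counts.
#' @param effect_classes named proportions of conserved / species_specific /
#'   inverse / null genes (must sum to 1).
#' @param effect_size_log2 magnitude of planted log2 fold changes.
#' @param depth_range per-sample sequencing-depth factor range.
#' @param n_batches batches for the focal species (1 = no batch structure).
#' @param batch_effect_log2 additive log2 shift of the second batch.
#' @param promoter_len promoter record length in bp (>= 2701 so the
#'   +2200/-500 window plus the TSS base is covered).
#' @param gene_spacing bp between consecutive TSSs on the synthetic genome.
#' @param tata_plant_rate,cgi_plant_rate named per-effect-class probabilities
#'   of planting a TATA box / CpG island in the promoter.
#' @param ocr_rate named per-effect-class probabilities that a gene's
#'   promoter carries an ATAC peak.
#' @param n_peaks optional override: exactly this many genes (sampled
#'   uniformly) carry a peak instead of the class-dependent rates.
#' @param ocr_class_probs probabilities of usage_conserved / usage_specific /
#'   species_specific truth labels for focal-species OCRs per reference.
#' @param minus_block_rate fraction of synteny blocks with - orientation.
#' @param synteny_block_len synteny block length in bp.
#' @param eqtl_fraction fraction of focal OCRs carrying an eQTL that targets
#'   the OCR's gene.
#' @param n_bg_eqtl background eQTLs placed uniformly in promoters.
#' @param cons_levels named per-effect-class mean conservation scores.
#' @param omega_by_class named per-effect-class dN/dS used when mutating CDS.
#' @param n_families,n_family_species gene-family table dimensions.
#' @param family_direction_bias probability that a copy of a pig-expanded
#'   family is upregulated.
#' @param seed master seed; all outputs derive sub-streams from it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps_per_group = 10,
                       species = c("pig", "mouse", "human"),
                       nb_dispersion = 0.05,
                       baseline_logmean_range = c(0, 11),
                       effect_classes = c(conserved = 0.24,
                                          species_specific = 0.045,
                                          inverse = 0.015,
                                          null = 0.70),
                       effect_size_log2 = 2,
                       depth_range = c(0.7, 1.4),
                       n_batches = 1,
                       batch_effect_log2 = 0.3,
                       promoter_len = 2701,
                       gene_spacing = 5000,
                       tata_plant_rate = c(conserved = 0.2,
                                           species_specific = 0.6,
                                           inverse = 0.6,
                                           null = 0.3),
                       cgi_plant_rate = c(conserved = 0.7,
                                          species_specific = 0.2,
                                          inverse = 0.2,
                                          null = 0.5),
                       ocr_rate = c(conserved = 0.4,
                                    species_specific = 0.6,
                                    inverse = 0.6,
                                    null = 0.5),
                       n_peaks = NULL,
                       ocr_class_probs = c(usage_conserved = 0.65,
                                           usage_specific = 0.20,
                                           species_specific = 0.15),
                       minus_block_rate = 0.2,
                       synteny_block_len = 5000,
                       eqtl_fraction = 0.3,
                       n_bg_eqtl = 200,
                       cons_levels = c(conserved = 0.65,
                                       species_specific = 0.35,
                                       inverse = 0.35,
                                       null = 0.5),
                       omega_by_class = c(conserved = 0.4,
                                          species_specific = 0.1,
                                          inverse = 0.1,
                                          null = 0.2),
                       n_families = 300,
                       n_family_species = 11,
                       family_direction_bias = 0.8,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  cls <- c("conserved", "species_specific", "inverse", "null")
  if (!setequal(names(cfg$effect_classes), cls)) {
    stop("effect_classes must name conserved, species_specific, inverse, null")
  }
  if (abs(sum(cfg$effect_classes) - 1) > 1e-8 || any(cfg$effect_classes < 0)) {
    stop("effect_classes proportions must be non-negative and sum to 1")
  }
  if (cfg$n_genes < 1 || cfg$n_reps_per_group < 1) stop("counts must be >= 1")
  if (length(cfg$species) != 3) stop("exactly 3 species are required")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$promoter_len < 2701) {
    stop("promoter_len must be >= 2701 to cover the +2200/-500 window")
  }
  if (!is.null(cfg$n_peaks) && cfg$n_peaks < 1) stop("n_peaks must be >= 1")
  invisible(cfg)
}

effect_class_levels <- c("conserved", "species_specific", "inverse", "null")

# Truth assignment shared by all generator stages: classes, signs, per-species
# true log2 fold changes, and which species carries a species-specific effect.
sim_truth <- function(config) {
  with_seed(substream_seed(config$seed, 1), {
    n <- config$n_genes
    cls <- sample(effect_class_levels, n, replace = TRUE,
                  prob = config$effect_classes[effect_class_levels])
    sign <- sample(c(-1, 1), n, replace = TRUE)
    target <- sample(config$species, n, replace = TRUE)
    e <- config$effect_size_log2
    lfc <- matrix(0, n, 3, dimnames = list(NULL, config$species))
    for (i in seq_len(n)) {
      if (cls[i] == "conserved") {
        lfc[i, ] <- sign[i] * e
      } else if (cls[i] == "species_specific") {
        lfc[i, target[i]] <- sign[i] * e
      } else if (cls[i] == "inverse") {
        lfc[i, 1] <- sign[i] * e
        lfc[i, 2:3] <- -sign[i] * e
      }
    }
    gid <- sprintf("OG%04d", seq_len(n))
    truth <- data.frame(gene_id = gid, true_class = cls,
                        stringsAsFactors = FALSE)
    for (sp in config$species) {
      truth[[paste0("true_lfc_", sp)]] <- lfc[, sp]
    }
    truth$baseline_log2mean <- runif(n, config$baseline_logmean_range[1],
                                     config$baseline_logmean_range[2])
    truth$planted_tata <- runif(n) < config$tata_plant_rate[cls]
    truth$planted_cgi <- runif(n) < config$cgi_plant_rate[cls]
    truth
  })
}

#' Simulate per-species count matrices with planted effects
#'
#' Negative-binomial gene x sample counts for each species, with the obese
#' group's mean shifted by the gene's true log2 fold change and per-sample
#' depth factors making normalization non-trivial. The ortholog map is the
#' identity over the synthetic ids. Deterministic given the seed.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{counts} (named list per species: counts matrix,
#'   samples data.frame), \code{lengths} (named list of per-gene effective
#'   lengths), \code{orthologs} (1:1:1 map), and \code{truth}.
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  truth <- sim_truth(config)
  n <- config$n_genes
  nr <- config$n_reps_per_group
  orth <- data.frame(lapply(config$species, function(sp) {
    paste0(truth$gene_id, "_", sp)
  }), stringsAsFactors = FALSE)
  names(orth) <- config$species
  counts <- list()
  lengths <- list()
  for (k in seq_along(config$species)) {
    sp <- config$species[k]
    res <- with_seed(substream_seed(config$seed, 10 + k), {
      gid <- orth[[sp]]
      len <- round(runif(n, 500, 5000))
      names(len) <- gid
      depth <- runif(2 * nr, config$depth_range[1], config$depth_range[2])
      cond <- rep(c("obese", "lean"), each = nr)
      mu0 <- 2^truth$baseline_log2mean
      lfc <- truth[[paste0("true_lfc_", sp)]]
      mu <- cbind(matrix(mu0 * 2^lfc, n, nr), matrix(mu0, n, nr))
      batch <- rep("b1", 2 * nr)
      if (k == 1 && config$n_batches > 1) {
        batch <- rep(rep(paste0("b", seq_len(config$n_batches)),
                         length.out = nr), 2)
        shift <- batch != "b1"
        mu[, shift] <- mu[, shift, drop = FALSE] * 2^config$batch_effect_log2
      }
      mu <- sweep(mu, 2, depth, "*")
      cm <- matrix(rnbinom(n * 2 * nr, mu = mu, size = 1 / config$nb_dispersion),
                   n, 2 * nr)
      rownames(cm) <- gid
      colnames(cm) <- paste0(sp, "_", cond, "_", rep(seq_len(nr), 2))
      samples <- data.frame(sample_id = colnames(cm), species = sp,
                            condition = cond, muscle = "skeletal",
                            replicate = rep(seq_len(nr), 2), batch = batch,
                            stringsAsFactors = FALSE)
      list(cm = cm, samples = samples, len = len)
    })
    counts[[sp]] <- list(counts = res$cm, samples = res$samples)
    lengths[[sp]] <- res$len
  }
  list(counts = counts, lengths = lengths, orthologs = orth, truth = truth)
}

# A CpG-dense, GC-rich island satisfying the Gardiner-Garden & Frommer
# criteria (length >= 200, GC >= 0.5, obs/exp CpG >= 0.6) by construction.
cgi_sequence <- function(len = 250) {
  units <- sample(c("CG", "GC", "AT", "CC", "GG"), ceiling(len / 2),
                  replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
  substr(paste(units, collapse = ""), 1, len)
}

tata_consensus <- function() "TATAAAAG"

#' Simulate gene models, promoter/CDS sequences, conservation and CGIs
#'
#' Builds one synthetic chromosome per species with evenly spaced TSSs and a
#' 50/50 strand mix; plants the TATA consensus inside the [+200,-50] TSS
#' window for genes flagged planted_tata and a Gardiner-Garden & Frommer
#' CpG island overlapping the [+300,-100] window for genes flagged
#' planted_cgi; emits a per-base conservation track over promoters whose
#' per-class mean levels come from \code{cons_levels}; and writes CDS pairs
#' mutated from the human sequence at the per-class dN/dS in
#' \code{omega_by_class}.
#'
#' @param config a \code{sim_config}.
#' @param sim output of \code{simulate_counts} (re-generated when NULL).
#' @param n_codons CDS length in codons.
#' @return list with per-species \code{genes} (gene_id, chrom, tss, strand;
#'   TSS 1-based), \code{genome} (DNAStringSet), \code{promoters}
#'   (DNAStringSet, transcribed strand, +2200/-500 window plus the TSS base),
#'   \code{conservation} (bedGraph-like data.frame), \code{cgi} (BED-like
#'   data.frame), \code{cds} (DNAStringSet), plus the \code{truth} table.
#' @export
simulate_annotation_and_sequences <- function(config, sim = NULL,
                                              n_codons = 120) {
  validate_sim_config(config)
  if (is.null(sim)) sim <- simulate_counts(config)
  truth <- sim$truth
  n <- config$n_genes
  out <- list(truth = truth)
  for (k in seq_along(config$species)) {
    sp <- config$species[k]
    out[[sp]] <- with_seed(substream_seed(config$seed, 20 + k), {
      chrom <- "chr1"
      chrom_len <- (n + 1) * config$gene_spacing
      gvec <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
      tss0 <- config$gene_spacing * seq_len(n)        # 0-based TSS position
      strand <- sample(c("+", "-"), n, replace = TRUE)
      cgi_list <- list()
      for (i in which(truth$planted_cgi)) {
        isl <- strsplit(cgi_sequence(250), "")[[1]]
        at <- tss0[i] - 125                            # spans the TSS
        gvec[(at + 1):(at + length(isl))] <- isl
        cgi_list[[length(cgi_list) + 1]] <-
          data.frame(chrom = chrom, start = at, end = at + length(isl),
                     name = paste0("CGI_", truth$gene_id[i]),
                     stringsAsFactors = FALSE)
      }
      # plant TATA at the canonical -30 position (transcribed orientation),
      # after CGIs so a TSS-spanning island cannot overwrite the box
      motif <- strsplit(tata_consensus(), "")[[1]]
      rcmotif <- rev(chartr("ACGT", "TGCA", motif))
      for (i in which(truth$planted_tata)) {
        if (strand[i] == "+") {
          at <- tss0[i] - 30                           # 0-based motif start
          gvec[(at + 1):(at + length(motif))] <- motif
        } else {
          at <- tss0[i] + 30 - length(motif) + 1
          gvec[(at + 1):(at + length(motif))] <- rcmotif
        }
      }
      cgi_rows <- if (length(cgi_list)) do.call(rbind, cgi_list) else
        data.frame(chrom = character(), start = integer(),
                   end = integer(), name = character())
      genes <- data.frame(gene_id = paste0(truth$gene_id, "_", sp),
                          chrom = chrom, tss = tss0 + 1, strand = strand,
                          stringsAsFactors = FALSE)
      gset <- Biostrings::DNAStringSet(setNames(paste(gvec, collapse = ""),
                                                chrom))
      win <- promoter_window(tss0, strand, upstream = 2200, downstream = 501)
      prom <- extract_windows(gset, rep(chrom, n), win$start, win$end, strand)
      names(prom) <- genes$gene_id
      # conservation: 50-bp runs around a class mean, clamped to [0, 1]
      lev <- config$cons_levels[truth$true_class]
      cons <- do.call(rbind, lapply(seq_len(n), function(i) {
        st <- seq(win$start[i], win$end[i] - 1, by = 50)
        en <- pmin(st + 50, win$end[i])
        data.frame(chrom = chrom, start = st, end = en,
                   score = round(pmin(pmax(lev[i] + rnorm(length(st), 0, 0.08),
                                           0), 1), 3))
      }))
      list(genes = genes, genome = gset, promoters = prom,
           conservation = cons, cgi = cgi_rows, tss0 = tss0, strand = strand)
    })
  }
  # CDS: human is the reference; other species are mutated copies whose
  # accepted substitutions follow the class dN/dS.
  human_cds <- with_seed(substream_seed(config$seed, 29),
                         vapply(seq_len(n), function(i) random_cds(n_codons), ""))
  for (k in seq_along(config$species)) {
    sp <- config$species[k]
    out[[sp]]$cds <- with_seed(substream_seed(config$seed, 30 + k), {
      if (sp == "human") {
        cds <- human_cds
      } else {
        om <- config$omega_by_class[truth$true_class]
        cds <- vapply(seq_len(n), function(i) {
          mutate_cds(human_cds[i], omega = om[i], n_events = 25)
        }, "")
      }
      Biostrings::DNAStringSet(setNames(cds, paste0(truth$gene_id, "_", sp)))
    })
  }
  out
}

# Random CDS with no internal stop codons, ATG start, terminal stop excluded.
random_cds <- function(n_codons) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    names(which(Biostrings::GENETIC_CODE == "*")))
  paste(c("ATG", sample(codons, n_codons - 1, replace = TRUE)), collapse = "")
}

# Propose random single-nucleotide changes; accept synonymous ones always and
# nonsynonymous ones with probability omega; reject changes creating stops.
mutate_cds <- function(seq, omega, n_events = 25) {
  code <- Biostrings::GENETIC_CODE
  s <- strsplit(seq, "")[[1]]
  nc <- length(s) %/% 3
  for (e in seq_len(n_events)) {
    pos <- sample(length(s), 1)
    cod_i <- (pos - 1) %/% 3
    cod <- paste(s[cod_i * 3 + 1:3], collapse = "")
    alt <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
    s2 <- s
    s2[pos] <- alt
    cod2 <- paste(s2[cod_i * 3 + 1:3], collapse = "")
    if (code[cod2] == "*") next
    syn <- code[cod] == code[cod2]
    if (syn || runif(1) < omega) s <- s2
  }
  paste(s, collapse = "")
}

#' Simulate ATAC peaks, synteny maps and eQTLs with known usage labels
#'
#' For each focal-species (first species) gene whose promoter carries a
#' planted peak, a usage truth label versus each reference species is drawn
#' from \code{ocr_class_probs} and realized by construction: species_specific
#' omits the synteny block over that promoter; usage_specific includes the
#' block but no reference peak; usage_conserved includes both, with the
#' reference peak placed at the homologous offset (orientation-aware for
#' minus blocks). eQTLs are planted inside \code{eqtl_fraction} of focal OCR
#' windows targeting the OCR's gene, plus uniform background eQTLs.
#'
#' @param config a \code{sim_config}.
#' @param ann output of \code{simulate_annotation_and_sequences}.
#' @return list with \code{peaks} (named per species: narrowPeak-like
#'   data.frame with summit offsets), \code{synteny} (named "focal_ref"
#'   block data.frames), \code{eqtl} (focal-species table), and
#'   \code{ocr_truth} (gene_id, peak id, anchor, per-reference true label).
#' @export
simulate_atac_and_synteny <- function(config, ann = NULL) {
  validate_sim_config(config)
  if (is.null(ann)) ann <- simulate_annotation_and_sequences(config)
  truth <- ann$truth
  n <- config$n_genes
  focal <- config$species[1]
  refs <- config$species[-1]
  with_seed(substream_seed(config$seed, 40), {
    if (is.null(config$n_peaks)) {
      has_peak <- runif(n) < config$ocr_rate[truth$true_class]
    } else {
      has_peak <- rep(FALSE, n)
      has_peak[sample(n, min(config$n_peaks, n))] <- TRUE
    }
    fg <- ann[[focal]]
    peaks <- list()
    synteny <- list()
    # focal peak anchors: uniform inside the +2200/-500 promoter window,
    # kept >= 260 bp from window edges so the 501-bp OCR stays inside it
    anchor_off <- round(runif(n, -1940, 240))          # offset from TSS, oriented
    anchor <- ifelse(fg$strand == "+", fg$tss0 + anchor_off,
                     fg$tss0 - anchor_off)
    half <- round(runif(n, 100, 400))
    ptab <- data.frame(chrom = "chr1",
                       start = pmax(anchor - half, 0),
                       end = anchor + half + 1,
                       name = paste0("peak_", truth$gene_id),
                       score = round(runif(n, 10, 1000)),
                       strand = ".", signalValue = round(runif(n, 1, 50), 2),
                       pValue = -1, qValue = -1,
                       summit = anchor - pmax(anchor - half, 0),
                       stringsAsFactors = FALSE)
    peaks[[focal]] <- ptab[has_peak, , drop = FALSE]
    ocr_truth <- data.frame(gene_id = truth$gene_id[has_peak],
                            peak_id = ptab$name[has_peak],
                            anchor = anchor[has_peak],
                            stringsAsFactors = FALSE)
    for (r in refs) {
      rg <- ann[[r]]
      lab <- sample(names(config$ocr_class_probs), sum(has_peak),
                    replace = TRUE, prob = config$ocr_class_probs)
      ocr_truth[[paste0("true_usage_", r)]] <- lab
      blk <- NULL
      ref_rows <- NULL
      idx <- which(has_peak)
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (lab[j] == "species_specific") next
        # block: focal promoter neighborhood -> homologous ref neighborhood
        L <- config$synteny_block_len
        src_s <- fg$tss0[i] - L %/% 2
        src_e <- src_s + L
        dst_s <- rg$tss0[i] - L %/% 2
        dst_e <- dst_s + L
        orient <- if (runif(1) < config$minus_block_rate) "-" else "+"
        blk <- rbind(blk, data.frame(src_chrom = "chr1", src_start = src_s,
                                     src_end = src_e, dst_chrom = "chr1",
                                     dst_start = dst_s, dst_end = dst_e,
                                     orientation = orient,
                                     stringsAsFactors = FALSE))
        if (lab[j] == "usage_conserved") {
          # reference peak centered on the homologous anchor
          a <- anchor[i]
          ra <- if (orient == "+") dst_s + (a - src_s) else
            dst_s + (src_e - 1 - a)
          rh <- 150
          ref_rows <- rbind(ref_rows, data.frame(
            chrom = "chr1", start = ra - rh, end = ra + rh + 1,
            name = paste0("peak_", r, "_", truth$gene_id[i]),
            score = 500, strand = ".", signalValue = 10, pValue = -1,
            qValue = -1, summit = rh, stringsAsFactors = FALSE))
        }
      }
      peaks[[r]] <- ref_rows %||%
        data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), score = numeric(), strand = character(),
                   signalValue = numeric(), pValue = numeric(),
                   qValue = numeric(), summit = integer())
      synteny[[paste0(focal, "_", r)]] <- blk %||%
        data.frame(src_chrom = character(), src_start = integer(),
                   src_end = integer(), dst_chrom = character(),
                   dst_start = integer(), dst_end = integer(),
                   orientation = character())
    }
    # eQTLs: planted inside a fraction of focal 501-bp OCR windows
    n_ocr <- nrow(ocr_truth)
    carry <- runif(n_ocr) < config$eqtl_fraction
    eq <- NULL
    if (any(carry)) {
      pos <- ocr_truth$anchor[carry] + sample(-250:250, sum(carry), TRUE)
      eq <- data.frame(chrom = "chr1", pos = pos,
                       target_gene = paste0(ocr_truth$gene_id[carry], "_", focal),
                       stringsAsFactors = FALSE)
    }
    if (config$n_bg_eqtl > 0) {
      gi <- sample(n, config$n_bg_eqtl, replace = TRUE)
      off <- round(runif(config$n_bg_eqtl, -2200, 499))
      pos <- ifelse(fg$strand[gi] == "+", fg$tss0[gi] + off,
                    fg$tss0[gi] - off)
      eq <- rbind(eq, data.frame(chrom = "chr1", pos = pos,
                                 target_gene = sample(paste0(truth$gene_id, "_",
                                                             focal), config$n_bg_eqtl,
                                                      replace = TRUE),
                                 stringsAsFactors = FALSE))
    }
    list(peaks = peaks, synteny = synteny,
         eqtl = eq %||% data.frame(chrom = character(), pos = integer(),
                                   target_gene = character()),
         ocr_truth = ocr_truth)
  })
}

#' Simulate gene-family copy-number tables with planted evolution
#'
#' Eleven-species copy-number rows with an external birth-death p-value
#' column. Planted pig-expanded (or contracted) families satisfy the
#' median-of-other-species rule by construction and carry a planted
#' direction bias in their member copies' log2 fold changes.
#'
#' @param config a \code{sim_config}.
#' @param prop_expanded,prop_contracted planted family fractions.
#' @return list with \code{families} (family_id, one copy column per
#'   species, p_value, true_evo) and \code{members} (family_id, gene_id,
#'   log2fc for the focal species).
#' @export
simulate_families <- function(config, prop_expanded = 0.15,
                              prop_contracted = 0.15) {
  validate_sim_config(config)
  sp11 <- c("rat", "mouse", "hamster", "macaque", "chimpanzee", "human",
            "horse", "pig", "cow", "sheep", "elephant")
  sp11 <- sp11[seq_len(max(3, min(config$n_family_species, 11)))]
  focal <- "pig"
  if (!focal %in% sp11) sp11[1] <- focal
  with_seed(substream_seed(config$seed, 50), {
    nf <- config$n_families
    evo <- sample(c("expanded", "contracted", "neither"), nf, TRUE,
                  prob = c(prop_expanded, prop_contracted,
                           1 - prop_expanded - prop_contracted))
    base <- sample(2:6, nf, TRUE)
    cp <- matrix(0L, nf, length(sp11), dimnames = list(NULL, sp11))
    for (s in sp11) cp[, s] <- pmax(base + sample(-1:1, nf, TRUE), 0L)
    med_others <- apply(cp[, setdiff(sp11, focal), drop = FALSE], 1, median)
    cp[, focal] <- ifelse(evo == "expanded",
                          ceiling(med_others) + sample(2:5, nf, TRUE),
                          ifelse(evo == "contracted",
                                 pmax(floor(med_others) - sample(1:2, nf, TRUE), 0L),
                                 round(med_others)))
    p <- ifelse(evo == "neither", runif(nf, 0.05, 1), runif(nf, 0, 0.049))
    fam <- data.frame(family_id = sprintf("FAM%04d", seq_len(nf)),
                      stringsAsFactors = FALSE)
    for (s in sp11) fam[[s]] <- cp[, s]
    fam$p_value <- p
    fam$true_evo <- evo
    members <- do.call(rbind, lapply(seq_len(nf), function(i) {
      k <- cp[i, focal]
      if (k == 0) return(NULL)
      bias <- switch(evo[i], expanded = config$family_direction_bias,
                     contracted = 1 - config$family_direction_bias, 0.5)
      up <- runif(k) < bias
      data.frame(family_id = fam$family_id[i],
                 gene_id = paste0(fam$family_id[i], "_g", seq_len(k)),
                 log2fc = ifelse(up, abs(rnorm(k, 1, 0.5)),
                                 -abs(rnorm(k, 1, 0.5))),
                 stringsAsFactors = FALSE)
    }))
    list(families = fam, members = members)
  })
}

#' @importFrom stats rnorm
NULL

#' Write a full synthetic data bundle to disk
#'
#' Emits every pipeline input as plain text: counts.<sp>.tsv, samples.tsv,
#' lengths.<sp>.tsv, orthologs.tsv, genes.<sp>.tsv, promoters.<sp>.fa,
#' cds.<sp>.fa, cons.<sp>.bedGraph, cgi.<sp>.bed, peaks.<sp>.narrowPeak,
#' synteny.<src>_<dst>.tsv, eqtl.<sp>.tsv, families.tsv,
#' family_members.tsv, truth.tsv.
#'
#' @param config a \code{sim_config}.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  ann <- simulate_annotation_and_sequences(config, sim)
  atac <- simulate_atac_and_synteny(config, ann)
  fams <- simulate_families(config)
  all_samples <- NULL
  for (sp in config$species) {
    cm <- sim$counts[[sp]]$counts
    write_tsv(data.frame(gene_id = rownames(cm), cm, check.names = FALSE),
              file.path(dir, paste0("counts.", sp, ".tsv")))
    write_tsv(data.frame(gene_id = names(sim$lengths[[sp]]),
                         length = sim$lengths[[sp]]),
              file.path(dir, paste0("lengths.", sp, ".tsv")))
    all_samples <- rbind(all_samples, sim$counts[[sp]]$samples)
    write_tsv(ann[[sp]]$genes, file.path(dir, paste0("genes.", sp, ".tsv")))
    Biostrings::writeXStringSet(ann[[sp]]$promoters,
                                file.path(dir, paste0("promoters.", sp, ".fa")))
    Biostrings::writeXStringSet(ann[[sp]]$cds,
                                file.path(dir, paste0("cds.", sp, ".fa")))
    write.table(ann[[sp]]$conservation,
                file.path(dir, paste0("cons.", sp, ".bedGraph")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(ann[[sp]]$cgi, file.path(dir, paste0("cgi.", sp, ".bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    pk <- atac$peaks[[sp]]
    if (!is.null(pk)) {
      write.table(pk, file.path(dir, paste0("peaks.", sp, ".narrowPeak")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  write_tsv(all_samples, file.path(dir, "samples.tsv"))
  write_tsv(sim$orthologs, file.path(dir, "orthologs.tsv"))
  for (nm in names(atac$synteny)) {
    write_tsv(atac$synteny[[nm]], file.path(dir, paste0("synteny.", nm, ".tsv")))
  }
  write_tsv(atac$eqtl, file.path(dir, paste0("eqtl.", config$species[1], ".tsv")))
  write_tsv(fams$families, file.path(dir, "families.tsv"))
  write_tsv(fams$members, file.path(dir, "family_members.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
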