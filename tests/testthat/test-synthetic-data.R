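test_that("configuration validation catches bad proportions and sizes", {
  expect_error(sim_config(effect_classes = c(conserved = 0.5,
                                             species_specific = 0.5,
                                             inverse = 0.5, null = 0.5)),
               "sum to 1")
  expect_error(sim_config(n_genes = 0), ">= 1")
  expect_error(sim_config(promoter_len = 100), "2701")
  expect_error(sim_config(species = c("a", "b")), "3 species")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_study(n_genes = 80, n_reps = 3, seed = 101)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$pig$counts, b$counts$pig$counts)
  expect_identical(a$truth, b$truth)
  annA <- simulate_annotation_and_sequences(cfg, a)
  annB <- simulate_annotation_and_sequences(cfg, b)
  expect_identical(as.character(annA$pig$promoters),
                   as.character(annB$pig$promoters))
  expect_identical(as.character(annA$mouse$cds), as.character(annB$mouse$cds))
  atacA <- simulate_atac_and_synteny(cfg, annA)
  atacB <- simulate_atac_and_synteny(cfg, annB)
  expect_identical(atacA$peaks$pig, atacB$peaks$pig)
  expect_identical(atacA$eqtl, atacB$eqtl)
  # different seed changes the data
  c2 <- simulate_counts(tiny_study(n_genes = 80, n_reps = 3, seed = 102))
  expect_false(identical(a$counts$pig$counts, c2$counts$pig$counts))
})

test_that("null simulation centers empirical log2FC on zero", {
  cfg <- sim_config(n_genes = 2000,
                    effect_classes = c(conserved = 0, species_specific = 0,
                                       inverse = 0, null = 1),
                    depth_range = c(1, 1), seed = 103)
  sim <- simulate_counts(cfg)
  cm <- sim$counts$pig$counts
  cond <- sim$counts$pig$samples$condition
  lfc <- log2((rowMeans(cm[, cond == "obese"]) + 0.5) /
              (rowMeans(cm[, cond == "lean"]) + 0.5))
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("planted conserved effects reproduce the NB group-mean shift", {
  cfg <- sim_config(n_genes = 400, n_reps_per_group = 10,
                    effect_classes = c(conserved = 1, species_specific = 0,
                                       inverse = 0, null = 0),
                    effect_size_log2 = 1, depth_range = c(1, 1),
                    baseline_logmean_range = c(6, 10), seed = 104)
  sim <- simulate_counts(cfg)
  ratio <- sapply(cfg$species, function(sp) {
    cm <- sim$counts[[sp]]$counts
    cond <- sim$counts[[sp]]$samples$condition
    log2(rowMeans(cm[, cond == "obese"]) / rowMeans(cm[, cond == "lean"]))
  })
  signed <- ratio * sign(sim$truth$true_lfc_pig)
  per_gene <- rowMeans(signed)
  expect_true(mean(abs(per_gene - 1) < 0.2) > 0.95)
  expect_lt(abs(mean(per_gene) - 1), 0.05)
})

test_that("planted class proportions match the configuration within sampling error", {
  cfg <- sim_config(n_genes = 2000, seed = 105)
  tr <- orthodiv:::sim_truth(cfg)
  expect_equal(nrow(tr), 2000)
  expect_false(anyDuplicated(tr$gene_id) > 0)
  obs <- table(tr$true_class)[names(cfg$effect_classes)] / 2000
  expect_true(all(abs(obs - cfg$effect_classes) < 0.03))
  p <- chisq.test(table(factor(tr$true_class,
                               levels = names(cfg$effect_classes))),
                  p = cfg$effect_classes)$p.value
  expect_gt(p, 0.001)
})

test_that("planted TATA and CGI features sit in their TSS windows, strand-aware", {
  cfg <- tiny_study(n_genes = 120, n_reps = 2, seed = 106)
  ann <- simulate_annotation_and_sequences(cfg, simulate_counts(cfg))
  tr <- ann$truth
  g <- ann$pig
  cons_str <- tata_consensus()
  for (i in which(tr$planted_tata)) {
    # the [+200, -50] oriented window cut from the promoter record
    win <- substr(as.character(g$promoters[[i]]), 2001, 2250)
    expect_true(grepl(cons_str, win, fixed = TRUE))
  }
  # minus-strand promoter record equals revcomp of the genomic plus window
  i <- which(g$strand == "-")[1]
  t0 <- g$tss0[i]
  raw <- Biostrings::subseq(g$genome[["chr1"]], t0 - 501 + 1, t0 + 2200)
  expect_equal(as.character(g$promoters[[i]]),
               as.character(Biostrings::reverseComplement(raw)))
  # plus-strand record is the plain genomic window (round trip)
  j <- which(g$strand == "+")[1]
  t0j <- g$tss0[j]
  expect_equal(as.character(g$promoters[[j]]),
               as.character(Biostrings::subseq(g$genome[["chr1"]],
                                               t0j - 2200 + 1, t0j + 501)))
  # strand mix near 50/50
  expect_lt(abs(mean(g$strand == "+") - 0.5), 0.15)
  # CGI rows overlap the [+300, -100] windows of flagged genes
  cls <- setNames(factor(tr$planted_cgi, levels = c(FALSE, TRUE)),
                  g$genes$gene_id)
  cg <- cgi_overlap_fraction(g$genes, g$cgi, cls)
  expect_equal(unname(cg$fractions[["TRUE"]]), 1)
  expect_equal(unname(cg$fractions[["FALSE"]]), 0)
})

test_that("planted CpG islands satisfy the Gardiner-Garden & Frommer criteria", {
  set.seed(107)
  for (i in 1:20) {
    s <- orthodiv:::cgi_sequence(250)
    expect_gte(nchar(s), 200)
    chars <- strsplit(s, "")[[1]]
    gc <- mean(chars %in% c("G", "C"))
    cpg <- length(gregexpr("CG", s, fixed = TRUE)[[1]])
    obs_exp <- cpg * nchar(s) / (sum(chars == "C") * sum(chars == "G"))
    expect_gte(gc, 0.5)
    expect_gte(obs_exp, 0.6)
  }
})

test_that("eQTL fraction zero yields a zero overlap statistic", {
  cfg <- tiny_study(n_genes = 100, n_reps = 2, seed = 108,
                    eqtl_fraction = 0, n_bg_eqtl = 0)
  ann <- simulate_annotation_and_sequences(cfg, simulate_counts(cfg))
  atac <- simulate_atac_and_synteny(cfg, ann)
  asg <- assign_promoter_ocrs(normalize_peak(atac$peaks$pig), ann$pig$genes)
  expect_equal(nrow(atac$eqtl), 0)
  r <- permutation_overlap_test(asg, atac$eqtl, ann$pig$genes, n_perm = 99)
  expect_equal(r$observed, 0)
})

test_that("simulated family tables satisfy the median rule by construction", {
  cfg <- tiny_study(seed = 109)
  fams <- simulate_families(cfg)
  sp <- setdiff(names(fams$families), c("family_id", "p_value", "true_evo"))
  med <- apply(fams$families[, setdiff(sp, "pig")], 1, median)
  exp_rows <- fams$families$true_evo == "expanded"
  con_rows <- fams$families$true_evo == "contracted"
  expect_true(all(fams$families$pig[exp_rows] > med[exp_rows]))
  expect_true(all(fams$families$pig[con_rows] < med[con_rows]))
  expect_true(all(fams$families$p_value[exp_rows | con_rows] < 0.05))
  # member counts match the focal copy number
  cnt <- table(fams$members$family_id)
  nz <- fams$families$pig > 0
  expect_equal(unname(cnt[fams$families$family_id[nz]]),
               unname(as.table(fams$families$pig[nz])),
               ignore_attr = TRUE)
})

test_that("a full simulation bundle writes plain-text files that re-read", {
  dir <- file.path(tempdir(), "simbundle")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- tiny_study(n_genes = 40, n_reps = 2, seed = 110)
  write_simulation(cfg, dir)
  files <- list.files(dir)
  expect_true(all(c("counts.pig.tsv", "samples.tsv", "orthologs.tsv",
                    "genes.human.tsv", "promoters.mouse.fa", "cds.pig.fa",
                    "cons.pig.bedGraph", "cgi.pig.bed",
                    "peaks.pig.narrowPeak", "synteny.pig_mouse.tsv",
                    "eqtl.pig.tsv", "families.tsv", "truth.tsv") %in% files))
  cm <- read.table(file.path(dir, "counts.pig.tsv"), header = TRUE,
                   sep = "\t", check.names = FALSE)
  expect_equal(nrow(cm), 40)
  prom <- Biostrings::readDNAStringSet(file.path(dir, "promoters.pig.fa"))
  expect_equal(length(prom), 40)
  expect_true(all(Biostrings::width(prom) == 2701))
})
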