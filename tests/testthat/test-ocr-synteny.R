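test_that("peak normalization emits 501-bp intervals, summit-anchored, edge-shifted", {
  p <- data.frame(chrom = "chr1", start = 1000, end = 1400)
  o <- normalize_peak(p)
  expect_equal(c(o$start, o$end), c(950, 1451))
  expect_equal(o$end - o$start, 501)

  # summit near the chromosome start shifts inward
  p2 <- data.frame(chrom = "chr1", start = 50, end = 300, summit = 50)
  o2 <- normalize_peak(p2, chrom_len = c(chr1 = 10000))
  expect_equal(c(o2$start, o2$end), c(0, 501))

  # summit anchoring (narrowPeak offset-from-start semantics)
  p3 <- data.frame(chrom = "chr1", start = 1000, end = 1400, summit = 100)
  expect_equal(normalize_peak(p3)$anchor, 1100)

  # short chromosome dropped with warning
  p4 <- data.frame(chrom = c("tiny", "chr1"), start = c(10, 600),
                   end = c(20, 800), summit = c(NA, NA))
  expect_warning(o4 <- normalize_peak(p4, chrom_len = c(tiny = 400, chr1 = 1e4)),
                 "dropped")
  expect_equal(nrow(o4), 1)
  expect_true(all(o4$end - o4$start == 501))
})

test_that("OCRs are assigned to the nearest promoter with lexicographic ties", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(10001, 20001), strand = "+")
  ocr_at <- function(center) data.frame(chrom = "chr1", start = center - 250,
                                        end = center + 251, peak_id = "p",
                                        anchor = center)
  # centered on a TSS -> retained
  a <- assign_promoter_ocrs(ocr_at(10000), genes)
  expect_equal(a$assigned_gene, "gA")
  # 3 kb upstream of every promoter -> dropped
  expect_equal(nrow(assign_promoter_ocrs(ocr_at(7000), genes)), 0)
  # equidistant between both TSSs -> lexicographically smaller gene
  mid <- assign_promoter_ocrs(ocr_at(15000), genes,
                              upstream = 6000, downstream = 6000)
  expect_equal(mid$assigned_gene, "gA")
})

test_that("synteny lifting is affine, orientation-aware and involutive", {
  map <- read_synteny(data.frame(src_chrom = "chr1", src_start = 1000,
                                 src_end = 6000, dst_chrom = "chr2",
                                 dst_start = 100000, dst_end = 105000,
                                 orientation = "+"))
  m <- map_interval_synteny("chr1", 2000, 2501, map)
  expect_equal(c(m$start, m$end), c(101000, 101501))
  expect_null(map_interval_synteny("chr1", 50, 551, map))
  expect_null(map_interval_synteny("chr9", 2000, 2501, map))

  neg <- read_synteny(data.frame(src_chrom = "chr1", src_start = 1000,
                                 src_end = 6000, dst_chrom = "chr2",
                                 dst_start = 100000, dst_end = 105000,
                                 orientation = "-"))
  fwd <- map_interval_synteny("chr1", 2000, 2501, neg)
  expect_equal(fwd$end - fwd$start, 501)
  back_map <- read_synteny(data.frame(src_chrom = "chr2", src_start = 100000,
                                      src_end = 105000, dst_chrom = "chr1",
                                      dst_start = 1000, dst_end = 6000,
                                      orientation = "-"))
  back <- map_interval_synteny(fwd$chrom, fwd$start, fwd$end, back_map)
  expect_equal(c(back$chrom, back$start, back$end),
               c("chr1", 2000, 2501))

  expect_error(read_synteny(data.frame(src_chrom = "chr1", src_start = 0,
                                       src_end = 10, dst_chrom = "chr1",
                                       dst_start = 0, dst_end = 11,
                                       orientation = "+")), "lengths differ")
})

test_that("usage classification distinguishes the three construction cases", {
  ocrs <- data.frame(chrom = "chr1", start = 2000, end = 2501,
                     peak_id = "p1", anchor = 2250)
  ident <- read_synteny(data.frame(src_chrom = "chr1", src_start = 0,
                                   src_end = 10000, dst_chrom = "chr1",
                                   dst_start = 0, dst_end = 10000,
                                   orientation = "+"))
  empty_map <- read_synteny(data.frame(src_chrom = character(),
                                       src_start = integer(),
                                       src_end = integer(),
                                       dst_chrom = character(),
                                       dst_start = integer(),
                                       dst_end = integer(),
                                       orientation = character()))
  none <- ocrs[0, ]
  expect_equal(classify_ocr_usage(ocrs, ocrs, ident), "usage_conserved")
  expect_equal(classify_ocr_usage(ocrs, none, ident), "usage_specific")
  expect_equal(classify_ocr_usage(ocrs, ocrs, empty_map), "species_specific")
})

test_that("planted usage labels are reproduced exactly on the synthetic ATAC set", {
  cfg <- tiny_study(n_genes = 250, n_reps = 2, seed = 23)
  ann <- simulate_annotation_and_sequences(cfg, simulate_counts(cfg))
  atac <- simulate_atac_and_synteny(cfg, ann)
  ocrs <- normalize_peak(atac$peaks$pig)
  expect_true(all(ocrs$end - ocrs$start == 501))
  asg <- assign_promoter_ocrs(ocrs, ann$pig$genes)
  expect_equal(nrow(asg), nrow(ocrs))   # peaks are planted inside promoters
  for (r in c("mouse", "human")) {
    lab <- classify_ocr_usage(asg, normalize_peak(atac$peaks[[r]]),
                              read_synteny(atac$synteny[[paste0("pig_", r)]]))
    truth <- atac$ocr_truth[[paste0("true_usage_", r)]][
      match(asg$peak_id, atac$ocr_truth$peak_id)]
    expect_equal(lab, truth)
  }
})

test_that("OCR density per class divides OCR counts by class sizes", {
  cls <- setNames(factor(c("high", "high", "low", "low"),
                         levels = c("low", "medium", "high")),
                  paste0("g", 1:4))
  asg <- data.frame(assigned_gene = c("g1", "g2", "g3", "g4"))
  d <- ocr_density_by_class(asg, cls)
  expect_equal(d$density[d$class %in% c("low", "high")], c(1, 1))
  expect_true(is.na(d$density[d$class == "medium"]))
  d0 <- ocr_density_by_class(asg[0, , drop = FALSE], cls)
  expect_equal(d0$density[d0$class == "high"], 0)
})

test_that("eQTL permutation test is maximal when all eQTLs sit inside OCRs", {
  genes <- data.frame(gene_id = paste0("g", 1:20), chrom = "chr1",
                      tss = seq(5001, by = 5000, length.out = 20),
                      strand = "+")
  anchors <- genes$tss - 1 - 500
  asg <- data.frame(chrom = "chr1", start = anchors - 250,
                    end = anchors + 251, peak_id = paste0("p", 1:20),
                    anchor = anchors, assigned_gene = genes$gene_id)
  eq <- data.frame(chrom = "chr1", pos = anchors, target_gene = genes$gene_id)
  r <- permutation_overlap_test(asg, eq, genes, n_perm = 199, seed = 3)
  expect_equal(r$observed, 1)
  expect_equal(r$p_value, 1 / 200)
  r2 <- permutation_overlap_test(asg, eq, genes, n_perm = 199, seed = 3)
  expect_identical(r$p_value, r2$p_value)
  expect_true(all(r$null >= 0 & r$null <= 1))
  expect_error(permutation_overlap_test(asg, eq, genes, upstream = 300,
                                        downstream = 100), "shorter than 501")
})
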