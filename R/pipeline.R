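#' Run the full cross-species divergence pipeline on synthetic data
#'
#' Generates a synthetic study from \code{config} and runs every stage:
#' per-species expression changes and DEG calls, the divergence table
#' (shrunken-log2FC SD, quartile classes, sign patterns), GSEA on the focal
#' species ranking, gene-family direction enrichment, promoter architecture
#' (TATA, CGI, conservation), OCR normalization, promoter assignment, usage
#' classification, density by class and the eQTL permutation test, and NG86
#' dN/dS by class.
#'
#' @param config a \code{sim_config}.
#' @param n_perm permutations for GSEA and the eQTL overlap test.
#' @param gene_sets optional named list of gene sets for GSEA; a default
#'   collection is built from the truth table's effect classes when NULL.
#' @return named list with each stage's results plus the generated inputs.
#' @export
run_pipeline <- function(config = sim_config(), n_perm = 200,
                         gene_sets = NULL) {
  sim <- simulate_counts(config)
  species <- config$species
  focal <- species[1]

  changes <- lapply(species, function(sp) {
    expression_changes(sim$counts[[sp]]$counts, sim$counts[[sp]]$samples,
                       sim$lengths[[sp]])
  })
  names(changes) <- species
  div <- divergence_table(changes, sim$orthologs)

  # divergence classes keyed per species gene ids
  classes <- lapply(species, function(sp) {
    setNames(div$divergence_class, div[[sp]])
  })
  names(classes) <- species

  ranked <- rank_genes(setNames(changes[[focal]]$log2fc_raw,
                                changes[[focal]]$gene_id))
  if (is.null(gene_sets)) {
    tr <- sim$truth
    gene_sets <- list(
      conserved_response = paste0(tr$gene_id[tr$true_class == "conserved"],
                                  "_", focal),
      species_specific_response = paste0(
        tr$gene_id[tr$true_class %in% c("species_specific", "inverse")],
        "_", focal))
  }
  gsea_res <- gsea(ranked, gene_sets, n_perm = max(n_perm, 100),
                   seed = substream_seed(config$seed, 60))

  fams <- simulate_families(config)
  evo <- flag_family_evolution(fams$families, "pig")
  expanded_fams <- fams$families$family_id[evo == "expanded"]
  fam_enrich <- family_direction_enrichment(
    fams$members$family_id %in% expanded_fams, fams$members$log2fc > 0)

  ann <- simulate_annotation_and_sequences(config, sim)
  proms <- lapply(species, function(sp) ann[[sp]]$promoters)
  names(proms) <- species
  tata <- tata_promoter_fraction(proms, classes)
  fg <- ann[[focal]]
  cgi <- cgi_overlap_fraction(fg$genes, fg$cgi, classes[[focal]])
  cons <- conservation_tss_profile(fg$genes, fg$conservation,
                                   classes[[focal]])

  atac <- simulate_atac_and_synteny(config, ann)
  ocrs <- normalize_peak(atac$peaks[[focal]])
  assigned <- assign_promoter_ocrs(ocrs, fg$genes)
  usage <- lapply(species[-1], function(r) {
    ref <- normalize_peak(atac$peaks[[r]])
    classify_ocr_usage(assigned, ref, read_synteny(atac$synteny[[paste0(focal, "_", r)]]))
  })
  names(usage) <- species[-1]
  density <- ocr_density_by_class(assigned, classes[[focal]])
  eqtl_test <- permutation_overlap_test(assigned, atac$eqtl, fg$genes,
                                        n_perm = n_perm,
                                        seed = substream_seed(config$seed, 61))

  dnds <- dnds_table(ann[[focal]]$cds, ann$human$cds,
                     gene_ids = names(ann[[focal]]$cds))
  omega <- setNames(dnds$omega, dnds$gene_id)
  omega_cmp <- compare_omega_by_class(omega, classes[[focal]])

  list(config = config, sim = sim, changes = changes, divergence = div,
       gsea = gsea_res, families = fams, family_evolution = evo,
       family_enrichment = fam_enrich, tata = tata, cgi = cgi,
       conservation = cons, ocrs = assigned, usage = usage,
       ocr_density = density, eqtl_test = eqtl_test, dnds = dnds,
       omega_comparison = omega_cmp)
}
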