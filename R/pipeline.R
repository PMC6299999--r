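# End-to-end convenience: one simulated study replicate through the whole
# pipeline, mirroring the real workflow — long-read sequencing for the
# affected/unaffected pair of the focal family, fragment-analysis-scale
# genotypes for the remaining relatives, other families and controls.

#' Locus libraries for a catalog
#'
#' @param catalog Repeat catalog; rows with a `compound` flag also carry
#'   sub-unit columns which are copied onto the library for downstream
#'   decomposition.
#' @param ref Named character vector of chromosome sequences.
#' @param flank_len Flank length in bases.
#' @return List of locus libraries.
#' @export
build_libraries <- function(catalog, ref, flank_len = 20) {
  lapply(seq_len(nrow(catalog)), function(i) {
    lib <- build_locus_library(catalog[i, ], ref, flank_len)
    if (isTRUE(catalog$compound[i])) {
      lib$sub_units <- c(catalog$sub1_unit[i], catalog$sub2_unit[i])
      lib$separator <- catalog$separator[i]
    }
    lib
  })
}

#' Run one simulated study replicate through the pipeline
#'
#' Simulates a reference with planted repeats, an X-linked pedigree with a
#' causal expansion, and capture reads for the sequenced affected/unaffected
#' pair of the causal family; trims, genotypes the pair from the reads, and
#' runs the candidate-filtering cascade with the remaining family members,
#' the other families and the control pool at fragment-analysis scale.
#'
#' @param config A [sim_config()].
#' @param seed Seed for this replicate (overrides the config seed).
#' @param mode Control-screen comparison mode.
#' @param min_support Minimum read support per genotype.
#' @return List: report (the [candidate_report()]), genotypes (combined
#'   table), pedigree, reference, truth (simulated genotype truth), reads.
#' @export
pipeline_replicate <- function(config = sim_config(), seed = config$seed,
                               mode = "sub_repeat", min_support = 5) {
  config$seed <- seed
  ref <- simulate_reference(config)
  ped <- simulate_pedigree_genotypes(config, ref)
  fam <- config$causal_family
  sequenced <- paste0(fam, c("_A1", "_U1"))

  reads <- simulate_reads(config, ref, ped$genotypes, sequenced)
  trimmed <- trim_adaptors(reads)
  libs <- build_libraries(ref$catalog, ref$ref)

  seq_gt <- do.call(rbind, lapply(sequenced, function(s) {
    gt <- genotype_sample(trimmed[trimmed$sample == s, , drop = FALSE],
                          libs, sample = s, min_support = min_support)
    as_genotype_table(gt, fam)
  }))
  others <- ped$genotypes[!ped$genotypes$sample %in% sequenced, , drop = FALSE]
  genotypes <- rbind(seq_gt, others[, names(seq_gt)])

  report <- candidate_report(genotypes, ped$pedigree, ped$linkage,
                             ped$controls, family = fam,
                             sequenced = sequenced, mode = mode)
  list(report = report, genotypes = genotypes, pedigree = ped$pedigree,
       reference = ref, truth = ped$genotypes, reads = reads)
}
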