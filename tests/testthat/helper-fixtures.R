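# Shared fixtures built in code.

# five moderate-GC planted loci (causal compound + four simple repeats);
# used when the property under test concerns the genotyper rather than the
# GC-dependent capture model
moderate_loci <- function() {
  list(
    list(id = "TRS01", type = "simple", unit = "GT", ref_copies = 20,
         gc_context = 0.45, pool = 16:24),
    list(id = "TRC02", type = "compound", sub_units = c("CT", "GT"),
         separator = "TTT", ref_sub = c(17, 26), gc_context = 0.45,
         pool1 = 11:20, pool2 = 24:37),
    list(id = "TRS03", type = "simple", unit = "AC", ref_copies = 18,
         gc_context = 0.45, pool = 14:22),
    list(id = "TRS04", type = "simple", unit = "TA", ref_copies = 16,
         gc_context = 0.45, pool = 12:20),
    list(id = "TRS05", type = "simple", unit = "CAG", ref_copies = 15,
         gc_context = 0.45, pool = 11:19))
}

# one simulated sample genotyped from reads, returning truth and called
# genotype tables for the sequenced affected/unaffected pair
genotype_replicate <- function(cfg, seed) {
  cfg$seed <- seed
  ref <- simulate_reference(cfg)
  ped <- simulate_pedigree_genotypes(cfg, ref)
  samples <- paste0(cfg$causal_family, c("_A1", "_U1"))
  reads <- simulate_reads(cfg, ref, ped$genotypes, samples)
  trimmed <- trim_adaptors(reads)
  libs <- build_libraries(ref$catalog, ref$ref)
  called <- do.call(rbind, lapply(samples, function(s)
    genotype_sample(trimmed[trimmed$sample == s, , drop = FALSE], libs,
                    sample = s)))
  truth <- ped$genotypes[ped$genotypes$sample %in% samples, , drop = FALSE]
  list(truth = truth, called = called, reference = ref, reads = reads)
}

# reference genotype-table fixture shaped like a published family table:
# an affected/unaffected sequenced pair, relatives, and carriers, for a
# single dinucleotide locus with alleles given in bp
family_locus_fixture <- function(aff_bp = 376, una_bp = 372,
                                 carrier2_bp = 372) {
  gts <- data.frame(
    sample = c("P1", "A2", "A3", "U1", "U2", "C1", "C2"),
    family = "FAM1",
    target_id = "LOC1", chrom = "chrX", start = 45606269, end = 45606355,
    unit_len = 2,
    allele1_bp = c(aff_bp, aff_bp, aff_bp, una_bp, una_bp, aff_bp, aff_bp),
    allele2_bp = c(NA, NA, NA, NA, NA, carrier2_bp, carrier2_bp),
    copies = NA_real_, sub1 = NA_integer_, sub2 = NA_integer_,
    sub1_2 = NA_integer_, sub2_2 = NA_integer_,
    stringsAsFactors = FALSE)
  ped <- data.frame(
    sample = c("P1", "A2", "A3", "U1", "U2", "C1", "C2"),
    family = "FAM1", sex = c("M", "M", "M", "M", "M", "F", "F"),
    phenotype = c("affected", "affected", "affected", "unaffected",
                  "unaffected", "carrier", "carrier"),
    stringsAsFactors = FALSE)
  list(genotypes = gts, pedigree = ped)
}
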