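test_that("linkage-interval restriction keeps overlapping loci only", {
  gts <- data.frame(sample = "P", family = "F", target_id = c("A", "B"),
                    chrom = "chrX",
                    start = c(45606269, 49999999),
                    end = c(45606355, 50000199),
                    unit_len = 2, allele1_bp = c(376, 100),
                    stringsAsFactors = FALSE)
  refined <- data.frame(chrom = "chrX", start = 42505937, end = 46534357)
  kept <- interval_restrict(gts, refined)
  expect_equal(kept$target_id, "A")
  set.seed(6)
  rnd <- data.frame(sample = "P", family = "F",
                    target_id = sprintf("L%02d", 1:40), chrom = "chrX",
                    start = sample(seq(1e6, 6e7, by = 1e5), 40))
  rnd$end <- rnd$start + 100
  iv <- data.frame(chrom = "chrX", start = c(5e6, 3e7), end = c(1e7, 4e7))
  got <- interval_restrict(rnd, iv)$target_id
  want <- rnd$target_id[(rnd$start < 1e7 & rnd$end > 5e6) |
                          (rnd$start < 4e7 & rnd$end > 3e7)]
  expect_setequal(got, want)
})

test_that("discordance uses copy-number units and excludes no-calls", {
  aff <- data.frame(sample = "P", family = "F",
                    target_id = c("L1", "L2", "L3"), chrom = "x",
                    start = 0, end = 100, unit_len = 2,
                    allele1_bp = c(376, 340, NA), sub1 = NA, sub2 = NA,
                    stringsAsFactors = FALSE)
  una <- aff
  una$sample <- "U"
  una$allele1_bp <- c(372, 340, 350)
  d <- discordant_loci(aff, una)
  expect_equal(d$target_id, c("L1", "L2"))
  expect_equal(d$delta_units, c(2, 0))     # 376 vs 372 at unit 2
  expect_equal(d$discordant, c(TRUE, FALSE))
  expect_equal(attr(d, "excluded"), "L3")
  # equal-length compound alleles of different composition are discordant
  aff$sub1 <- c(21, NA, NA); aff$sub2 <- c(33, NA, NA)
  una$allele1_bp[1] <- 376
  una$sub1 <- c(19, NA, NA); una$sub2 <- c(35, NA, NA)
  d2 <- discordant_loci(aff, una)
  expect_true(d2$discordant[d2$target_id == "L1"])
})

test_that("segregation verdicts follow the X-linked model", {
  # published-family pattern: affected males share 376, unaffected 372,
  # carriers heterozygous 376/372 -> consistent
  fx <- family_locus_fixture(376, 372, 372)
  expect_equal(segregation_check(fx$genotypes, fx$pedigree, "P1"),
               "consistent")
  # an unaffected male sharing the proband allele -> inconsistent
  bad <- fx$genotypes
  bad$allele1_bp[bad$sample == "U1"] <- 376
  expect_equal(segregation_check(bad, fx$pedigree, "P1"), "inconsistent")
  # every member identical: no discriminating allele -> inconsistent
  all_same <- family_locus_fixture(376, 376, 376)
  expect_equal(segregation_check(all_same$genotypes, all_same$pedigree, "P1"),
               "inconsistent")
  # a homozygous carrier is not heterozygous -> inconsistent
  hom <- fx$genotypes
  hom$allele2_bp[hom$sample == "C1"] <- 376
  expect_equal(segregation_check(hom, fx$pedigree, "P1"), "inconsistent")
  # missing member genotype -> unevaluable, not failed
  miss <- fx$genotypes[fx$genotypes$sample != "A3", ]
  expect_equal(segregation_check(miss, fx$pedigree, "P1"), "unevaluable")
  miss2 <- fx$genotypes
  miss2$allele1_bp[miss2$sample == "A3"] <- NA
  expect_equal(segregation_check(miss2, fx$pedigree, "P1"), "unevaluable")
})

test_that("adding family members can break but never restore consistency", {
  fx <- family_locus_fixture(376, 372, 372)
  sub_ped <- fx$pedigree[fx$pedigree$sample != "U2", ]
  sub_gts <- fx$genotypes[fx$genotypes$sample != "U2", ]
  expect_equal(segregation_check(sub_gts, sub_ped, "P1"), "consistent")
  # the added member carries the proband allele while unaffected
  extra_gts <- fx$genotypes
  extra_gts$allele1_bp[extra_gts$sample == "U2"] <- 376
  expect_equal(segregation_check(extra_gts, fx$pedigree, "P1"),
               "inconsistent")
})

test_that("cross-family uniqueness compares at the finest shared scale", {
  proband <- data.frame(allele1_bp = 376, sub1 = NA, sub2 = NA)
  other <- data.frame(sample = "X1", family = "F2", allele1_bp = c(372, 380),
                      allele2_bp = NA, stringsAsFactors = FALSE)
  expect_true(cross_family_unique(proband, other))
  other$allele1_bp[1] <- 376
  expect_false(cross_family_unique(proband, other))
  # the allele hiding on a carrier's second allele is found
  other2 <- data.frame(allele1_bp = 372, allele2_bp = 376)
  expect_false(cross_family_unique(proband, other2))
  # same bp, different sub-repeat composition -> still unique
  pc <- data.frame(allele1_bp = 111, sub1 = 21, sub2 = 33)
  oc <- data.frame(allele1_bp = 111, allele2_bp = NA, sub1 = 17, sub2 = 37)
  expect_true(cross_family_unique(pc, oc))
  oc2 <- data.frame(allele1_bp = 111, allele2_bp = NA, sub1 = 21, sub2 = 33)
  expect_false(cross_family_unique(pc, oc2))
  set.seed(19)
  for (i in 1:20) {   # set-membership oracle on random allele tables
    alleles <- sample(300:320, 12, TRUE)
    p <- data.frame(allele1_bp = sample(300:320, 1))
    o <- data.frame(allele1_bp = alleles, allele2_bp = NA)
    expect_equal(cross_family_unique(p, o), !(p$allele1_bp %in% alleles))
  }
})

test_that("control screening distinguishes total length from sub-repeats", {
  proband <- data.frame(allele1_bp = 111, sub1 = 21, sub2 = 33)
  controls <- data.frame(
    sample = sprintf("C%02d", 1:6), target_id = "T",
    allele1_bp = c(111, 111, 99, 103, 107, 95),
    sub1 = c(17, 20, 15, 17, 19, 13),
    sub2 = c(37, 34, 33, 33, 33, 33), stringsAsFactors = FALSE)
  tl <- control_screen(proband, controls, compare = "total_length")
  expect_equal(tl$verdict, "common")
  expect_equal(tl$n_matches, 2L)   # (17,37) and (20,34) share the length
  sr <- control_screen(proband, controls, compare = "sub_repeat")
  expect_equal(sr$verdict, "unique")
  expect_equal(sr$n_matches, 0L)
  # a verbatim match is common in both modes
  verb <- rbind(controls,
                data.frame(sample = "C07", target_id = "T",
                           allele1_bp = 111, sub1 = 21, sub2 = 33))
  expect_equal(control_screen(proband, verb, "sub_repeat")$verdict, "common")
  expect_error(control_screen(proband, controls[0, ], "total_length"),
               "empty")
  expect_error(control_screen(data.frame(allele1_bp = 111),
                              controls, "sub_repeat"), "sub_repeat")
})

test_that("the cascade recovers a planted causal locus as sole candidate", {
  r <- pipeline_replicate(sim_config(n_controls = 50), seed = 321)
  rep_df <- r$report
  expect_s3_class(rep_df, "candidate_report")
  expect_equal(rep_df$target_id[rep_df$stage == "candidate"], "TRC02")
  # the locus planted beyond the linkage interval is staged as outside
  expect_equal(rep_df$stage[rep_df$target_id == "TRS05"], "outside_interval")
  expect_true(all(table(rep_df$target_id) == 1))   # one terminal stage each
  out <- capture.output(print(rep_df))
  expect_true(any(grepl("TRC02", out)))
})

test_that("sub-repeat resolution decides the control screen verdict", {
  # an allele shared by controls at total length but unique by sub-repeats
  # is a candidate only under sub_repeat comparison
  cfg <- sim_config(n_controls = 60)
  r_sub <- pipeline_replicate(cfg, seed = 50, mode = "sub_repeat")
  r_tot <- pipeline_replicate(cfg, seed = 50, mode = "total_length")
  stage_sub <- r_sub$report$stage[r_sub$report$target_id == "TRC02"]
  stage_tot <- r_tot$report$stage[r_tot$report$target_id == "TRC02"]
  expect_equal(stage_sub, "candidate")
  expect_equal(stage_tot, "found_in_controls")
  tot_matches <- r_tot$report$control_matches[
    r_tot$report$target_id == "TRC02"]
  expect_gt(tot_matches, 0)
})

test_that("adding control samples can only shrink the candidate set", {
  r <- pipeline_replicate(sim_config(n_controls = 100), seed = 99)
  ped <- simulate_pedigree_genotypes(sim_config(seed = 99, n_controls = 100),
                                     r$reference)
  for (nc in c(10, 40, 100)) {
    sub_controls <- ped$controls[ped$controls$sample %in%
                                   sprintf("CTL%03d", 1:nc), ]
    rep_nc <- candidate_report(r$genotypes, r$pedigree,
                               data.frame(chrom = "chrS",
                                          start = min(r$genotypes$start) - 500,
                                          end = max(r$genotypes$end) + 500),
                               sub_controls, family = "F1",
                               sequenced = c("F1_A1", "F1_U1"))
    cand <- rep_nc$target_id[rep_nc$stage == "candidate"]
    if (nc == 10) cand10 <- cand
    if (nc == 40) expect_true(all(cand %in% cand10))
    if (nc == 100) expect_true(all(cand %in% cand10))
  }
})
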