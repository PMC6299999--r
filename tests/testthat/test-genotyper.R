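lib_fixture <- function(seed = 3, unit = "GT", copies = 20) {
  set.seed(seed)
  ref <- c(c1 = paste0(random_seq(500), strrep(unit, copies), random_seq(500)))
  locus <- data.frame(id = "T1", chrom = "c1", start = 500,
                      end = 500 + nchar(unit) * copies,
                      unit_seq = unit, unit_len = nchar(unit),
                      stringsAsFactors = FALSE)
  list(ref = ref, locus = locus,
       lib = build_locus_library(locus, ref, flank_len = 20))
}

test_that("locus libraries hold the exact adjacent flanks", {
  fx <- lib_fixture()
  expect_equal(fx$lib$left, substr(fx$ref[[1]], 481, 500))
  expect_equal(fx$lib$right, substr(fx$ref[[1]], 541, 560))
  expect_equal(fx$lib$ref_copies, 20)
  expect_error(build_locus_library(fx$locus, fx$ref, flank_len = 0),
               "positive")
  set.seed(8)
  for (i in 1:20) {   # slicing oracle on random loci
    ref <- c(x = random_seq(300))
    s <- sample(50:200, 1); e <- s + sample(10:50, 1)
    locus <- data.frame(id = "L", chrom = "x", start = s, end = e,
                        unit_seq = "AC", unit_len = 2)
    lib <- build_locus_library(locus, ref, 15)
    expect_equal(lib$left, substr(ref[[1]], s - 14, s))
    expect_equal(lib$right, substr(ref[[1]], e + 1, e + 15))
  }
  # a locus at the contig edge gets a truncated flank with a warning
  near <- data.frame(id = "E", chrom = "c1", start = 14, end = 40,
                     unit_seq = "A", unit_len = 1)
  expect_warning(libe <- build_locus_library(near, fx$ref, 20), "truncated")
  expect_equal(nchar(libe$left), 14)
  at_edge <- data.frame(id = "E2", chrom = "c1", start = 5, end = 40,
                        unit_seq = "A", unit_len = 1)
  expect_error(build_locus_library(at_edge, fx$ref, 20), "12")
})

test_that("the 300-base proximity filter has inclusive boundaries", {
  target <- data.frame(chrom = "c1", start = 5000, end = 5500)
  aln <- data.frame(read_id = c("a", "b", "c", "d"),
                    chrom = "c1",
                    start = c(4201, 4199, 5400, 6099),
                    end = c(4701, 4699, 5900, 6599),
                    stringsAsFactors = FALSE)
  # gaps: 299 (in), 301 (out), overlap (in), 599 (out)
  expect_setequal(filter_reads_near_target(aln, target, 300), c("a", "c"))
  set.seed(12)
  rnd <- data.frame(read_id = sprintf("r%02d", 1:50), chrom = "c1",
                    start = sample(3000:7000, 50))
  rnd$end <- rnd$start + 500
  got <- filter_reads_near_target(rnd, target, 300)
  want <- rnd$read_id[pmax(target$start - rnd$end,
                           rnd$start - target$end, 0) <= 300]
  expect_setequal(got, want)
})

test_that("per-read calls measure compound and partial alleles exactly", {
  fx <- lib_fixture(31)
  lib <- fx$lib
  allele <- paste0(strrep("CT", 21), "TTT", strrep("GT", 33))
  read <- paste0(random_seq(50), lib$left, allele, lib$right, random_seq(50))
  call <- call_allele_per_read(read, lib)
  expect_equal(call$status, "spanning")
  expect_equal(call$length_bp, 111)      # 21*2 + 3 + 33*2
  expect_false(call$is_lower_bound)
  expect_equal(call$allele_seq, allele)
  # reverse-complement reads give the same call
  rc_call <- call_allele_per_read(revcomp(read), lib)
  expect_equal(rc_call$length_bp, 111)
  expect_equal(rc_call$orientation, "-")
  expect_equal(rc_call$allele_seq, allele)

  partial <- paste0(random_seq(80), lib$left, strrep("GT", 28))
  pc <- call_allele_per_read(partial, lib)
  expect_equal(pc$status, "partial_left")
  expect_equal(pc$copies, 28)
  expect_true(pc$is_lower_bound)

  pr <- call_allele_per_read(paste0(strrep("GT", 15), lib$right,
                                    random_seq(80)), lib)
  expect_equal(pr$status, "partial_right")
  expect_equal(pr$copies, 15)

  expect_equal(call_allele_per_read(random_seq(300), lib)$status, "absent")
})

test_that("flank matching tolerates 10% substitutions and no more", {
  fx <- lib_fixture(37)
  lib <- fx$lib
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    flip <- c(A = "C", C = "G", G = "T", T = "A")
    pos <- seq(2, by = 3, length.out = k)
    ch[pos] <- flip[ch[pos]]
    paste(ch, collapse = "")
  }
  mk_read <- function(left) paste0(random_seq(40), left, strrep("GT", 20),
                                   lib$right, random_seq(40))
  for (k in 0:3) {
    read <- mk_read(mutate(lib$left, k))
    call <- call_allele_per_read(read, lib)
    # ceiling(0.1 * 20) = 2 substitutions tolerated
    if (k <= 2) expect_equal(call$status, "spanning", info = k)
    else expect_equal(call$status, "partial_right", info = k)
    # agreement with the exhaustive mismatch-count oracle
    hits <- oracle_hamming_hits(lib$left, read, 2)
    expect_equal(length(hits) > 0, call$status == "spanning", info = k)
  }
})

test_that("genotypes pool stutter around the modal allele", {
  mk_calls <- function(lens) {
    data.frame(read_id = seq_along(lens), target_id = "T",
               status = "spanning", length_bp = lens, copies = lens / 2,
               is_lower_bound = FALSE, multimatch = FALSE, orientation = "+",
               allele_seq = strrep("GT", lens / 2), stringsAsFactors = FALSE)
  }
  g <- genotype_locus(mk_calls(rep(40, 10)), unit_len = 2)
  expect_true(g$called)
  expect_equal(g$allele1_copies, 20)
  expect_equal(g$allele1_support, 10)

  g2 <- genotype_locus(mk_calls(c(rep(40, 8), 38, 42)), unit_len = 2)
  expect_equal(g2$allele1_bp, 40)
  expect_equal(g2$allele1_support, 10)   # stutter pooled within one unit

  g3 <- genotype_locus(mk_calls(rep(40, 4)), unit_len = 2, min_support = 5)
  expect_false(g3$called)

  # modal tie breaks toward the longer allele and is flagged
  g4 <- genotype_locus(mk_calls(c(rep(38, 5), rep(44, 5))), unit_len = 2)
  expect_equal(g4$allele1_bp, 44)
  expect_true(g4$tie)

  # diploid: two well-supported modes
  g5 <- genotype_locus(mk_calls(c(rep(40, 6), rep(50, 5))), unit_len = 2,
                       sex_model = "diploid")
  expect_equal(g5$allele1_bp, 40)
  expect_equal(g5$allele2_bp, 50)
  # hemizygous ignores the second mode
  g6 <- genotype_locus(mk_calls(c(rep(40, 6), rep(50, 5))), unit_len = 2)
  expect_true(is.na(g6$allele2_bp))

  none <- mk_calls(40)[0, , drop = FALSE]
  g7 <- genotype_locus(none, unit_len = 2)
  expect_false(g7$called)
  expect_equal(g7$informative, 0L)
})

test_that("expansions are flagged only when no read spans", {
  lib <- list(target_id = "T", unit_len = 26, ref_copies = 15)
  mk <- function(status, copies) {
    data.frame(read_id = seq_along(copies), target_id = "T", status = status,
               length_bp = copies * 26, copies = copies,
               is_lower_bound = status != "spanning",
               stringsAsFactors = FALSE)
  }
  ex <- detect_expansion(mk("partial_left", 24:35), lib)
  expect_true(ex$expanded)
  expect_equal(ex$bound_copies, 35)
  expect_equal(ex$bound_bp, 910)
  # a single spanning read disproves the expansion
  ex2 <- detect_expansion(rbind(mk("partial_left", 24:35),
                                mk("spanning", 16)), lib)
  expect_false(ex2$expanded)
  # partials below the reference copy number are just short fragments
  ex3 <- detect_expansion(mk("partial_left", c(8, 11, 14)), lib)
  expect_false(ex3$expanded)
})

test_that("compound decomposition parses greedily and round-trips", {
  expect_equal(unname(decompose_compound(
    paste0(strrep("CT", 21), "TTT", strrep("GT", 33)))), c(21, 33))
  expect_equal(unname(decompose_compound(
    paste0(strrep("CT", 17), "TTT", strrep("GT", 37)))), c(17, 37))
  expect_equal(unname(decompose_compound(
    paste0("TTT", strrep("GT", 5)))), c(0, 5))
  expect_warning(d <- decompose_compound(strrep("CT", 10)), "separator")
  expect_equal(unname(d), c(10, NA))
  set.seed(41)
  for (i in 1:20) {   # rebuild-and-reparse identity
    a <- sample(0:25, 1); b <- sample(1:40, 1)
    seq <- paste0(strrep("CT", a), "TTT", strrep("GT", b))
    expect_equal(unname(decompose_compound(seq)), c(a, b))
  }
})

test_that("noiseless reads recover every planted allele exactly", {
  cfg <- sim_config(seed = 404, loci = moderate_loci(), sub_rate = 0,
                    stutter_prob = 0, n_controls = 10)
  fx <- genotype_replicate(cfg, seed = 404)
  m <- merge(fx$called, fx$truth, by = c("sample", "target_id"))
  expect_equal(nrow(m), 10L)  # 2 samples x 5 loci
  expect_true(all(m$called))
  expect_equal(m$allele1_bp.x, m$allele1_bp.y)
  # copies times unit length equals measured length for pure planted repeats
  expect_equal(m$allele1_copies * m$unit_len.x, m$allele1_bp.x)
  # compound sub-repeat decomposition matches the planted truth
  cc <- m[!is.na(m$sub1.y), ]
  expect_equal(cc$sub1.x, cc$sub1.y)
  expect_equal(cc$sub2.x, cc$sub2.y)
})

test_that("partial-read bounds never exceed the planted copy number", {
  # a 35-copy expansion of a 26-base unit cannot be spanned by <=900-base
  # fragments; every call is partial and bounds the allele from below
  unit <- paste(rep(c("A", "C", "G", "T"), 7)[1:26], collapse = "")
  cfg <- sim_config(seed = 77,
                    loci = list(list(id = "EXP1", type = "simple",
                                     unit = unit, ref_copies = 15,
                                     gc_context = 0.5, pool = 13:17)),
                    causal_locus = "EXP1", proband_sub = NULL,
                    frag_len = c(800L, 900L), sub_rate = 0, stutter_prob = 0,
                    coverage = 15L, n_controls = 5)
  ref <- simulate_reference(cfg)
  truth <- data.frame(sample = "S1", family = "F1", target_id = "EXP1",
                      chrom = cfg$chrom, start = ref$catalog$start,
                      end = ref$catalog$end, unit_len = 26,
                      allele1_bp = 35 * 26, allele2_bp = NA,
                      copies = 35, sub1 = NA, sub2 = NA,
                      sub1_2 = NA, sub2_2 = NA, stringsAsFactors = FALSE)
  reads <- simulate_reads(cfg, ref, truth, "S1")
  trimmed <- trim_adaptors(reads)
  lib <- build_locus_library(ref$catalog[1, ], ref$ref)
  calls <- call_alleles(trimmed, lib)
  expect_false(any(calls$status == "spanning"))
  part <- calls[calls$status %in% c("partial_left", "partial_right"), ]
  expect_gt(nrow(part), 0)
  expect_true(all(part$copies <= 35))
  ex <- detect_expansion(calls, lib)
  expect_true(ex$expanded)
  expect_gt(ex$bound_copies, lib$ref_copies)
  expect_lte(ex$bound_bp, 910)
})
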