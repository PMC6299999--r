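test_that("a perfect dinucleotide repeat is found with its unit and copies", {
  r <- find_tandem_repeats("ACACACAC", 1, 6, min_total_len = 8,
                           min_copies = 2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit_seq, "AC")
  expect_equal(r$copies, 4)
  expect_equal(r$purity, 100)
  expect_equal(c(r$start, r$end), c(0L, 8L))
})

test_that("input validation rejects bad thresholds and alphabets", {
  expect_error(find_tandem_repeats("ACGT", 0, 6), "min_unit")
  expect_error(find_tandem_repeats("ACGT", 3, 2), "min_unit")
  expect_error(find_tandem_repeats("ACXT", 1, 2), "outside")
})

test_that("a planted repeat is recovered at its exact coordinates", {
  set.seed(11)
  bg <- random_seq(2000)
  planted <- paste0(substr(bg, 1, 800), strrep("GT", 33),
                    substr(bg, 801, 2000))
  r <- find_tandem_repeats(planted, 1, 6, min_total_len = 30, min_copies = 5)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(800L, 866L))
  expect_equal(r$copies, 33)
  expect_equal(r$unit_seq, "GT")
})

test_that("a random sequence yields no long repeats, matching the oracle", {
  set.seed(5)
  s <- random_seq(1000)
  r <- find_tandem_repeats(s, 1, 6, min_total_len = 30, min_copies = 5)
  o <- oracle_find_repeats(s, 1, 6, 30, 5)
  expect_equal(nrow(r), 0L)
  expect_equal(nrow(o), 0L)
})

test_that("repeat detection equals the exhaustive scan oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    bg <- random_seq(260)
    # plant a pure and an impure repeat to exercise merging across mismatches
    imp <- paste0(strrep("CA", 6), "TT", strrep("CA", 7))
    s <- paste0(substr(bg, 1, 60), strrep("TAG", 8), substr(bg, 61, 160),
                imp, substr(bg, 161, 260))
    r <- find_tandem_repeats(s, 1, 4, min_total_len = 12, min_copies = 3)
    o <- oracle_find_repeats(s, 1, 4, 12, 3)
    expect_equal(r$start, o$start, info = paste("seed", seed))
    expect_equal(r$end, o$end, info = paste("seed", seed))
    expect_equal(r$unit_len, o$unit_len, info = paste("seed", seed))
    expect_equal(r$unit_seq, o$unit_seq, info = paste("seed", seed))
    expect_equal(r$purity, o$purity, tolerance = 1e-12)
  }
})

test_that("purity matches hand counts and the brute-force oracle", {
  expect_equal(compute_purity(strrep("CA", 10), 0, 20, "CA"), 100)
  mut <- paste0("CG", substr(strrep("CA", 10), 3, 18), "CT")  # 2 of 20 off
  expect_equal(compute_purity(mut, 0, 20, "CA"), 90)
  expect_error(compute_purity("CACA", 0, 2, "CACAC"), "shorter")
  set.seed(9)
  for (i in 1:15) {
    unit <- random_seq(sample(1:5, 1))
    tract <- strrep(unit, 8)
    ch <- strsplit(tract, "")[[1]]
    flip <- sample(length(ch), 3)
    ch[flip] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    s <- paste(ch, collapse = "")
    expect_equal(compute_purity(s, 0, nchar(s), unit),
                 oracle_purity(s, 0, nchar(s), unit))
  }
})

test_that("variability score is monotone and equals its linear form", {
  base <- data.frame(unit_len = 2, copies = 10, purity = 100)
  more <- data.frame(unit_len = 2, copies = 20, purity = 100)
  impure <- data.frame(unit_len = 2, copies = 10, purity = 80)
  expect_gte(score_variability(more), score_variability(base))
  expect_gte(score_variability(base), score_variability(impure))
  set.seed(2)
  loci <- data.frame(unit_len = sample(1:6, 10, TRUE),
                     copies = runif(10, 2, 50), purity = runif(10, 60, 100))
  co <- serv_coefficients()
  manual <- co$intercept + co$log2_copies * log2(loci$copies) +
    co$purity * loci$purity / 100 + co$unit_len * loci$unit_len
  expect_equal(score_variability(loci), manual, tolerance = 1e-9)
  expect_error(score_variability(data.frame(unit_len = 2)), "carry")
  expect_error(serv_coefficients(log2_copies = -1), "non-negative")
})

test_that("annotation classes follow the documented precedence", {
  models <- data.frame(
    chrom = "c1",
    start = c(1000, 3000, 5000, 4500, 8000),
    end = c(1500, 3200, 5100, 5600, 8500),
    feature = c("coding", "cpg", "mirna", "gene", "intron"),
    strand = c("+", "+", "+", "+", "+"),
    name = c("ex1", "cpg1", "mir1", "g1", "g1_int"),
    stringsAsFactors = FALSE)
  loci <- data.frame(id = paste0("L", 1:5), chrom = "c1",
                     start = c(1100, 3050, 5165, 8100, 20000),
                     end = c(1140, 3090, 5205, 8140, 20040),
                     stringsAsFactors = FALSE)
  ann <- classify_annotation(loci, models)
  expect_equal(ann$annotation,
               c("coding", "regulatory", "regulatory", "intronic",
                 "intergenic"))
  # L3 sits 65 bp downstream of the miRNA gene on the plus strand
  expect_equal(ann$subtype[3], "downstream")
  # coding precedence over a regulatory overlap at the same spot
  both <- classify_annotation(
    data.frame(id = "X", chrom = "c1", start = 1100, end = 3090),
    models)
  expect_equal(both$annotation, "coding")
  # no models at all
  none <- classify_annotation(loci, NULL)
  expect_true(all(none$annotation == "intergenic"))
})

test_that("tier predicates select and exclude on the documented bounds", {
  cfg1 <- target_config(g5_quota = 1, g6_quota = 1)
  mk <- function(...) {
    d <- data.frame(id = "L", chrom = "c", start = 0, end = 400,
                    annotation = "intronic", serv = 0.9, gc = 0.5,
                    unit_len = 2, copies = 16, n_probes = 3,
                    stringsAsFactors = FALSE)
    mods <- list(...)
    d[names(mods)] <- mods
    d
  }
  sel <- function(...) select_targets(mk(...), config = cfg1)$group
  expect_equal(sel(), 5L)
  expect_true(is.na(sel(gc = 0.75)))
  expect_true(is.na(sel(n_probes = 2)))
  expect_true(is.na(sel(copies = 14)))
  # coding tier is bounded at 500 bp span
  expect_equal(sel(annotation = "coding", end = 500), 1L)
  expect_true(is.na(sel(annotation = "coding", end = 501)))
  # regulatory tiers by score
  expect_equal(sel(annotation = "regulatory", serv = 1.2), 2L)
  expect_equal(sel(annotation = "regulatory", serv = 0.7), 3L)
  # intergenic tier needs score > 1
  expect_equal(sel(annotation = "intergenic", serv = 1.1), 6L)
  expect_true(is.na(sel(annotation = "intergenic", serv = 0.95)))
})

test_that("tier-4 proximity and quota thinning behave deterministically", {
  set.seed(4)
  n <- 30
  cat_df <- data.frame(
    id = sprintf("L%02d", 1:n), chrom = "c",
    start = seq(0, by = 1000, length.out = n))
  cat_df$end <- cat_df$start + 100
  cat_df$annotation <- "intronic"
  cat_df$serv <- runif(n, 0.81, 2)
  cat_df$gc <- 0.5; cat_df$unit_len <- 2; cat_df$copies <- 20
  cat_df$n_probes <- 3
  sel <- select_targets(cat_df, config = target_config(g5_quota = 10),
                        chrom_len = 30000)
  expect_equal(sum(sel$group == 5, na.rm = TRUE), 10L)
  # shuffling the catalog does not change the selected set
  perm <- sample(n)
  sel2 <- select_targets(cat_df[perm, ], config = target_config(g5_quota = 10),
                         chrom_len = 30000)
  expect_setequal(sel$id[which(sel$group == 5)],
                  sel2$id[which(sel2$group == 5)])
  # a regulatory repeat near a listed gene joins tier 4
  cat_df$annotation[1] <- "regulatory"; cat_df$serv[1] <- 0.2
  genes <- data.frame(chrom = "c", start = 600, end = 900, name = "G")
  sel3 <- select_targets(cat_df, xlid_genes = genes,
                         config = target_config(g5_quota = 10),
                         chrom_len = 30000)
  expect_equal(sel3$group[1], 4L)
  # quota larger than the eligible pool warns and keeps all
  expect_warning(
    sel4 <- select_targets(cat_df[2:4, ],
                           config = target_config(g5_quota = 10),
                           chrom_len = 30000),
    "quota")
  expect_equal(sum(sel4$group == 5, na.rm = TRUE), 3L)
})

test_that("copies times unit length equals the span for pure loci", {
  set.seed(21)
  bg <- random_seq(3000)
  s <- paste0(substr(bg, 1, 1000), strrep("CAG", 12),
              substr(bg, 1001, 2000), strrep("AT", 20),
              substr(bg, 2001, 3000))
  r <- find_tandem_repeats(s, 1, 6, min_total_len = 24, min_copies = 5)
  pure <- r[r$purity == 100, ]
  expect_gte(nrow(pure), 2L)
  expect_equal(pure$copies * pure$unit_len, pure$end - pure$start)
})
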