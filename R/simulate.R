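# Synthetic data generation: a reference chromosome with planted tandem
# repeats, X-linked pedigree genotypes with a planted causal expansion,
# capture + circular-consensus-style reads with configurable error and
# stutter, and a patient-versus-controls expression matrix.  Every generator
# is a deterministic function of (config, seed).

#' Simulation configuration
#'
#' Defaults emulate the capture + long-read design the pipeline assumes:
#' 800-1000 bp captured fragments, >= 6 passes per consensus read, a
#' GC-dependent capture recovery curve flattening to ~30% above 70% GC, a
#' compound (CT)n-TTT-(GT)m causal repeat planted 65 bp downstream of a
#' microRNA-like gene, normal allele pools of 11-20 CT and 24-37 GT copies
#' with a proband expansion to 21 CT copies, three families of an X-linked
#' pedigree, and a 100-male control pool.
#'
#' @param seed Base seed; all generators derive their randomness from it.
#' @param ... Overrides for any configuration field.
#' @return A list of class "sim_config".
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chrom = "chrS",
    background_gc = 0.45,
    margin = 1500L, spacing = 2500L,
    # planted loci, in chromosome order; the compound locus is the causal one
    loci = list(
      list(id = "TRS01", type = "simple", unit = "GT", ref_copies = 20,
           gc_context = 0.45, pool = 16:24),
      list(id = "TRC02", type = "compound", sub_units = c("CT", "GT"),
           separator = "TTT", ref_sub = c(17, 26), gc_context = 0.45,
           pool1 = 11:20, pool2 = 24:37),
      list(id = "TRS03", type = "simple", unit = "AC", ref_copies = 18,
           gc_context = 0.45, pool = 14:22),
      list(id = "TRS04", type = "simple", unit = "TA", ref_copies = 16,
           gc_context = 0.40, pool = 12:20),
      list(id = "TRS05", type = "simple", unit = "GGC", ref_copies = 15,
           gc_context = 0.80, pool = 11:19)),
    causal_locus = "TRC02",
    proband_sub = c(21, 33),
    linkage_covers = 4L,      # loci 1..4 inside the linkage interval
    families = c("F1", "F2", "F3"),
    causal_family = "F1",
    n_affected = 3L, n_unaffected = 2L, n_carriers = 2L,
    n_controls = 100L,
    # read model
    coverage = 10L, frag_len = c(800L, 1000L),
    sub_rate = 0.01, stutter_prob = 0.05,
    min_passes = 6L, polymerase_meanlog = log(15000), polymerase_sdlog = 0.35,
    adaptor5 = "ATCTCTCTCAACAACAACAACGGAGGAGGAGG",
    adaptor3 = "CCTCCTCCTCCGTTGTTGTTGTTGAGAGAGAT",
    # capture model: logistic decline with GC, floor ~30%
    capture_mid = 0.70, capture_floor = 0.30, capture_steep = 25,
    # expression model
    n_genes = 60L, n_expr_controls = 3L, down_gene = "MIRX",
    down_fold = 6, n_up_targets = 21L, up_fold = c(2, 8),
    n_null_targets = 10L)
  mods <- list(...)
  bad <- setdiff(names(mods), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(mods)] <- mods
  class(cfg) <- "sim_config"
  cfg
}

# allele sequence from a locus spec and allele parameters
allele_sequence <- function(spec, copies = NULL, sub = NULL) {
  if (spec$type == "compound") {
    paste0(strrep(spec$sub_units[1], sub[1]), spec$separator,
           strrep(spec$sub_units[2], sub[2]))
  } else {
    strrep(spec$unit, copies)
  }
}

allele_bp <- function(spec, copies = NULL, sub = NULL) {
  nchar(allele_sequence(spec, copies, sub))
}

locus_unit_len <- function(spec) {
  if (spec$type == "compound") nchar(spec$sub_units[2]) else nchar(spec$unit)
}

#' Simulate a reference chromosome with planted repeats
#'
#' Plants each configured repeat (reference allele) in a random background
#' at evenly spaced offsets, each inside a 700 bp context block of the
#' configured GC content, and emits the truth catalog plus a small gene
#' model: a microRNA-like gene ending 65 bp upstream of the causal repeat
#' (making it a downstream regulatory repeat) and a gene/intron pair
#' enclosing the third locus.
#'
#' @param config A [sim_config()].
#' @return List: ref (named character vector of one chromosome), catalog
#'   (truth repeat catalog with sub-repeat columns for the compound locus),
#'   annotation (gene-model data.frame), config.
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  nl <- length(config$loci)
  chrom_len <- 2L * config$margin + max(nl, 1L) * config$spacing
  bg <- random_dna(chrom_len, config$background_gc)
  if (nl == 0L) {
    cat0 <- empty_catalog()
    cat0$compound <- logical(0)
    ann0 <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), feature = character(0),
                       strand = character(0), name = character(0),
                       stringsAsFactors = FALSE)
    return(list(ref = stats::setNames(bg, config$chrom), catalog = cat0,
                annotation = ann0, config = config))
  }

  pieces <- character(0)
  cursor <- 0L
  rows <- list()
  for (i in seq_len(nl)) {
    spec <- config$loci[[i]]
    pos <- config$margin + (i - 1L) * config$spacing   # locus start, 0-based
    aseq <- if (spec$type == "compound")
      allele_sequence(spec, sub = spec$ref_sub)
    else allele_sequence(spec, copies = spec$ref_copies)
    ctx_half <- 350L
    block_start <- pos - ctx_half
    block <- paste0(random_dna(ctx_half, spec$gc_context), aseq,
                    random_dna(ctx_half, spec$gc_context))
    # guard bases: several context positions on each side must break the
    # repeat tiling, so the planted tract is maximal and the truth
    # coordinates are exact
    bc <- strsplit(block, "", fixed = TRUE)[[1]]
    ul1 <- if (spec$type == "compound") nchar(spec$sub_units[1]) else
      nchar(spec$unit)
    ul2 <- locus_unit_len(spec)
    alen0 <- nchar(aseq)
    for (k in 0:2) {
      gl <- ctx_half - k * ul1
      if (bc[gl] == bc[gl + ul1])
        bc[gl] <- setdiff(c("A", "C", "G", "T"),
                          c(bc[gl + ul1], bc[gl - 1], bc[gl + 1]))[1]
      gr <- ctx_half + alen0 + 1L + k * ul2
      if (bc[gr] == bc[gr - ul2])
        bc[gr] <- setdiff(c("A", "C", "G", "T"),
                          c(bc[gr - ul2], bc[gr - 1], bc[gr + 1]))[1]
    }
    block <- paste(bc, collapse = "")
    if (block_start < cursor) stop("planted loci overlap; increase spacing")
    pieces <- c(pieces, substr(bg, cursor + 1L, block_start), block)
    cursor <- block_start + nchar(block)
    end0 <- pos + nchar(aseq)
    ulen <- locus_unit_len(spec)
    unit <- if (spec$type == "compound") spec$sub_units[2] else spec$unit
    rows[[i]] <- data.frame(
      id = spec$id, chrom = config$chrom, start = pos, end = end0,
      unit_seq = unit, unit_len = ulen,
      copies = (end0 - pos) / ulen, purity = NA_real_, gc = NA_real_,
      compound = spec$type == "compound",
      sub1_unit = if (spec$type == "compound") spec$sub_units[1] else NA,
      sub2_unit = if (spec$type == "compound") spec$sub_units[2] else NA,
      separator = if (spec$type == "compound") spec$separator else NA,
      ref_sub1 = if (spec$type == "compound") spec$ref_sub[1] else NA,
      ref_sub2 = if (spec$type == "compound") spec$ref_sub[2] else NA,
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, substr(bg, cursor + 1L, chrom_len))
  refseq <- paste(pieces, collapse = "")
  catalog <- do.call(rbind, rows)
  catalog$purity <- vapply(seq_len(nl), function(i)
    compute_purity(refseq, catalog$start[i], catalog$end[i],
                   catalog$unit_seq[i]), numeric(1))
  catalog$gc <- gc_fraction(vapply(seq_len(nl), function(i)
    subseq0(refseq, catalog$start[i], catalog$end[i]), character(1)))

  ci <- match(config$causal_locus, catalog$id)
  ann <- list()
  if (!is.na(ci)) {
    mirna_end <- catalog$start[ci] - 65L
    ann[[1]] <- data.frame(chrom = config$chrom, start = mirna_end - 85L,
                           end = mirna_end, feature = "mirna", strand = "+",
                           name = "MIRX", stringsAsFactors = FALSE)
  }
  if (nl >= 3L) {
    gene3_start <- catalog$start[3] - 400L
    ann[[length(ann) + 1L]] <- data.frame(
      chrom = config$chrom,
      start = c(gene3_start, catalog$start[3] - 100L),
      end = c(gene3_start + 1200L, catalog$end[3] + 100L),
      feature = c("gene", "intron"), strand = "+",
      name = c("GENE3", "GENE3_intron1"), stringsAsFactors = FALSE)
  }
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               feature = character(0), strand = character(0),
               name = character(0), stringsAsFactors = FALSE)

  ref <- stats::setNames(refseq, config$chrom)
  list(ref = ref, catalog = catalog, annotation = annotation, config = config)
}

draw_haplotype <- function(config) {
  lapply(config$loci, function(spec) {
    if (spec$type == "compound")
      list(sub = c(sample(spec$pool1, 1), sample(spec$pool2, 1)))
    else list(copies = sample(spec$pool, 1))
  })
}

hap_genotype_rows <- function(config, hap, hap2 = NULL, sample, family,
                              reference) {
  cat_df <- reference$catalog
  rows <- lapply(seq_along(config$loci), function(i) {
    spec <- config$loci[[i]]
    a1 <- hap[[i]]
    bp1 <- allele_bp(spec, copies = a1$copies, sub = a1$sub)
    bp2 <- NA_real_; s1 <- s2 <- s1b <- s2b <- NA_integer_
    if (spec$type == "compound") { s1 <- a1$sub[1]; s2 <- a1$sub[2] }
    if (!is.null(hap2)) {
      a2 <- hap2[[i]]
      bp2 <- allele_bp(spec, copies = a2$copies, sub = a2$sub)
      if (spec$type == "compound") { s1b <- a2$sub[1]; s2b <- a2$sub[2] }
    }
    data.frame(sample = sample, family = family,
               target_id = cat_df$id[i], chrom = cat_df$chrom[i],
               start = cat_df$start[i], end = cat_df$end[i],
               unit_len = cat_df$unit_len[i],
               allele1_bp = bp1, allele2_bp = bp2,
               copies = bp1 / cat_df$unit_len[i],
               sub1 = s1, sub2 = s2, sub1_2 = s1b, sub2_2 = s2b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate X-linked pedigree genotypes with a planted causal expansion
#'
#' Each family has a founder disease haplotype; in the causal family that
#' haplotype carries the expanded compound allele (proband CT copies above
#' the entire normal pool), elsewhere it is drawn from the normal pools.
#' Affected males carry the disease haplotype, unaffected males carry fresh
#' population haplotypes, carrier females are heterozygous (disease plus a
#' fresh haplotype).  Controls are hemizygous males drawn from the normal
#' pools.  Because linked loci ride along on the disease haplotype, neutral
#' repeats segregate perfectly too; only the control screen distinguishes
#' them, which is exactly the situation the filter cascade addresses.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return List: pedigree, genotypes (truth, fragment-analysis scale),
#'   controls (with target_id), linkage (interval data.frame).
#' @export
simulate_pedigree_genotypes <- function(config, reference) {
  set.seed(config$seed + 1L)
  cat_df <- reference$catalog
  ci <- match(config$causal_locus, cat_df$id)

  ped <- list(); gts <- list()
  for (fam in config$families) {
    disease <- draw_haplotype(config)
    if (fam == config$causal_family && !is.na(ci) && config$n_affected > 0L)
      disease[[ci]] <- list(sub = config$proband_sub)
    members <- c(
      stats::setNames(rep("affected", config$n_affected),
                      sprintf("%s_A%d", fam, seq_len(config$n_affected))),
      stats::setNames(rep("unaffected", config$n_unaffected),
                      sprintf("%s_U%d", fam, seq_len(config$n_unaffected))),
      stats::setNames(rep("carrier", config$n_carriers),
                      sprintf("%s_C%d", fam, seq_len(config$n_carriers))))
    for (s in names(members)) {
      phen <- members[[s]]
      sex <- if (phen == "carrier") "F" else "M"
      role <- if (s == paste0(fam, "_A1")) "proband"
              else if (s == paste0(fam, "_U1")) "sequenced_unaffected"
              else "relative"
      ped[[s]] <- data.frame(sample = s, family = fam, sex = sex,
                             phenotype = phen, role = role,
                             stringsAsFactors = FALSE)
      gts[[s]] <- switch(phen,
        affected = hap_genotype_rows(config, disease, NULL, s, fam, reference),
        unaffected = hap_genotype_rows(config, draw_haplotype(config), NULL,
                                       s, fam, reference),
        carrier = hap_genotype_rows(config, disease, draw_haplotype(config),
                                    s, fam, reference))
    }
  }
  controls <- lapply(seq_len(config$n_controls), function(k) {
    s <- sprintf("CTL%03d", k)
    hap_genotype_rows(config, draw_haplotype(config), NULL, s, "controls",
                      reference)
  })
  lk <- min(config$linkage_covers, nrow(cat_df))
  linkage <- data.frame(
    chrom = config$chrom,
    start = cat_df$start[1] - 500L,
    end = cat_df$end[lk] + 500L,
    stringsAsFactors = FALSE)
  list(pedigree = do.call(rbind, c(ped, make.row.names = FALSE)),
       genotypes = do.call(rbind, c(gts, make.row.names = FALSE)),
       controls = do.call(rbind, c(controls, make.row.names = FALSE)),
       linkage = linkage)
}

add_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
    ch[hit] <- vapply(ch[hit], function(b) sample(alt[[b]], 1), character(1))
  }
  paste(ch, collapse = "")
}

capture_prob <- function(gc, config) {
  config$capture_floor + (1 - config$capture_floor) /
    (1 + exp(config$capture_steep * (gc - config$capture_mid)))
}

#' Simulate captured consensus reads for one or more samples
#'
#' For each sample and locus, fragments of the configured length range are
#' drawn from the sample's haplotype sequence (reference context with the
#' sample's allele substituted for the reference repeat).  A captured
#' fragment contains the repeat with both flanks whenever the fragment is
#' long enough; alleles longer than the fragment yield partial coverage
#' only.  Fragments are retained with the GC-dependent capture probability,
#' dropped when the simulated polymerase read supports fewer than
#' `min_passes` passes, sequenced with the configured substitution rate and
#' per-read stutter (+/- one unit), read in a random orientation, and
#' flanked by the 32-base adaptors.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param truth Genotype truth table from [simulate_pedigree_genotypes()]
#'   (hemizygous samples only).
#' @param samples Character vector of sample ids to sequence.
#' @param seed Seed for this sequencing run (default derives from config).
#' @return Read data.frame: id, sample, seq, qual, passes.
#' @export
simulate_reads <- function(config, reference, truth, samples,
                           seed = config$seed + 2L) {
  set.seed(seed)
  refseq <- reference$ref[[1]]
  cat_df <- reference$catalog
  ids <- character(0); seqs <- character(0); quals <- character(0)
  samp <- character(0); passes_v <- integer(0)
  for (s in samples) {
    st <- truth[truth$sample == s, , drop = FALSE]
    if (!nrow(st)) stop("sample ", s, " not in truth table")
    for (i in seq_len(nrow(cat_df))) {
      spec <- config$loci[[match(cat_df$id[i], vapply(config$loci, `[[`,
                                                      character(1), "id"))]]
      row <- st[st$target_id == cat_df$id[i], , drop = FALSE]
      if (!nrow(row)) next
      base_sub <- c(row$sub1, row$sub2)
      base_copies <- if (spec$type == "compound") NULL else
        round(row$allele1_bp / cat_df$unit_len[i])
      lctx <- subseq0(refseq, max(0L, cat_df$start[i] - 600L), cat_df$start[i])
      rctx <- subseq0(refseq, cat_df$end[i],
                      min(nchar(refseq), cat_df$end[i] + 600L))
      p_cap <- capture_prob(cat_df$gc[i], config)
      for (k in seq_len(config$coverage)) {
        if (stats::runif(1) > p_cap) next
        # per-read stutter: whole-unit shift of one sub-run
        copies <- base_copies; sub <- base_sub
        if (stats::runif(1) < config$stutter_prob) {
          shift <- sample(c(-1L, 1L), 1)
          if (spec$type == "compound") {
            j <- sample(1:2, 1)
            sub[j] <- max(1L, sub[j] + shift)
          } else copies <- max(1L, copies + shift)
        }
        aseq <- allele_sequence(spec, copies = copies, sub = sub)
        win <- paste0(lctx, aseq, rctx)
        alen <- nchar(aseq); rep_s <- nchar(lctx); rep_e <- rep_s + alen
        L <- sample(seq.int(config$frag_len[1], config$frag_len[2]), 1)
        L <- min(L, nchar(win))
        if (L >= alen + 100L) {
          lo <- max(0L, rep_e + 50L - L); hi <- min(rep_s - 50L, nchar(win) - L)
          if (lo > hi) { lo <- max(0L, rep_s - 50L) ; hi <- lo }
        } else {
          lo <- max(0L, rep_s - L + 30L)
          hi <- max(lo, min(rep_e - 30L, nchar(win) - L))
        }
        fs <- if (hi > lo) sample(seq.int(lo, hi), 1) else lo
        frag <- subseq0(win, fs, fs + L)
        plen <- stats::rlnorm(1, config$polymerase_meanlog,
                              config$polymerase_sdlog)
        np <- as.integer(plen %/% (L + 2L * nchar(config$adaptor5)))
        if (np < config$min_passes) next
        frag <- add_substitutions(frag, config$sub_rate)
        if (stats::runif(1) < 0.5) frag <- revcomp(frag)
        read <- paste0(config$adaptor5, frag, config$adaptor3)
        ids <- c(ids, sprintf("%s_%s_r%03d", s, cat_df$id[i], k))
        seqs <- c(seqs, read)
        quals <- c(quals, strrep("I", nchar(read)))
        samp <- c(samp, s)
        passes_v <- c(passes_v, np)
      }
    }
  }
  data.frame(id = ids, sample = samp, seq = seqs, qual = quals,
             passes = passes_v, stringsAsFactors = FALSE)
}

#' Simulate a patient-versus-controls expression data set
#'
#' Control samples are drawn log-normally around per-gene means; the patient
#' value of the designated microRNA-like gene is decreased by the configured
#' fold, a set of its predicted targets is increased, and the remaining
#' genes are null.  Also emits a Ct table for the delta-delta-Ct utility
#' (patient target Ct shifted up by log2(down_fold)).
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to config seed).
#' @return List: matrix (gene x sample data.frame), truth (gene, effect
#'   fold), targets (predicted-target gene names), flags (gene, de_flag),
#'   ct (sample, gene, replicate, ct), calibrator.
#' @export
simulate_expression <- function(config, seed = config$seed + 3L) {
  set.seed(seed)
  ng <- config$n_genes; nc <- config$n_expr_controls
  genes <- c(config$down_gene, sprintf("G%03d", seq_len(ng - 1L)))
  up <- genes[1L + seq_len(config$n_up_targets)]
  null_genes <- setdiff(genes, c(config$down_gene, up))
  targets <- c(up, sample(null_genes, min(config$n_null_targets,
                                          length(null_genes))))
  mu <- stats::runif(ng, 3, 9)
  ctrl <- matrix(exp(stats::rnorm(ng * nc, rep(mu, nc), 0.08)), ng, nc,
                 dimnames = list(genes, paste0("C", seq_len(nc))))
  effect <- stats::setNames(rep(1, ng), genes)
  effect[config$down_gene] <- 1 / config$down_fold
  effect[up] <- stats::runif(length(up), config$up_fold[1], config$up_fold[2])
  pat <- exp(stats::rnorm(ng, mu, 0.08)) * effect
  mat <- data.frame(gene = genes, PAT = pat, ctrl,
                    stringsAsFactors = FALSE, check.names = FALSE)

  flags <- data.frame(gene = genes, de_flag = effect != 1,
                      stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, effect = unname(effect),
                      stringsAsFactors = FALSE)

  ct_samples <- c("PAT", paste0("C", seq_len(nc)))
  ct_rows <- list()
  for (s in ct_samples) {
    for (r in 1:3) {
      base <- stats::rnorm(1, 0, 0.03)
      tshift <- if (s == "PAT") log2(config$down_fold) else 0
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample = s, gene = c(config$down_gene, "REF1", "REF2"),
        replicate = r,
        ct = c(25 + tshift + stats::rnorm(1, 0, 0.03) + base,
               20 + stats::rnorm(1, 0, 0.03) + base,
               22 + stats::rnorm(1, 0, 0.03) + base),
        stringsAsFactors = FALSE)
    }
  }
  list(matrix = mat, truth = truth, targets = targets, flags = flags,
       ct = do.call(rbind, ct_rows), calibrator = "C1")
}
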