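# Tandem repeat discovery, purity, variability scoring, annotation and
# tiered target selection.
#
# A repeat catalog is a plain data.frame with one row per locus and columns
#   id, chrom, start, end   (0-based half-open),
#   unit_seq, unit_len, copies, purity, gc, score
# plus, once annotated/scored, annotation, subtype, serv, group.

# All maximal scoring subsequences (Ruzzo-Tompa) of a numeric score vector.
# Returns a matrix with columns start, end (1-based, inclusive) and score.
max_scoring_segments <- function(v) {
  n <- length(v)
  cap <- max(16L, sum(v > 0))
  st <- integer(cap); en <- integer(cap); Lv <- numeric(cap); Rv <- numeric(cap)
  m <- 0L
  cum <- 0
  for (k in seq_len(n)) {
    if (v[k] <= 0) { cum <- cum + v[k]; next }
    L <- cum; cum <- cum + v[k]; R <- cum
    s <- k
    repeat {
      j <- 0L
      if (m > 0L) {
        hit <- which(Lv[seq_len(m)] < L)
        if (length(hit)) j <- max(hit)
      }
      if (j == 0L || Rv[j] >= R) {
        m <- m + 1L
        st[m] <- s; en[m] <- k; Lv[m] <- L; Rv[m] <- R
        break
      }
      # merge: absorb I_j .. I_m into the current subsequence
      s <- st[j]; L <- Lv[j]
      m <- j - 1L
    }
  }
  if (m == 0L)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("start", "end", "score"))))
  cbind(start = st[seq_len(m)], end = en[seq_len(m)],
        score = Rv[seq_len(m)] - Lv[seq_len(m)])
}

# Per-phase consensus unit of a repeat tract (majority base per column,
# alphabetical tie-break).
consensus_unit <- function(chars, unit_len) {
  span <- length(chars)
  vapply(seq_len(unit_len), function(p) {
    col <- chars[seq(p, span, by = unit_len)]
    col <- col[col != "N"]
    if (!length(col)) return("N")
    tab <- table(col)
    names(tab)[which.max(tab)]  # ties resolved alphabetically by table order
  }, character(1))
}

purity_core <- function(chars, unit_chars) {
  span <- length(chars)
  u <- length(unit_chars)
  best <- 0L
  for (p in seq_len(u) - 1L) {
    tile <- unit_chars[((seq_len(span) - 1L + p) %% u) + 1L]
    best <- max(best, sum(chars == tile & chars != "N"))
  }
  100 * best / span
}

#' Detect tandem repeats in a nucleotide sequence
#'
#' Scans the sequence for tandem repeats with unit sizes between `min_unit`
#' and `max_unit`, in the spirit of the EMBOSS etandem scan: for each unit
#' size the sequence is compared against itself at lag `unit_len` (position i
#' versus i + u), each agreement scores +1 and each disagreement scores
#' `-mismatch_penalty`, and the maximal-scoring segments of that score vector
#' (all maximal scoring subsequences in the Ruzzo-Tompa sense) become
#' candidate repeat tracts.  Candidates below the length, copy-number or
#' purity floors are discarded; overlapping candidates from different unit
#' sizes are resolved deterministically by highest score, then smallest unit,
#' then leftmost start.
#'
#' The consensus unit of a tract is the per-phase majority base
#' (alphabetical tie-break); purity is computed against the best cyclic phase
#' of that unit.  N bases count as mismatches.
#'
#' @param seq A single nucleotide string (ACGTN).
#' @param min_unit,max_unit Unit-size range, within [1, 50].
#' @param min_total_len Minimum tract span in bases.
#' @param min_copies Minimum copy number (span / unit length).
#' @param min_purity Purity floor in percent.
#' @param mismatch_penalty Score penalty per mismatching position in the
#'   lag-u self comparison (default 3).
#' @param chrom Sequence name recorded in the catalog.
#' @return A repeat catalog data.frame (possibly with zero rows), sorted by
#'   start, with 0-based half-open coordinates.
#' @examples
#' find_tandem_repeats("ACACACAC", 1, 6, min_total_len = 8, min_copies = 2)
#' @export
find_tandem_repeats <- function(seq, min_unit = 1, max_unit = 6,
                                min_total_len = 22, min_copies = 2,
                                min_purity = 70, mismatch_penalty = 3,
                                chrom = "seq") {
  if (!(min_unit >= 1 && min_unit <= max_unit && max_unit <= 50))
    stop("require 1 <= min_unit <= max_unit <= 50")
  if (min_total_len < 2 || min_copies < 1 || mismatch_penalty <= 0)
    stop("invalid thresholds")
  seq <- check_dna(seq)
  ss <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ss)

  cand <- list()
  for (u in seq.int(min_unit, max_unit)) {
    if (n < 2L * u) break
    i <- seq_len(n - u)
    ok <- ss[i] == ss[i + u] & ss[i] != "N"
    v <- ifelse(ok, 1, -mismatch_penalty)
    segs <- max_scoring_segments(v)
    if (!nrow(segs)) next
    for (r in seq_len(nrow(segs))) {
      a <- segs[r, "start"]; b <- segs[r, "end"]
      start0 <- a - 1L          # 0-based start
      end0 <- b + u             # 0-based exclusive end
      span <- end0 - start0
      if (span < min_total_len || span / u < min_copies) next
      tract <- ss[a:(b + u)]
      unit <- consensus_unit(tract, u)
      pur <- purity_core(tract, unit)
      if (pur < min_purity) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = chrom, start = start0, end = end0,
        unit_seq = paste(unit, collapse = ""), unit_len = u,
        copies = span / u, purity = pur,
        gc = gc_fraction(paste(tract, collapse = "")),
        score = segs[r, "score"],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_catalog())

  cat_df <- do.call(rbind, cand)
  # overlap resolution: highest score, then smallest unit, then leftmost
  ord <- order(-cat_df$score, cat_df$unit_len, cat_df$start)
  cat_df <- cat_df[ord, , drop = FALSE]
  keep <- logical(nrow(cat_df))
  acc_s <- integer(0); acc_e <- integer(0)
  for (i in seq_len(nrow(cat_df))) {
    s <- cat_df$start[i]; e <- cat_df$end[i]
    if (!any(s < acc_e & e > acc_s)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
    }
  }
  cat_df <- cat_df[keep, , drop = FALSE]
  cat_df <- cat_df[order(cat_df$start), , drop = FALSE]
  cat_df <- cbind(id = sprintf("TR%04d", seq_len(nrow(cat_df))), cat_df,
                  stringsAsFactors = FALSE)
  rownames(cat_df) <- NULL
  cat_df
}

empty_catalog <- function() {
  data.frame(id = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             unit_seq = character(0), unit_len = integer(0),
             copies = numeric(0), purity = numeric(0), gc = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Purity of a repeat tract
#'
#' Purity is the percentage of tract positions that match a perfect tiling
#' of the unit sequence, maximised over the `unit_len` cyclic phases of the
#' tiling.  N bases never match.
#'
#' @param seq Reference (or any) nucleotide string containing the tract.
#' @param start,end Tract coordinates, 0-based half-open.
#' @param unit_seq Repeat unit.
#' @return Purity in percent, in [0, 100].
#' @examples
#' compute_purity(strrep("CA", 10), 0, 20, "CA")  # 100
#' @export
compute_purity <- function(seq, start, end, unit_seq) {
  seq <- check_dna(seq)
  unit_seq <- check_dna(unit_seq)
  span <- end - start
  if (start < 0 || end > nchar(seq) || span <= 0)
    stop("tract coordinates out of range")
  if (span < nchar(unit_seq)) stop("tract span shorter than the unit")
  chars <- strsplit(subseq0(seq, start, end), "", fixed = TRUE)[[1]]
  purity_core(chars, strsplit(unit_seq, "", fixed = TRUE)[[1]])
}

#' Default coefficients for the repeat variability score
#'
#' The variability score used for target selection is a linear form in unit
#' length, log2 copy number and purity.  The published thresholds this
#' package uses (0.4 / 0.8 / 1.0) refer to whatever score configuration is
#' plugged in; the shipped defaults place long pure dinucleotide arrays in
#' the 1-3 "highly variable" band and short or impure arrays below it.
#'
#' @param intercept,log2_copies,purity,unit_len Linear coefficients; `purity`
#'   multiplies purity/100 and must be non-negative (as must `log2_copies`)
#'   for the score to preserve the documented monotonicities.
#' @return A named list of coefficients.
#' @export
serv_coefficients <- function(intercept = -1.0, log2_copies = 0.4,
                              purity = 1.0, unit_len = -0.05) {
  if (log2_copies < 0 || purity < 0)
    stop("copy-number and purity coefficients must be non-negative")
  list(intercept = intercept, log2_copies = log2_copies,
       purity = purity, unit_len = unit_len)
}

#' Predicted variability score of tandem repeats
#'
#' @param catalog A repeat catalog data.frame with columns `unit_len`,
#'   `copies` and `purity`, or a single-locus list with those fields.
#' @param coefficients Score configuration from [serv_coefficients()].
#' @return Numeric vector of scores (monotone non-decreasing in copies and
#'   purity for valid coefficient sets).
#' @export
score_variability <- function(catalog, coefficients = serv_coefficients()) {
  need <- c("unit_len", "copies", "purity")
  if (!all(need %in% names(catalog)))
    stop("catalog must carry unit_len, copies and purity")
  if (any(is.na(catalog$unit_len)) || any(is.na(catalog$copies)) ||
      any(is.na(catalog$purity)))
    stop("unit_len, copies and purity must be populated")
  with(coefficients,
       intercept +
         log2_copies * log2(as.numeric(catalog$copies)) +
         purity * (as.numeric(catalog$purity) / 100) +
         unit_len * as.numeric(catalog$unit_len))
}

# Feature vocabularies for gene-model annotation.
.coding_features <- "coding"
.regulatory_features <- c("utr", "utr5", "utr3", "cpg", "tfbs")
.gene_features <- c("gene", "mirna")
.intronic_features <- c("intron", "gene", "mirna")

#' Annotate repeats against a gene model
#'
#' Assigns each locus one annotation class with the precedence
#' coding > regulatory > intronic > intergenic.  Regulatory hits are direct
#' overlaps with UTR/CpG-island/TFBS features, or proximity within `window`
#' bases upstream/downstream of a gene or microRNA feature (strand-aware).
#' Loci touching no feature are intergenic.
#'
#' @param catalog Repeat catalog.
#' @param models Gene-model data.frame with columns chrom, start, end
#'   (0-based half-open), feature (one of coding, utr, utr5, utr3, cpg,
#'   tfbs, gene, mirna, intron), strand ("+"/"-") and optionally name.
#' @param window Proximity window in bases for up/downstream classification.
#' @return The catalog with `annotation` and `subtype` columns added.
#' @export
classify_annotation <- function(catalog, models, window = 1000) {
  if (!nrow(catalog)) {
    catalog$annotation <- character(0); catalog$subtype <- character(0)
    return(catalog)
  }
  if (is.null(models) || !nrow(models)) {
    catalog$annotation <- "intergenic"
    catalog$subtype <- NA_character_
    return(catalog)
  }
  stopifnot(all(models$end > models$start))
  loci <- GenomicRanges::GRanges(catalog$chrom,
                                 IRanges::IRanges(catalog$start + 1, catalog$end))
  feat <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(models$start + 1, models$end))

  overlaps_class <- function(classes) {
    idx <- which(models$feature %in% classes)
    hit <- rep(NA_integer_, nrow(catalog))
    if (length(idx)) {
      ov <- GenomicRanges::findOverlaps(loci, feat[idx])
      hit[S4Vectors::queryHits(ov)] <- idx[S4Vectors::subjectHits(ov)]
    }
    hit
  }

  ann <- rep("intergenic", nrow(catalog))
  sub <- rep(NA_character_, nrow(catalog))

  # proximity to gene/miRNA features (strand-aware up/downstream)
  gidx <- which(models$feature %in% .gene_features)
  prox_sub <- rep(NA_character_, nrow(catalog))
  if (length(gidx)) {
    for (i in seq_len(nrow(catalog))) {
      best_d <- Inf; best_lab <- NA_character_
      for (j in gidx) {
        if (models$chrom[j] != catalog$chrom[i]) next
        strand <- if (!is.null(models$strand)) models$strand[j] else "+"
        gs <- models$start[j]; ge <- models$end[j]
        # downstream flank of the gene
        down <- if (strand == "+") c(ge, ge + window) else c(gs - window, gs)
        up <- if (strand == "+") c(gs - window, gs) else c(ge, ge + window)
        if (catalog$start[i] < down[2] && catalog$end[i] > down[1]) {
          d <- interval_distance(catalog$start[i], catalog$end[i], gs, ge)
          if (d < best_d) { best_d <- d; best_lab <- "downstream" }
        }
        if (catalog$start[i] < up[2] && catalog$end[i] > up[1]) {
          d <- interval_distance(catalog$start[i], catalog$end[i], gs, ge)
          if (d < best_d) { best_d <- d; best_lab <- "upstream" }
        }
      }
      prox_sub[i] <- best_lab
    }
  }

  hit_cod <- overlaps_class(.coding_features)
  hit_reg <- overlaps_class(.regulatory_features)
  hit_int <- overlaps_class(.intronic_features)

  reg <- !is.na(hit_reg) | !is.na(prox_sub)
  ann[!is.na(hit_int)] <- "intronic"
  ann[reg] <- "regulatory"
  sub[reg] <- ifelse(!is.na(hit_reg[reg]), models$feature[hit_reg[reg]],
                     prox_sub[reg])
  ann[!is.na(hit_cod)] <- "coding"
  sub[!is.na(hit_cod)] <- NA_character_

  catalog$annotation <- ann
  catalog$subtype <- sub
  catalog
}

#' Default configuration for tiered target selection
#'
#' Thresholds mirror the six selection tiers used for the capture design:
#' (1) coding repeats up to 500 bp; (2) regulatory repeats with variability
#' score >= 1 and span <= 500 bp; (3) regulatory repeats of any size with
#' score in (0.4, 1); (4) regulatory repeats within 1 kb of a disease gene
#' list and not yet selected; (5) intronic repeats with score > 0.8, >= 15
#' copies, unit >= 2 bp, span <= 500 bp, GC 30-70% and >= 3 probes, thinned
#' evenly along the chromosome to a quota; (6) intergenic repeats under the
#' same structural bounds with score > 1.
#'
#' @param ... Overrides for individual thresholds.
#' @return A named list of selection parameters.
#' @export
target_config <- function(...) {
  cfg <- list(max_span = 500,
              g2_serv = 1, g3_lo = 0.4, g3_hi = 1, g4_window = 1000,
              g5_serv = 0.8, g6_serv = 1,
              min_copies = 15, min_unit = 2,
              gc_range = c(0.30, 0.70), min_probes = 3,
              g5_quota = 1000, g6_quota = Inf)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

# Evenly thin candidate indices along [0, chrom_len): one bin per quota slot,
# best score per bin, then round-robin fill from remaining candidates.
even_thin <- function(idx, starts, serv, quota, chrom_len) {
  if (length(idx) <= quota) return(idx)
  breaks <- seq(0, chrom_len, length.out = quota + 1)
  bin <- pmin(findInterval(starts[idx], breaks, rightmost.closed = TRUE), quota)
  ord <- order(-serv[idx], starts[idx])
  idx <- idx[ord]; bin <- bin[ord]
  chosen <- idx[!duplicated(bin)]
  if (length(chosen) < quota) {
    rest <- idx[duplicated(bin)]
    chosen <- c(chosen, rest[seq_len(quota - length(chosen))])
  }
  sort(chosen)
}

#' Tiered selection of capture targets
#'
#' Applies the six selection-group predicates of [target_config()] in order;
#' each locus receives at most one group label (the first tier it matches).
#'
#' @param catalog Annotated, scored catalog (columns annotation, serv, gc,
#'   unit_len, copies, start, end; optionally n_probes).
#' @param xlid_genes Optional data.frame (chrom, start, end, name) of disease
#'   gene intervals for tier 4 proximity.
#' @param config Selection thresholds, see [target_config()].
#' @param chrom_len Chromosome length used for the tier-5/6 even thinning;
#'   defaults to the maximum locus end.
#' @return The catalog with an integer `group` column (NA = not selected).
#' @export
select_targets <- function(catalog, xlid_genes = NULL,
                           config = target_config(), chrom_len = NULL) {
  need <- c("annotation", "serv", "gc", "unit_len", "copies", "start", "end")
  if (!all(need %in% names(catalog)))
    stop("catalog must carry ", paste(need, collapse = ", "))
  n <- nrow(catalog)
  if (is.null(chrom_len)) chrom_len <- max(catalog$end, 0)
  probes <- if ("n_probes" %in% names(catalog)) catalog$n_probes else
    rep(Inf, n)
  span <- catalog$end - catalog$start
  grp <- rep(NA_integer_, n)
  free <- function() is.na(grp)

  grp[free() & catalog$annotation == "coding" & span <= config$max_span] <- 1L
  grp[free() & catalog$annotation == "regulatory" &
        catalog$serv >= config$g2_serv & span <= config$max_span] <- 2L
  grp[free() & catalog$annotation == "regulatory" &
        catalog$serv > config$g3_lo & catalog$serv < config$g3_hi] <- 3L

  if (!is.null(xlid_genes) && nrow(xlid_genes)) {
    near <- vapply(seq_len(n), function(i) {
      any(xlid_genes$chrom == catalog$chrom[i] &
            interval_distance(catalog$start[i], catalog$end[i],
                              xlid_genes$start, xlid_genes$end) <=
            config$g4_window)
    }, logical(1))
    grp[free() & catalog$annotation == "regulatory" & near] <- 4L
  }

  structural <- span <= config$max_span &
    catalog$copies >= config$min_copies &
    catalog$unit_len >= config$min_unit &
    catalog$gc >= config$gc_range[1] & catalog$gc <= config$gc_range[2] &
    probes >= config$min_probes

  for (tier in list(list(g = 5L, ann = "intronic", serv = config$g5_serv,
                         quota = config$g5_quota),
                    list(g = 6L, ann = "intergenic", serv = config$g6_serv,
                         quota = config$g6_quota))) {
    elig <- which(free() & catalog$annotation == tier$ann &
                    catalog$serv > tier$serv & structural)
    if (is.finite(tier$quota) && tier$quota > length(elig) && length(elig))
      warning(sprintf("tier %d quota (%d) exceeds eligible loci (%d)",
                      tier$g, tier$quota, length(elig)))
    if (is.finite(tier$quota) && length(elig) > tier$quota)
      elig <- even_thin(elig, catalog$start, catalog$serv, tier$quota,
                        chrom_len)
    grp[elig] <- tier$g
  }

  catalog$group <- grp
  catalog
}
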