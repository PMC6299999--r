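# Candidate-filtering cascade for an X-linked pedigree: linkage-interval
# restriction, affected/unaffected discordance, family segregation,
# cross-family uniqueness, and control-population screening.
#
# Genotype tables are data.frames with columns sample, family, target_id,
# chrom, start, end, unit_len, allele1_bp (and allele2_bp for females;
# NA for no-calls), optionally sub1/sub2 sub-repeat copy numbers.
# Pedigrees are data.frames with columns sample, family, sex ("M"/"F") and
# phenotype (affected / unaffected / carrier / unknown).

#' Restrict genotypes to linkage intervals
#'
#' @param genotypes Genotype table with locus coordinates.
#' @param intervals data.frame (chrom, start, end), 0-based half-open.
#' @return The rows whose locus overlaps at least one interval.
#' @export
interval_restrict <- function(genotypes, intervals) {
  if (!nrow(genotypes) || is.null(intervals) || !nrow(intervals))
    return(genotypes[0, , drop = FALSE])
  g <- GenomicRanges::GRanges(genotypes$chrom,
                              IRanges::IRanges(genotypes$start + 1,
                                               genotypes$end))
  iv <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1,
                                                intervals$end))
  keep <- GenomicRanges::countOverlaps(g, iv) > 0
  out <- genotypes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# allele equality within a bp tolerance (fragment-analysis rounding)
allele_eq <- function(x, ref_bp, tol_bp = 0) {
  !is.na(x) & abs(x - ref_bp) <= tol_bp
}

#' Loci discordant between an affected and an unaffected sample
#'
#' @param affected_gt,unaffected_gt Genotype tables for the two sequenced
#'   samples (hemizygous males; allele1_bp used).
#' @param min_diff_units Minimum copy-number difference in repeat units.
#' @return Merged table of loci genotyped in both samples, with
#'   `delta_units` and a logical `discordant` column; loci uncallable in
#'   either sample are excluded and their ids attached as attribute
#'   "excluded".
#' @export
discordant_loci <- function(affected_gt, unaffected_gt, min_diff_units = 1) {
  m <- merge(affected_gt, unaffected_gt, by = "target_id",
             suffixes = c(".aff", ".una"))
  callable <- !is.na(m$allele1_bp.aff) & !is.na(m$allele1_bp.una)
  excluded <- m$target_id[!callable]
  m <- m[callable, , drop = FALSE]
  m$delta_units <- abs(m$allele1_bp.aff - m$allele1_bp.una) / m$unit_len.aff
  # compound alleles with decompositions on both sides compare sub-repeat
  # copy numbers, resolving equal-length alleles of different composition
  if (all(c("sub1.aff", "sub1.una") %in% names(m))) {
    both <- !is.na(m$sub1.aff) & !is.na(m$sub2.aff) &
      !is.na(m$sub1.una) & !is.na(m$sub2.una)
    dsub <- pmax(abs(m$sub1.aff - m$sub1.una), abs(m$sub2.aff - m$sub2.una))
    m$delta_units[both] <- pmax(m$delta_units[both], dsub[both])
  }
  m$discordant <- m$delta_units >= min_diff_units - 1e-9
  attr(m, "excluded") <- excluded
  rownames(m) <- NULL
  m
}

#' Check X-linked segregation of a candidate allele in one family
#'
#' Under the X-linked recessive model the locus segregates with the
#' phenotype iff every affected male carries the proband allele, no
#' unaffected male carries it, and every carrier female is heterozygous for
#' it (carries it alongside a different allele).  Members with missing
#' genotypes make the locus unevaluable rather than failed.
#'
#' @param locus_gts Genotype rows for one locus across the family's members.
#' @param pedigree Pedigree table for the family.
#' @param proband Sample id whose allele defines the candidate; defaults to
#'   the first affected male with a genotype.
#' @param tol_bp Allele equality tolerance in bp.
#' @return "consistent", "inconsistent" or "unevaluable".
#' @export
segregation_check <- function(locus_gts, pedigree, proband = NULL,
                              tol_bp = 0) {
  ped <- pedigree[pedigree$phenotype %in%
                    c("affected", "unaffected", "carrier"), , drop = FALSE]
  gt_of <- function(s) locus_gts[match(s, locus_gts$sample), , drop = FALSE]
  if (is.null(proband)) {
    aff_m <- ped$sample[ped$phenotype == "affected" & ped$sex == "M"]
    ok <- aff_m[!is.na(gt_of(aff_m)$allele1_bp)]
    if (!length(ok)) return("unevaluable")
    proband <- ok[1]
  }
  prow <- gt_of(proband)
  if (nrow(prow) != 1L || is.na(prow$allele1_bp)) return("unevaluable")

  verdict <- "consistent"
  for (i in seq_len(nrow(ped))) {
    g <- gt_of(ped$sample[i])
    if (ped$phenotype[i] == "carrier") {
      if (nrow(g) == 0L || is.na(g$allele1_bp) || is.na(g$allele2_bp))
        return("unevaluable")
      m1 <- allele1_matches(prow, g, tol_bp)
      m2 <- allele2_matches(prow, g, tol_bp)
      if (!(m1 || m2) || (m1 && m2)) verdict <- "inconsistent"
    } else {
      if (nrow(g) == 0L || is.na(g$allele1_bp)) return("unevaluable")
      carries <- allele1_matches(prow, g, tol_bp)
      if (ped$phenotype[i] == "affected" && !carries) verdict <- "inconsistent"
      if (ped$phenotype[i] == "unaffected" && carries) verdict <- "inconsistent"
    }
  }
  verdict
}

# Allele comparisons at the finest resolution both sides share: sub-repeat
# copy numbers for compound alleles carrying a decomposition (columns
# sub1/sub2 for allele 1, sub1_2/sub2_2 for allele 2), length in bp
# otherwise.
has_sub <- function(row, cols = c("sub1", "sub2")) {
  all(cols %in% names(row)) && !is.na(row[[cols[1]]]) && !is.na(row[[cols[2]]])
}

# does allele 1 of `row` equal the proband's allele 1?
allele1_matches <- function(proband, row, tol_bp = 0) {
  if (has_sub(proband) && has_sub(row))
    return(row$sub1 == proband$sub1 && row$sub2 == proband$sub2)
  isTRUE(allele_eq(row$allele1_bp, proband$allele1_bp, tol_bp))
}

# does allele 2 of `row` (if any) equal the proband's allele 1?
allele2_matches <- function(proband, row, tol_bp = 0) {
  if (is.null(row$allele2_bp) || is.na(row$allele2_bp)) return(FALSE)
  if (has_sub(proband) && has_sub(row, c("sub1_2", "sub2_2")))
    return(row$sub1_2 == proband$sub1 && row$sub2_2 == proband$sub2)
  isTRUE(allele_eq(row$allele2_bp, proband$allele1_bp, tol_bp))
}

matches_proband_allele <- function(proband, row, tol_bp = 0) {
  allele1_matches(proband, row, tol_bp) || allele2_matches(proband, row, tol_bp)
}

#' Is the proband allele absent from all other families?
#'
#' Each other-family allele is compared at the finest resolution both sides
#' share: sub-repeat copy numbers for compound alleles with a decomposition,
#' total length in bp otherwise.
#'
#' @param proband One-row proband genotype (allele1_bp, optional sub1/sub2).
#' @param other_gts Genotype rows for the same locus in other families'
#'   samples.
#' @param tol_bp Allele length tolerance.
#' @return TRUE iff no sample of another family carries the allele.
#' @export
cross_family_unique <- function(proband, other_gts, tol_bp = 0) {
  if (is.null(other_gts) || !nrow(other_gts)) return(TRUE)
  if (is.numeric(proband)) proband <- data.frame(allele1_bp = proband)
  !any(vapply(seq_len(nrow(other_gts)), function(i)
    matches_proband_allele(proband, other_gts[i, , drop = FALSE], tol_bp),
    logical(1)))
}

#' Screen a proband allele against a control population
#'
#' `total_length` mode compares allele length in bp, emulating fragment
#' analysis (set `tol_bp = 1` for instrument rounding); `sub_repeat` mode
#' compares the (motif1, motif2) sub-repeat copy numbers and resolves
#' alleles that coincide in total length but differ in composition.
#'
#' @param proband One-row genotype (allele1_bp, and sub1/sub2 for
#'   sub_repeat mode).
#' @param controls Control genotype table for the same locus.
#' @param compare "total_length" or "sub_repeat".
#' @param tol_bp Length tolerance for total_length mode.
#' @return List: verdict ("unique" iff zero control matches, else "common"),
#'   n_matches, matches (the matching control rows).
#' @export
control_screen <- function(proband, controls,
                           compare = c("total_length", "sub_repeat"),
                           tol_bp = 0) {
  compare <- match.arg(compare)
  if (is.null(controls) || !nrow(controls))
    stop("control table is empty; screen undefined")
  if (compare == "total_length") {
    hit <- allele_eq(controls$allele1_bp, proband$allele1_bp, tol_bp)
    if ("allele2_bp" %in% names(controls))
      hit <- hit | allele_eq(controls$allele2_bp, proband$allele1_bp, tol_bp)
  } else {
    if (!all(c("sub1", "sub2") %in% names(controls)) ||
        !all(c("sub1", "sub2") %in% names(proband)))
      stop("sub_repeat mode requires sub1/sub2 on both proband and controls")
    if (is.na(proband$sub1) || is.na(proband$sub2))
      stop("proband sub-repeat decomposition missing")
    hit <- !is.na(controls$sub1) & !is.na(controls$sub2) &
      controls$sub1 == proband$sub1 & controls$sub2 == proband$sub2
  }
  list(verdict = if (any(hit)) "common" else "unique",
       n_matches = sum(hit),
       matches = controls[hit, , drop = FALSE])
}

candidate_stages <- c("outside_interval", "concordant", "non_segregating",
                      "shared_across_families", "found_in_controls",
                      "candidate")

#' Run the full candidate-filtering cascade
#'
#' For each locus genotyped in the sequenced affected male of the focal
#' family the cascade records the terminal stage reached: outside the
#' linkage interval; concordant with the sequenced unaffected male; not
#' segregating with the phenotype in the family; allele shared with another
#' family; allele found in the control population; or candidate (passed all
#' stages).  Loci whose segregation is unevaluable (missing member
#' genotypes) stop at `non_segregating` with the audit column noting
#' "unevaluable".
#'
#' @param genotypes Genotype table for all samples of all families
#'   (fragment-analysis-scale genotypes are fine for non-sequenced members).
#' @param pedigree Pedigree table (all families).
#' @param intervals Linkage intervals (chrom, start, end).
#' @param controls Control genotype table with a target_id column.
#' @param family Focal family id.
#' @param sequenced Character vector c(affected, unaffected) of the two
#'   sequenced sample ids.
#' @param mode Control comparison mode, see [control_screen()].
#' @param tol_bp Allele equality tolerance.
#' @param min_diff_units Discordance threshold in repeat units.
#' @return data.frame of class "candidate_report": one row per
#'   interval-restricted locus with stage and audit columns.
#' @export
candidate_report <- function(genotypes, pedigree, intervals, controls,
                             family, sequenced, mode = "sub_repeat",
                             tol_bp = 0, min_diff_units = 1) {
  stopifnot(length(sequenced) == 2L)
  fam_ped <- pedigree[pedigree$family == family, , drop = FALSE]
  aff_gt <- genotypes[genotypes$sample == sequenced[1], , drop = FALSE]
  una_gt <- genotypes[genotypes$sample == sequenced[2], , drop = FALSE]

  audit <- aff_gt[, c("target_id", "chrom", "start", "end", "unit_len"),
                  drop = FALSE]
  audit$allele_bp <- aff_gt$allele1_bp
  audit$stage <- NA_character_
  audit$delta_units <- NA_real_
  audit$segregation <- NA_character_
  audit$other_family_matches <- NA_integer_
  audit$control_matches <- NA_integer_

  inside <- interval_restrict(aff_gt, intervals)$target_id
  disc <- discordant_loci(aff_gt, una_gt, min_diff_units)

  for (i in seq_len(nrow(audit))) {
    tid <- audit$target_id[i]
    if (!tid %in% inside) { audit$stage[i] <- "outside_interval"; next }
    d <- disc[disc$target_id == tid, , drop = FALSE]
    audit$delta_units[i] <- if (nrow(d)) d$delta_units else NA_real_
    if (!nrow(d) || !d$discordant) { audit$stage[i] <- "concordant"; next }

    fam_gts <- genotypes[genotypes$family == family &
                           genotypes$target_id == tid, , drop = FALSE]
    seg <- segregation_check(fam_gts, fam_ped, proband = sequenced[1],
                             tol_bp = tol_bp)
    audit$segregation[i] <- seg
    if (seg != "consistent") { audit$stage[i] <- "non_segregating"; next }

    other <- genotypes[genotypes$family != family &
                         genotypes$target_id == tid, , drop = FALSE]
    prow_x <- aff_gt[aff_gt$target_id == tid, , drop = FALSE]
    n_match <- if (nrow(other))
      sum(vapply(seq_len(nrow(other)), function(j)
        matches_proband_allele(prow_x, other[j, , drop = FALSE], tol_bp),
        logical(1))) else 0L
    audit$other_family_matches[i] <- n_match
    if (n_match > 0L) { audit$stage[i] <- "shared_across_families"; next }

    ctl <- controls[controls$target_id == tid, , drop = FALSE]
    if (!nrow(ctl)) { audit$stage[i] <- "candidate"; audit$control_matches[i] <- 0L; next }
    prow <- aff_gt[aff_gt$target_id == tid, , drop = FALSE]
    # sub-repeat resolution only applies where a decomposition exists
    locus_mode <- mode
    if (mode == "sub_repeat" &&
        (!all(c("sub1", "sub2") %in% names(prow)) || is.na(prow$sub1) ||
         is.na(prow$sub2) || !all(c("sub1", "sub2") %in% names(ctl)) ||
         all(is.na(ctl$sub1))))
      locus_mode <- "total_length"
    scr <- control_screen(prow, ctl, compare = locus_mode, tol_bp = tol_bp)
    audit$control_matches[i] <- scr$n_matches
    audit$stage[i] <- if (scr$verdict == "unique") "candidate"
                      else "found_in_controls"
  }
  class(audit) <- c("candidate_report", "data.frame")
  audit
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate filtering cascade:", nrow(x), "loci\n")
  tab <- table(factor(x$stage, levels = candidate_stages))
  for (s in names(tab)) cat(sprintf("  %-24s %d\n", s, tab[[s]]))
  cand <- x$target_id[x$stage == "candidate"]
  if (length(cand)) cat("Candidates:", paste(cand, collapse = ", "), "\n")
  invisible(x)
}
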