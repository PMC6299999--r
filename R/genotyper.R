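# Flank-anchored genotyping: per-locus libraries of flanking sequences,
# per-read allele calls (spanning or partial), locus genotypes with stutter
# pooling, expansion flagging from partial-read lower bounds, and compound
# sub-repeat decomposition.

#' Build a flank library for one locus
#'
#' The library holds the `flank_len` reference bases immediately 5' and 3'
#' of the repeat tract, the repeat unit, and the reference copy number (used
#' as both the low and high end of the expected range).  Allele length is
#' later measured as the distance between matches to these two flanks within
#' a single read.
#'
#' @param locus One catalog row (id, chrom, start, end, unit_seq, unit_len).
#' @param ref Named character vector of chromosome sequences.
#' @param flank_len Flank length in bases (default 20); at a contig edge a
#'   truncated flank of at least 12 bases is used with a warning.
#' @return A list of class "locus_library".
#' @export
build_locus_library <- function(locus, ref, flank_len = 20) {
  if (flank_len <= 0) stop("flank_len must be positive")
  ref <- as_ref_list(ref)
  chrom <- as.character(locus$chrom)
  seqlen <- nchar(ref[[chrom]])
  s <- as.integer(locus$start); e <- as.integer(locus$end)
  ls <- max(0L, s - flank_len); re <- min(seqlen, e + flank_len)
  if (s - ls < flank_len || re - e < flank_len) {
    if (s - ls < 12L || re - e < 12L)
      stop("flank shorter than 12 bases at contig edge for ", locus$id)
    warning("truncated flank at contig edge for ", locus$id, call. = FALSE)
  }
  ref_copies <- (e - s) / locus$unit_len
  structure(list(
    target_id = as.character(locus$id), chrom = chrom, start = s, end = e,
    left = subseq0(ref[[chrom]], ls, s),
    right = subseq0(ref[[chrom]], e, re),
    unit_seq = as.character(locus$unit_seq),
    unit_len = as.integer(locus$unit_len),
    ref_copies = ref_copies, lo = ref_copies, hi = ref_copies),
    class = "locus_library")
}

#' Reads mapped near a target
#'
#' @param alignments Alignment data.frame.
#' @param target One catalog row (chrom, start, end).
#' @param distance Maximum gap in bases between the alignment interval and
#'   the target interval (default 300); overlapping reads have distance 0.
#' @return Character vector of read ids.
#' @export
filter_reads_near_target <- function(alignments, target, distance = 300) {
  if (!nrow(alignments)) return(character(0))
  d <- interval_distance(alignments$start, alignments$end,
                         target$start, target$end)
  ok <- alignments$chrom == as.character(target$chrom) & d <= distance
  unique(alignments$read_id[ok])
}

# Mismatch-tolerant occurrence starts of a flank in each of a set of reads
# (list of 1-based start vectors, possibly empty).
flank_occurrences_set <- function(flank, reads_dna, max_mm) {
  m <- Biostrings::vmatchPattern(flank, reads_dna, max.mismatch = max_mm,
                                 with.indels = FALSE)
  Biostrings::startIndex(m)
}

#' Call an allele from a single read
#'
#' Locates the locus' left and right flanking sequences in the read
#' (substitution-tolerant; both orientations are tried and the call is
#' reported in reference orientation).  If both flanks are found the read
#' spans the repeat and the allele length is the distance between the flank
#' inner edges; if only one flank is found the read runs off the end of the
#' repeat and the distance from that flank's inner edge to the read end is a
#' lower bound on the allele length.  With multiple flank placements the
#' outermost pair (maximising the inter-flank distance) is used and the call
#' is flagged.
#'
#' @param read_seq A single read sequence (adaptor-trimmed).
#' @param lib Locus library from [build_locus_library()].
#' @param max_mismatch_frac Tolerated substitution fraction per flank
#'   (ceiling of `frac * flank_len` mismatches; no indels).
#' @return One-row data.frame: target_id, status (spanning / partial_left /
#'   partial_right / absent), length_bp, copies, is_lower_bound, multimatch,
#'   orientation, allele_seq (spanning calls only).
#' @export
call_allele_per_read <- function(read_seq, lib, max_mismatch_frac = 0.1) {
  out <- call_alleles(data.frame(id = "read", seq = read_seq,
                                 stringsAsFactors = FALSE),
                      lib, max_mismatch_frac = max_mismatch_frac)
  out$read_id <- NULL
  out
}

#' Allele calls for a set of reads at one locus
#'
#' Vectorised flank search over all reads (the per-read contract is
#' documented at [call_allele_per_read()]).
#'
#' @param reads Read data.frame (id, seq).
#' @param lib Locus library.
#' @param max_mismatch_frac Tolerated substitution fraction per flank.
#' @return data.frame of per-read calls with a read_id column.
#' @export
call_alleles <- function(reads, lib, max_mismatch_frac = 0.1) {
  empty <- data.frame(read_id = character(0), target_id = character(0),
                      status = character(0), length_bp = numeric(0),
                      copies = numeric(0), is_lower_bound = logical(0),
                      multimatch = logical(0), orientation = character(0),
                      allele_seq = character(0), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  seqs <- toupper(reads$seq)
  max_mm_l <- ceiling(max_mismatch_frac * nchar(lib$left))
  max_mm_r <- ceiling(max_mismatch_frac * nchar(lib$right))
  lw <- nchar(lib$left); rw <- nchar(lib$right)

  scan_set <- function(x) {
    dna <- Biostrings::DNAStringSet(x)
    list(left = flank_occurrences_set(lib$left, dna, max_mm_l),
         right = flank_occurrences_set(lib$right, dna, max_mm_r))
  }
  fwd <- scan_set(seqs)
  nf <- function(sc, i) (length(sc$left[[i]]) > 0) + (length(sc$right[[i]]) > 0)
  found_f <- vapply(seq_along(seqs), function(i) nf(fwd, i), numeric(1))
  need_rc <- which(found_f < 2)
  orient <- rep("+", length(seqs))
  seq_or <- seqs
  left_hits <- fwd$left; right_hits <- fwd$right
  if (length(need_rc)) {
    rcs <- revcomp(seqs[need_rc])
    rev <- scan_set(rcs)
    for (k in seq_along(need_rc)) {
      i <- need_rc[k]
      if (nf(rev, k) > found_f[i]) {
        orient[i] <- "-"
        seq_or[i] <- rcs[k]
        left_hits[i] <- list(rev$left[[k]])
        right_hits[i] <- list(rev$right[[k]])
      }
    }
  }

  rows <- lapply(seq_along(seqs), function(i) {
    ls <- left_hits[[i]]; rs <- right_hits[[i]]
    has_l <- length(ls) > 0; has_r <- length(rs) > 0
    multi <- length(ls) > 1 || length(rs) > 1
    res <- function(status, length_bp = NA_real_, lower = NA,
                    allele = NA_character_) {
      data.frame(read_id = reads$id[i], target_id = lib$target_id,
                 status = status, length_bp = length_bp,
                 copies = if (is.na(length_bp)) NA_real_ else
                   length_bp / lib$unit_len,
                 is_lower_bound = lower, multimatch = multi,
                 orientation = orient[i], allele_seq = allele,
                 stringsAsFactors = FALSE)
    }
    if (!has_l && !has_r) return(res("absent"))
    if (has_l && has_r) {
      le <- min(ls) + lw - 1L          # leftmost left flank, inner edge
      rstart <- max(rs)                # rightmost right flank, inner edge
      len <- rstart - le - 1L
      if (len < 0L) return(res("absent"))
      return(res("spanning", len, lower = FALSE,
                 allele = if (len > 0L) substr(seq_or[i], le + 1L, rstart - 1L)
                          else ""))
    }
    if (has_l) {
      le <- min(ls) + lw - 1L
      return(res("partial_left", nchar(seq_or[i]) - le, lower = TRUE))
    }
    res("partial_right", max(rs) - 1L, lower = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Majority-vote consensus of equal-length strings.
consensus_seq <- function(seqs) {
  seqs <- seqs[!is.na(seqs)]
  if (!length(seqs)) return(NA_character_)
  if (length(seqs) == 1L || nchar(seqs[1]) == 0L) return(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(mat, 2, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]
  }), collapse = "")
}

#' Genotype one locus from per-read allele calls
#'
#' Under the hemizygous (single X) model the modal spanning allele length
#' wins; ties are broken toward the longer allele and flagged.  Calls within
#' one repeat unit of the mode are pooled as stutter and counted as support.
#' A genotype is emitted only when pooled support reaches `min_support`.
#' Under the diploid model up to two modes are called, the second requiring
#' both the support floor and a minor-allele fraction of the informative
#' reads.  The allele sequence reported for sequenced alleles is the
#' column-majority consensus of the spanning reads at the modal length.
#'
#' @param calls Per-read calls from [call_alleles()] for one locus/sample.
#' @param unit_len Repeat unit length in bases.
#' @param min_support Minimum pooled read support per allele (default 5).
#' @param sex_model "hemizygous" or "diploid".
#' @param minor_frac Minimum minor-allele fraction (diploid only).
#' @return One-row data.frame: called, allele1_bp, allele1_copies,
#'   allele1_support, allele2_* (diploid), informative, tie, allele_seq.
#' @export
genotype_locus <- function(calls, unit_len, min_support = 5,
                           sex_model = c("hemizygous", "diploid"),
                           minor_frac = 0.2) {
  sex_model <- match.arg(sex_model)
  informative <- sum(calls$status != "absent")
  span <- calls[calls$status == "spanning", , drop = FALSE]
  no_call <- data.frame(called = FALSE, allele1_bp = NA_real_,
                        allele1_copies = NA_real_, allele1_support = NA_integer_,
                        allele2_bp = NA_real_, allele2_copies = NA_real_,
                        allele2_support = NA_integer_,
                        informative = informative, tie = FALSE,
                        allele_seq = NA_character_, stringsAsFactors = FALSE)
  if (!nrow(span)) return(no_call)

  pick_mode <- function(lens) {
    tab <- table(lens)
    vals <- as.numeric(names(tab))
    top <- vals[tab == max(tab)]
    list(mode = max(top), tie = length(top) > 1L)
  }
  lens <- span$length_bp
  m1 <- pick_mode(lens)
  pooled1 <- abs(lens - m1$mode) <= unit_len
  sup1 <- sum(pooled1)
  if (sup1 < min_support) return(no_call)
  cons <- consensus_seq(span$allele_seq[lens == m1$mode])

  out <- data.frame(called = TRUE, allele1_bp = m1$mode,
                    allele1_copies = round(m1$mode / unit_len, 2),
                    allele1_support = sup1,
                    allele2_bp = NA_real_, allele2_copies = NA_real_,
                    allele2_support = NA_integer_,
                    informative = informative, tie = m1$tie,
                    allele_seq = cons, stringsAsFactors = FALSE)
  if (sex_model == "diploid") {
    rest <- lens[!pooled1]
    if (length(rest)) {
      m2 <- pick_mode(rest)
      pooled2 <- abs(rest - m2$mode) <= unit_len
      sup2 <- sum(pooled2)
      if (sup2 >= min_support && sup2 >= minor_frac * informative) {
        out$allele2_bp <- m2$mode
        out$allele2_copies <- round(m2$mode / unit_len, 2)
        out$allele2_support <- sup2
        out$tie <- out$tie || m2$tie
      }
    }
  }
  out
}

#' Convert a per-sample genotype table to the pedigree-analysis schema
#'
#' Reshapes the output of [genotype_sample()] into the genotype-table layout
#' consumed by the segregation filter (sample, family, target_id,
#' coordinates, allele1_bp/allele2_bp, copies, sub1/sub2); no-calls become
#' NA alleles.
#'
#' @param gt Output of [genotype_sample()].
#' @param family Family id to record.
#' @return Genotype table data.frame.
#' @export
as_genotype_table <- function(gt, family) {
  data.frame(sample = gt$sample, family = family, target_id = gt$target_id,
             chrom = gt$chrom, start = gt$start, end = gt$end,
             unit_len = gt$unit_len,
             allele1_bp = ifelse(gt$called, gt$allele1_bp, NA_real_),
             allele2_bp = ifelse(gt$called, gt$allele2_bp, NA_real_),
             copies = ifelse(gt$called, gt$allele1_copies, NA_real_),
             sub1 = gt$sub1, sub2 = gt$sub2,
             sub1_2 = NA_integer_, sub2_2 = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Flag a repeat expansion from partial reads
#'
#' A locus is flagged as expanded when no read spans the full repeat and at
#' least one partial read implies more copies than the reference: the allele
#' then exceeds the captured fragment length and only a lower bound on its
#' size is measurable.
#'
#' @param calls Per-read calls for one locus/sample.
#' @param lib Locus library (for the reference copy number and unit length).
#' @return List: expanded (logical), bound_copies and bound_bp (the largest
#'   partial-read lower bound; NA when not expanded), n_partial.
#' @export
detect_expansion <- function(calls, lib) {
  span_n <- sum(calls$status == "spanning")
  part <- calls[calls$status %in% c("partial_left", "partial_right"), ,
                drop = FALSE]
  expanded <- span_n == 0L && nrow(part) > 0L &&
    any(part$copies > lib$ref_copies)
  list(expanded = expanded,
       bound_copies = if (expanded) max(part$copies) else NA_real_,
       bound_bp = if (expanded) max(part$copies) * lib$unit_len else NA_real_,
       n_partial = nrow(part))
}

#' Decompose a compound repeat allele into sub-repeat copy numbers
#'
#' Greedy left-to-right parse of an allele sequence laid out as
#' (motif1)^a separator (motif2)^b: the maximal run of the first motif, then
#' the separator, then the maximal run of the second motif.  A mismatching
#' residue ends a run.  If the separator is not found where expected the
#' function falls back to the single-motif count with a warning.
#'
#' @param allele_seq Allele sequence between the flanks.
#' @param sub_units Character vector of the two ordered motifs.
#' @param separator Spacer sequence between the sub-repeats (may be "").
#' @return Named integer vector of the two copy numbers (second is NA on
#'   separator fallback).
#' @examples
#' decompose_compound(paste0(strrep("CT", 21), "TTT", strrep("GT", 33)))
#' @export
decompose_compound <- function(allele_seq, sub_units = c("CT", "GT"),
                               separator = "TTT") {
  stopifnot(length(sub_units) == 2L, all(nchar(sub_units) >= 1))
  allele_seq <- toupper(allele_seq)
  run_len <- function(seq, pos, motif) {
    l <- nchar(motif); k <- 0L
    while (substr(seq, pos + k * l, pos + (k + 1L) * l - 1L) == motif)
      k <- k + 1L
    k
  }
  a <- run_len(allele_seq, 1L, sub_units[1])
  pos <- 1L + a * nchar(sub_units[1])
  ls <- nchar(separator)
  if (ls > 0L && substr(allele_seq, pos, pos + ls - 1L) != separator) {
    warning("separator not found after first sub-repeat; ",
            "single-motif decomposition", call. = FALSE)
    out <- c(a, NA_integer_)
    names(out) <- sub_units
    return(out)
  }
  pos <- pos + ls
  b <- run_len(allele_seq, pos, sub_units[2])
  out <- c(a, b)
  names(out) <- sub_units
  out
}

#' Genotype one sample across a set of loci
#'
#' Convenience wrapper running [call_alleles()], [genotype_locus()] and
#' [detect_expansion()] per locus, with compound decomposition of the
#' consensus allele sequence where the library declares sub-units.
#'
#' @param reads Trimmed read data.frame for one sample.
#' @param libs List of locus libraries; elements may carry `sub_units` and
#'   `separator` fields for compound loci.
#' @param sample Sample id recorded in the output.
#' @param min_support,sex_model,... Passed to the stage functions.
#' @return Genotype table: one row per locus with sample, target coordinates,
#'   allele fields, support, expanded flag and bounds, sub-repeat copies.
#' @export
genotype_sample <- function(reads, libs, sample = "S1", min_support = 5,
                            sex_model = "hemizygous", ...) {
  rows <- lapply(libs, function(lib) {
    calls <- call_alleles(reads, lib, ...)
    gt <- genotype_locus(calls, lib$unit_len, min_support = min_support,
                         sex_model = sex_model)
    ex <- detect_expansion(calls, lib)
    sub1 <- sub2 <- NA_integer_
    if (!is.null(lib$sub_units) && gt$called && !is.na(gt$allele_seq)) {
      dec <- suppressWarnings(
        decompose_compound(gt$allele_seq, lib$sub_units,
                           if (is.null(lib$separator)) "" else lib$separator))
      sub1 <- dec[[1]]; sub2 <- dec[[2]]
    }
    cbind(data.frame(sample = sample, target_id = lib$target_id,
                     chrom = lib$chrom, start = lib$start, end = lib$end,
                     unit_len = lib$unit_len, stringsAsFactors = FALSE),
          gt,
          data.frame(expanded = ex$expanded, bound_copies = ex$bound_copies,
                     bound_bp = ex$bound_bp, sub1 = sub1, sub2 = sub2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
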