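# Read preparation: adaptor trimming, local alignment to target windows,
# duplicate removal, and the yield accounting used to judge a capture run
# (including soft-clip rescue of reads whose clipped tails re-match the
# opposite repeat flank).
#
# Reads are a data.frame with columns id, seq and optionally qual; alignments
# are a data.frame with columns read_id, chrom, start, end (0-based
# half-open), strand, clip_left, clip_right (soft-clip lengths in reference
# orientation) and score.

#' Trim fixed-length adaptors from both read ends
#'
#' Removes `n` bases from each end of every read; reads of length <= 2n are
#' dropped and counted.
#'
#' @param reads Read data.frame (id, seq, optional qual).
#' @param n Bases to trim from each side (default 32, the adaptor length of
#'   the capture libraries emulated here).
#' @return Trimmed read data.frame; the number of dropped reads is attached
#'   as attribute "n_dropped".
#' @export
trim_adaptors <- function(reads, n = 32) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)),
            n >= 1)
  len <- nchar(reads$seq)
  keep <- len > 2L * n
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " read(s) shorter than ", 2 * n + 1, " bases dropped")
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, n + 1L, len[keep] - n)
  if ("qual" %in% names(out))
    out$qual <- substr(out$qual, n + 1L, len[keep] - n)
  attr(out, "n_dropped") <- dropped
  rownames(out) <- NULL
  out
}

# 5x5 nucleotide scoring matrix; N is mildly penalised against everything.
nucleotide_matrix <- function(match = 1, mismatch = -3) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- -1; m[, "N"] <- -1
  m
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Align reads to target windows by local alignment
#'
#' Each target defines a window of the target interval plus `flank` bases on
#' both sides.  Candidate read/window pairs are found by a shared k-mer
#' prefilter (both orientations), then scored by affine-gap local
#' (Smith-Waterman) alignment; every read is assigned its best-scoring window
#' placement, and reads whose best score falls below `min_score` are left
#' unmapped.
#'
#' @param reads Read data.frame (trimmed).
#' @param ref Named character vector of chromosome sequences.
#' @param targets Catalog/data.frame with chrom, start, end (and id).
#' @param flank Window extension in bases (default 1000).
#' @param k Prefilter k-mer size.
#' @param match,mismatch,gap_open,gap_ext Alignment scores (gap penalties are
#'   positive costs).
#' @param min_score Minimum accepted local alignment score.
#' @return Alignment data.frame of mapped reads; unmapped read ids are
#'   attached as attribute "unmapped".
#' @export
align_to_windows <- function(reads, ref, targets, flank = 1000, k = 13,
                             match = 1, mismatch = -3, gap_open = 5,
                             gap_ext = 2, min_score = 30) {
  ref <- as_ref_list(ref)
  wins <- lapply(seq_len(nrow(targets)), function(i) {
    chrom <- as.character(targets$chrom[i])
    ws <- max(0L, targets$start[i] - flank)
    we <- min(nchar(ref[[chrom]]), targets$end[i] + flank)
    list(chrom = chrom, start = ws, end = we,
         seq = subseq0(ref[[chrom]], ws, we))
  })
  # merge overlapping windows so a read is not aligned twice to one region
  if (length(wins) > 1) {
    ord <- order(vapply(wins, `[[`, character(1), "chrom"),
                 vapply(wins, function(w) as.numeric(w$start), numeric(1)))
    merged <- list(wins[[ord[1]]])
    for (i in ord[-1]) {
      w <- wins[[i]]; last <- merged[[length(merged)]]
      if (w$chrom == last$chrom && w$start <= last$end) {
        last$end <- max(last$end, w$end)
        last$seq <- subseq0(ref[[last$chrom]], last$start, last$end)
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- w
    }
    wins <- merged
  }
  wkmers <- lapply(wins, function(w) kmer_set(w$seq, k))
  submat <- nucleotide_matrix(match, mismatch)

  rows <- vector("list", nrow(reads))
  unmapped <- character(0)
  for (i in seq_len(nrow(reads))) {
    rseq <- toupper(reads$seq[i])
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") rseq else revcomp(rseq)
      qk <- kmer_set(q, k)
      for (w in seq_along(wins)) {
        if (!any(qk %in% wkmers[[w]])) next
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(wins[[w]]$seq),
          type = "local", substitutionMatrix = submat,
          gapOpening = gap_open, gapExtension = gap_ext)
        sc <- Biostrings::score(al)
        if (is.null(best) || sc > best$score) {
          pr <- Biostrings::pattern(al); su <- Biostrings::subject(al)
          best <- list(score = sc, strand = strand, win = w,
                       qstart = BiocGenerics::start(pr),
                       qend = BiocGenerics::end(pr),
                       sstart = BiocGenerics::start(su),
                       send = BiocGenerics::end(su),
                       qlen = nchar(q))
        }
      }
    }
    if (is.null(best) || best$score < min_score) {
      unmapped <- c(unmapped, reads$id[i])
      next
    }
    w <- wins[[best$win]]
    rows[[i]] <- data.frame(
      read_id = reads$id[i], chrom = w$chrom,
      start = w$start + best$sstart - 1L, end = w$start + best$send,
      strand = best$strand,
      clip_left = best$qstart - 1L, clip_right = best$qlen - best$qend,
      score = best$score, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), clip_left = integer(0),
                      clip_right = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  attr(out, "unmapped") <- unmapped
  rownames(out) <- NULL
  out
}

#' Remove duplicate read placements
#'
#' Among alignments sharing (chrom, start, end, strand) one record survives:
#' the highest-scoring, then the lexicographically smallest read id.
#' The operation is idempotent.
#'
#' @param alignments Alignment data.frame.
#' @return Deduplicated alignments, sorted by position.
#' @export
remove_duplicates <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  key <- paste(alignments$chrom, alignments$start, alignments$end,
               alignments$strand, sep = "\r")
  ord <- order(key, -alignments$score, alignments$read_id)
  alignments <- alignments[ord, , drop = FALSE]
  alignments <- alignments[!duplicated(key[ord]), , drop = FALSE]
  alignments <- alignments[order(alignments$chrom, alignments$start,
                                 alignments$end), , drop = FALSE]
  rownames(alignments) <- NULL
  alignments
}

# Does `tail_seq` contain `flank_seq` within the mismatch tolerance?
clip_rematches_flank <- function(tail_seq, flank_seq, max_mm_frac = 0.1,
                                 min_len = 20) {
  if (nchar(flank_seq) < min_len || nchar(tail_seq) < nchar(flank_seq))
    return(FALSE)
  max_mm <- floor(max_mm_frac * nchar(flank_seq))
  length(Biostrings::matchPattern(flank_seq, Biostrings::DNAString(tail_seq),
                                  max.mismatch = max_mm,
                                  with.indels = FALSE)) > 0
}

#' Sequencing yield per read category
#'
#' Classifies reads into the nested categories used to summarise a capture
#' run: total, unmapped, mapped within 1000 bases of a target, intersecting a
#' target, spanning a target, and "useful" (spanning the target together
#' with at least `flank_useful` bases of both flanks).  A soft-clipped read
#' whose alignment covers one flank and whose clipped tail re-matches the
#' opposite flank (at most 10% mismatches over at least 20 bases) counts as
#' spanning and useful: that is the signature of an allele whose repeat
#' differs too much from the reference for a contiguous alignment.
#'
#' @param reads Read data.frame (id, seq) as aligned.
#' @param alignments Alignment data.frame (after duplicate removal).
#' @param targets Catalog with chrom, start, end.
#' @param ref Named character vector of chromosome sequences.
#' @param near Distance defining "within N bases" (default 1000).
#' @param flank_useful Flank coverage required for a useful read (default 20).
#' @param rescue_min_len,rescue_mm_frac Soft-clip rescue parameters.
#' @return data.frame of class "yield_summary" (category, reads, fraction);
#'   per-read category flags are attached as attribute "flags".
#' @export
yield_summary <- function(reads, alignments, targets, ref, near = 1000,
                          flank_useful = 20, rescue_min_len = 20,
                          rescue_mm_frac = 0.1) {
  ref <- as_ref_list(ref)
  n_total <- nrow(reads)
  aln <- alignments[match(reads$id, alignments$read_id), , drop = FALSE]
  mapped <- !is.na(aln$start)

  flg <- data.frame(read_id = reads$id, mapped = mapped,
                    within = FALSE, intersecting = FALSE,
                    spanning = FALSE, useful = FALSE,
                    stringsAsFactors = FALSE)

  for (t in seq_len(nrow(targets))) {
    ts <- targets$start[t]; te <- targets$end[t]
    tc <- as.character(targets$chrom[t])
    onchrom <- mapped & aln$chrom == tc
    ov_near <- onchrom & aln$start < te + near & aln$end > ts - near
    ov_int <- onchrom & aln$start < te & aln$end > ts
    span_plain <- onchrom & aln$start <= ts & aln$end >= te
    useful_plain <- onchrom & aln$start <= ts - flank_useful &
      aln$end >= te + flank_useful

    # soft-clip rescue
    lf <- subseq0(ref[[tc]], max(ts - flank_useful, 0L), ts)
    rf <- subseq0(ref[[tc]], te, min(te + flank_useful, nchar(ref[[tc]])))
    rescue <- rep(FALSE, n_total)
    cand <- which(ov_int & !useful_plain &
                    (aln$clip_left >= rescue_min_len |
                       aln$clip_right >= rescue_min_len))
    for (i in cand) {
      ro <- if (aln$strand[i] == "+") toupper(reads$seq[i]) else
        revcomp(toupper(reads$seq[i]))
      n <- nchar(ro)
      covers_left <- aln$start[i] <= ts - flank_useful
      covers_right <- aln$end[i] >= te + flank_useful
      if (covers_left && aln$clip_right[i] >= rescue_min_len &&
          clip_rematches_flank(substr(ro, n - aln$clip_right[i] + 1L, n), rf,
                               rescue_mm_frac, rescue_min_len))
        rescue[i] <- TRUE
      if (covers_right && aln$clip_left[i] >= rescue_min_len &&
          clip_rematches_flank(substr(ro, 1L, aln$clip_left[i]), lf,
                               rescue_mm_frac, rescue_min_len))
        rescue[i] <- TRUE
    }

    flg$within <- flg$within | ov_near
    flg$intersecting <- flg$intersecting | ov_int
    flg$spanning <- flg$spanning | span_plain | rescue
    flg$useful <- flg$useful | useful_plain | rescue
  }

  counts <- c(total = n_total,
              unmapped = sum(!mapped),
              within_1000 = sum(flg$within),
              intersecting = sum(flg$intersecting),
              spanning = sum(flg$spanning),
              useful = sum(flg$useful))
  out <- data.frame(category = names(counts), reads = as.integer(counts),
                    fraction = as.numeric(counts) / max(n_total, 1L),
                    stringsAsFactors = FALSE)
  class(out) <- c("yield_summary", "data.frame")
  attr(out, "flags") <- flg
  out
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Sequencing yield\n")
  df <- as.data.frame(x)
  df$fraction <- sprintf("%.2f%%", 100 * df$fraction)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
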