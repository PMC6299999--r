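# Capture probe design: four probe types per target, a genomic uniqueness
# screen, outward-shift rescue of failed targets, and GC-based replication.
#
# A probe table is a data.frame with columns
#   probe_id, target_id, type, chrom, start, end, start2, end2, seq, gc,
#   shift, verdict (after screening), replication (after replication).
# `double` probes have two genomic segments; start2/end2 hold the second.

probe_types <- c("left_flank", "right_flank", "spanning", "double")

as_ref_list <- function(ref) {
  if (is.character(ref)) {
    if (is.null(names(ref))) names(ref) <- paste0("seq", seq_along(ref))
    return(as.list(ref))
  }
  stop("ref must be a (named) character vector of chromosome sequences")
}

#' Generate candidate capture probes for a repeat locus
#'
#' Produces up to four probes: a left flanking probe ending at the repeat
#' start, a right flanking probe starting at the repeat end, a spanning probe
#' centered on the repeat midpoint, and a double probe concatenating
#' `probe_len/2` bases from each flank.  Types whose coordinates fall outside
#' the chromosome are omitted with a warning.
#'
#' @param locus One catalog row (or list) with id, chrom, start, end.
#' @param ref Named character vector of chromosome sequences.
#' @param probe_len Probe length in bases (default 120; must be even).
#' @return Probe table with one row per available type.
#' @export
generate_probes <- function(locus, ref, probe_len = 120) {
  if (probe_len < 2 || probe_len %% 2 != 0)
    stop("probe_len must be a positive even number")
  ref <- as_ref_list(ref)
  chrom <- as.character(locus$chrom)
  if (is.null(ref[[chrom]])) stop("chromosome ", chrom, " not in reference")
  seqlen <- nchar(ref[[chrom]])
  s <- as.integer(locus$start); e <- as.integer(locus$end)
  half <- probe_len %/% 2L
  sp_start <- (s + e - probe_len) %/% 2L

  spec <- list(
    left_flank  = list(start = s - probe_len, end = s),
    right_flank = list(start = e, end = e + probe_len),
    spanning    = list(start = sp_start, end = sp_start + probe_len),
    double      = list(start = s - half, end = s, start2 = e, end2 = e + half))

  rows <- lapply(names(spec), function(ty) {
    p <- spec[[ty]]
    coords <- c(p$start, p$end, p$start2, p$end2)
    if (any(coords < 0) || any(coords > seqlen)) {
      warning("probe type ", ty, " out of range for ", locus$id, call. = FALSE)
      return(NULL)
    }
    sq <- subseq0(ref[[chrom]], p$start, p$end)
    if (!is.null(p$start2)) sq <- paste0(sq, subseq0(ref[[chrom]], p$start2, p$end2))
    data.frame(probe_id = paste0(locus$id, "_", ty),
               target_id = as.character(locus$id), type = ty,
               chrom = chrom, start = p$start, end = p$end,
               start2 = if (is.null(p$start2)) NA_integer_ else p$start2,
               end2 = if (is.null(p$end2)) NA_integer_ else p$end2,
               seq = sq, gc = gc_fraction(sq), shift = 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe_id = character(0), target_id = character(0),
                      type = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      seq = character(0), gc = numeric(0), shift = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Mismatch-bounded hits of one oriented pattern against one chromosome.
# Returns 0-based half-open hit intervals on the plus strand.
pattern_hits <- function(pattern, chrom_seq, max_mm) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(chrom_seq),
                                   max.mismatch = max_mm, with.indels = FALSE)
  if (!length(hits)) return(NULL)
  data.frame(start = BiocGenerics::start(hits) - 1L,
             end = BiocGenerics::end(hits), stringsAsFactors = FALSE)
}

#' Screen a probe for genomic uniqueness
#'
#' A hit is any genomic window (either strand) matching the probe sequence
#' with at most `max_mismatch` substitutions overall and at most
#' `seed_max_mismatch` substitutions in the probe's first `seed_len` bases (a
#' seed-and-total-penalty reinterpretation of short-read aligner screening
#' settings; indels are not modelled).  The probe's own footprint counts as
#' the expected hit; windows overlapping it are ignored.  `double` probes are
#' screened per segment and receive the worst verdict of the two.
#'
#' @param probe One probe-table row.
#' @param ref Named character vector of chromosome sequences.
#' @param seed_len,seed_max_mismatch,max_mismatch Screen parameters.
#' @param clusters Optional data.frame (chrom, start, end) of declared
#'   duplication clusters: extra hits falling inside them yield the verdict
#'   `cluster_specific` instead of `ambiguous`.
#' @return One of "unique", "cluster_specific", "ambiguous", with the extra
#'   hits attached as attribute "hits".
#' @export
uniqueness_screen <- function(probe, ref, seed_len = 15,
                              seed_max_mismatch = 3, max_mismatch = 6,
                              clusters = NULL) {
  ref <- as_ref_list(ref)
  if (!all(nzchar(unlist(ref)))) stop("empty reference sequence")
  segs <- list(list(seq = if (probe$type == "double")
                      subseq0(ref[[probe$chrom]], probe$start, probe$end)
                    else probe$seq,
                    start = probe$start, end = probe$end))
  if (probe$type == "double")
    segs <- c(segs, list(list(seq = subseq0(ref[[probe$chrom]], probe$start2,
                                            probe$end2),
                              start = probe$start2, end = probe$end2)))

  verdicts <- character(0)
  all_extra <- list()
  for (sg in segs) {
    if (nchar(sg$seq) < seed_len) stop("probe segment shorter than the seed")
    pat_f <- sg$seq
    pat_r <- revcomp(sg$seq)
    extra <- list()
    for (chrom in names(ref)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pat_f else pat_r
        h <- pattern_hits(pat, ref[[chrom]], max_mismatch)
        if (is.null(h)) next
        for (r in seq_len(nrow(h))) {
          win <- subseq0(ref[[chrom]], h$start[r], h$end[r])
          # compare in probe orientation so the seed is the probe 5' end
          win_p <- if (strand == "+") win else revcomp(win)
          mm <- strsplit(win_p, "")[[1]] != strsplit(sg$seq, "")[[1]]
          if (sum(mm[seq_len(seed_len)]) > seed_max_mismatch) next
          self <- chrom == probe$chrom &&
            h$start[r] < sg$end && h$end[r] > sg$start
          if (self) next
          extra[[length(extra) + 1L]] <-
            data.frame(chrom = chrom, start = h$start[r], end = h$end[r],
                       strand = strand, mismatches = sum(mm),
                       stringsAsFactors = FALSE)
        }
      }
    }
    extra <- if (length(extra)) do.call(rbind, extra) else NULL
    v <- if (is.null(extra)) "unique"
    else {
      in_cluster <- if (is.null(clusters) || !nrow(clusters)) {
        rep(FALSE, nrow(extra))
      } else {
        vapply(seq_len(nrow(extra)), function(i) {
          any(clusters$chrom == extra$chrom[i] &
                extra$start[i] < clusters$end & extra$end[i] > clusters$start)
        }, logical(1))
      }
      if (all(in_cluster)) "cluster_specific" else "ambiguous"
    }
    verdicts <- c(verdicts, v)
    if (!is.null(extra)) all_extra[[length(all_extra) + 1L]] <- extra
  }
  rank <- c(unique = 1, cluster_specific = 2, ambiguous = 3)
  out <- names(rank)[max(rank[verdicts])]
  attr(out, "hits") <- if (length(all_extra)) do.call(rbind, all_extra) else NULL
  out
}

#' Screen a probe table
#'
#' @param probes Probe table.
#' @param ref,clusters,... Passed to [uniqueness_screen()].
#' @return The table with a `verdict` column.
#' @export
screen_probes <- function(probes, ref, clusters = NULL, ...) {
  probes$verdict <- vapply(seq_len(nrow(probes)), function(i)
    as.character(uniqueness_screen(probes[i, ], ref, clusters = clusters, ...)),
    character(1))
  probes
}

# Probe of the given type shifted `shift` bases outward from the repeat.
shifted_probe <- function(locus, ref, type, shift, probe_len) {
  s <- as.integer(locus$start); e <- as.integer(locus$end)
  half <- probe_len %/% 2L
  shifted <- list(id = locus$id, chrom = locus$chrom,
                  start = s - shift, end = e + shift)
  p <- switch(type,
    left_flank  = list(start = s - shift - probe_len, end = s - shift),
    right_flank = list(start = e + shift, end = e + shift + probe_len),
    double      = list(start = s - shift - half, end = s - shift,
                       start2 = e + shift, end2 = e + shift + half),
    stop("type ", type, " cannot be shifted"))
  refl <- as_ref_list(ref)
  seqlen <- nchar(refl[[as.character(locus$chrom)]])
  if (p$start < 0 || (is.null(p$end2) && p$end > seqlen) ||
      (!is.null(p$end2) && p$end2 > seqlen)) return(NULL)
  sq <- subseq0(refl[[as.character(locus$chrom)]], p$start, p$end)
  if (!is.null(p$start2))
    sq <- paste0(sq, subseq0(refl[[as.character(locus$chrom)]], p$start2, p$end2))
  data.frame(probe_id = sprintf("%s_%s_s%d", locus$id, type, shift),
             target_id = as.character(locus$id), type = type,
             chrom = as.character(locus$chrom),
             start = p$start, end = p$end,
             start2 = if (is.null(p$start2)) NA_integer_ else p$start2,
             end2 = if (is.null(p$end2)) NA_integer_ else p$end2,
             seq = sq, gc = gc_fraction(sq), shift = as.integer(shift),
             stringsAsFactors = FALSE)
}

#' Rescue a target by shifting probes outward
#'
#' For each shiftable probe type (left flank, right flank, double) the probe
#' is moved outward from the repeat in `step`-base increments up to
#' `max_shift`; at the first passing coarse shift the search refines in
#' 1-base steps so the reported probe is the most proximal (smallest passing
#' shift) one.  Spanning probes are anchored to the repeat midpoint and are
#' not shiftable.
#'
#' @param locus One catalog row.
#' @param ref Named character vector of chromosome sequences.
#' @param probe_len Probe length.
#' @param max_shift Maximum outward shift in bases.
#' @param step Coarse search step in bases.
#' @param clusters,... Passed to [uniqueness_screen()].
#' @return Probe table of rescued probes (possibly empty), one row per type,
#'   with `shift` and `verdict` recorded.
#' @export
shift_and_rescue <- function(locus, ref, probe_len = 120, max_shift = 500,
                             step = 10, clusters = NULL, ...) {
  passing <- function(p) {
    if (is.null(p)) return(NULL)
    v <- uniqueness_screen(p, ref, clusters = clusters, ...)
    if (v %in% c("unique", "cluster_specific")) { p$verdict <- as.character(v); p }
    else NULL
  }
  out <- list()
  for (type in c("left_flank", "right_flank", "double")) {
    found <- NULL
    coarse <- unique(c(0L, seq.int(step, max_shift, by = step)))
    for (s in coarse) {
      hit <- passing(shifted_probe(locus, ref, type, s, probe_len))
      if (!is.null(hit)) {
        if (s > 0L) {
          for (fine in seq.int(max(s - step + 1L, 1L), s)) {
            fhit <- passing(shifted_probe(locus, ref, type, fine, probe_len))
            if (!is.null(fhit)) { hit <- fhit; break }
          }
        }
        found <- hit
        break
      }
    }
    if (!is.null(found)) out[[type]] <- found
  }
  if (!length(out))
    return(empty_probe_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_probe_table <- function() {
  data.frame(probe_id = character(0), target_id = character(0),
             type = character(0), chrom = character(0), start = integer(0),
             end = integer(0), start2 = integer(0), end2 = integer(0),
             seq = character(0), gc = numeric(0), shift = integer(0),
             verdict = character(0), stringsAsFactors = FALSE)
}

#' Apply GC-based probe replication
#'
#' Probes with extreme GC content capture poorly, so any probe with GC
#' strictly below `gc_low` or strictly above `gc_high` is multiplied by 4;
#' all others keep the base replication.
#'
#' @param probes Probe table.
#' @param base_replication Replication for probes of moderate GC.
#' @param gc_low,gc_high GC bounds (strict inequalities).
#' @return The table with a `replication` column; totals are available via
#'   [design_summary()].
#' @export
replicate_probes <- function(probes, base_replication = 1,
                             gc_low = 0.40, gc_high = 0.70) {
  if (!nrow(probes)) { probes$replication <- integer(0); return(probes) }
  if (any(is.na(probes$gc))) stop("probe gc must be populated")
  probes$replication <- ifelse(probes$gc < gc_low | probes$gc > gc_high,
                               4L, as.integer(base_replication))
  probes
}

#' Totals of a replicated probe design
#'
#' @param probes Replicated probe table.
#' @return data.frame with the number of probe records, total probe count
#'   (replication included) and capture size in bases.
#' @export
design_summary <- function(probes) {
  stopifnot("replication" %in% names(probes))
  data.frame(n_probe_records = nrow(probes),
             total_probes = sum(probes$replication),
             capture_size_bp = sum(probes$replication * nchar(probes$seq)))
}

#' Design capture probes for a whole catalog
#'
#' Generates the four candidate types per target, screens them for
#' uniqueness, rescues failed flank/double probes by outward shifting, and
#' applies GC-based replication.  At most one probe per type survives per
#' target.
#'
#' @param catalog Repeat catalog.
#' @param ref Named character vector of chromosome sequences.
#' @param probe_len,max_shift,step,clusters,base_replication,... See the
#'   stage functions.
#' @return Replicated probe table for all targets.
#' @export
design_probes <- function(catalog, ref, probe_len = 120, max_shift = 500,
                          step = 10, clusters = NULL, base_replication = 1,
                          ...) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    locus <- catalog[i, ]
    cand <- generate_probes(locus, ref, probe_len)
    if (!nrow(cand)) return(NULL)
    cand <- screen_probes(cand, ref, clusters = clusters, ...)
    ok <- cand$verdict %in% c("unique", "cluster_specific")
    kept <- cand[ok, , drop = FALSE]
    failed_types <- setdiff(cand$type[!ok], "spanning")
    if (length(failed_types)) {
      resc <- shift_and_rescue(locus, ref, probe_len, max_shift, step,
                               clusters = clusters, ...)
      resc <- resc[resc$type %in% failed_types, , drop = FALSE]
      kept <- rbind(kept, resc)
    }
    kept
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_probe_table()
  out <- replicate_probes(out, base_replication)
  rownames(out) <- NULL
  out
}
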