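# Coordinate convention: all internal coordinates are 0-based, half-open
# [start, end).  Published tables use 1-based inclusive positions; converters
# below translate between the two.

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of sequences over the ACGTN alphabet
#'   (case-insensitive; case is preserved).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' GC fraction of sequences
#'
#' N bases count as non-GC but remain in the denominator, so a run of Ns has
#' GC fraction 0, not NA.
#'
#' @param x Character vector of sequences.
#' @return Numeric vector of GC fractions in [0, 1].
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0L, gc / n, NA_real_)
}

# 0-based half-open substring extraction.
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Published locus tables print 1-based inclusive positions (for example
#' chrX:45,606,270-45,606,355, an 86 bp dinucleotide tract of 43 copies);
#' internally everything is 0-based half-open.
#'
#' @param start,end Numeric vectors of coordinates.
#' @return A list with components `start` and `end` in the other convention.
#' @export
coords_one_to_zero <- function(start, end) {
  stopifnot(all(end >= start))
  list(start = start - 1, end = end)
}

#' @rdname coords_one_to_zero
#' @export
coords_zero_to_one <- function(start, end) {
  stopifnot(all(end > start))
  list(start = start + 1, end = end)
}

#' Copy number implied by locus coordinates and unit length
#'
#' @param start,end Locus coordinates.
#' @param unit_len Repeat unit length in bases.
#' @param coords Either `"zero"` (0-based half-open, the internal convention)
#'   or `"one"` (1-based inclusive, the convention of printed tables).
#' @return Numeric vector of copy numbers (span / unit length).
#' @examples
#' locus_copies(45606270, 45606355, 2, coords = "one")  # 43
#' @export
locus_copies <- function(start, end, unit_len, coords = c("zero", "one")) {
  coords <- match.arg(coords)
  stopifnot(all(unit_len >= 1))
  span <- if (coords == "zero") end - start else end - start + 1
  if (any(span <= 0)) stop("locus span must be positive")
  span / unit_len
}

#' Probability of several independent causal factors co-occurring
#'
#' With a per-individual background rate of sporadic disease, the chance that
#' `k` independent causes co-occur within one family is `rate^k`; at the 2%
#' population prevalence this gives 4e-4 for two and 8e-6 for three factors,
#' which is why a single segregating cause is the favoured explanation in a
#' multiplex family.
#'
#' @param rate Per-event probability in (0, 1).
#' @param k Integer number of independent co-occurring events.
#' @return `rate ^ k`.
#' @export
cooccurrence_probability <- function(rate, k) {
  stopifnot(rate > 0, rate < 1, k >= 1)
  rate^k
}

#' Maximum measurable repeat length for circular consensus reads
#'
#' Building an accurate consensus requires a minimum number of polymerase
#' passes over the insert, so the longest measurable insert is the polymerase
#' read length divided by the minimum pass count (15 kb reads at 6 passes
#' give 2.5 kb).
#'
#' @param read_len Mean polymerase read length (any unit).
#' @param min_passes Minimum number of passes required for a consensus read.
#' @return Maximum insert (hence repeat) length, in the unit of `read_len`.
#' @export
max_measurable_repeat <- function(read_len, min_passes = 6) {
  stopifnot(read_len > 0, min_passes >= 1)
  read_len / min_passes
}

# Validate a nucleotide string; returns the uppercased sequence.
check_dna <- function(seq, allow_n = TRUE) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop("sequence must be a single non-empty character string")
  seq <- toupper(seq)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), seq))
    stop("sequence contains characters outside ", alphabet)
  seq
}

# Hamming distance between two equal-length strings.
count_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Random DNA of length n with a given GC fraction (uniform within class).
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Distance between two half-open intervals (0 when they overlap or touch
# counts as gap 0 only on true overlap; touching intervals have distance 0).
interval_distance <- function(s1, e1, s2, e2) {
  d <- pmax(s2 - e1, s1 - e2)
  pmax(d, 0)
}
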