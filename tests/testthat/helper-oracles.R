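# Independent brute-force oracles.  These deliberately avoid the package's
# internal algorithms: quadratic scans, recursive extraction and explicit
# loops stand in for the optimised implementations they check.

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# All maximal positive-scoring segments of v by recursive extraction of the
# best segment.  Ties take the rightmost start and then the shortest
# segment: a merge across a tie does not improve the score, so tied
# overlapping candidates stay separate, matching the all-maximal-scoring-
# subsequences definition.  O(n^2) per level.
oracle_segments <- function(v) {
  out <- list()
  recurse <- function(lo, hi) {
    if (lo > hi) return(invisible())
    best <- NULL
    for (a in lo:hi) {
      run <- cumsum(v[a:hi])
      b_rel <- which(run == max(run))[1]   # shortest best end for this start
      sc <- run[b_rel]
      if (sc > 0 && (is.null(best) || sc >= best$sc))
        best <- list(a = a, b = a + b_rel - 1L, sc = sc)
    }
    if (is.null(best)) return(invisible())
    out[[length(out) + 1L]] <<- best
    recurse(lo, best$a - 1L)
    recurse(best$b + 1L, hi)
  }
  recurse(1L, length(v))
  if (!length(out)) return(matrix(numeric(0), ncol = 3,
                                  dimnames = list(NULL, c("start", "end", "score"))))
  m <- do.call(rbind, lapply(out, function(x) c(x$a, x$b, x$sc)))
  colnames(m) <- c("start", "end", "score")
  m[order(m[, "start"]), , drop = FALSE]
}

# position-by-position purity with explicit phase loop
oracle_purity <- function(seq, start, end, unit) {
  chars <- strsplit(substr(seq, start + 1, end), "")[[1]]
  uch <- strsplit(unit, "")[[1]]
  span <- length(chars); u <- length(uch)
  best <- 0
  for (p in 0:(u - 1)) {
    tile <- uch[((seq_len(span) - 1 + p) %% u) + 1]
    best <- max(best, sum(chars == tile & chars != "N"))
  }
  100 * best / span
}

# exhaustive repeat scan: oracle segmentation per unit size, consensus unit
# by explicit column majority, then the documented overlap-resolution rule
oracle_find_repeats <- function(seq, min_unit, max_unit, min_total_len,
                                min_copies, min_purity = 70, k = 3) {
  ss <- strsplit(seq, "")[[1]]
  n <- length(ss)
  cand <- list()
  for (u in min_unit:max_unit) {
    if (n < 2 * u) break
    i <- seq_len(n - u)
    v <- ifelse(ss[i] == ss[i + u] & ss[i] != "N", 1, -k)
    segs <- oracle_segments(v)
    for (r in seq_len(nrow(segs))) {
      a <- segs[r, "start"]; b <- segs[r, "end"]
      start0 <- a - 1; end0 <- b + u
      span <- end0 - start0
      if (span < min_total_len || span / u < min_copies) next
      tract <- ss[a:(b + u)]
      unit <- character(u)
      for (c in 1:u) {
        col <- tract[seq(c, span, by = u)]
        col <- col[col != "N"]
        tb <- sort(table(col), decreasing = TRUE)
        # alphabetical among tied majorities
        top <- names(tb)[tb == max(tb)]
        unit[c] <- sort(top)[1]
      }
      unit <- paste(unit, collapse = "")
      pur <- oracle_purity(seq, start0, end0, unit)
      if (pur < min_purity) next
      cand[[length(cand) + 1]] <- data.frame(
        start = start0, end = end0, unit_len = u, unit_seq = unit,
        purity = pur, score = segs[r, "score"])
    }
  }
  if (!length(cand)) return(data.frame(start = integer(0), end = integer(0),
                                       unit_len = integer(0)))
  df <- do.call(rbind, cand)
  df <- df[order(-df$score, df$unit_len, df$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df)); acc <- list()
  for (i in seq_len(nrow(df))) {
    ov <- any(vapply(acc, function(x) df$start[i] < x[2] && df$end[i] > x[1],
                     logical(1)))
    if (!ov) { keep[i] <- TRUE; acc[[length(acc) + 1]] <- c(df$start[i], df$end[i]) }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

# all substring positions matching a pattern within max_mm substitutions
oracle_hamming_hits <- function(pattern, subject, max_mm) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  np <- length(pc); ns <- length(sc)
  hits <- integer(0)
  if (ns < np) return(hits)
  for (s in 1:(ns - np + 1)) {
    if (sum(sc[s:(s + np - 1)] != pc) <= max_mm) hits <- c(hits, s)
  }
  hits
}

# affine-gap local alignment (Gotoh), small inputs only; returns best score
oracle_local_score <- function(q, s, match = 1, mismatch = -3,
                               gap_open = 5, gap_ext = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# binomial upper-tail by explicit summation
oracle_binom_tail <- function(x, n, p) {
  sum(vapply(x:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# deregulation ratio by explicit loop
oracle_R <- function(P, controls) {
  dmin <- Inf
  for (c in controls) dmin <- min(dmin, abs(P - c))
  dmin / (max(controls) - min(controls))
}

# read-category counts by direct interval arithmetic on true placements
oracle_yield_counts <- function(placements, targets, near = 1000, fl = 20) {
  # placements: data.frame(start, end, mapped)
  n <- nrow(placements)
  within <- inter <- span <- useful <- rep(FALSE, n)
  for (t in seq_len(nrow(targets))) {
    ts <- targets$start[t]; te <- targets$end[t]
    for (i in seq_len(n)) {
      if (!placements$mapped[i]) next
      s <- placements$start[i]; e <- placements$end[i]
      if (s < te + near && e > ts - near) within[i] <- TRUE
      if (s < te && e > ts) inter[i] <- TRUE
      if (s <= ts && e >= te) span[i] <- TRUE
      if (s <= ts - fl && e >= te + fl) useful[i] <- TRUE
    }
  }
  c(total = n, unmapped = sum(!placements$mapped), within_1000 = sum(within),
    intersecting = sum(inter), spanning = sum(span), useful = sum(useful))
}
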