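# Independent brute-force oracles used across tests. These deliberately
# avoid the package's implementation paths (no shared C++ code).

# DNA alphabet helper
.BASES <- c("A", "C", "G", "T")

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force sliding Hamming bait scan: best (bait, offset, mismatches)
# with ties to fewer mismatches, smaller offset, earlier bait.
oracle_scan <- function(read, baits, max_mm) {
  bl <- nchar(baits[1])
  best <- NULL
  if (nchar(read) < bl) return(NULL)
  for (off in 0:(nchar(read) - bl)) {
    win <- strsplit(substr(read, off + 1, off + bl), "")[[1]]
    for (b in seq_along(baits)) {
      bb <- strsplit(baits[b], "")[[1]]
      mm <- sum(win != bb | !win %in% .BASES)
      if (mm <= max_mm && (is.null(best) || mm < best$mm)) {
        best <- list(bait = b, offset = off, mm = mm)
      }
    }
  }
  best
}

# Brute-force all-offsets overlap search mirroring the merge rule:
# minimal mismatch ratio, ties to the longer overlap.
oracle_overlap <- function(s1, s2rc, min_overlap, max_ratio) {
  l1 <- nchar(s1); l2 <- nchar(s2rc)
  best <- list(o = 0L, mm = 0L, ratio = 2)
  for (o in min_overlap:min(l1, l2)) {
    a <- strsplit(substr(s1, l1 - o + 1, l1), "")[[1]]
    b <- strsplit(substr(s2rc, 1, o), "")[[1]]
    mm <- sum(a != b)
    ratio <- mm / o
    if (ratio <= max_ratio &&
        (ratio < best$ratio - 1e-12 ||
           (abs(ratio - best$ratio) <= 1e-12 && o > best$o))) {
      best <- list(o = o, mm = mm, ratio = ratio)
    }
  }
  best
}

# Exhaustive ungapped alignment of one flank over a small genome; returns
# all best placements (contig, pos, strand, mm).
oracle_align <- function(flank, genome, max_frac) {
  L <- nchar(flank)
  allow <- floor(max_frac * L)
  hits <- list()
  for (orient in c("+", "-")) {
    q <- if (orient == "+") flank else oracle_revcomp(flank)
    qc <- strsplit(q, "")[[1]]
    for (ctg in names(genome)) {
      g <- genome[[ctg]]
      if (nchar(g) < L) next
      gc <- strsplit(g, "")[[1]]
      for (p in 0:(nchar(g) - L)) {
        mm <- sum(qc != gc[(p + 1):(p + L)])
        if (mm <= allow) {
          hits[[length(hits) + 1]] <-
            list(contig = ctg, pos = p, strand = orient, mm = mm)
        }
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  hits[mms == min(mms)]
}

# Binomial pmf by multiplicative recurrence (no dbinom), normalised.
oracle_binom_pmf <- function(t, pr) {
  logp <- numeric(t + 1)
  # log pmf via cumulated logs for numerical stability
  lr <- log(pr) - log1p(-pr)
  logp[1] <- t * log1p(-pr)
  if (t > 0) {
    for (k in 1:t) {
      logp[k + 1] <- logp[k] + log(t - k + 1) - log(k) + lr
    }
  }
  p <- exp(logp)
  p / sum(p)
}

# Full-enumeration conditional exact test matching the defined tie rule.
oracle_exact_test <- function(ya, yb, na, nb) {
  t <- ya + yb
  if (t == 0) return(1)
  pr <- na / (na + nb)
  d <- oracle_binom_pmf(t, pr)
  min(1, sum(d[d <= d[ya + 1] * (1 + 1e-7)]))
}

# Random DNA from the test RNG
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE), collapse = ""), character(1))
}

mutate_positions <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(.BASES, ch[p])[sample.int(3, 1)]
  paste(ch, collapse = "")
}
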