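# Bait matching, flank extraction, linker stripping and the internal
# HML-2 filter.

el <- hml2_elements()
bs <- bait_set(elements = el)
read_tbl <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  tibble::tibble(read_id = ids, seq = seqs,
                 qual = strrep("I", nchar(seqs)), merged = TRUE)
}

test_that("bait matching honours the 20-bp / 90% identity contract", {
  set.seed(10)
  bait <- bs$seq[1]
  host <- rand_dna(1, 60)
  r <- read_tbl(paste0(bait, host))
  hit <- match_baits(r, bs)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$read_offset, 0L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$bait_name, bs$bait_name[1])

  # 2 mismatches of 20 -> identity 0.90, accepted at the >= threshold
  b2 <- mutate_positions(bait, c(3, 11))
  hit2 <- match_baits(read_tbl(paste0(host, b2)), bs)
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$identity, 0.90)
  expect_equal(hit2$read_offset, 60L)

  # 3 mismatches -> identity 0.85, rejected
  b3 <- mutate_positions(bait, c(3, 11, 17))
  hit3 <- match_baits(read_tbl(paste0(host, b3)), bs)
  expect_equal(nrow(hit3), 0L)

  # reads shorter than the bait are counted as too short
  short <- match_baits(read_tbl(substr(bait, 1, 15)), bs)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "metrics")$n_too_short, 1L)

  # 'N' never matches: a bait with 2 mutations plus an N fails
  bN <- sub("^(..)", "\\1N", mutate_positions(bait, c(7, 13)))
  expect_equal(nrow(match_baits(read_tbl(paste0(host, bN)), bs)), 0L)
})

test_that("bait scan equals the brute-force sliding Hamming oracle", {
  set.seed(11)
  scan_baits <- c(bs$seq, oracle_revcomp(bs$seq))
  n <- 200
  reads <- character(n)
  for (i in seq_len(n)) {
    if (i %% 2 == 0) {
      # planted bait with 0-4 mutations at a random offset/orientation
      b <- sample(scan_baits, 1)
      nmut <- sample(0:4, 1)
      if (nmut > 0) b <- mutate_positions(b, sample.int(20, nmut))
      left <- rand_dna(1, sample(0:80, 1))
      reads[i] <- paste0(left, b, rand_dna(1, sample(10:60, 1)))
    } else {
      reads[i] <- rand_dna(1, sample(30:150, 1))
    }
  }
  got <- match_baits(read_tbl(reads), bs)
  for (i in seq_len(n)) {
    want <- oracle_scan(reads[i], scan_baits, max_mm = 2)
    row <- got[got$read_id == paste0("r", i), ]
    if (is.null(want)) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(nrow(row), 1L)
      expect_equal(row$read_offset, want$offset)
      expect_equal(row$identity, (20 - want$mm) / 20)
    }
  }
})

test_that("flank extraction is strand-symmetric and junction-outward", {
  set.seed(12)
  host <- rand_dna(1, 30)
  bait5 <- bs$seq[bs$ltr_end == "five_prime"][1]
  ltr_tail <- substr(el$ltr[[1]], 21, 30)
  read <- paste0(host, bait5, ltr_tail)   # host | LTR start | LTR interior
  hit <- extract_flanks(match_baits(read_tbl(read), bs))
  expect_equal(nrow(hit), 1L)
  # junction-outward: the stored flank is the reverse complement of the
  # host prefix, i.e. it reads away from the LTR junction
  expect_equal(hit$flank_seq, oracle_revcomp(host))

  rc_read <- oracle_revcomp(read)
  hit_rc <- extract_flanks(match_baits(read_tbl(rc_read), bs))
  expect_equal(hit_rc$flank_seq, hit$flank_seq)
  expect_equal(hit_rc$ltr_end, hit$ltr_end)

  # three_prime: host follows the LTR end
  bait3 <- bs$seq[bs$ltr_end == "three_prime"][1]
  read3 <- paste0(substr(el$ltr[[1]], 900, 948), host)
  # the last 20 bases of the LTR are the three_prime bait
  read3 <- paste0(substr(el$ltr[[1]], nchar(el$ltr[[1]]) - 48,
                         nchar(el$ltr[[1]])), host)
  hit3 <- extract_flanks(match_baits(read_tbl(read3), bs))
  expect_equal(hit3$flank_seq, host)
  expect_equal(extract_flanks(match_baits(read_tbl(oracle_revcomp(read3)),
                                          bs))$flank_seq, host)

  # zero-length flank is dropped and counted
  only_bait <- read_tbl(paste0(bait5, ltr_tail))
  fl0 <- extract_flanks(match_baits(only_bait, bs))
  expect_equal(nrow(fl0), 0L)
  expect_equal(attr(fl0, "metrics")$n_empty_flank, 1L)
})

test_that("linker stripping removes the best suffix overlap and enforces min_flank", {
  set.seed(13)
  linker <- default_protocol()$linker_seq
  mk_hit <- function(flank) {
    tibble::tibble(read_id = "r", ltr_end = "three_prime",
                   flank_seq = flank, flank_qual = strrep("I", nchar(flank)))
  }
  clean <- rand_dna(1, 40)
  expect_equal(strip_linker(mk_hit(clean), linker)$flank_seq, clean)

  # full linker stripped
  expect_equal(strip_linker(mk_hit(paste0(clean, linker)), linker)$flank_seq,
               clean)
  # partial (prefix) linker stripped
  expect_equal(strip_linker(mk_hit(paste0(clean, substr(linker, 1, 9))),
                            linker)$flank_seq, clean)
  # 10-nt flank survives, 9-nt flank is abandoned
  f10 <- paste0(rand_dna(1, 10), substr(linker, 1, 12))
  expect_equal(nchar(strip_linker(mk_hit(f10), linker)$flank_seq), 10L)
  f9 <- paste0(rand_dna(1, 9), substr(linker, 1, 12))
  out9 <- strip_linker(mk_hit(f9), linker)
  expect_equal(nrow(out9), 0L)
  expect_equal(attr(out9, "metrics")$n_dropped, 1L)
})

test_that("linker strip boundary equals a brute-force best-overlap search", {
  set.seed(14)
  linker <- default_protocol()$linker_seq
  lk <- nchar(linker)
  for (i in 1:60) {
    flank <- rand_dna(1, sample(15:60, 1))
    o_true <- sample(0:lk, 1)
    full <- if (o_true > 0) paste0(flank, substr(linker, 1, o_true)) else flank
    got <- strip_linker(
      tibble::tibble(read_id = "r", flank_seq = full,
                     flank_qual = strrep("I", nchar(full))),
      linker, min_flank = 1)
    # oracle: longest suffix/prefix overlap with <= 10% mismatches, >= 6 nt
    L <- nchar(full)
    best <- 0
    for (o in min(lk, L):6) {
      a <- substr(full, L - o + 1, L)
      b <- substr(linker, 1, o)
      mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (mm <= floor(0.1 * o)) { best <- o; break }
    }
    expect_equal(nchar(got$flank_seq), L - best)
  }
})

test_that("the internal filter removes retroviral flanks and keeps host flanks", {
  set.seed(15)
  targets <- c(el$ltr, internal = el$internal)
  mk <- function(flank) {
    tibble::tibble(read_id = paste0("f", seq_along(flank)),
                   flank_seq = flank,
                   flank_qual = strrep("I", nchar(flank)))
  }
  gag <- substr(el$internal, 101, 180)        # planted internal fragment
  random_flank <- rand_dna(1, 80)
  out <- filter_internal_hervk(mk(c(gag, random_flank)), targets)
  expect_equal(out$read_id, "f2")
  expect_equal(attr(out, "metrics")$n_internal, 1L)

  # reverse-complemented internal sequence is also caught
  out_rc <- filter_internal_hervk(mk(oracle_revcomp(gag)), targets)
  expect_equal(nrow(out_rc), 0L)

  # a 20-nt exact internal match inside a host flank is caught
  mixed <- paste0(rand_dna(1, 30), substr(el$internal, 501, 520),
                  rand_dna(1, 30))
  expect_equal(nrow(filter_internal_hervk(mk(mixed), targets)), 0L)
})

test_that("simulated proviral internal amplicons are removed, host flanks retained", {
  s <- small_sim()
  one <- s$pairs[s$pairs$sample_id == "ind01_r1", ]
  reads <- prep_reads(one)
  flanks <- find_chimeras(reads, bs, default_protocol()$linker_seq,
                          c(el$ltr, internal = el$internal))
  tags <- parse_truth_tags(flanks$read_id)
  expect_equal(sum(tags$kind == "internal"), 0L)
  expect_gt(sum(tags$kind == "host"), 0L)
  # chimera-stage recall of host-junction molecules at error 0, relative
  # to the molecules that survive sequence-level deduplication
  prep_tags <- parse_truth_tags(reads$read_id)
  mol_host <- unique(prep_tags$mol[prep_tags$kind == "host"])
  mol_kept <- unique(tags$mol[tags$kind == "host"])
  expect_gte(length(mol_kept) / length(mol_host), 0.999)
  # survivors satisfy the stage contract
  expect_true(all(nchar(flanks$flank_seq) >= 10))
  expect_true(all(flanks$identity >= 0.90))
})
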