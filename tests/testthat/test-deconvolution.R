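# minimal sort result wrapper around a set of hit bead member indices
fake_sort <- function(members) {
  structure(list(hit_beads = data.frame(event = seq_along(members),
                                        member = members),
                 hit_bead_count = length(members)),
            class = "del_sort_result")
}

test_that("error-free sequencing reproduces member tags exactly", {
  cat <- tiny_catalog()
  reads <- reads_from_hits(fake_sort(c(1L, 5L, 12L, 5L)), cat,
                           error_rate = 0, seed = 1)
  expect_equal(reads$sequence, cat$members$tag[c(1, 5, 12, 5)])
  expect_identical(reads,
                   reads_from_hits(fake_sort(c(1L, 5L, 12L, 5L)), cat,
                                   error_rate = 0, seed = 1))
  expect_error(reads_from_hits(fake_sort(1L), cat, error_rate = 0.5,
                               seed = 1), "error_rate")
})

test_that("substitution count matches the binomial mean", {
  cat <- synthetic_library(8, 12, seed = 6)
  members <- rep_len(1:96, 600)
  reads <- reads_from_hits(fake_sort(members), cat, error_rate = 0.1,
                           seed = 33)
  truth <- cat$members$tag[members]
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$sequence, truth)
  L <- nchar(truth[1])
  expect_equal(mean(mism), 0.1 * L, tolerance = 0.1)
})

test_that("reads survive a FASTQ round trip", {
  cat <- tiny_catalog()
  reads <- reads_from_hits(fake_sort(c(3L, 8L)), cat, error_rate = 0,
                           seed = 2)
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$read_id, reads$read_id)
})

test_that("decoding corrects single substitutions and rejects junk", {
  cat <- tiny_catalog()
  tag5 <- cat$members$tag[5]
  # one substitution inside the AA segment
  mut <- tag5
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "G" else "A"
  # one substitution inside the CA segment
  mut2 <- tag5
  substr(mut2, 20, 20) <- if (substr(mut2, 20, 20) == "G") "T" else "G"
  # five N positions: matches several tags under wildcard correction
  amb <- tag5
  substr(amb, 1, 5) <- "NNNNN"
  bad <- paste(rep("A", 24), collapse = "")  # far from every c1..c4 tag
  res <- decode_reads(c(tag5, mut, mut2, amb, bad, "ACGT"), cat)
  expect_equal(res$counts$member_id, cat$members$member_id[5])
  expect_equal(res$counts$k, 3L)
  expect_equal(sort(res$discarded$reason),
               sort(c("ambiguous", "unmatched", "bad_length")))

  # nearest-tag oracle: every 1-substitution variant of every member tag
  # decodes back to that member
  for (m in c(1L, 7L, 12L)) {
    tg <- cat$members$tag[m]
    for (pos in c(1, 6, 13, 24)) {
      v <- tg
      substr(v, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(tg, pos, pos))[1]
      r <- decode_reads(v, cat)
      expect_equal(r$counts$member_id, cat$members$member_id[m])
    }
  }
})

test_that("decode conserves reads: decoded + discarded = input", {
  cat <- synthetic_library(8, 12, seed = 6)
  members <- sample.int(96, 400, replace = TRUE)
  reads <- reads_from_hits(fake_sort(members), cat, error_rate = 0.02,
                           seed = 9)
  res <- decode_reads(reads, cat)
  expect_equal(res$n_decoded + nrow(res$discarded), 400L)
  expect_equal(sum(res$counts$k), res$n_decoded)
  # with error-free reads the decode is the identity on the simulator
  clean <- reads_from_hits(fake_sort(members), cat, error_rate = 0,
                           seed = 9)
  res0 <- decode_reads(clean, cat)
  expect_equal(res0$n_decoded, 400L)
  tab <- table(members)
  expect_equal(res0$counts$k,
               as.integer(tab[as.character(res0$counts$member)]))
})

test_that("ambiguous catalogs are rejected at decode", {
  aa <- building_blocks(c("a1", "a2"), 1,
                        c("AAAAAAAAAAAA", "AAAAAAAAAAAC"))  # distance 1
  ca <- building_blocks("c1", 2, "GGGGGGGGGGGG")
  cat <- suppressWarnings(enumerate_library(aa, ca))
  expect_error(decode_reads("AAAAAAAAAAAAGGGGGGGGGGGG", cat), "ambiguous")
})

test_that("k classes aggregate member counts into cumulative BB counts", {
  cat <- tiny_catalog()
  # m(a1,c1) = member 1, m(a1,c2) = member 2
  kc <- k_class_table(data.frame(member_id = c("m000001", "m000002"),
                                 k = c(3L, 4L)), cat, "uv100")
  expect_equal(kc$members$k, c(3L, 4L))
  expect_equal(kc$bb$cum_k[kc$bb$bb_id == "a1"], 7L)
  expect_equal(kc$bb$cum_k[kc$bb$bb_id == "c1"], 3L)
  expect_equal(kc$bb$cum_k[kc$bb$bb_id == "c2"], 4L)
  expect_true(all(kc$members$replicate_supported))

  single <- k_class_table(data.frame(member_id = "m000001", k = 5L), cat)
  expect_equal(single$bb$cum_k, c(5L, 5L))

  # random count table: cumulative k equals a brute-force double loop
  set.seed(17)
  sel <- sample(12, 8)
  counts <- data.frame(member_id = cat$members$member_id[sel],
                       k = sample(1:9, 8, replace = TRUE))
  kc2 <- k_class_table(counts, cat)
  for (bb in kc2$bb$bb_id) {
    expected <- 0L
    for (i in seq_len(nrow(counts))) {
      row <- cat$members[cat$members$member_id == counts$member_id[i], ]
      if (row$aa_id == bb || row$ca_id == bb) {
        expected <- expected + counts$k[i]
      }
    }
    expect_equal(kc2$bb$cum_k[kc2$bb$bb_id == bb], expected)
  }
  expect_equal(sum(kc2$members$k), sum(counts$k))
  expect_error(k_class_table(data.frame(member_id = "zzz", k = 1L), cat),
               "absent")
})

test_that("dose comparison tiers follow the k-threshold rules", {
  cat <- tiny_catalog()
  mk <- function(counts, label) k_class_table(counts, cat, label)
  high <- mk(data.frame(member_id = c("m000001", "m000005", "m000009",
                                      "m000002", "m000012"),
                        k = c(8L, 7L, 5L, 12L, 3L)), "uv100")
  low <- mk(data.frame(member_id = c("m000001", "m000005", "m000009",
                                     "m000012"),
                       k = c(5L, 6L, 4L, 2L)), "uv030")
  rep <- dose_compare(high, low, min_k = 4L, noise_k = 3L)
  tier <- function(bb) rep$bb$tier[rep$bb$bb_id == bb]
  # c1 appears in members 1 (aa1), 5 (aa2), 9 (aa3): k 20 high / 15 low
  expect_equal(tier("c1"), "high_priority")
  # c2 only via member 2: k 12 high, 0 low -> enriched at high dose only
  expect_equal(tier("c2"), "dose_limited")
  # c4 via member 12: k 3 high / 2 low -> experimental noise
  expect_equal(tier("c4"), "noise")
  # report is sorted by combined k, ties by bb id
  comb <- rep$bb$k_high + rep$bb$k_low
  expect_true(all(diff(comb) <= 0))
  # disynthon table: only pairs with combined k >= 2
  expect_true(all(rep$disynthons$k_high + rep$disynthons$k_low >= 2))
  expect_true("m000012" %in% rep$disynthons$member_id)

  other <- synthetic_library(3, 4, seed = 50)
  expect_error(
    dose_compare(high, k_class_table(data.frame(member_id = "m000001",
                                                k = 5L), other, "x")),
    "different catalogs")
})
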