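test_that("re-alphabeting follows the three physicochemical schemes", {
  expect_equal(transform_sequence("ATCGTA", "purine_pyrimidine"), "RYYRYR")
  expect_equal(transform_sequence("ATCGTA", "amino_keto"), "MKMKKM")
  expect_equal(transform_sequence("ATCGTA", "weak_strong"), "WWSSWW")
  expect_equal(transform_sequence("AAAA", "amino_keto"), "MMMM")
  # lower case and RNA normalize before mapping
  expect_equal(transform_sequence("aucg", "purine_pyrimidine"), "RYYR")
  # ambiguity codes become the break sentinel
  expect_equal(substring(transform_sequence("ACNGT", "weak_strong"), 3, 3),
               "x")
  # agreement with an independent chartr() mapping on random sequences
  for (i in 1:10) {
    s <- random_dna(60, seed = 100 + i)
    for (nm in names(pcmer_schemes()))
      expect_equal(transform_sequence(s, nm), oracle_transform(s, nm))
  }
})

test_that("grouping schemes partition the alphabet two-and-two", {
  schemes <- pcmer_schemes()
  expect_equal(names(schemes),
               c("purine_pyrimidine", "amino_keto", "weak_strong"))
  for (s in schemes) {
    expect_equal(sum(s$nucleotide_map == "low"), 2L)
    expect_equal(sum(s$nucleotide_map == "high"), 2L)
  }
  expect_equal(schemes$purine_pyrimidine$nucleotide_map[c("A", "G")],
               c(A = "low", G = "low"))
  expect_equal(schemes$amino_keto$nucleotide_map[c("G", "T")],
               c(G = "high", T = "high"))
  expect_equal(schemes$weak_strong$nucleotide_map[c("C", "G")],
               c(C = "low", G = "low"))
})

test_that("cgr_step implements the halving recurrence on [1, 2^k]", {
  expect_equal(cgr_step(2, 0, k = 2), 1)
  expect_equal(cgr_step(1, 4, k = 2), 3)
  for (k in 1:6)  # absorbing corners
    expect_equal(cgr_step(2^k, 2^k, k), 2^k)
  expect_equal(cgr_step(1, 0, k = 3), 1)
  # direct arithmetic oracle on every (index, endpoint) pair at small k
  for (k in 1:4) {
    for (ind in seq_len(2^k)) {
      for (ep in c(0, 2^k)) {
        got <- cgr_step(ind, ep, k)
        expect_equal(got, ceiling((ind + ep) / 2))
        expect_gte(got, 1)
        expect_lte(got, 2^k)
      }
    }
  }
  expect_error(cgr_step(1, 3, k = 2), "endpoint")
  expect_error(cgr_step(0, 0, k = 2), "index")
})

test_that("a k-step walk enumerates binary k-mers with the newest symbol as MSB", {
  # exhaustive: every binary word of length k, walked from the midpoint,
  # lands at 1 + sum_t bit_t 2^(t-1) (t = 1 oldest .. k newest)
  for (k in 1:5) {
    seen <- integer(0)
    for (word in 0:(2^k - 1)) {
      bits <- bitwAnd(word %/% 2^(0:(k - 1)), 1)  # bits[t], t = 1 oldest
      ind <- 2^k / 2
      for (t in seq_len(k)) ind <- cgr_step(ind, bits[t] * 2^k, k)
      expect_equal(ind, 1 + sum(bits * 2^(0:(k - 1))))
      seen <- c(seen, ind)
    }
    expect_setequal(seen, seq_len(2^k))  # bijection
  }
})

test_that("encode_pcmer reproduces hand-traced profiles", {
  p <- encode_pcmer("AC", k = 2)
  expect_equal(p$counts$purine_pyrimidine, c(1L, 0L, 1L, 0L))
  expect_equal(p$counts$amino_keto, c(2L, 0L, 0L, 0L))
  expect_equal(p$counts$weak_strong, c(0L, 1L, 1L, 0L))
  expect_equal(p$positions_counted, 2L)

  p1 <- encode_pcmer("AAAA", k = 1)
  expect_equal(p1$counts$purine_pyrimidine, c(4L, 0L))
  expect_equal(p1$counts$amino_keto, c(4L, 0L))
  expect_equal(p1$counts$weak_strong, c(0L, 4L))
})

test_that("the demonstration sequence ATCGTA matches per-scheme binary 2-mer counts", {
  p <- encode_pcmer("ATCGTA", k = 2, mode = "kmer_only")
  for (nm in names(pcmer_schemes())) {
    trans <- oracle_transform("ATCGTA", nm)
    expect_identical(p$counts[[nm]],
                     brute_force_binary_kmer_counts(trans, 2))
  }
  expect_equal(p$positions_counted, 5L)  # 6 - 2 + 1 windows
})

test_that("brute-force binary counter matches naive window tables", {
  b <- brute_force_binary_kmer_counts("RY", 2)
  expect_equal(b, c(0L, 0L, 1L, 0L))  # (prev=R, last=Y) is cell 3
  expect_equal(brute_force_binary_kmer_counts("RRRR", 2)[1], 3L)
  expect_equal(sum(brute_force_binary_kmer_counts("RYRYYR", 3)), 6 - 3 + 1)
  expect_equal(brute_force_binary_kmer_counts("RY", 5), integer(2^5))
  # against an alphabet-agnostic substring table
  set.seed(41)
  for (i in 1:10) {
    s <- paste(sample(c("M", "K"), 40, replace = TRUE), collapse = "")
    for (k in c(1, 2, 4)) {
      counts <- brute_force_binary_kmer_counts(s, k)
      tab <- oracle_kmer_table(s, k)
      expect_equal(sum(counts), sum(tab))
      for (km in names(tab)) {
        bits <- strsplit(km, "")[[1]] == "K"
        expect_equal(counts[1 + sum(bits * 2^(seq_len(k) - 1))],
                     unname(tab[km]))
      }
    }
  }
})

test_that("walk-based encoding equals brute-force counts on random sequences", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_dna(sample(50:300, 1))
    for (k in sample(1:8, 3)) {
      p <- encode_pcmer(s, k, mode = "kmer_only")
      for (nm in names(pcmer_schemes())) {
        expect_identical(p$counts[[nm]], brute_force_binary_kmer_counts(
          transform_sequence(s, nm), k))
      }
    }
  }
})

test_that("profile counts are conserved and the feature-size law holds", {
  set.seed(8)
  for (i in 1:10) {
    len <- sample(30:200, 1)
    s <- random_dna(len)
    k <- sample(1:6, 1)
    pa <- encode_pcmer(s, k, "all_positions")
    pk <- encode_pcmer(s, k, "kmer_only")
    for (nm in names(pcmer_schemes())) {
      expect_equal(sum(pa$counts[[nm]]), len)
      expect_equal(sum(pk$counts[[nm]]), max(len - k + 1, 0))
      expect_true(all(pa$counts[[nm]] >= 0))
    }
    expect_length(feature_vector(pa), 3 * 2^k)
  }
  expect_equal(pcmer_feature_length(12), 12288)
  expect_equal(fcgr_feature_length(7), 16384)
  expect_equal(fcgr_feature_length(12), 16777216)
})

test_that("ambiguity codes reset the walk like a sequence break", {
  # counts on ACGNNTGCA (kmer_only) = counts on the clean runs ACG and TGCA
  s <- "ACGNNTGCA"
  for (k in 1:3) {
    p <- encode_pcmer(s, k, "kmer_only")
    p1 <- encode_pcmer("ACG", k, "kmer_only")
    p2 <- encode_pcmer("TGCA", k, "kmer_only")
    for (nm in names(pcmer_schemes()))
      expect_identical(p$counts[[nm]], p1$counts[[nm]] + p2$counts[[nm]])
  }
  # all_positions mode: every valid position is counted, breaks excluded
  pa <- encode_pcmer(s, 2, "all_positions")
  expect_equal(pa$positions_counted, 7L)
})

test_that("encoding is deterministic and validates its inputs", {
  s <- random_dna(100, seed = 77)
  expect_identical(encode_pcmer(s, 5), encode_pcmer(s, 5))
  expect_error(encode_pcmer(s, 0), "positive integer")
  expect_error(encode_pcmer(s, 2.5), "positive integer")
  expect_error(encode_pcmer(s, 25), "at most 24")
  expect_error(encode_pcmer("", 3), "non-empty")
})

test_that("frequency normalization divides by counted positions", {
  s <- random_dna(120, seed = 3)
  p <- normalize_profile(encode_pcmer(s, 4))
  expect_true(p$normalized)
  for (nm in names(pcmer_schemes()))
    expect_equal(sum(p$counts[[nm]]), 1)
  # idempotent
  expect_identical(normalize_profile(p), p)
})
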