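# Frozen MurmurHash3 x64_128 (low 64 bits, seed 42) reference values,
# computed with an independent implementation of the published algorithm.
MURMUR_REF <- c(
  "ACGT" = "240daf601d2a7447",
  "AAAA" = "f77b39a1b9dd6ec3",
  "TTTT" = "82d97eb37907d91e",
  "ACGTACGTACGTACGTACGTA" = "b4e9c495b633d387",
  "MFLIVPA" = "3325914b4738aed2",
  "A" = "e874824f39c26128",
  "KKKKKKK" = "7da38b3e3592ab1d",
  "GATTACAGATTACAGATTACA" = "c7a819a7ba2c5e27"
)

test_that("k-mer hashing matches the frozen MurmurHash3 reference values", {
  # protein mode hashes the string as-is (no canonicalization)
  for (s in names(MURMUR_REF)) {
    expect_identical(unname(hash_kmer(s, "protein")), unname(MURMUR_REF[s]))
  }
})

test_that("DNA hashing canonicalizes to the lexicographically smaller strand", {
  expect_identical(hash_kmer("AAAA", "dna"), hash_kmer("TTTT", "dna"))
  expect_identical(unname(hash_kmer("AAAA", "dna")),
                   unname(MURMUR_REF["AAAA"]))  # AAAA < TTTT
  # GATTACA... revcomp is TGTAATC... > G..., so hashed as-is
  expect_identical(unname(hash_kmer("GATTACAGATTACAGATTACA", "dna")),
                   unname(MURMUR_REF["GATTACAGATTACAGATTACA"]))
  expect_identical(hash_kmer("ACGT", "dna"), hash_kmer("ACGT", "dna"))
})

test_that("hash values are uniform: retention at scaled=1000 is binomial", {
  set.seed(42)
  s <- paste0(sample(c("A", "C", "G", "T"), 1e5 + 20, replace = TRUE),
              collapse = "")
  sk_all <- sketch_sequence(s, k = 21, scaled = 1, molecule = "dna")
  sk_sub <- sketch_sequence(s, k = 21, scaled = 1000, molecule = "dna")
  n <- length(sk_all$hashes)
  frac <- length(sk_sub$hashes) / n
  se <- sqrt((1 / 1000) * (1 - 1 / 1000) / n)
  expect_lt(abs(frac - 1 / 1000), 3 * se)
})

test_that("sketching skips invalid-character k-mers and flags short input", {
  sk <- sketch_sequence("ACGTNACGT", k = 4, scaled = 1, molecule = "dna")
  # valid 4-mers: ACGT (twice, canonical-identical): positions 1 and 6 only
  expect_identical(sk$n_kmers, 2)
  expect_length(sk$hashes, 1L)
  expect_warning(
    short <- sketch_sequence("ACG", k = 4, scaled = 1, molecule = "dna"),
    "shorter than k"
  )
  expect_length(short$hashes, 0L)

  pro <- sketch_sequence("MF*LIVPA", k = 3, scaled = 1, molecule = "protein")
  # k-mers crossing '*' are skipped: only LIV, IVP, VPA survive
  expect_identical(pro$n_kmers, 3)
})

test_that("scaled=1 containment equals brute-force k-mer set containment", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_cds(60, seed = 100 + i)
    b <- mutate_selected(a, 0.05, "uniform", seed = 200 + i)
    ska <- sketch_sequence(a, k = 9, scaled = 1, molecule = "dna", name = "a")
    skb <- sketch_sequence(b, k = 9, scaled = 1, molecule = "dna", name = "b")
    got <- containment(ska, skb)$containment
    expect_equal(got, oracle_containment(a, b, 9), tolerance = 1e-12)
  }
})

test_that("no stored hash reaches the retention threshold 2^64/scaled", {
  set.seed(8)
  s <- paste0(sample(c("A", "C", "G", "T"), 5e4, replace = TRUE),
              collapse = "")
  for (scaled in c(10, 100)) {
    sk <- sketch_sequence(s, k = 15, scaled = scaled, molecule = "dna")
    # hex strings sort lexicographically in numeric order
    thr <- format_hex_threshold(scaled)
    expect_true(all(sk$hashes < thr))
  }
})

test_that("containment is 1 for self, 0 for disjoint, and monotone in the target", {
  a <- random_cds(80, seed = 31)
  ska <- sketch_sequence(a, k = 12, scaled = 1, molecule = "dna", name = "a")
  expect_equal(containment(ska, ska)$containment, 1)

  b <- random_cds(80, seed = 32)
  skb <- sketch_sequence(b, k = 12, scaled = 1, molecule = "dna", name = "b")
  inter <- length(intersect(ska$hashes, skb$hashes))
  if (inter == 0) {
    expect_equal(containment(ska, skb)$containment, 0)
  }

  # growing the target never decreases containment of a fixed query
  c1 <- containment(ska, skb)$containment
  skb2 <- sketch_sequence(paste0(b, a), k = 12, scaled = 1,
                          molecule = "dna", name = "b2")
  c2 <- containment(ska, skb2)$containment
  expect_gte(c2, c1)
})

test_that("engineered quarter-overlap gives containment 0.25 at scaled=1", {
  # query = 4 disjoint blocks, target contains exactly one of them;
  # k-mers crossing block boundaries are broken by an N spacer
  set.seed(55)
  blocks <- replicate(4, paste0(
    sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""))
  q <- paste(blocks, collapse = "N")
  t <- blocks[1]
  k <- 15
  skq <- sketch_sequence(q, k = k, scaled = 1, molecule = "dna", name = "q")
  skt <- sketch_sequence(t, k = k, scaled = 1, molecule = "dna", name = "t")
  got <- containment(skq, skt)$containment
  expect_equal(got, oracle_containment(q, t, k), tolerance = 1e-12)
  expect_equal(got, 0.25, tolerance = 0.01)
})

test_that("incompatible sketches and empty queries are rejected or flagged", {
  a <- random_cds(40, seed = 41)
  s1 <- sketch_sequence(a, k = 9, scaled = 1, molecule = "dna")
  s2 <- sketch_sequence(a, k = 12, scaled = 1, molecule = "dna")
  expect_error(containment(s1, s2), "incompatible")
  s3 <- sketch_sequence(a, k = 9, scaled = 2, molecule = "dna")
  expect_error(containment(s1, s3), "incompatible")

  suppressWarnings(empty <- sketch_sequence("AC", k = 9, scaled = 1,
                                            molecule = "dna"))
  r <- containment(empty, s1)
  expect_true(is.na(r$containment))
  expect_true(r$flag_empty_query)
})

test_that("multisearch reports ordered pairs above threshold, no self-pairs", {
  seqs <- c(a = random_cds(60, seed = 61),
            b = random_cds(60, seed = 62),
            c = random_cds(60, seed = 63))
  # engineer b to share half of a
  seqs[["b"]] <- paste0(substr(seqs[["a"]], 1, 90), substr(seqs[["b"]], 1, 90))
  sks <- lapply(names(seqs), function(n) {
    sketch_sequence(seqs[[n]], k = 9, scaled = 1, molecule = "dna", name = n)
  })
  all_pairs <- multisearch(sks, sks, threshold = 0)
  expect_identical(nrow(all_pairs), 6L)  # 3*3 - 3 self
  expect_false(any(all_pairs$query == all_pairs$target))

  hi <- multisearch(sks, sks, threshold = 0.4)
  expect_true(all(hi$containment >= 0.4))
  expect_true(any(hi$query == "b" & hi$target == "a"))

  none <- multisearch(sks, sks, threshold = 1.01)
  expect_identical(nrow(none), 0L)

  withself <- multisearch(sks, sks, threshold = 0, include_self = TRUE)
  expect_identical(nrow(withself), 9L)
})

test_that("sketch JSON round-trips byte-identically", {
  a <- random_cds(50, seed = 71)
  sk <- list(
    sketch_sequence(a, k = 9, scaled = 1, molecule = "dna", name = "x"),
    sketch_sequence(translate_cds(a), k = 3, scaled = 1,
                    molecule = "protein", name = "y")
  )
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_sketches(sk, f1)
  back <- read_sketches(f1)
  expect_identical(back[[1]]$hashes, sk[[1]]$hashes)
  expect_identical(back[[2]]$k, 3L)
  expect_identical(back[[2]]$molecule, "protein")
  write_sketches(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round-tripped sketches still compare
  expect_equal(containment(back[[1]], back[[1]])$containment, 1)
})

test_that("debiased containment at scaled>1 is unbiased for the true value", {
  # fixed half-overlap construction, resampled sequences per replicate
  set.seed(99)
  n_rep <- 60
  est <- exact <- numeric(n_rep)
  for (i in 1:n_rep) {
    target <- paste0(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                     collapse = "")
    novel <- paste0(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                    collapse = "")
    query <- paste0(substr(target, 1, 10000), "N", novel)
    skq1 <- sketch_sequence(query, k = 21, scaled = 1, molecule = "dna")
    skt1 <- sketch_sequence(target, k = 21, scaled = 1, molecule = "dna")
    exact[i] <- containment(skq1, skt1)$containment
    skq <- sketch_sequence(query, k = 21, scaled = 50, molecule = "dna")
    skt <- sketch_sequence(target, k = 21, scaled = 50, molecule = "dna")
    est[i] <- containment(skq, skt)$containment
  }
  expect_lt(abs(mean(est) - mean(exact)) / mean(exact), 0.02)
})
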