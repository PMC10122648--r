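test_that("reverse complement is correct, an involution, and validates input", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("TGACGTCA"), "TGACGTCA")
  expect_identical(reverse_complement("TGACTCA"), "TGAGTCA")
  expect_error(reverse_complement("ACXT"), "position 3")
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(sample(2:40, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("palindromy is detected from self-reverse-complementarity", {
  expect_true(is_palindromic("TGACGTCA"))
  expect_false(is_palindromic("TGACTCA"))
  expect_true(is_palindromic("AT"))
  set.seed(12)
  for (i in 1:20) {
    s <- random_dna(sample(2:20, 1))
    expect_identical(is_palindromic(s), s == reverse_complement(s))
  }
})

test_that("orientation vector enumeration is complete, ordered and duplicate-free", {
  expect_identical(enumerate_orientation_vectors(1), list("NT", "T"))
  expect_length(enumerate_orientation_vectors(2), 4L)
  expect_length(enumerate_orientation_vectors(3), 8L)
  expect_error(enumerate_orientation_vectors(0), "positive")
  for (n in 1:5) {
    v <- enumerate_orientation_vectors(n)
    keys <- vapply(v, paste, character(1), collapse = "")
    expect_length(unique(keys), 2L^n)
    expect_identical(keys, sort(keys))  # lexicographic, NT < T
  }
})

test_that("permutation enumeration matches n!/(n-k)! and excludes repeats", {
  m18 <- grammar_motifs()
  expect_length(enumerate_permutations(m18, 2), 306L)
  expect_length(enumerate_permutations(m18, 3), 4896L)
  expect_length(enumerate_permutations(c("a", "b", "c"), 2), 6L)
  expect_error(enumerate_permutations(c("a", "a"), 1), "duplicate")
  for (n in 2:6) for (k in 1:n) {
    perms <- enumerate_permutations(letters[1:n], k)
    expect_length(perms, factorial(n) / factorial(n - k))
    expect_true(all(vapply(perms, function(p) !anyDuplicated(p), logical(1))))
    keys <- vapply(perms, paste, character(1), collapse = "|")
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("modal pair distance follows the brute-force histogram with ties to the smaller", {
  expect_identical(as.integer(most_frequent_pair_distance(
    c(0, 100, 200), c(7, 107, 207), max_gap = 50)), 7L)
  expect_warning(
    d <- most_frequent_pair_distance(0, 500, max_gap = 100), "fallback")
  expect_identical(as.integer(d), 10L)
  expect_true(attr(d, "fallback"))
  a <- c(0, 10, 20, 30)
  expect_identical(as.integer(most_frequent_pair_distance(a, a, max_gap = 15)), 10L)
  # brute-force oracle on random tracks
  set.seed(21)
  for (i in 1:10) {
    pa <- sort(sample(0:300, 15)); pb <- sort(sample(0:300, 15))
    d_all <- abs(outer(pb, pa, "-"))
    d_all <- d_all[d_all > 0 & d_all <= 60]
    if (length(d_all) == 0) next
    tab <- table(d_all)
    expected <- min(as.integer(names(tab)[tab == max(tab)]))
    expect_identical(as.integer(most_frequent_pair_distance(pa, pb, max_gap = 60)),
                     expected)
  }
})

test_that("tile construction substitutes placement windows and rejects collisions", {
  m <- motif_roster("X", "CGT")
  bg <- toy_background(10L)
  t1 <- build_tile(bg[1, ], placements("X", 3L, "NT"), m)
  expect_identical(t1$sequence, "AAACGTAAAA")
  t2 <- build_tile(bg[1, ], placements("X", 3L, "T"), m)
  expect_identical(t2$sequence, "AAAACGAAAA")  # revcomp("CGT") == "ACG"
  expect_error(build_tile(bg[1, ], placements(c("X", "X"), c(3L, 4L), c("NT", "NT")), m),
               "overlap")
  expect_error(build_tile(bg[1, ], placements("X", 9L, "NT"), m), "bounds")
})

test_that("generated libraries have the closed-form tile counts and preserve length", {
  m3 <- toy_motifs()
  bg <- background_set("b1", markov_from_seed(200L, 77L))
  pair_cfg <- design_config(spacings = "5", categories = "pair")
  d <- generate_library(m3, bg, pair_cfg)
  expect_identical(nrow(d), 6L * 4L)  # 6 ordered pairs x 4 orientation vectors
  homo_cfg <- design_config(copies = c(1L, 2L), spacings = "5",
                            categories = "homotypic")
  d2 <- generate_library(m3[1, ], bg, homo_cfg)
  expect_identical(nrow(d2), 6L)  # 2^1 + 2^2
  expect_true(all(nchar(d$sequence) == 200L))
  expect_true(all(nchar(d2$sequence) == 200L))
})

test_that("placements are recoverable from tile sequences by exact matching", {
  m3 <- toy_motifs()
  bg <- background_set("b1", markov_from_seed(200L, 78L))
  d <- generate_library(m3, bg, design_config(copies = c(1L, 3L), spacings = "10",
                                              categories = c("homotypic", "pair")))
  km <- stats::setNames(m3$kmer, m3$name)
  for (i in seq_len(nrow(d))) {
    pl <- tile_placements(d[i, ])
    for (j in seq_len(nrow(pl))) {
      ins <- km[[pl$motif_name[j]]]
      if (pl$orientation[j] == "T") ins <- reverse_complement(ins)
      expect_identical(substr(d$sequence[i], pl$offset[j] + 1L,
                              pl$offset[j] + nchar(ins)), ins)
    }
  }
})

test_that("library generation is deterministic", {
  m3 <- toy_motifs()
  bg <- example_backgrounds()
  cfg <- design_config(copies = c(1L, 2L, 4L), categories = c("homotypic", "pair"))
  d1 <- generate_library(m3, bg, cfg)
  d2 <- generate_library(m3, bg, cfg)
  expect_identical(d1, d2)
  f1 <- tempfile(); f2 <- tempfile()
  write_design(d1, f1); write_design(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # TSV round trip preserves content
  d3 <- read_design(f1)
  expect_identical(d3$sequence, d1$sequence)
  expect_identical(d3$tile_id, d1$tile_id)
})

test_that("oversized configurations are skipped with a record, not an error", {
  m <- motif_roster("LONG", strrep("ACGT", 15))  # 60-bp site
  bg <- toy_background(100L)
  d <- generate_library(m, bg, design_config(copies = c(1L, 2L), spacings = "5",
                                             categories = "homotypic"))
  expect_true(all(lengths(strsplit(d$motif_names, ",")) == 1L))
  expect_true(length(attr(d, "skipped")) > 0L)
})

test_that("half-open region arithmetic gives 200 bp for the printed background interval", {
  r <- parse_region("chr9:83,712,583-83,712,783")
  expect_identical(r$width, 200)
  expect_identical(r$chrom, "chr9")
})
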