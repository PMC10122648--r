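test_that("PFM to PWM log-odds follows the formula", {
  uni <- matrix(25, 4, 6)
  pwm <- pfm_to_pwm(uni)
  expect_true(all(abs(pwm$matrix) < 1e-12))
  # background equal to column frequencies gives near-zero scores
  pfm <- matrix(c(40, 30, 20, 10), 4, 3)
  pwm2 <- pfm_to_pwm(pfm, background = c(0.4, 0.3, 0.2, 0.1), pseudocount = 0)
  expect_true(all(abs(pwm2$matrix) < 1e-12))
  # single-base column under uniform background approaches log2(4)
  one <- matrix(c(100, 0, 0, 0), 4, 1)
  pwm3 <- pfm_to_pwm(one, pseudocount = 0.01)
  expect_equal(unname(pwm3$matrix["A", 1]), 2, tolerance = 0.01)
  expect_error(pfm_to_pwm(matrix(0, 4, 2), pseudocount = 0), "pseudocount")
  expect_error(pfm_to_pwm(matrix(1, 3, 2)), "4 rows")
})

test_that("score threshold matches enumeration on small alphabets", {
  # width-1 uniform background, p = 0.25: only the top base is rarer-or-equal
  pwm <- pfm_to_pwm(matrix(c(70, 20, 8, 2), 4, 1), pseudocount = 0.1)
  thr <- score_threshold(pwm, p_value = 0.25)
  expect_equal(as.numeric(thr$threshold), max(pwm$matrix), tolerance = 2e-3)
  expect_lte(attr(thr$threshold, "attained_p"), 0.25)
  # a permissive p admits (nearly) every score: the threshold is the
  # smallest distribution value whose tail is within p
  pwm2 <- pfm_to_pwm(random_pfm(2))
  thr2 <- score_threshold(pwm2, p_value = 0.999)
  dist2 <- tfbsgrammar:::pwm_score_distribution(pwm2)
  tails <- rev(cumsum(rev(dist2$probs)))
  expect_equal(as.numeric(thr2$threshold), min(dist2$values[tails <= 0.999]))
})

test_that("threshold DP tail equals brute-force enumeration for widths up to 8", {
  set.seed(201)
  for (w in c(3L, 5L, 8L)) {
    pwm <- pfm_to_pwm(random_pfm(w), background = c(0.3, 0.2, 0.2, 0.3))
    dp <- tfbsgrammar:::pwm_score_distribution(pwm)
    bf <- brute_force_tail(pwm)
    for (p in c(0.2, 0.05, 1e-3)) {
      thr <- score_threshold(pwm, p_value = p)$threshold
      dp_tail <- sum(dp$probs[dp$values >= thr])
      bf_tail <- sum(bf$probs[bf$values >= as.numeric(thr) - 1e-9])
      expect_equal(dp_tail, bf_tail, tolerance = 1e-12)
      if (!attr(thr, "unattainable")) expect_lte(bf_tail, p)
    }
  }
})

test_that("scanning finds planted sites on both strands with forward coordinates", {
  consensus <- "TGACTCA"
  pfm <- sapply(strsplit(consensus, "")[[1]], function(b) {
    col <- rep(1, 4); col[match(b, c("A", "C", "G", "T"))] <- 97; col
  })
  pwm <- score_threshold(pfm_to_pwm(pfm, name = "AP1"), p_value = 1e-3)
  bgseq <- markov_from_seed(200L, 301L)
  fwd <- paste0(substr(bgseq, 1, 50), consensus, substr(bgseq, 58, 200))
  hits <- scan_sequence(fwd, pwm, seqname = "s1")
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start == 50 & plus$end == 57))
  rev <- paste0(substr(bgseq, 1, 50), reverse_complement(consensus),
                substr(bgseq, 58, 200))
  hits2 <- scan_sequence(rev, pwm, seqname = "s1")
  minus <- hits2[hits2$strand == "-", ]
  expect_true(any(minus$start == 50 & minus$end == 57))
  # too-short input and N windows
  expect_identical(nrow(scan_sequence("ACG", pwm)), 0L)
  expect_identical(nrow(scan_sequence(paste0(substr(consensus, 1, 3), "N",
                                             substr(consensus, 5, 7)),
                                      pwm)), 0L)
})

test_that("scanner agrees with brute-force window scoring", {
  set.seed(202)
  pwm <- score_threshold(pfm_to_pwm(random_pfm(6), name = "toy"), p_value = 0.02)
  seq <- random_dna(800)
  hits <- scan_sequence(seq, pwm)
  chars <- strsplit(seq, "")[[1]]
  w <- ncol(pwm$matrix)
  brute <- list()
  for (i in seq_len(length(chars) - w + 1L)) {
    win <- paste(chars[i:(i + w - 1L)], collapse = "")
    sc_f <- sum(pwm$matrix[cbind(match(strsplit(win, "")[[1]], c("A","C","G","T")),
                                 seq_len(w))])
    rc <- reverse_complement(win)
    sc_r <- sum(pwm$matrix[cbind(match(strsplit(rc, "")[[1]], c("A","C","G","T")),
                                 seq_len(w))])
    if (sc_f >= pwm$threshold)
      brute[[length(brute) + 1L]] <- data.frame(start = i - 1L, strand = "+",
                                                score = sc_f)
    if (sc_r >= pwm$threshold)
      brute[[length(brute) + 1L]] <- data.frame(start = i - 1L, strand = "-",
                                                score = sc_r)
  }
  brute <- do.call(rbind, brute)
  expect_identical(nrow(hits), nrow(brute))
  ord_h <- order(hits$start, hits$strand); ord_b <- order(brute$start, brute$strand)
  expect_identical(hits$start[ord_h], brute$start[ord_b])
  expect_identical(hits$strand[ord_h], brute$strand[ord_b])
  expect_equal(hits$score[ord_h], brute$score[ord_b])
})

test_that("MEME parsing recovers motif matrices and background frequencies", {
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "Background letter frequencies",
            "A 0.3 C 0.2 G 0.2 T 0.3", "",
            "MOTIF MA0000.1 TOY",
            "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
            " 0.7 0.1 0.1 0.1",
            " 0.1 0.7 0.1 0.1",
            " 0.1 0.1 0.1 0.7")
  f <- tempfile(fileext = ".meme")
  writeLines(meme, f)
  pfms <- read_meme(f)
  expect_identical(names(pfms), "TOY")
  expect_identical(dim(pfms$TOY), c(4L, 3L))
  expect_equal(unname(pfms$TOY["A", 1]), 0.7)
  expect_equal(attr(pfms, "background"), c(0.3, 0.2, 0.2, 0.3))
})

test_that("promoter extraction is strand-aware, TSS-anchored and edge-truncated", {
  chr <- markov_from_seed(12000L, 302L)
  genome <- c(chrT = chr)
  gtf <- c(
    "chrT\ttest\tgene\t10001\t10500\t.\t+\t.\tgene_id \"gplus\";",
    "chrT\ttest\tgene\t2001\t3000\t.\t-\t.\tgene_id \"gminus\";",
    "chrT\ttest\tgene\t101\t200\t.\t+\t.\tgene_id \"gedge\";")
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  pr <- extract_promoters(f, genome, upstream = 2500L)
  # '+' gene starting at 1-based 10001: promoter covers 0-based [7500, 10000)
  expect_identical(pr$sequences[["gplus"]], substr(chr, 7501, 10000))
  info <- pr$info
  expect_identical(info$start[info$gene_id == "gplus"], 7500L)
  expect_identical(info$end[info$gene_id == "gplus"], 10000L)
  # '-' gene ending at 3000: downstream flank revcomped, reads toward the TSS
  expect_identical(pr$sequences[["gminus"]],
                   reverse_complement(substr(chr, 3001, 5500)))
  # gene near the contig edge is truncated and flagged
  expect_identical(nchar(pr$sequences[["gedge"]]), 100L)
  expect_true(info$truncated[info$gene_id == "gedge"])
  expect_identical(unname(pr$tss["gplus"]), 2500L)
})

test_that("consecutive homotypic asymmetry gives exact binomial inference", {
  occ <- data.frame(chrom = "p1", start = seq(0, 180, by = 20), end = seq(0, 180, by = 20) + 7,
                    name = "M", score = 1, strand = "+")
  res <- consecutive_homotypic_asymmetry(occ, max_gap = 100)
  expect_equal(res$S, 1.0)
  expect_identical(res$n_same, 9L)  # 10 occurrences -> 9 adjacent pairs
  expect_equal(res$p_raw, 2 * 0.5^9)
  # balanced strands: S = 0.5, p = 1
  occ2 <- occ
  occ2$strand <- rep(c("+", "+", "-", "-"), length.out = 10)
  res2 <- consecutive_homotypic_asymmetry(occ2, max_gap = 100)
  expect_lt(abs(res2$S - 0.5), 0.2)
  # far-apart occurrences are not consecutive
  occ3 <- occ
  occ3$start <- occ3$start * 100L; occ3$end <- occ3$start + 7L
  expect_null(consecutive_homotypic_asymmetry(occ3, max_gap = 100))
})

test_that("asymmetry S is invariant under reverse-complementing the input sequences", {
  set.seed(203)
  occ <- data.frame(chrom = rep(sprintf("p%d", 1:10), each = 6),
                    start = rep(seq(0, 150, by = 30), 10) +
                      sample(0:5, 60, replace = TRUE),
                    name = "M", score = 1,
                    strand = sample(c("+", "-"), 60, replace = TRUE))
  occ$end <- occ$start + 8L
  L <- 400L
  flipped <- occ
  flipped$start <- L - occ$end
  flipped$end <- L - occ$start
  flipped$strand <- ifelse(occ$strand == "+", "-", "+")
  r1 <- consecutive_homotypic_asymmetry(occ, max_gap = 100)
  r2 <- consecutive_homotypic_asymmetry(flipped, max_gap = 100)
  expect_equal(r1$S, r2$S)
  expect_equal(r1$p_raw, r2$p_raw)
})

test_that("pair order preference applies the exact binomial to proximal counts", {
  # A always TSS-proximal across 8 co-occurrences
  tss <- stats::setNames(rep(500, 8), sprintf("p%d", 1:8))
  occ_a <- data.frame(chrom = names(tss), start = 450, end = 457,
                      name = "A", score = 1, strand = "+")
  occ_b <- data.frame(chrom = names(tss), start = 400, end = 407,
                      name = "B", score = 1, strand = "+")
  res <- pair_order_preference(occ_a, occ_b, tss, window = 100)
  expect_equal(res$fraction, 1)
  expect_equal(res$p_raw, 2 * 0.5^8)
  # perfectly alternating proximity: p = 1
  occ_a2 <- occ_a; occ_a2$start <- rep(c(450, 350), 4); occ_a2$end <- occ_a2$start + 7
  occ_b2 <- occ_b; occ_b2$start <- rep(c(400, 420), 4); occ_b2$end <- occ_b2$start + 7
  res2 <- pair_order_preference(occ_a2, occ_b2, tss, window = 100)
  expect_equal(res2$fraction, 0.5)
  expect_equal(res2$p_raw, 1)
  expect_null(pair_order_preference(occ_a[0, ], occ_b, tss))
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  expect_identical(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  set.seed(204)
  for (i in 1:30) {
    s <- random_dna(sample(10:120, 1))
    sh <- dinucleotide_shuffle(s, seed = i)
    expect_identical(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, nchar(sh), nchar(sh)), substr(s, nchar(s), nchar(s)))
  }
  # deterministic per seed
  s <- random_dna(60)
  expect_identical(dinucleotide_shuffle(s, seed = 99), dinucleotide_shuffle(s, seed = 99))
})

test_that("shuffle outputs lie exactly in the brute-force valid set for short strings", {
  s <- "ACGCA"
  perms <- unique(apply(expand.grid(rep(list(c("A", "C", "G")), 3)), 1, function(mid)
    paste0("A", paste(mid, collapse = ""), "A")))
  # valid arrangements share s's dinucleotide multiset
  ref <- dinucleotide_counts(s)
  valid <- perms[vapply(perms, function(p)
    identical(dinucleotide_counts(p), ref), logical(1))]
  seen <- unique(vapply(1:40, function(i) dinucleotide_shuffle(s, seed = i),
                        character(1)))
  expect_true(all(seen %in% valid))
})

test_that("pair enrichment fractions are conditional on close pairs", {
  occ <- data.frame(chrom = "c1",
                    start = c(100, 150, 5000, 5050, 9000),
                    end = c(107, 157, 5007, 5057, 9007),
                    name = c("A", "B", "A", "B", "A"),
                    score = 1, strand = "+")
  elements <- data.frame(chrom = "c1",
                         start = c(0, 4900), end = c(300, 5200),
                         class = c("PLS", "dELS"))
  res <- ccre_pair_enrichment(occ, elements, pair_window = 100)
  expect_identical(res$n_pairs, 2L)  # the 9000 occurrence pairs with nothing
  expect_equal(res$PLS, 0.5)
  expect_equal(res$dELS, 0.5)
  expect_error(ccre_pair_enrichment(occ, elements[0, ]), "empty")
})

test_that("pair distance histogram counts start-to-start spacings in range", {
  a <- c(0, 100, 200, 300)
  b <- a + 12
  h <- pair_distance_histogram(a, b, max_gap = 50)
  expect_identical(h$distance[which.max(h$count)], 12L)
  expect_identical(max(h$count), 4L)
  empty <- pair_distance_histogram(numeric(0), b, max_gap = 50)
  expect_identical(nrow(empty), 0L)
})
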