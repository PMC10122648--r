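#' Validate a DNA string
#'
#' Checks that `seq` is a single uppercase string over the alphabet ACGT
#' (optionally allowing N). The first offending position is reported so that
#' malformed motif tables fail loudly.
#'
#' @param seq character scalar.
#' @param allow_n allow the ambiguity code N.
#' @return `seq`, invisibly, if valid; otherwise an error.
#' @keywords internal
check_dna <- function(seq, allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("expected a single DNA string")
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d", chars[bad[1L]], bad[1L]))
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over ACGT (N allowed and mapped to N).
#' @return The Watson-Crick reverse complement. Applying the function twice
#'   returns the input (involution); palindromic sites such as the CREB1
#'   motif TGACGTCA are fixed points.
#' @examples
#' reverse_complement("TGACTCA")   # AP1 -> "TGAGTCA"
#' reverse_complement("TGACGTCA")  # palindrome, unchanged
#' @export
reverse_complement <- function(seq) {
  check_dna(seq, allow_n = TRUE)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Is a kmer palindromic?
#'
#' A site is (reverse-complement) palindromic when it equals its own reverse
#' complement, in which case strand orientation is unobservable and the motif
#' serves as a negative control in orientation analyses.
#'
#' @param kmer DNA string.
#' @return logical scalar.
#' @examples
#' is_palindromic("TGACGTCA")  # TRUE  (CREB1)
#' is_palindromic("TGACTCA")   # FALSE (AP1)
#' @export
is_palindromic <- function(kmer) {
  check_dna(kmer)
  identical(kmer, reverse_complement(kmer))
}

#' GC skew and AT skew of a kmer
#'
#' `gc_skew` is (G - C) / (G + C) and `at_skew` is (A - T) / (A + T), each
#' defined as 0 when its denominator is empty. Any palindrome has both skews
#' equal to 0.
#'
#' @param kmer DNA string.
#' @return numeric scalar in \[-1, 1\].
#' @examples
#' gc_skew("TGACTCA")  # (1 - 2) / 3
#' gc_skew("TGACGTCA") # 0
#' @export
gc_skew <- function(kmer) {
  check_dna(kmer)
  chars <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  g <- sum(chars == "G"); c_ <- sum(chars == "C")
  if (g + c_ == 0L) return(0)
  (g - c_) / (g + c_)
}

#' @rdname gc_skew
#' @export
at_skew <- function(kmer) {
  check_dna(kmer)
  chars <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  a <- sum(chars == "A"); t_ <- sum(chars == "T")
  if (a + t_ == 0L) return(0)
  (a - t_) / (a + t_)
}

#' Parse a genome-browser style region string
#'
#' Accepts "chr9:83,712,583-83,712,783" style strings and returns the contig,
#' start, end and width under 0-based half-open arithmetic (width =
#' end - start), the coordinate convention used throughout the package.
#'
#' @param region character scalar like "chr:start-end"; commas are ignored.
#' @return list with `chrom`, `start`, `end`, `width`.
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  x <- gsub(",", "", region, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1L]]
  if (length(m) != 4L) stop("cannot parse region string: ", region)
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (end < start) stop("region end precedes start")
  list(chrom = m[2L], start = start, end = end, width = end - start)
}

#' Dinucleotide counts of a sequence
#'
#' @param seq DNA string of length >= 2.
#' @return named integer vector of counts over the 16 dinucleotides.
#' @export
dinucleotide_counts <- function(seq) {
  check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  lv <- as.vector(outer(bases, bases, paste0))
  if (n < 2L) return(stats::setNames(integer(16L), lv))
  di <- paste0(chars[-n], chars[-1L])
  table(factor(di, levels = lv))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Randomizes a sequence while keeping its dinucleotide multiset exactly
#' (hence also mononucleotide counts and the first and last base), using the
#' Altschul-Erickson Euler-path construction: the sequence is a walk on the
#' 4-vertex base graph whose edges are its dinucleotides; a uniformly random
#' in-tree rooted at the final base is drawn, the remaining out-edges of each
#' vertex are permuted, and the unique Eulerian walk consistent with that
#' edge ordering is read off. Used to build composition-controlled nulls for
#' the strand-asymmetry statistics.
#'
#' @param seq DNA string of length >= 2.
#' @param seed optional integer; when supplied the shuffle is deterministic.
#' @return shuffled DNA string with identical [dinucleotide_counts()].
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) stop("sequence must have length >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  bases <- unique(chars)
  first <- chars[1L]; last <- chars[n]
  # adjacency: out-edge target lists per vertex
  out_edges <- split(chars[-1L], factor(chars[-n], levels = bases))
  repeat {
    # Draw a random in-tree rooted at `last` by loop-erased style sampling:
    # for each non-root vertex pick a "last exit" edge; accept if the chosen
    # edges form a tree into the root (every vertex reaches `last`).
    pick <- vapply(bases, function(v) {
      if (v == last) NA_character_ else sample(out_edges[[v]], 1L)
    }, character(1L))
    names(pick) <- bases
    ok <- TRUE
    for (v in bases) {
      if (v == last) next
      seen <- character(0L); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(pick[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur); cur <- pick[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # Order each vertex's out-edges uniformly, forcing the chosen last-exit
  # edge to the final slot (root vertex: fully random order).
  ordered <- lapply(bases, function(v) {
    ee <- out_edges[[v]]
    if (v == last || length(ee) == 0L) return(sample(ee, length(ee)))
    ee2 <- ee
    drop_i <- match(pick[[v]], ee2)
    ee2 <- ee2[-drop_i]
    c(sample(ee2, length(ee2)), pick[[v]])
  })
  names(ordered) <- bases
  ptr <- stats::setNames(rep(1L, length(bases)), bases)
  walk <- character(n)
  walk[1L] <- first
  cur <- first
  for (i in 2L:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    walk[i] <- nxt
    cur <- nxt
  }
  paste(walk, collapse = "")
}

#' Random DNA from a first-order Markov chain over dinucleotide frequencies
#'
#' @param length output length in bp.
#' @param dinuc_freq optional 16-long named numeric vector of dinucleotide
#'   frequencies (names like "AC"); uniform when `NULL`.
#' @return DNA string.
#' @keywords internal
markov_sequence <- function(length, dinuc_freq = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(dinuc_freq)) {
    trans <- matrix(0.25, 4, 4, dimnames = list(bases, bases))
    start_p <- rep(0.25, 4)
  } else {
    lv <- as.vector(outer(bases, bases, paste0))
    f <- dinuc_freq[lv]
    f[is.na(f)] <- 0
    m <- matrix(f, 4, 4, byrow = TRUE, dimnames = list(bases, bases))
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    trans <- m / rs
    trans[rowSums(m) == 0, ] <- 0.25
    start_p <- rowSums(m) / sum(m)
  }
  out <- character(length)
  out[1L] <- sample(bases, 1L, prob = start_p)
  for (i in seq_len(length - 1L))
    out[i + 1L] <- sample(bases, 1L, prob = trans[out[i], ])
  paste(out, collapse = "")
}
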