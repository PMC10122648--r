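#' Extract promoter sequences upstream of gene starts
#'
#' Promoters are the `upstream` bp ending at the gene's transcription start:
#' for '+' genes the interval \[start - upstream, start) and for '-' genes
#' (end, end + upstream\], reverse-complemented, so every returned sequence
#' reads 5'->3' toward the TSS, with the TSS at its right end. Intervals
#' are truncated at contig edges and flagged; genes on contigs missing from
#' the genome are skipped with a warning.
#'
#' @param gtf path to a GTF file, or a pre-imported GRanges; records with
#'   `type == "gene"` are used (all records when no type column).
#' @param genome a named character vector, `DNAStringSet`, or FASTA path.
#' @param upstream promoter length in bp (default 2500).
#' @return list: `sequences` (named character, one per gene),
#'   `info` (data.frame gene_id, chrom, strand, start, end, truncated) and
#'   `tss` (named numeric; TSS position in promoter coordinates, equal to
#'   each sequence's length).
#' @export
extract_promoters <- function(gtf, genome, upstream = 2500L) {
  if (is.character(gtf) && length(gtf) == 1L) gtf <- rtracklayer::import(gtf)
  md <- as.data.frame(gtf)
  if ("type" %in% names(md) && any(md$type == "gene"))
    md <- md[md$type == "gene", , drop = FALSE]
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  # FASTA headers may carry descriptions after whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  ids <- if ("gene_id" %in% names(md)) md$gene_id else sprintf("gene%04d", seq_len(nrow(md)))
  seqs <- character(0L); info <- list()
  for (i in seq_len(nrow(md))) {
    chrom <- as.character(md$seqnames[i])
    if (!chrom %in% names(genome)) {
      warning("contig not in genome, skipping: ", chrom)
      next
    }
    L <- nchar(genome[[chrom]])
    strand <- as.character(md$strand[i])
    if (strand == "-") {
      # md holds 1-based closed coords; downstream flank of the gene end
      s1 <- md$end[i] + 1L
      e1 <- min(md$end[i] + upstream, L)
      if (s1 > e1) next
      seq <- reverse_complement(substr(genome[[chrom]], s1, e1))
      truncated <- (e1 - s1 + 1L) < upstream
    } else {
      e1 <- md$start[i] - 1L
      s1 <- max(md$start[i] - upstream, 1L)
      if (s1 > e1) next
      seq <- substr(genome[[chrom]], s1, e1)
      truncated <- (e1 - s1 + 1L) < upstream
    }
    seqs[ids[i]] <- seq
    info[[length(info) + 1L]] <- data.frame(
      gene_id = ids[i], chrom = chrom, strand = strand,
      start = s1 - 1L, end = e1, truncated = truncated,
      stringsAsFactors = FALSE)
  }
  info <- do.call(rbind, info)
  list(sequences = seqs, info = info,
       tss = stats::setNames(nchar(seqs), names(seqs)))
}

# merge overlapping same-motif occurrences, keeping the higher score
.merge_overlaps <- function(occ) {
  occ <- occ[order(occ$chrom, occ$start, -occ$score), , drop = FALSE]
  keep <- logical(nrow(occ))
  last_end <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(occ))) {
    if (occ$chrom[i] != last_chrom || occ$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- occ$end[i]; last_chrom <- occ$chrom[i]
    }
  }
  occ[keep, , drop = FALSE]
}

#' Strand asymmetry of consecutive homotypic TFBS occurrences
#'
#' For each motif, adjacent same-sequence occurrence pairs with
#' edge-to-edge gap below `max_gap` are classified as same-strand or
#' opposite-strand. The asymmetry statistic is `S = n_same / (n_same +
#' n_opposite)` (0.5 under no orientation bias) with a two-sided exact
#' binomial test against 0.5, Bonferroni-corrected over the motifs with at
#' least one eligible pair. Overlapping same-motif occurrences are merged
#' to the higher-scoring one before pairing.
#'
#' @param occurrences BED6-style data.frame (chrom, start, end, name,
#'   score, strand).
#' @param max_gap maximum inter-motif gap in bp (default 100; 50 is the
#'   stricter preset).
#' @return data.frame, one row per motif: n_same, n_opposite, S, p_raw,
#'   p_adjusted, family_m.
#' @export
consecutive_homotypic_asymmetry <- function(occurrences, max_gap = 100L) {
  rows <- lapply(sort(unique(occurrences$name)), function(m) {
    occ <- .merge_overlaps(occurrences[occurrences$name == m, , drop = FALSE])
    occ <- occ[order(occ$chrom, occ$start), , drop = FALSE]
    if (nrow(occ) < 2L) return(NULL)
    same_chrom <- occ$chrom[-1L] == occ$chrom[-nrow(occ)]
    gap <- occ$start[-1L] - occ$end[-nrow(occ)]
    elig <- same_chrom & gap >= 0 & gap < max_gap
    if (!any(elig)) return(NULL)
    same <- occ$strand[-1L][elig] == occ$strand[-nrow(occ)][elig]
    n_same <- sum(same); n_total <- length(same)
    bt <- stats::binom.test(n_same, n_total, p = 0.5)
    data.frame(motif = m, n_same = n_same, n_opposite = n_total - n_same,
               S = n_same / n_total, p_raw = bt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, nrow(out))
  out$family_m <- nrow(out)
  rownames(out) <- NULL
  out
}

#' Order preference of a TFBS pair relative to the TSS
#'
#' For every A/B co-occurrence on the same sequence within `window` bp
#' (start-to-start), records whether the A occurrence is the TSS-proximal
#' member, and tests the proximal fraction against 0.5 with a two-sided
#' exact binomial test.
#'
#' @param occ_a,occ_b BED6-style occurrence tables for motifs A and B.
#' @param tss named numeric vector of TSS coordinates per sequence.
#' @param window co-occurrence window in bp (default 100).
#' @param m_tests Bonferroni family size (number of pairs screened).
#' @return one-row data.frame: n_a_proximal, n_total, fraction, p_raw,
#'   p_adjusted; `NULL` when there are no co-occurrences.
#' @export
pair_order_preference <- function(occ_a, occ_b, tss, window = 100L,
                                  m_tests = 1L) {
  n_prox <- 0L; n_tot <- 0L
  for (chrom in intersect(unique(occ_a$chrom), unique(occ_b$chrom))) {
    if (!chrom %in% names(tss)) next
    a <- occ_a[occ_a$chrom == chrom, , drop = FALSE]
    b <- occ_b[occ_b$chrom == chrom, , drop = FALSE]
    d <- abs(outer(a$start, b$start, "-"))
    hits <- which(d <= window, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    mid_a <- (a$start[hits[, 1L]] + a$end[hits[, 1L]]) / 2
    mid_b <- (b$start[hits[, 2L]] + b$end[hits[, 2L]]) / 2
    a_prox <- abs(mid_a - tss[[chrom]]) < abs(mid_b - tss[[chrom]])
    n_prox <- n_prox + sum(a_prox)
    n_tot <- n_tot + length(a_prox)
  }
  if (n_tot == 0L) return(NULL)
  bt <- stats::binom.test(n_prox, n_tot, p = 0.5)
  data.frame(n_a_proximal = n_prox, n_total = n_tot,
             fraction = n_prox / n_tot, p_raw = bt$p.value,
             p_adjusted = bonferroni_adjust(bt$p.value, m_tests),
             family_m = m_tests, stringsAsFactors = FALSE)
}

#' Histogram of start-to-start distances between two occurrence tracks
#'
#' Shares the distance core of [most_frequent_pair_distance()]; used to
#' find preferred pairwise spacings (the "genomic mode" spacing rule).
#'
#' @param occ_a,occ_b BED6-style occurrence tables (or numeric start
#'   vectors, single sequence).
#' @param max_gap maximum distance tallied.
#' @return data.frame distance, count (empty when no pair in range).
#' @export
pair_distance_histogram <- function(occ_a, occ_b, max_gap = 200L) {
  if (is.numeric(occ_a))
    occ_a <- data.frame(chrom = rep("seq", length(occ_a)), start = occ_a)
  if (is.numeric(occ_b))
    occ_b <- data.frame(chrom = rep("seq", length(occ_b)), start = occ_b)
  dd <- integer(0L)
  for (chrom in intersect(unique(occ_a$chrom), unique(occ_b$chrom))) {
    a <- occ_a$start[occ_a$chrom == chrom]
    b <- occ_b$start[occ_b$chrom == chrom]
    d <- abs(outer(a, b, "-"))
    dd <- c(dd, d[d > 0 & d <= max_gap])
  }
  if (length(dd) == 0L)
    return(data.frame(distance = integer(0L), count = integer(0L)))
  tab <- table(dd)
  data.frame(distance = as.integer(names(tab)), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' TFBS pair enrichment across labeled genomic element classes
#'
#' For each motif pair, the fraction of close co-occurring pairs (within
#' `pair_window` bp start-to-start) whose spanning interval overlaps each
#' element class (e.g. the ENCODE cCRE classes PLS, pELS, dELS,
#' DNase-H3K4me3, CTCF-only, DNase-only, Low-DNase). Pairs overlapping no
#' element contribute to the denominator only, so rows sum to at most 1.
#'
#' @param occurrences BED6-style occurrence table (several motifs).
#' @param elements data.frame chrom, start, end, class.
#' @param pair_window pairing distance in bp (default 100).
#' @return data.frame: motif_a, motif_b, n_pairs, one fraction column per
#'   element class.
#' @export
ccre_pair_enrichment <- function(occurrences, elements, pair_window = 100L) {
  if (nrow(elements) == 0L) stop("empty element set")
  classes <- sort(unique(elements$class))
  motifs <- sort(unique(occurrences$name))
  if (length(motifs) < 2L) stop("need occurrences for >= 2 motifs")
  combs <- utils::combn(motifs, 2L)
  rows <- list()
  for (k in seq_len(ncol(combs))) {
    ma <- combs[1L, k]; mb <- combs[2L, k]
    a_all <- occurrences[occurrences$name == ma, , drop = FALSE]
    b_all <- occurrences[occurrences$name == mb, , drop = FALSE]
    n_pairs <- 0L
    hit_class <- stats::setNames(numeric(length(classes)), classes)
    for (chrom in intersect(unique(a_all$chrom), unique(b_all$chrom))) {
      a <- a_all[a_all$chrom == chrom, , drop = FALSE]
      b <- b_all[b_all$chrom == chrom, , drop = FALSE]
      d <- abs(outer(a$start, b$start, "-"))
      hits <- which(d <= pair_window, arr.ind = TRUE)
      if (nrow(hits) == 0L) next
      span_start <- pmin(a$start[hits[, 1L]], b$start[hits[, 2L]])
      span_end <- pmax(a$end[hits[, 1L]], b$end[hits[, 2L]])
      n_pairs <- n_pairs + nrow(hits)
      el <- elements[elements$chrom == chrom, , drop = FALSE]
      if (nrow(el) == 0L) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = span_start + 1L, end = span_end),
        IRanges::IRanges(start = el$start + 1L, end = el$end))
      if (length(ov) == 0L) next
      # count each pair once per class it touches
      touched <- unique(data.frame(q = S4Vectors::queryHits(ov),
                                   cls = el$class[S4Vectors::subjectHits(ov)]))
      tc <- table(factor(touched$cls, levels = classes))
      hit_class <- hit_class + as.numeric(tc)
    }
    if (n_pairs == 0L) next
    row <- data.frame(motif_a = ma, motif_b = mb, n_pairs = n_pairs,
                      stringsAsFactors = FALSE)
    for (cl in classes) row[[cl]] <- hit_class[[cl]] / n_pairs
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write BED6 occurrence tables
#'
#' @param occ BED6-style data.frame.
#' @param path file path.
#' @export
write_bed <- function(occ, path) {
  utils::write.table(occ[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  out <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(out)[seq_len(min(6L, ncol(out)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(out)))]
  out
}
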