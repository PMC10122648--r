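#' Planted grammar-effect model
#'
#' Encodes a tile-level log2-activity model from which synthetic MPRA counts
#' are generated: a background baseline, per-motif per-orientation effects
#' with a saturating (power-law) dose response in copy number, a linear
#' position term, ordered pair interactions and tile-level Gaussian noise.
#'
#' @param mu_bg named numeric, baseline log2 activity per background id.
#' @param beta named numeric, per-copy log2 effect keyed "motif|NT" /
#'   "motif|T".
#' @param dose_exponent named numeric per motif in (0, 1]; copies enter as
#'   `copies^dose_exponent` (saturating when < 1).
#' @param position_slope named numeric per motif: log2 effect per 100 bp of
#'   movement toward the TSS (tile positions are in \[-200, 0)).
#' @param pair_interaction named numeric keyed "A|B" for motif A occurring
#'   upstream (TSS-distal) of motif B.
#' @param noise_sd tile-by-replicate Gaussian sd on log2 activity.
#' @return list of class `effect_model`.
#' @export
effect_model <- function(mu_bg, beta, dose_exponent = NULL,
                         position_slope = NULL, pair_interaction = NULL,
                         noise_sd = 0.25) {
  if (is.null(dose_exponent)) dose_exponent <- numeric(0L)
  if (any(dose_exponent <= 0 | dose_exponent > 1))
    stop("dose_exponent must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(mu_bg = mu_bg, beta = beta,
                 dose_exponent = dose_exponent,
                 position_slope = if (is.null(position_slope)) numeric(0L) else position_slope,
                 pair_interaction = if (is.null(pair_interaction)) numeric(0L) else pair_interaction,
                 noise_sd = noise_sd),
            class = "effect_model")
}

#' Default planted-effect model for a motif roster
#'
#' Deterministic defaults spanning the effect classes the statistics must
#' recover: per-motif baseline effects spread over about \[-0.5, 0.8\] log2
#' units, orientation contrasts spread over \[-0.6, 0.6\] (zero for
#' palindromic motifs, which cannot carry strand information), a saturating
#' dose exponent of 0.5 everywhere, and the second background 0.5 log2
#' units below the first. `noise_sd` defaults to 0.55, which puts simulated
#' replicate-to-replicate Pearson r in the low-to-mid 0.7s to low 0.8s for
#' the bundled homotypic library.
#'
#' @param motifs a `motif_roster`.
#' @param orientation_delta optional single value overriding every
#'   non-palindromic motif's NT-minus-T contrast (used by planted-recovery
#'   checks); `NULL` keeps the spread.
#' @param noise_sd tile-by-replicate Gaussian sd (default 0.55).
#' @return an [effect_model()].
#' @export
default_effect_model <- function(motifs, orientation_delta = NULL,
                                 noise_sd = 0.55) {
  nm <- sort(motifs$name)
  n <- length(nm)
  base <- seq(-0.5, 0.8, length.out = max(n, 2L))[seq_len(n)]
  delta <- seq(-0.6, 0.6, length.out = max(n, 2L))[seq_len(n)]
  # decorrelate delta from base so orientation and copy effects separate
  delta <- delta[((seq_len(n) - 1L) * 7L) %% n + 1L]
  pal <- motifs$palindromic[match(nm, motifs$name)]
  if (!is.null(orientation_delta)) delta <- rep(orientation_delta, n)
  delta[pal] <- 0
  beta <- c(stats::setNames(base + delta / 2, paste0(nm, "|NT")),
            stats::setNames(base - delta / 2, paste0(nm, "|T")))
  effect_model(
    mu_bg = c(bg1 = 0, bg2 = -0.5),
    beta = beta,
    dose_exponent = stats::setNames(rep(0.5, n), nm),
    position_slope = stats::setNames(rep(0, n), nm),
    pair_interaction = NULL,
    noise_sd = noise_sd)
}

#' Expected log2 activity of a tile under an effect model
#'
#' `a = mu_bg + sum_(m,o) beta(m,o) * copies(m,o)^dose_exponent(m) +
#' sum_m position_slope(m) * (mean position + 100)/100 +
#' sum ordered pairs pair_interaction(A|B)`, where a motif's position is
#' the offset of its 5'-most base minus the tile length (so in \[-200, 0)
#' for 200-bp tiles) and ordered pairs are taken over first occurrences of
#' distinct motifs along the tile.
#'
#' @param tile one design row (see [generate_library()]).
#' @param model an [effect_model()].
#' @return numeric log2 activity (deterministic; noise is added at count
#'   simulation time).
#' @export
tile_activity <- function(tile, model) {
  a <- model$mu_bg[[tile$background_id]]
  if (is.null(a) || is.na(a)) stop("unknown background: ", tile$background_id)
  pl <- tile_placements(tile)
  if (nrow(pl) == 0L) return(unname(a))
  L <- nchar(tile$sequence)
  known <- unique(c(sub("\\|(NT|T)$", "", names(model$beta))))
  unknown <- setdiff(unique(pl$motif_name), known)
  if (length(unknown)) stop("motif(s) without coefficients: ",
                            paste(unknown, collapse = ", "))
  # orientation-dose terms
  grp <- paste(pl$motif_name, pl$orientation, sep = "|")
  for (g in unique(grp)) {
    m <- sub("\\|.*$", "", g)
    copies <- sum(grp == g)
    de <- if (m %in% names(model$dose_exponent)) model$dose_exponent[[m]] else 1
    b <- if (g %in% names(model$beta)) model$beta[[g]] else 0
    a <- a + b * copies^de
  }
  # position terms (mean position of each motif's placements)
  for (m in unique(pl$motif_name)) {
    sl <- if (m %in% names(model$position_slope)) model$position_slope[[m]] else 0
    if (sl != 0) {
      pos <- mean(pl$offset[pl$motif_name == m]) - L
      a <- a + sl * (pos + 100) / 100
    }
  }
  # ordered pair interactions over first occurrences of distinct motifs
  if (length(model$pair_interaction)) {
    first <- pl[!duplicated(pl$motif_name), ]
    mm <- first$motif_name[order(first$offset)]
    if (length(mm) > 1L) {
      for (i in seq_len(length(mm) - 1L)) for (j in (i + 1L):length(mm)) {
        key <- paste(mm[i], mm[j], sep = "|")
        if (key %in% names(model$pair_interaction))
          a <- a + model$pair_interaction[[key]]
      }
    }
  }
  unname(a)
}

#' Simulation configuration for barcode-level counts
#'
#' @param barcodes_per_tile_mean mean of the (zero-truncated) Poisson
#'   barcode count per tile (default 50, the typical barcode multiplicity
#'   of a lentiMPRA oligo pool).
#' @param replicates number of biological replicates (default 3).
#' @param dna_depth,rna_depth total sequencing depth per replicate; `NULL`
#'   means 200 reads per barcode on average.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson; default 10).
#' @param seed integer seed; mandatory, every run is reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(barcodes_per_tile_mean = 50, replicates = 3L,
                       dna_depth = NULL, rna_depth = NULL,
                       dispersion = 10, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(barcodes_per_tile_mean > 0, replicates >= 1, dispersion > 0)
  structure(list(barcodes_per_tile_mean = barcodes_per_tile_mean,
                 replicates = as.integer(replicates),
                 dna_depth = dna_depth, rna_depth = rna_depth,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a barcode count table from a design and planted effects
#'
#' Per tile, a barcode count is drawn Poisson(`barcodes_per_tile_mean`)
#' truncated at 1. Per barcode and replicate, `dna_count` is negative
#' binomial around the per-barcode DNA depth share and `rna_count` is
#' negative binomial around `dna_mean * 2^(a + eps) * depth_ratio`, where
#' `a` is [tile_activity()] and `eps` is a tile-by-replicate Gaussian with
#' sd `model$noise_sd` (this is what keeps replicate correlations below 1).
#' Identical seeds give byte-identical tables.
#'
#' @param tiles a `tile_design` data.frame.
#' @param model an [effect_model()].
#' @param config a [sim_config()].
#' @return data.frame of class `barcode_counts` with columns tile_id,
#'   barcode_id, replicate, dna_count, rna_count; attribute `activity`
#'   holds the planted per-tile log2 activities.
#' @export
simulate_counts <- function(tiles, model, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_tiles <- nrow(tiles)
  act <- vapply(seq_len(n_tiles), function(i) tile_activity(tiles[i, ], model),
                numeric(1L))
  nbc <- stats::rpois(n_tiles, config$barcodes_per_tile_mean)
  nbc[nbc == 0L] <- 1L
  total_bc <- sum(nbc)
  dna_depth <- if (is.null(config$dna_depth)) 200 * total_bc else config$dna_depth
  rna_depth <- if (is.null(config$rna_depth)) 200 * total_bc else config$rna_depth
  dna_mean <- dna_depth / total_bc
  depth_ratio <- rna_depth / dna_depth
  # mean-center planted activity so RNA depth is spent evenly
  scale_adj <- mean(2^act)
  tile_idx <- rep.int(seq_len(n_tiles), nbc)
  bc_id <- unlist(lapply(nbc, function(k) sprintf("bc%03d", seq_len(k))),
                  use.names = FALSE)
  reps <- config$replicates
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    eps <- stats::rnorm(n_tiles, 0, model$noise_sd)
    mu_rna <- dna_mean * 2^(act[tile_idx] + eps[tile_idx]) * depth_ratio / scale_adj
    out[[r]] <- data.frame(
      tile_id = tiles$tile_id[tile_idx],
      barcode_id = bc_id,
      replicate = r,
      dna_count = stats::rnbinom(length(tile_idx), mu = dna_mean,
                                 size = config$dispersion),
      rna_count = stats::rnbinom(length(tile_idx), mu = mu_rna,
                                 size = config$dispersion),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("barcode_counts", "data.frame")
  attr(res, "activity") <- stats::setNames(act, tiles$tile_id)
  res
}

#' Simulate promoters with planted TFBS orientation and order biases
#'
#' Generates first-order Markov background sequences (dinucleotide
#' controlled) read 5'->3' toward the TSS at the right end. In each
#' promoter one consecutive homotypic occurrence pair is planted whose
#' second member matches the first's orientation with probability `p_same`,
#' and one heterotypic A/B pair whose designated A motif is TSS-proximal
#' with probability `p_proximal`. Truth occurrences are returned in BED6
#' layout (0-based half-open; strand "+" = motif kmer on the promoter
#' forward strand).
#'
#' @param n_promoters number of promoters.
#' @param length promoter length in bp (default 2500, the conventional
#'   upstream window).
#' @param p_same probability the planted homotypic pair is co-oriented.
#' @param p_proximal probability the first motif of the heterotypic pair is
#'   the TSS-proximal member.
#' @param motifs a `motif_roster`; the first two non-palindromic motifs are
#'   the heterotypic A/B pair and homotypic pairs cycle over all motifs.
#' @param seed integer seed.
#' @param dinuc_freq optional dinucleotide frequency vector for the
#'   background chain (uniform when NULL).
#' @return list with `sequences` (named character), `truth` (BED6-style
#'   data.frame: chrom, start, end, name, score, strand) and `tss` (named
#'   numeric, TSS coordinate per promoter, equal to `length`).
#' @export
simulate_promoter_set <- function(n_promoters, length = 2500L, p_same = 0.5,
                                  p_proximal = 0.5, motifs = grammar_motifs(),
                                  seed, dinuc_freq = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(p_same >= 0, p_same <= 1, p_proximal >= 0, p_proximal <= 1)
  maxw <- max(nchar(motifs$kmer))
  # the two planted pairs live in separate halves with a >= 140 bp buffer so
  # they never form a spurious "consecutive" pair at the default 100 bp gap
  if (length < 2L * (2L * maxw + 50L + 130L))
    stop("promoter length too short for planted pairs")
  set.seed(seed)
  km <- stats::setNames(motifs$kmer, motifs$name)
  nonpal <- motifs$name[!motifs$palindromic]
  if (length(nonpal) < 2L) stop("need >= 2 non-palindromic motifs")
  hetA <- nonpal[1L]; hetB <- nonpal[2L]
  seqs <- character(n_promoters)
  names(seqs) <- sprintf("prom%05d", seq_len(n_promoters))
  truth <- vector("list", n_promoters)
  half <- length %/% 2L
  for (i in seq_len(n_promoters)) {
    s <- markov_sequence(length, dinuc_freq)
    occ <- list()
    put <- function(s, motif, start, strand) {
      ins <- km[[motif]]
      if (strand == "-") ins <- reverse_complement(ins)
      substr(s, start + 1L, start + nchar(ins)) <- ins
      s
    }
    # homotypic pair in the left half, cycling over motifs
    hm <- motifs$name[(i - 1L) %% nrow(motifs) + 1L]
    w <- nchar(km[[hm]])
    gap <- sample(5:50, 1L)
    start1 <- sample.int(half - 120L - (2L * w + gap), 1L) - 1L
    start2 <- start1 + w + gap
    strand1 <- sample(c("+", "-"), 1L)
    strand2 <- if (stats::runif(1) < p_same) strand1 else setdiff(c("+", "-"), strand1)
    s <- put(s, hm, start1, strand1); s <- put(s, hm, start2, strand2)
    occ[[1L]] <- data.frame(chrom = names(seqs)[i],
                            start = c(start1, start2),
                            end = c(start1, start2) + w,
                            name = hm, score = 0,
                            strand = c(strand1, strand2),
                            stringsAsFactors = FALSE)
    # heterotypic A/B pair in the right half; proximal = closer to TSS
    wa <- nchar(km[[hetA]]); wb <- nchar(km[[hetB]])
    gap2 <- sample(5:50, 1L)
    span <- wa + wb + gap2
    startL <- half + 20L + sample.int(length - half - 20L - span, 1L) - 1L
    a_proximal <- stats::runif(1) < p_proximal
    # the downstream (larger-coordinate) slot is TSS-proximal
    if (a_proximal) { mL <- hetB; mR <- hetA } else { mL <- hetA; mR <- hetB }
    wL <- nchar(km[[mL]])
    startR <- startL + wL + gap2
    s <- put(s, mL, startL, "+"); s <- put(s, mR, startR, "+")
    occ[[2L]] <- data.frame(chrom = names(seqs)[i],
                            start = c(startL, startR),
                            end = c(startL + wL, startR + nchar(km[[mR]])),
                            name = c(mL, mR), score = 0, strand = "+",
                            stringsAsFactors = FALSE)
    seqs[i] <- s
    truth[[i]] <- do.call(rbind, occ)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth,
       tss = stats::setNames(rep(as.numeric(length), n_promoters), names(seqs)))
}

#' Read / write barcode count tables as TSV
#'
#' @param counts a `barcode_counts` data.frame.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tile_id", "barcode_id", "replicate", "dna_count", "rna_count")
  if (!all(need %in% names(out)))
    stop("count TSV needs columns: ", paste(need, collapse = ", "))
  class(out) <- c("barcode_counts", "data.frame")
  out
}
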