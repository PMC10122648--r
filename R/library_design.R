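#' Enumerate strand-orientation vectors
#'
#' All assignments of non-template (NT) / template (T) orientation to `n`
#' sites, in deterministic lexicographic order with NT < T. A single site
#' has 2 vectors, a pair 4, a triplet 8.
#'
#' @param n number of sites (>= 1).
#' @return list of character vectors over c("NT", "T"), length `2^n`.
#' @export
enumerate_orientation_vectors <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  grid <- expand.grid(rep(list(c("NT", "T")), n), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; reverse for lexicographic
  grid <- grid[, rev(seq_len(n)), drop = FALSE]
  ord <- do.call(order, as.list(grid))
  grid <- grid[ord, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

#' Enumerate ordered k-tuples of motifs without repetition
#'
#' Permutation enumeration for heterotypic clusters: 18 motifs give 306
#' ordered pairs and 4,896 ordered triplets.
#'
#' @param motifs character vector of unique motif names (or a
#'   `motif_roster`, whose `name` column is used).
#' @param k tuple size, 1 <= k <= length(motifs).
#' @return list of character k-vectors, in stable lexicographic-by-index
#'   order; length `n! / (n-k)!`.
#' @export
enumerate_permutations <- function(motifs, k) {
  if (inherits(motifs, "motif_roster")) motifs <- motifs$name
  motifs <- as.character(motifs)
  if (anyDuplicated(motifs)) stop("duplicate motif names")
  n <- length(motifs)
  if (k < 1 || k > n) stop("k must be in 1..length(motifs)")
  k <- as.integer(k)
  acc <- list(integer(0L))
  for (depth in seq_len(k)) {
    acc <- unlist(lapply(acc, function(prefix) {
      rest <- setdiff(seq_len(n), prefix)
      lapply(rest, function(j) c(prefix, j))
    }), recursive = FALSE)
  }
  lapply(acc, function(idx) motifs[idx])
}

#' Modal pairwise start-to-start distance between two occurrence tracks
#'
#' Scans all cross pairs of start coordinates and returns the most frequent
#' distance in (0, max_gap]; ties break toward the smaller distance. When no
#' pair falls inside the window (or either track is empty) the documented
#' fallback of 10 bp is returned with attribute `fallback = TRUE` and a
#' warning. This is the "most frequent genomic distance" used as the third
#' spacing rule in library design.
#'
#' @param positions_a,positions_b sorted integer start coordinates on a
#'   common axis.
#' @param max_gap search window in bp (default 200).
#' @param fallback distance returned when no pair is in range (default 10).
#' @return integer distance; attribute `fallback` is TRUE when defaulted.
#' @export
most_frequent_pair_distance <- function(positions_a, positions_b,
                                        max_gap = 200L, fallback = 10L) {
  if (max_gap <= 0) stop("max_gap must be positive")
  if (length(positions_a) == 0L || length(positions_b) == 0L) {
    warning("empty position list; returning fallback distance")
    return(structure(as.integer(fallback), fallback = TRUE))
  }
  d <- abs(outer(positions_b, positions_a, "-"))
  d <- d[d > 0 & d <= max_gap]
  if (length(d) == 0L) {
    warning("no pair within max_gap; returning fallback distance")
    return(structure(as.integer(fallback), fallback = TRUE))
  }
  tab <- table(d)
  best <- as.integer(names(tab)[tab == max(tab)])
  structure(min(best), fallback = FALSE)
}

#' Construct a placement table
#'
#' @param motif_name character vector.
#' @param offset integer 0-based offsets of each site's 5'-most base on the
#'   tile forward strand.
#' @param orientation "NT" (kmer on the forward strand) or "T" (reverse
#'   complement on the forward strand).
#' @return data.frame with columns motif_name, offset, orientation.
#' @export
placements <- function(motif_name, offset, orientation) {
  stopifnot(length(motif_name) == length(offset),
            length(offset) == length(orientation))
  if (!all(orientation %in% c("NT", "T"))) stop("orientation must be NT or T")
  out <- data.frame(motif_name = as.character(motif_name),
                    offset = as.integer(offset),
                    orientation = as.character(orientation),
                    stringsAsFactors = FALSE)
  out[order(out$offset), , drop = FALSE]
}

#' Write motif placements into a background sequence
#'
#' Overwrites each placement window with the motif kmer (`NT`) or its
#' reverse complement (`T`). The output length equals the background length
#' and the sequence differs from the background only inside placement
#' windows; re-scanning the tile for the exact written strings recovers
#' every placement.
#'
#' @param background one row of a [background_set()] (or a list with `id`
#'   and `sequence`).
#' @param placement a [placements()] data.frame, ascending offsets,
#'   non-overlapping, in bounds.
#' @param motifs a `motif_roster` supplying kmers.
#' @param tile_id identifier for the tile.
#' @param category design category label.
#' @param spacing_rule free-text spacing label recorded in the design row.
#' @return one-row design data.frame (see [generate_library()] for the
#'   column layout).
#' @export
build_tile <- function(background, placement, motifs,
                       tile_id = "tile", category = "custom",
                       spacing_rule = NA_character_) {
  bg_seq <- background$sequence
  bg_id <- background$id
  L <- nchar(bg_seq)
  km <- stats::setNames(motifs$kmer, motifs$name)
  unknown <- setdiff(placement$motif_name, names(km))
  if (length(unknown)) stop("unknown motif(s): ", paste(unknown, collapse = ", "))
  w <- nchar(km[placement$motif_name])
  if (any(placement$offset < 0L) || any(placement$offset + w > L))
    stop("placement out of bounds for ",
         paste(placement$motif_name[placement$offset < 0L | placement$offset + w > L],
               collapse = ", "))
  ends <- placement$offset + w
  if (nrow(placement) > 1L) {
    ov <- which(placement$offset[-1L] < ends[-length(ends)])
    if (length(ov))
      stop("overlapping placements: ",
           paste(sprintf("%s@%d/%s@%d", placement$motif_name[ov],
                         placement$offset[ov], placement$motif_name[ov + 1L],
                         placement$offset[ov + 1L]), collapse = "; "))
  }
  seq <- bg_seq
  for (i in seq_len(nrow(placement))) {
    ins <- km[[placement$motif_name[i]]]
    if (placement$orientation[i] == "T") ins <- reverse_complement(ins)
    substr(seq, placement$offset[i] + 1L, placement$offset[i] + nchar(ins)) <- ins
  }
  data.frame(tile_id = tile_id, background_id = bg_id, category = category,
             motif_names = paste(placement$motif_name, collapse = ","),
             orientations = paste(placement$orientation, collapse = ","),
             offsets = paste(placement$offset, collapse = ","),
             spacing_rule = spacing_rule, sequence = seq,
             stringsAsFactors = FALSE)
}

#' Recover the placement table of a design row
#'
#' @param design_row one row of a design data.frame.
#' @return a [placements()] data.frame (zero rows for an empty tile).
#' @export
tile_placements <- function(design_row) {
  if (is.na(design_row$motif_names) || design_row$motif_names == "")
    return(placements(character(0L), integer(0L), character(0L)))
  placements(strsplit(design_row$motif_names, ",", fixed = TRUE)[[1L]],
             as.integer(strsplit(design_row$offsets, ",", fixed = TRUE)[[1L]]),
             strsplit(design_row$orientations, ",", fixed = TRUE)[[1L]])
}

#' Library design configuration
#'
#' @param copies homotypic copy-number set (default c(1,2,3,4,5,6,8)).
#' @param spacings character vector from c("5", "10", "genomic"): fixed 5-bp
#'   and 10-bp inter-motif gaps and the most frequent genomic distance.
#' @param categories which design categories to emit.
#' @param pair_copies copies per member for heterotypic pairs (subset of
#'   1:3; default 1).
#' @param max_full_orient largest homotypic copy number for which the full
#'   `2^n` orientation enumeration is emitted (default 6); above it only
#'   all-NT, all-T and the two alternating vectors are used.
#' @param position_bin width of position-sweep bins in bp (default 40).
#' @param genomic_gaps optional named numeric vector "A|B" -> edge-to-edge
#'   gap in bp for the genomic spacing rule; missing entries use
#'   `genomic_default`.
#' @param genomic_default default genomic-mode gap (10 bp).
#' @param anchor "right" (promoter-proximal, default), "left" or "center".
#' @return list of class `design_config`.
#' @export
design_config <- function(copies = c(1L, 2L, 3L, 4L, 5L, 6L, 8L),
                          spacings = c("5", "10", "genomic"),
                          categories = c("homotypic", "position_sweep",
                                         "pair", "triplet"),
                          pair_copies = 1L,
                          max_full_orient = 6L,
                          position_bin = 40L,
                          genomic_gaps = NULL,
                          genomic_default = 10L,
                          anchor = c("right", "center", "left")) {
  anchor <- match.arg(anchor)
  stopifnot(all(spacings %in% c("5", "10", "genomic")),
            all(pair_copies %in% 1:3), position_bin > 0)
  structure(list(copies = as.integer(copies), spacings = spacings,
                 categories = categories, pair_copies = as.integer(pair_copies),
                 max_full_orient = as.integer(max_full_orient),
                 position_bin = as.integer(position_bin),
                 genomic_gaps = genomic_gaps,
                 genomic_default = as.integer(genomic_default),
                 anchor = anchor),
            class = "design_config")
}

# gap in bp for a spacing rule between two named motifs
.spacing_gap <- function(rule, a, b, config) {
  if (rule %in% c("5", "10")) return(as.integer(rule))
  key <- paste(a, b, sep = "|")
  g <- config$genomic_gaps
  if (!is.null(g) && key %in% names(g)) return(as.integer(g[[key]]))
  config$genomic_default
}

# offsets for a motif block (kmers in order, gaps between consecutive
# sites), anchored inside a tile of length L; NULL if it does not fit
.block_offsets <- function(widths, gaps, L, anchor) {
  total <- sum(widths) + sum(gaps)
  if (total > L) return(NULL)
  start <- switch(anchor,
                  right = L - total,
                  left = 0L,
                  center = (L - total) %/% 2L)
  offs <- integer(length(widths))
  cur <- start
  for (i in seq_along(widths)) {
    offs[i] <- cur
    cur <- cur + widths[i] + if (i < length(widths)) gaps[i] else 0L
  }
  offs
}

.orient_vectors_for <- function(n, max_full) {
  if (n <= max_full) return(enumerate_orientation_vectors(n))
  alt1 <- rep(c("NT", "T"), length.out = n)
  alt2 <- rep(c("T", "NT"), length.out = n)
  list(rep("NT", n), rep("T", n), alt1, alt2)
}

#' Generate the combinatorial TFBS tile library
#'
#' Emits, per background: (a) homotypic tiles for every motif x copy number
#' x orientation vector x spacing rule; (b) single-motif position-sweep
#' tiles, one per bin of the tile in both orientations; (c) heterotypic
#' pair tiles for all ordered pairs x 4 orientation vectors x spacing rules
#' (x copies per member); (d) heterotypic triplet tiles for all ordered
#' triplets x 8 orientation vectors at the genomic-mode spacing only.
#' Configurations that do not fit the background are skipped and recorded
#' in the `skipped` attribute. Output is deterministic: the same inputs
#' give a byte-identical design table.
#'
#' @param motifs a `motif_roster`.
#' @param backgrounds a `background_set`.
#' @param config a [design_config()].
#' @return design data.frame (tile_id, background_id, category,
#'   motif_names, orientations, offsets, spacing_rule, sequence) of class
#'   `tile_design`, with attribute `skipped` (character vector of skipped
#'   configuration ids).
#' @export
generate_library <- function(motifs, backgrounds, config = design_config()) {
  stopifnot(inherits(motifs, "motif_roster"), inherits(backgrounds, "background_set"))
  km <- stats::setNames(motifs$kmer, motifs$name)
  skipped <- character(0L)
  rows <- vector("list", 0L)
  emit <- function(bg, names_, orients, rule, cat, id) {
    widths <- nchar(km[names_])
    gaps <- if (length(names_) > 1L)
      vapply(seq_len(length(names_) - 1L), function(i)
        .spacing_gap(rule, names_[i], names_[i + 1L], config), integer(1L))
    else integer(0L)
    offs <- .block_offsets(widths, gaps, bg$length, config$anchor)
    if (is.null(offs)) { skipped <<- c(skipped, id); return(invisible(NULL)) }
    pl <- placements(names_, offs, orients)
    rows[[length(rows) + 1L]] <<- build_tile(bg, pl, motifs, tile_id = id,
                                             category = cat, spacing_rule = rule)
    invisible(NULL)
  }
  for (b in seq_len(nrow(backgrounds))) {
    bg <- backgrounds[b, ]
    if ("homotypic" %in% config$categories) {
      for (m in motifs$name) for (cc in config$copies) {
        ovs <- .orient_vectors_for(cc, config$max_full_orient)
        for (rule in config$spacings) for (ov in ovs) {
          id <- paste("homo", bg$id, m, cc, paste(ov, collapse = ""), rule, sep = "_")
          emit(bg, rep(m, cc), ov, rule, "homotypic", id)
        }
      }
    }
    if ("position_sweep" %in% config$categories) {
      nb <- bg$length %/% config$position_bin
      for (m in motifs$name) for (bin in seq_len(nb) - 1L) {
        off <- bin * config$position_bin
        if (off + nchar(km[[m]]) > bg$length) next
        for (or in c("NT", "T")) {
          id <- paste("pos", bg$id, m, off, or, sep = "_")
          pl <- placements(m, off, or)
          rows[[length(rows) + 1L]] <- build_tile(bg, pl, motifs, tile_id = id,
                                                  category = "position_sweep",
                                                  spacing_rule = NA_character_)
        }
      }
    }
    if ("pair" %in% config$categories && nrow(motifs) >= 2L) {
      perms <- enumerate_permutations(motifs, 2L)
      ovs <- enumerate_orientation_vectors(2L)
      for (pp in perms) for (cc in config$pair_copies)
        for (rule in config$spacings) for (ov in ovs) {
          names_ <- c(rep(pp[1L], cc), rep(pp[2L], cc))
          orients <- c(rep(ov[1L], cc), rep(ov[2L], cc))
          id <- paste("pair", bg$id, paste(pp, collapse = "."), cc,
                      paste(ov, collapse = ""), rule, sep = "_")
          emit(bg, names_, orients, rule, "pair", id)
        }
    }
    if ("triplet" %in% config$categories && nrow(motifs) >= 3L) {
      perms <- enumerate_permutations(motifs, 3L)
      ovs <- enumerate_orientation_vectors(3L)
      for (pp in perms) for (ov in ovs) {
        id <- paste("trip", bg$id, paste(pp, collapse = "."),
                    paste(ov, collapse = ""), "genomic", sep = "_")
        emit(bg, pp, ov, "genomic", "triplet", id)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$tile_id)) stop("internal error: duplicate tile ids")
  class(out) <- c("tile_design", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Read / write a tile design table as TSV
#'
#' @param design a `tile_design` data.frame.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  class(out) <- c("tile_design", "data.frame")
  out
}

#' Write tile sequences as FASTA
#'
#' @param design a `tile_design`.
#' @param path output FASTA path.
#' @export
write_design_fasta <- function(design, path) {
  x <- Biostrings::DNAStringSet(design$sequence)
  names(x) <- design$tile_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
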