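#' Build a motif roster
#'
#' A motif roster is a data.frame with one row per transcription factor
#' binding site (TFBS): `name`, `kmer` (the site written 5'->3' on the
#' non-template strand), `source_id` (free-text provenance, e.g. a JASPAR
#' accession) and a derived `palindromic` flag. Each factor is represented
#' by a single fixed kmer, so "orientation" is well defined for every
#' non-palindromic entry.
#'
#' @param name character vector of unique TF names.
#' @param kmer character vector of uppercase ACGT kmers.
#' @param source_id optional character vector of identifiers.
#' @return data.frame of class `motif_roster`.
#' @seealso [grammar_motifs()] for the built-in 18-factor roster,
#'   [read_motifs()] / [write_motifs()] for TSV round-trips.
#' @export
motif_roster <- function(name, kmer, source_id = NA_character_) {
  stopifnot(length(name) == length(kmer))
  if (anyDuplicated(name)) stop("duplicate motif names: ",
                                paste(unique(name[duplicated(name)]), collapse = ", "))
  for (k in kmer) check_dna(k)
  if (any(nchar(kmer) == 0L)) stop("empty kmer")
  out <- data.frame(name = as.character(name),
                    kmer = as.character(kmer),
                    source_id = rep_len(as.character(source_id), length(name)),
                    stringsAsFactors = FALSE)
  out$palindromic <- vapply(out$kmer, is_palindromic, logical(1L))
  class(out) <- c("motif_roster", "data.frame")
  out
}

#' The built-in eighteen-factor liver TFBS roster
#'
#' Eighteen liver-associated and general transcription factors used for
#' combinatorial grammar libraries: AHR, AP1, CEBPA, CREB1, CTCF, FOXA1,
#' GABPA, HNF1A, HNF4A, NR2F2, ONECUT1, PPARA, REST, RXRA, SP1, TFAP2C,
#' XBP1 and YY1. The AP1 (TGACTCA) and CREB1 (TGACGTCA) sites are the
#' literature consensus kmers; CREB1 is the single palindromic entry and
#' acts as the orientation negative control. The remaining sixteen kmers are
#' SYNTHETIC stand-ins (deterministically generated, non-palindromic, 7-10
#' bp) carried under the real factor names so that the full combinatorial
#' machinery can be exercised without external motif databases; their
#' `source_id` is "synthetic".
#'
#' @return a `motif_roster` with 18 rows.
#' @export
grammar_motifs <- function() {
  real <- data.frame(
    name = c("AP1", "CREB1"),
    kmer = c("TGACTCA", "TGACGTCA"),
    source_id = c("consensus", "consensus"),
    stringsAsFactors = FALSE)
  others <- c("AHR", "CEBPA", "CTCF", "FOXA1", "GABPA", "HNF1A", "HNF4A",
              "NR2F2", "ONECUT1", "PPARA", "REST", "RXRA", "SP1", "TFAP2C",
              "XBP1", "YY1")
  # Deterministic synthetic kmers: seeded per name, rejected if palindromic
  # or clashing with another roster kmer.
  kmers <- character(0L)
  for (i in seq_along(others)) {
    len <- 7L + (i %% 4L)
    kk <- .synthetic_kmer(others[i], len,
                          avoid = c(real$kmer, kmers))
    kmers <- c(kmers, kk)
  }
  motif_roster(c(real$name, others), c(real$kmer, kmers),
               c(real$source_id, rep("synthetic", length(others))))
}

# Seeded, palindrome-free kmer derived from a name hash; independent of the
# caller's RNG state.
.synthetic_kmer <- function(name, len, avoid = character(0L)) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(h)
  bases <- c("A", "C", "G", "T")
  repeat {
    k <- paste(sample(bases, len, replace = TRUE), collapse = "")
    if (!is_palindromic(k) && !k %in% avoid) return(k)
  }
}

#' Read / write a motif roster as TSV
#'
#' The TSV has columns name, kmer, source_id.
#'
#' @param path file path.
#' @return `read_motifs` returns a `motif_roster`; `write_motifs` returns
#'   `path` invisibly.
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "kmer")
  if (!all(need %in% names(df))) stop("motif TSV needs columns: name, kmer")
  motif_roster(df$name, df$kmer,
               if ("source_id" %in% names(df)) df$source_id else NA_character_)
}

#' @rdname read_motifs
#' @param motifs a `motif_roster`.
#' @export
write_motifs <- function(motifs, path) {
  utils::write.table(motifs[, c("name", "kmer", "source_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Background sequences for tile construction
#'
#' A background is a neutral (enhancer-negative) carrier sequence into which
#' motif placements are written; library backgrounds are 200 bp. Two
#' deterministic synthetic 200-bp backgrounds, `bg1` and `bg2`, are provided
#' by `example_backgrounds()`; in the assay the second background carries a
#' lower baseline, and the bundled simulator defaults mirror that.
#'
#' @param id character vector of identifiers.
#' @param sequence character vector of DNA strings.
#' @return data.frame of class `background_set` with columns id, sequence,
#'   length.
#' @export
background_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  for (s in sequence) check_dna(s)
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("background_set", "data.frame")
  out
}

#' @rdname background_set
#' @param length background length in bp (default 200).
#' @export
example_backgrounds <- function(length = 200L) {
  s1 <- markov_from_seed(length, seed = 9001L)
  s2 <- markov_from_seed(length, seed = 9002L)
  background_set(c("bg1", "bg2"), c(s1, s2))
}

#' Deterministic uniform-composition random DNA
#'
#' Draws a uniform-base sequence under its own seed without disturbing the
#' caller's RNG state; used for reproducible synthetic backgrounds.
#'
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @return DNA string.
#' @export
markov_from_seed <- function(length, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Read backgrounds from a FASTA file
#'
#' @param path FASTA file.
#' @return a `background_set`.
#' @export
read_backgrounds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  background_set(names(x), as.character(x))
}
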