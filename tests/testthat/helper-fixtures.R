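# shared in-code fixtures; everything is generated at test time

toy_motifs <- function() {
  motif_roster(c("AP1", "CREB1", "FOX"),
               c("TGACTCA", "TGACGTCA", "TGTTTAC"))
}

toy_background <- function(length = 60L, id = "bg1") {
  background_set(id, strrep("A", length))
}

# a design of n_per_group single-copy tiles of one motif per orientation,
# with unique tile ids (the library proper has one tile per configuration;
# recovery checks need many independent tiles per group)
replicated_orientation_design <- function(motifs, motif, n_per_group,
                                          backgrounds = example_backgrounds()) {
  bg <- backgrounds[1L, ]
  rows <- lapply(seq_len(2L * n_per_group), function(i) {
    or <- if (i <= n_per_group) "NT" else "T"
    build_tile(bg, placements(motif, 100L, or), motifs,
               tile_id = sprintf("%s_%s_%04d", motif, or, i),
               category = "homotypic")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tile_design", "data.frame")
  out
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_pfm <- function(width) {
  matrix(stats::rpois(4L * width, 20) + 1, nrow = 4L)
}

# tail probability P(score >= t) by exhaustive enumeration over all 4^w
# sequences, on the same discretized score grid the DP uses
brute_force_tail <- function(pwm, granularity = 1e-3) {
  s_int <- round(pwm$matrix / granularity)
  w <- ncol(s_int)
  bg <- pwm$background
  total <- expand.grid(rep(list(1:4), w))
  scores <- numeric(nrow(total))
  probs <- numeric(nrow(total))
  sc <- as.matrix(total)
  scores <- rowSums(matrix(s_int[cbind(as.vector(sc),
                                       rep(seq_len(w), each = nrow(sc)))],
                           nrow(sc), w))
  probs <- apply(sc, 1L, function(r) prod(bg[r]))
  list(values = scores * granularity, probs = probs)
}
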