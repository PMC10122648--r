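#' Convert a position frequency matrix to a log-odds PWM
#'
#' `score(b, j) = log2( (count(b, j) + pseudocount * bg(b)) /
#' (colsum(j) + pseudocount) / bg(b) )`. Count matrices (JASPAR) and
#' probability matrices (MEME letter-probability blocks, colsum 1) are both
#' accepted.
#'
#' @param pfm 4 x w non-negative matrix, rows A, C, G, T.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount total pseudocount spread by background (default 0.1).
#' @param name motif name carried on the object.
#' @return list of class `pwm`: `name`, `matrix` (4 x w log2-odds),
#'   `background`, and `threshold` (NA until [score_threshold()] is
#'   applied).
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.1,
                       name = "motif") {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(pfm) < 1L) stop("PFM must have >= 1 column")
  if (any(pfm < 0)) stop("PFM counts must be non-negative")
  background <- background / sum(background)
  cs <- colSums(pfm)
  if (any(cs == 0) && pseudocount == 0)
    stop("zero column sum requires a pseudocount")
  prob <- sweep(pfm + pseudocount * background, 2L, cs + pseudocount, "/")
  mat <- log2(sweep(prob, 1L, background, "/"))
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(name = name, matrix = mat, background = background,
                 threshold = NA_real_),
            class = "pwm")
}

#' @method print pwm
#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, threshold %s\n", x$name, ncol(x$matrix),
              if (is.na(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

# Exact score distribution under the background model, by dynamic
# programming over integer-discretized scores (position-wise convolution).
# Returns list(values = integer scores * granularity, probs).
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  mat <- pwm$matrix
  bg <- pwm$background
  s_int <- round(mat / granularity)
  w <- ncol(s_int)
  lo <- sum(apply(s_int, 2L, min))
  hi <- sum(apply(s_int, 2L, max))
  probs <- numeric(hi - lo + 1L)  # index i <-> integer score lo + i - 1
  # DP forward over columns
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(w)) {
    cj <- s_int[, j]
    new_lo <- cur_lo + min(cj)
    new_hi <- cur_lo + length(cur) - 1L + max(cj)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cur_lo + cj[b] - new_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  keep <- cur > 0
  list(values = (cur_lo + which(keep) - 1L) * granularity,
       probs = cur[keep], granularity = granularity)
}

#' Exact p-value score threshold for a PWM
#'
#' Computes the full score distribution under the background model by
#' dynamic programming over discretized scores and returns the smallest
#' achievable score `t` with `P(score >= t | background) <= p_value`. If
#' even the maximum score is more probable than `p_value`, the maximum
#' score is returned with attribute `unattainable = TRUE`. The PWM's score
#' matrix is discretized to the same granularity, so scanning and the
#' threshold share one exact score scale.
#'
#' @param pwm a [pfm_to_pwm()] object.
#' @param p_value tail probability (default 1e-4, the conventional motif
#'   scanning stringency).
#' @param granularity score discretization step (default 1e-3 log2 units).
#' @return the `pwm` with `threshold` set; attributes `attained_p` (the
#'   achieved tail probability) and `unattainable`.
#' @export
score_threshold <- function(pwm, p_value = 1e-4, granularity = 1e-3) {
  if (p_value <= 0 || p_value >= 1) stop("p_value must be in (0, 1)")
  dist <- pwm_score_distribution(pwm, granularity)
  pwm$matrix <- round(pwm$matrix / granularity) * granularity
  pwm$granularity <- granularity
  tail_p <- rev(cumsum(rev(dist$probs)))
  ok <- which(tail_p <= p_value)
  if (length(ok) == 0L) {
    pwm$threshold <- max(dist$values)
    attr(pwm$threshold, "attained_p") <- tail_p[length(tail_p)]
    attr(pwm$threshold, "unattainable") <- TRUE
  } else {
    i <- ok[1L]
    pwm$threshold <- dist$values[i]
    attr(pwm$threshold, "attained_p") <- tail_p[i]
    attr(pwm$threshold, "unattainable") <- FALSE
  }
  pwm
}

# score all windows of seq against matrix `mat`; NA where a window holds N
.window_scores <- function(idx, mat) {
  w <- ncol(mat)
  L <- length(idx)
  if (L < w) return(numeric(0L))
  n_win <- L - w + 1L
  sc <- numeric(n_win)
  for (j in seq_len(w)) {
    v <- mat[, j][idx[j:(j + n_win - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Scan a sequence for PWM matches on both strands
#'
#' Scores every window on the forward strand and (via the
#' reverse-complemented matrix) on the reverse strand, reporting windows
#' whose score reaches the PWM threshold. Coordinates are 0-based
#' half-open on the forward strand for both strands; windows containing N
#' are skipped.
#'
#' @param seq DNA string over ACGTN.
#' @param pwm a `pwm` with threshold set ([score_threshold()]); a numeric
#'   `threshold` argument overrides it.
#' @param threshold optional score cutoff.
#' @param seqname chrom label recorded in the output (default "seq").
#' @return BED6-style data.frame: chrom, start, end, name, score, strand.
#' @export
scan_sequence <- function(seq, pwm, threshold = NULL, seqname = "seq") {
  check_dna(seq, allow_n = TRUE)
  thr <- if (!is.null(threshold)) threshold else pwm$threshold
  if (is.na(thr)) stop("no threshold: run score_threshold() or pass one")
  mat <- pwm$matrix
  w <- ncol(mat)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) < w)
    return(data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), name = character(0L),
                      score = numeric(0L), strand = character(0L),
                      stringsAsFactors = FALSE))
  idx <- match(chars, c("A", "C", "G", "T"))  # N -> NA
  # reverse strand: score of revcomp(window) under mat == score of window
  # under the reverse-complemented matrix
  mat_rc <- mat[4:1, w:1, drop = FALSE]
  dimnames(mat_rc) <- dimnames(mat)
  fw <- .window_scores(idx, mat)
  rv <- .window_scores(idx, mat_rc)
  # tolerance absorbs float error in sums of grid-discretized scores
  hit_f <- which(!is.na(fw) & fw >= thr - 1e-9)
  hit_r <- which(!is.na(rv) & rv >= thr - 1e-9)
  n_hit <- length(hit_f) + length(hit_r)
  out <- data.frame(
    chrom = rep(seqname, n_hit),
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + w,
    name = rep(pwm$name, n_hit),
    score = c(fw[hit_f], rv[hit_r]),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Read MEME-format position frequency matrices
#'
#' Parses MEME minimal format (as distributed by JASPAR): `MOTIF` lines
#' followed by `letter-probability matrix` blocks. Background frequencies
#' are taken from the `Background letter frequencies` line when present.
#'
#' @param path MEME file.
#' @return named list of 4 x w probability matrices (rows A, C, G, T), with
#'   attribute `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(tok))
    nm <- tok[is.na(vals)]
    vv <- vals[!is.na(vals)]
    if (length(vv) == 4L && identical(toupper(nm), c("A", "C", "G", "T")))
      bg <- vv
  }
  motif_i <- grep("^MOTIF\\b", lines)
  out <- list()
  for (mi in motif_i) {
    toks <- strsplit(trimws(lines[mi]), "\\s+")[[1L]]
    name <- if (length(toks) >= 3L) toks[3L] else toks[2L]
    hdr <- mi + grep("letter-probability matrix",
                     lines[(mi + 1L):min(mi + 10L, length(lines))])[1L]
    if (is.na(hdr)) next
    wm <- regmatches(lines[hdr], regexec("w=\\s*([0-9]+)", lines[hdr]))[[1L]]
    w <- if (length(wm) == 2L) as.integer(wm[2L]) else NA_integer_
    rows <- list()
    j <- hdr + 1L
    while (j <= length(lines)) {
      tok <- strsplit(trimws(lines[j]), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) != 4L || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
      if (!is.na(w) && length(rows) == w) break
    }
    if (length(rows) == 0L) next
    m <- t(do.call(rbind, rows))
    rownames(m) <- c("A", "C", "G", "T")
    out[[name]] <- m
  }
  attr(out, "background") <- bg
  out
}
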