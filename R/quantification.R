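#' Filter a barcode count table
#'
#' Two-stage filter: barcodes whose DNA count is below `min_count` are
#' removed (the boundary value is retained), then tiles left with fewer
#' than `min_barcodes` surviving barcodes in a replicate are dropped for
#' that replicate. Removal counts are recorded in the `filter_log`
#' attribute.
#'
#' @param table a `barcode_counts` data.frame.
#' @param min_count minimum DNA count per barcode (default 3).
#' @param min_barcodes minimum surviving barcodes per tile per replicate
#'   (default 3).
#' @return filtered `barcode_counts`; attribute `filter_log` is a list with
#'   `barcodes_removed` and `tile_replicates_removed`.
#' @export
filter_barcodes <- function(table, min_count = 3L, min_barcodes = 3L) {
  keep <- table$dna_count >= min_count
  n_bc_removed <- sum(!keep)
  out <- table[keep, , drop = FALSE]
  key <- paste(out$tile_id, out$replicate, sep = "\r")
  tab <- table(key)
  ok <- names(tab)[tab >= min_barcodes]
  n_tr_removed <- length(tab) - length(ok)
  out <- out[key %in% ok, , drop = FALSE]
  if (nrow(out) == 0L) warning("no barcodes survive filtering")
  rownames(out) <- NULL
  class(out) <- c("barcode_counts", "data.frame")
  attr(out, "filter_log") <- list(barcodes_removed = n_bc_removed,
                                  tile_replicates_removed = n_tr_removed)
  out
}

#' Depth-normalized per-barcode expression
#'
#' expression = log2( (rna / rna_total) / (dna / dna_total) ) with totals
#' taken per replicate over the filtered table. Barcodes with zero RNA get
#' a pseudocount of 1 added to both counts (before totals), so no barcode
#' is lost to log of zero.
#'
#' @param table a filtered `barcode_counts`.
#' @return the table with an added `expression` column.
#' @export
normalize_expression <- function(table) {
  if (any(table$dna_count <= 0))
    stop("normalize_expression requires DNA-filtered input (dna_count >= 1)")
  dna <- table$dna_count
  rna <- table$rna_count
  zero <- rna == 0
  rna[zero] <- rna[zero] + 1
  dna[zero] <- dna[zero] + 1
  rep_f <- factor(table$replicate)
  dna_tot <- as.numeric(tapply(dna, rep_f, sum)[rep_f])
  rna_tot <- as.numeric(tapply(rna, rep_f, sum)[rep_f])
  table$expression <- log2((rna / rna_tot) / (dna / dna_tot))
  table
}

#' Aggregate barcode expression to tile expression
#'
#' Per replicate, the tile value is the mean of its barcode expressions;
#' the combined value is the mean over replicates in which the tile
#' survived filtering.
#'
#' @param table output of [normalize_expression()].
#' @return data.frame of class `tile_expression`: tile_id, one `repN`
#'   column per replicate (NA when absent), `combined`, and `n_barcodes`
#'   (total over replicates).
#' @export
aggregate_tiles <- function(table) {
  if (!"expression" %in% names(table)) stop("run normalize_expression() first")
  reps <- sort(unique(table$replicate))
  tiles <- unique(table$tile_id)
  mat <- matrix(NA_real_, length(tiles), length(reps),
                dimnames = list(tiles, paste0("rep", reps)))
  agg <- tapply(table$expression,
                list(factor(table$tile_id, levels = tiles),
                     factor(table$replicate, levels = reps)),
                mean)
  mat[, ] <- agg
  nbc <- tapply(table$expression,
                factor(table$tile_id, levels = tiles), length)
  out <- data.frame(tile_id = tiles, mat,
                    combined = rowMeans(mat, na.rm = TRUE),
                    n_barcodes = as.integer(nbc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$combined[is.nan(out$combined)] <- NA_real_
  class(out) <- c("tile_expression", "data.frame")
  out
}

#' Quantify tile expression from raw barcode counts
#'
#' Convenience wrapper: [filter_barcodes()], [normalize_expression()],
#' [aggregate_tiles()].
#'
#' @inheritParams filter_barcodes
#' @return a `tile_expression` data.frame.
#' @export
quantify <- function(table, min_count = 3L, min_barcodes = 3L) {
  aggregate_tiles(normalize_expression(
    filter_barcodes(table, min_count = min_count, min_barcodes = min_barcodes)))
}

#' Pairwise Pearson correlation between replicates
#'
#' @param expr a `tile_expression` data.frame.
#' @param min_shared minimum tiles shared by a replicate pair (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(expr, min_shared = 3L) {
  rep_cols <- grep("^rep[0-9]+$", names(expr), value = TRUE)
  if (length(rep_cols) < 2L) stop("need >= 2 replicates")
  m <- as.matrix(expr[, rep_cols])
  n_shared <- crossprod(!is.na(m))
  if (any(n_shared[upper.tri(n_shared)] < min_shared))
    stop("insufficient shared tiles between replicates")
  r <- stats::cor(m, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Read / write tile expression tables as TSV
#'
#' @param expr a `tile_expression` data.frame.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("tile_expression", "data.frame")
  out
}
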