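#' Motif-count feature matrix for activity modelling
#'
#' Strand-agnostic features count each motif's occurrences per tile (18
#' columns for the full roster); strand-aware features split each count by
#' orientation (36 columns). Column order is deterministic: motifs
#' alphabetical, NT before T. By construction the aware matrix summed over
#' orientation equals the agnostic matrix.
#'
#' @param design a `tile_design` data.frame.
#' @param motifs a `motif_roster`.
#' @param strand_aware logical.
#' @return numeric matrix, rownames = tile ids.
#' @export
featurize <- function(design, motifs, strand_aware = TRUE) {
  nm <- sort(motifs$name)
  pls <- strsplit(design$motif_names, ",", fixed = TRUE)
  ors <- strsplit(design$orientations, ",", fixed = TRUE)
  pls[is.na(design$motif_names) | design$motif_names == ""] <- list(character(0L))
  ors[is.na(design$orientations) | design$orientations == ""] <- list(character(0L))
  unknown <- setdiff(unique(unlist(pls)), nm)
  if (length(unknown)) stop("unknown motif(s): ", paste(unknown, collapse = ", "))
  if (strand_aware) {
    cols <- as.vector(t(outer(nm, c("NT", "T"), paste, sep = "|")))
    X <- matrix(0, nrow(design), length(cols),
                dimnames = list(design$tile_id, cols))
    for (i in seq_along(pls)) {
      if (!length(pls[[i]])) next
      key <- paste(pls[[i]], ors[[i]], sep = "|")
      tab <- table(key)
      X[i, names(tab)] <- as.numeric(tab)
    }
  } else {
    X <- matrix(0, nrow(design), length(nm), dimnames = list(design$tile_id, nm))
    for (i in seq_along(pls)) {
      if (!length(pls[[i]])) next
      tab <- table(pls[[i]])
      X[i, names(tab)] <- as.numeric(tab)
    }
  }
  X
}

#' Cross-validated lasso model of tile activity from motif counts
#'
#' Fits an L1-penalized linear model of expression on motif-count features
#' with `folds`-fold outer cross-validation; within each training split the
#' penalty is chosen by inner cross-validation (`glmnet::cv.glmnet`,
#' lambda.min). Held-out predictions from all outer folds are concatenated
#' and summarized by pooled Pearson r and Spearman rho; per-fold Pearson
#' and Spearman values are also reported. Features are standardized inside
#' glmnet and the intercept is unpenalized. An optional background
#' indicator covariate can be added unpenalized (for models pooled over
#' backgrounds with unequal baselines). A final model on the full data
#' supplies the reported coefficients.
#'
#' @param X feature matrix from [featurize()].
#' @param y numeric response (combined tile expression).
#' @param folds outer folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param background optional factor/character of background ids per row.
#' @return object of class `mpra_lasso`: list with `fold_r`, `fold_rho`,
#'   `pooled_r`, `pooled_rho`, `predictions` (data.frame y, yhat, fold),
#'   `coefficients`, `folds`, `seed`, `strand_aware` (guessed from column
#'   names), `fit` (the full-data glmnet fit at the chosen lambda).
#' @export
fit_lasso_cv <- function(X, y, folds = 10L, seed = 1L, background = NULL) {
  stopifnot(nrow(X) == length(y))
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::sd(y) == 0) stop("constant response")
  if (nrow(X) < 10L * folds) stop("need at least 10 rows per fold")
  pen <- rep(1, ncol(X))
  Xm <- X
  if (!is.null(background)) {
    bgf <- factor(background)
    if (nlevels(bgf) > 1L) {
      ind <- stats::model.matrix(~ bgf)[, -1L, drop = FALSE]
      colnames(ind) <- paste0("background:", levels(bgf)[-1L])
      Xm <- cbind(X, ind)
      pen <- c(pen, rep(0, ncol(ind)))
    }
  }
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(Xm)))
  yhat <- numeric(nrow(Xm))
  fold_r <- fold_rho <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    cvfit <- glmnet::cv.glmnet(Xm[tr, , drop = FALSE], y[tr],
                               penalty.factor = pen, nfolds = 5L)
    yhat[!tr] <- as.numeric(stats::predict(cvfit, Xm[!tr, , drop = FALSE],
                                           s = "lambda.min"))
    fold_r[f] <- suppressWarnings(stats::cor(y[!tr], yhat[!tr]))
    fold_rho[f] <- suppressWarnings(stats::cor(y[!tr], yhat[!tr],
                                               method = "spearman"))
  }
  full <- glmnet::cv.glmnet(Xm, y, penalty.factor = pen, nfolds = 5L)
  cf <- as.matrix(stats::coef(full, s = "lambda.min"))
  coefs <- stats::setNames(cf[, 1L], rownames(cf))
  structure(list(
    fold_r = fold_r, fold_rho = fold_rho,
    pooled_r = stats::cor(y, yhat),
    pooled_rho = stats::cor(y, yhat, method = "spearman"),
    predictions = data.frame(tile_id = rownames(X), y = y, yhat = yhat,
                             fold = fold_id, stringsAsFactors = FALSE),
    coefficients = coefs,
    folds = as.integer(folds), seed = as.integer(seed),
    strand_aware = any(grepl("\\|(NT|T)$", colnames(X))),
    fit = full),
    class = "mpra_lasso")
}

#' @method print mpra_lasso
#' @export
print.mpra_lasso <- function(x, ...) {
  cat(sprintf("%s lasso activity model (%d-fold CV, seed %d)\n",
              if (x$strand_aware) "Strand-aware" else "Strand-agnostic",
              x$folds, x$seed))
  cat(sprintf("  pooled held-out r = %.3f, rho = %.3f\n",
              x$pooled_r, x$pooled_rho))
  cat(sprintf("  per-fold r: %s\n",
              paste(sprintf("%.3f", x$fold_r), collapse = " ")))
  nz <- sum(x$coefficients[-1L] != 0)
  cat(sprintf("  %d non-zero coefficients of %d features\n",
              nz, length(x$coefficients) - 1L))
  invisible(x)
}

#' @method coef mpra_lasso
#' @export
coef.mpra_lasso <- function(object, ...) object$coefficients

#' @export
predict.mpra_lasso <- function(object, newx, ...) {
  as.numeric(stats::predict(object$fit, newx, s = "lambda.min"))
}

#' Percent improvement of the strand-aware over the agnostic model
#'
#' `100 * (r_aware - r_agnostic) / r_agnostic` on pooled held-out
#' correlations; both models must come from identical fold assignments
#' (same seed, folds and tile set) or the comparison is refused.
#'
#' @param report_aware,report_agnostic two `mpra_lasso` fits.
#' @return numeric percent improvement (sign preserved).
#' @export
compare_models <- function(report_aware, report_agnostic) {
  if (!identical(report_aware$predictions$fold,
                 report_agnostic$predictions$fold) ||
      !identical(report_aware$predictions$tile_id,
                 report_agnostic$predictions$tile_id))
    stop("models were fitted on different folds or tiles")
  100 * (report_aware$pooled_r - report_agnostic$pooled_r) /
    report_agnostic$pooled_r
}

#' Top model coefficients by magnitude
#'
#' @param report an `mpra_lasso` fit.
#' @param k how many coefficients (default 30); the intercept and any
#'   background covariate are excluded.
#' @param motifs optional `motif_roster` used to flag palindromic motifs.
#' @return data.frame feature, motif, orientation, coefficient,
#'   palindromic; ranked by |coefficient|.
#' @export
top_coefficients <- function(report, k = 30L, motifs = NULL) {
  cf <- report$coefficients
  cf <- cf[!names(cf) %in% "(Intercept)"]
  cf <- cf[!grepl("^background:", names(cf))]
  ord <- order(abs(cf), decreasing = TRUE)
  cf <- cf[ord][seq_len(min(k, length(cf)))]
  if (length(cf) == 0L)
    return(data.frame(feature = character(0L), motif = character(0L),
                      orientation = character(0L), coefficient = numeric(0L),
                      palindromic = logical(0L), stringsAsFactors = FALSE))
  motif <- sub("\\|(NT|T)$", "", names(cf))
  orientation <- ifelse(grepl("\\|NT$", names(cf)), "NT",
                        ifelse(grepl("\\|T$", names(cf)), "T", NA_character_))
  pal <- if (is.null(motifs)) NA else motifs$palindromic[match(motif, motifs$name)]
  data.frame(feature = names(cf), motif = motif, orientation = orientation,
             coefficient = unname(cf), palindromic = pal,
             row.names = NULL, stringsAsFactors = FALSE)
}
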