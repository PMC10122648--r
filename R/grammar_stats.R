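#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` with an explicit family size `m`, which may
#' exceed the number of p-values supplied (screens are corrected for the
#' full analysis family, e.g. 18 motifs or 306 pairs, even when only a
#' subset is computed).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m family size, `m >= length(p)` allowed.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  pmin(1, p * m)
}

# shared constructor for two-group comparison results
.asym_result <- function(groups, x1, x2, p_raw, m_tests, test_name,
                         statistic = NA_real_) {
  mean1 <- mean(x1); mean2 <- mean(x2)
  data.frame(group1 = groups[1L], group2 = groups[2L],
             n1 = length(x1), n2 = length(x2),
             mean1 = mean1, mean2 = mean2,
             # ratio of means on the linear activity scale; difference on log2
             ratio = mean(2^x1) / mean(2^x2),
             difference = mean1 - mean2,
             relative_difference = abs(mean1 - mean2),
             statistic = statistic,
             p_raw = p_raw,
             p_adjusted = bonferroni_adjust(p_raw, m_tests),
             family_m = m_tests,
             test_name = test_name,
             stringsAsFactors = FALSE)
}

#' Orientation strand-asymmetry test
#'
#' Two-sided two-sample t-test comparing tile expression between the
#' non-template and template orientation groups of one motif. The effect is
#' reported two ways: ratio of group means on the linear activity scale
#' (`mean(2^NT) / mean(2^T)`, so "21% higher" statements are well defined)
#' and the difference of means on the log2 scale.
#'
#' @param expr_nt,expr_t numeric expression vectors for the non-template
#'   and template groups (each n >= 2).
#' @param m_tests Bonferroni family size (default 1).
#' @param var_equal Student's pooled-variance t-test when TRUE (default);
#'   Welch when FALSE.
#' @return one-row data.frame (group labels, n, means, ratio, difference,
#'   p_raw, p_adjusted, family_m, test_name).
#' @export
orientation_asymmetry_test <- function(expr_nt, expr_t, m_tests = 1L,
                                       var_equal = TRUE) {
  if (length(expr_nt) < 2L) stop("non-template group has fewer than 2 values")
  if (length(expr_t) < 2L) stop("template group has fewer than 2 values")
  tt <- stats::t.test(expr_nt, expr_t, var.equal = var_equal)
  .asym_result(c("NT", "T"), expr_nt, expr_t, tt$p.value, m_tests,
               if (var_equal) "t" else "welch",
               statistic = unname(tt$statistic))
}

#' Order-effect test for a heterotypic pair
#'
#' Same machinery as [orientation_asymmetry_test()] but the two groups are
#' keyed by TFBS order: tiles where motif A is TSS-proximal ("closest")
#' versus tiles where it is TSS-distal.
#'
#' @param expr_ab,expr_ba expression for the two orders.
#' @inheritParams orientation_asymmetry_test
#' @return one-row data.frame as for [orientation_asymmetry_test()].
#' @export
order_effect_test <- function(expr_ab, expr_ba, m_tests = 1L,
                              var_equal = TRUE) {
  if (length(expr_ab) < 2L || length(expr_ba) < 2L)
    stop("each order group needs >= 2 values")
  tt <- stats::t.test(expr_ab, expr_ba, var.equal = var_equal)
  .asym_result(c("AB", "BA"), expr_ab, expr_ba, tt$p.value, m_tests,
               if (var_equal) "t" else "welch",
               statistic = unname(tt$statistic))
}

#' Levene test for orientation-dependent variance
#'
#' Brown-Forsythe flavor (absolute deviations from the group median) by
#' default, comparing expression variance between the two orientation
#' groups.
#'
#' @param expr_nt,expr_t expression vectors, each n >= 3.
#' @param m_tests Bonferroni family size.
#' @param center "median" (default) or "mean".
#' @return one-row data.frame as for [orientation_asymmetry_test()], with
#'   `test_name = "levene"`.
#' @export
variance_difference_test <- function(expr_nt, expr_t, m_tests = 1L,
                                     center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(expr_nt) < 3L || length(expr_t) < 3L)
    stop("each group needs >= 3 values")
  y <- c(expr_nt, expr_t)
  g <- factor(rep(c("NT", "T"), c(length(expr_nt), length(expr_t))))
  lv <- car::leveneTest(y, g, center = if (center == "median") stats::median else mean)
  .asym_result(c("NT", "T"), expr_nt, expr_t, lv[["Pr(>F)"]][1L], m_tests,
               "levene", statistic = lv[["F value"]][1L])
}

#' Spearman trend of expression in copy number
#'
#' @param copies integer copy numbers per tile (>= 3 distinct levels).
#' @param expression matching expression values.
#' @param m_tests Bonferroni family size.
#' @return one-row data.frame: predictor, rho, p_raw, p_adjusted, family_m,
#'   n; `rho` is NA with `degenerate = TRUE` when expression is constant.
#' @export
copy_number_trend <- function(copies, expression, m_tests = 1L) {
  stopifnot(length(copies) == length(expression))
  if (length(unique(copies)) < 3L) stop("need >= 3 distinct copy levels")
  .trend_result("copies", copies, expression, m_tests)
}

.trend_result <- function(predictor, x, y, m_tests) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(data.frame(predictor = predictor, rho = NA_real_, p_raw = NA_real_,
                      p_adjusted = NA_real_, family_m = m_tests,
                      n = length(y), degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(predictor = predictor, rho = unname(ct$estimate),
             p_raw = ct$p.value,
             p_adjusted = bonferroni_adjust(ct$p.value, m_tests),
             family_m = m_tests, n = length(y), degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Positional trend of expression toward the TSS
#'
#' Spearman correlation between position-bin midpoint and expression, plus
#' the percent change of the mean linear activity in the TSS-proximal bin
#' (\[-40, 0)) relative to the TSS-distal bin (\[-200, -160)), the headline
#' position statistic.
#'
#' @param position_bin lower edge of each tile's position bin (negative bp
#'   upstream of the TSS, e.g. -200, -160, ..., -40).
#' @param expression matching expression values.
#' @param m_tests Bonferroni family size.
#' @param near_bin,far_bin lower edges of the comparison bins (-40, -200).
#' @return one-row data.frame: trend columns plus `percent_change` (NA with
#'   `percent_change_defined = FALSE` if the reference bin is empty).
#' @export
position_trend <- function(position_bin, expression, m_tests = 1L,
                           near_bin = -40, far_bin = -200) {
  stopifnot(length(position_bin) == length(expression))
  if (length(unique(position_bin)) < 3L) stop("need >= 3 populated bins")
  out <- .trend_result("position_bin", position_bin, expression, m_tests)
  near <- expression[position_bin == near_bin]
  far <- expression[position_bin == far_bin]
  if (length(far) && length(near)) {
    out$percent_change <- 100 * (mean(2^near) / mean(2^far) - 1)
    out$percent_change_defined <- TRUE
  } else {
    out$percent_change <- NA_real_
    out$percent_change_defined <- FALSE
  }
  out
}

#' Monte-Carlo test for copy-number gain in orientation asymmetry
#'
#' Tests whether the absolute expression difference between orientations is
#' larger at four copies than at one. The observed statistic is
#' `|mean(NT4) - mean(T4)| - |mean(NT1) - mean(T1)|`; the null is built by
#' permuting orientation labels independently within each copy-number
#' stratum, and the one-sided p-value is `(1 + #{null >= observed}) /
#' (1 + n_perm)`.
#'
#' @param nt1,t1 expression at one copy, by orientation (n >= 2 each).
#' @param nt4,t4 expression at four copies, by orientation (n >= 2 each).
#' @param n_perm permutations (>= 100; default 10000).
#' @param seed integer seed.
#' @return list with `observed`, `p_value`, `n_perm`.
#' @export
monte_carlo_gain_test <- function(nt1, t1, nt4, t4, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (min(length(nt1), length(t1), length(nt4), length(t4)) < 2L)
    stop("each of the four groups needs >= 2 values")
  obs <- abs(mean(nt4) - mean(t4)) - abs(mean(nt1) - mean(t1))
  p1 <- c(nt1, t1); p4 <- c(nt4, t4)
  k1 <- length(nt1); k4 <- length(nt4)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    s1 <- sample.int(length(p1), k1)
    s4 <- sample.int(length(p4), k4)
    abs(mean(p4[s4]) - mean(p4[-s4])) - abs(mean(p1[s1]) - mean(p1[-s1]))
  }, numeric(1L))
  list(observed = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}

#' One-way ANOVA over orientation/order configuration groups
#'
#' Used for the four pair-orientation groups, the eight triplet-orientation
#' groups and the three triplet-slot groups. Groups with fewer than 2
#' values are dropped with a warning.
#'
#' @param groups named list mapping configuration label to expression
#'   vector.
#' @param m_tests Bonferroni family size.
#' @return one-row data.frame: k (groups used), n, F statistic, p_raw,
#'   p_adjusted, family_m; a degenerate fit (zero within- and
#'   between-group variance) is flagged with `degenerate = TRUE`.
#' @export
config_anova <- function(groups, m_tests = 1L) {
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warning("dropping group(s) with n < 2: ",
            paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) stop("need >= 2 groups with n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (stats::sd(y) == 0) {
    return(data.frame(k = length(groups), n = length(y),
                      statistic = 0, p_raw = NA_real_, p_adjusted = NA_real_,
                      family_m = m_tests, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  data.frame(k = length(groups), n = length(y),
             statistic = unname(ft$statistic), p_raw = ft$p.value,
             p_adjusted = bonferroni_adjust(ft$p.value, m_tests),
             family_m = m_tests, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Association between motif GC skew and orientation asymmetry
#'
#' Kendall tau between per-motif [gc_skew()] (or any skew measure) and the
#' per-motif orientation-dependent expression difference.
#'
#' @param skews numeric vector, one per motif (>= 5 motifs).
#' @param asymmetries matching orientation expression differences.
#' @return one-row data.frame: tau, p_raw, n.
#' @export
skew_asymmetry_association <- function(skews, asymmetries) {
  stopifnot(length(skews) == length(asymmetries))
  if (length(skews) < 5L) stop("need >= 5 motifs")
  ct <- suppressWarnings(stats::cor.test(skews, asymmetries, method = "kendall"))
  data.frame(tau = unname(ct$estimate), p_raw = ct$p.value,
             n = length(skews), stringsAsFactors = FALSE)
}

# ---- design-aware screen helpers -------------------------------------------

# join expression onto design and keep homotypic tiles of one motif
.homotypic_subset <- function(design, expr, motif) {
  d <- design[design$category == "homotypic" & design$motif_names != "", ]
  first <- sub(",.*$", "", d$motif_names)
  pure <- vapply(strsplit(d$motif_names, ",", fixed = TRUE),
                 function(x) length(unique(x)) == 1L, logical(1L))
  d <- d[pure & first == motif, , drop = FALSE]
  d$combined <- expr$combined[match(d$tile_id, expr$tile_id)]
  d[!is.na(d$combined), , drop = FALSE]
}

#' Per-motif homotypic orientation screen
#'
#' For each motif, compares expression of homotypic tiles whose copies are
#' all non-template against tiles whose copies are all template
#' ([orientation_asymmetry_test()]), Bonferroni-corrected over the motif
#' family.
#'
#' @param design a `tile_design`.
#' @param expr a `tile_expression`.
#' @param motifs a `motif_roster`.
#' @param var_equal passed through to the t-test.
#' @return data.frame, one row per testable motif.
#' @export
orientation_screen <- function(design, expr, motifs, var_equal = TRUE) {
  m_tests <- nrow(motifs)
  rows <- lapply(motifs$name, function(m) {
    d <- .homotypic_subset(design, expr, m)
    if (nrow(d) == 0L) return(NULL)
    ors <- strsplit(d$orientations, ",", fixed = TRUE)
    all_nt <- vapply(ors, function(o) all(o == "NT"), logical(1L))
    all_t <- vapply(ors, function(o) all(o == "T"), logical(1L))
    nt <- d$combined[all_nt]; t_ <- d$combined[all_t]
    if (length(nt) < 2L || length(t_) < 2L) return(NULL)
    cbind(motif = m,
          orientation_asymmetry_test(nt, t_, m_tests = m_tests,
                                     var_equal = var_equal),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-motif copy-number trend screen
#'
#' Spearman trend of combined expression in homotypic copy number, per
#' motif, Bonferroni over the motif family.
#'
#' @inheritParams orientation_screen
#' @return data.frame, one row per testable motif.
#' @export
copy_number_screen <- function(design, expr, motifs) {
  m_tests <- nrow(motifs)
  rows <- lapply(motifs$name, function(m) {
    d <- .homotypic_subset(design, expr, m)
    if (nrow(d) == 0L) return(NULL)
    copies <- lengths(strsplit(d$motif_names, ",", fixed = TRUE))
    if (length(unique(copies)) < 3L) return(NULL)
    cbind(motif = m, copy_number_trend(copies, d$combined, m_tests = m_tests),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
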