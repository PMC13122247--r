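# Criterion-sweep Type-2 ROC metacognitive sensitivity, multivariate outlier
# screening and the AUROC2 ~ AQ correlation analyses.

#' Criterion-sweep Type-2 ROC curve
#'
#' Each confidence level on the 11-point 0-100 grid is taken as a criterion
#' separating low from high confidence: starting where only a rating of 0 is
#' low confidence, the criterion is raised until only the maximum rating
#' counts as high. For each criterion the hit rate
#' `H = P(high confidence | correct)` and false-alarm rate
#' `F = P(high confidence | incorrect)` are recorded; the anchors (0,0) and
#' (1,1) close the curve.
#'
#' @param confidence integer ratings on the 0-100 grid (steps of 10).
#' @param correct binary correctness (0/1 or logical).
#' @return Object of class `type2_roc`: list with `curve` (data.frame
#'   `criterion`, `fa`, `hit`, anchored), `n_correct`, `n_incorrect`,
#'   `defined`. The curve is undefined (flag, not an error) when either
#'   outcome class is empty.
#' @export
type2_roc <- function(confidence, correct) {
  correct <- as.integer(correct)
  stopifnot(length(confidence) == length(correct),
            all(correct %in% c(0L, 1L)))
  if (!all(confidence %in% CONFIDENCE_GRID)) {
    stop("confidence must be on the 0-100 grid in steps of 10",
         call. = FALSE)
  }
  n1 <- sum(correct == 1L)
  n0 <- sum(correct == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(structure(list(curve = NULL, n_correct = n1, n_incorrect = n0,
                          defined = FALSE), class = "type2_roc"))
  }
  # criterion c: "high confidence" means rating >= c; c = 0 gives the (1,1)
  # anchor, c = Inf the (0,0) anchor.
  criteria <- c(CONFIDENCE_GRID, Inf)
  hit <- vapply(criteria, function(c) mean(confidence[correct == 1L] >= c),
                numeric(1))
  fa <- vapply(criteria, function(c) mean(confidence[correct == 0L] >= c),
               numeric(1))
  curve <- data.frame(criterion = criteria, fa = fa, hit = hit)
  structure(list(curve = curve, n_correct = n1, n_incorrect = n0,
                 defined = TRUE), class = "type2_roc")
}

#' @export
print.type2_roc <- function(x, ...) {
  if (!x$defined) {
    cat("Type-2 ROC: undefined (", x$n_correct, "correct /", x$n_incorrect,
        "incorrect trials)\n")
  } else {
    cat("Type-2 ROC over", nrow(x$curve), "criteria;",
        x$n_correct, "correct /", x$n_incorrect, "incorrect trials\n")
    print(x$curve, row.names = FALSE)
  }
  invisible(x)
}

#' Area under the Type-2 ROC curve
#'
#' Trapezoidal area over the anchored criterion-sweep curve; 0.5 indicates
#' confidence carrying no information about correctness, 1 perfect
#' metacognitive sensitivity.
#'
#' @param x a [type2_roc()] object, or a confidence vector (with `correct`
#'   supplied) for convenience.
#' @param correct correctness vector when `x` is raw confidences.
#' @return AUROC2 in `[0, 1]`, or `NA` when the curve is undefined.
#' @export
auroc2 <- function(x, correct = NULL) {
  if (!inherits(x, "type2_roc")) x <- type2_roc(x, correct)
  if (!x$defined) return(NA_real_)
  cv <- x$curve[order(x$curve$fa, x$curve$hit), ]
  sum(diff(cv$fa) * (utils::head(cv$hit, -1) + utils::tail(cv$hit, -1)) / 2)
}

#' Pairwise-comparison oracle for AUROC2
#'
#' Independent route to the same quantity: over all (correct, incorrect)
#' trial pairs, the fraction in which the correct trial carries the higher
#' confidence, counting ties as 1/2. Used to cross-check the trapezoidal
#' criterion sweep; agreement is exact for ratings on a shared grid.
#'
#' @param confidence ratings on the 0-100 grid.
#' @param correct binary correctness.
#' @return Value in `[0, 1]`, or `NA` when no pairs exist.
#' @export
auroc2_pairwise <- function(confidence, correct) {
  correct <- as.integer(correct)
  cc <- confidence[correct == 1L]
  ci <- confidence[correct == 0L]
  if (!length(cc) || !length(ci)) return(NA_real_)
  cmp <- outer(cc, ci, ">") + 0.5 * outer(cc, ci, "==")
  mean(cmp)
}

#' Per-subject AUROC2 table
#'
#' @param trials single-task trial table with confidence ratings. For the
#'   implicit task, pass object-present trials to match the accuracy
#'   analyses.
#' @return data.frame with `subject_id`, `auroc2`, `n_correct`,
#'   `n_incorrect`, `defined`.
#' @export
subject_auroc2 <- function(trials) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(s) {
    st <- trials[trials$subject_id == s, ]
    roc <- type2_roc(st$confidence, st$correct)
    data.frame(subject_id = s, auroc2 = auroc2(roc),
               n_correct = roc$n_correct, n_incorrect = roc$n_incorrect,
               defined = roc$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mahalanobis multivariate outlier screen
#'
#' Squared Mahalanobis distance of each point from the sample mean under the
#' sample covariance, flagged against the chi-square quantile (df = number
#' of variables) at the given alpha. Default use: the bivariate
#' (AQ, AUROC2) plane before the trait correlations.
#'
#' @param x numeric matrix or data.frame of points (rows = subjects).
#' @param alpha tail probability of the chi-square cutoff (default 0.025).
#' @return list with `distance` (squared distances), `outlier` (logical),
#'   `cutoff`, `alpha`.
#' @export
mahalanobis_outliers <- function(x, alpha = 0.025) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (anyNA(x)) stop("points contain NA; drop undefined subjects first",
                     call. = FALSE)
  S <- stats::cov(x)
  if (rcond(S) < 1e-12) stop("singular sample covariance", call. = FALSE)
  d2 <- stats::mahalanobis(x, colMeans(x), S)
  cutoff <- stats::qchisq(1 - alpha, df = ncol(x))
  list(distance = d2, outlier = d2 > cutoff, cutoff = cutoff, alpha = alpha)
}

#' Spearman rank correlation with t-approximation inference
#'
#' Rho is the Pearson correlation of tie-averaged ranks;
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `df = n - 2` and a two-sided
#' p from the t distribution. A permutation p-value (rho permutation null)
#' is available instead of the t approximation.
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list with `rho`, `t`, `df`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 10000L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined")
    return(list(rho = NA_real_, t = NA_real_, df = n - 2L, p = NA_real_,
                n = n, method = method))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p_t <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_t <- 2 * stats::pt(-abs(tstat), n - 2L)
  }
  p <- p_t
  if (method == "permutation") {
    perm <- vapply(seq_len(n_perm),
                   function(i) stats::cor(rx, sample(ry)), numeric(1))
    p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  }
  list(rho = rho, t = tstat, df = n - 2L, p = p, n = n, method = method)
}

#' Median-split group comparison of metacognitive sensitivity
#'
#' Splits subjects at the sample median of AQ (ties to the low group) and
#' compares the two groups' values with a Welch two-sample t test. Both the
#' two-sided p and the one-sided p for the high group scoring lower are
#' reported.
#'
#' @param values per-subject values (e.g. AUROC2).
#' @param aq_scores per-subject AQ totals, same order.
#' @return list with `median`, `mean_low`, `mean_high`, `n_low`, `n_high`,
#'   `t`, `df`, `p_two_sided`, `p_one_sided` (high < low).
#' @export
median_split_compare <- function(values, aq_scores) {
  stopifnot(length(values) == length(aq_scores))
  med <- stats::median(aq_scores)
  low <- aq_scores <= med
  if (sum(low) < 2L || sum(!low) < 2L) {
    stop("median split leaves fewer than 2 subjects in a group",
         call. = FALSE)
  }
  tt <- stats::t.test(values[!low], values[low])
  t1 <- stats::t.test(values[!low], values[low], alternative = "less")
  list(median = med,
       mean_low = mean(values[low]), mean_high = mean(values[!low]),
       n_low = sum(low), n_high = sum(!low),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, p_one_sided = t1$p.value)
}

#' AUROC2 ~ AQ correlation analysis for one task
#'
#' Per-subject AUROC2, Mahalanobis screening on the (AQ, AUROC2) plane,
#' Spearman correlations with and without the flagged outliers, and the
#' AQ median-split comparison. Subjects with undefined AUROC2 (no correct or
#' no incorrect trials) are dropped with a recorded count.
#'
#' @param trials single-task trials (implicit: object-present rows).
#' @param subjects subject table with `aq_score`.
#' @param alpha Mahalanobis chi-square tail (default 0.025).
#' @return list with `auroc2` (per-subject table incl. `aq_score`,
#'   `outlier`), `n_undefined`, `cor_excluded`, `cor_all`, `median_split`
#'   (on the outlier-screened set), `alpha`.
#' @export
metacog_analysis <- function(trials, subjects, alpha = 0.025) {
  tab <- subject_auroc2(trials)
  subjects <- validate_subjects(subjects)
  tab$aq_score <- subjects$aq_score[match(tab$subject_id,
                                          subjects$subject_id)]
  if (anyNA(tab$aq_score)) stop("trials reference subjects without AQ",
                                call. = FALSE)
  n_undef <- sum(!tab$defined)
  def <- tab[tab$defined, ]
  mh <- mahalanobis_outliers(def[, c("aq_score", "auroc2")], alpha = alpha)
  def$outlier <- mh$outlier
  keep <- def[!def$outlier, ]
  list(
    auroc2 = def,
    n_undefined = n_undef,
    n_outliers = sum(def$outlier),
    cor_excluded = spearman_test(keep$auroc2, keep$aq_score),
    cor_all = spearman_test(def$auroc2, def$aq_score),
    median_split = median_split_compare(keep$auroc2, keep$aq_score),
    alpha = alpha
  )
}
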