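# ROI definition, per-condition summaries and the statistical comparison
# layer: Student t-tests and Cohen's d effect sizes with the published
# category breakpoints (moderate [0.8, 1.5), strong [1.5, 2),
# very strong [2, Inf); |d| below 0.8 is negligible).

#' Define regions of interest over an image
#'
#' The default scheme splits the image into 4 quadrants. For odd dimensions
#' the split puts the extra row/column into the first half (deterministic;
#' reported with a message when the areas are unequal).
#'
#' @param image_shape Integer `c(rows, cols)`.
#' @param scheme `"quadrants"` or `"custom"`.
#' @param masks For `scheme = "custom"`: list of logical matrices; they must
#'   be pairwise disjoint.
#' @return An object of class `roi_set`: list with `masks` (named list of
#'   logical matrices) and `scheme`.
#' @export
define_rois <- function(image_shape, scheme = c("quadrants", "custom"),
                        masks = NULL) {
  scheme <- match.arg(scheme)
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  if (scheme == "quadrants") {
    r <- image_shape[1]; c <- image_shape[2]
    r1 <- ceiling(r / 2); c1 <- ceiling(c / 2)
    rows1 <- seq_len(r1); rows2 <- setdiff(seq_len(r), rows1)
    cols1 <- seq_len(c1); cols2 <- setdiff(seq_len(c), cols1)
    mk <- function(rr, cc) {
      m <- matrix(FALSE, r, c); m[rr, cc] <- TRUE; m
    }
    masks <- list(q1 = mk(rows1, cols1), q2 = mk(rows1, cols2),
                  q3 = mk(rows2, cols1), q4 = mk(rows2, cols2))
    areas <- vapply(masks, sum, 0L)
    if (length(unique(areas)) > 1L)
      message("define_rois: odd image dimensions; quadrant areas {",
              paste(areas, collapse = ", "), "}")
  } else {
    stopifnot(is.list(masks), length(masks) >= 1L)
    tot <- matrix(0L, image_shape[1], image_shape[2])
    for (m in masks) {
      stopifnot(is.logical(m), all(dim(m) == image_shape))
      tot <- tot + m
    }
    if (any(tot > 1L)) stop("custom ROI masks overlap")
    if (is.null(names(masks)))
      names(masks) <- paste0("roi", seq_along(masks))
  }
  structure(list(masks = masks, scheme = scheme), class = "roi_set")
}

#' Summarize a parametric map over ROIs
#'
#' Mean, SD and count over QC-valid pixels of each ROI. ROIs with no valid
#' pixels are flagged (NA mean/SD, n = 0) rather than fatal.
#'
#' @param map A [parametric_map()] (QC-failed pixels are `NA`).
#' @param rois A [define_rois()] result.
#' @param qc_mask Optional logical matrix of additionally valid pixels.
#' @return A data.frame with columns `roi`, `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_parameter <- function(map, rois, qc_mask = NULL) {
  stopifnot(inherits(map, "parametric_map"), inherits(rois, "roi_set"))
  vals <- map$values
  valid <- is.finite(vals)
  if (!is.null(qc_mask)) valid <- valid & (qc_mask %in% TRUE)
  rows <- lapply(names(rois$masks), function(nm) {
    sel <- rois$masks[[nm]] & valid
    v <- vals[sel]
    data.frame(roi = nm, parameter = map$name,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Effect-size category from |d|
#'
#' Pure step function with the published breakpoints: `negligible` below 0.8,
#' `moderate` in `[0.8, 1.5)`, `strong` in `[1.5, 2)`, `very_strong` at 2 and
#' above.
#'
#' @param d Cohen's d (vectorized; the absolute value is categorized).
#' @return Character vector of categories.
#' @export
effect_size_category <- function(d) {
  a <- abs(d)
  out <- rep("negligible", length(a))
  out[a >= 0.8] <- "moderate"
  out[a >= 1.5] <- "strong"
  out[a >= 2] <- "very_strong"
  out[is.na(a)] <- NA_character_
  out
}

#' Cohen's d effect size with Student t-test
#'
#' Classic pooled-SD Cohen's d,
#' \eqn{d = (\bar x_a - \bar x_b)/s_p} with
#' \eqn{s_p^2 = ((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}, plus a two-sample
#' Student (equal-variance) t-test p-value and the effect-size category.
#' A zero pooled SD with unequal means yields `d = Inf` (category
#' `very_strong`); with equal means, `d = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's t-test instead of Student's (default FALSE).
#' @return An object of class `effect_size`: `d`, `category`, `p_value`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' cohens_d(c(-1, 0, 1, 0), c(0, 1, 2, 1))
#' @export
cohens_d <- function(group_a, group_b, welch = FALSE) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  dm <- mean(a) - mean(b)
  d <- if (sp2 > 0) dm / sqrt(sp2) else if (dm == 0) 0 else Inf * sign(dm)
  p <- if (sp2 > 0 || stats::var(a) + stats::var(b) > 0)
    stats::t.test(a, b, var.equal = !welch)$p.value
  else if (dm == 0) 1 else 0
  structure(list(d = d, category = effect_size_category(d), p_value = p,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s), p = %.3g (n = %d, %d)\n",
              x$d, x$category, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Pairwise condition comparisons
#'
#' Runs all contrasts of a plan over ROI-level replicate values: for each
#' (condition pair, parameter), a Student t-test and Cohen's d with category.
#' A contrast is flagged `reportable` only when the category is at least
#' moderate (mirroring the convention of showing p-values only for moderate
#' to very strong effect sizes).
#'
#' @param values Data.frame of ROI-level values with columns `condition`,
#'   `parameter`, `value` (one row per ROI replicate).
#' @param plan Optional data.frame with columns `condition_a`, `condition_b`;
#'   default: all unordered condition pairs.
#' @param welch Passed to [cohens_d()].
#' @return A data.frame with columns `condition_a`, `condition_b`,
#'   `parameter`, `mean_a`, `mean_b`, `d`, `category`, `p`, `reportable`.
#'   Contrasts where a condition lacks a parameter (or has < 2 replicates)
#'   are skipped with a warning.
#' @export
compare_conditions <- function(values, plan = NULL, welch = FALSE) {
  stopifnot(all(c("condition", "parameter", "value") %in% names(values)))
  conds <- unique(values$condition)
  if (is.null(plan)) {
    if (length(conds) < 2) stop("need at least 2 conditions")
    plan <- do.call(rbind, utils::combn(conds, 2, function(p)
      data.frame(condition_a = p[1], condition_b = p[2],
                 stringsAsFactors = FALSE), simplify = FALSE))
  }
  params <- unique(values$parameter)
  rows <- list()
  for (k in seq_len(nrow(plan))) {
    ca <- plan$condition_a[k]; cb <- plan$condition_b[k]
    for (pp in params) {
      va <- values$value[values$condition == ca & values$parameter == pp]
      vb <- values$value[values$condition == cb & values$parameter == pp]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) < 2 || length(vb) < 2) {
        warning("contrast ", ca, " vs ", cb, " skipped for '", pp,
                "': fewer than 2 replicates", call. = FALSE)
        next
      }
      es <- cohens_d(va, vb, welch = welch)
      rows[[length(rows) + 1L]] <- data.frame(
        condition_a = ca, condition_b = cb, parameter = pp,
        mean_a = es$mean_a, mean_b = es$mean_b, d = es$d,
        category = es$category, p = es$p_value,
        reportable = es$category != "negligible",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(condition_a = character(), condition_b = character(),
                      parameter = character(), mean_a = numeric(),
                      mean_b = numeric(), d = numeric(),
                      category = character(), p = numeric(),
                      reportable = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
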