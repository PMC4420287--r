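# Per-group differential-abundance statistics on the raw intensity scale:
# fold changes (case mean / control mean), Welch t-tests, the "at least
# 2-fold and P < alpha" selection filter, CV quality control, and pairwise
# ANOVA with Bonferroni correction. Gene-level collapse of multi-spot
# proteins (isoform spot trains) uses the minimum p-value by default.

#' Differential filter parameters
#'
#' @param fold_threshold ratio-scale fold-change cutoff (> 1). A protein is
#'   fold-selected when its fold is `>= fold_threshold` or
#'   `<= 1/fold_threshold`; the boundary is inclusive ("at least 2-fold").
#' @param alpha two-sided significance level in (0, 1).
#' @param min_obs_per_group minimum non-missing observations per side for a
#'   protein to be testable.
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(fold_threshold = 2, alpha = 0.05,
                          min_obs_per_group = 3) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 1) {
    stop("`fold_threshold` must be > 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  structure(list(fold_threshold = fold_threshold, alpha = alpha,
                 min_obs_per_group = as.integer(min_obs_per_group)),
            class = "filter_params")
}

#' Fold change between two groups of intensities
#'
#' Ratio of the case mean to the control mean on the raw intensity scale;
#' missing values are skipped.
#'
#' @param case_values,control_values numeric vectors (`NA` = missing).
#' @return the fold change (positive real; 1 means no change).
#' @export
#' @examples
#' fold_change(c(180, 220), c(90, 110))  # 2
fold_change <- function(case_values, control_values) {
  mc <- mean(case_values, na.rm = TRUE)
  mk <- mean(control_values, na.rm = TRUE)
  if (!is.finite(mc)) stop("all case values missing", call. = FALSE)
  if (!is.finite(mk)) stop("all control values missing", call. = FALSE)
  if (mk <= 0) stop("fold change undefined: control mean is not positive",
                    call. = FALSE)
  mc / mk
}

# Vectorised Welch statistics for matrices with matching rows
# (proteins x samples); returns n per side, means, t, df and two-sided p.
# Degenerate rows (zero pooled variance): equal means -> p = 1, unequal
# means -> p floored at 1e-300 so p stays in (0, 1].
welch_rows <- function(x, y) {
  nx <- rowSums(!is.na(x))
  ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / pmax(nx - 1, 1) + (vy / ny)^2 / pmax(ny - 1, 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- is.finite(mx) & is.finite(my) & se2 == 0
  p[zero_var & mx == my] <- 1
  tstat[zero_var & mx == my] <- 0
  p[zero_var & mx != my] <- 1e-300
  p <- clamp(p, 1e-300, 1)
  list(n_case = nx, n_control = ny, mean_case = mx, mean_control = my,
       statistic = tstat, df = df, p = p)
}

#' Welch two-sample t-test p-value
#'
#' Independent-samples t-test with the Welch (unequal-variance)
#' approximation, the safer default for the unequal group sizes typical of
#' clinical cohorts. Two identical constant groups give p = 1.
#'
#' @param case_values,control_values numeric vectors (`NA` = missing).
#' @param min_obs minimum non-missing observations required per side.
#' @return two-sided p-value in (0, 1].
#' @export
independent_t_test <- function(case_values, control_values, min_obs = 3) {
  nx <- sum(!is.na(case_values))
  ny <- sum(!is.na(control_values))
  if (nx < min_obs || ny < min_obs) {
    stop(sprintf("t-test needs >= %d observations per group (got %d case, %d control)",
                 min_obs, nx, ny), call. = FALSE)
  }
  welch_rows(matrix(case_values, nrow = 1), matrix(control_values, nrow = 1))$p
}

#' Coefficient of variation, in percent
#'
#' `100 * sample sd / mean`; the gel-to-gel reproducibility metric used for
#' spot-abundance quality control. Scale-invariant: `cv(c * x) == cv(x)`.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return CV as a percentage.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 3))  # 70.71
coefficient_of_variation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("CV needs >= 2 non-missing values", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(v) / m
}

#' Apply the fold-change and significance selection filter
#'
#' Keeps records at least `fold_threshold`-fold changed in either direction
#' (boundary inclusive) with `p < alpha`. Idempotent and order-invariant.
#'
#' @param stats data.frame with columns `fold` and `p`.
#' @param params a [filter_params] object.
#' @return the selected subset of `stats`.
#' @export
two_fold_filter <- function(stats, params = filter_params()) {
  keep <- (stats$fold >= params$fold_threshold |
             stats$fold <= 1 / params$fold_threshold) &
    stats$p < params$alpha
  stats[keep, , drop = FALSE]
}

#' Per-gene differential statistics for one group versus control
#'
#' Computes, for every testable protein, the fold change and Welch t-test
#' p-value of `group` samples against the (pooled) control samples, maps
#' proteins to genes, and collapses multi-spot genes. The full gene list with
#' p-values — not just the selected subset — is what the subnetwork search
#' consumes; `selected` marks the records passing [two_fold_filter()].
#'
#' @param study an [intensity_study].
#' @param map a [protein_gene_map]. Unmapped proteins are excluded with a
#'   message reporting the count (also in attribute `n_unmapped`).
#' @param group case group label.
#' @param control_group one or more control group labels. With
#'   `combine_controls = TRUE` (default) they are pooled into a single
#'   control; otherwise a named list of per-control tables is returned.
#' @param params a [filter_params].
#' @param collapse how to collapse multiple spots mapping to one gene:
#'   `"min"` (default; the minimum p-value and the fold of that spot — the
#'   most significantly changing isoform represents the gene) or `"mean"`
#'   (mean p and mean fold).
#' @param combine_controls pool control groups before testing?
#' @return data.frame with columns `gene, group, fold, p, selected` (and
#'   attribute `n_unmapped`), or a named list of such data.frames when
#'   `combine_controls = FALSE`.
#' @export
group_differential <- function(study, map, group, control_group,
                               params = filter_params(),
                               collapse = c("min", "mean"),
                               combine_controls = TRUE) {
  stopifnot(inherits(study, "intensity_study"))
  collapse <- match.arg(collapse)
  present <- unique(study$groups)
  for (g in c(group, control_group)) {
    if (!g %in% present) stop("group not in study: ", g, call. = FALSE)
  }
  if (!combine_controls && length(control_group) > 1L) {
    res <- lapply(control_group, function(cg) {
      group_differential(study, map, group, cg, params, collapse, TRUE)
    })
    names(res) <- control_group
    return(res)
  }
  case <- group_matrix(study, group)
  ctrl <- group_matrix(study, control_group)

  pid <- rownames(study$intensities)
  mapped <- pid %in% names(map)
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L) {
    message(sprintf("group_differential: excluded %d unmapped protein(s)",
                    n_unmapped))
  }
  case <- case[mapped, , drop = FALSE]
  ctrl <- ctrl[mapped, , drop = FALSE]
  pid <- pid[mapped]

  w <- welch_rows(case, ctrl)
  testable <- w$n_case >= params$min_obs_per_group &
    w$n_control >= params$min_obs_per_group & w$mean_control > 0
  if (!any(testable)) stop("no testable proteins for group ", group, call. = FALSE)

  d <- data.frame(protein_id = pid[testable],
                  gene = as.character(unclass(map)[pid[testable]]),
                  fold = (w$mean_case / w$mean_control)[testable],
                  p = w$p[testable],
                  stringsAsFactors = FALSE)
  if (collapse == "min") {
    ord <- order(d$gene, d$p, method = "radix")
    d <- d[ord, , drop = FALSE]
    d <- d[!duplicated(d$gene), , drop = FALSE]
  } else {
    fold <- tapply(d$fold, d$gene, mean)
    p <- tapply(d$p, d$gene, mean)
    d <- data.frame(gene = names(fold), fold = as.numeric(fold),
                    p = as.numeric(p), stringsAsFactors = FALSE)
  }
  out <- data.frame(gene = d$gene, group = group, fold = d$fold, p = d$p,
                    stringsAsFactors = FALSE)
  out$selected <- (out$fold >= params$fold_threshold |
                     out$fold <= 1 / params$fold_threshold) &
    out$p < params$alpha
  out <- out[order(out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Pairwise group comparisons with one-way ANOVA and Bonferroni correction
#'
#' For each protein: a one-way ANOVA F-test across all groups, followed by
#' all pairwise Welch comparisons with each pairwise p-value multiplied by
#' the number of pairs (capped at 1).
#'
#' @param study an [intensity_study].
#' @param params a [filter_params]; proteins need
#'   `>= min_obs_per_group` non-missing values in every group.
#' @return data.frame with columns `protein_id, anova_p, group_a, group_b,
#'   p_raw, p_corr` (one row per protein and group pair).
#' @export
anova_pairwise <- function(study, params = filter_params()) {
  stopifnot(inherits(study, "intensity_study"))
  grps <- sort(unique(study$groups))
  if (length(grps) < 2L) stop("need >= 2 groups", call. = FALSE)
  mats <- lapply(grps, function(g) group_matrix(study, g))
  names(mats) <- grps
  counts <- vapply(mats, function(m) rowSums(!is.na(m)), numeric(nrow(study$intensities)))
  testable <- apply(counts >= params$min_obs_per_group, 1L, all)
  if (!any(testable)) stop("no proteins testable in all groups", call. = FALSE)
  mats <- lapply(mats, function(m) m[testable, , drop = FALSE])
  pid <- rownames(study$intensities)[testable]

  # one-way ANOVA per protein, vectorised from group sums
  ns <- vapply(mats, function(m) rowSums(!is.na(m)), numeric(length(pid)))
  means <- vapply(mats, function(m) rowMeans(m, na.rm = TRUE), numeric(length(pid)))
  ss_within <- Reduce(`+`, lapply(seq_along(mats), function(i) {
    rowSums((mats[[i]] - means[, i])^2, na.rm = TRUE)
  }))
  n_tot <- rowSums(ns)
  grand <- rowSums(ns * means) / n_tot
  ss_between <- rowSums(ns * (means - grand)^2)
  df1 <- length(grps) - 1L
  df2 <- n_tot - length(grps)
  f <- (ss_between / df1) / (ss_within / df2)
  anova_p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  anova_p[ss_within == 0 & ss_between == 0] <- 1

  pairs <- utils::combn(grps, 2L)
  m_pairs <- ncol(pairs)
  rows <- lapply(seq_len(m_pairs), function(j) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    w <- welch_rows(mats[[a]], mats[[b]])
    data.frame(protein_id = pid, anova_p = anova_p, group_a = a, group_b = b,
               p_raw = w$p, p_corr = pmin(1, m_pairs * w$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$group_a, out$group_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}
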