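#' One-way ANOVA across groups
#'
#' Classic fixed-effects between/within decomposition: `F = MSB/MSW` with the
#' p-value from the F distribution (computed via [stats::oneway.test()] with
#' equal variances).
#'
#' @param groups named list of numeric vectors, one per group (each `n >= 2`).
#' @return A list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) stop("group values must be finite", call. = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
  msb <- sum(ns * (vapply(groups, mean, numeric(1L)) - mean(y))^2)
  if (msw == 0 && msb > 0)
    stop("degenerate within-group variance (MSW = 0)", call. = FALSE)
  if (msw == 0 && msb == 0)
    return(list(F = 0, df_between = length(groups) - 1L,
                df_within = length(y) - length(groups), p = 1))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df_between = unname(fit$parameter[1L]),
       df_within = unname(fit$parameter[2L]),
       p = unname(fit$p.value))
}

#' Post-hoc pairwise Welch t-tests
#'
#' Unequal-variance (Welch) two-sample t-tests for each requested pair of
#' groups.
#'
#' @param groups named list of numeric vectors (each `n >= 2`).
#' @param pairs optional list of length-2 character vectors naming the pairs;
#'   default: all pairs.
#' @return A data.frame with `group1`, `group2`, `mean_diff` (group2 - group1),
#'   `t`, `df`, `p`.
#' @export
posthoc_ttests <- function(groups, pairs = NULL) {
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)) && length(groups) > 0L)
    names(groups) <- paste0("g", seq_along(groups))
  if (is.null(pairs)) {
    cmb <- utils::combn(names(groups), 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  rows <- lapply(pairs, function(pr) {
    a <- groups[[pr[1L]]]
    b <- groups[[pr[2L]]]
    tt <- stats::t.test(b, a, var.equal = FALSE)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               mean_diff = mean(b) - mean(a),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation; the p-value uses the t transform with `n - 2`
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite, each with
#'   nonzero variance.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(x))
}

#' Benjamini-Hochberg FDR flags
#'
#' Standard step-up procedure at level `q`: a p-value passes when it is at or
#' below the largest `p_(k)` with `p_(k) <= k q / m`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector of pass flags, aligned with `p` (monotone in `p`).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0L))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH") <= q
}

#' Run the full statistical battery on a feature table
#'
#' Per kinematic parameter: one-way ANOVA across the groups present; pairwise
#' Welch post-hoc t-tests for parameters whose ANOVA reaches `alpha`;
#' per-group Pearson correlations between each parameter and each
#' adaptive-function score domain, with Benjamini-Hochberg flags computed
#' over the whole correlation table.
#'
#' @param features feature table from [extract_cohort_features()] (columns
#'   `group`, the twelve parameters, optionally score columns).
#' @param score_cols score columns to correlate against.
#' @param alpha ANOVA significance gate for the post-hoc stage.
#' @param q FDR level for the correlation table.
#' @param aggregate `"trial"` analyses trial-level rows; `"subject"` first
#'   averages each parameter within subject so rows are independent subjects.
#' @return A list with data.frames `anova`, `posthoc`, `correlations`.
#' @export
run_battery <- function(features, score_cols = c("vabs_com", "vabs_dl", "vabs_soc"),
                        alpha = 0.05, q = 0.05,
                        aggregate = c("trial", "subject")) {
  aggregate <- match.arg(aggregate)
  params <- intersect(kinematic_feature_names(), names(features))
  if (length(params) == 0L) stop("no kinematic parameter columns found", call. = FALSE)
  if (length(unique(features$group)) < 2L)
    stop("need at least two groups", call. = FALSE)
  score_cols <- intersect(score_cols, names(features))
  if (aggregate == "subject") {
    agg <- stats::aggregate(features[, c(params, score_cols), drop = FALSE],
                            by = list(subject_id = features$subject_id,
                                      group = features$group),
                            FUN = mean)
    features <- agg
  }
  grp_split <- function(col) split(features[[col]], features$group)
  anova_rows <- lapply(params, function(pn) {
    res <- anova_oneway(grp_split(pn))
    data.frame(parameter = pn, F = res$F, df_between = res$df_between,
               df_within = res$df_within, p = res$p)
  })
  anova_df <- do.call(rbind, anova_rows)
  ph <- lapply(params[anova_df$p < alpha], function(pn) {
    out <- posthoc_ttests(grp_split(pn))
    cbind(parameter = pn, out)
  })
  posthoc_df <- if (length(ph) > 0L) do.call(rbind, ph) else
    data.frame(parameter = character(0L), group1 = character(0L),
               group2 = character(0L), mean_diff = numeric(0L),
               t = numeric(0L), df = numeric(0L), p = numeric(0L))
  cor_rows <- list()
  for (grp in sort(unique(features$group))) {
    sub <- features[features$group == grp, , drop = FALSE]
    for (sc in score_cols) {
      if (all(is.na(sub[[sc]]))) next
      for (pn in params) {
        ok <- stats::complete.cases(sub[[pn]], sub[[sc]])
        if (sum(ok) < 3L) next
        res <- tryCatch(pearson_r(sub[[pn]][ok], sub[[sc]][ok]),
                        error = function(e) NULL)
        if (is.null(res)) next
        cor_rows[[length(cor_rows) + 1L]] <-
          data.frame(group = grp, parameter = pn, score = sc,
                     r = res$r, p = res$p, n = res$n)
      }
    }
  }
  cor_df <- if (length(cor_rows) > 0L) do.call(rbind, cor_rows) else
    data.frame(group = character(0L), parameter = character(0L),
               score = character(0L), r = numeric(0L), p = numeric(0L),
               n = integer(0L))
  cor_df$fdr_pass <- if (nrow(cor_df) > 0L) benjamini_hochberg(cor_df$p, q) else
    logical(0L)
  rownames(anova_df) <- rownames(posthoc_df) <- rownames(cor_df) <- NULL
  list(anova = anova_df, posthoc = posthoc_df, correlations = cor_df)
}
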