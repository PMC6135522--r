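#' Mann-Whitney comparison of a parameter between two groups
#'
#' Rank-sum comparison of one network parameter between two conditions
#' (e.g. control vs isolated repeats). The U statistic uses midranks for
#' ties; the two-sided p-value is exact by enumeration for small untied
#' samples and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param data data frame with one row per repeat.
#' @param value column (tidy-select) with the parameter values.
#' @param group column with the two-level condition labels.
#' @param exact_limit exact p-values are used when n_a + n_b does not exceed
#'   this and there are no ties.
#' @return one-row tibble: group labels and sizes, `statistic` (U of the
#'   first group), `p_value`, `method`.
#' @export
#' @examples
#' df <- tibble::tibble(w = c(1, 2, 3, 4, 5, 6),
#'                      grp = rep(c("ctrl", "iso"), each = 3))
#' mann_whitney(df, w, grp)
mann_whitney <- function(data, value, group, exact_limit = 12L) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  stopifnot(nlevels(g) == 2L, all(is.finite(v)))
  a <- v[g == levels(g)[1]]; b <- v[g == levels(g)[2]]
  if (length(unique(v)) == 1L) {
    warn("all values identical across both groups; p = 1")
    return(tibble(group_a = levels(g)[1], group_b = levels(g)[2],
                  n_a = length(a), n_b = length(b),
                  statistic = length(a) * length(b) / 2, p_value = 1,
                  method = "degenerate"))
  }
  ties <- any(duplicated(v))
  exact <- (length(a) + length(b)) <= exact_limit && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble(group_a = levels(g)[1], group_b = levels(g)[2],
         n_a = length(a), n_b = length(b),
         statistic = unname(wt$statistic),
         p_value = wt$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Scheirer-Ray-Hare rank-based two-way analysis
#'
#' The non-parametric two-way extension of the Kruskal-Wallis test: all
#' observations are ranked jointly (midranks for ties), two-way sums of
#' squares are computed on the ranks, and each effect's H statistic is its
#' SS divided by the total mean square of the ranks (N(N+1)/12 without ties,
#' tie-corrected otherwise), referred to a chi-square distribution with the
#' effect's degrees of freedom.
#'
#' @param data data frame.
#' @param value response column (tidy-select).
#' @param factor_a,factor_b the two factors.
#' @return tibble with one row per term (factor_a, factor_b, interaction):
#'   df, sum_sq (of ranks), h_statistic, p_value.
#' @export
scheirer_ray_hare <- function(data, value, factor_a, factor_b) {
  v <- dplyr::pull(data, {{ value }})
  fa <- factor(dplyr::pull(data, {{ factor_a }}))
  fb <- factor(dplyr::pull(data, {{ factor_b }}))
  stopifnot(all(is.finite(v)))
  if (any(table(fa, fb) == 0))
    abort("empty cells: the two-factor layout must be complete",
          class = "flynet_empty_cell")
  r <- rank(v)   # midranks
  n <- length(r)
  df <- data.frame(r = r, fa = fa, fb = fb)
  use_a <- nlevels(fa) > 1; use_b <- nlevels(fb) > 1
  has_int <- use_a && use_b && n > nlevels(fa) * nlevels(fb)
  rhs <- c(if (use_a) "fa", if (use_b) "fb", if (has_int) "fa:fb")
  if (!length(rhs))
    abort("both factors are degenerate (single level)", class = "flynet_empty_cell")
  form <- stats::as.formula(paste("r ~", paste(rhs, collapse = " + ")))
  aov_tab <- anova(lm(form, data = df))
  ms_total <- sum((r - mean(r))^2) / (n - 1)   # tie-corrected total mean square
  terms <- rownames(aov_tab)
  pick <- function(term) {
    k <- match(term, terms)
    if (is.na(k)) return(NULL)
    ss <- aov_tab[k, "Sum Sq"]; d <- aov_tab[k, "Df"]
    h <- ss / ms_total
    tibble(term = term, df = d, sum_sq = ss, h_statistic = h,
           p_value = pchisq(h, d, lower.tail = FALSE))
  }
  out <- dplyr::bind_rows(pick("fa"), pick("fb"), pick("fa:fb"))
  lbl <- c(fa = rlang::as_label(rlang::enquo(factor_a)),
           fb = rlang::as_label(rlang::enquo(factor_b)))
  out$term <- dplyr::recode(out$term, fa = lbl[["fa"]], fb = lbl[["fb"]],
                            "fa:fb" = paste0(lbl[["fa"]], ":", lbl[["fb"]]))
  out
}

#' Pairwise correlation map of per-fly parameters
#'
#' Pearson correlations between all pairs of parameter columns (e.g.
#' walking distance, degrees, clustering coefficient) with a significance
#' mask at `p < alpha`. Zero-variance columns give `NA` entries, flagged in
#' the output.
#'
#' @param data data frame of per-fly parameters, one row per fly.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha significance threshold for the mask.
#' @return A `correlation_map`: tibble (var_a, var_b, r, p_value,
#'   significant) covering every ordered pair once (upper triangle plus
#'   diagonal).
#' @export
correlation_map <- function(data, method = c("pearson", "spearman"),
                            alpha = 0.01) {
  method <- match.arg(method)
  num <- dplyr::select(data, dplyr::where(is.numeric))
  stopifnot(ncol(num) >= 2, nrow(num) >= 3)
  vars <- names(num)
  combos <- tidyr::expand_grid(var_a = vars, var_b = vars) |>
    dplyr::filter(match(.data$var_a, vars) <= match(.data$var_b, vars))
  res <- purrr::pmap_dfr(combos, function(var_a, var_b) {
    x <- num[[var_a]]; y <- num[[var_b]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(tibble(var_a = var_a, var_b = var_b, r = NA_real_,
                    p_value = NA_real_, significant = NA))
    if (var_a == var_b)
      return(tibble(var_a = var_a, var_b = var_b, r = 1, p_value = 0,
                    significant = TRUE))
    ct <- suppressWarnings(cor.test(x, y, method = method))
    tibble(var_a = var_a, var_b = var_b, r = unname(ct$estimate),
           p_value = ct$p.value, significant = ct$p.value < alpha)
  })
  class(res) <- c("correlation_map", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  res
}

#' @export
autoplot.correlation_map <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$r), .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(.data$var_b, .data$var_a,
                                   size = abs(.data$r), colour = .data$r)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "firebrick", mid = "white",
                                    high = "steelblue", limits = c(-1, 1)) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "r", size = "|r|",
                  title = sprintf("Parameter correlations (filled: p < %g)",
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
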