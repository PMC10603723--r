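#' Ecological (gross) conversion efficiency
#'
#' The proportion of ingested food converted into somatic growth,
#' `Eg = 100 * Gd / Cd` (percent), where `Gd` is the daily growth rate
#' and `Cd` the daily ingestion rate in the same units. Efficiencies
#' above 100% (growth exceeding ingestion) are physiologically
#' impossible and trigger a warning; they usually indicate swapped
#' arguments or mismatched units.
#'
#' @param g_d Daily growth rate (>= 0). Vectorized.
#' @param c_d Daily ingestion rate (> 0), same units as `g_d`.
#' @param g_units,c_units Optional unit tags (e.g. `"g/day"`). When both
#'   are given they must match; this enforces the dimensionless-ratio
#'   contract without converting anything silently.
#' @return Conversion efficiency in percent.
#' @examples
#' conversion_efficiency(22.36, 110.54)  # 20.23 %
#' @export
conversion_efficiency <- function(g_d, c_d, g_units = NULL, c_units = NULL) {
  if (!is.null(g_units) && !is.null(c_units) && !identical(g_units, c_units)) {
    stop(sprintf("unit mismatch: Gd in %s but Cd in %s.", g_units, c_units),
         call. = FALSE)
  }
  if (any(!is.finite(c_d)) || any(c_d <= 0)) {
    stop("`c_d` must be positive: efficiency is undefined without ingestion.",
         call. = FALSE)
  }
  if (any(g_d < 0)) stop("`g_d` must be >= 0.", call. = FALSE)
  e_g <- 100 * g_d / c_d
  if (any(e_g > 100)) {
    warning("conversion efficiency exceeds 100%: growth cannot exceed ingestion; check argument order and units.",
            call. = FALSE)
  }
  e_g
}

#' Compare rates across groups (one-way ANOVA + Tukey letters)
#'
#' One-way analysis of variance of a rate across groups, followed by
#' Tukey honest-significant-difference pairwise comparisons summarized
#' as a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`. Letters are assigned by the
#' insert-and-absorb algorithm with groups ordered by ascending mean.
#'
#' @param data Data frame of replicate measurements.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param alpha Significance level for the letter display. Default 0.05.
#' @return An object of class `group_comparison`: list with `anova`
#'   (tibble: `df_between`, `df_within`, `F`, `p`), `tukey` (tibble of
#'   pairwise differences and adjusted p), and `letters` (tibble:
#'   `group`, `mean`, `n`, `letters`).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 4),
#'                 y = c(1, 1.1, 0.9, 1, 5, 5.2, 4.9, 5.1))
#' compare_groups(d, "y", "g")
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  if (!all(c(value, group) %in% names(data))) {
    stop("`value` and `group` must name columns of `data`.", call. = FALSE)
  }
  y <- data[[value]]
  g <- as.character(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  counts <- table(g)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning(sprintf("excluding group(s) with < 2 replicates: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(g %in% small)
    y <- y[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2) {
    stop("need at least 2 groups with >= 2 replicates each.", call. = FALSE)
  }
  g <- factor(g)
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- tibble::tibble(
    group1 = pairs[, 1], group2 = pairs[, 2],
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  means <- tapply(y, g, mean)
  ord <- names(sort(means))
  sig <- tukey[tukey$p_adj <= alpha, c("group1", "group2")]
  letters_map <- compact_letter_display(ord, Map(c, sig$group1, sig$group2))
  structure(
    list(
      anova = tibble::tibble(
        df_between = an$Df[1], df_within = an$Df[2],
        F = an$`F value`[1], p = an$`Pr(>F)`[1]
      ),
      tukey = tukey,
      letters = tibble::tibble(
        group = ord,
        mean = as.numeric(means[ord]),
        n = as.integer(table(g)[ord]),
        letters = unname(letters_map[ord])
      ),
      alpha = alpha
    ),
    class = "group_comparison"
  )
}

# Insert-and-absorb compact letter display. `groups` are ordered by
# ascending mean (ties already broken); `sig_pairs` is a list of
# length-2 character vectors naming significantly different pairs.
# Returns a named character vector of letter strings.
compact_letter_display <- function(groups, sig_pairs) {
  cols <- list(groups)  # start with one column connecting everything
  for (pr in sig_pairs) {
    i <- pr[1]; j <- pr[2]
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by position of their lowest-mean member for stable letters
  first_pos <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_pos)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols)) {
    for (gname in cols[[k]]) out[gname] <- paste0(out[gname], letters[k])
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  print(as.data.frame(x$letters), row.names = FALSE)
  invisible(x)
}
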