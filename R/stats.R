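#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped; the
#' exact null distribution is used for up to 25 informative pairs when the
#' absolute differences are free of ties, otherwise the normal
#' approximation with continuity correction is used. If every difference
#' is zero the comparison is degenerate and flagged rather than tested.
#'
#' @param values_a,values_b Equal-length paired samples (e.g. per-subject
#'   condition means).
#' @param alpha Significance level for the `significant` flag.
#' @return List with `statistic` (V, the sum of positive ranks), `p_value`,
#'   `significant`, `n_effective` (pairs after dropping zeros), `exact`,
#'   and `degenerate`.
#' @export
paired_wilcoxon <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length")
  d <- values_a - values_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, n_effective = 0L, exact = NA,
                degenerate = TRUE))
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha, n_effective = n,
       exact = use_exact, degenerate = FALSE)
}

#' Pairwise condition comparisons of a long-format summary table
#'
#' Runs [paired_wilcoxon()] for every requested condition pair within each
#' band x metric stratum of a condition table (one value per subject,
#' condition, band and metric). Subjects must be complete within each
#' compared pair; missing subjects are reported by name.
#'
#' @param table Data frame with columns `subject`, `condition`, `band`,
#'   `metric`, `value`.
#' @param pairs List of length-2 character vectors of condition labels,
#'   e.g. `list(c("Tra", "VO"))`.
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default, matching per-pair testing at alpha)
#'   or `"holm"` for a Holm correction across all rows of the result.
#' @return Data frame with one row per band x metric x pair: `band`,
#'   `metric`, `condition_a`, `condition_b`, `statistic`, `p_value`,
#'   `significant`, `n`.
#' @export
compare_conditions <- function(table, pairs, alpha = 0.05,
                               p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("subject", "condition", "band", "metric", "value")
  if (!all(need %in% names(table)))
    stop("condition table must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(band = character(), metric = character(),
                    condition_a = character(), condition_b = character(),
                    statistic = numeric(), p_value = numeric(),
                    significant = logical(), n = integer())
  if (length(pairs) == 0L) return(out)
  for (pair in pairs) {
    if (!all(pair %in% table$condition))
      stop("condition(s) not present in table: ",
           paste(setdiff(pair, table$condition), collapse = ", "))
    for (bd in unique(table$band)) {
      for (mt in unique(table$metric)) {
        a <- table[table$condition == pair[1] & table$band == bd &
                   table$metric == mt, ]
        b <- table[table$condition == pair[2] & table$band == bd &
                   table$metric == mt, ]
        if (nrow(a) == 0L && nrow(b) == 0L) next
        miss <- c(setdiff(a$subject, b$subject), setdiff(b$subject, a$subject))
        if (length(miss) > 0L)
          stop("subjects missing from one condition (", bd, ", ", mt, "): ",
               paste(unique(miss), collapse = ", "))
        b <- b[match(a$subject, b$subject), ]
        wt <- paired_wilcoxon(a$value, b$value, alpha)
        out[nrow(out) + 1L, ] <- list(bd, mt, pair[1], pair[2],
                                      wt$statistic, wt$p_value,
                                      isTRUE(wt$significant), wt$n_effective)
      }
    }
  }
  if (p_adjust == "holm" && nrow(out) > 0L) {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  out
}
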