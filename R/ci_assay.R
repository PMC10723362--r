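# Cytoplasmic-incompatibility hatch-rate analysis: pooled per-cross
# hatch proportions over the assay days, a minimum-egg filter, and a
# one-sided rank-sum test of IC (incompatible) vs CC (compatible)
# crosses.

#' Read an egg-hatch table
#'
#' @param path TSV with columns `cross_id`, `type` (`IC`/`CC`), `day`,
#'   `eggs`, `hatched`.
#' @return validated data frame.
#' @export
read_hatch_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_hatch_table(df)
}

validate_hatch_table <- function(df) {
  need <- c("cross_id", "type", "day", "eggs", "hatched")
  wc_assert(all(need %in% names(df)),
            paste("hatch table needs columns:", paste(need, collapse = ", ")),
            "wolclock_input_error")
  wc_assert(all(df$type %in% c("IC", "CC")), "type must be IC or CC",
            "wolclock_input_error")
  wc_assert(all(df$eggs >= 0) && all(df$hatched >= 0) &&
              all(df$hatched <= df$eggs),
            "need 0 <= hatched <= eggs", "wolclock_input_error")
  wc_assert(all(df$day %in% 1:5) &&
              !anyDuplicated(df[, c("cross_id", "day")]),
            "each cross may have at most one row per day 1..5",
            "wolclock_input_error")
  df
}

#' Pooled hatch proportions per cross, filtering low-egg crosses
#'
#' Eggs and hatched counts are summed over the assay days for each
#' cross; crosses whose total egg count is below `min_eggs` are removed
#' (a cross laying exactly `min_eggs` is retained).
#'
#' @param table hatch data frame (see [read_hatch_table()]).
#' @param min_eggs minimum total eggs per cross (default 10).
#' @return data frame `cross_id`, `type`, `eggs`, `hatched`,
#'   `proportion`.
#' @export
pooled_hatch <- function(table, min_eggs = 10) {
  table <- validate_hatch_table(table)
  agg <- aggregate(cbind(eggs, hatched) ~ cross_id + type, table, sum)
  agg <- agg[agg$eggs >= min_eggs, , drop = FALSE]
  if (!nrow(agg))
    wc_stop("all crosses filtered out by the minimum-egg rule",
            "wolclock_degenerate_error")
  agg$proportion <- agg$hatched / agg$eggs
  agg[order(agg$type, agg$cross_id), , drop = FALSE]
}

#' One-sided rank-sum test: are IC hatch proportions lower than CC?
#'
#' Mann-Whitney / Wilcoxon rank-sum with alternative "IC stochastically
#' smaller than CC"; exact when tie-free and `m + n <= 20`, otherwise
#' normal approximation with tie and continuity correction.
#'
#' @param ic,cc numeric vectors of per-cross hatch proportions.
#' @return list with `statistic` (Mann-Whitney U of the IC group),
#'   `p_value`, `method`.
#' @export
wilcoxon_one_sided <- function(ic, cc) {
  wc_assert(length(ic) >= 1 && length(cc) >= 1,
            "both groups must be non-empty", "wolclock_input_error")
  res <- mwu_core(ic, cc, alternative = "less")
  list(statistic = res$statistic, p_value = res$p.value,
       method = res$method)
}

#' Full incompatibility analysis of a hatch table
#'
#' @inheritParams pooled_hatch
#' @return a `ci_test` list: the pooled per-cross table, group
#'   summaries, and the one-sided rank-sum result.
#' @export
ci_test <- function(table, min_eggs = 10) {
  pooled <- pooled_hatch(table, min_eggs)
  ic <- pooled$proportion[pooled$type == "IC"]
  cc <- pooled$proportion[pooled$type == "CC"]
  wc_assert(length(ic) >= 1 && length(cc) >= 1,
            "need both IC and CC crosses after filtering",
            "wolclock_input_error")
  test <- wilcoxon_one_sided(ic, cc)
  out <- list(pooled = pooled,
              summary = data.frame(
                type = c("IC", "CC"), n = c(length(ic), length(cc)),
                mean = c(mean(ic), mean(cc)), sd = c(sd(ic), sd(cc))),
              statistic = test$statistic, p_value = test$p_value,
              method = test$method, min_eggs = min_eggs)
  class(out) <- "ci_test"
  out
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("CI assay (min %d eggs): one-sided rank-sum p = %.4g (%s)\n",
              x$min_eggs, x$p_value, x$method))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
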