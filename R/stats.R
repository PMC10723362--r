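# Resampling and rank-based statistics used on the windowed dN/dS
# profiles and structure scores: BCa bootstrap intervals, Mann-Whitney /
# Kruskal-Wallis + Dunn group comparisons with a compact letter display,
# and Spearman correlation with an exact small-n p-value.

# BCa endpoint adjustment given bootstrap draws, bias z0 and
# acceleration a; separated from bca_interval so the z0 = a = 0
# reduction to the percentile interval is testable directly.
bca_endpoints <- function(boot_stats, z0, accel, level = 0.95) {
  alpha <- (1 - level) / 2
  za <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + za) / (1 - accel * (z0 + za)))
  quantile(boot_stats, probs = adj, names = FALSE, type = 7)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa: the bias correction `z0` is the normal quantile of the
#' fraction of bootstrap statistics below the observed statistic, and
#' the acceleration `a` comes from the jackknife skewness; the interval
#' endpoints are percentile endpoints at the adjusted levels.
#'
#' @param values numeric sample (length >= 2).
#' @param statistic function of a numeric vector (default `mean`).
#' @param n_boot number of bootstrap resamples (>= 200).
#' @param seed optional integer seed.
#' @param level confidence level.
#' @return numeric `c(low, high)`; zero-width at the observed value
#'   (with a warning) when the bootstrap distribution is degenerate.
#' @export
bca_interval <- function(values, statistic = mean, n_boot = 2000,
                         seed = NULL, level = 0.95) {
  wc_assert(length(values) >= 2, "need >= 2 values",
            "wolclock_input_error")
  wc_assert(n_boot >= 200, "n_boot must be >= 200")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  obs <- statistic(values)
  boot_stats <- vapply(seq_len(n_boot), function(b)
    statistic(values[sample.int(n, n, replace = TRUE)]), 0)
  if (sd(boot_stats) == 0 || all(boot_stats == obs)) {
    warning("degenerate bootstrap distribution: zero-width interval")
    return(c(obs, obs))
  }
  prop <- sum(boot_stats < obs) / n_boot
  prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(values[-i]), 0)
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  accel <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  bca_endpoints(boot_stats, z0, accel, level)
}

# ---- rank tests ---------------------------------------------------------

# Mann-Whitney U with midranks; exact null via pwilcox when tie-free and
# small, else normal approximation with tie correction.
mwu_core <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  exact <- !has_ties && (m + n) <= 20
  if (exact) {
    p <- switch(alternative,
      less = pwilcox(U, m, n),
      greater = pwilcox(U - 1, m, n, lower.tail = FALSE),
      two.sided = min(1, 2 * min(pwilcox(U, m, n),
                                 pwilcox(U - 1, m, n, lower.tail = FALSE))))
  } else {
    N <- m + n
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (m * n / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence either way
    } else {
      mu <- m * n / 2
      cc <- 0.5
      p <- switch(alternative,
        less = pnorm((U - mu + cc) / sqrt(sigma2)),
        greater = pnorm((U - mu - cc) / sqrt(sigma2), lower.tail = FALSE),
        two.sided = {
          z <- (U - mu - sign(U - mu) * cc) / sqrt(sigma2)
          min(1, 2 * pnorm(-abs(z)))
        })
    }
  }
  list(statistic = U, p.value = p,
       method = if (exact) "exact" else "normal approximation")
}

# Dunn's all-pairs z tests after Kruskal-Wallis, with multiplicity
# adjustment
dunn_pairs <- function(values, labels, adjust = "holm") {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- split(r, labels)
  gn <- names(groups)
  cmb <- combn(length(gn), 2)
  res <- data.frame(group1 = gn[cmb[1, ]], group2 = gn[cmb[2, ]],
                    z = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(cmb))) {
    g1 <- groups[[cmb[1, k]]]; g2 <- groups[[cmb[2, k]]]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / length(g1) + 1 / length(g2)))
    z <- (mean(g1) - mean(g2)) / se
    res$z[k] <- z
    res$p[k] <- 2 * pnorm(-abs(z))
  }
  res$p_adjusted <- p.adjust(res$p, method = adjust)
  res
}

# compact letter display from a logical "significantly different"
# pairwise indicator (insert-and-absorb)
letter_display <- function(group_names, sig_pairs) {
  classes <- list(group_names)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[k]; b <- sig_pairs$group2[k]
    if (!sig_pairs$sig[k]) next
    for (ci in seq_along(classes)) {
      cl <- classes[[ci]]
      if (a %in% cl && b %in% cl) {
        classes[[ci]] <- setdiff(cl, a)
        classes <- c(classes, list(setdiff(cl, b)))
      }
    }
    # absorb classes contained in another
    keep <- rep(TRUE, length(classes))
    for (i in seq_along(classes)) for (j in seq_along(classes))
      if (i != j && keep[i] && keep[j] &&
          all(classes[[i]] %in% classes[[j]])) keep[i] <- FALSE
    classes <- classes[keep]
  }
  letters_out <- setNames(rep("", length(group_names)), group_names)
  for (ci in seq_along(classes))
    for (g in classes[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  letters_out
}

#' Rank-based group comparison with a compact letter display
#'
#' Two groups: two-sided Mann-Whitney U (exact when tie-free and
#' `m + n <= 20`, else normal approximation with tie correction).  More
#' than two: Kruskal-Wallis followed by all-pairs Dunn tests with
#' multiplicity adjustment.  Groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values numeric vector (NA dropped).
#' @param labels group labels, same length.
#' @param alpha significance level for the letter display.
#' @param adjust p-adjustment method for Dunn tests (default
#'   `"holm"`; any [stats::p.adjust()] method).
#' @return a `group_comparison` list: `test`, `p_value`, `pairwise`
#'   (data frame or `NULL`), `letters`, `n`.
#' @export
group_compare <- function(values, labels, alpha = 0.05, adjust = "holm") {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 values: %s",
                    paste(small, collapse = ", ")))
    keep <- !(labels %in% small)
    values <- values[keep]; labels <- labels[keep]
  }
  gn <- sort(unique(labels))
  if (length(gn) < 2)
    wc_stop("need >= 2 usable groups", "wolclock_input_error")
  if (length(gn) == 2) {
    res <- mwu_core(values[labels == gn[1]], values[labels == gn[2]],
                    "two.sided")
    sig <- data.frame(group1 = gn[1], group2 = gn[2],
                      sig = res$p.value < alpha)
    out <- list(test = paste("Mann-Whitney U,", res$method),
                p_value = res$p.value, pairwise = NULL,
                letters = letter_display(gn, sig),
                n = setNames(as.integer(table(labels)[gn]), gn))
  } else {
    kw <- kruskal.test(values, factor(labels))
    pw <- dunn_pairs(values, labels, adjust)
    pw$sig <- pw$p_adjusted < alpha & kw$p.value < alpha
    out <- list(test = sprintf("Kruskal-Wallis + Dunn (%s)", adjust),
                p_value = kw$p.value, pairwise = pw,
                letters = letter_display(gn, pw),
                n = setNames(as.integer(table(labels)[gn]), gn))
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, ": p =", format.pval(x$p_value), "\n")
  print(x$letters)
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for
# the exact-test sizes used here (n <= 9)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks for ties; the two-sided p-value is exact (enumeration
#' of all rank permutations) for `n <= 9` and uses the t approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `rho` and `p_value` (`NA` with a warning if either
#'   variable has zero rank variance).
#' @export
spearman_test <- function(x, y) {
  wc_assert(length(x) == length(y) && length(x) >= 3,
            "need equal lengths >= 3", "wolclock_input_error")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    warning("zero rank variance: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_perms(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p_value = p)
}
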