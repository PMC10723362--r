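# Cladogenic co-divergence rate calibration: point rates from printed
# divergences and host divergence times, credible-interval propagation,
# pooling, and the rate priors used to scale relative chronograms.

#' Substitution rate implied by cladogenic co-divergence
#'
#' Pairwise divergence accrues along both lineages since the host split,
#' so `rate = (d / 100) / (2 * T)`.
#'
#' @param d_percent percent divergence (e.g. third-position, JC
#'   corrected).
#' @param T_years host divergence time in years.
#' @return substitutions per site per year.
#' @examples
#' cladogenic_rate(0.2, 0.46e6)  # ~2.2e-9
#' @export
cladogenic_rate <- function(d_percent, T_years) {
  wc_assert(all(d_percent >= 0), "divergence must be >= 0")
  if (any(T_years <= 0))
    wc_stop("host divergence time must be > 0", "wolclock_domain_error")
  (d_percent / 100) / (2 * T_years)
}

#' Rate estimate with credible bounds propagated from host-time bounds
#'
#' The mapping time -> rate is inverse and monotone, so the lower rate
#' bound comes from the upper time bound and vice versa.
#'
#' @inheritParams cladogenic_rate
#' @param T_low,T_high 95% credible bounds on the host divergence time.
#' @param name source pair label.
#' @param basis `"third"` or `"synonymous"`.
#' @return a `rate_estimate` list: `rate`, `rate_low`, `rate_high`,
#'   `basis`, `source`.
#' @export
rate_interval <- function(d_percent, T_years, T_low, T_high,
                          name = NA_character_, basis = "third") {
  wc_assert(T_low > 0 && T_low <= T_years && T_years <= T_high,
            "need 0 < T_low <= T_years <= T_high")
  structure(list(rate = cladogenic_rate(d_percent, T_years),
                 rate_low = cladogenic_rate(d_percent, T_high),
                 rate_high = cladogenic_rate(d_percent, T_low),
                 basis = basis, source = name),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate [%s]: %.3g (%.3g-%.3g) substitutions/site/year\n",
              ifelse(is.na(x$source), "", x$source), x$basis,
              x$rate, x$rate_low, x$rate_high))
  invisible(x)
}

#' Weighted pooling of substitution-rate estimates
#'
#' @param rates numeric vector of rates.
#' @param weights probabilities of the same length summing to 1
#'   (default: equal weights).
#' @return weighted arithmetic mean.
#' @export
pooled_rate <- function(rates, weights = rep(1 / length(rates), length(rates))) {
  wc_assert(length(rates) == length(weights), "length mismatch")
  wc_assert(all(weights >= 0) && abs(sum(weights) - 1) < 1e-9,
            "weights must be >= 0 and sum to 1")
  sum(rates * weights)
}

# ---- rate priors --------------------------------------------------------

#' Construct one of the named substitution-rate priors
#'
#' All rates are in substitutions per third-position site per year.
#' The four co-divergence priors share a mean of about 1.65e-9:
#'
#' * `N1`: `N(1, 0.34) x 1.65e-9`
#' * `U1`: `U(0.33, 1.67) x 1.65e-9`
#' * `N2`: mixture, `N(1, 0.36) x 0.56e-9` w.p. 1/3 and
#'   `N(1, 0.08) x 2.2e-9` w.p. 2/3
#' * `U2`: mixture, `U(0.3, 1.7) x 0.56e-9` w.p. 1/3 and
#'   `U(0.84, 1.16) x 2.2e-9` w.p. 2/3
#' * `legacy`: `Gamma(shape 7, rate 7) x 6.87e-9` (mutation-rate based)
#'
#' Normal components are truncated at zero (a rate must be positive) and
#' rescaled so each component keeps its nominal mean; see
#' [sample_prior()].
#'
#' @param name one of `"N1"`, `"U1"`, `"N2"`, `"U2"`, `"legacy"`.
#' @return a `rate_prior` object.
#' @export
make_prior <- function(name = c("N1", "U1", "N2", "U2", "legacy")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) wc_stop(
                     paste0("unknown prior name: ", name[1]),
                     "wolclock_config_error"))
  comp <- switch(name,
    N1 = data.frame(weight = 1, family = "normal", p1 = 1, p2 = 0.34,
                    scale = 1.65e-9),
    U1 = data.frame(weight = 1, family = "uniform", p1 = 0.33, p2 = 1.67,
                    scale = 1.65e-9),
    N2 = data.frame(weight = c(1 / 3, 2 / 3), family = "normal",
                    p1 = c(1, 1), p2 = c(0.36, 0.08),
                    scale = c(0.56e-9, 2.2e-9)),
    U2 = data.frame(weight = c(1 / 3, 2 / 3), family = "uniform",
                    p1 = c(0.3, 0.84), p2 = c(1.7, 1.16),
                    scale = c(0.56e-9, 2.2e-9)),
    legacy = data.frame(weight = 1, family = "gamma", p1 = 7, p2 = 7,
                        scale = 6.87e-9))
  structure(list(name = name, components = comp), class = "rate_prior")
}

#' Analytic mean of a rate prior
#'
#' @param prior a `rate_prior`.
#' @return mean rate in substitutions/site/year.
#' @export
prior_mean <- function(prior) {
  wc_assert(inherits(prior, "rate_prior"), "not a rate_prior",
            "wolclock_input_error")
  comp <- prior$components
  mu <- vapply(seq_len(nrow(comp)), function(i) {
    with(comp[i, ], switch(family,
      normal = p1,            # truncation is mean-preserving by rescaling
      uniform = (p1 + p2) / 2,
      gamma = p1 / p2))
  }, 0)
  sum(comp$weight * mu * comp$scale)
}

#' Draw substitution rates from a rate prior
#'
#' Mixture components are selected with their weights.  Normal draws are
#' truncated at zero by rejection (a substitution rate must be
#' positive), then divided by the analytic truncated-normal mean factor
#' so the component mean stays at its nominal value.
#'
#' @param prior a `rate_prior` from [make_prior()].
#' @param n number of draws.
#' @param seed optional integer for reproducibility.
#' @return numeric vector of `n` positive rates.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  wc_assert(inherits(prior, "rate_prior"), "not a rate_prior",
            "wolclock_input_error")
  wc_assert(n >= 1, "n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- prior$components
  which_comp <- if (nrow(comp) == 1) rep(1L, n) else
    sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  out <- numeric(n)
  for (i in seq_len(nrow(comp))) {
    idx <- which(which_comp == i)
    if (!length(idx)) next
    m <- length(idx)
    ci <- comp[i, ]
    draws <- switch(ci$family,
      normal = {
        x <- rnorm(m, ci$p1, ci$p2)
        while (any(neg <- x <= 0)) x[neg] <- rnorm(sum(neg), ci$p1, ci$p2)
        # mean of N(mu, sd) truncated to (0, Inf), relative to mu:
        alpha <- ci$p1 / ci$p2
        x / (1 + (ci$p2 / ci$p1) * dnorm(alpha) / pnorm(alpha))
      },
      uniform = runif(m, ci$p1, ci$p2),
      gamma = rgamma(m, shape = ci$p1, rate = ci$p2))
    out[idx] <- draws * ci$scale
  }
  out
}

#' @export
print.rate_prior <- function(x, ...) {
  cat(sprintf("rate_prior %s (mean %.4g substitutions/site/year)\n",
              x$name, prior_mean(x)))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Read a table of cladogenic calibration pairs
#'
#' @param path TSV with columns `name`, `d_third_percent`,
#'   `d_syn_percent`, `T_years`, `T_low`, `T_high` (times in years,
#'   `NA` bounds allowed).
#' @return data frame of calibration pairs.
#' @export
read_cladogenic_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "d_third_percent", "d_syn_percent", "T_years",
            "T_low", "T_high")
  wc_assert(all(need %in% names(df)),
            paste("pairs table needs columns:", paste(need, collapse = ", ")),
            "wolclock_input_error")
  bounded <- !is.na(df$T_low) & !is.na(df$T_high)
  wc_assert(all(df$T_years > 0) &&
              all(df$T_low[bounded] <= df$T_years[bounded]) &&
              all(df$T_years[bounded] <= df$T_high[bounded]),
            "invalid divergence times or bounds", "wolclock_input_error")
  df
}

#' Rate estimates for a table of calibration pairs
#'
#' @param pairs data frame from [read_cladogenic_pairs()].
#' @param basis `"third"` or `"synonymous"`.
#' @return data frame with `name`, `rate`, `rate_low`, `rate_high`.
#' @export
calibrate_rates <- function(pairs, basis = c("third", "synonymous")) {
  basis <- match.arg(basis)
  dcol <- if (basis == "third") "d_third_percent" else "d_syn_percent"
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- pairs[[dcol]][i]
    if (is.na(d)) return(data.frame(name = pairs$name[i], rate = NA_real_,
                                    rate_low = NA_real_, rate_high = NA_real_))
    r <- cladogenic_rate(d, pairs$T_years[i])
    if (!is.na(pairs$T_low[i]) && !is.na(pairs$T_high[i])) {
      ri <- rate_interval(d, pairs$T_years[i], pairs$T_low[i],
                          pairs$T_high[i], pairs$name[i], basis)
      data.frame(name = pairs$name[i], rate = ri$rate,
                 rate_low = ri$rate_low, rate_high = ri$rate_high)
    } else {
      data.frame(name = pairs$name[i], rate = r,
                 rate_low = NA_real_, rate_high = NA_real_)
    }
  })
  do.call(rbind, res)
}
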