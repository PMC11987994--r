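#' Descriptive statistics of one speed group
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of a group of windowed speed means. A single-value group has no
#' sample SD; it is reported as 0 with a warning.
#'
#' @param values numeric vector of (non-negative) windowed mean speeds.
#' @return data.frame with \code{n}, \code{mean}, \code{sd}, \code{min},
#'   \code{max}.
#' @export
describeGroup <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  s <- if (length(values) == 1) {
    warning("single observation: sd reported as 0")
    0
  } else stats::sd(values)
  data.frame(n = length(values), mean = mean(values), sd = s,
             min = min(values), max = max(values))
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Tests the sample against a normal distribution with the sample's own
#' mean and standard deviation. With estimated parameters the test is
#' anti-conservative (the Lilliefors effect); it is used only as a gate for
#' choosing the nonparametric group tests, as in the workflow it supports.
#'
#' @param values numeric vector, \code{n >= 8}, non-degenerate.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
ksNormality <- function(values) {
  stopifnot(length(values) >= 8)
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: sd is 0")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Kruskal-Wallis omnibus test over speed groups
#'
#' Rank-based k-sample omnibus test with tie correction; p-value from the
#' chi-square approximation with k - 1 degrees of freedom.
#'
#' @param groups named list of numeric vectors (one per group).
#' @return list with \code{H}, \code{df}, \code{p.value}.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 1))
  allv <- unlist(groups, use.names = FALSE)
  if (length(unique(allv)) == 1)           # fully tied: H = 0 by convention
    return(list(H = 0, df = length(groups) - 1, p.value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Dunn post hoc test with Bonferroni correction
#'
#' Pairwise z-statistics on mean ranks of the pooled sample with tie
#' correction; two-sided p-values are multiplied by the number of pairs
#' k(k-1)/2 and capped at 1. Computed unconditionally -- the caller decides
#' whether the omnibus test licenses its interpretation (the conventional
#' sequence runs it only after a significant Kruskal-Wallis result).
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the difference flags.
#' @return list with \code{p.adjusted} (symmetric matrix, unit diagonal),
#'   \code{z} (signed z matrix, zero diagonal), \code{different} (logical
#'   matrix, \code{p.adjusted < alpha} off-diagonal), \code{m} (number of
#'   comparisons) and \code{alpha}.
#' @examples
#' g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(10, 11, 12, 13))
#' dunnBonferroni(g)$p.adjusted
#' @export
dunnBonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  gidx <- rep(seq_len(k), n)
  rbar <- tapply(r, gidx, mean)
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  varfac <- N * (N + 1) / 12 - tiecorr
  m <- k * (k - 1) / 2
  z <- matrix(0, k, k, dimnames = list(labs, labs))
  p <- matrix(1, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(varfac * (1 / n[i] + 1 / n[j]))
      zij <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
      pij <- min(1, 2 * stats::pnorm(-abs(zij)) * m)
      z[i, j] <- zij; z[j, i] <- -zij
      p[i, j] <- pij; p[j, i] <- pij
    }
  }
  diff <- p < alpha
  diag(diff) <- FALSE
  list(p.adjusted = p, z = z, different = diff, m = m, alpha = alpha)
}

#' Generate synthetic windowed-speed groups
#'
#' Draws each group from a normal distribution truncated at zero (speeds
#' cannot be negative), with the given pre-truncation moments. The default
#' template reproduces the four-group effect-size pattern of the ammonia
#' dose study the package's statistics were built for: group means
#' 91.24, 83.87, 52.11, 24.22 mm/s with SDs 39.90, 23.88, 22.95, 9.34.
#'
#' @param means,sds numeric vectors of pre-truncation group moments (mm/s).
#' @param n observations per group (3600 windows in a full 10-h trial).
#' @param seed RNG seed; draws are reproducible per seed.
#' @param labels group labels.
#' @return Named list of numeric vectors.
#' @export
synthSpeedGroups <- function(means = c(91.24, 83.87, 52.11, 24.22),
                             sds = c(39.90, 23.88, 22.95, 9.34),
                             n = 3600, seed = 1,
                             labels = c("control", "100", "200", "400")) {
  stopifnot(length(means) == length(sds), n >= 1,
            length(labels) == length(means), all(sds >= 0))
  set.seed(seed)
  out <- vector("list", length(means))
  names(out) <- labels
  for (g in seq_along(means)) {
    if (sds[g] == 0) {
      out[[g]] <- rep(means[g], n)
      next
    }
    x <- stats::rnorm(n, means[g], sds[g])
    while (any(neg <- x < 0))                  # rejection sampling at 0
      x[neg] <- stats::rnorm(sum(neg), means[g], sds[g])
    out[[g]] <- x
  }
  out
}

#' Full statistical report over speed groups
#'
#' Descriptive statistics per group, the KS normality screen, the
#' Kruskal-Wallis omnibus test and the unconditional Dunn-Bonferroni
#' pairwise matrix, with the omnibus gate recorded.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level.
#' @return list with \code{descriptives} (data.frame), \code{ks}
#'   (data.frame per group), \code{omnibus}, \code{pairwise} and
#'   \code{omnibus_significant}.
#' @export
statsReport <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  desc <- do.call(rbind, lapply(groups, describeGroup))
  desc <- cbind(group = names(groups), desc)
  rownames(desc) <- NULL
  ks <- do.call(rbind, lapply(groups, function(v) {
    kt <- ksNormality(v)
    data.frame(statistic = kt$statistic, p.value = kt$p.value)
  }))
  ks <- cbind(group = names(groups), ks)
  rownames(ks) <- NULL
  omn <- kruskalWallis(groups)
  pw <- dunnBonferroni(groups, alpha)
  list(descriptives = desc, ks = ks, omnibus = omn, pairwise = pw,
       omnibus_significant = omn$p.value < alpha)
}
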