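# Statistical primitives used throughout the screens. These are
# self-contained so that every p-value in the pipeline is reproducible from
# first principles and checkable against brute-force oracles.

# Exact null distribution of the Mann-Whitney U statistic for group sizes
# (n, m): counts[u + 1] = number of labelings with U == u, u = 0..n*m.
# Equivalent to counting integer partitions of u into at most n parts each
# at most m; memoized because screens reuse a handful of (n, m) pairs.
mw_count_cache <- new.env(parent = emptyenv())

mw_exact_counts <- function(n, m) {
  a <- min(n, m); b <- max(n, m)
  key <- paste(a, b)
  hit <- mw_count_cache[[key]]
  if (!is.null(hit)) return(hit)
  umax <- a * b
  # rows j = 0..b (max part size); iterate i = 1..a (number of parts)
  prev <- rep(list(c(1, rep(0, umax))), b + 1)  # i = 0: only u = 0
  for (i in seq_len(a)) {
    cur <- vector("list", b + 1)
    cur[[1]] <- c(1, rep(0, umax))              # parts <= 0
    for (j in seq_len(b)) {
      shifted <- c(rep(0, j), prev[[j + 1]][seq_len(umax + 1 - j)])
      cur[[j + 1]] <- shifted + cur[[j]]
    }
    prev <- cur
  }
  counts <- prev[[b + 1]]
  out <- list(counts = counts, cum = cumsum(counts), total = sum(counts))
  mw_count_cache[[key]] <- out
  out
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample unpaired rank test as used for every tumor-versus-normal
#' comparison in the screens. The p-value is exact (full enumeration of the
#' U null distribution) when `min(length(x), length(y)) <= 25` and there are
#' no ties; otherwise a normal approximation with tie correction and a 0.5
#' continuity correction is used. The two-sided p-value is
#' `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param x,y Numeric vectors (no missing values; remove them first).
#' @param alternative `"two.sided"` (default), `"greater"` (x stochastically
#'   larger) or `"less"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact computation;
#'   `NULL` (default) decides by the rule above. An exact request is
#'   downgraded to the approximation (with a warning) when ties are present.
#' @return A one-row tibble: `statistic` (U for `x`), `p_value`,
#'   `alternative`, `method` (`"exact"` or `"approx"`).
#' @examples
#' mw_test(c(1, 2, 3), c(10, 11, 12))
#' @export
mw_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    exact = NULL) {
  alternative <- match.arg(alternative)
  res <- mw_p(x, y, alternative, exact)
  tibble::tibble(statistic = res$statistic, p_value = res$p_value,
                 alternative = alternative, method = res$method)
}

# scalar core of mw_test, used directly by the screens (no tibble overhead)
mw_p <- function(x, y, alternative = "two.sided", exact = NULL) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("missing values must be removed by the caller")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- if (is.null(exact)) min(n, m) <= 25 && !ties else isTRUE(exact)
  if (use_exact && ties) {
    warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    dist <- mw_exact_counts(n, m)
    lower <- dist$cum[u + 1] / dist$total                       # P(U <= u)
    upper <- if (u == 0) 1 else
      (dist$total - dist$cum[u]) / dist$total                   # P(U >= u)
    p <- switch(alternative,
      greater = upper,
      less = lower,
      two.sided = min(1, 2 * min(lower, upper))
    )
    method <- "exact"
  } else {
    mu <- n * m / 2
    tab <- tabulate(match(pooled, unique(pooled)))
    tie_term <- sum(tab^3 - tab) / ((n + m) * (n + m - 1))
    sigma2 <- (n * m / 12) * ((n + m + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        greater = pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
        less = pnorm((u - mu + 0.5) / sigma),
        two.sided = {
          z <- (u - mu - sign(u - mu) * 0.5) / sigma
          min(1, 2 * pnorm(-abs(z)))
        }
      )
    }
    method <- "approx"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Produces monotone q-values with `q >= p` and `q <= 1`. Callers apply it
#' within explicitly declared families (one family per tissue and assay in
#' the screens).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * n / seq.int(n, 1)))
  q[order(o)]
}

#' Spearman rank correlation
#'
#' Pairwise-complete: pairs with a missing member are dropped before
#' ranking. Ties receive average ranks. At least 3 complete pairs are
#' required; with fewer, or when either variable is constant after pair
#' removal, the correlation is undefined and `NA` is returned (never 0).
#'
#' @param x,y Numeric vectors of equal length.
#' @return The rank correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

#' Spearman correlation with a large-sample p-value
#'
#' Same correlation as [spearman_rho()]; the p-value comes from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @inheritParams spearman_rho
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A one-row tibble: `rho`, `n` (complete pairs), `p_value`.
#' @export
spearman_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  rho <- spearman_rho(x, y)
  if (is.na(rho) || n < 3) {
    return(tibble::tibble(rho = NA_real_, n = n, p_value = NA_real_))
  }
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- switch(alternative,
      two.sided = 2 * pt(-abs(tstat), df = n - 2),
      greater = pt(tstat, df = n - 2, lower.tail = FALSE),
      less = pt(tstat, df = n - 2)
    )
  }
  tibble::tibble(rho = rho, n = n, p_value = min(1, p))
}

hyper_pmf <- function(x, m, n, k) {
  # P(X = x) drawing k from m "white" and n "black", via log binomials
  exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
}

#' Fisher's exact test on a 2x2 table
#'
#' One-sided `"greater"` tests enrichment of the top-left cell; the
#' two-sided p-value sums the probabilities of all tables no more likely
#' than the observed one. A table with a zero margin has p = 1.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` (default, matching the enrichment tests in
#'   the pipeline), `"less"` or `"two.sided"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact_p(matrix(c(5, 0, 0, 5), 2, 2))
#' @export
fisher_exact_p <- function(table,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) abort("table must be 2x2")
  if (any(tab < 0) || any(tab != trunc(tab))) {
    abort("table cells must be non-negative integers")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 margin ("white")
  n <- sum(tab[2, ])   # row-2 margin ("black")
  k <- sum(tab[, 1])   # column-1 margin (draws)
  if (m + n == 0) abort("at least one margin must be positive")
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  pmf <- hyper_pmf(support, m, n, k)
  obs <- pmf[match(a, support)]
  min(1, switch(alternative,
    greater = sum(pmf[support >= a]),
    less = sum(pmf[support <= a]),
    two.sided = sum(pmf[pmf <= obs * (1 + 1e-7)])
  ))
}

#' Exact binomial test
#'
#' The two-sided p-value follows the minimum-likelihood rule: the sum of the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The exact p-value.
#' @examples
#' binomial_test_p(9, 10, 0.5)  # 0.021484375
#' @export
binomial_test_p <- function(k, n, p0 = 0.5,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (k < 0 || k > n) abort("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly in (0, 1)")
  ks <- 0:n
  # direct products are exact to the last bit for small n (e.g. dyadic p0);
  # the log form avoids overflow for large n
  pmf <- if (n <= 64) choose(n, ks) * p0^ks * (1 - p0)^(n - ks)
         else dbinom(ks, n, p0)
  min(1, switch(alternative,
    greater = sum(pmf[(k + 1):(n + 1)]),
    less = sum(pmf[1:(k + 1)]),
    two.sided = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  ))
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests whether `query` overlaps `annotated` more (or, two-sided, more
#' extremely) than expected by drawing `|query|` ids at random from
#' `universe`. The one-sided `"greater"` p equals [fisher_exact_p()] on the
#' induced 2x2 table. When `annotated` is a named list of sets, one test is
#' run per set and a Bonferroni step-down (Holm) adjusted p is added.
#'
#' @param query Character vector of ids; must be contained in `universe`.
#' @param annotated Character vector of annotated ids, or a named list of
#'   such vectors. Ids outside `universe` are ignored.
#' @param universe Character vector enumerating the tested universe.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return For a single set, the p-value. For a list, a tibble with one row
#'   per set: `set`, `n_annotated`, `overlap`, `p_value`, `p_holm`.
#' @export
hypergeom_ora <- function(query, annotated, universe,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe))) {
    abort("query must be contained in the universe")
  }
  one <- function(ann) {
    ann <- intersect(unique(ann), universe)
    k <- length(intersect(query, ann))
    tab <- matrix(c(k, length(query) - k,
                    length(ann) - k,
                    length(universe) - length(query) - length(ann) + k),
                  nrow = 2)
    fisher_exact_p(tab, alternative = alternative)
  }
  if (is.list(annotated)) {
    if (is.null(names(annotated))) abort("annotated list must be named")
    p <- vapply(annotated, one, numeric(1), USE.NAMES = FALSE)
    tibble::tibble(
      set = names(annotated),
      n_annotated = vapply(annotated, function(a)
        length(intersect(unique(a), universe)), integer(1), USE.NAMES = FALSE),
      overlap = vapply(annotated, function(a)
        length(intersect(query, intersect(a, universe))), integer(1),
        USE.NAMES = FALSE),
      p_value = p,
      p_holm = stats::p.adjust(p, method = "holm")
    )
  } else {
    one(annotated)
  }
}
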