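# Evaluation statistics, implemented from first principles: these
# primitives are part of the validated method, so they are authored here
# (base-R equivalents serve as independent cross-checks in the test
# suite, never as the implementation).

#' Fisher exact test for a 2x2 contingency table
#'
#' Exact two-sided p-value by hypergeometric enumeration in log space:
#' with margins fixed, the p-value is the sum of point probabilities of
#' all tables whose probability does not exceed the observed table's
#' (with 1e-12 relative slack, the usual guard against floating-point
#' ties). Any empty margin gives p = 1 by convention.
#'
#' @param table 2x2 integer matrix (rows = method, columns = outcome), or
#'   the count `a` with `b`, `c`, `d` supplied separately.
#' @param b,c,d Optional counts when `table` is given as scalar `a`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(246, 34, 246, 31), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) table <- matrix(c(table, b, c, d), 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)) || any(!is.finite(table)))
    stop("fisher_exact_2x2: need a 2x2 table of non-negative integer counts")
  a <- table[1, 1]; bb <- table[1, 2]; cc <- table[2, 1]; dd <- table[2, 2]
  n <- a + bb + cc + dd
  if (n == 0) stop("fisher_exact_2x2: empty table")
  r1 <- a + bb; r2 <- cc + dd; c1 <- a + cc
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  lps <- lp(xs)
  obs <- lp(a)
  min(1, sum(exp(lps[lps <= obs + 1e-12 * abs(obs)])))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Krippendorff's alpha for nominal ratings
#'
#' Chance-corrected inter-rater agreement via the coincidence-matrix
#' formulation with missing-data support: within each item rated by
#' `m >= 2` raters, every ordered pair of ratings from different raters
#' contributes `1/(m-1)` to the coincidence matrix; alpha =
#' `1 - D_o / D_e` where `D_o` is the observed and `D_e` the expected
#' disagreement under the nominal metric. Items with fewer than two
#' ratings are ignored. An optional item-level bootstrap gives a CI.
#'
#' @param ratings Items x raters matrix (nominal codes; `NA` = missing).
#' @param bootstrap Number of bootstrap resamples for the CI (0 = none).
#' @param seed Seed for the bootstrap (required when `bootstrap > 0`).
#' @param conf Confidence level (default 0.95).
#' @return List with `alpha`, `n_items`, `n_pairable`, and (with
#'   bootstrap) `ci`.
#' @export
krippendorff_alpha <- function(ratings, bootstrap = 0, seed = NULL,
                               conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) stop("need at least 2 raters")
  usable <- rowSums(!is.na(ratings)) >= 2
  if (sum(usable) < 1)
    stop("no item is rated by at least 2 raters")
  alpha <- .kripp_alpha_value(ratings[usable, , drop = FALSE])
  out <- list(alpha = alpha, n_items = nrow(ratings),
              n_pairable = sum(usable))
  if (bootstrap > 0) {
    if (is.null(seed)) stop("bootstrap CI requires a seed")
    set.seed(as.integer(seed))
    items <- which(usable)
    reps <- vapply(seq_len(bootstrap), function(i) {
      pick <- sample(items, length(items), replace = TRUE)
      .kripp_alpha_value(ratings[pick, , drop = FALSE])
    }, 0)
    reps <- reps[is.finite(reps)]
    qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    out$ci <- qs
    out$bootstrap <- bootstrap
  }
  out
}

.kripp_alpha_value <- function(ratings) {
  vals <- sort(unique(as.vector(ratings[!is.na(ratings)])))
  nv <- length(vals)
  if (nv < 2) return(1)  # zero observed and expected disagreement
  o <- matrix(0, nv, nv, dimnames = list(vals, vals))
  for (u in seq_len(nrow(ratings))) {
    r <- ratings[u, ]
    r <- r[!is.na(r)]
    m <- length(r)
    if (m < 2) next
    idx <- match(r, vals)
    tab <- tabulate(idx, nv)
    # ordered pairs from different raters, weighted by 1/(m-1)
    pair <- tab %o% tab - diag(tab, nv)
    o <- o + pair / (m - 1)
  }
  nc <- rowSums(o)
  n <- sum(nc)
  d_o <- sum(o) - sum(diag(o))
  d_e <- (sum(nc %o% nc) - sum(nc^2)) / (n - 1)
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

#' Paired t-test from first principles
#'
#' Classical two-tailed paired t-test of per-pair differences, with a
#' `conf`-level CI from the t quantile with n-1 degrees of freedom. With
#' zero variance of the differences, p = 1 when the mean difference is 0
#' and a degenerate flag with p -> 0 otherwise.
#'
#' @param x,y Paired numeric vectors (`y` omitted: `x` are differences).
#' @param conf Confidence level (default 0.95).
#' @return List with `mean_diff`, `ci`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_test <- function(x, y = NULL, conf = 0.95) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  n <- length(d)
  if (n < 3) stop("paired_t_test: need at least 3 pairs")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(mean_diff = m, ci = c(m, m), t = if (m == 0) 0 else Inf,
                df = n - 1, p = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tval <- m / se
  p <- 2 * pt(-abs(tval), df = n - 1)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  list(mean_diff = m, ci = c(m - tq * se, m + tq * se), t = tval,
       df = n - 1, p = p, degenerate = FALSE)
}

#' Random-intercept difference model by method of moments
#'
#' One-way random-effects decomposition of per-pair differences
#' `d_ij = beta0 + U_i + e_ij` (patient i, electrode j): `beta0` is the
#' grand mean, `sigma2` the within-patient mean square, and `tau2` the
#' ANOVA moment estimate `(MSB - MSW) / n0` truncated at zero, with
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`. The CI for `beta0` uses the
#' between-patient variance of patient means (t quantile, a-1 df), which
#' respects within-patient clustering. A single patient falls back to
#' [paired_t_test()] with a warning.
#'
#' @param x,y Paired numeric vectors (`y` omitted: `x` are differences).
#' @param patient Patient id per pair.
#' @param conf Confidence level (default 0.95).
#' @return List with `beta0`, `tau2`, `sigma2`, `ci`, `p` (Z-test of
#'   beta0 = 0), `n_patients`, `n_pairs`.
#' @export
random_intercept_fit <- function(x, y = NULL, patient, conf = 0.95) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  patient <- as.character(patient)
  if (length(patient) != length(d) || any(is.na(patient)) ||
      any(patient == ""))
    stop("need one non-empty patient id per pair")
  groups <- split(d, patient)
  a <- length(groups)
  if (a < 2) {
    warning("single patient: falling back to paired_t_test")
    tt <- paired_t_test(d, conf = conf)
    return(list(beta0 = tt$mean_diff, tau2 = NA_real_,
                sigma2 = stats::var(d), ci = tt$ci, p = tt$p,
                n_patients = 1L, n_pairs = length(d)))
  }
  N <- length(d)
  ni <- vapply(groups, length, 1L)
  mi <- vapply(groups, mean, 0)
  grand <- mean(d)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  msw <- ssw / (N - a)
  ssb <- sum(ni * (mi - grand)^2)
  msb <- ssb / (a - 1)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  sigma2 <- msw
  tau2 <- max(0, (msb - msw) / n0)
  se <- stats::sd(mi) / sqrt(a)
  tq <- qt(1 - (1 - conf) / 2, df = a - 1)
  z <- if (se > 0) grand / se else Inf * sign(grand)
  p <- 2 * stats::pnorm(-abs(z))
  list(beta0 = grand, tau2 = tau2, sigma2 = sigma2,
       ci = c(grand - tq * se, grand + tq * se), p = p,
       n_patients = a, n_pairs = N)
}

#' Read a ratings CSV into an items x raters matrix
#'
#' Columns `item_id`, `rater_id`, `rating`; missing cells are simply
#' absent rows.
#'
#' @param path File path.
#' @return Items x raters character matrix with `NA` for missing ratings.
#' @export
read_ratings_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "rater_id", "rating")
  if (!all(need %in% names(df)))
    stop(sprintf("ratings CSV %s: need columns %s", path,
                 paste(need, collapse = ", ")))
  items <- unique(df$item_id)
  raters <- unique(df$rater_id)
  m <- matrix(NA_character_, length(items), length(raters),
              dimnames = list(items, raters))
  m[cbind(match(df$item_id, items), match(df$rater_id, raters))] <-
    as.character(df$rating)
  m
}
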