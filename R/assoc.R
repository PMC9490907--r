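#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation over pairwise-complete observations, average ranks for
#' ties; the p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @return List with `rho`, `p.value`, `n` (complete pairs). Zero variance in
#'   either variable yields `rho = NA` with a warning.
#' @examples
#' spearman_cor(1:4, c(10, 20, 30, 25))$rho  # 0.8
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(rho = NA_real_, p.value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Differential rank correlation between two groups
#'
#' Computes the Spearman correlation of `x` and `y` within each group, the
#' Fisher z difference statistic
#' \deqn{z_{diff} = \frac{\mathrm{atanh}(\rho_A) - \mathrm{atanh}(\rho_B)}
#'       {\sqrt{1/(n_A-3) + 1/(n_B-3)}}}
#' and a two-sided empirical p-value from random permutations of the group
#' membership: \eqn{p = (1 + \#\{|z_{perm}| \ge |z_{obs}|\})/(P+1)}, so the
#' smallest attainable p is `1/(n_perm+1)`.
#'
#' @param x,y Numeric vectors.
#' @param group Two-level grouping vector.
#' @param n_perm Number of permutations.
#' @param seed Permutation seed (recorded in the result).
#' @return List with `rho_A`, `rho_B`, `z_diff`, `empirical_p`, `n_A`, `n_B`,
#'   `n_permutations`, `seed`.
#' @export
differential_correlation <- function(x, y, group, n_perm = 10000, seed = 1L) {
  ok <- stats::complete.cases(x, y, group)
  x <- x[ok]; y <- y[ok]; g <- factor(group[ok])
  if (nlevels(g) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  ga <- g == levels(g)[1]
  n_a <- sum(ga); n_b <- sum(!ga)
  if (min(n_a, n_b) < 5L) stop("each group needs at least 5 observations", call. = FALSE)
  zstat <- function(is_a) {
    ra <- stats::cor(rank(x[is_a]), rank(y[is_a]))
    rb <- stats::cor(rank(x[!is_a]), rank(y[!is_a]))
    if (abs(ra) > 1 - 1e-10 || abs(rb) > 1 - 1e-10)
      stop("perfect within-group correlation; Fisher z diverges", call. = FALSE)
    list(z = (atanh(ra) - atanh(rb)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3)),
         ra = ra, rb = rb)
  }
  obs <- zstat(ga)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    perm <- sample(ga)
    zp <- tryCatch(zstat(perm)$z, error = function(e) Inf)
    if (abs(zp) >= abs(obs$z)) exceed <- exceed + 1L
  }
  list(rho_A = obs$ra, rho_B = obs$rb, z_diff = obs$z,
       empirical_p = (1 + exceed) / (n_perm + 1),
       n_A = n_a, n_B = n_b, n_permutations = n_perm, seed = seed)
}

# quantile discretisation into up to n_levels bins; already-discrete inputs
# (few unique values) are used as-is
discretize_var <- function(v, n_levels = 3) {
  if (is.factor(v) || is.character(v) || length(unique(v)) <= n_levels)
    return(factor(v))
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_levels + 1),
                               na.rm = TRUE))
  if (length(br) < 3L) return(factor(v > br[1]))
  cut(v, breaks = br, include.lowest = TRUE)
}

#' Chi-square (conditional) independence test via contingency mutual information
#'
#' Continuous variables are discretised into `n_levels` sample-quantile bins.
#' The statistic is \eqn{G = 2 N \cdot MI} where MI is the (conditional)
#' mutual information of the contingency table in natural log units
#' (`0 log 0 = 0`), asymptotically chi-square with
#' \eqn{df = (|X|-1)(|Y|-1) \cdot |Z|} degrees of freedom (marginal test,
#' \eqn{df = (|X|-1)(|Y|-1)}, when `z` is absent). Empty conditioning strata
#' are dropped from the degrees of freedom with a warning.
#'
#' @param x,y Variables to test.
#' @param z Optional conditioning variable(s); a vector or data frame.
#' @param n_levels Quantile bins for continuous variables.
#' @return List with `G`, `mi` (raw mutual information in nats), `df`,
#'   `p.value`, `n`, and the `discretization` spec.
#' @examples
#' x <- rep(c(0, 1), c(40, 40))
#' y <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
#' conditional_independence(x, y)$G  # about 20.93
#' @export
conditional_independence <- function(x, y, z = NULL, n_levels = 3) {
  zf <- if (!is.null(z)) {
    if (is.data.frame(z)) interaction(lapply(z, discretize_var, n_levels = n_levels),
                                      drop = TRUE)
    else discretize_var(z, n_levels)
  }
  ok <- if (is.null(z)) stats::complete.cases(x, y)
        else stats::complete.cases(x, y, zf)
  xf <- discretize_var(x[ok], n_levels)
  yf <- discretize_var(y[ok], n_levels)
  n <- length(xf)
  if (n < 20L) stop("need at least 20 observations", call. = FALSE)
  plogp_sum <- function(p) sum(ifelse(p > 0, p * log(p), 0))
  if (is.null(z)) {
    tab <- table(xf, yf)
    p <- tab / n
    mi <- plogp_sum(p) - plogp_sum(rowSums(p)) - plogp_sum(colSums(p))
    df <- (nlevels(xf) - 1) * (nlevels(yf) - 1)
    n_strata <- NULL
  } else {
    zf <- droplevels(zf[ok])
    tab <- table(xf, yf, zf)
    pz_all <- apply(tab, 3, sum) / n
    nonempty <- pz_all > 0
    if (any(!nonempty))
      warning(sum(!nonempty), " empty conditioning strata dropped from df")
    mi <- 0
    for (k in which(nonempty)) {
      pk <- tab[, , k] / n
      pz <- sum(pk)
      # sum p(x,y,z) log[ p(x,y,z) p(z) / (p(x,z) p(y,z)) ]
      mi <- mi + plogp_sum(pk) + pz * log(pz) -
        plogp_sum(rowSums(pk)) - plogp_sum(colSums(pk))
    }
    df <- (nlevels(xf) - 1) * (nlevels(yf) - 1) * sum(nonempty)
    n_strata <- sum(nonempty)
  }
  mi <- max(mi, 0)
  G <- 2 * n * mi
  list(G = G, mi = mi, df = df,
       p.value = stats::pchisq(G, df = df, lower.tail = FALSE), n = n,
       discretization = list(n_levels = n_levels,
                             x_levels = nlevels(xf), y_levels = nlevels(yf),
                             z_strata = n_strata))
}

#' Compare a variable between two groups
#'
#' Numeric variables are compared with a Welch two-sample t-test; binary
#' (0/1) variables with a pooled two-proportions z-test (optionally with
#' continuity correction).
#'
#' @param values Numeric or 0/1 vector.
#' @param group Two-level grouping vector.
#' @param continuity Continuity correction for the proportions test.
#' @return List with `statistic`, `p.value`, `method`, group summaries.
#' @examples
#' group_compare(c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
#'               rep(c("a", "b"), each = 100))$statistic  # about 3.536
#' @export
group_compare <- function(values, group, continuity = FALSE) {
  ok <- stats::complete.cases(values, group)
  values <- values[ok]; g <- factor(group[ok])
  if (nlevels(g) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  x <- values[g == levels(g)[1]]; y <- values[g == levels(g)[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (all(values %in% c(0, 1))) {
    n1 <- length(x); n2 <- length(y)
    p1 <- mean(x); p2 <- mean(y)
    pp <- (sum(x) + sum(y)) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    num <- p1 - p2
    if (continuity) num <- sign(num) * max(0, abs(num) - 0.5 * (1 / n1 + 1 / n2))
    zstat <- if (se > 0) num / se else 0
    list(statistic = zstat, p.value = 2 * stats::pnorm(-abs(zstat)),
         method = "two-proportions z", estimate = c(p1 = p1, p2 = p2))
  } else {
    if (stats::sd(values) == 0)
      return(list(statistic = 0, p.value = 1, method = "Welch t",
                  estimate = c(mean1 = mean(x), mean2 = mean(y))))
    tt <- stats::t.test(x, y)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         method = "Welch t", estimate = c(mean1 = mean(x), mean2 = mean(y)))
  }
}
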