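# Factorial statistics stage on per-animal metric tables: two-factor
# omnibus ANOVA (Type III sums of squares under sum-to-zero coding, robust
# to the unequal group sizes typical of these cohorts), Sidak-adjusted
# pairwise comparisons on the pooled residual, and the unpaired t /
# Mann-Whitney tests used for amyloid and CAA outcomes.

#' Two-way omnibus ANOVA (Type III)
#'
#' Fits `value ~ A * B` under sum-to-zero contrasts and reports Type III
#' sums of squares, so main effects are tested adjusting for the other
#' factor and the interaction even when the design is unbalanced. F is the
#' effect mean square over the residual mean square.
#'
#' @param values Numeric response (one value per animal).
#' @param factorA,factorB Two-level factors (character or factor), e.g.
#'   amyloid-transgene genotype and apoA-I genotype.
#' @return An `anova_table` data frame with rows `factorA`, `factorB`,
#'   `interaction`, `residual` and columns `sum_sq`, `df`, `mean_sq`, `F`,
#'   `p`. Attributes carry the residual mean square and df, the cell means
#'   and group sizes for downstream pairwise comparisons.
#' @export
two_way_anova <- function(values, factorA, factorB) {
  a <- factor(factorA); b <- factor(factorB)
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both factors must have exactly two observed levels")
  if (any(table(a, b) == 0)) stop("empty design cell")
  n <- length(values)
  if (n - 4 < 1) stop("residual degrees of freedom must be >= 1")
  d <- data.frame(y = as.numeric(values), a = a, b = b)
  stats::contrasts(d$a) <- stats::contr.sum(2)
  stats::contrasts(d$b) <- stats::contr.sum(2)
  X <- stats::model.matrix(~ a * b, d)
  # Type III SS by comparing the full fit against each single-term deletion
  # under sum-to-zero coding
  rss <- function(cols)
    sum(stats::lm.fit(X[, cols, drop = FALSE], d$y)$residuals^2)
  rss_full <- rss(1:4)
  ss <- c(rss(c(1, 3, 4)) - rss_full,   # factor A
          rss(c(1, 2, 4)) - rss_full,   # factor B
          rss(1:3) - rss_full,          # interaction
          rss_full)
  ss <- pmax(ss, 0)
  df <- c(1, 1, 1, n - 4)
  ms <- ss / df
  tot <- sum((d$y - mean(d$y))^2)
  zero_resid <- !is.finite(ms[4]) || rss_full <= 1e-12 * max(tot, .Machine$double.xmin)
  Fv <- c(ms[1:3] / ms[4], NA)
  pv <- c(stats::pf(Fv[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  if (zero_resid) { Fv[1:3] <- NA; pv[1:3] <- NA }
  out <- data.frame(
    effect = c("factorA", "factorB", "interaction", "residual"),
    sum_sq = ss, df = df, mean_sq = ms, F = Fv, p = pv,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cell <- interaction(a, b, drop = FALSE, sep = ".")
  structure(out, class = c("anova_table", "data.frame"),
            ms_resid = ms[4], df_resid = df[4],
            zero_residual = zero_resid,
            cell_means = tapply(d$y, cell, mean),
            cell_n = as.vector(table(cell)),
            cell_names = levels(cell))
}

#' Sidak-adjusted pairwise comparisons
#'
#' Pairwise t comparisons of group means on the pooled within-group residual
#' (the two-way fit's residual mean square),
#' `t = (mean_i - mean_j) / sqrt(MS_res (1/n_i + 1/n_j))` with the residual
#' df, two-sided raw p, and the Sidak familywise adjustment
#' `p_adj = 1 - (1 - p_raw)^m` over the `m` requested comparisons. By
#' default the family is the four simple-effect comparisons of a 2x2 design
#' (each level of one factor compared across the other).
#'
#' @param values Numeric response.
#' @param groups Group labels (the `A.B` cell names).
#' @param comparisons List of length-2 character vectors naming the pairs;
#'   `NULL` uses the four simple-effect pairs of a 2x2 layout
#'   `WT/APPPS1 x HEM/KO`.
#' @return Data frame with one row per comparison: `group_i`, `group_j`,
#'   `mean_diff`, `t_stat`, `df`, `p_raw`, `p_adj`, `m`.
#' @export
sidak_pairwise <- function(values, groups, comparisons = NULL) {
  g <- factor(groups)
  if (is.null(comparisons)) {
    comparisons <- list(c("WT.KO", "WT.HEM"), c("APPPS1.KO", "APPPS1.HEM"),
                        c("APPPS1.HEM", "WT.HEM"), c("APPPS1.KO", "WT.KO"))
  }
  bad <- setdiff(unlist(comparisons), levels(g))
  if (length(bad)) stop("comparison references unknown group: ",
                        paste(bad, collapse = ", "))
  means <- tapply(as.numeric(values), g, mean)
  ns <- tapply(values, g, length)
  df_res <- length(values) - nlevels(g)
  ms_res <- sum(tapply(as.numeric(values), g, function(x)
    sum((x - mean(x))^2))) / df_res
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(ms_res * (1 / ns[[i]] + 1 / ns[[j]]))
    t <- if (se > 0) diff / se else if (diff == 0) 0 else NA_real_
    p_raw <- if (is.na(t)) NA_real_ else
      2 * stats::pt(abs(t), df_res, lower.tail = FALSE)
    data.frame(group_i = i, group_j = j, mean_diff = diff, t_stat = t,
               df = df_res, p_raw = p_raw,
               p_adj = pmin(pmax(1 - (1 - p_raw)^m, p_raw), 1), m = m,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Unpaired two-sample t test
#'
#' Student's pooled-variance test by default; Welch-Satterthwaite df when
#' `welch = TRUE`. Two-sided.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param welch Use the Welch test.
#' @return List with `t`, `df`, `p` and a `degenerate` flag (TRUE when the
#'   pooled variance is zero, in which case the statistics are NA unless the
#'   samples are identical in mean, where t = 0 and p = 1).
#' @export
unpaired_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1, degenerate = TRUE))
    return(list(t = NA_real_, df = length(x) + length(y) - 2, p = NA_real_,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' `U` counts pairs with `x_i > y_j`, ties counting one half. For
#' `n_x + n_y <= max_exact` the two-sided p-value is exact: the complete
#' permutation distribution of U over all `C(n_x + n_y, n_x)` group
#' labelings of the observed values (valid with ties, since the
#' distribution is conditioned on the observed values). Otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Numeric samples (each n >= 1).
#' @param max_exact Largest combined sample size for complete enumeration.
#' @return List with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, max_exact = 16) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples need n >= 1")
  u_stat <- function(xv, yv) {
    cmp <- outer(xv, yv, function(a, b) (a > b) + 0.5 * (a == b))
    sum(cmp)
  }
  U <- u_stat(x, y)
  N <- nx + ny
  if (N <= max_exact) {
    pool <- c(x, y)
    idx <- utils::combn(N, nx)
    mid <- nx * ny / 2
    dev <- abs(U - mid)
    us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
    p <- mean(abs(us - mid) >= dev - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  pool <- c(x, y)
  ties <- table(pool)
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal")
}

#' Run the statistics plan over a per-animal metric table
#'
#' For each metric/region: either the two-way omnibus ANOVA with Sidak
#' post-hoc comparisons (computed only when an omnibus effect is significant
#' at `alpha`, unless the gate is disabled), or — as used for amyloid and
#' CAA outcomes, which exist only in transgenic animals — an unpaired t or
#' Mann-Whitney comparison of the KO vs HEM transgenic groups.
#'
#' @param table Data frame with `animal_id`, `app_genotype`,
#'   `apoa1_genotype`, `metric`, `region`, `value`.
#' @param plan Named character vector metric -> test
#'   (`"anova"`, `"t"`, `"mannwhitney"`); metrics not named default to
#'   `"anova"`.
#' @param alpha Omnibus significance gate for post-hoc comparisons.
#' @param posthoc_gate Apply the gate (default TRUE).
#' @return List of per-metric/region results: `anova` tables, `posthoc`
#'   comparison tables (possibly NULL when gated), or two-group test
#'   results.
#' @export
run_stats_plan <- function(table, plan = NULL, alpha = 0.05,
                           posthoc_gate = TRUE) {
  need <- c("animal_id", "app_genotype", "apoa1_genotype", "metric", "value")
  if (!all(need %in% names(table))) stop("metric table lacks columns: ",
                                         paste(setdiff(need, names(table)), collapse = ", "))
  if (is.null(table$region)) table$region <- "all"
  out <- list()
  for (key in unique(paste(table$metric, table$region, sep = "/"))) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    sub <- table[table$metric == parts[1] & table$region == parts[2] &
                   !is.na(table$value), ]
    test <- if (!is.null(plan) && parts[1] %in% names(plan)) plan[[parts[1]]] else "anova"
    res <- list(metric = parts[1], region = parts[2], test = test,
                n = nrow(sub))
    if (test == "anova") {
      res$anova <- tryCatch(
        two_way_anova(sub$value, sub$app_genotype, sub$apoa1_genotype),
        error = function(e) e$message)
      if (inherits(res$anova, "anova_table")) {
        sig <- any(res$anova$p[1:3] < alpha, na.rm = TRUE)
        if (sig || !posthoc_gate) {
          res$posthoc <- sidak_pairwise(
            sub$value, paste(sub$app_genotype, sub$apoa1_genotype, sep = "."))
        } else res$posthoc <- NULL
        res$gated_out <- posthoc_gate && !sig
      }
    } else {
      tg <- sub[sub$app_genotype == "APPPS1", ]
      xs <- tg$value[tg$apoa1_genotype == "KO"]
      ys <- tg$value[tg$apoa1_genotype == "HEM"]
      if (length(xs) >= 2 && length(ys) >= 2) {
        res$result <- if (test == "t") unpaired_t(xs, ys) else mann_whitney(xs, ys)
      } else res$result <- "insufficient transgenic animals"
    }
    out[[key]] <- res
  }
  out
}
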