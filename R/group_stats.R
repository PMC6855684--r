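#' Pool left/right measures by affected side
#'
#' Re-expresses per-subject left/right hand (or hemisphere) measures as
#' affected/unaffected: subjects with right-hand CRPS have their left/right
#' values swapped so the affected side is aligned across all patients;
#' left-CRPS subjects are unchanged; controls get a fixed pseudo-assignment
#' (left hand = "affected") recorded in the output. Missing values
#' propagate. Applying the pooling twice is the identity on patients.
#'
#' @param left,right numeric vectors of per-subject measures.
#' @param group vector/factor in `control`, `left-CRPS`, `right-CRPS`.
#' @return data frame of class `pooled_measures`: `group` (collapsed to
#'   control/CRPS), `affected`, `unaffected`, `affected_side`.
#' @export
pool_by_affected_side <- function(left, right, group) {
  group <- as.character(group)
  ok <- group %in% c("control", "left-CRPS", "right-CRPS")
  if (!all(ok)) stop("unknown group label: ", paste(unique(group[!ok]), collapse = ", "))
  flip <- group == "right-CRPS"
  affected <- ifelse(flip, right, left)
  unaffected <- ifelse(flip, left, right)
  out <- data.frame(
    group = factor(ifelse(group == "control", "control", "CRPS"),
                   levels = c("control", "CRPS")),
    affected = affected, unaffected = unaffected,
    affected_side = ifelse(group == "right-CRPS", "right", "left"),
    stringsAsFactors = FALSE)
  attr(out, "control_pseudo_side") <- "left"
  class(out) <- c("pooled_measures", "data.frame")
  out
}

#' Student t test
#'
#' Thin wrapper returning the pooled-variance independent-samples t test
#' (df = n1 + n2 - 2) or the paired t test on difference scores, two-tailed.
#'
#' @param values1,values2 numeric samples (pairs matched by position when
#'   `paired`); missing pairs are dropped.
#' @param paired logical.
#' @return list `t`, `df`, `p`.
#' @export
ttest <- function(values1, values2, paired = FALSE) {
  if (paired) {
    ok <- !is.na(values1) & !is.na(values2)
    values1 <- values1[ok]; values2 <- values2[ok]
    if (length(values1) < 2) stop("need at least 2 complete pairs")
    degenerate <- stats::sd(values1 - values2) == 0
    df <- length(values1) - 1
    delta <- mean(values1 - values2)
  } else {
    values1 <- values1[!is.na(values1)]; values2 <- values2[!is.na(values2)]
    if (length(values1) < 2 || length(values2) < 2) {
      stop("need at least 2 observations per sample")
    }
    degenerate <- stats::sd(values1) == 0 && stats::sd(values2) == 0
    df <- length(values1) + length(values2) - 2
    delta <- mean(values1) - mean(values2)
  }
  if (degenerate) {
    # zero-variance input: the statistic is the exact limit, not NaN
    t <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(t = t, df = df, p = if (delta == 0) 1 else 0))
  }
  ht <- if (paired) stats::t.test(values1, values2, paired = TRUE)
  else stats::t.test(values1, values2, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Jeffreys-Zellner-Siow Bayes factor for a t statistic
#'
#' Default-prior Bayes factor `BF10` for a point null against a Cauchy
#' prior with scale `cauchy_scale` on the standardized effect size:
#' the marginal likelihood of the observed t under the alternative
#' (noncentral t integrated over the prior) divided by its central-t
#' likelihood under the null. Two-sample when `n2` is given
#' (`df = n1 + n2 - 2`, effective n `n1*n2/(n1+n2)`), one-sample/paired
#' otherwise (`df = n1 - 1`, effective n `n1`).
#'
#' @param t observed t statistic.
#' @param n1 first sample size (or number of pairs).
#' @param n2 second sample size, or `NULL` for the one-sample form.
#' @param cauchy_scale prior scale (default `sqrt(2)/2`, i.e. 0.707).
#' @return `BF10`.
#' @export
jzs_bf_ttest <- function(t, n1, n2 = NULL, cauchy_scale = sqrt(2) / 2) {
  if (n1 <= 1 || (!is.null(n2) && n2 <= 1)) stop("sample sizes must exceed 1")
  if (is.null(n2)) {
    nu <- n1 - 1; neff <- n1
  } else {
    nu <- n1 + n2 - 2; neff <- n1 * n2 / (n1 + n2)
  }
  # noncentral-t densities at extreme ncp underflow with a precision warning;
  # the integrand is effectively zero there
  marg <- suppressWarnings(stats::integrate(
    function(delta) {
      stats::dt(t, df = nu, ncp = delta * sqrt(neff)) *
        stats::dcauchy(delta, scale = cauchy_scale)
    }, -Inf, Inf, rel.tol = 1e-9, abs.tol = 0)$value)
  marg / stats::dt(t, df = nu)
}

#' 2x2 mixed-design ANOVA
#'
#' Classical mixed ANOVA for one within-subject factor `side` (affected vs
#' unaffected, one observation per cell) and one between-subjects factor
#' `group` (control vs CRPS): the group effect is tested against the
#' between-subject error stratum and side and side-by-group against the
#' within-subject residual. Subjects with a missing value on either side
#' are dropped listwise (count reported).
#'
#' @param pooled a [pool_by_affected_side()] data frame (columns `group`,
#'   `affected`, `unaffected`).
#' @return object of class `mixed_anova`: data frame `table` with one row
#'   per effect (`F`, `df1`, `df2`, `p`, `eta_sq`, `pes`), `n_used`,
#'   `n_dropped`.
#' @export
mixed_anova_2x2 <- function(pooled) {
  cc <- stats::complete.cases(pooled[, c("group", "affected", "unaffected")])
  d <- pooled[cc, , drop = FALSE]
  if (any(table(d$group) < 2)) {
    stop("need at least 2 complete subjects per group")
  }
  n <- nrow(d)
  long <- data.frame(
    id = factor(rep(seq_len(n), 2L)),
    group = factor(rep(as.character(d$group), 2L)),
    side = factor(rep(c("affected", "unaffected"), each = n)),
    value = c(d$affected, d$unaffected))
  fit <- stats::aov(value ~ group * side + Error(id), data = long)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: id"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  rn <- function(df) trimws(rownames(df))
  pick <- function(df, term) df[match(term, rn(df)), , drop = FALSE]
  ss_all <- sum(btw$`Sum Sq`, wth$`Sum Sq`)
  row_of <- function(df, term, err) {
    r <- pick(df, term); e <- pick(df, err)
    f <- r$`Sum Sq` / r$Df / (e$`Sum Sq` / e$Df)
    c(F = f, df1 = r$Df, df2 = e$Df, p = f_to_p(f, r$Df, e$Df),
      eta_sq = r$`Sum Sq` / ss_all,
      pes = r$`Sum Sq` / (r$`Sum Sq` + e$`Sum Sq`))
  }
  tab <- rbind(
    group = row_of(btw, "group", "Residuals"),
    side = row_of(wth, "side", "Residuals"),
    `side:group` = row_of(wth, "group:side", "Residuals"))
  structure(list(table = as.data.frame(tab), n_used = n,
                 n_dropped = sum(!cc)),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("2x2 mixed ANOVA (n = %d complete, %d dropped)\n",
              x$n_used, x$n_dropped))
  print(round(x$table, 4))
  invisible(x)
}

#' Shapiro-Wilk normality check with log fallback
#'
#' Tests normality at `alpha`; if rejected and all values are strictly
#' positive, applies a natural-log transform and re-tests. Rejection with
#' nonpositive values is an explicit error (no silent offset is added).
#'
#' @param values numeric (NAs dropped), 3-5000 observations.
#' @param alpha Shapiro-Wilk level (default 0.05).
#' @return list `values` (possibly transformed), `transformed` flag,
#'   `W`, `p` (original test), `W_log`, `p_log` (post-transform, or `NA`).
#' @export
normality_log_pipeline <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  ht <- stats::shapiro.test(values)
  if (ht$p.value >= alpha) {
    return(list(values = values, transformed = FALSE,
                W = unname(ht$statistic), p = ht$p.value,
                W_log = NA_real_, p_log = NA_real_))
  }
  if (any(values <= 0)) {
    stop("non-normal values include nonpositive entries; ",
         "log transform is undefined (no offset is applied silently)")
  }
  lv <- log(values)
  ht2 <- stats::shapiro.test(lv)
  list(values = lv, transformed = TRUE,
       W = unname(ht$statistic), p = ht$p.value,
       W_log = unname(ht2$statistic), p_log = ht2$p.value)
}

#' Compare two correlation coefficients via Fisher's z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed normal p-value. Used to compare affected- versus
#' unaffected-side correlations between map and clinical measures.
#'
#' @param r1,r2 Pearson correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list `z`, `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg critical values
#'
#' Step-up FDR control at rate `q` for a family of m tests: the i-th
#' smallest p-value is compared against `i*q/m`. Returns, in the original
#' test order, each test's assigned critical value and whether the test is
#' declared significant by the step-up rule.
#'
#' @param p_values numeric vector of p-values.
#' @param q false discovery rate (default 0.05).
#' @return data frame `p`, `rank`, `critical`, `pass` (original order).
#' @export
bh_critical_values <- function(p_values, q = 0.05) {
  m <- length(p_values)
  ord <- order(p_values)
  rank <- integer(m); rank[ord] <- seq_len(m)
  critical <- rank * q / m
  below <- which(p_values[ord] <= seq_len(m) * q / m)
  k <- if (length(below)) max(below) else 0L
  pass <- rank <= k
  data.frame(p = p_values, rank = rank, critical = critical, pass = pass)
}

#' Pressure-pain severity score
#'
#' Severity of the affected-hand pressure-pain deficit as a normalized
#' threshold difference:
#' `(ppt_unaffected - ppt_affected) / (ppt_unaffected + ppt_affected)`,
#' in `[-1, 1]`; 0 for equal thresholds, 1 when the affected hand's
#' threshold vanishes. `normalized = FALSE` gives the plain difference.
#'
#' @param ppt_affected,ppt_unaffected thresholds in kg/cm^2 (>= 0, not both
#'   zero).
#' @param normalized divide by the sum (default) or return the plain
#'   difference.
#' @return severity score (vectorized).
#' @export
pp_severity <- function(ppt_affected, ppt_unaffected, normalized = TRUE) {
  if (any(ppt_affected < 0 | ppt_unaffected < 0, na.rm = TRUE)) {
    stop("PPTs must be nonnegative")
  }
  if (any(ppt_affected + ppt_unaffected == 0, na.rm = TRUE)) {
    stop("undefined severity: both PPTs are zero")
  }
  d <- ppt_unaffected - ppt_affected
  if (normalized) d / (ppt_unaffected + ppt_affected) else d
}
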