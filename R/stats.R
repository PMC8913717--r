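# Inferential layer: two-sample / paired t-tests and mixed factorial
# (split-plot) ANOVA with Mauchly sphericity test and Greenhouse-Geisser
# correction. Implemented from sums of squares rather than wrapping model
# fitters, so degenerate inputs (zero variance) follow explicit conventions;
# the test suite checks equivalence against stats::aov / stats::anova.mlm.

#' Student/Welch/paired t-test with explicit degenerate conventions
#'
#' Two-sided throughout. Unpaired tests default to the pooled-variance
#' Student statistic (`var_equal = TRUE`); Welch's unequal-variance form is
#' available by flag. When every observation is identical (zero variance):
#' equal means give `t = 0, p = 1`; a nonzero mean difference with zero
#' variance gives an infinite statistic reported as `p = 0` with the
#' `degenerate` flag set.
#'
#' @param x numeric sample (or first member of the pair)
#' @param y numeric sample; required for paired tests
#' @param paired treat `x` and `y` as paired observations
#' @param var_equal pooled-variance Student statistic for unpaired tests
#' @return list of class `at_ttest`: `statistic`, `df`, `p_value`,
#'   `mean_difference`, `kind`, `degenerate`
#' @export
t_test <- function(x, y = NULL, paired = FALSE, var_equal = TRUE) {
  if (paired) {
    if (is.null(y) || length(x) != length(y))
      at_stop("paired test needs equal-length x and y", "allotrace_contract_error")
    d <- x - y
    n <- length(d)
    if (n < 2L) at_stop("need at least 2 pairs", "allotrace_sample_size_error")
    md <- mean(d); s <- stats::sd(d); df <- n - 1
    if (s == 0) {
      res <- if (md == 0) list(statistic = 0, p_value = 1) else
        list(statistic = sign(md) * Inf, p_value = 0)
      return(structure(c(res, list(df = df, mean_difference = md,
                                   kind = "paired", degenerate = TRUE)),
                       class = "at_ttest"))
    }
    t <- md / (s / sqrt(n))
    return(structure(list(statistic = t, df = df,
                          p_value = 2 * stats::pt(-abs(t), df),
                          mean_difference = md, kind = "paired",
                          degenerate = FALSE), class = "at_ttest"))
  }
  if (is.null(y)) at_stop("two samples required", "allotrace_contract_error")
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    at_stop("each sample needs at least 2 observations", "allotrace_sample_size_error")
  md <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0 || !is.finite(df)) {
    res <- if (md == 0) list(statistic = 0, p_value = 1) else
      list(statistic = sign(md) * Inf, p_value = 0)
    return(structure(c(res, list(df = if (var_equal) n1 + n2 - 2 else NA_real_,
                                 mean_difference = md, kind = "unpaired",
                                 degenerate = TRUE)), class = "at_ttest"))
  }
  t <- md / se
  structure(list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
                 mean_difference = md, kind = "unpaired", degenerate = FALSE),
            class = "at_ttest")
}

#' @export
print.at_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.4g) = %.4g, p = %.4g\n", x$kind, x$df,
              x$statistic, x$p_value))
  invisible(x)
}

#' Format a test result in the field's notation
#' @param x an `at_ttest` or one row of a [mixed_anova()] table
#' @return character scalar like `"t(9) = -3.89, p = 0.004"`
#' @export
format_test <- function(x) {
  if (inherits(x, "at_ttest"))
    return(sprintf("t(%s) = %s, p = %s", format(round(x$df, 2)),
                   format(round(x$statistic, 2)), format(round(x$p_value, 3))))
  sprintf("F(%s, %s) = %s, p = %s", format(round(x$df1, 2)),
          format(round(x$df2, 2)), format(round(x$F, 2)),
          format(round(x$p_value, 3)))
}

# Orthonormal contrast matrix orthogonal to the intercept, (k-1) x k.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  t(m %*% diag(1 / sqrt(colSums(m^2)), ncol(m), ncol(m)))
}

#' Mixed factorial (split-plot) ANOVA with sphericity handling
#'
#' One between-subject factor (treatment group) and one within-subject
#' factor (time), complete and balanced: every subject observed at every
#' time level. Classical split-plot sums of squares: the group effect is
#' tested against the between-subject error, time and the group x time
#' interaction against the subject x time error. Mauchly's test is applied
#' to the pooled within-group covariance of the time profiles; when
#' sphericity is rejected at `alpha_sphericity` (or always, by config), the
#' Greenhouse-Geisser epsilon multiplies both degrees of freedom of the
#' within-subject effects.
#'
#' @param data long data.frame/data.table with one row per subject x time
#' @param value,subject,time,group column names
#' @param sphericity `"mauchly"` (correct when Mauchly p < alpha),
#'   `"always"`, or `"never"`
#' @param alpha_sphericity Mauchly rejection level (default 0.05)
#' @return `data.table` with one row per effect (`group`, `time`,
#'   `group:time`): `F`, `df1`, `df2`, `p_value`, `gg_epsilon`, `corrected`,
#'   `mauchly_W`, `mauchly_p`, `degenerate`
#' @export
mixed_anova <- function(data, value = "value", subject = "subject",
                        time = "time", group = "group",
                        sphericity = c("mauchly", "always", "never"),
                        alpha_sphericity = 0.05) {
  sphericity <- match.arg(sphericity)
  dt0 <- data.table::as.data.table(data)
  dt <- data.table::data.table(subject = as.character(dt0[[subject]]),
                               time = as.character(dt0[[time]]),
                               group = as.character(dt0[[group]]),
                               value = as.numeric(dt0[[value]]))
  times <- unique(dt$time)
  subjects <- unique(dt$subject)
  k <- length(times); n <- length(subjects)
  cells <- dt[, .N, by = .(subject, time)]
  if (nrow(cells) != n * k || any(cells$N != 1L))
    at_stop("mixed_anova requires a complete balanced table (every subject at every timepoint, once)",
            "allotrace_contract_error")
  wide <- data.table::dcast(dt, subject + group ~ time, value.var = "value")
  data.table::setkey(wide, NULL)
  y <- as.matrix(wide[, ..times])
  grp <- factor(wide$group)
  g <- nlevels(grp)
  if (any(table(grp) < 2L))
    at_stop("each group needs at least 2 subjects", "allotrace_sample_size_error")

  grand <- mean(y)
  subj_means <- rowMeans(y)
  time_means <- colMeans(y)
  grp_means <- tapply(subj_means, grp, mean)
  n_g <- as.vector(table(grp))

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (grp_means[levels(grp)] - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_time <- n * sum((time_means - grand)^2)
  cell_means <- rowsum(y, grp) / n_g  # g x k group-by-time means
  ss_gt <- sum(n_g * (cell_means - outer(as.vector(grp_means[levels(grp)]), rep(1, k)) -
                        outer(rep(1, g), time_means) + grand)^2)
  ss_within_err <- ss_total - ss_between_subj - ss_time - ss_gt

  df_group <- g - 1; df_subj_err <- n - g
  df_time <- k - 1; df_gt <- (g - 1) * (k - 1); df_win_err <- (n - g) * (k - 1)

  # pooled within-group covariance of the time profiles (error covariance)
  centered <- y - cell_means[as.integer(grp), , drop = FALSE]
  S <- crossprod(centered) / (n - g)
  C <- orthonormal_contrasts(k)
  E <- C %*% S %*% t(C)
  trE <- sum(diag(E))
  eps_lower <- 1 / (k - 1)
  if (trE <= 0) {
    gg_eps <- 1; mauchly_w <- NA_real_; mauchly_p <- NA_real_
  } else {
    gg_eps <- trE^2 / ((k - 1) * sum(E * E))
    detE <- det(E)
    mauchly_w <- detE / (trE / (k - 1))^(k - 1)
    if (!is.finite(mauchly_w) || mauchly_w <= 0) {
      mauchly_p <- NA_real_
      at_warn("singular within-covariance; Mauchly test unavailable, epsilon lower-bounded")
      gg_eps <- max(eps_lower, gg_eps, na.rm = TRUE)
    } else {
      # Box's chi-square approximation with the second-order term
      pp <- k - 1; d_err <- n - g
      rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * d_err)
      w2 <- (pp + 2) * (pp - 1) * (pp - 2) * (2 * pp^3 + 6 * pp^2 + 3 * k + 2) /
        (288 * (d_err * pp * rho)^2)
      z <- -d_err * rho * log(mauchly_w)
      f_df <- pp * (pp + 1) / 2 - 1
      pr1 <- stats::pchisq(z, f_df, lower.tail = FALSE)
      pr2 <- stats::pchisq(z, f_df + 4, lower.tail = FALSE)
      mauchly_p <- pr1 + w2 * (pr2 - pr1)
    }
    gg_eps <- min(1, max(eps_lower, gg_eps))
  }
  correct <- switch(sphericity,
                    mauchly = is.finite(mauchly_p) && mauchly_p < alpha_sphericity,
                    always = TRUE, never = FALSE)

  effect_row <- function(effect, ss_eff, df1, ss_err, df2, within) {
    ms_eff <- ss_eff / df1; ms_err <- ss_err / df2
    degen <- FALSE
    if (ms_err <= 0) {
      degen <- TRUE
      if (ms_eff <= 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
      eps_used <- NA_real_; corr <- FALSE
      d1 <- df1; d2 <- df2
    } else {
      F <- ms_eff / ms_err
      corr <- within && correct
      eps_used <- if (within) gg_eps else NA_real_
      d1 <- if (corr) gg_eps * df1 else df1
      d2 <- if (corr) gg_eps * df2 else df2
      p <- stats::pf(F, d1, d2, lower.tail = FALSE)
    }
    data.table::data.table(effect = effect, F = F, df1 = d1, df2 = d2,
                           p_value = p, gg_epsilon = eps_used,
                           corrected = corr, mauchly_W = mauchly_w,
                           mauchly_p = mauchly_p, degenerate = degen)
  }
  res <- rbind(
    effect_row("group", ss_group, df_group, ss_subj_err, df_subj_err, FALSE),
    effect_row("time", ss_time, df_time, ss_within_err, df_win_err, TRUE),
    effect_row("group:time", ss_gt, df_gt, ss_within_err, df_win_err, TRUE))
  res[]
}

#' The cohort's headline test battery
#'
#' Reproduces the analysis battery applied to the pipeline's metric tables:
#' paired pre- vs post-transplant t-tests (both treatment groups pooled, per
#' phenotype) for the donor-reactive clonotype percentage and cumulative
#' frequency; mixed factorial ANOVAs (treatment x time) for clonality, R20,
#' clone-turnover JSD and virus-specific cumulative frequencies; and a
#' paired t-test comparing CMV-specific mass inside the donor-reactive set
#' against the bulk repertoire. Two-sided, alpha 0.05, no multiplicity
#' adjustment (the analysis is exploratory by design).
#'
#' Paired statistics are computed as pre minus post, so an increase after
#' transplantation yields a negative t.
#'
#' @param results output bundle of [run_pipeline()] (or a list with the same
#'   tables: `dr_tracking`, `metrics`, `specificity`, `dr_specificity`)
#' @param post_policy `"M1"` (headline contrast uses the first
#'   post-transplant timepoint) or `"mean_post"`
#' @param sphericity passed to [mixed_anova()]
#' @return `data.table` battery: `test`, `phenotype`, `measure`, `effect`,
#'   `statistic`, `df1`, `df2`, `p_value`, `gg_epsilon`, `corrected`,
#'   `formatted`
#' @export
headline_contrasts <- function(results, post_policy = c("M1", "mean_post"),
                               sphericity = "mauchly") {
  post_policy <- match.arg(post_policy)
  rows <- list()
  add_t <- function(test, ph, measure, tt) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      test = test, phenotype = ph, measure = measure, effect = "pre_vs_post",
      statistic = tt$statistic, df1 = tt$df, df2 = NA_real_,
      p_value = tt$p_value, gg_epsilon = NA_real_, corrected = FALSE,
      formatted = format_test(tt))
  }
  add_anova <- function(test, ph, measure, an) {
    for (i in seq_len(nrow(an))) {
      r <- an[i]
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        test = test, phenotype = ph, measure = measure, effect = r$effect,
        statistic = r$F, df1 = r$df1, df2 = r$df2, p_value = r$p_value,
        gg_epsilon = r$gg_epsilon, corrected = r$corrected,
        formatted = format_test(r))
    }
  }

  dr <- data.table::as.data.table(results$dr_tracking)
  dr[, timepoint := as.character(timepoint)]
  for (ph in sort(unique(dr$phenotype))) {
    sub <- dr[phenotype == ph]
    d <- delta_table(sub, metrics = c("pct_clonotypes", "cum_freq"),
                     post_policy = post_policy)$per_patient
    add_t("donor_reactive_pre_vs_post", ph, "pct_clonotypes",
          t_test(d$pct_clonotypes_pre, d$pct_clonotypes_post, paired = TRUE))
    add_t("donor_reactive_pre_vs_post", ph, "cum_freq",
          t_test(d$cum_freq_pre, d$cum_freq_post, paired = TRUE))
    add_anova("donor_reactive_group_time", ph, "pct_clonotypes",
              mixed_anova(sub, value = "pct_clonotypes", subject = "patient_id",
                          time = "timepoint", group = "group",
                          sphericity = sphericity))
  }

  metrics <- data.table::as.data.table(results$metrics)
  for (m in intersect(c("clonality", "r20", "jsd_top_clones"),
                      unique(metrics$metric))) {
    for (ph in sort(unique(metrics$phenotype))) {
      sub <- metrics[metric == m & phenotype == ph]
      if (data.table::uniqueN(sub$timepoint) < 2L) next
      add_anova("repertoire_metric_group_time", ph, m,
                mixed_anova(sub, value = "mean", subject = "patient_id",
                            time = "timepoint", group = "group",
                            sphericity = sphericity))
    }
  }

  if (!is.null(results$specificity) && nrow(results$specificity)) {
    spc <- data.table::as.data.table(results$specificity)
    for (sp in sort(unique(spc$antigen_species))) {
      for (ph in sort(unique(spc$phenotype))) {
        sub <- spc[antigen_species == sp & phenotype == ph]
        if (nrow(sub) == 0L || data.table::uniqueN(sub$timepoint) < 2L) next
        add_anova("virus_specific_group_time", ph, sp,
                  mixed_anova(sub, value = "cum_freq", subject = "patient_id",
                              time = "timepoint", group = "group",
                              sphericity = sphericity))
      }
    }
  }

  if (!is.null(results$dr_specificity) && nrow(results$dr_specificity)) {
    en <- data.table::as.data.table(results$dr_specificity)
    for (sp in sort(unique(en$antigen_species))) {
      for (ph in sort(unique(en$phenotype))) {
        sub <- en[antigen_species == sp & phenotype == ph]
        if (nrow(sub) < 2L) next
        add_t("donor_reactive_virus_enrichment", ph, sp,
              t_test(sub$bulk_cum_freq, sub$dr_cum_freq, paired = TRUE))
      }
    }
  }
  data.table::rbindlist(rows)
}
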