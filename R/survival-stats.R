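#' Negative-geotaxis performance index
#'
#' PI = 0.5 * (N_top + N_middle + N_bottom + N_top - N_bottom) / N_total,
#' equivalently 0.5 * (1 + (N_top - N_bottom) / N_total): 1 when every fly
#' reaches the top zone within the climb window, 0.5 when the top and bottom
#' zones balance, 0 when every fly stays at the bottom. Invariant to scaling
#' all three counts by the same positive factor.
#'
#' @param n_top,n_middle,n_bottom non-negative fly counts (vectorized).
#'   Alternatively pass a data frame with these columns as `n_top`.
#' @return Numeric PI in [0, 1], one value per trial.
#' @examples
#' performance_index(10, 0, 0)   # 1
#' performance_index(0, 10, 0)   # 0.5
#' performance_index(0, 0, 10)   # 0
#' @export
performance_index <- function(n_top, n_middle = NULL, n_bottom = NULL) {
  if (is.data.frame(n_top)) {
    d <- n_top
    n_top <- d$n_top
    n_middle <- d$n_middle
    n_bottom <- d$n_bottom
  }
  if (any(n_top < 0 | n_middle < 0 | n_bottom < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  total <- n_top + n_middle + n_bottom
  if (any(total < 1)) {
    stop("undefined index: at least one fly must be scored", call. = FALSE)
  }
  0.5 * (n_top + n_middle + n_bottom + n_top - n_bottom) / total
}

.check_survival_records <- function(records) {
  req <- c("day", "censored")
  if (!is.data.frame(records) || !all(req %in% names(records)) ||
      nrow(records) == 0L) {
    stop("survival records must be a non-empty data frame with columns ",
         "'day' and 'censored'", call. = FALSE)
  }
  if (any(records$day <= 0) || any(!is.finite(records$day))) {
    stop("invalid record: all days must be positive and finite",
         call. = FALSE)
  }
  invisible(records)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the cumulative probability of survival over
#' distinct event days; censored flies leave the risk set without
#' contributing an event step. Computed via [survival::survfit()].
#'
#' @param records data frame with columns `day` (> 0) and `censored`
#'   (logical or 0/1).
#' @return Object of class `km_curve`: a data frame (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`) with the step function starting at
#'   S(0) = 1.
#' @export
kaplan_meier <- function(records) {
  .check_survival_records(records)
  fit <- survival::survfit(
    survival::Surv(records$day, !as.logical(records$censored)) ~ 1,
    conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a `km_curve` from [kaplan_meier()].
#' @param t times (>= 0).
#' @return S(t), right-continuous, with S(t) = 1 before the first event.
#' @export
km_at <- function(km, t) {
  steps <- km$time[km$n_event > 0]
  surv <- km$surv[km$n_event > 0]
  vapply(t, function(ti) {
    i <- findInterval(ti, steps)
    if (i == 0L) 1 else surv[i]
  }, 1.0)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Day",
                          ylab = "Cumulative probability of survival") {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[seq_len(2 * nrow(x) - 1)])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Two-group log-rank tabulation over distinct event times, vectorized.
# time/event/in_a are parallel vectors; returns the chi-square pieces.
# Tied deaths are grouped at their distinct time with the hypergeometric
# variance.
.logrank_core <- function(time, event, in_a) {
  ut <- sort(unique(time))
  idx <- match(time, ut)
  m <- length(ut)
  n_at <- tabulate(idx, m)                       # leaving risk set at ut
  n_at_a <- tabulate(idx[in_a], m)
  d <- tabulate(idx[event], m)                   # deaths at ut
  d_a <- tabulate(idx[event & in_a], m)
  n_risk <- rev(cumsum(rev(n_at)))               # at risk just before ut
  n_risk_a <- rev(cumsum(rev(n_at_a)))
  has_d <- d > 0L
  nj <- n_risk[has_d]
  naj <- n_risk_a[has_d]
  dj <- d[has_d]
  daj <- d_a[has_d]
  e <- dj * naj / nj
  v <- ifelse(nj > 1L,
              dj * (naj / nj) * (1 - naj / nj) * (nj - dj) / (nj - 1L), 0)
  oe <- sum(daj - e)
  vv <- sum(v)
  list(oe = oe, var = vv,
       chisq = if (vv > 0) oe^2 / vv else 0)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each distinct
#' event time the observed number of deaths in group A is compared with its
#' hypergeometric expectation given the pooled deaths and risk sets, and
#' `chi_square = (sum(O - E))^2 / sum(V)` is referred to a 1-df chi-square
#' distribution. Ties are grouped at distinct event times with the
#' hypergeometric variance. Symmetric in group order.
#'
#' @param group_a,group_b data frames of survival records (`day`,
#'   `censored`); each group needs at least one uncensored event.
#' @return Object of class `logrank_result`: `chi_square`, `df` (1),
#'   `p_value`, and `obs_minus_exp` for group A (positive when group A dies
#'   earlier than expected under the null).
#' @export
logrank_test <- function(group_a, group_b) {
  .check_survival_records(group_a)
  .check_survival_records(group_b)
  ev_a <- !as.logical(group_a$censored)
  ev_b <- !as.logical(group_b$censored)
  if (!any(ev_a) || !any(ev_b)) {
    stop("degenerate test: each group needs >= 1 uncensored event",
         call. = FALSE)
  }
  time <- c(group_a$day, group_b$day)
  event <- c(ev_a, ev_b)
  in_a <- c(rep(TRUE, nrow(group_a)), rep(FALSE, nrow(group_b)))
  core <- .logrank_core(time, event, in_a)
  structure(
    list(chi_square = core$chisq, df = 1L,
         p_value = stats::pchisq(core$chisq, 1L, lower.tail = FALSE),
         obs_minus_exp = core$oe),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

# signed within-genotype induction effect: log-rank chi-square of induced vs
# uninduced, signed positive when induction increases mortality.
.signed_induction_chisq <- function(day, event, induced) {
  core <- .logrank_core(day, event, induced)
  sign_oe <- if (core$oe >= 0) 1 else -1
  sign_oe * core$chisq
}

#' Permutation test for genotype-by-induction interaction in survival
#'
#' Tests whether induction shortens lifespan differently in the two
#' genotypes of a 2x2 genotype-by-induction design. The observed statistic
#' is the difference between the two genotypes' induced-versus-uninduced
#' log-rank chi-squares, each signed by the direction of the induction
#' effect. The null distribution is built by permuting genotype labels
#' within induction strata (so each permutation preserves the marginal
#' induction effect); the two-sided p-value uses the add-one rule,
#' `p = (1 + #{|perm| >= |obs|}) / (1 + n_perm)`, and is therefore never
#' exactly zero.
#'
#' @param records data frame with columns `genotype` (2 levels),
#'   `induction` (2 levels), `day`, `censored`; all four cells non-empty.
#' @param n_perm number of permutations (default 10000; fewer than 100
#'   triggers a precision warning).
#' @param seed integer seed (required for reproducibility).
#' @return Object of class `perm_interaction`: `p_value`, `observed`,
#'   `n_perm`, `seed`, and `null_stats` (the permuted statistics).
#' @export
permutation_interaction_test <- function(records, n_perm = 10000L, seed) {
  .check_survival_records(records)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!all(c("genotype", "induction") %in% names(records))) {
    stop("records need 'genotype' and 'induction' columns", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (n_perm < 100L) {
    warning("n_perm < 100 gives a very coarse p-value", call. = FALSE)
  }
  g <- factor(records$genotype)
  ind <- factor(records$induction)
  if (nlevels(g) != 2L || nlevels(ind) != 2L) {
    stop("invalid design: need exactly two genotypes and two induction ",
         "levels", call. = FALSE)
  }
  if (any(table(g, ind) == 0L)) {
    stop("invalid design: every genotype x induction cell must be non-empty",
         call. = FALSE)
  }
  day <- records$day
  event <- !as.logical(records$censored)
  induced <- ind == levels(ind)[2L]
  is_g1 <- g == levels(g)[1L]

  stat_for <- function(g1_mask) {
    .signed_induction_chisq(day[g1_mask], event[g1_mask], induced[g1_mask]) -
      .signed_induction_chisq(day[!g1_mask], event[!g1_mask],
                              induced[!g1_mask])
  }
  observed <- stat_for(is_g1)

  set.seed(as.integer(seed))
  strata <- split(seq_along(day), induced)
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    mask <- logical(length(day))
    for (s in strata) {
      mask[sample(s)] <- is_g1[s]     # permute genotype within stratum
    }
    null_stats[b] <- stat_for(mask)
  }
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (1 + n_perm)
  structure(
    list(p_value = p, observed = observed, n_perm = n_perm,
         seed = as.integer(seed), null_stats = null_stats),
    class = "perm_interaction"
  )
}

#' @export
print.perm_interaction <- function(x, ...) {
  cat(sprintf(paste0("Permutation interaction test: observed = %.4g, ",
                     "p = %.4g (%d permutations)\n"),
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Permutation test for a genotype difference in climbing PI
#'
#' Compares the mean performance index between two genotypes at matched
#' timepoints by permuting genotype labels within timepoints. The statistic
#' is the mean over timepoints of the genotype difference in PI.
#'
#' @param pi_table data frame with columns `genotype` (2 levels),
#'   `timepoint`, `pi`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Object of class `perm_interaction` (two-sided add-one p-value).
#' @export
permutation_pi_test <- function(pi_table, n_perm = 10000L, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(all(c("genotype", "timepoint", "pi") %in% names(pi_table)))
  g <- factor(pi_table$genotype)
  if (nlevels(g) != 2L) stop("need exactly two genotypes", call. = FALSE)
  is_g1 <- g == levels(g)[1L]
  pi_v <- pi_table$pi
  stat_for <- function(mask) mean(pi_v[mask]) - mean(pi_v[!mask])
  observed <- stat_for(is_g1)
  set.seed(as.integer(seed))
  strata <- split(seq_along(pi_v), pi_table$timepoint)
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    mask <- logical(length(pi_v))
    for (s in strata) mask[sample(s)] <- is_g1[s]
    null_stats[b] <- stat_for(mask)
  }
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (1 + n_perm)
  structure(
    list(p_value = p, observed = observed, n_perm = n_perm,
         seed = as.integer(seed), null_stats = null_stats),
    class = "perm_interaction"
  )
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' F = MS_between / MS_within on (k - 1, N - k) degrees of freedom, with all
#' pairwise group comparisons adjusted by Tukey's honestly-significant-
#' difference procedure (studentized-range distribution). Fitted via
#' [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param groups a named list of numeric vectors (one per group, each with
#'   at least 2 observations), or a data frame with columns `value` and
#'   `group`.
#' @return Object of class `anova_tukey`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, and `tukey`, a data frame of pairwise mean
#'   differences with adjusted p-values.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    d <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      names(groups) <- paste0("g", seq_along(groups))
    }
    d <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)),
                     levels = names(groups)))
  }
  d <- d[is.finite(d$value), , drop = FALSE]
  sizes <- table(d$group)
  if (length(sizes) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("invalid group: every group needs n >= 2", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1L]]
  f_stat <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  # all observations numerically identical: no variance to partition
  tot_ss <- sum((d$value - mean(d$value))^2)
  if (!is.finite(f_stat) || tot_ss <= 1e-12 * max(1, mean(d$value)^2)) {
    f_stat <- 0
    p <- 1
  }
  if (is.na(p)) p <- 1
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(
    list(f_stat = f_stat, df_between = an[["Df"]][1L],
         df_within = an[["Df"]][2L], p_value = p, tukey = tukey),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  cat("Tukey HSD:\n")
  print.data.frame(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}
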