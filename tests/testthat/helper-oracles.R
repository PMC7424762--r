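# Independent oracles, coded separately from the package internals.

# --- brute-force transient detector -----------------------------------------
# Enumerates candidate peaks from an rle of the trace (plateaus collapse to
# their first frame; endpoints count one-sidedly), then walks transient by
# transient applying the onset / offset / burst rules literally: onset is
# the first frame of the non-decreasing run rising into the first peak, and
# the transient ends at the first post-peak frame back within the offset
# band of the onset value. Returns a flat integer encoding per transient:
# onset, offset, truncated, peak frames (all 1-based) so structural
# agreement can be checked with identical().
oracle_detect_flat <- function(x, thr = 0.1, band = 0.2) {
  n <- length(x)
  r <- rle(x)
  len <- r$lengths
  v <- r$values
  m <- length(v)
  starts <- cumsum(len) - len + 1L
  ismax <- logical(n)
  if (m > 1L) {
    for (q in 1:m) {
      hi_l <- q == 1L || v[q - 1L] < v[q]
      hi_r <- q == m || v[q + 1L] < v[q]
      if (hi_l && hi_r) ismax[starts[q]] <- TRUE
    }
  }
  peakf <- ismax & x > thr
  out <- integer()
  pos <- 1L
  repeat {
    p <- 0L
    for (q in pos:n) if (peakf[q]) { p <- q; break }
    if (!p) break
    on <- p
    while (on > 1L && x[on - 1L] <= x[on]) on <- on - 1L
    pk <- p
    off <- n
    closed <- FALSE
    j <- p + 1L
    while (j <= n) {
      if (x[j] - x[on] <= band) { off <- j; closed <- TRUE; break }
      if (peakf[j]) pk <- c(pk, j)
      j <- j + 1L
    }
    out <- c(out, on, off, as.integer(pk[length(pk)] == n), pk)
    if (!closed) break
    pos <- off
  }
  out
}

# flatten the internal detector core's transient list (1-based already)
flat_core <- function(tr) {
  if (!length(tr)) return(integer())
  unlist(lapply(tr, function(t) {
    c(t$onset, t$offset, as.integer(t$truncated), t$peaks)
  }), use.names = FALSE)
}

# flatten a glut_transients result (0-based) into the oracle's 1-based coding
flat_transients <- function(tr) {
  if (nrow(tr) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(tr)), function(i) {
    c(tr$onset_frame[i] + 1L, tr$offset_frame[i] + 1L,
      as.integer(tr$truncated[i]), tr$peak_frames[[i]] + 1L)
  }), use.names = FALSE)
}

# --- hand log-rank tabulation -----------------------------------------------
# Literal O/E/V loop over distinct event times of the pooled sample.
oracle_logrank_chisq <- function(group_a, group_b) {
  day <- c(group_a$day, group_b$day)
  event <- c(!as.logical(group_a$censored), !as.logical(group_b$censored))
  in_a <- rep(c(TRUE, FALSE), c(nrow(group_a), nrow(group_b)))
  times <- sort(unique(day[event]))
  oe <- 0
  vv <- 0
  for (t in times) {
    at_risk <- day >= t
    nj <- sum(at_risk)
    naj <- sum(at_risk & in_a)
    dj <- sum(event & day == t)
    daj <- sum(event & day == t & in_a)
    oe <- oe + daj - dj * naj / nj
    if (nj > 1) {
      vv <- vv + dj * (naj / nj) * (1 - naj / nj) * (nj - dj) / (nj - 1)
    }
  }
  oe^2 / vv
}

# --- hand one-way ANOVA sums of squares -------------------------------------
oracle_anova_f <- function(groups) {
  allv <- unlist(groups)
  grand <- mean(allv)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, 1.0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  k <- length(groups)
  n <- length(allv)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, df_between = k - 1, df_within = n - k)
}

# --- misc test fixtures -----------------------------------------------------
toy_survival <- function(genotype, induction, day,
                         censored = rep(FALSE, length(day))) {
  data.frame(fly_id = paste0("f", seq_along(day)), genotype = genotype,
             induction = induction, day = day, censored = censored,
             stringsAsFactors = FALSE)
}
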