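# Independent brute-force oracles used to check the vectorized/interval-tree
# implementations. These deliberately work from plain lists and loops.

# Per-base feature labeler with priority promoter > exon > intron >
# intergenic, promoter oriented by strand.
oracle_feature_label <- function(desc, pos, window = c(2000, 500)) {
  vapply(pos, function(p) {
    in_prom <- FALSE; in_exon <- FALSE; in_span <- FALSE
    for (g in desc) {
      tss <- if (g$strand == "+") g$start else g$end
      pr <- if (g$strand == "+") {
        c(tss - window[1], tss + window[2] - 1)
      } else {
        c(tss - window[2] + 1, tss + window[1])
      }
      if (p >= max(1, pr[1]) && p <= pr[2]) in_prom <- TRUE
      for (e in g$exons) if (p >= e[1] && p <= e[2]) in_exon <- TRUE
      if (p >= g$start && p <= g$end) in_span <- TRUE
    }
    if (in_prom) "promoter"
    else if (in_exon) "exon"
    else if (in_span) "intron"
    else "intergenic"
  }, character(1))
}

# Gap in bases strictly between two closed intervals (0 when touching or
# overlapping).
oracle_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) max(0L, s2 - e1 - 1L)
  else if (e2 < s1) max(0L, s1 - e2 - 1L)
  else 0L
}

# Exhaustive nearest-gene scan with the documented tie-break.
oracle_nearest_gene <- function(peak_start, peak_end, desc, max_dist = 10000) {
  best <- NULL
  for (g in desc) {
    d <- oracle_gap(peak_start, peak_end, g$start, g$end)
    if (d > max_dist) next
    if (is.null(best) || d < best$d ||
        (d == best$d && (g$start < best$start ||
                         (g$start == best$start && g$gene_id < best$id)))) {
      best <- list(d = d, start = g$start, id = g$gene_id)
    }
  }
  if (is.null(best)) list(gene_id = NA_character_, distance = NA_integer_)
  else list(gene_id = best$id, distance = as.integer(best$d))
}

# Direct local-regression lowess: tricube weights over the ceiling(f*n)
# nearest points, fitted with lm() at each position.
oracle_lowess <- function(y, f) {
  n <- length(y)
  x <- seq_len(n)
  r <- min(n, max(2L, as.integer(ceiling(f * n))))
  vapply(x, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[r]
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    fit <- stats::lm(y ~ x, weights = w)
    unname(stats::predict(fit, newdata = data.frame(x = x0)))
  }, numeric(1))
}

# All-pairs interval overlap count (>= min_overlap shared bases).
oracle_overlap_fraction <- function(q_start, q_end, s_start, s_end,
                                    min_overlap = 1L) {
  hit <- vapply(seq_along(q_start), function(i) {
    any(pmin(q_end[i], s_end) - pmax(q_start[i], s_start) + 1L >= min_overlap)
  }, logical(1))
  mean(hit)
}

# Textbook two-group log-rank chi-square over shared event times.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  stopifnot(max(g) == 2L)
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t0 in ts) {
    n1 <- sum(time >= t0 & g == 1L)
    n2 <- sum(time >= t0 & g == 2L)
    d1 <- sum(time == t0 & event == 1 & g == 1L)
    d2 <- sum(time == t0 & event == 1 & g == 2L)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2L) next
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Product-limit estimator by explicit loop (events before censorings at
# tied times).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}
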