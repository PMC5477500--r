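#' Median split of a cohort by gene expression
#'
#' Patients strictly above the cohort median are labeled \code{high};
#' patients at or below it (including the median itself) are \code{low}.
#'
#' @param cohort Data frame with one row per patient and a numeric
#'   expression column named after \code{gene}.
#' @param gene Column name of the gene's expression.
#' @return Factor with levels \code{c("low", "high")}, parallel to the
#'   cohort rows.
#' @export
split_by_expression <- function(cohort, gene) {
  x <- cohort_expression(cohort, gene)
  med <- stats::median(x)
  if (all(x == x[1L])) {
    stop("all expression values identical; no median split possible for ",
         gene, call. = FALSE)
  }
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

cohort_expression <- function(cohort, gene) {
  if (!gene %in% names(cohort)) {
    stop("cohort table has no expression column '", gene, "'", call. = FALSE)
  }
  x <- cohort[[gene]]
  if (!is.numeric(x) || anyNA(x)) {
    stop("expression for ", gene, " must be numeric and complete",
         call. = FALSE)
  }
  x
}

#' Four-group stratification by two genes' expression
#'
#' Crosses the median splits of two genes into the four groups
#' low/low, low/high, high/low and high/high (first gene first), the
#' dual-marker stratification of the screen.
#'
#' @param cohort Patient data frame.
#' @param geneA,geneB Expression column names.
#' @return Factor with levels \code{c("low_low", "low_high", "high_low",
#'   "high_high")} (\code{geneA} level first).
#' @export
four_group_stratify <- function(cohort, geneA, geneB) {
  a <- split_by_expression(cohort, geneA)
  b <- split_by_expression(cohort, geneB)
  factor(paste(as.character(a), as.character(b), sep = "_"),
         levels = c("low_low", "low_high", "high_low", "high_high"))
}

#' Compare expression between relapsed and non-relapsed patients
#'
#' Welch's unequal-variance two-sample t-test of the gene's expression in
#' relapse = \code{"yes"} versus relapse = \code{"no"} patients (patients
#' with unknown relapse status are ignored). The statistic's sign follows
#' (relapsed minus non-relapsed).
#'
#' @param cohort Patient data frame with a \code{relapse} column coded
#'   \code{"yes"}/\code{"no"} (other values ignored).
#' @param gene Expression column name.
#' @return List with \code{statistic}, \code{p_value}, \code{df},
#'   \code{mean_relapsed}, \code{mean_nonrelapsed}, \code{n_relapsed},
#'   \code{n_nonrelapsed}.
#' @export
compare_relapse_groups <- function(cohort, gene) {
  x <- cohort_expression(cohort, gene)
  if (is.null(cohort$relapse)) {
    stop("cohort table has no 'relapse' column", call. = FALSE)
  }
  yes <- x[cohort$relapse == "yes"]
  no <- x[cohort$relapse == "no"]
  if (length(yes) < 2L || length(no) < 2L) {
    stop("need at least 2 patients per relapse group", call. = FALSE)
  }
  tt <- stats::t.test(yes, no, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_relapsed = mean(yes), mean_nonrelapsed = mean(no),
       n_relapsed = length(yes), n_nonrelapsed = length(no))
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve via [survival::survfit()]. The returned
#' step function has S(0) = 1 and is nonincreasing.
#'
#' @param times Positive survival/follow-up times.
#' @param events Event indicators (1 = death/relapse, 0 = censored).
#' @return Data frame with columns \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}.
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

check_surv <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (any(times <= 0)) stop("survival times must be > 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) {
    stop("event indicators must be 0 or 1", call. = FALSE)
  }
  if (length(times) != length(events)) {
    stop("times and events differ in length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Survival probability at given times from a KM curve
#'
#' Step-function evaluation of a [km_estimate()] result.
#'
#' @param km A [km_estimate()] data frame.
#' @param at Numeric times.
#' @return Survival probabilities at \code{at}.
#' @export
km_survival_at <- function(km, at) {
  vapply(at, function(t0) {
    i <- which(km$time <= t0)
    if (length(i) == 0L) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected log-rank chi-square over the shared
#' risk sets (via [survival::survdiff()]), with df = number of groups - 1.
#'
#' @param times Positive survival/follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param labels Group labels (at least 2 nonempty groups).
#' @return List with \code{chisq}, \code{df}, \code{p_value},
#'   \code{observed} and \code{expected} per group.
#' @export
logrank <- function(times, events, labels) {
  check_surv(times, events)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) {
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ labels)
  df <- nlevels(labels) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}
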