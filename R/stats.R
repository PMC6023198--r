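#' @include AllClasses.R
NULL

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic is computed by the rank-sum formula with midranks for
#' ties; the two-sided p-value uses the exact distribution for small
#' tie-free samples (both groups <= 8) and the normal approximation with
#' tie correction otherwise (the convention of mainstream statistical
#' packages).
#'
#' @param a,b numeric samples.
#' @return list with \code{U} (for sample \code{a}) and \code{p}
#' @export
mannWhitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 8L && length(b) <= 8L
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE))
  list(U = unname(U), p = unname(wt$p.value))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return list with \code{chi2} and \code{p}
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time.
#'
#' @param times follow-up times (months, > 0).
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return data.frame with \code{time}, \code{nRisk}, \code{nEvent} and
#'   \code{surv} (the step-function value at each observed time)
#' @export
kaplanMeier <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times <= 0)) stop("times must be positive")
  fit <- survfit(Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param timesA,eventsA group A follow-up and event indicators.
#' @param timesB,eventsB group B likewise.
#' @return list with \code{chi2} and \code{p} (df = 1)
#' @export
logrank <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0L || length(timesB) == 0L) stop("empty group")
  ev <- c(as.integer(eventsA), as.integer(eventsB))
  if (sum(ev) == 0L) stop("no events in either group")
  tm <- c(timesA, timesB)
  gr <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survdiff(Surv(tm, ev) ~ gr)
  list(chi2 = unname(sd$chisq),
       p = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)))
}

#' Optimal survival cutpoint scan
#'
#' Exhaustively scans the midpoints between consecutive sorted unique
#' values of a marker, keeps thresholds leaving at least
#' \code{minGroupFrac} of subjects on each side, and returns the
#' threshold maximizing the log-rank chi-square. The reported p-value is
#' unadjusted for the multiplicity of the scan and is flagged as such
#' (the behaviour of cutpoint-optimizing tools such as X-tile).
#'
#' @param values marker values (>= 2 distinct).
#' @param times,events survival data aligned with \code{values}.
#' @param minGroupFrac minimum fraction of the cohort per side
#'   (default 0.1).
#' @return list: \code{threshold}, \code{chi2}, \code{p},
#'   \code{groupSizes} (low/high), \code{pUncorrected} = TRUE, and the
#'   full \code{scan} data.frame
#' @export
optimalCutpoint <- function(values, times, events, minGroupFrac = 0.1) {
  stopifnot(length(values) == length(times),
            length(values) == length(events))
  u <- sort(unique(values))
  if (length(u) < 2L) stop("need at least 2 distinct marker values")
  thr <- (u[-length(u)] + u[-1L]) / 2
  n <- length(values)
  rows <- lapply(thr, function(th) {
    lo <- values <= th
    if (sum(lo) < minGroupFrac * n || sum(!lo) < minGroupFrac * n)
      return(NULL)
    lr <- tryCatch(logrank(times[lo], events[lo], times[!lo], events[!lo]),
                   error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    data.frame(threshold = th, chi2 = lr$chi2, p = lr$p,
               nLow = sum(lo), nHigh = sum(!lo))
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0L)
    stop("no admissible threshold under the group-size constraint")
  best <- scan[which.max(scan$chi2), ]
  list(threshold = best$threshold, chi2 = best$chi2, p = best$p,
       groupSizes = c(low = best$nLow, high = best$nHigh),
       pUncorrected = TRUE, scan = scan)
}

#' Median and Tukey-hinge interquartile summary by IDH1 status
#'
#' For each conventional PET parameter: median (25th; 75th percentile,
#' Tukey hinges) in the whole cohort and within the IDH1 wild-type and
#' mutant groups, with the two-sided Mann-Whitney p-value for the group
#' contrast.
#'
#' @param cohort a cohort data.frame with an \code{idh1_mutant} column
#'   (see \code{\link{readCohort}}).
#' @param vars columns to summarise.
#' @return data.frame, one row per variable
#' @export
idh1Summary <- function(cohort,
                        vars = c("tbr_max", "tbr_mean", "ttp_min",
                                 "slope_suv_h")) {
  if (!all(vars %in% names(cohort)))
    stop("missing columns: ",
         paste(setdiff(vars, names(cohort)), collapse = ", "))
  if (!"idh1_mutant" %in% names(cohort)) stop("idh1_mutant column required")
  fmt <- function(x) {
    f <- fivenum(x)
    c(median = f[3L], q25 = f[2L], q75 = f[4L])
  }
  out <- lapply(vars, function(v) {
    x <- cohort[[v]]
    wt <- x[!cohort$idh1_mutant]
    mu <- x[cohort$idh1_mutant]
    a <- fmt(x); w <- fmt(wt); m <- fmt(mu)
    p <- if (length(wt) && length(mu)) mannWhitney(wt, mu)$p else NA_real_
    data.frame(variable = v,
               median_all = a["median"], q25_all = a["q25"],
               q75_all = a["q75"],
               median_wt = w["median"], q25_wt = w["q25"],
               q75_wt = w["q75"],
               median_mut = m["median"], q25_mut = m["q25"],
               q75_mut = m["q75"],
               p = p,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' IDH1 enrichment above a centroid-#1 threshold
#'
#' Splits the cohort at \code{pct_c1 > threshold} and tabulates IDH1
#' status in the high and low groups, with the Pearson chi-square test
#' on the resulting 2x2 table.
#'
#' @param cohort cohort data.frame.
#' @param threshold centroid-#1 percentage cutoff (default 90).
#' @return list: \code{table} (2x2, rows high/low, cols mutant/wild),
#'   fractions \code{pctMutantHigh}/\code{pctMutantLow}, \code{chi2},
#'   \code{p}
#' @export
centroid1Stratification <- function(cohort, threshold = 90) {
  hi <- cohort$pct_c1 > threshold
  mut <- cohort$idh1_mutant
  tab <- matrix(c(sum(hi & mut), sum(hi & !mut),
                  sum(!hi & mut), sum(!hi & !mut)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("high", "low"), c("mutant", "wild")))
  ct <- chiSquare2x2(tab)
  list(table = tab,
       pctMutantHigh = 100 * tab["high", "mutant"] / sum(tab["high", ]),
       pctMutantLow = 100 * tab["low", "mutant"] / sum(tab["low", ]),
       chi2 = ct$chi2, p = ct$p)
}
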