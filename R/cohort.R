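## Sample stratification by ECv pattern and survival comparison.

#' Ward hierarchical clustering of samples or features
#'
#' Agglomerative clustering with Euclidean distances under the
#' squared-distance Ward update (R's \code{"ward.D2"} convention: distances
#' are squared inside the Lance-Williams recurrence, merge heights stay on
#' the original distance scale). Duplicated items merge at height zero and
#' the procedure is deterministic for a fixed input order.
#'
#' @param m an [EcvMatrix-class] or numeric samples-by-features matrix.
#' @param k number of clusters to cut the tree into (default 2).
#' @param axis \code{"samples"} (cluster rows) or \code{"features"}
#'   (cluster columns).
#' @return list with components \code{labels} (named integer cluster
#'   assignment), \code{tree} (the \code{hclust} object) and \code{heights}
#'   (merge heights).
#' @export
wardCluster <- function(m, k = 2L, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  v <- if (is(m, "EcvMatrix")) m@values else as.matrix(m)
  if (axis == "features") v <- t(v)
  if (k < 1L || k > nrow(v))
    stop("parameter error: k must lie between 1 and the number of items")
  tree <- stats::hclust(stats::dist(v, method = "euclidean"),
                        method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree, heights = tree$height)
}

.checkSurvival <- function(records) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(records)))
    stop("survival records need columns sample, time, event")
  if (any(records$time < 0)) stop("survival times must be >= 0")
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (deceased)")
  records
}

.alignLabels <- function(records, labels) {
  if (!is.null(names(labels))) {
    idx <- match(records$sample, names(labels))
    if (anyNA(idx))
      stop("grouping error: no label for sample(s) ",
           paste(records$sample[is.na(idx)], collapse = ", "))
    labels <- labels[idx]
  } else if (length(labels) != nrow(records)) {
    stop("labels must be named by sample or match the record order")
  }
  g <- factor(labels)
  if (nlevels(g) != 2L)
    stop("grouping error: exactly two non-empty groups required")
  g
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison: at each distinct event time the observed
#' minus hypergeometric-expected events in group one are accumulated and
#' normalized by the summed hypergeometric variance; the statistic is
#' compared to a chi-square with one degree of freedom. Censoring ties at an
#' event time are handled with the censored-after-events convention.
#'
#' @param records data.frame with columns \code{sample}, \code{time},
#'   \code{event} (1 = deceased, 0 = censored).
#' @param labels two-group assignment, named by sample or in record order.
#' @return list with components \code{statistic} (chi-square), \code{p} and
#'   \code{df} (always 1).
#' @export
logrankTest <- function(records, labels) {
  records <- .checkSurvival(records)
  g <- .alignLabels(records, labels)
  if (sum(records$event) < 1L)
    stop("undefined test: no events in the data")
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ g,
                           rho = 0)
  stat <- unname(sd$chisq)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator per group: a right-continuous step function
#' starting at 1, non-increasing, dropping at event times.
#'
#' @inheritParams logrankTest
#' @return named list (one per group) of data.frames with columns
#'   \code{time}, \code{surv}, \code{nRisk}, \code{nEvent}; each includes
#'   the origin point (time 0, survival 1).
#' @export
kmCurve <- function(records, labels) {
  records <- .checkSurvival(records)
  g <- .alignLabels(records, labels)
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ g)
  strata <- rep(names(fit$strata), fit$strata)
  out <- list()
  for (lev in levels(g)) {
    sel <- strata == paste0("g=", lev)
    out[[lev]] <- rbind(
      data.frame(time = 0, surv = 1, nRisk = sum(g == lev), nEvent = 0),
      data.frame(time = fit$time[sel], surv = fit$surv[sel],
                 nRisk = fit$n.risk[sel], nEvent = fit$n.event[sel]))
    rownames(out[[lev]]) <- NULL
  }
  out
}

#' Drop survival records with over-long follow-up
#'
#' Removes patients whose follow-up or decease time exceeds
#' \code{maxDays}, a cohort-preprocessing filter applied before
#' stratification when clinical data are supplied.
#'
#' @param records survival data.frame (\code{sample}, \code{time},
#'   \code{event}).
#' @param maxDays maximum follow-up in days (default 2000).
#' @return filtered data.frame.
#' @export
filterFollowUp <- function(records, maxDays = 2000) {
  records <- .checkSurvival(records)
  out <- records[records$time <= maxDays, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read survival records from TSV
#'
#' Expects columns \code{sample}, \code{time_days}, \code{event}.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{sample}, \code{time}, \code{event}.
#' @export
readSurvival <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time_days", "event") %in% names(d)))
    stop("survival TSV needs columns sample, time_days, event")
  .checkSurvival(data.frame(sample = as.character(d$sample),
                            time = as.numeric(d$time_days),
                            event = as.integer(d$event),
                            stringsAsFactors = FALSE))
}

#' Write survival records as TSV
#'
#' @param records data.frame with columns \code{sample}, \code{time},
#'   \code{event}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSurvival <- function(records, path) {
  records <- .checkSurvival(records)
  out <- data.frame(sample = records$sample,
                    time_days = sprintf("%.10g", records$time),
                    event = records$event, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
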