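# Per-trial phenotype statistics and the cross-trial confidence classifier.
#
# Direction convention, used everywhere: for survival-type assays (lifespan,
# dauer exit, thermotolerance, pathogen resistance, reproductive span)
# direction +1 means the mutant survives/stays longer; for dauer-entry
# counts +1 means more dauers in the mutant.

trialTestResult <- function(statistic, df, p, direction, assay = NA) {
  structure(list(statistic = statistic, df = df, p = p,
                 direction = direction, assay = assay),
            class = "TrialTestResult")
}

#' @export
print.TrialTestResult <- function(x, ...) {
  cat(sprintf("chisq = %.4g (df %d), p = %.4g, direction %+d\n",
              x$statistic, x$df, x$p, x$direction))
  invisible(x)
}

#' Two-group log-rank test with right censoring
#'
#' Standard two-group log-rank chi-square (df = 1) comparing mutant against
#' control survival within one trial, computed with
#' \code{\link[survival]{survdiff}}.
#'
#' @param trial data.frame with columns \code{duration}, \code{event}
#'   (1 = death observed, 0 = right-censored) and \code{group}
#'   (\code{"control"}/\code{"mutant"}), as produced by
#'   \code{\link{simulateSurvivalTrials}}.
#' @return A \code{TrialTestResult}: chi-square statistic, df, two-sided p,
#'   and direction (+1 if the mutant survives longer, i.e. fewer observed
#'   than expected deaths).
#' @examples
#' tr <- simulateSurvivalTrials(0.4, n_per_group = 30, n_trials = 1, seed = 2)
#' logrankRightCensored(tr)
#' @export
logrankRightCensored <- function(trial) {
  stopifnot(all(c("duration", "event", "group") %in% names(trial)))
  trial$group <- factor(trial$group, levels = c("control", "mutant"))
  if (any(is.na(trial$group)) || any(table(trial$group) == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  if (any(trial$duration <= 0))
    stop("durations must be positive", call. = FALSE)
  if (sum(trial$event) == 0L)
    stop("log-rank statistic undefined: no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(duration, event) ~ group,
                           data = trial)
  stat <- as.numeric(sd$chisq)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  # fewer deaths than expected in the mutant => longer survival => +1
  dmut <- sd$exp[2] - sd$obs[2]
  direction <- if (abs(dmut) < sqrt(.Machine$double.eps)) 0L
               else as.integer(sign(dmut))
  trialTestResult(stat, 1L, p, direction, assay = "survival")
}

# Validate the shared inspection grid: every finite bound must be an
# inspection time of the pooled grid and no event interval may span more
# than one inspection interval.
checkInspectionGrid <- function(L, R) {
  fin <- is.finite(R)
  grid <- sort(unique(c(L, R[fin])))
  for (i in which(fin)) {
    inside <- grid[grid > L[i] + 1e-9 & grid < R[i] - 1e-9]
    if (length(inside))
      stop("inconsistent inspection grids within the trial", call. = FALSE)
  }
  invisible(grid)
}

#' Grouped-time log-rank test for interval-censored survival
#'
#' For assays scored on a shared inspection grid, each death is known only
#' up to an interval \code{(L, R]}.  The test is the grouped-time (discrete)
#' log-rank: deaths are assigned to the interval's right endpoint, animals
#' alive at the last inspection are right-censored there, and the standard
#' log-rank statistic is computed on the resulting discrete times.
#'
#' @param trial data.frame with columns \code{L}, \code{R} (\code{Inf} =
#'   right-open) and \code{group}, as from
#'   \code{\link{simulateIntervalTrials}}.
#' @return A \code{TrialTestResult} (df = 1).
#' @examples
#' tr <- simulateIntervalTrials(0.5, n_per_group = 30, n_trials = 1, seed = 3)
#' logrankIntervalCensored(tr)
#' @export
logrankIntervalCensored <- function(trial) {
  stopifnot(all(c("L", "R", "group") %in% names(trial)))
  if (any(trial$L >= trial$R))
    stop("interval bounds must satisfy L < R", call. = FALSE)
  checkInspectionGrid(trial$L, trial$R)
  ev <- is.finite(trial$R)
  if (!any(ev))
    stop("log-rank statistic undefined: no events observed", call. = FALSE)
  tt <- ifelse(ev, trial$R, trial$L)
  grouped <- data.frame(duration = tt, event = as.integer(ev),
                        group = trial$group)
  res <- logrankRightCensored(grouped)
  res$assay <- "interval_survival"
  res
}

#' Exact hypergeometric test for a 2x2 dauer count table
#'
#' Exact two-sided test conditioning on both margins of the table
#' (mutant/control x dauer/non-dauer).  The default two-sided p sums the
#' probabilities of all tables no more likely than the observed one (the
#' method of small p-values, as in Fisher's exact test); a doubling rule is
#' available.
#'
#' @param mutant_dauers,mutant_total counts in the mutant group.
#' @param control_dauers,control_total counts in the control group.
#' @param two_sided_rule \code{"minlike"} (default) or \code{"doubling"}.
#' @return A \code{TrialTestResult}; \code{direction} is the sign of the
#'   dauer-proportion difference (mutant minus control) and
#'   \code{statistic} is the equivalent chi-square quantile
#'   \code{qchisq(1 - p, 1)} for cross-trial combination.
#' @examples
#' hypergeomCountTest(3, 3, 0, 3)  # p = 0.10
#' @export
hypergeomCountTest <- function(mutant_dauers, mutant_total,
                               control_dauers, control_total,
                               two_sided_rule = c("minlike", "doubling")) {
  two_sided_rule <- match.arg(two_sided_rule)
  if (mutant_total < 1 || control_total < 1)
    stop("group totals must be >= 1", call. = FALSE)
  stopifnot(mutant_dauers >= 0, mutant_dauers <= mutant_total,
            control_dauers >= 0, control_dauers <= control_total)
  K <- mutant_dauers + control_dauers        # dauers overall
  N <- mutant_total + control_total
  lo <- max(0L, K - control_total)
  hi <- min(K, mutant_total)
  support <- lo:hi
  dens <- dhyper(support, K, N - K, mutant_total)
  pobs <- dhyper(mutant_dauers, K, N - K, mutant_total)
  if (two_sided_rule == "minlike") {
    p <- sum(dens[dens <= pobs * (1 + 1e-7)])
  } else {
    lower <- sum(dens[support <= mutant_dauers])
    upper <- sum(dens[support >= mutant_dauers])
    p <- min(1, 2 * min(lower, upper))
  }
  p <- min(1, p)
  dprop <- mutant_dauers / mutant_total - control_dauers / control_total
  direction <- if (abs(dprop) < sqrt(.Machine$double.eps)) 0L
               else as.integer(sign(dprop))
  stat <- qchisq(p, df = 1, lower.tail = FALSE)
  trialTestResult(stat, 1L, p, direction, assay = "dauer_entry")
}

# Convenience: run the count test on one trial of a long-format count table.
countTestForTrial <- function(counts, trial_id,
                              mutant = "mutant", control = "control",
                              group_col = "group") {
  tr <- counts[counts$trial == trial_id, ]
  m <- tr[tr[[group_col]] == mutant, ]
  c_ <- tr[tr[[group_col]] == control, ]
  stopifnot(nrow(m) == 1L, nrow(c_) == 1L)
  hypergeomCountTest(m$dauers, m$total, c_$dauers, c_$total)
}

#' Combine per-trial test results into one p-value
#'
#' Two combination rules: \code{"chisq_sum"} sums the per-trial chi-square
#' statistics and refers the sum to a chi-square distribution with df =
#' number of trials; \code{"count_glm"} fits a binomial regression of dauer
#' proportion on genotype with trial as a blocking factor and reports the
#' likelihood-ratio p for the genotype term.
#'
#' @param results list of \code{TrialTestResult}s (needed for
#'   \code{"chisq_sum"}; all must come from the same assay family).
#' @param method \code{"chisq_sum"} or \code{"count_glm"}.
#' @param counts for \code{"count_glm"}: long-format count table with
#'   columns \code{trial}, \code{group}, \code{dauers}, \code{total}.
#' @return combined p-value (numeric scalar).
#' @examples
#' r <- list(trialTestResult(1, 1L, pchisq(1, 1, lower.tail = FALSE), 1L),
#'           trialTestResult(1, 1L, pchisq(1, 1, lower.tail = FALSE), 1L))
#' combineTrials(r)  # exp(-1)
#' @export
combineTrials <- function(results, method = c("chisq_sum", "count_glm"),
                          counts = NULL) {
  method <- match.arg(method)
  if (method == "chisq_sum") {
    if (length(results) < 1L) stop("need >= 1 trial", call. = FALSE)
    assays <- vapply(results, function(r) as.character(r$assay), "")
    if (length(unique(assays)) > 1L)
      stop("cannot combine results from mixed assay types", call. = FALSE)
    x <- sum(vapply(results, function(r) r$statistic, 0))
    pchisq(x, df = length(results), lower.tail = FALSE)
  } else {
    stopifnot(!is.null(counts),
              all(c("trial", "group", "dauers", "total") %in% names(counts)))
    counts$group <- factor(counts$group, levels = c("control", "mutant"))
    counts$trial <- factor(counts$trial)
    form <- if (nlevels(counts$trial) > 1L)
      cbind(dauers, total - dauers) ~ group + trial
    else cbind(dauers, total - dauers) ~ group
    fit <- glm(form, family = binomial(), data = counts)
    fit0 <- glm(update(form, . ~ . - group), family = binomial(),
                data = counts)
    lr <- max(0, fit0$deviance - fit$deviance)
    pchisq(lr, df = fit0$df.residual - fit$df.residual, lower.tail = FALSE)
  }
}

#' Classify a cross-trial phenotype call as high/low/variable confidence
#'
#' Three criteria: (1) the combined p across all trials is below 0.01 at
#' the corresponding degrees of freedom; (2) when tested in two labs, the
#' per-trial p is below 0.05 in the majority of trials in both labs;
#' (3) when tested in one lab, the per-trial p is below 0.05 in the
#' majority of trials and in at least 2 trials.  A high-confidence call
#' requires criterion 1 plus the applicable lab criterion; criterion 1
#' alone gives a low-confidence call.  If significant trials occur in both
#' directions the call is "variable" regardless.
#'
#' @param per_trial list of \code{TrialTestResult}s, one per trial.
#' @param combined_p combined p from \code{\link{combineTrials}}.
#' @param lab_ids character vector of lab identifiers, one per trial (1 or
#'   2 distinct labs).
#' @param alpha_trial per-trial significance level (0.05).
#' @param alpha_combined combined-level threshold (0.01).
#' @return A \code{ConfidenceCall} list: \code{level} (high/low/variable/
#'   none), \code{direction}, \code{combined_p}, \code{n_trials},
#'   \code{n_labs}, and the per-trial record.
#' @export
classifyConfidence <- function(per_trial, combined_p, lab_ids,
                               alpha_trial = 0.05, alpha_combined = 0.01) {
  if (length(per_trial) == 0L) stop("empty trial list", call. = FALSE)
  stopifnot(length(lab_ids) == length(per_trial))
  n_labs <- length(unique(lab_ids))
  if (!n_labs %in% c(1L, 2L))
    stop("lab count must be 1 or 2", call. = FALSE)
  p <- vapply(per_trial, function(r) r$p, 0)
  dir <- vapply(per_trial, function(r) as.integer(r$direction), 0L)
  sig <- p < alpha_trial
  crit1 <- combined_p < alpha_combined
  majority <- function(flags) mean(flags) > 0.5
  labcrit <- if (n_labs == 2L) {
    all(vapply(split(sig, lab_ids), majority, TRUE))
  } else {
    majority(sig) && sum(sig) >= 2L
  }
  both_dirs <- any(sig & dir > 0) && any(sig & dir < 0)
  level <- if (both_dirs) "variable"
           else if (crit1 && labcrit) "high"
           else if (crit1) "low"
           else "none"
  sdir <- dir[sig]
  direction <- if (!length(sdir) || sum(sign(sdir)) == 0) 0L
               else as.integer(sign(sum(sign(sdir))))
  structure(list(level = level, direction = direction,
                 combined_p = combined_p, n_trials = length(per_trial),
                 n_labs = n_labs,
                 trials = data.frame(p = p, direction = dir,
                                     lab = lab_ids, significant = sig)),
            class = "ConfidenceCall")
}

#' @export
print.ConfidenceCall <- function(x, ...) {
  cat(sprintf("%s-confidence call (direction %+d), combined p = %.3g, %d trial(s) in %d lab(s)\n",
              x$level, x$direction, x$combined_p, x$n_trials, x$n_labs))
  invisible(x)
}

# Assay vocabulary; the three dauer-entry screens can be aggregated into one
# biological process.
dauerEntryAssays <- c("dauer_entry", "dauer_entry_daf2", "dauer_entry_daf28")

screenAssays <- function() {
  c(dauerEntryAssays, "dauer_exit", "lifespan", "thermotolerance",
    "pathogen_resistance", "reproductive_span")
}

#' Build the binary ILP-by-process phenotype incidence matrix
#'
#' @param calls data.frame with columns \code{ilp}, \code{assay},
#'   \code{level} (high/low/variable/none) and optionally
#'   \code{direction}.
#' @param aggregate_dauer_entry collapse the three dauer-entry screens
#'   (plain, daf-2- and daf-28-sensitized) into one process column by OR.
#' @param include_low count low-confidence calls as hits too.
#' @param ilps row universe (default: all mutants in \code{calls}).
#' @param assays column universe before aggregation (default: the full
#'   8-assay screen vocabulary).
#' @return binary incidence matrix, ILPs in rows, processes in columns.
#' @export
buildPhenotypeMatrix <- function(calls, aggregate_dauer_entry = TRUE,
                                 include_low = FALSE, ilps = NULL,
                                 assays = screenAssays()) {
  stopifnot(all(c("ilp", "assay", "level") %in% names(calls)))
  if (!all(calls$assay %in% assays))
    stop("unknown assay in calls: ",
         paste(setdiff(calls$assay, assays), collapse = ", "), call. = FALSE)
  if (is.null(ilps)) ilps <- sort(unique(calls$ilp))
  keep <- c("high", if (include_low) "low")
  hits <- calls[calls$level %in% keep, , drop = FALSE]
  mat <- matrix(0L, length(ilps), length(assays),
                dimnames = list(ilps, assays))
  if (nrow(hits))
    mat[cbind(match(hits$ilp, ilps), match(hits$assay, assays))] <- 1L
  if (aggregate_dauer_entry) {
    de <- as.integer(rowSums(mat[, dauerEntryAssays, drop = FALSE]) > 0)
    mat <- cbind(dauer_entry = de,
                 mat[, setdiff(assays, dauerEntryAssays), drop = FALSE])
  }
  mat
}

#' Per-ILP pleiotropy: percentage of processes affected
#'
#' @param matrix binary incidence matrix from
#'   \code{\link{buildPhenotypeMatrix}}.
#' @return named numeric vector, row sums as a percentage of the number of
#'   processes.
#' @export
pleiotropy <- function(matrix) {
  100 * rowSums(matrix) / ncol(matrix)
}

#' Curated high-confidence screen calls for the 35 ILP deletion panel
#'
#' Loads the curated table of published high-confidence phenotype calls for
#' 35 C. elegans ILP mutants across the 8 screens (dauer entry in three
#' backgrounds, dauer exit, lifespan, thermotolerance, pathogen resistance,
#' reproductive span), as reported in the study's results summary.  Curated
#' at call level from the published summary; calls visible only in the
#' full published dataset may be missing.
#'
#' @return data.frame with columns \code{ilp}, \code{assay}, \code{level},
#'   \code{direction}; \code{attr(, "panel")} lists all 35 assayed mutants.
#' @export
ilpScreenCalls <- function() {
  path <- system.file("extdata", "ilp_screen_calls.tsv", package = "ilpnet")
  calls <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  panel <- c(paste0("ins-", c(1:15, 18, 20:31, 33:35, 37:39)), "daf-28")
  attr(calls, "panel") <- panel
  calls
}
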