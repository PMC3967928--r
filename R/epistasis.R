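# Double-mutant interaction analysis for dauer-entry counts: independence
# expectation, per-trial deviation tests and the interaction-class decision
# tree.

#' Expected double-mutant dauer probability under independence
#'
#' If the two mutations act independently, an animal stays out of dauer only
#' if it escapes the effect of both: P_xy = P_x + P_y - P_x * P_y.
#' The model sits behind this one function so an alternative (e.g.
#' baseline-relative odds) can be swapped in.
#'
#' @param p_x,p_y single-mutant dauer-entry probabilities.
#' @param model \code{"independent_escape"} (default) or
#'   \code{"odds"} (odds-multiplicative alternative).
#' @return expected double-mutant probability in [0, 1].
#' @examples
#' expectedDoubleProbability(0.2, 0.3)  # 0.44
#' @export
expectedDoubleProbability <- function(p_x, p_y,
                                      model = c("independent_escape",
                                                "odds")) {
  model <- match.arg(model)
  assertProbability(p_x); assertProbability(p_y)
  if (model == "independent_escape") {
    p_x + p_y - p_x * p_y
  } else {
    ox <- p_x / (1 - p_x); oy <- p_y / (1 - p_y)
    if (!is.finite(ox) || !is.finite(oy)) return(1)
    oxy <- ox * oy
    oxy / (1 + oxy)
  }
}

# Largest-remainder rounding of n * prob into integer (dauers, non-dauers)
# summing exactly to n.
expectedCounts <- function(p_xy, n) {
  raw <- c(p_xy, 1 - p_xy) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  setNames(as.integer(base), c("dauers", "non_dauers"))
}

#' Per-trial deviation of a double mutant from its additive expectation
#'
#' The expectation is computed from the same-trial single-mutant
#' proportions; expected counts at the double mutant's scored n are rounded
#' by largest remainder.  The default test conditions on both margins of
#' the observed-vs-expected table (exact hypergeometric); a binomial test
#' of the observed count against P_xy is available.
#'
#' @param double_dauers,double_total observed double-mutant counts.
#' @param p_x,p_y same-trial single-mutant proportions.
#' @param method \code{"exact_conditional"} or \code{"binomial"}.
#' @param model expectation model, see
#'   \code{\link{expectedDoubleProbability}}.
#' @return list with \code{p}, \code{direction} (+1 above expectation, -1
#'   below, 0 at), \code{expectation} (P_xy), \code{expected_counts}.
#' @export
deviationTest <- function(double_dauers, double_total, p_x, p_y,
                          method = c("exact_conditional", "binomial"),
                          model = "independent_escape") {
  method <- match.arg(method)
  p_xy <- expectedDoubleProbability(p_x, p_y, model = model)
  ec <- expectedCounts(p_xy, double_total)
  dprop <- double_dauers / double_total - ec[["dauers"]] / double_total
  direction <- if (abs(dprop) < sqrt(.Machine$double.eps)) 0L
               else as.integer(sign(dprop))
  p <- if (method == "exact_conditional") {
    hypergeomCountTest(double_dauers, double_total,
                       ec[["dauers"]], double_total)$p
  } else {
    stats::binom.test(double_dauers, double_total, p_xy)$p.value
  }
  list(p = p, direction = direction, expectation = unname(p_xy),
       expected_counts = ec)
}

# >= half of trials significant: the rule used for strain-vs-strain
# comparisons.
atLeastHalf <- function(p, alpha = 0.05) mean(p < alpha) >= 0.5

# strict majority: the rule used for the deviation-direction tally
# (exactly half resolves conservatively as no majority).
strictMajority <- function(flags) mean(flags) > 0.5

pairP <- function(counts, a, b) {
  vapply(sort(unique(counts$trial)), function(tr) {
    ca <- counts[counts$trial == tr & counts$strain == a, ]
    cb <- counts[counts$trial == tr & counts$strain == b, ]
    hypergeomCountTest(ca$dauers, ca$total, cb$dauers, cb$total)$p
  }, 0)
}

pairDir <- function(counts, a, b) {
  pa <- sum(counts$dauers[counts$strain == a]) /
    sum(counts$total[counts$strain == a])
  pb <- sum(counts$dauers[counts$strain == b]) /
    sum(counts$total[counts$strain == b])
  sign(pa - pb)
}

#' Classify a double-mutant genetic interaction
#'
#' Decision tree over per-trial deviation tests and pairwise strain
#' comparisons.  A strict majority of trials significantly above the
#' additive expectation gives \code{"synergistic"}.  Otherwise, after
#' ruling out \code{"no_effect"} (no strain differs from wild type), the
#' call depends on the single mutants: opposing effects give
#' \code{"suppression"} when the double is pulled significantly below the
#' increasing single, the ambiguous \code{"non_synergistic"} when the
#' double differs from one single only yet not from expectation, and
#' \code{"no_interaction"} otherwise; concordant singles with phenotypes
#' give \code{"non_additive"} when the double falls below expectation and
#' \code{"additive"} when it stays within it; remaining patterns resolve
#' to \code{"non_synergistic"}/\code{"no_interaction"} by the same
#' differs-from-one-single-only rule.
#' Strain-vs-strain differences are deemed significant when at least half
#' of the trials show p < 0.05.
#'
#' @param counts long-format count table with one row per (trial, strain),
#'   strains \code{wild_type}, \code{single_x}, \code{single_y},
#'   \code{double} (as from \code{\link{simulateDoubleMutantCounts}}).
#' @param method,model passed to \code{\link{deviationTest}}.
#' @param alpha per-comparison significance level.
#' @return An \code{InteractionCall} list: \code{class}, per-trial
#'   deviation table, pairwise comparison summary, expectation.
#' @export
classifyInteraction <- function(counts, method = "exact_conditional",
                                model = "independent_escape",
                                alpha = 0.05) {
  need <- c("trial", "strain", "dauers", "total")
  stopifnot(all(need %in% names(counts)))
  strains <- c("wild_type", "single_x", "single_y", "double")
  if (!all(strains %in% counts$strain))
    stop("counts must contain wild_type, both singles and the double",
         call. = FALSE)
  trials <- sort(unique(counts$trial))
  for (tr in trials) {
    if (!all(strains %in% counts$strain[counts$trial == tr]))
      stop("every trial needs same-trial singles and wild type",
           call. = FALSE)
  }

  dev <- lapply(trials, function(tr) {
    ct <- counts[counts$trial == tr, ]
    row <- function(s) ct[ct$strain == s, ]
    deviationTest(row("double")$dauers, row("double")$total,
                  p_x = row("single_x")$dauers / row("single_x")$total,
                  p_y = row("single_y")$dauers / row("single_y")$total,
                  method = method, model = model)
  })
  devp <- vapply(dev, `[[`, 0, "p")
  devdir <- vapply(dev, function(d) as.integer(d$direction), 0L)
  above <- strictMajority(devp < alpha & devdir > 0)
  below <- strictMajority(devp < alpha & devdir < 0)

  cmp <- list(x_wt = pairP(counts, "single_x", "wild_type"),
              y_wt = pairP(counts, "single_y", "wild_type"),
              d_wt = pairP(counts, "double", "wild_type"),
              d_x = pairP(counts, "double", "single_x"),
              d_y = pairP(counts, "double", "single_y"))
  sig <- lapply(cmp, atLeastHalf, alpha = alpha)
  dirx <- pairDir(counts, "single_x", "wild_type")
  diry <- pairDir(counts, "single_y", "wild_type")

  class <- if (above) {
    "synergistic"
  } else if (!sig$x_wt && !sig$y_wt && !sig$d_wt) {
    "no_effect"
  } else if (sig$x_wt && sig$y_wt && dirx * diry < 0) {
    # opposing singles: does the suppressor pull the double below the
    # dauer-promoting single?
    upSingle <- if (dirx > 0) "d_x" else "d_y"
    upDir <- pairDir(counts, "double",
                     if (dirx > 0) "single_x" else "single_y")
    if (sig[[upSingle]] && upDir < 0) {
      "suppression"
    } else if (xor(sig$d_x, sig$d_y) && !above && !below) {
      # differs from one single only, yet not from the additive
      # expectation: too ambiguous to call either way
      "non_synergistic"
    } else {
      "no_interaction"
    }
  } else if (sig$x_wt && sig$y_wt) {
    # concordant singles: did the increased rates add up?
    if (below) "non_additive" else "additive"
  } else if (xor(sig$d_x, sig$d_y) && !below) {
    # the double differs from one single only, yet not from expectation:
    # conservatively non-synergistic when the distinguished single carries
    # its own phenotype (ambiguous additive-vs-not); plain no-interaction
    # when the undistinguished single is simply the whole story
    diffSingleSig <- if (sig$d_x) sig$x_wt else sig$y_wt
    if (diffSingleSig) "non_synergistic" else "no_interaction"
  } else if (below) {
    "non_additive"
  } else {
    "no_interaction"
  }

  structure(list(class = class,
                 deviation = data.frame(trial = trials, p = devp,
                                        direction = devdir),
                 comparisons = data.frame(
                   comparison = names(cmp),
                   significant = unlist(sig),
                   row.names = NULL),
                 expectation = mean(vapply(dev, `[[`, 0, "expectation"))),
            class = "InteractionCall")
}

#' @export
print.InteractionCall <- function(x, ...) {
  cat(sprintf("interaction class: %s (expectation P_xy = %.3f, %d trial(s))\n",
              x$class, x$expectation, nrow(x$deviation)))
  invisible(x)
}

#' All pairwise strain comparisons
#'
#' Exact count test for every strain pair, pooled per trial and combined
#' by the chi-square sum rule; supports triple-mutant analyses (triple vs
#' each double vs each single).
#'
#' @param counts long-format count table with columns \code{trial},
#'   \code{strain}, \code{dauers}, \code{total}.
#' @return symmetric matrix of combined p-values (diagonal NA).
#' @export
multiStrainTest <- function(counts) {
  strains <- sort(unique(counts$strain))
  out <- matrix(NA_real_, length(strains), length(strains),
                dimnames = list(strains, strains))
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (i == j) next
      pv <- pairP(counts, strains[i], strains[j])
      stats <- qchisq(pv, df = 1, lower.tail = FALSE)
      out[i, j] <- pchisq(sum(stats), df = length(pv), lower.tail = FALSE)
    }
  }
  out
}
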