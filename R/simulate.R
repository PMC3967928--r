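# Synthetic-data generators.  Every generator draws from its own RNG
# substream derived from (seed, generator-name), so outputs are reproducible
# bit-for-bit and independent of call order.

#' Simulate dauer-entry count trials
#'
#' Each trial distributes \code{n_eggs} eggs per plate for a control and a
#' mutant group and scores dauers 48 h later; counts are binomial draws at
#' the stated per-group probabilities.
#'
#' @param p_control,p_mutant probability of dauer entry per animal.
#' @param n_eggs eggs scored per group per trial (default 50, one plate).
#' @param n_trials number of independent trials.
#' @param seed integer seed.
#' @param lab,background,temperature metadata attached to every trial.
#' @return data.frame with one row per (trial, group): columns \code{trial},
#'   \code{group}, \code{dauers}, \code{total}, \code{lab},
#'   \code{background}, \code{temperature}.  Ground-truth probabilities are
#'   attached as \code{attr(, "truth")}.
#' @examples
#' simulateDauerTrials(0.05, 0.5, n_trials = 2, seed = 1)
#' @export
simulateDauerTrials <- function(p_control, p_mutant, n_eggs = 50L,
                                n_trials = 3L, seed = 1L,
                                lab = "lab1", background = "wild-type",
                                temperature = 27) {
  assertProbability(p_control); assertProbability(p_mutant)
  n_eggs <- assertCount(n_eggs); n_trials <- assertCount(n_trials)
  withSeed(deriveSeed(seed, "dauer_trials"), {
    out <- data.frame(
      trial = rep(seq_len(n_trials), each = 2L),
      group = rep(c("control", "mutant"), n_trials),
      dauers = as.vector(rbind(rbinom(n_trials, n_eggs, p_control),
                               rbinom(n_trials, n_eggs, p_mutant))),
      total = n_eggs,
      lab = lab, background = background, temperature = temperature,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(p_control = p_control, p_mutant = p_mutant)
    out
  })
}

# Upper bound u of a Uniform(0, u) censoring law giving the requested
# censoring fraction against Exp(rate) event times.
censorUpper <- function(rate, fraction) {
  if (fraction <= 0) return(Inf)
  f <- function(u) (1 - exp(-rate * u)) / (rate * u) - fraction
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate right-censored survival trials
#'
#' Control event times are exponential with rate 1 (time unit = control mean
#' lifespan); mutant times are scaled by \code{1 / hazard_ratio}, the
#' proportional-hazards alternative the log-rank test is powered against.
#' Independent Uniform(0, u) right-censoring is calibrated so that the
#' expected censored fraction equals \code{censor_fraction}.
#'
#' @param hazard_ratio mutant-vs-control hazard ratio (> 0); values < 1 mean
#'   longer-lived mutants.
#' @param n_per_group animals per group per trial.
#' @param censor_fraction expected fraction right-censored, in [0, 1).
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param lab,assay metadata attached to every trial.
#' @return data.frame with one row per animal: \code{trial}, \code{group},
#'   \code{duration}, \code{event} (1 = death observed, 0 = censored),
#'   \code{lab}, \code{assay}; truth in \code{attr(, "truth")}.
#' @examples
#' simulateSurvivalTrials(0.5, n_per_group = 20, n_trials = 1, seed = 1)
#' @export
simulateSurvivalTrials <- function(hazard_ratio, n_per_group = 50L,
                                   censor_fraction = 0, n_trials = 3L,
                                   seed = 1L, lab = "lab1",
                                   assay = "lifespan") {
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    stop("'hazard_ratio' must be > 0", call. = FALSE)
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("'censor_fraction' must be in [0, 1)", call. = FALSE)
  n_per_group <- assertCount(n_per_group)
  n_trials <- assertCount(n_trials)
  withSeed(deriveSeed(seed, "survival_trials"), {
    rows <- lapply(seq_len(n_trials), function(tr) {
      n <- n_per_group
      t_ctrl <- rexp(n, rate = 1)
      t_mut <- rexp(n, rate = hazard_ratio)
      tt <- c(t_ctrl, t_mut)
      grp <- rep(c("control", "mutant"), each = n)
      rate <- rep(c(1, hazard_ratio), each = n)
      if (censor_fraction > 0) {
        cc <- c(runif(n, 0, censorUpper(1, censor_fraction)),
                runif(n, 0, censorUpper(hazard_ratio, censor_fraction)))
        ev <- as.integer(tt <= cc)
        tt <- pmin(tt, cc)
      } else ev <- rep(1L, 2L * n)
      data.frame(trial = tr, group = grp, duration = tt, event = ev,
                 lab = lab, assay = assay, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(hazard_ratio = hazard_ratio,
                               censor_fraction = censor_fraction)
    out
  })
}

#' Simulate interval-censored survival trials
#'
#' Latent exponential death times are observed only at shared inspection
#' times spaced \code{inspection_spacing} apart (e.g. worms scored every
#' 8-9 h on a killing assay).  A death in \code{(k-1, k]}-th interval is
#' recorded as bounds \code{(L, R]}; animals alive at the last inspection
#' carry \code{R = Inf}.
#'
#' @param hazard_ratio mutant-vs-control hazard ratio.
#' @param inspection_spacing spacing of the shared inspection grid (> 0), in
#'   units of the control mean lifespan.
#' @param n_per_group animals per group per trial.
#' @param n_trials number of trials.
#' @param n_inspections number of inspections; animals outliving the grid
#'   are right-censored at the last inspection.
#' @param seed integer seed.
#' @param lab metadata.
#' @return data.frame with one row per animal: \code{trial}, \code{group},
#'   \code{L}, \code{R}, \code{lab}; truth (latent times included) in
#'   \code{attr(, "truth")}.
#' @examples
#' simulateIntervalTrials(1, inspection_spacing = 0.4, n_per_group = 10,
#'                        n_trials = 1, seed = 1)
#' @export
simulateIntervalTrials <- function(hazard_ratio, inspection_spacing = 0.35,
                                   n_per_group = 50L, n_trials = 3L,
                                   n_inspections = 20L, seed = 1L,
                                   lab = "lab1") {
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    stop("'hazard_ratio' must be > 0", call. = FALSE)
  if (!is.numeric(inspection_spacing) || inspection_spacing <= 0)
    stop("'inspection_spacing' must be > 0", call. = FALSE)
  n_per_group <- assertCount(n_per_group)
  n_trials <- assertCount(n_trials)
  withSeed(deriveSeed(seed, "interval_trials"), {
    grid_end <- inspection_spacing * n_inspections
    rows <- lapply(seq_len(n_trials), function(tr) {
      n <- n_per_group
      latent <- c(rexp(n, 1), rexp(n, hazard_ratio))
      k <- ceiling(latent / inspection_spacing)
      L <- (k - 1) * inspection_spacing
      R <- k * inspection_spacing
      open <- latent > grid_end
      L[open] <- grid_end
      R[open] <- Inf
      data.frame(trial = tr,
                 group = rep(c("control", "mutant"), each = n),
                 L = L, R = R, lab = lab,
                 latent = latent, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    truth <- list(hazard_ratio = hazard_ratio,
                  inspection_spacing = inspection_spacing,
                  latent = out$latent)
    out$latent <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a perturbation qPCR dataset with planted regulatory edges
#'
#' Generates log-normal copy numbers for \code{n_genes} assayed genes plus
#' \code{n_reference} stable reference genes, across a wild-type sample
#' group and one null-mutant group per gene in \code{mutants}.  Each planted
#' edge (regulator, target, sign, log2fc) shifts the target's mean in the
#' regulator's mutant following the null-allele convention: knocking out an
#' activator (+1) lowers its target by \code{log2fc}; knocking out an
#' inhibitor (-1) de-represses it by \code{log2fc}.
#'
#' @param n_genes number of assayed (non-reference) genes; named
#'   \code{g1..gN} unless \code{gene_names} is given.
#' @param n_mutants number of mutant genotypes (null alleles of the first
#'   \code{n_mutants} genes).
#' @param planted_edges data.frame with columns \code{regulator},
#'   \code{target}, \code{sign} (+1/-1) and optionally \code{log2fc}
#'   (magnitude, default 1); or NULL for a null dataset.
#' @param n_replicates replicates per genotype (3-4 typical).
#' @param noise_cv coefficient of variation of the multiplicative assay
#'   noise (default 0.10).
#' @param n_reference number of stable reference genes (default 2).
#' @param n_low_expression number of assayed genes emitted below the
#'   detection floor (ignored when \code{low_genes} is given).
#' @param low_genes explicit set of genes to emit below the detection
#'   floor; such genes cannot be planted targets (their transcripts are
#'   unanalyzable) but may be regulators (their mutants are still
#'   profiled).
#' @param baseline_copies median wild-type expression level.
#' @param detection_floor copies/reaction detection floor (default 10).
#' @param gene_names,mutants optional explicit names.
#' @param seed integer seed.
#' @return A \linkS4class{QPCRExperiment}; the planted edge list and other
#'   truth are in \code{S4Vectors::metadata()} under \code{"truth"}.
#' @examples
#' qe <- simulateQPCRDataset(n_genes = 6, n_mutants = 3,
#'   planted_edges = data.frame(regulator = "g1", target = "g2", sign = -1),
#'   seed = 1)
#' S4Vectors::metadata(qe)$truth$edges
#' @export
simulateQPCRDataset <- function(n_genes = 40L, n_mutants = 35L,
                                planted_edges = NULL, n_replicates = 4L,
                                noise_cv = 0.10, n_reference = 2L,
                                n_low_expression = 0L, low_genes = NULL,
                                baseline_copies = 1000,
                                detection_floor = 10,
                                gene_names = NULL, mutants = NULL,
                                seed = 1L) {
  n_genes <- assertCount(n_genes)
  n_mutants <- assertCount(n_mutants)
  n_replicates <- assertCount(n_replicates, min = 2L)
  n_reference <- assertCount(n_reference, min = 0L)
  n_low_expression <- assertCount(n_low_expression, min = 0L)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (n_mutants > n_genes)
    stop("cannot have more mutants than genes", call. = FALSE)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(n_genes))
  refs <- if (n_reference > 0) paste0("ref", seq_len(n_reference))
          else character()
  if (is.null(mutants)) mutants <- gene_names[seq_len(n_mutants)]
  stopifnot(all(mutants %in% gene_names))

  if (is.null(planted_edges) || NROW(planted_edges) == 0L) {
    planted_edges <- data.frame(regulator = character(),
                                target = character(), sign = numeric(),
                                log2fc = numeric())
  } else {
    planted_edges <- as.data.frame(planted_edges)
    if (is.null(planted_edges$log2fc)) planted_edges$log2fc <- 1
    if (any(planted_edges$regulator %in% refs) ||
        any(planted_edges$target %in% refs))
      stop("planted edges may not involve reference genes", call. = FALSE)
    stopifnot(all(planted_edges$regulator %in% mutants),
              all(planted_edges$target %in% gene_names),
              all(planted_edges$sign %in% c(-1, 1)))
  }

  if (!is.null(low_genes)) {
    stopifnot(all(low_genes %in% gene_names))
    if (any(planted_edges$target %in% low_genes))
      stop("planted targets must be analyzable (not low-expression)",
           call. = FALSE)
  }
  withSeed(deriveSeed(seed, "qpcr_dataset"), {
    if (is.null(low_genes)) {
      low_genes <- if (n_low_expression > 0) {
        # low-expression transcripts cannot be planted targets
        eligible <- setdiff(gene_names, planted_edges$target)
        if (length(eligible) < n_low_expression)
          stop("not enough unplanted genes to mark as low expression",
               call. = FALSE)
        sample(eligible, n_low_expression)
      } else character()
    }

    genotypes <- c("wild_type", mutants)
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           genotype = genotypes, stringsAsFactors = FALSE)
    all_genes <- c(gene_names, refs)
    # per-gene wild-type means: log-uniform spread around the baseline
    base_mu <- setNames(
      baseline_copies * 2^runif(length(all_genes), -2, 2), all_genes)
    base_mu[refs] <- baseline_copies
    base_mu[low_genes] <- detection_floor / 5

    ns <- nrow(samples)
    mu <- matrix(rep(base_mu, ns), nrow = length(all_genes),
                 dimnames = list(all_genes, NULL))
    # self-deletion: a null mutant expresses (almost) none of its own gene
    for (i in seq_len(ns)) {
      g <- samples$genotype[i]
      if (g != "wild_type" && g %in% rownames(mu))
        mu[g, i] <- detection_floor / 100
    }
    # planted regulatory shifts (null-allele convention)
    if (nrow(planted_edges)) {
      for (k in seq_len(nrow(planted_edges))) {
        e <- planted_edges[k, ]
        idx <- which(samples$genotype == e$regulator)
        shift <- if (e$sign > 0) -abs(e$log2fc) else abs(e$log2fc)
        mu[e$target, idx] <- mu[e$target, idx] * 2^shift
      }
    }
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(rlnorm(length(mu), -sdlog^2 / 2, sdlog), nrow = nrow(mu))
    if (noise_cv == 0) noise[] <- 1
    copies <- mu * noise
    colnames(copies) <- paste(samples$genotype, samples$replicate, sep = ".")

    QPCRExperiment(copies, genotype = samples$genotype,
                   replicate = samples$replicate,
                   referenceGenes = refs, detectionFloor = detection_floor,
                   metadata = list(truth = list(
                     edges = planted_edges, low_genes = low_genes,
                     mutants = mutants, noise_cv = noise_cv,
                     base_mu = base_mu)))
  })
}

# Class-specific generating parameters for double-mutant datasets.  Strong
# singles (0.65) reflect the sensitized, near-saturating backgrounds used for
# dauer-entry interaction screens; suppression needs a raised baseline so a
# suppressor single can fall below it.
doubleMutantClassParams <- function(class_label, p_x, p_y, p_control) {
  defaults <- switch(class_label,
    no_effect   = list(p0 = 0.05, px = NA, py = NA),
    suppression = list(p0 = 0.30, px = 0.65, py = 0.05),
    synergistic = list(p0 = 0.05, px = 0.30, py = 0.30),
    no_interaction = list(p0 = 0.05, px = 0.65, py = NA),
    list(p0 = 0.05, px = 0.65, py = 0.65))
  if (is.null(p_control)) p_control <- defaults$p0
  if (is.null(p_x)) p_x <- if (is.na(defaults$px)) p_control else defaults$px
  if (is.null(p_y)) p_y <- if (is.na(defaults$py)) p_control else defaults$py
  list(p_control = p_control, p_x = p_x, p_y = p_y)
}

#' Simulate double-mutant dauer-entry counts with a planted interaction class
#'
#' Generates wild-type, two single-mutant, and double-mutant dauer counts
#' per trial.  The double mutant's generating probability is set by the
#' planted class relative to the independence expectation
#' \eqn{P_{xy} = P_x + P_y - P_x P_y}: at it (\code{additive}), above it
#' (\code{synergistic}), at the stronger single (\code{non_additive}),
#' suppressed below the increasing single (\code{suppression}), at the
#' stronger single with one inactive single (\code{no_interaction}), or at
#' baseline everywhere (\code{no_effect}).
#'
#' @param class_label one of \code{"additive"}, \code{"synergistic"},
#'   \code{"non_additive"}, \code{"suppression"}, \code{"no_interaction"},
#'   \code{"no_effect"}.
#' @param p_x,p_y single-mutant dauer probabilities; class-specific
#'   defaults are used when NULL.
#' @param p_control wild-type baseline probability.
#' @param n_eggs eggs per strain per trial.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param temperature metadata (26.5 used for near-saturating strains).
#' @return data.frame with one row per (trial, strain), strains
#'   \code{wild_type}, \code{single_x}, \code{single_y}, \code{double};
#'   ground truth in \code{attr(, "truth")}.
#' @examples
#' simulateDoubleMutantCounts("synergistic", n_trials = 2, seed = 1)
#' @export
simulateDoubleMutantCounts <- function(class_label, p_x = NULL, p_y = NULL,
                                       p_control = NULL, n_eggs = 50L,
                                       n_trials = 3L, seed = 1L,
                                       temperature = 26.5) {
  classes <- c("additive", "synergistic", "non_additive", "suppression",
               "no_interaction", "no_effect")
  class_label <- match.arg(class_label, classes)
  n_eggs <- assertCount(n_eggs); n_trials <- assertCount(n_trials)
  pp <- doubleMutantClassParams(class_label, p_x, p_y, p_control)
  p_control <- assertProbability(pp$p_control)
  p_x <- assertProbability(pp$p_x); p_y <- assertProbability(pp$p_y)
  exp_xy <- expectedDoubleProbability(p_x, p_y)
  p_xy <- switch(class_label,
    additive = exp_xy,
    synergistic = {
      if (exp_xy > 0.95)
        stop("synergistic class unreachable: expectation already ~1",
             call. = FALSE)
      min(1, exp_xy + 0.75 * (1 - exp_xy))
    },
    non_additive = max(p_x, p_y),
    suppression = {
      if (p_x <= p_control && p_y <= p_control)
        stop("suppression needs one dauer-promoting single", call. = FALSE)
      0.6 * min(p_x, p_y) + 0.4 * p_control
    },
    no_interaction = max(p_x, p_y),
    no_effect = p_control)
  withSeed(deriveSeed(seed, "double_mutant_counts"), {
    probs <- c(wild_type = p_control, single_x = p_x, single_y = p_y,
               double = p_xy)
    out <- data.frame(
      trial = rep(seq_len(n_trials), each = 4L),
      strain = rep(names(probs), n_trials),
      dauers = rbinom(4L * n_trials, n_eggs, rep(probs, n_trials)),
      total = n_eggs, temperature = temperature,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(class = class_label, probs = probs,
                               expectation = exp_xy)
    out
  })
}

#' Simulate a planted-partition bipartite incidence matrix
#'
#' Rows and columns are split as evenly as possible into \code{n_modules}
#' groups; a cell is filled with probability \code{p_within} when its row
#' and column groups match and \code{p_between} otherwise.
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param n_modules number of planted modules.
#' @param p_within,p_between fill probabilities (\code{p_within >
#'   p_between} except in deliberate null settings).
#' @param seed integer seed.
#' @return list with \code{matrix} (binary incidence), \code{rowModules},
#'   \code{colModules}.
#' @examples
#' simulatePlantedBipartite(6, 6, 2, 1, 0, seed = 1)$matrix
#' @export
simulatePlantedBipartite <- function(n_rows, n_cols, n_modules = 2L,
                                     p_within = 0.9, p_between = 0.1,
                                     seed = 1L) {
  n_rows <- assertCount(n_rows); n_cols <- assertCount(n_cols)
  n_modules <- assertCount(n_modules)
  assertProbability(p_within); assertProbability(p_between)
  if (n_modules > min(n_rows, n_cols))
    stop("more modules than rows or columns", call. = FALSE)
  rowMod <- rep_len(seq_len(n_modules), n_rows)[order(rep_len(
    seq_len(n_modules), n_rows))]
  rowMod <- sort(rep_len(seq_len(n_modules), n_rows))
  colMod <- sort(rep_len(seq_len(n_modules), n_cols))
  withSeed(deriveSeed(seed, "planted_bipartite"), {
    p <- outer(rowMod, colMod, function(a, b)
      ifelse(a == b, p_within, p_between))
    m <- matrix(rbinom(length(p), 1L, as.vector(p)), n_rows, n_cols,
                dimnames = list(paste0("r", seq_len(n_rows)),
                                paste0("c", seq_len(n_cols))))
    list(matrix = m, rowModules = rowMod, colModules = colMod)
  })
}
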