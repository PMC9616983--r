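# Orchestration of the full forward and reverse MR analysis grids.

#' Build or read a run configuration
#'
#' A run configuration names the exposure and outcome summary-statistic
#' sources and fixes every analysis choice: the primary (5e-8) and fallback
#' (5e-6) instrument-selection thresholds, the LD pruning threshold, the
#' minimum instrument count, the palindrome ambiguity window, the estimator
#' list, the FDR grouping of outcomes, the reverse-analysis settings, and
#' the seed. `exposures`/`outcomes` entries may be file paths (read with
#' [read_summary_stats()]) or in-memory tables.
#'
#' @param exposures Named list: trait name -> path or [summary_table()].
#' @param outcomes Named list: trait name -> path or [summary_table()].
#' @param ld Optional [ld_table()] or path to one.
#' @param p_threshold_primary,p_threshold_fallback Selection thresholds
#'   (defaults 5e-8 and 5e-6).
#' @param r2_max LD pruning threshold (default 0.001).
#' @param min_snps Minimum instruments before falling back (default 3).
#' @param ambiguity_window Palindrome ambiguity window (default
#'   `c(0.42, 0.58)`).
#' @param methods Estimators to run per cell (default ivw, egger,
#'   weighted_median, presso).
#' @param fdr_groups Named character vector mapping outcome name -> FDR
#'   group label; outcomes absent from the map form their own group.
#' @param exclude_cross_trait If `TRUE` (default), SNPs associated with more
#'   than one exposure at the selection threshold are excluded up front.
#' @param reverse Logical: is this configuration intended for a reverse
#'   (outcome-to-exposure) run?
#' @param reverse_overlap_pair Character length-2: the two exposure traits
#'   of the reverse run whose shared genome-wide-significant SNPs are
#'   removed from both instrument sets (e.g. cortical surface area and
#'   thickness).
#' @param n_boot,n_sim Bootstrap/simulation sizes for the stochastic
#'   estimators.
#' @param seed Integer seed making the whole run deterministic.
#' @return List of class `run_config`.
#' @export
run_config <- function(exposures, outcomes, ld = NULL,
                       p_threshold_primary = 5e-8,
                       p_threshold_fallback = 5e-6,
                       r2_max = 0.001, min_snps = 3,
                       ambiguity_window = c(0.42, 0.58),
                       methods = c("ivw", "egger", "weighted_median",
                                   "presso"),
                       fdr_groups = NULL,
                       exclude_cross_trait = TRUE,
                       reverse = FALSE,
                       reverse_overlap_pair = NULL,
                       n_boot = 1000, n_sim = 1000, seed = 1L) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            p_threshold_primary > 0, p_threshold_primary < 1,
            p_threshold_fallback > 0, p_threshold_fallback < 1)
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    stop("exposures and outcomes must be named lists")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments (`exposures`/`outcomes` as name: path mappings).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(exposures = as.list(y$exposures),
               outcomes = as.list(y$outcomes))
  for (f in c("ld", "p_threshold_primary", "p_threshold_fallback", "r2_max",
              "min_snps", "ambiguity_window", "methods", "exclude_cross_trait",
              "reverse", "reverse_overlap_pair", "n_boot", "n_sim", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$fdr_groups)) args$fdr_groups <- unlist(y$fdr_groups)
  do.call(run_config, args)
}

.load_table <- function(x, name) {
  t <- if (is.character(x)) read_summary_stats(x, trait_name = name)
  else if (inherits(x, "summary_table")) x
  else summary_table(as.data.frame(x), trait_name = name)
  attr(t, "trait_name") <- name  # config name wins in reports
  t
}

.load_ld <- function(x) {
  if (is.null(x)) NULL
  else if (is.character(x)) read_ld_table(x)
  else x
}

# One exposure x outcome analysis cell: returns report rows.
.run_cell <- function(inst, outcome_tab, cfg, cell_seed) {
  exp_name <- inst$exposure_name
  out_name <- attr(outcome_tab, "trait_name")
  empty_row <- function(note) {
    data.frame(exposure = exp_name, outcome = out_name, method = note,
               nSNP = 0L, beta = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, p = NA_real_, p_adjusted = NA_real_,
               Q = NA_real_, Q_p = NA_real_, egger_intercept = NA_real_,
               egger_intercept_p = NA_real_, stringsAsFactors = FALSE)
  }
  if (inst$insufficient || inst$n_snps == 0) {
    return(empty_row("no_instruments"))
  }
  h <- harmonize_set(inst, outcome_tab, cfg$ambiguity_window)
  usable <- .usable_pairs(h)
  if (nrow(usable) == 0) return(empty_row("no_usable_pairs"))

  rows <- list()
  qd <- if (nrow(usable) >= 2) cochran_q(h) else NULL
  for (m in cfg$methods) {
    r <- tryCatch(switch(
      m,
      ivw = if (nrow(usable) >= 2) mr_ivw(h) else
        wald_ratio(usable$bx[1], usable$by[1], usable$se_y[1],
                   snp_id = usable$snp_id[1]),
      egger = mr_egger(h),
      weighted_median = mr_weighted_median(h, n_boot = cfg$n_boot,
                                           seed = cell_seed),
      presso = mr_presso(h, n_sim = cfg$n_sim, seed = cell_seed + 1L),
      stop("unknown method: ", m)
    ), error = function(e) NULL)
    if (is.null(r)) next
    row <- as.data.frame(r)
    row$exposure <- exp_name
    row$outcome <- out_name
    if (m %in% c("ivw", "wald") && !is.null(qd)) {
      row$Q <- qd$q; row$Q_p <- qd$p
    }
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) return(empty_row("no_estimator_ran"))
  do.call(rbind, rows)
}

# Grouped BH adjustment across the grid: one family per (FDR group, method).
.adjust_grid <- function(report, fdr_groups) {
  grp <- if (is.null(fdr_groups)) report$outcome else {
    g <- fdr_groups[report$outcome]
    ifelse(is.na(g), report$outcome, g)
  }
  ok <- !is.na(report$p)
  if (any(ok)) {
    fam <- paste(grp[ok], report$method[ok], sep = "|")
    report$p_adjusted[ok] <- bh_adjust(report$p[ok], fam)$p_adjusted
  }
  report
}

#' Run the forward MR analysis grid
#'
#' For every exposure x outcome pair: select instruments at the primary
#' threshold (falling back to the relaxed threshold when fewer than
#' `min_snps` SNPs survive, with the fallback recorded), harmonize against
#' the outcome, run the configured estimators and heterogeneity diagnostics,
#' and finally apply grouped BH-FDR adjustment across the grid (one family
#' per FDR group and method). Exposures with no instruments at either
#' threshold yield a `no_instruments` row rather than an error. The run is
#' deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return data.frame with the report columns (see [write_report()]) plus
#'   attribute `"selection"`: per-exposure threshold used and SNP count.
#' @export
run_forward <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exp_tabs <- Map(.load_table, config$exposures, names(config$exposures))
  out_tabs <- Map(.load_table, config$outcomes, names(config$outcomes))
  ld <- .load_ld(config$ld)
  cross <- if (isTRUE(config$exclude_cross_trait) && length(exp_tabs) > 1) {
    cross_trait_snps(exp_tabs, config$p_threshold_fallback)
  } else character(0)

  insts <- lapply(exp_tabs, function(tab) {
    inst <- select_instruments(tab, config$p_threshold_primary, cross, ld,
                               config$min_snps, config$r2_max)
    if (inst$insufficient) {
      inst <- select_instruments(tab, config$p_threshold_fallback, cross, ld,
                                 config$min_snps, config$r2_max)
      inst$fallback <- TRUE
    } else {
      inst$fallback <- FALSE
    }
    inst
  })

  rows <- list()
  cell <- 0L
  for (i in seq_along(insts)) {
    for (k in seq_along(out_tabs)) {
      cell <- cell + 1L
      rows[[cell]] <- .run_cell(insts[[i]], out_tabs[[k]], config,
                                cell_seed = config$seed + 1000L * cell)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report <- .adjust_grid(report, config$fdr_groups)
  attr(report, "selection") <- data.frame(
    exposure = vapply(insts, function(x) x$exposure_name, character(1)),
    p_threshold = vapply(insts, function(x) x$p_threshold, numeric(1)),
    fallback = vapply(insts, function(x) x$fallback, logical(1)),
    n_snps = vapply(insts, function(x) x$n_snps, integer(1)),
    insufficient = vapply(insts, function(x) x$insufficient, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  report
}

#' Run the reverse MR analysis grid
#'
#' Tests reverse causation by swapping roles: the forward outcomes become
#' exposures, instrumented at the genome-wide-significant threshold only (no
#' relaxed fallback), against the forward exposures as outcomes. Before
#' selection, SNPs reaching genome-wide significance for both traits named
#' in `reverse_overlap_pair` (typically cortical surface area and thickness,
#' which share the MRI measurement) are removed from both instrument sets to
#' limit pleiotropy. Refuses to run unless the config's `reverse` flag is
#' set.
#'
#' @param config A [run_config()] with `reverse = TRUE`; its `exposures`
#'   are the reverse run's exposures (the forward outcomes) and its
#'   `outcomes` the reverse run's outcomes.
#' @return As [run_forward()].
#' @export
run_reverse <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!isTRUE(config$reverse)) {
    stop("this configuration is not flagged for a reverse analysis; ",
         "set reverse = TRUE to confirm the role swap")
  }
  exp_tabs <- Map(.load_table, config$exposures, names(config$exposures))
  overlap <- character(0)
  pair <- config$reverse_overlap_pair
  if (!is.null(pair)) {
    if (!all(pair %in% names(exp_tabs))) {
      stop("reverse_overlap_pair names traits absent from the exposures")
    }
    thr <- config$p_threshold_primary
    a <- exp_tabs[[pair[1]]]; b <- exp_tabs[[pair[2]]]
    overlap <- intersect(a$snp_id[a$p <= thr], b$snp_id[b$p <= thr])
  }
  fwd <- run_config(
    exposures = config$exposures, outcomes = config$outcomes,
    ld = config$ld,
    p_threshold_primary = config$p_threshold_primary,
    p_threshold_fallback = config$p_threshold_primary,  # no relaxed fallback
    r2_max = config$r2_max, min_snps = config$min_snps,
    ambiguity_window = config$ambiguity_window,
    methods = config$methods, fdr_groups = config$fdr_groups,
    exclude_cross_trait = FALSE,
    n_boot = config$n_boot, n_sim = config$n_sim, seed = config$seed)
  # drop the shared genome-wide hits from both traits of the overlap pair
  exp_tabs2 <- lapply(names(exp_tabs), function(nm) {
    t <- exp_tabs[[nm]]
    if (!(nm %in% pair) || length(overlap) == 0) return(t)
    keep <- !(t$snp_id %in% overlap)
    summary_table(as.data.frame(t)[keep, , drop = FALSE],
                  trait_name = attr(t, "trait_name"),
                  trait_units = attr(t, "trait_units"))
  })
  names(exp_tabs2) <- names(exp_tabs)
  fwd$exposures <- exp_tabs2
  report <- run_forward(fwd)
  attr(report, "overlap_excluded") <- overlap
  report
}
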