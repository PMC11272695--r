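# Dataset-level evaluation: simulate every study under a strategy, score
# profiles, aggregate per compound and per strategy by medians, run strategy
# grids and the three-step evaluation workflow.

#' Construct a study record
#'
#' @param study_id,compound_id Labels.
#' @param dosing An `htpbk_dosing`.
#' @param observations An `htpbk_profile` of observed concentrations
#'   (non-empty).
#' @param demographics Optional list (sex, age, weight, height).
#' @return An `htpbk_study` object.
#' @export
study_record <- function(study_id, compound_id, dosing, observations,
                         demographics = NULL) {
  stopifnot(inherits(dosing, "htpbk_dosing"), nrow(observations) >= 1)
  if (dosing$dose_mg <= 0) stop("study dose must be > 0")
  structure(list(study_id = study_id, compound_id = compound_id,
                 dosing = dosing, observations = observations,
                 demographics = demographics),
            class = "htpbk_study")
}

.study_route <- function(study)
  if (study$dosing$route == "oral") "po" else "iv"

#' Simulate one study under a parameterisation strategy
#'
#' Resolves the compound's inputs for the study's route, scales the
#' physiology by the study demographics when present (reference healthy adult
#' male otherwise), assembles partition coefficients and clearance, and
#' integrates the model at exactly the observed timepoints.
#'
#' @param study An `htpbk_study`.
#' @param strat An `htpbk_strategy`.
#' @param compounds Named list of `htpbk_compound` (from
#'   [load_property_table()] or the synthetic generator).
#' @param phys Reference `htpbk_physiology`.
#' @param blood_plasma_ratio Scalar blood:plasma ratio.
#' @param engine Engine settings, see [engine_defaults()].
#' @return An `htpbk_profile` predicted at the observed times.
#' @export
simulate_study <- function(study, strat, compounds, phys = reference_human(),
                           blood_plasma_ratio = 1, engine = engine_defaults()) {
  compound <- compounds[[study$compound_id]]
  if (is.null(compound)) stop("unknown compound: ", study$compound_id)
  params <- resolve_inputs(compound, strat, .study_route(study))
  dem <- study$demographics
  sphys <- if (is.null(dem)) phys else
    scale_physiology(phys, sex = dem$sex, age = dem$age,
                     weight = dem$weight, height = dem$height)
  part <- compute_partition_set(strat$partitioning_method, params, sphys,
                                blood_plasma_ratio)
  clear <- assemble_clearance(strat, params, sphys)
  times <- study$observations$time_h
  spec <- simulation_spec(params, part, clear, sphys, study$dosing,
                          output_times = times,
                          blood_plasma_ratio = blood_plasma_ratio,
                          engine = engine)
  prof <- simulate_profile(spec)
  attr(prof, "study_id") <- study$study_id
  prof
}

#' Median aggregation of per-study values
#'
#' The representative value for a compound is the median over its studies so
#' that individual outlier studies do not distort results; with an even
#' count, the mean of the two central values.
#'
#' @param study_values Non-empty numeric vector.
#' @return The median.
#' @export
aggregate_compound <- function(study_values) {
  if (length(study_values) == 0) stop("no study values to aggregate")
  median(study_values)
}

#' Evaluate one strategy against a study dataset
#'
#' Simulates every study, scores each profile (relative/absolute Log2 error
#' over datapoints, log2 Cmax/Tmax/AUC ratios), takes per-compound medians
#' and summarises the strategy by the median over compounds plus fold-range
#' tables of the per-compound median Cmax and AUC ratios. Studies that fail
#' to resolve or integrate are excluded from the medians but counted and
#' reported.
#'
#' @inheritParams simulate_study
#' @param dataset List of `htpbk_study`.
#' @param loq Observed values at or below this are excluded from the
#'   datapoint metrics.
#' @return An `htpbk_strategy_result`: list with `label`, `per_study` and
#'   `per_compound` data.frames, `median_absolute_log2`,
#'   `median_relative_log2`, `fold_table`, `n_failed`, `failures`.
#' @export
evaluate_strategy <- function(dataset, strat, compounds,
                              phys = reference_human(),
                              blood_plasma_ratio = 1,
                              engine = engine_defaults(), loq = 0) {
  if (length(dataset) == 0) stop("empty dataset")
  rows <- list(); failures <- character(0)
  for (study in dataset) {
    res <- tryCatch({
      pred <- simulate_study(study, strat, compounds, phys,
                             blood_plasma_ratio, engine)
      err <- profile_log2_errors(pred, study$observations, loq = loq)
      np <- nca(pred); no <- nca(study$observations)
      data.frame(study_id = study$study_id, compound_id = study$compound_id,
                 n_points = err$n_points, n_excluded = err$n_excluded,
                 relative_log2 = err$relative_log2,
                 absolute_log2 = err$absolute_log2,
                 cmax_log2 = log2(max(np$cmax, 1e-12) / max(no$cmax, 1e-12)),
                 tmax_log2 = log2(max(np$tmax, 1e-6) / max(no$tmax, 1e-6)),
                 auc_log2 = log2(max(np$auc_0_last, 1e-12) /
                                 max(no$auc_0_last, 1e-12)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", study$study_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0)
    stop("all simulations failed:\n", paste(failures, collapse = "\n"))
  per_study <- do.call(rbind, rows)
  agg <- function(col) vapply(split(per_study[[col]], per_study$compound_id),
                              aggregate_compound, numeric(1))
  ids <- sort(unique(per_study$compound_id))
  per_compound <- data.frame(
    compound_id = ids,
    n_studies = as.integer(table(per_study$compound_id)[ids]),
    relative_log2 = agg("relative_log2")[ids],
    absolute_log2 = agg("absolute_log2")[ids],
    cmax_log2 = agg("cmax_log2")[ids],
    tmax_log2 = agg("tmax_log2")[ids],
    auc_log2 = agg("auc_log2")[ids],
    row.names = NULL, stringsAsFactors = FALSE
  )
  fold_table <- rbind(
    cmax = fold_summaries(2^per_compound$cmax_log2,
                          rep(1, nrow(per_compound))),
    auc = fold_summaries(2^per_compound$auc_log2,
                         rep(1, nrow(per_compound))))
  structure(list(
    label = strat$label,
    strategy = strat,
    per_study = per_study,
    per_compound = per_compound,
    median_absolute_log2 = aggregate_compound(per_compound$absolute_log2),
    median_relative_log2 = aggregate_compound(per_compound$relative_log2),
    fold_table = fold_table,
    n_failed = length(failures),
    failures = failures
  ), class = "htpbk_strategy_result")
}

#' @export
print.htpbk_strategy_result <- function(x, ...) {
  cat(sprintf(paste0("<htpbk_strategy_result> %s: %d compounds, %d studies",
                     " (%d failed)\n  median |log2 error| %.3f, median log2",
                     " error %+.3f\n"),
              x$label, nrow(x$per_compound), nrow(x$per_study), x$n_failed,
              x$median_absolute_log2, x$median_relative_log2))
  invisible(x)
}

# Apply one grid option (possibly compound: clearance carries mode + renal
# flag, lipophilicity options may be "a+b" consensus sets) to a strategy.
.apply_slot <- function(strat, slot, value) {
  if (slot == "lipophilicity_source") {
    strat$lipophilicity_sources <- strsplit(value, "+", fixed = TRUE)[[1]]
    strat$lipophilicity_consensus <- length(strat$lipophilicity_sources) > 1
  } else if (slot == "clearance") {
    parts <- strsplit(value, "/", fixed = TRUE)[[1]]
    strat$clearance_source <- parts[1]
    strat$clearance_mode <- if (length(parts) > 1) parts[2] else "plasma"
    strat$renal_passive <- length(parts) > 2 && parts[3] == "renal"
  } else if (slot %in% c("pka_source", "partitioning_method", "fu_source",
                         "solubility_source", "solubility_subtype",
                         "permeability_source", "permeability_subtype",
                         "permeability_scaling", "lipophilicity_conversion")) {
    strat[[slot]] <- value
  } else stop("unknown grid slot: ", slot)
  strat
}

#' Evaluate a grid of parameterisation strategies
#'
#' Builds the cartesian product of the per-slot options applied to a base
#' strategy, evaluates each combination and ranks them by median absolute
#' Log2 error (ties broken lexicographically by strategy label).
#'
#' @param slot_options Named list: slot -> character vector of options.
#'   Recognised slots: `lipophilicity_source` (use `"a+b"` for a consensus
#'   mean of several tools), `pka_source`, `partitioning_method`,
#'   `fu_source`, `clearance` (encoded `"source/mode"` or
#'   `"source/intrinsic/renal"`), `solubility_source`, `solubility_subtype`,
#'   `permeability_source`, `permeability_subtype`, `permeability_scaling`,
#'   `lipophilicity_conversion`.
#' @param base An `htpbk_strategy` supplying every slot the grid leaves
#'   untouched.
#' @inheritParams evaluate_strategy
#' @return An `htpbk_grid_result`: list with `table` (ranked data.frame of
#'   label, slot values, metrics) and `results` (named list of
#'   `htpbk_strategy_result`).
#' @export
run_grid <- function(slot_options, dataset, compounds, base,
                     phys = reference_human(), blood_plasma_ratio = 1,
                     engine = engine_defaults(), loq = 0) {
  if (length(slot_options) == 0 || any(!lengths(slot_options)))
    stop("every grid slot must offer at least one option")
  combos <- expand.grid(slot_options, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  results <- list(); rows <- list()
  for (i in seq_len(nrow(combos))) {
    strat <- base
    for (slot in names(combos)) strat <- .apply_slot(strat, slot, combos[i, slot])
    strat$label <- paste(sprintf("%s=%s", names(combos), combos[i, ]),
                         collapse = "|")
    res <- evaluate_strategy(dataset, strat, compounds, phys,
                             blood_plasma_ratio, engine, loq)
    results[[strat$label]] <- res
    rows[[i]] <- cbind(data.frame(label = strat$label,
                                  stringsAsFactors = FALSE),
                       combos[i, , drop = FALSE],
                       data.frame(
                         median_absolute_log2 = res$median_absolute_log2,
                         median_relative_log2 = res$median_relative_log2,
                         n_failed = res$n_failed))
  }
  table <- do.call(rbind, rows)
  table <- table[order(table$median_absolute_log2, table$label), ,
                 drop = FALSE]
  rownames(table) <- NULL
  structure(list(table = table, results = results),
            class = "htpbk_grid_result")
}

#' @export
print.htpbk_grid_result <- function(x, ...) {
  cat(sprintf("<htpbk_grid_result> %d strategies\n", nrow(x$table)))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Three-step parameterisation evaluation workflow
#'
#' Step 1 evaluates the physico-chemical grid (lipophilicity source, pKa
#' source, partitioning method) on the IV dataset while clearance and Fu are
#' pinned to high-quality benchmark sources. Step 2 keeps the winning
#' physico-chemical choices and evaluates the Fu x clearance grid on the
#' same IV data. Step 3 keeps all previous winners and evaluates the
#' solubility x permeability grid on the PO data -- first on the
#' liquid-formulation subset (solution/suspension, no dissolution parameter
#' needed), then on the full PO dataset. The full strategy assembled from
#' the winners is returned.
#'
#' @param dataset_iv,dataset_po Lists of `htpbk_study` (IV and PO routes).
#' @param options List with elements `step1`, `step2`, `step3`: per-step
#'   `slot_options` as in [run_grid()].
#' @param benchmark List naming the step-1 benchmark sources:
#'   `fu_source` and `clearance` (encoded as in [run_grid()]).
#' @param base Base `htpbk_strategy` supplying untouched slots.
#' @inheritParams evaluate_strategy
#' @return List with `step1`, `step2`, `step3_liquid`, `step3_all`
#'   (`htpbk_grid_result`s) and `selected` (the winning `htpbk_strategy`).
#' @export
stepwise_workflow <- function(dataset_iv, dataset_po, options, base,
                              benchmark = list(fu_source = "measured",
                                               clearance = "in vivo/plasma"),
                              compounds, phys = reference_human(),
                              blood_plasma_ratio = 1,
                              engine = engine_defaults(), loq = 0) {
  if (length(dataset_iv) == 0 || length(dataset_po) == 0)
    stop("both IV and PO datasets are required")
  if (is.null(benchmark$fu_source) || is.null(benchmark$clearance))
    stop("step 1 requires benchmark fu and clearance sources")
  bench_base <- .apply_slot(.apply_slot(base, "fu_source",
                                        benchmark$fu_source),
                            "clearance", benchmark$clearance)
  step1 <- run_grid(options$step1, dataset_iv, compounds, bench_base, phys,
                    blood_plasma_ratio, engine, loq)
  best1 <- bench_base
  for (slot in names(options$step1))
    best1 <- .apply_slot(best1, slot, step1$table[1, slot])

  step2 <- run_grid(options$step2, dataset_iv, compounds, best1, phys,
                    blood_plasma_ratio, engine, loq)
  best2 <- best1
  for (slot in names(options$step2))
    best2 <- .apply_slot(best2, slot, step2$table[1, slot])

  liquid <- Filter(function(s)
    s$dosing$formulation %in% c("solution", "suspension"), dataset_po)
  step3_liquid <- if (length(liquid))
    run_grid(options$step3, liquid, compounds, best2, phys,
             blood_plasma_ratio, engine, loq) else NULL
  step3_all <- run_grid(options$step3, dataset_po, compounds, best2, phys,
                        blood_plasma_ratio, engine, loq)
  selected <- best2
  for (slot in names(options$step3))
    selected <- .apply_slot(selected, slot, step3_all$table[1, slot])
  selected$label <- "selected_full_strategy"
  list(step1 = step1, step2 = step2, step3_liquid = step3_liquid,
       step3_all = step3_all, selected = selected)
}
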