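# Synthetic ground truth: sampled compounds, emulated property-prediction
# tools with log-scale bias and noise, and multi-study IV/PO datasets whose
# observations come from the engine itself under the truth parameters.

#' Default synthetic study design
#'
#' Emulates the structure of a curated human PK dataset: several studies per
#' compound across IV and PO routes, four formulation labels, sparse
#' (8-14 point) log-spaced sampling over 24 h (IV) or 36 h (PO),
#' multiplicative log-normal observation noise (default CV 25%) and
#' inter-study variability expressed as a log-normal perturbation of subject
#' body weight.
#'
#' @param studies_per_compound Integer range to sample from.
#' @param routes Candidate routes.
#' @param obs_cv Observation coefficient of variation (multiplicative).
#' @param physiology_sd Log-scale SD of the per-study body-weight
#'   perturbation.
#' @param dose_range_mg Dose sampled log-uniformly from this range.
#' @param n_timepoints Range of sampling points per study.
#' @return A list of design settings.
#' @export
synthetic_design <- function(studies_per_compound = 1:6,
                             routes = c("iv", "po"),
                             obs_cv = 0.25, physiology_sd = 0.1,
                             dose_range_mg = c(10, 500),
                             n_timepoints = c(8, 14)) {
  list(studies_per_compound = studies_per_compound, routes = routes,
       obs_cv = obs_cv, physiology_sd = physiology_sd,
       dose_range_mg = dose_range_mg, n_timepoints = n_timepoints)
}

.runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Sample a ground-truth compound
#'
#' Draws one compound from the modelled chemical space: MW uniform on
#' \[150, 900\] g/mol, lipophilicity (LogD) normal(2, 1.5) truncated to
#' \[-3, 7\], Fu log-uniform on \[0.01, 1\], plasma clearance log-uniform on
#' \[0.5, 50\] L/h, hepatocyte CLint log-uniform on \[1, 100\]
#' ul/min/1e6 cells, aqueous solubility log-uniform on \[1, 1e4\] mg/L,
#' CACO2-type permeability log-uniform over three decades
#' (\[6e-5, 6e-2\] cm/min) and 0-2 pKa sites (acid or base, uniform on
#' \[3, 11\]). All records carry the source label `"truth"`.
#'
#' @param compound_id Label for the sampled compound.
#' @return An `htpbk_compound`.
#' @export
sample_compound <- function(compound_id) {
  mw <- runif(1, 150, 900)
  repeat {
    logd <- rnorm(1, 2, 1.5)
    if (logd >= -3 && logd <= 7) break
  }
  fu <- .runif_log(1, 0.01, 1)
  cl <- .runif_log(1, 0.5, 50)
  clint <- .runif_log(1, 1, 100)
  sol <- .runif_log(1, 1, 1e4)
  perm <- .runif_log(1, 6e-5, 6e-2)
  n_pka <- sample(0:2, 1)
  rec <- data.frame(
    property = c("lipophilicity", "fu", "clearance", "clearance",
                 "solubility", "permeability"),
    subtype = c("LogD", "fu", "plasma_CL", "hepatocyte_CLint",
                "aqueous", "CACO2"),
    value = c(logd, fu, cl, clint, sol, perm),
    source = "truth", stringsAsFactors = FALSE)
  if (n_pka > 0) {
    rec <- rbind(rec, data.frame(
      property = "pka",
      subtype = sample(c("acid", "base"), n_pka, replace = TRUE),
      value = runif(n_pka, 3, 11),
      source = "truth", stringsAsFactors = FALSE))
  }
  compound_properties(compound_id, mw, rec)
}

#' Emulate property-prediction tools
#'
#' For each emulated tool, predicted values are the truth perturbed on the
#' scale natural to the property: multiplicative `10^(bias + e)`,
#' `e ~ N(0, sd)`, for positive-scale properties (clearance, solubility,
#' permeability); additive `bias + e` for lipophilicity and pKa (already
#' log-scale); logit-scale perturbation clamped to \[0, 1\] for Fu. Records
#' are appended to each compound under the tool's source label.
#'
#' @param compounds Named list of truth `htpbk_compound`s.
#' @param tool_specs data.frame with columns `tool`, `property`, `bias`,
#'   `sd` (and optionally `subtype` to restrict the records emulated).
#' @return The compounds with emulated records appended.
#' @export
emulate_tool_predictions <- function(compounds, tool_specs) {
  tool_specs <- as.data.frame(tool_specs, stringsAsFactors = FALSE)
  if (nrow(tool_specs) == 0) stop("tool_specs must be non-empty")
  if (any(tool_specs$sd < 0)) stop("tool error SDs must be >= 0")
  for (id in names(compounds)) {
    cmp <- compounds[[id]]
    new <- list()
    for (j in seq_len(nrow(tool_specs))) {
      ts <- tool_specs[j, ]
      rec <- cmp$records[cmp$records$property == ts$property &
                           cmp$records$source == "truth", , drop = FALSE]
      if (!is.null(ts$subtype) && !is.na(ts$subtype))
        rec <- rec[rec$subtype == ts$subtype, , drop = FALSE]
      if (nrow(rec) == 0) next
      eps <- ts$bias + rnorm(nrow(rec), 0, ts$sd)
      rec$value <- if (ts$property %in% c("lipophilicity", "pka")) {
        rec$value + eps
      } else if (ts$property == "fu") {
        v <- pmin(pmax(rec$value, 1e-6), 1 - 1e-6)
        stats::plogis(stats::qlogis(v) + log(10) * eps)
      } else {
        rec$value * 10^eps
      }
      rec$source <- ts$tool
      new[[length(new) + 1]] <- rec
    }
    if (length(new))
      cmp$records <- rbind(cmp$records, do.call(rbind, new))
    compounds[[id]] <- cmp
  }
  compounds
}

# Truth strategy used to generate observations (and as the zero-error
# reference in closed-loop tests).
#' The strategy that reads every slot from the truth source
#'
#' @param partitioning_method Partitioning method used for the truth runs.
#' @param clearance_mode Clearance mode of the truth runs.
#' @return An `htpbk_strategy` whose every slot points at source "truth".
#' @export
truth_strategy <- function(partitioning_method = "rodgers_rowland",
                           clearance_mode = "plasma") {
  strategy("truth",
           lipophilicity_sources = "truth",
           pka_source = "truth",
           partitioning_method = partitioning_method,
           fu_source = "truth",
           clearance_source = "truth",
           clearance_mode = clearance_mode,
           solubility_source = "truth", solubility_subtype = "aqueous",
           permeability_source = "truth", permeability_subtype = "CACO2")
}

#' Generate a synthetic multi-study PK dataset
#'
#' Samples `n_compounds` ground-truth compounds, emulates the configured
#' prediction tools, and simulates 1-6 studies per compound: IV (bolus or
#' infusion) and PO (all four formulation labels) doses, log-spaced sparse
#' sampling, per-study physiology perturbation (log-normal body weight) and
#' multiplicative log-normal observation noise. Observations are engine
#' simulations under the truth parameters, so with zero noise the truth
#' strategy reproduces them exactly (closed loop).
#'
#' @param n_compounds Number of compounds (>= 1).
#' @param design See [synthetic_design()].
#' @param tool_specs Optional tool emulation table passed to
#'   [emulate_tool_predictions()].
#' @param seed Integer seed; recorded in the output.
#' @param phys Reference physiology.
#' @param truth_strat Strategy used to generate observations.
#' @return List with `studies` (list of `htpbk_study`), `compounds` (named
#'   list of `htpbk_compound` incl. emulated records), `truth` (data.frame
#'   of the sampled truth values) and `seed`.
#' @export
generate_dataset <- function(n_compounds, design = synthetic_design(),
                             tool_specs = NULL, seed = 1,
                             phys = reference_human(),
                             truth_strat = truth_strategy()) {
  if (n_compounds < 1) stop("n_compounds must be >= 1")
  if (design$obs_cv < 0 || design$physiology_sd < 0)
    stop("noise parameters must be >= 0")
  set.seed(seed)
  compounds <- list()
  for (i in seq_len(n_compounds)) {
    id <- sprintf("SYN%03d", i)
    compounds[[id]] <- sample_compound(id)
  }
  if (!is.null(tool_specs))
    compounds <- emulate_tool_predictions(compounds, tool_specs)
  sigma <- sqrt(log(1 + design$obs_cv^2))
  studies <- list(); k <- 0
  for (id in names(compounds)) {
    n_st <- if (length(design$studies_per_compound) > 1)
      sample(design$studies_per_compound, 1) else design$studies_per_compound
    for (s in seq_len(n_st)) {
      k <- k + 1
      route <- if (length(design$routes) > 1)
        sample(design$routes, 1) else design$routes
      dose <- .runif_log(1, design$dose_range_mg[1], design$dose_range_mg[2])
      if (route == "iv") {
        infusion <- runif(1) < 0.3
        dosing <- if (infusion)
          dosing_event("iv_infusion", dose, infusion_h = runif(1, 0.25, 2))
        else dosing_event("iv_bolus", dose)
        horizon <- 24
      } else {
        form <- sample(c("solution", "suspension", "capsule", "tablet"), 1)
        dosing <- dosing_event("oral", dose, formulation = form)
        horizon <- 36
      }
      npt <- sample(seq(design$n_timepoints[1], design$n_timepoints[2]), 1)
      times <- exp(seq(log(5 / 60), log(horizon), length.out = npt))
      weight <- phys$body_weight_kg *
        exp(rnorm(1, 0, design$physiology_sd))
      dem <- list(sex = "male", age = 30, weight = weight, height = 176)
      study_id <- sprintf("%s_S%02d_%s", id, s, route)
      shell <- study_record(study_id, id, dosing,
                            profile(times, rep(0, npt)), demographics = dem)
      sim <- simulate_study(shell, truth_strat, compounds, phys)
      conc <- sim$conc_mg_per_L * exp(rnorm(npt, 0, sigma))
      studies[[study_id]] <- study_record(
        study_id, id, dosing,
        profile(times, conc, compound_id = id, study_id = study_id),
        demographics = dem)
    }
  }
  truth <- do.call(rbind, lapply(compounds, function(cmp) {
    rec <- cmp$records[cmp$records$source == "truth", , drop = FALSE]
    cbind(data.frame(compound_id = cmp$compound_id, MW = cmp$MW), rec)
  }))
  rownames(truth) <- NULL
  list(studies = studies, compounds = compounds, truth = truth, seed = seed)
}
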