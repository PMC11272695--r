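# Whole-body simulation: dosing events, oral-absorption helpers and the
# simulate() front-end over the compiled integrator.

#' Engine defaults for oral absorption and integration
#'
#' Single well-mixed gut lumen with a fixed mean transit residence time,
#' fixed effective absorption area and fasted-state fluid volume; first-order
#' gastric emptying. These collapse a multi-segment intestine into one
#' compartment, which is known to overestimate the velocity of oral
#' absorption (early Tmax) -- an accepted bias.
#'
#' @param gastric_emptying_h Gastric emptying rate constant, 1/h.
#' @param transit_time_h Mean small-intestinal residence time, h.
#' @param absorption_area_cm2 Effective absorption area, cm^2.
#' @param lumen_volume_L Lumen fluid volume, L.
#' @param rtol,atol Integrator relative / absolute (mg) tolerances.
#' @return Named list of engine settings.
#' @export
engine_defaults <- function(gastric_emptying_h = 2.8, transit_time_h = 3.5,
                            absorption_area_cm2 = 6600, lumen_volume_L = 0.25,
                            rtol = 1e-8, atol = 1e-10) {
  list(gastric_emptying_h = gastric_emptying_h,
       transit_time_h = transit_time_h,
       absorption_area_cm2 = absorption_area_cm2,
       lumen_volume_L = lumen_volume_L, rtol = rtol, atol = atol)
}

#' Construct a dosing event
#'
#' @param route "iv_bolus", "iv_infusion" or "oral".
#' @param dose_mg Dose in mg, positive.
#' @param infusion_h Infusion duration (h), required (> 0) for iv_infusion.
#' @param formulation "solution", "suspension", "capsule" or "tablet"
#'   (oral only). Solutions and suspensions are treated as fully dissolved at
#'   administration.
#' @param t80_min 80% dissolution time (min) for solid formulations; when
#'   missing, the defaults are 25 min for capsules and 40 min for tablets.
#' @return An `htpbk_dosing` list.
#' @export
dosing_event <- function(route = c("iv_bolus", "iv_infusion", "oral"),
                         dose_mg, infusion_h = 0,
                         formulation = c("solution", "suspension", "capsule",
                                         "tablet"),
                         t80_min = NULL) {
  route <- match.arg(route)
  if (!is.numeric(dose_mg) || dose_mg < 0) stop("dose_mg must be >= 0")
  if (route == "iv_infusion" && (!is.numeric(infusion_h) || infusion_h <= 0))
    stop("iv_infusion requires infusion_h > 0")
  if (route != "iv_infusion") infusion_h <- 0
  formulation <- if (route == "oral") match.arg(formulation) else NA_character_
  if (identical(formulation, "capsule") && is.null(t80_min)) t80_min <- 25
  if (identical(formulation, "tablet") && is.null(t80_min)) t80_min <- 40
  if (route == "oral" && formulation %in% c("capsule", "tablet") &&
      (!is.numeric(t80_min) || t80_min <= 0))
    stop("solid formulations require a positive t80_min")
  structure(list(route = route, dose_mg = dose_mg, infusion_h = infusion_h,
                 formulation = formulation,
                 t80_min = if (route == "oral" &&
                               formulation %in% c("capsule", "tablet"))
                   t80_min else NA_real_),
            class = "htpbk_dosing")
}

#' Dissolved fraction of a formulation over time
#'
#' Solutions and suspensions are fully dissolved at administration. Solid
#' formulations follow a piecewise-linear profile reaching 80% at the
#' formulation's 80% dissolution time `t80` and 100% at `1.25 * t80`,
#' monotone non-decreasing.
#'
#' @param formulation Formulation label.
#' @param t80_min 80% dissolution time, minutes (solids).
#' @param t_min Time since administration, minutes (vectorised).
#' @return Dissolved fraction in \[0, 1\].
#' @examples
#' dissolved_fraction("capsule", 25, 25)  # 0.80
#' @export
dissolved_fraction <- function(formulation, t80_min, t_min) {
  stopifnot(all(t_min >= 0))
  if (formulation %in% c("solution", "suspension"))
    return(rep(1, length(t_min)))
  if (!formulation %in% c("capsule", "tablet"))
    stop("unknown formulation: ", formulation)
  if (!is.numeric(t80_min) || t80_min <= 0)
    stop("solid formulations require t80_min > 0")
  ifelse(t_min < t80_min, 0.8 * t_min / t80_min,
         pmin(1, 0.8 + 0.2 * (t_min - t80_min) / (0.25 * t80_min)))
}

#' Scaling factor from predicted to engine-optimal permeabilities
#'
#' Given paired predicted and target (engine-optimal) permeabilities, the
#' factor `10^(mean(log10 target - log10 predicted))` minimises the mean
#' log10 ratio; applying it to the predictions centres them on the targets.
#'
#' @param predicted,target Positive paired permeability values, >= 3 pairs.
#' @return A positive scalar factor.
#' @export
caco2_scaling_factor <- function(predicted, target) {
  if (length(predicted) != length(target) || length(predicted) < 3)
    stop("need >= 3 paired values")
  if (any(predicted <= 0) || any(target <= 0))
    stop("permeability values must be positive")
  10^mean(log10(target) - log10(predicted))
}

#' Engine-internal permeability surrogate
#'
#' The engine's internal intestinal-permeability prediction is driven by
#' molecular weight and membrane-affinity lipophilicity:
#' `a * 10^(b * logMA) * MW^c`. The exact published coefficients are not
#' available, so the defaults are a calibrated surrogate (see the methods
#' vignette); all three coefficients are configurable.
#'
#' @param MW Molecular weight, g/mol.
#' @param logMA Membrane-affinity lipophilicity.
#' @param coeffs List with `a`, `b`, `c`.
#' @return Permeability in cm/min, positive.
#' @export
engine_permeability <- function(MW, logMA,
                                coeffs = list(a = 2.8e6, b = 1, c = -4.5)) {
  if (is.null(coeffs$a) || is.null(coeffs$b) || is.null(coeffs$c))
    stop("coeffs must supply a, b and c")
  coeffs$a * 10^(coeffs$b * logMA) * MW^coeffs$c
}

#' Assemble a simulation specification
#'
#' @param params An `htpbk_parameters` (resolved compound inputs).
#' @param partition An `htpbk_partition_set`.
#' @param clearance An `htpbk_clearance`.
#' @param phys An `htpbk_physiology`.
#' @param dosing An `htpbk_dosing`.
#' @param output_times Simulation output times, h (need not include 0).
#' @param blood_plasma_ratio Scalar blood:plasma ratio (default 1).
#' @param engine Engine settings, see [engine_defaults()].
#' @return An `htpbk_simspec` list.
#' @export
simulation_spec <- function(params, partition, clearance, phys, dosing,
                            output_times, blood_plasma_ratio = 1,
                            engine = engine_defaults()) {
  stopifnot(inherits(partition, "htpbk_partition_set"),
            inherits(clearance, "htpbk_clearance"),
            inherits(dosing, "htpbk_dosing"))
  if (any(output_times < 0)) stop("output_times must be >= 0")
  structure(list(params = params, partition = partition,
                 clearance = clearance, phys = phys, dosing = dosing,
                 output_times = sort(unique(as.numeric(output_times))),
                 blood_plasma_ratio = blood_plasma_ratio, engine = engine),
            class = "htpbk_simspec")
}

# Effective absorption permeability (cm/min) for the PO route.
.effective_permeability <- function(params, engine_coeffs = NULL) {
  perm <- params$permeability
  if (is.null(perm)) stop("PO simulation without a resolved permeability")
  if (identical(perm$scaling, "engine_equation")) {
    lip <- params$lipophilicity
    val <- if (is.null(engine_coeffs))
      engine_permeability(params$MW, lip$value)
    else engine_permeability(params$MW, lip$value, engine_coeffs)
    return(val)
  }
  val <- perm$value
  if (identical(perm$scaling, "scaled")) val <- val * perm$factor
  val
}

#' Simulate a concentration-time profile
#'
#' Integrates the whole-body flow-limited system: per organ
#' `dA/dt = Q * (C_art - C_tissue / (Kp/BP))`, venous pooling, the lung
#' between venous and arterial blood, gut and spleen draining through the
#' liver. Hepatic elimination in intrinsic mode acts on the unbound liver
#' concentration (`CLint_liver * fu * C_liver / Kp_liver`); plasma-mode and
#' renal elimination act on the venous plasma concentration. Oral doses pass
#' from the stomach to a single gut lumen, dissolve according to the
#' formulation profile with the dissolved concentration capped at the
#' compound's solubility, are absorbed into the liver inflow at a rate
#' proportional to permeability, absorption area and dissolved lumen
#' concentration, and leave the lumen by intestinal transit.
#'
#' @param spec An `htpbk_simspec`.
#' @return An `htpbk_profile` of venous plasma concentrations (mg/L) at the
#'   requested output times, with attributes `auc_mg_h_L` (integrated AUC at
#'   the last output time), `mass_balance_error` (maximum relative deviation
#'   of compartment totals + eliminated from the administered dose) and
#'   `states` (matrix of all compartment amounts at the output times).
#' @export
simulate_profile <- function(spec) {
  stopifnot(inherits(spec, "htpbk_simspec"))
  phys <- spec$phys
  org <- phys$organs
  kp <- c(1, 1, spec$partition$kp[org$name[-(1:2)]])
  if (anyNA(kp)) stop("partition set lacks organs: ",
                      paste(org$name[-(1:2)][is.na(kp[-(1:2)])], collapse = ", "))
  bp <- spec$blood_plasma_ratio
  dosing <- spec$dosing
  eng <- spec$engine
  oral <- dosing$route == "oral"
  solid <- oral && dosing$formulation %in% c("capsule", "tablet")
  ka <- 0; solub <- 0
  if (oral) {
    perm_cm_min <- .effective_permeability(spec$params)
    ka <- perm_cm_min * 60 * eng$absorption_area_cm2 /
      (eng$lumen_volume_L * 1000)
    solub <- spec$params$solubility %||% 0
    if (is.null(spec$params$solubility))
      stop("PO simulation without a resolved solubility")
  }
  t80_h <- if (solid) dosing$t80_min / 60 else 0
  pars <- list(
    V = org$volume_L, Q = org$flow_L_h, Kpb = kp / bp,
    Kp_liver = unname(kp[org$name == "liver"]), BP = bp,
    fu = spec$params$fu %||% 1,
    cl_plasma = spec$clearance$plasma_CL_L_h,
    cl_int = spec$clearance$intrinsic_liver_CL_L_h,
    cl_renal = spec$clearance$renal_CL_L_h,
    inf_rate = if (dosing$route == "iv_infusion")
      dosing$dose_mg / dosing$infusion_h else 0,
    inf_dur = dosing$infusion_h,
    oral = oral, dose_oral = if (oral) dosing$dose_mg else 0,
    kge = eng$gastric_emptying_h, kt = 1 / eng$transit_time_h, ka = ka,
    V_lumen = eng$lumen_volume_L, solub = solub, solid = solid, t80 = t80_h
  )
  y0 <- numeric(21)
  if (dosing$route == "iv_bolus") y0[1] <- dosing$dose_mg
  if (oral) { if (solid) y0[15] <- dosing$dose_mg else y0[16] <- dosing$dose_mg }
  times <- spec$output_times
  breaks <- c(if (dosing$route == "iv_infusion") dosing$infusion_h,
              if (solid) c(t80_h, 1.25 * t80_h))
  states <- .pbk_integrate(y0, pars, times, eng$rtol, eng$atol,
                           as.numeric(breaks %||% numeric(0)))
  colnames(states) <- c(org$name, "stomach_undissolved", "stomach_dissolved",
                        "lumen_undissolved", "lumen_dissolved", "transited",
                        "eliminated", "auc")
  vven <- org$volume_L[org$name == "venous_blood"]
  conc <- pmax(states[, "venous_blood"] / vven / bp, 0)
  administered <- switch(dosing$route,
    iv_bolus = rep(dosing$dose_mg, length(times)),
    oral = rep(dosing$dose_mg, length(times)),
    iv_infusion = dosing$dose_mg * pmin(times, dosing$infusion_h) /
      dosing$infusion_h)
  total <- rowSums(states[, 1:20, drop = FALSE])  # compartments + eliminated
  mbe <- if (dosing$dose_mg > 0)
    max(abs(total - administered) / dosing$dose_mg) else 0
  if (any(states[, 1:19] < -1e-6 * max(dosing$dose_mg, 1)))
    stop("integrator produced a negative state beyond tolerance")
  prof <- profile(times, conc,
                  compound_id = spec$params$compound_id %||% NA_character_)
  attr(prof, "auc_mg_h_L") <- unname(states[nrow(states), "auc"])
  attr(prof, "mass_balance_error") <- mbe
  attr(prof, "states") <- states
  prof
}
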