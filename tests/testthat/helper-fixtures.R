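# Shared fixtures: all built in code, no stored data.

ref_phys <- reference_human()

organ_names <- function(phys = ref_phys)
  setdiff(phys$organs$name, c("venous_blood", "arterial_blood"))

# A partition set with one fixed Kp everywhere (bypasses the methods).
manual_kp <- function(value = 1, phys = ref_phys)
  structure(list(method = "manual",
                 kp = setNames(rep(value, length(organ_names(phys))),
                               organ_names(phys))),
            class = "htpbk_partition_set")

manual_clearance <- function(plasma = 0, intrinsic = 0, renal = 0)
  structure(list(mode = if (intrinsic > 0 || (plasma == 0 && renal > 0))
                   "intrinsic" else "plasma",
                 plasma_CL_L_h = plasma, intrinsic_liver_CL_L_h = intrinsic,
                 renal_CL_L_h = renal),
            class = "htpbk_clearance")

basic_params <- function(fu = 0.5, logd = 2, mw = 300, solubility = NULL,
                         permeability = NULL) {
  perm <- if (!is.null(permeability))
    list(value = permeability, subtype = "CACO2", scaling = "direct",
         factor = 1)
  list(compound_id = "FIX", MW = mw, fu = fu,
       lipophilicity = list(value = logd, subtype = "LogD"),
       pka = data.frame(value = numeric(0), type = character(0)),
       solubility = solubility, clearance = NULL, permeability = perm)
}

# A small in-code property table for resolver tests.
fixture_compound <- function(id = "CPD1") {
  compound_properties(id, MW = 350, records = data.frame(
    property = c("lipophilicity", "lipophilicity", "lipophilicity",
                 "pka", "pka", "fu", "fu", "solubility", "clearance",
                 "clearance", "permeability"),
    subtype = c("LogD", "LogMA", "LogP", "base", "acid", "fu", "fu",
                "aqueous", "plasma_CL", "hepatocyte_CLint", "CACO2"),
    value = c(2.1, 2.7, 3.2, 8.5, 4.2, 0.25, 0.31, 120, 12, 8, 2e-3),
    source = c("BayerLogD", "BayerLogMA", "OCHEM", "ChemAxon", "ChemAxon",
               "measured", "ADMETLab", "SimPlus", "in vivo", "httk",
               "ADMETLab"),
    unit = NA_character_, stringsAsFactors = FALSE))
}

fixture_strategy <- function(...) {
  args <- modifyList(list(
    label = "fixture",
    lipophilicity_sources = "BayerLogD",
    pka_source = "ChemAxon",
    partitioning_method = "rodgers_rowland",
    fu_source = "measured",
    clearance_source = "in vivo",
    clearance_mode = "plasma",
    solubility_source = "SimPlus", solubility_subtype = "aqueous",
    permeability_source = "ADMETLab", permeability_subtype = "CACO2"
  ), list(...))
  do.call(strategy, args)
}

# Random but reproducible simulation spec; used by the property batteries.
random_simspec <- function(i, horizon = NULL) {
  set.seed(1000 + i)
  cmp <- sample_compound(sprintf("RND%03d", i))
  strat <- truth_strategy(
    partitioning_method = sample(c("pksim_standard", "schmitt",
                                   "rodgers_rowland", "poulin_theil",
                                   "berezhkovskiy"), 1))
  route <- sample(c("iv_bolus", "iv_infusion", "oral"), 1)
  dose <- exp(runif(1, log(5), log(500)))
  dosing <- switch(route,
    iv_bolus = dosing_event("iv_bolus", dose),
    iv_infusion = dosing_event("iv_infusion", dose,
                               infusion_h = runif(1, 0.25, 2)),
    oral = dosing_event("oral", dose,
                        formulation = sample(c("solution", "suspension",
                                               "capsule", "tablet"), 1)))
  params <- resolve_inputs(cmp, strat,
                           if (route == "oral") "po" else "iv")
  part <- compute_partition_set(strat$partitioning_method, params, ref_phys)
  clear <- assemble_clearance(strat, params, ref_phys)
  horizon <- horizon %||% if (route == "oral") 36 else 24
  times <- exp(seq(log(5 / 60), log(horizon), length.out = 11))
  simulation_spec(params, part, clear, ref_phys, dosing, times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
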