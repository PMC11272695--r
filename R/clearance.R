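# Elimination specification: IVIVE scaling of hepatocyte intrinsic clearance,
# plasma-clearance mode and the passive-renal on/off rule.

#' Scale hepatocyte intrinsic clearance to whole-liver clearance
#'
#' In vivo intrinsic liver clearance (ul/min) equals
#' `CLint (ul/min/1e6 cells) x hepatocellularity (cells/g) x liver density
#' (g/ml) x liver volume (ml)`, converted here to L/h. Hepatocellularity and
#' liver density come from the physiology (defaults 1.1e8 cells/g and
#' 1.05 g/ml).
#'
#' @param clint Intrinsic clearance, ul/min/1e6 cells, non-negative.
#' @param phys An `htpbk_physiology`.
#' @return Whole-liver intrinsic clearance in L/h.
#' @examples
#' # 1 ul/min/1e6 cells in a 1 L liver: 110 * 1.05 * 1000 ul/min = 6.93 L/h
#' @export
scale_clint_to_liver <- function(clint, phys) {
  if (!is.numeric(clint) || clint < 0)
    stop("clint must be a non-negative number (ul/min/1e6 cells)")
  liver_ml <- phys$organs$volume_L[phys$organs$name == "liver"] * 1000
  ul_min <- clint * (phys$hepatocellularity_cells_g / 1e6) *
    phys$liver_density_g_ml * liver_ml
  ul_min * 60 / 1e6  # ul/min -> L/h
}

#' Passive renal clearance from glomerular filtration
#'
#' Only the unbound fraction is filtered: renal clearance = GFR x Fu.
#'
#' @param fu Fraction unbound in plasma, in \[0, 1\].
#' @param phys An `htpbk_physiology`.
#' @return Renal clearance in L/h.
#' @export
renal_passive_clearance <- function(fu, phys) {
  if (!is.numeric(fu) || fu < 0 || fu > 1)
    stop("fu must lie in [0, 1]")
  phys$GFR_L_h * fu
}

#' Assemble the engine's clearance specification
#'
#' In plasma mode the whole-body plasma clearance carries all systemic
#' elimination, so passive renal clearance is never added on top (a request
#' to do so is ignored with a warning). In intrinsic mode the hepatocyte
#' CLint is scaled to the liver via [scale_clint_to_liver()] and passive
#' renal clearance (GFR x Fu) is added when the strategy asks for it.
#' Plasma clearance declared per kilogram (`unit = "L/h/kg"`) is scaled by
#' the subject body weight.
#'
#' @param strat An `htpbk_strategy` (supplies mode and the renal flag).
#' @param params An `htpbk_parameters` from [resolve_inputs()].
#' @param phys An `htpbk_physiology`.
#' @return An `htpbk_clearance` list: `mode`, `plasma_CL_L_h`,
#'   `intrinsic_liver_CL_L_h`, `renal_CL_L_h`.
#' @export
assemble_clearance <- function(strat, params, phys) {
  cl <- params$clearance
  if (is.null(cl)) stop(params$compound_id, ": no clearance record resolved")
  if (cl$mode == "plasma") {
    value <- cl$value
    if (!is.na(cl$unit) && identical(cl$unit, "L/h/kg"))
      value <- value * phys$body_weight_kg
    if (isTRUE(strat$renal_passive))
      warning("renal_passive ignored in plasma-clearance mode: plasma ",
              "clearance already represents all systemic elimination")
    spec <- list(mode = "plasma", plasma_CL_L_h = value,
                 intrinsic_liver_CL_L_h = 0, renal_CL_L_h = 0)
  } else {
    spec <- list(mode = "intrinsic", plasma_CL_L_h = 0,
                 intrinsic_liver_CL_L_h = scale_clint_to_liver(cl$value, phys),
                 renal_CL_L_h = if (isTRUE(strat$renal_passive))
                   renal_passive_clearance(params$fu, phys) else 0)
  }
  structure(spec, class = "htpbk_clearance")
}
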