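#' @useDynLib htpbk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median rnorm runif setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Organ labels used throughout the engine. Blood compartments come first,
# lung sits between venous and arterial blood, gut and spleen drain into the
# liver (portal vein). "rest" lumps all remaining perfused tissue.
.htpbk_organs <- c("venous_blood", "arterial_blood", "lung", "liver", "kidney",
                   "gut", "spleen", "muscle", "adipose", "skin", "brain",
                   "heart", "bone", "rest")

.htpbk_portal <- c("gut", "spleen")

#' Reference adult-male human physiology
#'
#' Returns the whole-body physiology used by every simulation: 12 perfused
#' tissues plus arterial and venous blood, glomerular filtration rate,
#' hepatocellularity and liver density. Volumes and blood flows are compiled
#' reference-man style values for a healthy 73 kg adult male (cardiac output
#' 390 L/h); tissue composition fractions are merged in from the shipped
#' composition table. Hepatocellularity is fixed at 1.1e8 cells/g and liver
#' density at 1.05 g/ml, the constants used for intrinsic-clearance scaling.
#'
#' @return An object of class `htpbk_physiology`: a list with elements
#'   `organs` (data.frame of name, volume_L, flow_L_h, composition fractions
#'   and an `eliminating` flag), `GFR_L_h`, `hepatocellularity_cells_g`,
#'   `liver_density_g_ml`, `body_weight_kg` and `demographics`.
#' @examples
#' phys <- reference_human()
#' phys$hepatocellularity_cells_g  # 1.1e8
#' @export
reference_human <- function() {
  organs <- data.frame(
    name = .htpbk_organs,
    volume_L = c(3.9, 1.7, 0.5, 1.8, 0.31, 1.1, 0.15, 29, 13.5, 3.3,
                 1.45, 0.33, 10.3, 2.5),
    # flow_L_h: lung carries total cardiac output; liver value is the hepatic
    # artery only (portal inflow comes from gut + spleen); blood pools 0.
    flow_L_h = c(0, 0, 390, 25.35, 74.1, 58.5, 11.7, 66.3, 19.5, 19.5,
                 46.8, 15.6, 19.5, 33.15),
    eliminating = .htpbk_organs %in% c("liver", "kidney"),
    stringsAsFactors = FALSE
  )
  comp <- tissue_composition()
  idx <- match(ifelse(organs$name %in% c("venous_blood", "arterial_blood"),
                      "plasma", organs$name), comp$tissue)
  organs$f_water <- comp$f_ew[idx] + comp$f_iw[idx]
  organs$f_neutral_lipid <- comp$f_nl[idx]
  organs$f_phospholipid <- comp$f_np[idx]
  organs$f_protein <- comp$f_protein[idx]
  organs$f_acidic_phospholipid <- comp$ap_mg_g[idx] / 1000
  phys <- structure(list(
    organs = organs,
    GFR_L_h = 7.2,
    hepatocellularity_cells_g = 1.1e8,
    liver_density_g_ml = 1.05,
    body_weight_kg = 73,
    demographics = list(sex = "male", age = 30, weight = 73, height = 176)
  ), class = "htpbk_physiology")
  validate_physiology(phys)
  phys
}

#' Validate a physiology object
#'
#' Checks positivity of volumes and flows, composition fractions in \[0, 1\]
#' with sums not exceeding 1, and the flow-balance invariant (cardiac output
#' through the lung equals the sum of systemic organ flows to 1e-9 relative).
#'
#' @param phys An `htpbk_physiology` object.
#' @return `phys`, invisibly; errors on violation.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "htpbk_physiology"))
  org <- phys$organs
  if (!identical(org$name, .htpbk_organs))
    stop("physiology must contain the fixed organ set in canonical order")
  if (any(org$volume_L <= 0)) stop("organ volumes must be positive")
  perfused <- !(org$name %in% c("venous_blood", "arterial_blood"))
  if (any(org$flow_L_h[perfused] <= 0))
    stop("perfused organ blood flows must be positive")
  fr <- org[, c("f_water", "f_neutral_lipid", "f_phospholipid", "f_protein",
                "f_acidic_phospholipid")]
  if (any(fr < 0 | fr > 1)) stop("composition fractions must lie in [0, 1]")
  if (any(rowSums(fr) > 1 + 1e-9)) stop("composition fractions must sum to <= 1")
  co <- org$flow_L_h[org$name == "lung"]
  systemic <- sum(org$flow_L_h[perfused & org$name != "lung"])
  if (abs(co - systemic) > 1e-9 * co)
    stop("flow balance violated: cardiac output != sum of systemic flows")
  for (f in c("GFR_L_h", "hepatocellularity_cells_g", "liver_density_g_ml",
              "body_weight_kg"))
    if (!is.numeric(phys[[f]]) || phys[[f]] <= 0)
      stop(sprintf("%s must be strictly positive", f))
  invisible(phys)
}

#' Scale a physiology to subject demographics
#'
#' Missing demographics leave the physiology unchanged. When a body weight is
#' given, organ volumes scale linearly with weight while blood flows and GFR
#' scale allometrically with exponent 0.75. Sex, age and height do not alter
#' the organ table (no alternative reference table is shipped); they are
#' recorded in the demographics slot.
#'
#' @param phys An `htpbk_physiology` object.
#' @param sex,age,weight,height Optional demographics (label, years, kg, cm).
#' @return A scaled `htpbk_physiology` object.
#' @examples
#' ref <- reference_human()
#' big <- scale_physiology(ref, weight = 2 * ref$body_weight_kg)
#' big$organs$volume_L[1] / ref$organs$volume_L[1]  # 2
#' @export
scale_physiology <- function(phys, sex = NULL, age = NULL, weight = NULL,
                             height = NULL) {
  validate_physiology(phys)
  if (!is.null(weight) && (!is.numeric(weight) || weight <= 0))
    stop("weight must be a positive number (kg)")
  if (!is.null(height) && (!is.numeric(height) || height <= 0))
    stop("height must be a positive number (cm)")
  out <- phys
  if (!is.null(sex)) out$demographics$sex <- sex
  if (!is.null(age)) out$demographics$age <- age
  if (!is.null(height)) out$demographics$height <- height
  if (!is.null(weight)) {
    r <- weight / phys$body_weight_kg
    out$organs$volume_L <- phys$organs$volume_L * r
    out$organs$flow_L_h <- phys$organs$flow_L_h * r^0.75
    out$GFR_L_h <- phys$GFR_L_h * r^0.75
    out$body_weight_kg <- weight
    out$demographics$weight <- weight
  }
  validate_physiology(out)
  out
}

#' Tissue composition table
#'
#' Fractional tissue composition (extracellular/intracellular water, neutral
#' lipid, neutral phospholipid, acidic phospholipid in mg/g, tissue:plasma
#' albumin and lipoprotein ratios, total protein) for the organs of the
#' whole-body model plus plasma, compiled from the partitioning-method
#' literature. Shipped as package data; values are implementer-compiled
#' approximations of the published tables.
#'
#' @return A data.frame with one row per tissue.
#' @export
tissue_composition <- function() {
  path <- system.file("extdata", "tissue_composition.csv", package = "htpbk",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise / deserialise a physiology as JSON
#'
#' @param phys An `htpbk_physiology` object.
#' @param path File path to write to / read from.
#' @return `write_physiology` returns `path` invisibly; `read_physiology`
#'   returns an `htpbk_physiology`.
#' @export
write_physiology <- function(phys, path) {
  validate_physiology(phys)
  jsonlite::write_json(unclass(phys), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$organs <- as.data.frame(x$organs, stringsAsFactors = FALSE)
  phys <- structure(x, class = "htpbk_physiology")
  validate_physiology(phys)
  phys
}

#' @export
print.htpbk_physiology <- function(x, ...) {
  cat(sprintf("<htpbk_physiology> %s, %g kg, CO %.0f L/h, GFR %.2f L/h\n",
              x$demographics$sex, x$body_weight_kg,
              x$organs$flow_L_h[x$organs$name == "lung"], x$GFR_L_h))
  print(x$organs[, c("name", "volume_L", "flow_L_h")], row.names = FALSE)
  invisible(x)
}
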