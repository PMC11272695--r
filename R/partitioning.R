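# Tissue:plasma partition coefficients.
#
# Five method families, all operating on the shipped tissue-composition table:
#   poulin_theil / berezhkovskiy  - lipid/water composition partitioning with
#     plasma- and tissue-protein binding; Berezhkovskiy corrects the
#     protein-association constant derived from plasma Fu by removing the
#     plasma-lipid partitioning contribution, which bounds Kp growth at very
#     high lipophilicity.
#   rodgers_rowland - ionisation-aware: strong bases bind acidic
#     phospholipids (intracellular pH 7.0), acids/neutrals/weak bases bind
#     albumin/lipoprotein.
#   schmitt / pksim_standard - membrane-affinity driven: a lipophilicity
#     value (ideally LogMA) sets the membrane partition coefficient; Schmitt
#     adds ionisation attenuation and cation-acidic-phospholipid affinity.
#
# Whatever lipophilicity subtype the strategy resolved is fed to each method
# as-is; conversions only happen when the strategy configures one.

.htpbk_rbc <- list(f_w = 0.63, f_nl = 0.0017, f_np = 0.0029,
                   ap_mg_g = 0.5, pH = 7.22, hct = 0.45)

#' Neutral fraction of a compound at a given pH
#'
#' Henderson-Hasselbalch: the neutral fraction is
#' `1 / (1 + sum of ionisation terms)` with `10^(pKa - pH)` per basic site
#' and `10^(pH - pKa)` per acidic site. An empty pKa set gives 1 (neutral
#' compound).
#'
#' @param pka data.frame with columns `value` and `type` ("acid"/"base"),
#'   possibly empty.
#' @param pH The pH (plasma 7.4, intracellular 7.0).
#' @return Neutral fraction in (0, 1].
#' @examples
#' fraction_neutral(data.frame(value = 7.4, type = "acid"), 7.4)  # 0.5
#' @export
fraction_neutral <- function(pka, pH = 7.4) {
  if (is.null(pka) || nrow(pka) == 0) return(1)
  stopifnot(all(pka$type %in% c("acid", "base")), all(is.finite(pka$value)))
  terms <- ifelse(pka$type == "base", 10^(pka$value - pH), 10^(pH - pka$value))
  1 / (1 + sum(terms))
}

.ion_factor <- function(pka, pH) 1 / fraction_neutral(pka, pH)  # 1 + sum(terms)

#' Tissue:plasma partition coefficients for one parameter set
#'
#' Computes one Kp per perfused organ of the whole-body model under the named
#' method. All methods consume the resolved lipophilicity (used as-is,
#' whatever its subtype), the plasma fraction unbound and, where the method
#' uses them, the pKa set and the blood:plasma ratio.
#'
#' @param method One of "pksim_standard", "schmitt", "rodgers_rowland",
#'   "poulin_theil", "berezhkovskiy".
#' @param params An `htpbk_parameters` object (see [resolve_inputs()]), or any
#'   list with `lipophilicity` (list value/subtype), `fu` and `pka`.
#' @param phys An `htpbk_physiology`.
#' @param blood_plasma_ratio Scalar blood:plasma concentration ratio
#'   (default 1).
#' @param composition Override tissue-composition table (for testing); one
#'   row per organ plus a "plasma" row, columns as in [tissue_composition()].
#' @return An `htpbk_partition_set`: list with `method` and `kp`, a named
#'   vector of positive finite tissue:plasma ratios for every perfused organ.
#' @export
compute_partition_set <- function(method, params, phys,
                                  blood_plasma_ratio = 1,
                                  composition = NULL) {
  methods <- c("pksim_standard", "schmitt", "rodgers_rowland",
               "poulin_theil", "berezhkovskiy")
  if (!method %in% methods) stop("unknown partitioning method: ", method)
  if (is.null(params$lipophilicity) || !is.finite(params$lipophilicity$value))
    stop(method, ": lipophilicity input is required")
  if (is.null(params$fu) || !is.finite(params$fu))
    stop(method, ": fraction unbound input is required")
  fu <- min(max(params$fu, 1e-6), 1)
  pka <- params$pka %||% data.frame(value = numeric(0), type = character(0))
  comp <- composition %||% tissue_composition()
  organs <- setdiff(phys$organs$name[!(phys$organs$name %in%
                      c("venous_blood", "arterial_blood"))], character(0))
  tissues <- comp[match(organs, comp$tissue), , drop = FALSE]
  if (anyNA(tissues$tissue))
    stop("composition table lacks rows for: ",
         paste(organs[is.na(tissues$tissue)], collapse = ", "))
  plasma <- comp[comp$tissue == "plasma", , drop = FALSE]
  if (nrow(plasma) != 1) stop("composition table must contain a plasma row")

  lip <- params$lipophilicity$value
  P <- 10^lip
  kp <- switch(method,
    poulin_theil  = .kp_poulin(tissues, plasma, P, fu, pka, corrected = FALSE),
    berezhkovskiy = .kp_poulin(tissues, plasma, P, fu, pka, corrected = TRUE),
    rodgers_rowland = .kp_rodgers(tissues, plasma, P, fu, pka,
                                  blood_plasma_ratio),
    schmitt       = .kp_membrane(tissues, P, fu, pka, ionise = TRUE),
    pksim_standard = .kp_membrane(tissues, P, fu, pka, ionise = FALSE)
  )
  names(kp) <- organs
  if (any(!is.finite(kp) | kp <= 0))
    stop(method, ": non-finite or non-positive Kp computed")
  structure(list(method = method, kp = kp), class = "htpbk_partition_set")
}

# Poulin & Theil style composition partitioning. The octanol partition
# coefficient carries lipid affinity; for adipose the distribution coefficient
# at pH 7.4 (neutral species only) is used and tissue binding is neglected.
# fu_t derives from plasma binding scaled by the tissue:plasma albumin ratio;
# the Berezhkovskiy variant subtracts the plasma-lipid term from the measured
# binding before scaling (clamped at zero).
.kp_poulin <- function(tissues, plasma, P, fu, pka, corrected) {
  fn <- fraction_neutral(pka, 7.4)
  X <- function(row, Puse)
    Puse * (row$f_nl + 0.3 * row$f_np) + (row$f_ew + row$f_iw + 0.7 * row$f_np)
  Xp  <- X(plasma, P)
  assoc <- if (corrected) pmax(0, 1 / fu - Xp) else (1 - fu) / fu
  kp <- numeric(nrow(tissues))
  for (i in seq_len(nrow(tissues))) {
    row <- tissues[i, ]
    if (row$tissue == "adipose") {
      D <- P * fn  # distribution coefficient at plasma pH
      kp[i] <- X(row, D) / X(plasma, D) * fu
    } else {
      fu_t <- 1 / (1 + row$alb_ratio * assoc)
      kp[i] <- X(row, P) / Xp * fu / fu_t
    }
  }
  kp
}

# Rodgers & Rowland. Moderate-to-strong bases (basic pKa >= 7) partition into
# acidic phospholipids with an association constant back-calculated from
# blood-cell partitioning; other classes bind albumin (acids, neutrals) or
# lipoprotein (weak bases). Intracellular pH 7.0, plasma 7.4, RBC 7.22.
.kp_rodgers <- function(tissues, plasma, P, fu, pka, bp) {
  base_pka <- pka$value[pka$type == "base"]
  strong_base <- length(base_pka) > 0 && max(base_pka) >= 7
  lipid <- function(row) P * row$f_nl + (0.3 * P + 0.7) * row$f_np
  if (strong_base) {
    pKa <- max(base_pka)
    Yp  <- 1 + 10^(pKa - 7.4)
    Yiw <- 1 + 10^(pKa - 7.0)
    rbc <- .htpbk_rbc
    Ybc <- 1 + 10^(pKa - rbc$pH)
    hct <- rbc$hct
    kpu_bc <- (bp - (1 - hct)) / hct / fu
    ka_ap <- (kpu_bc - rbc$f_w * Ybc / Yp -
                (P * rbc$f_nl + (0.3 * P + 0.7) * rbc$f_np) / Yp) /
             (rbc$ap_mg_g * (Ybc - 1) / Yp)
    ka_ap <- max(ka_ap, 0)
    kpu <- vapply(seq_len(nrow(tissues)), function(i) {
      row <- tissues[i, ]
      row$f_ew + (Yiw / Yp) * row$f_iw +
        ka_ap * row$ap_mg_g * (Yiw - 1) / Yp + lipid(row) / Yp
    }, numeric(1))
  } else {
    Zp  <- .ion_factor(pka, 7.4)
    Ziw <- .ion_factor(pka, 7.0)
    prot_assoc <- max(0, 1 / fu - 1 - lipid(plasma) / Zp)
    is_acid_or_neutral <- nrow(pka) == 0 || any(pka$type == "acid")
    kpu <- vapply(seq_len(nrow(tissues)), function(i) {
      row <- tissues[i, ]
      ratio <- if (is_acid_or_neutral) row$alb_ratio else row$lip_ratio
      row$f_ew + (Ziw / Zp) * row$f_iw + lipid(row) / Zp + ratio * prot_assoc
    }, numeric(1))
  }
  kpu * fu
}

# Membrane-affinity family. The lipophilicity value sets the membrane
# partition coefficient K = 10^lip (LogMA when the strategy supplies one).
# Tissue affinity per ml = water + K*lipids + Kprot*protein with the
# empirical protein affinity Kprot = 0.163 + 0.0221*K; plasma side is 1/fu.
# Schmitt additionally attenuates K for the ionised fraction (factor 0.05)
# and gives cations a 20-fold acidic-phospholipid affinity.
.kp_membrane <- function(tissues, P, fu, pka, ionise) {
  K <- P
  ap_mult <- 1
  if (ionise) {
    fn <- fraction_neutral(pka, 7.4)
    K <- P * (fn + 0.05 * (1 - fn))
    if (any(pka$type == "base")) {
      fb <- 1 - fraction_neutral(pka[pka$type == "base", , drop = FALSE], 7.4)
      ap_mult <- 1 + 19 * fb
    }
  }
  kprot <- 0.163 + 0.0221 * K
  vapply(seq_len(nrow(tissues)), function(i) {
    row <- tissues[i, ]
    a_t <- (row$f_ew + row$f_iw) + K * (row$f_nl + row$f_np) +
      K * ap_mult * row$ap_mg_g / 1000 + kprot * row$f_protein
    a_t * fu
  }, numeric(1))
}

#' @export
print.htpbk_partition_set <- function(x, ...) {
  cat(sprintf("<htpbk_partition_set> %s\n", x$method))
  print(round(x$kp, 3))
  invisible(x)
}
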