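# Source-tagged compound properties and strategy resolution.
#
# A compound is a bag of PropertyRecords: (property, subtype, value, source,
# unit). A ParameterisationStrategy names one source (or a consensus of
# sources) per parameter slot; resolve_inputs() turns the pair into the single
# concrete parameter set a simulation consumes.

.htpbk_properties <- c("lipophilicity", "pka", "fu", "solubility",
                       "clearance", "permeability")

#' Construct a compound property set
#'
#' @param compound_id Character label, unique per table.
#' @param MW Molecular weight (g/mol), positive. The modelled chemical space
#'   is small molecules (< 900 Da); larger values trigger a warning.
#' @param records data.frame with columns `property`, `subtype`, `value`,
#'   `source` and optionally `unit` (canonical units assumed when absent:
#'   pKa dimensionless, Fu fraction, solubility mg/L, plasma clearance L/h,
#'   intrinsic clearance ul/min/1e6 cells, permeability cm/min).
#' @return An `htpbk_compound` object.
#' @export
compound_properties <- function(compound_id, MW, records) {
  stopifnot(is.character(compound_id), length(compound_id) == 1,
            is.numeric(MW), MW > 0)
  if (MW >= 900)
    warning(sprintf("%s: MW %.0f outside the modelled space (< 900 Da)",
                    compound_id, MW))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("property", "subtype", "value", "source")
  if (!all(need %in% names(records)))
    stop("records must have columns property, subtype, value, source")
  if (is.null(records$unit)) records$unit <- NA_character_
  bad <- !records$property %in% .htpbk_properties
  if (any(bad))
    stop("unknown property label(s): ",
         paste(unique(records$property[bad]), collapse = ", "))
  fu <- records$property == "fu"
  if (any(fu & (records$value < 0 | records$value > 1)))
    stop(compound_id, ": Fu values must lie in [0, 1]")
  nonneg <- records$property %in% c("solubility", "clearance", "permeability")
  if (any(nonneg & records$value < 0))
    stop(compound_id, ": solubility, clearance and permeability must be >= 0")
  structure(list(compound_id = compound_id, MW = MW,
                 records = records[, c(need, "unit")]),
            class = "htpbk_compound")
}

#' @export
print.htpbk_compound <- function(x, ...) {
  cat(sprintf("<htpbk_compound> %s (MW %.1f), %d records\n",
              x$compound_id, x$MW, nrow(x$records)))
  invisible(x)
}

#' Load a compound property table
#'
#' Reads a long-format CSV (or XLSX, if readxl is installed) with mandatory
#' columns `compound_id`, `property`, `subtype`, `value`, `source`, `MW` and
#' an optional `unit` column. Duplicate (compound, property, subtype, source)
#' rows are averaged into one record with a warning, mirroring the use of
#' average values when several measurements of one property exist. Malformed
#' rows are reported with their row numbers.
#'
#' @param path File to read.
#' @return Named list of `htpbk_compound` objects (possibly empty).
#' @export
load_property_table <- function(path) {
  tab <- .read_table(path)
  need <- c("compound_id", "property", "subtype", "value", "source", "MW")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("property table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(list())
  if (is.null(tab$unit)) tab$unit <- NA_character_
  val <- suppressWarnings(as.numeric(tab$value))
  if (any(is.na(val)))
    stop("non-numeric value in property table row(s): ",
         paste(which(is.na(val)), collapse = ", "))
  tab$value <- val
  tab <- .normalise_units(tab)
  out <- list()
  for (id in unique(tab$compound_id)) {
    rows <- tab[tab$compound_id == id, , drop = FALSE]
    mw <- unique(rows$MW)
    if (length(mw) != 1)
      stop(id, ": inconsistent MW across rows")
    key <- paste(rows$property, rows$subtype, rows$source, sep = "\r")
    if (anyDuplicated(key)) {
      warning(id, ": duplicate (property, subtype, source) rows averaged")
      agg <- aggregate(rows$value, by = list(key = key), FUN = mean)
      first <- rows[!duplicated(key), , drop = FALSE]
      first$value <- agg$x[match(paste(first$property, first$subtype,
                                       first$source, sep = "\r"), agg$key)]
      rows <- first
    }
    out[[id]] <- compound_properties(id, mw,
      rows[, c("property", "subtype", "value", "source", "unit")])
  }
  out
}

# Convert declared alternative units to the canonical ones at load time.
# Canonical: solubility mg/L, plasma CL L/h (L/h/kg kept, scaled at assembly),
# CLint ul/min/1e6 cells, permeability cm/min, concentrations mg/L.
.normalise_units <- function(tab) {
  u <- tolower(ifelse(is.na(tab$unit), "", tab$unit))
  conv <- function(rows, factor, new_unit) {
    tab$value[rows] <<- tab$value[rows] * factor
    tab$unit[rows] <<- new_unit
  }
  sol <- tab$property == "solubility"
  conv(sol & u == "g/l", 1000, "mg/L")
  moll <- sol & u == "mol/l"
  if (any(moll)) {
    tab$value[moll] <- tab$value[moll] * tab$MW[moll] * 1000
    tab$unit[moll] <- "mg/L"
  }
  perm <- tab$property == "permeability"
  conv(perm & u == "cm/s", 60, "cm/min")
  conv(perm & u == "1e-6 cm/s", 60e-6, "cm/min")
  cl <- tab$property == "clearance"
  conv(cl & u == "ml/min", 0.06, "L/h")
  tab
}

.read_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package")
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Consensus (mean) of property records from several sources
#'
#' Consensus parameterisation simply takes the arithmetic mean of the values
#' predicted by different tools for the same property subtype.
#'
#' @param records data.frame of PropertyRecords sharing one property/subtype.
#' @return The arithmetic mean value.
#' @export
consensus_value <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop("consensus of an empty record set")
  if (length(unique(records$property)) != 1 ||
      length(unique(records$subtype)) != 1)
    stop("consensus requires records of a single property/subtype")
  mean(records$value)
}

#' Lipophilicity conversion table
#'
#' Linear regressions mapping LogP or LogD values to membrane affinity
#' (LogMA). Coefficients are configuration data shipped with the package
#' (implementer-transcribed from the cited regressions), not hard-coded.
#'
#' @return data.frame with columns name, input_subtype, slope, intercept,
#'   citation.
#' @export
lipophilicity_conversions <- function() {
  read.csv(system.file("extdata", "lipophilicity_conversions.csv",
                       package = "htpbk", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Convert a lipophilicity value to membrane affinity (LogMA)
#'
#' Applies `slope * value + intercept` for the named conversion, after
#' checking that the record subtype matches the conversion's expected input.
#'
#' @param value Lipophilicity value (LogP or LogD).
#' @param conv One row of [lipophilicity_conversions()], or a list with
#'   `input_subtype`, `slope`, `intercept`.
#' @param subtype Subtype of `value` ("LogP" or "LogD").
#' @return The converted value (subtype LogMA).
#' @export
convert_lipophilicity <- function(value, conv, subtype) {
  if (!identical(conv$input_subtype, subtype))
    stop(sprintf("conversion expects %s input, got %s",
                 conv$input_subtype, subtype))
  conv$slope * value + conv$intercept
}

#' Define a parameterisation strategy
#'
#' One choice of source/method per parameter slot; the unit that is being
#' benchmarked. PO simulations additionally require solubility and
#' permeability slots.
#'
#' @param label Strategy name (used for ranking tie-breaks).
#' @param lipophilicity_sources Character vector of source labels; with
#'   `lipophilicity_consensus = TRUE` their mean is used.
#' @param lipophilicity_consensus Take the mean over sources (default TRUE
#'   when several sources are named).
#' @param lipophilicity_conversion Name of a row of
#'   [lipophilicity_conversions()] applied per record before averaging, or
#'   NULL.
#' @param pka_source Source label for pKa values, or "none" to treat every
#'   compound as neutral.
#' @param partitioning_method One of "pksim_standard", "schmitt",
#'   "rodgers_rowland", "poulin_theil", "berezhkovskiy".
#' @param fu_source Source label for fraction unbound.
#' @param clearance_source Source label for clearance.
#' @param clearance_mode "plasma" (whole-body plasma clearance) or
#'   "intrinsic" (hepatocyte CLint scaled to the liver).
#' @param renal_passive Add passive renal clearance (GFR x Fu). Only honoured
#'   in intrinsic mode; plasma clearance already contains all systemic
#'   elimination, so the flag is ignored (with a warning) in plasma mode.
#' @param solubility_source,solubility_subtype Solubility slot (PO only).
#' @param permeability_source,permeability_subtype Permeability slot (PO).
#' @param permeability_scaling "direct", "scaled" (multiply by
#'   `permeability_scale_factor`, see [caco2_scaling_factor()]) or
#'   "engine_equation" (predict from MW and LogMA, see
#'   [engine_permeability()]).
#' @param permeability_scale_factor Scalar used when scaling is "scaled".
#' @return An `htpbk_strategy` object.
#' @export
strategy <- function(label,
                     lipophilicity_sources,
                     lipophilicity_consensus = length(lipophilicity_sources) > 1,
                     lipophilicity_conversion = NULL,
                     pka_source = "none",
                     partitioning_method = "pksim_standard",
                     fu_source,
                     clearance_source,
                     clearance_mode = c("plasma", "intrinsic"),
                     renal_passive = FALSE,
                     solubility_source = NULL,
                     solubility_subtype = NULL,
                     permeability_source = NULL,
                     permeability_subtype = NULL,
                     permeability_scaling = c("direct", "scaled",
                                              "engine_equation"),
                     permeability_scale_factor = 1) {
  clearance_mode <- match.arg(clearance_mode)
  permeability_scaling <- match.arg(permeability_scaling)
  methods <- c("pksim_standard", "schmitt", "rodgers_rowland",
               "poulin_theil", "berezhkovskiy")
  if (!partitioning_method %in% methods)
    stop("unknown partitioning method: ", partitioning_method)
  structure(list(
    label = label,
    lipophilicity_sources = lipophilicity_sources,
    lipophilicity_consensus = lipophilicity_consensus,
    lipophilicity_conversion = lipophilicity_conversion,
    pka_source = pka_source,
    partitioning_method = partitioning_method,
    fu_source = fu_source,
    clearance_source = clearance_source,
    clearance_mode = clearance_mode,
    renal_passive = renal_passive,
    solubility_source = solubility_source,
    solubility_subtype = solubility_subtype,
    permeability_source = permeability_source,
    permeability_subtype = permeability_subtype,
    permeability_scaling = permeability_scaling,
    permeability_scale_factor = permeability_scale_factor
  ), class = "htpbk_strategy")
}

#' @export
print.htpbk_strategy <- function(x, ...) {
  cat(sprintf(paste0("<htpbk_strategy> %s\n  lipophilicity: %s%s | pKa: %s | ",
                     "partitioning: %s\n  fu: %s | clearance: %s (%s%s)\n"),
              x$label, paste(x$lipophilicity_sources, collapse = "+"),
              if (isTRUE(x$lipophilicity_consensus) &&
                  length(x$lipophilicity_sources) > 1) " (consensus)" else "",
              x$pka_source, x$partitioning_method, x$fu_source,
              x$clearance_source, x$clearance_mode,
              if (isTRUE(x$renal_passive)) " + renal" else ""))
  invisible(x)
}

#' Read / write strategy documents (JSON)
#'
#' Strategy documents use the exact slot names of [strategy()]. Three named
#' configurations mirroring the benchmarked full strategies ship with the
#' package: `"best_overall"`, `"best_insilico_proprietary"`,
#' `"best_insilico_free"` (pass the name instead of a path).
#'
#' @param path Path to a JSON strategy document, or a shipped strategy name.
#' @param strat An `htpbk_strategy`.
#' @return `read_strategy` returns an `htpbk_strategy`; `write_strategy`
#'   returns `path` invisibly.
#' @export
read_strategy <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", "strategies", paste0(path, ".json"),
                           package = "htpbk")
    if (nzchar(shipped)) path <- shipped else stop("no such strategy: ", path)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$lipophilicity_conversion <- x$lipophilicity_conversion %||% NULL
  do.call(strategy, x[!vapply(x, is.null, logical(1))])
}

#' @rdname read_strategy
#' @export
write_strategy <- function(strat, path) {
  stopifnot(inherits(strat, "htpbk_strategy"))
  jsonlite::write_json(unclass(strat), path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pick_records <- function(compound, property, source, subtype = NULL) {
  r <- compound$records
  sel <- r$property == property & r$source == source
  if (!is.null(subtype)) sel <- sel & r$subtype == subtype
  r[sel, , drop = FALSE]
}

#' Resolve a strategy into concrete simulation parameters
#'
#' Looks up, for one compound, the record each strategy slot names; applies
#' the configured lipophilicity conversion and/or consensus mean; returns the
#' single concrete parameter set used to build a simulation. With
#' `pka_source = "none"` the pKa set is empty, i.e. the compound is treated
#' as neutral.
#'
#' @param compound An `htpbk_compound`.
#' @param strat An `htpbk_strategy`.
#' @param route "iv" or "po"; the PO route requires solubility and
#'   permeability slots in the strategy and records for them in the compound.
#' @return An `htpbk_parameters` list with elements `lipophilicity`
#'   (value + subtype), `pka` (data.frame value/type), `fu`, `solubility`,
#'   `clearance` (value/mode/unit), `permeability` (value/subtype/scaling),
#'   `MW`, `compound_id`.
#' @export
resolve_inputs <- function(compound, strat, route = c("iv", "po")) {
  route <- match.arg(route)
  stopifnot(inherits(compound, "htpbk_compound"),
            inherits(strat, "htpbk_strategy"))
  fail <- function(slot, source)
    stop(sprintf("%s: no %s record from source '%s'",
                 compound$compound_id, slot, source), call. = FALSE)

  # lipophilicity: per-source value, optional conversion, optional consensus
  conv <- NULL
  if (!is.null(strat$lipophilicity_conversion)) {
    ct <- lipophilicity_conversions()
    conv <- as.list(ct[ct$name == strat$lipophilicity_conversion, ])
    if (length(conv$name) == 0)
      stop("unknown lipophilicity conversion: ", strat$lipophilicity_conversion)
  }
  vals <- numeric(0); subs <- character(0)
  for (src in strat$lipophilicity_sources) {
    rec <- .pick_records(compound, "lipophilicity", src)
    if (nrow(rec) == 0) fail("lipophilicity", src)
    v <- mean(rec$value); s <- rec$subtype[1]
    if (!is.null(conv)) { v <- convert_lipophilicity(v, conv, s); s <- "LogMA" }
    vals <- c(vals, v); subs <- c(subs, s)
  }
  lipo <- if (isTRUE(strat$lipophilicity_consensus) || length(vals) == 1) {
    list(value = mean(vals),
         subtype = if (length(unique(subs)) == 1) subs[1] else "mixed")
  } else {
    list(value = vals[1], subtype = subs[1])
  }

  # an empty pKa set from a named source means "no ionisable sites", not a
  # missing slot: the compound is treated as neutral either way
  pka <- data.frame(value = numeric(0), type = character(0))
  if (!identical(strat$pka_source, "none")) {
    rec <- .pick_records(compound, "pka", strat$pka_source)
    if (nrow(rec) > 0) pka <- data.frame(value = rec$value, type = rec$subtype)
  }

  rec <- .pick_records(compound, "fu", strat$fu_source)
  if (nrow(rec) == 0) fail("fu", strat$fu_source)
  fu <- mean(rec$value)

  cl_sub <- if (strat$clearance_mode == "plasma") "plasma_CL" else
    "hepatocyte_CLint"
  rec <- .pick_records(compound, "clearance", strat$clearance_source, cl_sub)
  if (nrow(rec) == 0) fail(paste0("clearance (", cl_sub, ")"),
                           strat$clearance_source)
  clearance <- list(value = mean(rec$value), mode = strat$clearance_mode,
                    unit = rec$unit[1])

  solubility <- NULL; permeability <- NULL
  if (route == "po") {
    if (is.null(strat$solubility_source) ||
        (is.null(strat$permeability_source) &&
         strat$permeability_scaling != "engine_equation"))
      stop("PO route requires solubility and permeability slots in the strategy")
    rec <- .pick_records(compound, "solubility", strat$solubility_source,
                         strat$solubility_subtype)
    if (nrow(rec) == 0) fail("solubility", strat$solubility_source)
    solubility <- mean(rec$value)
    if (strat$permeability_scaling == "engine_equation") {
      permeability <- list(value = NA_real_, subtype = "engine",
                           scaling = "engine_equation", factor = 1)
    } else {
      rec <- .pick_records(compound, "permeability",
                           strat$permeability_source,
                           strat$permeability_subtype)
      if (nrow(rec) == 0) fail("permeability", strat$permeability_source)
      permeability <- list(value = mean(rec$value), subtype = rec$subtype[1],
                           scaling = strat$permeability_scaling,
                           factor = strat$permeability_scale_factor)
    }
  }

  structure(list(compound_id = compound$compound_id, MW = compound$MW,
                 lipophilicity = lipo, pka = pka, fu = fu,
                 solubility = solubility, clearance = clearance,
                 permeability = permeability),
            class = "htpbk_parameters")
}
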