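# Readers/writers for study tables and result sets, plus run manifests.
#
# Canonical on-disk units: time h, dose mg, concentration mg/L, clearance
# L/h, CLint ul/min/1e6 cells, permeability cm/min. Columns may declare
# alternatives via the column map and are converted on load.

#' Default column map for study tables
#'
#' Maps canonical study fields to the columns of a long-format table (one
#' row per observed datapoint) and declares units. Override entries to adapt
#' to a foreign layout, e.g. a supplementary workbook.
#'
#' @param ... Named overrides of the default mapping.
#' @return A named list: canonical field -> column name, plus `conc_unit`
#'   ("mg/L", "ug/mL", "ng/mL", "umol/L" or "nmol/L" -- molar units require
#'   an `MW` column or compound MW lookup) and `time_unit` ("h" or "min").
#' @export
column_map <- function(...) {
  modifyList(list(
    study_id = "study_id", compound_id = "compound_id", route = "route",
    dose = "dose_mg", infusion = "infusion_h", formulation = "formulation",
    t80 = "t80_min", sex = "sex", age = "age", weight = "weight",
    height = "height", time = "time_h", conc = "conc",
    conc_unit = "mg/L", time_unit = "h", MW = "MW"
  ), list(...))
}

.conc_to_mg_L <- function(x, unit, mw) {
  switch(unit,
         "mg/L" = x, "ug/mL" = x, "ng/mL" = x / 1000, "ug/L" = x / 1000,
         "umol/L" = x * mw / 1000, "nmol/L" = x * mw / 1e6,
         stop("unknown concentration unit: ", unit))
}

#' Load a study table
#'
#' Reads a long-format CSV/XLSX (one row per observed concentration) into
#' validated study records. Route labels are normalised ("iv" with a
#' positive infusion duration becomes an infusion; "po"/"oral" are oral).
#' Rows violating the profile invariants (non-increasing times, negative
#' concentrations) are rejected with their study id; unit conversions follow
#' the column map.
#'
#' @param path File to read.
#' @param colmap See [column_map()].
#' @return Named list of `htpbk_study`.
#' @export
load_study_table <- function(path, colmap = column_map()) {
  tab <- .read_table(path)
  need <- c("study_id", "compound_id", "route", "dose", "time", "conc")
  cols <- unlist(colmap[need])
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("study table is missing mapped column(s): ",
         paste(miss, collapse = ", "))
  get <- function(field, default = NULL) {
    col <- colmap[[field]]
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else default
  }
  time <- as.numeric(get("time"))
  if (identical(colmap$time_unit, "min")) time <- time / 60
  conc_raw <- as.numeric(get("conc"))
  mw <- get("MW", default = rep(NA_real_, nrow(tab)))
  if (colmap$conc_unit %in% c("umol/L", "nmol/L") && anyNA(mw))
    stop("molar concentration units require an MW column")
  conc <- .conc_to_mg_L(conc_raw, colmap$conc_unit, mw)
  route_raw <- tolower(get("route"))
  infusion <- suppressWarnings(as.numeric(get("infusion",
                                              rep(0, nrow(tab)))))
  infusion[is.na(infusion)] <- 0
  formulation <- get("formulation", rep("solution", nrow(tab)))
  formulation[is.na(formulation) | formulation == ""] <- "solution"
  t80 <- suppressWarnings(as.numeric(get("t80", rep(NA_real_, nrow(tab)))))
  out <- list()
  for (sid in unique(tab[[colmap$study_id]])) {
    i <- which(tab[[colmap$study_id]] == sid)
    ord <- order(time[i]); i <- i[ord]
    if (any(diff(time[i]) <= 0))
      stop(sprintf("study %s: non-increasing observation times (rows %s)",
                   sid, paste(i[c(diff(time[i]) <= 0, FALSE)],
                              collapse = ", ")))
    if (any(conc[i] < 0))
      stop(sprintf("study %s: negative concentration (rows %s)", sid,
                   paste(i[conc[i] < 0], collapse = ", ")))
    r1 <- i[1]
    route <- switch(route_raw[r1],
                    "iv" = if (infusion[r1] > 0) "iv_infusion" else "iv_bolus",
                    "iv_bolus" = "iv_bolus", "iv_infusion" = "iv_infusion",
                    "po" = "oral", "oral" = "oral",
                    stop(sprintf("study %s: unknown route '%s'", sid,
                                 route_raw[r1])))
    dosing <- dosing_event(route, as.numeric(tab[[colmap$dose]][r1]),
                           infusion_h = infusion[r1],
                           formulation = if (route == "oral")
                             tolower(formulation[r1]) else "solution",
                           t80_min = if (!is.na(t80[r1])) t80[r1] else NULL)
    dem <- NULL
    w <- suppressWarnings(as.numeric(get("weight",
                                         rep(NA_real_, nrow(tab)))[r1]))
    if (!is.na(w)) {
      dem <- list(sex = get("sex", rep(NA, nrow(tab)))[r1],
                  age = suppressWarnings(
                    as.numeric(get("age", rep(NA_real_, nrow(tab)))[r1])),
                  weight = w,
                  height = suppressWarnings(
                    as.numeric(get("height", rep(NA_real_, nrow(tab)))[r1])))
      dem <- dem[!vapply(dem, function(x) all(is.na(x)), logical(1))]
    }
    cid <- tab[[colmap$compound_id]][r1]
    out[[sid]] <- study_record(sid, cid, dosing,
                               profile(time[i], conc[i], compound_id = cid,
                                       study_id = sid),
                               demographics = dem)
  }
  out
}

#' Write a study list back to the canonical CSV layout
#'
#' @param studies Named list of `htpbk_study`.
#' @param path Output CSV path.
#' @return `path`, invisibly. `load_study_table()` on the output reproduces
#'   the input.
#' @export
write_study_table <- function(studies, path) {
  rows <- lapply(studies, function(s) {
    n <- nrow(s$observations)
    data.frame(
      study_id = s$study_id, compound_id = s$compound_id,
      route = sub("iv_.*", "iv", s$dosing$route),
      dose_mg = s$dosing$dose_mg, infusion_h = s$dosing$infusion_h,
      formulation = ifelse(is.na(s$dosing$formulation), "",
                           s$dosing$formulation),
      t80_min = s$dosing$t80_min,
      sex = (s$demographics$sex) %||% NA,
      age = (s$demographics$age) %||% NA_real_,
      weight = (s$demographics$weight) %||% NA_real_,
      height = (s$demographics$height) %||% NA_real_,
      time_h = signif(s$observations$time_h, 12),
      conc = signif(s$observations$conc_mg_per_L, 12),
      stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write evaluation results with a reproducibility manifest
#'
#' Emits per-study, per-compound and per-strategy CSV tables plus a JSON
#' manifest carrying the RNG seed, package version and a hash of the
#' serialised strategy configuration.
#'
#' @param results Non-empty list of `htpbk_strategy_result`.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed recorded in the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(results, out_dir, seed = NA_integer_) {
  if (length(results) == 0) stop("no results to write")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  per_study <- do.call(rbind, lapply(results, function(r)
    cbind(strategy = r$label, r$per_study)))
  per_compound <- do.call(rbind, lapply(results, function(r)
    cbind(strategy = r$label, r$per_compound)))
  strategies <- do.call(rbind, lapply(results, function(r)
    data.frame(strategy = r$label,
               median_absolute_log2 = r$median_absolute_log2,
               median_relative_log2 = r$median_relative_log2,
               n_compounds = nrow(r$per_compound),
               n_studies = nrow(r$per_study), n_failed = r$n_failed)))
  num <- function(df) { # stable 12-digit serialisation for exact round-trips
    for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 12)
    df
  }
  files <- file.path(out_dir, c("per_study.csv", "per_compound.csv",
                                "strategies.csv", "manifest.json"))
  write.csv(num(per_study), files[1], row.names = FALSE)
  write.csv(num(per_compound), files[2], row.names = FALSE)
  write.csv(num(strategies), files[3], row.names = FALSE)
  cfg <- vapply(results, function(r)
    jsonlite::toJSON(unclass(r$strategy), auto_unbox = TRUE, digits = NA),
    character(1))
  manifest <- list(
    package = "htpbk",
    version = as.character(utils::packageVersion("htpbk")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    strategies = names(results) %||% vapply(results, `[[`, "", "label"),
    config_hash = vapply(cfg, .fnv1a, character(1), USE.NAMES = FALSE),
    failures = unlist(lapply(results, `[[`, "failures")) %||% character(0)
  )
  jsonlite::write_json(manifest, files[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

# Small dependency-free FNV-1a hash for config fingerprints. The 32-bit
# modular multiply is split into 16-bit halves to stay within double
# precision.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h >= 2^31) * 2^31
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
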