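#' Atom percent excess of 15N
#'
#' Enrichment of a sample above its natural-abundance baseline, computed as
#' the difference between the atom% 15N of incubated nodules and that of
#' non-incubated (control) nodules from the same shrub. Negative values can
#' arise from analytical noise when true enrichment is at or below the
#' detection limit; they are returned as-is so that downstream QC can flag
#' the assay, rather than silently censored here.
#'
#' @param incubated_atm_pct atom% 15N of incubated nodules, in \[0, 100\].
#' @param control_atm_pct atom% 15N of control nodules, in \[0, 100\].
#' @return Numeric vector of atom percent excess (APE, percentage points).
#'   A `below_detection` attribute-free result; use [nodule_fixation_rate()]
#'   for flagged records.
#' @examples
#' atom_percent_excess(0.4663, 0.3663)
#' @export
atom_percent_excess <- function(incubated_atm_pct, control_atm_pct) {
  check_atm_pct(incubated_atm_pct, "incubated_atm_pct")
  check_atm_pct(control_atm_pct, "control_atm_pct")
  incubated_atm_pct - control_atm_pct
}

check_atm_pct <- function(x, name) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop(sprintf("%s outside [0, 100] at record(s) %s",
                 name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Nodule nitrogen content on a molar basis
#'
#' Converts nodule N mass fraction (%) to micromoles of N per gram of dry
#' nodule, the quantity entering the tracer mass balance.
#'
#' @param nodule_pct_n nodule N mass fraction, percent, in (0, 100).
#' @param molar_mass molar mass of N in g mol^-1.
#' @return umol N per g dry nodule.
#' @examples
#' nodule_n_content(2.0)
#' @export
nodule_n_content <- function(nodule_pct_n, molar_mass = N_MOLAR_MASS) {
  bad <- which(!is.na(nodule_pct_n) & (nodule_pct_n <= 0 | nodule_pct_n >= 100))
  if (length(bad)) {
    stop(sprintf("nodule_pct_n must be in (0, 100); violated at record(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  (nodule_pct_n / 100) / molar_mass * 1e6
}

#' Per-nodule nitrogen fixation rate from a 15N2 incubation
#'
#' Implements the tracer mass balance for excised-nodule incubations in
#' 15N2-enriched headspace:
#'
#'   Nfix = (APE_fraction x N_nodule) / (time_h x headspace_fraction)
#'
#' where APE_fraction and headspace_fraction are atom fractions (atom% / 100)
#' and N_nodule is umol N per g dry nodule. The resulting rate has units
#' umol N g^-1 dry nodule h^-1. Both enrichments enter as fractions so that
#' the ratio is dimensionless and the units are carried by N_nodule / time.
#'
#' Records whose APE is negative (enrichment below detection) get a rate of
#' 0 and `below_detection = TRUE`; the raw APE is preserved in the output.
#'
#' @param records data frame with columns `incubated_atm_pct`,
#'   `control_atm_pct`, `nodule_pct_n`, `incubation_time` (hours) and
#'   `headspace_atm_pct`; optional `shrub_id` and `community` are carried
#'   through.
#' @param molar_mass molar mass of N in g mol^-1.
#' @return data frame with `ape` (%), `rate` (umol N g^-1 h^-1) and
#'   `below_detection` columns appended to any identifier columns present.
#' @examples
#' rec <- data.frame(incubated_atm_pct = 0.4163, control_atm_pct = 0.3663,
#'                   nodule_pct_n = 2, incubation_time = 1 / 6,
#'                   headspace_atm_pct = 20)
#' nodule_fixation_rate(rec)
#' @export
nodule_fixation_rate <- function(records, molar_mass = N_MOLAR_MASS) {
  required <- c("incubated_atm_pct", "control_atm_pct", "nodule_pct_n",
                "incubation_time", "headspace_atm_pct")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("incubation records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(records$incubation_time <= 0, na.rm = TRUE)) {
    stop("incubation_time must be > 0", call. = FALSE)
  }
  if (any(records$headspace_atm_pct <= 0 | records$headspace_atm_pct > 100,
          na.rm = TRUE)) {
    stop("headspace_atm_pct must be in (0, 100]", call. = FALSE)
  }
  ape <- atom_percent_excess(records$incubated_atm_pct, records$control_atm_pct)
  n_nod <- nodule_n_content(records$nodule_pct_n, molar_mass)
  rate <- (pmax(ape, 0) / 100 * n_nod) /
    (records$incubation_time * records$headspace_atm_pct / 100)
  out <- records[intersect(c("shrub_id", "community"), names(records))]
  out$ape <- ape
  out$rate <- rate
  out$below_detection <- ape < 0
  out
}

#' Read an incubation table from CSV
#'
#' Column names may be remapped through a named list (or a YAML file holding
#' one) whose names are the canonical fields and values the CSV headers, so
#' tables exported from other systems load without editing.
#'
#' @param path CSV file path.
#' @param col_map optional named list/character vector, or path to a YAML
#'   file, mapping canonical names to the file's column names.
#' @return data frame of incubation records with canonical column names.
#' @export
read_incubation_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  apply_col_map(df, col_map)
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
    col_map <- yaml::read_yaml(col_map)
  }
  col_map <- unlist(col_map)
  for (canonical in names(col_map)) {
    src <- col_map[[canonical]]
    if (!src %in% names(df)) {
      stop(sprintf("column '%s' (mapped to '%s') not found", src, canonical),
           call. = FALSE)
    }
    names(df)[names(df) == src] <- canonical
  }
  df
}
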