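# Exact mass deltas (Da) between a neutral molecule and its singly charged
# ESI adduct ion: proton mass for (de)protonation, formate anion for the
# [M+HCOO]- adduct. Values include the electron mass and are applied to
# machine precision; rounding happens only in reports.
ADDUCT_DELTA <- c(
  M_PLUS_H       = +1.007276,
  M_MINUS_H      = -1.007276,
  M_PLUS_FORMATE = +44.998204
)
ADDUCT_POLARITY <- c(
  M_PLUS_H = "positive", M_MINUS_H = "negative", M_PLUS_FORMATE = "negative"
)

#' Adduct specification table
#'
#' @return data.frame of the supported single-charge ESI adducts with their
#'   mass deltas (Da) and polarities.
#' @export
adduct_specs <- function() {
  data.frame(mode = names(ADDUCT_DELTA),
             mass_delta = unname(ADDUCT_DELTA),
             polarity = unname(ADDUCT_POLARITY[names(ADDUCT_DELTA)]),
             stringsAsFactors = FALSE)
}

#' Expected m/z of an ESI adduct ion
#'
#' `neutral_mass + mass_delta(mode)` for singly charged adducts
#' `[M+H]+`, `[M-H]-`, `[M+HCOO]-`. Vectorized; modes recycle against masses.
#'
#' @param neutral_mass neutral monoisotopic mass in Da, `> 0`.
#' @param mode adduct mode (canonical name, see [adduct_specs()], or a raw
#'   ion-mode label accepted by [parse_ion_mode()]).
#' @return expected m/z in Da (full precision; round for display).
#' @examples
#' adduct_mz(170.0215, "M_MINUS_H")      # gallic acid [M-H]-
#' adduct_mz(362.1213, "[M + HCOO]−")    # catalpol formate adduct
#' @export
adduct_mz <- function(neutral_mass, mode) {
  if (any(is.na(neutral_mass)) || any(neutral_mass <= 0)) {
    stop("neutral mass must be positive", call. = FALSE)
  }
  mode <- vapply(as.character(mode), function(m) {
    if (m %in% names(ADDUCT_DELTA)) m else parse_ion_mode(m)
  }, character(1), USE.NAMES = FALSE)
  unname(neutral_mass + ADDUCT_DELTA[mode])
}

#' Audit a monitoring-ion table against expected adduct masses
#'
#' For each compound record whose neutral monoisotopic mass is supplied,
#' computes the expected m/z for its ionization mode and flags the row `pass`
#' if the monitored m/z lies within `tolerance` Da, else `fail`. Rows without
#' a supplied mass are reported as `unchecked`, never failed. Monitoring-ion
#' settings in published tables are often low-resolution targets rather than
#' exact masses, hence the permissive default tolerance of 0.2 Da.
#'
#' @param records a `compound_table` from [read_compound_table()].
#' @param masses named numeric vector (names = compound ids) of neutral
#'   monoisotopic masses, e.g. from [read_mass_table()].
#' @param tolerance maximum |observed - expected| in Da; default 0.2.
#' @return data.frame with one row per record: `compound_id`, `name`,
#'   `ion_mode`, `mz_observed`, `mz_expected` (rounded to 4 dp for display),
#'   `delta`, `status`. Comparison uses full precision; the rounded column is
#'   cosmetic.
#' @export
check_sim_table <- function(records, masses = numeric(), tolerance = 0.2) {
  stopifnot(inherits(records, "compound_table"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("tolerance must be a positive scalar", call. = FALSE)
  }
  n <- nrow(records)
  expected <- rep(NA_real_, n)
  has_mass <- records$compound_id %in% names(masses)
  if (any(has_mass)) {
    expected[has_mass] <- adduct_mz(masses[records$compound_id[has_mass]],
                                    records$ion_mode[has_mass])
  }
  delta <- records$mz_monitored - expected
  status <- ifelse(!has_mass, "unchecked",
                   ifelse(abs(delta) <= tolerance, "pass", "fail"))
  data.frame(compound_id = records$compound_id,
             name = records$name,
             ion_mode = records$ion_mode,
             mz_observed = records$mz_monitored,
             mz_expected = round(expected, 4),
             delta = round(delta, 4),
             status = status,
             stringsAsFactors = FALSE)
}

#' Read a neutral monoisotopic mass table
#'
#' TSV with a `component` column and a mass column
#' (`neutral_monoisotopic_mass` or `mass`); other columns (e.g. a molecular
#' formula) are ignored.
#'
#' @param path TSV path.
#' @return named numeric vector keyed by [compound_id()].
#' @export
read_mass_table <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    fileEncoding = "UTF-8")
  mass_col <- intersect(c("neutral_monoisotopic_mass", "mass"), names(raw))[1]
  if (!"component" %in% names(raw) || is.na(mass_col)) {
    stop(sprintf("mass table '%s' needs 'component' and a mass column", path))
  }
  m <- suppressWarnings(as.numeric(raw[[mass_col]]))
  if (anyNA(m)) stop(sprintf("non-numeric mass in '%s'", path), call. = FALSE)
  stats::setNames(m, compound_id(raw$component))
}
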