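KEV_TO_J <- 1.602176634e-16   # joules per keV

#' S-factor tables (OpenDose-style CSV export)
#'
#' An S factor is the absorbed dose rate to a target region per unit
#' activity in a source region, for a given computational phantom. Tables
#' are consumed as data in an OpenDose-export-compatible CSV layout with
#' header `phantom,source_region,target_region,S_mGy_per_MBq_h` and an
#' optional `unit` column; values are converted to mGy/(MBq h) at load.
#' Lookups of absent (source, target) pairs are errors, never silent zeros.
#'
#' @param path CSV file.
#' @param provenance Free-text provenance note stored with the table.
#' @return An object of class `sfactor_table`.
#' @export
load_sfactor_table <- function(path, provenance = path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phantom", "source_region", "target_region", "S_mGy_per_MBq_h")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("S-factor CSV is missing columns: ", paste(miss, collapse = ", "))
  if ("unit" %in% names(d)) {
    fac <- c(mGy_per_MBq_h = 1, Gy_per_MBq_h = 1e3, uGy_per_MBq_h = 1e-3,
             mGy_per_MBq_s = 3600)
    bad <- setdiff(unique(d$unit), names(fac))
    if (length(bad)) stop("unknown S-value unit(s): ",
                          paste(bad, collapse = ", "))
    d$S_mGy_per_MBq_h <- d$S_mGy_per_MBq_h * fac[d$unit]
    d$unit <- NULL
  }
  sfactor_table(d, provenance)
}

#' @rdname load_sfactor_table
#' @param entries Data frame with the four columns above (values already in
#'   mGy/(MBq h)).
#' @export
sfactor_table <- function(entries, provenance = "in-memory") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(entries$phantom %in% c("M", "F")))
    stop("phantom must be 'M' or 'F'")
  if (any(!is.finite(entries$S_mGy_per_MBq_h)) ||
      any(entries$S_mGy_per_MBq_h < 0))
    stop("S values must be finite and >= 0")
  key <- paste(entries$phantom, entries$source_region,
               entries$target_region, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (phantom, source, target) entries: ",
         paste(unique(gsub("\r", " -> ", key[duplicated(key)])),
               collapse = "; "))
  structure(list(entries = entries, provenance = provenance),
            class = "sfactor_table")
}

#' @rdname load_sfactor_table
#' @param table An `sfactor_table`.
#' @param source_region,target_region Region names.
#' @param phantom `"M"` or `"F"`.
#' @export
sfactor <- function(table, source_region, target_region, phantom = "M") {
  stopifnot(inherits(table, "sfactor_table"))
  e <- table$entries
  i <- which(e$phantom == phantom & e$source_region == source_region &
               e$target_region == target_region)
  if (length(i) == 0)
    stop("no S entry for phantom ", phantom, ", ", source_region, " -> ",
         target_region, " (table: ", table$provenance, ")")
  e$S_mGy_per_MBq_h[i]
}

#' @export
print.sfactor_table <- function(x, ...) {
  cat("sfactor_table:", nrow(x$entries), "entries (",
      x$provenance, ")\n")
  invisible(x)
}

#' Phantom region masses
#'
#' Masses needed to convert cumulated activities into concentrations for
#' the concentration-based bone-marrow self-dose. Presets carry the ICRP
#' adult reference values: male 73 kg body / 1170 g active marrow, female
#' 60 kg / 900 g. The low-compartment mass defaults to the body mass minus
#' a configurable high-compartment mass (default 0).
#'
#' @param m_BM_g Active (red) marrow mass, g.
#' @param m_body_g Whole-body mass, g.
#' @param m_high_g Mass assigned to the high-uptake compartment, g.
#' @param m_low_g Low-compartment mass, g; default `m_body_g - m_high_g`.
#' @param preset `"icrp_adult_male"` or `"icrp_adult_female"` (explicit
#'   arguments override).
#' @return An object of class `phantom_masses`.
#' @export
phantom_masses <- function(m_BM_g = NULL, m_body_g = NULL, m_high_g = 0,
                           m_low_g = NULL, preset = NULL) {
  base <- list()
  if (!is.null(preset)) {
    base <- switch(preset,
      icrp_adult_male = list(m_BM_g = 1170, m_body_g = 73000),
      icrp_adult_female = list(m_BM_g = 900, m_body_g = 60000),
      stop("unknown masses preset: ", preset))
  }
  m <- utils::modifyList(base, Filter(Negate(is.null),
         list(m_BM_g = m_BM_g, m_body_g = m_body_g)))
  if (is.null(m$m_BM_g) || is.null(m$m_body_g))
    stop("m_BM_g and m_body_g are required (directly or via preset)")
  m$m_low_g <- m_low_g %||% (m$m_body_g - m_high_g)
  if (any(unlist(m) <= 0)) stop("all masses must be > 0")
  if (m$m_BM_g > m$m_body_g || m$m_low_g > m$m_body_g)
    stop("m_BM_g and m_low_g must not exceed m_body_g")
  structure(m[c("m_BM_g", "m_body_g", "m_low_g")], class = "phantom_masses")
}

#' MIRD dose to a target region
#'
#' Sum over source regions of cumulated activity times the S factor,
#' `D = sum_S A~_S S(target <- S)`, with the mGy -> Gy conversion applied.
#'
#' @param cumulated Named numeric vector/list: cumulated activity (MBq h)
#'   per source region; names are source-region names.
#' @param sfactors An [sfactor_table()].
#' @param target_region Target region name.
#' @param phantom `"M"` or `"F"`.
#' @return Dose in Gy.
#' @export
mird_dose <- function(cumulated, sfactors, target_region, phantom = "M") {
  cumulated <- unlist(cumulated)
  if (is.null(names(cumulated)) || any(names(cumulated) == ""))
    stop("cumulated must be named by source region")
  if (any(cumulated < 0)) stop("cumulated activities must be >= 0")
  s <- vapply(names(cumulated),
              function(src) sfactor(sfactors, src, target_region, phantom),
              numeric(1))
  sum(cumulated * s) * 1e-3
}

#' Bone-marrow cumulated activity from the low compartment
#'
#' Assumes (as in blood-based marrow dosimetry) that the activity
#' concentration in marrow is proportional to that of the low-uptake
#' compartment: `A~_BM = kappa (A~_low / m_low) m_BM`.
#'
#' @param A_tilde_low Low-compartment cumulated activity, MBq h.
#' @param kappa Marrow-to-low concentration ratio (>= 0, default 1).
#' @param masses A [phantom_masses()].
#' @return Marrow cumulated activity, MBq h.
#' @export
bm_cumulated_from_low <- function(A_tilde_low, kappa = 1, masses) {
  stopifnot(inherits(masses, "phantom_masses"))
  if (kappa < 0) stop("kappa must be >= 0")
  if (A_tilde_low < 0) stop("A_tilde_low must be >= 0")
  kappa * (A_tilde_low / masses$m_low_g) * masses$m_BM_g
}

#' Concentration-based marrow (or lesion) beta self-dose
#'
#' `D = C~ phi Delta` with the cumulated activity concentration `C~` in
#' MBq h per gram: decays per gram `= C~ x 1e6 x 3600`, energy per decay
#' `= Delta keV`, absorbed locally with fraction `phi`, divided by 1e-3 kg
#' per gram of tissue.
#'
#' @param C_tilde Cumulated activity concentration, MBq h / g (>= 0).
#' @param phi Absorbed fraction for self-irradiation, in `[0, 1]`
#'   (approximately 1 for electrons in marrow).
#' @param delta_keV Mean energy emitted (locally absorbed) per decay, keV;
#'   default 147 (177Lu).
#' @return Dose in Gy.
#' @export
bm_self_dose_concentration <- function(C_tilde, phi = 1, delta_keV = 147) {
  if (C_tilde < 0) stop("C_tilde must be >= 0")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (delta_keV <= 0) stop("delta_keV must be > 0")
  C_tilde * 1e6 * 3600 * phi * delta_keV * KEV_TO_J / 1e-3
}

#' Assemble the bone-marrow dose report
#'
#' Sums the marrow self-dose, the photon cross-doses from the high- and
#' low-uptake compartments, and (when present) the beta dose from skeletal
#' lesions. The self term is computed either from the concentration formula
#' (`self_dose_mode = "concentration"`, using `phi` and `delta_keV`) or
#' from an `S(BM <- BM)` table entry (`"sfactor"`). The lesion term is
#' always concentration-based, with its own absorbed fraction `phi_SL` and
#' affected-marrow mass.
#'
#' @param cumulated Named list with `A_tilde_high`, `A_tilde_low` (MBq h)
#'   and optionally `A_tilde_BM` (otherwise derived via
#'   [bm_cumulated_from_low()] with `kappa`) and `A_tilde_SL`.
#' @param sfactors An [sfactor_table()] (may be `NULL` when both cross
#'   S values are supplied through `config$S_override`).
#' @param masses A [phantom_masses()].
#' @param config List of dosimetry parameters: `kappa` (default 1),
#'   `delta_keV` (147), `phi` (1), `phi_SL` (1),
#'   `self_dose_mode` (`"concentration"` or `"sfactor"`),
#'   `m_SL_affected_g` (defaults to `masses$m_BM_g`), `phantom`
#'   (`"M"`/`"F"`), region names `high_region` (`"high"`), `low_region`
#'   (`"low"`), `bm_region` (`"red_marrow"`), and optional `S_override`
#'   (named vector, mGy/(MBq h), keyed by source region) taking precedence
#'   over table lookups.
#' @return A `dose_report`: `D_BM_total_Gy`, `components`
#'   (`self`, `from_high`, `from_low`, `from_SL`, Gy) and an `inputs` echo.
#' @export
bm_dose <- function(cumulated, sfactors = NULL, masses, config = list()) {
  cfg <- utils::modifyList(list(
    kappa = 1, delta_keV = 147, phi = 1, phi_SL = 1,
    self_dose_mode = "concentration", m_SL_affected_g = masses$m_BM_g,
    phantom = "M", high_region = "high", low_region = "low",
    bm_region = "red_marrow", S_override = NULL), config)
  if (!cfg$self_dose_mode %in% c("concentration", "sfactor"))
    stop("self_dose_mode must be 'concentration' or 'sfactor'")
  a_high <- cumulated$A_tilde_high %||% 0
  a_low <- cumulated$A_tilde_low %||% 0
  a_bm <- cumulated$A_tilde_BM %||%
    bm_cumulated_from_low(a_low, cfg$kappa, masses)
  a_sl <- cumulated$A_tilde_SL %||% 0
  if (any(c(a_high, a_low, a_bm, a_sl) < 0))
    stop("cumulated activities must be >= 0")

  s_for <- function(src) {
    if (!is.null(cfg$S_override) && src %in% names(cfg$S_override))
      return(unname(cfg$S_override[[src]]))
    if (is.null(sfactors))
      stop("no S-factor table and no S_override entry for source '",
           src, "'")
    sfactor(sfactors, src, cfg$bm_region, cfg$phantom)
  }
  self <- if (cfg$self_dose_mode == "concentration") {
    bm_self_dose_concentration(a_bm / masses$m_BM_g, cfg$phi, cfg$delta_keV)
  } else {
    a_bm * s_for(cfg$bm_region) * 1e-3
  }
  from_high <- a_high * s_for(cfg$high_region) * 1e-3
  from_low <- a_low * s_for(cfg$low_region) * 1e-3
  from_sl <- if (a_sl > 0) {
    bm_self_dose_concentration(a_sl / cfg$m_SL_affected_g, cfg$phi_SL,
                               cfg$delta_keV)
  } else 0
  comp <- c(self = self, from_high = from_high, from_low = from_low,
            from_SL = from_sl)
  structure(list(D_BM_total_Gy = sum(comp), components = comp,
                 inputs = list(cumulated = list(A_tilde_high = a_high,
                                                A_tilde_low = a_low,
                                                A_tilde_BM = a_bm,
                                                A_tilde_SL = a_sl),
                               masses = unclass(masses),
                               config = cfg[setdiff(names(cfg),
                                                    "S_override")],
                               S_override = cfg$S_override)),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("bone-marrow dose:", format(signif(x$D_BM_total_Gy, 4)), "Gy\n")
  for (nm in names(x$components))
    cat(sprintf("  %-10s %s Gy\n", nm,
                format(signif(x$components[[nm]], 4))))
  invisible(x)
}

#' Clinical dose-grid generation
#'
#' Evaluates the bone-marrow dose over a grid of administered activities
#' and high/low activity splits, for the male and female phantom
#' configurations - the calculation-table layout intended for everyday
#' clinical use. The split is applied to the scale factors (initial
#' compartment activities); cumulated activities follow from the closed
#' forms, so every cell is strictly linear in `A0` at fixed split.
#'
#' @param A0_MBq Numeric vector of administered activities, MBq.
#' @param splits List of `c(high, low)` percentage pairs, each summing
#'   to 100.
#' @param kinetics A [compartment_kinetics()].
#' @param masses_M,masses_F [phantom_masses()] per phantom.
#' @param sfactors An [sfactor_table()] or `NULL` (with `config$S_override`).
#' @param config As in [bm_dose()]; `phantom` is set per row.
#' @return Data frame: `A0_MBq`, `high_pct`, `low_pct`, `phantom`,
#'   `D_BM_Gy`.
#' @export
dose_table <- function(A0_MBq, splits, kinetics, masses_M, masses_F,
                       sfactors = NULL, config = list()) {
  rows <- list()
  for (sp in splits) {
    if (length(sp) != 2 || abs(sum(sp) - 100) > 1e-9)
      stop("each split must be a (high, low) pair summing to 100")
    for (a0 in A0_MBq) {
      s_high <- a0 * sp[1] / 100
      s_low <- a0 * sp[2] / 100
      cum <- list(
        A_tilde_high = cumulated_activity_high(s_high, kinetics),
        A_tilde_low = cumulated_activity_low(s_low, kinetics))
      for (ph in c("M", "F")) {
        masses <- if (ph == "M") masses_M else masses_F
        rep <- bm_dose(cum, sfactors, masses,
                       utils::modifyList(config, list(phantom = ph)))
        rows[[length(rows) + 1]] <- data.frame(
          A0_MBq = a0, high_pct = sp[1], low_pct = sp[2], phantom = ph,
          D_BM_Gy = rep$D_BM_total_Gy)
      }
    }
  }
  do.call(rbind, rows)
}
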