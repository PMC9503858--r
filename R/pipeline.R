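default_study_config <- function() {
  list(
    kinetics = list(preset = "lu177_dotatate", t_half_M_h = NULL,
                    t_half_S_h = NULL, t_half_F_h = NULL,
                    w_S = NULL, w_F = NULL),
    segmentation = list(selection = "plateau", nnuf_cutoff = 0.5,
                        connectivity = 8, body_fraction = 0.01,
                        n_steps = 100),
    dosimetry = list(kappa = 1, delta_keV = 147, phi = 1, phi_SL = 1,
                     self_dose_mode = "concentration",
                     sfactors_csv = NULL, S_override = NULL,
                     masses = list(preset = NULL, m_BM_g = NULL,
                                   m_body_g = NULL, m_high_g = 0),
                     m_SL_affected_g = NULL, phantom = "from_scan",
                     high_region = "high", low_region = "low",
                     bm_region = "red_marrow"),
    lesions = list(skeletal_focus_labels = integer(0)))
}

#' Read and validate a study configuration
#'
#' YAML configuration with sections `kinetics`, `segmentation`, `dosimetry`
#' and `lesions`; unknown keys are rejected, and every default is resolved
#' so the configuration echoed into reports is complete. Activities inside
#' the config may carry a unit suffix (`"7400 MBq"`, `"7.4 GBq"`,
#' `"200 mCi"`); the internal unit is MBq.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @param overrides Named nested list merged over the file contents.
#' @return A `study_config` list with all defaults resolved.
#' @export
read_study_config <- function(path = NULL, overrides = list()) {
  cfg <- default_study_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  user <- modify_config(user, overrides)
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  check_keys(user, names(cfg), "top level")
  for (sec in names(user)) {
    check_keys(user[[sec]], names(cfg[[sec]]), sec)
    if (sec == "dosimetry" && !is.null(user$dosimetry$masses))
      check_keys(user$dosimetry$masses, names(cfg$dosimetry$masses),
                 "dosimetry$masses")
    cfg[[sec]] <- modify_config(cfg[[sec]], user[[sec]])
  }
  if (!cfg$dosimetry$self_dose_mode %in% c("concentration", "sfactor"))
    stop("dosimetry$self_dose_mode must be 'concentration' or 'sfactor'")
  if (!cfg$segmentation$selection %in% c("plateau", "nnuf_cutoff"))
    stop("segmentation$selection must be 'plateau' or 'nnuf_cutoff'")
  structure(cfg, class = "study_config")
}

# modifyList that descends into lists but replaces scalars/vectors
modify_config <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_config(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

#' Parse an activity with unit suffix to MBq
#'
#' Accepted suffixes: `MBq`, `GBq`, `mCi` (37 MBq exactly); a bare number
#' is taken as MBq.
#'
#' @param x Number, or string like `"7.4 GBq"`.
#' @return Activity in MBq.
#' @export
parse_activity_MBq <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(MBq|GBq|mCi)?\\s*$", x))[[1]]
  if (length(m) == 0 || m[2] == "") stop("cannot parse activity: ", x)
  v <- as.numeric(m[2])
  switch(ifelse(m[3] == "", "MBq", m[3]),
         MBq = v, GBq = v * 1e3, mCi = v * 37)
}

kinetics_from_config <- function(kc) {
  compartment_kinetics(t_half_M_h = kc$t_half_M_h,
                       t_half_S_h = kc$t_half_S_h,
                       t_half_F_h = kc$t_half_F_h,
                       w_S = kc$w_S, w_F = kc$w_F, preset = kc$preset)
}

masses_from_config <- function(mc) {
  phantom_masses(m_BM_g = mc$m_BM_g, m_body_g = mc$m_body_g,
                 m_high_g = mc$m_high_g %||% 0, preset = mc$preset)
}

#' One-command planar dosimetry run
#'
#' Executes the full workflow on a stored scan: geometric-mean image,
#' threshold sweep and automatic two-compartment segmentation,
#' self-calibrated scale factors from the counts ratio at the scan time,
#' closed-form cumulated activities, and the MIRD bone-marrow dose report.
#' Skeletal-lesion foci (configured by focus label) contribute a separate
#' beta term: their share of the high-compartment cumulated activity,
#' allocated proportionally to focus counts, is moved from the high-
#' compartment source to the lesion source.
#'
#' @param scan_path Scan directory for [read_planar_scan()], or a
#'   `planar_scan` object.
#' @param config_path YAML study configuration (see [read_study_config()]),
#'   a `study_config` object, or `NULL` for defaults.
#' @param out_dir Optional output directory; when given, writes
#'   `nuf_curve.csv`, `body_mask.csv` / `high_mask.csv` / `low_mask.csv`
#'   (run-length CSV) and `report.json` (component breakdown plus the
#'   complete resolved configuration; floats at 9 significant digits).
#' @return The `dose_report`, with the segmentation, scale factors and
#'   resolved config attached; invisibly when `out_dir` is given.
#' @export
run_planar_dosimetry <- function(scan_path, config_path = NULL,
                                 out_dir = NULL) {
  cfg <- if (inherits(config_path, "study_config")) config_path
         else read_study_config(config_path)
  scan <- if (inherits(scan_path, "planar_scan")) scan_path
          else read_planar_scan(scan_path)
  kin <- kinetics_from_config(cfg$kinetics)
  sc <- cfg$segmentation
  dc <- cfg$dosimetry

  gm <- geometric_mean_image(scan)
  curve <- nuf_curve(gm, n_steps = sc$n_steps,
                     connectivity = sc$connectivity)
  thr <- if (sc$selection == "plateau") select_plateau_threshold(curve)
         else select_segmentation_threshold(curve, sc$nnuf_cutoff)
  body <- body_mask(gm, sc$body_fraction, sc$connectivity)
  seg <- segment_compartments(gm, thr$chosen_Cthr, body, sc$connectivity,
                              scan$acquisition_duration_s)
  rho <- counts_ratio(seg)
  A0 <- parse_activity_MBq(scan$patient$administered_activity_MBq)
  sf <- solve_scale_factors(A0, rho, scan$time_post_admin_h, kin)
  cum <- list(A_tilde_high = cumulated_activity_high(sf),
              A_tilde_low = cumulated_activity_low(sf))

  lesion_labels <- cfg$lesions$skeletal_focus_labels
  if (length(lesion_labels)) {
    bad <- setdiff(lesion_labels, seq_along(seg$foci))
    if (length(bad)) stop("skeletal_focus_labels outside 1..",
                          length(seg$foci), ": ",
                          paste(bad, collapse = ", "))
    seg$skeletal_lesion_labels <- as.integer(lesion_labels)
    gmv <- gm$values
    lesion_counts <- sum(vapply(lesion_labels,
      function(i) sum(gmv[seg$foci[[i]]]), numeric(1)))
    share <- lesion_counts / seg$counts_high
    cum$A_tilde_SL <- cum$A_tilde_high * share
    cum$A_tilde_high <- cum$A_tilde_high * (1 - share)
  }

  phantom <- if (identical(dc$phantom, "from_scan")) scan$patient$sex
             else dc$phantom
  masses_cfg <- dc$masses
  if (is.null(masses_cfg$preset) && is.null(masses_cfg$m_BM_g))
    masses_cfg$preset <- if (phantom == "F") "icrp_adult_female"
                         else "icrp_adult_male"
  masses <- masses_from_config(masses_cfg)
  sfactors <- if (!is.null(dc$sfactors_csv))
    load_sfactor_table(dc$sfactors_csv) else NULL
  s_override <- if (!is.null(dc$S_override)) unlist(dc$S_override) else NULL
  bm_cfg <- list(kappa = dc$kappa, delta_keV = dc$delta_keV, phi = dc$phi,
                 phi_SL = dc$phi_SL, self_dose_mode = dc$self_dose_mode,
                 m_SL_affected_g = dc$m_SL_affected_g %||% masses$m_BM_g,
                 phantom = phantom, high_region = dc$high_region,
                 low_region = dc$low_region, bm_region = dc$bm_region,
                 S_override = s_override)
  report <- bm_dose(cum, sfactors, masses, bm_cfg)
  report$segmentation <- seg
  report$scale_factors <- sf
  report$nuf_curve <- curve
  report$config <- cfg

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nuf_curve(curve, file.path(out_dir, "nuf_curve.csv"))
    write_mask_rle(seg$body_mask, file.path(out_dir, "body_mask.csv"))
    write_mask_rle(seg$high_mask, file.path(out_dir, "high_mask.csv"))
    write_mask_rle(seg$low_mask, file.path(out_dir, "low_mask.csv"))
    write_dose_report_json(report, file.path(out_dir, "report.json"))
    return(invisible(report))
  }
  report
}

#' Serialize a dose report to JSON
#'
#' Versioned schema, stable key order, floats at 9 significant digits, so
#' re-running identical inputs yields byte-identical files.
#'
#' @param report A `dose_report` (normally from [run_planar_dosimetry()]).
#' @param path Output JSON file.
#' @export
write_dose_report_json <- function(report, path) {
  sig <- function(x) if (is.numeric(x)) signif(x, 9) else x
  seg <- report$segmentation
  out <- list(
    schema = "planardose-report/1",
    D_BM_total_Gy = sig(report$D_BM_total_Gy),
    components_Gy = lapply(as.list(report$components), sig),
    cumulated_MBq_h = lapply(report$inputs$cumulated, sig),
    scale_factors = if (!is.null(report$scale_factors)) list(
      S_high_MBq = sig(report$scale_factors$S_high_MBq),
      S_low_MBq = sig(report$scale_factors$S_low_MBq),
      A0_MBq = sig(report$scale_factors$A0_MBq),
      t_obs_h = sig(report$scale_factors$t_obs_h),
      rho = sig(report$scale_factors$rho)),
    segmentation = if (!is.null(seg)) list(
      chosen_Cthr = sig(seg$chosen_Cthr),
      chosen_ThI = sig(seg$chosen_ThI),
      counts_high = sig(seg$counts_high),
      counts_low = sig(seg$counts_low),
      n_foci = length(seg$foci),
      skeletal_lesion_labels = seg$skeletal_lesion_labels),
    masses_g = lapply(report$inputs$masses, sig),
    dosimetry_params = lapply(report$inputs$config, sig),
    resolved_config = unclass(report$config))
  out <- Filter(Negate(is.null), out)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}
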