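synthetic_sfactors <- function() {
  load_sfactor_table(system.file("extdata", "sfactors_synthetic.csv",
                                 package = "planardose"))
}

test_that("S-factor tables load, validate and reject silent misses", {
  tab <- synthetic_sfactors()
  expect_s3_class(tab, "sfactor_table")
  expect_equal(nrow(tab$entries), 8)
  expect_equal(sfactor(tab, "high", "red_marrow", "M"), 2.6e-4)
  expect_equal(sfactor(tab, "red_marrow", "red_marrow", "F"), 94.2)
  expect_error(sfactor(tab, "liver", "red_marrow", "M"), "no S entry")

  dir <- withr::local_tempdir()
  f <- file.path(dir, "s.csv")
  writeLines(c("phantom,source_region,target_region,S_mGy_per_MBq_h",
               "M,a,b,1.0", "M,a,b,2.0"), f)
  expect_error(load_sfactor_table(f), "duplicate")
  writeLines(c("phantom,source_region,target_region,S_mGy_per_MBq_h",
               "M,a,b,-1.0"), f)
  expect_error(load_sfactor_table(f), ">= 0")
  writeLines(c("phantom,source,target", "M,a,b"), f)
  expect_error(load_sfactor_table(f), "missing columns")
})

test_that("unit column converts S values to mGy/(MBq h) at load", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s.csv")
  writeLines(c("phantom,source_region,target_region,S_mGy_per_MBq_h,unit",
               "M,a,b,1.0,Gy_per_MBq_h",
               "M,c,b,3600,uGy_per_MBq_h",
               "M,d,b,0.001,mGy_per_MBq_s"), f)
  tab <- load_sfactor_table(f)
  expect_equal(sfactor(tab, "a", "b", "M"), 1000)
  expect_equal(sfactor(tab, "c", "b", "M"), 3.6)
  expect_equal(sfactor(tab, "d", "b", "M"), 3.6)
  writeLines(c("phantom,source_region,target_region,S_mGy_per_MBq_h,unit",
               "M,a,b,1.0,furlongs"), f)
  expect_error(load_sfactor_table(f), "unknown S-value unit")
})

test_that("MIRD sum weights cumulated activities by S factors", {
  tab <- sfactor_table(data.frame(
    phantom = "M", source_region = c("x", "y"), target_region = "t",
    S_mGy_per_MBq_h = c(2, 4)))
  expect_equal(mird_dose(c(x = 1, y = 0), tab, "t"), 0.002)
  expect_equal(mird_dose(c(x = 0, y = 0), tab, "t"), 0)
  expect_equal(mird_dose(c(x = 10, y = 5), tab, "t"), 0.040)
  expect_error(mird_dose(c(z = 1), tab, "t"), "no S entry")
  expect_error(mird_dose(c(1, 2), tab, "t"), "named")
})

test_that("marrow cumulated activity scales from the low compartment", {
  ms <- phantom_masses(m_BM_g = 1200, m_body_g = 61200,
                       m_low_g = 60000)
  expect_equal(bm_cumulated_from_low(1000, 0, ms), 0)
  expect_equal(bm_cumulated_from_low(1000, 1, ms), 20)
  ms2 <- phantom_masses(m_BM_g = 1000, m_body_g = 70000, m_low_g = 1000)
  expect_equal(bm_cumulated_from_low(123, 1, ms2), 123)
  expect_error(phantom_masses(m_BM_g = -1, m_body_g = 100), "> 0")
  expect_error(phantom_masses(m_BM_g = 200, m_body_g = 100),
               "not exceed")
})

test_that("concentration self-dose applies the unit-conversion chain", {
  # independent arithmetic: MBq h/g -> decays/g -> J/g -> Gy
  expected <- (1e6 * 3600) * (147e3 * 1.602176634e-19) / 1e-3
  expect_equal(bm_self_dose_concentration(1, 1, 147), expected)
  expect_equal(bm_self_dose_concentration(1, 1, 147), 0.0848,
               tolerance = 2e-3)
  expect_equal(bm_self_dose_concentration(0, 1, 147), 0)
  expect_equal(bm_self_dose_concentration(1, 0.5, 147), expected / 2)
  expect_error(bm_self_dose_concentration(-1), ">= 0")
  expect_error(bm_self_dose_concentration(1, 2), "phi")
})

test_that("marrow dose report assembles and decomposes the MIRD terms", {
  masses <- phantom_masses(preset = "icrp_adult_male")
  tab <- synthetic_sfactors()
  cum <- list(A_tilde_high = 400000, A_tilde_low = 50000)
  rep <- bm_dose(cum, tab, masses, list(kappa = 1))
  # independent hand assembly of the same terms
  a_bm <- 1 * 50000 / masses$m_low_g * masses$m_BM_g
  self <- (a_bm / masses$m_BM_g) * 1e6 * 3600 * 147e3 *
    1.602176634e-19 / 1e-3
  expect_equal(rep$components[["self"]], self)
  expect_equal(rep$components[["from_high"]], 400000 * 2.6e-4 * 1e-3)
  expect_equal(rep$components[["from_low"]], 50000 * 2.0e-4 * 1e-3)
  expect_equal(rep$components[["from_SL"]], 0)
  expect_equal(rep$D_BM_total_Gy, sum(rep$components))

  # with a lesion term, the report reduces to the no-lesion one at SL = 0
  rep_sl <- bm_dose(c(cum, list(A_tilde_SL = 0)), tab, masses)
  expect_equal(rep_sl$D_BM_total_Gy, rep$D_BM_total_Gy)
  rep_sl2 <- bm_dose(c(cum, list(A_tilde_SL = 2000)), tab, masses,
                     list(phi_SL = 0.8, m_SL_affected_g = 300))
  expect_equal(rep_sl2$components[["from_SL"]],
               bm_self_dose_concentration(2000 / 300, 0.8, 147))

  # uniform S factorizes over total cumulated activity (sfactor self mode)
  utab <- sfactor_table(data.frame(
    phantom = "M",
    source_region = c("red_marrow", "high", "low"),
    target_region = "red_marrow", S_mGy_per_MBq_h = 5))
  rep_u <- bm_dose(cum, utab, masses,
                   list(self_dose_mode = "sfactor", kappa = 1))
  expect_equal(rep_u$D_BM_total_Gy,
               5e-3 * (a_bm + cum$A_tilde_high + cum$A_tilde_low))
})

test_that("concentration mode equals the S-matrix mode with the derived self-S", {
  masses <- phantom_masses(preset = "icrp_adult_male")
  # self-S implied by full local absorption of 147 keV in the marrow mass
  s_self <- (1e6 * 3600) * (147e3 * 1.602176634e-19) /
    (masses$m_BM_g * 1e-3) * 1e3   # mGy/(MBq h)
  tab <- sfactor_table(data.frame(
    phantom = "M",
    source_region = c("red_marrow", "high", "low"),
    target_region = "red_marrow",
    S_mGy_per_MBq_h = c(s_self, 2.6e-4, 2.0e-4)))
  cum <- list(A_tilde_high = 123456, A_tilde_low = 65432)
  r_conc <- bm_dose(cum, tab, masses,
                    list(self_dose_mode = "concentration", phi = 1))
  r_sfac <- bm_dose(cum, tab, masses, list(self_dose_mode = "sfactor"))
  expect_equal(r_conc$D_BM_total_Gy, r_sfac$D_BM_total_Gy,
               tolerance = 1e-12)
})

test_that("dose grids are strictly linear in administered activity", {
  kin <- lu_kin()
  mM <- phantom_masses(preset = "icrp_adult_male")
  mF <- phantom_masses(preset = "icrp_adult_female")
  tab <- synthetic_sfactors()
  grid <- dose_table(c(5600, 7400, 8300), list(c(57, 43), c(63, 37)),
                     kin, mM, mF, tab)
  expect_equal(nrow(grid), 12)
  for (sp in c(57, 63)) for (ph in c("M", "F")) {
    d <- grid[grid$high_pct == sp & grid$phantom == ph, ]
    expect_equal(d$D_BM_Gy[d$A0_MBq == 8300] /
                   d$D_BM_Gy[d$A0_MBq == 5600], 8300 / 5600,
                 tolerance = 1e-12)
  }
  # higher focal share shifts dose between compartments monotonically
  expect_error(dose_table(7400, list(c(60, 30)), kin, mM, mF, tab),
               "summing to 100")
  # all-zero S and kappa = 0 gives an all-zero table
  ztab <- sfactor_table(data.frame(
    phantom = rep(c("M", "F"), each = 2),
    source_region = c("high", "low"), target_region = "red_marrow",
    S_mGy_per_MBq_h = 0))
  zgrid <- dose_table(7400, list(c(57, 43)), kin, mM, mF, ztab,
                      list(kappa = 0))
  expect_true(all(zgrid$D_BM_Gy == 0))
})
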