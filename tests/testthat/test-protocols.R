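test_that("protocol configuration validates windows and agents", {
  cfg <- protocol_config("thermodox", 50)
  expect_equal(cfg$agent, "thermodox")
  expect_false(is.null(cfg$hyperthermia_window))
  expect_error(protocol_config("classical_chemo", 50, agent = "thermodox"),
               "hyperthermia")
  expect_error(protocol_config("classical_chemo", -5), "non-negative")
  p <- default_params()
  p$protocol$hyperthermia_window <- c(0, 48 * 3600)  # beyond the simulation
  expect_error(protocol_config("thermochemo", 50, params = p), "within")
})

test_that("a zero-dose run reduces to drug-free exponential growth", {
  p <- default_params()
  res <- run_protocol(protocol_config("classical_chemo", 0, params = p))
  oracle <- exp((p$pd$k_p - p$pd$k_deg) * res$series$time)
  expect_equal(res$series$N, oracle, tolerance = 1e-10)
  expect_equal(max(res$series$CF_ecm), 0)
})

test_that("identical configurations reproduce bit-identical results", {
  p <- default_params()
  p$protocol$total_sim_time <- 2 * 3600
  cfg <- protocol_config("classical_chemo", 50, params = p)
  r1 <- run_protocol(cfg)
  r2 <- run_protocol(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final, r2$final)
})

test_that("every concentration trajectory is linear in the injected dose", {
  s50 <- get_run("classical50")$series
  s100 <- get_run("classical100")$series
  cols <- c("F_sys", "B_sys", "CF_ecm", "CB_ecm", "C_int")
  for (cl in cols) {
    expect_equal(s100[[cl]], 2 * s50[[cl]], tolerance = 1e-9)
  }
  # hence concentration ratios between protocols are dose-invariant
  expect_equal(get_run("classical100")$summary$peak_interstitial_free,
               2 * get_run("classical50")$summary$peak_interstitial_free,
               tolerance = 1e-9)
})

test_that("whole-system drug mass is audited to well under 0.5%", {
  for (nm in c("classical50", "thermochemo50", "thermodox50")) {
    expect_lt(get_run(nm)$summary$max_mass_error, 0.005)
  }
})

test_that("free drug accumulates preferentially in the proliferative zone", {
  res <- get_run("classical50")
  g <- build_domain(default_params())
  # exposure integrated over the delivery phase (first 6 h); at much later
  # times the slowly draining core dominates the residue instead
  phase <- res$snapshot_times <= 6 * 3600
  cum_cf <- rowSums(res$snapshots$CF[, phase])
  i_max <- which.max(cum_cf)
  expect_equal(as.character(g$zones$zone[i_max]), "proliferative")
  # and the spatial maximum at the concentration peak is in the same zone
  s <- res$series
  j <- which.min(abs(res$snapshot_times - s$time[which.max(s$CF_ecm)]))
  expect_equal(as.character(g$zones$zone[which.max(res$snapshots$CF[, j])]),
               "proliferative")
})

test_that("intracellular drug peaks about 20 minutes after extracellular free drug", {
  s <- get_run("classical50")$series
  lag <- s$time[which.max(s$C_int)] - s$time[which.max(s$CF_ecm)]
  expect_gte(lag, 15 * 60)
  expect_lte(lag, 25 * 60)
})

test_that("intracellular drug washes out after the exposure ends", {
  s <- get_run("classical50")$series
  pk <- max(s$C_int)
  i_pk <- which.max(s$C_int)
  # monotone decline after the peak (no secondary accumulation)
  expect_true(all(diff(s$C_int[i_pk:length(s$C_int)]) <= 1e-12))
  expect_lt(s$C_int[s$time == 24 * 3600], 0.01 * pk)
})

test_that("mild hyperthermia increases interstitial free-drug exposure", {
  s_cl <- get_run("classical50")$series
  s_tc <- get_run("thermochemo50")$series
  expect_gt(sum(s_tc$CF_ecm), sum(s_cl$CF_ecm))
  expect_gt(max(s_tc$CF_ecm), max(s_cl$CF_ecm))
})

test_that("liposome release collapses vessel liposomes and boosts free drug", {
  s <- get_run("thermodox50")$series
  # sharp intravascular release during the heating hour: within the window,
  # vessel liposomes peak early and are largely consumed by its end
  # (afterwards they re-accumulate from the still-circulating systemic pool)
  win <- s$time <= 3600
  i_pk <- which.max(s$T_ves[win])
  expect_lt(s$time[win][i_pk], 1800)
  expect_lt(s$T_ves[s$time == 3600], 0.5 * max(s$T_ves[win]))
  fold <- compare_free_drug_gain(get_run("thermodox50"), get_run("classical50"))
  expect_gt(fold, 2.6)
  expect_equal(compare_free_drug_gain(get_run("classical50"),
                                      get_run("classical50")), 1)
  expect_error(compare_free_drug_gain(get_run("thermodox50"),
                                      get_run("classical100")), "dose")
})

test_that("liposomes accumulate at the tumor periphery during the supply phase", {
  res <- get_run("thermodox50")
  g <- res$domain
  i_rim <- which.min(abs(g$r - 4.9e-3))
  early <- res$snapshot_times > 0 & res$snapshot_times <= 4 * 3600
  expect_true(all(res$snapshots$CT[i_rim, early] >
                    res$snapshots$CT[1, early]))
})

test_that("drug returns to the microvessels after the heating window ends", {
  res <- get_run("thermodox50")
  p <- default_params()
  g <- res$domain
  j <- which(res$snapshot_times == 7200)       # 1 h after heating stops
  tum <- g$in_tumor
  Fv <- res$series$F_ves[res$series$time == 7200]
  zones <- build_domain(p)$zones
  J <- transvascular_flux(Fv, res$snapshots$CF[tum, j], res$flow$phi_v[tum],
                          p$transport$P_F[["tumor"]],
                          p$transport$sigma_f_F[["tumor"]],
                          zones$sv[tum], 37, p)
  expect_lt(min(J), 0)
})

test_that("protocols rank ThermoDox > thermochemo > classical in 24-h kill", {
  k_cl <- get_run("classical50")$summary$kill_end
  k_tc <- get_run("thermochemo50")$summary$kill_end
  k_td <- get_run("thermodox50")$summary$kill_end
  expect_gt(k_td, k_tc)
  expect_gt(k_tc, k_cl)
})

test_that("kill fractions are monotone in the injected dose", {
  k <- vapply(c("classical50", "classical100", "classical150"),
              function(nm) get_run(nm)$summary$kill_6h, numeric(1))
  expect_true(all(diff(k) > 0))
})

test_that("hyperthermia delays the tumor growth onset", {
  o_cl <- get_run("classical50")$summary$growth_onset
  o_tc <- get_run("thermochemo50")$summary$growth_onset
  o_td <- get_run("thermodox50")$summary$growth_onset
  expect_gt(o_tc, o_cl)
  # the liposome protocol suppresses regrowth at least as long again
  expect_true(is.na(o_td) || o_td > o_tc)
})

test_that("ablation-first necroses the core and starves the sublethal ring", {
  res <- get_ablation_run()
  zr <- as.character(res$ablation$zones_radial)
  # lesion nested inside the tumor
  expect_lt(res$ablation$radii[["gamma"]], res$domain$tumor_radius)
  expect_true(all(res$final$N[zr == "alpha"] == 0))
  # sublethal ring survives ablation but sees sub-therapeutic drug
  beta <- zr == "beta"
  expect_true(all(res$final$N[beta] > 0))
  p <- central_lesion_params()
  beta_cint <- max(colMeans(res$snapshots$Cint[beta, , drop = FALSE]))
  expect_lt(beta_cint, p$pd$EC50)
  # the undamaged proliferative rim is exposed above EC50
  zz <- as.character(build_domain(p)$zones$zone)
  intact <- zz == "proliferative" & res$flow$damage == 1
  expect_gt(max(colMeans(res$snapshots$Cint[intact, , drop = FALSE])),
            p$pd$EC50)
  # perfusion damage propagated into the flow solve
  expect_true(all(res$flow$phi_v[zr == "alpha"] == 0))
})

test_that("medication-first applies ablation at the end of the window", {
  p <- central_lesion_params()
  p$protocol$total_sim_time <- 6 * 3600
  res <- run_protocol(protocol_config("medication_then_ablation", 50,
                                      params = p))
  zr <- as.character(res$ablation$zones_radial)
  expect_true(all(res$final$N[zr == "alpha"] == 0))
  # during the medication window the core was still alive (drug saw cells)
  expect_gt(res$series$N[res$series$time == 3 * 3600], 0.5)
})
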