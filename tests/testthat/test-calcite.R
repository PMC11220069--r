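reg <- default_registry()

test_that("coccolith calcite follows the shape-factor model", {
  expect_equal(coccolith_pic(1.8, 0.03), 0.472392, tolerance = 1e-9)
  expect_equal(round(coccolith_pic(1.8, 0.03), 2), 0.47)
  expect_equal(coccolith_pic(5, 0.007), 2.3625, tolerance = 1e-12)
  expect_equal(coccolith_pic(1e-6, 0.05), 0.05 * 1e-18 * 2.7)
  expect_error(coccolith_pic(0, 0.03), "positive")
  expect_error(coccolith_pic(2, -1), "positive")
})

test_that("shape-factor back-calculation inverts the mass model", {
  expect_equal(back_calculate_ks(2.5, 5), 2.5 / (125 * 2.7),
               tolerance = 1e-12)
  expect_equal(signif(back_calculate_ks(2.5, 5), 1), 0.007)
  expect_equal(back_calculate_ks(2.7, 1), 1)
  set.seed(13)
  for (i in 1:20) {
    cl <- stats::runif(1, 0.5, 15); ks <- stats::runif(1, 0.005, 0.2)
    expect_equal(back_calculate_ks(coccolith_pic(cl, ks), cl), ks,
                 tolerance = 1e-12)
  }
})

test_that("cellular calcite multiplies per-coccolith mass by count", {
  expect_equal(cellular_pic(coccolith_pic(1.8, 0.03), 14), 6.613488,
               tolerance = 1e-9)
  expect_equal(cellular_pic(3.21, 1), 3.21)
  expect_equal(cellular_pic(2.3625, 20), 47.25)
  expect_error(cellular_pic(1, 0), ">= 1")
})

test_that("appendage rules reproduce the arm-calcite constants", {
  mich <- resolve_taxon(taxon_key("Michaelsarsia"), reg)
  oph <- resolve_taxon(taxon_key("Ophiaster"), reg)
  a <- appendage_calcite(mich, n_appendages = NA)
  expect_equal(a$mass, 100)
  expect_true(a$assumed)
  expect_equal(appendage_calcite(mich, n_appendages = 10)$mass, 125)
  expect_equal(appendage_calcite(oph, present = TRUE)$mass, 33)
  expect_equal(appendage_calcite(oph, present = FALSE)$mass, 0)
  ehux <- resolve_taxon(taxon_key("Emiliania", "huxleyi"), reg)
  expect_error(appendage_calcite(ehux, 2), "no appendage rule")
})

test_that("dimorphic coccospheres split 50/50 with a 5 um spine fallback", {
  rh <- resolve_taxon(taxon_key("Rhabdosphaera", "clavigera"), reg)
  dm <- dimorphic_pic(2.0, NA, 20, rh)
  expect_equal(dm$body_total, 10 * 0.025 * 8 * 2.7)       # 0.54 pg each
  expect_equal(dm$spinose_total, 10 * rh$ks_spinose * 125 * 2.7)
  expect_true(dm$spine_fallback_used)
  dm2 <- dimorphic_pic(2.0, 6.2, 20, rh)
  expect_equal(dm2$spinose_total, 10 * rh$ks_spinose * 6.2^3 * 2.7)
  expect_false(dm2$spine_fallback_used)
  # degenerate fraction reduces to the monomorphic model
  rh0 <- rh; rh0$dimorphic_spinose_fraction <- 0
  expect_equal(dimorphic_pic(2.0, NA, 20, rh0)$body_total,
               cellular_pic(coccolith_pic(2.0, rh$ks_body), 20))
  expect_error(dimorphic_pic(2.0, NA, 0, rh), ">= 1")
})

test_that("exothecal calcite counts XCs at the shared shape factor", {
  expect_equal(exothecal_calcite(0, 2), 0)
  expect_equal(exothecal_calcite(10, 2, 0.02), 4.32, tolerance = 1e-12)
  expect_equal(exothecal_calcite(1, 1, 0.02), 0.054, tolerance = 1e-12)
  expect_error(exothecal_calcite(-1, 2), ">= 0")
})

test_that("holococcolith counts back-calculate from surface areas", {
  expect_equal(holococcolith_cn_estimate(8, 2, 1.5), 85)
  expect_equal(holococcolith_cn_estimate(3, 3, 3), 4)   # scale-free ratio
  expect_equal(holococcolith_cn_estimate(4, 1, 1), 64)
  expect_error(holococcolith_cn_estimate(0.3, 1, 1), "count < 1")
  expect_error(holococcolith_cn_estimate(8, 1.5, 2), "c_w")
  # halving the packing halves the count
  expect_equal(holococcolith_cn_estimate(8, 2, 1.5, packing = 0.5),
               round(0.5 * 4 * 64 / 3))
})

test_that("Umbellosphaera average length is the cubic mean of sizes", {
  u <- umbellosphaera_average_cl(c(3, 3, 3))
  expect_equal(u$average_cl, 3)
  expect_equal(u$ratio_to_max, 1)
  u <- umbellosphaera_average_cl(c(2, 4))
  expect_equal(u$average_cl, 36^(1 / 3), tolerance = 1e-12)
  expect_equal(u$ratio_to_max, 36^(1 / 3) / 4, tolerance = 1e-12)
  u <- umbellosphaera_average_cl(c(1, 1, 5))
  expect_equal(u$average_cl, (127 / 3)^(1 / 3), tolerance = 1e-12)
  expect_equal(u$ratio_to_max, 0.697, tolerance = 1e-3)
  expect_error(umbellosphaera_average_cl(numeric(0)), "non-empty")
  # cubic mean dominates the arithmetic mean; ratio is 1 iff sizes equal
  set.seed(17)
  for (i in 1:10) {
    lens <- stats::rlnorm(sample(2:30, 1), log(5), 0.3)
    u <- umbellosphaera_average_cl(lens)
    expect_gte(u$average_cl, mean(lens) - 1e-12)
    expect_lte(u$ratio_to_max, 1)
    if (stats::sd(lens) > 1e-8) expect_lt(u$ratio_to_max, 1)
  }
})

test_that("total cellular calcite orchestrates the fallback rules", {
  # Florisphaera: fixed count 145
  fl <- resolve_taxon(taxon_key("Florisphaera", "profunda",
                                life_cycle_phase = "nannolith"), reg)
  bd <- total_cell_calcite(make_record(cl = 2), fl)
  expect_equal(bd$cellular_pic, 0.03 * 8 * 2.7 * 145, tolerance = 1e-12)
  expect_true("fixed_cn_used" %in% bd$flags)

  # Michaelsarsia: body calcite plus 100 pg assumed appendages
  mich <- resolve_taxon(taxon_key("Michaelsarsia"), reg)
  bd <- total_cell_calcite(make_record(cl = 3.5, cn = 18), mich)
  body <- cellular_pic(coccolith_pic(3.5, mich$ks_body), 18)
  expect_equal(bd$cellular_pic, body + 100, tolerance = 1e-12)
  expect_true("appendages_assumed" %in% bd$flags)

  # plain record reduces to coccolith PIC x C_N
  sy <- resolve_taxon(taxon_key("Syracosphaera",
                                morpho_group = "molischii group"), reg)
  bd <- total_cell_calcite(make_record(cl = 2.5, cn = 24), sy)
  expect_equal(bd$cellular_pic, cellular_pic(coccolith_pic(2.5, 0.022), 24),
               tolerance = 1e-12)

  # missing measurement with no fallback errors with the record id
  expect_error(total_cell_calcite(make_record(record_id = "x9", cn = 10), sy),
               "x9")
  expect_error(total_cell_calcite(make_record(record_id = "x9", cl = 2), sy),
               "x9")
})

test_that("cellular calcite equals an explicit per-coccolith enumeration", {
  # brute-force oracle: list every component coccolith and sum the mass model
  set.seed(23)
  sy <- resolve_taxon(taxon_key("Syracosphaera",
                                morpho_group = "pulchra group"), reg)
  for (i in 1:15) {
    cl <- stats::runif(1, 1, 9)
    cn <- sample(6:60, 1)
    n_xc <- sample(0:12, 1)
    xc_len <- stats::runif(1, 0.5, 6)
    rec <- make_record(cl = cl, cn = cn, n_xc = n_xc, xc_len = xc_len)
    bd <- total_cell_calcite(rec, sy)
    component_lengths <- c(rep(cl, cn), rep(xc_len, n_xc))
    component_ks <- c(rep(sy$ks_body, cn), rep(sy$ks_exothecal, n_xc))
    oracle <- sum(component_ks * component_lengths^3 * 2.7)
    expect_equal(bd$cellular_pic, oracle, tolerance = 1e-12)
  }
})

test_that("breakdown components always sum to cellular calcite", {
  set.seed(29)
  taxa <- list(
    list(key = taxon_key("Syracosphaera", morpho_group = "pulchra group"),
         xc = TRUE),
    list(key = taxon_key("Michaelsarsia"), app = TRUE),
    list(key = taxon_key("Rhabdosphaera", "clavigera")),
    list(key = taxon_key("Ophiaster"), present = TRUE))
  for (t in taxa) {
    p <- resolve_taxon(t$key, reg)
    rec <- make_record(cl = stats::runif(1, 1, 6), cn = sample(8:40, 1),
                       n_xc = if (isTRUE(t$xc)) 5 else 0, xc_len = 2,
                       n_app = if (isTRUE(t$app)) 7 else NA,
                       app_present = isTRUE(t$present))
    bd <- total_cell_calcite(rec, p)
    expect_identical(bd$cellular_pic,
                     bd$body_total + bd$cfc_total + bd$exothecal_total +
                       bd$appendage_total)
    expect_true(all(c(bd$body_total, bd$cfc_total, bd$exothecal_total,
                      bd$appendage_total) >= 0))
  }
})

test_that("calcite scales cubically in lengths except fixed appendage masses", {
  set.seed(31)
  sy <- resolve_taxon(taxon_key("Syracosphaera",
                                morpho_group = "pulchra group"), reg)
  mich <- resolve_taxon(taxon_key("Michaelsarsia"), reg)
  for (k in c(0.5, 1.7, 3)) {
    rec <- make_record(cl = 3, cn = 20, n_xc = 6, xc_len = 2)
    rec_k <- make_record(cl = 3 * k, cn = 20, n_xc = 6, xc_len = 2 * k)
    expect_equal(total_cell_calcite(rec_k, sy)$cellular_pic,
                 k^3 * total_cell_calcite(rec, sy)$cellular_pic,
                 tolerance = 1e-12)
    # appendage mass is a fixed constant, invariant under scaling
    rec2 <- make_record(cl = 3, cn = 20, n_app = 8)
    rec2_k <- make_record(cl = 3 * k, cn = 20, n_app = 8)
    expect_equal(total_cell_calcite(rec2_k, mich)$appendage_total,
                 total_cell_calcite(rec2, mich)$appendage_total)
  }
})
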