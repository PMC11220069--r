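reg <- default_registry()

clean_mix <- function() {
  # taxa whose calcite has no fixed-mass component (pure mass-model records)
  mix <- Filter(function(t) t$genus %in% c("Emiliania", "Syracosphaera"),
                coccotraits:::default_taxon_mix())
  tot <- sum(vapply(mix, `[[`, numeric(1), "abundance"))
  lapply(mix, function(t) { t$abundance <- t$abundance / tot; t })
}

test_that("closed-form perturbation responses match the narrated extremes", {
  expect_equal(closed_form_change("CL", -0.30), -65.7, tolerance = 1e-12)
  expect_equal(closed_form_change("CL", 0.30), 119.7, tolerance = 1e-12)
  expect_equal(closed_form_change("CL", 0.15), 52.0875, tolerance = 1e-12)
  expect_equal(closed_form_change("KS", 0), 0)
  expect_equal(closed_form_change("KS", 0.2), 20)
  expect_equal(closed_form_change("CN", -2, c_n = 9), -100 * 2 / 9,
               tolerance = 1e-12)
  expect_error(closed_form_change("CN", 2), "c_n")
})

test_that("recomputed sensitivity agrees with the closed forms to 1e-9", {
  cfg <- synthetic_config(taxon_mix = clean_mix(), within_sd = 0,
                          noise = no_noise(), seed = 101)
  sim <- generate_coccospheres(cfg, 25)
  sens <- run_sensitivity(sim$records, reg)
  cl <- sens[sens$parameter == "CL", ]
  for (j in seq_len(nrow(cl))) {
    expect_equal(cl$pct_change[j], closed_form_change("CL", cl$magnitude[j]),
                 tolerance = 1e-9)
  }
  ks <- sens[sens$parameter == "KS", ]
  for (j in seq_len(nrow(ks))) {
    expect_equal(ks$pct_change[j], closed_form_change("KS", ks$magnitude[j]),
                 tolerance = 1e-9)
  }
  # CN responses are exactly linear in the effective count for records
  # whose calcite is all body coccoliths (exothecal calcite does not follow
  # the body count, so XC-bearing records are excluded here)
  plain_ids <- sim$records$record_id[sim$records$n_exothecal == 0]
  cn_tab <- sens[sens$parameter == "CN" & sens$record_id %in% plain_ids, ]
  expect_gt(nrow(cn_tab), 0)
  eff_cn <- sim$truth$true_cn[match(cn_tab$record_id, sim$truth$record_id)]
  expect_equal(cn_tab$pct_change,
               unname(mapply(closed_form_change, "CN", cn_tab$magnitude,
                             c_n = eff_cn)),
               tolerance = 1e-9)
})

test_that("fixed appendage masses attenuate the length response", {
  mix <- Filter(function(t) t$genus == "Michaelsarsia",
                coccotraits:::default_taxon_mix())
  mix[[1]]$abundance <- 1
  cfg <- synthetic_config(taxon_mix = mix, within_sd = 0,
                          noise = no_noise(), seed = 7)
  sim <- generate_coccospheres(cfg, 10)
  sens <- run_sensitivity(sim$records, reg)
  cl <- sens[sens$parameter == "CL", ]
  for (j in seq_len(nrow(cl))) {
    expect_lt(abs(cl$pct_change[j]),
              abs(closed_form_change("CL", cl$magnitude[j])))
  }
})

test_that("KS and CN responses are antisymmetric; CL is not", {
  cfg <- synthetic_config(taxon_mix = clean_mix(), within_sd = 0,
                          noise = no_noise(), seed = 5)
  sim <- generate_coccospheres(cfg, 8)
  sens <- run_sensitivity(sim$records, reg)
  for (rid in unique(sens$record_id)) {
    s <- sens[sens$record_id == rid, ]
    for (m in c(0.05, 0.2)) {
      expect_equal(s$pct_change[s$parameter == "KS" & s$magnitude == m],
                   -s$pct_change[s$parameter == "KS" & s$magnitude == -m],
                   tolerance = 1e-9)
    }
    for (m in c(2, 5)) {
      expect_equal(s$pct_change[s$parameter == "CN" & s$magnitude == m],
                   -s$pct_change[s$parameter == "CN" & s$magnitude == -m],
                   tolerance = 1e-9)
    }
    expect_gt(s$pct_change[s$parameter == "CL" & s$magnitude == 0.2],
              -s$pct_change[s$parameter == "CL" & s$magnitude == -0.2])
  }
})

test_that("count perturbations floor the perturbed count at one", {
  sy <- resolve_taxon(taxon_key("Syracosphaera",
                                morpho_group = "molischii group"), reg)
  rec <- make_record(cl = 2.5, cn = 3)
  base <- total_cell_calcite(rec, sy)$cellular_pic
  pert <- total_cell_calcite(rec, sy, cn_delta = -5)$cellular_pic
  expect_equal(pert / base, 1 / 3, tolerance = 1e-12)  # floored at 1 of 3
})

test_that("degenerate sensitivity inputs error", {
  expect_error(run_sensitivity(data.frame(), reg), "non-empty")
  expect_error(perturbation_spec(rel_magnitudes = c(0.1, 1.2)), "\\(0, 1\\)")
  expect_error(perturbation_spec(cn_deltas = c(1.5)), "integers")
})
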