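reg <- default_registry()

test_that("default registry encodes the documented constants", {
  p <- resolve_taxon(taxon_key("Syracosphaera", morpho_group = "pulchra group"),
                     reg)
  expect_equal(p$ks_body, 0.03)
  expect_equal(p$y_fraction, 0.65)
  expect_identical(p$resolution_level, "morpho_group")

  p <- resolve_taxon(taxon_key("Alisphaera", life_cycle_phase = "polycrater"),
                     reg)
  expect_equal(p$fixed_cn, 400)
  expect_equal(p$fixed_cl, 0.8)

  p <- resolve_taxon(taxon_key("Florisphaera", "profunda",
                               life_cycle_phase = "nannolith"), reg)
  expect_equal(p$fixed_cn, 145)
  expect_equal(p$y_fraction, 0.10)
  expect_equal(p$ks_body, 0.03)

  p <- resolve_taxon(taxon_key("Emiliania", "huxleyi"), reg)
  expect_equal(p$y_fraction, 0.86)
  expect_equal(p$coccolith_thickness, 0.13)

  p <- resolve_taxon(taxon_key("Umbellosphaera"), reg)
  expect_equal(p$cn_multiplier, 3)
  expect_equal(p$umbellosphaera_cl_factor, 0.7)

  p <- resolve_taxon(taxon_key("Rhabdosphaera", "clavigera"), reg)
  expect_equal(p$ks_body, 0.025)
  expect_equal(p$dimorphic_spinose_fraction, 0.5)
  expect_equal(p$fixed_spine_length, 5)

  p <- resolve_taxon(taxon_key("Michaelsarsia"), reg)
  expect_equal(p$appendage_pg_per_appendage, 12.5)
  expect_equal(p$appendage_default_count, 8)

  p <- resolve_taxon(taxon_key("Ophiaster"), reg)
  expect_equal(p$appendage_fixed_total_pg, 33)

  p <- resolve_taxon(taxon_key("Calciosolenia"), reg)
  expect_equal(p$ks_body, 0.007)
  expect_identical(p$shape_class, "DOUBLE_CONE")
})

test_that("resolution falls back species -> group -> genus -> phase default", {
  # Syracosphaera not identified to species or group: genus-level 0.02
  p <- resolve_taxon(taxon_key("Syracosphaera"), reg)
  expect_equal(p$ks_body, 0.02)
  expect_identical(p$resolution_level, "genus")
  # unknown species of a known genus falls through to the genus row
  p <- resolve_taxon(taxon_key("Syracosphaera", "nonexistens"), reg)
  expect_identical(p$resolution_level, "genus")
  # any holococcolith-phase key without a species entry hits the default
  p <- resolve_taxon(taxon_key("Calyptrolithina", "multipora",
                               life_cycle_phase = "holococcolith"), reg)
  expect_equal(p$ks_body, 0.036)
  expect_equal(p$y_fraction, 0.80)
  expect_identical(p$resolution_level, "phase_default")
  # unknown genus: strict errors, lenient returns NULL
  expect_error(resolve_taxon(taxon_key("Nullosphaera"), reg), "unresolved")
  expect_null(resolve_taxon(taxon_key("Nullosphaera"), reg, strict = FALSE))
})

test_that("matching is case-insensitive and deterministic", {
  a <- resolve_taxon(taxon_key("EMILIANIA", "HUXLEYI"), reg)
  b <- resolve_taxon(taxon_key("emiliania", "huxleyi"), reg)
  expect_identical(a, b)
  expect_identical(a$ks_body,
                   resolve_taxon(taxon_key("Emiliania", "huxleyi"),
                                 reg)$ks_body)
})

test_that("registry round-trips through write/load exactly", {
  f <- tempfile(fileext = ".csv")
  write_registry(reg, f)
  reg2 <- load_registry(f)
  for (col in coccotraits:::REGISTRY_NUMERIC_COLS) {
    expect_identical(reg[[col]], reg2[[col]])
  }
  expect_identical(reg$genus, reg2$genus)
})

test_that("malformed registries are rejected with named fields", {
  df <- as.data.frame(reg)
  f <- tempfile(fileext = ".csv")

  bad <- df; bad$ks_body[1] <- 1.5
  write_registry(structure(bad, class = class(reg)), f)
  expect_error(load_registry(f), "ks_body")

  bad <- df; bad$cn_multiplier[2] <- 5
  write_registry(structure(bad, class = class(reg)), f)
  expect_error(load_registry(f), "cn_multiplier")

  bad <- rbind(df, df[1, ])
  write_registry(structure(bad, class = class(reg)), f)
  expect_error(load_registry(f), "duplicate")

  writeLines(paste(coccotraits:::REGISTRY_COLS, collapse = ","), f)
  expect_error(load_registry(f), "no rows")
})

test_that("every taxon in the packaged synthetic mix resolves", {
  for (t in coccotraits:::default_taxon_mix()) {
    key <- taxon_key(genus = t$genus, species = t$species,
                     morpho_group = t$morpho_group,
                     life_cycle_phase = t$phase)
    expect_no_error(resolve_taxon(key, reg))
  }
})
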