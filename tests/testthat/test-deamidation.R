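test_that("peptide occupancy follows the intensity-weighted convention", {
  # one Q; unmodified at 3e6, deamidated at 1e6 -> 1e6/4e6
  psms <- rbind(
    make_psm("s1", "GAQGPK", "B1", 1, intensity = 3e6),
    make_psm("s1", "GAQGPK", "B1", 1, intensity = 1e6,
             modifications = "deamidation@3"))
  pd <- peptide_deamidation(psms, "Q")
  expect_equal(pd$fraction, 0.25)
  expect_equal(pd$weight_basis, "intensity")
  expect_equal(pd$n_sites, 1L)

  # two Qs, one event on a single PSM -> occupancy 0.5
  one <- make_psm("s1", "GQAQGK", "B1", 1, modifications = "deamidation@2")
  expect_equal(peptide_deamidation(one, "Q")$fraction, 0.5)

  # no deamidated PSM among 5 -> 0
  none <- do.call(rbind, replicate(5, make_psm("s1", "GAQGPK", "B1", 1),
                                   simplify = FALSE))
  expect_equal(peptide_deamidation(none, "Q")$fraction, 0)

  # missing intensity anywhere -> fall back to PSM counting
  mixed <- rbind(
    make_psm("s1", "GAQGPK", "B1", 1, intensity = NA),
    make_psm("s1", "GAQGPK", "B1", 1, intensity = 9e9,
             modifications = "deamidation@3"))
  pd2 <- peptide_deamidation(mixed, "Q")
  expect_equal(pd2$fraction, 0.5)
  expect_equal(pd2$weight_basis, "psm_count")

  expect_error(peptide_deamidation(one, "N"), "no N residue")
})

test_that("summaries report mean, sd and n across peptide fractions", {
  db <- collagen_db(list(
    chain_record("B1", "Bos taurus", "COL1A1", "GAQGPKGPQGAR")))
  # peptide 1 fraction 0.10; peptide 2 fraction 0.30 (by intensity)
  psms <- rbind(
    make_psm("s1", "GAQGPK", "B1", 1, intensity = 9e5),
    make_psm("s1", "GAQGPK", "B1", 1, intensity = 1e5,
             modifications = "deamidation@3"),
    make_psm("s1", "GPQGAR", "B1", 7, intensity = 7e5),
    make_psm("s1", "GPQGAR", "B1", 7, intensity = 3e5,
             modifications = "deamidation@3"))
  s <- summarize_deamidation(psms, db, scope = "chain")
  q <- s[s$residue_class == "Q", ]
  expect_equal(q$mean_fraction, 20)
  expect_equal(q$sd, 14.14, tolerance = 1e-3)
  expect_equal(q$n_peptides, 2L)

  # single-chain sample: per-chain and global summaries agree
  g <- summarize_deamidation(psms, db, scope = "global")
  gq <- g[g$residue_class == "Q", ]
  expect_equal(gq$mean_fraction, q$mean_fraction)
  expect_equal(gq$sd, q$sd)
  expect_equal(gq$n_peptides, q$n_peptides)

  # duplicating every PSM leaves fractions unchanged
  s2 <- summarize_deamidation(rbind(psms, psms), db, scope = "chain")
  q2 <- s2[s2$residue_class == "Q", ]
  expect_equal(q2$mean_fraction, q$mean_fraction)
})

test_that("global mean lies within the range of per-chain means", {
  cfg <- simulation_config(seed = 77, n_psms = 400)
  db <- generate_collagen_db(cfg)
  psms <- generate_psm_table(cfg, db)$psms
  per_chain <- summarize_deamidation(psms, db, scope = "chain")
  global <- summarize_deamidation(psms, db, scope = "global")
  for (cls in c("N", "Q")) {
    pc <- per_chain$mean_fraction[per_chain$residue_class == cls]
    gl <- global$mean_fraction[global$residue_class == cls]
    expect_gte(gl, min(pc) - 1e-9)
    expect_lte(gl, max(pc) + 1e-9)
  }
})

test_that("a deamidation rate of 0.35 is recovered from deep sampling", {
  # single-run smoke check at 3 SE; the strict 2-SE coverage property
  # is exercised over the full replicate grid in the acceptance suite
  cfg <- simulation_config(seed = 220001, species = "Bos taurus",
                           n_psms = 1000, deamidation_rate_n = 0.35,
                           deamidation_rate_q = 0.35)
  db <- generate_collagen_db(cfg)
  psms <- generate_psm_table(cfg, db)$psms
  g <- summarize_deamidation(psms, db, scope = "global")
  for (cls in c("N", "Q")) {
    row <- g[g$residue_class == cls, ]
    se <- row$sd / sqrt(row$n_peptides)
    expect_lt(abs(row$mean_fraction - 35), 3 * se)
  }
})

test_that("compare_scopes orders groups and breaks ties stably", {
  s <- data.frame(sample_id = c("b", "h", "a"),
                  species = NA, chain_type = NA,
                  residue_class = "Q",
                  mean_fraction = c(5, 50, 5),
                  sd = c(1, 2, 1), n_peptides = c(10L, 10L, 10L))
  cmp <- compare_scopes(s, groups = c("bone", "hide", "bone"))
  expect_equal(cmp$sample_id, c("a", "b", "h"))   # tie 5/5 by label
  expect_equal(cmp$rank, 1:3)
  expect_equal(cmp$group, c("bone", "bone", "hide"))

  single <- compare_scopes(s[2, , drop = FALSE])
  expect_equal(nrow(single), 1L)

  s$residue_class <- c("Q", "N", "Q")
  expect_error(compare_scopes(s), "single residue class")
})

test_that("bone-like and hide-like cohorts order as expected", {
  cohort <- data.frame(sample_id = c("bone1", "bone2", "hide1", "hide2"),
                       deamidation_rate_q = c(0.05, 0.05, 0.5, 0.5),
                       deamidation_rate_n = c(0.05, 0.05, 0.5, 0.5))
  cfg <- simulation_config(seed = 901, n_psms = 300, samples = cohort)
  db <- generate_collagen_db(cfg)
  psms <- generate_psm_table(cfg, db)$psms
  g <- summarize_deamidation(psms, db, scope = "global")
  gq <- g[g$residue_class == "Q", ]
  bone <- mean(gq$mean_fraction[gq$sample_id %in% c("bone1", "bone2")])
  hide <- mean(gq$mean_fraction[gq$sample_id %in% c("hide1", "hide2")])
  expect_lt(bone, hide)
})
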