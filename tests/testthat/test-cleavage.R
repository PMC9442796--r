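test_that("terminus specificity follows the trypsin rule with P-block", {
  ch <- "AKGNDRGPK"
  full <- terminus_specificity("GNDR", ch, 3)
  expect_true(full$nterm_specific && full$cterm_specific)
  expect_equal(full$category, "fully_tryptic")

  semi_n <- terminus_specificity("NDR", ch, 4)   # preceded by G
  expect_equal(semi_n$category, "semitryptic")
  semi_c <- terminus_specificity("GND", ch, 3)   # ends at D
  expect_equal(semi_c$category, "semitryptic")
  non <- terminus_specificity("ND", ch, 4)
  expect_equal(non$category, "nonspecific")

  # protein termini always count as specific
  expect_equal(terminus_specificity("AK", ch, 1)$category, "fully_tryptic")
  expect_equal(terminus_specificity("GPK", ch, 7)$category, "fully_tryptic")

  # proline block: R followed by P is not a site
  expect_false(terminus_specificity("GPK", "AKGNDRPGPK", 8)$nterm_specific)

  expect_error(terminus_specificity("GNDR", ch, 8), "outside chain")
})

test_that("cleavage index is semitryptic PSMs over tryptic + semitryptic", {
  db <- collagen_db(list(
    chain_record("B1", "Bos taurus", "COL1A1", "GPAGNKGDQGRGPMGNR")))
  full <- do.call(rbind, replicate(
    7, make_psm("s1", "GDQGR", "B1", 7), simplify = FALSE))
  semi <- do.call(rbind, replicate(
    3, make_psm("s1", "DQGR", "B1", 8), simplify = FALSE))
  ci <- cleavage_index(rbind(full, semi), db, scope = "chain")
  expect_equal(ci$fraction, 0.3)
  expect_equal(ci$n_semitryptic, 3L)
  expect_equal(ci$n_total, 10L)

  expect_equal(cleavage_index(full, db, scope = "chain")$fraction, 0)

  # nonspecific PSMs are excluded from the ratio but reported
  non <- make_psm("s1", "DQG", "B1", 8)
  ci2 <- cleavage_index(rbind(full, semi, non), db, scope = "chain")
  expect_equal(ci2$fraction, 0.3)
  expect_equal(ci2$n_nonspecific, 1L)

  # score cutoff is inclusive at 25
  at25 <- rbind(make_psm("s1", "GDQGR", "B1", 7, ion_score = 25),
                make_psm("s1", "DQGR", "B1", 8, ion_score = 24.99))
  ci3 <- cleavage_index(at25, db, scope = "chain")
  expect_equal(ci3$n_total, 1L)
  expect_equal(ci3$fraction, 0)
})

test_that("every scored PSM falls in exactly one specificity category", {
  cfg <- simulation_config(seed = 55, n_psms = 200, semitryptic_prob = 0.3)
  db <- generate_collagen_db(cfg)
  psms <- generate_psm_table(cfg, db)$psms
  cats <- collaglue:::psm_categories(psms, as.data.frame(db))
  expect_true(all(cats %in% c("fully_tryptic", "semitryptic",
                              "nonspecific")))
  ci <- cleavage_index(psms, db, score_cutoff = 0, scope = "sample")
  expect_equal(ci$n_total + ci$n_nonspecific, nrow(psms))
})

test_that("cleavage probability is recovered, exactly at the boundaries", {
  for (q in c(0, 1)) {
    cfg <- simulation_config(seed = 4000 + q, n_psms = 250,
                             semitryptic_prob = q)
    db <- generate_collagen_db(cfg)
    psms <- generate_psm_table(cfg, db)$psms
    ci <- cleavage_index(psms, db, score_cutoff = 0, scope = "sample")
    expect_equal(ci$fraction, q)
  }
  cfg <- simulation_config(seed = 4001, n_psms = 1000,
                           semitryptic_prob = 0.4)
  db <- generate_collagen_db(cfg)
  psms <- generate_psm_table(cfg, db)$psms
  ci <- cleavage_index(psms, db, scope = "sample")
  se <- sqrt(ci$fraction * (1 - ci$fraction) / ci$n_total)
  expect_lt(abs(ci$fraction - 0.4), 2 * se)
})

test_that("duplication changes counts but not the cleavage fraction", {
  cfg <- simulation_config(seed = 56, n_psms = 150)
  db <- generate_collagen_db(cfg)
  psms <- generate_psm_table(cfg, db)$psms
  a <- cleavage_index(psms, db, scope = "sample")
  b <- cleavage_index(rbind(psms, psms), db, scope = "sample")
  expect_equal(b$fraction, a$fraction)
  expect_equal(b$n_total, 2L * a$n_total)
})

test_that("site states encode deamidation/oxidation observations", {
  ch <- chain_record("B1", "Bos taurus", "COL1A1", "GAQGPKGNMGARGQK")
  # positions: Q3 N8 M9 Q14
  psms <- rbind(
    make_psm("s1", "GAQGPK", "B1", 1, modifications = "deamidation@3"),
    make_psm("s1", "GAQGPK", "B1", 1, modifications = "deamidation@3"),
    make_psm("s1", "GNMGAR", "B1", 7,
             modifications = "deamidation@2;oxidation@3"),
    make_psm("s1", "GNMGAR", "B1", 7, modifications = "oxidation@3"))
  map <- site_state_map(psms, ch)
  states <- setNames(map$state, map$position)
  expect_equal(states[["3"]], "D")    # only ever deamidated
  expect_equal(states[["8"]], "DX")   # both forms seen
  expect_equal(states[["9"]], "OX")   # always oxidized
  expect_equal(states[["14"]], "NF")  # never covered
  # totality: every N/Q/M position gets a state
  chars <- strsplit(ch$sequence, "")[[1]]
  expect_setequal(map$position, which(chars %in% c("N", "Q", "M")))

  # methionine seen both ways gets the explicit composite state
  both <- rbind(psms,
                make_psm("s1", "GNMGAR", "B1", 7,
                         modifications = "deamidation@2"))
  map2 <- site_state_map(both, ch)
  expect_equal(map2$state[map2$position == 9], "OXX")

  # unlocalized deamidation with several candidates is excluded
  amb <- make_psm("s1", "GNMGARGQK", "B1", 7,
                  modifications = "deamidation@?")
  map3 <- site_state_map(amb, ch)
  expect_equal(map3$state[map3$position == 8], "NF")
  # with a single candidate it localizes
  loc <- make_psm("s1", "GAQGPK", "B1", 1, modifications = "deamidation@?")
  map4 <- site_state_map(loc, ch)
  expect_equal(map4$state[map4$position == 3], "D")
})

test_that("site maps are total and respect boundary deamidation rates", {
  for (rate in c(0, 1)) {
    cfg <- simulation_config(seed = 600 + rate, species = "Bos taurus",
                             n_psms = 200, deamidation_rate_n = rate,
                             deamidation_rate_q = rate)
    db <- generate_collagen_db(cfg)
    psms <- generate_psm_table(cfg, db)$psms
    for (i in seq_len(nrow(db))) {
      map <- site_state_map(psms, db[i, ])
      chars <- strsplit(db$sequence[i], "")[[1]]
      expect_setequal(map$position, which(chars %in% c("N", "Q", "M")))
      nq <- map[map$residue %in% c("N", "Q"), ]
      if (rate == 0) expect_true(all(nq$state %in% c("X", "NF")))
      if (rate == 1) expect_true(all(nq$state %in% c("D", "NF")))
    }
  }
})
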