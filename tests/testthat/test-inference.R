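test_that("chain acceptance needs 2 disjoint peptides above score 40", {
  db <- collagen_db(list(
    chain_record("B1", "Bos taurus", "COL1A1",
                 "GPAGNKGDQGRGPMGNRGAPGDKGEAGPSGPAGPR")))
  idx <- build_peptide_index(db)

  two <- rbind(make_psm("s1", "GPAGNK", "B1", 1, ion_score = 41),
               make_psm("s1", "GDQGR", "B1", 7, ion_score = 55))
  ev <- infer_chains(two, idx)
  expect_true(ev$accepted)
  expect_equal(ev$n_nonoverlapping, 2L)

  one <- make_psm("s1", "GPAGNK", "B1", 1, ion_score = 90)
  expect_false(infer_chains(one, idx)$accepted)

  # boundary: 40.0 is excluded ("above the 40 ion score threshold")
  atline <- rbind(make_psm("s1", "GPAGNK", "B1", 1, ion_score = 40),
                  make_psm("s1", "GDQGR", "B1", 7, ion_score = 40))
  expect_equal(nrow(infer_chains(atline, idx)), 0L)

  expect_equal(nrow(infer_chains(two[0, ], idx)), 0L)
})

test_that("overlapping peptides do not count as independent evidence", {
  ch <- chain_record("B1", "Bos taurus", "COL1A1",
                     "GPAGNKGDQGRGPMGNRGAPGDKGEAGPSGPAGPR")
  db <- collagen_db(list(ch))
  idx <- build_peptide_index(db)
  # three mutually overlapping peptides (all contain residues 7..11)
  over <- rbind(
    make_psm("s1", "GPAGNKGDQGR", "B1", 1, ion_score = 50),
    make_psm("s1", "GDQGR", "B1", 7, ion_score = 60),
    make_psm("s1", "GDQGRGPMGNR", "B1", 7, ion_score = 70))
  expect_false(infer_chains(over, idx)$accepted)
  # a disjoint fourth flips it
  four <- rbind(over, make_psm("s1", "GAPGDK", "B1", 18, ion_score = 45))
  expect_true(infer_chains(four, idx)$accepted)
})

test_that("greedy disjoint count equals brute-force max independent set", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    start <- sample(1:40, n, replace = TRUE)
    end <- start + sample(3:12, n, replace = TRUE)
    # unique keys: each interval is a distinct peptide
    expect_equal(collaglue:::max_disjoint_peptides(
      start, end, paste0("p", seq_len(n))),
      brute_max_disjoint(start, end))
  }
  # a repeated peptide contributes only its earliest occurrence
  expect_equal(collaglue:::max_disjoint_peptides(
    c(1L, 20L, 40L), c(5L, 25L, 45L), c("a", "a", "b")), 2L)
})

test_that("evidence is monotone in PSMs and invariant to row order", {
  cfg <- simulation_config(seed = 300, n_psms = 120)
  db <- generate_collagen_db(cfg)
  idx <- build_peptide_index(db)
  psms <- generate_psm_table(cfg, db)$psms
  ev_all <- infer_chains(psms, idx)

  set.seed(1)
  ev_half <- infer_chains(psms[sample(nrow(psms), 60), ], idx)
  acc_half <- ev_half[ev_half$accepted,
                      c("sample_id", "species", "chain_type")]
  acc_all <- ev_all[ev_all$accepted, c("sample_id", "species", "chain_type")]
  expect_true(all(do.call(paste, acc_half) %in% do.call(paste, acc_all)))

  shuffled <- psms[sample(nrow(psms)), ]
  expect_equal(infer_chains(shuffled, idx), ev_all)
})

test_that("tissue and purity rules follow the type-III / fish logic", {
  # one species, all three chains incl. COL3A1 -> pure hide
  ev <- data.frame(sample_id = "g1",
                   species = "Oryctolagus cuniculus",
                   chain_type = c("COL1A1", "COL1A2", "COL3A1"),
                   accepted = TRUE)
  cls <- classify_glue(ev)
  expect_equal(cls$tissue, "hide")
  expect_equal(cls$purity, "pure")
  expect_equal(cls$label, "HP")

  # several species, no COL3A1 -> mixed bone
  ev2 <- data.frame(sample_id = "g2",
                    species = rep(c("Bos taurus", "Sus scrofa",
                                    "Ovis aries", "Equus asinus"), each = 2),
                    chain_type = rep(c("COL1A1", "COL1A2"), 4),
                    accepted = TRUE)
  cls2 <- classify_glue(ev2)
  expect_equal(cls2$tissue, "bone")
  expect_equal(cls2$purity, "mixed")

  # a fish species dominates the tissue call even without COL3A1
  ev3 <- data.frame(sample_id = "g3",
                    species = "Scyliorhinus canicula",
                    chain_type = c("COL1A1", "COL1A2"),
                    accepted = TRUE)
  expect_equal(classify_glue(ev3)$tissue, "fish-mixed")
  expect_equal(classify_glue(ev3)$label, "FM")

  # nothing accepted -> unclassified, not an error
  ev4 <- data.frame(sample_id = "g4", species = "Bos taurus",
                    chain_type = "COL1A1", accepted = FALSE)
  cls4 <- classify_glue(ev4)
  expect_equal(cls4$tissue, "unclassified")
  expect_equal(cls4$n_species, 0L)
})

test_that("the 19-sample detection matrix reproduces every label", {
  mat <- read_detection_matrix(table2_path())
  cls <- classify_from_matrix(mat)
  expect_equal(nrow(cls), 19L)
  expect_equal(sum(cls$tissue == "hide"), 13L)
  expect_equal(sum(cls$tissue == "hide" & cls$purity == "pure"), 8L)
  expect_equal(sum(cls$tissue == "hide" & cls$purity == "mixed"), 5L)
  expect_equal(sum(cls$tissue == "bone"), 5L)
  expect_true(all(cls$purity[cls$tissue == "bone"] == "mixed"))
  expect_equal(sum(cls$tissue == "fish-mixed"), 1L)
  # sample ids are the published labels: prefix must match 19/19
  expect_equal(cls$label, substr(cls$sample_id, 1, 2))

  # row order must not matter
  set.seed(5)
  cls2 <- classify_from_matrix(mat[sample(nrow(mat)), ])
  expect_equal(cls2, cls)

  bad <- mat
  bad$species[1] <- "Canis lupus"
  expect_error(classify_from_matrix(bad), "unknown species")

  single <- data.frame(sample = "x", species = "Bos taurus",
                       col1a1 = "yes", col1a2 = "no", col3a1 = "yes")
  c1 <- classify_from_matrix(single)
  expect_equal(c1$tissue, "hide")
  expect_equal(c1$purity, "pure")
})
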