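write_contact_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# total_frames:1 interaction_types:all", lines), path)
  path
}

test_that("contact parsing keeps only TCR-peptide rows", {
  path <- write_contact_fixture(c(
    "0\thbbb\tD:ALA:30:N\tC:GLU:1:O",     # TCR-peptide
    "0\tvdw\tC:PRO:4:CB\tE:TYR:100:CZ",   # peptide-TCR
    "0\thbsb\tA:LYS:66:NZ\tD:ASP:55:OD1", # HLA-TCR
    "0\tsb\tA:ARG:62:NH1\tE:GLU:40:OE1",  # HLA-TCR
    "0\thp\tD:VAL:28:CG1\tE:LEU:98:CD1"   # TCR-TCR
  ))
  rec <- parse_contacts(path, peptide_chain = "C")
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$peptide_position, c(1L, 4L))
  expect_setequal(rec$partner_chain, c("D", "E"))
})

test_that("empty tables give empty record sets and all-pseudo weights", {
  path <- write_contact_fixture(character(0))
  rec <- parse_contacts(path, peptide_chain = "C")
  expect_equal(nrow(rec), 0L)
  cm <- build_contact_weights(rec)
  expect_equal(as.numeric(cm$weights), rep(0.5, 9))
})

test_that("unknown interaction types and out-of-range contacts are caught", {
  bad <- write_contact_fixture("0\txb\tD:ALA:30:N\tC:GLU:1:O")
  expect_error(parse_contacts(bad, peptide_chain = "C"),
               "unknown interaction type 'xb'")
  far <- write_contact_fixture(c(
    "0\thbbb\tD:ALA:30:N\tC:GLU:1:O",
    "0\tvdw\tD:ALA:30:CB\tC:XXX:12:CA"))
  expect_warning(rec <- parse_contacts(far, peptide_chain = "C"),
                 "outside peptide positions")
  expect_equal(nrow(rec), 1L)
})

test_that("the A3A crystal counts reproduce the published penalty vector", {
  cm <- build_contact_weights(c("1" = 3, "4" = 4, "5" = 2, "7" = 1,
                                "8" = 1))
  expect_identical(as.numeric(cm$weights),
                   c(3.0, 0.5, 0.5, 4.0, 2.0, 0.5, 1.0, 1.0, 0.5))
  expect_identical(as.numeric(cm_crystal()$weights),
                   c(3.0, 0.5, 0.5, 4.0, 2.0, 0.5, 1.0, 1.0, 0.5))
  expect_identical(as.numeric(cm_custom()$weights),
                   c(3.0, 0.5, 2.0, 4.0, 2.0, 0.5, 1.0, 1.0, 2.0))
})

test_that("weight building is permutation-invariant and matches a tally", {
  rec <- random_contact_records(200, n_frames = 5, seed = 101)
  cm <- build_contact_weights(rec, per_frame_dedup = FALSE)
  oracle <- as.numeric(table(factor(rec$peptide_position, levels = 1:9)))
  expect_equal(cm$counts, oracle)
  shuffled <- rec[sample.int(nrow(rec)), ]
  expect_equal(build_contact_weights(shuffled,
                                     per_frame_dedup = FALSE)$weights,
               cm$weights)
  # dedup mode equals tallying distinct (frame, type, partner, position)
  cmd <- build_contact_weights(rec, per_frame_dedup = TRUE)
  dedup <- unique(rec)
  oracle2 <- as.numeric(table(factor(dedup$peptide_position, levels = 1:9)))
  expect_equal(cmd$counts, oracle2)
})

test_that("pseudo-count and override validation", {
  expect_error(build_contact_weights(c("1" = 2), pseudo = 0), "> 0")
  expect_error(build_contact_weights(c("10" = 2)), "outside 1..9")
  cm <- cm_crystal()
  expect_error(apply_weight_overrides(cm, c("3" = -1)), "> 0")
  expect_error(apply_weight_overrides(cm, c("12" = 1)), "within 1..9")
})

test_that("overrides touch only their positions and can be undone", {
  cm <- cm_crystal()
  same <- apply_weight_overrides(cm, stats::setNames(numeric(0),
                                                     character(0)))
  expect_equal(as.numeric(same$weights), as.numeric(cm$weights))
  over <- apply_weight_overrides(cm, c("3" = 2, "9" = 2))
  expect_identical(over$provenance, "custom")
  back <- apply_weight_overrides(over, c("3" = 0.5, "9" = 0.5))
  expect_equal(as.numeric(back$weights), as.numeric(cm$weights))
})

test_that("equal contact counts rank exactly like uniform weights", {
  pm <- build_property_matrix(synth_property_table(12, seed = 10), 0.95)
  db <- synth_peptidome(n = 200, seed = 102)
  flat <- build_contact_weights(stats::setNames(rep(3, 9), as.character(1:9)))
  r_flat <- cross_screen("EVDPIGHLY", db, matrix = pm, weights = flat)
  r_unif <- cross_screen("EVDPIGHLY", db, matrix = pm)
  expect_identical(r_flat$peptide, r_unif$peptide)
  expect_equal(r_flat$rds, 3 * r_unif$rds)
})

test_that("the packaged synthetic contact fixture yields CM-crystal", {
  path <- system.file("extdata", "contacts_a3a_synthetic.tsv",
                      package = "xreact")
  rec <- parse_contacts(path, peptide_chain = "C")
  cm <- build_contact_weights(rec)
  expect_equal(cm$counts, c(3, 0, 0, 4, 2, 0, 1, 1, 0))
  expect_equal(as.numeric(cm$weights), as.numeric(cm_crystal()$weights))
})
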