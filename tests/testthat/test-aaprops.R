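test_that("AAIndex1 flat files round-trip through the parser", {
  scales <- random_scales(3, seed = 11)
  path <- write_aaindex_fixture(scales)
  tab <- parse_aaindex1(path)
  expect_s3_class(tab, "property_table")
  expect_equal(ncol(tab$values), 3L)
  expect_identical(colnames(tab$values), names(scales))
  for (acc in names(scales)) {
    expect_identical(unname(tab$values[, acc]), scales[[acc]])
  }
})

test_that("missing values are preserved and later dropped by the filter", {
  scales <- random_scales(4, seed = 12)
  scales[[2]][match("W", AA20)] <- NA
  tab <- parse_aaindex1(write_aaindex_fixture(scales))
  expect_true(is.na(tab$values["W", 2]))
  expect_equal(sum(!is.finite(tab$values)), 1L)
  pm <- build_property_matrix(tab, 0.95)
  expect_equal(pm$n_dropped, 1L)
})

test_that("malformed AAIndex records raise errors naming the accession", {
  scales <- random_scales(2, seed = 13)
  path <- write_aaindex_fixture(scales)
  lines <- readLines(path)
  # remove the I line of the first record
  writeLines(lines[-3], f1 <- tempfile())
  expect_error(parse_aaindex1(f1), "FIX0001")
  # truncate one value from the second value row of record 2
  lines2 <- lines
  lines2[11] <- sub("\\s+\\S+$", "", lines2[11])
  writeLines(lines2, f2 <- tempfile())
  expect_error(parse_aaindex1(f2), "FIX0002")
})

test_that("a rank-1 table collapses to one component explaining everything", {
  base <- stats::rnorm(20)
  vals <- sapply(1:6, function(i) i * base + i)   # affine copies
  rownames(vals) <- AA20
  pm <- build_property_matrix(property_table(vals), 0.95)
  expect_equal(ncol(pm$coords), 1L)
  expect_equal(pm$explained_variance[1], 1, tolerance = 1e-9)
})

test_that("retained dimensionality matches an independent eigen oracle", {
  for (seed in c(21, 22, 23)) {
    tab <- synth_property_table(5, seed = seed)
    pm <- build_property_matrix(tab, 0.95)
    z <- scale(tab$values)
    lam <- eigen(stats::cov(z), symmetric = TRUE)$values
    lam <- lam[lam > 1e-12]
    k_oracle <- which(cumsum(lam) / sum(lam) >= 0.95 - 1e-12)[1]
    expect_equal(ncol(pm$coords), k_oracle)
  }
})

test_that("explained variance over all components sums to one", {
  tab <- synth_property_table(30, seed = 31)
  pm <- build_property_matrix(tab, 0.5)
  expect_equal(sum(pm$explained_variance_all), 1, tolerance = 1e-9)
  expect_gte(sum(pm$explained_variance), 0.5)
})

test_that("matrix construction is deterministic and sign-flip invariant", {
  tab <- synth_property_table(12, seed = 41)
  pm1 <- build_property_matrix(tab, 0.9)
  pm2 <- build_property_matrix(tab, 0.9)
  expect_identical(pm1$coords, pm2$coords)
  # flipping component signs must leave all pairwise distances unchanged
  flip <- pm1
  flip$coords <- sweep(pm1$coords, 2,
                       sample(c(-1, 1), ncol(pm1$coords), replace = TRUE),
                       "*")
  expect_equal(as.matrix(dist(flip$coords)), as.matrix(dist(pm1$coords)),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  tab <- synth_property_table(5, seed = 51, missing_fraction = 1)
  expect_error(build_property_matrix(tab), "at least 2 complete")
  good <- synth_property_table(5, seed = 52)
  expect_error(build_property_matrix(good, 0), "variance_target")
  expect_error(build_property_matrix(good, 1.2), "variance_target")
})

test_that("residue correlations are Pearson, symmetric, unit diagonal", {
  m <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(3, 1, 2))
  g <- residue_correlation(m)
  expect_equal(diag(g), c(A = 1, B = 1, C = 1))
  expect_equal(g, t(g))
  expect_equal(g["A", "B"], 1)                       # exact affine copy
  expect_equal(g["A", "C"], cor(c(1, 2, 3), c(3, 1, 2)))
  expect_error(residue_correlation(rbind(A = c(1, 1, 1), B = c(1, 2, 3))),
               "zero-variance")
})

test_that("acidic residues correlate; opposite charges do not", {
  g <- residue_correlation(default_property_matrix())
  expect_equal(g["E", "E"], 1)
  expect_gt(g["E", "D"], g["D", "H"])
  expect_gt(g["L", "V"], 0)
})

test_that("the TSV artifact round-trips matrix and metadata", {
  pm <- build_property_matrix(synth_property_table(10, seed = 61), 0.9)
  pm <- calibrate_rds_scale(
    pm, data.frame(a = "EVDPIGHLY", b = "EVDPIGHVY", value = 1.35))
  path <- tempfile(fileext = ".tsv")
  write_property_matrix(pm, path)
  back <- read_property_matrix(path)
  expect_equal(back$coords, pm$coords, tolerance = 1e-12)
  expect_equal(back$rds_scale, pm$rds_scale, tolerance = 1e-12)
  expect_identical(back$matrix_id, pm$matrix_id)
  expect_equal(back$explained_variance, pm$explained_variance,
               tolerance = 1e-12)
})

test_that("the packaged AAIndex collection yields a complete-filtered space", {
  tab <- aaindex_property_table()
  expect_equal(ncol(tab$values), 544L)
  expect_gte(sum(colSums(!is.finite(tab$values)) == 0), 500L)
  pm <- default_property_matrix()
  expect_true(all(is.finite(pm$coords)))
  expect_gte(sum(pm$explained_variance), 0.95)
})
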