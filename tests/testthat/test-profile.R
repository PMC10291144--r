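pm_small <- build_property_matrix(synth_property_table(15, seed = 7), 0.95)

test_that("encoding is a pure row lookup into the property matrix", {
  prof <- encode_peptide("EVDPIGHLY", pm_small)
  expect_equal(dim(prof), c(9L, ncol(pm_small$coords)))
  expect_equal(unname(unclass(prof)[1, ]), unname(pm_small$coords["E", ]))
  expect_equal(unname(unclass(prof)[9, ]), unname(pm_small$coords["Y", ]))
  # peptides differing at one position differ in exactly that row
  a <- encode_peptide("EVDPIGHLY", pm_small)
  b <- encode_peptide("EVDPIGHVY", pm_small)
  diff_rows <- unname(which(rowSums(unclass(a) != unclass(b)) > 0))
  expect_identical(diff_rows, 8L)
})

test_that("invalid peptides are hard errors with position information", {
  expect_error(encode_peptide("EVDPIGHXY", pm_small), "position 8")
  expect_error(encode_peptide("EVDPIGHL", pm_small), "length 8")
  expect_error(encode_peptide("EVDPIGHLYK", pm_small), "length 10")
  expect_identical(validate_peptides("evdpighly"), "EVDPIGHLY")
})

test_that("relatedness is zero on identity and symmetric", {
  p <- encode_peptide("EVDPIGHLY", pm_small)
  expect_identical(relatedness(p, p), 0)
  set.seed(71)
  for (i in 1:10) {
    a <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    w <- weight_vector(stats::runif(9, 0.2, 4))
    expect_equal(relatedness(a, b, w, matrix = pm_small),
                 relatedness(b, a, w, matrix = pm_small))
  }
})

test_that("relatedness equals a brute-force recomputation from raw rows", {
  set.seed(72)
  for (i in 1:10) {
    a <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    expected <- 0
    for (pos in 1:9) {
      ra <- pm_small$coords[substr(a, pos, pos), ]
      rb <- pm_small$coords[substr(b, pos, pos), ]
      expected <- expected + sum((ra - rb)^2)
    }
    expect_equal(relatedness(a, b, matrix = pm_small), expected / 9)
  }
})

test_that("weights act only where residues differ, monotonically", {
  a <- "EVDPIGHLY"
  b <- "EVDPIGHVY"   # differs at position 8 only
  w <- rep(1, 9)
  base <- relatedness(a, b, weight_vector(w), matrix = pm_small)
  w_up <- w; w_up[8] <- 3
  expect_gt(relatedness(a, b, weight_vector(w_up), matrix = pm_small), base)
  w_match <- w; w_match[1] <- 10   # position 1 matches
  expect_equal(relatedness(a, b, weight_vector(w_match), matrix = pm_small),
               base)
})

test_that("scaling all weights by c scales the score by c", {
  set.seed(73)
  for (cc in c(0.25, 2, 7)) {
    a <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    w <- stats::runif(9, 0.5, 3)
    expect_equal(
      relatedness(a, b, weight_vector(cc * w), matrix = pm_small),
      cc * relatedness(a, b, weight_vector(w), matrix = pm_small))
  }
})

test_that("scores are invariant to orthogonal rotation of the components", {
  k <- ncol(pm_small$coords)
  set.seed(74)
  q <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  rotated <- pm_small
  rotated$coords <- pm_small$coords %*% q
  for (i in 1:5) {
    a <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    expect_equal(relatedness(a, b, matrix = rotated),
                 relatedness(a, b, matrix = pm_small),
                 tolerance = 1e-9)
  }
})

test_that("profiles from different matrices refuse to be compared", {
  other <- build_property_matrix(synth_property_table(15, seed = 8), 0.95)
  a <- encode_peptide("EVDPIGHLY", pm_small)
  b <- encode_peptide("EVDPIGHVY", other)
  expect_error(relatedness(a, b), "different property matrices")
})

test_that("weight vectors must be positive and length-matched", {
  expect_error(weight_vector(c(1, -1, rep(1, 7))), "> 0")
  expect_error(weight_vector(c(0, rep(1, 8))), "> 0")
  a <- encode_peptide("EVDPIGHLY", pm_small)
  expect_error(relatedness(a, a, weight_vector(rep(1, 5))), "length 5")
})

test_that("ungapped substitution scores match hand computation", {
  # BLOSUM62 diagonal for E,V,D,P,I,G,H,L,Y sums to 51
  expect_identical(blosum_score("EVDPIGHLY", "EVDPIGHLY", "BLOSUM62"), 51L)
  # single substitution: self score - diag(L) + entry(L,V) = 51 - 4 + 1
  expect_identical(blosum_score("EVDPIGHLY", "EVDPIGHVY", "BLOSUM62"), 48L)
  set.seed(75)
  for (i in 1:5) {
    a <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    expect_identical(blosum_score(a, b, "BLOSUM100"),
                     blosum_score(b, a, "BLOSUM100"))
  }
  expect_error(blosum_score("EVDPIGHLY", "EVDPIGHLY", "NOSUCH62"),
               "unknown substitution matrix")
})
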