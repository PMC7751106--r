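scales <- aa_scales()

test_that("property scales standardize to mean 0 and population SD 1", {
  for (s in list(scales$H1, scales$H2, scales$M)) {
    expect_equal(mean(s), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(s^2)), 1, tolerance = 1e-9)
  }
  expect_error(aa_scales(list(hydrophobicity = c(A = 1),
                              hydrophilicity = c(A = 1),
                              mass = c(A = 1))), "all 20")
})

test_that("AAC is the normalized residue frequency", {
  expect_equal(unname(encode_aac(protein_record("h", "AAAA"))$values),
               c(1, rep(0, 19)))
  expect_equal(unname(encode_aac(protein_record("u", "ACDEFGHIKLMNPQRSTVWY"))$values),
               rep(0.05, 20))
  v <- encode_aac(protein_record("p", "AC"))$values
  expect_equal(unname(v[c("aac_A", "aac_C")]), c(0.5, 0.5))
  expect_equal(sum(v), 1)
})

test_that("PAAC is the normalized dipeptide frequency", {
  v <- encode_paac(protein_record("t", "AAA"))$values
  expect_length(v, 400L)
  expect_equal(unname(v["paac_AA"]), 1)
  v2 <- encode_paac(protein_record("t2", "ACA"))$values
  expect_equal(unname(v2[c("paac_AC", "paac_CA")]), c(0.5, 0.5))
  for (i in 1:5) {
    r <- random_record(paste0("rp", i), 30L + i, i)
    expect_equal(sum(encode_paac(r)$values), 1, tolerance = 1e-9)
  }
  expect_error(encode_paac(protein_record("s", "A")), "length >= 2")
})

test_that("sequence-order correlation factors match hand evaluation", {
  hom <- protein_record("hom", strrep("A", 10))
  expect_equal(theta_factors(hom, 3L, scales), rep(0, 3))
  expect_identical(theta_factors(hom, 0L, scales), numeric(0))
  ## frozen hand computation of Theta(A, C) from the standardized scales
  expect_equal(theta_factors(protein_record("ac", "AC"), 1L, scales),
               0.438123065950, tolerance = 1e-9)
  expect_error(theta_factors(protein_record("ac", "AC"), 2L, scales), "lambda")
})

test_that("PseAAC reduces to AAC at lambda 0 and matches hand arithmetic", {
  for (i in 1:25) {
    r <- random_record(paste0("ps", i), 50L + i, 100L + i)
    expect_equal(encode_pseaac(r, 0L, scales = scales)$values,
                 stats::setNames(encode_aac(r)$values,
                                 paste0("pseaac_", memvote:::AA_ALPHABET)))
  }
  hom <- protein_record("hom", strrep("L", 60))
  vh <- encode_pseaac(hom, 5L, scales = scales)$values
  expect_equal(unname(vh[21:25]), rep(0, 5))
  expect_equal(unname(vh["pseaac_L"]), 1)
  ## frozen: "AC", lambda 1, omega 0.05, theta_1 = 0.438123065950
  v <- encode_pseaac(protein_record("ac", "AC"), 1L, omega = 0.05, scales = scales)
  expect_length(v$values, 21L)
  expect_equal(unname(v$values["pseaac_A"]), 0.489281719644, tolerance = 1e-9)
  expect_equal(unname(v$values["pseaac_theta1"]), 0.021436560712, tolerance = 1e-9)
  expect_equal(sum(v$values), 1, tolerance = 1e-12)
})

test_that("PseAAC components are a unit simplex for random inputs", {
  for (i in 1:10) {
    r <- random_record(paste0("sx", i), 80L, 200L + i)
    v <- encode_pseaac(r, 10L, scales = scales)$values
    expect_length(v, 30L)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("SAAC concatenates terminal and interior compositions", {
  v <- encode_saac(protein_record("a50", strrep("A", 50)))$values
  expect_length(v, 60L)
  expect_equal(unname(v["saac_N_A"]), 1)
  expect_equal(unname(v["saac_C_A"]), 1)
  expect_equal(sum(v[21:40]), 0) # empty interior convention
  s <- paste0(strrep("A", 25), strrep("C", 25), strrep("A", 25))
  v2 <- encode_saac(protein_record("mid", s))$values
  expect_equal(unname(v2["saac_M_C"]), 1)
  expect_error(encode_saac(protein_record("short", strrep("A", 49))), "L >= 50")
  for (i in 1:5) {
    v3 <- encode_saac(random_record(paste0("sb", i), 50L + 7L * i, 300L + i))$values
    expect_true(all(abs(c(sum(v3[1:20]), sum(v3[41:60])) - 1) < 1e-9))
    expect_true(abs(sum(v3[21:40]) - 1) < 1e-9 || sum(v3[21:40]) == 0)
  }
})

test_that("profile standardization is a row z-score with a zero-variance convention", {
  p <- profile_matrix("z", rbind(rep(1, 20), c(2, rep(0, 19))))
  s <- standardize_profile(p)
  expect_equal(unname(s$scores[1, ]), rep(0, 20))
  ## frozen hand z-score of (2, 0, ..., 0)
  expect_equal(unname(s$scores[2, 1]), 4.358898943541, tolerance = 1e-9)
  expect_equal(unname(s$scores[2, 2]), -0.229415733871, tolerance = 1e-9)
  set.seed(9)
  pr <- profile_matrix("r", matrix(rnorm(100), 5, 20))
  sr <- standardize_profile(pr)$scores
  expect_equal(unname(rowMeans(sr)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(sqrt(rowMeans(sr^2))), rep(1, 5), tolerance = 1e-9)
  so <- standardize_profile(pr, center_only = TRUE)$scores
  expect_equal(unname(rowMeans(so)), rep(0, 5), tolerance = 1e-9)
  expect_equal(so, pr$scores - rowMeans(pr$scores))
})

test_that("profile descriptor matches its definition", {
  set.seed(11)
  p2 <- profile_matrix("two", matrix(rnorm(40), 2, 20))
  v <- encode_psepssm(p2, 1L)$values
  expect_length(v, 40L)
  expect_equal(unname(v[21:40]), unname((p2$scores[1, ] - p2$scores[2, ])^2))
  expect_equal(unname(v[1:20]), unname(colMeans(p2$scores)))
  expect_equal(unname(encode_psepssm(p2, 0L)$values[21:40]), rep(0, 20))
  z <- profile_matrix("zero", matrix(0, 4, 20))
  expect_equal(unname(encode_psepssm(z, 2L)$values), rep(0, 40))
  expect_error(encode_psepssm(p2, 2L), "lambda")
})

test_that("profile descriptor equals a brute-force recomputation on random profiles", {
  for (i in 1:10) {
    set.seed(500 + i)
    p <- profile_matrix(paste0("bf", i), matrix(rnorm(100), 5, 20))
    for (lam in 0:2) {
      v <- encode_psepssm(p, lam)$values
      ebar <- vapply(1:20, function(j) mean(p$scores[, j]), numeric(1))
      g <- vapply(1:20, function(j) {
        if (lam == 0L) return(0)
        idx <- 1:(5 - lam)
        mean((p$scores[idx, j] - p$scores[idx + lam, j])^2)
      }, numeric(1))
      expect_equal(unname(v), c(ebar, g), tolerance = 1e-12)
    }
  }
})

test_that("dataset-level encoding produces named feature matrices", {
  ds <- make_synth(4L, seed = 5L)
  X <- encode_dataset(ds, "psepssm", lambda = 2L)
  expect_identical(dim(X), c(8L, 40L))
  expect_identical(rownames(X), ds$ids)
  Xa <- encode_dataset(ds, "aac")
  expect_identical(colnames(Xa), paste0("aac_", memvote:::AA_ALPHABET))
  ds2 <- ds; ds2$profiles <- NULL
  expect_error(encode_dataset(ds2, "psepssm"), "profiles")
})
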