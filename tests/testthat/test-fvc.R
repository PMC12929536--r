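test_that("fragment vectors have the documented count, dimension and layout", {
  p10 <- random_profile(10, seed = 1)
  fv <- fragment_vectors(p10, 10)
  expect_equal(nrow(fv), 1L)
  expect_length(fv$v[[1]], 80L)
  p12 <- random_profile(12, seed = 2)
  expect_equal(nrow(fragment_vectors(p12, 9)), 4L)
  ## un-flattening reproduces the profile slice exactly (residue-major,
  ## native block before denatured within each residue)
  fv3 <- fragment_vectors(p12, 3)
  w <- fv3$v[[2]]  # window starting at residue 2
  slice <- as.matrix(p12[2:4, -(1:3)])
  expect_identical(matrix(w, nrow = 3, byrow = TRUE), unname(slice))
  expect_error(fragment_vectors(p10, 11), "L must")
})

test_that("FVC cosines match self-similarity, antipodes and the double-loop oracle", {
  a <- random_profile(30, seed = 3, id = "a")
  res <- fvc_compare(a, a, L = 12, cutoff = -1)
  diag_hits <- dplyr::filter(res$matches, start_a == start_b)
  expect_true(all(abs(diag_hits$cosine - 1) < 1e-12))
  ## antipodal fragment
  b <- a
  b[, -(1:3)] <- -a[, -(1:3)]
  anti <- fvc_compare(a, b, L = 12, cutoff = -1)
  anti_diag <- dplyr::filter(anti$matches, start_a == start_b)
  expect_true(all(abs(anti_diag$cosine + 1) < 1e-12))
  ## double-loop oracle on random pairs
  withr::with_seed(17, {
    for (rep in 1:5) {
      La <- sample(15:40, 1); Lb <- sample(15:40, 1); L <- sample(5:12, 1)
      pa <- random_profile(La, seed = rep * 100, id = "pa")
      pb <- random_profile(Lb, seed = rep * 100 + 1, id = "pb")
      out <- fvc_compare(pa, pb, L = L, cutoff = -1)
      Fa <- emmtools:::fragment_matrix(pa, L)
      Fb <- emmtools:::fragment_matrix(pb, L)
      for (k in sample(nrow(out$matches), 4)) {
        i <- out$matches$start_a[k]; j <- out$matches$start_b[k]
        expect_equal(out$matches$cosine[k],
                     oracle_cosine(Fa[i, ], Fb[j, ]), tolerance = 1e-12)
      }
    }
  })
})

test_that("FVC results are symmetric, complete and scale-invariant", {
  pa <- random_profile(25, seed = 4, id = "pa")
  pb <- random_profile(18, seed = 5, id = "pb")
  ab <- fvc_compare(pa, pb, L = 7, cutoff = -1)
  ba <- fvc_compare(pb, pa, L = 7, cutoff = -1)
  expect_equal(ab$background$n_expected, (25 - 7 + 1) * (18 - 7 + 1))
  expect_equal(length(ab$background$scores), ab$background$n_expected)
  tr <- dplyr::arrange(
    dplyr::rename(ba$matches, start_a = start_b, start_b = start_a),
    dplyr::desc(cosine), start_a, start_b
  )
  expect_equal(ab$matches$cosine, tr$cosine, tolerance = 1e-12)
  expect_equal(ab$matches$start_a, tr$start_a)
  ## positive rescaling of one member leaves every cosine unchanged
  pc <- pa
  pc[, -(1:3)] <- pa[, -(1:3)] * 37.5
  sc <- fvc_compare(pc, pb, L = 7, cutoff = -1)
  expect_equal(ab$matches$cosine, sc$matches$cosine, tolerance = 1e-12)
})

test_that("planted epitopes beat the background; degenerate windows cannot", {
  pa <- random_profile(60, seed = 6, id = "pa")
  pb <- random_profile(80, seed = 7, id = "pb")
  pb2 <- plant_fragment(pa, pb, length = 15, start_a = 11, start_b = 41)
  et <- epitope_background_test(pa, pb2, L = 15, start_a = 11, start_b = 41)
  expect_true(et$above_average)
  expect_equal(et$epitope_cosine, 1.0, tolerance = 1e-12)
  bg <- attr(et, "background")
  expect_equal(et$epitope_cosine, max(bg$scores), tolerance = 1e-12)
  ## window spanning both full proteins: background of one score
  pe <- random_profile(20, seed = 8, id = "pe")
  pf <- random_profile(20, seed = 9, id = "pf")
  deg <- epitope_background_test(pe, pf, L = 20, start_a = 1, start_b = 1)
  expect_false(deg$above_average)
  expect_equal(attr(deg, "background")$summary$count, 1L)
  expect_error(epitope_background_test(pe, pf, L = 20, start_a = 2,
                                       start_b = 1), "out of range")
})

test_that("binomial tails are exact for every k at small n", {
  expect_equal(binomial_tail(0, 11), 1.0)
  expect_equal(binomial_tail(11, 11), 2^-11)
  for (n in c(5, 9, 12)) {
    for (k in 0:n) {
      expect_equal(binomial_tail(k, n, 0.5), enumerate_binom_tail(k, n),
                   tolerance = 1e-12)
    }
  }
  expect_error(binomial_tail(3, 5, 0), "p0")
  expect_error(binomial_tail(6, 5), "k must")
})

test_that("alignment weights respect their contract", {
  pa <- random_profile(50, seed = 10, id = "pa")
  w_self <- alignment_weight(pa, pa, offset = 0)
  expect_equal(w_self$f, 1.0)
  expect_equal(w_self$N, 50L - 20L + 1L)
  ## orthogonal constant profiles: every in-register cosine is 0
  zero <- function(id) {
    p <- random_profile(40, seed = 11, id = id)
    p[, -(1:3)] <- 0
    p
  }
  oa <- zero("oa"); oa$dG_native <- 1
  ob <- zero("ob"); ob$dH_pol_denatured <- 1
  w0 <- alignment_weight(oa, ob, offset = 0)
  expect_equal(w0$f, 0.0)
  ## planted fragment: M agrees with a brute-force in-register count
  long <- random_profile(120, seed = 12, id = "long")
  short <- random_profile(80, seed = 13, id = "short")
  short2 <- plant_fragment(long, short, length = 30, start_a = 21, start_b = 11)
  off <- 10L  # places the copied block of short2 onto its source in long
  w <- alignment_weight(short2, long, offset = off, L = 20, cutoff = 0.95)
  Fs <- emmtools:::fragment_matrix(short2, 20)
  Fl <- emmtools:::fragment_matrix(long, 20)
  brute <- sum(sapply(seq_len(nrow(Fs)), function(i) {
    oracle_cosine(Fs[i, ], Fl[i + off, ]) > 0.95
  }))
  expect_equal(w$M, brute)
  expect_gte(w$M, 11L)  # the 30-residue copied block holds 11 full windows
  ## f never increases with the cutoff
  w_lo <- alignment_weight(short2, long, offset = off, cutoff = 0.5)
  w_hi <- alignment_weight(short2, long, offset = off, cutoff = 0.99)
  expect_gte(w_lo$f, w$f)
  expect_gte(w$f, w_hi$f)
  expect_true(w$f >= 0 && w$f <= 1)
  ## overlap shorter than the window: weight undefined
  tiny <- random_profile(10, seed = 14, id = "tiny")
  expect_message(w_na <- alignment_weight(tiny, long, offset = 0, L = 20),
                 "undefined")
  expect_true(is.na(w_na$f))
})
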