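test_that("substitution scores reward perfect association and vanish under independence", {
  ## environment e co-occurs only with amino acid number e+1
  env <- rep(0:7, each = 50)
  residue <- rep(c("A","C","D","E","F","G","H","I"), each = 50)
  enc <- manual_encoded(env)
  enc$residue <- residue
  mat <- build_substitution_matrix(enc, "native")
  for (e in 0:7) {
    expect_equal(which.max(mat$scores[e + 1, ]), which(colnames(mat$scores) ==
                 c("A","C","D","E","F","G","H","I")[e + 1]),
                 ignore_attr = TRUE)
  }
  ## exactly uniform counts -> all scores zero
  grid <- expand.grid(env = 0:7, aa = c("A","C","D","E","F","G","H","I","K",
                                        "L","M","N","P","Q","R","S","T","V",
                                        "W","Y"))
  unif <- manual_encoded(rep(grid$env, times = 5))
  unif$residue <- rep(as.character(grid$aa), times = 5)
  mat0 <- build_substitution_matrix(unif, "native")
  expect_lt(max(abs(mat0$scores)), 1e-12)
})

test_that("substitution matrix equals the count-and-log oracle", {
  s <- test_setup()
  for (state in c("native", "denatured")) {
    mat <- build_substitution_matrix(s$corpus, state)
    oracle <- oracle_submatrix(s$corpus[[paste0("env_", state)]],
                               s$corpus$residue)
    expect_equal(unname(mat$scores), oracle, tolerance = 1e-12)
    ## expected score under independence is non-positive
    e_score <- sum(outer(mat$env_freq, mat$aa_freq) * mat$scores)
    expect_lte(e_score, 0)
  }
  expect_error(build_substitution_matrix(manual_encoded(integer(0)), "native"),
               "empty")
})

test_that("register scores match hand sums and reject bad offsets", {
  scores <- matrix(0, 8, 20)
  scores[3 + 1, 11] <- 1.5   # env 3 vs M
  scores[5 + 1, 9] <- -0.5   # env 5 vs K
  mat <- manual_matrix(scores)
  q <- manual_encoded(c(3L, 5L))
  expect_equal(score_register(q, "MK", 0, mat), 1.0)
  expect_error(score_register(q, "MK", 1, mat), "offset")
  zero <- manual_matrix(matrix(0, 8, 20))
  expect_equal(score_register(q, "MK", 0, zero), 0)
})

test_that("all-register scores agree with the sliding double-loop oracle", {
  s <- test_setup()
  mat <- s$matrices$native
  withr::with_seed(99, {
    for (rep in 1:30) {
      m <- sample(5:60, 1)
      n <- sample(5:80, 1)
      env <- sample(0:7, m, replace = TRUE)
      aa_idx <- sample(1:20, n, replace = TRUE)
      fast <- emmtools:::score_all_registers(env, aa_idx, mat$scores)
      slow <- oracle_register_scores(env, aa_idx, mat$scores)
      expect_equal(length(fast), abs(m - n) + 1L)
      expect_equal(fast, slow, tolerance = 1e-12)
    }
  })
})

test_that("Gumbel significances satisfy the closed-form identities", {
  s <- test_setup()
  null <- test_nulls()$native
  mu <- null$a + null$b * log(120 * 700)
  expect_equal(register_significance(mu, 120, 700, null), 1 - exp(-1))
  raw05 <- mu + null$beta * log(-1 / log(0.95))
  expect_equal(register_significance(raw05, 120, 700, null), 0.05,
               tolerance = 1e-12)
  expect_equal(register_significance(-1e9, 120, 700, null), 1)
  expect_gte(min(register_significance(c(1e9, mu), 50, 50, null)), 1e-300)
})

test_that("null calibration gives a positive length slope and demands variance", {
  null <- test_nulls()$native
  expect_gt(null$b, 0)
  ## doubling both lengths raises the fitted location
  expect_gt(null$a + null$b * log(160 * 480), null$a + null$b * log(80 * 240))
  zero <- manual_matrix(matrix(0, 8, 20))
  expect_error(
    calibrate_null(zero, length_grid = list(c(20L, 40L)), n_shuffles = 100,
                   seed = 1),
    "[Dd]egenerate"
  )
  expect_error(
    calibrate_null(test_setup()$matrices$native, n_shuffles = 50, seed = 1),
    "100"
  )
})

test_that("eTFR alignment maximises S over registers with low-offset ties", {
  s <- test_setup()
  nulls <- test_nulls()
  ## equal-length pair: exactly one register
  q <- s$encoded[[1]]
  self_seq <- s$seqs[1, ]
  hit <- etfr_align(q, self_seq, s$matrices, nulls)
  expect_equal(hit$offset, 0L)
  expect_equal(hit$S, -log10(hit$p_native) - log10(hit$p_denatured))
  expect_gte(hit$S, 0)
  ## agreement with explicit per-register evaluation on an unequal pair
  target <- s$seqs[which.max(s$seqs$length), ]
  hit2 <- etfr_align(q, target, s$matrices, nulls)
  n_reg <- abs(nrow(q) - target$length) + 1L
  S_all <- sapply(0:(n_reg - 1L), function(o) {
    pn <- register_significance(score_register(q, target, o, s$matrices$native,
                                               "native"),
                                nrow(q), target$length, nulls$native)
    pd <- register_significance(score_register(q, target, o,
                                               s$matrices$denatured,
                                               "denatured"),
                                nrow(q), target$length, nulls$denatured)
    -log10(pn) - log10(pd)
  })
  expect_equal(hit2$S, max(S_all))
  expect_equal(hit2$offset, which.max(S_all) - 1L)
})

test_that("containment registers are orientation-symmetric", {
  s <- test_setup()
  mat <- s$matrices$native
  withr::with_seed(7, {
    env <- sample(0:7, 30, replace = TRUE)
    aa_idx <- sample(1:20, 50, replace = TRUE)
    a <- emmtools:::score_all_registers(env, aa_idx, mat$scores)
    ## recompute with the long member treated as the fixed frame
    b <- sapply(0:20, function(o) {
      sum(mat$scores[cbind(env + 1L, aa_idx[seq_len(30) + o])])
    })
    expect_equal(a, b, tolerance = 1e-12)
  })
})

test_that("database scans rank the query's own sequence first", {
  s <- test_setup()
  nulls <- test_nulls()
  own <- s$seqs[3, ]
  decoys <- withr::with_seed(31, {
    tibble::tibble(
      id = sprintf("decoy%02d", 1:20),
      seq = replicate(20, paste(sample(strsplit(own$seq, "")[[1]]),
                                collapse = "")),
      length = own$length
    )
  })
  targets <- dplyr::bind_rows(own, decoys)
  ranked <- scan_database(s$encoded[[3]], targets, s$matrices, nulls)
  expect_equal(nrow(ranked), 21L)
  expect_equal(ranked$target[1], own$id)
  ranked2 <- scan_database(s$encoded[[3]], targets, s$matrices, nulls)
  expect_identical(ranked, ranked2)
  one <- scan_database(s$encoded[[3]], targets[1, ], s$matrices, nulls)
  expect_equal(nrow(one), 1L)
})

test_that("substitution matrices and null models round-trip through files", {
  s <- test_setup()
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_substitution_matrix(s$matrices$native, mp)
  back <- read_substitution_matrix(mp)
  expect_equal(back$scores, s$matrices$native$scores, tolerance = 1e-12)
  expect_equal(back$env_freq, s$matrices$native$env_freq, tolerance = 1e-12)
  expect_equal(back$state, "native")
  np <- withr::local_tempfile(fileext = ".json")
  null <- test_nulls()$native
  write_null_model(null, np)
  nback <- read_null_model(np)
  expect_equal(nback$a, null$a)
  expect_equal(nback$beta, null$beta)
  expect_equal(register_significance(5, 80, 240, nback),
               register_significance(5, 80, 240, null))
})
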