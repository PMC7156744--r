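test_that("direct-repeat construction yields the expected geometry", {
  half <- matrix(0.25, nrow = 7, ncol = 4)
  m <- build_direct_repeat_motif(half, spacer = 4)
  expect_equal(m$width, 18)
  expect_equal(m$half_site_width, 7)
  expect_equal(m$spacer, 4L)
  # half-site blocks identical, spacer columns equal the background
  expect_equal(m$probs[1:7, ], m$probs[12:18, ])
  for (j in 8:11) expect_equal(unname(m$probs[j, ]), unname(m$background))

  m0 <- build_direct_repeat_motif(half, spacer = 0)
  expect_equal(m0$width, 14)

  mu <- build_direct_repeat_motif(half, spacer = 2,
                                  background = background_from_gc(0.5))
  expect_true(all(abs(mu$probs - 0.25) < 1e-12))

  bad <- half
  bad[1, 1] <- 0.5
  expect_error(build_direct_repeat_motif(bad, 4), "sum to 1")
})

test_that("log-odds table matches closed forms", {
  m <- motif_matrix(matrix(0.25, 3, 4), background = background_from_gc(0.5))
  expect_true(all(abs(log_odds(m, epsilon = 0)) < 1e-12))

  pa <- matrix(c(1, 0, 0, 0), 1, 4)
  m2 <- motif_matrix(pa, background = background_from_gc(0.5))
  lo <- log_odds(m2, epsilon = 0)
  expect_equal(unname(lo[1, "A"]), 2)  # log2(1 / 0.25)

  # full-sequence score equals the sum of per-column entries (width-3 toy)
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
                 c(0.25, 0.25, 0.25, 0.25))
  m3 <- motif_matrix(probs, background = background_from_gc(0.6))
  expect_equal(score_sequences("ACG", m3),
               brute_motif_score("ACG", m3$probs, m3$background))
})

test_that("scan equals exhaustive enumeration for a width-6 motif", {
  probs <- rbind(
    c(0.9, 0.04, 0.03, 0.03), c(0.05, 0.8, 0.1, 0.05),
    c(0.25, 0.25, 0.25, 0.25), c(0.1, 0.1, 0.7, 0.1),
    c(0.05, 0.05, 0.05, 0.85), c(0.4, 0.3, 0.2, 0.1)
  )
  m <- motif_matrix(probs, background = background_from_gc(0.69))
  kmers <- all_kmers(6)
  got <- score_sequences(kmers, m)
  want <- vapply(kmers, function(s) brute_motif_score(s, m$probs, m$background),
                 numeric(1))
  expect_equal(got, unname(want), tolerance = 1e-12)

  # scanning one long string containing every 6-mer window agrees too
  g <- generate_genome(3000, gc = 0.5, seed = 61)
  hits <- scan_sequence(g, m, score_threshold = -Inf)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 3000 - 6 + 1)
  idx <- seq(1, nrow(fwd), by = 60)
  for (i in idx) {
    sub <- substr(g$seq, fwd$start[i] + 1, fwd$start[i] + 6)
    expect_equal(fwd$score[i], brute_motif_score(sub, m$probs, m$background),
                 tolerance = 1e-12)
  }
})

test_that("scan has strand symmetry, N exclusion and threshold monotonicity", {
  m <- example_direct_repeat_motif(conservation = 1)
  consensus <- paste0("GCCGTCA", "GGGG", "GCCGTCA")
  g <- paste0(strrep("AT", 40), consensus, strrep("AT", 40))
  hits <- scan_sequence(g, m, score_threshold = 20)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 80L)
  expect_equal(hits$strand, "+")

  # reverse-complemented genome: same hits with strands flipped
  hits_rc <- scan_sequence(reverse_complement(g), m, score_threshold = 20)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, nchar(g) - 18 - 80L)

  # windows overlapping N are excluded
  gn <- paste0(strrep("AT", 40), "GCCGTCAGGNGGCCGTCA", strrep("AT", 40))
  expect_equal(nrow(scan_sequence(gn, m, score_threshold = -1000)),
               2 * (nchar(gn) - 18 + 1) - 2 * 18)

  g2 <- generate_genome(20000, gc = 0.69, seed = 62)
  counts <- vapply(c(-10, -5, 0, 5, 10), function(th) {
    nrow(scan_sequence(g2, example_direct_repeat_motif(), th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("null sampling is deterministic and matches exact enumeration in the tail", {
  m <- example_direct_repeat_motif()
  n1 <- sample_null_scores(m, 0.69, n = 5000, seed = 71)
  n2 <- sample_null_scores(m, 0.69, n = 5000, seed = 71)
  expect_identical(n1$scores, n2$scores)

  # background motif -> null scores centered near 0 bits
  mb <- motif_matrix(matrix(rep(background_from_gc(0.69), each = 5), 5, 4),
                     background = background_from_gc(0.69))
  nb <- sample_null_scores(mb, 0.69, n = 20000, seed = 72, epsilon = 0)
  expect_lt(abs(mean(nb$scores)), 0.05)

  # width-4 motif at gc = 0.5: exact tail probability by enumerating 4^4
  probs <- rbind(
    c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.7),
    c(0.4, 0.2, 0.2, 0.2), c(0.25, 0.25, 0.25, 0.25)
  )
  m4 <- motif_matrix(probs, background = background_from_gc(0.5))
  kmers <- all_kmers(4)
  exact_scores <- score_sequences(kmers, m4)
  exact_p <- rep(0.25^4, length(kmers))
  null <- sample_null_scores(m4, 0.5, n = 40000, seed = 73)
  for (th in stats::quantile(exact_scores, c(0.5, 0.8, 0.95))) {
    p_exact <- sum(exact_p[exact_scores >= th])
    p_emp <- mean(null$scores >= th)
    se <- sqrt(p_exact * (1 - p_exact) / null$n_samples)
    expect_lt(abs(p_emp - p_exact), 3 * se + 1e-12)
  }
})

test_that("empirical p-values follow the add-one rule and agree with a sum oracle", {
  null <- structure(
    list(n_samples = 999L, gc = 0.5, scores = sort(rnorm(999)), seed = 1),
    class = "nap_null"
  )
  expect_equal(empirical_pvalue(min(null$scores) - 10, null), 1.0)
  expect_equal(empirical_pvalue(max(null$scores) + 10, null), 1 / 1000)
  probe <- c(null$scores[c(3, 500, 997)], rnorm(20))
  want <- vapply(probe, function(s) (sum(null$scores >= s) + 1) / 1000,
                 numeric(1))
  expect_equal(empirical_pvalue(probe, null), want)
})

test_that("threshold_for_pvalue round-trips and rejects unattainable targets", {
  m <- example_direct_repeat_motif()
  null <- sample_null_scores(m, 0.69, n = 9999, seed = 81)
  expect_equal(threshold_for_pvalue(null, 1.0), min(null$scores))
  for (p in c(0.5, 0.1, 0.01, 0.001)) {
    thr <- threshold_for_pvalue(null, p)
    expect_lte(empirical_pvalue(thr, null), p)
  }
  expect_error(threshold_for_pvalue(null, 1e-6), "unattainable")
})

test_that("MEME minimal format round-trips a motif", {
  m <- example_direct_repeat_motif()
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(m, f)
  back <- read_meme(f)
  expect_equal(back$width, m$width)
  expect_equal(back$probs, m$probs, tolerance = 1e-5)
  expect_equal(back$background, m$background, tolerance = 1e-4)
})
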