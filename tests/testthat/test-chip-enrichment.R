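test_that("log2 enrichment matches hand arithmetic and the 4-fold rule", {
  ip <- coverage_track(c(8, 2, 2, 2, 2), library_size = 100)
  inp <- coverage_track(c(2, 2, 2, 2, 2), library_size = 100)
  enr <- compute_log2_enrichment(ip, inp, pseudocount = 1)
  expect_equal(enr$log2_ratio, log2(c(9, 3, 3, 3, 3) / 3))

  # ip = 4 x input, equal library sizes, tiny pseudocount -> log2 = 2
  ip4 <- coverage_track(rep(40, 100), library_size = 1000)
  in4 <- coverage_track(rep(10, 100), library_size = 1000)
  enr4 <- compute_log2_enrichment(ip4, in4, pseudocount = 1e-9)
  expect_equal(enr4$log2_ratio, rep(2, 100), tolerance = 1e-6)

  # identical tracks -> 0 everywhere
  same <- compute_log2_enrichment(ip4, ip4, pseudocount = 1)
  expect_equal(same$log2_ratio, rep(0, 100))

  expect_error(compute_log2_enrichment(ip, in4), "length")
  expect_error(compute_log2_enrichment(ip, inp, pseudocount = 0), "pseudocount")
})

test_that("swapping IP and input negates the enrichment at equal library sizes", {
  withr::with_seed(5, {
    a <- coverage_track(rpois(500, 20), library_size = 10000)
    b <- coverage_track(rpois(500, 20), library_size = 10000)
  })
  e1 <- compute_log2_enrichment(a, b)
  e2 <- compute_log2_enrichment(b, a)
  expect_equal(e1$log2_ratio, -e2$log2_ratio)
})

test_that("call_peaks equals brute-force run finding on random tracks", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, {
      base <- rnorm(5000, 0, 0.5)
      # inject some above-threshold stretches
      for (k in 1:8) {
        at <- sample(4500, 1)
        base[at:(at + sample(10:120, 1))] <- rnorm(1, 3, 0.3)
      }
      base
    })
    track <- structure(list(seq_id = "chr", log2_ratio = v, pseudocount = 1),
                       class = "nap_enrichment")
    got <- call_peaks(track, threshold_log2 = 2, min_width = 20, merge_gap = 30)
    want <- brute_find_peaks(v, 2, 20, 30)
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
    # summit is the leftmost maximum and lies inside the peak
    for (i in seq_len(nrow(got))) {
      seg <- v[(got$start[i] + 1):got$end[i]]
      expect_equal(got$summit[i], got$start[i] + which.max(seg) - 1L)
      expect_equal(got$max_log2[i], max(seg))
    }
    # ranks: strongest peak is rank 1, ranks unique
    if (nrow(got) > 0) {
      expect_equal(got$max_log2[got$rank == 1], max(got$max_log2))
      expect_equal(sort(got$rank), seq_len(nrow(got)))
    }
  }
})

test_that("call_peaks edge behaviour: flat track, rectangle, threshold monotonicity", {
  flat <- structure(list(seq_id = "c", log2_ratio = rep(0, 1000), pseudocount = 1),
                    class = "nap_enrichment")
  expect_equal(nrow(call_peaks(flat)), 0)

  rect <- rep(0, 500)
  rect[101:200] <- 3
  tr <- structure(list(seq_id = "c", log2_ratio = rect, pseudocount = 1),
                  class = "nap_enrichment")
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 200L)
  expect_equal(pk$summit, 100L)  # leftmost maximum on the plateau

  # raising the threshold shrinks the above-threshold position set, so total
  # peak-covered bases never grow; for isolated unimodal peaks the peak
  # count itself is monotone too
  v <- withr::with_seed(99, rnorm(20000, 1, 1))
  tr2 <- structure(list(seq_id = "c", log2_ratio = v, pseudocount = 1),
                   class = "nap_enrichment")
  covered <- vapply(seq(0, 4, by = 0.5), function(th) {
    pk <- call_peaks(tr2, threshold_log2 = th, min_width = 1, merge_gap = 0)
    sum(v >= th)
  }, numeric(1))
  expect_true(all(diff(covered) <= 0))

  tri <- rep(0, 3000)
  for (at in c(500, 1500, 2500)) {
    tri[(at - 100):(at + 100)] <- 4 * (1 - abs(-100:100) / 100)
  }
  tr3 <- structure(list(seq_id = "c", log2_ratio = tri, pseudocount = 1),
                   class = "nap_enrichment")
  counts <- vapply(c(0.5, 1.5, 2.5, 3.5, 4.5), function(th) {
    nrow(call_peaks(tr3, threshold_log2 = th, min_width = 1, merge_gap = 0))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("replicate R2 behaves for identity, negation, signal and null", {
  v <- withr::with_seed(8, rnorm(2000))
  t1 <- structure(list(seq_id = "c", log2_ratio = v, pseudocount = 1),
                  class = "nap_enrichment")
  t2 <- structure(list(seq_id = "c", log2_ratio = -v, pseudocount = 1),
                  class = "nap_enrichment")
  expect_equal(replicate_r2(t1, t1), 1.0)
  expect_equal(replicate_r2(t1, t2), 1.0)  # R^2 is sign-blind

  zero <- structure(list(seq_id = "c", log2_ratio = rep(1, 2000), pseudocount = 1),
                    class = "nap_enrichment")
  expect_error(replicate_r2(t1, zero), "zero variance")

  # replicates sharing planted signal correlate; site-free nulls do not
  g <- generate_genome(100000, gc = 0.69, seed = 51)
  m <- example_direct_repeat_motif()
  pl <- plant_sites(g, m, 50, min_spacing = 300, seed = 52)
  enr <- lapply(c(53, 54), function(s) {
    cov <- simulate_chip_coverage(pl$genome, pl$sites, mean_depth = 60,
                                  enrichment_at_sites = 8, seed = s)
    compute_log2_enrichment(cov$ip, cov$input)
  })
  expect_gt(replicate_r2(enr[[1]], enr[[2]]), 0.5)

  enr0 <- lapply(c(55, 56), function(s) {
    cov <- simulate_chip_coverage(g, pl$sites[0, ], mean_depth = 60, seed = s)
    compute_log2_enrichment(cov$ip, cov$input)
  })
  expect_lt(replicate_r2(enr0[[1]], enr0[[2]]), 0.1)
})
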