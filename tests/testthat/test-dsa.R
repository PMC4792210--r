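test_that("distance vectors are Euclidean and follow the canonical pair order", {
  b <- synthetic_bundle(2L)
  ch <- toy_chain(matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE), b)
  expect_equal(chain_distance_vector(ch, enumerate_pairs(b)), 5)

  # 10-residue chain against an independent double-loop oracle
  b10 <- synthetic_bundle(c(4L, 6L))
  set.seed(42)
  xyz <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  ch10 <- toy_chain(xyz, b10)
  pairs <- enumerate_pairs(b10)
  got <- chain_distance_vector(ch10, pairs)
  oracle <- mapply(function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2)),
                   pairs$i, pairs$j)
  expect_equal(got, oracle, tolerance = 1e-12)

  # masked endpoints give NA entries
  ch_mask <- toy_chain(xyz, b10, present = c(FALSE, rep(TRUE, 9)))
  v <- chain_distance_vector(ch_mask, pairs)
  expect_equal(sum(is.na(v)), 9L)  # pairs touching position 1

  # a fully present reference-sized chain defines all 14,365 entries
  spec <- synthetic_spec(n_chains = 2, seed = 1)
  full <- make_ideal_bundle(spec)
  bb <- synthetic_bundle(spec$helix_lengths)
  expect_equal(sum(!is.na(chain_distance_vector(full, enumerate_pairs(bb)))),
               14365L)
})

test_that("score = mean/sd against hand-computed three-chain toy values", {
  b <- synthetic_bundle(2L)
  chains <- lapply(c(4, 5, 6), function(d) {
    toy_chain(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE), b,
              id = paste0("C", d))
  })
  ens <- do.call(rbind, chains)

  st <- pair_statistics(ens, b, std = "population")
  expect_equal(st$n_chains, 3L)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, sqrt(2 / 3), tolerance = 1e-12)      # 0.8164966
  expect_equal(st$score, 5 / sqrt(2 / 3), tolerance = 1e-12)  # 6.123724

  st2 <- pair_statistics(ens, b, std = "sample")
  expect_equal(st2$sd, 1)
  expect_equal(st2$score, 5)
})

test_that("identical chains give zero spread and infinite scores", {
  spec <- synthetic_spec(n_chains = 4, seed = 8, sigma = 0,
                         max_rotation = 20, max_translation = 5)
  ens <- make_ensemble(spec)
  st <- pair_statistics(ens, synthetic_bundle(spec$helix_lengths))
  expect_true(all(st$sd < 1e-9))
  expect_true(all(is.infinite(st$score)))
})

test_that("all statistics are invariant under per-chain rigid motions", {
  spec <- synthetic_spec(helix_lengths = c(5L, 4L, 6L), n_chains = 4, seed = 13)
  b <- synthetic_bundle(spec$helix_lengths)
  ens <- make_ensemble(spec)
  moved <- rigid_jitter_ensemble(ens, seed = 123)
  st0 <- pair_statistics(ens, b)
  st1 <- pair_statistics(moved, b)
  expect_equal(st1$mean, st0$mean, tolerance = 1e-9)
  expect_equal(st1$sd, st0$sd, tolerance = 1e-9)
  expect_equal(st1$score, st0$score, tolerance = 1e-8)
})

test_that("uniform scaling scales means and sds, leaving scores unchanged", {
  spec <- synthetic_spec(helix_lengths = c(4L, 5L), n_chains = 3, seed = 17)
  b <- synthetic_bundle(spec$helix_lengths)
  ens <- make_ensemble(spec)
  scaled <- dplyr::mutate(ens, x = 2.5 * x, y = 2.5 * y, z = 2.5 * z)
  st0 <- pair_statistics(ens, b)
  st1 <- pair_statistics(scaled, b)
  expect_equal(st1$mean, 2.5 * st0$mean, tolerance = 1e-12)
  expect_equal(st1$sd, 2.5 * st0$sd, tolerance = 1e-12)
  expect_equal(st1$score, st0$score, tolerance = 1e-9)
})

test_that("production statistics match the brute-force oracle on small bundles", {
  for (seed in c(3, 14)) {
    spec <- synthetic_spec(helix_lengths = c(5L, 6L, 4L), n_chains = 5,
                           seed = seed)
    b <- synthetic_bundle(spec$helix_lengths)
    ens <- make_ensemble(spec, declared_missing = if (seed == 3) "2.50" else character())
    for (std in c("population", "sample")) {
      got <- pair_statistics(ens, b, std = std)
      ref <- brute_force_stats(ens, b, std = std)
      expect_equal(got$i, ref$i)
      expect_equal(got$j, ref$j)
      expect_equal(got$n_chains, ref$n)
      expect_equal(got$mean, ref$mean, tolerance = 1e-9)
      expect_equal(got$sd, ref$sd, tolerance = 1e-9)
      expect_equal(got$score, ref$score, tolerance = 1e-9)
    }
  }
})

test_that("pair_statistics rejects degenerate inputs", {
  spec <- synthetic_spec(helix_lengths = c(4L, 5L), n_chains = 2, seed = 1)
  b <- synthetic_bundle(spec$helix_lengths)
  ens <- make_ensemble(spec)
  one <- ens[ens$chain == "SYN01.A", ]
  expect_error(pair_statistics(one, b), class = "dsa_data_error")
  expect_error(pair_statistics(ens, synthetic_bundle(c(4L, 6L))),
               class = "dsa_data_error")
})

test_that("ranking is descending with canonical-order tie-breaks", {
  st <- tibble::tibble(pair = 1:4, group = "A", class = "intra",
                       score = c(2, 9, 9, 1))
  r <- rank_pairs(st)
  expect_equal(r$pair, c(2L, 3L, 1L, 4L))
  expect_equal(r$rank, 1:4)

  # all-identical ensemble: infinite scores everywhere, ranking = pair order
  spec <- synthetic_spec(helix_lengths = c(4L, 4L), n_chains = 3, seed = 2,
                         sigma = 0)
  b <- synthetic_bundle(spec$helix_lengths)
  st_inf <- pair_statistics(make_ensemble(spec), b)
  expect_equal(rank_pairs(st_inf)$pair, st_inf$pair)

  # random ensemble against a brute-force sort oracle
  spec2 <- synthetic_spec(helix_lengths = c(10L, 10L), n_chains = 4, seed = 31)
  st2 <- pair_statistics(make_ensemble(spec2), synthetic_bundle(spec2$helix_lengths))
  r2 <- rank_pairs(st2)
  oracle <- st2[order(-st2$score, st2$pair), ]
  expect_equal(r2$pair, oracle$pair)

  # undefined scores are excluded and counted
  st3 <- st
  st3$score[2] <- NA_real_
  r3 <- rank_pairs(st3)
  expect_equal(nrow(r3), 3L)
  expect_equal(attr(r3, "n_undefined"), 1L)
})

test_that("cumulative ratio curves have the partition and monotonicity properties", {
  spec <- synthetic_spec(n_chains = 6, seed = 19)
  b <- synthetic_bundle(spec$helix_lengths)
  st <- pair_statistics(make_ensemble(spec), b)
  intra <- st[st$class == "intra", ]
  ranked <- rank_pairs(intra)
  cr <- cumulative_ratio(ranked, top_n = 1000L)

  # raw top-r counts across groups always sum to r
  by_rank <- tapply(cr$count, cr$rank, sum)
  expect_equal(as.numeric(by_rank), as.numeric(names(by_rank)))
  # curves are monotone non-decreasing within [0, 1]
  for (g in unique(cr$group)) {
    v <- cr$ratio[cr$group == g]
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= 0 & v <= 1))
  }

  # grand-total normalisation sums to r / total at each rank
  crg <- cumulative_ratio(ranked, top_n = 100L, denominator = "grand")
  tot <- sum(attr(ranked, "group_totals"))
  expect_equal(sum(crg$ratio[crg$rank == 100L]), 100 / tot, tolerance = 1e-12)
})

test_that("a group occupying the top ranks saturates at k/|g| and stays flat", {
  st <- tibble::tibble(pair = 1:10,
                       group = rep(c("A", "B"), each = 5), class = "intra",
                       score = c(10:6, 5:1))  # all of A above all of B
  cr <- cumulative_ratio(rank_pairs(st), top_n = 10L)
  a <- cr[cr$group == "A", ]
  expect_equal(a$ratio, c(1:5 / 5, rep(1, 5)))
  b <- cr[cr$group == "B", ]
  expect_equal(b$ratio, c(rep(0, 5), 1:5 / 5))
})

test_that("an empty group warns and yields a zero curve", {
  st <- tibble::tibble(pair = 1:3, group = "A", class = "intra", score = 3:1)
  totals <- c(A = 3, B = 0)
  expect_warning(cr <- cumulative_ratio(rank_pairs(st), top_n = 3L,
                                        totals = totals),
                 regexp = "Empty group")
  expect_equal(cr$ratio[cr$group == "B"], rep(0, 3))
})

test_that("score-distance tables carry hand-computed values and drop undefined rows", {
  b <- synthetic_bundle(2L)
  chains <- lapply(c(4, 6), function(d) {
    toy_chain(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE), b,
              id = paste0("C", d))
  })
  st <- pair_statistics(do.call(rbind, chains), b, min_chains = 2L)
  tbl <- score_distance_table(st)
  expect_equal(tbl$mean, 5)
  expect_equal(tbl$score, 5 / 1)          # population sd of {4,6} is 1
  expect_equal(tbl$class, "intra")

  # everything filtered out: empty table, no crash
  st$score <- NA_real_
  expect_equal(nrow(score_distance_table(st)), 0L)
})

test_that("the dsa() driver exposes tidy(), glance() and a stable summary", {
  spec <- synthetic_spec(n_chains = 5, seed = 23)
  b <- synthetic_bundle(spec$helix_lengths)
  fit <- dsa(make_ensemble(spec), b)
  expect_s3_class(fit, "dsa")
  expect_equal(nrow(tidy(fit)), 14365L)
  g <- glance(fit)
  expect_equal(g$n_pairs, 14365L)
  expect_equal(g$n_intra, 1992L)
  expect_equal(g$n_inter, 12373L)
  expect_equal(g$n_chains, 5L)
  expect_output(print(fit), "5 chains")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("optional linear detrending removes the score-distance slope", {
  spec <- synthetic_spec(n_chains = 6, seed = 29)
  st <- pair_statistics(make_ensemble(spec), synthetic_bundle(spec$helix_lengths))
  dt <- detrend_scores(st)
  ok <- is.finite(dt$score)
  # residual scores are uncorrelated with distance; raw column preserved
  expect_lt(abs(stats::cor(dt$mean[ok], dt$score[ok])), 1e-8)
  expect_equal(dt$score_raw, st$score)
  expect_equal(mean(dt$score[ok]), mean(st$score[ok]), tolerance = 1e-9)
  expect_error(detrend_scores(st[1:2, ]), class = "dsa_data_error")
})
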