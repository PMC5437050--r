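test_that("pair distances are Euclidean, symmetric and isometry-invariant", {
  fr <- generate_helix_frames(data.frame(a = "1.35", b = "2.65", mean = 5),
                              jitter_sd = 0, n_frames = 3, seed = 1)
  # plant explicit coordinates: (0,0,0) and (3,4,0)
  fr$coords[, "1.35", ] <- 0
  fr$coords[, "2.65", ] <- matrix(rep(c(3, 4, 0), each = 3), nrow = 3)
  d <- pair_distance_series(fr, "1.35", "2.65")
  expect_equal(d$distances, rep(5, 3))
  expect_equal(pair_distance_series(fr, "2.65", "1.35")$distances,
               d$distances)

  # identical points
  fr$coords[, "2.65", ] <- 0
  expect_equal(pair_distance_series(fr, "1.35", "2.65")$mean, 0)

  # rigid rotation + translation leaves the summary unchanged
  fr2 <- generate_helix_frames(jitter_sd = 0.4, n_frames = 25, seed = 2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr3 <- fr2
  for (f in seq_len(fr2$n_frames))
    fr3$coords[f, , ] <- fr2$coords[f, , ] %*% rot +
      matrix(rep(c(10, -4, 2), each = dim(fr2$coords)[2]), ncol = 3)
  s2 <- pair_distance_series(fr2, "4.50", "5.50")
  s3 <- pair_distance_series(fr3, "4.50", "5.50")
  expect_equal(s2$mean, s3$mean, tolerance = 1e-12)
  expect_equal(s2$sd, s3$sd, tolerance = 1e-12)

  expect_error(pair_distance_series(fr2, "4.50", "9.99"), "missing")
})

test_that("frame generator reproduces configured distances", {
  # zero jitter: exact distances in every frame
  fr0 <- generate_helix_frames(jitter_sd = 0, n_frames = 10, seed = 5)
  expect_equal(pair_distance_series(fr0, "4.50", "5.50")$distances,
               rep(11, 10))

  # Gaussian jitter: sample mean within 3 SE of the configured mean
  fr <- generate_helix_frames(data.frame(a = "4.50", b = "5.50", mean = 10),
                              jitter_sd = 0.5, n_frames = 1000, seed = 6)
  s <- pair_distance_series(fr, "4.50", "5.50")
  expect_lt(abs(s$mean - 10), 3 * 0.5 / sqrt(1000))
  expect_equal(s$sem, s$sd / sqrt(1000))

  # seed reproducibility
  fa <- generate_helix_frames(n_frames = 20, seed = 9)
  fb <- generate_helix_frames(n_frames = 20, seed = 9)
  expect_identical(fa$coords, fb$coords)
})

test_that("SEM scales as 1/sqrt(n) on resampled frames", {
  fr <- generate_helix_frames(n_frames = 400, seed = 13)
  s_all <- pair_distance_series(fr, "1.35", "2.65")
  fr100 <- fr
  fr100$coords <- fr$coords[1:100, , , drop = FALSE]
  fr100$n_frames <- 100L
  s_sub <- pair_distance_series(fr100, "1.35", "2.65")
  expect_equal(s_all$sem * sqrt(400), s_all$sd)
  expect_gt(s_sub$sem, s_all$sem)
})

test_that("ligand-vs-apo distance deltas recover built-in offsets", {
  apo_means <- data.frame(a = c("1.35", "3.40", "4.50"),
                          b = c("2.65", "6.44", "5.50"),
                          mean = c(12.0, 10.0, 11.0))
  apo <- generate_helix_frames(apo_means, jitter_sd = 0.5, n_frames = 200,
                               seed = 21)
  spip_means <- apo_means
  spip_means$mean[spip_means$a == "4.50"] <- 11.0 + 2.3
  spip <- generate_helix_frames(spip_means, jitter_sd = 0.5, n_frames = 200,
                                seed = 22)
  halo_means <- apo_means
  halo_means$mean[halo_means$a == "1.35"] <- 12.0 + 1.7
  halo <- generate_helix_frames(halo_means, jitter_sd = 0.5, n_frames = 200,
                                seed = 23)

  pairs <- list(c("1.35", "2.65"), c("3.40", "6.44"), c("4.50", "5.50"))
  summarize <- function(fr) {
    out <- lapply(pairs, function(p) pair_distance_series(fr, p[1], p[2]))
    stats::setNames(out, vapply(out, function(s) s$pair, character(1L)))
  }
  dd <- distance_delta_summary(list(spiperone = summarize(spip),
                                    haloperidol = summarize(halo)),
                               summarize(apo))
  tab <- dd$table
  r1 <- tab[tab$condition == "spiperone" & tab$pair == "4.50-5.50", ]
  expect_lt(abs(r1$delta - 2.3), 3 * r1$se)
  r2 <- tab[tab$condition == "haloperidol" & tab$pair == "1.35-2.65", ]
  expect_lt(abs(r2$delta - 1.7), 3 * r2$se)
  # untouched pair shows no offset
  r3 <- tab[tab$condition == "spiperone" & tab$pair == "3.40-6.44", ]
  expect_lt(abs(r3$delta), 3 * r3$se)
  expect_true(all(c("4.50-5.50", "1.35-2.65") %in% names(dd$tukey)))

  # apo vs apo: zero delta
  dd0 <- distance_delta_summary(summarize(apo), summarize(apo))
  expect_true(all(dd0$table$delta == 0))
})

test_that("multi-MODEL PDB round trip preserves labelled coordinates", {
  fr <- generate_helix_frames(n_frames = 30, seed = 33)
  pdb <- tempfile(fileext = ".pdb")
  map <- tempfile(fileext = ".csv")
  write_helix_frames(fr, pdb, map)
  back <- read_helix_frames(pdb, map)
  expect_equal(back$n_frames, 30L)
  # PDB fixed-format stores 3 decimals
  expect_lt(max(abs(back$coords - fr$coords)), 6e-4)
  s1 <- pair_distance_series(fr, "4.50", "5.50")
  s2 <- pair_distance_series(back, "4.50", "5.50")
  expect_equal(s1$mean, s2$mean, tolerance = 1e-4)
})
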