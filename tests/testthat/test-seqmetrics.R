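test_that("SCD reproduces hand-derived values", {
  expect_equal(scd("GGGG")$q_scd, 0)
  expect_equal(scd("QQQQQK")$q_scd, 0)     # single charge
  expect_equal(scd("EK")$q_scd, -0.5)      # (1/2)(-1)(+1)sqrt(1)
  # frozen brute-force value for KEKE:
  # (-1 + sqrt2 - 1 - sqrt3 + sqrt2 - 1)/4
  expect_equal(scd("KEKE")$q_scd, -0.47590595, tolerance = 1e-7)
  expect_equal(scd("KEKE")$q_scd, scd_brute("KEKE"), tolerance = 1e-14)
})

test_that("SCD matches the brute-force double sum on random sequences", {
  set.seed(19)
  for (i in 1:300) {
    n <- sample(2:120, 1)
    s <- make_random_sequence(n)
    v <- scd(s)$q_scd
    b <- scd_brute(s)
    expect_equal(v, b, tolerance = 1e-12 * max(1, abs(b)))
  }
})

test_that("SCD is invariant under charge sign flip and sequence reversal", {
  set.seed(23)
  flip <- c(E = "K", K = "E", D = "R", R = "D")
  for (i in 1:40) {
    s <- make_random_sequence(sample(5:80, 1))
    chars <- strsplit(s, "")[[1]]
    flipped <- paste(ifelse(chars %in% names(flip), flip[chars], chars),
                     collapse = "")
    reversed <- paste(rev(chars), collapse = "")
    expect_equal(scd(flipped)$q_scd, scd(s)$q_scd, tolerance = 1e-14)
    expect_equal(scd(reversed)$q_scd, scd(s)$q_scd, tolerance = 1e-14)
  }
})

test_that("charge statistics follow the table's formal charges", {
  cs <- charge_stats("EK")
  expect_equal(cs$net_charge, 0)
  expect_equal(cs$n_charged, 2)
  expect_equal(cs$frac_charged, 1)
  # histidine is neutral in the shipped table
  expect_equal(charge_stats("HHHH")$n_charged, 0)
  fus <- charge_stats(wt_sequence("fus_pld"))
  expect_equal(fus$n_charged, 2)
  expect_equal(fus$n_negative, 2)
  expect_equal(fus$n_positive, 0)
})

test_that("hydropathy statistics and population maps are positionwise means", {
  hs <- hydropathy_stats(strrep("G", 12))
  expect_equal(hs$mean_lambda, 0.64865, tolerance = 1e-12)
  # one higher-lambda substitution strictly increases the mean
  expect_gt(hydropathy_stats("GGGFGG")$mean_lambda,
            hydropathy_stats("GGGGGG")$mean_lambda)
  # two-sequence change map equals the mean of individual difference vectors
  wt <- "GAGAG"
  pop <- c("GFGAG", "GAGWG")
  cm <- population_change_map(wt, pop)
  lam <- function(s) hydropathy_stats(s)$per_residue$lambda
  manual <- (lam(pop[1]) - lam(wt)) / 2 + (lam(pop[2]) - lam(wt)) / 2
  expect_equal(cm$d_lambda, manual, tolerance = 1e-14)
  expect_error(population_map(c("AA", "AAA")), "equal-length")
})

test_that("chunk shuffling conserves composition and replays deterministically", {
  fus <- wt_sequence("fus_pld")
  set.seed(3)
  sh <- chunk_shuffle(fus, l = 4, steps = 30)
  expect_identical(sort(strsplit(sh$final, "")[[1]]),
                   sort(strsplit(fus, "")[[1]]))
  expect_equal(nrow(sh$swaps), 30)
  expect_equal(sh$trace$pairs_changed, (0:30) * 4)
  # logged swaps reproduce the final sequence exactly
  expect_identical(apply_swaps(fus, sh$swaps, 4), sh$final)
  # seeded determinism
  s1 <- idpevolve:::with_preserved_seed(9, chunk_shuffle(fus, 3, 10))
  s2 <- idpevolve:::with_preserved_seed(9, chunk_shuffle(fus, 3, 10))
  expect_identical(s1$trace, s2$trace)
  # swapped windows never overlap for l < n
  n <- nchar(fus)
  d <- pmin((s1$swaps$p2 - s1$swaps$p1) %% n, (s1$swaps$p1 - s1$swaps$p2) %% n)
  expect_true(all(d >= 3))
})

test_that("full-length chunks act as cyclic rotations", {
  s <- "ACDEFG"
  set.seed(5)
  sh <- chunk_shuffle(s, l = 6, steps = 1)
  expect_identical(sort(strsplit(sh$final, "")[[1]]),
                   sort(strsplit(s, "")[[1]]))
  # final is a rotation of the original
  doubled <- paste0(s, s)
  expect_true(grepl(sh$final, doubled, fixed = TRUE))
})

test_that("biased shuffling draws only from the most hydrophobic windows", {
  # hydrophobic block (F) on a polar background (S)
  s <- paste0(strrep("S", 30), strrep("F", 10), strrep("S", 20))
  l <- 3; frac <- 0.3
  set.seed(11)
  sh <- chunk_shuffle(s, l = l, steps = 8, bias_fraction = frac)
  lam <- setNames(default_tab$residues$lambda, default_tab$residues$code)
  cur <- s
  n <- nchar(s)
  for (k in seq_len(nrow(sh$swaps))) {
    lam_seq <- lam[strsplit(cur, "")[[1]]]
    win_mean <- vapply(seq_len(n), function(p)
      mean(lam_seq[idpevolve:::circ_window(p, l, n)]), 0)
    top <- order(win_mean, decreasing = TRUE)[seq_len(ceiling(frac * n))]
    expect_true(sh$swaps$p1[k] %in% top)
    expect_true(sh$swaps$p2[k] %in% top)
    cur <- apply_swaps(cur, sh$swaps[k, ], l)
  }
  expect_identical(cur, sh$final)
})

test_that("glycine scanning tiles the sequence and recovers mean lambda", {
  fus <- wt_sequence("fus_pld")
  gs <- glycine_scan(fus, 6)
  expect_equal(nrow(gs), ceiling(nchar(fus) / 6))
  expect_true(all(gs$start == (gs$chunk - 1) * 6 + 1))
  expect_equal(max(gs$end), nchar(fus))
  # an all-glycine chunk has delta_lambda 0 and an unchanged variant
  s <- paste0("GGGGGG", "FFFFFF")
  gs2 <- glycine_scan(s, 6)
  expect_equal(gs2$delta_lambda[1], 0)
  expect_identical(gs2$variant[1], s)
  # an all-F chunk scores lambda(F) - lambda(G)
  expect_equal(gs2$delta_lambda[2], 1 - 0.64865, tolerance = 1e-12)
  # weighted chunk means reconstruct the sequence mean exactly
  lam <- setNames(default_tab$residues$lambda, default_tab$residues$code)
  lam_g <- lam[["G"]]
  recon <- sum((gs$end - gs$start + 1) * (gs$delta_lambda + lam_g)) /
    nchar(fus)
  expect_equal(recon, mean(lam[strsplit(fus, "")[[1]]]), tolerance = 1e-12)
  # backend-evaluated relative fitness responds to hydrophobicity
  be <- backend_surrogate_lambda(default_tab)
  gs3 <- glycine_scan(s, 6, backend = be)
  expect_lt(gs3$fitness[2], 1)   # glycine-substituting the F block hurts
  expect_equal(gs3$fitness[1], 1)   # replacing the G block with G is neutral
})

test_that("g(r) is unity for an ideal gas and integrates to the pair count", {
  set.seed(41)
  n <- 250; nf <- 40; L <- 40
  frames <- replicate(nf, matrix(runif(3 * n, 0, L), n, 3),
                      simplify = FALSE)
  traj <- manual_traj(frames, c(L, L, L), type = rep("G", n))
  r <- radial_distribution(traj, dr = 1)
  mid <- r$r > 4 & r$r < 18
  expect_true(all(abs(r$g[mid] - 1) < 0.1))
  expect_true(all(r$g >= 0))
  # counting closure: rho * integral g 4 pi r^2 dr = mean neighbours in rmax
  rho <- n / L^3
  shell <- 4 / 3 * pi * ((r$r + 0.5)^3 - (r$r - 0.5)^3)
  integral <- sum(r$g * rho * shell)
  # independent neighbour count: brute force with minimum image on one frame
  fr <- frames[[1]]
  cnt <- 0
  for (i in 1:(n - 1)) {
    dx <- abs(fr[i, 1] - fr[(i + 1):n, 1]); dx <- pmin(dx, L - dx)
    dy <- abs(fr[i, 2] - fr[(i + 1):n, 2]); dy <- pmin(dy, L - dy)
    dz <- abs(fr[i, 3] - fr[(i + 1):n, 3]); dz <- pmin(dz, L - dz)
    cnt <- cnt + sum(dx^2 + dy^2 + dz^2 < max(r$r + 0.5)^2)
  }
  expect_equal(integral, 2 * cnt / n, tolerance = 0.05)
})

test_that("g(r) vanishes at the repulsive core in a dense liquid", {
  traj <- toy_slab_traj()
  r <- radial_distribution(traj, dr = 0.5)
  expect_true(all(r$g[r$r < 3] == 0))
  expect_gt(max(r$g), 1)   # structured first shell
  expect_warning(radial_distribution(traj, dr = 0.5, rmax = 100),
                 "truncated")
})

test_that("energy decomposition matches the engine's own logs", {
  traj <- toy_slab_traj()
  tab <- toy_slab_table()
  dec <- energy_decomposition(traj, tab)
  n <- dim(traj$frames)[1]
  expect_equal(dec$e_lj, mean(traj$log$e_lj) / n, tolerance = 1e-10)
  expect_equal(dec$e_coul, mean(traj$log$e_coul) / n, tolerance = 1e-10)
  expect_equal(dec$e_bond, mean(traj$log$e_bond) / n, tolerance = 1e-10)
  # a fully neutral sequence has exactly zero Coulomb energy
  expect_equal(dec$e_coul, 0)
})
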