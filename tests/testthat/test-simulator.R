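test_that("slab construction counts beads and bonds and respects spacing", {
  tab <- toy_table()
  spec <- system_spec("GASPGASPGS", n_chains = 4,
                      box = c(40, 40, 60), seed = 5, table = tab)
  cfg <- build_slab(spec, tab)
  expect_equal(nrow(cfg$positions), 40)
  expect_equal(nrow(cfg$bonds), 36)
  sig_min <- min(residue_params(tab, unique(cfg$type))$sigma)
  md <- idpevolve:::cpp_min_dist(cfg$positions, cfg$box, cfg$bonds - 1L)
  expect_gte(md, 0.8 * sig_min)
  # positions wrapped into the primary cell
  expect_true(all(cfg$positions >= 0))
  expect_true(all(sweep(cfg$positions, 2, cfg$box) < 0))
  # seed determinism
  cfg2 <- build_slab(spec, tab)
  expect_identical(cfg$positions, cfg2$positions)
  spec3 <- spec; spec3$seed <- 99L
  expect_false(identical(build_slab(spec3, tab)$positions, cfg$positions))
  # over-packing fails loudly
  spec_dense <- system_spec(strrep("W", 40), n_chains = 400,
                            box = c(30, 30, 40), seed = 1, table = tab)
  expect_error(build_slab(spec_dense, tab), "density too high")
})

test_that("mixed systems replace the stated fraction with equal-length poly-U", {
  tab <- toy_table()
  tab$residues <- dplyr::bind_rows(
    tab$residues,
    tibble::tibble(code = "U", lambda = 0.3, sigma = 6.0, charge = -1L,
                   mass = 306.2))
  spec <- system_spec(strrep("AG", 5), n_chains = 16, box = c(40, 40, 80),
                      seed = 2, table = tab)
  cfg <- build_mixed_system(spec, 1 / 8, tab)
  is_rna <- grepl("^U+$", cfg$sequences)
  expect_equal(sum(is_rna), 2)
  expect_equal(sum(!is_rna), 14)
  expect_true(all(nchar(cfg$sequences[is_rna]) == 10))
  # fraction 0 degenerates to the plain slab
  cfg0 <- build_mixed_system(spec, 0, tab)
  expect_identical(cfg0$positions, build_slab(spec, tab)$positions)
  # non-integer chain counts and missing parameters are rejected
  expect_error(build_mixed_system(spec, 1 / 3, tab), "integer")
  expect_error(build_mixed_system(spec, 1 / 8, toy_table()), "poly-U")
})

test_that("identical spec and seed give bit-identical thermodynamic logs", {
  tab <- toy_table()
  spec <- system_spec(strrep("AG", 4), n_chains = 4, box = c(30, 30, 45),
                      temperature = 300, n_equil = 100, n_prod = 300,
                      sample_interval = 50, seed = 8, table = tab)
  cfg <- build_slab(spec, tab)
  t1 <- run_langevin(cfg, spec, tab)
  t2 <- run_langevin(cfg, spec, tab)
  expect_identical(t1$log, t2$log)
  expect_identical(t1$frames, t2$frames)
  expect_equal(dim(t1$frames)[3], floor(spec$n_prod / spec$sample_interval))
  expect_true(all(diff(t1$log$time_fs) > 0))
})

test_that("a zero-temperature harmonic dimer at its minimum stays put", {
  tab <- toy_table(epsilon = 0)
  spec <- system_spec("GG", n_chains = 1, box = c(30, 30, 30),
                      temperature = 0, friction = 1, n_equil = 0,
                      n_prod = 500, sample_interval = 100, seed = 1,
                      table = tab)
  pos0 <- rbind(c(15, 15, 13.1), c(15, 15, 13.1 + 3.8))
  cfg <- manual_config(pos0, spec$box, c("G", "G"), chain_id = c(1L, 1L),
                       bonds = matrix(c(1L, 2L), 1), sequences = "GG")
  traj <- run_langevin(cfg, spec, tab)
  expect_equal(traj$final$positions, pos0, tolerance = 1e-10)
})

test_that("kinetic temperature equipartitions to the thermostat setting", {
  tab <- ideal_table()
  spec <- system_spec("G", n_chains = 60, box = c(60, 60, 60),
                      temperature = 300, friction = 2, n_equil = 500,
                      n_prod = 6000, sample_interval = 20, seed = 4,
                      table = tab)
  cfg <- build_bulk(spec, tab)
  traj <- run_langevin(cfg, spec, tab)
  kB <- 1.987204259e-3
  ke_per_dof <- mean(traj$log$kinetic) / (3 * 60)
  # standard error inflated for velocity autocorrelation
  se <- sd(traj$log$kinetic / (3 * 60)) / sqrt(nrow(traj$log) / 4)
  expect_lt(abs(ke_per_dof - kB * 300 / 2), 3 * se + 1e-4)
})

test_that("zero-friction limit conserves total energy", {
  tab <- toy_table()
  spec <- system_spec(strrep("AG", 3), n_chains = 2, box = c(30, 30, 36),
                      temperature = 150, friction = 0, timestep = 5,
                      n_equil = 0, n_prod = 10000, sample_interval = 100,
                      seed = 6, table = tab)
  cfg <- build_slab(spec, tab)
  traj <- run_langevin(cfg, spec, tab)
  etot <- traj$log$kinetic + traj$log$e_lj + traj$log$e_coul + traj$log$e_bond
  scale <- max(abs(etot[1]), traj$log$kinetic[1])
  drift <- abs(etot[length(etot)] - etot[1]) / scale
  expect_lt(drift, 1e-4)
  expect_lt(max(abs(etot - etot[1])) / scale, 1e-3)
})

test_that("intensive observables are stable under system-size doubling", {
  tab <- toy_table()
  mk <- function(nc, lz, seed) {
    spec <- system_spec(strrep("A", 8), n_chains = nc, box = c(34, 34, lz),
                        temperature = 300, n_equil = 1500, n_prod = 2500,
                        sample_interval = 50, seed = seed, table = tab)
    traj <- run_langevin(build_bulk(spec, tab), spec, tab)
    c(tbar = mean(traj$log$temperature),
      elj = mean(traj$log$e_lj) / (nc * 8))
  }
  a <- mk(6, 68, 21)
  b <- mk(12, 136, 22)
  expect_equal(unname(a["tbar"]), 300, tolerance = 0.05)
  expect_equal(unname(b["tbar"]), 300, tolerance = 0.05)
  expect_equal(unname(a["elj"]), unname(b["elj"]),
               tolerance = 0.25)
})

test_that("MSD vanishes at lag zero and for a frozen trajectory", {
  frame <- matrix(runif(30, 0, 20), 10, 3)
  traj <- manual_traj(rep(list(frame), 8), c(20, 20, 20),
                      type = rep("G", 10))
  msd <- mean_squared_displacement(traj)
  expect_equal(msd$msd[1], 0)
  expect_equal(max(msd$msd), 0)
  expect_equal(diffusion_coefficient(msd), 0)
  short <- manual_traj(rep(list(frame), 3), c(20, 20, 20), rep("G", 10))
  expect_error(mean_squared_displacement(short), "insufficient")
})

test_that("free Brownian beads diffuse at kBT/(m gamma)", {
  tab <- ideal_table()
  spec <- system_spec("G", n_chains = 80, box = c(80, 80, 80),
                      temperature = 300, friction = 1, n_equil = 0,
                      n_prod = 15000, sample_interval = 25, seed = 9,
                      table = tab)
  cfg <- build_bulk(spec, tab)
  traj <- run_langevin(cfg, spec, tab)
  D <- diffusion_coefficient(mean_squared_displacement(traj,
                                                       max_lag_frac = 0.3),
                             fit_window = c(0.1, 0.9))
  kB <- 1.987204259e-3; f_conv <- 4.184e-4
  D_theory <- kB * 300 * f_conv / (57.05 * 1e-3) * 1e6
  expect_equal(D, D_theory, tolerance = 0.1)
})
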