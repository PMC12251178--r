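test_that("founder counts are largest-remainder apportionments", {
  p <- sim_params(n_total = 1e6, generations = 0, u = 0)
  expect_equal(make_population(p)$count, c(50000, 50000, 450000, 450000))

  p2 <- sim_params(n_total = 100, generations = 0, u = 0,
                   initial_fractions = rep(0.25, 4))
  expect_equal(make_population(p2)$count, c(25, 25, 25, 25))

  p3 <- sim_params(n_total = 10, generations = 0, u = 0,
                   initial_fractions = c(0.33, 0.33, 0.34, 0))
  pop <- make_population(p3)
  expect_equal(pop$count, c(3, 3, 4))      # zero-count lineage pruned
  expect_equal(sum(pop$count), 10)
  expect_true(all(pop$fitness == 1))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(initial_fractions = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(sim_params(u = -1e-5), "0, 1")
  expect_error(dfe_params("gamma", mean_s = 0.01, shape = -1), "positive")
  expect_error(dfe_params("gamma", mean_s = 0), "positive")
})

test_that("sampled effects follow the configured DFE", {
  expect_equal(sample_effects(5, dfe_params("fixed", 0.01)), rep(0.01, 5))

  set.seed(11)
  x <- sample_effects(1e5, dfe_params("gamma", mean_s = 0.01, shape = 1))
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 0.01), 3 * 0.01 / sqrt(1e5))

  y <- sample_effects(1e5, dfe_params("gamma", mean_s = 0.01, shape = 100))
  expect_lt(abs(var(y) - 1e-6), 0.1 * 1e-6)
})

test_that("one neutral generation is plain multinomial resampling", {
  p <- sim_params(n_total = 1000, generations = 1, u = 0,
                  initial_fractions = c(0.5, 0.5, 0, 0))
  state <- make_population(p)
  set.seed(21)
  counts <- replicate(1e4, wf_step(state$marker_id, state$fitness,
                                   state$count, p)$count[1])
  se <- sqrt(1000 * 0.25) / sqrt(1e4)
  expect_lt(abs(mean(counts) - 500), 3 * se)
})

test_that("a single lineage with u = 0 is invariant under resampling", {
  p <- sim_params(n_total = 500, generations = 1, u = 0,
                  initial_fractions = c(1, 0, 0, 0))
  state <- make_population(p)
  nxt <- advance_generation(state, p)
  expect_equal(nxt$count, 500)
  expect_equal(nxt$marker_id, 0L)
})

test_that("selection shifts expected frequencies by the WF recursion", {
  # two lineages at 0.5 with fitnesses 1.01 and 1: expected mutant frequency
  # after one generation is 0.5 * 1.01 / (0.5 * 1.01 + 0.5) = 0.50249
  p <- sim_params(n_total = 1000, generations = 1, u = 0,
                  initial_fractions = c(0.5, 0.5, 0, 0))
  set.seed(31)
  freqs <- replicate(1e4, {
    stp <- wf_step(c(0L, 1L), c(1.01, 1), c(500, 500), p)
    sum(stp$count[stp$marker == 0]) / 1000
  })
  expected <- 0.5 * 1.01 / (0.5 * 1.01 + 0.5)
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - expected), 3 * se)
})

test_that("census size is conserved through every generation", {
  p <- sim_params(n_total = 2000, generations = 40, u = 1e-3,
                  dfe = dfe_params("gamma", 0.05, 1), seed = 5,
                  record_every = 1)
  set.seed(p$seed)
  state <- make_population(p)
  for (g in 1:40) {
    state <- advance_generation(state, p)
    expect_identical(sum(state$count), 2000)
  }
})

test_that("replicates are bit-identical for identical parameters and seed", {
  p <- sim_params(n_total = 5000, generations = 60, u = 1e-4,
                  dfe = dfe_params("gamma", 0.02, 1), seed = 77)
  expect_identical(run_replicate(p), run_replicate(p))
})

test_that("mutation counts match the N*u*g expectation", {
  # 200 replicates at N=1e4, g=50, u=1e-3: E[mutations] = 500
  set.seed(41)
  counts <- vapply(1:200, function(i) {
    run_replicate(sim_params(n_total = 1e4, generations = 50, u = 1e-3,
                             dfe = dfe_params("fixed", 0.01),
                             seed = 4000 + i))$n_mutations_arisen
  }, numeric(1))
  se <- sd(counts) / sqrt(200)
  expect_lt(abs(mean(counts) - 500), 3 * se)
})

test_that("trajectory snapshots land where requested and sum to one", {
  p <- sim_params(n_total = 1000, generations = 47, u = 0, seed = 9,
                  record_every = 18)
  tr <- tidy(run_replicate(p))
  expect_setequal(unique(tr$generation), c(0, 18, 36, 47))
  sums <- tr %>% dplyr::group_by(generation) %>%
    dplyr::summarise(s = sum(frequency))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("outcome classification implements the experimental pattern", {
  p <- sim_params(n_total = 1e4, generations = 5, u = 0, seed = 1)
  r <- run_replicate(p)
  # neutral short run keeps all four markers: incompatible
  out <- classify_outcome(r)
  expect_equal(out$markers_maintained_A, 2L)
  expect_equal(out$markers_maintained_B1, 2L)
  expect_false(out$compatible)

  # doctor the final snapshot into the experimental pattern
  r2 <- r
  fin <- r2$trajectory$generation == max(r2$trajectory$generation)
  r2$trajectory$within_strain_frequency[fin] <- c(0, 1, 0.4, 0.6)
  r2$trajectory$frequency[fin] <- c(0, 0.1, 0.36, 0.54)
  out2 <- classify_outcome(r2)
  expect_equal(out2$markers_maintained_A, 1L)
  expect_equal(out2$markers_maintained_B1, 2L)
  expect_true(out2$compatible)

  # strain A entirely absent: incompatible regardless of B1
  r3 <- r2
  r3$trajectory$frequency[fin] <- c(0, 0, 0.4, 0.6)
  r3$trajectory$within_strain_frequency[fin] <- c(NA, NA, 0.4, 0.6)
  out3 <- classify_outcome(r3)
  expect_false(out3$strain_A_extant)
  expect_false(out3$compatible)
})

test_that("neutral heterozygosity decays as (1 - 1/N)^t", {
  # Wright-Fisher closed form at N=100, two lineages at 0.5
  n_rep <- 3000
  N <- 100
  h <- matrix(NA_real_, n_rep, 2)
  for (i in seq_len(n_rep)) {
    tr <- tidy(run_replicate(sim_params(
      n_total = N, generations = 50, u = 0,
      initial_fractions = c(0.5, 0.5, 0, 0), seed = 50000 + i,
      record_every = 10)))
    for (j in 1:2) {
      t_at <- c(10, 50)[j]
      pj <- tr$frequency[tr$generation == t_at & tr$marker_id == 0]
      h[i, j] <- 2 * pj * (1 - pj)
    }
  }
  for (j in 1:2) {
    t_at <- c(10, 50)[j]
    expected <- 0.5 * (1 - 1 / N)^t_at
    se <- sd(h[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(h[, j]) - expected), 3 * se)
  }
})

test_that("mean selected-lineage frequency follows the logistic recursion", {
  # lineage at x0 = 0.2 with fitness 1+s: x_t = x0(1+s)^t/(x0(1+s)^t + 1-x0)
  s <- 0.1; x0 <- 0.2; N <- 2000; tmax <- 20
  n_rep <- 400
  p <- sim_params(n_total = N, generations = 1, u = 0,
                  initial_fractions = c(x0, 1 - x0, 0, 0))
  set.seed(61)
  traj <- matrix(NA_real_, n_rep, tmax)
  for (i in seq_len(n_rep)) {
    marker <- c(0L, 1L); fitness <- c(1 + s, 1); count <- c(x0 * N, (1 - x0) * N)
    for (t in seq_len(tmax)) {
      stp <- wf_step(marker, fitness, count, p)
      marker <- stp$marker; fitness <- stp$fitness; count <- stp$count
      traj[i, t] <- sum(count[marker == 0]) / N
    }
  }
  for (t in c(5, 10, 20)) {
    expected <- x0 * (1 + s)^t / (x0 * (1 + s)^t + 1 - x0)
    se <- sd(traj[, t]) / sqrt(n_rep)
    expect_lt(abs(mean(traj[, t]) - expected), 3 * se)
  }
})

test_that("simulation trajectories round-trip through TSV", {
  r <- run_replicate(sim_params(n_total = 500, generations = 10, u = 0,
                                seed = 3, record_every = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sim_result(r, path)
  back <- read_tsv_commented(path)
  expect_equal(as.data.frame(back), as.data.frame(r$trajectory),
               tolerance = 1e-12)
  hdr <- readLines(path)
  expect_true(any(grepl("^# seed=3", hdr)))
})
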