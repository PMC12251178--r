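test_that("generators are deterministic given the configuration seed", {
  cfg <- synth_config(seed = 5, ref_length = 2000, tract = c(500, 1500),
                      n_reads = 300)
  expect_identical(gen_marker_trajectories(cfg), gen_marker_trajectories(cfg))
  expect_identical(gen_variant_tables(cfg), gen_variant_tables(cfg))
  expect_identical(gen_coverage(cfg, 0.5), gen_coverage(cfg, 0.5))
  expect_identical(gen_reads(cfg), gen_reads(cfg))
  expect_identical(gen_growth(cfg), gen_growth(cfg))
  expect_identical(gen_competition(cfg), gen_competition(cfg))
})

test_that("trajectory generator encodes the planted outcomes", {
  cfg <- synth_config(seed = 8, n_mice = 4, load_log10_sd = 0)
  mt <- gen_marker_trajectories(cfg)
  # zero-noise B1 loads sit at 10^8.5, split between two markers
  b1 <- mt$trajectory %>%
    dplyr::mutate(strain = marker_strain(marker)) %>%
    dplyr::filter(strain == "B1") %>%
    dplyr::group_by(mouse_id, day) %>%
    dplyr::summarise(total = sum(cfu_per_g), .groups = "drop")
  expect_true(all(abs(log10(b1$total) - 8.5) < 0.01))
  # a lost marker is emitted as 0 from its day of loss onward
  lostA <- mt$truth %>% dplyr::filter(strain == "A", truth_status == "lost")
  expect_equal(nrow(lostA), 4)   # p_loss A defaults to 1
  for (i in seq_len(nrow(lostA))) {
    lost_marker <- setdiff(c("CFP", "YFP"), lostA$truth_fixed_marker[i])
    late <- mt$trajectory %>%
      dplyr::filter(mouse_id == lostA$mouse_id[i], marker == lost_marker,
                    day >= lostA$truth_day_of_loss[i])
    expect_true(all(late$cfu_per_g == 0))
  }
})

test_that("classification recovers the generator's planted truth", {
  cfg <- synth_config(seed = 12, n_mice = 8, load_log10_sd = 0.2)
  mt <- gen_marker_trajectories(cfg)
  calls <- classify_polymorphism(mt$trajectory)
  merged <- dplyr::inner_join(calls, mt$truth, by = c("mouse_id", "strain"))
  expect_gte(mean(merged$status == merged$truth_status), 0.95)
  lost <- merged[merged$status == "lost", ]
  expect_true(all(lost$fixed_marker == lost$truth_fixed_marker))
})

test_that("simulator-driven trajectories compose simulator frequencies with loads", {
  cfg <- synth_config(seed = 3, n_mice = 2, load_log10_sd = 0,
                      days = c(0, 44, 88))
  sims <- lapply(1:2, function(i) {
    run_replicate(sim_params(n_total = 1e4, generations = 1584, u = 0,
                             seed = 30 + i))
  })
  mt <- gen_marker_trajectories(cfg, mode = "from_simulator",
                                sim_results = sims)
  for (m in 1:2) {
    tr <- sims[[m]]$trajectory
    for (d in c(0, 44, 88)) {
      snap <- tr %>% dplyr::filter(generation == d * 18)
      wsf <- snap$within_strain_frequency[snap$marker_id == 2]
      emitted <- mt$trajectory %>%
        dplyr::filter(mouse_id == m, day == d, marker == "mCherry")
      expected <- round(10^8.5 * wsf)
      if (expected < 300) expected <- 0
      expect_equal(emitted$cfu_per_g, expected)
    }
  }
})

test_that("variant generator plants parallelism, sweeps and frequency sums", {
  cfg <- synth_config(seed = 21, parallelism_fraction = 0)
  vt <- gen_variant_tables(cfg)
  par <- parallel_targets(vt$variants %>% dplyr::filter(strain == "B1"))
  expect_equal(nrow(par), 0)

  cfg2 <- synth_config(seed = 22, parallelism_fraction = 0.5)
  vt2 <- gen_variant_tables(cfg2)
  par2 <- parallel_targets(vt2$variants %>% dplyr::filter(strain == "B1"))
  expect_gt(nrow(par2), 0)

  sw <- find_sweeps(vt2$variants %>% dplyr::filter(strain == "A"))
  truth_a <- vt2$truth$sweeps$truth_n_sweeps[vt2$truth$sweeps$strain == "A"]
  expect_equal(nrow(sw), truth_a)
  expect_equal(truth_a, 9L)
  sw_b1 <- find_sweeps(vt2$variants %>% dplyr::filter(strain == "B1"))
  expect_equal(nrow(sw_b1), 0L)

  # M(t) computed from the table equals the truth frequency sums
  for (st in c("A", "B1")) {
    tab <- vt2$variants %>% dplyr::filter(strain == st)
    r <- tidy(mutation_rate(tab, generations = 1584))
    truth <- vt2$truth$per_mouse %>% dplyr::filter(strain == st)
    expect_equal(sort(r$freq_sum), sort(truth$truth_freq_sum),
                 tolerance = 1e-12)
  }
})

test_that("read generator output round-trips through FASTA with truth labels", {
  skip_if_not_installed("Biostrings")
  cfg <- synth_config(seed = 9, ref_length = 1500, tract = c(400, 1100),
                      n_reads = 120)
  rd <- gen_reads(cfg)
  expect_true(all(nchar(rd$reads$seq) == cfg$read_length))
  expect_true(all(rd$reads$truth_origin %in% c("donor", "recipient")))
  reads_path <- withr::local_tempfile(fileext = ".fasta")
  refs_path <- withr::local_tempfile(fileext = ".fasta")
  write_read_fasta(rd, reads_path, refs_path)
  back <- Biostrings::readDNAStringSet(reads_path)
  expect_equal(length(back), 120)
  expect_equal(unname(as.character(back)), rd$reads$seq)
  expect_true(all(grepl("origin=(donor|recipient) tract=400-1100",
                        names(back))))
  refs <- Biostrings::readDNAStringSet(refs_path)
  expect_equal(as.character(refs[["recipient"]]), rd$recipient_ref)
  # references differ exactly at the reported variant sites
  a <- strsplit(rd$recipient_ref, NULL)[[1]]
  b <- strsplit(rd$donor_ref, NULL)[[1]]
  expect_equal(which(a != b) - 1L, rd$variant_sites)
})

test_that("zero-donor and all-donor tracts produce the expected calls", {
  cfg0 <- synth_config(seed = 31, ref_length = 3000, tract = c(1000, 2000),
                       n_reads = 2500, donor_fraction = 0)
  rd0 <- gen_reads(cfg0)
  sites0 <- rd0$variant_sites[rd0$variant_sites >= 1000 &
                                rd0$variant_sites < 2000]
  calls0 <- purrr::map_dfr(sites0, function(p) {
    classify_hgt_variant(rd0$reads, rd0$donor_ref, rd0$recipient_ref, p)
  })
  expect_true(all(!calls0$hgt_flag[!calls0$no_call]))

  cfg1 <- synth_config(seed = 32, ref_length = 3000, tract = c(1000, 2000),
                       n_reads = 2500, donor_fraction = 1)
  rd1 <- gen_reads(cfg1)
  rl <- cfg1$read_length
  core <- rd1$variant_sites[rd1$variant_sites >= 1000 + rl &
                              rd1$variant_sites < 2000 - rl]
  calls1 <- purrr::map_dfr(core, function(p) {
    classify_hgt_variant(rd1$reads, rd1$donor_ref, rd1$recipient_ref, p)
  })
  calls1 <- calls1[!calls1$no_call, ]
  expect_true(all(calls1$hgt_flag))
})

test_that("growth and competition generators hit their planted parameters", {
  g <- gen_growth(synth_config(seed = 14,
                               growth = list(r = 1.08, k = 0.8, x0 = 1e-3,
                                             blank = 0.04, noise_sd = 0)))
  fit <- max_growth_rate(g$curve, blank = 0.04)
  expect_lt(abs(fit$rate - 1.08) / 1.08, 0.05)

  comp <- gen_competition(synth_config(
    seed = 15, competition = list(s_per_day = 4.0, noise_sd = 0, n_mice = 4,
                                  days = 0:4, ref_cfu = 1e6)))
  est <- glance(selection_coefficient(comp$series))
  expect_equal(est$s_per_day, 4.0, tolerance = 1e-9)
  expect_equal(est$s_per_generation_rounded, 0.22)
})

test_that("generator tables round-trip through the TSV interchange format", {
  cfg <- synth_config(seed = 17, n_mice = 3)
  vt <- gen_variant_tables(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_commented(vt$variants, path, header = "synthetic variants")
  back <- read_tsv_commented(path)
  expect_equal(as.data.frame(back), as.data.frame(vt$variants),
               tolerance = 1e-12)
})
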