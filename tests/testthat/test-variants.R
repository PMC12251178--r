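test_that("generation conversion uses 18 generations per day", {
  expect_equal(elapsed_generations(88), 1584)
  expect_equal(elapsed_generations(43), 774)
  expect_equal(elapsed_generations(0), 0)
})

test_that("ancestral false-positive filter applies the strict thresholds", {
  evolved <- tibble::tibble(position = c(10, 20, 30, 40),
                            var_class = "SNP_NS",
                            frequency = c(0.3, 0.4, 0.5, 0.6),
                            supporting_reads = 30)
  anc <- tibble::tibble(
    position = c(10, 20, 30),
    var_class = "SNP_NS",
    frequency = c(0.02, 0.015, 0.5),   # 0.015 is NOT above the threshold
    supporting_reads = c(4, 10, 3))    # 3 is NOT more than three
  out <- filter_ancestral_false_positives(evolved, anc)
  expect_equal(out$position, c(20, 30, 40))

  # idempotent, and identity on an empty blacklist
  expect_equal(filter_ancestral_false_positives(out, anc), out)
  expect_equal(filter_ancestral_false_positives(evolved, anc[0, ]),
               tibble::as_tibble(evolved))

  # consensus-mode ancestral calls are blacklisted regardless of thresholds
  anc2 <- tibble::tibble(position = 40, var_class = "SNP_NS",
                         frequency = 0.001, supporting_reads = 1,
                         mode = "consensus")
  expect_equal(filter_ancestral_false_positives(evolved, anc2)$position,
               c(10, 20, 30))
})

test_that("event counts reproduce the printed per-strain totals and means", {
  tbl <- make_printed_variant_table()
  counts <- count_events(tbl, n_mice = 8)
  b1 <- counts[counts$strain == "B1", ]
  a <- counts[counts$strain == "A", ]
  expect_equal(unique(b1$total), 82L)
  expect_equal(unique(a$total), 38L)
  expect_equal(unique(b1$mean_per_mouse), 10.3)  # 82/8 = 10.25 -> 10.3
  expect_equal(unique(a$mean_per_mouse), 4.8)    # 38/8 = 4.75 -> 4.8
  expect_equal(b1$n[b1$var_class == "SNP_NS"], 34L)
  expect_equal(sum(b1$n), 82L)
  expect_equal(sum(a$n), 38L)
  expect_equal(nrow(count_events(tbl[0, ])), 0)
})

test_that("event totals are additive and permutation invariant", {
  tbl <- make_printed_variant_table()
  shuf <- tbl[sample(nrow(tbl)), ]
  expect_equal(dplyr::arrange(count_events(shuf, 8), strain, var_class),
               dplyr::arrange(count_events(tbl, 8), strain, var_class))
  half <- count_events(tbl[tbl$mouse_id <= 4, ], 8)
  other <- count_events(tbl[tbl$mouse_id > 4, ], 8)
  expect_equal(sum(half$n[half$strain == "B1"]) +
                 sum(other$n[other$strain == "B1"]), 82L)
})

test_that("dN/dS is the raw count ratio with a division guard", {
  tbl <- make_printed_variant_table()
  d <- dn_ds(tbl)
  expect_equal(d$dnds[d$strain == "B1"], 34 / 4)  # 8.5
  expect_equal(d$dnds[d$strain == "A"], 5)
  none <- tibble::tibble(strain = "A", var_class = rep("SNP_NS", 10))
  d2 <- dn_ds(none)
  expect_true(d2$undefined)
  expect_true(is.na(d2$dnds))
  equal <- tibble::tibble(strain = "A",
                          var_class = rep(c("SNP_NS", "SNP_S"), 5))
  expect_equal(dn_ds(equal)$dnds, 1.0)
})

test_that("sweep detection uses a strict 95% threshold and flags fixation", {
  tbl <- tibble::tibble(strain = "A", mouse_id = c(1, 1, 2),
                        position = 1:3, var_class = "SNP_NS",
                        frequency = c(0.96, 0.95, 1.0))
  sw <- find_sweeps(tbl)
  expect_equal(sort(sw$frequency), c(0.96, 1.0))
  expect_equal(sw$fixed[sw$frequency == 1], TRUE)
  expect_false(0.95 %in% sw$frequency)
})

test_that("parallelism separates gene-level from mutation-level hits", {
  tbl <- tibble::tibble(
    strain = "A",
    mouse_id = c(1, 3, 5, 2, 4, 6),
    position = c(100, 200, 300, 400, 400, 999),
    var_class = "SNP_NS",
    target = c("frlR", "frlR", "frlR", "fimE", "fimE", "unique1"),
    frequency = 0.5)
  par <- parallel_targets(tbl)
  frl <- par[par$target == "frlR", ]
  expect_equal(frl$level, "gene")
  expect_equal(frl$n_mice, 3L)
  fim <- par[par$target == "fimE", ]
  expect_setequal(fim$level, c("gene", "mutation"))  # identical SNP, 2 mice
  expect_true(all(fim$n_mice == 2))
  expect_false("unique1" %in% par$target)
  expect_equal(par$n_mice, sort(par$n_mice, decreasing = TRUE))

  uniq <- tibble::tibble(strain = "A", mouse_id = 1:3, position = 1:3,
                         var_class = "SNP_NS", target = c("a", "b", "c"),
                         frequency = 0.5)
  expect_equal(nrow(parallel_targets(uniq)), 0)
  expect_error(parallel_targets(uniq[1, ]), "two mice")
})

test_that("convergence detects shared genes and shared pathways", {
  ta <- tibble::tibble(mouse_id = c(1, 2), target = c("fimH", "barA"))
  tb <- tibble::tibble(mouse_id = c(1, 3), target = c("fimH", "uvrY"))
  pm <- tibble::tibble(target = c("barA", "uvrY"),
                       pathway = "BarA/UvrY")
  conv <- convergent_targets(ta, tb, pm)
  gene <- conv[conv$level == "gene", ]
  expect_equal(gene$target, "fimH")
  expect_true(gene$same_mouse)
  path <- conv[conv$level == "pathway", ]
  expect_equal(path$target, "BarA/UvrY")
  expect_equal(path$targets_A, "barA")
  expect_equal(path$targets_B1, "uvrY")
  expect_false(path$same_mouse)
  empty <- convergent_targets(tibble::tibble(mouse_id = 1, target = "x"),
                              tibble::tibble(mouse_id = 1, target = "y"))
  expect_equal(nrow(empty), 0)
})

test_that("M(t) is the frequency sum over generations, linear in frequency", {
  one <- tibble::tibble(mouse_id = 1, frequency = 1)
  expect_equal(glance(mutation_rate(one, 1584))$mean_m_t, 1 / 1584)

  # frequency sums on the scale of the strain B1 and A estimates
  freqs_b1 <- c(0.9, 0.8, 0.7, 0.451)            # sums to 2.851
  tbl <- tibble::tibble(mouse_id = 1, frequency = freqs_b1)
  expect_equal(glance(mutation_rate(tbl, 1584))$mean_m_t, 2.851 / 1584)
  expect_equal(signif(glance(mutation_rate(tbl, 1584))$mean_m_t, 3), 1.80e-3)

  doubled <- tbl
  doubled$frequency <- pmin(doubled$frequency * 2, 1)
  # linearity checked with an uncapped doubling
  tbl_small <- tibble::tibble(mouse_id = 1, frequency = c(0.1, 0.2))
  tbl_big <- tibble::tibble(mouse_id = 1, frequency = c(0.2, 0.4))
  expect_equal(glance(mutation_rate(tbl_big, 774))$mean_m_t,
               2 * glance(mutation_rate(tbl_small, 774))$mean_m_t)

  expect_equal(glance(mutation_rate(one[0, ], 1584))$mean_m_t, 0)
  expect_error(mutation_rate(one, 0), "> 0")

  # mice without events enter the mean as zeros; normalization divides by bp
  two <- tibble::tibble(mouse_id = c(1, 1), frequency = c(0.5, 0.5))
  g <- glance(mutation_rate(two, 100, n_mice = 2, genome_size = 4.5e6))
  expect_equal(g$mean_m_t, mean(c(1 / 100, 0)))
  expect_equal(g$mean_m_t_per_bp, g$mean_m_t / 4.5e6)
  expect_equal(g$n_mice, 2)
})
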