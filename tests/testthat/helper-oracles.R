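# Independent brute-force Fisher oracle: hypergeometric probabilities from
# binomial coefficients, enumerating every table with the observed margins.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) return(1)
  n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  p_obs <- prob(a)
  p <- 0
  for (x in lo:hi) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7) + 1e-12) p <- p + px
  }
  min(p, 1)
}

# small deterministic marker trajectory: strain A loses its CFP marker by
# day 40, strain B1 keeps both markers at 50/50, constant loads, no noise
make_fixture_trajectory <- function(days = c(0, 10, 20, 30, 40, 50, 60),
                                    n_mice = 2) {
  purrr::map_dfr(seq_len(n_mice), function(m) {
    load_A <- 10^7.4
    load_B1 <- 10^8.5
    f_cfp <- pmax(0, 0.5 * (1 - days / 40))
    dplyr::bind_rows(
      tibble::tibble(mouse_id = m, day = days, marker = "CFP",
                     cfu_per_g = round(load_A * f_cfp)),
      tibble::tibble(mouse_id = m, day = days, marker = "YFP",
                     cfu_per_g = round(load_A * (1 - f_cfp))),
      tibble::tibble(mouse_id = m, day = days, marker = "mCherry",
                     cfu_per_g = round(load_B1 * 0.5)),
      tibble::tibble(mouse_id = m, day = days, marker = "sfGFP",
                     cfu_per_g = round(load_B1 * 0.5)))
  })
}

# variant table reproducing the printed per-class event breakdowns of the
# two strains, spread evenly over 8 mice
make_printed_variant_table <- function() {
  classes_B1 <- c(SNP_NS = 34, SNP_S = 4, SNP_intergenic = 16,
                  IS_insertion = 8, small_indel = 9, large_deletion = 11)
  classes_A <- c(SNP_NS = 10, SNP_S = 2, SNP_intergenic = 1,
                 IS_insertion = 11, small_indel = 5, large_deletion = 9)
  build <- function(strain, classes) {
    n <- sum(classes)
    tibble::tibble(
      strain = strain,
      mouse_id = rep_len(1:8, n),
      day = 88,
      position = seq_len(n) * 1000,
      target = sprintf("%s_gene_%03d", strain, seq_len(n)),
      var_class = rep(names(classes), classes),
      frequency = 0.5,
      supporting_reads = 50)
  }
  dplyr::bind_rows(build("B1", classes_B1), build("A", classes_A))
}
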