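make_pg_fixture <- function() {
  des <- two_group_design(3, names = c("ctrl", "ko"))
  tibble::tibble(
    protein_id = paste0("p", 1:6),
    gene_name = paste0("G", 1:6),
    molecular_weight_kda = 50,
    reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    potential_contaminant = FALSE,
    only_identified_by_site = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    go_terms = c("", "", "blood microparticle;cytosol", "", "", ""),
    localisation = "cytosol",
    is_histone = FALSE,
    ctrl_1 = c(1, 1, 1, 0, 1, 2), ctrl_2 = c(1, 1, 1, 0, 1, 2),
    ctrl_3 = c(1, 1, 1, 0, 1, 2),
    ko_1 = c(1, 1, 1, 0, 1, 4), ko_2 = c(1, 1, 1, 1, 1, 4),
    ko_3 = c(1, 1, 1, 1, 1, 4)
  ) -> tab
  list(table = tab, design = des)
}

test_that("filtering applies flag, GO and zero-count rules in order", {
  fx <- make_pg_fixture()
  # engineered: p1 decoy, p2 site-only, p3 excluded GO, p4 has 4 zeros -> p5,p6 survive
  out <- filter_protein_groups(fx$table, fx$design)
  expect_equal(out$protein_id, c("p5", "p6"))
  rc <- attr(out, "removal_counts")
  expect_equal(rc$rule, c("decoy_contaminant_site", "excluded_go", "zero_values"))
  expect_equal(rc$removed, c(2L, 1L, 1L))
  # a row with 4 zeros of 6 exceeds max_zeros = 3
  tab4 <- fx$table[4, ]
  tab4$reverse <- FALSE
  out4 <- filter_protein_groups(tab4, fx$design)
  expect_equal(nrow(out4), 0)
  # nothing to remove: table unchanged
  clean <- fx$table[5:6, ]
  out_clean <- filter_protein_groups(clean, fx$design, excluded_go = character(0))
  expect_equal(out_clean$protein_id, clean$protein_id)
  expect_equal(sum(attr(out_clean, "removal_counts")$removed), 0L)
  # unknown sample in the design
  bad_design <- dplyr::bind_rows(fx$design,
                                 tibble::tibble(sample = "ghost", group = "ko"))
  expect_error(filter_protein_groups(fx$table, bad_design), "ghost",
               class = "polysomics_input_error")
})

test_that("log2 transform maps zeros to missing and round-trips", {
  fx <- make_pg_fixture()
  tab <- fx$table[5:6, ]
  tab$ctrl_1 <- c(8, 0)
  lg <- log2_transform(tab, fx$design)
  expect_equal(lg$ctrl_1, c(3, NA))
  # round trip of non-missing entries
  set.seed(10)
  tab2 <- tab
  for (s in fx$design$sample) tab2[[s]] <- runif(2, 1, 1e9)
  lg2 <- log2_transform(tab2, fx$design)
  expect_equal(2^as.matrix(lg2[fx$design$sample]),
               as.matrix(tab2[fx$design$sample]), tolerance = 1e-12,
               ignore_attr = TRUE)
  tab_neg <- tab
  tab_neg$ctrl_2[1] <- -1
  expect_error(log2_transform(tab_neg, fx$design), "egative",
               class = "polysomics_input_error")
})

test_that("downshifted imputation draws from the target normal", {
  # column engineered to observed mean 25, sd 2 exactly, 10,000 missing
  set.seed(11)
  obs <- rnorm(500)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 25
  col <- c(obs, rep(NA_real_, 10000))
  data <- as_intensity_tbl(matrix(col, ncol = 1))
  imp <- impute_downshifted(data, seed = 12)
  filled <- imp$s1[is.na(col)]
  expect_lt(abs(mean(filled) - 21.4), 0.05)
  expect_lt(abs(sd(filled) - 0.6), 0.05)
  # distribution matches its target normal (Kolmogorov-Smirnov)
  ks <- suppressWarnings(stats::ks.test(filled, "pnorm", 21.4, 0.6))
  expect_gt(ks$p.value, 0.01)
  # the reported fraction equals the constructed missingness
  expect_equal(imputation_fraction(imp), 10000 / 10500)
  # no missing values: unchanged matrix, fraction 0
  clean <- as_intensity_tbl(matrix(rnorm(50), ncol = 5))
  imp0 <- impute_downshifted(clean, seed = 1)
  expect_equal(as.matrix(imp0[-1]), as.matrix(clean[-1]), ignore_attr = TRUE)
  expect_equal(imputation_fraction(imp0), 0)
  # seeded determinism
  expect_identical(impute_downshifted(data, seed = 5)$s1,
                   impute_downshifted(data, seed = 5)$s1)
  # a 6.68%-missing fixture reports 6.68%
  set.seed(13)
  m <- matrix(rnorm(10000, 25, 2), ncol = 4)
  miss <- sample(length(m), round(0.0668 * length(m)))
  m[miss] <- NA
  imp668 <- impute_downshifted(as_intensity_tbl(m), seed = 14)
  expect_equal(imputation_fraction(imp668), 0.0668, tolerance = 1e-6)
  # under-observed columns direct the user to filter
  tiny <- as_intensity_tbl(matrix(c(1, NA, NA, NA), ncol = 1))
  expect_error(impute_downshifted(tiny), "[Ff]ilter",
               class = "polysomics_input_error")
})

test_that("global imputation scope pools observed statistics", {
  set.seed(15)
  m <- matrix(rnorm(2000, 20, 3), ncol = 4)
  m[sample(length(m), 200)] <- NA
  data <- as_intensity_tbl(m)
  obs <- m[!is.na(m)]
  imp <- impute_downshifted(data, scope = "global", seed = 16)
  filled <- as.matrix(imp[-1])[is.na(m)]
  expect_lt(abs(mean(filled) - (mean(obs) - 1.8 * sd(obs))), 0.1)
  expect_lt(abs(sd(filled) - 0.3 * sd(obs)), 0.1)
})

test_that("with s0 = 0 the moderated d equals the Welch t statistic", {
  set.seed(17)
  fx <- null_matrix_tbl(200, 3)
  res <- s0_permutation_test(fx$data, fx$design, s0 = 0, seed = 1)
  mat <- as.matrix(fx$data[-1])
  t_oracle <- welch_t_oracle(mat, 1:3, 4:6)
  expect_equal(res$d, t_oracle, tolerance = 1e-10)
  # pooled variant against its own direct formula
  res_p <- s0_permutation_test(fx$data, fx$design, s0 = 0,
                               variance = "pooled", seed = 1)
  t_pooled <- apply(mat, 1, function(x) {
    a <- x[1:3]; b <- x[4:6]
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    (mean(b) - mean(a)) / sqrt(sp2 * (2 / 3))
  })
  expect_equal(res_p$d, t_pooled, tolerance = 1e-10)
})

test_that("q-values are monotone in |d| and input contracts are enforced", {
  set.seed(18)
  fx <- null_matrix_tbl(500, 3)
  res <- s0_permutation_test(fx$data, fx$design, s0 = 0.1, seed = 2)
  ord <- order(abs(res$d))
  expect_true(all(diff(res$q[ord]) <= 1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_equal(res$significant, res$q < 0.05)
  # contracts
  expect_error(s0_permutation_test(fx$data, fx$design, s0 = -1),
               class = "polysomics_config_error")
  with_na <- fx$data
  with_na$a_1[1] <- NA
  expect_error(s0_permutation_test(with_na, fx$design), "impute",
               class = "polysomics_input_error")
  small <- fx$data[c("protein_id", "a_1", "b_1", "b_2")]
  small_design <- fx$design[fx$design$sample %in% c("a_1", "b_1", "b_2"), ]
  expect_error(s0_permutation_test(small, small_design),
               class = "polysomics_input_error")
})

test_that("permutation subsampling is seeded and bounded by n_perm", {
  set.seed(19)
  fx <- null_matrix_tbl(100, 4)
  r1 <- s0_permutation_test(fx$data, fx$design, n_perm = 10, seed = 3)
  r2 <- s0_permutation_test(fx$data, fx$design, n_perm = 10, seed = 3)
  expect_identical(r1$q, r2$q)
  expect_equal(attr(r1, "n_perm_used"), 10L)
  r_all <- s0_permutation_test(fx$data, fx$design, n_perm = 250, seed = 3)
  expect_equal(attr(r_all, "n_perm_used"), 34L)  # C(8,4)/2 - 1
})

test_that("automatic s0 selection stabilises d across the variance range", {
  set.seed(20)
  fx <- null_matrix_tbl(1000, 3)
  s0 <- s0_tusher(fx$data, fx$design)
  expect_true(is.numeric(s0) && length(s0) == 1 && s0 > 0)
})

test_that("the proteomic ruler reproduces hand-computed masses and copies", {
  # histone-only table: total mass equals the DNA mass exactly
  h <- tibble::tibble(protein_id = c("h1", "h2"), is_histone = TRUE,
                      molecular_weight_kda = c(11, 14), i = c(2e6, 3e6))
  r <- proteomic_ruler(h, "i", dna_mass_pg = 6.5)
  expect_equal(sum(r$mass_pg), 6.5, tolerance = 1e-12)
  # worked toy: histone 1e6, protein 2e6 at 50 kDa, 6.5 pg DNA
  tab <- tibble::tibble(protein_id = c("h", "x"), is_histone = c(TRUE, FALSE),
                        molecular_weight_kda = c(11, 50), i = c(1e6, 2e6))
  r2 <- proteomic_ruler(tab, "i", dna_mass_pg = 6.5)
  x <- r2[r2$protein_id == "x", ]
  expect_equal(x$mass_pg, 13, tolerance = 1e-12)
  expect_equal(x$copies_per_cell, 13e-12 / 50000 * 6.02214076e23,
               tolerance = 1e-12)
  expect_equal(round(x$copies_per_cell / 1e8, 3), 1.566)
  # scale invariance
  tab2 <- tab
  tab2$i <- tab2$i * 2
  r3 <- proteomic_ruler(tab2, "i", dna_mass_pg = 6.5)
  expect_equal(r3$mass_pg, r2$mass_pg)
  expect_equal(r3$copies_per_cell, r2$copies_per_cell)
  # genome-size alternative
  expect_equal(dna_mass_from_genome(2.7e9, 2),
               2.7e9 * 2 * 615.8771 / 6.02214076e23 * 1e12)
  # failure modes
  no_h <- tab
  no_h$is_histone <- FALSE
  expect_error(proteomic_ruler(no_h, "i", dna_mass_pg = 6.5), "histone",
               class = "polysomics_input_error")
  zero_mw <- tab
  zero_mw$molecular_weight_kda[2] <- 0
  expect_warning(proteomic_ruler(zero_mw, "i", dna_mass_pg = 6.5), "MW")
})

test_that("organelle mass partitioning conserves mass and splits multi-labels", {
  tab <- tibble::tibble(
    protein_id = c("h", "a", "b", "c"),
    is_histone = c(TRUE, FALSE, FALSE, FALSE),
    molecular_weight_kda = c(11, 50, 40, 30),
    i = c(1e6, 1e6, 1e6, 2e6)
  )
  r <- proteomic_ruler(tab, "i", dna_mass_pg = 5)
  loc <- tibble::tibble(
    protein_id = c("h", "a", "b", "c"),
    compartment = c("nucleus", "mitochondrion", "mitochondrion;cytosol", "")
  )
  fr <- organelle_mass_fractions(r, loc)
  expect_equal(sum(fr$percent), 100, tolerance = 1e-9)
  expect_equal(sum(fr$mass_pg), sum(r$mass_pg), tolerance = 1e-9 * sum(r$mass_pg))
  # hand-computed: masses h=5, a=5, b=5 (2.5+2.5), c=10; total 25
  get <- function(comp) fr$mass_pg[fr$compartment == comp]
  expect_equal(get("nucleus"), 5)
  expect_equal(get("mitochondrion"), 5 + 2.5)
  expect_equal(get("cytosol"), 2.5)
  expect_equal(get("unassigned"), 10)
  # single compartment: 100%; two equal proteins in two compartments: 50/50
  fr_all <- organelle_mass_fractions(
    r, tibble::tibble(protein_id = tab$protein_id, compartment = "mitochondrion")
  )
  expect_equal(fr_all$percent, 100)
  two <- proteomic_ruler(
    tibble::tibble(protein_id = c("h", "p1", "p2"),
                   is_histone = c(TRUE, FALSE, FALSE),
                   molecular_weight_kda = 10, i = c(1e6, 5e5, 5e5)),
    "i", dna_mass_pg = 4
  )
  fr2 <- organelle_mass_fractions(
    two, tibble::tibble(protein_id = c("h", "p1", "p2"),
                        compartment = c("nucleus", "er", "golgi"))
  )
  expect_equal(fr2$percent[fr2$compartment == "er"],
               fr2$percent[fr2$compartment == "golgi"])
})
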