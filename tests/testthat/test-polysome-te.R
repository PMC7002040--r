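test_that("pool_fractions splits fractions at the ribosome boundary", {
  counts <- tibble::tibble(transcript_id = c("t1", "t2"),
                           f1 = c(1, 2), f2 = c(1, 2), f3 = c(1, 2),
                           f4 = c(1, 2), f5 = c(1, 2))
  map <- c(f1 = 1, f2 = 2, f3 = 3, f4 = 4, f5 = 5)
  pooled <- pool_fractions(counts, map)
  expect_equal(pooled$light, c(3, 6))
  expect_equal(pooled$heavy, c(2, 4))
  expect_equal(pooled$subpolysomal, c(0, 0))
  # ribosome-free fraction goes to the subpolysomal pool
  sub <- pool_fractions(tibble::tibble(transcript_id = "t", f0 = 7), c(f0 = 0))
  expect_equal(sub$subpolysomal, 7)
  expect_equal(sub$heavy + sub$light, 0)
  # conservation on a random fixture
  set.seed(1)
  rnd <- tibble::tibble(transcript_id = paste0("t", 1:20))
  for (f in names(map)) rnd[[f]] <- rpois(20, 50)
  pooled_rnd <- pool_fractions(rnd, map)
  expect_equal(pooled_rnd$light + pooled_rnd$heavy + pooled_rnd$subpolysomal,
               rowSums(as.matrix(rnd[names(map)])))
  # boundary is configurable; unknown fraction is an input error
  pooled2 <- pool_fractions(counts, map, boundary = 2)
  expect_equal(pooled2$light[1], 2)
  expect_equal(pooled2$heavy[1], 3)
  expect_error(pool_fractions(counts, map[-1]), "f1",
               class = "polysomics_input_error")
})

test_that("compute_te forms within-sample proportions and replicate ratios", {
  counts <- tibble::tibble(
    transcript_id = c("a", "b", "c"),
    control_1_heavy = c(10, 30, 60),
    control_1_light = c(30, 30, 40)
  )
  sheet <- hl_sheet(conditions = "control", replicates = 1)
  te <- compute_te(counts, sheet, min_total = 0, pseudocount = 0)
  # hand oracle: heavy props (.1,.3,.6) over light props (.3,.3,.4)
  expect_equal(te$te_control, c(1 / 3, 1, 1.5))
})

test_that("TE is 1 when heavy and light are identical and is depth-invariant", {
  set.seed(2)
  sheet <- hl_sheet(replicates = 2)
  counts <- tibble::tibble(transcript_id = paste0("t", 1:50))
  base <- rpois(50, 100)
  for (s in sheet$sample_id) counts[[s]] <- base
  te <- compute_te(counts, sheet, min_total = 0)
  expect_equal(te$te_control, rep(1, 50))
  expect_equal(te$te_knockdown, rep(1, 50))
  # scaling one heavy sample's library leaves TE unchanged
  counts2 <- counts
  for (s in sheet$sample_id) counts2[[s]] <- rpois(50, 80)
  te_a <- compute_te(counts2, sheet, min_total = 0, pseudocount = 0)
  counts3 <- counts2
  counts3$control_1_heavy <- 2 * counts3$control_1_heavy
  te_b <- compute_te(counts3, sheet, min_total = 0, pseudocount = 0)
  expect_equal(te_b$te_control, te_a$te_control, tolerance = 1e-12)
})

test_that("low-count transcripts are dropped and reported, bad designs error", {
  sheet <- hl_sheet(replicates = 1)
  counts <- tibble::tibble(
    transcript_id = c("hi", "lo"),
    control_1_heavy = c(100, 1), control_1_light = c(100, 2),
    knockdown_1_heavy = c(100, 1), knockdown_1_light = c(100, 2)
  )
  expect_message(te <- compute_te(counts, sheet, min_total = 10), "dropped 1")
  expect_equal(te$transcript_id, "hi")
  expect_equal(attr(te, "dropped")$transcript_id, "lo")
  # missing light member for a replicate names the replicate
  bad_sheet <- sheet[sheet$sample_id != "knockdown_1_light", ]
  expect_error(compute_te(counts[-4], bad_sheet), "knockdown replicate 1",
               class = "polysomics_input_error")
})

test_that("change_in_te is a symmetric log2 ratio with flagged degenerates", {
  te <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                       te_control = c(2, 1.5, 0),
                       te_knockdown = c(2, 0.75, 1))
  out <- suppressMessages(change_in_te(te))
  expect_equal(out$log2_change[1], 0)
  expect_equal(out$log2_change[2], -1)  # TE halved
  expect_true(is.na(out$log2_change[3]) && out$excluded[3])
  expect_equal(nrow(out), 3)  # flagged, not dropped
  # antisymmetry under condition swap
  swapped <- suppressMessages(
    change_in_te(te, knockdown = "control", control = "knockdown")
  )
  expect_equal(swapped$log2_change[1:2], -out$log2_change[1:2])
})

test_that("shift classification uses strict +/- threshold inequalities", {
  cls <- classify_te_shift(c(-2, -1, 0, 1, 2))
  expect_equal(as.character(cls), c("down", "none", "none", "none", "up"))
  counts <- attr(cls, "class_counts")
  expect_equal(counts$n, c(1L, 3L, 1L))
  expect_equal(as.character(classify_te_shift(c(-1.2, 1.2))), c("down", "up"))
  expect_error(classify_te_shift(c(0, Inf)), "non-finite",
               class = "polysomics_input_error")
  # data-frame interface
  df <- classify_te_shift(tibble::tibble(log2_change = c(-3, 0.2, NA)))
  expect_equal(as.character(df$shift_class), c("down", "none", NA))
  expect_equal(shift_class_counts(df)$n, c(1L, 1L, 0L))
})

test_that("estimated change in TE recovers the simulated effects", {
  cfg <- synth_config(seed = 9, n_transcripts = 2000, beta_gc = -0.6,
                      beta_mito = 0, n_mito = 0, noise_sd = 0,
                      nb_dispersion = 1e-6, library_size = 5e6)
  ts <- generate_transcriptome(cfg, sequences = FALSE)
  sim <- simulate_polysome_experiment(ts, cfg)
  te <- suppressMessages(change_in_te(compute_te(sim$counts, sim$sample_sheet)))
  d <- dplyr::inner_join(te, sim$true_effects, by = "transcript_id")
  d <- dplyr::filter(d, !d$excluded)
  fit <- stats::lm(log2_change ~ true_log2_dte, data = d)
  expect_gt(stats::coef(fit)[2], 0.9)
  expect_lt(stats::coef(fit)[2], 1.1)
  # with all effects zero the mean estimated change is near zero
  cfg0 <- synth_config(seed = 10, n_transcripts = 2000, beta_gc = 0,
                       beta_mito = 0, noise_sd = 0)
  ts0 <- generate_transcriptome(cfg0, sequences = FALSE)
  sim0 <- simulate_polysome_experiment(ts0, cfg0)
  te0 <- suppressMessages(change_in_te(compute_te(sim0$counts, sim0$sample_sheet)))
  expect_lt(abs(mean(te0$log2_change, na.rm = TRUE)), 0.05)
})
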