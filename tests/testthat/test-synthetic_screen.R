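test_that("screen layout places every gene once per replicate on the expected plate count", {
  cfg <- sim_config(n_genes = 700L, seed = 2)
  sim <- simulate_screen(cfg)
  capacity <- 384 - (16 + 4 + 4 + 4)
  n_plates_per_rep <- ceiling(700 / capacity)
  expect_equal(length(unique(sim$wells$plate)), n_plates_per_rep * 3L)
  samples <- sim$wells[sim$wells$role == "sample", ]
  placement <- table(samples$gene, samples$replicate)
  expect_true(all(placement == 1L))
  # roles partition the plate: every plate carries the full control block
  per_plate <- table(sim$wells$plate, sim$wells$role)
  expect_true(all(per_plate[, "ns_control"] == 16L))
  expect_true(all(per_plate[, "pos_control_npc1"] == 4L))
  expect_true(all(rowSums(per_plate) == 384L))
  # control positions are randomised, not fixed
  ns_wells <- sim$wells$well[sim$wells$role == "ns_control"]
  expect_gt(length(unique(ns_wells)), 16L)
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 150L, seed = 7)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$truth, s2$truth)
  d1 <- simulate_deconvolution(cfg, s1$truth, s1$truth$gene[1:10])
  d2 <- simulate_deconvolution(cfg, s2$truth, s2$truth$gene[1:10])
  expect_identical(d1$wells, d2$wells)
  e1 <- simulate_expression(cfg, s1$truth)
  expect_identical(e1, simulate_expression(cfg, s2$truth))
  # a different seed changes the data
  expect_false(identical(s1$wells$mean_intensity,
                         simulate_screen(sim_config(n_genes = 150L, seed = 8))$wells$mean_intensity))
})

test_that("null screens with plate effects yield plate-centred robust z for NS wells", {
  # plates differ in raw scale, but per-plate standardization recentres them
  cfg <- sim_config(n_genes = 356L * 17L, frac_true_up = 0, frac_true_down = 0,
                    cytotox_fraction = 0, plate_effect_sd = 0.3, seed = 1)
  sim <- simulate_screen(cfg)
  norm <- normalize_screen(sim$wells, screen_config())
  expect_gte(length(unique(norm$plate_stats$plate)), 50L)
  # raw plate medians really do vary (multiplicative plate effect present)
  expect_gt(max(norm$plate_stats$center) / min(norm$plate_stats$center), 1.5)
  ns_z <- norm$wellz$z[norm$wellz$role == "ns_control" & norm$wellz$qc_flag == "ok"]
  expect_lt(abs(median(ns_z)), 0.1)
})

test_that("NPC1 positive-control wells run ~30% above the NS wells by construction", {
  cfg <- sim_config(n_genes = 2000L, frac_true_up = 0, frac_true_down = 0,
                    cytotox_fraction = 0, seed = 4)
  sim <- simulate_screen(cfg)
  w <- sim$wells
  ratios <- vapply(unique(w$plate), function(p) {
    mean(w$mean_intensity[w$plate == p & w$role == "pos_control_npc1"]) /
      mean(w$mean_intensity[w$plate == p & w$role == "ns_control"])
  }, numeric(1))
  expect_equal(mean(ratios), 1.30, tolerance = 0.02)
  # and the LDLR negative control sits below NS
  neg <- vapply(unique(w$plate), function(p) {
    mean(w$mean_intensity[w$plate == p & w$role == "neg_control_ldlr"]) /
      mean(w$mean_intensity[w$plate == p & w$role == "ns_control"])
  }, numeric(1))
  expect_lt(mean(neg), 0.5)
})

test_that("deconvolution wells inherit attenuated gene effects with per-siRNA efficacy", {
  cfg <- sim_config(n_genes = 50L, n_replicates = 3L, well_noise_cv = 0.02,
                    cytotox_fraction = 0, seed = 9)
  sim <- simulate_screen(cfg)
  cand <- sim$truth$gene[1:10]
  dc <- simulate_deconvolution(cfg, sim$truth, cand)
  samples <- dc$wells[dc$wells$role == "sample", ]
  expect_equal(nrow(samples), 10L * 3L * 3L)
  expect_equal(nrow(dc$efficacy), 30L)
  expect_true(all(dc$efficacy$efficacy >= 0.3 & dc$efficacy$efficacy <= 1.0))

  # a gene with zero true effect stays at the NS level for every siRNA
  null_gene <- sim$truth$gene[sim$truth$true_screen_effect == 0][1]
  stopifnot(null_gene %in% cand)
  per_plate_ns <- tapply(dc$wells$mean_intensity[dc$wells$role == "ns_control"],
                         dc$wells$plate[dc$wells$role == "ns_control"], mean)
  g <- samples[samples$gene == null_gene, ]
  rel <- g$mean_intensity / per_plate_ns[g$plate]
  expect_equal(unname(mean(rel)), 1.0, tolerance = 0.03)

  # empty candidate list is an empty table, not an error
  empty <- simulate_deconvolution(cfg, sim$truth, character(0))
  expect_equal(nrow(empty$wells), 0L)
})

test_that("expression generator has the stated arity, noise-free limit and null fold-changes", {
  cfg <- sim_config(n_genes = 100L, seed = 3)
  sim <- simulate_screen(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  expect_equal(nrow(expr), 100L * 3L * 2L)
  expect_true(all(expr$expression > 0))

  # noise-free limit: statin/control ratio equals the spiked fold-change
  truth1 <- data.frame(gene = "gX", true_screen_effect = 0, cytotoxic = FALSE,
                       true_statin_log2fc = log2(1.2), true_nldl_log2fc = 0,
                       lipid_gwas_flag = FALSE)
  cfg0 <- sim_config(n_genes = 1L, expr_noise_sd = 1e-9, seed = 5)
  e0 <- simulate_expression(cfg0, truth1)
  ratio <- mean(e0$expression[e0$condition == "statin"]) /
    mean(e0$expression[e0$condition == "control"])
  expect_equal(ratio, 1.2, tolerance = 1e-6)

  # under the null, per-gene mean fold-change ratios centre on 1
  cfgn <- sim_config(n_genes = 2000L, frac_modulated = 0, seed = 6)
  simn <- simulate_screen(cfgn)
  exprn <- simulate_expression(cfgn, simn$truth)
  mt <- tapply(exprn$expression[exprn$condition == "statin"],
               exprn$gene[exprn$condition == "statin"], mean)
  mc <- tapply(exprn$expression[exprn$condition == "control"],
               exprn$gene[exprn$condition == "control"], mean)
  r <- mt / mc[names(mt)]
  expect_lt(abs(mean(r) - 1), 3 * sd(r) / sqrt(length(r)))
})
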