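test_that("gene summaries aggregate usable replicates and drop exclusions", {
  wz <- rbind(make_wellz("gA", c(2.5, 2.1, 0.5)),
              make_wellz("gB", c(1.0, 2.2, 2.3),
                         qc_flag = c("excluded_low_cell_count", "ok", "ok")),
              make_wellz("gC", c(0, 0, 0), qc_flag = "excluded_low_cell_count"))
  wz$z[wz$qc_flag != "ok"] <- NA_real_
  s <- summarize_genes(wz)
  sA <- s[s$gene == "gA", ]
  expect_equal(sA$mean_z, 1.7)
  expect_equal(sA$n_replicates_used, 3L)
  sB <- s[s$gene == "gB", ]
  expect_equal(sB$n_replicates_used, 2L)
  expect_equal(sB$mean_z, 2.25)
  sC <- s[s$gene == "gC", ]
  expect_equal(sC$n_replicates_used, 0L)
  expect_false(sC$scorable)

  # completeness report for genes absent from the z table
  s2 <- summarize_genes(wz, design_genes = c("gA", "gB", "gC", "gD"))
  expect_equal(attr(s2, "missing_genes"), "gD")

  # controls never enter the summaries
  wzc <- rbind(wz, make_wellz("NS", c(3, 3, 3), role = "ns_control"))
  expect_false("NS" %in% summarize_genes(wzc)$gene)
})

test_that("primary hit calls follow the inclusive two-of-three directional rule", {
  wz <- rbind(make_wellz("up1", c(2.5, 2.1, 0.5)),
              make_wellz("mix", c(2.5, -2.1, 1.9)),
              make_wellz("dn1", c(-2.0, -2.0, 0)),
              make_wellz("one", c(2.5, 1.9, 0)),
              make_wellz("up2", c(2.0, 2.0, -0.5)))
  hits <- call_primary_hits(summarize_genes(wz), t = 2.0, k = 2L)
  call <- setNames(hits$hit_call, hits$gene)
  expect_equal(call[["up1"]], "up")
  expect_equal(call[["mix"]], "none")   # one replicate per direction
  expect_equal(call[["dn1"]], "down")   # threshold inclusive: z = -2.0 counts
  expect_equal(call[["one"]], "none")
  expect_equal(call[["up2"]], "up")     # z = +2.0 counts
  expect_equal(hits$n_beyond_up[hits$gene == "up1"], 2L)
})

test_that("raising the threshold or replicate requirement never grows the hit set", {
  # set inclusion is guaranteed in the directional regime 2k > r, where a
  # gene cannot exceed in both directions at once (the published operating
  # point k=2, r=3 lives there)
  set.seed(23)
  wz <- do.call(rbind, lapply(1:200, function(i) {
    make_wellz(sprintf("g%03d", i), rnorm(3, 0, 1.6))
  }))
  s <- summarize_genes(wz)
  hit_set <- function(t, k) {
    h <- call_primary_hits(s, t = t, k = k)
    h$gene[h$hit_call != "none"]
  }
  prev <- hit_set(1.0, 2L)
  for (t in c(1.5, 2.0, 2.5, 3.0)) {
    cur <- hit_set(t, 2L)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_true(all(hit_set(1.5, 3L) %in% hit_set(1.5, 2L)))

  # outside that regime the mixed-direction policy can break inclusion:
  # at k=1 this gene is contradictory (hence none), at k=2 it is an up-hit
  mixed <- summarize_genes(make_wellz("gm", c(2.6, 2.7, -1.8)))
  expect_equal(call_primary_hits(mixed, t = 1.5, k = 1L)$hit_call, "none")
  expect_equal(call_primary_hits(mixed, t = 1.5, k = 2L)$hit_call, "up")
})

test_that("hit ranking orders by mean z with alphabetical tie-break", {
  wz <- rbind(make_wellz("gb", c(2.4, 2.4, 2.4)),
              make_wellz("ga", c(2.4, 2.4, 2.4)),
              make_wellz("gc", c(3.1, 3.1, 3.1)),
              make_wellz("gd", c(-2.8, -2.8, -2.8)),
              make_wellz("ge", c(-2.2, -2.2, -2.2)),
              make_wellz("gn", c(0, 0, 0)))
  ranked <- rank_hits(call_primary_hits(summarize_genes(wz)))
  expect_equal(ranked$gene, c("gc", "ga", "gb", "gd", "ge"))

  none <- call_primary_hits(summarize_genes(make_wellz("gz", c(0, 0, 0))))
  expect_equal(nrow(rank_hits(none)), 0L)
  single <- call_primary_hits(summarize_genes(make_wellz("gz", c(3, 3, 3))))
  expect_equal(rank_hits(single)$gene, "gz")

  expect_error(rank_hits(summarize_genes(wz)), "call_primary_hits")
})

test_that("deconvolution validation is direction-conditional with inclusive bounds", {
  recs <- data.frame(
    gene = c("a", "b", "c", "d"),
    primary_direction = c("up", "up", "down", "down"),
    sirna_z_1 = c(1.7, -1.8, -1.6, 1.9),
    sirna_z_2 = c(0.2, -1.7, 0.0, 1.8),
    sirna_z_3 = c(-0.3, 0.1, 0.0, -1.0),
    stringsAsFactors = FALSE
  )
  v <- validate_deconvolution(recs, t = 1.6, m = 1L)
  expect_equal(v$validated, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(v$n_validating, c(1L, 0L, 1L, 0L))

  # stricter requirement: two concordant siRNAs
  v2 <- validate_deconvolution(recs, t = 1.6, m = 2L)
  expect_equal(sum(v2$validated), 0L)

  bad <- recs; bad$primary_direction[2] <- NA
  expect_error(validate_deconvolution(bad), "primary hit direction")
})

test_that("deconvolution aggregation mirrors the primary screen's mean-of-replicates", {
  cfg <- sim_config(n_genes = 60L, seed = 21)
  sim <- simulate_screen(cfg)
  cand <- sim$truth$gene[1:8]
  dc <- simulate_deconvolution(cfg, sim$truth, cand)
  norm <- normalize_screen(dc$wells, screen_config())
  hits <- data.frame(gene = cand, hit_call = rep(c("up", "down"), 4))
  recs <- aggregate_deconvolution(norm$wellz, hits)
  expect_equal(nrow(recs), 8L)
  expect_equal(recs$primary_direction, hits$hit_call[match(recs$gene, hits$gene)])
  # spot-check one siRNA against a direct mean over its QC-passing wells
  ok <- norm$wellz[norm$wellz$qc_flag == "ok" & norm$wellz$role == "sample", ]
  g <- recs$gene[1]
  manual <- mean(ok$z[ok$gene == g & ok$sirna == 2])
  expect_equal(recs$sirna_z_2[recs$gene == g], manual)
})

test_that("up-hits have positive mean z on simulated screens (direction coherence)", {
  cfg <- sim_config(n_genes = 800L, seed = 31)
  sim <- simulate_screen(cfg)
  norm <- normalize_screen(sim$wells, screen_config())
  hits <- call_primary_hits(summarize_genes(norm$wellz))
  expect_true(all(hits$mean_z[hits$hit_call == "up"] > 0))
  expect_true(all(hits$mean_z[hits$hit_call == "down"] < 0))
})
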