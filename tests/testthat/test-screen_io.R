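test_that("well tables parse, validate roles and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plate,well,replicate,gene,role,valid_object_count,mean_intensity",
    "R1_P001,A01,1,g001,sample,1200,950.5",
    "R1_P001,A02,1,NS,ns_control,1100,1010",
    "R1_P001,A03,1,g002,sample,900,870.25"
  ), path)
  df <- read_well_table(path)
  expect_equal(nrow(df), 3L)
  expect_equal(sum(df$role == "ns_control"), 1L)
  expect_type(df$mean_intensity, "double")
  expect_equal(df$valid_object_count, c(1200L, 1100L, 900L))

  # round-trip identity on randomized valid tables, both separators
  for (seed in 1:3) {
    tbl <- random_well_table(seed = seed)
    for (sep in c(",", "\t")) {
      out <- withr::local_tempfile(fileext = ".csv")
      write_well_table(tbl, out, sep = sep)
      back <- read_well_table(out)
      expect_equal(back, read_well_table(out))  # reader is deterministic
      ord <- tbl[order(tbl$plate, tbl$well, tbl$replicate), ]
      rownames(ord) <- NULL
      expect_equal(back, ord)
    }
  }
})

test_that("well table reader rejects corrupted fields with row positions", {
  base <- c(
    "plate,well,replicate,gene,role,valid_object_count,mean_intensity",
    "R1_P001,A01,1,g001,sample,1200,950.5",
    "R1_P001,A02,1,g002,sample,1100,1010"
  )
  write_lines <- function(lines) {
    p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(lines, p)
    p
  }
  # negative intensity, row number cited
  bad <- base; bad[3] <- "R1_P001,A02,1,g002,sample,1100,-4"
  expect_error(read_well_table(write_lines(bad)), "mean_intensity.*row\\(s\\) 2")
  # negative count
  bad <- base; bad[2] <- "R1_P001,A01,1,g001,sample,-5,950.5"
  expect_error(read_well_table(write_lines(bad)), "valid_object_count.*row\\(s\\) 1")
  # invalid role
  bad <- base; bad[2] <- "R1_P001,A01,1,g001,treatment,1200,950.5"
  expect_error(read_well_table(write_lines(bad)), "invalid role 'treatment'")
  # non-integer replicate
  bad <- base; bad[3] <- "R1_P001,A02,1.5,g002,sample,1100,1010"
  expect_error(read_well_table(write_lines(bad)), "replicate")
  # missing column named in the message
  bad <- c("plate,well,replicate,gene,role,valid_object_count",
           "R1_P001,A01,1,g001,sample,1200")
  expect_error(read_well_table(write_lines(bad)), "mean_intensity")
})

test_that("expression tables parse with case-folded conditions and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  grid <- expand.grid(gene = c("g1", "g2"), condition = c("control", "nLDL", "statin"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  grid$expression <- round(runif(nrow(grid), 100, 500), 3)
  write_expression_table(grid, path)
  df <- read_expression_table(path)
  expect_equal(nrow(df), 12L)

  # case variant accepted and normalised
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,condition,replicate,expression",
               "g1,Statin,1,200", "g1,CONTROL,1,180"), p2)
  df2 <- read_expression_table(p2)
  expect_equal(df2$condition, c("statin", "control"))

  # zero expression rejected with row number
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,condition,replicate,expression",
               "g1,control,1,0"), p3)
  expect_error(read_expression_table(p3), "expression.*row\\(s\\) 1")

  # unknown condition rejected
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,condition,replicate,expression",
               "g1,vehicle,1,100"), p4)
  expect_error(read_expression_table(p4), "unknown condition 'vehicle'")
})

test_that("flag tables parse, reject duplicates, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  flags <- data.frame(gene = c("g1", "g2", "g3"),
                      lipid_gwas_flag = c(TRUE, FALSE, TRUE))
  write_flag_table(flags, path)
  expect_equal(read_flag_table(path), flags)

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,lipid_gwas_flag", "g1,1", "g1,0"), p2)
  expect_error(read_flag_table(p2), "duplicated gene")
})

test_that("config loading takes defaults, applies overrides, fails on typos", {
  empty <- withr::local_tempfile(fileext = ".cfg")
  writeLines(character(0), empty)
  cfg <- load_config(empty)
  expect_s3_class(cfg, "screen_config")
  expect_identical(cfg$min_valid_objects, 500L)
  expect_identical(cfg$primary_z_threshold, 2.0)
  expect_identical(cfg$deconv_z_threshold, 1.6)
  expect_identical(cfg$de_alpha, 0.05)
  expect_identical(cfg$de_fc_threshold, 1.1)

  over <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "primary_z_threshold: 2.5"), over)
  cfg2 <- load_config(over)
  expect_identical(cfg2$primary_z_threshold, 2.5)
  expect_identical(cfg2$min_valid_objects, 500L)

  typo <- withr::local_tempfile(fileext = ".cfg")
  writeLines("z_thresold: 2.0", typo)
  expect_error(load_config(typo), "unknown config key 'z_thresold'")

  badfc <- withr::local_tempfile(fileext = ".cfg")
  writeLines("de_fc_threshold: 0.9", badfc)
  expect_error(load_config(badfc), "de_fc_threshold")
})
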