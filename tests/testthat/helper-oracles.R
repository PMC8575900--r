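# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid stats::median/mad and the package's own code
# paths: medians are computed from explicit sorting.

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

oracle_mad <- function(x, constant = 1.0) {
  oracle_median(abs(x - oracle_median(x))) * constant
}

oracle_z <- function(x, constant = 1.0) {
  (x - oracle_median(x)) / oracle_mad(x, constant)
}

# two-sided Student-t p-value for df = 2 in closed form:
# P(|T_2| >= t) = 1 - t / sqrt(t^2 + 2)
oracle_p_df2 <- function(t) 1 - abs(t) / sqrt(t^2 + 2)

# Apply the printed screening rules directly to a raw well table: exclude
# wells under the cell-count floor, per-plate sort-based median/MAD robust
# z, call genes with >= k replicates beyond +/- t in the same direction,
# then score direction-aware recovery against ground truth.
oracle_hit_metrics <- function(wells, truth, min_cells = 500, t = 2, k = 2,
                               constant = 1.0) {
  z <- rep(NA_real_, nrow(wells))
  for (p in unique(wells$plate)) {
    i <- which(wells$plate == p & wells$role != "empty" &
                 wells$valid_object_count >= min_cells)
    x <- wells$mean_intensity[i]
    m <- oracle_median(x)
    s <- oracle_mad(x, constant)
    z[i] <- (x - m) / s
  }
  genes <- sort(unique(wells$gene[wells$role == "sample"]))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (g in genes) {
    zz <- z[wells$gene == g & wells$role == "sample"]
    zz <- zz[!is.na(zz)]
    if (length(zz) < 2L) next  # unscorable: outside every denominator
    call <- "none"
    if (sum(zz >= t) >= k && sum(zz <= -t) < k) call <- "up"
    if (sum(zz <= -t) >= k && sum(zz >= t) < k) call <- "down"
    eff <- truth$true_screen_effect[truth$gene == g]
    true_dir <- if (eff > 0) "up" else if (eff < 0) "down" else "none"
    if (call != "none") {
      if (call == true_dir) tp <- tp + 1L else fp <- fp + 1L
    }
    if (true_dir != "none" && call != true_dir) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# --- small constructors for hand-built inputs ---------------------------

make_wells <- function(intensity, count = 1500L, plate = "P1", well = NULL,
                       replicate = 1L, gene = NULL, role = "sample") {
  n <- length(intensity)
  data.frame(
    plate = rep_len(plate, n),
    well = if (is.null(well)) well_ids(384)[seq_len(n)] else well,
    replicate = rep_len(as.integer(replicate), n),
    gene = if (is.null(gene)) sprintf("g%03d", seq_len(n)) else rep_len(gene, n),
    role = rep_len(role, n),
    valid_object_count = rep_len(as.integer(count), n),
    mean_intensity = as.numeric(intensity),
    stringsAsFactors = FALSE
  )
}

# a hand-specified per-gene z table (one well per replicate)
make_wellz <- function(gene, z, qc_flag = "ok", role = "sample") {
  n <- length(z)
  data.frame(
    plate = sprintf("R%d_P001", seq_len(n)),
    well = rep("A01", n),
    replicate = seq_len(n),
    gene = rep_len(gene, n),
    role = rep_len(role, n),
    valid_object_count = 1500L,
    mean_intensity = 1000,
    z = as.numeric(z),
    qc_flag = rep_len(qc_flag, n),
    stringsAsFactors = FALSE
  )
}

random_well_table <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  roles <- sample(c("sample", "ns_control", "pos_control_npc1",
                    "neg_control_ldlr", "cytotox_control_kif11"),
                  n, replace = TRUE, prob = c(.8, .1, .04, .03, .03))
  data.frame(
    plate = sample(c("R1_P001", "R1_P002"), n, replace = TRUE),
    well = sample(well_ids(384), n),
    replicate = sample(1:3, n, replace = TRUE),
    gene = ifelse(roles == "sample", sprintf("g%04d", seq_len(n)), "NS"),
    role = roles,
    valid_object_count = rpois(n, 1200),
    mean_intensity = round(rlnorm(n, log(1000), 0.2), 4),
    stringsAsFactors = FALSE
  )
}
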