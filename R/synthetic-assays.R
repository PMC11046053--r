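# Simulators for the bioprocess readouts: batch-culture time series and
# qPCR quantification-cycle tables.

#' Simulate a batch-culture time series
#'
#' Viable cell density follows logistic growth from the seeding density;
#' the titer increment of each interval is `qp_true` times the trapezoidal
#' viable-cell integral of that interval (units: qp in pg/cell/day, VCD in
#' cells/mL, titer in ug/mL, 1 ug = 1e6 pg), so quantitation on the
#' noiseless series recovers `qp_true` exactly.
#'
#' @param growth_rate Specific growth rate (/day).
#' @param capacity Carrying capacity (cells/mL).
#' @param qp_true True specific productivity (pg/cell/day).
#' @param days Number of days (daily sampling from day 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param seed_density Seeding density (cells/mL).
#' @param noise_sd Additive Gaussian noise SD on titer (ug/mL).
#' @return `data.frame` with `day`, `vcd`, `viability`, `titer` of class
#'   `culture_series`.
#' @export
simulate_culture <- function(growth_rate, capacity = 1e7, qp_true = 20,
                             days = 8L, seed = 1L, seed_density = 0.3e6,
                             noise_sd = 0) {
  if (capacity <= 0 || qp_true < 0 || days < 1 || seed_density <= 0)
    stop("culture parameters must be positive")
  if (growth_rate < 0) stop("growth_rate must be >= 0")
  day <- 0:days
  vcd <- if (growth_rate == 0) rep(seed_density, length(day)) else
    capacity * seed_density /
      (seed_density + (capacity - seed_density) * exp(-growth_rate * day))
  step_ivcd <- (head(vcd, -1) + tail(vcd, -1)) / 2 * diff(day)
  titer <- c(0, cumsum(qp_true * step_ivcd)) * 1e-6
  viability <- pmax(60, pmin(100, 98 - 0.02 * (vcd / capacity) * day^2))
  out <- with_seed(seed, {
    if (noise_sd > 0) titer <- pmax(0, titer + rnorm(length(titer), 0, noise_sd))
    data.frame(day = day, vcd = vcd, viability = viability, titer = titer)
  })
  class(out) <- c("culture_series", "data.frame")
  out
}

#' Simulate a qPCR quantification-cycle table
#'
#' Two samples (`"sample"`, `"control"`) and two genes (`"target"`,
#' `"reference"`). Amplification efficiency is fixed at 100% (one doubling
#' per cycle), so the noiseless target Ct difference between the samples
#' equals minus the log2 copy ratio; the reference gene Ct is equal across
#' samples up to noise.
#'
#' @param copy_target_sample,copy_target_control Target-region copy numbers.
#' @param replicates Technical replicates per (sample, gene).
#' @param noise_sd Ct noise SD (cycles).
#' @param seed Integer seed.
#' @param base_ct Target Ct at one copy; `reference_ct` is the reference-gene
#'   Ct.
#' @param reference_ct Reference-gene Ct (both samples).
#' @return `data.frame` with `sample`, `gene`, `replicate`, `ct` of class
#'   `ct_table`.
#' @export
simulate_qpcr <- function(copy_target_sample, copy_target_control,
                          replicates = 3L, noise_sd = 0, seed = 1L,
                          base_ct = 28, reference_ct = 20) {
  if (copy_target_sample <= 0 || copy_target_control <= 0)
    stop("copy numbers must be positive")
  if (replicates < 1) stop("at least one replicate required")
  grid <- expand.grid(sample = c("sample", "control"),
                      gene = c("target", "reference"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  copies <- ifelse(grid$sample == "sample", copy_target_sample,
                   copy_target_control)
  ct0 <- ifelse(grid$gene == "target", base_ct - log2(copies), reference_ct)
  out <- with_seed(seed, {
    ct <- ct0 + if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    data.frame(grid, ct = ct)
  })
  class(out) <- c("ct_table", "data.frame")
  out
}
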