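# Simulators with the statistical structure the analysis assumes:
# beta-binomial junction counts for splicing, and ramp-and-hold passive
# stress traces with a known titin/collagen partition for mechanics.
# Defaults encode the study conditions (group sizes, printed group means
# and SDs, qualitative PSI shifts); seeds are mandatory.

#' Configuration for the splice-count simulator
#'
#' @param true_psi data.frame with columns `bin_id`, `genotype`, `muscle`,
#'   `psi`: the true inclusion level of each bin in each group. See
#'   [default_titin_psi_profile()].
#' @param junction_coverage Mean junction-informative reads per bin and
#'   sample (Poisson mean, default 1000).
#' @param overdispersion Beta-binomial intra-class correlation rho in
#'   \[0, 1); 0 gives binomial sampling (default 0.01).
#' @param n_per_group Samples per genotype-by-muscle group (default 4).
#' @param seed Integer seed (required; no wall-clock entropy).
#' @return A `splice_sim_config`.
#' @export
splice_sim_config <- function(true_psi, junction_coverage = 1000,
                              overdispersion = 0.01, n_per_group = 4L,
                              seed) {
  stopifnot(is.data.frame(true_psi),
            all(c("bin_id", "genotype", "muscle", "psi") %in% names(true_psi)))
  if (missing(seed)) stop("seed is mandatory in simulator configs")
  if (any(true_psi$psi < 0 | true_psi$psi > 1))
    stop("true PSI values must lie in [0, 1]")
  if (junction_coverage <= 0) stop("coverage must be positive")
  if (overdispersion < 0 || overdispersion >= 1)
    stop("overdispersion must lie in [0, 1)")
  structure(list(true_psi = true_psi,
                 junction_coverage = junction_coverage,
                 overdispersion = overdispersion,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "splice_sim_config")
}

rbetabinom <- function(n, size, prob, rho) {
  out <- integer(n)
  mid <- prob > 0 & prob < 1
  if (rho == 0) {
    out[mid] <- stats::rbinom(sum(mid), size[mid], prob[mid])
  } else {
    a <- prob[mid] * (1 - rho) / rho
    b <- (1 - prob[mid]) * (1 - rho) / rho
    p <- stats::rbeta(sum(mid), a, b)
    out[mid] <- stats::rbinom(sum(mid), size[mid], p)
  }
  out[prob == 1] <- size[prob == 1]
  out[prob == 0] <- 0L
  out
}

#' Simulate junction read counts per counting bin
#'
#' Per bin and sample, the number of junction-informative reads is
#' Poisson(`junction_coverage`); inclusion reads are beta-binomial with
#' mean equal to the group's true PSI and intra-class correlation
#' `overdispersion` (binomial when 0). Position denominators are 1 (the
#' generated classes are junction-balanced). Output is fully reproducible
#' given the config seed.
#'
#' @param config A [splice_sim_config()].
#' @return list with `counts` (bin-count data.frame readable by
#'   [build_psi_table()]), `metadata` (sample_id, genotype, muscle), and
#'   `truth` (the config's `true_psi`).
#' @export
simulate_splice_counts <- function(config) {
  stopifnot(inherits(config, "splice_sim_config"))
  set.seed(config$seed)
  tp <- config$true_psi
  groups <- unique(tp[, c("genotype", "muscle")])
  groups <- groups[order(groups$genotype, groups$muscle), , drop = FALSE]
  counts <- list(); meta <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups$genotype[gi]; mus <- groups$muscle[gi]
    bins <- tp[tp$genotype == g & tp$muscle == mus, , drop = FALSE]
    bins <- bins[order(bins$bin_id), , drop = FALSE]
    for (k in seq_len(config$n_per_group)) {
      sid <- sprintf("%s_%s_%02d", g, mus, k)
      total <- stats::rpois(nrow(bins), config$junction_coverage)
      inc <- rbetabinom(nrow(bins), total, bins$psi, config$overdispersion)
      counts[[length(counts) + 1L]] <- data.frame(
        sample_id = sid, bin_id = bins$bin_id,
        inclusion_reads = inc, exclusion_reads = total - inc,
        inclusion_positions = 1L, exclusion_positions = 1L,
        stringsAsFactors = FALSE)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sid, genotype = g, muscle = mus,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts), metadata = do.call(rbind, meta),
       truth = tp)
}

#' Default titin true-PSI profile
#'
#' A generator input encoding the qualitative splicing pattern of mdm
#' muscle: PEVK exons 124-127, 133-134 and 138-145 shifted down in mdm EDL
#' and soleus (only 138-139 in psoas), Z-repeat exons 12-13 shifted up in
#' mdm fast muscles, and the M-band exon 346 (Mex5) at its reported group
#' PSI levels (wild type: EDL 0.63, psoas 0.58, soleus 0.97; mdm fast
#' muscles about 0.9). These are simulator inputs, not measurements.
#'
#' @return data.frame `bin_id`, `genotype`, `muscle`, `psi` for genotypes
#'   WT/mdm and muscles EDL/psoas/soleus.
#' @export
default_titin_psi_profile <- function() {
  muscles <- c("EDL", "psoas", "soleus")
  pevk_exons <- c(124:127, 133:134, 138:145)
  zr_exons <- c(12, 13)
  rows <- list()
  add <- function(bin, genotype, muscle, psi)
    rows[[length(rows) + 1L]] <<- data.frame(
      bin_id = as.character(bin), genotype = genotype, muscle = muscle,
      psi = psi, stringsAsFactors = FALSE)
  for (mus in muscles) {
    for (ex in pevk_exons) {
      down <- mus %in% c("EDL", "soleus") || ex %in% c(138, 139)
      add(ex, "WT", mus, 0.90)
      add(ex, "mdm", mus, if (down) 0.55 else 0.90)
    }
    for (ex in zr_exons) {
      fast <- mus %in% c("EDL", "psoas")
      add(ex, "WT", mus, 0.30)
      add(ex, "mdm", mus, if (fast) 0.70 else 0.30)
    }
  }
  mex_wt <- c(EDL = 0.63, psoas = 0.58, soleus = 0.97)
  mex_mdm <- c(EDL = 0.88, psoas = 0.93, soleus = 0.97)
  for (mus in muscles) {
    add(346, "WT", mus, mex_wt[[mus]])
    add(346, "mdm", mus, mex_mdm[[mus]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for the fiber-bundle mechanics simulator
#'
#' Defaults reproduce the study conditions for soleus fiber bundles:
#' total steady-state stress Normal(27.0, 0.97) mN/mm^2 for mdm (n = 20)
#' and Normal(13.0, 2.14) for wild type (n = 21), truncated at 0; titin
#' fractions 20.4/27.0 and 10.5/13.0 of the total; trypsin-resistant titin
#' fractions chosen so post-trypsin steady stresses average 16.1 and 8.3.
#'
#' @param mu,sd Named vectors (per genotype) of total-stress mean and SD,
#'   mN/mm^2.
#' @param titin_fraction Named vector: titin-based share of total stress.
#' @param trypsin_resistant Named vector: share of the titin component
#'   surviving trypsin alone.
#' @param n_bundles Named integer vector of bundles per genotype.
#' @param relaxation_tau Stress-relaxation time constant during the hold, s.
#' @param noise_sd Gaussian stress noise on the trace, mN/mm^2.
#' @param hz Sampling rate, Hz.
#' @param ramp_s Ramp duration, s (0.4 um at 0.04 um/s).
#' @param hold_s Hold duration, s.
#' @param peak_factor Peak (end-of-ramp) stress as a multiple of the
#'   steady-state stress.
#' @param diameter_range Uniform range for bundle diameters, um.
#' @param seed Integer seed (required).
#' @return A `mech_sim_config`.
#' @export
mech_sim_config <- function(mu = c(WT = 13.0, mdm = 27.0),
                            sd = c(WT = 2.14, mdm = 0.97),
                            titin_fraction = c(WT = 10.5 / 13.0,
                                               mdm = 20.4 / 27.0),
                            trypsin_resistant = c(WT = (8.3 - 2.6) / 10.5,
                                                  mdm = (16.1 - 6.7) / 20.4),
                            n_bundles = c(WT = 21L, mdm = 20L),
                            relaxation_tau = 5, noise_sd = 0.2, hz = 50,
                            ramp_s = 10, hold_s = 60, peak_factor = 1.4,
                            diameter_range = c(150, 250), seed) {
  if (missing(seed)) stop("seed is mandatory in simulator configs")
  genos <- names(mu)
  stopifnot(!is.null(genos), identical(sort(genos), sort(names(sd))),
            identical(sort(genos), sort(names(titin_fraction))),
            identical(sort(genos), sort(names(n_bundles))))
  if (any(titin_fraction < 0 | titin_fraction > 1) ||
      any(trypsin_resistant < 0 | trypsin_resistant > 1))
    stop("fractions must lie in [0, 1]")
  if (any(sd < 0)) stop("SDs must be non-negative")
  structure(list(mu = mu, sd = sd, titin_fraction = titin_fraction,
                 trypsin_resistant = trypsin_resistant,
                 n_bundles = n_bundles, relaxation_tau = relaxation_tau,
                 noise_sd = noise_sd, hz = hz, ramp_s = ramp_s,
                 hold_s = hold_s, peak_factor = peak_factor,
                 diameter_range = diameter_range, seed = as.integer(seed)),
            class = "mech_sim_config")
}

#' Simulate skinned-fiber ramp-and-hold traces across extraction treatments
#'
#' Per bundle, a total steady-state stress is drawn from the genotype's
#' truncated normal; the collagen component is `total * (1 -
#' titin_fraction)`; the post-trypsin steady stress is collagen plus the
#' trypsin-resistant share of the titin component; the post-trypsin+KCl+KI
#' steady stress is the collagen component alone. Each condition is
#' rendered as a force trace: stress rising during the 10-s ramp (SL 2.6 to
#' 3.0 um at 0.04 um/s) to `peak_factor` times the steady value, then
#' exponential relaxation with time constant `relaxation_tau` toward the
#' steady value over the 60-s hold, plus Gaussian noise. Forces are stress
#' times the bundle's cross-sectional area, with diameters drawn uniformly
#' and recorded.
#'
#' @param config A [mech_sim_config()].
#' @return list with `traces` (long data.frame `bundle_id`,
#'   `treatment_state`, `time_s`, `force_mN`, `sl_um`), `bundles`
#'   (`bundle_id`, `genotype`, `muscle_id`, `diameter_um`), and `truth`
#'   (per-bundle drawn stresses and configured fractions).
#' @export
simulate_fiber_bundles <- function(config) {
  stopifnot(inherits(config, "mech_sim_config"))
  set.seed(config$seed)
  tgrid <- seq(0, config$ramp_s + config$hold_s, by = 1 / config$hz)
  sl <- pmin(2.6 + 0.04 * tgrid, 3.0)
  traces <- list(); bundles <- list(); truth <- list()
  for (g in names(config$mu)) {
    for (k in seq_len(config$n_bundles[[g]])) {
      bid <- sprintf("%s_b%02d", g, k)
      total <- stats::rnorm(1, config$mu[[g]], config$sd[[g]])
      while (total <= 0) total <- stats::rnorm(1, config$mu[[g]], config$sd[[g]])
      f <- config$titin_fraction[[g]]
      collagen <- total * (1 - f)
      titin <- total * f
      steady <- c(control = total,
                  trypsin = collagen + titin * config$trypsin_resistant[[g]],
                  trypsin_kcl_ki = collagen)
      dia <- stats::runif(1, config$diameter_range[1], config$diameter_range[2])
      area <- cross_sectional_area(dia)
      for (state in names(steady)) {
        s <- steady[[state]]
        peak <- s * config$peak_factor
        stress <- ifelse(
          tgrid <= config$ramp_s,
          peak * (tgrid / config$ramp_s)^2,
          s + (peak - s) * exp(-(tgrid - config$ramp_s) / config$relaxation_tau))
        force <- (stress + stats::rnorm(length(tgrid), 0, config$noise_sd)) * area
        traces[[length(traces) + 1L]] <- data.frame(
          bundle_id = bid, treatment_state = state, time_s = tgrid,
          force_mN = force, sl_um = sl, stringsAsFactors = FALSE)
      }
      bundles[[length(bundles) + 1L]] <- data.frame(
        bundle_id = bid, genotype = g, muscle_id = "soleus",
        diameter_um = dia, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        bundle_id = bid, genotype = g, total_true = total,
        titin_fraction = f, collagen_true = collagen,
        trypsin_resistant = config$trypsin_resistant[[g]],
        diameter_um = dia, stringsAsFactors = FALSE)
    }
  }
  list(traces = do.call(rbind, traces),
       bundles = do.call(rbind, bundles),
       truth = do.call(rbind, truth))
}

#' Write simulator outputs to disk
#'
#' `write_splice_sim()` writes `counts.tsv`, `metadata.tsv` and `truth.tsv`;
#' `write_mech_sim()` writes `traces.csv`, `bundles.tsv` and `truth.tsv`.
#' All files round-trip through [read_counts_tsv()], [read_traces_csv()]
#' and [read_bundles_tsv()] / `read.delim`.
#'
#' @param sim Output of [simulate_splice_counts()] or
#'   [simulate_fiber_bundles()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_splice_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_splice_sim
#' @export
write_mech_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$traces, file.path(dir, "traces.csv"),
                   quote = FALSE, row.names = FALSE)
  utils::write.table(sim$bundles, file.path(dir, "bundles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read fiber-bundle traces and bundle tables
#'
#' @param path CSV of traces (`bundle_id`, `treatment_state`, `time_s`,
#'   `force_mN`, `sl_um`) or TSV of bundle records.
#' @return data.frame.
#' @export
read_traces_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bundle_id", "treatment_state", "time_s", "force_mN", "sl_um")
  if (!all(need %in% names(tab)))
    stop("traces CSV must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_traces_csv
#' @export
read_bundles_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("bundle_id", "diameter_um") %in% names(tab)))
    stop("bundles TSV must have columns bundle_id, diameter_um")
  tab
}
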