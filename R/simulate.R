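# Seeded synthetic MRM data with the statistical structure the pipeline
# assumes: matrix-matched calibration series, QC injections, matrix blanks
# with high endogenous NAD+/NADH, 13C ISTD channels, natural-abundance
# crosstalk injection, a five-timepoint biological experiment with planted
# effects, and bioreactor physiology time series. Ground truth is exported
# alongside every table so parameter recovery is testable end to end.

# multiplicative lognormal noise with mean exactly 1 and the given CV
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic MRM generator with defaults that
#' mirror the study design the pipeline targets: a twelve-point duplicate
#' calibration series from 50 to 10,000 nM in pooled matrix, a 0.78-100 nM
#' doubling dilution series for LOD/LOQ, QC levels 250/2500/7500 nM injected
#' in triplicate on three days, matrix blanks whose endogenous NAD+ and NADH
#' exceed the low QC, a 10\% 13C-labelled-extract ISTD spike, and a
#' biological experiment of five timepoints x 2 biological x 5 technical
#' replicates with planted effects (NADP+/NADPH halved from T2 on, NCA and
#' NR tripled, ADPR doubled from T3 on, NAD+/NADH unchanged, NMN baseline
#' below the LOQ).
#'
#' Noise model: areas are positive and heteroscedastic, so all noise is
#' multiplicative lognormal (mean 1). \code{cv_injection} is shared by both
#' channels of a sample and cancels in the isotope-dilution ratio (this is
#' the point of the ISTD); \code{cv_technical} is the residual CV of the
#' response ratio; \code{cv_biological} acts on true pools per biological
#' replicate.
#'
#' @param panel analyte panel (default [nad_panel()]).
#' @param cal_levels calibration levels, nM.
#' @param cal_dups duplicate injections per level.
#' @param low_levels low-range series for LOD/LOQ, nM.
#' @param qc_levels,qc_reps,qc_days QC design.
#' @param n_blanks matrix blanks per batch.
#' @param matrix_endogenous named nM vector of endogenous matrix
#'   concentrations.
#' @param baseline_pools named vector, true intracellular pools at the
#'   aerobic reference, nmol per g CDW.
#' @param effects named list analyte -> length-5 multiplier vector over
#'   timepoints T1..T5.
#' @param response_factor area counts per nM (single value or named).
#' @param istd_nM ISTD concentration in the final extract, nM.
#' @param istd_spike_fraction volume fraction of labelled extract (metadata).
#' @param cv_technical,cv_biological,cv_injection noise CVs.
#' @param crosstalk inject natural-abundance bleed-through (default TRUE,
#'   NAD+ M+1 into the NAAD channel).
#' @param timepoints,n_bio,n_tech biological design.
#' @param cdw_g_L per-timepoint cell dry weight, g/L.
#' @param dilution_factor,extract_volume_L,broth_volume_L sampling metadata.
#' @param mu_aerobic,mu_linear_micro,mu_linear_anaerobic,q_s,q_p,rq,
#'   glucose_0,biomass_0,t_samples physiology regime (see
#'   [simulate_physiology()]).
#' @return list of class \code{"nad_sim_config"}.
#' @export
sim_config <- function(
    panel = nad_panel(),
    cal_levels = round(50 * (10000 / 50)^(seq(0, 11) / 11)),
    cal_dups = 2L,
    low_levels = 0.78 * 2^(0:7),
    qc_levels = c(250, 2500, 7500), qc_reps = 3L, qc_days = 3L,
    n_blanks = 3L,
    matrix_endogenous = c(
      "NAM" = 30, "NCA" = 8, "1-mNAM" = 0, "NR" = 6, "FAD" = 150,
      "NADH" = 400, "ADPR" = 15, "NAD+" = 1200, "NAAD" = 0, "NMN" = 3,
      "NAMN" = 20, "NADPH" = 100, "NADP+" = 150),
    baseline_pools = c(
      "NAM" = 40, "NCA" = 25, "1-mNAM" = 0, "NR" = 20, "FAD" = 200,
      "NADH" = 250, "ADPR" = 40, "NAD+" = 800, "NAAD" = 0, "NMN" = 2,
      "NAMN" = 50, "NADPH" = 120, "NADP+" = 150),
    effects = list(
      "NADP+" = c(1, 0.5, 0.5, 0.5, 0.5),
      "NADPH" = c(1, 0.5, 0.5, 0.5, 0.5),
      "NCA" = c(1, 3, 3, 3, 3),
      "NR" = c(1, 3, 3, 3, 3),
      "ADPR" = c(1, 1, 2, 2, 2)),
    response_factor = 100, istd_nM = 1000, istd_spike_fraction = 0.1,
    cv_technical = 0.05, cv_biological = 0.10, cv_injection = 0.10,
    crosstalk = TRUE,
    timepoints = paste0("T", 1:5), n_bio = 2L, n_tech = 5L,
    cdw_g_L = c(0.8, 1.6, 1.8, 2.0, 2.1),
    dilution_factor = 1, extract_volume_L = 3e-4, broth_volume_L = 1e-3,
    mu_aerobic = 0.61, mu_linear_micro = 0.30, mu_linear_anaerobic = 0.19,
    q_s = 1.9,
    q_p = list(acetate = c(0.01, 0.30, 0.23), formate = c(0.01, 0.29, 0.43),
               lactate = c(0.01, 0.15, 0.47), succinate = c(0.0, 0.0, 0.06),
               ethanol = c(0.0, 0.11, 0.21)),
    rq = c(aerobic = 1.0, micro = 1.13),
    glucose_0 = 20, biomass_0 = 0.04,
    t_samples = c(T1 = 4.9, T2 = 6.8, T3 = 8.0, T4 = 9.0, T5 = 10.0)) {
  an <- names(panel$analytes)
  bad <- setdiff(unique(c(names(matrix_endogenous), names(baseline_pools),
                          names(effects))), an)
  if (length(bad)) stop("config references analyte(s) absent from panel: ",
                        paste(bad, collapse = ", "))
  if (length(response_factor) == 1L && is.null(names(response_factor))) {
    response_factor <- stats::setNames(rep(response_factor, length(an)), an)
  }
  stopifnot(all(matrix_endogenous >= 0), all(baseline_pools >= 0),
            cv_technical >= 0, cv_biological >= 0, cv_injection >= 0)
  structure(as.list(environment()), class = "nad_sim_config")
}

# rows for one sample: 12C channels for all analytes at the given extract
# concentrations (nM), 13C channels for own-ISTD analytes; crosstalk adds
# the source M+k fraction of the source 12C area into the target channel.
.sample_rows <- function(cfg, sample_id, role, conc, level = NA_real_,
                         extra = list()) {
  an <- names(cfg$panel$analytes)
  rf <- cfg$response_factor
  inj <- .lognoise(1, cfg$cv_injection)
  a12 <- rf[an] * conc[an] * inj * .lognoise(length(an), cfg$cv_technical)
  if (isTRUE(cfg$crosstalk)) {
    # default injection scope: the NAD+ M+1 -> NAAD bleed-through
    if (all(c("NAD+", "NAAD") %in% an)) {
      k <- round(cfg$panel$analytes[["NAAD"]]$parent_mz -
                   cfg$panel$analytes[["NAD+"]]$parent_mz)
      frac <- isotope_ratio(cfg$panel$analytes[["NAD+"]]$formula, k)
      a12[["NAAD"]] <- a12[["NAAD"]] + a12[["NAD+"]] * frac
    }
  }
  own <- an[vapply(cfg$panel$analytes, function(a) a$istd == a$name, TRUE)]
  a13 <- rf[own] * cfg$istd_nM * inj
  df <- data.frame(
    sample_id = sample_id,
    channel_id = c(paste0(an, "|12C"), paste0(own, "|13C")),
    area = c(a12, a13),
    rt = vapply(cfg$panel$analytes[c(an, own)], `[[`, 0, "retention_time"),
    role = role, level = level, stringsAsFactors = FALSE
  )
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  rownames(df) <- NULL
  df
}

#' Simulate a calibration/QC batch of MRM peak tables
#'
#' Generates, for one analytical batch: matrix blanks (endogenous signal
#' only), the matrix-matched calibration series (endogenous + nominal), QC
#' injections at three levels over several days (also matrix-matched), and
#' a separate solvent low-range dilution series for LOD/LOQ. Peak areas are
#' response_factor x concentration with shared injection noise (cancelled by
#' the ISTD ratio) and technical response noise; when crosstalk is on, the
#' NAAD channel receives the NAD+ M+1 fraction of the NAD+ area, so a
#' matrix blank shows NAAD signal even at zero true NAAD.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed; identical (config, seed) pairs give identical
#'   output.
#' @return list: \code{peaks} (blanks + standards + QCs, \code{"nad_peaks"}
#'   layout with a \code{day} column on QCs), \code{low_peaks} (solvent
#'   low-range series), \code{truth} (list with true response factors,
#'   endogenous concentrations and QC nominal levels).
#' @export
simulate_peak_tables <- function(config, seed = 1L) {
  cfg <- config
  stopifnot(inherits(cfg, "nad_sim_config"))
  set.seed(seed)
  an <- names(cfg$panel$analytes)
  endo <- stats::setNames(rep(0, length(an)), an)
  endo[names(cfg$matrix_endogenous)] <- cfg$matrix_endogenous
  rows <- list()
  for (b in seq_len(cfg$n_blanks)) {
    rows[[length(rows) + 1L]] <-
      .sample_rows(cfg, sprintf("BLK%02d", b), "blank", endo)
  }
  for (lv in cfg$cal_levels) {
    for (d in seq_len(cfg$cal_dups)) {
      rows[[length(rows) + 1L]] <-
        .sample_rows(cfg, sprintf("STD%05d_%d", lv, d), "standard",
                     endo + lv, level = lv)
    }
  }
  for (day in seq_len(cfg$qc_days)) {
    for (lv in cfg$qc_levels) {
      for (r in seq_len(cfg$qc_reps)) {
        rows[[length(rows) + 1L]] <-
          .sample_rows(cfg, sprintf("QC%04d_d%d_r%d", lv, day, r), "qc",
                       endo + lv, level = lv, extra = list(day = day))
      }
    }
  }
  peaks <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$day)) r$day <- NA_integer_; r
  }))
  low_rows <- list()
  zero <- stats::setNames(rep(0, length(an)), an)
  for (lv in cfg$low_levels) {
    for (d in seq_len(cfg$cal_dups)) {
      low_rows[[length(low_rows) + 1L]] <-
        .sample_rows(cfg, sprintf("LOW%07.2f_%d", lv, d), "standard",
                     zero + lv, level = lv)
    }
  }
  list(peaks = peaks, low_peaks = do.call(rbind, low_rows),
       truth = list(response_factor = cfg$response_factor,
                    endogenous = endo, qc_levels = cfg$qc_levels,
                    istd_nM = cfg$istd_nM))
}

#' Simulate the biological experiment
#'
#' Generates unknown-sample peak tables and metadata for the oxygen-shift
#' design: timepoints T1 (aerobic reference) through T5, biological and
#' technical replicates, with per-timepoint true pools = baseline x planted
#' multiplier x biological noise. Pools (nmol per g CDW) are converted to
#' extract concentrations (nM) through the per-timepoint CDW, sampled broth
#' volume, dilution and extract volume — the exact inverse of
#' [normalize_to_cdw()] — and then to peak areas as in
#' [simulate_peak_tables()].
#'
#' @inheritParams simulate_peak_tables
#' @return list: \code{peaks}, \code{meta} (one row per sample), and
#'   \code{truth} (data.frame of per-sample true extract nM and true pools,
#'   plus the multiplier matrix).
#' @export
simulate_experiment <- function(config, seed = 1L) {
  cfg <- config
  stopifnot(inherits(cfg, "nad_sim_config"))
  set.seed(seed + 1L)
  an <- names(cfg$panel$analytes)
  base <- stats::setNames(rep(0, length(an)), an)
  base[names(cfg$baseline_pools)] <- cfg$baseline_pools
  mult <- matrix(1, length(an), length(cfg$timepoints),
                 dimnames = list(an, cfg$timepoints))
  for (a in names(cfg$effects)) mult[a, ] <- cfg$effects[[a]]
  rows <- list(); meta <- list(); truth <- list()
  for (ti in seq_along(cfg$timepoints)) {
    tp <- cfg$timepoints[ti]
    cdw <- cfg$cdw_g_L[ti]
    for (b in seq_len(cfg$n_bio)) {
      bio_noise <- .lognoise(length(an), cfg$cv_biological)
      pools_bio <- base * mult[, tp] * bio_noise
      for (r in seq_len(cfg$n_tech)) {
        sid <- sprintf("%s_b%d_t%d", tp, b, r)
        extract_nM <- pools_bio * cdw * cfg$broth_volume_L /
          (cfg$dilution_factor * cfg$extract_volume_L)
        rows[[length(rows) + 1L]] <-
          .sample_rows(cfg, sid, "unknown", extract_nM,
                       extra = list(timepoint = tp, bio_rep = b,
                                    tech_rep = r))
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sid, dilution_factor = cfg$dilution_factor,
          extract_volume_L = cfg$extract_volume_L,
          broth_volume_L = cfg$broth_volume_L, cdw_g_L = cdw,
          timepoint = tp, bio_rep = b, tech_rep = r,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, analyte = an, timepoint = tp, bio_rep = b,
          true_pool = unname(pools_bio),
          true_extract_nM = unname(extract_nM),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(peaks = do.call(rbind, rows), meta = do.call(rbind, meta),
       truth = list(samples = do.call(rbind, truth), multipliers = mult,
                    baseline = base))
}

#' Simulate bioreactor physiology
#'
#' Piecewise culture time series on a regular grid: exponential biomass
#' growth at \code{mu_aerobic} until T1, then linear growth (slopes
#' \code{mu_linear_micro}, \code{mu_linear_anaerobic}) through the
#' oxygen-limited and anaerobic phases; glucose consumed at the configured
#' specific uptake rate \code{q_s}; organic acids and ethanol accumulating
#' at phase-specific specific production rates \code{q_p}; off-gas fractions
#' consistent with the configured RQ per aerated phase (zero O2 uptake in
#' the N2-sparged anaerobic phase). Integrals over biomass are evaluated in
#' closed form per phase, so interval kinetics recover the configured rates
#' exactly on noiseless output.
#'
#' @inheritParams simulate_peak_tables
#' @param dt grid step, h (default 0.05).
#' @return data.frame time series (columns time_h, biomass_g_L,
#'   glucose_g_L, one per product, o2_in/o2_out/co2_in/co2_out) with
#'   attribute \code{"truth"} listing the configured rates.
#' @export
simulate_physiology <- function(config, dt = 0.05) {
  cfg <- config
  stopifnot(inherits(cfg, "nad_sim_config"))
  t1 <- cfg$t_samples[["T1"]]; t2 <- cfg$t_samples[["T2"]]
  t_end <- max(cfg$t_samples)
  tt <- seq(0, t_end, by = dt)
  x1 <- cfg$biomass_0 * exp(cfg$mu_aerobic * t1)
  x2 <- x1 + cfg$mu_linear_micro * (t2 - t1)
  biomass <- ifelse(tt <= t1, cfg$biomass_0 * exp(cfg$mu_aerobic * tt),
             ifelse(tt <= t2, x1 + cfg$mu_linear_micro * (tt - t1),
                    x2 + cfg$mu_linear_anaerobic * (tt - t2)))
  # closed-form integral of biomass from 0 to t, piecewise
  int_x <- function(t) {
    i1 <- (cfg$biomass_0 / cfg$mu_aerobic) *
      (exp(cfg$mu_aerobic * pmin(t, t1)) - 1)
    i2 <- ifelse(t > t1, {
      tm <- pmin(t, t2) - t1
      x1 * tm + cfg$mu_linear_micro * tm^2 / 2
    }, 0)
    i3 <- ifelse(t > t2, {
      ta <- t - t2
      x2 * ta + cfg$mu_linear_anaerobic * ta^2 / 2
    }, 0)
    i1 + i2 + i3
  }
  ix <- int_x(tt)
  glucose <- pmax(cfg$glucose_0 - cfg$q_s * ix, 0)
  phase_of <- function(t) ifelse(t <= t1, 1L, ifelse(t <= t2, 2L, 3L))
  ts <- data.frame(time_h = tt, biomass_g_L = biomass, glucose_g_L = glucose)
  ix_t1 <- int_x(t1); ix_t2 <- int_x(t2)
  for (p in names(cfg$q_p)) {
    qp <- cfg$q_p[[p]]
    conc <- qp[1] * pmin(ix, ix_t1) +
      qp[2] * pmax(pmin(ix, ix_t2) - ix_t1, 0) +
      qp[3] * pmax(ix - ix_t2, 0)
    ts[[p]] <- conc
  }
  ph <- phase_of(tt)
  o2_in <- ifelse(ph == 3L, 0, 0.2095)
  co2_in <- ifelse(ph == 3L, 0, 0.0004)
  uptake <- ifelse(ph == 3L, 0, 0.02)
  rq_t <- ifelse(ph == 1L, cfg$rq[["aerobic"]],
                 ifelse(ph == 2L, cfg$rq[["micro"]], 0))
  ts$o2_in <- o2_in; ts$o2_out <- o2_in - uptake
  ts$co2_in <- co2_in; ts$co2_out <- co2_in + rq_t * uptake
  attr(ts, "truth") <- list(
    mu_aerobic = cfg$mu_aerobic, q_s = cfg$q_s, q_p = cfg$q_p, rq = cfg$rq,
    yields = lapply(cfg$q_p, function(q) q / cfg$q_s),
    t_samples = cfg$t_samples)
  ts
}
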