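#' Validate a pipeline configuration
#'
#' Checks a YAML configuration (path or already-parsed list) against the
#' pipeline schema and returns *all* violations at once as a character
#' vector of diagnostics — an empty vector means the configuration is
#' valid. Nothing is executed.
#'
#' The schema has sections `name`, `seed`, `simulate` (with `n_peaks`,
#' `noise_sd`, `grid`, optional `region`, `lineshape` and a list of
#' `arms`, each `label` / `n_replicates` / `model`), optional `ccsd`
#' (`tol_h`, `tol_c`, `scaling_c`, `by_label`), optional `chemometrics`
#' (`n_components`) and optional `comparison` (`reference`,
#' `comparisons` with `query` / `kind`).
#'
#' @param config path to a YAML file, or a list.
#' @return Character vector of diagnostics (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      return(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) return("config must be a YAML mapping")
  diags <- character(0)
  note <- function(msg) diags <<- c(diags, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (is.null(config$name) || !nzchar(config$name[1]))
    note("name: missing or empty")
  if (is.null(config$seed) || !num1(config$seed))
    note("seed: required integer (no wall-clock seeding)")
  sim <- config$simulate
  if (is.null(sim)) {
    note("simulate: section missing")
  } else {
    if (!is.null(sim$n_peaks) && (!num1(sim$n_peaks) || sim$n_peaks < 1))
      note("simulate.n_peaks: must be a positive integer")
    if (!is.null(sim$noise_sd) && (!num1(sim$noise_sd) || sim$noise_sd < 0))
      note("simulate.noise_sd: must be >= 0")
    if (!is.null(sim$grid) &&
        (!is.numeric(sim$grid) || length(sim$grid) != 2L || any(sim$grid < 2)))
      note("simulate.grid: must be two integers >= 2")
    if (!is.null(sim$region)) {
      r <- sim$region
      for (f in c("bin_h", "bin_c"))
        if (!is.null(r[[f]]) && (!num1(r[[f]]) || r[[f]] <= 0))
          note(paste0("simulate.region.", f, ": bin width must be > 0"))
      if (num1(r$h_min) && num1(r$h_max) && r$h_min >= r$h_max)
        note("simulate.region: h_min must be < h_max")
      if (num1(r$c_min) && num1(r$c_max) && r$c_min >= r$c_max)
        note("simulate.region: c_min must be < c_max")
    }
    if (!is.null(sim$lineshape)) {
      ls <- sim$lineshape
      if (!is.null(ls$shape) &&
          !ls$shape %in% c("gaussian", "lorentzian", "pseudo_voigt"))
        note("simulate.lineshape.shape: must be one of gaussian, lorentzian, pseudo_voigt")
      for (f in c("fwhm_h", "fwhm_c"))
        if (!is.null(ls[[f]]) && (!num1(ls[[f]]) || ls[[f]] <= 0))
          note(paste0("simulate.lineshape.", f, ": must be > 0"))
    }
    if (is.null(sim$arms) || !length(sim$arms)) {
      note("simulate.arms: at least one arm required")
    } else {
      labels <- character(0)
      for (i in seq_along(sim$arms)) {
        a <- sim$arms[[i]]
        where <- sprintf("simulate.arms[%d]", i)
        if (is.null(a$label) || !nzchar(a$label))
          note(paste0(where, ".label: missing"))
        else labels <- c(labels, a$label)
        if (!is.null(a$n_replicates) &&
            (!num1(a$n_replicates) || a$n_replicates < 1))
          note(paste0(where, ".n_replicates: must be >= 1"))
        m <- a$model
        if (is.null(m)) { note(paste0(where, ".model: missing")); next }
        if (!is.null(m$p_disappear) &&
            (!num1(m$p_disappear) || m$p_disappear < 0 || m$p_disappear > 1))
          note(paste0(where, ".model.p_disappear: must be in [0, 1]"))
        for (f in c("shift_sd_h", "shift_sd_c", "intensity_jitter_cv"))
          if (!is.null(m[[f]]) && (!num1(m[[f]]) || m[[f]] < 0))
            note(paste0(where, ".model.", f, ": must be >= 0"))
        if (!is.null(m$shift_magnitude_mode) &&
            !m$shift_magnitude_mode %in% c("gaussian",
                                           "fixed_magnitude_random_sign"))
          note(paste0(where, ".model.shift_magnitude_mode: must be one of ",
                      "gaussian, fixed_magnitude_random_sign"))
      }
      if (anyDuplicated(labels))
        note("simulate.arms: arm labels must be unique")
    }
  }
  cc <- config$ccsd
  if (!is.null(cc)) {
    for (f in c("tol_h", "tol_c", "scaling_c"))
      if (!is.null(cc[[f]]) && (!num1(cc[[f]]) || cc[[f]] <= 0))
        note(paste0("ccsd.", f, ": must be > 0"))
  }
  ch <- config$chemometrics
  if (!is.null(ch) && !is.null(ch$n_components) &&
      (!num1(ch$n_components) || ch$n_components < 1))
    note("chemometrics.n_components: must be >= 1")
  cp <- config$comparison
  if (!is.null(cp) && !is.null(cp$comparisons)) {
    kinds <- c("timepoint", "batch", "stress")
    for (i in seq_along(cp$comparisons)) {
      k <- cp$comparisons[[i]]$kind
      if (!is.null(k) && !k %in% kinds)
        note(sprintf("comparison.comparisons[%d].kind: '%s' not one of %s",
                     i, k, paste(kinds, collapse = ", ")))
    }
  }
  diags
}

# internal: turn a validated config list into a scenario object
config_to_scenario <- function(config) {
  sim <- config$simulate
  region <- if (is.null(sim$region)) spectral_region() else
    do.call(spectral_region, sim$region)
  lineshape <- if (is.null(sim$lineshape)) lineshape_params() else
    do.call(lineshape_params, sim$lineshape)
  arms <- lapply(sim$arms, function(a) {
    m <- a$model
    model <- perturbation_model(
      shift_sd_h = if (is.null(m$shift_sd_h)) 0 else m$shift_sd_h,
      shift_sd_c = if (is.null(m$shift_sd_c)) 0 else m$shift_sd_c,
      shift_magnitude_mode = if (is.null(m$shift_magnitude_mode))
        "gaussian" else m$shift_magnitude_mode,
      p_disappear = if (is.null(m$p_disappear)) 0 else m$p_disappear,
      intensity_jitter_cv = if (is.null(m$intensity_jitter_cv)) 0
        else m$intensity_jitter_cv)
    scenario_arm(a$label, model,
                 if (is.null(a$n_replicates)) 1L else a$n_replicates)
  })
  rep_model <- if (is.null(sim$replicate_model))
    perturbation_model(shift_sd_h = 5e-4, shift_sd_c = 2e-3,
                       intensity_jitter_cv = 0.02)
  else do.call(perturbation_model, sim$replicate_model)
  scenario(name = config$name, arms = arms,
           replicate_model = rep_model,
           reference_batch = if (is.null(sim$reference_batch)) "reference"
             else sim$reference_batch,
           region = region, lineshape = lineshape,
           noise_sd = if (is.null(sim$noise_sd)) 0.01 else sim$noise_sd,
           grid = if (is.null(sim$grid)) c(512L, 256L) else sim$grid,
           n_peaks = if (is.null(sim$n_peaks)) 110L else sim$n_peaks,
           seed = config$seed)
}

#' Run the full comparability pipeline
#'
#' Executes simulate -> match/CCSD -> bin/normalize -> PCA/distances ->
#' reports from a single YAML configuration, writing all numeric tables
#' and a run log to `out_dir`. The run is a pure function of
#' (configuration, seed): repeated runs produce identical outputs.
#'
#' Written tables: `ccsd_profiles.tsv` (per comparison and spin system:
#' CCSD in ppb, disappeared flag), `ccsd_summary.tsv` (average CCSD with
#' confidence halfwidth per comparison), `ccsd_matrix.tsv` (pairwise
#' average-CCSD, Table-1-style), `pca_scores.tsv`,
#' `explained_variance.tsv`, `distances.tsv` (full matrix),
#' `distances_to_reference.tsv`, `disappeared.tsv` and `run_log.txt`.
#'
#' @param config path to a YAML configuration, or a list.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the configuration's seed.
#' @return Invisibly, a list with the in-memory results: `bundle`,
#'   `profiles`, `ccsd_matrix`, `pca`, `distances`, `disappeared`,
#'   `reference_id`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config_path <- if (is.character(config)) config else "<inline>"
  if (is.character(config)) config <- yaml::read_yaml(config)
  diags <- validate_config(config)
  if (length(diags))
    stop("run_pipeline: invalid configuration:\n  ",
         paste(diags, collapse = "\n  "))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("hosnmr run: %s", config$name),
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("hosnmr"))),
                 sprintf("config: %s", config_path),
                 sprintf("seed: %d", config$seed))
  stage <- "simulate"
  result <- tryCatch({
    sc <- config_to_scenario(config)
    bundle <- simulate_study(sc, out_dir = file.path(out_dir, "simulated"))
    log_lines <- c(log_lines,
                   sprintf("simulate: %d peaks, %d arm(s), %d spectra",
                           sc$n_peaks, length(sc$arms),
                           length(bundle$peaklists)))

    stage <- "ccsd"
    cc <- config$ccsd
    tol_h <- if (is.null(cc$tol_h)) 0.02 else cc$tol_h
    tol_c <- if (is.null(cc$tol_c)) 0.2 else cc$tol_c
    scal <- if (is.null(cc$scaling_c)) 0.251 else cc$scaling_c
    by_label <- if (is.null(cc$by_label)) TRUE else isTRUE(cc$by_label)
    ref <- bundle$reference
    profiles <- lapply(bundle$peaklists, function(pl) {
      ccsd_profile(match_peaks(ref, pl, tol_h, tol_c, by_label = by_label,
                               scaling_c = scal), scaling_c = scal)
    })
    prof_rows <- do.call(rbind, lapply(names(profiles), function(id) {
      p <- profiles[[id]]
      rbind(
        data.frame(comparison = id, label = names(p$per_peak),
                   ccsd_ppb = unname(p$per_peak), disappeared = FALSE,
                   stringsAsFactors = FALSE),
        if (length(p$disappeared))
          data.frame(comparison = id, label = p$disappeared,
                     ccsd_ppb = NA_real_, disappeared = TRUE,
                     stringsAsFactors = FALSE))
    }))
    write_tsv <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    write_tsv(prof_rows, "ccsd_profiles.tsv")
    write_tsv(data.frame(
      comparison = names(profiles),
      average_ccsd_ppb = vapply(profiles, `[[`, numeric(1), "average_ccsd"),
      ci_halfwidth_ppb = vapply(profiles, `[[`, numeric(1), "ci_halfwidth"),
      n_values = vapply(profiles, `[[`, integer(1), "n_values"),
      n_disappeared = vapply(profiles, function(p) length(p$disappeared),
                             integer(1)),
      stringsAsFactors = FALSE), "ccsd_summary.tsv")

    all_lists <- c(stats::setNames(list(ref), sc$reference_batch),
                   bundle$peaklists)
    cm <- ccsd_matrix(all_lists, tol_h, tol_c, scal, by_label = by_label)
    mdf <- data.frame(id = cm$ids, round(cm$values, 6), check.names = FALSE,
                      stringsAsFactors = FALSE)
    write_tsv(mdf, "ccsd_matrix.tsv")
    log_lines <- c(log_lines,
                   sprintf("ccsd: tol_h=%g tol_c=%g scaling_c=%g by_label=%s",
                           tol_h, tol_c, scal, by_label))

    stage <- "chemometrics"
    binned <- lapply(bundle$spectra, function(s)
      normalize_total_area(bin_spectrum(s, sc$region)))
    ncomp <- if (is.null(config$chemometrics$n_components)) 2L
      else config$chemometrics$n_components
    pca <- spectra_pca(binned, n_components = ncomp)
    write_tsv(data.frame(id = pca$ids, pca$scores, check.names = FALSE,
                         stringsAsFactors = FALSE), "pca_scores.tsv")
    write_tsv(data.frame(component = colnames(pca$scores),
                         explained_variance_ratio =
                           pca$explained_variance_ratio,
                         stringsAsFactors = FALSE),
              "explained_variance.tsv")
    dm <- distance_matrix(binned)
    write_tsv(data.frame(id = dm$ids, dm$values, check.names = FALSE,
                         stringsAsFactors = FALSE), "distances.tsv")
    ref_spec_id <- if (!is.null(config$comparison$reference))
      config$comparison$reference else dm$ids[1L]
    if (ref_spec_id %in% dm$ids)
      write_tsv(distances_to_reference(dm, ref_spec_id),
                "distances_to_reference.tsv")
    rep_dis <- disappeared_report(profiles)
    write_tsv(rep_dis$by_label, "disappeared.tsv")
    log_lines <- c(log_lines,
                   sprintf("chemometrics: %d bins, %d components",
                           length(binned[[1]]$values),
                           ncol(pca$scores)),
                   "status: ok")
    list(bundle = bundle, profiles = profiles, ccsd_matrix = cm,
         pca = pca, distances = dm, disappeared = rep_dis,
         reference_id = sc$reference_batch)
  }, error = function(e) {
    log_lines <- c(log_lines, sprintf("status: FAILED at stage '%s': %s",
                                      stage, conditionMessage(e)))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    stop("run_pipeline: stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}
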