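# Tabular readers/writers, run configuration and the end-to-end pipeline.
# Conventions: times in hours, shifts in ppm, concentrations in uM; CSV with
# '.' decimal, UTF-8, LF endings; floats written with 6 significant digits;
# 0-based indices in provenance fields, 1-based residue numbering.

.fmt <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write a ThT set as plate + annotation tables
#'
#' Plate CSV: column 1 = time (h), remaining columns = wells. Annotation
#' CSV: well, ratio, replicate, seed_mode.
#'
#' @param set a \code{tht_set}.
#' @param path plate-table CSV path.
#' @param annotation_path annotation CSV path.
#' @export
write_plate_table <- function(set, path, annotation_path) {
  stopifnot(inherits(set, "tht_set"))
  tab <- data.frame(time = .fmt(set$t), .fmt(as.data.frame(set$Y)),
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(set$anno, annotation_path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a ThT plate table with its well annotation
#'
#' The annotation must cover every well column of the plate table; curves
#' are ordered by the annotation. Non-numeric cells and non-increasing time
#' are rejected with their location.
#'
#' @param path plate-table CSV (time + one column per well).
#' @param annotation_path annotation CSV (well, ratio, replicate, and
#'   optionally seed_mode).
#' @return a \code{tht_set}.
#' @export
read_plate_table <- function(path, annotation_path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  anno <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 2L, all(c("well", "ratio", "replicate") %in%
                                   names(anno)))
  wells <- names(tab)[-1L]
  missing_anno <- setdiff(wells, anno$well)
  if (length(missing_anno))
    stop("annotation missing for well(s): ",
         paste(missing_anno, collapse = ", "))
  anno <- anno[anno$well %in% wells, , drop = FALSE]
  num <- suppressWarnings(
    vapply(tab, function(col) as.numeric(col), numeric(nrow(tab))))
  bad <- which(is.na(num) & !(is.na(tab) | tab == "NA"), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell in ", basename(path), " at data row ",
         bad[1, 1], ", column '", names(tab)[bad[1, 2]], "'")
  t <- num[, 1L]
  if (any(diff(t) <= 0))
    stop("time column not strictly increasing at data row ",
         which(diff(t) <= 0)[1] + 1L)
  Y <- num[, anno$well, drop = FALSE]
  if (!"seed_mode" %in% names(anno)) anno$seed_mode <- "none"
  structure(list(t = t, Y = Y,
                 anno = anno[, c("well", "ratio", "replicate", "seed_mode")]),
            class = "tht_set")
}

#' Write a peak list
#'
#' @param peaks peak-list data.frame (\code{residue}, optional \code{chain},
#'   \code{shift_H}, \code{shift_X}, \code{intensity}, optional
#'   \code{linewidth}).
#' @param path output CSV path.
#' @export
write_peak_list <- function(peaks, path) {
  stopifnot(all(c("residue", "shift_H", "shift_X", "intensity") %in%
                  names(peaks)))
  out <- as.data.frame(lapply(peaks, .fmt))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak list
#'
#' Tabular peak list with a header (\code{residue}, optional \code{chain},
#' \code{shift_H}, \code{shift_X}, \code{intensity}, optional
#' \code{linewidth}); lines starting with \code{#} are skipped. Duplicate
#' residue ids (within a chain) are an error.
#'
#' @param path CSV path.
#' @return peak-list data.frame.
#' @export
read_peak_list <- function(path) {
  peaks <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("residue", "shift_H", "shift_X", "intensity")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak list missing column(s): ", paste(miss, collapse = ", "))
  key <- if ("chain" %in% names(peaks))
    paste(peaks$chain, peaks$residue) else peaks$residue
  if (anyDuplicated(key))
    stop("duplicate residue id in peak list: ", key[duplicated(key)][1])
  if (any(peaks$intensity < 0)) stop("negative intensity in peak list")
  peaks
}

#' Default run configuration
#'
#' All stage parameters with their standard defaults: smoothing window 11,
#' derivative depth 4, segmentation threshold 5\%, CSP weighting 0.14,
#' broadening threshold 0.26, PRE loss threshold 0.5, strict-majority
#' fraction 0.5, bootstrap n 1000, the 1:5000..1:1 ten-ratio dose design
#' plus control, and the simulator defaults. Serializes losslessly to YAML.
#'
#' @param ... overrides of any default field (nested lists merged at the
#'   top level of each component).
#' @return object of class \code{run_config} (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    run_id = "demo",
    out_dir = "amykin_run",
    rng_seed = 1L,
    window = 11L, deriv_depth = 4L, threshold_frac = 0.05,
    align_replicates = TRUE, normalize = "raw",
    csp_alpha = 0.14, broadening_threshold = 0.26,
    pre_loss_threshold = 0.5, majority_frac = 0.5,
    n_boot = 1000L,
    dose = list(n_ratios = 10L, ratio_min = 1 / 5000, ratio_max = 1,
                include_control = TRUE),
    simulator = list(m_tot = 5, kn = 1e-8, nc = 2L, kplus = 30, k2 = 3e-4,
                     n2 = 2L, Kend = 0.1, Ksurf = 0.05, K_plat = 1,
                     noise_sd = 2, lag_jitter_sd = 0.3,
                     t_max = 50, dt = 0.1, n_replicates = 3L),
    titration = list(KD = 61, koff = 6000, L0 = 29,
                     ratios = c(0, 0.4, 0.75, 1.25, 2, 3, 5, 8)),
    bli = list(KD = 11, Rmax = 1,
               concs = c(0.5, 1.5, 5, 15, 50, 150), noise_sd = 0.01))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by \code{\link{write_config}} (or
#'   hand-edited); missing fields take their defaults.
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# tiny FNV-1a content hash for provenance stamping of outputs
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(yaml::as.yaml(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full demonstration pipeline
#'
#' Simulation to results in one call: (1) generate a ThT dose-series assay
#' and extract the kinetic-parameter table; (2) simulate the fast-exchange
#' titration, compute CSP profiles and fit K_D with bootstrap errors;
#' (3) simulate PRE profiles, classify interface residues and build the
#' receptor and ligand restraint sets; (4) simulate and fit the BLI
#' steady-state isotherm. Writes CSV/JSON tables and restraint files into
#' \code{config$out_dir}, each stamped with the config hash; deterministic
#' under a fixed \code{rng_seed}.
#'
#' @param config a \code{run_config}.
#' @param quiet suppress progress messages (default FALSE).
#' @return (invisibly) a list with the in-memory results: \code{kinetics},
#'   \code{csp_profiles}, \code{kd_fit}, \code{pre}, \code{restraints},
#'   \code{bli_fit}, \code{paths}.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[amykin] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  pth <- function(f) file.path(config$out_dir, f)

  # 1. ThT kinetics -------------------------------------------------------
  say("simulating ThT assay")
  sim <- config$simulator
  model <- aggregation_model(m_tot = sim$m_tot, kn = sim$kn, nc = sim$nc,
                             kplus = sim$kplus, k2 = sim$k2, n2 = sim$n2,
                             Kend = sim$Kend, Ksurf = sim$Ksurf,
                             K_plat = sim$K_plat)
  design <- assay_design(n_ratios = config$dose$n_ratios,
                         ratio_min = config$dose$ratio_min,
                         ratio_max = config$dose$ratio_max,
                         include_control = config$dose$include_control,
                         n_replicates = sim$n_replicates,
                         t_grid = seq(0, sim$t_max, by = sim$dt),
                         noise_sd = sim$noise_sd,
                         lag_jitter_sd = sim$lag_jitter_sd,
                         rng_seed = config$rng_seed)
  set <- generate_tht_assay(model, design)
  write_plate_table(set, pth("plate.csv"), pth("wells.csv"))
  say("extracting kinetic parameters")
  kin <- extract_kinetics(set, align = config$align_replicates,
                          normalize = config$normalize,
                          window = config$window,
                          deriv_depth = config$deriv_depth,
                          threshold_frac = config$threshold_frac)
  kin_out <- kin
  kin_out[] <- lapply(kin_out, .fmt)
  utils::write.csv(cbind(kin_out, config_hash = hash), pth("kinetics.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config_hash = hash, parameters = kin_out),
                       pth("kinetics.json"), auto_unbox = TRUE, digits = NA)

  # 2. Titration CSP + K_D fit -------------------------------------------
  say("simulating NMR titration and fitting K_D")
  tit_cfg <- config$titration
  ex <- exchange_model(KD = tit_cfg$KD, koff = tit_cfg$koff,
                       L0 = tit_cfg$L0)
  series <- simulate_titration(ex, tit_cfg$ratios)
  apo <- series$peaks[[1]]
  profiles <- lapply(series$peaks[-1], function(pk)
    suppressMessages(compute_csp(apo, pk, alpha = config$csp_alpha)))
  kd_fit <- fit_kd_titration(series, n_boot = config$n_boot,
                             rng_seed = config$rng_seed)

  # 3. PRE + restraints ---------------------------------------------------
  say("simulating PRE profiles and selecting restraints")
  truth <- pre_ground_truth(
    active_residues = list(
      alpha = c(8, 9, 12, 20, 22, 24, 26, 29, 31, 37, 41, 65, 118, 125,
                129, 132, 135, 146),
      beta = c(4, 12, 15, 17, 22, 24, 26, 34, 46, 58, 81),
      betap = c(4, 12, 15, 17, 22, 24, 26, 34, 58, 61, 81, 107)))
  residues <- list(alpha = 1:150, beta = 1:120, betap = 1:120)
  pre <- simulate_pre_profile(truth, residues, rng_seed = config$rng_seed)
  pre_prof <- classify_pre(pre$dia, pre$para,
                           loss_threshold = config$pre_loss_threshold)
  receptor <- select_receptor_actives(pre_prof,
                                      loss_threshold = config$pre_loss_threshold)
  ligand <- select_ligand_actives(profiles,
                                  majority_frac = config$majority_frac)
  export_restraints(receptor, pth("receptor_restraints.txt"), "plain")
  export_restraints(ligand, pth("ligand_restraints.txt"), "plain")
  combined <- restraint_set(c(ligand$chains, receptor$chains))
  export_restraints(combined, pth("restraints_air.tbl"), "air")

  # 4. BLI ---------------------------------------------------------------
  say("simulating and fitting BLI steady state")
  bli_cfg <- config$bli
  bli_tab <- simulate_bli(bli_cfg$KD, bli_cfg$Rmax, bli_cfg$concs,
                          noise_sd = bli_cfg$noise_sd,
                          rng_seed = config$rng_seed)
  bli_fit <- fit_bli_steady_state(bli_tab$conc, bli_tab$response,
                                  n_boot = config$n_boot,
                                  rng_seed = config$rng_seed)

  results <- list(
    config_hash = hash, run_id = config$run_id,
    kd_titration = list(KD = kd_fit$KD, KD_err = kd_fit$KD_err),
    kd_bli = list(KD = bli_fit$KD, KD_err = bli_fit$KD_err,
                  Rmax = bli_fit$Rmax),
    ligand_actives = ligand$chains,
    receptor_actives = receptor$chains)
  jsonlite::write_json(results, pth("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", config$out_dir)
  invisible(list(kinetics = kin, csp_profiles = profiles, kd_fit = kd_fit,
                 pre = pre_prof,
                 restraints = list(ligand = ligand, receptor = receptor),
                 bli_fit = bli_fit,
                 paths = vapply(c("plate.csv", "wells.csv", "kinetics.csv",
                                  "kinetics.json", "receptor_restraints.txt",
                                  "ligand_restraints.txt",
                                  "restraints_air.tbl", "results.json"),
                                pth, "")))
}
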