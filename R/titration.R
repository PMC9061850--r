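# Synthetic NMR and BLI observables for a 1:1 fast-exchange chaperone-peptide
# interaction: titration peak lists, PRE intensity-loss profiles, Langmuir
# steady-state responses.

#' Two-state fast-exchange binding model
#'
#' 1:1 binding of a ligand peptide (concentration \code{L0}) to a chaperone
#' complex treated as one binding unit (\code{P0}), with dissociation
#' constant \code{KD} and off-rate \code{koff}. Per-residue chemical shifts
#' and transverse relaxation rates of the free and bound states define the
#' fast-exchange observables.
#'
#' @param KD dissociation constant (uM, > 0).
#' @param koff off-rate (s^-1, > 0).
#' @param P0 chaperone concentration (uM).
#' @param L0 ligand concentration (uM).
#' @param shifts data.frame with columns \code{residue}, \code{H_free},
#'   \code{X_free}, \code{H_bound}, \code{X_bound} (ppm; X is the 15N or 13C
#'   dimension). Defaults to \code{\link{default_iapp_shifts}()}.
#' @param R2_free,R2_bound transverse relaxation rates (s^-1).
#' @param spectrometer_freq 1H frequency (MHz, default 850).
#' @return an object of class \code{exchange_model}.
#' @export
exchange_model <- function(KD = 61, koff = 6000, P0 = 29, L0 = 29,
                           shifts = default_iapp_shifts(),
                           R2_free = 15, R2_bound = 600,
                           spectrometer_freq = 850) {
  stopifnot(KD > 0, koff > 0, P0 >= 0, L0 > 0, R2_free > 0, R2_bound > 0,
            spectrometer_freq > 0)
  need <- c("residue", "H_free", "X_free", "H_bound", "X_bound")
  if (!all(need %in% names(shifts)))
    stop("shifts must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(shifts$residue)) stop("duplicate residue ids in shifts")
  structure(list(KD = KD, koff = koff, P0 = P0, L0 = L0, shifts = shifts,
                 R2_free = R2_free, R2_bound = R2_bound,
                 spectrometer_freq = spectrometer_freq),
            class = "exchange_model")
}

#' Default per-residue shift table emulating an IAPP titration
#'
#' 37 residues with reproducible pseudo-random free-state amide shifts in the
#' disordered region of the 1H/15N map. Bound-state shift changes are large
#' (0.25 ppm composite) for the two binding segments plus residue 6 — the
#' residue set {6, 10-13, 17-19, 24, 26-28} — and small (0.02 ppm) elsewhere,
#' so that the above-average-CSP rule recovers exactly that set.
#'
#' @param active_residues residues given large bound-state shift changes.
#' @param delta_active,delta_inactive composite bound-state shift change
#'   (ppm) split between the 1H and scaled 15N dimensions.
#' @return data.frame of per-residue free/bound shifts (ppm).
#' @export
default_iapp_shifts <- function(active_residues = c(6, 10:13, 17:19, 24, 26:28),
                                delta_active = 0.25, delta_inactive = 0.02) {
  n <- 37L
  res <- seq_len(n)
  # fixed spread of free shifts; deterministic, no RNG involvement
  H_free <- 8.2 + 0.3 * sin(res * 2.399)
  X_free <- 118 + 6 * sin(res * 1.117 + 0.5)
  act <- res %in% active_residues
  dd <- ifelse(act, delta_active, delta_inactive)
  # split the composite CSP sqrt(0.14 dX^2 + dH^2) equally between terms
  dH <- dd / sqrt(2)
  dX <- dd / sqrt(2) / sqrt(0.14)
  sgn <- ifelse(res %% 2 == 0, 1, -1)
  data.frame(residue = res, H_free = H_free, X_free = X_free,
             H_bound = H_free + sgn * dH, X_bound = X_free + sgn * dX)
}

#' Bound fraction from the 1:1 quadratic isotherm
#'
#' Exact closed form for the concentration of complex at equilibrium,
#' \deqn{[PL] = \frac{(P_0 + L_0 + K_D) - \sqrt{(P_0 + L_0 + K_D)^2 -
#'   4 P_0 L_0}}{2},}
#' returned as the fraction of ligand bound, \eqn{p_b = [PL]/L_0 \in [0,1]}.
#'
#' @param KD dissociation constant (uM).
#' @param P0,L0 total protein and ligand concentrations (uM).
#' @return bound fraction(s) in [0, 1].
#' @export
bound_fraction <- function(KD, P0, L0) {
  stopifnot(KD > 0, all(P0 >= 0), all(L0 > 0))
  s <- P0 + L0 + KD
  bound <- (s - sqrt(s^2 - 4 * P0 * L0)) / 2
  pmin(pmax(bound / L0, 0), 1)
}

#' Simulate a fast-exchange NMR titration
#'
#' For each chaperone:ligand molar ratio, produces a peak list in which every
#' residue resonates at the population-weighted average of its free and
#' bound positions (fast exchange), the linewidth interpolates the free and
#' bound relaxation rates the same way, and the intensity decreases with the
#' bound fraction as \eqn{I = I_0 R_{2,free}/R_{2,obs}}.
#'
#' @param model an \code{exchange_model}; \code{L0} is held fixed and the
#'   chaperone concentration set to \code{ratio * L0} per point.
#' @param ratios chaperone:ligand molar ratios (>= 0); ratio 0 gives the apo
#'   peak list.
#' @param I0 reference intensity of a free peak (default 100).
#' @param noise_sd additive peak-position noise (ppm) applied to the 1H
#'   dimension and, scaled by \eqn{1/\sqrt{0.14}}, to the X dimension
#'   (default 0: noiseless).
#' @param rng_seed seed for the position noise.
#' @return a \code{titration_series}: list with \code{points} (data.frame:
#'   ratio, P0, L0, p_b) and \code{peaks} (list of peak-list data.frames with
#'   columns residue, shift_H, shift_X, intensity, linewidth).
#' @export
simulate_titration <- function(model, ratios, I0 = 100, noise_sd = 0,
                               rng_seed = 1L) {
  stopifnot(inherits(model, "exchange_model"), noise_sd >= 0)
  if (any(ratios < 0)) stop("ratios must be >= 0")
  sh <- model$shifts
  if (noise_sd > 0) set.seed(rng_seed)
  peaks <- vector("list", length(ratios))
  pb <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    P0 <- ratios[i] * model$L0
    p_b <- if (P0 > 0) bound_fraction(model$KD, P0, model$L0) else 0
    R2 <- model$R2_free + p_b * (model$R2_bound - model$R2_free)
    n <- nrow(sh)
    eH <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    eX <- if (noise_sd > 0)
      stats::rnorm(n, 0, noise_sd / sqrt(0.14)) else 0
    peaks[[i]] <- data.frame(
      residue = sh$residue,
      shift_H = sh$H_free + p_b * (sh$H_bound - sh$H_free) + eH,
      shift_X = sh$X_free + p_b * (sh$X_bound - sh$X_free) + eX,
      intensity = I0 * model$R2_free / R2,
      linewidth = R2 / pi)
    pb[i] <- p_b
  }
  structure(list(points = data.frame(ratio = ratios,
                                     P0 = ratios * model$L0,
                                     L0 = model$L0, p_b = pb),
                 peaks = peaks),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("Fast-exchange titration series:", nrow(x$points), "points, ",
      nrow(x$peaks[[1]]), "residues\n")
  print(x$points)
  invisible(x)
}

#' Ground truth for a PRE interface map
#'
#' Residues in \code{active_residues} lose more than half their signal
#' intensity in the paramagnetic sample; inactive residues lose less, so the
#' 50\%-loss classification rule can recover the interface exactly in the
#' noiseless case.
#'
#' @param active_residues named list, chain label -> integer residue ids.
#' @param loss_active mean fractional intensity loss at interface residues
#'   (> 0.5).
#' @param loss_inactive mean loss elsewhere (< 0.5, >= 0).
#' @param noise_sd multiplicative (lognormal-scale) noise SD on intensity
#'   ratios.
#' @return object of class \code{pre_ground_truth}.
#' @export
pre_ground_truth <- function(active_residues, loss_active = 0.8,
                             loss_inactive = 0.1, noise_sd = 0) {
  stopifnot(is.list(active_residues), length(names(active_residues)) > 0)
  if (!(loss_active > 0.5))
    stop("loss_active must exceed 0.5 (invariant: classification recoverable)")
  if (!(loss_inactive < 0.5 && loss_inactive >= 0))
    stop("loss_inactive must lie in [0, 0.5)")
  for (ch in names(active_residues))
    if (anyDuplicated(active_residues[[ch]]))
      stop("duplicate residue ids in chain ", ch)
  structure(list(active_residues = active_residues,
                 loss_active = loss_active, loss_inactive = loss_inactive,
                 noise_sd = noise_sd),
            class = "pre_ground_truth")
}

#' Simulate paired diamagnetic/paramagnetic intensity tables
#'
#' Diamagnetic (reference) intensities are constant; paramagnetic intensities
#' are attenuated by the ground-truth fractional loss, with optional
#' multiplicative noise. Before noise, I_para/I_dia < 0.5 for every active
#' residue and > 0.5 for every inactive one.
#'
#' @param truth a \code{pre_ground_truth}.
#' @param residues named list, chain label -> residue ids measured on that
#'   chain (must contain the active residues).
#' @param I0 diamagnetic intensity (default 100).
#' @param rng_seed seed for the multiplicative noise.
#' @return list with \code{dia} and \code{para} data.frames (chain, residue,
#'   intensity).
#' @export
simulate_pre_profile <- function(truth, residues, I0 = 100, rng_seed = 1L) {
  stopifnot(inherits(truth, "pre_ground_truth"), is.list(residues))
  rows <- do.call(rbind, lapply(names(residues), function(ch) {
    ids <- residues[[ch]]
    if (anyDuplicated(ids)) stop("duplicate residue ids in chain ", ch)
    data.frame(chain = ch, residue = ids,
               active = ids %in% truth$active_residues[[ch]])
  }))
  loss <- ifelse(rows$active, truth$loss_active, truth$loss_inactive)
  ratio <- 1 - loss
  if (truth$noise_sd > 0) {
    set.seed(rng_seed)
    ratio <- ratio * exp(stats::rnorm(length(ratio), 0, truth$noise_sd))
  }
  list(dia = data.frame(chain = rows$chain, residue = rows$residue,
                        intensity = rep(I0, nrow(rows))),
       para = data.frame(chain = rows$chain, residue = rows$residue,
                         intensity = I0 * ratio))
}

#' Simulate steady-state BLI responses
#'
#' Langmuir 1:1 isotherm \eqn{R_{eq} = [A] R_{max} / ([A] + K_D)} with
#' optional additive Gaussian noise.
#'
#' @param KD dissociation constant (uM).
#' @param Rmax maximum response.
#' @param concs analyte concentrations (uM, > 0).
#' @param noise_sd additive response noise SD.
#' @param rng_seed seed for the noise.
#' @return data.frame with columns \code{conc} (uM) and \code{response}.
#' @export
simulate_bli <- function(KD, Rmax, concs, noise_sd = 0, rng_seed = 1L) {
  stopifnot(KD > 0, Rmax > 0, all(concs > 0))
  r <- concs * Rmax / (concs + KD)
  if (noise_sd > 0) {
    set.seed(rng_seed)
    r <- r + stats::rnorm(length(r), 0, noise_sd)
  }
  data.frame(conc = concs, response = r)
}
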