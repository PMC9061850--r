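# NMR and BLI binding analysis: chemical shift perturbations, peak
# broadening, PRE classification, 1:1 isotherm K_D fitting with bootstrap
# errors, a reduced two-site exchange lineshape model for k_off, and the
# Langmuir steady-state BLI fit.

# match two peak lists on residue (and chain when present); error on
# duplicates, report unmatched ids
.match_peaks <- function(ref, obs, ref_name = "apo", obs_name = "holo") {
  key <- function(df) {
    if ("chain" %in% names(df)) paste(df$chain, df$residue) else
      as.character(df$residue)
  }
  kr <- key(ref); ko <- key(obs)
  if (anyDuplicated(kr)) stop("duplicate residue ids in ", ref_name, " list")
  if (anyDuplicated(ko)) stop("duplicate residue ids in ", obs_name, " list")
  common <- intersect(kr, ko)
  unmatched <- c(setdiff(kr, ko), setdiff(ko, kr))
  if (length(unmatched))
    message("unmatched residues dropped from comparison: ",
            paste(unmatched, collapse = ", "))
  list(ref = ref[match(common, kr), , drop = FALSE],
       obs = obs[match(common, ko), , drop = FALSE],
       unmatched = unmatched)
}

#' Chemical shift perturbations between two peak lists
#'
#' Combined CSP per residue,
#' \eqn{\Delta\delta = \sqrt{\alpha\,\Delta X^2 + \Delta H^2}} with the
#' conventional 15N weighting \eqn{\alpha = 0.14}. The above-average flag
#' compares each residue to the mean CSP over the residues measurable in
#' both lists.
#'
#' @param apo,holo peak-list data.frames (columns \code{residue},
#'   \code{shift_H}, \code{shift_X}; optional \code{chain},
#'   \code{intensity}).
#' @param alpha weighting of the X (15N/13C) dimension, default 0.14.
#' @return data.frame with \code{residue}, \code{csp} (ppm) and
#'   \code{csp_above_avg}; unmatched residues are reported via message and
#'   stored in the \code{unmatched} attribute.
#' @export
compute_csp <- function(apo, holo, alpha = 0.14) {
  m <- .match_peaks(apo, holo)
  dH <- m$obs$shift_H - m$ref$shift_H
  dX <- m$obs$shift_X - m$ref$shift_X
  csp <- sqrt(alpha * dX^2 + dH^2)
  out <- data.frame(residue = m$ref$residue, csp = csp,
                    csp_above_avg = csp >= mean(csp))
  if ("chain" %in% names(m$ref)) out <- cbind(chain = m$ref$chain, out)
  attr(out, "unmatched") <- m$unmatched
  attr(out, "mean_csp") <- mean(csp)
  out
}

#' Peak-broadening intensity ratios
#'
#' Ratio \eqn{I/I_0} of peak intensity with binding partner present to the
#' free reference. Residues at or below the broadening threshold (default
#' 0.26) are flagged.
#'
#' @param apo,holo peak lists with \code{residue} and \code{intensity}.
#' @param threshold broadened when \eqn{I/I_0 \le} threshold (default 0.26).
#' @return data.frame with \code{residue}, \code{intensity_ratio},
#'   \code{broadened}; residues with \eqn{I_0 = 0} get \code{NA} ratios and
#'   are flagged undefined.
#' @export
broadening_ratios <- function(apo, holo, threshold = 0.26) {
  m <- .match_peaks(apo, holo)
  I0 <- m$ref$intensity
  ratio <- ifelse(I0 > 0, m$obs$intensity / I0, NA_real_)
  out <- data.frame(residue = m$ref$residue,
                    intensity_ratio = ratio,
                    broadened = !is.na(ratio) & ratio <= threshold,
                    ratio_undefined = is.na(ratio))
  if ("chain" %in% names(m$ref)) out <- cbind(chain = m$ref$chain, out)
  out
}

#' Classify PRE-broadened interface residues
#'
#' A residue is PRE-active when it loses more than \code{loss_threshold}
#' (default 50\%) of its signal intensity in the paramagnetic sample
#' relative to the diamagnetic reference:
#' \eqn{1 - I_{para}/I_{dia} >} threshold. Chains are kept separate.
#'
#' @param dia,para peak lists with \code{residue}, \code{intensity} and
#'   optional \code{chain}; diamagnetic intensities must be positive.
#' @param loss_threshold fractional intensity-loss cutoff (default 0.5).
#' @return data.frame with \code{chain} (if given), \code{residue},
#'   \code{pre_ratio} (\eqn{I_{para}/I_{dia}}) and \code{pre_active}.
#'   Paramagnetic residues without a diamagnetic partner are excluded with a
#'   warning.
#' @export
classify_pre <- function(dia, para, loss_threshold = 0.5) {
  key <- function(df)
    if ("chain" %in% names(df)) paste(df$chain, df$residue) else
      as.character(df$residue)
  kd <- key(dia); kp <- key(para)
  if (anyDuplicated(kd)) stop("duplicate residue ids in diamagnetic list")
  if (anyDuplicated(kp)) stop("duplicate residue ids in paramagnetic list")
  orphan <- setdiff(kp, kd)
  if (length(orphan))
    warning("residues without diamagnetic partner excluded: ",
            paste(orphan, collapse = ", "))
  common <- intersect(kp, kd)
  d <- dia[match(common, kd), , drop = FALSE]
  p <- para[match(common, kp), , drop = FALSE]
  if (any(d$intensity <= 0)) stop("diamagnetic intensities must be > 0")
  ratio <- p$intensity / d$intensity
  out <- data.frame(residue = d$residue, pre_ratio = ratio,
                    pre_active = (1 - ratio) > loss_threshold)
  if ("chain" %in% names(d)) out <- cbind(chain = d$chain, out)
  out
}

# CSP matrix (residue x titration point) from a titration_series, relative
# to its first point (which must be the apo reference)
.csp_matrix <- function(series, alpha = 0.14) {
  stopifnot(inherits(series, "titration_series"))
  if (series$points$ratio[1] != 0)
    stop("first titration point must be the apo reference (ratio 0)")
  apo <- series$peaks[[1]]
  sapply(series$peaks[-1], function(pk)
    suppressMessages(compute_csp(apo, pk, alpha))$csp)
}

#' Fit a dissociation constant to fast-exchange titration CSPs
#'
#' Global 1:1 fit: for every residue the observed CSP obeys
#' \eqn{\Delta\delta_{obs} = \Delta\delta_{bound}\, p_b(K_D; P_0, L_0)} with
#' the bound fraction from the exact quadratic isotherm
#' (\code{\link{bound_fraction}}). The per-residue bound-state amplitudes
#' are profiled out analytically (linear least squares), leaving a 1-D
#' search over \eqn{\log K_D}. The error is the SD of \eqn{K_D} over
#' residue-resampling bootstrap replicates.
#'
#' @param series a \code{titration_series} whose first point is the apo
#'   reference, or a numeric matrix of CSPs (residues x points).
#' @param P0,L0 total chaperone and ligand concentrations per non-apo point
#'   (uM); taken from the series metadata when omitted.
#' @param min_csp residues whose maximal CSP stays below this floor (ppm)
#'   are excluded from the fit (default 0.02).
#' @param n_boot bootstrap replicates (default 1000).
#' @param rng_seed seed for the bootstrap.
#' @param interval log10 K_D search interval (uM), default \code{c(-3, 5)}.
#' @return an object of class \code{binding_fit} with \code{KD},
#'   \code{KD_err}, per-residue \code{delta_bound}, \code{residuals},
#'   \code{n_boot}, \code{rng_seed}. A fit where the bound fraction never
#'   exceeds 20\% triggers an identifiability warning but is still
#'   returned.
#' @export
fit_kd_titration <- function(series, P0 = NULL, L0 = NULL, min_csp = 0.02,
                             n_boot = 1000L, rng_seed = 1L,
                             interval = c(-3, 5)) {
  if (inherits(series, "titration_series")) {
    C <- .csp_matrix(series)
    if (is.null(P0)) P0 <- series$points$P0[-1]
    if (is.null(L0)) L0 <- series$points$L0[-1]
    res_ids <- series$peaks[[1]]$residue
  } else {
    C <- as.matrix(series)
    if (is.null(P0) || is.null(L0))
      stop("P0 and L0 per titration point are required with a CSP matrix")
    res_ids <- rownames(C)
    if (is.null(res_ids)) res_ids <- seq_len(nrow(C))
  }
  if (ncol(C) < 4L) stop("need at least 4 titration points")
  stopifnot(length(P0) == ncol(C), length(L0) == ncol(C))
  keep <- apply(C, 1L, max) > min_csp
  if (!any(keep)) stop("no residue with CSP above the noise floor ", min_csp)
  C <- C[keep, , drop = FALSE]
  res_ids <- res_ids[keep]

  sse <- function(log10_kd, Cm) {
    pb <- bound_fraction(10^log10_kd, P0, L0)
    a <- drop(Cm %*% pb) / sum(pb^2)
    sum((Cm - outer(a, pb))^2)
  }
  fit_one <- function(Cm)
    10^stats::optimize(sse, interval, Cm = Cm)$minimum
  KD <- fit_one(C)
  pb_hat <- bound_fraction(KD, P0, L0)
  if (max(pb_hat) < 0.2)
    warning("bound fraction never exceeds 20% across the series; ",
            "K_D weakly identifiable")
  delta_bound <- drop(C %*% pb_hat) / sum(pb_hat^2)
  names(delta_bound) <- res_ids
  resid <- C - outer(delta_bound, pb_hat)

  set.seed(rng_seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(nrow(C), replace = TRUE)
    fit_one(C[idx, , drop = FALSE])
  })
  structure(list(method = "titration_csp", KD = KD, KD_err = stats::sd(boots),
                 delta_bound = delta_bound, residuals = resid,
                 bound_fraction = pb_hat, n_boot = as.integer(n_boot),
                 rng_seed = as.integer(rng_seed)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Binding fit (", x$method, ")\n", sep = "")
  cat(sprintf("  K_D   = %.3g +/- %.2g uM (bootstrap SD, n = %d)\n",
              x$KD, x$KD_err, x$n_boot))
  if (!is.null(x$koff))
    cat(sprintf("  k_off = %.3g s^-1\n", x$koff))
  if (!is.null(x$Rmax))
    cat(sprintf("  R_max = %.3g\n", x$Rmax))
  invisible(x)
}

#' Two-site exchange 1D lineshape
#'
#' Absorptive spectrum of a spin exchanging between a free and a bound
#' environment, from the 2x2 frequency-domain exchange (McConnell-type)
#' matrix: site angular frequencies from the ppm shifts and spectrometer
#' frequency, widths \code{R2_free}/\code{R2_bound}, exchange rates
#' \eqn{k_{b\to f} = k_{off}} and \eqn{k_{f\to b} = k_{off} p_b / p_f}. The
#' integrated intensity is independent of \code{koff} (magnetization
#' conservation).
#'
#' @param model an \code{exchange_model}; populations come from its
#'   concentrations via the quadratic isotherm.
#' @param freq_grid frequencies (Hz) at which to evaluate the spectrum.
#' @param residue residue id from the model's shift table (default: first);
#'   the 1H dimension is used.
#' @return data.frame with \code{freq} (Hz) and \code{intensity}.
#' @export
lineshape_two_site <- function(model, freq_grid, residue = NULL) {
  stopifnot(inherits(model, "exchange_model"))
  if (model$R2_free <= 0 || model$R2_bound <= 0)
    stop("linewidths must be positive")
  sh <- model$shifts
  if (is.null(residue)) residue <- sh$residue[1]
  row <- sh[sh$residue == residue, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown residue: ", residue)
  p_b <- bound_fraction(model$KD, model$P0, model$L0)
  y <- .two_site_spectrum(
    freq_grid,
    nu_f = row$H_free * model$spectrometer_freq,
    nu_b = row$H_bound * model$spectrometer_freq,
    R2f = model$R2_free, R2b = model$R2_bound,
    p_b = p_b, koff = model$koff)
  data.frame(freq = freq_grid, intensity = y)
}

# core two-site exchange spectrum; frequencies in Hz, rates in s^-1
.two_site_spectrum <- function(freq, nu_f, nu_b, R2f, R2b, p_b, koff) {
  p_f <- 1 - p_b
  kf <- if (p_f > 0) koff * p_b / p_f else Inf
  kb <- koff
  wf <- 2 * pi * nu_f
  wb <- 2 * pi * nu_b
  w <- 2 * pi * freq
  # S(w) = Re( 1' (iw I - L)^{-1} p ),  L = iW - R - K
  a11 <- 1i * (w - wf) + R2f + kf
  a22 <- 1i * (w - wb) + R2b + kb
  det <- a11 * a22 - kf * kb
  # (iwI - L)^{-1} p summed over rows, closed form for the 2x2 inverse
  s <- ((a22 + kf) * p_f + (a11 + kb) * p_b) / det
  Re(s)
}

#' Simulate a titration series of 1D lineshapes
#'
#' One spectrum per (titration ratio, residue) from the two-site exchange
#' model, with populations per ratio from the quadratic isotherm.
#'
#' @param model an \code{exchange_model} (its \code{koff} is the ground
#'   truth).
#' @param ratios chaperone:ligand molar ratios.
#' @param residues residue ids to simulate (default: first residue).
#' @param freq_grid frequencies (Hz); default spans the free/bound positions
#'   of the selected residues with margin.
#' @return object of class \code{lineshape_series}: list of spectra plus
#'   metadata (ratio, residue, p_b).
#' @export
lineshape_series <- function(model, ratios, residues = NULL,
                             freq_grid = NULL) {
  stopifnot(inherits(model, "exchange_model"))
  sh <- model$shifts
  if (is.null(residues)) residues <- sh$residue[1]
  rows <- sh[match(residues, sh$residue), , drop = FALSE]
  if (anyNA(rows$residue)) stop("unknown residue id(s)")
  if (is.null(freq_grid)) {
    nus <- c(rows$H_free, rows$H_bound) * model$spectrometer_freq
    span <- max(nus) - min(nus) + 20 * model$R2_bound / (2 * pi)
    center <- mean(range(nus))
    freq_grid <- seq(center - span, center + span, length.out = 1024L)
  }
  meta <- expand.grid(residue = residues, ratio = ratios,
                      KEEP.OUT.ATTRS = FALSE)
  meta$p_b <- vapply(meta$ratio, function(r)
    if (r > 0) bound_fraction(model$KD, r * model$L0, model$L0) else 0,
    numeric(1))
  spectra <- lapply(seq_len(nrow(meta)), function(i) {
    row <- rows[rows$residue == meta$residue[i], ]
    .two_site_spectrum(freq_grid,
                       nu_f = row$H_free * model$spectrometer_freq,
                       nu_b = row$H_bound * model$spectrometer_freq,
                       R2f = model$R2_free, R2b = model$R2_bound,
                       p_b = meta$p_b[i], koff = model$koff)
  })
  structure(list(freq = freq_grid, meta = meta, spectra = spectra,
                 model = model),
            class = "lineshape_series")
}

#' Fit a shared off-rate to a lineshape titration series
#'
#' Joint least-squares fit of one \code{koff} across all residues and
#' titration points of a \code{lineshape_series}, holding populations,
#' site positions and widths at the values supplied by the model (the
#' reduced, 1-D analogue of global 2D lineshape fitting).
#'
#' @param series a \code{lineshape_series} (observed spectra).
#' @param model exchange model providing everything except \code{koff};
#'   defaults to the series' generating model.
#' @param interval log10 koff search interval (s^-1), default
#'   \code{c(1, 7)}.
#' @return a \code{binding_fit} with \code{koff} (and the model's KD).
#' @export
fit_koff_lineshape <- function(series, model = series$model,
                               interval = c(1, 7)) {
  stopifnot(inherits(series, "lineshape_series"))
  sh <- model$shifts
  obj <- function(log10_koff) {
    k <- 10^log10_koff
    sum(vapply(seq_len(nrow(series$meta)), function(i) {
      row <- sh[sh$residue == series$meta$residue[i], ]
      pred <- .two_site_spectrum(series$freq,
                                 nu_f = row$H_free * model$spectrometer_freq,
                                 nu_b = row$H_bound * model$spectrometer_freq,
                                 R2f = model$R2_free, R2b = model$R2_bound,
                                 p_b = series$meta$p_b[i], koff = k)
      sum((series$spectra[[i]] - pred)^2)
    }, numeric(1)))
  }
  koff <- 10^stats::optimize(obj, interval)$minimum
  structure(list(method = "lineshape_two_site", KD = model$KD,
                 KD_err = NA_real_, koff = koff,
                 n_boot = 0L, rng_seed = NA_integer_),
            class = "binding_fit")
}

#' Fit the Langmuir steady-state BLI isotherm
#'
#' Nonlinear least squares for \eqn{R_{eq} = [A] R_{max}/([A] + K_D)} with
#' bootstrap errors over concentration points.
#'
#' @param concs analyte concentrations (uM); at least 3 distinct values
#'   spanning a >= 10-fold range.
#' @param responses equilibrium responses, same length.
#' @param n_boot bootstrap replicates (default 1000).
#' @param rng_seed seed for the bootstrap.
#' @return a \code{binding_fit} with \code{KD}, \code{KD_err}, \code{Rmax}.
#' @export
fit_bli_steady_state <- function(concs, responses, n_boot = 1000L,
                                 rng_seed = 1L) {
  stopifnot(length(concs) == length(responses), all(concs > 0))
  if (length(unique(concs)) < 3L)
    stop("need at least 3 distinct analyte concentrations")
  if (max(concs) / min(concs) < 10)
    stop("concentrations must span at least a 10-fold range")
  if (stats::sd(responses) == 0)
    stop("responses have zero variance; K_D unidentifiable")
  fit_one <- function(x, y) {
    Rmax0 <- max(y) * 1.2
    KD0 <- x[which.min(abs(y - Rmax0 / 2))]
    fit <- minpack.lm::nlsLM(y ~ x * Rmax / (x + KD),
                             start = list(Rmax = Rmax0, KD = max(KD0, 1e-6)),
                             lower = c(Rmax = 0, KD = 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)
  }
  est <- fit_one(concs, responses)
  set.seed(rng_seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(length(concs), replace = TRUE)
    out <- tryCatch(fit_one(concs[idx], responses[idx])[["KD"]],
                    error = function(e) NA_real_)
    out
  })
  fitted <- concs * est[["Rmax"]] / (concs + est[["KD"]])
  structure(list(method = "bli_steady_state", KD = est[["KD"]],
                 KD_err = stats::sd(boots, na.rm = TRUE),
                 Rmax = est[["Rmax"]], residuals = responses - fitted,
                 n_boot = as.integer(n_boot),
                 rng_seed = as.integer(rng_seed)),
            class = "binding_fit")
}
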