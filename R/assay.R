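# Synthetic ThT plate assays: dose layout, seeding, replicate noise and lag
# jitter, on top of the moment-equation simulator.

#' Define a ThT assay design
#'
#' Mirrors the layout of a dose-response aggregation assay: one
#' inhibitor-free control plus \code{n_ratios} conditions at logarithmically
#' equidistant inhibitor:monomer molar ratios, each in replicate. Seeded modes
#' add preformed fibrils: \code{"sonicated"} seeds are short (many ends,
#' elongation-dominated kinetics), \code{"non_sonicated"} seeds are long
#' (surface available for secondary nucleation).
#'
#' @param n_ratios number of non-zero inhibitor conditions (default 10).
#' @param ratio_min,ratio_max bounds of the inhibitor:monomer molar ratio
#'   (defaults 1/5000 and 1).
#' @param include_control prepend a ratio-0 control condition (default TRUE).
#' @param n_replicates replicates per condition (default 3).
#' @param seed_mode \code{"none"}, \code{"sonicated"} or
#'   \code{"non_sonicated"}.
#' @param seed_fraction seed mass as a fraction of total monomer (monomer
#'   equivalent), in [0, 0.2]; default 0.085.
#' @param t_grid sampling times (h), strictly increasing, at least 60 points.
#' @param noise_sd additive fluorescence noise SD (FI units).
#' @param lag_jitter_sd per-replicate horizontal time-shift SD (h).
#' @param gain,baseline fluorescence calibration: FI = gain * M + baseline.
#' @param rng_seed integer seed; per-well substreams are derived
#'   deterministically from it.
#' @return an object of class \code{assay_design}.
#' @export
assay_design <- function(n_ratios = 10, ratio_min = 1 / 5000, ratio_max = 1,
                         include_control = TRUE, n_replicates = 3,
                         seed_mode = c("none", "sonicated", "non_sonicated"),
                         seed_fraction = 0.085,
                         t_grid = seq(0, 50, by = 0.1),
                         noise_sd = 2, lag_jitter_sd = 0.3,
                         gain = 100, baseline = 10, rng_seed = 1L) {
  seed_mode <- match.arg(seed_mode)
  stopifnot(n_ratios >= 1, ratio_min > 0, ratio_min < ratio_max,
            ratio_max <= 1, n_replicates >= 1,
            seed_fraction >= 0, seed_fraction <= 0.2,
            noise_sd >= 0, lag_jitter_sd >= 0, gain > 0)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  structure(list(n_ratios = as.integer(n_ratios), ratio_min = ratio_min,
                 ratio_max = ratio_max, include_control = include_control,
                 n_replicates = as.integer(n_replicates),
                 seed_mode = seed_mode, seed_fraction = seed_fraction,
                 t_grid = t_grid, noise_sd = noise_sd,
                 lag_jitter_sd = lag_jitter_sd, gain = gain,
                 baseline = baseline, rng_seed = as.integer(rng_seed)),
            class = "assay_design")
}

# mean seed fibril length (monomers) by preparation; sonication fragments
# fibrils, multiplying ends at constant mass
.seed_length <- c(sonicated = 50, non_sonicated = 1000)

#' Generate a synthetic ThT replicate set
#'
#' One fluorescence curve per (condition, replicate): the moment-equation
#' trajectory at the condition's inhibitor concentration, scaled to
#' fluorescence (\code{gain * M + baseline}), time-shifted by a per-replicate
#' lag jitter (linear re-interpolation onto the design grid, edge values
#' held), plus additive Gaussian noise. Bit-reproducible for a fixed
#' \code{rng_seed}.
#'
#' @param model an \code{aggregation_model}; its \code{c_inh} field is
#'   overridden per condition as \code{ratio * m_tot}.
#' @param design an \code{assay_design}.
#' @return a \code{tht_set}: list with \code{t} (time grid, h), \code{Y}
#'   (fluorescence matrix, one column per well) and \code{anno} (data.frame:
#'   well, ratio, replicate, seed_mode).
#' @export
generate_tht_assay <- function(model, design) {
  stopifnot(inherits(model, "aggregation_model"),
            inherits(design, "assay_design"))
  if (length(design$t_grid) < 60L)
    stop("t_grid must have at least 60 points (smoothing/derivative/plateau ",
         "windows of 11/20/50 points would be degenerate)")
  ratios <- build_dose_series(design$ratio_min, design$ratio_max,
                              design$n_ratios,
                              include_control = design$include_control)
  if (design$seed_mode != "none") {
    M0 <- design$seed_fraction * model$m_tot
    P0 <- M0 / .seed_length[[design$seed_mode]]
  } else {
    M0 <- model$M0
    P0 <- model$P0
  }
  n_cond <- length(ratios)
  n_well <- n_cond * design$n_replicates
  anno <- data.frame(
    well = sprintf("W%02d", seq_len(n_well)),
    ratio = rep(ratios, each = design$n_replicates),
    replicate = rep(seq_len(design$n_replicates), times = n_cond),
    seed_mode = design$seed_mode,
    stringsAsFactors = FALSE)

  # trajectory per condition (deterministic part, shared across replicates)
  traj <- lapply(ratios, function(r) {
    m <- model
    m$c_inh <- r * model$m_tot
    m$M0 <- M0
    m$P0 <- P0
    simulate_aggregation(m, design$t_grid)$M
  })

  set.seed(design$rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_well)
  Y <- matrix(NA_real_, nrow = length(design$t_grid), ncol = n_well,
              dimnames = list(NULL, anno$well))
  for (w in seq_len(n_well)) {
    set.seed(sub_seeds[w])
    cond <- (w - 1L) %/% design$n_replicates + 1L
    M <- traj[[cond]]
    if (design$lag_jitter_sd > 0) {
      shift <- stats::rnorm(1, 0, design$lag_jitter_sd)
      M <- shift_curve(design$t_grid, M, shift)
    }
    y <- design$gain * M + design$baseline
    if (design$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, design$noise_sd)
    Y[, w] <- y
  }
  structure(list(t = design$t_grid, Y = Y, anno = anno), class = "tht_set")
}

#' @export
print.tht_set <- function(x, ...) {
  cat("ThT replicate set:", ncol(x$Y), "wells,",
      length(unique(x$anno$ratio)), "conditions,",
      length(x$t), "time points (",
      format(min(x$t)), "-", format(max(x$t)), "h )\n")
  invisible(x)
}

#' Extract one curve from a ThT set
#'
#' @param set a \code{tht_set}.
#' @param well well id (column name of \code{set$Y}).
#' @return a \code{tht_curve}: list(t, y, meta).
#' @export
tht_curve <- function(set, well) {
  stopifnot(inherits(set, "tht_set"))
  if (!well %in% colnames(set$Y)) stop("unknown well: ", well)
  structure(list(t = set$t, y = set$Y[, well],
                 meta = set$anno[set$anno$well == well, , drop = FALSE]),
            class = "tht_curve")
}

# horizontal time shift with linear re-interpolation; values shifted past the
# recorded range are held at the boundary value
shift_curve <- function(t, y, shift) {
  stats::approx(t + shift, y, xout = t, rule = 2)$y
}
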