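# Conversion of NMR interface maps into active-residue restraint lists for
# data-driven docking, and their export (plain and AIR-style).

#' Construct a restraint set
#'
#' @param chains named list: chain label -> integer residue ids (sorted,
#'   unique).
#' @param provenance named list: chain label -> character vector (rule and
#'   threshold per residue), same lengths as \code{chains}.
#' @param construct label of the docking construct the set targets
#'   (\code{"monomer-dock"}, \code{"fibril-surface-dock"},
#'   \code{"fibril-end-dock"}).
#' @return object of class \code{restraint_set}.
#' @export
restraint_set <- function(chains, provenance = NULL,
                          construct = c("monomer-dock", "fibril-surface-dock",
                                        "fibril-end-dock")) {
  construct <- match.arg(construct)
  stopifnot(is.list(chains), !is.null(names(chains)))
  chains <- lapply(chains, function(x) sort(unique(as.integer(x))))
  for (ch in names(chains))
    if (anyDuplicated(chains[[ch]]))
      stop("duplicate residue ids within chain ", ch)
  if (is.null(provenance))
    provenance <- lapply(chains, function(x)
      rep("unspecified", length(x)))
  structure(list(chains = chains, provenance = provenance,
                 construct = construct),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("Restraint set (", x$construct, ")\n", sep = "")
  for (ch in names(x$chains))
    cat("  ", ch, ": ", paste(x$chains[[ch]], collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Select ligand active residues from titration CSP profiles
#'
#' A residue is active when it is flagged above-average-CSP in strictly more
#' than \code{majority_frac} of the titration ratios ("most of the ratios",
#' formalized as a strict majority).
#'
#' @param profiles list of CSP profile data.frames (one per titration
#'   ratio; columns \code{residue}, \code{csp_above_avg}), as returned by
#'   \code{\link{compute_csp}}.
#' @param majority_frac strict-majority fraction (default 0.5).
#' @param chain chain label for the ligand (default \code{"A"}).
#' @param construct passed to \code{\link{restraint_set}}.
#' @return a \code{restraint_set} with one chain.
#' @export
select_ligand_actives <- function(profiles, majority_frac = 0.5,
                                  chain = "A", construct = "monomer-dock") {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  if (!all(vapply(profiles, nrow, 1L) > 0)) {
    warning("empty CSP profile(s); returning empty restraint set")
    return(restraint_set(stats::setNames(list(integer()), chain),
                         construct = construct))
  }
  residues <- sort(unique(unlist(lapply(profiles, `[[`, "residue"))))
  counts <- vapply(residues, function(r)
    sum(vapply(profiles, function(p) {
      i <- match(r, p$residue)
      !is.na(i) && isTRUE(p$csp_above_avg[i])
    }, logical(1))), integer(1))
  active <- residues[counts > majority_frac * length(profiles)]
  prov <- sprintf("csp_above_avg in %d/%d ratios (majority_frac=%g)",
                  counts[match(active, residues)], length(profiles),
                  majority_frac)
  restraint_set(stats::setNames(list(active), chain),
                provenance = stats::setNames(list(prov), chain),
                construct = construct)
}

#' Select receptor active residues from PRE profiles
#'
#' Per-chain classification by the fractional intensity-loss rule
#' (\code{\link{classify_pre}} semantics): active when
#' \eqn{1 - I_{para}/I_{dia} >} \code{loss_threshold}. Chains (e.g. the
#' alpha, beta and beta' subunits of a heterohexamer) are kept distinct.
#'
#' @param pre_profiles data.frame as returned by \code{\link{classify_pre}}
#'   (columns \code{chain}, \code{residue}, \code{pre_ratio}), or a named
#'   list of per-chain data.frames.
#' @param loss_threshold fractional loss cutoff (default 0.5).
#' @param construct passed to \code{\link{restraint_set}}.
#' @return a \code{restraint_set} with one entry per chain.
#' @export
select_receptor_actives <- function(pre_profiles, loss_threshold = 0.5,
                                    construct = "monomer-dock") {
  if (is.data.frame(pre_profiles)) {
    stopifnot("chain" %in% names(pre_profiles))
    pre_profiles <- split(pre_profiles, pre_profiles$chain)
  }
  chains <- lapply(pre_profiles, function(p) {
    if (nrow(p) == 0L) {
      warning("chain with no measurable residues; empty active list")
      return(integer())
    }
    if (anyDuplicated(p$residue))
      stop("duplicate residue ids within a chain profile")
    p$residue[(1 - p$pre_ratio) > loss_threshold]
  })
  prov <- lapply(chains, function(ids)
    rep(sprintf("pre_loss > %g", loss_threshold), length(ids)))
  restraint_set(chains, provenance = prov, construct = construct)
}

#' Export a restraint set
#'
#' \code{"plain"} style writes one line per non-empty chain,
#' \code{"CHAIN: id,id,..."}; \code{"air"} style writes one
#' ambiguous-interaction-restraint stanza per active residue, listing every
#' active residue on the other chains as an allowed partner, in a TBL-like
#' plain-text dialect. Output is byte-deterministic.
#'
#' @param rset a \code{restraint_set} with at least one non-empty chain.
#' @param path output file; \code{NULL} returns the lines invisibly.
#' @param style \code{"plain"} or \code{"air"}.
#' @param distance upper bound (Angstrom) written in AIR stanzas
#'   (default 2.0, with 2.0 lower slack, HADDOCK convention).
#' @return the character vector of output lines, invisibly.
#' @export
export_restraints <- function(rset, path = NULL, style = c("plain", "air"),
                              distance = 2.0) {
  stopifnot(inherits(rset, "restraint_set"))
  style <- match.arg(style)
  chains <- rset$chains[vapply(rset$chains, length, 1L) > 0]
  if (!length(chains)) stop("restraint set has no non-empty chain")
  if (style == "plain") {
    lines <- vapply(names(chains), function(ch)
      paste0(ch, ": ", paste(chains[[ch]], collapse = ",")), "")
  } else {
    lines <- character()
    for (ch in names(chains)) {
      partners <- chains[names(chains) != ch]
      for (res in chains[[ch]]) {
        sel <- unlist(lapply(names(partners), function(pc)
          sprintf("(segid %s and resid %d)", pc, partners[[pc]])))
        if (!length(sel))
          sel <- "(not segid)"  # no partner chain: unrestrained target
        lines <- c(lines,
                   sprintf("assign (segid %s and resid %d)", ch, res),
                   "(",
                   paste0("     ", sel[1]),
                   if (length(sel) > 1) paste0("  or ", sel[-1]),
                   sprintf(") %.1f %.1f 0.0", distance, distance),
                   "")
      }
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a plain-style restraint file
#'
#' Inverse of \code{export_restraints(style = "plain")}.
#'
#' @param path file with \code{"CHAIN: id,id,..."} lines.
#' @param construct construct label for the resulting set.
#' @return a \code{restraint_set}.
#' @export
read_restraints <- function(path, construct = "monomer-dock") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  chains <- stats::setNames(
    lapply(parts, function(p)
      as.integer(strsplit(trimws(p[2]), ",", fixed = TRUE)[[1]])),
    vapply(parts, function(p) trimws(p[1]), ""))
  restraint_set(chains, construct = construct)
}
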