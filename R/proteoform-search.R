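# Proteoform hypothesis enumeration and tolerance matching. The search space
# models the proteolytic processing of a latent plant PPO: a fixed mature
# N-terminus, a ragged main-core C-terminus, an optional disulfide-attached
# residual C-terminal peptide with its own ragged end, uncleaved (latent)
# variants, and counted modifications.

#' Define a proteoform search space
#'
#' @param sequence Mature protein sequence (transit peptide already removed;
#'   coordinates are 1-based on this string).
#' @param core_end_window Integer vector of candidate C-terminal positions of
#'   the main core.
#' @param peptide_start Start coordinate of the disulfide-attached C-terminal
#'   peptide, or `NULL` if no attached peptide is modelled.
#' @param peptide_end_window Integer vector of candidate peptide end positions.
#' @param latent_end_window Integer vector of candidate C-terminal positions
#'   of the uncleaved pro-enzyme, or `NULL`.
#' @param mods List of [modification] objects; each is enumerated at counts
#'   `0..max_count`.
#' @param oxidation_max Maximum number of ~16 Da oxidations enumerated as
#'   satellite variants (0 disables).
#' @param conditions Subset of `c("non_reducing", "reducing")`.
#' @param n_disulfide_attached Disulfide count when the peptide is attached
#'   (internal bridges plus the core-peptide link).
#' @param n_disulfide_core Disulfide count for the core alone.
#' @param n_disulfide_latent Disulfide count for the uncleaved pro-enzyme.
#' @param n_thioether Thioether (Cys-His) bridge count, common to all
#'   topologies.
#' @return An object of class `search_space`.
#' @export
search_space <- function(sequence,
                         core_end_window = NULL,
                         peptide_start = NULL,
                         peptide_end_window = NULL,
                         latent_end_window = NULL,
                         mods = list(),
                         oxidation_max = 0L,
                         conditions = "non_reducing",
                         n_disulfide_attached = 3L,
                         n_disulfide_core = 2L,
                         n_disulfide_latent = 3L,
                         n_thioether = 1L) {
  validate_sequence(sequence)
  n <- nchar(sequence)
  chk_window <- function(w, what) {
    if (is.null(w)) return(NULL)
    w <- as.integer(w)
    if (any(w < 1L) || any(w > n))
      stop(what, " outside sequence bounds [1, ", n, "]")
    sort(unique(w))
  }
  core_end_window <- chk_window(core_end_window, "core_end_window")
  peptide_end_window <- chk_window(peptide_end_window, "peptide_end_window")
  latent_end_window <- chk_window(latent_end_window, "latent_end_window")
  if (!is.null(peptide_start)) {
    peptide_start <- as.integer(peptide_start)
    if (peptide_start < 1L || peptide_start > n)
      stop("peptide_start outside sequence bounds")
    if (is.null(peptide_end_window))
      stop("peptide_end_window required when peptide_start is given")
    if (any(peptide_end_window < peptide_start))
      stop("peptide_end_window must not precede peptide_start")
    if (!is.null(core_end_window) && max(core_end_window) >= peptide_start)
      stop("core_end_window and attached-peptide window overlap")
  }
  conditions <- match.arg(conditions, c("non_reducing", "reducing"),
                          several.ok = TRUE)
  for (m in mods) if (!inherits(m, "modification"))
    stop("mods must be a list of modification objects")
  structure(
    list(sequence = toupper(sequence),
         core_end_window = core_end_window,
         peptide_start = peptide_start,
         peptide_end_window = peptide_end_window,
         latent_end_window = latent_end_window,
         mods = mods,
         oxidation_max = as.integer(oxidation_max),
         conditions = conditions,
         n_disulfide_attached = as.integer(n_disulfide_attached),
         n_disulfide_core = as.integer(n_disulfide_core),
         n_disulfide_latent = as.integer(n_disulfide_latent),
         n_thioether = as.integer(n_thioether)),
    class = "search_space"
  )
}

mod_count_grid <- function(space) {
  mods <- space$mods
  if (space$oxidation_max > 0L) {
    ox <- builtin_modifications()$oxidation
    ox$max_count <- space$oxidation_max
    mods <- c(mods, list(ox))
  }
  if (length(mods) == 0L)
    return(list(mods = list(), grid = data.frame(row = 1L)[, 0, drop = FALSE]))
  counts <- lapply(mods, function(m) 0L:m$max_count)
  names(counts) <- vapply(mods, function(m) m$name, character(1))
  grid <- do.call(expand.grid, c(counts, KEEP.OUT.ATTRS = FALSE))
  list(mods = mods, grid = grid)
}

#' Enumerate proteoform hypotheses
#'
#' Cartesian product of core C-terminal positions, attached-peptide state
#' (absent or each peptide end), modification counts and conditions, plus
#' uncleaved latent variants over the latent end window. Ordering is
#' deterministic: topologies first (core ends ascending, peptide absent before
#' each peptide end, then latent ends), then modification counts, then
#' conditions.
#'
#' @param space A [search_space].
#' @return List of [proteoform] objects; each carries a `label` attribute.
#' @export
enumerate_hypotheses <- function(space) {
  stopifnot(inherits(space, "search_space"))
  seq <- space$sequence

  topologies <- list()
  add <- function(chains, n_ss, label)
    topologies[[length(topologies) + 1L]] <<-
      list(chains = chains, n_ss = n_ss, label = label)

  for (e in space$core_end_window) {
    core <- chain(substr(seq, 1L, e), id = sprintf("core 1-%d", e),
                  start = 1L, end = e)
    add(list(core), space$n_disulfide_core, sprintf("1-%d", e))
    if (!is.null(space$peptide_start)) {
      for (f in space$peptide_end_window) {
        pep <- chain(substr(seq, space$peptide_start, f),
                     id = sprintf("peptide %d-%d", space$peptide_start, f),
                     start = space$peptide_start, end = f)
        add(list(core, pep), space$n_disulfide_attached,
            sprintf("1-%d//%d-%d", e, space$peptide_start, f))
      }
    }
  }
  for (l in space$latent_end_window) {
    lat <- chain(substr(seq, 1L, l), id = sprintf("latent 1-%d", l),
                 start = 1L, end = l)
    add(list(lat), space$n_disulfide_latent, sprintf("latent 1-%d", l))
  }

  mg <- mod_count_grid(space)
  out <- list()
  for (topo in topologies) {
    for (g in seq_len(max(1L, nrow(mg$grid)))) {
      modset <- list()
      mod_label <- ""
      if (length(mg$mods) > 0L) {
        for (k in seq_along(mg$mods)) {
          cnt <- mg$grid[g, k]
          if (cnt > 0L) {
            modset[[length(modset) + 1L]] <- list(mod = mg$mods[[k]],
                                                  count = as.integer(cnt))
            mod_label <- paste0(mod_label, sprintf(" +%dx%s", cnt,
                                                   mg$mods[[k]]$name))
          }
        }
      }
      for (cond in space$conditions) {
        h <- proteoform(topo$chains, n_disulfide = topo$n_ss,
                        n_thioether = space$n_thioether,
                        modifications = modset, condition = cond)
        attr(h, "label") <- paste0(topo$label, mod_label, " [", cond, "]")
        out[[length(out) + 1L]] <- h
      }
    }
  }
  out
}

#' Match observed neutral masses to proteoform hypotheses
#'
#' Every observed estimate is paired with all enumerated hypotheses whose
#' calculated mass falls within tolerance; assignments are ranked by absolute
#' mass error, ties broken by parsimony (fewer modifications, then fewer
#' chains), so a satellite (e.g. oxidized) variant never outranks an
#' unmodified hypothesis at equal error. Observed estimates with no hypothesis
#' in tolerance are reported with `NA` columns.
#'
#' @param observed A `neutral_mass_estimates` data frame from [deconvolute],
#'   or a numeric vector of neutral masses (then `mass_sd` is taken as 0).
#' @param space A [search_space] (or a pre-built list of hypotheses from
#'   [enumerate_hypotheses]).
#' @param tol_da Absolute tolerance in Da; default
#'   `max(3 * mass_sd, 0.5)` per estimate.
#' @param tol_ppm Relative tolerance in ppm (overrides `tol_da` if given;
#'   appropriate at peptide scale).
#' @param scale Mass scale used for the calculated masses: `"avg"` for intact
#'   proteins, `"mono"` for peptide-scale work.
#' @return Data frame of class `proteoform_assignments`: `observed_mass`,
#'   `observed_sd`, `label`, `calc_mass`, `delta_da`, `delta_ppm`, `rank`,
#'   `n_mods`, `n_chains`, `condition`. The hypothesis list is attached as
#'   attribute `hypotheses`, indexed by column `hyp_index`.
#' @export
match_proteoforms <- function(observed, space, tol_da = NULL, tol_ppm = NULL,
                              scale = c("avg", "mono")) {
  scale <- match.arg(scale)
  if (is.numeric(observed))
    observed <- data.frame(mass = observed, mass_sd = 0)
  if (nrow(observed) == 0L) stop("no observed masses")
  hyps <- if (inherits(space, "search_space")) enumerate_hypotheses(space)
          else space
  if (length(hyps) == 0L) stop("empty hypothesis list")
  calc <- vapply(hyps, proteoform_mass, numeric(1), scale = scale)
  n_mods <- vapply(hyps, function(h)
    sum(vapply(h$modifications, function(m) m$count, numeric(1)), 0), numeric(1))
  n_chains <- vapply(hyps, function(h) length(h$chains), integer(1))
  cond <- vapply(hyps, function(h) h$condition, character(1))
  labels <- vapply(hyps, function(h) attr(h, "label") %||% "", character(1))

  rows <- list()
  for (i in seq_len(nrow(observed))) {
    m_obs <- observed$mass[i]
    sd_obs <- if ("mass_sd" %in% names(observed)) observed$mass_sd[i] else 0
    if (is.na(sd_obs)) sd_obs <- 0
    tol <- if (!is.null(tol_ppm)) tol_ppm * 1e-6 * m_obs
           else if (!is.null(tol_da)) tol_da
           else max(3 * sd_obs, 0.5)
    delta <- m_obs - calc
    hit <- which(abs(delta) <= tol)
    if (length(hit) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        observed_mass = m_obs, observed_sd = sd_obs, hyp_index = NA_integer_,
        label = NA_character_, calc_mass = NA_real_, delta_da = NA_real_,
        delta_ppm = NA_real_, rank = NA_integer_, n_mods = NA_real_,
        n_chains = NA_integer_, condition = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    ord <- hit[order(abs(delta[hit]), n_mods[hit], n_chains[hit])]
    rows[[length(rows) + 1L]] <- data.frame(
      observed_mass = m_obs, observed_sd = sd_obs, hyp_index = ord,
      label = labels[ord], calc_mass = calc[ord], delta_da = delta[ord],
      delta_ppm = delta[ord] / calc[ord] * 1e6,
      rank = seq_along(ord), n_mods = n_mods[ord], n_chains = n_chains[ord],
      condition = cond[ord], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hypotheses") <- hyps
  class(out) <- c("proteoform_assignments", "data.frame")
  out
}

#' Explain a mass shift between two species
#'
#' Searches combinations of at most `max_items` known mass deltas --
#' modifications, single-residue losses, water, 2H -- whose sum matches the
#' absolute difference `|m1 - m2|` within tolerance.
#'
#' @param m1,m2 The two neutral masses in Da.
#' @param tol Matching tolerance in Da (> 0).
#' @param scale `"avg"` or `"mono"`.
#' @param max_items Maximum number of combined deltas (1 or 2).
#' @return Data frame `explanation`, `delta`, `error`, sorted by absolute
#'   error. Zero rows when nothing matches (e.g. a zero shift).
#' @export
explain_shift <- function(m1, m2, tol = 0.5, scale = c("avg", "mono"),
                          max_items = 2L) {
  scale <- match.arg(scale)
  if (tol <= 0) stop("tol must be positive")
  target <- abs(m1 - m2)
  mods <- builtin_modifications()
  deltas <- vapply(mods, function(m)
    if (scale == "avg") m$delta_avg else m$delta_mono, numeric(1))
  res <- residue_masses(scale)
  names(res) <- paste0("loss_", names(res))
  h <- if (scale == "avg") .MASS_CONST$hydrogen_avg else .MASS_CONST$hydrogen_mono
  w <- if (scale == "avg") .MASS_CONST$water_avg else .MASS_CONST$water_mono
  cand <- c(deltas, res, water = w, `2H` = 2 * h)

  singles <- data.frame(explanation = names(cand), delta = unname(cand),
                        stringsAsFactors = FALSE)
  out <- singles
  if (max_items >= 2L) {
    idx <- which(upper.tri(matrix(0, length(cand), length(cand)), diag = TRUE),
                 arr.ind = TRUE)
    pairs <- data.frame(
      explanation = paste(names(cand)[idx[, 1]], "+", names(cand)[idx[, 2]]),
      delta = unname(cand[idx[, 1]] + cand[idx[, 2]]),
      stringsAsFactors = FALSE)
    out <- rbind(out, pairs)
  }
  out$error <- abs(out$delta - target)
  out <- out[out$error <= tol & target > 0, , drop = FALSE]
  out <- out[order(out$error), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the mature sequence from a precursor
#'
#' Locates an anchor peptide of known mature coordinates inside a precursor
#' sequence (e.g. a UniProt record including the chloroplast transit peptide)
#' and trims the precursor so that numbering starts at the mature N-terminus.
#'
#' @param precursor Full precursor sequence.
#' @param anchor Peptide whose mature coordinates are known.
#' @param anchor_start 1-based start coordinate of `anchor` in the mature
#'   protein.
#' @return Mature sequence string.
#' @export
mature_sequence <- function(precursor, anchor, anchor_start) {
  validate_sequence(precursor)
  pos <- regexpr(anchor, precursor, fixed = TRUE)[1]
  if (pos < 0) stop("anchor peptide not found in precursor")
  if (pos < anchor_start)
    stop("precursor too short upstream of the anchor for the stated numbering")
  substr(precursor, pos - anchor_start + 1L, nchar(precursor))
}
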