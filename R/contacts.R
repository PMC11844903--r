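#' Intermolecular contact frequencies by sequence position
#'
#' Counts pairs of beads on different chains whose minimum-image distance
#' is below the sequence-dependent cutoff 1.2 sigma_ij (just beyond the
#' pair potential minimum at ~1.122 sigma_ij, so only significantly bound
#' pairs are counted).  Intra-chain pairs are excluded.  All chains must
#' share the same sequence; counts are accumulated over frames and over
#' all distinct chain pairs, symmetrized over positions.
#'
#' @param traj a `cg_trajectory` with at least 2 chains.
#' @param model a [cg_model()].
#' @param T temperature tag in K used to resolve the model (the analysis
#'   convention is 0.95 Tc of the system under study).
#' @param cutoff_factor contact cutoff in units of sigma_ij (default 1.2).
#' @param stride analyse every `stride`-th frame (default 1).
#' @return object of class `contact_map`: `f` (L x L symmetric count
#'   matrix), `n_frames`, `n_chain_pairs`, `cutoff_factor`, `temperature`.
#' @export
intermolecular_contact_frequencies <- function(traj, model, T = 298,
                                               cutoff_factor = 1.2,
                                               stride = 1) {
  contact_maps_impl(traj, model, T, cutoff_factor, stride,
                    with_energy = FALSE)$freq
}

contact_maps_impl <- function(traj, model, T, cutoff_factor, stride,
                              with_energy) {
  stopifnot(inherits(traj, "cg_trajectory"), length(traj$frames) >= 1)
  n_chains <- length(unique(traj$chain))
  if (n_chains < 2) stop("contact analysis requires at least 2 chains")
  tab <- table(traj$chain)
  if (length(unique(tab)) != 1) {
    stop("all chains must have the same length")
  }
  L <- as.integer(tab[1])
  seqpos <- integer(length(traj$chain))
  for (c in unique(traj$chain)) {
    idx <- which(traj$chain == c)
    seqpos[idx] <- seq_along(idx) - 1L
  }
  par <- engine_params(model, T)
  types <- bead_types(model, traj$residue)
  use <- seq(1, length(traj$frames), by = stride)
  f <- e <- matrix(0, L, L)
  for (k in use) {
    m <- cpp_contact_maps(traj$frames[[k]], traj$box, traj$chain, types,
                          seqpos, L, par, cutoff_factor, with_energy)
    f <- f + m$fmap
    e <- e + m$emap
  }
  np <- n_chains * (n_chains - 1) / 2
  freq <- structure(list(f = f, n_frames = length(use),
                         n_chain_pairs = np,
                         cutoff_factor = cutoff_factor, temperature = T,
                         residue = traj$residue[traj$chain ==
                                                  traj$chain[1]]),
                    class = "contact_map")
  list(freq = freq, esum = e)
}

#' Intermolecular contact-energy map
#'
#' For every contacted position pair, accumulates the hydrophobic +
#' electrostatic pair energy of the model evaluated at the observed
#' interacting distance, averaged over analysed frames and distinct chain
#' pairs.
#'
#' @inheritParams intermolecular_contact_frequencies
#' @return list with `energy` (L x L map in kJ/mol), the accompanying
#'   `frequencies` ([intermolecular_contact_frequencies()] output) and the
#'   analysis `temperature` recorded in metadata.
#' @export
contact_energy_map <- function(traj, model, T = 298, cutoff_factor = 1.2,
                               stride = 1) {
  m <- contact_maps_impl(traj, model, T, cutoff_factor, stride,
                         with_energy = TRUE)
  denom <- m$freq$n_frames * m$freq$n_chain_pairs
  list(energy = m$esum / denom, frequencies = m$freq, temperature = T)
}

#' Ranked residue-type pair interaction strengths
#'
#' Aggregates the positional contact frequencies f_ij by residue-type
#' pair, weights each pair by its model interaction energy (hydrophobic +
#' electrostatic, evaluated at the pair potential minimum distance) and
#' normalizes by the sequence abundance of the two types:
#' strength(a, b) = f_ab (E_hyd + E_elec) / (N_a N_b),
#' finally rescaled so the largest-magnitude pair is 1.
#'
#' @param frequencies a `contact_map` from
#'   [intermolecular_contact_frequencies()].
#' @param model a [cg_model()].
#' @param sequence the chain sequence (types absent from it are skipped
#'   with a warning if contacts name them).
#' @param T temperature in K for the energy evaluation.
#' @return data.frame (i, j, f, energy, N_i, N_j, strength) sorted by
#'   strength, strongest first.  `strength` uses the positive-attractive
#'   convention and has maximum magnitude 1.
#' @export
ranked_pair_interactions <- function(frequencies, model, sequence,
                                     T = 298) {
  stopifnot(inherits(frequencies, "contact_map"))
  if (sum(frequencies$f) == 0) stop("contact map is empty")
  rm <- resolve_model(model, T)
  res <- frequencies$residue
  chars <- strsplit(sequence, "")[[1]]
  comp <- table(factor(chars, levels = model$alphabet))
  types <- sort(unique(res))
  rows <- list()
  for (a in types) {
    for (b in types[types >= a]) {
      ia <- which(res == a)
      ib <- which(res == b)
      f_ab <- sum(frequencies$f[ia, ib])
      if (a == b) f_ab <- f_ab / 2 + sum(diag(
        frequencies$f[ia, ia, drop = FALSE])) / 2
      if (f_ab == 0) next
      Na <- comp[a]; Nb <- comp[b]
      if (Na == 0 || Nb == 0) {
        warning("type pair ", a, "-", b,
                " has contacts but zero sequence abundance; skipped")
        next
      }
      i <- match(a, model$alphabet); j <- match(b, model$alphabet)
      r_min <- if (rm$hscheme == 1L) 2^(1 / 6) * rm$hsig[i, j] else
        wang_frenkel_rmin(rm$hsig[i, j], rm$hshape[i, j],
                          r_c = rm$hcut[i, j])
      E <- pair_energy_resolved(rm, i, j, r_min, include_catpi = FALSE)
      rows[[paste(a, b)]] <- data.frame(
        i = a, j = b, f = f_ab, energy = E, N_i = Na, N_j = Nb,
        strength = f_ab * (-E) / (Na * Nb))
    }
  }
  out <- do.call(rbind, rows)
  out$strength <- out$strength / max(abs(out$strength))
  out <- out[order(-out$strength), ]  # strongest attraction first
  rownames(out) <- NULL
  out
}
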