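# Independent O(N^2) brute-force oracle for energies, forces, stress and
# contacts.  Uses only the exported scalar pair-potential functions plus
# plain R loops; deliberately shares no code path with the C++ engine.

min_image <- function(d, L) d - L * round(d / L)

# total energy by double loop over all bead pairs + bonds
brute_force_energy <- function(model, conf, T = 298) {
  rm <- cgphase:::resolve_model(model, T)
  pos <- conf$positions
  box <- conf$box
  n <- nrow(pos)
  idx <- match(conf$residue, model$alphabet)
  e_pair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bonded <- conf$chain[i] == conf$chain[j] && abs(i - j) == 1
      if (bonded) next
      d <- min_image(pos[i, ] - pos[j, ], box)
      r <- sqrt(sum(d^2))
      e_pair <- e_pair + oracle_pair_energy(rm, idx[i], idx[j], r)
    }
  }
  e_bond <- 0
  for (i in seq_len(n - 1)) {
    if (conf$chain[i] == conf$chain[i + 1]) {
      d <- min_image(pos[i, ] - pos[i + 1, ], box)
      e_bond <- e_bond + bond_energy(sqrt(sum(d^2)) * 10,
                                     k = model$bond_k, r0 = model$bond_r0)
    }
  }
  list(energy = e_pair + e_bond, e_pair = e_pair, e_bond = e_bond)
}

oracle_pair_energy <- function(rm, ti, tj, r) {
  e <- 0
  if (rm$hscheme == 1) {
    e <- e + ashbaugh_hatch_energy(r, rm$heps[ti, tj], rm$hsig[ti, tj],
                                   rm$hshape[ti, tj],
                                   r_cut = rm$hcut[ti, tj])
  } else {
    e <- e + wang_frenkel_energy(r, rm$heps[ti, tj], rm$hsig[ti, tj],
                                 rm$hshape[ti, tj], r_c = rm$hcut[ti, tj])
  }
  e <- e + yukawa_energy(r, rm$epref[ti, tj], rm$kappa, r_cut = rm$ecut)
  if (rm$cpeps[ti, tj] != 0) {
    e <- e + cation_pi_energy(r, rm$cpeps[ti, tj], rm$cpsig[ti, tj],
                              r_cut = 3 * rm$cpsig[ti, tj])
  }
  e
}

# central-difference force check, h in nm
numeric_forces <- function(model, conf, T = 298, h = 1e-5) {
  pos <- conf$positions
  F <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (a in 1:3) {
      pp <- pos; pp[i, a] <- pp[i, a] + h
      cm <- pos; cm[i, a] <- cm[i, a] - h
      cp <- configuration(pp, conf$box, conf$chain, conf$residue)
      cn <- configuration(cm, conf$box, conf$chain, conf$residue)
      ep <- total_energy_forces(model, cp, T)$energy
      en <- total_energy_forces(model, cn, T)$energy
      F[i, a] <- -(ep - en) / (2 * h)
    }
  }
  F
}

# brute-force intermolecular contact count per position pair
brute_force_contacts <- function(model, conf, T = 298, factor = 1.2) {
  rm <- cgphase:::resolve_model(model, T)
  pos <- conf$positions
  n <- nrow(pos)
  idx <- match(conf$residue, model$alphabet)
  L <- sum(conf$chain == conf$chain[1])
  seqpos <- unlist(lapply(table(conf$chain), seq_len))
  f <- matrix(0, L, L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (conf$chain[i] == conf$chain[j]) next
      d <- min_image(pos[i, ] - pos[j, ], conf$box)
      r <- sqrt(sum(d^2))
      if (r < factor * rm$hsig[idx[i], idx[j]]) {
        si <- seqpos[i]; sj <- seqpos[j]
        f[si, sj] <- f[si, sj] + 1
        if (si != sj) f[sj, si] <- f[sj, si] + 1
      }
    }
  }
  f
}

# random multi-chain configuration for oracle tests (small, may overlap)
random_configuration <- function(model, n_chains, chain_len, box,
                                 seed = 1, min_sep = 0.35) {
  set.seed(seed)
  alphabet <- model$alphabet
  res <- sample(alphabet, n_chains * chain_len, replace = TRUE)
  r0 <- model$bond_r0 / 10
  pos <- matrix(0, 0, 3)
  for (c in seq_len(n_chains)) {
    p <- matrix(0, chain_len, 3)
    p[1, ] <- runif(3) * box
    for (k in seq_len(chain_len - 1)) {
      repeat {
        u <- rnorm(3)
        cand <- p[k, ] + r0 * u / sqrt(sum(u^2))
        # keep beads separated so potentials stay finite
        if (nrow(pos) == 0 && k < 2) break
        all_prev <- rbind(pos, p[seq_len(k), , drop = FALSE])
        dd <- min_image(t(all_prev) - cand, box)  # column-recycled per axis
        d <- sqrt(colSums(dd^2))
        if (min(d) > min_sep) break
      }
      p[k + 1, ] <- cand
    }
    pos <- rbind(pos, p)
  }
  configuration(pos, box, rep(seq_len(n_chains), each = chain_len), res)
}
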