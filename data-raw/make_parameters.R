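# Generates the packaged parameter tables under inst/extdata/params and the
# synthetic A1-LCD sequence fixtures under inst/extdata/sequences.
# Run from the package root:  Rscript data-raw/make_parameters.R
#
# Residue sigma (nm), masses (g/mol) and integer charges are standard values
# used across the one-bead-per-residue model family.  The KR, Urry and
# CALVADOS2 hydropathy scales are transcriptions of the published scales.
# The Mpipi / Mpipi-Recharged pair tables and the HPS-cation-pi epsilon are
# SYNTHETIC surrogates (see file headers): they preserve the documented
# qualitative structure of those models (pair-specific interactions,
# W > Y > F aromatic ranking, cation-pi dominance, charge-product sign
# structure of the Yukawa amplitudes) but are not the published numbers.

aa <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

sigma <- c(A=0.504,R=0.656,N=0.568,D=0.558,C=0.548,Q=0.602,E=0.592,G=0.450,
           H=0.608,I=0.618,L=0.618,K=0.636,M=0.618,F=0.636,P=0.556,S=0.518,
           T=0.562,W=0.678,Y=0.646,V=0.586)

mass <- c(A=71.08,R=156.19,N=114.10,D=115.09,C=103.14,Q=128.13,E=129.12,
          G=57.05,H=137.14,I=113.16,L=113.16,K=128.17,M=131.19,F=147.18,
          P=97.12,S=87.08,T=101.10,W=186.21,Y=163.18,V=99.07)

charge <- c(A=0,R=1,N=0,D=-1,C=0,Q=0,E=-1,G=0,H=0,I=0,
            L=0,K=1,M=0,F=0,P=0,S=0,T=0,W=0,Y=0,V=0)

# Kapcha-Rossky hydropathy scale (HPS); note F > W > Y ranking.
lambda_kr <- c(A=0.730,R=0.000,N=0.432,D=0.378,C=0.595,Q=0.514,E=0.459,
               G=0.649,H=0.514,I=0.973,L=0.973,K=0.514,M=0.838,F=1.000,
               P=1.000,S=0.595,T=0.676,W=0.946,Y=0.865,V=0.892)

# Urry hydropathy scale (HPS-Urry); W > Y > F ranking.
lambda_urry <- c(A=0.603,R=0.559,N=0.589,D=0.295,C=0.648,Q=0.549,E=0.000,
                 G=0.579,H=0.764,I=0.693,L=0.721,K=0.427,M=0.890,F=0.827,
                 P=0.759,S=0.589,T=0.582,W=1.000,Y=0.896,V=0.664)

# CALVADOS2 optimized lambda (Bayesian fit to Rg/PRE data); W > Y > F.
lambda_c2 <- c(A=0.2743,R=0.7307,N=0.4255,D=0.0416,C=0.5615,Q=0.3934,
               E=0.0006,G=0.7058,H=0.4663,I=0.5423,L=0.6440,K=0.1790,
               M=0.5308,F=0.8672,P=0.3593,S=0.4625,T=0.3713,W=0.9893,
               Y=0.9774,V=0.2083)

dirp <- "inst/extdata/params"
dirs <- "inst/extdata/sequences"
dir.create(dirp, recursive = TRUE, showWarnings = FALSE)
dir.create(dirs, recursive = TRUE, showWarnings = FALSE)

write_residues <- function(lambda, file, header) {
  df <- data.frame(res = aa, q = charge[aa], lambda = lambda[aa],
                   sigma = sigma[aa], mass = mass[aa])
  con <- file(file.path(dirp, file), "w")
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
}

write_residues(lambda_kr, "hps_kr_residues.csv",
  "# HPS residue table: Kapcha-Rossky hydropathy scale; sigma nm, mass g/mol, q in e")
write_residues(lambda_urry, "hps_urry_residues.csv",
  "# HPS-Urry residue table: Urry hydropathy scale; sigma nm, mass g/mol, q in e")
write_residues(lambda_c2, "calvados2_residues.csv",
  "# CALVADOS2 residue table: optimized lambda; sigma nm, mass g/mol, q in e")
write_residues(rep(NA_real_, 20), "mpipi_residues.csv",
  "# Mpipi/Mpipi-Recharged residue table (lambda unused; pair table carries eps/sigma/nu)")

## ---- synthetic Mpipi Wang-Frenkel pair table ------------------------------
# contact propensity (synthetic, W > Y > F) and aromatic boosts
cont <- c(A=0.30,R=0.45,N=0.35,D=0.25,C=0.40,Q=0.35,E=0.25,G=0.30,H=0.45,
          I=0.50,L=0.50,K=0.30,M=0.50,F=0.55,P=0.40,S=0.30,T=0.32,W=0.75,
          Y=0.65,V=0.45)
boost <- c(F=1.35, Y=1.60, W=1.90)
arom <- c("F","W","Y")

pairs <- expand.grid(i = aa, j = aa, stringsAsFactors = FALSE)
pairs <- pairs[match(pairs$i, aa) <= match(pairs$j, aa), ]
eps0 <- 0.9
eps <- mapply(function(a, b) {
  e <- eps0 * (cont[a] + cont[b]) / 2
  if (a %in% arom && b %in% arom) e <- e * boost[a] * boost[b]
  # cation-pi: strong for R-aromatic, weak for K-aromatic (Mpipi-like)
  if ((a == "R" && b %in% arom) || (b == "R" && a %in% arom)) {
    e <- 1.15 * boost[intersect(c(a, b), arom)[1]]
  }
  unname(e)
}, pairs$i, pairs$j)
nu <- mapply(function(a, b) {
  if ((a %in% arom || a %in% c("R","K")) && (b %in% arom || b %in% c("R","K")) &&
      (a %in% arom || b %in% arom)) 2 else 1
}, pairs$i, pairs$j)
sig_ij <- (sigma[pairs$i] + sigma[pairs$j]) / 2

con <- file(file.path(dirp, "mpipi_pairs_synthetic.csv"), "w")
writeLines(c(
 "# SYNTHETIC Wang-Frenkel pair table for the Mpipi-family models.",
 "# Surrogate values: preserve pair-specific structure and W>Y>F /",
 "# cation-pi ranking of the published models, but are NOT the published",
 "# numbers. eps kJ/mol, sigma nm, nu dimensionless."), con)
write.csv(data.frame(i = pairs$i, j = pairs$j,
                     eps = round(eps, 4), sigma = round(sig_ij, 4), nu = nu),
          con, row.names = FALSE, quote = FALSE)
close(con)

## ---- synthetic Mpipi-Recharged Yukawa amplitude table ---------------------
# A_ij = C q_i q_j s_ij with pair-specific modulation s_ij that is not a
# product of single-residue factors (i<->j symmetric).
charged <- c("R","K","D","E")
smod <- matrix(1, 4, 4, dimnames = list(charged, charged))
smod["R","R"] <- 1.10; smod["R","K"] <- smod["K","R"] <- 1.05
smod["R","D"] <- smod["D","R"] <- 0.85; smod["R","E"] <- smod["E","R"] <- 0.90
smod["K","K"] <- 1.00; smod["K","D"] <- smod["D","K"] <- 0.95
smod["K","E"] <- smod["E","K"] <- 1.00
smod["D","D"] <- 1.10; smod["D","E"] <- smod["E","D"] <- 1.05
smod["E","E"] <- 1.00
C0 <- 138.935458 / 78.4   # kJ nm/mol per unit charge product at 298 K
yp <- expand.grid(i = charged, j = charged, stringsAsFactors = FALSE)
yp <- yp[match(yp$i, charged) <= match(yp$j, charged), ]
yp$A <- round(C0 * charge[yp$i] * charge[yp$j] * smod[cbind(yp$i, yp$j)], 4)

con <- file(file.path(dirp, "mpipi_recharged_yukawa_synthetic.csv"), "w")
writeLines(c(
 "# SYNTHETIC Yukawa amplitude table for the Mpipi-Recharged model.",
 "# Surrogate values: sign structure follows the charge product; the",
 "# pair-specific modulation is not reducible to single-residue factors.",
 "# A in kJ nm/mol."), con)
write.csv(yp, con, row.names = FALSE, quote = FALSE)
close(con)

## ---- synthetic HPS-cation-pi epsilon table --------------------------------
cp <- expand.grid(i = c("R","K"), j = arom, stringsAsFactors = FALSE)
cp$eps <- 3.35   # kJ/mol, uniform surrogate (~4x the AH aromatic depth)
cp$sigma <- round((sigma[cp$i] + sigma[cp$j]) / 2, 4)
con <- file(file.path(dirp, "hps_cation_pi_synthetic.csv"), "w")
writeLines(c(
 "# SYNTHETIC cation-pi Lennard-Jones table for the HPS-cation-pi model.",
 "# Uniform surrogate well depth; eps kJ/mol, sigma nm."), con)
write.csv(cp, con, row.names = FALSE, quote = FALSE)
close(con)

## ---- model registry -------------------------------------------------------
registry <- list(
  HPS = list(
    residue_table = "hps_kr_residues.csv",
    hydrophobic = "ashbaugh_hatch", ah_eps = 0.8368,
    electrostatic = "debye_huckel_fixed", kappa = 1.0, eps_r = 80,
    bond_k = 9.6, bond_r0 = 3.81, elec_cutoff = 3.5, hyd_cutoff_factor = 3),
  `HPS-cation-pi` = list(
    residue_table = "hps_kr_residues.csv",
    hydrophobic = "ashbaugh_hatch", ah_eps = 0.8368,
    electrostatic = "debye_huckel_fixed", kappa = 1.0, eps_r = 80,
    cation_pi_table = "hps_cation_pi_synthetic.csv",
    bond_k = 2.4, bond_r0 = 3.81, elec_cutoff = 3.5, hyd_cutoff_factor = 3),
  `HPS-Urry` = list(
    residue_table = "hps_urry_residues.csv",
    hydrophobic = "ashbaugh_hatch", ah_eps = 0.8368,
    electrostatic = "debye_huckel_fixed", kappa = 1.0, eps_r = 80,
    bond_k = 4.8, bond_r0 = 3.81, elec_cutoff = 2.0, hyd_cutoff_factor = 3),
  CALVADOS2 = list(
    residue_table = "calvados2_residues.csv",
    hydrophobic = "ashbaugh_hatch", ah_eps = 0.8368,
    electrostatic = "debye_huckel_salt_T", salt = 150,
    bond_k = 9.6, bond_r0 = 3.81, elec_cutoff = 4.0, hyd_cutoff_factor = 3),
  Mpipi = list(
    residue_table = "mpipi_residues.csv",
    hydrophobic = "wang_frenkel", pair_table = "mpipi_pairs_synthetic.csv",
    electrostatic = "debye_huckel_fixed", kappa = 1.26, eps_r = 80,
    bond_k = 9.6, bond_r0 = 3.81, elec_cutoff = 3.5, hyd_cutoff_factor = 3),
  `Mpipi-Recharged` = list(
    residue_table = "mpipi_residues.csv",
    hydrophobic = "wang_frenkel", pair_table = "mpipi_pairs_synthetic.csv",
    electrostatic = "yukawa", salt = 150,
    yukawa_table = "mpipi_recharged_yukawa_synthetic.csv",
    bond_k = 9.6, bond_r0 = 3.81, elec_cutoff = 3.5, hyd_cutoff_factor = 3)
)
yaml::write_yaml(registry, file.path(dirp, "models.yaml"))

## ---- synthetic A1-LCD sequence surrogates ---------------------------------
# 137-residue surrogate of the A1-LCD WT+NLS construct: 19 mutable aromatic
# sticker positions (7Y + 12F, pattern-conserved across variants) spaced
# every 7 residues, plus one non-mutable Y in the NLS-like C-terminal tail;
# whole-sequence WT composition 8Y + 12F.
spacer_pool <- c("G","S","G","N","G","R","G","S","Q","G","S","D","G","N","G","K")
sticker_pos <- seq(4, by = 7, length.out = 19)
wt_stickers <- ifelse(seq_len(19) %% 3 == 0 | seq_len(19) == 19, "Y", "F")
stopifnot(sum(wt_stickers == "Y") == 7, sum(wt_stickers == "F") == 12)

build_seq <- function(stickers) {
  s <- character(133)
  s[sticker_pos] <- stickers
  s[-sticker_pos] <- rep(spacer_pool, length.out = 133 - 19)
  paste0(paste(s, collapse = ""), "GKNY")   # NLS-like tail with fixed Y136
}

wm <- wt_stickers
variants <- list(
  "WT+NLS" = build_seq(wm),
  "allF"   = build_seq(rep("F", 19)),
  "allY"   = build_seq(rep("Y", 19)),
  "allW"   = build_seq(rep("W", 19)),
  "YtoW"   = build_seq(ifelse(wm == "Y", "W", wm)),
  "FtoW"   = build_seq(ifelse(wm == "F", "W", wm)),
  "W-"     = build_seq(ifelse(seq_len(19) %% 3 == 2, "G", "W"))
)
stopifnot(sum(seq_len(19) %% 3 == 2) == 6)  # W- keeps 13 W stickers

fa <- file.path(dirs, "a1lcd_variants_synthetic.fasta")
con <- file(fa, "w")
for (nm in names(variants)) {
  writeLines(sprintf(">%s synthetic A1-LCD surrogate", nm), con)
  writeLines(variants[[nm]], con)
}
close(con)

cat("wrote parameter tables and sequence fixtures\n")
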