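# Shared molecule fixtures, parsed once per test run.

.tr_mol_env <- new.env(parent = emptyenv())

tr_mols <- function() {
  if (!exists("mols", .tr_mol_env)) {
    assign("mols", smiles_to_mol(c(
      methane = "C",
      ethane = "CC",
      butane = "CCCC",
      benzene = "c1ccccc1",
      toluene = "Cc1ccccc1",
      phenol = "Oc1ccccc1",
      pyridine = "c1ccncc1",
      naphthalene = "c1ccc2ccccc2c1",
      anthracene = "c1ccc2cc3ccccc3cc2c1",
      biphenyl = "c1ccccc1-c1ccccc1",
      spiro = "C1CCC2(CC1)CCCC2",
      indole = "c1ccc2[nH]ccc2c1",
      anthraquinone = "O=C1c2ccccc2C(=O)c2ccccc21",
      benzoic_acid = "OC(=O)c1ccccc1",
      cyproheptadine = "CN1CCC(=C2c3ccccc3C=Cc3ccccc32)CC1",
      norcyproheptadine = "C1CC(=C2c3ccccc3C=Cc3ccccc32)CCN1",
      cf4 = "FC(F)(F)F"
    )), .tr_mol_env)
  }
  get("mols", .tr_mol_env)
}

# one cached conformer per named molecule (seed fixed for the whole suite)
tr_confs <- function(names) {
  if (!exists("confs", .tr_mol_env))
    assign("confs", list(), .tr_mol_env)
  confs <- get("confs", .tr_mol_env)
  missing <- setdiff(names, names(confs))
  if (length(missing)) {
    new <- generate_conformers_batch(tr_mols()[missing], n = 1, seed = 42)
    confs <- c(confs, lapply(new, `[[`, 1))
    assign("confs", confs, .tr_mol_env)
  }
  confs[names]
}

# independent 3D numerical-integration oracle for the pairwise Gaussian
# overlap: integrates the product of the two summed densities on a cubic
# grid (0.1 A spacing by default)
grid_overlap_oracle <- function(xa, ra, xb, rb, h = 0.1, pad = 4.5) {
  p <- 2.7
  kappa <- pi * (3 * p / (4 * pi))^(2 / 3)
  lo <- pmin(apply(xa, 2, min), apply(xb, 2, min)) - pad
  hi <- pmax(apply(xa, 2, max), apply(xb, 2, max)) + pad
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  dens <- function(x, r) {
    out <- numeric(nrow(grid))
    for (i in seq_len(nrow(x))) {
      alpha <- kappa / r[i]^2
      d2 <- (grid[, 1] - x[i, 1])^2 + (grid[, 2] - x[i, 2])^2 +
        (grid[, 3] - x[i, 3])^2
      out <- out + p * exp(-alpha * d2)
    }
    out
  }
  sum(dens(xa, ra) * dens(xb, rb)) * h^3
}
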