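# Synthetic stand-in for the quantum-chemistry inputs of the workflow: a
# PM6-style descriptor table (26 descriptors per congener) and DFT-style
# adsorption energies from a configurable linear ground truth plus Gaussian
# noise.  The generator preserves exactly the structure the QSPR model
# assumes, so parameter recovery is a meaningful end-to-end check.

#' Parameters of the synthetic descriptor/energy generator
#'
#' Defaults emulate the study conditions: an additive total energy on an
#' atomic-unit-like scale, bond dipoles with the chlorine moment larger than
#' the bromine one (electronegativity Cl 3.16 > Br 2.96 on the Pauling
#' scale), idealized in-plane substituent directions respecting the skeleton
#' symmetry, and a linear adsorption-energy ground truth whose default
#' coefficients give energies spanning roughly -22 to +1 kcal/mol, negative
#' (favourable) for hydrogen-rich congeners and near zero for the fully
#' halogenated ones.  Noise defaults to 0.5 kcal/mol, inside the 0.3-0.7
#' kcal/mol error band quoted for the M06-2X functional.
#'
#' @param atom_energy Named numeric: per-atom energy increments for
#'   C, O, H, Cl, Br (a.u.-like arbitrary scale).
#' @param bond_dipole Named numeric, positive bond-dipole magnitudes for Cl
#'   and Br (debye-like units), measured relative to C-H (hydrogen
#'   contributes zero).  Must satisfy `Cl > Br`.
#' @param position_vectors 8 x 2 matrix of unit-length in-plane C-X bond
#'   directions per position, rows ordered (1,2,3,4,6,7,8,9), columns (x, y);
#'   x is the long molecular axis through the ring oxygens, y the short
#'   in-plane axis.  The default uses the idealized +-30/+-90 degree
#'   geometry and is equivariant under the skeleton symmetry group.
#' @param true_coefficients Named numeric of length 5: intercept and
#'   coefficients on `nH`, `TE`, `Dx`, `Dy` in the adsorption-energy ground
#'   truth (kcal/mol per descriptor unit).
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   adsorption energies (kcal/mol).
#' @param nuisance_cor Correlation in [0, 1) between each nuisance descriptor
#'   and one of the four informative descriptors (0 = independent noise).
#' @param n_nuisance Number of nuisance descriptors (default 22, for a table
#'   of 26 descriptors in total).
#' @param seed Integer seed for all randomness in the generator.
#' @return Object of class `generator_params` (a list).
#' @export
generator_params <- function(atom_energy = c(C = -38, O = -75, H = -0.5,
                                             Cl = -460, Br = -2574),
                             bond_dipole = c(Cl = 1.6, Br = 1.2),
                             position_vectors = default_position_vectors(),
                             true_coefficients = c(intercept = 1.5,
                                                   nH = -2.9,
                                                   TE = 5e-4,
                                                   Dx = 1.2,
                                                   Dy = -0.8),
                             noise_sd = 0.5,
                             nuisance_cor = 0,
                             n_nuisance = 22L,
                             seed = 2017L) {
  stopifnot(all(c("C", "O", "H", "Cl", "Br") %in% names(atom_energy)),
            all(c("Cl", "Br") %in% names(bond_dipole)),
            is.matrix(position_vectors), dim(position_vectors) == c(8L, 2L),
            length(true_coefficients) == 5L,
            noise_sd >= 0, nuisance_cor >= 0, nuisance_cor < 1)
  if (bond_dipole[["Cl"]] <= bond_dipole[["Br"]]) {
    stop("bond_dipole must satisfy Cl > Br (electronegativity ordering)")
  }
  names(true_coefficients) <- c("intercept", "nH", "TE", "Dx", "Dy")
  structure(list(atom_energy = atom_energy,
                 bond_dipole = bond_dipole,
                 position_vectors = position_vectors,
                 true_coefficients = true_coefficients,
                 noise_sd = noise_sd,
                 nuisance_cor = nuisance_cor,
                 n_nuisance = as.integer(n_nuisance),
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Idealized substituent bond directions
#'
#' Unit vectors of the in-plane C-X bond directions for positions
#' (1,2,3,4,6,7,8,9) on an idealized planar skeleton: lateral positions
#' (2,3,7,8) point +-30 degrees off the long (x) axis, axial positions
#' (1,4,6,9) point along +-y.  Applying a symmetry-group permutation to the
#' rows equals applying the corresponding in-plane point-group operation
#' (mirror or rotation) to the vectors.
#'
#' @return 8 x 2 numeric matrix with rows `pos1..pos9`, columns `x`, `y`.
#' @export
default_position_vectors <- function() {
  s <- sqrt(3) / 2
  m <- rbind(
    pos1 = c(0, 1),
    pos2 = c(s, 0.5),
    pos3 = c(s, -0.5),
    pos4 = c(0, -1),
    pos6 = c(0, 1),
    pos7 = c(-s, 0.5),
    pos8 = c(-s, -0.5),
    pos9 = c(0, -1)
  )
  colnames(m) <- c("x", "y")
  m
}

#' Hydrogen count of a congener
#'
#' The model descriptor `#H`: 8 minus the number of halogen substituents.
#'
#' @inheritParams canonicalize
#' @return Integer in 0..8.
#' @export
count_hydrogens <- function(state) {
  .check_state(state)
  sum(state == "H")
}

#' Additive total energy of a congener
#'
#' Emulates the PM6 total-energy descriptor with a strictly additive atomic
#' model: 12 carbons, 2 oxygens, plus the per-substituent increments.  Depends
#' only on composition, hence is constant on symmetry orbits.
#'
#' @inheritParams canonicalize
#' @param params A [generator_params()] object.
#' @return Total energy (a.u.-like scale).
#' @export
total_energy <- function(state, params = generator_params()) {
  .check_state(state)
  a <- params$atom_energy
  12 * a[["C"]] + 2 * a[["O"]] +
    sum(state == "H") * a[["H"]] +
    sum(state == "Cl") * a[["Cl"]] +
    sum(state == "Br") * a[["Br"]]
}

#' In-plane dipole components of a congener
#'
#' Vector sum over substituted positions of the halogen bond-dipole magnitude
#' times the position's unit direction; hydrogens contribute nothing (bond
#' dipoles are referenced to C-H).  Returns the components along the long (x)
#' and short in-plane (y) molecular axes.
#'
#' @inheritParams total_energy
#' @return Named numeric `c(Dx = ..., Dy = ...)` (debye-like units).
#' @examples
#' dipole_components(rep("H", 8))  # c(0, 0): full symmetry
#' @export
dipole_components <- function(state, params = generator_params()) {
  .check_state(state)
  mu <- c(H = 0, params$bond_dipole)[state]
  d <- colSums(params$position_vectors * mu)
  c(Dx = unname(d[1L]), Dy = unname(d[2L]))
}

#' Generate the synthetic descriptor table
#'
#' One row per congener with the four informative descriptors (`nH`, `TE`,
#' `Dx`, `Dy`) computed from the substitution pattern, plus `n_nuisance`
#' seeded Gaussian nuisance descriptors (`d05`, `d06`, ...) with optional
#' correlation to the informative block.  Bit-reproducible for a fixed seed.
#'
#' @param congeners A [congener_table()] data frame (or any data frame with a
#'   `canonical_tuple` column).
#' @param params A [generator_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return `data.frame` with columns `index`, `name`, `nH`, `TE`, `Dx`, `Dy`,
#'   `d05` ... (26 descriptors in total with the defaults).
#' @export
generate_descriptor_table <- function(congeners, params = generator_params(),
                                      seed = params$seed) {
  if (!nrow(congeners)) stop("empty congener set")
  states <- congener_states(congeners)
  n <- nrow(states)
  nH <- rowSums(states == "H")
  nCl <- rowSums(states == "Cl")
  nBr <- rowSums(states == "Br")
  a <- params$atom_energy
  TE <- 12 * a[["C"]] + 2 * a[["O"]] +
    nH * a[["H"]] + nCl * a[["Cl"]] + nBr * a[["Br"]]
  mu <- c(H = 0, params$bond_dipole)
  M <- matrix(mu[states], n, 8L)
  Dx <- as.vector(M %*% params$position_vectors[, 1L])
  Dy <- as.vector(M %*% params$position_vectors[, 2L])
  tab <- data.frame(index = congeners$index, name = congeners$name,
                    nH = nH, TE = TE, Dx = Dx, Dy = Dy,
                    stringsAsFactors = FALSE)
  k <- params$n_nuisance
  if (k > 0L) {
    set.seed(seed)
    Z <- matrix(stats::rnorm(n * k), n, k)
    rho <- params$nuisance_cor
    if (rho > 0) {
      info <- scale(cbind(nH, TE, Dx, Dy))
      anchor <- info[, rep_len(1:4, k), drop = FALSE]
      Z <- rho * anchor + sqrt(1 - rho^2) * Z
    }
    colnames(Z) <- sprintf("d%02d", 5:(4 + k))
    tab <- cbind(tab, as.data.frame(Z))
  }
  tab
}

#' Descriptor column names of a descriptor table
#'
#' @param table A descriptor table.
#' @return Character vector: `nH`, `TE`, `Dx`, `Dy` plus the nuisance names.
#' @export
descriptor_names <- function(table) {
  setdiff(colnames(table), c("index", "name", "E_ads"))
}

#' Generate ground-truth adsorption energies
#'
#' Adsorption energy of each congener's fullerene complex, in kcal/mol:
#' `E_ads = c0 + c1*nH + c2*TE + c3*Dx + c4*Dy + noise`, with seeded Gaussian
#' noise of standard deviation `params$noise_sd`.  More negative values mean
#' more favourable adsorption.
#'
#' @param table Descriptor table from [generate_descriptor_table()].
#' @param params A [generator_params()] object.
#' @param seed Integer seed for the noise; defaults to `params$seed + 1` so
#'   noise is independent of the nuisance-descriptor draw.
#' @return `data.frame` with columns `congener_index`, `E_ads`, `provenance`.
#' @export
generate_adsorption_energies <- function(table, params = generator_params(),
                                         seed = params$seed + 1L) {
  cf <- params$true_coefficients
  mu <- cf[["intercept"]] + cf[["nH"]] * table$nH + cf[["TE"]] * table$TE +
    cf[["Dx"]] * table$Dx + cf[["Dy"]] * table$Dy
  eps <- 0
  if (params$noise_sd > 0) {
    set.seed(seed)
    eps <- stats::rnorm(nrow(table), 0, params$noise_sd)
  }
  data.frame(congener_index = table$index,
             E_ads = mu + eps,
             provenance = "ground_truth",
             stringsAsFactors = FALSE)
}

#' Read a user-supplied descriptor/energy table
#'
#' Loads a CSV obeying the package's descriptor-table header contract
#' (`index`, `name`, `nH`, `TE`, `Dx`, `Dy`, further descriptor columns, and
#' optionally `E_ads`), e.g. a table assembled from published supplementary
#' data, so the pipeline can run on real quantum-chemistry descriptors
#' instead of the synthetic generator.
#'
#' @param path CSV file path.
#' @return The table as a `data.frame`.
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("descriptor table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "nH", "TE", "Dx", "Dy")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    stop("descriptor table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}
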