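# Solvent-composition arithmetic: mol % water, wt % dissolved cellulose and
# the per-species atom bookkeeping that reproduces the simulation
# composition tables.

#' Species atom-count model
#'
#' Atoms per molecule for the TBPCl-water-cellulose system: TBP has 53 atoms
#' (P + 16 C + 36 H), chloride 1, water 3; a cellulose strand of `g` glycans
#' has `21 g + 3` atoms.
#'
#' @return list with `atoms_per_tbp`, `atoms_per_cl`, `atoms_per_water` and
#'   function `atoms_per_strand(g)`.
#' @export
species_atom_model <- function() {
  list(atoms_per_tbp = 53L, atoms_per_cl = 1L, atoms_per_water = 3L,
       atoms_per_strand = function(g) 21L * g + 3L)
}

#' Molecular masses (amu) of the species
#'
#' TBP cation, chloride, their ion pair, water, and the anhydroglucose
#' (glycan) residue C6H10O5.
#' @return named numeric vector.
#' @export
species_masses <- function() {
  m <- ELEMENT_MASSES
  tbp <- m["P"] + 16 * m["C"] + 36 * m["H"]
  c(TBP = unname(tbp), Cl = unname(m["Cl"]), TBPCl = unname(tbp + m["Cl"]),
    water = unname(m["O"] + 2 * m["H"]),
    glycan = unname(6 * m["C"] + 10 * m["H"] + 5 * m["O"]))
}

#' Mol percent water of a TBPCl-water mixture
#'
#' `100 * n_water / (n_water + n_tbpcl)`.
#'
#' @param n_water number of water molecules.
#' @param n_tbpcl number of TBPCl ion pairs.
#' @return percent in `[0, 100]`.
#' @examples
#' round(mol_percent_water(2616, 1530), 1)  # 63.1
#' @export
mol_percent_water <- function(n_water, n_tbpcl) {
  if (any(n_water + n_tbpcl <= 0)) stop("n_water + n_tbpcl must be positive")
  100 * n_water / (n_water + n_tbpcl)
}

#' Mol percent TBPCl (complement of mol percent water)
#' @inheritParams mol_percent_water
#' @return percent in `[0, 100]`.
#' @export
mol_percent_tbpcl <- function(n_water, n_tbpcl) {
  100 - mol_percent_water(n_water, n_tbpcl)
}

#' Weight percent dissolved cellulose
#'
#' `100 * m_dissolved / (m_dissolved + m_water + m_tbpcl)`.  The denominator
#' is the total mass of dissolved cellulose plus solvent; all masses in amu
#' (any common unit works).
#'
#' @param m_dissolved dissolved cellulose mass.
#' @param m_water total water mass.
#' @param m_tbpcl total TBPCl mass.
#' @return percent in `[0, 100]`.
#' @export
wt_percent_dissolved <- function(m_dissolved, m_water, m_tbpcl) {
  tot <- m_dissolved + m_water + m_tbpcl
  if (tot <= 0) stop("total mass must be positive")
  100 * m_dissolved / tot
}

#' Atom counts for a bundle + solvent composition
#'
#' @param n_strands,n_glycans bundle dimensions (0 strands for pure solvent).
#' @param n_tbpcl TBPCl ion pairs.
#' @param n_water water molecules.
#' @param model a [species_atom_model()].
#' @return named integer vector `cellulose_atoms`, `solvent_atoms`,
#'   `total_atoms`.
#' @examples
#' count_atoms(18, 12, 1530, 2616)  # 4590, 90468, 95058
#' @export
count_atoms <- function(n_strands, n_glycans, n_tbpcl, n_water,
                        model = species_atom_model()) {
  cell <- if (n_strands > 0) n_strands * model$atoms_per_strand(n_glycans) else 0L
  solv <- n_tbpcl * (model$atoms_per_tbp + model$atoms_per_cl) +
    n_water * model$atoms_per_water
  c(cellulose_atoms = as.integer(cell), solvent_atoms = as.integer(solv),
    total_atoms = as.integer(cell + solv))
}

#' Mass of a number of dissolved glycans
#'
#' @param n_dissolved_glycans count of glycans flagged dissolved.
#' @param glycan_mass anhydroglucose residue mass, amu (default C6H10O5).
#' @return mass in amu.
#' @export
dissolved_mass <- function(n_dissolved_glycans,
                           glycan_mass = species_masses()[["glycan"]]) {
  stopifnot(n_dissolved_glycans >= 0)
  n_dissolved_glycans * glycan_mass
}

#' Composition table for a set of solvent mixtures
#'
#' Reproduces the bundle composition bookkeeping (total / cellulose /
#' solvent atoms) for given molecule counts, with mol \% water rounded to one
#' decimal.
#'
#' @param n_tbpcl,n_water equal-length vectors of molecule counts.
#' @param n_strands,n_glycans bundle dimensions.
#' @return data.frame with columns `mol_pct_water`, `total_atoms`,
#'   `cellulose_atoms`, `solvent_atoms`, `n_cl`, `n_tbp`, `n_water`.
#' @export
composition_table <- function(n_tbpcl, n_water, n_strands, n_glycans) {
  stopifnot(length(n_tbpcl) == length(n_water))
  rows <- lapply(seq_along(n_tbpcl), function(i) {
    ct <- count_atoms(n_strands, n_glycans, n_tbpcl[i], n_water[i])
    data.frame(mol_pct_water = round(mol_percent_water(n_water[i], n_tbpcl[i]), 1),
               total_atoms = ct[["total_atoms"]],
               cellulose_atoms = ct[["cellulose_atoms"]],
               solvent_atoms = ct[["solvent_atoms"]],
               n_cl = n_tbpcl[i], n_tbp = n_tbpcl[i], n_water = n_water[i])
  })
  do.call(rbind, rows)
}
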