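# PDB topology + coordinate I/O.  Reading leans on bio3d's parser; writing
# emits standard fixed-width records (CRYST1 + ATOM + MODEL blocks).
#
# Conventions: cellulose residues are written as BGC with one chain letter
# per strand (recycled A..Z; a strand boundary is a chain change or a
# residue-number decrease) and resno = glycan number; solvent residues are
# TBP, CL and HOH on chain X with one residue per molecule.

RESNAME_SPECIES <- c(BGC = "cellulose", TBP = "TBP", CL = "Cl",
                     HOH = "water", WAT = "water", TIP = "water",
                     SPC = "water", TP3 = "water")

#' Write a topology + frame(s) to a PDB file
#'
#' Multi-frame input produces a multi-model PDB (MODEL/ENDMDL blocks); the
#' box is stored in a CRYST1 record.
#'
#' @param topology a [topology()].
#' @param frames a [frame()] or list of frames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, frames, path) {
  if (inherits(frames, "frame")) frames <- list(frames)
  at <- topology$atoms
  n <- nrow(at)
  resid <- character(n)
  chain <- character(n)
  resno <- integer(n)
  cell <- at$species == "cellulose"
  resid[cell] <- "BGC"
  chain[cell] <- LETTERS[(at$strand[cell] - 1L) %% 26L + 1L]
  resno[cell] <- at$glycan[cell]
  solv <- !cell
  resid[solv] <- c(TBP = "TBP", Cl = "CL", water = "HOH")[at$species[solv]]
  chain[solv] <- "X"
  resno[solv] <- (at$mol_id[solv] - 1L) %% 9999L + 1L

  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1]]$box
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  multi <- length(frames) > 1L
  eleno <- (seq_len(n) - 1L) %% 99999L + 1L
  name4 <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1, 4),
                  sprintf(" %-3s", at$name))
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    X <- frames[[m]]$coords
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      eleno, name4, resid, chain, resno, X[, 1], X[, 2], X[, 3], 1, 0,
      at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a topology (and first frame) from a PDB file
#'
#' Species assignment is by residue name (BGC cellulose, TBP, CL, HOH/WAT
#' water); unknown residue names raise a classification error.  Cellulose
#' strands are runs of constant chain id (a residue-number decrease also
#' starts a new strand) with resno as the glycan number; each solvent
#' residue is one molecule.  Bonds are reconstructed from the known
#' chemistry of the recognised residues when the atom ordering follows the
#' package's builder conventions (a warning is issued otherwise).
#'
#' @param path PDB file path.
#' @return list(topology, frame).
#' @export
read_topology <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  resup <- toupper(substr(a$resid, 1, 3))
  sp <- RESNAME_SPECIES[resup]
  if (anyNA(sp)) {
    bad <- unique(a$resid[is.na(sp)])
    stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  }
  n <- nrow(a)
  name <- a$elety
  element <- element_from_name(name)
  strand <- rep(NA_integer_, n)
  glycan <- rep(NA_integer_, n)
  mol_id <- rep(NA_integer_, n)

  cell <- which(sp == "cellulose")
  if (length(cell)) {
    ch <- a$chain[cell]
    rn <- a$resno[cell]
    new_strand <- c(TRUE, ch[-1] != ch[-length(ch)] | diff(rn) < 0)
    strand[cell] <- cumsum(new_strand)
    glycan[cell] <- rn
  }
  solv <- which(sp != "cellulose")
  if (length(solv)) {
    key <- paste(a$chain[solv], resup[solv], a$resno[solv])
    new_mol <- c(TRUE, key[-1] != key[-length(key)])
    mol_id[solv] <- cumsum(new_mol)
  }
  atoms <- data.frame(
    atom_id = seq_len(n), name = name, element = element,
    mass = unname(ELEMENT_MASSES[element]), charge = NA_real_,
    strand = strand, glycan = glycan, species = unname(sp),
    mol_id = mol_id, stringsAsFactors = FALSE
  )
  ng <- if (length(cell)) max(glycan[cell]) else 0L
  topo <- topology(atoms, rebuild_bonds(atoms), n_glycans = ng)

  box <- read_cryst1(path)
  X <- cbind(a$x, a$y, a$z)
  if (is.null(box)) box <- pmax(apply(X, 2, function(v) diff(range(v))), 1) + 50
  list(topology = topo, frame = frame(X, box, time = 0))
}

read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 200L), value = TRUE)
  if (!length(ln)) return(NULL)
  v <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
                    substr(ln[1], 25, 33)))
  if (anyNA(v) || any(v <= 0)) NULL else v
}

# Reconstruct covalent bonds from known residue chemistry.  Cellulose
# glycans must present the 21 template atom names in template order (plus
# the three chain-cap atoms); waters are any O + 2 H triple; TBP follows the
# builder template order.
rebuild_bonds <- function(atoms) {
  bonds <- list()
  tmpl_names <- rownames(glycan_template())
  tb <- glycan_template_bonds()
  warn <- FALSE

  cell <- which(atoms$species == "cellulose")
  if (length(cell)) {
    for (s in unique(atoms$strand[cell])) {
      si <- cell[atoms$strand[cell] == s]
      gs <- sort(unique(atoms$glycan[si]))
      o4_prev <- NA_integer_
      for (j in gs) {
        gi <- si[atoms$glycan[si] == j]
        core <- gi[atoms$name[gi] %in% tmpl_names]
        if (length(core) == 21L && all(atoms$name[core] == tmpl_names)) {
          bonds[[length(bonds) + 1L]] <- cbind(core[tb[, 1]], core[tb[, 2]])
          if (!is.na(o4_prev))
            bonds[[length(bonds) + 1L]] <- cbind(o4_prev, core[4L])
          o4_prev <- core[9L]
          caps <- gi[!(gi %in% core)]
          for (cp in caps) {
            nm <- atoms$name[cp]
            partner <- switch(nm,
                              O1 = core[4L],
                              HO1 = caps[atoms$name[caps] == "O1"][1],
                              HO4 = core[9L],
                              NA_integer_)
            if (!is.na(partner))
              bonds[[length(bonds) + 1L]] <- cbind(cp, partner)
            else warn <- TRUE
          }
        } else warn <- TRUE
      }
    }
  }
  for (sp in c("water", "TBP", "Cl")) {
    si <- which(atoms$species == sp)
    if (!length(si)) next
    for (m in unique(atoms$mol_id[si])) {
      mi <- si[atoms$mol_id[si] == m]
      if (sp == "water") {
        o <- mi[atoms$element[mi] == "O"]
        h <- mi[atoms$element[mi] == "H"]
        if (length(o) == 1L && length(h) == 2L)
          bonds[[length(bonds) + 1L]] <- cbind(o, h)
        else warn <- TRUE
      } else if (sp == "TBP") {
        tmpl <- tbp_template()
        if (length(mi) == 53L && all(atoms$name[mi] == tmpl$name))
          bonds[[length(bonds) + 1L]] <- mi[1] - 1L + tmpl$bonds
        else warn <- TRUE
      }
    }
  }
  if (warn)
    warning("some molecules did not match the builder atom ordering; ",
            "their bonds were not reconstructed")
  out <- do.call(rbind, bonds)
  if (is.null(out)) matrix(integer(), 0, 2) else out
}
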