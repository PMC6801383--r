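#' Molecule container with elements, coordinates, charges and bonds
#'
#' `mol3d` is the package's working representation of a single molecule:
#' parallel vectors of element symbols, Cartesian coordinates (Angstrom),
#' formal charges, and a bond table. Bonds are stored with `i < j` and an
#' integer order (1, 2, 3; 4 denotes aromatic as in SDF V2000).
#'
#' @param mol_id single string identifying the molecule.
#' @param elements character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom). May be all-zero before coordinate generation.
#' @param formal_charges integer vector of per-atom formal charges.
#' @param bonds integer matrix with columns `i`, `j`, `order`; zero rows
#'   allowed.
#' @return an object of class `mol3d`.
#' @export
mol3d <- function(mol_id, elements, coords, formal_charges = NULL,
                  bonds = NULL) {
  stopifnot(is.character(mol_id), length(mol_id) == 1L)
  n <- length(elements)
  coords <- as.matrix(coords)
  if (n == 0L) stop("empty molecule")
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching elements")
  if (is.null(formal_charges)) formal_charges <- integer(n)
  if (length(formal_charges) != n)
    stop("formal_charges length must match elements")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3L)
  bonds <- matrix(as.integer(bonds), ncol = ncol(bonds),
                  dimnames = list(NULL, c("i", "j", "order")[seq_len(ncol(bonds))]))
  if (ncol(bonds) == 2L) bonds <- cbind(bonds, order = rep(1L, nrow(bonds)))
  if (nrow(bonds) > 0L) {
    swap <- bonds[, 1L] > bonds[, 2L]
    if (any(swap)) bonds[swap, 1:2] <- bonds[swap, 2:1]
    if (any(bonds[, 1L] < 1L | bonds[, 2L] > n | bonds[, 1L] == bonds[, 2L]))
      stop("bond indices out of range")
    if (anyDuplicated(bonds[, 1:2, drop = FALSE]))
      stop("duplicate bonds")
  }
  structure(
    list(mol_id = mol_id, elements = as.character(elements),
         coords = unname(coords), formal_charges = as.integer(formal_charges),
         bonds = bonds),
    class = "mol3d"
  )
}

#' @export
print.mol3d <- function(x, ...) {
  cat(sprintf("<mol3d> %s: %d atoms (%s), %d bonds, net charge %+d\n",
              x$mol_id, length(x$elements),
              paste(names(sort(-table(x$elements))), collapse = ""),
              nrow(x$bonds), sum(x$formal_charges)))
  invisible(x)
}

# V2000 old-style charge code -> formal charge
.v2000_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Build a mol3d from a ChemmineR SDF object (one record).
.sdf_to_mol3d <- function(sdf, mol_id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charges <- .v2000_charge(ab[, 5L])
  # M CHG property lines override the atom-block charge column
  raw <- ChemmineR::sdf2str(sdf)
  chg_lines <- grep("^M  CHG", raw, value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(substring(ln, 7L)), "\\s+")[[1L]])
    k <- f[1L]
    for (e in seq_len(k)) {
      charges[f[2L * e]] <- f[2L * e + 1L]
    }
  }
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- matrix(integer(0), ncol = 3L)
  } else {
    bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]),
                   as.integer(bb[, 3L]))
  }
  mol3d(mol_id, elements, coords, charges, bonds)
}

#' Parse SMILES into a `mol3d` graph
#'
#' Converts a SMILES string through Open Babel, adding explicit hydrogens.
#' Coordinates are a flat 2D depiction layout (z = 0); use [wash()] to
#' generate 3D conformers.
#'
#' @param smiles single SMILES string.
#' @param mol_id identifier for the molecule (default: the SMILES itself).
#' @param layout2d if `TRUE` (default) compute a 2D depiction layout,
#'   otherwise leave coordinates at zero.
#' @return a [mol3d()] object.
#' @export
parse_smiles <- function(smiles, mol_id = smiles, layout2d = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  opts <- if (layout2d) {
    data.frame(names = c("h", "gen2d"), args = c("", ""))
  } else {
    data.frame(names = "h", args = "")
  }
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"),
                              options = opts),
    error = function(e) "")
  if (!nzchar(txt) || !grepl("V2000", txt))
    stop("unparseable SMILES: ", smiles)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  natoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
  if (isTRUE(natoms == 1L)) {
    # ChemmineR rejects single-atom records; build the mol3d directly
    at <- lines[5L]
    xyz <- as.numeric(c(substr(at, 1, 10), substr(at, 11, 20),
                        substr(at, 21, 30)))
    elem <- trimws(substr(at, 32, 34))
    chg <- 0L
    ml <- grep("^M  CHG", lines, value = TRUE)
    if (length(ml) > 0L) {
      f <- as.integer(strsplit(trimws(substring(ml[1L], 7L)), "\\s+")[[1L]])
      chg <- f[3L]
    }
    return(mol3d(mol_id, elem, matrix(xyz, 1L, 3L), chg))
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  .sdf_to_mol3d(sdfset[[1L]], mol_id)
}

#' Canonical SMILES via Open Babel
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where a string could
#'   not be parsed.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- vapply(smiles, function(s) {
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) "")
    res <- sub("[\t ].*$", "", sub("\n$", "", res))
    if (!nzchar(res)) NA_character_ else res
  }, character(1L))
  unname(out)
}

# Heavy (non-hydrogen) atom and carbon counts per SMILES, via Open Babel.
.atom_counts <- function(smiles) {
  m <- tryCatch(parse_smiles(smiles),
                error = function(e) NULL)
  if (is.null(m)) return(c(heavy = NA_integer_, carbon = NA_integer_))
  c(heavy = sum(m$elements != "H"), carbon = sum(m$elements == "C"))
}

#' Format molecules as SDF V2000 text
#'
#' Writes 3D coordinates, formal charges (atom-block column and `M  CHG`
#' lines) and optional named data fields.
#'
#' @param mols list of [mol3d()] objects.
#' @param path output file path.
#' @param fields optional data.frame of per-molecule data fields (one row
#'   per molecule); written as `> <name>` blocks.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, fields = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  rev_code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
                `-1` = 5L, `-2` = 6L, `-3` = 7L)
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    n <- length(m$elements)
    nb <- nrow(m$bonds)
    writeLines(c(m$mol_id, " molsnap          3D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    code <- rev_code[as.character(m$formal_charges)]
    code[is.na(code)] <- 0L
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       m$coords[, 1L], m$coords[, 2L], m$coords[, 3L],
                       m$elements, code), con)
    if (nb > 0L)
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         m$bonds[, 1L], m$bonds[, 2L], m$bonds[, 3L]), con)
    chg <- which(m$formal_charges != 0L)
    if (length(chg) > 0L) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8L))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp,
                                         m$formal_charges[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    if (!is.null(fields)) {
      for (nm in names(fields)) {
        writeLines(c(sprintf("> <%s>", nm), as.character(fields[[nm]][k]), ""),
                   con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read an SDF file into `mol3d` objects
#'
#' @param path SDF V2000 file.
#' @return named list with `mols` (list of [mol3d()]) and `fields`
#'   (data.frame of data fields, one row per molecule, or `NULL`).
#' @export
read_sdf_mols <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ids <- vapply(ChemmineR::SDFset2SDF(sdfset), function(s)
    ChemmineR::header(s)[[1L]], character(1L))
  mols <- lapply(seq_along(sdfset), function(i)
    .sdf_to_mol3d(sdfset[[i]], ids[i]))
  blocks <- lapply(seq_along(sdfset), function(i)
    ChemmineR::datablock(sdfset[[i]]))
  fields <- NULL
  if (length(blocks) > 0L && length(blocks[[1L]]) > 0L) {
    fields <- as.data.frame(do.call(rbind, blocks),
                            stringsAsFactors = FALSE)
  }
  list(mols = mols, fields = fields)
}
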