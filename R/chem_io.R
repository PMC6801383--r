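#' Percent activity from raw assay signals
#'
#' Normalises a compound-well signal against the plate's negative (DMSO)
#' and positive control medians:
#' `((v_compound - v_dmso) / (v_pos - v_dmso)) * 100`. Values are not
#' clamped; scores outside `[0, 100]` are possible for signals outside the
#' control range.
#'
#' @param v_compound numeric vector of compound-well signals.
#' @param v_dmso negative-control (DMSO) median signal.
#' @param v_pos positive-control median signal.
#' @return numeric vector of percent activities.
#' @export
percent_activity <- function(v_compound, v_dmso, v_pos) {
  if (isTRUE(all.equal(v_pos, v_dmso)))
    stop("degenerate controls: positive and DMSO signals are equal")
  (v_compound - v_dmso) / (v_pos - v_dmso) * 100
}

#' Classify an activity score
#'
#' Scores of 40-100 are active; 1-39 are inconclusive (mapped to inactive
#' in the default binary mode); exactly 0 is inactive.
#'
#' @param activity_score numeric vector in `[0, 100]`.
#' @param mode `"binary"` (default) collapses inconclusive to inactive;
#'   `"ternary"` keeps all three classes.
#' @return character vector of labels.
#' @export
assign_label <- function(activity_score, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  if (any(!is.finite(activity_score)) ||
      any(activity_score < 0 | activity_score > 100))
    stop("activity score must be within [0, 100]")
  out <- ifelse(activity_score >= 40, "active",
                ifelse(activity_score == 0, "inactive", "inconclusive"))
  if (mode == "binary") out[out == "inconclusive"] <- "inactive"
  out
}

#' Read a SMILES activity table
#'
#' Accepts CSV or TSV with header columns matching (case-insensitively)
#' an identifier (`id`, `record_id`, `cid`), a `smiles` column, and a
#' score column (`score`, `activity_score`, `activity`).
#'
#' @param path file path.
#' @return data.frame with columns `record_id`, `smiles`, `activity_score`.
#' @export
read_smiles_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1L]
    if (is.na(i)) stop("missing column: one of ", paste(cands, collapse = "/"))
    df[[i]]
  }
  out <- data.frame(
    record_id = as.character(pick(c("id", "record_id", "cid", "name"))),
    smiles = as.character(pick("smiles")),
    activity_score = suppressWarnings(
      as.numeric(pick(c("score", "activity_score", "activity")))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$record_id))
    stop("record_id values must be unique")
  out
}

# Largest-organic-fragment canonical key. Returns NA for unparseable input
# and "" for structures with no carbon in any fragment.
.structure_key <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return(NA_character_)
  counts <- t(vapply(frags, .atom_counts, c(heavy = 0L, carbon = 0L)))
  if (anyNA(counts)) return(NA_character_)
  organic <- counts[, "carbon"] > 0L
  if (!any(organic)) return("")
  keep <- which(organic)
  keep <- keep[order(-counts[keep, "heavy"], frags[keep])][1L]
  canonical_smiles(frags[keep])
}

#' Curate raw activity records into labeled molecule records
#'
#' Applies the dataset-hygiene rules used before model building: records
#' are keyed by the canonical SMILES of their largest organic fragment
#' (salts/solvents stripped); structures containing no carbon are dropped
#' as nonorganic; same-structure duplicates with consistent binary labels
#' collapse to one record (keeping all source ids, score = median); and
#' duplicates whose binary labels conflict are removed entirely, since
#' their activity is indeterminate.
#'
#' @param records data.frame with columns `record_id`, `smiles`,
#'   `activity_score` (see [read_smiles_table()]).
#' @return list with `records` (data.frame: `structure_key`, `smiles`,
#'   `activity_score`, `label`, `source_ids` list-column) and `report`
#'   (data.frame: `record_id`, `reason` for every dropped input record).
#' @export
curate <- function(records) {
  empty_rec <- data.frame(structure_key = character(0),
                          smiles = character(0),
                          activity_score = numeric(0),
                          label = character(0),
                          stringsAsFactors = FALSE)
  empty_rec$source_ids <- list()
  report <- data.frame(record_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(list(records = empty_rec, report = report))

  drop <- function(ids, reason) {
    report <<- rbind(report, data.frame(record_id = ids, reason = reason,
                                        stringsAsFactors = FALSE))
  }
  ok_score <- is.finite(records$activity_score) &
    records$activity_score >= 0 & records$activity_score <= 100
  if (any(!ok_score)) {
    drop(records$record_id[!ok_score], "indefinite activity score")
    records <- records[ok_score, , drop = FALSE]
  }
  keys <- vapply(records$smiles, .structure_key, character(1L))
  bad <- is.na(keys)
  if (any(bad)) {
    drop(records$record_id[bad], "unparseable structure")
    records <- records[!bad, , drop = FALSE]
    keys <- keys[!bad]
  }
  nonorg <- keys == ""
  if (any(nonorg)) {
    drop(records$record_id[nonorg], "nonorganic")
    records <- records[!nonorg, , drop = FALSE]
    keys <- keys[!nonorg]
  }
  if (nrow(records) == 0L) return(list(records = empty_rec, report = report))

  out <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    labs <- assign_label(records$activity_score[idx])
    if (length(unique(labs)) > 1L) {
      drop(records$record_id[idx], "conflicting label")
      next
    }
    rec <- data.frame(structure_key = key, smiles = key,
                      activity_score = stats::median(records$activity_score[idx]),
                      label = labs[1L], stringsAsFactors = FALSE)
    rec$source_ids <- list(records$record_id[idx])
    out[[length(out) + 1L]] <- rec
  }
  recs <- if (length(out)) do.call(rbind, out) else empty_rec
  rownames(recs) <- NULL
  list(records = recs, report = report)
}

#' Specify a structure-washing protocol
#'
#' A wash combines a protonation adjustment with a coordinate-generation
#' mode; an optional second stage chains another pair (applied to the
#' output of the first).
#'
#' @param protonation one of `"none"`, `"dominant"`, `"neutralize"`.
#' @param coordinates one of `"depict2d"`, `"rebuild3d"`, `"corina_like"`.
#' @param chained optional second `wash_spec` (without its own chain).
#' @param ph assay pH used by the `"dominant"` rule table (default 7).
#' @return an object of class `wash_spec`.
#' @export
wash_spec <- function(protonation = c("none", "dominant", "neutralize"),
                      coordinates = c("depict2d", "rebuild3d", "corina_like"),
                      chained = NULL, ph = 7) {
  protonation <- match.arg(protonation)
  coordinates <- match.arg(coordinates)
  if (!is.null(chained) && !inherits(chained, "wash_spec"))
    stop("chained must be a wash_spec")
  if (!is.numeric(ph) || ph <= 0) stop("ph must be positive")
  structure(list(protonation = protonation, coordinates = coordinates,
                 chained = chained, ph = ph), class = "wash_spec")
}

# Deterministic per-molecule seed: global seed XOR a string hash of the id,
# kept within the 31-bit non-negative integer range.
.mix_seed <- function(seed, mol_id) {
  h <- 0
  for (code in utf8ToInt(mol_id)) h <- (h * 31 + code) %% 2147483647
  bitwXor(as.integer(seed %% 2147483647), as.integer(h))
}

.neighbors <- function(mol) {
  n <- length(mol$elements)
  nb <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1L]; j <- mol$bonds[r, 2L]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# Maximum bond order incident to each atom (0 when unbonded).
.max_order <- function(mol) {
  n <- length(mol$elements)
  mo <- integer(n)
  if (nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds[r, 3L]
      mo[mol$bonds[r, 1L]] <- max(mo[mol$bonds[r, 1L]], o)
      mo[mol$bonds[r, 2L]] <- max(mo[mol$bonds[r, 2L]], o)
    }
  }
  mo
}

# Remove atom indices from a molecule, reindexing bonds.
.drop_atoms <- function(mol, idx) {
  if (length(idx) == 0L) return(mol)
  keep <- setdiff(seq_along(mol$elements), idx)
  remap <- integer(length(mol$elements))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    ok <- !(b[, 1L] %in% idx) & !(b[, 2L] %in% idx)
    b <- b[ok, , drop = FALSE]
    b[, 1L] <- remap[b[, 1L]]
    b[, 2L] <- remap[b[, 2L]]
  }
  mol3d(mol$mol_id, mol$elements[keep], mol$coords[keep, , drop = FALSE],
        mol$formal_charges[keep], b)
}

.add_hydrogen <- function(mol, to) {
  n <- length(mol$elements)
  mol3d(mol$mol_id, c(mol$elements, "H"),
        rbind(mol$coords, mol$coords[to, ] + c(0.5, 0.5, 0.5)),
        c(mol$formal_charges, 0L),
        rbind(mol$bonds, c(n + 1L, to, 1L)))
}

# Neutralize formal charges where valence rules permit: anions on C/N/O/S
# gain a hydrogen per unit charge; cations carrying hydrogens lose one per
# unit charge. Quaternary cations (no H to remove) are left charged.
.neutralize <- function(mol) {
  repeat {
    nb <- .neighbors(mol)
    anion <- which(mol$formal_charges < 0L &
                     mol$elements %in% c("C", "N", "O", "S", "P"))
    if (length(anion) > 0L) {
      a <- anion[1L]
      mol$formal_charges[a] <- mol$formal_charges[a] + 1L
      mol <- .add_hydrogen(mol, a)
      next
    }
    cation <- which(mol$formal_charges > 0L)
    done <- TRUE
    for (a in cation) {
      hs <- nb[[a]][mol$elements[nb[[a]]] == "H"]
      if (length(hs) > 0L) {
        mol$formal_charges[a] <- mol$formal_charges[a] - 1L
        mol <- .drop_atoms(mol, hs[1L])
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  mol
}

# Dominant protonation state at (approximately) the given pH via a small
# acid/base rule table: carboxylic/sulfonic acid O-H deprotonated, aliphatic
# amines (not amides, not aromatic) protonated. An approximation of a full
# pKa model; applied to the neutralized parent structure.
.dominant <- function(mol, ph = 7) {
  mol <- .neutralize(mol)
  if (ph < 5 || ph > 9) return(mol)  # rule table is calibrated near pH 7
  nb <- .neighbors(mol)
  ord <- mol$bonds[, 3L]
  has_double_O <- function(c_idx) {
    if (nrow(mol$bonds) == 0L) return(FALSE)
    hit <- (mol$bonds[, 1L] == c_idx | mol$bonds[, 2L] == c_idx) & ord == 2L
    any(vapply(which(hit), function(r) {
      other <- setdiff(mol$bonds[r, 1:2], c_idx)
      mol$elements[other] == "O"
    }, logical(1L)))
  }
  # acidic O-H: O single-bonded to a C or S that carries at least one =O
  acidic_h <- integer(0)
  for (o in which(mol$elements == "O" & mol$formal_charges == 0L)) {
    hs <- nb[[o]][mol$elements[nb[[o]]] == "H"]
    heavy <- nb[[o]][mol$elements[nb[[o]]] != "H"]
    if (length(hs) == 1L && length(heavy) == 1L &&
        mol$elements[heavy] %in% c("C", "S") && has_double_O(heavy)) {
      acidic_h <- c(acidic_h, hs[1L])
      mol$formal_charges[o] <- -1L
    }
  }
  if (length(acidic_h) > 0L) mol <- .drop_atoms(mol, acidic_h)
  # basic N: sp3 amine, all heavy neighbors carbon, none of them a carbonyl C
  nb <- .neighbors(mol)
  mo <- .max_order(mol)
  basic <- integer(0)
  for (a in which(mol$elements == "N" & mol$formal_charges == 0L)) {
    if (mo[a] > 1L) next                      # imine/nitrile/aromatic N
    heavy <- nb[[a]][mol$elements[nb[[a]]] != "H"]
    if (length(nb[[a]]) > 3L) next
    if (!all(mol$elements[heavy] == "C")) next
    if (any(vapply(heavy, has_double_O, logical(1L)))) next  # amide
    basic <- c(basic, a)
  }
  for (a in basic) {
    mol$formal_charges[a] <- 1L
    mol <- .add_hydrogen(mol, a)
  }
  mol
}

# Regenerate a 2D depiction layout for the (possibly protonation-modified)
# molecule through Open Babel.
.layout2d <- function(mol) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  write_sdf(list(mol), tf)
  txt <- ChemmineOB::convertFormat("SDF", "SDF", paste(
    c(readLines(tf), ""), collapse = "\n"),
    options = data.frame(names = "gen2d", args = ""))
  writeLines(txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  out <- .sdf_to_mol3d(sdfset[[1L]], mol$mol_id)
  out
}

#' Wash a structure: adjust protonation and generate coordinates
#'
#' Applies the selected protonation rule (`none`, `neutralize`,
#' `dominant`) followed by coordinate generation: `depict2d` (flat layout),
#' `rebuild3d` (seeded distance-geometry embedding), or `corina_like`
#' (seeded embedding plus force-field-style refinement, yielding exactly
#' one low-energy conformer per molecule). A chained spec applies its two
#' stages sequentially. The same `(smiles, spec, seed)` always yields
#' identical output; the effective per-molecule seed mixes the global seed
#' with a hash of `mol_id` so results are stable under library reordering.
#'
#' @param smiles SMILES string, or a [mol3d()] object.
#' @param spec a [wash_spec()].
#' @param seed integer global seed.
#' @param mol_id identifier (defaults to the SMILES string).
#' @return a [mol3d()] with updated charges and coordinates.
#' @export
wash <- function(smiles, spec = wash_spec(), seed = 1L, mol_id = NULL) {
  if (inherits(smiles, "mol3d")) {
    mol <- smiles
    if (!is.null(mol_id)) mol$mol_id <- mol_id
  } else {
    if (is.null(mol_id)) mol_id <- smiles
    mol <- parse_smiles(smiles, mol_id = mol_id)
  }
  stages <- list(spec)
  if (!is.null(spec$chained)) stages <- c(stages, list(spec$chained))
  for (st in stages) {
    mol <- switch(st$protonation,
                  none = mol,
                  neutralize = .neutralize(mol),
                  dominant = .dominant(mol, st$ph))
    mol <- switch(st$coordinates,
                  depict2d = .layout2d(mol),
                  rebuild3d = embed_molecule(mol, seed = .mix_seed(seed, mol$mol_id),
                                             refine = "light"),
                  corina_like = embed_molecule(mol, seed = .mix_seed(seed, mol$mol_id),
                                               refine = "full"))
  }
  mol
}
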