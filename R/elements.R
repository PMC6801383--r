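# Element property tables used by bond perception and rendering.
# Covalent radii: classic single-bond radii (Pauling-style), in Angstrom.
# Van der Waals radii: Bondi (1964) values, in Angstrom.
# Colors: conventional CPK element coloring (Jmol-style hex values).

.covalent_radii <- c(
  H = 0.37, B = 0.82, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
  Na = 1.54, Mg = 1.30, Si = 1.11, P = 1.06, S = 1.02, Cl = 0.99,
  K = 1.96, Ca = 1.74, Fe = 1.25, Zn = 1.31, Se = 1.16, Br = 1.14,
  I = 1.33
)

.vdw_radii <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  K = 2.75, Ca = 2.31, Fe = 2.00, Zn = 1.39, Se = 1.90, Br = 1.85,
  I = 1.98
)

# CPK colors as RGB triples in [0,1]
.cpk_colors <- rbind(
  H  = c(1.00, 1.00, 1.00),
  B  = c(1.00, 0.71, 0.71),
  C  = c(0.56, 0.56, 0.56),
  N  = c(0.19, 0.31, 0.97),
  O  = c(1.00, 0.05, 0.05),
  F  = c(0.56, 0.88, 0.31),
  Na = c(0.67, 0.36, 0.95),
  Mg = c(0.54, 1.00, 0.00),
  Si = c(0.94, 0.78, 0.63),
  P  = c(1.00, 0.50, 0.00),
  S  = c(1.00, 1.00, 0.19),
  Cl = c(0.12, 0.94, 0.12),
  K  = c(0.56, 0.25, 0.83),
  Ca = c(0.24, 1.00, 0.00),
  Fe = c(0.88, 0.40, 0.20),
  Zn = c(0.49, 0.50, 0.69),
  Se = c(1.00, 0.63, 0.00),
  Br = c(0.65, 0.16, 0.16),
  I  = c(0.58, 0.00, 0.58)
)

#' Look up covalent radii for element symbols
#'
#' @param elements character vector of element symbols (case-sensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return numeric vector of single-bond covalent radii in Angstrom.
#' @export
covalent_radius <- function(elements) {
  r <- .covalent_radii[elements]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Look up van der Waals radii for element symbols
#'
#' @inheritParams covalent_radius
#' @return numeric vector of Bondi van der Waals radii in Angstrom.
#' @export
vdw_radius <- function(elements) {
  r <- .vdw_radii[elements]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

#' CPK display colors for element symbols
#'
#' @inheritParams covalent_radius
#' @return numeric matrix with one row per element and columns R, G, B
#'   in `[0, 1]`.
#' @export
cpk_color <- function(elements) {
  idx <- match(elements, rownames(.cpk_colors))
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  m <- .cpk_colors[idx, , drop = FALSE]
  dimnames(m) <- list(elements, c("r", "g", "b"))
  m
}

# Default valence per element, used by the neutralize rule.
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
                      Si = 4, P = 3, S = 2, Cl = 1, Br = 1, I = 1)
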