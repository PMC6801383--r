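# Synthetic labeled molecule libraries and assay-plate signals with a known
# structure-label relationship, so every pipeline stage is testable without
# any external download.

# Scaffold cores: halogen-free, single-ring or acyclic, all organic.
# Concatenating an alkyl chain prefix keeps every SMILES valid.
.toy_cores <- c(
  "c1ccccc1",        # benzene
  "c1ccncc1",        # pyridine
  "c1ccco1",         # furan
  "c1cccs1",         # thiophene
  "C1CCCCC1",        # cyclohexane
  "C1CCCC1",         # cyclopentane
  "C(=O)O",          # carboxylic acid
  "C(=O)N",          # amide
  "CO",              # alcohol terminus
  "N",               # amine
  "C#N",             # nitrile
  "C=C",             # alkene
  "S",               # thioether
  "OC",              # methyl ether terminus
  "C(C)C"            # branched alkyl
)
# Two-ring cores for the ring-count rule.
.toy_cores_2ring <- c(
  "c1ccc2ccccc2c1",            # naphthalene
  "c1ccc(cc1)-c1ccccc1",       # biphenyl
  "C1CCC2(CC1)CCCCC2",         # spiro bicycloalkane
  "c1ccc2[nH]ccc2c1",          # indole
  "c1ccc2occc2c1"              # benzofuran
)
.toy_halogens <- c("F", "Cl", "Br")

# Additional structures exercised by curation/wash tests: charged species
# and one carbon-free (nonorganic) record.
.toy_extras <- c(
  acetate       = "CC(=O)[O-]",
  ammonium      = "CC[NH3+]",
  glycine_zwit  = "C(C(=O)[O-])[NH3+]",
  sulfate_salt  = "OS(=O)(=O)[O-].[Na+]",
  nonorganic    = "O=S(=O)(O)O"
)

#' Structure rules available to the toy library generator
#'
#' `halogen_present`: the molecule contains F, Cl, Br or I.
#' `ring_count_ge_2`: at least two rings (SSSR count via bond cycles).
#' `heavy_atoms_ge_k`: at least `k` non-hydrogen atoms (default 12).
#'
#' @param smiles character vector.
#' @param rule rule name.
#' @param k threshold for `heavy_atoms_ge_k`.
#' @return logical vector.
#' @export
structure_rule <- function(smiles,
                           rule = c("halogen_present", "ring_count_ge_2",
                                    "heavy_atoms_ge_k"), k = 12L) {
  rule <- match.arg(rule)
  vapply(smiles, function(s) {
    m <- parse_smiles(s)
    switch(rule,
           halogen_present = any(m$elements %in% c("F", "Cl", "Br", "I")),
           ring_count_ge_2 = (nrow(m$bonds) - length(m$elements) + 1L) >= 2L,
           heavy_atoms_ge_k = sum(m$elements != "H") >= k)
  }, logical(1L))
}

#' Generate a labeled toy molecule library
#'
#' Emits `n` parseable, structurally distinct SMILES built from shipped
#' scaffold cores with alkyl-chain substituents, such that exactly
#' `round(n * active_fraction)` satisfy the chosen structural rule.
#' Rule-satisfying molecules draw activity scores uniformly from 40-100,
#' the rest from 0-39, so the binary label is a deterministic function of
#' the structure; `label_noise` flips the score side for a seeded random
#' subset. The default 10.8% active fraction mirrors the class imbalance
#' of large nuclear-receptor screening libraries.
#'
#' @param n library size (>= 4).
#' @param active_fraction fraction of rule-satisfying molecules, in (0,1).
#' @param rule structural rule (see [structure_rule()]).
#' @param label_noise flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @param include_extras append a few charged/multi-component/nonorganic
#'   records (score 0) that exercise curation and washing; off by default.
#' @return data.frame with columns `record_id`, `smiles`,
#'   `activity_score` (the chem-io input format).
#' @export
make_toy_library <- function(n = 60L, active_fraction = 0.108,
                             rule = c("halogen_present", "ring_count_ge_2",
                                      "heavy_atoms_ge_k"),
                             label_noise = 0, seed = 1L,
                             include_extras = FALSE) {
  rule <- match.arg(rule)
  if (n < 4L) stop("n must be >= 4")
  if (active_fraction <= 0 || active_fraction >= 1)
    stop("active_fraction must be in (0,1)")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5)")
  n_active <- round(n * active_fraction)
  if (n_active < 1L || n_active >= n)
    stop("unsatisfiable spec: round(n * active_fraction) must be in [1, n-1]")
  set.seed(seed)

  chain <- function(len) strrep("C", len)
  build <- function(i, cores, prefix = "") {
    core <- cores[(i - 1L) %% length(cores) + 1L]
    len <- (i - 1L) %/% length(cores) + 1L
    paste0(prefix, chain(len), core)
  }
  gen <- switch(rule,
    halogen_present = list(
      active = function(i) build(i, .toy_cores,
                                 prefix = .toy_halogens[(i - 1L) %% 3L + 1L]),
      inactive = function(i) build(i, .toy_cores)),
    ring_count_ge_2 = list(
      active = function(i) build(i, .toy_cores_2ring),
      inactive = function(i) build(i, .toy_cores)),
    heavy_atoms_ge_k = list(
      active = function(i) paste0(strrep("C", 11L), build(i, .toy_cores)),
      inactive = function(i) build(i, c("CO", "N", "O", "C(=O)O", "C=C"))))

  smiles <- c(vapply(seq_len(n_active), gen$active, character(1L)),
              vapply(seq_len(n - n_active), gen$inactive, character(1L)))
  is_active <- c(rep(TRUE, n_active), rep(FALSE, n - n_active))
  sat <- structure_rule(smiles, rule)
  if (!identical(unname(sat), is_active))
    stop("unsatisfiable spec: n too large for rule '", rule,
         "' (generated structures cross the rule boundary)")
  if (anyDuplicated(canonical_smiles(smiles)))
    stop("unsatisfiable spec: n too large for rule '", rule,
         "' (scaffold space exhausted)")
  scores <- ifelse(is_active,
                   sample(40:100, n, replace = TRUE),
                   sample(0:39, n, replace = TRUE))
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    scores[flip] <- ifelse(is_active[flip],
                           sample(0:39, sum(flip), replace = TRUE),
                           sample(40:100, sum(flip), replace = TRUE))
  }
  out <- data.frame(record_id = sprintf("TOY%04d", seq_len(n)),
                    smiles = smiles, activity_score = scores,
                    stringsAsFactors = FALSE)
  if (include_extras) {
    out <- rbind(out, data.frame(
      record_id = paste0("EXTRA_", names(.toy_extras)),
      smiles = unname(.toy_extras),
      activity_score = 0, stringsAsFactors = FALSE))
  }
  out
}

#' Simulate assay-plate well signals with known percent activity
#'
#' Inverts the percent-activity normalisation to generate compound-well
#' signals: `v = v_dmso + p/100 * (v_pos - v_dmso) + noise`. With
#' `noise_sd = 0` the percent activities are recovered exactly (and the
#' output is seed-independent); otherwise recovery is unbiased in
#' expectation.
#'
#' @param v_dmso,v_pos control signals (must differ).
#' @param true_percents numeric vector of target percent activities.
#' @param noise_sd Gaussian noise standard deviation (signal units, >= 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return numeric vector of compound-well signals.
#' @export
make_plate <- function(v_dmso, v_pos, true_percents, noise_sd = 0,
                       seed = 1L) {
  if (isTRUE(all.equal(v_pos, v_dmso)))
    stop("degenerate controls: positive and DMSO signals are equal")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  v <- v_dmso + true_percents / 100 * (v_pos - v_dmso)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  v
}
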