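# Shared fixtures built in code at test time.

# A fixed 3D molecule (no chemistry engine needed): ethane-like geometry.
fixture_mol <- function(id = "fix1") {
  mol3d(id,
        elements = c("C", "C", "H", "H", "H", "H", "H", "H"),
        coords = rbind(
          c(0, 0, 0), c(1.54, 0, 0),
          c(-0.5, 1.0, 0), c(-0.5, -0.5, 0.9), c(-0.5, -0.5, -0.9),
          c(2.04, 1.0, 0), c(2.04, -0.5, 0.9), c(2.04, -0.5, -0.9)),
        bonds = cbind(c(1, 1, 1, 1, 2, 2, 2), c(2, 3, 4, 5, 6, 7, 8),
                      rep(1L, 7)))
}

# Deterministic per-image prediction table for evaluation tests.
fixture_predictions <- function(probs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%02d", seq_along(probs))
  data.frame(mol_id = ids, probability = probs, stringsAsFactors = FALSE)
}

# Brute-force AUC over all (active, inactive) pairs, ties counted 1/2.
oracle_auc <- function(scores, labels) {
  act <- scores[labels == "active"]
  ina <- scores[labels == "inactive"]
  tot <- 0
  for (a in act) for (b in ina)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(act) * length(ina))
}

# Brute-force metric formulas straight from the confusion counts.
oracle_metrics <- function(tp, fp, tn, fn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  list(sensitivity = sens, specificity = spec, bac = (sens + spec) / 2,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = prec, recall = sens,
       f_value = 2 * sens * prec / (sens + prec),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# Build a score/label vector realising exact confusion counts at cut 0.5.
scores_for_counts <- function(tp, fp, tn, fn) {
  list(scores = c(rep(0.9, tp), rep(0.9, fp), rep(0.1, tn), rep(0.1, fn)),
       labels = c(rep("active", tp), rep("inactive", fp),
                  rep("inactive", tn), rep("active", fn)))
}
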