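#' Run the full snapshot QSAR pipeline on a record table
#'
#' End-to-end convenience driver: curate the records, wash each molecule
#' (protonation + seeded 3D conformer), render ball-and-stick snapshots
#' over the rotation grid, split molecules (stratified, molecule-level)
#' into train/validation/test, train the reference image classifier,
#' predict per-image probabilities on every split, aggregate to molecule
#' scores by median, select the cutoff on the validation set by the
#' Youden index, and evaluate on the held-out test set.
#'
#' @param records data.frame with `record_id`, `smiles`, `activity_score`
#'   (e.g. from [make_toy_library()] or [read_smiles_table()]).
#' @param outdir directory for rendered snapshots.
#' @param wash wash protocol, a [wash_spec()].
#' @param params a [render_params()].
#' @param ratio train:val:test ratio (see [split_ratio()]).
#' @param config a [training_config()].
#' @param seed integer master seed for washing, splitting and training.
#' @param permute if `TRUE`, labels are randomly permuted across molecules
#'   before splitting/training (the permutation-test negative control).
#' @return list with `metrics` (test-set `metrics_bundle`), `val_metrics`,
#'   `threshold`, `model`, `assignment`, `manifest`, `scores` (test
#'   molecule scores), `curated`.
#' @export
run_snapshot_pipeline <- function(records, outdir,
                                  wash = wash_spec("neutralize", "corina_like"),
                                  params = render_params(),
                                  ratio = "1:1:1",
                                  config = training_config(),
                                  seed = 1L, permute = FALSE) {
  cur <- curate(records)
  mols_df <- cur$records
  if (nrow(mols_df) < sum(split_ratio(ratio)))
    stop("too few curated molecules for the requested split")
  labels <- mols_df$label
  if (permute) labels <- permute_labels(labels, seed = seed + 101L)
  mol_ids <- sprintf("M%04d", seq_len(nrow(mols_df)))

  mols <- vector("list", nrow(mols_df))
  for (k in seq_len(nrow(mols_df)))
    mols[[k]] <- wash(mols_df$smiles[k], spec = wash, seed = seed,
                      mol_id = mol_ids[k])

  manifest <- snap_dataset(mols, labels = labels, params = params,
                           outdir = outdir)
  assignment <- split_molecules(mol_ids, ratio, seed = seed,
                                labels = labels)
  manifest <- attach_images(assignment, manifest)

  sets <- lapply(c(train = "train", val = "val", test = "test"),
                 function(s) load_images(
                   manifest[manifest$split == s, , drop = FALSE],
                   size = config$input_size))
  model <- train_image_classifier(sets$train, sets$val, config)

  label_map <- stats::setNames(labels, mol_ids)
  pred_val <- predict_images(model, sets$val)
  pred_test <- predict_images(model, sets$test)
  val_scores <- aggregate_median(pred_val)
  threshold <- select_cutoff(val_scores$score,
                             unname(label_map[val_scores$mol_id]))
  val_metrics <- confusion_metrics(val_scores$score,
                                   unname(label_map[val_scores$mol_id]),
                                   threshold)
  test_scores <- aggregate_median(pred_test)
  metrics <- confusion_metrics(test_scores$score,
                               unname(label_map[test_scores$mol_id]),
                               threshold)
  list(metrics = metrics, val_metrics = val_metrics, threshold = threshold,
       model = model, assignment = assignment, manifest = manifest,
       scores = test_scores, curated = cur)
}
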