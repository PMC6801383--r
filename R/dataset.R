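#' Parse a "train:val:test" ratio string
#'
#' @param x character like `"26:26:1"`, or a numeric length-3 vector.
#' @return named integer vector `c(train, val, test)`.
#' @export
split_ratio <- function(x) {
  if (is.character(x)) x <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (length(x) != 3L || any(!is.finite(x)) || any(x < 1) ||
      any(x != round(x)))
    stop("ratio must be three positive integers, e.g. \"26:26:1\"")
  stats::setNames(as.integer(x), c("train", "val", "test"))
}

# Largest-remainder apportionment of n into parts proportional to weights.
.apportion <- function(n, weights) {
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign molecules to train/validation/test splits
#'
#' Molecules are shuffled with the seed and apportioned to the three
#' splits by largest-remainder rounding of the ratio. When labels are
#' supplied (the default workflow), the split is stratified: each class is
#' apportioned separately in proportion to the split sizes, so every
#' split's active fraction matches the global fraction within the rounding
#' of one molecule. All images of a molecule inherit its split downstream,
#' so no structure ever straddles splits.
#'
#' @param mol_ids character vector of unique molecule identifiers.
#' @param ratio a [split_ratio()] (or string / numeric accepted by it).
#' @param seed integer seed.
#' @param labels optional character vector parallel to `mol_ids`; when
#'   given, stratified assignment is used.
#' @return named character vector: `mol_id` -> `"train"|"val"|"test"`.
#' @export
split_molecules <- function(mol_ids, ratio, seed = 1L, labels = NULL) {
  ratio <- split_ratio(ratio)
  n <- length(mol_ids)
  if (anyDuplicated(mol_ids)) stop("mol_ids must be unique")
  if (n < sum(ratio))
    stop("need at least ", sum(ratio), " molecules for ratio ",
         paste(ratio, collapse = ":"), "; got ", n)
  sizes <- .apportion(n, ratio)
  assignment <- stats::setNames(rep(NA_character_, n), mol_ids)
  set.seed(seed)
  if (is.null(labels)) {
    perm <- sample(mol_ids)
    assignment[perm] <- rep(names(ratio), times = sizes)
  } else {
    stopifnot(length(labels) == n)
    remaining <- sizes
    for (cls in sort(unique(labels))) {
      ids <- mol_ids[labels == cls]
      take <- .apportion(length(ids), pmax(sizes, 1e-9))
      # never exceed what is left in a split
      over <- take > remaining
      while (any(over)) {
        excess <- sum(take[over] - remaining[over])
        take[over] <- remaining[over]
        room <- which(!over & take < remaining)
        for (r in room) {
          add <- min(excess, remaining[r] - take[r])
          take[r] <- take[r] + add
          excess <- excess - add
          if (excess == 0) break
        }
        over <- take > remaining
        if (excess > 0 && !any(take < remaining)) break
      }
      perm <- sample(ids)
      assignment[perm] <- rep(names(ratio), times = take)
      remaining <- remaining - take
    }
  }
  assignment
}

#' Attach manifest images to a split assignment
#'
#' Every image inherits the split of its molecule; a manifest row whose
#' molecule is missing from the assignment is an error (it would silently
#' leak data otherwise).
#'
#' @param assignment named vector from [split_molecules()].
#' @param manifest data.frame from [snap_dataset()].
#' @return the manifest with an added `split` column.
#' @export
attach_images <- function(assignment, manifest) {
  orphan <- setdiff(unique(manifest$mol_id), names(assignment))
  if (length(orphan) > 0L)
    stop("manifest molecules missing from assignment: ",
         paste(orphan, collapse = ", "))
  manifest$split <- unname(assignment[manifest$mol_id])
  manifest
}

#' Randomly permute activity labels (permutation-test control)
#'
#' Reassigns the existing multiset of labels uniformly at random across
#' molecules, leaving structures untouched. Used as the negative control:
#' a classifier trained on permuted labels should perform at chance.
#'
#' @param labels character vector of labels.
#' @param seed integer seed.
#' @return permuted label vector of the same multiset.
#' @export
permute_labels <- function(labels, seed = 1L) {
  if (length(labels) == 0L) stop("nonempty input required")
  set.seed(seed)
  sample(labels)
}
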